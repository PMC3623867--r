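# Small models and objectives built in code for the unit tests.

# one-state exponential decay dx/dt = -k x, closed-form solution available
decay_model <- function(k = 0.5, times = seq(0, 5, length.out = 51)) {
  make_dynamical_model(
    id = "decay", kind = "ode", state_names = "x",
    param_space = parameter_set("k", k, lower = 0, upper = 2),
    default_initial_state = 1, default_times = times,
    rhs = function(t, y, p) -p[1] * y)
}

# two-state constant system dx/dt = 0
zero_model <- function() {
  make_dynamical_model(
    id = "zero", kind = "ode", state_names = c("u", "v"),
    param_space = parameter_set("p", 1, lower = 0, upper = 2),
    default_initial_state = c(2, -3), default_times = 0:10,
    rhs = function(t, y, p) c(0, 0))
}

# finite-time blow-up dx/dt = x^2, x(0) = 1 diverges at t = 1
blowup_model <- function() {
  make_dynamical_model(
    id = "blowup", kind = "ode", state_names = "x",
    param_space = parameter_set("p", 1, lower = 0, upper = 2),
    default_initial_state = 1, default_times = seq(0, 2, length.out = 21),
    rhs = function(t, y, p) y^2)
}

# diverging user map for the divergence-error contract
explode_map_model <- function() {
  make_dynamical_model(
    id = "explode", kind = "map", state_names = "x",
    param_space = parameter_set("g", 4, lower = 1, upper = 10),
    default_initial_state = 10, default_times = 0:50,
    map_step = function(x, p) p[1] * x)
}

# separable quadratic with known minimum, for optimizer sanity checks
quad_objective <- function(center) function(x) sum((x - center)^2)

quad_space <- function(d = 3, lo = -1, hi = 1) {
  parameter_set(paste0("x", seq_len(d)), rep(0, d),
                lower = rep(lo, d), upper = rep(hi, d))
}

random_molecule <- function(space, objective, ke_max = 5) {
  x <- runif(length(space$names), space$lower, space$upper)
  scro:::new_molecule(x, objective(x), runif(1, 0, ke_max))
}

total_energy <- function(...) {
  sum(vapply(list(...), function(m) m$pe + m$ke, numeric(1)))
}

# Newton refinement of an equilibrium of an ODE model (numerical Jacobian)
newton_equilibrium <- function(model, params, x0, iter = 50) {
  x <- as.numeric(x0)
  for (i in seq_len(iter)) {
    f <- ode_rhs(model, x, params)
    if (sqrt(sum(f^2)) < 1e-12) break
    J <- vapply(seq_along(x), function(j) {
      h <- max(1e-7, 1e-7 * abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      (ode_rhs(model, xp, params) - f) / h
    }, numeric(length(x)))
    x <- x - solve(J, f)
  }
  x
}
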