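#' Construct a dynamical model
#'
#' A dynamical model bundles everything an estimation run needs to know about
#' a system: the state names, the deterministic dynamics (an ODE right-hand
#' side or a discrete map step), a parameter-space template with box bounds,
#' and reproducible defaults (initial state and sampling grid).
#'
#' @param id short identifier used by the registry and the command line.
#' @param kind `"ode"` or `"map"`.
#' @param state_names character vector of state identifiers.
#' @param param_space a [parameter_set()] template (values = defaults).
#' @param default_initial_state numeric initial state, one entry per state.
#' @param default_times default sampling grid (strictly increasing; for maps
#'   the integer grid `0:n`).
#' @param rhs for ODE models, `function(t, state, pars)` returning the vector
#'   of derivatives (pars is the numeric parameter vector in template order).
#'   Ignored when a compiled right-hand side is supplied.
#' @param map_step for map models, `function(state, pars)` returning the next
#'   state (deterministic part only).
#' @param compiled optional list `list(func=, initfunc=)` naming a compiled
#'   derivative routine in this package's shared library; used by the fast
#'   path of [integrate_model()].
#' @param process_noise_sd optional per-state standard deviations of additive
#'   process noise for map models (`NULL` = none).
#' @param fixed optional named numeric vector of parameters held fixed (and
#'   removed from the free search space); see [fix_parameters()].
#' @return An object of class `dynamical_model`.
#' @seealso [benchmark_model()] for the built-in systems.
#' @export
make_dynamical_model <- function(id, kind = c("ode", "map"), state_names,
                                 param_space, default_initial_state,
                                 default_times, rhs = NULL, map_step = NULL,
                                 compiled = NULL, process_noise_sd = NULL,
                                 fixed = NULL) {
  kind <- match.arg(kind)
  s <- length(state_names)
  if (s < 1L) stop("at least one state is required")
  if (length(default_initial_state) != s)
    stop("default_initial_state must have one entry per state")
  if (any(diff(default_times) <= 0))
    stop("default_times must be strictly increasing")
  if (!inherits(param_space, "parameter_set"))
    stop("param_space must be a parameter_set")
  if (kind == "ode" && is.null(rhs) && is.null(compiled))
    stop("an ODE model needs rhs or a compiled derivative routine")
  if (kind == "map" && is.null(map_step) && id != "simulated_nonlinear")
    stop("a map model needs map_step")
  structure(
    list(id = id, kind = kind, state_names = as.character(state_names),
         param_space = param_space,
         default_initial_state = stats::setNames(
           as.numeric(default_initial_state), state_names),
         default_times = as.numeric(default_times),
         rhs = rhs, map_step = map_step, compiled = compiled,
         process_noise_sd = process_noise_sd, fixed = fixed),
    class = "dynamical_model"
  )
}

#' @export
print.dynamical_model <- function(x, ...) {
  cat("Dynamical model '", x$id, "' (", x$kind, ")\n", sep = "")
  cat("  states:    ", paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters:", length(x$param_space$names),
      if (length(x$fixed)) paste0(" free (", length(x$fixed), " fixed)"),
      "\n", sep = "")
  cat("  grid:      ", length(x$default_times), " points in [",
      format(min(x$default_times)), ", ", format(max(x$default_times)),
      "]\n", sep = "")
  invisible(x)
}

#' Built-in benchmark systems
#'
#' Returns one of the three benchmark models shipped with the package.
#'
#' `"simulated_nonlinear"` is a three-state discrete map with two unknown
#' parameters, `x1' = a*x1 + x2/(1+x2^2) + e1`, `x2' = b*x2*(1-x2) + e2`,
#' `x3' = x1*x2 + e3`, with true values `(a, b) = (0.8, 1.5)` and independent
#' zero-mean Gaussian process noise (sd 0.02 per state by default).  The
#' default orbit length is 800 steps from `x0 = (0.1, 0.1, 0.1)`.
#'
#' `"oscillator"` is a synthetic two-switch transcriptional oscillator in
#' which an RNA activator A turns switch Sw21 on (Hill threshold `K1`,
#' coefficient `n1`), Sw21 transcribes an RNA inhibitor B, B turns switch
#' Sw12 off (threshold `K2`, coefficient `n2`), and Sw12 transcribes A at
#' rate `v`; all relaxation rates are scaled to 1.  True parameters are
#' `(0.57 uM, 1.5, 2.5 uM, 6.5, 6.5)`.  The default grid spans two to three
#' periods of the oscillation.
#'
#' `"protease"` is a six-state DegS--DegU extracellular protease production
#' network (AprE, DegU, DegU~P, DegU~P dimer, mAprE, mDegU) with 17
#' mass-action/Michaelis parameters; defaults and bounds follow the
#' benchmark's published table.  Its kinetics span four decades of
#' timescale, so the default grid is two-phase: log-spaced points through
#' the sub-second phosphorylation/dimerisation equilibration, then uniform
#' coverage of the slow transcriptional transient to 400 s.
#'
#' @param id one of `"simulated_nonlinear"`, `"oscillator"`, `"protease"`.
#' @return A `dynamical_model`.
#' @examples
#' m <- benchmark_model("oscillator")
#' tr <- integrate_model(m)
#' head(tr$states)
#' @export
benchmark_model <- function(id = c("simulated_nonlinear", "oscillator",
                                   "protease")) {
  id <- match.arg(id)
  switch(id,
    simulated_nonlinear = make_dynamical_model(
      id = "simulated_nonlinear", kind = "map",
      state_names = c("x1", "x2", "x3"),
      param_space = parameter_set(c("a", "b"), c(0.8, 1.5),
                                  lower = c(0, 0), upper = c(1, 3)),
      default_initial_state = c(0.1, 0.1, 0.1),
      default_times = 0:800,
      process_noise_sd = c(0.02, 0.02, 0.02)
    ),
    oscillator = make_dynamical_model(
      id = "oscillator", kind = "ode",
      state_names = c("A", "B", "C", "D"),
      param_space = parameter_set(
        c("K1", "n1", "K2", "n2", "v"),
        c(0.57, 1.5, 2.5, 6.5, 6.5),
        lower = c(0.1, 0.5, 1.0, 3.0, 3.0),
        upper = c(1.2, 3.0, 5.0, 10.0, 10.0),
        units = c("uM", "", "uM", "", "")),
      default_initial_state = c(1, 1, 0.5, 0.5),
      default_times = seq(0, 20, length.out = 100),
      rhs = oscillator_rhs,
      compiled = list(func = "scro_deriv_osc", initfunc = "scro_init_osc")
    ),
    protease = make_dynamical_model(
      id = "protease", kind = "ode",
      state_names = c("AprE", "DegU", "DegUP", "Dim", "mAprE", "mDegU"),
      param_space = parameter_set(
        paste0("k", 1:17),
        c(0.04, 0.0004, 0.15, 0.04, 0.004, 0.025, 0.1, 7, 0.02, 12, 7,
          0.0099, 0.4, 0.004, 0.048, 7, 7),
        lower = c(0.02, 0.0002, 0.05, 0.02, 0.002, 0.010, 0.05, 5, 0.005,
                  10, 5, 0.0001, 0.2, 0.002, 0.02, 5, 5),
        upper = c(0.06, 0.0006, 0.30, 0.06, 0.006, 0.035, 0.20, 9, 0.04,
                  14, 9, 0.0100, 0.6, 0.006, 0.06, 9, 9),
        units = c("s-1", "s-1", "s-1", "s-1", "s-1", "s-1", "s-1", "s-1",
                  "#/s", "s-1", "s-1", "s-1", "#/s", "", "#/s", "s-1",
                  "s-1")),
      default_initial_state = c(0, 1, 0, 0, 0, 0),
      default_times = c(0, exp(seq(log(0.02), log(2), length.out = 29)),
                        seq(6, 400, length.out = 70)),
      rhs = protease_rhs,
      compiled = list(func = "scro_deriv_prot", initfunc = "scro_init_prot")
    )
  )
}

# Reference R implementations of the compiled derivatives.  Kept for
# user-level inspection and as the fallback when the shared library is not
# loaded; unit tests assert they agree with the compiled versions.
oscillator_rhs <- function(t, state, pars) {
  A <- max(state[1], 0); B <- max(state[2], 0)
  an <- A^pars[2]; kn <- pars[1]^pars[2]
  bn <- B^pars[4]; k2n <- pars[3]^pars[4]
  act <- if (an + kn > 0) an / (an + kn) else 0
  rep <- if (bn + k2n > 0) k2n / (bn + k2n) else 0
  c(pars[5] * state[4] - state[1],
    pars[5] * state[3] - state[2],
    act - state[3],
    rep - state[4])
}

protease_rhs <- function(t, state, k) {
  C <- max(state[3], 0); D <- max(state[4], 0)
  deph <- (k[16] + k[17]) * C
  c(k[7] * state[5] - k[4] * state[1],
    k[13] + k[1] * state[6] + deph - (k[10] + k[2]) * state[2],
    k[10] * state[2] - deph - k[3] * C - 2 * k[8] * C^2 + 2 * k[11] * D,
    k[8] * C^2 - (k[11] + k[5]) * D,
    k[15] * D / (k[14] + D) - k[12] * state[5],
    k[9] - k[6] * state[6])
}

#' Fix a subset of model parameters
#'
#' Returns a copy of the model in which the named parameters are pinned to
#' the given values and removed from the free search space.  Used to build
#' reduced ("ablated") model variants for model selection.
#'
#' @param model a `dynamical_model`.
#' @param fixed named numeric vector, e.g. `c(k9 = 0, k13 = 0)`.
#' @return A `dynamical_model` whose `param_space` contains only the free
#'   parameters.
#' @export
fix_parameters <- function(model, fixed) {
  if (is.null(names(fixed)) || any(!names(fixed) %in% model$param_space$names))
    stop("fixed must be a named vector of existing parameters")
  sp <- model$param_space
  keep <- !(sp$names %in% names(fixed))
  if (!any(keep)) stop("cannot fix every parameter")
  model$fixed <- c(model$fixed, fixed)
  model$param_space <- parameter_set(
    sp$names[keep], sp$values[keep], sp$lower[keep], sp$upper[keep],
    units = if (!is.null(sp$units)) sp$units[keep])
  model$full_space <- if (is.null(model$full_space)) sp else model$full_space
  model
}

# Expand a free parameter vector to the full vector the dynamics expect,
# filling in fixed entries.
expand_params <- function(model, theta) {
  if (is.null(model$fixed)) return(theta)
  full <- model$full_space
  out <- stats::setNames(numeric(length(full$names)), full$names)
  out[model$param_space$names] <- theta
  out[names(model$fixed)] <- model$fixed
  unname(out)
}

#' Simulate a discrete-map model
#'
#' Iterates the map from the model's initial state for `n_steps` steps,
#' optionally adding seeded zero-mean Gaussian process noise (the only
#' stochastic term: with `noise = FALSE` the orbit is fully deterministic).
#'
#' @param model a `dynamical_model` with `kind = "map"`.
#' @param params parameter values (`NULL` = model defaults, a numeric vector
#'   in template order, or a named vector / `parameter_set`).
#' @param n_steps number of iterations (>= 0); the returned trajectory has
#'   `n_steps + 1` rows, the first being the initial state.
#' @param seed integer seed for the process noise.
#' @param noise logical; disable to obtain the deterministic skeleton.
#' @param initial_state optional replacement initial state.
#' @return A `trajectory` (times `0:n_steps`, states matrix).
#' @export
simulate_map <- function(model, params = NULL, n_steps = NULL, seed = NULL,
                         noise = TRUE, initial_state = NULL) {
  if (model$kind != "map") stop("simulate_map needs a map model")
  if (is.null(n_steps)) n_steps <- length(model$default_times) - 1L
  n_steps <- as.integer(n_steps)
  if (n_steps < 0L) stop("n_steps must be >= 0")
  theta <- expand_params(model, param_values(model$param_space, params))
  x0 <- if (is.null(initial_state)) model$default_initial_state else
    as.numeric(initial_state)
  s <- length(model$state_names)
  e <- NULL
  if (noise && !is.null(model$process_noise_sd) && n_steps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    e <- matrix(stats::rnorm(n_steps * s), n_steps, s) *
      rep(model$process_noise_sd, each = n_steps)
  }
  states <- if (model$id == "simulated_nonlinear") {
    .Call(scro_sim_map, as.numeric(theta), as.numeric(x0), n_steps, e)
  } else {
    out <- matrix(NA_real_, n_steps + 1L, s)
    out[1L, ] <- x0
    x <- as.numeric(x0)
    for (i in seq_len(n_steps)) {
      x <- model$map_step(x, theta)
      if (!is.null(e)) x <- x + e[i, ]
      if (any(!is.finite(x)) || any(abs(x) > 1e8))
        stop("discrete map diverged at step ", i)
      out[i + 1L, ] <- x
    }
    out
  }
  colnames(states) <- model$state_names
  trajectory(0:n_steps, states)
}

#' Evaluate an ODE model's right-hand side
#'
#' Pure function of `(state, params)`; used for inspection and testing.
#'
#' @param model an ODE `dynamical_model`.
#' @param state numeric state vector (length = number of states).
#' @param params parameter values (see [simulate_map()] for accepted forms).
#' @param t time point (the built-in systems are autonomous).
#' @return Numeric vector of derivatives, one per state.
#' @export
ode_rhs <- function(model, state, params = NULL, t = 0) {
  if (model$kind != "ode") stop("ode_rhs needs an ODE model")
  if (length(state) != length(model$state_names))
    stop("state must have length ", length(model$state_names))
  if (any(!is.finite(state))) stop("state must be finite")
  theta <- expand_params(model, param_values(model$param_space, params))
  as.numeric(model$rhs(t, as.numeric(state), theta))
}

#' Integrate an ODE model over a sampling grid
#'
#' Solves the initial-value problem with `deSolve::ode` (lsoda,
#' adaptive-step error control; default tolerances `rtol = 1e-6`,
#' `atol = 1e-8`) and returns the solution sampled exactly at `times`.
#' The first element of `times` is the time of `initial_state`.
#'
#' @inheritParams ode_rhs
#' @param times strictly increasing sampling grid (default: the model grid).
#' @param initial_state state at `times[1]` (default: the model default).
#' @param rtol,atol solver tolerances.
#' @return A `trajectory`.
#' @export
integrate_model <- function(model, params = NULL, times = NULL,
                            initial_state = NULL, rtol = 1e-6, atol = 1e-8) {
  if (model$kind != "ode") stop("integrate_model needs an ODE model")
  if (is.null(times)) times <- model$default_times
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(initial_state)) initial_state <- model$default_initial_state
  theta <- expand_params(model, param_values(model$param_space, params))
  out <- integrate_raw(model, theta, times, as.numeric(initial_state),
                       rtol, atol)
  if (is.character(out)) stop("integration failed near t = ", out)
  colnames(out) <- model$state_names
  trajectory(times, out)
}

# Bare-metal integration used by both integrate_model and the objective hot
# loop: returns the state matrix, or a character scalar (the failing time)
# on solver failure.
integrate_raw <- function(model, theta, times, y0, rtol = 1e-6,
                          atol = 1e-8) {
  res <- if (!is.null(model$compiled)) {
    try(suppressWarnings(deSolve::ode(
      y = y0, times = times, func = model$compiled$func, parms = theta,
      dllname = "scro", initfunc = model$compiled$initfunc,
      rtol = rtol, atol = atol)), silent = TRUE)
  } else {
    f <- model$rhs
    try(suppressWarnings(deSolve::ode(
      y = y0, times = times,
      func = function(t, y, p) list(f(t, y, p)), parms = theta,
      rtol = rtol, atol = atol)), silent = TRUE)
  }
  if (inherits(res, "try-error")) return(format(times[1]))
  if (nrow(res) < length(times) || any(!is.finite(res)))
    return(format(res[nrow(res), 1]))
  unname(res[, -1, drop = FALSE])
}

#' Trajectory container
#'
#' @param times numeric vector of sampling instants.
#' @param states numeric matrix, one row per time, one column per state.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, states) {
  states <- as.matrix(states)
  if (nrow(states) != length(times))
    stop("states must have one row per time point")
  structure(list(times = as.numeric(times), states = states),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory: ", nrow(x$states), " time points, ",
      ncol(x$states), " states (", paste(colnames(x$states), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Read / write trajectories as CSV
#'
#' The on-disk dialect is a plain CSV with a `time` column followed by one
#' column per state.
#'
#' @param x a `trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `trajectory`.
#' @export
write_trajectory <- function(x, path) {
  df <- data.frame(time = x$times, x$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  trajectory(df$time, as.matrix(df[, -1, drop = FALSE]))
}
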