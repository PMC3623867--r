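#' Optimizer configuration
#'
#' Collects the tunable coefficients of the four population methods.  The
#' defaults follow the benchmark study conditions: 20 solutions and 100
#' iterations, firefly attractiveness `beta0 = 0.5` with light absorption
#' `mu = 0.01`, differential-evolution mutation factor `F = 2.5` with the
#' crossover coefficient clamped into `[0, 1]`.
#'
#' @param NP population size (>= 2).
#' @param iterations number of iterations (>= 1).
#' @param beta0 initial firefly attractiveness.
#' @param mu light absorption coefficient.
#' @param alpha firefly random-step scale, as a fraction of each
#'   coordinate's bound width.
#' @param alpha_decay geometric per-iteration decay of `alpha` (canonical
#'   firefly practice; set to 1 for a constant step).
#' @param loss_rate CRO kinetic-energy loss rate `LR` in `[0, 1]`: on an
#'   accepted on-wall collision the surviving kinetic energy is a uniform
#'   fraction `q ~ U(LR, 1)` of the energy surplus.
#' @param initial_ke initial kinetic energy per molecule (default 1, a
#'   modest tolerance budget; raise it on rugged landscapes where escaping
#'   local optima matters more than convergence depth).
#' @param de_F differential-evolution mutation factor.
#' @param de_CR differential-evolution crossover probability (values above
#'   1 are clamped to 1).
#' @param split_fraction fraction of the population assigned to the
#'   potential sub-population by the S-CRO initial selection step.
#' @param onwall_scale on-wall perturbation scale (fraction of bound width).
#' @param decomp_scale decomposition perturbation scale (fraction of bound
#'   width; large by design, the offspring should differ substantially from
#'   the parent).
#' @param onwall_decay optional geometric per-iteration decay of the
#'   on-wall/inter-collision perturbation scale (1 = constant, the
#'   canonical behaviour; values below 1 anneal the kernel from coarse to
#'   fine, useful on smooth objectives).
#' @param cro_step logical; internal switch disabling the evolutionary
#'   combinatorial step of S-CRO (used for ablation analysis).
#' @return A list of class `optimizer_control`.
#' @export
optimizer_control <- function(NP = 20, iterations = 100, beta0 = 0.5,
                              mu = 0.01, alpha = 0.2, alpha_decay = 0.97,
                              loss_rate = 0.2, initial_ke = 1,
                              de_F = 2.5, de_CR = 1, split_fraction = 0.5,
                              onwall_scale = 0.01, decomp_scale = 0.5,
                              onwall_decay = 1, cro_step = TRUE) {
  if (NP < 2) stop("NP must be >= 2")
  if (iterations < 1) stop("iterations must be >= 1")
  if (loss_rate < 0 || loss_rate > 1) stop("loss_rate must be in [0, 1]")
  if (split_fraction <= 0 || split_fraction > 1)
    stop("split_fraction must be in (0, 1]")
  structure(list(NP = as.integer(NP), iterations = as.integer(iterations),
                 beta0 = beta0, mu = mu, alpha = alpha,
                 alpha_decay = alpha_decay, loss_rate = loss_rate,
                 initial_ke = initial_ke, de_F = de_F,
                 de_CR = min(de_CR, 1), split_fraction = split_fraction,
                 onwall_scale = onwall_scale, decomp_scale = decomp_scale,
                 onwall_decay = onwall_decay, cro_step = isTRUE(cro_step)),
            class = "optimizer_control")
}

new_molecule <- function(position, pe, ke = 0) {
  list(position = position, pe = pe, ke = ke)
}

#' Initialise a population uniformly within the search space
#'
#' Each coordinate of each molecule is drawn uniformly between its lower
#' and upper bound; fitness (potential energy) is evaluated immediately and
#' every molecule receives the same initial kinetic energy.
#'
#' @param space a [parameter_set()] template supplying the bounds.
#' @param NP population size.
#' @param objective function mapping a parameter vector to a fitness value.
#' @param seed optional integer seed.
#' @param initial_ke kinetic energy per molecule; `NULL` resolves to
#'   0.2 times the mean finite initial fitness (the runner passes its
#'   configured value instead).
#' @return A list of class `population` with elements `molecules` (list of
#'   molecules: `position`, `pe`, `ke`), `global_best` (snapshot of the best
#'   molecule seen so far) and `initial_ke` (the resolved value).
#' @export
init_population <- function(space, NP, objective, seed = NULL,
                            initial_ke = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(space$names)
  mol <- vector("list", NP)
  for (i in seq_len(NP)) {
    x <- stats::runif(d, space$lower, space$upper)
    mol[[i]] <- new_molecule(x, objective(x))
  }
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  if (is.null(initial_ke)) {
    fin <- pe[is.finite(pe)]
    initial_ke <- if (length(fin)) 0.2 * mean(fin) else 1
  }
  for (i in seq_len(NP)) mol[[i]]$ke <- initial_ke
  best <- mol[[which.min(pe)]]
  structure(list(molecules = mol, global_best = best,
                 initial_ke = initial_ke),
            class = "population")
}

#' Firefly geometry and movement
#'
#' `fa_distance` is the Euclidean distance between two positions;
#' `fa_attractiveness` is the canonical distance-decaying attractiveness
#' `beta0 * exp(-mu * r^2)`; `fa_move` moves a solution towards a brighter
#' (better-fitness) neighbour and adds a bounded uniform perturbation
#' scaled by each coordinate's bound width, clamping the result into the
#' box.
#'
#' @param xi,xj numeric positions (xj the brighter neighbour).
#' @param r distance between two solutions.
#' @param beta0,mu attractiveness coefficients (see [optimizer_control()]).
#' @param beta attractiveness used for the move.
#' @param alpha random-step scale (fraction of bound width).
#' @param lower,upper box bounds.
#' @return `fa_distance`/`fa_attractiveness`: a scalar; `fa_move`: the new
#'   position.
#' @export
fa_distance <- function(xi, xj) sqrt(sum((xi - xj)^2))

#' @rdname fa_distance
#' @export
fa_attractiveness <- function(r, beta0, mu) beta0 * exp(-mu * r^2)

#' @rdname fa_distance
#' @export
fa_move <- function(xi, xj, beta, alpha, lower, upper) {
  d <- length(xi)
  step <- alpha * (stats::runif(d) - 0.5) * (upper - lower)
  clamp(xi + beta * (xj - xi) + step, lower, upper)
}

#' CRO reaction operators
#'
#' The four elementary reactions of chemical reaction optimization, acting
#' on molecules (`list(position, pe, ke)` with `pe` the potential energy =
#' fitness and `ke` the kinetic-energy tolerance budget).  Every operator
#' conserves or loses total energy: an accepted outcome never increases
#' `sum(pe + ke)` over the molecules involved.
#'
#' * `cro_on_wall`: a small single-molecule perturbation (Gaussian, scale
#'   `step_scale` of the bound width), accepted iff
#'   `pe_new <= pe + ke`; the surviving kinetic energy is
#'   `(pe + ke - pe_new) * q` with `q ~ U(loss_rate, 1)`.
#' * `cro_decompose`: splits one molecule into two strongly perturbed
#'   offspring, executed only when the parent's total energy covers both
#'   offspring potential energies; the surplus is split between the
#'   offspring by a uniform `k` and `1 - k`.
#' * `cro_inter_collision`: simultaneous on-wall-style perturbation of a
#'   pair, accepted iff the pair's total energy covers both new potential
#'   energies; the surplus is redistributed by a uniform share.
#' * `cro_synthesis`: combines a pair into one molecule (per-coordinate
#'   recombination), accepted under the same total-energy condition; the
#'   new kinetic energy is the entire surplus, hence large whenever the
#'   synthesised potential energy is close to the better parent's.
#'
#' @param m,m1,m2 molecules.
#' @param objective fitness function.
#' @param lower,upper box bounds.
#' @param loss_rate kinetic-energy loss rate `LR`.
#' @param step_scale perturbation scale as a fraction of the bound width.
#' @return A list with `accepted` (logical) and either `molecule` or
#'   `molecules` (the resulting molecule(s); on rejection the inputs are
#'   returned unchanged).
#' @export
cro_on_wall <- function(m, objective, lower, upper, loss_rate = 0.2,
                        step_scale = 0.01) {
  d <- length(m$position)
  cand <- clamp(m$position + stats::rnorm(d, 0, step_scale * (upper - lower)),
                lower, upper)
  pe_new <- objective(cand)
  if (pe_new <= m$pe + m$ke) {
    q <- stats::runif(1, loss_rate, 1)
    list(accepted = TRUE,
         molecule = new_molecule(cand, pe_new, (m$pe + m$ke - pe_new) * q))
  } else {
    list(accepted = FALSE, molecule = m)
  }
}

#' @rdname cro_on_wall
#' @export
cro_decompose <- function(m, objective, lower, upper, step_scale = 0.5) {
  d <- length(m$position)
  width <- upper - lower
  x1 <- clamp(m$position + stats::rnorm(d, 0, step_scale * width),
              lower, upper)
  x2 <- clamp(m$position + stats::rnorm(d, 0, step_scale * width),
              lower, upper)
  pe1 <- objective(x1); pe2 <- objective(x2)
  surplus <- m$pe + m$ke - pe1 - pe2
  if (!is.finite(surplus) || surplus < 0)
    return(list(accepted = FALSE, molecule = m))
  k <- stats::runif(1)
  list(accepted = TRUE,
       molecules = list(new_molecule(x1, pe1, surplus * k),
                        new_molecule(x2, pe2, surplus * (1 - k))))
}

#' @rdname cro_on_wall
#' @export
cro_inter_collision <- function(m1, m2, objective, lower, upper,
                                step_scale = 0.01) {
  d <- length(m1$position)
  width <- upper - lower
  x1 <- clamp(m1$position + stats::rnorm(d, 0, step_scale * width),
              lower, upper)
  x2 <- clamp(m2$position + stats::rnorm(d, 0, step_scale * width),
              lower, upper)
  pe1 <- objective(x1); pe2 <- objective(x2)
  total <- m1$pe + m1$ke + m2$pe + m2$ke
  surplus <- total - pe1 - pe2
  if (!is.finite(surplus) || surplus < 0)
    return(list(accepted = FALSE, molecules = list(m1, m2)))
  p <- stats::runif(1)
  list(accepted = TRUE,
       molecules = list(new_molecule(x1, pe1, surplus * p),
                        new_molecule(x2, pe2, surplus * (1 - p))))
}

#' @rdname cro_on_wall
#' @export
cro_synthesis <- function(m1, m2, objective, lower, upper) {
  d <- length(m1$position)
  pick <- stats::runif(d) < 0.5
  cand <- ifelse(pick, m1$position, m2$position)
  pe_new <- objective(cand)
  total <- m1$pe + m1$ke + m2$pe + m2$ke
  if (!is.finite(pe_new) || pe_new > total)
    return(list(accepted = FALSE, molecules = list(m1, m2)))
  list(accepted = TRUE, molecule = new_molecule(cand, pe_new, total - pe_new))
}

#' Map a uniform draw to a CRO reaction operator
#'
#' The selection rule of the hybrid's evolutionary combinatorial step:
#' draws at or below 0.33 select the on-wall collision, draws in
#' (0.33, 0.5) decomposition, draws in \[0.5, 0.7\] synthesis, and draws
#' above 0.7 the inter-molecular collision.
#'
#' @param r a uniform random number in `[0, 1]`.
#' @return One of `"on_wall"`, `"decomposition"`, `"synthesis"`,
#'   `"inter_collision"`.
#' @export
select_cro_operator <- function(r) {
  if (r <= 0.33) "on_wall"
  else if (r < 0.5) "decomposition"
  else if (r <= 0.7) "synthesis"
  else "inter_collision"
}

#' Sort and split a population into potential and weak sub-populations
#'
#' The S-CRO initial selection step: molecules are sorted by fitness
#' (ascending, ties kept in insertion order) and the best
#' `ceiling(split_fraction * NP)` form the potential sub-population.
#'
#' @param pop a `population` (or plain list of molecules).
#' @param split_fraction fraction in `(0, 1]`.
#' @return `list(potential = , weak = )`, two lists of molecules; every
#'   molecule appears in exactly one.
#' @export
split_population <- function(pop, split_fraction = 0.5) {
  mol <- if (inherits(pop, "population")) pop$molecules else pop
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  ord <- order(pe)                      # stable: ties by insertion order
  n1 <- ceiling(split_fraction * length(mol))
  list(potential = mol[ord[seq_len(n1)]],
       weak = if (n1 < length(mol)) mol[ord[(n1 + 1):length(mol)]] else
         list())
}

#' Best-guided random re-initialisation of a weak solution
#'
#' The S-CRO random update step: the new position is a stochastic
#' combination of the current position, the global best, and a fresh
#' uniform point in the box,
#' `x + r1 * (best - x) + r2 * (u - x)` with scalar `r1, r2 ~ U(0, 1)`,
#' clamped to the bounds.  With `r2 = 0` the move is a pure contraction
#' towards the best solution.
#'
#' @param m molecule (or bare position vector) to update.
#' @param best global best molecule (or position).
#' @param lower,upper box bounds.
#' @return The new position vector.
#' @export
random_update_weak <- function(m, best, lower, upper) {
  x <- if (is.list(m)) m$position else m
  b <- if (is.list(best)) best$position else best
  d <- length(x)
  r1 <- stats::runif(1); r2 <- stats::runif(1)
  u <- stats::runif(d, lower, upper)
  clamp(x + r1 * (b - x) + r2 * (u - x), lower, upper)
}

# ---- S-CRO internals -------------------------------------------------------

# Firefly sweep over a list of molecules (used on the potential
# sub-population and by the standalone FA).  Comparisons use the fitness
# snapshot taken at sweep start; positions update cumulatively and each
# molecule is re-evaluated once after its inner loop (canonical firefly
# bookkeeping).  Kinetic energies are left untouched.
fa_sweep <- function(mol, objective, lower, upper, beta0, mu, alpha,
                     per_move = FALSE, attractor = NULL) {
  pe0 <- vapply(mol, `[[`, numeric(1), "pe")
  n <- length(mol)
  for (i in seq_len(n)) {
    if (per_move) {
      # sequential variant used inside the hybrid: each attraction move is
      # evaluated immediately, so later comparisons see current fitness
      for (j in seq_len(n)) {
        if (j != i && mol[[j]]$pe < mol[[i]]$pe) {
          r <- fa_distance(mol[[i]]$position, mol[[j]]$position)
          beta <- fa_attractiveness(r, beta0, mu)
          xi <- fa_move(mol[[i]]$position, mol[[j]]$position, beta, alpha,
                        lower, upper)
          mol[[i]]$position <- xi
          mol[[i]]$pe <- objective(xi)
        }
      }
      # the population is drawn towards the current global best solution
      if (!is.null(attractor) && attractor$pe < mol[[i]]$pe) {
        r <- fa_distance(mol[[i]]$position, attractor$position)
        beta <- fa_attractiveness(r, beta0, mu)
        xi <- fa_move(mol[[i]]$position, attractor$position, beta, alpha,
                      lower, upper)
        mol[[i]]$position <- xi
        mol[[i]]$pe <- objective(xi)
      }
    } else {
      # canonical firefly bookkeeping: comparisons against the sweep-start
      # snapshot, one re-evaluation per member
      xi <- mol[[i]]$position
      moved <- FALSE
      for (j in seq_len(n)) {
        if (j != i && pe0[j] < pe0[i]) {
          r <- fa_distance(xi, mol[[j]]$position)
          beta <- fa_attractiveness(r, beta0, mu)
          xi <- fa_move(xi, mol[[j]]$position, beta, alpha, lower, upper)
          moved <- TRUE
        }
      }
      if (moved) {
        mol[[i]]$position <- xi
        mol[[i]]$pe <- objective(xi)
      }
    }
  }
  mol
}

# Evolutionary combinatorial pass over the potential sub-population: each
# surviving member draws one reaction; pair reactions take a uniformly
# chosen partner (excluding self).  Decomposition grows and synthesis
# shrinks the list; the size is repaired at merge time.
cro_sweep <- function(mol, objective, lower, upper, control) {
  i <- 1L
  while (i <= length(mol)) {
    op <- select_cro_operator(stats::runif(1))
    if (op %in% c("synthesis", "inter_collision") && length(mol) < 2)
      op <- "on_wall"
    if (op == "on_wall") {
      res <- cro_on_wall(mol[[i]], objective, lower, upper,
                         control$loss_rate, control$onwall_scale)
      mol[[i]] <- res$molecule
      i <- i + 1L
    } else if (op == "decomposition") {
      res <- cro_decompose(mol[[i]], objective, lower, upper,
                           control$decomp_scale)
      if (res$accepted) {
        mol[[i]] <- res$molecules[[1]]
        mol[[length(mol) + 1L]] <- res$molecules[[2]]
      }
      i <- i + 1L
    } else {
      j <- sample(setdiff(seq_along(mol), i), 1L)
      if (op == "inter_collision") {
        res <- cro_inter_collision(mol[[i]], mol[[j]], objective, lower,
                                   upper, control$onwall_scale)
        mol[[i]] <- res$molecules[[1]]
        mol[[j]] <- res$molecules[[2]]
        i <- i + 1L
      } else {
        res <- cro_synthesis(mol[[i]], mol[[j]], objective, lower, upper)
        if (res$accepted) {
          mol[[i]] <- res$molecule
          mol[[j]] <- NULL              # partner absorbed
          if (j < i) i <- i - 1L
        }
        i <- i + 1L
      }
    }
  }
  mol
}

weak_sweep <- function(mol, best, objective, lower, upper, initial_ke) {
  for (i in seq_along(mol)) {
    x <- random_update_weak(mol[[i]], best, lower, upper)
    mol[[i]] <- new_molecule(x, objective(x), initial_ke)
  }
  mol
}

# Restore the population to exactly NP molecules: drop the worst when too
# many, refill with best-guided random clones when too few.
repair_size <- function(mol, NP, best, objective, lower, upper,
                        initial_ke) {
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  if (length(mol) > NP) {
    mol <- mol[order(pe)[seq_len(NP)]]
  } else while (length(mol) < NP) {
    x <- random_update_weak(best, best, lower, upper)
    mol[[length(mol) + 1L]] <- new_molecule(x, objective(x), initial_ke)
  }
  mol
}

#' One iteration of the S-CRO hybrid
#'
#' Performs, in order: the initial selection step (sort by fitness and
#' split into potential and weak sub-populations), the neighbouring
#' improvement step (a firefly sweep over the potential sub-population)
#' followed by the evolutionary combinatorial step (one CRO reaction per
#' potential member), the random update step on the weak sub-population
#' (best-guided re-initialisation, kinetic energy re-endowed), and finally
#' the merge with population-size repair and a refresh of the global best.
#'
#' @param pop a `population` (from [init_population()]).
#' @param objective fitness function.
#' @param space a [parameter_set()] supplying the bounds.
#' @param control an [optimizer_control()].
#' @param alpha overriding firefly step scale for this iteration (`NULL` =
#'   `control$alpha`); the runner applies the geometric decay here.
#' @return The updated `population`.
#' @export
scro_iterate <- function(pop, objective, space, control = optimizer_control(),
                         alpha = NULL) {
  if (is.null(alpha)) alpha <- control$alpha
  lo <- space$lower; up <- space$upper
  parts <- split_population(pop, control$split_fraction)
  p1 <- fa_sweep(parts$potential, objective, lo, up, control$beta0,
                 control$mu, alpha, per_move = TRUE,
                 attractor = pop$global_best)
  if (control$cro_step) p1 <- cro_sweep(p1, objective, lo, up, control)
  p2 <- weak_sweep(parts$weak, pop$global_best, objective, lo, up,
                   pop$initial_ke)
  mol <- c(p1, p2)
  mol <- repair_size(mol, control$NP, pop$global_best, objective, lo, up,
                     pop$initial_ke)
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  ibest <- which.min(pe)
  if (pe[ibest] < pop$global_best$pe) pop$global_best <- mol[[ibest]]
  pop$molecules <- mol
  pop
}

# ---- standalone baselines --------------------------------------------------

fa_iterate <- function(pop, objective, space, control, alpha) {
  mol <- fa_sweep(pop$molecules, objective, space$lower, space$upper,
                  control$beta0, control$mu, alpha)
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  ibest <- which.min(pe)
  if (pe[ibest] < pop$global_best$pe) pop$global_best <- mol[[ibest]]
  pop$molecules <- mol
  pop
}

cro_iterate <- function(pop, objective, space, control) {
  mol <- cro_sweep(pop$molecules, objective, space$lower, space$upper,
                   control)
  mol <- repair_size(mol, control$NP, pop$global_best, objective,
                     space$lower, space$upper, pop$initial_ke)
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  ibest <- which.min(pe)
  if (pe[ibest] < pop$global_best$pe) pop$global_best <- mol[[ibest]]
  pop$molecules <- mol
  pop
}

de_iterate <- function(pop, objective, space, control) {
  mol <- pop$molecules
  n <- length(mol)
  d <- length(space$lower)
  for (i in seq_len(n)) {
    abc <- sample(setdiff(seq_len(n), i), 3L)
    mutant <- mol[[abc[1]]]$position +
      control$de_F * (mol[[abc[2]]]$position - mol[[abc[3]]]$position)
    jrand <- sample.int(d, 1L)
    cross <- stats::runif(d) < control$de_CR
    cross[jrand] <- TRUE
    trial <- ifelse(cross, mutant, mol[[i]]$position)
    trial <- clamp(trial, space$lower, space$upper)
    pe_new <- objective(trial)
    if (pe_new <= mol[[i]]$pe) mol[[i]] <- new_molecule(trial, pe_new,
                                                        mol[[i]]$ke)
  }
  pe <- vapply(mol, `[[`, numeric(1), "pe")
  ibest <- which.min(pe)
  if (pe[ibest] < pop$global_best$pe) pop$global_best <- mol[[ibest]]
  pop$molecules <- mol
  pop
}

#' Run a population optimizer on an arbitrary objective
#'
#' The low-level runner behind [fit_model()]: initialises a population in
#' the given search space and applies `control$iterations` iterations of
#' the selected algorithm.  All randomness flows from R's RNG, seeded once
#' at entry, so identical `(method, space, control, seed)` give identical
#' results.
#'
#' @param objective function mapping a parameter vector to a non-negative
#'   fitness (may return `Inf`).
#' @param space a [parameter_set()] search-space template.
#' @param method `"scro"`, `"de"`, `"fa"` or `"cro"`.
#' @param control an [optimizer_control()].
#' @param seed integer seed.
#' @return A list of class `optim_result`: `best_params` (a
#'   `parameter_set`), `best_fitness`, `trace` (best fitness after each
#'   iteration, non-increasing), `n_evaluations`, `method`, `seed`,
#'   `control`.
#' @export
run_optimizer <- function(objective, space, method = c("scro", "de", "fa",
                                                       "cro"),
                          control = optimizer_control(), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  counter <- new.env(parent = emptyenv())
  counter$n <- 0L
  obj <- function(x) {
    counter$n <- counter$n + 1L
    objective(x)
  }
  pop <- init_population(space, control$NP, obj,
                         initial_ke = control$initial_ke)
  trace <- numeric(control$iterations)
  alpha <- control$alpha
  ctl_it <- control
  for (it in seq_len(control$iterations)) {
    pop <- switch(method,
      scro = scro_iterate(pop, obj, space, ctl_it, alpha = alpha),
      fa = fa_iterate(pop, obj, space, ctl_it, alpha = alpha),
      cro = cro_iterate(pop, obj, space, ctl_it),
      de = de_iterate(pop, obj, space, ctl_it))
    alpha <- alpha * control$alpha_decay
    ctl_it$onwall_scale <- ctl_it$onwall_scale * control$onwall_decay
    trace[it] <- pop$global_best$pe
  }
  best <- pop$global_best
  structure(list(
    best_params = set_values(space, best$position),
    best_fitness = best$pe,
    trace = trace,
    n_evaluations = counter$n,
    method = method, seed = seed, control = control),
    class = "optim_result")
}

#' @export
print.optim_result <- function(x, ...) {
  cat("<", toupper(x$method), " run: ", x$control$NP, " solutions x ",
      x$control$iterations, " iterations, ", x$n_evaluations,
      " evaluations>\n", sep = "")
  cat("best fitness: ", format(x$best_fitness), "\n", sep = "")
  print(x$best_params)
  invisible(x)
}
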