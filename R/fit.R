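#' Fit a dynamical model to time-series data
#'
#' The package's main estimation front end: builds the nonlinear
#' least-squares objective for `(model, data)` and minimises it with one of
#' the four population metaheuristics.  Returns a fitted-model object with
#' the usual accessor methods (`coef`, `predict`, `residuals`, `fitted`,
#' `summary`, `plot`).
#'
#' @param model a `dynamical_model` (see [benchmark_model()],
#'   [make_dynamical_model()]).
#' @param data a `dyn_dataset` sampled on the model's simulation grid.
#' @param method optimisation algorithm: the S-CRO hybrid (default) or one
#'   of the baselines `"de"`, `"fa"`, `"cro"`.
#' @param control an [optimizer_control()]; see [scenario_control()] for
#'   the per-benchmark study settings.
#' @param seed integer seed (all randomness in the run derives from it).
#' @param initial_state optional replacement initial state for the
#'   simulations.
#' @return An object of class `dynfit`.
#' @examples
#' m <- benchmark_model("oscillator")
#' bench <- make_benchmark(m, noise = noise_spec(15), seed = 1)
#' fit <- fit_model(m, bench$data, control = optimizer_control(
#'   NP = 10, iterations = 10), seed = 1)
#' coef(fit)
#' @export
fit_model <- function(model, data, method = c("scro", "de", "fa", "cro"),
                      control = optimizer_control(), seed = NULL,
                      initial_state = NULL) {
  method <- match.arg(method)
  objective <- make_objective(model, data, initial_state)
  res <- run_optimizer(objective, model$param_space, method = method,
                       control = control, seed = seed)
  structure(list(model = model, data = data, result = res,
                 method = method, seed = seed,
                 initial_state = initial_state),
            class = "dynfit")
}

#' Study settings for the built-in benchmarks
#'
#' Returns the optimizer configuration used by the benchmark studies:
#' 20 solutions / 50 iterations for the discrete map, 20 solutions / 100
#' iterations with `beta0 = 0.5`, `mu = 0.01` for the oscillator, and 50
#' solutions / 200 iterations with `beta0 = 0.7`, `mu = 0.05` (DE
#' coefficients raised to `F = 3`) for the protease network.
#'
#' @param model_id a benchmark id (see [benchmark_model()]).
#' @param ... overrides passed on to [optimizer_control()].
#' @return An [optimizer_control()].
#' @export
scenario_control <- function(model_id, ...) {
  base <- switch(model_id,
    simulated_nonlinear = list(NP = 20, iterations = 50, beta0 = 0.5,
                               mu = 0.01),
    oscillator = list(NP = 20, iterations = 100, beta0 = 0.5, mu = 0.01),
    protease = list(NP = 50, iterations = 200, beta0 = 0.7, mu = 0.05,
                    de_F = 3, de_CR = 1),
    list())
  do.call(optimizer_control, utils::modifyList(base, list(...)))
}

#' @export
coef.dynfit <- function(object, ...) object$result$best_params$values

#' @export
print.dynfit <- function(x, ...) {
  cat("Dynamical model fit ('", x$model$id, "', method ",
      toupper(x$method), ")\n", sep = "")
  cat("  best fitness (SSE): ", format(x$result$best_fitness), " over ",
      sum(x$data$mask), " observed entries\n", sep = "")
  cat("  evaluations: ", x$result$n_evaluations, "; seed: ",
      format(x$seed), "\n", sep = "")
  print(x$result$best_params)
  invisible(x)
}

#' @export
summary.dynfit <- function(object, gamma = 0.95, ...) {
  rv <- object$data$noise_meta$real_variance
  idt <- if (!is.null(rv))
    identifiability_test(object, gamma = gamma)
  n <- sum(object$data$mask)
  d <- length(object$model$param_space$names)
  out <- list(fit = object,
              n_obs = n, n_par = d,
              mse = object$result$best_fitness / n,
              aic = aic_score(object$result$best_fitness, n, d),
              identifiability = idt)
  class(out) <- "summary.dynfit"
  out
}

#' @export
print.summary.dynfit <- function(x, ...) {
  print(x$fit)
  cat("\n  n = ", x$n_obs, " observed entries, D = ", x$n_par,
      " parameters\n", sep = "")
  cat("  MSE = ", format(x$mse), ",  AIC = ", format(x$aic), "\n", sep = "")
  if (!is.null(x$identifiability)) {
    cat("\n")
    print(x$identifiability)
  }
  invisible(x)
}

#' Predicted trajectory at the fitted parameters
#'
#' @param object a `dynfit`.
#' @param times optional alternative sampling grid (ODE models only).
#' @param ... unused.
#' @return A `trajectory`.
#' @export
predict.dynfit <- function(object, times = NULL, ...) {
  m <- object$model
  theta <- unname(object$result$best_params$values)
  if (m$kind == "map") {
    n <- length(object$data$times) - 1L
    simulate_map(m, theta, n_steps = n, noise = FALSE,
                 initial_state = object$initial_state)
  } else {
    integrate_model(m, theta,
                    times = if (is.null(times)) object$data$times else times,
                    initial_state = object$initial_state)
  }
}

#' @export
fitted.dynfit <- function(object, ...) {
  pred <- predict(object)
  pred$states[, colnames(object$data$observations), drop = FALSE]
}

#' Residuals of a fitted dynamical model
#'
#' Observed minus predicted over the masked-in entries, either stacked
#' (default) or as a per-state list.
#'
#' @param object a `dynfit`.
#' @param by_state return a named list with one residual vector per
#'   observed state.
#' @param ... unused.
#' @export
residuals.dynfit <- function(object, by_state = FALSE, ...) {
  r <- residual_vectors(predict(object), object$data)
  if (by_state) r else unlist(r, use.names = FALSE)
}

#' Convergence trace plot
#'
#' Best fitness value against iteration, on a log scale when the trace is
#' strictly positive.
#'
#' @param x a `dynfit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dynfit <- function(x, ...) {
  tr <- x$result$trace
  graphics::plot(seq_along(tr), tr, type = "s",
                 log = if (all(tr > 0)) "y" else "",
                 xlab = "iteration", ylab = "best fitness",
                 main = paste0(x$model$id, " (", toupper(x$method), ")"),
                 ...)
  invisible(x)
}

#' Simulate synthetic data from a fitted model
#'
#' Draws `nsim` replicate datasets from the fitted parameters, reusing the
#' noise specification recorded in the fitted data (percent level and
#' scheme).
#'
#' @param object a `dynfit`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return A list of `dyn_dataset`s.
#' @export
simulate.dynfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  meta <- object$data$noise_meta
  pct <- if (is.null(meta)) 0 else meta$percent
  sch <- if (is.null(meta)) "relative" else meta$scheme
  truth <- predict(object)
  seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  lapply(seeds, function(s)
    add_noise(truth, noise_spec(pct, sch, seed = s)))
}

#' Serialise an optimisation result to JSON
#'
#' Writes the estimated parameters, fitness, convergence trace, evaluation
#' count, seed and configuration, so a run can be archived or re-read by
#' the command-line tools.
#'
#' @param x a `dynfit` or `optim_result`.
#' @param path output file.
#' @export
write_result <- function(x, path) {
  res <- if (inherits(x, "dynfit")) x$result else x
  out <- list(
    model = if (inherits(x, "dynfit")) x$model$id,
    method = res$method,
    seed = res$seed,
    best_params = as.list(res$best_params$values),
    best_fitness = res$best_fitness,
    n_evaluations = res$n_evaluations,
    trace = res$trace,
    control = res$control[c("NP", "iterations", "beta0", "mu", "alpha",
                            "loss_rate", "de_F", "de_CR",
                            "split_fraction")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
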