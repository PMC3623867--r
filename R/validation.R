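#' Per-state residual vectors
#'
#' Observed minus predicted (`e = y_obs - y_model`) over the masked-in
#' entries of each observed state.  The sum of squares of all residuals is
#' exactly the [fitness()] of the prediction.
#'
#' @param prediction a `trajectory` on the data grid.
#' @param data a `dyn_dataset`.
#' @return Named list with one numeric vector per observed state.
#' @export
residual_vectors <- function(prediction, data) {
  obs_states <- colnames(data$observations)
  if (any(!obs_states %in% colnames(prediction$states)))
    stop("prediction lacks observed states")
  pred <- prediction$states[, obs_states, drop = FALSE]
  out <- lapply(seq_along(obs_states), function(s)
    (data$observations[, s] - pred[, s])[data$mask[, s]])
  names(out) <- obs_states
  out
}

#' Point estimate of the residual variance
#'
#' Unbiased sample variance of a residual vector (divisor `N - 1`).  By
#' default residuals are centred about their mean; `center = "zero"`
#' centres about zero instead, leaning on the zero-mean noise assumption
#' (the two differ at order mean(e)^2).
#'
#' @param e numeric residual vector (length >= 2).
#' @param center `"mean"` (default) or `"zero"`.
#' @return Non-negative scalar.
#' @export
variance_point <- function(e, center = c("mean", "zero")) {
  center <- match.arg(center)
  n <- length(e)
  if (n < 2) stop("need at least two residuals")
  mu <- if (center == "mean") mean(e) else 0
  sum((e - mu)^2) / (n - 1)
}

#' Chi-square confidence interval for a variance
#'
#' The standard two-sided interval
#' `[(N-1) s2 / chi2_{(1+gamma)/2, N-1}, (N-1) s2 / chi2_{(1-gamma)/2, N-1}]`
#' at confidence level `100 * gamma` percent.  It always contains the point
#' estimate, and its width shrinks to zero as `N` grows at fixed `s2`.
#'
#' @param s2 variance point estimate.
#' @param N sample size (>= 2).
#' @param gamma confidence level in (0, 1); 0.95 corresponds to a
#'   significance level of 0.05.
#' @return Numeric vector `c(lower, upper)`.
#' @export
variance_interval <- function(s2, N, gamma = 0.95) {
  if (N < 2) stop("need at least two residuals for an interval")
  if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1)")
  c(lower = (N - 1) * s2 / stats::qchisq((1 + gamma) / 2, N - 1),
    upper = (N - 1) * s2 / stats::qchisq((1 - gamma) / 2, N - 1))
}

#' Residual-variance test of practical identifiability
#'
#' For each observed state, compares a reference ("real") noise variance
#' with the chi-square confidence interval around the variance of the
#' fit's residuals.  If the real variance falls outside the interval for
#' any state, the model output could not plausibly have been generated by
#' the estimated parameter set at confidence level `100 * gamma` percent,
#' and the overall test fails (the per-state verdicts are AND-ed into one
#' Pass/Fail).
#'
#' For synthetic data the reference is the variance of the actually
#' injected noise sample, which [make_benchmark()] records in the dataset's
#' metadata; a theoretical noise variance can be supplied instead via
#' `real_variance`.
#'
#' @param object a `dynfit`, or a `dynamical_model` (then `params` is
#'   required).
#' @param data the dataset (taken from the fit when omitted).
#' @param params parameter values when `object` is a bare model.
#' @param real_variance named per-state reference variances (default: the
#'   dataset's recorded injected-noise variances).
#' @param gamma confidence level (default 0.95, i.e. significance 0.05).
#' @param initial_state optional initial state override.
#' @return An object of class `identifiability_test`: a data frame with
#'   columns `state`, `real_variance`, `variance_point`, `lower`, `upper`,
#'   `passed`, plus attributes `passed` (overall) and `gamma`.
#' @export
identifiability_test <- function(object, data = NULL, params = NULL,
                                 real_variance = NULL, gamma = 0.95,
                                 initial_state = NULL) {
  if (inherits(object, "dynfit")) {
    model <- object$model
    if (is.null(data)) data <- object$data
    pred <- predict(object)
  } else {
    model <- object
    if (is.null(data)) stop("data is required")
    if (is.null(params)) stop("params is required for a bare model")
    theta <- param_values(model$param_space, params)
    pred <- if (model$kind == "map")
      simulate_map(model, theta, n_steps = length(data$times) - 1L,
                   noise = FALSE, initial_state = initial_state)
    else
      integrate_model(model, theta, times = data$times,
                      initial_state = initial_state)
  }
  if (is.null(real_variance))
    real_variance <- data$noise_meta$real_variance
  if (is.null(real_variance))
    stop("no reference variance available; supply real_variance")
  res <- residual_vectors(pred, data)
  states <- names(res)
  rows <- lapply(states, function(s) {
    e <- res[[s]]
    s2 <- variance_point(e)
    ci <- variance_interval(s2, length(e), gamma)
    rv <- real_variance[[s]]
    data.frame(state = s, real_variance = rv, variance_point = s2,
               lower = ci[["lower"]], upper = ci[["upper"]],
               passed = rv >= ci[["lower"]] && rv <= ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("identifiability_test", "data.frame"),
            passed = all(out$passed), gamma = gamma)
}

#' @export
print.identifiability_test <- function(x, ...) {
  cat("Residual-variance identifiability test (gamma = ",
      attr(x, "gamma"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$real_variance <- signif(df$real_variance, 3)
  df$variance_point <- signif(df$variance_point, 3)
  df$interval <- sprintf("[%.3g, %.3g]", df$lower, df$upper)
  print(df[, c("state", "real_variance", "variance_point", "interval",
               "passed")], row.names = FALSE)
  cat("Overall: ", if (attr(x, "passed")) "Pass" else "Fail", "\n",
      sep = "")
  invisible(x)
}

#' Akaike information criterion from a least-squares fit
#'
#' `AIC = N * log(MSE) + 2 * D` with `MSE = best_fitness / N`, where `N` is
#' the number of observed entries and `D` the number of estimated
#' parameters.  A perfect fit (`MSE <= 0`) is floored at machine epsilon.
#' Constant-offset AIC variants shift every candidate equally, so the
#' model-selection verdict does not depend on the convention.
#'
#' @param best_fitness sum of squared residuals at the optimum.
#' @param n_obs number of observed data entries `N`.
#' @param n_par number of estimated parameters `D`.
#' @return Scalar AIC (smaller is better).
#' @export
aic_score <- function(best_fitness, n_obs, n_par) {
  if (best_fitness < 0) stop("best_fitness must be >= 0")
  if (n_obs < 1) stop("n_obs must be >= 1")
  mse <- max(best_fitness / n_obs, .Machine$double.eps)
  n_obs * log(mse) + 2 * n_par
}

#' Fit and compare candidate model structures on one dataset
#'
#' Refits every candidate on the same experimental data, runs the
#' residual-variance identifiability test for each, computes the AIC, and
#' declares the AIC-minimal candidate the winner (ties broken by
#' declaration order).
#'
#' @param candidates named list of `dynamical_model`s (e.g. an original
#'   model and an ablated variant built with [fix_parameters()]).
#' @param data the shared `dyn_dataset`.
#' @param method optimisation algorithm (see [fit_model()]).
#' @param control an [optimizer_control()].
#' @param seed integer seed; candidate `i` is fitted with `seed + i - 1`.
#' @param gamma confidence level of the variance test.
#' @param real_variance optional reference variances (default: recorded in
#'   the dataset metadata).
#' @return An object of class `model_selection`: a list with per-candidate
#'   entries (`fit`, `aic`, `variance_test`) and `winner`, the name of the
#'   AIC-minimal candidate.
#' @export
compare_models <- function(candidates, data, method = "scro",
                           control = optimizer_control(), seed = 1,
                           gamma = 0.95, real_variance = NULL) {
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be a named list of models")
  fits <- vector("list", length(candidates))
  names(fits) <- names(candidates)
  for (i in seq_along(candidates)) {
    m <- candidates[[i]]
    fit <- fit_model(m, data, method = method, control = control,
                     seed = seed + i - 1L)
    n <- sum(data$mask)
    fits[[i]] <- list(
      fit = fit,
      aic = aic_score(fit$result$best_fitness, n,
                      length(m$param_space$names)),
      variance_test = identifiability_test(fit, gamma = gamma,
                                           real_variance = real_variance))
  }
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  structure(list(candidates = fits, aic = aics,
                 winner = names(fits)[which.min(aics)]),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection (", length(x$candidates), " candidates)\n",
      sep = "")
  for (nm in names(x$candidates)) {
    cand <- x$candidates[[nm]]
    cat("\n-- ", nm, if (nm == x$winner) "  [winner]", "\n", sep = "")
    cat("AIC = ", format(cand$aic), "\n", sep = "")
    print(cand$variance_test)
  }
  invisible(x)
}
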