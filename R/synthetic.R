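#' Measurement-noise specification
#'
#' Describes the percent white Gaussian noise added to model predictions
#' when generating synthetic data.  The default `"relative"` scheme is
#' signal-proportional, `y * (1 + (percent/100) * z)` with `z` iid standard
#' normal; `"absolute"` scales the noise by each state's signal standard
#' deviation instead.
#'
#' @param percent noise level in percent (>= 0); the benchmark studies use
#'   5, 10 and 15.
#' @param scheme `"relative"` (default) or `"absolute"`.
#' @param seed integer seed for the noise draw.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(percent = 10, scheme = c("relative", "absolute"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  if (percent < 0) stop("percent must be >= 0")
  structure(list(percent = percent, scheme = scheme, seed = seed),
            class = "noise_spec")
}

#' Add percent white Gaussian noise to a trajectory
#'
#' @param truth a `trajectory` (the noiseless model prediction).
#' @param spec a [noise_spec()].
#' @return A `dyn_dataset` with an all-true mask and the noise metadata
#'   (including the per-state variance of the actually injected noise
#'   sample, used as the reference in the identifiability test).
#' @export
add_noise <- function(truth, spec = noise_spec()) {
  y <- truth$states
  if (!is.null(spec$seed)) set.seed(spec$seed)
  z <- matrix(stats::rnorm(length(y)), nrow(y), ncol(y))
  p <- spec$percent / 100
  obs <- switch(spec$scheme,
    relative = y * (1 + p * z),
    absolute = y + p * rep(apply(y, 2, stats::sd), each = nrow(y)) * z)
  dimnames(obs) <- dimnames(y)
  rv <- if (spec$percent == 0) {
    stats::setNames(numeric(ncol(y)), colnames(y))
  } else {
    apply(obs - y, 2, function(e) variance_point(e))
  }
  make_dataset(truth$times, obs,
               noise_meta = list(percent = spec$percent,
                                 scheme = spec$scheme, seed = spec$seed,
                                 real_variance = rv))
}

#' Mask out a random fraction of observed entries
#'
#' Emulates incomplete experimental data: an exact count
#' `round(fraction * n_observed)` of currently observed entries is masked
#' out, sampling without replacement, while guaranteeing that every state
#' keeps at least one observation.
#'
#' @param data a `dyn_dataset`.
#' @param fraction fraction of observed entries to drop, in `[0, 1)`.
#' @param seed integer seed.
#' @return A `dyn_dataset` with an updated mask (and updated per-state
#'   injected-noise variances when noise metadata is present).
#' @export
mask_missing <- function(data, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  if (fraction == 0) return(data)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(data$mask)
  n_drop <- round(fraction * length(idx))
  if (n_drop == 0) return(data)
  drop <- sample(idx, n_drop)
  mask <- data$mask
  mask[drop] <- FALSE
  # every state keeps at least one observation
  for (s in which(colSums(mask) == 0)) {
    back <- intersect(drop, (s - 1L) * nrow(mask) + seq_len(nrow(mask)))
    mask[back[1L]] <- TRUE
  }
  data$mask <- mask
  data
}

#' Generate a complete benchmark scenario
#'
#' One call reproduces any of the package's in-silico study conditions:
#' simulate the model at the given (default: true) parameters, add percent
#' white Gaussian noise, optionally mask out a fraction of entries, and
#' record the per-state variance of the injected noise sample over the
#' observed entries (the "real variance" reference of the identifiability
#' test, computed with the same estimator as the test itself).
#'
#' @param model a `dynamical_model` or a benchmark id string.
#' @param params data-generating parameters (`NULL` = model defaults).
#' @param noise a [noise_spec()]; its seed is derived from `seed` when
#'   unset.
#' @param missing_fraction fraction of entries masked out (default 0).
#' @param seed master seed from which the process-noise, measurement-noise
#'   and masking seeds are derived.
#' @return A list of class `benchmark` with elements `truth` (trajectory),
#'   `data` (`dyn_dataset`), `real_variance` (named per-state vector),
#'   `model`, and `params`.
#' @export
make_benchmark <- function(model, params = NULL,
                           noise = noise_spec(percent = 15),
                           missing_fraction = 0, seed = 1) {
  if (is.character(model)) model <- benchmark_model(model)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  truth <- if (model$kind == "map") {
    simulate_map(model, params, seed = sub[1])
  } else {
    integrate_model(model, params)
  }
  if (is.null(noise$seed)) noise$seed <- sub[2]
  data <- add_noise(truth, noise)
  if (missing_fraction > 0)
    data <- mask_missing(data, missing_fraction, seed = sub[3])
  rv <- vapply(seq_len(ncol(data$observations)), function(s) {
    e <- (data$observations[, s] - truth$states[, s])[data$mask[, s]]
    if (length(e) < 2 || noise$percent == 0) 0 else variance_point(e)
  }, numeric(1))
  names(rv) <- colnames(data$observations)
  data$noise_meta$real_variance <- rv
  structure(list(truth = truth, data = data, real_variance = rv,
                 model = model, params = params, seed = seed),
            class = "benchmark")
}
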