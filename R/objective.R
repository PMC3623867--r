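#' Time-series dataset container
#'
#' Holds (possibly incomplete) observations of a subset of model states on a
#' sampling grid.  Missing entries are marked by the logical `mask`
#' (`TRUE` = observed); masked-out entries never contribute to the fit.
#'
#' @param times strictly increasing sampling instants.
#' @param observations numeric matrix (rows = times, named columns = states);
#'   `NA` entries are treated as missing.
#' @param mask optional logical matrix of the same shape; defaults to
#'   `!is.na(observations)`.
#' @param noise_meta optional record describing how synthetic noise was
#'   generated (see [add_noise()]).
#' @return An object of class `dyn_dataset`.
#' @export
make_dataset <- function(times, observations, mask = NULL,
                         noise_meta = NULL) {
  observations <- as.matrix(observations)
  if (is.null(colnames(observations)))
    stop("observation columns must be named after states")
  if (nrow(observations) != length(times))
    stop("observations must have one row per time point")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (is.null(mask)) mask <- !is.na(observations)
  mask <- as.matrix(mask) & !is.na(observations)
  if (!identical(dim(mask), dim(observations)))
    stop("mask shape must match observations")
  if (!any(mask)) stop("dataset contains no observed entries")
  dimnames(mask) <- dimnames(observations)
  structure(list(times = as.numeric(times), observations = observations,
                 mask = mask, noise_meta = noise_meta),
            class = "dyn_dataset")
}

#' @export
print.dyn_dataset <- function(x, ...) {
  cat("Dataset: ", length(x$times), " time points, ",
      ncol(x$observations), " states, ",
      sum(x$mask), "/", length(x$mask), " entries observed\n", sep = "")
  if (!is.null(x$noise_meta))
    cat("  noise: ", x$noise_meta$percent, "% (", x$noise_meta$scheme,
        "), seed ", format(x$noise_meta$seed), "\n", sep = "")
  invisible(x)
}

#' Read / write datasets as CSV
#'
#' Same dialect as [write_trajectory()]; blank cells encode missing entries.
#' A JSON sidecar (`<path>.json`) stores the noise metadata when present.
#'
#' @param data a `dyn_dataset`.
#' @param path CSV file path.
#' @export
write_dataset <- function(data, path) {
  obs <- data$observations
  obs[!data$mask] <- NA
  df <- data.frame(time = data$times, obs, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  if (!is.null(data$noise_meta)) {
    meta <- data$noise_meta
    if (!is.null(meta$real_variance))
      meta$real_variance <- as.list(meta$real_variance)  # keep state names
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "time") stop("first column must be 'time'")
  meta <- NULL
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$real_variance)) meta$real_variance <-
        unlist(meta$real_variance)
  }
  make_dataset(df$time, as.matrix(df[, -1, drop = FALSE]), noise_meta = meta)
}

#' Nonlinear least-squares fitness
#'
#' The objective minimised by every optimizer in the package: the sum of
#' squared residuals between a model trajectory and the observed entries of
#' a dataset, with state columns aligned by name and masked-out entries
#' contributing nothing.  No normalisation by the number of samples is
#' applied; [aic_score()] converts to a mean squared error where needed.
#'
#' @param prediction a `trajectory` on the same grid as the data.
#' @param data a `dyn_dataset`.
#' @return Non-negative scalar; 0 iff the prediction matches every observed
#'   entry.
#' @export
fitness <- function(prediction, data) {
  if (length(prediction$times) != length(data$times) ||
      any(abs(prediction$times - data$times) >
          1e-8 * pmax(1, abs(data$times))))
    stop("prediction and data are on different sampling grids")
  obs_states <- colnames(data$observations)
  if (any(!obs_states %in% colnames(prediction$states)))
    stop("prediction lacks observed states: ",
         paste(setdiff(obs_states, colnames(prediction$states)),
               collapse = ", "))
  if (!any(data$mask)) stop("dataset contains no observed entries")
  pred <- prediction$states[, obs_states, drop = FALSE]
  r <- (pred - data$observations)[data$mask]
  sum(r * r)
}

#' Evaluate a parameter vector against a dataset
#'
#' Composes simulation ([integrate_model()] or the deterministic
#' [simulate_map()] skeleton) with [fitness()].  Integration failure maps to
#' `+Inf` rather than an error so that population methods can keep going
#' when a proposed parameter set makes the system unstable.
#'
#' @inheritParams integrate_model
#' @param data a `dyn_dataset` whose grid matches the model simulation grid.
#' @return Non-negative scalar fitness (possibly `Inf`).
#' @export
evaluate_params <- function(model, params, data, initial_state = NULL) {
  obj <- make_objective(model, data, initial_state)
  obj(expandless_values(model, params))
}

# flexible input -> free-parameter numeric vector
expandless_values <- function(model, params) {
  param_values(model$param_space, params)
}

# Build the fast objective closure used by the optimizers: maps a free
# parameter vector to the sum of squared residuals (Inf on failure).
# Everything alignable is precomputed outside the hot loop.
make_objective <- function(model, data, initial_state = NULL) {
  obs_states <- colnames(data$observations)
  col_idx <- match(obs_states, model$state_names)
  if (any(is.na(col_idx)))
    stop("dataset observes unknown states: ",
         paste(obs_states[is.na(col_idx)], collapse = ", "))
  obs <- data$observations
  mask <- data$mask
  times <- data$times
  y0 <- if (is.null(initial_state)) model$default_initial_state else
    as.numeric(initial_state)

  if (model$kind == "map") {
    n_steps <- length(times) - 1L
    if (any(abs(times - (0:n_steps)) > 1e-8))
      stop("map datasets must be sampled on the integer grid 0:n")
    function(theta) {
      full <- expand_params(model, theta)
      pred <- tryCatch({
        if (model$id == "simulated_nonlinear")
          .Call(scro_sim_map, as.numeric(full), as.numeric(y0), n_steps,
                NULL)
        else {
          out <- matrix(NA_real_, n_steps + 1L, length(model$state_names))
          out[1L, ] <- y0
          x <- as.numeric(y0)
          for (i in seq_len(n_steps)) {
            x <- model$map_step(x, full)
            out[i + 1L, ] <- x
          }
          out
        }
      }, error = function(e) NULL)
      if (is.null(pred) || any(!is.finite(pred))) return(Inf)
      r <- (pred[, col_idx, drop = FALSE] - obs)[mask]
      sum(r * r)
    }
  } else {
    function(theta) {
      full <- expand_params(model, theta)
      out <- integrate_raw(model, full, times, y0)
      if (is.character(out)) return(Inf)
      r <- (out[, col_idx, drop = FALSE] - obs)[mask]
      sum(r * r)
    }
  }
}
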