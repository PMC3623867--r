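#' Create a bounded parameter set
#'
#' A parameter set is the basic search-space object used throughout the
#' package: a named vector of values together with box bounds, optionally
#' annotated with units.  Units are carried as metadata only; no conversion
#' is ever performed.
#'
#' @param names character vector of parameter identifiers.
#' @param values numeric vector of current values (one per name).
#' @param lower,upper numeric vectors of box bounds.  `lower[d] <= upper[d]`
#'   is required; a zero-width interval is allowed and pins the parameter.
#' @param units optional character vector of unit labels (metadata only).
#' @return An object of class `parameter_set`.
#' @examples
#' parameter_set(c("a", "b"), c(0.8, 1.5), lower = c(0, 0), upper = c(1, 3))
#' @export
parameter_set <- function(names, values, lower, upper, units = NULL) {
  names <- as.character(names)
  values <- as.numeric(values)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  d <- length(names)
  if (d < 1L) stop("a parameter set needs at least one parameter")
  if (length(values) != d || length(lower) != d || length(upper) != d)
    stop("names, values, lower and upper must have equal length")
  if (anyDuplicated(names)) stop("parameter names must be unique")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower > upper)) stop("lower bound exceeds upper bound")
  if (any(values < lower - 1e-12) || any(values > upper + 1e-12))
    stop("values must lie within the bounds")
  if (!is.null(units) && length(units) != d)
    stop("units must have one entry per parameter")
  structure(
    list(names = names, values = stats::setNames(values, names),
         lower = stats::setNames(lower, names),
         upper = stats::setNames(upper, names),
         units = units),
    class = "parameter_set"
  )
}

#' @export
print.parameter_set <- function(x, ...) {
  df <- data.frame(value = x$values, lower = x$lower, upper = x$upper,
                   row.names = x$names)
  if (!is.null(x$units)) df$unit <- x$units
  cat("Parameter set (", length(x$names), " parameters)\n", sep = "")
  print(df, ...)
  invisible(x)
}

#' @export
length.parameter_set <- function(x) length(x$names)

#' @export
as.double.parameter_set <- function(x, ...) unname(x$values)

# Replace the values of a parameter set, recycling names from the template.
# Accepts a bare numeric vector (positional) or a named vector.
set_values <- function(space, values) {
  if (inherits(values, "parameter_set")) values <- values$values
  if (!is.null(names(values))) {
    unknown <- setdiff(names(values), space$names)
    if (length(unknown))
      stop("unknown parameters: ", paste(unknown, collapse = ", "))
    merged <- space$values
    merged[names(values)] <- values
    values <- merged
  }
  if (length(values) != length(space$names))
    stop("expected ", length(space$names), " parameter values")
  parameter_set(space$names, as.numeric(values), space$lower, space$upper,
                units = space$units)
}

# Numeric parameter vector in template order from flexible input.
param_values <- function(space, params = NULL) {
  if (is.null(params)) return(unname(space$values))
  if (inherits(params, "parameter_set")) return(unname(params$values))
  v <- set_values(space, params)
  unname(v$values)
}

clamp <- function(x, lower, upper) pmin(pmax(x, lower), upper)
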