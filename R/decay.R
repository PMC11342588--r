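#' Distance-decay configuration
#'
#' Bundles the parameters of the Gaussian distance-decay kernel used
#' throughout the accessibility engine.
#'
#' @param catchment_minutes Positive catchment radius in minutes: the maximum
#'   travel time patients are assumed willing to travel. Default 120.
#' @param shape_factor Positive shape constant of the Gaussian kernel
#'   \eqn{w = \exp(-d_{ij}^2 / (s \cdot d^2))}. Default 0.2.
#' @param truncate_beyond_catchment If `TRUE` (default) weights are zeroed for
#'   travel times beyond `catchment_minutes`, making the kernel a true
#'   floating-catchment weight; if `FALSE` the unbounded Gaussian tail is kept.
#'
#' @return A list of class `decay_config`.
#' @export
#' @examples
#' decay_config()
#' decay_config(catchment_minutes = 90, truncate_beyond_catchment = FALSE)
decay_config <- function(catchment_minutes = 120,
                         shape_factor = 0.2,
                         truncate_beyond_catchment = TRUE) {
  stopifnot(is.numeric(catchment_minutes), length(catchment_minutes) == 1,
            is.numeric(shape_factor), length(shape_factor) == 1,
            is.logical(truncate_beyond_catchment))
  if (!(catchment_minutes > 0)) stop("catchment_minutes must be > 0")
  if (!(shape_factor > 0)) stop("shape_factor must be > 0")
  structure(list(catchment_minutes = catchment_minutes,
                 shape_factor = shape_factor,
                 truncate_beyond_catchment = truncate_beyond_catchment),
            class = "decay_config")
}

# weights below this are stored as exact zeros to keep weight maps sparse
.WEIGHT_EPS <- 1e-12

#' Gaussian distance-decay weight
#'
#' Maps travel time in minutes to an attraction weight in \[0, 1\] with the
#' Gaussian kernel \eqn{w_{ij} = \exp(-d_{ij}^2 / (s \cdot d^2))}, where
#' \eqn{d} is the catchment radius and \eqn{s} the shape factor. With
#' truncation on, times beyond the catchment get weight 0.
#'
#' @param d_ij Nonnegative travel time(s) in minutes (vectorised).
#' @param config A [decay_config()].
#' @return Numeric vector of weights in \[0, 1\]; values below 1e-12 are
#'   returned as exact zeros.
#' @export
#' @examples
#' cfg <- decay_config()
#' gaussian_weight(c(0, 60, 120), cfg)
gaussian_weight <- function(d_ij, config = decay_config()) {
  stopifnot(inherits(config, "decay_config"), is.numeric(d_ij))
  if (any(d_ij < 0, na.rm = TRUE)) stop("travel time d_ij must be nonnegative")
  d <- config$catchment_minutes
  w <- exp(-(d_ij^2) / (config$shape_factor * d^2))
  if (config$truncate_beyond_catchment) w[d_ij > d] <- 0
  w[w < .WEIGHT_EPS] <- 0
  w
}

#' Sparse decay-weight map over municipality pairs
#'
#' Applies [gaussian_weight()] to a long-form travel-time table and keeps only
#' the strictly positive entries. No symmetry is imposed: the map is symmetric
#' exactly when the input is.
#'
#' @param od Tibble with columns `origin`, `destination`, `minutes`.
#' @param config A [decay_config()].
#' @return Tibble with columns `origin`, `destination`, `weight` (> 0 only).
#' @export
weight_matrix <- function(od, config = decay_config()) {
  stopifnot(all(c("origin", "destination", "minutes") %in% names(od)))
  w <- gaussian_weight(od$minutes, config)
  keep <- w > 0
  tibble::tibble(origin = od$origin[keep],
                 destination = od$destination[keep],
                 weight = w[keep])
}
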