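#' Normalize angles into [0, 360)
#'
#' Compass headings may arrive as any real number of degrees (e.g. 370, -15).
#' All of `magtaxis` stores angles on the half-open interval \[0, 360) in the
#' topographic compass convention: 0 deg = magnetic North, increasing
#' clockwise.
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector of the same length, each value in \[0, 360).
#' @examples
#' normalize_deg(c(370, -15, 360))
#' @export
normalize_deg <- function(deg) {
  if (!is.numeric(deg)) stop("angles must be numeric", call. = FALSE)
  out <- deg %% 360
  # %% can return 360 for tiny negative arguments through rounding
  out[out >= 360] <- 0
  out
}

# Compass degrees -> radians. All internal trigonometry uses "compass
# radians" with unit vectors (sin theta = East, cos theta = North), so the
# clockwise-from-North convention is self-consistent end to end and only
# this pair of helpers touches the conversion.
.deg2rad <- function(deg) deg * pi / 180
.rad2deg <- function(rad) rad * 180 / pi

#' Construct a sample of circular angles
#'
#' The elementary container for directional data: a vector of headings in
#' compass degrees with optional nonnegative weights. Angles are normalized
#' into \[0, 360) on construction.
#'
#' @param angles numeric vector of headings in degrees (any real values;
#'   normalized to \[0, 360)).
#' @param weights optional nonnegative weights, one per angle, with positive
#'   sum. Default: all 1.
#' @return an object of class `angle_sample`: a list with elements `angles`
#'   and `weights`.
#' @examples
#' angle_sample(c(0, 90, 370))
#' @export
angle_sample <- function(angles, weights = NULL) {
  if (length(angles) == 0) stop("no angles supplied: sample is empty", call. = FALSE)
  if (anyNA(angles)) stop("angles contain NA", call. = FALSE)
  angles <- normalize_deg(as.numeric(angles))
  if (is.null(weights)) {
    weights <- rep(1, length(angles))
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != length(angles))
      stop("weights must have the same length as angles", call. = FALSE)
    if (anyNA(weights) || any(weights < 0))
      stop("weights must be nonnegative and non-missing", call. = FALSE)
    if (sum(weights) <= 0) stop("weights must have positive sum", call. = FALSE)
  }
  structure(list(angles = angles, weights = weights), class = "angle_sample")
}

#' @export
print.angle_sample <- function(x, ...) {
  cat("Circular sample:", length(x$angles), "angles (degrees, compass)\n")
  cat(" ", paste(utils::head(round(x$angles, 1), 8), collapse = ", "))
  if (length(x$angles) > 8) cat(", ...")
  cat("\n")
  invisible(x)
}

#' @export
length.angle_sample <- function(x) length(x$angles)

as_angle_sample <- function(x) {
  if (inherits(x, "angle_sample")) x else angle_sample(x)
}
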