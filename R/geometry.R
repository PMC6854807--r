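#' Construct a spatial vector
#'
#' Length-3 numeric vector (x, y, z components) with a `basis` attribute
#' recording which vectorcardiographic quantity it represents
#' (e.g. "QRSpeak", "Tarea", "SVGpeak").  Peak vectors are in microvolts,
#' area vectors in microvolt-milliseconds.
#'
#' @param x,y,z finite numeric components.
#' @param basis character label for the quantity.
#' @return object of class `spatial_vector`.
#' @export
spatial_vector <- function(x, y, z, basis = "generic") {
  v <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (any(!is.finite(v))) stop("spatial vector components must be finite")
  structure(v, basis = basis, class = "spatial_vector")
}

#' @export
print.spatial_vector <- function(x, ...) {
  cat(sprintf("<spatial_vector %s> x=%.3f y=%.3f z=%.3f (|v|=%.3f)\n",
              attr(x, "basis"), x[1], x[2], x[3], magnitude(x)))
  invisible(x)
}

as_sv <- function(v) {
  if (inherits(v, "spatial_vector")) return(unclass(v))
  v <- as.numeric(v)
  if (length(v) != 3L || any(!is.finite(v)))
    stop("expected 3 finite components")
  v
}

#' Euclidean magnitude of a spatial vector
#'
#' @param v spatial vector (or any length-3 numeric).
#' @return norm, in the vector's own units (microvolts for peak vectors,
#'   microvolt-milliseconds for area vectors).
#' @export
magnitude <- function(v) {
  v <- as_sv(v)
  sqrt(sum(v^2))
}

#' Angle between two spatial vectors, in degrees
#'
#' The spatial QRS-T angle is `spatial_angle(qrs, t)` for either the peak
#' or the area (mean) QRS and T vectors; the result is scale-invariant.
#'
#' @param a,b spatial vectors with non-zero magnitude.
#' @return angle in degrees, clamped to \[0, 180\].
#' @export
spatial_angle <- function(a, b) {
  a <- as_sv(a); b <- as_sv(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("undefined angle: zero-magnitude vector")
  cosv <- sum(a * b) / (na * nb)
  acos(min(1, max(-1, cosv))) * 180 / pi
}

#' Azimuth of a spatial vector, in degrees
#'
#' Quadrant-aware angle in the transverse X-Z plane, measured from +X
#' (leftward) towards +Z (posterior); range (-180, 180].  A plain arctan
#' of Z/X cannot distinguish front from back, so atan2 is used.
#'
#' @param v spatial vector with x and z not both zero.
#' @return azimuth in degrees.
#' @export
azimuth <- function(v) {
  v <- as_sv(v)
  if (v[1] == 0 && v[3] == 0) stop("undefined azimuth: x and z both zero")
  atan2(v[3], v[1]) * 180 / pi
}

#' Elevation of a spatial vector, in degrees
#'
#' `mode = "conventional"` (default) returns the geometric polar angle from
#' the +Y axis (positive downward), `atan2(sqrt(x^2 + z^2), y)`, range
#' \[0, 180\].  `mode = "literal"` returns `atan(x / y)`, range (-90, 90),
#' the plain-arctan form seen in some published formulations; it cannot
#' distinguish quadrants and is provided for comparability only.  Reported
#' elevations should state the mode.
#'
#' @param v spatial vector with non-zero magnitude.
#' @param mode `"conventional"` or `"literal"`.
#' @return elevation in degrees.
#' @export
elevation <- function(v, mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  v <- as_sv(v)
  if (all(v == 0)) stop("undefined elevation: zero vector")
  if (mode == "conventional") {
    atan2(sqrt(v[1]^2 + v[3]^2), v[2]) * 180 / pi
  } else {
    if (v[2] == 0) stop("literal elevation undefined for y = 0")
    atan(v[1] / v[2]) * 180 / pi
  }
}

#' Peak spatial ventricular gradient vector
#'
#' Componentwise sum of the spatial peak QRS and peak T vectors.
#'
#' @param qrs_peak,t_peak peak spatial vectors in microvolts.
#' @return `spatial_vector` with basis "SVGpeak".
#' @export
svg_peak <- function(qrs_peak, t_peak) {
  a <- as_sv(qrs_peak); b <- as_sv(t_peak)
  spatial_vector(a[1] + b[1], a[2] + b[2], a[3] + b[3], basis = "SVGpeak")
}

# unit vector for a (azimuth, elevation) direction pair, degrees,
# conventional elevation from +Y
dir_to_unit <- function(az_deg, el_deg) {
  az <- az_deg * pi / 180
  el <- el_deg * pi / 180
  c(x = sin(el) * cos(az), y = cos(el), z = sin(el) * sin(az))
}

# minimal circular difference between two azimuths in degrees
azimuth_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, 360 - d, d)
}
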