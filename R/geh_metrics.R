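# trapezoidal integral of each column over sample indices `rows`,
# dt in ms; returns named length-3 vector in uV*ms
trapz_xyz <- function(beat, rows) {
  m <- cbind(beat$x, beat$y, beat$z)[rows, , drop = FALSE]
  dt <- 1000 / beat$fs
  if (nrow(m) < 2L) return(c(x = 0, y = 0, z = 0))
  v <- (colSums(m) - (m[1, ] + m[nrow(m), ]) / 2) * dt
  c(x = v[1], y = v[2], z = v[3])
}

trapz_scalar <- function(vals, fs) {
  if (length(vals) < 2L) return(0)
  (sum(vals) - (vals[1] + vals[length(vals)]) / 2) * 1000 / fs
}

check_windows <- function(beat) {
  if (!(beat$qrs_onset >= 1 && beat$qrs_onset < beat$qrs_offset &&
        beat$qrs_offset < beat$t_offset && beat$t_offset <= length(beat$x)))
    stop("invalid fiducial windows: require qrs_onset < qrs_offset < t_offset within the beat")
}

#' Spatial peak QRS and T vectors
#'
#' The peak QRS vector is the XYZ sample of maximal spatial vector
#' magnitude within \[QRS onset, QRS offset\]; the peak T vector likewise
#' within (QRS offset, T offset\].  Ties break to the earliest sample.
#'
#' @param beat an origin-corrected `median_beat_xyz`.
#' @return list with `qrs_peak` and `t_peak` (`spatial_vector`s,
#'   microvolts).
#' @export
peak_vectors <- function(beat) {
  check_windows(beat)
  vm <- vector_magnitude(beat)
  qw <- beat$qrs_onset:beat$qrs_offset
  tw <- (beat$qrs_offset + 1L):beat$t_offset
  if (!length(qw) || !length(tw)) stop("empty fiducial window")
  iq <- qw[which.max(vm[qw])]
  it <- tw[which.max(vm[tw])]
  list(qrs_peak = spatial_vector(beat$x[iq], beat$y[iq], beat$z[iq], "QRSpeak"),
       t_peak = spatial_vector(beat$x[it], beat$y[it], beat$z[it], "Tpeak"))
}

#' Spatial area (mean) QRS and T vectors
#'
#' Componentwise trapezoidal time-integrals of the XYZ beat over the QRS
#' window \[QRS onset, QRS offset\] and the T window (QRS offset,
#' T offset\]; the shared boundary node is counted once in each trapezoid
#' so the two integrals sum exactly to the full QRS-onset-to-T-offset
#' integral.
#'
#' @param beat an origin-corrected `median_beat_xyz`.
#' @return list with `qrs_area` and `t_area` (`spatial_vector`s,
#'   microvolt-milliseconds).
#' @export
area_vectors <- function(beat) {
  check_windows(beat)
  qa <- trapz_xyz(beat, beat$qrs_onset:beat$qrs_offset)
  ta <- trapz_xyz(beat, beat$qrs_offset:beat$t_offset)
  list(qrs_area = spatial_vector(qa[1], qa[2], qa[3], "QRSarea"),
       t_area = spatial_vector(ta[1], ta[2], ta[3], "Tarea"))
}

#' Spatial area SVG vector (Wilson ventricular gradient)
#'
#' Componentwise trapezoidal integral of the XYZ beat over the full
#' QRS-onset-to-T-offset window, in microvolt-milliseconds.
#'
#' @param beat an origin-corrected `median_beat_xyz`.
#' @return `spatial_vector` with basis "SVGarea".
#' @export
svg_area <- function(beat) {
  check_windows(beat)
  v <- trapz_xyz(beat, beat$qrs_onset:beat$t_offset)
  spatial_vector(v[1], v[2], v[3], "SVGarea")
}

#' Sum absolute QRST integral (SAI QRST)
#'
#' Sum of the absolute-value trapezoidal integrals of X, Y and Z over the
#' QRS-onset-to-T-offset window, converted to millivolt-milliseconds.
#'
#' @param beat an origin-corrected `median_beat_xyz`.
#' @return SAI QRST in mV*ms.
#' @export
sai_qrst <- function(beat) {
  check_windows(beat)
  rows <- beat$qrs_onset:beat$t_offset
  (trapz_scalar(abs(beat$x[rows]), beat$fs) +
   trapz_scalar(abs(beat$y[rows]), beat$fs) +
   trapz_scalar(abs(beat$z[rows]), beat$fs)) / 1000
}

#' Bazett-corrected QT interval
#'
#' @param qt_ms QT interval, ms.
#' @param rr_ms RR interval, ms (must be positive).
#' @return QTc in ms: `qt_ms / sqrt(rr_ms / 1000)`.
#' @export
qtc_bazett <- function(qt_ms, rr_ms) {
  if (any(rr_ms <= 0)) stop("RR interval must be positive")
  qt_ms / sqrt(rr_ms / 1000)
}

#' Compute all GEH and traditional metrics for a 12-lead record
#'
#' Facade running the full measurement chain: Kors transform, time-coherent
#' median beat, origin detection/correction, then the peak and area QRS-T
#' angles, SVG azimuth/elevation/magnitude (peak and area forms), SAI QRST,
#' heart rate, QRS duration and Bazett QTc.
#'
#' @param record an `ecg12_record`.
#' @param elevation_mode passed to [elevation()]; reported elevations
#'   should state the mode.
#' @return object of class `geh_metrics`: a one-row data.frame with
#'   columns `peak_qrst_angle`, `area_qrst_angle` (degrees),
#'   `peak_svg_azimuth`, `peak_svg_elevation`, `area_svg_azimuth`,
#'   `area_svg_elevation` (degrees), `peak_svg_magnitude` (microvolts),
#'   `area_svg_magnitude` (microvolt-ms), `sai_qrst` (mV*ms),
#'   `heart_rate` (bpm), `qrs_duration`, `qtc` (ms).
#' @export
compute_geh <- function(record, elevation_mode = c("conventional", "literal")) {
  elevation_mode <- match.arg(elevation_mode)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  xyz <- stage("kors_transform", kors_transform(record))
  mb <- stage("build_median_beat",
              build_median_beat(xyz, record$beat_labels, record$r_peaks,
                                record$fs, record$fiducials))
  beat <- stage("detect_origin", detect_origin(mb)$beat)
  pk <- stage("peak_vectors", peak_vectors(beat))
  ar <- stage("area_vectors", area_vectors(beat))
  svgp <- svg_peak(pk$qrs_peak, pk$t_peak)
  svga <- stage("svg_area", svg_area(beat))
  qt_ms <- (beat$t_offset - beat$qrs_onset) / beat$fs * 1000
  qrs_ms <- (beat$qrs_offset - beat$qrs_onset) / beat$fs * 1000
  out <- data.frame(
    peak_qrst_angle = spatial_angle(pk$qrs_peak, pk$t_peak),
    area_qrst_angle = spatial_angle(ar$qrs_area, ar$t_area),
    peak_svg_azimuth = azimuth(svgp),
    peak_svg_elevation = elevation(svgp, elevation_mode),
    area_svg_azimuth = azimuth(svga),
    area_svg_elevation = elevation(svga, elevation_mode),
    peak_svg_magnitude = magnitude(svgp),
    area_svg_magnitude = magnitude(svga),
    sai_qrst = sai_qrst(beat),
    heart_rate = 60000 / beat$rr_median,
    qrs_duration = qrs_ms,
    qtc = qtc_bazett(qt_ms, beat$rr_median))
  rownames(out) <- NULL
  attr(out, "elevation_mode") <- elevation_mode
  attr(out, "n_beats_used") <- beat$n_beats_used
  class(out) <- c("geh_metrics", class(out))
  out
}
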