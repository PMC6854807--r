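#' Parameters for the synthetic 12-lead ECG generator
#'
#' The generator synthesizes an XYZ dipole as two time-localized Gaussian
#' lobes per beat (a narrow QRS lobe and a broader T lobe) whose spatial
#' peak vectors equal the requested directions and magnitudes, then maps
#' the dipole to the eight independent standard leads through the
#' Moore-Penrose right-inverse of the Kors matrix, so the forward Kors
#' transform recovers the dipole to numerical tolerance.  This gives every
#' downstream vectorcardiographic metric an exact ground truth.
#'
#' @param heart_rate beats per minute.
#' @param n_beats number of beats; 10 beats at 60 bpm gives a 10-s-class
#'   record.
#' @param fs sampling rate in Hz.
#' @param qrs_duration QRS duration in ms.
#' @param qt_interval QT interval (QRS onset to T offset) in ms; must
#'   exceed `qrs_duration` and fit inside one RR interval.
#' @param qrs_peak_dir,t_peak_dir length-2 `(azimuth, elevation)` in
#'   degrees (conventional elevation from +Y) of the QRS and T spatial
#'   peak vectors.
#' @param qrs_peak_mag,t_peak_mag peak vector magnitudes in microvolts.
#' @param noise_sd additive white noise SD per lead, microvolts.
#' @param baseline_wander_amp amplitude of a 0.3-Hz sinusoidal baseline
#'   wander per lead, microvolts.
#' @param pvc_positions integer beat indices turned into premature-
#'   ventricular-complex-like beats (wide, large, reversed QRS direction);
#'   neighbouring sinus beats are labelled `pre_post_pvc`.
#' @param seed integer seed; identical seeds give identical records.
#' @return validated parameter list of class `ecg_gen_params`.
#' @export
ecg_gen_params <- function(heart_rate = 60, n_beats = 10, fs = 500,
                           qrs_duration = 100, qt_interval = 400,
                           qrs_peak_dir = c(0, 45), qrs_peak_mag = 1500,
                           t_peak_dir = c(30, 60), t_peak_mag = 500,
                           noise_sd = 0, baseline_wander_amp = 0,
                           pvc_positions = integer(0), seed = 1L) {
  p <- list(heart_rate = heart_rate, n_beats = as.integer(n_beats), fs = fs,
            qrs_duration = qrs_duration, qt_interval = qt_interval,
            qrs_peak_dir = qrs_peak_dir, qrs_peak_mag = qrs_peak_mag,
            t_peak_dir = t_peak_dir, t_peak_mag = t_peak_mag,
            noise_sd = noise_sd, baseline_wander_amp = baseline_wander_amp,
            pvc_positions = as.integer(pvc_positions), seed = as.integer(seed))
  rr <- 60000 / p$heart_rate
  if (p$fs <= 0) stop("fs must be positive")
  if (p$heart_rate <= 0) stop("heart_rate must be positive")
  if (p$n_beats < 1) stop("need at least one beat")
  if (!(p$qrs_duration > 0 && p$qrs_duration < p$qt_interval))
    stop("inconsistent timing: require 0 < qrs_duration < qt_interval")
  if (p$qt_interval >= rr)
    stop("inconsistent timing: qt_interval must be shorter than the RR interval (",
         round(rr), " ms at ", p$heart_rate, " bpm)")
  if (p$qrs_peak_mag < 0 || p$t_peak_mag < 0 || p$noise_sd < 0 ||
      p$baseline_wander_amp < 0)
    stop("magnitudes and noise amplitudes must be non-negative")
  if (length(p$qrs_peak_dir) != 2L || length(p$t_peak_dir) != 2L)
    stop("peak directions must be (azimuth, elevation) pairs in degrees")
  if (length(p$pvc_positions) &&
      (min(p$pvc_positions) < 1 || max(p$pvc_positions) > p$n_beats))
    stop("pvc_positions out of beat range")
  class(p) <- "ecg_gen_params"
  p
}

# Gaussian lobe: peak `mag` at time `center` (ms), nominal support `width`
# (ms) ~ 6 sigma.
gauss_lobe <- function(t_ms, center, width, mag) {
  s <- width / 6
  mag * exp(-((t_ms - center)^2) / (2 * s^2))
}

# Single-beat clean dipole evaluated at times t_ms (ms) relative to QRS
# onset at `onset` ms.  Returns n x 3 matrix.
beat_dipole <- function(t_ms, onset, qrs_dur, qt, u_q, mag_q, u_t, mag_t) {
  c_q <- onset + qrs_dur / 2
  c_t <- onset + (qrs_dur + qt) / 2          # centre of the T window
  gq <- gauss_lobe(t_ms, c_q, qrs_dur, mag_q)
  gt <- gauss_lobe(t_ms, c_t, qt - qrs_dur, mag_t)
  cbind(gq * u_q[1] + gt * u_t[1],
        gq * u_q[2] + gt * u_t[2],
        gq * u_q[3] + gt * u_t[3])
}

#' Generate a synthetic multi-beat 12-lead ECG with known vector geometry
#'
#' See [ecg_gen_params()] for the construction.  Ground-truth peak and
#' area vectors, angles, SVG direction/magnitude and SAI QRST of the clean
#' single-beat dipole are computed by fine-grid (0.1 ms) quadrature and
#' stored in `$ground_truth`, independent of the measurement code path.
#'
#' @param params an `ecg_gen_params` object.
#' @return object of class `ecg12_record`: `signal` (samples x 12 matrix,
#'   microvolts, columns [LEAD_NAMES_12]), `fs`, `lead_names`,
#'   `beat_labels`, `r_peaks` (sample indices), `fiducials` (list of
#'   `qrs_onset`, `qrs_offset`, `t_offset` offsets relative to the R peak,
#'   in samples), `ground_truth`, `params`.
#' @export
generate_ecg12 <- function(params) {
  if (!inherits(params, "ecg_gen_params")) params <- do.call(ecg_gen_params, params)
  p <- params
  set.seed(p$seed)
  rr <- 60000 / p$heart_rate                     # ms
  fs <- p$fs
  dur_ms <- (p$n_beats + 0.5) * rr
  n <- ceiling(dur_ms / 1000 * fs)
  t_ms <- (seq_len(n) - 1) / fs * 1000

  u_q <- dir_to_unit(p$qrs_peak_dir[1], p$qrs_peak_dir[2])
  u_t <- dir_to_unit(p$t_peak_dir[1], p$t_peak_dir[2])

  # beat geometry: R peak (QRS lobe centre) of beat k at (k - 0.25) * rr
  r_times <- (seq_len(p$n_beats) - 0.25) * rr    # ms
  onsets <- r_times - p$qrs_duration / 2
  is_pvc <- seq_len(p$n_beats) %in% p$pvc_positions

  xyz <- matrix(0, n, 3)
  for (k in seq_len(p$n_beats)) {
    if (is_pvc[k]) {
      # wide, large, reversed-direction ventricular beat
      xyz <- xyz + beat_dipole(t_ms, onsets[k], p$qrs_duration * 1.6,
                               p$qt_interval * 1.2, -u_q, p$qrs_peak_mag * 1.8,
                               -u_t, p$t_peak_mag * 1.5)
    } else {
      xyz <- xyz + beat_dipole(t_ms, onsets[k], p$qrs_duration,
                               p$qt_interval, u_q, p$qrs_peak_mag,
                               u_t, p$t_peak_mag)
    }
  }

  # map dipole -> 8 independent leads via the Kors right-inverse, then
  # derive the redundant limb leads
  L8 <- xyz %*% t(kors_right_inverse())
  I <- L8[, 1]; II <- L8[, 2]
  sig <- cbind(I, II, II - I, -(I + II) / 2, I - II / 2, II - I / 2,
               L8[, 3:8])
  colnames(sig) <- LEAD_NAMES_12

  if (p$baseline_wander_amp > 0) {
    ph <- runif(12, 0, 2 * pi)
    for (j in 1:12)
      sig[, j] <- sig[, j] +
        p$baseline_wander_amp * sin(2 * pi * 0.3 * t_ms / 1000 + ph[j])
  }
  if (p$noise_sd > 0)
    sig <- sig + matrix(rnorm(n * 12, 0, p$noise_sd), n, 12)

  labels <- rep("normal_sinus", p$n_beats)
  labels[is_pvc] <- "pvc"
  nb <- unique(c(p$pvc_positions - 1L, p$pvc_positions + 1L))
  nb <- nb[nb >= 1 & nb <= p$n_beats & !(nb %in% p$pvc_positions)]
  labels[nb] <- "pre_post_pvc"

  r_peaks <- round(r_times / 1000 * fs) + 1L
  fid <- list(qrs_onset = as.integer(round(-p$qrs_duration / 2 / 1000 * fs)),
              qrs_offset = as.integer(round(p$qrs_duration / 2 / 1000 * fs)),
              t_offset = as.integer(round((p$qt_interval - p$qrs_duration / 2) /
                                            1000 * fs)))

  structure(list(signal = sig, fs = fs, lead_names = LEAD_NAMES_12,
                 beat_labels = labels, r_peaks = r_peaks, fiducials = fid,
                 ground_truth = ecg_ground_truth(p, u_q, u_t),
                 params = p),
            class = "ecg12_record")
}

# Fine-grid quadrature ground truth for the clean single-beat dipole.
# Deliberately independent of the median-beat / trapezoid measurement path.
ecg_ground_truth <- function(p, u_q, u_t) {
  dt <- 0.1                                     # ms
  tt <- seq(0, p$qt_interval, by = dt)
  d <- beat_dipole(tt, 0, p$qrs_duration, p$qt_interval, u_q, p$qrs_peak_mag,
                   u_t, p$t_peak_mag)
  seg_int <- function(rows) colSums(d[rows, , drop = FALSE]) * dt
  qrs_rows <- tt <= p$qrs_duration
  qrs_area <- seg_int(qrs_rows)
  t_area <- seg_int(!qrs_rows)
  svg_area <- qrs_area + t_area
  sai <- sum(abs(d)) * dt / 1000               # mV*ms
  qrs_peak <- p$qrs_peak_mag * u_q
  t_peak <- p$t_peak_mag * u_t
  svgp <- qrs_peak + t_peak
  list(qrs_peak = qrs_peak, t_peak = t_peak,
       peak_qrst_angle = spatial_angle(qrs_peak, t_peak),
       area_qrst_angle = spatial_angle(qrs_area, t_area),
       svg_peak = svgp,
       peak_svg_azimuth = azimuth(svgp),
       peak_svg_elevation = elevation(svgp),
       peak_svg_magnitude = magnitude(svgp),
       qrs_area = qrs_area, t_area = t_area, svg_area = svg_area,
       area_svg_azimuth = azimuth(svg_area),
       area_svg_elevation = elevation(svg_area),
       area_svg_magnitude = magnitude(svg_area),
       sai_qrst = sai,
       rr_ms = 60000 / p$heart_rate,
       qrs_duration = p$qrs_duration, qt_interval = p$qt_interval)
}

#' @export
print.ecg12_record <- function(x, ...) {
  cat(sprintf("<ecg12_record> %d samples x 12 leads @ %g Hz, %d beats (%s)\n",
              nrow(x$signal), x$fs, length(x$beat_labels),
              paste(table(x$beat_labels), names(table(x$beat_labels)),
                    collapse = ", ")))
  invisible(x)
}
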