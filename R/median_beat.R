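#' Per-sample spatial vector magnitude
#'
#' @param beat a `median_beat_xyz` object, or a numeric matrix with 3
#'   columns (X, Y, Z) in microvolts.
#' @return numeric vector, `sqrt(x^2 + y^2 + z^2)` per sample, microvolts.
#' @export
vector_magnitude <- function(beat) {
  m <- if (inherits(beat, "median_beat_xyz")) cbind(beat$x, beat$y, beat$z)
       else as.matrix(beat)
  if (ncol(m) != 3L) stop("expected 3 columns (X, Y, Z)")
  sqrt(rowSums(m^2))
}

#' Build a time-coherent median beat from an XYZ signal
#'
#' Beats labelled `pvc`, `pre_post_pvc` or `noisy` never contribute.  The
#' remaining normal sinus beats are windowed around their R peaks on a
#' grid spanning the median RR interval, aligned by maximizing the
#' cross-correlation of their spatial vector magnitude against a running
#' median template (one refinement pass), and the output is the per-sample
#' median across aligned beats, componentwise in X, Y, Z.
#'
#' @param xyz samples x 3 matrix in microvolts (output of
#'   [kors_transform()]).
#' @param beat_labels character vector, one label per beat, classes
#'   `normal_sinus`, `pvc`, `pre_post_pvc`, `noisy`, `other`.  Only
#'   `normal_sinus` beats are used.
#' @param r_peaks strictly increasing sample indices of the R peaks, one
#'   per beat.
#' @param fs sampling rate, Hz.
#' @param fiducials list with `qrs_onset`, `qrs_offset`, `t_offset`:
#'   offsets relative to the R peak, in samples.
#' @param max_lag maximum alignment shift searched, in samples.
#' @return object of class `median_beat_xyz`: `x`, `y`, `z` (microvolts),
#'   `fs`, sample indices `qrs_onset`, `qrs_offset`, `t_offset`, `r_peak`,
#'   `origin` (zero until [detect_origin()] is applied), `n_beats_used`,
#'   `rr_median` (ms).
#' @export
build_median_beat <- function(xyz, beat_labels, r_peaks, fs, fiducials,
                              max_lag = 10L) {
  if (length(beat_labels) != length(r_peaks))
    stop("beat_labels and r_peaks lengths differ")
  if (is.unsorted(r_peaks, strictly = TRUE))
    stop("r_peaks must be strictly increasing")
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)

  rr_samp <- if (length(r_peaks) > 1) round(median(diff(r_peaks)))
             else round(0.9 * fs)
  pre <- max(round(0.3 * rr_samp),
             -fiducials$qrs_onset + round(0.06 * fs))
  post <- max(rr_samp - pre - 1L, fiducials$t_offset + round(0.02 * fs))

  usable <- which(beat_labels == "normal_sinus" &
                  r_peaks - pre >= 1 & r_peaks + post <= n)
  if (length(usable) < 3L) stop("insufficient beats: ", length(usable),
                                " usable normal sinus beat(s), need >= 3")

  extract <- function(centers) {
    lapply(centers, function(r) xyz[(r - pre):(r + post), , drop = FALSE])
  }
  centers <- r_peaks[usable]
  segs <- extract(centers)

  align_pass <- function(centers, segs) {
    vm <- vapply(segs, vector_magnitude, numeric(pre + post + 1L))
    templ <- apply(vm, 1, median)
    lags <- -max_lag:max_lag
    new_centers <- vapply(seq_along(centers), function(b) {
      sc <- vapply(lags, function(l) {
        r <- centers[b] + l
        if (r - pre < 1 || r + post > n) return(-Inf)
        sum(templ * vector_magnitude(xyz[(r - pre):(r + post), , drop = FALSE]))
      }, numeric(1))
      centers[b] + lags[which.max(sc)]
    }, numeric(1))
    new_centers
  }

  # initial R-peak alignment, then one cross-correlation refinement pass
  centers <- align_pass(centers, segs)
  segs <- extract(centers)
  centers <- align_pass(centers, segs)
  segs <- extract(centers)

  arr <- array(unlist(segs), dim = c(pre + post + 1L, 3L, length(segs)))
  med <- apply(arr, c(1, 2), median)

  structure(list(x = med[, 1], y = med[, 2], z = med[, 3], fs = fs,
                 r_peak = pre + 1L,
                 qrs_onset = pre + 1L + fiducials$qrs_onset,
                 qrs_offset = pre + 1L + fiducials$qrs_offset,
                 t_offset = pre + 1L + fiducials$t_offset,
                 origin = c(0, 0, 0),
                 n_beats_used = length(segs),
                 rr_median = rr_samp / fs * 1000),
            class = "median_beat_xyz")
}

#' @export
print.median_beat_xyz <- function(x, ...) {
  cat(sprintf(paste0("<median_beat_xyz> %d samples @ %g Hz, %d beats used,",
                     " RR %.0f ms, QRSon/QRSoff/Toff = %d/%d/%d\n"),
              length(x$x), x$fs, x$n_beats_used, x$rr_median,
              x$qrs_onset, x$qrs_offset, x$t_offset))
  invisible(x)
}

#' Detect and subtract the heart-vector origin point
#'
#' The origin is the mean XYZ over the electrically quietest 20-ms window
#' (minimum mean absolute spatial velocity) found in the 40 ms preceding
#' QRS onset; subtracting it zero-references the median beat before any
#' vector measurement.
#'
#' @param beat a `median_beat_xyz`.
#' @return list with `origin` (a `spatial_vector`, microvolts) and `beat`
#'   (the corrected `median_beat_xyz`, with `$origin` recorded).
#' @export
detect_origin <- function(beat) {
  stopifnot(inherits(beat, "median_beat_xyz"))
  fs <- beat$fs
  m <- cbind(beat$x, beat$y, beat$z)
  win <- max(2L, round(0.020 * fs))
  lo <- beat$qrs_onset - round(0.040 * fs)
  if (lo < 1L) {
    warning("origin search window clipped at beat start")
    lo <- 1L
  }
  hi <- beat$qrs_onset - win + 1L
  if (hi < lo) hi <- lo
  vel <- rbind(0, diff(m))
  speed <- sqrt(rowSums(vel^2))
  starts <- lo:hi
  score <- vapply(starts, function(s) mean(speed[s:(s + win - 1L)]), numeric(1))
  s <- starts[which.min(score)]
  origin <- colMeans(m[s:(s + win - 1L), , drop = FALSE])
  beat$x <- beat$x - origin[1]
  beat$y <- beat$y - origin[2]
  beat$z <- beat$z - origin[3]
  beat$origin <- as.numeric(origin)
  list(origin = spatial_vector(origin[1], origin[2], origin[3], "origin"),
       beat = beat)
}
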