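#' Write a 12-lead record as a CSV signal + JSON metadata pair
#'
#' Produces `<prefix>_signal.csv` (samples x 12, header row = lead names)
#' and `<prefix>_meta.json` (sampling rate, units, beat labels, R peaks,
#' fiducials, and any stored ground truth).
#'
#' @param record an `ecg12_record`.
#' @param prefix file path prefix (directories must exist).
#' @return invisibly, the two paths written.
#' @export
write_ecg12_csv <- function(record, prefix) {
  stopifnot(inherits(record, "ecg12_record"))
  sig_path <- paste0(prefix, "_signal.csv")
  meta_path <- paste0(prefix, "_meta.json")
  write.csv(as.data.frame(record$signal), sig_path, row.names = FALSE)
  meta <- list(fs = record$fs, units = "uV", lead_names = record$lead_names,
               beat_labels = record$beat_labels, r_peaks = record$r_peaks,
               fiducials = record$fiducials,
               ground_truth = record$ground_truth)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(signal = sig_path, meta = meta_path))
}

#' Read a 12-lead record from a CSV + JSON pair
#'
#' @param prefix path prefix used by [write_ecg12_csv()].
#' @return an `ecg12_record`.
#' @export
read_ecg12_csv <- function(prefix) {
  sig <- as.matrix(read.csv(paste0(prefix, "_signal.csv"), check.names = FALSE))
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  fid <- lapply(meta$fiducials, as.integer)
  structure(list(signal = sig, fs = meta$fs,
                 lead_names = meta$lead_names,
                 beat_labels = meta$beat_labels,
                 r_peaks = as.integer(meta$r_peaks), fiducials = fid,
                 ground_truth = meta$ground_truth, params = NULL),
            class = "ecg12_record")
}

#' Write / read a cohort table CSV
#'
#' @param cohort a `cohort_table`-shaped data.frame.
#' @param path CSV path.
#' @return `write_cohort_csv`: invisibly, the path; `read_cohort_csv`:
#'   the validated cohort data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path)
  need <- c("participant_id", "visit", "time_to_event_years", "event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("cohort CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(d$event %in% 0:2)) stop("event codes must be 0, 1 or 2")
  class(d) <- c("cohort_table", class(d))
  d
}
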