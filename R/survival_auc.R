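#' Nearest-neighbour span from the number of observations
#'
#' The fraction of observations in each marker neighbourhood of the
#' nearest-neighbour ROC(t) estimator.  The default rule is
#' `0.25 * n^(1/3)` per cent of the observations, i.e.
#' `0.25 * n^(1/3) / 100` as a fraction, clipped to (0, 1).  An
#' alternative `"power"` rule `0.25 * n^(-1/5)`, common in reference
#' implementations of the estimator, is available for comparison.
#'
#' @param n number of observations in the analysis set (>= 2).
#' @param method `"percent_cuberoot"` (default) or `"power"`.
#' @return span fraction in (0, 1).
#' @export
span_from_n <- function(n, method = c("percent_cuberoot", "power")) {
  method <- match.arg(method)
  if (!is.finite(n) || n < 2) stop("n must be >= 2")
  s <- switch(method,
              percent_cuberoot = 0.25 * n^(1 / 3) / 100,
              power = 0.25 * n^(-1 / 5))
  min(max(s, 1e-6), 1 - 1e-6)
}

# Weighted Kaplan-Meier survival at `horizon` for the subjects in one
# marker neighbourhood (indicator weights).
km_at_horizon <- function(tt, ss, horizon) {
  ev <- ss == 1 & tt <= horizon
  if (!any(ev)) return(1)
  et <- sort(unique(tt[ev]))
  d <- vapply(et, function(u) sum(tt == u & ss == 1), numeric(1))
  Y <- vapply(et, function(u) sum(tt >= u), numeric(1))
  prod(1 - d / Y)
}

#' Time-dependent ROC curve via the nearest-neighbour estimator
#'
#' Cumulative-case / dynamic-control ROC at a fixed horizon for censored
#' survival data, using the nearest-neighbour bivariate survival estimator
#' (Heagerty, Lumley & Pepe; Akritas smoothing): the conditional survival
#' `S(t | marker)` is a Kaplan-Meier computed inside a symmetric
#' neighbourhood containing `span * n` observations in marker rank space,
#' which allows censoring to depend on the marker.  Sensitivity and
#' specificity follow from the smoothed bivariate survival
#' `S(c, t) = mean(S(t | M_i) * 1[M_i > c])`:
#' `sens(c, t) = ((1 - F(c)) - S(c, t)) / (1 - S(t))` and
#' `spec(c, t) = 1 - S(c, t) / S(t)`.  Where the raw estimator is
#' non-monotone along the cutpoint grid it is repaired by a cumulative
#' maximum (repair count returned); the AUC is the trapezoidal area over
#' the empirical cutpoint grid.
#'
#' @param marker numeric marker values (higher = higher risk).
#' @param time follow-up times, years (>= 0).
#' @param status 1 = event of interest, 0 = censored (a competing death is
#'   coded 0 at its time).
#' @param horizon evaluation time, years.
#' @param span fraction of observations per neighbourhood; default
#'   [span_from_n()] of `length(marker)`.
#' @return object of class `roc_curve`: `horizon`, `cutpoints`,
#'   `sensitivity`, `specificity`, `auc`, `span`, `n`, `n_events`
#'   (events by the horizon), `n_repaired`.
#' @export
roc_t_nn <- function(marker, time, status, horizon, span = NULL) {
  n <- length(marker)
  stopifnot(length(time) == n, length(status) == n)
  if (any(!is.finite(marker))) stop("marker values must be finite")
  if (any(time < 0)) stop("negative follow-up time")
  if (is.null(span)) span <- span_from_n(n)
  if (!(span > 0 && span < 1)) stop("span must be in (0, 1)")
  n_events <- sum(status == 1 & time <= horizon)
  if (n_events == 0) stop("inestimable at horizon: no events by t = ", horizon)

  ord <- order(marker)
  m_s <- marker[ord]; t_s <- time[ord]; s_s <- status[ord]

  h <- max(0L, floor(span * n / 2))
  p <- vapply(seq_len(n), function(i) {
    w <- max(1L, i - h):min(n, i + h)
    km_at_horizon(t_s[w], s_s[w], horizon)
  }, numeric(1))

  S_t <- mean(p)
  if (S_t <= 0) stop("inestimable at horizon: no smoothed survivors at t")
  if (S_t >= 1) stop("inestimable at horizon: smoothed event probability is 0")
  # cutpoints at each distinct marker value; S(c,t) and 1-F(c) use M > c
  dup <- duplicated(m_s, fromLast = TRUE)
  cut_idx <- which(!dup)                      # last index of each distinct value
  rev_cum_p <- rev(cumsum(rev(p)))            # sum of p over ranks >= i
  n_gt <- n - cut_idx                         # count of M > c
  S_ct <- ifelse(cut_idx < n, rev_cum_p[pmin(cut_idx + 1L, n)], 0) / n
  sens <- ((n_gt / n) - S_ct) / (1 - S_t)
  spec <- 1 - S_ct / S_t
  sens <- pmin(1, pmax(0, sens))
  spec <- pmin(1, pmax(0, spec))

  # prepend the c = -Inf point (everyone test-positive)
  sens <- c(1, sens); fpr <- c(1, 1 - spec)
  # monotone repair: both must be non-increasing along ascending cutpoints
  sens_r <- rev(cummax(rev(sens)))
  fpr_r <- rev(cummax(rev(fpr)))
  n_repaired <- sum(sens_r != sens) + sum(fpr_r != fpr)

  # trapezoid over (FPR, TPR), closing at (0, 0)
  xs <- c(fpr_r, 0); ys <- c(sens_r, 0)
  auc <- sum((xs[-length(xs)] - xs[-1]) * (ys[-length(ys)] + ys[-1]) / 2)

  structure(list(horizon = horizon, cutpoints = m_s[cut_idx],
                 sensitivity = sens_r[-1], specificity = 1 - fpr_r[-1],
                 auc = auc, span = span, n = n, n_events = n_events,
                 n_repaired = n_repaired),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> t = %g y: AUC = %.4f (n = %d, %d events, span = %.4f)\n",
              x$horizon, x$auc, x$n, x$n_events, x$span))
  invisible(x)
}

#' Divide a longitudinal cohort into k non-overlapping partitions
#'
#' Every record (participant-visit) is assigned to exactly one partition
#' and no participant appears more than once within a partition.  A
#' participant with `k` visits contributes exactly one visit to each
#' partition (the visit-to-partition mapping is a random permutation);
#' participants with fewer visits are assigned to a random subset of
#' distinct partitions.
#'
#' @param cohort a `cohort_table`-shaped data.frame with `participant_id`
#'   and `visit` columns.
#' @param k number of partitions (default 5).
#' @param seed integer seed for the random assignment.
#' @return the cohort with an integer `partition` column added.
#' @export
partition_cohort <- function(cohort, k = 5, seed = 1L) {
  stopifnot(all(c("participant_id", "visit") %in% names(cohort)))
  set.seed(as.integer(seed))
  sp <- split(seq_len(nrow(cohort)), cohort$participant_id)
  part <- integer(nrow(cohort))
  for (rows in sp) {
    v <- length(rows)
    if (v > k) stop("participant with more than ", k, " visit records")
    part[rows] <- if (v == k) sample.int(k) else sample.int(k, v)
  }
  cohort$partition <- part
  cohort
}

#' Bootstrap confidence interval for the nearest-neighbour ROC(t) AUC
#'
#' The point estimate comes from the original sample; participants are
#' resampled with replacement `B` times and the 2.5th/97.5th percentiles
#' of the replicate AUCs form the percentile CI.  Replicates with no
#' events by the horizon are skipped (count returned).
#'
#' @param marker,time,status,horizon,span as in [roc_t_nn()]; `span`
#'   defaults to [span_from_n()] of the original sample size and is held
#'   fixed across replicates.
#' @param B bootstrap replicates (default 500); `B = 0` skips the CI.
#' @param seed integer seed.
#' @param ids optional participant ids; resampling is by unique id so
#'   repeated records of one participant move together.
#' @return list: `auc`, `lower`, `upper`, `n_events`, `n`, `span`,
#'   `B_used`, `B_skipped`.
#' @export
bootstrap_auc <- function(marker, time, status, horizon, span = NULL,
                          B = 500, seed = 1L, ids = NULL) {
  n <- length(marker)
  if (is.null(span)) span <- span_from_n(n)
  point <- roc_t_nn(marker, time, status, horizon, span)
  if (B == 0)
    return(list(auc = point$auc, lower = NA_real_, upper = NA_real_,
                n_events = point$n_events, n = n, span = span,
                B_used = 0L, B_skipped = 0L))
  set.seed(as.integer(seed))
  if (is.null(ids)) ids <- seq_len(n)
  uid <- unique(ids)
  idx_by_id <- split(seq_len(n), match(ids, uid))
  aucs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    pick <- sample.int(length(uid), replace = TRUE)
    rows <- unlist(idx_by_id[pick], use.names = FALSE)
    aucs[b] <- tryCatch(
      roc_t_nn(marker[rows], time[rows], status[rows], horizon, span)$auc,
      error = function(e) NA_real_)
  }
  used <- sum(!is.na(aucs))
  if (used == 0) stop("all bootstrap replicates inestimable at horizon")
  ci <- quantile(aucs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(auc = point$auc, lower = ci[1], upper = ci[2],
       n_events = point$n_events, n = n, span = span,
       B_used = as.integer(used), B_skipped = as.integer(B - used))
}

#' Horizon-by-horizon predictive accuracy of a marker with 5-partition
#' internal validation
#'
#' For the chosen outcome the competing death is treated as censoring at
#' its time.  The cohort is divided into `k` non-overlapping partitions
#' ([partition_cohort()]); within each partition and at each horizon the
#' nearest-neighbour ROC(t) AUC and its bootstrap percentile CI are
#' computed (span from the partition's record count), and point estimates
#' and CI bounds are averaged across the estimable partitions to give the
#' aggregate row.
#'
#' @param cohort a `cohort_table`-shaped data.frame.
#' @param marker_name column to evaluate.
#' @param outcome `"SCD"` (event code 1) or `"nonSCD"` (event code 2).
#' @param horizons years (default 3, 6, 9 months and 1, 2, 3, 5, 10, 15
#'   years).
#' @param k number of partitions.
#' @param B bootstrap replicates per partition-horizon (`B = 0`: point
#'   estimates only).
#' @param seed integer seed driving partitioning and all bootstraps.
#' @param span_method passed to [span_from_n()].
#' @return data.frame, one row per horizon x (partition or "aggregate"):
#'   `marker`, `outcome`, `horizon`, `partition`, `auc`, `lower`, `upper`,
#'   `n_events`, `n`.
#' @export
evaluate_marker <- function(cohort, marker_name, outcome = c("SCD", "nonSCD"),
                            horizons = c(0.25, 0.5, 0.75, 1, 2, 3, 5, 10, 15),
                            k = 5, B = 500, seed = 1L,
                            span_method = "percent_cuberoot") {
  outcome <- match.arg(outcome)
  if (!marker_name %in% names(cohort))
    stop("marker column not found: ", marker_name)
  code <- if (outcome == "SCD") 1L else 2L
  status <- as.integer(cohort$event == code)
  part <- partition_cohort(cohort, k = k, seed = seed)$partition

  out <- list()
  for (hi in seq_along(horizons)) {
    hz <- horizons[hi]
    per <- vector("list", k)
    for (pt in seq_len(k)) {
      rows <- which(part == pt)
      span <- span_from_n(length(rows), method = span_method)
      res <- tryCatch(
        bootstrap_auc(cohort[[marker_name]][rows],
                      cohort$time_to_event_years[rows], status[rows],
                      hz, span = span, B = B,
                      seed = as.integer(seed) + 1000L * pt + hi,
                      ids = cohort$participant_id[rows]),
        error = function(e) NULL)
      per[[pt]] <- if (is.null(res)) {
        data.frame(marker = marker_name, outcome = outcome, horizon = hz,
                   partition = as.character(pt), auc = NA_real_,
                   lower = NA_real_, upper = NA_real_, n_events = 0L,
                   n = length(rows))
      } else {
        data.frame(marker = marker_name, outcome = outcome, horizon = hz,
                   partition = as.character(pt), auc = res$auc,
                   lower = res$lower, upper = res$upper,
                   n_events = res$n_events, n = res$n)
      }
    }
    per <- do.call(rbind, per)
    est <- per[!is.na(per$auc), , drop = FALSE]
    agg <- data.frame(marker = marker_name, outcome = outcome, horizon = hz,
                      partition = "aggregate",
                      auc = if (nrow(est)) mean(est$auc) else NA_real_,
                      lower = if (nrow(est)) mean(est$lower) else NA_real_,
                      upper = if (nrow(est)) mean(est$upper) else NA_real_,
                      n_events = sum(per$n_events), n = sum(per$n))
    if (nrow(est) < k)
      message("horizon ", hz, " y: ", k - nrow(est),
              " partition(s) inestimable, aggregated over the rest")
    out[[hi]] <- rbind(per, agg)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
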