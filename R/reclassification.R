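#' Fit a logistic risk model and return in-sample predicted probabilities
#'
#' Maximum-likelihood logistic regression via [stats::glm()] (IWLS,
#' tolerance 1e-8, up to 50 iterations).  Quasi-complete separation is
#' flagged with a warning when any coefficient exceeds 15 in absolute
#' value.
#'
#' @param y binary 0/1 outcome.
#' @param X data.frame or matrix of covariates.
#' @return list: `p` (in-sample predicted probabilities), `fit` (the glm
#'   object), `separation` (logical flag).
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (sum(y) == 0 || sum(y) == length(y))
    stop("need at least one event and one non-event")
  df <- as.data.frame(X)
  df$.y <- y
  fit <- glm(.y ~ ., data = df, family = binomial(),
             control = list(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) stop("logistic fit did not converge")
  sep <- any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)
  if (sep) warning("possible separation: |coefficient| > 15")
  list(p = as.numeric(fitted(fit)), fit = fit, separation = sep)
}

check_reclass_inputs <- function(p_old, p_new, y) {
  stopifnot(length(p_old) == length(y), length(p_new) == length(y))
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("need at least one event and one non-event")
}

#' Integrated discrimination improvement
#'
#' `IDI = [mean(p_new | y=1) - mean(p_old | y=1)] -
#'        [mean(p_new | y=0) - mean(p_old | y=0)]`,
#' the change in discrimination slope between nested risk models; equals
#' the improvement in average sensitivity plus average specificity.  The
#' p-value is the asymptotic paired z-test on the per-subject probability
#' differences (Pencina et al. 2008).
#'
#' @param p_old,p_new predicted probabilities from the baseline and
#'   extended models.
#' @param y binary outcome.
#' @return list: `idi`, `se`, `z`, `p_value`.
#' @export
idi <- function(p_old, p_new, y) {
  check_reclass_inputs(p_old, p_new, y)
  d <- p_new - p_old
  d1 <- d[y == 1]; d0 <- d[y == 0]
  est <- mean(d1) - mean(d0)
  se <- sqrt(var(d1) / length(d1) + var(d0) / length(d0))
  z <- if (is.na(se) || se == 0) { if (est == 0) 0 else Inf } else est / se
  p <- if (is.finite(z)) 2 * pnorm(-abs(z)) else 0
  if (est == 0 && (is.na(se) || se == 0)) p <- 1
  list(idi = est, se = se, z = z, p_value = p)
}

#' Category-free (continuous) net reclassification improvement
#'
#' `NRI = [P(up | y=1) - P(down | y=1)] + [P(down | y=0) - P(up | y=0)]`
#' where "up"/"down" is any increase/decrease of the predicted
#' probability; range \[-2, 2\].  The p-value uses the standard
#' two-proportion z construction on the event and non-event components.
#'
#' @inheritParams idi
#' @return list: `nri`, `se`, `z`, `p_value`.
#' @export
nri_category_free <- function(p_old, p_new, y) {
  check_reclass_inputs(p_old, p_new, y)
  up <- p_new > p_old; down <- p_new < p_old
  nri_part <- function(sel) {
    n <- sum(sel)
    pu <- mean(up[sel]); pd <- mean(down[sel])
    c(est = pu - pd, var = (pu + pd - (pu - pd)^2) / n)
  }
  e <- nri_part(y == 1); ne <- nri_part(y == 0)
  # net events up plus net non-events down
  est <- e["est"] - ne["est"]
  se <- sqrt(e["var"] + ne["var"])
  z <- if (se == 0) { if (est == 0) 0 else Inf } else est / se
  p <- if (se == 0 && est == 0) 1 else 2 * pnorm(-abs(z))
  list(nri = unname(est), se = unname(se), z = unname(z), p_value = unname(p))
}

#' Two-category net reclassification improvement at a risk threshold
#'
#' Subjects are classed low/intermediate vs. high risk by `threshold` on
#' each model's predicted probability; the NRI counts net upward crossings
#' among events plus net downward crossings among non-events.  Also
#' reports the events reclassified upward as a "k/n (percent)" string.
#'
#' @inheritParams idi
#' @param threshold high-risk probability cutoff in (0, 1) (0.25 for
#'   short prediction windows, 0.10 for windows of a year and beyond).
#' @return list: `nri`, `se`, `z`, `p_value`, `threshold`, `events_up`,
#'   `events_down`, `n_events`, `events_up_label`.
#' @export
nri_two_category <- function(p_old, p_new, y, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  check_reclass_inputs(p_old, p_new, y)
  hi_old <- p_old >= threshold; hi_new <- p_new >= threshold
  up <- !hi_old & hi_new; down <- hi_old & !hi_new
  nri_part <- function(sel) {
    n <- sum(sel)
    pu <- mean(up[sel]); pd <- mean(down[sel])
    c(est = pu - pd, var = (pu + pd - (pu - pd)^2) / n)
  }
  e <- nri_part(y == 1); ne <- nri_part(y == 0)
  # net events up plus net non-events down
  est <- unname(e["est"] - ne["est"])
  se <- sqrt(unname(e["var"] + ne["var"]))
  z <- if (se == 0) { if (est == 0) 0 else Inf } else est / se
  p <- if (se == 0 && est == 0) 1 else 2 * pnorm(-abs(z))
  k <- sum(up & y == 1); n1 <- sum(y == 1)
  list(nri = est, se = se, z = z, p_value = p, threshold = threshold,
       events_up = k, events_down = sum(down & y == 1), n_events = n1,
       events_up_label = if (k == 0) "0" else
         sprintf("%d/%d (%.0f%%)", k, n1, 100 * k / n1))
}

#' Default prediction windows and high-risk thresholds
#'
#' Six landmark windows after the ECG (in days): 1-90, 91-180, 181-365,
#' 366-730, 731-1825, and beyond 5 years, with high-risk threshold 0.25
#' for the sub-year windows and 0.10 thereafter.
#'
#' @return data.frame with `label`, `start_days`, `end_days`, `threshold`.
#' @export
default_windows <- function() {
  data.frame(label = c("1-90 d", "91-180 d", "181-365 d", "365-730 d",
                       "731-1825 d", ">5 years"),
             start_days = c(0, 90, 180, 365, 730, 1825),
             end_days = c(90, 180, 365, 730, 1825, Inf),
             threshold = c(0.25, 0.25, 0.25, 0.10, 0.10, 0.10))
}

#' Landmark risk sets for windowed binary outcomes
#'
#' For each prediction window, the risk set is the subjects still at risk
#' (no event or censoring) at the window start; `y = 1` if the target
#' event occurred inside the window, subjects censored (or lost to the
#' competing death) inside the window without the target event are
#' dropped, and subjects surviving past the window end are controls.
#'
#' @param cohort `cohort_table`-shaped data.frame (times in years).
#' @param outcome `"SCD"` (event code 1) or `"nonSCD"` (code 2).
#' @param windows as [default_windows()].
#' @return named list of data.frames (one per non-empty window), each the
#'   cohort rows of the risk set plus `y` and `threshold`; empty windows
#'   are skipped with a message.
#' @export
window_risk_sets <- function(cohort, outcome = c("SCD", "nonSCD"),
                             windows = default_windows()) {
  outcome <- match.arg(outcome)
  code <- if (outcome == "SCD") 1L else 2L
  t_days <- cohort$time_to_event_years * 365.25
  is_target <- cohort$event == code
  out <- list()
  for (w in seq_len(nrow(windows))) {
    at_risk <- t_days > windows$start_days[w]
    ev_in <- at_risk & is_target & t_days <= windows$end_days[w]
    # within-window censorings are dropped from bounded windows; in the
    # final open-ended window every event-free at-risk subject is a control
    drop <- at_risk & !is_target & t_days <= windows$end_days[w] &
      is.finite(windows$end_days[w])
    keep <- at_risk & !drop
    if (!any(keep) || !any(ev_in)) {
      message("window ", windows$label[w], ": empty or event-free risk set, skipped")
      next
    }
    d <- cohort[keep, , drop = FALSE]
    d$y <- as.integer(ev_in[keep])
    d$threshold <- windows$threshold[w]
    out[[windows$label[w]]] <- d
  }
  out
}

#' Incremental value of one marker over the clinical risk model, by window
#'
#' For each landmark window, fits the clinical logistic model and the
#' clinical + marker model on the window risk set and reports the absolute
#' IDI, the events reclassified upward across the window's high-risk
#' threshold, and the category-free NRI, each with its p-value.
#'
#' @param cohort `cohort_table`-shaped data.frame.
#' @param marker_name marker column to add to the clinical model.
#' @param outcome `"SCD"` or `"nonSCD"`.
#' @param covariates clinical covariate columns for the baseline model.
#' @param windows as [default_windows()].
#' @return data.frame, one row per window: `outcome`, `marker`, `window`,
#'   `threshold`, `n`, `n_events`, `idi`, `idi_p`, `events_up_label`,
#'   `nri_cf`, `nri_cf_p`, `nri_2cat`, `nri_2cat_p`, `separation`.
#' @export
reclass_analysis <- function(cohort, marker_name, outcome = c("SCD", "nonSCD"),
                             covariates = c("age", "sex", "race", "diabetes",
                                            "hypertension", "chd", "stroke"),
                             windows = default_windows()) {
  outcome <- match.arg(outcome)
  if (!marker_name %in% names(cohort))
    stop("marker column not found: ", marker_name)
  sets <- window_risk_sets(cohort, outcome, windows)
  rows <- lapply(names(sets), function(lab) {
    d <- sets[[lab]]
    if (sum(d$y) < 2) return(NULL)
    old <- fit_logistic(d$y, d[, covariates, drop = FALSE])
    new <- fit_logistic(d$y, d[, c(covariates, marker_name), drop = FALSE])
    i <- idi(old$p, new$p, d$y)
    ncf <- nri_category_free(old$p, new$p, d$y)
    n2 <- nri_two_category(old$p, new$p, d$y, d$threshold[1])
    data.frame(outcome = outcome, marker = marker_name, window = lab,
               threshold = d$threshold[1], n = nrow(d), n_events = sum(d$y),
               idi = i$idi, idi_p = i$p_value,
               events_up_label = n2$events_up_label,
               nri_cf = ncf$nri, nri_cf_p = ncf$p_value,
               nri_2cat = n2$nri, nri_2cat_p = n2$p_value,
               separation = old$separation || new$separation)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
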