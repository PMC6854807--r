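#' Hanley-McNeil standard error of an AUC
#'
#' Binormal-exponential approximation to the standard error of an AUC
#' estimated from `n_events` cases and `n_nonevents` controls (Hanley &
#' McNeil, Radiology 1982): with `A` the AUC, `Q1 = A / (2 - A)`,
#' `Q2 = 2 A^2 / (1 + A)`,
#' `SE = sqrt((A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)) / (n1 n2))`.
#'
#' @param auc AUC in (0, 1).
#' @param n_events,n_nonevents case and control counts (>= 1).
#' @return standard error of the AUC.
#' @export
hanley_mcneil_se <- function(auc, n_events, n_nonevents) {
  if (any(auc <= 0 | auc >= 1)) stop("auc must be in (0, 1)")
  if (any(n_events < 1 | n_nonevents < 1)) stop("counts must be >= 1")
  A <- auc
  Q1 <- A / (2 - A)
  Q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n_events - 1) * (Q1 - A^2) +
          (n_nonevents - 1) * (Q2 - A^2)) / (n_events * n_nonevents))
}

#' Expected confidence interval for an AUC at a given sample size
#'
#' Analytic expected two-sided CI around an observed AUC for given event
#' and non-event counts, from the Hanley-McNeil standard error: the width
#' is `2 * z * SE` with `z` the full-precision normal quantile, and the
#' bounds are symmetric (`auc -/+ width / 2`, not clipped to \[0, 1\]).
#' Used to judge whether an estimated ROC(t) AUC at a sparse horizon was
#' adequately powered.
#'
#' @param auc observed AUC in (0, 1); vectorized.
#' @param n_events,n_nonevents case and control counts.
#' @param level confidence level in (0, 1), default 0.95.
#' @return data.frame of class `auc_power_result` with columns `auc`,
#'   `n_events`, `n_nonevents`, `se`, `width`, `lower`, `upper`.
#' @export
expected_ci <- function(auc, n_events, n_nonevents, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  se <- hanley_mcneil_se(auc, n_events, n_nonevents)
  z <- qnorm((1 + level) / 2)
  width <- 2 * z * se
  out <- data.frame(auc = auc, n_events = n_events,
                    n_nonevents = n_nonevents, se = se, width = width,
                    lower = auc - width / 2, upper = auc + width / 2)
  class(out) <- c("auc_power_result", class(out))
  out
}
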