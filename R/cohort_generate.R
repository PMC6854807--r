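#' Parameters for the competing-risk cohort generator
#'
#' Participants carry a latent standard-normal marker level; two competing
#' death modes (sudden cardiac death, SCD, and non-SCD death) have
#' cause-specific exponential hazards `lambda * exp(beta * z + covariate
#' effects)` in events per person-year, with an independent exponential
#' censoring process and administrative censoring.  Each participant can
#' contribute up to five repeated visits; the marker follows a random walk
#' across visits around its baseline value, and each visit record measures
#' time from that visit's ECG to the first subsequent event or censoring.
#'
#' Defaults emulate a large middle-aged epidemiological cohort: visit
#' spacing 3 years, ~25 years of follow-up, SCD rarer than non-SCD death.
#'
#' @param n_participants number of participants.
#' @param n_visits visits per participant, 1-5.
#' @param visit_spacing years between consecutive visits.
#' @param baseline_hazard_scd,baseline_hazard_nonscd cause-specific
#'   baseline hazards, events per person-year.
#' @param beta_scd,beta_nonscd log-hazard per SD of the marker for each
#'   cause.
#' @param censor_rate independent censoring hazard, events per
#'   person-year (0 disables random censoring).
#' @param admin_censor_time administrative censoring, years from baseline
#'   (may be `Inf`).
#' @param marker_visit_drift_sd SD of the per-visit random-walk increment
#'   of the marker, in marker SD units.
#' @param covariate_effects named numeric log-hazard effects for the
#'   clinical covariates (applied, centred, to both cause-specific
#'   hazards).
#' @param seed integer seed.
#' @return validated parameter list of class `surv_gen_params`.
#' @export
surv_gen_params <- function(n_participants = 1000, n_visits = 5,
                            visit_spacing = 3,
                            baseline_hazard_scd = 0.003,
                            baseline_hazard_nonscd = 0.004,
                            beta_scd = 0, beta_nonscd = 0,
                            censor_rate = 0.01, admin_censor_time = 25,
                            marker_visit_drift_sd = 0.2,
                            covariate_effects = c(age = 0.04, sex = -0.4,
                                                  race = -0.2, diabetes = 0.5,
                                                  hypertension = 0.4,
                                                  chd = 0.7, stroke = 0.5),
                            seed = 1L) {
  p <- list(n_participants = as.integer(n_participants),
            n_visits = as.integer(n_visits), visit_spacing = visit_spacing,
            baseline_hazard_scd = baseline_hazard_scd,
            baseline_hazard_nonscd = baseline_hazard_nonscd,
            beta_scd = beta_scd, beta_nonscd = beta_nonscd,
            censor_rate = censor_rate, admin_censor_time = admin_censor_time,
            marker_visit_drift_sd = marker_visit_drift_sd,
            covariate_effects = covariate_effects, seed = as.integer(seed))
  if (p$n_participants < 1) stop("need at least one participant")
  if (p$n_visits < 1 || p$n_visits > 5) stop("n_visits must be in [1, 5]")
  if (min(p$baseline_hazard_scd, p$baseline_hazard_nonscd, p$censor_rate) < 0)
    stop("hazard and censoring rates must be non-negative")
  if (p$visit_spacing < 0 || p$admin_censor_time <= 0)
    stop("visit_spacing must be >= 0 and admin_censor_time > 0")
  if (p$marker_visit_drift_sd < 0) stop("marker_visit_drift_sd must be >= 0")
  class(p) <- "surv_gen_params"
  p
}

#' Generate a longitudinal competing-risk cohort
#'
#' See [surv_gen_params()].  Event coding in the returned table: 0 =
#' censored, 1 = SCD, 2 = non-SCD death; for a cause-specific analysis the
#' competing death is treated as censoring at its time (this is how
#' [evaluate_marker()] consumes the table).  Visits at or after the
#' event/censoring time do not produce records.
#'
#' @param params a `surv_gen_params`.
#' @return data.frame of class `cohort_table` with columns
#'   `participant_id`, `visit`, `ecg_time_years`, `time_to_event_years`,
#'   `event`, `age`, `sex`, `race`, `diabetes`, `hypertension`, `chd`,
#'   `stroke`, `marker`.
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "surv_gen_params")) params <- do.call(surv_gen_params, params)
  p <- params
  set.seed(p$seed)
  n <- p$n_participants

  age <- rnorm(n, 54.2, 5.8)
  sex <- rbinom(n, 1, 0.55)          # 1 = female
  race <- rbinom(n, 1, 0.73)         # 1 = white
  diabetes <- rbinom(n, 1, 0.12)
  hypertension <- rbinom(n, 1, 0.35)
  chd <- rbinom(n, 1, 0.05)
  stroke <- rbinom(n, 1, 0.017)

  ce <- p$covariate_effects
  cov_lp <- ce[["age"]] * (age - 54.2) + ce[["sex"]] * sex +
    ce[["race"]] * race + ce[["diabetes"]] * diabetes +
    ce[["hypertension"]] * hypertension + ce[["chd"]] * chd +
    ce[["stroke"]] * stroke

  z <- rnorm(n)                      # z-scored baseline marker
  lam_scd <- p$baseline_hazard_scd * exp(p$beta_scd * z + cov_lp)
  lam_non <- p$baseline_hazard_nonscd * exp(p$beta_nonscd * z + cov_lp)

  t_scd <- ifelse(lam_scd > 0, rexp(n) / lam_scd, Inf)
  t_non <- ifelse(lam_non > 0, rexp(n) / lam_non, Inf)
  t_cen <- if (p$censor_rate > 0) rexp(n) / p$censor_rate else rep(Inf, n)
  t_adm <- p$admin_censor_time

  t_obs <- pmin(t_scd, t_non, t_cen, t_adm)
  event <- integer(n)
  event[t_obs == t_scd] <- 1L
  event[t_obs == t_non & event == 0L] <- 2L

  # marker random walk across visits
  marker <- matrix(z, n, p$n_visits)
  if (p$n_visits > 1)
    for (v in 2:p$n_visits)
      marker[, v] <- marker[, v - 1] +
        rnorm(n, 0, p$marker_visit_drift_sd)

  rows <- vector("list", p$n_visits)
  for (v in seq_len(p$n_visits)) {
    tv <- (v - 1) * p$visit_spacing
    alive <- which(t_obs > tv)
    rows[[v]] <- data.frame(
      participant_id = alive, visit = v, ecg_time_years = tv,
      time_to_event_years = t_obs[alive] - tv, event = event[alive],
      age = age[alive] + tv, sex = sex[alive], race = race[alive],
      diabetes = diabetes[alive], hypertension = hypertension[alive],
      chd = chd[alive], stroke = stroke[alive],
      marker = marker[alive, v])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$visit), ]
  rownames(out) <- NULL
  class(out) <- c("cohort_table", class(out))
  out
}

#' Generate a single-visit binormal case-control survival cohort
#'
#' Calibration fixture with a known true AUC: a fraction `prevalence` of
#' participants experience the event inside `horizon` years (event times
#' uniform on (0, horizon)), the rest later; the marker is standard normal
#' in non-cases and shifted by `delta` SD in cases, so the true
#' cumulative-case AUC at `horizon` is `pnorm(delta / sqrt(2))`
#' ([binormal_true_auc()]).  Optional light independent exponential
#' censoring.
#'
#' @param n participants (one visit each).
#' @param delta case-control marker separation, SD units.
#' @param prevalence event fraction by `horizon`.
#' @param horizon years.
#' @param censor_rate censoring hazard per person-year (0 = none).
#' @param seed integer seed.
#' @return `cohort_table`-shaped data.frame (event: 1 = event,
#'   0 = censored).
#' @export
generate_binormal_cohort <- function(n, delta, prevalence = 0.5, horizon = 1,
                                     censor_rate = 0, seed = 1L) {
  set.seed(as.integer(seed))
  case <- rbinom(n, 1, prevalence)
  marker <- rnorm(n) + delta * case
  t_ev <- ifelse(case == 1, runif(n) * horizon,
                 horizon * (1.001 + rexp(n, 0.5)))
  t_cen <- if (censor_rate > 0) rexp(n) / censor_rate else rep(Inf, n)
  time <- pmin(t_ev, t_cen)
  event <- as.integer(t_ev <= t_cen)
  data.frame(participant_id = seq_len(n), visit = 1L, ecg_time_years = 0,
             time_to_event_years = time, event = event, marker = marker)
}

#' True binormal AUC for a given case-control separation
#'
#' Closed-form AUC when case and control marker distributions are
#' unit-variance Gaussians separated by `delta` SD:
#' `Phi(delta / sqrt(2))`.
#'
#' @param delta separation in SD units.
#' @return probability in \[0, 1\].
#' @export
binormal_true_auc <- function(delta) {
  stopifnot(is.finite(delta))
  pnorm(delta / sqrt(2))
}
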