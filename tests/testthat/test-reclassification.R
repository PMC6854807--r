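test_that("logistic fit recovers closed-form saturated probabilities", {
  # intercept-only: all probabilities equal the event rate
  y <- c(1, 1, 0, 0, 0, 1)
  f <- fit_logistic(y, data.frame(x = rep(1, 6)))
  expect_equal(f$p, rep(mean(y), 6), tolerance = 1e-6)
  # single binary covariate: probabilities equal the cell event rates
  x <- c(0, 0, 0, 0, 1, 1, 1, 1)
  y2 <- c(1, 0, 0, 0, 1, 1, 1, 0)
  f2 <- fit_logistic(y2, data.frame(x = x))
  expect_equal(f2$p[x == 0], rep(0.25, 4), tolerance = 1e-6)
  expect_equal(f2$p[x == 1], rep(0.75, 4), tolerance = 1e-6)
})

test_that("perfectly separable data triggers the separation warning", {
  # tight-margin separable data forces the slope to diverge
  y <- rep(c(0, 1), each = 10)
  x <- c(-(10:1) / 10, (1:10) / 10)
  w <- capture_warnings(f <- fit_logistic(y, data.frame(x = x)))
  expect_true(any(grepl("separation", w)))
  expect_true(f$separation)
})

test_that("idi and nri hand-computed examples and identities", {
  y <- c(1, 0)
  expect_equal(idi(c(0.5, 0.5), c(0.7, 0.3), y)$idi, 0.4)
  expect_equal(nri_category_free(c(0.5, 0.5), c(0.7, 0.3), y)$nri, 2)
  # identical models: exact zeros with p = 1
  set.seed(41)
  p <- runif(50); yy <- rbinom(50, 1, p)
  yy[1] <- 1; yy[2] <- 0
  expect_equal(idi(p, p, yy)$idi, 0)
  expect_equal(idi(p, p, yy)$p_value, 1)
  expect_equal(nri_category_free(p, p, yy)$nri, 0)
  # label swap negates the IDI
  p2 <- pmin(1, p + runif(50, 0, 0.2))
  expect_equal(idi(p, p2, yy)$idi, -idi(p, p2, 1 - yy)$idi, tolerance = 1e-12)
  # maximum NRI: every event up, every non-event down
  up <- ifelse(yy == 1, p + 0.01, p - 0.01)
  expect_equal(nri_category_free(p, up, yy)$nri, 2)
})

test_that("idi equals the difference of discrimination slopes", {
  set.seed(42)
  n <- 300
  x <- rnorm(n); m <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + x + 0.5 * m))
  p_old <- fit_logistic(y, data.frame(x))$p
  p_new <- fit_logistic(y, data.frame(x, m))$p
  slope <- function(p) mean(p[y == 1]) - mean(p[y == 0])
  expect_equal(idi(p_old, p_new, y)$idi, slope(p_new) - slope(p_old),
               tolerance = 1e-12)
})

test_that("two-category NRI counts threshold crossings as printed", {
  # 11 events, 2 cross upward at the 25% threshold, nothing else moves
  y <- c(rep(1, 11), rep(0, 20))
  p_old <- c(rep(0.20, 11), rep(0.05, 20))
  p_new <- p_old
  p_new[1:2] <- 0.30
  r <- nri_two_category(p_old, p_new, y, threshold = 0.25)
  expect_equal(r$events_up, 2)
  expect_equal(r$events_up_label, "2/11 (18%)")
  expect_equal(r$nri, 2 / 11, tolerance = 1e-12)
  # threshold nobody crosses
  r0 <- nri_two_category(p_old, p_new, y, threshold = 0.9)
  expect_equal(r0$nri, 0)
  expect_equal(r0$events_up_label, "0")
  # swapping models exchanges up and down movers
  r_sw <- nri_two_category(p_new, p_old, y, threshold = 0.25)
  expect_equal(r_sw$events_down, r$events_up)
})

test_that("window risk sets match brute-force enumeration", {
  p <- surv_gen_params(n_participants = 1000, n_visits = 1,
                       baseline_hazard_scd = 0.02,
                       baseline_hazard_nonscd = 0.02, seed = 77)
  d <- generate_cohort(p)
  sets <- window_risk_sets(d, "SCD")
  wins <- default_windows()
  t_days <- d$time_to_event_years * 365.25
  for (w in seq_len(nrow(wins))) {
    lab <- wins$label[w]
    if (!lab %in% names(sets)) next
    at_risk <- t_days > wins$start_days[w]
    y_brute <- d$event == 1 & at_risk & t_days <= wins$end_days[w]
    drop_brute <- at_risk & d$event != 1 & t_days <= wins$end_days[w] &
      is.finite(wins$end_days[w])
    expect_equal(nrow(sets[[lab]]), sum(at_risk & !drop_brute))
    expect_equal(sum(sets[[lab]]$y), sum(y_brute))
    expect_equal(sets[[lab]]$threshold[1], wins$threshold[w])
  }
  # spec-level single-subject bookkeeping
  one <- data.frame(participant_id = 1:4, visit = 1,
                    time_to_event_years = c(100 / 365.25, 30 / 365.25, 3, 10),
                    event = c(1, 0, 2, 0), age = 50, sex = 0, race = 1,
                    diabetes = 0, hypertension = 0, chd = 0, stroke = 0,
                    marker = 0)
  s1 <- suppressMessages(window_risk_sets(one, "SCD"))
  # SCD at day 100: an event in the 91-180 d window ...
  expect_true(1 %in% s1[["91-180 d"]]$participant_id &&
                s1[["91-180 d"]]$y[s1[["91-180 d"]]$participant_id == 1] == 1)
  # ... and absent from every later window
  for (lab in intersect(c("181-365 d", "365-730 d"), names(s1)))
    expect_false(1 %in% s1[[lab]]$participant_id)
  # censored at day 30: dropped from the first window, at risk nowhere else
  for (lab in names(s1))
    expect_false(2 %in% s1[[lab]]$participant_id)
})

test_that("reclass_analysis produces a coherent table on an informative marker", {
  p <- surv_gen_params(n_participants = 3000, n_visits = 1, beta_scd = 0.8,
                       baseline_hazard_scd = 0.01,
                       baseline_hazard_nonscd = 0.01, seed = 55)
  d <- generate_cohort(p)
  res <- suppressMessages(reclass_analysis(d, "marker", "SCD"))
  expect_true(nrow(res) >= 3)
  expect_true(all(res$nri_cf >= -2 & res$nri_cf <= 2))
  expect_true(all(res$idi_p >= 0 & res$idi_p <= 1, na.rm = TRUE))
  # an informative marker should improve discrimination in the long windows
  expect_gt(mean(res$idi), 0)
})
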