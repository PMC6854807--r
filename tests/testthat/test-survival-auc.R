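test_that("span follows the cube-root-percent rule", {
  expect_equal(span_from_n(1000), 0.025)
  expect_equal(span_from_n(8), 0.005)
  expect_equal(span_from_n(3000), 0.25 * 3000^(1 / 3) / 100)
  expect_equal(span_from_n(1000, method = "power"), 0.25 * 1000^(-0.2))
  expect_error(span_from_n(1), ">= 2")
})

test_that("with no censoring the NN AUC matches pairwise concordance", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(60:200, 1)
    m <- rnorm(n)
    tt <- rexp(n, 0.25 * exp(0.7 * m))
    ss <- rep(1L, n)
    hz <- quantile(tt, 0.4)
    auc <- roc_t_nn(m, tt, ss, hz)$auc
    expect_equal(auc, concordance_oracle(m, as.integer(tt <= hz)),
                 tolerance = 0.02)
  }
})

test_that("degenerate markers: complete ties give 0.5, perfect ordering ~1", {
  set.seed(22)
  tt <- rexp(100); ss <- rep(1L, 100)
  expect_equal(roc_t_nn(rep(3, 100), tt, ss, median(tt))$auc, 0.5)
  # marker = reversed event-time rank separates cases and controls exactly
  m <- rank(-tt)
  expect_gt(roc_t_nn(m, tt, ss, median(tt))$auc, 0.99)
})

test_that("no events by the horizon is inestimable", {
  expect_error(roc_t_nn(rnorm(50), runif(50, 5, 10), rep(1L, 50), 1),
               "inestimable")
})

test_that("AUC is invariant under monotone marker transforms and flips under negation", {
  set.seed(23)
  n <- 150
  m <- rnorm(n)
  tt <- rexp(n, 0.3 * exp(0.6 * m))
  ss <- rbinom(n, 1, 0.8)
  hz <- 1.5
  a0 <- roc_t_nn(m, tt, ss, hz)$auc
  expect_equal(roc_t_nn(exp(m), tt, ss, hz)$auc, a0, tolerance = 1e-10)
  expect_equal(roc_t_nn(rank(m), tt, ss, hz)$auc, a0, tolerance = 1e-10)
  expect_equal(roc_t_nn(-m, tt, ss, hz)$auc, 1 - a0, tolerance = 0.03)
})

test_that("partitioning is exhaustive, disjoint, and respects the 5-visit rule", {
  p <- surv_gen_params(n_participants = 100, n_visits = 5, censor_rate = 0,
                       admin_censor_time = Inf, seed = 3)
  d <- generate_cohort(p)
  full <- d[ave(d$participant_id, d$participant_id, FUN = length) == 5, ]
  pc <- partition_cohort(full, k = 5, seed = 1)
  # every record in exactly one partition
  expect_equal(sort(unique(pc$partition)), 1:5)
  expect_equal(nrow(pc), nrow(full))
  # each full participant appears exactly once per partition
  tab <- table(pc$participant_id, pc$partition)
  expect_true(all(tab == 1))
  # partitions of a 5-visit cohort have equal size
  expect_true(all(table(pc$partition) == length(unique(full$participant_id))))
})

test_that("participants with a single visit land in exactly one partition", {
  d <- data.frame(participant_id = 1:40, visit = 1)
  pc <- partition_cohort(d, k = 5, seed = 2)
  expect_equal(length(pc$partition), 40)
  expect_true(all(pc$partition %in% 1:5))
  d6 <- data.frame(participant_id = rep(1, 6), visit = 1:6)
  expect_error(partition_cohort(d6, k = 5), "more than 5")
})

test_that("bootstrap CI is deterministic given a seed and degenerate when AUC is 1", {
  set.seed(25)
  n <- 80
  m <- c(rnorm(40, 5), rnorm(40, -5))        # perfectly separated
  tt <- c(runif(40, 0, 1), runif(40, 2, 3))
  ss <- rep(1L, n)
  r1 <- bootstrap_auc(m, tt, ss, horizon = 1.5, B = 50, seed = 99)
  r2 <- bootstrap_auc(m, tt, ss, horizon = 1.5, B = 50, seed = 99)
  expect_identical(r1, r2)
  expect_gt(r1$lower, 0.99)
  expect_equal(r1$upper, 1, tolerance = 1e-9)
  # on an overlapping marker, different seeds give different replicate CIs
  m2 <- rnorm(n); tt2 <- rexp(n, 0.5 * exp(0.5 * m2)); ss2 <- rep(1L, n)
  b1 <- bootstrap_auc(m2, tt2, ss2, horizon = 1, B = 50, seed = 99)
  b2 <- bootstrap_auc(m2, tt2, ss2, horizon = 1, B = 50, seed = 100)
  expect_false(identical(b1$lower, b2$lower) && identical(b1$upper, b2$upper))
})

test_that("evaluate_marker returns one block per horizon and a sound aggregate", {
  d <- generate_binormal_cohort(600, delta = 1, prevalence = 0.4, horizon = 1,
                                seed = 5)
  res <- evaluate_marker(d, "marker", "SCD", horizons = c(0.5, 1), k = 5,
                         B = 30, seed = 7)
  expect_equal(nrow(res), 2 * 6)
  agg <- res[res$partition == "aggregate", ]
  per <- res[res$partition != "aggregate" & res$horizon == 1, ]
  expect_equal(agg$auc[agg$horizon == 1], mean(per$auc))
  expect_equal(agg$lower[agg$horizon == 1], mean(per$lower))
  expect_true(all(per$lower <= per$auc + 1e-9 & per$auc <= per$upper + 1e-9))
})

test_that("marker tied to SCD hazard only discriminates SCD, not non-SCD", {
  p <- surv_gen_params(n_participants = 1500, n_visits = 1, beta_scd = 1,
                       beta_nonscd = 0, baseline_hazard_scd = 0.02,
                       baseline_hazard_nonscd = 0.02, censor_rate = 0,
                       seed = 61)
  d <- generate_cohort(p)
  scd <- evaluate_marker(d, "marker", "SCD", horizons = 5, B = 0, seed = 1)
  non <- evaluate_marker(d, "marker", "nonSCD", horizons = 5, B = 0, seed = 1)
  a_scd <- scd$auc[scd$partition == "aggregate"]
  a_non <- non$auc[non$partition == "aggregate"]
  expect_gt(a_scd, 0.6)
  expect_lt(abs(a_non - 0.5), 0.08)
})
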