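test_that("vector algebra primitives match their definitions", {
  expect_equal(magnitude(c(3, 4, 0)), 5)
  expect_equal(magnitude(c(0, 0, 0)), 0)
  expect_equal(spatial_angle(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(spatial_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(spatial_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(spatial_angle(c(0, 0, 0), c(1, 0, 0)), "undefined angle")
  expect_equal(azimuth(c(1, 0, 0)), 0)
  expect_equal(azimuth(c(0, 0, 1)), 90)
  expect_equal(azimuth(c(-1, 0, 0)), 180)   # quadrant-aware, beyond plain arctan
  expect_error(azimuth(c(0, 1, 0)), "undefined azimuth")
  expect_equal(elevation(c(0, 1, 0)), 0)
  expect_equal(elevation(c(1, 0, 0)), 90)
  expect_equal(elevation(c(1, 1, 0), mode = "literal"), 45)
  sv <- svg_peak(spatial_vector(100, 0, 0), spatial_vector(0, 100, 0))
  expect_equal(unname(unclass(sv)), c(100, 100, 0), ignore_attr = TRUE)
  expect_equal(unname(unclass(svg_peak(c(5, -2, 1), c(-5, 2, -1)))),
               c(0, 0, 0), ignore_attr = TRUE)
})

test_that("angle properties: symmetry, scale invariance, range", {
  set.seed(11)
  for (i in 1:25) {
    a <- rnorm(3); b <- rnorm(3); s <- runif(1, 0.1, 50)
    ang <- spatial_angle(a, b)
    expect_gte(ang, 0); expect_lte(ang, 180)
    expect_equal(ang, spatial_angle(b, a))
    expect_equal(ang, spatial_angle(s * a, b), tolerance = 1e-10)
    expect_equal(elevation(a), elevation(s * a), tolerance = 1e-10)
  }
})

test_that("qtc follows Bazett", {
  expect_equal(qtc_bazett(400, 1000), 400)
  expect_equal(qtc_bazett(400, 640), 500)
  expect_equal(qtc_bazett(420, 800), 420 / sqrt(0.8), tolerance = 1e-12)
  expect_error(qtc_bazett(400, 0), "positive")
})

test_that("area integrals match the analytic/oversampled oracle", {
  # constant 1 uV on x over the 100-ms QRS window
  fx <- function(t) as.numeric(t >= 100 & t <= 200)
  beat <- make_beat(fx, function(t) 0 * t, function(t) 0 * t)
  av <- area_vectors(beat)
  expect_equal(unclass(av$qrs_area)[["x"]], 100, tolerance = 1e-9)
  # smooth random-ish beat vs. 10x Riemann oracle, within 0.5%
  fx <- function(t) 800 * exp(-((t - 150)^2) / 450) + 30 * sin(t / 40)
  fy <- function(t) 300 * exp(-((t - 330)^2) / 4000)
  fz <- function(t) -200 * exp(-((t - 150)^2) / 600) + 50 * cos(t / 60)
  beat <- make_beat(fx, fy, fz)
  av <- area_vectors(beat)
  sv <- svg_area(beat)
  t_on <- (beat$qrs_onset - 1) / beat$fs * 1000
  t_off <- (beat$qrs_offset - 1) / beat$fs * 1000
  t_end <- (beat$t_offset - 1) / beat$fs * 1000
  expect_equal(unclass(av$qrs_area)[["x"]],
               riemann_oracle(fx, t_on, t_off, beat$fs), tolerance = 0.005)
  expect_equal(unclass(av$t_area)[["y"]],
               riemann_oracle(fy, t_off, t_end, beat$fs), tolerance = 0.005)
  expect_equal(unclass(sv)[["z"]],
               riemann_oracle(fz, t_on, t_end, beat$fs), tolerance = 0.005)
  # QRS + T areas sum exactly to the full-window SVG area
  expect_equal(unclass(av$qrs_area) + unclass(av$t_area), unclass(sv),
               tolerance = 1e-9, ignore_attr = TRUE)
  # sign flip negates the areas
  beat_neg <- make_beat(function(t) -fx(t), function(t) -fy(t),
                        function(t) -fz(t))
  expect_equal(unclass(svg_area(beat_neg)), -unclass(sv), ignore_attr = TRUE)
})

test_that("zero-mean sinusoid over whole periods integrates to ~0", {
  f <- function(t) 100 * sin(2 * pi * (t - 100) / 50)  # 7 whole periods in 350 ms
  beat <- make_beat(f, function(t) 0 * t, function(t) 0 * t)
  expect_lt(abs(unclass(svg_area(beat))[["x"]]), 20)   # vs. amplitude scale 35000
})

test_that("sai_qrst: constant case, zero case, triangle inequality", {
  f1k <- function(t) rep(1000, length(t))
  beat <- make_beat(f1k, f1k, f1k, qrs_onset_ms = 100, t_offset_ms = 300)
  expect_equal(sai_qrst(beat), 600, tolerance = 1e-9)  # 3 x 1000 uV x 200 ms
  z <- function(t) 0 * t
  expect_equal(sai_qrst(make_beat(z, z, z)), 0)
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(3, 0, 400); ph <- runif(3, 50, 120)
    fs <- lapply(1:3, function(j) {
      force(j); function(t) a[j] * exp(-((t - 200)^2) / ph[j]^2)
    })
    b <- make_beat(fs[[1]], fs[[2]], fs[[3]])
    expect_gte(sai_qrst(b) + 1e-9, magnitude(svg_area(b)) / 1000)
  }
})

test_that("peak vectors: boundary, tie-break, and window errors", {
  ramp <- function(t) ifelse(t >= 100 & t <= 200, t - 100, 0)
  z <- function(t) 0 * t
  beat <- make_beat(ramp, z, z)
  pk <- peak_vectors(beat)
  expect_equal(unclass(pk$qrs_peak)[["x"]], 100)  # monotone VM peaks at qrs_offset
  # tie in VM resolves to the earliest sample
  flat <- function(t) ifelse(t >= 120 & t <= 180, 500, 0)
  beat2 <- make_beat(flat, z, z)
  pk2 <- peak_vectors(beat2)
  vm <- vector_magnitude(beat2)
  first_max <- min(which(vm[beat2$qrs_onset:beat2$qrs_offset] ==
                           max(vm[beat2$qrs_onset:beat2$qrs_offset])))
  expect_equal(unclass(pk2$qrs_peak)[["x"]], 500)
  expect_equal(first_max, 120 * beat2$fs / 1000 + 1 - beat2$qrs_onset + 1)
})

test_that("vector_magnitude equals the per-sample Euclidean norm", {
  set.seed(17)
  m <- matrix(rnorm(60), 20, 3)
  expect_equal(vector_magnitude(m),
               apply(m, 1, function(r) sqrt(sum(r^2))))
  expect_equal(vector_magnitude(matrix(c(3, 4, 0), 1, 3)), 5)
})

test_that("compute_geh homogeneity and polarity symmetries", {
  rec <- quick_record(qrs_peak_dir = c(25, 55), t_peak_dir = c(60, 75),
                      t_peak_mag = 600)
  g1 <- compute_geh(rec)
  rec2 <- rec; rec2$signal <- rec$signal * 2
  g2 <- compute_geh(rec2)
  expect_equal(g2$peak_qrst_angle, g1$peak_qrst_angle, tolerance = 1e-6)
  expect_equal(g2$area_qrst_angle, g1$area_qrst_angle, tolerance = 1e-6)
  expect_equal(g2$peak_svg_magnitude, 2 * g1$peak_svg_magnitude,
               tolerance = 1e-6)
  expect_equal(g2$area_svg_magnitude, 2 * g1$area_svg_magnitude,
               tolerance = 1e-6)
  expect_equal(g2$sai_qrst, 2 * g1$sai_qrst, tolerance = 1e-6)
  # X-polarity flip mirrors the azimuth, leaves the QRS-T angle alone
  rec3 <- quick_record(qrs_peak_dir = c(180 - 25, 55),
                       t_peak_dir = c(180 - 60, 75), t_peak_mag = 600)
  g3 <- compute_geh(rec3)
  expect_equal(g3$peak_qrst_angle, g1$peak_qrst_angle, tolerance = 0.1)
  expect_equal(abs(g3$peak_svg_azimuth - 90) , abs(90 - g1$peak_svg_azimuth),
               tolerance = 0.1)
})
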