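test_that("compartment means are exact on a hand-built toy raster", {
  # 2x2 frames: two vascular pixels of value 10, two tissue pixels of value 2
  f <- matrix(c(10, 10, 2, 2), 2, 2)
  m <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  sq <- toy_sequence(list(f, f * 2), times = c(0, 20))
  tr <- extract_traces(sq, m, tissue_margin_px = 0)
  expect_equal(tr$vascular_mean, c(10, 20))
  expect_equal(tr$tissue_mean, c(2, 4))

  u <- matrix(7, 4, 4)
  squ <- toy_sequence(list(u), times = 0)
  mu <- matrix(c(rep(TRUE, 8), rep(FALSE, 8)), 4, 4)
  tru <- extract_traces(squ, mu, tissue_margin_px = 0)
  expect_equal(tru$vascular_mean, 7)
  expect_equal(tru$tissue_mean, 7)

  expect_error(extract_traces(squ, matrix(FALSE, 4, 4)), "empty vascular")
  expect_error(extract_traces(squ, matrix(FALSE, 2, 2)), "shape")
})

test_that("trace extraction matches ground-truth noiseless intensities", {
  net <- straight_vessel_network()
  cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                           snr = Inf, psf_sigma_px = 0, seed = 1)
  sq <- render_sequence(net, cfg)
  tr <- extract_traces(sq, sq$ground_truth$mask, tissue_margin_px = 0)
  gt <- sq$ground_truth$intensity
  expect_equal(tr$vascular_mean, gt$vascular_true, tolerance = 1e-4)
  expect_equal(tr$tissue_mean, gt$tissue_true, tolerance = 1e-4)
})

test_that("a step trace gives the step completion time and slope", {
  t <- seq(0, 200, by = 20)
  v <- ifelse(t >= 100, 5, 0)
  tr <- compartment_trace(t, v, injection_time = 0)
  fk <- fill_curve(tr)
  expect_equal(fk$completion_s, 100)
  expect_equal(fk$max_variation_per_s, 5 / 20)
  expect_equal(fk$i_max, 5)
})

test_that("exponential fill metrics match the closed form", {
  tau <- 40
  t <- seq(0, 600, by = 20)
  v <- 1 - exp(-t / tau)
  tr <- compartment_trace(t, v, injection_time = 0)
  fk <- fill_curve(tr)
  i_max <- mean(tail(v, 3))
  # first frame at which (1 - exp(-t/tau))/i_max >= 0.95: 2.996*tau = 119.8 s
  expect_equal(fk$completion_s, 120)
  expect_equal(fk$i_max, i_max)
  expect_equal(fk$max_variation_per_s, (1 - exp(-20 / 40)) / 20)
  expect_equal(fk$data$fill_pct, 100 * v / i_max)
})

test_that("fill curve handles degenerate and incomplete traces", {
  t <- seq(0, 180, by = 20)
  # rises then declines: the 95% level is never sustained to the end
  v <- c(0, 0.2, 0.4, 0.6, 0.8, 1, 0.9, 0.85, 0.8, 0.75)
  tr <- compartment_trace(t, v, injection_time = 0)
  fk <- fill_curve(tr, imax = "quantile")
  expect_false(fk$completion_reached)
  expect_true(is.na(fk$completion_s))
  expect_error(fill_curve(compartment_trace(c(0, 20), c(0, 1),
                                            injection_time = 0)),
               "3 frames")
  expect_error(fill_curve(compartment_trace(t, rep(0, length(t)),
                                            injection_time = 0)),
               "plateau")
})

test_that("relative variation and per-minute rate are exact on known traces", {
  t <- seq(0, 480, by = 20)
  tiss <- rep(0.2, length(t))
  tr <- compartment_trace(t, rep(1, length(t)), tiss, injection_time = -120)
  lk <- leakage_curve(tr)
  expect_equal(lk$data$delta_rel, rep(0, length(t)))
  expect_equal(lk$rate_per_min, 0)

  tiss2 <- 0.2 * (1 + 0.02 * t / 60)     # 2% of reference per minute
  tr2 <- compartment_trace(t, rep(1, length(t)), tiss2, injection_time = -120)
  lk2 <- leakage_curve(tr2)
  expect_equal(lk2$rate_per_min, 0.02, tolerance = 1e-12)
  lk2e <- leakage_curve(tr2, rate_method = "endpoint")
  expect_equal(lk2e$rate_per_min, 0.02, tolerance = 1e-12)

  tr3 <- compartment_trace(t, rep(1, length(t)), rep(0, length(t)),
                           injection_time = -120)
  expect_error(leakage_curve(tr3), "positive")
})

test_that("segmented fit recovers an exact breakpoint and flags one-regime data", {
  t <- c(seq(0, 480, by = 20), seq(600, 1800, by = 120))
  b <- 480; s <- 0.03
  y <- s * pmin(t, b) / 60
  fit <- segmented_fit(tibble::tibble(time_s = t, delta_rel = y),
                       reference_time = 0)
  expect_true(fit$breakpoint_detected)
  expect_equal(fit$breakpoint_s, 480, tolerance = 1e-6)
  expect_equal(fit$slope_per_min, s, tolerance = 1e-9)
  expect_equal(fit$plateau, s * 480 / 60, tolerance = 1e-9)

  lin <- segmented_fit(tibble::tibble(time_s = t, delta_rel = 0.001 * t),
                       reference_time = 0)
  expect_false(lin$breakpoint_detected)
})

test_that("normalized metrics are invariant to intensity scaling and shifts", {
  t <- seq(0, 400, by = 20)
  v <- 1 - exp(-t / 35)
  tiss <- 0.2 * (1 + 0.01 * t / 60)
  tr <- compartment_trace(t, v, tiss, injection_time = 0)
  trs <- compartment_trace(t, 3.7 * v, 3.7 * tiss, injection_time = 0)
  expect_equal(fill_curve(tr)$data$fill_pct, fill_curve(trs)$data$fill_pct)
  expect_equal(leakage_curve(tr)$data$delta_rel,
               leakage_curve(trs)$data$delta_rel)
  troff <- compartment_trace(t, v + 2, tiss, injection_time = 0)
  expect_equal(fill_curve(troff)$max_variation_per_s,
               fill_curve(tr)$max_variation_per_s)
})

test_that("scalar metrics agree with direct arithmetic on a 5-frame trace", {
  t <- c(0, 20, 40, 60, 80)
  v <- c(0.1, 0.5, 0.8, 0.9, 0.91)
  tiss <- c(0.2, 0.21, 0.23, 0.24, 0.25)
  tr <- compartment_trace(t, v, tiss, injection_time = 0)
  fk <- fill_curve(tr, imax_frames = 3)
  i_max <- (0.8 + 0.9 + 0.91) / 3
  expect_equal(fk$i_max, i_max)
  expect_equal(fk$max_variation_per_s, max(diff(v) / 20))
  expect_equal(fk$data$fill_pct, 100 * v / i_max)
  # completion: first sustained frame with pct >= 95 -> 0.9/i_max = 103.4%
  expect_equal(fk$completion_s, 60)
  lk <- leakage_curve(tr, reference_time = 0, window = c(0, 80))
  x <- t / 60; y <- (tiss - 0.2) / 0.2
  slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(lk$rate_per_min, slope)
})

test_that("leakage rate is recovered from simulated sequences", {
  rates <- vapply(1:4, function(s) {
    sq <- simulate_angiography("ep-leak", seed = s,
                               n_arterioles = 2, n_venules = 2,
                               field_px = c(128, 128))
    tr <- extract_traces(sq, build_mask(sq, reference_window = c(-60, 0)))
    leakage_curve(tr)$rate_per_min
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.04) / 0.04, 0.10)
})
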