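test_that("FWHM of a top-hat cross-section equals its width", {
  # rendered ribbon of caliber 50 um at 2 um/px -> 25 px top-hat
  net <- straight_vessel_network(caliber_um = 50, pixel_size_um = 2)
  cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                           snr = Inf, psf_sigma_px = 0, seed = 1)
  sq <- render_sequence(net, cfg)
  frame <- sq$frames[[length(sq$frames)]]
  d <- measure_diameter(frame, net$segments[1, ], pixel_size_um = 2)
  expect_lt(abs(d - 50), 2 * 2)      # within 2 pixels
})

test_that("FWHM of a Gaussian cross-section equals 2.355 sigma", {
  H <- 96; W <- 96; sigma <- 4
  y <- matrix(0:(H - 1), H, W)
  frame <- exp(-(y - 48)^2 / (2 * sigma^2))    # horizontal Gaussian ridge
  seg <- list(polyline = list(cbind(c(10, 48, 86), c(48, 48, 48))),
              caliber_um = 2 * sigma * 2)      # expected radius ~ sigma px
  d_px <- measure_diameter(frame, seg, pixel_size_um = 1,
                           expected_radius_px = 2 * sigma)
  expect_equal(d_px, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.02)
})

test_that("a noiseless 50 um vessel measures 50 um within quantization", {
  net <- straight_vessel_network(caliber_um = 50, pixel_size_um = 2,
                                 orientation_deg = 25)
  cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                           snr = Inf, seed = 1)
  sq <- render_sequence(net, cfg)
  d <- measure_diameter(sq$frames[[length(sq$frames)]], net$segments[1, ],
                        pixel_size_um = 2)
  expect_lt(abs(d - 50), 2 * 2)
})

test_that("measured diameter is robust to vessel orientation", {
  ds <- vapply(c(0, 30, 45, 60, 90), function(th) {
    net <- straight_vessel_network(caliber_um = 40, orientation_deg = th)
    cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                             snr = Inf, seed = 1)
    sq <- render_sequence(net, cfg)
    measure_diameter(sq$frames[[length(sq$frames)]], net$segments[1, ],
                     pixel_size_um = 2)
  }, numeric(1))
  expect_lt((max(ds) - min(ds)) / mean(ds), 0.05)
})

test_that("diameters are scale-equivariant in physical units", {
  d_um <- vapply(c(2, 4), function(px) {
    net <- straight_vessel_network(caliber_um = 60, pixel_size_um = px,
                                   field_px = c(128, 128))
    cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                             snr = Inf, seed = 1)
    sq <- render_sequence(net, cfg)
    measure_diameter(sq$frames[[length(sq$frames)]], net$segments[1, ],
                     pixel_size_um = px)
  }, numeric(1))
  # microns are unchanged; pixel-unit FWHM halves when the pixel doubles
  expect_lt(abs(d_um[1] - d_um[2]) / 60, 0.05)
  px_fwhm <- d_um / c(2, 4)
  expect_lt(abs(px_fwhm[1] - 2 * px_fwhm[2]) / px_fwhm[1], 0.05)
})

test_that("an unfilled vessel is unmeasurable, never a spurious diameter", {
  net <- straight_vessel_network()
  cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                           snr = Inf, seed = 1)
  sq <- render_sequence(net, cfg)
  pre <- sq$frames[[1]]       # at the injection: no tracer yet
  expect_true(is.na(measure_diameter(pre, net$segments[1, ],
                                     pixel_size_um = 2)))
})

test_that("time courses normalize to the last pre-EP frame", {
  net <- straight_vessel_network(caliber_um = 50)
  dyn <- dynamics_model(constriction = list(
    arteriole = constriction_profile(),
    venule = constriction_profile(amplitude = 0.3, recovery_s = 840)))
  cfg <- simulation_config(dynamics = dyn,
                           schedule = acquisition_schedule("pre_injection"),
                           snr = Inf, seed = 1)
  sq <- render_sequence(net, cfg)
  ts <- diameter_timecourse(sq, net$segments[1, ])
  expect_equal(attr(ts, "baseline_time_s"), 0)
  expect_equal(ts$normalized[ts$time_s == 0], 1)
  post <- ts$normalized[ts$time_s == 20]
  expect_lt(abs(post - (1 - 0.3 * (1 - 20 / 840))), 0.05)
  late <- ts$normalized[ts$time_s >= 840]
  expect_true(all(abs(late - 1) < 0.05))

  blank <- toy_sequence(lapply(1:4, function(i) matrix(0.1, 128, 128)),
                        times = c(-40, -20, 0, 20))
  expect_error(diameter_timecourse(blank, net$segments[1, ]),
               "baseline diameter unmeasurable")
})

test_that("control normalized diameters stay near one at SNR 10", {
  # clean single vessel: every frame within 5% of baseline
  net <- straight_vessel_network(caliber_um = 50)
  cfg <- simulation_config(schedule = acquisition_schedule("pre_injection"),
                           snr = 10, seed = 8)
  sq <- render_sequence(net, cfg)
  ts <- diameter_timecourse(sq, net$segments[1, ])
  post <- ts$normalized[ts$time_s > 0]
  expect_true(all(abs(post - 1) < 0.05))

  # full network with QC: small average deviation
  sqn <- control_sequence()
  d <- suppressWarnings(measure_network_diameters(sqn, sqn$network$segments))
  d <- qc_stable_segments(d)
  post <- d[d$time_s > 0 & !is.na(d$normalized), ]
  expect_gt(nrow(post), 0)
  expect_lt(mean(abs(post$normalized - 1)), 0.03)
})

test_that("vessel classification follows the morphology convention", {
  segs <- tibble::tibble(
    diameter_um = c(30, 180, 150),
    tortuosity = c(1.0, 1.4, 1.0),
    n_branches = c(0, 4, 0)
  )
  out <- classify_vessel(segs)
  expect_equal(out$label, c("arteriole", "venule", "venule"))
  expect_equal(out$low_confidence, c(FALSE, FALSE, TRUE))
  # user labels take precedence
  segs$label <- c(NA, NA, "arteriole")
  out2 <- classify_vessel(segs)
  expect_equal(out2$label[3], "arteriole")
  expect_false(out2$low_confidence[3])
})

test_that("stability QC removes erratically measured segments", {
  good <- tibble::tibble(segment = 1L, class = "venule",
                         time_s = seq(-60, 0, 20),
                         diameter_um = c(40, 40.3, 39.8, 40.1),
                         normalized = 1, baseline_um = 40)
  bad <- tibble::tibble(segment = 2L, class = "venule",
                        time_s = seq(-60, 0, 20),
                        diameter_um = c(40, 22, 41, 30),
                        normalized = 1, baseline_um = 30)
  kept <- qc_stable_segments(rbind(good, bad), min_keep = 1)
  expect_equal(unique(kept$segment), 1L)
})
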