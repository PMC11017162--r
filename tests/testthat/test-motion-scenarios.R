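test_that("S2 baseline shift of -7 mm lands at 90 s", {
  spec <- scenario_spec("S2", amplitude_jitter = 0)
  tr <- make_motion_trace(spec, duration_s = 180, dt_ms = 98.6)
  # averaging over whole cycles away from the step isolates the baseline:
  # compare windows of 16 whole 5 s cycles before and after the shift
  pre <- tr$time_s > 5 & tr$time_s < 85
  post <- tr$time_s > 95 & tr$time_s < 175
  shift <- mean(tr$amplitude[post]) - mean(tr$amplitude[pre])
  # tolerance from cycle-averaging: windows cover whole cycles to ~1 cycle
  # slack out of 16, bounding the residual at p2p * mean(sin^4) / 16
  tol <- 20 * (3 / 8) / 16
  expect_equal(shift, -7, tolerance = tol / 7)
})

test_that("peak-to-peak amplitude and frame count match the configuration", {
  spec <- scenario_spec("S1", amplitude_jitter = 0)
  tr <- make_motion_trace(spec, duration_s = 180, dt_ms = 98.6)
  expect_identical(tr$n_t, 1826L)
  one_cycle <- tr$amplitude[tr$time_s < 5]
  expect_equal(max(one_cycle) - min(one_cycle), 20, tolerance = 0.01)
  # zero amplitude: constant trace
  flat <- make_motion_trace(scenario_spec("S1", peak_to_peak_mm = 0,
                                          amplitude_jitter = 0), 30, 98.6)
  expect_true(all(flat$amplitude == 0))
})

test_that("scenario family shapes: jitter, period change, decay", {
  expect_error(scenario_spec("S9"), "unknown")
  # S1 jitter: cycle maxima vary
  tr1 <- make_motion_trace(scenario_spec("S1", seed = 5), 60, 98.6)
  peaks <- tapply(-tr1$amplitude, floor(tr1$time_s / 5), max)
  expect_gt(sd(peaks), 0.1)
  # jitter is seed-deterministic
  tr1b <- make_motion_trace(scenario_spec("S1", seed = 5), 60, 98.6)
  expect_identical(tr1$amplitude, tr1b$amplitude)
  # S4: spectral period shortens after the change point
  tr4 <- make_motion_trace(scenario_spec("S4", amplitude_jitter = 0), 120, 98.6)
  zc <- function(x) sum(diff(sign(x + 10)) != 0)  # crossings of midline
  early <- tr4$amplitude[tr4$time_s < 60]
  late <- tr4$amplitude[tr4$time_s >= 60]
  expect_gt(zc(late), zc(early) * 1.2)
  # S5: amplitude decays
  tr5 <- make_motion_trace(scenario_spec("S5"), 180, 98.6)
  amp_first <- max(-tr5$amplitude[tr5$time_s < 40])
  amp_last <- max(-tr5$amplitude[tr5$time_s > 140])
  expect_lt(amp_last, amp_first * 0.85)
})

test_that("scenario YAML round trip", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("scenario_id: S2", "period_s: 4.0", "seed: 9"), path)
  spec <- read_scenario_yaml(path)
  expect_identical(spec$scenario_id, "S2")
  expect_equal(spec$period_s, 4)
  expect_equal(spec$baseline_shift_mm, -7)   # S2 preset preserved
})

test_that("analytic basis modes are orthogonal, normalized and calibrated", {
  dims <- c(24, 24, 24)
  basis <- make_analytic_basis(dims, 4)
  for (i in 1:3) expect_equal(dvf_norm(basis$modes[[i]]), 1, tolerance = 1e-12)
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(dvf_inner(basis$modes[[i]], basis$modes[[j]])), 1e-6)
  # SI mode peaks at the diaphragm plane
  m1 <- basis$modes[[1]]$vectors
  zplane <- basis$diaphragm_plane + 1
  expect_equal(max(abs(m1)), max(abs(m1[, , zplane, 3])))

  # scaling mode 1 to a 20 mm diaphragm displacement moves the
  # diaphragm intensity edge by 5 voxels at 4 mm voxels (edge tracking
  # along the dome apex column)
  ph <- small_phantom()
  z <- complex_volume(ph$data + 0i, 4)
  d <- basis$modes[[1]]
  d$vectors <- d$vectors * (20 / basis$gains[1])
  w <- warp_volume(z, d)
  col <- round(0.68 * 24) + 1
  edge <- function(vol) {
    line <- Re(vol[col, 12, ])
    which.max(abs(diff(line)))
  }
  shift <- edge(z$data) - edge(w$data)
  expect_equal(abs(shift), 5, tolerance = 0.21)  # within 1 voxel
})

test_that("render_cine maps the trace linearly onto the motion modes", {
  dims <- c(16, 16, 16)
  basis <- make_analytic_basis(dims, 4)
  ref <- complex_volume(array(rnorm(prod(dims)) + 0i, dims), 4)
  spec <- scenario_spec("S1", amplitude_jitter = 0)
  tr <- make_motion_trace(spec, 10, 100)
  cine <- render_cine(ref, basis, tr)
  expect_identical(cine$n_t, tr$n_t)
  # exhale amplitude (zero) maps to the zero DVF (up to the sub-0.1 mm
  # residual of the lagged AP/LR couplings at the exhale instant)
  t0 <- which.min(abs(tr$amplitude))
  expect_lt(max(abs(cine_dvf(cine, t0)$vectors)), 0.1)
  # doubling the trace doubles every DVF component
  tr2 <- tr
  tr2$amplitude <- 2 * tr$amplitude
  cine2 <- render_cine(ref, basis, tr2)
  expect_equal(cine2$weights, 2 * cine$weights, tolerance = 1e-12)
  # frames equal warp(reference, dvf) by construction
  fr <- cine_frame(cine, 5)
  expect_identical(fr$data,
                   warp_volume(ref, cine_dvf(cine, 5))$data)
  # zero-amplitude trace: identity on all frames
  trz <- make_motion_trace(scenario_spec("S1", peak_to_peak_mm = 0,
                                         amplitude_jitter = 0), 10, 100)
  cz <- render_cine(ref, basis, trz)
  expect_equal(cine_frame(cz, 3)$data, ref$data, tolerance = 1e-12)
})
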