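test_that("target fields superpose disk and vortex beamlet templates", {
  # radius-0 disk: a single nonzero pixel
  tf <- build_target_field(list(target_spec(0, c(40, 60), disk_radius_px = 0)),
                           grid_shape = c(128, 128))
  expect_equal(sum(Mod(tf) > 0), 1)
  expect_gt(Mod(tf[61, 41]), 0)
  # vortex: phase singularity means zero amplitude on axis
  tv <- build_target_field(list(target_spec(0, c(64, 64), shape = "vortex",
                                            L = 5)),
                           grid_shape = c(128, 128))
  expect_equal(Mod(tv[65, 65]), 0)
  expect_gt(sum(Mod(tv) > 0), 10)
  # two disjoint disks: support is the union
  t2 <- build_target_field(list(
    target_spec(0, c(30, 30), disk_radius_px = 2),
    target_spec(1, c(90, 90), disk_radius_px = 2)),
    grid_shape = c(128, 128))
  n1 <- sum(Mod(build_target_field(
    list(target_spec(0, c(30, 30), disk_radius_px = 2)),
    grid_shape = c(128, 128))) > 0)
  expect_equal(sum(Mod(t2) > 0), 2 * n1)
  # off-grid target errors with the cell named
  expect_error(build_target_field(list(target_spec(7, c(500, 0))),
                                  grid_shape = c(128, 128)), "cell 7")
})

test_that("propagation conserves energy and obeys the shift theorem", {
  # flat phase: a single dominant focus at the grid centre
  ii <- simulate_intensity(matrix(0, 64, 64))
  pk <- which(ii == max(ii), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(33, 33))
  expect_gt(max(ii), 0.99)
  # energy conservation of the unitary transform
  ph <- withr::with_seed(1, matrix(stats::runif(64 * 64, 0, 2 * pi), 64))
  ii2 <- simulate_intensity(ph)
  expect_equal(attr(ii2, "total_power"), 64 * 64, tolerance = 1e-9)
  expect_equal(sum(ii2), 1, tolerance = 1e-12)
  # linear phase ramp displaces the focus proportionally to the slope
  kx <- 5
  ramp <- outer(rep(1, 64), 0:63) * 2 * pi * kx / 64
  ii3 <- simulate_intensity(ramp %% (2 * pi))
  pk3 <- which(ii3 == max(ii3), arr.ind = TRUE)
  expect_equal(unname(pk3[1, ]), c(33, 33 + kx))
})

test_that("GS converges with non-increasing focal error and hits point targets", {
  tgs <- list(target_spec(0, c(60, 60), disk_radius_px = 0),
              target_spec(1, c(180, 100), disk_radius_px = 0),
              target_spec(2, c(100, 200), disk_radius_px = 0))
  tf <- build_target_field(tgs, grid_shape = c(256, 256))
  mask <- gs_phase_mask(tf, n_iterations = 30, seed = 0)
  errs <- attr(mask, "errors")
  expect_true(all(diff(errs) <= 1e-10))
  ii <- simulate_intensity(mask)
  # each target has an intensity peak within 1 px
  ctrs <- attr(tf, "centers")
  work <- ii
  for (i in seq_len(nrow(ctrs))) {
    pk <- which(work == max(work), arr.ind = TRUE)[1, ]
    d <- sqrt(rowSums((ctrs - matrix(pk, nrow(ctrs), 2, byrow = TRUE))^2))
    expect_lte(min(d), 1)
    blk <- calstream:::annulus_pixels(pk[2] - 1, pk[1] - 1, 0, 6, dim(work))
    work[calstream:::idx_linear(blk, nrow(work))] <- 0
  }
  # efficiency beats the one-iteration mask
  m1 <- gs_phase_mask(tf, n_iterations = 1, seed = 0)
  eff30 <- target_efficiency(ii, ctrs)
  eff1 <- target_efficiency(simulate_intensity(m1), ctrs)
  expect_gte(eff30, eff1)
  # determinism: same seed gives bit-identical masks
  expect_identical(mask$phase, gs_phase_mask(tf, 30, seed = 0)$phase)
})

test_that("a realizable target converges essentially immediately", {
  slm0 <- exp(1i * withr::with_seed(3,
    matrix(stats::runif(64 * 64, 0, 2 * pi), 64)))
  target <- calstream:::propagate_fwd(slm0)
  attr(target, "support") <- matrix(TRUE, 64, 64)
  mask <- gs_phase_mask(target, n_iterations = 2, seed = 5)
  expect_lt(attr(mask, "errors")[2], 1e-10)
})

test_that("capture efficiency is proportional for uniform intensity", {
  ii <- matrix(1 / (64 * 64), 64, 64)
  ctr <- matrix(c(32, 32), 1)
  eff <- target_efficiency(ii, ctr, capture_radius_px = 10)
  frac <- nrow(calstream:::annulus_pixels(31, 31, 0, 10, c(64, 64))) /
    (64 * 64)
  expect_equal(eff, frac)
  # all intensity inside one capture disk: efficiency 1
  conc <- matrix(0, 64, 64); conc[33, 33] <- 1
  expect_equal(target_efficiency(conc, ctr, 5), 1)
})

test_that("vortex beamlets keep a central intensity null for modes 4-6", {
  for (L in 4:6) {
    tf <- build_target_field(list(target_spec(0, c(64, 64), shape = "vortex",
                                              L = L)),
                             grid_shape = c(128, 128))
    ii <- simulate_intensity(gs_phase_mask(tf, 30, seed = L))
    expect_lt(ii[65, 65], 0.01 * max(ii))
  }
})

test_that("mask sequences are per-target, timed and reproducible", {
  tgs <- list(target_spec(0, c(30, 30)), target_spec(1, c(60, 60)),
              target_spec(2, c(90, 90)))
  sq <- sequence_masks(tgs, grid_shape = c(128, 128), rate_hz = 2,
                       n_iterations = 5, seed = 3)
  expect_length(sq, 3)
  expect_equal(vapply(sq, `[[`, numeric(1), "dwell_s"), rep(0.5, 3))
  expect_equal(vapply(sq, `[[`, numeric(1), "cell_id"), c(0, 1, 2))
  sq2 <- sequence_masks(tgs, grid_shape = c(128, 128), rate_hz = 2,
                        n_iterations = 5, seed = 3)
  for (i in 1:3) expect_identical(sq[[i]]$mask$phase, sq2[[i]]$mask$phase)
  expect_length(sequence_masks(tgs[1], grid_shape = c(128, 128),
                               n_iterations = 2), 1)
})

test_that("stimulation events are recorded with their parameters", {
  lg <- event_log_open(tempfile(fileext = ".jsonl"))
  tgs <- list(target_spec(3, c(10, 10)), target_spec(8, c(20, 20)))
  rec <- stimulate(lg, 12.5, tgs, params = list(duration_ms = 30, period_s = 3))
  expect_equal(rec$cell_ids, c(3, 8))
  expect_equal(rec$duration_ms, 30)
  expect_equal(rec$period_s, 3)
  rec2 <- stimulate(lg, 13.5, tgs)
  event_log_close(lg)
  recs <- read_event_log(lg$path, "stimulation")
  expect_length(recs, 2)
  expect_lt(recs[[1]]$time_s, recs[[2]]$time_s)
})

test_that("calibration maps are affine and recovered from correspondences", {
  p <- tempfile(fileext = ".csv")
  A <- matrix(c(1.1, 0.1, -0.05, 0.9), 2); b <- c(3, -2)
  fov <- matrix(c(0, 0, 100, 0, 0, 100, 50, 70), ncol = 2, byrow = TRUE)
  slm <- t(apply(fov, 1, function(x) A %*% x + b))
  utils::write.csv(data.frame(fov_x = fov[, 1], fov_y = fov[, 2],
                              slm_x = slm[, 1], slm_y = slm[, 2]),
                   p, row.names = FALSE)
  cal <- load_calibration(p)
  expect_equal(unname(cal$A), A, tolerance = 1e-8)
  expect_equal(unname(cal$b), b, tolerance = 1e-8)
  expect_error(calibration_map(matrix(c(1, 1, 1, 1), 2)), "invertible")
})
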