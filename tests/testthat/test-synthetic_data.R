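test_that("ground truth is fully determined by (config, seed)", {
  cf <- synth_config(height = 64, width = 64, n_cells = 6, duration_s = 10)
  a <- generate_ground_truth(cf, seed = 3)
  b <- generate_ground_truth(cf, seed = 3)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$centers, b$centers)
  expect_identical(a$drift, b$drift)
  c2 <- generate_ground_truth(cf, seed = 4)
  expect_false(identical(a$spikes, c2$spikes))
})

test_that("coupling controls the correlation structure of the traces", {
  cf0 <- synth_config(height = 64, width = 64, n_cells = 12, duration_s = 30,
                      coupling = 0, response_amp_spikes = 0)
  gt0 <- generate_ground_truth(cf0, seed = 6)  # 900 frames
  sp0 <- gt0$spikes
  rownames(sp0) <- 0:11
  rho0 <- pairwise_correlations(sp0)$rho
  off0 <- abs(rho0[upper.tri(rho0)])
  expect_lt(stats::median(off0, na.rm = TRUE), 0.1)

  cf1 <- synth_config(height = 96, width = 96, n_cells = 20, duration_s = 120,
                      coupling = 0.8, response_amp_spikes = 0)
  gt1 <- generate_ground_truth(cf1, seed = 7)
  tr1 <- ground_truth_dff(gt1, noise_sd = 0.02, seed = 2)
  rho1 <- pairwise_correlations(tr1)$rho
  within <- rho1[1:5, 1:5][upper.tri(matrix(0, 5, 5))]
  between <- rho1[6:20, 6:20][upper.tri(matrix(0, 15, 15))]
  expect_gt(mean(within) - mean(between), 0.3)
})

test_that("a null movie yields flat dF/F0 through the whole pipeline", {
  cf <- synth_config(height = 64, width = 64, n_cells = 5, duration_s = 8,
                     background_rate_hz = 0, group_rate_hz = 0,
                     response_amp_spikes = 0, noise_sd_frac = 0, drift_px = 0)
  gt <- generate_ground_truth(cf, seed = 2)
  expect_equal(sum(gt$spikes), 0)
  d <- tempfile(); dir.create(d)
  p <- file.path(d, "null.raw")
  render_movie(gt, p)
  cfg <- pipeline_config(
    stream = stream_config(p, "raw_u16", 64, 64),
    centers_path = { cp <- file.path(d, "c.csv")
      utils::write.csv(gt$centers, cp, row.names = FALSE); cp },
    out_dir = file.path(d, "out"),
    registration = list(enabled = FALSE),
    synchrony = list(enabled = FALSE))
  res <- run_pipeline(cfg)
  dff <- ts_series(res$store, "dff")
  expect_lt(max(abs(dff), na.rm = TRUE), 1e-6)
  unlink(d, recursive = TRUE)
})

test_that("a single spike produces a single well-timed dF/F0 transient", {
  cf <- synth_config(height = 64, width = 64, n_cells = 3, duration_s = 12,
                     background_rate_hz = 0, group_rate_hz = 0,
                     response_amp_spikes = 0, noise_sd_frac = 0, drift_px = 0)
  gt <- generate_ground_truth(cf, seed = 2)
  spike_frame <- 200L
  gt$spikes[2, spike_frame] <- 1L
  d <- tempfile(); dir.create(d)
  p <- file.path(d, "one.raw")
  render_movie(gt, p)
  cp <- file.path(d, "c.csv")
  utils::write.csv(gt$centers, cp, row.names = FALSE)
  cfg <- pipeline_config(stream = stream_config(p, "raw_u16", 64, 64),
                         centers_path = cp, out_dir = file.path(d, "out"),
                         registration = list(enabled = FALSE),
                         synchrony = list(enabled = FALSE))
  res <- run_pipeline(cfg)
  dff <- ts_series(res$store, "dff")
  peak <- which.max(dff[2, ])
  kpeak <- which.max(calcium_kernel(cf$kernel_rise_s, cf$kernel_decay_s,
                                    cf$frame_rate))
  expect_lte(abs(peak - (spike_frame + kpeak - 1)), 2)
  # other cells see at most a small neuropil-coupling residue
  expect_lt(max(abs(dff[c(1, 3), ]), na.rm = TRUE), 0.05)
  unlink(d, recursive = TRUE)
})

test_that("rendered drift is recovered by registration within 0.2 px RMS", {
  cf <- synth_config(height = 128, width = 128, n_cells = 12, duration_s = 4,
                     background_rate_hz = 0, group_rate_hz = 0,
                     response_amp_spikes = 0, noise_sd_frac = 0.01,
                     drift_px = 5, drift_lead_frames = 10)
  gt <- generate_ground_truth(cf, seed = 9)
  d <- tempfile(); dir.create(d)
  p <- file.path(d, "drift.raw")
  withr::with_seed(1, render_movie(gt, p))
  frames <- read_all_frames(stream_config(p, "raw_u16", 128, 128))
  tmpl <- build_template(frames[1:10])
  est <- t(vapply(frames, function(f) {
    s <- estimate_shift(f, tmpl, upsample = 10)
    c(s$dy, s$dx)
  }, numeric(2)))
  rmse <- sqrt(mean((est - gt$drift)^2))
  expect_lt(rmse, 0.2)
  unlink(d, recursive = TRUE)
})

test_that("fixture bundles carry the full schedule and load end to end", {
  b <- tiny_bundle()
  expect_true(all(file.exists(unlist(b[c("movie", "centers", "schedule",
                                         "ground_truth")]))))
  sched <- load_schedule(b$schedule)
  expect_equal(nrow(sched), 8 * 3 * 10)  # full design regardless of duration
  ctr <- load_centers(b$centers, c(96, 96))
  expect_equal(nrow(ctr), 8)
  gt_json <- jsonlite::fromJSON(b$ground_truth)
  expect_equal(gt_json$n_frames, 900)
  # two seeds differ in pixels but share the schema
  d2 <- file.path(tempdir(), "calstream_tiny2")
  b2 <- write_fixture_bundle(b$config, seed = 6, d2)
  expect_false(identical(readBin(b$movie, "raw", 1e4),
                         readBin(b2$movie, "raw", 1e4)))
  expect_identical(names(jsonlite::fromJSON(b2$ground_truth)),
                   names(gt_json))
  unlink(d2, recursive = TRUE)
})
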