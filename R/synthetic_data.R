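#' Configuration for the synthetic-movie generator
#'
#' The defaults describe the canonical demo session: a 256 x 256 px, 30 Hz,
#' 120 s movie with 60 ring-shaped somata over a diffuse neuropil
#' background, GCaMP-like calcium kernels (0.05 s rise, 1.5 s decay),
#' Gaussian noise at 2% of soma baseline, a five-cell latent correlation
#' group with coupling 0.8, frequency-tuned tone responses on the
#' half-octave 4-45.3 kHz x 50/60/70 dB grid, and a slow linear x-y drift
#' that starts after the template batch.
#'
#' @param height,width frame size (px).
#' @param n_cells number of somata.
#' @param frame_rate Hz.
#' @param duration_s movie length (s).
#' @param r_inner,r_outer soma ring radii (px).
#' @param cell_brightness soma ring baseline intensity (counts).
#' @param interior_frac interior disk brightness relative to the ring.
#' @param transient_amp dF/F amplitude of a single spike at the soma.
#' @param background_offset dark offset (counts).
#' @param neuropil_brightness neuropil field scale (counts).
#' @param neuropil_dilution fraction of the population-mean transient
#'   carried by the neuropil.
#' @param noise_sd_frac Gaussian noise sd as a fraction of
#'   `cell_brightness`.
#' @param kernel_rise_s,kernel_decay_s calcium kernel time constants (s).
#' @param background_rate_hz per-cell background Poisson spike rate.
#' @param group_cells 0-based ids coupled most strongly to the population
#'   events.
#' @param group_rate_hz population event rate (spontaneous population
#'   events in dense cortical networks occur at roughly 1-2 Hz).
#' @param coupling probability a group cell joins a population event; the
#'   rest of the population participates with graded probabilities drawn
#'   uniformly from `[0, bg_coupling_frac * coupling]`, emulating the
#'   graded population coupling (soloists vs choristers) of cortical data.
#' @param bg_coupling_frac ceiling of the background coupling gradient,
#'   relative to `coupling`.
#' @param tone_f_start_khz,tone_n_steps half-octave tone ladder.
#' @param levels_db sound pressure levels.
#' @param n_repeats repeats per (frequency, level) combination.
#' @param tone_duration_s,intertrial_s,schedule_onset_s tone timing.
#' @param tuning_width_oct Gaussian tuning width in octaves (sub-octave,
#'   as in primary auditory cortex).
#' @param response_reliability probability a cell responds at all on a
#'   70 dB trial (scaled down with level).
#' @param response_amp_spikes mean spike count of a best-frequency
#'   response; off-BF responses are amplitude-tuned (Poisson counts with
#'   Gaussian log-frequency falloff). Set 0 for a spontaneous-only
#'   session.
#' @param drift_px total linear drift over the session (+y, -x).
#' @param drift_lead_frames frames with zero drift at session start.
#' @return a `synth_config` list.
#' @export
synth_config <- function(height = 256, width = 256, n_cells = 60,
                         frame_rate = 30, duration_s = 120,
                         r_inner = 2, r_outer = 6,
                         cell_brightness = 1000, interior_frac = 0.6,
                         transient_amp = 1, background_offset = 100,
                         neuropil_brightness = 300, neuropil_dilution = 0.3,
                         noise_sd_frac = 0.02,
                         kernel_rise_s = 0.05, kernel_decay_s = 1.5,
                         background_rate_hz = 0.15,
                         group_cells = 0:4, group_rate_hz = 1.5,
                         coupling = 0.8, bg_coupling_frac = 0.375,
                         tone_f_start_khz = 4, tone_n_steps = 8,
                         levels_db = c(50, 60, 70), n_repeats = 10,
                         tone_duration_s = 1, intertrial_s = 3,
                         schedule_onset_s = 5,
                         tuning_width_oct = 0.4, response_reliability = 0.9,
                         response_amp_spikes = 3,
                         drift_px = 2, drift_lead_frames = 30) {
  structure(as.list(environment()), class = "synth_config")
}

#' Randomized tone-presentation schedule over a frequency x level grid
#'
#' All `n_repeats` repeats of every (frequency, level) combination in a
#' shuffled order, 1 s tones with a fixed intertrial interval by default.
#'
#' @param freqs_khz tone frequencies (kHz).
#' @param levels_db sound levels (dB).
#' @param n_repeats repeats per combination.
#' @param tone_duration_s,intertrial_s,onset0_s timing parameters.
#' @param seed shuffle seed.
#' @return schedule data frame (`onset_s,duration_s,frequency_hz,level_db`).
#' @export
make_tone_schedule <- function(freqs_khz, levels_db, n_repeats = 10,
                               tone_duration_s = 1, intertrial_s = 3,
                               onset0_s = 5, seed = 1) {
  grid <- expand.grid(frequency_hz = freqs_khz * 1000, level_db = levels_db)
  trials <- grid[rep(seq_len(nrow(grid)), n_repeats), ]
  trials <- withr::with_seed(seed, trials[sample.int(nrow(trials)), ])
  trials$onset_s <- onset0_s +
    (seq_len(nrow(trials)) - 1) * (tone_duration_s + intertrial_s)
  trials$duration_s <- tone_duration_s
  rownames(trials) <- NULL
  trials[, c("onset_s", "duration_s", "frequency_hz", "level_db")]
}

#' Difference-of-exponentials calcium kernel (peak normalized to 1)
#' @param rise_s,decay_s time constants (s).
#' @param frame_rate Hz.
#' @return numeric kernel sampled per frame.
#' @export
calcium_kernel <- function(rise_s = 0.05, decay_s = 1.5, frame_rate = 30) {
  t <- seq(0, 5 * decay_s, by = 1 / frame_rate)
  k <- exp(-t / decay_s) - exp(-t / rise_s)
  k / max(k)
}

#' Generate the ground truth of a synthetic session
#'
#' Draws non-overlapping cell centres, per-cell spike trains (background
#' Poisson rate, shared latent events within the correlation group, and
#' tone-locked tuned responses with Gaussian log-frequency falloff scaled by
#' sound level), best frequencies cycling through the tone ladder, the tone
#' schedule, and the drift trajectory. Fully determined by
#' `(config, seed)`.
#'
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @return a `ground_truth` list.
#' @export
generate_ground_truth <- function(config = synth_config(), seed = 1) {
  cf <- config
  n_frames <- round(cf$duration_s * cf$frame_rate)
  freqs_khz <- half_octave_ladder(cf$tone_f_start_khz, cf$tone_n_steps)
  schedule <- make_tone_schedule(freqs_khz, cf$levels_db, cf$n_repeats,
                                 cf$tone_duration_s, cf$intertrial_s,
                                 cf$schedule_onset_s, seed = seed)
  gt <- withr::with_seed(seed, {
    # centres: rejection sampling with a minimum separation; greedy
    # placement can dead-end on dense configs, so restart after repeated
    # failures and, as a last resort, relax the separation
    min_sep <- 2 * cf$r_outer + 3
    margin <- cf$r_outer + 2
    xs <- numeric(0); ys <- numeric(0)
    fails <- 0L; restarts <- 0L
    while (length(xs) < cf$n_cells) {
      x <- round(stats::runif(1, margin, cf$width - 1 - margin))
      y <- round(stats::runif(1, margin, cf$height - 1 - margin))
      if (!length(xs) || all(sqrt((xs - x)^2 + (ys - y)^2) >= min_sep)) {
        xs <- c(xs, x); ys <- c(ys, y)
        fails <- 0L
      } else if ((fails <- fails + 1L) > 200L) {
        xs <- numeric(0); ys <- numeric(0); fails <- 0L
        if ((restarts <- restarts + 1L) %% 50L == 0L && min_sep > 2)
          min_sep <- min_sep - 1
      }
    }
    centers <- data.frame(cell_id = 0:(cf$n_cells - 1), x = xs, y = ys)
    bf_khz <- freqs_khz[(centers$cell_id %% length(freqs_khz)) + 1]

    spikes <- matrix(0L, cf$n_cells, n_frames)
    # background
    spikes[] <- stats::rbinom(cf$n_cells * n_frames, 1L,
                              cf$background_rate_hz / cf$frame_rate)
    # population events with graded per-cell coupling; group cells at the top
    p_cell <- stats::runif(cf$n_cells, 0, cf$bg_coupling_frac * cf$coupling)
    p_cell[cf$group_cells + 1L] <- cf$coupling
    ev <- which(stats::rbinom(n_frames, 1L,
                              cf$group_rate_hz / cf$frame_rate) == 1L)
    for (fr in ev) {
      hit <- stats::rbinom(cf$n_cells, 1L, p_cell) == 1L
      spikes[hit, fr] <- spikes[hit, fr] + 1L
    }
    # tone-locked tuned responses: amplitude-tuned Poisson spike counts
    # behind a level-scaled reliability gate
    if (cf$response_amp_spikes > 0) {
      for (e in seq_len(nrow(schedule))) {
        fr0 <- ceiling(schedule$onset_s[e] * cf$frame_rate) + 1L
        if (fr0 > n_frames) next
        f_khz <- schedule$frequency_hz[e] / 1000
        tune <- exp(-log2(f_khz / bf_khz)^2 / (2 * cf$tuning_width_oct^2))
        gate <- stats::rbinom(cf$n_cells, 1L,
                              cf$response_reliability *
                                schedule$level_db[e] / max(cf$levels_db))
        cnt <- stats::rpois(cf$n_cells, cf$response_amp_spikes * tune) * gate
        spikes[, fr0] <- spikes[, fr0] + cnt
      }
    }

    drift <- matrix(0, n_frames, 2, dimnames = list(NULL, c("dy", "dx")))
    ramp <- seq_len(n_frames) > cf$drift_lead_frames
    if (any(ramp)) {
      s <- (seq_len(n_frames)[ramp] - cf$drift_lead_frames) /
           max(1, n_frames - cf$drift_lead_frames)
      drift[ramp, "dy"] <- cf$drift_px * s
      drift[ramp, "dx"] <- -cf$drift_px * s
    }
    list(centers = centers, bf_khz = bf_khz, spikes = spikes, drift = drift)
  })
  structure(c(gt, list(schedule = schedule, freqs_khz = freqs_khz,
                       config = cf, seed = seed, n_frames = n_frames)),
            class = "ground_truth")
}

#' Noise-free per-cell dF/F traces implied by a ground truth
#'
#' Spike trains convolved with the calcium kernel, scaled by the transient
#' amplitude; optional additive Gaussian noise for trace-level simulations.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param noise_sd additive Gaussian noise sd on the dF/F scale.
#' @param seed noise seed.
#' @return cells x frames matrix (rownames = cell ids).
#' @export
ground_truth_dff <- function(gt, noise_sd = 0, seed = 1) {
  cf <- gt$config
  k <- calcium_kernel(cf$kernel_rise_s, cf$kernel_decay_s, cf$frame_rate)
  n <- gt$n_frames
  tr <- t(apply(gt$spikes, 1, function(s) {
    stats::convolve(s, rev(k), type = "open")[seq_len(n)]
  })) * cf$transient_amp
  if (noise_sd > 0)
    tr <- tr + withr::with_seed(seed,
      matrix(stats::rnorm(length(tr), 0, noise_sd), nrow(tr)))
  rownames(tr) <- gt$centers$cell_id
  tr
}

# Smooth multiplicative neuropil field in [0.5, 1] from low-frequency noise.
neuropil_field <- function(h, w, seed) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(h * w), h, w)
    ky <- fft_freqs(h); kx <- fft_freqs(w)
    lp <- outer(ky^2, rep(1, w)) + outer(rep(1, h), kx^2) <= 4^2
    s <- Re(ifft2(fft2(z) * lp))
    0.5 + 0.5 * (s - min(s)) / (max(s) - min(s))
  })
}

#' Render a ground truth as a movie on disk
#'
#' Per frame: each soma is a bright ring (with a dimmer interior) scaled by
#' `1 + transient_amp * trace`; the neuropil is a smooth background carrying
#' a diluted mixture of all cell traces; the frame is shifted by the drift
#' trajectory (Fourier, median fill), Gaussian noise is added, and the
#' result is clipped to the unsigned 16-bit range and appended to `path`.
#'
#' @param gt a [generate_ground_truth()] result.
#' @param path output movie file.
#' @param dialect `"raw_u16"`, `"raw_s16"` or `"tif"`.
#' @return a [stream_config()] describing the written movie, invisibly.
#' @export
render_movie <- function(gt, path, dialect = "raw_u16") {
  cf <- gt$config
  h <- cf$height; w <- cf$width
  tr <- ground_truth_dff(gt) / cf$transient_amp  # unit-spike traces
  ring_idx <- interior_idx <- vector("list", cf$n_cells)
  for (i in seq_len(cf$n_cells)) {
    cx <- gt$centers$x[i]; cy <- gt$centers$y[i]
    ring_idx[[i]] <- idx_linear(
      annulus_pixels(cx, cy, cf$r_inner, cf$r_outer, c(h, w)), h)
    interior_idx[[i]] <- idx_linear(
      annulus_pixels(cx, cy, 0, cf$r_inner - 1e-9, c(h, w)), h)
  }
  npf <- neuropil_field(h, w, gt$seed + 1L)
  noise_sd <- cf$noise_sd_frac * cf$cell_brightness
  pop_mean <- colMeans(tr)
  first <- TRUE
  tif_pages <- if (dialect == "tif") vector("list", gt$n_frames)
  for (t in seq_len(gt$n_frames)) {
    img <- matrix(cf$background_offset, h, w)
    img <- img + cf$neuropil_brightness * npf *
      (1 + cf$neuropil_dilution * pop_mean[t])
    for (i in seq_len(cf$n_cells)) {
      gain <- 1 + cf$transient_amp * tr[i, t]
      img[ring_idx[[i]]] <- img[ring_idx[[i]]] + cf$cell_brightness * gain
      img[interior_idx[[i]]] <- img[interior_idx[[i]]] +
        cf$interior_frac * cf$cell_brightness * gain
    }
    dy <- gt$drift[t, "dy"]; dx <- gt$drift[t, "dx"]
    if (dy != 0 || dx != 0) img <- translate_image(img, dy, dx)
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
    img <- pmin(pmax(round(img), 0), 65535)
    if (dialect == "tif") {
      tif_pages[[t]] <- img
    } else {
      write_raw_frames(list(img), path, dialect, append = !first)
      first <- FALSE
    }
  }
  if (dialect == "tif") write_tif_stack(tif_pages, path)
  invisible(stream_config(path, dialect, height = h, width = w,
                          frame_rate = cf$frame_rate))
}

#' Write a complete synthetic fixture bundle
#'
#' The canonical "demo session": movie, cell-centres CSV, stimulus-schedule
#' CSV and a ground-truth JSON (spike trains stored sparsely), exactly the
#' formats the pipeline consumes.
#'
#' @param config a [synth_config()].
#' @param seed integer seed (noise in the rendered movie included).
#' @param out_dir output directory (created).
#' @param dialect movie format.
#' @return named list of paths plus the movie's [stream_config()].
#' @export
write_fixture_bundle <- function(config = synth_config(), seed = 1, out_dir,
                                 dialect = "raw_u16") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gt <- generate_ground_truth(config, seed)
  movie <- file.path(out_dir, paste0("movie.",
                                     if (dialect == "tif") "tif" else "raw"))
  # render with the seeded RNG so movie noise is reproducible too
  scfg <- withr::with_seed(seed + 1000L, render_movie(gt, movie, dialect))
  centers_path <- file.path(out_dir, "centers.csv")
  utils::write.csv(gt$centers, centers_path, row.names = FALSE)
  sched_path <- file.path(out_dir, "schedule.csv")
  utils::write.csv(gt$schedule, sched_path, row.names = FALSE)
  gt_path <- file.path(out_dir, "ground_truth.json")
  spikes_sparse <- lapply(seq_len(nrow(gt$spikes)), function(i) {
    fr <- which(gt$spikes[i, ] > 0)
    list(frames = fr - 1L, counts = gt$spikes[i, fr])
  })
  jsonlite::write_json(
    list(seed = seed, n_frames = gt$n_frames,
         centers = gt$centers, bf_khz = gt$bf_khz,
         group_cells = gt$config$group_cells,
         drift = gt$drift, spikes = spikes_sparse),
    gt_path, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(list(
    stream = list(source_path = movie, dialect = dialect,
                  height = config$height, width = config$width,
                  frame_rate = config$frame_rate),
    centers_path = centers_path,
    out_dir = file.path(out_dir, "out"),
    tuning = list(enabled = TRUE, schedule_path = sched_path)), cfg_path)
  list(movie = movie, centers = centers_path, schedule = sched_path,
       ground_truth = gt_path, config_yaml = cfg_path, stream = scfg,
       gt = gt)
}
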