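# Shared fixtures, built in code and cached for the duration of the run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Smooth textured image (low-pass filtered white noise), good for
# registration: strong gradients, no periodicity.
textured_image <- function(h = 128, w = 128, seed = 1, cutoff = 15) {
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(h * w), h, w)
    fk <- function(n) { k <- 0:(n - 1); k[k > n %/% 2] <- k[k > n %/% 2] - n; k }
    lp <- outer(fk(h)^2, rep(1, w)) + outer(rep(1, h), fk(w)^2) <= cutoff^2
    s <- Re(stats::fft(stats::fft(z) * lp, inverse = TRUE)) / (h * w)
    (s - min(s)) / (max(s) - min(s)) * 1000
  })
}

# Circular (wrap-around) translation oracles, independent of apply_shift.
circ_shift_int <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
}
circ_shift_subpix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  fk <- function(n) { k <- 0:(n - 1); k[k > n %/% 2] <- k[k > n %/% 2] - n; k }
  ph <- exp(-2i * pi * (outer(fk(h), rep(1, w)) * dy / h +
                        outer(rep(1, h), fk(w)) * dx / w))
  Re(stats::fft(stats::fft(m) * ph, inverse = TRUE)) / (h * w)
}

# Small session used by several unit tests: 96x96, 8 cells, 30 s.
tiny_bundle <- function() {
  cache_get("tiny", function() {
    d <- file.path(tempdir(), "calstream_tiny")
    cf <- synth_config(height = 96, width = 96, n_cells = 8, duration_s = 30,
                       group_cells = 0:2, drift_px = 1)
    b <- write_fixture_bundle(cf, seed = 5, d)
    b$config <- cf
    b
  })
}

# 120 s cadence-contract session: small frames so two full runs stay cheap.
cadence_bundle <- function() {
  cache_get("cadence", function() {
    d <- file.path(tempdir(), "calstream_cadence")
    cf <- synth_config(height = 64, width = 64, n_cells = 10, duration_s = 120,
                       group_cells = 0:2, drift_px = 1)
    b <- write_fixture_bundle(cf, seed = 11, d)
    b$config <- cf
    b
  })
}

# Canonical demo session (spontaneous block): 256x256, 60 cells, 120 s.
demo_bundle <- function() {
  cache_get("demo", function() {
    d <- file.path(tempdir(), "calstream_demo")
    cf <- synth_config(response_amp_spikes = 0)
    b <- write_fixture_bundle(cf, seed = 1, d)
    b$config <- cf
    b
  })
}

run_demo_pipeline <- function() {
  cache_get("demo_run", function() {
    b <- demo_bundle()
    cfg <- pipeline_config(stream = b$stream, centers_path = b$centers,
                           out_dir = file.path(tempdir(), "calstream_demo_out"))
    run_pipeline(cfg)
  })
}

# Start a background process that appends `movie_src` to `dest` in chunks,
# emulating a microscope writing frames; returns immediately.
start_live_writer <- function(movie_src, dest, frame_bytes,
                              chunk_frames = 60, sleep_s = 0.02) {
  script <- sprintf(
    'src <- "%s"; dest <- "%s"; fb <- %d; ch <- %d
     bytes <- readBin(src, "raw", file.size(src))
     n <- length(bytes) %%/%% fb
     con <- file(dest, "wb")
     i <- 0
     while (i < n) {
       take <- min(ch, n - i)
       writeBin(bytes[(i*fb+1):((i+take)*fb)], con)
       flush(con)
       i <- i + take
       Sys.sleep(%f)
     }
     close(con)', movie_src, dest, frame_bytes, chunk_frames, sleep_s)
  sf <- tempfile(fileext = ".R")
  writeLines(script, sf)
  system2("Rscript", sf, wait = FALSE, stdout = FALSE, stderr = FALSE)
  invisible(dest)
}

# Independent minimal-spanning-tree weight by exhaustive Prufer-sequence
# enumeration (all n^(n-2) labelled spanning trees).
min_spanning_weight_bruteforce <- function(W) {
  n <- nrow(W)
  if (n == 2) return(W[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- seqs[r, ]
    deg <- rep(1L, n)
    for (v in pr) deg[v] <- deg[v] + 1L
    wsum <- 0
    for (v in pr) {
      leaf <- which(deg == 1L)[1]
      wsum <- wsum + W[leaf, v]
      deg[leaf] <- 0L
      deg[v] <- deg[v] - 1L
    }
    ends <- which(deg == 1L)
    wsum <- wsum + W[ends[1], ends[2]]
    if (wsum < best) best <- wsum
  }
  best
}

# Direct-summation Pearson correlation per the printed formula.
rho_direct <- function(a, b) {
  n <- length(a)
  za <- (a - mean(a)) / stats::sd(a)
  zb <- (b - mean(b)) / stats::sd(b)
  sum(za * zb) / (n - 1)
}

# Re-scan baseline oracle: sort-based median, mean of strictly smaller
# samples, constant-window fallback.
baseline_rescan <- function(Fser, t, wlen) {
  win <- Fser[max(1, t - wlen + 1):t]
  s <- sort(win)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  sub <- win[win < med]
  if (length(sub) == 0) med else mean(sub)
}
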