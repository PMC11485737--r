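#' Per-cell fluorescence extraction from one frame
#'
#' Arithmetic mean of the pixels under each cell's soma ring and neuropil
#' annulus. Cells with an empty mask get `NA` (missing, never zero).
#'
#' @param frame frame or pixel matrix.
#' @param roiset a `roi_set`.
#' @return list with numeric vectors `F_soma` and `F_NP` (one entry per
#'   cell, in `roi_set` order).
#' @export
extract_fluorescence <- function(frame, roiset) {
  px <- as_pixels(frame)
  f_soma <- vapply(roiset$cells, function(cc) {
    if (length(cc$soma) == 0) NA_real_ else mean(px[cc$soma])
  }, numeric(1))
  f_np <- vapply(roiset$cells, function(cc) {
    if (length(cc$neuropil) == 0) NA_real_ else mean(px[cc$neuropil])
  }, numeric(1))
  list(F_soma = unname(f_soma), F_NP = unname(f_np))
}

#' Neuropil correction
#'
#' `F = F_soma - alpha * F_NP`, with the neuropil coefficient `alpha`
#' (default 0.7, adjustable) controlling how much of the surrounding diffuse
#' signal is subtracted.
#'
#' @param F_soma,F_NP somatic and neuropil fluorescence (vectorized).
#' @param alpha neuropil coefficient in \[0, 1\].
#' @return corrected fluorescence `F`.
#' @export
neuropil_correct <- function(F_soma, F_NP, alpha = 0.7) {
  stopifnot(alpha >= 0, alpha <= 1)
  F_soma - alpha * F_NP
}

#' Sliding-window baseline estimate
#'
#' Over the trailing `window_s` seconds of the corrected series (including
#' the current sample), `F0` is the mean of the samples strictly below the
#' window's 50th percentile (linear-interpolation median). If no sample lies
#' strictly below it (a constant window), `F0` falls back to the window
#' median; this also makes the very first sample's baseline equal itself.
#' Missing samples are excluded.
#'
#' @param F_history numeric series of corrected fluorescence up to now.
#' @param now_index 1-based index of the current sample.
#' @param window_s window length in seconds (default 10).
#' @param frame_rate frames per second.
#' @return baseline `F0` (or `NA` if the window holds no finite samples).
#' @export
update_baseline <- function(F_history, now_index = length(F_history),
                            window_s = 10, frame_rate = 30) {
  wlen <- max(1L, round(window_s * frame_rate))
  lo <- max(1L, now_index - wlen + 1L)
  win <- F_history[lo:now_index]
  win <- win[is.finite(win)]
  if (length(win) == 0) return(NA_real_)
  p50 <- unname(stats::quantile(win, 0.5, type = 7))
  sub <- win[win < p50]
  if (length(sub) == 0) p50 else mean(sub)
}

#' Relative fluorescence change
#'
#' `dF/F0 = (F - F0) / F0`. A non-positive baseline makes the ratio
#' meaningless, so the value is recorded missing (the caller flags the cell
#' as low-signal).
#'
#' @param F corrected fluorescence.
#' @param F0 baseline.
#' @return dF/F0 (vectorized; `NA` where `F0 <= 0` or missing).
#' @export
compute_dff <- function(F, F0) {
  out <- (F - F0) / F0
  out[!is.finite(F0) | F0 <= 0] <- NA_real_
  out
}

#' Append-only per-cell trace store
#'
#' Holds the five per-cell series produced by the real-time loop: raw soma
#' fluorescence, neuropil fluorescence, corrected fluorescence, sliding
#' baseline and dF/F0. Rows are cells, columns are frames; storage grows by
#' doubling.
#'
#' @param cell_ids integer cell ids (row order).
#' @param alpha neuropil coefficient.
#' @param window_s baseline window (seconds).
#' @param frame_rate frames per second.
#' @param capacity initial number of frame columns.
#' @return a `trace_store` environment.
#' @export
trace_store <- function(cell_ids, alpha = 0.7, window_s = 10, frame_rate = 30,
                        capacity = 1024L) {
  ts <- new.env(parent = emptyenv())
  ts$cell_ids <- as.integer(cell_ids)
  ts$alpha <- alpha; ts$window_s <- window_s; ts$frame_rate <- frame_rate
  n <- length(cell_ids)
  for (nm in c("F_soma", "F_NP", "F", "F0", "dff"))
    assign(nm, matrix(NA_real_, n, capacity), envir = ts)
  ts$n_frames <- 0L
  class(ts) <- "trace_store"
  ts
}

ts_grow <- function(ts, need) {
  cap <- ncol(ts$F)
  if (need <= cap) return(invisible())
  newcap <- max(need, 2L * cap)
  for (nm in c("F_soma", "F_NP", "F", "F0", "dff")) {
    m <- get(nm, envir = ts)
    m2 <- matrix(NA_real_, nrow(m), newcap)
    m2[, seq_len(ncol(m))] <- m
    assign(nm, m2, envir = ts)
  }
  invisible()
}

#' Append one frame of fluorescence values to a trace store
#'
#' Computes the corrected fluorescence, updates the sliding baseline and
#' dF/F0 for every cell, and appends all five series.
#'
#' @param ts a [trace_store()].
#' @param F_soma,F_NP per-cell fluorescence for this frame.
#' @return the frame's dF/F0 vector, invisibly.
#' @export
ts_append <- function(ts, F_soma, F_NP) {
  t <- ts$n_frames + 1L
  ts_grow(ts, t)
  Fc <- neuropil_correct(F_soma, F_NP, ts$alpha)
  ts$F_soma[, t] <- F_soma
  ts$F_NP[, t] <- F_NP
  ts$F[, t] <- Fc
  wlen <- max(1L, round(ts$window_s * ts$frame_rate))
  lo <- max(1L, t - wlen + 1L)
  F0 <- vapply(seq_along(ts$cell_ids), function(i) {
    win <- ts$F[i, lo:t]
    win <- win[is.finite(win)]
    if (length(win) == 0) return(NA_real_)
    p50 <- unname(stats::quantile(win, 0.5, type = 7))
    sub <- win[win < p50]
    if (length(sub) == 0) p50 else mean(sub)
  }, numeric(1))
  ts$F0[, t] <- F0
  dff <- compute_dff(Fc, F0)
  ts$dff[, t] <- dff
  ts$n_frames <- t
  invisible(dff)
}

#' Extract a series matrix from a trace store
#' @param ts a [trace_store()].
#' @param what one of `"dff"`, `"F"`, `"F0"`, `"F_soma"`, `"F_NP"`.
#' @param frames optional column (frame) selection.
#' @return cells x frames numeric matrix.
#' @export
ts_series <- function(ts, what = "dff", frames = NULL) {
  m <- get(what, envir = ts)[, seq_len(ts$n_frames), drop = FALSE]
  rownames(m) <- ts$cell_ids
  if (!is.null(frames)) m <- m[, frames, drop = FALSE]
  m
}

#' Write a trace store as a wide CSV
#'
#' Columns: `frame`, `time_s`, then one dF/F0 column per cell.
#' @param ts a [trace_store()].
#' @param path output CSV.
#' @export
ts_write_csv <- function(ts, path) {
  d <- ts_series(ts, "dff")
  df <- data.frame(frame = seq_len(ncol(d)) - 1L,
                   time_s = (seq_len(ncol(d)) - 1L) / ts$frame_rate)
  for (i in seq_along(ts$cell_ids))
    df[[paste0("cell_", ts$cell_ids[i])]] <- d[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trace_store <- function(x, ...) {
  cat("<trace_store> ", length(x$cell_ids), " cells x ", x$n_frames,
      " frames; alpha=", x$alpha, ", baseline window ", x$window_s,
      " s @ ", x$frame_rate, " Hz\n", sep = "")
  invisible(x)
}
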