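#' Half-octave-spaced tone frequency ladder
#'
#' `f_k = f_start * 2^(k/2)` for `k = 0..n_steps-1`. Units follow the input
#' (kHz in, kHz out).
#'
#' @param f_start_hz starting frequency (> 0).
#' @param n_steps number of frequencies (>= 1).
#' @return numeric vector of frequencies.
#' @export
half_octave_ladder <- function(f_start_hz, n_steps) {
  stopifnot(f_start_hz > 0, n_steps >= 1)
  f_start_hz * 2^((seq_len(n_steps) - 1) / 2)
}

#' Load a stimulus schedule from CSV
#'
#' Expects columns `onset_s,duration_s,frequency_hz,level_db`. Events must
#' not overlap in time.
#'
#' @param path CSV path.
#' @return data frame sorted by onset, with the (frequency, level) grid in
#'   attributes `freqs` and `levels`.
#' @export
load_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("onset_s", "duration_s", "frequency_hz", "level_db")
  if (!all(need %in% names(df))) stop("schedule must have columns ",
                                      paste(need, collapse = ","))
  df <- df[order(df$onset_s), , drop = FALSE]
  if (nrow(df) > 1 &&
      any(df$onset_s[-1] < (df$onset_s + df$duration_s)[-nrow(df)]))
    stop("overlapping stimulus events in schedule")
  attr(df, "freqs") <- sort(unique(df$frequency_hz))
  attr(df, "levels") <- sort(unique(df$level_db))
  df
}

#' Map stimulus events to frame windows
#'
#' An event covers the frames whose sample time `t = index / frame_rate`
#' satisfies `onset_s <= t < onset_s + duration_s`. An event shorter than
#' one frame keeps the single frame covering its onset; events past the end
#' of the stream are marked pending.
#'
#' @param schedule data frame from [load_schedule()].
#' @param frame_rate frames per second.
#' @param n_frames frames acquired so far (events needing later frames are
#'   pending).
#' @return list per event: `frames` (0-based indices), `pending`,
#'   `frequency_hz`, `level_db`.
#' @export
assign_trials <- function(schedule, frame_rate, n_frames) {
  lapply(seq_len(nrow(schedule)), function(i) {
    on <- schedule$onset_s[i]; du <- schedule$duration_s[i]
    first <- ceiling(on * frame_rate)
    last <- ceiling((on + du) * frame_rate) - 1
    if (last < first) first <- last <- floor(on * frame_rate)
    frames <- seq(first, last)
    pending <- (last + 1) > n_frames  # frames are 0-based
    list(frames = as.integer(frames[frames < n_frames]), pending = pending,
         frequency_hz = schedule$frequency_hz[i],
         level_db = schedule$level_db[i])
  })
}

#' Empty receptive field over a frequency x level grid
#'
#' @param freqs ordered unique stimulus frequencies.
#' @param levels ordered unique sound levels (dB).
#' @return a `receptive_field` with `mean_response` and `n_trials` matrices
#'   (frequencies in rows, levels in columns).
#' @export
receptive_field <- function(freqs, levels) {
  m <- matrix(NA_real_, length(freqs), length(levels),
              dimnames = list(freqs, levels))
  structure(list(freqs = freqs, levels = levels, mean_response = m,
                 n_trials = matrix(0L, length(freqs), length(levels),
                                   dimnames = list(freqs, levels))),
            class = "receptive_field")
}

#' Fold one completed trial into a receptive field
#'
#' The trial response is the mean dF/F0 over the presentation window; the
#' receptive-field entry for that (frequency, level) is updated as a running
#' mean over repeats. A trial whose dF/F0 is missing for the whole window is
#' skipped.
#'
#' @param rf a [receptive_field()].
#' @param dff dF/F0 samples over the event's frame window.
#' @param frequency_hz,level_db the completed event's stimulus.
#' @return the updated `receptive_field` (attribute `"skipped"` set if the
#'   trial carried no data).
#' @export
update_receptive_field <- function(rf, dff, frequency_hz, level_db) {
  fi <- match(frequency_hz, rf$freqs); li <- match(level_db, rf$levels)
  if (is.na(fi) || is.na(li)) stop("stimulus not on the receptive-field grid")
  resp <- mean(dff[is.finite(dff)])
  if (!is.finite(resp)) {
    attr(rf, "skipped") <- TRUE
    return(rf)
  }
  n <- rf$n_trials[fi, li]
  prev <- if (n == 0L) 0 else rf$mean_response[fi, li]
  rf$mean_response[fi, li] <- (prev * n + resp) / (n + 1)
  rf$n_trials[fi, li] <- n + 1L
  attr(rf, "skipped") <- FALSE
  rf
}

#' Best frequency of a receptive field
#'
#' The stimulus frequency with the highest mean dF/F0 response at any sound
#' level; ties break toward the lowest frequency. Undefined (and logged as
#' `NA`) when no entry has a completed trial.
#'
#' @param rf a [receptive_field()].
#' @return best frequency (same units as the grid) or `NA`.
#' @export
best_frequency <- function(rf) {
  m <- rf$mean_response
  m[rf$n_trials == 0L] <- NA
  if (all(is.na(m))) return(NA_real_)
  best_per_freq <- suppressWarnings(apply(m, 1, max, na.rm = TRUE))
  best_per_freq[!is.finite(best_per_freq)] <- -Inf
  rf$freqs[which.max(best_per_freq)]  # which.max takes the first (lowest) tie
}

#' @export
print.receptive_field <- function(x, ...) {
  cat("<receptive_field> ", length(x$freqs), " freqs x ", length(x$levels),
      " levels, ", sum(x$n_trials), " trials; BF = ",
      format(best_frequency(x)), "\n", sep = "")
  invisible(x)
}
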