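# Internal numerical helpers shared across modules.

# Signed DFT frequency indices 0,1,...,-1 (numpy fftfreq * n convention).
fft_freqs <- function(n) {
  k <- 0L:(n - 1L)
  k[k > n %/% 2L] <- k[k > n %/% 2L] - n
  k
}

# Move DC (index 1) to the grid centre floor(n/2)+1 and back.
shift_idx <- function(n, k) ((seq_len(n) - 1L - k) %% n) + 1L

fftshift2 <- function(m) {
  m[shift_idx(nrow(m), nrow(m) %/% 2L), shift_idx(ncol(m), ncol(m) %/% 2L),
    drop = FALSE]
}

ifftshift2 <- function(m) {
  m[shift_idx(nrow(m), -(nrow(m) %/% 2L)), shift_idx(ncol(m), -(ncol(m) %/% 2L)),
    drop = FALSE]
}

fft2 <- function(m) stats::fft(m)
ifft2 <- function(m) stats::fft(m, inverse = TRUE) / length(m)

# Translate an image by (ty, tx) pixels (rows, cols), subpixel via Fourier
# phase shift; wrapped border rows/cols are replaced by `fill` (NULL keeps
# the circular wrap, which makes translations compose exactly).
translate_image <- function(px, ty, tx, fill = stats::median(px)) {
  if (ty == 0 && tx == 0) return(px)
  h <- nrow(px); w <- ncol(px)
  ky <- fft_freqs(h); kx <- fft_freqs(w)
  phase <- exp(-2i * pi * (outer(ky, rep(1, w)) * ty / h +
                           outer(rep(1, h), kx) * tx / w))
  out <- Re(ifft2(fft2(px) * phase))
  if (is.null(fill)) return(out)
  ny <- min(h, ceiling(abs(ty))); nx <- min(w, ceiling(abs(tx)))
  if (ny > 0) {
    rows <- if (ty > 0) seq_len(ny) else (h - ny + 1L):h
    out[rows, ] <- fill
  }
  if (nx > 0) {
    cols <- if (tx > 0) seq_len(nx) else (w - nx + 1L):w
    out[, cols] <- fill
  }
  out
}

# Pixel (row, col) pairs whose centre lies within [r_lo, r_hi] of (cx, cy)
# (0-based x = column, y = row), clipped to the frame. Returns a 2-column
# integer matrix of 1-based matrix indices.
annulus_pixels <- function(cx, cy, r_lo, r_hi, frame_shape) {
  h <- frame_shape[1]; w <- frame_shape[2]
  rmax <- ceiling(r_hi)
  rows <- max(0, floor(cy - rmax)):min(h - 1, ceiling(cy + rmax))
  cols <- max(0, floor(cx - rmax)):min(w - 1, ceiling(cx + rmax))
  if (length(rows) == 0 || length(cols) == 0) {
    return(matrix(integer(), ncol = 2))
  }
  g <- expand.grid(row = rows, col = cols)
  d <- sqrt((g$row - cy)^2 + (g$col - cx)^2)
  keep <- d >= r_lo & d <= r_hi
  cbind(row = g$row[keep] + 1L, col = g$col[keep] + 1L)
}

idx_linear <- function(px_mat, h) {
  unname((px_mat[, 2L] - 1L) * h + px_mat[, 1L])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
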