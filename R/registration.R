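#' Build a registration template from an initial batch of frames
#'
#' The template is the pixelwise arithmetic mean of the batch, mirroring the
#' time-averaged image used for cell identification. It stays fixed for the
#' whole session.
#'
#' @param frames list of frames (from [open_stream()]) or pixel matrices.
#' @return a `cal_template` with `$pixels` and `$n_frames_averaged`.
#' @export
build_template <- function(frames) {
  if (length(frames) == 0) stop("cannot build a template from zero frames")
  mats <- lapply(frames, as_pixels)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("frames differ in shape")
  structure(list(pixels = Reduce(`+`, mats) / length(mats),
                 n_frames_averaged = length(mats)),
            class = "cal_template")
}

as_pixels <- function(x) {
  if (is.matrix(x)) x
  else if (inherits(x, c("cal_frame", "cal_template"))) x$pixels
  else stop("expected a frame, template or matrix")
}

# Upsampled portion of the inverse DFT of `ft` (matrix-multiply DFT),
# evaluated on a (nor x noc) grid at 1/usfac pixel spacing offset by
# (roff, coff). Single-step subpixel refinement kernel.
dftups <- function(ft, nor, noc, usfac, roff, coff) {
  nr <- nrow(ft); nc <- ncol(ft)
  kern_c <- exp((2i * pi / (nc * usfac)) *
                outer(fft_freqs(nc), (0:(noc - 1)) - coff))
  kern_r <- exp((2i * pi / (nr * usfac)) *
                outer((0:(nor - 1)) - roff, fft_freqs(nr)))
  kern_r %*% ft %*% kern_c
}

#' Estimate the x-y drift of a frame against the template
#'
#' Discrete-Fourier-transform registration with single-step upsampled
#' refinement: the integer-pixel cross-correlation peak is located from the
#' full-frame DFT, then the cross-correlation is re-evaluated on an upsampled
#' grid around that peak by a matrix-multiply DFT, giving `1/upsample` pixel
#' precision without ever upsampling the images themselves.
#'
#' The returned `(dy, dx)` is the displacement of the frame content relative
#' to the template (frame ~ template translated by `(dy, dx)`);
#' [apply_shift()] undoes it.
#'
#' @param frame frame or pixel matrix.
#' @param template [build_template()] result or pixel matrix.
#' @param upsample upsampling factor (>= 1); 10 gives 0.1 px precision.
#' @param max_shift estimates beyond this many pixels are clamped and
#'   flagged.
#' @return a `cal_shift`: `dy`, `dx`, `registration_error` (normalized
#'   residual, `NA` when degenerate), `degenerate`, `clamped`.
#' @export
estimate_shift <- function(frame, template, upsample = 10, max_shift = 20) {
  f <- as_pixels(frame); t <- as_pixels(template)
  stopifnot(identical(dim(f), dim(t)), upsample >= 1)
  h <- nrow(f); w <- ncol(f); n <- h * w
  if (stats::sd(f) == 0 || stats::sd(t) == 0) {
    return(structure(list(dy = 0, dx = 0, registration_error = NA_real_,
                          degenerate = TRUE, clamped = FALSE),
                     class = "cal_shift"))
  }
  Fh <- fft2(f); Th <- fft2(t)
  cp <- Fh * Conj(Th)
  cc <- ifft2(cp)
  pk <- which.max(Mod(cc)) - 1L
  r0 <- pk %% h; c0 <- pk %/% h
  dy <- if (r0 > h / 2) r0 - h else r0
  dx <- if (c0 > w / 2) c0 - w else c0
  clamped <- FALSE
  if (abs(dy) > max_shift || abs(dx) > max_shift) {
    dy <- max(min(dy, max_shift), -max_shift)
    dx <- max(min(dx, max_shift), -max_shift)
    clamped <- TRUE
  }
  ccmax <- cc[r0 + 1L, c0 + 1L]
  if (upsample > 1) {
    us <- ceiling(upsample * 1.5)
    dftshift <- floor(us / 2)
    cc_up <- dftups(cp, us, us, upsample,
                    dftshift - dy * upsample, dftshift - dx * upsample) / n
    pk2 <- which.max(Mod(cc_up)) - 1L
    r2 <- pk2 %% us; c2 <- pk2 %/% us
    dy <- dy + (r2 - dftshift) / upsample
    dx <- dx + (c2 - dftshift) / upsample
    ccmax <- cc_up[r2 + 1L, c2 + 1L]
  }
  # normalized residual error a la single-step DFT registration
  rf00 <- sum(Mod(Fh)^2) / n
  rg00 <- sum(Mod(Th)^2) / n
  err2 <- 1 - Mod(ccmax)^2 / (rf00 * rg00)
  structure(list(dy = dy, dx = dx,
                 registration_error = sqrt(abs(err2)),
                 degenerate = FALSE, clamped = clamped),
            class = "cal_shift")
}

#' Apply (undo) an estimated shift
#'
#' Translates the frame by `-(dy, dx)` via a Fourier phase shift so that a
#' frame registered against the template lines back up with it. Pixels that
#' would come from outside the field of view are filled with the frame
#' median, which is neutral with respect to dF/F0 baselines.
#'
#' @param frame frame or pixel matrix.
#' @param shift a `cal_shift` or `list(dy=, dx=)`.
#' @param fill replace wrapped border pixels with the frame median; set
#'   `FALSE` for a pure (circular) translation, which composes exactly.
#' @return same type as `frame`, translated.
#' @export
apply_shift <- function(frame, shift, fill = TRUE) {
  px <- as_pixels(frame)
  out <- if (fill) translate_image(px, -shift$dy, -shift$dx)
         else translate_image(px, -shift$dy, -shift$dx, fill = NULL)
  if (inherits(frame, "cal_frame")) {
    frame$pixels <- out
    frame
  } else out
}
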