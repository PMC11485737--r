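#' Stream configuration
#'
#' Describes a source of grayscale movie frames: a headerless raw-binary file
#' (frame-major, row-major within frame, little-endian 16-bit, either unsigned
#' ThorImage-style or signed PrairieView-style samples) or a multi-page TIF
#' stack. Frame geometry and rate are taken from the configuration, never from
#' vendor metadata.
#'
#' @param source_path path to the movie file (may not exist yet in live mode).
#' @param dialect one of `"raw_u16"`, `"raw_s16"`, `"tif"`.
#' @param height,width frame dimensions in pixels.
#' @param frame_rate acquisition rate in Hz.
#' @param poll_interval_s polling period while waiting for new bytes (live
#'   mode).
#' @param replay if `TRUE` the file is treated as complete (offline replay);
#'   if `FALSE` the reader polls a growing file.
#' @param timeout_s live mode only: end the stream if no complete new frame
#'   appears within this many seconds.
#' @param signed_mode how signed samples are mapped to unsigned, see
#'   [convert_signed()].
#' @return a `stream_config` list.
#' @export
stream_config <- function(source_path,
                          dialect = c("raw_u16", "raw_s16", "tif"),
                          height, width, frame_rate = 30,
                          poll_interval_s = 0.02, replay = TRUE,
                          timeout_s = 10, signed_mode = "clamp") {
  dialect <- match.arg(dialect)
  stopifnot(height > 0, width > 0, frame_rate > 0)
  structure(list(source_path = source_path, dialect = dialect,
                 height = as.integer(height), width = as.integer(width),
                 frame_rate = frame_rate, poll_interval_s = poll_interval_s,
                 replay = replay, timeout_s = timeout_s,
                 signed_mode = signed_mode),
            class = "stream_config")
}

new_frame <- function(pixels, index, frame_rate) {
  structure(list(pixels = pixels, index = as.integer(index),
                 time_s = index / frame_rate),
            class = "cal_frame")
}

#' Map signed 16-bit samples to the unsigned intensity range
#'
#' PrairieView raw binaries store signed 16-bit samples; downstream analysis
#' runs on unsigned intensities. The default `"clamp"` mode sets negative
#' samples (PMT offsets below zero, which carry no signal) to 0; `"offset"`
#' adds 32768 instead. Both maps are deterministic and monotone.
#'
#' @param raw numeric matrix/vector of signed 16-bit values.
#' @param mode `"clamp"` (default) or `"offset"`.
#' @return values in \[0, 65535\].
#' @export
convert_signed <- function(raw, mode = c("clamp", "offset")) {
  mode <- match.arg(mode)
  out <- if (mode == "clamp") pmax(raw, 0) else raw + 32768
  pmin(out, 65535)
}

read_raw_frame <- function(con, h, w, signed, signed_mode) {
  v <- readBin(con, "integer", n = h * w, size = 2L, signed = signed,
               endian = "little")
  if (length(v) < h * w) return(NULL)
  if (signed) v <- convert_signed(v, signed_mode)
  # file is row-major; R matrices are column-major
  matrix(v, nrow = h, ncol = w, byrow = TRUE)
}

#' Read a grayscale TIF stack as a list of frames
#'
#' Pages are yielded in file order; 8-bit input is upcast to the unsigned
#' 16-bit range without rescaling. Non-grayscale (e.g. RGB) pages are a fatal
#' format error.
#'
#' @param path TIF file path.
#' @return list of integer-valued pixel matrices.
#' @export
read_tif_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      stop("non-grayscale TIF page (", paste(dim(p), collapse = "x"), ")")
    storage.mode(p) <- "double"
    p
  })
}

#' Open a frame stream
#'
#' Returns an iterator over [stream_config()] frames. In replay mode the file
#' is read straight through; in live mode the reader polls the growing file
#' and only yields a frame once all of its bytes are present, so a partially
#' written frame is never seen. A truncated final frame ends the stream
#' cleanly before it.
#'
#' @param config a [stream_config()].
#' @return an object with `$next_frame()` (returns a frame or `NULL` at end
#'   of stream) and `$close()`.
#' @export
open_stream <- function(config) {
  stopifnot(inherits(config, "stream_config"))
  h <- config$height; w <- config$width
  frame_bytes <- h * w * 2L
  idx <- 0L

  if (config$dialect == "tif") {
    if (!file.exists(config$source_path)) stop("unreadable source: ",
                                               config$source_path)
    pages <- read_tif_stack(config$source_path)
    bad <- vapply(pages, function(p) nrow(p) != h || ncol(p) != w, logical(1))
    if (any(bad)) stop("TIF page shape does not match configured geometry")
    nf <- function() {
      if (idx >= length(pages)) return(NULL)
      idx <<- idx + 1L
      new_frame(pages[[idx]], idx - 1L, config$frame_rate)
    }
    return(structure(list(next_frame = nf, close = function() invisible()),
                     class = "frame_stream"))
  }

  if (config$replay && !file.exists(config$source_path))
    stop("unreadable source: ", config$source_path)
  signed <- config$dialect == "raw_s16"
  con <- NULL
  ensure_con <- function() {
    if (is.null(con) && file.exists(config$source_path))
      con <<- file(config$source_path, "rb")
    !is.null(con)
  }
  nf <- function() {
    need <- (idx + 1) * frame_bytes
    if (config$replay) {
      if (!ensure_con()) return(NULL)
      if (file.size(config$source_path) < need) return(NULL)
    } else {
      t0 <- Sys.time()
      while (!ensure_con() ||
             (file.size(config$source_path) %||% 0) < need) {
        if (as.numeric(Sys.time() - t0, units = "secs") > config$timeout_s)
          return(NULL)
        Sys.sleep(config$poll_interval_s)
      }
    }
    px <- read_raw_frame(con, h, w, signed, config$signed_mode)
    if (is.null(px)) return(NULL)
    idx <<- idx + 1L
    new_frame(px, idx - 1L, config$frame_rate)
  }
  structure(list(next_frame = nf,
                 close = function() if (!is.null(con)) close(con)),
            class = "frame_stream")
}

#' Collect every frame of a stream into a list
#' @param config a [stream_config()].
#' @return list of frames.
#' @export
read_all_frames <- function(config) {
  st <- open_stream(config)
  on.exit(st$close())
  out <- list()
  while (!is.null(f <- st$next_frame())) out[[length(out) + 1L]] <- f
  out
}

# u16 little-endian encoding that is safe for values > 32767
u16_bytes <- function(v) {
  v <- as.integer(round(v))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

#' Append frames to a raw-binary movie file
#'
#' Writes headerless little-endian 16-bit frames (row-major within frame).
#' Used by the synthetic-movie renderer and by live-mode test writers.
#'
#' @param pixels_list list of pixel matrices (values clipped to the dialect's
#'   range).
#' @param path output file.
#' @param dialect `"raw_u16"` or `"raw_s16"`.
#' @param append append to an existing file.
#' @export
write_raw_frames <- function(pixels_list, path, dialect = "raw_u16",
                             append = FALSE) {
  con <- file(path, if (append) "ab" else "wb")
  on.exit(close(con))
  for (px in pixels_list) {
    v <- as.vector(t(px))  # row-major
    if (dialect == "raw_s16") {
      v <- as.integer(round(pmin(pmax(v, -32768), 32767)))
      v[v < 0] <- v[v < 0] + 65536L
    } else {
      v <- pmin(pmax(round(v), 0), 65535)
    }
    writeBin(u16_bytes(v), con)
  }
  invisible(path)
}

#' Write frames as a 16-bit grayscale multi-page TIF
#' @param pixels_list list of pixel matrices with values in \[0, 65535\].
#' @param path output file.
#' @export
write_tif_stack <- function(pixels_list, path) {
  imgs <- lapply(pixels_list, function(px) pmin(pmax(px, 0), 65535) / 65535)
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}
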