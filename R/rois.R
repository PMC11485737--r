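#' Load cell-centre coordinates from CSV
#'
#' Expects a header `cell_id,x,y` with 0-based pixel coordinates
#' (x = column, y = row). Centres outside the frame are dropped with a
#' warning; duplicate ids are an error; an empty file is an error.
#'
#' @param path CSV path.
#' @param frame_shape `c(height, width)` in pixels.
#' @return data frame with columns `cell_id`, `x`, `y`.
#' @export
load_centers <- function(path, frame_shape) {
  df <- utils::read.csv(path)
  if (!all(c("cell_id", "x", "y") %in% names(df)))
    stop("centers file must have header cell_id,x,y")
  if (nrow(df) == 0) stop("no cells in centers file")
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in centers file")
  inb <- df$x >= 0 & df$x <= frame_shape[2] - 1 &
         df$y >= 0 & df$y <= frame_shape[1] - 1
  if (any(!inb)) {
    warning(sum(!inb), " center(s) outside frame bounds dropped")
    df <- df[inb, , drop = FALSE]
  }
  if (nrow(df) == 0) stop("no cells in bounds")
  df[, c("cell_id", "x", "y")]
}

#' Build ring-shaped soma masks for each cell centre
#'
#' Each soma mask is the annulus of pixels whose centre lies between
#' `r_inner` and `r_outer` (inclusive, Euclidean distance to the cell
#' centre), clipped to the frame.
#'
#' @param centers data frame from [load_centers()].
#' @param geometry list with `r_inner`, `r_outer` in pixels.
#' @param frame_shape `c(height, width)`.
#' @param pixel_size_um microns per pixel (used later for the neuropil
#'   extent); the default corresponds to a ~370 um field of view at 512 px.
#' @return a `roi_set`.
#' @export
build_soma_masks <- function(centers, geometry = list(r_inner = 2, r_outer = 6),
                             frame_shape, pixel_size_um = 370 / 512) {
  cells <- lapply(seq_len(nrow(centers)), function(i) {
    px <- annulus_pixels(centers$x[i], centers$y[i],
                         geometry$r_inner, geometry$r_outer, frame_shape)
    list(cell_id = centers$cell_id[i], x = centers$x[i], y = centers$y[i],
         soma = idx_linear(px, frame_shape[1]),
         soma_raw = idx_linear(px, frame_shape[1]),
         neuropil = integer(), inactive = FALSE)
  })
  names(cells) <- as.character(centers$cell_id)
  structure(list(cells = cells, geometry = geometry,
                 frame_shape = as.integer(frame_shape),
                 pixel_size_um = pixel_size_um, overlaps_resolved = FALSE),
            class = "roi_set")
}

#' Remove pixels shared by two or more soma masks
#'
#' Closely juxtaposed neurons can claim the same pixels; any pixel belonging
#' to at least two soma masks is excluded from all of them. A cell whose mask
#' becomes empty is flagged inactive with a warning. The pre-resolution masks
#' are retained internally so that neuropil annuli still exclude every
#' somatic pixel.
#'
#' @param roiset a [build_soma_masks()] result.
#' @return the updated `roi_set`.
#' @export
resolve_overlaps <- function(roiset) {
  all_px <- unlist(lapply(roiset$cells, `[[`, "soma"), use.names = FALSE)
  dup <- unique(all_px[duplicated(all_px)])
  for (i in seq_along(roiset$cells)) {
    keep <- !(roiset$cells[[i]]$soma %in% dup)
    roiset$cells[[i]]$soma <- roiset$cells[[i]]$soma[keep]
    if (length(roiset$cells[[i]]$soma) == 0) {
      roiset$cells[[i]]$inactive <- TRUE
      warning("cell ", roiset$cells[[i]]$cell_id,
              " has an empty soma mask after overlap resolution")
    }
  }
  roiset$overlaps_resolved <- TRUE
  roiset
}

#' Build neuropil annulus masks
#'
#' For each cell, the neuropil mask extends from 1 pixel beyond the soma
#' outer radius to 15 um (converted with `pixel_size_um`), excluding every
#' pixel assigned to any soma (including the cell's own).
#'
#' @param roiset a resolved `roi_set`.
#' @param pixel_size_um microns per pixel; defaults to the value stored in
#'   the `roi_set`.
#' @param neuropil_extent_um outer extent of the annulus in microns.
#' @return the updated `roi_set`.
#' @export
build_neuropil_masks <- function(roiset, pixel_size_um = NULL,
                                 neuropil_extent_um = 15) {
  pixel_size_um <- pixel_size_um %||% roiset$pixel_size_um
  r_out <- roiset$geometry$r_outer
  soma_union <- unique(unlist(lapply(roiset$cells, `[[`, "soma_raw"),
                              use.names = FALSE))
  for (i in seq_along(roiset$cells)) {
    cc <- roiset$cells[[i]]
    px <- annulus_pixels(cc$x, cc$y, r_out + 1,
                         r_out + neuropil_extent_um / pixel_size_um,
                         roiset$frame_shape)
    idx <- idx_linear(px, roiset$frame_shape[1])
    roiset$cells[[i]]$neuropil <- setdiff(idx, soma_union)
  }
  roiset$pixel_size_um <- pixel_size_um
  roiset
}

#' Full ROI construction from a centres file
#'
#' Convenience wrapper: load centres, build soma rings, resolve overlaps,
#' build neuropil annuli.
#'
#' @inheritParams load_centers
#' @inheritParams build_soma_masks
#' @return a `roi_set`.
#' @export
build_roi_set <- function(path, frame_shape,
                          geometry = list(r_inner = 2, r_outer = 6),
                          pixel_size_um = 370 / 512) {
  centers <- load_centers(path, frame_shape)
  rs <- build_soma_masks(centers, geometry, frame_shape, pixel_size_um)
  rs <- resolve_overlaps(rs)
  build_neuropil_masks(rs)
}

#' Export ROI masks as a label image
#'
#' Writes a 16-bit grayscale TIF: 0 background, `cell_id + 1` for soma
#' pixels, `cell_id + 1 + offset` for neuropil pixels.
#'
#' @param roiset a `roi_set`.
#' @param path output TIF path.
#' @param neuropil_offset label offset for neuropil pixels.
#' @export
write_roi_labels <- function(roiset, path, neuropil_offset = 10000L) {
  lab <- matrix(0L, roiset$frame_shape[1], roiset$frame_shape[2])
  for (cc in roiset$cells) {
    lab[cc$neuropil] <- as.integer(cc$cell_id) + 1L + neuropil_offset
    lab[cc$soma] <- as.integer(cc$cell_id) + 1L
  }
  write_tif_stack(list(lab), path)
}

#' @export
print.roi_set <- function(x, ...) {
  n_np <- sum(vapply(x$cells, function(c) length(c$neuropil) > 0, logical(1)))
  cat("<roi_set> ", length(x$cells), " cells on ",
      paste(x$frame_shape, collapse = "x"),
      "; r_inner=", x$geometry$r_inner, " r_outer=", x$geometry$r_outer,
      "; overlaps ", if (x$overlaps_resolved) "resolved" else "unresolved",
      "; neuropil masks: ", n_np, "\n", sep = "")
  invisible(x)
}
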