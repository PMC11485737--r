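#' Affine calibration from imaging FOV to SLM-conjugate coordinates
#'
#' Maps FOV pixel coordinates to the simulated focal plane via an invertible
#' affine transform (2x2 matrix plus offset). The default is the identity; a
#' 3-point correspondence file (CSV with columns
#' `fov_x,fov_y,slm_x,slm_y`) determines the transform uniquely.
#'
#' @param A 2x2 matrix.
#' @param b length-2 offset.
#' @return a `calibration_map`.
#' @export
calibration_map <- function(A = diag(2), b = c(0, 0)) {
  stopifnot(all(dim(A) == c(2, 2)), length(b) == 2)
  if (abs(det(A)) < 1e-12) stop("calibration transform is not invertible")
  structure(list(A = A, b = b), class = "calibration_map")
}

#' @rdname calibration_map
#' @param path CSV with >= 3 correspondence rows.
#' @export
load_calibration <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(nrow(df) >= 3)
  X <- cbind(df$fov_x, df$fov_y, 1)
  bx <- stats::lm.fit(X, df$slm_x)$coefficients
  by <- stats::lm.fit(X, df$slm_y)$coefficients
  calibration_map(A = rbind(bx[1:2], by[1:2]), b = c(bx[3], by[3]))
}

map_fov <- function(calib, xy) as.vector(calib$A %*% xy + calib$b)

#' Specify a photostimulation target
#'
#' @param cell_id integer id.
#' @param fov_xy `c(x, y)` pixel coordinates in the imaging FOV.
#' @param shape `"disk"` or `"vortex"`.
#' @param disk_radius_px disk beamlet radius (disk shape).
#' @param L optical-vortex mode (nonzero integer; vortex shape). Fig-style
#'   modes 4-6 give rings of increasing size.
#' @param vortex_r0 base ring radius; the ring radius is `r0 * sqrt(|L|)`.
#' @return a `target_spec`.
#' @export
target_spec <- function(cell_id, fov_xy, shape = c("disk", "vortex"),
                        disk_radius_px = 3, L = 5, vortex_r0 = 3) {
  shape <- match.arg(shape)
  if (shape == "vortex" && L == 0) stop("vortex mode L must be nonzero")
  structure(list(cell_id = cell_id, fov_xy = fov_xy, shape = shape,
                 disk_radius_px = disk_radius_px, L = as.integer(L),
                 vortex_r0 = vortex_r0),
            class = "target_spec")
}

#' Superposed complex target amplitude field for a set of beamlets
#'
#' Disk targets contribute a uniform-amplitude disk; vortex targets a thin
#' ring of radius `r0 * sqrt(|L|)` carrying the spiral phase
#' `exp(i * L * theta)` (ring-shaped intensity with a central null). The
#' returned field also carries a logical `support` matrix marking the
#' constraint region each target claims (for a vortex this includes the
#' dark interior, so the null is enforced, not accidental).
#'
#' @param targets list of [target_spec()]s.
#' @param calib a [calibration_map()].
#' @param grid_shape `c(height, width)` of the virtual focal grid.
#' @return complex matrix with attributes `support` (logical matrix) and
#'   `centers` (n x 2 matrix of mapped row/col positions, 1-based).
#' @export
build_target_field <- function(targets, calib = calibration_map(),
                               grid_shape = c(512, 512)) {
  stopifnot(length(targets) >= 1)
  h <- grid_shape[1]; w <- grid_shape[2]
  field <- matrix(0 + 0i, h, w)
  support <- matrix(FALSE, h, w)
  centers <- matrix(0, length(targets), 2)
  for (ti in seq_along(targets)) {
    tg <- targets[[ti]]
    p <- map_fov(calib, tg$fov_xy)  # (x, y) in focal pixels, 0-based
    row <- p[2] + 1; col <- p[1] + 1
    if (row < 1 || row > h || col < 1 || col > w)
      stop("target for cell ", tg$cell_id, " maps off-grid")
    centers[ti, ] <- c(row, col)
    if (tg$shape == "disk") {
      px <- annulus_pixels(p[1], p[2], 0, tg$disk_radius_px, grid_shape)
      idx <- idx_linear(px, h)
      field[idx] <- field[idx] + 1
      support[idx] <- TRUE
    } else {
      rl <- tg$vortex_r0 * sqrt(abs(tg$L))
      disk <- annulus_pixels(p[1], p[2], 0, rl + 1, grid_shape)
      support[idx_linear(disk, h)] <- TRUE
      ring <- annulus_pixels(p[1], p[2], rl - 0.5, rl + 0.5, grid_shape)
      th <- atan2(ring[, 1] - 1 - p[2], ring[, 2] - 1 - p[1])
      idx <- idx_linear(ring, h)
      field[idx] <- field[idx] + exp(1i * tg$L * th)
    }
  }
  attr(field, "support") <- support
  attr(field, "centers") <- centers
  field
}

# Unitary single-lens far-field propagation between SLM and focal planes,
# with the focal DC at the grid centre.
propagate_fwd <- function(slm_field) fftshift2(fft2(slm_field)) / sqrt(length(slm_field))
propagate_inv <- function(focal_field)
  stats::fft(ifftshift2(focal_field), inverse = TRUE) / sqrt(length(focal_field))

#' Gerchberg-Saxton phase mask for a target field
#'
#' Iterates between the SLM plane (unit amplitude imposed, phase kept) and
#' the focal plane (target complex amplitude imposed on its support region,
#' field left free elsewhere) under the discrete far-field propagation
#' transform. The initial SLM phase is uniform random in \[0, 2pi), seeded.
#' The focal-plane residual on the support is recorded per iteration and is
#' non-increasing.
#'
#' @param target_field a [build_target_field()] result (or complex matrix;
#'   support defaults to `Mod(field) > 0`).
#' @param n_iterations number of GS iterations (>= 1, default 30).
#' @param seed RNG seed for the initial phase.
#' @return a `phase_mask`: `phase` matrix in \[0, 2pi), `slm_shape`, and
#'   attribute `errors` (per-iteration focal residual).
#' @export
gs_phase_mask <- function(target_field, n_iterations = 30, seed = 1) {
  stopifnot(n_iterations >= 1)
  amp <- Mod(target_field)
  if (all(amp == 0)) stop("all-zero target field")
  support <- attr(target_field, "support")
  if (is.null(support)) support <- amp > 0
  n <- length(target_field)
  # scale so the target carries the full beam energy
  target <- target_field * sqrt(n / sum(amp^2))
  phase0 <- withr::with_seed(seed,
    matrix(stats::runif(n, 0, 2 * pi), nrow(target_field)))
  slm <- exp(1i * phase0)
  errors <- numeric(n_iterations)
  for (it in seq_len(n_iterations)) {
    focal <- propagate_fwd(slm)
    errors[it] <- sqrt(sum(Mod(focal[support] - target[support])^2) / n)
    focal[support] <- target[support]
    back <- propagate_inv(focal)
    slm <- exp(1i * Arg(back))
  }
  structure(list(phase = Arg(slm) %% (2 * pi),
                 slm_shape = dim(target_field)),
            class = "phase_mask", errors = errors,
            centers = attr(target_field, "centers"))
}

#' Simulated focal-plane intensity of a phase mask
#'
#' Propagates a unit-amplitude field carrying the mask's phase to the focal
#' plane and returns `|.|^2` normalized to total 1. The pre-normalization
#' total equals the input power (energy conservation) and is kept in
#' attribute `total_power`.
#'
#' @param mask a [gs_phase_mask()] result (or phase matrix).
#' @return intensity matrix summing to 1.
#' @export
simulate_intensity <- function(mask) {
  phase <- if (inherits(mask, "phase_mask")) mask$phase else mask
  focal <- propagate_fwd(exp(1i * phase))
  ii <- Mod(focal)^2
  tot <- sum(ii)
  structure(ii / tot, total_power = tot)
}

#' Fraction of focal intensity captured at the targets
#'
#' Sum of the (normalized) simulated intensity within a capture disk around
#' each mapped target position.
#'
#' @param intensity a [simulate_intensity()] result.
#' @param centers n x 2 matrix of target (row, col) positions (1-based), as
#'   stored on a `phase_mask`, or a list of [target_spec()]s plus `calib`.
#' @param capture_radius_px capture disk radius.
#' @param calib calibration used when `centers` is a target list.
#' @return fraction in \[0, 1\].
#' @export
target_efficiency <- function(intensity, centers, capture_radius_px = 5,
                              calib = calibration_map()) {
  if (is.list(centers) && !is.matrix(centers)) {
    centers <- t(vapply(centers, function(tg) {
      p <- map_fov(calib, tg$fov_xy); c(p[2] + 1, p[1] + 1)
    }, numeric(2)))
  }
  h <- nrow(intensity)
  idx <- unique(unlist(lapply(seq_len(nrow(centers)), function(i) {
    px <- annulus_pixels(centers[i, 2] - 1, centers[i, 1] - 1, 0,
                         capture_radius_px, dim(intensity))
    idx_linear(px, h)
  })))
  sum(intensity[idx])
}

#' Precompute the mask sequence for sequential stimulation
#'
#' One phase mask per target, in list order, each with dwell `1 / rate_hz`;
#' masks are fully computed before the sequence starts (the virtual
#' equivalent of predownloading them to the SLM driver). Seeds are derived
#' deterministically per target, so the same call reproduces bit-identical
#' masks.
#'
#' @param targets list of [target_spec()]s.
#' @param calib a [calibration_map()].
#' @param grid_shape virtual SLM grid.
#' @param rate_hz sequence rate (> 0).
#' @param n_iterations GS iterations per mask.
#' @param seed base seed.
#' @return list of `list(mask, dwell_s, cell_id)`.
#' @export
sequence_masks <- function(targets, calib = calibration_map(),
                           grid_shape = c(512, 512), rate_hz = 2,
                           n_iterations = 30, seed = 1) {
  stopifnot(rate_hz > 0)
  lapply(seq_along(targets), function(i) {
    tf <- build_target_field(targets[i], calib, grid_shape)
    list(mask = gs_phase_mask(tf, n_iterations, seed = seed + i - 1L),
         dwell_s = 1 / rate_hz, cell_id = targets[[i]]$cell_id)
  })
}

#' Record a (virtual) photostimulation event
#'
#' Appends a stimulation record to the event log; in virtual mode no
#' hardware I/O happens. Laser-power values are metadata echoed in the
#' record, never used in computation.
#'
#' @param event_log an [event_log_open()] handle (or `NULL` to only return
#'   the record).
#' @param time_s stream time of the trigger.
#' @param targets list of [target_spec()]s.
#' @param params list of stimulation parameters; defaults: duration 30 ms,
#'   period 3 s.
#' @param mask_files optional character vector of phase-mask file
#'   references.
#' @return the stimulation record (list), invisibly logged.
#' @export
stimulate <- function(event_log, time_s, targets,
                      params = list(duration_ms = 30, period_s = 3),
                      mask_files = NULL) {
  shp <- vapply(targets, `[[`, character(1), "shape")
  rec <- list(
    cell_ids = vapply(targets, `[[`, numeric(1), "cell_id"),
    shape = unique(shp),
    L = if (any(shp == "vortex"))
      vapply(targets[shp == "vortex"], `[[`, numeric(1), "L") else NULL,
    radius_px = if (any(shp == "disk"))
      vapply(targets[shp == "disk"], `[[`, numeric(1), "disk_radius_px")
      else NULL,
    duration_ms = params$duration_ms %||% 30,
    period_s = params$period_s %||% 3,
    power_mw = params$power_mw,
    mask_files = mask_files)
  rec <- rec[!vapply(rec, is.null, logical(1))]
  if (!is.null(event_log)) log_event(event_log, time_s, "stimulation", rec)
  invisible(c(list(time_s = time_s), rec))
}

#' Write a phase mask as an 8-bit grayscale PNG
#'
#' Phase is mapped linearly from \[0, 2pi) to \[0, 255\]. A lossless
#' plain-text CSV of the raw phase values can be written alongside.
#'
#' @param mask a `phase_mask`.
#' @param path output PNG path.
#' @param csv_path optional CSV path for the float phase values.
#' @export
write_phase_mask <- function(mask, path, csv_path = NULL) {
  png::writePNG(mask$phase / (2 * pi), path)
  if (!is.null(csv_path))
    utils::write.table(mask$phase, csv_path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
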