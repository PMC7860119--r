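#' Simulation / acquisition configuration
#'
#' Collects the physical calibration and camera-noise parameters shared by the
#' synthetic-data generator and the analysis stages. Defaults reproduce the
#' Slimfield acquisition geometry: 50 nm pixels, 5 ms frames, and a Gaussian
#' point-spread function whose fitted full width at half maximum falls in the
#' diffraction-limited 250-300 nm band.
#'
#' @param pixel_size_um Length of one camera pixel, in micrometres.
#' @param frame_interval_s Time between consecutive frames, in seconds.
#' @param n_frames Number of movie frames.
#' @param image_shape Integer vector `c(ny, nx)`: image height and width in
#'   pixels.
#' @param psf_sigma_um Gaussian PSF standard deviation, in micrometres. The
#'   default 0.12 um corresponds to a FWHM of ~283 nm.
#' @param unitary_brightness Camera counts collected from one fluorophore in
#'   one frame (integrated over the PSF).
#' @param bleach_rate Per-fluorophore probability of irreversible
#'   photobleaching per frame, in `[0, 1]`.
#' @param read_noise_sd Gaussian camera read noise, in counts.
#' @param autofluorescence_level Mean cellular autofluorescence, counts per
#'   pixel inside the cell.
#' @param background_level Mean extracellular background, counts per pixel.
#' @param shot_noise Apply Poisson shot noise? Set `FALSE` (together with
#'   `read_noise_sd = 0`) for noise-free ground-truth rendering.
#' @param cell_axes_um Semi-axes `c(a, b)` of the elliptical cell body, in
#'   micrometres.
#' @param cell_centre_um Centre of the cell, in micrometres; defaults to the
#'   image centre.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 10, image_shape = c(64, 64))
#' cfg$pixel_size_um
sim_config <- function(pixel_size_um = 0.05,
                       frame_interval_s = 0.005,
                       n_frames = 100L,
                       image_shape = c(128L, 128L),
                       psf_sigma_um = 0.12,
                       unitary_brightness = 150,
                       bleach_rate = 0.01,
                       read_noise_sd = 3,
                       autofluorescence_level = 10,
                       background_level = 5,
                       shot_noise = TRUE,
                       cell_axes_um = NULL,
                       cell_centre_um = NULL) {
  check_number(pixel_size_um, "pixel_size_um", 0, strict_min = TRUE)
  check_number(frame_interval_s, "frame_interval_s", 0, strict_min = TRUE)
  check_number(n_frames, "n_frames", 1)
  if (length(image_shape) != 2L || any(image_shape < 8)) {
    abort("`image_shape` must be c(ny, nx) with both >= 8")
  }
  check_number(psf_sigma_um, "psf_sigma_um", 0, strict_min = TRUE)
  check_number(unitary_brightness, "unitary_brightness", 0, strict_min = TRUE)
  check_number(bleach_rate, "bleach_rate", 0, 1)
  check_number(read_noise_sd, "read_noise_sd", 0)
  check_number(autofluorescence_level, "autofluorescence_level", 0)
  check_number(background_level, "background_level", 0)
  ny <- as.integer(image_shape[1]); nx <- as.integer(image_shape[2])
  if (is.null(cell_axes_um)) {
    cell_axes_um <- c(0.32, 0.27) * nx * pixel_size_um
  }
  if (any(cell_axes_um <= 0)) abort("`cell_axes_um` must be positive")
  if (is.null(cell_centre_um)) {
    cell_centre_um <- c(nx / 2, ny / 2) * pixel_size_um
  }
  structure(list(
    pixel_size_um = pixel_size_um,
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    image_shape = c(ny, nx),
    psf_sigma_um = psf_sigma_um,
    unitary_brightness = unitary_brightness,
    bleach_rate = bleach_rate,
    read_noise_sd = read_noise_sd,
    autofluorescence_level = autofluorescence_level,
    background_level = background_level,
    shot_noise = isTRUE(shot_noise),
    cell_axes_um = cell_axes_um,
    cell_centre_um = cell_centre_um
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  image %d x %d px, %.0f nm/px, %.1f ms/frame, %d frames\n",
              x$image_shape[2], x$image_shape[1], x$pixel_size_um * 1000,
              x$frame_interval_s * 1000, x$n_frames))
  cat(sprintf("  PSF sigma %.0f nm (FWHM %.0f nm), I1 = %.0f counts\n",
              x$psf_sigma_um * 1000, 2.355 * x$psf_sigma_um * 1000,
              x$unitary_brightness))
  cat(sprintf("  bleach %.3g/frame, read noise %.1f, autofl %.1f, bg %.1f\n",
              x$bleach_rate, x$read_noise_sd, x$autofluorescence_level,
              x$background_level))
  invisible(x)
}

# TRUE for points (in um) inside the elliptical cell body.
inside_cell <- function(config, x_um, y_um) {
  cx <- config$cell_centre_um[1]; cy <- config$cell_centre_um[2]
  a <- config$cell_axes_um[1]; b <- config$cell_axes_um[2]
  ((x_um - cx) / a)^2 + ((y_um - cy) / b)^2 <= 1
}

#' Cell-body mask and membrane contour of a simulation configuration
#'
#' The cell body is a filled ellipse; the membrane is its boundary contour
#' (nominal physical width 7 nm, far below one pixel, so the contour is a
#' curve, not a region).
#'
#' @param config A [sim_config()].
#' @return `cell_mask()`: a logical matrix (`TRUE` inside the cell).
#'   `cell_contour()`: a tibble with columns `x_um`, `y_um`, `x_px`, `y_px`,
#'   closed (last point equals the first), of class `membrane_contour`.
#' @export
cell_mask <- function(config) {
  ny <- config$image_shape[1]; nx <- config$image_shape[2]
  px <- config$pixel_size_um
  xc <- (seq_len(nx) - 0.5) * px
  yc <- (seq_len(ny) - 0.5) * px
  outer(yc, xc, function(y, x) inside_cell(config, x, y))
}

#' @rdname cell_mask
#' @param n_points Number of contour vertices before closing.
#' @export
cell_contour <- function(config, n_points = 720L) {
  th <- seq(0, 2 * pi, length.out = n_points + 1L)
  x <- config$cell_centre_um[1] + config$cell_axes_um[1] * cos(th)
  y <- config$cell_centre_um[2] + config$cell_axes_um[2] * sin(th)
  new_contour(x, y, config$pixel_size_um)
}

# Constructor for a closed membrane contour from um coordinates.
new_contour <- function(x_um, y_um, pixel_size_um) {
  if (abs(x_um[1] - x_um[length(x_um)]) > 1e-9 ||
      abs(y_um[1] - y_um[length(y_um)]) > 1e-9) {
    x_um <- c(x_um, x_um[1]); y_um <- c(y_um, y_um[1])
  }
  out <- tibble(
    x_um = x_um, y_um = y_um,
    x_px = x_um / pixel_size_um, y_px = y_um / pixel_size_um
  )
  attr(out, "pixel_size_um") <- pixel_size_um
  attr(out, "membrane_width_um") <- 0.007
  class(out) <- c("membrane_contour", class(out))
  out
}

#' Arc length of a closed membrane contour
#'
#' @param contour A contour tibble from [cell_contour()] or
#'   [mask_contour()].
#' @return Total perimeter in micrometres.
#' @export
contour_perimeter <- function(contour) {
  dx <- diff(contour$x_um); dy <- diff(contour$y_um)
  sum(sqrt(dx^2 + dy^2))
}

#' Extract a sub-pixel membrane contour from a cell mask
#'
#' Smooths the binary mask lightly and traces the 0.5 level set, giving a
#' closed sub-pixel boundary curve suitable for
#' [contiguous_membrane_signal()].
#'
#' @param mask Logical matrix (`TRUE` inside the cell).
#' @param pixel_size_um Pixel size in micrometres.
#' @param smooth_sigma_px Gaussian smoothing applied to the mask before
#'   tracing, in pixels.
#' @return A closed contour tibble (see [cell_contour()]). If several closed
#'   level-set curves exist, the longest is returned.
#' @export
mask_contour <- function(mask, pixel_size_um, smooth_sigma_px = 1) {
  z <- gauss_blur(mask * 1, smooth_sigma_px)
  # contourLines treats x as rows; pass pixel-centre coordinates (0-based
  # continuous convention: centre of pixel i is i - 0.5).
  ny <- nrow(z); nx <- ncol(z)
  cl <- grDevices::contourLines(x = seq_len(ny) - 0.5, y = seq_len(nx) - 0.5,
                                z = z, levels = 0.5)
  if (!length(cl)) abort("no boundary found in mask")
  len <- vapply(cl, function(c0) length(c0$x), numeric(1))
  c0 <- cl[[which.max(len)]]
  # contourLines x follows rows (our y), y follows columns (our x)
  new_contour(c0$y * pixel_size_um, c0$x * pixel_size_um, pixel_size_um)
}
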