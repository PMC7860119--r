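# Per-focus stoichiometry, MSD/diffusion fitting and whole-cell copy number.

#' Initial unbleached brightness of a tracked focus
#'
#' Fits a single-exponential decay to the track's background-corrected
#' intensity series and evaluates it at the first frame; if the fit does not
#' converge the mean of the first three frames is used instead.
#'
#' @param intensity Numeric intensity series (counts), in time order.
#' @param frame Optional frame indices (defaults to `0:(n-1)`).
#' @return A list: `I0` (counts), `method` (`"exponential"` or
#'   `"first3_mean"`), `warning` flag for degenerate traces.
#' @export
#' @examples
#' initial_brightness(600 * exp(-(0:99) / 50))$I0
initial_brightness <- function(intensity, frame = NULL) {
  n <- length(intensity)
  if (n < 3L) abort("track must have at least 3 frames")
  if (is.null(frame)) frame <- seq_len(n) - 1L
  t0 <- frame - frame[1]
  if (all(intensity == 0)) {
    return(list(I0 = 0, method = "degenerate", warning = TRUE))
  }
  fit <- tryCatch({
    d <- data.frame(t = t0, y = intensity)
    m <- nls(y ~ A * exp(-t / tau), data = d,
             start = list(A = max(intensity),
                          tau = max(n / 2, 1)),
             control = stats::nls.control(warnOnly = FALSE, maxiter = 100))
    unname(predict(m, newdata = data.frame(t = 0)))
  }, error = function(e) NULL)
  if (is.null(fit) && all(intensity > 0)) {
    # noise-free or near-perfect decays defeat nls (zero-residual start);
    # the log-linear fit is exact there
    lf <- stats::lm(log(intensity) ~ t0)
    fit <- exp(unname(coef(lf)[1]))
  }
  if (!is.null(fit) && is.finite(fit) && fit >= 0) {
    list(I0 = fit, method = "exponential", warning = FALSE)
  } else {
    list(I0 = mean(intensity[1:3]), method = "first3_mean", warning = FALSE)
  }
}

#' Stoichiometry of a focus
#'
#' Molecules per focus: the initial unbleached brightness of the track
#' divided by the calibrated brightness of a single fluorophore. The
#' continuous value is retained (no rounding).
#'
#' @param intensity Track intensity series, counts.
#' @param I1 Unitary brightness: a positive number or a
#'   `unitary_brightness` object from [estimate_unitary_brightness()].
#' @param track_id Optional identifier stamped into the result.
#' @return One-row tibble: `track_id`, `S`, `I0`, `I1`, `method`.
#' @export
stoichiometry <- function(intensity, I1, track_id = NA_integer_) {
  if (inherits(I1, "unitary_brightness")) I1 <- I1$I1
  if (!is.numeric(I1) || I1 <= 0) abort("`I1` must be > 0")
  ib <- initial_brightness(intensity)
  tibble(track_id = track_id, S = ib$I0 / I1, I0 = ib$I0, I1 = I1,
         method = ib$method)
}

#' Stoichiometry for every track in a linked spot table
#'
#' @param tracks Output of [link_tracks()] (needs `track_id`, `frame`,
#'   `intensity`).
#' @param I1 See [stoichiometry()].
#' @param min_length Tracks shorter than this are skipped.
#' @return Tibble with one row per retained track.
#' @export
track_stoichiometries <- function(tracks, I1, min_length = 3L) {
  tracks <- arrange(as_tibble(tracks), .data$track_id, .data$frame)
  splits <- split(tracks$intensity, tracks$track_id)
  splits <- splits[vapply(splits, length, integer(1)) >= min_length]
  bind_rows(purrr::imap(splits, function(x, id) {
    stoichiometry(x, I1, track_id = as.integer(id))
  }))
}

#' Mean square displacement of a track
#'
#' For each time lag `k * frame_interval` the MSD is the mean squared 2-D
#' displacement over all ordered same-track position pairs separated by `k`
#' frames (overlapping pairs included by default).
#'
#' @param track Tibble with `frame`, `x_um`, `y_um` for one track.
#' @param frame_interval_s Frame interval, s.
#' @param overlapping Use all (overlapping) pairs (`TRUE`, default) or only
#'   non-overlapping independent pairs.
#' @param max_lag Largest lag (frames) to evaluate; default all available.
#' @return A tibble of class `msd_curve`: `lag` (frames), `tau_s`, `msd`
#'   (um^2), `n_pairs`.
#' @export
compute_msd <- function(track, frame_interval_s = 0.005, overlapping = TRUE,
                        max_lag = NULL) {
  track <- arrange(as_tibble(track), .data$frame)
  n <- nrow(track)
  if (n < 2L) abort("track must have at least 2 points")
  fr <- track$frame
  lags <- seq_len(if (is.null(max_lag)) max(fr) - min(fr) else max_lag)
  rows <- purrr::map(lags, function(k) {
    if (overlapping) {
      i <- seq_len(n); j <- match(fr + k, fr)
      ok <- !is.na(j)
      i <- i[ok]; j <- j[ok]
    } else {
      # independent pairs: stride k through the frames present
      i <- j <- integer(0)
      nxt <- 1L
      while (nxt <= n) {
        jj <- match(fr[nxt] + k, fr)
        if (!is.na(jj)) { i <- c(i, nxt); j <- c(j, jj); nxt <- jj }
        else nxt <- nxt + 1L
      }
    }
    if (!length(i)) return(NULL)
    d2 <- (track$x_um[j] - track$x_um[i])^2 +
      (track$y_um[j] - track$y_um[i])^2
    tibble(lag = k, tau_s = k * frame_interval_s, msd = mean(d2),
           n_pairs = length(i))
  })
  out <- bind_rows(rows)
  class(out) <- c("msd_curve", class(out))
  out
}

#' Apparent diffusion coefficient from an MSD curve
#'
#' Least-squares slope of `msd - 4 * sigma^2` against lag time over the
#' first `n_lags` lags, with the intercept constrained to zero — i.e. the
#' fitted line passes exactly through `4 * sigma^2` at zero lag, the
#' contribution of the localisation precision sigma (default 40 nm). The
#' apparent microscopic diffusion coefficient is `D = slope / 4`; negative
#' slopes are clipped to `D = 0` and flagged.
#'
#' @param msd An `msd_curve` from [compute_msd()] (or any tibble with
#'   `tau_s` and `msd`).
#' @param sigma_um Localisation precision, um.
#' @param n_lags Number of initial lags used in the fit.
#' @param track_id Optional identifier.
#' @return An object of class `diffusion_fit`: fields `D` (um^2/s),
#'   `sigma_um`, `n_lags`, `clipped`, `residual_rms`, `track_id`. Supports
#'   [generics::tidy()] and [generics::glance()].
#' @export
#' @examples
#' msd <- tibble::tibble(tau_s = (1:5) * 0.005,
#'                       msd = 0.4 * (1:5) * 0.005 + 4 * 0.04^2)
#' fit_diffusion(msd)$D
fit_diffusion <- function(msd, sigma_um = 0.04, n_lags = 5L,
                          track_id = NA_integer_) {
  if (nrow(msd) < n_lags) {
    abort(sprintf("MSD curve has %d lags; %d required", nrow(msd), n_lags))
  }
  msd <- msd[seq_len(n_lags), ]
  y <- msd$msd - 4 * sigma_um^2
  tau <- msd$tau_s
  m <- sum(tau * y) / sum(tau^2)
  clipped <- m < 0
  D <- max(m, 0) / 4
  resid <- y - m * tau
  structure(list(D = D, slope = m, sigma_um = sigma_um,
                 n_lags = as.integer(n_lags), clipped = clipped,
                 residual_rms = sqrt(mean(resid^2)), track_id = track_id),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s (sigma = %.0f nm, %d lags%s)\n",
              x$D, x$sigma_um * 1000, x$n_lags,
              if (x$clipped) ", negative slope clipped" else ""))
  invisible(x)
}

#' Per-track diffusion coefficients for a linked spot table
#'
#' @param tracks Output of [link_tracks()].
#' @param frame_interval_s Frame interval, s.
#' @param sigma_um Localisation precision, um.
#' @param n_lags Lags used per fit; tracks with fewer than `n_lags + 1`
#'   spots are excluded.
#' @param overlapping Passed to [compute_msd()].
#' @return Tibble: `track_id`, `D`, `clipped`, `residual_rms`, `n_spots`.
#' @export
track_diffusion <- function(tracks, frame_interval_s = 0.005,
                            sigma_um = 0.04, n_lags = 5L,
                            overlapping = TRUE) {
  tracks <- arrange(as_tibble(tracks), .data$track_id, .data$frame)
  splits <- split(tracks[, c("frame", "x_um", "y_um")], tracks$track_id)
  splits <- splits[vapply(splits, nrow, integer(1)) >= n_lags + 1L]
  rows <- purrr::imap(splits, function(tr, id) {
    msd <- compute_msd(tr, frame_interval_s, overlapping, max_lag = n_lags)
    if (nrow(msd) < n_lags) return(NULL)
    f <- fit_diffusion(msd, sigma_um, n_lags)
    tibble(track_id = as.integer(id), D = f$D, clipped = f$clipped,
           residual_rms = f$residual_rms, n_spots = nrow(tr))
  })
  bind_rows(rows)
}

#' Whole-cell copy number from corrected integrated density
#'
#' The integrated density (summed pixel counts) over the cell measurement
#' region in the first, least-bleached frame is corrected by subtracting the
#' expected extracellular background and cellular autofluorescence, then
#' divided by the unitary brightness of one fluorophore.
#'
#' @param im Numeric matrix: the first frame of the channel.
#' @param mask Logical matrix: measurement region (cell mask, normally
#'   dilated a few PSF sigma so membrane-proximal signal is fully captured).
#' @param I1 Unitary brightness (counts/molecule/frame) or a
#'   `unitary_brightness` object.
#' @param background_per_px Extracellular background, counts/pixel.
#' @param autofluorescence_per_px Cellular autofluorescence averaged over
#'   the same measurement region, counts/pixel (measure with
#'   [autofluorescence_reference()] on matched non-expressing cells).
#' @param cell_id Optional identifier.
#' @return One-row tibble: `cell_id`, `copies`, `integrated_density`,
#'   `background_term`, `autofluorescence_term`, `negative_corrected` flag.
#' @export
copy_number <- function(im, mask, I1, background_per_px = 0,
                        autofluorescence_per_px = 0,
                        cell_id = NA_integer_) {
  if (inherits(I1, "unitary_brightness")) I1 <- I1$I1
  if (!any(mask)) abort("empty cell mask")
  if (I1 <= 0) abort("`I1` must be > 0")
  area <- sum(mask)
  integ <- sum(im[mask])
  bg_term <- area * background_per_px
  af_term <- area * autofluorescence_per_px
  corrected <- integ - bg_term - af_term
  neg <- corrected < 0
  if (neg) warn("corrected integrated density is negative; copies set to 0")
  tibble(cell_id = cell_id, copies = max(corrected, 0) / I1,
         integrated_density = integ, background_term = bg_term,
         autofluorescence_term = af_term, negative_corrected = neg)
}

#' Per-pixel autofluorescence from a non-expressing reference image
#'
#' Mean counts over the measurement region of a matched emitter-free
#' (non-expressing) cell image, minus the extracellular background — the
#' autofluorescence term subtracted by [copy_number()].
#'
#' @param im Reference image (matrix).
#' @param mask Measurement region used for [copy_number()].
#' @param background_per_px Extracellular background, counts/pixel.
#' @return Autofluorescence per pixel (counts).
#' @export
autofluorescence_reference <- function(im, mask, background_per_px = 0) {
  if (!any(mask)) abort("empty cell mask")
  mean(im[mask]) - background_per_px
}

#' Copy number of a synthetic scene, with matched reference correction
#'
#' Convenience wrapper running the full integrated-density procedure on a
#' [simulate_slimfield_movie()] scene: the measurement region is the cell
#' mask dilated by `dilate_px`, the background is measured outside that
#' region in the reference scene, and the autofluorescence term comes from
#' an emitter-free reference scene over the same region.
#'
#' @param scene A `synthetic_scene` with emitters.
#' @param reference A `synthetic_scene` simulated with zero emitters under
#'   the same configuration.
#' @param I1 Unitary brightness; defaults to the scene's configured value.
#' @param dilate_px Dilation of the cell mask, pixels (~3 PSF sigma).
#' @return One-row tibble as [copy_number()].
#' @export
scene_copy_number <- function(scene, reference, I1 = NULL, dilate_px = 8L) {
  if (is.null(I1)) I1 <- scene$config$unitary_brightness
  roi <- dilate_mask(scene$cell_mask, dilate_px)
  ref_im <- movie_frame(reference$movie, 0)
  bg <- mean(ref_im[!roi])
  af <- autofluorescence_reference(ref_im, roi, bg)
  copy_number(movie_frame(scene$movie, 0), roi, I1,
              background_per_px = bg, autofluorescence_per_px = af)
}

#' Kernel density summary of a sample
#'
#' Gaussian-kernel density with a declared bandwidth rule plus exact summary
#' statistics, as used for focus diffusion-coefficient and intensity
#' distributions.
#'
#' @param values Numeric sample.
#' @param bw Bandwidth rule or value, passed to [stats::density()].
#' @return A list of class `kde_summary`: `density` (tibble `x`, `y`; `NULL`
#'   if `n < 2`), `summary` (tibble: `mean`, `sd`, `sem`, `n`), `bw`.
#' @export
kde_summary <- function(values, bw = "nrd0") {
  values <- values[is.finite(values)]
  n <- length(values)
  summ <- tibble(mean = mean(values), sd = if (n > 1) sd(values) else 0,
                 sem = if (n > 1) sd(values) / sqrt(n) else 0, n = n)
  dens <- NULL
  bw_used <- NA_real_
  if (n >= 2 && sd(values) > 0) {
    d <- density(values, bw = bw)
    dens <- tibble(x = d$x, y = d$y)
    bw_used <- d$bw
  }
  structure(list(density = dens, summary = summ, bw = bw_used),
            class = "kde_summary")
}

#' @export
print.kde_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<kde_summary> n = %d, mean = %.4g +/- %.4g (sem), sd = %.4g\n",
              s$n, s$mean, s$sem, s$sd))
  invisible(x)
}

#' Keep foci near the membrane contour
#'
#' Filters a focus/spot table to entries within `max_dist_px` of the closed
#' membrane contour, the criterion used for plasma-membrane-localised
#' proteins.
#'
#' @param foci Tibble with `x_px`, `y_px`.
#' @param contour A membrane contour (see [cell_contour()]).
#' @param max_dist_px Maximum distance to the contour, pixels.
#' @return The filtered tibble with a `membrane_dist_px` column.
#' @export
membrane_proximal <- function(foci, contour, max_dist_px = 3) {
  if (!nrow(foci)) {
    foci$membrane_dist_px <- numeric(0)
    return(foci)
  }
  d <- vapply(seq_len(nrow(foci)), function(i) {
    min(sqrt((contour$x_px - foci$x_px[i])^2 +
               (contour$y_px - foci$y_px[i])^2))
  }, numeric(1))
  foci$membrane_dist_px <- d
  foci[d <= max_dist_px, ]
}
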