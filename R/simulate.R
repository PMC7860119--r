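#' Movie container
#'
#' A `movie_stack` is a time-ordered series of 2-D images with physical
#' calibration. Frames are stored as a numeric array `[ny, nx, n_frames]` in
#' camera counts.
#'
#' @param frames Numeric array `[ny, nx, n_frames]`, or a list of equally
#'   sized matrices.
#' @param pixel_size_um,frame_interval_s Physical calibration.
#' @param channel Channel label, e.g. `"green"` or `"red"`.
#' @return An object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size_um, frame_interval_s,
                        channel = "green") {
  if (is.list(frames)) {
    shp <- vapply(frames, dim, integer(2))
    if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
      abort("all frames must have identical dimensions")
    }
    frames <- array(unlist(frames), dim = c(shp[1, 1], shp[2, 1],
                                            length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_interval_s = frame_interval_s, channel = channel),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie_stack> %d x %d px, %d frames, %.0f nm/px, %s channel\n",
              d[2], d[1], d[3], x$pixel_size_um * 1000, x$channel))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A [movie_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame of a movie as a matrix
#' @param movie A [movie_stack()].
#' @param frame Frame index, 0-based (frame 0 is the first acquired frame).
#' @return Numeric matrix.
#' @export
movie_frame <- function(movie, frame = 0L) {
  movie$frames[, , frame + 1L]
}

# Add a pixel-integrated Gaussian spot of total intensity `amp` centred at
# continuous pixel coordinates (x_px, y_px) to image `im` (in place value
# semantics). sigma in pixels.
add_psf <- function(im, x_px, y_px, sigma_px, amp) {
  ny <- nrow(im); nx <- ncol(im)
  h <- ceiling(6 * sigma_px)
  x0 <- max(floor(x_px - h), 0L); x1 <- min(ceiling(x_px + h), nx)
  y0 <- max(floor(y_px - h), 0L); y1 <- min(ceiling(y_px + h), ny)
  if (x1 <= x0 || y1 <= y0) return(im)
  # pixel i (0-based) spans [i, i+1)
  ex <- diff(pnorm(x0:x1, mean = x_px, sd = sigma_px))
  ey <- diff(pnorm(y0:y1, mean = y_px, sd = sigma_px))
  im[(y0 + 1L):y1, (x0 + 1L):x1] <-
    im[(y0 + 1L):y1, (x0 + 1L):x1] + amp * outer(ey, ex)
  im
}

# Brownian trajectory in um with bounce-back reflection at the elliptical cell
# boundary. Returns an n x 2 matrix.
brownian_path <- function(config, x0, y0, n_steps, D) {
  dt <- config$frame_interval_s
  sdstep <- sqrt(2 * D * dt)
  xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
  xs[1] <- x0; ys[1] <- y0
  if (sdstep == 0) {
    return(cbind(rep(x0, n_steps + 1L), rep(y0, n_steps + 1L)))
  }
  dxs <- rnorm(n_steps, sd = sdstep)
  dys <- rnorm(n_steps, sd = sdstep)
  for (i in seq_len(n_steps)) {
    px <- xs[i] + dxs[i]; py <- ys[i] + dys[i]
    if (!inside_cell(config, px, py)) {
      # bounce back: reflect the step at the current position
      px <- xs[i] - dxs[i]; py <- ys[i] - dys[i]
      if (!inside_cell(config, px, py)) { px <- xs[i]; py <- ys[i] }
    }
    xs[i + 1L] <- px; ys[i + 1L] <- py
  }
  cbind(xs, ys)
}

#' Simulate a Slimfield single-molecule movie with ground truth
#'
#' Renders diffusing diffraction-limited emitters, each composed of `S`
#' fluorophores that photobleach independently and irreversibly with a
#' geometric per-frame probability. Each unbleached fluorophore contributes a
#' pixel-integrated Gaussian PSF of total intensity
#' `config$unitary_brightness`. Cellular autofluorescence is added inside the
#' elliptical cell body and a uniform background everywhere; Poisson shot
#' noise and Gaussian read noise model the camera. Emitters move by 2-D
#' Brownian steps with per-axis variance `2 * D * frame_interval`, reflected
#' at the cell boundary.
#'
#' @param config A [sim_config()].
#' @param emitters A data frame with one row per emitter and columns `x_um`,
#'   `y_um` (initial position), `S` (integer initial stoichiometry, >= 1) and
#'   `D` (diffusion coefficient, um^2/s).
#' @param seed Integer seed for all randomness (trajectories, bleach times,
#'   camera noise); `NULL` uses the current RNG state.
#' @return An object of class `synthetic_scene`: a list with elements
#'   `movie` ([movie_stack()]), `truth` (tibble: `frame`, `emitter_id`,
#'   `x_um`, `y_um`, `n_unbleached`), `emitters` (input plus per-fluorophore
#'   bleach frames), `cell_mask`, `contour` and `config`.
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 5, image_shape = c(48, 48), bleach_rate = 0)
#' em <- tibble::tibble(x_um = 1.2, y_um = 1.2, S = 3, D = 0.05)
#' sc <- simulate_slimfield_movie(cfg, em, seed = 1)
#' sc$truth
simulate_slimfield_movie <- function(config, emitters, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  emitters <- as_tibble(emitters)
  need <- c("x_um", "y_um", "S", "D")
  if (nrow(emitters) && !all(need %in% names(emitters))) {
    abort("`emitters` needs columns x_um, y_um, S, D")
  }
  if (nrow(emitters)) {
    if (any(emitters$S < 1)) abort("emitter S must be >= 1")
    if (any(emitters$D < 0)) abort("emitter D must be >= 0")
    ok <- inside_cell(config, emitters$x_um, emitters$y_um)
    if (!all(ok)) {
      abort(sprintf("emitter(s) %s start outside the cell body",
                    paste(which(!ok), collapse = ", ")))
    }
  }
  with_seed(seed, {
    nf <- config$n_frames
    ny <- config$image_shape[1]; nx <- config$image_shape[2]
    px <- config$pixel_size_um
    mask <- cell_mask(config)
    base <- config$background_level + config$autofluorescence_level * mask

    n_em <- nrow(emitters)
    paths <- vector("list", n_em)
    bleach <- vector("list", n_em)
    for (i in seq_len(n_em)) {
      paths[[i]] <- brownian_path(config, emitters$x_um[i], emitters$y_um[i],
                                  nf - 1L, emitters$D[i])
      s <- as.integer(emitters$S[i])
      bleach[[i]] <- if (config$bleach_rate > 0) {
        rgeom(s, config$bleach_rate) + 1L  # emits on frames 0..(b-1)
      } else rep(Inf, s)
    }

    frames <- array(0, dim = c(ny, nx, nf))
    truth <- vector("list", n_em)
    for (t in seq_len(nf)) {
      im <- matrix(0, ny, nx)
      for (i in seq_len(n_em)) {
        n_live <- sum(bleach[[i]] > (t - 1L))
        if (n_live > 0) {
          im <- add_psf(im, paths[[i]][t, 1] / px, paths[[i]][t, 2] / px,
                        config$psf_sigma_um / px,
                        n_live * config$unitary_brightness)
        }
      }
      expected <- im + base
      if (config$shot_noise) {
        obs <- matrix(rpois(length(expected), expected), ny, nx)
      } else {
        obs <- expected
      }
      if (config$read_noise_sd > 0) {
        obs <- obs + matrix(rnorm(length(obs), sd = config$read_noise_sd),
                            ny, nx)
      }
      frames[, , t] <- obs
    }
    for (i in seq_len(n_em)) {
      truth[[i]] <- tibble(
        frame = 0:(nf - 1L), emitter_id = i,
        x_um = paths[[i]][, 1], y_um = paths[[i]][, 2],
        n_unbleached = vapply(0:(nf - 1L),
                              function(t) sum(bleach[[i]] > t), numeric(1))
      )
    }
    emitters$bleach_frames <- bleach
    structure(list(
      movie = movie_stack(frames, px, config$frame_interval_s),
      truth = if (n_em) bind_rows(truth) else
        tibble(frame = integer(), emitter_id = integer(), x_um = numeric(),
               y_um = numeric(), n_unbleached = numeric()),
      emitters = emitters, cell_mask = mask,
      contour = cell_contour(config), config = config
    ), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d emitters\n", nrow(x$emitters)))
  print(x$movie)
  invisible(x)
}

#' Simulate free Brownian tracks with localisation noise
#'
#' Generates unconfined 2-D Brownian trajectories sampled at the frame
#' interval, optionally corrupted with independent Gaussian localisation
#' error of standard deviation `loc_noise_um` per axis — the track-level
#' analogue of [simulate_slimfield_movie()] when only motion statistics are
#' needed.
#'
#' @param n_tracks Number of tracks.
#' @param D Diffusion coefficient, um^2/s.
#' @param n_frames Frames per track.
#' @param frame_interval_s Frame interval, s.
#' @param loc_noise_um Localisation error SD per axis, um (0.04 um matches
#'   the instrument's 40 nm super-resolution precision).
#' @param seed Integer seed or `NULL`.
#' @return Tibble: `track_id`, `frame`, `x_um`, `y_um` (observed),
#'   `x_true_um`, `y_true_um`.
#' @export
simulate_tracks <- function(n_tracks, D, n_frames, frame_interval_s = 0.005,
                            loc_noise_um = 0, seed = NULL) {
  with_seed(seed, {
    sdstep <- sqrt(2 * D * frame_interval_s)
    out <- purrr::map(seq_len(n_tracks), function(id) {
      x <- cumsum(c(0, rnorm(n_frames - 1L, sd = sdstep)))
      y <- cumsum(c(0, rnorm(n_frames - 1L, sd = sdstep)))
      tibble(track_id = id, frame = 0:(n_frames - 1L),
             x_true_um = x, y_true_um = y,
             x_um = x + rnorm(n_frames, sd = loc_noise_um),
             y_um = y + rnorm(n_frames, sd = loc_noise_um))
    })
    bind_rows(out)
  })
}

#' Simulate a stepwise-photobleaching intensity trace
#'
#' The ideal trace starts at `S * unitary_brightness` and drops by exactly
#' one `unitary_brightness` each time a fluorophore bleaches (independent
#' geometric bleach times), reaching zero when all have bleached; Gaussian
#' noise is added on top. The per-fluorophore bleach frames are recorded as
#' ground truth.
#'
#' @param S Integer number of fluorophores (>= 1).
#' @param unitary_brightness Counts per fluorophore per frame.
#' @param bleach_rate Per-frame bleach probability in `[0, 1]`.
#' @param noise_sd Gaussian noise SD, counts.
#' @param n_frames Trace length.
#' @param frame_interval_s Frame interval, s.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `photobleach_sim`: `trace` (tibble: `frame`,
#'   `time_s`, `intensity`, `ideal`, `n_unbleached`), `step_frames` (sorted
#'   bleach frames within the trace) and the generating parameters.
#' @export
#' @examples
#' tr <- simulate_photobleach_trace(3, 150, noise_sd = 0, seed = 2)
#' tr$step_frames
simulate_photobleach_trace <- function(S, unitary_brightness,
                                       bleach_rate = 0.01, noise_sd = 30,
                                       n_frames = 200L,
                                       frame_interval_s = 0.005,
                                       seed = NULL) {
  if (S < 1) abort("`S` must be >= 1")
  check_number(bleach_rate, "bleach_rate", 0, 1)
  with_seed(seed, {
    b <- if (bleach_rate > 0) rgeom(S, bleach_rate) + 1L else rep(Inf, S)
    frames <- 0:(n_frames - 1L)
    n_live <- vapply(frames, function(t) sum(b > t), numeric(1))
    ideal <- n_live * unitary_brightness
    intensity <- ideal + if (noise_sd > 0) rnorm(n_frames, sd = noise_sd)
                         else 0
    structure(list(
      trace = tibble(frame = frames, time_s = frames * frame_interval_s,
                     intensity = intensity, ideal = ideal,
                     n_unbleached = n_live),
      step_frames = sort(b[b <= n_frames]),
      S = as.integer(S), unitary_brightness = unitary_brightness,
      bleach_rate = bleach_rate, noise_sd = noise_sd
    ), class = "photobleach_sim")
  })
}

#' Simulate a two-channel confocal eisosome scene
#'
#' Places `n_eisosomes` red puncta on the membrane contour of an elliptical
#' (circular by default) cell and `n_cargo` green cargo foci that are either
#' colocalised with a red punctum or kept at least `exclusion_um` away from
#' every punctum along the membrane. Both channels are rendered as
#' pixel-integrated Gaussian spots over background with optional camera
#' noise; the class of every focus is recorded as ground truth.
#'
#' @param n_eisosomes Number of red membrane puncta (>= 0).
#' @param n_cargo Number of green cargo foci.
#' @param colocalised_fraction Fraction of cargo foci placed at a red
#'   punctum, in `[0, 1]`.
#' @param membrane_radius_um Radius of the circular membrane contour, um.
#' @param puncta_amplitude Mean integrated intensity of a red punctum,
#'   counts.
#' @param puncta_cv Coefficient of variation of punctum intensities
#'   (log-normal); 0 gives identical puncta.
#' @param cargo_amplitude Mean integrated intensity of a green focus, counts.
#' @param min_separation_um Minimum arc separation between red puncta, um.
#' @param exclusion_um Minimum arc distance of a "distinct" cargo focus from
#'   every red punctum, um.
#' @param config A [sim_config()]; supplies image geometry, PSF and noise.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `confocal_scene`: `red`, `green` (noisy count
#'   matrices), `red_clean`, `green_clean` (noise-free expectations),
#'   `truth` (tibble: `id`, `channel`, `x_um`, `y_um`, `x_px`, `y_px`,
#'   `amplitude`, `class`), `contour`, `config`.
#' @export
simulate_confocal_scene <- function(n_eisosomes, n_cargo = n_eisosomes,
                                    colocalised_fraction = 0.5,
                                    membrane_radius_um = 2,
                                    puncta_amplitude = 5000,
                                    puncta_cv = 0.2,
                                    cargo_amplitude = 3000,
                                    min_separation_um = 0.3,
                                    exclusion_um = 0.15,
                                    config = sim_config(),
                                    seed = NULL) {
  check_number(colocalised_fraction, "colocalised_fraction", 0, 1)
  circ <- 2 * pi * membrane_radius_um
  if (n_eisosomes * min_separation_um > circ) {
    abort(sprintf(
      "%d puncta with %.2f um separation do not fit on a %.2f um contour",
      n_eisosomes, min_separation_um, circ))
  }
  with_seed(seed, {
    ny <- config$image_shape[1]; nx <- config$image_shape[2]
    px <- config$pixel_size_um
    cx <- config$cell_centre_um[1]; cy <- config$cell_centre_um[2]

    # red puncta: equally spaced angles plus a bounded random jitter keeps the
    # minimum separation guaranteed by construction
    th_red <- numeric(0)
    if (n_eisosomes > 0) {
      base <- seq(0, 2 * pi, length.out = n_eisosomes + 1L)[-(n_eisosomes + 1L)]
      slack <- (circ / max(n_eisosomes, 1) - min_separation_um) / 2 /
        membrane_radius_um
      th_red <- base + runif(n_eisosomes, -slack, slack) + runif(1, 0, 2 * pi)
    }
    amp_red <- if (puncta_cv > 0 && n_eisosomes > 0) {
      sl <- sqrt(log(1 + puncta_cv^2))
      puncta_amplitude * exp(rnorm(n_eisosomes, -sl^2 / 2, sl))
    } else rep(puncta_amplitude, n_eisosomes)

    # green cargo
    n_col <- round(n_cargo * colocalised_fraction)
    cls <- rep("distinct", n_cargo)
    if (n_cargo > 0 && n_col > 0) cls[seq_len(n_col)] <- "colocalised"
    th_green <- numeric(n_cargo)
    excl_th <- exclusion_um / membrane_radius_um
    if (n_cargo > 0) {
      if (n_col > 0) {
        if (n_eisosomes == 0) abort("cannot colocalise cargo without puncta")
        th_green[seq_len(n_col)] <- th_red[
          sample.int(n_eisosomes, n_col, replace = n_col > n_eisosomes)]
      }
      for (i in seq_len(n_cargo)) {
        if (cls[i] == "colocalised") next
        th <- NA_real_
        for (try in 1:5000) {
          cand <- runif(1, 0, 2 * pi)
          if (n_eisosomes == 0) { th <- cand; break }
          d <- abs(((cand - th_red + pi) %% (2 * pi)) - pi)
          if (min(d) >= excl_th) { th <- cand; break }
        }
        if (is.na(th)) {
          abort(paste("could not place a distinct cargo focus;",
                      "reduce n_eisosomes or exclusion_um"))
        }
        th_green[i] <- th
      }
    }

    place <- function(th) {
      cbind(cx + membrane_radius_um * cos(th),
            cy + membrane_radius_um * sin(th))
    }
    render <- function(pos, amp) {
      im <- matrix(config$background_level, ny, nx)
      for (i in seq_len(nrow(pos))) {
        im <- add_psf(im, pos[i, 1] / px, pos[i, 2] / px,
                      config$psf_sigma_um / px, amp[i])
      }
      im
    }
    noisy <- function(im) {
      out <- if (config$shot_noise) {
        matrix(rpois(length(im), im), ny, nx)
      } else im
      if (config$read_noise_sd > 0) {
        out <- out + matrix(rnorm(length(im), sd = config$read_noise_sd),
                            ny, nx)
      }
      out
    }
    pos_red <- place(th_red)
    pos_green <- place(th_green)
    amp_green <- rep(cargo_amplitude, n_cargo)
    red_clean <- render(pos_red, amp_red)
    green_clean <- render(pos_green, amp_green)

    th_cont <- seq(0, 2 * pi, length.out = 721L)
    contour <- new_contour(cx + membrane_radius_um * cos(th_cont),
                           cy + membrane_radius_um * sin(th_cont), px)
    truth <- bind_rows(
      if (n_eisosomes > 0) tibble(
        id = seq_len(n_eisosomes), channel = "red",
        x_um = pos_red[, 1], y_um = pos_red[, 2],
        amplitude = amp_red, class = "eisosome"),
      if (n_cargo > 0) tibble(
        id = seq_len(n_cargo), channel = "green",
        x_um = pos_green[, 1], y_um = pos_green[, 2],
        amplitude = amp_green, class = cls)
    )
    if (is.null(truth) || !ncol(truth)) {
      truth <- tibble(id = integer(), channel = character(),
                      x_um = numeric(), y_um = numeric(),
                      amplitude = numeric(), class = character())
    }
    truth$x_px <- truth$x_um / px
    truth$y_px <- truth$y_um / px
    structure(list(red = noisy(red_clean), green = noisy(green_clean),
                   red_clean = red_clean, green_clean = green_clean,
                   truth = truth, contour = contour, config = config),
              class = "confocal_scene")
  })
}
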