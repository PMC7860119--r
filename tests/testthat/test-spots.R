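# Sub-pixel spot detection and optimal-assignment track linking.

test_that("featureless frames yield no spots and bad pixels are an error", {
  expect_equal(nrow(detect_spots(matrix(7, 32, 32), 0.05)), 0L)
  im <- matrix(1, 16, 16); im[4, 4] <- NA
  expect_error(detect_spots(im, 0.05), "non-finite")
})

test_that("localisation error stays within the 40 nm precision at
          single-molecule signal levels", {
  errs <- vapply(1:100, function(s) {
    cfg <- sim_config(n_frames = 1, image_shape = c(32, 32),
                      bleach_rate = 0, unitary_brightness = 2000,
                      read_noise_sd = 3, autofluorescence_level = 10,
                      background_level = 5)
    pos <- 0.8 + (s %% 10) * 0.005  # sub-pixel ladder of true centres
    sc <- simulate_slimfield_movie(
      cfg, tibble::tibble(x_um = pos, y_um = 0.8, S = 1, D = 0), seed = s)
    sp <- detect_spots(movie_frame(sc$movie, 0), 0.05)
    if (nrow(sp) != 1L) return(NA_real_)
    sqrt((sp$x_um - pos)^2 + (sp$y_um - 0.8)^2)
  }, numeric(1))
  expect_gt(mean(!is.na(errs)), 0.95)
  expect_lt(sqrt(mean(errs^2, na.rm = TRUE)) * 1000, 40)
})

test_that("two spots 4 sigma apart are resolved with accurate intensities", {
  cfg <- sim_config(n_frames = 1, image_shape = c(48, 48), bleach_rate = 0,
                    unitary_brightness = 4000)
  sep <- 4 * cfg$psf_sigma_um
  sc <- simulate_slimfield_movie(
    cfg, tibble::tibble(x_um = c(1.0, 1.0 + sep), y_um = 1.0, S = 1, D = 0),
    seed = 3)
  sp <- detect_spots(movie_frame(sc$movie, 0), 0.05)
  expect_equal(nrow(sp), 2L)
  expect_true(all(abs(sp$intensity - 4000) / 4000 < 0.10))
})

test_that("detection is equivariant to integer pixel shifts", {
  cfg <- sim_config(n_frames = 1, image_shape = c(48, 48), bleach_rate = 0,
                    read_noise_sd = 0, shot_noise = FALSE,
                    autofluorescence_level = 0, background_level = 10,
                    unitary_brightness = 4000)
  sc <- simulate_slimfield_movie(
    cfg, tibble::tibble(x_um = 1.13, y_um = 1.27, S = 1, D = 0), seed = 1)
  im <- movie_frame(sc$movie, 0)
  sh <- matrix(10, 48, 48)  # shift by (+3, +5) px into a fresh background
  sh[(1 + 5):48, (1 + 3):48] <- im[1:(48 - 5), 1:(48 - 3)]
  a <- detect_spots(im, 0.05)
  b <- detect_spots(sh, 0.05)
  expect_equal(nrow(a), 1L)
  expect_equal(b$x_px, a$x_px + 3, tolerance = 1e-6)
  expect_equal(b$y_px, a$y_px + 5, tolerance = 1e-6)
})

test_that("summed intensity is linear in spot amplitude", {
  cfg <- function(ub) sim_config(n_frames = 1, image_shape = c(48, 48),
                                 bleach_rate = 0, read_noise_sd = 0,
                                 shot_noise = FALSE,
                                 autofluorescence_level = 0,
                                 background_level = 0,
                                 unitary_brightness = ub)
  em <- tibble::tibble(x_um = 1.21, y_um = 1.17, S = 1, D = 0)
  i1 <- detect_spots(movie_frame(
    simulate_slimfield_movie(cfg(2000), em, seed = 1)$movie, 0), 0.05)
  i2 <- detect_spots(movie_frame(
    simulate_slimfield_movie(cfg(4000), em, seed = 1)$movie, 0), 0.05)
  expect_equal(i2$intensity / i1$intensity, 2, tolerance = 0.01)
})

test_that("localisation error decreases monotonically with signal level", {
  rms_at <- function(ub) {
    errs <- vapply(1:60, function(s) {
      cfg <- sim_config(n_frames = 1, image_shape = c(32, 32),
                        bleach_rate = 0, unitary_brightness = ub,
                        read_noise_sd = 3)
      sc <- simulate_slimfield_movie(
        cfg, tibble::tibble(x_um = 0.81, y_um = 0.79, S = 1, D = 0),
        seed = s)
      sp <- detect_spots(movie_frame(sc$movie, 0), 0.05)
      if (nrow(sp) != 1L) return(NA_real_)
      sqrt((sp$x_um - 0.81)^2 + (sp$y_um - 0.79)^2)
    }, numeric(1))
    sqrt(mean(errs^2, na.rm = TRUE))
  }
  ladder <- c(rms_at(800), rms_at(2500), rms_at(8000))
  expect_true(all(diff(ladder) < 0))
})

test_that("the Hungarian solver matches brute-force enumeration", {
  set.seed(42)
  for (r in 1:50) {
    n <- sample(1:5, 1); m <- n + sample(0:2, 1)
    a <- matrix(runif(n * m), n, m)
    asg <- slimquant:::hungarian(a)
    expect_equal(sum(a[cbind(seq_len(n), asg)]), brute_force_assignment(a),
                 tolerance = 1e-12)
  }
})

test_that("an immobile spot links into a single full-length track", {
  sp <- tibble::tibble(frame = 0:9, x_px = 10.2, y_px = 11.7)
  lk <- link_tracks(sp, link_radius_px = 5)
  expect_equal(unique(lk$track_id), 1L)
  expect_equal(nrow(lk), 10L)
  expect_equal(nrow(link_tracks(sp[0, ])), 0L)
})

test_that("identities survive when swapping would exceed the link radius", {
  sp <- dplyr::bind_rows(
    tibble::tibble(frame = 0:19, x_px = 10 + 0.1 * (0:19), y_px = 10,
                   truth = 1L),
    tibble::tibble(frame = 0:19, x_px = 40 - 0.1 * (0:19), y_px = 40,
                   truth = 2L))
  lk <- link_tracks(sp, link_radius_px = 5)
  tab <- table(lk$track_id, lk$truth)
  expect_equal(length(unique(lk$track_id)), 2L)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1L))
})

test_that("most true frame-to-frame links are recovered for diffusing
          emitters", {
  tr <- simulate_tracks(20, D = 0.1, n_frames = 50, loc_noise_um = 0.04,
                        seed = 5)
  offs <- with_seed_local(9, tibble::tibble(
    track_id = 1:20, ox = runif(20, 0, 100), oy = runif(20, 0, 100)))
  sp <- dplyr::left_join(tr, offs, by = "track_id")
  sp$x_px <- sp$x_um / 0.05 + sp$ox
  sp$y_px <- sp$y_um / 0.05 + sp$oy
  sp <- sp[with_seed_local(1, sample(nrow(sp))),
           c("frame", "x_px", "y_px", "track_id")]
  names(sp)[4] <- "truth"
  link_key <- function(df, id_col) {
    df <- df[order(df[[id_col]], df$frame), ]
    unlist(lapply(split(df, df[[id_col]]), function(d) {
      if (nrow(d) < 2) return(character(0))
      paste(head(d$frame, -1), head(round(d$x_px, 6), -1),
            d$frame[-1], round(d$x_px[-1], 6), sep = "|")
    }), use.names = FALSE)
  }
  lk <- link_tracks(sp, link_radius_px = 5, max_gap = 1)
  true_links <- link_key(sp, "truth")
  got_links <- link_key(lk, "track_id")
  jacc <- length(intersect(true_links, got_links)) /
    length(union(true_links, got_links))
  expect_gte(jacc, 0.95)
  # determinism
  lk2 <- link_tracks(sp, link_radius_px = 5, max_gap = 1)
  expect_identical(lk, lk2)
})
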