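# Stoichiometry, MSD/diffusion and copy-number quantification.

test_that("initial brightness recovers constants and exponential decays", {
  expect_equal(initial_brightness(rep(7, 10))$I0, 7, tolerance = 1e-6)
  ib <- initial_brightness(600 * exp(-(0:99) / 50))
  expect_equal(ib$I0, 600, tolerance = 0.01)
  expect_equal(ib$method, "exponential")
  z <- initial_brightness(rep(0, 10))
  expect_equal(z$I0, 0)
  expect_true(z$warning)
  expect_error(initial_brightness(c(1, 2)), "3 frames")
})

test_that("stoichiometry is the ratio I0 / I1 and rejects bad I1", {
  expect_equal(stoichiometry(rep(150, 10), 150)$S, 1, tolerance = 1e-6)
  expect_equal(stoichiometry(rep(0, 10), 150)$S, 0)
  expect_error(stoichiometry(rep(1, 10), 0), "I1")
  # global count rescaling cancels
  x <- simulate_photobleach_trace(5, 150, noise_sd = 20, seed = 1)
  s1 <- stoichiometry(x$trace$intensity, 150)$S
  s2 <- stoichiometry(x$trace$intensity * 7, 150 * 7)$S
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("per-focus stoichiometry recovery over S in 2..20 is within 15%", {
  trs <- lapply(1:50, function(i) {
    simulate_photobleach_trace(
      with_seed_local(i, sample(5:15, 1)), 150, bleach_rate = 0.008,
      noise_sd = 30, n_frames = 300, seed = i)$trace$intensity
  })
  I1 <- estimate_unitary_brightness(trs, n_boot = 0)$I1
  rel <- vapply(2:20, function(S) {
    mean(vapply(1:8, function(r) {
      tr <- simulate_photobleach_trace(S, 150, bleach_rate = 0.008,
                                       noise_sd = 30, n_frames = 200,
                                       seed = S * 100 + r)
      abs(stoichiometry(tr$trace$intensity, I1)$S - S) / S
    }, numeric(1)))
  }, numeric(1))
  expect_lte(mean(rel), 0.15)
})

test_that("MSD is exact for immobile and ballistic tracks", {
  tr0 <- tibble::tibble(frame = 0:9, x_um = 2, y_um = 3)
  expect_true(all(compute_msd(tr0)$msd == 0))
  v <- 0.7  # um/s along x
  trv <- tibble::tibble(frame = 0:9, x_um = v * (0:9) * 0.005, y_um = 0)
  msd <- compute_msd(trv, 0.005)
  expect_equal(msd$msd, (v * msd$tau_s)^2, tolerance = 1e-12)
  expect_equal(msd$n_pairs, 9:1)
})

test_that("pooled Brownian MSD matches 4 D tau + 4 sigma^2 at short lags", {
  D <- 0.1; s <- 0.04
  tr <- simulate_tracks(500, D = D, n_frames = 50, loc_noise_um = s,
                        seed = 21)
  curves <- lapply(split(tr, tr$track_id), compute_msd,
                   frame_interval_s = 0.005, max_lag = 5)
  pooled <- vapply(1:5, function(k) {
    mean(vapply(curves, function(cv) cv$msd[k], numeric(1)))
  }, numeric(1))
  expected <- 4 * D * (1:5) * 0.005 + 4 * s^2
  expect_equal(pooled, expected, tolerance = 0.05)
})

test_that("the constrained diffusion fit passes through 4 sigma^2 and is
          exact on constructed lines", {
  s <- 0.04
  flat <- tibble::tibble(tau_s = (1:5) * 0.005, msd = rep(4 * s^2, 5))
  f0 <- fit_diffusion(flat, sigma_um = s)
  expect_equal(f0$D, 0)
  expect_false(f0$clipped)

  line <- tibble::tibble(tau_s = (1:5) * 0.005,
                         msd = 0.4 * (1:5) * 0.005 + 4 * s^2)
  f1 <- fit_diffusion(line, sigma_um = s)
  expect_equal(f1$D, 0.1, tolerance = 1e-12)
  expect_equal(f1$residual_rms, 0, tolerance = 1e-12)
  expect_equal(generics::glance(f1)$intercept, 4 * s^2)

  down <- tibble::tibble(tau_s = (1:5) * 0.005, msd = 4 * s^2 - 0.001 * 1:5)
  fd <- fit_diffusion(down, sigma_um = s)
  expect_equal(fd$D, 0)
  expect_true(fd$clipped)

  expect_error(fit_diffusion(line[1:3, ]), "lags")
})

test_that("median per-track D is recovered within 15% from simulated
          tracks", {
  tr <- simulate_tracks(500, D = 0.05, n_frames = 100, loc_noise_um = 0.04,
                        seed = 31)
  td <- track_diffusion(tr, 0.005, sigma_um = 0.04)
  expect_equal(nrow(td), 500L)
  expect_lt(abs(median(td$D) - 0.05) / 0.05, 0.15)
})

test_that("copy number handles exact-background cells, empty masks and is
          additive over disjoint regions", {
  im <- matrix(15, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  cn <- copy_number(im, mask, I1 = 150, background_per_px = 5,
                    autofluorescence_per_px = 10)
  expect_equal(cn$copies, 0)
  expect_error(copy_number(im, mask & FALSE, 150), "empty")
  expect_warning(
    copy_number(im, mask, 150, background_per_px = 20), "negative")

  im2 <- im + matrix(runif(1600, 0, 50), 40, 40)
  left <- mask; left[, 21:40] <- FALSE
  right <- mask; right[, 1:20] <- FALSE
  total <- copy_number(im2, mask, 150, 5, 10)$copies
  parts <- copy_number(im2, left, 150, 5, 10)$copies +
    copy_number(im2, right, 150, 5, 10)$copies
  expect_equal(parts, total, tolerance = 1e-9)
})

test_that("integrated density recovers a known emitter count within 10%", {
  cfg <- sim_config(n_frames = 1, image_shape = c(160, 160),
                    unitary_brightness = 150, psf_sigma_um = 0.12,
                    autofluorescence_level = 10, background_level = 5)
  ref <- simulate_slimfield_movie(cfg, place_emitters(cfg, 0, 1)[0, ],
                                  seed = 999)
  est <- vapply(1:5, function(s) {
    sc <- simulate_slimfield_movie(cfg, place_emitters(cfg, 500, s),
                                   seed = s)
    scene_copy_number(sc, ref)$copies
  }, numeric(1))
  expect_lt(abs(mean(est) - 500) / 500, 0.10)
})

test_that("copy number is invariant to a global rescaling of counts", {
  im <- matrix(100, 30, 30)
  mask <- matrix(TRUE, 30, 30)
  a <- copy_number(im, mask, 150, 5, 10)$copies
  b <- copy_number(im * 3, mask, 450, 15, 30)$copies
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("kernel density summaries are normalised with exact statistics", {
  k0 <- kde_summary(rep(3, 5))
  expect_equal(k0$summary$mean, 3)
  expect_equal(k0$summary$sd, 0)
  expect_null(k0$density)

  x <- with_seed_local(1, rnorm(10000))
  k <- kde_summary(x)
  grid_dx <- diff(k$density$x[1:2])
  expect_equal(sum(k$density$y) * grid_dx, 1, tolerance = 1e-3)
  expect_lt(abs(k$density$x[which.max(k$density$y)]), 0.1)
})

test_that("membrane-proximal filtering keeps only foci near the contour", {
  cfg <- sim_config(image_shape = c(128, 128))
  cont <- cell_contour(cfg)
  foci <- tibble::tibble(
    x_px = c(cont$x_px[1], cfg$cell_centre_um[1] / 0.05),
    y_px = c(cont$y_px[1], cfg$cell_centre_um[2] / 0.05))
  kept <- membrane_proximal(foci, cont, max_dist_px = 3)
  expect_equal(nrow(kept), 1L)
  expect_lt(kept$membrane_dist_px, 1e-6)
})
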