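# Projections, bleach correction, segmentation, colocalisation and
# contiguous membrane signal.

test_that("top projection combines slices as documented", {
  sl <- matrix(runif(64), 8, 8)
  same <- array(rep(sl, 5), c(8, 8, 5))
  expect_equal(top_projection(same), sl, ignore_attr = TRUE)

  ladder <- array(0, c(8, 8, 5))
  for (k in 1:5) ladder[, , k] <- k
  expect_true(all(top_projection(ladder) == 3))
  expect_true(all(top_projection(ladder, mode = "max") == 5))

  rnd <- array(runif(8 * 8 * 5), c(8, 8, 5))
  expect_true(all(top_projection(rnd) <= top_projection(rnd, mode = "max")))
  expect_error(top_projection(rnd[, , 1:4]), "slices")
  expect_equal(attr(top_projection(rnd), "projection_mode"), "average")
})

test_that("histogram-matching bleach correction restores frame statistics,
          preserves ranks and is idempotent", {
  base <- matrix(runif(1024, 10, 100), 32, 32)
  un <- array(rep(base, 4), c(32, 32, 4))
  expect_equal(bleach_correct(un), un)

  dec <- array(0, c(32, 32, 6))
  for (t in 1:6) dec[, , t] <- base * 0.9^(t - 1)
  cor <- bleach_correct(dec)
  expect_equal(apply(cor, 3, mean), rep(mean(base), 6), tolerance = 0.01)
  for (t in 2:6) {
    expect_identical(order(cor[, , t]), order(dec[, , t]))
  }
  expect_equal(bleach_correct(cor), cor)
  expect_error(bleach_correct(array(1, c(4, 4, 1))), "2 frames")
})

test_that("fixed-threshold segmentation follows the inclusive 16-bit
          convention", {
  expect_equal(nrow(segment_eisosomes(matrix(10, 32, 32), 17)), 0L)
  one <- matrix(0, 32, 32); one[16, 16] <- 17
  rois <- segment_eisosomes(one, 17, min_size_px = 1L)
  expect_equal(nrow(rois), 1L)
  expect_equal(rois$area_px, 1L)
  expect_error(segment_eisosomes(one, 70000), "65535")
})

test_that("thirty well-separated puncta segment into thirty ROIs with
          accurate intensities", {
  sc <- well_separated_scene(11)
  rois <- segment_eisosomes(sc$red, 17, pixel_size_um = 0.05)
  expect_equal(nrow(rois), 30L)
  clean <- segment_eisosomes(sc$red_clean, 17, pixel_size_um = 0.05)
  expect_equal(nrow(clean), 30L)
  cnt <- count_eisosomes(rois)
  expect_equal(cnt$n_rois, 30L)

  # per-ROI mean intensity against the noise-free expectation over the same
  # footprint, on a bright sparse scene where photon noise permits a 5% bar
  cfg <- sim_config(image_shape = c(256, 256), background_level = 5,
                    read_noise_sd = 2, psf_sigma_um = 0.12)
  br <- simulate_confocal_scene(
    15, n_cargo = 0, colocalised_fraction = 0, membrane_radius_um = 4,
    puncta_amplitude = 20000, puncta_cv = 0.15, min_separation_um = 1.2,
    config = cfg, seed = 21)
  rb <- segment_eisosomes(br$red, 17, pixel_size_um = 0.05)
  expect_equal(nrow(rb), 15L)
  lab <- attr(rb, "label_matrix")
  truth_mean <- vapply(rb$label, function(id) {
    mean(br$red_clean[lab == id])
  }, numeric(1))
  expect_lt(max(abs(rb$mean_intensity - truth_mean) / truth_mean), 0.05)
})

test_that("auto-Li segmentation counts are invariant to affine intensity
          rescaling", {
  sc <- well_separated_scene(12)
  a <- segment_eisosomes(sc$red, mode = "li", pixel_size_um = 0.05)
  b <- segment_eisosomes(sc$red * 2.5 + 40, mode = "li",
                         pixel_size_um = 0.05)
  expect_equal(nrow(a), nrow(b))
})

test_that("merged puncta count as one ROI and are flagged by area", {
  im <- matrix(0, 64, 64)
  paint <- function(im, x, y) {
    for (dx in -2:2) for (dy in -2:2) {
      if (dx^2 + dy^2 <= 4) im[y + dy, x + dx] <- 100
    }
    im
  }
  im <- paint(im, 10, 10); im <- paint(im, 30, 30)
  im <- paint(im, 50, 50); im <- paint(im, 53, 50)  # merged pair
  rois <- segment_eisosomes(im, 17, pixel_size_um = 0.05)
  expect_equal(nrow(rois), 3L)
  cnt <- count_eisosomes(rois)
  expect_equal(cnt$n_area_outliers, 1L)
})

test_that("foci classification obeys its geometric definition and is
          symmetric in the channels", {
  pts <- tibble::tibble(x_px = c(10, 20, 30), y_px = c(10, 20, 30))
  same <- classify_foci(pts, pts, radius_px = 2)
  expect_true(all(same$class == "colocalised"))
  expect_true(all(same$partner_distance_px == 0))

  far <- tibble::tibble(x_px = c(100, 110), y_px = c(100, 110))
  split2 <- classify_foci(pts, far, radius_px = 2)
  expect_true(all(split2$class == "distinct"))

  g <- tibble::tibble(x_px = c(10, 20.5), y_px = c(10, 20))
  r <- tibble::tibble(x_px = c(10.5, 50), y_px = c(10, 50))
  ab <- classify_foci(g, r, radius_px = 2)
  ba <- classify_foci(r, g, radius_px = 2)
  pair_ab <- ab[ab$channel == "green" & ab$mutual_pair,
                c("id", "partner_id")]
  pair_ba <- ba[ba$channel == "red" & ba$mutual_pair,
                c("partner_id", "id")]
  expect_equal(unname(as.matrix(pair_ab)), unname(as.matrix(pair_ba)))
})

test_that("a simulated half-colocalised scene is recovered within 0.05", {
  sc <- simulate_confocal_scene(
    60, n_cargo = 500, colocalised_fraction = 0.5, membrane_radius_um = 4,
    min_separation_um = 0.35, exclusion_um = 0.15,
    config = sim_config(image_shape = c(256, 256)), seed = 13)
  g <- sc$truth[sc$truth$channel == "green", c("id", "x_px", "y_px")]
  r <- sc$truth[sc$truth$channel == "red", c("id", "x_px", "y_px")]
  cl <- classify_foci(g, r, radius_px = 2)
  frac <- mean(cl$class[cl$channel == "green"] == "colocalised")
  expect_lt(abs(frac - 0.5), 0.05)
})

test_that("per-class intensity statistics match closed-form expectations", {
  eq <- tibble::tibble(class = rep(c("colocalised", "distinct"), each = 20),
                       intensity = rep(rep(c(5, 7), 10), 2))
  st <- foci_intensity_stats(eq)
  expect_equal(st$test$estimate, 0)
  expect_gt(st$test$p.value, 0.95)

  sh <- tibble::tibble(
    class = rep(c("colocalised", "distinct"), each = 50),
    intensity = c(with_seed_local(1, rnorm(50, 0, 1)),
                  with_seed_local(2, rnorm(50, 5, 1))))
  st2 <- foci_intensity_stats(sh)
  expect_lt(st2$test$p.value, 1e-6)
  sw <- sh; sw$class <- rev(sh$class)
  st3 <- foci_intensity_stats(sw)
  expect_equal(st3$test$estimate, -st2$test$estimate, tolerance = 1e-9)
})

test_that("contiguous membrane signal measures arc lengths correctly", {
  px <- 0.05
  th <- seq(0, 2 * pi, length.out = 721)
  cont <- slimquant:::new_contour(3.2 + 2 * cos(th), 3.2 + 2 * sin(th), px)

  dark <- matrix(0, 128, 128)
  expect_equal(nrow(contiguous_membrane_signal(dark, cont, 50)), 0L)

  bright <- matrix(100, 128, 128)
  full <- contiguous_membrane_signal(bright, cont, 50)
  expect_equal(nrow(full), 1L)
  expect_equal(full$length_um, 2 * pi * 2, tolerance = 1e-3)

  arc <- matrix(0, 128, 128)
  for (t in seq(0, pi / 2, length.out = 800)) {
    for (dr in seq(-0.12, 0.12, by = 0.02)) {
      x <- (3.2 + (2 + dr) * cos(t)) / px
      y <- (3.2 + (2 + dr) * sin(t)) / px
      arc[floor(y) + 1, floor(x) + 1] <- 100
    }
  }
  seg <- contiguous_membrane_signal(arc, cont, 50)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$length_um, pi, tolerance = 0.03)

  open_cont <- cont[1:700, ]
  attr(open_cont, "pixel_size_um") <- px
  expect_error(contiguous_membrane_signal(dark, open_cont, 50), "closed")
  expect_error(contiguous_membrane_signal(dark, cont, 50, step_px = 1),
               "step_px")
})

test_that("total contiguous signal never exceeds the contour perimeter", {
  px <- 0.05
  th <- seq(0, 2 * pi, length.out = 721)
  cont <- slimquant:::new_contour(3.2 + 2 * cos(th), 3.2 + 2 * sin(th), px)
  for (s in 1:5) {
    im <- with_seed_local(s, matrix(runif(128 * 128, 0, 100), 128, 128))
    seg <- contiguous_membrane_signal(im, cont, 50)
    expect_lte(sum(seg$length_um), attr(seg, "perimeter_um") + 1e-9)
  }
})

test_that("a mask-derived contour matches the analytic cell boundary", {
  cfg <- sim_config(image_shape = c(128, 128))
  m <- cell_mask(cfg)
  cont <- mask_contour(m, cfg$pixel_size_um)
  expect_equal(contour_perimeter(cont), contour_perimeter(cell_contour(cfg)),
               tolerance = 0.05)
})
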