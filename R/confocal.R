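# Confocal/Airyscan quantification: projections, bleach correction, eisosome
# segmentation, foci colocalisation and contiguous membrane signal.

#' Combine the top z-slices of a confocal stack into one image
#'
#' The top-of-cell projection combines the configured number of slices
#' (default five at 0.18 um spacing) by per-pixel average intensity; a
#' per-pixel maximum mode is available. The mode used is recorded in the
#' result's `projection_mode` attribute.
#'
#' @param stack Numeric array `[ny, nx, n_slices]` or list of matrices.
#' @param n_expected Required slice count; a mismatch is an error.
#' @param mode `"average"` (default) or `"max"`.
#' @return A numeric matrix with attribute `projection_mode`.
#' @export
top_projection <- function(stack, n_expected = 5L,
                           mode = c("average", "max")) {
  mode <- match.arg(mode)
  if (is.list(stack)) {
    stack <- array(unlist(stack), c(dim(stack[[1]]), length(stack)))
  }
  ns <- dim(stack)[3]
  if (!is.null(n_expected) && ns != n_expected) {
    abort(sprintf("expected %d slices, got %d", n_expected, ns))
  }
  out <- if (mode == "average") {
    apply(stack, c(1, 2), mean)
  } else {
    apply(stack, c(1, 2), max)
  }
  attr(out, "projection_mode") <- mode
  out
}

#' Histogram-matching photobleaching correction
#'
#' Every frame's intensity histogram is monotonically remapped so that it
#' matches the histogram of the first frame: pixel values are replaced,
#' rank for rank, by the sorted values of frame one. The transform is
#' rank-preserving within each frame and idempotent.
#'
#' @param movie A [movie_stack()] or a numeric array `[ny, nx, n_frames]`.
#' @return Corrected movie of the same type.
#' @export
bleach_correct <- function(movie) {
  is_stack <- inherits(movie, "movie_stack")
  frames <- if (is_stack) movie$frames else movie
  nf <- dim(frames)[3]
  if (nf < 2L) abort("bleach correction needs at least 2 frames")
  ref <- sort(as.vector(frames[, , 1]))
  for (t in 2:nf) {
    v <- as.vector(frames[, , t])
    frames[, , t] <- ref[rank(v, ties.method = "first")]
  }
  if (is_stack) {
    movie$frames <- frames
    movie
  } else frames
}

#' Li minimum-cross-entropy threshold
#'
#' Iterative minimum-cross-entropy threshold of Li and Tam; used as the
#' automatic alternative to the fixed 17/65,535 threshold.
#'
#' @param im Numeric matrix with non-negative values.
#' @param tol Relative convergence tolerance on the threshold (fraction of
#'   the intensity range); kept tight so the threshold transforms exactly
#'   covariantly under affine intensity rescaling.
#' @return Threshold value on the image's intensity scale.
#' @export
li_threshold <- function(im, tol = 1e-8) {
  v <- as.vector(im)
  v <- v[is.finite(v)]
  lo <- min(v)
  v <- v - lo + 1e-9  # log needs positive values
  rng <- max(v)
  t_new <- mean(v)
  for (it in 1:200) {
    t_old <- t_new
    fg <- v[v > t_old]; bg <- v[v <= t_old]
    if (!length(fg) || !length(bg)) break
    mf <- mean(fg); mb <- mean(bg)
    t_new <- (mf - mb) / (log(mf) - log(mb))
    if (!is.finite(t_new) || abs(t_new - t_old) < tol * rng) break
  }
  t_new + lo - 1e-9
}

#' Segment punctate eisosomes by intensity thresholding
#'
#' Binarises the image at a fixed threshold on the 16-bit scale (inclusive,
#' `>=`; the comparable-across-conditions choice is 17 on 0-65,535) or at
#' the automatic Li minimum-cross-entropy threshold, labels 8-connected
#' components, discards components below the minimum size, and measures
#' each ROI.
#'
#' @param im Numeric matrix in counts on a 16-bit scale.
#' @param threshold Fixed threshold value (used when
#'   `mode = "fixed"`); must lie in `[0, 65535]`.
#' @param mode `"fixed"` or `"li"`.
#' @param min_size_px Minimum ROI area in pixels.
#' @param pixel_size_um Pixel size for areas in um^2.
#' @return A tibble of class `eisosome_rois`: `label`, `area_px`,
#'   `area_um2`, `mean_intensity`, `x_px`, `y_px` (intensity-weighted
#'   centroid, 0-based continuous). The label matrix is attached as
#'   attribute `label_matrix`, the threshold used as `threshold`.
#' @export
segment_eisosomes <- function(im, threshold = 17, mode = c("fixed", "li"),
                              min_size_px = 3L, pixel_size_um = 0.05) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (threshold < 0 || threshold > 65535) {
      abort("`threshold` must lie in [0, 65535]")
    }
    thr <- threshold
  } else {
    thr <- li_threshold(im)
  }
  mask <- im >= thr
  lab <- label_components(mask, 8L)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  rows <- purrr::map(ids, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    if (nrow(px) < min_size_px) return(NULL)
    ints <- im[px]
    w <- ints / sum(ints)
    tibble(label = id, area_px = nrow(px),
           area_um2 = nrow(px) * pixel_size_um^2,
           mean_intensity = mean(ints),
           x_px = sum(w * (px[, 2] - 0.5)),
           y_px = sum(w * (px[, 1] - 0.5)))
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(label = integer(), area_px = integer(),
                  area_um2 = numeric(), mean_intensity = numeric(),
                  x_px = numeric(), y_px = numeric())
    lab[] <- 0L
  } else {
    # renumber kept components consecutively, in the label matrix too
    remap <- integer(max(ids))
    remap[out$label] <- seq_len(nrow(out))
    keep <- lab > 0L & lab %in% out$label
    lab[!keep] <- 0L
    lab[keep] <- remap[lab[keep]]
    out$label <- seq_len(nrow(out))
  }
  attr(out, "label_matrix") <- lab
  attr(out, "threshold") <- thr
  attr(out, "mode") <- mode
  class(out) <- c("eisosome_rois", class(out))
  out
}

#' Count segmented eisosomes, flagging merged pairs
#'
#' Counts ROIs per cell and flags area outliers (likely unresolved merged
#' puncta) as those larger than `outlier_factor` times the median ROI area.
#'
#' @param rois ROI tibble from [segment_eisosomes()], optionally with a
#'   `cell_id` column.
#' @param outlier_factor Area multiple of the median that flags an ROI.
#' @return A tibble per cell: `cell_id`, `n_rois`, `n_area_outliers`,
#'   `median_area_px`.
#' @export
count_eisosomes <- function(rois, outlier_factor = 1.5) {
  if (!"cell_id" %in% names(rois)) rois$cell_id <- 1L
  rois |>
    group_by(.data$cell_id) |>
    summarise(
      n_rois = dplyr::n(),
      n_area_outliers = sum(.data$area_px >
                              outlier_factor * median(.data$area_px)),
      median_area_px = median(.data$area_px),
      .groups = "drop"
    )
}

#' Classify two-channel foci as colocalised or distinct
#'
#' A focus is `colocalised` when its nearest other-channel focus lies
#' within the colocalisation radius (default 2 pixels = 100 nm at
#' 50 nm/pixel), else `distinct`. Additionally, foci are paired one-to-one
#' by mutual proximity: candidate cross-channel pairs within the radius are
#' accepted greedily in order of increasing distance (ties by lowest focus
#' id), each focus entering at most one pair; the `mutual_pair` flag marks
#' the members of such exclusive pairs.
#'
#' @param green,red Tibbles with sub-pixel `x_px`, `y_px` (and optionally
#'   `id`, `intensity`) in a shared coordinate frame.
#' @param radius_px Colocalisation radius, pixels.
#' @return A tibble: `id`, `channel`, `x_px`, `y_px`, `class`,
#'   `partner_id`, `partner_distance_px` (the nearest other-channel focus
#'   and its distance; NA when the other channel is empty), `mutual_pair`,
#'   plus `intensity` if supplied.
#' @export
classify_foci <- function(green, red, radius_px = 2) {
  green <- as_tibble(green); red <- as_tibble(red)
  if (!"id" %in% names(green)) green$id <- seq_len(nrow(green))
  if (!"id" %in% names(red)) red$id <- seq_len(nrow(red))
  ng <- nrow(green); nr <- nrow(red)
  nn_g <- rep(NA_integer_, ng); nn_r <- rep(NA_integer_, nr)
  dist_g <- rep(NA_real_, ng); dist_r <- rep(NA_real_, nr)
  mut_g <- rep(FALSE, ng); mut_r <- rep(FALSE, nr)
  if (ng && nr) {
    d <- outer(seq_len(ng), seq_len(nr), function(i, j) {
      sqrt((green$x_px[i] - red$x_px[j])^2 +
             (green$y_px[i] - red$y_px[j])^2)
    })
    nn_g <- apply(d, 1, which.min)
    dist_g <- d[cbind(seq_len(ng), nn_g)]
    nn_r <- apply(d, 2, which.min)
    dist_r <- d[cbind(nn_r, seq_len(nr))]
    cand <- which(d <= radius_px, arr.ind = TRUE)
    if (nrow(cand)) {
      o <- order(d[cand], green$id[cand[, 1]], red$id[cand[, 2]])
      for (k in o) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!mut_g[i] && !mut_r[j]) {
          mut_g[i] <- mut_r[j] <- TRUE
          nn_g[i] <- j; nn_r[j] <- i
          dist_g[i] <- dist_r[j] <- d[i, j]
        }
      }
    }
  }
  mk <- function(tb, channel, nn, dist, mut, other) {
    out <- tibble(
      id = tb$id, channel = channel, x_px = tb$x_px, y_px = tb$y_px,
      class = ifelse(!is.na(dist) & dist <= radius_px,
                     "colocalised", "distinct"),
      partner_id = ifelse(is.na(nn), NA_integer_, other$id[nn]),
      partner_distance_px = dist,
      mutual_pair = mut
    )
    if ("intensity" %in% names(tb)) out$intensity <- tb$intensity
    out
  }
  bind_rows(mk(green, "green", nn_g, dist_g, mut_g, red),
            mk(red, "red", nn_r, dist_r, mut_r, green))
}

#' Per-class focus intensity statistics
#'
#' Mean, SD and SEM of focus intensities per colocalisation class, with a
#' two-sided Welch two-sample t-test between the classes when both have at
#' least two members. When several such comparisons are made together,
#' adjust the p-values with [holm_sidak()].
#'
#' @param foci Classified focus tibble with `class` and `intensity`.
#' @return A list: `summary` (per-class tibble: `class`, `n`, `mean`, `sd`,
#'   `sem`), `test` (tibble: `estimate` = mean difference
#'   colocalised - distinct, `statistic`, `p.value`, `df`; `NULL` if a class
#'   has < 2 members).
#' @export
foci_intensity_stats <- function(foci) {
  summ <- foci |>
    group_by(.data$class) |>
    summarise(n = dplyr::n(), mean = mean(.data$intensity),
              sd = sd(.data$intensity),
              sem = sd(.data$intensity) / sqrt(dplyr::n()),
              .groups = "drop")
  test <- NULL
  cls <- split(foci$intensity, foci$class)
  if (length(cls) == 2L && all(lengths(cls) >= 2L)) {
    a <- cls[["colocalised"]]; b <- cls[["distinct"]]
    if (is.null(a) || is.null(b)) { a <- cls[[1]]; b <- cls[[2]] }
    if (sd(c(a, b)) == 0) {
      test <- tibble(estimate = 0, statistic = 0, p.value = 1,
                     df = length(a) + length(b) - 2)
    } else {
      tt <- t.test(a, b)
      test <- tibble(estimate = unname(diff(rev(tt$estimate))),
                     statistic = unname(tt$statistic),
                     p.value = tt$p.value,
                     df = unname(tt$parameter))
    }
  }
  list(summary = summ, test = test)
}

#' Contiguous above-threshold signal along the plasma membrane
#'
#' Samples the image intensity along the closed membrane contour at
#' sub-pixel arc steps, binarises at the threshold, and reports the arc
#' length of every maximal contiguous above-threshold run. The contour is
#' treated as circular, so runs may wrap across the start point.
#'
#' @param im Numeric matrix.
#' @param contour Closed membrane contour (see [cell_contour()],
#'   [mask_contour()]); an open contour is an error.
#' @param threshold Signal threshold, counts (inclusive, `>=`).
#' @param step_px Arc-length sampling step, pixels (must be <= 0.5).
#' @return A tibble: `segment`, `start_um` (arc position of the run start),
#'   `length_um`. Attribute `perimeter_um` carries the contour length.
#' @export
contiguous_membrane_signal <- function(im, contour, threshold,
                                       step_px = 0.5) {
  if (step_px > 0.5) abort("`step_px` must be <= 0.5")
  px_um <- attr(contour, "pixel_size_um")
  if (is.null(px_um)) {
    abort("contour lacks pixel-size metadata; build it with cell_contour()/mask_contour()")
  }
  if (abs(contour$x_um[1] - contour$x_um[nrow(contour)]) > 1e-9 ||
      abs(contour$y_um[1] - contour$y_um[nrow(contour)]) > 1e-9) {
    abort("contour must be closed")
  }
  # resample at uniform arc length
  dx <- diff(contour$x_um); dy <- diff(contour$y_um)
  arc <- c(0, cumsum(sqrt(dx^2 + dy^2)))
  per <- arc[length(arc)]
  step_um <- step_px * px_um
  n_s <- max(8L, ceiling(per / step_um))
  s <- seq(0, per, length.out = n_s + 1L)[-(n_s + 1L)]
  xs <- stats::approx(arc, contour$x_um, xout = s)$y
  ys <- stats::approx(arc, contour$y_um, xout = s)$y
  v <- interp_bilinear(im, xs / px_um, ys / px_um)
  above <- v >= threshold
  empty <- tibble(segment = integer(), start_um = numeric(),
                  length_um = numeric())
  attr(empty, "perimeter_um") <- per
  if (!any(above)) return(empty)
  ds <- per / n_s
  if (all(above)) {
    out <- tibble(segment = 1L, start_um = 0, length_um = per)
    attr(out, "perimeter_um") <- per
    return(out)
  }
  # rotate so the sequence starts on a below-threshold sample, then runs
  # cannot wrap
  first_low <- which(!above)[1]
  rot <- c(above[first_low:n_s], above[seq_len(first_low - 1L)])
  r <- rle(rot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  out <- tibble(
    segment = seq_along(hi),
    start_um = ((starts[hi] - 1L + first_low - 1L) %% n_s) * ds,
    length_um = r$lengths[hi] * ds
  )
  attr(out, "perimeter_um") <- per
  out
}
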