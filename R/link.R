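# Frame-to-frame track linking by globally optimal bipartite assignment.

# Hungarian algorithm (Jonker-Volgenant potentials, O(n^3)) for an n x m cost
# matrix with n <= m. Returns, for each row, the assigned column index.
# Costs must be finite; use a large penalty for forbidden pairs.
hungarian <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m, all(is.finite(a)))
  u <- numeric(n)
  v <- numeric(m + 1L)        # index j + 1; j = 0 is the dummy column
  p <- integer(m + 1L)        # p[j + 1]: row assigned to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[2:(m + 1L)])
      cur <- a[i0, free] - u[i0] - v[free + 1L]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd] + 1L] <- j0
      }
      k <- which.min(minv[free])
      j1 <- free[k]
      delta <- minv[j1]
      usedcols <- which(used)
      for (jj in usedcols) {
        if (p[jj] > 0L || jj == 1L) {
          if (p[jj] > 0L) u[p[jj]] <- u[p[jj]] + delta
          v[jj] <- v[jj] - delta
        }
      }
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Link per-frame spots into trajectories
#'
#' Spots in consecutive frames are linked by the assignment that minimises
#' the total squared displacement among candidate pairs within the linking
#' radius (optimal bipartite assignment via the Hungarian algorithm).
#' Unassigned spots start new tracks; a track may bridge up to `max_gap`
#' consecutive missed frames before it ends.
#'
#' @param spots A spot tibble from [detect_movie_spots()] (needs `frame`,
#'   `x_px`, `y_px`; other columns are carried through).
#' @param link_radius_px Maximum allowed frame-to-frame displacement in
#'   pixels.
#' @param max_gap Number of consecutive frames a track may go undetected.
#' @return The input tibble with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(spots, link_radius_px = 5, max_gap = 1L) {
  spots <- as_tibble(spots)
  if (!nrow(spots)) {
    spots$track_id <- integer(0)
    return(spots)
  }
  if (!all(c("frame", "x_px", "y_px") %in% names(spots))) {
    abort("`spots` needs columns frame, x_px, y_px")
  }
  ord <- order(spots$frame)
  spots <- spots[ord, ]
  track_id <- integer(nrow(spots))
  frames <- sort(unique(spots$frame))
  # active track state
  act_id <- integer(0); act_x <- numeric(0); act_y <- numeric(0)
  act_f <- numeric(0)
  next_id <- 1L
  r2 <- link_radius_px^2
  for (f in frames) {
    idx <- which(spots$frame == f)
    cand <- which(f - act_f <= max_gap + 1L)
    assigned_sp <- rep(FALSE, length(idx))
    if (length(cand) && length(idx)) {
      d2 <- outer(seq_along(cand), seq_along(idx), function(i, j) {
        (act_x[cand[i]] - spots$x_px[idx[j]])^2 +
          (act_y[cand[i]] - spots$y_px[idx[j]])^2
      })
      big <- 1e6 * (r2 + 1)
      cost <- ifelse(d2 <= r2, d2, big)
      nr <- length(cand); nc <- length(idx)
      nn <- max(nr, nc)
      sq <- matrix(big, nn, nn)
      sq[seq_len(nr), seq_len(nc)] <- cost
      asg <- hungarian(sq)
      for (i in seq_len(nr)) {
        j <- asg[i]
        if (j <= nc && sq[i, j] < big) {
          ti <- cand[i]
          track_id[idx[j]] <- act_id[ti]
          act_x[ti] <- spots$x_px[idx[j]]
          act_y[ti] <- spots$y_px[idx[j]]
          act_f[ti] <- f
          assigned_sp[j] <- TRUE
        }
      }
    }
    for (j in which(!assigned_sp)) {
      track_id[idx[j]] <- next_id
      act_id <- c(act_id, next_id)
      act_x <- c(act_x, spots$x_px[idx[j]])
      act_y <- c(act_y, spots$y_px[idx[j]])
      act_f <- c(act_f, f)
      next_id <- next_id + 1L
    }
    keep <- f - act_f <= max_gap
    act_id <- act_id[keep]; act_x <- act_x[keep]; act_y <- act_y[keep]
    act_f <- act_f[keep]
  }
  spots$track_id <- track_id
  dplyr::arrange(spots, .data$track_id, .data$frame)
}

#' Summarise linked tracks
#'
#' @param tracks Output of [link_tracks()].
#' @return A tibble with one row per track: length, first/last frame, number
#'   of skipped frames (`gaps`) and mean intensity if present.
#' @export
track_summary <- function(tracks) {
  tracks |>
    group_by(.data$track_id) |>
    summarise(
      n_spots = dplyr::n(),
      first_frame = min(.data$frame),
      last_frame = max(.data$frame),
      gaps = (max(.data$frame) - min(.data$frame) + 1L) - dplyr::n(),
      mean_intensity = if ("intensity" %in% names(tracks))
        mean(.data$intensity) else NA_real_,
      .groups = "drop"
    )
}
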