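# Internal numerical helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm rnorm rpois rgeom runif median mad sd var density
#'   nls coef predict fft t.test setNames quantile optimize complete.cases
#' @importFrom utils head tail read.csv write.csv packageVersion
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) abort(sprintf("`%s` must be > %g", name, min))
  if (!strict_min && x < min) abort(sprintf("`%s` must be >= %g", name, min))
  if (x > max) abort(sprintf("`%s` must be <= %g", name, max))
  invisible(x)
}

# Separable Gaussian blur with edge replication. `sigma` in pixels.
gauss_blur <- function(im, sigma) {
  if (sigma <= 0) return(im)
  h <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  im <- conv1(im, k, along = 1L)
  conv1(im, k, along = 2L)
}

# 1-D convolution of a matrix along rows (along = 1) or columns (along = 2),
# replicating edges. Kernel length must be odd.
conv1 <- function(im, k, along) {
  h <- (length(k) - 1L) %/% 2L
  n <- if (along == 1L) nrow(im) else ncol(im)
  out <- matrix(0, nrow(im), ncol(im))
  for (j in seq_along(k)) {
    off <- j - h - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + k[j] * (if (along == 1L) im[idx, , drop = FALSE]
                         else im[, idx, drop = FALSE])
  }
  out
}

# Bilinear interpolation of image values at continuous pixel coordinates
# (0-based convention: pixel (ix, iy) spans [ix, ix+1) x [iy, iy+1), centre at
# ix + 0.5). `x` indexes columns, `y` rows.
interp_bilinear <- function(im, x, y) {
  # shift to pixel-centre grid
  xc <- x - 0.5
  yc <- y - 0.5
  nx <- ncol(im); ny <- nrow(im)
  x0 <- pmin(pmax(floor(xc), 0), nx - 1L)
  y0 <- pmin(pmax(floor(yc), 0), ny - 1L)
  x1 <- pmin(x0 + 1, nx - 1L)
  y1 <- pmin(y0 + 1, ny - 1L)
  fx <- pmin(pmax(xc - x0, 0), 1)
  fy <- pmin(pmax(yc - y0, 0), 1)
  v00 <- im[cbind(y0 + 1L, x0 + 1L)]
  v01 <- im[cbind(y0 + 1L, x1 + 1L)]
  v10 <- im[cbind(y1 + 1L, x0 + 1L)]
  v11 <- im[cbind(y1 + 1L, x1 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Binary dilation of a logical matrix with a disc of radius r pixels.
dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  r <- as.integer(ceiling(r))
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, , drop = FALSE]
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  for (i in seq_len(nrow(offs))) {
    dy <- offs$dy[i]; dx <- offs$dx[i]
    ys <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
    xs <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
    out <- out | mask[ys, xs, drop = FALSE]
  }
  out
}

# 8-connected labelling of a logical matrix by flood fill. Returns an integer
# matrix of component labels (0 = background).
label_components <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (connectivity == 8L) {
    dy <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dx <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dy <- c(-1L, 1L, 0L, 0L)
    dx <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  todo <- which(mask)
  for (p in todo) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      qy <- ((q - 1L) %% ny) + 1L
      qx <- ((q - 1L) %/% ny) + 1L
      yy <- qy + dy
      xx <- qx + dx
      ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
      nb <- (xx[ok] - 1L) * ny + yy[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}
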