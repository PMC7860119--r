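# Independent oracles and shared fixture builders.

# All permutations of a vector (tiny n only) for brute-force assignment.
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Brute-force minimal assignment cost of rows of `a` to distinct columns.
brute_force_assignment <- function(a) {
  n <- nrow(a); m <- ncol(a)
  best <- Inf
  cols <- utils::combn(m, n, simplify = FALSE)
  for (cs in cols) {
    for (p in all_perms(cs)) {
      best <- min(best, sum(a[cbind(seq_len(n), p)]))
    }
  }
  best
}

# Naive position-by-position degenerate-motif matcher (1-based starts).
naive_motif_scan <- function(seq, sets) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(sets)
  hits <- integer(0)
  if (length(chars) < L) return(hits)
  for (s in seq_len(length(chars) - L + 1L)) {
    ok <- TRUE
    for (k in seq_len(L)) {
      if (!(chars[s + k - 1L] %in% sets[[k]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

reverse_complement_chr <- function(seq) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# A confocal scene whose 30 puncta are guaranteed well separated.
well_separated_scene <- function(seed, n_eisosomes = 30L, n_cargo = 15L,
                                 colocalised_fraction = 0.5) {
  cfg <- sim_config(image_shape = c(256L, 256L), background_level = 5,
                    read_noise_sd = 2, psf_sigma_um = 0.12)
  simulate_confocal_scene(
    n_eisosomes, n_cargo = n_cargo,
    colocalised_fraction = colocalised_fraction,
    membrane_radius_um = 4, puncta_amplitude = 1500, puncta_cv = 0.15,
    min_separation_um = 0.6, config = cfg, seed = seed)
}

# Emitters placed uniformly over the elliptical cell (slightly shrunk so all
# start strictly inside).
place_emitters <- function(config, n, seed, S = 1L, D = 0.1) {
  with_seed_local(seed, {
    th <- runif(n, 0, 2 * pi)
    rr <- sqrt(runif(n, 0, 0.97))
    tibble::tibble(
      x_um = config$cell_centre_um[1] + rr * config$cell_axes_um[1] * cos(th),
      y_um = config$cell_centre_um[2] + rr * config$cell_axes_um[2] * sin(th),
      S = S, D = D)
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
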