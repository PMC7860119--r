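# Promoter motif scanning, interactor-set overlaps, delta-delta-Ct fold
# changes and Holm-Sidak multiple testing.

#' Degenerate DNA motif specification
#'
#' A motif over per-position allowed base sets, written as an IUPAC string.
#' The default `"SYGGGG"` encodes the glucose-repressor consensus binding
#' motif (G/C)(C/T)GGGG.
#'
#' @param pattern IUPAC-coded motif string (A, C, G, T plus ambiguity
#'   codes).
#' @return An object of class `motif_spec` with the pattern and its
#'   per-position allowed sets.
#' @export
#' @examples
#' motif_spec()          # (G/C)(C/T)GGGG
#' motif_spec("TATAWA")
motif_spec <- function(pattern = "SYGGGG") {
  pattern <- toupper(pattern)
  if (nchar(pattern) < 1L) abort("motif must have length >= 1")
  map <- Biostrings::IUPAC_CODE_MAP
  letters <- strsplit(pattern, "")[[1]]
  bad <- setdiff(letters, names(map))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC letter(s): %s", paste(bad, collapse = ", ")))
  }
  sets <- strsplit(unname(map[letters]), "")
  structure(list(pattern = pattern, sets = sets), class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat(sprintf("<motif_spec> %s = %s\n", x$pattern,
              paste(vapply(x$sets, function(s)
                if (length(s) == 1) s else
                  paste0("(", paste(s, collapse = "/"), ")"),
                character(1)), collapse = "")))
  invisible(x)
}

#' Scan promoter windows for a degenerate motif
#'
#' Reports every (possibly overlapping) start position where the motif's
#' per-position base sets match. `N` in a sequence never matches. In
#' both-strand mode, matches of the reverse-complemented motif are reported
#' in forward coordinates with strand `"-"`.
#'
#' @param sequences A named character vector of sequences, a
#'   `Biostrings::DNAStringSet`, or a tibble with columns `gene` and
#'   `sequence` (e.g. the -500..-1 promoter windows upstream of each start
#'   codon).
#' @param motif A [motif_spec()] or an IUPAC pattern string.
#' @param strands `"forward"` or `"both"`.
#' @return A tibble: `gene`, `start`, `end` (1-based, inclusive, forward
#'   coordinates), `strand`, `match` (the matched forward-strand text).
#' @export
#' @examples
#' motif_scan(c(geneA = "ATGCGGGGAT"))
motif_scan <- function(sequences, motif = motif_spec(),
                       strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (is.character(motif)) motif <- motif_spec(motif)
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$gene)
  }
  if (!inherits(sequences, "DNAStringSet")) {
    nms <- names(sequences)
    seqs <- toupper(as.character(sequences))
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) abort("sequences may contain only A, C, G, T, N")
    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- nms
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  scan_one <- function(pat, strand) {
    hits <- Biostrings::vmatchPattern(
      pat, sequences, fixed = c(pattern = FALSE, subject = TRUE))
    rows <- purrr::imap(as.list(hits), function(ir, nm) {
      if (!length(ir)) return(NULL)
      st <- Biostrings::start(ir); en <- Biostrings::end(ir)
      tibble(gene = nm, start = st, end = en, strand = strand,
             match = as.character(Biostrings::extractAt(
               sequences[[nm]], ir)))
    })
    bind_rows(rows)
  }
  out <- scan_one(motif$pattern, "+")
  if (strands == "both") {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif$pattern)))
    out <- bind_rows(out, scan_one(rc, "-"))
  }
  if (!nrow(out)) {
    out <- tibble(gene = character(), start = integer(), end = integer(),
                  strand = character(), match = character())
  }
  arrange(out, .data$gene, .data$start, .data$strand)
}

#' Read promoter windows from a FASTA file
#'
#' Parses the description line for the gene identifier (first word) and
#' optionally trims each sequence to its last `window` bases — the region
#' immediately upstream of the start codon.
#'
#' @param path FASTA file path.
#' @param window Window length in bp (`NULL` keeps full sequences).
#' @return Tibble: `gene`, `sequence`.
#' @export
read_promoters <- function(path, window = 500L) {
  ss <- Biostrings::readDNAStringSet(path)
  gene <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  seqs <- as.character(ss)
  if (!is.null(window)) {
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      substr(s, max(1L, n - window + 1L), n)
    }, character(1), USE.NAMES = FALSE)
  }
  tibble(gene = gene, sequence = seqs)
}

#' Group motif-hit genes by functional category
#'
#' Collapses a hit table to gene-level presence (a gene with any promoter
#' hit counts once) and joins user-supplied functional annotations; genes
#' without an annotation fall into `"unassigned"`.
#'
#' @param hits Hit tibble from [motif_scan()].
#' @param annotations Tibble with columns `gene` and `category`.
#' @return A list: `genes` (tibble `gene`, `category`), `counts` (tibble
#'   `category`, `n`, sorted by category).
#' @export
classify_targets <- function(hits, annotations) {
  genes <- tibble(gene = sort(unique(hits$gene)))
  genes <- left_join(genes, as_tibble(annotations), by = "gene")
  genes$category[is.na(genes$category)] <- "unassigned"
  counts <- genes |>
    dplyr::count(.data$category, name = "n") |>
    arrange(.data$category)
  list(genes = genes, counts = counts)
}

#' Overlap between two identifier sets
#'
#' Exact set algebra on normalised gene identifiers (upper-cased, optionally
#' mapped through an alias table so standard and systematic yeast names
#' compare equal), with deterministic sorted output.
#'
#' @param a,b Character vectors of identifiers.
#' @param alias_map Optional named character vector mapping aliases to
#'   canonical names (applied after upper-casing).
#' @return A list of class `set_overlap`: `intersection`, `only_a`,
#'   `only_b` (sorted), `n_a`, `n_b`, `n_intersection`.
#' @export
#' @examples
#' set_overlap(c("LSP1", "PIL1"), c("lsp1", "SLM1"))$intersection
set_overlap <- function(a, b, alias_map = NULL) {
  norm <- function(x) {
    x <- toupper(trimws(x))
    if (!is.null(alias_map)) {
      nm <- toupper(names(alias_map)); al <- toupper(alias_map)
      hit <- match(x, nm)
      x[!is.na(hit)] <- al[hit[!is.na(hit)]]
    }
    unique(x[nzchar(x)])
  }
  a <- norm(a); b <- norm(b)
  structure(list(
    intersection = sort(intersect(a, b)),
    only_a = sort(setdiff(a, b)),
    only_b = sort(setdiff(b, a)),
    n_a = length(a), n_b = length(b),
    n_intersection = length(intersect(a, b))
  ), class = "set_overlap")
}

#' @export
print.set_overlap <- function(x, ...) {
  cat(sprintf("<set_overlap> |A| = %d, |B| = %d, |A n B| = %d\n",
              x$n_a, x$n_b, x$n_intersection))
  if (x$n_intersection) {
    cat("  shared:", paste(x$intersection, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Relative expression by the comparative Ct method
#'
#' Technical replicates are averaged per (sample, gene); then
#' `dCt = Ct_gene - Ct_reference` within each sample,
#' `ddCt = dCt_sample - dCt_control`, and the fold change is
#' `2^(-ddCt)`. Statistics should be run on the Ct values, not on fold
#' changes.
#'
#' @param ct Tibble with columns `sample`, `gene`, `ct` (one row per
#'   technical replicate is fine).
#' @param reference_gene Housekeeping reference gene(s); with several, the
#'   mean of their (replicate-averaged) Cts is used.
#' @param control_sample The sample all others are normalised to.
#' @return Tibble: `sample`, `gene`, `delta_ct`, `delta_delta_ct`,
#'   `fold_change`, for all non-reference genes.
#' @export
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("glucose", "raffinose"), each = 2),
#'   gene = rep(c("ACT1", "YAP1801"), 2),
#'   ct = c(20, 25, 20, 23))
#' ddct_fold_change(ct, "ACT1", "glucose")
ddct_fold_change <- function(ct, reference_gene, control_sample) {
  ct <- as_tibble(ct)
  need <- c("sample", "gene", "ct")
  if (!all(need %in% names(ct))) {
    abort("`ct` needs columns sample, gene, ct")
  }
  if (any(!is.finite(ct$ct))) abort("all Ct values must be finite")
  avg <- ct |>
    group_by(.data$sample, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop")
  refs <- avg |>
    filter(.data$gene %in% reference_gene) |>
    group_by(.data$sample) |>
    summarise(ref_ct = mean(.data$ct), .groups = "drop")
  missing_ref <- setdiff(unique(avg$sample), refs$sample)
  if (length(missing_ref)) {
    abort(sprintf("sample(s) without reference-gene Ct: %s",
                  paste(missing_ref, collapse = ", ")))
  }
  if (!control_sample %in% avg$sample) {
    abort(sprintf("control sample '%s' not present", control_sample))
  }
  dct <- avg |>
    filter(!.data$gene %in% reference_gene) |>
    left_join(refs, by = "sample") |>
    mutate(delta_ct = .data$ct - .data$ref_ct)
  ctrl <- dct |>
    filter(.data$sample == control_sample) |>
    dplyr::select("gene", control_dct = "delta_ct")
  dct |>
    left_join(ctrl, by = "gene") |>
    mutate(delta_delta_ct = .data$delta_ct - .data$control_dct,
           fold_change = 2^(-.data$delta_delta_ct)) |>
    dplyr::select("sample", "gene", "delta_ct", "delta_delta_ct",
                  "fold_change")
}

# Step-down Sidak adjustment of a p-value vector; returns adjusted p-values
# in the input order.
holm_sidak_adjust <- function(p) {
  m <- length(p)
  o <- order(p)
  padj <- 1 - (1 - p[o])^(m - seq_len(m) + 1L)
  padj <- cummax(pmin(padj, 1))
  out <- numeric(m)
  out[o] <- padj
  out
}

#' Holm-Sidak multiple-comparison t-tests
#'
#' Runs an unpaired Welch t-test for every comparison and applies the
#' step-down Sidak correction: the i-th smallest p-value is compared
#' against `1 - (1 - alpha)^(1 / (m - i + 1))`, rejecting until the first
#' failure, which keeps the decisions monotone. Precomputed p-values can be
#' supplied instead of samples.
#'
#' @param comparisons Either a numeric vector of p-values, or a named list
#'   of two-element lists/sample pairs `list(x, y)`.
#' @param alpha Family-wise error rate.
#' @return A tibble: `comparison`, `statistic`, `df`, `p.value`,
#'   `p.adjusted`, `reject`. Comparisons with fewer than two values in a
#'   group are excluded with a warning.
#' @export
#' @examples
#' holm_sidak(c(a = 0.01, b = 0.2, c = 0.03))
holm_sidak <- function(comparisons, alpha = 0.05) {
  check_number(alpha, "alpha", 0, 1)
  if (is.numeric(comparisons)) {
    nm <- names(comparisons)
    if (is.null(nm)) nm <- paste0("comparison", seq_along(comparisons))
    res <- tibble(comparison = nm, statistic = NA_real_, df = NA_real_,
                  p.value = as.numeric(comparisons))
  } else {
    nm <- names(comparisons)
    if (is.null(nm)) nm <- paste0("comparison", seq_along(comparisons))
    rows <- purrr::map2(comparisons, nm, function(cmp, nm1) {
      x <- cmp[[1]]; y <- cmp[[2]]
      if (length(x) < 2L || length(y) < 2L) {
        warn(sprintf("comparison '%s' has a group with n < 2; excluded",
                     nm1))
        return(NULL)
      }
      tt <- t.test(x, y)
      tibble(comparison = nm1, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p.value = tt$p.value)
    })
    res <- bind_rows(rows)
    if (!nrow(res)) abort("no valid comparisons")
  }
  res$p.adjusted <- holm_sidak_adjust(res$p.value)
  res$reject <- res$p.adjusted <= alpha
  res
}
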