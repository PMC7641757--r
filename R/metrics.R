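#' Per-gene codon frequency table
#'
#' Counts every codon occurrence in each coding sequence, including the stop
#' codons. Codons containing ambiguity characters are excluded from the tally
#' (a message reports how many).
#'
#' @param cds a coding-sequence tibble (see [cds_table()]).
#' @return A tibble with the identifier columns followed by 64 codon-count
#'   columns in lexicographic codon order. Row sums over the codon columns
#'   equal the number of (unambiguous) codons in each record.
#' @examples
#' cds <- cds_table("s1", "g1", seq = "ATGATGTAA")
#' codon_counts(cds)$ATG  # 2
#' @export
codon_counts <- function(cds) {
  long <- cds_codons(cds)
  codons <- all_codons()
  mat <- matrix(0L, nrow = nrow(cds), ncol = 64L, dimnames = list(NULL, codons))
  if (nrow(long) > 0) {
    tab <- table(factor(long$.row, levels = seq_len(nrow(cds))),
                 factor(long$codon, levels = codons))
    mat[] <- as.integer(tab)
  }
  bind_cols(cds[, id_cols()], as_tibble(mat))
}

#' Averted codons per gene
#'
#' A codon is averted by a gene when it never occurs in its coding sequence.
#'
#' @param cds a coding-sequence tibble, or the output of [codon_counts()].
#' @param include_stops count aversion over all 64 codons (default, the three
#'   stop codons included) or only the 61 sense codons.
#' @return A tibble with the identifier columns, `averted` (a list-column of
#'   sorted codon vectors) and `motif` (the same set collapsed to a
#'   `|`-separated string).
#' @export
codon_aversion <- function(cds, include_stops = TRUE) {
  counts <- if (all(all_codons() %in% names(cds))) cds else codon_counts(cds)
  universe <- if (include_stops) all_codons() else sense_codons()
  mat <- as.matrix(counts[, universe])
  averted <- lapply(seq_len(nrow(mat)), function(i) universe[mat[i, ] == 0L])
  out <- counts[, id_cols()]
  out$averted <- averted
  out$motif <- vapply(averted, paste, character(1), collapse = "|")
  out
}

#' Identical codon pairing within a ribosomal window
#'
#' Two occurrences of the same codon pair when they fall within one ribosomal
#' footprint, modelled as a window of `window` codons: positions i < j pair
#' iff j - i <= window - 1. Each position is counted as paired at most once
#' (a position j counts iff the same codon occurs anywhere in the window - 1
#' codons before it), so a run of k identical codons contributes k - 1.
#' Stop codons never participate in pairing.
#'
#' @param cds a coding-sequence tibble.
#' @param window ribosomal window size in codons; default 9, the approximate
#'   footprint of a ribosome. Must be >= 2.
#' @return A tibble with the identifier columns followed by 61 sense-codon
#'   columns of pairing counts.
#' @examples
#' cds <- cds_table("s1", "g1", seq = "AAACCCAAA")
#' codon_pairing(cds)$AAA  # 1
#' @export
codon_pairing <- function(cds, window = 9L) {
  check_window(window)
  long <- cds_codons(cds)
  long <- long[long$codon %in% sense_codons(), , drop = FALSE]
  paired <- long |>
    group_by(.row, .data$codon) |>
    summarise(n_paired = sum(diff(.data$pos) <= window - 1L), .groups = "drop")
  wide <- tidyr::pivot_wider(
    tidyr::complete(paired, .row = seq_len(nrow(cds)),
                    codon = sense_codons(), fill = list(n_paired = 0L)),
    names_from = "codon", values_from = "n_paired"
  ) |> arrange(.row)
  bind_cols(cds[, id_cols()], wide[, sense_codons()])
}

#' Co-tRNA codon pairing within a ribosomal window
#'
#' Counts, per amino acid, positions whose codon is preceded within
#' `window - 1` codons by a synonymous but non-identical codon. Identical
#' pairs are excluded; single-codon families (Met, Trp) therefore always
#' score 0.
#'
#' @inheritParams codon_pairing
#' @return A tibble with the identifier columns followed by 20 amino-acid
#'   columns (one-letter codes, alphabetical).
#' @examples
#' cds <- cds_table("s1", "g1", seq = "CTGCTA")
#' cotrna_pairing(cds)$L  # 1
#' @export
cotrna_pairing <- function(cds, window = 9L) {
  check_window(window)
  code <- genetic_code()$codon_to_aa
  long <- cds_codons(cds)
  long <- long[long$codon %in% sense_codons(), , drop = FALSE]
  long$aa <- unname(code[long$codon])
  paired <- long |>
    group_by(.row, .data$aa) |>
    summarise(n_paired = cotrna_count(.data$pos, .data$codon, window),
              .groups = "drop")
  wide <- tidyr::pivot_wider(
    tidyr::complete(paired, .row = seq_len(nrow(cds)),
                    aa = amino_acids(), fill = list(n_paired = 0L)),
    names_from = "aa", values_from = "n_paired"
  ) |> arrange(.row)
  bind_cols(cds[, id_cols()], wide[, amino_acids()])
}

# positions/codons of one amino-acid family in one gene, already in order
cotrna_count <- function(pos, codon, window) {
  n <- length(pos)
  if (n < 2L) return(0L)
  hits <- vapply(2L:n, function(k) {
    j <- seq_len(k - 1L)
    any(pos[k] - pos[j] <= window - 1L & codon[j] != codon[k])
  }, logical(1))
  sum(hits)
}

#' Relative synonymous codon usage (RSCU) per gene
#'
#' RSCU of codon c with count X_c in a synonymous family of size k is
#' k * X_c / sum of counts over the family: the observed count divided by the
#' expected count under uniform synonymous usage. Families with zero observed
#' codons have undefined RSCU and are reported as `NA` (missing, not zero).
#' Stop codons are excluded.
#'
#' @param cds a coding-sequence tibble, or the output of [codon_counts()].
#' @return A tibble with the identifier columns followed by 61 sense-codon
#'   RSCU columns. For every observed family the values sum to the family
#'   size (equivalently average 1).
#' @export
rscu <- function(cds) {
  counts <- if (all(all_codons() %in% names(cds))) cds else codon_counts(cds)
  mat <- as.matrix(counts[, sense_codons()])
  vals <- t(apply(mat, 1L, rscu_vector))
  if (nrow(mat) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, sense_codons()))
  bind_cols(counts[, id_cols()], as_tibble(vals))
}

# RSCU from one 61-long named count vector
rscu_vector <- function(x) {
  fams <- genetic_code()$families
  out <- setNames(rep(NA_real_, length(x)), names(x))
  for (aa in amino_acids()) {
    fam <- fams[[aa]]
    tot <- sum(x[fam])
    if (tot > 0) out[fam] <- length(fam) * x[fam] / tot
  }
  out[names(x)]
}

#' Reference RSCU table from a set of coding sequences
#'
#' Pools codon counts over all records (e.g. the longest isoform of every
#' gene in a reference assembly) and computes a single RSCU value per sense
#' codon. Used as the per-codon translational-speed proxy for ramp-sequence
#' detection.
#'
#' @param cds a coding-sequence tibble.
#' @return A named numeric vector of length 61 (RSCU per sense codon; `NA`
#'   for families never observed).
#' @export
rscu_reference <- function(cds) {
  counts <- codon_counts(cds)
  pooled <- colSums(as.matrix(counts[, sense_codons()]))
  rscu_vector(pooled)
}

#' Nucleotide composition and GC content per gene
#'
#' @param cds a coding-sequence tibble.
#' @return A tibble with the identifier columns, counts `A`, `C`, `G`, `T`
#'   and `gc_content` = (G + C) / (A + C + G + T).
#' @export
nucleotide_composition <- function(cds) {
  out <- cds[, id_cols()]
  for (nt in c("A", "C", "G", "T")) {
    out[[nt]] <- stringr::str_count(cds$seq, stringr::fixed(nt))
  }
  tot <- out$A + out$C + out$G + out$T
  out$gc_content <- ifelse(tot > 0, (out$G + out$C) / tot, NA_real_)
  out
}

check_window <- function(window) {
  if (!is.numeric(window) || length(window) != 1L || window < 2L) {
    abort("`window` must be a single integer >= 2")
  }
  invisible(TRUE)
}
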