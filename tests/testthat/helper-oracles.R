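# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (full pair enumeration, character tallies) so they can
# arbitrate the optimized implementations.

# random sense-codon sequence as a single string
random_codon_seq <- function(n, alphabet = sense_codons()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

split_codons <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

# brute-force tally by scanning nucleotides 3 at a time
oracle_codon_counts <- function(seq) {
  codons <- split_codons(seq)
  tab <- table(factor(codons, levels = all_codons()))
  as.integer(tab)
}

# identical pairing: position j counts iff any earlier equal codon within
# window - 1; full enumeration over all (i, j) pairs
oracle_identical_pairing <- function(codons, window) {
  counts <- setNames(integer(length(sense_codons())), sense_codons())
  n <- length(codons)
  if (n >= 2) {
    for (j in 2:n) {
      if (!codons[j] %in% sense_codons()) next
      hit <- FALSE
      for (i in 1:(j - 1)) {
        if (codons[i] == codons[j] && j - i <= window - 1) hit <- TRUE
      }
      if (hit) counts[codons[j]] <- counts[codons[j]] + 1L
    }
  }
  counts
}

# co-tRNA pairing: synonymous but non-identical earlier codon within window
oracle_cotrna_pairing <- function(codons, window) {
  code <- genetic_code()$codon_to_aa
  counts <- setNames(integer(length(amino_acids())), amino_acids())
  n <- length(codons)
  if (n >= 2) {
    for (j in 2:n) {
      aj <- code[[codons[j]]]
      if (aj == "*") next
      hit <- FALSE
      for (i in 1:(j - 1)) {
        if (code[[codons[i]]] == aj && codons[i] != codons[j] &&
            j - i <= window - 1) hit <- TRUE
      }
      if (hit) counts[aj] <- counts[aj] + 1L
    }
  }
  counts
}

# path-length matrix of a phylo tree (independent of the NJ implementation
# under test: sums edge lengths along tip-to-tip paths via ape cophenetic)
tree_path_lengths <- function(tree) ape::cophenetic.phylo(tree)

pairing_row <- function(seq, window = 9) {
  p <- codon_pairing(cds_table("s", "g", seq = seq, validate = FALSE),
                     window = window)
  unlist(p[1, sense_codons()])
}

cotrna_row <- function(seq, window = 9) {
  p <- cotrna_pairing(cds_table("s", "g", seq = seq, validate = FALSE),
                      window = window)
  unlist(p[1, amino_acids()])
}
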