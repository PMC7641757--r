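test_that("codon counting matches direct inspection and a brute-force tally", {
  cds <- cds_table("s1", "g1", seq = "ATGATGTAA")
  cc <- codon_counts(cds)
  expect_equal(cc$ATG, 2L)
  expect_equal(cc$TAA, 1L)
  expect_equal(sum(as.matrix(cc[, all_codons()])), 3L)

  # empty sequence: all-zero table
  cc0 <- codon_counts(cds_table("s1", "g1", seq = ""))
  expect_equal(sum(as.matrix(cc0[, all_codons()])), 0L)

  set.seed(42)
  for (rep in 1:5) {
    seq <- random_codon_seq(300, alphabet = all_codons())
    cc <- codon_counts(cds_table("s", "g", seq = seq))
    expect_equal(unname(unlist(cc[1, all_codons()])), oracle_codon_counts(seq))
  }
})

test_that("count conservation: codon counts sum to sequence length for many inputs", {
  set.seed(7)
  lens <- c(0, 1, 2, 10, 100, 333)
  cds <- cds_table("s", paste0("g", seq_along(lens)),
                   seq = vapply(lens, random_codon_seq, character(1)))
  cc <- codon_counts(cds)
  expect_equal(unname(rowSums(as.matrix(cc[, all_codons()]))), lens)
})

test_that("non-multiple-of-3 records are rejected naming the record", {
  expect_warning(
    cds <- cds_table(c("s1", "s2"), c("gA", "gB"), seq = c("ATGTAA", "ATGC")),
    "s2\\|gB"
  )
  expect_equal(nrow(cds), 1L)
})

test_that("ambiguity codons are excluded from counts but positions are kept", {
  expect_message(
    cc <- codon_counts(cds_table("s", "g", seq = "ATGNNNATG")),
    "non-ACGT"
  )
  expect_equal(cc$ATG, 2L)
  expect_equal(sum(as.matrix(cc[, all_codons()])), 2L)
  # the two ATG are 2 positions apart despite the N codon between them
  expect_message(p <- codon_pairing(cds_table("s", "g", seq = "ATGNNNATG")))
  expect_equal(p$ATG, 1L)
})

test_that("codon aversion is the complement of the count support", {
  # a sequence with only ATG and TAA averts the other 62 codons
  av <- codon_aversion(cds_table("s", "g", seq = "ATGTAA"), include_stops = TRUE)
  expect_length(av$averted[[1]], 62)
  expect_false(any(c("ATG", "TAA") %in% av$averted[[1]]))

  # all 64 codons present: nothing averted
  all64 <- paste(all_codons(), collapse = "")
  av64 <- codon_aversion(cds_table("s", "g", seq = all64))
  expect_length(av64$averted[[1]], 0)
  expect_equal(av64$motif, "")

  set.seed(13)
  seq <- random_codon_seq(100, alphabet = all_codons())
  cc <- codon_counts(cds_table("s", "g", seq = seq))
  present <- all_codons()[unlist(cc[1, all_codons()]) > 0]
  av <- codon_aversion(cds_table("s", "g", seq = seq))
  expect_setequal(av$averted[[1]], setdiff(all_codons(), present))
  # sense-only universe
  av61 <- codon_aversion(cds_table("s", "g", seq = seq), include_stops = FALSE)
  expect_setequal(av61$averted[[1]], setdiff(sense_codons(), present))
})

test_that("identical pairing matches hand-worked window examples", {
  expect_equal(unname(pairing_row("AAACCCAAA")["AAA"]), 1L)
  expect_equal(unname(pairing_row("AAAAAAAAA")["AAA"]), 2L)  # run of 3 -> 2
  # offset 9 is outside a 9-codon footprint
  far <- paste(c("AAA", rep("CCC", 8), "AAA"), collapse = "")
  expect_equal(unname(pairing_row(far)["AAA"]), 0L)
  expect_equal(unname(pairing_row(far)["CCC"]), 7L)
  # but it pairs under window 10
  expect_equal(unname(pairing_row(far, window = 10)["AAA"]), 1L)
})

test_that("co-tRNA pairing counts synonymous non-identical codons only", {
  expect_equal(unname(cotrna_row("CTGCTA")["L"]), 1L)
  r <- cotrna_row("CTGCTG")
  expect_equal(unname(r["L"]), 0L)  # identical pairs excluded
  expect_equal(unname(pairing_row("CTGCTG")["CTG"]), 1L)
  expect_equal(sum(cotrna_row("ATGTGG")), 0L)  # Met/Trp cannot co-tRNA pair
})

test_that("window parameter is validated", {
  cds <- cds_table("s", "g", seq = "ATGATG")
  expect_error(codon_pairing(cds, window = 1), "window")
  expect_error(cotrna_pairing(cds, window = 0), "window")
})

test_that("pairing counters match the brute-force pair enumerator on random sequences", {
  set.seed(101)
  alphabet4 <- c("CTA", "CTG", "AAA", "ATG")  # two Leu synonyms, Lys, Met
  for (rep in 1:60) {
    n <- sample(2:30, 1)
    window <- sample(2:12, 1)
    codons <- sample(alphabet4, n, replace = TRUE)
    seq <- paste(codons, collapse = "")
    expect_equal(unname(pairing_row(seq, window)),
                 unname(oracle_identical_pairing(codons, window)))
    expect_equal(unname(cotrna_row(seq, window)),
                 unname(oracle_cotrna_pairing(codons, window)))
  }
  # and over the full sense alphabet
  for (rep in 1:20) {
    codons <- sample(sense_codons(), 30, replace = TRUE)
    seq <- paste(codons, collapse = "")
    expect_equal(unname(pairing_row(seq, 9)),
                 unname(oracle_identical_pairing(codons, 9)))
    expect_equal(unname(cotrna_row(seq, 9)),
                 unname(oracle_cotrna_pairing(codons, 9)))
  }
})

test_that("pairing counts never decrease when the window grows and stay below occurrences", {
  set.seed(202)
  for (rep in 1:20) {
    codons <- sample(c("AAA", "AAG", "CCC", "GGG"), 25, replace = TRUE)
    seq <- paste(codons, collapse = "")
    p5 <- pairing_row(seq, 5); p9 <- pairing_row(seq, 9); p25 <- pairing_row(seq, 25)
    expect_true(all(p9 >= p5))
    expect_true(all(p25 >= p9))
    counts <- table(factor(codons, levels = sense_codons()))
    expect_true(all(p25[p25 > 0] + 1 <= counts[p25 > 0]))
    c5 <- cotrna_row(seq, 5); c9 <- cotrna_row(seq, 9)
    expect_true(all(c9 >= c5))
  }
})

test_that("RSCU follows the family-normalised formula and flags unobserved families", {
  # all six Leu codons once each -> RSCU 1 for each
  leu <- genetic_code()$families[["L"]]
  r <- rscu(cds_table("s", "g", seq = paste(leu, collapse = "")))
  expect_equal(unname(unlist(r[1, leu])), rep(1, 6))
  # two-fold family with counts 3:1 -> 1.5 / 0.5
  r2 <- rscu(cds_table("s", "g", seq = "AAAAAAAAAAAG"))
  expect_equal(r2$AAA, 1.5)
  expect_equal(r2$AAG, 0.5)
  # unobserved family -> missing, not zero
  expect_true(is.na(r2$CTG))
})

test_that("RSCU family sums equal family sizes for observed families on random tables", {
  set.seed(303)
  fams <- genetic_code()$families
  for (rep in 1:20) {
    seq <- random_codon_seq(sample(c(30, 100, 300), 1))
    r <- rscu(cds_table("s", "g", seq = seq))
    for (aa in amino_acids()) {
      vals <- unlist(r[1, fams[[aa]]])
      if (all(is.na(vals))) next
      expect_equal(sum(vals), length(vals), tolerance = 1e-9)
    }
  }
})

test_that("nucleotide composition matches a character tally", {
  expect_equal(nucleotide_composition(cds_table("s", "g", seq = "ATGC", validate = FALSE))$gc_content, 0.5)
  expect_equal(nucleotide_composition(cds_table("s", "g", seq = "GGGCCC"))$gc_content, 1)
  set.seed(404)
  seq <- random_codon_seq(200)
  comp <- nucleotide_composition(cds_table("s", "g", seq = seq))
  chars <- strsplit(seq, "")[[1]]
  for (nt in c("A", "C", "G", "T")) {
    expect_equal(comp[[nt]], sum(chars == nt))
  }
  expect_equal(comp$A + comp$C + comp$G + comp$T, 600L)
  expect_equal(comp$gc_content, mean(chars %in% c("G", "C")))
})
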