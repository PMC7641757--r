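#' Build a coding-sequence table
#'
#' The package's central input is a tibble of coding sequences (CDS), one row
#' per (sample, gene, isoform, allele). All metric functions take this table
#' as their first argument and return a tibble, so calls chain with the pipe.
#'
#' @param sample_id,gene_id,isoform_id,allele,seq vectors of equal length (or
#'   length 1, recycled). `seq` holds the nucleotide sequence (A/C/G/T;
#'   ambiguity codes are tolerated here and handled downstream). `allele` is
#'   1 or 2 for diploid data.
#' @param validate if `TRUE` (default), drop records whose length is not a
#'   multiple of 3, with a warning naming them.
#' @return A tibble with columns `sample_id`, `gene_id`, `isoform_id`,
#'   `allele`, `seq`, `n_codons`.
#' @examples
#' cds_table(sample_id = "s1", gene_id = "g1", seq = "ATGCTGCTATAA")
#' @export
cds_table <- function(sample_id, gene_id, seq, isoform_id = "1", allele = 1L,
                      validate = TRUE) {
  cds <- tibble(
    sample_id = as.character(sample_id),
    gene_id = as.character(gene_id),
    isoform_id = as.character(isoform_id),
    allele = as.integer(allele),
    seq = toupper(as.character(seq))
  )
  if (validate) cds <- validate_cds(cds) else cds$n_codons <- nchar(cds$seq) %/% 3L
  cds
}

#' Validate a coding-sequence table
#'
#' Drops records whose nucleotide length is not a multiple of 3 (partial
#' codons), warning with the offending record identifiers. Codons containing
#' ambiguity codes (e.g. N) are not dropped here; they are excluded from
#' counts by the metric functions.
#'
#' @param cds a coding-sequence tibble (see [cds_table()]).
#' @return The validated tibble with an `n_codons` column.
#' @export
validate_cds <- function(cds) {
  stopifnot(all(c("sample_id", "gene_id", "seq") %in% names(cds)))
  if (!"isoform_id" %in% names(cds)) cds$isoform_id <- "1"
  if (!"allele" %in% names(cds)) cds$allele <- 1L
  cds$seq <- toupper(cds$seq)
  bad <- nchar(cds$seq) %% 3L != 0L
  if (any(bad)) {
    ids <- paste(cds$sample_id[bad], cds$gene_id[bad], sep = "|")
    warn(paste0(
      sum(bad), " record(s) skipped: length not a multiple of 3 (",
      paste(head(ids, 5), collapse = ", "),
      if (sum(bad) > 5) ", ..." else "", ")"
    ))
    cds <- cds[!bad, , drop = FALSE]
  }
  cds$n_codons <- nchar(cds$seq) %/% 3L
  cds[, c("sample_id", "gene_id", "isoform_id", "allele", "seq", "n_codons")]
}

# Long codon view: one row per codon with its record index and 1-based
# position. Codons containing non-ACGT characters are dropped (with a single
# message when any are found); positions keep the original numbering so
# window distances are unaffected.
cds_codons <- function(cds, keep_ambiguous = FALSE) {
  n <- cds$n_codons
  if (sum(n) == 0) {
    return(tibble(.row = integer(), pos = integer(), codon = character()))
  }
  codons <- unlist(lapply(cds$seq, function(s) {
    if (nchar(s) == 0L) return(character(0))
    substring(s, seq(1L, nchar(s), by = 3L), seq(3L, nchar(s), by = 3L))
  }), use.names = FALSE)
  out <- tibble(
    .row = rep.int(seq_len(nrow(cds)), n),
    pos = unlist(lapply(n, seq_len), use.names = FALSE),
    codon = codons
  )
  if (!keep_ambiguous) {
    ok <- out$codon %in% all_codons()
    if (!all(ok)) {
      inform(paste0(sum(!ok), " codon(s) with non-ACGT characters excluded from counts"))
      out <- out[ok, , drop = FALSE]
    }
  }
  out
}

id_cols <- function() c("sample_id", "gene_id", "isoform_id", "allele")

#' Read coding sequences from FASTA
#'
#' Record headers are expected to carry the identifiers
#' `sample<delim>gene<delim>isoform<delim>allele` (e.g. `HG001|IRGM|1|2`).
#' Headers with fewer fields are filled with defaults (`isoform = "1"`,
#' `allele = 1`); headers with more fields trigger a record-level warning and
#' the record is skipped, as are records whose length is not a multiple of 3.
#'
#' @param path path to a FASTA file.
#' @param delim single-character field delimiter in headers (default `"|"`).
#' @return A validated coding-sequence tibble (see [cds_table()]).
#' @export
read_cds_fasta <- function(path, delim = "|") {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- Biostrings::readDNAStringSet(path)
  headers <- sub("\\s.*$", "", names(ss))
  fields <- strsplit(headers, delim, fixed = TRUE)
  nf <- lengths(fields)
  bad <- nf < 1L | nf > 4L
  if (any(bad)) {
    warn(paste0(sum(bad), " record(s) skipped: malformed header (",
                paste(head(headers[bad], 3), collapse = ", "), ")"))
    ss <- ss[!bad]; fields <- fields[!bad]
  }
  get <- function(i, default) {
    vapply(fields, function(f) if (length(f) >= i) f[[i]] else default, character(1))
  }
  cds_table(
    sample_id = get(1L, "sample"),
    gene_id = get(2L, "gene"),
    isoform_id = get(3L, "1"),
    allele = suppressWarnings(as.integer(get(4L, "1"))),
    seq = as.character(ss)
  )
}

#' Write coding sequences to FASTA
#'
#' Inverse of [read_cds_fasta()]: headers are
#' `sample<delim>gene<delim>isoform<delim>allele`.
#'
#' @param cds a coding-sequence tibble.
#' @param path output path.
#' @param delim header field delimiter.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(cds, path, delim = "|") {
  ss <- Biostrings::DNAStringSet(cds$seq)
  names(ss) <- paste(cds$sample_id, cds$gene_id, cds$isoform_id, cds$allele,
                     sep = delim)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a sample-to-population assignment table
#'
#' A TSV with columns `sample_id`, `population` and optionally
#' `superpopulation` (continental-level grouping). When `superpopulation` is
#' absent it is set equal to `population`.
#'
#' @param path path to the TSV.
#' @return A tibble with columns `sample_id`, `population`, `superpopulation`.
#' @export
read_population_assignment <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("sample_id", "population") %in% names(tab)))
  if (!"superpopulation" %in% names(tab)) tab$superpopulation <- tab$population
  as_tibble(tab[, c("sample_id", "population", "superpopulation")])
}
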