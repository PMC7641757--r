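#' Materialize per-sample haplotype sequences from a reference CDS
#'
#' Applies phased single-nucleotide variants (in 1-based CDS coordinates) to
#' a reference coding sequence, producing the two allele sequences of each
#' sample. Unphased input is rejected: each variant row must carry explicit
#' `allele1` / `allele2` indicators (0 = reference base, 1 = alternate).
#'
#' @param reference a single-row coding-sequence tibble (the reference CDS
#'   of one gene).
#' @param variants a data frame with columns `sample_id`, `cds_position`
#'   (1-based nucleotide within the CDS), `ref`, `alt` (single bases) and
#'   `allele1`, `allele2` in \{0, 1\}.
#' @return A coding-sequence tibble with two rows (allele 1 and 2) per
#'   sample, `gene_id`/`isoform_id` inherited from the reference.
#' @examples
#' ref <- cds_table("ref", "g1", seq = "ATGCTGTAA")
#' vars <- data.frame(sample_id = "s1", cds_position = 6, ref = "G",
#'                    alt = "A", allele1 = 0, allele2 = 1)
#' materialize_haplotypes(ref, vars)
#' @export
materialize_haplotypes <- function(reference, variants) {
  stopifnot(nrow(reference) == 1L)
  need <- c("sample_id", "cds_position", "ref", "alt", "allele1", "allele2")
  stopifnot(all(need %in% names(variants)))
  if (!all(unlist(variants[, c("allele1", "allele2")]) %in% c(0L, 1L))) {
    abort("unphased or non-binary genotypes: allele1/allele2 must be 0 or 1")
  }
  if (!all(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L)) {
    abort("only single-nucleotide variants are supported")
  }
  refseq <- reference$seq
  pos <- as.integer(variants$cds_position)
  if (any(pos < 1L | pos > nchar(refseq))) {
    abort(paste0("variant position outside CDS in ", reference$gene_id))
  }
  obs <- substring(refseq, pos, pos)
  bad <- obs != toupper(variants$ref)
  if (any(bad)) {
    abort(paste0("reference base mismatch in ", reference$gene_id,
                 " at CDS position ", pos[which(bad)[1L]], ": CDS has ",
                 obs[which(bad)[1L]], ", variant says ", variants$ref[which(bad)[1L]]))
  }
  samples <- unique(variants$sample_id)
  rows <- lapply(samples, function(s) {
    v <- variants[variants$sample_id == s, ]
    mk <- function(which_allele) {
      alt_here <- v[v[[which_allele]] == 1L, ]
      sq <- refseq
      if (nrow(alt_here) > 0) {
        for (k in seq_len(nrow(alt_here))) {
          p <- as.integer(alt_here$cds_position[k])
          substr(sq, p, p) <- toupper(alt_here$alt[k])
        }
      }
      sq
    }
    tibble(sample_id = s, gene_id = reference$gene_id,
           isoform_id = reference$isoform_id, allele = 1:2,
           seq = c(mk("allele1"), mk("allele2")))
  })
  validate_cds(bind_rows(rows))
}
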