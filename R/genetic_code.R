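#' The standard genetic code
#'
#' Returns the standard nuclear genetic code as a small lookup object: the
#' codon-to-amino-acid map over all 64 DNA codons and the synonymous-codon
#' family of every amino acid. Stop codons are translated as `"*"`.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{codon_to_aa}{named character vector of length 64, codons in
#'       lexicographic (A < C < G < T) order, values one-letter amino-acid
#'       codes with `"*"` for the three stop codons.}
#'     \item{families}{named list mapping each amino acid (and `"*"`) to the
#'       sorted character vector of its codons.}
#'   }
#' @examples
#' gc <- genetic_code()
#' gc$codon_to_aa["ATG"]     # "M"
#' gc$families[["L"]]        # the six leucine codons
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[order(names(code))]
  list(
    codon_to_aa = code,
    families = split(names(code), unname(code))
  )
}

#' All 64 codons in lexicographic order
#' @return Character vector of length 64.
#' @export
all_codons <- function() names(genetic_code()$codon_to_aa)

#' The 61 sense (amino-acid encoding) codons in lexicographic order
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  code <- genetic_code()$codon_to_aa
  names(code)[code != "*"]
}

#' The three stop codons
#' @return Character vector of length 3.
#' @export
stop_codons <- function() {
  code <- genetic_code()$codon_to_aa
  names(code)[code == "*"]
}

#' The 20 amino acids (one-letter codes), alphabetical
#' @return Character vector of length 20.
#' @export
amino_acids <- function() sort(setdiff(unique(unname(genetic_code()$codon_to_aa)), "*"))
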