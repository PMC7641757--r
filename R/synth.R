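#' Configuration for a synthetic cohort
#'
#' Bundles the knobs of the synthetic-data generator. The defaults describe
#' a small cohort with strongly divergent synonymous-codon preferences: 3
#' populations of 40 haploid genomes, 50 genes of 300 codons each, and a
#' per-family Dirichlet concentration of 1 (preference vectors essentially
#' independent between populations). All randomness flows from `seed`.
#'
#' @param n_populations number of populations.
#' @param n_individuals individuals (haploid genomes) per population.
#' @param n_genes genes per genome.
#' @param n_codons sense codons per gene (a terminal stop is appended when
#'   `terminal_stop`).
#' @param concentration Dirichlet concentration of per-population synonymous
#'   preferences around the shared base profile; larger values pull all
#'   populations toward the base (identical in the limit), smaller values
#'   make them more distinct.
#' @param polymorphism per-codon probability that an individual's codon is
#'   resampled from its population profile instead of carrying the
#'   population consensus: the within-population synonymous polymorphism
#'   rate (default 0.01).
#' @param base_bias ratio of the geometric preference series that defines
#'   the shared base profile within each synonym family (default 0.35): the
#'   second-ranked codon of a family gets 0.35 times the weight of the
#'   first, and so on. 1 gives uniform (unbiased) usage; values well below 1
#'   give the pronounced species-level codon bias — rare synonyms with RSCU
#'   far below 1 — that ramp detection relies on.
#' @param slow_prefix,speed_factor ramp-planting defaults used by
#'   [plant_ramp()]: prefix length in codons and target speed multiplier in
#'   \[0, 1\] (1 = leave codons untouched, 0 = slowest synonym).
#' @param terminal_stop append a stop codon to every gene (default `TRUE`).
#' @param seed integer random seed (mandatory: all generators are
#'   seed-deterministic).
#' @return A list of class `cub_sim_config`.
#' @export
simulation_config <- function(n_populations = 3L, n_individuals = 40L,
                              n_genes = 50L, n_codons = 300L,
                              concentration = 1, polymorphism = 0.01,
                              base_bias = 0.35,
                              slow_prefix = 9L, speed_factor = 0.05,
                              terminal_stop = TRUE, seed = 1L) {
  stopifnot(n_populations >= 1, n_individuals >= 1, n_genes >= 1,
            n_codons >= 1, concentration > 0,
            polymorphism >= 0, polymorphism <= 1,
            base_bias > 0, base_bias <= 1, slow_prefix >= 1,
            speed_factor >= 0, speed_factor <= 1, is.numeric(seed))
  structure(list(
    n_populations = as.integer(n_populations),
    n_individuals = as.integer(n_individuals),
    n_genes = as.integer(n_genes), n_codons = as.integer(n_codons),
    concentration = concentration, polymorphism = polymorphism,
    base_bias = base_bias,
    slow_prefix = as.integer(slow_prefix),
    speed_factor = speed_factor, terminal_stop = isTRUE(terminal_stop),
    seed = as.integer(seed)
  ), class = "cub_sim_config")
}

# draw one codon per amino acid from a single population's profile tibble
draw_from_profile <- function(aa_vec, prof) {
  out <- character(length(aa_vec))
  for (aa in unique(aa_vec)) {
    idx <- which(aa_vec == aa)
    fam <- prof[prof$aa == aa, ]
    out[idx] <- if (nrow(fam) == 1L) fam$codon else {
      fam$codon[sample.int(nrow(fam), length(idx), replace = TRUE,
                           prob = fam$prob)]
    }
  }
  out
}

rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))  # degenerate tiny-alpha draw
  x / sum(x)
}

#' Sample per-population synonymous-codon preference profiles
#'
#' For every amino acid (and the stop "family"), each population's
#' synonymous-codon probability vector is drawn from a Dirichlet
#' distribution centred on a shared base profile with concentration
#' `config$concentration * family size * base`, so the expected profile is
#' the base profile at any concentration and all populations coincide with
#' it as the concentration grows. The base profile itself is biased: codons
#' of each family (in lexicographic order) get geometrically decaying
#' weights with ratio `config$base_bias`, emulating species-level codon
#' usage bias.
#'
#' @param config a [simulation_config()].
#' @return A tibble with columns `population`, `aa`, `codon`, `prob`;
#'   probabilities sum to 1 within each (population, amino acid).
#' @export
simulate_profiles <- function(config) {
  stopifnot(inherits(config, "cub_sim_config"))
  set.seed(config$seed)
  fams <- genetic_code()$families
  pops <- sprintf("POP%d", seq_len(config$n_populations))
  rows <- lapply(pops, function(pop) {
    per_fam <- lapply(names(fams), function(aa) {
      fam <- fams[[aa]]
      base <- config$base_bias^(seq_along(fam) - 1)
      base <- base / sum(base)
      p <- if (length(fam) == 1L) 1 else {
        rdirichlet1(config$concentration * length(fam) * base)
      }
      tibble(population = pop, aa = aa, codon = fam, prob = p)
    })
    bind_rows(per_fam)
  })
  bind_rows(rows)
}

#' Generate a synthetic cohort of coding sequences
#'
#' Draws one amino-acid sequence per gene (shared by the whole cohort, so
#' every codon difference between individuals is synonymous). Each
#' population then draws a consensus codon sequence per gene from its
#' preference profile, and each individual carries that consensus except at
#' a sparse set of positions (per-codon probability `polymorphism`) where
#' its codon is resampled from the population profile — mimicking cohorts of
#' resequenced individuals, which differ from a shared sequence only at
#' (synonymous) variant sites. Genes start with Met and optionally end with
#' a stop codon drawn from the population's stop preference.
#'
#' @param config a [simulation_config()].
#' @param profiles optional output of [simulate_profiles()]; generated from
#'   `config` when omitted.
#' @return A list with `cds` (coding-sequence tibble; sample ids
#'   `POP<i>_S<j>`), `assignment` (sample_id / population / superpopulation)
#'   and `profiles`.
#' @export
simulate_cohort <- function(config, profiles = NULL) {
  stopifnot(inherits(config, "cub_sim_config"))
  if (is.null(profiles)) profiles <- simulate_profiles(config)
  set.seed(config$seed + 1L)
  aas <- amino_acids()
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  # shared amino-acid sequence per gene; position 1 is Met
  aa_seq <- lapply(genes, function(g) {
    s <- c("M", sample(aas, config$n_codons - 1L, replace = TRUE))
    if (config$terminal_stop) c(s, "*") else s
  })
  names(aa_seq) <- genes
  pops <- sprintf("POP%d", seq_len(config$n_populations))
  samples <- as.vector(t(outer(pops, sprintf("S%02d", seq_len(config$n_individuals)),
                               paste, sep = "_")))
  sample_pop <- rep(pops, each = config$n_individuals)
  aa_flat <- unlist(aa_seq, use.names = FALSE)  # all genes concatenated
  gene_of_pos <- rep.int(genes, lengths(aa_seq))
  # per-population consensus codons, then sparse per-individual resampling
  consensus <- lapply(pops, function(pop) {
    draw_from_profile(aa_flat, profiles[profiles$population == pop, ])
  })
  names(consensus) <- pops
  rows <- lapply(seq_along(samples), function(i) {
    pop <- sample_pop[i]
    codons <- consensus[[pop]]
    hit <- which(stats::runif(length(codons)) < config$polymorphism)
    if (length(hit) > 0) {
      codons[hit] <- draw_from_profile(aa_flat[hit],
                                       profiles[profiles$population == pop, ])
    }
    tibble(sample_id = samples[i], gene_id = genes,
           seq = vapply(split(codons, factor(gene_of_pos, levels = genes)),
                        paste, character(1), collapse = ""))
  })
  cds <- bind_rows(rows)
  cds <- cds_table(sample_id = cds$sample_id, gene_id = cds$gene_id,
                   seq = cds$seq)
  assignment <- tibble(sample_id = samples, population = sample_pop,
                       superpopulation = sample_pop)
  list(cds = cds, assignment = assignment, profiles = profiles)
}

#' Plant a ramp sequence at the start of a gene
#'
#' Replaces each codon in the leading `slow_prefix` codons by the synonymous
#' codon whose reference RSCU is closest to `speed_factor` times the current
#' codon's RSCU. `speed_factor = 1` leaves the gene unchanged;
#' `speed_factor = 0` substitutes every prefix codon by its slowest
#' (lowest-RSCU) synonym.
#'
#' @param seq a nucleotide sequence (single string, length a multiple of 3).
#' @param reference named RSCU vector (see [rscu_reference()]).
#' @param slow_prefix prefix length in codons.
#' @param speed_factor target speed multiplier in \[0, 1\].
#' @return The modified nucleotide sequence.
#' @export
plant_ramp <- function(seq, reference, slow_prefix = 9L, speed_factor = 0.05) {
  stopifnot(nchar(seq) %% 3 == 0, speed_factor >= 0, speed_factor <= 1)
  n <- nchar(seq) %/% 3
  if (slow_prefix >= n) abort("`slow_prefix` must be shorter than the gene")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  code <- genetic_code()$codon_to_aa
  fams <- genetic_code()$families
  for (i in seq_len(slow_prefix)) {
    aa <- code[[codons[i]]]
    if (aa == "*") next
    fam <- fams[[aa]]
    r <- reference[fam]
    ok <- !is.na(r) & r > 0  # a zero-RSCU codon would have undefined speed
    if (!any(ok)) next
    fam <- fam[ok]; r <- r[ok]
    target <- speed_factor * reference[[codons[i]]]
    codons[i] <- fam[which.min(abs(r - target))]
  }
  paste(codons, collapse = "")
}

#' Simulate a per-population genotype table
#'
#' Draws diploid genotypes (alternate-allele dosage 0/1/2) as Binomial(2, p)
#' with a population-specific allele frequency per variant, to exercise the
#' minor-allele-frequency and Tukey comparisons on known truth.
#'
#' @param freqs a data frame with columns `population`, `variant_id`, `p`
#'   (alternate-allele frequency in \[0, 1\]).
#' @param n_per_population samples per population.
#' @param seed integer seed.
#' @return A list with `genotypes` (`sample_id`, `variant_id`, `genotype`)
#'   and `assignment`.
#' @export
simulate_genotypes <- function(freqs, n_per_population = 100L, seed = 1L) {
  stopifnot(all(c("population", "variant_id", "p") %in% names(freqs)),
            all(freqs$p >= 0 & freqs$p <= 1))
  set.seed(seed)
  pops <- unique(freqs$population)
  samples <- tibble(
    sample_id = as.vector(t(outer(pops, sprintf("S%03d", seq_len(n_per_population)),
                                  paste, sep = "_"))),
    population = rep(pops, each = n_per_population)
  )
  gt <- inner_join(samples, freqs, by = "population",
                   relationship = "many-to-many")
  gt$genotype <- rbinom(nrow(gt), 2L, gt$p)
  list(
    genotypes = gt[, c("sample_id", "variant_id", "genotype")],
    assignment = tibble(sample_id = samples$sample_id,
                        population = samples$population,
                        superpopulation = samples$population)
  )
}
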