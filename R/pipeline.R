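#' Run the full codon-usage pipeline and write its outputs
#'
#' Metrics, then (optionally) population statistics and alignment-free
#' clustering, with every stage written to CSV under `out_dir`. Inputs come
#' either from a FASTA + assignment TSV on disk or from the synthetic
#' simulator when `simulate = TRUE`.
#'
#' @param fasta path to a CDS FASTA (headers `sample|gene|isoform|allele`),
#'   or `NULL` when `simulate = TRUE`.
#' @param assignment path to a sample-population TSV, or `NULL` when
#'   simulating.
#' @param out_dir output directory (created if absent).
#' @param simulate generate the inputs with [simulate_cohort()] instead of
#'   reading them.
#' @param sim_config a [simulation_config()] used when `simulate = TRUE`.
#' @param window ribosomal window in codons.
#' @param mode motif mode for clustering, `"pairing"` or `"aversion"`.
#' @param stages character vector among `"metrics"`, `"ramp"`, `"stats"`,
#'   `"cluster"`; metrics always run.
#' @param alpha family-wise error rate for the stats stage (Bonferroni
#'   corrected over the tests actually run).
#' @param leading_fraction,outlier_z ramp-detection parameters (see
#'   [ramp_scan()]).
#' @return Invisibly, a named list of the paths written plus the in-memory
#'   results (`metrics`, `cluster`, `stats`).
#' @export
run_pipeline <- function(fasta = NULL, assignment = NULL, out_dir = ".",
                         simulate = FALSE, sim_config = simulation_config(),
                         window = 9L, mode = c("pairing", "aversion"),
                         stages = c("metrics", "ramp", "stats", "cluster"),
                         alpha = 0.05, leading_fraction = 0.01, outlier_z = 2) {
  mode <- match.arg(mode)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  if (simulate) {
    sim <- simulate_cohort(sim_config)
    cds <- sim$cds
    assign_tab <- sim$assignment
    readr::write_tsv(assign_tab, file.path(out_dir, "assignment.tsv"))
    write_cds_fasta(cds, file.path(out_dir, "cohort.fasta"))
    jsonlite::write_json(unclass(sim_config), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$fasta <- file.path(out_dir, "cohort.fasta")
    paths$assignment <- file.path(out_dir, "assignment.tsv")
    paths$config <- file.path(out_dir, "config.json")
  } else {
    if (is.null(fasta)) abort("either `fasta` or `simulate = TRUE` is required")
    cds <- read_cds_fasta(fasta)
    assign_tab <- if (!is.null(assignment)) read_population_assignment(assignment) else NULL
  }
  inform(paste0("pipeline: ", nrow(cds), " coding sequences from ",
                length(unique(cds$sample_id)), " samples"))

  freq <- codon_counts(cds)
  out <- list(metrics = list(frequency = freq))
  wr <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(x, p)
    inform(paste0("wrote ", nrow(x), " rows: ", p))
    p
  }
  paths$frequency <- wr(freq, "frequency")
  aver <- codon_aversion(cds)
  paths$aversion <- wr(select(aver, -"averted"), "aversion")
  pair <- codon_pairing(cds, window = window)
  paths$pairing <- wr(pair, "pairing")
  cot <- cotrna_pairing(cds, window = window)
  paths$cotrna <- wr(cot, "cotrna")
  comp <- nucleotide_composition(cds)
  paths$composition <- wr(comp, "composition")
  out$metrics <- list(frequency = freq, aversion = aver, pairing = pair,
                      cotrna = cot, composition = comp)

  if ("ramp" %in% stages) {
    reference <- rscu_reference(cds)
    ramps <- detect_ramps(cds, reference, window = window,
                          leading_fraction = leading_fraction,
                          outlier_z = outlier_z)
    paths$ramp <- wr(ramps, "ramp")
    out$metrics$ramp <- ramps
  }

  if ("stats" %in% stages && !is.null(assign_tab)) {
    long <- tidyr::pivot_longer(pair, all_of(sense_codons()),
                                names_to = "codon", values_to = "value") |>
      inner_join(assign_tab[, c("sample_id", "superpopulation")], by = "sample_id")
    per_test <- long |>
      group_by(.data$gene_id, .data$codon) |>
      filter(stats::var(.data$value) > 0) |>  # constant codons carry no signal
      dplyr::group_modify(~ pop_anova(.x, value, superpopulation)) |>
      ungroup()
    thr <- bonferroni_threshold(alpha, nrow(per_test))
    per_test$significant <- per_test$p_value < thr
    out$stats <- per_test
    paths$stats <- wr(per_test, "stats_anova")
  }

  if ("cluster" %in% stages && !is.null(assign_tab)) {
    cl <- cluster_populations(cds, assign_tab, mode = mode, window = window)
    paths$cluster_report <- wr(cl$report, "cluster_report")
    ape::write.tree(cl$tree, file.path(out_dir, "tree.nwk"))
    paths$tree <- file.path(out_dir, "tree.nwk")
    d <- as.data.frame(cl$dist)
    readr::write_csv(bind_cols(tibble(sample_id = rownames(cl$dist)), d),
                     file.path(out_dir, "distances.csv"))
    paths$distances <- file.path(out_dir, "distances.csv")
    out$cluster <- cl
  }
  invisible(c(paths, out))
}
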