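#' Per-gene codon motifs for alignment-free comparison
#'
#' A gene's motif is the sorted, duplicate-free tuple of codons that either
#' pair at least once within the ribosomal window (`mode = "pairing"`,
#' identical pairing; sense codons only) or are completely absent from the
#' gene (`mode = "aversion"`, all 64 codons). Motifs are the unit of
#' comparison for alignment-free population identification.
#'
#' @param cds a coding-sequence tibble.
#' @param mode `"pairing"` or `"aversion"`.
#' @param window ribosomal window for pairing mode (default 9).
#' @param include_cotrna in pairing mode, also add amino acids that co-tRNA
#'   pair at least once, tagged `aa:<letter>` to keep the namespaces
#'   distinct (default `FALSE`; identical pairing only).
#' @return A tibble with the identifier columns and a `motif` column
#'   (codons joined with `|`; possibly the empty string).
#' @export
gene_motifs <- function(cds, mode = c("pairing", "aversion"), window = 9L,
                        include_cotrna = FALSE) {
  mode <- match.arg(mode)
  if (mode == "aversion") {
    return(codon_aversion(cds, include_stops = TRUE)[, c(id_cols(), "motif")])
  }
  pairing <- codon_pairing(cds, window = window)
  mat <- as.matrix(pairing[, sense_codons()]) > 0L
  motif <- apply(mat, 1L, function(r) paste(sense_codons()[r], collapse = "|"))
  out <- pairing[, id_cols()]
  out$motif <- motif
  if (include_cotrna) {
    co <- cotrna_pairing(cds, window = window)
    comat <- as.matrix(co[, amino_acids()]) > 0L
    extra <- apply(comat, 1L, function(r) {
      paste(paste0("aa:", amino_acids()[r]), collapse = "|")
    })
    out$motif <- ifelse(extra == "", out$motif,
                        ifelse(out$motif == "", extra,
                               paste(out$motif, extra, sep = "|")))
  }
  out
}

#' Collapse per-gene motifs into one motif set per genome
#'
#' Gene names are discarded: identical motifs arising from different genes
#' collapse to a single set element.
#'
#' @param motifs output of [gene_motifs()].
#' @return A tibble with `sample_id` and a `motifs` list-column of unique
#'   motif strings.
#' @export
genome_motif_sets <- function(motifs) {
  motifs |>
    group_by(.data$sample_id) |>
    summarise(motifs = list(unique(.data$motif)), .groups = "drop")
}

#' Jaccard distance matrix between genome motif sets
#'
#' d(A, B) = 1 - |A intersect B| / |A union B|: the set-union-normalised
#' dissimilarity between two genomes' motif collections.
#'
#' @param sets output of [genome_motif_sets()].
#' @return A symmetric numeric matrix with zero diagonal, entries in
#'   \[0, 1\], dimnames = sample ids.
#' @export
motif_distance_matrix <- function(sets) {
  ids <- sets$sample_id
  universe <- unique(unlist(sets$motifs, use.names = FALSE))
  if (length(universe) == 0L) abort("motif sets are all empty; distance undefined")
  inc <- Matrix::sparseMatrix(
    i = rep.int(seq_along(ids), lengths(sets$motifs)),
    j = match(unlist(sets$motifs, use.names = FALSE), universe),
    x = 1, dims = c(length(ids), length(universe))
  )
  inter <- as.matrix(Matrix::tcrossprod(inc))
  sizes <- Matrix::rowSums(inc)
  union <- outer(sizes, sizes, "+") - inter
  if (any(union == 0)) abort("two genomes have empty motif sets; distance undefined")
  d <- 1 - inter / union
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou–Nei agglomeration (via \pkg{ape}). Negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with a message.
#'
#' @param d symmetric numeric matrix (zero diagonal, non-negative entries)
#'   with sample ids as dimnames, or a [stats::dist] object.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) abort("distance matrix must be symmetric")
  if (any(d < 0)) abort("distance matrix must be non-negative")
  if (any(diag(d) != 0)) abort("distance matrix must have a zero diagonal")
  if (nrow(d) < 3L) abort("neighbor-joining needs >= 3 samples")
  tree <- ape::nj(as.dist(d))
  if (any(tree$edge.length < 0)) {
    inform(paste0(sum(tree$edge.length < 0),
                  " negative NJ branch length(s) clamped to 0"))
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Count same-population clusters on a tree
#'
#' Roots the tree (midpoint of the longest path by default) and counts, for
#' each population, the maximal clades consisting solely of its individuals
#' — the "largest discrete groupings" uninterrupted by any other population.
#' Every individual belongs to exactly one such cluster; a population whose
#' members form a single clade scores 1 cluster.
#'
#' @param tree a `phylo` tree whose tip labels are sample ids.
#' @param assignment a population assignment table with `sample_id` and
#'   `superpopulation` columns covering every tip.
#' @param root `"midpoint"` (default) to midpoint-root unrooted input, or
#'   `"asis"` to keep the tree's current (possibly arbitrary) rooting.
#' @return A tibble with one row per population: `population`,
#'   `n_individuals`, `n_clusters`, `percent_accuracy` (see
#'   [percent_predictive_accuracy()]).
#' @export
count_population_clusters <- function(tree, assignment, root = c("midpoint", "asis")) {
  root <- match.arg(root)
  missing <- setdiff(tree$tip.label, assignment$sample_id)
  if (length(missing) > 0) {
    abort(paste0("tree tips without population assignment: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  if (root == "midpoint") tree <- phangorn::midpoint(tree)
  ntip <- length(tree$tip.label)
  pops <- assignment$superpopulation[match(tree$tip.label, assignment$sample_id)]
  # node_pop[v]: the population if all tips under v share it, else NA
  node_pop <- c(pops, rep(NA_character_, tree$Nnode))
  mixed <- c(rep(FALSE, ntip), rep(FALSE, tree$Nnode))
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; ch <- edge[k, 2L]
    if (mixed[ch]) {
      mixed[p] <- TRUE
    } else if (is.na(node_pop[p]) && !mixed[p]) {
      node_pop[p] <- node_pop[ch]
    } else if (!identical(node_pop[p], node_pop[ch])) {
      mixed[p] <- TRUE
      node_pop[p] <- NA_character_
    }
  }
  # a pure node is a cluster root iff its parent is mixed (or it is the root)
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[edge[, 2L]] <- edge[, 1L]
  pure <- which(!mixed & !is.na(node_pop))
  is_cluster <- vapply(pure, function(v) {
    is.na(parent[v]) || mixed[parent[v]]
  }, logical(1))
  clusters <- table(factor(node_pop[pure[is_cluster]], levels = sort(unique(pops))))
  sizes <- table(factor(pops, levels = sort(unique(pops))))
  tibble(
    population = names(sizes),
    n_individuals = as.integer(sizes),
    n_clusters = as.integer(clusters),
    percent_accuracy = percent_predictive_accuracy(as.integer(clusters),
                                                   as.integer(sizes))
  )
}

#' Percent predictive accuracy of population clustering
#'
#' Scores how completely a population forms a single clade on a recovered
#' tree: 100 * (1 - (n_clusters - 1) / n_individuals). One cluster scores
#' 100; every individual in its own cluster scores 100 / n.
#'
#' @param n_clusters number of same-population clusters (clades), between 1
#'   and `n_individuals`. Vectorised.
#' @param n_individuals number of individuals in the population.
#' @return Percent accuracy in (0, 100].
#' @examples
#' percent_predictive_accuracy(9, 661)   # 98.7897
#' percent_predictive_accuracy(26, 504)  # 95.0397
#' @export
percent_predictive_accuracy <- function(n_clusters, n_individuals) {
  if (any(n_clusters < 1 | n_clusters > n_individuals)) {
    abort("need 1 <= n_clusters <= n_individuals")
  }
  100 * (1 - (n_clusters - 1) / n_individuals)
}

#' Alignment-free population identification
#'
#' End-to-end pipeline: per-gene motifs (codon pairing or codon aversion)
#' are collapsed into one motif set per genome, Jaccard distances between
#' genomes feed neighbor-joining, the tree is midpoint-rooted, and
#' same-population clades are counted and scored with percent predictive
#' accuracy.
#'
#' @inheritParams gene_motifs
#' @param assignment a population assignment table (see
#'   [read_population_assignment()]).
#' @param reference_cds optional single-row coding-sequence tibble added as
#'   an extra leaf (e.g. a reference genome); it takes population label
#'   `"reference"` and may split otherwise-pure clades.
#' @return An object of class `cub_clustering`: a list with the per-
#'   population report (`report`), the NJ `tree`, the distance matrix
#'   (`dist`) and the motif `mode`. Use [generics::tidy()] for the report
#'   tibble and [ggplot2::autoplot()] for an accuracy chart.
#' @export
cluster_populations <- function(cds, assignment, mode = c("pairing", "aversion"),
                                window = 9L, include_cotrna = FALSE,
                                reference_cds = NULL) {
  mode <- match.arg(mode)
  if (!is.null(reference_cds)) {
    reference_cds$sample_id <- "reference"
    cds <- bind_rows(cds, reference_cds)
    assignment <- bind_rows(
      assignment,
      tibble(sample_id = "reference", population = "reference",
             superpopulation = "reference")
    )
  }
  motifs <- gene_motifs(cds, mode = mode, window = window,
                        include_cotrna = include_cotrna)
  sets <- genome_motif_sets(motifs)
  d <- motif_distance_matrix(sets)
  tree <- nj_tree(d)
  report <- count_population_clusters(tree, assignment)
  structure(list(report = report, tree = tree, dist = d, mode = mode),
            class = "cub_clustering")
}

#' @export
print.cub_clustering <- function(x, ...) {
  cat("<cub_clustering>", x$mode, "motifs,", nrow(x$dist), "genomes\n")
  print(x$report)
  invisible(x)
}

#' @export
tidy.cub_clustering <- function(x, ...) x$report

#' @export
glance.cub_clustering <- function(x, ...) {
  tibble(
    mode = x$mode, n_samples = nrow(x$dist),
    n_populations = nrow(x$report),
    mean_accuracy = mean(x$report$percent_accuracy),
    min_accuracy = min(x$report$percent_accuracy)
  )
}

#' @describeIn cluster_populations bar chart of percent predictive accuracy
#'   per population.
#' @param object a `cub_clustering` object.
#' @param ... unused.
#' @export
autoplot.cub_clustering <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$population, y = .data$percent_accuracy)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_clusters), vjust = -0.4) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "percent predictive accuracy",
                  subtitle = paste0(object$mode, " motifs; label = cluster count"))
}
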