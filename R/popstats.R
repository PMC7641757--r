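#' One-way ANOVA on grouped metric values
#'
#' Classical fixed-effects one-way analysis of variance (equal-variance F
#' test) of a numeric metric against a grouping factor, e.g. per-individual
#' codon-pairing counts against superpopulation.
#'
#' @param data a data frame with one row per individual.
#' @param value unquoted column holding the metric value.
#' @param group unquoted column holding the group label.
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`, `n_groups`, `n_total`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b"), each = 5), y = c(1:5, 3:7))
#' pop_anova(d, y, g)
#' @export
pop_anova <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  sizes <- table(g)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    abort("one-way ANOVA needs >= 2 groups with >= 2 values each")
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(fit$statistic),
    df_between = unname(fit$parameter[1L]),
    df_within = unname(fit$parameter[2L]),
    p_value = unname(fit$p.value),
    n_groups = length(sizes), n_total = length(y)
  )
}

#' All pairwise two-sample t-tests between groups
#'
#' One Student's (pooled-variance) t-test per unordered pair of groups, with
#' the pooled-sd Cohen's d effect size attached; Welch's unequal-variance
#' test is available behind `var_equal = FALSE`. Intended as the follow-up
#' to a significant one-way ANOVA.
#'
#' @inheritParams pop_anova
#' @param threshold significance threshold applied to each pair (e.g. a
#'   Bonferroni-corrected level from [bonferroni_threshold()]).
#' @param var_equal pooled-variance Student's test (default) or Welch.
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `statistic`, `p_value`, `cohens_d`, `significant`.
#' @export
pairwise_t_tests <- function(data, value, group, threshold = 0.05,
                             var_equal = TRUE) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  levs <- levels(g)
  if (length(levs) < 2L) abort("need >= 2 groups")
  pairs <- combn(levs, 2L)
  res <- apply(pairs, 2L, function(p) {
    a <- y[g == p[1L]]; b <- y[g == p[2L]]
    if (length(a) < 2L || length(b) < 2L) {
      abort(paste0("group with < 2 values: ", p[1L], " vs ", p[2L]))
    }
    tt <- if (sd(c(a - mean(a), b - mean(b))) == 0) {
      list(statistic = 0, p.value = 1)  # identical constant groups
    } else {
      t.test(a, b, var.equal = var_equal)
    }
    tibble(group1 = p[1L], group2 = p[2L],
           statistic = unname(tt$statistic), p_value = unname(tt$p.value),
           cohens_d = cohens_d(a, b))
  })
  out <- bind_rows(res)
  out$significant <- out$p_value < threshold
  out
}

#' Cohen's d effect size (pooled standard deviation)
#'
#' (mean(a) - mean(b)) / s_pooled with the unbiased pooled variance
#' ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2). Undefined (NA) when
#' the pooled variance is zero.
#'
#' @param a,b numeric vectors of per-individual values.
#' @return A single numeric value; antisymmetric in its arguments.
#' @examples
#' cohens_d(c(2, 4), c(1, 3))  # mean diff 1 over pooled sd sqrt(2)
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) abort("cohens_d() needs >= 2 values per group")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) return(NA_real_)
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Number of pairwise tests in a full metric scan
#'
#' One test per gene, per codon, per unordered pair of populations:
#' n_genes * n_codons * choose(n_groups, 2).
#'
#' @param n_genes,n_codons,n_groups positive integers.
#' @return The total number of pairwise tests.
#' @examples
#' count_pairwise_tests(17634, 61, 5)  # 10756740
#' @export
count_pairwise_tests <- function(n_genes, n_codons, n_groups) {
  stopifnot(n_genes >= 1, n_codons >= 1, n_groups >= 2)
  n_genes * n_codons * choose(n_groups, 2)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests in the family, >= 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 15)  # 0.003333...
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1)
  alpha / n_tests
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based pairwise comparisons after a one-way ANOVA,
#' controlling the family-wise error rate across all group pairs.
#'
#' @inheritParams pop_anova
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `estimate` (difference in means), `conf_low`, `conf_high`,
#'   `p_value` (Tukey-adjusted).
#' @export
pop_tukey <- function(data, value, group, conf_level = 0.95) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  keep <- !is.na(y) & !is.na(g)
  d <- data.frame(y = y[keep], g = droplevels(g[keep]))
  if (nlevels(d$g) < 2L) abort("need >= 2 groups")
  hsd <- TukeyHSD(aov(y ~ g, data = d), conf.level = conf_level)$g
  nm <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tibble(
    group1 = vapply(nm, `[`, character(1), 1L),
    group2 = vapply(nm, `[`, character(1), 2L),
    estimate = hsd[, "diff"], conf_low = hsd[, "lwr"],
    conf_high = hsd[, "upr"], p_value = hsd[, "p adj"]
  )
}

#' Per-population minor-allele frequencies
#'
#' The minor allele is defined on the pooled cohort: if the alternate
#' allele's pooled frequency exceeds 0.5, the reference allele is taken as
#' minor. Per-population frequencies of that pooled-minor allele may then
#' exceed 0.5. Missing genotypes reduce the per-group denominator.
#'
#' @param genotypes a data frame with columns `sample_id`, `variant_id` and
#'   `genotype` (diploid alternate-allele dosage 0/1/2; NA allowed).
#' @param assignment a population assignment (see
#'   [read_population_assignment()]); grouping uses its `superpopulation`
#'   column.
#' @return A tibble with one row per (variant, population): `variant_id`,
#'   `population`, `n` (genotyped samples), `maf`, and `minor_allele`
#'   (`"alt"` or `"ref"`, constant within a variant).
#' @export
minor_allele_frequency <- function(genotypes, assignment) {
  stopifnot(all(c("sample_id", "variant_id", "genotype") %in% names(genotypes)))
  stopifnot(all(genotypes$genotype %in% c(0L, 1L, 2L, NA)))
  gt <- inner_join(genotypes, assignment[, c("sample_id", "superpopulation")],
                   by = "sample_id")
  pooled <- gt |>
    filter(!is.na(.data$genotype)) |>
    group_by(.data$variant_id) |>
    summarise(alt_pooled = sum(.data$genotype) / (2 * n()), .groups = "drop") |>
    mutate(minor_allele = ifelse(.data$alt_pooled > 0.5, "ref", "alt"))
  gt |>
    filter(!is.na(.data$genotype)) |>
    group_by(.data$variant_id, population = .data$superpopulation) |>
    summarise(n = n(), alt_freq = sum(.data$genotype) / (2 * n()),
              .groups = "drop") |>
    left_join(pooled, by = "variant_id") |>
    mutate(maf = ifelse(.data$minor_allele == "alt",
                        .data$alt_freq, 1 - .data$alt_freq)) |>
    select("variant_id", "population", "n", "maf", "minor_allele")
}
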