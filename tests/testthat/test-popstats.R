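test_that("one-way ANOVA matches a hand-computed sum-of-squares table", {
  # 3 groups; SS decomposition worked out independently below
  d <- data.frame(
    g = rep(c("a", "b", "c"), each = 4),
    y = c(1, 2, 3, 4, 2, 4, 4, 6, 5, 6, 7, 8)
  )
  means <- tapply(d$y, d$g, mean)
  grand <- mean(d$y)
  ss_between <- sum(4 * (means - grand)^2)
  ss_within <- sum((d$y - means[d$g])^2)
  f_manual <- (ss_between / 2) / (ss_within / 9)
  res <- pop_anova(d, y, g)
  expect_equal(res$statistic, f_manual, tolerance = 1e-12)
  expect_equal(res$p_value, pf(f_manual, 2, 9, lower.tail = FALSE))
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 9)
})

test_that("ANOVA F equals zero for identical groups and t-squared for two groups", {
  d0 <- data.frame(g = rep(c("a", "b"), each = 3), y = rep(5, 6))
  # all values equal: between-group variance is 0
  expect_equal(suppressWarnings(pop_anova(d0, y, g)$statistic), NaN)

  d1 <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 5))
  f <- pop_anova(d1, y, g)$statistic
  t <- t.test(y ~ g, data = d1, var.equal = TRUE)$statistic
  expect_equal(f, unname(t)^2, tolerance = 1e-9)

  set.seed(21)
  for (rep in 1:10) {
    d <- data.frame(g = rep(c("a", "b"), each = 8), y = rnorm(16))
    expect_equal(pop_anova(d, y, g)$statistic,
                 unname(t.test(y ~ g, data = d, var.equal = TRUE)$statistic)^2,
                 tolerance = 1e-9)
  }
  expect_error(pop_anova(data.frame(g = "a", y = 1), y, g), ">= 2")
})

test_that("pairwise t-tests cover every group pair and attach Cohen's d", {
  set.seed(31)
  d <- data.frame(g = rep(letters[1:4], each = 10), y = rnorm(40))
  res <- pairwise_t_tests(d, y, g)
  expect_equal(nrow(res), choose(4, 2))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$significant, res$p_value < 0.05)

  # identical groups: p ~ 1, d = 0
  d2 <- data.frame(g = rep(c("a", "b"), each = 5), y = rep(c(1, 2, 3, 4, 5), 2))
  res2 <- pairwise_t_tests(d2, y, g)
  expect_equal(res2$p_value, 1)
  expect_equal(res2$cohens_d, 0)

  # planted shift of one pooled sd at n = 100/group
  set.seed(32)
  d3 <- data.frame(g = rep(c("a", "b"), each = 100),
                   y = c(rnorm(100), rnorm(100) + 1))
  res3 <- pairwise_t_tests(d3, y, g)
  expect_true(res3$significant)
  expect_equal(abs(res3$cohens_d), 1, tolerance = 0.25)
})

test_that("Cohen's d is definitional, antisymmetric and missing on zero variance", {
  expect_equal(cohens_d(c(1, 2, 3), c(1, 2, 3)), 0)
  # textbook pooled-sd hand calculation
  a <- c(2, 4, 6); b <- c(1, 3, 5)
  sp <- sqrt(((2) * var(a) + (2) * var(b)) / 4)
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / sp)
  # difference of one pooled sd -> d = 1 (both groups have sd sqrt(2))
  expect_equal(cohens_d(c(0, 2) + sqrt(2), c(0, 2)), 1, tolerance = 1e-9)
  expect_equal(cohens_d(a, b), -cohens_d(b, a))
  expect_true(is.na(cohens_d(c(1, 1), c(1, 1))))
})

test_that("pairwise test counting matches an explicit triple loop", {
  expect_equal(count_pairwise_tests(17634, 61, 5), 10756740)
  expect_equal(count_pairwise_tests(1, 1, 2), 1)
  set.seed(41)
  for (rep in 1:10) {
    ng <- sample(1:5, 1); nc <- sample(1:6, 1); np <- sample(2:6, 1)
    tally <- 0
    for (g in seq_len(ng)) for (cc in seq_len(nc)) {
      for (i in seq_len(np - 1)) for (j in (i + 1):np) tally <- tally + 1
    }
    expect_equal(count_pairwise_tests(ng, nc, np), tally)
  }
})

test_that("Bonferroni threshold is alpha/n and strictly decreasing in n", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 15), 0.05 / 15)
  ns <- c(1, 2, 10, 100, 1e6)
  thr <- vapply(ns, bonferroni_threshold, numeric(1), alpha = 0.05)
  expect_true(all(diff(thr) < 0))
  expect_error(bonferroni_threshold(1.5, 10))
})

test_that("Tukey HSD flags only a strongly shifted group and agrees with the t-test on two groups", {
  d0 <- data.frame(g = rep(c("a", "b", "c"), each = 6),
                   y = rep(c(1, 2, 3, 1, 2, 3), 3))
  expect_true(all(pop_tukey(d0, y, g)$p_value > 0.99))

  set.seed(51)
  d <- data.frame(g = rep(c("a", "b", "c", "d"), each = 30),
                  y = c(rnorm(30), rnorm(30), rnorm(30), rnorm(30) + 3))
  res <- pop_tukey(d, y, g)
  with_d <- res$group1 == "d" | res$group2 == "d"
  expect_true(all(res$p_value[with_d] < 0.001))
  expect_true(all(res$p_value[!with_d] > 0.05))

  # two groups: Tukey and the pooled t-test must agree in decision
  set.seed(52)
  for (rep in 1:10) {
    shift <- sample(c(0, 1.5), 1)
    d2 <- data.frame(g = rep(c("a", "b"), each = 15),
                     y = c(rnorm(15), rnorm(15) + shift))
    tk <- pop_tukey(d2, y, g)$p_value
    tt <- pairwise_t_tests(d2, y, g)$p_value
    expect_equal(tk < 0.05, tt < 0.05)
    expect_equal(tk, tt, tolerance = 1e-6)
  }
})

test_that("ANOVA type-I error is calibrated at the nominal level under the null", {
  set.seed(61)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    d <- data.frame(g = rep(letters[1:5], each = 20), y = rnorm(100))
    pop_anova(d, y, g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("minor-allele frequencies are folded on the pooled cohort", {
  asg <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                        population = c("A", "A", "B", "B"),
                        superpopulation = population)
  # all homozygous reference
  gt0 <- tidyr::expand_grid(sample_id = asg$sample_id, variant_id = "v1")
  gt0$genotype <- 0L
  expect_equal(minor_allele_frequency(gt0, asg)$maf, c(0, 0))

  # one het among 2 diploids per group
  gt1 <- gt0
  gt1$genotype <- c(1L, 0L, 0L, 0L)
  maf <- minor_allele_frequency(gt1, asg)
  expect_equal(maf$maf[maf$population == "A"], 0.25)
  expect_equal(maf$maf[maf$population == "B"], 0)

  # pooled alt frequency > 0.5: minor allele is ref, group MAF may exceed 0.5
  gt2 <- gt0
  gt2$genotype <- c(2L, 2L, 2L, 0L)
  maf2 <- minor_allele_frequency(gt2, asg)
  expect_equal(unique(maf2$minor_allele), "ref")
  expect_equal(maf2$maf[maf2$population == "A"], 0)
  expect_equal(maf2$maf[maf2$population == "B"], 0.5)

  # random table matches a direct tally; missing genotypes shrink denominators
  set.seed(71)
  gt3 <- tidyr::expand_grid(sample_id = asg$sample_id,
                            variant_id = c("v1", "v2"))
  gt3$genotype <- sample(c(0L, 1L, 2L, NA), nrow(gt3), replace = TRUE)
  maf3 <- minor_allele_frequency(gt3, asg)
  for (k in seq_len(nrow(maf3))) {
    rows <- gt3$variant_id == maf3$variant_id[k] &
      gt3$sample_id %in% asg$sample_id[asg$population == maf3$population[k]] &
      !is.na(gt3$genotype)
    alt <- sum(gt3$genotype[rows]) / (2 * sum(rows))
    pooled_rows <- gt3$variant_id == maf3$variant_id[k] & !is.na(gt3$genotype)
    pooled <- sum(gt3$genotype[pooled_rows]) / (2 * sum(pooled_rows))
    expect_equal(maf3$maf[k], if (pooled > 0.5) 1 - alt else alt)
  }
})

test_that("a population-specific allele-frequency shift is recovered by MAF + Tukey", {
  freqs <- tidyr::expand_grid(population = c("A", "B", "C"), variant_id = "v1")
  freqs$p <- c(0.4, 0.1, 0.1)
  sim <- simulate_genotypes(freqs, n_per_population = 80, seed = 99)
  maf <- minor_allele_frequency(sim$genotypes, sim$assignment)
  expect_equal(maf$maf[maf$population == "A"], 0.4, tolerance = 0.12)
  # per-sample dosage comparison: the shifted group differs from both others
  d <- dplyr::inner_join(sim$genotypes, sim$assignment, by = "sample_id")
  tk <- pop_tukey(d, genotype, population)
  with_a <- tk$group1 == "A" | tk$group2 == "A"
  expect_true(all(tk$p_value[with_a] < 0.01))
  expect_true(all(tk$p_value[!with_a] > 0.05))
})
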