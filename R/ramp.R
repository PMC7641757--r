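#' Harmonic mean
#'
#' The harmonic mean n / sum(1/x) is the appropriate average for ratios such
#' as RSCU-based translational speeds and is robust to single large values.
#'
#' @param x non-empty numeric vector of strictly positive values.
#' @return The harmonic mean.
#' @examples
#' harmonic_mean(c(1, 1/3))  # 0.5
#' @export
harmonic_mean <- function(x) {
  if (length(x) == 0L) abort("harmonic_mean() needs a non-empty input")
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort("harmonic_mean() is defined for strictly positive values")
  }
  length(x) / sum(1 / x)
}

#' Sliding-window harmonic-mean speeds
#'
#' Harmonic mean of per-codon speeds in every contiguous window of `window`
#' codons across a gene: one value per window start, length
#' `length(speeds) - window + 1`.
#'
#' @param speeds numeric vector of strictly positive per-codon speeds.
#' @param window window size in codons (>= 2, <= gene length).
#' @return Numeric vector of window harmonic means.
#' @export
window_speeds <- function(speeds, window = 9L) {
  check_window(window)
  n <- length(speeds)
  if (n < window) abort("gene shorter than the ribosomal window")
  if (any(!is.finite(speeds)) || any(speeds <= 0)) {
    abort("speeds must be strictly positive (check the reference RSCU table)")
  }
  inv <- cumsum(c(0, 1 / speeds))
  window / (inv[(window + 1L):(n + 1L)] - inv[1L:(n - window + 1L)])
}

#' Scan one speed profile for a ramp sequence
#'
#' A ramp sequence is a run of slowly translated (low-RSCU) codons at the
#' beginning of a gene. The scan computes harmonic-mean speeds in all sliding
#' ribosomal windows, flags outlier minima (window mean below
#' `mean - outlier_z * sd` of all window means) and calls a ramp when an
#' outlier window starts within the leading fraction of the gene. The ramp
#' extends from the first codon through the end of the contiguous outlier
#' region containing that leading outlier.
#'
#' @param speeds numeric vector of strictly positive per-codon speeds
#'   (typically reference RSCU values per codon; see [rscu_reference()]).
#' @param window ribosomal window in codons (default 9).
#' @param leading_fraction fraction of the gene in which the outlier window
#'   must start for a ramp call (default 0.01, the first percentile; always
#'   at least the first window).
#' @param outlier_z number of standard deviations below the mean window
#'   speed that defines an outlier (default 2).
#' @param gene_id optional label carried into the result.
#' @return An object of class `cub_ramp`: a list with the window means, the
#'   outlier threshold, `has_ramp`, `ramp_end_codon`, `hmean_ramp` (harmonic
#'   mean of speeds inside the ramp) and `hmean_gene` (over the whole gene).
#' @seealso [detect_ramps()] for the data-frame interface.
#' @export
ramp_scan <- function(speeds, window = 9L, leading_fraction = 0.01,
                      outlier_z = 2, gene_id = NA_character_) {
  check_window(window)
  if (!is.numeric(leading_fraction) || leading_fraction <= 0 || leading_fraction > 1) {
    abort("`leading_fraction` must be in (0, 1]")
  }
  if (!is.numeric(outlier_z) || outlier_z <= 0) abort("`outlier_z` must be > 0")
  wm <- window_speeds(speeds, window)
  n <- length(speeds)
  threshold <- mean(wm) - outlier_z * sd(wm)
  outlier <- is.finite(threshold) & wm < threshold
  leading_limit <- max(1L, ceiling(leading_fraction * n))
  lead_hits <- which(outlier[seq_len(min(leading_limit, length(wm)))])
  has_ramp <- length(lead_hits) > 0L
  ramp_end <- NA_integer_
  hmean_ramp <- NA_real_
  if (has_ramp) {
    # contiguous run of outlier windows containing the first leading hit
    run_end <- lead_hits[1L]
    while (run_end < length(outlier) && outlier[run_end + 1L]) run_end <- run_end + 1L
    ramp_end <- run_end + window - 1L
    hmean_ramp <- harmonic_mean(speeds[seq_len(ramp_end)])
  }
  structure(list(
    gene_id = gene_id, window = as.integer(window),
    leading_fraction = leading_fraction, outlier_z = outlier_z,
    window_means = wm, threshold = threshold, outlier = outlier,
    has_ramp = has_ramp, ramp_end_codon = ramp_end,
    hmean_ramp = hmean_ramp, hmean_gene = harmonic_mean(speeds)
  ), class = "cub_ramp")
}

#' @export
print.cub_ramp <- function(x, ...) {
  cat("<cub_ramp>", if (!is.na(x$gene_id)) x$gene_id else "", "\n")
  cat("  codons:", length(x$window_means) + x$window - 1L,
      " window:", x$window, "\n")
  if (x$has_ramp) {
    cat(sprintf("  ramp: codons 1-%d (%d nt), hmean %.4g vs gene %.4g\n",
                x$ramp_end_codon, 3L * x$ramp_end_codon,
                x$hmean_ramp, x$hmean_gene))
  } else {
    cat("  no ramp detected; gene hmean", format(x$hmean_gene, digits = 4), "\n")
  }
  invisible(x)
}

#' @export
tidy.cub_ramp <- function(x, ...) {
  tibble(
    gene_id = x$gene_id, has_ramp = x$has_ramp,
    ramp_end_codon = x$ramp_end_codon,
    ramp_length_nt = if (x$has_ramp) 3L * x$ramp_end_codon else NA_integer_,
    hmean_ramp = x$hmean_ramp, hmean_gene = x$hmean_gene
  )
}

#' @export
glance.cub_ramp <- function(x, ...) {
  tibble(
    n_codons = length(x$window_means) + x$window - 1L,
    n_windows = length(x$window_means), n_outlier_windows = sum(x$outlier),
    threshold = x$threshold, has_ramp = x$has_ramp
  )
}

#' @describeIn ramp_scan plot the window speed profile, the outlier
#'   threshold, and the detected ramp region.
#' @param object a `cub_ramp` object.
#' @param ... unused.
#' @export
autoplot.cub_ramp <- function(object, ...) {
  df <- tibble(start = seq_along(object$window_means),
               speed = object$window_means)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$speed)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "window start (codon)",
      y = sprintf("harmonic-mean speed (%d-codon window)", object$window),
      title = if (!is.na(object$gene_id)) object$gene_id else NULL
    )
  if (object$has_ramp) {
    p <- p + ggplot2::annotate("rect",
      xmin = 1, xmax = object$ramp_end_codon, ymin = -Inf, ymax = Inf,
      alpha = 0.15, fill = "red"
    )
  }
  p
}

#' Detect ramp sequences across a cohort of coding sequences
#'
#' Maps each record's codons to translational speeds with a reference RSCU
#' table and runs [ramp_scan()] per record. A terminal stop codon is dropped
#' before speed mapping; genes shorter than the window are skipped with a
#' warning and reported with `has_ramp = NA`.
#'
#' @param cds a coding-sequence tibble.
#' @param reference named RSCU vector from [rscu_reference()] (61 sense
#'   codons).
#' @inheritParams ramp_scan
#' @return A tibble with the identifier columns plus `has_ramp`,
#'   `ramp_end_codon`, `ramp_length_nt`, `hmean_ramp`, `hmean_gene`.
#' @export
detect_ramps <- function(cds, reference, window = 9L, leading_fraction = 0.01,
                         outlier_z = 2) {
  stopifnot(is.numeric(reference), !is.null(names(reference)))
  long <- cds_codons(cds)
  by_row <- split(long$codon, factor(long$.row, levels = seq_len(nrow(cds))))
  res <- lapply(seq_len(nrow(cds)), function(i) {
    codons <- by_row[[i]]
    nc <- length(codons)
    if (nc > 0 && codons[nc] %in% stop_codons()) codons <- codons[-nc]
    if (any(codons %in% stop_codons())) {
      abort(paste0("internal stop codon in ", cds$sample_id[i], "|", cds$gene_id[i]))
    }
    if (length(codons) < window) {
      warn(paste0("gene shorter than window, skipped: ",
                  cds$sample_id[i], "|", cds$gene_id[i]))
      return(tibble(has_ramp = NA, ramp_end_codon = NA_integer_,
                    ramp_length_nt = NA_integer_, hmean_ramp = NA_real_,
                    hmean_gene = NA_real_))
    }
    speeds <- unname(reference[codons])
    if (any(is.na(speeds) | speeds <= 0)) {
      abort(paste0("zero or missing reference RSCU for a codon in ",
                   cds$sample_id[i], "|", cds$gene_id[i]))
    }
    tidy.cub_ramp(ramp_scan(speeds, window, leading_fraction, outlier_z,
                            gene_id = cds$gene_id[i]))[, -1L]
  })
  bind_cols(cds[, id_cols()], bind_rows(res))
}
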