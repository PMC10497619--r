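## Enrichment calling: relative abundance, fold change versus the plasmid
## pool, Welch t-tests across replicates, hit classification and summaries.

#' Convert per-element counts to relative abundance (%)
#'
#' Each column is scaled by its total so abundances sum to 100%.  All-zero
#' columns are flagged and come back as `NA`.
#'
#' @param counts Integer matrix, elements x samples (or a vector).
#' @return Numeric matrix of abundances in percent; attribute
#'   `undefined_columns` names any all-zero columns.
#' @export
relative_abundance <- function(counts) {
  m <- as.matrix(counts)
  totals <- colSums(m)
  ab <- sweep(m, 2, totals, "/") * 100
  bad <- totals == 0
  if (any(bad)) {
    ab[, bad] <- NA_real_
    warning("abundance undefined for all-zero column(s): ",
            paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  }
  attr(ab, "undefined_columns") <- colnames(m)[bad]
  ab
}

#' Fold change of sorted-population abundance over the pDNA baseline
#'
#' `FC = (mean(sorted) + pseudo) / (mean(pdna) + pseudo)`.  The pseudocount
#' (in percentage points) keeps FC finite for pDNA dropouts while barely
#' perturbing typical abundances (~0.1%); with both means zero the FC is 1
#' (neutral by construction).
#'
#' @param sorted_abund,pdna_abund Replicate abundance vectors (%).
#' @param pseudo Pseudocount in percentage points.
#' @return Fold change (scalar).
#' @export
fold_change <- function(sorted_abund, pdna_abund, pseudo = 0.005) {
  stopifnot(length(sorted_abund) > 0, length(pdna_abund) > 0)
  (mean(sorted_abund) + pseudo) / (mean(pdna_abund) + pseudo)
}

#' Two-tailed unpaired t-test with degenerate-case conventions
#'
#' Wraps [stats::t.test()].  The default is the pooled-variance (Student)
#' test — the default unpaired t-test of the mainstream GraphPad-style
#' analysis stack, and the only variant with usable degrees of freedom at
#' two replicates per group (df = 2; the Welch approximation collapses
#' towards df = 1 there, making p < 0.05 nearly unreachable).  Set
#' `var_equal = FALSE` for Welch.  When both groups have zero variance the
#' statistic is undefined: equal means are reported as `p = 1` (no
#' difference), unequal means as `NA` with `undetermined = TRUE`.
#'
#' @param group_a,group_b Numeric vectors of length >= 2.
#' @param var_equal Pool the variances (Student) or not (Welch).
#' @return List with `p_value`, `statistic`, `df`, `undetermined`.
#' @export
t_test_two_tailed <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop_input("each group needs at least 2 values")
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(p_value = 1, statistic = 0, df = NA_real_,
                  undetermined = FALSE))
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                undetermined = TRUE))
  }
  tt <- t.test(group_a, group_b, var.equal = var_equal,
               alternative = "two.sided")
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), undetermined = FALSE)
}

#' Classify elements as enriched, depleted or neutral
#'
#' Strict thresholds: enriched iff `FC > fc_up` and `p < alpha`; depleted
#' iff `FC < fc_down` and `p < alpha`; otherwise neutral.  Rows with an
#' undefined p-value are `undetermined`.
#'
#' @param results Data frame with columns `fc` and `p_value`.
#' @param fc_up,fc_down Fold-change thresholds.
#' @param alpha Significance level.
#' @return The input with a `call` column.
#' @export
call_hits <- function(results, fc_up = 1.5, fc_down = 0.67, alpha = 0.05) {
  call <- rep("neutral", nrow(results))
  undet <- is.na(results$p_value)
  call[undet] <- "undetermined"
  sig <- !undet & results$p_value < alpha
  call[sig & results$fc > fc_up] <- "enriched"
  call[sig & results$fc < fc_down] <- "depleted"
  results$call <- call
  results
}

#' Per-element enrichment versus the pDNA baseline
#'
#' For each sorted population (grouped by `population` and `day` in the
#' sample sheet), computes per-element fold change of mean abundance over
#' the pDNA mean and a Welch t-test across replicate abundances, then
#' classifies hits.
#'
#' @param counts Elements x samples count matrix (columns named as in the
#'   sample sheet).
#' @param sample_sheet Data frame with `sample`, `population`, `day`,
#'   `replicate`, `role` (`"sorted"` or `"pdna"`).
#' @param pseudo Pseudocount for [fold_change()].
#' @param fc_up,fc_down,alpha Thresholds for [call_hits()].
#' @param p_adjust Multiple-testing correction method passed to
#'   [stats::p.adjust()] within each population; `"none"` (default) mirrors
#'   a screen analysed on raw p-values, `"BH"` is available as an option.
#' @param var_equal Passed to [t_test_two_tailed()].
#' @return Data frame: `element_id`, `population`, `day`, `fc`, `p_value`,
#'   `call` (plus `p_adjusted` when correction is on).
#' @export
compute_enrichment <- function(counts, sample_sheet, pseudo = 0.005,
                               fc_up = 1.5, fc_down = 0.67, alpha = 0.05,
                               p_adjust = "none", var_equal = TRUE) {
  stopifnot(all(sample_sheet$sample %in% colnames(counts)))
  ab <- relative_abundance(counts[, sample_sheet$sample, drop = FALSE])
  pdna_cols <- sample_sheet$sample[sample_sheet$role == "pdna"]
  if (length(pdna_cols) == 0L) stop_input("sample sheet has no pdna samples")
  pdna_ab <- ab[, pdna_cols, drop = FALSE]
  sorted_sheet <- sample_sheet[sample_sheet$role == "sorted", , drop = FALSE]
  groups <- unique(sorted_sheet[, c("population", "day")])
  out <- NULL
  for (gi in seq_len(nrow(groups))) {
    pop <- groups$population[gi]; day <- groups$day[gi]
    cols <- sorted_sheet$sample[sorted_sheet$population == pop &
                                  sorted_sheet$day %in% day]
    sab <- ab[, cols, drop = FALSE]
    fc <- vapply(seq_len(nrow(ab)), function(i)
      fold_change(sab[i, ], pdna_ab[i, ], pseudo), numeric(1))
    p <- vapply(seq_len(nrow(ab)), function(i)
      t_test_two_tailed(sab[i, ], pdna_ab[i, ], var_equal)$p_value,
      numeric(1))
    res <- data.frame(element_id = rownames(ab), population = pop, day = day,
                      fc = fc, p_value = p, stringsAsFactors = FALSE)
    if (p_adjust != "none") {
      res$p_adjusted <- stats::p.adjust(res$p_value, method = p_adjust)
      res <- call_hits(transform(res, p_value = p_adjusted),
                       fc_up, fc_down, alpha)
      res$p_value <- p
    } else {
      res <- call_hits(res, fc_up, fc_down, alpha)
    }
    out <- rbind(out, res)
  }
  rownames(out) <- NULL
  out
}

#' Category composition of a hit list
#'
#' @param hit_ids Element identifiers of the hits.
#' @param manifest Data frame with `id` and `category_label` for the whole
#'   library.
#' @return Data frame `category`, `count`, `percent` (percentages sum to
#'   100); zero rows for an empty hit list.
#' @export
hit_composition <- function(hit_ids, manifest) {
  if (length(hit_ids) == 0L)
    return(data.frame(category = character(), count = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  idx <- match(hit_ids, manifest$id)
  if (anyNA(idx)) stop_input("hit element(s) absent from the manifest")
  tab <- table(manifest$category_label[idx])
  data.frame(category = names(tab), count = as.integer(tab),
             percent = 100 * as.integer(tab) / length(hit_ids),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Pearson correlation between replicate abundance profiles
#'
#' By default computed on `log10(abundance + pseudo)`; zero-variance input
#' yields `NA`.
#'
#' @param abund_a,abund_b Equal-length abundance vectors (n >= 3).
#' @param log_transform Correlate log10-transformed abundances?
#' @param pseudo Pseudocount used inside the log transform.
#' @return Pearson r (scalar, `NA` if undefined).
#' @export
replicate_correlation <- function(abund_a, abund_b, log_transform = TRUE,
                                  pseudo = 0.005) {
  stopifnot(length(abund_a) == length(abund_b), length(abund_a) >= 3)
  if (log_transform) {
    abund_a <- log10(abund_a + pseudo)
    abund_b <- log10(abund_b + pseudo)
  }
  if (stats::sd(abund_a) == 0 || stats::sd(abund_b) == 0) return(NA_real_)
  cor(abund_a, abund_b)
}

#' Mean of a set of replicate correlations
#'
#' @param r Vector of correlation coefficients.
#' @return Their mean.
#' @export
mean_correlation <- function(r) mean(r)

#' Library coverage and cumulative abundance curve
#'
#' @param counts Per-element counts (or abundances) over the full library.
#' @return List with `coverage_percent` (% of elements with a nonzero
#'   value) and `curve`, a data frame of sorted-ascending abundance
#'   fractions cumulated to 1.
#' @export
coverage_and_cumulative <- function(counts) {
  x <- as.numeric(counts)
  coverage <- 100 * mean(x > 0)
  total <- sum(x)
  frac <- if (total > 0) sort(x) / total else rep(0, length(x))
  list(coverage_percent = coverage,
       curve = data.frame(rank_fraction = seq_along(x) / length(x),
                          cumulative_fraction = cumsum(frac)))
}

#' Volcano-plot export table
#'
#' @param results Output of [compute_enrichment()] for one population.
#' @return Data frame `element_id`, `log2_fc`, `neg_log10_p`, `call`.
#' @export
volcano_table <- function(results) {
  data.frame(element_id = results$element_id,
             log2_fc = log2(results$fc),
             neg_log10_p = -log10(results$p_value),
             call = results$call, stringsAsFactors = FALSE)
}

#' Replicate-averaged abundance matrix for heatmap export
#'
#' Averages abundance across replicates within each population/day group
#' (and across the pDNA technical replicates).
#'
#' @param counts Elements x samples count matrix.
#' @param sample_sheet Sample sheet as in [compute_enrichment()].
#' @return Numeric matrix, elements x population groups.
#' @export
heatmap_matrix <- function(counts, sample_sheet) {
  ab <- relative_abundance(counts[, sample_sheet$sample, drop = FALSE])
  key <- ifelse(sample_sheet$role == "pdna", "pDNA",
                paste0(sample_sheet$population, "_d", sample_sheet$day))
  out <- vapply(unique(key), function(kk)
    rowMeans(ab[, sample_sheet$sample[key == kk], drop = FALSE]),
    numeric(nrow(ab)))
  out
}
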