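# Tumor-level statistics on per-cell records: mean-of-medians aggregation,
# the mean - 1 SD negativity rule, quadrant contingency analysis, and the
# genotype comparison tests. Tumors, not cells, are the independent units.

measurement_column <- function(channel, compartment) {
  paste0(channel, "_", compartment, "_median")
}

#' Aggregate per-cell medians to tumor summaries
#'
#' One summary row per tumor: the mean of per-cell median intensities for
#' every `<channel>_<compartment>_median` column, with missing cytoplasm
#' medians excluded pairwise (per-column contributing counts are reported
#' in the `n_used` attribute).
#'
#' @param records Data frame from [measure_cells()] (or
#'   [simulate_cell_records()]); must carry `tumor_id` and `genotype`.
#' @return Data frame with `tumor_id`, `genotype`, `n_cells` and one
#'   mean-of-medians column per measured channel/compartment.
#' @export
aggregate_tumors <- function(records) {
  med_cols <- grep("_median$", names(records), value = TRUE)
  if (nrow(records) == 0) {
    out <- records[, c("tumor_id", "genotype", med_cols), drop = FALSE]
    out$n_cells <- integer(0)
    return(out[, c("tumor_id", "genotype", "n_cells", med_cols)])
  }
  stopifnot(all(c("tumor_id", "genotype") %in% names(records)))
  split_idx <- split(seq_len(nrow(records)), records$tumor_id)
  out <- do.call(rbind, lapply(split_idx, function(ii) {
    row <- data.frame(tumor_id = records$tumor_id[ii[1]],
                      genotype = records$genotype[ii[1]],
                      n_cells = length(ii))
    for (cl in med_cols)
      row[[cl]] <- mean(records[[cl]][ii], na.rm = TRUE)
    row
  }))
  rownames(out) <- NULL
  n_used <- vapply(med_cols, function(cl)
    sum(!is.na(records[[cl]])), integer(1))
  attr(out, "n_used") <- n_used
  out
}

#' Fit a marker negativity threshold from reference cells
#'
#' The cutoff is mean minus one sample standard deviation (n - 1
#' denominator) of per-cell medians pooled over all cells of the reference
#' genotype, reflecting the convention that reference-genotype tumors show
#' relatively uniform positive staining.
#'
#' @param records Per-cell records.
#' @param channel,compartment Which measurement to threshold.
#' @param reference_genotype Genotype whose cells define the rule; `NULL`
#'   uses all records.
#' @return List of class `threshold_rule`: `channel`, `compartment`,
#'   `reference_genotype`, `cutoff`, `mean`, `sd`, `n_reference_cells`.
#' @export
fit_threshold <- function(records, channel, compartment = "cytoplasm",
                          reference_genotype = NULL) {
  col <- measurement_column(channel, compartment)
  stopifnot(col %in% names(records))
  v <- records[[col]]
  if (!is.null(reference_genotype))
    v <- v[records$genotype == reference_genotype]
  v <- v[!is.na(v)]
  if (length(v) < 2)
    stop("fit_threshold needs at least 2 reference cells")
  m <- mean(v); s <- stats::sd(v)
  structure(list(channel = channel, compartment = compartment,
                 reference_genotype = reference_genotype,
                 cutoff = m - s, mean = m, sd = s,
                 n_reference_cells = length(v)),
            class = "threshold_rule")
}

#' Classify cells into quadrants by joint positivity
#'
#' A cell is positive for a channel when its compartment median is at or
#' above the rule's cutoff; strictly below is negative. Channel A is by
#' convention the nuclear transcription factor (classified on the nucleus
#' compartment) and channel B a cytoplasmic marker. Cells missing either
#' measurement are excluded and counted.
#'
#' @param records Per-cell records.
#' @param rule_a,rule_b [fit_threshold()] rules for channels A and B.
#' @return List of class `quadrant_classification`: `classes` (per-cell
#'   factor with levels `A+B+`, `A+B-`, `A-B+`, `A-B-`, `NA` for excluded
#'   cells), `table` (genotype x class count matrix of class
#'   `quadrant_table`), and `n_excluded`.
#' @export
classify_quadrants <- function(records, rule_a, rule_b) {
  col_a <- measurement_column(rule_a$channel, rule_a$compartment)
  col_b <- measurement_column(rule_b$channel, rule_b$compartment)
  stopifnot(col_a %in% names(records), col_b %in% names(records))
  a <- records[[col_a]] >= rule_a$cutoff
  b <- records[[col_b]] >= rule_b$cutoff
  cls <- ifelse(a & b, "A+B+",
         ifelse(a & !b, "A+B-",
         ifelse(!a & b, "A-B+", "A-B-")))
  cls <- factor(cls, levels = c("A+B+", "A+B-", "A-B+", "A-B-"))
  keep <- !is.na(cls)
  tab <- table(genotype = records$genotype[keep], class = cls[keep])
  tab <- unclass(tab)[, , drop = FALSE]
  class(tab) <- c("quadrant_table", class(tab))
  attr(tab, "channel_pair") <- c(A = rule_a$channel, B = rule_b$channel)
  structure(list(classes = cls, table = tab, n_excluded = sum(!keep)),
            class = "quadrant_classification")
}

#' Chi-squared test of genotype against quadrant distribution
#'
#' Pearson chi-squared on the genotype x class contingency table without
#' continuity correction; a warning is issued when any expected count falls
#' below 5.
#'
#' @param table A genotype x class count matrix (e.g. the `table` element of
#'   [classify_quadrants()]).
#' @return List with `statistic`, `df`, `p_value` and `expected`.
#' @export
chi_squared_genotype <- function(table) {
  tab <- unclass(as.matrix(table))
  if (nrow(tab) < 2) stop("need at least 2 genotypes")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a row or column is all zero")
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5))
    warning("some expected counts are below 5; chi-squared approximation ",
            "may be inaccurate")
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Per-genotype Spearman correlation between two measurements
#'
#' Cells are pooled across tumors within genotype (matching per-cell
#' scatter analyses); a tumor-stratified variant averages within-tumor
#' coefficients weighted by cell count. Ties get average ranks. Constant
#' input yields an `NA` estimate with a flag rather than an error.
#'
#' @param records Per-cell records.
#' @param channel_x,compartment_x,channel_y,compartment_y The two
#'   measurements.
#' @param stratify_by_tumor Average within-tumor coefficients instead of
#'   pooling cells.
#' @param n_boot Bootstrap replicates for a 95% CI (0 = none).
#' @return Data frame with one row per genotype: `genotype`, `rho`, `n`,
#'   `undefined` (constant input), and optionally `ci_lo`, `ci_hi`.
#' @export
spearman_by_genotype <- function(records, channel_x, compartment_x,
                                 channel_y, compartment_y,
                                 stratify_by_tumor = FALSE, n_boot = 0) {
  col_x <- measurement_column(channel_x, compartment_x)
  col_y <- measurement_column(channel_y, compartment_y)
  stopifnot(col_x %in% names(records), col_y %in% names(records))
  one_rho <- function(x, y) {
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  res <- lapply(split(records, records$genotype), function(df) {
    ok <- !is.na(df[[col_x]]) & !is.na(df[[col_y]])
    df <- df[ok, , drop = FALSE]
    rho <- if (stratify_by_tumor) {
      per <- vapply(split(df, df$tumor_id), function(d)
        one_rho(d[[col_x]], d[[col_y]]), numeric(1))
      wts <- vapply(split(df, df$tumor_id), nrow, integer(1))
      stats::weighted.mean(per, wts, na.rm = TRUE)
    } else one_rho(df[[col_x]], df[[col_y]])
    row <- data.frame(genotype = df$genotype[1], rho = rho, n = nrow(df),
                      undefined = is.na(rho))
    if (n_boot > 0 && !is.na(rho)) {
      bs <- replicate(n_boot, {
        ii <- sample.int(nrow(df), replace = TRUE)
        one_rho(df[[col_x]][ii], df[[col_y]][ii])
      })
      qs <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
      row$ci_lo <- qs[1]; row$ci_hi <- qs[2]
    }
    row
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum test on tumor summaries
#'
#' Two-sided rank-sum comparison of tumor-level mean-of-medians between two
#' genotypes. The exact null distribution is used when the combined sample
#' size is at most 12 and there are no ties; otherwise the normal
#' approximation with tie correction (no continuity correction) applies.
#'
#' @param summaries Output of [aggregate_tumors()].
#' @param genotypes Character vector of the two genotypes to compare.
#' @param channel,compartment Which summary column to test.
#' @return List with `W`, `p_value`, `method` and group sizes.
#' @export
tumor_wilcoxon <- function(summaries, genotypes, channel,
                           compartment = "cytoplasm") {
  stopifnot(length(genotypes) == 2)
  col <- measurement_column(channel, compartment)
  stopifnot(col %in% names(summaries))
  x <- summaries[[col]][summaries$genotype == genotypes[1]]
  y <- summaries[[col]][summaries$genotype == genotypes[2]]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("both genotype groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(W = unname(res$statistic), p_value = res$p.value,
       method = if (exact) "exact" else "normal approximation",
       n = c(length(x), length(y)))
}

#' One-way ANOVA with Tukey HSD on tumor summaries
#'
#' Fixed-effects one-way ANOVA across three or more groups of tumor
#' summaries, followed by Tukey's honest significant difference on all
#' pairs via the studentized range distribution.
#'
#' @param summaries Output of [aggregate_tumors()].
#' @param channel,compartment Which summary column to test.
#' @param group_col Grouping column (default `genotype`; use a combined
#'   genotype-by-timepoint label for designs crossing both).
#' @return List with `F`, `df`, `p_value` and `tukey` (data frame of
#'   pairwise differences and adjusted p values).
#' @export
anova_tukey <- function(summaries, channel, compartment = "cytoplasm",
                        group_col = "genotype") {
  col <- measurement_column(channel, compartment)
  stopifnot(col %in% names(summaries), group_col %in% names(summaries))
  df <- data.frame(y = summaries[[col]],
                   g = factor(summaries[[group_col]]))
  df <- df[!is.na(df$y), ]
  counts <- table(df$g)
  if (length(counts) < 3) stop("need at least 3 groups")
  if (any(counts < 2))
    stop(sprintf("groups with fewer than 2 tumors: %s",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(F = an$`F value`[1], df = c(an$Df[1], an$Df[2]),
       p_value = an$`Pr(>F)`[1], tukey = tukey)
}

#' Sample size per group for a two-sample t-test
#'
#' Solves power(n) = `target_power` for the two-sided two-sample t-test
#' with noncentral-t power function (noncentrality `(delta/sd) sqrt(n/2)`,
#' `2(n - 1)` degrees of freedom), by root-finding on continuous n.
#'
#' @param delta True difference in means.
#' @param sd Common standard deviation.
#' @param sig_level Two-sided type-I error rate.
#' @param target_power Desired power.
#' @return Required n per group (real; round up for a design).
#' @export
power_n_per_group <- function(delta, sd, sig_level = 0.05,
                              target_power = 0.8) {
  stopifnot(delta > 0, sd > 0, sig_level > 0, sig_level < 1,
            target_power > 0, target_power < 1)
  stats::power.t.test(delta = delta, sd = sd, sig.level = sig_level,
                      power = target_power, type = "two.sample",
                      alternative = "two.sided", tol = 1e-10)$n
}
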