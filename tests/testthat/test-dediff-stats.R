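records_from_values <- function(values, tumor = "t1", genotype = "BRAF",
                                channel = "marker",
                                compartment = "cytoplasm") {
  df <- data.frame(cell_id = seq_along(values),
                   tumor_id = rep_len(tumor, length(values)),
                   genotype = rep_len(genotype, length(values)))
  df[[paste0(channel, "_", compartment, "_median")]] <- values
  df
}

test_that("tumor aggregation is the mean of per-cell medians", {
  expect_equal(aggregate_tumors(
    records_from_values(10))$marker_cytoplasm_median, 10)
  expect_equal(aggregate_tumors(
    records_from_values(c(10, 20)))$marker_cytoplasm_median, 15)
  empty <- aggregate_tumors(records_from_values(numeric(0)))
  expect_equal(nrow(empty), 0)
  # missing cytoplasm medians drop out pairwise with reported counts
  mixed <- records_from_values(c(1, NA, 3))
  agg <- aggregate_tumors(mixed)
  expect_equal(agg$marker_cytoplasm_median, 2)
  expect_equal(unname(attr(agg, "n_used")[["marker_cytoplasm_median"]]), 2L)
})

test_that("threshold rule is mean minus one sample SD of reference cells", {
  rec <- records_from_values(c(10, 12, 14, 16, 18))
  rule <- fit_threshold(rec, "marker")
  expect_equal(rule$mean, 14)
  expect_equal(rule$sd, sqrt(10))
  expect_equal(rule$cutoff, 14 - sqrt(10))
  flat <- fit_threshold(records_from_values(rep(7, 4)), "marker")
  expect_equal(flat$cutoff, 7)
  expect_error(fit_threshold(records_from_values(5), "marker"),
               "at least 2")
  # only the reference genotype contributes
  two <- rbind(records_from_values(c(10, 12, 14, 16, 18)),
               records_from_values(c(0, 0), genotype = "MUT"))
  expect_equal(fit_threshold(two, "marker",
                             reference_genotype = "BRAF")$cutoff,
               14 - sqrt(10))
})

test_that("a Normal reference leaves ~15.9% of its own cells negative", {
  set.seed(33)
  rec <- records_from_values(rnorm(5000, 1000, 120))
  rule <- fit_threshold(rec, "marker")
  frac <- mean(rec$marker_cytoplasm_median < rule$cutoff)
  expect_gte(frac, 0.139)
  expect_lte(frac, 0.179)
})

test_that("quadrant classification respects the at-or-above convention", {
  rec <- data.frame(cell_id = 1:4, tumor_id = "t", genotype = "g",
                    tf_nucleus_median = c(10, 10, 1, 1),
                    marker_cytoplasm_median = c(10, 1, 10, 1))
  rule_a <- list(channel = "tf", compartment = "nucleus", cutoff = 5)
  rule_b <- list(channel = "marker", compartment = "cytoplasm", cutoff = 5)
  q <- classify_quadrants(rec, rule_a, rule_b)
  expect_equal(as.vector(q$table), c(1, 1, 1, 1))
  expect_equal(as.character(q$classes),
               c("A+B+", "A+B-", "A-B+", "A-B-"))
  # boundary: exactly at cutoff is positive; strictly below negative
  rec2 <- rec; rec2$tf_nucleus_median <- c(5, 5, 4.999, 5)
  rec2$marker_cytoplasm_median <- c(5, 6, 7, 8)
  q2 <- classify_quadrants(rec2, rule_a, rule_b)
  expect_equal(as.character(q2$classes),
               c("A+B+", "A+B+", "A-B+", "A+B+"))
  # missing measurements are excluded and counted
  rec3 <- rec; rec3$marker_cytoplasm_median[2] <- NA
  q3 <- classify_quadrants(rec3, rule_a, rule_b)
  expect_equal(q3$n_excluded, 1)
  expect_equal(sum(q3$table), 3)
})

test_that("chi-squared matches its definition and handles degeneracy", {
  tab <- matrix(c(20, 10, 10, 20), 2, byrow = TRUE)
  res <- chi_squared_genotype(tab)
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))
  same <- matrix(c(30, 15, 60, 30), 2)
  res0 <- chi_squared_genotype(same)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  expect_error(chi_squared_genotype(matrix(c(5, 0, 7, 0), 2)),
               "degenerate")
  expect_warning(chi_squared_genotype(matrix(c(2, 3, 50, 60), 2)),
                 "expected")
  set.seed(4)
  for (i in 1:100) {
    t2 <- matrix(rpois(8, 20) + 1, 2, 4)
    got <- suppressWarnings(chi_squared_genotype(t2))
    want <- chisq_oracle(t2)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df)
  }
})

test_that("spearman by genotype recovers monotone and copula structure", {
  rec <- data.frame(cell_id = 1:5, tumor_id = "t", genotype = "g",
                    tf_nucleus_median = 1:5,
                    marker_cytoplasm_median = c(2, 4, 6, 8, 10))
  r <- spearman_by_genotype(rec, "tf", "nucleus", "marker", "cytoplasm")
  expect_equal(r$rho, 1)
  rec$marker_cytoplasm_median <- c(10, 8, 6, 4, 2)
  expect_equal(spearman_by_genotype(rec, "tf", "nucleus", "marker",
                                    "cytoplasm")$rho, -1)
  rec$marker_cytoplasm_median <- rep(3, 5)
  flagged <- spearman_by_genotype(rec, "tf", "nucleus", "marker",
                                  "cytoplasm")
  expect_true(flagged$undefined)
  set.seed(5)
  big <- simulate_cell_records(n_tumors = 4, cells_per_tumor = 500,
                               inter_channel_rank_correlation = 0.5)
  est <- spearman_by_genotype(big, "tf", "nucleus", "marker", "cytoplasm")
  expect_lt(abs(est$rho - 0.5), 0.05)
})

test_that("rank-sum test is exact for small samples and matches enumeration", {
  r <- tumor_wilcoxon(
    data.frame(tumor_id = 1:6, genotype = rep(c("a", "b"), each = 3),
               marker_cytoplasm_median = c(1, 2, 3, 4, 5, 6)),
    c("a", "b"), "marker")
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  same <- tumor_wilcoxon(
    data.frame(tumor_id = 1:6, genotype = rep(c("a", "b"), each = 3),
               marker_cytoplasm_median = c(1, 2, 3, 1, 2, 3)),
    c("a", "b"), "marker")
  expect_equal(same$p_value, 1)
  set.seed(6)
  for (i in 1:100) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    v <- sample(1000, nx + ny)  # distinct values, no ties
    df <- data.frame(tumor_id = seq_len(nx + ny),
                     genotype = rep(c("a", "b"), c(nx, ny)),
                     marker_cytoplasm_median = v)
    got <- tumor_wilcoxon(df, c("a", "b"), "marker")
    expect_equal(got$p_value, wilcox_exact_oracle(v[1:nx], v[-(1:nx)]),
                 tolerance = 1e-12)
  }
})

test_that("one-way ANOVA matches the direct sums oracle and Tukey nulls", {
  df <- data.frame(tumor_id = 1:9, genotype = rep(c("a", "b", "c"), each = 3),
                   marker_cytoplasm_median = rep(c(1, 2, 3), 3))
  res <- anova_tukey(df, "marker")
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_true(all(res$tukey$p_adj > 0.999))
  set.seed(7)
  for (i in 1:100) {
    k <- sample(3:4, 1)
    n <- sample(3:6, k, replace = TRUE)
    df2 <- data.frame(tumor_id = seq_len(sum(n)),
                      genotype = rep(letters[1:k], n),
                      marker_cytoplasm_median = rnorm(sum(n)))
    got <- anova_tukey(df2, "marker")
    expect_equal(got$F, f_oracle(df2$marker_cytoplasm_median, df2$genotype),
                 tolerance = 1e-10)
  }
  # a strongly shifted group is flagged by Tukey, the null pair is not
  set.seed(8)
  df3 <- data.frame(tumor_id = 1:15, genotype = rep(c("a", "b", "c"), 5),
                    marker_cytoplasm_median = rnorm(15) +
                      rep(c(0, 0, 10), 5))
  res3 <- anova_tukey(df3, "marker")
  pc <- res3$tukey$p_adj[res3$tukey$comparison %in% c("c-a", "c-b")]
  expect_true(all(pc < 0.001))
  expect_gt(res3$tukey$p_adj[res3$tukey$comparison == "b-a"], 0.5)
  expect_error(anova_tukey(df3[-c(1, 4, 7, 10, 13), ][-1, ], "marker"),
               "fewer than 2|at least 3")
})

test_that("sample-size solver matches the noncentral-t oracle", {
  n_study <- power_n_per_group(2895.4, 918, 0.05, 0.8)
  expect_equal(n_study, power_n_oracle(2895.4, 918, 0.05, 0.8),
               tolerance = 1e-5)
  expect_equal(power_n_per_group(1, 1, 0.05, 0.8), 16.71477,
               tolerance = 1e-4)
  # the study's reported 3.4 animals per group arises at 90% power
  expect_equal(round(power_n_per_group(2895.4, 918, 0.05, 0.9), 1), 3.4)
  # monotone in delta, and scale invariant in (delta, sd)
  deltas <- c(500, 1000, 2000, 4000)
  ns <- vapply(deltas, function(d) power_n_per_group(d, 918), numeric(1))
  expect_true(all(diff(ns) < 0))
  expect_equal(power_n_per_group(2, 1), power_n_per_group(200, 100),
               tolerance = 1e-9)
})
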