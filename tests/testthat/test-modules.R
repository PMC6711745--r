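# Planted-block expression matrix with latent-factor structure, built
# directly so module recovery is tested independently of the full
# generator.
planted_blocks <- function(n_per_block = 50, n_blocks = 3, n_noise = 0,
                           n_samples = 20, latent_sd = 1, noise_sd = 0.2,
                           seed = 1) {
  set.seed(seed)
  genes <- n_per_block * n_blocks + n_noise
  lat <- matrix(rnorm(n_blocks * n_samples, 0, latent_sd), n_blocks)
  truth <- rep(c(seq_len(n_blocks), 0L),
               c(rep(n_per_block, n_blocks), n_noise))
  m <- matrix(0, genes, n_samples)
  for (g in seq_len(genes)) {
    base <- if (truth[g] > 0) lat[truth[g], ] else rnorm(n_samples, 0,
                                                         latent_sd)
    m[g, ] <- 100 * exp(base * (truth[g] > 0) +
                        rnorm(n_samples, 0, noise_sd) +
                        (truth[g] == 0) * rnorm(n_samples, 0, 0.3))
  }
  rownames(m) <- sprintf("g%04d", seq_len(genes))
  list(m = m, truth = truth)
}

test_that("expression filter applies a strict lower bound on the mean", {
  m <- matrix(100, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(nrow(filter_expressed(m, 40)), 5)
  m[2, ] <- 40          # exactly at the bound: dropped
  m[3, ] <- 40.0001
  kept <- filter_expressed(m, 40)
  expect_setequal(rownames(kept), c("g1", "g3", "g4", "g5"))
  expect_equal(attr(kept, "n_dropped"), 1L)
  expect_error(filter_expressed(m * 0, 40), "no gene")
})

test_that("generator low-expression block is removed exactly by the filter", {
  cfg <- expr_sim_config(effect_log2fc = 0, rng_seed = 19)
  sim <- generate_expression_matrix(cfg)
  norm <- normalize_counts(sim$counts)
  kept <- filter_expressed(norm, 40)
  high <- cfg$genes$gene_id[cfg$genes$category != "low"]
  expect_setequal(rownames(kept), high)
  expect_equal(nrow(kept) / cfg$n_genes, 0.7)
})

test_that("planted blocks are recovered with high agreement", {
  pb <- planted_blocks(seed = 3)
  asg <- coexpression_modules(pb$m, beta = 3, cut_height = 0.9)
  ari <- mclust::adjustedRandIndex(asg$modules, pb$truth)
  expect_gte(ari, 0.9)
  expect_equal(length(asg$sizes), 3)
  # TOM dissimilarity recovers the same partition
  asg_tom <- coexpression_modules(pb$m, beta = 3, use_tom = TRUE,
                                  cut_height = 0.8)
  expect_gte(mclust::adjustedRandIndex(asg_tom$modules, pb$truth), 0.9)
})

test_that("independent noise genes stay unassigned", {
  pb <- planted_blocks(n_per_block = 40, n_blocks = 1, n_noise = 200,
                       seed = 5)
  asg <- coexpression_modules(pb$m)
  noise <- rownames(pb$m)[pb$truth == 0]
  expect_gte(mean(asg$modules[noise] == 0), 0.9)
})

test_that("assignments are deterministic and correlation invariant", {
  pb <- planted_blocks(n_per_block = 40, n_blocks = 2, n_noise = 30,
                       seed = 7)
  a1 <- coexpression_modules(pb$m)
  a2 <- coexpression_modules(pb$m)
  expect_identical(a1$modules, a2$modules)
  # sample order
  a3 <- coexpression_modules(pb$m[, sample(ncol(pb$m))])
  expect_identical(a1$modules, a3$modules)
  # per-gene positive affine rescaling
  scaled <- pb$m * runif(nrow(pb$m), 0.5, 2) + runif(nrow(pb$m), 0, 10)
  a4 <- coexpression_modules(scaled)
  expect_identical(a1$modules, a4$modules)
  # constant genes are flagged into module 0
  flat <- pb$m
  flat[3, ] <- 42
  expect_warning(a5 <- coexpression_modules(flat), "constant")
  expect_equal(unname(a5$modules[3]), 0L)
})

test_that("marker-bearing module selection counts and breaks ties", {
  modules <- stats::setNames(c(rep(1L, 5), rep(2L, 5)),
                             sprintf("g%02d", 1:10))
  asg <- structure(list(modules = modules), class = "module_assignment")
  sets <- list(AT1 = c("g01", "g02", "g03"), AT2 = c("g04", "g06"))
  sel <- select_marker_module(asg, sets)
  expect_equal(sel$module, 1)
  expect_false(sel$tie)
  expect_equal(sel$counts$n_markers[sel$counts$module == 1], 4L)
  expect_equal(sel$counts$n_markers[sel$counts$module == 2], 1L)
  # 60/40 split
  sets2 <- list(AT1 = sprintf("g%02d", c(1:3, 6:7)))
  expect_equal(select_marker_module(asg, sets2)$module, 1)
  # exact tie goes to the lower module id and is reported
  sets3 <- list(AT1 = c("g01", "g06"))
  tie <- select_marker_module(asg, sets3)
  expect_equal(tie$module, 1)
  expect_true(tie$tie)
  expect_error(select_marker_module(asg, list(AT1 = "zz")), "no marker")
})

test_that("three-factor screen requires all three conditions", {
  modules <- stats::setNames(c(1L, 1L, 2L, 0L), c("reg", "tf_in_weak",
                                                  "tf_out", "tf_none"))
  asg <- structure(list(modules = modules), class = "module_assignment")
  de <- data.frame(gene_id = c("reg", "tf_in_weak", "tf_out", "tf_none"),
                   adj_p = c(0.001, 0.5, 1e-6, 0.01))
  tab <- three_factor_screen(asg, 1, c("reg", "tf_in_weak", "tf_out",
                                       "tf_none"), de)
  pass <- tab$gene_id[tab$passes_all]
  expect_equal(pass, "reg")
  expect_false(tab$passes_all[tab$gene_id == "tf_out"])     # wrong module
  expect_false(tab$passes_all[tab$gene_id == "tf_in_weak"]) # adjP too big
  # empty TF list is valid and yields no candidates
  none <- three_factor_screen(asg, 1, character(0), de)
  expect_false(any(none$passes_all))
})
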