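# Synthetic count matrices with block-correlated gene modules, four
# cell-type reference profiles for marker-set construction, and a planted
# transcription-factor regulator down-regulated alongside one marker block.

#' Configuration for the expression-matrix simulator
#'
#' The generator plants a fixed gene layout, deterministic given the
#' configuration: co-expression modules driven by shared latent factors, a
#' set of cell-type-specific reference markers tied to those modules
#' (type-2-like and most type-1-like markers in the affected module,
#' mirroring an identity-bearing co-expression cluster), pair-shared marker
#' genes that create designed top-100 overlaps, decoy transcription factors
#' inside and outside the affected module, and a planted regulator inside
#' the affected module. Group-B samples down-regulate the affected module by
#' `effect_log2fc`.
#'
#' Gene id layout (ids `g0001...`): pair-shared marker genes come first so
#' the documented gene-id tie-break of [build_marker_sets()] resolves ties in
#' their favour; then module genes (markers, regulator, fillers), decoy TFs
#' among unassigned well-expressed genes, remaining well-expressed noise
#' genes, and finally low-expressed genes.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_group Samples per genotype group.
#' @param module_sizes Integer sizes of the planted co-expression modules;
#'   must sum to at most `n_genes` and accommodate the marker layout.
#' @param module_latent_sd SD of the per-sample module latent factor (log
#'   scale). Latents are mean-centered within each group so planted log2
#'   fold changes are exactly the group contrast.
#' @param gene_noise_sd SD of independent per-gene, per-sample log-normal
#'   noise.
#' @param library_size Expected total counts per sample.
#' @param nb_dispersion Negative-binomial dispersion (Var = mu + a mu^2),
#'   constant across genes; 0 gives Poisson counts.
#' @param affected_module_index Module down-regulated in group B.
#' @param effect_log2fc log2 fold change (group B vs A) applied to every
#'   gene of the affected module, including the planted regulator.
#' @param n_specific_per_type Exclusive reference markers per cell type.
#' @param overlap_per_pair Pair-shared marker genes per pair of cell types;
#'   with four types each top-100 set is
#'   `n_specific_per_type + 3 * overlap_per_pair` genes, so the defaults
#'   (82 + 3 x 6) give sets of exactly 100 with pairwise overlaps of 6.
#' @param frac_low_expressed Fraction of genes given a low base mean (well
#'   under the expression filter), all outside modules and marker sets.
#' @param n_decoy_tfs_in_modules,n_decoy_tfs_noise Decoy transcription
#'   factors placed in the unaffected modules and among unassigned genes.
#' @param group_labels Two genotype labels, reference group first.
#' @param rng_seed Integer seed.
#' @return Object of class `expr_sim_config` with the resolved gene layout
#'   in `$genes` (gene_id, module, category, celltype, is_tf, true_log2fc)
#'   and `$planted_regulator_gene`.
#' @export
expr_sim_config <- function(n_genes = 2000, n_samples_per_group = 8,
                            module_sizes = c(250, 150, 150),
                            module_latent_sd = 0.4, gene_noise_sd = 0.15,
                            library_size = 5e5, nb_dispersion = 0.05,
                            affected_module_index = 1, effect_log2fc = -2,
                            n_specific_per_type = 82, overlap_per_pair = 6,
                            frac_low_expressed = 0.3,
                            n_decoy_tfs_in_modules = 20,
                            n_decoy_tfs_noise = 10,
                            group_labels = c("BRAF", "BRAF_PIK3CA"),
                            rng_seed = 1L) {
  stopifnot(n_genes >= 1, n_samples_per_group >= 2,
            all(module_sizes >= 1), length(module_sizes) >= 1,
            module_latent_sd >= 0, gene_noise_sd >= 0,
            library_size > 0, nb_dispersion >= 0,
            affected_module_index >= 1,
            affected_module_index <= length(module_sizes),
            n_specific_per_type >= 1, overlap_per_pair >= 0,
            frac_low_expressed >= 0, frac_low_expressed < 1,
            length(group_labels) == 2)
  if (sum(module_sizes) > n_genes)
    stop("module_sizes exceed n_genes")

  types <- c("AT1", "AT2", "club", "ciliated")
  pairs <- utils::combn(types, 2)
  set_size <- n_specific_per_type + (length(types) - 1) * overlap_per_pair

  genes <- expr_gene_layout(n_genes, module_sizes, affected_module_index,
                            n_specific_per_type, overlap_per_pair,
                            frac_low_expressed,
                            n_decoy_tfs_in_modules, n_decoy_tfs_noise,
                            types, pairs)
  genes$true_log2fc <- ifelse(genes$module == affected_module_index,
                              effect_log2fc, 0)

  cfg <- list(n_genes = n_genes, n_samples_per_group = n_samples_per_group,
              n_modules = length(module_sizes), module_sizes = module_sizes,
              module_latent_sd = module_latent_sd,
              gene_noise_sd = gene_noise_sd,
              library_size = library_size, nb_dispersion = nb_dispersion,
              affected_module_index = affected_module_index,
              effect_log2fc = effect_log2fc,
              n_specific_per_type = n_specific_per_type,
              overlap_per_pair = overlap_per_pair,
              marker_set_size = set_size,
              celltypes = types,
              group_labels = group_labels,
              genes = genes,
              planted_regulator_gene =
                genes$gene_id[genes$category == "regulator"],
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "expr_sim_config"
  cfg
}

# Deterministic gene layout shared by the count generator and the reference
# profile table. Categories: shared_<A>_<B>, marker_<type>, regulator,
# module_filler, decoy_tf, noise, low.
expr_gene_layout <- function(n_genes, module_sizes, affected,
                             n_spec, overlap, frac_low,
                             n_decoy_mod, n_decoy_noise, types, pairs) {
  categories <- character(0); modules <- integer(0)
  celltypes <- character(0); is_tf <- logical(0)
  add <- function(n, category, module, celltype = NA_character_, tf = FALSE) {
    categories <<- c(categories, rep(category, n))
    modules <<- c(modules, rep(module, n))
    celltypes <<- c(celltypes, rep(celltype, n))
    is_tf <<- c(is_tf, rep(tf, n))
  }

  # Pair-shared marker genes first (lowest ids, wins gene-id tie-breaks).
  # The AT1/AT2 pair lives in the affected module with the other AT1/AT2
  # markers; the remaining pairs are unassigned background structure.
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    mod <- if (a == "AT1" && b == "AT2") affected else 0L
    add(overlap, sprintf("shared_%s_%s", a, b), mod)
  }

  # Affected module: all AT2 markers, ~3/4 of AT1 markers, the regulator.
  n_at1_in <- round(0.75 * n_spec)
  add(n_spec, "marker_AT2", affected, "AT2")
  add(n_at1_in, "marker_AT1", affected, "AT1")
  add(1, "regulator", affected, tf = TRUE)
  used_aff <- ncol(pairs) * 0 + n_spec + n_at1_in + 1 + overlap  # in module
  if (module_sizes[affected] < used_aff)
    stop("affected module too small for the marker layout")
  add(module_sizes[affected] - used_aff, "module_filler", affected)

  # Remaining modules: leftover AT1 markers and club markers go to the
  # first unaffected module, ciliated markers to the next; decoy TFs split
  # across unaffected modules.
  others <- setdiff(seq_along(module_sizes), affected)
  decoy_per_mod <- if (length(others) > 0)
    diff(round(seq(0, n_decoy_mod, length.out = length(others) + 1)))
  else integer(0)
  leftovers <- list(
    list(n = n_spec - n_at1_in, category = "marker_AT1", celltype = "AT1"),
    list(n = n_spec, category = "marker_club", celltype = "club"),
    list(n = n_spec, category = "marker_ciliated", celltype = "ciliated"))
  li <- 1
  for (k in seq_along(others)) {
    m <- others[k]
    room <- module_sizes[m] - decoy_per_mod[k]
    while (li <= length(leftovers) && leftovers[[li]]$n <= room) {
      x <- leftovers[[li]]
      add(x$n, x$category, m, x$celltype)
      room <- room - x$n
      li <- li + 1
    }
    add(decoy_per_mod[k], "decoy_tf", m, tf = TRUE)
    add(room, "module_filler", m)
  }
  if (li <= length(leftovers))
    stop("module_sizes cannot accommodate the marker layout")

  # Unassigned genes: decoy TFs, well-expressed noise, low-expressed genes.
  n_low <- round(frac_low * n_genes)
  n_used <- length(categories)
  n_noise <- n_genes - n_used - n_decoy_noise - n_low
  if (n_noise < 0)
    stop("n_genes too small for the configured layout")
  add(n_decoy_noise, "decoy_tf", 0L, tf = TRUE)
  add(n_noise, "noise", 0L)
  add(n_low, "low", 0L)

  data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
             module = modules, category = categories,
             celltype = celltypes, is_tf = is_tf,
             stringsAsFactors = FALSE)
}

#' Simulate a gene-by-sample count matrix with planted structure
#'
#' Counts are negative-binomial draws around sample-specific means
#' `library-scale * base_g * s_j * exp(latent_m(g),j + noise_gj) *
#' 2^(log2fc_g)` for group-B samples. Genes in one module share a latent
#' factor, giving positive within-module correlation; module latents are
#' mean-centered within each group so the realized group contrast of every
#' affected-module gene is the planted `effect_log2fc`.
#'
#' @param config An [expr_sim_config()].
#' @return List with `counts` (integer matrix, genes x samples, rownames =
#'   gene ids), `groups` (data frame: sample_id, group), and `truth` (the
#'   per-gene layout with `module` and `true_log2fc`).
#' @export
generate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$rng_seed)

  genes <- config$genes
  n_g <- nrow(genes)
  n_s <- 2L * config$n_samples_per_group
  group <- rep(config$group_labels, each = config$n_samples_per_group)
  sample_id <- sprintf("%s_s%02d", group,
                       rep(seq_len(config$n_samples_per_group), 2))

  base <- numeric(n_g)
  low <- genes$category == "low"
  base[!low] <- stats::rlnorm(sum(!low), meanlog = log(300), sdlog = 0.5)
  base[low] <- stats::rlnorm(sum(low), meanlog = log(5), sdlog = 0.5)

  sf <- stats::rlnorm(n_s, 0, 0.15)
  lat <- matrix(0, config$n_modules, n_s)
  for (m in seq_len(config$n_modules)) {
    z <- stats::rnorm(n_s, 0, config$module_latent_sd)
    for (g in unique(group)) {
      sel <- group == g
      z[sel] <- z[sel] - mean(z[sel])
    }
    lat[m, ] <- z
  }

  scale <- config$library_size / sum(base)
  eps <- matrix(stats::rnorm(n_g * n_s, 0, config$gene_noise_sd), n_g, n_s)
  latg <- matrix(0, n_g, n_s)
  assigned <- genes$module > 0
  latg[assigned, ] <- lat[genes$module[assigned], , drop = FALSE]
  fc <- outer(genes$true_log2fc,
              as.numeric(group == config$group_labels[2])) * log(2)
  mu <- scale * base * t(sf * t(exp(latg + eps + fc)))

  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(n_g * n_s, mu = mu, size = 1 / config$nb_dispersion),
           n_g, n_s)
  } else {
    matrix(stats::rpois(n_g * n_s, lambda = mu), n_g, n_s)
  }
  dimnames(counts) <- list(genes$gene_id, sample_id)
  list(counts = counts,
       groups = data.frame(sample_id = sample_id, group = group,
                           stringsAsFactors = FALSE),
       truth = genes[, c("gene_id", "module", "category", "celltype",
                         "is_tf", "true_log2fc")])
}

#' Reference mean-expression profiles for marker-set construction
#'
#' Emits a deterministic gene x cell-type table of reference means encoding
#' the configured marker layout: exclusive markers are high in their own
#' type only, pair-shared markers tie the within-type maximum in exactly two
#' types, and all remaining genes are flat across types. Feeding this table
#' to [build_marker_sets()] with the configured set size recovers top sets
#' of exactly `marker_set_size` genes per type whose pairwise overlaps equal
#' `overlap_per_pair`.
#'
#' @param config An [expr_sim_config()].
#' @return Numeric matrix (genes x 4 cell types, rownames = gene ids).
#' @export
generate_celltype_markers <- function(config) {
  stopifnot(inherits(config, "expr_sim_config"))
  if (config$marker_set_size < 100 && config$n_specific_per_type < 100)
    invisible(NULL)  # sets smaller than 100 are allowed but non-default
  genes <- config$genes
  types <- config$celltypes
  prof <- matrix(5, nrow(genes), length(types),
                 dimnames = list(genes$gene_id, types))
  for (t in types) {
    sel <- genes$celltype %in% t
    prof[sel, ] <- 2
    prof[sel, t] <- 100
  }
  shared <- grep("^shared_", genes$category)
  for (i in shared) {
    pair <- strsplit(sub("^shared_", "", genes$category[i]), "_")[[1]]
    prof[i, ] <- 0
    prof[i, pair] <- 50
  }
  prof
}
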