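# Soft-threshold co-expression module detection and the three-factor
# candidate-regulator screen: expression filter, |cor|^beta adjacency
# (optionally topological overlap), average-linkage clustering with a
# static cut, marker-bearing module selection, and the intersection of
# module membership, transcription-factor annotation and differential
# expression.

#' Filter genes by minimal expression
#'
#' Keeps genes whose mean normalized count across samples is strictly
#' greater than `min_level` (default 40, the conventional low-expression
#' floor for co-expression clustering).
#'
#' @param norm_counts Normalized expression matrix, genes x samples.
#' @param min_level Strict lower bound on the per-gene mean.
#' @param statistic `"mean"` (default), `"min"` or `"max"` of the per-gene
#'   normalized counts.
#' @return The row-subset matrix, with `n_kept`/`n_dropped` attributes.
#' @export
filter_expressed <- function(norm_counts, min_level = 40,
                             statistic = c("mean", "min", "max")) {
  statistic <- match.arg(statistic)
  m <- as.matrix(norm_counts)
  stat <- switch(statistic,
                 mean = rowMeans(m),
                 min = apply(m, 1, min),
                 max = apply(m, 1, max))
  keep <- stat > min_level
  if (!any(keep)) stop("no gene passes the expression filter")
  out <- m[keep, , drop = FALSE]
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Topological overlap matrix from an adjacency matrix (unsigned,
# zero diagonal): TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i,k_j) + 1 - a_ij)
tom_similarity <- function(adj) {
  diag(adj) <- 0
  num <- adj %*% adj + adj
  k <- rowSums(adj)
  kmin <- outer(k, k, pmin)
  tom <- num / (kmin + 1 - adj)
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules by soft-threshold clustering
#'
#' Adjacency is `|cor(g_i, g_j)|^beta` (Pearson, unsigned network, or
#' `((1 + cor)/2)^beta` when `signed`); dissimilarity is `1 - adjacency`
#' or `1 - TOM` similarity when `use_tom`; genes are clustered by
#' average-linkage hierarchical clustering and the tree is cut statically
#' at `cut_height`. Clusters smaller than `min_size` dissolve into module
#' 0 (unassigned); surviving modules are renumbered by decreasing size.
#' Constant (zero-variance) genes go to module 0 with a warning. The
#' procedure is deterministic.
#'
#' @param norm_counts Normalized expression matrix, genes x samples
#'   (typically pre-filtered with [filter_expressed()]).
#' @param beta Soft-thresholding power (default 3, chosen where the
#'   scale-free topology fit plateaus for these data sizes).
#' @param use_tom Use topological overlap similarity instead of raw
#'   adjacency.
#' @param cut_height Static tree-cut height on the dissimilarity scale.
#' @param min_size Minimum module size.
#' @param signed Use a signed network.
#' @return List of class `module_assignment`: `modules` (named integer
#'   vector, 0 = unassigned), `sizes`, `mean_intramodule_cor`, `params`.
#' @export
coexpression_modules <- function(norm_counts, beta = 3, use_tom = FALSE,
                                 cut_height = 0.9, min_size = 30,
                                 signed = FALSE) {
  m <- as.matrix(norm_counts)
  stopifnot(ncol(m) >= 3, nrow(m) >= 2)
  gene_ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  rownames(m) <- gene_ids
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  if (any(constant))
    warning(sprintf("%d constant gene(s) assigned to module 0",
                    sum(constant)))
  modules <- stats::setNames(rep(0L, nrow(m)), gene_ids)
  work <- m[!constant, , drop = FALSE]
  if (nrow(work) >= max(2, min_size)) {
    cc <- stats::cor(t(work))
    adj <- if (signed) ((1 + cc) / 2)^beta else abs(cc)^beta
    sim <- if (use_tom) tom_similarity(adj) else adj
    diss <- 1 - sim
    diag(diss) <- 0
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    raw <- stats::cutree(hc, h = cut_height)
    tab <- table(raw)
    keep <- as.integer(names(tab)[tab >= min_size])
    raw[!(raw %in% keep)] <- 0L
    # renumber by decreasing size, ties by first occurrence
    if (any(raw > 0)) {
      sizes <- sort(table(raw[raw > 0]), decreasing = TRUE)
      map <- stats::setNames(seq_along(sizes), names(sizes))
      raw[raw > 0] <- map[as.character(raw[raw > 0])]
    }
    modules[rownames(work)] <- as.integer(raw)
  }
  mods <- sort(unique(modules[modules > 0]))
  mean_cor <- vapply(mods, function(k) {
    g <- names(modules)[modules == k]
    cm <- stats::cor(t(m[g, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  structure(list(modules = modules,
                 sizes = stats::setNames(
                   vapply(mods, function(k) sum(modules == k), integer(1)),
                   mods),
                 mean_intramodule_cor = stats::setNames(mean_cor, mods),
                 params = list(beta = beta, use_tom = use_tom,
                               cut_height = cut_height, min_size = min_size,
                               signed = signed)),
            class = "module_assignment")
}

#' Select the marker-bearing module
#'
#' Returns the module holding the largest combined number of members of the
#' supplied marker sets (conventionally the type-1 and type-2 pneumocyte
#' top-100 sets); ties go to the lower module id and are reported.
#'
#' @param assignment A `module_assignment` from [coexpression_modules()].
#' @param marker_sets Named list of character vectors of marker gene ids.
#' @return List: `module` (selected id), `counts` (data frame of per-module
#'   gene and marker counts, the module-membership table), `tie`.
#' @export
select_marker_module <- function(assignment, marker_sets) {
  modules <- assignment$modules
  markers <- unique(unlist(marker_sets))
  mods <- sort(unique(modules))
  counts <- data.frame(module = mods,
                       n_genes = vapply(mods, function(k)
                         sum(modules == k), integer(1)))
  for (nm in names(marker_sets)) {
    counts[[paste0("n_", nm)]] <- vapply(mods, function(k)
      sum(names(modules)[modules == k] %in% marker_sets[[nm]]), integer(1))
  }
  counts$n_markers <- vapply(mods, function(k)
    sum(names(modules)[modules == k] %in% markers), integer(1))
  cand <- counts[counts$module > 0, , drop = FALSE]
  if (nrow(cand) == 0 || all(cand$n_markers == 0))
    stop("no marker gene is assigned to any module")
  best <- max(cand$n_markers)
  winners <- cand$module[cand$n_markers == best]
  list(module = min(winners), counts = counts, tie = length(winners) > 1)
}

#' Three-factor candidate-regulator screen
#'
#' A gene passes when it (1) belongs to the marker-bearing module, (2) is
#' an annotated transcription factor, and (3) is differentially expressed
#' at `adj_p < adjp_cutoff` (a deliberately promiscuous default of 0.2 so
#' the intersection, not the DE test alone, carries the specificity).
#'
#' @param assignment A `module_assignment`.
#' @param marker_module Module id from [select_marker_module()].
#' @param tf_list Character vector of transcription-factor gene ids.
#' @param de A `de_result` from [nb_wald_test()].
#' @param adjp_cutoff Strict upper bound on BH-adjusted p.
#' @return Data frame of class `candidate_table` covering every gene in the
#'   union of the three inputs: `gene_id`, `in_marker_module`, `is_tf`,
#'   `adj_p`, `passes_all`; passing genes sorted first by `adj_p`.
#' @export
three_factor_screen <- function(assignment, marker_module, tf_list, de,
                                adjp_cutoff = 0.2) {
  modules <- assignment$modules
  genes <- unique(c(names(modules), tf_list, de$gene_id))
  adj_p <- de$adj_p[match(genes, de$gene_id)]
  tab <- data.frame(
    gene_id = genes,
    in_marker_module = genes %in% names(modules)[modules == marker_module],
    is_tf = genes %in% tf_list,
    adj_p = adj_p,
    stringsAsFactors = FALSE)
  tab$passes_all <- tab$in_marker_module & tab$is_tf &
    !is.na(tab$adj_p) & tab$adj_p < adjp_cutoff
  tab <- tab[order(-tab$passes_all, tab$adj_p, tab$gene_id), ]
  rownames(tab) <- NULL
  class(tab) <- c("candidate_table", class(tab))
  tab
}
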