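# Cell-type marker set construction by specificity ranking, and classic
# preranked GSEA: weighted Kolmogorov-Smirnov running-sum enrichment score,
# gene-permutation null, sign-stratified NES normalization, BH across sets.

#' Build cell-type marker sets by specificity ranking
#'
#' The specificity score of gene g for cell type t is
#' `log2(mean_t + 1) - log2(max over other types + 1)`; each type's set is
#' the top `k` genes by score with ties broken by gene id. Sets may
#' overlap (shared genes can tie the top score in more than one type).
#'
#' @param profiles Numeric matrix or data frame of reference mean
#'   expression, genes x cell types, rownames = gene ids.
#' @param k Set size (default 100, the "top-100" convention).
#' @return Named list of character vectors (one gene set per cell type),
#'   with per-gene scores in the `scores` attribute.
#' @export
build_marker_sets <- function(profiles, k = 100) {
  prof <- as.matrix(profiles)
  stopifnot(ncol(prof) >= 2, !is.null(rownames(prof)))
  if (k > nrow(prof))
    stop("k exceeds the number of genes in the profile table")
  scores <- matrix(NA_real_, nrow(prof), ncol(prof),
                   dimnames = dimnames(prof))
  sets <- list()
  for (j in seq_len(ncol(prof))) {
    others <- prof[, -j, drop = FALSE]
    max_other <- apply(others, 1, max)
    s <- log2(prof[, j] + 1) - log2(max_other + 1)
    scores[, j] <- s
    ord <- order(-s, rownames(prof))
    sets[[colnames(prof)[j]]] <- rownames(prof)[ord[seq_len(k)]]
  }
  attr(sets, "scores") <- scores
  sets
}

# Enrichment score from hit positions in a ranked list. Hits increment the
# running sum by |r|^p / sum(|r_hits|^p), misses decrement by 1/(N - Nh);
# the ES is the extremum of largest absolute value. Positions must be
# sorted increasing. Returns c(es, which extremum sign).
es_from_positions <- function(stat_sorted, pos, weight_p) {
  n <- length(stat_sorted)
  nh <- length(pos)
  w <- abs(stat_sorted[pos])^weight_p
  wsum <- sum(w)
  if (wsum == 0) { w <- rep(1, nh); wsum <- nh }  # flat-statistic fallback
  miss <- 1 / (n - nh)
  cum_w <- cumsum(w) / wsum
  miss_before <- (pos - seq_len(nh)) * miss
  after_hit <- cum_w - miss_before          # running sum right after hit i
  before_hit <- c(0, cum_w[-nh]) - miss_before  # just before hit i
  hi <- max(after_hit)
  lo <- min(before_hit)
  # extremum of larger magnitude; exact magnitude ties (compared with a
  # small relative tolerance so float noise cannot flip the sign) go to
  # the positive extremum
  tol <- 1e-12 * max(abs(hi), abs(lo), 1)
  if (hi >= abs(lo) - tol) hi else lo
}

#' Preranked GSEA for a single gene set
#'
#' Computes the weighted-KS enrichment score of `set` in the ranked list,
#' with a gene-permutation null: `n_perm` random same-size gene sets drawn
#' without replacement. The normalized score divides ES by the mean |null
#' ES| of matching sign, and the permutation p value uses the add-one
#' correction `(1 + #(|null| >= |ES|, same sign)) / (1 + #null same sign)`.
#'
#' @param ranked Named numeric vector of ranking statistics (any order;
#'   sorted internally, decreasing, ties by gene id).
#' @param set Character vector of member gene ids, or a list with elements
#'   `name` and `genes`.
#' @param weight_p Hit-weight exponent (1 = classic weighted GSEA; 0 =
#'   unweighted KS).
#' @param n_perm Number of permutations (must be >= 1).
#' @param rng_seed Integer seed for the permutation null.
#' @return One-row data frame: `set`, `size` (members present), `es`,
#'   `nes`, `p_value`, plus `leading_edge` (comma-joined gene ids).
#' @export
gsea_preranked <- function(ranked, set, weight_p = 1, n_perm = 1000,
                           rng_seed = 1L) {
  if (is.list(set)) {
    set_name <- set$name; members <- set$genes
  } else {
    set_name <- deparse(substitute(set)); members <- set
  }
  if (n_perm < 1) stop("n_perm must be at least 1")
  stopifnot(!is.null(names(ranked)))
  ord <- order(-ranked, names(ranked))
  stat <- ranked[ord]
  genes <- names(stat)
  pos <- sort(match(intersect(members, genes), genes))
  if (length(pos) == 0) {
    warning(sprintf("gene set '%s' has no members in the ranked list",
                    set_name))
    return(NULL)
  }
  if (length(pos) >= length(genes))
    stop("gene set covers the whole ranked list")

  es <- es_from_positions(stat, pos, weight_p)

  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    es_from_positions(stat, sort(sample.int(length(genes), length(pos))),
                      weight_p)
  }, numeric(1))

  same_sign <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))

  # leading edge: members at or before (after, for negative ES) the extremum
  le <- leading_edge_genes(stat, pos, weight_p, es)
  data.frame(set = set_name, size = length(pos), es = es, nes = nes,
             p_value = p, leading_edge = paste(le, collapse = ","),
             stringsAsFactors = FALSE)
}

leading_edge_genes <- function(stat_sorted, pos, weight_p, es) {
  n <- length(stat_sorted); nh <- length(pos)
  w <- abs(stat_sorted[pos])^weight_p
  wsum <- sum(w); if (wsum == 0) { w <- rep(1, nh); wsum <- nh }
  miss <- 1 / (n - nh)
  after_hit <- cumsum(w) / wsum - (pos - seq_len(nh)) * miss
  before_hit <- c(0, cumsum(w)[-nh] / wsum) - (pos - seq_len(nh)) * miss
  if (es >= 0) {
    peak <- which.max(after_hit)
    names(stat_sorted)[pos[seq_len(peak)]]
  } else {
    trough <- which.min(before_hit)
    names(stat_sorted)[pos[pos >= pos[trough]]]
  }
}

#' Preranked GSEA over a collection of gene sets
#'
#' Runs [gsea_preranked()] per set with set-specific seeds derived from
#' `rng_seed`, then applies Benjamini-Hochberg correction across all sets
#' of the collection as one family. Sets with no members in the ranked
#' list are skipped with a warning.
#'
#' @param ranked Named numeric vector of ranking statistics.
#' @param sets Named list of character vectors (e.g. from [read_gmt()] or
#'   [build_marker_sets()]).
#' @param weight_p,n_perm,rng_seed See [gsea_preranked()].
#' @return Data frame of class `enrichment_result`, one row per usable set,
#'   with `adj_p` added.
#' @export
gsea_collection <- function(ranked, sets, weight_p = 1, n_perm = 1000,
                            rng_seed = 1L) {
  stopifnot(length(sets) >= 1, !is.null(names(sets)))
  rows <- lapply(seq_along(sets), function(i) {
    gsea_preranked(ranked, list(name = names(sets)[i], genes = sets[[i]]),
                   weight_p = weight_p, n_perm = n_perm,
                   rng_seed = rng_seed + i)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no usable gene set in the collection")
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p_value)
  class(out) <- c("enrichment_result", class(out))
  out
}
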