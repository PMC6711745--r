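# Independent brute-force oracles used to pin down expected values.

# Pearson chi-squared by the definition sum (O - E)^2 / E.
chisq_oracle <- function(tab) {
  tot <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / tot
  list(statistic = sum((tab - e)^2 / e),
       df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# One-way F statistic by direct sums of squares.
f_oracle <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Step-up BH by the definition adj_i = min over {j : p_j >= p_i} of
# m p_j / rank_j (rank with ties sharing the larger rank), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    sel <- p >= p[i]
    min(1, min(m * p[sel] / r[sel]))
  }, numeric(1))
}

# Exact two-sided rank-sum p by full enumeration of label arrangements.
wilcox_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  all_ranks <- rank(c(x, y))
  ws <- apply(combos, 2, function(ii) sum(all_ranks[ii]) - nx * (nx + 1) / 2)
  p_le <- mean(ws <= w_obs); p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Weighted-KS enrichment score by an explicit position-by-position running
# sum; extremum of largest magnitude, positive extremum wins exact ties.
es_oracle <- function(stat_sorted, is_hit, weight_p) {
  n <- length(stat_sorted)
  nh <- sum(is_hit)
  w <- abs(stat_sorted)^weight_p
  wsum <- sum(w[is_hit])
  if (wsum == 0) { w <- rep(1, n); wsum <- nh }
  run <- 0
  hi <- 0; lo <- 0
  for (i in seq_len(n)) {
    run <- if (is_hit[i]) run + w[i] / wsum else run - 1 / (n - nh)
    hi <- max(hi, run); lo <- min(lo, run)
  }
  tol <- 1e-12 * max(abs(hi), abs(lo), 1)
  unname(if (hi >= abs(lo) - tol) hi else lo)
}

# Noncentral-t solve for two-sample t-test sample size (independent of
# power.t.test): power(n) with ncp = (delta/sd) sqrt(n/2), df = 2(n-1).
# Upper-tail (non-strict) two-sided power, the standard convention.
power_n_oracle <- function(delta, sd, alpha = 0.05, power = 0.8) {
  pw <- function(n) {
    df <- 2 * (n - 1)
    q <- qt(1 - alpha / 2, df)
    ncp <- (delta / sd) * sqrt(n / 2)
    pt(q, df, ncp = ncp, lower.tail = FALSE)
  }
  uniroot(function(n) pw(n) - power, c(1.001, 1e7), tol = 1e-9)$root
}

# Match detected nucleus centroids to true centers within a radius;
# greedy one-to-one matching by increasing distance.
match_centroids <- function(labels, true_rc, max_dist = 5) {
  labs <- sort(unique(labels[labels > 0]))
  h <- nrow(labels)
  if (length(labs) == 0)
    return(list(precision = NA, recall = 0, f1 = 0, matches = integer(0)))
  cent <- t(vapply(labs, function(l) {
    idx <- which(labels == l)
    c(mean((idx - 1L) %% h + 1L), mean((idx - 1L) %/% h + 1L))
  }, numeric(2)))
  d <- sqrt(outer(cent[, 1], true_rc[, 1], "-")^2 +
            outer(cent[, 2], true_rc[, 2], "-")^2)
  pairs <- which(d <= max_dist, arr.ind = TRUE)
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_det <- logical(nrow(cent)); used_true <- logical(nrow(true_rc))
  matches <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (!used_det[i] && !used_true[j]) {
      used_det[i] <- TRUE; used_true[j] <- TRUE
      matches[length(matches) + 1L] <- labs[i]
    }
  }
  tp <- sum(used_det)
  precision <- tp / nrow(cent)
  recall <- tp / nrow(true_rc)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1, matches = matches)
}

# Brute-force Euclidean distance from every pixel to a nucleus label set:
# reference implementation for ring/propagation geometry.
nearest_seed_oracle <- function(nuclei, cap) {
  h <- nrow(nuclei); w <- ncol(nuclei)
  labs <- sort(unique(nuclei[nuclei > 0]))
  out <- matrix(0L, h, w)
  best <- matrix(Inf, h, w)
  for (l in labs) {
    idx <- which(nuclei == l)
    pr <- (idx - 1L) %% h + 1L; pc <- (idx - 1L) %/% h + 1L
    for (r in 1:h) for (cc in 1:w) {
      d <- sqrt(min((r - pr)^2 + (cc - pc)^2))
      if (d <= cap && d < best[r, cc]) {
        best[r, cc] <- d; out[r, cc] <- l
      }
    }
  }
  out[nuclei > 0] <- nuclei[nuclei > 0]
  out
}

# Small disk raster helper.
disk_raster <- function(h, w, centers, radii, inside = 10000, outside = 100) {
  m <- matrix(outside, h, w)
  for (i in seq_along(radii)) {
    for (r in 1:h) for (cc in 1:w) {
      if ((r - centers[i, 1])^2 + (cc - centers[i, 2])^2 <= radii[i]^2)
        m[r, cc] <- inside
    }
  }
  m
}
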