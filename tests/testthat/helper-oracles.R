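# Independent brute-force oracles used to verify the implementation.
# These are deliberately naive (sorting, enumeration, double loops) and
# never share code with the package internals they check.

# step-up FDR: sort ascending, p * n / rank, cumulative minimum from the tail
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# upper-tail hypergeometric by direct enumeration of choose() terms
hyper_enum <- function(N, K1, K2, m) {
  lo <- max(0, K1 + K2 - N)
  hi <- min(K1, K2)
  if (m > hi) return(0)
  tot <- choose(N, K2)
  sum(vapply(max(m, lo):hi, function(i) choose(K1, i) * choose(N - K1, K2 - i),
             numeric(1))) / tot
}

# AUC by exhaustive pair counting (ties count 1/2)
auc_pairs <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# partial correlation as the correlation of regression residuals
partial_resid <- function(x, y, z) {
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  stats::cor(rx, ry)
}

# all-pairs Pearson/Spearman r and p by an explicit double loop over cor.test
cor_loop <- function(A, B, method = "pearson") {
  out <- list()
  for (i in rownames(A)) for (j in rownames(B)) {
    r <- stats::cor(A[i, ], B[j, ], method = method)
    n <- ncol(A)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    out[[length(out) + 1]] <- data.frame(
      a_id = i, b_id = j, r = r, p_value = 2 * stats::pt(-abs(tt), n - 2),
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df[order(df$a_id, df$b_id), ]
}

# best achievable gene coverage with exactly k sets, by exhaustive subset search
best_coverage_k <- function(adj, k, genes) {
  circ <- names(adj)
  best <- 0
  for (sel in utils::combn(length(circ), k, simplify = FALSE)) {
    cov <- length(unique(unlist(adj[sel])))
    if (cov > best) best <- cov
  }
  best / length(genes)
}

# smallest set size reaching the coverage target, by exhaustive search
min_cover_size <- function(adj, target, genes) {
  total <- length(genes)
  for (k in seq_along(adj)) {
    if (best_coverage_k(adj, k, genes) >= target) return(k)
  }
  Inf
}
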