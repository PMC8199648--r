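# Paired tumor vs non-tumor differential expression with fold-change and
# FDR gating, plus hierarchical sample clustering on the DE features.

#' Paired two-sided t-test on matched tumor/non-tumor values
#'
#' Missing pairs are deleted pairwise. Degenerate cases follow the
#' pipeline's documented contract: identical vectors give t = 0, p = 1;
#' identical nonzero differences (zero SD) give p = 0 with a degenerate
#' flag; fewer than 3 complete pairs skips the feature (all-NA result with
#' `skipped = TRUE`).
#'
#' @param x tumor values, one per patient
#' @param y matched non-tumor values
#' @return list(t_stat, p_value, df, n, degenerate, skipped)
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stopf("paired_t_test: unequal lengths")
  keep <- !is.na(x) & !is.na(y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 3)
    return(list(t_stat = NA_real_, p_value = NA_real_, df = NA_real_, n = n,
                degenerate = FALSE, skipped = TRUE))
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0)
      return(list(t_stat = 0, p_value = 1, df = n - 1, n = n,
                  degenerate = FALSE, skipped = FALSE))
    return(list(t_stat = sign(m) * Inf, p_value = 0, df = n - 1, n = n,
                degenerate = TRUE, skipped = FALSE))
  }
  t_stat <- m / (s / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * stats::pt(-abs(t_stat), n - 1),
       df = n - 1, n = n, degenerate = FALSE, skipped = FALSE)
}

#' Benjamini-Hochberg (or Benjamini-Yekutieli) adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving in
#' the input. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param p p-values in \[0, 1\] (NA allowed, propagated)
#' @param method `"BH"` (default) or `"BY"`
#' @return q-values in input order
#' @export
bh_adjust <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("bh_adjust: p-values outside [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Differential expression between tumor and matched non-tumor samples
#'
#' One record per feature with the tumor - non-tumor log2 fold change, the
#' signed linear fold change (positive `2^log2fc` for up, negative
#' `-2^(-log2fc)` for down, the usual microarray reporting convention),
#' the (paired by default) t statistic, raw p, BH q, and the call:
#' `up` iff linear FC >= `fc_threshold` and q <= `de_fdr`; `down` iff
#' linear FC <= `1/fc_threshold` and q <= `de_fdr`; otherwise `ns`.
#'
#' @param em [expr_matrix()] (log2 values)
#' @param clinical clinical table defining the tumor/non-tumor pairing
#' @param fc_threshold linear fold-change gate (default 1.5)
#' @param de_fdr FDR gate (default 0.05)
#' @param paired paired t-test (default) or unpaired Welch
#' @param adjust `"BH"` or `"BY"`
#' @return data frame of DE records, one row per retained feature
#' @export
differential_expression <- function(em, clinical, fc_threshold = 1.5, de_fdr = 0.05,
                                    paired = TRUE, adjust = "BH") {
  v <- em$values
  tum <- clinical$sample_id[clinical$tissue == "tumor"]
  non <- clinical$sample_id[clinical$tissue == "non_tumor"]
  pat_t <- clinical$patient_id[match(tum, clinical$sample_id)]
  pat_n <- clinical$patient_id[match(non, clinical$sample_id)]
  non <- non[match(pat_t, pat_n)]  # align non-tumor columns to tumor patients
  miss <- setdiff(c(tum, non), colnames(v))
  if (length(miss)) stopf("differential_expression: samples absent from matrix: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  Vt <- v[, tum, drop = FALSE]
  Vn <- v[, non, drop = FALSE]
  log2fc <- rowMeans(Vt) - rowMeans(Vn)
  n <- ncol(Vt)
  degenerate <- rep(FALSE, nrow(v))
  if (paired) {
    D <- Vt - Vn
    m <- rowMeans(D)
    s <- sqrt(rowSums((D - m)^2) / (n - 1))
    t_stat <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf), m / (s / sqrt(n)))
    p <- ifelse(s == 0, ifelse(m == 0, 1, 0), 2 * stats::pt(-abs(m / (s / sqrt(n))), n - 1))
    degenerate <- s == 0 & m != 0
  } else {
    m1 <- rowMeans(Vt); m2 <- rowMeans(Vn)
    s1 <- apply(Vt, 1, stats::sd); s2 <- apply(Vn, 1, stats::sd)
    se2 <- s1^2 / ncol(Vt) + s2^2 / ncol(Vn)
    t_stat <- ifelse(se2 == 0, ifelse(m1 == m2, 0, sign(m1 - m2) * Inf),
                     (m1 - m2) / sqrt(se2))
    df <- se2^2 / (s1^4 / (ncol(Vt)^2 * (ncol(Vt) - 1)) + s2^4 / (ncol(Vn)^2 * (ncol(Vn) - 1)))
    p <- ifelse(se2 == 0, ifelse(m1 == m2, 1, 0), 2 * stats::pt(-abs(t_stat), df))
    degenerate <- se2 == 0 & m1 != m2
  }
  q <- bh_adjust(p, method = adjust)
  lth <- log2(fc_threshold)
  status <- rep("ns", nrow(v))
  status[log2fc >= lth & q <= de_fdr] <- "up"
  status[log2fc <= -lth & q <= de_fdr] <- "down"
  data.frame(feature_id = rownames(v), rna_class = em$rna_class,
             log2fc = log2fc, fc = ifelse(log2fc >= 0, 2^log2fc, -2^(-log2fc)),
             t_stat = t_stat, p_value = p, q_value = q, status = status,
             degenerate = degenerate, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of samples on a feature subset
#'
#' Agglomerative clustering with Euclidean distance and average linkage.
#' Columns are sorted by sample id before clustering so the result is
#' invariant to input sample order (ties broken by id).
#'
#' @param em [expr_matrix()]
#' @param features feature subset (default: all)
#' @return list(hclust, order = sample ids in leaf order)
#' @export
cluster_samples <- function(em, features = NULL) {
  v <- em$values
  if (!is.null(features)) {
    miss <- setdiff(features, rownames(v))
    if (length(miss)) stopf("cluster_samples: unknown features: %s",
                            paste(utils::head(miss, 3), collapse = ", "))
    v <- v[features, , drop = FALSE]
  }
  if (ncol(v) < 2) stopf("cluster_samples: need >= 2 samples")
  v <- v[, order(colnames(v)), drop = FALSE]
  hc <- stats::hclust(stats::dist(t(v), method = "euclidean"), method = "average")
  list(hclust = hc, order = hc$labels[hc$order])
}
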