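# Biomarker evaluation (ROC with Youden cut, ridge-stabilized logistic
# panels over the study's three tumor-grade contrasts) and gene-set
# over-representation.

#' ROC curve, AUC and Youden operating point
#'
#' AUC via the rank (Mann-Whitney) statistic with tie correction (ties
#' count 1/2); p-value from the normal approximation of U. Higher scores
#' are treated as indicating the positive class. The operating point
#' maximizes Youden's J = sensitivity + specificity - 1, ties broken by the
#' smallest threshold.
#'
#' @param scores numeric scores
#' @param labels logical (or 0/1) positive-class indicator
#' @return list(auc, auc_p, curve = data.frame(cut, fpr, tpr), youden_cut,
#'   sensitivity, specificity)
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stopf("roc_auc: NA in scores or labels")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("roc_auc: both classes must be present")
  n <- n1 + n0
  r <- rank(scores)
  U <- sum(r[labels]) - n1 * (n1 + 1) / 2
  auc <- U / (n1 * n0)
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n0 / 12 * ((n + 1) - tie_term)
  auc_p <- if (sigma2 <= 0) 1 else 2 * stats::pnorm(-abs((U - n1 * n0 / 2) / sqrt(sigma2)))
  cuts <- sort(unique(scores))
  tpr <- vapply(cuts, function(c) sum(scores >= c & labels) / n1, numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores >= c & !labels) / n0, numeric(1))
  curve <- data.frame(cut = c(cuts, Inf), fpr = c(fpr, 0), tpr = c(tpr, 0))
  curve <- curve[order(curve$fpr, curve$tpr), ]
  rownames(curve) <- NULL
  j <- tpr - fpr
  best <- which(j == max(j))
  best <- best[which.min(cuts[best])]
  list(auc = auc, auc_p = auc_p, curve = curve, youden_cut = cuts[best],
       sensitivity = tpr[best], specificity = 1 - fpr[best])
}

#' Logistic-regression biomarker panel with ridge stabilization
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' with a small L2 ridge (not applied to the intercept) for numerical
#' stability on separable panels. If the fit has not converged after
#' `max_iter` iterations the ridge is increased 1000-fold once and the fit
#' retried. The panel score is the fitted probability; its ROC (in-sample)
#' is returned.
#'
#' @param X samples x features numeric matrix (or data frame)
#' @param labels logical/0-1 outcome
#' @param panel feature subset (default: all columns)
#' @param ridge L2 penalty (default 1e-6)
#' @param max_iter IRLS iteration cap
#' @return list(weights (incl. intercept), scores, roc, converged,
#'   separable, ridge_used)
#' @export
logistic_panel <- function(X, labels, panel = NULL, ridge = 1e-6, max_iter = 100) {
  X <- as.matrix(X)
  labels <- as.numeric(as.logical(labels))
  if (!is.null(panel)) X <- X[, panel, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  if (n < 2 * (p + 1))
    stopf("logistic_panel: need n >= 2*(panel size + 1) (n=%d, panel=%d)", n, p)
  D <- cbind(`(intercept)` = 1, X)
  fit_once <- function(lambda) {
    beta <- rep(0, ncol(D))
    pen <- diag(c(0, rep(lambda, p)), ncol(D))
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- as.numeric(D %*% beta)
      mu <- 1 / (1 + exp(-eta))
      w <- pmax(mu * (1 - mu), 1e-10)
      z <- eta + (labels - mu) / w
      H <- crossprod(D, D * w) + pen
      beta_new <- tryCatch(solve(H, crossprod(D, w * z)), error = function(e) NULL)
      if (is.null(beta_new)) break
      delta <- max(abs(beta_new - beta))
      beta <- as.numeric(beta_new)
      if (delta < 1e-8) { conv <- TRUE; break }
    }
    list(beta = beta, converged = conv)
  }
  ft <- fit_once(ridge)
  ridge_used <- ridge
  if (!ft$converged) {
    ridge_used <- ridge * 1000
    ft <- fit_once(ridge_used)
  }
  beta <- stats::setNames(ft$beta, colnames(D))
  scores <- as.numeric(1 / (1 + exp(-(D %*% ft$beta))))
  pos <- labels == 1
  separable <- (min(scores[pos]) > max(scores[!pos])) &&
    all(scores[pos] > 0.99) && all(scores[!pos] < 0.01)
  list(weights = beta, scores = scores, roc = roc_auc(scores, labels == 1),
       converged = ft$converged, separable = separable, ridge_used = ridge_used)
}

#' Gene-set over-representation analysis (hypergeometric)
#'
#' Upper-tail hypergeometric p per set with BH adjustment across sets. The
#' query is deduplicated and restricted to the background on entry.
#'
#' @param query character vector of genes of interest
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()])
#' @param background character vector: the gene universe
#' @return data frame: set_name, overlap_m, set_k, query_n, background_n,
#'   hyper_p, q_value; ordered by p then set name
#' @export
ora <- function(query, gene_sets, background) {
  background <- unique(background)
  query <- unique(intersect(query, background))
  if (!length(query)) stopf("ora: empty query (after restriction to background)")
  N <- length(background); n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(intersect(gene_sets[[nm]], background))
    K <- length(set)
    m <- length(intersect(query, set))
    p <- if (K == 0) 1 else stats::phyper(m - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap_m = m, set_k = K, query_n = n,
               background_n = N, hyper_p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- bh_adjust(res$hyper_p)
  res <- res[order(res$hyper_p, res$set_name), ]
  rownames(res) <- NULL
  res
}

#' ROC evaluation of features and panels over the grade contrasts
#'
#' Three classification contrasts are evaluated: non-tumor vs tumor of
#' grade 1-2; tumor grade 1-2 vs grade 3-4; and non-tumor vs tumor of
#' grade 3-4 (positive class = tumor, or the higher grade). Each feature is
#' scored alone by [roc_auc()]; each panel by [logistic_panel()].
#'
#' @param em [expr_matrix()] holding the candidate features
#' @param clinical clinical table
#' @param features feature ids evaluated individually
#' @param panels named list of feature-id vectors fitted jointly
#' @param ridge ridge for the panel fits
#' @return data frame: contrast, name, kind (feature/panel), n_pos, n_neg,
#'   auc, auc_p, youden_cut, sensitivity, specificity, separable
#' @export
roc_contrasts <- function(em, clinical, features, panels = list(), ridge = 1e-6) {
  v <- em$values
  tum <- clinical[clinical$tissue == "tumor", ]
  non <- clinical[clinical$tissue == "non_tumor", ]
  g12 <- tum$sample_id[!is.na(tum$grade) & tum$grade %in% 1:2]
  g34 <- tum$sample_id[!is.na(tum$grade) & tum$grade %in% 3:4]
  contrasts <- list(
    nontumor_vs_grade12 = list(neg = non$sample_id, pos = g12),
    grade12_vs_grade34 = list(neg = g12, pos = g34),
    nontumor_vs_grade34 = list(neg = non$sample_id, pos = g34))
  out <- list()
  for (cn in names(contrasts)) {
    cc <- contrasts[[cn]]
    samp <- c(cc$neg, cc$pos)
    labels <- c(rep(FALSE, length(cc$neg)), rep(TRUE, length(cc$pos)))
    if (!length(cc$pos) || !length(cc$neg)) next
    for (f in features) {
      rr <- roc_auc(v[f, samp], labels)
      out[[length(out) + 1]] <- data.frame(
        contrast = cn, name = f, kind = "feature",
        n_pos = length(cc$pos), n_neg = length(cc$neg),
        auc = rr$auc, auc_p = rr$auc_p, youden_cut = rr$youden_cut,
        sensitivity = rr$sensitivity, specificity = rr$specificity,
        separable = NA, stringsAsFactors = FALSE)
    }
    for (pn in names(panels)) {
      feats <- panels[[pn]]
      if (length(samp) < 2 * (length(feats) + 1)) next
      lp <- logistic_panel(t(v[feats, samp, drop = FALSE]), labels, ridge = ridge)
      out[[length(out) + 1]] <- data.frame(
        contrast = cn, name = pn, kind = "panel",
        n_pos = length(cc$pos), n_neg = length(cc$neg),
        auc = lp$roc$auc, auc_p = lp$roc$auc_p, youden_cut = lp$roc$youden_cut,
        sensitivity = lp$roc$sensitivity, specificity = lp$roc$specificity,
        separable = lp$separable, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(contrast = character(0), name = character(0), kind = character(0),
               n_pos = integer(0), n_neg = integer(0), auc = numeric(0),
               auc_p = numeric(0), youden_cut = numeric(0), sensitivity = numeric(0),
               specificity = numeric(0), separable = logical(0))
  rownames(res) <- NULL
  res
}
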