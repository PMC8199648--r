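# ceRNA inference: miRNA-target interaction filtering, shared-miRNA
# hypergeometric test, partial Pearson correlation (PPC), sensitivity
# correlation (SPPC), Gaussian conditional mutual information (CMI) with a
# stratified permutation p, pair tiering and triplet construction.

#' Filter predicted miRNA-target links by inverse expression correlation
#'
#' A link is retained iff it is predicted by at least `min_predictors`
#' registry predictors AND its Spearman correlation between miRNA and
#' target expression is negative with p <= `p_max` (two-sided, t
#' approximation with df = n - 2). Links whose ids are absent from the
#' matrices are dropped (reported via `message`).
#'
#' @param targets target table (see [read_target_table()])
#' @param expr named list of [expr_matrix()] with elements `miRNA` and the
#'   target classes present (`circRNA`, `mRNA`)
#' @param min_predictors minimum predictor support (default 2)
#' @param p_max Spearman p gate (default 0.05)
#' @param samples optional sample subset
#' @return data frame: mirna_id, target_id, target_class, n_predictors,
#'   spearman_rho, spearman_p, retained
#' @export
filter_interactions <- function(targets, expr, min_predictors = 2, p_max = 0.05,
                                samples = NULL) {
  mi <- expr$miRNA$values
  keep <- targets$mirna_id %in% rownames(mi)
  for (cl in unique(targets$target_class)) {
    sel <- targets$target_class == cl
    keep[sel] <- keep[sel] & targets$target_id[sel] %in% rownames(expr[[cl]]$values)
  }
  if (any(!keep))
    message(sprintf("filter_interactions: dropped %d links with ids absent from matrices",
                    sum(!keep)))
  tt <- targets[keep, , drop = FALSE]
  if (!nrow(tt))
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), n_predictors = integer(0),
                      spearman_rho = numeric(0), spearman_p = numeric(0),
                      retained = logical(0)))
  shared <- colnames(mi)
  for (cl in unique(tt$target_class)) shared <- intersect(shared, colnames(expr[[cl]]$values))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  n <- length(shared)
  if (n < 4) stopf("filter_interactions: need >= 4 shared samples")
  rho <- p <- numeric(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    x <- mi[tt$mirna_id[i], shared]
    y <- expr[[tt$target_class[i]]]$values[tt$target_id[i], shared]
    r <- stats::cor(x, y, method = "spearman")
    rho[i] <- r
    if (is.na(r)) { p[i] <- NA_real_; next }
    rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
    p[i] <- 2 * stats::pt(-abs(rc * sqrt((n - 2) / (1 - rc^2))), n - 2)
    if (abs(r) >= 1) p[i] <- 0
  }
  res <- data.frame(mirna_id = tt$mirna_id, target_id = tt$target_id,
                    target_class = tt$target_class,
                    n_predictors = tt$n_predictors %||% lengths(strsplit(tt$predictors, ",")),
                    spearman_rho = rho, spearman_p = p, stringsAsFactors = FALSE)
  res$retained <- !is.na(rho) & res$n_predictors >= min_predictors &
    rho < 0 & p <= p_max
  res <- res[order(res$mirna_id, res$target_id), ]
  rownames(res) <- NULL
  res
}

#' Upper-tail hypergeometric test for shared miRNAs
#'
#' Probability that two RNAs with `K1` and `K2` bound miRNAs out of a
#' universe of `N` share at least `m` by chance:
#' P(X >= m) for X ~ Hypergeometric(N, K1, K2).
#'
#' @param N universe size (miRNAs in the retained interaction set)
#' @param K1,K2 miRNA set sizes of the two RNAs
#' @param m observed shared miRNAs
#' @return upper-tail p-value
#' @export
shared_mirna_hypergeom <- function(N, K1, K2, m) {
  if (any(c(N, K1, K2, m) < 0) || K1 > N || K2 > N || m > min(K1, K2))
    stopf("shared_mirna_hypergeom: inconsistent counts (N=%s, K1=%s, K2=%s, m=%s)",
          N, K1, K2, m)
  stats::phyper(m - 1, K1, N - K1, K2, lower.tail = FALSE)
}

#' Partial Pearson correlation given one conditioning vector
#'
#' `r_xy|z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, with a
#' two-sided p from the t transform with n - 3 df. A conditioner perfectly
#' correlated with either variable makes the partial correlation undefined
#' (degenerate flag).
#'
#' @param x,y,z numeric vectors of equal length (n >= 4)
#' @return list(r, p_value, df, degenerate)
#' @export
partial_pearson <- function(x, y, z) {
  n <- length(x)
  if (n < 4 || length(y) != n || length(z) != n)
    stopf("partial_pearson: need equal-length vectors, n >= 4")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (anyNA(c(rxy, rxz, ryz)) || abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    return(list(r = NA_real_, p_value = NA_real_, df = n - 3, degenerate = TRUE))
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- min(max(r, -1), 1)
  rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t_stat <- rc * sqrt((n - 3) / (1 - rc^2))
  p <- 2 * stats::pt(-abs(t_stat), n - 3)
  if (abs(r) >= 1) p <- 0
  list(r = r, p_value = p, df = n - 3, degenerate = FALSE)
}

#' Sensitivity correlation (SPPC) of a pair given shared miRNAs
#'
#' Per shared miRNA i, the sensitivity `S_i = r_xy - r_xy|z_i` measures how
#' much of the pair's correlation the miRNA explains; the pair's SPPC value
#' is the mean over shared miRNAs (degenerate conditioners are skipped).
#'
#' @param x,y expression vectors of the pair
#' @param Z matrix with one column per shared miRNA (or a single vector)
#' @return list(sppc_value, s = per-miRNA sensitivities, n_used)
#' @export
sensitivity_correlation <- function(x, y, Z) {
  if (is.vector(Z)) Z <- matrix(Z, ncol = 1)
  rxy <- stats::cor(x, y)
  s <- rep(NA_real_, ncol(Z))
  for (j in seq_len(ncol(Z))) {
    pp <- partial_pearson(x, y, Z[, j])
    if (!pp$degenerate) s[j] <- rxy - pp$r
  }
  ok <- !is.na(s)
  list(sppc_value = if (any(ok)) mean(s[ok]) else NA_real_, s = s, n_used = sum(ok))
}

#' Gaussian conditional mutual information with stratified permutation p
#'
#' `I(X;Y|Z) = -0.5 ln(1 - r_xy|z^2)` (nats), which is >= 0 and exactly 0
#' when the partial correlation vanishes. The p-value is a permutation test:
#' x is permuted within strata of the rank of z (preserving the x-z
#' dependence), the partial correlation recomputed, and the two-sided
#' exceedance probability returned as `(1 + #{|r*| >= |r|}) / (n_perm + 1)`.
#'
#' @param x,y,z numeric vectors (n >= 10)
#' @param n_perm number of permutations (default 1000)
#' @param n_strata number of z-rank strata (default: strata of ~7 samples)
#' @param seed optional integer seed for the permutations
#' @return list(cmi_value, cmi_p, r_partial, degenerate)
#' @export
conditional_mutual_information <- function(x, y, z, n_perm = 1000, n_strata = NULL,
                                           seed = NULL) {
  n <- length(x)
  if (n < 10) stopf("conditional_mutual_information: need n >= 10")
  pp <- partial_pearson(x, y, z)
  if (pp$degenerate)
    return(list(cmi_value = NA_real_, cmi_p = NA_real_, r_partial = NA_real_,
                degenerate = TRUE))
  cmi <- -0.5 * log(1 - pp$r^2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_strata)) n_strata <- max(2L, floor(n / 7))
  strata <- split(order(z), cut(seq_len(n), breaks = n_strata, labels = FALSE))
  xs <- as.numeric(scale(x)); ys <- as.numeric(scale(y)); zs <- as.numeric(scale(z))
  ryz <- sum(ys * zs) / (n - 1)
  idx <- matrix(0L, n, n_perm)
  base <- seq_len(n)
  for (b in seq_len(n_perm)) {
    perm <- base
    for (s in strata) perm[s] <- s[sample.int(length(s))]
    idx[, b] <- perm
  }
  XP <- matrix(xs[idx], n, n_perm)
  rxy_p <- as.numeric(crossprod(XP, ys)) / (n - 1)
  rxz_p <- as.numeric(crossprod(XP, zs)) / (n - 1)
  denom <- sqrt(pmax((1 - rxz_p^2) * (1 - ryz^2), 1e-300))
  r_p <- (rxy_p - rxz_p * ryz) / denom
  p <- (1 + sum(abs(r_p) >= abs(pp$r))) / (n_perm + 1)
  list(cmi_value = cmi, cmi_p = p, r_partial = pp$r, degenerate = FALSE)
}

#' Tier a scored ceRNA pair
#'
#' `highly_confident` requires all five criteria: hypergeometric
#' p <= `hyper_p`, positive Pearson correlation with p <= `pc_p`, partial
#' Pearson p <= `ppc_p`, SPPC value >= `sppc_min` and CMI permutation
#' p <= `cmi_p`. `moderate` requires the PC and PPC criteria only.
#' Otherwise `none`. NA statistics fail their criterion, so a pair with a
#' degenerate conditioner cannot be highly confident. Tiering is monotone:
#' relaxing any threshold never demotes a pair.
#'
#' @param pairs data frame with columns hyper_p, pc_r, pc_p, ppc_p,
#'   sppc_value, cmi_p (one row per pair)
#' @param thresholds named list; see [run_config()] defaults
#' @return character vector of tiers
#' @export
classify_pair <- function(pairs, thresholds = run_config()) {
  ok <- function(v) !is.na(v) & v
  pc_ok <- ok(pairs$pc_r > 0) & ok(pairs$pc_p <= thresholds$pc_p)
  ppc_ok <- ok(pairs$ppc_p <= thresholds$ppc_p)
  moderate <- pc_ok & ppc_ok
  high <- moderate & ok(pairs$hyper_p <= thresholds$hyper_p) &
    ok(pairs$sppc_value >= thresholds$sppc_min) &
    ok(pairs$cmi_p <= thresholds$cmi_p)
  ifelse(high, "highly_confident", ifelse(moderate, "moderate", "none"))
}

#' Score all ceRNA pairs from a retained interaction set
#'
#' Candidate pairs are all unordered pairs of RNAs (circRNA-circRNA,
#' circRNA-mRNA, mRNA-mRNA) in the retained interaction set that share at
#' least one miRNA. The miRNA universe N for the hypergeometric test is the
#' set of miRNAs appearing in the retained interactions. PPC/SPPC/CMI
#' condition on each shared miRNA separately; the pair's PPC and CMI
#' p-values aggregate conservatively (maximum across shared miRNAs, the
#' reported value being the one attaining it) and SPPC aggregates by mean.
#' CMI permutations are seeded per run for reproducibility.
#'
#' @param interactions output of [filter_interactions()]
#' @param expr named list of [expr_matrix()] per class
#' @param thresholds named list of tier thresholds; see [run_config()]
#' @param samples optional sample subset for the correlations
#' @param seed integer seed for CMI permutations
#' @return data frame, one row per candidate pair, with the hypergeometric
#'   counts and p, PC, PPC, SPPC, CMI statistics, shared miRNAs
#'   (comma-joined) and tier
#' @export
cerna_pairs <- function(interactions, expr, thresholds = run_config(),
                        samples = NULL, seed = thresholds$seed %||% 1) {
  ret <- interactions[interactions$retained, , drop = FALSE]
  empty <- data.frame(rna1_id = character(0), rna2_id = character(0),
                      pair_class = character(0), shared_mirnas = character(0),
                      n_universe = integer(0), k1 = integer(0), k2 = integer(0),
                      m = integer(0), hyper_p = numeric(0), pc_r = numeric(0),
                      pc_p = numeric(0), ppc_value = numeric(0), ppc_p = numeric(0),
                      sppc_value = numeric(0), cmi_value = numeric(0),
                      cmi_p = numeric(0), tier = character(0), stringsAsFactors = FALSE)
  if (!nrow(ret)) return(empty)
  mir_sets <- lapply(split(ret$mirna_id, ret$target_id), unique)
  classes <- ret$target_class[match(names(mir_sets), ret$target_id)]
  names(classes) <- names(mir_sets)
  N <- length(unique(ret$mirna_id))
  shared_samp <- Reduce(intersect, lapply(expr, function(e) colnames(e$values)))
  if (!is.null(samples)) shared_samp <- intersect(shared_samp, samples)
  n <- length(shared_samp)
  if (n < 10) stopf("cerna_pairs: need >= 10 shared samples")
  targets <- sort(names(mir_sets))
  set.seed(seed)
  out <- list()
  for (i in seq_along(targets)) {
    for (j in seq_len(i - 1L)) {
      t1 <- targets[j]; t2 <- targets[i]
      sh <- sort(intersect(mir_sets[[t1]], mir_sets[[t2]]))
      if (!length(sh)) next
      cl1 <- classes[t1]; cl2 <- classes[t2]
      pair_class <- paste(sort(c(cl1, cl2)), collapse = "-")
      x <- expr[[cl1]]$values[t1, shared_samp]
      y <- expr[[cl2]]$values[t2, shared_samp]
      k1 <- length(mir_sets[[t1]]); k2 <- length(mir_sets[[t2]]); m <- length(sh)
      hyper <- shared_mirna_hypergeom(N, k1, k2, m)
      pc_r <- stats::cor(x, y)
      rc <- pmin(pmax(pc_r, -1 + 1e-15), 1 - 1e-15)
      pc_p <- 2 * stats::pt(-abs(rc * sqrt((n - 2) / (1 - rc^2))), n - 2)
      ppc_r <- ppc_pv <- cmi_v <- cmi_pv <- rep(NA_real_, length(sh))
      s_vals <- rep(NA_real_, length(sh))
      for (k in seq_along(sh)) {
        z <- expr$miRNA$values[sh[k], shared_samp]
        pp <- partial_pearson(x, y, z)
        if (pp$degenerate) next
        ppc_r[k] <- pp$r; ppc_pv[k] <- pp$p_value
        s_vals[k] <- pc_r - pp$r
        cm <- conditional_mutual_information(x, y, z,
                                             n_perm = thresholds$cmi_n_perm %||% 1000)
        cmi_v[k] <- cm$cmi_value; cmi_pv[k] <- cm$cmi_p
      }
      agg <- thresholds$ppc_aggregate %||% "max"
      pick <- function(p_vec) {
        if (all(is.na(p_vec))) return(NA_integer_)
        if (agg == "min") which.min(p_vec) else which.max(p_vec)
      }
      kp <- pick(ppc_pv); kc <- pick(cmi_pv)
      out[[length(out) + 1]] <- data.frame(
        rna1_id = t1, rna2_id = t2, pair_class = pair_class,
        shared_mirnas = paste(sh, collapse = ","),
        n_universe = N, k1 = k1, k2 = k2, m = m, hyper_p = hyper,
        pc_r = pc_r, pc_p = pc_p,
        ppc_value = if (is.na(kp)) NA_real_ else ppc_r[kp],
        ppc_p = if (is.na(kp)) NA_real_ else ppc_pv[kp],
        sppc_value = if (any(!is.na(s_vals))) mean(s_vals, na.rm = TRUE) else NA_real_,
        cmi_value = if (is.na(kc)) NA_real_ else cmi_v[kc],
        cmi_p = if (is.na(kc)) NA_real_ else cmi_pv[kc],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  if ((thresholds$cerna_adjust %||% "none") == "BH") {
    res$pc_p <- bh_adjust(res$pc_p)
    res$ppc_p <- bh_adjust(res$ppc_p)
  }
  res$tier <- classify_pair(res, thresholds)
  res <- res[order(res$rna1_id, res$rna2_id), ]
  rownames(res) <- NULL
  res
}

#' Expand tiered ceRNA pairs into circRNA/mRNA-miRNA-RNA triplets
#'
#' One triplet per (pair, shared miRNA) for pairs at or above `min_tier`.
#' Deduplicated and deterministically ordered.
#'
#' @param pairs output of [cerna_pairs()]
#' @param min_tier `"moderate"` (default) or `"highly_confident"`
#' @return data frame: rna1_id, mirna_id, rna2_id, pair_class, tier,
#'   clinical_flag (NA until [intersect_clinical()])
#' @export
build_triplets <- function(pairs, min_tier = c("moderate", "highly_confident")) {
  min_tier <- match.arg(min_tier)
  keep_tiers <- if (min_tier == "moderate") c("moderate", "highly_confident") else
    "highly_confident"
  sel <- pairs[pairs$tier %in% keep_tiers, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(rna1_id = character(0), mirna_id = character(0),
                      rna2_id = character(0), pair_class = character(0),
                      tier = character(0), clinical_flag = logical(0),
                      stringsAsFactors = FALSE))
  mir <- strsplit(sel$shared_mirnas, ",", fixed = TRUE)
  res <- data.frame(rna1_id = rep(sel$rna1_id, lengths(mir)),
                    mirna_id = unlist(mir),
                    rna2_id = rep(sel$rna2_id, lengths(mir)),
                    pair_class = rep(sel$pair_class, lengths(mir)),
                    tier = rep(sel$tier, lengths(mir)),
                    clinical_flag = NA, stringsAsFactors = FALSE)
  res <- res[!duplicated(paste(res$rna1_id, res$mirna_id, res$rna2_id)), ]
  res <- res[order(res$rna1_id, res$mirna_id, res$rna2_id), ]
  rownames(res) <- NULL
  res
}

#' Flag triplets whose (circRNA, mRNA) pair is a clinically relevant
#' co-expression edge
#'
#' @param triplets output of [build_triplets()]
#' @param edges retained co-expression edges (`a_id`, `b_id`)
#' @return `triplets` with `clinical_flag` set
#' @export
intersect_clinical <- function(triplets, edges) {
  keys <- pair_key(edges$a_id, edges$b_id)
  triplets$clinical_flag <- pair_key(triplets$rna1_id, triplets$rna2_id) %in% keys
  triplets
}

#' Simple 7-mer seed-match target predictor (stand-in)
#'
#' Predicts a miRNA-target link when the reverse complement of the miRNA
#' seed (positions 2-8) occurs in the target sequence. This is a built-in
#' stand-in so the pipeline runs without external prediction tables; real
#' predictor tables are the primary path.
#'
#' @param mirna_seqs named character vector of miRNA sequences (RNA or DNA
#'   alphabet), or a FASTA path (read via the seqinr package)
#' @param target_seqs named character vector of target sequences or FASTA path
#' @param target_class class label for the targets
#' @param predictor_name registry name to emit (default `"seed7"`)
#' @return target-table data frame (mirna_id, target_id, target_class,
#'   predictors)
#' @export
seed_match_predict <- function(mirna_seqs, target_seqs, target_class = "mRNA",
                               predictor_name = "seed7") {
  load_fa <- function(x) {
    if (length(x) == 1 && is.null(names(x)) && file.exists(x)) {
      if (!requireNamespace("seqinr", quietly = TRUE))
        stopf("seed_match_predict: reading FASTA requires the seqinr package")
      fa <- seqinr::read.fasta(x, as.string = TRUE, forceDNAtolower = FALSE)
      stats::setNames(toupper(unlist(fa)), names(fa))
    } else toupper(x)
  }
  mirna_seqs <- load_fa(mirna_seqs); target_seqs <- load_fa(target_seqs)
  norm <- function(s) chartr("U", "T", s)
  revcomp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  out <- list()
  for (mi in names(mirna_seqs)) {
    s <- norm(mirna_seqs[[mi]])
    if (nchar(s) < 8) next
    site <- revcomp(substr(s, 2, 8))
    hits <- names(target_seqs)[grepl(site, norm(target_seqs), fixed = TRUE)]
    if (length(hits))
      out[[length(out) + 1]] <- data.frame(mirna_id = mi, target_id = hits,
                                           target_class = target_class,
                                           predictors = predictor_name,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      target_class = character(0), predictors = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$mirna_id, res$target_id), ]
}
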