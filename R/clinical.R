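# Association of deregulated features with clinical phenotypes (Welch t for
# binary groupings, log-rank for survival) and prognosis-direction calling.

#' Welch t-test between worse- and better-prognosis patient groups
#'
#' Values are log2 tumor expression. The group fold change is
#' `2^(mean_worse - mean_better)`. Degenerate cases: zero pooled variance
#' with different means gives p = 0 and a degenerate flag; either group
#' smaller than 2 returns a skipped result.
#'
#' @param worse log2 values in the worse-prognosis group
#' @param better log2 values in the better-prognosis group
#' @return list(group_fc, t_stat, df, p_value, n_worse, n_better,
#'   degenerate, skipped)
#' @export
associate_binary <- function(worse, better) {
  worse <- worse[!is.na(worse)]; better <- better[!is.na(better)]
  n1 <- length(worse); n2 <- length(better)
  if (n1 < 2 || n2 < 2)
    return(list(group_fc = NA_real_, t_stat = NA_real_, df = NA_real_,
                p_value = NA_real_, n_worse = n1, n_better = n2,
                degenerate = FALSE, skipped = TRUE))
  m1 <- mean(worse); m2 <- mean(better)
  se2 <- stats::var(worse) / n1 + stats::var(better) / n2
  fc <- 2^(m1 - m2)
  if (se2 == 0) {
    if (m1 == m2)
      return(list(group_fc = 1, t_stat = 0, df = n1 + n2 - 2, p_value = 1,
                  n_worse = n1, n_better = n2, degenerate = FALSE, skipped = FALSE))
    return(list(group_fc = fc, t_stat = sign(m1 - m2) * Inf, df = n1 + n2 - 2,
                p_value = 0, n_worse = n1, n_better = n2, degenerate = TRUE,
                skipped = FALSE))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((stats::var(worse) / n1)^2 / (n1 - 1) +
                 (stats::var(better) / n2)^2 / (n2 - 1))
  list(group_fc = fc, t_stat = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       n_worse = n1, n_better = n2, degenerate = FALSE, skipped = FALSE)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 df, via
#' [survival::survdiff()]. Requires at least one event; otherwise the test
#' is skipped.
#'
#' @param time survival times (months)
#' @param event 0/1 event indicator
#' @param group two-level grouping vector
#' @return list(chi2, p_value, obs, exp, n, skipped); `obs`/`exp` are the
#'   observed and expected event counts per group (named by group level)
#' @export
logrank_test <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- as.factor(as.character(group[keep]))
  if (nlevels(group) != 2 || sum(event) < 1 || min(table(group)) < 1)
    return(list(chi2 = NA_real_, p_value = NA_real_, obs = NULL, exp = NULL,
                n = length(time), skipped = TRUE))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = sd$chisq, p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       obs = stats::setNames(sd$obs, levels(group)),
       exp = stats::setNames(sd$exp, levels(group)),
       n = length(time), skipped = FALSE)
}

#' Associate DE features with clinical phenotypes
#'
#' For every feature called up or down and every clinical variable in
#' [worse_level_coding()]: binary variables (and grade binarized 1,2 vs 3,4)
#' are tested by Welch t on tumor-sample expression between the worse and
#' better patient groups, significant iff |group FC| >= `clin_fc` and
#' p <= `clin_p`; survival is tested by log-rank on a median tumor-expression
#' split, significant iff p <= `clin_p`. Direction is `higher_in_worse` when
#' the worse group (or, for survival, the group with excess observed events)
#' has higher expression. Missing clinical values are excluded per test.
#' Multiple testing across clinical variables is not corrected by default
#' (`adjust = "BH"` applies BH across all tests of a class).
#'
#' @param de DE table from [differential_expression()]
#' @param em [expr_matrix()] for the same class
#' @param clinical clinical table
#' @param clin_fc group fold-change gate (default 1.5)
#' @param clin_p p-value gate (default 0.05)
#' @param adjust `"none"` (default) or `"BH"`
#' @return data frame, one row per (feature, clinical variable) test
#' @export
clinical_associations <- function(de, em, clinical, clin_fc = 1.5, clin_p = 0.05,
                                  adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  feats <- de$feature_id[de$status != "ns"]
  coding <- worse_level_coding()
  tum <- clinical[clinical$tissue == "tumor", ]
  v <- em$values[, tum$sample_id, drop = FALSE]
  out <- list()
  for (f in feats) {
    x <- v[f, ]
    for (i in seq_len(nrow(coding))) {
      var <- coding$variable[i]
      rec <- list(feature_id = f, rna_class = em$rna_class, clinical_variable = var,
                  category = coding$category[i])
      if (coding$type[i] == "survival") {
        ok <- !is.na(tum$os_time) & !is.na(tum$os_event)
        med <- stats::median(x[ok])
        grp <- ifelse(x > med, "high", "low")
        lr <- logrank_test(tum$os_time[ok], tum$os_event[ok], grp[ok])
        if (lr$skipped) next
        # excess observed vs expected events in the high-expression group
        # means higher expression tracks worse survival
        dir <- if (lr$obs["high"] >= lr$exp["high"]) "higher_in_worse" else "higher_in_better"
        out[[length(out) + 1]] <- data.frame(
          rec, test = "logrank", n_worse = unname(lr$obs["high"] + 0),
          n_better = unname(lr$obs["low"] + 0), group_fc = NA_real_,
          stat = lr$chi2, p_value = lr$p_value, direction = dir,
          degenerate = FALSE, stringsAsFactors = FALSE)
        next
      }
      vals <- if (var == "grade") tum$grade else tum[[var]]
      if (is.null(vals)) next
      if (coding$type[i] == "grade") {
        worse_sel <- !is.na(vals) & vals %in% c(3, 4)
        better_sel <- !is.na(vals) & vals %in% c(1, 2)
      } else {
        wv <- as.numeric(coding$worse_value[i])
        worse_sel <- !is.na(vals) & vals == wv
        better_sel <- !is.na(vals) & vals != wv
      }
      ab <- associate_binary(x[worse_sel], x[better_sel])
      if (ab$skipped) next
      dir <- if (ab$group_fc >= 1) "higher_in_worse" else "higher_in_better"
      out[[length(out) + 1]] <- data.frame(
        rec, test = "welch_t", n_worse = ab$n_worse, n_better = ab$n_better,
        group_fc = ab$group_fc, stat = ab$t_stat, p_value = ab$p_value,
        direction = dir, degenerate = ab$degenerate, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(feature_id = character(0), rna_class = character(0),
                      clinical_variable = character(0), category = character(0),
                      test = character(0), n_worse = numeric(0), n_better = numeric(0),
                      group_fc = numeric(0), stat = numeric(0), p_value = numeric(0),
                      direction = character(0), degenerate = logical(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  p_use <- if (adjust == "BH") bh_adjust(res$p_value) else res$p_value
  lfc_ok <- ifelse(res$test == "logrank", TRUE,
                   abs(log2(res$group_fc)) >= log2(clin_fc))
  res$significant <- p_use <= clin_p & lfc_ok
  rownames(res) <- NULL
  res
}

#' Call prognosis direction per feature
#'
#' A feature is `worse_prognostic` iff it is up in tumors and every
#' significant clinical association has higher expression in the worse
#' group; `better_prognostic` iff it is down in tumors and every significant
#' association has higher expression in the better group; otherwise
#' `unclear`. Features with no significant association are not called.
#'
#' @param de DE table
#' @param assoc association table from [clinical_associations()]
#' @return data frame: feature_id, rna_class, status, n_significant,
#'   variables (comma-joined), call
#' @export
call_prognosis <- function(de, assoc) {
  sig <- assoc[assoc$significant, , drop = FALSE]
  feats <- sort(unique(sig$feature_id))
  if (!length(feats))
    return(data.frame(feature_id = character(0), rna_class = character(0),
                      status = character(0), n_significant = integer(0),
                      variables = character(0), call = character(0),
                      stringsAsFactors = FALSE))
  out <- lapply(feats, function(f) {
    rows <- sig[sig$feature_id == f, ]
    status <- de$status[match(f, de$feature_id)]
    dirs <- unique(rows$direction)
    call <- if (status == "up" && identical(dirs, "higher_in_worse")) "worse_prognostic"
            else if (status == "down" && identical(dirs, "higher_in_better")) "better_prognostic"
            else "unclear"
    data.frame(feature_id = f, rna_class = rows$rna_class[1], status = status,
               n_significant = nrow(rows),
               variables = paste(sort(unique(rows$clinical_variable)), collapse = ","),
               call = call, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Venn region counts for clinical-category feature sets
#'
#' @param sets named list of at most 3 character vectors (features associated
#'   with each clinical category)
#' @return data frame with one row per non-empty region label (e.g. `A&B`)
#'   and the count of features exactly in that region, plus the count of
#'   features in >= 2 sets as attribute `multi`
#' @export
venn_counts <- function(sets) {
  k <- length(sets)
  if (k < 1 || k > 3) stopf("venn_counts: between 1 and 3 sets required")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stopf("venn_counts: sets must be named")
  univ <- unique(unlist(sets))
  member <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, nm))
  out <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    sel <- rep(TRUE, length(univ))
    for (j in seq_len(k)) sel <- sel & (member[, j] == inset[j])
    out[[length(out) + 1]] <- data.frame(
      region = paste(nm[inset], collapse = "&"),
      n_sets = sum(inset), count = sum(sel), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "multi") <- if (length(univ)) sum(rowSums(member) >= 2) else 0L
  res
}
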