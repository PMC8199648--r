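# circRNA-mRNA co-expression networks: all-pairs correlation screening,
# connected components, greedy nodal (master) circRNA selection, and
# circRNA/host-gene fold-change concordance.

#' All-pairs correlation edges between two feature sets
#'
#' Pearson (default) or Spearman correlation of every row of `a` against
#' every row of `b` over the shared samples, with two-sided p from the
#' t transform (df = n - 2) and BH adjustment across all tested pairs.
#' An edge is retained iff |r| >= `r_min` and q <= `fdr`. Zero-variance
#' features are excluded from testing (reported via `message`).
#'
#' @param a,b [expr_matrix()] objects or plain feature x sample matrices
#' @param features_a,features_b optional row subsets
#' @param samples optional sample subset (default: shared samples)
#' @param r_min absolute correlation gate (default 0.7)
#' @param fdr BH FDR gate (default 0.05)
#' @param method `"pearson"` or `"spearman"`
#' @param all return all tested pairs (with `retained` flag) rather than
#'   retained edges only
#' @return data frame: a_id, b_id, r, p_value, q_value, method, retained
#' @export
cor_edges <- function(a, b, features_a = NULL, features_b = NULL, samples = NULL,
                      r_min = 0.7, fdr = 0.05, method = c("pearson", "spearman"),
                      all = FALSE) {
  method <- match.arg(method)
  A <- if (inherits(a, "expr_matrix")) a$values else a
  B <- if (inherits(b, "expr_matrix")) b$values else b
  if (!is.null(features_a)) A <- A[intersect(features_a, rownames(A)), , drop = FALSE]
  if (!is.null(features_b)) B <- B[intersect(features_b, rownames(B)), , drop = FALSE]
  shared <- intersect(colnames(A), colnames(B))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 4) stopf("cor_edges: need >= 4 shared samples")
  A <- A[, shared, drop = FALSE]; B <- B[, shared, drop = FALSE]
  va <- apply(A, 1, stats::var); vb <- apply(B, 1, stats::var)
  if (any(va == 0) || any(vb == 0)) {
    message(sprintf("cor_edges: skipping %d zero-variance features",
                    sum(va == 0) + sum(vb == 0)))
    A <- A[va > 0, , drop = FALSE]; B <- B[vb > 0, , drop = FALSE]
  }
  if (nrow(A) == 0 || nrow(B) == 0)
    return(data.frame(a_id = character(0), b_id = character(0), r = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      method = character(0), retained = logical(0)))
  n <- length(shared)
  R <- stats::cor(t(A), t(B), method = method)
  r <- as.vector(R)
  df <- data.frame(a_id = rep(rownames(A), times = ncol(R)),
                   b_id = rep(colnames(R), each = nrow(R)),
                   r = r, stringsAsFactors = FALSE)
  # guard |r| = 1 in the t transform
  rc <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- rc * sqrt((n - 2) / (1 - rc^2))
  df$p_value <- 2 * stats::pt(-abs(tt), n - 2)
  df$p_value[abs(r) >= 1] <- 0
  df$q_value <- bh_adjust(df$p_value)
  df$method <- method
  df$retained <- abs(df$r) >= r_min & df$q_value <= fdr
  df <- df[order(df$a_id, df$b_id), ]
  rownames(df) <- NULL
  if (all) df else df[df$retained, , drop = FALSE]
}

#' Pearson co-expression edges (study gate: |r| >= 0.7, FDR <= 0.05)
#'
#' Convenience wrapper around [cor_edges()] with the study's circRNA-mRNA
#' screening parameters.
#' @inheritParams cor_edges
#' @return retained edges (see [cor_edges()])
#' @export
pearson_edges <- function(a, b, features_a = NULL, features_b = NULL, samples = NULL,
                          r_min = 0.7, fdr = 0.05, all = FALSE) {
  cor_edges(a, b, features_a, features_b, samples, r_min, fdr,
            method = "pearson", all = all)
}

#' Connected components of an edge list
#'
#' Components are returned sorted by size (descending), ties broken by the
#' lexicographically smallest node id; node ids within a component are
#' sorted.
#'
#' @param edges data frame with node id columns `a_id`, `b_id`
#' @param nodes optional node universe (isolated nodes become singleton
#'   components)
#' @return list of character vectors
#' @export
network_components <- function(edges, nodes = NULL) {
  ids <- unique(c(edges$a_id, edges$b_id, nodes))
  if (!length(ids)) return(list())
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a_id, to = edges$b_id, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  cmp <- igraph::components(g)
  groups <- split(names(cmp$membership), cmp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, character(1), 1))
  unname(groups[ord])
}

#' Greedy nodal (master) circRNA selection by gene coverage
#'
#' Formalizes "a handful of circRNAs covering most network genes" as greedy
#' maximum coverage over the bipartite circRNA-gene edge set: repeatedly add
#' the circRNA covering the most still-uncovered genes (ties broken by
#' higher total degree, then lexicographically smaller id) until the
#' covered-gene fraction reaches `coverage_target`. If the target is
#' unreachable, the full useful selection is returned with a warning.
#'
#' @param edges bipartite edge data frame: `a_id` = circRNA, `b_id` = gene
#' @param coverage_target fraction of genes to cover (default 0.93)
#' @return list: `selected` (circRNA ids in selection order), `steps`
#'   (per-step data frame: circ_id, gain, covered, coverage), `coverage`
#'   (achieved fraction), `reached` (logical)
#' @export
nodal_cover <- function(edges, coverage_target = 0.93) {
  if (!nrow(edges))
    return(list(selected = character(0),
                steps = data.frame(circ_id = character(0), gain = integer(0),
                                   covered = integer(0), coverage = numeric(0)),
                coverage = 0, reached = FALSE))
  adj <- lapply(split(edges$b_id, edges$a_id), unique)
  genes <- unique(edges$b_id)
  total <- length(genes)
  deg <- lengths(adj)
  covered <- character(0)
  selected <- character(0)
  steps <- list()
  repeat {
    frac <- length(covered) / total
    if (frac >= coverage_target) break
    gains <- vapply(adj, function(s) length(setdiff(s, covered)), integer(1))
    gains[selected] <- -1L
    best <- max(gains)
    if (best <= 0) {
      warnf("nodal_cover: coverage target %.3f unreachable; achieved %.3f",
            coverage_target, frac)
      break
    }
    cand <- names(gains)[gains == best]
    cand <- cand[order(-deg[cand], cand)]
    pick <- cand[1]
    covered <- union(covered, adj[[pick]])
    selected <- c(selected, pick)
    steps[[length(steps) + 1]] <- data.frame(
      circ_id = pick, gain = best, covered = length(covered),
      coverage = length(covered) / total, stringsAsFactors = FALSE)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(circ_id = character(0), gain = integer(0),
               covered = integer(0), coverage = numeric(0))
  list(selected = selected, steps = steps, coverage = length(covered) / total,
       reached = length(covered) / total >= coverage_target)
}

#' circRNA / host-gene fold-change concordance
#'
#' Pearson correlation of (circRNA log2FC, host-gene log2FC) over annotated
#' circRNAs whose host gene is present in the mRNA DE table, with a quadrant
#' label per pair: ii = both up, iii = both down (concordant); i = circ
#' down / host up, iv = circ up / host down (discordant).
#'
#' @param circ_de circRNA DE table
#' @param mrna_de mRNA DE table
#' @param annotation circRNA annotation with `circ_id`, `host_gene`
#' @return list(r, n, pairs); `pairs` has circ_id, host_gene, circ_log2fc,
#'   host_log2fc, quadrant, concordant
#' @export
host_concordance <- function(circ_de, mrna_de, annotation) {
  df <- merge(circ_de[, c("feature_id", "log2fc")],
              annotation[, c("circ_id", "host_gene")],
              by.x = "feature_id", by.y = "circ_id")
  names(df)[names(df) == "log2fc"] <- "circ_log2fc"
  df <- merge(df, mrna_de[, c("feature_id", "log2fc")],
              by.x = "host_gene", by.y = "feature_id")
  names(df)[names(df) == "log2fc"] <- "host_log2fc"
  if (!nrow(df)) return(list(r = NA_real_, n = 0L,
                             pairs = data.frame(circ_id = character(0))))
  df$quadrant <- ifelse(df$circ_log2fc >= 0 & df$host_log2fc >= 0, "ii",
                 ifelse(df$circ_log2fc < 0 & df$host_log2fc < 0, "iii",
                 ifelse(df$circ_log2fc < 0, "i", "iv")))
  df$concordant <- df$quadrant %in% c("ii", "iii")
  df <- df[order(df$feature_id), c("feature_id", "host_gene", "circ_log2fc",
                                   "host_log2fc", "quadrant", "concordant")]
  names(df)[1] <- "circ_id"
  rownames(df) <- NULL
  r <- if (nrow(df) >= 3 && stats::sd(df$circ_log2fc) > 0 && stats::sd(df$host_log2fc) > 0)
    stats::cor(df$circ_log2fc, df$host_log2fc) else NA_real_
  list(r = r, n = nrow(df), pairs = df)
}
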