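# End-to-end orchestration: DE -> clinical association -> prognosis ->
# co-expression network + nodal cover -> ceRNA scoring/tiers -> triplets ->
# clinical intersection -> biomarker ROC -> (optional) enrichment -> report.
# Each stage reads its predecessors' files from the run directory and
# writes its own, so stage-by-stage execution composes identically to
# run_all().

PIPELINE_STAGES <- c("de", "clinical", "coexpr", "cerna", "biomarker",
                     "enrich", "report")

read_stage_cohort <- function(dir) {
  expr <- lapply(RNA_CLASSES, function(cl)
    read_expression_matrix(file.path(dir, paste0("expr_", cl, ".tsv")), cl, scale = "log2"))
  names(expr) <- RNA_CLASSES
  list(expr = expr, clinical = read_clinical_table(file.path(dir, "clinical.tsv")))
}

cor_sample_set <- function(clinical, config) {
  if (isTRUE(config$tumor_only)) clinical$sample_id[clinical$tissue == "tumor"] else NULL
}

stage_de <- function(dir, config) {
  ch <- read_stage_cohort(dir)
  for (cl in RNA_CLASSES) {
    de <- differential_expression(ch$expr[[cl]], ch$clinical,
                                  fc_threshold = config$fc_threshold,
                                  de_fdr = config$de_fdr,
                                  paired = config$de_paired,
                                  adjust = config$de_adjust)
    write_tsv(de, file.path(dir, paste0("de_", cl, ".tsv")))
    log_line(dir, sprintf("de[%s]: %d features -> %d up, %d down", cl, nrow(de),
                          sum(de$status == "up"), sum(de$status == "down")))
    de_feats <- de$feature_id[de$status != "ns"]
    if (length(de_feats) >= 2) {
      cs <- cluster_samples(ch$expr[[cl]], de_feats)
      write_tsv(data.frame(position = seq_along(cs$order), sample_id = cs$order),
                file.path(dir, paste0("sample_order_", cl, ".tsv")))
    }
  }
  invisible(dir)
}

stage_clinical <- function(dir, config) {
  ch <- read_stage_cohort(dir)
  assoc_all <- list(); prog_all <- list(); venn_all <- list()
  for (cl in RNA_CLASSES) {
    de <- read_tsv(file.path(dir, paste0("de_", cl, ".tsv")))
    assoc <- clinical_associations(de, ch$expr[[cl]], ch$clinical,
                                   clin_fc = config$clin_fc, clin_p = config$clin_p,
                                   adjust = config$clin_adjust)
    prog <- call_prognosis(de, assoc)
    assoc_all[[cl]] <- assoc; prog_all[[cl]] <- prog
    sig <- assoc[assoc$significant, , drop = FALSE]
    sets <- lapply(split(sig$feature_id, sig$category), unique)
    sets <- sets[lengths(sets) > 0]
    if (length(sets)) {
      vc <- venn_counts(sets)
      vc$rna_class <- cl
      vc$multi <- attr(vc, "multi")
      venn_all[[cl]] <- vc
    }
    log_line(dir, sprintf("clinical[%s]: %d DE features -> %d clinically associated",
                          cl, sum(de$status != "ns"), length(unique(sig$feature_id))))
  }
  write_tsv(do.call(rbind, assoc_all), file.path(dir, "assoc.tsv"))
  write_tsv(do.call(rbind, prog_all), file.path(dir, "prognosis.tsv"))
  vc <- if (length(venn_all)) do.call(rbind, venn_all) else
    data.frame(region = character(0), n_sets = integer(0), count = integer(0),
               rna_class = character(0), multi = integer(0))
  write_tsv(vc, file.path(dir, "venn.tsv"))
  invisible(dir)
}

stage_coexpr <- function(dir, config) {
  ch <- read_stage_cohort(dir)
  de_c <- read_tsv(file.path(dir, "de_circRNA.tsv"))
  de_m <- read_tsv(file.path(dir, "de_mRNA.tsv"))
  assoc <- read_tsv(file.path(dir, "assoc.tsv"))
  sig_circ <- unique(assoc$feature_id[assoc$significant & assoc$rna_class == "circRNA"])
  circ_set <- intersect(de_c$feature_id[de_c$status != "ns"], sig_circ)
  mrna_set <- de_m$feature_id[de_m$status != "ns"]
  samples <- cor_sample_set(ch$clinical, config)
  edges <- if (length(circ_set) && length(mrna_set))
    pearson_edges(ch$expr$circRNA, ch$expr$mRNA, circ_set, mrna_set,
                  samples = samples, r_min = config$coexpr_r, fdr = config$coexpr_fdr)
  else data.frame(a_id = character(0), b_id = character(0), r = numeric(0),
                  p_value = numeric(0), q_value = numeric(0), method = character(0),
                  retained = logical(0))
  write_tsv(edges, file.path(dir, "edges.tsv"))
  log_line(dir, sprintf("coexpr: %d circ x %d mRNA -> %d retained edges",
                        length(circ_set), length(mrna_set), nrow(edges)))
  comps <- network_components(edges)
  comp_df <- if (length(comps)) do.call(rbind, lapply(seq_along(comps), function(i)
    data.frame(component = i, size = length(comps[[i]]), node_id = comps[[i]],
               stringsAsFactors = FALSE))) else
    data.frame(component = integer(0), size = integer(0), node_id = character(0))
  write_tsv(comp_df, file.path(dir, "components.tsv"))
  nc <- nodal_cover(edges, coverage_target = config$coverage_target)
  write_tsv(nc$steps, file.path(dir, "nodal.tsv"))
  log_line(dir, sprintf("coexpr: nodal cover %d circRNAs, coverage %.3f",
                        length(nc$selected), nc$coverage))
  annot_path <- file.path(dir, "annotation.tsv")
  hc_row <- data.frame(r = NA_real_, n = 0L)
  if (file.exists(annot_path)) {
    hc <- host_concordance(de_c, de_m, read_circ_annotation(annot_path))
    write_tsv(hc$pairs, file.path(dir, "host_concordance.tsv"))
    hc_row <- data.frame(r = hc$r, n = hc$n)
  }
  write_tsv(hc_row, file.path(dir, "host_concordance_summary.tsv"))
  prog <- read_tsv(file.path(dir, "prognosis.tsv"))
  node_ids <- sort(unique(c(edges$a_id, edges$b_id)))
  if (length(node_ids)) {
    nodes <- data.frame(id = node_ids,
                        type = ifelse(node_ids %in% de_c$feature_id, "circRNA", "mRNA"),
                        prognosis = ifelse(node_ids %in% prog$feature_id,
                                           prog$call[match(node_ids, prog$feature_id)],
                                           "not_associated"),
                        nodal = node_ids %in% nc$selected,
                        stringsAsFactors = FALSE)
    edge_exp <- data.frame(source = edges$a_id, relation = "coexpr",
                           target = edges$b_id, stringsAsFactors = FALSE)
    write_network(nodes, edge_exp, file.path(dir, "network.sif"), "SIF")
    write_network(nodes, edge_exp, file.path(dir, "network.graphml"), "GraphML")
  }
  invisible(dir)
}

stage_cerna <- function(dir, config) {
  ch <- read_stage_cohort(dir)
  targets <- read_target_table(file.path(dir, "targets.tsv"))
  de <- lapply(RNA_CLASSES, function(cl) read_tsv(file.path(dir, paste0("de_", cl, ".tsv"))))
  names(de) <- RNA_CLASSES
  de_ids <- lapply(de, function(d) d$feature_id[d$status != "ns"])
  keep <- targets$mirna_id %in% de_ids$miRNA &
    ((targets$target_class == "circRNA" & targets$target_id %in% de_ids$circRNA) |
     (targets$target_class == "mRNA" & targets$target_id %in% de_ids$mRNA))
  samples <- cor_sample_set(ch$clinical, config)
  inter <- filter_interactions(targets[keep, , drop = FALSE], ch$expr,
                               min_predictors = config$min_predictors,
                               p_max = config$interaction_p, samples = samples)
  write_tsv(inter, file.path(dir, "interactions.tsv"))
  log_line(dir, sprintf("cerna: %d candidate links -> %d retained",
                        nrow(inter), sum(inter$retained)))
  pairs <- cerna_pairs(inter, ch$expr, thresholds = config, samples = samples,
                       seed = config$seed)
  write_tsv(pairs, file.path(dir, "pairs.tsv"))
  trip <- build_triplets(pairs, min_tier = "moderate")
  edges <- read_tsv(file.path(dir, "edges.tsv"))
  trip <- intersect_clinical(trip, edges)
  write_tsv(trip, file.path(dir, "triplets.tsv"))
  log_line(dir, sprintf("cerna: %d pairs (%d highly confident) -> %d triplets (%d clinical)",
                        nrow(pairs), sum(pairs$tier == "highly_confident"),
                        nrow(trip), sum(trip$clinical_flag)))
  invisible(dir)
}

stage_biomarker <- function(dir, config) {
  ch <- read_stage_cohort(dir)
  nodal <- read_tsv(file.path(dir, "nodal.tsv"))
  feats <- nodal$circ_id
  if (!length(feats)) {
    write_tsv(data.frame(contrast = character(0), name = character(0),
                         kind = character(0), n_pos = integer(0), n_neg = integer(0),
                         auc = numeric(0), auc_p = numeric(0), youden_cut = numeric(0),
                         sensitivity = numeric(0), specificity = numeric(0),
                         separable = logical(0)),
              file.path(dir, "roc.tsv"))
    log_line(dir, "biomarker: no nodal circRNAs, skipped")
    return(invisible(dir))
  }
  panels <- list(nodal_panel = feats[seq_len(min(config$panel_size, length(feats)))])
  rc <- roc_contrasts(ch$expr$circRNA, ch$clinical, feats, panels, ridge = config$ridge)
  write_tsv(rc, file.path(dir, "roc.tsv"))
  log_line(dir, sprintf("biomarker: %d nodal circRNAs over %d contrasts",
                        length(feats), length(unique(rc$contrast))))
  invisible(dir)
}

stage_enrich <- function(dir, config) {
  gmt_path <- file.path(dir, "genesets.gmt")
  if (!file.exists(gmt_path)) {
    log_line(dir, "enrich: no genesets.gmt, skipped")
    return(invisible(dir))
  }
  sets <- read_gmt(gmt_path)
  edges <- read_tsv(file.path(dir, "edges.tsv"))
  de_m <- read_tsv(file.path(dir, "de_mRNA.tsv"))
  query <- sort(unique(edges$b_id))
  if (!length(query)) {
    log_line(dir, "enrich: empty network gene list, skipped")
    return(invisible(dir))
  }
  enr <- ora(query, sets, background = de_m$feature_id)
  write_tsv(enr, file.path(dir, "enrichment.tsv"))
  log_line(dir, sprintf("enrich: %d sets tested on %d network genes",
                        nrow(enr), length(query)))
  invisible(dir)
}

stage_report <- function(dir, config) {
  de <- lapply(RNA_CLASSES, function(cl) read_tsv(file.path(dir, paste0("de_", cl, ".tsv"))))
  names(de) <- RNA_CLASSES
  assoc <- read_tsv(file.path(dir, "assoc.tsv"))
  prog <- read_tsv(file.path(dir, "prognosis.tsv"))
  edges <- read_tsv(file.path(dir, "edges.tsv"))
  comps <- read_tsv(file.path(dir, "components.tsv"))
  nodal <- read_tsv(file.path(dir, "nodal.tsv"))
  inter <- read_tsv(file.path(dir, "interactions.tsv"))
  pairs <- read_tsv(file.path(dir, "pairs.tsv"))
  trip <- read_tsv(file.path(dir, "triplets.tsv"))
  hc <- read_tsv(file.path(dir, "host_concordance_summary.tsv"))
  roc_path <- file.path(dir, "roc.tsv")
  roc <- if (file.exists(roc_path)) read_tsv(roc_path) else NULL
  sig <- assoc[assoc$significant, , drop = FALSE]
  per_class <- lapply(RNA_CLASSES, function(cl) {
    d <- de[[cl]]
    list(n_features = nrow(d), up = sum(d$status == "up"), down = sum(d$status == "down"),
         clinically_associated = length(unique(sig$feature_id[sig$rna_class == cl])))
  })
  names(per_class) <- RNA_CLASSES
  comp_sizes <- if (nrow(comps)) as.integer(tapply(comps$size, comps$component, max)) else integer(0)
  tier_tab <- table(factor(pairs$tier, levels = c("highly_confident", "moderate", "none")))
  n_trip <- nrow(trip)
  n_clin_trip <- if (n_trip) sum(trip$clinical_flag) else 0L
  stopifnot(n_clin_trip <= n_trip)
  panel_auc <- if (!is.null(roc) && nrow(roc)) {
    pr <- roc[roc$kind == "panel", ]
    stats::setNames(as.list(pr$auc), paste0(pr$contrast, ".", pr$name))
  } else list()
  report <- list(
    package_version = as.character(utils::packageVersion("cernet")),
    seed = config$seed,
    config = config,
    de = per_class,
    prognosis = as.list(table(factor(prog$call, levels = c("worse_prognostic",
                                                           "better_prognostic", "unclear")))),
    coexpr = list(n_edges = nrow(edges), n_components = length(comp_sizes),
                  component_sizes = comp_sizes,
                  nodal = nodal$circ_id,
                  nodal_coverage = if (nrow(nodal)) nodal$coverage[nrow(nodal)] else 0,
                  host_concordance_r = hc$r[1], host_concordance_n = hc$n[1]),
    cerna = list(n_links_tested = nrow(inter), n_links_retained = sum(inter$retained),
                 n_pairs = nrow(pairs),
                 n_highly_confident = unname(tier_tab[["highly_confident"]]),
                 n_moderate = unname(tier_tab[["moderate"]]),
                 n_triplets = n_trip, n_clinical_triplets = n_clin_trip),
    biomarker = list(panel_auc = panel_auc))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    "ceRNA network pipeline run report",
    sprintf("seed: %d", config$seed),
    sprintf("DE (|FC| >= %.2f, FDR <= %.2f):", config$fc_threshold, config$de_fdr),
    vapply(RNA_CLASSES, function(cl) sprintf(
      "  %s: %d up / %d down of %d; clinically associated: %d", cl,
      per_class[[cl]]$up, per_class[[cl]]$down, per_class[[cl]]$n_features,
      per_class[[cl]]$clinically_associated), character(1)),
    sprintf("prognosis calls: %s", paste(names(table(prog$call)),
                                         table(prog$call), sep = "=", collapse = ", ")),
    sprintf("co-expression edges (|r| >= %.2f, FDR <= %.2f): %d in %d component(s)",
            config$coexpr_r, config$coexpr_fdr, nrow(edges), length(comp_sizes)),
    sprintf("nodal circRNAs: %s (coverage %.3f)",
            paste(nodal$circ_id, collapse = ", "),
            if (nrow(nodal)) nodal$coverage[nrow(nodal)] else 0),
    sprintf("ceRNA: %d retained links, %d pairs (%d highly confident, %d moderate)",
            sum(inter$retained), nrow(pairs), unname(tier_tab[["highly_confident"]]),
            unname(tier_tab[["moderate"]])),
    sprintf("triplets: %d (%d clinically relevant)", n_trip, n_clin_trip))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(report)
}

#' Run one pipeline stage against a run directory
#'
#' Stages read their inputs from files written by earlier stages, so
#' running them one at a time composes identically to [run_all()].
#'
#' @param stage one of `"de"`, `"clinical"`, `"coexpr"`, `"cerna"`,
#'   `"biomarker"`, `"enrich"`, `"report"`
#' @param dir run directory holding the cohort TSVs
#' @param config a [run_config()]
#' @return invisibly, the directory (or, for `"report"`, the report list)
#' @export
run_stage <- function(stage, dir, config = run_config()) {
  stage <- match.arg(stage, PIPELINE_STAGES)
  fn <- switch(stage, de = stage_de, clinical = stage_clinical,
               coexpr = stage_coexpr, cerna = stage_cerna,
               biomarker = stage_biomarker, enrich = stage_enrich,
               report = stage_report)
  tryCatch(fn(dir, config),
           error = function(e) stopf("pipeline stage '%s' failed: %s", stage,
                                     conditionMessage(e)))
}

#' Run the full pipeline
#'
#' Executes the workflow stages in order against `dir`. If `sim` is a
#' [sim_config()], the cohort is first simulated and written to `dir`. The
#' run is a pure function of (inputs, config, seed): re-running with the
#' same inputs produces byte-identical outputs.
#'
#' @param dir run directory; must contain (or will receive) the cohort TSVs
#' @param config a [run_config()]
#' @param sim optional [sim_config()] to generate the cohort first
#' @return the run report (list), invisibly
#' @export
run_all <- function(dir, config = run_config(), sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim)) write_cohort(simulate_cohort(sim), dir)
  unlink(file.path(dir, "run_log.txt"))
  log_line(dir, sprintf("run_all: seed %d", config$seed))
  for (stage in setdiff(PIPELINE_STAGES, "report")) run_stage(stage, dir, config)
  invisible(run_stage("report", dir, config))
}
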