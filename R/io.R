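# Readers and writers for the pipeline's external formats. No statistics here.

RNA_CLASSES <- c("circRNA", "miRNA", "mRNA")

#' Construct an expression matrix object
#'
#' A lightweight container for a features x samples matrix of log2 expression
#' values together with its RNA class and the scale it was read on.
#'
#' @param values numeric matrix, rows = features, columns = samples, with
#'   unique dimnames; values are on the log2 scale.
#' @param rna_class one of `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @param scale_flag scale the source file was on (`"log2"` or `"linear"`).
#' @return an object of class `expr_matrix`: a list with elements `values`,
#'   `rna_class`, `scale_flag`.
#' @export
expr_matrix <- function(values, rna_class, scale_flag = "log2") {
  rna_class <- match.arg(rna_class, RNA_CLASSES)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs feature and sample ids as dimnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate feature ids: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample ids: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!is.finite(values)))
    stopf("expression matrix contains %d non-finite values after load",
          sum(!is.finite(values)))
  structure(list(values = values, rna_class = rna_class, scale_flag = scale_flag),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %s: %d features x %d samples (source scale: %s)\n",
              x$rna_class, nrow(x$values), ncol(x$values), x$scale_flag))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' First column = feature id, header row = sample ids. Values are stored on
#' the log2 scale; linear inputs are transformed as `log2(x + pseudocount)`.
#' With `scale = "auto"` the file is treated as linear when any value exceeds
#' 30 (log2 expression from arrays or RNA-seq summaries stays well below
#' that), otherwise as log2.
#'
#' @param path file path
#' @param rna_class RNA class of the features
#' @param scale `"log2"`, `"linear"` or `"auto"`
#' @param pseudocount added before log2 for linear inputs
#' @param na_action `"error"` (default) or `"drop"` rows containing missing
#'   values (the number dropped is reported via `message`)
#' @return an [expr_matrix()]
#' @export
read_expression_matrix <- function(path, rna_class, scale = c("auto", "log2", "linear"),
                                   pseudocount = 1, na_action = c("error", "drop")) {
  scale <- match.arg(scale)
  na_action <- match.arg(na_action)
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stopf("%s: expected feature id column plus sample columns", path)
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stopf("%s: duplicate feature ids: %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals), dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stopf("%s: non-numeric value '%s' at feature '%s', sample '%s'", path,
          vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]], colnames(vals)[bad[1, 2]])
  rownames(num) <- ids
  if (anyNA(num)) {
    if (na_action == "error")
      stopf("%s: %d missing values (set na_action='drop' to drop those rows)",
            path, sum(is.na(num)))
    drop <- rowSums(is.na(num)) > 0
    message(sprintf("%s: dropped %d/%d features containing missing values",
                    path, sum(drop), length(drop)))
    num <- num[!drop, , drop = FALSE]
  }
  scale_flag <- scale
  if (scale == "auto") scale_flag <- if (max(num) > 30) "linear" else "log2"
  if (scale_flag == "linear") {
    if (any(num < 0)) stopf("%s: negative values in a linear-scale matrix", path)
    num <- log2(num + pseudocount)
  }
  expr_matrix(num, rna_class, scale_flag = scale_flag)
}

#' Write an expression matrix as TSV (log2 values)
#' @param em [expr_matrix()]
#' @param path output path
#' @return invisibly, `path`
#' @export
write_expression_matrix <- function(em, path) {
  df <- data.frame(feature_id = rownames(em$values),
                   as.data.frame(em$values, check.names = FALSE),
                   check.names = FALSE)
  write_tsv(df, path)
}

CLINICAL_COLUMNS <- c("patient_id", "sample_id", "tissue", "grade", "size_group",
                      "encapsulation", "degree_encapsulation", "vascular_invasion",
                      "tumor_invasion", "stage_group", "os_time", "os_event")

#' Clinical-variable coding: which level means worse prognosis
#'
#' One row per clinical variable used by the association stage, with its
#' type, the level coding worse prognosis, and its category grouping
#' (tumor properties / invasion & metastasis / prognosis). The coding is
#' total: every testable variable maps to a declared worse level. Binary
#' variables use 0/1 codes: size_group 1 = large, encapsulation 1 = capsule
#' present, degree_encapsulation 1 = complete capsule, vascular_invasion and
#' tumor_invasion 1 = present, stage_group 1 = late stage. Tumor grade is
#' binarized 1,2 vs 3,4; survival is tested by log-rank on a median
#' expression split.
#'
#' @return data frame with columns `variable`, `type`, `worse_value`,
#'   `category`
#' @export
worse_level_coding <- function() {
  data.frame(
    variable = c("grade", "size_group", "encapsulation", "degree_encapsulation",
                 "vascular_invasion", "tumor_invasion", "stage_group", "survival"),
    type = c("grade", "binary", "binary", "binary", "binary", "binary", "binary",
             "survival"),
    worse_value = c("3,4", "1", "0", "0", "1", "1", "1", NA),
    category = c("tumor_properties", "tumor_properties", "tumor_properties",
                 "tumor_properties", "invasion_metastasis", "invasion_metastasis",
                 "prognosis", "prognosis"),
    stringsAsFactors = FALSE)
}

#' Read and validate a per-sample clinical sheet
#'
#' Tab-delimited, one row per sample. Required columns: `patient_id`,
#' `sample_id`, `tissue` (`tumor`/`non_tumor`). Recognized clinical columns:
#' grade (1-4), size_group, encapsulation, degree_encapsulation,
#' vascular_invasion, tumor_invasion, stage_group (0/1 codes; see
#' [worse_level_coding()]), os_time (months), os_event (0/1). Unknown columns
#' are dropped with a warning. The paired design is enforced: every patient
#' must have exactly one tumor and one non-tumor sample. Missing clinical
#' values are allowed and excluded per-test downstream.
#'
#' @param path file path
#' @return validated data frame of class `clinical_table`
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_clinical_table(df, src = path)
}

#' Validate a clinical table already in memory
#' @param df data frame
#' @param src label used in error messages
#' @return the validated table, class `clinical_table`
#' @export
validate_clinical_table <- function(df, src = "clinical table") {
  need <- c("patient_id", "sample_id", "tissue")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing required columns: %s", src, paste(miss, collapse = ", "))
  unknown <- setdiff(names(df), CLINICAL_COLUMNS)
  if (length(unknown)) {
    warnf("%s: ignoring unknown columns: %s", src, paste(unknown, collapse = ", "))
    df <- df[, setdiff(names(df), unknown), drop = FALSE]
  }
  if (anyDuplicated(df$sample_id))
    stopf("%s: duplicate sample ids", src)
  if (!all(df$tissue %in% c("tumor", "non_tumor")))
    stopf("%s: tissue must be 'tumor' or 'non_tumor'", src)
  tab <- table(df$patient_id, df$tissue)
  bad <- rownames(tab)[tab[, match("tumor", colnames(tab))] != 1 |
                       tab[, match("non_tumor", colnames(tab))] != 1]
  if (length(bad))
    stopf("%s: paired design violated for patient(s): %s", src, paste(bad, collapse = ", "))
  if ("grade" %in% names(df)) {
    g <- df$grade[!is.na(df$grade)]
    if (length(g) && (!all(g %in% 1:4)))
      stopf("%s: grade outside 1-4: %s", src, paste(unique(g[!g %in% 1:4]), collapse = ", "))
  }
  if ("os_time" %in% names(df) && any(df$os_time < 0, na.rm = TRUE))
    stopf("%s: negative os_time", src)
  if ("os_event" %in% names(df)) {
    e <- df$os_event[!is.na(df$os_event)]
    if (length(e) && !all(e %in% c(0, 1))) stopf("%s: os_event must be 0/1", src)
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a miRNA-target prediction table
#'
#' Tab-delimited with columns `mirna_id`, `target_id`, `target_class`
#' (`circRNA`/`mRNA`) and `predictors` (comma-joined predictor names from a
#' declared registry, e.g. miranda,pita). Duplicate (miRNA, target) records
#' are an error.
#'
#' @param path file path
#' @param predictor_registry allowed predictor names
#' @return data frame with the `predictors` column kept comma-joined and an
#'   added `n_predictors` count
#' @export
read_target_table <- function(path, predictor_registry = c("miranda", "pita")) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_target_table(df, predictor_registry, src = path)
}

#' Validate a target table in memory
#' @param df data frame with mirna_id, target_id, target_class, predictors
#' @param predictor_registry allowed predictor names
#' @param src label for error messages
#' @return validated data frame
#' @export
validate_target_table <- function(df, predictor_registry = c("miranda", "pita"),
                                  src = "target table") {
  need <- c("mirna_id", "target_id", "target_class", "predictors")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing columns: %s", src, paste(miss, collapse = ", "))
  key <- paste(df$mirna_id, df$target_id)
  if (anyDuplicated(key))
    stopf("%s: duplicate (mirna, target) records: %s", src,
          paste(utils::head(unique(key[duplicated(key)]), 3), collapse = "; "))
  if (!all(df$target_class %in% c("circRNA", "mRNA")))
    stopf("%s: target_class must be circRNA or mRNA", src)
  preds <- strsplit(df$predictors, ",", fixed = TRUE)
  unknown <- setdiff(unique(unlist(preds)), predictor_registry)
  if (length(unknown))
    stopf("%s: predictors outside the registry (%s): %s", src,
          paste(predictor_registry, collapse = ", "), paste(unknown, collapse = ", "))
  df$n_predictors <- lengths(preds)
  df
}

#' Write a target table as TSV
#' @param df target table
#' @param path output path
#' @return invisibly, `path`
#' @export
write_target_table <- function(df, path) {
  keep <- intersect(c("mirna_id", "target_id", "target_class", "predictors"), names(df))
  write_tsv(df[, keep, drop = FALSE], path)
}

#' Read a circRNA annotation table
#'
#' Columns: `circ_id`, `chrom`, `start`, `end` (1-based inclusive), `strand`
#' (+/-), `host_gene`, `circ_type` (exonic/intronic/intergenic/sense/antisense).
#' @param path file path
#' @return validated data frame
#' @export
read_circ_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("circ_id", "chrom", "start", "end", "strand", "host_gene", "circ_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("%s: missing columns: %s", path, paste(miss, collapse = ", "))
  if (any(df$start > df$end)) stopf("%s: start > end", path)
  types <- c("exonic", "intronic", "intergenic", "sense", "antisense")
  if (!all(df$circ_type %in% types))
    stopf("%s: circ_type outside {%s}", path, paste(types, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stopf("%s: strand must be + or -", path)
  df
}

#' Read a GMT gene-set file
#'
#' Standard dialect: one set per line, tab-delimited: name, description,
#' then members. Lines with fewer than 3 fields are an error (reported with
#' the line number).
#'
#' @param path file path
#' @return named list of character vectors; each has a `description` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stopf("%s: line %d has %d fields, expected >= 3 (name, description, members)",
            path, i, length(parts))
    nm <- parts[1]
    if (nm %in% names(sets)) stopf("%s: duplicate set name '%s' (line %d)", path, nm, i)
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stopf("%s: empty set '%s' (line %d)", path, nm, i)
    sets[[nm]] <- structure(members, description = parts[2])
  }
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors (optional `description` attribute)
#' @param path output path
#' @return invisibly, `path`
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description") %||% ""
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network for Cytoscape import (SIF or GraphML)
#'
#' Deterministic output: edges are written in the order given, node
#' attributes in fixed column order.
#'
#' @param nodes data frame with column `id` plus arbitrary attribute columns
#' @param edges data frame with columns `source`, `relation`, `target`
#' @param path output path
#' @param format `"SIF"` or `"GraphML"`
#' @return invisibly, `path`
#' @export
write_network <- function(nodes, edges, path, format = c("SIF", "GraphML")) {
  format <- match.arg(format)
  if (nrow(edges) && !all(c(edges$source, edges$target) %in% nodes$id))
    stopf("network export: edges reference unknown nodes")
  if (format == "SIF") {
    lines <- if (nrow(edges)) paste(edges$source, edges$relation, edges$target, sep = "\t") else character(0)
    solo <- setdiff(nodes$id, c(edges$source, edges$target))
    writeLines(c(lines, solo), path)
    return(invisible(path))
  }
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  attrs <- setdiff(names(nodes), "id")
  for (a in attrs) {
    key <- xml2::xml_add_child(doc, "key", id = a, `for` = "node",
                               `attr.name` = a, `attr.type` = "string")
  }
  xml2::xml_add_child(doc, "key", id = "relation", `for` = "edge",
                      `attr.name` = "relation", `attr.type` = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = nodes$id[i])
    for (a in attrs) {
      d <- xml2::xml_add_child(nd, "data", key = a)
      xml2::xml_text(d) <- as.character(nodes[[a]][i])
    }
  }
  for (i in seq_len(nrow(edges))) {
    ed <- xml2::xml_add_child(g, "edge", source = edges$source[i], target = edges$target[i])
    d <- xml2::xml_add_child(ed, "data", key = "relation")
    xml2::xml_text(d) <- as.character(edges$relation[i])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Default run configuration
#'
#' Every threshold in the pipeline in one place. Values follow the study
#' design: DE gate |FC| >= 1.5 at BH FDR <= 0.05; clinical gate |FC| >= 1.5
#' at raw p <= 0.05; co-expression |r| >= 0.7 at BH FDR <= 0.05;
#' miRNA-target retention needs both registry predictors, negative Spearman
#' rho and p <= 0.05; ceRNA tiers use raw p <= 0.05 per statistic with
#' `sppc_min` an artifact calibration parameter. `tumor_only = FALSE`
#' computes correlations over all samples (tumor + non-tumor).
#'
#' @param ... overrides of any default
#' @return named list
#' @export
run_config <- function(...) {
  cfg <- list(
    fc_threshold = 1.5, de_fdr = 0.05, de_paired = TRUE, de_adjust = "BH",
    clin_fc = 1.5, clin_p = 0.05, clin_adjust = "none",
    coexpr_r = 0.7, coexpr_fdr = 0.05, coexpr_method = "pearson",
    tumor_only = FALSE, coverage_target = 0.93,
    min_predictors = 2, interaction_p = 0.05,
    hyper_p = 0.05, pc_p = 0.05, ppc_p = 0.05, sppc_min = 0.1, cmi_p = 0.05,
    cmi_n_perm = 1000, ppc_aggregate = "max", cerna_adjust = "none",
    panel_size = 4, ridge = 1e-6,
    pseudocount = 1, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a YAML run configuration
#' @param path YAML file; keys as in [run_config()]
#' @return config list
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#' @param cfg config list
#' @param path output path
#' @return invisibly, `path`
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
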