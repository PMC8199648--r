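# Paired tumor/non-tumor cohort simulator with planted differential
# expression, planted grade associations and planted miRNA-mediated ceRNA
# triplets, plus the ground truth needed to score recovery at every stage.

#' Simulation configuration
#'
#' Defaults emulate the study design this pipeline targets: 49 patients with
#' one tumor and one matched non-tumor sample each, planted log2 fold change
#' 1.5 for differentially expressed features, per-sample noise SD 0.5 log2
#' units. Feature counts are desk-scale (150/60/300) with 10% of circRNAs
#' and mRNAs and 20% of miRNAs differentially expressed, echoing the
#' relative DE rates of bulk tumor profiling. `coupling_b` (default 2.3)
#' and `baseline_sd` (default 0.75) jointly place planted triplet members
#' in the regime the pipeline's gates screen for: circRNA-mRNA marginal
#' correlations around 0.85 (clearing the |r| >= 0.7 gate) while the
#' coupling-induced extra variance still leaves the paired DE t-statistic
#' near 3.5, detectable at FDR 0.05.
#'
#' @param n_patients number of paired patients
#' @param n_circ,n_mirna,n_mrna feature counts per RNA class
#' @param frac_de fraction of features differentially expressed, scalar or
#'   named per-class vector (`circRNA`, `miRNA`, `mRNA`)
#' @param log2fc_de planted tumor - non-tumor log2 fold change
#' @param n_clin_assoc DE features per class additionally shifted by tumor
#'   grade (planted clinical association); triplet miRNAs fill these slots
#'   first so the grade signal propagates through the ceRNA coupling
#' @param grade_shift log2 units added per grade step above 1 (signed by the
#'   feature's DE direction)
#' @param n_triplets planted circRNA-miRNA-mRNA ceRNA triplets
#' @param coupling_b strength of miRNA-mediated suppression: tumor values of
#'   the triplet circRNA and mRNA receive `-coupling_b * (m - mean(m))`
#'   where `m` is the triplet miRNA's tumor abundance
#' @param noise_sd per-sample noise SD (log2)
#' @param baseline_mean,baseline_sd distribution of the per-feature,
#'   per-patient baseline (shared within a patient pair)
#' @param n_survival DE features whose tumor expression scales the hazard
#' @param survival_scale baseline mean survival (months)
#' @param survival_effect hazard multiplier per SD of tumor expression
#' @param censor_max independent uniform censoring horizon (months)
#' @param decoy_factor decoy miRNA-target links per planted link
#' @param host_frac probability a DE circRNA's host gene is a DE mRNA with
#'   the same direction (drives host-gene concordance)
#' @param seed integer seed; one global seed drives all draws
#' @return validated config list of class `sim_config`
#' @export
sim_config <- function(n_patients = 49, n_circ = 150, n_mirna = 60, n_mrna = 300,
                       frac_de = c(circRNA = 0.10, miRNA = 0.20, mRNA = 0.10),
                       log2fc_de = 1.5, n_clin_assoc = 10, grade_shift = 0.4,
                       n_triplets = 10, coupling_b = 2.3, noise_sd = 0.5,
                       baseline_mean = 8, baseline_sd = 0.75,
                       n_survival = 3, survival_scale = 60, survival_effect = 2,
                       censor_max = 120, decoy_factor = 5, host_frac = 0.6,
                       seed = 1) {
  if (length(frac_de) == 1) frac_de <- c(circRNA = frac_de, miRNA = frac_de, mRNA = frac_de)
  frac_de <- frac_de[RNA_CLASSES]
  cfg <- as.list(environment())
  counts <- c(n_patients, n_circ, n_mirna, n_mrna, n_clin_assoc, n_triplets,
              n_survival, decoy_factor)
  if (any(counts < 0)) stopf("sim_config: counts must be >= 0")
  if (any(frac_de < 0 | frac_de > 1)) stopf("sim_config: frac_de must be in [0,1]")
  if (noise_sd <= 0) stopf("sim_config: noise_sd must be > 0")
  structure(cfg, class = "sim_config")
}

#' Simulate a paired tumor/non-tumor cohort with planted structure
#'
#' Generative model, per RNA class: a per-feature, per-patient baseline
#' `N(baseline_mean, baseline_sd)` shared by the patient's two samples, plus
#' `N(0, noise_sd)` per sample. Planted DE features add `+/- log2fc_de` to
#' tumor samples; planted clinically associated features additionally add
#' `grade_shift * (grade - 1)` (signed by DE direction); for each planted
#' triplet the centered tumor abundance of its miRNA is subtracted (scaled
#' by `coupling_b`) from both the circRNA's and the mRNA's tumor values,
#' inducing miRNA-target inverse correlation and miRNA-mediated
#' circRNA-mRNA positive correlation that attenuates under conditioning on
#' the miRNA. Survival times are exponential with hazard scaled by
#' `survival_effect` per SD of tumor expression of the planted survival
#' features, with independent uniform censoring. The target table contains
#' all planted (miRNA, target) links labelled by both registry predictors
#' plus `decoy_factor` times as many random decoy links.
#'
#' @param config a [sim_config()]
#' @return list with elements `expr` (list of [expr_matrix()] per class),
#'   `clinical` (clinical table), `targets` (target table), `annotation`
#'   (circRNA annotation), `truth` (planted ground truth: `de` per class
#'   with direction, `clin_assoc`, `triplets`, `coupled_pairs`, `survival`)
#'   and `config`
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_patients
  patients <- sprintf("P%02d", seq_len(np))
  n_feat <- c(circRNA = config$n_circ, miRNA = config$n_mirna, mRNA = config$n_mrna)
  ids <- list(circRNA = sprintf("circR%04d", seq_len(n_feat["circRNA"])),
              miRNA = sprintf("miR%04d", seq_len(n_feat["miRNA"])),
              mRNA = sprintf("gene%04d", seq_len(n_feat["mRNA"])))

  # clinical phenotypes drawn before expression so planted clinical effects
  # are causal in the simulation
  grade <- sample(1:4, np, replace = TRUE)
  binv <- function() sample(0:1, np, replace = TRUE)
  clin_pat <- data.frame(patient_id = patients, grade = grade,
                         size_group = binv(), encapsulation = binv(),
                         degree_encapsulation = binv(), vascular_invasion = binv(),
                         tumor_invasion = binv(), stage_group = binv(),
                         stringsAsFactors = FALSE)

  # planted DE features and directions
  n_de <- round(config$frac_de * n_feat)
  names(n_de) <- RNA_CLASSES
  if (config$n_triplets > 0) {
    if (n_de["circRNA"] < config$n_triplets || n_de["mRNA"] < config$n_triplets ||
        n_de["miRNA"] < config$n_triplets)
      stopf("simulate_cohort: n_triplets (%d) exceeds planted DE features per class",
            config$n_triplets)
  }
  de <- list()
  for (cl in RNA_CLASSES) {
    feats <- if (n_de[cl] > 0) sort(sample(ids[[cl]], n_de[cl])) else character(0)
    dir <- if (n_de[cl] > 0) sample(c(1, -1), n_de[cl], replace = TRUE) else numeric(0)
    de[[cl]] <- data.frame(feature_id = feats, direction = dir, stringsAsFactors = FALSE)
  }
  # triplet members come from the planted DE sets: circRNA/mRNA forced up,
  # miRNA forced down (the canonical oncogenic sponge configuration)
  triplets <- data.frame(circ_id = character(0), mirna_id = character(0),
                         mrna_id = character(0), stringsAsFactors = FALSE)
  if (config$n_triplets > 0) {
    tc <- sample(de$circRNA$feature_id, config$n_triplets)
    tm <- sample(de$miRNA$feature_id, config$n_triplets)
    tg <- sample(de$mRNA$feature_id, config$n_triplets)
    de$circRNA$direction[de$circRNA$feature_id %in% tc] <- 1
    de$miRNA$direction[de$miRNA$feature_id %in% tm] <- -1
    de$mRNA$direction[de$mRNA$feature_id %in% tg] <- 1
    triplets <- data.frame(circ_id = tc, mirna_id = tm, mrna_id = tg,
                           stringsAsFactors = FALSE)
  }
  # clinically associated features: DE features shifted by grade. Triplet
  # miRNAs are included first: their grade shift propagates through the
  # ceRNA coupling to the triplet circRNA and mRNA, which makes the planted
  # triplets clinically relevant end to end (the structure the pipeline
  # screens for). Triplet circRNAs/mRNAs are not directly shifted; their
  # induced associations are recorded in the truth with mode "induced".
  clin_assoc <- data.frame(feature_id = character(0), rna_class = character(0),
                           variable = character(0), mode = character(0),
                           stringsAsFactors = FALSE)
  for (cl in RNA_CLASSES) {
    k <- min(config$n_clin_assoc, n_de[cl])
    if (k == 0) next
    pool <- de[[cl]]$feature_id
    excl <- switch(cl, circRNA = triplets$circ_id, mRNA = triplets$mrna_id,
                   miRNA = character(0))
    pref <- if (cl == "miRNA") intersect(pool, triplets$mirna_id) else character(0)
    rest <- setdiff(pool, union(pref, excl))
    pick <- c(pref, sample(rest))
    pick <- pick[seq_len(min(k, length(pick)))]
    if (!length(pick)) next
    clin_assoc <- rbind(clin_assoc,
                        data.frame(feature_id = sort(pick), rna_class = cl,
                                   variable = "grade", mode = "planted",
                                   stringsAsFactors = FALSE))
  }
  if (nrow(triplets) > 0) {
    coupled_mi <- triplets$mirna_id %in% clin_assoc$feature_id
    if (any(coupled_mi)) {
      ind <- rbind(
        data.frame(feature_id = triplets$circ_id[coupled_mi], rna_class = "circRNA",
                   variable = "grade", mode = "induced", stringsAsFactors = FALSE),
        data.frame(feature_id = triplets$mrna_id[coupled_mi], rna_class = "mRNA",
                   variable = "grade", mode = "induced", stringsAsFactors = FALSE))
      clin_assoc <- rbind(clin_assoc, ind)
    }
  }

  samp_t <- paste0(patients, "_T")
  samp_n <- paste0(patients, "_N")
  gen_class <- function(cl) {
    nf <- n_feat[cl]
    base <- matrix(stats::rnorm(nf * np, config$baseline_mean, config$baseline_sd),
                   nf, np, dimnames = list(ids[[cl]], patients))
    tum <- base + matrix(stats::rnorm(nf * np, 0, config$noise_sd), nf, np)
    non <- base + matrix(stats::rnorm(nf * np, 0, config$noise_sd), nf, np)
    if (nrow(de[[cl]]) > 0)
      tum[de[[cl]]$feature_id, ] <- tum[de[[cl]]$feature_id, ] +
        de[[cl]]$direction * config$log2fc_de
    ca <- clin_assoc[clin_assoc$rna_class == cl & clin_assoc$mode == "planted", ]
    if (nrow(ca) > 0) {
      dirs <- de[[cl]]$direction[match(ca$feature_id, de[[cl]]$feature_id)]
      tum[ca$feature_id, ] <- tum[ca$feature_id, ] +
        outer(dirs * config$grade_shift, grade - 1)
    }
    list(tumor = tum, non_tumor = non)
  }
  mats <- lapply(RNA_CLASSES, gen_class)
  names(mats) <- RNA_CLASSES

  # miRNA-mediated coupling for planted triplets (tumor samples only)
  for (i in seq_len(nrow(triplets))) {
    m <- mats$miRNA$tumor[triplets$mirna_id[i], ]
    delta <- -config$coupling_b * (m - mean(m))
    mats$circRNA$tumor[triplets$circ_id[i], ] <-
      mats$circRNA$tumor[triplets$circ_id[i], ] + delta
    mats$mRNA$tumor[triplets$mrna_id[i], ] <-
      mats$mRNA$tumor[triplets$mrna_id[i], ] + delta
  }

  # survival: hazard scaled by planted survival features' tumor expression
  all_de <- do.call(rbind, lapply(RNA_CLASSES, function(cl)
    if (nrow(de[[cl]])) data.frame(feature_id = de[[cl]]$feature_id, rna_class = cl,
                                   stringsAsFactors = FALSE)))
  surv_feats <- data.frame(feature_id = character(0), rna_class = character(0))
  lp <- rep(0, np)
  if (config$n_survival > 0 && !is.null(all_de) && nrow(all_de) > 0) {
    k <- min(config$n_survival, nrow(all_de))
    sel <- all_de[sort(sample(nrow(all_de), k)), ]
    surv_feats <- sel
    for (i in seq_len(nrow(sel))) {
      v <- mats[[sel$rna_class[i]]]$tumor[sel$feature_id[i], ]
      lp <- lp + log(config$survival_effect) * as.numeric(scale(v))
    }
  }
  hazard <- exp(lp) / config$survival_scale
  t_event <- stats::rexp(np, rate = hazard)
  t_cens <- stats::runif(np, 0, config$censor_max)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)

  clinical <- rbind(
    data.frame(clin_pat, sample_id = samp_t, tissue = "tumor",
               os_time = os_time, os_event = os_event, stringsAsFactors = FALSE),
    data.frame(clin_pat, sample_id = samp_n, tissue = "non_tumor",
               os_time = os_time, os_event = os_event, stringsAsFactors = FALSE))
  clinical <- clinical[, c("patient_id", "sample_id", "tissue", "grade", "size_group",
                           "encapsulation", "degree_encapsulation", "vascular_invasion",
                           "tumor_invasion", "stage_group", "os_time", "os_event")]
  clinical <- validate_clinical_table(clinical, src = "simulated clinical table")

  expr <- lapply(RNA_CLASSES, function(cl) {
    vals <- cbind(mats[[cl]]$tumor, mats[[cl]]$non_tumor)
    colnames(vals) <- c(samp_t, samp_n)
    expr_matrix(vals, cl)
  })
  names(expr) <- RNA_CLASSES

  # target table: planted links (both predictors) + decoys with mixed labels
  planted <- data.frame(mirna_id = character(0), target_id = character(0),
                        target_class = character(0), predictors = character(0),
                        stringsAsFactors = FALSE)
  if (nrow(triplets) > 0) {
    planted <- rbind(
      data.frame(mirna_id = triplets$mirna_id, target_id = triplets$circ_id,
                 target_class = "circRNA", predictors = "miranda,pita",
                 stringsAsFactors = FALSE),
      data.frame(mirna_id = triplets$mirna_id, target_id = triplets$mrna_id,
                 target_class = "mRNA", predictors = "miranda,pita",
                 stringsAsFactors = FALSE))
  }
  n_decoy <- config$decoy_factor * nrow(planted)
  decoys <- NULL
  if (n_decoy > 0) {
    pool_t <- rbind(data.frame(target_id = ids$circRNA, target_class = "circRNA",
                               stringsAsFactors = FALSE),
                    data.frame(target_id = ids$mRNA, target_class = "mRNA",
                               stringsAsFactors = FALSE))
    dm <- sample(ids$miRNA, n_decoy, replace = TRUE)
    dt <- pool_t[sample(nrow(pool_t), n_decoy, replace = TRUE), ]
    pred_pool <- c("miranda,pita", "miranda,pita", "miranda", "pita")
    decoys <- data.frame(mirna_id = dm, target_id = dt$target_id,
                         target_class = dt$target_class,
                         predictors = sample(pred_pool, n_decoy, replace = TRUE),
                         stringsAsFactors = FALSE)
  }
  targets <- rbind(planted, decoys)
  if (nrow(targets) > 0) {
    targets <- targets[!duplicated(paste(targets$mirna_id, targets$target_id)), ]
    targets <- targets[order(targets$mirna_id, targets$target_id), ]
    rownames(targets) <- NULL
  }
  targets <- validate_target_table(targets, src = "simulated target table")

  # circRNA annotation: DE circRNAs preferentially hosted by a same-direction
  # DE mRNA so that host-gene concordance is positive, as in real tumors
  host <- sample(ids$mRNA, n_feat["circRNA"], replace = TRUE)
  names(host) <- ids$circRNA
  if (nrow(de$circRNA) > 0 && nrow(de$mRNA) > 0) {
    for (i in seq_len(nrow(de$circRNA))) {
      same <- de$mRNA$feature_id[de$mRNA$direction == de$circRNA$direction[i]]
      if (length(same) && stats::runif(1) < config$host_frac)
        host[de$circRNA$feature_id[i]] <- sample(same, 1)
    }
  }
  starts <- sample(1e4:1e8, n_feat["circRNA"], replace = TRUE)
  annotation <- data.frame(
    circ_id = ids$circRNA,
    chrom = paste0("chr", sample(c(1:22, "X"), n_feat["circRNA"], replace = TRUE)),
    start = starts, end = starts + sample(200:5000, n_feat["circRNA"], replace = TRUE),
    strand = sample(c("+", "-"), n_feat["circRNA"], replace = TRUE),
    host_gene = unname(host),
    circ_type = sample(c("exonic", "intronic", "intergenic", "sense", "antisense"),
                       n_feat["circRNA"], replace = TRUE,
                       prob = c(0.85, 0.06, 0.04, 0.03, 0.02)),
    stringsAsFactors = FALSE)

  truth <- list(de = de, clin_assoc = clin_assoc, triplets = triplets,
                coupled_pairs = if (nrow(triplets)) data.frame(
                  circ_id = triplets$circ_id, mrna_id = triplets$mrna_id,
                  stringsAsFactors = FALSE) else
                  data.frame(circ_id = character(0), mrna_id = character(0)),
                survival = surv_feats)
  list(expr = expr, clinical = clinical, targets = targets,
       annotation = annotation, truth = truth, config = config)
}

#' Score recovery of planted structure
#'
#' @param calls character vector of called identifiers (any stage)
#' @param truth character vector of planted identifiers
#' @return list with `sensitivity` = |calls intersect truth| / |truth|
#'   (NA when truth is empty), `fdp` = |calls minus truth| / |calls|
#'   (0 when there are no calls), and the counts
#' @export
score_recovery <- function(calls, truth) {
  calls <- unique(calls); truth <- unique(truth)
  tp <- length(intersect(calls, truth))
  list(sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
       fdp = if (length(calls)) (length(calls) - tp) / length(calls) else 0,
       n_calls = length(calls), n_truth = length(truth), n_hit = tp)
}

#' Shuffle the miRNA column of a target table (negative control)
#'
#' Destroys the planted miRNA-target pairing while preserving the marginal
#' distribution of miRNAs and targets; duplicates created by the shuffle are
#' dropped.
#' @param targets target table
#' @param seed integer seed
#' @return shuffled target table
#' @export
shuffle_target_mirnas <- function(targets, seed = 1) {
  set.seed(seed)
  targets$mirna_id <- sample(targets$mirna_id)
  targets <- targets[!duplicated(paste(targets$mirna_id, targets$target_id)), ]
  rownames(targets) <- NULL
  targets
}

#' Write a simulated cohort to a directory of TSV files
#' @param cohort result of [simulate_cohort()]
#' @param dir output directory (created if needed)
#' @return invisibly, `dir`
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(cohort$expr))
    write_expression_matrix(cohort$expr[[cl]], file.path(dir, paste0("expr_", cl, ".tsv")))
  write_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_target_table(cohort$targets, file.path(dir, "targets.tsv"))
  write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  if (!is.null(cohort$truth))
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory path
#' @return cohort list (without `config`; `truth` present if truth.json exists)
#' @export
read_cohort <- function(dir) {
  expr <- lapply(RNA_CLASSES, function(cl)
    read_expression_matrix(file.path(dir, paste0("expr_", cl, ".tsv")), cl, scale = "log2"))
  names(expr) <- RNA_CLASSES
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path))
    jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
  list(expr = expr,
       clinical = read_clinical_table(file.path(dir, "clinical.tsv")),
       targets = read_target_table(file.path(dir, "targets.tsv")),
       annotation = read_circ_annotation(file.path(dir, "annotation.tsv")),
       truth = truth)
}
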