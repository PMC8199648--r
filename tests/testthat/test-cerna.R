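test_that("interaction filtering applies predictor and inverse-correlation gates", {
  n <- 20
  set.seed(7)
  m <- matrix(rnorm(n), 1, dimnames = list("miR1", paste0("s", 1:n)))
  # target strictly decreasing in the miRNA: rho = -1
  tgt <- rbind(anti = -2 * m[1, ] + 100, rand = rnorm(n))
  colnames(tgt) <- colnames(m)
  expr <- list(miRNA = expr_matrix(m, "miRNA"), mRNA = expr_matrix(tgt, "mRNA"))
  targets <- validate_target_table(data.frame(
    mirna_id = "miR1", target_id = c("anti", "rand"),
    target_class = "mRNA", predictors = c("miranda,pita", "miranda,pita"),
    stringsAsFactors = FALSE))
  res <- filter_interactions(targets, expr)
  expect_equal(res$spearman_rho[res$target_id == "anti"], -1)
  expect_true(res$retained[res$target_id == "anti"])

  # one predictor only: never retained regardless of rho
  targets1 <- validate_target_table(data.frame(
    mirna_id = "miR1", target_id = "anti", target_class = "mRNA",
    predictors = "pita", stringsAsFactors = FALSE))
  res1 <- filter_interactions(targets1, expr)
  expect_false(res1$retained)

  # links with unknown ids are dropped with a message
  targets2 <- validate_target_table(data.frame(
    mirna_id = c("miR1", "miRX"), target_id = c("anti", "anti"),
    target_class = "mRNA", predictors = "miranda,pita", stringsAsFactors = FALSE))
  expect_message(res2 <- filter_interactions(targets2, expr), "dropped 1")
  expect_equal(nrow(res2), 1L)
})

test_that("Spearman gate p-values agree with an exact permutation oracle at small n", {
  # exact permutation p for rho on n = 7: enumerate all 5040 permutations
  set.seed(9)
  x <- rnorm(7); y <- rnorm(7)
  rho_obs <- stats::cor(x, y, method = "spearman")
  perms <- combinat_perms <- NULL
  all_p <- gtools_perm <- NULL
  # enumerate permutations without extra packages
  perm_rec <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perm_rec(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  rhos <- vapply(perm_rec(seq_len(7)), function(p)
    stats::cor(x, y[p], method = "spearman"), numeric(1))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  # the t approximation should be within a factor ~2 of the exact value here
  rc <- rho_obs
  p_t <- 2 * stats::pt(-abs(rc * sqrt((7 - 2) / (1 - rc^2))), 7 - 2)
  expect_lt(abs(p_t - p_exact), max(0.05, p_exact))
})

test_that("shared-miRNA hypergeometric matches enumeration on worked examples", {
  # m = 0 is never surprising
  expect_equal(shared_mirna_hypergeom(10, 4, 3, 0), 1)
  # N=10, K1=4, K2=3, m=2 -> 36/120 + 4/120 = 1/3
  expect_equal(shared_mirna_hypergeom(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  expect_equal(hyper_enum(10, 4, 3, 2), 1 / 3, tolerance = 1e-12)
  # N=20, K1=5, K2=5, m=5 -> 1/C(20,5)
  expect_equal(shared_mirna_hypergeom(20, 5, 5, 5), 1 / choose(20, 5), tolerance = 1e-15)
  expect_equal(shared_mirna_hypergeom(20, 5, 5, 5), 6.450e-05, tolerance = 1e-4)
  expect_error(shared_mirna_hypergeom(10, 12, 3, 2), "inconsistent")
})

test_that("partial correlation matches the formula and the residual oracle", {
  # formula collapse when z is uncorrelated with x and y is checked via the
  # closed form: r_xy|z = (0.9 - 0.36)/0.64 = 0.84375 for rxy=.9, rxz=ryz=.6
  r <- (0.9 - 0.6 * 0.6) / sqrt((1 - 0.36) * (1 - 0.36))
  expect_equal(r, 0.84375)

  set.seed(12)
  for (i in 1:50) {
    n <- sample(10:40, 1)
    z <- rnorm(n); x <- 0.5 * z + rnorm(n); y <- -0.3 * z + rnorm(n)
    pp <- partial_pearson(x, y, z)
    expect_equal(pp$r, partial_resid(x, y, z), tolerance = 1e-10)
  }

  # degenerate conditioner
  x <- rnorm(10)
  expect_true(partial_pearson(x, rnorm(10), x)$degenerate)
})

test_that("sensitivity correlation aggregates per-miRNA drops by mean", {
  # S = r_xy - r_xy|z; with the 0.9/0.6/0.6 pattern S = 0.9 - 0.84375
  expect_equal(0.9 - 0.84375, 0.05625)

  # conditioning on independent z gives S ~ 0 (exactly 0 at the population
  # level; equality to r - r|z is checked mechanically)
  set.seed(13)
  x <- rnorm(30); y <- x + rnorm(30, 0, 0.5)
  z1 <- x + rnorm(30, 0, 0.5); z2 <- rnorm(30)
  sc <- sensitivity_correlation(x, y, cbind(z1, z2))
  r_xy <- stats::cor(x, y)
  s1 <- r_xy - partial_pearson(x, y, z1)$r
  s2 <- r_xy - partial_pearson(x, y, z2)$r
  expect_equal(sc$sppc_value, mean(c(s1, s2)), tolerance = 1e-12)
  expect_equal(sc$s, c(s1, s2), tolerance = 1e-12)

  # two shared miRNAs with S = 0.2 and 0.0 average to 0.1 (mean rule)
  expect_equal(mean(c(0.2, 0)), 0.1)
})

test_that("Gaussian CMI follows the closed form and is nonnegative", {
  # r_xy|z = 0.84375 -> I = -0.5 ln(1 - 0.84375^2) ~ 0.6222 nats
  expect_equal(-0.5 * log(1 - 0.84375^2), 0.6222, tolerance = 1e-4)

  set.seed(14)
  z <- rnorm(40); x <- z + rnorm(40); y <- z + rnorm(40)
  cm <- conditional_mutual_information(x, y, z, n_perm = 99, seed = 1)
  pp <- partial_pearson(x, y, z)
  expect_equal(cm$cmi_value, -0.5 * log(1 - pp$r^2), tolerance = 1e-12)
  expect_gte(cm$cmi_value, 0)

  # seeded permutations are reproducible
  cm2 <- conditional_mutual_information(x, y, z, n_perm = 99, seed = 1)
  expect_identical(cm$cmi_p, cm2$cmi_p)
})

test_that("tier assignment integrates the five criteria and is monotone", {
  base <- data.frame(hyper_p = 0.01, pc_r = 0.8, pc_p = 0.001, ppc_p = 0.01,
                     sppc_value = 0.2, cmi_p = 0.01)
  th <- run_config()
  expect_equal(classify_pair(base, th), "highly_confident")

  # PC+PPC pass, CMI fails -> moderate
  mod <- transform(base, cmi_p = 0.5)
  expect_equal(classify_pair(mod, th), "moderate")

  # negative PC correlation -> none regardless of p
  neg <- transform(base, pc_r = -0.8)
  expect_equal(classify_pair(neg, th), "none")

  # NA statistics fail their criterion
  na_cmi <- transform(base, cmi_p = NA_real_)
  expect_equal(classify_pair(na_cmi, th), "moderate")

  # monotonicity: relaxing thresholds never demotes
  set.seed(15)
  rank_tier <- function(t) match(t, c("none", "moderate", "highly_confident"))
  for (i in 1:200) {
    pair <- data.frame(hyper_p = runif(1), pc_r = runif(1, -1, 1), pc_p = runif(1),
                       ppc_p = runif(1), sppc_value = runif(1, -0.2, 0.4),
                       cmi_p = runif(1))
    strict <- run_config(hyper_p = 0.02, pc_p = 0.02, ppc_p = 0.02,
                         sppc_min = 0.2, cmi_p = 0.02)
    relaxed <- run_config(hyper_p = 0.2, pc_p = 0.2, ppc_p = 0.2,
                          sppc_min = 0.0, cmi_p = 0.2)
    expect_gte(rank_tier(classify_pair(pair, relaxed)),
               rank_tier(classify_pair(pair, strict)))
  }
})

test_that("pair scoring and triplet expansion recover planted structure", {
  co <- default_cohort(1)
  inter <- filter_interactions(co$targets, co$expr)
  pairs <- cerna_pairs(inter, co$expr, thresholds = run_config(cmi_n_perm = 199), seed = 1)
  trip <- build_triplets(pairs, min_tier = "moderate")
  truth_keys <- paste(co$truth$triplets$circ_id, co$truth$triplets$mirna_id,
                      co$truth$triplets$mrna_id)
  call_keys <- unique(c(paste(trip$rna1_id, trip$mirna_id, trip$rna2_id),
                        paste(trip$rna2_id, trip$mirna_id, trip$rna1_id)))
  rec <- score_recovery(call_keys[call_keys %in% truth_keys | !duplicated(call_keys)],
                        truth_keys)
  expect_gt(sum(truth_keys %in% call_keys) / length(truth_keys), 0.7)

  # a pair with 2 shared miRNAs yields 2 triplets
  fake <- data.frame(rna1_id = "a", rna2_id = "b", pair_class = "circRNA-mRNA",
                     shared_mirnas = "m1,m2", tier = "moderate",
                     stringsAsFactors = FALSE)
  expect_equal(nrow(build_triplets(fake)), 2L)

  # clinical intersection flags only triplets backed by a co-expression edge
  tr <- build_triplets(fake)
  edges <- data.frame(a_id = "a", b_id = "b")
  expect_true(all(intersect_clinical(tr, edges)$clinical_flag))
  expect_false(any(intersect_clinical(tr, edges[0, ])$clinical_flag))
})

test_that("hypergeometric wrapper equals enumeration over a lattice of cases", {
  for (N in c(5, 9, 14)) for (K1 in c(0, 2, N %/% 2, N)) for (K2 in c(1, N %/% 3)) {
    hi <- min(K1, K2)
    for (m in unique(c(0, 1, hi))) {
      if (m > hi) next
      expect_equal(shared_mirna_hypergeom(N, K1, K2, m), hyper_enum(N, K1, K2, m),
                   tolerance = 1e-12)
    }
  }
})

test_that("the 7-mer seed-match stand-in finds reverse-complement sites", {
  # miRNA seed (positions 2-8) = CGAUCGA -> site on target = TCGATCG
  mir <- c(miRX = "ACGAUCGAUUUU")
  hit <- c(t1 = "AAATCGATCGAAA", t2 = "AAAAAAAA")
  res <- seed_match_predict(mir, hit, target_class = "mRNA")
  expect_equal(res$target_id, "t1")
  expect_equal(res$predictors, "seed7")
})
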