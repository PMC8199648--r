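test_that("ROC AUC matches exhaustive pair counting on worked examples", {
  # positives {3,5}, negatives {1,4}: 3 of 4 pairs concordant
  r <- roc_auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 0.75)

  # perfect separation
  r2 <- roc_auc(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 1)
  expect_equal(r2$sensitivity, 1)
  expect_equal(r2$specificity, 1)

  # all scores tied: AUC = 0.5 by the tie correction
  r3 <- roc_auc(rep(2, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r3$auc, 0.5)
  expect_equal(r3$auc_p, 1)

  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC AUC equals brute-force pair counting on random instances", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    scores <- sample(1:8, n, replace = TRUE) + ifelse(runif(n) < 0.5, 0, 0.5)
    labels <- runif(n) < 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels)$auc, auc_pairs(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone and the Youden point is on the curve", {
  set.seed(42)
  scores <- rnorm(40); labels <- runif(40) < 0.4
  r <- roc_auc(scores, labels)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_true(all(r$curve$fpr >= 0 & r$curve$fpr <= 1))
  j <- r$sensitivity + r$specificity - 1
  # recompute J at the reported cut
  tpr <- mean(scores[labels] >= r$youden_cut)
  fpr <- mean(scores[!labels] >= r$youden_cut)
  expect_equal(j, tpr - fpr, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(43)
  for (i in 1:10) {
    scores <- rnorm(30); labels <- runif(30) < 0.5
    if (!any(labels) || all(labels)) next
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                           direction = "<"))))
    expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
  }
})

test_that("logistic panels fit by IRLS with ridge stabilization", {
  set.seed(44)
  # separable single feature: AUC 1, flagged
  X <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c(FALSE, TRUE), each = 20)
  fit <- logistic_panel(X, y)
  expect_equal(fit$roc$auc, 1)
  expect_true(fit$separable)

  # symmetric balanced data with a zero-effect feature: intercept ~ 0
  X0 <- matrix(rep(c(-1, 1), 30), ncol = 1, dimnames = list(NULL, "f"))
  y0 <- rep(c(TRUE, FALSE), 30)
  fit0 <- logistic_panel(X0, y0)
  expect_lt(abs(fit0$weights["(intercept)"]), 1e-6)

  # agrees with glm on a well-behaved problem
  Xg <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  eta <- 0.5 + 1 * Xg[, 1] - 0.7 * Xg[, 2]
  yg <- runif(100) < 1 / (1 + exp(-eta))
  fit_g <- logistic_panel(Xg, yg)
  ref <- stats::glm(yg ~ Xg, family = stats::binomial())
  expect_equal(unname(fit_g$weights), unname(stats::coef(ref)), tolerance = 1e-4)

  expect_error(logistic_panel(Xg[1:4, ], yg[1:4]), "need n")
})

test_that("null features carry no real signal through the panel fit", {
  # the raw score of a label-independent feature has AUC centered at 0.5;
  # the fitted in-sample panel AUC folds at 0.5 (it is max(a, 1-a) for a
  # single feature) so it sits slightly above 0.5 but shows no real signal
  set.seed(45)
  raw <- fitted <- numeric(40)
  for (i in 1:40) {
    X <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "f"))
    y <- rep(c(TRUE, FALSE), each = 30)
    raw[i] <- roc_auc(X[, 1], y)$auc
    fitted[i] <- logistic_panel(X, y)$roc$auc
  }
  expect_lt(abs(mean(raw) - 0.5), 0.04)
  expect_equal(fitted, pmax(raw, 1 - raw), tolerance = 1e-9)
  expect_lt(mean(fitted), 0.65)
})

test_that("over-representation matches enumeration and handles edge cases", {
  sets <- list(hit = paste0("g", 1:10), missed = paste0("x", 1:5))
  bg <- c(paste0("g", 1:10), paste0("x", 1:5), paste0("b", 1:85))
  res <- ora(paste0("g", 1:5), sets, bg)
  # N=100, K=10, n=5, m=5 -> C(10,5)/C(100,5)
  expect_equal(res$hyper_p[res$set_name == "hit"], choose(10, 5) / choose(100, 5),
               tolerance = 1e-12)
  expect_equal(signif(res$hyper_p[res$set_name == "hit"], 4), 3.347e-06)
  expect_equal(res$hyper_p[res$set_name == "missed"], 1)

  # query disjoint from every set
  res2 <- ora(paste0("b", 1:3), sets, bg)
  expect_true(all(res2$hyper_p == 1))

  # duplicates and order do not matter
  res3 <- ora(rev(c(paste0("g", 1:5), "g1", "g1")), sets, bg)
  expect_equal(res3$hyper_p, res$hyper_p)

  expect_error(ora(character(0), sets, bg), "empty query")
  expect_error(ora("zzz", sets, bg), "empty query")
})

test_that("grade contrasts evaluate nodal circRNAs and panels", {
  co <- default_cohort(1)
  feats <- co$truth$triplets$circ_id[1:3]
  rc <- roc_contrasts(co$expr$circRNA, co$clinical, feats,
                      panels = list(p1 = feats))
  expect_setequal(unique(rc$contrast),
                  c("nontumor_vs_grade12", "grade12_vs_grade34", "nontumor_vs_grade34"))
  expect_true(all(rc$auc >= 0 & rc$auc <= 1))
  expect_equal(sum(rc$kind == "panel"), 3L)
  # higher-grade tumors separate from non-tumor better than low-grade ones
  # for grade-coupled circRNAs (directional sanity, averaged over features)
  a12 <- mean(rc$auc[rc$contrast == "nontumor_vs_grade12" & rc$kind == "feature"])
  a34 <- mean(rc$auc[rc$contrast == "nontumor_vs_grade34" & rc$kind == "feature"])
  expect_gt(a34, a12 - 0.05)
})
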