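test_that("binary association matches the Welch oracle and flags degeneracy", {
  # identical group means
  r <- associate_binary(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$group_fc, 1)
  expect_equal(r$p_value, 1)

  # forced means with zero variance: FC = 2^(5-3) = 4, degenerate
  r <- associate_binary(c(5, 5), c(3, 3))
  expect_equal(r$group_fc, 4)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)

  # worse (2,3,4) vs better (1,2,3): FC = 2, Welch t = 1.2247, p ~ 0.288
  r <- associate_binary(c(2, 3, 4), c(1, 2, 3))
  expect_equal(r$group_fc, 2)
  expect_equal(r$t_stat, 1 / sqrt(2 / 3), tolerance = 1e-4)
  expect_equal(round(r$t_stat, 3), 1.225)
  expect_equal(round(r$p_value, 3), 0.288)

  # agrees with stats::t.test on random data
  set.seed(4)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(6, 1)
    r <- associate_binary(a, b)
    tt <- stats::t.test(a, b)
    expect_equal(r$t_stat, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(r$p_value, tt$p.value, tolerance = 1e-12)
  }

  expect_true(associate_binary(c(1), c(1, 2))$skipped)
})

test_that("log-rank test matches hand tabulation on small examples", {
  # both groups identical: chi2 = 0, p = 1
  r <- logrank_test(c(1, 2, 1, 2), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(r$chi2, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  # group A events at t=1,2; group B at t=3,4; no censoring.
  # Hand tabulation over the 4 event times:
  # t=1: risk 2A+2B, O_A=1, E_A=1/2; t=2: risk 1A+2B, O_A=1, E_A=1/3
  # t=3: risk 2B, O_A=0, E_A=0;     t=4: risk 1B, O_A=0, E_A=0
  # O_A=2, E_A=5/6; V = sum of hypergeometric variances
  v1 <- (2 * 2 * 1 * (4 - 1)) / (4^2 * (4 - 1))  # 1/4
  v2 <- (1 * 2 * 1 * (3 - 1)) / (3^2 * (3 - 1))  # 2/9
  chi2_hand <- (2 - 5 / 6)^2 / (v1 + v2)
  r <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("a", "a", "b", "b"))
  expect_equal(r$chi2, chi2_hand, tolerance = 1e-10)

  # zero events: skipped
  expect_true(logrank_test(c(1, 2), c(0, 0), c("a", "b"))$skipped)
})

test_that("the worse-level coding is total over the tested variables", {
  coding <- worse_level_coding()
  expect_setequal(coding$variable,
                  c("grade", "size_group", "encapsulation", "degree_encapsulation",
                    "vascular_invasion", "tumor_invasion", "stage_group", "survival"))
  expect_true(all(!is.na(coding$worse_value[coding$type != "survival"])))
  expect_setequal(unique(coding$category),
                  c("tumor_properties", "invasion_metastasis", "prognosis"))
})

test_that("prognosis calls follow the consistency rule", {
  de <- data.frame(feature_id = c("f_up", "f_mix", "f_dn"),
                   status = c("up", "up", "down"), stringsAsFactors = FALSE)
  assoc <- data.frame(
    feature_id = c("f_up", "f_mix", "f_mix", "f_dn"),
    rna_class = "circRNA",
    clinical_variable = c("grade", "grade", "encapsulation", "encapsulation"),
    direction = c("higher_in_worse", "higher_in_worse", "higher_in_better",
                  "higher_in_better"),
    significant = TRUE, stringsAsFactors = FALSE)
  calls <- call_prognosis(de, assoc)
  expect_equal(calls$call[calls$feature_id == "f_up"], "worse_prognostic")
  expect_equal(calls$call[calls$feature_id == "f_mix"], "unclear")
  expect_equal(calls$call[calls$feature_id == "f_dn"], "better_prognostic")

  # a feature with no significant association is not called
  assoc$significant <- FALSE
  expect_equal(nrow(call_prognosis(de, assoc)), 0L)

  # order independence
  calls2 <- call_prognosis(de[3:1, ], assoc[c(4, 2, 3, 1), ] |> transform(significant = TRUE))
  expect_equal(calls2[order(calls2$feature_id), ]$call,
               calls[order(calls$feature_id), ]$call)
})

test_that("planted grade associations are recovered with sensitivity above FDP", {
  co <- default_cohort(1)
  truth <- co$truth$clin_assoc
  hits <- c()
  calls <- c()
  for (cl in c("circRNA", "miRNA", "mRNA")) {
    de <- differential_expression(co$expr[[cl]], co$clinical)
    assoc <- clinical_associations(de, co$expr[[cl]], co$clinical)
    sig <- unique(assoc$feature_id[assoc$significant & assoc$clinical_variable == "grade"])
    calls <- c(calls, sig)
  }
  rec <- score_recovery(calls, truth$feature_id)
  expect_gt(rec$sensitivity, rec$fdp)
})

test_that("venn region counts enumerate 2^k - 1 regions correctly", {
  r <- venn_counts(list(A = c("a", "b"), B = c("b", "c"), C = c("c")))
  expect_equal(nrow(r), 7L)
  get <- function(reg) r$count[r$region == reg]
  expect_equal(get("A"), 1L)      # a
  expect_equal(get("A&B"), 1L)    # b
  expect_equal(get("B&C"), 1L)    # c
  expect_equal(get("C"), 0L)
  expect_equal(get("A&B&C"), 0L)
  expect_equal(attr(r, "multi"), 2L)

  # disjoint sets: no intersections
  r2 <- venn_counts(list(A = "a", B = "b"))
  expect_equal(r2$count[r2$region == "A&B"], 0L)
  # identical sets: only the full intersection
  r3 <- venn_counts(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(r3$count[r3$region == "A&B"], 2L)
  expect_equal(sum(r3$count), 2L)

  expect_error(venn_counts(list(A = "a", B = "b", C = "c", D = "d")), "3")
})
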