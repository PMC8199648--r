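test_that("correlation edges match the hand formula and retention gates", {
  A <- matrix(c(1, 2, 3, 4), 1, dimnames = list("x", paste0("s", 1:4)))
  B <- matrix(c(1, 2, 3, 5), 1, dimnames = list("y", paste0("s", 1:4)))
  e <- pearson_edges(A, B, r_min = 0.7, fdr = 0.05, all = TRUE)
  expect_equal(e$r, stats::cor(c(1, 2, 3, 4), c(1, 2, 3, 5)), tolerance = 1e-12)
  expect_equal(round(e$r, 4), 0.9827)

  # y = x exactly: r = 1, retained
  e2 <- pearson_edges(A, `rownames<-`(A, "y"), all = TRUE)
  expect_equal(e2$r, 1)
  expect_true(e2$retained)
})

test_that("edge statistics equal a naive double-loop implementation", {
  set.seed(21)
  A <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("a", sprintf("%02d", 1:20)),
                                                  paste0("s", 1:10)))
  B <- matrix(rnorm(150), 15, 10, dimnames = list(paste0("b", sprintf("%02d", 1:15)),
                                                  paste0("s", 1:10)))
  for (m in c("pearson", "spearman")) {
    mine <- cor_edges(A, B, method = m, all = TRUE)
    oracle <- cor_loop(A, B, method = m)
    expect_equal(mine$r, oracle$r, tolerance = 1e-12)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-12)
  }
})

test_that("zero-variance features are skipped with a message", {
  A <- matrix(c(1, 1, 1, 1, 1, 2, 3, 4), 2, byrow = TRUE,
              dimnames = list(c("flat", "ok"), paste0("s", 1:4)))
  B <- matrix(1:4, 1, dimnames = list("y", paste0("s", 1:4)))
  expect_message(e <- cor_edges(A, B, all = TRUE), "zero-variance")
  expect_equal(e$a_id, "ok")
})

test_that("connected components sort by size with deterministic tie-breaks", {
  edges <- data.frame(a_id = c("a", "c"), b_id = c("b", "d"))
  comps <- network_components(edges)
  expect_equal(lengths(comps), c(2L, 2L))
  expect_equal(comps[[1]], c("a", "b"))  # tie broken by smallest node id

  # empty edge set: every node a singleton
  comps2 <- network_components(edges[0, ], nodes = c("x", "y"))
  expect_equal(lengths(comps2), c(1L, 1L))

  # star of 1 circ + 5 genes plus a detached pair
  edges3 <- data.frame(a_id = c(rep("hub", 5), "solo"),
                       b_id = c(paste0("g", 1:5), "g9"))
  comps3 <- network_components(edges3)
  expect_equal(lengths(comps3), c(6L, 2L))
})

test_that("greedy nodal cover picks the minimal set on the worked example", {
  edges <- data.frame(
    a_id = c(rep("circA", 5), rep("circB", 3), rep("circC", 2)),
    b_id = c(paste0("g", 1:5), paste0("g", 4:6), paste0("g", 6:7)))
  nc <- nodal_cover(edges, coverage_target = 1.0)
  expect_equal(nc$selected, c("circA", "circC"))
  expect_equal(nc$coverage, 1)
  # brute force confirms 2 sets are necessary and sufficient
  adj <- lapply(split(edges$b_id, edges$a_id), unique)
  expect_equal(min_cover_size(adj, 1.0, unique(edges$b_id)), 2)

  # single circRNA covering everything
  e1 <- data.frame(a_id = rep("c1", 3), b_id = paste0("g", 1:3))
  expect_equal(nodal_cover(e1, 1.0)$selected, "c1")

  # identical neighborhoods: lexicographically smaller wins
  e2 <- data.frame(a_id = c("cB", "cB", "cA", "cA"), b_id = c("g1", "g2", "g1", "g2"))
  expect_equal(nodal_cover(e2, 1.0)$selected, "cA")

  # unreachable target warns and reports achieved coverage
  expect_warning(r <- nodal_cover(e2, 2.0), "unreachable")
  expect_equal(r$coverage, 1)
})

test_that("greedy cover respects the (1 - 1/e) guarantee against exhaustive optima", {
  set.seed(31)
  for (rep in 1:25) {
    n_circ <- sample(4:9, 1); n_gene <- sample(6:14, 1)
    edges <- expand.grid(a_id = paste0("c", seq_len(n_circ)),
                         b_id = paste0("g", seq_len(n_gene)),
                         stringsAsFactors = FALSE)
    edges <- edges[runif(nrow(edges)) < 0.3, ]
    if (!nrow(edges)) next
    nc <- nodal_cover(edges, coverage_target = 1.0)
    adj <- lapply(split(edges$b_id, edges$a_id), unique)
    genes <- unique(edges$b_id)
    for (k in seq_along(nc$selected)) {
      greedy_cov <- nc$steps$coverage[k]
      opt_cov <- best_coverage_k(adj, k, genes)
      expect_gte(greedy_cov, (1 - 1 / exp(1)) * opt_cov - 1e-12)
    }
  }
})

test_that("host-gene concordance computes r and quadrant labels", {
  circ_de <- data.frame(feature_id = c("c1", "c2", "c3", "c4"),
                        log2fc = c(1, 2, -1, 2), stringsAsFactors = FALSE)
  mrna_de <- data.frame(feature_id = c("h1", "h2", "h3", "h4"),
                        log2fc = c(2, 1, -2, -1), stringsAsFactors = FALSE)
  ann <- data.frame(circ_id = c("c1", "c2", "c3", "c4"),
                    host_gene = c("h1", "h2", "h3", "h4"), stringsAsFactors = FALSE)
  hc <- host_concordance(circ_de, mrna_de, ann)
  expect_equal(hc$n, 4L)
  expect_equal(hc$r, stats::cor(c(1, 2, -1, 2), c(2, 1, -2, -1)), tolerance = 1e-12)
  expect_equal(hc$pairs$quadrant, c("ii", "ii", "iii", "iv"))
  expect_equal(sum(!hc$pairs$concordant), 1L)

  # equal fold changes: r = 1, all concordant
  mrna_de2 <- transform(mrna_de, log2fc = circ_de$log2fc)
  hc2 <- host_concordance(circ_de, mrna_de2, ann)
  expect_equal(hc2$r, 1)
  expect_true(all(hc2$pairs$concordant))

  # no annotated pairs: empty result
  hc3 <- host_concordance(circ_de, mrna_de, ann[0, ])
  expect_equal(hc3$n, 0L)
  expect_true(is.na(hc3$r))
})

test_that("planted coupled pairs are recovered among retained edges", {
  co <- default_cohort(1)
  truth_keys <- paste(co$truth$coupled_pairs$circ_id, co$truth$coupled_pairs$mrna_id)
  e <- pearson_edges(co$expr$circRNA, co$expr$mRNA,
                     features_a = co$truth$de$circRNA$feature_id,
                     features_b = co$truth$de$mRNA$feature_id)
  rec <- score_recovery(paste(e$a_id, e$b_id), truth_keys)
  expect_gt(rec$sensitivity, rec$fdp)
  expect_gte(rec$sensitivity, 0.5)
})
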