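test_that("candidate pair counting follows the at-least-one-marked rule", {
  expect_equal(count_candidate_pairs(0, 100), 0)
  expect_equal(count_candidate_pairs(10, 10), choose(10, 2))
  expect_equal(count_candidate_pairs(2, 4), 5)
  expect_error(count_candidate_pairs(-1, 5), "non-negative")
  expect_error(count_candidate_pairs(6, 5), "exceed")
})

test_that("pair enumeration is exact, canonical and matches brute force", {
  out <- enumerate_pairs(c("A", "B"), c("A", "B", "C", "D"))
  expect_equal(out, data.frame(gene_i = c("A", "A", "A", "B", "B"),
                               gene_j = c("B", "C", "D", "C", "D"),
                               stringsAsFactors = FALSE))
  set.seed(6)
  for (i in 1:5) {
    universe <- sprintf("G%03d", sample(1:500, sample(5:40, 1)))
    marked <- sample(universe, sample(0:length(universe), 1))
    got <- enumerate_pairs(marked, universe)
    ## brute force: every unordered pair, filtered
    all_pairs <- if (length(universe) >= 2) t(utils::combn(sort(universe), 2))
    keep <- all_pairs[, 1] %in% marked | all_pairs[, 2] %in% marked
    expect_equal(nrow(got), sum(keep))
    expect_equal(nrow(got), count_candidate_pairs(length(marked),
                                                  length(universe)))
    expect_true(all(got$gene_i < got$gene_j))
    expect_false(anyDuplicated(paste(got$gene_i, got$gene_j)) > 0)
  }
  expect_error(enumerate_pairs("Z", c("A", "B")), "not present")
})

test_that("the expression difference is the between-group mean contrast", {
  ## responders s1,s2 have differences {2, 2}; non-responders {-1, 1}
  expr <- tiny_expr(c(5, 6, 4, 6,
                      3, 4, 5, 5),
                    c("gi", "gj"), c("s1", "s2", "s3", "s4"))
  labels <- mk_labels(colnames(expr), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(compute_ed(c("gi", "gj"), expr, labels), 2)
  ## antisymmetry and orientation
  expect_equal(compute_ed(c("gj", "gi"), expr, labels), -2)
  rec <- orient_pair(c("gj", "gi"), expr, labels)
  expect_equal(rec$gene_i, "gi")
  expect_equal(rec$ed, 2)
  ## identical group means: rejected
  expr0 <- tiny_expr(c(5, 3, 6, 2,
                       4, 2, 5, 1),
                     c("ga", "gb"), c("s1", "s2", "s3", "s4"))
  expect_null(orient_pair(c("ga", "gb"), expr0, labels))
  expect_error(compute_ed(c("gi", "zz"), expr, labels), "zz")
})

test_that("rank-sum p-values match exact enumeration for tiny groups", {
  ## complete separation at 3 vs 3: p = 2 / C(6,3) = 0.1
  expr <- tiny_expr(c(9, 8, 7, 1, 2, 3,
                      1, 2, 3, 2, 4, 6),   # diffs 8,6,4 vs -1,-2,-3: no ties
                    c("gi", "gj"), sprintf("s%d", 1:6))
  labels <- mk_labels(colnames(expr), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(wilcoxon_reo_test(c("gi", "gj"), expr, labels), 0.1)

  set.seed(33)
  for (i in 1:25) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- stats::rnorm(n1); y <- stats::rnorm(n2)
    e <- rbind(gi = c(x, y) + 5, gj = rep(5, n1 + n2))
    colnames(e) <- sprintf("s%d", seq_len(n1 + n2))
    lab <- mk_labels(colnames(e), c(rep(TRUE, n1), rep(FALSE, n2)))
    expect_equal(wilcoxon_reo_test(c("gi", "gj"), e, lab),
                 enum_wilcox_p(x, y), tolerance = 1e-12)
  }
})

test_that("large-sample rank-sum branch reproduces wilcox.test with ties", {
  set.seed(44)
  for (i in 1:20) {
    n1 <- sample(10:25, 1); n2 <- sample(5:20, 1)
    d <- sample(seq(-3, 3, by = 0.5), n1 + n2, replace = TRUE)  # forces ties
    e <- rbind(gi = d + 5, gj = rep(5, n1 + n2))
    colnames(e) <- sprintf("s%d", seq_len(n1 + n2))
    lab <- mk_labels(colnames(e), c(rep(TRUE, n1), rep(FALSE, n2)))
    ref <- suppressWarnings(stats::wilcox.test(d[seq_len(n1)],
                                               d[n1 + seq_len(n2)],
                                               exact = FALSE,
                                               correct = TRUE)$p.value)
    expect_equal(wilcoxon_reo_test(c("gi", "gj"), e, lab), ref,
                 tolerance = 1e-12)
  }
  ## identical values in both groups: no separation, p = 1
  e1 <- rbind(gi = rep(7, 8), gj = rep(2, 8))
  colnames(e1) <- sprintf("s%d", 1:8)
  lab1 <- mk_labels(colnames(e1), rep(c(TRUE, FALSE), each = 4))
  expect_equal(wilcoxon_reo_test(c("gi", "gj"), e1, lab1), 1)
})

test_that("rank-sum p is invariant to increasing transforms of the diffs", {
  set.seed(55)
  x <- stats::rnorm(12); g <- rep(c(TRUE, FALSE), each = 6)
  e <- rbind(gi = x + 5, gj = rep(5, 12))
  e2 <- rbind(gi = exp(x) + 5, gj = rep(5, 12))   # exp(x) monotone in x
  colnames(e) <- colnames(e2) <- sprintf("s%d", 1:12)
  lab <- mk_labels(colnames(e), g)
  expect_equal(wilcoxon_reo_test(c("gi", "gj"), e, lab),
               wilcoxon_reo_test(c("gi", "gj"), e2, lab))
})

test_that("the exact binomial filter matches a direct tail sum", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    k <- sample(0:n, 1)
    p0 <- stats::runif(1, 0.3, 0.9)
    rec <- list(tp = k, tn = 0, fp = 0, fn = n - k)
    got <- binomial_filter(rec, null_p = p0)
    expect_equal(got$p_value, binom_tail_sum(k, n, p0), tolerance = 1e-12)
    expect_equal(got$p_value,
                 stats::binom.test(k, n, p0,
                                   alternative = "greater")$p.value,
                 tolerance = 1e-12)
  }
  ## all 47 correct under a 36/47 no-information rate: p = (36/47)^47
  all47 <- list(tp = 36, tn = 11, fp = 0, fn = 0)
  got <- binomial_filter(all47, null_p = 36 / 47)
  expect_equal(got$p_value, (36 / 47)^47, tolerance = 1e-12)
  expect_true(got$pass)
  ## exactly the expected count under the null is no evidence
  mid <- list(tp = 30, tn = 0, fp = 0, fn = 20)
  got_mid <- binomial_filter(mid, null_p = 0.6)
  expect_gt(got_mid$p_value, 0.4)
  expect_false(got_mid$pass)
  ## degenerate null can never pass
  got_one <- binomial_filter(all47, null_p = 1)
  expect_false(got_one$pass)
  expect_error(binomial_filter(list(tp = 0, tn = 0, fp = 0, fn = 0),
                               null_p = 0.5), "no labeled")
})

test_that("the pair F-score is the classification accuracy", {
  expect_equal(round(pair_f_score(list(tp = 33, tn = 11, fp = 0, fn = 3)), 2),
               0.94)
  expect_equal(pair_f_score(list(tp = 10, tn = 5, fp = 0, fn = 0)), 1)
  expect_equal(pair_f_score(list(tp = 0, tn = 0, fp = 5, fn = 10)), 0)
  expect_error(pair_f_score(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
})

test_that("the batch pair screen agrees with the per-pair operations", {
  cfg <- sim_config(n_genes = 60, n_samples = 30, n_responders = 20,
                    n_planted_pairs = 2, n_response_genes = 8, seed = 21)
  sim <- simulate_dataset(cfg)
  labels <- derive_labels(sim$clinical)
  pt <- screen_pairs(sim$expr, labels, sim$truth$response_gene_ids,
                     pair_screen_params(wilcoxon_p_threshold = 0.2))
  expect_true(all(pt$ed > 0))
  expect_true(all(pt$tp + pt$tn + pt$fp + pt$fn == 30))
  expect_equal(pt$f_score, (pt$tp + pt$tn) / 30, tolerance = 1e-12)
  funnel <- attr(pt, "funnel")
  expect_equal(funnel$n_pairs_total, count_candidate_pairs(8, 60))
  expect_equal(funnel$binomial_null_p, 20 / 30)
  set.seed(9)
  for (k in sample(nrow(pt), 8)) {
    rec <- orient_pair(pt[k, c("gene_i", "gene_j")], sim$expr, labels)
    expect_identical(rec$gene_i, pt$gene_i[k])  # already oriented, ed > 0
    expect_equal(rec$ed, pt$ed[k], tolerance = 1e-12)
    expect_equal(wilcoxon_reo_test(pt[k, ], sim$expr, labels),
                 pt$wilcoxon_p[k], tolerance = 1e-12)
    expect_equal(binomial_filter(pt[k, ], null_p = 20 / 30)$p_value,
                 pt$binomial_p[k], tolerance = 1e-12)
    expect_equal(pair_f_score(pt[k, ]), pt$f_score[k], tolerance = 1e-12)
  }
  ## candidate pool: binomial passers, capped, in deterministic order
  cand <- candidate_pairs(pt, cap = 5)
  expect_lte(nrow(cand), 5)
  expect_true(all(cand$binomial_pass))
})
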