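test_that("vote thresholds implement the strict-majority rule", {
  expect_equal(default_threshold(3), 2L)
  expect_equal(default_threshold(1), 1L)
  expect_equal(default_threshold(4), 3L)
  expect_error(default_threshold(0), "at least 1")
})

test_that("signature construction validates its invariants", {
  p <- data.frame(gene_i = c("a", "c"), gene_j = c("b", "d"))
  sig <- new_signature(p)
  expect_equal(sig$vote_threshold, 2L)     # strict majority of 2 by default
  expect_error(new_signature(p[c(1, 1), ]), "more than once")
  flipped <- data.frame(gene_i = c("a", "b"), gene_j = c("b", "a"))
  expect_error(new_signature(flipped), "more than once")
  expect_error(new_signature(p, vote_threshold = 3), "between 1")
})

test_that("sample scoring counts responder-indicating orderings", {
  expr <- tiny_expr(c(9, 1, 5,
                      1, 9, 4,
                      8, 2, 6,
                      2, 8, 5.5,
                      7, 3, 3.5,
                      3, 7, 3.6),
                    sprintf("g%d", 1:6), c("all3", "none", "mix"))
  sig <- new_signature(data.frame(gene_i = c("g1", "g3", "g5"),
                                  gene_j = c("g2", "g4", "g6")),
                       vote_threshold = 2)
  sc <- score_samples(sig, expr)
  expect_equal(sc$score, c(3L, 0L, 2L))
  expect_equal(sc$predicted, c("responder", "non_responder", "responder"))
  ## score 1 with threshold 2 is a non-responder call
  sig1 <- new_signature(sig$pairs[1, , drop = FALSE], vote_threshold = 1)
  expect_equal(score_samples(sig1, expr)$predicted[2], "non_responder")
  expect_error(score_samples(
    new_signature(data.frame(gene_i = "g1", gene_j = "zz")), expr), "zz")
})

test_that("scores are invariant under per-sample monotone distortion", {
  cfg <- sim_config(n_genes = 80, n_samples = 25, n_responders = 15,
                    n_planted_pairs = 3, n_response_genes = 6, seed = 13)
  sim <- simulate_dataset(cfg)
  sig <- new_signature(sim$truth$planted_pairs)
  base <- score_samples(sig, sim$expr)
  for (s in c(4, 99)) {
    distorted <- apply_monotone_distortion(sim$expr, seed = s)
    expect_identical(score_samples(sig, distorted), base)
  }
})

test_that("forward selection handles the single-candidate case", {
  expr <- tiny_expr(c(5, 6, 1, 2,
                      1, 2, 5, 6),
                    c("gi", "gj"), sprintf("s%d", 1:4))
  labels <- mk_labels(colnames(expr), c(TRUE, TRUE, FALSE, FALSE))
  cand <- data.frame(gene_i = "gi", gene_j = "gj", stringsAsFactors = FALSE)
  sig <- forward_select(cand, expr, labels)
  expect_equal(nrow(sig$pairs), 1)
  expect_equal(sig$vote_threshold, 1L)
  expect_equal(sig$provenance$f_score, 1)
  expect_error(forward_select(cand[0, ], expr, labels), "empty")
})

test_that("greedy growth is validated against exhaustive subset search", {
  ## on candidate sets of <= 12 pairs: the accuracy trajectory increases
  ## strictly, the greedy result is at least as good as its seed alone and
  ## never better than the exhaustive optimum over subsets containing the
  ## seed, and every greedy step picks the best single addition
  subset_acc <- function(votes, sel, y) {
    score <- colSums(votes[sel, , drop = FALSE])
    thr <- ceiling(length(sel) / 2)
    mean((score >= thr) == y)
  }
  for (seed in c(101, 202, 303)) {
    cfg <- sim_config(n_genes = 40, n_samples = 21, n_responders = 13,
                      n_planted_pairs = 2, planted_flip_prob = 0.25,
                      n_response_genes = 4, seed = seed)
    sim <- simulate_dataset(cfg)
    labels <- derive_labels(sim$clinical)
    set.seed(seed)
    gs <- sample(rownames(sim$expr), 24)
    cand0 <- data.frame(gene_i = pmin(gs[1:12], gs[13:24]),
                        gene_j = pmax(gs[1:12], gs[13:24]),
                        stringsAsFactors = FALSE)
    recs <- build_pair_records(cand0, sim$expr, labels)
    sig <- forward_select(recs, sim$expr, labels, n_seeds = 5)

    traj <- sig$provenance$trajectory
    if (length(traj) > 1) expect_true(all(diff(traj) > 0))

    lab <- labels$labels
    y <- lab == "responder"
    ord <- order(-recs$f_score, recs$wilcoxon_p, recs$gene_i, recs$gene_j)
    cand <- recs[ord, ]
    votes <- sim$expr[cand$gene_i, names(lab), drop = FALSE] >
      sim$expr[cand$gene_j, names(lab), drop = FALSE]
    key <- paste(cand$gene_i, cand$gene_j)
    sel <- match(paste(sig$pairs$gene_i, sig$pairs$gene_j), key)
    seed_idx <- sel[1]
    expect_gte(sig$provenance$f_score, subset_acc(votes, seed_idx, y))
    ## exhaustive optimum over all subsets containing the winning seed
    others <- setdiff(seq_len(nrow(cand)), seed_idx)
    best <- 0
    for (k in 0:length(others)) {
      if (k == 0) { best <- max(best, subset_acc(votes, seed_idx, y)); next }
      sets <- utils::combn(others, k)
      for (cidx in seq_len(ncol(sets))) {
        best <- max(best, subset_acc(votes, c(seed_idx, sets[, cidx]), y))
      }
    }
    expect_lte(sig$provenance$f_score, best + 1e-12)
    ## each greedy step is the best single addition at that point
    for (step in seq_along(sel)[-1]) {
      cur <- sel[seq_len(step - 1)]
      gains <- vapply(setdiff(seq_len(nrow(cand)), cur), function(j)
        subset_acc(votes, c(cur, j), y), numeric(1))
      expect_equal(subset_acc(votes, sel[seq_len(step)], y), max(gains),
                   tolerance = 1e-12)
    }
  }
})

test_that("a flip-free planted signature attains perfect training accuracy", {
  cfg <- sim_config(n_genes = 100, n_samples = 47, n_responders = 36,
                    n_planted_pairs = 3, planted_flip_prob = 0,
                    n_response_genes = 5, seed = 77)
  sim <- simulate_dataset(cfg)
  labels <- derive_labels(sim$clinical)
  sig <- new_signature(sim$truth$planted_pairs, vote_threshold = 2)
  sc <- score_samples(sig, sim$expr)
  expect_equal(confusion_metrics(sc, labels)$f_score, 1)
})

test_that("selection is dominated by planted pairs, not noise", {
  ## across seeded replicates of the planted-signal experiment the
  ## selected signature is anchored on the planted pairs: it always
  ## contains at least one, its seed pair is almost always planted, and
  ## planted pairs make up the bulk of everything selected
  reps <- lapply(1:20, recovery_replicate, n_noise = 100)
  expect_true(all(vapply(reps, function(r) r$n_planted_selected >= 1,
                         logical(1))))
  expect_gte(sum(vapply(reps, `[[`, logical(1), "seed_is_planted")), 17)
  frac_planted <- sum(vapply(reps, `[[`, numeric(1), "n_planted_selected")) /
    sum(vapply(reps, `[[`, numeric(1), "sig_size"))
  expect_gte(frac_planted, 0.6)
  ## with flip probability 0.05 training accuracy saturates
  expect_gte(min(vapply(reps, `[[`, numeric(1), "f_score")), 0.95)
})
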