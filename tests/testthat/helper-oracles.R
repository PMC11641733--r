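## Shared fixtures and independent oracles used across the test files.

## small expression matrix with explicit values
tiny_expr <- function(values, gene_ids, sample_ids) {
  matrix(values, nrow = length(gene_ids), byrow = TRUE,
         dimnames = list(gene_ids, sample_ids))
}

mk_labels <- function(sample_ids, responder) {
  stats::setNames(ifelse(responder, "responder", "non_responder"), sample_ids)
}

## exact two-sided rank-sum p-value by full enumeration of the C(n, n1)
## group assignments of the observed values (no ties assumed), using the
## same two-sided doubling rule as the implementation but with the null
## distribution obtained by brute force rather than pwilcox
enum_wilcox_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  combos <- utils::combn(n1 + n2, n1)
  W_all <- apply(combos, 2, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  W_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p_low <- mean(W_all <= W_obs)
  p_high <- mean(W_all >= W_obs)
  min(1, 2 * min(p_low, p_high))
}

## direct binomial upper-tail sum (independent of pbinom's lower.tail path)
binom_tail_sum <- function(k, n, p) sum(stats::dbinom(k:n, n, p))

## all-pairs AUC oracle
auc_bruteforce <- function(scores_resp, scores_non) {
  tot <- 0
  for (a in scores_resp) for (b in scores_non)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(scores_resp) * length(scores_non))
}

## normal-approximation power of the two-sided Wilcoxon rank-sum test for
## a Gaussian location shift, with the variance of the Mann-Whitney count
## evaluated under the alternative (placement probabilities p1, p2, p3 by
## numeric integration)
mw_power_analytic <- function(n1, n2, d, alpha = 0.05) {
  p1 <- stats::pnorm(d / sqrt(2))
  p2 <- stats::integrate(function(x) stats::pnorm(d - x)^2 * stats::dnorm(x),
                         -Inf, Inf)$value
  p3 <- stats::integrate(function(y) stats::pnorm(y)^2 * stats::dnorm(y - d),
                         -Inf, Inf)$value
  mu <- n1 * n2 * p1
  s0 <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  sA <- sqrt(n1 * n2 * p1 * (1 - p1) + n1 * n2 * (n2 - 1) * (p2 - p1^2) +
               n1 * n2 * (n1 - 1) * (p3 - p1^2))
  crit_hi <- n1 * n2 / 2 + stats::qnorm(1 - alpha / 2) * s0
  crit_lo <- n1 * n2 / 2 - stats::qnorm(1 - alpha / 2) * s0
  stats::pnorm((mu - crit_hi) / sA) + stats::pnorm((crit_lo - mu) / sA)
}

## Monte-Carlo power of the two-sided correlation test on bivariate
## normal draws; method "pearson" simulates the model underlying the
## critical-r power formula, "spearman" the rank-test variant (t
## approximation on rho, the implementation's default p-value route)
cor_test_mc_power <- function(n, r, alpha = 0.05, reps = 10000,
                              method = c("pearson", "spearman"), seed = 1) {
  method <- match.arg(method)
  set.seed(seed)
  rej <- 0L
  for (i in seq_len(reps)) {
    z <- stats::rnorm(n)
    x <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    if (method == "pearson") {
      rho <- stats::cor(x, z)
    } else {
      rho <- stats::cor(rank(x), rank(z))
    }
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    if (p < alpha) rej <- rej + 1L
  }
  rej / reps
}

## build oriented candidate records (ed, wilcoxon_p, confusion, f_score)
## for an explicit list of unordered pairs, through the public per-pair
## operations
build_pair_records <- function(pairs_df, expr, labels) {
  recs <- do.call(rbind, lapply(seq_len(nrow(pairs_df)), function(k)
    orient_pair(pairs_df[k, ], expr, labels)))
  lab <- if (inherits(labels, "reo_labels")) labels$labels else labels
  sub <- expr[, names(lab), drop = FALSE]
  v <- sub[recs$gene_i, , drop = FALSE] > sub[recs$gene_j, , drop = FALSE]
  resp <- lab == "responder"
  tp <- rowSums(v[, resp, drop = FALSE])
  tn <- rowSums(!v[, !resp, drop = FALSE])
  recs$tp <- tp; recs$tn <- tn
  recs$fp <- sum(!resp) - tn; recs$fn <- sum(resp) - tp
  recs$f_score <- (tp + tn) / length(lab)
  recs$wilcoxon_p <- vapply(seq_len(nrow(recs)), function(k)
    wilcoxon_reo_test(recs[k, ], expr, labels), numeric(1))
  recs
}

## one replicate of the planted-pair recovery experiment: 3 planted pairs
## (flip 0.05, 47 samples) plus n_noise background pairs as candidates
recovery_replicate <- function(rep_seed, n_noise = 500) {
  cfg <- sim_config(n_genes = 2 * n_noise + 100, n_samples = 47,
                    n_responders = 36, n_planted_pairs = 3,
                    planted_flip_prob = 0.05, n_response_genes = 0,
                    seed = rep_seed)
  sim <- simulate_dataset(cfg)
  labels <- derive_labels(sim$clinical)
  set.seed(rep_seed + 10000L)
  bg <- setdiff(rownames(sim$expr), unlist(sim$truth$planted_pairs))
  noise <- matrix(sample(bg, 2 * n_noise), ncol = 2)
  cand0 <- rbind(sim$truth$planted_pairs,
                 data.frame(gene_i = pmin(noise[, 1], noise[, 2]),
                            gene_j = pmax(noise[, 1], noise[, 2]),
                            stringsAsFactors = FALSE))
  recs <- build_pair_records(cand0, sim$expr, labels)
  sig <- forward_select(recs, sim$expr, labels)
  sel <- paste(sig$pairs$gene_i, sig$pairs$gene_j)
  planted <- paste(sim$truth$planted_pairs$gene_i,
                   sim$truth$planted_pairs$gene_j)
  list(all_planted_in_sig = all(planted %in% sel),
       seed_is_planted = sel[1] %in% planted,
       n_planted_selected = sum(sel %in% planted),
       sig_size = length(sel),
       f_score = sig$provenance$f_score)
}
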