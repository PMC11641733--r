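## Gene-pair engine: enumeration, expression-difference orientation, and
## the Wilcoxon / exact-binomial screening filters.

#' Number of unordered gene pairs containing at least one marked gene
#'
#' `C(n_marked, 2) + n_marked * (n_total - n_marked)`: all pairs of two
#' marked genes plus all marked-unmarked pairs.
#'
#' @param n_marked Number of marked (response) genes.
#' @param n_total Total gene universe size.
#' @return The pair count (numeric, exact for counts below 2^53).
#' @export
count_candidate_pairs <- function(n_marked, n_total) {
  if (n_marked < 0 || n_total < 0) stop("counts must be non-negative")
  if (n_marked > n_total) stop("n_marked cannot exceed n_total")
  choose(n_marked, 2) + n_marked * (n_total - n_marked)
}

#' Enumerate the unordered candidate pairs
#'
#' Yields every unordered pair containing at least one marked gene exactly
#' once, canonically oriented with `gene_i < gene_j` lexicographically and
#' sorted by (`gene_i`, `gene_j`).
#'
#' @param response_genes Character vector of marked gene ids, or a
#'   response-gene data.frame from [screen_response_genes()].
#' @param all_genes Character vector of the full gene universe.
#' @return A data.frame with columns `gene_i`, `gene_j`.
#' @export
enumerate_pairs <- function(response_genes, all_genes) {
  if (is.data.frame(response_genes)) response_genes <- response_genes$gene_id
  marked <- sort(unique(response_genes))
  if (length(setdiff(marked, all_genes)))
    stop("response genes not present in the gene universe: ",
         paste(setdiff(marked, all_genes), collapse = ", "))
  other <- sort(setdiff(all_genes, marked))
  within <- if (length(marked) >= 2L) {
    mm <- t(utils::combn(marked, 2L))
    data.frame(gene_i = mm[, 1], gene_j = mm[, 2], stringsAsFactors = FALSE)
  } else {
    data.frame(gene_i = character(0), gene_j = character(0),
               stringsAsFactors = FALSE)
  }
  cross <- if (length(marked) && length(other)) {
    g <- expand.grid(a = marked, b = other, stringsAsFactors = FALSE)
    data.frame(gene_i = pmin(g$a, g$b), gene_j = pmax(g$a, g$b),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_i = character(0), gene_j = character(0),
               stringsAsFactors = FALSE)
  }
  out <- rbind(within, cross)
  out <- out[order(out$gene_i, out$gene_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## indices of the labeled samples in the expression matrix, split by group
label_indices <- function(expr, labels) {
  if (inherits(labels, "reo_labels")) labels <- labels$labels
  missing_s <- setdiff(names(labels), colnames(expr))
  if (length(missing_s))
    stop("labeled samples missing from expression matrix: ",
         paste(missing_s, collapse = ", "))
  cols <- match(names(labels), colnames(expr))
  resp <- which(labels == "responder")
  nonresp <- which(labels == "non_responder")
  if (!length(resp) || !length(nonresp))
    stop("both label groups must be non-empty")
  list(cols = cols, resp = resp, nonresp = nonresp)
}

#' Expression difference (ED) of a gene pair
#'
#' The mean of (E_i - E_j) over the responder samples minus the same mean
#' over the non-responder samples.  Its sign orients the pair: ED > 0
#' means the ordering gene i above gene j indicates response.
#'
#' @param pair Character vector `c(gene_i, gene_j)` (or list/data.frame
#'   row with `gene_i`, `gene_j`).
#' @param expr Gene-by-sample matrix.
#' @param labels A `reo_labels` object or named label vector.
#' @return The ED value (numeric scalar).
#' @export
compute_ed <- function(pair, expr, labels) {
  p <- as_pair(pair, expr)
  li <- label_indices(expr, labels)
  d <- expr[p[1], li$cols] - expr[p[2], li$cols]
  mean(d[li$resp]) - mean(d[li$nonresp])
}

as_pair <- function(pair, expr) {
  if (is.data.frame(pair) || is.list(pair))
    pair <- c(pair$gene_i, pair$gene_j)
  pair <- as.character(pair)
  if (length(pair) != 2L) stop("a pair must consist of exactly two genes")
  absent <- setdiff(pair, rownames(expr))
  if (length(absent))
    stop("gene(s) not in expression matrix: ", paste(absent, collapse = ", "))
  pair
}

#' Orient a pair by the sign of its ED
#'
#' Evaluates the ED in the given orientation; if negative the genes are
#' swapped so the stored `ed` is positive, and pairs with ED exactly zero
#' are rejected (no informative orientation).
#'
#' @inheritParams compute_ed
#' @return A one-row data.frame (`gene_i`, `gene_j`, `ed`) or `NULL` when
#'   the pair is rejected.
#' @export
orient_pair <- function(pair, expr, labels) {
  p <- as_pair(pair, expr)
  ed <- compute_ed(p, expr, labels)
  if (ed == 0) return(NULL)
  if (ed < 0) { p <- rev(p); ed <- -ed }
  data.frame(gene_i = p[1], gene_j = p[2], ed = ed, stringsAsFactors = FALSE)
}

## Row-wise two-sided Wilcoxon rank-sum p-values for a matrix of
## within-sample differences.  Exact null distribution when the total
## group size is <= 25 and the row has no ties; otherwise the normal
## approximation with tie correction and continuity correction.
row_ranksum_p <- function(D, resp, nonresp) {
  n1 <- length(resp); n2 <- length(nonresp); n <- n1 + n2
  use_exact_n <- n <= 25L
  mu <- n1 * n2 / 2
  p <- numeric(nrow(D))
  for (k in seq_len(nrow(D))) {
    d <- D[k, c(resp, nonresp)]
    r <- rank(d)
    W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # Mann-Whitney U
    tie_tab <- tabulate(match(d, unique(d)))
    has_ties <- any(tie_tab > 1L)
    if (use_exact_n && !has_ties) {
      pk <- if (W > mu)
        stats::pwilcox(W - 1, n1, n2, lower.tail = FALSE)
      else stats::pwilcox(W, n1, n2)
      p[k] <- min(2 * pk, 1)
    } else {
      sigma <- sqrt((n1 * n2 / 12) *
                      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1))))
      if (sigma == 0) { p[k] <- 1; next }
      z <- W - mu
      z <- (z - sign(z) * 0.5) / sigma
      p[k] <- min(2 * min(stats::pnorm(z),
                          stats::pnorm(z, lower.tail = FALSE)), 1)
    }
  }
  p
}

#' Wilcoxon rank-sum test on a pair's within-sample differences
#'
#' Two-sided rank-sum test comparing the within-sample differences
#' E_i - E_j between responders and non-responders.  Exact when the total
#' labeled sample count is at most 25 with no tied differences; otherwise
#' the normal approximation with tie and continuity corrections.
#'
#' @inheritParams compute_ed
#' @return Two-sided p-value.
#' @export
wilcoxon_reo_test <- function(pair, expr, labels) {
  p <- as_pair(pair, expr)
  li <- label_indices(expr, labels)
  d <- expr[p[1], li$cols] - expr[p[2], li$cols]
  row_ranksum_p(matrix(d, nrow = 1), li$resp, li$nonresp)
}

#' Pair-screening parameters
#'
#' @param wilcoxon_p_threshold Raw p-value cutoff of the rank-sum screen
#'   (default 0.01).
#' @param binomial_alpha Level of the one-sided exact binomial filter
#'   (default 0.05).
#' @param binomial_null_p Null success probability of the binomial filter.
#'   The default `NULL` means the no-information rate — the majority-class
#'   proportion of the training labels — computed at screening time.
#' @return A validated `pair_screen_params` list.
#' @export
pair_screen_params <- function(wilcoxon_p_threshold = 0.01,
                               binomial_alpha = 0.05,
                               binomial_null_p = NULL) {
  if (!(wilcoxon_p_threshold > 0 && wilcoxon_p_threshold < 1))
    stop("wilcoxon_p_threshold must be in (0,1)")
  if (!(binomial_alpha > 0 && binomial_alpha < 1))
    stop("binomial_alpha must be in (0,1)")
  if (!is.null(binomial_null_p) &&
      !(binomial_null_p > 0 && binomial_null_p <= 1))
    stop("binomial_null_p must be in (0,1]")
  structure(list(wilcoxon_p_threshold = wilcoxon_p_threshold,
                 binomial_alpha = binomial_alpha,
                 binomial_null_p = binomial_null_p),
            class = "pair_screen_params")
}

#' One-sided exact binomial filter on a pair's accuracy
#'
#' Tests whether a pair's vote (E_i > E_j predicts responder) classifies
#' more labeled samples correctly than the no-information rate: the exact
#' upper tail probability of at least `tp + tn` successes in
#' `tp + tn + fp + fn` trials under success probability `null_p`.
#'
#' @param record A list/one-row data.frame with confusion counts `tp`,
#'   `tn`, `fp`, `fn`.
#' @param params A [pair_screen_params()] object.
#' @param null_p Null success probability; overrides `params`.  Required
#'   (here or in `params`) since the default is label-dependent.
#' @return A list with `p_value` and `pass`.
#' @export
binomial_filter <- function(record, params = pair_screen_params(),
                            null_p = NULL) {
  k <- record$tp + record$tn
  nn <- record$tp + record$tn + record$fp + record$fn
  if (nn == 0) stop("no labeled samples in the confusion counts")
  p0 <- if (!is.null(null_p)) null_p else params$binomial_null_p
  if (is.null(p0))
    stop("a null success probability is required (null_p or params$binomial_null_p)")
  p <- stats::pbinom(k - 1, nn, p0, lower.tail = FALSE)
  list(p_value = p, pass = p < params$binomial_alpha)
}

#' Accuracy-style F-score of a pair's confusion counts
#'
#' `(TP + TN) / (TP + FN + TN + FP)` — the classification accuracy (this
#' field's usage of "F-score", not the harmonic-mean F1).
#'
#' @param record A list/one-row data.frame with `tp`, `tn`, `fp`, `fn`.
#' @return Accuracy in \[0, 1\].
#' @export
pair_f_score <- function(record) {
  nn <- record$tp + record$tn + record$fp + record$fn
  if (nn == 0) stop("confusion counts sum to zero")
  (record$tp + record$tn) / nn
}

#' Screen candidate gene pairs end to end
#'
#' Enumerates all pairs containing at least one response gene, orients
#' them by ED (rejecting ED = 0 and flipping negative EDs), applies the
#' two-sided Wilcoxon rank-sum screen on the within-sample differences,
#' computes per-pair confusion counts from the vote E_i > E_j (strict
#' inequality; ties vote non-responder), the accuracy F-score, and the
#' one-sided exact binomial filter against the no-information rate.
#'
#' @param expr Gene-by-sample matrix.
#' @param labels A `reo_labels` object or named label vector.
#' @param response_genes Character vector (or screen table) of response
#'   gene ids.
#' @param params A [pair_screen_params()] object.
#' @param block_size Pairs processed per block (memory control).
#' @return A data.frame of oriented records passing the Wilcoxon screen
#'   (columns `gene_i`, `gene_j`, `ed`, `wilcoxon_p`, `binomial_p`, `tp`,
#'   `tn`, `fp`, `fn`, `f_score`, `binomial_pass`), sorted by the
#'   deterministic order (-f_score, wilcoxon_p, gene_i, gene_j);
#'   attribute `funnel` records the pair counts after each filtering
#'   step.  Use [candidate_pairs()] to extract the forward-selection
#'   pool.
#' @export
screen_pairs <- function(expr, labels, response_genes,
                         params = pair_screen_params(),
                         block_size = 50000L) {
  check_expression(expr)
  if (inherits(labels, "reo_labels")) labels <- labels$labels
  li <- label_indices(expr, labels)
  n1 <- length(li$resp); n2 <- length(li$nonresp); nlab <- n1 + n2
  p0 <- if (!is.null(params$binomial_null_p)) params$binomial_null_p
        else max(n1, n2) / nlab

  pairs <- enumerate_pairs(response_genes, rownames(expr))
  n_total <- nrow(pairs)
  sub <- expr[, li$cols, drop = FALSE]

  n_ed_pos <- 0L
  res <- vector("list", ceiling(max(n_total, 1) / block_size))
  bi <- 0L
  for (start in seq.int(1L, max(n_total, 1L), by = block_size)) {
    if (n_total == 0L) break
    idx <- start:min(start + block_size - 1L, n_total)
    gi <- pairs$gene_i[idx]; gj <- pairs$gene_j[idx]
    D <- sub[gi, , drop = FALSE] - sub[gj, , drop = FALSE]
    ed <- rowMeans(D[, li$resp, drop = FALSE]) -
      rowMeans(D[, li$nonresp, drop = FALSE])
    flip <- ed < 0
    if (any(flip)) {
      tmp <- gi[flip]; gi[flip] <- gj[flip]; gj[flip] <- tmp
      D[flip, ] <- -D[flip, , drop = FALSE]
      ed[flip] <- -ed[flip]
    }
    keep <- ed > 0
    if (!any(keep)) next
    n_ed_pos <- n_ed_pos + sum(keep)
    gi <- gi[keep]; gj <- gj[keep]
    D <- D[keep, , drop = FALSE]; ed <- ed[keep]
    wp <- row_ranksum_p(D, li$resp, li$nonresp)
    keep2 <- wp < params$wilcoxon_p_threshold
    if (!any(keep2)) next
    gi <- gi[keep2]; gj <- gj[keep2]
    D <- D[keep2, , drop = FALSE]; ed <- ed[keep2]; wp <- wp[keep2]
    vote <- D > 0                              # strict: ties vote non-responder
    tp <- as.integer(rowSums(vote[, li$resp, drop = FALSE]))
    tn <- as.integer(rowSums(!vote[, li$nonresp, drop = FALSE]))
    fn <- n1 - tp; fp <- n2 - tn
    f <- (tp + tn) / nlab
    bp <- stats::pbinom(tp + tn - 1, nlab, p0, lower.tail = FALSE)
    bi <- bi + 1L
    res[[bi]] <- data.frame(gene_i = gi, gene_j = gj, ed = ed,
                            wilcoxon_p = wp, binomial_p = bp,
                            tp = tp, tn = tn, fp = fp, fn = fn,
                            f_score = f, binomial_pass = bp < params$binomial_alpha,
                            stringsAsFactors = FALSE)
  }
  out <- if (bi > 0L) do.call(rbind, res[seq_len(bi)]) else
    data.frame(gene_i = character(0), gene_j = character(0), ed = numeric(0),
               wilcoxon_p = numeric(0), binomial_p = numeric(0),
               tp = integer(0), tn = integer(0), fp = integer(0),
               fn = integer(0), f_score = numeric(0),
               binomial_pass = logical(0), stringsAsFactors = FALSE)
  out <- out[order(-out$f_score, out$wilcoxon_p, out$gene_i, out$gene_j), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            funnel = list(n_pairs_total = n_total,
                          n_ed_positive = n_ed_pos,
                          n_wilcoxon_pass = nrow(out),
                          n_binomial_pass = sum(out$binomial_pass),
                          binomial_null_p = p0))
}

#' Candidate pool for forward selection
#'
#' Pairs passing both the Wilcoxon and the exact-binomial filters, in the
#' deterministic order (-f_score, wilcoxon_p, gene_i, gene_j), capped at
#' `cap` records for tractability.
#'
#' @param pair_table Output of [screen_pairs()].
#' @param cap Maximum pool size (default 10000).
#' @return The capped candidate data.frame.
#' @export
candidate_pairs <- function(pair_table, cap = 10000L) {
  out <- pair_table[pair_table$binomial_pass, , drop = FALSE]
  if (nrow(out) > cap) out <- out[seq_len(cap), , drop = FALSE]
  rownames(out) <- NULL
  out
}
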