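#' Construct a gene-pair signature object
#'
#' @param pairs data.frame with columns `gene_i`, `gene_j`, one oriented
#'   pair per row (gene i above gene j indicates response).
#' @param vote_threshold Minimum score (number of pairs in the
#'   responder-indicating ordering) to call a sample a responder; default
#'   the strict majority of the signature size.
#' @param provenance Optional selection log.
#' @return An object of class `reo_signature`.
#' @export
new_signature <- function(pairs, vote_threshold = NULL, provenance = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_i", "gene_j") %in% names(pairs)))
    stop("pairs need columns gene_i and gene_j")
  pairs <- pairs[, c("gene_i", "gene_j")]
  k <- nrow(pairs)
  if (k < 1L) stop("a signature needs at least one pair")
  key <- paste(pmin(pairs$gene_i, pairs$gene_j),
               pmax(pairs$gene_i, pairs$gene_j))
  if (anyDuplicated(key))
    stop("a pair appears more than once (possibly in both orientations)")
  if (is.null(vote_threshold)) vote_threshold <- default_threshold(k)
  vote_threshold <- as.integer(vote_threshold)
  if (vote_threshold < 1L || vote_threshold > k)
    stop("vote_threshold must be between 1 and the number of pairs")
  structure(list(pairs = pairs, vote_threshold = vote_threshold,
                 provenance = provenance),
            class = "reo_signature")
}

#' @export
print.reo_signature <- function(x, ...) {
  cat(sprintf("reo_signature: %d gene pair(s), responder if score >= %d\n",
              nrow(x$pairs), x$vote_threshold))
  for (k in seq_len(nrow(x$pairs)))
    cat(sprintf("  %s > %s\n", x$pairs$gene_i[k], x$pairs$gene_j[k]))
  invisible(x)
}

#' Strict-majority vote threshold
#'
#' `floor(k/2) + 1` — e.g. 2 of 3 pairs.
#'
#' @param k Signature size (>= 1).
#' @return The threshold (integer).
#' @export
default_threshold <- function(k) {
  if (k < 1) stop("signature size must be at least 1")
  as.integer(k %/% 2 + 1L)
}

#' Score samples with a gene-pair signature
#'
#' A sample's score is the number of signature pairs whose
#' responder-indicating ordering E_i > E_j (strict) holds within that
#' sample; samples scoring at least the vote threshold are classified as
#' responders.  Only the sample's own column is used, so the classifier
#' applies to a single sample and is invariant to any strictly increasing
#' within-sample transform.
#'
#' @param sig A `reo_signature`.
#' @param expr Gene-by-sample matrix containing every signature gene.
#' @return A data.frame (`sample_id`, `score`, `predicted`).
#' @export
score_samples <- function(sig, expr) {
  check_expression(expr)
  genes <- unique(c(sig$pairs$gene_i, sig$pairs$gene_j))
  absent <- setdiff(genes, rownames(expr))
  if (length(absent))
    stop("signature gene(s) missing from expression matrix: ",
         paste(absent, collapse = ", "))
  votes <- expr[sig$pairs$gene_i, , drop = FALSE] >
    expr[sig$pairs$gene_j, , drop = FALSE]
  score <- as.integer(colSums(votes))
  data.frame(sample_id = colnames(expr), score = score,
             predicted = ifelse(score >= sig$vote_threshold,
                                "responder", "non_responder"),
             stringsAsFactors = FALSE)
}

## Vote threshold used while a signature is growing: "at least half",
## ceiling(k/2).  Identical to the strict majority at odd sizes (2 of 3),
## but at transient even sizes it keeps the rule a true majority vote
## rather than an AND over k/2+1 pairs; an AND rule can never improve on
## a high-specificity seed, which would freeze greedy growth at size 1.
selection_threshold <- function(k) as.integer(ceiling(k / 2))

## majority-vote accuracy of candidate subsets, from a precomputed vote
## matrix (pairs x labeled samples) and the logical truth vector
subset_correct_count <- function(votes, sel, y_resp) {
  score <- colSums(votes[sel, , drop = FALSE])
  thr <- selection_threshold(length(sel))
  sum((score >= thr) == y_resp)
}

#' Greedy forward selection of a gene-pair signature
#'
#' The candidates are ordered by (-f_score, wilcoxon_p, gene_i, gene_j);
#' each of the top `n_seeds` pairs seeds a signature that grows greedily:
#' at every step all remaining candidates are scanned and the one giving
#' the largest strict increase in signature-level accuracy (majority-vote
#' classification re-thresholded at each size) is added, until no
#' addition strictly improves accuracy or `max_pairs` is reached.  The
#' best of the seeded signatures is returned (highest accuracy; ties
#' broken by fewer pairs, then seed order).
#'
#' @param candidates data.frame of oriented pairs (`gene_i`, `gene_j`,
#'   and — if present — `f_score`, `wilcoxon_p` used for ordering).
#' @param expr Gene-by-sample matrix.
#' @param labels A `reo_labels` object or named label vector.
#' @param n_seeds Number of top candidates used as seeds (default 20).
#' @param max_pairs Safety bound on the signature size (default 11).
#' @return A `reo_signature` whose `provenance` records the seed pair,
#'   the accuracy trajectory of the winning signature, and a per-seed
#'   summary.
#' @export
forward_select <- function(candidates, expr, labels, n_seeds = 20L,
                           max_pairs = 11L) {
  if (!nrow(candidates)) stop("candidate list is empty")
  if (inherits(labels, "reo_labels")) labels <- labels$labels
  li <- label_indices(expr, labels)
  ord <- if (all(c("f_score", "wilcoxon_p") %in% names(candidates)))
    order(-candidates$f_score, candidates$wilcoxon_p,
          candidates$gene_i, candidates$gene_j)
  else order(candidates$gene_i, candidates$gene_j)
  cand <- candidates[ord, , drop = FALSE]
  rownames(cand) <- NULL
  nlab <- length(li$cols)
  y_resp <- logical(nlab); y_resp[li$resp] <- TRUE
  sub <- expr[, li$cols, drop = FALSE]
  votes <- sub[cand$gene_i, , drop = FALSE] > sub[cand$gene_j, , drop = FALSE]
  nc <- nrow(cand)
  y_mat_true <- matrix(y_resp, nrow = nc, ncol = nlab, byrow = TRUE)

  n_seeds <- min(n_seeds, nc)
  runs <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    sel <- s
    best <- subset_correct_count(votes, sel, y_resp)
    trajectory <- best
    repeat {
      if (length(sel) >= max_pairs) break
      remaining <- setdiff(seq_len(nc), sel)
      if (!length(remaining)) break
      base <- colSums(votes[sel, , drop = FALSE])
      thr <- selection_threshold(length(sel) + 1L)
      scores <- sweep(votes[remaining, , drop = FALSE] * 1L, 2L, base, "+")
      correct <- (scores >= thr) == y_mat_true[remaining, , drop = FALSE]
      counts <- rowSums(correct)
      j <- which.max(counts)               # first maximum: candidate order
      if (counts[j] <= best) break         # no strict improvement
      sel <- c(sel, remaining[j])
      best <- counts[j]
      trajectory <- c(trajectory, best)
    }
    runs[[s]] <- list(sel = sel, correct = best,
                      f_score = best / nlab, trajectory = trajectory / nlab)
  }
  corrects <- vapply(runs, `[[`, numeric(1), "correct")
  sizes <- vapply(runs, function(r) length(r$sel), numeric(1))
  win <- order(-corrects, sizes, seq_len(n_seeds))[1]
  w <- runs[[win]]
  sig_pairs <- cand[w$sel, c("gene_i", "gene_j"), drop = FALSE]
  provenance <- list(
    seed_pair = cand[w$sel[1], c("gene_i", "gene_j")],
    seed_rank = win,
    f_score = w$f_score,
    trajectory = w$trajectory,
    n_candidates = nc,
    seeds = lapply(runs, function(r)
      list(size = length(r$sel), f_score = r$f_score)))
  new_signature(sig_pairs,
                vote_threshold = selection_threshold(nrow(sig_pairs)),
                provenance = provenance)
}
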