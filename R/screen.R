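#' Screening parameters for response genes
#'
#' @param p_threshold Raw two-sided significance level (default 0.05).
#'   No multiple-testing correction is applied at this stage; the screen
#'   filters on the raw p-value.
#' @param r_threshold Absolute Spearman correlation cutoff (default 0.3).
#' @return A validated `screen_params` list.
#' @export
screen_params <- function(p_threshold = 0.05, r_threshold = 0.3) {
  if (!(p_threshold > 0 && p_threshold < 1)) stop("p_threshold must be in (0,1)")
  if (!(r_threshold >= 0 && r_threshold < 1)) stop("r_threshold must be in [0,1)")
  structure(list(p_threshold = p_threshold, r_threshold = r_threshold),
            class = "screen_params")
}

#' Screen response genes by Spearman correlation with a continuous
#' response measure
#'
#' For every gene, the Spearman rank correlation (average ranks on ties)
#' with the lesion-size measure is computed across samples, with a
#' two-sided p-value from the t approximation on rho (df = n - 2), or by
#' the exact null distribution for n <= 10 when `exact = TRUE`.  A gene is
#' retained when p < `p_threshold` and |rho| > `r_threshold`.  Genes with
#' zero variance (rho undefined) are skipped and counted.
#'
#' @param expr Gene-by-sample matrix.
#' @param lesion Named numeric vector of the continuous response measure;
#'   names must match sample ids in `expr`.  Samples with missing lesion
#'   values are dropped.
#' @param params A [screen_params()] object.
#' @param exact Use the exact Spearman null distribution (n <= 10, no
#'   ties) instead of the t approximation.
#' @return A data.frame (`gene_id`, `rho`, `p_value`) of retained genes,
#'   sorted by p-value; attributes `n_tested`, `n_skipped_constant`.
#' @export
screen_response_genes <- function(expr, lesion, params = screen_params(),
                                  exact = FALSE) {
  check_expression(expr)
  if (is.null(names(lesion))) stop("lesion vector must be named by sample id")
  lesion <- lesion[!is.na(lesion)]
  common <- intersect(colnames(expr), names(lesion))
  if (length(setdiff(names(lesion), colnames(expr))))
    stop("lesion names not present in the expression matrix: ",
         paste(setdiff(names(lesion), colnames(expr)), collapse = ", "))
  if (length(common) < 4L)
    stop("need at least 4 samples with non-missing lesion values, have ",
         length(common))
  x <- expr[, common, drop = FALSE]
  y <- lesion[common]
  n <- length(common)

  const <- apply(x, 1, function(v) max(v) == min(v))
  xt <- x[!const, , drop = FALSE]
  ry <- rank(y)
  rx <- t(apply(xt, 1, rank))
  rho <- as.numeric(stats::cor(t(rx), ry))

  if (exact) {
    if (n > 10L) stop("exact Spearman p-values are supported for n <= 10")
    p <- vapply(seq_len(nrow(xt)), function(k)
      stats::cor.test(xt[k, ], y, method = "spearman", exact = TRUE)$p.value,
      numeric(1))
  } else {
    tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p[abs(rho) >= 1] <- 0
  }

  keep <- p < params$p_threshold & abs(rho) > params$r_threshold
  out <- data.frame(gene_id = rownames(xt)[keep], rho = rho[keep],
                    p_value = p[keep], stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_tested = nrow(xt), n_skipped_constant = sum(const),
            n_samples = n)
}

#' Analytic power of the two-sided rank-correlation screen
#'
#' Power of the two-sided test of zero correlation at sample size `n`,
#' assumed population correlation `r` and level `alpha`, by the
#' critical-r construction: the critical correlation is obtained from the
#' t distribution with n - 2 df, and the comparison is made on the
#' Fisher-z (atanh) scale with standard deviation `1/sqrt(n - 3)` and the
#' small-sample mean correction `r / (2 (n - 1))`.
#'
#' @param n Sample size (>= 4).
#' @param r Assumed correlation, |r| < 1.
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
power_spearman <- function(n, r, alpha = 0.05) {
  if (n < 4) stop("n must be at least 4")
  if (!(abs(r) < 1)) stop("|r| must be < 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  r <- abs(r)
  tc <- stats::qt(1 - alpha / 2, df = n - 2)
  rc <- tc / sqrt(tc^2 + n - 2)           # critical |correlation|
  za <- atanh(rc)
  zr <- atanh(r) + r / (2 * (n - 1))      # mean-corrected Fisher z
  s <- 1 / sqrt(n - 3)
  stats::pnorm((zr - za) / s) + stats::pnorm((-za - zr) / s)
}
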