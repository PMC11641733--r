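#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' Defaults emulate the training cohort the signature method targets:
#' 47 metastatic colorectal cancer samples (36 responders, 11 non-responders)
#' on a log2-scale expression matrix, with a handful of planted informative
#' gene pairs, a block of genes correlated with a continuous lesion-size
#' response measure, and exponential progression-free survival whose hazard
#' depends on true responder status.
#'
#' @param n_genes Number of genes in the matrix.
#' @param n_samples Number of samples.
#' @param n_responders Number of true responders (the rest are
#'   non-responders).
#' @param n_planted_pairs Number of planted informative gene pairs.  Each
#'   pair occupies two dedicated genes, disjoint from all other planted
#'   genes and from the response-gene block.
#' @param planted_flip_prob Probability that a planted pair's
#'   responder-indicating ordering (gene i above gene j) is violated in a
#'   responder sample, and holds in a non-responder sample.
#' @param n_response_genes Number of genes correlated with the lesion-size
#'   measure.
#' @param lesion_corr Target magnitude of the (Pearson, latent-scale)
#'   correlation between each response gene and the lesion measure, in (0,1).
#' @param hazard_ratio_true Non-responder vs responder hazard ratio for
#'   progression-free survival (> 1 means non-responders progress faster).
#' @param censor_rate Marginal probability that a sample is censored.
#' @param seed Integer seed; the generator is fully reproducible given the
#'   configuration.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000L, n_samples = 47L, n_responders = 36L,
                       n_planted_pairs = 3L, planted_flip_prob = 0.05,
                       n_response_genes = 50L, lesion_corr = 0.6,
                       hazard_ratio_true = 2, censor_rate = 0.2,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples = as.integer(n_samples),
              n_responders = as.integer(n_responders),
              n_planted_pairs = as.integer(n_planted_pairs),
              planted_flip_prob = planted_flip_prob,
              n_response_genes = as.integer(n_response_genes),
              lesion_corr = lesion_corr,
              hazard_ratio_true = hazard_ratio_true,
              censor_rate = censor_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  with(cfg, {
    if (n_genes < 1L) stop("n_genes must be a positive integer")
    if (n_samples < 2L) stop("n_samples must be at least 2")
    if (n_responders < 1L || n_samples - n_responders < 1L)
      stop("need at least one responder and one non-responder")
    if (n_planted_pairs < 0L || n_response_genes < 0L)
      stop("n_planted_pairs and n_response_genes must be non-negative")
    if (2L * n_planted_pairs + n_response_genes > n_genes)
      stop("planted pairs and response genes do not fit in n_genes: ",
           "need ", 2L * n_planted_pairs + n_response_genes,
           " genes, have ", n_genes)
    if (planted_flip_prob < 0 || planted_flip_prob > 1)
      stop("planted_flip_prob must be in [0, 1]")
    if (!(lesion_corr > 0 && lesion_corr < 1))
      stop("lesion_corr must be in (0, 1)")
    if (hazard_ratio_true <= 0) stop("hazard_ratio_true must be positive")
    if (censor_rate < 0 || censor_rate > 1)
      stop("censor_rate must be in [0, 1]")
    if (!is.finite(seed)) stop("seed must be a finite integer")
  })
  invisible(cfg)
}

#' Simulate an expression/clinical dataset with known ground truth
#'
#' Background genes are i.i.d. Gaussian on a log2-like intensity scale
#' (mean 7, sd 1.5).  Planted informative pairs are imposed by swapping the
#' two genes' values within a sample so that the responder-indicating
#' ordering holds with probability `1 - planted_flip_prob` in responders and
#' `planted_flip_prob` in non-responders; the marginal distributions are
#' untouched.  Response genes are tied to a latent lesion-size variable
#' (larger in non-responders) so that both the continuous rank-correlation
#' screen and the binary rank-sum screen see consistent signal.
#' Progression-free survival is exponential with the configured
#' non-responder/responder hazard ratio and independent exponential
#' censoring calibrated to the marginal censoring rate.
#'
#' @param config A [sim_config()] object.
#' @return A list with components
#'   \describe{
#'     \item{expr}{numeric gene-by-sample matrix with gene/sample ids as
#'       dimnames,}
#'     \item{clinical}{a data.frame with columns `sample_id`,
#'       `response_category`, `lesion_size`, `pfs_time`, `pfs_event`,
#'       `age`, `gender`, `stage`, `location`,}
#'     \item{truth}{the ground truth: `planted_pairs` (data.frame
#'       `gene_i`, `gene_j`; gene i is the one elevated in responders),
#'       `response_gene_ids`, `true_labels` (named character,
#'       responder/non_responder), `true_lesion`.}
#'   }
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples
  gene_ids <- sprintf("g%05d", seq_len(ng))
  sample_ids <- sprintf("s%03d", seq_len(ns))

  lab <- sample(c(rep("responder", config$n_responders),
                  rep("non_responder", ns - config$n_responders)))
  names(lab) <- sample_ids
  resp <- lab == "responder"

  expr <- matrix(stats::rnorm(ng * ns, mean = 7, sd = 1.5), nrow = ng,
                 dimnames = list(gene_ids, sample_ids))

  ## lesion size: continuous response measure, larger in non-responders
  lesion <- stats::rnorm(ns, mean = ifelse(resp, 0, 1.5), sd = 1)
  names(lesion) <- sample_ids

  ## response genes: correlated with the (standardized) lesion measure
  n_rg <- config$n_response_genes
  rg_idx <- seq_len(n_rg) + 2L * config$n_planted_pairs
  if (n_rg > 0L) {
    z <- as.numeric(scale(lesion))
    rho <- config$lesion_corr
    sgn <- rep_len(c(1, -1), n_rg)        # both correlation directions
    for (k in seq_len(n_rg)) {
      eps <- stats::rnorm(ns)
      expr[rg_idx[k], ] <- 7 + 1.5 * (sgn[k] * rho * z + sqrt(1 - rho^2) * eps)
    }
  }

  ## planted pairs: gene i is itself lesion-correlated (negatively: high
  ## expression in the small-lesion responders) so planted pairs contain a
  ## response gene and enter the candidate-pair universe; the
  ## responder-indicating ordering is then imposed by swapping the two
  ## genes' values within a sample, which preserves both marginals and
  ## enforces the ordering probabilities exactly
  npp <- config$n_planted_pairs
  planted <- data.frame(gene_i = character(0), gene_j = character(0),
                        stringsAsFactors = FALSE)
  if (npp > 0L) {
    gi <- 2L * seq_len(npp) - 1L
    gj <- 2L * seq_len(npp)
    planted <- data.frame(gene_i = gene_ids[gi], gene_j = gene_ids[gj],
                          stringsAsFactors = FALSE)
    z <- as.numeric(scale(lesion))
    rho <- config$lesion_corr
    for (k in seq_len(npp)) {
      eps <- stats::rnorm(ns)
      expr[gi[k], ] <- 7 + 1.5 * (-rho * z + sqrt(1 - rho^2) * eps)
    }
    p_hold <- ifelse(resp, 1 - config$planted_flip_prob,
                     config$planted_flip_prob)
    for (k in seq_len(npp)) {
      want <- stats::runif(ns) < p_hold   # TRUE: gene_i above gene_j
      xi <- expr[gi[k], ]; xj <- expr[gj[k], ]
      swap <- (xi > xj) != want
      tmp <- xi[swap]; xi[swap] <- xj[swap]; xj[swap] <- tmp
      expr[gi[k], ] <- xi; expr[gj[k], ] <- xj
    }
  }

  ## survival: exponential PFS, hazard ratio between the true groups,
  ## independent exponential censoring hitting the marginal censor rate
  h_resp <- log(2) / 12                  # responder median PFS 12 months
  h <- ifelse(resp, h_resp, h_resp * config$hazard_ratio_true)
  t_event <- stats::rexp(ns, rate = h)
  if (config$censor_rate > 0) {
    c_rate <- h * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(ns, rate = c_rate)
  } else {
    t_cens <- rep(Inf, ns)
  }
  pfs_time <- pmin(t_event, t_cens)
  pfs_event <- as.integer(t_event <= t_cens)

  n_cr <- max(1L, round(0.2 * config$n_responders))
  cat_resp <- sample(c(rep("CR", n_cr),
                       rep("PR", config$n_responders - n_cr)))
  response_category <- ifelse(resp, NA_character_, "PD")
  response_category[resp] <- cat_resp

  clinical <- data.frame(
    sample_id = sample_ids,
    response_category = response_category,
    lesion_size = round(lesion, 4),
    pfs_time = round(pfs_time, 4),
    pfs_event = pfs_event,
    age = round(stats::rnorm(ns, mean = 62, sd = 10)),
    gender = sample(c("male", "female"), ns, replace = TRUE),
    stage = sample(c("III", "IV"), ns, replace = TRUE, prob = c(0.3, 0.7)),
    location = sample(c("left", "right", "rectum"), ns, replace = TRUE),
    stringsAsFactors = FALSE
  )
  rownames(clinical) <- NULL

  truth <- list(planted_pairs = planted,
                response_gene_ids = gene_ids[rg_idx],
                true_labels = lab,
                true_lesion = lesion)
  list(expr = expr, clinical = clinical, truth = truth)
}

#' Distort each sample by a random strictly increasing transform
#'
#' Applies an independently drawn strictly monotone function to every
#' sample (column): `f(x) = a x + b (x - m)^3 + c` with `a, b > 0` and `m`
#' the sample median.  Within-sample ranks — and therefore every
#' relative-expression-ordering quantity downstream — are preserved
#' exactly.  This emulates batch/platform effects that rank-based
#' classification must be invariant to.
#'
#' @param expr Numeric gene-by-sample matrix with finite values.
#' @param seed Integer seed; each sample gets an independent sub-stream so
#'   a column's transform does not depend on how many other columns exist.
#' @param fns Optional list of per-sample functions overriding the random
#'   draw (e.g. `identity`); length 1 or `ncol(expr)`.
#' @return A matrix of the same shape and dimnames.
#' @export
apply_monotone_distortion <- function(expr, seed = 1L, fns = NULL) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expr must be a numeric matrix")
  if (!all(is.finite(expr))) stop("expr contains non-finite values")
  ns <- ncol(expr)
  if (!is.null(fns)) {
    fns <- rep_len(fns, ns)
  } else {
    set.seed(as.integer(seed))
    sub_seeds <- sample.int(.Machine$integer.max, ns)
    fns <- lapply(seq_len(ns), function(s) {
      set.seed(sub_seeds[s])
      a <- stats::runif(1, 0.5, 2)
      b <- stats::runif(1, 0.05, 0.5)
      cc <- stats::runif(1, -3, 3)
      m <- stats::median(expr[, s])
      function(x) a * x + b * (x - m)^3 + cc
    })
  }
  out <- expr
  for (s in seq_len(ns)) out[, s] <- fns[[s]](expr[, s])
  out
}
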