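#' Confusion metrics of predicted response labels
#'
#' Responders are the positive class.  Sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP), and the accuracy-style F-score
#' (TP+TN)/(TP+FN+TN+FP).
#'
#' @param predicted A score data.frame from [score_samples()] (columns
#'   `sample_id`, `predicted`) or a named character vector of
#'   `responder`/`non_responder` predictions.
#' @param labels A `reo_labels` object or named label vector; every
#'   labeled sample must have a prediction.
#' @return A list (class `reo_confusion`) with `tp`, `tn`, `fp`, `fn`,
#'   `sensitivity`, `specificity`, `f_score`.
#' @export
confusion_metrics <- function(predicted, labels) {
  if (is.data.frame(predicted)) {
    pred <- predicted$predicted
    names(pred) <- predicted$sample_id
  } else pred <- predicted
  if (inherits(labels, "reo_labels")) labels <- labels$labels
  missing_p <- setdiff(names(labels), names(pred))
  if (length(missing_p))
    stop("labeled samples without a prediction: ",
         paste(missing_p, collapse = ", "))
  pred <- pred[names(labels)]
  tp <- sum(pred == "responder" & labels == "responder")
  tn <- sum(pred == "non_responder" & labels == "non_responder")
  fp <- sum(pred == "responder" & labels == "non_responder")
  fn <- sum(pred == "non_responder" & labels == "responder")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 f_score = (tp + tn) / (tp + tn + fp + fn)),
            class = "reo_confusion")
}

#' @export
print.reo_confusion <- function(x, ...) {
  cat(sprintf(
    "confusion: TP=%d TN=%d FP=%d FN=%d | sens=%.3f spec=%.3f acc/F=%.3f\n",
    x$tp, x$tn, x$fp, x$fn, x$sensitivity, x$specificity, x$f_score))
  invisible(x)
}

#' Rank-based AUC of per-sample scores
#'
#' The probability that a random responder outscores a random
#' non-responder, counting ties as one half — the Mann-Whitney
#' formulation of the area under the ROC curve.
#'
#' @param scores Named numeric/integer vector of per-sample scores, or a
#'   score data.frame from [score_samples()].
#' @param labels A `reo_labels` object or named label vector; both
#'   classes must be present among the scored samples.
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  if (is.data.frame(scores)) {
    s <- scores$score
    names(s) <- scores$sample_id
  } else s <- scores
  if (inherits(labels, "reo_labels")) labels <- labels$labels
  labels <- labels[names(labels) %in% names(s)]
  s <- s[names(labels)]
  resp <- labels == "responder"
  n1 <- sum(resp); n2 <- sum(!resp)
  if (n1 == 0 || n2 == 0)
    stop("AUC needs both responders and non-responders")
  r <- rank(s)
  (sum(r[resp]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Survival validation of a binary predicted grouping
#'
#' Fits a univariate Cox proportional-hazards model of progression-free
#' survival on the predicted group (non-responder as the reference level,
#' so a hazard ratio below 1 means predicted responders progress more
#' slowly), a multivariate model adding the requested clinical
#' covariates, and per-group Kaplan-Meier curves.  Efron handling of tied
#' event times; Wald 95% confidence intervals on the log-hazard scale.
#'
#' @param predicted A score data.frame from [score_samples()] or named
#'   vector of `responder`/`non_responder` predictions.
#' @param clinical Clinical table with `sample_id`, `pfs_time`,
#'   `pfs_event` and any requested covariate columns.
#' @param covariates Character vector of clinical column names to adjust
#'   for in the multivariate model (default none).
#' @return A list (class `reo_survival`) with `estimable`,
#'   `hr_univariate` and `hr_multivariate` (each `hr`, `ci_low`,
#'   `ci_high`, `p`), `km` (data.frame `time`, `surv`, `group`), and
#'   `n_per_group`.  When one predicted group is empty or there are no
#'   events, `estimable` is `FALSE` and no fit is attempted.
#' @export
survival_validation <- function(predicted, clinical, covariates = character(0)) {
  if (is.data.frame(predicted)) {
    grp <- predicted$predicted
    names(grp) <- predicted$sample_id
  } else grp <- predicted
  df <- clinical[match(names(grp), clinical$sample_id), , drop = FALSE]
  if (anyNA(df$sample_id))
    stop("predictions for samples absent from the clinical table: ",
         paste(names(grp)[is.na(df$sample_id)], collapse = ", "))
  keep <- !is.na(df$pfs_time) & !is.na(df$pfs_event)
  df <- df[keep, , drop = FALSE]
  grp <- grp[keep]
  df$.group <- factor(grp, levels = c("non_responder", "responder"))
  n_per_group <- table(df$.group)
  not_est <- function(reason)
    structure(list(estimable = FALSE, reason = reason,
                   n_per_group = as.list(n_per_group)),
              class = "reo_survival")
  if (any(n_per_group == 0)) return(not_est("a predicted group is empty"))
  if (sum(df$pfs_event) == 0) return(not_est("no events in either group"))

  surv <- survival::Surv(df$pfs_time, df$pfs_event)
  fit_u <- survival::coxph(surv ~ .group, data = df, ties = "efron")
  su <- summary(fit_u)
  hr_row <- function(s, term) {
    i <- grep(term, rownames(s$conf.int))[1]
    list(hr = unname(s$conf.int[i, "exp(coef)"]),
         ci_low = unname(s$conf.int[i, "lower .95"]),
         ci_high = unname(s$conf.int[i, "upper .95"]),
         p = unname(s$coefficients[i, "Pr(>|z|)"]))
  }
  hr_uni <- hr_row(su, "^\\.group")

  hr_multi <- NULL
  if (length(covariates)) {
    missing_c <- setdiff(covariates, names(df))
    if (length(missing_c))
      stop("covariates absent from the clinical table: ",
           paste(missing_c, collapse = ", "))
    fml <- stats::as.formula(paste("surv ~ .group +",
                                   paste(covariates, collapse = " + ")))
    fit_m <- tryCatch(survival::coxph(fml, data = df, ties = "efron"),
                      error = function(e) NULL)
    if (!is.null(fit_m)) hr_multi <- hr_row(summary(fit_m), "^\\.group")
  }

  km_fit <- survival::survfit(surv ~ .group, data = df)
  km_groups <- rep(sub("^\\.group=", "", names(km_fit$strata)),
                   km_fit$strata)
  km <- data.frame(time = km_fit$time, surv = km_fit$surv,
                   group = km_groups, stringsAsFactors = FALSE)

  structure(list(estimable = TRUE, hr_univariate = hr_uni,
                 hr_multivariate = hr_multi, km = km,
                 n_per_group = as.list(n_per_group),
                 n_events = sum(df$pfs_event)),
            class = "reo_survival")
}

#' @export
print.reo_survival <- function(x, ...) {
  if (!x$estimable) {
    cat("survival validation not estimable:", x$reason, "\n")
    return(invisible(x))
  }
  u <- x$hr_univariate
  cat(sprintf("univariate HR (responder vs non-responder) = %.2f [%.2f, %.2f], p = %.3g\n",
              u$hr, u$ci_low, u$ci_high, u$p))
  if (!is.null(x$hr_multivariate)) {
    m <- x$hr_multivariate
    cat(sprintf("multivariate HR = %.2f [%.2f, %.2f], p = %.3g\n",
                m$hr, m$ci_low, m$ci_high, m$p))
  }
  invisible(x)
}

#' Monte-Carlo power of the two-sided Wilcoxon rank-sum test
#'
#' Simulates two Gaussian samples separated by `effect` standard
#' deviations and reports the empirical rejection rate of
#' [stats::wilcox.test()] at level `alpha`.
#'
#' @param n1,n2 Group sizes.
#' @param effect Location shift between the groups, in sd units.
#' @param alpha Two-sided significance level.
#' @param n_reps Number of Monte-Carlo replicates (>= 100).
#' @param seed Integer seed.
#' @return Empirical power in \[0, 1\].
#' @export
power_wilcoxon_mc <- function(n1, n2, effect, alpha = 0.05, n_reps = 1000L,
                              seed = 1L) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  if (n_reps < 100) stop("n_reps must be at least 100")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  set.seed(as.integer(seed))
  rej <- vapply(seq_len(n_reps), function(i) {
    x <- stats::rnorm(n1)
    y <- stats::rnorm(n2, mean = effect)
    suppressWarnings(stats::wilcox.test(x, y)$p.value) < alpha
  }, logical(1))
  mean(rej)
}
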