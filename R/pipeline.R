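## File-based pipeline stages.  Each stage reads only the declared TSV/JSON
## artifacts in `out_dir`, writes its own, and appends its counts to the
## run manifest, so stages are individually re-runnable and a full run is
## reproducible from the configuration and seed alone.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] for the simulation stage.
#' @param screen A [screen_params()].
#' @param pairs A [pair_screen_params()].
#' @param n_seeds,max_pairs,candidate_cap Forward-selection settings.
#' @param covariates Clinical covariates for the multivariate survival
#'   model.
#' @param seed Master seed (also used for the monotone-distortion check
#'   helper).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), screen = screen_params(),
                            pairs = pair_screen_params(), n_seeds = 20L,
                            max_pairs = 11L, candidate_cap = 10000L,
                            covariates = c("age", "gender", "stage", "location"),
                            seed = 1L) {
  structure(list(sim = sim, screen = screen, pairs = pairs,
                 n_seeds = as.integer(n_seeds),
                 max_pairs = as.integer(max_pairs),
                 candidate_cap = as.integer(candidate_cap),
                 covariates = covariates, seed = as.integer(seed)),
            class = "pipeline_config")
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

update_manifest <- function(out_dir, stage, entry) {
  path <- manifest_path(out_dir)
  manifest <- if (file.exists(path))
    jsonlite::read_json(path) else list(package_version =
                                          as.character(utils::packageVersion("reogps")),
                                        stages = list())
  manifest$stages[[stage]] <- entry
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Pipeline stages
#'
#' `pipeline_simulate()` writes `expression.tsv`, `clinical.tsv` and
#' `truth.json`; `pipeline_screen_genes()` writes `response_genes.tsv`;
#' `pipeline_screen_pairs()` writes `pairs.tsv` (records passing the
#' rank-sum screen, with binomial flags); `pipeline_select()` writes
#' `signature.tsv` and `selection_log.json`; `pipeline_apply()` writes
#' `scores.tsv`; `pipeline_evaluate()` writes `report.json`.
#' [run_pipeline()] chains all six.  Every stage logs its sample / gene /
#' pair counts into `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Artifact directory (created if needed).
#' @return Each stage invisibly returns its main in-memory artifact.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config$sim)
  write_expression(sim$expr, file.path(out_dir, "expression.tsv"))
  write_clinical(sim$clinical, file.path(out_dir, "clinical.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  update_manifest(out_dir, "simulate",
                  list(config = unclass(config$sim),
                       n_genes = nrow(sim$expr), n_samples = ncol(sim$expr)))
  invisible(sim)
}

#' @rdname pipeline
#' @export
pipeline_screen_genes <- function(config, out_dir) {
  expr <- read_expression(file.path(out_dir, "expression.tsv"))
  clinical <- read_clinical(file.path(out_dir, "clinical.tsv"))
  lesion <- stats::setNames(clinical$lesion_size, clinical$sample_id)
  rg <- screen_response_genes(expr, lesion, config$screen)
  utils::write.table(rg, file.path(out_dir, "response_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  update_manifest(out_dir, "screen_genes",
                  list(n_tested = attr(rg, "n_tested"),
                       n_skipped_constant = attr(rg, "n_skipped_constant"),
                       n_response_genes = nrow(rg),
                       p_threshold = config$screen$p_threshold,
                       r_threshold = config$screen$r_threshold))
  invisible(rg)
}

#' @rdname pipeline
#' @export
pipeline_screen_pairs <- function(config, out_dir) {
  expr <- read_expression(file.path(out_dir, "expression.tsv"))
  clinical <- read_clinical(file.path(out_dir, "clinical.tsv"))
  labels <- derive_labels(clinical)
  rg <- utils::read.delim(file.path(out_dir, "response_genes.tsv"),
                          stringsAsFactors = FALSE)
  pt <- screen_pairs(expr, labels, rg$gene_id, config$pairs)
  pt_out <- pt
  pt_out$binomial_pass <- NULL
  write_pair_table(pt_out, file.path(out_dir, "pairs.tsv"))
  funnel <- attr(pt, "funnel")
  update_manifest(out_dir, "screen_pairs",
                  c(funnel, list(n_labeled = length(labels$labels),
                                 n_excluded = length(labels$excluded_samples))))
  invisible(pt)
}

#' @rdname pipeline
#' @export
pipeline_select <- function(config, out_dir) {
  expr <- read_expression(file.path(out_dir, "expression.tsv"))
  clinical <- read_clinical(file.path(out_dir, "clinical.tsv"))
  labels <- derive_labels(clinical)
  pt <- read_pair_table(file.path(out_dir, "pairs.tsv"))
  pt$binomial_pass <- pt$binomial_p <
    config$pairs$binomial_alpha
  cand <- candidate_pairs(pt, config$candidate_cap)
  sig <- forward_select(cand, expr, labels, n_seeds = config$n_seeds,
                        max_pairs = config$max_pairs)
  write_signature(sig, file.path(out_dir, "signature.tsv"))
  jsonlite::write_json(sig$provenance,
                       file.path(out_dir, "selection_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  update_manifest(out_dir, "select",
                  list(n_candidates = nrow(cand),
                       n_pairs = nrow(sig$pairs),
                       vote_threshold = sig$vote_threshold,
                       training_f_score = sig$provenance$f_score))
  invisible(sig)
}

#' @rdname pipeline
#' @export
pipeline_apply <- function(config, out_dir) {
  expr <- read_expression(file.path(out_dir, "expression.tsv"))
  sig <- read_signature(file.path(out_dir, "signature.tsv"))
  scores <- score_samples(sig, expr)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  update_manifest(out_dir, "apply",
                  list(n_scored = nrow(scores),
                       n_predicted_responder =
                         sum(scores$predicted == "responder")))
  invisible(scores)
}

#' @rdname pipeline
#' @export
pipeline_evaluate <- function(config, out_dir) {
  clinical <- read_clinical(file.path(out_dir, "clinical.tsv"))
  labels <- derive_labels(clinical)
  scores <- utils::read.delim(file.path(out_dir, "scores.tsv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(sample_id = "character"))
  conf <- confusion_metrics(scores, labels)
  auc <- auc_from_scores(scores, labels)
  surv <- survival_validation(scores, clinical,
                              covariates = config$covariates)
  report <- list(confusion = unclass(conf), auc = auc,
                 survival = unclass(surv)[setdiff(names(unclass(surv)), "km")])
  write_report_json(report, file.path(out_dir, "report.json"))
  if (surv$estimable)
    utils::write.table(surv$km, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  update_manifest(out_dir, "evaluate",
                  list(f_score = conf$f_score, auc = auc,
                       survival_estimable = surv$estimable))
  invisible(report)
}

#' @rdname pipeline
#' @export
run_pipeline <- function(config, out_dir) {
  pipeline_simulate(config, out_dir)
  pipeline_screen_genes(config, out_dir)
  pipeline_screen_pairs(config, out_dir)
  pipeline_select(config, out_dir)
  pipeline_apply(config, out_dir)
  pipeline_evaluate(config, out_dir)
}
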