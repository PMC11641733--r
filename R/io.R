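## Readers/writers for the plain-text artifact formats, plus the
## preprocessing and labeling rules applied to incoming cohorts.

#' Write / read a gene-by-sample expression matrix as TSV
#'
#' The dialect is a tab-separated table whose first column is `gene_id`
#' and whose remaining columns are samples (log-scale intensities), as in
#' transposed GEO series-matrix exports.  No quoting.
#'
#' @param expr Numeric matrix with gene ids as rownames and sample ids as
#'   colnames; all values finite.
#' @param path File path.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns the matrix.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("expected first column 'gene_id' in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  check_expression(m)
  m
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids")
  if (!all(is.finite(expr))) stop("expression values must all be finite")
  invisible(expr)
}

clinical_columns <- c("sample_id", "response_category", "lesion_size",
                      "pfs_time", "pfs_event", "age", "gender", "stage",
                      "location")

#' Write / read a clinical table as TSV
#'
#' Columns: `sample_id`, `response_category` (CR/PR/SD/PD or NA),
#' `lesion_size` (continuous response measure), `pfs_time` (months),
#' `pfs_event` (0/1), `age`, `gender`, `stage`, `location`.
#'
#' @param clinical A data.frame with the columns above.
#' @param path File path.
#' @export
write_clinical <- function(clinical, path) {
  check_clinical(clinical)
  utils::write.table(clinical[, clinical_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character"))
  check_clinical(df)
  df
}

check_clinical <- function(clinical) {
  missing_cols <- setdiff(clinical_columns, names(clinical))
  if (length(missing_cols))
    stop("clinical table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample ids")
  ev <- clinical$pfs_event
  if (!all(is.na(ev) | ev %in% c(0L, 1L))) stop("pfs_event must be 0/1")
  tt <- clinical$pfs_time
  if (any(!is.na(tt) & tt < 0)) stop("pfs_time must be non-negative")
  invisible(clinical)
}

#' Collapse a probe-level matrix to unique gene ids
#'
#' Probes mapping to no gene or to more than one gene are excluded;
#' when several probes map to the same gene their expression values are
#' averaged per sample (arithmetic mean on the provided log scale).
#' Genes left with any missing value are dropped — relative orderings are
#' undefined on missing values — and counted in the `n_na_dropped`
#' attribute.
#'
#' @param probe_matrix Numeric probe-by-sample matrix with unique probe
#'   rownames.
#' @param probe_map A data.frame with columns `probe_id` and `gene_id`,
#'   one row per probe-to-gene assignment (a probe with several rows maps
#'   to several genes and is excluded).
#' @return A gene-by-sample matrix (rows sorted by gene id) with
#'   attributes `n_probes_unmapped`, `n_probes_ambiguous`, `n_na_dropped`.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  if (!is.matrix(probe_matrix) || is.null(rownames(probe_matrix)))
    stop("probe_matrix must be a matrix with probe ids as rownames")
  if (anyDuplicated(rownames(probe_matrix)))
    stop("probe ids must be unique in the input matrix")
  if (!all(c("probe_id", "gene_id") %in% names(probe_map)))
    stop("probe_map needs columns probe_id and gene_id")
  probes <- rownames(probe_matrix)
  map <- unique(probe_map[probe_map$probe_id %in% probes &
                            !is.na(probe_map$gene_id), c("probe_id", "gene_id")])
  genes_per_probe <- table(map$probe_id)
  ambiguous <- names(genes_per_probe)[genes_per_probe > 1]
  unmapped <- setdiff(probes, map$probe_id)
  keep_map <- map[!(map$probe_id %in% ambiguous), , drop = FALSE]
  if (nrow(keep_map) == 0L)
    stop("no probes left after filtering: ", length(unmapped), " unmapped, ",
         length(ambiguous), " ambiguous (multi-gene) probes")
  sub <- probe_matrix[keep_map$probe_id, , drop = FALSE]
  gene <- factor(keep_map$gene_id, levels = sort(unique(keep_map$gene_id)))
  out <- apply(sub, 2, function(col) tapply(col, gene, mean))
  if (length(levels(gene)) == 1L) {
    out <- matrix(out, nrow = 1,
                  dimnames = list(levels(gene), colnames(probe_matrix)))
  }
  has_na <- apply(out, 1, anyNA)
  n_na <- sum(has_na)
  out <- out[!has_na, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("no genes left after dropping rows with missing values")
  structure(out, n_probes_unmapped = length(unmapped),
            n_probes_ambiguous = length(ambiguous), n_na_dropped = n_na)
}

#' Derive binary response labels from RECIST categories
#'
#' CR and PR become `responder`, PD becomes `non_responder`; SD and
#' missing categories are excluded from the labeled set (stable disease is
#' not dichotomized).
#'
#' @param clinical A clinical table (see [read_clinical()]); only
#'   `sample_id` and `response_category` are used.
#' @return An object of class `reo_labels`: list with `labels` (named
#'   character vector, values `responder`/`non_responder`) and
#'   `excluded_samples`.
#' @export
derive_labels <- function(clinical) {
  if (!all(c("sample_id", "response_category") %in% names(clinical)))
    stop("clinical table needs sample_id and response_category")
  cat <- clinical$response_category
  known <- c("CR", "PR", "SD", "PD")
  bad <- !is.na(cat) & !(cat %in% known)
  if (any(bad))
    stop("unknown response categories for samples: ",
         paste(clinical$sample_id[bad], collapse = ", "))
  lab <- ifelse(cat %in% c("CR", "PR"), "responder",
                ifelse(cat %in% "PD", "non_responder", NA_character_))
  names(lab) <- clinical$sample_id
  excluded <- clinical$sample_id[is.na(lab)]
  labels <- lab[!is.na(lab)]
  structure(list(labels = labels, excluded_samples = excluded),
            class = "reo_labels")
}

#' @export
print.reo_labels <- function(x, ...) {
  cat(sprintf("reo_labels: %d responders, %d non-responders, %d excluded\n",
              sum(x$labels == "responder"),
              sum(x$labels == "non_responder"),
              length(x$excluded_samples)))
  invisible(x)
}

#' Write / read a gene-pair signature as TSV
#'
#' Format: a comment line `#threshold=<k>`, a header `gene_i<TAB>gene_j`,
#' then one oriented pair per line (gene i is the one whose higher
#' expression indicates response).
#'
#' @param sig A `reo_signature` (see [forward_select()]) or any list with
#'   `pairs` (data.frame `gene_i`, `gene_j`) and `vote_threshold`.
#' @param path File path.
#' @export
write_signature <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#threshold=%d", as.integer(sig$vote_threshold)), con)
  writeLines("gene_i\tgene_j", con)
  writeLines(sprintf("%s\t%s", sig$pairs$gene_i, sig$pairs$gene_j), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  lines <- readLines(path)
  thr_line <- grep("^#threshold=", lines, value = TRUE)
  if (length(thr_line) != 1L)
    stop("signature file must carry exactly one '#threshold=' line")
  thr <- as.integer(sub("^#threshold=", "", thr_line))
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  new_signature(df[, c("gene_i", "gene_j")], vote_threshold = thr)
}

#' Write a pair-screening table as TSV
#'
#' Columns: gene_i, gene_j, ed, wilcoxon_p, binomial_p, tp, tn, fp, fn,
#' f_score.
#'
#' @param pairs A pair table as returned by [screen_pairs()].
#' @param path File path.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- c("gene_i", "gene_j", "ed", "wilcoxon_p", "binomial_p",
            "tp", "tn", "fp", "fn", "f_score")
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene_i = "character",
                                   gene_j = "character"))
}

#' Write an arbitrary report object as JSON
#' @param x A list (e.g. an evaluation report).
#' @param path File path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
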