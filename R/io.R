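#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample IDs and a first column of gene (or probe)
#' identifiers; the numeric body may contain missing values as empty cells or
#' `NA`. When a [probe_map()] is supplied, probe rows are collapsed to one
#' row per gene with [collapse_probes()].
#'
#' @param path Path to a TSV file.
#' @param probe_map Optional [probe_map()]; when given, row IDs are treated
#'   as probe IDs and collapsed.
#' @param cohort_id Cohort label for the returned container.
#' @return An [expression_cohort()] (without outcome; see
#'   [attach_clinical()]).
#' @export
read_expression <- function(path, probe_map = NULL, cohort_id = NULL) {
  if (!file.exists(path)) rxa_abort("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) rxa_abort("malformed expression file (need header + data): ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) < 1 || any(!nzchar(samples)))
    rxa_abort("malformed header in ", path)
  if (anyDuplicated(samples))
    rxa_abort("duplicate sample ID in header of ", path, ": ",
              paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- vapply(body, `[[`, "", 1L)
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples),
                 dimnames = list(ids, samples))
  for (i in seq_along(body)) {
    row <- body[[i]][-1]
    if (length(row) != length(samples))
      rxa_abort("row ", i + 1L, " of ", path, " has ", length(row),
                " values, expected ", length(samples))
    num <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(num) & !(row %in% c("", "NA", "na", "NaN")))
    if (length(bad))
      rxa_abort("non-numeric value '", row[bad[1]], "' at row ", i + 1L,
                " (", ids[i], "), column ", bad[1] + 1L, " (",
                samples[bad[1]], ") of ", path)
    vals[i, ] <- num
  }
  if (!is.null(probe_map)) vals <- collapse_probes(vals, probe_map)
  if (anyDuplicated(rownames(vals)))
    rxa_abort("duplicate gene IDs in ", path, ": ",
              paste(unique(rownames(vals)[duplicated(rownames(vals))]),
                    collapse = ", "),
              " (supply a probe_map to collapse)")
  expression_cohort(vals, cohort_id = cohort_id %||%
                      sub("\\.[^.]*$", "", basename(path)))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]; round-trips values at full precision.
#'
#' @param x An `ExpressionCohort` or a numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name for the leading identifier column.
#' @export
write_expression <- function(x, path, id_col = "gene") {
  m <- if (inherits(x, "ExpressionCohort")) x$values else x
  df <- data.frame(id = rownames(m), format(m, digits = 17, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `time_years`, `event`, followed by any
#' number of categorical/ordinal covariate columns. Missing covariates are
#' permitted; missing time/event marks a sample without outcome.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with validated outcome columns.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) rxa_abort("file not found: ", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  need <- c("sample_id", "time_years", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    rxa_abort("clinical table ", path, " lacks column(s): ",
              paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    rxa_abort("duplicate sample_id in ", path, ": ",
              paste(unique(df$sample_id[duplicated(df$sample_id)]),
                    collapse = ", "))
  has <- !is.na(df$time_years) | !is.na(df$event)
  if (any(has & (is.na(df$time_years) | is.na(df$event))))
    rxa_abort("samples with an outcome need both time_years and event in ", path)
  if (any(df$time_years < 0, na.rm = TRUE))
    rxa_abort("negative time_years in ", path)
  if (!all(df$event[!is.na(df$event)] %in% c(0, 1)))
    rxa_abort("event must be 0/1 in ", path)
  df
}

#' Attach clinical outcome and covariates to a cohort
#'
#' @param cohort An `ExpressionCohort`.
#' @param clinical A data.frame from [read_clinical()].
#' @return The cohort with `time`, `event` and `covariates` filled in;
#'   samples absent from the clinical table keep an `NA` outcome.
#' @export
attach_clinical <- function(cohort, clinical) {
  idx <- match(cohort$samples, clinical$sample_id)
  time <- clinical$time_years[idx]
  event <- clinical$event[idx]
  cov_cols <- setdiff(names(clinical), c("sample_id", "time_years", "event"))
  covs <- if (length(cov_cols)) clinical[idx, cov_cols, drop = FALSE] else NULL
  expression_cohort(cohort$values, cohort_id = cohort$cohort_id,
                    time = time, event = event, covariates = covs)
}

#' Read a gene list (one symbol per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of unique symbols in file order.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) rxa_abort("file not found: ", path)
  g <- trimws(readLines(path))
  g <- g[nzchar(g)]
  if (!length(g)) rxa_abort("empty gene list: ", path)
  if (anyDuplicated(g)) {
    warning("dropping duplicated symbols in ", path)
    g <- unique(g)
  }
  g
}

#' Collapse probe rows to gene rows by highest across-sample variance
#'
#' For every gene with multiple probes, the probe row with the largest
#' across-sample variance (sample variance, n-1 denominator, missing values
#' excluded) represents the gene; no averaging is performed. Variance ties
#' are broken by lexicographic probe ID so the choice is deterministic.
#'
#' @param values Numeric probe-by-sample matrix with probe rownames.
#' @param map A [probe_map()] covering every probe in `values`.
#' @return Gene-by-sample matrix (genes in order of first appearance of each
#'   gene among the input probes), with the chosen probe IDs in attribute
#'   `"probe_selected"`.
#' @export
collapse_probes <- function(values, map) {
  probes <- rownames(values)
  if (is.null(probes)) rxa_abort("`values` must have probe rownames")
  hit <- match(probes, map$probe_id)
  if (anyNA(hit))
    rxa_abort("unmapped probe(s): ",
              paste(probes[is.na(hit)][seq_len(min(5, sum(is.na(hit))))],
                    collapse = ", "))
  gene <- map$gene[hit]
  v <- apply(values, 1, var, na.rm = TRUE)
  v[is.na(v)] <- -Inf  # all-missing or single-value rows never win on variance
  ord <- order(match(gene, unique(gene)), -v, probes)
  keep <- ord[!duplicated(gene[ord])]
  keep <- keep[order(match(gene[keep], unique(gene)))]
  out <- values[keep, , drop = FALSE]
  rownames(out) <- gene[keep]
  attr(out, "probe_selected") <- structure(probes[keep], names = gene[keep])
  out
}

#' Write a per-sample prognostic index table
#'
#' TSV with columns `sample_id`, `index`, `group` (the export format used
#' for validation-cohort index tables).
#'
#' @param index A `gsp_index` from [compute_index()].
#' @param path Output path.
#' @export
write_index <- function(index, path) {
  write.table(index, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
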