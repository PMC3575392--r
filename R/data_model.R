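#' Expression cohort container
#'
#' Bundles a gene-by-sample matrix of log-scale expression values with an
#' optional right-censored survival outcome and per-sample categorical
#' covariates. All downstream screening operates on this container.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty rownames (gene symbols) and colnames (sample IDs).
#'   Values are log-scale expression in whatever units the platform provides;
#'   the index statistic is invariant to per-sample additive shifts so units
#'   need not agree across cohorts. `NA` entries are permitted.
#' @param cohort_id Single string labelling the cohort.
#' @param time Optional numeric vector of follow-up times in years, one per
#'   sample (`NA` = no outcome recorded). Must be `>= 0` where present.
#' @param event Optional event indicator, 0 (censored) / 1 (event), aligned
#'   with `time`; `time` and `event` must be missing together.
#' @param covariates Optional data.frame of per-sample clinical covariates
#'   (one row per sample, in column order of `values`).
#'
#' @return An object of class `ExpressionCohort`: a list with elements
#'   `cohort_id`, `genes`, `samples`, `values`, `time`, `event`,
#'   `covariates`.
#' @export
expression_cohort <- function(values, cohort_id = "cohort", time = NULL,
                              event = NULL, covariates = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    rxa_abort("`values` must be a numeric matrix (genes x samples)")
  genes <- rownames(values)
  samples <- colnames(values)
  if (is.null(genes) || is.null(samples))
    rxa_abort("`values` must carry gene rownames and sample colnames")
  if (anyDuplicated(genes))
    rxa_abort("duplicate gene symbols: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (anyDuplicated(samples))
    rxa_abort("duplicate sample IDs: ",
              paste(unique(samples[duplicated(samples)]), collapse = ", "))
  n <- ncol(values)
  if (is.null(time) != is.null(event))
    rxa_abort("`time` and `event` must be supplied together")
  if (!is.null(time)) {
    if (length(time) != n || length(event) != n)
      rxa_abort("`time`/`event` length must equal the number of samples")
    has <- !is.na(time) | !is.na(event)
    if (any(has & (is.na(time) | is.na(event))))
      rxa_abort("samples with an outcome need both time and event")
    if (any(time[has] < 0)) rxa_abort("follow-up time must be >= 0")
    if (!all(event[has] %in% c(0, 1))) rxa_abort("event must be 0 or 1")
  } else {
    time <- rep(NA_real_, n)
    event <- rep(NA_integer_, n)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n)
      rxa_abort("`covariates` must have one row per sample")
    rownames(covariates) <- samples
  }
  structure(
    list(cohort_id = cohort_id, genes = genes, samples = samples,
         values = values, time = as.numeric(time), event = as.integer(event),
         covariates = covariates),
    class = "ExpressionCohort"
  )
}

#' @export
print.ExpressionCohort <- function(x, ...) {
  n_out <- sum(!is.na(x$time))
  cat(sprintf(
    "ExpressionCohort '%s': %d genes x %d samples (%d with outcome, %d events)\n",
    x$cohort_id, length(x$genes), length(x$samples), n_out,
    sum(x$event == 1, na.rm = TRUE)))
  invisible(x)
}

#' Candidate gene sets for the screen
#'
#' The two biologically pre-defined marker lists feeding the gene-set-pair
#' enumeration: `poor` holds candidates whose high relative expression is
#' hypothesized to confer poor prognosis, `good` the converse.
#'
#' @param poor Character vector of poor-prognosis candidates (>= 2, unique).
#' @param good Character vector of good-prognosis candidates (>= 2, unique).
#' @return Object of class `CandidateSets` with elements `poor` and `good`.
#' @export
candidate_sets <- function(poor, good) {
  poor <- as.character(poor); good <- as.character(good)
  if (anyDuplicated(poor) || anyDuplicated(good))
    rxa_abort("candidate lists must not contain duplicates")
  if (length(poor) < 2 || length(good) < 2)
    rxa_abort("each candidate set needs at least 2 genes")
  overlap <- intersect(poor, good)
  if (length(overlap))
    rxa_abort("candidate sets must be disjoint; shared: ",
              paste(overlap, collapse = ", "))
  structure(list(poor = poor, good = good), class = "CandidateSets")
}

#' @export
print.CandidateSets <- function(x, ...) {
  cat(sprintf("CandidateSets: %d poor (%s), %d good (%s)\n",
              length(x$poor), paste(x$poor, collapse = ","),
              length(x$good), paste(x$good, collapse = ",")))
  invisible(x)
}

#' Probe-to-gene map
#'
#' @param probe_id Character vector of probe(set) IDs (unique).
#' @param gene Character vector of gene symbols, parallel to `probe_id`.
#' @return A data.frame of class `ProbeMap` with columns `probe_id`, `gene`.
#' @export
probe_map <- function(probe_id, gene) {
  probe_id <- as.character(probe_id); gene <- as.character(gene)
  if (length(probe_id) != length(gene))
    rxa_abort("`probe_id` and `gene` must have equal length")
  if (anyDuplicated(probe_id))
    rxa_abort("each probe must map to exactly one gene; duplicated: ",
              paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  structure(data.frame(probe_id = probe_id, gene = gene,
                       stringsAsFactors = FALSE),
            class = c("ProbeMap", "data.frame"))
}
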