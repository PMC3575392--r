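#' Liptak-Stouffer weighted p-value combination
#'
#' Combines one-sided per-cohort p-values as a weighted sum of inverse-normal
#' transforms,
#' \deqn{Z = \frac{\sum_i W_i \Phi^{-1}(1 - p_i)}{\sqrt{\sum_i W_i^2}},
#'   \qquad p_{meta} = 1 - \Phi(Z),}
#' with weights proportional to cohort sample sizes. Inputs are clamped to
#' `[1e-15, 1 - 1e-15]` before the quantile transform for numeric safety.
#'
#' @param p_values One-sided p-values, one per cohort.
#' @param weights Positive weights (cohort sample sizes); defaults to equal.
#' @return List with `z_combined` and `p_meta`.
#' @examples
#' liptak_stouffer(c(0.05, 0.05), c(1, 1))  # p_meta ~ 0.00999
#' @export
liptak_stouffer <- function(p_values, weights = rep(1, length(p_values))) {
  if (length(p_values) < 1 || length(p_values) != length(weights))
    rxa_abort("`p_values` and `weights` must have equal length >= 1")
  if (any(!is.finite(weights)) || any(weights <= 0))
    rxa_abort("all weights must be positive")
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    rxa_abort("p-values must lie in [0, 1]")
  p <- pmin(pmax(p_values, 1e-15), 1 - 1e-15)
  z <- sum(weights * qnorm(1 - p)) / sqrt(sum(weights^2))
  list(z_combined = z, p_meta = pnorm(z, lower.tail = FALSE))
}

#' Bonferroni adjustment
#'
#' @param p P-value(s).
#' @param n_tests Size of the test family (here: the number of enumerated
#'   gene-set pairs).
#' @return `min(1, p * n_tests)`, vectorized.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  if (n_tests < 1) rxa_abort("`n_tests` must be >= 1")
  pmin(1, p * n_tests)
}

#' Meta-analyze per-cohort screen records
#'
#' Stacks the per-cohort records of [screen_cohort()] and, per gene-set
#' pair, combines the one-sided Cox p-values across cohorts with
#' [liptak_stouffer()] (weights = evaluable samples per cohort), applies
#' Bonferroni control over the enumerated family, and evaluates the three
#' selection criteria: (i) Bonferroni-adjusted meta p < `alpha_family`;
#' (ii) balanced grouping in every cohort; (iii) HR > 1 with cohort-level
#' log-rank p < alpha in every cohort (already flagged per record).
#' Degenerate or missing-p records fail criteria (ii)/(iii) and contribute
#' no evidence.
#'
#' @param records data.frame: row-bound output of [screen_cohort()] over all
#'   cohorts. Every pair must appear once per cohort.
#' @param n_tests Bonferroni family size; defaults to the number of distinct
#'   pairs in `records`.
#' @param alpha_family Familywise significance level.
#' @return data.frame with one row per pair, in first-appearance (canonical)
#'   order: `gsp_id`, `z_combined`, `p_meta`, `p_bonferroni`, `meta_sig`,
#'   `all_balanced`, `all_direction_ok`, `selected`.
#' @export
meta_analyze <- function(records, n_tests = NULL, alpha_family = 0.05) {
  ids <- unique(records$gsp_id)
  cohorts <- unique(records$cohort_id)
  n_tests <- n_tests %||% length(ids)
  tab <- table(records$gsp_id)
  bad <- names(tab)[tab != length(cohorts)]
  if (length(bad))
    rxa_abort("missing per-cohort record(s) for GSP: ",
              paste(head(bad, 3), collapse = ", "))
  out <- data.frame(gsp_id = ids, z_combined = NA_real_, p_meta = NA_real_,
                    p_bonferroni = NA_real_, meta_sig = FALSE,
                    all_balanced = FALSE, all_direction_ok = FALSE,
                    selected = FALSE, stringsAsFactors = FALSE)
  sp <- split(seq_len(nrow(records)), records$gsp_id)
  for (j in seq_along(ids)) {
    rows <- records[sp[[ids[j]]], , drop = FALSE]
    out$all_balanced[j] <- all(rows$balanced)
    out$all_direction_ok[j] <- all(rows$direction_ok)
    pv <- rows$p_cox_onesided
    w <- rows$n_poor_group + rows$n_good_group
    if (!anyNA(pv) && all(w > 0)) {
      ls <- liptak_stouffer(pv, w)
      out$z_combined[j] <- ls$z_combined
      out$p_meta[j] <- ls$p_meta
      out$p_bonferroni[j] <- bonferroni_adjust(ls$p_meta, n_tests)
      out$meta_sig[j] <- out$p_bonferroni[j] < alpha_family
    }
  }
  out$selected <- out$meta_sig & out$all_balanced & out$all_direction_ok
  out
}

#' Select and rank gene-set pairs
#'
#' Applies the conjunction of the three selection criteria (already encoded
#' in the flags of [meta_analyze()]) and ranks the survivors by ascending
#' meta p-value, ties broken by canonical enumeration order.
#'
#' @param meta data.frame from [meta_analyze()].
#' @return The selected rows, ranked, with a `rank` column prepended.
#' @export
select_gsps <- function(meta) {
  sel <- meta[meta$selected, , drop = FALSE]
  if (nrow(sel)) {
    sel <- sel[order(sel$p_meta, seq_len(nrow(sel))), , drop = FALSE]
    sel <- cbind(rank = seq_len(nrow(sel)), sel)
    rownames(sel) <- NULL
  } else {
    sel <- cbind(rank = integer(0), sel)
  }
  sel
}

#' Run the full multi-cohort screen
#'
#' Enumerates all gene-set pairs from the candidate sets, screens every
#' training cohort, meta-analyzes, and applies the selection criteria.
#'
#' @param cohorts List of `ExpressionCohort` with outcomes (the training
#'   cohorts).
#' @param cands A [candidate_sets()] object.
#' @param balance_min,alpha_cohort,alpha_family Selection thresholds.
#' @return List with `gsps` (enumeration), `screen` (stacked per-cohort
#'   records), `meta` (per-pair meta records), `selected` (ranked winners).
#' @export
gsp_screen <- function(cohorts, cands, balance_min = 0.2,
                       alpha_cohort = 0.05, alpha_family = 0.05) {
  gsps <- enumerate_gsps(cands)
  screen <- do.call(rbind, lapply(cohorts, screen_cohort, gsps = gsps,
                                  balance_min = balance_min,
                                  alpha_cohort = alpha_cohort))
  rownames(screen) <- NULL
  meta <- meta_analyze(screen, n_tests = length(gsps),
                       alpha_family = alpha_family)
  list(gsps = gsps, screen = screen, meta = meta,
       selected = select_gsps(meta))
}

#' Write screen + meta results as a wide TSV
#'
#' One row per gene-set pair with per-cohort HR / p / balance columns and
#' the meta columns appended (the format of a full screening results table).
#'
#' @param result List from [gsp_screen()].
#' @param path Output path.
#' @param header Optional character vector of `#`-prefixed provenance lines.
#' @export
write_screen_results <- function(result, path, header = NULL) {
  meta <- result$meta
  wide <- data.frame(gsp_id = meta$gsp_id,
                     m_plus = vapply(result$gsps, function(g)
                       paste(g$m_plus, collapse = ","), ""),
                     m_minus = vapply(result$gsps, function(g)
                       paste(g$m_minus, collapse = ","), ""),
                     stringsAsFactors = FALSE)
  for (cid in unique(result$screen$cohort_id)) {
    rows <- result$screen[result$screen$cohort_id == cid, , drop = FALSE]
    rows <- rows[match(meta$gsp_id, rows$gsp_id), , drop = FALSE]
    for (col in c("hazard_ratio", "p_logrank", "p_cox_onesided",
                  "n_poor_group", "n_good_group", "balanced"))
      wide[[paste0(col, ".", cid)]] <- rows[[col]]
  }
  wide <- cbind(wide, meta[, c("z_combined", "p_meta", "p_bonferroni",
                               "selected")])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(wide, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
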