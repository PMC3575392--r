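#' Freeman-Halton exact test for an r x 2 contingency table
#'
#' Exact conditional test of independence between an r-level clinical
#' category and the two-level prognostic grouping, generalizing Fisher's
#' 2 x 2 test: with all margins fixed, the p-value is the total
#' (multivariate hypergeometric) probability of every table no more probable
#' than the observed one. Implemented by direct enumeration over all tables
#' with the observed margins, which is exact and fast at clinical-cohort
#' scale (total count up to 10^4, a few category levels).
#'
#' @param counts Non-negative integer matrix with r >= 2 rows and exactly
#'   2 columns; all row and column margins must be positive.
#' @return The exact two-sided p-value.
#' @examples
#' fisher_exact_rx2(rbind(c(64, 11), c(72, 29), c(73, 45)))  # ~0.0017
#' @export
fisher_exact_rx2 <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2 || nrow(counts) < 2)
    rxa_abort("`counts` must be an r x 2 matrix with r >= 2")
  if (any(counts < 0) || any(counts != round(counts)))
    rxa_abort("`counts` must hold non-negative integers")
  R <- rowSums(counts); C <- colSums(counts); N <- sum(counts)
  if (any(R == 0) || any(C == 0)) rxa_abort("all margins must be positive")
  if (N > 1e4) rxa_abort("total count exceeds the exact enumeration bound (1e4)")
  r <- nrow(counts); C1 <- C[1]
  # enumerate first-column entries of rows 1..r-1; the last row is implied
  grid <- expand.grid(lapply(R[-r], function(Ri) 0:Ri))
  if (nrow(grid) > 5e7) rxa_abort("table too large for direct enumeration")
  xr <- C1 - rowSums(grid)
  ok <- xr >= 0 & xr <= R[r]
  grid <- grid[ok, , drop = FALSE]; xr <- xr[ok]
  logp <- lchoose(R[r], xr) - lchoose(N, C1)
  for (i in seq_len(r - 1)) logp <- logp + lchoose(R[i], grid[[i]])
  logp_obs <- sum(lchoose(R, counts[, 1])) - lchoose(N, C1)
  # relative tolerance as in standard exact-test practice
  sum(exp(logp[logp <= logp_obs + 1e-7]))
}

#' Spearman rank correlation of expression against a clinical ordinal
#'
#' Rank correlation with mid-ranks for ties and the t-distribution
#' approximation for the p-value:
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n-2 degrees of freedom.
#' Used to relate one gene's expression to ordered clinical factors such as
#' tumor grade.
#'
#' @param values Numeric per-sample values (e.g. one gene's expression).
#' @param ordinal Ordered categories (factor/ordered/numeric); internally
#'   converted to integer level codes.
#' @return List with `rho`, `p`, `n`, `degenerate` (constant input).
#' @export
spearman_assoc <- function(values, ordinal) {
  if (is.character(ordinal)) ordinal <- factor(ordinal)
  o <- as.numeric(ordinal)
  keep <- !is.na(values) & !is.na(o)
  x <- values[keep]; y <- o[keep]
  n <- length(x)
  if (n < 3) rxa_abort("need at least 3 complete pairs")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) return(list(rho = rho, p = 0, n = n, degenerate = FALSE))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), df = n - 2), n = n, degenerate = FALSE)
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test comparing a continuous measurement
#' between two groups.
#'
#' @param values Numeric vector.
#' @param labels Two-level grouping vector.
#' @return List with `t` (second level minus first), `p`, `df`, `means`.
#' @export
two_group_t <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  f <- droplevels(as.factor(labels[keep]))
  if (nlevels(f) != 2) rxa_abort("`labels` must have exactly two levels")
  if (any(table(f) < 2)) rxa_abort("each group needs at least 2 values")
  ht <- stats::t.test(values[f == levels(f)[2]], values[f == levels(f)[1]],
                      var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       means = structure(rev(unname(ht$estimate)), names = levels(f)))
}

#' Clinical-covariate association table for a prognostic grouping
#'
#' For each covariate column, cross-tabulates its categories against the
#' good/poor grouping and computes the Freeman-Halton exact p — the layout
#' of a clinical-characteristics association table.
#'
#' @param covariates data.frame of categorical covariates (one row per
#'   sample).
#' @param groups Two-level grouping aligned with `covariates` rows.
#' @return List of per-covariate entries, each with `table` (r x 2 counts,
#'   columns good/poor) and `p`; plus a `summary` data.frame
#'   (covariate, n_levels, n_used, p).
#' @export
assoc_table <- function(covariates, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    rxa_abort("`groups` must have exactly two levels")
  out <- list()
  summ <- data.frame(covariate = character(), n_levels = integer(),
                     n_used = integer(), p = numeric(),
                     stringsAsFactors = FALSE)
  for (cv in names(covariates)) {
    keep <- !is.na(covariates[[cv]]) & !is.na(groups)
    tab <- table(covariates[[cv]][keep], droplevels(groups[keep]))
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    p <- if (nrow(tab) >= 2 && all(colSums(tab) > 0))
      fisher_exact_rx2(unclass(tab)) else NA_real_
    out[[cv]] <- list(table = tab, p = p)
    summ <- rbind(summ, data.frame(covariate = cv, n_levels = nrow(tab),
                                   n_used = sum(keep), p = p,
                                   stringsAsFactors = FALSE))
  }
  out$summary <- summ
  out
}
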