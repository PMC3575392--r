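#' Number of gene-set pairs
#'
#' Closed-form count of pairs (m_plus, m_minus) with m_plus a subset of the
#' poor candidates, m_minus a subset of the good candidates, and at least two
#' genes on each side:
#' \deqn{N = (2^{|Sp|} - |Sp| - 1)(2^{|Sg|} - |Sg| - 1)}
#'
#' @param n_poor Number of poor-prognosis candidates (>= 2).
#' @param n_good Number of good-prognosis candidates (>= 2).
#' @return Integer-valued count (as numeric to avoid overflow).
#' @examples
#' count_gsps(8, 4)  # 2717
#' @export
count_gsps <- function(n_poor, n_good) {
  if (length(n_poor) != 1 || length(n_good) != 1 ||
      n_poor < 2 || n_good < 2 || n_poor != round(n_poor) ||
      n_good != round(n_good))
    rxa_abort("`n_poor` and `n_good` must be integers >= 2")
  (2^n_poor - n_poor - 1) * (2^n_good - n_good - 1)
}

# All subsets of size >= 2 of a gene vector, in canonical order:
# ascending size, lexicographic member order within size (members sorted).
subsets_ge2 <- function(genes) {
  genes <- sort(genes)
  out <- list()
  for (k in 2:length(genes)) {
    cmb <- combn(genes, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Canonical label for a gene-set pair
#'
#' @param gsp A `GeneSetPair`.
#' @return Single string, e.g. `"A+B_vs_C+D"`.
#' @export
gsp_id <- function(gsp) {
  paste0(paste(gsp$m_plus, collapse = "+"), "_vs_",
         paste(gsp$m_minus, collapse = "+"))
}

#' Construct a gene-set pair
#'
#' @param m_plus Poor-prognosis member genes (>= 2).
#' @param m_minus Good-prognosis member genes (>= 2), disjoint from `m_plus`.
#' @return Object of class `GeneSetPair`.
#' @export
gene_set_pair <- function(m_plus, m_minus) {
  m_plus <- as.character(m_plus); m_minus <- as.character(m_minus)
  if (length(m_plus) < 2 || length(m_minus) < 2)
    rxa_abort("each side of a gene-set pair needs >= 2 genes")
  if (length(intersect(m_plus, m_minus)))
    rxa_abort("m_plus and m_minus must be disjoint")
  structure(list(m_plus = sort(m_plus), m_minus = sort(m_minus)),
            class = "GeneSetPair")
}

#' @export
print.GeneSetPair <- function(x, ...) {
  cat("GeneSetPair:", gsp_id(x), "\n")
  invisible(x)
}

#' Enumerate all qualifying gene-set pairs
#'
#' Emits every pair of subsets (>= 2 genes per side) of the candidate sets
#' exactly once, in a deterministic canonical order: subsets ordered by
#' (size, lexicographic member order), with the poor-side subset varying
#' slowest. The length always equals [count_gsps()].
#'
#' @param cands A [candidate_sets()] object.
#' @return List of `GeneSetPair` objects.
#' @export
enumerate_gsps <- function(cands) {
  if (!inherits(cands, "CandidateSets"))
    rxa_abort("`cands` must be a CandidateSets object")
  sp <- subsets_ge2(cands$poor)
  sg <- subsets_ge2(cands$good)
  out <- vector("list", length(sp) * length(sg))
  i <- 0L
  for (p in sp) for (g in sg) {
    i <- i + 1L
    out[[i]] <- structure(list(m_plus = p, m_minus = g),
                          class = "GeneSetPair")
  }
  out
}

# Column medians of a (small-k) x n matrix, vectorized: one order() call
# sorts within columns; NA-containing columns fall back to a slower path.
col_medians <- function(X) {
  k <- nrow(X); n <- ncol(X)
  if (k == 0L || n == 0L) return(rep(NA_real_, n))
  if (anyNA(X)) {
    return(apply(X, 2, function(col) {
      col <- col[!is.na(col)]
      if (length(col) == 0) NA_real_ else median(col)
    }))
  }
  Y <- matrix(X[order(col(X), X)], nrow = k)
  if (k %% 2L == 1L) Y[(k + 1L) %/% 2L, ] else (Y[k %/% 2L, ] + Y[k %/% 2L + 1L, ]) / 2
}

# Median per sample over a gene subset, requiring >= min_genes non-missing
# values; returns NA where the requirement fails.
subset_medians <- function(values, genes, min_genes = 2L) {
  X <- values[genes, , drop = FALSE]
  m <- col_medians(X)
  nn <- colSums(!is.na(X))
  m[nn < min_genes] <- NA_real_
  m
}

#' Individualized prognostic index for one gene-set pair
#'
#' For each sample s the index is
#' \deqn{I_s = \mathrm{median}_{g \in M^+} e(g, s) -
#'   \mathrm{median}_{g \in M^-} e(g, s)}
#' and a strictly positive index assigns the sample to the poor-prognosis
#' group (ties at exactly zero go to the good-prognosis group). The even-set
#' median is the mean of the two central values. Because the same constant
#' added to every gene of a sample cancels in the difference, the index is
#' invariant to per-sample normalization shifts, which is what lets cohorts
#' from different platforms be screened without joint renormalization.
#'
#' Gene-set members absent from the cohort trigger a warning and are dropped;
#' if fewer than two members remain on either side the whole pair is
#' unevaluable. Per sample, at least two non-missing values per side are
#' required; failing samples get an `NA` index and group.
#'
#' @param cohort An `ExpressionCohort`.
#' @param gsp A `GeneSetPair`.
#' @return A data.frame of class `gsp_index` with columns `sample_id`,
#'   `index`, `group` (factor good/poor) and attributes `gsp` and
#'   `n_unevaluable`.
#' @export
compute_index <- function(cohort, gsp) {
  mp <- intersect(gsp$m_plus, cohort$genes)
  mm <- intersect(gsp$m_minus, cohort$genes)
  absent <- setdiff(c(gsp$m_plus, gsp$m_minus), cohort$genes)
  if (length(absent))
    warning("gene-set member(s) absent from cohort '", cohort$cohort_id,
            "': ", paste(absent, collapse = ", "))
  n <- length(cohort$samples)
  if (length(mp) < 2 || length(mm) < 2) {
    idx <- rep(NA_real_, n)
  } else {
    idx <- subset_medians(cohort$values, mp) -
      subset_medians(cohort$values, mm)
  }
  group <- factor(ifelse(idx > 0, "poor", "good"), levels = c("good", "poor"))
  out <- data.frame(sample_id = cohort$samples, index = idx, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("gsp_index", "data.frame")
  attr(out, "gsp") <- gsp
  attr(out, "n_unevaluable") <- sum(is.na(idx))
  out
}
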