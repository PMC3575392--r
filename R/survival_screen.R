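#' Dichotomize samples by the sign of the prognostic index
#'
#' Samples with a strictly positive index form the poor-prognosis group, the
#' rest the good-prognosis group. The balance flag records whether each group
#' holds at least `balance_min` (default 20%, inclusive) of the evaluable
#' samples — the clinical-feasibility criterion of the screen.
#'
#' @param index A `gsp_index` from [compute_index()], or a numeric vector.
#' @param balance_min Minimum group fraction for the balance flag.
#' @return List with `groups` (factor good/poor, `NA` where unevaluable),
#'   `n_poor`, `n_good`, `n_unevaluable`, `balanced`.
#' @export
dichotomize <- function(index, balance_min = 0.2) {
  idx <- if (is.data.frame(index)) index$index else as.numeric(index)
  if (length(idx) == 0 || all(is.na(idx)))
    rxa_abort("no evaluable samples to dichotomize")
  groups <- factor(ifelse(idx > 0, "poor", "good"), levels = c("good", "poor"))
  n_poor <- sum(groups == "poor", na.rm = TRUE)
  n_good <- sum(groups == "good", na.rm = TRUE)
  tot <- n_poor + n_good
  list(groups = groups, n_poor = n_poor, n_good = n_good,
       n_unevaluable = sum(is.na(idx)),
       balanced = tot > 0 && min(n_poor, n_good) / tot >= balance_min)
}

# ---- fast two-group survival kernels -------------------------------------
#
# The screen evaluates thousands of group assignments against a fixed
# outcome, so the per-call work is split: surv_context() does the sorting
# and per-event-time bookkeeping once, and the per-group kernels only
# tabulate group membership. Both kernels are property-tested against
# survival::survdiff / survival::coxph.

surv_context <- function(time, event) {
  stopifnot(!anyNA(time), !anyNA(event))
  tt <- sort(unique(time))
  idx <- match(time, tt)
  K <- length(tt)
  cnt <- tabulate(idx, K)
  d <- tabulate(idx[event == 1], K)
  atr <- rev(cumsum(rev(cnt)))
  ev <- which(d > 0)
  de <- d[ev]
  # Efron tie handling: expand each event time with d deaths into d terms
  # with fractional weights l/d, l = 0..d-1 (precomputable once).
  list(n = length(time), K = K, idx = idx, event = event == 1,
       ev = ev, de = de, ne = atr[ev],
       exp_idx = rep(seq_along(ev), de),
       fr = unlist(lapply(de, function(dd) (seq_len(dd) - 1) / dd)),
       d1tot_all = sum(de))
}

# g: logical vector (TRUE = poor group) aligned with the context samples.
logrank_kernel <- function(ctx, g) {
  if (length(ctx$ev) == 0L)
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  n1 <- rev(cumsum(rev(tabulate(ctx$idx[g], ctx$K))))[ctx$ev]
  d1 <- tabulate(ctx$idx[g & ctx$event], ctx$K)[ctx$ev]
  n <- ctx$ne; d <- ctx$de
  E <- sum(d * n1 / n)
  V <- sum(d * (n1 / n) * (1 - n1 / n) * ((n - d) / pmax(n - 1, 1)))
  if (!is.finite(V) || V <= 1e-12)
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  stat <- (sum(d1) - E)^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       degenerate = FALSE)
}

# Single binary covariate Cox fit (Efron ties), Newton-Raphson on the
# partial likelihood. Returns the poor-vs-good hazard ratio, Wald p, and
# the one-sided p in the HR > 1 direction used by the meta-analysis.
cox_binary_kernel <- function(ctx, g) {
  out <- list(hazard_ratio = NA_real_, beta = NA_real_, se = NA_real_,
              p_wald = NA_real_, p_onesided = NA_real_, separation = FALSE,
              degenerate = FALSE)
  if (length(ctx$ev) == 0L) { out$degenerate <- TRUE; return(out) }
  n1 <- rev(cumsum(rev(tabulate(ctx$idx[g], ctx$K))))[ctx$ev]
  d1 <- tabulate(ctx$idx[g & ctx$event], ctx$K)[ctx$ev]
  ei <- ctx$exp_idx; fr <- ctx$fr
  M1 <- n1[ei]; M0 <- (ctx$ne - n1)[ei]
  D1 <- d1[ei]; D0 <- (ctx$de - d1)[ei]
  d1tot <- sum(d1)
  b <- 0; info <- NA_real_
  for (iter in 1:30) {
    eb <- exp(b)
    A <- (M0 + M1 * eb) - fr * (D0 + D1 * eb)
    Ap <- eb * (M1 - fr * D1)
    r <- Ap / A
    U <- d1tot - sum(r)
    info <- sum(r * (1 - r))
    if (!is.finite(info) || info <= 1e-10) { out$degenerate <- TRUE; return(out) }
    step <- U / info
    step <- max(min(step, 5), -5)
    b <- b + step
    if (abs(b) > 18) { out$separation <- TRUE; break }
    if (abs(step) < 1e-9) break
  }
  if (out$separation) {
    # monotone likelihood: report the boundary HR and fall back to the
    # score test at beta = 0 for the p-value
    r0 <- (M1 - fr * D1) / ((M0 + M1) - fr * (D0 + D1))
    U0 <- d1tot - sum(r0)
    I0 <- sum(r0 * (1 - r0))
    z <- if (I0 > 0) U0 / sqrt(I0) else 0
    out$hazard_ratio <- if (b > 0) Inf else 0
    out$beta <- b
    out$p_wald <- 2 * pnorm(-abs(z))
    out$p_onesided <- pnorm(z, lower.tail = FALSE)
    return(out)
  }
  se <- 1 / sqrt(info)
  z <- b / se
  out$hazard_ratio <- exp(b)
  out$beta <- b; out$se <- se
  out$p_wald <- 2 * pnorm(-abs(z))
  out$p_onesided <- pnorm(z, lower.tail = FALSE)
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank chi-square test of equality of survival
#' between two groups, with the hypergeometric variance at each distinct
#' event time. Invariant to monotone rescaling of the time axis.
#'
#' @param time Follow-up times.
#' @param event Event indicator (0/1).
#' @param group Two-level factor/logical/vector; the second level (or
#'   `TRUE`) is the poor-prognosis group.
#' @return List with `statistic` (1-df chi-square), `p` (two-sided), and
#'   `degenerate` (`TRUE` when no events occur and p is pinned at 1).
#' @export
logrank_test <- function(time, event, group) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  g <- to_poor_logical(group)
  if (length(unique(g)) < 2)
    rxa_abort("logrank_test needs two non-empty groups")
  logrank_kernel(surv_context(time, event), g)
}

to_poor_logical <- function(group) {
  if (is.logical(group)) return(group)
  f <- as.factor(group)
  if (nlevels(f) != 2) rxa_abort("`group` must have exactly two levels")
  f == levels(f)[2]
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ x` with Efron tie handling via
#' [survival::coxph()]. For a two-level `x` the reported hazard ratio is
#' second level vs first (poor vs good under the package's factor
#' convention); for numeric `x` it is per unit increase. The one-sided
#' p-value in the HR > 1 direction (`p_onesided = 1 - Phi(z)`) is what the
#' Liptak-Stouffer meta-analysis consumes. Monotone likelihood (complete
#' separation) is flagged and the p-value falls back to the score test.
#'
#' @param x Covariate: two-level factor/logical, or numeric (e.g. the
#'   continuous index, or one gene's expression).
#' @param time,event Right-censored outcome.
#' @return List with `hazard_ratio`, `beta`, `se`, `ci` (95% Wald),
#'   `p_wald`, `p_onesided`, `separation`.
#' @export
cox_univariate <- function(x, time, event) {
  keep <- !is.na(time) & !is.na(event) & !is.na(x)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (sum(event == 1) < 2) rxa_abort("need at least 2 events for a Cox fit")
  if (!is.numeric(x)) x <- as.numeric(to_poor_logical(x))
  sep <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(fit$coefficients[1])
  se <- sqrt(unname(fit$var[1, 1]))
  if (sep || abs(beta) > 15) {
    sc <- summary(fit)$sctest
    z0 <- sign(beta) * sqrt(max(sc[["test"]], 0))
    return(list(hazard_ratio = if (beta > 0) Inf else 0, beta = beta,
                se = se, ci = c(NA_real_, NA_real_),
                p_wald = unname(sc[["pvalue"]]),
                p_onesided = pnorm(z0, lower.tail = FALSE),
                separation = TRUE))
  }
  z <- beta / se
  list(hazard_ratio = exp(beta), beta = beta, se = se,
       ci = exp(beta + c(-1, 1) * qnorm(0.975) * se),
       p_wald = 2 * pnorm(-abs(z)),
       p_onesided = pnorm(z, lower.tail = FALSE),
       separation = FALSE)
}

#' Multivariate Cox proportional-hazards fit
#'
#' Joint fit of several covariates on complete cases, with an explicit
#' rank-deficiency check that names the collinear columns. The overall model
#' p-value is the likelihood-ratio test against the null model.
#'
#' @param covariates data.frame of covariates (factors and/or numerics).
#' @param time,event Right-censored outcome.
#' @return List with `terms` (data.frame: term, hazard_ratio, ci_lower,
#'   ci_upper, p_wald), `model_p` (LRT), `n_used`, and the underlying `fit`.
#' @export
cox_multivariate <- function(covariates, time, event) {
  covariates <- as.data.frame(covariates)
  keep <- complete.cases(covariates) & !is.na(time) & !is.na(event)
  dat <- covariates[keep, , drop = FALSE]
  time <- time[keep]; event <- event[keep]
  if (sum(event == 1) < 2) rxa_abort("need at least 2 events for a Cox fit")
  mm <- stats::model.matrix(~., data = dat)
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    aliased <- colnames(mm)[qd$pivot[(qd$rank + 1):ncol(mm)]]
    rxa_abort("rank-deficient design; collinear term(s): ",
              paste(aliased, collapse = ", "))
  }
  dat$.time <- time; dat$.event <- event
  f <- stats::as.formula(paste(
    "Surv(.time, .event) ~",
    paste(sprintf("`%s`", setdiff(names(dat), c(".time", ".event"))),
          collapse = " + ")))
  fit <- coxph(f, data = dat, ties = "efron")
  s <- summary(fit)
  terms <- data.frame(
    term = rownames(s$coefficients),
    hazard_ratio = unname(s$coefficients[, "exp(coef)"]),
    ci_lower = unname(s$conf.int[, "lower .95"]),
    ci_upper = unname(s$conf.int[, "upper .95"]),
    p_wald = unname(s$coefficients[, "Pr(>|z|)"]),
    stringsAsFactors = FALSE)
  list(terms = terms, model_p = unname(s$logtest[["pvalue"]]),
       n_used = sum(keep), fit = fit)
}

#' Screen every gene-set pair against one cohort
#'
#' Computes the index for each pair, dichotomizes by sign, and evaluates the
#' two groups with a log-rank test and a binary-covariate Cox fit. Records
#' carry the balance flag (both groups >= `balance_min` of evaluable
#' samples) and the direction flag (HR > 1 and log-rank p < `alpha_cohort`,
#' the per-cohort selection criterion). Degenerate pairs (an empty group, or
#' no events) are flagged, never dropped, so downstream selection sees every
#' pair in enumeration order. Identical group assignments share one fit via
#' an internal cache, which is what makes screening thousands of pairs cheap.
#'
#' @param cohort An `ExpressionCohort` with outcome.
#' @param gsps List of `GeneSetPair` (e.g. from [enumerate_gsps()]).
#' @param balance_min Balance threshold (fraction, inclusive).
#' @param alpha_cohort Per-cohort significance level for the direction flag.
#' @return data.frame with one row per pair: `gsp_id`, `cohort_id`,
#'   `n_poor_group`, `n_good_group`, `n_unevaluable`, `hazard_ratio`,
#'   `p_logrank`, `p_cox_onesided`, `p_cox_wald`, `balanced`,
#'   `direction_ok`, `degenerate`.
#' @export
screen_cohort <- function(cohort, gsps, balance_min = 0.2,
                          alpha_cohort = 0.05) {
  if (!length(gsps)) rxa_abort("empty GSP list")
  has_out <- !is.na(cohort$time) & !is.na(cohort$event)
  if (!any(has_out))
    rxa_abort("cohort '", cohort$cohort_id, "' has no samples with outcome")
  n <- length(cohort$samples)

  pk <- vapply(gsps, function(g) paste(g$m_plus, collapse = "|"), "")
  gk <- vapply(gsps, function(g) paste(g$m_minus, collapse = "|"), "")
  upk <- unique(pk); ugk <- unique(gk)
  med_for <- function(keys) {
    out <- matrix(NA_real_, nrow = length(keys), ncol = n,
                  dimnames = list(keys, NULL))
    for (k in keys) {
      genes <- intersect(strsplit(k, "|", fixed = TRUE)[[1]], cohort$genes)
      if (length(genes) >= 2)
        out[k, ] <- subset_medians(cohort$values, genes)
    }
    out
  }
  P <- med_for(upk); G <- med_for(ugk)

  ctx_cache <- new.env(hash = TRUE, parent = emptyenv())
  stat_cache <- new.env(hash = TRUE, parent = emptyenv())
  nr <- length(gsps)
  res <- data.frame(
    gsp_id = vapply(gsps, gsp_id, ""), cohort_id = cohort$cohort_id,
    n_poor_group = NA_integer_, n_good_group = NA_integer_,
    n_unevaluable = NA_integer_, hazard_ratio = NA_real_,
    p_logrank = NA_real_, p_cox_onesided = NA_real_, p_cox_wald = NA_real_,
    balanced = FALSE, direction_ok = FALSE, degenerate = FALSE,
    stringsAsFactors = FALSE)

  pad <- (8 - length(has_out) %% 8) %% 8
  bitkey <- function(x) paste(packBits(c(x, rep(FALSE, pad)), type = "raw"),
                              collapse = "")
  for (i in seq_len(nr)) {
    idx <- P[pk[i], ] - G[gk[i], ]
    evaluable <- !is.na(idx) & has_out
    g <- idx > 0 & evaluable
    np <- sum(g); ng <- sum(evaluable) - np
    res$n_poor_group[i] <- np; res$n_good_group[i] <- ng
    res$n_unevaluable[i] <- sum(is.na(idx))
    tot <- np + ng
    res$balanced[i] <- tot > 0 && min(np, ng) / tot >= balance_min
    if (np == 0 || ng == 0) { res$degenerate[i] <- TRUE; next }
    key <- paste0(bitkey(evaluable), ":", bitkey(g))
    st <- stat_cache[[key]]
    if (is.null(st)) {
      ckey <- bitkey(evaluable)
      ctx <- ctx_cache[[ckey]]
      if (is.null(ctx)) {
        ctx <- surv_context(cohort$time[evaluable], cohort$event[evaluable])
        ctx_cache[[ckey]] <- ctx
      }
      gg <- g[evaluable]
      lr <- logrank_kernel(ctx, gg)
      cx <- cox_binary_kernel(ctx, gg)
      st <- list(lr = lr, cx = cx)
      stat_cache[[key]] <- st
    }
    res$p_logrank[i] <- st$lr$p
    res$hazard_ratio[i] <- st$cx$hazard_ratio
    res$p_cox_onesided[i] <- st$cx$p_onesided
    res$p_cox_wald[i] <- st$cx$p_wald
    res$degenerate[i] <- st$lr$degenerate || st$cx$degenerate
    res$direction_ok[i] <- isTRUE(!res$degenerate[i] &&
                                    st$cx$hazard_ratio > 1 &&
                                    st$lr$p < alpha_cohort)
  }
  res
}

#' Kaplan-Meier plot of the two prognostic groups
#'
#' Convenience plot (not part of any numeric contract): survival curves for
#' the good/poor index groups with the log-rank p in the legend.
#'
#' @param time,event Right-censored outcome.
#' @param group Two-level grouping (second level = poor).
#' @param main Plot title.
#' @param ... Passed to `plot.survfit`.
#' @export
plot_km <- function(time, event, group, main = "DMFS by GSP group", ...) {
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  group <- droplevels(as.factor(group[keep]))
  fit <- survfit(Surv(time[keep], event[keep]) ~ group)
  lr <- logrank_test(time[keep], event[keep], group)
  plot(fit, col = c("forestgreen", "firebrick"), lwd = 2,
       xlab = "Years", ylab = "Metastasis-free survival", main = main, ...)
  legend("bottomleft", bty = "n",
         legend = c(levels(group), sprintf("log-rank p = %.3g", lr$p)),
         col = c("forestgreen", "firebrick", NA), lwd = c(2, 2, NA))
  invisible(fit)
}
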