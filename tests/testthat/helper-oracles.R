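# Independent oracles and small fixture builders shared across test files.

# Brute-force subset-pair generator over bitmasks: independent of both the
# closed-form count and the combn-based enumeration in the package.
oracle_count_pairs <- function(n_poor, n_good) {
  popcount <- function(x) sum(bitwAnd(x, 2^(0:30)) > 0)
  np <- sum(vapply(seq_len(2^n_poor - 1), popcount, 0) >= 2)
  ng <- sum(vapply(seq_len(2^n_good - 1), popcount, 0) >= 2)
  np * ng
}

# Cohort with explicit values and outcome for hand-checkable cases.
make_cohort <- function(values, time = NULL, event = NULL, id = "test") {
  expression_cohort(values, cohort_id = id, time = time, event = event)
}

# Small matrix with named genes/samples.
gene_matrix <- function(genes, samples, values) {
  matrix(values, nrow = length(genes), ncol = length(samples),
         dimnames = list(genes, samples), byrow = TRUE)
}

# Random right-censored survival data with a binary group effect.
sim_surv <- function(n, hr = 1, p_group = 0.5, baseline = 0.1,
                     cens = 0.08) {
  g <- stats::rbinom(n, 1, p_group) == 1
  t_ev <- stats::rexp(n, baseline * ifelse(g, hr, 1))
  t_c <- stats::rexp(n, cens)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c), group = g)
}

# Random r x 2 contingency table with positive margins, total <= max_total.
random_rx2 <- function(max_total = 60) {
  repeat {
    r <- sample(2:4, 1)
    n <- sample((2 * r):max_total, 1)
    tab <- matrix(stats::rmultinom(1, n, runif(2 * r, 0.2, 1)), nrow = r)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}
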