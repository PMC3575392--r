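#' Configuration for the multi-cohort simulator
#'
#' Describes the world the generator emulates: several author-normalized
#' expression cohorts on different "platforms" (per-cohort location/scale
#' shifts), a latent poor-prognosis subpopulation in which the planted
#' poor-prognosis genes are up-shifted and the planted good-prognosis genes
#' down-shifted, and exponential survival whose hazard is driven by the sign
#' of the planted pair's true index (so the generator plants exactly the
#' model the screen assumes). Censoring is independent exponential,
#' calibrated to the target censored fraction.
#'
#' @param n_cohorts Number of training cohorts.
#' @param n_samples Samples per cohort (scalar or vector).
#' @param n_genes Total measured genes (candidates + background).
#' @param n_poor_candidates,n_good_candidates Candidate set sizes.
#' @param planted_sizes Sizes `c(|m_plus|, |m_minus|)` of the planted pair
#'   (taken as the first genes of each candidate list).
#' @param beta Log hazard ratio attached to `1[Is > 0]` (0 = null world).
#' @param baseline_hazard Events per year in the good-index group.
#' @param censoring_rate Target fraction of censored samples, in [0, 1).
#' @param delta Expression shift of planted genes between the latent
#'   subpopulations (log-scale units). The default (0.5, i.e. half the
#'   within-gene noise SD) encodes weak single-gene marginal effects: no
#'   individual marker separates the subpopulations on its own, only the
#'   paired-set index does — the regime the screening method is built for.
#' @param noise_sd Per-gene, per-sample Gaussian noise SD.
#' @param poor_fraction Prevalence of the latent poor subpopulation.
#' @param cohort_shift,cohort_scale Per-cohort platform location/scale
#'   (recycled to `n_cohorts`).
#' @param seed Integer seed.
#' @return Validated list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cohorts = 3, n_samples = 300, n_genes = 1000,
                              n_poor_candidates = 8, n_good_candidates = 4,
                              planted_sizes = c(5, 2), beta = log(2.5),
                              baseline_hazard = 0.05, censoring_rate = 0.6,
                              delta = 0.5, noise_sd = 1, poor_fraction = 0.5,
                              cohort_shift = NULL, cohort_scale = NULL,
                              seed = 1) {
  if (n_cohorts < 1 || any(n_samples < 10))
    rxa_abort("need >= 1 cohort with >= 10 samples")
  if (n_poor_candidates < 2 || n_good_candidates < 2)
    rxa_abort("candidate sets need >= 2 genes")
  if (length(planted_sizes) != 2 || any(planted_sizes < 2) ||
      planted_sizes[1] > n_poor_candidates ||
      planted_sizes[2] > n_good_candidates)
    rxa_abort("planted sizes must be >= 2 and fit inside the candidate sets")
  if (n_genes < n_poor_candidates + n_good_candidates)
    rxa_abort("`n_genes` must cover the candidate genes")
  if (baseline_hazard <= 0 || noise_sd <= 0)
    rxa_abort("rates and noise must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    rxa_abort("infeasible censoring target (need 0 <= rate < 1)")
  if (poor_fraction <= 0 || poor_fraction >= 1)
    rxa_abort("`poor_fraction` must be in (0, 1)")
  structure(list(
    n_cohorts = n_cohorts,
    n_samples = rep_len(n_samples, n_cohorts),
    n_genes = n_genes, n_poor_candidates = n_poor_candidates,
    n_good_candidates = n_good_candidates, planted_sizes = planted_sizes,
    beta = beta, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, delta = delta, noise_sd = noise_sd,
    poor_fraction = poor_fraction,
    cohort_shift = rep_len(cohort_shift %||% (1.5 * (seq_len(n_cohorts) - 1)),
                           n_cohorts),
    cohort_scale = rep_len(cohort_scale %||%
                             (1 + 0.1 * (seq_len(n_cohorts) - 1)), n_cohorts),
    seed = as.integer(seed)), class = "SimulationConfig")
}

# exponential censoring rate hitting the target censored fraction for a
# population with per-sample hazards h
censoring_rate_for <- function(h, target) {
  if (target == 0) return(0)
  f <- function(mu) mean(mu / (mu + h)) - target
  uniroot(f, lower = 1e-12, upper = 1e12, tol = 1e-12)$root
}

#' Simulate multi-cohort expression + survival data
#'
#' Draws each cohort per [simulation_config()]: gene baselines are shared
#' across cohorts, platform differences enter as per-cohort location/scale
#' transforms (to which the index is insensitive), the planted pair's true
#' index is computed from the realized expression, and survival is
#' exponential with hazard `baseline_hazard * exp(beta * 1[Is > 0])` under
#' independent exponential censoring. Fully seeded: the same config yields
#' bit-identical cohorts.
#'
#' @param config A `SimulationConfig`.
#' @return List of `ExpressionCohort`, with attributes `planted_gsp`
#'   (`GeneSetPair`), `candidates` ([candidate_sets()]), `latent` (list of
#'   per-cohort 0/1 latent subpopulation vectors), and `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  np <- config$n_poor_candidates; ng <- config$n_good_candidates
  poor <- sprintf("POOR%02d", seq_len(np))
  good <- sprintf("GOOD%02d", seq_len(ng))
  genes <- c(poor, good,
             sprintf("GENE%04d", seq_len(config$n_genes - np - ng)))
  planted <- gene_set_pair(poor[seq_len(config$planted_sizes[1])],
                           good[seq_len(config$planted_sizes[2])])
  # Shared platform-free baselines. Modest between-gene spread (sd 0.25):
  # the index thresholds at zero, so gene-baseline offsets much larger than
  # the within-gene noise would make the sign split degenerate rather than
  # reflect the latent biology the generator plants.
  mu <- rnorm(length(genes), mean = 7, sd = 0.25)
  cohorts <- vector("list", config$n_cohorts)
  latent <- vector("list", config$n_cohorts)
  for (c_i in seq_len(config$n_cohorts)) {
    n <- config$n_samples[c_i]
    z <- rbinom(n, 1, config$poor_fraction)
    vals <- matrix(rnorm(length(genes) * n, sd = config$noise_sd),
                   nrow = length(genes),
                   dimnames = list(genes, sprintf("C%d_S%03d", c_i,
                                                  seq_len(n)))) + mu
    # symmetric latent shift: poor markers sit delta/2 above their baseline
    # in the latent poor subpopulation and delta/2 below it otherwise (and
    # conversely for good markers), so the zero threshold of the index
    # separates the subpopulations rather than arbitrary baseline offsets
    vals[planted$m_plus, ] <- vals[planted$m_plus, ] +
      config$delta * rep(z - 0.5, each = length(planted$m_plus))
    vals[planted$m_minus, ] <- vals[planted$m_minus, ] -
      config$delta * rep(z - 0.5, each = length(planted$m_minus))
    idx <- subset_medians(vals, planted$m_plus) -
      subset_medians(vals, planted$m_minus)
    h <- config$baseline_hazard * exp(config$beta * (idx > 0))
    t_event <- rexp(n, rate = h)
    mu_c <- censoring_rate_for(h, config$censoring_rate)
    t_cens <- if (mu_c > 0) rexp(n, rate = mu_c) else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    vals <- config$cohort_shift[c_i] + config$cohort_scale[c_i] * vals
    cohorts[[c_i]] <- expression_cohort(
      vals, cohort_id = sprintf("cohort%d", c_i), time = time, event = event)
    latent[[c_i]] <- z
  }
  attr(cohorts, "planted_gsp") <- planted
  attr(cohorts, "candidates") <- candidate_sets(poor, good)
  attr(cohorts, "latent") <- latent
  attr(cohorts, "config") <- config
  cohorts
}

#' Simulate clinical tables with a grade covariate
#'
#' Adds a 3-level ordinal tumor grade to each simulated cohort, linked to
#' the latent poor subpopulation through a cumulative-logit shift of
#' `assoc_log_odds` (0 = independent), enabling association-table and
#' multivariate-Cox fixtures. The covariate is attached to the returned
#' cohorts and also emitted as clinical data.frames in the on-disk format
#' of [read_clinical()].
#'
#' @param config The `SimulationConfig` used for the cohorts.
#' @param cohorts Output of [simulate_cohorts()].
#' @param assoc_log_odds Log-odds shift of grade in the latent poor
#'   subpopulation.
#' @param seed Seed for the grade draw (default derived from the config).
#' @return List with `cohorts` (covariate attached) and `clinical` (list of
#'   data.frames: sample_id, time_years, event, grade).
#' @export
simulate_clinical <- function(config, cohorts, assoc_log_odds = 1.5,
                              seed = config$seed + 1L) {
  set.seed(seed)
  latent <- attr(cohorts, "latent")
  cuts <- qnorm(c(0.35, 0.70))  # baseline grade mix ~35/35/30
  out_cohorts <- vector("list", length(cohorts))
  clinical <- vector("list", length(cohorts))
  for (c_i in seq_along(cohorts)) {
    co <- cohorts[[c_i]]
    z <- latent[[c_i]]
    lp <- assoc_log_odds * z + rnorm(length(z))
    grade <- cut(lp, c(-Inf, cuts, Inf), labels = c("I", "II", "III"),
                 ordered_result = TRUE)
    covs <- data.frame(grade = grade)
    out_cohorts[[c_i]] <- expression_cohort(
      co$values, cohort_id = co$cohort_id, time = co$time, event = co$event,
      covariates = covs)
    clinical[[c_i]] <- data.frame(sample_id = co$samples,
                                  time_years = co$time, event = co$event,
                                  grade = as.character(grade),
                                  stringsAsFactors = FALSE)
  }
  for (a in c("planted_gsp", "candidates", "latent", "config"))
    attr(out_cohorts, a) <- attr(cohorts, a)
  list(cohorts = out_cohorts, clinical = clinical)
}
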