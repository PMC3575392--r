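test_that("config validation rejects infeasible worlds", {
  expect_error(simulation_config(censoring_rate = 1), "infeasible")
  expect_error(simulation_config(planted_sizes = c(1, 2)), "planted")
  expect_error(simulation_config(planted_sizes = c(9, 2)), "planted")
  expect_error(simulation_config(n_genes = 5), "cover")
  expect_error(simulation_config(baseline_hazard = 0), "positive")
})

test_that("same seed gives bit-identical cohorts", {
  cfg <- simulation_config(n_cohorts = 2, n_samples = 50, n_genes = 30,
                           n_poor_candidates = 4, n_good_candidates = 3,
                           planted_sizes = c(3, 2), seed = 77)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a[[1]]$values, b[[1]]$values)
  expect_identical(a[[2]]$time, b[[2]]$time)
  expect_identical(attr(a, "latent"), attr(b, "latent"))
})

test_that("censoring calibration hits its target", {
  cfg <- simulation_config(n_cohorts = 1, n_samples = 4000, n_genes = 20,
                           n_poor_candidates = 4, n_good_candidates = 3,
                           planted_sizes = c(3, 2), censoring_rate = 0.6,
                           seed = 5)
  co <- simulate_cohorts(cfg)[[1]]
  expect_equal(mean(co$event == 0), 0.6, tolerance = 0.05)
})

test_that("planted hazard ratio is recovered by the Cox route", {
  # median over 5 replicates: a single n=500 draw has sd(log HR) ~ 0.14,
  # wide enough to leave the check band by seed luck alone
  hrs <- vapply(1:5, function(i) {
    cfg <- simulation_config(n_cohorts = 1, n_samples = 500, n_genes = 50,
                             n_poor_candidates = 4, n_good_candidates = 3,
                             planted_sizes = c(3, 2), beta = log(2),
                             seed = 13 + i)
    sim <- simulate_cohorts(cfg)
    idx <- compute_index(sim[[1]], attr(sim, "planted_gsp"))
    cox_univariate(idx$group, sim[[1]]$time, sim[[1]]$event)$hazard_ratio
  }, 0)
  expect_gt(median(hrs), 1.6)
  expect_lt(median(hrs), 2.5)
})

test_that("under beta = 0 the planted pair's log-rank p is uniform", {
  ps <- vapply(1:200, function(i) {
    cfg <- simulation_config(n_cohorts = 1, n_samples = 150, n_genes = 20,
                             n_poor_candidates = 4, n_good_candidates = 3,
                             planted_sizes = c(3, 2), beta = 0,
                             seed = 5000 + i)
    sim <- simulate_cohorts(cfg)
    idx <- compute_index(sim[[1]], attr(sim, "planted_gsp"))
    logrank_test(sim[[1]]$time, sim[[1]]$event, idx$group)$p
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("per-cohort location shifts change nothing downstream", {
  cfg <- simulation_config(n_cohorts = 2, n_samples = 150, n_genes = 30,
                           n_poor_candidates = 4, n_good_candidates = 3,
                           planted_sizes = c(3, 2), seed = 19,
                           cohort_shift = c(0, 0), cohort_scale = c(1, 1))
  base <- simulate_cohorts(cfg)
  cands <- attr(base, "candidates")
  shifted <- lapply(seq_along(base), function(i) {
    co <- base[[i]]
    expression_cohort(co$values + c(-500, 1e4)[i], cohort_id = co$cohort_id,
                      time = co$time, event = co$event)
  })
  r1 <- gsp_screen(base, cands)
  r2 <- gsp_screen(shifted, cands)
  expect_equal(r1$screen, r2$screen)
  expect_equal(r1$selected, r2$selected)
})

test_that("simulate_clinical links grade to the latent subpopulation", {
  cfg <- simulation_config(n_cohorts = 1, n_samples = 300, n_genes = 20,
                           n_poor_candidates = 4, n_good_candidates = 3,
                           planted_sizes = c(3, 2), seed = 23)
  base <- simulate_cohorts(cfg)
  # strong knob: detected in >= 90% of replicate draws
  hits <- vapply(1:10, function(i) {
    sim <- simulate_clinical(cfg, base, assoc_log_odds = 2, seed = 100 + i)
    co <- sim$cohorts[[1]]
    idx <- compute_index(co, attr(sim$cohorts, "planted_gsp"))
    at <- assoc_table(co$covariates, idx$group)
    at$grade$p < 0.01
  }, NA)
  expect_gte(mean(hits), 0.9)
  # zero knob: grade margins still sum to n, association only at chance level
  sim0 <- simulate_clinical(cfg, base, assoc_log_odds = 0, seed = 9)
  expect_equal(sum(table(sim0$cohorts[[1]]$covariates$grade)), 300)
  ps <- vapply(1:20, function(i) {
    s <- simulate_clinical(cfg, base, assoc_log_odds = 0, seed = 200 + i)
    co <- s$cohorts[[1]]
    idx <- compute_index(co, attr(s$cohorts, "planted_gsp"))
    assoc_table(co$covariates, idx$group)$grade$p
  }, 0)
  expect_gte(mean(ps > 0.05), 0.8)
})
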