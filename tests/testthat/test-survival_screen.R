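test_that("dichotomize applies the sign rule and the inclusive 20% balance", {
  d <- dichotomize(c(1, -1, 2, -2))
  expect_equal(c(d$n_poor, d$n_good), c(2, 2))
  expect_true(d$balanced)
  # 1/5 = 20% exactly: "at least 20%" is inclusive
  d2 <- dichotomize(c(1, 1, 1, 1, -1))
  expect_equal(c(d2$n_poor, d2$n_good), c(4, 1))
  expect_true(d2$balanced)
  d3 <- dichotomize(c(1, 2, 3))
  expect_equal(d3$n_good, 0)
  expect_false(d3$balanced)
  expect_error(dichotomize(c(NA_real_, NA_real_)), "no evaluable")
})

test_that("log-rank matches the hand calculation on the 4-sample case", {
  # group A events at t=1,2; group B censored at t=3,4
  # t=1: O-E = 1 - 2/4, V = (1/2)(1/2)(3/3); t=2: O-E = 1 - 1/3, V = (1/3)(2/3)
  # chisq = (7/6)^2 / (1/4 + 2/9)
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 0, 0),
                     factor(c("A", "A", "B", "B")))
  expect_equal(lr$statistic, (7 / 6)^2 / (1 / 4 + 2 / 9), tolerance = 1e-12)
  expect_equal(lr$p, pchisq((7 / 6)^2 / (17 / 36), 1, lower.tail = FALSE))
})

test_that("log-rank degeneracies and invariances", {
  # identical survival in both groups: statistic 0, p 1 (no events at all)
  lr0 <- logrank_test(c(1, 2, 1, 2), c(0, 0, 0, 0), c("A", "B", "A", "B"))
  expect_equal(lr0$p, 1)
  expect_true(lr0$degenerate)
  set.seed(11)
  s <- sim_surv(120, hr = 2)
  lr1 <- logrank_test(s$time, s$event, s$group)
  # invariant to time-unit rescaling
  lr2 <- logrank_test(s$time * 365.25, s$event, s$group)
  expect_equal(lr1$statistic, lr2$statistic)
  expect_error(logrank_test(s$time, s$event, rep("A", 120)), "two")
})

test_that("log-rank p is uniform under the permutation null", {
  set.seed(99)
  s <- sim_surv(80, hr = 1)
  ctx <- rxagsp:::surv_context(s$time, s$event)
  ps <- replicate(1000, rxagsp:::logrank_kernel(ctx, sample(s$group))$p)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("fast kernels equal survival::survdiff / coxph on random data", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(30:150, 1)
    time <- round(rexp(n, 0.1), 1)  # heavy ties
    event <- rbinom(n, 1, 0.6)
    g <- rbinom(n, 1, 0.4) == 1
    if (length(unique(g)) < 2 || sum(event) < 3) next
    lr <- logrank_test(time, event, g)
    expect_equal(lr$statistic,
                 survival::survdiff(survival::Surv(time, event) ~ g)$chisq,
                 tolerance = 1e-8)
    cx <- rxagsp:::cox_binary_kernel(rxagsp:::surv_context(time, event), g)
    cf <- survival::coxph(survival::Surv(time, event) ~ g, ties = "efron")
    expect_equal(cx$beta, unname(coef(cf)), tolerance = 1e-6)
    expect_equal(cx$se, sqrt(cf$var[1, 1]), tolerance = 1e-6)
  }
})

test_that("cox_univariate recovers a planted hazard ratio and basic identities", {
  set.seed(7)
  s <- sim_surv(500, hr = 2)
  cx <- cox_univariate(s$group, s$time, s$event)
  expect_gt(cx$hazard_ratio, 1.6)
  expect_lt(cx$hazard_ratio, 2.5)
  # sign flip of a continuous covariate inverts the hazard ratio
  x <- rnorm(500)
  c1 <- cox_univariate(x, s$time, s$event)
  c2 <- cox_univariate(-x, s$time, s$event)
  expect_equal(c2$hazard_ratio, 1 / c1$hazard_ratio, tolerance = 1e-8)
  expect_equal(c1$p_wald, c2$p_wald, tolerance = 1e-10)
  # identical survival in both groups: HR ~ 1, p ~ 1
  tt <- rep(c(1, 2, 3, 4, 5), 2); ee <- rep(c(1, 0, 1, 0, 1), 2)
  gg <- rep(c(0, 1), each = 5)
  c0 <- cox_univariate(gg, tt, ee)
  expect_equal(c0$hazard_ratio, 1, tolerance = 1e-6)
  expect_gt(c0$p_wald, 0.99)
})

test_that("cox_univariate flags complete separation", {
  # all events in one group, which is always at risk ahead of the other
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  g <- c(1, 1, 1, 0, 0, 0)
  cx <- cox_univariate(g, time, event)
  expect_true(cx$separation)
  expect_true(is.infinite(cx$hazard_ratio))
  expect_true(cx$p_wald <= 1 && cx$p_wald >= 0)
})

test_that("cox_multivariate recovers two planted effects and checks rank", {
  set.seed(21)
  n <- 1000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  h <- 0.1 * exp(log(1.5) * x1 + log(2) * x2)
  t_ev <- rexp(n, h); t_c <- rexp(n, 0.05)
  time <- pmin(t_ev, t_c); event <- as.integer(t_ev <= t_c)
  fit <- cox_multivariate(data.frame(x1 = x1, x2 = x2), time, event)
  expect_equal(fit$terms$hazard_ratio[1], 1.5, tolerance = 0.25)
  expect_equal(fit$terms$hazard_ratio[2], 2.0, tolerance = 0.25)
  expect_lt(fit$model_p, 1e-6)
  # single covariate matches the univariate fit
  f1 <- cox_multivariate(data.frame(x1 = x1), time, event)
  u1 <- cox_univariate(x1, time, event)
  expect_equal(f1$terms$hazard_ratio, u1$hazard_ratio, tolerance = 1e-8)
  # duplicated column -> named rank-deficiency error
  expect_error(cox_multivariate(data.frame(x1 = x1, dup = x1), time, event),
               "dup")
})

test_that("screen_cohort emits one flagged record per pair in order", {
  set.seed(5)
  cfg <- simulation_config(n_cohorts = 1, n_samples = 120, n_genes = 30,
                           n_poor_candidates = 4, n_good_candidates = 3,
                           planted_sizes = c(3, 2), seed = 5)
  co <- simulate_cohorts(cfg)[[1]]
  cands <- attr(simulate_cohorts(cfg), "candidates")
  gsps <- enumerate_gsps(cands)
  rec <- screen_cohort(co, gsps)
  expect_equal(nrow(rec), count_gsps(4, 3))
  expect_equal(rec$gsp_id, vapply(gsps, gsp_id, ""))
  expect_equal(rec$n_poor_group + rec$n_good_group +
                 rec$n_unevaluable, rep(120L, nrow(rec)))
  # screen statistics agree with the one-at-a-time public route
  i <- which.min(rec$p_logrank)
  idx <- compute_index(co, gsps[[i]])
  keep <- !is.na(idx$index)
  lr <- logrank_test(co$time[keep], co$event[keep], idx$group[keep])
  expect_equal(rec$p_logrank[i], lr$p)
  cx <- cox_univariate(idx$group[keep], co$time[keep], co$event[keep])
  expect_equal(rec$hazard_ratio[i], cx$hazard_ratio, tolerance = 1e-6)
  expect_equal(rec$p_cox_onesided[i], cx$p_onesided, tolerance = 1e-6)
})

test_that("degenerate single-group pairs are flagged, not dropped", {
  m <- gene_matrix(c("p1", "p2", "g1", "g2"), paste0("S", 1:6),
                   c(9, 9, 9, 9, 9, 9,  8, 8, 8, 8, 8, 8,
                     1, 1, 1, 1, 1, 1,  2, 2, 2, 2, 2, 2))
  co <- make_cohort(m, time = 1:6, event = rep(1L, 6))
  rec <- screen_cohort(co, list(gene_set_pair(c("p1", "p2"), c("g1", "g2"))))
  expect_equal(rec$n_good_group, 0L)
  expect_false(rec$balanced)
  expect_true(rec$degenerate)
  expect_false(rec$direction_ok)
})
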