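# Frozen oracle values below were computed with an independent
# implementation of the same integrals (dense-grid quadrature, plus an
# external cross-check of the JZS and correlation Bayes factors) and are
# asserted at the quadrature tolerance.

test_that("paired summaries fill t, df and Cohen's d consistently", {
  ps <- paired_t_from_summary(5.3, 8.7, 489)
  expect_equal(ps$cohen_d, 5.3 / 8.7)
  expect_equal(ps$t, (5.3 / 8.7) * sqrt(489))
  expect_equal(ps$df, 488L)
  expect_equal(paired_t_from_summary(0, 2, 30)$t, 0)
  expect_equal(paired_t_from_summary(-5.3, 8.7, 489)$t,
               -paired_t_from_summary(5.3, 8.7, 489)$t)
  expect_error(paired_t_from_summary(1, 0, 30), "positive")
  expect_error(paired_t_from_summary(1, -2, 30), "positive")
})

test_that("JZS log BF matches the dense-grid oracle on a (t, n, r) lattice", {
  lattice <- expand.grid(t = c(0.5, 2.2, 6, 13.47135),
                         n = c(12, 80, 489),
                         r = c(sqrt(2) / 2, 1))
  for (i in seq_len(nrow(lattice))) {
    t <- lattice$t[i]; n <- lattice$n[i]; r <- lattice$r[i]
    got <- jzs_log_bf10(t, n, r)
    want <- oracle_jzs_log_bf10(t, n, r)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("JZS log BF behaves like a Bayes factor", {
  # t = 0: averaging over the prior cannot beat the point null
  expect_lt(jzs_log_bf10(0, 50), 0)
  expect_lt(jzs_log_bf10(0, 489), 0)
  # strictly increasing in |t| at fixed n, r
  ts <- seq(0, 8, by = 0.5)
  lb <- vapply(ts, function(t) jzs_log_bf10(t, 60), 0)
  expect_true(all(diff(lb) > 0))
  expect_error(jzs_log_bf10(Inf, 50), "finite")
})

test_that("the paired-summary inputs reproduce the published inference", {
  # from the printed cohort summary (mean 5.3, SD 8.7, N = 489); the
  # printed statistics were computed from unrounded data, so agreement is
  # within the tolerance induced by one-decimal rounding of the inputs
  ps <- paired_t_from_summary(5.3, 8.7, 489)
  lb <- jzs_log_bf10(ps$t, ps$n)
  expect_equal(lb, 73.34, tolerance = 0.02)       # 73.777 at rounded inputs
  post <- delta_posterior_summary(ps$t, ps$n)
  expect_equal(post$median, 0.604, tolerance = 0.02)
  expect_equal(post$ci95[1], 0.508, tolerance = 0.02)
  expect_equal(post$ci95[2], 0.701, tolerance = 0.02)
  ord <- order_constrained_evaluation(ps$t, ps$n, posterior = post)
  expect_gte(ord$pmp_gic, 0.999)
  # the losing tail is far below double underflow but still quantified
  expect_lt(post$log_mass_neg, log(1e-30))
})

test_that("the delta posterior is a proper, symmetric-under-sign density", {
  post <- delta_posterior_summary(3.2, 45)
  w <- post$grid[2] - post$grid[1]
  expect_lt(abs(sum(post$density) * w - 1), 1e-6)
  expect_true(post$ci95[1] < post$median && post$median < post$ci95[2])
  # grid quantiles agree with an independent dense-grid CDF
  want <- oracle_delta_quantiles(3.2, 45)
  expect_equal(post$ci95[1], want[1], tolerance = 1e-4)
  expect_equal(post$median, want[2], tolerance = 1e-4)
  expect_equal(post$ci95[2], want[3], tolerance = 1e-4)
  # sign flip mirrors the posterior
  neg <- delta_posterior_summary(-3.2, 45)
  expect_equal(neg$median, -post$median, tolerance = 1e-6)
})

test_that("order-constrained evaluation is symmetric and calibrated", {
  at0 <- order_constrained_evaluation(0, 40)
  expect_equal(at0$pmp_gic, 0.5, tolerance = 1e-6)
  expect_equal(at0$log_bf_pos_neg, 0, tolerance = 1e-5)
  pos <- order_constrained_evaluation(2.5, 40)
  neg <- order_constrained_evaluation(-2.5, 40)
  expect_equal(pos$log_bf_pos_neg, -neg$log_bf_pos_neg, tolerance = 1e-5)
  expect_equal(pos$pmp_gic + pos$pmp_sas, 1)
  expect_gt(pos$pmp_gic, 0.95)
})

test_that("robustness and sequential analyses are consistent", {
  rob <- bf_robustness(13.47135, 489)
  expect_equal(rob$r, c(sqrt(2) / 2, 1, sqrt(2)))
  expect_true(all(rob$log_bf10 > 70))
  expect_lt(max(rob$log_bf10) - min(rob$log_bf10), 5)

  set.seed(81)
  diffs <- rnorm(40, 0.6, 1)
  seq_bf <- bf_sequential(diffs)
  expect_equal(seq_bf$n, 2:40)
  # the final sequential value equals the batch analysis of the full vector
  batch <- jzs_log_bf10(mean(diffs) / sd(diffs) * sqrt(40), 40)
  expect_equal(seq_bf$log_bf10[nrow(seq_bf)], batch, tolerance = 1e-8)
  expect_error(bf_sequential(diffs, min_n = 1), "n >= 2")
})

test_that("correlation log BF matches oracle, symmetry, and published value", {
  # dense-grid oracle on moderate correlations
  for (case in list(c(0.2, 50), c(-0.4, 120), c(0.35, 489))) {
    got <- jeffreys_correlation_log_bf(case[1], case[2])$log_bf10
    expect_equal(got, oracle_cor_log_bf10(case[1], case[2]),
                 tolerance = 1e-6)
  }
  # prior symmetry and the null pull at r = 0
  expect_equal(jeffreys_correlation_log_bf(0.3, 100)$log_bf10,
               jeffreys_correlation_log_bf(-0.3, 100)$log_bf10,
               tolerance = 1e-8)
  expect_lt(jeffreys_correlation_log_bf(0, 100)$log_bf10, 0)
  # published value from the two-decimal printed correlation (r = .35,
  # N = 489 -> log BF 27.88); rounding of r dominates the tolerance
  expect_equal(jeffreys_correlation_log_bf(0.35, 489)$log_bf10, 27.88,
               tolerance = 0.05)
  expect_error(jeffreys_correlation_log_bf(1, 50), "inside")
})

test_that("the correlation matrix uses pairwise-complete observations", {
  df <- data.frame(categories_pct = c(1:9, NA), sle_pct = 10:1,
                   npe_pct = c(NA, 2:10), rpe_pct = rnorm(10),
                   ie_pct = rnorm(10))
  cm <- bayes_correlation_matrix(df)
  expect_equal(nrow(cm), 10L)   # choose(5, 2)
  row <- cm[cm$var1 == "categories_pct" & cm$var2 == "npe_pct", ]
  expect_equal(row$n, 8L)
  expect_error(bayes_correlation_matrix(df, columns = "nope"), "unknown")
})

test_that("end-to-end: a simulated cohort recovers its generating effect", {
  # cohorts generated under delta_true in {0, 0.6}; posterior medians land
  # on the generating side with matching order-constraint verdicts
  null_coh <- score_cohort(simulate_cohort(
    agent_params(p_pers_nonrep = 0.08, p_pers_rep = 0.08), 120,
    master_seed = 91))
  d0 <- null_coh$ese[is.finite(null_coh$ese)]
  t0 <- mean(d0) / sd(d0) * sqrt(length(d0))
  expect_lt(abs(delta_posterior_summary(t0, length(d0))$median), 0.25)

  gic_coh <- score_cohort(simulate_cohort(
    agent_params(p_pers_nonrep = 0.14, p_pers_rep = 0.03), 120,
    master_seed = 92))
  d1 <- gic_coh$ese[is.finite(gic_coh$ese)]
  t1 <- mean(d1) / sd(d1) * sqrt(length(d1))
  ord <- order_constrained_evaluation(t1, length(d1))
  expect_gt(ord$pmp_gic, 0.99)
})
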