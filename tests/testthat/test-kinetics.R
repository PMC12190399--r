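test_that("the log-linear estimator is exact on noise-free exponentials", {
  f <- matrix(c(0, 0.39346934, 0.63212056), nrow = 1)
  fit <- fit_first_order(f, times = c(0, 1, 2))
  expect_equal(fit$k_app, 0.5, tolerance = 1e-7)
  expect_equal(fit$r2, 1, tolerance = 1e-7)
  expect_equal(fit$n_used, 3L)

  # whole synthetic genome: relative error below 1e-9 at every site
  g <- tiny_genome(seed = 17L, n_genes = 8L)
  tc <- genome_timecourse(g, noise = "none")
  r <- fit_first_order(tc)
  expect_true(all(r$estimable))
  expect_lt(max(abs(r$k_app - g$sites$truth_rate) / g$sites$truth_rate),
            1e-9)
})

test_that("saturated points are capped and deduplicated as specified", {
  # all points above the cap: only the first survives -> unestimable
  f <- matrix(c(0.995, 0.999, 0.9999), nrow = 1)
  fit <- fit_first_order(f, times = 1:3)
  expect_equal(fit$n_used, 1L)
  expect_false(fit$estimable)
  expect_true(fit$capped)

  # one point above the cap is kept (capped at 0.99), the rest dropped
  f2 <- matrix(c(0.5, 0.8, 0.995, 0.999), nrow = 1)
  fit2 <- fit_first_order(f2, times = c(30, 60, 120, 240))
  expect_equal(fit2$n_used, 3L)
  expect_true(fit2$estimable)

  # raising the cap never decreases the number of points used
  set.seed(23)
  for (i in 1:20) {
    k <- runif(1, 0.005, 0.08)
    f <- matrix(1 - exp(-k * c(30, 60, 120, 240)), nrow = 1)
    n95 <- fit_first_order(f, times = c(30, 60, 120, 240), cap = 0.95)$n_used
    n99 <- fit_first_order(f, times = c(30, 60, 120, 240), cap = 0.99)$n_used
    expect_gte(n99, n95)
  }
})

test_that("mtDNA reference modes agree and reduce to the median", {
  expect_equal(mtdna_reference(c(0.01, 0.02, 0.03)), 0.02)
  expect_equal(mtdna_reference(0.015), 0.015)
  expect_error(mtdna_reference(numeric(0)), "no estimable mtDNA")

  g <- tiny_genome(seed = 29L, n_genes = 4L, mt_length = 20000L)
  tc <- genome_timecourse(g, noise = "none")
  r <- fit_first_order(tc)
  k_site <- mtdna_reference(r)
  k_traj <- mtdna_reference(r, timecourse = tc, mode = "median_trajectory")
  expect_lt(abs(k_site - k_traj) / k_site, 0.01)
  expect_equal(k_site, g$config$mt_rate, tolerance = 1e-9)
})

test_that("genome-median reference matches a direct median-then-fit oracle", {
  times <- c(30, 60, 120, 240)
  # homogeneous rates: the reference is that rate
  f <- 1 - exp(-outer(rep(0.004, 21), times))
  tc <- methyl_timecourse(data.table::data.table(chrom = "c", pos = 1:21),
                          times, f)
  expect_equal(genome_median_reference(tc), 0.004, tolerance = 1e-9)

  # mixed rates: recompute the median trajectory and its fit by hand
  # (rates chosen so no fraction reaches the 0.99 saturation cap)
  k <- rep(c(0.002, 0.006), c(10, 11))
  f2 <- 1 - exp(-outer(k, times))
  tc2 <- methyl_timecourse(data.table::data.table(chrom = "c", pos = 1:21),
                           times, f2)
  med <- apply(f2, 2, median)
  oracle <- -unname(coef(lm(log(1 - med) ~ times))[2])
  expect_equal(genome_median_reference(tc2), oracle, tolerance = 1e-9)

  # kinetic scaling: doubling all rates doubles the reference
  f3 <- 1 - exp(-outer(2 * k, times))
  tc3 <- methyl_timecourse(data.table::data.table(chrom = "c", pos = 1:21),
                           times, f3)
  expect_equal(genome_median_reference(tc3),
               2 * genome_median_reference(tc2), tolerance = 1e-6)
})

test_that("normalization is exact and invariant under global rate scaling", {
  expect_equal(normalize_rates(0.016, 0.02), 0.8)
  expect_equal(normalize_rates(0.02, 0.02), 1.0)
  expect_error(normalize_rates(0.01, 0), "> 0")

  g <- tiny_genome(seed = 33L, n_genes = 6L)
  base <- normalize_rates(g$sites$truth_rate,
                          median(g$sites[region == "mt", truth_rate]))
  scaled <- normalize_rates(3 * g$sites$truth_rate,
                            median(3 * g$sites[region == "mt", truth_rate]))
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("region summaries reproduce the generating class rates", {
  # CG density so the gene-body median is sampled finely
  g <- make_genome(sim_config(n_genes = 300L, n_trna = 0L, motif = "CG",
                              mean_site_interval = 16, seed = 37L))
  tc <- genome_timecourse(g, noise = "none")
  r <- fit_first_order(tc)
  nr <- normalize_rates(r, mtdna_reference(r))
  summ <- region_rate_summary(nr)
  expect_equal(summ[region == "mt", median], 1.0, tolerance = 1e-9)
  expect_equal(summ[region == "promoter_NDR", median], 1.3,
               tolerance = 1e-9)
  expect_equal(summ[region == "gene_body", median], 0.80, tolerance = 0.02)
})

test_that("fit quality on noisy data stays in the observed R2 range", {
  g <- tiny_genome(seed = 41L, n_genes = 4L, mt_length = 30000L)
  tc <- genome_timecourse(g, noise = "binomial", coverage = 200)
  k <- mtdna_reference(fit_first_order(tc), timecourse = tc,
                       mode = "median_trajectory")
  med <- apply(tc$fractions[tc$sites$region == "mt", ], 2, median)
  fit <- fit_first_order(matrix(med, nrow = 1), times = tc$times)
  expect_gte(fit$r2, 0.86)
  expect_gt(k, 0)
})
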