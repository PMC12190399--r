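# a minimal population fit standing in for phase_fit output
fake_pop_fit <- function(params, fit_range = c(-50L, 1000L)) {
  structure(list(params = params,
                 quality = list(ssr = 0, sst = 1, n = 1051L, p = 6L),
                 fit_range = fit_range),
            class = "sine_fit")
}

test_that("unbiased rates anchor gene deviations at the population mean", {
  p <- wt_landscape()
  pop <- fake_pop_fit(p)
  pop_mean <- sine_curve_mean(p)
  set.seed(2)
  off <- sample(-50:1000, 30)

  # sites exactly on the population curve -> unbiased rate = population mean
  on_curve <- data.table::data.table(gene_id = "g1", offset = off,
                                     value = sine_model_eval(p, off))
  rec <- gene_unbiased_rates(on_curve, pop)
  expect_equal(rec$unbiased_rate, pop_mean, tolerance = 1e-12)
  expect_equal(rec$bias, rec$raw_mean - rec$unbiased_rate)

  # a uniform +0.1 deviation shifts the unbiased rate by +0.1
  above <- data.table::data.table(gene_id = "g2", offset = off,
                                  value = sine_model_eval(p, off) + 0.1)
  rec2 <- gene_unbiased_rates(above, pop)
  expect_equal(rec2$unbiased_rate, pop_mean + 0.1, tolerance = 1e-12)

  # genes under the site threshold are kept but not ranked
  few <- data.table::data.table(gene_id = "g3", offset = off[1:3],
                                value = 1)
  rec3 <- gene_unbiased_rates(few, pop)
  expect_false(rec3$ranked)
})

test_that("gene ranks recover known per-gene rate offsets", {
  p <- wt_landscape()
  pop <- fake_pop_fit(p)
  set.seed(14)
  n_genes <- 60L
  shift <- runif(n_genes, -0.3, 0.3)
  assign <- data.table::rbindlist(lapply(seq_len(n_genes), function(i) {
    off <- sample(-50:1000, 40)
    data.table::data.table(gene_id = sprintf("g%03d", i), offset = off,
                           value = sine_model_eval(p, off) + shift[i])
  }))
  rec <- gene_unbiased_rates(assign, pop)
  ord <- match(sprintf("g%03d", seq_len(n_genes)), rec$gene_id)
  expect_gte(cor(rank(rec$unbiased_rate[ord]), rank(shift),
                 method = "spearman"), 0.95)
})

test_that("quintile partition is balanced, ordered and deterministic", {
  rec10 <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:10), n_sites = 10L, raw_mean = 0,
    bias = 0, unbiased_rate = (10:1) / 10, ranked = TRUE)
  q10 <- assign_quintiles(rec10)
  expect_equal(as.integer(table(q10$quintile)), rep(2L, 5))
  # the two smallest rates land in Q1
  expect_setequal(q10[quintile == 1, gene_id], c("g09", "g10"))

  rec7 <- rec10[1:7]
  q7 <- assign_quintiles(rec7)
  expect_equal(as.integer(table(q7$quintile)), c(2L, 2L, 1L, 1L, 1L))

  # all-tied rates: assignment falls back to gene id order
  rec_tie <- data.table::copy(rec10)[, unbiased_rate := 1]
  q_tie <- assign_quintiles(rec_tie)
  expect_equal(q_tie[order(gene_id), quintile], rep(1:5, each = 2))
  expect_identical(q_tie$quintile, assign_quintiles(rec_tie)$quintile)

  # quintile gene counts always add up to the ranked population
  expect_equal(sum(!is.na(q7$quintile)), 7L)

  # mean unbiased rate is non-decreasing from Q1 to Q5
  means <- q10[, mean(unbiased_rate), keyby = quintile]$V1
  expect_true(all(diff(means) >= 0))
})

test_that("a global rate shift moves unbiased rates but not quintiles", {
  p <- wt_landscape()
  pop <- fake_pop_fit(p)
  set.seed(6)
  assign <- data.table::rbindlist(lapply(1:12, function(i) {
    off <- sample(-50:1000, 20)
    data.table::data.table(gene_id = sprintf("g%02d", i), offset = off,
                           value = sine_model_eval(p, off) + runif(1, -0.2, 0.2))
  }))
  rec <- assign_quintiles(gene_unbiased_rates(assign, pop))
  shifted <- data.table::copy(assign)[, value := value + 0.5]
  rec_s <- assign_quintiles(gene_unbiased_rates(shifted, pop))
  expect_equal(rec_s$unbiased_rate, rec$unbiased_rate + 0.5,
               tolerance = 1e-12)
  expect_identical(rec_s$quintile, rec$quintile)
})

test_that("quintile fits agree on a homogeneous genome", {
  g <- make_genome(sim_config(n_genes = 500L, n_trna = 0L, seed = 47L,
                              mean_site_interval = 128))
  tc <- genome_timecourse(g, noise = "none")
  nr <- normalize_rates(fit_first_order(tc), g$config$mt_rate)
  pf <- phase_fit(nr, g$genes)
  assign <- site_offsets(nr[estimable == TRUE, .(chrom, pos)], g$genes)
  assign[nr, on = c("chrom", "pos"), value := i.ratio]
  rec <- assign_quintiles(gene_unbiased_rates(assign, pf$fit))
  fits <- quintile_phase_fits(rec, nr, g$genes)
  spacings <- vapply(fits, function(f) f$derived$spacing_bp, 1)
  amps <- vapply(fits, function(f) f$derived$amplitude, 1)
  expect_lt(diff(range(spacings)), 0.5)
  expect_lt(diff(range(amps)), 0.02)
})
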