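# shared fixtures and brute-force oracles (all built in code at test time)

wt_landscape <- function() {
  params_from_descriptors(spacing_bp = 166.3, amplitude = 0.39,
                          decay_per_period = 0.86, slope_per_kb = -0.12,
                          adj_mean = 0.80)
}

tiny_genome <- function(seed = 42L, n_genes = 4L, n_trna = 0L,
                        motif = "GATC", interval = 256, mt_length = 3000L,
                        ...) {
  make_genome(sim_config(n_genes = n_genes, n_trna = n_trna, n_chrom = 1L,
                         motif = motif, mean_site_interval = interval,
                         mt_length = mt_length, seed = seed, ...))
}

# O(n*m) reference implementation of the half-site counting rule
brute_half_site_counts <- function(fragments, sites) {
  n <- nrow(sites)
  out <- data.frame(ends_at_G = integer(n), ends_at_A = integer(n),
                    starts_at_T = integer(n), starts_at_C = integer(n),
                    cov_G = integer(n), cov_C = integer(n))
  for (i in seq_len(n)) {
    g <- sites$pos[i]
    fr <- fragments[fragments$chrom == sites$chrom[i], ]
    out$ends_at_G[i] <- sum(fr$end == g + 1)
    out$ends_at_A[i] <- sum(fr$end == g + 2)
    out$starts_at_T[i] <- sum(fr$start == g + 2)
    out$starts_at_C[i] <- sum(fr$start == g + 3)
    out$cov_G[i] <- sum(fr$start <= g & fr$end > g)
    out$cov_C[i] <- sum(fr$start <= g + 3 & fr$end > g + 3)
  }
  out
}

# relative error with a floor on the denominator for near-zero truths
rel_err <- function(est, truth, floor = 1e-3) {
  abs(est - truth) / pmax(abs(truth), floor)
}

# circular difference between two phases
phase_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}

expect_params_close <- function(fit_params, true_params, tol) {
  expect_lt(rel_err(fit_params$A, true_params$A), tol)
  expect_lt(rel_err(fit_params$omega, true_params$omega), tol)
  expect_lt(rel_err(fit_params$lam, true_params$lam), tol)
  expect_lt(phase_diff(fit_params$theta, true_params$theta),
            tol * max(abs(true_params$theta), 1))
  expect_lt(rel_err(fit_params$slope, true_params$slope), tol)
  expect_lt(rel_err(fit_params$baseline, true_params$baseline), tol)
}

# draw sine parameters comfortably inside the fit's invariant bounds
draw_params <- function() {
  spacing <- runif(1, 135, 210)
  decay <- runif(1, 0.6, 0.95)
  theta <- sample(c(-1, 1), 1) * runif(1, 0.3, 2.8)
  sine_params(A = runif(1, 0.1, 0.8),
              lam = -log(decay) / spacing,
              omega = 2 * pi / spacing,
              theta = theta,
              slope = sample(c(-1, 1), 1) * runif(1, 5e-5, 5e-4),
              baseline = runif(1, 0.6, 1.5))
}
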