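#' Bias-corrected per-gene mean methylation rates
#'
#' The simple mean of a gene's site rates is biased because sites are
#' unevenly distributed along the population-average phasing curve (a gene
#' whose sites happen to sit in linkers looks fast). The bias is estimated
#' from the population sine fit: `bias = mean(curve at the gene's site
#' offsets) - population curve mean`, and the unbiased rate is
#' `raw_mean - bias` — equivalently the gene's mean deviation from the
#' fitted curve, anchored at the population mean so values are comparable
#' to the population's adjusted mean rate.
#'
#' @param assignments data.table `(gene_id, offset, value)` of normalized
#'   site rates assigned to genes (see [site_offsets()]); only offsets
#'   within `fit_range` are used.
#' @param pop_fit the population `sine_fit` (or `phase_fit`).
#' @param fit_range gene-body window, default `[-50, 1000]`.
#' @param n_min genes with fewer sites in the window are emitted but not
#'   ranked (no quintile).
#' @return data.table `(gene_id, n_sites, raw_mean, bias, unbiased_rate,
#'   ranked)`.
#' @export
gene_unbiased_rates <- function(assignments, pop_fit,
                                fit_range = c(-50L, 1000L), n_min = 5L) {
  if (inherits(pop_fit, "phase_fit")) pop_fit <- pop_fit$fit
  params <- pop_fit$params
  pop_mean <- sine_curve_mean(params, pop_fit$fit_range)
  dt <- as.data.table(assignments)
  dt <- dt[offset >= fit_range[1] & offset <= fit_range[2] &
             is.finite(value)]
  rec <- dt[, .(n_sites = .N,
                raw_mean = mean(value),
                bias = mean(sine_model_eval(params, offset)) - pop_mean),
            by = gene_id]
  rec[, unbiased_rate := raw_mean - bias]
  rec[, ranked := n_sites >= n_min]
  rec[]
}

#' Assign methylation-rate quintiles
#'
#' Ranked genes are sorted ascending by unbiased rate (ties broken by
#' gene id, so the assignment is deterministic) and split into five groups
#' whose sizes differ by at most one; Q1 holds the slowest genes, Q5 the
#' fastest. Unranked genes get `NA`.
#'
#' @param records [gene_unbiased_rates()] output.
#' @return `records` with an integer `quintile` column.
#' @export
assign_quintiles <- function(records) {
  rec <- copy(as.data.table(records))
  rec[, quintile := NA_integer_]
  idx <- which(rec$ranked)
  if (length(idx) < 5L) stop("need at least 5 ranked genes for quintiles")
  ord <- idx[order(rec$unbiased_rate[idx], rec$gene_id[idx])]
  n <- length(ord)
  base <- n %/% 5L
  extra <- n %% 5L
  sizes <- rep(base, 5L) + (seq_len(5L) <= extra)
  rec[ord, quintile := rep(1:5, times = sizes)]
  rec[]
}

#' Phasing fits per methylation-rate quintile
#'
#' Reapplies the decaying sine wave model to the combined profile of the
#' genes in each quintile.
#'
#' @param records quintile-labeled [assign_quintiles()] output.
#' @param norm_rates,genes,... passed to [phase_fit()].
#' @return list of five `phase_fit` objects, Q1 to Q5.
#' @export
quintile_phase_fits <- function(records, norm_rates, genes, ...) {
  rec <- as.data.table(records)
  lapply(1:5, function(q) {
    ids <- rec[quintile == q, gene_id]
    if (!length(ids)) stop("quintile ", q, " is empty")
    phase_fit(norm_rates, genes, gene_subset = ids, ...)
  })
}
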