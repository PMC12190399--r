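#' Assign sites to strand-aware dyad-relative offsets
#'
#' For every gene carrying a +1 nucleosome dyad, sites within the offset
#' window are assigned a signed offset (positive = downstream in gene
#' orientation): `pos - dyad` on the plus strand, `dyad - pos` on the
#' minus strand. A site may be assigned to more than one gene (each gene's
#' alignment is independent); genes without a dyad are skipped with a
#' warning.
#'
#' @param sites data.table with `chrom`, `pos` (0-based).
#' @param genes gene table with `gene_id`, `chrom`, `strand`,
#'   `plus1_dyad`.
#' @param window offset window kept, default `[-1000, 1500]` bp.
#' @return data.table `(gene_id, chrom, pos, offset)`.
#' @export
site_offsets <- function(sites, genes, window = c(-1000L, 1500L)) {
  sites <- as.data.table(sites)
  genes <- as.data.table(genes)
  nod <- is.na(genes$plus1_dyad)
  if (any(nod)) {
    warning("skipping ", sum(nod), " gene(s) without a +1 dyad")
    genes <- genes[!nod]
  }
  gw <- genes[, .(gene_id, chrom, strand, plus1_dyad,
                  wstart = ifelse(strand == "+", plus1_dyad + window[1],
                                  plus1_dyad - window[2]),
                  wend = ifelse(strand == "+", plus1_dyad + window[2],
                                plus1_dyad - window[1]))]
  st <- sites[, .(chrom, pos, s2 = pos, e2 = pos)]
  setkey(gw, chrom, wstart, wend)
  ov <- foverlaps(st, gw, by.x = c("chrom", "s2", "e2"),
                  by.y = c("chrom", "wstart", "wend"), nomatch = NULL)
  ov[, offset := as.integer(ifelse(strand == "+", pos - plus1_dyad,
                                   plus1_dyad - pos))]
  ov[, .(gene_id, chrom, pos, offset)]
}

#' Per-offset phasing profile
#'
#' The raw profile is the mean site value at each dyad-relative offset; the
#' smoothed profile applies a centered 21-bp box filter on the raw profile
#' (on the complete integer offset grid, shrinking symmetrically at the
#' edges; offsets with no sites are excluded from each window's mean).
#' Sine wave fits use the raw profile; smoothing is for display only.
#'
#' @param offset,value per-assignment offset and site value (a site
#'   assigned to several genes contributes once per gene).
#' @param smooth_window box filter width, odd, default 21 bp.
#' @return data.table `(offset, raw_mean, smoothed_mean, n_sites)` for
#'   offsets with at least one site.
#' @export
build_profile <- function(offset, value, smooth_window = 21L) {
  if (length(offset) == 0L) stop("no site assignments to profile")
  stopifnot(length(offset) == length(value))
  dt <- data.table(offset = as.integer(offset), value = as.numeric(value))
  dt <- dt[is.finite(value)]
  if (nrow(dt) == 0L) stop("no finite site values to profile")
  raw <- dt[, .(raw_mean = mean(value), n_sites = .N), by = offset]
  setkey(raw, offset)
  grid <- seq(min(raw$offset), max(raw$offset))
  v <- rep(NA_real_, length(grid))
  v[match(raw$offset, grid)] <- raw$raw_mean
  sm <- box_smooth(v, smooth_window)
  raw[, smoothed_mean := sm[match(offset, grid)]]
  setcolorder(raw, c("offset", "raw_mean", "smoothed_mean", "n_sites"))
  raw[]
}

#' Phasing profile and decaying sine wave fit for a gene set
#'
#' Composes the pipeline stage: assign dyad-relative offsets, average
#' normalized rates per offset, and fit the decaying sine wave over the
#' gene-body window.
#'
#' @param norm_rates table with `chrom`, `pos`, `ratio` (normalized rate)
#'   and, if present, `estimable`.
#' @param genes gene table (see [site_offsets()]).
#' @param gene_subset optional character vector of gene ids to restrict to.
#' @param fit_range sine fitting window, default `[-50, 1000]`.
#' @param window profile export window, default `[-1000, 1500]`.
#' @param smooth_window display smoothing width.
#' @param ... passed to [fit_sine()].
#' @return list of class `phase_fit`: `profile`, `fit` (`sine_fit`),
#'   `derived` (`sine_fit_derived`), `n_genes`.
#' @export
phase_fit <- function(norm_rates, genes, gene_subset = NULL,
                      fit_range = c(-50L, 1000L),
                      window = c(-1000L, 1500L), smooth_window = 21L, ...) {
  genes <- as.data.table(genes)
  if (!is.null(gene_subset)) {
    genes <- genes[gene_id %in% gene_subset]
    if (nrow(genes) == 0L) stop("gene_subset matches no genes")
  }
  nr <- as.data.table(norm_rates)
  if ("estimable" %in% names(nr)) nr <- nr[estimable == TRUE]
  nr <- nr[is.finite(ratio)]
  assign <- site_offsets(nr[, .(chrom, pos)], genes, window = window)
  assign[nr, on = c("chrom", "pos"), value := i.ratio]
  profile <- build_profile(assign$offset, assign$value,
                           smooth_window = smooth_window)
  fit <- fit_sine(profile$offset, profile$raw_mean, fit_range = fit_range,
                  ...)
  structure(list(profile = profile, fit = fit,
                 derived = derive_sine_fit(fit), n_genes = nrow(genes)),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat(sprintf("phasing fit over %d genes\n", x$n_genes))
  print(x$derived)
  invisible(x)
}
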