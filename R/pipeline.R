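#' Run the full methylation-kinetics pipeline
#'
#' Drives the analysis end to end: (optional) fragment-end quantification
#' into per-site fractions, per-site first-order rate estimation,
#' internal-control normalization, the +1-dyad-aligned phasing profile and
#' decaying sine wave fit, per-gene bias-corrected rates with quintile
#' fits, and tRNA region kinetics. Stage outputs are written under
#' `config$out_dir` together with a machine-readable `summary.json`.
#'
#' @param config a list:
#' \describe{
#'   \item{mode}{`"dam"` (GATC, mtDNA reference) or `"sssi"` (CG,
#'     genome-median reference); the reference can be overridden with
#'     `reference` = `"mtdna"` or `"genome"`.}
#'   \item{genes}{gene table or TSV path ([read_genes()] format).}
#'   \item{fractions, times}{bedGraph paths (one per timepoint) + minutes,
#'     or `fractions_long` = long TSV path. Alternatively
#'     \code{fragments} = per-timepoint fragment BED paths plus
#'     \code{sites} = site catalog BED for qDA quantification.}
#'   \item{out_dir}{output directory.}
#'   \item{cap, min_points, min_neighbor_bp, n_min, min_genes_per_offset,
#'     fit_range, smooth_window, window}{thresholds (all optional).}
#' }
#' @return list (invisible): `rates`, `reference_value`, `region_summary`,
#'   `phase` (`phase_fit`), `gene_rates`, `quintile_fits`, `trna`,
#'   `summary_path`.
#' @export
run_pipeline <- function(config) {
  t0 <- Sys.time()
  stage <- function(name, expr) {
    ts <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), ts, units = "secs"))))
    res
  }
  mode <- config$mode %||% "dam"
  reference <- config$reference %||%
    if (mode == "dam") "mtdna" else "genome"
  fit_range <- config$fit_range %||% c(-50L, 1000L)
  window <- config$window %||% c(-1000L, 1500L)
  smooth_window <- config$smooth_window %||% 21L
  cap <- config$cap %||% 0.99
  min_points <- config$min_points %||% 3L
  min_neighbor_bp <- config$min_neighbor_bp %||% 200
  n_min <- config$n_min %||% 5L
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mt_chrom <- config$mt_chrom %||% "chrM"

  genes <- stage("genes", {
    if (is.character(config$genes)) read_genes(config$genes)
    else as.data.table(config$genes)
  })

  tc <- stage("fractions", {
    if (!is.null(config$fragments)) {
      sites <- if (is.character(config$sites)) {
        bed <- fread(config$sites, header = FALSE,
                     col.names = c("chrom", "pos", "end"))
        bed[, .(chrom, pos)]
      } else as.data.table(config$sites)[, .(chrom, pos)]
      setkey(sites, chrom, pos)
      fr_list <- lapply(seq_along(config$fragments), function(i) {
        fr <- if (is.character(config$fragments[[i]]))
          fread(config$fragments[[i]], header = FALSE,
                col.names = c("chrom", "start", "end"))
        else as.data.table(config$fragments[[i]])
        setkey(fr, chrom, start)
        cnt <- count_half_sites(fr, sites)
        quantify_fractions(cnt, min_neighbor_bp = min_neighbor_bp)$fraction
      })
      methyl_timecourse(sites, config$times,
                        do.call(cbind, fr_list))
    } else if (!is.null(config$fractions_long)) {
      read_fractions(long = config$fractions_long)
    } else {
      read_fractions(paths = config$fractions, times = config$times)
    }
  })

  if (!"region" %in% names(tc$sites))
    tc$sites[, region := fifelse(chrom == mt_chrom, "mt", "nuclear")]

  rates <- stage("rates", {
    r <- fit_first_order(tc, cap = cap, min_points = min_points)
    ref <- if (reference == "mtdna")
      mtdna_reference(r) else genome_median_reference(tc, cap = cap,
                                                      min_points = min_points)
    r <- normalize_rates(r, ref)
    attr(r, "reference_value") <- ref
    r
  })
  ref_value <- attr(rates, "reference_value")
  write_pk_tsv(rates[, .(chrom, pos, k_app, intercept_b, r2, n_used,
                         ratio)],
               file.path(out_dir, "rates.tsv"))
  write_bedgraph(rates[estimable == TRUE,
                       .(chrom, pos, value = ratio)],
                 file.path(out_dir, "normalized_rates.bedGraph"))
  region_summary <- region_rate_summary(rates)

  coding <- if ("klass" %in% names(genes)) genes[klass == "coding"] else genes
  phase <- stage("phase", {
    phase_fit(rates, coding, fit_range = fit_range, window = window,
              smooth_window = smooth_window)
  })
  write_pk_tsv(phase$profile, file.path(out_dir, "profile.tsv"))
  write_sine_fit_json(phase$fit, file.path(out_dir, "phase_fit.json"))

  generate_quintiles <- isTRUE(config$quintiles %||% TRUE)
  gene_rates <- NULL; qfits <- NULL
  if (generate_quintiles) {
    gene_rates <- stage("genes_rates", {
      nr <- rates[estimable == TRUE & is.finite(ratio)]
      assign <- site_offsets(nr[, .(chrom, pos)], coding, window = window)
      assign[nr, on = c("chrom", "pos"), value := i.ratio]
      rec <- gene_unbiased_rates(assign, phase$fit, fit_range = fit_range,
                                 n_min = n_min)
      assign_quintiles(rec)
    })
    write_pk_tsv(gene_rates, file.path(out_dir, "gene_rates.tsv"))
    qfits <- stage("quintile_fits", {
      quintile_phase_fits(gene_rates, rates, coding, fit_range = fit_range,
                          window = window, smooth_window = smooth_window)
    })
    for (q in 1:5)
      write_sine_fit_json(qfits[[q]]$fit,
                          file.path(out_dir, sprintf("quintile_q%d_fit.json", q)))
  }

  trna <- NULL
  if ("klass" %in% names(genes) && any(genes$klass == "tRNA")) {
    trna <- stage("trna", {
      tg <- genes[klass == "tRNA"]
      regions <- make_trna_regions(tg)
      kin <- trna_kinetics(rates, regions, timecourse = tc)
      map <- tryCatch(
        trna_aligned_map(rates, tg,
                         min_genes_per_offset =
                           config$min_genes_per_offset %||% 10L),
        error = function(e) NULL)
      list(regions = regions, kinetics = kin, map = map)
    })
    fwrite(trna$regions[, .(chrom, start, end, name = paste(gene_id, klass,
                                                            sep = "_"))],
           file.path(out_dir, "trna_regions.bed"), sep = "\t",
           col.names = FALSE)
    write_pk_tsv(trna$kinetics$summary,
                 file.path(out_dir, "trna_class_summary.tsv"))
    if (!is.null(trna$map))
      write_pk_tsv(trna$map, file.path(out_dir, "trna_aligned_map.tsv"))
  }

  summary_path <- file.path(out_dir, "summary.json")
  summ <- list(
    mode = mode, reference = reference, reference_value = ref_value,
    n_sites = nrow(tc$sites), n_estimable = sum(rates$estimable),
    phase = list(params = unclass(phase$fit$params),
                 derived = unclass(phase$derived)),
    region_summary = region_summary,
    quintiles = if (!is.null(qfits)) lapply(qfits, function(f)
      unclass(f$derived)),
    trna_ratios = if (!is.null(trna)) as.list(trna$kinetics$ratios))
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  message(sprintf("[pipeline] complete in %.1fs",
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(list(rates = rates, reference_value = ref_value,
                 region_summary = region_summary, phase = phase,
                 gene_rates = gene_rates, quintile_fits = qfits,
                 trna = trna, summary_path = summary_path))
}
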