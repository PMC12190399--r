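#' First-order methylation time course
#'
#' Generates per-site methylated fractions under pseudo-first-order
#' kinetics, `f(t) = 1 - (1 - f0) * exp(-k t)`, optionally with binomial
#' sampling noise at a given molecule coverage.
#'
#' @param rates per-site first-order rate constants (per minute).
#' @param timepoints minutes after induction, strictly increasing, `>= 0`.
#' @param noise `"none"` (exact fractions) or `"binomial"`
#'   (`Binomial(coverage, f)/coverage`, seeded).
#' @param coverage molecules per site per timepoint for binomial noise.
#' @param seed optional seed applied before sampling (binomial noise only).
#' @param f0 pre-induction background methylated fraction.
#' @return sites x timepoints matrix of fractions, columns named by time.
#' @export
simulate_timecourse <- function(rates, timepoints,
                                noise = c("none", "binomial"),
                                coverage = 100, seed = NULL, f0 = 0) {
  noise <- match.arg(noise)
  stopifnot(all(rates > 0), all(timepoints >= 0),
            all(diff(timepoints) > 0), f0 >= 0, f0 < 1)
  f <- 1 - (1 - f0) * exp(-outer(rates, timepoints))
  if (noise == "binomial") {
    if (coverage < 1) stop("binomial noise requires coverage >= 1")
    if (!is.null(seed)) set.seed(seed)
    cov <- round(coverage)
    f[] <- rbinom(length(f), cov, f) / cov
  }
  colnames(f) <- as.character(timepoints)
  f
}

#' Methylation time course container
#'
#' @param sites data.table/data.frame with at least `chrom` and `pos`
#'   (0-based motif start); one row per site.
#' @param times minutes after induction, ascending.
#' @param fractions sites x times matrix in `[0, 1]`; `NA` marks missing
#'   observations.
#' @return list of class `methyl_timecourse`.
#' @export
methyl_timecourse <- function(sites, times, fractions) {
  sites <- as.data.table(sites)
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != nrow(sites) || ncol(fractions) != length(times))
    stop("fractions matrix must be sites x times")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  bad <- which(!is.na(fractions) & (fractions < 0 | fractions > 1),
               arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("fraction outside [0, 1] at site %s:%d (t=%g min)",
                 sites$chrom[bad[1, 1]], sites$pos[bad[1, 1]],
                 times[bad[1, 2]]))
  structure(list(sites = sites, times = as.numeric(times),
                 fractions = fractions),
            class = "methyl_timecourse")
}

#' @export
print.methyl_timecourse <- function(x, ...) {
  cat(sprintf("methylation time course: %d sites x %d timepoints (%s min); %d missing values\n",
              nrow(x$sites), length(x$times),
              paste(x$times, collapse = ","), sum(is.na(x$fractions))))
  invisible(x)
}

#' Simulate the induction time course for a synthetic genome
#'
#' Convenience wrapper building a [methyl_timecourse()] from a genome's
#' ground-truth rates under the genome's configured timepoints and noise.
#'
#' @param genome a [make_genome()] result.
#' @param noise,coverage,seed,f0 overrides of the genome config.
#' @export
genome_timecourse <- function(genome, noise = NULL, coverage = NULL,
                              seed = NULL, f0 = NULL) {
  cfg <- genome$config
  f <- simulate_timecourse(genome$sites$truth_rate, cfg$timepoints,
                           noise = noise %||% cfg$noise,
                           coverage = coverage %||% cfg$coverage,
                           seed = seed %||% (cfg$seed + 1L),
                           f0 = f0 %||% cfg$f0)
  methyl_timecourse(genome$sites[, .(chrom, pos, motif, region, gene_id, offset)],
                    cfg$timepoints, f)
}
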