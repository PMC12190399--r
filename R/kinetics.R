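#' Per-site pseudo-first-order rate constants
#'
#' Fits `ln(1 - fraction) = -k * t + b` by ordinary least squares at every
#' site. Fractions above `cap` are set to `cap`, and of the points
#' exceeding `cap` only the first is retained (later saturated points are
#' dropped, not capped), avoiding saturation bias. Sites with fewer than
#' `min_points` usable observations are flagged unestimable (`k_app = NA`)
#' and excluded downstream. Natural logarithms throughout; `t = 0`
#' observations participate, with the intercept absorbing any background
#' methylation.
#'
#' @param timecourse a [methyl_timecourse()], or a sites x times fraction
#'   matrix (then `times` must be given).
#' @param times timepoints in minutes (ignored when `timecourse` is a
#'   `methyl_timecourse`).
#' @param cap saturation cap on fractions (0.99).
#' @param min_points minimum usable points for a defensible regression.
#' @return data.table with one row per site: `k_app` (per minute, the
#'   sign-flipped slope), `intercept_b`, `r2`, `n_used`, `capped`,
#'   `estimable`. Site identifiers are carried through when present.
#' @export
fit_first_order <- function(timecourse, times = NULL, cap = 0.99,
                            min_points = 3L) {
  if (inherits(timecourse, "methyl_timecourse")) {
    f <- timecourse$fractions
    times <- timecourse$times
    site_info <- timecourse$sites
  } else {
    f <- as.matrix(timecourse)
    if (is.null(times)) stop("times must be supplied with a plain matrix")
    site_info <- NULL
  }
  stopifnot(ncol(f) == length(times))

  over <- !is.na(f) & f > cap
  cum <- over
  if (ncol(f) > 1L)
    for (j in 2:ncol(f)) cum[, j] <- cum[, j - 1L] + over[, j]
  w <- (!is.na(f)) & (!over | (over & cum == 1L))  # keep first point > cap
  fc <- pmin(f, cap)
  y <- suppressWarnings(log1p(-fc))
  y[!w] <- 0
  wn <- w * 1

  n <- rowSums(wn)
  t1 <- as.numeric(times)
  Sx <- as.vector(wn %*% t1)
  Sxx <- as.vector(wn %*% t1^2)
  Sy <- rowSums(wn * y)
  Sxy <- as.vector((wn * y) %*% t1)
  Syy <- rowSums(wn * y^2)

  den <- Sxx - Sx^2 / n
  slope <- (Sxy - Sx * Sy / n) / den
  intercept <- Sy / n - slope * Sx / n
  sst <- Syy - Sy^2 / n
  ssr <- pmax(sst - slope^2 * den, 0)
  r2 <- ifelse(sst > 0, 1 - ssr / sst, NA_real_)

  estimable <- n >= min_points & is.finite(slope) & den > 0
  res <- data.table(
    k_app = ifelse(estimable, -slope, NA_real_),
    intercept_b = ifelse(estimable, intercept, NA_real_),
    r2 = ifelse(estimable, r2, NA_real_),
    n_used = as.integer(n),
    capped = rowSums(over) > 0L,
    estimable = estimable)
  if (!is.null(site_info)) res <- cbind(as.data.table(site_info), res)
  res[]
}

#' Mitochondrial internal-control reference rate
#'
#' The mtDNA is non-nucleosomal, so its methylation rate reflects enzyme
#' concentration rather than chromatin; dividing nuclear rates by this
#' reference cancels concentration differences between strains. Two modes:
#' the default takes the median of the per-site rate constants over mtDNA
#' sites; `"median_trajectory"` first takes the median mtDNA fraction at
#' each timepoint and fits the first-order model to that median time
#' course. The modes agree on homogeneous data.
#'
#' @param rates [fit_first_order()] output carrying a `region` column, or a
#'   numeric vector of mtDNA rate constants.
#' @param timecourse required for `mode = "median_trajectory"`.
#' @param mode `"site_median"` or `"median_trajectory"`.
#' @param mt_class region label identifying mtDNA sites.
#' @return reference rate constant (per minute).
#' @export
mtdna_reference <- function(rates, timecourse = NULL,
                            mode = c("site_median", "median_trajectory"),
                            mt_class = "mt") {
  mode <- match.arg(mode)
  if (mode == "median_trajectory") {
    if (is.null(timecourse)) stop("median_trajectory mode needs the time course")
    sel <- timecourse$sites$region == mt_class
    if (!any(sel)) stop("no mtDNA sites in time course")
    med <- apply(timecourse$fractions[sel, , drop = FALSE], 2,
                 median, na.rm = TRUE)
    fit <- fit_first_order(matrix(med, nrow = 1), times = timecourse$times)
    if (!fit$estimable[1]) stop("median mtDNA trajectory not estimable")
    return(fit$k_app[1])
  }
  if (is.data.frame(rates)) {
    if (!"region" %in% names(rates))
      stop("rates table needs a 'region' column to locate mtDNA sites")
    rr <- as.data.table(rates)
    k <- rr[region == mt_class & estimable == TRUE, k_app]
  } else k <- rates[is.finite(rates)]
  if (!length(k)) stop("no estimable mtDNA sites")
  median(k)
}

#' Genome-median reference rate
#'
#' Reference used for CG-mode (M.SssI) data: the median methylated fraction
#' over all sites of all chromosomes (mitochondrial and plasmid included)
#' is taken at each timepoint, and the first-order model is fitted to that
#' median trajectory.
#'
#' @param timecourse a [methyl_timecourse()].
#' @param cap,min_points passed to [fit_first_order()].
#' @return reference rate constant (per minute).
#' @export
genome_median_reference <- function(timecourse, cap = 0.99, min_points = 3L) {
  if (length(timecourse$times) < min_points)
    stop("genome-median reference needs at least min_points timepoints")
  med <- apply(timecourse$fractions, 2, median, na.rm = TRUE)
  fit <- fit_first_order(matrix(med, nrow = 1), times = timecourse$times,
                         cap = cap, min_points = min_points)
  if (!fit$estimable[1]) stop("median genome trajectory not estimable")
  fit$k_app[1]
}

#' Normalize rate constants to a reference
#'
#' @param rates [fit_first_order()] output (or numeric vector of rates).
#' @param reference_value reference rate constant, `> 0`.
#' @return for a table input, the table with a `ratio` column added;
#'   for a vector, the vector of ratios.
#' @export
normalize_rates <- function(rates, reference_value) {
  if (!is.finite(reference_value) || reference_value <= 0)
    stop("reference_value must be > 0")
  if (is.data.frame(rates)) {
    res <- copy(as.data.table(rates))
    res[, ratio := k_app / reference_value]
    return(res[])
  }
  rates / reference_value
}

#' Normalized-rate summary per region class
#'
#' @param norm_rates [normalize_rates()] table with `region` and `ratio`.
#' @param min_n classes with fewer estimable sites are omitted with a
#'   warning.
#' @return data.table: per region class the count, median, and quartiles
#'   of the normalized rate.
#' @export
region_rate_summary <- function(norm_rates, min_n = 1L) {
  dt <- as.data.table(norm_rates)[estimable == TRUE & is.finite(ratio)]
  out <- dt[, .(n = .N,
                q25 = quantile(ratio, 0.25, names = FALSE),
                median = median(ratio),
                q75 = quantile(ratio, 0.75, names = FALSE)),
            by = region][order(region)]
  small <- out[n < min_n, region]
  if (length(small)) {
    warning("omitting region class(es) with too few sites: ",
            paste(small, collapse = ", "))
    out <- out[n >= min_n]
  }
  out[]
}
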