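#' Decaying sine wave parameters
#'
#' Constructs the parameter set of the decaying sine wave model used to
#' describe nucleosome phasing profiles,
#' \deqn{y(x) = A e^{-\lambda x} \sin(\omega x + \theta) + k x + b,}
#' where `x` is the position in bp relative to the +1 nucleosome dyad.
#'
#' @param A initial amplitude at the +1 dyad (rate-ratio units), `A >= 0`.
#' @param lam exponential amplitude decay constant per bp, `lam >= 0`.
#' @param omega angular frequency per bp; the period `2*pi/omega` is the
#'   average nucleosome spacing.
#' @param theta phase in radians, wrapped into `(-pi, pi]`.
#' @param slope linear baseline slope `k` (rate-ratio per bp); `1000*slope`
#'   is the change in mean rate over 1 kb.
#' @param baseline baseline `b` at `x = 0` (rate-ratio units).
#' @return An object of class `sine_params` (named list).
#' @export
sine_params <- function(A, lam, omega, theta, slope, baseline) {
  stopifnot(is.finite(A), is.finite(lam), is.finite(omega),
            is.finite(theta), is.finite(slope), is.finite(baseline))
  if (A < 0) stop("amplitude A must be >= 0")
  if (lam < 0) stop("decay constant lam must be >= 0")
  if (omega <= 0) stop("angular frequency omega must be > 0")
  theta <- wrap_theta(theta)
  structure(list(A = A, lam = lam, omega = omega, theta = theta,
                 slope = slope, baseline = baseline),
            class = "sine_params")
}

wrap_theta <- function(theta) {
  th <- (theta + pi) %% (2 * pi) - pi
  if (th <= -pi) th <- th + 2 * pi
  th
}

#' @export
print.sine_params <- function(x, ...) {
  cat(sprintf(
    "decaying sine wave: A=%.4g lambda=%.4g/bp period=%.1f bp theta=%.3f rad slope=%.4g/bp baseline=%.4g\n",
    x$A, x$lam, 2 * pi / x$omega, x$theta, x$slope, x$baseline))
  invisible(x)
}

#' Evaluate the decaying sine wave model
#'
#' @param params a [sine_params()] object.
#' @param x numeric vector of offsets (bp from the +1 nucleosome dyad).
#' @return numeric vector of model values.
#' @export
sine_model_eval <- function(params, x) {
  params$A * exp(-params$lam * x) * sin(params$omega * x + params$theta) +
    params$slope * x + params$baseline
}

#' Mean of the fitted curve over integer offsets
#'
#' @param params a [sine_params()] object.
#' @param fit_range two integers; mean is taken over every integer offset in
#'   `[fit_range[1], fit_range[2]]` (1051 positions for the default window).
#' @export
sine_curve_mean <- function(params, fit_range = c(-50L, 1000L)) {
  mean(sine_model_eval(params, seq(fit_range[1], fit_range[2])))
}

#' Build model parameters from tabulated phasing descriptors
#'
#' Inverts the derived descriptors (spacing, per-period decay, slope per kb,
#' curve mean over the fitting window) back to raw model parameters. The
#' baseline enters the curve mean linearly, so it is solved exactly:
#' `baseline = adj_mean - mean(A e^(-lam x) sin(omega x + theta) + slope x)`.
#'
#' @param spacing_bp nucleosome spacing (model period), bp.
#' @param amplitude initial amplitude `A`.
#' @param decay_per_period proportional amplitude decrease after one period,
#'   `exp(-lam * spacing_bp)`, in (0, 1].
#' @param slope_per_kb change in mean rate over 1 kb (`1000 * slope`).
#' @param adj_mean target mean of the curve over integer offsets in
#'   `fit_range`.
#' @param theta phase; the default `-pi/2` puts a trough at the +1 dyad.
#' @param fit_range window over which `adj_mean` is defined.
#' @export
params_from_descriptors <- function(spacing_bp, amplitude, decay_per_period,
                                    slope_per_kb, adj_mean, theta = -pi / 2,
                                    fit_range = c(-50L, 1000L)) {
  stopifnot(spacing_bp > 0, decay_per_period > 0, decay_per_period <= 1)
  omega <- 2 * pi / spacing_bp
  lam <- -log(decay_per_period) / spacing_bp
  slope <- slope_per_kb / 1000
  x <- seq(fit_range[1], fit_range[2])
  varying <- mean(amplitude * exp(-lam * x) * sin(omega * x + theta) + slope * x)
  sine_params(A = amplitude, lam = lam, omega = omega, theta = theta,
              slope = slope, baseline = adj_mean - varying)
}

#' Adjusted coefficient of determination of a sine fit
#'
#' Standard adjusted R-squared for a 6-parameter model:
#' `1 - (SSR/SST) * (n - 1) / (n - 7)`. A perfect fit gives 1.
#'
#' @param quality list with `ssr`, `sst`, `n` (and `p`, fixed at 6).
#' @return adjusted R-squared; `NA` (with a warning) when `sst == 0`.
#' @export
adjusted_r2 <- function(quality) {
  p <- if (is.null(quality$p)) 6L else quality$p
  n <- quality$n
  if (n <= p + 1) stop("adjusted R2 requires n > p + 1 points")
  if (!is.finite(quality$sst) || quality$sst <= 0) {
    warning("total sum of squares is zero; adjusted R2 undefined")
    return(NA_real_)
  }
  1 - (quality$ssr / quality$sst) * (n - 1) / (n - p - 1)
}

sine_residual_fun <- function(x, y) {
  function(p) {
    p["A"] * exp(-p["lam"] * x) * sin(p["omega"] * x + p["theta"]) +
      p["slope"] * x + p["b"] - y
  }
}

sine_jacobian_fun <- function(x, y) {
  function(p) {
    e <- exp(-p["lam"] * x)
    arg <- p["omega"] * x + p["theta"]
    s <- sin(arg); co <- cos(arg)
    cbind(A     = e * s,
          lam   = -p["A"] * x * e * s,
          omega = p["A"] * x * e * co,
          theta = p["A"] * e * co,
          slope = x,
          b     = rep(1, length(x)))
  }
}

#' Fit the decaying sine wave model to a phasing profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) with a fixed deterministic multi-start grid over the
#' period (140-200 bp, step 5) and the phase (`-pi/2, 0, pi/2, pi`). The
#' period is constrained to `[120, 220]` bp during optimization, bracketing
#' all plausible nucleosome spacings with margin; `A >= 0` and `lam >= 0`
#' resolve the sign/phase ambiguity. The start with the lowest sum of
#' squared residuals wins; no randomness is involved, so refits are
#' bit-reproducible.
#'
#' @param offset,value profile points (typically per-offset mean normalized
#'   rates at integer offsets).
#' @param fit_range offsets outside `[fit_range[1], fit_range[2]]` are
#'   ignored.
#' @param period_grid,theta_grid multi-start grids.
#' @param period_bounds hard period bounds (bp) during optimization.
#' @param min_points minimum number of usable points.
#' @return `sine_fit` object: `params` ([sine_params()]), `quality`
#'   (`ssr`, `sst`, `n`, `p`), `fit_range`, and `data` (points used).
#' @export
fit_sine <- function(offset, value, fit_range = c(-50L, 1000L),
                     period_grid = seq(140, 200, by = 5),
                     theta_grid = c(-pi / 2, 0, pi / 2, pi),
                     period_bounds = c(120, 220),
                     min_points = 50L) {
  keep <- offset >= fit_range[1] & offset <= fit_range[2] & is.finite(value)
  x <- as.numeric(offset[keep]); y <- as.numeric(value[keep])
  if (length(x) < min_points)
    stop(sprintf("fit_sine needs >= %d points within the fit range (got %d)",
                 min_points, length(x)))
  sst <- sum((y - mean(y))^2)

  # linear part of the start: detrended residual scale seeds the amplitude
  lin <- stats::lm.fit(cbind(1, x), y)
  b0 <- lin$coefficients[1]; slope0 <- lin$coefficients[2]
  a0 <- max(stats::sd(lin$residuals) * sqrt(2), 1e-6)

  lower <- c(A = 0, lam = 0, omega = 2 * pi / period_bounds[2],
             theta = -pi, slope = -Inf, b = -Inf)
  upper <- c(A = Inf, lam = 0.05, omega = 2 * pi / period_bounds[1],
             theta = pi, slope = Inf, b = Inf)
  fn <- sine_residual_fun(x, y)
  jac <- sine_jacobian_fun(x, y)

  best <- NULL
  degenerate_tol <- max(1e-14 * max(sst, 1), 1e-24)
  for (p0 in period_grid) {
    for (th0 in theta_grid) {
      start <- c(A = unname(a0), lam = 0.0015, omega = 2 * pi / p0,
                 theta = th0, slope = unname(slope0), b = unname(b0))
      res <- tryCatch(
        minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                           fn = fn, jac = jac,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 300, ftol = 1e-14, ptol = 1e-14)),
        error = function(e) NULL)
      if (is.null(res)) next
      ssr <- res$deviance
      if (is.null(best) || ssr < best$deviance) best <- res
      if (!is.null(best) && best$deviance < degenerate_tol) break
    }
    if (!is.null(best) && best$deviance < degenerate_tol) break
  }
  if (is.null(best)) stop("sine fit failed from every start")

  p <- best$par
  if (p[["A"]] < 1e-8)
    warning("fitted amplitude ~ 0: profile is effectively a straight line")
  params <- sine_params(A = p[["A"]], lam = p[["lam"]], omega = p[["omega"]],
                        theta = wrap_theta(p[["theta"]]), slope = p[["slope"]],
                        baseline = p[["b"]])
  structure(list(
    params = params,
    quality = list(ssr = best$deviance, sst = sst, n = length(x), p = 6L),
    fit_range = fit_range,
    data = data.frame(offset = x, value = y)
  ), class = "sine_fit")
}

#' Derived phasing descriptors of a sine fit
#'
#' @param fit a `sine_fit` object (or a list with `params`, `quality`,
#'   `fit_range`).
#' @return list of class `sine_fit_derived`: `spacing_bp` (period),
#'   `amplitude`, `slope_per_kb`, `decay_per_period`
#'   (`exp(-lam * spacing)`; reported as 1 when `A ~ 0`, where the decay is
#'   undefined), `adj_mean_rate` (mean of the fitted curve over integer
#'   offsets in the fit range), `adj_r2`, `n_points`.
#' @export
derive_sine_fit <- function(fit) {
  pr <- fit$params
  spacing <- 2 * pi / pr$omega
  decay <- if (pr$A < 1e-8) 1 else exp(-pr$lam * spacing)
  structure(list(
    spacing_bp = spacing,
    amplitude = pr$A,
    slope_per_kb = 1000 * pr$slope,
    decay_per_period = decay,
    adj_mean_rate = sine_curve_mean(pr, fit$fit_range),
    adj_r2 = adjusted_r2(fit$quality),
    n_points = fit$quality$n
  ), class = "sine_fit_derived")
}

#' @export
print.sine_fit <- function(x, ...) {
  d <- derive_sine_fit(x)
  cat(sprintf(
    "decaying sine wave fit (%d points, offsets %d..%d)\n",
    x$quality$n, x$fit_range[1], x$fit_range[2]))
  cat(sprintf(
    "  spacing %.1f bp | amplitude %.2f | slope/kb %.2f | decay/period %.2f | adj mean %.2f | adj R2 %.2f\n",
    d$spacing_bp, d$amplitude, d$slope_per_kb, d$decay_per_period,
    d$adj_mean_rate, d$adj_r2))
  invisible(x)
}

#' @export
print.sine_fit_derived <- function(x, ...) {
  cat(sprintf(
    "spacing %.1f bp | amplitude %.2f | slope/kb %.2f | decay/period %.2f | adj mean %.2f | adj R2 %.2f (n=%d)\n",
    x$spacing_bp, x$amplitude, x$slope_per_kb, x$decay_per_period,
    x$adj_mean_rate, x$adj_r2, x$n_points))
  invisible(x)
}

#' Serialize a sine fit report to JSON
#'
#' @param fit a `sine_fit` object.
#' @param path output file.
#' @export
write_sine_fit_json <- function(fit, path) {
  d <- derive_sine_fit(fit)
  obj <- list(params = unclass(fit$params),
              derived = unclass(d),
              quality = fit$quality,
              fit_range = fit$fit_range)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
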