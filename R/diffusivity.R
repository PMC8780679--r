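#' Position autocovariance of a restrained window trace
#'
#' \eqn{C_{zz}(\tau) =} mean over time origins of
#' \eqn{(z(t)-\bar z)(z(t+\tau)-\bar z)} with biased (1/n) normalisation,
#' so that \eqn{C_{zz}(0)} equals the (population) variance of z exactly.
#' Computed via FFT (Wiener-Khinchin with zero padding).
#'
#' @param trace a `window_trace` with uniform time stride.
#' @param max_lag largest lag, ps; must not exceed half the trace duration.
#' @return object of class `acf_series`: `lags` (ps), `values` (nm^2),
#'   `n_origin` (trace length) and `dt` (sample stride, ps).
#' @export
autocorrelation <- function(trace, max_lag = 50) {
  z <- trace$z
  n <- length(z)
  dts <- diff(trace$times)
  if (max(abs(dts - dts[1])) > 1e-9 * dts[1])
    stop("trace must have a uniform time stride")
  dt <- dts[1]
  L <- floor(max_lag / dt + 1e-9)
  if (L > n %/% 2)
    stop("max_lag exceeds half the trace length")
  zc <- z - mean(z)
  m <- stats::nextn(2L * n)
  ft <- stats::fft(c(zc, rep(0, m - n)))
  ac <- Re(stats::fft(Mod(ft)^2, inverse = TRUE)) / m
  values <- ac[seq_len(L + 1L)] / n      # biased normalisation
  structure(list(lags = dt * (0:L), values = values,
                 n_origin = n, dt = dt),
            class = "acf_series")
}

#' Integrate an autocovariance series
#'
#' Trapezoidal integral of \eqn{C_{zz}(\tau)} from lag 0. The infinite
#' upper limit of the underlying estimator is handled by truncation:
#' with `rule = "first_zero"` (default) the integral stops at the first
#' non-positive ACF value (included as the final trapezoid endpoint),
#' the usual bias/variance compromise for noisy ACF tails; with
#' `rule = "full"` the whole tabulated range is integrated.
#'
#' @param acf an `acf_series`.
#' @param rule `"first_zero"` or `"full"`.
#' @return the integral in nm^2 ps, with attribute `truncation_lag` (ps).
#' @export
integrate_acf <- function(acf, rule = c("first_zero", "full")) {
  rule <- match.arg(rule)
  v <- acf$values
  if (v[1] <= 0) stop("ACF must be positive at lag 0")
  iend <- length(v)
  if (rule == "first_zero") {
    nz <- which(v <= 0)
    if (length(nz)) iend <- nz[1]
  }
  lags <- acf$lags[seq_len(iend)]
  vv <- v[seq_len(iend)]
  val <- if (iend == 1L) 0 else
    sum(diff(lags) * (vv[-1] + vv[-iend]) / 2)
  attr(val, "truncation_lag") <- lags[iend]
  val
}

#' Local diffusion coefficient from one restrained window
#'
#' Variance/autocorrelation estimator for a harmonically restrained
#' coordinate:
#' \deqn{D = \frac{\mathrm{var}(z)^2}{\int_0^\infty C_{zz}(t)\,dt},}
#' i.e. the squared fluctuation amplitude over the integrated position
#' autocovariance. The estimate is anchored at the window's sample-mean
#' position (where the fluctuations were actually measured), not at the
#' bias centre.
#'
#' @inheritParams autocorrelation
#' @inheritParams integrate_acf
#' @return list with `z_mean` (nm), `D` (nm^2/ps), `var` (nm^2),
#'   `acf_integral` (nm^2 ps) and `truncation_lag` (ps).
#' @export
window_diffusivity <- function(trace, max_lag = 50,
                               rule = c("first_zero", "full")) {
  rule <- match.arg(rule)
  ac <- autocorrelation(trace, max_lag)
  I <- integrate_acf(ac, rule)
  if (I <= 0)
    stop("non-positive ACF integral: sampling inadequate for this window")
  v <- ac$values[1]
  list(z_mean = mean(trace$z), D = v^2 / as.numeric(I), var = v,
       acf_integral = as.numeric(I),
       truncation_lag = attr(I, "truncation_lag"))
}

#' Assemble a position-dependent diffusivity profile
#'
#' Per-window estimates ([window_diffusivity()]) are linearly interpolated
#' onto the PMF grid, with constant extrapolation beyond the outermost
#' window means. For `side = "cancer"` the one-leaflet estimates are
#' mirrored about z = 0 first, the same duplication convention used for
#' the symmetric-membrane PMF.
#'
#' @param traces list of `window_trace` (>= 2 windows).
#' @param pmf_grid z grid (nm) the profile is evaluated on.
#' @param side `"full"` (use windows as-is) or `"cancer"` (mirror the
#'   z <= 0 leaflet's estimates about the core).
#' @inheritParams window_diffusivity
#' @return object of class `diffusivity_profile`: `z`, `D` and the
#'   per-window estimate table in `windows`.
#' @export
diffusivity_profile <- function(traces, pmf_grid,
                                side = c("full", "cancer"),
                                max_lag = 50, rule = "first_zero") {
  side <- match.arg(side)
  if (length(traces) < 2L) stop("need at least two windows")
  est <- lapply(seq_along(traces), function(i) {
    tryCatch(window_diffusivity(traces[[i]], max_lag, rule),
             error = function(e) stop(sprintf("window %d: %s", i,
                                              conditionMessage(e)),
                                      call. = FALSE))
  })
  wtab <- data.frame(
    window = seq_along(est),
    z_mean = vapply(est, `[[`, numeric(1), "z_mean"),
    var = vapply(est, `[[`, numeric(1), "var"),
    acf_integral = vapply(est, `[[`, numeric(1), "acf_integral"),
    D = vapply(est, `[[`, numeric(1), "D"))
  pts_z <- wtab$z_mean
  pts_D <- wtab$D
  if (side == "cancer") {
    pts_z <- c(pts_z, -pts_z)
    pts_D <- c(pts_D, pts_D)
  }
  ord <- order(pts_z)
  D <- stats::approx(pts_z[ord], pts_D[ord], xout = pmf_grid,
                     rule = 2, ties = mean)$y
  structure(list(z = pmf_grid, D = D, windows = wtab, side = side,
                 max_lag = max_lag, rule = rule),
            class = "diffusivity_profile")
}

#' @export
print.diffusivity_profile <- function(x, ...) {
  cat(sprintf("<diffusivity_profile (%s): %d grid points, %d windows, D in [%.3g, %.3g] nm^2/ps>\n",
              x$side, length(x$z), nrow(x$windows), min(x$D), max(x$D)))
  invisible(x)
}
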