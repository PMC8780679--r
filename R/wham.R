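#' Bin umbrella-window traces into a shared histogram set
#'
#' All windows are binned on one common grid of half-open bins
#' `[edge_i, edge_{i+1})`. Samples outside `range` are not binned; their
#' fraction is reported as the `overflow_fraction` attribute and a warning
#' is raised when it reaches 1%, since WHAM then no longer sees all data.
#'
#' @param traces list of `window_trace` objects.
#' @param bin_width bin width, nm.
#' @param range numeric length-2, the binning range `[z_lo, z_hi]` in nm.
#' @return object of class `histogram_set`: bin edges/midpoints, a
#'   windows x bins count matrix, per-window totals and bias metadata.
#' @export
build_histograms <- function(traces, bin_width = 0.02, range = c(-2.2, 2.2)) {
  if (length(traces) == 0L) stop("no traces supplied")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (range[2] <= range[1]) stop("zero-width range")
  n_bins <- round((range[2] - range[1]) / bin_width)
  if (n_bins < 1L) stop("range narrower than one bin")
  edges <- range[1] + bin_width * (0:n_bins)
  counts <- matrix(0L, nrow = length(traces), ncol = n_bins)
  n_in <- n_total <- numeric(length(traces))
  for (i in seq_along(traces)) {
    z <- traces[[i]]$z
    idx <- findInterval(z, edges)          # [edge_i, edge_{i+1}) half-open
    keep <- idx >= 1L & idx <= n_bins & z < edges[n_bins + 1L]
    counts[i, ] <- tabulate(idx[keep], nbins = n_bins)
    n_in[i] <- sum(keep)
    n_total[i] <- length(z)
  }
  overflow <- 1 - sum(n_in) / sum(n_total)
  if (overflow >= 0.01)
    warning(sprintf("%.2f%% of samples fall outside the histogram range",
                    100 * overflow))
  structure(list(
    bin_edges = edges,
    mids = edges[-length(edges)] + bin_width / 2,
    bin_width = bin_width,
    counts = counts,
    n_samples = n_in,
    centers = vapply(traces, function(tr) tr$center, numeric(1)),
    force_constant = vapply(traces, function(tr) tr$force_constant, numeric(1)),
    overflow_fraction = overflow),
    class = "histogram_set")
}

pmf_profile <- function(z, dG, stderr = NULL, reference = "raw",
                        side = "full", smoothed = FALSE,
                        temperature = 310, bin_width = NA_real_,
                        extra = list()) {
  structure(c(list(z = z, dG = dG, stderr = stderr, reference = reference,
                   side = side, smoothed = smoothed,
                   temperature = temperature, bin_width = bin_width),
              extra),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("<pmf_profile (%s, %s%s): %d bins on [%.3g, %.3g] nm>\n",
              x$side, x$reference, if (x$smoothed) ", smoothed" else "",
              length(x$z), min(x$z), max(x$z)))
  invisible(x)
}

#' Solve the WHAM equations for an unbiased free-energy profile
#'
#' Direct iteration of the standard coupled equations for umbrella
#' sampling with harmonic biases \eqn{w_i(z) = k_i/2 (z - c_i)^2}:
#' \deqn{\rho(z_b) = \frac{\sum_i n_i(z_b)}
#'       {\sum_i N_i f_i e^{-\beta w_i(z_b)}}, \qquad
#'       f_i^{-1} = \sum_b \rho(z_b) e^{-\beta w_i(z_b)} \Delta z,}
#' iterated until the largest change in the window free energies
#' \eqn{-RT \ln f_i} between sweeps falls below `tol`. The profile is
#' \eqn{\Delta G(z_b) = -RT \ln \rho(z_b)}, reported "raw" (arbitrary
#' additive constant; see [reference_to_bulk()]). Bins with zero total
#' count are masked (NA) rather than interpolated.
#'
#' @param hist a [build_histograms()] result.
#' @param temperature temperature, K.
#' @param tol convergence threshold on the window free energies, kJ/mol.
#' @param max_iter iteration cap; non-convergence raises a warning and is
#'   flagged in the returned profile's `converged` field.
#' @param side leaflet label carried into the profile
#'   ("outer", "inner" or "full").
#' @return a `pmf_profile` with fields `iterations`, `converged`,
#'   `window_free_energies` and a logical `mask` of usable bins.
#' @export
solve_wham <- function(hist, temperature = 310, tol = 1e-7,
                       max_iter = 1e5, side = "full") {
  stopifnot(inherits(hist, "histogram_set"))
  mids <- hist$mids
  counts <- hist$counts                  # windows x bins
  total <- colSums(counts)
  mask <- total > 0
  if (!any(mask)) stop("all histogram bins are empty")
  N <- hist$n_samples
  dz <- hist$bin_width
  beta <- 1 / (RGAS * temperature)
  # bias Boltzmann factors, bins x windows
  bias <- 0.5 * outer(mids, hist$centers, "-")^2 *
    rep(hist$force_constant, each = length(mids))
  expw <- exp(-beta * bias)
  f <- rep(1, length(N))
  Fi <- numeric(length(N))
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    denom <- as.vector(expw %*% (N * f))
    rho <- ifelse(mask, total / pmax(denom, .Machine$double.xmin), 0)
    rho <- rho / (sum(rho) * dz)          # fix the gauge: unit integral
    finv <- as.vector(crossprod(expw, rho)) * dz
    f_new <- 1 / finv
    Fi_new <- -RGAS * temperature * log(f_new)
    if (max(abs(Fi_new - Fi)) < tol) {
      f <- f_new; Fi <- Fi_new; converged <- TRUE; break
    }
    f <- f_new; Fi <- Fi_new
  }
  if (!converged)
    warning(sprintf("WHAM did not converge in %d iterations (tol %g kJ/mol)",
                    as.integer(max_iter), tol))
  denom <- as.vector(expw %*% (N * f))
  rho <- ifelse(mask, total / pmax(denom, .Machine$double.xmin), NA_real_)
  rho <- rho / (sum(rho[mask]) * dz)
  dG <- -RGAS * temperature * log(rho)
  pmf_profile(mids, dG, reference = "raw", side = side,
              temperature = temperature, bin_width = dz,
              extra = list(mask = mask, iterations = it,
                           converged = converged,
                           window_free_energies = Fi))
}

#' Zero-reference a PMF to its bulk-water region
#'
#' Subtracts the mean free energy over the declared bulk region so that
#' \eqn{\Delta G = 0} in bulk solvent. Idempotent.
#'
#' @param pmf a `pmf_profile`.
#' @param bulk_region either a numeric length-2 interval `[z_a, z_b]` or a
#'   list of such intervals (e.g. both bulk flanks of a full profile).
#'   The default takes |z| >= 2.0 nm as bulk.
#' @return the referenced `pmf_profile` (`reference = "bulk-zeroed"`).
#' @export
reference_to_bulk <- function(pmf, bulk_region = list(c(-2.2, -2.0), c(2.0, 2.2))) {
  stopifnot(inherits(pmf, "pmf_profile"))
  if (is.numeric(bulk_region)) bulk_region <- list(bulk_region)
  in_bulk <- Reduce(`|`, lapply(bulk_region, function(iv) {
    pmf$z >= min(iv) & pmf$z <= max(iv)
  }))
  usable <- in_bulk & !is.na(pmf$dG)
  if (!any(usable)) stop("bulk region does not overlap any populated bins")
  shift <- mean(pmf$dG[usable])
  pmf$dG <- pmf$dG - shift
  pmf$reference <- "bulk-zeroed"
  pmf$bulk_region <- bulk_region
  pmf
}

#' Moving-average smoothing of a PMF
#'
#' Centred moving average: each grid point is replaced by the mean of all
#' unmasked points within +/- span/2 (default span 0.05 nm, i.e. 0.5
#' Angstrom). The window is truncated, not padded, at the profile ends.
#'
#' @param pmf a `pmf_profile`.
#' @param span averaging span, nm; must be at least one bin wide.
#' @return the smoothed profile (`smoothed = TRUE`).
#' @export
smooth_pmf <- function(pmf, span = 0.05) {
  stopifnot(inherits(pmf, "pmf_profile"))
  bw <- if (is.na(pmf$bin_width)) min(diff(pmf$z)) else pmf$bin_width
  if (span < bw) stop("smoothing span is smaller than one bin")
  half <- span / 2 + 1e-12
  z <- pmf$z; g <- pmf$dG
  out <- vapply(seq_along(z), function(i) {
    sel <- abs(z - z[i]) <= half & !is.na(g)
    if (!any(sel)) return(NA_real_)
    mean(g[sel])
  }, numeric(1))
  out[is.na(g)] <- NA_real_               # masked bins stay masked
  pmf$dG <- out
  pmf$smoothed <- TRUE
  pmf$smoothing_span <- span
  pmf
}

#' Mirror-duplicate a one-leaflet PMF into a full symmetric profile
#'
#' For a bilayer with identical leaflet compositions the PMF of one
#' leaflet (bulk to core, z in [-L, 0]) is duplicated to the other by
#' reflection: \eqn{\Delta G(+z) = \Delta G(-z)}.
#'
#' @param half a `pmf_profile` on negative z reaching the core (its last
#'   grid point within one bin of z = 0).
#' @return a full `pmf_profile` on the mirrored grid, exactly symmetric.
#' @export
symmetrize_cancer <- function(half) {
  stopifnot(inherits(half, "pmf_profile"))
  bw <- if (is.na(half$bin_width)) min(diff(half$z)) else half$bin_width
  if (max(half$z) < -bw)
    stop("half profile does not reach the membrane core (z = 0)")
  neg <- half$z < 0
  z_neg <- half$z[neg]; g_neg <- half$dG[neg]
  has_zero <- any(abs(half$z) < bw / 4)
  z_full <- c(z_neg, if (has_zero) 0, rev(-z_neg))
  g_full <- c(g_neg, if (has_zero) half$dG[abs(half$z) < bw / 4][1], rev(g_neg))
  pmf_profile(z_full, g_full, reference = half$reference, side = "full",
              smoothed = half$smoothed, temperature = half$temperature,
              bin_width = bw,
              extra = list(assembly = "mirror-duplicated"))
}

#' Join independently sampled leaflet PMFs into one full profile
#'
#' The outer- and inner-leaflet profiles, each bulk-referenced on its own
#' side, are concatenated; the inner half is shifted additively so the two
#' agree at the core (z = 0). The applied shift is reported in the result
#' as `core_mismatch` — a diagnostic of how consistently the two
#' independent samplings located the core free energy.
#'
#' @param outer `pmf_profile` on z <= 0, bulk-referenced.
#' @param inner `pmf_profile` on z >= 0, bulk-referenced.
#' @return a full `pmf_profile`; field `core_mismatch` holds
#'   outer(0) - inner(0) before shifting.
#' @export
join_normal_leaflets <- function(outer, inner) {
  stopifnot(inherits(outer, "pmf_profile"), inherits(inner, "pmf_profile"))
  if (!identical(outer$reference, "bulk-zeroed") ||
      !identical(inner$reference, "bulk-zeroed"))
    stop("both leaflet profiles must be bulk-referenced before joining")
  bw <- if (is.na(outer$bin_width)) min(diff(outer$z)) else outer$bin_width
  if (max(outer$z) < -bw || min(inner$z) > bw)
    stop("leaflet profiles do not meet at the core (z = 0)")
  io <- which.max(outer$z)
  ii <- which.min(inner$z)
  if (is.na(outer$dG[io]) || is.na(inner$dG[ii]))
    stop("core bins are masked; cannot join leaflets")
  mismatch <- outer$dG[io] - inner$dG[ii]
  g_in <- inner$dG + mismatch
  pmf_profile(c(outer$z, inner$z), c(outer$dG, g_in),
              reference = "bulk-zeroed", side = "full",
              smoothed = outer$smoothed && inner$smoothed,
              temperature = outer$temperature, bin_width = bw,
              extra = list(assembly = "leaflets-joined",
                           core_mismatch = mismatch))
}

#' Check PMF convergence over cumulative sampling intervals
#'
#' Re-estimates the (bulk-referenced) PMF from cumulative fractions of
#' every window's data (by default 50%, 75%, 100%) and reports the largest
#' absolute change between successive estimates over shared populated
#' bins. Small final deltas indicate the profile no longer drifts with
#' more sampling.
#'
#' @param traces list of `window_trace`.
#' @param n_intervals number of cumulative slices (>= 2).
#' @param bin_width,range,temperature,tol,max_iter passed to
#'   [build_histograms()] / [solve_wham()].
#' @param bulk_region passed to [reference_to_bulk()].
#' @param threshold convergence threshold on the final delta, kJ/mol.
#' @return list with `fractions`, `deltas` (length n_intervals - 1),
#'   `converged` flag and the per-slice profiles.
#' @export
check_convergence <- function(traces, n_intervals = 3,
                              bin_width = 0.02, range = c(-2.2, 2.2),
                              temperature = 310, tol = 1e-7, max_iter = 1e5,
                              bulk_region = list(c(-2.2, -2.0), c(2.0, 2.2)),
                              threshold = 1.0) {
  if (n_intervals < 2) stop("n_intervals must be at least 2")
  fractions <- seq(0.5, 1, length.out = n_intervals)
  profiles <- lapply(fractions, function(f) {
    sliced <- lapply(traces, function(tr) {
      n <- max(1L, floor(length(tr$z) * f))
      window_trace(tr$times[seq_len(n)], tr$z[seq_len(n)], tr$center,
                   tr$force_constant, tr$temperature, tr$seed)
    })
    h <- build_histograms(sliced, bin_width, range)
    if (sum(colSums(h$counts) > 0) < 2L)
      stop("slice too short to populate the histogram")
    reference_to_bulk(solve_wham(h, temperature, tol, max_iter), bulk_region)
  })
  deltas <- vapply(seq_len(n_intervals - 1L), function(i) {
    a <- profiles[[i]]; b <- profiles[[i + 1L]]
    ok <- !is.na(a$dG) & !is.na(b$dG)
    max(abs(a$dG[ok] - b$dG[ok]))
  }, numeric(1))
  list(fractions = fractions, deltas = deltas,
       converged = deltas[length(deltas)] < threshold,
       profiles = profiles)
}

#' Per-bin PMF standard error by block averaging
#'
#' Splits every window trace into `n_blocks` contiguous blocks, solves
#' WHAM on each block independently (bulk-referenced) and reports the
#' standard error of the per-bin free energies across blocks.
#'
#' @inheritParams check_convergence
#' @param pmf the full-data profile the errors attach to.
#' @param n_blocks number of contiguous blocks per window.
#' @return `pmf` with its `stderr` field filled (NA where any block left
#'   the bin unpopulated).
#' @export
pmf_block_stderr <- function(pmf, traces, n_blocks = 5,
                             bin_width = 0.02, range = c(-2.2, 2.2),
                             temperature = 310, tol = 1e-7, max_iter = 1e5,
                             bulk_region = list(c(-2.2, -2.0), c(2.0, 2.2))) {
  stopifnot(inherits(pmf, "pmf_profile"), n_blocks >= 2)
  block_dG <- sapply(seq_len(n_blocks), function(b) {
    sliced <- lapply(traces, function(tr) {
      n <- length(tr$z)
      idx <- seq.int(floor((b - 1) * n / n_blocks) + 1L,
                     floor(b * n / n_blocks))
      window_trace(tr$times[idx], tr$z[idx], tr$center,
                   tr$force_constant, tr$temperature, tr$seed)
    })
    h <- build_histograms(sliced, bin_width, range)
    p <- reference_to_bulk(solve_wham(h, temperature, tol, max_iter),
                           bulk_region)
    p$dG
  })
  pmf$stderr <- apply(block_dG, 1, stats::sd) / sqrt(n_blocks)
  pmf
}
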