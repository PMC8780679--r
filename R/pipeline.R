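#' Pipeline run configuration
#'
#' All tunable parameters of the trace -> PMF -> D(z) -> permeability
#' pipeline, with the package defaults: WHAM bin width 0.02 nm,
#' tolerance 1e-7 kJ/mol, bulk region |z| >= 2.0 nm, moving-average span
#' 0.05 nm (0.5 Angstrom), ISD integration bounds the full sampled span,
#' ACF truncation at the first zero crossing with a 50 ps maximum lag.
#'
#' @param temperature temperature, K.
#' @param bin_width WHAM bin width, nm.
#' @param wham_tol,wham_max_iter WHAM convergence settings (kJ/mol, count).
#' @param smoothing_span moving-average span, nm (0 disables smoothing).
#' @param bulk_edge |z| beyond which the profile is treated as bulk, nm.
#' @param z1,z2 resistivity integration bounds, nm.
#' @param max_lag,acf_rule ACF settings for [window_diffusivity()].
#' @param membrane_mode `"cancer"` (symmetric bilayer: sample one leaflet,
#'   mirror-duplicate) or `"normal"` (asymmetric: sample both leaflets
#'   independently and join at the core).
#' @param support sampled z span, nm.
#' @param use_smoothed_pmf feed the smoothed PMF (not the raw one) into
#'   the resistivity integrand.
#' @return object of class `run_config`.
#' @export
run_config <- function(temperature = 310, bin_width = 0.02,
                       wham_tol = 1e-7, wham_max_iter = 1e5,
                       smoothing_span = 0.05, bulk_edge = 2.0,
                       z1 = -2.2, z2 = 2.2,
                       max_lag = 50, acf_rule = "first_zero",
                       membrane_mode = c("cancer", "normal"),
                       support = c(-2.2, 2.2),
                       use_smoothed_pmf = TRUE) {
  membrane_mode <- match.arg(membrane_mode)
  stopifnot(temperature > 0, bin_width > 0, wham_tol > 0,
            smoothing_span >= 0, bulk_edge > 0, z1 < z2, max_lag > 0)
  structure(list(temperature = temperature, bin_width = bin_width,
                 wham_tol = wham_tol, wham_max_iter = wham_max_iter,
                 smoothing_span = smoothing_span, bulk_edge = bulk_edge,
                 z1 = z1, z2 = z2, max_lag = max_lag, acf_rule = acf_rule,
                 membrane_mode = membrane_mode, support = support,
                 use_smoothed_pmf = use_smoothed_pmf),
            class = "run_config")
}

# WHAM + referencing + smoothing for one leaflet, cut to its own half
leaflet_pmf <- function(traces, config, side) {
  sup <- config$support
  # histogram range extends past the core so bias spill-over is not lost
  range <- if (side == "outer") c(sup[1], min(0.5, sup[2]))
           else c(max(-0.5, sup[1]), sup[2])
  bulk <- if (side == "outer") list(c(sup[1], -config$bulk_edge))
          else list(c(config$bulk_edge, sup[2]))
  h <- build_histograms(traces, config$bin_width, range)
  p <- solve_wham(h, config$temperature, config$wham_tol,
                  config$wham_max_iter, side = side)
  p <- reference_to_bulk(p, bulk)
  if (config$smoothing_span > 0) p <- smooth_pmf(p, config$smoothing_span)
  keep <- if (side == "outer") p$z < 0 else p$z > 0
  pmf_profile(p$z[keep], p$dG[keep], reference = p$reference, side = side,
              smoothed = p$smoothed, temperature = p$temperature,
              bin_width = p$bin_width)
}

#' Run the full permeability pipeline on umbrella-window traces
#'
#' Executes histogramming, WHAM, bulk referencing, moving-average
#' smoothing, leaflet assembly (mirror duplication in `"cancer"` mode,
#' independent-leaflet joining in `"normal"` mode), window-wise diffusivity
#' estimation, resistivity integration and unit conversion to a
#' permeability coefficient in cm/s. Deterministic given the input traces.
#'
#' @param traces list of `window_trace`.
#' @param sides character vector, `"outer"`/`"inner"` tag per trace
#'   (defaults to the sign of each window's bias centre).
#' @param config a [run_config()].
#' @return list with `pmf`, `diffusivity`, `resistivity`, `result`
#'   (a `permeability_result`) and `config`.
#' @export
run_pipeline <- function(traces, config = run_config(), sides = NULL) {
  stopifnot(inherits(config, "run_config"), length(traces) >= 2L)
  if (is.null(sides))
    sides <- ifelse(vapply(traces, `[[`, numeric(1), "center") <= 0,
                    "outer", "inner")
  stage <- "wham"
  res <- tryCatch({
    if (config$membrane_mode == "cancer") {
      outer_traces <- traces[sides == "outer"]
      if (length(outer_traces) < 2L)
        stop("cancer mode needs the outer-leaflet (z <= 0) windows")
      half <- leaflet_pmf(outer_traces, config, "outer")
      pmf <- symmetrize_cancer(half)
      stage <- "diffusivity"
      dp <- diffusivity_profile(outer_traces, pmf$z, side = "cancer",
                                max_lag = config$max_lag,
                                rule = config$acf_rule)
    } else {
      outer_traces <- traces[sides == "outer"]
      inner_traces <- traces[sides == "inner"]
      if (length(outer_traces) < 2L || length(inner_traces) < 2L)
        stop("normal mode needs windows on both leaflets")
      pmf <- join_normal_leaflets(leaflet_pmf(outer_traces, config, "outer"),
                                  leaflet_pmf(inner_traces, config, "inner"))
      stage <- "diffusivity"
      dp <- diffusivity_profile(traces, pmf$z, side = "full",
                                max_lag = config$max_lag,
                                rule = config$acf_rule)
    }
    stage <- "resistivity"
    rp <- resistivity_profile(pmf, dp, config$temperature)
    stage <- "permeability"
    z1 <- max(config$z1, min(rp$z))
    z2 <- min(config$z2, max(rp$z))
    R_eff <- effective_resistivity(rp, z1, z2)
    result <- permeability(R_eff, z1, z2, config$temperature)
    list(pmf = pmf, diffusivity = dp, resistivity = rp,
         result = result, config = config)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' Simulate an umbrella study and analyse it end-to-end
#'
#' Convenience wrapper: generates the window traces the membrane mode
#' requires (one leaflet for `"cancer"`, both for `"normal"`) with
#' [simulate_protocol()], then runs [run_pipeline()].
#'
#' @param landscape,diffusivity the ground-truth landscape pair.
#' @param protocol an [umbrella_protocol()]; in cancer mode only its
#'   centres <= 0 are simulated.
#' @param config a [run_config()].
#' @return the [run_pipeline()] result, plus `traces`, `manifest` and the
#'   ground truth inputs.
#' @export
run_synthetic_study <- function(landscape, diffusivity,
                                protocol = umbrella_protocol(),
                                config = run_config()) {
  centers <- protocol$window_centers
  if (config$membrane_mode == "cancer") {
    keep <- centers <= 0
    protocol$window_centers <- centers[keep]
  }
  sim <- simulate_protocol(landscape, diffusivity, protocol)
  out <- run_pipeline(sim$traces, config, sides = sim$manifest$side)
  out$traces <- sim$traces
  out$manifest <- sim$manifest
  out$truth <- list(landscape = landscape, diffusivity = diffusivity)
  out
}
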