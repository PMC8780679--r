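#' Umbrella-sampling protocol
#'
#' Bundles the window layout and integrator settings of a synthetic
#' umbrella-sampling run. The defaults mirror a typical solute-permeation
#' protocol: 22 harmonic windows spaced 0.2 nm along the bilayer normal,
#' force constant 100 kJ/mol/nm^2, 310 K, with the first 20% of each
#' window discarded as equilibration.
#'
#' @param window_centers window bias centres, nm, sorted ascending.
#' @param force_constant harmonic bias force constant, kJ/mol/nm^2.
#' @param temperature temperature, K.
#' @param dt integration time step, ps.
#' @param n_steps number of integration steps per window.
#' @param discard_fraction fraction of initial steps dropped (in [0, 1)).
#' @param save_stride steps between saved samples.
#' @param base_seed integer; window i uses seed `base_seed + i`.
#' @return object of class `umbrella_protocol`.
#' @export
umbrella_protocol <- function(window_centers = seq(-2.1, 2.1, by = 0.2),
                              force_constant = 100,
                              temperature = 310,
                              dt = 0.01,
                              n_steps = 2e5,
                              discard_fraction = 0.2,
                              save_stride = 10L,
                              base_seed = 1L) {
  if (is.unsorted(window_centers, strictly = TRUE))
    stop("window_centers must be sorted strictly ascending")
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must lie in [0, 1)")
  if (dt <= 0) stop("dt must be positive")
  if (force_constant <= 0) stop("force_constant must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(window_centers = as.numeric(window_centers),
                 force_constant = force_constant,
                 temperature = temperature,
                 dt = dt, n_steps = as.integer(n_steps),
                 discard_fraction = discard_fraction,
                 save_stride = as.integer(save_stride),
                 base_seed = as.integer(base_seed)),
            class = "umbrella_protocol")
}

#' @export
print.umbrella_protocol <- function(x, ...) {
  cat(sprintf(paste0("<umbrella_protocol: %d windows [%g, %g] nm, ",
                     "k = %g kJ/mol/nm^2, T = %g K>\n"),
              length(x$window_centers), min(x$window_centers),
              max(x$window_centers), x$force_constant, x$temperature))
  invisible(x)
}

window_trace <- function(times, z, center, force_constant, temperature,
                         seed = NA_integer_) {
  structure(list(times = times, z = z, center = center,
                 force_constant = force_constant,
                 temperature = temperature, seed = seed),
            class = "window_trace")
}

#' @export
print.window_trace <- function(x, ...) {
  cat(sprintf("<window_trace: %d samples, center %.3g nm, k = %g, seed %s>\n",
              length(x$z), x$center, x$force_constant,
              ifelse(is.na(x$seed), "NA", as.character(x$seed))))
  invisible(x)
}

# tabulate forces/diffusivity on a fine uniform grid for the C++ integrator
landscape_tables <- function(landscape, diffusivity, dz = 0.001) {
  sup <- landscape$support
  grid <- seq(sup[1], sup[2], by = dz)
  list(grid = grid,
       grad_g = landscape$gradient(grid),
       d_val = diffusivity$value(grid),
       d_grad = diffusivity$gradient(grid))
}

#' Simulate one umbrella window by overdamped Langevin dynamics
#'
#' Integrates the Ito SDE
#' \deqn{dz = [-\beta D(z) (\Delta G'(z) + k(z - c)) + D'(z)]\,dt
#'       + \sqrt{2 D(z)\,dt}\,\xi}
#' with Euler-Maruyama steps and reflecting boundaries at the support
#' edges. The spurious-drift term \eqn{D'(z)} is included so that the
#' stationary density is the Boltzmann law of the biased potential even
#' when D depends on position. The window is initialised at its bias
#' centre; the first `discard_fraction` of steps is dropped and the rest
#' saved every `save_stride` steps.
#'
#' @param landscape an [energy_landscape()].
#' @param diffusivity a [diffusivity_model()].
#' @param center harmonic bias centre, nm; must lie inside the support.
#' @param protocol an [umbrella_protocol()].
#' @param window_index integer; the RNG seed is
#'   `protocol$base_seed + window_index`.
#' @param spurious_drift include the \eqn{D'(z)} drift (default TRUE;
#'   FALSE only to demonstrate the sampling bias its omission causes).
#' @return a `window_trace` with uniformly strided times (ps) and
#'   positions (nm).
#' @export
simulate_window <- function(landscape, diffusivity, center, protocol,
                            window_index = 0L, spurious_drift = TRUE) {
  stopifnot(inherits(landscape, "energy_landscape"),
            inherits(diffusivity, "diffusivity_model"),
            inherits(protocol, "umbrella_protocol"))
  sup <- landscape$support
  if (center < sup[1] || center > sup[2])
    stop(sprintf("bias center %.3g nm outside the landscape support", center))
  tab <- landscape_tables(landscape, diffusivity)
  if (any(tab$d_val <= 0)) stop("diffusivity must be positive everywhere")
  beta <- 1 / (RGAS * protocol$temperature)
  # explicit Euler stability guard for the biased harmonic relaxation
  if (protocol$dt * max(tab$d_val) * beta * protocol$force_constant >= 0.1)
    stop("time step too large: dt * D * beta * k must be < 0.1")
  n_discard <- floor(protocol$n_steps * protocol$discard_fraction)
  seed <- protocol$base_seed + as.integer(window_index)
  set.seed(seed)
  z <- langevin_window_cpp(tab$grid, tab$grad_g, tab$d_val, tab$d_grad,
                           z0 = center, center = center,
                           force_constant = protocol$force_constant,
                           beta = beta, dt = protocol$dt,
                           n_steps = protocol$n_steps,
                           n_discard = n_discard,
                           save_stride = protocol$save_stride,
                           zmin = sup[1], zmax = sup[2],
                           spurious_drift = spurious_drift)
  dt_save <- protocol$dt * protocol$save_stride
  times <- (n_discard * protocol$dt) + dt_save * seq_along(z)
  window_trace(times, z, center, protocol$force_constant,
               protocol$temperature, seed)
}

#' Simulate a full umbrella-sampling protocol
#'
#' One [simulate_window()] run per bias centre with independent,
#' reproducible seeds (`base_seed + window_index`). Windows with centre
#' <= 0 are tagged as belonging to the outer leaflet, centre > 0 to the
#' inner leaflet.
#'
#' @inheritParams simulate_window
#' @return list with `traces` (list of `window_trace`) and `manifest`
#'   (data.frame with columns window_id, center_nm,
#'   force_constant_kj_mol_nm2, seed, trace_path, side).
#' @export
simulate_protocol <- function(landscape, diffusivity, protocol) {
  centers <- protocol$window_centers
  traces <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    traces[[i]] <- tryCatch(
      simulate_window(landscape, diffusivity, centers[i], protocol,
                      window_index = i),
      error = function(e) stop(sprintf("window %d (center %.3g nm): %s",
                                       i, centers[i], conditionMessage(e)),
                               call. = FALSE))
  }
  manifest <- data.frame(
    window_id = seq_along(centers),
    center_nm = centers,
    force_constant_kj_mol_nm2 = protocol$force_constant,
    seed = protocol$base_seed + seq_along(centers),
    trace_path = NA_character_,
    side = ifelse(centers <= 0, "outer", "inner"),
    stringsAsFactors = FALSE)
  class(manifest) <- c("window_manifest", "data.frame")
  list(traces = traces, manifest = manifest)
}
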