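#' Local resistivity profile of the inhomogeneous solubility-diffusion model
#'
#' \deqn{R(z) = \frac{e^{\beta \Delta G(z)}}{D(z)}}
#' with \eqn{\beta = 1/(R_{gas} T)} (molar energies, so the gas constant in
#' kJ/mol/K). The PMF must be bulk-referenced so that R equals 1/D in bulk
#' solvent. Masked PMF bins remain masked.
#'
#' @param pmf a bulk-referenced `pmf_profile`.
#' @param diff a `diffusivity_profile` on the same grid.
#' @param temperature temperature, K.
#' @return object of class `resistivity_profile` (`R` in ps/nm^2).
#' @export
resistivity_profile <- function(pmf, diff, temperature = 310) {
  stopifnot(inherits(pmf, "pmf_profile"),
            inherits(diff, "diffusivity_profile"))
  if (!identical(pmf$reference, "bulk-zeroed"))
    stop("PMF must be bulk-referenced before computing resistivity")
  if (length(pmf$z) != length(diff$z) ||
      max(abs(pmf$z - diff$z)) > 1e-9)
    stop("PMF and diffusivity grids are not aligned")
  if (any(diff$D <= 0)) stop("diffusivity must be positive everywhere")
  beta <- 1 / (RGAS * temperature)
  structure(list(z = pmf$z, R = exp(beta * pmf$dG) / diff$D,
                 temperature = temperature, beta = beta),
            class = "resistivity_profile")
}

#' Effective (integrated) resistivity
#'
#' \deqn{R_{eff} = \int_{z_1}^{z_2} R(z)\,dz}
#' by the trapezoidal rule on the profile grid.
#'
#' @param r a `resistivity_profile`.
#' @param z1,z2 integration bounds, nm (z1 < z2, inside the grid span).
#' @return effective resistivity, ps/nm.
#' @export
effective_resistivity <- function(r, z1 = -2.2, z2 = 2.2) {
  stopifnot(inherits(r, "resistivity_profile"))
  if (z1 >= z2) stop("z1 must be smaller than z2")
  eps <- 1e-9
  sel <- r$z >= z1 - eps & r$z <= z2 + eps
  if (sum(sel) < 2L) stop("integration bounds enclose fewer than two grid points")
  if (anyNA(r$R[sel]))
    stop("masked resistivity bins inside the integration bounds")
  z <- r$z[sel]; R <- r$R[sel]
  sum(diff(z) * (R[-1] + R[-length(R)]) / 2)
}

#' Permeability coefficient from the effective resistivity
#'
#' \eqn{P = 1/R_{eff}} in nm/ps, converted to cm/s
#' (1 nm/ps = 1e-7 cm / 1e-12 s = 1e5 cm/s).
#'
#' @param R_eff effective resistivity, ps/nm (positive).
#' @param z1,z2,temperature optional metadata recorded in the result.
#' @return object of class `permeability_result`: `R_eff` (ps/nm),
#'   `P_nm_per_ps`, `P_cm_per_s`, `logP` (log10 of P in cm/s).
#' @export
permeability <- function(R_eff, z1 = NA_real_, z2 = NA_real_,
                         temperature = NA_real_) {
  if (!is.numeric(R_eff) || R_eff <= 0) stop("R_eff must be positive")
  P_nm_ps <- 1 / R_eff
  P_cm_s <- P_nm_ps * 1e5
  structure(list(R_eff = R_eff, P_nm_per_ps = P_nm_ps,
                 P_cm_per_s = P_cm_s, logP = log10(P_cm_s),
                 z1 = z1, z2 = z2, temperature = temperature),
            class = "permeability_result")
}

#' @export
print.permeability_result <- function(x, ...) {
  cat(sprintf("<permeability: P = %.4g cm/s (log P = %.2f), R_eff = %.4g ps/nm>\n",
              x$P_cm_per_s, x$logP, x$R_eff))
  invisible(x)
}

#' Base-10 log of a permeability coefficient
#'
#' @param P permeability in cm/s (positive).
#' @return log10(P); round at report time only.
#' @export
log_permeability <- function(P) {
  if (any(!is.numeric(P)) || any(P <= 0)) stop("P must be positive")
  log10(P)
}

#' Closed-form ISD permeability of an analytic landscape
#'
#' Evaluates the resistivity integrand \eqn{e^{\beta \Delta G(z)}/D(z)}
#' directly from the analytic landscape on a dense grid (trapezoid), with
#' no sampling involved — the ground-truth permeability a synthetic
#' pipeline run should recover.
#'
#' @param landscape an [energy_landscape()].
#' @param diffusivity a [diffusivity_model()].
#' @param z1,z2 integration bounds, nm.
#' @param temperature temperature, K.
#' @param dz quadrature resolution, nm.
#' @return a `permeability_result`.
#' @export
isd_permeability <- function(landscape, diffusivity, z1 = -2.2, z2 = 2.2,
                             temperature = 310, dz = 0.001) {
  beta <- 1 / (RGAS * temperature)
  z <- seq(z1, z2, by = dz)
  integrand <- exp(beta * landscape$value(z)) / diffusivity$value(z)
  R_eff <- sum(diff(z) * (integrand[-1] + integrand[-length(z)]) / 2)
  permeability(R_eff, z1, z2, temperature)
}
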