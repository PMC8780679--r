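#' Analytic free-energy landscape along the bilayer normal
#'
#' An `energy_landscape` bundles a free-energy function \eqn{\Delta G(z)}
#' (kJ/mol) with its exact derivative (kJ/mol/nm) on a stated support along
#' the reaction coordinate z (nm, the bilayer normal; z = 0 is the
#' hydrophobic core, negative z the outer leaflet). These play the role of
#' the "true" permeation free-energy profile that the umbrella-sampling /
#' WHAM pipeline must recover.
#'
#' @param name label for the landscape.
#' @param value function of z returning \eqn{\Delta G(z)} in kJ/mol;
#'   must be vectorised.
#' @param gradient function of z returning \eqn{d\Delta G/dz} in kJ/mol/nm.
#' @param support numeric length-2, the z interval (nm) on which the
#'   landscape is defined.
#' @return an object of class `energy_landscape`.
#' @seealso [make_reference_landscape()]
#' @export
energy_landscape <- function(name, value, gradient, support = c(-2.2, 2.2)) {
  stopifnot(is.function(value), is.function(gradient),
            length(support) == 2L, support[1] < support[2])
  zs <- seq(support[1], support[2], length.out = 101L)
  if (!all(is.finite(value(zs))) || !all(is.finite(gradient(zs))))
    stop("landscape value/gradient must be finite on its support")
  structure(list(name = name, value = value, gradient = gradient,
                 support = support),
            class = "energy_landscape")
}

#' Position-dependent diffusivity model
#'
#' Local diffusion coefficient \eqn{D(z)} (nm^2/ps) with exact derivative,
#' the mobility the window-wise estimator must recover.
#'
#' @param value function of z returning D(z) in nm^2/ps (strictly positive).
#' @param gradient function of z returning dD/dz in nm/ps.
#' @param support z interval (nm).
#' @return object of class `diffusivity_model`.
#' @export
diffusivity_model <- function(value, gradient, support = c(-2.2, 2.2)) {
  stopifnot(is.function(value), is.function(gradient))
  zs <- seq(support[1], support[2], length.out = 101L)
  dv <- value(zs)
  if (!all(is.finite(dv)) || any(dv <= 0))
    stop("diffusivity must be finite and strictly positive on the support")
  structure(list(value = value, gradient = gradient, support = support),
            class = "diffusivity_model")
}

#' Construct a diffusivity model preset
#'
#' @param D0 baseline diffusion coefficient, nm^2/ps. Must be positive.
#' @param type one of `"constant"`, `"linear"` (D0 + slope*z),
#'   `"exponential"` (D0*exp(rate*z)) or `"core_dip"`
#'   (D0*(1 - depth*exp(-z^2/(2*sigma^2))), a reduced mobility in the
#'   bilayer core).
#' @param slope,rate,depth,sigma shape parameters of the non-constant types.
#' @param support z interval (nm).
#' @return a [diffusivity_model()].
#' @export
make_diffusivity <- function(D0 = 0.04,
                             type = c("constant", "linear", "exponential", "core_dip"),
                             slope = 0.01, rate = 1, depth = 0.5, sigma = 0.6,
                             support = c(-2.2, 2.2)) {
  type <- match.arg(type)
  if (!is.numeric(D0) || D0 <= 0) stop("D0 must be positive")
  switch(type,
    constant = diffusivity_model(
      function(z) rep(D0, length(z)),
      function(z) rep(0, length(z)), support),
    linear = diffusivity_model(
      function(z) D0 + slope * z,
      function(z) rep(slope, length(z)), support),
    exponential = diffusivity_model(
      function(z) D0 * exp(rate * z),
      function(z) D0 * rate * exp(rate * z), support),
    core_dip = {
      if (depth >= 1) stop("core_dip depth must be < 1 to keep D positive")
      diffusivity_model(
        function(z) D0 * (1 - depth * exp(-z^2 / (2 * sigma^2))),
        function(z) D0 * depth * z / sigma^2 * exp(-z^2 / (2 * sigma^2)),
        support)
    })
}

#' Reference free-energy / diffusivity landscapes
#'
#' Presets used as ground truth for validating the whole pipeline:
#' \describe{
#'   \item{flat}{\eqn{\Delta G(z) = 0}: bulk solvent everywhere.}
#'   \item{gaussian_barrier}{a single Gaussian barrier of the given
#'     `height` (kJ/mol) and width `sigma` (nm) centred at the bilayer
#'     core, as for solutes whose main permeation barrier is the
#'     hydrophobic core.}
#'   \item{square_barrier}{a flat-topped barrier of `height` over `width`
#'     nm, smoothed by logistic shoulders of scale `steepness` so the
#'     gradient exists everywhere.}
#'   \item{membrane_like}{interfacial binding wells of depth `well_depth`
#'     (kJ/mol, negative) near |z| = `well_pos` plus a central barrier of
#'     height `barrier`, the generic shape of amphiphile permeation
#'     profiles (maximum at z = 0, minima at the head-group region). Its
#'     diffusivity preset has a mobility dip in the core
#'     (`core_dip`, `core_sigma`).}
#' }
#' All presets decay to zero free energy in bulk solvent
#' (|z| near the support edge).
#'
#' @param name preset name.
#' @param D0 bulk diffusion coefficient, nm^2/ps.
#' @param height barrier height, kJ/mol (gaussian/square barrier).
#' @param sigma Gaussian barrier width, nm.
#' @param width square-barrier top width, nm; must fit inside the support.
#' @param steepness logistic shoulder scale of the square barrier, nm.
#' @param well_depth,well_pos,well_sigma,barrier,barrier_sigma shape of the
#'   membrane_like profile (kJ/mol and nm).
#' @param core_dip,core_sigma mobility reduction in the core for the
#'   membrane_like diffusivity (fraction in [0,1) and nm).
#' @param support z interval, nm.
#' @return list with elements `landscape` ([energy_landscape()]) and
#'   `diffusivity` ([diffusivity_model()]).
#' @examples
#' ref <- make_reference_landscape("gaussian_barrier", height = 10, sigma = 0.5)
#' ref$landscape$value(0)     # 10
#' @export
make_reference_landscape <- function(name = c("flat", "square_barrier",
                                              "gaussian_barrier", "membrane_like"),
                                     D0 = 0.04,
                                     height = 10, sigma = 0.5,
                                     width = 1, steepness = 0.05,
                                     well_depth = -4, well_pos = 1.3,
                                     well_sigma = 0.25,
                                     barrier = 12, barrier_sigma = 0.4,
                                     core_dip = 0.5, core_sigma = 0.6,
                                     support = c(-2.2, 2.2)) {
  name <- match.arg(name)
  if (D0 <= 0) stop("D0 must be positive")
  diff <- make_diffusivity(D0, "constant", support = support)
  land <- switch(name,
    flat = energy_landscape("flat",
      function(z) rep(0, length(z)),
      function(z) rep(0, length(z)), support),
    gaussian_barrier = {
      h <- height; s <- sigma
      energy_landscape("gaussian_barrier",
        function(z) h * exp(-z^2 / (2 * s^2)),
        function(z) -h * z / s^2 * exp(-z^2 / (2 * s^2)), support)
    },
    square_barrier = {
      if (width / 2 >= max(abs(support)))
        stop("barrier width exceeds the landscape support")
      h <- height; w2 <- width / 2; s <- steepness
      # product of two logistic shoulders: smooth, ~h on |z|<w/2, ~0 in bulk
      val <- function(z) {
        a <- stats::plogis((z + w2) / s)
        b <- stats::plogis((w2 - z) / s)
        h * a * b
      }
      grd <- function(z) {
        a <- stats::plogis((z + w2) / s)
        b <- stats::plogis((w2 - z) / s)
        h * (a * (1 - a) * b / s - a * b * (1 - b) / s)
      }
      energy_landscape("square_barrier", val, grd, support)
    },
    membrane_like = {
      b <- barrier; sb <- barrier_sigma
      wd <- well_depth; wp <- well_pos; sw <- well_sigma
      val <- function(z) {
        b * exp(-z^2 / (2 * sb^2)) +
          wd * (exp(-(z - wp)^2 / (2 * sw^2)) + exp(-(z + wp)^2 / (2 * sw^2)))
      }
      grd <- function(z) {
        -b * z / sb^2 * exp(-z^2 / (2 * sb^2)) -
          wd * ((z - wp) / sw^2 * exp(-(z - wp)^2 / (2 * sw^2)) +
                (z + wp) / sw^2 * exp(-(z + wp)^2 / (2 * sw^2)))
      }
      diff <- make_diffusivity(D0, "core_dip", depth = core_dip,
                               sigma = core_sigma, support = support)
      energy_landscape("membrane_like", val, grd, support)
    })
  list(landscape = land, diffusivity = diff)
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf("<energy_landscape '%s' on [%g, %g] nm>\n",
              x$name, x$support[1], x$support[2]))
  invisible(x)
}

#' @export
print.diffusivity_model <- function(x, ...) {
  zs <- seq(x$support[1], x$support[2], length.out = 5L)
  cat(sprintf("<diffusivity_model on [%g, %g] nm; D at core %.4g nm^2/ps>\n",
              x$support[1], x$support[2], x$value(0)))
  invisible(x)
}
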