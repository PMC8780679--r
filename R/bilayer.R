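#' Generate a toy lipid-bilayer snapshot
#'
#' Builds a schematic two-leaflet configuration for exercising the
#' structural metrics (density profiles, Voronoi area per lipid, deuterium
#' order parameters) without any molecular dynamics. Each lipid carries a
#' leaflet tag (outer lipids at negative z, inner at positive z — the
#' extracellular side is negative by convention), a species tag, a triad
#' of head-group atom positions in the membrane plane, a z coordinate, a
#' mass and one C-H orientation unit vector per tail carbon.
#'
#' @param n_outer,n_inner lipids per leaflet (> 0).
#' @param box `c(Lx, Ly, Lz)` box dimensions, nm; xy coordinates are
#'   wrapped into `[0, Lx) x [0, Ly)`, z spans `[-Lz/2, Lz/2]`.
#' @param placement `"grid"` (square lattice), `"uniform"` (uniform random)
#'   or `"jittered_grid"` (lattice plus Gaussian jitter of sd `jitter` nm).
#' @param jitter jitter standard deviation for `"jittered_grid"`, nm.
#' @param tilt_angle_dist orientation-vector distribution: a list with
#'   `type` one of `"delta"` (all vectors at polar angle `theta` with
#'   uniform azimuth), `"isotropic"` (uniform on the sphere) or
#'   `"wrapped_normal"` (polar angle `theta` + Gaussian spread `sd`,
#'   radians). A bare number is shorthand for a delta at that angle.
#' @param composition `"cancer"` (POPC/POPS 24/12 in each leaflet),
#'   `"normal"` (outer 36 POPC / 0 POPS, inner 12 POPC / 24 POPS, scaled
#'   to the requested counts) or a function(n, leaflet) returning species
#'   tags.
#' @param n_carbons tail carbons per lipid.
#' @param leaflet_z unsigned distance of the lipid plane from the core, nm.
#' @param z_spread Gaussian spread of lipid z positions, nm.
#' @param n_water water particles, placed uniformly in the two bulk slabs
#'   beyond |z| = `water_edge`.
#' @param water_edge |z| where bulk water starts, nm.
#' @param seed RNG seed.
#' @return object of class `toy_bilayer`: `box`, data.frame `lipids`
#'   (id, leaflet, species, x, y, z, mass, triad coordinates), list
#'   `orient` of n_carbons x 3 unit-vector matrices, data.frame `water`.
#' @export
make_toy_bilayer <- function(n_outer = 36, n_inner = 36,
                             box = c(6, 6, 6),
                             placement = c("jittered_grid", "grid", "uniform"),
                             jitter = 0.1,
                             tilt_angle_dist = list(type = "isotropic"),
                             composition = "cancer",
                             n_carbons = 14,
                             leaflet_z = 1.0, z_spread = 0.1,
                             n_water = 400, water_edge = 1.8,
                             seed = 1L) {
  placement <- match.arg(placement)
  if (n_outer <= 0 || n_inner <= 0) stop("lipid counts must be positive")
  if (any(box <= 0)) stop("box dimensions must be positive")
  if (is.numeric(tilt_angle_dist))
    tilt_angle_dist <- list(type = "delta", theta = tilt_angle_dist)
  if (!tilt_angle_dist$type %in% c("delta", "isotropic", "wrapped_normal"))
    stop(sprintf("unknown orientation distribution '%s'", tilt_angle_dist$type))
  set.seed(seed)

  place_xy <- function(n) {
    switch(placement,
      uniform = cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2])),
      grid = , jittered_grid = {
        ncol_ <- ceiling(sqrt(n))
        nrow_ <- ceiling(n / ncol_)
        gx <- (seq_len(ncol_) - 0.5) * box[1] / ncol_
        gy <- (seq_len(nrow_) - 0.5) * box[2] / nrow_
        xy <- as.matrix(expand.grid(x = gx, y = gy))[seq_len(n), , drop = FALSE]
        if (placement == "jittered_grid")
          xy <- xy + matrix(stats::rnorm(2 * n, sd = jitter), ncol = 2)
        xy
      })
  }
  wrap <- function(v, L) v - L * floor(v / L)

  species_for <- function(n, leaflet) {
    if (is.function(composition)) return(composition(n, leaflet))
    frac_pops <- switch(composition,
      cancer = 1 / 3,
      normal = if (leaflet == "outer") 0 else 2 / 3,
      stop(sprintf("unknown composition '%s'", composition)))
    n_pops <- round(n * frac_pops)
    c(rep("POPS", n_pops), rep("POPC", n - n_pops))
  }

  draw_orient <- function(n) {
    d <- tilt_angle_dist
    theta <- switch(d$type,
      delta = rep(d$theta %||% 0, n),
      isotropic = acos(stats::runif(n, -1, 1)),
      wrapped_normal = abs((d$theta %||% 0) + stats::rnorm(n, sd = d$sd %||% 0.2)))
    phi <- if (d$type == "delta" && isTRUE((d$theta %||% 0) == 0))
      rep(0, n) else stats::runif(n, 0, 2 * pi)
    cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  }

  build_leaflet <- function(n, leaflet) {
    xy <- place_xy(n)
    zsign <- if (leaflet == "outer") -1 else 1
    z <- zsign * abs(leaflet_z + stats::rnorm(n, sd = z_spread))
    sp <- species_for(n, leaflet)
    mass <- ifelse(sp == "POPS", 784, 760)   # amu, POPS slightly heavier
    # triad atoms: small equilateral triangle around the head-group site
    r <- 0.15
    ang <- matrix(c(0, 2 * pi / 3, 4 * pi / 3), nrow = n, ncol = 3, byrow = TRUE)
    data.frame(
      leaflet = leaflet, species = sp,
      x = wrap(xy[, 1], box[1]), y = wrap(xy[, 2], box[2]),
      z = z, mass = mass,
      t1x = wrap(xy[, 1] + r * cos(ang[, 1]), box[1]),
      t1y = wrap(xy[, 2] + r * sin(ang[, 1]), box[2]),
      t2x = wrap(xy[, 1] + r * cos(ang[, 2]), box[1]),
      t2y = wrap(xy[, 2] + r * sin(ang[, 2]), box[2]),
      t3x = wrap(xy[, 1] + r * cos(ang[, 3]), box[1]),
      t3y = wrap(xy[, 2] + r * sin(ang[, 3]), box[2]),
      stringsAsFactors = FALSE)
  }

  lipids <- rbind(build_leaflet(n_outer, "outer"),
                  build_leaflet(n_inner, "inner"))
  lipids$id <- seq_len(nrow(lipids))
  orient <- lapply(seq_len(nrow(lipids)), function(i) draw_orient(n_carbons))

  water <- if (n_water > 0) {
    zmax <- box[3] / 2
    zb <- stats::runif(n_water, water_edge, zmax) *
      sample(c(-1, 1), n_water, replace = TRUE)
    data.frame(x = stats::runif(n_water, 0, box[1]),
               y = stats::runif(n_water, 0, box[2]),
               z = zb, mass = 18)
  } else {
    data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
               mass = numeric(0))
  }

  structure(list(box = box, lipids = lipids, orient = orient,
                 water = water, n_carbons = n_carbons, seed = seed),
            class = "toy_bilayer")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.toy_bilayer <- function(x, ...) {
  cat(sprintf("<toy_bilayer: %d lipids (%d outer / %d inner), %d waters, box %g x %g x %g nm>\n",
              nrow(x$lipids), sum(x$lipids$leaflet == "outer"),
              sum(x$lipids$leaflet == "inner"), nrow(x$water),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}
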