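#' Mass density profile along the bilayer normal
#'
#' Mass-weighted histogram of particle z positions divided by slab volume
#' Lx*Ly*bin_width, averaged over snapshots when several are given.
#' Densities are in kg/m^3 (masses in amu, lengths in nm). The z
#' convention matches the leaflet tags: negative z is the outer
#' (extracellular) leaflet.
#'
#' @param snapshots a `toy_bilayer` or list of them.
#' @param bin_width slab thickness, nm.
#' @param components named list mapping component labels to selector
#'   functions of the particle table (columns kind, species, x, y, z,
#'   mass). The default reports system, lipid, water and each lipid
#'   species present.
#' @return object of class `density_profile`: `z` (slab midpoints, nm)
#'   and a density matrix with one column per component, kg/m^3.
#' @export
density_profile <- function(snapshots, bin_width = 0.1, components = NULL) {
  if (inherits(snapshots, "toy_bilayer")) snapshots <- list(snapshots)
  if (bin_width <= 0) stop("bin_width must be positive")
  box <- snapshots[[1]]$box
  amu_per_nm3_to_kg_m3 <- 1.66053906660

  particle_table <- function(s) {
    rbind(
      data.frame(kind = "lipid", species = s$lipids$species,
                 z = s$lipids$z, mass = s$lipids$mass,
                 stringsAsFactors = FALSE),
      if (nrow(s$water))
        data.frame(kind = "water", species = "water",
                   z = s$water$z, mass = s$water$mass,
                   stringsAsFactors = FALSE))
  }
  tabs <- lapply(snapshots, particle_table)
  if (is.null(components)) {
    spp <- sort(unique(tabs[[1]]$species[tabs[[1]]$kind == "lipid"]))
    components <- c(
      list(system = function(p) rep(TRUE, nrow(p)),
           lipid = function(p) p$kind == "lipid",
           water = function(p) p$kind == "water"),
      stats::setNames(lapply(spp, function(sp) {
        force(sp); function(p) p$species == sp
      }), spp))
  }
  if (length(components) == 0L) stop("empty component grouping")

  zmax <- box[3] / 2
  n_bins <- ceiling(2 * zmax / bin_width)
  edges <- -zmax + bin_width * (0:n_bins)
  mids <- edges[-length(edges)] + bin_width / 2
  slab_vol <- box[1] * box[2] * bin_width

  dens <- sapply(names(components), function(nm) {
    sel <- components[[nm]]
    per_snap <- sapply(tabs, function(p) {
      q <- p[sel(p), , drop = FALSE]
      idx <- findInterval(q$z, edges, rightmost.closed = TRUE)
      idx[idx < 1L] <- 1L; idx[idx > n_bins] <- n_bins
      as.vector(tapply(q$mass, factor(idx, levels = seq_len(n_bins)),
                       sum, default = 0))
    })
    rowMeans(per_snap) / slab_vol * amu_per_nm3_to_kg_m3
  })
  structure(list(z = mids, density = dens, bin_width = bin_width,
                 box = box, components = names(components)),
            class = "density_profile")
}

# clip a convex polygon (matrix of vertices) by the half-plane of points
# closer to `site` than to `other` (Sutherland-Hodgman against the bisector)
clip_halfplane <- function(poly, site, other) {
  d <- other - site
  m <- (site + other) / 2
  s <- as.vector((poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2])
  inside <- s <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(NULL)
  n <- nrow(poly)
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Area per lipid by periodic Voronoi tessellation
#'
#' Lipid sites are the centroids of each lipid's triad-atom xy positions,
#' projected onto the membrane plane. Periodicity is handled by 3x3 image
#' replication; each central-cell Voronoi polygon is obtained by clipping
#' the box rectangle against the perpendicular bisectors towards every
#' other site (nearby sites first, stopping once no further site can cut
#' the cell), and its area computed with the shoelace formula. The
#' polygons partition the box, so areas sum to Lx*Ly exactly.
#'
#' @param snapshot a `toy_bilayer`.
#' @param leaflet `"outer"` or `"inner"`.
#' @return object of class `area_per_lipid`: per-lipid polygon `areas`
#'   (nm^2), their `mean_area`, the `leaflet` and lipid ids.
#' @export
area_per_lipid <- function(snapshot, leaflet = c("outer", "inner")) {
  leaflet <- match.arg(leaflet)
  lp <- snapshot$lipids[snapshot$lipids$leaflet == leaflet, , drop = FALSE]
  if (nrow(lp) < 3L) stop("need at least three lipids in the leaflet")
  Lx <- snapshot$box[1]; Ly <- snapshot$box[2]
  # triad centroid with periodic-aware averaging: unwrap triad atoms
  # towards the head-group position before averaging
  unwrap1 <- function(v, ref, L) v + L * round((ref - v) / L)
  sx <- (unwrap1(lp$t1x, lp$x, Lx) + unwrap1(lp$t2x, lp$x, Lx) +
         unwrap1(lp$t3x, lp$x, Lx)) / 3
  sy <- (unwrap1(lp$t1y, lp$y, Ly) + unwrap1(lp$t2y, lp$y, Ly) +
         unwrap1(lp$t3y, lp$y, Ly)) / 3
  sx <- sx - Lx * floor(sx / Lx)
  sy <- sy - Ly * floor(sy / Ly)
  n <- length(sx)
  if (n >= 3L) {
    spread <- max(max(sx) - min(sx), max(sy) - min(sy))
    if (spread < 1e-12) stop("degenerate lipid sites (all coincident)")
  }
  # 3x3 images
  shifts <- as.matrix(expand.grid(ix = -1:1, iy = -1:1))
  img_x <- as.vector(outer(sx, shifts[, 1] * Lx, `+`))
  img_y <- as.vector(outer(sy, shifts[, 2] * Ly, `+`))
  img_owner <- rep(seq_len(n), times = nrow(shifts))

  box_poly <- matrix(c(0, 0, Lx, 0, Lx, Ly, 0, Ly), ncol = 2, byrow = TRUE)
  n_img <- length(img_x)
  areas <- numeric(n)
  # the box is tiled by the in-box parts of every image's Voronoi cell;
  # each image cell's area accrues to the lipid owning that image
  for (k in seq_len(n_img)) {
    site <- c(img_x[k], img_y[k])
    d2 <- (img_x - site[1])^2 + (img_y - site[2])^2
    d2[k] <- Inf
    if (min(d2) < 1e-20) stop("degenerate lipid sites (coincident)")
    ord <- order(d2)
    poly <- box_poly
    for (j in ord) {
      # a site farther than twice the cell's max radius cannot cut it
      rmax2 <- max((poly[, 1] - site[1])^2 + (poly[, 2] - site[2])^2)
      if (d2[j] > 4 * rmax2) break
      poly <- clip_halfplane(poly, site, c(img_x[j], img_y[j]))
      if (is.null(poly) || nrow(poly) < 3L) { poly <- NULL; break }
    }
    if (!is.null(poly))
      areas[img_owner[k]] <- areas[img_owner[k]] + shoelace(poly)
  }
  structure(list(areas = areas, mean_area = mean(areas),
                 leaflet = leaflet, lipid_id = lp$id,
                 sites = cbind(x = sx, y = sy), box = snapshot$box),
            class = "area_per_lipid")
}

#' @export
print.area_per_lipid <- function(x, ...) {
  cat(sprintf("<area_per_lipid (%s): %d lipids, mean %.3f nm^2>\n",
              x$leaflet, length(x$areas), x$mean_area))
  invisible(x)
}

#' Deuterium order parameters of lipid tails
#'
#' \deqn{S_{CD} = -\tfrac12 \langle 3\cos^2\theta - 1\rangle}
#' where theta is the angle between each C-H bond vector and the bilayer
#' normal (z axis); the average runs over lipids of the requested species
#' (and leaflet) and over snapshots, separately per carbon index. The
#' value ranges from -1 (bonds along the normal) through 0 (magic angle)
#' to +0.5 (bonds in the membrane plane).
#'
#' @param snapshots a `toy_bilayer` or list of them.
#' @param species lipid species tag, or `NULL` for all lipids.
#' @param leaflet optional leaflet restriction (`"outer"`/`"inner"`).
#' @return object of class `order_parameter_profile`: `carbon` indices and
#'   `S_CD` values.
#' @export
order_parameters <- function(snapshots, species = NULL, leaflet = NULL) {
  if (inherits(snapshots, "toy_bilayer")) snapshots <- list(snapshots)
  acc <- NULL; nacc <- 0L
  for (s in snapshots) {
    sel <- rep(TRUE, nrow(s$lipids))
    if (!is.null(species)) sel <- sel & s$lipids$species == species
    if (!is.null(leaflet)) sel <- sel & s$lipids$leaflet == leaflet
    if (!any(sel)) next
    mats <- s$orient[sel]
    if (any(vapply(mats, is.null, logical(1))))
      stop("missing orientation vectors")
    cos2 <- sapply(mats, function(m) m[, 3]^2)  # carbons x lipids
    if (is.null(dim(cos2))) cos2 <- matrix(cos2, nrow = 1L)
    acc <- if (is.null(acc)) rowSums(cos2) else acc + rowSums(cos2)
    nacc <- nacc + sum(sel)
  }
  if (nacc == 0L)
    stop(sprintf("no lipids match species '%s'", species %||% "<any>"))
  scd <- -0.5 * (3 * acc / nacc - 1)
  structure(list(carbon = seq_along(scd), S_CD = scd,
                 species = species %||% "all", n_lipids = nacc),
            class = "order_parameter_profile")
}

#' @export
print.order_parameter_profile <- function(x, ...) {
  cat(sprintf("<order_parameters (%s): %d carbons, S_CD in [%.3f, %.3f]>\n",
              x$species, length(x$S_CD), min(x$S_CD), max(x$S_CD)))
  invisible(x)
}
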