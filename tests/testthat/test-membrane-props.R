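test_that("density profiles conserve mass and scale linearly", {
  snap <- make_toy_bilayer(n_outer = 24, n_inner = 24, box = c(6, 6, 6),
                           n_water = 300, seed = 7)
  dp <- density_profile(snap, bin_width = 0.2)
  amu <- 1.66053906660
  total_mass <- sum(snap$lipids$mass) + sum(snap$water$mass)
  integral <- sum(dp$density[, "system"]) * 6 * 6 * 0.2 / amu
  expect_equal(integral, total_mass, tolerance = 1e-9)

  # doubling every mass doubles every density
  snap2 <- snap
  snap2$lipids$mass <- 2 * snap2$lipids$mass
  snap2$water$mass <- 2 * snap2$water$mass
  dp2 <- density_profile(snap2, bin_width = 0.2)
  expect_equal(dp2$density, 2 * dp$density, tolerance = 1e-12)
})

test_that("the asymmetric membrane has no outer-leaflet PS density", {
  snap <- make_toy_bilayer(n_outer = 36, n_inner = 36,
                           composition = "normal", seed = 9)
  dp <- density_profile(snap, bin_width = 0.2)
  expect_true(all(dp$density[dp$z < 0, "POPS"] == 0))
  expect_gt(sum(dp$density[dp$z > 0, "POPS"]), 0)
  expect_gt(sum(dp$density[dp$z < 0, "POPC"]), 0)
})

test_that("mirroring a snapshot in z reverses the density profile", {
  snap <- make_toy_bilayer(n_outer = 16, n_inner = 16, seed = 11,
                           n_water = 100)
  mirrored <- snap
  mirrored$lipids$z <- -mirrored$lipids$z
  mirrored$water$z <- -mirrored$water$z
  a <- density_profile(snap, bin_width = 0.25)$density[, "system"]
  b <- density_profile(mirrored, bin_width = 0.25)$density[, "system"]
  expect_equal(b, rev(a), tolerance = 1e-12)
})

test_that("a square lattice tessellates into exactly unit cells", {
  snap <- make_toy_bilayer(n_outer = 4, n_inner = 4, box = c(2, 2, 6),
                           placement = "grid", seed = 1)
  apl <- area_per_lipid(snap, "outer")
  expect_equal(apl$areas, rep(1, 4), tolerance = 1e-9)
  expect_equal(apl$mean_area, 1, tolerance = 1e-9)
})

test_that("Voronoi cells partition the leaflet for arbitrary configurations", {
  for (s in 1:100) {
    snap <- make_toy_bilayer(n_outer = 10, n_inner = 3, box = c(4, 4, 6),
                             placement = "uniform", n_water = 0, seed = s)
    apl <- area_per_lipid(snap, "outer")
    expect_equal(sum(apl$areas), 16, tolerance = 1e-9)
    expect_true(all(apl$areas > 0))
    # the partition property pins the mean: box area over lipid count
    expect_equal(apl$mean_area, 16 / 10, tolerance = 1e-9)
  }
})

test_that("Voronoi areas agree with a nearest-site rasterization oracle", {
  snap <- make_toy_bilayer(n_outer = 16, n_inner = 3, box = c(4, 4, 6),
                           placement = "jittered_grid", jitter = 0.15,
                           n_water = 0, seed = 21)
  apl <- area_per_lipid(snap, "outer")
  sx <- apl$sites[, "x"]; sy <- apl$sites[, "y"]
  h <- 0.002
  px <- seq(h / 2, 4 - h / 2, by = h)
  gx <- rep(px, times = length(px))
  gy <- rep(px, each = length(px))
  best <- rep(Inf, length(gx)); owner <- integer(length(gx))
  for (i in seq_along(sx)) {
    for (ix in -1:1) for (iy in -1:1) {
      d2 <- (gx - sx[i] - 4 * ix)^2 + (gy - sy[i] - 4 * iy)^2
      upd <- d2 < best
      best[upd] <- d2[upd]; owner[upd] <- i
    }
  }
  raster_area <- tabulate(owner, nbins = length(sx)) * h^2
  expect_lt(max(abs(raster_area - apl$areas) / apl$areas), 0.01)
})

test_that("degenerate leaflets are rejected", {
  snap <- make_toy_bilayer(n_outer = 4, n_inner = 4, box = c(2, 2, 6),
                           placement = "grid", seed = 1)
  snap$lipids <- snap$lipids[snap$lipids$leaflet == "inner" |
                               snap$lipids$id %in% 1:2, ]
  expect_error(area_per_lipid(snap, "outer"), "at least three")
})

test_that("order parameters hit the analytic endpoints", {
  endpoint <- function(theta)
    order_parameters(make_toy_bilayer(n_outer = 5, n_inner = 5,
                                      tilt_angle_dist = theta,
                                      n_carbons = 4, seed = 2))$S_CD
  expect_equal(endpoint(0), rep(-1, 4), tolerance = 1e-12)
  expect_equal(endpoint(pi / 2), rep(0.5, 4), tolerance = 1e-12)
  expect_equal(endpoint(acos(1 / sqrt(3))), rep(0, 4), tolerance = 1e-12)
})

test_that("isotropic orientations average to zero order", {
  snap <- make_toy_bilayer(n_outer = 5000, n_inner = 5000,
                           tilt_angle_dist = list(type = "isotropic"),
                           n_carbons = 4, n_water = 0, seed = 5)
  scd <- order_parameters(snap)
  expect_equal(scd$n_lipids, 10000)
  expect_lt(max(abs(scd$S_CD)), 0.02)
  expect_true(all(scd$S_CD >= -1 & scd$S_CD <= 0.5))
})

test_that("S_CD is invariant under azimuthal rotation about the normal", {
  snap <- make_toy_bilayer(n_outer = 12, n_inner = 12,
                           tilt_angle_dist = list(type = "wrapped_normal",
                                                  theta = 0.4, sd = 0.2),
                           n_carbons = 6, seed = 8)
  base <- order_parameters(snap)$S_CD
  for (ang in c(0.3, 1.1, 2.0, 4.2, 5.9)) {
    rot <- snap
    Rm <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
    rot$orient <- lapply(rot$orient, function(m) m %*% Rm)
    expect_lt(max(abs(order_parameters(rot)$S_CD - base)), 1e-12)
  }
})

test_that("species filtering selects the right lipids or fails loudly", {
  snap <- make_toy_bilayer(n_outer = 12, n_inner = 12,
                           composition = "normal", seed = 3)
  pops <- order_parameters(snap, species = "POPS")
  expect_equal(pops$n_lipids, 8)   # inner leaflet only, 2/3 of 12
  expect_error(order_parameters(snap, species = "CHOL"), "no lipids")
})
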