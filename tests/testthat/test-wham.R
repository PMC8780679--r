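test_that("histograms bin half-open and keep windows separate", {
  tr <- mk_trace(rep(0.05, 40))
  h <- build_histograms(list(tr), bin_width = 0.1, range = c(0, 0.2))
  expect_equal(as.vector(h$counts), c(40L, 0L))

  tr2 <- mk_trace(rep(0.15, 10))
  h2 <- build_histograms(list(tr, tr2), bin_width = 0.1, range = c(0, 0.2))
  expect_equal(dim(h2$counts), c(2L, 2L))
  expect_equal(h2$counts[1, ], c(40L, 0L))
  expect_equal(h2$counts[2, ], c(0L, 10L))
  expect_equal(h2$n_samples, c(40, 10))

  expect_error(build_histograms(list(), 0.1), "no traces")
  expect_error(build_histograms(list(tr), 0.1, range = c(1, 1)), "range")
  expect_warning(build_histograms(list(mk_trace(c(rep(0.05, 9), 5))),
                                  0.1, c(0, 0.2)), "outside")
})

test_that("every window's modal bin sits at its bias center on a flat landscape", {
  flat <- make_reference_landscape("flat")
  sim <- simulate_protocol(flat$landscape, flat$diffusivity,
                           umbrella_protocol(n_steps = 4e4, base_seed = 12))
  h <- build_histograms(sim$traces, bin_width = 0.02)
  for (i in seq_len(nrow(h$counts))) {
    mode_z <- h$mids[which.max(h$counts[i, ])]
    expect_lt(abs(mode_z - sim$manifest$center_nm[i]), 0.06)
  }
})

test_that("single-window WHAM equals analytic reweighting exactly", {
  flat <- make_reference_landscape("flat")
  proto <- umbrella_protocol(n_steps = 1.25e6, base_seed = 3)
  tr <- simulate_window(flat$landscape, flat$diffusivity, 0, proto, 1)
  h <- build_histograms(list(tr), bin_width = 0.02, range = c(-1, 1))
  pmf <- solve_wham(h)
  ok <- !is.na(pmf$dG)
  # direct unbiasing oracle: -RT ln(counts) - w(z) up to a constant
  w <- 0.5 * tr$force_constant * h$mids^2
  oracle <- -RT310 * log(h$counts[1, ]) - w
  d <- (pmf$dG - oracle)[ok & h$counts[1, ] > 0]
  expect_lt(max(abs(d - mean(d))), 1e-9)
  # and the recovered profile is flat where well sampled
  well <- ok & h$counts[1, ] >= 100
  expect_lt(sqrt(mean((pmf$dG[well] - mean(pmf$dG[well]))^2)), 0.2)
})

test_that("two overlapping windows on a flat landscape give a flat PMF", {
  flat <- make_reference_landscape("flat")
  proto <- umbrella_protocol(n_steps = 5e5, base_seed = 14)
  t1 <- simulate_window(flat$landscape, flat$diffusivity, -0.1, proto, 1)
  t2 <- simulate_window(flat$landscape, flat$diffusivity, 0.1, proto, 2)
  h <- build_histograms(list(t1, t2), 0.02, c(-1, 1))
  pmf <- solve_wham(h)
  well <- !is.na(pmf$dG) & colSums(h$counts) >= 100
  expect_lt(sqrt(mean((pmf$dG[well] - mean(pmf$dG[well]))^2)), 0.2)
  expect_true(pmf$converged)
})

test_that("bulk referencing zeroes the bulk mean and is idempotent", {
  p <- mk_pmf(c(0.1, 0.3, 0.5), c(5, 5, 3), reference = "raw")
  r <- reference_to_bulk(p, c(0, 0.4))
  expect_equal(r$dG, c(0, 0, -2))
  expect_identical(r$reference, "bulk-zeroed")
  r2 <- reference_to_bulk(r, c(0, 0.4))
  expect_equal(r2$dG, r$dG)
  expect_error(reference_to_bulk(p, c(5, 6)), "overlap")
})

test_that("moving-average smoothing behaves like a truncated boxcar", {
  z <- seq(-1, 1, by = 0.02)
  const <- mk_pmf(z, rep(3, length(z)), bin_width = 0.02)
  expect_equal(smooth_pmf(const, 0.05)$dG, const$dG)

  spike <- rep(0, length(z)); spike[51] <- 9
  sp <- smooth_pmf(mk_pmf(z, spike, bin_width = 0.02), 0.05)
  expect_equal(sp$dG[51], 3)        # 3-bin average of a lone spike
  expect_true(sp$smoothed)

  # brute-force oracle on an arbitrary profile, including the truncated ends
  set.seed(4)
  g <- sin(3 * z) + rnorm(length(z), sd = 0.2)
  sm <- smooth_pmf(mk_pmf(z, g, bin_width = 0.02), 0.11)
  oracle <- vapply(seq_along(z), function(i)
    mean(g[abs(z - z[i]) <= 0.055 + 1e-12]), numeric(1))
  expect_equal(sm$dG, oracle, tolerance = 1e-12)

  expect_error(smooth_pmf(mk_pmf(z, g, bin_width = 0.02), 0.01), "span")
})

test_that("mirror duplication produces an exactly symmetric full profile", {
  half <- mk_pmf(c(-2, -1, 0), c(0, 3, 10))
  full <- symmetrize_cancer(half)
  expect_equal(full$z, c(-2, -1, 0, 1, 2))
  expect_equal(full$dG, c(0, 3, 10, 3, 0))
  expect_equal(full$dG, rev(full$dG))
  expect_identical(full$z[which.max(full$dG)], 0)

  # midpoint grids (no bin at exactly zero) mirror without duplication
  zh <- seq(-1.99, -0.01, by = 0.02)
  fh <- symmetrize_cancer(mk_pmf(zh, -zh, bin_width = 0.02))
  expect_equal(fh$z, c(zh, rev(-zh)))
  expect_equal(fh$dG, rev(fh$dG))

  expect_error(symmetrize_cancer(mk_pmf(c(-2, -1.5), c(0, 1))), "core")
})

test_that("independent leaflets join continuously with the shift reported", {
  zo <- seq(-1.99, -0.01, by = 0.02)
  zi <- rev(-zo)
  g <- 5 * exp(-zo^2)
  same <- join_normal_leaflets(mk_pmf(zo, g, side = "outer"),
                               mk_pmf(zi, rev(g), side = "inner"))
  expect_equal(same$core_mismatch, 0)
  expect_equal(same$dG, rev(same$dG))

  off <- join_normal_leaflets(mk_pmf(zo, g, side = "outer"),
                              mk_pmf(zi, rev(g) + 1, side = "inner"))
  expect_equal(abs(off$core_mismatch), 1)
  n <- length(zo)
  expect_equal(off$dG[n], off$dG[n + 1L], tolerance = 1e-12)

  raw <- mk_pmf(zo, g, reference = "raw")
  expect_error(join_normal_leaflets(raw, mk_pmf(zi, rev(g))), "referenced")
  expect_error(join_normal_leaflets(mk_pmf(zo, g),
                                    mk_pmf(zi[-1] + 1, rev(g)[-1])), "core")
})

test_that("an asymmetric landscape is recovered leaflet by leaflet", {
  # different well depths per leaflet: a landscape with a genuine asymmetry
  land <- energy_landscape("asym",
    function(z) 6 * exp(-z^2 / 0.32) - 3 * exp(-(z + 1.3)^2 / 0.125) -
      1 * exp(-(z - 1.3)^2 / 0.125),
    function(z) -6 * 2 * z / 0.32 * exp(-z^2 / 0.32) +
      3 * 2 * (z + 1.3) / 0.125 * exp(-(z + 1.3)^2 / 0.125) +
      1 * 2 * (z - 1.3) / 0.125 * exp(-(z - 1.3)^2 / 0.125))
  d <- make_diffusivity(0.04)
  out <- run_synthetic_study(land, d, umbrella_protocol(base_seed = 21),
                             run_config(membrane_mode = "normal"))
  pmf <- out$pmf
  truth <- land$value(pmf$z)
  sel <- abs(pmf$z) <= 2 & !is.na(pmf$dG)
  expect_lt(sqrt(mean((pmf$dG[sel] - truth[sel])^2)), 0.5)
  # continuity at the core by construction
  n <- sum(pmf$z < 0)
  expect_lt(abs(pmf$dG[n] - pmf$dG[n + 1L]), 0.5)
})

test_that("PMF convergence diagnostics", {
  # periodic data: every cumulative slice has identical proportions
  pattern <- c(-0.15, -0.05, 0.05, 0.15, -0.05, 0.05)
  tr <- mk_trace(rep(pattern, 200), center = 0)
  rep_conv <- check_convergence(list(tr), n_intervals = 3, bin_width = 0.1,
                                range = c(-0.2, 0.2),
                                bulk_region = c(-0.2, 0.2))
  expect_lt(max(rep_conv$deltas), 1e-9)

  flat <- make_reference_landscape("flat")
  sim <- simulate_protocol(flat$landscape, flat$diffusivity,
                           umbrella_protocol(n_steps = 1e5, base_seed = 6))
  conv <- check_convergence(sim$traces, n_intervals = 3)
  expect_true(conv$converged)
  expect_length(conv$deltas, 2L)

  expect_error(check_convergence(sim$traces, n_intervals = 1), "at least 2")
})

test_that("tightening the WHAM tolerance never worsens the recovery", {
  gb <- make_reference_landscape("gaussian_barrier", height = 6, sigma = 0.5)
  proto <- umbrella_protocol(window_centers = seq(-1.5, 1.5, by = 0.25),
                             n_steps = 5e4, base_seed = 19)
  sim <- simulate_protocol(gb$landscape, gb$diffusivity, proto)
  h <- build_histograms(sim$traces, 0.02, c(-1.8, 1.8))
  rms <- vapply(c(0.5, 0.25, 0.125, 0.0625), function(tol) {
    p <- reference_to_bulk(suppressWarnings(
      solve_wham(h, tol = tol, max_iter = 1e5)),
      list(c(-1.8, -1.5), c(1.5, 1.8)))
    sel <- !is.na(p$dG) & abs(p$z) <= 1.5
    sqrt(mean((p$dG[sel] - gb$landscape$value(p$z[sel]))^2))
  }, numeric(1))
  expect_true(all(diff(rms) <= 1e-9))
})

test_that("block averaging attaches finite standard errors", {
  flat <- make_reference_landscape("flat")
  sim <- simulate_protocol(flat$landscape, flat$diffusivity,
                           umbrella_protocol(n_steps = 1e5, base_seed = 23))
  h <- build_histograms(sim$traces, 0.02)
  pmf <- reference_to_bulk(solve_wham(h))
  pmf <- pmf_block_stderr(pmf, sim$traces, n_blocks = 5)
  ok <- !is.na(pmf$stderr)
  expect_gt(sum(ok), 100)
  expect_true(all(pmf$stderr[ok] >= 0))
  expect_lt(stats::median(pmf$stderr[ok]), 0.5)
})
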