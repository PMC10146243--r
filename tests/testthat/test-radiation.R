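test_that("solar position: equinox noon, night, independent ephemeris", {
  eq <- solar_position(0, 0, 80, 12)
  expect_equal(unname(eq["elevation"]), 90, tolerance = 1)

  night <- solar_position(34.5, 0, 200, 0)
  expect_lt(night["elevation"], 0)

  # oracle: Cooper/Meeus-style declination + spherical trig, written
  # independently of the implementation
  oracle_elev <- function(lat, doy, hour) {
    decl <- -asin(0.39779 * cos(0.98565 * pi / 180 * (doy + 10) +
                                  1.914 * pi / 180 *
                                  sin(0.98565 * pi / 180 * (doy - 2))))
    H <- 15 * (hour - 12) * pi / 180
    phi <- lat * pi / 180
    asin(sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)) * 180 / pi
  }
  set.seed(2)
  for (i in 1:10) {
    lat <- runif(1, -50, 50); doy <- sample(365, 1); hr <- runif(1, 0, 24)
    got <- solar_position(lat, 0, doy, hr)["elevation"]
    expect_lt(abs(got - oracle_elev(lat, doy, hr)), 0.5)
  }

  expect_error(solar_position(34, 0, 400, 12), "doy")
})

test_that("diffuse/direct split conserves and saturates when overcast", {
  z <- split_diffuse_direct(0, 45, 180)
  expect_equal(z$direct + z$diffuse, 0)

  # overcast regime of the clearness-index model: kt <= 0.22 -> all diffuse.
  # oracle: extraterrestrial horizontal flux recomputed by hand
  doy <- 200; el <- 40
  S0 <- 2760 * (1 + 0.033 * cos(2 * pi * doy / 365)) * sin(el * pi / 180)
  dim_ppfd <- 0.9 * 0.22 * S0
  sp <- split_diffuse_direct(dim_ppfd, el, doy)
  expect_equal(sp$diffuse, dim_ppfd)
  expect_equal(sp$direct, 0)

  set.seed(7)
  tot <- runif(1000, 0, 2300)
  elv <- runif(1000, -10, 90)
  sp2 <- split_diffuse_direct(tot, elv, sample(365, 1000, TRUE))
  expect_equal(sp2$direct + sp2$diffuse, tot, tolerance = 1e-12)
  expect_true(all(sp2$direct >= 0 & sp2$diffuse >= 0))
  expect_true(all(sp2$direct[elv <= 0] == 0))

  # diffuse fraction non-increasing in clearness at fixed geometry
  tot_seq <- seq(10, 2000, by = 10)
  fd <- split_diffuse_direct(tot_seq, 50, 180)
  expect_true(all(diff(fd$diffuse / tot_seq) <= 1e-12))
})

test_that("longwave and NIR estimates behave physically", {
  # NIR split mirrors the PPFD split exactly
  r <- estimate_longwave_nir(1500, 25, 60, 55, 200)
  expect_equal(r$nir_direct_wm2 / (r$nir_direct_wm2 + r$nir_diffuse_wm2),
               r$ppfd_direct / 1500, tolerance = 1e-12)

  # longwave strictly increases with air temperature at fixed RH
  lw <- vapply(c(10, 15, 20, 25, 30),
               function(tt) estimate_longwave_nir(800, tt, 60, 45, 200)$longwave_wm2,
               numeric(1))
  expect_true(all(diff(lw) > 0))

  # clear sky: within 15% of the sigma * eps_clear * T^4 closed form with a
  # published clear-sky emissivity (Idso-Jackson form as the oracle)
  tk <- 293.15
  eps_ij <- 1 - 0.261 * exp(-7.77e-4 * (273.15 - tk)^2)
  oracle <- eps_ij * 5.670e-8 * tk^4
  clear <- estimate_longwave_nir(1900, 20, 50, 60, 172)$longwave_wm2
  expect_lt(abs(clear - oracle) / oracle, 0.15)

  expect_error(estimate_longwave_nir(800, 20, 150, 45, 200), "rh")
})

test_that("voxelization conserves leaf area and localizes single leaves", {
  sc <- small_scene(seed = 4)
  g <- voxelize(sc, 0.3)
  expect_equal(sum(g$lad) * 0.3^3, sum(sc$leaves$area_cm2) * 1e-4,
               tolerance = 1e-3 * sum(sc$leaves$area_cm2) * 1e-4)

  # a lone 50 cm^2 leaf in 1 m voxels: one occupied voxel, LAD 0.005
  m <- default_model()
  one <- small_scene(seed = 1, n = c(long = 1))
  one$leaves <- one$leaves[1, ]
  one$leaves$area_cm2 <- 50
  one$bbox <- rbind(c(0, 0, 0), c(1, 1, 1)) * 0 +
    rbind(unlist(one$leaves[1, c("ax", "ay", "az")]) - 0.05,
          unlist(one$leaves[1, c("ax", "ay", "az")]) + 0.05)
  g1 <- voxelize(one, 1)
  expect_equal(sum(g1$lad > 0), 1)
  expect_equal(max(g1$lad), 0.005, tolerance = 1e-12)

  # refinement and clip method leave the total invariant
  for (s in 1:10) {
    sci <- small_scene(seed = 100 + s, n = c(long = 4, short = 4, bourse = 2))
    tot <- sum(sci$leaves$area_cm2) * 1e-4
    expect_equal(sum(voxelize(sci, 0.3)$lad) * 0.3^3, tot, tolerance = 1e-9)
    expect_equal(sum(voxelize(sci, 0.15)$lad) * 0.15^3, tot, tolerance = 1e-9)
    expect_equal(sum(voxelize(sci, 0.3, method = "clip")$lad) * 0.3^3, tot,
                 tolerance = 1e-9)
  }
})

test_that("G-function limits and spherical value against a MC oracle", {
  expect_equal(g_function(0, 0, 90), 1, tolerance = 1e-9)
  expect_lt(g_function(0, 0, 0.01), 0.01)
  # vertical leaves, vertical beam: G = 0 analytically
  expect_lt(g_function(90, 0, 90), 1e-9)

  # Monte-Carlo oracle: random leaf normals + random beam azimuths
  set.seed(10)
  th <- acos(runif(20000)) * 180 / pi    # spherical normal distribution
  for (el in c(15, 45, 75)) {
    expect_equal(g_function(th, 0, el), 0.5, tolerance = 0.01)
  }
})

test_that("beam interception: empty grid, closed form, monotonicity", {
  g0 <- manual_grid(array(0, c(3, 3, 3)))
  b0 <- beam_interception(g0, 0, 60)
  expect_equal(b0$transmitted, b0$incident_power)
  expect_equal(sum(b0$intercepted), 0)

  # homogeneous slab, periodic wrap: T = exp(-G LAI / sin h) with
  # vertical normals (G = sin h), i.e. exp(-LAD * H)
  lad <- 1.1; dims <- c(4L, 4L, 6L); edge <- 0.25
  gh <- manual_grid(array(lad, dims), edge)
  for (el in c(90, 50, 25)) {
    bh <- beam_interception(gh, 77, el, lateral = "periodic")
    expect_equal(bh$transmitted / bh$incident_power, exp(-lad * dims[3] * edge),
                 tolerance = 1e-6)
  }

  # transmittance decreases monotonically with LAD
  trans <- vapply(c(0.2, 0.6, 1.2, 2.4), function(l) {
    b <- beam_interception(manual_grid(array(l, c(3, 3, 4))), 30, 55)
    b$transmitted / b$incident_power
  }, numeric(1))
  expect_true(all(diff(trans) < 0))

  expect_error(beam_interception(gh, 0, -5), "elevation")
})

test_that("irradiance field: dark step, thin-grid limit, isotropic sky", {
  sky <- sky_model()
  g <- manual_grid(array(0.5, c(2, 2, 2)))
  dark <- compute_irradiance(g, sky, list(ppfd_total = 0, doy = 200, hour = 2))
  expect_equal(sum(dark$abs_direct) + sum(dark$abs_diffuse), 0)

  # optically thin single voxel: absorbed ~ incident * G * LAD * path * abs
  thin_lad <- 0.01
  gt <- manual_grid(array(thin_lad, c(1, 1, 1)), edge = 0.5)
  bi <- beam_interception(gt, 0, 90, incident = 1000)
  first_order <- 1000 * 1 * thin_lad * 0.5 * (0.5 * 0.5)  # * footprint area
  expect_equal(sum(bi$intercepted), first_order, tolerance = first_order * 0.01)

  # 46-direction weights sum to 1 and an empty grid transmits the whole
  # isotropic sky onto the ground
  expect_equal(sum(sky$directions$weight), 1, tolerance = 1e-12)
  empty <- manual_grid(array(0, c(3, 3, 2)))
  dc <- precompute_diffuse(empty, sky, rays_per_edge = 4,
                           lateral = "periodic")
  expect_equal(dc$transmitted_frac, 1, tolerance = 0.03)
})

test_that("whole-canopy interception converges when the voxel edge halves", {
  # the convergence property is stated for foliage that satisfies the
  # turbid-medium assumption (locally homogeneous leaf area); a Poisson
  # leaf cloud probes exactly that regime
  sc <- poisson_leaf_cloud(n = 4000, seed = 1)
  sky <- sky_model()
  rec <- list(ppfd_total = 1600, doy = 200, hour = 12)
  frac <- vapply(c(0.3, 0.15), function(e) {
    g <- voxelize(sc, e)
    f <- compute_irradiance(g, sky, rec,
                            precompute_diffuse(g, sky, 2), rays_per_edge = 4)
    sum((f$abs_direct + f$abs_diffuse) * g$leaf_area)
  }, numeric(1))
  expect_lt(abs(frac[2] - frac[1]) / frac[1], 0.03)
})
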