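test_that("daily integration arithmetic and flags", {
  r <- integrate_day(rep(10, 48), rep(1, 48))
  expect_identical(r$A_c, 864)
  expect_identical(r$E_c, 86.4)
  expect_equal(r$WUE_c, 10)

  z <- integrate_day(rep(0, 48), rep(0, 48))
  expect_true(is.na(z$WUE_c))
  expect_equal(attr(z$WUE_c, "flag"), "E_c is zero")

  # integration is linear
  a <- rnorm(48, 5); e <- runif(48, 0, 2)
  r1 <- integrate_day(a, e)
  r3 <- integrate_day(3 * a, e)
  expect_equal(r3$A_c, 3 * r1$A_c, tolerance = 1e-12)

  expect_error(integrate_day(rep(1, 47), rep(1, 47)), "48")
})

test_that("day classification thresholds", {
  expect_equal(classify_day(50), "sunny")
  expect_equal(classify_day(10), "cloudy")
  expect_equal(classify_day(30), "intermediate")
  expect_equal(classify_day(c(45, 15)), c("intermediate", "intermediate"))
  expect_error(classify_day(-1), "PPFD_d")
})

test_that("night step: dark respiration only, no transpiration", {
  sc <- small_scene(seed = 2, n = c(long = 5, short = 5, bourse = 2))
  grid <- voxelize(sc, 0.3)
  sky <- sky_model()
  funcs <- default_funcs()
  occ <- which(grid$leaf_area > 0)
  vp <- scale_params_from_light(rep(30, length(occ)), funcs)
  rec <- list(ppfd_total = 0, air_temp = 18, rh = 80, wind = 1, doy = 200,
              hour = 1.25)
  s <- simulate_step(grid, funcs, rec, sky, voxel_params = vp,
                     config = fast_config())
  rd18 <- vp$Rd25[1] * canopyflux:::arrhenius(farquhar_constants()$Ea_Rd, 18)
  expect_equal(s$A_h, -rd18, tolerance = 1e-9)
  expect_equal(s$E_h, 0)
})

test_that("big-leaf identity: transparent single voxel equals leaf model", {
  grid <- manual_grid(array(1e-6, c(1, 1, 1)), edge = 1)
  sky <- sky_model()
  funcs <- default_funcs()
  vp <- scale_params_from_light(30, funcs)
  rec <- list(ppfd_total = 1400, air_temp = 26, rh = 55, wind = 1.5,
              doy = 200, hour = 12)
  s <- simulate_step(grid, funcs, rec, sky, voxel_params = vp,
                     diffuse_cache = precompute_diffuse(grid, sky, 4),
                     config = fast_config())
  # reconstruct the leaf-level forcing the step used and call the leaf model
  f <- compute_irradiance(grid, sky, rec, precompute_diffuse(grid, sky, 4),
                          rays_per_edge = 2)
  fs <- f$sunlit_fraction[1, 1, 1]
  p_sun <- f$abs_diffuse[1, 1, 1] + f$abs_direct[1, 1, 1] / fs
  p_sh <- f$abs_diffuse[1, 1, 1]
  vpd <- canopyflux:::svp_kpa(26) * (1 - 0.55)
  st_sun <- couple_leaf(p_sun, 26, vpd, funcs = funcs, N_a = vp$N_a)
  st_sh <- couple_leaf(p_sh, 26, vpd, funcs = funcs, N_a = vp$N_a)
  expect_equal(s$A_h, fs * st_sun$A_l + (1 - fs) * st_sh$A_l,
               tolerance = 1e-6)
  expect_equal(s$E_h, fs * st_sun$E_l + (1 - fs) * st_sh$E_l,
               tolerance = 1e-6)
})

test_that("per-leaf-area rates are invariant to uniform area scaling", {
  # optically thin canopy: doubling every leaf's area (and hence LAD)
  # leaves the per-leaf-area forcing, and so the per-leaf-area canopy
  # rates, essentially unchanged
  set.seed(17)
  lad <- array(runif(8, 1e-4, 3e-4), c(2, 2, 2))
  sky <- sky_model()
  funcs <- default_funcs()
  rec <- list(ppfd_total = 1000, air_temp = 24, rh = 60, wind = 1, doy = 200,
              hour = 10.25)
  g1 <- manual_grid(lad)
  occ <- which(g1$leaf_area > 0)
  vp <- scale_params_from_light(rep(30, length(occ)), funcs)
  s1 <- simulate_step(g1, funcs, rec, sky, voxel_params = vp,
                      config = fast_config())
  g2 <- manual_grid(lad * 2)
  s2 <- simulate_step(g2, funcs, rec, sky, voxel_params = vp,
                      config = fast_config())
  expect_equal(s2$A_h, s1$A_h, tolerance = 1e-4)
  expect_equal(s2$E_h, s1$E_h, tolerance = 1e-4)

  # normalization identity: canopy rate is the weight-averaged leaf rate
  expect_equal(s1$A_h,
               sum(s1$states$weight * s1$states$A_l) / sum(g1$leaf_area),
               tolerance = 1e-12)
})

test_that("canopy A_h never exceeds the full-light upper bound", {
  sc <- small_scene(seed = 9, n = c(long = 8, short = 6, bourse = 3))
  grid <- voxelize(sc, 0.3)
  sky <- sky_model()
  funcs <- default_funcs()
  occ <- which(grid$leaf_area > 0)
  cache <- precompute_diffuse(grid, sky, 1)
  ppfd_ref <- voxel_ppfd_day(grid, sky, 200, fast_config(), cache)
  vp <- scale_params_from_light(as.vector(ppfd_ref)[occ], funcs)
  rec <- list(ppfd_total = 1700, air_temp = 27, rh = 50, wind = 1.5,
              doy = 200, hour = 12.25)
  s <- simulate_step(grid, funcs, rec, sky, voxel_params = vp,
                     diffuse_cache = cache, config = fast_config())
  vpd <- canopyflux:::svp_kpa(27) * 0.5
  upper <- couple_leaf(1700 * 0.85, 27, vpd, funcs = funcs, N_a = max(vp$N_a))
  expect_lte(s$A_h, upper$A_l + 1e-9)
})

test_that("run_season closes the loop with the weather generator", {
  sc <- small_scene(seed = 3, n = c(long = 6, short = 5, bourse = 2))
  funcs <- default_funcs()
  w <- gen_weather(2, day_mix = c(sunny = 0.5, cloudy = 0.5,
                                  intermediate = 0), seed = 21)
  res <- run_season(sc, funcs, w, fast_config())
  expect_equal(nrow(res$days), 2)
  expect_setequal(res$days$class, c("sunny", "cloudy"))

  # deterministic re-run
  res2 <- run_season(sc, funcs, w, fast_config())
  expect_identical(res$days, res2$days)

  # the WUE column is the elementwise ratio
  expect_equal(res$days$WUE_c, res$days$A_c / res$days$E_c, tolerance = 1e-12)

  # gap detection
  expect_error(run_season(sc, funcs, w[-10, ], fast_config()), "gaps")
})
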