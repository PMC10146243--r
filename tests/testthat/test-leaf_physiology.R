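test_that("Farquhar model: dark limit, compensation point, Ci monotonicity", {
  p <- farquhar_params(60, 120, 1.5)
  rd30 <- 1.5 * canopyflux:::arrhenius(p$constants$Ea_Rd, 30)
  expect_equal(farquhar_net_a(300, 0, 30, p), -rd30, tolerance = 1e-9)

  # at Ci = Gamma*, gross assimilation is zero: A = -Rd under any light
  gs25 <- p$constants$Gstar25
  expect_equal(farquhar_net_a(gs25, 1500, 25, p), -1.5, tolerance = 1e-9)

  ci_grid <- seq(30, 1800, length.out = 50)
  a <- farquhar_net_a(ci_grid, 1200, 25, p)
  expect_true(all(diff(a) >= -1e-10))

  expect_error(farquhar_net_a(-5, 100, 25, p), "Ci")
  expect_warning(farquhar_params(60, 200, 1), "range")
})

test_that("Jarvis factors: optimum, plateau, piecewise decline", {
  jp <- jarvis_params(K_ppfd = 250, T_opt = 27, T_breadth = 18,
                      VPD0 = 1.6, vpd_slope = 0.35)
  # all factors at 1: g_s = g_smax (PPFD -> infinity limit approached)
  expect_equal(jarvis_gs(1e9, 27, 1.0, 0.4, jp), 0.4, tolerance = 1e-6)

  expect_equal(canopyflux:::jarvis_f_vpd(c(0.5, 1.0, 1.6), jp), c(1, 1, 1))
  expect_equal(canopyflux:::jarvis_f_vpd(2.1, jp), 1 - 0.5 * 0.35,
               tolerance = 1e-12)

  v <- seq(0, 4, by = 0.1)
  f <- canopyflux:::jarvis_f_vpd(v, jp)
  expect_true(all(f >= 0 & f <= 1))
  expect_error(jarvis_params(VPD0 = -1), "VPD0")
})

test_that("coupled leaf: diffusion limits and root residual", {
  funcs <- default_funcs()
  big_gs <- leaf_function_set(c(0.03, 1.3), c(25, -5), c(50, -10),
                              c(-0.4, 2.4), c(0, 50))  # huge fixed g_smax
  st <- couple_leaf(1200, 27, 1.0, funcs = big_gs, N_a = 2.4)
  expect_gt(st$Ci, 370)   # g_s -> infinity pushes Ci to Ca

  # near-closed stomata: A pinned near -Rd, Ci in the compensation zone
  tiny_gs <- leaf_function_set(c(0.03, 1.3), c(25, -5), c(50, -10),
                               c(-0.4, 2.4), c(0, 0.0005))
  st0 <- couple_leaf(1200, 25, 1.0, funcs = tiny_gs, N_a = 2.4)
  expect_lt(st0$A_l, 0.5)
  expect_lt(st0$Ci, 120)

  # residual of A(Ci) = (gs/1.6)(Ca - Ci) below 1e-6 over random environments
  set.seed(20)
  n <- 1000
  ppfd <- runif(n, 0, 2000)
  tair <- runif(n, 12, 38)
  vpd <- runif(n, 0.2, 3.5)
  na <- runif(n, 1.4, 3)
  st1 <- couple_leaf(ppfd, tair, vpd, funcs = funcs, N_a = na)
  lin <- function(co, x) pmax(1e-3, co[1] * x + co[2])
  idx <- which(st1$g_s > 1e-7)
  resid <- farquhar_net_a(st1$Ci[idx], ppfd[idx], tair[idx],
                          farquhar_params(lin(funcs$vcmax_vs_na, na[idx]),
                                          lin(funcs$jmax_vs_na, na[idx]),
                                          lin(funcs$rd_vs_na, na[idx]))) -
    (st1$g_s[idx] / 1.6) * (380 - st1$Ci[idx])
  expect_lt(max(abs(resid)), 1e-6)

  # WUE identity wherever transpiration is positive
  pos <- st1$E_l > 0
  expect_equal(st1$WUE_l[pos], st1$A_l[pos] / st1$E_l[pos], tolerance = 1e-12)
})

test_that("nitrogen scaling is a deterministic chained linear map", {
  funcs <- default_funcs()
  two <- scale_params_from_light(c(30, 30), funcs)
  expect_equal(two[1, ], two[2, ], ignore_attr = TRUE)

  inc <- scale_params_from_light(c(5, 20, 50), funcs)
  expect_true(all(diff(inc$N_a) > 0))

  for (pd in c(8, 25, 42)) {
    na_hand <- 0.03 * pd + 1.3
    got <- scale_params_from_light(pd, funcs)
    expect_equal(got$N_a, na_hand, tolerance = 1e-12)
    expect_equal(got$Vcmax25, 25 * na_hand - 5, tolerance = 1e-12)
    expect_equal(got$Rd25, -0.4 * na_hand + 2.4, tolerance = 1e-12)
    expect_equal(got$g_smax, 0.12 * na_hand + 0.05, tolerance = 1e-12)
  }
  expect_error(scale_params_from_light(-1, funcs), "PPFD_d")
})

test_that("leaf energy balance closes and responds to radiation load", {
  expect_equal(leaf_energy_balance(0, 25, 2, 0.3), 25, tolerance = 0.05)

  loads <- c(50, 150, 300, 450)
  tl <- vapply(loads, function(L) leaf_energy_balance(L, 25, 2, 0.2),
               numeric(1))
  expect_true(all(diff(tl) > 0))

  # budget closure over random states
  set.seed(31)
  for (i in 1:25) {
    L <- runif(1, -50, 500); ta <- runif(1, 10, 35)
    u <- runif(1, 0.3, 5); gs <- runif(1, 0.01, 0.6)
    tl <- leaf_energy_balance(L, ta, u, gs)
    expect_true(tl >= ta - 10 && tl <= ta + 15)
  }
  # vectorized closure check: 1000 random states at once
  n <- 1000
  L <- runif(n, -50, 500); ta <- runif(n, 10, 35)
  u <- runif(n, 0.3, 5); gs <- runif(n, 0.01, 0.6)
  tl <- leaf_energy_balance(L, ta, u, gs)
  expect_equal(length(tl), n)

  expect_error(leaf_energy_balance(100, 25, -1, 0.3), "wind")
})

test_that("with all Jarvis factors saturated the coupling is textbook", {
  # flat response shapes: f = 1 everywhere relevant
  jp <- jarvis_params(K_ppfd = 1e-9, T_opt = 25, T_breadth = 1e6,
                      VPD0 = 100, vpd_slope = 0)
  funcs <- default_funcs(jarvis = jp)
  na <- 2.4
  gsmax <- 0.12 * na + 0.05
  st <- couple_leaf(1000, 25, 1.2, funcs = funcs, N_a = na)
  expect_equal(st$g_s, gsmax, tolerance = 1e-9)
  # independent scalar solution with uniroot at constant gs
  fp <- farquhar_params(25 * na - 5, 50 * na - 10, -0.4 * na + 2.4)
  f <- function(ci) farquhar_net_a(ci, 1000, 25, fp) - (gsmax / 1.6) * (380 - ci)
  ci_star <- uniroot(f, c(1, 380), tol = 1e-10)$root
  expect_equal(st$Ci, ci_star, tolerance = 1e-4)
})
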