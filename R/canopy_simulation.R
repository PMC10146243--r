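#' Simulation configuration
#'
#' Knobs of the canopy simulation engine with their defaults: voxel edge
#' 0.3 m (resolves a 3-3.5 m crown into about ten layers), leaf PAR
#' absorptance 0.85 with scattering neglected, site latitude 34.5 N
#' (configurable; only the site altitude is known), ambient CO2
#' 380 umol mol^-1, and ray supersampling factors for the direct beam and
#' the 46-direction diffuse sky.
#'
#' @param voxel_edge Voxel edge length (m).
#' @param absorptance Leaf PAR absorptance.
#' @param latitude,longitude Site coordinates (deg).
#' @param Ca Ambient CO2 (umol mol^-1).
#' @param rays_per_edge Direct-beam ray supersampling per voxel edge.
#' @param diffuse_rays Ray supersampling for the diffuse precomputation.
#' @param energy_balance Couple the leaf energy budget?
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(voxel_edge = 0.3, absorptance = 0.85, latitude = 34.5,
                       longitude = 0, Ca = 380, rays_per_edge = 2,
                       diffuse_rays = 2, energy_balance = FALSE) {
  structure(list(voxel_edge = voxel_edge, absorptance = absorptance,
                 latitude = latitude, longitude = longitude, Ca = Ca,
                 rays_per_edge = rays_per_edge, diffuse_rays = diffuse_rays,
                 energy_balance = energy_balance), class = "sim_config")
}

#' Per-voxel daily light climate on a clear reference day
#'
#' Computes each voxel's daily cumulated absorbed PPFD per unit leaf area
#' (mol m^-2 d^-1) for an idealized clear day (clearness index 0.75) at the
#' given day of year. This static light climate drives the nitrogen
#' gradient: leaf nitrogen acclimates slowly relative to the simulated
#' window, so per-voxel biochemical parameters are computed once at season
#' start from this reference day and held fixed.
#'
#' @param grid A `voxel_grid`.
#' @param sky A [sky_model()].
#' @param doy Reference day of year.
#' @param config A [sim_config()].
#' @param diffuse_cache Optional [precompute_diffuse()] result.
#' @return A 3D array of PPFD_d (mol m^-2 d^-1) per voxel.
#' @export
voxel_ppfd_day <- function(grid, sky, doy = 190, config = sim_config(),
                           diffuse_cache = NULL) {
  if (is.null(diffuse_cache)) {
    diffuse_cache <- precompute_diffuse(grid, sky, config$diffuse_rays)
  }
  hours <- seq(0.25, 23.75, by = 0.5)
  acc <- array(0, dim = grid$dim)
  for (h in hours) {
    el <- solar_position(sky$latitude, sky$longitude, doy, h)["elevation"]
    if (el <= 0) next
    ppfd <- 2760 * 0.75 * (1 + 0.033 * cos(2 * pi * doy / 365)) *
      sin(deg2rad(el))
    rec <- list(ppfd_total = ppfd, doy = doy, hour = h)
    f <- compute_irradiance(grid, sky, rec, diffuse_cache,
                            absorptance = config$absorptance,
                            rays_per_edge = config$rays_per_edge)
    acc <- acc + (f$abs_direct + f$abs_diffuse) * 1800 * 1e-6
  }
  acc
}

#' Simulate one half-hour step of canopy gas exchange
#'
#' Per occupied voxel, leaves are split into a sunlit class (absorbed
#' direct plus diffuse PPFD) and a shaded class (diffuse only), weighted by
#' the voxel's sunlit leaf-area fraction. Each class is run through the
#' coupled Farquhar-Jarvis leaf model with the voxel's nitrogen-scaled
#' parameters, and the canopy instantaneous rates are the leaf-area-weighted
#' means per unit leaf area.
#'
#' @param grid A `voxel_grid`.
#' @param funcs A [leaf_function_set()].
#' @param record One weather row (`ppfd_total`, `air_temp`, `rh`, `wind`,
#'   `doy`, `hour`).
#' @param sky A [sky_model()].
#' @param voxel_params Data.frame from [scale_params_from_light()] for the
#'   occupied voxels (in `which(leaf_area > 0)` order); computed on the fly
#'   if `NULL`.
#' @param diffuse_cache Optional [precompute_diffuse()] result.
#' @param config A [sim_config()].
#' @return A list: `A_h` (umol m^-2 leaf s^-1), `E_h` (mmol m^-2 leaf
#'   s^-1), `states` (per-voxel-and-class leaf states with weights).
#' @export
simulate_step <- function(grid, funcs, record, sky, voxel_params = NULL,
                          diffuse_cache = NULL, config = sim_config()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(funcs, "leaf_function_set"))
  occ <- which(grid$leaf_area > 0)
  if (!length(occ)) stop("simulate_step: grid has no leaf area")
  if (is.null(voxel_params)) {
    ppfd_d <- voxel_ppfd_day(grid, sky, record$doy, config, diffuse_cache)
    voxel_params <- scale_params_from_light(as.vector(ppfd_d)[occ], funcs)
  }
  field <- compute_irradiance(grid, sky, record, diffuse_cache,
                              absorptance = config$absorptance,
                              rays_per_edge = config$rays_per_edge)
  la <- as.vector(grid$leaf_area)[occ]
  dif <- as.vector(field$abs_diffuse)[occ]
  dir_la <- as.vector(field$abs_direct)[occ]       # per total leaf area
  fs <- as.vector(field$sunlit_fraction)[occ]
  fs[dir_la <= 0] <- 0
  ppfd_sun <- dif + ifelse(fs > 1e-9, dir_la / pmax(fs, 1e-9), 0)
  ppfd_sh <- dif
  vpd_air <- max(0, svp_kpa(record$air_temp) * (1 - record$rh / 100))

  st_sun <- couple_leaf(ppfd_sun, record$air_temp, vpd_air, Ca = config$Ca,
                        funcs = funcs, N_a = voxel_params$N_a,
                        energy_balance = config$energy_balance,
                        wind = record$wind)
  st_sh <- couple_leaf(ppfd_sh, record$air_temp, vpd_air, Ca = config$Ca,
                       funcs = funcs, N_a = voxel_params$N_a,
                       energy_balance = config$energy_balance,
                       wind = record$wind)
  w_sun <- la * fs
  w_sh <- la * (1 - fs)
  tot <- sum(la)
  A_h <- sum(w_sun * st_sun$A_l + w_sh * st_sh$A_l) / tot
  E_h <- sum(w_sun * st_sun$E_l + w_sh * st_sh$E_l) / tot
  st_sun$class <- "sunlit"; st_sun$weight <- w_sun; st_sun$voxel <- occ
  st_sh$class <- "shaded"; st_sh$weight <- w_sh; st_sh$voxel <- occ
  list(A_h = A_h, E_h = E_h, states = rbind(st_sun, st_sh))
}

#' Integrate half-hourly rates to daily totals
#'
#' Daily canopy photosynthesis and transpiration per unit leaf area from
#' the 48 half-hourly instantaneous rates:
#' \eqn{A_c = \sum A_h \cdot 30 \cdot 60 \cdot 10^{-3}} (mmol m^-2 d^-1)
#' and \eqn{E_c = \sum E_h \cdot 30 \cdot 60 \cdot 10^{-3}} (mol m^-2
#' d^-1); daily water-use efficiency is their ratio.
#'
#' @param A_h 48 instantaneous canopy photosynthesis rates
#'   (umol m^-2 s^-1).
#' @param E_h 48 instantaneous transpiration rates (mmol m^-2 s^-1).
#' @return A list: `A_c`, `E_c`, `WUE_c` (`NA` with a flag attribute when
#'   E_c is 0).
#' @export
integrate_day <- function(A_h, E_h) {
  if (length(A_h) != 48 || length(E_h) != 48) {
    stop("integrate_day: need exactly 48 half-hourly steps per day")
  }
  A_c <- sum(A_h * 30 * 60 * 1e-3)
  E_c <- sum(E_h * 30 * 60 * 1e-3)
  wue <- if (E_c > 0) A_c / E_c else structure(NA_real_, flag = "E_c is zero")
  list(A_c = A_c, E_c = E_c, WUE_c = wue)
}

#' Classify a day by its light integral
#'
#' Days with a daily cumulated PPFD above 45 mol m^-2 d^-1 are sunny,
#' below 15 cloudy, and in between intermediate (the latter are retained in
#' outputs but excluded from sunny/cloudy contrasts).
#'
#' @param PPFD_d Daily cumulated incident PPFD (mol m^-2 d^-1, >= 0).
#'   Vectorized.
#' @return Character vector: `"sunny"`, `"cloudy"` or `"intermediate"`.
#' @export
classify_day <- function(PPFD_d) {
  if (any(PPFD_d < 0)) stop("classify_day: PPFD_d must be >= 0")
  ifelse(PPFD_d > 45, "sunny", ifelse(PPFD_d < 15, "cloudy", "intermediate"))
}

#' Run a multi-day canopy simulation
#'
#' The season engine: voxelize the (static) scene once, precompute the
#' diffuse interception geometry and the per-voxel nitrogen-scaled
#' parameters from a clear reference day, then loop over the half-hourly
#' weather driving radiation and leaf gas exchange, integrating each day
#' and classifying it by light integral.
#'
#' @param scene A `canopy_scene`.
#' @param funcs A [leaf_function_set()].
#' @param weather A `weather_series` covering whole days (48 steps each).
#' @param config A [sim_config()].
#' @return A list of class `simulation_result`: `steps` (per-step
#'   data.frame: `doy`, `hour`, `A_h`, `E_h`), `days` (per-day: `doy`,
#'   `A_c`, `E_c`, `WUE_c`, `PPFD_d`, `class`), `label`.
#' @export
run_season <- function(scene, funcs, weather, config = sim_config()) {
  stopifnot(inherits(scene, "canopy_scene"))
  days <- split(weather, weather$doy)
  nsteps <- vapply(days, nrow, integer(1))
  if (any(nsteps != 48)) {
    stop("run_season: weather has gaps; days with != 48 steps: ",
         paste(names(days)[nsteps != 48], collapse = ", "))
  }
  doys <- as.integer(names(days))
  if (any(diff(sort(doys)) != 1)) {
    stop("run_season: weather days are not consecutive")
  }
  grid <- voxelize(scene, edge = config$voxel_edge)
  sky <- sky_model(config$latitude, config$longitude)
  cache <- precompute_diffuse(grid, sky, config$diffuse_rays)
  occ <- which(grid$leaf_area > 0)
  ppfd_d_ref <- voxel_ppfd_day(grid, sky, min(doys), config, cache)
  vparams <- scale_params_from_light(as.vector(ppfd_d_ref)[occ], funcs)

  step_rows <- vector("list", length(days))
  day_rows <- vector("list", length(days))
  for (k in seq_along(days)) {
    w <- days[[k]]
    w <- w[order(w$hour), ]
    A_h <- numeric(48); E_h <- numeric(48)
    for (i in seq_len(48)) {
      s <- simulate_step(grid, funcs, w[i, ], sky, voxel_params = vparams,
                         diffuse_cache = cache, config = config)
      A_h[i] <- s$A_h; E_h[i] <- s$E_h
    }
    daily <- integrate_day(A_h, E_h)
    ppfd_d <- sum(w$ppfd_total) * 1800 * 1e-6
    step_rows[[k]] <- data.frame(doy = w$doy, hour = w$hour, A_h = A_h,
                                 E_h = E_h)
    day_rows[[k]] <- data.frame(doy = w$doy[1], A_c = daily$A_c,
                                E_c = daily$E_c,
                                WUE_c = as.numeric(daily$WUE_c),
                                PPFD_d = ppfd_d,
                                class = classify_day(ppfd_d))
  }
  structure(list(steps = do.call(rbind, step_rows),
                 days = do.call(rbind, day_rows),
                 label = funcs$label),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation result (%s): %d days\n", x$label, nrow(x$days)))
  print(x$days, row.names = FALSE)
  invisible(x)
}
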