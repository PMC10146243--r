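# Shared fixtures: all built in code at test time.

default_model <- function() {
  allometric_model(9, 20, 0.35, 2, 0.62, 0.7, 0.2, 0.3, 0.5)
}

default_funcs <- function(label = "VD Fuji",
                          jarvis = jarvis_params()) {
  leaf_function_set(na_vs_ppfdd = c(0.03, 1.3),
                    vcmax_vs_na = c(25, -5),
                    jmax_vs_na = c(50, -10),
                    rd_vs_na = c(-0.4, 2.4),
                    gsmax_vs_na = c(0.12, 0.05),
                    jarvis = jarvis, label = label)
}

small_scene <- function(seed = 7, n = c(long = 10, short = 10, bourse = 5)) {
  sh <- gen_shoot_skeleton(list(crown_center = c(0, 0, 1.5),
                                crown_radii = c(0.6, 0.6, 1.0),
                                n_shoots = n), seed = seed)
  assemble_canopy(sh, default_model(), seed = seed)
}

# Hand-built voxel grid with prescribed LAD and all leaf normals vertical
# (so the projection coefficient is exactly sin(beam elevation)).
manual_grid <- function(lad, edge = 0.3) {
  dims <- dim(lad)
  nv <- prod(dims)
  structure(list(origin = c(0, 0, 0), edge = edge, dim = dims, lad = lad,
                 leaf_area = lad * edge^3,
                 patch_voxel = seq_len(nv), patch_area = rep(1, nv),
                 patch_normal = matrix(rep(c(0, 0, 1), each = nv), ncol = 3),
                 total_area = sum(lad) * edge^3),
            class = "voxel_grid")
}

# Independent Monte-Carlo ray-casting oracle: jittered-stratified ray
# origins on the top face, fixed-step marching with horizontal wrap.
# Returns per-voxel intercepted fraction of the incident power.
mc_interception_oracle <- function(grid, azimuth, elevation, n_side = 316,
                                   ds = 0.005) {
  dims <- grid$dim; edge <- grid$edge; nv <- prod(dims)
  d <- -c(sin(azimuth * pi / 180) * cos(elevation * pi / 180),
          cos(azimuth * pi / 180) * cos(elevation * pi / 180),
          sin(elevation * pi / 180))
  nray <- n_side^2
  Lx <- dims[1] * edge; Ly <- dims[2] * edge; ztop <- dims[3] * edge
  gx <- (rep(seq_len(n_side), n_side) - runif(nray)) / n_side * Lx
  gy <- (rep(seq_len(n_side), each = n_side) - runif(nray)) / n_side * Ly
  sig <- sin(elevation * pi / 180) * as.vector(grid$lad)
  P <- rep(sin(elevation * pi / 180) * Lx * Ly / nray, nray)
  P0 <- sum(P)
  dep <- numeric(nv)
  x <- gx; y <- gy; z <- rep(ztop, nray)
  nstep <- ceiling(ztop / (abs(d[3]) * ds))
  for (s in seq_len(nstep)) {
    xm <- (x + d[1] * ds / 2) %% Lx
    ym <- (y + d[2] * ds / 2) %% Ly
    zm <- z + d[3] * ds / 2
    alive <- zm > 0
    if (!any(alive)) break
    ix <- pmin(floor(xm / edge), dims[1] - 1)
    iy <- pmin(floor(ym / edge), dims[2] - 1)
    iz <- pmin(floor(zm / edge), dims[3] - 1)
    idx <- 1 + ix + dims[1] * (iy + dims[2] * iz)
    tr <- exp(-sig[idx] * ds)
    dint <- ifelse(alive, P * (1 - tr), 0)
    acc <- rowsum(dint[alive], idx[alive])
    ui <- as.integer(rownames(acc))
    dep[ui] <- dep[ui] + acc[, 1]
    P <- ifelse(alive, P * tr, P)
    x <- x + d[1] * ds; y <- y + d[2] * ds; z <- z + d[3] * ds
  }
  dep / P0
}

# One synthetic day of 48 half-hour weather rows with a constant-shape
# clear diurnal course scaled to a target light integral.
flat_day <- function(doy = 200, target_mol = 50, latitude = 34.5,
                     air_temp = 25, rh = 55, wind = 1.5) {
  hours <- seq(0.25, 23.75, by = 0.5)
  elev <- vapply(hours, function(h) {
    solar_position(latitude, 0, doy, h)["elevation"]
  }, numeric(1))
  shape <- pmax(0, sin(pmax(elev, 0) * pi / 180))
  shape[elev <= 0] <- 0
  ppfd <- shape * target_mol / (sum(shape) * 1800 * 1e-6)
  data.frame(timestamp = as.POSIXct("2013-01-01", tz = "UTC") +
               (doy - 1) * 86400 + hours * 3600,
             doy = doy, hour = hours, ppfd_total = ppfd,
             air_temp = air_temp, rh = rh, wind = wind,
             day_class = "synthetic")
}

fast_config <- function(...) {
  sim_config(rays_per_edge = 2, diffuse_rays = 1, ...)
}

# Quasi-homogeneous canopy: small horizontal leaves at uniform random
# positions in a 1.5 m cube (the regime where the turbid-medium
# homogenization is exact in the limit).
poisson_leaf_cloud <- function(n = 4000, seed = 1, box = 1.5,
                               area_cm2 = 20) {
  set.seed(seed)
  ctr <- cbind(runif(n, 0, box), runif(n, 0, box), runif(n, 0, box))
  half <- sqrt(area_cm2 * 1e-4) / 2
  V <- cbind(ctr[, 1] - half, ctr[, 2] - half, ctr[, 3],
             ctr[, 1] + half, ctr[, 2] - half, ctr[, 3],
             ctr[, 1] + half, ctr[, 2] + half, ctr[, 3],
             ctr[, 1] - half, ctr[, 2] + half, ctr[, 3],
             ctr[, 1] - half, ctr[, 2], ctr[, 3],
             ctr[, 1], ctr[, 2], ctr[, 3])
  colnames(V) <- paste0("v", rep(1:6, each = 3), c("x", "y", "z"))
  lv <- data.frame(shoot_id = seq_len(n), node_rank = 1, area_cm2 = area_cm2,
                   azimuth = 0, elevation = 0, rolling = 0, petiole_cm = 1,
                   ax = ctr[, 1], ay = ctr[, 2], az = ctr[, 3],
                   nx = 0, ny = 0, nz = 1, V)
  structure(list(leaves = lv, tree_spacing = c(2, 3.5),
                 bbox = rbind(c(0, 0, 0), rep(box, 3))),
            class = "canopy_scene")
}
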