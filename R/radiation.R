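#' Solar position
#'
#' Elevation and azimuth of the sun from standard astronomical formulas
#' (Spencer's Fourier series for the solar declination, spherical
#' trigonometry for the hour angle). Time is local solar time, so longitude
#' enters only through the caller's conversion from clock time; it is kept
#' in the signature for completeness.
#'
#' @param latitude Latitude (deg, positive North).
#' @param longitude Longitude (deg, positive East); unused under solar time.
#' @param doy Day of year (1-366).
#' @param solar_hour Local solar time (h, 0-24; 12 = solar noon).
#' @return Named vector: `elevation` (deg above horizon, negative at night)
#'   and `azimuth` (deg clockwise from North).
#' @export
solar_position <- function(latitude, longitude = 0, doy, solar_hour) {
  if (any(doy < 1 | doy > 366)) stop("solar_position: doy must be in [1, 366]")
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)   # radians (Spencer 1971)
  phi <- deg2rad(latitude)
  H <- deg2rad(15 * (solar_hour - 12))
  sin_el <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(H)
  el <- asin(pmin(1, pmax(-1, sin_el)))
  east <- -cos(decl) * sin(H)
  north <- cos(phi) * sin(decl) - sin(phi) * cos(decl) * cos(H)
  az <- (rad2deg(atan2(east, north))) %% 360
  c(elevation = rad2deg(el), azimuth = az)
}

#' Discretized sky for diffuse radiation
#'
#' The canonical 46-direction "turtle" discretization of the sky vault used
#' in voxel canopy radiation models: eight elevation rings with 10, 5, 5,
#' 10, 5, 5, 5 directions plus the zenith. Direction weights are the
#' fraction of horizontal diffuse irradiance carried by each sector under a
#' uniform-overcast radiance, computed by numerical integration of
#' `sin(e) cos(e)` over the spherical Voronoi cell of each direction; they
#' sum to 1 exactly.
#'
#' @param latitude,longitude Site coordinates (deg) carried along for solar
#'   position; latitude defaults to 34.5 N and should be set to the actual
#'   site when known.
#' @return A list of class `sky_model`: `directions` (data.frame with
#'   `elevation`, `azimuth`, `weight`), `latitude`, `longitude`.
#' @export
sky_model <- function(latitude = 34.5, longitude = 0) {
  ring_elev <- c(9.23, 10.81, 26.57, 31.08, 47.41, 52.62, 69.16, 90)
  ring_n <- c(10, 5, 5, 10, 5, 5, 5, 1)
  ring_off <- c(0, 36, 0, 18, 36, 0, 36, 0)
  dirs <- do.call(rbind, lapply(seq_along(ring_elev), function(i) {
    data.frame(elevation = ring_elev[i],
               azimuth = (ring_off[i] + (0:(ring_n[i] - 1)) * 360 / ring_n[i]) %% 360)
  }))
  # unit vectors of the 46 directions
  U <- t(apply(dirs, 1, function(r) dir_vector(r["azimuth"], r["elevation"])))
  # fine hemisphere grid; assign each cell to its nearest direction
  e_grid <- seq(0.5, 89.5, by = 1)
  a_grid <- seq(0.5, 359.5, by = 1)
  cells <- expand.grid(a = a_grid, e = e_grid)
  V <- cbind(sin(deg2rad(cells$a)) * cos(deg2rad(cells$e)),
             cos(deg2rad(cells$a)) * cos(deg2rad(cells$e)),
             sin(deg2rad(cells$e)))
  nearest <- max.col(V %*% t(U))
  # horizontal-flux weight of each cell under uniform radiance:
  # dPhi ~ sin(e) * cos(e) de da
  wcell <- sin(deg2rad(cells$e)) * cos(deg2rad(cells$e))
  w <- vapply(seq_len(nrow(dirs)), function(i) sum(wcell[nearest == i]),
              numeric(1))
  dirs$weight <- w / sum(w)
  structure(list(directions = dirs, latitude = latitude,
                 longitude = longitude), class = "sky_model")
}

#' Partition total PPFD into direct and diffuse
#'
#' Clearness-index piecewise model in the Spitters et al. (1986) hourly
#' form: the diffuse fraction is 1 in the overcast regime (clearness index
#' kt <= 0.22), falls smoothly through the intermediate regimes, and
#' plateaus at the clear-sky residual fraction that depends on solar
#' elevation. Direct + diffuse always equals the input exactly, and all
#' radiation is diffuse when the sun is below the horizon.
#'
#' @param ppfd_total Measured total horizontal PPFD (umol m^-2 s^-1, >= 0).
#' @param solar_elevation Solar elevation (deg).
#' @param doy Day of year (for the sun-earth distance factor).
#' @return A list with `direct` and `diffuse` (umol m^-2 s^-1) and the
#'   clearness index `kt`.
#' @export
split_diffuse_direct <- function(ppfd_total, solar_elevation, doy) {
  if (any(ppfd_total < 0)) stop("split_diffuse_direct: ppfd_total must be >= 0")
  n <- max(length(ppfd_total), length(solar_elevation))
  ppfd_total <- rep_len(ppfd_total, n)
  solar_elevation <- rep_len(solar_elevation, n)
  doy <- rep_len(doy, n)
  sin_h <- sin(deg2rad(pmax(solar_elevation, 0)))
  # extraterrestrial horizontal PPFD; 2760 umol m^-2 s^-1 at normal incidence
  S0 <- 2760 * (1 + 0.033 * cos(2 * pi * doy / 365)) * sin_h
  kt <- ifelse(S0 > 0, pmin(ppfd_total / S0, 1.2), 0)
  R <- 0.847 - 1.61 * sin_h + 1.04 * sin_h^2
  ktu <- (1.47 - R) / 1.66
  fd <- ifelse(kt <= 0.22, 1,
        ifelse(kt <= 0.35, 1 - 6.4 * (kt - 0.22)^2,
        ifelse(kt <= ktu, 1.47 - 1.66 * kt, R)))
  fd[solar_elevation <= 0] <- 1
  fd <- pmin(1, pmax(0, fd))
  diffuse <- fd * ppfd_total
  list(direct = ppfd_total - diffuse, diffuse = diffuse, kt = kt)
}

#' Atmospheric longwave and near-infrared radiation
#'
#' Longwave from a clear-sky emissivity formula (Brutsaert 1975, driven by
#' vapour pressure and air temperature) modulated by cloudiness inferred
#' from the clearness index (Crawford & Duchon 1999 form). NIR is derived
#' from the PAR energy flux assuming PAR is 48% of total shortwave, and is
#' split into direct and diffuse in exactly the same ratio as PPFD.
#'
#' @param ppfd_total Total horizontal PPFD (umol m^-2 s^-1).
#' @param air_temp Air temperature (degC).
#' @param rh Relative humidity in percent (0 to 100).
#' @param solar_elevation Solar elevation (deg).
#' @param doy Day of year.
#' @return List: `longwave_wm2`, `nir_direct_wm2`, `nir_diffuse_wm2`,
#'   `ppfd_direct`, `ppfd_diffuse`, `emissivity`.
#' @export
estimate_longwave_nir <- function(ppfd_total, air_temp, rh, solar_elevation,
                                  doy) {
  if (any(rh < 0 | rh > 100)) stop("estimate_longwave_nir: rh must be in [0, 100]")
  sp <- split_diffuse_direct(ppfd_total, solar_elevation, doy)
  Tk <- air_temp + 273.15
  ea_hpa <- 10 * svp_kpa(air_temp) * rh / 100   # vapour pressure, hPa
  eps_clear <- 1.24 * (ea_hpa / Tk)^(1 / 7)
  s <- pmin(1, sp$kt / 0.75)                    # sunshine fraction proxy
  s[solar_elevation <= 0] <- 0.5                # night: assume broken cloud
  clf <- 1 - s
  eps <- pmin(1, clf + (1 - clf) * eps_clear)
  lw <- eps * 5.670e-8 * Tk^4
  par_wm2 <- ppfd_total / 4.57
  nir_tot <- par_wm2 * (1 - 0.48) / 0.48
  fdir <- ifelse(ppfd_total > 0, sp$direct / ppfd_total, 0)
  list(longwave_wm2 = lw, nir_direct_wm2 = nir_tot * fdir,
       nir_diffuse_wm2 = nir_tot * (1 - fdir),
       ppfd_direct = sp$direct, ppfd_diffuse = sp$diffuse, emissivity = eps)
}

#' Discretize a canopy scene into a voxel grid
#'
#' Builds the turbid-medium representation: per-voxel leaf area density
#' (m^2 m^-3) on a regular grid aligned with the scene bounding box. Leaves
#' are assigned to voxels by their centroid (default) or by splitting their
#' area across voxels using a deterministic dense point sampling of each
#' hexagon (`method = "clip"`). Per-leaf areas and unit normals are carried
#' along so the projection coefficient (G-function) can be evaluated per
#' voxel and per direction from the actual leaf orientations.
#'
#' @param scene A `canopy_scene`.
#' @param edge Voxel edge length (m, > 0), default 0.3.
#' @param method `"centroid"` or `"clip"`.
#' @return A list of class `voxel_grid`: `origin`, `edge`, `dim` (nx,ny,nz),
#'   `lad` (3D array, m^2 m^-3), `leaf_area` (3D array, m^2), `patch_voxel`
#'   (voxel index per leaf patch), `patch_area` (m^2), `patch_normal`
#'   (matrix), `total_area`.
#' @export
voxelize <- function(scene, edge = 0.3, method = c("centroid", "clip")) {
  stopifnot(inherits(scene, "canopy_scene"))
  method <- match.arg(method)
  if (edge <= 0) stop("voxelize: edge must be > 0")
  lv <- scene$leaves
  if (nrow(lv) == 0 || any(!is.finite(scene$bbox))) {
    stop("voxelize: degenerate scene bounding box")
  }
  span <- scene$bbox[2, ] - scene$bbox[1, ]
  if (any(span <= 0)) span[span <= 0] <- edge
  pad <- 1e-6
  origin <- scene$bbox[1, ] - pad
  dims <- pmax(1L, as.integer(ceiling((span + 2 * pad) / edge)))

  vx <- as.matrix(lv[, paste0("v", 1:6, "x")])
  vy <- as.matrix(lv[, paste0("v", 1:6, "y")])
  vz <- as.matrix(lv[, paste0("v", 1:6, "z")])
  if (method == "centroid") {
    pts <- cbind(rowMeans(vx), rowMeans(vy), rowMeans(vz))
    areas <- lv$area_cm2 * 1e-4
    normals <- as.matrix(lv[, c("nx", "ny", "nz")])
  } else {
    # deterministic splitting: sample each hexagon on a barycentric fan grid
    bary <- expand.grid(u = seq(0.1, 0.9, by = 0.2), v = seq(0.1, 0.9, by = 0.2))
    bary <- bary[bary$u + bary$v < 1, ]
    pts_list <- vector("list", nrow(lv))
    for (i in seq_len(nrow(lv))) {
      cx <- mean(vx[i, ]); cy <- mean(vy[i, ]); cz <- mean(vz[i, ])
      tri <- lapply(1:6, function(j) {
        j2 <- j %% 6 + 1
        p1 <- c(vx[i, j], vy[i, j], vz[i, j])
        p2 <- c(vx[i, j2], vy[i, j2], vz[i, j2])
        p0 <- c(cx, cy, cz)
        t(apply(bary, 1, function(b) {
          p0 + b[["u"]] * (p1 - p0) + b[["v"]] * (p2 - p0)
        }))
      })
      pts_list[[i]] <- do.call(rbind, tri)
    }
    npt <- nrow(pts_list[[1]])
    pts <- do.call(rbind, pts_list)
    areas <- rep(lv$area_cm2 * 1e-4 / npt, each = npt)
    normals <- as.matrix(lv[rep(seq_len(nrow(lv)), each = npt),
                            c("nx", "ny", "nz")])
  }
  ijk <- sweep(pts, 2, origin, `-`) / edge
  ijk <- pmin(pmax(floor(ijk), 0), matrix(rep(dims - 1L, each = nrow(ijk)),
                                          ncol = 3))
  idx <- 1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])

  leaf_area <- array(0, dim = dims)
  acc <- rowsum(areas, idx)
  leaf_area[as.integer(rownames(acc))] <- acc[, 1]
  structure(list(origin = origin, edge = edge, dim = dims,
                 lad = leaf_area / edge^3, leaf_area = leaf_area,
                 patch_voxel = as.integer(idx), patch_area = areas,
                 patch_normal = normals, total_area = sum(areas)),
            class = "voxel_grid")
}

# Per-voxel projection coefficient toward a direction, from the actual leaf
# normals in each voxel: G_v = sum(area_i |n_i . u|) / sum(area_i).
voxel_g <- function(grid, azimuth, elevation) {
  u <- dir_vector(azimuth, elevation)
  proj <- abs(grid$patch_normal %*% u)[, 1] * grid$patch_area
  g <- rep(0.5, prod(grid$dim))
  num <- rowsum(proj, grid$patch_voxel)
  den <- rowsum(grid$patch_area, grid$patch_voxel)
  g[as.integer(rownames(num))] <- num[, 1] / den[, 1]
  g
}

#' Leaf-angle projection coefficient (G-function)
#'
#' Mean projection of unit leaf area onto the plane normal to a beam, for
#' leaves of given inclination with azimuthally uniform orientation. With a
#' numeric vector input the values are leaf-normal zenith angles (deg) with
#' equal weight; with an [angle_distribution()] the pooled elevation
#' histogram is used (leaf-normal zenith = |midrib elevation|, the planar
#' hexagon approximation). The azimuthal average is computed by direct
#' numerical integration, so G is exact to quadrature accuracy for any
#' inclination; G always lies in \[0, 1\].
#'
#' @param angles Numeric vector of leaf-normal zenith angles (deg), or an
#'   `angle_distribution`.
#' @param azimuth,elevation Beam direction (deg); elevation must be > 0.
#' @return Scalar G.
#' @export
g_function <- function(angles, azimuth = 0, elevation = 90) {
  if (elevation <= 0) stop("g_function: beam elevation must be > 0")
  if (inherits(angles, "angle_distribution")) {
    h <- angles$elevation[[1]]
    mids <- abs((h$breaks[-1] + h$breaks[-length(h$breaks)]) / 2)
    wts <- h$prob
  } else {
    mids <- abs(angles)
    wts <- rep(1 / length(angles), length(angles))
  }
  phi <- seq(0, 2 * pi, length.out = 721)[-721]
  thn <- deg2rad(mids)
  sin_h <- sin(deg2rad(elevation))
  cos_h <- cos(deg2rad(elevation))
  g_each <- vapply(thn, function(t) {
    mean(abs(cos(t) * sin_h + sin(t) * cos_h * cos(phi)))
  }, numeric(1))
  sum(wts * g_each)
}

#' Beam interception through the voxel grid
#'
#' Propagates a parallel beam through the turbid medium with exact
#' Beer-Lambert attenuation: rays are spawned on a regular supersampled
#' entry plane above the grid, traversed voxel-by-voxel with the
#' Amanatides-Woo algorithm (vectorized across rays), and attenuated by
#' `exp(-G * LAD * path)` in each voxel. The flux decrement is deposited in
#' the voxel, so interception plus transmission equals the incident flux on
#' the grid footprint exactly (no scattering). With `lateral = "periodic"`
#' rays wrap around horizontally, emulating a laterally infinite canopy;
#' with the default `"open"` they exit freely (isolated tree).
#'
#' @param grid A `voxel_grid`.
#' @param azimuth,elevation Direction the radiation comes FROM (deg);
#'   elevation must be > 0.
#' @param incident Flux density per unit area normal to the beam (any unit;
#'   outputs share it). Must be >= 0.
#' @param lateral `"open"` or `"periodic"`.
#' @param rays_per_edge Rays spawned per voxel edge (supersampling factor).
#' @return A list: `intercepted` (3D array, power per voxel),
#'   `transmitted` (total exiting power), `incident_power` (power entering
#'   the footprint), `sunlit_fraction` (3D array: path-weighted mean beam
#'   transmittance reaching each voxel), `path_length` (3D array: total
#'   ray path per voxel, for diagnostics).
#' @export
beam_interception <- function(grid, azimuth, elevation, incident = 1,
                              lateral = c("open", "periodic"),
                              rays_per_edge = 4) {
  stopifnot(inherits(grid, "voxel_grid"))
  lateral <- match.arg(lateral)
  if (elevation <= 0) stop("beam_interception: beam elevation must be > 0")
  if (incident < 0) stop("beam_interception: incident must be >= 0")
  d <- -dir_vector(azimuth, elevation)         # propagation direction (down)
  nx <- grid$dim[1]; ny <- grid$dim[2]; nz <- grid$dim[3]
  edge <- grid$edge
  gvec <- voxel_g(grid, azimuth, elevation)
  sigma <- gvec * as.vector(grid$lad)          # extinction per unit path

  # spawn rays on the top plane; for the open case extend the footprint to
  # cover the horizontal drift of oblique rays
  sp <- edge / rays_per_edge
  zt <- grid$origin[3] + nz * edge
  H <- nz * edge
  drift_x <- if (d[3] != 0) abs(d[1] / d[3]) * H else 0
  drift_y <- if (d[3] != 0) abs(d[2] / d[3]) * H else 0
  if (lateral == "open") {
    x0 <- grid$origin[1] - (if (d[1] > 0) drift_x else 0)
    x1 <- grid$origin[1] + nx * edge + (if (d[1] < 0) drift_x else 0)
    y0 <- grid$origin[2] - (if (d[2] > 0) drift_y else 0)
    y1 <- grid$origin[2] + ny * edge + (if (d[2] < 0) drift_y else 0)
  } else {
    x0 <- grid$origin[1]; x1 <- grid$origin[1] + nx * edge
    y0 <- grid$origin[2]; y1 <- grid$origin[2] + ny * edge
  }
  xs <- seq(x0 + sp / 2, x1 - sp / 2 + 1e-12, by = sp)
  ys <- seq(y0 + sp / 2, y1 - sp / 2 + 1e-12, by = sp)
  org <- as.matrix(expand.grid(x = xs, y = ys))
  nray <- nrow(org)
  # power carried by one ray: flux through its horizontal cell
  ray_p0 <- incident * sin(deg2rad(elevation)) * sp * sp
  pos <- cbind(org[, 1], org[, 2], rep(zt, nray))

  # clip to grid entry: advance each ray to its AABB entry point
  lo <- grid$origin; hi <- grid$origin + grid$dim * edge
  t_entry <- rep(0, nray)
  if (lateral == "open") {
    for (ax in 1:2) {
      if (d[ax] > 0) t_entry <- pmax(t_entry, (lo[ax] - pos[, ax]) / d[ax])
      if (d[ax] < 0) t_entry <- pmax(t_entry, (hi[ax] - pos[, ax]) / d[ax])
    }
  }
  pos <- pos + outer(t_entry, c(1, 1, 1)) * matrix(d, nray, 3, byrow = TRUE)
  keep <- pos[, 1] >= lo[1] - 1e-9 & pos[, 1] <= hi[1] + 1e-9 &
    pos[, 2] >= lo[2] - 1e-9 & pos[, 2] <= hi[2] + 1e-9 &
    pos[, 3] >= lo[3] - 1e-9
  pos <- pos[keep, , drop = FALSE]
  nray <- nrow(pos)
  if (nray == 0) {
    z <- array(0, dim = grid$dim)
    return(list(intercepted = z, transmitted = 0, incident_power = 0,
                sunlit_fraction = z, path_length = z))
  }

  ijk <- pmin(pmax(floor(sweep(pos, 2, lo, `-`) / edge), 0),
              matrix(rep(grid$dim - 1L, each = nray), ncol = 3))
  stp <- sign(d)
  tdelta <- ifelse(d != 0, edge / abs(d), Inf)
  tmax <- matrix(Inf, nray, 3)
  for (ax in 1:3) {
    if (d[ax] != 0) {
      bnd <- lo[ax] + (ijk[, ax] + (stp[ax] > 0)) * edge
      tmax[, ax] <- (bnd - pos[, ax]) / d[ax]
    }
  }
  tcur <- rep(0, nray)
  P <- rep(ray_p0, nray)
  P0 <- P
  dep <- numeric(prod(grid$dim))
  wtrans <- numeric(prod(grid$dim))   # path-weighted transmittance numerator
  wpath <- numeric(prod(grid$dim))
  transmitted <- 0
  active <- rep(TRUE, nray)
  max_iter <- (nx + ny + nz) * (if (lateral == "periodic") 20L else 2L) + 10L

  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    ai <- which(active)
    idx <- 1L + ijk[ai, 1] + nx * (ijk[ai, 2] + ny * ijk[ai, 3])
    tnext <- pmin(tmax[ai, 1], tmax[ai, 2], tmax[ai, 3])
    len <- tnext - tcur[ai]
    len[len < 0] <- 0
    tr <- exp(-sigma[idx] * len)
    dint <- P[ai] * (1 - tr)
    add <- rowsum(cbind(dint, P[ai] * len, P0[ai] * len), idx)
    ui <- as.integer(rownames(add))
    dep[ui] <- dep[ui] + add[, 1]
    wtrans[ui] <- wtrans[ui] + add[, 2]
    wpath[ui] <- wpath[ui] + add[, 3]
    P[ai] <- P[ai] * tr
    tcur[ai] <- tnext
    # advance each ray across the face it hits first
    axsel <- max.col(-tmax[ai, , drop = FALSE], ties.method = "first")
    for (ax in 1:3) {
      sel <- ai[axsel == ax]
      if (!length(sel)) next
      ijk[sel, ax] <- ijk[sel, ax] + stp[ax]
      tmax[sel, ax] <- tmax[sel, ax] + tdelta[ax]
      if (lateral == "periodic" && ax <= 2) {
        ijk[sel, ax] <- ijk[sel, ax] %% grid$dim[ax]
      }
    }
    out <- ijk[, 1] < 0 | ijk[, 1] >= nx | ijk[, 2] < 0 | ijk[, 2] >= ny |
      ijk[, 3] < 0 | ijk[, 3] >= nz
    done <- active & out
    if (any(done)) {
      transmitted <- transmitted + sum(P[done])
      active[done] <- FALSE
    }
  }
  transmitted <- transmitted + sum(P[active])   # safety: unfinished rays

  sunlit <- ifelse(wpath > 0, wtrans / wpath, 0)
  list(intercepted = array(dep, dim = grid$dim),
       transmitted = transmitted,
       incident_power = sum(P0),
       sunlit_fraction = array(pmin(1, sunlit), dim = grid$dim),
       path_length = array(wpath, dim = grid$dim))
}

#' Diffuse interception geometry for a grid
#'
#' Interception is linear in the incident flux, so the per-voxel intercepted
#' power per unit horizontal diffuse PPFD can be precomputed once per scene
#' by summing the 46 sky directions with their weights. Reused by
#' [compute_irradiance()] across all timesteps.
#'
#' @param grid A `voxel_grid`.
#' @param sky A [sky_model()].
#' @param rays_per_edge Supersampling factor passed to [beam_interception()].
#' @param lateral `"open"` (isolated tree; side-entering sky rays included)
#'   or `"periodic"` (laterally infinite canopy).
#' @return A list: `frac` (3D array: intercepted power per unit horizontal
#'   diffuse flux), `transmitted_frac` (transmitted power over the incident
#'   power on the grid footprint).
#' @export
precompute_diffuse <- function(grid, sky, rays_per_edge = 2,
                               lateral = c("open", "periodic")) {
  lateral <- match.arg(lateral)
  acc <- array(0, dim = grid$dim)
  trans <- 0
  footprint <- prod(grid$dim[1:2]) * grid$edge^2
  for (i in seq_len(nrow(sky$directions))) {
    dd <- sky$directions[i, ]
    bi <- beam_interception(grid, dd$azimuth, dd$elevation,
                            incident = dd$weight / sin(deg2rad(dd$elevation)),
                            lateral = lateral,
                            rays_per_edge = rays_per_edge)
    acc <- acc + bi$intercepted
    trans <- trans + bi$transmitted
  }
  list(frac = acc, transmitted_frac = trans / footprint)
}

#' Per-voxel absorbed irradiance for one weather record
#'
#' Drives the full radiation chain for a single half-hour step: solar
#' position, diffuse/direct partitioning of measured total PPFD, direct-beam
#' interception at the current solar direction, diffuse interception from
#' the 46-direction sky, and conversion to absorbed PPFD per unit leaf area
#' using the leaf absorptance (scattering neglected by default, so energy
#' conservation is exact).
#'
#' @param grid A `voxel_grid`.
#' @param sky A [sky_model()].
#' @param record One weather row: needs `ppfd_total`, `doy`, `hour`.
#' @param diffuse_cache Optional result of [precompute_diffuse()].
#' @param absorptance Leaf PAR absorptance, default 0.85.
#' @param rays_per_edge Supersampling for the direct beam.
#' @return A list of class `irradiance_field`: `abs_direct`, `abs_diffuse`
#'   (3D arrays, umol m^-2 leaf s^-1), `sunlit_fraction` (3D array),
#'   `ppfd_direct`, `ppfd_diffuse` (scalars, horizontal incident),
#'   `solar` (position).
#' @export
compute_irradiance <- function(grid, sky, record, diffuse_cache = NULL,
                               absorptance = 0.85, rays_per_edge = 4) {
  stopifnot(inherits(grid, "voxel_grid"))
  sunpos <- solar_position(sky$latitude, sky$longitude, record$doy, record$hour)
  sp <- split_diffuse_direct(record$ppfd_total, sunpos["elevation"], record$doy)
  la <- grid$leaf_area
  zero <- array(0, dim = grid$dim)
  if (record$ppfd_total <= 0) {
    return(structure(list(abs_direct = zero, abs_diffuse = zero,
                          sunlit_fraction = zero, ppfd_direct = 0,
                          ppfd_diffuse = 0, solar = sunpos),
                     class = "irradiance_field"))
  }
  if (is.null(diffuse_cache)) diffuse_cache <- precompute_diffuse(grid, sky)
  abs_diff <- zero
  occ <- la > 0
  abs_diff[occ] <- absorptance * sp$diffuse * diffuse_cache$frac[occ] / la[occ]
  abs_dir <- zero
  sunlit <- zero
  if (sp$direct > 0 && sunpos["elevation"] > 0) {
    bi <- beam_interception(grid, sunpos["azimuth"], sunpos["elevation"],
                            incident = sp$direct / sin(deg2rad(sunpos["elevation"])),
                            rays_per_edge = rays_per_edge)
    abs_dir[occ] <- absorptance * bi$intercepted[occ] / la[occ]
    sunlit <- bi$sunlit_fraction
  }
  structure(list(abs_direct = abs_dir, abs_diffuse = abs_diff,
                 sunlit_fraction = sunlit, ppfd_direct = sp$direct,
                 ppfd_diffuse = sp$diffuse, solar = sunpos),
            class = "irradiance_field")
}

#' Dump a voxel grid (with optional irradiance) to CSV
#'
#' @param grid A `voxel_grid`.
#' @param path Output CSV path.
#' @param field Optional `irradiance_field` to append absorbed-PPFD columns.
#' @return `path`, invisibly.
#' @export
export_grid_csv <- function(grid, path, field = NULL) {
  ijk <- expand.grid(ix = seq_len(grid$dim[1]), iy = seq_len(grid$dim[2]),
                     iz = seq_len(grid$dim[3]))
  out <- cbind(ijk, lad = as.vector(grid$lad),
               leaf_area = as.vector(grid$leaf_area))
  if (!is.null(field)) {
    out$abs_ppfd_direct <- as.vector(field$abs_direct)
    out$abs_ppfd_diffuse <- as.vector(field$abs_diffuse)
    out$sunlit_fraction <- as.vector(field$sunlit_fraction)
  }
  utils::write.csv(out[out$lad > 0 | !is.null(field), ], path,
                   row.names = FALSE)
  invisible(path)
}
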