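#' Leaf-angle distributions and phyllotaxy settings
#'
#' Histogram descriptions of the leaf Euler angles used when dressing a
#' shoot skeleton with leaves: midrib elevation and lamina rolling angle,
#' per shoot type, plus the constant phyllotactic angle and the
#' petiole-shoot insertion angle. Leaf azimuths advance by the phyllotactic
#' angle from node to node (144 degrees for a 2/5 phyllotaxy); elevation and
#' rolling are drawn from the histograms (uniform within the selected bin).
#'
#' Defaults describe gently drooping apple leaves: elevations concentrated
#' between -50 and +20 degrees from the horizontal, rolling within +/- 30
#' degrees, identical across shoot types.
#'
#' @param elevation Named list (per shoot type, or a single `default`) of
#'   lists with `breaks` (bin edges, deg) and `prob` (bin masses summing
#'   to 1).
#' @param rolling Same structure for the rolling angle.
#' @param beta Phyllotactic azimuth advance (deg); 144 for 2/5 phyllotaxy.
#' @param petiole_angle Angle between petiole and shoot axis (deg).
#' @return A list of class `angle_distribution`.
#' @export
angle_distribution <- function(elevation = NULL, rolling = NULL,
                               beta = 144, petiole_angle = 45) {
  default_elev <- list(breaks = seq(-60, 30, by = 10),
                       prob = c(0.05, 0.1, 0.15, 0.2, 0.2, 0.15, 0.08, 0.05,
                                0.02))
  default_roll <- list(breaks = seq(-30, 30, by = 10),
                       prob = c(0.1, 0.2, 0.25, 0.25, 0.15, 0.05))
  if (is.null(elevation)) elevation <- list(default = default_elev)
  if (is.null(rolling)) rolling <- list(default = default_roll)
  for (h in c(elevation, rolling)) {
    if (abs(sum(h$prob) - 1) > 1e-8) {
      stop("angle_distribution: histogram masses must sum to 1")
    }
    if (length(h$breaks) != length(h$prob) + 1) {
      stop("angle_distribution: breaks must be one longer than prob")
    }
  }
  structure(list(elevation = elevation, rolling = rolling, beta = beta,
                 petiole_angle = petiole_angle), class = "angle_distribution")
}

#' Build an angle distribution from field-measured angles
#'
#' @param samples Data.frame with columns `type`, `elevation`, `rolling`
#'   (deg).
#' @param binwidth Histogram bin width (deg), default 10.
#' @param beta,petiole_angle Passed to [angle_distribution()].
#' @return An `angle_distribution`.
#' @export
angle_distribution_from_samples <- function(samples, binwidth = 10,
                                            beta = 144, petiole_angle = 45) {
  mk <- function(v) {
    lo <- floor(min(v) / binwidth) * binwidth
    hi <- ceiling(max(v) / binwidth) * binwidth
    if (hi == lo) hi <- lo + binwidth
    br <- seq(lo, hi, by = binwidth)
    h <- hist(v, breaks = br, plot = FALSE)
    list(breaks = br, prob = h$counts / sum(h$counts))
  }
  types <- split(samples, samples$type)
  angle_distribution(
    elevation = lapply(types, function(d) mk(d$elevation)),
    rolling = lapply(types, function(d) mk(d$rolling)),
    beta = beta, petiole_angle = petiole_angle)
}

# Pick the histogram for a shoot type, falling back to the pooled default.
hist_for_type <- function(hists, type) {
  if (!is.null(hists[[type]])) hists[[type]] else hists[[1]]
}

sample_hist <- function(n, h) {
  bin <- sample.int(length(h$prob), n, replace = TRUE, prob = h$prob)
  stats::runif(n, h$breaks[bin], h$breaks[bin + 1])
}

#' Build a leaf hexagon in its local frame
#'
#' Leaves are planar hexagons calibrated against the allometry: length along
#' the midrib equals the leaf length `LL`, maximum width equals the
#' predicted leaf width `LW(LL)`, and the free shape parameter (the extent
#' of the parallel-sided mid-section) is solved so the polygon area equals
#' the allometric target `a_LA * LL^2`. The construction is exact whenever
#' the target shape factor `area / (LL * LW)` lies in (0.5, 1), which holds
#' for the default apple allometry; outside that window the mid-section is
#' clamped and widths rescaled to preserve the area, with a warning.
#'
#' @param LL Leaf length (cm, > 0).
#' @param model An [allometric_model()].
#' @return A list: `vertices` (6 x 2 matrix, cm, midrib along x from the
#'   petiole junction at the origin), `LL`, `LW`, `PL`, `area` (cm^2).
#' @export
build_hexagon <- function(LL, model) {
  stopifnot(inherits(model, "allometric_model"))
  if (LL <= 0) stop("build_hexagon: LL must be > 0")
  LW <- model$a_LW * LL + model$b_LW
  if (LW <= 0) {
    stop(sprintf("build_hexagon: predicted leaf width %.3g <= 0 at LL = %.3g cm",
                 LW, LL))
  }
  PL <- model$a_PL * LL + model$b_PL
  target <- model$a_LA * LL^2
  delta <- 2 * target / LW - LL     # parallel-sided extent; area = LW (LL+delta)/2
  if (delta < 0 || delta > 0.98 * LL) {
    delta <- min(max(delta, 0), 0.98 * LL)
    LW <- 2 * target / (LL + delta)
    warning("build_hexagon: infeasible shape factor; leaf width rescaled to preserve area")
  }
  xa <- (LL - delta) / 2
  xb <- (LL + delta) / 2
  v <- rbind(c(0, 0), c(xa, LW / 2), c(xb, LW / 2), c(LL, 0),
             c(xb, -LW / 2), c(xa, -LW / 2))
  list(vertices = v, LL = LL, LW = LW, PL = max(PL, 0),
       area = polygon_area_2d(v))
}

#' Dress one shoot with leaves
#'
#' Applies the reconstruction principles to a single shoot record: leaf
#' number and total leaf area from the allometry, identical leaves of the
#' mean area, petiole insertion points evenly segmented along the shoot
#' axis at the mean internode length, azimuths advancing by the
#' phyllotactic angle from a random initial azimuth, elevation and rolling
#' drawn from the shoot type's histograms, petiole held in the plane of the
#' shoot axis and the leaf azimuth at the petiole-shoot angle, and the
#' lamina origin placed at the petiole tip.
#'
#' @param shoot A one-row shoot record (as from [gen_shoot_skeleton()]).
#' @param model An [allometric_model()] (cm units).
#' @param angles An [angle_distribution()].
#' @param seed Integer seed (per-shoot substream derived from it and the
#'   shoot id, so scenes are reproducible and translation-invariant).
#' @return A data.frame, one row per leaf: `shoot_id`, `node_rank`,
#'   `area_cm2`, `azimuth`, `elevation`, `rolling`, `petiole_cm`,
#'   `ax`,`ay`,`az` (attachment, m), `nx`,`ny`,`nz` (unit normal) and the
#'   18 flattened vertex coordinates `v1x` ... `v6z` (m).
#' @export
layout_shoot <- function(shoot, model, angles, seed = 1L) {
  stopifnot(inherits(model, "allometric_model"),
            inherits(angles, "angle_distribution"))
  prox <- c(shoot$x0, shoot$y0, shoot$z0)
  dist <- c(shoot$x1, shoot$y1, shoot$z1)
  axis_v <- dist - prox
  SL_m <- sqrt(sum(axis_v^2))
  if (SL_m <= 0) stop("layout_shoot: shoot length must be > 0")
  a <- axis_v / SL_m
  SL_cm <- SL_m * 100
  pred <- predict_shoot(model, SL_cm)
  SLN <- pred$SLN
  mean_LA <- pred$mean_LA
  if (mean_LA <= 0) return(empty_leaf_df())
  LL <- sqrt(mean_LA / model$a_LA)
  hex <- build_hexagon(LL, model)

  with_seed(substream_seed(seed, paste0("shoot", shoot$shoot_id)), {
    alpha0 <- stats::runif(1, 0, 360)
    elev <- sample_hist(SLN, hist_for_type(angles$elevation, shoot$type))
    roll <- sample_hist(SLN, hist_for_type(angles$rolling, shoot$type))
    rows <- vector("list", SLN)
    for (i in seq_len(SLN)) {
      azim <- (alpha0 + (i - 1) * angles$beta) %% 360
      insertion <- prox + a * (i * SL_m / SLN)
      # petiole: in the plane of the shoot axis and the leaf azimuth,
      # at the petiole-shoot angle from the axis
      h <- dir_vector(azim, 0)
      h_perp <- h - sum(h * a) * a
      nh <- sqrt(sum(h_perp^2))
      if (nh < 1e-9) {                 # azimuth parallel to shoot axis
        h_perp <- cross3(a, c(0, 0, 1))
        nh <- sqrt(sum(h_perp^2))
        if (nh < 1e-9) { h_perp <- c(1, 0, 0); nh <- 1 }
      }
      h_perp <- h_perp / nh
      gam <- deg2rad(angles$petiole_angle)
      pdir <- cos(gam) * a + sin(gam) * h_perp
      origin <- insertion + pdir * (hex$PL / 100)

      m <- dir_vector(azim, elev[i])
      u <- cross3(c(0, 0, 1), m)
      if (sqrt(sum(u^2)) < 1e-9) u <- c(1, 0, 0)
      u <- u / sqrt(sum(u^2))
      w <- rotate_about(u, m, deg2rad(roll[i]))
      vx <- hex$vertices[, 1] / 100    # cm -> m
      vy <- hex$vertices[, 2] / 100
      verts <- sweep(outer(vx, m) + outer(vy, w), 2, origin, `+`)
      nrm <- cross3(m, w)
      nrm <- nrm / sqrt(sum(nrm^2))
      rows[[i]] <- data.frame(
        shoot_id = shoot$shoot_id, node_rank = i, area_cm2 = hex$area,
        azimuth = azim, elevation = elev[i], rolling = roll[i],
        petiole_cm = hex$PL,
        ax = origin[1], ay = origin[2], az = origin[3],
        nx = nrm[1], ny = nrm[2], nz = nrm[3],
        t(as.vector(t(verts))) |> as.data.frame() |>
          stats::setNames(paste0("v", rep(1:6, each = 3), c("x", "y", "z")))
      )
    }
    do.call(rbind, rows)
  })
}

empty_leaf_df <- function() {
  cols <- c("shoot_id", "node_rank", "area_cm2", "azimuth", "elevation",
            "rolling", "petiole_cm", "ax", "ay", "az", "nx", "ny", "nz",
            paste0("v", rep(1:6, each = 3), c("x", "y", "z")))
  as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Assemble a full canopy scene
#'
#' Dresses every shoot in a skeleton with leaves and returns the scene
#' together with the orchard tree spacing (2.0 m within rows, 3.5 m between
#' rows by default) used by [compute_lai()].
#'
#' @param shoots Shoot-record data.frame (>= 1 row).
#' @param model An [allometric_model()].
#' @param angles An [angle_distribution()].
#' @param seed Integer seed.
#' @param tree_spacing c(row, inter-row) spacing in m.
#' @return A list of class `canopy_scene`: `leaves` (per-leaf data.frame),
#'   `tree_spacing`, `bbox` (2 x 3 matrix).
#' @export
assemble_canopy <- function(shoots, model, angles = angle_distribution(),
                            seed = 1L, tree_spacing = c(2.0, 3.5)) {
  if (is.null(shoots) || nrow(shoots) == 0) {
    stop("assemble_canopy: need at least one shoot")
  }
  leaves <- do.call(rbind, lapply(seq_len(nrow(shoots)), function(i) {
    layout_shoot(shoots[i, ], model, angles, seed = seed)
  }))
  vcols_x <- paste0("v", 1:6, "x"); vcols_y <- paste0("v", 1:6, "y")
  vcols_z <- paste0("v", 1:6, "z")
  bbox <- rbind(
    c(min(unlist(leaves[vcols_x])), min(unlist(leaves[vcols_y])),
      min(unlist(leaves[vcols_z]))),
    c(max(unlist(leaves[vcols_x])), max(unlist(leaves[vcols_y])),
      max(unlist(leaves[vcols_z]))))
  structure(list(leaves = leaves, tree_spacing = tree_spacing, bbox = bbox),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("Canopy scene: %d leaves, %.3f m^2 leaf area, LAI %.2f\n",
              nrow(x$leaves), sum(x$leaves$area_cm2) * 1e-4, compute_lai(x)))
  invisible(x)
}

#' Leaf area index of a scene
#'
#' Total scene leaf area (m^2) divided by the ground area allotted to one
#' tree (row spacing times inter-row spacing).
#'
#' @param scene A `canopy_scene`.
#' @return LAI (dimensionless). An empty scene has LAI 0.
#' @export
compute_lai <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  if (any(scene$tree_spacing <= 0)) stop("compute_lai: tree spacing must be positive")
  sum(scene$leaves$area_cm2) * 1e-4 / prod(scene$tree_spacing)
}

#' Export a canopy scene
#'
#' `export_scene_csv` writes one row per leaf (flattened vertices, area,
#' angles, shoot id); `export_scene_obj` writes a Wavefront OBJ with each
#' hexagon triangulated as a fan.
#'
#' @param scene A `canopy_scene`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_scene_csv <- function(scene, path) {
  utils::write.csv(scene$leaves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname export_scene_csv
#' @export
export_scene_obj <- function(scene, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lv <- scene$leaves
  for (i in seq_len(nrow(lv))) {
    for (j in 1:6) {
      writeLines(sprintf("v %.6f %.6f %.6f", lv[i, paste0("v", j, "x")],
                         lv[i, paste0("v", j, "y")],
                         lv[i, paste0("v", j, "z")]), con)
    }
    base <- (i - 1) * 6
    for (j in 2:5) {
      writeLines(sprintf("f %d %d %d", base + 1, base + j, base + j + 1), con)
    }
  }
  invisible(path)
}
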