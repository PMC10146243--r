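#' Ground-truth configuration for the synthetic-data generator
#'
#' Collects every "true" parameter the generator uses, so that all inverse
#' procedures in the package can be tested as round trips against known
#' truth. Defaults describe a realistic spindle-trained apple canopy:
#' allometry in cm-based units, Farquhar parameters of a well-lit apple
#' leaf, Jarvis shapes with a VPD closure threshold inside the measured
#' 1.0-3.5 kPa window, and a nitrogen gradient spanning roughly
#' 1.5-3 g m^-2 over daily light integrals of 5-50 mol m^-2 d^-1.
#'
#' @param allometry An [allometric_model()]; default truth uses
#'   SLA = 9 SL + 20, SLN = 0.35 SL + 2, LA = 0.62 LL^2, LW = 0.7 LL + 0.2,
#'   PL = 0.3 LL + 0.5 (all cm / cm^2).
#' @param farquhar A [farquhar_params()]; default Vcmax25 = 60,
#'   Jmax25 = 120, Rd25 = 1.5 umol m^-2 s^-1.
#' @param jarvis A [jarvis_params()]; default threshold VPD0 = 1.6 kPa.
#' @param na_gradient c(slope, intercept) of N_a (g m^-2) vs PPFD_d
#'   (mol m^-2 d^-1); slope must be positive.
#' @param noise_sd Named list of observation noise standard deviations:
#'   `aci` (umol m^-2 s^-1 on A), `gs` (on g_s/g_smax), `allometry`
#'   (cm^2 on areas).
#' @param seed Master integer seed; every generator derives its own
#'   substream from it.
#' @return A list of class `truth_config`.
#' @export
truth_config <- function(allometry = allometric_model(9, 20, 0.35, 2, 0.62,
                                                      0.7, 0.2, 0.3, 0.5),
                         farquhar = farquhar_params(60, 120, 1.5),
                         jarvis = jarvis_params(),
                         na_gradient = c(0.03, 1.3),
                         noise_sd = list(aci = 0.5, gs = 0.05, allometry = 0.5),
                         seed = 1L) {
  if (jarvis$VPD0 < 0.8 || jarvis$VPD0 > 3.0) {
    stop("truth_config: VPD breakpoint must lie in [0.8, 3.0] kPa")
  }
  if (na_gradient[1] <= 0) stop("truth_config: N_a gradient slope must be > 0")
  structure(list(allometry = allometry, farquhar = farquhar, jarvis = jarvis,
                 na_gradient = na_gradient, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "truth_config")
}

#' Generate a synthetic shoot skeleton
#'
#' Places current-year leafy shoots inside an ellipsoidal crown envelope.
#' Shoot proximal points are uniform within the ellipsoid; shoot directions
#' mimic spindle training with scaffold branches tied below horizontal
#' (long-shoot inclinations 100-120 degrees from vertical), while short and
#' bourse shoots point in nearly arbitrary directions. Long and short shoot
#' lengths respect the 5 cm classification threshold by construction.
#'
#' @param tree_params List with `crown_center` (xyz, m), `crown_radii`
#'   (xyz semi-axes, m, all > 0) and `n_shoots` named vector with counts for
#'   `long`, `short`, `bourse` (all >= 0).
#' @param seed Integer seed.
#' @return A data.frame of shoot records: `shoot_id`, `type`, proximal
#'   `x0,y0,z0` and distal `x1,y1,z1` coordinates (m), `length_m`.
#' @export
gen_shoot_skeleton <- function(tree_params = list(
                                 crown_center = c(0, 0, 1.8),
                                 crown_radii = c(0.8, 0.8, 1.4),
                                 n_shoots = c(long = 60, short = 90, bourse = 40)),
                               seed = 1L) {
  cc <- tree_params$crown_center
  cr <- tree_params$crown_radii
  if (any(cr <= 0)) stop("gen_shoot_skeleton: crown dimensions must be positive")
  n <- tree_params$n_shoots
  if (any(n < 0)) stop("gen_shoot_skeleton: shoot counts must be >= 0")
  types <- rep(names(n), n)
  total <- length(types)
  if (total == 0) {
    return(data.frame(shoot_id = integer(), type = character(),
                      x0 = numeric(), y0 = numeric(), z0 = numeric(),
                      x1 = numeric(), y1 = numeric(), z1 = numeric(),
                      length_m = numeric()))
  }
  with_seed(substream_seed(seed, "shoots"), {
    # uniform points in the unit ball, scaled to the crown ellipsoid
    pts <- matrix(stats::rnorm(3 * total), ncol = 3)
    pts <- pts / sqrt(rowSums(pts^2)) * stats::runif(total)^(1 / 3)
    prox <- sweep(sweep(pts, 2, cr, `*`), 2, cc, `+`)
    len <- numeric(total)
    incl <- numeric(total)  # inclination from vertical, degrees
    for (i in seq_len(total)) {
      len[i] <- switch(types[i],
        long = stats::runif(1, 0.06, 0.40),
        short = stats::runif(1, 0.01, 0.049),
        bourse = stats::runif(1, 0.01, 0.08))
      incl[i] <- switch(types[i],
        long = stats::runif(1, 100, 120),
        stats::runif(1, 60, 130))
    }
    az <- stats::runif(total, 0, 360)
    d <- t(vapply(seq_len(total),
                  function(i) dir_vector(az[i], 90 - incl[i]),
                  numeric(3)))
    dist <- prox + d * len
    data.frame(shoot_id = seq_len(total), type = types,
               x0 = prox[, 1], y0 = prox[, 2], z0 = prox[, 3],
               x1 = dist[, 1], y1 = dist[, 2], z1 = dist[, 3],
               length_m = len)
  })
}

#' Generate half-hourly synthetic weather
#'
#' Builds a 30-min weather series whose daily light integrals are guaranteed
#' to match their day class: sunny days integrate to more than 45, cloudy
#' days to less than 15 mol m^-2 d^-1 (the classifier thresholds), and
#' intermediate days fall in between. The diurnal PPFD shape is the sine of
#' solar elevation at the site latitude, rescaled exactly to the day's
#' target integral; cloudy days carry multiplicative half-hour noise before
#' rescaling. Air temperature follows a diurnal sine (cooler on cloudy
#' days), relative humidity mirrors temperature, and wind is a bounded
#' random walk.
#'
#' @param n_days Number of days (> 0).
#' @param day_mix Named fractions `c(sunny=, cloudy=, intermediate=)`
#'   summing to 1. Days are assigned classes in proportion, deterministically
#'   shuffled.
#' @param latitude Site latitude (deg N), default 34.5.
#' @param seed Integer seed.
#' @param start_doy First day of year, default 190 (the phase with completed
#'   shoot growth).
#' @return A data.frame (class `weather_series`): `timestamp` (POSIXct UTC,
#'   30-min), `doy`, `hour`, `ppfd_total` (umol m^-2 s^-1), `air_temp`
#'   (degC), `rh` (%), `wind` (m s^-1), `day_class` (generation label).
#' @export
gen_weather <- function(n_days, day_mix = c(sunny = 0.5, cloudy = 0.3,
                                            intermediate = 0.2),
                        latitude = 34.5, seed = 1L, start_doy = 190L) {
  if (n_days <= 0) stop("gen_weather: n_days must be > 0")
  if (abs(sum(day_mix) - 1) > 1e-8) stop("gen_weather: day_mix must sum to 1")
  counts <- round_half_up(day_mix * n_days)
  # fix rounding drift on the largest class
  counts[which.max(counts)] <- counts[which.max(counts)] + n_days - sum(counts)
  classes <- rep(names(day_mix), counts)
  hours <- seq(0.25, 23.75, by = 0.5)  # mid-interval times of the 48 steps
  with_seed(substream_seed(seed, "weather"), {
    classes <- sample(classes)
    out <- vector("list", n_days)
    for (d in seq_len(n_days)) {
      doy <- start_doy + d - 1L
      cls <- classes[d]
      elev <- vapply(hours, function(h) {
        solar_position(latitude, 0, doy, h)["elevation"]
      }, numeric(1))
      shape <- pmax(0, sin(deg2rad(pmax(elev, 0))))
      shape[elev <= 0] <- 0
      if (cls == "cloudy") {
        shape <- shape * exp(stats::rnorm(length(shape), 0, 0.35))
        shape[elev <= 0] <- 0
      }
      target <- switch(cls,
        sunny = stats::runif(1, 47, 58),
        cloudy = stats::runif(1, 6, 13),
        intermediate = stats::runif(1, 20, 40))
      raw_mol <- sum(shape) * 1800 * 1e-6
      ppfd <- shape * (target / raw_mol)
      tmin <- stats::runif(1, 14, 18) - 2 * (cls == "cloudy")
      tmax <- tmin + switch(cls, sunny = stats::runif(1, 12, 15),
                            cloudy = stats::runif(1, 5, 8),
                            stats::runif(1, 8, 12))
      tair <- tmin + (tmax - tmin) * pmax(0, sin(pi * (hours - 6) / 15))
      rh <- pmin(100, pmax(20, 95 - 2.8 * (tair - tmin) +
                             stats::rnorm(length(hours), 0, 2)))
      wind <- pmax(0.2, 1.5 + cumsum(stats::rnorm(length(hours), 0, 0.15)))
      out[[d]] <- data.frame(doy = doy, hour = hours, ppfd_total = ppfd,
                             air_temp = tair, rh = rh, wind = wind,
                             day_class = cls)
    }
    w <- do.call(rbind, out)
    w$timestamp <- as.POSIXct(sprintf("2013-01-01 00:00:00"), tz = "UTC") +
      (w$doy - 1) * 86400 + w$hour * 3600
    w <- w[, c("timestamp", "doy", "hour", "ppfd_total", "air_temp", "rh",
               "wind", "day_class")]
    class(w) <- c("weather_series", "data.frame")
    w
  })
}

#' Generate synthetic A-Ci observations
#'
#' Simulates the standard CO2-response protocol: ambient CO2 stepped through
#' the 12-step sequence 400, 300, 200, 100, 50, 400, 600, 800, 1000, 1200,
#' 1500, 1800 umol mol^-1 at saturating PPFD (1500 umol m^-2 s^-1 incident)
#' and 30 degC leaf temperature. Intercellular CO2 is taken at a fixed 0.7
#' draw-down ratio of ambient; net assimilation is the Farquhar forward
#' model evaluated at the truth parameters plus Gaussian noise.
#'
#' @param truth A [truth_config()].
#' @param ca_sequence Ambient CO2 steps (umol mol^-1), all > 0.
#' @param n_leaves Number of replicate leaves.
#' @param T_leaf Leaf temperature during the protocol (degC).
#' @param absorptance Leaf PAR absorptance applied to incident PPFD.
#' @return A data.frame: `leaf`, `step`, `Ca`, `Ci`, `ppfd_abs`, `T_leaf`,
#'   `A_obs`.
#' @export
gen_aci_dataset <- function(truth, ca_sequence = c(400, 300, 200, 100, 50, 400,
                                                   600, 800, 1000, 1200, 1500,
                                                   1800),
                            n_leaves = 1L, T_leaf = 30, absorptance = 0.85) {
  stopifnot(inherits(truth, "truth_config"))
  if (length(ca_sequence) == 0) stop("gen_aci_dataset: ca_sequence is empty")
  if (any(ca_sequence <= 0)) stop("gen_aci_dataset: Ca must be positive")
  ppfd_abs <- 1500 * absorptance
  with_seed(substream_seed(truth$seed, "aci"), {
    out <- lapply(seq_len(n_leaves), function(l) {
      ci <- 0.7 * ca_sequence
      a <- farquhar_net_a(ci, ppfd_abs, T_leaf, truth$farquhar) +
        stats::rnorm(length(ci), 0, truth$noise_sd$aci)
      data.frame(leaf = l, step = seq_along(ca_sequence), Ca = ca_sequence,
                 Ci = ci, ppfd_abs = ppfd_abs, T_leaf = T_leaf, A_obs = a)
    })
    do.call(rbind, out)
  })
}

#' Generate synthetic stomatal response observations
#'
#' One environmental factor is swept over a grid while the others are held
#' at the measurement holding values (PPFD 1500 umol m^-2 s^-1, leaf
#' temperature 30 degC, VPD 1.2 kPa). Relative conductance g_s/g_smax is
#' normalized to the holding conditions, so the expectation is the swept
#' factor's Jarvis response alone (plateauing at exactly 1), plus Gaussian
#' noise.
#'
#' @param truth A [truth_config()].
#' @param factor One of `"PPFD"`, `"T"`, `"VPD"`.
#' @param grid Values of the swept factor. A warning is issued outside the
#'   measured ranges (PPFD 0-1500, T 20-35 degC, VPD 1.0-3.5 kPa).
#' @return A data.frame: `factor`, `value`, `ppfd`, `T_leaf`, `vpd`,
#'   `gs_rel_obs`.
#' @export
gen_gs_response <- function(truth, factor = c("PPFD", "T", "VPD"),
                            grid = NULL) {
  stopifnot(inherits(truth, "truth_config"))
  factor <- match.arg(factor)
  if (is.null(grid)) {
    grid <- switch(factor,
      PPFD = seq(0, 1500, length.out = 25),
      T = seq(20, 35, length.out = 25),
      VPD = seq(1.0, 3.5, length.out = 25))
  }
  rng <- switch(factor, PPFD = c(0, 1500), T = c(20, 35), VPD = c(1.0, 3.5))
  if (any(grid < rng[1]) || any(grid > rng[2])) {
    warning(sprintf("gen_gs_response: %s grid extends outside the measured range [%g, %g]",
                    factor, rng[1], rng[2]))
  }
  hold <- list(ppfd = 1500, T_leaf = 30, vpd = 1.2)
  ppfd <- if (factor == "PPFD") grid else rep(hold$ppfd, length(grid))
  tl <- if (factor == "T") grid else rep(hold$T_leaf, length(grid))
  vpd <- if (factor == "VPD") grid else rep(hold$vpd, length(grid))
  p <- truth$jarvis
  # relative conductance is normalized to the holding conditions, so only
  # the swept factor's response remains (plateaus at exactly 1)
  mu <- switch(factor,
    PPFD = jarvis_f_ppfd(ppfd, p),
    T = jarvis_f_temp(tl, p),
    VPD = jarvis_f_vpd(vpd, p))
  with_seed(substream_seed(truth$seed, paste0("gs_", factor)), {
    data.frame(factor = factor, value = grid, ppfd = ppfd, T_leaf = tl,
               vpd = vpd,
               gs_rel_obs = mu + stats::rnorm(length(mu), 0, truth$noise_sd$gs))
  })
}

#' Generate synthetic allometry observation tables
#'
#' Emulates the destructive shoot sample used to calibrate the allometric
#' relationships: per-shoot totals (shoot length with its leaf area and
#' leaf count) and per-leaf dimensions (length, area, width, petiole
#' length), each equal to the truth relation plus Gaussian noise. Leaf
#' counts are left on the continuous scale of the linear relation --
#' rounding to whole leaves happens only at reconstruction time -- so a
#' zero-noise sample inverts exactly under [fit_line()] / [fit_power_la()].
#'
#' @param truth A [truth_config()].
#' @param n_shoots Number of sampled shoots.
#' @param n_leaves Number of sampled leaves.
#' @return A list of two data.frames: `shoots` (`SL`, `SLA`, `SLN`) and
#'   `leaves` (`LL`, `LA`, `LW`, `PL`), cm-based units.
#' @export
gen_allometry_samples <- function(truth, n_shoots = 60, n_leaves = 100) {
  stopifnot(inherits(truth, "truth_config"))
  m <- truth$allometry
  sd <- truth$noise_sd$allometry
  with_seed(substream_seed(truth$seed, "allometry"), {
    SL <- stats::runif(n_shoots, 2, 40)
    shoots <- data.frame(
      SL = SL,
      SLA = m$a_SLA * SL + m$b_SLA + stats::rnorm(n_shoots, 0, sd),
      SLN = m$a_SLN * SL + m$b_SLN + stats::rnorm(n_shoots, 0, sd / 5))
    LL <- stats::runif(n_leaves, 4, 12)
    leaves <- data.frame(
      LL = LL,
      LA = m$a_LA * LL^2 + stats::rnorm(n_leaves, 0, sd),
      LW = m$a_LW * LL + m$b_LW + stats::rnorm(n_leaves, 0, sd / 5),
      PL = m$a_PL * LL + m$b_PL + stats::rnorm(n_leaves, 0, sd / 5))
    list(shoots = shoots, leaves = leaves)
  })
}

#' Export synthetic inputs to plain-text files
#'
#' Writes `shoots.csv`, `weather.csv`, `aci.csv`, `gsresp.csv` and
#' `truth.json` into a directory, the on-disk dialects read back by the
#' reconstruction and fitting modules.
#'
#' @param dir Output directory (created if missing).
#' @param truth A [truth_config()].
#' @param shoots,weather,aci,gsresp Optional pre-generated tables; any that
#'   are `NULL` are generated from `truth` with defaults.
#' @return The directory path, invisibly.
#' @export
export_synthetic <- function(dir, truth = truth_config(), shoots = NULL,
                             weather = NULL, aci = NULL, gsresp = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(shoots)) shoots <- gen_shoot_skeleton(seed = truth$seed)
  if (is.null(weather)) weather <- gen_weather(4, seed = truth$seed)
  if (is.null(aci)) aci <- gen_aci_dataset(truth, n_leaves = 3)
  if (is.null(gsresp)) {
    gsresp <- rbind(gen_gs_response(truth, "PPFD"),
                    gen_gs_response(truth, "T"),
                    gen_gs_response(truth, "VPD"))
  }
  utils::write.csv(shoots, file.path(dir, "shoots.csv"), row.names = FALSE)
  wx <- weather
  wx$timestamp <- format(wx$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(wx, file.path(dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(aci, file.path(dir, "aci.csv"), row.names = FALSE)
  utils::write.csv(gsresp, file.path(dir, "gsresp.csv"), row.names = FALSE)
  tr <- list(allometry = unclass(truth$allometry)[
               c("a_SLA", "b_SLA", "a_SLN", "b_SLN", "a_LA", "a_LW", "b_LW",
                 "a_PL", "b_PL")],
             farquhar = truth$farquhar[c("Vcmax25", "Jmax25", "Rd25")],
             jarvis = unclass(truth$jarvis),
             na_gradient = truth$na_gradient,
             noise_sd = truth$noise_sd, seed = truth$seed)
  jsonlite::write_json(tr, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a shoots.csv table
#'
#' @param path Path to a CSV in the `shoots.csv` dialect written by
#'   [export_synthetic()].
#' @return A shoot-record data.frame as from [gen_shoot_skeleton()].
#' @export
read_shoots_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("shoot_id", "type", "x0", "y0", "z0", "x1", "y1", "z1")
  if (!all(need %in% names(x))) {
    stop("read_shoots_csv: missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  }
  if (is.null(x$length_m)) {
    x$length_m <- sqrt((x$x1 - x$x0)^2 + (x$y1 - x$y0)^2 + (x$z1 - x$z0)^2)
  }
  x
}
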