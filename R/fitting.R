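#' Fit the Farquhar model to an A-Ci curve
#'
#' Nonlinear least squares of the net-assimilation forward model
#' ([farquhar_net_a()]) against observed A over intercellular CO2, with the
#' parameters expressed directly at the 25 degC reference so that the
#' back-transformation from the measurement temperature uses exactly the
#' same temperature-response constants as the forward model. Optimization is
#' multistart (default 5 starting points spanning typical leaf capacities)
#' with best-RSS selection; dark respiration can be fixed (e.g. measured
#' pre-dawn) or co-estimated.
#'
#' @param obs Data.frame with columns `Ci`, `A_obs`, and optionally
#'   `ppfd_abs` and `T_leaf` (defaults 1275 umol m^-2 s^-1 and the
#'   `T_leaf` argument).
#' @param T_leaf Measurement leaf temperature (degC) used when `obs` carries
#'   no `T_leaf` column.
#' @param Rd25 If non-`NULL`, fix dark respiration at this 25 degC value.
#' @param constants A [farquhar_constants()] set.
#' @param n_starts Number of multistart points (>= 1).
#' @return A list of class `fit_result`: `estimates` (named: Vcmax25,
#'   Jmax25, Rd25), `se` (asymptotic, from the numerical Hessian), `rss`,
#'   `converged`, `n_obs`, `warnings`.
#' @export
fit_aci <- function(obs, T_leaf = 30, Rd25 = NULL,
                    constants = farquhar_constants(), n_starts = 5) {
  ci <- obs$Ci
  a <- obs$A_obs
  if (length(unique(round(ci, 6))) < 6) {
    stop("fit_aci: need >= 6 distinct Ci values spanning both limitation regimes")
  }
  ppfd <- if (!is.null(obs$ppfd_abs)) obs$ppfd_abs else rep(1275, length(ci))
  tl <- if (!is.null(obs$T_leaf)) obs$T_leaf else rep(T_leaf, length(ci))
  fixed_rd <- !is.null(Rd25)

  rss_fun <- function(par) {
    p <- exp(par)   # positivity via log-parameterization
    rd <- if (fixed_rd) Rd25 else p[3]
    suppressWarnings({
      pr <- farquhar_params(p[1], p[2], rd, constants = constants)
      r <- a - farquhar_net_a(ci, ppfd, tl, pr)
    })
    sum(r^2)
  }
  starts <- list(c(60, 120, 1.5), c(30, 60, 0.8), c(100, 180, 2.5),
                 c(45, 140, 1), c(80, 100, 2))
  starts <- starts[seq_len(max(1, min(n_starts, length(starts))))]
  best <- NULL
  for (s in starts) {
    par0 <- log(if (fixed_rd) s[1:2] else s)
    o <- tryCatch(stats::optim(par0, rss_fun, method = "Nelder-Mead",
                               control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("fit_aci: all optimization starts failed")
  p <- exp(best$par)
  est <- c(Vcmax25 = p[1], Jmax25 = p[2],
           Rd25 = if (fixed_rd) Rd25 else p[3])

  warn <- character()
  # identifiability screen: is the fitted transition inside the Ci range?
  pr <- farquhar_params(est[1], est[2], est[3], constants = constants)
  k <- constants
  grid_ci <- seq(min(ci), max(ci), length.out = 50)
  Kc <- k$Kc25 * arrhenius(k$Ea_Kc, mean(tl))
  Ko <- k$Ko25 * arrhenius(k$Ea_Ko, mean(tl))
  Gs <- k$Gstar25 * arrhenius(k$Ea_Gstar, mean(tl))
  Vc <- est[1] * arrhenius(k$Ea_Vcmax, mean(tl))
  aI <- k$alpha_J * mean(ppfd)
  Jm <- est[2] * arrhenius(k$Ea_Jmax, mean(tl))
  J <- (aI + Jm - sqrt((aI + Jm)^2 - 4 * k$theta_J * aI * Jm)) / (2 * k$theta_J)
  wc <- Vc * (grid_ci - Gs) / (grid_ci + Kc * (1 + k$O / Ko))
  wj <- J * (grid_ci - Gs) / (4 * grid_ci + 8 * Gs)
  if (all(wc <= wj)) warn <- c(warn, "curve entirely Rubisco-limited; Jmax25 weakly identified")
  if (all(wj <= wc)) warn <- c(warn, "curve entirely RuBP-limited; Vcmax25 weakly identified")

  se <- tryCatch({
    h <- stats::optimHess(best$par, rss_fun)
    npar <- length(best$par)
    s2 <- best$value / max(1, length(a) - npar)
    cv <- 2 * s2 * solve(h)
    # delta method back from log scale
    sqrt(pmax(0, diag(cv))) * exp(best$par)
  }, error = function(e) rep(NA_real_, length(best$par)))
  se_full <- c(se[1], se[2], if (fixed_rd) 0 else se[3])
  names(se_full) <- names(est)

  structure(list(estimates = est, se = se_full, rss = best$value,
                 converged = best$convergence == 0, n_obs = length(a),
                 warnings = warn), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result (", if (x$converged) "converged" else "NOT converged",
      ", n = ", x$n_obs, ", RSS = ", signif(x$rss, 4), ")\n", sep = "")
  est <- data.frame(estimate = x$estimates, se = x$se)
  print(est)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Fit the plateau-then-decline VPD response
#'
#' Two-segment model for relative stomatal conductance versus VPD: flat at 1
#' up to the breakpoint VPD0, then a linear decline with continuity enforced
#' at the breakpoint. Conditional on VPD0 the decline slope has a closed
#' form, so the breakpoint is profiled over a grid of candidates spanning
#' the observed VPD range and the best candidate refined by golden-section
#' search between its neighbours.
#'
#' @param obs Data.frame with columns `vpd` and `gs_rel_obs`
#'   (or `value`/`gs_rel_obs` as written by [gen_gs_response()]).
#' @param n_grid Number of profile grid points, default 201.
#' @return A list of class `fit_result`: `estimates` (`VPD0`, `slope`),
#'   `rss`, `converged`, `n_obs`.
#' @export
fit_vpd_threshold <- function(obs, n_grid = 201) {
  v <- if (!is.null(obs$vpd)) obs$vpd else obs$value
  y <- obs$gs_rel_obs
  stopifnot(length(v) == length(y), length(v) >= 4)
  rng <- range(v)
  rss_at <- function(b) {
    d <- pmax(0, v - b)
    if (all(d == 0)) return(list(rss = sum((y - 1)^2), slope = 0))
    s <- sum((1 - y) * d) / sum(d^2)
    s <- max(0, s)
    list(rss = sum((y - (1 - s * d))^2), slope = s)
  }
  cand <- seq(rng[1], rng[2], length.out = n_grid)
  rss <- vapply(cand, function(b) rss_at(b)$rss, numeric(1))
  i <- which.min(rss)
  if (i == 1 || i == n_grid) {
    stop("fit_vpd_threshold: breakpoint unidentifiable (all points on one segment)")
  }
  opt <- stats::optimize(function(b) rss_at(b)$rss,
                         lower = cand[i - 1], upper = cand[i + 1], tol = 1e-8)
  sol <- rss_at(opt$minimum)
  structure(list(estimates = c(VPD0 = opt$minimum, slope = sol$slope),
                 se = c(VPD0 = NA_real_, slope = NA_real_),
                 rss = sol$rss, converged = TRUE, n_obs = length(v),
                 warnings = character()), class = "fit_result")
}

#' Fit a single Jarvis response shape
#'
#' Least-squares fit of the PPFD saturating hyperbola (half-saturation
#' `K_ppfd`) or the symmetric temperature optimum curve (`T_opt`,
#' `T_breadth`) to relative-conductance observations.
#'
#' @param obs Data.frame with columns `value` (the swept factor) and
#'   `gs_rel_obs`.
#' @param factor `"PPFD"` or `"T"`.
#' @return A `fit_result` with the shape estimates.
#' @export
fit_response <- function(obs, factor = c("PPFD", "T")) {
  factor <- match.arg(factor)
  x <- obs$value
  y <- obs$gs_rel_obs
  if (length(x) < 5) stop("fit_response: need >= 5 points")
  if (factor == "PPFD") {
    o <- stats::optimize(function(K) sum((y - x / (x + K))^2),
                         lower = 1, upper = 5000, tol = 1e-8)
    est <- c(K_ppfd = o$minimum)
    rss <- o$objective
  } else {
    fn <- function(p) {
      f <- pmin(1, pmax(0, 1 - ((x - p[1]) / p[2])^2))
      sum((y - f)^2)
    }
    o <- stats::optim(c(27, 15), fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    if (o$convergence != 0) stop("fit_response: optimizer did not converge")
    est <- c(T_opt = o$par[1], T_breadth = abs(o$par[2]))
    rss <- o$value
  }
  structure(list(estimates = est, se = rep(NA_real_, length(est)),
                 rss = rss, converged = TRUE, n_obs = length(x),
                 warnings = character()), class = "fit_result")
}

#' Estimate maximum stomatal conductance by the percentile rule
#'
#' Filters observations to the optimal-environment windows
#' (800 <= PPFD <= 1500 umol m^-2 s^-1, 20 <= T <= 30 degC,
#' 1.4 <= VPD <= 2 kPa, ambient CO2 380 umol mol^-1) and summarizes the
#' upper tail of the filtered conductances. The default rule is the mean of
#' the values strictly above the 90th percentile; `rule = "p90"` returns
#' the 90th percentile itself (the verbal form of the rule is ambiguous between
#' the two readings, so both are provided).
#'
#' @param obs Data.frame with columns `gs`, `ppfd`, `T_leaf`, `vpd`, and
#'   optionally `Ca` (rows with `Ca` != 380 are excluded when present).
#' @param rule `"mean_above_p90"` (default) or `"p90"`.
#' @return g_smax (mol m^-2 s^-1).
#' @export
estimate_gsmax <- function(obs, rule = c("mean_above_p90", "p90")) {
  rule <- match.arg(rule)
  conds <- list(
    ppfd = obs$ppfd >= 800 & obs$ppfd <= 1500,
    temp = obs$T_leaf >= 20 & obs$T_leaf <= 30,
    vpd = obs$vpd >= 1.4 & obs$vpd <= 2,
    ca = if (!is.null(obs$Ca)) abs(obs$Ca - 380) < 1e-6 else TRUE
  )
  keep <- Reduce(`&`, conds)
  if (!any(keep)) {
    fails <- vapply(conds, function(x) sum(!x), numeric(1))
    stop("estimate_gsmax: no observation passes the optimal-condition filter; ",
         "most restrictive condition: ", names(which.max(fails)))
  }
  g <- obs$gs[keep]
  q90 <- stats::quantile(g, 0.9, names = FALSE)
  if (rule == "p90") return(q90)
  top <- g[g > q90]
  if (!length(top)) return(q90)
  mean(top)
}

#' Fit all nitrogen-scaling lines
#'
#' Ordinary least squares of the five linear relations of the
#' light/nitrogen gradient: N_a versus daily cumulated PPFD, and Vcmax25,
#' Jmax25, Rd25 and g_smax versus N_a. Delegates to [fit_line()].
#'
#' @param samples Data.frame with per-leaf columns `PPFD_d`, `N_a`,
#'   `Vcmax25`, `Jmax25`, `Rd25`, `g_smax`.
#' @param jarvis,constants Shapes and constants for the assembled set.
#' @param label Treatment label.
#' @return A [leaf_function_set()] with an `r2` attribute (named vector) and
#'   a `fits` attribute carrying the full per-line results.
#' @export
fit_scaling_lines <- function(samples, jarvis = jarvis_params(),
                              constants = farquhar_constants(),
                              label = "fitted") {
  if (nrow(samples) < 3) stop("fit_scaling_lines: need >= 3 leaves")
  fits <- list(
    na = fit_line(samples$PPFD_d, samples$N_a),
    vcmax = fit_line(samples$N_a, samples$Vcmax25),
    jmax = fit_line(samples$N_a, samples$Jmax25),
    rd = fit_line(samples$N_a, samples$Rd25),
    gsmax = fit_line(samples$N_a, samples$g_smax)
  )
  co <- function(f) c(f$slope, f$intercept)
  out <- leaf_function_set(co(fits$na), co(fits$vcmax), co(fits$jmax),
                           co(fits$rd), co(fits$gsmax), jarvis = jarvis,
                           constants = constants, label = label)
  attr(out, "r2") <- vapply(fits, `[[`, numeric(1), "r2")
  attr(out, "fits") <- fits
  out
}

#' Simulation study of the A-Ci estimator
#'
#' Repeatedly generates noisy synthetic A-Ci curves at the standard 12-step
#' CO2 protocol and refits them, reporting bias and RMSE of the recovered
#' parameters -- the built-in check that the fitting pipeline recovers known
#' truth under realistic noise.
#'
#' @param truth A [truth_config()].
#' @param n_reps Number of replicate curves.
#' @param seed Integer seed.
#' @param n_starts Multistart count passed to [fit_aci()] (the default of 2
#'   keeps the study fast; raise for production use).
#' @return A list: `estimates` (n_reps x 2 matrix), `median_bias_pct`,
#'   `rmse`, `truth`.
#' @export
aci_simulation_study <- function(truth = truth_config(), n_reps = 100,
                                 seed = 1L, n_starts = 2) {
  est <- matrix(NA_real_, n_reps, 2,
                dimnames = list(NULL, c("Vcmax25", "Jmax25")))
  for (r in seq_len(n_reps)) {
    tr <- truth
    tr$seed <- substream_seed(seed, paste0("acistudy", r))
    d <- gen_aci_dataset(tr, n_leaves = 1)
    f <- fit_aci(d, T_leaf = 30, Rd25 = truth$farquhar$Rd25,
                 constants = truth$farquhar$constants, n_starts = n_starts)
    est[r, ] <- f$estimates[c("Vcmax25", "Jmax25")]
  }
  tru <- c(truth$farquhar$Vcmax25, truth$farquhar$Jmax25)
  bias <- sweep(est, 2, tru) / rep(tru, each = n_reps) * 100
  list(estimates = est,
       median_bias_pct = apply(abs(bias), 2, stats::median),
       rmse = sqrt(colMeans(sweep(est, 2, tru)^2)),
       truth = tru)
}
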