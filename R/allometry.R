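#' Fit an ordinary least-squares line
#'
#' Simple linear regression used for all the allometric relationships of the
#' form \eqn{y = a x + b} (shoot leaf area and leaf number versus shoot
#' length, leaf width and petiole length versus leaf length) as well as for
#' the nitrogen-scaling lines of the leaf-physiology module.
#'
#' @param x Predictor values (numeric, length >= 3, not constant).
#' @param y Response values, same length as `x`.
#' @return A list with `slope`, `intercept`, `r2`, `slope_se`,
#'   `intercept_se`, `n`.
#' @export
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fit_line: need at least 3 finite points")
  if (diff(range(x)) == 0) stop("fit_line: degenerate design, x is constant")
  fit <- stats::lm(y ~ x)
  # exact collinear input is legitimate here (zero-noise round trips)
  s <- suppressWarnings(summary(fit))
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    slope_se = s$coefficients[2, 2],
    intercept_se = s$coefficients[1, 2],
    n = length(x)
  )
}

#' Fit the quadratic leaf-area allometry
#'
#' Leaf area scales with the square of leaf length, \eqn{LA = a_{LA} LL^2},
#' with no intercept. The least-squares estimate is closed form:
#' \eqn{a = \sum LA \cdot LL^2 / \sum LL^4}.
#'
#' @param LL Leaf lengths (cm), all > 0.
#' @param LA Leaf areas (cm^2), all > 0.
#' @return The scalar coefficient `a_LA` (dimensionless).
#' @export
fit_power_la <- function(LL, LA) {
  stopifnot(length(LL) == length(LA), length(LL) >= 1)
  if (any(LL <= 0) || any(LA <= 0)) {
    stop("fit_power_la: leaf lengths and areas must be positive")
  }
  sum(LA * LL^2) / sum(LL^4)
}

#' Compare regression lines between groups (ANCOVA)
#'
#' Nested-model F-tests on the pooled regression: first a test for equality
#' of slopes (the x-by-group interaction), then a test for equality of
#' intercepts under a common slope (the group main effect in the additive
#' model). This is the slope-then-intercept testing order used to contrast
#' genotype/interstock combinations.
#'
#' @param groups A list of two or more elements, each a list or data.frame
#'   with components `x` and `y`.
#' @return A list of class `line_comparison`: `slope_p`, `intercept_p`, and
#'   per-group `slopes` and `intercepts`.
#' @export
compare_lines <- function(groups) {
  if (length(groups) < 2) stop("compare_lines: need at least 2 groups")
  dat <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(x = g$x, y = g$y, g = factor(i, levels = seq_along(groups)))
  }))
  full <- stats::lm(y ~ x * g, data = dat)
  add <- stats::lm(y ~ x + g, data = dat)
  nog <- stats::lm(y ~ x, data = dat)
  # nested-model F-tests computed explicitly; tiny negative SS differences
  # from floating-point cancellation are clamped at zero (F = 0, p = 1)
  nested_p <- function(small, big) {
    rss_s <- sum(stats::residuals(small)^2)
    rss_b <- sum(stats::residuals(big)^2)
    df_num <- small$df.residual - big$df.residual
    f <- max(0, (rss_s - rss_b) / df_num) / (rss_b / big$df.residual)
    stats::pf(f, df_num, big$df.residual, lower.tail = FALSE)
  }
  slope_p <- nested_p(add, full)
  intercept_p <- nested_p(nog, add)
  per <- lapply(groups, function(g) fit_line(g$x, g$y))
  structure(list(
    slope_p = slope_p,
    intercept_p = intercept_p,
    slopes = vapply(per, `[[`, numeric(1), "slope"),
    intercepts = vapply(per, `[[`, numeric(1), "intercept")
  ), class = "line_comparison")
}

#' Construct an allometric model
#'
#' Bundles the coefficients of the five allometric relationships that turn a
#' shoot skeleton into leaves: shoot leaf area (`SLA`, cm^2) and shoot leaf
#' number (`SLN`) as linear functions of shoot length (`SL`, cm), leaf area
#' (cm^2) as `a_LA * LL^2` of leaf length (cm), and leaf width / petiole
#' length (cm) as linear functions of leaf length.
#'
#' @param a_SLA,b_SLA Slope (cm^2 per cm) and intercept (cm^2) of SLA vs SL.
#' @param a_SLN,b_SLN Slope (leaves per cm) and intercept (leaves) of SLN vs SL.
#' @param a_LA Quadratic leaf-area coefficient (> 0, dimensionless).
#' @param a_LW,b_LW Slope and intercept (cm) of leaf width vs leaf length.
#' @param a_PL,b_PL Slope and intercept (cm) of petiole length vs leaf length.
#' @param r2 Optional named numeric vector of fit qualities per relation.
#' @return An object of class `allometric_model`.
#' @export
allometric_model <- function(a_SLA, b_SLA, a_SLN, b_SLN, a_LA,
                             a_LW, b_LW, a_PL, b_PL, r2 = NULL) {
  coefs <- c(a_SLA = a_SLA, b_SLA = b_SLA, a_SLN = a_SLN, b_SLN = b_SLN,
             a_LA = a_LA, a_LW = a_LW, b_LW = b_LW, a_PL = a_PL, b_PL = b_PL)
  if (any(!is.finite(coefs))) stop("allometric_model: all coefficients must be finite")
  if (a_LA <= 0) stop("allometric_model: a_LA must be > 0")
  structure(c(as.list(coefs), list(r2 = r2)), class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat("Allometric model:\n")
  cat(sprintf("  SLA = %.4g SL %+.4g   (cm^2)\n", x$a_SLA, x$b_SLA))
  cat(sprintf("  SLN = %.4g SL %+.4g   (leaves)\n", x$a_SLN, x$b_SLN))
  cat(sprintf("  LA  = %.4g LL^2      (cm^2)\n", x$a_LA))
  cat(sprintf("  LW  = %.4g LL %+.4g   (cm)\n", x$a_LW, x$b_LW))
  cat(sprintf("  PL  = %.4g LL %+.4g   (cm)\n", x$a_PL, x$b_PL))
  invisible(x)
}

#' Predict shoot-level leaf attributes from shoot length
#'
#' Applies the allometric model to a shoot length: shoot leaf area and leaf
#' number from their linear relations (leaf number rounded to the nearest
#' integer with a floor of one leaf; leaf area clamped at zero), mean leaf
#' area as their ratio, and mean internode length as `SL / SLN`.
#'
#' @param model An `allometric_model`.
#' @param SL Shoot length (cm, > 0). Vectorized.
#' @return A data.frame with columns `SL`, `SLA`, `SLN`, `mean_LA`,
#'   `internode`.
#' @export
predict_shoot <- function(model, SL) {
  stopifnot(inherits(model, "allometric_model"))
  if (any(SL <= 0)) stop("predict_shoot: SL must be > 0")
  SLA <- pmax(0, model$a_SLA * SL + model$b_SLA)
  SLN <- pmax(1, round_half_up(model$a_SLN * SL + model$b_SLN))
  data.frame(SL = SL, SLA = SLA, SLN = SLN,
             mean_LA = SLA / SLN, internode = SL / SLN)
}

#' Serialize / deserialize an allometric model as JSON
#'
#' @param model An `allometric_model`.
#' @param path File path to write to (or read from).
#' @return `write_allometric_model` returns `path` invisibly;
#'   `read_allometric_model` returns an `allometric_model`.
#' @export
write_allometric_model <- function(model, path) {
  stopifnot(inherits(model, "allometric_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_allometric_model
#' @export
read_allometric_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  allometric_model(x$a_SLA, x$b_SLA, x$a_SLN, x$b_SLN, x$a_LA,
                   x$a_LW, x$b_LW, x$a_PL, x$b_PL,
                   r2 = if (!is.null(x$r2)) unlist(x$r2))
}
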