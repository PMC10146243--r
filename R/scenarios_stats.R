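#' Build the scenario-switching design
#'
#' Twelve simulation specifications built from the four cultivar-by-
#' interstock treatments: the reference set S0 (rows a-d) pairs each
#' treatment's own leaf distribution (3D scene) with its own leaf functions;
#' S1 (rows e-h) swaps leaf functions between cultivars at a fixed
#' interstock; S2 (rows i-l) swaps leaf functions between interstocks at a
#' fixed cultivar. Comparing S0 and the switched scenarios disentangles the
#' contribution of canopy structure from that of leaf function.
#'
#' @param treatments Character vector of exactly 4 labels in the order
#'   `"<interstockA> <cultivarA>"`, ..., i.e. two interstocks crossed with
#'   two cultivars, e.g. `c("VD Fuji", "VD Gala", "VV Fuji", "VV Gala")`.
#' @return A data.frame of class `scenario_design` with columns
#'   `scenario_id` (e.g. `"S1e"`), `scenario` (`"S0"|"S1"|"S2"`), `row`
#'   (letter a-l), `distribution_source`, `function_source`.
#' @export
build_scenarios <- function(treatments = c("VD Fuji", "VD Gala",
                                           "VV Fuji", "VV Gala")) {
  if (length(treatments) != 4 || anyDuplicated(treatments)) {
    stop("build_scenarios: need exactly 4 distinct treatments")
  }
  parts <- strsplit(treatments, " ", fixed = TRUE)
  if (any(lengths(parts) != 2)) {
    stop("build_scenarios: treatments must be '<interstock> <cultivar>' labels")
  }
  inter <- vapply(parts, `[`, character(1), 1)
  cult <- vapply(parts, `[`, character(1), 2)
  if (length(unique(inter)) != 2 || length(unique(cult)) != 2) {
    stop("build_scenarios: treatments must cross 2 interstocks with 2 cultivars")
  }
  swap_cult <- function(t) {
    i <- which(treatments == t)
    other <- setdiff(unique(cult), cult[i])
    treatments[inter == inter[i] & cult == other]
  }
  swap_inter <- function(t) {
    i <- which(treatments == t)
    other <- setdiff(unique(inter), inter[i])
    treatments[cult == cult[i] & inter == other]
  }
  dist_src <- rep(treatments, 3)
  fun_src <- c(treatments,
               vapply(treatments, swap_cult, character(1)),
               vapply(treatments, swap_inter, character(1)))
  scen <- rep(c("S0", "S1", "S2"), each = 4)
  rows <- letters[1:12]
  out <- data.frame(scenario_id = paste0(scen, rows), scenario = scen,
                    row = rows, distribution_source = dist_src,
                    function_source = unname(fun_src))
  class(out) <- c("scenario_design", "data.frame")
  out
}

#' Run all scenarios of a design
#'
#' Simulates every scenario with the scene of its distribution source and
#' the leaf-function set of its function source, and returns one tidy row
#' per day per scenario.
#'
#' @param specs A `scenario_design` from [build_scenarios()].
#' @param scenes Named list of `canopy_scene`s, one per treatment.
#' @param funcs Named list of [leaf_function_set()]s, one per treatment.
#' @param weather A `weather_series`.
#' @param config A [sim_config()].
#' @return A data.frame: `scenario_id`, `scenario`, `distribution_source`,
#'   `function_source`, `doy`, `A_c`, `E_c`, `WUE_c`, `PPFD_d`, `class`.
#' @export
run_scenarios <- function(specs, scenes, funcs, weather,
                          config = sim_config()) {
  need <- unique(c(specs$distribution_source, specs$function_source))
  miss <- setdiff(need, intersect(names(scenes), names(funcs)))
  if (length(miss)) {
    stop("run_scenarios: missing scene or function set for treatment(s): ",
         paste(miss, collapse = ", "))
  }
  out <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    res <- run_season(scenes[[sp$distribution_source]],
                      funcs[[sp$function_source]], weather, config)
    out[[i]] <- cbind(sp[rep(1, nrow(res$days)),
                         c("scenario_id", "scenario", "distribution_source",
                           "function_source")],
                      res$days, row.names = NULL)
  }
  do.call(rbind, out)
}

#' Percent contrast between two means
#'
#' `100 * (x - ref) / ref`, the convention used for all treatment contrasts
#' (e.g. a VD-versus-VV difference expressed relative to VV).
#'
#' @param x Scenario or treatment mean.
#' @param ref Reference mean (non-zero).
#' @return Percent difference.
#' @export
percent_contrast <- function(x, ref) {
  if (any(ref == 0)) stop("percent_contrast: reference must be non-zero")
  100 * (x - ref) / ref
}

#' Two-way variance partition
#'
#' Sequential (type-I) sum-of-squares decomposition of a response into two
#' factors and their interaction, reporting for each term the percent of
#' total sum of squares and the F-test p-value. Intended for balanced
#' designs (every factor-level combination observed equally often), where
#' the sequential decomposition is order-invariant; unbalanced inputs are
#' rejected.
#'
#' @param data Data.frame containing the response and factor columns.
#' @param response Response column name.
#' @param factors Character vector of exactly 2 factor column names.
#' @return A list of class `variance_partition`: `table` (data.frame with
#'   `term`, `ss`, `percent`, `p`), rows being factor A, factor B, the
#'   interaction and the residual; percentages sum to 100.
#' @export
variance_partition <- function(data, response, factors) {
  if (length(factors) != 2) stop("variance_partition: exactly 2 factors required")
  df <- data.frame(y = data[[response]],
                   A = factor(data[[factors[1]]]),
                   B = factor(data[[factors[2]]]))
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    stop("variance_partition: each factor needs >= 2 levels")
  }
  tab <- table(df$A, df$B)
  if (any(tab == 0)) stop("variance_partition: empty factor-level cells")
  if (length(unique(as.vector(tab))) != 1) {
    stop("variance_partition: design must be balanced")
  }
  fit <- stats::aov(y ~ A * B, data = df)
  # noise-free designs (zero residual SS) are legitimate inputs here
  an <- suppressWarnings(stats::anova(fit))
  ss <- an[["Sum Sq"]]
  total <- sum(ss)
  terms <- c(factors[1], factors[2],
             paste(factors[1], factors[2], sep = ":"), "residual")
  out <- data.frame(term = terms, ss = ss,
                    percent = if (total > 0) 100 * ss / total else rep(0, 4),
                    p = c(an[["Pr(>F)"]][1:3], NA))
  structure(list(table = out), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("Variance partition (sequential SS):\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' RMSE, relative RMSE and accuracy class
#'
#' Root mean square error between observed and simulated values, its
#' percentage relative to the observed mean, and the conventional accuracy
#' class: excellent below 10%, good in \[10, 20)%, fair in \[20, 30)%, poor
#' at 30% and above.
#'
#' @param observed,simulated Equal-length numeric vectors (length >= 1).
#' @return A list: `rmse`, `rrmse` (percent; `NA` when the observed mean is
#'   zero), `class` (`NA` when rrmse is undefined), `n`.
#' @export
rmse_rrmse <- function(observed, simulated) {
  if (length(observed) != length(simulated) || length(observed) < 1) {
    stop("rmse_rrmse: inputs must be equal-length, non-empty")
  }
  rmse <- sqrt(mean((observed - simulated)^2))
  ob <- mean(observed)
  if (ob == 0) {
    warning("rmse_rrmse: observed mean is zero; RRMSE undefined")
    return(list(rmse = rmse, rrmse = NA_real_, class = NA_character_,
                n = length(observed)))
  }
  rrmse <- rmse / ob * 100
  cls <- if (rrmse < 10) "excellent" else if (rrmse < 20) "good"
         else if (rrmse < 30) "fair" else "poor"
  list(rmse = rmse, rrmse = rrmse, class = cls, n = length(observed))
}

#' Pairwise Welch comparisons between treatments
#'
#' Simple pairwise Welch t-tests with Holm adjustment, the package's
#' stand-in for a classical multiple-mean-comparison post-hoc.
#'
#' @param values Numeric response.
#' @param groups Grouping vector.
#' @return Data.frame: `group1`, `group2`, `diff`, `p`, `p_adj`.
#' @export
pairwise_welch <- function(values, groups) {
  g <- factor(groups)
  combs <- utils::combn(levels(g), 2)
  res <- apply(combs, 2, function(pr) {
    a <- values[g == pr[1]]; b <- values[g == pr[2]]
    tt <- stats::t.test(a, b)
    c(diff = mean(a) - mean(b), p = tt$p.value)
  })
  out <- data.frame(group1 = combs[1, ], group2 = combs[2, ],
                    diff = res["diff", ], p = res["p", ])
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}
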