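#' Plasticity scenario specification
#'
#' Defines the hypothetical cultivars of a plasticity scenario experiment:
#' each scenario fixes the yield-ability at `beta_fixed` and varies only the
#' yield-plasticity `alpha`, so simulated yields isolate the value of
#' responsiveness to environmental quality. The default six alphas span the
#' range observed in temperate japonica panels (0 to 0.6).
#'
#' @param alphas plasticity values, one per scenario (scenario names are
#'   CV1, CV2, ... in order).
#' @param beta_fixed fixed yield-ability, t/ha.
#' @param spy standardized potential yield, t/ha.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(alphas = seq(0, 0.6, length.out = 6),
                          beta_fixed = 8, spy = 8) {
  if (!length(alphas)) stop("alphas must be nonempty")
  if (!is.finite(beta_fixed) || beta_fixed <= 0) stop("beta_fixed must be > 0")
  structure(list(alphas = as.numeric(alphas), beta_fixed = beta_fixed,
                 spy = spy),
            class = "scenario_spec")
}

#' Run plasticity scenarios over a set of environments
#'
#' Simulates, for each scenario alpha, the yield
#' `alpha * (yp - spy) + beta_fixed` in every supplied environment, and
#' aggregates to calendar-decade means. The relative gain of each scenario
#' is reported against the first (zero- or lowest-plasticity) scenario:
#' `100 * (mean_s - mean_CV1) / mean_CV1` per decade.
#'
#' @param yp potential yields, t/ha, one per environment.
#' @param years calendar year of each environment.
#' @param spec a [scenario_spec()].
#' @return A list with `yields` (long data frame: scenario, alpha, year, yp,
#'   yield) and `decades` (scenario x decade means with `rel_gain_pct`).
#' @examples
#' run_scenarios(c(6, 8, 10), c(1985, 1995, 2005), scenario_spec())$decades
#' @export
run_scenarios <- function(yp, years, spec = scenario_spec()) {
  if (length(yp) != length(years)) stop("yp and years lengths differ")
  if (any(!is.finite(yp))) stop("yp must be finite")
  nm <- paste0("CV", seq_along(spec$alphas))
  yields <- do.call(rbind, lapply(seq_along(spec$alphas), function(s) {
    data.frame(scenario = nm[s], alpha = spec$alphas[s], year = years,
               yp = yp,
               yield = spec$alphas[s] * (yp - spec$spy) + spec$beta_fixed,
               stringsAsFactors = FALSE)
  }))
  yields$decade <- (yields$year %/% 10) * 10
  agg <- stats::aggregate(yield ~ scenario + alpha + decade, data = yields,
                          FUN = mean)
  names(agg)[names(agg) == "yield"] <- "mean_yield"
  cnt <- stats::aggregate(yield ~ scenario + decade, data = yields,
                          FUN = length)
  names(cnt)[names(cnt) == "yield"] <- "n"
  agg <- merge(agg, cnt, by = c("scenario", "decade"), sort = FALSE)
  ref <- agg[agg$scenario == nm[1], c("decade", "mean_yield")]
  names(ref)[2] <- "ref_yield"
  agg <- merge(agg, ref, by = "decade", sort = FALSE)
  agg$rel_gain_pct <- 100 * (agg$mean_yield - agg$ref_yield) / agg$ref_yield
  agg$ref_yield <- NULL
  agg <- agg[order(agg$scenario, agg$decade), ]
  rownames(agg) <- NULL
  list(yields = yields, decades = agg)
}

#' Ordinary linear trend over calendar years
#'
#' OLS of a quantity on year with a two-sided t-test on the slope. The slope
#' is reported both in y-units per year and scaled by 1000 (kg/ha/year when
#' y is in t/ha), the convention of genetic-gain reporting.
#'
#' @param years calendar years.
#' @param y values (e.g., yield-ability per cultivar, or yield).
#' @return A list of class `trend_result`: `slope`, `slope_per_1000`
#'   (slope x 1000), `intercept`, `p_value`, `n`, `se`.
#' @examples
#' linear_trend(1980:2010, 0.01 * (1980:2010 - 1920) + 5)
#' @export
linear_trend <- function(years, y) {
  ok <- is.finite(years) & is.finite(y)
  years <- years[ok]; y <- y[ok]
  n <- length(y)
  if (n < 3) stop("need at least 3 paired finite values")
  if (stats::var(years) == 0) stop("constant x: years have no spread")
  xc <- years - mean(years)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(years)
  res <- y - (intercept + slope * years)
  sigma2 <- sum(res^2) / (n - 2)
  se <- sqrt(sigma2 / sum(xc^2))
  tstat <- if (se > 0) slope / se else Inf * sign(slope)
  p <- if (is.finite(tstat)) 2 * stats::pt(abs(tstat), df = n - 2,
                                           lower.tail = FALSE)
       else 0
  if (se == 0 && slope == 0) p <- 1
  structure(list(slope = slope, slope_per_1000 = slope * 1000,
                 intercept = intercept, p_value = p, n = n, se = se),
            class = "trend_result")
}

#' Genetic gain of the genotypic coefficients
#'
#' Regresses yield-plasticity (alpha) and yield-ability (beta) on cultivar
#' release year, for the full coefficient table and optionally for a named
#' subgroup (e.g., the most widely grown cultivars). Also reports the
#' relative plasticity gain, the alpha slope expressed as percent per year
#' of the group's mean alpha.
#'
#' @param coeffs a `cultivar_coefficients` data frame that carries a
#'   `release_year` column.
#' @param subgroup_ids optional character vector of cultivar ids defining
#'   the subgroup; every id must be present in `coeffs`.
#' @return A list with elements `all` and (if requested) `subgroup`, each a
#'   list of `trend_result`s for `alpha` and `beta` plus
#'   `alpha_rel_gain_pct_per_yr`.
#' @export
subgroup_gain <- function(coeffs, subgroup_ids = NULL) {
  if (!"release_year" %in% names(coeffs))
    stop("coeffs must carry a release_year column")
  gain_one <- function(d) {
    a <- linear_trend(d$release_year, d$alpha)
    b <- linear_trend(d$release_year, d$beta)
    list(alpha = a, beta = b,
         alpha_rel_gain_pct_per_yr = 100 * a$slope / mean(d$alpha))
  }
  out <- list(all = gain_one(coeffs))
  if (!is.null(subgroup_ids)) {
    missing_ids <- setdiff(subgroup_ids, coeffs$cultivar_id)
    if (length(missing_ids))
      stop("subgroup ids absent from coefficients: ",
           paste(missing_ids, collapse = ", "))
    out$subgroup <- gain_one(coeffs[coeffs$cultivar_id %in% subgroup_ids, ])
  }
  out
}

#' Significance band label
#'
#' Formats a p-value with the report bands used throughout the package
#' figures: `***` P<0.001, `**` P<0.01, `*` P<0.05, `+` P<0.1, else `ns`.
#'
#' @param p p-value(s).
#' @return Character label(s).
#' @export
significance_band <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, 0.1, Inf),
      labels = c("***", "**", "*", "+", "ns"))
}
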