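#' Crop growth model parameters
#'
#' Collects the constants of the simple weather-driven crop growth model used
#' to compute the theoretical potential yield (Yp). The model integrates daily
#' canopy radiation capture and radiation-use efficiency, modulated by a
#' temperature response, and discounts grain yield by cold-induced spikelet
#' sterility driven by cooling degree-days during the reproductive window.
#'
#' Canopy closure follows a logistic curve in the developmental index (DVI)
#' up to heading (DVI = 1), after which interception declines linearly with
#' DVI at the senescence rate. Radiation-use efficiency is scaled by a
#' trapezoid temperature response. Spikelet fertility declines as a symmetric
#' logistic in accumulated cooling degree-days (CDD, base `t_base_cold`).
#'
#' @param rue_base radiation-use efficiency, g dry matter per MJ intercepted.
#' @param t_base_dev base temperature (deg C) for developmental effective
#'   temperature; daily development is driven by `max(0, tmean - t_base_dev)`.
#' @param t_base_cold base temperature (deg C) for cooling degree-days.
#' @param t_low,t_opt1,t_opt2,t_high knots (deg C) of the trapezoid
#'   temperature response on radiation use: 0 at/below `t_low`, 1 on
#'   `[t_opt1, t_opt2]`, 0 at/above `t_high`, linear in between.
#' @param f_max maximum fraction of incident radiation intercepted by a
#'   closed canopy.
#' @param f0 interception fraction at transplanting (DVI = 0).
#' @param dvi_closure DVI at which the canopy is effectively closed
#'   (interception reaches at least 95% of `f_max`).
#' @param senescence_rate decline in interception fraction per DVI unit
#'   beyond heading (DVI > 1).
#' @param harvest_index fraction of total biomass partitioned to grain.
#' @param cdd50 cooling degree-days (deg C d) at which fertility is 50%.
#' @param cdd_steepness logistic steepness of the sterility curve, per deg C d.
#' @param dvi_lo,dvi_hi DVI bounds of the cold-sensitive reproductive window.
#' @param moisture_target grain moisture content of the reported yield
#'   (0.14 = 14% moisture, the yield-trial convention).
#'
#' @return An object of class `cgm_params` (a named list).
#' @examples
#' p <- cgm_params()
#' temperature_factor(25, p)
#' @export
cgm_params <- function(rue_base = 1.6,
                       t_base_dev = 10,
                       t_base_cold = 20,
                       t_low = 10, t_opt1 = 20, t_opt2 = 30, t_high = 42,
                       f_max = 0.95,
                       f0 = 0.05,
                       dvi_closure = 0.7,
                       senescence_rate = 0.5,
                       harvest_index = 0.45,
                       cdd50 = 40,
                       cdd_steepness = 0.15,
                       dvi_lo = 0.75, dvi_hi = 1.0,
                       moisture_target = 0.14) {
  p <- list(rue_base = rue_base, t_base_dev = t_base_dev,
            t_base_cold = t_base_cold,
            t_low = t_low, t_opt1 = t_opt1, t_opt2 = t_opt2, t_high = t_high,
            f_max = f_max, f0 = f0, dvi_closure = dvi_closure,
            senescence_rate = senescence_rate, harvest_index = harvest_index,
            cdd50 = cdd50, cdd_steepness = cdd_steepness,
            dvi_lo = dvi_lo, dvi_hi = dvi_hi,
            moisture_target = moisture_target)
  validate_cgm_params(p)
  structure(p, class = "cgm_params")
}

validate_cgm_params <- function(p) {
  fr <- c("f_max", "f0", "harvest_index", "moisture_target")
  for (f in fr) {
    if (!is.finite(p[[f]]) || p[[f]] < 0 || p[[f]] > 1)
      stop(sprintf("cgm parameter '%s' must be a fraction in [0, 1]", f))
  }
  if (p$t_base_cold <= p$t_base_dev)
    stop("t_base_cold must exceed t_base_dev")
  if (!(p$t_low < p$t_opt1 && p$t_opt1 < p$t_opt2 && p$t_opt2 < p$t_high))
    stop("temperature knots must satisfy t_low < t_opt1 < t_opt2 < t_high")
  if (!(p$dvi_lo < p$dvi_hi && p$dvi_hi <= 1))
    stop("sensitive window must satisfy dvi_lo < dvi_hi <= 1")
  if (p$rue_base < 0 || p$senescence_rate < 0 || p$cdd50 <= 0 ||
      p$cdd_steepness <= 0)
    stop("rue_base, senescence_rate must be >= 0; cdd50, cdd_steepness > 0")
  invisible(p)
}

# --- weather / phenology validation ------------------------------------------

#' Construct a daily weather series
#'
#' @param site_id site identifier.
#' @param date vector of `Date`s (or coercible strings), strictly increasing
#'   with no gaps.
#' @param tmean daily mean air temperature, deg C.
#' @param srad daily solar radiation, MJ m-2 d-1 (>= 0).
#' @return A `data.frame` of class `weather_series` with columns
#'   `site_id`, `date`, `tmean_c`, `srad_mj_m2`.
#' @export
weather_series <- function(site_id, date, tmean, srad) {
  date <- as.Date(date)
  if (anyNA(date)) stop("weather dates contain NA or unparseable values")
  if (length(date) != length(tmean) || length(date) != length(srad))
    stop("date, tmean, srad must have equal length")
  if (any(!is.finite(tmean))) stop("tmean must be finite")
  if (any(!is.finite(srad) | srad < 0)) stop("srad must be finite and >= 0")
  d <- diff(as.integer(date))
  if (length(d) && any(d != 1L))
    stop("weather dates must be strictly increasing daily with no gaps")
  structure(
    data.frame(site_id = rep_len(site_id, length(date)), date = date,
               tmean_c = as.numeric(tmean), srad_mj_m2 = as.numeric(srad),
               stringsAsFactors = FALSE),
    class = c("weather_series", "data.frame"))
}

#' @param transplanting_date,heading_date,maturity_date calendar dates
#'   (`Date` or coercible), transplanting < heading < maturity.
#' @rdname weather_series
#' @export
phenology_record <- function(transplanting_date, heading_date, maturity_date) {
  d <- as.Date(c(transplanting_date, heading_date, maturity_date))
  if (anyNA(d)) stop("phenology dates contain NA or unparseable values")
  if (!(d[1] < d[2] && d[2] < d[3]))
    stop("phenology must satisfy transplanting < heading < maturity")
  structure(list(transplanting_date = d[1], heading_date = d[2],
                 maturity_date = d[3]),
            class = "phenology_record")
}

# Subset weather to [transplanting, maturity]; errors if not fully covered.
season_weather <- function(weather, phen) {
  idx <- weather$date >= phen$transplanting_date &
    weather$date <= phen$maturity_date
  w <- weather[idx, , drop = FALSE]
  expected <- as.integer(phen$maturity_date - phen$transplanting_date) + 1L
  if (nrow(w) != expected)
    stop(sprintf("weather series does not cover the season %s..%s (%d of %d days present)",
                 phen$transplanting_date, phen$maturity_date, nrow(w), expected))
  w
}

# --- developmental index -----------------------------------------------------

#' Developmental index (DVI) from effective temperature
#'
#' Computes the daily developmental index, the phenology scale that is 0 at
#' transplanting, 1 at heading and 2 at maturity. Within each phase the daily
#' increment is the day's effective temperature (exceedance of `tmean` above
#' `t_base_dev`) divided by the phase's cumulative effective temperature, so
#' the endpoints are exact by construction and no cultivar-specific thermal
#' requirements or daylength inputs are needed.
#'
#' The increment attributed to a boundary day belongs to the phase it closes:
#' days after transplanting up to and including heading advance DVI 0 to 1;
#' days after heading up to and including maturity advance DVI 1 to 2.
#'
#' @param weather a [weather_series()] covering the season.
#' @param phen a [phenology_record()].
#' @param t_base_dev base temperature, deg C (default 10).
#' @return A `data.frame` with columns `date` and `dvi` for every day of the
#'   closed season interval.
#' @examples
#' w <- weather_series("s", seq(as.Date("2000-05-01"), by = 1, length.out = 61),
#'                     tmean = rep(20, 61), srad = rep(15, 61))
#' ph <- phenology_record("2000-05-01", "2000-05-31", "2000-06-30")
#' dvi <- compute_dvi(w, ph)
#' dvi$dvi[dvi$date == as.Date("2000-05-31")]  # exactly 1
#' @export
compute_dvi <- function(weather, phen, t_base_dev = 10) {
  w <- season_weather(weather, phen)
  eff <- pmax(0, w$tmean_c - t_base_dev)
  phase <- ifelse(w$date <= phen$heading_date, 1L, 2L)
  # day 1 (transplanting) anchors DVI = 0; its effective temperature is not
  # consumed by either phase
  inc <- numeric(nrow(w))
  for (ph in 1:2) {
    sel <- which(phase == ph)
    if (ph == 1L) sel <- sel[sel != 1L]
    tot <- sum(eff[sel])
    if (tot <= 0)
      stop(sprintf("undevelopable phase: phase %d has zero cumulative effective temperature", ph))
    inc[sel] <- eff[sel] / tot
  }
  dvi <- cumsum(inc)
  data.frame(date = w$date, dvi = dvi)
}

# --- daily process curves ----------------------------------------------------

#' Canopy radiation interception as a function of DVI
#'
#' Logistic closure up to heading, then a linear senescence decline: for
#' `dvi <= 1` the intercepted fraction rises from `f0` at DVI 0 towards
#' `f_max`, reaching at least 95% of `f_max` at `dvi_closure`; beyond heading
#' it declines at `senescence_rate` per DVI unit, floored at 0.
#'
#' @param dvi developmental index value(s) in \[0, 2\].
#' @param params a [cgm_params()] object.
#' @return Fraction(s) of incident radiation captured, in \[0, `f_max`\].
#' @export
canopy_interception <- function(dvi, params = cgm_params()) {
  if (any(!is.finite(dvi) | dvi < 0 | dvi > 2))
    stop("dvi must lie in [0, 2]")
  # logistic through (0, f0) with >= 0.95*f_max at dvi_closure
  k <- logistic_rate(params$f0, params$f_max, params$dvi_closure)
  x0 <- log(params$f_max / params$f0 - 1) / k
  f_head <- params$f_max / (1 + exp(-k * (pmin(dvi, 1) - x0)))
  decline <- params$senescence_rate * pmax(0, dvi - 1)
  pmin(params$f_max, pmax(0, f_head - decline))
}

# Steepness k such that the logistic rising from f0 at x=0 toward f_max
# reaches 0.95*f_max at x = dvi_closure.
logistic_rate <- function(f0, f_max, dvi_closure) {
  (log(f_max / f0 - 1) - log(1 / 0.95 - 1)) / dvi_closure
}

#' Temperature response of radiation use
#'
#' Trapezoid response: 0 at/below `t_low`, rising linearly to 1 at `t_opt1`,
#' flat at 1 up to `t_opt2`, falling linearly to 0 at `t_high`.
#'
#' @param tmean daily mean air temperature(s), deg C.
#' @inheritParams canopy_interception
#' @return Factor(s) in \[0, 1\].
#' @export
temperature_factor <- function(tmean, params = cgm_params()) {
  if (any(!is.finite(tmean))) stop("tmean must be finite")
  up <- (tmean - params$t_low) / (params$t_opt1 - params$t_low)
  down <- (params$t_high - tmean) / (params$t_high - params$t_opt2)
  pmin(1, pmax(0, pmin(up, down)))
}

#' Cooling degree-days over the cold-sensitive window
#'
#' Accumulates `max(0, t_base_cold - tmean)` over the days whose DVI lies in
#' the reproductive-sensitive window `[dvi_lo, dvi_hi]` (booting to heading
#' by default). This is the driver of cold-induced spikelet sterility.
#'
#' @param weather a [weather_series()].
#' @param dvi the data frame returned by [compute_dvi()] (aligned by date).
#' @inheritParams canopy_interception
#' @return Cooling degree-days, deg C d (>= 0).
#' @export
cooling_degree_days <- function(weather, dvi, params = cgm_params()) {
  m <- match(dvi$date, weather$date)
  if (anyNA(m)) stop("dvi dates not aligned with weather days")
  tmean <- weather$tmean_c[m]
  inwin <- dvi$dvi >= params$dvi_lo & dvi$dvi <= params$dvi_hi
  if (!any(inwin)) {
    warning("empty cold-sensitive window; CDD set to 0")
    return(0)
  }
  sum(pmax(0, params$t_base_cold - tmean[inwin]))
}

#' Spikelet fertility as a function of cooling degree-days
#'
#' Symmetric logistic decline centered at `cdd50`: fertility is 1 with no
#' cold stress, 0.5 at `cdd50`, and strictly decreasing in CDD. The curve is
#' normalized so that fertility(0) is exactly 1.
#'
#' @param cdd cooling degree-days, deg C d (>= 0).
#' @inheritParams canopy_interception
#' @return Fertile fraction(s) in \[0, 1\].
#' @export
spikelet_fertility <- function(cdd, params = cgm_params()) {
  if (any(!is.finite(cdd) | cdd < 0)) stop("cdd must be finite and >= 0")
  raw <- function(x) 1 / (1 + exp(params$cdd_steepness * (x - params$cdd50)))
  pmin(1, pmax(0, raw(cdd) / raw(0)))
}

# --- season simulation -------------------------------------------------------

#' Simulate the theoretical potential yield for one environment
#'
#' Runs the daily crop growth model across the closed season interval
#' \[transplanting, maturity\]: each day's biomass increment is
#' `srad * canopy_interception(dvi) * rue_base * temperature_factor(tmean)`
#' (g dry matter m-2); total biomass times the harvest index and the spikelet
#' fertility gives grain dry mass, which is converted to fresh yield at the
#' target moisture content (dry mass / (1 - moisture)) and expressed in t/ha.
#'
#' @inheritParams compute_dvi
#' @inheritParams canopy_interception
#' @return A list of class `yp_result` with elements `yp` (t/ha at the target
#'   moisture), `biomass` (t dry matter/ha), `fertility` (fraction), `cdd`
#'   (deg C d) and `dvi` (the per-day DVI data frame).
#' @examples
#' w <- weather_series("s", seq(as.Date("2000-05-01"), by = 1, length.out = 121),
#'                     tmean = rep(24, 121), srad = rep(16, 121))
#' ph <- phenology_record("2000-05-01", "2000-07-20", "2000-08-29")
#' simulate_potential_yield(w, ph)$yp
#' @export
simulate_potential_yield <- function(weather, phen, params = cgm_params()) {
  w <- season_weather(weather, phen)
  dvi <- compute_dvi(weather, phen, params$t_base_dev)
  interc <- canopy_interception(dvi$dvi, params)
  tfac <- temperature_factor(w$tmean_c, params)
  inc_g_m2 <- w$srad_mj_m2 * interc * params$rue_base * tfac
  biomass_g_m2 <- sum(inc_g_m2)
  biomass_t_ha <- biomass_g_m2 * 0.01      # g m-2 -> t ha-1
  cdd <- cooling_degree_days(w, dvi, params)
  fert <- spikelet_fertility(cdd, params)
  grain_dry <- biomass_t_ha * params$harvest_index * fert
  yp <- grain_dry / (1 - params$moisture_target)
  structure(list(yp = yp, biomass = biomass_t_ha, fertility = fert,
                 cdd = cdd, dvi = dvi),
            class = "yp_result")
}

#' Add a potential-yield column to a trial table
#'
#' For every trial row, subsets the weather table to the row's site and
#' season, runs [simulate_potential_yield()], and appends `yp_t_ha` plus the
#' season-cumulative effective temperature (`cum_temp_c`) and solar radiation
#' (`cum_srad_mj`) used by the predictor-comparison analysis.
#'
#' Rows whose weather coverage or phenology is invalid get `NA` with the
#' reason collected in the `"dropped"` attribute rather than failing the
#' whole table.
#'
#' @param trials a trial data frame with columns `cultivar_id`, `site_id`,
#'   `year`, `transplanting_date`, `heading_date`, `maturity_date`,
#'   `yield_t_ha`.
#' @param weather a [weather_series()] (possibly covering several sites,
#'   row-bound).
#' @inheritParams canopy_interception
#' @return `trials` with columns `yp_t_ha`, `cum_temp_c`, `cum_srad_mj`
#'   appended; attribute `dropped` is a data frame of failed rows and reasons.
#' @export
add_potential_yield <- function(trials, weather, params = cgm_params()) {
  stopifnot(is.data.frame(trials))
  n <- nrow(trials)
  yp <- cumt <- cums <- rep(NA_real_, n)
  fail <- character(0); fail_row <- integer(0)
  for (i in seq_len(n)) {
    res <- tryCatch({
      phen <- phenology_record(trials$transplanting_date[i],
                               trials$heading_date[i],
                               trials$maturity_date[i])
      wsite <- weather[weather$site_id == trials$site_id[i], , drop = FALSE]
      r <- simulate_potential_yield(wsite, phen, params)
      w <- season_weather(wsite, phen)
      list(yp = r$yp,
           cumt = sum(pmax(0, w$tmean_c - params$t_base_dev)),
           cums = sum(w$srad_mj_m2))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fail <- c(fail, conditionMessage(res)); fail_row <- c(fail_row, i)
    } else {
      yp[i] <- res$yp; cumt[i] <- res$cumt; cums[i] <- res$cums
    }
  }
  trials$yp_t_ha <- yp
  trials$cum_temp_c <- cumt
  trials$cum_srad_mj <- cums
  attr(trials, "dropped") <-
    data.frame(row = fail_row, reason = fail, stringsAsFactors = FALSE)
  trials
}
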