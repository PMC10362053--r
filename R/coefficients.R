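#' Standardized-potential-yield configuration
#'
#' Settings for converting per-cultivar yield regressions into the two
#' genotypic coefficients: `spy` is the standardized potential yield at which
#' yield-ability is read off (8 t/ha covers the potential-yield range most
#' cultivars experience), `min_trials` the minimum number of trials a
#' cultivar must retain to be fit, and `outlier_sd` the outlier rule
#' multiplier (records more than `outlier_sd` standard deviations from the
#' cultivar median are dropped).
#'
#' @param spy standardized potential yield, t/ha (> 0).
#' @param min_trials minimum retained trials per cultivar (inclusive bound).
#' @param outlier_sd standard-deviation multiplier of the outlier rule.
#' @return An object of class `spy_config`.
#' @export
spy_config <- function(spy = 8, min_trials = 20, outlier_sd = 4.0) {
  if (!is.finite(spy) || spy <= 0) stop("spy must be > 0")
  if (!is.finite(outlier_sd) || outlier_sd <= 0) stop("outlier_sd must be > 0")
  if (!is.finite(min_trials) || min_trials < 3) stop("min_trials must be >= 3")
  structure(list(spy = spy, min_trials = as.integer(min_trials),
                 outlier_sd = outlier_sd),
            class = "spy_config")
}

#' Clean yield-trial records
#'
#' Cleaning applied before any regression. First, records with negative or
#' non-finite yields are dropped as invalid. Then per cultivar:
#' (1) drop records whose yield lies more than `outlier_sd` standard
#' deviations (sample SD about the mean) from the cultivar's *median* yield;
#' (2) drop cultivars left with fewer than `min_trials` records. Every
#' dropped record is listed in the exclusion log with the rule that removed
#' it.
#'
#' @param records trial data frame with at least `cultivar_id` and
#'   `yield_t_ha` columns.
#' @param cfg a [spy_config()].
#' @return A list with `kept` (the surviving records) and `log` (a data
#'   frame: `cultivar_id`, `row`, `yield_t_ha`, `rule`).
#' @export
clean_trials <- function(records, cfg = spy_config()) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    warning("no trial records supplied")
    return(list(kept = records,
                log = data.frame(cultivar_id = character(0), row = integer(0),
                                 yield_t_ha = numeric(0), rule = character(0),
                                 stringsAsFactors = FALSE)))
  }
  records$.row <- seq_len(nrow(records))
  keep <- rep(TRUE, nrow(records))
  rule <- rep(NA_character_, nrow(records))
  bad <- !is.finite(records$yield_t_ha) | records$yield_t_ha < 0
  keep[bad] <- FALSE
  rule[bad] <- "invalid: negative or non-finite yield"
  for (cv in unique(records$cultivar_id)) {
    idx <- which(records$cultivar_id == cv & keep)
    y <- records$yield_t_ha[idx]
    med <- stats::median(y)
    s <- stats::sd(y)
    if (is.finite(s) && s > 0) {
      out <- abs(y - med) > cfg$outlier_sd * s
      keep[idx[out]] <- FALSE
      rule[idx[out]] <- sprintf("outlier: |yield - median| > %.1f SD", cfg$outlier_sd)
    }
    left <- idx[keep[idx]]
    if (length(left) < cfg$min_trials) {
      keep[left] <- FALSE
      rule[left] <- sprintf("cultivar below %d trials", cfg$min_trials)
    }
  }
  log <- data.frame(cultivar_id = records$cultivar_id[!keep],
                    row = records$.row[!keep],
                    yield_t_ha = records$yield_t_ha[!keep],
                    rule = rule[!keep], stringsAsFactors = FALSE)
  kept <- records[keep, setdiff(names(records), ".row"), drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, log = log)
}

#' Fit the yield regression of one cultivar
#'
#' Ordinary least squares of observed yield on potential yield for a single
#' cultivar: `yield = alpha * yp + b`. The intercept is reparameterized at
#' the standardized potential yield as the yield-ability
#' `beta = alpha * spy + b`, the expected yield when the environment offers
#' `spy` t/ha of potential yield; `alpha` is the yield-plasticity, the
#' responsiveness of the cultivar to environmental quality.
#'
#' @param yp potential yields, t/ha (the environmental index).
#' @param yield_obs observed yields, t/ha.
#' @param cfg a [spy_config()].
#' @param cultivar_id optional identifier carried into the result.
#' @return A one-row data frame of class `cultivar_coefficients` with columns
#'   `cultivar_id`, `n_trials`, `alpha`, `beta`, `b`, `rmse`, `r2_fit`.
#' @examples
#' fit_cultivar_coefficients(c(4, 6, 8, 10), c(4, 5, 6, 7))
#' @export
fit_cultivar_coefficients <- function(yp, yield_obs, cfg = spy_config(),
                                      cultivar_id = NA_character_) {
  if (length(yp) != length(yield_obs)) stop("yp and yield_obs lengths differ")
  if (length(yp) < 3) stop("need at least 3 (yp, yield) pairs")
  if (any(!is.finite(yp)) || any(!is.finite(yield_obs)))
    stop("yp and yield_obs must be finite")
  if (stats::var(yp) == 0) stop("degenerate design: all yp values identical")
  fit <- stats::lm.fit(cbind(1, yp), yield_obs)
  b <- unname(fit$coefficients[1]); alpha <- unname(fit$coefficients[2])
  res <- fit$residuals
  rmse <- sqrt(mean(res^2))
  sst <- sum((yield_obs - mean(yield_obs))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 1
  structure(
    data.frame(cultivar_id = cultivar_id, n_trials = length(yp),
               alpha = alpha, beta = alpha * cfg$spy + b, b = b,
               rmse = rmse, r2_fit = r2, stringsAsFactors = FALSE),
    class = c("cultivar_coefficients", "data.frame"))
}

#' Leave-one-out cross-validation of the cultivar regression
#'
#' For each environment j, refits the yield-on-Yp regression without j,
#' predicts environment j, and compares the ratio of predicted-value
#' variation to total variation (`r2_pred`) with the in-sample coefficient
#' of determination (`r2_fit`). A small gap indicates the cultivar
#' regression is robust and does not overfit. `r2_pred` can be negative and
#' is reported as computed.
#'
#' @inheritParams fit_cultivar_coefficients
#' @return A list with `r2_fit` and `r2_pred`.
#' @export
loocv_r2 <- function(yp, yield_obs) {
  n <- length(yp)
  if (n < 3) stop("need at least 3 pairs for LOOCV")
  if (stats::var(yp) == 0) stop("degenerate design: all yp values identical")
  pred <- numeric(n)
  for (j in seq_len(n)) {
    if (stats::var(yp[-j]) == 0)
      stop(sprintf("leave-one-out fold %d is degenerate (constant yp)", j))
    f <- stats::lm.fit(cbind(1, yp[-j]), yield_obs[-j])
    pred[j] <- f$coefficients[1] + f$coefficients[2] * yp[j]
  }
  sst <- sum((yield_obs - mean(yield_obs))^2)
  full <- stats::lm.fit(cbind(1, yp), yield_obs)
  r2_fit <- if (sst > 0) 1 - sum(full$residuals^2) / sst else 1
  r2_pred <- if (sst > 0) 1 - sum((yield_obs - pred)^2) / sst else 1
  list(r2_fit = r2_fit, r2_pred = r2_pred)
}

#' Fit coefficients for every cultivar in a trial table
#'
#' Convenience wrapper: cleans the table with [clean_trials()], then fits
#' [fit_cultivar_coefficients()] and [loocv_r2()] per cultivar on the rows
#' with a finite `yp_t_ha`.
#'
#' @param trials trial data frame with `cultivar_id`, `yield_t_ha`,
#'   `yp_t_ha` columns (see [add_potential_yield()]).
#' @param cfg a [spy_config()].
#' @param loocv compute LOOCV r2_pred per cultivar (O(n^2) per cultivar).
#' @return A `cultivar_coefficients` data frame, one row per retained
#'   cultivar, with `r2_pred` (NA unless `loocv = TRUE`); the cleaning log is
#'   in attribute `"exclusions"`.
#' @export
fit_all_cultivars <- function(trials, cfg = spy_config(), loocv = FALSE) {
  miss <- !is.finite(trials$yp_t_ha)
  if (any(miss)) trials <- trials[!miss, , drop = FALSE]
  cl <- clean_trials(trials, cfg)
  out <- lapply(unique(cl$kept$cultivar_id), function(cv) {
    d <- cl$kept[cl$kept$cultivar_id == cv, ]
    cc <- fit_cultivar_coefficients(d$yp_t_ha, d$yield_t_ha, cfg, cv)
    cc$r2_pred <- if (loocv) loocv_r2(d$yp_t_ha, d$yield_t_ha)$r2_pred else NA_real_
    cc
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cultivar_id = character(0), n_trials = integer(0),
                      alpha = numeric(0), beta = numeric(0), b = numeric(0),
                      rmse = numeric(0), r2_fit = numeric(0),
                      r2_pred = numeric(0), stringsAsFactors = FALSE)
  attr(res, "exclusions") <- cl$log
  class(res) <- c("cultivar_coefficients", "data.frame")
  res
}

#' Compare the potential-yield predictor against alternatives
#'
#' For each cultivar, regresses observed yield separately on each candidate
#' single predictor (the crop-model potential yield, season cumulative
#' temperature or radiation, panicle traits) and reports the per-cultivar
#' RMSE, plus the percent difference of each alternative relative to the
#' potential-yield RMSE: `100 * (rmse_x - rmse_yp) / rmse_x`.
#'
#' @param records trial data frame containing `cultivar_id`, `yield_t_ha`
#'   and the predictor columns.
#' @param predictors character vector of predictor column names; must
#'   include `"yp_t_ha"` for the percent-difference baseline.
#' @param min_n minimum records per cultivar to attempt a fit.
#' @return Long-format data frame: `cultivar_id`, `predictor`, `n`, `rmse`,
#'   `pct_diff_vs_yp`.
#' @export
compare_predictor_rmse <- function(records,
                                   predictors = c("yp_t_ha", "cum_temp_c",
                                                  "cum_srad_mj"),
                                   min_n = 3) {
  missing_cols <- setdiff(predictors, names(records))
  if (length(missing_cols))
    stop("predictor columns absent: ", paste(missing_cols, collapse = ", "))
  rows <- list()
  for (cv in unique(records$cultivar_id)) {
    d <- records[records$cultivar_id == cv, , drop = FALSE]
    for (p in predictors) {
      x <- d[[p]]; y <- d$yield_t_ha
      ok <- is.finite(x) & is.finite(y)
      rmse <- NA_real_
      if (sum(ok) >= min_n) {
        if (stats::var(x[ok]) == 0) {
          warning(sprintf("predictor '%s' constant within cultivar %s; RMSE recorded as NA",
                          p, cv))
        } else {
          f <- stats::lm.fit(cbind(1, x[ok]), y[ok])
          rmse <- sqrt(mean(f$residuals^2))
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(cultivar_id = cv, predictor = p, n = sum(ok), rmse = rmse,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  base <- out[out$predictor == "yp_t_ha", c("cultivar_id", "rmse")]
  names(base)[2] <- "rmse_yp"
  out <- merge(out, base, by = "cultivar_id", sort = FALSE)
  out$pct_diff_vs_yp <- 100 * (out$rmse - out$rmse_yp) / out$rmse
  out$rmse_yp <- NULL
  out
}

#' Predict yield from the genotypic coefficients
#'
#' Evaluates `alpha * (yp - spy) + beta` for a cultivar: at `yp = spy` the
#' prediction is exactly the yield-ability `beta`.
#'
#' @param coeffs a one-row `cultivar_coefficients` data frame, or any list
#'   with `alpha` and `beta` elements.
#' @param yp potential yield(s), t/ha.
#' @param cfg a [spy_config()] (supplies `spy`).
#' @return Predicted yield(s), t/ha.
#' @export
predict_yield <- function(coeffs, yp, cfg = spy_config()) {
  if (any(!is.finite(yp))) stop("yp must be finite")
  coeffs$alpha * (yp - cfg$spy) + coeffs$beta
}
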