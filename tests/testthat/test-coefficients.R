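test_that("cleaning drops outliers from the median and thin cultivars", {
  cfg <- spy_config(min_trials = 20)
  # all identical yields: zero deviation, nothing dropped
  same <- data.frame(cultivar_id = "cv1", yield_t_ha = rep(6, 25))
  expect_equal(nrow(clean_trials(same, cfg)$kept), 25)
  # 21 records, one gross outlier: direct median/SD arithmetic flags it
  y <- c(seq(5.5, 6.5, length.out = 20), 30)
  expect_gt(abs(30 - median(y)), 4 * sd(y))
  tb <- data.frame(cultivar_id = "cv1", yield_t_ha = y)
  cl <- clean_trials(tb, cfg)
  expect_equal(nrow(cl$kept), 20)
  expect_equal(cl$log$yield_t_ha, 30)
  expect_match(cl$log$rule, "outlier")
  # a cultivar left with 19 records is excluded entirely
  thin <- data.frame(cultivar_id = "cv2",
                     yield_t_ha = c(seq(5.5, 6.5, length.out = 19), 30))
  cl2 <- clean_trials(thin, cfg)
  expect_equal(nrow(cl2$kept), 0)
  expect_equal(sum(grepl("outlier", cl2$log$rule)), 1)
  expect_equal(sum(grepl("below 20", cl2$log$rule)), 19)
  # exactly 20 survivors are kept (inclusive threshold)
  ok20 <- data.frame(cultivar_id = "cv3",
                     yield_t_ha = seq(5, 7, length.out = 20))
  expect_equal(nrow(clean_trials(ok20, cfg)$kept), 20)
  expect_warning(clean_trials(same[0, , drop = FALSE], cfg), "no trial")
})

test_that("coefficient fits reproduce exact lines and the flat response", {
  cfg <- spy_config(spy = 8)
  yp <- c(2, 4, 6, 8, 10)
  cc <- fit_cultivar_coefficients(yp, 0.5 * yp + 2, cfg)
  expect_equal(cc$alpha, 0.5, tolerance = 1e-12)
  expect_equal(cc$b, 2, tolerance = 1e-12)
  expect_equal(cc$beta, 6, tolerance = 1e-12)
  expect_equal(cc$rmse, 0, tolerance = 1e-10)
  expect_equal(cc$r2_fit, 1, tolerance = 1e-12)
  # constant yield 8 over any yp spread: zero plasticity, ability 8
  flat <- fit_cultivar_coefficients(yp, rep(8, 5), cfg)
  expect_equal(flat$alpha, 0, tolerance = 1e-12)
  expect_equal(flat$beta, 8, tolerance = 1e-12)
  expect_error(fit_cultivar_coefficients(rep(5, 5), 1:5, cfg), "degenerate")
  expect_error(fit_cultivar_coefficients(1:2, 1:2, cfg), "at least 3")
})

test_that("fits equal the closed-form normal-equations oracle", {
  set.seed(42)
  for (rep in 1:5) {
    yp <- runif(50, 1, 10)
    y <- 0.4 * yp + 3 + rnorm(50, 0, 0.8)
    cc <- fit_cultivar_coefficients(yp, y)
    o <- ols_oracle(yp, y)
    expect_equal(cc$alpha, o$slope, tolerance = 1e-10)
    expect_equal(cc$b, o$intercept, tolerance = 1e-10)
    expect_equal(cc$rmse, o$rmse, tolerance = 1e-10)
    expect_equal(cc$r2_fit, o$r2, tolerance = 1e-10)
  }
})

test_that("beta identity and shift equivariance hold for every fit", {
  set.seed(7)
  cfg <- spy_config(spy = 8)
  for (rep in 1:20) {
    yp <- runif(30, 0.5, 9.5)
    y <- runif(1, -0.2, 0.9) * yp + runif(1, 2, 6) + rnorm(30, 0, 0.84)
    cc <- fit_cultivar_coefficients(yp, y, cfg)
    expect_equal(cc$beta, cc$alpha * 8 + cc$b, tolerance = 1e-12)
    # +c on yields moves b and beta by c, alpha fixed
    cc_y <- fit_cultivar_coefficients(yp, y + 1.7, cfg)
    expect_equal(cc_y$alpha, cc$alpha, tolerance = 1e-10)
    expect_equal(cc_y$beta, cc$beta + 1.7, tolerance = 1e-10)
    expect_equal(cc_y$b, cc$b + 1.7, tolerance = 1e-10)
    # +d on yp leaves alpha and shifts beta by -alpha*d: the refit line is
    # the old line translated right, so its value at the fixed SPY drops
    cc_x <- fit_cultivar_coefficients(yp + 2.5, y, cfg)
    expect_equal(cc_x$alpha, cc$alpha, tolerance = 1e-10)
    expect_equal(cc_x$beta, cc$beta - cc$alpha * 2.5, tolerance = 1e-10)
  }
})

test_that("LOOCV equals the brute-force refit-per-fold oracle", {
  # perfect line: both coefficients of determination are 1
  yp <- c(2, 5, 8, 11)
  r <- loocv_r2(yp, 0.3 * yp + 4)
  expect_equal(r$r2_fit, 1, tolerance = 1e-12)
  expect_equal(r$r2_pred, 1, tolerance = 1e-9)
  # minimal n=3 case: each fold is an exact 2-point fit
  expect_silent(loocv_r2(c(1, 2, 3), c(1.1, 1.9, 3.2)))
  # seeded noisy pairs vs a naive per-fold oracle
  set.seed(11)
  yp <- runif(30, 1, 10)
  y <- 0.5 * yp + 2 + rnorm(30, 0, 0.84)
  got <- loocv_r2(yp, y)
  pred <- vapply(seq_along(yp), function(j) {
    o <- ols_oracle(yp[-j], y[-j])
    o$intercept + o$slope * yp[j]
  }, numeric(1))
  r2_pred_oracle <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(got$r2_pred, r2_pred_oracle, tolerance = 1e-10)
  expect_equal(got$r2_fit, ols_oracle(yp, y)$r2, tolerance = 1e-10)
})

test_that("prediction from coefficients is the SPY-centered line", {
  cfg <- spy_config(spy = 8)
  cc <- list(alpha = 0.6, beta = 8)
  expect_equal(predict_yield(cc, 8, cfg), 8)
  expect_equal(predict_yield(cc, 10, cfg), 9.2)
  expect_equal(predict_yield(list(alpha = 0, beta = 8), c(1, 5, 12), cfg),
               rep(8, 3))
  expect_error(predict_yield(cc, NaN, cfg), "finite")
})

test_that("predictor RMSE comparison ranks the true driver first", {
  set.seed(21)
  n <- 80
  yp <- runif(n, 1, 10)
  d <- data.frame(cultivar_id = "cv1", yp_t_ha = yp,
                  yield_t_ha = 0.5 * yp + 2 + rnorm(n, 0, 0.5),
                  cum_temp_c = yp, noise = rnorm(n),
                  const = 1)
  out <- compare_predictor_rmse(d, c("yp_t_ha", "cum_temp_c", "noise"))
  rm <- setNames(out$rmse, out$predictor)
  # identical regressor: identical RMSE, zero percent difference
  expect_equal(unname(rm["cum_temp_c"]), unname(rm["yp_t_ha"]),
               tolerance = 1e-12)
  expect_equal(out$pct_diff_vs_yp[out$predictor == "cum_temp_c"], 0,
               tolerance = 1e-9)
  # pure-noise predictor loses to the true driver
  expect_gt(rm["noise"], rm["yp_t_ha"])
  expect_gt(out$pct_diff_vs_yp[out$predictor == "noise"], 0)
  # constant predictor: NA with a warning
  expect_warning(out2 <- compare_predictor_rmse(d, c("yp_t_ha", "const")),
                 "constant")
  expect_true(is.na(out2$rmse[out2$predictor == "const"]))
  # zero-residual fit has RMSE 0
  d0 <- data.frame(cultivar_id = "c", yp_t_ha = 1:10,
                   yield_t_ha = 0.3 * (1:10) + 1)
  expect_equal(compare_predictor_rmse(d0, "yp_t_ha")$rmse, 0,
               tolerance = 1e-10)
})

test_that("fit_all_cultivars ties cleaning, fitting and LOOCV together", {
  truth <- gen_truth(4, seed = 5)
  trials <- gen_trials(truth, env_count = 40, seed = 6, sd_resid = 0.3)
  co <- fit_all_cultivars(trials, spy_config(min_trials = 20), loocv = TRUE)
  expect_equal(nrow(co), 4)
  expect_equal(co$cultivar_id, truth$cultivar_id)
  expect_true(all(abs(co$alpha - truth$alpha) < 0.1))
  expect_true(all(is.finite(co$r2_pred)))
  expect_true(all(abs(co$beta - (co$alpha * 8 + co$b)) < 1e-12))
})
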