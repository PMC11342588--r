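test_that("min-max standardization rescales to [0,1] and rejects constants", {
  expect_equal(minmax_standardize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 1)
  expect_equal(minmax_standardize(x), x)        # idempotent on [0,1] span
  set.seed(1); z <- rnorm(10)
  expect_equal(order(minmax_standardize(z)), order(z))  # order-preserving
  expect_error(minmax_standardize(c(5, 5, 5), "wait"), "wait")
})

test_that("the lagged panel joins mobility at t with indices at t-1", {
  provinces <- sprintf("P%03d", 1:87)
  idx <- expand.grid(province_id = provinces, year = 2019:2021,
                     attraction = c("interventions", "quality"),
                     stringsAsFactors = FALSE)
  set.seed(5)
  idx$gravity <- rnorm(nrow(idx))
  idx$total <- idx$intra <- idx$inter <- abs(idx$gravity)
  mob <- expand.grid(province_id = provinces, year = 2020:2022,
                     stringsAsFactors = FALSE)
  mob$paz_intra <- 80
  mob$paz_inter <- 20
  panel <- build_lagged_panel(idx, mob)
  expect_equal(nrow(panel), 261)  # 87 provinces x 3 mobility years
  expect_setequal(unique(panel$year), 2020:2022)
  # the I_G attached to mobility year t is the index of year t-1
  expect_equal(panel$I_G[panel$province_id == "P001" & panel$year == 2020],
               idx$gravity[idx$province_id == "P001" & idx$year == 2019 &
                             idx$attraction == "interventions"])

  # a mobility year with no prior index year is dropped
  mob2 <- mob
  mob2$year <- mob2$year + 10
  expect_error(suppressMessages(build_lagged_panel(idx, mob2)), "empty panel")
  mob3 <- rbind(mob, data.frame(province_id = "P001", year = 2030,
                                paz_intra = 1, paz_inter = 1))
  expect_message(p3 <- build_lagged_panel(idx, mob3), "dropped 1")
  expect_equal(nrow(p3), 261)
})

test_that("the within estimator recovers noiseless slopes exactly and equals LSDV", {
  clean <- sim_panel(2, n_units = 5, n_periods = 4,
                     beta = c(x1 = -1.5, x2 = 0.75), noise_sd = 0)
  fit <- fit_fixed_effects(clean, y ~ x1 + x2)
  expect_equal(setNames(fit$coefficients$estimate, fit$coefficients$term),
               c(x1 = -1.5, x2 = 0.75))
  expect_equal(fit$within_r2, 1)

  noisy <- sim_panel(3, n_units = 5, n_periods = 6,
                     beta = c(x1 = 2, x2 = -1), noise_sd = 0.5)
  fe <- fit_fixed_effects(noisy, y ~ x1 + x2)
  lsdv <- stats::lm(y ~ x1 + x2 + factor(province_id), data = noisy)
  expect_equal(fe$coefficients$estimate,
               unname(coef(lsdv)[c("x1", "x2")]), tolerance = 1e-10)
  # residual degrees of freedom account for the absorbed unit means
  expect_equal(fe$df_resid, df.residual(lsdv))
})

test_that("HC1 errors on the within fit match the sandwich estimator on LSDV", {
  skip_if_not_installed("sandwich")
  noisy <- sim_panel(4, n_units = 8, n_periods = 5, beta = c(x1 = 1))
  fe <- fit_fixed_effects(noisy, y ~ x1, robust = "HC1")
  lsdv <- stats::lm(y ~ x1 + factor(province_id), data = noisy)
  V <- sandwich::vcovHC(lsdv, type = "HC1")
  expect_equal(fe$coefficients$std_error, sqrt(V["x1", "x1"]),
               tolerance = 1e-8)
})

test_that("time-invariant regressors are dropped loudly under fixed effects", {
  p <- sim_panel(5, n_units = 6, n_periods = 4, beta = c(x1 = 1))
  pos <- setNames(rep(0:2, each = 2), sprintf("u%02d", 1:6))
  p$position <- pos[p$province_id]
  expect_warning(fit <- fit_fixed_effects(p, y ~ x1 + position),
                 "position")
  expect_identical(fit$dropped_terms, "position")
  expect_identical(fit$coefficients$term, "x1")
})

test_that("the Hausman statistic is zero for identical fits and matches the scalar formula", {
  p <- sim_panel(6, n_units = 10, n_periods = 5, beta = c(x1 = 2))
  fe <- fit_fixed_effects(p, y ~ x1, robust = "classical")
  h0 <- hausman_test(fe, fe)
  expect_equal(h0$statistic, 0)
  expect_equal(h0$p_value, 1)

  re <- fit_random_effects(p, y ~ x1)
  h <- hausman_test(fe, re)
  b_fe <- fe$coefficients$estimate
  b_re <- re$coefficients$estimate[re$coefficients$term == "x1"]
  v <- fe$vcov["x1", "x1"] - re$vcov["x1", "x1"]
  expect_equal(h$statistic, (b_fe - b_re)^2 / v)
  expect_equal(h$df, 1)
})

test_that("the Hausman test rejects when unit effects correlate with the regressor", {
  rej <- vapply(1:200, function(s) {
    p <- sim_panel(1000 + s, n_units = 30, n_periods = 5, beta = c(x1 = 2),
                   unit_effect_sd = 1, noise_sd = 1, correlate_effects = 1)
    fe <- suppressWarnings(fit_fixed_effects(p, y ~ x1, robust = "classical"))
    re <- fit_random_effects(p, y ~ x1)
    suppressWarnings(hausman_test(fe, re)$p_value) < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.95)
})

test_that("Cook's distances match leave-one-out refits and catch planted outliers", {
  # brute-force LOO oracle on a 10-row panel
  p <- sim_panel(7, n_units = 2, n_periods = 5, beta = c(x1 = 1))
  flt <- cooks_distance_filter(p, y ~ x1, threshold = 0)
  fit <- stats::lm(y ~ x1 + factor(province_id), data = p)
  s2 <- sum(residuals(fit)^2) / df.residual(fit)
  k <- length(coef(fit))
  loo <- vapply(seq_len(nrow(p)), function(i) {
    f_i <- stats::lm(y ~ x1 + factor(province_id), data = p[-i, ])
    yhat_i <- predict(f_i, newdata = p)
    sum((fitted(fit) - yhat_i)^2) / (k * s2)
  }, numeric(1))
  expect_equal(sort(flt$removed$cooks_d), sort(loo), tolerance = 1e-9)

  # planted 10-SD outlier in a 100-row panel is removed at the 4/n threshold
  p2 <- sim_panel(8, n_units = 20, n_periods = 5, beta = c(x1 = 1),
                  noise_sd = 0.2)
  p2$y[37] <- p2$y[37] + 10 * 0.2
  flt2 <- cooks_distance_filter(p2, y ~ x1)
  expect_true(paste(p2$province_id[37], p2$year[37]) %in%
                paste(flt2$removed$unit, flt2$removed$year))
  expect_equal(nrow(flt2$panel), nrow(p2) - nrow(flt2$removed))

  # noiseless data has no outliers at all
  p3 <- sim_panel(9, n_units = 10, n_periods = 4, beta = c(x1 = 1),
                  noise_sd = 0)
  expect_equal(nrow(cooks_distance_filter(p3, y ~ x1)$removed), 0)
})

test_that("the Breusch-Pagan LM statistic is n R2 of the auxiliary regression", {
  skip_if_not_installed("lmtest")
  set.seed(10)
  n <- 120
  x <- rnorm(n)
  y <- 1 + x + rnorm(n, sd = 0.3 + 0.6 * abs(x))
  fit <- stats::lm(y ~ x)
  got <- breusch_pagan_test(residuals(fit), cbind(x = x))
  ref <- lmtest::bptest(fit)  # studentized (Koenker) form: n R2
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)

  # residuals with constant magnitude carry no heteroscedasticity signal
  expect_equal(breusch_pagan_test(rep(c(1, -1), 10),
                                  cbind(z = rnorm(20)))$statistic, 0)
})

test_that("the Breusch-Pagan test has power against variance tied to a regressor", {
  rej <- vapply(1:200, function(s) {
    set.seed(3000 + s)
    n <- 261
    x <- runif(n)
    y <- x + rnorm(n, sd = 0.2 + x)
    fit <- stats::lm(y ~ x)
    breusch_pagan_test(residuals(fit), cbind(x = x))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})
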