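#' Min-max standardization to \[0, 1\]
#'
#' Rescales a column as \eqn{(x - \min x) / (\max x - \min x)}, computed over
#' the pooled panel (all years together) so a variable's scale stays
#' comparable across the panel. Order-preserving and idempotent on data
#' already spanning \[0, 1\].
#'
#' @param x Numeric vector.
#' @param name Column name used in the error message for constant input.
#' @return Vector in \[0, 1\].
#' @export
minmax_standardize <- function(x, name = deparse(substitute(x))) {
  r <- range(x, na.rm = TRUE)
  if (!(r[2] > r[1]))
    stop(sprintf("cannot standardize constant column '%s'", name))
  (x - r[1]) / (r[2] - r[1])
}

#' Assemble the lagged province-year regression panel
#'
#' Joins each province's passive mobility in year t with its gravity
#' accessibility indices and socio-economic covariates of year t-1 (the
#' explanatory variables are lagged one year relative to mobility, so e.g.
#' indices for 2019-2021 explain mobility for 2020-2022). Provinces missing
#' either side of a join are dropped with a logged count.
#'
#' @param indices Province-level tibble from [aggregate_province()] (long by
#'   `attraction`); the `gravity` column supplies `I_G` (interventions) and
#'   `Q_G` (quality).
#' @param mobility Tibble with `province_id`, `year`, `paz_intra`, `paz_inter`
#'   (or a precomputed `M`).
#' @param covariates Optional province-year covariate tibble (columns
#'   `province_id`, `year`, plus covariate columns such as `income`,
#'   `education`, `waiting_times`, `health_expenditure`, `specialists`,
#'   `satisfaction`, `position`).
#' @return Tibble keyed (`province_id`, `year`) where `year` is the mobility
#'   year; `I_G`, `Q_G` and covariates refer to `year - 1`.
#' @export
build_lagged_panel <- function(indices, mobility, covariates = NULL) {
  if (!("M" %in% names(mobility)))
    mobility$M <- passive_mobility(mobility$paz_intra, mobility$paz_inter)
  mob <- mobility[!is.na(mobility$M), c("province_id", "year", "M")]

  idx_wide <- tibble::tibble(
    province_id = indices$province_id[indices$attraction == "interventions"],
    year = indices$year[indices$attraction == "interventions"],
    I_G = indices$gravity[indices$attraction == "interventions"])
  qg <- indices[indices$attraction == "quality",
                c("province_id", "year", "gravity")]
  names(qg)[3] <- "Q_G"
  idx_wide <- dplyr::inner_join(idx_wide, qg, by = c("province_id", "year"))
  idx_wide$year <- idx_wide$year + 1  # align index year t-1 to mobility year t

  panel <- dplyr::inner_join(mob, idx_wide, by = c("province_id", "year"))
  if (!is.null(covariates)) {
    cov <- covariates
    cov$year <- cov$year + 1
    panel <- dplyr::inner_join(panel, cov, by = c("province_id", "year"))
  }
  dropped <- nrow(mob) - nrow(panel)
  if (dropped > 0)
    message(sprintf("dropped %d mobility rows without a matching lagged index/covariate row",
                    dropped))
  if (nrow(panel) == 0) stop("empty panel: no province-year rows joined")
  dplyr::arrange(panel, province_id, year)
}

# model response and design matrix (no intercept column) from a formula
.design <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(formula, data = data), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  list(y = y, X = X, rows = as.integer(rownames(mf)))
}

#' Fixed-effects (within) panel estimator with robust standard errors
#'
#' Estimates the formula by the within transformation: response and
#' regressors are demeaned inside each unit (province), removing
#' unit-specific intercepts, and the slopes are obtained by least squares on
#' the demeaned data. Coefficients are identical to least squares with unit
#' dummies; degrees of freedom account for the absorbed unit means.
#' Regressors that are constant within every unit (e.g. a territorial
#' position code under province fixed effects) are dropped with a warning
#' naming them. Standard errors are heteroscedasticity-consistent (HC1) by
#' default; `robust = "cluster"` clusters them by unit (CR1),
#' `robust = "classical"` gives homoscedastic OLS errors.
#'
#' @param panel Data frame with one row per (unit, time).
#' @param formula Model formula, e.g. `M ~ I_G + Q_G`.
#' @param unit Name of the unit (fixed-effect) column. Default "province_id".
#' @param robust One of `"HC1"`, `"cluster"`, `"classical"`.
#' @return Object of class `fe_fit`: list with `coefficients` (tibble:
#'   term, estimate, std_error, t, p_value, stars), `vcov`, `within_r2`,
#'   `n_obs`, `n_units`, `df_resid`, `sigma2`, `residuals`, `X_demeaned`,
#'   `dropped_terms`, `formula`, `unit`.
#' @export
fit_fixed_effects <- function(panel, formula, unit = "province_id",
                              robust = c("HC1", "cluster", "classical")) {
  robust <- match.arg(robust)
  stopifnot(unit %in% names(panel))
  d <- .design(formula, panel)
  g <- factor(panel[[unit]][d$rows])
  if (any(table(g) < 2))
    warning("unit(s) with a single observation contribute nothing to the within estimator")

  demean <- function(v) v - ave(v, g)
  yd <- demean(d$y)
  Xd <- apply(d$X, 2, demean)
  if (is.null(dim(Xd))) Xd <- matrix(Xd, ncol = ncol(d$X),
                                     dimnames = list(NULL, colnames(d$X)))
  # time-invariant regressors vanish under demeaning
  gone <- apply(Xd, 2, function(v) max(abs(v)) < 1e-10)
  if (any(gone)) {
    warning(sprintf("dropping regressor(s) constant within units under fixed effects: %s",
                    paste(colnames(Xd)[gone], collapse = ", ")))
    Xd <- Xd[, !gone, drop = FALSE]
  }
  if (ncol(Xd) == 0) stop("no regressor varies within units")
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) stop("singular design after demeaning")

  beta <- qr.coef(qrX, yd)
  e <- yd - Xd %*% beta
  n <- length(yd); k <- ncol(Xd); n_units <- nlevels(g)
  df_resid <- n - k - n_units
  if (df_resid <= 0) stop("not enough observations for the fixed-effects fit")
  sigma2 <- sum(e^2) / df_resid
  XtXinv <- solve(crossprod(Xd))
  V <- switch(robust,
    classical = sigma2 * XtXinv,
    HC1 = {
      meat <- crossprod(Xd * as.numeric(e))
      (n / df_resid) * XtXinv %*% meat %*% XtXinv
    },
    cluster = {
      scores <- rowsum(Xd * as.numeric(e), g)
      G <- nlevels(g)
      adj <- G / (G - 1) * (n - 1) / df_resid
      adj * XtXinv %*% crossprod(scores) %*% XtXinv
    })
  se <- sqrt(diag(V))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_resid, lower.tail = FALSE)
  within_r2 <- 1 - sum(e^2) / sum(yd^2)

  structure(list(
    coefficients = tibble::tibble(term = colnames(Xd),
                                  estimate = unname(beta),
                                  std_error = unname(se),
                                  t = unname(tval), p_value = unname(pval),
                                  stars = .stars(pval)),
    vcov = V, within_r2 = within_r2, n_obs = n, n_units = n_units,
    df_resid = df_resid, sigma2 = sigma2,
    residuals = as.numeric(e), X_demeaned = Xd,
    dropped_terms = colnames(d$X)[gone], formula = formula, unit = unit,
    robust = robust), class = "fe_fit")
}

.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.fe_fit <- function(x, ...) {
  cat(sprintf("Fixed-effects (within) fit: %d obs, %d units, within-R2 = %.3f\n",
              x$n_obs, x$n_units, x$within_r2))
  print(as.data.frame(x$coefficients), digits = 3)
  if (length(x$dropped_terms) > 0)
    cat("dropped (time-invariant):", paste(x$dropped_terms, collapse = ", "), "\n")
  invisible(x)
}

#' Random-effects (GLS) panel estimator
#'
#' Swamy-Arora feasible GLS: error variance from the within fit, the unit
#' effect variance from the between regression, then quasi-demeaning by
#' \eqn{\theta_i = 1 - \sqrt{\sigma^2_e / (T_i \sigma^2_u + \sigma^2_e)}} and
#' pooled least squares on the transformed data. Used mainly as the
#' comparison fit for [hausman_test()].
#'
#' @inheritParams fit_fixed_effects
#' @return Object of class `re_fit` with `coefficients` (tibble), `vcov`
#'   (classical GLS), variance components `sigma2_e`, `sigma2_u`, `n_obs`,
#'   `n_units`.
#' @export
fit_random_effects <- function(panel, formula, unit = "province_id") {
  d <- .design(formula, panel)
  g <- factor(panel[[unit]][d$rows])
  X1 <- cbind(`(Intercept)` = 1, d$X)
  n <- length(d$y); k <- ncol(d$X); n_units <- nlevels(g)

  fe <- suppressWarnings(fit_fixed_effects(panel, formula, unit,
                                           robust = "classical"))
  sigma2_e <- fe$sigma2
  # between regression on unit means
  ym <- tapply(d$y, g, mean)
  Xm <- apply(X1, 2, function(v) tapply(v, g, mean))
  Ti <- as.numeric(table(g))
  fit_b <- stats::lm.fit(Xm, ym)
  ssr_b <- sum(fit_b$residuals^2)
  df_b <- n_units - fit_b$rank
  if (df_b <= 0) stop("too few units for the between regression")
  Tbar <- n_units / sum(1 / Ti)  # harmonic mean of unit sizes
  sigma2_u <- max(0, ssr_b / df_b - sigma2_e / Tbar)

  theta <- 1 - sqrt(sigma2_e / (Ti * sigma2_u + sigma2_e))
  th <- theta[as.integer(g)]
  ys <- d$y - th * ave(d$y, g)
  Xs <- apply(X1, 2, function(v) v - th * ave(v, g))
  fit_g <- stats::lm.fit(Xs, ys)
  beta <- fit_g$coefficients
  e <- fit_g$residuals
  s2 <- sum(e^2) / (n - fit_g$rank)
  if (fit_g$rank < ncol(Xs)) stop("singular design in the GLS regression")
  XtXinv <- solve(crossprod(Xs))
  V <- s2 * XtXinv
  se <- sqrt(diag(V))
  z <- beta / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)

  structure(list(
    coefficients = tibble::tibble(term = names(beta), estimate = unname(beta),
                                  std_error = unname(se), t = unname(z),
                                  p_value = unname(p), stars = .stars(p)),
    vcov = V, sigma2_e = sigma2_e, sigma2_u = sigma2_u,
    n_obs = n, n_units = n_units, formula = formula, unit = unit),
    class = "re_fit")
}

#' @export
print.re_fit <- function(x, ...) {
  cat(sprintf("Random-effects (GLS) fit: %d obs, %d units, sigma2_u = %.4g, sigma2_e = %.4g\n",
              x$n_obs, x$n_units, x$sigma2_u, x$sigma2_e))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Hausman specification test
#'
#' Compares fixed- and random-effects estimates of the coefficients they
#' share: \eqn{H = (b_{FE} - b_{RE})' (V_{FE} - V_{RE})^{-1} (b_{FE} -
#' b_{RE})}, chi-square with as many degrees of freedom as compared
#' coefficients. A significant H indicates correlation between unit effects
#' and regressors, favouring fixed effects. If the covariance difference is
#' not positive definite the Moore-Penrose pseudo-inverse is used with a
#' warning. Both fits must use classical covariances for the statistic to
#' have its textbook distribution; the FE fit is re-fit classically if
#' needed.
#'
#' @param fe An `fe_fit`.
#' @param re An `re_fit` of the same formula (or any list with compatible
#'   `coefficients` and `vcov`).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
hausman_test <- function(fe, re) {
  common <- intersect(fe$coefficients$term, re$coefficients$term)
  if (length(common) == 0) stop("no common coefficients between FE and RE fits")
  b_fe <- setNames(fe$coefficients$estimate, fe$coefficients$term)[common]
  b_re <- setNames(re$coefficients$estimate, re$coefficients$term)[common]
  V_fe <- fe$vcov[common, common, drop = FALSE]
  V_re <- re$vcov[common, common, drop = FALSE]
  d <- b_fe - b_re
  Vd <- V_fe - V_re
  ev <- eigen(Vd, symmetric = TRUE, only.values = TRUE)$values
  H <- if (all(d == 0)) {
    0
  } else if (any(ev < -1e-12 * max(abs(ev), 1)) || min(ev) <= 0) {
    warning("covariance difference not positive definite; using pseudo-inverse")
    as.numeric(t(d) %*% MASS::ginv(Vd) %*% d)
  } else {
    as.numeric(t(d) %*% solve(Vd, d))
  }
  H <- max(0, H)
  df <- length(common)
  tibble::tibble(statistic = H, df = df,
                 p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

#' Cook's-distance outlier filter
#'
#' Computes Cook's distance for every observation from the pooled
#' least-squares fit with unit dummies (the LSDV parameterization of the
#' fixed-effects model) and removes, in a single pass, all rows with
#' \eqn{D_k} above the threshold — by convention 4/n. Removals are reported
#' per year.
#'
#' @param panel Data frame with one row per (unit, time).
#' @param formula Model formula (slopes only; unit dummies are added).
#' @param unit Unit column name.
#' @param threshold Cut-off for Cook's distance; default `4 / nrow(panel)`.
#' @return List with `panel` (filtered tibble), `removed` (tibble:
#'   unit, year, cooks_d), `by_year` (tibble of removal counts),
#'   `threshold`.
#' @export
cooks_distance_filter <- function(panel, formula, unit = "province_id",
                                  threshold = NULL) {
  if (is.null(threshold)) threshold <- 4 / nrow(panel)
  f_lsdv <- stats::update(formula,
                          paste(". ~ . +", sprintf("factor(%s)", unit)))
  fit <- stats::lm(f_lsdv, data = panel)
  D <- stats::cooks.distance(fit)
  # an (essentially) perfect fit has no outliers; residual ratios there are
  # floating-point noise
  y <- stats::model.response(stats::model.frame(fit))
  if (sum(stats::residuals(fit)^2) <= 1e-20 * max(sum(y^2), 1))
    D[] <- 0
  out <- rep(FALSE, nrow(panel))
  out[as.integer(names(D))] <- D > threshold & is.finite(D)
  removed <- tibble::tibble(unit = panel[[unit]][out],
                            year = if ("year" %in% names(panel))
                              panel$year[out] else NA,
                            cooks_d = unname(D[match(which(out),
                                                     as.integer(names(D)))]))
  by_year <- if (nrow(removed) > 0)
    dplyr::count(removed, year, name = "n_removed")
  else tibble::tibble(year = numeric(0), n_removed = integer(0))
  list(panel = tibble::as_tibble(panel[!out, ]), removed = removed,
       by_year = by_year, threshold = threshold)
}

#' Breusch-Pagan test for heteroscedasticity
#'
#' Lagrange-multiplier form: squared residuals are regressed on the design,
#' and \eqn{LM = n R^2} of that auxiliary regression is referred to a
#' chi-square with as many degrees of freedom as regressors (the studentized,
#' Koenker form of the test).
#'
#' @param residuals Residual vector of the fitted model.
#' @param design Numeric matrix of regressors (no intercept column needed;
#'   one is added to the auxiliary regression).
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
breusch_pagan_test <- function(residuals, design) {
  design <- as.matrix(design)
  stopifnot(length(residuals) == nrow(design))
  e2 <- residuals^2
  aux <- stats::lm.fit(cbind(1, design), e2)
  r2 <- 1 - sum(aux$residuals^2) / sum((e2 - mean(e2))^2)
  if (!is.finite(r2)) r2 <- 0  # constant squared residuals
  lm_stat <- length(e2) * max(0, r2)
  df <- aux$rank - 1
  tibble::tibble(statistic = lm_stat, df = df,
                 p_value = stats::pchisq(lm_stat, df, lower.tail = FALSE))
}
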