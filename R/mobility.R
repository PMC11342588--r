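#' Passive mobility index
#'
#' Fraction of a province's treated patients who underwent surgery outside
#' their region of residence: \eqn{M = paz^{INTER} / (paz^{INTRA} +
#' paz^{INTER})}. Provinces with zero treated patients have no defined
#' mobility and are returned as `NA` with a warning.
#'
#' @param paz_intra,paz_inter Nonnegative patient counts (vectorised).
#' @return Mobility in \[0, 1\], `NA` where the total is 0.
#' @export
#' @examples
#' passive_mobility(80, 20)  # 0.2
passive_mobility <- function(paz_intra, paz_inter) {
  if (any(paz_intra < 0, na.rm = TRUE) || any(paz_inter < 0, na.rm = TRUE))
    stop("patient counts must be nonnegative")
  total <- paz_intra + paz_inter
  if (any(total == 0, na.rm = TRUE))
    warning("province(s) with zero treated patients: mobility undefined, returned as NA")
  ifelse(total > 0, paz_inter / total, NA_real_)
}

#' Year differences in passive mobility: ANOVA and paired t-tests
#'
#' Tests whether passive mobility differs between years with a classical
#' one-way ANOVA across years, followed by all pairwise paired t-tests where
#' provinces are paired by id (only provinces observed in both years of a
#' pair enter that test). Per-year mean and standard deviation of M are
#' reported alongside. Pairwise p-values are raw by default; set
#' `bonferroni = TRUE` to adjust them.
#'
#' A year pair whose paired differences have zero variance (e.g. a constant
#' shift applied to every province) has no defined t-statistic; it is reported
#' as `NA` with a note in the `degenerate` column. Years with fewer than two
#' observations are excluded with a warning.
#'
#' @param mobility Tibble with columns `province_id`, `year` and either `M` or
#'   the raw counts `paz_intra`, `paz_inter`.
#' @param bonferroni Adjust pairwise p-values for multiplicity? Default FALSE.
#' @return List with elements `anova` (tibble: F, df1, df2, p_value),
#'   `by_year` (tibble: year, n, mean, sd) and `pairwise` (tibble: year1,
#'   year2, n_pairs, t, df, p_value, degenerate).
#' @export
year_anova <- function(mobility, bonferroni = FALSE) {
  if (!("M" %in% names(mobility)))
    mobility$M <- passive_mobility(mobility$paz_intra, mobility$paz_inter)
  mobility <- mobility[!is.na(mobility$M), ]
  counts <- table(mobility$year)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    warning(sprintf("excluding year(s) with < 2 observations: %s",
                    paste(small, collapse = ", ")))
    mobility <- mobility[!(mobility$year %in% as.numeric(small)), ]
  }
  years <- sort(unique(mobility$year))
  if (length(years) < 2) stop("need at least 2 years with >= 2 observations")

  fit <- stats::aov(M ~ factor(year), data = mobility)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble::tibble(F = an[1, "F value"], df1 = an[1, "Df"],
                              df2 = an[2, "Df"], p_value = an[1, "Pr(>F)"])
  if (!is.finite(anova_tbl$F)) {  # zero within- and between-variance: no signal
    anova_tbl$F <- 0
    anova_tbl$p_value <- 1
  }

  by_year <- mobility %>%
    dplyr::group_by(year) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(M), sd = stats::sd(M),
                     .groups = "drop")

  pairs <- utils::combn(years, 2, simplify = FALSE)
  pw <- lapply(pairs, function(p) {
    a <- mobility[mobility$year == p[1], c("province_id", "M")]
    b <- mobility[mobility$year == p[2], c("province_id", "M")]
    m <- dplyr::inner_join(a, b, by = "province_id", suffix = c("_1", "_2"))
    d <- m$M_2 - m$M_1
    degenerate <- nrow(m) < 2 ||
      stats::sd(d) <= 1e-12 * max(abs(d), 1)  # constant shift: t undefined
    if (degenerate) {
      tibble::tibble(year1 = p[1], year2 = p[2], n_pairs = nrow(m),
                     t = if (all(d == 0) && nrow(m) >= 2) 0 else NA_real_,
                     df = NA_real_, p_value = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(m$M_2, m$M_1, paired = TRUE)
      tibble::tibble(year1 = p[1], year2 = p[2], n_pairs = nrow(m),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p_value = tt$p.value, degenerate = FALSE)
    }
  })
  pw <- dplyr::bind_rows(pw)
  if (bonferroni) pw$p_value <- pmin(1, pw$p_value * nrow(pw))
  list(anova = anova_tbl, by_year = by_year, pairwise = pw)
}
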