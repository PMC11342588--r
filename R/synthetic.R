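#' Configuration of the synthetic country generator
#'
#' Defines a synthetic regionalized country — regions containing provinces
#' containing municipalities on a plane — together with the stochastic models
#' for populations, hospital placement, intervention volumes, readmission
#' rates, travel times, socio-economic covariates and patient mobility. The
#' seed fully determines every generated table.
#'
#' The defaults describe the study conditions the generator emulates: coarse
#' municipal units with a median 55+ population of 20,000 (log-normal,
#' sdlog 0.6), hospitals preferentially hosted by populous municipalities,
#' over-dispersed annual volumes around 120 interventions, readmission rates
#' around 4.5% with the southern macro-area shifted 3 points worse (the
#' north-south quality gap), car travel at 60 km/h, an annual hip-replacement
#' incidence of 0.5% among the 55+, and a mobility choice model on the logit
#' scale with gravity-accessibility effects `beta_I = -1` and `beta_Q = -0.5`
#' per unit of min-max standardized index.
#'
#' @param preset `"small"` (3 regions x 5 provinces x 3 municipalities) or
#'   `"study-scale"` (15 regions, 87 provinces, 261 municipalities — the
#'   scale of the study panel: 87 provinces over 3 years).
#' @param seed Integer seed; fully determines all generated tables.
#' @param n_regions,provinces_per_region,municipalities_per_province Country
#'   layout; `provinces_per_region` may be a vector (one entry per region).
#' @param years Index (supply-side) years; mobility is generated for
#'   `years + 1`.
#' @param pop55_median,pop55_sdlog Log-normal model of the municipal 55+
#'   population.
#' @param plane_km Side of the square the country occupies, km.
#' @param province_spread_km,muni_spread_km Gaussian spread of province
#'   centres around region centres and of municipalities around province
#'   centres.
#' @param speed_km_per_min Average car speed (1 km/min = 60 km/h).
#' @param od_noise_sdlog Log-normal multiplicative noise on travel times
#'   (road-network irregularity; symmetric).
#' @param facility_intercept,facility_slope Logistic model of the probability
#'   that a municipality hosts a hospital, as a function of
#'   `log(pop55 / pop55_median)`. The largest municipality of each region
#'   always hosts one.
#' @param volume_mean,volume_dispersion Negative-binomial annual intervention
#'   volume: mean `volume_mean * pop55 / pop55_median`, size
#'   `volume_dispersion`.
#' @param ret30_mean,ret30_sd,ret30_gradient Normal (truncated at 0) model of
#'   the adjusted 30-day readmission rate; `ret30_gradient` is added to the
#'   mean in the southern macro-area.
#' @param incidence Annual hip-replacement incidence among the 55+.
#' @param alpha0 Baseline mobility on the logit scale (default `qlogis(0.2)`).
#' @param alpha_sd Standard deviation of province-level mobility effects.
#' @param beta_I,beta_Q Ground-truth effects of the min-max standardized
#'   gravity indices on logit mobility (negative: better in-region
#'   accessibility retains patients).
#' @param hausman_corr Strength of the correlation between province effects
#'   and the standardized intervention gravity index (0 = exogenous effects;
#'   positive values violate the random-effects assumption so the Hausman
#'   test rejects).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(preset = NULL, seed = 1,
                             n_regions = 4, provinces_per_region = 3,
                             municipalities_per_province = 4,
                             years = 2019:2021,
                             pop55_median = 20000, pop55_sdlog = 0.6,
                             plane_km = 500,
                             province_spread_km = 40, muni_spread_km = 15,
                             speed_km_per_min = 1, od_noise_sdlog = 0.1,
                             facility_intercept = -0.5, facility_slope = 1.5,
                             volume_mean = 120, volume_dispersion = 8,
                             ret30_mean = 4.5, ret30_sd = 2,
                             ret30_gradient = 3,
                             incidence = 0.005,
                             alpha0 = stats::qlogis(0.2), alpha_sd = 0.3,
                             beta_I = -1, beta_Q = -0.5,
                             hausman_corr = 0) {
  cfg <- as.list(environment())
  cfg$preset <- NULL
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("small", "study-scale"))
    if (preset == "small") {
      cfg$n_regions <- 3; cfg$provinces_per_region <- 5
      cfg$municipalities_per_province <- 3
    } else {
      cfg$n_regions <- 15
      cfg$provinces_per_region <- c(rep(6, 12), rep(5, 3))  # 87 provinces
      cfg$municipalities_per_province <- 3
    }
  }
  cfg$provinces_per_region <- rep_len(cfg$provinces_per_region, cfg$n_regions)
  stopifnot(cfg$n_regions >= 1, all(cfg$provinces_per_region >= 1),
            cfg$municipalities_per_province >= 1, length(cfg$years) >= 1)
  structure(cfg, class = "synthetic_config")
}

# macro-area ordinal of a region: regions are split into thirds by index
# (north = 0, centre = 1, south = 2)
.region_position <- function(region_idx, n_regions) {
  pmin(2L, ((region_idx - 1L) * 3L) %/% n_regions)
}

.position_of <- function(region_id, n_regions) {
  .region_position(as.integer(sub("^R", "", region_id)), n_regions)
}

#' Generate the synthetic geography
#'
#' Lays out region centres uniformly on the plane, province centres around
#' them, municipalities around provinces; draws log-normal 55+ populations;
#' and derives a symmetric long-form travel-time matrix (zero diagonal) as
#' Euclidean distance over average speed times multiplicative log-normal
#' noise, so travel times may violate the triangle inequality, as road
#' networks do.
#'
#' @param config A [synthetic_config()].
#' @return List with `municipalities` (tibble with coordinates and a
#'   `position` macro-area column) and `od` (long tibble
#'   origin/destination/minutes over all ordered pairs).
#' @export
gen_geography <- function(config) {
  set.seed(config$seed)
  rx <- stats::runif(config$n_regions, 0, config$plane_km)
  ry <- stats::runif(config$n_regions, 0, config$plane_km)
  rows <- list()
  p_global <- 0
  for (r in seq_len(config$n_regions)) {
    for (p in seq_len(config$provinces_per_region[r])) {
      p_global <- p_global + 1
      px <- stats::rnorm(1, rx[r], config$province_spread_km)
      py <- stats::rnorm(1, ry[r], config$province_spread_km)
      m <- config$municipalities_per_province
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region_id = sprintf("R%02d", r),
        province_id = sprintf("P%03d", p_global),
        muni_id = sprintf("P%03d-M%02d", p_global, seq_len(m)),
        x = stats::rnorm(m, px, config$muni_spread_km),
        y = stats::rnorm(m, py, config$muni_spread_km))
    }
  }
  munis <- dplyr::bind_rows(rows)
  n <- nrow(munis)
  munis$pop55 <- round(stats::rlnorm(n, log(config$pop55_median),
                                     config$pop55_sdlog))
  munis$excluded <- FALSE
  munis$position <- .position_of(munis$region_id, config$n_regions)
  munis <- munis[c("muni_id", "province_id", "region_id", "pop55",
                   "excluded", "position", "x", "y")]

  dist_km <- as.matrix(stats::dist(cbind(munis$x, munis$y)))
  noise <- matrix(1, n, n)
  up <- upper.tri(noise)
  noise[up] <- stats::rlnorm(sum(up), 0, config$od_noise_sdlog)
  noise[lower.tri(noise)] <- t(noise)[lower.tri(noise)]
  minutes <- dist_km / config$speed_km_per_min * noise
  diag(minutes) <- 0
  od <- tibble::tibble(
    origin = rep(munis$muni_id, times = n),
    destination = rep(munis$muni_id, each = n),
    minutes = as.vector(minutes))
  list(municipalities = munis, od = od)
}

#' Generate synthetic hospital facilities
#'
#' Chooses host municipalities with probability increasing in population
#' (quality structures concentrate in or near populous places; the largest
#' municipality of each region always hosts one), then draws, per year,
#' over-dispersed intervention volumes and truncated-normal readmission
#' rates with the configured southern penalty, and derives the quality level.
#'
#' @param config A [synthetic_config()].
#' @param municipalities Municipality table from [gen_geography()].
#' @param years Facility years; defaults to `config$years`.
#' @return Facility tibble (one row per facility-year) with
#'   `quality_level` derived by [quality_level()].
#' @export
gen_facilities <- function(config, municipalities, years = config$years) {
  set.seed(config$seed + 1L)
  m <- municipalities
  eta <- config$facility_intercept +
    config$facility_slope * log(pmax(m$pop55, 1) / config$pop55_median)
  host <- stats::runif(nrow(m)) < stats::plogis(eta)
  # every region keeps at least one hospital, in its largest municipality
  for (r in unique(m$region_id)) {
    in_r <- which(m$region_id == r)
    if (!any(host[in_r])) host[in_r[which.max(m$pop55[in_r])]] <- TRUE
  }
  hosts <- m[host, ]
  south <- hosts$position == 2L
  rows <- lapply(years, function(yr) {
    mu <- config$volume_mean * hosts$pop55 / config$pop55_median
    interventions <- stats::rnbinom(nrow(hosts), mu = mu,
                                    size = config$volume_dispersion)
    ret30 <- pmax(0, stats::rnorm(nrow(hosts),
                                  config$ret30_mean +
                                    config$ret30_gradient * south,
                                  config$ret30_sd))
    tibble::tibble(facility_id = sprintf("F%03d", seq_len(nrow(hosts))),
                   muni_id = hosts$muni_id, year = yr,
                   interventions = as.numeric(interventions),
                   ret30 = ret30,
                   quality_level = quality_level(interventions, ret30))
  })
  dplyr::bind_rows(rows)
}

#' Generate synthetic socio-economic covariates
#'
#' Income and education are drawn at municipality level (with a macro-area
#' gradient: the south poorer and less educated) and aggregated to provinces
#' by population weighting; waiting times, health expenditure, specialists
#' and satisfaction are drawn at region level per year and broadcast to the
#' region's provinces; `position` is the macro-area ordinal (0 north,
#' 1 centre, 2 south).
#'
#' @param config A [synthetic_config()].
#' @param municipalities Municipality table from [gen_geography()].
#' @param years Covariate years; defaults to `config$years`.
#' @return Province-year covariate tibble with columns `province_id`, `year`,
#'   `income`, `education`, `waiting_times`, `health_expenditure`,
#'   `specialists`, `satisfaction`, `position`.
#' @export
gen_covariates <- function(config, municipalities, years = config$years) {
  set.seed(config$seed + 2L)
  m <- municipalities
  out <- list()
  for (yr in years) {
    income_mu <- c(22000, 19000, 16000)[m$position + 1L]
    edu_mu <- c(66, 62, 58)[m$position + 1L]
    muni_cov <- tibble::tibble(
      province_id = m$province_id, pop55 = m$pop55,
      income = stats::rlnorm(nrow(m), log(income_mu), 0.12),
      education = pmin(100, pmax(0, stats::rnorm(nrow(m), edu_mu, 5))))
    prov <- muni_cov %>%
      dplyr::group_by(province_id) %>%
      dplyr::summarise(income = sum(income * pop55) / sum(pop55),
                       education = sum(education * pop55) / sum(pop55),
                       .groups = "drop")
    regions <- dplyr::distinct(m[c("region_id", "position")])
    reg <- tibble::tibble(
      region_id = regions$region_id,
      waiting_times = pmax(5, stats::rnorm(nrow(regions),
                                           80 + 20 * regions$position, 25)),
      health_expenditure = stats::rnorm(nrow(regions),
                                        2150 - 80 * regions$position, 150),
      specialists = stats::rnorm(nrow(regions), 30, 3),
      satisfaction = pmin(100, pmax(0, stats::rnorm(nrow(regions),
                                                    50 - 5 * regions$position,
                                                    10))))
    p2r <- dplyr::distinct(m[c("province_id", "region_id", "position")])
    prov <- prov %>%
      dplyr::left_join(p2r, by = "province_id") %>%
      dplyr::left_join(reg, by = "region_id")
    prov$year <- yr
    out[[length(out) + 1L]] <-
      prov[c("province_id", "year", "income", "education", "waiting_times",
             "health_expenditure", "specialists", "satisfaction", "position")]
  }
  dplyr::bind_rows(out)
}

#' Generate synthetic passive-mobility counts
#'
#' Province-level choice model with known ground truth: for each province and
#' index year t, expected mobility in year t+1 follows
#' `logit(E[M]) = alpha0 + u_p + beta_I * std(I_G) + beta_Q * std(Q_G)`,
#' where `std()` is the min-max standardization over the pooled
#' province-years, and `u_p` are province effects (optionally correlated with
#' the standardized intervention index via `hausman_corr`). Total treated
#' patients are Poisson with mean `incidence * province pop55`; patients
#' treated out of region are binomial with the model probability. Provinces
#' drawing a zero total yield undefined mobility downstream.
#'
#' @param config A [synthetic_config()].
#' @param province_indices Province aggregation of the accessibility surface
#'   ([aggregate_province()]) for the index years, long by `attraction`.
#' @param municipalities Municipality table (for province populations).
#' @return Mobility tibble `province_id`, `year` (= index year + 1),
#'   `paz_intra`, `paz_inter`, with the ground-truth parameters attached as
#'   attribute `truth`.
#' @export
gen_mobility <- function(config, province_indices, municipalities) {
  set.seed(config$seed + 3L)
  prov_pop <- municipalities %>%
    dplyr::group_by(province_id) %>%
    dplyr::summarise(pop55 = sum(pop55), .groups = "drop")
  if (!all(province_indices$province_id %in% prov_pop$province_id))
    stop("surface/province mismatch: unknown province in province_indices")
  idx <- province_indices[province_indices$attraction == "interventions",
                          c("province_id", "year", "gravity")]
  names(idx)[3] <- "I_G"
  qg <- province_indices[province_indices$attraction == "quality",
                         c("province_id", "year", "gravity")]
  names(qg)[3] <- "Q_G"
  idx <- dplyr::inner_join(idx, qg, by = c("province_id", "year"))
  idx$I_std <- minmax_standardize(idx$I_G, "I_G")
  idx$Q_std <- minmax_standardize(idx$Q_G, "Q_G")

  provinces <- sort(unique(idx$province_id))
  u <- stats::rnorm(length(provinces), 0, config$alpha_sd)
  if (config$hausman_corr != 0) {
    pm <- tapply(idx$I_std, idx$province_id, mean)[provinces]
    u <- u + config$hausman_corr * (pm - mean(pm))
  }
  names(u) <- provinces

  eta <- config$alpha0 + u[idx$province_id] +
    config$beta_I * idx$I_std + config$beta_Q * idx$Q_std
  p <- stats::plogis(eta)
  pop <- prov_pop$pop55[match(idx$province_id, prov_pop$province_id)]
  total <- stats::rpois(nrow(idx), config$incidence * pop)
  inter <- stats::rbinom(nrow(idx), total, p)
  out <- tibble::tibble(province_id = idx$province_id,
                        year = idx$year + 1,
                        paz_intra = total - inter, paz_inter = inter)
  attr(out, "truth") <- list(beta_I = config$beta_I, beta_Q = config$beta_Q,
                             alpha0 = config$alpha0, u = u)
  out
}

#' Generate a complete synthetic country and run the supply-side pipeline
#'
#' Convenience wrapper: geography, facilities, accessibility surface,
#' province aggregation, covariates and mobility in one call, all determined
#' by `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @param decay A [decay_config()].
#' @return List with `municipalities`, `od`, `facilities`, `surface`,
#'   `province_indices`, `covariates`, `mobility`, `config`, `decay`.
#' @export
gen_country <- function(config = synthetic_config(), decay = decay_config()) {
  geo <- gen_geography(config)
  facilities <- gen_facilities(config, geo$municipalities)
  bundle <- structure(list(municipalities = geo$municipalities,
                           facilities = validate_facilities(facilities,
                                                            geo$municipalities),
                           od = geo$od, config = decay),
                      class = "access_bundle")
  surface <- compute_accessibility(bundle)
  province_indices <- aggregate_province(surface, geo$municipalities)
  covariates <- gen_covariates(config, geo$municipalities)
  mobility <- gen_mobility(config, province_indices, geo$municipalities)
  list(municipalities = geo$municipalities, od = geo$od,
       facilities = bundle$facilities, surface = surface,
       province_indices = province_indices, covariates = covariates,
       mobility = mobility, config = config, decay = decay)
}
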