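# in-code fixtures and independent oracles shared across the suite

# three municipalities in two regions, one facility
toy_bundle <- function(decay = decay_config()) {
  munis <- tibble::tibble(
    muni_id = c("A", "B", "C"),
    province_id = c("p1", "p1", "p2"),
    region_id = c("r1", "r1", "r2"),
    pop55 = c(100, 200, 300),
    excluded = FALSE)
  facilities <- tibble::tibble(
    facility_id = "F1", muni_id = "A", year = 2020,
    interventions = 100, ret30 = 2.5)
  od <- tibble::tibble(
    origin = c("A", "B", "C", "B", "A", "C"),
    destination = c("B", "A", "A", "C", "C", "B"),
    minutes = c(60, 60, 120, 90, 120, 90))
  list(municipalities = validate_municipalities(munis),
       facilities = validate_facilities(facilities,
                                        validate_municipalities(munis)),
       od = od, config = decay)
}

write_toy_csvs <- function(dir = tempfile("fixtures"), excluded_muni = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- toy_bundle()
  munis <- b$municipalities
  if (!is.null(excluded_muni))
    munis$excluded[munis$muni_id %in% excluded_muni] <- TRUE
  paths <- list(municipalities = file.path(dir, "municipalities.csv"),
                facilities = file.path(dir, "facilities.csv"),
                od = file.path(dir, "od.csv"))
  utils::write.csv(munis, paths$municipalities, row.names = FALSE)
  utils::write.csv(b$facilities[c("facility_id", "muni_id", "year",
                                  "interventions", "ret30")],
                   paths$facilities, row.names = FALSE)
  utils::write.csv(b$od, paths$od, row.names = FALSE)
  paths
}

# seeded random instance for property tests
random_instance <- function(seed, n_muni = NULL, n_fac = NULL,
                            n_regions = 3, decay = decay_config()) {
  set.seed(seed)
  if (is.null(n_muni)) n_muni <- sample(3:50, 1)
  if (is.null(n_fac)) n_fac <- sample(1:10, 1)
  munis <- tibble::tibble(
    muni_id = sprintf("m%02d", seq_len(n_muni)),
    province_id = sprintf("p%d", sample(seq_len(2 * n_regions), n_muni,
                                        replace = TRUE)),
    pop55 = sample(50:5000, n_muni, replace = TRUE),
    excluded = FALSE)
  munis$region_id <- sprintf("r%d",
                             (as.integer(sub("p", "", munis$province_id)) - 1) %/%
                               2 + 1)
  pairs <- expand.grid(origin = munis$muni_id, destination = munis$muni_id,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$origin != pairs$destination, ]
  pairs$minutes <- stats::runif(nrow(pairs), 0, 200)
  facilities <- tibble::tibble(
    facility_id = sprintf("f%02d", seq_len(n_fac)),
    muni_id = sample(munis$muni_id, n_fac, replace = TRUE),
    year = 2020,
    interventions = sample(0:400, n_fac, replace = TRUE),
    ret30 = stats::runif(n_fac, 0, 11))
  munis <- validate_municipalities(munis)
  list(municipalities = munis,
       facilities = validate_facilities(facilities, munis),
       od = tibble::as_tibble(pairs), config = decay)
}

# naive triple-loop E2SFCA oracle, scalar arithmetic only
naive_accessibility <- function(bundle, attraction = "interventions") {
  munis <- bundle$municipalities
  fac <- bundle$facilities
  w_of <- function(i, j) {  # muni id -> muni id decay weight
    if (i == j) return(gaussian_weight(0, bundle$config))
    row <- bundle$od[bundle$od$origin == i & bundle$od$destination == j, ]
    if (nrow(row) == 0) 0 else gaussian_weight(row$minutes[1], bundle$config)
  }
  out <- NULL
  for (yr in sort(unique(fac$year))) {
    fy <- fac[fac$year == yr, ]
    Rj <- numeric(nrow(fy))
    for (j in seq_len(nrow(fy))) {
      Pj <- 0
      for (i in seq_len(nrow(munis)))
        Pj <- Pj + munis$pop55[i] * w_of(munis$muni_id[i], fy$muni_id[j])
      nj <- if (attraction == "interventions") fy$interventions[j]
            else fy$quality_level[j]
      Rj[j] <- if (Pj > 0) nj / Pj else 0
    }
    for (i in seq_len(nrow(munis))) {
      intra <- 0; inter <- 0
      for (j in seq_len(nrow(fy))) {
        contrib <- Rj[j] * w_of(munis$muni_id[i], fy$muni_id[j])
        if (fy$region_id[j] == munis$region_id[i]) intra <- intra + contrib
        else inter <- inter + contrib
      }
      out <- rbind(out, data.frame(muni_id = munis$muni_id[i], year = yr,
                                   attraction = attraction,
                                   total = intra + inter, intra = intra,
                                   inter = inter, gravity = intra - inter))
    }
  }
  out
}

# literal transcription of the quality-level step table (independent of the
# implementation's findInterval route)
quality_oracle <- function(interventions, ret30) {
  if (interventions <= 72) return(0)
  if (ret30 <= 3) 1
  else if (ret30 <= 4.5) 0.8
  else if (ret30 <= 6) 0.6
  else if (ret30 <= 7.5) 0.4
  else if (ret30 <= 9) 0.2
  else 0
}

# balanced noisy panel with known slopes, for estimator tests
sim_panel <- function(seed, n_units = 20, n_periods = 5, beta = c(x1 = 2),
                      unit_effect_sd = 1, noise_sd = 0.1,
                      correlate_effects = 0) {
  set.seed(seed)
  units <- sprintf("u%02d", seq_len(n_units))
  df <- expand.grid(province_id = units, year = seq_len(n_periods),
                    stringsAsFactors = FALSE)
  mu <- stats::rnorm(n_units)
  names(mu) <- units
  for (v in names(beta)) df[[v]] <- stats::rnorm(nrow(df)) +
    correlate_effects * mu[df$province_id]
  u <- unit_effect_sd * mu
  df$y <- as.matrix(df[names(beta)]) %*% beta + u[df$province_id] +
    stats::rnorm(nrow(df), 0, noise_sd)
  df$y <- as.numeric(df$y)
  tibble::as_tibble(df)
}
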