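#' Default pipeline configuration
#'
#' @param synthetic Use the synthetic-country generator instead of input
#'   files?
#' @param preset Synthetic preset passed to [synthetic_config()].
#' @param seed Seed for the synthetic generator.
#' @param paths Named list of input CSV paths (ignored when `synthetic`).
#' @param decay List of [decay_config()] arguments.
#' @param regression List of regression options: `cooks_threshold` (NULL =
#'   4/n), `robust_type` ("HC1", "cluster" or "classical"), `year_dummies`
#'   (add year indicator terms?), `logit_response` (regress `qlogis(M)`
#'   instead of `M`?).
#' @return Nested configuration list.
#' @export
pipeline_config <- function(synthetic = TRUE, preset = "small", seed = 1,
                            paths = NULL,
                            decay = list(),
                            regression = list(cooks_threshold = NULL,
                                              robust_type = "HC1",
                                              year_dummies = FALSE,
                                              logit_response = FALSE)) {
  list(synthetic = synthetic, preset = preset, seed = seed, paths = paths,
       decay = decay, regression = regression)
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return Configuration list merged over [pipeline_config()] defaults.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

.regression_csv <- function(fit, path) {
  .write_csv(as.data.frame(fit$coefficients), path)
}

#' Run the full accessibility-and-mobility pipeline
#'
#' Orchestrates ingest (or synthetic generation), quality scoring, decay
#' weights, the two-step accessibility engine, province aggregation, passive
#' mobility, year tests, panel assembly, Cook's-distance filtering and the
#' fixed-effects regressions. Two regression artifacts are always fitted:
#' the base model (mobility on the two gravity indices only) and the
#' extended model (adding the socio-economic covariates). All regression
#' variables are min-max standardized over the pooled panel before fitting.
#'
#' Writes `surface.csv`, `province_indices.csv`, `mobility.csv`,
#' `panel.csv`, `regression_base.csv`, `regression_extended.csv`,
#' `diagnostics.txt` and `manifest.json` to `output_dir`.
#'
#' @param config Configuration list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML/JSON config file.
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`bundle`, `surface`,
#'   `province_indices`, `mobility`, `panel`, `fit_base`, `fit_extended`,
#'   `diagnostics`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir = tempfile("run")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  decay <- do.call(decay_config, as.list(config$decay))

  if (isTRUE(config$synthetic)) {
    country <- .stage("generate", {
      scfg <- synthetic_config(preset = config$preset, seed = config$seed)
      gen_country(scfg, decay)
    })
    munis <- country$municipalities
    surface <- country$surface
    province_indices <- country$province_indices
    mobility <- country$mobility
    covariates <- country$covariates
    bundle <- list(municipalities = munis, facilities = country$facilities,
                   od = country$od, config = decay)
  } else {
    bundle <- .stage("ingest", read_inputs(config$paths, decay))
    munis <- bundle$municipalities
    surface <- .stage("accessibility", compute_accessibility(bundle))
    province_indices <- .stage("aggregate",
                               aggregate_province(surface, munis))
    mobility <- bundle$mobility
    covariates <- bundle$covariates
  }

  if (is.null(mobility))
    stop("pipeline stage 'mobility' failed: no mobility table available and regression requested",
         call. = FALSE)
  mobility$M <- .stage("mobility",
                       passive_mobility(mobility$paz_intra,
                                        mobility$paz_inter))
  year_tests <- .stage("year-tests", year_anova(mobility))

  panel <- .stage("panel",
                  build_lagged_panel(province_indices, mobility, covariates))
  reg_cfg <- config$regression
  covar_terms <- intersect(c("income", "education", "waiting_times",
                             "health_expenditure", "specialists",
                             "satisfaction", "position"), names(panel))
  std_cols <- c("M", "I_G", "Q_G", covar_terms)
  for (cc in std_cols) panel[[paste0(cc, "_std")]] <-
    minmax_standardize(panel[[cc]], cc)

  # logit response works on raw M (clipped away from 0/1), not the min-max scale
  resp <- if (isTRUE(reg_cfg$logit_response))
    "qlogis(pmin(pmax(M, 1e-4), 1 - 1e-4))" else "M_std"
  extra <- if (isTRUE(reg_cfg$year_dummies)) " + factor(year)" else ""
  f_base <- stats::as.formula(paste(resp, "~ I_G_std + Q_G_std", extra))
  f_ext <- stats::as.formula(
    paste(resp, "~ I_G_std + Q_G_std",
          if (length(covar_terms) > 0)
            paste("+", paste(paste0(covar_terms, "_std"), collapse = " + "))
          else "", extra))

  fit_one <- function(f, label) {
    flt <- .stage(paste0("cooks-", label),
                  cooks_distance_filter(panel, f,
                                        threshold = reg_cfg$cooks_threshold))
    fit <- .stage(paste0("regression-", label),
                  fit_fixed_effects(flt$panel, f,
                                    robust = reg_cfg$robust_type %||% "HC1"))
    re <- tryCatch(fit_random_effects(flt$panel, f), error = function(e) NULL)
    haus <- if (!is.null(re)) tryCatch(hausman_test(
      suppressWarnings(fit_fixed_effects(flt$panel, f, robust = "classical")),
      re), error = function(e) NULL) else NULL
    bp <- breusch_pagan_test(fit$residuals, fit$X_demeaned)
    list(fit = fit, filter = flt, hausman = haus, breusch_pagan = bp)
  }
  base <- fit_one(f_base, "base")
  extended <- fit_one(f_ext, "extended")

  # outputs
  write_surface(surface, file.path(output_dir, "surface.csv"))
  .write_csv(as.data.frame(province_indices),
             file.path(output_dir, "province_indices.csv"))
  .write_csv(as.data.frame(mobility), file.path(output_dir, "mobility.csv"))
  .write_csv(as.data.frame(panel), file.path(output_dir, "panel.csv"))
  .regression_csv(base$fit, file.path(output_dir, "regression_base.csv"))
  .regression_csv(extended$fit,
                  file.path(output_dir, "regression_extended.csv"))

  diag_txt <- c(
    "== Year differences in passive mobility ==",
    sprintf("ANOVA: F = %.4f (df %d, %d), p = %.4g", year_tests$anova$F,
            year_tests$anova$df1, year_tests$anova$df2,
            year_tests$anova$p_value),
    utils::capture.output(as.data.frame(year_tests$by_year)),
    utils::capture.output(as.data.frame(year_tests$pairwise)),
    "", "== Base model diagnostics ==", .diag_block(base),
    "", "== Extended model diagnostics ==", .diag_block(extended))
  writeLines(diag_txt, file.path(output_dir, "diagnostics.txt"))

  manifest <- list(
    seed = config$seed,
    synthetic = isTRUE(config$synthetic),
    preset = if (isTRUE(config$synthetic)) config$preset else NULL,
    config_hash = .config_hash(config),
    package_version = as.character(utils::packageVersion("hospaccess")),
    n_municipalities = nrow(munis),
    n_facility_rows = nrow(bundle$facilities),
    n_panel_rows = nrow(panel),
    n_removed_base = nrow(base$filter$removed),
    n_removed_extended = nrow(extended$filter$removed),
    output_hashes = .file_hashes(output_dir))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(bundle = bundle, surface = surface,
                 province_indices = province_indices, mobility = mobility,
                 year_tests = year_tests, panel = panel,
                 base = base, extended = extended,
                 manifest = manifest, output_dir = output_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.diag_block <- function(m) {
  c(sprintf("n_obs = %d, n_units = %d, within-R2 = %.4f, removed outliers = %d (threshold %.4g)",
            m$fit$n_obs, m$fit$n_units, m$fit$within_r2,
            nrow(m$filter$removed), m$filter$threshold),
    if (nrow(m$filter$by_year) > 0)
      utils::capture.output(as.data.frame(m$filter$by_year)),
    if (!is.null(m$hausman))
      sprintf("Hausman: chi2 = %.4f (df %d), p = %.4g",
              m$hausman$statistic, m$hausman$df, m$hausman$p_value),
    sprintf("Breusch-Pagan: LM = %.4f (df %d), p = %.4g",
            m$breusch_pagan$statistic, m$breusch_pagan$df,
            m$breusch_pagan$p_value),
    if (length(m$fit$dropped_terms) > 0)
      sprintf("dropped time-invariant regressor(s): %s",
              paste(m$fit$dropped_terms, collapse = ", ")))
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

.file_hashes <- function(dir) {
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  h <- tools::md5sum(file.path(dir, files))
  as.list(setNames(unname(h), files))
}
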