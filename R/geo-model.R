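#' @importFrom dplyr %>% left_join inner_join group_by summarise mutate arrange
#'   filter select distinct n bind_rows across all_of ungroup
#' @importFrom stats setNames ave
NULL

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("schema error in %s table: missing column(s) %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Validate a municipality table
#'
#' Checks the demand-side table: unique `muni_id`, nonnegative `pop55`
#' (residents aged 55 and over, the reference population for hip-replacement
#' demand), and a consistent province-to-region nesting (each province belongs
#' to exactly one region). Municipalities flagged `excluded` (islands or
#' otherwise unreachable areas) are dropped with a message.
#'
#' @param munis Data frame with columns `muni_id`, `province_id`, `region_id`,
#'   `pop55` and optionally `excluded` (logical).
#' @return Validated tibble without excluded rows.
#' @export
validate_municipalities <- function(munis) {
  .require_cols(munis, c("muni_id", "province_id", "region_id", "pop55"),
                "municipality")
  munis <- tibble::as_tibble(munis)
  if (!("excluded" %in% names(munis))) munis$excluded <- FALSE
  munis$excluded[is.na(munis$excluded)] <- FALSE
  if (anyDuplicated(munis$muni_id))
    stop("integrity error: duplicated muni_id in municipality table")
  if (any(munis$pop55 < 0))
    stop("integrity error: negative pop55")
  p2r <- dplyr::distinct(munis[c("province_id", "region_id")])
  if (anyDuplicated(p2r$province_id))
    stop("integrity error: some province_id maps to more than one region_id")
  n_excl <- sum(munis$excluded)
  if (n_excl > 0)
    message(sprintf("dropping %d excluded municipalit%s", n_excl,
                    if (n_excl == 1) "y" else "ies"))
  munis[!munis$excluded, ]
}

#' Validate a facility table and derive quality levels
#'
#' Checks referential integrity against the municipality table, nonnegative
#' volumes and readmission rates, and derives `quality_level` with
#' [quality_level()] when absent. Facilities inherit province and region from
#' their host municipality; facilities hosted in excluded (dropped)
#' municipalities are dropped with them.
#'
#' @param facilities Data frame with columns `facility_id`, `muni_id`, `year`,
#'   `interventions`, `ret30` (and optionally `quality_level`).
#' @param munis Validated municipality table.
#' @return Tibble with `province_id`, `region_id` and `quality_level` columns
#'   appended.
#' @export
validate_facilities <- function(facilities, munis) {
  .require_cols(facilities,
                c("facility_id", "muni_id", "year", "interventions", "ret30"),
                "facility")
  facilities <- tibble::as_tibble(facilities)
  dangling <- setdiff(facilities$muni_id, munis$muni_id)
  if (length(dangling) > 0)
    stop(sprintf("integrity error: facility host municipality not found: %s",
                 paste(unique(dangling), collapse = ", ")), call. = FALSE)
  if (any(facilities$interventions < 0) || any(facilities$ret30 < 0))
    stop("integrity error: negative interventions or ret30")
  if (anyDuplicated(facilities[c("facility_id", "year")]))
    stop("integrity error: duplicated (facility_id, year)")
  if (!("quality_level" %in% names(facilities))) {
    facilities$quality_level <-
      quality_level(facilities$interventions, facilities$ret30)
  } else if (!all(facilities$quality_level %in% c(0, 0.2, 0.4, 0.6, 0.8, 1))) {
    stop("integrity error: quality_level outside {0, 0.2, 0.4, 0.6, 0.8, 1}")
  }
  dplyr::left_join(
    facilities,
    dplyr::select(munis, "muni_id", "province_id", "region_id"),
    by = "muni_id")
}

#' Validate a long-form travel-time table
#'
#' Keeps only pairs between known (non-excluded) municipalities; a pair absent
#' from the table is treated as unreachable (decay weight 0), never as an
#' error, mirroring the exclusion of areas whose residents cannot reach
#' mainland facilities.
#'
#' @param od Data frame with columns `origin`, `destination`, `minutes`.
#' @param munis Validated municipality table.
#' @return Tibble restricted to known municipality pairs.
#' @export
validate_od <- function(od, munis) {
  .require_cols(od, c("origin", "destination", "minutes"), "travel-time")
  od <- tibble::as_tibble(od)
  if (any(od$minutes < 0)) stop("integrity error: negative travel time")
  known <- od$origin %in% munis$muni_id & od$destination %in% munis$muni_id
  dropped <- sum(!known)
  if (dropped > 0)
    message(sprintf("dropping %d OD pairs referencing unknown or excluded municipalities",
                    dropped))
  od[known, ]
}

#' Validate province-year mobility counts
#'
#' @param mobility Data frame with columns `province_id`, `year`, `paz_intra`
#'   (patients treated inside their region of residence) and `paz_inter`
#'   (treated outside it).
#' @param munis Validated municipality table (for the province universe);
#'   optional.
#' @return Validated tibble.
#' @export
validate_mobility <- function(mobility, munis = NULL) {
  .require_cols(mobility, c("province_id", "year", "paz_intra", "paz_inter"),
                "mobility")
  mobility <- tibble::as_tibble(mobility)
  if (any(mobility$paz_intra < 0) || any(mobility$paz_inter < 0))
    stop("integrity error: negative patient counts")
  if (!is.null(munis)) {
    dangling <- setdiff(mobility$province_id, munis$province_id)
    if (length(dangling) > 0)
      stop(sprintf("integrity error: mobility province not found: %s",
                   paste(unique(dangling), collapse = ", ")), call. = FALSE)
  }
  mobility
}

#' Read and validate the full input bundle
#'
#' Reads the comma-separated input tables (UTF-8, header row mandatory; the
#' travel-time matrix in long `origin,destination,minutes` form) and enforces
#' referential integrity across them. Excluded municipalities are dropped
#' together with their facilities and OD pairs.
#'
#' @param paths Named list/vector of file paths with elements `municipalities`,
#'   `facilities`, `od`, and optionally `mobility` and `covariates`.
#' @param config A [decay_config()] carried along in the bundle.
#' @return A list of class `access_bundle` with elements `municipalities`,
#'   `facilities`, `od`, `mobility` (or NULL), `covariates` (or NULL), `config`.
#' @export
read_inputs <- function(paths, config = decay_config()) {
  need <- c("municipalities", "facilities", "od")
  if (!all(need %in% names(paths)))
    stop("paths must name at least municipalities, facilities and od files")
  read1 <- function(p) {
    if (!file.exists(p)) stop(sprintf("input file not found: %s", p))
    tibble::as_tibble(utils::read.csv(p, stringsAsFactors = FALSE,
                                      fileEncoding = "UTF-8"))
  }
  munis_raw <- read1(paths[["municipalities"]])
  munis <- validate_municipalities(munis_raw)
  excluded_ids <- if ("excluded" %in% names(munis_raw))
    munis_raw$muni_id[munis_raw$excluded %in% TRUE] else character(0)
  facilities <- read1(paths[["facilities"]])
  in_excluded <- facilities$muni_id %in% excluded_ids
  if (any(in_excluded)) {
    message(sprintf("dropping %d facility rows hosted in excluded municipalities",
                    sum(in_excluded)))
    facilities <- facilities[!in_excluded, ]
  }
  facilities <- validate_facilities(facilities, munis)
  od <- validate_od(read1(paths[["od"]]), munis)
  mobility <- if (!is.null(paths[["mobility"]]))
    validate_mobility(read1(paths[["mobility"]]), munis) else NULL
  covariates <- if (!is.null(paths[["covariates"]]))
    tibble::as_tibble(read1(paths[["covariates"]])) else NULL
  structure(list(municipalities = munis, facilities = facilities, od = od,
                 mobility = mobility, covariates = covariates,
                 config = config),
            class = "access_bundle")
}

#' @export
print.access_bundle <- function(x, ...) {
  cat("<access_bundle>\n")
  cat(sprintf("  municipalities: %d (%d provinces, %d regions)\n",
              nrow(x$municipalities),
              dplyr::n_distinct(x$municipalities$province_id),
              dplyr::n_distinct(x$municipalities$region_id)))
  cat(sprintf("  facilities:     %d rows, years %s\n", nrow(x$facilities),
              paste(sort(unique(x$facilities$year)), collapse = ", ")))
  cat(sprintf("  OD pairs:       %d\n", nrow(x$od)))
  if (!is.null(x$mobility))
    cat(sprintf("  mobility rows:  %d\n", nrow(x$mobility)))
  invisible(x)
}

# CSVs are written with full double precision (15 significant digits) so a
# read-back reproduces the values bit-for-bit on the decimal representation.
.write_csv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
}

#' Write an accessibility surface to CSV
#'
#' One row per (municipality, year, attraction variable) with columns
#' `total`, `intra`, `inter`, `gravity`. Numbers are written with 15
#' significant digits so that [read_surface()] round-trips them exactly.
#'
#' @param surface Tibble as returned by [compute_accessibility()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path) {
  cols <- c("muni_id", "year", "attraction", "total", "intra", "inter",
            "gravity")
  .require_cols(surface, cols, "surface")
  if (nrow(surface) == 0) warning("writing an empty accessibility surface")
  .write_csv(surface[cols], path)
  invisible(path)
}

#' Read an accessibility surface written by [write_surface()]
#' @param path File path.
#' @return Tibble with the surface columns.
#' @export
read_surface <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                          fileEncoding = "UTF-8"))
  .require_cols(df, c("muni_id", "year", "attraction", "total", "intra",
                      "inter", "gravity"), "surface")
  df
}
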