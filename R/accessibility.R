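#' Distance-weighted catchment population of a facility
#'
#' First step of the two-step floating catchment area: the potential demand
#' \eqn{P_j = \sum_i P_i w_{ij}} seen by a facility, where \eqn{P_i} is the
#' reference population (residents aged 55+) of municipality \eqn{i} and
#' \eqn{w_{ij}} the decay weight from \eqn{i} to the facility's host
#' municipality.
#'
#' @param pop55 Vector of municipal reference populations.
#' @param weights Vector of decay weights from each municipality to the
#'   facility's host municipality (same length/order as `pop55`).
#' @return Nonnegative scalar \eqn{P_j}; 0 when no municipality is in reach.
#' @export
weighted_demand <- function(pop55, weights) {
  stopifnot(length(pop55) == length(weights))
  sum(pop55 * weights)
}

#' Supply-to-demand ratio of a facility
#'
#' \eqn{R_j = n_j / P_j}, the facility's attraction (intervention volume or
#' quality level) per distance-weighted resident in its catchment. A facility
#' with empty catchment (\eqn{P_j = 0}) contributes nothing downstream: its
#' ratio is returned as 0 with a warning.
#'
#' @param attraction Nonnegative numerator(s) \eqn{n_j} (vectorised).
#' @param demand Catchment population(s) \eqn{P_j} from [weighted_demand()].
#' @return Ratio(s) \eqn{R_j \ge 0}.
#' @export
supply_ratio <- function(attraction, demand) {
  stopifnot(length(attraction) == length(demand) || length(demand) == 1 ||
            length(attraction) == 1)
  if (any(attraction < 0, na.rm = TRUE)) stop("attraction must be nonnegative")
  r <- ifelse(demand > 0, attraction / demand, 0)
  if (any(demand == 0 & attraction > 0))
    warning(sprintf("%d facilit%s with positive attraction but empty catchment; contribution set to 0",
                    sum(demand == 0 & attraction > 0),
                    if (sum(demand == 0 & attraction > 0) == 1) "y" else "ies"))
  r
}

# dense municipality x municipality weight matrix from the long OD table;
# missing pairs are unreachable (0); the diagonal is 1 (d = 0) unless the OD
# table states otherwise
.dense_weights <- function(muni_ids, od, config) {
  n <- length(muni_ids)
  W <- matrix(0, n, n, dimnames = list(muni_ids, muni_ids))
  diag(W) <- 1
  if (nrow(od) > 0) {
    i <- match(od$origin, muni_ids)
    j <- match(od$destination, muni_ids)
    W[cbind(i, j)] <- gaussian_weight(od$minutes, config)
  }
  W
}

#' Accessibility index of one municipality
#'
#' Second step of the method: the distance-weighted sum of supply-to-demand
#' ratios \eqn{A_i = \sum_j R_j w_{ij}}, optionally restricted to facilities
#' inside (`scope = "intra"`) or outside (`scope = "inter"`) the
#' municipality's region of residence.
#'
#' @param ratios Vector \eqn{R_j} over facilities.
#' @param weights Vector \eqn{w_{ij}} from the municipality to each facility's
#'   host municipality.
#' @param same_region Logical vector: is facility j in the municipality's
#'   region? Required for `intra`/`inter` scopes.
#' @param scope One of `"all"`, `"intra"`, `"inter"`.
#' @return Nonnegative scalar \eqn{A_i}.
#' @export
accessibility_index <- function(ratios, weights, same_region = NULL,
                                scope = c("all", "intra", "inter")) {
  scope <- match.arg(scope)
  stopifnot(length(ratios) == length(weights))
  keep <- switch(scope,
                 all = rep(TRUE, length(ratios)),
                 intra = { stopifnot(!is.null(same_region)); same_region },
                 inter = { stopifnot(!is.null(same_region)); !same_region })
  sum(ratios[keep] * weights[keep])
}

#' Gravity composite of the accessibility decomposition
#'
#' \eqn{A^G = A^{INTRA} - A^{INTER}}: positive when in-region facilities
#' dominate the attraction felt at a municipality, negative when out-of-region
#' facilities do. Negative values are meaningful and never clipped.
#'
#' @param intra,inter Intra- and interregional components (vectorised).
#' @return \eqn{A^G}, possibly negative.
#' @export
gravity_index <- function(intra, inter) intra - inter

#' Full E2SFCA accessibility surface
#'
#' Runs both steps of the enhanced two-step floating catchment area per year
#' and per attraction variable (intervention volume and quality level),
#' decomposing each municipal index into intraregional and interregional
#' components (facilities inside vs outside the municipality's region, region
#' membership taken from the facility's host municipality) and the gravity
#' composite. Distances between a municipality and a facility are the
#' centroid-to-centroid travel times of their host municipalities;
#' intra-municipal distance is 0 (weight 1). Facilities with quality level 0
#' still enter the quality-weighted index with numerator 0, so catchment
#' demand is identical across attraction variables.
#'
#' @param bundle An `access_bundle` from [read_inputs()] (or any list with
#'   validated `municipalities`, `facilities`, `od`, `config`).
#' @param attractions Character subset of `c("interventions", "quality")`.
#' @return Tibble with columns `muni_id`, `year`, `attraction`, `total`,
#'   `intra`, `inter`, `gravity`; `total = intra + inter` exactly.
#' @export
compute_accessibility <- function(bundle,
                                  attractions = c("interventions", "quality")) {
  attractions <- match.arg(attractions, several.ok = TRUE)
  munis <- bundle$municipalities
  W <- .dense_weights(munis$muni_id, bundle$od, bundle$config)
  out <- list()
  for (yr in sort(unique(bundle$facilities$year))) {
    fac <- bundle$facilities[bundle$facilities$year == yr, ]
    host <- match(fac$muni_id, munis$muni_id)
    # weights from every municipality i to every facility j (n_muni x n_fac)
    Wf <- W[, host, drop = FALSE]
    Pj <- as.numeric(crossprod(Wf, munis$pop55))
    same_region <- outer(munis$region_id, fac$region_id, "==")
    for (attr in attractions) {
      nj <- if (attr == "interventions") fac$interventions else fac$quality_level
      Rj <- supply_ratio(nj, Pj)
      intra <- as.numeric((Wf * same_region) %*% Rj)
      inter <- as.numeric((Wf * !same_region) %*% Rj)
      out[[length(out) + 1L]] <- tibble::tibble(
        muni_id = munis$muni_id, year = yr, attraction = attr,
        total = intra + inter, intra = intra, inter = inter,
        gravity = gravity_index(intra, inter))
    }
  }
  dplyr::bind_rows(out)
}

#' Population-weighted aggregation of the surface to provinces
#'
#' Aggregates municipal indices to the province by the reference-population
#' weighted mean \eqn{I^G_p = \sum_{i \in p} I^G_i P_i / \sum_{i \in p} P_i},
#' applied to every component column. Provinces whose total reference
#' population is 0 are emitted as missing with a warning.
#'
#' @param surface Tibble from [compute_accessibility()].
#' @param munis Validated municipality table.
#' @return Tibble with columns `province_id`, `year`, `attraction`, `total`,
#'   `intra`, `inter`, `gravity`.
#' @export
aggregate_province <- function(surface, munis) {
  .aggregate_by(surface, munis, "province_id")
}

#' Population-weighted aggregation of the surface to regions
#'
#' Same weighted mean as [aggregate_province()], at region granularity, for
#' users wanting regional summaries.
#' @inheritParams aggregate_province
#' @return Tibble keyed by `region_id`, `year`, `attraction`.
#' @export
aggregate_region <- function(surface, munis) {
  .aggregate_by(surface, munis, "region_id")
}

.aggregate_by <- function(surface, munis, key) {
  df <- dplyr::inner_join(surface,
                          munis[c("muni_id", key, "pop55")], by = "muni_id")
  wmean <- function(x, w) if (sum(w) > 0) sum(x * w) / sum(w) else NA_real_
  out <- df %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "year", "attraction")))) %>%
    dplyr::summarise(dplyr::across(dplyr::all_of(c("total", "intra", "inter",
                                                   "gravity")),
                                   ~ wmean(.x, pop55)),
                     .groups = "drop")
  if (anyNA(out$gravity))
    warning("province(s) with zero reference population emitted as missing")
  out
}
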