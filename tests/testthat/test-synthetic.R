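test_that("geography generation counts, determinism and speed scaling hold", {
  cfg <- synthetic_config(seed = 42, n_regions = 2, provinces_per_region = 2,
                          municipalities_per_province = 5)
  g1 <- gen_geography(cfg)
  expect_equal(nrow(g1$municipalities), 20)
  expect_equal(nrow(g1$od), 400)  # all ordered pairs incl. the zero diagonal

  g2 <- gen_geography(cfg)
  expect_identical(g1, g2)

  cfg_fast <- cfg
  cfg_fast$speed_km_per_min <- 2 * cfg$speed_km_per_min
  g3 <- gen_geography(cfg_fast)
  expect_equal(g3$od$minutes, g1$od$minutes / 2)

  # symmetric with zero diagonal
  m <- matrix(g1$od$minutes, 20, 20)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 20))
})

test_that("the readmission gradient depresses quality in the southern macro-area", {
  diffs <- vapply(1:50, function(s) {
    cfg <- synthetic_config(seed = s, n_regions = 6, provinces_per_region = 2,
                            municipalities_per_province = 3,
                            ret30_gradient = 3)
    g <- gen_geography(cfg)
    f <- gen_facilities(cfg, g$municipalities, years = 2020)
    pos <- g$municipalities$position[match(f$muni_id,
                                           g$municipalities$muni_id)]
    mean(f$quality_level[pos == 2]) - mean(f$quality_level[pos < 2])
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gt(mean(diffs < 0), 0.9)
})

test_that("without a gradient there is no systematic north-south quality gap", {
  pvals <- vapply(1:50, function(s) {
    cfg <- synthetic_config(seed = 100 + s, n_regions = 6,
                            provinces_per_region = 2,
                            municipalities_per_province = 3,
                            ret30_gradient = 0)
    g <- gen_geography(cfg)
    f <- gen_facilities(cfg, g$municipalities, years = 2020)
    pos <- g$municipalities$position[match(f$muni_id,
                                           g$municipalities$muni_id)]
    if (sum(pos == 2) < 2 || sum(pos < 2) < 2) return(NA_real_)
    stats::t.test(f$ret30[pos == 2], f$ret30[pos < 2])$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.05, na.rm = TRUE), 0.9)
})

test_that("zero-volume facilities are legal and score quality 0", {
  cfg <- synthetic_config(seed = 9, n_regions = 2, provinces_per_region = 2,
                          municipalities_per_province = 2, volume_mean = 1)
  g <- gen_geography(cfg)
  f <- gen_facilities(cfg, g$municipalities, years = 2020)
  expect_true(any(f$interventions == 0))
  expect_true(all(f$quality_level[f$interventions <= 72] == 0))
})

test_that("covariates carry all panel columns, constant within region, seeded", {
  cfg <- synthetic_config(seed = 4, preset = "small")
  g <- gen_geography(cfg)
  cov <- gen_covariates(cfg, g$municipalities)
  expect_true(all(c("province_id", "year", "income", "education",
                    "waiting_times", "health_expenditure", "specialists",
                    "satisfaction", "position") %in% names(cov)))
  p2r <- unique(g$municipalities[c("province_id", "region_id")])
  cov2 <- merge(cov, p2r)
  spread <- tapply(cov2$waiting_times,
                   paste(cov2$region_id, cov2$year), function(x) diff(range(x)))
  expect_true(all(spread == 0))
  expect_identical(cov, gen_covariates(cfg, g$municipalities))
})

test_that("mobility generation respects its choice model and degenerate totals", {
  cfg <- synthetic_config(seed = 11, preset = "small")
  cty <- gen_country(cfg)
  expect_true(all(cty$mobility$paz_intra >= 0 & cty$mobility$paz_inter >= 0))
  expect_setequal(unique(cty$mobility$year), cfg$years + 1)
  truth <- attr(cty$mobility, "truth")
  expect_equal(truth$beta_I, -1)

  # zero incidence draws zero totals: mobility undefined downstream
  cfg0 <- synthetic_config(seed = 11, preset = "small", incidence = 0)
  mob0 <- gen_mobility(cfg0, cty$province_indices, cty$municipalities)
  expect_warning(m <- passive_mobility(mob0$paz_intra, mob0$paz_inter))
  expect_true(all(is.na(m)))

  # unknown province in the surface is rejected
  bad <- cty$province_indices
  bad$province_id[1] <- "P999"
  expect_error(gen_mobility(cfg, bad, cty$municipalities), "mismatch")
})

test_that("the full synthetic pipeline is bit-for-bit reproducible under a seed", {
  cfg <- synthetic_config(seed = 21, preset = "small")
  c1 <- gen_country(cfg)
  c2 <- gen_country(cfg)
  expect_identical(c1$surface, c2$surface)
  expect_identical(c1$mobility, c2$mobility)
  expect_identical(c1$covariates, c2$covariates)
})
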