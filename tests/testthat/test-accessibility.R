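test_that("catchment demand and supply ratios follow the two-step arithmetic", {
  expect_equal(weighted_demand(c(100, 100), c(1, 0.5)), 150)
  expect_equal(weighted_demand(c(100, 100), c(0, 0)), 0)
  expect_equal(weighted_demand(500, 1), 500)

  expect_equal(supply_ratio(100, 150), 100 / 150)
  expect_equal(supply_ratio(0, 150), 0)
  expect_warning(r <- supply_ratio(10, 0), "empty catchment")
  expect_equal(r, 0)
})

test_that("municipal indices sum ratio-weight products with region scoping", {
  expect_equal(accessibility_index(100 / 150, 0.5), 100 / 150 * 0.5)
  expect_equal(accessibility_index(c(1, 2), c(0.5, 0.5),
                                   same_region = c(FALSE, FALSE),
                                   scope = "intra"), 0)
  r <- c(0.3, 0.7); w <- c(0.9, 0.1); same <- c(TRUE, FALSE)
  expect_equal(accessibility_index(r, w, same, "intra") +
                 accessibility_index(r, w, same, "inter"),
               accessibility_index(r, w, scope = "all"))

  expect_equal(gravity_index(5, 2), 3)
  expect_equal(gravity_index(0, 4), -4)
  expect_equal(gravity_index(7, 7), 0)
})

test_that("the vectorised engine matches the naive triple-loop oracle", {
  for (seed in 1:12) {
    n_m <- sample(2:5, 1)
    b <- random_instance(seed, n_muni = n_m, n_fac = sample(1:3, 1))
    for (attr in c("interventions", "quality")) {
      got <- suppressWarnings(compute_accessibility(b, attr))
      want <- naive_accessibility(b, attr)
      expect_equal(got$total, want$total, tolerance = 1e-12)
      expect_equal(got$intra, want$intra, tolerance = 1e-12)
      expect_equal(got$inter, want$inter, tolerance = 1e-12)
      expect_equal(got$gravity, want$gravity, tolerance = 1e-12)
    }
  }
})

test_that("attraction mass is conserved and the regional split is exact", {
  for (seed in 1:20) {
    b <- random_instance(seed)
    surf <- suppressWarnings(compute_accessibility(b, "interventions"))
    W <- hospaccess:::.dense_weights(b$municipalities$muni_id, b$od, b$config)
    host <- match(b$facilities$muni_id, b$municipalities$muni_id)
    Pj <- as.numeric(crossprod(W[, host, drop = FALSE],
                               b$municipalities$pop55))
    supplied <- sum(b$facilities$interventions[Pj > 0])
    absorbed <- sum(b$municipalities$pop55 * surf$total)
    if (supplied > 0)
      expect_equal(absorbed, supplied, tolerance = 1e-9)
    expect_equal(surf$total, surf$intra + surf$inter)
    expect_true(all(surf$intra >= 0 & surf$inter >= 0))
  }
})

test_that("indices scale linearly in attraction and inversely in population", {
  b <- random_instance(101, n_muni = 20, n_fac = 5)
  s1 <- suppressWarnings(compute_accessibility(b, "interventions"))
  b2 <- b
  b2$facilities$interventions <- 2 * b$facilities$interventions
  s2 <- suppressWarnings(compute_accessibility(b2, "interventions"))
  expect_equal(s2$total, 2 * s1$total)
  b3 <- b
  b3$municipalities$pop55 <- 2 * b$municipalities$pop55
  s3 <- suppressWarnings(compute_accessibility(b3, "interventions"))
  expect_equal(s3$total, s1$total / 2)
})

test_that("province aggregation is the population-weighted mean of its municipalities", {
  munis <- tibble::tibble(muni_id = c("a", "b"), province_id = "p1",
                          region_id = "r1", pop55 = c(100, 300))
  surf <- tibble::tibble(muni_id = c("a", "b"), year = 2020,
                         attraction = "interventions",
                         total = c(2, 4), intra = c(2, 4), inter = 0,
                         gravity = c(2, 4))
  agg <- aggregate_province(surf, munis)
  expect_equal(agg$gravity, 3.5)  # (2*100 + 4*300) / 400

  # single municipality: identity; constant values: unchanged
  agg1 <- aggregate_province(surf[1, ], munis[1, ])
  expect_equal(agg1$gravity, 2)
  surf$gravity <- 7; surf$total <- 7
  expect_equal(aggregate_province(surf, munis)$gravity, 7)

  # aggregate bounded by municipal extremes on random instances
  for (seed in 31:35) {
    b <- random_instance(seed)
    s <- suppressWarnings(compute_accessibility(b, "interventions"))
    a <- aggregate_province(s, b$municipalities)
    rng <- dplyr::summarise(
      dplyr::group_by(dplyr::inner_join(
        s, b$municipalities[c("muni_id", "province_id")], by = "muni_id"),
        province_id),
      lo = min(gravity), hi = max(gravity), .groups = "drop")
    m <- dplyr::inner_join(a, rng, by = "province_id")
    expect_true(all(m$gravity >= m$lo - 1e-12 & m$gravity <= m$hi + 1e-12))
  }
})
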