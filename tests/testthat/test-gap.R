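test_that("deficit fraction uses supply as the divisor", {
  expect_equal(round(deficit_fraction(141579, 144410), 3), -0.020)
  expect_equal(round(deficit_fraction(149563, 157490), 3), -0.053)
  expect_equal(round(deficit_fraction(152160, 173918), 3), -0.143)
  expect_equal(deficit_fraction(100, 100), 0)
  expect_error(deficit_fraction(0, 10), "> 0")
})

test_that("deficit fraction is monotone in both arguments", {
  s <- 120; n <- 100
  expect_gt(deficit_fraction(s + 1, n), deficit_fraction(s, n))
  expect_lt(deficit_fraction(s, n + 1), deficit_fraction(s, n))
})

test_that("ratio per 100k has the right units and homogeneity", {
  expect_equal(round(ratio_per_100k(141579, 44366332)), 319)
  expect_equal(ratio_per_100k(0, 1e6), 0)
  expect_equal(ratio_per_100k(100, 100000), 100)
  expect_equal(ratio_per_100k(500, 2e6), ratio_per_100k(500 * 3, 2e6 * 3))
  expect_error(ratio_per_100k(10, 0), "> 0")
})

test_that("pyramid summaries count women and under-51s correctly", {
  st <- specialty_stock(specialties = "1")
  st["1", "female", ] <- 1
  ps <- pyramid_summaries(st)
  expect_equal(ps$pct_women, 1)

  st2 <- specialty_stock(specialties = "1")
  st2["1", "male", "50"] <- 10
  st2["1", "male", "51"] <- 10
  # "under 51" means attained age <= 50
  expect_equal(pyramid_summaries(st2)$pct_under_51, 0.5)

  expect_error(pyramid_summaries(specialty_stock(specialties = "1")),
               "empty stock")
  expect_error(pyramid_summaries(st, specialty = "nope"), "unknown")
})

test_that("pyramid summaries agree with a scalar recount", {
  set.seed(21)
  st <- random_stock(S = 3)
  ps <- pyramid_summaries(st, specialty = "2")
  tot <- 0; women <- 0; under <- 0; agesum <- 0
  ages <- stock_ages(st)
  for (x in 1:2) for (a in seq_along(ages)) {
    c0 <- st[2, x, a]
    tot <- tot + c0
    if (x == 1) women <- women + c0
    if (ages[a] <= 50) under <- under + c0
    agesum <- agesum + c0 * ages[a]
  }
  expect_equal(ps$pct_women, women / tot, tolerance = 1e-12)
  expect_equal(ps$pct_under_51, under / tot, tolerance = 1e-12)
  expect_equal(ps$mean_age, agesum / tot, tolerance = 1e-12)
  expect_equal(sum(ps$pyramid$count), tot, tolerance = 1e-12)
})

test_that("specialty ranking orders by deficit with id tie-break", {
  res <- run_scenario(small_scenario(S = 3))
  rk <- rank_specialties(res, 2025)
  expect_equal(rk$deficit_pct, sort(rk$deficit_pct))
  expect_error(rank_specialties(res, 1999), "not present")

  # tie-break on equal deficits: lower id first (synthetic tie)
  res2 <- res
  res2$table$deficit_pct <- rep(-0.05, nrow(res2$table))
  rk2 <- rank_specialties(res2, 2025)
  expect_equal(rk2$specialty, as.character(1:3))

  # 43-specialty fixture against an independent full sort
  res43 <- run_scenario(generate_spain_like_scenario(seed = 3))
  rk43 <- rank_specialties(res43, 2025)
  tab <- res43$table[res43$table$year == 2025, ]
  want <- tab$specialty[order(tab$deficit_pct, as.numeric(tab$specialty))]
  expect_equal(rk43$specialty, want)
})

test_that("aggregate deficit pools supply and need, not per-specialty means", {
  res <- run_scenario(small_scenario(S = 3))
  tab <- res$table[res$table$year == 2025, ]
  agg <- res$aggregate[res$aggregate$year == 2025, ]
  pooled <- (sum(tab$supply_head) - sum(tab$need)) / sum(tab$supply_head)
  expect_equal(agg$deficit_pct, pooled, tolerance = 1e-12)
  mean_frac <- mean(tab$deficit_pct)
  expect_false(isTRUE(all.equal(pooled, mean_frac, tolerance = 1e-6)))
})
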