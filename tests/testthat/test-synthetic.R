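test_that("fixture generation is seed-deterministic", {
  spec <- fixture_spec(seed = 123)
  s1 <- generate_initial_stock(spec)
  s2 <- generate_initial_stock(spec)
  expect_identical(unclass(s1), unclass(s2))
  s3 <- generate_initial_stock(fixture_spec(seed = 124))
  expect_false(identical(unclass(s1), unclass(s3)))
})

test_that("generated totals hit the calibration target", {
  spec <- fixture_spec(supply_target = 141579, seed = 2)
  st <- generate_initial_stock(spec)
  expect_lt(abs(stock_total(st) - 141579) / 141579, 0.001)
  expect_true(all(st >= 0))
  expect_error(fixture_spec(supply_target = 0), "impossible calibration")
})

test_that("pyramid shape families honour their contracts", {
  spec <- fixture_spec(n_specialties = 9,
                       shapes = rep(c("old_heavy", "uniform",
                                      "young_feminized"), each = 3),
                       supply_target = 9000, seed = 31)
  st <- generate_initial_stock(spec)
  for (s in 1:9) {
    ps <- pyramid_summaries(st, specialty = as.character(s))
    if (spec$shapes[s] == "old_heavy") {
      expect_gte(ps$mean_age, 50)
    } else if (spec$shapes[s] == "young_feminized") {
      expect_lte(ps$mean_age, 42)
      expect_gte(ps$pct_women, 0.55)
    }
  }
})

test_that("synthetic mortality is Gompertz-shaped and sex-ordered", {
  spec <- fixture_spec(n_specialties = 2, seed = 1)
  tabs <- generate_rate_tables(spec)
  mort <- tabs$exits$mortality
  ages <- 30:65
  # closed form to numerical precision
  expect_equal(unname(mort["male", ]), 5e-4 * exp(0.09 * (ages - 30)),
               tolerance = 1e-12)
  expect_gt(mort["male", "65"], mort["male", "30"])
  expect_true(all(mort["female", ] <= mort["male", ]))
  expect_true(all(mort >= 0 & mort <= 1))

  flat <- generate_rate_tables(spec, beta = 0)$exits$mortality
  expect_equal(diff(range(flat["male", ])), 0)

  expect_error(generate_rate_tables(spec, m0 = 0.5, beta = 0.2),
               "above 1")
})

test_that("the Spain-like baseline reproduces its aggregate anchors", {
  sc <- generate_spain_like_scenario(seed = 1)
  expect_equal(nrow(validate_scenario(sc)), 0) # schema-closed generation
  res <- run_scenario(sc)
  a08 <- res$aggregate[res$aggregate$year == 2008, ]
  expect_lt(abs(a08$deficit_pct - (-0.02)), 0.003)
  expect_lt(abs(a08$ratio_per_100k - 319), 2)
  a25 <- res$aggregate[res$aggregate$year == 2025, ]
  expect_equal(a25$need / a08$need, 173918 / 144410, tolerance = 1e-6)
})

test_that("every generated fixture passes consumer validation", {
  for (seed in c(5, 6)) {
    sc <- generate_spain_like_scenario(seed = seed, n_specialties = 7)
    expect_equal(nrow(validate_scenario(sc)), 0)
    res <- run_scenario(sc)
    expect_true(all(is.finite(res$aggregate$supply_head)))
  }
})

test_that("fixture generation leaves the caller's RNG stream alone", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(generate_initial_stock(fixture_spec(n_specialties = 2, seed = 7)))
  after <- runif(1)
  expect_identical(before, after)
})
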