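test_that("cumulative growth compounds geometrically", {
  expect_equal(cumulative_growth(0, 17), 0)
  expect_equal(cumulative_growth(0.006, 17), 1.006^17 - 1)
  expect_equal(cumulative_growth(0.013, 17), 1.013^17 - 1)
  expect_equal(cumulative_growth(-0.006, 17), 0.994^17 - 1)
  expect_error(cumulative_growth(-1, 5), "exceed -1")
  expect_error(cumulative_growth(0.01, -1), ">= 0")
})

test_that("cumulative growth composes over split horizons exactly", {
  for (g in c(-0.006, 0, 0.006, 0.013, 0.2)) {
    for (ab in list(c(3, 14), c(0, 17), c(8, 9))) {
      lhs <- cumulative_growth(g, sum(ab))
      rhs <- (1 + cumulative_growth(g, ab[1])) *
        (1 + cumulative_growth(g, ab[2])) - 1
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("moderate population path reproduces its anchors exactly", {
  ps <- population_scenario("moderate")
  expect_equal(population_at(ps, 2008), 44366332)
  expect_equal(population_at(ps, 2015), 46333661)
  expect_equal(population_at(ps, 2025), 48018184)
  # geometric interpolation: constant growth within each anchor interval
  p <- ps$population
  r <- p[as.character(2009:2015)] / p[as.character(2008:2014)]
  expect_equal(diff(range(r)), 0, tolerance = 1e-12)
  expect_error(population_at(ps, 2030), "does not cover")
})

test_that("rapid / moderate / slow populations are ordered every year", {
  rapid <- population_scenario("rapid")
  moderate <- population_scenario("moderate")
  slow <- population_scenario("slow")
  expect_true(all(rapid$population >= moderate$population))
  expect_true(all(moderate$population >= slow$population))
})

test_that("need trajectory follows ratio x growth x population / 100k", {
  ps <- population_scenario("moderate", years = 2008:2025,
                            population = stats::setNames(
                              rep(1e6, 18), 2008:2025))
  std <- need_standard("1", base_ratio = 10, group = "stable")
  expect_equal(unname(need_trajectory(std, ps)), rep(100, 18))

  std_up <- need_standard("1", base_ratio = 10,
                          group = "sharply_increasing")
  nt <- need_trajectory(std_up, ps)
  expect_equal(unname(nt[["2025"]] / nt[["2008"]]),
               1 + cumulative_growth(0.013, 17))
  # log-linear in time under constant population
  expect_equal(diff(log(unname(nt))), rep(log(1.013), 17),
               tolerance = 1e-12)
  # base year value is exact
  expect_equal(unname(nt[["2008"]]), 10 * 1e6 / 1e5)
})

test_that("total need is additive over specialties", {
  ps <- population_scenario("moderate")
  std <- need_standard("1", 12, "stable_increasing")
  one <- need_trajectory(std, ps)
  two <- total_need(list(std, std), ps)
  expect_equal(two, 2 * one)
  expect_error(total_need(list(), ps), "empty")

  set.seed(15)
  standards <- data.frame(
    specialty_id = as.character(1:43),
    base_ratio_per_100k = runif(43, 1, 20),
    demand_group = sample(names(demand_group_rates()), 43, replace = TRUE),
    stringsAsFactors = FALSE)
  got <- total_need(standards, ps, years = 2020)
  want <- 0
  for (i in 1:43) {
    g <- demand_group_rates()[[standards$demand_group[i]]]
    want <- want + standards$base_ratio_per_100k[i] * (1 + g)^12 *
      population_at(ps, 2020) / 1e5
  }
  expect_lt(abs(got - want), 1e-9)
})

test_that("custom population paths validate coverage and positivity", {
  expect_error(population_scenario(years = 2008:2010,
                                   population = c("2008" = 1e6,
                                                  "2009" = 1e6)),
               "missing years")
  expect_error(population_scenario(years = 2008:2009,
                                   population = c("2008" = 1e6,
                                                  "2009" = -1)),
               "> 0")
})
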