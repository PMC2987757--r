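test_that("rerunning a scenario is bit-identical", {
  sc <- small_scenario()
  r1 <- run_scenario(sc)
  r2 <- run_scenario(sc)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$aggregate, r2$aggregate)
  expect_identical(r1$trajectory$counts, r2$trajectory$counts)
})

test_that("an admissions increase from 2009 acts only after the 10-year lag", {
  base <- small_scenario(admissions = c("2008" = 600))
  up <- small_scenario(admissions = c("2008" = 600, "2009" = 720))
  rb <- run_scenario(base)
  ru <- run_scenario(up)
  sup_b <- rb$aggregate$supply_head
  sup_u <- ru$aggregate$supply_head
  yrs <- rb$aggregate$year
  expect_identical(sup_u[yrs <= 2018], sup_b[yrs <= 2018])
  expect_true(all(sup_u[yrs >= 2019] > sup_b[yrs >= 2019]))
})

test_that("deficits order with the population scenario every year", {
  rapid <- run_scenario(small_scenario(population = "rapid"))
  moderate <- run_scenario(small_scenario(population = "moderate"))
  slow <- run_scenario(small_scenario(population = "slow"))
  # more population -> more need -> deeper (more negative) deficit
  expect_true(all(rapid$aggregate$deficit_pct <=
                    moderate$aggregate$deficit_pct))
  expect_true(all(moderate$aggregate$deficit_pct <=
                    slow$aggregate$deficit_pct))
  # supply is unaffected by the population path
  expect_identical(rapid$aggregate$supply_head,
                   slow$aggregate$supply_head)
})

test_that("compare_scenarios is zero against itself and aligned long-form", {
  sc <- small_scenario()
  res <- run_scenario(sc)
  cmp <- compare_scenarios(list(res, res))
  expect_true(all(cmp$diff_vs_ref == 0))
  expect_setequal(unique(cmp$metric),
                  c("supply_head", "supply_fte", "need", "deficit_head",
                    "deficit_pct", "ratio_per_100k"))
  expect_error(compare_scenarios(list(res)), "at least 2")

  short <- run_scenario(small_scenario(horizon = c(2008, 2015)))
  expect_error(compare_scenarios(list(res, short)), "mismatched horizons")
})

test_that("swapping non-reference scenarios only permutes rows", {
  a <- run_scenario(small_scenario(name = "a"))
  b <- run_scenario(small_scenario(name = "b", seed = 43))
  c_ <- run_scenario(small_scenario(name = "c", seed = 44))
  cmp1 <- compare_scenarios(list(a, b, c_))
  cmp2 <- compare_scenarios(list(a, c_, b))
  key <- function(d) d[order(d$metric, d$year, d$scenario), ]
  expect_equal(key(cmp1), key(cmp2), ignore_attr = TRUE)
})

test_that("admissions sweep yields monotone 2025 supply", {
  sc <- small_scenario()
  sw <- sweep_parameter(sc, "numerus_clausus", c(400, 600, 800))
  finals <- vapply(sw, function(r)
    r$aggregate$supply_head[r$aggregate$year == 2025], 0)
  expect_true(all(diff(finals) >= 0))
})

test_that("retirement-age sweep never lowers final supply", {
  sc <- small_scenario()
  sw <- sweep_parameter(sc, "retirement_age", c(65, 66, 67))
  finals <- vapply(sw, function(r)
    r$aggregate$supply_head[r$aggregate$year == 2025], 0)
  expect_true(all(diff(finals) >= -1e-9))
})

test_that("demand-rate sweep scales 2025 need by (1+g)^17", {
  sc <- small_scenario()
  sw <- sweep_parameter(sc, "demand_rate", c(0, 0.006, 0.013))
  needs <- vapply(sw, function(r)
    r$aggregate$need[r$aggregate$year == 2025], 0)
  base <- needs[["0"]]
  expect_equal(unname(needs[["0.006"]] / base), 1.006^17,
               tolerance = 1e-12)
  expect_equal(unname(needs[["0.013"]] / base), 1.013^17,
               tolerance = 1e-12)
})

test_that("sweep validates its parameter name and leaves input untouched", {
  sc <- small_scenario()
  before <- sc$schedule
  expect_error(sweep_parameter(sc, "bogus", 1), "valid names")
  expect_length(sweep_parameter(sc, "retirement_age", numeric()), 0)
  sw <- sweep_parameter(sc, "retirement_age", 66)
  expect_identical(sc$schedule, before)
})

test_that("validation reports schedule gaps when carry-forward is disabled", {
  sc <- small_scenario()
  ra <- stats::setNames(rep(65, 17), setdiff(2008:2025, 2020))
  sc$schedule <- parameter_schedule(
    numerus_clausus = stats::setNames(rep(600, 18), 2008:2025),
    residency_positions = sc$schedule$residency_positions,
    retirement_age = ra,
    fte = sc$schedule$fte,
    carry_forward = FALSE)
  rep <- validate_scenario(sc)
  expect_true(has_errors(rep))
  msgs <- rep$message[rep$severity == "error"]
  expect_true(any(grepl("retirement_age, 2020", msgs)))
  expect_length(msgs, 1)
  expect_error(run_scenario(sc), "retirement_age, 2020")
})

test_that("a clean scenario validates with zero findings", {
  rep <- validate_scenario(small_scenario())
  expect_s3_class(rep, "validation_report")
  expect_equal(nrow(rep), 0)
})

test_that("missing standards or population coverage are validation errors", {
  sc <- small_scenario()
  sc$standards <- sc$standards[-1, ]
  rep <- validate_scenario(sc)
  expect_true(any(grepl("no need standard", rep$message)))

  sc2 <- small_scenario()
  sc2$population <- population_scenario("moderate", years = 2008:2015)
  rep2 <- validate_scenario(sc2)
  expect_true(any(grepl("population path missing", rep2$message)))
})
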