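test_that("zero flows and disabled retirement give a pure age shift", {
  st <- specialty_stock(specialties = c("1", "2"))
  set.seed(1)
  # occupy ages 30-64; the top age stays empty so the shift is an identity
  for (a in as.character(30:64)) st[, , a] <- matrix(runif(4), 2, 2)
  ex <- exit_rates(retirement_age = Inf, specialties = c("1", "2"))
  out <- step_year(st, ex, year = 2008)
  shifted <- unclass(out$stock)[, , as.character(31:65)]
  orig <- unclass(st)[, , as.character(30:64)]
  expect_identical(as.vector(shifted), as.vector(orig))
  expect_true(all(out$stock[, , "30"] == 0))
  expect_equal(ledger_net(out$ledger), 0)
})

test_that("a lone 64-year-old retires after two steps, leaving one exit", {
  st <- specialty_stock(specialties = "1")
  st["1", "male", "64"] <- 1
  ex <- exit_rates(retirement_age = 65, specialties = "1")
  s1 <- step_year(st, ex, year = 2008)
  expect_equal(sum(s1$stock), 1)
  expect_equal(unname(s1$stock["1", "male", "65"]), 1)
  s2 <- step_year(s1$stock, ex, year = 2009)
  expect_equal(sum(s2$stock), 0)
  expect_equal(unname(s2$ledger$totals["retirement"]), 1)
  expect_equal(sum(s2$ledger$outflows) - s2$ledger$totals[["retirement"]], 0)
})

test_that("every step conserves headcount against its flow ledger exactly", {
  set.seed(202)
  for (rep in 1:100) {
    S <- sample(1:4, 1)
    st <- random_stock(S = S)
    ex <- random_exits(S = S, retirement_age = sample(c(60, 65, 66, Inf), 1))
    pl <- if (runif(1) < 0.5) random_pipeline(S = S) else NULL
    im <- if (runif(1) < 0.5) random_immigration(S = S) else NULL
    out <- step_year(st, ex, pl, im, year = 2010)
    expect_lt(abs((sum(out$stock) - sum(st)) - ledger_net(out$ledger)), 1e-9)
    expect_true(all(out$stock >= 0))
  }
})

test_that("vectorized step equals the per-cell scalar oracle over 5 steps", {
  set.seed(303)
  st <- random_stock(S = 3)
  ex <- random_exits(S = 3)
  pl <- random_pipeline(S = 3)
  im <- random_immigration(S = 3)
  cur <- st
  for (k in 1:5) {
    yr <- 2007 + k
    vec <- step_year(cur, ex, pl, im, year = yr)$stock
    ora <- oracle_step(cur, ex, pl, im, year = yr)
    expect_lt(max(abs(unclass(vec) - unclass(ora))), 1e-9)
    cur <- vec
  }
})

test_that("full-size 43x2x36 run over 18 years matches the scalar oracle", {
  set.seed(404)
  S <- 43
  st <- random_stock(S = S, scale = 200)
  ex <- random_exits(S = S)
  pl <- random_pipeline(S = S)
  im <- random_immigration(S = S)
  years <- 2008:2025
  traj <- simulate_supply(st, ex, pl, im, years)
  ora <- oracle_simulate(st, ex, pl, im, years)
  for (y in years) {
    expect_lt(max(abs(unclass(stock_at(traj, y)) -
                        unclass(ora[[as.character(y)]]))), 1e-9)
  }
})

test_that("negative net immigration may not drive a cell below zero", {
  st <- specialty_stock(specialties = "1")
  st["1", "female", "35"] <- 1
  ex <- exit_rates(retirement_age = Inf, specialties = "1")
  im <- immigration_flow(-500, sex_split = 1,
                         age_distribution = as.numeric(30:65 == 36),
                         specialties = "1")
  expect_error(step_year(st, ex, immigration = im, year = 2008),
               "emigration exceeds stock.*specialty=1")
})

test_that("missing or mis-sized rate tables are rejected", {
  st <- specialty_stock(specialties = c("1", "2"))
  ex_small <- exit_rates(specialties = "1")
  expect_error(step_year(st, ex_small, year = 2008), "cover every")
  expect_error(exit_rates(mortality = 1.2, specialties = "1"), "\\[0, 1\\]")
  expect_error(exit_rates(retirement_age = 30, specialties = "1"),
               "youngest")
})

test_that("fte_supply matches identities and a scalar loop", {
  st <- specialty_stock(specialties = "1")
  st["1", "female", "40"] <- 100
  st["1", "male", "40"] <- 100
  expect_equal(fte_supply(st, fte_ratio(1)), stock_total(st))
  fr <- fte_ratio(rbind(rep(0.8, 36), rep(1, 36)))
  expect_equal(fte_supply(st, fr), 180)

  set.seed(9)
  st2 <- random_stock(S = 3)
  ratio <- matrix(runif(72, 0.5, 1.2), 2, 36)
  got <- fte_supply(st2, fte_ratio(ratio))
  want <- 0
  for (s in 1:3) for (x in 1:2) for (a in 1:36) {
    want <- want + st2[s, x, a] * ratio[x, a]
  }
  expect_lt(abs(got - want), 1e-9)
  expect_error(fte_ratio(0), "positive")
})

test_that("supply declines faster from an old-heavy pyramid than a young one", {
  spec_old <- fixture_spec(n_specialties = 1, shapes = "old_heavy",
                           supply_target = 1000, seed = 5)
  spec_young <- fixture_spec(n_specialties = 1, shapes = "young_feminized",
                             supply_target = 1000, seed = 5)
  ex <- generate_rate_tables(spec_old)$exits
  years <- 2008:2025
  old_traj <- simulate_supply(generate_initial_stock(spec_old), ex,
                              years = years)
  young_traj <- simulate_supply(generate_initial_stock(spec_young), ex,
                                years = years)
  old_final <- sum(stock_at(old_traj, 2025))
  young_final <- sum(stock_at(young_traj, 2025))
  expect_lt(old_final, young_final)
})

test_that("raising retirement age, admissions or immigration never lowers supply", {
  set.seed(77)
  S <- 3
  st <- random_stock(S = S)
  ex <- random_exits(S = S, retirement_age = 63)
  pl <- random_pipeline(S = S)
  years <- 2008:2020
  totals <- function(traj) apply(traj$counts, 4, sum)

  base <- simulate_supply(st, ex, pl, years = years)
  higher_ra <- simulate_supply(st, ex, pl, years = years,
                               retirement_schedule = c("2008" = 66))
  expect_true(all(totals(higher_ra) - totals(base) >= -1e-12))

  pl_up <- pl
  pl_up$admissions <- pl$admissions * 1.5
  pl_up$warmup_value <- pl$warmup_value * 1.5
  more_adm <- simulate_supply(st, ex, pl_up, years = years)
  expect_true(all(totals(more_adm) - totals(base) >= -1e-12))

  im <- immigration_flow(rep(10, S), specialties = as.character(1:S))
  more_im <- simulate_supply(st, ex, pl, im, years = years)
  expect_true(all(totals(more_im) - totals(base) >= -1e-12))
})

test_that("an admissions shock propagates only after the training delay", {
  set.seed(88)
  S <- 3
  st <- random_stock(S = S)
  ex <- random_exits(S = S)
  pl <- training_pipeline(
    admissions = c("2000" = 1000),
    positions = rep(400, S), d_med = 6, d_res = 4,
    specialties = as.character(1:S))
  years <- 2008:2025
  base <- simulate_supply(st, ex, pl, years = years)
  pl2 <- pl
  pl2$admissions <- c("2000" = 1000, "2009" = 2000)
  shock <- simulate_supply(st, ex, pl2, years = years)
  # 2009 admissions first reach the stock in 2009 + 6 + 4 = 2019
  for (y in 2008:2018) {
    expect_identical(stock_at(shock, y), stock_at(base, y))
  }
  expect_gt(sum(stock_at(shock, 2019)), sum(stock_at(base, 2019)))
})
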