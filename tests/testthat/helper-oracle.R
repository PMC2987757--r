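# Independent scalar reference implementations: plain per-cell loops over
# (specialty, sex, age), no array vectorization. Used as oracles against the
# package's vectorized update.

oracle_training_inflow <- function(pipeline, year) {
  S <- length(pipeline$specialties)
  out <- matrix(0, S, 2L)
  for (s in seq_len(S)) {
    res_start <- year - pipeline$d_res[s]
    adm_year <- res_start - pipeline$d_med
    adm_years <- as.integer(names(pipeline$admissions))
    if (adm_year < adm_years[1]) {
      adm <- pipeline$warmup_value
    } else {
      adm <- unname(pipeline$admissions[[as.character(
        max(adm_years[adm_years <= adm_year]))]])
    }
    grads <- adm * pipeline$exam_pass
    pos_years <- as.integer(names(pipeline$positions))
    ok <- pos_years[pos_years <= res_start]
    pos <- if (length(ok)) pipeline$positions[[as.character(max(ok))]] else
      pipeline$positions[[1]]
    tot <- 0
    for (k in seq_len(S)) tot <- tot + pos[k]
    share <- if (tot > 0) pos[s] / tot else 0
    intake <- min(grads * share, pos[s])
    inflow <- intake * pipeline$completion[s]
    out[s, 1] <- inflow * pipeline$sex_split
    out[s, 2] <- inflow * (1 - pipeline$sex_split)
  }
  out
}

oracle_step <- function(stock, exits, pipeline = NULL, immigration = NULL,
                        year, retirement_age = NULL) {
  ages <- stock_ages(stock)
  S <- dim(stock)[1]; A <- dim(stock)[3]
  ra <- if (is.null(retirement_age)) exits$retirement_age else retirement_age
  new <- array(0, dim(stock), dimnames(stock))
  for (s in seq_len(S)) for (x in 1:2) for (a in seq_len(A)) {
    c0 <- stock[s, x, a]
    if (c0 == 0) next
    if (ages[a] >= ra) next                      # mandatory retirement
    m <- exits$mortality[x, a]
    d <- exits$dropout[s, x, a]
    e <- exits$early_retirement[x, a]
    surv <- c0 * (1 - m) * (1 - d) * (1 - e)
    if (a < A) new[s, x, a + 1] <- new[s, x, a + 1] + surv
    # occupants of the top age with retirement disabled age out
  }
  if (!is.null(pipeline)) {
    infl <- oracle_training_inflow(pipeline, year + 1)
    for (s in seq_len(S)) for (x in 1:2) for (a in seq_len(A)) {
      new[s, x, a] <- new[s, x, a] + infl[s, x] * pipeline$entry_age_dist[a]
    }
  }
  if (!is.null(immigration)) {
    yrs <- as.integer(names(immigration$net_entrants))
    ok <- yrs[yrs <= year + 1]
    net <- if (length(ok))
      immigration$net_entrants[[as.character(max(ok))]] else rep(0, S)
    sexw <- c(immigration$sex_split, 1 - immigration$sex_split)
    for (s in seq_len(S)) for (x in 1:2) for (a in seq_len(A)) {
      new[s, x, a] <- new[s, x, a] +
        net[s] * sexw[x] * immigration$age_distribution[a]
      if (new[s, x, a] < 0) new[s, x, a] <- 0
    }
  }
  specialty_stock(new, specialties = stock_specialties(stock), ages = ages)
}

oracle_simulate <- function(initial, exits, pipeline = NULL,
                            immigration = NULL, years,
                            retirement_schedule = NULL) {
  st <- initial
  out <- list()
  out[[as.character(years[1])]] <- st
  for (i in seq_along(years)[-1]) {
    ra <- NULL
    if (!is.null(retirement_schedule)) {
      yrs <- as.integer(names(retirement_schedule))
      ok <- yrs[yrs <= years[i - 1]]
      ra <- if (length(ok))
        unname(retirement_schedule[[as.character(max(ok))]]) else
        unname(retirement_schedule[[1]])
    }
    st <- oracle_step(st, exits, pipeline, immigration, year = years[i - 1],
                      retirement_age = ra)
    out[[as.character(years[i])]] <- st
  }
  out
}

# Random test instances -------------------------------------------------

random_stock <- function(S = 3, ages = 30:65, scale = 100) {
  st <- specialty_stock(specialties = as.character(seq_len(S)), ages = ages)
  st[] <- scale * stats::runif(length(st))
  st
}

random_exits <- function(S = 3, ages = 30:65, retirement_age = 65) {
  A <- length(ages)
  exit_rates(
    mortality = matrix(stats::runif(2 * A, 0, 0.02), 2, A),
    dropout = array(stats::runif(S * 2 * A, 0, 0.03), c(S, 2, A)),
    early_retirement = matrix(stats::runif(2 * A, 0, 0.01), 2, A),
    retirement_age = retirement_age,
    specialties = as.character(seq_len(S)), ages = ages)
}

random_pipeline <- function(S = 3, ages = 30:65) {
  training_pipeline(
    admissions = stats::setNames(round(stats::runif(3, 500, 1500)),
                                 c(2006, 2008, 2012)),
    positions = stats::setNames(
      list(round(stats::runif(S, 50, 300))), "2000"),
    d_res = sample(c(4L, 5L), S, replace = TRUE),
    exam_pass = 0.9, completion = stats::runif(S, 0.9, 1),
    sex_split = 2 / 3,
    specialties = as.character(seq_len(S)), ages = ages)
}

random_immigration <- function(S = 3, ages = 30:65) {
  immigration_flow(stats::runif(S, 0, 20), sex_split = 0.5,
                   specialties = as.character(seq_len(S)), ages = ages)
}

# A small runnable scenario used across engine tests.
small_scenario <- function(name = "test", S = 3, seed = 42,
                           horizon = c(2008, 2025), population = "moderate",
                           admissions = c("2008" = 600)) {
  spec <- fixture_spec(n_specialties = S, supply_target = 5000,
                       need_target = 5100, seed = seed)
  stock <- generate_initial_stock(spec)
  tables <- generate_rate_tables(spec)
  standards <- data.frame(
    specialty_id = as.character(seq_len(S)),
    base_ratio_per_100k = rep(5100 / S, S) * 1e5 /
      population_at(population_scenario("moderate",
                                        years = horizon[1]:horizon[2]),
                    horizon[1]),
    demand_group = rep(c("stable", "stable_increasing",
                         "sharply_increasing"), length.out = S),
    stringsAsFactors = FALSE)
  sched <- parameter_schedule(
    numerus_clausus = admissions,
    residency_positions = stats::setNames(list(rep(250, S)), "2000"),
    retirement_age = c("2008" = 65),
    fte = stats::setNames(list(tables$fte), "2008"))
  scenario(name = name, initial_stock = stock, exits = tables$exits,
           schedule = sched, standards = standards,
           population = population, horizon = horizon,
           pipeline_opts = list(sex_split = 2 / 3))
}
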