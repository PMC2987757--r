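#' Specification of a synthetic input fixture
#'
#' Describes a complete synthetic input set: how many specialties, the shape
#' family of each specialty's age pyramid, how feminized the young cohorts
#' are, and the aggregate calibration targets. The generated data are
#' synthetic stand-ins for a real specialist census: aggregates are
#' calibrated, per-specialty values are invented.
#'
#' Shape families capture the two poles observed in real registries:
#' `old_heavy` (traditional specialties: old pyramids, few women),
#' `young_feminized` (young pyramids, mostly women — two of every three new
#' doctors are women), and `uniform` in between.
#'
#' @param n_specialties number of specialties (default 43)
#' @param shapes character vector of length `n_specialties`, each
#'   `"old_heavy"`, `"uniform"` or `"young_feminized"`; default: one third
#'   of each, in that order
#' @param feminization fraction of new entrants who are women (default 2/3)
#' @param supply_target total base-year headcount to calibrate to
#' @param need_target total base-year need to calibrate to
#' @param seed integer RNG seed
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_specialties = 43, shapes = NULL,
                         feminization = 2 / 3,
                         supply_target = 141579, need_target = 144410,
                         seed = 1) {
  if (is.null(shapes)) {
    k <- ceiling(n_specialties / 3)
    shapes <- rep(c("old_heavy", "uniform", "young_feminized"),
                  times = c(k, k, n_specialties - 2 * k))
  }
  shapes <- rep_len(shapes, n_specialties)
  if (!all(shapes %in% c("old_heavy", "uniform", "young_feminized"))) {
    stop("shapes must be old_heavy, uniform or young_feminized")
  }
  if (supply_target <= 0 && n_specialties > 0) {
    stop("impossible calibration: supply_target must be > 0")
  }
  if (need_target <= 0 && n_specialties > 0) {
    stop("impossible calibration: need_target must be > 0")
  }
  structure(list(n_specialties = n_specialties, shapes = shapes,
                 feminization = feminization,
                 supply_target = supply_target, need_target = need_target,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Beta-density age profile per shape family, with a mild seeded jitter.
shape_age_weights <- function(shape, ages, jitter = c(1, 1)) {
  par <- switch(shape,
                old_heavy = c(6, 2),
                uniform = c(1, 1),
                young_feminized = c(2, 6))
  par <- par * jitter
  breaks <- seq(0, 1, length.out = length(ages) + 1L)
  w <- diff(stats::pbeta(breaks, par[1], par[2]))
  w / sum(w)
}

shape_female_share <- function(shape, u) {
  # u in [0,1): small seeded jitter inside the family's plausible band
  switch(shape,
         old_heavy = 0.25 + 0.10 * u,        # 0.25-0.35
         uniform = 0.45 + 0.10 * u,          # 0.45-0.55
         young_feminized = 0.60 + 0.10 * u)  # 0.60-0.70
}

#' Generate a calibrated synthetic initial stock
#'
#' Draws per-specialty sizes (Dirichlet-like, via gamma weights), builds
#' each specialty's age profile from its shape family's beta density, splits
#' sexes by the family's female share, and rescales so the total equals the
#' supply calibration target exactly. Reproducible given the seed.
#'
#' Shape contracts: `old_heavy` pyramids have mean age at least 50 and
#' `young_feminized` at most 42 with a female share of at least 0.55.
#'
#' @param spec a `fixture_spec`
#' @param ages ages covered, default `30:65`
#' @return a `specialty_stock` whose total equals `spec$supply_target`.
#' @export
generate_initial_stock <- function(spec, ages = 30:65) {
  stopifnot(inherits(spec, "fixture_spec"))
  S <- spec$n_specialties
  with_seed(spec$seed, {
    sizes <- stats::rgamma(S, shape = 5, rate = 1)
    sizes <- sizes / sum(sizes)
    jit <- matrix(stats::runif(2 * S, 0.95, 1.05), S, 2)
    ufem <- stats::runif(S)
    st <- specialty_stock(specialties = as.character(seq_len(S)),
                          ages = ages)
    for (s in seq_len(S)) {
      w <- shape_age_weights(spec$shapes[s], ages, jit[s, ])
      fs <- shape_female_share(spec$shapes[s], ufem[s])
      tot <- spec$supply_target * sizes[s]
      st[s, "female", ] <- tot * fs * w
      st[s, "male", ] <- tot * (1 - fs) * w
    }
    validate_stock(st)
  })
}

#' Generate synthetic exit-rate, FTE and immigration tables
#'
#' Mortality follows a Gompertz-type schedule
#' `m(age) = m0 * exp(beta * (age - 30))` for men, with female mortality a
#' fixed fraction of male mortality at every age (so female <= male
#' throughout). Drop-out is constant by sex, higher for women. FTE ratios
#' are below 1 for women, 1 for men. Immigration defaults to zero.
#'
#' @param spec a `fixture_spec`
#' @param m0 male mortality hazard at age 30 (default 5e-4)
#' @param beta Gompertz log-slope per year of age (default 0.09)
#' @param female_factor female/male mortality ratio (default 0.8)
#' @param dropout_female,dropout_male annual drop-out probabilities
#' @param fte_female,fte_male FTE conversion ratios
#' @param retirement_age mandatory retirement age (default 65)
#' @param ages ages covered
#' @return list with `exits` (an `exit_rates`), `fte` (an `fte_ratio`) and
#'   `immigration` (an `immigration_flow`).
#' @export
generate_rate_tables <- function(spec, m0 = 5e-4, beta = 0.09,
                                 female_factor = 0.8,
                                 dropout_female = 0.006,
                                 dropout_male = 0.003,
                                 fte_female = 0.9, fte_male = 1,
                                 retirement_age = 65, ages = 30:65) {
  stopifnot(inherits(spec, "fixture_spec"))
  male <- m0 * exp(beta * (ages - min(ages)))
  if (any(male * pmax(female_factor, 1) > 1)) {
    stop("mortality parameters produce rates above 1")
  }
  mort <- rbind(female = female_factor * male, male = male)
  drop <- rbind(female = rep(dropout_female, length(ages)),
                male = rep(dropout_male, length(ages)))
  specialties <- as.character(seq_len(spec$n_specialties))
  list(
    exits = exit_rates(mortality = mort, dropout = drop,
                       retirement_age = retirement_age,
                       specialties = specialties, ages = ages),
    fte = fte_ratio(rbind(rep(fte_female, length(ages)),
                          rep(fte_male, length(ages))), ages = ages),
    immigration = immigration_flow(0, specialties = specialties,
                                   ages = ages))
}

# Solve the demand-group need-share mix whose 17-year compounded factor
# matches `target_factor`, holding the stable and decreasing shares fixed.
solve_group_mix <- function(target_factor, rates = demand_group_rates(),
                            n_years = 17, w_stable = 0.15,
                            w_decreasing = 0.10) {
  f <- (1 + rates)^n_years
  free <- 1 - w_stable - w_decreasing
  rhs <- target_factor - w_stable * f[["stable"]] -
    w_decreasing * f[["decreasing"]]
  w1 <- (rhs - f[["stable_increasing"]] * free) /
    (f[["sharply_increasing"]] - f[["stable_increasing"]])
  w2 <- free - w1
  if (w1 < 0 || w2 < 0) {
    stop("target demand-growth factor ", signif(target_factor, 6),
         " is not attainable with the fixed stable/decreasing shares")
  }
  c(sharply_increasing = w1, stable_increasing = w2,
    stable = w_stable, decreasing = w_decreasing)
}

#' Generate a calibrated, Spain-like baseline scenario
#'
#' A complete synthetic baseline emulating the published aggregate anchors:
#' base-year (2008) total supply 141,579 and total need 144,410 (a 2.0%
#' deficit, 319 specialists per 100,000), a moderate population path through
#' the 2008/2015/2025 census anchors, and a demand-group mix solved so that
#' aggregate need reaches the 173,918 anchor by 2025. Per-specialty values
#' are synthetic; only the aggregates are calibrated.
#'
#' The baseline schedule holds all policy parameters constant: 7,000
#' medical-school admissions per year (with pre-2008 warm-up cohorts at the
#' same level), residency positions distributed proportionally to specialty
#' size, mandatory retirement at 65, no net immigration.
#'
#' @param seed integer seed for the synthetic fixture draws (the simulation
#'   itself is deterministic)
#' @param n_specialties number of specialties (default 43)
#' @param horizon simulated year range, default `c(2008, 2025)`
#' @return a `scenario` ready for [run_scenario()].
#' @examples
#' res <- run_scenario(generate_spain_like_scenario(seed = 1))
#' summary(res, years = c(2008, 2015, 2025))
#' @export
generate_spain_like_scenario <- function(seed = 1, n_specialties = 43,
                                         horizon = c(2008, 2025)) {
  spec <- fixture_spec(n_specialties = n_specialties, seed = seed)
  stock <- generate_initial_stock(spec)
  tables <- generate_rate_tables(spec)
  pop <- population_scenario("moderate", years = horizon[1]:horizon[2])

  # demand-group mix reproducing the 2025 need anchor
  p0 <- population_at(pop, 2008)
  need_factor <- (173918 / 144410) / (48018184 / 44366332)
  w <- solve_group_mix(need_factor, n_years = 17)
  groups <- names(demand_group_rates())
  n_per <- pmax(1L, round(unname(w) * n_specialties))
  # adjust rounding so the group sizes sum to n_specialties
  while (sum(n_per) != n_specialties) {
    i <- if (sum(n_per) > n_specialties) which.max(n_per) else which.min(n_per)
    n_per[i] <- n_per[i] + sign(n_specialties - sum(n_per))
  }
  group_of <- rep(groups, times = n_per)
  base_need <- spec$need_target * rep(unname(w) / n_per, times = n_per)
  standards <- data.frame(
    specialty_id = as.character(seq_len(n_specialties)),
    base_ratio_per_100k = base_need * 1e5 / p0,
    demand_group = group_of,
    stringsAsFactors = FALSE)

  sizes <- stock_total(stock, by = "specialty")
  positions <- 7000 * sizes / sum(sizes)
  d_res <- rep(4L, n_specialties)
  d_res[seq_len(n_specialties) %% 3L == 0L] <- 5L

  sched <- parameter_schedule(
    numerus_clausus = c("2008" = 7000),
    residency_positions = stats::setNames(list(unname(positions)), "2008"),
    retirement_age = c("2008" = 65),
    fte = stats::setNames(list(tables$fte), "2008"))

  scenario(name = paste0("spain-like baseline (seed ", seed, ")"),
           initial_stock = stock, exits = tables$exits, schedule = sched,
           standards = standards, population = pop, horizon = horizon,
           pipeline_opts = list(d_res = d_res,
                                sex_split = spec$feminization),
           immigration_opts = list())
}
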