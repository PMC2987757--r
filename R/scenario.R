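#' Per-year schedule of the policy-controllable parameters
#'
#' The planner's levers, each settable per calendar year: medical-school
#' admissions (numerus clausus), residency positions per specialty, the
#' mandatory retirement age, the full-time-equivalent conversion ratio, and
#' net immigration per specialty. Schedules use carry-forward semantics: a
#' value set in year `y` holds for every later year until overridden, which
#' matches the baseline convention that parameters remain at their current
#' values, and keeps configurations short.
#'
#' @param numerus_clausus named numeric vector (`year -> admissions`)
#' @param residency_positions residency positions per specialty: named list
#'   (`year -> numeric[S]`), a single `numeric[S]` for all years, or a
#'   scalar total split equally
#' @param retirement_age named numeric vector (`year -> age`), or a scalar
#' @param fte num or named list (`year ->` scalar or `2 x A` matrix) of FTE
#'   conversion ratios
#' @param immigration named list (`year -> numeric[S]` net entrants), a
#'   single vector for all years, or a scalar per specialty
#' @param demand_rates optional named numeric vector overriding the default
#'   demand-group annual rates (see [demand_group_rates()]); applies to the
#'   whole horizon
#' @param carry_forward if `FALSE`, validation requires an explicit value of
#'   every scheduled parameter for every simulated year
#' @return object of class `parameter_schedule`.
#' @export
parameter_schedule <- function(numerus_clausus, residency_positions,
                               retirement_age = 65, fte = 1,
                               immigration = NULL, demand_rates = NULL,
                               carry_forward = TRUE) {
  numerus_clausus <- as_year_vector(numerus_clausus, "numerus_clausus")
  if (any(numerus_clausus < 0)) stop("numerus_clausus must be >= 0")
  retirement_age <- as_year_vector(retirement_age, "retirement_age")
  if (!is.list(fte)) fte <- stats::setNames(list(fte), "0")
  if (!is.null(demand_rates)) {
    bad <- setdiff(names(demand_rates), names(demand_group_rates()))
    if (length(bad)) {
      stop("unknown demand group(s) in demand_rates: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(list(numerus_clausus = numerus_clausus,
                 residency_positions = residency_positions,
                 retirement_age = retirement_age,
                 fte = fte, immigration = immigration,
                 demand_rates = demand_rates,
                 carry_forward = isTRUE(carry_forward)),
            class = "parameter_schedule")
}

as_year_vector <- function(x, what) {
  if (is.null(names(x))) {
    if (length(x) != 1L) stop("`", what, "` must be named by year or scalar")
    names(x) <- "0"
  }
  x[order(as.integer(names(x)))]
}

#' @export
print.parameter_schedule <- function(x, ...) {
  cat("<parameter_schedule>\n")
  cat("  numerus_clausus:", paste(x$numerus_clausus, collapse = ", "),
      "(years", paste(names(x$numerus_clausus), collapse = ", "), ")\n")
  cat("  retirement_age:", paste(x$retirement_age, collapse = ", "), "\n")
  cat("  carry_forward:", x$carry_forward, "\n")
  invisible(x)
}

#' A complete, runnable projection scenario
#'
#' Binds everything one run needs: the initial age-sex stocks, the exit-rate
#' tables, the policy schedule, the need standards and the population path.
#' Runs are fully deterministic: rerunning a scenario reproduces its results
#' bit for bit.
#'
#' @param name scenario name
#' @param initial_stock a `specialty_stock` describing the base year
#' @param exits an `exit_rates` (its retirement age may be overridden per
#'   year by the schedule)
#' @param schedule a `parameter_schedule`
#' @param standards need standards: data.frame with `specialty_id`,
#'   `base_ratio_per_100k`, `demand_group`
#' @param population a `population_scenario` or one of its labels
#'   (`"moderate"`, `"rapid"`, `"slow"`)
#' @param horizon length-2 integer vector, first and last simulated year
#' @param pipeline_opts list of training-pipeline settings: `d_med`, `d_res`,
#'   `exam_pass`, `completion`, `sex_split`, `entry_age_dist`, `warmup`,
#'   `warmup_value` (see [training_pipeline()])
#' @param immigration_opts list with `sex_split` and `age_distribution`
#'   (see [immigration_flow()])
#' @return object of class `scenario`.
#' @export
scenario <- function(name, initial_stock, exits, schedule, standards,
                     population = "moderate", horizon = c(2008, 2025),
                     pipeline_opts = list(), immigration_opts = list()) {
  horizon <- as.integer(horizon)
  if (length(horizon) != 2L || horizon[2] < horizon[1]) {
    stop("horizon must be c(first_year, last_year)")
  }
  if (is.character(population)) {
    population <- population_scenario(population,
                                      years = horizon[1]:horizon[2])
  }
  sc <- structure(list(name = name, initial_stock = initial_stock,
                       exits = exits, schedule = schedule,
                       standards = standards, population = population,
                       horizon = horizon,
                       pipeline_opts = pipeline_opts,
                       immigration_opts = immigration_opts),
                  class = "scenario")
  sc
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> '", x$name, "', ", x$horizon[1], "-", x$horizon[2], ", ",
      dim(x$initial_stock)[1], " specialties, population '",
      x$population$label, "'\n", sep = "")
  invisible(x)
}

# Assemble the pipeline / immigration objects a scenario implies.
build_pipeline <- function(sc) {
  po <- sc$pipeline_opts
  args <- list(admissions = sc$schedule$numerus_clausus,
               positions = sc$schedule$residency_positions,
               specialties = stock_specialties(sc$initial_stock),
               ages = stock_ages(sc$initial_stock))
  do.call(training_pipeline, c(args, po))
}

build_immigration <- function(sc) {
  if (is.null(sc$schedule$immigration)) return(NULL)
  io <- sc$immigration_opts
  args <- list(net_entrants = sc$schedule$immigration,
               specialties = stock_specialties(sc$initial_stock),
               ages = stock_ages(sc$initial_stock))
  do.call(immigration_flow, c(args, io))
}

scenario_rates <- function(sc) {
  rates <- demand_group_rates()
  ov <- sc$schedule$demand_rates
  if (!is.null(ov)) rates[names(ov)] <- ov
  rates
}

fte_for_year <- function(sc, year) {
  val <- schedule_value_list(sc$schedule$fte, year)
  if (inherits(val, "fte_ratio")) return(val)
  fte_ratio(val, ages = stock_ages(sc$initial_stock))
}

schedule_value_list <- function(lst, year) {
  yrs <- as.integer(names(lst))
  ok <- yrs[yrs <= year]
  if (length(ok) == 0L) return(lst[[1L]])
  lst[[as.character(max(ok))]]
}

#' Run a scenario
#'
#' Simulates the supply trajectory over the horizon, evaluates the need
#' trajectory of every specialty, and derives the headline outputs per
#' specialty and year: headcount and FTE supply, need, deficit (headcount
#' and as a fraction of supply), the ratio per 100,000 inhabitants, the
#' percentage of women and the percentage under 51 years of age, plus the
#' aggregate over all specialties.
#'
#' @param sc a `scenario`
#' @param fte_deficit if `TRUE`, deficit columns compare FTE supply (rather
#'   than headcount) with need
#' @return object of class `scenario_result` with elements `name`, `years`,
#'   `trajectory` (the full `supply_trajectory`, pyramids recoverable for
#'   any specialty and year via [stock_at()]), `table` (long per-specialty
#'   data.frame), `aggregate` (per-year data.frame) and `population`.
#' @examples
#' sc <- generate_spain_like_scenario(seed = 1)
#' res <- run_scenario(sc)
#' summary(res)
#' @export
run_scenario <- function(sc, fte_deficit = FALSE) {
  rep <- validate_scenario(sc)
  stop_on_errors(rep)
  years <- sc$horizon[1]:sc$horizon[2]
  pipeline <- build_pipeline(sc)
  immigration <- build_immigration(sc)
  traj <- simulate_supply(sc$initial_stock, sc$exits, pipeline, immigration,
                          years,
                          retirement_schedule = sc$schedule$retirement_age)
  specialties <- stock_specialties(sc$initial_stock)
  ages <- stock_ages(sc$initial_stock)
  rates <- scenario_rates(sc)
  standards <- as_standard_list(sc$standards)
  std_by_id <- stats::setNames(standards,
                               vapply(standards, `[[`, "", "specialty"))
  missing_std <- setdiff(specialties, names(std_by_id))
  if (length(missing_std)) {
    stop("no need standard for specialty(ies): ",
         paste(missing_std, collapse = ", "))
  }
  base_year <- sc$horizon[1]
  pop <- population_at(sc$population, years)

  need_mat <- vapply(specialties, function(s) {
    need_trajectory(std_by_id[[s]], sc$population, base_year = base_year,
                    years = years, rates = rates)
  }, numeric(length(years)))
  if (is.null(dim(need_mat))) need_mat <- matrix(need_mat, nrow = 1L)
  # need_mat: years x specialties

  nY <- length(years); nS <- length(specialties)
  supply_head <- matrix(0, nY, nS)
  supply_fte <- matrix(0, nY, nS)
  pctw <- matrix(NA_real_, nY, nS)
  pctu <- matrix(NA_real_, nY, nS)
  for (i in seq_len(nY)) {
    st_i <- stock_at(traj, years[i])
    fte_i <- fte_for_year(sc, years[i])
    supply_head[i, ] <- stock_total(st_i, by = "specialty")
    supply_fte[i, ] <- fte_supply(st_i, fte_i, by = "specialty")
    by_sex <- apply(unclass(st_i), c(1L, 2L), sum)
    under <- apply(unclass(st_i)[, , ages <= 50, drop = FALSE], 1L, sum)
    tot_s <- supply_head[i, ]
    pctw[i, ] <- ifelse(tot_s > 0, by_sex[, "female"] / tot_s, NA_real_)
    pctu[i, ] <- ifelse(tot_s > 0, under / tot_s, NA_real_)
  }

  sup_for_def <- if (fte_deficit) supply_fte else supply_head
  deficit_head <- sup_for_def - need_mat
  deficit_pct <- ifelse(sup_for_def > 0, deficit_head / sup_for_def,
                        NA_real_)

  table <- data.frame(
    scenario = sc$name,
    specialty = rep(specialties, each = nY),
    year = rep(years, nS),
    supply_head = as.vector(supply_head),
    supply_fte = as.vector(supply_fte),
    need = as.vector(need_mat),
    deficit_head = as.vector(deficit_head),
    deficit_pct = as.vector(deficit_pct),
    ratio_per_100k = as.vector(supply_head / rep(pop, nS) * 1e5),
    pct_women = as.vector(pctw),
    pct_under_51 = as.vector(pctu),
    stringsAsFactors = FALSE)

  agg_sup <- rowSums(supply_head)
  agg_fte <- rowSums(supply_fte)
  agg_need <- rowSums(need_mat)
  agg_def_base <- if (fte_deficit) agg_fte else agg_sup
  aggregate <- data.frame(
    scenario = sc$name,
    year = years,
    population = pop,
    supply_head = agg_sup,
    supply_fte = agg_fte,
    need = agg_need,
    deficit_head = agg_def_base - agg_need,
    deficit_pct = ifelse(agg_def_base > 0,
                         (agg_def_base - agg_need) / agg_def_base, NA_real_),
    ratio_per_100k = agg_sup / pop * 1e5,
    pct_women = rowSums(supply_head * pctw) / agg_sup,
    pct_under_51 = rowSums(supply_head * pctu) / agg_sup,
    stringsAsFactors = FALSE)

  structure(list(name = sc$name, years = years, specialties = specialties,
                 trajectory = traj, table = table, aggregate = aggregate,
                 population = sc$population, fte_deficit = fte_deficit,
                 scenario = sc),
            class = "scenario_result")
}

#' Compare scenarios against a reference
#'
#' Aligns the aggregate metrics of two or more scenario results (or
#' scenarios, which are run first) and reports, in long format, each
#' scenario's value and its difference from the first (reference) scenario.
#'
#' @param scenarios list of `scenario` or `scenario_result` objects sharing
#'   one horizon; the first is the reference
#' @param metrics aggregate metrics to compare
#' @return data.frame with columns `metric`, `year`, `scenario`, `value`,
#'   `diff_vs_ref`.
#' @export
compare_scenarios <- function(scenarios,
                              metrics = c("supply_head", "supply_fte",
                                          "need", "deficit_head",
                                          "deficit_pct", "ratio_per_100k")) {
  if (length(scenarios) < 2L) stop("need at least 2 scenarios to compare")
  results <- lapply(scenarios, function(s) {
    if (inherits(s, "scenario_result")) s else run_scenario(s)
  })
  yrs <- results[[1L]]$years
  for (r in results[-1L]) {
    if (!identical(r$years, yrs)) {
      stop("scenarios have mismatched horizons: ",
           paste(range(yrs), collapse = "-"), " vs ",
           paste(range(r$years), collapse = "-"))
    }
  }
  nm <- vapply(results, `[[`, "", "name")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  out <- do.call(rbind, lapply(seq_along(results), function(i) {
    agg <- results[[i]]$aggregate
    do.call(rbind, lapply(metrics, function(m) {
      data.frame(metric = m, year = yrs, scenario = nm[i],
                 value = agg[[m]],
                 diff_vs_ref = agg[[m]] - results[[1L]]$aggregate[[m]],
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

# Schedulable parameter names accepted by sweep_parameter.
sweepable_parameters <- function() {
  c("numerus_clausus", "residency_positions", "retirement_age", "fte",
    "immigration", "demand_rate")
}

#' Sweep one parameter over a set of values
#'
#' Sensitivity analysis: reruns a scenario once per value, holding the
#' parameter constant over the whole horizon at that value. The input
#' scenario is left unmodified.
#'
#' @param sc a `scenario`
#' @param parameter one of `"numerus_clausus"`, `"residency_positions"`,
#'   `"retirement_age"`, `"fte"`, `"immigration"`, `"demand_rate"`
#'   (`demand_rate` sets every demand group's annual rate to the value)
#' @param values vector (or list, for vector-valued parameters) of values
#' @return named list of `scenario_result`, one per value, in order.
#' @export
sweep_parameter <- function(sc, parameter, values) {
  if (!parameter %in% sweepable_parameters()) {
    stop("unknown parameter '", parameter, "'; valid names: ",
         paste(sweepable_parameters(), collapse = ", "))
  }
  if (length(values) == 0L) return(stats::setNames(list(), character()))
  vals <- if (is.list(values)) values else as.list(values)
  out <- lapply(vals, function(v) {
    sc2 <- sc
    sc2$schedule <- set_schedule_parameter(sc$schedule, parameter, v)
    sc2$name <- paste0(sc$name, " [", parameter, "=",
                       paste(signif(unlist(v), 6), collapse = ","), "]")
    run_scenario(sc2)
  })
  names(out) <- vapply(vals, function(v)
    paste(signif(unlist(v), 6), collapse = ","), "")
  out
}

set_schedule_parameter <- function(sched, parameter, value) {
  if (parameter == "demand_rate") {
    sched$demand_rates <- stats::setNames(
      rep(as.numeric(value), length(demand_group_rates())),
      names(demand_group_rates()))
  } else if (parameter == "residency_positions") {
    sched$residency_positions <- value
  } else if (parameter == "immigration") {
    sched$immigration <- if (is.list(value)) value else
      stats::setNames(list(value), "0")
  } else if (parameter == "fte") {
    sched$fte <- if (is.list(value)) value else
      stats::setNames(list(value), "0")
  } else {
    v <- value
    if (is.null(names(v))) names(v) <- "0"
    sched[[parameter]] <- v
  }
  sched
}
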