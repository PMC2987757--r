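#' Default demand-group growth rates
#'
#' Specialties are assigned by expert judgement to one of four demand groups,
#' each with an annual per-capita growth rate of its specialists-per-100,000
#' need ratio. Defaults follow the published planning rates: sharply
#' increasing +1.3%/yr, stable/increasing +0.6%/yr, stable 0%/yr, decreasing
#' -0.6%/yr. Over the 17 years of a 2008-2025 horizon these compound to
#' +24.6%, +10.7%, 0% and -9.7%.
#'
#' @return named numeric vector of annual rates keyed by group label.
#' @export
demand_group_rates <- function() {
  c(sharply_increasing = 0.013,
    stable_increasing = 0.006,
    stable = 0.0,
    decreasing = -0.006)
}

#' Cumulative growth over a number of years
#'
#' Geometric compounding: `(1 + annual_rate)^n_years - 1`. This is the
#' conversion behind planning tables that print an annual per-capita rate
#' next to its cumulative horizon growth (e.g. 0.6%/yr over 17 years is
#' +10.7%).
#'
#' @param annual_rate annual growth rate (must exceed -1)
#' @param n_years non-negative integer number of years
#' @return cumulative growth as a fraction.
#' @examples
#' cumulative_growth(0.006, 17) # 0.1070
#' cumulative_growth(0.013, 17) # 0.2455
#' @export
cumulative_growth <- function(annual_rate, n_years) {
  if (any(annual_rate <= -1)) stop("annual_rate must exceed -1")
  if (any(n_years < 0)) stop("n_years must be >= 0")
  (1 + annual_rate)^n_years - 1
}

# Default population anchors. The moderate path is the published baseline
# (2008/2015/2025 census projections); the rapid path extends the fast
# immigration-driven growth of the five years before 2008 and the slow path
# a near-stagnant projection. Intermediate years are interpolated
# geometrically, so the anchors are reproduced exactly.
default_population_anchors <- function() {
  list(
    moderate = c("2008" = 44366332, "2015" = 46333661, "2025" = 48018184),
    rapid    = c("2008" = 44366332, "2025" = 49888525),
    slow     = c("2008" = 44366332, "2025" = 46211959)
  )
}

#' Population scenario: inhabitants per simulation year
#'
#' A demographic path for the projection horizon. The bundled scenarios are
#' `moderate` (the baseline census projection through its 2008, 2015 and
#' 2025 anchors), `rapid` and `slow`. Years between anchors are interpolated
#' geometrically (constant annual growth between consecutive anchors), which
#' preserves ordering and reproduces the anchors exactly. A fully custom
#' path can be supplied via `population`.
#'
#' @param label one of `"moderate"`, `"rapid"`, `"slow"` (ignored when
#'   `population` is given, except as the scenario's name)
#' @param years simulation years, default `2008:2025`
#' @param anchors optional named numeric vector (`year -> inhabitants`)
#'   replacing the bundled anchors for `label`
#' @param population optional full named vector (`year -> inhabitants`)
#'   covering every year; takes precedence over anchors
#' @return object of class `population_scenario` with elements `label`,
#'   `years`, `population`.
#' @examples
#' ps <- population_scenario("moderate")
#' population_at(ps, 2008) # 44366332
#' @export
population_scenario <- function(label = c("moderate", "rapid", "slow"),
                                years = 2008:2025, anchors = NULL,
                                population = NULL) {
  years <- as.integer(years)
  if (is.null(population)) {
    label <- match.arg(label)
    if (is.null(anchors)) anchors <- default_population_anchors()[[label]]
    population <- interpolate_geometric(anchors, years)
  } else {
    label <- if (is.character(label)) label[1L] else "custom"
    if (is.null(names(population))) names(population) <- years
    missing <- setdiff(as.character(years), names(population))
    if (length(missing)) {
      stop("population path missing years: ", paste(missing, collapse = ", "))
    }
    population <- population[as.character(years)]
  }
  if (any(population <= 0)) stop("population must be > 0 for all years")
  structure(list(label = label, years = years, population = population),
            class = "population_scenario")
}

# Piecewise-geometric interpolation through (year, value) anchors; constant
# growth is extrapolated beyond the outermost anchors.
interpolate_geometric <- function(anchors, years) {
  ay <- as.integer(names(anchors))
  ord <- order(ay); ay <- ay[ord]; av <- unname(anchors[ord])
  if (length(ay) == 1L) {
    return(stats::setNames(rep(av, length(years)), years))
  }
  out <- stats::setNames(numeric(length(years)), years)
  for (i in seq_along(years)) {
    y <- years[i]
    if (y <= ay[1L]) {
      r <- (av[2L] / av[1L])^(1 / (ay[2L] - ay[1L]))
      out[i] <- av[1L] * r^(y - ay[1L])
    } else if (y >= ay[length(ay)]) {
      k <- length(ay)
      r <- (av[k] / av[k - 1L])^(1 / (ay[k] - ay[k - 1L]))
      out[i] <- av[k] * r^(y - ay[k])
    } else {
      k <- max(which(ay <= y))
      r <- (av[k + 1L] / av[k])^(1 / (ay[k + 1L] - ay[k]))
      out[i] <- av[k] * r^(y - ay[k])
    }
  }
  out
}

#' @export
print.population_scenario <- function(x, ...) {
  cat("<population_scenario> '", x$label, "', ", min(x$years), "-",
      max(x$years), ", ", format(round(x$population[1]), big.mark = " "),
      " -> ",
      format(round(x$population[length(x$population)]), big.mark = " "),
      "\n", sep = "")
  invisible(x)
}

#' Population of a scenario in a given year
#' @param scenario a `population_scenario`
#' @param year calendar year (must be covered)
#' @return inhabitants in that year
#' @export
population_at <- function(scenario, year) {
  i <- match(as.integer(year), scenario$years)
  if (any(is.na(i))) {
    stop("population scenario '", scenario$label, "' does not cover year(s) ",
         paste(year[is.na(i)], collapse = ", "))
  }
  unname(scenario$population[i])
}

#' Normative need standard of one specialty
#'
#' A base-year specialists-per-100,000-inhabitants ratio plus the demand
#' group whose annual rate drives its evolution.
#'
#' @param specialty specialty id
#' @param base_ratio specialists per 100,000 inhabitants in the base year
#'   (must be > 0)
#' @param group demand-group label (see [demand_group_rates()])
#' @return object of class `need_standard`.
#' @export
need_standard <- function(specialty, base_ratio,
                          group = c("stable", "sharply_increasing",
                                    "stable_increasing", "decreasing")) {
  group <- match.arg(group)
  if (base_ratio <= 0) stop("base_ratio must be > 0")
  structure(list(specialty = as.character(specialty),
                 base_ratio = base_ratio, group = group),
            class = "need_standard")
}

#' Need trajectory of one specialty
#'
#' `Need(t) = base_ratio x (1 + g)^(t - base_year) x P(t) / 100000`, where
#' `g` is the specialty's demand-group annual rate and `P(t)` the scenario
#' population. At the base year this is exactly `base_ratio x P / 100000`.
#'
#' @param standard a `need_standard`
#' @param scenario a `population_scenario`
#' @param base_year base year of the standard
#' @param years years to evaluate (default: the scenario's years)
#' @param rates demand-group rate table (label -> annual rate); override to
#'   re-run under different growth assumptions
#' @return named numeric vector of need headcounts per year.
#' @export
need_trajectory <- function(standard, scenario, base_year = 2008,
                            years = scenario$years,
                            rates = demand_group_rates()) {
  if (!inherits(standard, "need_standard")) {
    stop("`standard` must be a need_standard")
  }
  g <- rates[[standard$group]]
  if (is.null(g)) stop("no rate for demand group '", standard$group, "'")
  p <- population_at(scenario, years)
  stats::setNames(
    standard$base_ratio * (1 + g)^(years - base_year) * p / 1e5,
    years)
}

#' Total need across specialties
#'
#' @param standards a list of `need_standard`s, or a data.frame with columns
#'   `specialty_id`, `base_ratio_per_100k`, `demand_group`
#' @param scenario a `population_scenario`
#' @param years years to evaluate
#' @param base_year base year of the standards
#' @param rates demand-group rate table
#' @return named numeric vector: summed need headcount per year.
#' @export
total_need <- function(standards, scenario, years = scenario$years,
                       base_year = 2008, rates = demand_group_rates()) {
  standards <- as_standard_list(standards)
  if (length(standards) == 0L) stop("`standards` must not be empty")
  Reduce(`+`, lapply(standards, need_trajectory, scenario = scenario,
                     base_year = base_year, years = years, rates = rates))
}

# Accept either a list of need_standard or the CSV-shaped data.frame.
as_standard_list <- function(standards) {
  if (is.data.frame(standards)) {
    need <- c("specialty_id", "base_ratio_per_100k", "demand_group")
    if (!all(need %in% names(standards))) {
      stop("standards data.frame must have columns: ",
           paste(need, collapse = ", "))
    }
    standards <- lapply(seq_len(nrow(standards)), function(i) {
      need_standard(standards$specialty_id[i],
                    standards$base_ratio_per_100k[i],
                    standards$demand_group[i])
    })
  }
  if (!all(vapply(standards, inherits, TRUE, "need_standard"))) {
    stop("`standards` must be need_standard objects or a standards data.frame")
  }
  standards
}

#' Read need standards from CSV
#' @param path CSV with columns `specialty_id`, `base_ratio_per_100k`,
#'   `demand_group`
#' @return the standards data.frame (validated)
#' @export
read_standards_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_standard_list(df) # validates
  df
}
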