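#' Deficit/surplus fraction of supply relative to need
#'
#' `(supply - need) / supply`: negative values are deficits (need exceeds
#' supply), positive values surpluses. The divisor is supply, the convention
#' under which a 141,579-strong supply facing a need of 144,410 is a 2.0%
#' deficit.
#'
#' @param supply specialist headcount (or FTE), must be > 0
#' @param need needed specialists on the same scale
#' @return signed fraction; `deficit_fraction(s, s) == 0`.
#' @examples
#' deficit_fraction(141579, 144410) # -0.0200
#' @export
deficit_fraction <- function(supply, need) {
  if (any(supply <= 0)) stop("supply must be > 0 to express a deficit fraction")
  (supply - need) / supply
}

#' Specialists per 100,000 inhabitants
#'
#' @param supply specialist headcount
#' @param population inhabitants, must be > 0
#' @return `supply x 100000 / population`. Homogeneous of degree zero:
#'   scaling supply and population together leaves it unchanged.
#' @examples
#' ratio_per_100k(141579, 44366332) # 319.1
#' @export
ratio_per_100k <- function(supply, population) {
  if (any(population <= 0)) stop("population must be > 0")
  supply * 1e5 / population
}

#' Demographic pyramid summaries of one specialty
#'
#' The standard workforce-ageing indicators: share of women, share under 51
#' years of age (attained age 50 or less), and the full age-sex pyramid
#' table.
#'
#' @param stock a `specialty_stock`
#' @param specialty specialty id to summarise; `NULL` (default) pools all
#'   specialties
#' @return list with `pct_women`, `pct_under_51`, `mean_age`, `total`, and
#'   `pyramid` (data.frame sex, age, count). Errors on an empty stock rather
#'   than returning silent zeros: the fractions are undefined.
#' @export
pyramid_summaries <- function(stock, specialty = NULL) {
  x <- unclass(stock)
  if (!is.null(specialty)) {
    specialty <- as.character(specialty)
    if (!specialty %in% stock_specialties(stock)) {
      stop("unknown specialty '", specialty, "'")
    }
    x <- x[specialty, , , drop = FALSE]
  }
  ages <- stock_ages(stock)
  tot <- sum(x)
  if (tot <= 0) {
    stop("empty stock", if (!is.null(specialty))
      paste0(" for specialty '", specialty, "'") else "",
      ": pyramid fractions are undefined")
  }
  by_sex_age <- apply(x, c(2L, 3L), sum) # 2 x A
  pct_women <- sum(by_sex_age["female", ]) / tot
  pct_under_51 <- sum(by_sex_age[, ages <= 50]) / tot
  mean_age <- sum(t(by_sex_age) * ages) / tot
  pyramid <- data.frame(
    sex = rep(c("female", "male"), each = length(ages)),
    age = rep(ages, 2L),
    count = c(by_sex_age["female", ], by_sex_age["male", ]))
  list(pct_women = pct_women, pct_under_51 = pct_under_51,
       mean_age = mean_age, total = tot, pyramid = pyramid)
}

#' Rank specialties by deficit severity
#'
#' Orders the per-specialty deficit fractions of a scenario result for one
#' year, most severe deficit first. Ties are broken by specialty id
#' (ascending), and the sort is stable.
#'
#' @param result a `scenario_result` (see [run_scenario()])
#' @param year year to rank
#' @return data.frame (specialty, supply_head, need, deficit_pct) ordered by
#'   `deficit_pct` ascending.
#' @export
rank_specialties <- function(result, year) {
  if (!inherits(result, "scenario_result")) {
    stop("`result` must be a scenario_result")
  }
  tab <- result$table[result$table$year == as.integer(year), , drop = FALSE]
  if (nrow(tab) == 0L) stop("year ", year, " not present in the result")
  ord <- order(tab$deficit_pct,
               suppressWarnings(as.numeric(tab$specialty)), tab$specialty)
  out <- tab[ord, c("specialty", "supply_head", "need", "deficit_pct")]
  rownames(out) <- NULL
  out
}
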