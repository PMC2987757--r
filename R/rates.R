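#' Exit-rate tables: mortality, drop-out, retirement
#'
#' Bundles the outflow components applied within each annual step: mortality
#' by sex and age, professional drop-out by specialty, sex and age, an
#' optional early-retirement rate, and the mandatory retirement age. Within a
#' year the order is fixed: mandatory retirement first, then mortality,
#' drop-out and early retirement applied multiplicatively to the survivors.
#'
#' @param mortality per-year probability of death: a scalar, or a `2 x A`
#'   matrix (rows `female`, `male`; columns ages).
#' @param dropout per-year probability of leaving the profession: a scalar, a
#'   `2 x A` matrix applied to every specialty, or a full `S x 2 x A` array.
#' @param retirement_age mandatory retirement age: every cell at age
#'   `>= retirement_age` exits at the start of the step. Use `Inf` to disable.
#' @param early_retirement optional per-year probability of retiring before
#'   the mandatory age; scalar or `2 x A` matrix. Default 0.
#' @param specialties,ages index sets the tables must cover (used to expand
#'   scalars and to validate matrices).
#' @return an object of class `exit_rates` with elements `mortality`
#'   (`2 x A`), `dropout` (`S x 2 x A`), `early_retirement` (`2 x A`) and
#'   `retirement_age`.
#' @examples
#' ex <- exit_rates(mortality = 0.002, dropout = 0.004, retirement_age = 65,
#'                  specialties = as.character(1:3))
#' @export
exit_rates <- function(mortality = 0, dropout = 0, retirement_age = 65,
                       early_retirement = 0,
                       specialties = as.character(1:43), ages = 30:65) {
  specialties <- as.character(specialties)
  S <- length(specialties); A <- length(ages)
  sexes <- c("female", "male")
  m <- expand_sex_age(mortality, sexes, ages, "mortality")
  e <- expand_sex_age(early_retirement, sexes, ages, "early_retirement")
  d <- expand_dropout(dropout, specialties, sexes, ages)
  for (nm in c("mortality", "dropout", "early_retirement")) {
    v <- switch(nm, mortality = m, dropout = d, early_retirement = e)
    if (any(v < 0) || any(v > 1)) stop(nm, " rates must lie in [0, 1]")
  }
  if (!is.infinite(retirement_age)) {
    retirement_age <- as.numeric(retirement_age)
    if (retirement_age <= min(ages)) {
      stop("retirement_age must exceed the youngest modelled age (",
           min(ages), ")")
    }
  }
  structure(list(mortality = m, dropout = d, early_retirement = e,
                 retirement_age = retirement_age,
                 specialties = specialties, ages = as.integer(ages)),
            class = "exit_rates")
}

expand_sex_age <- function(x, sexes, ages, what) {
  A <- length(ages)
  if (length(x) == 1L) x <- matrix(x, 2L, A)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, A))) {
    stop(what, " must be a scalar or a 2 x ", A, " (sex x age) matrix")
  }
  dimnames(x) <- list(sex = sexes, age = as.character(ages))
  x
}

expand_dropout <- function(x, specialties, sexes, ages) {
  S <- length(specialties); A <- length(ages)
  dn <- list(specialty = specialties, sex = sexes, age = as.character(ages))
  if (length(x) == 1L) {
    return(array(x, c(S, 2L, A), dimnames = dn))
  }
  if (is.matrix(x) && all(dim(x) == c(2L, A))) {
    out <- aperm(array(x, c(2L, A, S)), c(3L, 1L, 2L))
    dimnames(out) <- dn
    return(out)
  }
  x <- as.array(x)
  if (length(dim(x)) == 3L && all(dim(x) == c(S, 2L, A))) {
    dimnames(x) <- dn
    return(x)
  }
  stop("dropout must be a scalar, a 2 x ", A, " matrix, or a ",
       S, " x 2 x ", A, " array")
}

#' @export
print.exit_rates <- function(x, ...) {
  cat("<exit_rates> retirement age ", x$retirement_age,
      "; mean mortality ", signif(mean(x$mortality), 3),
      "; mean dropout ", signif(mean(x$dropout), 3), "\n", sep = "")
  invisible(x)
}

#' Full-time-equivalent conversion ratios
#'
#' FTE supply is headcount scaled by a conversion ratio reflecting hours
#' actually worked: `FTE = headcount x ratio`. Ratios may differ by sex and
#' age (feminization of the profession reduces the average effective
#' workweek, which is the reason the model carries sexes separately).
#'
#' @param ratio strictly positive scalar or `2 x A` (sex x age) matrix,
#'   values in `(0, 1.5]`.
#' @param ages ages covered, default `30:65`.
#' @return object of class `fte_ratio`.
#' @export
fte_ratio <- function(ratio = 1, ages = 30:65) {
  m <- expand_sex_age(ratio, c("female", "male"), ages, "fte ratio")
  if (any(m <= 0)) stop("fte ratio must be strictly positive")
  if (any(m > 1.5)) stop("fte ratio must not exceed 1.5")
  structure(list(ratio = m, ages = as.integer(ages)), class = "fte_ratio")
}

#' FTE supply of a stock
#'
#' @param stock a `specialty_stock`
#' @param fte an `fte_ratio` (or a number, expanded to one)
#' @param by `"all"` for a grand total or `"specialty"` for a named vector.
#' @return FTE supply; `FTE <= headcount` whenever all ratios are `<= 1`.
#' @examples
#' st <- specialty_stock(specialties = "1")
#' st["1", "female", "40"] <- 100; st["1", "male", "40"] <- 100
#' fte_supply(st, fte_ratio(rbind(rep(0.8, 36), rep(1, 36)))) # 180
#' @export
fte_supply <- function(stock, fte = fte_ratio(1, ages = stock_ages(stock)),
                       by = c("all", "specialty")) {
  by <- match.arg(by)
  if (is.numeric(fte)) fte <- fte_ratio(fte, ages = stock_ages(stock))
  if (!inherits(fte, "fte_ratio")) stop("`fte` must be an fte_ratio")
  if (!identical(fte$ages, stock_ages(stock))) {
    stop("fte ratio ages do not match the stock's ages")
  }
  S <- dim(stock)[1]
  w <- aperm(array(fte$ratio, c(2L, dim(stock)[3], S)), c(3L, 1L, 2L))
  weighted <- unclass(stock) * w
  if (by == "all") sum(weighted) else apply(weighted, 1L, sum)
}

#' Net immigration flow of specialists
#'
#' Net entrants per specialty and year (negative = net emigration), split by
#' sex at a fixed fraction and spread over an entry-age distribution.
#'
#' @param net_entrants either a named list `year -> numeric[S]`, a single
#'   numeric vector of per-specialty net entrants applied every year, or a
#'   scalar. Carry-forward: the most recent year at or before the queried
#'   year applies.
#' @param sex_split fraction of entrants who are women, in `[0, 1]`.
#' @param age_distribution probability weights over the stock's ages (must
#'   sum to 1 within 1e-9). Default: uniform over ages 30-40.
#' @param specialties,ages index sets.
#' @return object of class `immigration_flow`.
#' @export
immigration_flow <- function(net_entrants = 0, sex_split = 0.5,
                             age_distribution = NULL,
                             specialties = as.character(1:43), ages = 30:65) {
  specialties <- as.character(specialties)
  S <- length(specialties)
  if (is.null(age_distribution)) {
    age_distribution <- as.numeric(ages >= 30 & ages <= 40)
    age_distribution <- age_distribution / sum(age_distribution)
  }
  if (length(age_distribution) != length(ages)) {
    stop("age_distribution must have one weight per age")
  }
  if (abs(sum(age_distribution) - 1) > 1e-9) {
    stop("age_distribution must sum to 1 (within 1e-9)")
  }
  if (any(age_distribution < 0)) stop("age_distribution weights must be >= 0")
  if (sex_split < 0 || sex_split > 1) stop("sex_split must lie in [0, 1]")
  if (!is.list(net_entrants)) {
    v <- rep_len(as.numeric(net_entrants), S)
    net_entrants <- stats::setNames(list(v), "0") # applies from year 0 onward
  }
  for (v in net_entrants) {
    if (length(v) != S) stop("each net_entrants vector must have length ", S)
  }
  structure(list(net_entrants = net_entrants, sex_split = sex_split,
                 age_distribution = age_distribution,
                 specialties = specialties, ages = as.integer(ages)),
            class = "immigration_flow")
}

# Net entrants per specialty for a calendar year (carry-forward lookup).
immigration_entrants <- function(imm, year) {
  yrs <- as.integer(names(imm$net_entrants))
  ok <- yrs[yrs <= year]
  if (length(ok) == 0L) return(rep(0, length(imm$specialties)))
  imm$net_entrants[[as.character(max(ok))]]
}
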