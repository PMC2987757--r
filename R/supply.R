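#' Advance the specialist stock by one annual step
#'
#' The discrete annual realisation of the stock-flow balance
#' `Stock(t+1) = Stock(t) + Inflow(t) - Outflow(t)`. Within the year the
#' operation order is fixed (it matters at the third decimal and is part of
#' the model definition):
#'
#' 1. mandatory retirement: every cell at age `>= retirement_age` exits;
#' 2. mortality, drop-out and early retirement applied multiplicatively to
#'    the survivors (deaths first, then drop-outs among those alive, then
#'    early retirements among those remaining);
#' 3. ageing: every cohort moves up one year of age; cohorts ageing past the
#'    oldest modelled age (possible only when retirement is disabled or set
#'    beyond it) exit as `aged_out`;
#' 4. training completions of the target year enter at the entry-age
#'    distribution;
#' 5. net immigration of the target year enters (negative values drain, but
#'    may never drive a cell negative).
#'
#' @param stock a `specialty_stock` describing year `year`
#' @param exits an `exit_rates`
#' @param pipeline a `training_pipeline`, or `NULL` for no training inflow
#' @param immigration an `immigration_flow`, or `NULL` for none
#' @param year calendar year of `stock`; the result describes `year + 1`
#' @param retirement_age optional override of `exits$retirement_age`
#'   (scheduling hook)
#' @return a list with elements `stock` (the next-year `specialty_stock`) and
#'   `ledger` (a `flow_ledger` recording every flow of the step, so that the
#'   conservation identity can be checked exactly).
#' @examples
#' st <- specialty_stock(specialties = "1")
#' st["1", "male", "64"] <- 1
#' ex <- exit_rates(retirement_age = 65, specialties = "1")
#' s1 <- step_year(st, ex, year = 2008)   # he ages to 65
#' s2 <- step_year(s1$stock, ex, year = 2009) # and retires
#' sum(s2$stock); s2$ledger$totals["retirement"]
#' @export
step_year <- function(stock, exits, pipeline = NULL, immigration = NULL,
                      year, retirement_age = NULL) {
  validate_stock(stock)
  check_rate_dims(stock, exits)
  ages <- stock_ages(stock)
  S <- dim(stock)[1]; A <- dim(stock)[3]
  specialties <- stock_specialties(stock)
  ra <- if (is.null(retirement_age)) exits$retirement_age else retirement_age
  x <- unclass(stock)

  # 1. mandatory retirement
  retire_idx <- which(ages >= ra)
  retirement <- rowSums(x[, , retire_idx, drop = FALSE])
  if (length(retire_idx)) x[, , retire_idx] <- 0

  # 2. multiplicative exits on survivors; decomposition is exact:
  #    deaths = c*m; dropouts = c*(1-m)*d; early = c*(1-m)*(1-d)*e
  m <- sex_age_to_array(exits$mortality, S)
  d <- unclass(exits$dropout)
  e <- sex_age_to_array(exits$early_retirement, S)
  deaths_a <- x * m
  dropout_a <- x * (1 - m) * d
  early_a <- x * (1 - m) * (1 - d) * e
  mortality <- apply(deaths_a, 1L, sum)
  dropout <- apply(dropout_a, 1L, sum)
  early <- apply(early_a, 1L, sum)
  x <- x - deaths_a - dropout_a - early_a

  # 3. ageing: shift the age index up by one
  aged_out <- rowSums(x[, , A, drop = FALSE]) # zero unless retirement disabled
  x[, , 2:A] <- x[, , 1:(A - 1L)]
  x[, , 1L] <- 0

  # 4. training completions entering in year + 1
  training <- rep(0, S)
  if (!is.null(pipeline)) {
    inflow <- training_inflow(pipeline, year + 1L) # specialty x sex
    training <- rowSums(inflow)
    add <- outer(inflow, pipeline$entry_age_dist) # S x 2 x A
    x <- x + add
  }

  # 5. net immigration entering in year + 1
  immig <- rep(0, S)
  if (!is.null(immigration)) {
    net <- immigration_entrants(immigration, year + 1L)
    sexw <- c(immigration$sex_split, 1 - immigration$sex_split)
    pre <- x
    x <- x + outer(outer(net, sexw), immigration$age_distribution)
    if (any(x < -1e-9)) {
      bad <- which(x < -1e-9, arr.ind = TRUE)[1L, ]
      stop(sprintf(paste0("net emigration exceeds stock in cell ",
                          "(specialty=%s, sex=%s, age=%s)"),
                   specialties[bad[1L]], c("female", "male")[bad[2L]],
                   as.character(ages)[bad[3L]]))
    }
    x[x < 0] <- 0 # absorb -1e-9..0 float dust
    immig <- apply(x - pre, 1L, sum) # realized net, keeps ledger exact
  }

  out <- specialty_stock(x, specialties = specialties, ages = ages)
  ledger <- flow_ledger(specialties,
                        outflows = list(retirement = retirement,
                                        mortality = mortality,
                                        dropout = dropout,
                                        early_retirement = early,
                                        aged_out = aged_out),
                        inflows = list(training = training,
                                       immigration = immig))
  list(stock = out, ledger = ledger)
}

# Broadcast a 2 x A sex-age matrix to S x 2 x A.
sex_age_to_array <- function(m, S) {
  aperm(array(m, c(2L, ncol(m), S)), c(3L, 1L, 2L))
}

check_rate_dims <- function(stock, exits) {
  if (!inherits(exits, "exit_rates")) stop("`exits` must be an exit_rates")
  A <- dim(stock)[3]; S <- dim(stock)[1]
  if (ncol(exits$mortality) != A || !all(dim(exits$dropout) == c(S, 2L, A))) {
    stop("exit-rate tables do not cover every (specialty, sex, age) cell ",
         "of the stock")
  }
  invisible(TRUE)
}

#' Flow ledger of one annual step
#'
#' Per-specialty record of every inflow and outflow applied during a step.
#' `Stock(t+1) - Stock(t)` equals `sum(inflows) - sum(outflows)` exactly.
#'
#' @param specialties specialty ids
#' @param outflows,inflows named lists of per-specialty numeric vectors
#' @return object of class `flow_ledger`: a list with per-specialty matrices
#'   `outflows` and `inflows`, and a named `totals` vector.
#' @export
flow_ledger <- function(specialties, outflows, inflows) {
  of <- do.call(cbind, outflows)
  inf <- do.call(cbind, inflows)
  rownames(of) <- rownames(inf) <- specialties
  structure(list(outflows = of, inflows = inf,
                 totals = c(colSums(of), colSums(inf))),
            class = "flow_ledger")
}

#' Net flow (total inflow minus total outflow) recorded in a ledger
#' @param ledger a `flow_ledger`
#' @return scalar net change of the stock total over the step
#' @export
ledger_net <- function(ledger) {
  sum(ledger$inflows) - sum(ledger$outflows)
}

#' @export
print.flow_ledger <- function(x, ...) {
  cat("<flow_ledger> net", format(ledger_net(x)), "\n")
  print(round(x$totals, 3))
  invisible(x)
}

#' Simulate the supply trajectory over a year range
#'
#' Steps the stock annually from the first to the last year of `years`,
#' retaining the full specialty-sex-age pyramid of every year, so that the
#' demographic pyramid of any specialty in any year of the horizon can be
#' recovered. Fully deterministic.
#'
#' @param initial `specialty_stock` describing the first year of `years`
#' @param exits an `exit_rates`
#' @param pipeline a `training_pipeline` or `NULL`
#' @param immigration an `immigration_flow` or `NULL`
#' @param years consecutive calendar years, e.g. `2008:2025`
#' @param retirement_schedule optional named numeric vector
#'   (`year -> retirement age`) overriding `exits$retirement_age` with
#'   carry-forward semantics; the age applying to the step out of year `t`
#'   is the scheduled value for year `t`.
#' @return object of class `supply_trajectory`: a list with `counts`
#'   (`S x 2 x A x Y` array), `years`, and `ledgers` (one `flow_ledger` per
#'   step).
#' @export
simulate_supply <- function(initial, exits, pipeline = NULL,
                            immigration = NULL, years,
                            retirement_schedule = NULL) {
  years <- as.integer(years)
  if (length(years) < 1L || any(diff(years) != 1L)) {
    stop("`years` must be consecutive calendar years")
  }
  validate_stock(initial)
  S <- dim(initial)[1]; A <- dim(initial)[3]
  counts <- array(0, c(S, 2L, A, length(years)),
                  dimnames = c(dimnames(initial), list(year = years)))
  counts[, , , 1L] <- initial
  ledgers <- vector("list", max(length(years) - 1L, 0L))
  st <- initial
  for (i in seq_along(years)[-1L]) {
    yr <- years[i - 1L]
    ra <- schedule_value(retirement_schedule, yr)
    stp <- step_year(st, exits, pipeline, immigration, year = yr,
                     retirement_age = ra)
    st <- stp$stock
    counts[, , , i] <- st
    ledgers[[i - 1L]] <- stp$ledger
  }
  structure(list(counts = counts, years = years, ledgers = ledgers),
            class = "supply_trajectory")
}

# Carry-forward lookup in a named-by-year vector; NULL -> NULL.
schedule_value <- function(sched, year) {
  if (is.null(sched)) return(NULL)
  yrs <- as.integer(names(sched))
  ok <- yrs[yrs <= year]
  if (length(ok) == 0L) return(unname(sched[[1L]]))
  unname(sched[[as.character(max(ok))]])
}

#' @export
print.supply_trajectory <- function(x, ...) {
  cat("<supply_trajectory> ", dim(x$counts)[1], " specialties, years ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  tot <- apply(x$counts, 4L, sum)
  cat("  total supply: ", format(round(tot[1])), " -> ",
      format(round(tot[length(tot)])), "\n", sep = "")
  invisible(x)
}

#' Extract the stock of a given year from a trajectory
#' @param traj a `supply_trajectory`
#' @param year a year inside the trajectory
#' @return a `specialty_stock`
#' @export
stock_at <- function(traj, year) {
  i <- match(as.integer(year), traj$years)
  if (is.na(i)) stop("year ", year, " not in trajectory")
  dn <- dimnames(traj$counts)
  x <- traj$counts[, , , i, drop = FALSE]
  dim(x) <- dim(traj$counts)[1:3]
  specialty_stock(x, specialties = dn$specialty, ages = as.integer(dn$age))
}
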