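#' Validation report
#'
#' A collection of (severity, location, message) findings produced by
#' [validate_scenario()] and the configuration loader. A scenario with at
#' least one `error` finding is never run.
#'
#' @param severity character vector, each `"error"` or `"warning"`
#' @param location character vector naming the offending component
#' @param message character vector of human-readable messages
#' @return object of class `validation_report` (a data.frame).
#' @export
validation_report <- function(severity = character(),
                              location = character(),
                              message = character()) {
  stopifnot(all(severity %in% c("error", "warning")))
  structure(data.frame(severity = severity, location = location,
                       message = message, stringsAsFactors = FALSE),
            class = c("validation_report", "data.frame"))
}

add_finding <- function(rep, severity, location, message) {
  rbind_report(rep, validation_report(severity, location, message))
}

rbind_report <- function(a, b) {
  structure(rbind(as.data.frame(a), as.data.frame(b)),
            class = c("validation_report", "data.frame"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<validation_report> clean (0 findings)\n")
    return(invisible(x))
  }
  cat("<validation_report> ", sum(x$severity == "error"), " error(s), ",
      sum(x$severity == "warning"), " warning(s)\n", sep = "")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %s: %s\n", x$severity[i], x$location[i],
                x$message[i]))
  }
  invisible(x)
}

#' Does a report contain errors?
#' @param rep a `validation_report`
#' @return `TRUE` if any finding has severity `error`.
#' @export
has_errors <- function(rep) any(rep$severity == "error")

stop_on_errors <- function(rep) {
  if (has_errors(rep)) {
    msgs <- rep$message[rep$severity == "error"]
    stop("scenario failed validation:\n  ",
         paste(msgs, collapse = "\n  "), call. = FALSE)
  }
  invisible(rep)
}

#' Validate a scenario before running it
#'
#' Checks structural consistency: the stock, the coverage of the rate
#' tables, schedule coverage of the horizon (every simulated year must have
#' a value for every scheduled parameter, explicitly or by carry-forward),
#' the standards table, and the population path.
#'
#' @param sc a `scenario`
#' @return a `validation_report`; empty when the scenario is runnable.
#' @export
validate_scenario <- function(sc) {
  rep <- validation_report()
  if (!inherits(sc, "scenario")) {
    return(add_finding(rep, "error", "scenario", "not a scenario object"))
  }
  years <- sc$horizon[1]:sc$horizon[2]

  rep <- tryCatch({ validate_stock(sc$initial_stock); rep },
    error = function(e) add_finding(rep, "error", "initial_stock",
                                    conditionMessage(e)))
  rep <- tryCatch({ check_rate_dims(sc$initial_stock, sc$exits); rep },
    error = function(e) add_finding(rep, "error", "exits",
                                    conditionMessage(e)))

  # schedule coverage
  sched <- sc$schedule
  if (!inherits(sched, "parameter_schedule")) {
    rep <- add_finding(rep, "error", "schedule", "not a parameter_schedule")
  } else {
    covered <- function(yrs_named) {
      have <- as.integer(names(yrs_named))
      if (sched$carry_forward) {
        years[years < min(have)]      # uncovered only before the first value
      } else {
        setdiff(years, have)
      }
    }
    for (p in c("numerus_clausus", "retirement_age")) {
      miss <- covered(sched[[p]])
      # a single year-0 (scalar) entry covers everything
      if (length(miss) && !identical(names(sched[[p]]), "0")) {
        for (y in miss) {
          rep <- add_finding(rep, "error", "schedule",
                             sprintf("missing value for (%s, %d)", p, y))
        }
      }
    }
    miss_pop <- setdiff(years, sc$population$years)
    if (length(miss_pop)) {
      rep <- add_finding(rep, "error", "population",
                         paste("population path missing years:",
                               paste(miss_pop, collapse = ", ")))
    }
  }

  rep <- tryCatch({
    stds <- as_standard_list(sc$standards)
    ids <- vapply(stds, `[[`, "", "specialty")
    missing_std <- setdiff(stock_specialties(sc$initial_stock), ids)
    if (length(missing_std)) {
      add_finding(rep, "error", "standards",
                  paste("no need standard for specialty(ies):",
                        paste(missing_std, collapse = ", ")))
    } else rep
  }, error = function(e) add_finding(rep, "error", "standards",
                                     conditionMessage(e)))
  rep
}
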