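#' @export
print.scenario_result <- function(x, ...) {
  a <- x$aggregate
  n <- nrow(a)
  cat("<scenario_result> '", x$name, "', ", length(x$specialties),
      " specialties, ", min(x$years), "-", max(x$years), "\n", sep = "")
  cat(sprintf("  %d: supply %s, need %s, deficit %.1f%%\n",
              a$year[1], format(round(a$supply_head[1]), big.mark = " "),
              format(round(a$need[1]), big.mark = " "),
              100 * a$deficit_pct[1]))
  cat(sprintf("  %d: supply %s, need %s, deficit %.1f%%\n",
              a$year[n], format(round(a$supply_head[n]), big.mark = " "),
              format(round(a$need[n]), big.mark = " "),
              100 * a$deficit_pct[n]))
  invisible(x)
}

#' Summarise a scenario result
#'
#' Prints the aggregate trajectory at selected years in the layout of a
#' planning summary table: inhabitants, total supply, total need,
#' deficit/surplus percentage, ratio per 100,000, percentage of women and
#' percentage under 51.
#'
#' @param object a `scenario_result`
#' @param years years to tabulate (default: first, middle anchor, last)
#' @param ... unused
#' @return invisibly, the summary data.frame (years as columns).
#' @export
summary.scenario_result <- function(object, years = NULL, ...) {
  a <- object$aggregate
  if (is.null(years)) {
    years <- unique(c(a$year[1],
                      a$year[which.min(abs(a$year - stats::median(a$year)))],
                      a$year[nrow(a)]))
  }
  sel <- a[a$year %in% years, , drop = FALSE]
  tab <- rbind(
    inhabitants = round(sel$population),
    supply_head = round(sel$supply_head, 1),
    supply_fte = round(sel$supply_fte, 1),
    need = round(sel$need, 1),
    deficit_pct = round(100 * sel$deficit_pct, 1),
    ratio_per_100k = round(sel$ratio_per_100k, 1),
    pct_women = round(100 * sel$pct_women, 1),
    pct_under_51 = round(100 * sel$pct_under_51, 1))
  colnames(tab) <- sel$year
  cat("Scenario '", object$name, "' (population '",
      object$population$label, "')\n\n", sep = "")
  print(tab)
  invisible(as.data.frame(tab))
}

#' @export
as.data.frame.scenario_result <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  x$table
}

#' Plot a scenario result
#'
#' Base-graphics overview: aggregate supply and need trajectories
#' (`which = "trajectory"`) or the age-sex pyramid of one specialty in one
#' year (`which = "pyramid"`).
#'
#' @param x a `scenario_result`
#' @param which `"trajectory"` or `"pyramid"`
#' @param specialty,year pyramid selection (defaults: first specialty, last
#'   year)
#' @param ... passed to the underlying plotting calls
#' @export
plot.scenario_result <- function(x, which = c("trajectory", "pyramid"),
                                 specialty = NULL, year = NULL, ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    a <- x$aggregate
    ylim <- range(a$supply_head, a$need)
    graphics::plot(a$year, a$supply_head, type = "l", lwd = 2,
                   xlab = "year", ylab = "specialists", ylim = ylim,
                   main = paste0("'", x$name, "': supply vs need"), ...)
    graphics::lines(a$year, a$need, lwd = 2, lty = 2)
    graphics::legend("topleft", c("supply", "need"), lwd = 2, lty = c(1, 2),
                     bty = "n")
  } else {
    if (is.null(specialty)) specialty <- x$specialties[1L]
    if (is.null(year)) year <- max(x$years)
    st <- stock_at(x$trajectory, year)
    ps <- pyramid_summaries(st, specialty)
    pyr <- ps$pyramid
    f <- pyr$count[pyr$sex == "female"]
    m <- pyr$count[pyr$sex == "male"]
    ages <- pyr$age[pyr$sex == "female"]
    graphics::barplot(-f, horiz = TRUE, names.arg = ages, col = "grey40",
                      xlim = c(-max(f, m), max(f, m)),
                      main = sprintf("specialty %s, %s (women left)",
                                     specialty, year),
                      xlab = "headcount", ...)
    graphics::barplot(m, horiz = TRUE, add = TRUE, col = "grey75",
                      names.arg = rep("", length(m)))
  }
  invisible(x)
}
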