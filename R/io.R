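# Scenario configuration files
#
# A scenario on disk is a YAML file plus the CSV tables it references.
# The schema is strict: unknown keys are errors, so parameter-name typos in
# policy experiments fail loudly instead of being silently ignored.
# Numbers use a decimal point and no thousands separators.

scenario_schema <- list(
  top = c("meta", "horizon", "supply_params", "demand_params", "files"),
  meta = c("name"),
  horizon = c("start", "end"),
  supply_params = c("d_med", "d_res", "exam_pass", "completion", "sex_split",
                    "entry_age", "retirement_age", "numerus_clausus",
                    "immigration_sex_split", "carry_forward",
                    "warmup_value"),
  demand_params = c("base_year", "population_scenario", "demand_rates"),
  files = c("initial_stock", "mortality", "dropout", "fte", "standards",
            "positions", "immigration", "population")
)

check_keys <- function(x, allowed, where, rep) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    rep <- add_finding(rep, "error", where,
                       paste0("unknown key(s): ", paste(bad, collapse = ", "),
                              " (allowed: ", paste(allowed, collapse = ", "),
                              ")"))
  }
  rep
}

#' Load a scenario from a YAML configuration file
#'
#' Reads the YAML file and every CSV table it references, validates against
#' a strict schema (unknown keys are errors) and assembles a runnable
#' [scenario()]. File paths in the `files` section are resolved relative to
#' the YAML file's directory.
#'
#' @param path path to the scenario YAML file
#' @param on_error `"stop"` (default) raises an error listing the findings;
#'   `"report"` returns the `validation_report` instead of a scenario
#' @return a `scenario`, or a `validation_report` when `on_error="report"`
#'   and the configuration is invalid.
#' @export
load_scenario <- function(path, on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) stop("scenario file not found: ", path)
  cfg <- yaml::read_yaml(path)
  dir <- dirname(normalizePath(path))
  rep <- validation_report()
  rep <- check_keys(cfg, scenario_schema$top, "scenario", rep)
  for (sec in intersect(names(cfg), scenario_schema$top)) {
    rep <- check_keys(cfg[[sec]], scenario_schema[[sec]], sec, rep)
  }
  for (sec in c("meta", "horizon", "files")) {
    if (is.null(cfg[[sec]])) {
      rep <- add_finding(rep, "error", sec, "required section missing")
    }
  }
  required_files <- c("initial_stock", "mortality", "dropout", "fte",
                      "standards", "positions")
  fpaths <- list()
  for (f in union(required_files, names(cfg$files %||% list()))) {
    rel <- cfg$files[[f]]
    if (is.null(rel)) {
      if (f %in% required_files) {
        rep <- add_finding(rep, "error", "files",
                           paste0("missing required file entry '", f, "'"))
      }
      next
    }
    fp <- file.path(dir, rel)
    if (!file.exists(fp)) {
      rep <- add_finding(rep, "error", "files",
                         paste0("file for '", f, "' not found: ", fp))
    }
    fpaths[[f]] <- fp
  }
  if (has_errors(rep)) {
    if (on_error == "report") return(rep)
    stop("invalid scenario configuration:\n  ",
         paste(rep$message[rep$severity == "error"], collapse = "\n  "),
         call. = FALSE)
  }

  horizon <- c(as.integer(cfg$horizon$start), as.integer(cfg$horizon$end))
  years <- horizon[1]:horizon[2]
  stock <- read_stock_csv(fpaths$initial_stock)
  specialties <- stock_specialties(stock)
  S <- length(specialties)
  ages <- stock_ages(stock)

  mort <- read_sex_age_csv(fpaths$mortality, "rate", ages)
  drop <- read_dropout_csv(fpaths$dropout, specialties, ages)
  fte_m <- read_sex_age_csv(fpaths$fte, "ratio", ages)
  standards <- read_standards_csv(fpaths$standards)
  positions <- read_year_specialty_csv(fpaths$positions, "positions",
                                       specialties)

  sp <- cfg$supply_params %||% list()
  retirement <- as_year_map(sp$retirement_age %||% 65)
  exits <- exit_rates(mortality = mort, dropout = drop,
                      retirement_age = retirement[[1L]],
                      specialties = specialties, ages = ages)

  immigration <- NULL
  if (!is.null(fpaths$immigration)) {
    immigration <- read_year_specialty_csv(fpaths$immigration,
                                           "net_entrants", specialties)
  }

  dp <- cfg$demand_params %||% list()
  pop_label <- dp$population_scenario %||% "moderate"
  if (!is.null(fpaths$population)) {
    pdf <- utils::read.csv(fpaths$population, stringsAsFactors = FALSE)
    need <- c("scenario", "year", "population")
    if (!all(need %in% names(pdf))) {
      stop("population CSV must have columns: ", paste(need, collapse = ", "))
    }
    sel <- pdf[pdf$scenario == pop_label, , drop = FALSE]
    if (nrow(sel) == 0L) stop("population CSV has no rows for scenario '",
                              pop_label, "'")
    anchors <- stats::setNames(sel$population, sel$year)
    population <- population_scenario(pop_label, years = years,
                                      anchors = anchors)
  } else {
    population <- population_scenario(pop_label, years = years)
  }

  demand_rates <- NULL
  if (!is.null(dp$demand_rates)) demand_rates <- unlist(dp$demand_rates)

  entry_age_dist <- NULL
  if (!is.null(sp$entry_age)) {
    entry_age_dist <- as.numeric(ages == as.integer(sp$entry_age))
    if (sum(entry_age_dist) != 1) stop("entry_age outside the modelled ages")
  }
  pipeline_opts <- list()
  for (k in c("d_med", "d_res", "exam_pass", "completion", "sex_split",
              "warmup_value")) {
    if (!is.null(sp[[k]])) pipeline_opts[[k]] <- unlist(sp[[k]])
  }
  if (!is.null(entry_age_dist)) pipeline_opts$entry_age_dist <- entry_age_dist

  sched <- parameter_schedule(
    numerus_clausus = as_year_map(sp$numerus_clausus %||%
                                    stop("supply_params.numerus_clausus ",
                                         "is required")),
    residency_positions = positions,
    retirement_age = as_year_map(sp$retirement_age %||% 65),
    fte = stats::setNames(list(fte_ratio(fte_m, ages = ages)), "0"),
    immigration = immigration,
    demand_rates = demand_rates,
    carry_forward = sp$carry_forward %||% TRUE)

  immigration_opts <- list()
  if (!is.null(sp$immigration_sex_split)) {
    immigration_opts$sex_split <- sp$immigration_sex_split
  }

  scenario(name = cfg$meta$name %||% "unnamed",
           initial_stock = stock, exits = exits, schedule = sched,
           standards = standards, population = population,
           horizon = horizon, pipeline_opts = pipeline_opts,
           immigration_opts = immigration_opts)
}

# YAML year-keyed maps arrive as named lists; scalars mean "every year".
as_year_map <- function(x) {
  if (is.list(x)) x <- unlist(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    if (length(x) != 1L) stop("year-scheduled values must be a year-keyed map")
    names(x) <- "0"
  }
  x[order(as.integer(names(x)))]
}

read_sex_age_csv <- function(path, value_col, ages) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", value_col)
  if (!all(need %in% names(df))) {
    stop(basename(path), " must have columns: ", paste(need, collapse = ", "))
  }
  m <- matrix(NA_real_, 2L, length(ages),
              dimnames = list(sex = c("female", "male"),
                              age = as.character(ages)))
  for (i in seq_len(nrow(df))) {
    m[tolower(df$sex[i]), as.character(df$age[i])] <- df[[value_col]][i]
  }
  if (any(is.na(m))) {
    miss <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop(basename(path), " missing value for (",
         rownames(m)[miss[1]], ", age ", colnames(m)[miss[2]], ")")
  }
  m
}

read_dropout_csv <- function(path, specialties, ages) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("specialty_id" %in% names(df)) {
    arr <- array(NA_real_, c(length(specialties), 2L, length(ages)),
                 dimnames = list(specialty = specialties,
                                 sex = c("female", "male"),
                                 age = as.character(ages)))
    for (i in seq_len(nrow(df))) {
      arr[as.character(df$specialty_id[i]), tolower(df$sex[i]),
          as.character(df$age[i])] <- df$rate[i]
    }
    if (any(is.na(arr))) stop(basename(path),
                              " does not cover every (specialty, sex, age)")
    arr
  } else {
    read_sex_age_csv(path, "rate", ages)
  }
}

read_year_specialty_csv <- function(path, value_col, specialties) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specialty_id", "year", value_col)
  if (!all(need %in% names(df))) {
    stop(basename(path), " must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (y in sort(unique(df$year))) {
    v <- stats::setNames(rep(0, length(specialties)), specialties)
    sel <- df[df$year == y, , drop = FALSE]
    unknown <- setdiff(as.character(sel$specialty_id), specialties)
    if (length(unknown)) {
      stop(basename(path), " references unknown specialty id(s): ",
           paste(unknown, collapse = ", "))
    }
    v[as.character(sel$specialty_id)] <- sel[[value_col]]
    out[[as.character(y)]] <- unname(v)
  }
  out
}

#' Save a scenario to a directory as YAML + CSV tables
#'
#' Inverse of [load_scenario()]: `load_scenario(save_scenario(sc, dir))`
#' reconstructs an equivalent scenario (round-trip identity up to floating
#' point text representation, which is written at full precision).
#'
#' @param sc a `scenario`
#' @param dir output directory (created if needed)
#' @return the path of the written YAML file, invisibly.
#' @export
save_scenario <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  specialties <- stock_specialties(sc$initial_stock)
  ages <- stock_ages(sc$initial_stock)
  write_stock_csv(sc$initial_stock, file.path(dir, "initial_stock.csv"))
  write_sex_age_csv(sc$exits$mortality, "rate",
                    file.path(dir, "mortality.csv"))
  write_dropout_csv(sc$exits$dropout, file.path(dir, "dropout.csv"))
  fte0 <- schedule_value_list(sc$schedule$fte, sc$horizon[1])
  if (!inherits(fte0, "fte_ratio")) fte0 <- fte_ratio(fte0, ages = ages)
  write_sex_age_csv(fte0$ratio, "ratio", file.path(dir, "fte.csv"))
  std <- sc$standards
  std$base_ratio_per_100k <- format_full(std$base_ratio_per_100k)
  utils::write.csv(std, file.path(dir, "standards.csv"),
                   row.names = FALSE, quote = FALSE)
  write_year_specialty_csv(sc$schedule$residency_positions, "positions",
                           specialties, file.path(dir, "positions.csv"))
  files <- list(initial_stock = "initial_stock.csv",
                mortality = "mortality.csv", dropout = "dropout.csv",
                fte = "fte.csv", standards = "standards.csv",
                positions = "positions.csv")
  if (!is.null(sc$schedule$immigration)) {
    write_year_specialty_csv(sc$schedule$immigration, "net_entrants",
                             specialties, file.path(dir, "immigration.csv"))
    files$immigration <- "immigration.csv"
  }
  pdf <- data.frame(scenario = sc$population$label,
                    year = sc$population$years,
                    population = format_full(sc$population$population))
  utils::write.csv(pdf, file.path(dir, "population.csv"),
                   row.names = FALSE, quote = FALSE)
  files$population <- "population.csv"

  po <- sc$pipeline_opts
  sp <- list(numerus_clausus = year_map_out(sc$schedule$numerus_clausus),
             retirement_age = year_map_out(sc$schedule$retirement_age),
             carry_forward = sc$schedule$carry_forward)
  for (k in c("d_med", "d_res", "exam_pass", "completion", "sex_split",
              "warmup_value")) {
    if (!is.null(po[[k]])) sp[[k]] <- po[[k]]
  }
  if (!is.null(po$entry_age_dist)) {
    sp$entry_age <- ages[which(po$entry_age_dist == 1)][1]
  }
  if (!is.null(sc$immigration_opts$sex_split)) {
    sp$immigration_sex_split <- sc$immigration_opts$sex_split
  }
  dp <- list(base_year = sc$horizon[1],
             population_scenario = sc$population$label)
  if (!is.null(sc$schedule$demand_rates)) {
    dp$demand_rates <- as.list(sc$schedule$demand_rates)
  }
  cfg <- list(meta = list(name = sc$name),
              horizon = list(start = sc$horizon[1], end = sc$horizon[2]),
              supply_params = sp, demand_params = dp, files = files)
  out <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(cfg, out, precision = 17)
  invisible(out)
}

year_map_out <- function(v) {
  as.list(stats::setNames(unname(v), names(v)))
}

write_sex_age_csv <- function(m, value_col, path) {
  df <- data.frame(sex = rep(rownames(m), times = ncol(m)),
                   age = rep(as.integer(colnames(m)), each = nrow(m)))
  df[[value_col]] <- format_full(as.vector(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_dropout_csv <- function(arr, path) {
  dn <- dimnames(arr)
  df <- expand.grid(specialty_id = dn$specialty, sex = dn$sex,
                    age = as.integer(dn$age),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$rate <- format_full(as.vector(arr))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

write_year_specialty_csv <- function(lst, value_col, specialties, path) {
  rows <- do.call(rbind, lapply(names(lst), function(y) {
    data.frame(specialty_id = specialties, year = as.integer(y),
               value = lst[[y]], stringsAsFactors = FALSE)
  }))
  names(rows)[names(rows) == "value"] <- value_col
  rows[[value_col]] <- format_full(rows[[value_col]])
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
}

#' Write the results of a scenario run to a directory
#'
#' Produces: `results_long.csv` (tidy long format: scenario, specialty,
#' year, metric, value, at full precision), `summary.csv` (the aggregate
#' planning summary, metrics as rows and years as columns), `pyramids.csv`
#' (age-sex pyramid counts per specialty and year) and `manifest.json`
#' (scenario configuration hash, package version, timestamp).
#'
#' @param result a `scenario_result`
#' @param dir output directory (created if needed)
#' @param pyramids write the pyramid table (default TRUE)
#' @return invisibly, the vector of written file paths.
#' @export
write_results <- function(result, dir, pyramids = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- result$table
  metrics <- setdiff(names(tab), c("scenario", "specialty", "year"))
  long <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(scenario = tab$scenario, specialty = tab$specialty,
               year = tab$year, metric = m, value = tab[[m]],
               stringsAsFactors = FALSE)
  }))
  long <- long[order(long$metric, long$specialty, long$year), ]
  long$value <- format_full(long$value)
  f_long <- file.path(dir, "results_long.csv")
  utils::write.csv(long, f_long, row.names = FALSE, quote = FALSE)

  a <- result$aggregate
  rows <- c("population", "supply_head", "supply_fte", "need",
            "deficit_head", "deficit_pct", "ratio_per_100k", "pct_women",
            "pct_under_51")
  smat <- t(as.matrix(a[, rows]))
  colnames(smat) <- a$year
  sdf <- data.frame(metric = rows, apply(smat, 2, format_full),
                    check.names = FALSE, stringsAsFactors = FALSE)
  f_sum <- file.path(dir, "summary.csv")
  utils::write.csv(sdf, f_sum, row.names = FALSE, quote = FALSE)

  written <- c(f_long, f_sum)
  if (pyramids) {
    counts <- result$trajectory$counts
    dn <- dimnames(counts)
    pyr <- expand.grid(specialty = dn$specialty, sex = dn$sex,
                       age = as.integer(dn$age),
                       year = as.integer(dn$year),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pyr$count <- format_full(as.vector(counts))
    f_pyr <- file.path(dir, "pyramids.csv")
    utils::write.csv(pyr, f_pyr, row.names = FALSE, quote = FALSE)
    written <- c(written, f_pyr)
  }

  manifest <- list(scenario = result$name,
                   config_hash = object_hash(result$scenario),
                   package = "workforcesim",
                   version = as.character(utils::packageVersion("workforcesim")),
                   years = range(result$years),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f_man <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, f_man))
}

#' Read back a long-format results CSV
#'
#' @param path `results_long.csv` written by [write_results()]
#' @return wide data.frame (scenario, specialty, year, one column per
#'   metric), numerically identical to the in-memory result table.
#' @export
read_results_long <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(specialty = "character"))
  wide <- stats::reshape(long, idvar = c("scenario", "specialty", "year"),
                         timevar = "metric", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  attr(wide, "reshapeWide") <- NULL
  rownames(wide) <- NULL
  wide
}
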