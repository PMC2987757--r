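#' Training pipeline: medical school and residency cohorts with their delays
#'
#' The supply side's time delays. A cohort admitted to medical school in year
#' `y` under the numerus clausus studies for `d_med` years, sits the national
#' residency examination, takes a residency position in one of the
#' specialties (4- or 5-year programmes), and enters the specialist stock in
#' year `y + d_med + d_res(specialty)`. Sex composition is set at admission
#' and preserved through the pipeline.
#'
#' @param admissions named numeric vector of medical-school admissions per
#'   calendar year (names are years). Years after the last named year carry
#'   the last value forward. Years before the first named year use the
#'   warm-up value.
#' @param positions residency positions per specialty and year: a named list
#'   `year -> numeric[S]` (carry-forward), a single `numeric[S]` applied to
#'   every year, or a scalar split equally across specialties.
#' @param d_med medical-school duration in years (default 6).
#' @param d_res residency duration per specialty, each 4 or 5 years; scalar
#'   or `numeric[S]` (default 4).
#' @param exam_pass fraction of graduates passing the national examination
#'   and entering a residency, in `[0, 1]` (default 1).
#' @param completion fraction of residents completing the programme, scalar
#'   or per specialty, in `[0, 1]` (default 1).
#' @param sex_split fraction of admitted students who are women (default 2/3,
#'   the contemporary intake composition the model emulates).
#' @param entry_age_dist probability weights over the stock's ages for newly
#'   qualified specialists; default a point mass at the youngest age.
#' @param warmup if `TRUE` (default), admission years before the recorded
#'   history use `warmup_value`; if `FALSE`, querying them is an error.
#' @param warmup_value admissions assumed for pre-history years; defaults to
#'   the earliest recorded admissions value.
#' @param specialties,ages index sets.
#' @return object of class `training_pipeline`.
#' @examples
#' pl <- training_pipeline(admissions = c("2008" = 7000),
#'                         positions = 7000, specialties = as.character(1:3))
#' training_inflow(pl, 2018) # first cohort out after 6 + 4 years
#' @export
training_pipeline <- function(admissions, positions, d_med = 6, d_res = 4,
                              exam_pass = 1, completion = 1,
                              sex_split = 2 / 3, entry_age_dist = NULL,
                              warmup = TRUE, warmup_value = NULL,
                              specialties = as.character(1:43), ages = 30:65) {
  specialties <- as.character(specialties)
  S <- length(specialties)
  if (is.null(names(admissions)) || any(!nzchar(names(admissions)))) {
    stop("`admissions` must be named by calendar year")
  }
  admissions <- admissions[order(as.integer(names(admissions)))]
  if (any(admissions < 0)) stop("admissions must be >= 0")
  positions <- normalize_positions(positions, S)
  d_res <- rep_len(as.integer(d_res), S)
  if (!all(d_res %in% c(4L, 5L))) stop("d_res must be 4 or 5 per specialty")
  completion <- rep_len(as.numeric(completion), S)
  stopifnot(exam_pass >= 0, exam_pass <= 1,
            all(completion >= 0), all(completion <= 1),
            sex_split >= 0, sex_split <= 1, d_med >= 1)
  if (is.null(entry_age_dist)) {
    entry_age_dist <- c(1, rep(0, length(ages) - 1L))
  }
  if (length(entry_age_dist) != length(ages) ||
      abs(sum(entry_age_dist) - 1) > 1e-9 || any(entry_age_dist < 0)) {
    stop("entry_age_dist must be non-negative weights over the ages, sum 1")
  }
  if (is.null(warmup_value)) warmup_value <- unname(admissions[1L])
  structure(list(admissions = admissions, positions = positions,
                 d_med = as.integer(d_med), d_res = d_res,
                 exam_pass = exam_pass, completion = completion,
                 sex_split = sex_split, entry_age_dist = entry_age_dist,
                 warmup = isTRUE(warmup), warmup_value = warmup_value,
                 specialties = specialties, ages = as.integer(ages)),
            class = "training_pipeline")
}

normalize_positions <- function(positions, S) {
  if (!is.list(positions)) {
    v <- if (length(positions) == 1L) rep(positions / S, S)
         else rep_len(as.numeric(positions), S)
    positions <- stats::setNames(list(v), "0")
  }
  if (is.null(names(positions))) stop("`positions` list must be named by year")
  for (v in positions) {
    if (length(v) != S) stop("each positions vector must have length ", S)
    if (any(v < 0)) stop("positions must be >= 0")
  }
  positions[order(as.integer(names(positions)))]
}

#' @export
print.training_pipeline <- function(x, ...) {
  cat("<training_pipeline> d_med ", x$d_med, ", d_res ",
      paste(range(x$d_res), collapse = "-"),
      "; admissions ", paste(range(x$admissions), collapse = "-"),
      "/yr over ", length(x$admissions), " recorded year(s)\n", sep = "")
  invisible(x)
}

# Admissions in a calendar year, with warm-up and carry-forward semantics.
admissions_in <- function(pipeline, year) {
  yrs <- as.integer(names(pipeline$admissions))
  if (year < yrs[1L]) {
    if (!pipeline$warmup) {
      stop("admissions history starts in ", yrs[1L], " but year ", year,
           " is required; supply warm-up cohorts (warmup_value) or extend ",
           "the admissions schedule")
    }
    return(pipeline$warmup_value)
  }
  unname(pipeline$admissions[[as.character(max(yrs[yrs <= year]))]])
}

positions_in <- function(pipeline, year) {
  yrs <- as.integer(names(pipeline$positions))
  ok <- yrs[yrs <= year]
  if (length(ok) == 0L) return(pipeline$positions[[1L]])
  pipeline$positions[[as.character(max(ok))]]
}

#' New-specialist inflow produced by the pipeline in a given year
#'
#' For each specialty `s`, the residents completing in `year` started
#' residency in `year - d_res(s)`, drawn from the graduates admitted
#' `d_med` years before that. Graduates (admissions times the examination
#' pass fraction) are allocated across specialties proportionally to the
#' residency positions on offer that year, capped by the positions, and
#' thinned by the per-specialty completion fraction:
#' `inflow(s) = min(graduates x share(s), positions(s)) x completion(s)`.
#'
#' @param pipeline a `training_pipeline`
#' @param year calendar year in which the new specialists enter the stock
#' @return a `S x 2` matrix (specialty x sex) of headcount inflows.
#' @export
training_inflow <- function(pipeline, year) {
  S <- length(pipeline$specialties)
  out <- matrix(0, S, 2L,
                dimnames = list(specialty = pipeline$specialties,
                                sex = c("female", "male")))
  for (dres in unique(pipeline$d_res)) {
    idx <- which(pipeline$d_res == dres)
    res_start <- year - dres
    adm_year <- res_start - pipeline$d_med
    grads <- admissions_in(pipeline, adm_year) * pipeline$exam_pass
    pos <- positions_in(pipeline, res_start)
    tot_pos <- sum(pos)
    share <- if (tot_pos > 0) pos / tot_pos else rep(0, S)
    intake <- pmin(grads * share, pos)
    inflow <- intake[idx] * pipeline$completion[idx]
    out[idx, "female"] <- inflow * pipeline$sex_split
    out[idx, "male"] <- inflow * (1 - pipeline$sex_split)
  }
  out
}
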