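#' Specialist stock: headcounts by specialty, sex and single-year age
#'
#' The model's state (level) variable: a non-negative real-valued array of
#' headcounts indexed by specialty, sex (`female`, `male`) and attained age in
#' completed years at the January-1 reference of a simulation year. Counts are
#' continuous reals; fractional people are deliberate (deterministic
#' cohort-component convention, no stochastic rounding).
#'
#' @param counts numeric array of dimension `S x 2 x A`, or `NULL` for an
#'   all-zero stock. Dimension order is specialty, sex, age.
#' @param specialties character vector of specialty identifiers. Defaults to
#'   `"1"..."43"`, the number of specialties modelled.
#' @param ages integer vector of single-year ages covered by the stock,
#'   default `30:65` (36 groups).
#' @return an object of class `specialty_stock`: the counts array with
#'   dimnames `specialty`, `sex`, `age`.
#' @examples
#' st <- specialty_stock(specialties = c("cardiology", "allergology"))
#' st["cardiology", "female", "40"] <- 120
#' stock_total(st)
#' @export
specialty_stock <- function(counts = NULL, specialties = as.character(1:43),
                            ages = 30:65) {
  specialties <- as.character(specialties)
  sexes <- c("female", "male")
  dn <- list(specialty = specialties, sex = sexes, age = as.character(ages))
  if (is.null(counts)) {
    counts <- array(0, dim = c(length(specialties), 2L, length(ages)),
                    dimnames = dn)
  } else {
    counts <- as.array(counts)
    if (length(dim(counts)) != 3L ||
        !all(dim(counts) == c(length(specialties), 2L, length(ages)))) {
      stop("`counts` must be a specialty x sex x age array of dimension ",
           length(specialties), " x 2 x ", length(ages))
    }
    dimnames(counts) <- dn
  }
  structure(counts, class = "specialty_stock")
}

#' @export
print.specialty_stock <- function(x, ...) {
  ages <- stock_ages(x)
  cat("<specialty_stock> ", dim(x)[1], " specialties x 2 sexes x ",
      dim(x)[3], " ages (", min(ages), "-", max(ages), ")\n", sep = "")
  cat("  total headcount: ", format(sum(x), big.mark = " "), "\n", sep = "")
  invisible(x)
}

#' @rdname specialty_stock
#' @param x a `specialty_stock`
#' @export
stock_ages <- function(x) as.integer(dimnames(x)$age)

#' @rdname specialty_stock
#' @export
stock_specialties <- function(x) dimnames(x)$specialty

#' Total headcount of a stock, optionally by margin
#'
#' @param x a `specialty_stock`
#' @param by one of `"all"`, `"specialty"`, `"sex"`, `"age"`
#' @return a scalar (`"all"`) or a named numeric vector over the margin.
#' @export
stock_total <- function(x, by = c("all", "specialty", "sex", "age")) {
  by <- match.arg(by)
  if (by == "all") return(sum(x))
  apply(x, match(by, c("specialty", "sex", "age")), sum)
}

#' @export
as.data.frame.specialty_stock <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  dn <- dimnames(x)
  out <- expand.grid(specialty = dn$specialty, sex = dn$sex,
                     age = as.integer(dn$age),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$count <- as.vector(x)
  out
}

# Internal validator used by step_year / simulate_supply / run_scenario.
validate_stock <- function(x) {
  if (!inherits(x, "specialty_stock")) stop("not a specialty_stock")
  if (any(!is.finite(x))) stop("stock contains non-finite counts")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    dn <- dimnames(x)
    stop(sprintf("negative count in cell (specialty=%s, sex=%s, age=%s)",
                 dn$specialty[bad[1]], dn$sex[bad[2]], dn$age[bad[3]]))
  }
  invisible(x)
}

#' Read an initial stock from CSV
#'
#' Expects columns `specialty_id`, `sex`, `age`, `count` (a `specialty_name`
#' column is allowed and ignored for indexing). Missing cells default to 0.
#'
#' @param path CSV file path
#' @param ages age range of the stock, default `30:65`
#' @return a `specialty_stock`
#' @export
read_stock_csv <- function(path, ages = 30:65) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specialty_id", "sex", "age", "count")
  if (!all(need %in% names(df))) {
    stop("stock CSV must have columns: ", paste(need, collapse = ", "))
  }
  ids <- as.character(sort(unique(as.integer(df$specialty_id))))
  st <- specialty_stock(specialties = ids, ages = ages)
  df$sex <- tolower(df$sex)
  if (!all(df$sex %in% c("female", "male"))) stop("sex must be female/male")
  if (!all(df$age %in% ages)) {
    stop("stock CSV contains ages outside ", min(ages), "-", max(ages))
  }
  for (i in seq_len(nrow(df))) {
    st[as.character(df$specialty_id[i]), df$sex[i], as.character(df$age[i])] <-
      st[as.character(df$specialty_id[i]), df$sex[i], as.character(df$age[i])] +
      df$count[i]
  }
  validate_stock(st)
}

#' Write a stock to CSV (long format)
#'
#' @param x a `specialty_stock`
#' @param path output file
#' @param drop_zero drop zero cells (default TRUE; keeps files small)
#' @export
write_stock_csv <- function(x, path, drop_zero = TRUE) {
  df <- as.data.frame(x)
  names(df)[names(df) == "specialty"] <- "specialty_id"
  if (drop_zero) df <- df[df$count != 0, , drop = FALSE]
  df$count <- format_full(df$count)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
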