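#' Annual life table
#'
#' Construct and validate an annual mortality schedule: for every integer age
#' from 0 up to the table's maximum age, the conditional probability `qx` of
#' dying within the year given survival to that age. The table is the
#' mortality backbone of both model strategies; the per-cycle death
#' probability is looked up from it (see [dp_at()]).
#'
#' Validation enforces the structural invariants the downstream Markov model
#' relies on: ages contiguous from 0 in steps of one year, every `qx` in
#' \[0, 1\], and closure (`qx = 1`) at the maximum age so that a cohort
#' followed long enough is fully absorbed by death.
#'
#' @param age Integer vector of ages in years, starting at 0, step 1.
#' @param qx Numeric vector of death probabilities, one per age.
#'
#' @return A `life_table`: a `data.frame` with columns `age` and `qx`.
#' @seealso [gompertz_makeham_table()], [read_life_table()], [dp_at()],
#'   [life_expectancy()]
#' @export
#' @examples
#' lt <- life_table(0:2, c(0.01, 0.5, 1))
#' life_expectancy(lt)
life_table <- function(age, qx) {
  if (length(age) != length(qx)) {
    stop("`age` and `qx` must have the same length", call. = FALSE)
  }
  if (anyNA(age) || anyNA(qx)) {
    stop("life table must not contain missing values", call. = FALSE)
  }
  age <- as.integer(age)
  if (age[1L] != 0L) {
    stop("life table must start at age 0", call. = FALSE)
  }
  if (length(age) > 1L) {
    d <- diff(age)
    if (any(d == 0L)) {
      stop(sprintf("duplicate ages: age %d repeated at row %d",
                   age[which(d == 0L)[1L] + 1L], which(d == 0L)[1L] + 1L),
           call. = FALSE)
    }
    if (any(d != 1L)) {
      i <- which(d != 1L)[1L]
      stop(sprintf("non-contiguous ages: age %d is followed by age %d at row %d",
                   age[i], age[i + 1L], i + 1L),
           call. = FALSE)
    }
  }
  qx <- as.numeric(qx)
  bad <- which(qx < 0 | qx > 1)
  if (length(bad)) {
    stop(sprintf("qx out of [0, 1] in row %d (age %d, qx = %g)",
                 bad[1L], age[bad[1L]], qx[bad[1L]]),
         call. = FALSE)
  }
  if (qx[length(qx)] != 1) {
    stop(sprintf(
      "life table must close with qx = 1 at its maximum age (age %d has qx = %g)",
      age[length(age)], qx[length(qx)]), call. = FALSE)
  }
  structure(data.frame(age = age, qx = qx),
            class = c("life_table", "data.frame"))
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Annual life table: ages 0-%d\n", max(x$age)))
  cat(sprintf("  life expectancy at birth: %.1f years (curtate)\n",
              life_expectancy(x)))
  cat(sprintf("  qx at ages 0 / 60 / max: %.5f / %s / %.3f\n",
              x$qx[1L],
              if (max(x$age) >= 60) sprintf("%.5f", x$qx[61L]) else "-",
              x$qx[nrow(x)]))
  invisible(x)
}

#' Synthetic Gompertz-Makeham life table
#'
#' Generate an annual life table from a Gompertz-Makeham hazard
#' \eqn{h(x) = a + b c^x}: an age-independent background rate `a` plus an
#' exponentially increasing senescent component. The death probability for
#' the year of age \eqn{x} is \eqn{q_x = 1 - \exp(-\int_x^{x+1} h(t)\,dt)}
#' with the integral available in closed form,
#' \eqn{\int_x^{x+1} h = a + b c^x (c - 1)/\log c}.
#'
#' The defaults are a deliberately simple synthetic stand-in for a
#' contemporary Southern-European all-cause mortality schedule (life
#' expectancy at birth close to 80 years); supply a real national table via
#' [read_life_table()] whenever one is available.
#'
#' @param a Background (Makeham) hazard, per year; `a >= 0`.
#' @param b Senescent hazard scale at age 0; `b > 0`.
#' @param c Senescent rate of increase per year of age; `c > 1`.
#' @param max_age Maximum age of the table (at least 120). `qx` is forced to
#'   1 at `max_age` to close the table.
#'
#' @return A [life_table()].
#' @export
#' @examples
#' lt <- gompertz_makeham_table()
#' life_expectancy(lt)
gompertz_makeham_table <- function(a = 5e-4, b = 3.5e-5, c = 1.095,
                                   max_age = 120L) {
  for (nm in c("a", "b", "c", "max_age")) {
    v <- get(nm, inherits = FALSE)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("parameter `%s` must be a single finite number", nm),
           call. = FALSE)
    }
  }
  if (a < 0) stop("parameter `a` must be >= 0", call. = FALSE)
  if (b <= 0) stop("parameter `b` must be > 0", call. = FALSE)
  if (c <= 1) stop("parameter `c` must be > 1", call. = FALSE)
  if (max_age < 120) stop("parameter `max_age` must be at least 120", call. = FALSE)
  x <- 0:as.integer(max_age)
  cum_haz <- a + b * c^x * (c - 1) / log(c)
  qx <- 1 - exp(-cum_haz)
  qx <- pmin(pmax(qx, 0), 1)
  qx[length(qx)] <- 1
  life_table(x, qx)
}

#' Per-cycle death probability with an age shift
#'
#' Look up the annual death probability for a person of a given age, after
#' adding `age_shift` years. The shift operationalises a stated reduction in
#' life expectancy relative to the general population (10 years for
#' achondroplasia): the mortality experienced at age \eqn{a} is the general
#' population's `qx` at age \eqn{a + } `age_shift`.
#'
#' @param table A [life_table()].
#' @param age Integer age(s) in years (vectorised).
#' @param age_shift Non-negative integer number of years added to the age
#'   before the lookup. Default 0 (general-population mortality).
#'
#' @return Numeric vector of death probabilities, one per `age`.
#' @export
#' @examples
#' lt <- gompertz_makeham_table()
#' dp_at(lt, 50, age_shift = 10) == lt$qx[lt$age == 60]
dp_at <- function(table, age, age_shift = 0L) {
  stopifnot(inherits(table, "life_table"))
  if (any(age < 0)) stop("`age` must be non-negative", call. = FALSE)
  if (length(age_shift) != 1L || age_shift < 0) {
    stop("`age_shift` must be a single non-negative integer", call. = FALSE)
  }
  target <- as.integer(age) + as.integer(age_shift)
  mx <- max(table$age)
  if (any(target > mx)) {
    a <- age[which(target > mx)[1L]]
    stop(sprintf(
      "life table ends at age %d but age %d with shift %d requires age %d",
      mx, a, as.integer(age_shift), a + as.integer(age_shift)),
      call. = FALSE)
  }
  table$qx[target + 1L]
}

#' Curtate life expectancy from a life table
#'
#' Expected number of whole years lived beyond `age`, computed as the sum of
#' the survival curve implied by `qx`: \eqn{e_x = \sum_{k \ge 1}
#' \prod_{j=0}^{k-1} (1 - q_{x+j})}.
#'
#' @inheritParams dp_at
#' @param age Age at which the expectation is taken (default 0, i.e. at
#'   birth).
#' @return A single number of years.
#' @export
life_expectancy <- function(table, age = 0L, age_shift = 0L) {
  stopifnot(inherits(table, "life_table"))
  start <- as.integer(age) + as.integer(age_shift)
  mx <- max(table$age)
  if (start > mx) {
    stop(sprintf("age %d with shift %d exceeds the table maximum %d",
                 as.integer(age), as.integer(age_shift), mx), call. = FALSE)
  }
  q <- table$qx[(start + 1L):(mx + 1L)]
  sum(cumprod(1 - q))
}

#' Read / write a life table as delimited text
#'
#' The file format is two columns, `age` and `qx`, comma-separated for
#' `.csv` and tab-separated otherwise, with an optional header row. Values
#' round-trip at full double precision. Structural problems (gaps,
#' duplicated ages, probabilities outside \[0, 1\]) are rejected with the
#' offending row identified.
#'
#' @param path File path; the delimiter is chosen from the extension.
#' @return `read_life_table()` returns a [life_table()];
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("life table file not found: %s", path), call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- readLines(path, n = 1L)
  fields <- strsplit(first, sep, fixed = TRUE)[[1L]]
  header <- anyNA(suppressWarnings(as.numeric(fields[1:2])))
  df <- utils::read.table(path, header = header, sep = sep,
                          colClasses = "numeric",
                          col.names = c("age", "qx"))
  life_table(df$age, df$qx)
}

#' @rdname read_life_table
#' @param table A [life_table()] to write.
#' @export
write_life_table <- function(table, path) {
  stopifnot(inherits(table, "life_table"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- c(paste("age", "qx", sep = sep),
             sprintf("%d%s%.17g", table$age, sep, table$qx))
  writeLines(lines, path)
  invisible(path)
}
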