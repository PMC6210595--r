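#' Month arithmetic for YYYYMM periods
#'
#' Prescribing extracts identify months as integer `YYYYMM` periods (the NHS
#' Digital dialect). Internally every computation uses a monotone month index
#' (`year * 12 + month - 1`) so that subtracting two indices gives the number
#' of calendar months between them.
#'
#' @param period integer or character vector of `YYYYMM` periods
#'   (e.g. `201509`, `"2015-09"` is also accepted).
#' @return `month_index()` returns an integer month index;
#'   `index_to_period()` its inverse (integer `YYYYMM`);
#'   `period_seq()` an integer vector of consecutive `YYYYMM` periods.
#' @examples
#' month_index(201510) - month_index(201509) # 1
#' period_seq(201411, 201502)
#' @export
month_index <- function(period) {
  p <- period
  if (is.character(p)) p <- gsub("-", "", p)
  p <- suppressWarnings(as.integer(p))
  y <- p %/% 100L
  m <- p %% 100L
  bad <- is.na(p) | y < 1900L | y > 2200L | m < 1L | m > 12L
  if (any(bad)) {
    stop("malformed period(s): ", paste(utils::head(period[bad], 5), collapse = ", "),
         " (expected YYYYMM with month 01-12)", call. = FALSE)
  }
  y * 12L + m - 1L
}

#' @rdname month_index
#' @param index integer month index as produced by [month_index()]
#' @export
index_to_period <- function(index) {
  index <- as.integer(index)
  (index %/% 12L) * 100L + (index %% 12L) + 1L
}

#' @rdname month_index
#' @param from,to first and last `YYYYMM` period, inclusive
#' @export
period_seq <- function(from, to) {
  index_to_period(seq(month_index(from), month_index(to)))
}

# month of year (1..12) from a YYYYMM period
month_of_year <- function(period) month_index(period) %% 12L + 1L
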