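#' Physiological filter bounds for purchase intervals
#'
#' Inclusive day bounds used to retain only inter-purchase intervals
#' compatible with a normal menstrual cycle. The conventional bounds are 21
#' and 35 days.
#'
#' @param lower_bound_days,upper_bound_days inclusive integer bounds.
#' @return An object of class `periodicity_config`.
#' @export
periodicity_config <- function(lower_bound_days = 21L, upper_bound_days = 35L) {
  lower <- as.integer(lower_bound_days)
  upper <- as.integer(upper_bound_days)
  if (is.na(lower) || is.na(upper) || lower <= 0L || lower > upper) {
    stop("bounds must satisfy 0 < lower <= upper")
  }
  structure(list(lower_bound_days = lower, upper_bound_days = upper),
            class = "periodicity_config")
}

#' Inter-purchase intervals between consecutive menstrual baskets
#'
#' For every customer with at least two menstrual baskets, computes the day
#' gaps between their date-sorted consecutive menstrual baskets. Same-day
#' menstrual baskets yield a gap of 0. Customers with fewer than two
#' menstrual baskets contribute nothing.
#'
#' @param baskets flagged basket table from [build_baskets()].
#' @return A `data.table` with columns `customer_id`, `interval` (integer
#'   days), one row per consecutive pair.
#' @export
compute_intervals <- function(baskets) {
  b <- as.data.table(baskets)[has_menstrual == TRUE]
  if (nrow(b) == 0L) {
    return(data.table(customer_id = character(), interval = integer()))
  }
  setorder(b, customer_id, date)
  out <- b[, if (.N >= 2L) .(interval = as.integer(diff(as.integer(date)))),
           by = customer_id]
  out[, customer_id := as.character(customer_id)]
  out[]
}

#' Apply the physiological filter to intervals
#'
#' Retains intervals `x` with `lower <= x <= upper` (inclusive bounds),
#' preserving order. Filtering is idempotent.
#'
#' @param intervals integer vector of day gaps, or the `data.table` returned
#'   by [compute_intervals()] (filtered on its `interval` column).
#' @param config a [periodicity_config()].
#' @return Same shape as the input, restricted to retained intervals.
#' @export
filter_intervals <- function(intervals, config = periodicity_config()) {
  stopifnot(inherits(config, "periodicity_config"))
  lo <- config$lower_bound_days
  hi <- config$upper_bound_days
  if (is.data.frame(intervals)) {
    dt <- as.data.table(intervals)
    return(dt[interval >= lo & interval <= hi])
  }
  intervals[intervals >= lo & intervals <= hi]
}

#' Summary statistics of purchase intervals
#'
#' Pooled summary across all supplied intervals: count, integer mode (ties
#' broken to the smallest value), arithmetic mean, population standard
#' deviation, median, minimum and maximum.
#'
#' @param intervals integer vector of day gaps or the output of
#'   [compute_intervals()].
#' @return A list of class `interval_summary` with fields `n`, `mode_days`,
#'   `mean_days`, `sd_days`, `median_days`, `min_days`, `max_days`; when the
#'   input is empty, `n = 0` and `empty = TRUE` with all statistics `NA`.
#' @export
interval_summary <- function(intervals) {
  x <- if (is.data.frame(intervals)) as.data.table(intervals)$interval
       else intervals
  if (length(x) == 0L) {
    return(structure(list(n = 0L, mode_days = NA_integer_,
                          mean_days = NA_real_, sd_days = NA_real_,
                          median_days = NA_real_, min_days = NA_integer_,
                          max_days = NA_integer_, empty = TRUE),
                     class = "interval_summary"))
  }
  structure(list(
    n = length(x),
    mode_days = int_mode(x),
    mean_days = mean(x),
    sd_days = pop_sd(x),
    median_days = median(x),
    min_days = min(x),
    max_days = max(x),
    empty = FALSE
  ), class = "interval_summary")
}

#' @export
print.interval_summary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("Interval summary: no intervals\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("Interval summary (n = %d): mode %d, mean %.2f ",
                     "± %.2f, median %g, range [%d, %d] days\n"),
              x$n, x$mode_days, x$mean_days, x$sd_days, x$median_days,
              x$min_days, x$max_days))
  invisible(x)
}

#' Full periodicity validation of the menstruation proxy
#'
#' Extracts menstrual inter-purchase intervals, summarises them before and
#' after the physiological filter, and reports both blocks. A periodic
#' menstruation signal shows up as a filtered mode/median at the cycle
#' length (about 28 days) while the unfiltered summary carries a long right
#' tail from missed trips and stock-ups.
#'
#' @param baskets flagged basket table.
#' @param config a [periodicity_config()].
#' @return A list with `unfiltered` and `filtered` [interval_summary()]
#'   blocks, the `config`, and `histogram` (a `data.table` of retained
#'   interval counts by day).
#' @export
periodicity_validation <- function(baskets, config = periodicity_config()) {
  iv <- compute_intervals(baskets)
  kept <- filter_intervals(iv, config)
  hist_dt <- if (nrow(kept) > 0) {
    kept[, .N, by = .(interval)][order(interval)]
  } else {
    data.table(interval = integer(), N = integer())
  }
  list(unfiltered = interval_summary(iv),
       filtered = interval_summary(kept),
       config = config,
       histogram = hist_dt)
}
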