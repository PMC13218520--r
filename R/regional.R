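#' Aggregate LSOA deprivation features to MSOA level
#'
#' Averages each numeric feature across the LSOAs of each MSOA (unweighted
#' arithmetic mean), mirroring the standard way LSOA-resolution deprivation
#' statistics are carried up to the MSOA geography.
#'
#' @param lsoa_table data.frame with `msoa_id`, `lsoa_id` and numeric
#'   feature columns.
#' @return A `data.table`, one row per MSOA, with the mean of every numeric
#'   feature.
#' @export
lsoa_to_msoa <- function(lsoa_table) {
  dt <- as.data.table(lsoa_table)
  if (!"msoa_id" %in% names(dt)) stop("`lsoa_table` must have `msoa_id`")
  feature_cols <- names(dt)[vapply(dt, is.numeric, logical(1))]
  if (length(feature_cols) == 0L) stop("no numeric feature columns found")
  out <- dt[, lapply(.SD, mean), by = msoa_id, .SDcols = feature_cols]
  setorder(out, msoa_id)
  out[]
}

#' Proxy measures pooled to MSOA level
#'
#' Assigns each basket to the MSOA of its store and computes the proxy
#' measures over the pooled baskets of each MSOA (stores in the same MSOA
#' are aggregated by pooling baskets, not by averaging per-store
#' probabilities, so the law of total probability holds exactly within each
#' MSOA). Baskets from stores with no MSOA mapping are excluded with a
#' message.
#'
#' @param baskets flagged basket table.
#' @param stores data.frame lookup with `store_id`, `msoa_id`.
#' @return A `data.table`, one row per MSOA with at least one basket:
#'   `msoa_id`, `total_transactions`, `p_m`, `p_p`, `p_p_given_m`,
#'   `p_p_given_notm`, `mpr`, `conditionals_defined`, `mpr_defined`.
#' @export
msoa_proxies <- function(baskets, stores) {
  b <- as.data.table(baskets)
  st <- as.data.table(stores)[, .(store_id = as.character(store_id), msoa_id)]
  b <- merge(b[, store_id := as.character(store_id)], st, by = "store_id",
             all.x = TRUE, sort = FALSE)
  n_unmapped <- sum(is.na(b$msoa_id))
  if (n_unmapped > 0) {
    message(n_unmapped, " basket(s) from stores with no MSOA mapping excluded")
    b <- b[!is.na(msoa_id)]
  }
  out <- b[, {
    n <- .N
    n_m <- sum(has_menstrual)
    n_p <- sum(has_pain)
    n_mp <- sum(has_menstrual & has_pain)
    p_p_given_m <- if (n_m > 0) n_mp / n_m else NA_real_
    p_p_given_notm <- if (n - n_m > 0) (n_p - n_mp) / (n - n_m) else NA_real_
    cond_def <- n_m > 0 && (n - n_m) > 0
    mpr_def <- cond_def && p_p_given_notm > 0
    .(total_transactions = n,
      p_m = n_m / n,
      p_p = n_p / n,
      p_p_given_m = p_p_given_m,
      p_p_given_notm = p_p_given_notm,
      mpr = if (mpr_def) p_p_given_m / p_p_given_notm else NA_real_,
      conditionals_defined = cond_def,
      mpr_defined = mpr_def)
  }, by = msoa_id]
  setorder(out, msoa_id)
  out[]
}

#' Build the full MSOA region table
#'
#' Joins the pooled MSOA proxy measures to the MSOA-level deprivation
#' features (see [lsoa_to_msoa()]).
#'
#' @param baskets flagged basket table.
#' @param lsoa_table LSOA deprivation table.
#' @param stores store-to-MSOA lookup.
#' @return A `data.table`, one row per MSOA with proxies and features.
#' @export
region_table <- function(baskets, lsoa_table, stores) {
  proxies <- msoa_proxies(baskets, stores)
  features <- lsoa_to_msoa(lsoa_table)
  merge(proxies, features, by = "msoa_id")
}

#' Correlation grid of deprivation features against proxy measures
#'
#' Pearson correlation (with two-sided p-value) of each feature column
#' against total transactions, P(M), P(P) and P(P|M) across MSOAs. MSOAs
#' with an undefined value for a measure are excluded pairwise for that
#' cell; a zero-variance column gives an `NA` (flagged undefined) cell.
#'
#' @param regions MSOA table from [region_table()].
#' @param features feature column names (default: the deprivation and
#'   population columns present).
#' @return A long-format `data.table`: `feature`, `measure`, `r`, `p_value`,
#'   `n`, `defined`.
#' @export
correlation_table <- function(regions,
                              features = c("imd_score", "household_income",
                                           "electricity_spend",
                                           "jobseekers_claimants",
                                           "room_occupancy", "population_all",
                                           "population_children",
                                           "population_working",
                                           "population_older")) {
  dt <- as.data.table(regions)
  features <- intersect(features, names(dt))
  if (length(features) == 0L) stop("none of the feature columns are present")
  measures <- c(total_transactions = "total_transactions", p_m = "p_m",
                p_p = "p_p", p_p_given_m = "p_p_given_m")

  grid <- CJ(feature = features, measure = names(measures), sorted = FALSE)
  res <- grid[, {
    x <- dt[[feature]]
    y <- dt[[measures[[measure]]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      .(r = NA_real_, p_value = NA_real_, n = sum(ok), defined = FALSE)
    } else {
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      .(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
        defined = TRUE)
    }
  }, by = .(feature, measure)]
  res[]
}

#' Income gradient in area-level menstrual-pain propensity
#'
#' Groups MSOAs into income quantile groups (deciles by default) by a chosen
#' income column and reports the relative difference in mean P(P|M) between
#' the top and bottom groups, as a percentage:
#' `100 * (top mean - bottom mean) / top mean`. A positive value means
#' lower-income areas are less likely to record menstrual-pain co-purchases.
#'
#' @param regions MSOA table with defined `p_p_given_m` and an income column.
#' @param income_col name of the income column.
#' @param n_groups number of quantile groups (default 10, i.e. deciles).
#' @return A list with `gradient_pct`, `top_mean`, `bottom_mean`,
#'   `n_top`, `n_bottom`.
#' @export
income_gradient <- function(regions, income_col = "household_income",
                            n_groups = 10L) {
  dt <- as.data.table(regions)
  if (!income_col %in% names(dt)) stop("missing income column: ", income_col)
  dt <- dt[is.finite(p_p_given_m) & is.finite(get(income_col))]
  if (nrow(dt) < n_groups) {
    stop("need at least ", n_groups, " MSOAs with defined P(P|M) to form ",
         n_groups, " income groups")
  }
  grp <- ceiling(n_groups * frank(dt[[income_col]], ties.method = "first") /
                   nrow(dt))
  bottom <- dt$p_p_given_m[grp == 1L]
  top <- dt$p_p_given_m[grp == n_groups]
  if (length(bottom) == 0L || length(top) == 0L) {
    stop("empty income group; cannot compute gradient")
  }
  top_mean <- mean(top)
  bottom_mean <- mean(bottom)
  list(gradient_pct = 100 * (top_mean - bottom_mean) / top_mean,
       top_mean = top_mean, bottom_mean = bottom_mean,
       n_top = length(top), n_bottom = length(bottom))
}
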