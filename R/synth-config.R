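#' Configuration for the synthetic transaction-log simulator
#'
#' Bundles every knob of the simulator into a validated object. The defaults
#' are calibrated so that the headline statistics of the downstream analysis
#' are recoverable: the per-basket pain-inclusion probabilities give a true
#' Menstrual Pain Purchasing Ratio of `0.50 / 0.1282` (about 3.9) within the
#' menstrual-pain customer set, 26.7% of menstrual customers are susceptible
#' to pain co-purchasing, cycle lengths follow a normal distribution with mean
#' 28 and sd 3.8 days truncated to the physiological 21--35 day range, and
#' area-level menstrual-pain propensity falls by 32% from the top to the
#' bottom household-income decile.
#'
#' @param n_customers number of loyalty-card customers to simulate.
#' @param n_msoas number of MSOAs (middle-layer small areas).
#' @param lsoas_per_msoa integer vector of candidate LSOA counts per MSOA;
#'   one value is drawn uniformly per MSOA (default 4:5, the typical nesting).
#' @param stores_per_msoa stores hosted by each MSOA.
#' @param period_start,period_end study period (Date or "YYYY-MM-DD"); the
#'   default spans two simulated years.
#' @param menstruating_fraction fraction of customers who menstruate and
#'   purchase menstrual products.
#' @param cycle_mean_days,cycle_sd_days menstrual cycle length distribution
#'   (days), truncated to `[21, 35]` when sampled.
#' @param purchase_miss_prob probability that a cycle onset produces no
#'   recorded menstrual purchase (shopping elsewhere, skipping a trip).
#' @param stockup_prob probability that an ordinary (non-onset) shopping trip
#'   additionally includes menstrual products (stocking up).
#' @param trip_rate_per_week expected ordinary shopping trips per week.
#' @param p_pain_given_menstrual probability that a menstrual basket of a
#'   susceptible customer also contains a pain product (before the area
#'   income scaling).
#' @param p_pain_given_nonmenstrual probability that a non-menstrual basket
#'   contains a pain product.
#' @param menstrual_pain_fraction fraction of menstruating customers whose
#'   menstrual baskets can contain pain products at all (customer-level
#'   susceptibility; the rest co-purchase pain only in non-menstrual baskets).
#' @param income_gradient relative reduction in menstrual-pain co-purchase
#'   propensity from the top to the bottom MSOA income decile (0.32 = 32%).
#' @param n_products named integer vector of catalogue sizes per category;
#'   names must include tampon, sanitary pad, Pain Relief Oral, Topical Pain
#'   Relief and other.
#' @param price_frequency_corr_pain,price_frequency_corr_menstrual target
#'   (negative) correlations between unit price and purchase popularity; the
#'   pain correlation is stronger in magnitude by default.
#' @param seed integer seed controlling all simulator randomness.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [true_parameters()], [simulate_study()]
#' @export
#' @examples
#' cfg <- simulation_config(n_customers = 200, n_msoas = 10, seed = 1)
#' true_parameters(cfg)$mpr
simulation_config <- function(n_customers = 5000L,
                              n_msoas = 100L,
                              lsoas_per_msoa = 4:5,
                              stores_per_msoa = 1L,
                              period_start = "2013-01-01",
                              period_end = "2014-12-31",
                              menstruating_fraction = 0.5,
                              cycle_mean_days = 28,
                              cycle_sd_days = 3.8,
                              purchase_miss_prob = 0.3,
                              stockup_prob = 0.05,
                              trip_rate_per_week = 0.5,
                              p_pain_given_menstrual = 0.50,
                              p_pain_given_nonmenstrual = 0.1282,
                              menstrual_pain_fraction = 0.267,
                              income_gradient = 0.32,
                              n_products = c("tampon" = 25L,
                                             "sanitary pad" = 25L,
                                             "Pain Relief Oral" = 40L,
                                             "Topical Pain Relief" = 15L,
                                             "other" = 150L),
                              price_frequency_corr_pain = -0.7,
                              price_frequency_corr_menstrual = -0.35,
                              seed = 1L) {
  assert_prob(menstruating_fraction, "menstruating_fraction")
  assert_prob(purchase_miss_prob, "purchase_miss_prob")
  assert_prob(stockup_prob, "stockup_prob")
  assert_prob(p_pain_given_menstrual, "p_pain_given_menstrual")
  assert_prob(p_pain_given_nonmenstrual, "p_pain_given_nonmenstrual")
  assert_prob(menstrual_pain_fraction, "menstrual_pain_fraction")
  if (p_pain_given_nonmenstrual <= 0) {
    stop("`p_pain_given_nonmenstrual` must be > 0 (the MPR denominator)")
  }
  if (cycle_mean_days < 21 || cycle_mean_days > 35) {
    stop("`cycle_mean_days` must lie within the physiological range [21, 35]")
  }
  if (cycle_sd_days < 0) stop("`cycle_sd_days` must be non-negative")
  if (income_gradient < 0 || income_gradient >= 1) {
    stop("`income_gradient` must lie in [0, 1)")
  }
  required_cats <- c("tampon", "sanitary pad", "Pain Relief Oral",
                     "Topical Pain Relief", "other")
  if (!all(required_cats %in% names(n_products)) ||
      any(n_products[required_cats] < 1L)) {
    stop("`n_products` must give a count >= 1 for each of: ",
         paste(required_cats, collapse = ", "))
  }
  period_start <- as.Date(period_start)
  period_end <- as.Date(period_end)
  if (is.na(period_start) || is.na(period_end) || period_end <= period_start) {
    stop("`period_end` must be a valid date after `period_start`")
  }
  if (as.integer(period_end - period_start) < 35) {
    stop("study period shorter than one menstrual cycle: no intervals derivable")
  }
  if (n_msoas < 2L) stop("`n_msoas` must be >= 2")
  if (n_msoas < 10L && income_gradient > 0) {
    warning("fewer than 10 MSOAs with a non-zero income gradient: ",
            "income deciles are degenerate")
  }
  if (trip_rate_per_week <= 0) stop("`trip_rate_per_week` must be positive")

  cfg <- list(
    n_customers = as.integer(n_customers),
    n_msoas = as.integer(n_msoas),
    lsoas_per_msoa = as.integer(lsoas_per_msoa),
    stores_per_msoa = as.integer(stores_per_msoa),
    period_start = period_start,
    period_end = period_end,
    menstruating_fraction = menstruating_fraction,
    cycle_mean_days = cycle_mean_days,
    cycle_sd_days = cycle_sd_days,
    purchase_miss_prob = purchase_miss_prob,
    stockup_prob = stockup_prob,
    trip_rate_per_week = trip_rate_per_week,
    p_pain_given_menstrual = p_pain_given_menstrual,
    p_pain_given_nonmenstrual = p_pain_given_nonmenstrual,
    menstrual_pain_fraction = menstrual_pain_fraction,
    income_gradient = income_gradient,
    n_products = n_products,
    price_frequency_corr_pain = price_frequency_corr_pain,
    price_frequency_corr_menstrual = price_frequency_corr_menstrual,
    seed = as.integer(seed)
  )
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic transaction-log simulation config\n")
  cat(sprintf("  %d customers (%.0f%% menstruating), %d MSOAs, %s to %s\n",
              x$n_customers, 100 * x$menstruating_fraction, x$n_msoas,
              format(x$period_start), format(x$period_end)))
  cat(sprintf("  cycle ~ N(%.1f, %.1f) days truncated to [21, 35]\n",
              x$cycle_mean_days, x$cycle_sd_days))
  cat(sprintf("  P(pain | menstrual) = %.4f, P(pain | non-menstrual) = %.4f\n",
              x$p_pain_given_menstrual, x$p_pain_given_nonmenstrual))
  cat(sprintf("  susceptible fraction = %.3f, income gradient = %.0f%%\n",
              x$menstrual_pain_fraction, 100 * x$income_gradient))
  invisible(x)
}

#' Income-decile scaling of the menstrual pain propensity
#'
#' Multiplicative factors applied to `p_pain_given_menstrual` by MSOA
#' household-income decile (1 = poorest, 10 = richest). The ramp is linear in
#' decile rank, normalised to unit mean so that the population-average
#' conditional probability (and hence the true MPR) is unchanged by the
#' gradient, while the bottom decile sits `income_gradient` below the top in
#' relative terms.
#'
#' @param income_gradient relative top-to-bottom reduction in [0, 1).
#' @return numeric vector of length 10, mean exactly 1.
#' @keywords internal
decile_scaling <- function(income_gradient) {
  g <- income_gradient
  s1 <- 2 * (1 - g) / (2 - g)
  s10 <- 2 / (2 - g)
  s1 + (s10 - s1) * (0:9) / 9
}

#' Deterministic ground truth implied by a simulation config
#'
#' Computes, by closed-form arithmetic and before any sampling, the parameter
#' values that the analysis pipeline should recover from data generated under
#' `config`: the true MPR and conditional pain probabilities (within the
#' menstrual-pain customer set), the truncated cycle-length distribution, the
#' expected fraction of menstrual customers with at least one menstrual-pain
#' basket, the per-decile income effect and the implied income gradient.
#'
#' @param config a [simulation_config()].
#' @return A list of class `ground_truth`.
#' @export
true_parameters <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  s <- decile_scaling(config$income_gradient)
  tm <- truncnorm_moments(config$cycle_mean_days, config$cycle_sd_days, 21, 35)
  days <- as.integer(config$period_end - config$period_start)

  # expected menstrual baskets per menstruating customer: onsets that produce
  # a purchase, plus stock-ups at ordinary trips
  n_cycles <- days / tm$mean
  n_trips <- config$trip_rate_per_week * days / 7
  m_baskets <- n_cycles * (1 - config$purchase_miss_prob) +
    n_trips * config$stockup_prob

  # a susceptible customer escapes the menstrual-pain set only if every one of
  # their menstrual baskets omits pain; average the escape probability over
  # income deciles (customers are uniform across MSOAs, MSOAs across deciles)
  p_eff <- pmin(1, config$p_pain_given_menstrual * s)
  p_escape <- mean((1 - p_eff)^m_baskets)
  mp_fraction <- config$menstrual_pain_fraction * (1 - p_escape)

  structure(list(
    mpr = config$p_pain_given_menstrual / config$p_pain_given_nonmenstrual,
    p_pain_given_menstrual = config$p_pain_given_menstrual,
    p_pain_given_nonmenstrual = config$p_pain_given_nonmenstrual,
    cycle_mean_days = config$cycle_mean_days,
    cycle_sd_days = config$cycle_sd_days,
    cycle_truncated_mean = tm$mean,
    cycle_truncated_sd = tm$sd,
    expected_menstrual_baskets = m_baskets,
    mp_customer_fraction = mp_fraction,
    decile_effect = p_eff,
    income_gradient_pct = 100 * config$income_gradient
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth implied by the simulation config\n")
  cat(sprintf("  MPR = %.4f  (P(P|M) = %.4f / P(P|not M) = %.4f)\n",
              x$mpr, x$p_pain_given_menstrual, x$p_pain_given_nonmenstrual))
  cat(sprintf("  menstrual-pain customer fraction = %.4f\n",
              x$mp_customer_fraction))
  cat(sprintf("  income gradient = %.1f%%\n", x$income_gradient_pct))
  cat(sprintf("  truncated cycle: mean %.2f, sd %.2f days\n",
              x$cycle_truncated_mean, x$cycle_truncated_sd))
  invisible(x)
}
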