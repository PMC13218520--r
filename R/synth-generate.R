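# Each generator draws from its own deterministic stream derived from
# config$seed, so catalogue/regions/transactions are independently
# reproducible and the caller's RNG state is left untouched.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate a synthetic product catalogue
#'
#' Creates a catalogue with the five category labels the classifier expects
#' (tampon, sanitary pad, Pain Relief Oral, Topical Pain Relief, other),
#' positive unit prices, pack sizes, and latent popularity weights. Weights
#' are drawn from a Gaussian copula against log unit price so that cheaper
#' items are bought more often, with a stronger (more negative)
#' price--popularity correlation for pain items than for menstrual items.
#'
#' @param config a [simulation_config()].
#' @return A `data.table` with columns `product_id`, `description`,
#'   `category`, `unit_price`, `pack_size`, `popularity` (weights sum to 1
#'   within each of the menstrual / pain / other classes).
#' @export
generate_catalogue <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  np <- config$n_products
  with_sim_seed(derive_seed(config$seed, 101L), {
    cats <- rep(names(np), np)
    n <- length(cats)
    cls <- product_class_from_category(cats)

    # per-pack prices, lognormal within category
    base <- c("tampon" = 1.8, "sanitary pad" = 1.5, "Pain Relief Oral" = 1.2,
              "Topical Pain Relief" = 3.5, "other" = 3.0)
    unit_price <- round(exp(log(base[cats]) + rnorm(n, 0, 0.45)), 2)
    unit_price <- pmax(unit_price, 0.05)

    pack_size <- sample(c(8L, 10L, 12L, 14L, 16L, 20L, 24L, 32L, 48L), n,
                        replace = TRUE)

    rho <- c(menstrual = config$price_frequency_corr_menstrual,
             pain = config$price_frequency_corr_pain,
             other = -0.15)
    popularity <- numeric(n)
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      z <- as.numeric(scale(log(unit_price[idx])))
      if (length(idx) < 2L || all(!is.finite(z))) z <- rep(0, length(idx))
      r <- abs(rho[[cl]])
      u <- r * (-z) + sqrt(1 - r^2) * rnorm(length(idx))
      w <- exp(1.2 * u)
      popularity[idx] <- w / sum(w)
    }

    data.table(
      product_id = seq_len(n),
      description = sprintf("%s item %02d", cats,
                            unlist(lapply(np, seq_len), use.names = FALSE)),
      category = cats,
      unit_price = unit_price,
      pack_size = pack_size,
      popularity = popularity
    )
  })
}

#' Generate synthetic area deprivation tables and a store lookup
#'
#' Produces an LSOA-level deprivation table nested in MSOAs, with the feature
#' set used by the regional linkage (IMD score, weekly household income,
#' electricity spend, jobseekers claimants, room occupancy and population
#' counts), plus a store-to-MSOA lookup. Household income varies across MSOAs
#' so that income deciles are well defined; the remaining features are drawn
#' with plausible (moderate) correlations with income.
#'
#' @param config a [simulation_config()].
#' @return A list of class `sim_regions` with elements `lsoa` (LSOA feature
#'   table with `msoa_id` parent), `msoa` (MSOA id, mean household income and
#'   income decile) and `stores` (store id and MSOA).
#' @export
generate_regions <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_msoas < 2L) stop("`n_msoas` must be >= 2")
  with_sim_seed(derive_seed(config$seed, 202L), {
    nm <- config$n_msoas
    msoa_income <- pmax(rnorm(nm, 520, 110), 150)  # GBP per week
    n_lsoa <- if (length(config$lsoas_per_msoa) == 1L) {
      rep(config$lsoas_per_msoa, nm)
    } else {
      sample(config$lsoas_per_msoa, nm, replace = TRUE)
    }

    msoa_id <- sprintf("MSOA%04d", seq_len(nm))
    lsoa <- data.table(
      msoa_id = rep(msoa_id, n_lsoa),
      lsoa_id = sprintf("LSOA%05d", seq_len(sum(n_lsoa)))
    )
    inc <- pmax(rep(msoa_income, n_lsoa) + rnorm(nrow(lsoa), 0, 40), 100)
    nl <- nrow(lsoa)

    # deprivation features carry moderate income correlations (area-level
    # noise plus neighbourhood-level noise), so income stays identifiable as
    # a driver without its correlates becoming near-duplicates
    zm <- rep(as.numeric(scale(msoa_income)), n_lsoa)
    mnoise <- function(s) rep(rnorm(nm, 0, s), n_lsoa)

    lsoa[, household_income := round(inc, 2)]
    lsoa[, imd_score := round(
      pmax(25 - 2.5 * zm + mnoise(5) + rnorm(nl, 0, 3), 1), 2)]
    lsoa[, electricity_spend := round(
      pmax(55 + 2 * zm + mnoise(5) + rnorm(nl, 0, 4), 5), 2)]
    lsoa[, jobseekers_claimants := round(
      pmax(3.5 - 0.6 * zm + mnoise(1.2) + rnorm(nl, 0, 0.8), 0), 3)]
    lsoa[, room_occupancy := round(
      pmax(0.55 + 0.01 * zm + mnoise(0.04) + rnorm(nl, 0, 0.04), 0.2), 4)]
    pop <- pmax(round(rnorm(nl, 1850, 250)), 800)
    kids <- round(pop * runif(nl, 0.15, 0.22))
    older <- round(pop * pmin(pmax(0.18 - 0.008 * zm + mnoise(0.03) +
                                     rnorm(nl, 0, 0.02), 0.05), 0.4))
    lsoa[, population_all := pop]
    lsoa[, population_children := kids]
    lsoa[, population_older := older]
    lsoa[, population_working := pop - kids - older]

    msoa <- lsoa[, .(household_income = mean(household_income)), by = msoa_id]
    msoa[, income_decile := as.integer(ceiling(10 * frank(household_income,
                                                          ties.method = "first") / .N))]

    stores <- data.table(
      store_id = sprintf("S%04d", seq_len(nm * config$stores_per_msoa)),
      msoa_id = rep(msoa_id, each = config$stores_per_msoa)
    )
    structure(list(lsoa = lsoa[], msoa = msoa[], stores = stores),
              class = "sim_regions")
  })
}

#' Generate a synthetic transaction log
#'
#' Simulates itemised loyalty-card transactions over the study period. Each
#' menstruating customer has cycle onsets at intervals drawn from the
#' truncated cycle-length distribution on `[21, 35]` days; an onset yields a
#' recorded menstrual basket with probability `1 - purchase_miss_prob`
#' (missed purchases emulate shopping at competing retailers). Ordinary
#' shopping trips arrive at `trip_rate_per_week`, and each can carry a
#' menstrual stock-up with probability `stockup_prob`. A menstrual basket of
#' a pain-susceptible customer includes at least one pain product with
#' probability `p_pain_given_menstrual` scaled by the customer's MSOA income
#' decile; every non-menstrual basket includes one with probability
#' `p_pain_given_nonmenstrual`.
#'
#' @param config a [simulation_config()].
#' @param catalogue output of [generate_catalogue()].
#' @param regions output of [generate_regions()].
#' @return A `data.table` transaction log sorted by customer then date, with
#'   columns `customer_id`, `basket_id`, `date`, `store_id`, `product_id`,
#'   `quantity`, `unit_price`.
#' @export
generate_transactions <- function(config, catalogue, regions) {
  stopifnot(inherits(config, "simulation_config"),
            is.data.frame(catalogue), inherits(regions, "sim_regions"))
  n_days <- as.integer(config$period_end - config$period_start)
  if (n_days < 35) stop("study period shorter than one menstrual cycle")

  with_sim_seed(derive_seed(config$seed, 303L), {
    scaling <- decile_scaling(config$income_gradient)

    ## -- customers ---------------------------------------------------------
    n <- config$n_customers
    stores <- regions$stores
    cust <- data.table(
      customer_id = seq_len(n),
      store_id = stores$store_id[sample.int(nrow(stores), n, replace = TRUE)]
    )
    cust <- merge(cust, stores, by = "store_id", sort = FALSE)
    cust <- merge(cust, regions$msoa[, .(msoa_id, income_decile)],
                  by = "msoa_id", sort = FALSE)
    cust[, menstruating := runif(.N) < config$menstruating_fraction]
    cust[, susceptible := menstruating &
           runif(.N) < config$menstrual_pain_fraction]
    setkey(cust, customer_id)

    ## -- cycle onsets for menstruating customers ---------------------------
    mens <- cust[menstruating == TRUE, customer_id]
    onset_dt <- NULL
    if (length(mens) > 0) {
      nm <- length(mens)
      max_cycles <- as.integer(ceiling(n_days / 21)) + 2L
      iv <- matrix(
        as.integer(round(rtruncnorm(nm * max_cycles, config$cycle_mean_days,
                                    config$cycle_sd_days, 21, 35))),
        nrow = nm
      )
      # uniform phase within the first cycle, then accumulate intervals
      onset <- matrix(0L, nm, max_cycles)
      onset[, 1L] <- as.integer(floor(runif(nm) * iv[, 1L]))
      for (j in 2:max_cycles) onset[, j] <- onset[, j - 1L] + iv[, j]
      keep <- onset <= n_days
      onset_dt <- data.table(
        customer_id = rep(mens, times = rowSums(keep)),
        day = as.integer(t(onset)[t(keep)]),
        onset = TRUE
      )
      # an onset becomes a recorded purchase only if the trip is not missed
      onset_dt <- onset_dt[runif(.N) >= config$purchase_miss_prob]
    }

    ## -- ordinary shopping trips -------------------------------------------
    n_trips <- rpois(n, config$trip_rate_per_week * n_days / 7)
    trip_dt <- data.table(
      customer_id = rep(cust$customer_id, n_trips),
      day = as.integer(sample.int(n_days + 1L, sum(n_trips),
                                  replace = TRUE)) - 1L,
      onset = FALSE
    )
    trip_dt <- unique(trip_dt, by = c("customer_id", "day"))

    ## -- one basket per (customer, day); onset wins a same-day collision ---
    baskets <- rbindlist(list(onset_dt, trip_dt), use.names = TRUE)
    setorder(baskets, customer_id, day, -onset)
    baskets <- unique(baskets, by = c("customer_id", "day"))
    baskets <- merge(baskets, cust, by = "customer_id", sort = FALSE)

    # stock-up: a non-onset trip of a menstruating customer can carry
    # menstrual products too
    baskets[, is_menstrual := onset |
              (menstruating & runif(.N) < config$stockup_prob)]

    ## -- pain inclusion ----------------------------------------------------
    p_eff <- pmin(1, config$p_pain_given_menstrual * scaling)
    baskets[, p_pain := fifelse(
      is_menstrual,
      fifelse(susceptible, p_eff[income_decile], 0),
      config$p_pain_given_nonmenstrual)]
    baskets[, has_pain := runif(.N) < p_pain]

    setorder(baskets, customer_id, day)
    baskets[, basket_id := .I]

    ## -- item lines --------------------------------------------------------
    cat_dt <- as.data.table(catalogue)
    cat_dt[, class := product_class_from_category(category)]
    pick <- function(cl, k) {
      pool <- cat_dt[class == cl]
      pool$product_id[sample.int(nrow(pool), k, replace = TRUE,
                                 prob = pool$popularity)]
    }
    mens_b <- baskets[is_menstrual == TRUE,
                      .(basket_id, customer_id, store_id, day)]
    pain_b <- baskets[has_pain == TRUE,
                      .(basket_id, customer_id, store_id, day)]
    # menstrual baskets carry another item ~60% of the time; ordinary trips
    # always buy something else
    oth_b <- baskets[is_menstrual == FALSE | runif(.N) < 0.6,
                     .(basket_id, customer_id, store_id, day)]
    mens_b[, product_id := pick("menstrual", .N)]
    pain_b[, product_id := pick("pain", .N)]
    oth_b[, product_id := pick("other", .N)]

    lines <- rbindlist(list(mens_b, pain_b, oth_b))
    lines[, quantity := 1L + rpois(.N, 0.25)]
    lines <- merge(lines, cat_dt[, .(product_id, unit_price)],
                   by = "product_id", sort = FALSE)
    lines[, date := config$period_start + day]

    out <- lines[, .(customer_id, basket_id, date, store_id, product_id,
                     quantity, unit_price)]
    setorder(out, customer_id, date, basket_id, product_id)
    out[]
  })
}

#' Run the full simulator
#'
#' Convenience wrapper generating catalogue, regions, transactions and the
#' deterministic ground-truth record from one config.
#'
#' @param config a [simulation_config()].
#' @return A list of class `sim_study` with elements `config`, `catalogue`,
#'   `regions`, `transactions`, `ground_truth`.
#' @export
#' @examples
#' sim <- simulate_study(simulation_config(n_customers = 100, n_msoas = 5,
#'                                         seed = 7))
#' nrow(sim$transactions)
simulate_study <- function(config) {
  catalogue <- generate_catalogue(config)
  regions <- generate_regions(config)
  transactions <- generate_transactions(config, catalogue, regions)
  structure(list(config = config,
                 catalogue = catalogue,
                 regions = regions,
                 transactions = transactions,
                 ground_truth = true_parameters(config)),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Writes `transactions.csv`, `catalogue.csv`, `regions_lsoa.csv`,
#' `stores.csv` and `ground_truth.json` into `dir` (created if needed).
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(sim$transactions, file.path(dir, "transactions.csv"))
  fwrite(sim$catalogue, file.path(dir, "catalogue.csv"))
  fwrite(sim$regions$lsoa, file.path(dir, "regions_lsoa.csv"))
  fwrite(sim$regions$stores, file.path(dir, "stores.csv"))
  jsonlite::write_json(unclass(sim$ground_truth),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
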