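test_that("catalogue respects category counts and flags menstrual products", {
  cfg <- simulation_config(
    n_customers = 10, n_msoas = 10,
    n_products = c("tampon" = 2L, "sanitary pad" = 3L,
                   "Pain Relief Oral" = 4L, "Topical Pain Relief" = 2L,
                   "other" = 5L), seed = 3)
  cat_dt <- generate_catalogue(cfg)
  expect_equal(nrow(cat_dt), 16L)
  cls <- classify_products(cat_dt)
  expect_equal(sum(cls$class == "menstrual"), 5L)
  expect_equal(sum(cls$class == "pain"), 6L)
  expect_true(all(cat_dt$unit_price > 0))
})

test_that("catalogue config without a required category is rejected", {
  expect_error(
    simulation_config(n_products = c("tampon" = 2L, "sanitary pad" = 3L,
                                     "Pain Relief Oral" = 4L,
                                     "Topical Pain Relief" = 0L,
                                     "other" = 5L)),
    "count >= 1")
})

test_that("catalogue price-popularity correlation is more negative for pain", {
  cat_dt <- generate_catalogue(simulation_config(seed = 11))
  cls <- classify_products(cat_dt)
  r_by_class <- sapply(c("menstrual", "pain"), function(cl) {
    idx <- cls$class == cl
    cor(cat_dt$unit_price[idx], cat_dt$popularity[idx])
  })
  expect_lt(r_by_class["pain"], 0)
  expect_lt(r_by_class["menstrual"], 0)
  expect_lt(r_by_class["pain"], r_by_class["menstrual"])
})

test_that("generators are bit-identical under a fixed seed", {
  cfg <- simulation_config(n_customers = 150, n_msoas = 10, seed = 99)
  expect_identical(generate_catalogue(cfg), generate_catalogue(cfg))
  r1 <- generate_regions(cfg)
  r2 <- generate_regions(cfg)
  expect_identical(r1$lsoa, r2$lsoa)
  t1 <- generate_transactions(cfg, generate_catalogue(cfg), r1)
  t2 <- generate_transactions(cfg, generate_catalogue(cfg), r2)
  expect_identical(t1, t2)
})

test_that("regions nest LSOAs in MSOAs with the full feature schema", {
  cfg <- simulation_config(n_customers = 10, n_msoas = 3,
                           lsoas_per_msoa = 4L, income_gradient = 0, seed = 5)
  reg <- generate_regions(cfg)
  expect_equal(nrow(reg$lsoa), 12L)
  expect_true(all(reg$lsoa$msoa_id %in% reg$msoa$msoa_id))
  feature_cols <- c("imd_score", "household_income", "electricity_spend",
                    "jobseekers_claimants", "room_occupancy",
                    "population_all", "population_children",
                    "population_working", "population_older")
  expect_true(all(feature_cols %in% names(reg$lsoa)))
  for (col in feature_cols) expect_true(all(is.finite(reg$lsoa[[col]])))
})

test_that("different seeds give different income draws", {
  cfg1 <- simulation_config(n_customers = 10, n_msoas = 12, seed = 1)
  cfg2 <- simulation_config(n_customers = 10, n_msoas = 12, seed = 2)
  expect_false(identical(generate_regions(cfg1)$msoa$household_income,
                         generate_regions(cfg2)$msoa$household_income))
})

test_that("fewer than 10 MSOAs with a gradient warns of degenerate deciles", {
  expect_warning(simulation_config(n_msoas = 5, income_gradient = 0.32),
                 "degenerate")
})

test_that("noise-free limit gives exactly 28-day menstrual purchase gaps", {
  cfg <- simulation_config(
    n_customers = 60, n_msoas = 10, menstruating_fraction = 1,
    cycle_sd_days = 0, purchase_miss_prob = 0, stockup_prob = 0,
    income_gradient = 0, seed = 8)
  sim <- simulate_study(cfg)
  b <- build_baskets(sim$transactions, classify_products(sim$catalogue))
  iv <- compute_intervals(b)
  expect_gt(nrow(iv), 0)
  expect_true(all(iv$interval == 28L))
})

test_that("inter-onset gaps stay inside [21, 35] before miss/stock-up noise", {
  cfg <- simulation_config(
    n_customers = 120, n_msoas = 10, menstruating_fraction = 1,
    purchase_miss_prob = 0, stockup_prob = 0, seed = 13)
  sim <- simulate_study(cfg)
  b <- build_baskets(sim$transactions, classify_products(sim$catalogue))
  iv <- compute_intervals(b)
  expect_true(all(iv$interval >= 21L & iv$interval <= 35L))
})

test_that("a study period shorter than one cycle is refused", {
  expect_error(simulation_config(period_start = "2013-01-01",
                                 period_end = "2013-01-20"),
               "shorter than one")
})

test_that("ground truth is closed-form arithmetic on the config", {
  gt <- true_parameters(simulation_config())
  expect_equal(gt$mpr, 0.50 / 0.1282)
  expect_equal(gt$income_gradient_pct, 32)
  # susceptible customers almost surely record a menstrual-pain basket over
  # two years, so the set fraction sits essentially at the susceptibility
  expect_equal(gt$mp_customer_fraction, 0.267, tolerance = 1e-3)
  expect_equal(mean(gt$decile_effect) / 0.5, 1, tolerance = 1e-12)
  expect_equal(gt$decile_effect[1] / gt$decile_effect[10], 1 - 0.32,
               tolerance = 1e-12)

  flat <- true_parameters(simulation_config(income_gradient = 0))
  expect_true(all(flat$decile_effect == flat$decile_effect[1]))

  indep <- true_parameters(simulation_config(
    p_pain_given_menstrual = 0.1282, p_pain_given_nonmenstrual = 0.1282))
  expect_equal(indep$mpr, 1)
})

test_that("conditional pain frequencies converge to configured values", {
  st <- default_study()
  px_mp <- compute_proxies(st$baskets, customers = st$sets$menstrual_pain)
  n_m <- round(px_mp$n_baskets * px_mp$p_m)
  n_nm <- px_mp$n_baskets - n_m
  # non-menstrual baskets are homogeneous Bernoulli(p)
  se_nm <- sqrt(0.1282 * (1 - 0.1282) / n_nm)
  expect_lt(abs(px_mp$p_p_given_notm - 0.1282), 3 * se_nm)
  # menstrual baskets cluster by customer income decile; include the
  # between-customer spread of the decile scaling in the standard error
  n_cust <- length(st$sets$menstrual_pain)
  se_m <- sqrt(0.25 / n_m + var(0.5 * decile_scaling(0.32)) / n_cust)
  expect_lt(abs(px_mp$p_p_given_m - 0.5), 3 * se_m)
})

test_that("simulated tables round-trip losslessly through the ingest readers", {
  cfg <- simulation_config(n_customers = 120, n_msoas = 10, seed = 21)
  sim <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  tx <- read_transactions(file.path(dir, "transactions.csv"))
  expect_equal(attr(tx, "n_rejected"), 0L)
  expect_equal(nrow(tx), nrow(sim$transactions))
  expect_equal(tx$date, sim$transactions$date)
  expect_equal(tx$quantity, sim$transactions$quantity)
  expect_equal(tx$unit_price, sim$transactions$unit_price)
  expect_equal(as.integer(tx$customer_id), sim$transactions$customer_id)
})
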