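test_that("LSOA features aggregate to MSOAs by unweighted means", {
  lsoa <- data.frame(
    msoa_id = c("A", "A", "A", "A", "B"),
    lsoa_id = paste0("L", 1:5),
    household_income = c(10, 20, 30, 40, 99),
    imd_score = c(1, 2, 3, 4, 7))
  agg <- lsoa_to_msoa(lsoa)
  expect_equal(agg[agg$msoa_id == "A"]$household_income, 25)
  expect_equal(agg[agg$msoa_id == "B"]$household_income, 99)  # pass-through
  expect_equal(agg[agg$msoa_id == "A"]$imd_score, 2.5)
})

test_that("aggregation matches a brute-force group-mean oracle", {
  withr::local_seed(5)
  lsoa <- data.frame(
    msoa_id = sample(LETTERS[1:6], 40, replace = TRUE),
    lsoa_id = paste0("L", 1:40),
    f1 = rnorm(40), f2 = runif(40))
  agg <- lsoa_to_msoa(lsoa)
  for (m in unique(lsoa$msoa_id)) {
    expect_equal(agg[agg$msoa_id == m]$f1, mean(lsoa$f1[lsoa$msoa_id == m]))
    expect_equal(agg[agg$msoa_id == m]$f2, mean(lsoa$f2[lsoa$msoa_id == m]))
  }
})

test_that("an MSOA with one store reproduces that store's proxies", {
  b <- make_baskets(has_menstrual = c(TRUE, TRUE, FALSE, FALSE),
                    has_pain = c(TRUE, FALSE, TRUE, FALSE))
  stores <- data.frame(store_id = "s1", msoa_id = "M1")
  mp <- msoa_proxies(b, stores)
  px <- compute_proxies(b)
  expect_equal(mp$p_m, px$p_m)
  expect_equal(mp$p_p_given_m, px$p_p_given_m)
  expect_equal(mp$mpr, px$mpr)
  expect_equal(mp$total_transactions, px$n_baskets)
})

test_that("stores in one MSOA are pooled, not averaged", {
  # store A: 1 menstrual basket with pain; store B: 3 menstrual, none with
  # pain => pooled P(P|M) = 1/4, averaged would be (1 + 0)/2
  b <- make_baskets(
    has_menstrual = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    has_pain = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE),
    store_id = c("sA", "sA", "sB", "sB", "sB", "sB"),
    customer_id = paste0("c", 1:6))
  stores <- data.frame(store_id = c("sA", "sB"), msoa_id = "M1")
  mp <- msoa_proxies(b, stores)
  pooled <- compute_proxies(b)
  expect_equal(mp$p_p_given_m, 1 / 4)
  expect_equal(mp$p_p_given_m, pooled$p_p_given_m)
  per_store_mean <- mean(c(1, 0))
  expect_false(isTRUE(all.equal(mp$p_p_given_m, per_store_mean)))
})

test_that("pooling invariant holds exactly on simulated data", {
  st <- default_study()
  stores <- st$sim$regions$stores
  mp <- msoa_proxies(st$baskets, stores)
  target_msoa <- mp$msoa_id[which.max(mp$total_transactions)]
  member_stores <- stores$store_id[stores$msoa_id == target_msoa]
  pooled <- compute_proxies(st$baskets[st$baskets$store_id %in% member_stores])
  row <- mp[mp$msoa_id == target_msoa]
  expect_identical(row$total_transactions, pooled$n_baskets)
  expect_identical(row$p_m, pooled$p_m)
  expect_identical(row$p_p_given_m, pooled$p_p_given_m)
})

test_that("MSOAs without menstrual baskets are flagged undefined", {
  b <- make_baskets(has_menstrual = c(FALSE, FALSE), has_pain = c(TRUE, FALSE),
                    store_id = c("s1", "s1"), customer_id = c("c1", "c2"))
  mp <- msoa_proxies(b, data.frame(store_id = "s1", msoa_id = "M1"))
  expect_false(mp$conditionals_defined)
  expect_true(is.na(mp$p_p_given_m))
})

test_that("baskets from unmapped stores are excluded with a message", {
  b <- make_baskets(has_menstrual = c(TRUE, FALSE), has_pain = c(TRUE, FALSE),
                    store_id = c("s1", "s9"), customer_id = c("c1", "c2"))
  expect_message(
    mp <- msoa_proxies(b, data.frame(store_id = "s1", msoa_id = "M1")),
    "no MSOA mapping")
  expect_equal(sum(mp$total_transactions), 1L)
})

test_that("correlation grid matches hand-computed Pearson values", {
  regions <- data.table::data.table(
    msoa_id = c("A", "B", "C"),
    total_transactions = c(1L, 2L, 3L),
    p_m = c(0.1, 0.2, 0.3), p_p = c(0.2, 0.2, 0.2),
    p_p_given_m = c(0.5, 0.4, 0.3), p_p_given_notm = 0.1,
    mpr = 1, conditionals_defined = TRUE, mpr_defined = TRUE,
    imd_score = c(0.1, 0.2, 0.3),       # identical to p_m => r = 1
    household_income = c(1, 3, 2))      # vs p_m [1,2,3] => r = 0.5
  ct <- correlation_table(regions,
                          features = c("imd_score", "household_income"))
  expect_equal(ct[ct$feature == "imd_score" & ct$measure == "p_m"]$r, 1)
  expect_equal(ct[ct$feature == "household_income" & ct$measure == "p_m"]$r,
               0.5)
  expect_true(all(abs(ct$r[ct$defined]) <= 1))
})

test_that("zero-variance columns yield flagged undefined correlations", {
  regions <- data.table::data.table(
    msoa_id = c("A", "B", "C"), total_transactions = c(1L, 2L, 3L),
    p_m = c(0.1, 0.2, 0.3), p_p = c(0.2, 0.2, 0.2),
    p_p_given_m = c(0.5, 0.4, 0.3),
    flat_feature = c(1, 1, 1))
  ct <- correlation_table(regions, features = "flat_feature")
  expect_true(all(!ct$defined))
  expect_true(all(is.na(ct$r)))
  # p_p has zero variance too: undefined even for a varying feature
  ct2 <- correlation_table(regions, features = "p_m")
  expect_false(ct2[ct2$measure == "p_p"]$defined)
})

test_that("income gradient matches decile-mean arithmetic", {
  regions <- data.table::data.table(
    msoa_id = sprintf("M%02d", 1:10),
    household_income = 1:10,
    p_p_given_m = c(0.34, rep(0.42, 8), 0.50))
  g <- income_gradient(regions)
  expect_equal(g$gradient_pct, 100 * (0.50 - 0.34) / 0.50)  # 32%
  expect_equal(g$n_top, 1L)
  expect_equal(g$n_bottom, 1L)

  flat <- data.table::copy(regions)[, p_p_given_m := 0.4]
  expect_equal(income_gradient(flat)$gradient_pct, 0)

  expect_error(income_gradient(regions[1:5]), "at least 10")
})

test_that("correlation of income with P(P|M) reflects the planted gradient", {
  st <- default_study()
  rt <- region_table(st$baskets, st$sim$regions$lsoa, st$sim$regions$stores)
  ct <- correlation_table(rt, features = "household_income")
  r <- ct[ct$measure == "p_p_given_m"]$r
  expect_gt(r, 0)
})

test_that("a zero income gradient is recovered as noise around zero", {
  grads <- numeric(10)
  signs <- numeric(10)
  for (s in 1:10) {
    cfg <- simulation_config(n_customers = 1500, n_msoas = 40,
                             income_gradient = 0, seed = 100 + s)
    sim <- simulate_study(cfg)
    b <- build_baskets(sim$transactions, classify_products(sim$catalogue))
    rt <- region_table(b, sim$regions$lsoa, sim$regions$stores)
    grads[s] <- income_gradient(rt)$gradient_pct
    ct <- correlation_table(rt, features = "household_income")
    signs[s] <- sign(ct[ct$measure == "p_p_given_m"]$r)
  }
  # median gradient within Monte-Carlo noise of zero (decile means over 4
  # MSOAs of ~190 menstruating customers each are noisy)
  expect_lt(abs(median(grads)), 15)
  # correlation sign is not systematically positive
  expect_lt(sum(signs > 0), 10)
  expect_gt(sum(signs > 0), 0)
})
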