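test_that("customer sets follow the basket-content definitions", {
  # one customer with separate M and P baskets, one with a joint basket
  b <- make_baskets(has_menstrual = c(TRUE, FALSE, TRUE),
                    has_pain = c(FALSE, TRUE, TRUE),
                    customer_id = c("c1", "c1", "c2"))
  sets <- customer_sets(b)
  expect_setequal(sets$menstrual, c("c1", "c2"))
  expect_setequal(sets$pain, c("c1", "c2"))
  expect_equal(sets$menstrual_pain, "c2")
  # the menstrual-pain set is a subset of both others
  expect_true(all(sets$menstrual_pain %in% sets$menstrual))
  expect_true(all(sets$menstrual_pain %in% sets$pain))
})

test_that("proxy measures match hand enumeration of four baskets", {
  b <- make_baskets(has_menstrual = c(TRUE, TRUE, FALSE, FALSE),
                    has_pain = c(FALSE, TRUE, TRUE, FALSE))
  px <- compute_proxies(b)
  expect_equal(px$n_baskets, 4L)
  expect_equal(px$p_m, 0.5)
  expect_equal(px$p_p, 0.5)
  expect_equal(px$p_p_given_m, 0.5)
  expect_equal(px$p_p_given_notm, 0.5)
  expect_equal(px$mpr, 1.0)
  expect_true(px$mpr_defined)
})

test_that("degenerate basket partitions are flagged, never divided by", {
  no_m <- compute_proxies(make_baskets(c(FALSE, FALSE), c(TRUE, FALSE)))
  expect_false(no_m$conditionals_defined)
  expect_true(is.na(no_m$p_p_given_m))
  expect_true(is.na(no_m$mpr))

  all_m <- compute_proxies(make_baskets(c(TRUE, TRUE), c(TRUE, FALSE)))
  expect_false(all_m$mpr_defined)
  expect_true(is.na(all_m$mpr))

  zero_pnm <- compute_proxies(make_baskets(c(TRUE, FALSE), c(TRUE, FALSE)))
  expect_false(zero_pnm$mpr_defined)
})

test_that("law of total probability holds exactly on random basket tables", {
  withr::local_seed(7)
  for (i in 1:25) {
    n <- sample(2:60, 1)
    b <- make_baskets(has_menstrual = runif(n) < runif(1),
                      has_pain = runif(n) < runif(1))
    px <- compute_proxies(b)
    if (!px$conditionals_defined) next
    expect_equal(px$p_p,
                 px$p_p_given_m * px$p_m + px$p_p_given_notm * (1 - px$p_m),
                 tolerance = 1e-12)
  }
})

test_that("MPR is invariant to duplicating every basket", {
  b <- make_baskets(has_menstrual = c(TRUE, TRUE, FALSE, FALSE, TRUE),
                    has_pain = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  doubled <- data.table::rbindlist(list(b, b))
  doubled$basket_id <- paste0("b", seq_len(nrow(doubled)))
  expect_equal(compute_proxies(doubled)$mpr, compute_proxies(b)$mpr)
})

test_that("a 50% basket subsample agrees within binomial sampling error", {
  st <- default_study()
  px_full <- compute_proxies(st$baskets)
  withr::local_seed(11)
  half <- st$baskets[sample.int(nrow(st$baskets), nrow(st$baskets) %/% 2)]
  px_half <- compute_proxies(half)
  se <- sqrt(px_full$p_m * (1 - px_full$p_m) / px_half$n_baskets)
  expect_lt(abs(px_half$p_m - px_full$p_m), 4 * se)
  se_p <- sqrt(px_full$p_p * (1 - px_full$p_p) / px_half$n_baskets)
  expect_lt(abs(px_half$p_p - px_full$p_p), 4 * se_p)
})

test_that("median MPR over 20 seeds recovers the ground truth within 0.15", {
  gt <- true_parameters(simulation_config())
  mprs <- vapply(1:20, function(s) {
    sim <- simulate_study(simulation_config(seed = s))
    b <- build_baskets(sim$transactions, classify_products(sim$catalogue))
    sets <- customer_sets(b)
    compute_proxies(b, customers = sets$menstrual_pain)$mpr
  }, numeric(1))
  expect_lt(abs(median(mprs) - gt$mpr), 0.15)
})

test_that("customer summaries equal a brute-force per-customer oracle", {
  b <- make_baskets(
    has_menstrual = c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    has_pain = c(FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    customer_id = c("c1", "c1", "c2", "c2", "c3", "c3"),
    n_items = c(3L, 1L, 2L, 1L, 4L, 1L),
    spend = c(5, 2, 3, 1, 8, 2))
  cs <- customer_summary(b)

  # brute force: mean over customers of per-customer totals, per set
  oracle <- function(ids) {
    per <- sapply(ids, function(cid) {
      rows <- b[b$customer_id == cid]
      c(nrow(rows), sum(rows$n_items), sum(rows$spend))
    })
    rowMeans(per)
  }
  sets <- customer_sets(b)
  for (nm in c("menstrual", "pain", "menstrual_pain")) {
    expected <- oracle(sets[[nm]])
    row <- cs$summary[cs$summary$set == nm]
    expect_equal(row$mean_transactions, expected[1])
    expect_equal(row$mean_items, expected[2])
    expect_equal(row$mean_spend, expected[3])
  }
  # single menstrual-pain customer c2: 2 baskets, 3 items, spend 4
  mp_row <- cs$summary[cs$summary$set == "menstrual_pain"]
  expect_equal(mp_row$n_customers, 1L)
  expect_equal(mp_row$mean_transactions, 2)
  expect_equal(mp_row$mean_items, 3)
  expect_equal(mp_row$mean_spend, 4)
  expect_equal(nrow(cs$ratios), 2L)
})

test_that("top products rank by units with correct shares and coverage", {
  cat_dt <- data.frame(
    product_id = c("m1", "m2", "m3"),
    category = c("tampon", "sanitary pad", "tampon"),
    unit_price = c(2, 1.5, 1))
  tx <- data.table::data.table(
    customer_id = "c1", basket_id = paste0("b", 1:3),
    date = as.Date("2013-01-05"), store_id = "s1",
    product_id = c("m1", "m2", "m3"),
    quantity = c(50L, 30L, 20L), unit_price = 1)
  top <- top_products(tx, cat_dt, "menstrual", k = 2L)
  expect_equal(top$table$product_id, c("m1", "m2"))
  expect_equal(top$table$share, c(50, 30))
  expect_equal(top$coverage, 80)
  expect_message(all3 <- top_products(tx, cat_dt, "menstrual", k = 10L),
                 "returning all")
  expect_equal(nrow(all3$table), 3L)
  expect_equal(all3$coverage, 100)
})

test_that("price-frequency correlation reproduces perfect orderings", {
  cat_dt <- data.frame(product_id = c("m1", "m2", "m3"),
                       category = "tampon", unit_price = c(1, 2, 3))
  tx_anti <- data.table::data.table(
    customer_id = "c1", basket_id = paste0("b", 1:3),
    date = as.Date("2013-01-05"), store_id = "s1",
    product_id = c("m1", "m2", "m3"), quantity = c(3L, 2L, 1L),
    unit_price = 1)
  expect_equal(price_frequency_correlation(tx_anti, cat_dt, "menstrual")$r, -1)
  tx_pos <- data.table::copy(tx_anti)[, quantity := c(1L, 2L, 3L)]
  expect_equal(price_frequency_correlation(tx_pos, cat_dt, "menstrual")$r, 1)

  flat <- data.frame(product_id = c("m1", "m2", "m3"),
                     category = "tampon", unit_price = c(2, 2, 2))
  res <- price_frequency_correlation(tx_anti, flat, "menstrual")
  expect_false(res$defined)
  expect_true(is.na(res$r))
})

test_that("synthetic sales correlate more strongly with price for pain items", {
  st <- default_study()
  r_pain <- price_frequency_correlation(st$sim$transactions,
                                        st$sim$catalogue, "pain")
  r_mens <- price_frequency_correlation(st$sim$transactions,
                                        st$sim$catalogue, "menstrual")
  expect_true(r_pain$defined && r_mens$defined)
  expect_lt(r_pain$r, 0)
  expect_lt(r_mens$r, 0)
  expect_gt(abs(r_pain$r), abs(r_mens$r))
})
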