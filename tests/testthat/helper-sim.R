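# Shared simulation fixtures, generated once per test run and cached.
# All fixture seeds are fixed constants so the suite is reproducible.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# desk-scale default study: 5,000 customers, 100 MSOAs, 2 years
default_study <- function() {
  cached("default_study", {
    sim <- simulate_study(simulation_config(seed = 42))
    baskets <- build_baskets(sim$transactions, classify_products(sim$catalogue))
    sets <- customer_sets(baskets)
    list(sim = sim, baskets = baskets, sets = sets)
  })
}

# mid-scale study used where binomial noise at 5,000 customers would dominate
mid_study <- function() {
  cached("mid_study", {
    sim <- simulate_study(simulation_config(n_customers = 10000L, seed = 42))
    baskets <- build_baskets(sim$transactions, classify_products(sim$catalogue))
    sets <- customer_sets(baskets)
    list(sim = sim, baskets = baskets, sets = sets)
  })
}

# hand-built basket table: each row one basket with explicit flags
make_baskets <- function(has_menstrual, has_pain,
                         customer_id = rep("c1", length(has_menstrual)),
                         date = as.Date("2013-01-01") +
                           seq_along(has_menstrual) - 1,
                         store_id = rep("s1", length(has_menstrual)),
                         n_items = rep(1L, length(has_menstrual)),
                         spend = rep(1, length(has_menstrual))) {
  data.table::data.table(
    basket_id = paste0("b", seq_along(has_menstrual)),
    customer_id = customer_id, store_id = store_id, date = date,
    n_items = n_items, spend = spend,
    has_menstrual = has_menstrual, has_pain = has_pain)
}

# minimal well-formed transaction CSV for ingest tests
write_tx_csv <- function(path, rows) {
  header <- "customer_id,basket_id,date,store_id,product_id,quantity,unit_price"
  writeLines(c(header, rows), path)
  path
}
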