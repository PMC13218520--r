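#' Customer sets defined by basket content
#'
#' Partitions customers by purchase history into the three (overlapping)
#' sets the analysis is built on: the *menstrual* set (at least one basket
#' with a menstrual item), the *pain* set (at least one basket with a pain
#' item) and the *menstrual-pain* set (at least one basket containing both).
#' The menstrual-pain set is by construction a subset of each of the others.
#'
#' @param baskets flagged basket table from [build_baskets()].
#' @return A list with character vectors `menstrual`, `pain`,
#'   `menstrual_pain`.
#' @export
customer_sets <- function(baskets) {
  b <- as.data.table(baskets)
  list(
    menstrual = as.character(unique(b[has_menstrual == TRUE, customer_id])),
    pain = as.character(unique(b[has_pain == TRUE, customer_id])),
    menstrual_pain = as.character(
      unique(b[has_menstrual & has_pain, customer_id]))
  )
}

#' Proxy measures for menstruation, pain and menstrual pain
#'
#' Estimates, over the basket universe supplied, the propensity of menstrual
#' purchase `P(M)` (proxy for menstruation prevalence), the propensity of
#' pain purchase `P(P)` (proxy for pain prevalence), the conditionals
#' `P(P|M)` and `P(P|!M)`, and their ratio, the Menstrual Pain Purchasing
#' Ratio:
#'
#' \deqn{MPR = P(P | M) / P(P | \neg M)}
#'
#' All probabilities are basket-frequency estimates; an MPR above 1 means
#' pain products are preferentially co-purchased with menstrual products.
#' To compute measures *within* a customer set (the convention used for the
#' headline MPR), pass `customers`.
#'
#' Degenerate denominators are never divided by: with no menstrual baskets
#' the conditionals are `NA` and flagged; with no non-menstrual baskets (or
#' `P(P|!M) = 0`) the MPR is `NA` and flagged.
#'
#' @param baskets flagged basket table from [build_baskets()].
#' @param customers optional customer ids restricting the basket universe.
#' @return An object of class `proxy_measures`: a list with `n_baskets`,
#'   `p_m`, `p_p`, `p_p_given_m`, `p_p_given_notm`, `mpr`,
#'   `conditionals_defined`, `mpr_defined`.
#' @export
#' @examples
#' b <- data.table::data.table(
#'   basket_id = 1:4, customer_id = "c1", store_id = "s", date = Sys.Date(),
#'   n_items = 1, spend = 1,
#'   has_menstrual = c(TRUE, TRUE, FALSE, FALSE),
#'   has_pain = c(FALSE, TRUE, TRUE, FALSE))
#' compute_proxies(b)  # P(M) = P(P) = 0.5, MPR = 1
compute_proxies <- function(baskets, customers = NULL) {
  b <- as.data.table(baskets)
  if (!is.null(customers)) {
    b <- b[as.character(customer_id) %in% as.character(customers)]
  }
  n <- nrow(b)
  if (n == 0L) stop("no baskets to compute proxies over")

  n_m <- sum(b$has_menstrual)
  n_p <- sum(b$has_pain)
  n_mp <- sum(b$has_menstrual & b$has_pain)
  n_p_notm <- n_p - n_mp

  p_m <- n_m / n
  p_p <- n_p / n
  p_p_given_m <- if (n_m > 0) n_mp / n_m else NA_real_
  p_p_given_notm <- if (n - n_m > 0) n_p_notm / (n - n_m) else NA_real_

  conditionals_defined <- n_m > 0 && (n - n_m) > 0
  mpr_defined <- conditionals_defined && p_p_given_notm > 0
  mpr <- if (mpr_defined) p_p_given_m / p_p_given_notm else NA_real_

  structure(list(
    n_baskets = n,
    p_m = p_m,
    p_p = p_p,
    p_p_given_m = p_p_given_m,
    p_p_given_notm = p_p_given_notm,
    mpr = mpr,
    conditionals_defined = conditionals_defined,
    mpr_defined = mpr_defined
  ), class = "proxy_measures")
}

#' @export
print.proxy_measures <- function(x, ...) {
  cat(sprintf("Proxy measures over %d baskets\n", x$n_baskets))
  cat(sprintf("  P(M) = %.4f   P(P) = %.4f\n", x$p_m, x$p_p))
  if (x$conditionals_defined) {
    cat(sprintf("  P(P|M) = %.4f   P(P|not M) = %.4f\n",
                x$p_p_given_m, x$p_p_given_notm))
  } else {
    cat("  conditionals undefined (degenerate basket partition)\n")
  }
  if (x$mpr_defined) {
    cat(sprintf("  MPR = %.3f\n", x$mpr))
  } else {
    cat("  MPR undefined\n")
  }
  invisible(x)
}

#' Per-customer summary statistics for the three customer sets
#'
#' For each customer set (menstrual, pain, menstrual-pain) computes the mean
#' number of transactions (baskets of any kind), items and spend per
#' customer, restricted to customers in the set, plus the cross-set ratios
#' of the menstrual-pain set against the other two (the "loyalty" ratios).
#'
#' @param baskets flagged basket table.
#' @param sets output of [customer_sets()]; recomputed when `NULL`.
#' @return A list with `summary` (one row per non-empty set: `set`,
#'   `n_customers`, `mean_transactions`, `mean_items`, `mean_spend`) and
#'   `ratios` (menstrual-pain vs pain and vs menstrual for each statistic).
#' @export
customer_summary <- function(baskets, sets = NULL) {
  b <- as.data.table(baskets)
  if (is.null(sets)) sets <- customer_sets(b)
  per_cust <- b[, .(n_transactions = .N, n_items = sum(n_items),
                    spend = sum(spend)), by = customer_id]
  per_cust[, customer_id := as.character(customer_id)]

  one <- function(name, ids) {
    if (length(ids) == 0L) {
      warning("customer set `", name, "` is empty; summary omitted")
      return(NULL)
    }
    s <- per_cust[customer_id %in% ids]
    data.table(set = name, n_customers = nrow(s),
               mean_transactions = mean(s$n_transactions),
               mean_items = mean(s$n_items),
               mean_spend = mean(s$spend))
  }
  summary <- rbindlist(list(
    one("menstrual", sets$menstrual),
    one("pain", sets$pain),
    one("menstrual_pain", sets$menstrual_pain)
  ))

  ratios <- NULL
  if (all(c("menstrual", "pain", "menstrual_pain") %in% summary$set)) {
    g <- function(set_name, col) summary[set == set_name][[col]]
    ratios <- data.table(
      comparison = c("menstrual_pain_vs_pain", "menstrual_pain_vs_menstrual"),
      transactions_ratio = g("menstrual_pain", "mean_transactions") /
        c(g("pain", "mean_transactions"), g("menstrual", "mean_transactions")),
      items_ratio = g("menstrual_pain", "mean_items") /
        c(g("pain", "mean_items"), g("menstrual", "mean_items")),
      spend_ratio = g("menstrual_pain", "mean_spend") /
        c(g("pain", "mean_spend"), g("menstrual", "mean_spend"))
    )
  }
  list(summary = summary, ratios = ratios)
}

#' Top-k products of a class by units sold
#'
#' Ranks the products of one class (menstrual or pain) by total units sold
#' and reports each product's share of the class's sales (in percent),
#' category, unit price, and the cumulative top-k coverage.
#'
#' @param transactions itemised transaction table.
#' @param catalogue catalogue with `product_id`, `category`, `unit_price`.
#' @param class "menstrual" or "pain".
#' @param k number of products to report; when `k` exceeds the number of
#'   products with sales, all are returned with a message.
#' @return A list with `table` (ranked `data.table`: `product_id`,
#'   `description` if present, `category`, `unit_price`, `units`, `share`)
#'   and `coverage` (sum of the reported shares, percent).
#' @export
top_products <- function(transactions, catalogue, class = c("menstrual", "pain"),
                         k = 20L) {
  class <- match.arg(class)
  stopifnot(k >= 1L)
  tx <- as.data.table(transactions)
  cat_dt <- as.data.table(catalogue)
  cat_dt[, product_id := as.character(product_id)]
  cls <- product_class_from_category(cat_dt$category)
  ids <- cat_dt$product_id[cls == class]

  sales <- tx[as.character(product_id) %in% ids,
              .(units = sum(quantity)), by = .(product_id = as.character(product_id))]
  if (nrow(sales) == 0L) stop("no sales of class `", class, "` products")
  total_units <- sum(sales$units)
  sales[, share := 100 * units / total_units]
  setorder(sales, -units, product_id)
  if (k > nrow(sales)) {
    message("k = ", k, " exceeds the ", nrow(sales),
            " products with sales; returning all")
    k <- nrow(sales)
  }
  top <- sales[seq_len(k)]
  keep_cols <- intersect(c("product_id", "description", "category", "unit_price"),
                         names(cat_dt))
  top <- merge(top, cat_dt[, keep_cols, with = FALSE], by = "product_id",
               sort = FALSE)
  setorder(top, -units, product_id)
  list(table = top[], coverage = sum(top$share))
}

#' Price--frequency correlation for a product class
#'
#' Pearson correlation between unit price and total units sold across the
#' products of a class. Products of the class with no recorded sales count
#' as zero frequency.
#'
#' @inheritParams top_products
#' @param class "menstrual", "pain" or "other".
#' @return A list with `r`, `p_value`, `n_products` and `defined` (FALSE,
#'   with `r = NA`, when prices have zero variance or fewer than 3 products
#'   have sales).
#' @export
price_frequency_correlation <- function(transactions, catalogue,
                                        class = c("menstrual", "pain", "other")) {
  class <- match.arg(class)
  tx <- as.data.table(transactions)
  cat_dt <- as.data.table(catalogue)
  cat_dt[, product_id := as.character(product_id)]
  cls <- product_class_from_category(cat_dt$category)
  prods <- cat_dt[cls == class, .(product_id, unit_price)]

  sales <- tx[, .(units = sum(quantity)),
              by = .(product_id = as.character(product_id))]
  prods <- merge(prods, sales, by = "product_id", all.x = TRUE)
  prods[is.na(units), units := 0]

  n_with_sales <- sum(prods$units > 0)
  if (n_with_sales < 3L || sd(prods$unit_price) == 0 || sd(prods$units) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n_products = nrow(prods),
                defined = FALSE))
  }
  ct <- cor.test(prods$unit_price, prods$units, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value,
       n_products = nrow(prods), defined = TRUE)
}
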