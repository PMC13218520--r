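# case-insensitive mapping of retailer category strings to the three
# analysis classes
product_class_from_category <- function(category) {
  lc <- tolower(trimws(category))
  out <- rep("other", length(category))
  out[lc %in% c("tampon", "sanitary pad")] <- "menstrual"
  out[lc %in% c("pain relief oral", "topical pain relief")] <- "pain"
  out
}

#' Read and validate a transaction log
#'
#' Reads an itemised transaction CSV (comma-separated, UTF-8, header row,
#' ISO-8601 dates) and validates it against the schema: non-empty ids,
#' parseable dates, `quantity >= 1` and `unit_price >= 0`. Offending rows are
#' dropped and counted; a missing required column or an empty file is a hard
#' error.
#'
#' @param path path to a CSV with columns `customer_id`, `basket_id`, `date`,
#'   `store_id`, `product_id`, `quantity`, `unit_price`.
#' @return A `data.table` of validated records; the number of rejected rows
#'   is attached as attribute `n_rejected` and reported with a message when
#'   non-zero.
#' @export
read_transactions <- function(path) {
  required <- c("customer_id", "basket_id", "date", "store_id", "product_id",
                "quantity", "unit_price")
  hdr <- names(fread(path, nrows = 0L))
  id_cols <- intersect(c("customer_id", "basket_id", "store_id", "product_id"),
                       hdr)
  dt <- fread(path, colClasses = stats::setNames(rep("character",
                                                     length(id_cols)),
                                                 id_cols))
  if (nrow(dt) == 0L) stop("empty transaction file: ", path)
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("transaction file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt[, date := as.Date(as.character(date), format = "%Y-%m-%d")]
  ok <- !is.na(dt$date) &
    !is.na(dt$quantity) & dt$quantity >= 1 &
    !is.na(dt$unit_price) & dt$unit_price >= 0 &
    nzchar(dt$customer_id) & nzchar(dt$basket_id) &
    nzchar(dt$store_id) & nzchar(dt$product_id)
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(n_rejected, " transaction row(s) rejected during validation")
  }
  out <- dt[ok]
  setattr(out, "n_rejected", n_rejected)
  out[]
}

#' Classify catalogue products into menstrual / pain / other
#'
#' Applies the strict category definitions: products categorised "tampon" or
#' "sanitary pad" are menstrual; "Pain Relief Oral" or "Topical Pain Relief"
#' are pain; everything else is other. Matching is exact but
#' case-insensitive. Category strings outside the known retailer vocabulary
#' are classified `other` with a warning.
#'
#' @param catalogue data.frame with columns `product_id` and `category`.
#' @return A `data.table` with columns `product_id`, `category`, `class`.
#' @export
classify_products <- function(catalogue) {
  cat_dt <- as.data.table(catalogue)
  if (!all(c("product_id", "category") %in% names(cat_dt))) {
    stop("catalogue must have `product_id` and `category` columns")
  }
  known <- c("tampon", "sanitary pad", "pain relief oral",
             "topical pain relief", "other")
  unknown <- setdiff(unique(tolower(trimws(cat_dt$category))), known)
  if (length(unknown) > 0) {
    warning("unknown category string(s) classified as `other`: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  cat_dt[, .(product_id = as.character(product_id), category,
             class = product_class_from_category(category))]
}

#' Group transaction lines into flagged baskets
#'
#' Collapses item lines to one row per basket (a till receipt) and sets the
#' content flags that all proxy probabilities are defined over:
#' `has_menstrual` if any line's product is classed menstrual, `has_pain` if
#' any is classed pain, plus total `spend` (sum of quantity times unit price)
#' and `n_items` (sum of quantities). A menstrual-pain basket is one with
#' both flags set. Transactions whose `basket_id` spans two customers
#' indicate a corrupt log and raise an error. If the input has no
#' `basket_id` column, one is synthesised from (customer, store, date).
#'
#' @param transactions validated transaction table (see
#'   [read_transactions()]).
#' @param product_classes output of [classify_products()] covering the
#'   products in `transactions`; unknown product ids are treated as other.
#' @return A `data.table` with one row per basket: `basket_id`,
#'   `customer_id`, `store_id`, `date`, `n_items`, `spend`, `has_menstrual`,
#'   `has_pain`.
#' @export
build_baskets <- function(transactions, product_classes) {
  tx <- as.data.table(transactions)
  cls_dt <- as.data.table(product_classes)
  cl <- cls_dt$class[match(as.character(tx$product_id),
                           as.character(cls_dt$product_id))]
  cl[is.na(cl)] <- "other"

  # narrow working copy with precomputed per-line columns keeps the
  # per-basket aggregation on data.table's optimised (GForce) path even for
  # logs with tens of millions of lines
  work <- data.table(
    basket_id = if ("basket_id" %in% names(tx)) tx$basket_id else
      paste(tx$customer_id, tx$store_id, tx$date, sep = "|"),
    customer_id = tx$customer_id,
    store_id = tx$store_id,
    date = tx$date,
    quantity = tx$quantity,
    line_total = tx$quantity * tx$unit_price,
    mens_line = cl == "menstrual",
    pain_line = cl == "pain"
  )

  if (uniqueN(work, by = c("basket_id", "customer_id")) >
      uniqueN(work, by = "basket_id")) {
    stop("corrupt log: at least one basket_id spans multiple customers")
  }

  baskets <- work[, .(
    customer_id = first(customer_id),
    store_id = first(store_id),
    date = first(date),
    n_items = sum(quantity),
    spend = sum(line_total),
    n_mens = sum(mens_line),
    n_pain = sum(pain_line)
  ), by = basket_id]
  baskets[, has_menstrual := n_mens > 0L]
  baskets[, has_pain := n_pain > 0L]
  baskets[, c("n_mens", "n_pain") := NULL]
  setorder(baskets, customer_id, date, basket_id)
  baskets[]
}
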