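#' Run the full synthetic-study pipeline
#'
#' Orchestrates every stage end-to-end on synthetic data: simulate
#' transaction logs, write them to disk, read them back through the ingest
#' readers (exercising the round trip), build baskets, compute customer sets
#' and proxy measures (overall and within the menstrual-pain customer set),
#' validate periodicity, aggregate to MSOAs, link deprivation features,
#' compute the correlation grid and income gradient, and optionally run the
#' area classification with Shapley attribution. A machine-readable
#' `report.json` with every headline statistic plus the ground-truth block,
#' and a human-readable `report.md`, are written to `out_dir`.
#'
#' @param sim_config a [simulation_config()].
#' @param out_dir output directory for stage outputs and reports.
#' @param periodicity a [periodicity_config()].
#' @param classify_targets targets to classify (subset of `p_m`, `p_p`,
#'   `p_p_given_m`); use `character()` to skip the classification stage.
#' @param seed seed for the classification/attribution stage.
#' @return A list of class `pipeline_result` with all stage outputs and the
#'   `report` list mirrored in `report.json`.
#' @export
run_pipeline <- function(sim_config = simulation_config(),
                         out_dir = tempfile("basketproxy_run_"),
                         periodicity = periodicity_config(),
                         classify_targets = "p_p_given_m",
                         seed = sim_config$seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    s <- simulate_study(sim_config)
    write_simulation(s, out_dir)
    s
  })

  ing <- stage("ingest", {
    tx <- read_transactions(file.path(out_dir, "transactions.csv"))
    classes <- classify_products(fread(file.path(out_dir, "catalogue.csv")))
    baskets <- build_baskets(tx, classes)
    list(transactions = tx, classes = classes, baskets = baskets)
  })

  prox <- stage("proxies", {
    sets <- customer_sets(ing$baskets)
    overall <- compute_proxies(ing$baskets)
    mp_set <- if (length(sets$menstrual_pain) > 0) {
      compute_proxies(ing$baskets, customers = sets$menstrual_pain)
    } else NULL
    summaries <- customer_summary(ing$baskets, sets)
    top_m <- top_products(ing$transactions, sim$catalogue, "menstrual", 20L)
    top_p <- top_products(ing$transactions, sim$catalogue, "pain", 20L)
    pf_m <- price_frequency_correlation(ing$transactions, sim$catalogue,
                                        "menstrual")
    pf_p <- price_frequency_correlation(ing$transactions, sim$catalogue,
                                        "pain")
    fwrite(top_m$table, file.path(out_dir, "top_products_menstrual.csv"))
    fwrite(top_p$table, file.path(out_dir, "top_products_pain.csv"))
    fwrite(summaries$summary, file.path(out_dir, "customer_summary.csv"))
    list(sets = sets, overall = overall, mp_set = mp_set,
         summaries = summaries, top_menstrual = top_m, top_pain = top_p,
         pf_menstrual = pf_m, pf_pain = pf_p)
  })

  per <- stage("periodicity", periodicity_validation(ing$baskets, periodicity))

  reg <- stage("regional", {
    regions <- region_table(ing$baskets, sim$regions$lsoa, sim$regions$stores)
    corr <- correlation_table(regions)
    grad <- if (sum(is.finite(regions$p_p_given_m)) >= 10) {
      income_gradient(regions)
    } else NULL
    fwrite(regions, file.path(out_dir, "msoa_table.csv"))
    fwrite(corr, file.path(out_dir, "correlations.csv"))
    list(table = regions, correlations = corr, gradient = grad)
  })

  cls <- if (length(classify_targets) > 0) {
    stage("classify", {
      out <- lapply(classify_targets, function(tg) {
        classify_regions(reg$table, tg, seed = seed)
      })
      names(out) <- classify_targets
      rep_dt <- rbindlist(lapply(out, function(o) {
        cbind(target = o$target, o$report$results)
      }))
      fwrite(rep_dt, file.path(out_dir, "model_report.csv"))
      fwrite(rbindlist(lapply(out, function(o) {
        cbind(target = o$target, o$shap$ranking)
      })), file.path(out_dir, "shap_ranking.csv"))
      out
    })
  } else NULL

  report <- list(
    ground_truth = unclass(sim$ground_truth),
    n_transactions = nrow(ing$transactions),
    n_baskets = nrow(ing$baskets),
    customer_sets = lapply(prox$sets, length),
    mp_customer_fraction_pct = if (length(prox$sets$menstrual) > 0) {
      100 * length(prox$sets$menstrual_pain) / length(prox$sets$menstrual)
    } else NA_real_,
    proxies_overall = unclass(prox$overall),
    proxies_mp_set = if (!is.null(prox$mp_set)) unclass(prox$mp_set) else NULL,
    price_frequency = list(menstrual = prox$pf_menstrual$r,
                           pain = prox$pf_pain$r),
    top_coverage = list(menstrual = prox$top_menstrual$coverage,
                        pain = prox$top_pain$coverage),
    intervals = list(unfiltered = unclass(per$unfiltered),
                     filtered = unclass(per$filtered)),
    income_gradient_pct = if (!is.null(reg$gradient)) {
      reg$gradient$gradient_pct
    } else NA_real_,
    classification = if (!is.null(cls)) {
      lapply(cls, function(o) list(
        best_family = o$report$best_family,
        accuracy = o$report$results[family == o$report$best_family,
                                    .(accuracy_mean, accuracy_sd)],
        majority_rate = o$report$majority_rate,
        top_feature = o$shap$ranking$feature[1]))
    } else NULL
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)

  result <- structure(list(sim = sim, ingest = ing, proxies = prox,
                           periodicity = per, regional = reg,
                           classification = cls, report = report,
                           out_dir = out_dir),
                      class = "pipeline_result")
  writeLines(make_report(result), file.path(out_dir, "report.md"))
  result
}

#' Render a human-readable markdown summary of a pipeline run
#'
#' Produces a markdown report with sections for the customer-set summary,
#' top products, proxy measures, periodicity validation, regional
#' correlations and gradient, and classification. Missing stages are marked
#' unavailable. Every number is read from the structures that `report.json`
#' serialises.
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @return Character vector of markdown lines.
#' @export
make_report <- function(result) {
  stopifnot(inherits(result, "pipeline_result"))
  r <- result$report
  fmt <- function(x, d = 4) formatC(x, format = "f", digits = d)
  lines <- c(
    "# Synthetic menstrual-pain proxy study report", "",
    sprintf("- transactions: %d, baskets: %d", r$n_transactions, r$n_baskets),
    sprintf("- customer sets: menstrual %d, pain %d, menstrual-pain %d",
            r$customer_sets$menstrual, r$customer_sets$pain,
            r$customer_sets$menstrual_pain),
    sprintf("- menstrual-pain customer fraction: %s%% (truth %s%%)",
            fmt(r$mp_customer_fraction_pct, 2),
            fmt(100 * r$ground_truth$mp_customer_fraction, 2)),
    "", "## Proxy measures", "",
    sprintf("- overall: P(M) %s, P(P) %s, P(P|M) %s, P(P|not M) %s",
            fmt(r$proxies_overall$p_m), fmt(r$proxies_overall$p_p),
            fmt(r$proxies_overall$p_p_given_m),
            fmt(r$proxies_overall$p_p_given_notm))
  )
  if (!is.null(r$proxies_mp_set)) {
    lines <- c(lines, sprintf(
      "- menstrual-pain customer set: P(P|M) %s, P(P|not M) %s, MPR %s (truth %s)",
      fmt(r$proxies_mp_set$p_p_given_m), fmt(r$proxies_mp_set$p_p_given_notm),
      fmt(r$proxies_mp_set$mpr, 3), fmt(r$ground_truth$mpr, 3)))
  }
  lines <- c(lines, "",
    sprintf("- price-frequency correlation: menstrual %s, pain %s",
            fmt(r$price_frequency$menstrual, 3), fmt(r$price_frequency$pain, 3)),
    sprintf("- top-20 coverage: menstrual %s%%, pain %s%%",
            fmt(r$top_coverage$menstrual, 1), fmt(r$top_coverage$pain, 1)),
    "", "## Periodicity validation", "")
  f <- r$intervals$filtered
  u <- r$intervals$unfiltered
  if (isTRUE(f$empty)) {
    lines <- c(lines, "- filtered intervals: unavailable (no retained intervals)")
  } else {
    lines <- c(lines, sprintf(
      "- filtered (n %d): mode %d, mean %s +/- %s, median %g, range [%d, %d]",
      f$n, f$mode_days, fmt(f$mean_days, 2), fmt(f$sd_days, 2),
      f$median_days, f$min_days, f$max_days))
  }
  if (!isTRUE(u$empty)) {
    lines <- c(lines, sprintf(
      "- unfiltered (n %d): mode %d, mean %s, median %g, max %d",
      u$n, u$mode_days, fmt(u$mean_days, 1), u$median_days, u$max_days))
  }
  lines <- c(lines, "", "## Regional analysis", "",
    if (is.finite(r$income_gradient_pct)) {
      sprintf("- income gradient in P(P|M), top vs bottom decile: %s%% (truth %s%%)",
              fmt(r$income_gradient_pct, 1),
              fmt(r$ground_truth$income_gradient_pct, 1))
    } else "- income gradient: unavailable",
    "", "## Classification", "")
  if (is.null(r$classification)) {
    lines <- c(lines, "- classification: unavailable (stage not run)")
  } else {
    for (tg in names(r$classification)) {
      cl <- r$classification[[tg]]
      lines <- c(lines, sprintf(
        "- %s: best %s, accuracy %s +/- %s (baseline %s), top feature %s",
        tg, cl$best_family, fmt(cl$accuracy$accuracy_mean, 3),
        fmt(cl$accuracy$accuracy_sd, 3), fmt(cl$majority_rate, 3),
        cl$top_feature))
    }
  }
  lines
}
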