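#' Binarise MSOA proxy measures into High/Low labels
#'
#' Labels an MSOA "High" for a target measure when its value is strictly
#' greater than the unweighted mean over the included MSOAs (the "national
#' mean" of the synthetic population), "Low" otherwise. MSOAs with an
#' undefined value for the target are excluded.
#'
#' @param regions MSOA table from [region_table()].
#' @param target one of `"p_m"`, `"p_p"`, `"p_p_given_m"`.
#' @return A list with `labels` (factor High/Low, named by `msoa_id`),
#'   `threshold` (the mean used) and `msoa_id`.
#' @export
binarize_targets <- function(regions, target = c("p_m", "p_p", "p_p_given_m")) {
  target <- match.arg(target)
  dt <- as.data.table(regions)
  dt <- dt[is.finite(get(target))]
  if (nrow(dt) < 2L) stop("need at least 2 MSOAs with a defined target")
  threshold <- mean(dt[[target]])
  labels <- factor(ifelse(dt[[target]] > threshold, "High", "Low"),
                   levels = c("Low", "High"))
  if (length(unique(labels)) < 2L) {
    stop("degenerate labels: every MSOA falls on one side of the mean; ",
         "training refused")
  }
  list(labels = setNames(labels, dt$msoa_id), threshold = threshold,
       msoa_id = dt$msoa_id)
}

#' Min-max feature scaling to [0, 1]
#'
#' Scales each feature to `[0, 1]`. When `bounds` are supplied (fitted on
#' training folds), they are applied and out-of-range values are clipped,
#' so no information leaks from held-out data. Zero-range features are
#' dropped with a warning.
#'
#' @param x numeric matrix or data.frame of features.
#' @param bounds optional list with `min` and `max` named vectors as
#'   returned in the `bounds` element.
#' @return A list with `x` (scaled matrix) and `bounds`.
#' @export
normalize_features <- function(x, bounds = NULL) {
  x <- as.matrix(x)
  if (is.null(bounds)) {
    mins <- apply(x, 2, min)
    maxs <- apply(x, 2, max)
    zero_range <- maxs - mins == 0
    if (any(zero_range)) {
      warning("dropping zero-range feature(s): ",
              paste(colnames(x)[zero_range], collapse = ", "))
      x <- x[, !zero_range, drop = FALSE]
      mins <- mins[!zero_range]
      maxs <- maxs[!zero_range]
    }
    bounds <- list(min = mins, max = maxs)
  } else {
    x <- x[, names(bounds$min), drop = FALSE]
  }
  scaled <- sweep(x, 2, bounds$min, "-")
  scaled <- sweep(scaled, 2, bounds$max - bounds$min, "/")
  scaled[scaled < 0] <- 0
  scaled[scaled > 1] <- 1
  list(x = scaled, bounds = bounds)
}

# deterministic stratified k-fold assignment (uses the current RNG state)
stratified_folds <- function(labels, k = 10L) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    idx <- which(labels == lv)
    if (length(idx) < k && length(idx) < 2L) {
      stop("class `", lv, "` too small to stratify into ", k, " folds")
    }
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# default, deliberately small hyperparameter grids per model family
default_grids <- function() {
  list(
    logistic_regression = data.frame(lambda = c(0.01, 0.1, 1, 10)),
    random_forest = expand.grid(num_trees = c(100L, 300L),
                                max_depth = c(3L, 6L, 0L)),
    support_vector = expand.grid(kernel = c("linear", "radial"),
                                 cost = c(0.1, 1, 10),
                                 stringsAsFactors = FALSE),
    neural_network = data.frame(size = c(8L, 16L, 32L))
  )
}

# fit one model family with given hyperparameters; returns an object with a
# uniform probability-of-High prediction interface
fit_classifier <- function(family, params, x, y) {
  model <- switch(family,
    logistic_regression = glmnet::glmnet(
      x, y, family = "binomial", alpha = 0,
      lambda = params$lambda),
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = y, probability = TRUE,
      num.trees = params$num_trees,
      max.depth = if (params$max_depth == 0L) NULL else params$max_depth,
      num.threads = 1L, seed = sample.int(.Machine$integer.max, 1L)),
    support_vector = e1071::svm(
      x = x, y = y, kernel = params$kernel, cost = params$cost,
      probability = TRUE),
    neural_network = nnet::nnet(
      x = x, y = as.numeric(y == "High"), size = params$size,
      decay = 5e-4, maxit = 300, trace = FALSE),
    stop("unknown model family: ", family)
  )
  structure(list(family = family, params = params, model = model,
                 feature_names = colnames(x)),
            class = "bp_classifier")
}

#' Predicted probability of the High class
#'
#' @param object a fitted classifier from [train_and_select()].
#' @param newdata numeric matrix of (normalised) features.
#' @param ... unused.
#' @return Numeric vector of P(High).
#' @export
predict_prob <- function(object, newdata, ...) {
  stopifnot(inherits(object, "bp_classifier"))
  x <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  switch(object$family,
    logistic_regression =
      as.numeric(predict(object$model, newx = x, type = "response")),
    random_forest = {
      p <- predict(object$model, data = as.data.frame(x),
                   num.threads = 1L)$predictions
      as.numeric(p[, "High"])
    },
    support_vector = {
      pr <- predict(object$model, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "High"])
    },
    neural_network = as.numeric(predict(object$model, x, type = "raw"))
  )
}

#' Train, cross-validate and select classifiers for a binarised target
#'
#' For each model family (ridge logistic regression, random forest, support
#' vector machine, single-hidden-layer neural network), runs a grid search
#' over a small documented hyperparameter grid under stratified 10-fold
#' cross-validation. Feature scaling bounds are fitted on the training folds
#' only and applied (with clipping) to the held-out fold. Accuracy is
#' correct/total per fold; each family reports the mean and standard
#' deviation over folds at its best grid point, and the best family is the
#' one with the highest mean accuracy. The selected model is refitted on the
#' full (normalised) data for downstream attribution.
#'
#' @param features data.frame/matrix of MSOA features (rows aligned with
#'   `labels`).
#' @param labels factor with levels Low/High from [binarize_targets()].
#' @param families model families to try (default all four).
#' @param k number of folds.
#' @param grids named list of hyperparameter grids; see `default_grids`
#'   in the package source for the defaults.
#' @param seed integer seed making fold assignment and fits reproducible.
#' @return A list of class `model_report`: `results` (one row per family:
#'   mean/sd accuracy, best hyperparameters), `best_family`, `best_model`
#'   (a fitted classifier), `bounds` (full-data scaling bounds), `x`
#'   (full normalised feature matrix), `labels`, `majority_rate`.
#' @export
train_and_select <- function(features, labels,
                             families = c("logistic_regression",
                                          "random_forest", "support_vector",
                                          "neural_network"),
                             k = 10L, grids = default_grids(), seed = 1L) {
  x_raw <- as.matrix(features)
  stopifnot(nrow(x_raw) == length(labels))
  labels <- factor(labels, levels = c("Low", "High"))
  if (nlevels(droplevels(labels)) < 2L) {
    stop("both classes must be present for training")
  }

  with_sim_seed(derive_seed(seed, 404L), {
    fold <- stratified_folds(labels, k)

    cv_accuracy <- function(family, params) {
      acc <- numeric(k)
      for (f in seq_len(k)) {
        tr <- fold != f
        norm_tr <- normalize_features(x_raw[tr, , drop = FALSE])
        x_tr <- norm_tr$x
        x_te <- normalize_features(x_raw[!tr, , drop = FALSE],
                                   bounds = norm_tr$bounds)$x
        if (nlevels(droplevels(labels[tr])) < 2L) {
          stop("a training fold contains a single class; use fewer folds")
        }
        m <- fit_classifier(family, params, x_tr, labels[tr])
        p <- predict_prob(m, x_te)
        pred <- ifelse(p > 0.5, "High", "Low")
        acc[f] <- mean(pred == as.character(labels[!tr]))
      }
      acc
    }

    results <- list()
    for (family in families) {
      grid <- grids[[family]]
      best <- NULL
      for (i in seq_len(nrow(grid))) {
        params <- as.list(grid[i, , drop = FALSE])
        acc <- cv_accuracy(family, params)
        if (is.null(best) || mean(acc) > best$mean_acc) {
          best <- list(params = params, mean_acc = mean(acc),
                       sd_acc = sd(acc))
        }
      }
      results[[family]] <- data.table(
        family = family,
        accuracy_mean = best$mean_acc,
        accuracy_sd = best$sd_acc,
        params = paste(names(best$params),
                       unlist(lapply(best$params, format)),
                       sep = "=", collapse = ", "))
    }
    results <- rbindlist(results)
    best_family <- results$family[which.max(results$accuracy_mean)]
    best_grid <- grids[[best_family]]
    best_row <- results[family == best_family]

    # refit the winning configuration on the full data
    full_norm <- normalize_features(x_raw)
    best_params_str <- best_row$params
    best_idx <- which(vapply(seq_len(nrow(best_grid)), function(i) {
      p <- as.list(best_grid[i, , drop = FALSE])
      paste(names(p), unlist(lapply(p, format)), sep = "=",
            collapse = ", ") == best_params_str
    }, logical(1)))[1]
    best_model <- fit_classifier(best_family,
                                 as.list(best_grid[best_idx, , drop = FALSE]),
                                 full_norm$x, labels)

    structure(list(results = results[],
                   best_family = best_family,
                   best_model = best_model,
                   bounds = full_norm$bounds,
                   x = full_norm$x,
                   labels = labels,
                   majority_rate = max(table(labels)) / length(labels)),
              class = "model_report")
  })
}

#' @export
print.model_report <- function(x, ...) {
  cat("Cross-validated classification report\n")
  print(x$results)
  cat(sprintf("best family: %s (majority-class baseline %.3f)\n",
              x$best_family, x$majority_rate))
  invisible(x)
}

#' Default MSOA feature columns for classification
#'
#' The deprivation and population feature set used for the area
#' classification tasks. Weekly household income is retained and any
#' collinear ONS income column (`ons_income`) is excluded when both are
#' present.
#'
#' @param regions MSOA table.
#' @return Character vector of feature column names present in `regions`.
#' @export
classification_features <- function(regions) {
  candidates <- c("imd_score", "household_income", "electricity_spend",
                  "jobseekers_claimants", "room_occupancy", "population_all",
                  "population_children", "population_working",
                  "population_older")
  feats <- intersect(candidates, names(as.data.table(regions)))
  if ("household_income" %in% feats) feats <- setdiff(feats, "ons_income")
  feats
}

#' End-to-end classification of one binarised target
#'
#' Convenience wrapper: binarises the target against the national mean,
#' extracts the default feature set, trains all families under stratified
#' 10-fold cross-validation, and attributes the best model with Shapley
#' values.
#'
#' @param regions MSOA table from [region_table()].
#' @param target `"p_m"`, `"p_p"` or `"p_p_given_m"`.
#' @param seed integer seed.
#' @param shap logical; compute the Shapley ranking for the best model.
#' @return A list with `target`, `report` (see [train_and_select()]) and
#'   `shap` (see [shap_rank()]; `NULL` when `shap = FALSE`).
#' @export
classify_regions <- function(regions, target = c("p_m", "p_p", "p_p_given_m"),
                             seed = 1L, shap = TRUE) {
  target <- match.arg(target)
  dt <- as.data.table(regions)
  bin <- binarize_targets(dt, target)
  feats <- classification_features(dt)
  x <- as.matrix(dt[msoa_id %in% bin$msoa_id, feats, with = FALSE])
  report <- train_and_select(x, bin$labels, seed = seed)
  shap_res <- if (shap) {
    shap_rank(report$best_model, report$x, seed = seed)
  } else NULL
  list(target = target, report = report, shap = shap_res,
       threshold = bin$threshold)
}
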