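#' Monte Carlo Shapley values for a fitted classifier
#'
#' Model-agnostic sampling estimator of Shapley values (the
#' permutation-sampling scheme of Strumbelj & Kononenko) for the predicted
#' probability of the High class. For each sampled feature permutation, the
#' marginal contribution of each feature is the change in the background-
#' averaged prediction when that feature's value is switched from the
#' background to the explained instance, features earlier in the permutation
#' already switched. Averaging over permutations and background rows gives
#' unbiased Shapley value estimates whose per-instance sum equals the
#' prediction minus the background-average prediction.
#'
#' @param model a fitted classifier (class `bp_classifier`), or any object
#'   understood by `pred_fun`.
#' @param x numeric matrix of normalised feature rows to explain.
#' @param background background feature matrix defining the reference
#'   distribution; defaults to `x` (subsampled to `max_background` rows).
#' @param n_perm number of feature permutations sampled.
#' @param max_background cap on background rows.
#' @param seed integer seed.
#' @param pred_fun function `(model, matrix) -> numeric` giving the score to
#'   attribute; defaults to [predict_prob()].
#' @return Matrix of Shapley values, `nrow(x)` by `ncol(x)`.
#' @export
shapley_values <- function(model, x, background = NULL, n_perm = 32L,
                           max_background = 50L, seed = 1L,
                           pred_fun = predict_prob) {
  x <- as.matrix(x)
  d <- ncol(x)
  n <- nrow(x)
  with_sim_seed(derive_seed(seed, 505L), {
    if (is.null(background)) background <- x
    background <- as.matrix(background)
    if (nrow(background) > max_background) {
      background <- background[sample.int(nrow(background), max_background), ,
                               drop = FALSE]
    }
    nb <- nrow(background)

    phi <- matrix(0, n, d, dimnames = list(NULL, colnames(x)))
    # rows: each explained instance paired with every background row
    idx_x <- rep(seq_len(n), each = nb)
    idx_b <- rep(seq_len(nb), times = n)

    for (p in seq_len(n_perm)) {
      perm <- sample.int(d)
      z <- background[idx_b, , drop = FALSE]   # start fully background
      prev <- pred_fun(model, z)
      for (j in perm) {
        z[, j] <- x[idx_x, j]
        cur <- pred_fun(model, z)
        contrib <- rowsum(cur - prev, group = idx_x) / nb
        phi[, j] <- phi[, j] + contrib[, 1]
        prev <- cur
      }
    }
    phi / n_perm
  })
}

#' Rank features by Shapley attribution
#'
#' Computes Shapley values for the model over an evaluation set and ranks
#' features by mean absolute attribution (descending). The signed summary
#' reports the mean Shapley value among instances whose feature value lies
#' above the feature's median: a positive value means high values of the
#' feature push predictions towards the High class.
#'
#' @inheritParams shapley_values
#' @param max_explain cap on explained rows (subsampled beyond this).
#' @return A list of class `shap_ranking` with `ranking` (a `data.table`:
#'   `feature`, `mean_abs_shap`, `signed_high`, `rank`) and `values` (the
#'   Shapley value matrix).
#' @export
shap_rank <- function(model, x, background = NULL, n_perm = 32L,
                      max_background = 50L, max_explain = 100L, seed = 1L,
                      pred_fun = predict_prob) {
  x <- as.matrix(x)
  with_sim_seed(derive_seed(seed, 606L), {
    if (nrow(x) > max_explain) {
      x <- x[sample.int(nrow(x), max_explain), , drop = FALSE]
    }
  })
  phi <- shapley_values(model, x, background = background, n_perm = n_perm,
                        max_background = max_background, seed = seed,
                        pred_fun = pred_fun)
  ranking <- data.table(
    feature = colnames(x),
    mean_abs_shap = colMeans(abs(phi)),
    signed_high = vapply(seq_len(ncol(x)), function(j) {
      high <- x[, j] > median(x[, j])
      if (!any(high)) return(0)
      mean(phi[high, j])
    }, numeric(1))
  )
  setorder(ranking, -mean_abs_shap)
  ranking[, rank := .I]
  structure(list(ranking = ranking[], values = phi), class = "shap_ranking")
}

#' @export
print.shap_ranking <- function(x, ...) {
  cat("Shapley feature attribution (mean |value|, descending)\n")
  print(x$ranking)
  invisible(x)
}
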