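#' Cross-validation split schemes
#'
#' Describes how observations are split for [run_crossval()]: repeated
#' k-fold (`"kfold"`), leave-one-out (`"loocv"`) or a repeated random
#' train/test fraction split (`"fraction"`).  Fold assignment draws a
#' uniform random permutation and cuts it into contiguous blocks (no
#' stratification); the seed is recorded so every split is reproducible.
#'
#' @param kind `"kfold"`, `"loocv"` or `"fraction"`.
#' @param k Number of folds (kfold).
#' @param fraction Training fraction (fraction splits), e.g. `2/3`.
#' @param repeats Number of repeats of the whole scheme.
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `split_scheme`.
#' @export
split_scheme <- function(kind = c("kfold", "loocv", "fraction"), k = 5L,
                         fraction = 2 / 3, repeats = 1L, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, k = as.integer(k), fraction = fraction,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "split_scheme")
}

#' Generate the test-fold index sets of a split scheme
#'
#' @param scheme A [split_scheme()].
#' @param n Number of observations.
#' @return List over repeats; each element is a list of integer vectors of
#'   test indices that partition `1:n` (k-fold, loocv) or a single held-out
#'   test set (fraction).
#' @export
make_folds <- function(scheme, n) {
  stopifnot(inherits(scheme, "split_scheme"))
  withr::with_seed(scheme$seed, {
    lapply(seq_len(scheme$repeats), function(r) {
      perm <- sample.int(n)
      switch(scheme$kind,
        kfold = {
          if (scheme$k > n) stop("more folds than observations")
          sizes <- rep(n %/% scheme$k, scheme$k)
          extra <- n %% scheme$k
          if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
          unname(lapply(split(perm, rep(seq_len(scheme$k), sizes)), unname))
        },
        loocv = as.list(perm),
        fraction = {
          n_train <- round(scheme$fraction * n)
          if (n_train < 1L || n_train >= n) stop("degenerate split sizes")
          list(perm[(n_train + 1L):n])
        })
    })
  })
}

#' Repeated cross-validation of a fate model
#'
#' For each repeat and fold: fit the chosen fate-model kind on the training
#' rows, predict the held-out rows, and record Spearman and Pearson
#' correlations, RMSE and the Kullback-Leibler loss.  5-fold with 200
#' repeats therefore yields exactly 1000 rows.  Folds whose test set is
#' smaller than 3 rows, or whose predictions have zero variance, carry `NA`
#' correlations; they are excluded from the joint-threshold counts (the
#' `flagged` column marks them).
#'
#' @param table Filtered `observation_table`.
#' @param fate Fate column to predict.
#' @param kind `"powerlaw"` or `"linear"`.
#' @param scheme A [split_scheme()].
#' @param epsilon,n_components Passed to [fit_fate_model()].
#' @return A data.frame of class `crossval_results`: one row per fold with
#'   columns repeat_, fold, spearman, pearson, rmse, kl, n_test, flagged.
#' @export
run_crossval <- function(table, fate, kind = c("powerlaw", "linear"),
                         scheme = split_scheme("kfold", k = 5L, repeats = 1L),
                         epsilon = 1e-6, n_components = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_observation_table(table))
  n <- nrow(table)
  folds <- make_folds(scheme, n)
  rows <- list()
  for (r in seq_along(folds)) {
    for (f in seq_along(folds[[r]])) {
      test_idx <- folds[[r]][[f]]
      train <- table[setdiff(seq_len(n), test_idx), ]
      test <- table[test_idx, ]
      model <- fit_fate_model(train, fate, kind, epsilon = epsilon,
                              n_components = n_components)
      y <- as.data.frame(test)[[fate]]
      y_hat <- predict_fate(model, test)
      ev <- eval_predictions(y, y_hat)
      flagged <- length(test_idx) < 3L ||
        is.na(ev$spearman) || is.na(ev$pearson)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = r, fold = f, spearman = ev$spearman, pearson = ev$pearson,
        rmse = ev$rmse, kl = ev$kl, n_test = ev$n_predictions,
        flagged = flagged)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- scheme$seed
  class(out) <- c("crossval_results", "data.frame")
  out
}

#' Count folds whose correlations jointly exceed a threshold
#'
#' Number of cross-validation results with both the Spearman and the
#' Pearson correlation above `tau`.  Flagged (undefined) folds never count.
#'
#' @param results A `crossval_results` data.frame (or any data.frame with
#'   `spearman` and `pearson` columns).
#' @param tau Threshold.
#' @return Integer count.
#' @export
count_joint_threshold <- function(results, tau) {
  if (NROW(results) == 0L) return(0L)
  ok <- !is.na(results$spearman) & !is.na(results$pearson)
  sum(ok & results$spearman > tau & results$pearson > tau)
}

#' Train on one cell line, test on another
#'
#' Fits the chosen fate model once on the full training table and evaluates
#' it once on the full test table, reporting Spearman, Pearson, RMSE and
#' Kullback-Leibler loss.  The two tables must share the same protein set.
#'
#' @param train,test Filtered `observation_table`s with identical protein
#'   sets.
#' @param fate Fate column present in both tables.
#' @param kind `"powerlaw"` or `"linear"`.
#' @param epsilon,n_components Passed to [fit_fate_model()].
#' @return Named list: `spearman`, `pearson`, `rmse`, `kl`,
#'   `n_predictions`, plus the fitted `model`.
#' @export
cross_cellline <- function(train, test, fate, kind = c("powerlaw", "linear"),
                           epsilon = 1e-6, n_components = NULL) {
  kind <- match.arg(kind)
  if (!setequal(signal_names(train), signal_names(test))) {
    stop("train and test tables must share the same protein set")
  }
  model <- fit_fate_model(train, fate, kind, epsilon = epsilon,
                          n_components = n_components)
  y <- as.data.frame(test)[[fate]]
  y_hat <- predict_fate(model, test)
  c(eval_predictions(y, y_hat), list(model = model))
}

#' Per-protein prediction protocol for response-free datasets
#'
#' For datasets with signaling measurements but no cell-fate readout, each
#' protein in turn is treated as the dependent variable and predicted from
#' all the others.  Per repeat, the observations are split at random into a
#' training fraction (default two thirds) and a held-out third; on the
#' training part leave-one-out cross-validation is run, the fitted
#' coefficient vectors (back-transformed, including the intercept) are
#' averaged over the folds, and the averaged model predicts the held-out
#' part.  The per-protein RMSEs are aggregated over proteins and repeats.
#'
#' @param table Filtered `observation_table` (signals only; fates ignored).
#' @param kind `"powerlaw"` or `"linear"`.
#' @param seed Integer seed for the repeated splits.
#' @param n_repeats Number of random splits (default 100).
#' @param fraction Training fraction (default 2/3).
#' @param epsilon Offset for the power-law kind.
#' @param n_components PLS components.
#' @return List: `mean_rmse` (scalar), `per_protein` (named mean RMSE per
#'   protein), `per_repeat` (matrix repeats x proteins).
#' @export
dream8_protein_cv <- function(table, kind = c("powerlaw", "linear"),
                              seed = 1L, n_repeats = 100L, fraction = 2 / 3,
                              epsilon = 1e-6, n_components = NULL) {
  kind <- match.arg(kind)
  stopifnot(is_observation_table(table))
  X <- signal_matrix(table, "signals")
  proteins <- colnames(X)
  if (length(proteins) < 3L) stop("need at least 3 proteins")
  n <- nrow(X)
  res <- withr::with_seed(seed, {
    sapply(seq_len(n_repeats), function(r) {
      perm <- sample.int(n)
      n_train <- round(fraction * n)
      if (n_train < 3L || n_train >= n) stop("degenerate split sizes")
      train_idx <- perm[seq_len(n_train)]
      test_idx <- perm[(n_train + 1L):n]
      vapply(seq_along(proteins), function(i) {
        predict_protein_loocv(X, i, train_idx, test_idx, kind, epsilon,
                              n_components)
      }, numeric(1L))
    })
  })
  res <- t(res)  # repeats x proteins
  colnames(res) <- proteins
  list(mean_rmse = mean(res), per_protein = colMeans(res), per_repeat = res)
}

# LOOCV-averaged coefficients on the training rows, evaluated on the test rows
predict_protein_loocv <- function(X, i, train_idx, test_idx, kind, epsilon,
                                  n_components) {
  y_all <- X[, i]
  Z_all <- X[, -i, drop = FALSE]
  if (kind == "powerlaw") {
    if (any(y_all <= epsilon)) {
      epsilon <- min(epsilon, min(y_all) / 2)
    }
    y_fit <- log(y_all - epsilon)
    Z_fit <- log(Z_all)
  } else {
    y_fit <- y_all
    Z_fit <- Z_all
  }
  coefs <- vapply(train_idx, function(held) {
    tr <- setdiff(train_idx, held)
    a <- default_components(length(tr), ncol(Z_fit), n_components)
    pls <- fit_pls(Z_fit[tr, , drop = FALSE], y_fit[tr], n_components = a)
    c(pls$intercept, drop(pls$coefficients))
  }, numeric(1L + ncol(Z_fit)))
  avg <- rowMeans(coefs)
  lin_pred <- drop(Z_fit[test_idx, , drop = FALSE] %*% avg[-1L]) + avg[1L]
  y_hat <- if (kind == "powerlaw") exp(lin_pred) + epsilon else lin_pred
  rmse(y_all[test_idx], y_hat)
}
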