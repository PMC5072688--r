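#' Kullback-Leibler loss between actual and predicted probabilities
#'
#' Base-2 Kullback-Leibler style loss over a list of m predictions,
#' \deqn{L(p, \hat p) = \sum_{i=1}^{m} p_i \log_2(p_i / \hat p_i),}
#' computed over the raw per-prediction probability pairs without
#' renormalizing them into a distribution (m is simply the number of
#' predictions pooled).  Terms with \eqn{p_i = 0} contribute exactly 0.
#' Because the fitted models can predict values outside (0, 1], predictions
#' are clipped into `[clip, 1]` before the logarithm.
#'
#' @param p Actual probabilities, each in \[0, 1\].
#' @param p_hat Predicted probabilities (same length as `p`).
#' @param clip Lower clipping bound for predictions; default `1e-12`.
#' @return Loss in bits (non-negative when predictions are proper).
#' @export
#' @examples
#' kl_divergence(c(0.5, 0.5), c(0.25, 0.75))  # 0.20752...
kl_divergence <- function(p, p_hat, clip = 1e-12) {
  if (length(p) != length(p_hat)) stop("p and p_hat must have equal length")
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]")
  }
  q <- pmin(pmax(p_hat, clip), 1)
  terms <- ifelse(p == 0, 0, p * log2(p / q))
  sum(terms)
}

#' Akaike information criterion from a Kullback-Leibler loss
#'
#' \deqn{AIC = \log(L(p, \hat p)) + 2k/m,}
#' where k is the number of model parameters and m the number of
#' predictions.  The logarithm defaults to base 2, consistent with the
#' base-2 loss of [kl_divergence()]; set `base = exp(1)` for a natural-log
#' variant.
#'
#' @param loss Positive loss value \eqn{L(p,\hat p)}.
#' @param k Number of model parameters.
#' @param m Number of predictions.
#' @param base Logarithm base (default 2).
#' @return AIC value.
#' @export
#' @examples
#' aic(450.5, k = 33, m = 32800)   # ~8.8
#' aic(1117.5, k = 33, m = 32800)  # ~10.1
aic <- function(loss, k, m, base = 2) {
  if (!is.finite(loss) || loss <= 0) stop("loss must be positive")
  if (m <= 0) stop("m must be positive")
  log(loss, base = base) + 2 * k / m
}

#' Goodness-of-fit statistics
#'
#' Returns the sum of squared errors, R-square, degrees-of-freedom adjusted
#' R-square and root mean squared error for a set of predictions.  Two RMSE
#' conventions are in use: curve-fitting tools divide the SSE by the
#' residual degrees of freedom (`rmse_type = "dof"`, the default here,
#' matching the curve-family reports), whereas prediction pipelines divide
#' by the number of predictions (`rmse_type = "mean"`).
#'
#' @param y Actual values.
#' @param y_hat Predicted values (same length).
#' @param n_params Number of fitted parameters k (for the adjusted
#'   statistics); default 0.
#' @param rmse_type `"dof"` (`sqrt(SSE / (n - k))`) or `"mean"`
#'   (`sqrt(SSE / n)`).
#' @return Named list: `sse`, `r2`, `adj_r2`, `rmse`.
#' @export
goodness_of_fit <- function(y, y_hat, n_params = 0L,
                            rmse_type = c("dof", "mean")) {
  rmse_type <- match.arg(rmse_type)
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  n <- length(y)
  sse <- sum((y - y_hat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  dof <- n - n_params
  adj_r2 <- if (sst > 0 && dof > 0 && n > 1L) {
    1 - (sse / dof) / (sst / (n - 1L))
  } else NA_real_
  rmse <- switch(rmse_type,
                 dof = if (dof > 0) sqrt(sse / dof) else NA_real_,
                 mean = sqrt(sse / n))
  list(sse = sse, r2 = r2, adj_r2 = adj_r2, rmse = rmse)
}

#' Root mean squared error (prediction convention)
#'
#' @param y,y_hat Numeric vectors of equal length.
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  sqrt(mean((y - y_hat)^2))
}

#' Spearman and Pearson correlations between actual and predicted values
#'
#' Spearman uses average ranks for ties (the standard definition:
#' Pearson correlation of the rank vectors).
#'
#' @param y Actual values (length >= 3).
#' @param y_hat Predicted values.
#' @return Named list `spearman`, `pearson`; `NA` entries if either vector
#'   has zero variance.
#' @export
rank_correlation <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("y and y_hat must have equal length")
  if (length(y) < 3L) stop("need at least 3 values for correlations")
  if (sd(y) == 0 || sd(y_hat) == 0) {
    return(list(spearman = NA_real_, pearson = NA_real_))
  }
  list(spearman = suppressWarnings(cor(y, y_hat, method = "spearman")),
       pearson = cor(y, y_hat, method = "pearson"))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test) comparing
#' the means of two or more groups, as used to compare correlation
#' coefficients between models across repeated validations.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values),
#'   or a named list.
#' @return Named list `f`, `p`, `df_between`, `df_within`.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("each group needs >= 2 values")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(seq_along(groups), sizes))
  ft <- stats::oneway.test(values ~ labels, var.equal = TRUE)
  list(f = unname(ft$statistic), p = unname(ft$p.value),
       df_between = unname(ft$parameter[1L]),
       df_within = unname(ft$parameter[2L]))
}

#' Evaluate predictions against observed fate probabilities
#'
#' Bundles the per-fold evaluation statistics used throughout the
#' cross-validation pipelines: Spearman and Pearson correlations, RMSE
#' (prediction convention) and the Kullback-Leibler loss.
#'
#' @param y Actual fate probabilities.
#' @param y_hat Predicted fate values.
#' @return Named list `spearman`, `pearson`, `rmse`, `kl`, `n_predictions`.
#' @export
eval_predictions <- function(y, y_hat) {
  rc <- if (length(y) >= 3L) rank_correlation(y, y_hat) else
    list(spearman = NA_real_, pearson = NA_real_)
  kl <- if (all(y >= 0 & y <= 1)) kl_divergence(y, y_hat) else NA_real_
  list(spearman = rc$spearman, pearson = rc$pearson,
       rmse = rmse(y, y_hat), kl = kl, n_predictions = length(y))
}
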