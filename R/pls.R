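#' Partial least squares regression (NIPALS)
#'
#' Fits a PLS2 regression of `Y` on `X` by NIPALS deflation.  Predictors and
#' responses are mean-centered and scaled to unit (sample) variance by
#' default; the implied regression coefficients are mapped back through the
#' centering/scaling so that [predict()] works on the original scale.  With
#' the full number of components on a full-rank problem the fit coincides
#' with ordinary least squares.
#'
#' @param X Numeric predictor matrix (n x p), no missing values.
#' @param Y Numeric response matrix or vector (n x q).
#' @param n_components Number of latent components, at most `min(p, n - 1)`.
#' @param center,scale Logical; center/scale columns of X and Y.  A
#'   zero-variance predictor column is an error when `scale = TRUE`;
#'   zero-variance response columns are centered but left unscaled.
#' @param tol Convergence tolerance of the NIPALS inner loop.
#' @param max_iter Maximum inner-loop iterations per component.
#'
#' @return An object of class `pls_model` with elements `weights` (p x A),
#'   `x_loadings` (p x A), `y_loadings` (q x A), `scores` (n x A),
#'   `coefficients` (p x q, original scale), `intercept` (length q),
#'   `x_center`, `x_scale`, `y_center`, `y_scale`, `n_components` (number
#'   actually extracted).
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, -2, 0.5) + rnorm(20, sd = 0.01)
#' fit <- fit_pls(X, y, n_components = 3)
#' max(abs(predict(fit, X) - y)) < 0.1
fit_pls <- function(X, Y, n_components, center = TRUE, scale = TRUE,
                    tol = 1e-12, max_iter = 500L) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  storage.mode(X) <- "double"
  storage.mode(Y) <- "double"
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (anyNA(X) || anyNA(Y)) stop("missing values are not allowed")
  a_max <- min(p, n - 1L)
  if (n_components < 1L || n_components > a_max) {
    stop("n_components must be between 1 and min(ncol(X), nrow(X) - 1) = ", a_max)
  }
  x_center <- if (center) colMeans(X) else rep(0, p)
  y_center <- if (center) colMeans(Y) else rep(0, q)
  x_scale <- if (scale) apply(X, 2L, sd) else rep(1, p)
  y_scale <- if (scale) apply(Y, 2L, sd) else rep(1, q)
  if (any(x_scale == 0)) {
    stop("zero-variance predictor column(s): ",
         paste(colnames(X)[x_scale == 0], collapse = ", "))
  }
  y_scale[y_scale == 0] <- 1  # constant response: centered residual is 0
  E <- sweep(sweep(X, 2L, x_center, "-"), 2L, x_scale, "/")
  Fm <- sweep(sweep(Y, 2L, y_center, "-"), 2L, y_scale, "/")

  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  C <- matrix(0, q, n_components)
  Tm <- matrix(0, n, n_components)
  a_used <- 0L
  for (a in seq_len(n_components)) {
    if (sum(E^2) < 1e-14 || sum(Fm^2) < 1e-14) break
    u <- Fm[, which.max(colSums(Fm^2))]
    t_old <- rep(Inf, n)
    t_sc <- NULL
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      wn <- sqrt(sum(w^2))
      if (wn < 1e-14) break
      w <- w / wn
      t_sc <- drop(E %*% w)
      cvec <- crossprod(Fm, t_sc) / sum(t_sc^2)
      u <- drop(Fm %*% cvec) / sum(cvec^2)
      if (sum((t_sc - t_old)^2) < tol * sum(t_sc^2)) break
      t_old <- t_sc
    }
    if (is.null(t_sc) || sum(t_sc^2) < 1e-14) break
    p_load <- crossprod(E, t_sc) / sum(t_sc^2)
    E <- E - tcrossprod(t_sc, p_load)
    Fm <- Fm - tcrossprod(t_sc, cvec)
    W[, a] <- w; P[, a] <- p_load; C[, a] <- cvec; Tm[, a] <- t_sc
    a_used <- a
  }
  if (a_used == 0L) {
    coef_scaled <- matrix(0, p, q)
  } else {
    Wa <- W[, seq_len(a_used), drop = FALSE]
    Pa <- P[, seq_len(a_used), drop = FALSE]
    Ca <- C[, seq_len(a_used), drop = FALSE]
    coef_scaled <- Wa %*% solve(crossprod(Pa, Wa), t(Ca))
  }
  coefficients <- (coef_scaled / x_scale) * rep(y_scale, each = p)
  intercept <- drop(y_center - crossprod(coefficients, x_center))
  dimnames(coefficients) <- list(colnames(X), colnames(Y))
  structure(list(
    n_components = a_used,
    requested_components = n_components,
    weights = W[, seq_len(max(a_used, 1L)), drop = FALSE],
    x_loadings = P[, seq_len(max(a_used, 1L)), drop = FALSE],
    y_loadings = C[, seq_len(max(a_used, 1L)), drop = FALSE],
    scores = Tm[, seq_len(max(a_used, 1L)), drop = FALSE],
    coefficients = coefficients,
    intercept = intercept,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    centered = center, scaled = scale
  ), class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  out <- newdata %*% object$coefficients +
    matrix(object$intercept, nrow(newdata), length(object$intercept), byrow = TRUE)
  out
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d component(s), %d predictor(s), %d response(s)\n",
              x$n_components, nrow(x$coefficients), ncol(x$coefficients)))
  invisible(x)
}

#' Project new observations onto the latent components
#'
#' Returns the X-scores of `newdata` under a fitted PLS model, using the
#' standard weights `W (P'W)^{-1}` so that deflation is accounted for.
#'
#' @param object A `pls_model`.
#' @param newdata Predictor matrix on the original scale.
#' @param n_components How many score columns to return (default: all fitted).
#' @return Matrix of scores (n x n_components).
#' @export
pls_scores <- function(object, newdata, n_components = object$n_components) {
  stopifnot(inherits(object, "pls_model"))
  n_components <- min(n_components, object$n_components)
  E <- sweep(sweep(as.matrix(newdata), 2L, object$x_center, "-"),
             2L, object$x_scale, "/")
  Wa <- object$weights[, seq_len(n_components), drop = FALSE]
  Pa <- object$x_loadings[, seq_len(n_components), drop = FALSE]
  Rw <- Wa %*% solve(crossprod(Pa, Wa))
  E %*% Rw
}

# rank-safe default component count used across the package
default_components <- function(n_rows, n_pred, requested = NULL) {
  bound <- min(n_pred, n_rows - 1L)
  if (is.null(requested)) min(10L, bound) else min(requested, bound)
}
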