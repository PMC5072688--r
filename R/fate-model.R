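#' Fit a fate model relating protein activities to a cell-fate probability
#'
#' Two model kinds are supported.  The linear baseline regresses the fate
#' value P directly on the protein activities x_i,
#' \deqn{P = \sum_i \alpha_i x_i + intercept.}
#' The nonlinear power-law model represents P as a product of power
#' functions of the activities,
#' \deqn{P = e^{\beta_0} \prod_i x_i^{\beta_i} + \epsilon,}
#' which is fitted in log space as the linear regression
#' \deqn{\ln(P - \epsilon) = \beta_0 + \sum_i \beta_i \ln(x_i).}
#' Both kinds are estimated by partial least squares regression
#' ([fit_pls()]); the stored coefficients are the PLS-implied regression
#' coefficients mapped back through the centering/scaling, so fitting the
#' power-law kind is exactly the linear fit of the log-transformed table.
#'
#' The offset \eqn{\epsilon} keeps the power function from being pinned to
#' the origin; it must be smaller than every training fate value so that
#' \eqn{\ln(P - \epsilon)} exists.
#'
#' @param table A filtered [observation_table()] (all signal and fate values
#'   strictly positive; see [filter_valid()]).
#' @param fate Name of the fate column to model.
#' @param kind `"powerlaw"` or `"linear"`.
#' @param epsilon Offset \eqn{\epsilon \ge 0}; default `1e-6`.  Ignored by
#'   the linear kind.
#' @param n_components PLS components; default `min(10, min(p, n - 1))`.
#' @param intercept Logical (linear kind only): fit an intercept.  Default
#'   `TRUE`; with `FALSE` the linear map is forced through the origin.
#' @return An object of class `fate_model`: list with `kind`,
#'   `protein_names`, `beta0` (intercept), `beta` (named coefficient
#'   vector), `epsilon`, `n_components`, and the underlying `pls` fit.
#' @seealso [predict_fate()], [write_fate_model()]
#' @export
fit_fate_model <- function(table, fate, kind = c("powerlaw", "linear"),
                           epsilon = 1e-6, n_components = NULL,
                           intercept = TRUE) {
  kind <- match.arg(kind)
  stopifnot(is_observation_table(table))
  if (!fate %in% fate_names(table)) stop("unknown fate column: ", fate)
  if (nrow(table) < 2L) stop("need at least 2 observations")
  X <- signal_matrix(table, "signals")
  y <- as.data.frame(table)[[fate]]
  if (anyNA(X) || anyNA(y)) stop("table contains missing values; run filter_valid() first")
  if (kind == "powerlaw") {
    if (any(X <= 0)) stop("power-law kind requires strictly positive signals")
    if (epsilon < 0) stop("epsilon must be non-negative")
    if (any(y <= epsilon)) {
      stop("epsilon (", epsilon, ") must be smaller than every fate value (min ",
           min(y), ")")
    }
    Xr <- log(X)
    yr <- log(y - epsilon)
    center <- TRUE
  } else {
    Xr <- X
    yr <- y
    center <- intercept
  }
  a <- default_components(nrow(Xr), ncol(Xr), n_components)
  pls <- fit_pls(Xr, yr, n_components = a, center = center, scale = center)
  beta <- drop(pls$coefficients)
  names(beta) <- colnames(X)
  structure(list(
    kind = kind,
    protein_names = colnames(X),
    fate = fate,
    beta0 = unname(pls$intercept),
    beta = beta,
    epsilon = if (kind == "powerlaw") epsilon else 0,
    n_components = pls$n_components,
    intercept = intercept,
    pls = pls
  ), class = "fate_model")
}

#' Number of free parameters of a fate model
#'
#' Coefficients plus the intercept (n + 1 for n proteins); used in the AIC
#' penalty.
#' @param model A `fate_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "fate_model"))
  length(model$beta) + 1L
}

#' Predict fate values from protein activities
#'
#' Applies a fitted [fit_fate_model()] to new signal data.  For the
#' power-law kind the prediction is
#' \eqn{e^{\beta_0} \prod_i x_i^{\beta_i} + \epsilon} and every signal must
#' be strictly positive; for the linear kind it is
#' \eqn{\sum_i \alpha_i x_i} plus the learned intercept.  Columns are
#' matched by protein name, so predictions are invariant to column order.
#'
#' @param model A `fate_model`.
#' @param signals A named numeric vector (one observation), a matrix or
#'   data.frame with protein-named columns, or an `observation_table`.
#' @return Numeric vector of predicted fate values, one per observation.
#' @export
predict_fate <- function(model, signals) {
  stopifnot(inherits(model, "fate_model"))
  X <- signals_as_matrix(signals, model$protein_names)
  if (model$kind == "powerlaw") {
    if (any(X <= 0)) stop("power-law prediction requires strictly positive signals")
    drop(exp(model$beta0 + log(X) %*% model$beta)) + model$epsilon
  } else {
    drop(X %*% model$beta) + model$beta0
  }
}

signals_as_matrix <- function(signals, protein_names) {
  if (is_observation_table(signals)) {
    X <- signal_matrix(signals, "signals")
  } else if (is.null(dim(signals))) {
    if (is.null(names(signals))) {
      if (length(signals) != length(protein_names)) {
        stop("unnamed signal vector of wrong length")
      }
      X <- matrix(signals, 1L, dimnames = list(NULL, protein_names))
    } else {
      X <- matrix(unlist(signals), 1L, dimnames = list(NULL, names(signals)))
    }
  } else {
    X <- as.matrix(signals)
  }
  absent <- setdiff(protein_names, colnames(X))
  if (length(absent) > 0L) {
    stop("missing proteins: ", paste(absent, collapse = ", "))
  }
  extra <- setdiff(colnames(X), protein_names)
  if (length(extra) > 0L) {
    stop("unknown proteins: ", paste(extra, collapse = ", "))
  }
  X[, protein_names, drop = FALSE]
}

#' @export
print.fate_model <- function(x, ...) {
  cat(sprintf("<fate_model> kind = %s, %d proteins, %d PLS component(s)\n",
              x$kind, length(x$beta), x$n_components))
  if (x$kind == "powerlaw") {
    cat(sprintf("  beta0 = %.4g, epsilon = %.3g\n", x$beta0, x$epsilon))
  } else {
    cat(sprintf("  intercept = %.4g\n", x$beta0))
  }
  cat("  coefficients:\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Serialize / reload a fate model
#'
#' Writes the model (kind, protein names, coefficients, offset, scaling
#' vectors and component count) as JSON so that a fit can be reloaded
#' exactly.
#'
#' @param model A `fate_model`.
#' @param path Output (input) file path.
#' @return `path` invisibly; `read_fate_model()` returns the `fate_model`.
#' @export
write_fate_model <- function(model, path) {
  stopifnot(inherits(model, "fate_model"))
  payload <- list(
    kind = model$kind,
    protein_names = model$protein_names,
    fate = model$fate,
    beta0 = model$beta0,
    beta = as.list(model$beta),
    epsilon = model$epsilon,
    n_components = model$n_components,
    intercept = model$intercept
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fate_model
#' @export
read_fate_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(payload$beta)
  structure(list(
    kind = payload$kind,
    protein_names = payload$protein_names,
    fate = payload$fate,
    beta0 = payload$beta0,
    beta = setNames(as.numeric(beta), names(beta)),
    epsilon = payload$epsilon,
    n_components = payload$n_components,
    intercept = payload$intercept,
    pls = NULL
  ), class = "fate_model")
}
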