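#' Fit the protein-on-protein power-law influence matrix
#'
#' Models every protein's activity as a power-law function of all the other
#' measured proteins,
#' \deqn{x_i = e^{\lambda_{i0}} \prod_{j \ne i} x_j^{\lambda_{ij}} + \epsilon_i,}
#' estimated as n independent log-space PLS regressions (protein i on all
#' proteins j != i).  The resulting matrix \eqn{\lambda} has
#' \eqn{\lambda_{ij}} = influence of protein j on protein i, with the
#' diagonal fixed at zero.
#'
#' @param table A filtered [observation_table()].
#' @param epsilon Per-protein offsets \eqn{\epsilon_i}: scalar recycled to
#'   all proteins, or a named/ordered vector.  Each must be smaller than the
#'   smallest observed value of its protein.  Default `1e-6`.
#' @param n_components PLS components per regression; default
#'   `min(10, min(n - 1, p - 1))`.
#' @return An object of class `influence_matrix`: list with `lambda`
#'   (n x n, zero diagonal, rownames = target protein), `lambda0`
#'   (per-target intercepts), `epsilon` (per-target offsets) and
#'   `protein_names`.
#' @export
fit_influence_matrix <- function(table, epsilon = 1e-6, n_components = NULL) {
  stopifnot(is_observation_table(table))
  X <- signal_matrix(table, "signals")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (anyNA(X) || any(X <= 0)) {
    stop("table must be filtered to strictly positive signals")
  }
  proteins <- colnames(X)
  n <- length(proteins)
  if (n < 2L) stop("need at least 2 proteins")
  eps <- rep_len(unlist(epsilon), n)
  names(eps) <- proteins
  too_big <- eps >= apply(X, 2L, min)
  if (any(too_big)) {
    stop("epsilon must be below the minimum observed value for: ",
         paste(proteins[too_big], collapse = ", "))
  }
  const_col <- apply(X, 2L, function(col) sd(col) == 0)
  if (any(const_col)) {
    stop("constant protein column(s): ",
         paste(proteins[const_col], collapse = ", "))
  }
  logX <- log(X)
  lambda <- matrix(0, n, n, dimnames = list(proteins, proteins))
  lambda0 <- setNames(numeric(n), proteins)
  for (i in seq_len(n)) {
    yi <- log(X[, i] - eps[i])
    Xi <- logX[, -i, drop = FALSE]
    a <- default_components(nrow(Xi), ncol(Xi), n_components)
    pls <- fit_pls(Xi, yi, n_components = a)
    lambda[i, -i] <- drop(pls$coefficients)
    lambda0[i] <- unname(pls$intercept)
  }
  structure(list(lambda = lambda, lambda0 = lambda0, epsilon = eps,
                 protein_names = proteins),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix> %d proteins\n", length(x$protein_names)))
  print(round(x$lambda, 3))
  invisible(x)
}

#' Serialize / reload an influence matrix as a labeled text file
#'
#' The matrix is written as a tab-delimited labeled square table with the
#' intercepts and offsets in leading columns.
#'
#' @param M An `influence_matrix`.
#' @param path File path.
#' @return `path` invisibly; `read_influence_matrix()` returns the object.
#' @export
write_influence_matrix <- function(M, path) {
  stopifnot(inherits(M, "influence_matrix"))
  df <- data.frame(protein = M$protein_names, lambda0 = M$lambda0,
                   epsilon = M$epsilon, M$lambda, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_influence_matrix
#' @export
read_influence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  proteins <- df$protein
  lambda <- as.matrix(df[, proteins, drop = FALSE])
  rownames(lambda) <- proteins
  structure(list(lambda = lambda,
                 lambda0 = setNames(df$lambda0, proteins),
                 epsilon = setNames(df$epsilon, proteins),
                 protein_names = proteins),
            class = "influence_matrix")
}

#' Virtual knock-down of one protein
#'
#' Simulates the removal of protein k from the signaling system: every
#' entry of column k of the influence matrix is set to zero (protein k no
#' longer influences any other protein), the fate coefficient
#' \eqn{\beta_k} is set to zero (no direct contribution to the fate), and
#' every remaining fate coefficient is rewired through the influence
#' matrix,
#' \deqn{\beta'_j = \sum_i \lambda_{ij} \beta_i,}
#' so that the contribution of protein j to the fate is the one it makes by
#' influencing the other proteins as intermediaries.  The order of
#' operations is fixed: zero column k, zero \eqn{\beta_k}, then compute
#' \eqn{\beta'}.  An additive variant
#' \eqn{\beta'_j = \beta_j + \sum_i \lambda_{ij} \beta_i}, which retains
#' the direct effects, is available with `rule = "additive"`.
#' \eqn{\beta_0} and \eqn{\epsilon} are left unchanged, and inputs are
#' never modified.  Knocking down a protein that the model already has
#' knocked down returns the model unchanged.
#'
#' @param M An `influence_matrix`.
#' @param fate_model A power-law `fate_model` sharing `M`'s protein order.
#' @param k Protein index or name to knock down.
#' @param rule `"replace"` (the literal rewiring rule, default) or
#'   `"additive"`.
#' @return A new `fate_model` with the rewired coefficients.
#' @export
virtual_knockdown <- function(M, fate_model, k, rule = c("replace", "additive")) {
  rule <- match.arg(rule)
  stopifnot(inherits(M, "influence_matrix"), inherits(fate_model, "fate_model"))
  if (fate_model$kind != "powerlaw") {
    stop("virtual knock-down is defined for the power-law fate model")
  }
  if (!identical(M$protein_names, fate_model$protein_names)) {
    stop("influence matrix and fate model must share the same protein order")
  }
  if (is.character(k)) k <- match(k, M$protein_names)
  n <- length(M$protein_names)
  if (is.na(k) || k < 1L || k > n) stop("protein index out of range")
  if (identical(fate_model$knocked, k)) return(fate_model)
  lam <- M$lambda
  lam[, k] <- 0
  beta <- fate_model$beta
  beta[k] <- 0
  beta_new <- switch(rule,
    replace = drop(crossprod(lam, beta)),
    additive = beta + drop(crossprod(lam, beta)))
  beta_new[k] <- 0
  names(beta_new) <- M$protein_names
  out <- fate_model
  out$beta <- beta_new
  out$knocked <- k
  out$pls <- NULL
  out
}

#' Rank virtual knock-downs against observed (drugged or stimulated) data
#'
#' For every candidate protein, applies [virtual_knockdown()], predicts the
#' fate on the observed table and measures the RMSE against the actual fate
#' values.  In `"blocked"` mode proteins are ranked by ascending RMSE: a
#' small error means that removing the protein's influence reproduces the
#' drugged data well, so the treatment most plausibly blocked the signal
#' flow through that protein.  `"enhanced"` mode ranks by descending RMSE
#' (a large post-knock-down discrepancy flags signals enhanced by a
#' stimulus).  Ties are broken by protein name for reproducibility.
#'
#' @param fate_model Power-law `fate_model` fitted on the control group.
#' @param M `influence_matrix` fitted on the control group.
#' @param observed Filtered `observation_table` of the drugged / stimulated
#'   group.
#' @param fate Fate column name in `observed`.
#' @param mode `"blocked"` (ascending RMSE) or `"enhanced"` (descending).
#' @param rule Rewiring rule passed to [virtual_knockdown()].
#' @return An object of class `knockdown_report`: list with `mode` and
#'   `entries`, a data.frame (protein, rmse, rank) sorted per mode.
#' @export
rank_knockdowns <- function(fate_model, M, observed, fate,
                            mode = c("blocked", "enhanced"),
                            rule = c("replace", "additive")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  stopifnot(is_observation_table(observed))
  if (nrow(observed) == 0L) stop("observed table is empty")
  if (!fate %in% fate_names(observed)) stop("unknown fate column: ", fate)
  y <- as.data.frame(observed)[[fate]]
  proteins <- fate_model$protein_names
  errs <- vapply(seq_along(proteins), function(k) {
    km <- virtual_knockdown(M, fate_model, k, rule = rule)
    rmse(y, predict_fate(km, observed))
  }, numeric(1L))
  df <- data.frame(protein = proteins, rmse = errs)
  ord <- if (mode == "blocked") order(df$rmse, df$protein)
         else order(-df$rmse, df$protein)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(list(mode = mode, entries = df), class = "knockdown_report")
}

#' @export
print.knockdown_report <- function(x, ...) {
  cat(sprintf("<knockdown_report> mode = %s\n", x$mode))
  print(x$entries, digits = 4)
  invisible(x)
}
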