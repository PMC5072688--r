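#' Generate an observation table from a known power-law ground truth
#'
#' Draws lognormal protein activities and computes the fate as
#' \deqn{P = e^{\beta_0} \prod_i x_i^{\beta_i} \cdot e^{\eta} + \epsilon,}
#' with multiplicative lognormal noise \eqn{\eta \sim N(0, \sigma^2)}.
#' With `noise_sd = 0` the table is an exact realization of the model, so
#' [fit_fate_model()] with full components recovers `beta` to numerical
#' precision -- the main parameter-recovery oracle of the test suite.
#'
#' @param n_obs Number of observations (>= n_proteins + 2).
#' @param n_proteins Number of proteins.
#' @param beta0 Intercept \eqn{\beta_0}.
#' @param beta Exponent vector (length `n_proteins`); default: evenly
#'   spaced in \[-0.5, 0.8\].
#' @param epsilon Offset \eqn{\epsilon \ge 0}.
#' @param noise_sd Standard deviation \eqn{\sigma} of the multiplicative
#'   log-scale noise.
#' @param signal_meanlog,signal_sdlog Lognormal parameters of the signals.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments.
#' @param cell_line Metadata label stamped on every record.
#' @return List: `table` (an [observation_table()] with fate column
#'   `"apoptosis"`) and `truth` (list of the generative parameters,
#'   including the seed).
#' @export
generate_powerlaw_dataset <- function(n_obs, n_proteins,
                                      beta0 = -1,
                                      beta = NULL,
                                      epsilon = 0.001,
                                      noise_sd = 0,
                                      signal_meanlog = 0,
                                      signal_sdlog = 1,
                                      seed = 1L,
                                      cell_line = "synthetic") {
  if (n_obs < n_proteins + 2L) stop("need n_obs >= n_proteins + 2")
  if (is.null(beta)) beta <- seq(-0.5, 0.8, length.out = n_proteins)
  if (length(beta) != n_proteins) stop("beta must have length n_proteins")
  proteins <- sprintf("prot%02d", seq_len(n_proteins))
  withr::with_seed(seed, {
    X <- matrix(rlnorm(n_obs * n_proteins, signal_meanlog, signal_sdlog),
                n_obs, n_proteins, dimnames = list(NULL, proteins))
    eta <- if (noise_sd > 0) rnorm(n_obs, 0, noise_sd) else rep(0, n_obs)
    P <- exp(beta0 + log(X) %*% beta + eta) + epsilon
  })
  if (any(P <= epsilon)) stop("generated fates not above epsilon")
  df <- data.frame(cell_line = cell_line,
                   treatment = "none",
                   time_point = 0,
                   replicate = seq_len(n_obs),
                   X, apoptosis = drop(P), check.names = FALSE)
  table <- observation_table(df, signals = proteins, fates = "apoptosis")
  truth <- list(beta0 = beta0, beta = setNames(beta, proteins),
                epsilon = epsilon, noise_sd = noise_sd, seed = seed)
  list(table = table, truth = truth)
}

#' A sparse cascade influence matrix for simulation studies
#'
#' Builds the lambda matrix of a signaling cascade
#' `prot01 -> prot02 -> ... -> protn` in which each protein drives the next
#' with exponent `strength` (lambda\[i+1, i\] = strength); all other
#' entries, including the diagonal, are zero.
#'
#' @param n_proteins Number of proteins (>= 2).
#' @param strength Power-law exponent along the chain.
#' @return n x n matrix with protein dimnames.
#' @export
cascade_lambda <- function(n_proteins, strength = 0.9) {
  proteins <- sprintf("prot%02d", seq_len(n_proteins))
  lambda <- matrix(0, n_proteins, n_proteins,
                   dimnames = list(proteins, proteins))
  for (i in seq_len(n_proteins - 1L)) lambda[i + 1L, i] <- strength
  lambda
}

#' A receptor-hub-effector influence matrix for knock-down benchmarks
#'
#' Builds the lambda matrix of a hub motif: an upstream receptor
#' (`prot01`) drives a hub kinase (`prot02`), which drives every remaining
#' protein (the effectors).  Blocking the hub severs all receptor-to-
#' effector signaling, which is the canonical drug-action scenario for the
#' virtual knock-down benchmark.
#'
#' @param n_proteins Total number of proteins (>= 3).
#' @param receptor_strength Exponent of receptor -> hub (default 0.9).
#' @param effector_strength Exponent of hub -> each effector (default 0.8).
#' @return n x n matrix with protein dimnames; the hub is row/column 2.
#' @export
hub_lambda <- function(n_proteins, receptor_strength = 0.9,
                       effector_strength = 0.8) {
  if (n_proteins < 3L) stop("need at least 3 proteins")
  proteins <- sprintf("prot%02d", seq_len(n_proteins))
  lambda <- matrix(0, n_proteins, n_proteins,
                   dimnames = list(proteins, proteins))
  lambda[2L, 1L] <- receptor_strength
  for (i in 3:n_proteins) lambda[i, 2L] <- effector_strength
  lambda
}

#' Generate paired control / drugged tables from an influence structure
#'
#' Emulates a drug-treatment experiment on a power-law signaling system.
#' Signals propagate through the directed influence structure `lambda`
#' (lambda\[i, j\] != 0 means protein j drives protein i): root proteins are
#' exogenous lognormal draws, and every non-root protein i is
#' \deqn{x_i = e^{\lambda_{i0}} \prod_j x_j^{\lambda_{ij}} e^{\eta_i} + \epsilon_i.}
#' The fate is a power law over all the proteins with exponents
#' `fate_beta`.
#'
#' In the drugged table the signal flow *into* `blocked_node` is severed:
#' its value is replaced by an independent exogenous draw (basal noise
#' uncorrelated with its parents), its children respond to that noise
#' level, and its direct contribution to the fate is removed
#' (`fate_beta[blocked] = 0`), emulating a drug that blocks both the
#' protein's activation and its downstream signaling.  With
#' `blocked_node = NULL` the drugged table is generated by the identical
#' scheme as the control (same seed gives an identical table).
#'
#' @param n_obs Observations per table.
#' @param lambda n x n influence matrix with zero diagonal; must be
#'   acyclic.
#' @param blocked_node Protein index or name blocked by the "drug", or
#'   `NULL`.
#' @param seed Integer seed.
#' @param lambda0 Per-protein intercepts (default 0).
#' @param epsilon Per-protein offsets (default 0.001).
#' @param noise_sd Log-scale noise sd of the propagation (default 0.05).
#' @param fate_beta Fate exponent vector (default 0.4 for every protein).
#' @param fate_beta0,fate_epsilon Fate intercept and offset.
#' @return List: `control` and `drugged` (observation tables with fate
#'   column `"apoptosis"`), and `truth` (generative parameters incl.
#'   `blocked_node` and `seed`).
#' @export
generate_influence_dataset <- function(n_obs, lambda, blocked_node = NULL,
                                       seed = 1L, lambda0 = NULL,
                                       epsilon = 0.001, noise_sd = 0.05,
                                       fate_beta = NULL, fate_beta0 = -1,
                                       fate_epsilon = 0.001) {
  lambda <- as.matrix(lambda)
  n <- nrow(lambda)
  if (ncol(lambda) != n) stop("lambda must be square")
  if (any(diag(lambda) != 0)) stop("lambda must have a zero diagonal")
  proteins <- rownames(lambda)
  if (is.null(proteins)) {
    proteins <- sprintf("prot%02d", seq_len(n))
    dimnames(lambda) <- list(proteins, proteins)
  }
  if (is.null(lambda0)) lambda0 <- setNames(rep(0, n), proteins)
  eps <- rep_len(unlist(epsilon), n)
  if (is.null(fate_beta)) fate_beta <- rep(0.4, n)
  if (is.character(blocked_node)) blocked_node <- match(blocked_node, proteins)
  order_idx <- topological_order(lambda)

  gen_table <- function(sub_seed, blocked) {
    withr::with_seed(sub_seed, {
      X <- matrix(NA_real_, n_obs, n, dimnames = list(NULL, proteins))
      for (i in order_idx) {
        parents <- which(lambda[i, ] != 0)
        exogenous <- length(parents) == 0L || (!is.null(blocked) && i == blocked)
        if (exogenous) {
          X[, i] <- rlnorm(n_obs, 0, 1)
        } else {
          eta <- rnorm(n_obs, 0, noise_sd)
          X[, i] <- exp(lambda0[i] +
                          log(X[, parents, drop = FALSE]) %*% lambda[i, parents] +
                          eta) + eps[i]
        }
      }
      fb <- fate_beta
      if (!is.null(blocked)) fb[blocked] <- 0
      P <- exp(fate_beta0 + log(X) %*% fb + rnorm(n_obs, 0, noise_sd)) +
        fate_epsilon
      df <- data.frame(cell_line = "synthetic",
                       treatment = if (is.null(blocked)) "control" else "drugged",
                       time_point = 0, replicate = seq_len(n_obs),
                       X, apoptosis = drop(P), check.names = FALSE)
      observation_table(df, signals = proteins, fates = "apoptosis")
    })
  }

  # both tables draw from the same stream root, so blocked_node = NULL
  # makes the drugged table identical to the control
  control <- gen_table(seed, NULL)
  drugged <- gen_table(seed, blocked_node)
  truth <- list(lambda = lambda, lambda0 = lambda0, epsilon = eps,
                noise_sd = noise_sd, fate_beta = setNames(fate_beta, proteins),
                fate_beta0 = fate_beta0, fate_epsilon = fate_epsilon,
                blocked_node = blocked_node, seed = seed)
  list(control = control, drugged = drugged, truth = truth)
}

# Kahn's algorithm on the parent structure lambda[i, j] != 0 (j -> i)
topological_order <- function(lambda) {
  n <- nrow(lambda)
  remaining <- seq_len(n)
  placed <- logical(n)
  order_idx <- integer(0)
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i) {
      parents <- which(lambda[i, ] != 0)
      all(placed[parents])
    }, logical(1L))]
    if (length(ready) == 0L) {
      stop("cyclic influence structure without a root ordering")
    }
    placed[ready] <- TRUE
    order_idx <- c(order_idx, ready)
    remaining <- setdiff(remaining, ready)
  }
  order_idx
}
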