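#' Construct a generalized Boolean signaling network
#'
#' A network of binary nodes connected by weighted activating or inhibiting
#' edges, with designated input nodes that receive an extracellular signal
#' level in \[0, 1\].  Used by [simulate_boolean()] to emulate stochastic
#' signal-transduction dynamics.
#'
#' @param nodes Character vector of node names.
#' @param edges data.frame with columns `source`, `target`, `sign`
#'   (`"activate"` or `"inhibit"`) and `weight` in \[0, 1\].  Self-loops are
#'   not allowed.
#' @param inputs Named numeric vector: input level in \[0, 1\] per input
#'   node.
#' @return An object of class `boolean_network`.
#' @export
boolean_network <- function(nodes, edges, inputs) {
  edges <- as.data.frame(edges)
  stopifnot(all(c("source", "target", "sign", "weight") %in% names(edges)))
  unknown <- setdiff(c(edges$source, edges$target, names(inputs)), nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unique(unknown), collapse = ", "))
  }
  if (any(edges$source == edges$target)) stop("self-loop edges are not allowed")
  if (!all(edges$sign %in% c("activate", "inhibit"))) {
    stop("edge sign must be 'activate' or 'inhibit'")
  }
  if (any(edges$weight < 0 | edges$weight > 1)) stop("edge weights must lie in [0, 1]")
  if (any(inputs < 0 | inputs > 1)) stop("input levels must lie in [0, 1]")
  structure(list(nodes = nodes, edges = edges, inputs = inputs),
            class = "boolean_network")
}

#' The 7-node cell-death regulation network
#'
#' The small apoptosis-regulation motif used throughout the simulation
#' studies: DNA damage activates the initiator caspases (Casp8, Casp9),
#' which activate the executioner Casp3, which triggers CellDeath; EGFR
#' drives an oncogenic (pro-survival) signature that inhibits Casp3.  EGFR
#' and DNADamage are the stimulated inputs.  All edge weights and both
#' input levels default to 0.8.
#'
#' @param weight Common edge weight in \[0, 1\].
#' @param input_level Common input level for EGFR and DNADamage.
#' @return A [boolean_network()].
#' @export
cell_death_network <- function(weight = 0.8, input_level = 0.8) {
  nodes <- c("Casp8", "Casp9", "OncogenicSignature", "Casp3", "CellDeath",
             "DNADamage", "EGFR")
  edges <- data.frame(
    source = c("EGFR", "OncogenicSignature", "DNADamage", "DNADamage",
               "Casp8", "Casp9", "Casp3"),
    target = c("OncogenicSignature", "Casp3", "Casp8", "Casp9",
               "Casp3", "Casp3", "CellDeath"),
    sign = c("activate", "inhibit", "activate", "activate",
             "activate", "activate", "activate"),
    weight = weight)
  boolean_network(nodes, edges,
                  inputs = c(EGFR = input_level, DNADamage = input_level))
}

#' Stochastic ensemble simulation of a generalized Boolean network
#'
#' Simulates a population of `n_cells` cells, each carrying its own binary
#' copy of the network, and reports for every node the fraction of cells in
#' which it is active at each step -- graded, saturating trajectories in
#' \[0, 1\] of the kind produced by signal-transduction simulators.
#'
#' Per cell and step, an inactive node activates with a probability built
#' from the node's incoming drive
#' `clamp01(sum of activating w * s - sum of inhibiting w * s)`
#' (s = source states in that cell).  The process separates time scales the
#' way signaling does: interior (signaling) nodes fire at the full drive
#' probability -- phosphorylation cascades are fast -- while the slow
#' committed steps are receptor engagement (input nodes activate with
#' probability `input_rate * input level` per step) and the terminal
#' phenotype (sink nodes, e.g. cell death, activate with probability
#' `commitment_rate * drive`).  By default activation is absorbing within a
#' cell (an engaged receptor stays engaged, a dead cell stays dead), which
#' makes every trajectory non-decreasing; `absorbing = FALSE` gives a
#' memoryless variant in which non-input nodes re-sample their state each
#' step.
#'
#' @param network A [boolean_network()].
#' @param n_steps Number of synchronous update steps (default 100).
#' @param seed Integer seed; the simulation is a pure function of
#'   (network, parameters, seed).
#' @param n_cells Ensemble size (default 5000).
#' @param input_rate Per-step engagement hazard scale of input nodes
#'   (default 0.015).
#' @param commitment_rate Per-step commitment hazard scale of sink nodes
#'   (default 0.033).
#' @param absorbing Logical; activated nodes stay active within a cell.
#' @return Matrix `n_steps` x nodes: fraction of cells with the node active.
#' @export
#' @examples
#' traj <- simulate_boolean(cell_death_network(), n_steps = 50, seed = 1,
#'                          n_cells = 500)
#' all(diff(traj[, "CellDeath"]) >= 0)
simulate_boolean <- function(network, n_steps = 100L, seed = 1L,
                             n_cells = 5000L, input_rate = 0.015,
                             commitment_rate = 0.033, absorbing = TRUE) {
  stopifnot(inherits(network, "boolean_network"), n_steps >= 1L, n_cells >= 1L)
  nodes <- network$nodes
  n <- length(nodes)
  edges <- network$edges
  w_act <- matrix(0, n, n, dimnames = list(nodes, nodes))  # [target, source]
  w_inh <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(edges))) {
    if (edges$sign[e] == "activate") {
      w_act[edges$target[e], edges$source[e]] <- edges$weight[e]
    } else {
      w_inh[edges$target[e], edges$source[e]] <- edges$weight[e]
    }
  }
  is_input <- nodes %in% names(network$inputs)
  is_sink <- !(nodes %in% edges$source) & !is_input
  input_level <- setNames(rep(0, n), nodes)
  input_level[names(network$inputs)] <- network$inputs
  withr::with_seed(seed, {
    S <- matrix(0L, n_cells, n, dimnames = list(NULL, nodes))
    traj <- matrix(0, n_steps, n, dimnames = list(NULL, nodes))
    for (t in seq_len(n_steps)) {
      drive <- S %*% t(w_act) - S %*% t(w_inh)
      drive <- pmin(pmax(drive, 0), 1)
      p_on <- drive
      p_on[, is_sink] <- commitment_rate * drive[, is_sink, drop = FALSE]
      for (i in which(is_input)) p_on[, i] <- input_rate * input_level[i]
      u <- matrix(runif(n_cells * n), n_cells, n)
      if (absorbing) {
        S[(S == 0L) & (u < p_on)] <- 1L
      } else {
        S <- matrix(as.integer(u < p_on), n_cells, n, dimnames = dimnames(S))
      }
      traj[t, ] <- colMeans(S)
    }
    traj
  })
}
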