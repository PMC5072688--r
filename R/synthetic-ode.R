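#' Deterministic ODE apoptosis cascade
#'
#' A small mass-action caspase cascade used as a continuous-dynamics data
#' source for validating the fate models: a constant death stimulus
#' activates a receptor species, which activates an initiator caspase,
#' which activates an effector caspase; cumulative cell death accumulates
#' with the effector activity and saturates at 1.  A survival input damps
#' the initiator, giving the system a mild nonlinearity beyond a pure
#' chain.
#'
#' \deqn{dR/dt = k_0 S - d_1 R}
#' \deqn{dC8/dt = k_1 R / (1 + s_v V) - d_2 C8}
#' \deqn{dC3/dt = k_2 C8 - d_3 C3}
#' \deqn{dV/dt = k_v S_v - d_v V}
#' \deqn{dD/dt = k_3 C3 (1 - D)}
#'
#' Death is monotone non-decreasing and increasing the stimulus never
#' decreases the final death level.
#'
#' @param t_grid Increasing vector of time points.
#' @param stimulus Death-stimulus level S >= 0.
#' @param survival_input Survival-stimulus level \eqn{S_v \ge 0}.
#' @param rates Named list/vector overriding any of k0, k1, k2, k3, kv,
#'   d1, d2, d3, dv, sv (all positive).
#' @param basal Small positive initial value of every species (keeps the
#'   log-space models defined at early times).
#' @return Matrix: rows = time points, columns `time`, `Receptor`,
#'   `InitiatorCasp`, `EffectorCasp`, `Survival`, `Death`.
#' @export
simulate_cascade_ode <- function(t_grid, stimulus = 1, survival_input = 0.5,
                                 rates = NULL, basal = 1e-3) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  if (stimulus < 0 || survival_input < 0) stop("stimuli must be non-negative")
  p <- list(k0 = 0.8, k1 = 1.2, k2 = 1.0, k3 = 0.03, kv = 0.6,
            d1 = 0.3, d2 = 0.4, d3 = 0.35, dv = 0.25, sv = 1.5)
  if (!is.null(rates)) {
    rates <- as.list(rates)
    if (any(unlist(rates) <= 0)) stop("rates must be positive")
    p <- modifyList(p, rates)
  }
  state <- c(R = basal, C8 = basal, C3 = basal, V = basal, D = basal)
  rhs <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      list(c(
        R = k0 * stimulus - d1 * R,
        C8 = k1 * R / (1 + sv * V) - d2 * C8,
        C3 = k2 * C8 - d3 * C3,
        V = kv * survival_input - dv * V,
        D = k3 * C3 * (1 - D)
      ))
    })
  }
  sol <- deSolve::ode(y = state, times = t_grid, func = rhs, parms = p)
  out <- as.matrix(as.data.frame(sol))
  colnames(out) <- c("time", "Receptor", "InitiatorCasp", "EffectorCasp",
                     "Survival", "Death")
  out
}

#' Subsample a trajectory every k-th time point
#'
#' Mirrors the standard thinning of dense ODE output before model fitting
#' (e.g. 20,000 integration points thinned every 200th give 100
#' observations).
#'
#' @param trajectory Matrix or data.frame of time-ordered rows.
#' @param every Keep every `every`-th row, starting at row `every`.
#' @return The thinned matrix/data.frame.
#' @export
subsample_trajectory <- function(trajectory, every) {
  every <- as.integer(every)
  if (every < 1L) stop("'every' must be >= 1")
  idx <- seq(every, nrow(trajectory), by = every)
  trajectory[idx, , drop = FALSE]
}

#' ODE-cascade observation table for cross-validation studies
#'
#' Runs [simulate_cascade_ode()] over a dense grid for several stimulus
#' doses, thins the trajectories, and assembles an [observation_table()]
#' with the non-death species as signals and cumulative death as the fate.
#' A small lognormal measurement noise (seeded) makes repeated
#' cross-validation non-degenerate.
#'
#' The treatment design crosses death-stimulus doses with survival-input
#' doses, so the death readout depends on the balance between the
#' pro-death and pro-survival channels (a ratio-like, multiplicative
#' relationship) rather than on any single species alone.
#'
#' @param n_dense Dense integration points per treatment (default 2000).
#' @param every Thinning stride (default 20, giving `n_dense / every`
#'   observations per treatment).
#' @param doses Death-stimulus doses.
#' @param survival_doses Survival-input doses crossed with `doses`.
#' @param t_max End time of the integration (default 10, which keeps the
#'   death readout in its transient range across the default doses).
#' @param noise_sd Log-scale measurement noise sd (default 0.05).
#' @param seed Integer seed.
#' @return An `observation_table` with fate column `"apoptosis"`.
#' @export
generate_ode_dataset <- function(n_dense = 2000L, every = 20L,
                                 doses = c(0.5, 1, 2),
                                 survival_doses = c(0.25, 1, 4), t_max = 10,
                                 noise_sd = 0.05, seed = 1L) {
  species <- c("Receptor", "InitiatorCasp", "EffectorCasp", "Survival")
  design <- expand.grid(dose = doses, survival = survival_doses)
  rows <- lapply(seq_len(nrow(design)), function(d) {
    t_grid <- seq(t_max / n_dense, t_max, length.out = n_dense)
    traj <- simulate_cascade_ode(t_grid, stimulus = design$dose[d],
                                 survival_input = design$survival[d])
    thin <- subsample_trajectory(traj, every)
    data.frame(cell_line = "ode",
               treatment = sprintf("dose_%g_sv_%g", design$dose[d],
                                   design$survival[d]),
               time_point = thin[, "time"], replicate = 1L,
               thin[, species, drop = FALSE],
               apoptosis = thin[, "Death"], check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  withr::with_seed(seed, {
    for (col in c(species, "apoptosis")) {
      df[[col]] <- df[[col]] * exp(rnorm(nrow(df), 0, noise_sd))
    }
  })
  observation_table(df, signals = species, fates = "apoptosis")
}
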