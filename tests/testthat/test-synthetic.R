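test_that("boolean networks validate their structure", {
  expect_error(boolean_network("a", data.frame(source = "a", target = "a",
                                               sign = "activate", weight = 0.5),
                               c(a = 0.5)), "self-loop")
  expect_error(boolean_network(c("a", "b"),
                               data.frame(source = "a", target = "b",
                                          sign = "activate", weight = 2),
                               c(a = 0.5)), "weights")
  net <- cell_death_network()
  expect_setequal(net$nodes, c("Casp8", "Casp9", "OncogenicSignature",
                               "Casp3", "CellDeath", "DNADamage", "EGFR"))
  expect_true(all(net$edges$weight == 0.8))
})

test_that("ensemble simulation is seeded, bounded and silent without input", {
  net <- cell_death_network()
  t1 <- simulate_boolean(net, n_steps = 40, seed = 8, n_cells = 400)
  t2 <- simulate_boolean(net, n_steps = 40, seed = 8, n_cells = 400)
  expect_identical(t1, t2)
  expect_true(all(t1 >= 0 & t1 <= 1))
  # absorbing dynamics: every trajectory is non-decreasing
  expect_true(all(apply(t1, 2, function(col) all(diff(col) >= -1e-12))))
  # zero input level: nothing ever activates
  silent <- simulate_boolean(cell_death_network(input_level = 0),
                             n_steps = 30, seed = 1, n_cells = 200)
  expect_true(all(silent == 0))
})

test_that("power-law dataset generation is reproducible and honors its parameters", {
  d1 <- generate_powerlaw_dataset(30, 3, seed = 77)
  d2 <- generate_powerlaw_dataset(30, 3, seed = 77)
  expect_identical(as.data.frame(d1$table), as.data.frame(d2$table))
  expect_true(all(signal_matrix(d1$table) > 0))
  # zero exponents: the fate is the constant exp(beta0) + epsilon
  d0 <- generate_powerlaw_dataset(20, 3, beta = c(0, 0, 0), beta0 = -2,
                                  epsilon = 0.01, seed = 78)
  expect_equal(d0$table$apoptosis, rep(exp(-2) + 0.01, 20))
  expect_error(generate_powerlaw_dataset(4, 3), "n_obs")
})

test_that("influence datasets propagate a blocked node only where intended", {
  lam <- hub_lambda(5)
  # no intervention: identical tables from the same seed
  d <- generate_influence_dataset(40, lam, blocked_node = NULL, seed = 9)
  expect_identical(as.data.frame(d$control), as.data.frame(d$drugged))
  # blocking decouples the hub from its parent in the drugged table only
  db <- generate_influence_dataset(400, lam, blocked_node = 2, seed = 10)
  ctl_cor <- cor(log(db$control$prot01), log(db$control$prot02))
  drg_cor <- cor(log(db$drugged$prot01), log(db$drugged$prot02))
  expect_gt(ctl_cor, 0.9)
  expect_lt(abs(drg_cor), 0.3)
  # noise-free tables reproduce lambda where parents are independent roots
  # (v-structure: prot03 = prot01^0.7 * prot02^0.5)
  lam_v <- matrix(0, 3, 3,
                  dimnames = rep(list(sprintf("prot%02d", 1:3)), 2))
  lam_v[3, 1] <- 0.7; lam_v[3, 2] <- 0.5
  d0 <- generate_influence_dataset(60, lam_v, seed = 11, noise_sd = 0,
                                   epsilon = 0)
  M <- fit_influence_matrix(filter_valid(d0$control), epsilon = 0)
  expect_lt(max(abs(M$lambda[lam_v != 0] - lam_v[lam_v != 0])), 1e-3)
  expect_error(generate_influence_dataset(10, matrix(1, 2, 2)), "diagonal")
})

test_that("the ODE cascade integrates to monotone, dose-responsive death", {
  grid <- seq(0.05, 10, length.out = 200)
  traj <- simulate_cascade_ode(grid, stimulus = 1)
  expect_true(all(diff(traj[, "Death"]) >= -1e-12))
  # without stimulus, death stays at its basal level
  none <- simulate_cascade_ode(grid, stimulus = 0)
  expect_lt(max(none[, "Death"]), 0.01)
  # doubling the stimulus never decreases the final death level
  hi <- simulate_cascade_ode(grid, stimulus = 2)
  expect_gte(hi[200, "Death"], traj[200, "Death"])
  expect_error(simulate_cascade_ode(c(1, 1, 2)), "increasing")
})

test_that("trajectory thinning mirrors the every-kth selection", {
  m <- matrix(seq_len(20000 * 2), 20000, 2)
  thin <- subsample_trajectory(m, 200)
  expect_equal(nrow(thin), 100L)
  expect_equal(thin[1, 1], 200)
  tab <- generate_ode_dataset(n_dense = 400, every = 20, seed = 2)
  expect_s3_class(tab, "observation_table")
  expect_equal(nrow(tab), 20 * 9)      # 20 per treatment, 3 x 3 dose design
})

test_that("the multi-variable power-law fit beats the linear fit on simulator output", {
  for (s in 1:3) {
    traj <- simulate_boolean(cell_death_network(), 100, seed = s)
    keep <- apply(traj, 1, function(r) all(r > 0))
    df <- as.data.frame(traj[keep, , drop = FALSE])
    tab <- observation_table(df,
                             signals = setdiff(colnames(traj), "CellDeath"),
                             fates = "CellDeath")
    nl <- fit_fate_model(tab, "CellDeath", "powerlaw", epsilon = 1e-6)
    li <- fit_fate_model(tab, "CellDeath", "linear")
    y <- df$CellDeath
    expect_lt(rmse(y, predict_fate(nl, tab)), rmse(y, predict_fate(li, tab)))
    expect_gt(cor(y, predict_fate(nl, tab)), cor(y, predict_fate(li, tab)))
  }
})
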