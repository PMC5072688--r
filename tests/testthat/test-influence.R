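test_that("influence regressions recover log-space relations and keep a zero diagonal", {
  # x2 = x1^2 exactly: lambda_21 = 2
  withr::with_seed(51, x1 <- rlnorm(40))
  df <- data.frame(p1 = x1, p2 = x1^2, fate = 0.5)
  tab <- observation_table(df, signals = c("p1", "p2"), fates = "fate")
  M <- fit_influence_matrix(tab, epsilon = 0)
  expect_equal(unname(M$lambda["p2", "p1"]), 2, tolerance = 1e-6)
  expect_equal(unname(diag(M$lambda)), c(0, 0))

  # sparse ground truth: large entries carry the right sign
  lam <- hub_lambda(5)
  d <- generate_influence_dataset(200, lam, seed = 61, noise_sd = 0.05,
                                  epsilon = 1e-4)
  Mf <- fit_influence_matrix(filter_valid(d$control), epsilon = 1e-5)
  expect_equal(unname(diag(Mf$lambda)), rep(0, 5))
  big <- which(lam != 0, arr.ind = TRUE)
  expect_true(all(Mf$lambda[big] > 0))
  expect_true(all(Mf$lambda[big] > 0.3))

  # errors: constant column, oversized epsilon
  dfc <- data.frame(p1 = x1, p2 = 2, fate = 0.5)
  tc <- observation_table(dfc, signals = c("p1", "p2"), fates = "fate")
  expect_error(fit_influence_matrix(tc), "constant")
  expect_error(fit_influence_matrix(tab, epsilon = 100), "epsilon")
})

test_that("influence matrices serialize to labeled text and reload exactly", {
  lam <- cascade_lambda(4)
  d <- generate_influence_dataset(60, lam, seed = 3)
  M <- fit_influence_matrix(filter_valid(d$control), epsilon = 1e-5)
  path <- tempfile(fileext = ".tsv")
  write_influence_matrix(M, path)
  M2 <- read_influence_matrix(path)
  expect_equal(M2$lambda, M$lambda)
  expect_equal(M2$lambda0, M$lambda0)
})

test_that("virtual knock-down applies the rewiring rule literally", {
  pn <- c("p1", "p2", "p3")
  lam <- matrix(0, 3, 3, dimnames = list(pn, pn))
  lam["p1", "p2"] <- 0.5               # protein 2 influences protein 1
  M <- structure(list(lambda = lam, lambda0 = setNames(rep(0, 3), pn),
                      epsilon = setNames(rep(0, 3), pn), protein_names = pn),
                 class = "influence_matrix")
  fm <- structure(list(kind = "powerlaw", protein_names = pn, beta0 = -1,
                       beta = setNames(c(1, 1, 1), pn), epsilon = 0.01,
                       fate = "p", n_components = 1L, intercept = TRUE),
                  class = "fate_model")
  # knock protein 3: beta' = (sum_i lambda_i1 beta_i, sum_i lambda_i2 beta_i, 0)
  kd <- virtual_knockdown(M, fm, 3)
  expect_equal(unname(kd$beta), c(0, 0.5, 0))
  expect_equal(kd$beta0, fm$beta0)
  expect_equal(kd$epsilon, fm$epsilon)
  # inputs never mutated
  expect_equal(unname(fm$beta), c(1, 1, 1))
  expect_equal(unname(M$lambda["p1", "p2"]), 0.5)
  # knocking the same protein again is a no-op
  expect_equal(virtual_knockdown(M, kd, 3)$beta, kd$beta)
  # zero influence matrix: only the intercept and offset survive
  M0 <- M; M0$lambda[] <- 0
  expect_equal(unname(virtual_knockdown(M0, fm, 2)$beta), c(0, 0, 0))
  # additive variant keeps the direct effects
  ka <- virtual_knockdown(M, fm, 3, rule = "additive")
  expect_equal(unname(ka$beta), c(1, 1.5, 0))
  expect_error(virtual_knockdown(M, fm, 9), "out of range")
})

test_that("knock-down rankings are deterministic, complete and mode-reversed", {
  lam <- hub_lambda(5)
  d <- generate_influence_dataset(150, lam, blocked_node = 2, seed = 71)
  ctl <- filter_valid(d$control)
  drg <- filter_valid(d$drugged)
  fm <- fit_fate_model(ctl, "apoptosis", "powerlaw", epsilon = 5e-4)
  M <- fit_influence_matrix(ctl, epsilon = 5e-4)
  b <- rank_knockdowns(fm, M, drg, "apoptosis", "blocked")
  e <- rank_knockdowns(fm, M, drg, "apoptosis", "enhanced")
  expect_setequal(b$entries$protein, fm$protein_names)
  expect_equal(b$entries$protein, rev(e$entries$protein))
  expect_false(is.unsorted(b$entries$rmse))
  b2 <- rank_knockdowns(fm, M, drg, "apoptosis", "blocked")
  expect_identical(b$entries, b2$entries)
})

test_that("the truly blocked hub is recovered, and control data shows less spread", {
  lam <- hub_lambda(5)
  ranks <- integer(0)
  spread_ratio <- numeric(0)
  for (s in 1:10) {
    d <- generate_influence_dataset(150, lam, blocked_node = 2, seed = s)
    ctl <- filter_valid(d$control)
    drg <- filter_valid(d$drugged)
    fm <- fit_fate_model(ctl, "apoptosis", "powerlaw", epsilon = 5e-4)
    M <- fit_influence_matrix(ctl, epsilon = 5e-4)
    rb <- rank_knockdowns(fm, M, drg, "apoptosis", "blocked", rule = "additive")
    ranks <- c(ranks, match("prot02", rb$entries$protein))
    rc <- rank_knockdowns(fm, M, ctl, "apoptosis", "blocked", rule = "additive")
    spread_ratio <- c(spread_ratio,
                      diff(range(rc$entries$rmse)) / diff(range(rb$entries$rmse)))
  }
  expect_true(all(ranks == 1L))
  # without a real intervention the knock-down errors differ much less
  expect_lt(median(spread_ratio), 1)
})
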