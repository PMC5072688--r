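test_that("delimited tables parse with roles, preserving rows and flagging bad cells", {
  df <- data.frame(cell_line = c("A", "A", "B"), x1 = c(1, 2, 3),
                   x2 = c(4, 5, 6), p = c(0.1, 0.2, 0.3))
  schema <- c(cell_line = "meta", x1 = "signal", x2 = "signal", p = "fate")
  for (sep in c(",", "\t")) {
    tab <- load_observation_table(write_fixture_csv(df, sep), schema)
    expect_s3_class(tab, "observation_table")
    expect_equal(nrow(tab), 3L)
    expect_equal(signal_names(tab), c("x1", "x2"))
    expect_equal(tab$x1, c(1, 2, 3))
  }

  # unparseable / NA cells become missing values, not errors
  df_bad <- df
  df_bad$x1 <- c("1.5", "NA", "oops")
  tab <- suppressWarnings(
    load_observation_table(write_fixture_csv(df_bad), schema))
  expect_equal(nrow(tab), 3L)
  expect_true(is.na(tab$x1[2]) && is.na(tab$x1[3]))

  expect_error(load_observation_table(tempfile(), schema), "not found")
  expect_error(
    load_observation_table(write_fixture_csv(df),
                           c(absent = "signal", p = "fate")),
    "absent")
})

test_that("filter_valid drops non-positive and missing rows, idempotently and in order", {
  df <- data.frame(x = c(1, 0, 2, 3, -1), y = c(2, 2, 2, 2, 2),
                   p = c(0.5, 0.5, NA, 0.2, 0.4))
  tab <- observation_table(df, signals = c("x", "y"), fates = "p")
  out <- filter_valid(tab)
  expect_equal(nrow(out), 2L)
  expect_equal(out$x, c(1, 3))           # original order preserved
  expect_identical(as.data.frame(filter_valid(out)), as.data.frame(out))
  expect_equal(nrow(tab), 5L)            # input unmodified

  # idempotence on a randomly corrupted table
  withr::with_seed(7, {
    n <- 50L
    df2 <- data.frame(a = rlnorm(n), b = rlnorm(n), p = runif(n))
    df2$a[sample(n, 8)] <- NA
    df2$b[sample(n, 8)] <- -df2$b[sample(n, 8)]
    df2$p[sample(n, 5)] <- 0
  })
  t2 <- observation_table(df2, signals = c("a", "b"), fates = "p")
  once <- filter_valid(t2)
  expect_identical(as.data.frame(filter_valid(once)), as.data.frame(once))
  vals <- cbind(signal_matrix(once), signal_matrix(once, "fates"))
  expect_true(all(is.finite(vals) & vals > 0))
})

test_that("fate counts convert to proportions that sum to one", {
  expect_equal(fate_probability(c(apoptosis = 20, other = 80)),
               c(apoptosis = 0.2, other = 0.8))
  expect_equal(fate_probability(c(a = 1, b = 1, c = 2)),
               c(a = 0.25, b = 0.25, c = 0.5))
  withr::with_seed(11, {
    for (i in 1:10) {
      counts <- runif(sample(2:6, 1), 0, 100)
      expect_equal(sum(fate_probability(counts)), 1)
    }
  })
  expect_error(fate_probability(c(0, 0)), "positive")
  expect_error(fate_probability(c(-1, 2)), "non-negative")
})

test_that("DREAM8 normalization reversal: factor, log2, SD standardization", {
  # log2 of {2,4,8} is {1,2,3}; sample SD is exactly 1
  expect_equal(reverse_dream8_normalization(c(1, 2, 4), 2), c(1, 2, 3))
  # identity factor, series whose log2 SD is 1
  v <- 2^c(0, 1, 2)
  expect_equal(reverse_dream8_normalization(v, 1), c(0, 1, 2))
  expect_error(reverse_dream8_normalization(c(2, 2, 2), 1), "zero variance")
  expect_error(reverse_dream8_normalization(c(-1, 2, 4), 1), "non-positive")
})

test_that("sigmoid normalization maps into (0,1), keeps ranks, handles degenerate columns", {
  m <- cbind(a = c(0, 1), b = c(5, 5), c = c(1, 2))
  out <- sigmoid_normalize(m)
  # hand value: z = (0 - 0.5) / sd(c(0,1)) = -0.7071; logistic gives 0.3302
  expect_equal(unname(out[, "a"]), c(0.330239, 0.669761), tolerance = 1e-5)
  expect_equal(unname(out[, "b"]), c(0.5, 0.5))
  withr::with_seed(3, {
    mm <- matrix(rnorm(60), 20, 3)
    oo <- sigmoid_normalize(mm)
    expect_true(all(oo > 0 & oo < 1))
    for (j in 1:3) expect_equal(order(oo[, j]), order(mm[, j]))
    # column mean maps to 0.5
    expect_equal(sigmoid_normalize(cbind(c(mm[, 1], mean(mm[, 1]))))[21],
                 0.5, tolerance = 1e-12)
  })
})

test_that("feature construction yields the advertised family sizes and values", {
  # 19 proteins x (baseline + 13 measured): 247 raw + 247 deriv + 57 summary
  tc <- timecourse_table(n_proteins = 19L, n_measured = 13L)
  feats <- build_ht29_features(tc)
  expect_equal(ncol(feats) - 1L, 19 * 13 + 19 * 13 + 3 * 19)  # 551 + treatment col
  expect_equal(ncol(build_ht29_features(tc, c("raw", "deriv", "max", "mean",
                                              "ss", "auc"))) - 1L, 570)

  # 1 protein, 3-point grid, derivative family only: 2 columns
  tc2 <- timecourse_table(n_proteins = 1L, n_measured = 2L)
  d <- build_ht29_features(tc2, families = "deriv")
  expect_equal(setdiff(names(d), "treatment"), c("P01@d1", "P01@d2"))

  # constant signal: derivatives 0, max = mean = steady state
  df <- data.frame(treatment = "t1", time_point = c(0, 1, 2, 3, 4), P = 3)
  tc3 <- observation_table(cbind(df, fate = 0.5), signals = "P", fates = "fate")
  f3 <- build_ht29_features(tc3)
  expect_true(all(f3[, grepl("@d", names(f3))] == 0))
  expect_equal(f3[["P@max"]], 3)
  expect_equal(f3[["P@mean"]], 3)
  expect_equal(f3[["P@ss"]], 3)

  # derivative values are difference quotients over adjacent time points
  df4 <- data.frame(treatment = "t1", time_point = c(0, 1, 3), P = c(1, 2, 6))
  tc4 <- observation_table(cbind(df4, fate = 0.5), signals = "P", fates = "fate")
  f4 <- build_ht29_features(tc4, families = "deriv")
  expect_equal(f4[["P@d1"]], 1)        # (2-1)/(1-0)
  expect_equal(f4[["P@d2"]], 2)        # (6-2)/(3-1)

  # a treatment missing a grid point is an error
  tc5 <- timecourse_table(n_proteins = 2L, n_measured = 3L,
                          treatments = c("t1", "t2"))
  broken <- as.data.frame(tc5)[-2L, ]
  tc5b <- observation_table(broken, signals = signal_names(tc5), fates = "fate")
  expect_error(build_ht29_features(tc5b), "missing time points")
})
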