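# Small fixtures shared across the suite; everything is generated in code.

# a tiny hand-built observation table
tiny_table <- function() {
  df <- data.frame(
    cell_line = c("A", "A", "B"),
    treatment = "t1",
    time_point = c(0, 1, 1),
    replicate = 1:3,
    EGFR = c(1.2, 2.5, 0.7),
    AKT = c(0.4, 1.1, 2.2),
    apoptosis = c(0.10, 0.30, 0.22))
  observation_table(df, signals = c("EGFR", "AKT"), fates = "apoptosis")
}

# write a delimited fixture file and return its path
write_fixture_csv <- function(df, sep = ",") {
  path <- tempfile(fileext = ".csv")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# time-course table: p proteins, a baseline row plus T measured points
timecourse_table <- function(n_proteins = 2L, n_measured = 3L,
                             treatments = "t1", seed = 42L) {
  grid <- c(0, seq_len(n_measured))
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  withr::with_seed(seed, {
    rows <- expand.grid(treatment = treatments, time_point = grid,
                        stringsAsFactors = FALSE)
    for (p in proteins) rows[[p]] <- runif(nrow(rows), 0.5, 2)
    rows$fate <- runif(nrow(rows), 0.1, 0.9)
  })
  observation_table(rows, signals = proteins, fates = "fate")
}

# converted supplementary archives would live here; they cannot be shipped
# with the package sources, so analyses that need them stop with guidance
supplementary_table <- function(name) {
  dir <- system.file("extdata", "supplementary", package = "powerfate")
  path <- if (nzchar(dir)) file.path(dir, name) else name
  if (!nzchar(dir) || !file.exists(path)) {
    stop("supplementary dataset '", name, "' is not available; convert the ",
         "published archive to delimited text under ",
         "inst/extdata/supplementary/ as described in the README")
  }
  path
}
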