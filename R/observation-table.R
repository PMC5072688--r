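#' Observation tables
#'
#' The universal container of the package: one row per observation, with
#' metadata columns (cell line, treatment, time point, replicate), positive
#' protein-activity columns ("signals") and cell-fate columns ("fates",
#' probabilities or raw cell counts).  An `observation_table` is a plain
#' `data.frame` carrying the column-role assignment as attributes, so all the
#' usual data-frame idioms keep working.
#'
#' @param data A data.frame, one observation per row.
#' @param signals Character vector of signal (protein-activity) column names.
#' @param fates Character vector of fate column names.
#' @param meta Character vector of metadata column names.  Defaults to every
#'   column not named as a signal or a fate.
#'
#' @return An object of class `observation_table` (inheriting from
#'   `data.frame`).
#' @export
#' @examples
#' df <- data.frame(cell_line = "A", x1 = c(1, 2), x2 = c(3, 4),
#'                  apoptosis = c(0.1, 0.2))
#' tab <- observation_table(df, signals = c("x1", "x2"), fates = "apoptosis")
#' signal_names(tab)
observation_table <- function(data, signals, fates,
                              meta = setdiff(names(data), c(signals, fates))) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(c(signals, fates, meta), names(data))
  if (length(missing_cols) > 0L) {
    stop("columns not present in data: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(signals)) stop("duplicate protein names in 'signals'")
  for (col in c(signals, fates)) {
    if (!is.numeric(data[[col]])) {
      data[[col]] <- suppressWarnings(as.numeric(as.character(data[[col]])))
    }
  }
  structure(data,
            signals = signals,
            fates = fates,
            meta = meta,
            class = c("observation_table", "data.frame"))
}

#' @rdname observation_table
#' @param x An `observation_table`.
#' @export
signal_names <- function(x) attr(x, "signals")

#' @rdname observation_table
#' @export
fate_names <- function(x) attr(x, "fates")

#' @rdname observation_table
#' @export
meta_names <- function(x) attr(x, "meta")

#' @rdname observation_table
#' @export
is_observation_table <- function(x) inherits(x, "observation_table")

#' Extract the signal or fate block as a numeric matrix
#'
#' @param x An `observation_table`.
#' @param which `"signals"` or `"fates"`.
#' @return Numeric matrix, observations in rows.
#' @export
signal_matrix <- function(x, which = c("signals", "fates")) {
  which <- match.arg(which)
  cols <- attr(x, which)
  as.matrix(as.data.frame(x)[, cols, drop = FALSE])
}

# Rebuild the class/attributes after a row subset (base [.data.frame drops them)
restore_obs_table <- function(data, template) {
  observation_table(as.data.frame(data),
                    signals = signal_names(template),
                    fates = fate_names(template),
                    meta = intersect(meta_names(template), names(data)))
}

#' @export
`[.observation_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) &&
      all(c(signal_names(x), fate_names(x)) %in% names(out))) {
    out <- restore_obs_table(out, x)
  }
  out
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf("<observation_table> %d observations, %d proteins, %d fates\n",
              nrow(x), length(signal_names(x)), length(fate_names(x))))
  cat("proteins:", paste(head(signal_names(x), 8L), collapse = ", "),
      if (length(signal_names(x)) > 8L) "..." else "", "\n")
  NextMethod()
  invisible(x)
}

#' Remove invalid observations
#'
#' Drops every observation in which any signal or fate value is missing,
#' zero or negative, keeping the remaining rows in their original order.
#' This is the standard preprocessing applied before fitting either fate
#' model: the power-law model works on logarithms, so only strictly positive
#' measurements are usable.  The operation is idempotent.
#'
#' @param table An `observation_table`.
#' @return The filtered `observation_table` (possibly with zero rows).
#' @export
#' @examples
#' df <- data.frame(x = c(1, 0, 2), p = c(0.5, 0.5, NA))
#' tab <- observation_table(df, signals = "x", fates = "p")
#' nrow(filter_valid(tab))  # 1
filter_valid <- function(table) {
  stopifnot(is_observation_table(table))
  vals <- cbind(signal_matrix(table, "signals"), signal_matrix(table, "fates"))
  if (nrow(vals) == 0L) return(table)
  keep <- apply(vals, 1L, function(r) all(is.finite(r) & r > 0))
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  restore_obs_table(out, table)
}
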