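#' Read an observation table from delimited text
#'
#' Reads a comma- or tab-delimited file (delimiter auto-detected from the
#' header line) into an [observation_table()].  A schema maps each column to
#' exactly one role: `meta`, `signal` or `fate`.  Cells that fail numeric
#' parsing in signal or fate columns become `NA` rather than errors; they are
#' removed later by [filter_valid()], which keeps the filtering step
#' auditable.
#'
#' @param path Path to the delimited text file (header row required).
#' @param schema Either a named character vector / list mapping column names
#'   to roles (`"meta"`, `"signal"`, `"fate"`), or the path to a YAML file
#'   with top-level keys `meta`, `signal`, `fate`, each listing column names.
#' @return An `observation_table` preserving the file's row order.
#' @export
load_observation_table <- function(path, schema) {
  if (!file.exists(path)) stop("file not found: ", path)
  schema <- normalize_schema(schema)
  raw <- data.table::fread(path, sep = "auto", header = TRUE,
                           data.table = FALSE, na.strings = c("NA", "NaN", ""))
  absent <- setdiff(names(schema), names(raw))
  if (length(absent) > 0L) {
    stop("schema references absent columns: ", paste(absent, collapse = ", "))
  }
  signals <- names(schema)[schema == "signal"]
  fates <- names(schema)[schema == "fate"]
  meta <- names(schema)[schema == "meta"]
  if (length(signals) == 0L) stop("schema assigns no signal columns")
  observation_table(raw[, names(schema), drop = FALSE],
                    signals = signals, fates = fates, meta = meta)
}

normalize_schema <- function(schema) {
  if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
    spec <- yaml::read_yaml(schema)
    schema <- c(
      setNames(rep("meta", length(spec$meta)), spec$meta),
      setNames(rep("signal", length(spec$signal)), spec$signal),
      setNames(rep("fate", length(spec$fate)), spec$fate)
    )
  }
  schema <- unlist(schema)
  bad <- setdiff(unique(schema), c("meta", "signal", "fate"))
  if (length(bad) > 0L) stop("unknown schema roles: ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(schema))) {
    stop("schema assigns a column to more than one role")
  }
  schema
}

#' Write an observation table or data frame as delimited text
#'
#' @param x Data frame (or `observation_table`).
#' @param path Output path.
#' @param sep Field delimiter; default tab.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(x, path, sep = "\t") {
  utils::write.table(as.data.frame(x), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
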