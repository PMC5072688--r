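#' Time-staggered input-output index pairing
#'
#' Signaling responses precede phenotypic responses by hours, so the fate
#' ("output") measured at time index t is paired with the signals ("input")
#' measured `degree` index positions earlier.  Output index 0 (the
#' untreated baseline) is always paired with input index 0; every other
#' output index o is paired with input index o - degree when that input
#' index exists, and dropped otherwise.
#'
#' With inputs at indices 0..7 and outputs at \{0, 6, 7, 8, 9\} (the
#' 10-point grid 0, 0.1, 0.25, 0.5, 1, 2, 4, 6, 8, 12 h), degree 2 yields
#' the pairs (0,0), (4,6), (5,7), (6,8), (7,9).
#'
#' @param input_indices Integer vector of available input (signal) time
#'   indices.
#' @param output_indices Integer vector of available output (fate) time
#'   indices.
#' @param degree Integer time-staggered degree (lag in index units).
#' @return data.frame with columns `input` and `output`, one row per pair,
#'   ordered by output index.
#' @export
#' @examples
#' stagger_pairs(0:7, c(0, 6:9), degree = 3)
stagger_pairs <- function(input_indices, output_indices, degree) {
  degree <- as.integer(degree)
  pairs <- lapply(sort(unique(output_indices)), function(o) {
    i <- if (o == 0L) 0L else o - degree
    if (i %in% input_indices) data.frame(input = i, output = o) else NULL
  })
  out <- do.call(rbind, pairs)
  if (is.null(out) || nrow(out) == 0L) {
    stop("degree ", degree, " produces no input-output pairs")
  }
  rownames(out) <- NULL
  out
}

#' Build a time-staggered observation table
#'
#' Joins a signal table and a fate table measured on a common time-index
#' grid according to [stagger_pairs()]: each fate observation at output
#' index o is matched with the signal observation of the same group
#' (cell line / treatment / replicate) at input index o - degree (index 0
#' maps to 0).  Unmatched observations are dropped.
#'
#' @param signals `observation_table` with a `time_index` metadata column
#'   (signal columns only are used).
#' @param fates `observation_table` with a `time_index` metadata column
#'   (fate columns only are used).
#' @param degree Integer time-staggered degree.
#' @param group_by Metadata columns identifying an experimental unit;
#'   default: the metadata columns shared by both tables other than
#'   `time_index` and `time_point`.
#' @return An `observation_table` whose rows combine the lagged signals
#'   with the fates; metadata records both `time_index_input` and
#'   `time_index_output`.
#' @export
time_staggered_pairs <- function(signals, fates, degree, group_by = NULL) {
  stopifnot(is_observation_table(signals), is_observation_table(fates))
  sdf <- as.data.frame(signals)
  fdf <- as.data.frame(fates)
  if (!"time_index" %in% names(sdf) || !"time_index" %in% names(fdf)) {
    stop("both tables need a 'time_index' metadata column")
  }
  if (is.null(group_by)) {
    group_by <- setdiff(intersect(meta_names(signals), meta_names(fates)),
                        c("time_index", "time_point"))
  }
  pairs <- stagger_pairs(unique(sdf$time_index), unique(fdf$time_index), degree)
  sig_cols <- signal_names(signals)
  fate_cols <- fate_names(fates)
  merged <- lapply(seq_len(nrow(pairs)), function(r) {
    s_sub <- sdf[sdf$time_index == pairs$input[r],
                 c(group_by, sig_cols), drop = FALSE]
    f_sub <- fdf[fdf$time_index == pairs$output[r],
                 c(group_by, fate_cols), drop = FALSE]
    if (nrow(s_sub) == 0L || nrow(f_sub) == 0L) return(NULL)
    m <- merge(s_sub, f_sub, by = group_by)
    if (nrow(m) == 0L) return(NULL)
    m$time_index_input <- pairs$input[r]
    m$time_index_output <- pairs$output[r]
    m
  })
  merged <- do.call(rbind, merged)
  if (is.null(merged) || nrow(merged) == 0L) {
    stop("no overlapping experimental units for degree ", degree)
  }
  observation_table(merged, signals = sig_cols, fates = fate_cols)
}
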