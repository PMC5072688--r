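#' Convert fate cell counts to probabilities
#'
#' Flow-cytometry style fate measurements arrive as counts of cells in each
#' fate category; the models work on the proportion of cells in the fate of
#' interest (e.g. the apoptotic fraction).  Categories are assumed
#' exhaustive, so the returned proportions sum to one.
#'
#' @param counts Named non-negative numeric vector of cell counts per fate
#'   category, positive total.
#' @return Named numeric vector of proportions summing to 1.
#' @export
#' @examples
#' fate_probability(c(apoptosis = 20, other = 80))
fate_probability <- function(counts) {
  counts <- unlist(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  total <- sum(counts)
  if (total <= 0) stop("total cell count must be positive")
  counts / total
}

#' Reverse the DREAM8 normalization of a protein series
#'
#' The DREAM8 reverse-phase protein-array release ships median-centered,
#' correction-factor normalized values.  To recover comparable activity
#' levels the pipeline is: (i) multiply each normalized linear value by the
#' per-protein correction factor, giving the median-centered linear ratio;
#' (ii) take log2 of that ratio; (iii) divide the log2 series by its
#' standard deviation.  The sample standard deviation (n-1 denominator) is
#' used throughout the package.
#'
#' @param values Positive numeric vector, one protein's normalized series.
#' @param correction_factor Positive scalar correction factor for the protein.
#' @return Numeric vector: standardized log2 series.
#' @export
#' @examples
#' reverse_dream8_normalization(c(1, 2, 4), 2)
reverse_dream8_normalization <- function(values, correction_factor) {
  if (any(!is.finite(values))) stop("values must be finite")
  if (!is.finite(correction_factor) || correction_factor <= 0) {
    stop("correction factor must be a positive scalar")
  }
  ratio <- values * correction_factor
  if (any(ratio <= 0)) stop("non-positive value before log2")
  l2 <- log2(ratio)
  s <- sd(l2)
  if (!is.finite(s) || s == 0) stop("series has zero variance; cannot standardize")
  l2 / s
}

#' Sigmoid normalization of a numeric matrix into (0, 1)
#'
#' Each column is z-scored (sample standard deviation) and passed through the
#' logistic function 1 / (1 + exp(-z)).  The transform is monotone within
#' each column, so rank order is preserved.  A zero-variance column maps to
#' 0.5 everywhere.
#'
#' @param matrix Numeric matrix or data frame.
#' @return Numeric matrix with all entries strictly inside (0, 1).
#' @export
sigmoid_normalize <- function(matrix) {
  m <- as.matrix(matrix)
  out <- apply(m, 2L, function(col) {
    s <- sd(col)
    if (!is.finite(s) || s == 0) return(rep(0.5, length(col)))
    plogis((col - mean(col)) / s)
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m), dimnames = dimnames(m))
  dimnames(out) <- dimnames(m)
  out
}

#' Build the high-dimensional HT-29 style feature table
#'
#' For time-course data (one measured value per protein, treatment and time
#' point) this constructs the derived predictor space used for the HT-29
#' analysis: the raw signal at every measured time point, the
#' finite-difference derivative over each pair of adjacent time points, and
#' per-protein summary features (maximum, mean, steady state).  The optional
#' `"auc"` family (trapezoidal area under the curve per protein) is off by
#' default.
#'
#' The time grid is taken to start with a pre-stimulus baseline point (time
#' 0) followed by T measured time points, as is usual for stimulus
#' time-course designs.  The raw and summary families are computed over the
#' T post-baseline points, while derivatives span every adjacent pair of the
#' full grid, so both the raw and the derivative family contribute p * T
#' columns (19 proteins x 13 measured time points gives 247 + 247, plus 57
#' summary columns: 551 in total, or 570 with `"auc"` enabled).  Set
#' `first_point_is_baseline = FALSE` for grids without a baseline row.
#'
#' Family sizes for p proteins and a grid of T measured points (plus
#' baseline):
#' \describe{
#'   \item{raw}{p * T columns, named `<protein>@t<k>`}
#'   \item{deriv}{p * T columns, named `<protein>@d<k>`, value
#'     (x(t_k) - x(t_{k-1})) / (t_k - t_{k-1})}
#'   \item{max, mean, ss}{p columns each, named `<protein>@max` etc.; the
#'     steady state is the mean of the final three time points}
#'   \item{auc}{p columns, named `<protein>@auc`}
#' }
#'
#' @param timecourse An `observation_table` with a `time_point` metadata
#'   column; one row per (group, time point).  Rows are grouped by the
#'   metadata in `group_by`.
#' @param families Character vector of enabled feature families, a subset of
#'   `c("raw", "deriv", "max", "mean", "ss", "auc")`.
#' @param group_by Metadata columns identifying one feature-table row
#'   (default `"treatment"`, plus `"replicate"` when present).
#' @param first_point_is_baseline Logical; when `TRUE` (default) the first
#'   grid point is the pre-stimulus baseline, excluded from the raw and
#'   summary families but anchoring the first derivative.
#' @return A data.frame: one row per group, feature columns plus the
#'   grouping metadata.
#' @export
build_ht29_features <- function(timecourse,
                                families = c("raw", "deriv", "max", "mean", "ss"),
                                group_by = NULL,
                                first_point_is_baseline = TRUE) {
  stopifnot(is_observation_table(timecourse))
  families <- match.arg(families,
                        c("raw", "deriv", "max", "mean", "ss", "auc"),
                        several.ok = TRUE)
  df <- as.data.frame(timecourse)
  if (!"time_point" %in% names(df)) stop("'time_point' metadata column required")
  if (is.null(group_by)) {
    group_by <- intersect(c("treatment", "replicate", "cell_line"), names(df))
    group_by <- group_by[vapply(group_by, function(g)
      length(unique(df[[g]])) > 1L || g == "treatment", logical(1L))]
    if (length(group_by) == 0L) group_by <- "treatment"
  }
  grid <- sort(unique(df$time_point))
  proteins <- signal_names(timecourse)
  key <- interaction(df[, group_by, drop = FALSE], drop = TRUE)
  rows <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    sub <- df[idx, , drop = FALSE]
    sub <- sub[order(sub$time_point), , drop = FALSE]
    if (!identical(sub$time_point, grid)) {
      stop("treatment group '", as.character(key[idx[1L]]),
           "' is missing time points from the common grid")
    }
    feats <- list()
    for (pr in proteins) {
      x <- sub[[pr]]
      tt <- sub$time_point
      # measured (post-baseline) series used for raw and summary families
      xm <- if (first_point_is_baseline && length(x) > 1L) x[-1L] else x
      tm <- if (first_point_is_baseline && length(x) > 1L) tt[-1L] else tt
      if ("raw" %in% families) {
        feats[paste0(pr, "@t", seq_along(xm))] <- as.list(xm)
      }
      if ("deriv" %in% families) {
        d <- diff(x) / diff(tt)
        feats[paste0(pr, "@d", seq_along(d))] <- as.list(d)
      }
      if ("max" %in% families) feats[[paste0(pr, "@max")]] <- max(xm)
      if ("mean" %in% families) feats[[paste0(pr, "@mean")]] <- mean(xm)
      if ("ss" %in% families) {
        feats[[paste0(pr, "@ss")]] <- mean(tail(xm, 3L))
      }
      if ("auc" %in% families) {
        feats[[paste0(pr, "@auc")]] <-
          sum(diff(tm) * (head(xm, -1L) + tail(xm, -1L)) / 2)
      }
    }
    cbind(sub[1L, group_by, drop = FALSE], as.data.frame(feats, check.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
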