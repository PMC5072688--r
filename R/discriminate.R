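#' Cell-line discrimination in PLS latent space
#'
#' Fits a PLS regression of the fate on the signals of the combined
#' (multi-cell-line) table -- on the log scale for the power-law kind --
#' and projects every observation onto the first two latent components.
#' Each observation is then assigned to the nearest cell-line centroid
#' (Euclidean distance in the 2-D score space); the misclassification count
#' is the number of observations whose nearest centroid differs from their
#' own cell line.
#'
#' @param combined Filtered `observation_table` with a `cell_line` metadata
#'   column covering >= 1 cell line.
#' @param fate Fate column used as the PLS response.
#' @param kind `"powerlaw"` (log-transformed signals) or `"linear"`.
#' @param n_components Number of PLS components to fit (>= 2; the first two
#'   are used for the projection).
#' @param epsilon Offset for the power-law response transform.
#' @return List of class `cellline_scores`: `scores` data.frame
#'   (`cell_line`, `comp1`, `comp2`, `assigned`), `centroids` matrix, and
#'   `n_misclassified`.
#' @export
cellline_scores <- function(combined, fate, kind = c("powerlaw", "linear"),
                            n_components = 2L, epsilon = 1e-6) {
  kind <- match.arg(kind)
  stopifnot(is_observation_table(combined))
  df <- as.data.frame(combined)
  if (!"cell_line" %in% names(df)) stop("'cell_line' metadata column required")
  if (!fate %in% fate_names(combined)) stop("unknown fate column: ", fate)
  X <- signal_matrix(combined, "signals")
  y <- df[[fate]]
  if (kind == "powerlaw") {
    if (any(X <= 0) || any(y <= epsilon)) {
      stop("power-law kind requires positive signals and fate > epsilon")
    }
    X <- log(X)
    y <- log(y - epsilon)
  }
  a <- max(2L, default_components(nrow(X), ncol(X), n_components))
  if (min(ncol(X), nrow(X) - 1L) < 2L) stop("fewer than 2 components available")
  pls <- fit_pls(X, y, n_components = a)
  if (pls$n_components < 2L) stop("fewer than 2 components extracted")
  sc <- pls_scores(pls, X, n_components = 2L)
  colnames(sc) <- c("comp1", "comp2")
  lines <- as.character(df$cell_line)
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(sc)), lines),
                                     function(idx) colMeans(sc[idx, , drop = FALSE])))
  d2 <- outer(seq_len(nrow(sc)), seq_len(nrow(centroids)), Vectorize(function(i, j) {
    sum((sc[i, ] - centroids[j, ])^2)
  }))
  assigned <- rownames(centroids)[apply(d2, 1L, which.min)]
  structure(list(
    scores = data.frame(cell_line = lines, comp1 = sc[, 1L], comp2 = sc[, 2L],
                        assigned = assigned),
    centroids = centroids,
    n_misclassified = sum(assigned != lines)
  ), class = "cellline_scores")
}

#' @export
print.cellline_scores <- function(x, ...) {
  cat(sprintf("<cellline_scores> %d observations, %d cell line(s), %d misclassified\n",
              nrow(x$scores), nrow(x$centroids), x$n_misclassified))
  invisible(x)
}
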