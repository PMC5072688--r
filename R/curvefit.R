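#' Fit one of the four candidate curve families
#'
#' Single-variable least-squares fit of one of the families
#' \deqn{Power: y = a x^b \quad Linear: y = a x + b}
#' \deqn{Exponential: y = a e^{b x} \quad Gaussian: y = a e^{-((x-b)/c)^2}}
#' The linear family is solved in closed form; the others by
#' Levenberg-Marquardt nonlinear least squares with deterministic
#' initialization (power and exponential from the log-linear closed form,
#' Gaussian from the peak value, peak location and half-range), plus three
#' jittered restarts under a fixed seed if the first attempt fails to
#' converge.  Fit statistics follow the curve-fitting-tool conventions:
#' RMSE uses the residual degrees of freedom (see [goodness_of_fit()]).
#'
#' @param x Predictor series (strictly positive for the power family).
#' @param y Response series, same length (at least parameters + 1 points).
#' @param family One of `"power"`, `"linear"`, `"exponential"`, `"gaussian"`.
#' @return An object of class `curve_fit`: list with `family`, `params`
#'   (named: `a`, `b`, and `c` for gaussian), `sse`, `r2`, `adj_r2`,
#'   `rmse`, `fitted`.
#' @export
#' @examples
#' x <- seq(0.1, 1, length.out = 50)
#' fit_family(x, 2 * x^0.5, "power")$params
fit_family <- function(x, y, family = c("power", "linear", "exponential",
                                        "gaussian")) {
  family <- match.arg(family)
  if (length(x) != length(y)) stop("x and y must have equal length")
  npar <- if (family == "gaussian") 3L else 2L
  if (length(x) < npar + 1L) stop("need at least ", npar + 1L, " points")
  if (family == "power" && any(x <= 0)) {
    stop("power family requires strictly positive x")
  }
  if (family == "linear") {
    fit <- lm(y ~ x)
    params <- c(a = unname(coef(fit)[2L]), b = unname(coef(fit)[1L]))
    fitted <- unname(fitted(fit))
  } else {
    init <- curve_init(x, y, family)
    formula <- switch(family,
      power = y ~ a * x^b,
      exponential = y ~ a * exp(b * x),
      gaussian = y ~ a * exp(-((x - b) / c)^2))
    nfit <- nls_with_restarts(formula, data = data.frame(x = x, y = y),
                              start = init)
    params <- coef(nfit)
    fitted <- unname(predict(nfit))
  }
  gof <- goodness_of_fit(y, fitted, n_params = npar, rmse_type = "dof")
  structure(list(family = family, params = params, sse = gof$sse,
                 r2 = gof$r2, adj_r2 = gof$adj_r2, rmse = gof$rmse,
                 fitted = fitted), class = "curve_fit")
}

curve_init <- function(x, y, family) {
  pos <- y > 0
  if (family == "power") {
    if (sum(pos) >= 3L) {
      lf <- lm(log(y[pos]) ~ log(x[pos]))
      c(a = unname(exp(coef(lf)[1L])), b = unname(coef(lf)[2L]))
    } else {
      c(a = max(abs(y)), b = 1)
    }
  } else if (family == "exponential") {
    if (sum(pos) >= 3L) {
      lf <- lm(log(y[pos]) ~ x[pos])
      c(a = unname(exp(coef(lf)[1L])), b = unname(coef(lf)[2L]))
    } else {
      c(a = max(abs(y)), b = 0.1)
    }
  } else {
    c(a = max(y), b = x[which.max(y)], c = max(diff(range(x)) / 2, 1e-6))
  }
}

nls_with_restarts <- function(formula, data, start, n_restarts = 3L) {
  attempt <- function(st) {
    tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = as.list(st),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  fit <- attempt(start)
  if (!is.null(fit)) return(fit)
  # deterministic jittered restarts
  for (r in seq_len(n_restarts)) {
    jitter <- withr::with_seed(1000L + r, rnorm(length(start), 0, 0.5))
    fit <- attempt(unlist(start) * exp(jitter))
    if (!is.null(fit)) return(fit)
  }
  stop("curve fit failed to converge after ", n_restarts, " restarts")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> family = %s\n", x$family))
  print(round(x$params, 6))
  cat(sprintf("  SSE = %.3g  R2 = %.4f  adjR2 = %.4f  RMSE = %.3g\n",
              x$sse, x$r2, x$adj_r2, x$rmse))
  invisible(x)
}

#' Compare the four curve families on one data series
#'
#' Fits all four families of [fit_family()] and designates a best family by
#' smallest RMSE, breaking ties by larger R-square and then by family name.
#'
#' @param x,y Data series (x strictly positive).
#' @return An object of class `curve_comparison`: list with `fits` (named
#'   list of `curve_fit`), `table` (data.frame mirroring the report layout:
#'   family, SSE, R2, adjusted R2, RMSE) and `best` (family name).
#' @export
compare_families <- function(x, y) {
  fams <- c("power", "linear", "exponential", "gaussian")
  fits <- lapply(fams, function(f) {
    tryCatch(fit_family(x, y, f), error = function(e) NULL)
  })
  names(fits) <- fams
  ok <- !vapply(fits, is.null, logical(1L))
  if (!any(ok)) stop("no curve family could be fitted")
  tab <- do.call(rbind, lapply(fits[ok], function(f) {
    data.frame(family = f$family, sse = f$sse, r2 = f$r2,
               adj_r2 = f$adj_r2, rmse = f$rmse)
  }))
  rownames(tab) <- NULL
  ord <- order(tab$rmse, -tab$r2, tab$family)
  best <- tab$family[ord[1L]]
  structure(list(fits = fits[ok], table = tab, best = best),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat("<curve_comparison> best family:", x$best, "\n")
  print(x$table, digits = 4)
  invisible(x)
}
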