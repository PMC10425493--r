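#' Weighted five-parameter logistic fit of a time response
#'
#' Fits the asymmetric sigmoid
#' \code{y = B + (T - B) / (1 + 10^(b * (xmid - x)))^s} on
#' \code{x = log10(t + offset)} by Levenberg-Marquardt least squares, then
#' iterates once with residual-based weights \code{w = 1 / max(eps, r^2)}.
#' Setting \code{s = 1} recovers the 4-parameter logistic.
#'
#' @param t times (hours); an offset keeps x finite at t = 0 (default half
#'   the smallest positive time).
#' @param y responses (log2FC scale).
#' @param offset log10 offset; default \code{min(t[t > 0]) / 2}.
#' @param eps floor of the squared residual in the weights.
#' @return list: \code{pars} (B, T, xmid, b, s), \code{offset},
#'   \code{fitted}, \code{converged}, and \code{predict(tNew)}.
#' @export
fit5pl <- function(t, y, offset = NULL, eps = 1e-3) {
  if (length(unique(t)) < 5L) stop("need >= 5 distinct time levels")
  if (is.null(offset)) offset <- min(t[t > 0]) / 2
  x <- log10(t + offset)
  dat <- data.frame(x = x, y = y)
  start <- list(B = min(y), T = max(y), xmid = stats::median(x), b = 2, s = 1)
  lower <- c(-Inf, -Inf, -Inf, -50, 1e-3)
  upper <- c(Inf, Inf, Inf, 50, 50)
  form <- y ~ B + (T - B) / (1 + 10^(b * (xmid - x)))^s
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    r <- stats::residuals(fit)
    w <- 1 / pmax(eps, r^2)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = as.list(stats::coef(fit)),
                        lower = lower, upper = upper, weights = w,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) fit)
  }
  if (is.null(fit)) {
    ## fallback: monotone-in-time interpolation of per-time mean responses
    tm <- sort(unique(t))
    ym <- vapply(tm, function(tt) mean(y[t == tt]), 0)
    return(list(pars = NULL, offset = offset, fitted = NULL,
                converged = FALSE,
                predict = function(tNew)
                  stats::approx(tm, ym, xout = pmin(pmax(tNew, min(tm)),
                                                    max(tm)))$y))
  }
  pars <- stats::coef(fit)
  list(pars = pars, offset = offset, fitted = stats::fitted(fit),
       converged = TRUE,
       predict = function(tNew) {
         xn <- log10(tNew + offset)
         unname(pars["B"] + (pars["T"] - pars["B"]) /
                  (1 + 10^(pars["b"] * (pars["xmid"] - xn)))^pars["s"])
       })
}

#' Predicted log2 fold change at a benchmark time
#'
#' Convenience wrapper: fit the weighted 5-PL to the probe's time response
#' and evaluate it at the BMT. Falls back (flagged) to monotone
#' interpolation of per-time means when the 5-PL does not converge.
#'
#' @param t,y response data as in \code{\link{fit5pl}}.
#' @param bmt time (hours) at which to predict.
#' @return list: \code{prediction}, \code{converged}.
#' @export
fit5plPredict <- function(t, y, bmt) {
  f <- fit5pl(t, y)
  list(prediction = f$predict(bmt), converged = f$converged)
}
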