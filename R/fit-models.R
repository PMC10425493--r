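## Least-squares fitting of the ten time-response families.
##
## Every family is linear in part of its parameters given the nonlinear
## ones, so fits profile the linear coefficients (exact solve) and search
## the at-most-two nonlinear parameters over a deterministic grid derived
## from the data's time quantiles, refined by bounded optimization. No
## random starts: fits are reproducible with no RNG dependency.

.lmProfile <- function(X, y) {
  p <- ncol(X)
  if (p == 1L) {
    x <- X[, 1L]
    sxx <- sum(x * x)
    if (sxx <= 0 || !is.finite(sxx))
      return(list(coef = NA_real_, rss = Inf))
    b <- sum(x * y) / sxx
    return(list(coef = b, rss = max(0, sum(y * y) - b * b * sxx)))
  }
  if (p == 2L) {
    ## closed-form 2x2 normal equations (grids hammer this path)
    x1 <- X[, 1L]; x2 <- X[, 2L]
    a11 <- sum(x1 * x1); a12 <- sum(x1 * x2); a22 <- sum(x2 * x2)
    b1 <- sum(x1 * y); b2 <- sum(x2 * y)
    det <- a11 * a22 - a12 * a12
    if (!is.finite(det) || abs(det) < 1e-12 * max(a11 * a22, 1))
      return(list(coef = c(NA_real_, NA_real_), rss = Inf))
    c1 <- (a22 * b1 - a12 * b2) / det
    c2 <- (a11 * b2 - a12 * b1) / det
    rss <- max(0, sum(y * y) - c1 * b1 - c2 * b2)
    return(list(coef = c(c1, c2), rss = rss))
  }
  fit <- stats::.lm.fit(X, y)
  list(coef = fit$coefficients, rss = sum(fit$residuals^2))
}

## direction sign used by Exp2/Exp3 (and as a hint elsewhere): sign of the
## difference between the last-level mean and the anchor mean.
.trendSign <- function(t, y) {
  tmax <- max(t)
  d <- mean(y[t == tmax]) - mean(y[t == 0])
  if (d >= 0) 1 else -1
}

.fitEngine <- function(family, t, y) {
  n <- length(y)
  tpos <- sort(unique(t[t > 0]))
  tmin <- min(tpos); tmax <- max(tpos)
  ok <- function(coef, rss, theta) list(theta = theta, rss = rss,
                                        converged = all(is.finite(theta)))
  fail <- list(theta = NA_real_, rss = Inf, converged = FALSE)

  if (family %in% c("Linear", "Poly2", "Poly3", "Poly4")) {
    deg <- switch(family, Linear = 1L, Poly2 = 2L, Poly3 = 3L, Poly4 = 4L)
    X <- stats::poly(t, degree = deg, raw = TRUE)
    X <- cbind(1, X)
    f <- .lmProfile(X, y)
    th <- stats::setNames(as.numeric(f$coef), .familyParNames(family))
    return(ok(f$coef, f$rss, th))
  }

  if (family == "Power") {
    obj <- function(delta) .lmProfile(cbind(1, t^delta), y)$rss
    grid <- c(1, 1.5, 2, 3, 4, 6, 9, 13, 18)
    rg <- vapply(grid, obj, 0)
    d0 <- grid[which.min(rg)]
    opt <- stats::optimize(obj, lower = max(1, d0 / 2), upper = min(18, d0 * 2))
    delta <- if (opt$objective < min(rg)) opt$minimum else d0
    f <- .lmProfile(cbind(1, t^delta), y)
    th <- stats::setNames(c(f$coef, delta), .familyParNames("Power"))
    return(ok(f$coef, f$rss, th))
  }

  if (family == "Hill") {
    obj <- function(par) {  # par = (log k, n)
      k <- exp(par[1]); nn <- par[2]
      x <- t^nn / (k^nn + t^nn)
      .lmProfile(cbind(1, x), y)$rss
    }
    kg <- log(exp(seq(log(tmin / 2), log(tmax * 2), length.out = 6)))
    ng <- c(0.5, 1, 2, 4, 8, 14)
    grid <- expand.grid(logk = kg, n = ng)
    rg <- apply(grid, 1, obj)
    p0 <- as.numeric(grid[which.min(rg), ])
    opt <- tryCatch(stats::nlminb(p0, obj,
                                  lower = c(log(tmin / 20), 1e-2),
                                  upper = c(log(tmax * 20), 18)),
                    error = function(e) NULL)
    par <- if (!is.null(opt) && opt$objective <= min(rg)) opt$par else p0
    k <- exp(par[1]); nn <- par[2]
    f <- .lmProfile(cbind(1, t^nn / (k^nn + t^nn)), y)
    th <- stats::setNames(c(f$coef[1], f$coef[2], k, nn),
                          .familyParNames("Hill"))
    return(ok(f$coef, f$rss, th))
  }

  sgn <- .trendSign(t, y)

  if (family == "Exp2") {
    obj <- function(logb) {
      b <- exp(logb)
      .lmProfile(cbind(exp(sgn * b * t)), y)$rss
    }
    bg <- log(c(1e-3, 5e-3, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2) * (24 / tmax))
    rg <- vapply(bg, obj, 0)
    b0 <- bg[which.min(rg)]
    opt <- stats::optimize(obj, lower = b0 - log(4), upper = b0 + log(4))
    logb <- if (opt$objective < min(rg)) opt$minimum else b0
    b <- exp(logb)
    f <- .lmProfile(cbind(exp(sgn * b * t)), y)
    th <- stats::setNames(c(f$coef[1], b, sgn), .familyParNames("Exp2"))
    return(ok(f$coef, f$rss, th))
  }

  if (family == "Exp3") {
    obj <- function(par) {  # (log b, d)
      b <- exp(par[1]); d <- par[2]
      .lmProfile(cbind(exp(sgn * (b * t)^d)), y)$rss
    }
    grid <- expand.grid(logb = log(c(0.01, 0.05, 0.1, 0.2, 0.5, 1) * (24 / tmax)),
                        d = c(1, 2, 4, 8))
    rg <- apply(grid, 1, obj)
    p0 <- as.numeric(grid[which.min(rg), ])
    opt <- tryCatch(stats::nlminb(p0, obj,
                                  lower = c(log(1e-4), 1), upper = c(log(10), 18)),
                    error = function(e) NULL)
    par <- if (!is.null(opt) && opt$objective <= min(rg)) opt$par else p0
    b <- exp(par[1]); d <- par[2]
    f <- .lmProfile(cbind(exp(sgn * (b * t)^d)), y)
    th <- stats::setNames(c(f$coef[1], b, d, sgn), .familyParNames("Exp3"))
    return(ok(f$coef, f$rss, th))
  }

  if (family == "Exp4" || family == "Exp5") {
    two_d <- family == "Exp5"
    obj <- function(par) {  # (log b [, d]); model = A + B exp(-(b t)^d)
      b <- exp(par[1]); d <- if (two_d) par[2] else 1
      .lmProfile(cbind(1, exp(-(b * t)^d)), y)$rss
    }
    logbg <- log(c(0.02, 0.05, 0.1, 0.2, 0.4, 0.8, 1.6) * (24 / tmax))
    grid <- if (two_d) expand.grid(logb = logbg, d = c(1, 2, 4, 8))
            else data.frame(logb = logbg)
    rg <- apply(grid, 1, obj)
    p0 <- as.numeric(grid[which.min(rg), ])
    lo <- c(log(1e-4), if (two_d) 1)
    hi <- c(log(20), if (two_d) 18)
    opt <- tryCatch(stats::nlminb(p0, obj, lower = lo, upper = hi),
                    error = function(e) NULL)
    par <- if (!is.null(opt) && opt$objective <= min(rg)) opt$par else p0
    b <- exp(par[1]); d <- if (two_d) par[2] else 1
    f <- .lmProfile(cbind(1, exp(-(b * t)^d)), y)
    A <- f$coef[1]; B <- f$coef[2]
    a <- A + B
    if (abs(a) < 1e-12) return(fail)   # baseline exactly zero: c undefined
    cc <- A / a
    th <- if (two_d)
      stats::setNames(c(a, b, cc, d), .familyParNames("Exp5"))
    else stats::setNames(c(a, b, cc), .familyParNames("Exp4"))
    return(ok(f$coef, f$rss, th))
  }
  stop("unknown model family: ", family)
}

## Gaussian log-likelihood at the MLE variance, with its constant terms; all
## families use the same convention so AICs are directly comparable.
.gaussLogLik <- function(rss, n) {
  s2 <- max(rss / n, .Machine$double.xmin)
  -n / 2 * (log(2 * pi * s2) + 1)
}

#' Fit one parametric family to a time response
#'
#' Least squares (Gaussian maximum likelihood) with the linear coefficients
#' profiled exactly and the nonlinear parameters searched over a
#' deterministic grid refined by bounded optimization. Reports the AIC
#' (counting the variance as one parameter) and a goodness-of-fit p value:
#' the likelihood-ratio test of the fitted curve against the saturated
#' per-time-means model, chi-squared with df = (number of time levels) -
#' (number of mean parameters), p = 1 when df <= 0.
#'
#' @param family one of \code{tenFamilies()}.
#' @param t times (hours), including the t = 0 anchor replicates.
#' @param y responses (log2FC scale), same length.
#' @return a \linkS4class{ModelFit}.
#' @export
fitFamily <- function(family, t, y) {
  stopifnot(length(t) == length(y))
  if (!family %in% TEN_FAMILIES) stop("unknown model family: ", family)
  n <- length(y)
  eng <- tryCatch(.fitEngine(family, t, y),
                  error = function(e) list(theta = NA_real_, rss = Inf,
                                           converged = FALSE))
  npar <- .familyNpar(family)
  if (!isTRUE(eng$converged)) {
    return(new("ModelFit", family = family, theta = NA_real_, rss = Inf,
               logLik = -Inf, npar = npar, aic = Inf, fitPValue = 0,
               converged = FALSE, t = t, y = y))
  }
  ll <- .gaussLogLik(eng$rss, n)
  aic <- 2 * (npar + 1) - 2 * ll
  ## saturated model: one mean per time level
  means <- stats::ave(y, t)
  rss_sat <- sum((y - means)^2)
  nlev <- length(unique(t))
  df <- nlev - npar
  scale <- sum(y^2) + .Machine$double.xmin
  fitp <- if (df <= 0) 1 else if (eng$rss / scale < 1e-10) 1 else {
    lrt <- n * log(eng$rss / max(rss_sat, scale * 1e-12))
    stats::pchisq(max(0, lrt), df, lower.tail = FALSE)
  }
  new("ModelFit", family = family, theta = eng$theta, rss = eng$rss,
      logLik = ll, npar = npar, aic = aic, fitPValue = fitp,
      converged = TRUE, t = t, y = y)
}

#' Fit all ten families
#'
#' @param t,y as in \code{\link{fitFamily}}.
#' @param families families to fit (default all ten).
#' @return named list of \linkS4class{ModelFit}.
#' @export
fitAllFamilies <- function(t, y, families = tenFamilies()) {
  stats::setNames(lapply(families, fitFamily, t = t, y = y), families)
}

#' Select the best fit by AIC
#'
#' Lowest AIC among converged fits wins; ties within 1e-6 go to the family
#' with fewer parameters, then to the canonical family order.
#'
#' @param fits list of \linkS4class{ModelFit} (one probe's fits).
#' @return the selected \linkS4class{ModelFit}.
#' @export
selectBestFit <- function(fits) {
  conv <- Filter(function(f) f@converged && is.finite(f@aic), fits)
  if (!length(conv)) stop("all fits failed")
  aics <- vapply(conv, function(f) f@aic, 0)
  best <- min(aics)
  cand <- conv[aics <= best + 1e-6]
  if (length(cand) > 1L) {
    npars <- vapply(cand, function(f) f@npar, 0L)
    cand <- cand[npars == min(npars)]
    if (length(cand) > 1L) {
      ordv <- match(vapply(cand, function(f) f@family, ""), TEN_FAMILIES)
      cand <- cand[order(ordv)]
    }
  }
  cand[[1]]
}

#' Predict from a fitted model
#'
#' @param fit a \linkS4class{ModelFit}.
#' @param t times at which to evaluate the fitted mean function.
#' @return numeric vector.
#' @export
predictCurve <- function(fit, t) {
  if (!fit@converged) stop("cannot predict from a failed fit")
  evalFamily(fit@family, fit@theta, t)
}
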