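## The ten-family catalogue of parametric time-response models.
##
## Parameterizations (t in hours, response on log2 fold-change scale):
##   Linear  beta0 + beta1*t
##   Poly2-4 beta0 + sum_k beta_k t^k
##   Power   gamma + beta * t^delta,            delta in [1, 18]
##   Hill    gamma + v * t^n / (k^n + t^n),     k > 0, n in (0, 18]
##   Exp2    a * exp(sigma * b * t),            b > 0, sigma = +/-1
##   Exp3    a * exp(sigma * (b*t)^d),          b > 0, d in [1, 18]
##   Exp4    a * (c - (c - 1) * exp(-b*t)),     b > 0
##   Exp5    a * (c - (c - 1) * exp(-(b*t)^d)), b > 0, d in [1, 18]
## Exponent caps at 18 prevent step-function degeneracy, the usual
## benchmark-dose constraint.

#' Evaluate a model family's mean function
#'
#' @param family one of \code{tenFamilies()}.
#' @param theta named parameter vector in the family's parameterization.
#' @param t times (hours) at which to evaluate.
#' @return numeric vector of mean responses.
#' @export
evalFamily <- function(family, theta, t) {
  th <- unname(theta)
  switch(family,
    Linear = th[1] + th[2] * t,
    Poly2  = th[1] + th[2] * t + th[3] * t^2,
    Poly3  = th[1] + th[2] * t + th[3] * t^2 + th[4] * t^3,
    Poly4  = th[1] + th[2] * t + th[3] * t^2 + th[4] * t^3 + th[5] * t^4,
    Power  = th[1] + th[2] * t^th[3],
    Hill   = th[1] + th[2] * t^th[4] / (th[3]^th[4] + t^th[4]),
    Exp2   = th[1] * exp(th[3] * th[2] * t),
    Exp3   = th[1] * exp(th[4] * (th[2] * t)^th[3]),
    Exp4   = th[1] * (th[3] - (th[3] - 1) * exp(-th[2] * t)),
    Exp5   = th[1] * (th[3] - (th[3] - 1) * exp(-(th[2] * t)^th[4])),
    stop("unknown model family: ", family)
  )
}

#' The ten model families
#' @return character vector of family names in canonical order.
#' @export
tenFamilies <- function() TEN_FAMILIES

## Canonical parameter names per family (order matters for evalFamily).
.familyParNames <- function(family) {
  switch(family,
    Linear = c("beta0", "beta1"),
    Poly2  = c("beta0", "beta1", "beta2"),
    Poly3  = c("beta0", "beta1", "beta2", "beta3"),
    Poly4  = c("beta0", "beta1", "beta2", "beta3", "beta4"),
    Power  = c("gamma", "beta", "delta"),
    Hill   = c("gamma", "v", "k", "n"),
    Exp2   = c("a", "b", "sigma"),
    Exp3   = c("a", "b", "d", "sigma"),
    Exp4   = c("a", "b", "c"),
    Exp5   = c("a", "b", "c", "d"),
    stop("unknown model family: ", family))
}

## Number of free mean parameters (sigma in Exp2/Exp3 is set by the data
## direction, not estimated freely, matching benchmark-dose convention).
.familyNpar <- function(family) {
  switch(family, Linear = 2L, Poly2 = 3L, Poly3 = 4L, Poly4 = 5L,
         Power = 3L, Hill = 4L, Exp2 = 2L, Exp3 = 3L, Exp4 = 3L, Exp5 = 4L)
}

## First t > 0 at which |mu(t) - mu(0)| reaches bmr, by coarse grid scan
## followed by bisection. Returns NA_real_ if never reached on (0, tmax].
.invertAtBmr <- function(mu, bmr, tmax, ngrid = 4000L, tol = 1e-10) {
  base <- mu(0)
  g <- function(t) abs(mu(t) - base) - bmr
  grid <- seq(tmax / ngrid, tmax, length.out = ngrid)
  gv <- g(grid)
  if (!all(is.finite(gv))) return(NA_real_)
  idx <- which(gv >= 0)
  if (!length(idx)) return(NA_real_)
  hi <- grid[idx[1]]
  lo <- if (idx[1] == 1L) 0 else grid[idx[1] - 1L]
  if (g(hi) == 0) return(hi)
  uniroot(g, lower = lo, upper = hi, tol = tol)$root
}

## BMT of a (family, theta) curve at benchmark response bmr: closed form for
## Linear/Power/Hill, guarded bisection otherwise. bmr is on the scale of
## |mu(t) - mu(0)|, so baseline offsets are irrelevant.
.bmtFromTheta <- function(family, theta, bmr, tmax) {
  stopifnot(bmr > 0)
  th <- unname(theta)
  if (family == "Linear") {
    if (abs(th[2]) < .Machine$double.eps) return(NA_real_)
    return(bmr / abs(th[2]))
  }
  if (family == "Power") {
    if (abs(th[2]) < .Machine$double.eps) return(NA_real_)
    return((bmr / abs(th[2]))^(1 / th[3]))
  }
  if (family == "Hill") {
    v <- abs(th[2]); k <- th[3]; n <- th[4]
    if (v <= bmr) return(NA_real_)
    return(k * (bmr / (v - bmr))^(1 / n))
  }
  mu <- function(t) evalFamily(family, theta, t)
  .invertAtBmr(mu, bmr, tmax)
}
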