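test_that("closed-form benchmark times match the definitions", {
  # Linear: t = bmr / |slope|
  expect_equal(trueBmt("Linear", c(beta0 = 0.3, beta1 = 0.5), bmr = 1), 2)
  expect_equal(trueBmt("Linear", c(beta0 = 0, beta1 = -0.25), bmr = 1), 4)
  # Power: t = (bmr/|beta|)^(1/delta)
  expect_equal(trueBmt("Power", c(gamma = 1, beta = 0.5, delta = 2), bmr = 2), 2)
  # Hill: t = k * (bmr/(v - bmr))^(1/n)
  expect_equal(trueBmt("Hill", c(gamma = 0, v = 4, k = 6, n = 2), bmr = 1),
               6 * (1 / 3)^(1 / 2))
  # unreachable plateau
  expect_true(is.na(trueBmt("Hill", c(gamma = 0, v = 0.8, k = 6, n = 2),
                            bmr = 1)))
  expect_error(trueBmt("NotAFamily", c(1, 2), 1), "invalid family")
})

test_that("numeric inversion agrees with dense-grid brute force", {
  cases <- list(
    list("Exp4", c(a = 1, b = 0.15, c = 4)),
    list("Exp5", c(a = 1, b = 0.1, c = 5, d = 2)),
    list("Exp2", c(a = 0.2, b = 0.2, sigma = 1)),
    list("Exp3", c(a = 0.3, b = 0.12, d = 1.5, sigma = 1)),
    list("Poly2", c(beta0 = 0, beta1 = 0.05, beta2 = 0.02)))
  for (cs in cases) {
    got <- trueBmt(cs[[1]], cs[[2]], bmr = 1, tmax = 100)
    want <- gridBmt(cs[[1]], cs[[2]], bmr = 1)
    expect_equal(got, want, tolerance = 1e-6,
                 label = paste("bisection BMT for", cs[[1]]))
  }
  # closed forms agree with the same grid oracle too
  for (cs in list(list("Linear", c(beta0 = 0, beta1 = 0.4)),
                  list("Power", c(gamma = 0, beta = 0.1, delta = 1.7)),
                  list("Hill", c(gamma = 0.2, v = 3, k = 5, n = 2.5)))) {
    expect_equal(trueBmt(cs[[1]], cs[[2]], bmr = 1),
                 gridBmt(cs[[1]], cs[[2]], bmr = 1), tolerance = 1e-6)
  }
})

test_that("exact data are interpolated and parameters recovered", {
  t <- standardTimes()
  # Linear, exact
  y <- 0.7 + 0.21 * t
  fit <- fitFamily("Linear", t, y)
  expect_equal(unname(fit@theta), c(0.7, 0.21), tolerance = 1e-8)
  expect_lt(fit@rss, 1e-10)
  expect_equal(fit@fitPValue, 1)
  # noiseless Hill recovers (v, k, n)
  th <- c(gamma = 0, v = 3, k = 6, n = 2.5)
  yh <- evalFamily("Hill", th, t)
  fh <- fitFamily("Hill", t, yh)
  expect_equal(unname(fh@theta[c("v", "k", "n")]), unname(th[c("v", "k", "n")]),
               tolerance = 1e-4)
})

test_that("AIC obeys the shared-constant Gaussian identity", {
  t <- standardTimes()
  set.seed(3)
  y <- 0.1 * t + rnorm(length(t), 0, 0.5)
  f1 <- fitFamily("Exp2", t, y)   # both have 2 mean parameters
  f2 <- fitFamily("Linear", t, y)
  n <- length(t)
  expect_equal(f1@aic - f2@aic, n * log(f1@rss / f2@rss), tolerance = 1e-8)
})

test_that("AIC selection prefers the true family and breaks ties as documented", {
  # injected AIC list: lowest wins
  mk <- function(fam, aic, npar) new("ModelFit", family = fam, theta = 0,
    rss = 1, logLik = 0, npar = as.integer(npar), aic = aic, fitPValue = 0.5,
    converged = TRUE, t = 0, y = 0)
  picked <- selectBestFit(list(mk("Hill", 10, 4), mk("Linear", 7, 2),
                               mk("Power", 12, 3)))
  expect_equal(picked@family, "Linear")
  # exact tie: fewer parameters wins
  picked <- selectBestFit(list(mk("Poly3", 5, 4), mk("Linear", 5, 2)))
  expect_equal(picked@family, "Linear")
  # single converged fit is selected
  bad <- mk("Hill", Inf, 4); bad@converged <- FALSE
  picked <- selectBestFit(list(bad, mk("Power", 99, 3)))
  expect_equal(picked@family, "Power")
  expect_error(selectBestFit(list(bad)), "all fits failed")
})

test_that("linear-truth noisy data selects a linear-capable family", {
  t <- standardTimes()
  nested_linear <- c("Linear", "Poly2", "Poly3", "Poly4", "Power")
  set.seed(42)
  hits <- 0L
  nrep <- 60L
  for (i in seq_len(nrep)) {
    y <- 0.15 * t + rnorm(length(t), 0, 0.4)
    best <- selectBestFit(fitAllFamilies(t, y))
    hits <- hits + (best@family %in% nested_linear)
  }
  expect_gte(hits / nrep, 0.9)
})

test_that("goodness-of-fit p flags lack of fit and passes adequate fits", {
  t <- standardTimes()
  # strongly sigmoidal truth, linear fit must lack fit
  y <- evalFamily("Hill", c(gamma = 0, v = 4, k = 8, n = 6), t)
  set.seed(1)
  y <- y + rnorm(length(y), 0, 0.2)
  expect_lt(fitFamily("Linear", t, y)@fitPValue, 0.01)
  expect_gt(fitFamily("Hill", t, y)@fitPValue, 0.1)
})
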