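# R-side oracle for the trend statistic: isotonic regression of the
# treatment-level means (equal per-level replication), amalgamated mean at
# the top level, pooled within-level variance.
williamsStatOracle <- function(y, times, sign = 1) {
  y <- sign * y
  lev <- sort(unique(times))
  means <- vapply(lev, function(t) mean(y[times == t]), 0)
  ns <- vapply(lev, function(t) sum(times == t), 0)
  ss <- sum(vapply(lev, function(t) {
    v <- y[times == t]; sum((v - mean(v))^2)
  }, 0))
  s2 <- ss / (length(y) - length(lev))
  iso <- stats::isoreg(means[-1])$yf      # equal weights across levels
  top <- iso[length(iso)]
  (top - means[1]) / sqrt(s2 * (1 / ns[length(ns)] + 1 / ns[1]))
}

test_that("the trend statistic matches an isotonic-regression oracle", {
  tp <- c(1, 2, 4, 6, 8, 12)
  times <- c(rep(0, 4), rep(tp, each = 3))   # equal treatment-level sizes
  set.seed(14)
  for (i in 1:20) {
    y <- rnorm(length(times), 0.05 * times, 0.5)
    got_up <- tempoBMT:::.williamsStat(y, match(times, sort(unique(times))) - 1L,
                                       length(tp) + 1L, 1L)
    got_down <- tempoBMT:::.williamsStat(y, match(times, sort(unique(times))) - 1L,
                                         length(tp) + 1L, -1L)
    expect_equal(got_up, williamsStatOracle(y, times, 1), tolerance = 1e-10)
    expect_equal(got_down, williamsStatOracle(y, times, -1), tolerance = 1e-10)
  }
})

test_that("degenerate and extreme trend inputs behave as defined", {
  times <- standardTimes(tp = c(1, 2, 4), nrep = 3, nAnchor = 3)
  # identical constants: p = 1
  wt <- williamsTrendTest(rep(2, length(times)), nPerm = 99, times = times)
  expect_equal(wt$p, 1)
  # noiseless strictly increasing means: p at the permutation floor 2/(B+1)
  y <- times   # strictly increasing with level, zero within-level variance
  set.seed(1)
  wt2 <- williamsTrendTest(y, nPerm = 199, times = times)
  expect_equal(wt2$p, 2 * 1 / 200)
  expect_error(williamsTrendTest(y[1:6], nPerm = 9, times = rep(c(0, 1), 3)),
               ">= 2 ordered levels")
})

test_that("the permutation p is deterministic under a fixed seed", {
  times <- standardTimes()
  set.seed(5)
  Y <- matrix(rnorm(3 * length(times)), nrow = 3)
  trs <- new("TimeResponseSet", response = Y, times = times, compound = "x")
  a <- tempoBMT:::.withFixedSeed(7L, williamsTrendTest(trs, nPerm = 200))
  b <- tempoBMT:::.withFixedSeed(7L, williamsTrendTest(trs, nPerm = 200))
  expect_identical(a, b)
})

test_that("the prefilter requires both trend significance and amplitude", {
  w <- data.frame(probe = c("a", "b", "c", "d"),
                  p = c(0.04, 0.04, 0.2, 0.01),
                  max_abs_lfc = c(1.5, 0.5, 1.5, 2))
  expect_equal(prefilterTrend(w), c("a", "d"))
})

test_that("planted responders pass the prefilter, inert probes rarely do", {
  sim <- simulateExperiment(smallConfig(nProbes = 120L, seed = 23L))
  cts <- SummarizedExperiment::assay(sim$experiment, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
  sel <- selectSamples(meta, "metalloid_early")
  f <- filterLowCounts(cts, c(sel$treated$sample_id, sel$control$sample_id))
  trs <- buildTimeResponse(f, meta, "metalloid_early")
  set.seed(2)
  wt <- williamsTrendTest(trs, nPerm = 300)
  elig <- prefilterTrend(wt)
  truth <- sim$truth[sim$truth$compound == "metalloid_early", ]
  # strong-signal responders (plateau comfortably above the |log2FC| > 1
  # amplitude cut) that survive the low-count filter; borderline-plateau or
  # near-zero-count genes can legitimately miss the prefilter
  resp <- truth$probe[truth$responder & truth$max_abs_lfc >= 1.5 &
                        truth$probe %in% rownames(f)]
  expect_gte(mean(resp %in% elig), 0.95)
  # inert compound: eligibility is a rare false-positive event
  trs0 <- buildTimeResponse(f, meta, "inert_control")
  set.seed(3)
  wt0 <- williamsTrendTest(trs0, nPerm = 300)
  expect_lt(length(prefilterTrend(wt0)) / nrow(cts), 0.05)
})
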