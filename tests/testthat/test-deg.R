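test_that("median-of-ratios size factors match the formula and DESeq2", {
  # identical columns: symmetry forces all factors to 1
  m <- matrix(c(5L, 9L, 5L, 9L, 5L, 9L), nrow = 2,
              dimnames = list(c("A_1", "B_2"), c("s1", "s2", "s3")))
  expect_equal(unname(sizeFactorsMedianRatio(m)), c(1, 1, 1))
  # 2x2 with sample2 = 2 * sample1: s = (1/sqrt(2), sqrt(2))
  m2 <- matrix(c(10L, 30L, 20L, 60L), nrow = 2,
               dimnames = list(c("A_1", "B_2"), c("s1", "s2")))
  expect_equal(unname(sizeFactorsMedianRatio(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # probes with any zero are excluded from the reference set
  m3 <- rbind(m2, C_3 = c(0L, 1000L))
  expect_equal(sizeFactorsMedianRatio(m3), sizeFactorsMedianRatio(m2))
  expect_error(sizeFactorsMedianRatio(rbind(c(0L, 2L), c(3L, 0L))),
               "no probe")
  # independent cross-check against the reference implementation
  set.seed(21)
  big <- matrix(rnbinom(600, mu = 100, size = 5), nrow = 60)
  dimnames(big) <- list(sprintf("P%d_%d", 1:60, 1:60), paste0("s", 1:10))
  expect_equal(unname(sizeFactorsMedianRatio(big)),
               unname(DESeq2::estimateSizeFactorsForMatrix(big)),
               tolerance = 1e-10)
})

test_that("size factors scale correctly when one sample's depth changes", {
  set.seed(4)
  m <- matrix(rnbinom(500, mu = 200, size = 10) + 1L, nrow = 50)
  dimnames(m) <- list(sprintf("P%d_%d", 1:50, 1:50), paste0("s", 1:10))
  s0 <- sizeFactorsMedianRatio(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4L
  s1 <- sizeFactorsMedianRatio(m2)
  # factor ratios scale by c; normalized counts change only by one global
  # constant (the geometric-mean reference absorbs c^(1/n))
  expect_equal(s1[3] / s1[-3], 4 * s0[3] / s0[-3], tolerance = 1e-10)
  n0 <- sweep(m, 2, s0, "/"); n1 <- sweep(m2, 2, s1, "/")
  expect_equal(n1 / n0, matrix(mean(n1 / n0), nrow(m), ncol(m),
                               dimnames = dimnames(m)), tolerance = 1e-10)
})

test_that("dispersion estimation recovers the simulation regime", {
  set.seed(31)
  n <- 400; reps <- 20
  sf <- rep(1, reps); names(sf) <- paste0("s", 1:reps)
  grp <- rep("g1", reps)
  # NB at alpha = 0.1
  m <- matrix(rnbinom(n * reps, mu = 300, size = 10), nrow = n,
              dimnames = list(sprintf("P%d_%d", 1:n, 1:n), names(sf)))
  est <- estimateDispersions(m, sf, grp, trendWeight = 0)
  expect_gt(median(est$alpha), 0.05)
  expect_lt(median(est$alpha), 0.2)
  # Poisson data: dispersions collapse toward zero
  mp <- matrix(rpois(n * reps, 300), nrow = n, dimnames = dimnames(m))
  estp <- estimateDispersions(mp, sf, grp, trendWeight = 0)
  expect_lt(median(estp$alpha), 0.01)
  # constant counts: exactly zero
  mc <- matrix(7L, 10, reps,
               dimnames = list(sprintf("C%d_%d", 1:10, 1:10), names(sf)))
  expect_true(all(estimateDispersions(mc, sf, grp)$alpha == 0))
  expect_error(estimateDispersions(m, sf, seq_len(reps)), "no group")
})

test_that("the NB Wald test is unbiased, symmetric and null-safe", {
  set.seed(77)
  n <- 300
  sf <- rep(1, 6); names(sf) <- paste0("s", 1:6)
  alpha <- rep(0.01, n)
  ctl <- matrix(rnbinom(n * 3, mu = 400, size = 100), nrow = n)
  trt <- matrix(rnbinom(n * 3, mu = 1600, size = 100), nrow = n)
  m <- cbind(ctl, trt)
  dimnames(m) <- list(sprintf("P%d_%d", 1:n, 1:n), names(sf))
  names(alpha) <- rownames(m)
  res <- nbWaldTest(m, paste0("s", 4:6), paste0("s", 1:3), sf, alpha)
  expect_equal(mean(res$log2FoldChange), 2, tolerance = 0.1)
  # swapping the group labels negates every lfc and preserves every p
  swp <- nbWaldTest(m, paste0("s", 1:3), paste0("s", 4:6), sf, alpha)
  expect_equal(swp$log2FoldChange, -res$log2FoldChange, tolerance = 1e-6)
  expect_equal(swp$pvalue, res$pvalue, tolerance = 1e-8)
  # identical groups: no signal at all
  mm <- cbind(ctl, ctl); dimnames(mm) <- dimnames(m)
  same <- nbWaldTest(mm, paste0("s", 4:6), paste0("s", 1:3), sf, alpha)
  expect_lt(max(abs(same$log2FoldChange)), 1e-6)
  expect_gt(min(same$pvalue), 1 - 1e-6)
  # all-zero probes are untestable, not errors
  mz <- m; mz[1, ] <- 0L
  rz <- nbWaldTest(mz, paste0("s", 4:6), paste0("s", 1:3), sf, alpha)
  expect_false(rz$testable[1])
  expect_equal(rz$pvalue[1], 1)
  expect_error(nbWaldTest(m, "s1", paste0("s", 1:3), sf, alpha), ">= 2 samples")
})

test_that("BH adjustment matches the step-up rule and its invariants", {
  expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustBH(0.5), 0.5)
  expect_equal(adjustBH(rep(1, 5)), rep(1, 5))
  expect_error(adjustBH(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(50)
  q <- adjustBH(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))   # monotone in the p order
})

test_that("per-time DEG series finds onsets and the earliest peak", {
  cfg <- smallConfig(nProbes = 120L, seed = 17L)
  sim <- simulateExperiment(cfg)
  cts <- SummarizedExperiment::assay(sim$experiment, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
  deg <- degTimeSeries(cts, meta, "metalloid_early")
  # archetype onsets are 2.5-4 h: almost nothing at 1 h, plenty by 8 h
  expect_lt(deg$nSignificant[["1"]], deg$nSignificant[["8"]] / 2)
  n_resp <- sum(sim$truth$responder[sim$truth$compound == "metalloid_early"])
  expect_gt(max(deg$nSignificant), 0.5 * n_resp)
  # inert compound: at most a trace of false positives
  deg0 <- degTimeSeries(cts, meta, "inert_control")
  expect_lt(max(deg0$nSignificant), 0.02 * nrow(cts) + 3)
  # peak-time tie rule: earliest maximum (checked on the selection logic)
  ns <- c(`1` = 0L, `2` = 3L, `4` = 10L, `6` = 10L)
  expect_equal(as.numeric(names(ns)[which.max(ns)]), 4)
})

test_that("Dunnett comparisons reduce to the t test and agree with multcomp", {
  set.seed(12)
  # k = 1: Dunnett equals the ordinary two-sided t test
  v <- c(rnorm(5, 0), rnorm(5, 1))
  g <- rep(c("ctl", "trt"), each = 5)
  d <- anovaDunnett(v, g, "ctl")
  tt <- t.test(v[g == "trt"], v[g == "ctl"], var.equal = TRUE)
  expect_equal(d$p_adjusted, tt$p.value, tolerance = 1e-6)
  # identical groups: p near 1
  v0 <- rep(c(1.0, 1.1, 0.9), 4)
  g0 <- rep(paste0("g", 1:4), each = 3)
  d0 <- anovaDunnett(v0, g0, "g1")
  expect_true(all(d0$p_adjusted > 0.99))
  # zero-variance degenerate cases
  dz <- anovaDunnett(rep(1, 6), rep(c("a", "b"), each = 3), "a")
  expect_equal(dz$p_adjusted, 1)
  dz2 <- anovaDunnett(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3), "a")
  expect_equal(dz2$p_adjusted, 0)
  # cross-check against multcomp on a 4-group design
  set.seed(13)
  v4 <- rnorm(20) + rep(c(0, 0.5, 1, 0), each = 5)
  g4 <- factor(rep(c("ctl", "t1", "t2", "t3"), each = 5))
  d4 <- anovaDunnett(v4, g4, "ctl")
  glht <- multcomp::glht(stats::aov(v4 ~ g4),
                         linfct = multcomp::mcp(g4 = "Dunnett"))
  pm <- summary(glht)$test$pvalues
  expect_equal(d4$p_adjusted, as.numeric(pm), tolerance = 5e-3)
})

test_that("Dunnett adjusted p values are calibrated against a Monte-Carlo oracle", {
  # null 4-groups-vs-control design: P(min adjusted p < 0.05) ~ 0.05.
  # Oracle: brute-force distribution of max |T| from the same design.
  set.seed(101)
  nrep <- 400; n <- 3; k <- 4
  minp <- replicate(nrep, {
    v <- rnorm(n * (k + 1))
    g <- rep(c("ctl", paste0("t", 1:k)), each = n)
    min(anovaDunnett(v, g, "ctl")$p_adjusted)
  })
  rate <- mean(minp < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("PCA coordinates separate an active compound's groups, not an inert's", {
  sim <- simulateExperiment(smallConfig(nProbes = 120L, seed = 19L))
  cts <- SummarizedExperiment::assay(sim$experiment, "counts")
  meta <- as.data.frame(SummarizedExperiment::colData(sim$experiment))
  sepScore <- function(cmp) {
    sel <- selectSamples(meta, cmp)
    samples <- c(sel$treated$sample_id, sel$control$sample_id)
    pc <- pcaCoordinates(cts[, samples, drop = FALSE])
    grp <- samples %in% sel$treated$sample_id
    max(abs(vapply(2:5, function(j) cor(pc[[j]], grp), 0)))
  }
  expect_equal(nrow(pcaCoordinates(cts[, 1:10])), 10)
  expect_gt(sepScore("metalloid_early"), 0.6)
  expect_lt(sepScore("inert_control"), 0.5)
})

test_that("reporter traces are anchored at their first point", {
  expect_equal(normalizeReporter(c(5, 7, 9)), c(0, 2, 4))
  expect_equal(normalizeReporter(rep(3, 4)), rep(0, 4))
  expect_equal(normalizeReporter(7), 0)
  expect_error(normalizeReporter(numeric()), "empty")
})
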