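test_that("benchmark-time inversion of fitted models matches closed forms", {
  t <- standardTimes()
  # Linear slope 0.5 log2FC/h, BMR 1 -> BMT 2 h
  fit <- fitFamily("Linear", t, 0.1 + 0.5 * t)
  expect_equal(computeBMT(fit, bmr = 1), 2, tolerance = 1e-8)
  # Hill (v=4, k=6, n=2), BMR 1 -> 6 / sqrt(3)
  th <- c(gamma = 0, v = 4, k = 6, n = 2)
  fh <- fitFamily("Hill", t, evalFamily("Hill", th, t))
  expect_equal(computeBMT(fh, bmr = 1), 6 * (1 / 3)^(1 / 2), tolerance = 1e-6)
  # monotone Exp fit: bisection matches the dense-grid brute force
  the <- c(a = 1, b = 0.12, c = 5)
  fe <- fitFamily("Exp4", t, evalFamily("Exp4", the, t))
  bmt <- computeBMT(fe, bmr = 1)
  expect_equal(bmt, gridBmt("Exp4", fe@theta, bmr = 1), tolerance = 1e-6)
  # flat fit: no BMT
  f0 <- fitFamily("Linear", t, rep(2, length(t)))
  expect_true(is.na(computeBMT(f0, bmr = 1)))
})

test_that("scaling the Hill effect moves the BMT earlier", {
  b <- vapply(c(1.5, 2, 3, 5, 8), function(v)
    trueBmt("Hill", c(gamma = 0, v = v, k = 6, n = 2), bmr = 1), 0)
  expect_true(all(diff(b) < 0))
})

test_that("time-unit equivariance: minutes scale BMTs by 60, decisions unchanged", {
  t <- standardTimes()
  set.seed(6)
  y <- evalFamily("Hill", c(gamma = 0, v = 3, k = 6, n = 3), t) +
    rnorm(length(t), 0, 0.3)
  trs_h <- new("TimeResponseSet", response = rbind(P_1 = y), times = t,
               compound = "x")
  trs_m <- new("TimeResponseSet", response = rbind(P_1 = y), times = t * 60,
               compound = "x")
  rh <- bmtAnalysis(trs_h, bmrSpec = "abs:1", nBoot = 80, seed = 42,
                    tMax = 24)
  rm_ <- bmtAnalysis(trs_m, bmrSpec = "abs:1", nBoot = 80, seed = 42,
                     tMin = 0.1 * 60, tMax = 24 * 60)
  expect_equal(rm_$bmt, 60 * rh$bmt, tolerance = 1e-3)
  expect_equal(rm_$bmtl, 60 * rh$bmtl, tolerance = 1e-2)
  expect_equal(rm_$bmtu, 60 * rh$bmtu, tolerance = 1e-2)
  expect_equal(rm_$ratio, rh$ratio, tolerance = 1e-6)
  expect_equal(rm_$fitPValue, rh$fitPValue, tolerance = 1e-6)
  expect_equal(rm_$retained, rh$retained)
})

test_that("noiseless data give a confidence ratio collapsing to 1", {
  t <- standardTimes()
  y <- evalFamily("Hill", c(gamma = 0, v = 3, k = 6, n = 3), t)
  fit <- fitFamily("Hill", t, y)
  ci <- bmtConfidence(fit, bmr = 1, nBoot = 60, seed = 2)
  expect_lt(ci["bmtu"] / ci["bmtl"], 1.001)
})

test_that("confidence ratios widen with the noise level", {
  t <- standardTimes()
  th <- c(gamma = 0, v = 3, k = 6, n = 3)
  med_ratio <- vapply(c(0.15, 0.45), function(sig) {
    set.seed(round(1000 * sig))
    median(replicate(8, {
      y <- evalFamily("Hill", th, t) + rnorm(length(t), 0, sig)
      fit <- selectBestFit(fitAllFamilies(t, y))
      ci <- bmtConfidence(fit, bmr = 1, nBoot = 60, seed = 3)
      ci["bmtu"] / ci["bmtl"]
    }))
  }, 0)
  expect_lt(med_ratio[1], med_ratio[2])
})

test_that("retention filters use the documented strict/inclusive semantics", {
  df <- data.frame(bmt = c(25, 12, 12, 12, NA, 0.05),
                   ratio = c(2, 40, 2, 2, 2, 2),
                   fitPValue = c(0.5, 0.5, 0.10, 0.5, 0.5, 0.5))
  out <- applyRetentionFilters(df)
  expect_equal(out$retained, c(FALSE,  # BMT outside window
                               FALSE,  # ratio = 40 exactly: strict <
                               FALSE,  # fit p = 0.10 exactly: strict >
                               TRUE, FALSE, FALSE))
})

test_that("accumulation curves are valid ECDF steps", {
  acc <- accumulationCurve(c(2, 2, 5))
  expect_equal(acc$time, c(2, 5))
  expect_equal(acc$cumulative, c(2L, 3L))
  expect_equal(max(acc$cumulative), 3L)
  expect_true(all(diff(acc$cumulative) > 0))
  expect_equal(nrow(accumulationCurve(numeric())), 0)
  set.seed(10)
  acc2 <- accumulationCurve(rexp(40, 0.2))
  expect_true(!is.unsorted(acc2$time))
  expect_true(!is.unsorted(acc2$cumulative))
  expect_equal(max(acc2$cumulative), 40L)
})

test_that("earliest-response genes rank by first time then amplitude", {
  mk <- function(genes, lfc, sig) data.frame(
    probe = paste0(genes, "_1"), gene = genes, log2FoldChange = lfc,
    significant = sig, stringsAsFactors = FALSE)
  tabs <- list(
    `4` = mk(c("A", "B", "C"), c(3, 2, 0.2), c(TRUE, TRUE, FALSE)),
    `20` = mk(c("A", "B", "C"), c(3, 2, -2), c(TRUE, TRUE, TRUE)),
    `24` = mk(c("A", "B", "C"), c(3, 2, -3), c(TRUE, TRUE, TRUE)))
  out <- earliestResponseGenes(tabs)
  expect_equal(out$gene, c("A", "B", "C"))       # tie at 4 h: |lfc| 3 before 2
  expect_equal(out$first_time_h, c(4, 4, 20))
  expect_equal(out$direction, c("up", "up", "down"))
  none <- lapply(tabs, function(x) { x$significant <- FALSE; x })
  expect_equal(nrow(earliestResponseGenes(none)), 0)
})

test_that("the weighted 5-PL recovers exact curves and nests the 4-PL", {
  t <- standardTimes()
  offset <- min(t[t > 0]) / 2
  x <- log10(t + offset)
  pars <- c(B = -0.1, T = 3, xmid = 0.8, b = 2.5, s = 1.6)
  y <- pars["B"] + (pars["T"] - pars["B"]) /
    (1 + 10^(pars["b"] * (pars["xmid"] - x)))^pars["s"]
  f <- fit5pl(t, as.numeric(y))
  expect_true(f$converged)
  expect_equal(unname(f$pars), unname(pars), tolerance = 1e-4)
  expect_equal(f$predict(6), as.numeric(pars["B"] + (pars["T"] - pars["B"]) /
    (1 + 10^(pars["b"] * (pars["xmid"] - log10(6 + offset))))^pars["s"]),
    tolerance = 1e-6)
  # constant data predict the constant
  fc <- fit5pl(t, rep(1.7, length(t)))
  expect_equal(fc$predict(c(2, 10)), c(1.7, 1.7), tolerance = 1e-6)
  # s = 1 truth: 5-PL agrees with an explicit 4-PL fit
  y4 <- -0.2 + (2.5 + 0.2) / (1 + 10^(1.8 * (0.7 - x)))
  f5 <- fit5pl(t, as.numeric(y4))
  expect_equal(f5$predict(8), as.numeric(-0.2 + 2.7 /
    (1 + 10^(1.8 * (0.7 - log10(8 + offset))))), tolerance = 1e-4)
  expect_error(fit5pl(c(0, 1, 2, 4), rnorm(4)), ">= 5 distinct")
})

test_that("per-probe BMT analysis recovers planted Hill responders", {
  t <- standardTimes()
  th <- c(gamma = 0, v = 3, k = 6, n = 3)
  tb <- trueBmt("Hill", th, bmr = 1)
  set.seed(8)
  Y <- t(replicate(12, evalFamily("Hill", th, t) + rnorm(length(t), 0, 0.35)))
  rownames(Y) <- sprintf("HILL%d_%d", 1:12, 1:12)
  trs <- new("TimeResponseSet", response = Y, times = t, compound = "x")
  res <- bmtAnalysis(trs, bmrSpec = "abs:1", nBoot = 80, seed = 5,
                     predictLfc = TRUE)
  expect_true(all(c("bmt", "bmtl", "bmtu", "ratio", "retained",
                    "predicted_lfc_at_bmt") %in% names(res)))
  expect_gt(mean(res$retained), 0.7)
  rel_err <- abs(res$bmt - tb) / tb
  expect_lt(median(rel_err), 0.2)
  # bounds bracket the point estimate
  ok <- res$retained
  expect_true(all(res$bmtl[ok] <= res$bmt[ok] + 1e-8))
  expect_true(all(res$bmtu[ok] >= res$bmt[ok] - 1e-8))
  # the 5-PL prediction at the BMT sits near the benchmark response
  expect_equal(median(abs(res$predicted_lfc_at_bmt[ok])), 1, tolerance = 0.35)
})
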