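#' Median-of-ratios size factors
#'
#' Per sample j, \code{s_j = median_g y_gj / geomean_g} over the probes with
#' strictly positive counts in every sample (only those have a finite,
#' nonzero geometric mean). Factors are not rescaled further.
#'
#' @param counts integer count matrix, probes x samples.
#' @return named numeric vector of positive size factors, one per sample.
#' @export
sizeFactorsMedianRatio <- function(counts) {
  logc <- log(counts)
  ref <- rowMeans(logc)            # log geometric mean; -Inf if any zero
  use <- is.finite(ref)
  if (!any(use)) stop("no probe has positive counts in all samples")
  sf <- apply(logc[use, , drop = FALSE], 2, function(lc)
    exp(stats::median(lc - ref[use])))
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

#' Moment-based dispersion estimates with trend shrinkage
#'
#' Per probe, a method-of-moments dispersion from within-group variances of
#' normalized counts: \code{alpha = (var - mu) / mu^2} pooled across groups
#' (weighted by degrees of freedom), floored at 0, then shrunk toward a
#' fitted mean-dispersion trend \code{a0 + a1/mu} by a weighted average.
#' This is a deliberately simple scheme, not a reimplementation of shrinkage
#' estimators from full differential-expression frameworks; it is exchanged
#' via the \code{trendWeight} knob (0 disables shrinkage).
#'
#' @param counts count matrix.
#' @param sizeFactors per-sample size factors.
#' @param grouping factor of condition labels (one per sample); groups with
#'   fewer than 2 replicates contribute nothing.
#' @param trendWeight weight of the trend in the shrunk estimate, in [0, 1].
#' @return list with \code{alpha} (named per-probe dispersions),
#'   \code{alphaRaw}, \code{trend} and \code{method}.
#' @export
estimateDispersions <- function(counts, sizeFactors, grouping,
                                trendWeight = 0.3) {
  grouping <- as.factor(grouping)
  norm <- sweep(counts, 2, sizeFactors, "/")
  groups <- levels(grouping)
  num <- rep(0, nrow(counts)); den <- rep(0, nrow(counts))
  for (g in groups) {
    idx <- which(grouping == g)
    if (length(idx) < 2L) next
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1, stats::var)
    df <- length(idx) - 1L
    ok <- m > 0
    num[ok] <- num[ok] + df * (v[ok] - m[ok]) / m[ok]^2
    den <- den + df
  }
  if (all(den == 0)) stop("no group with >= 2 replicates")
  alpha_raw <- pmax(0, num / den)
  base_mean <- rowMeans(norm)
  ## parametric trend alpha ~ a0 + a1 / mean, fitted on informative probes
  trend <- rep(0, nrow(counts))
  fit_ok <- alpha_raw > 0 & base_mean > 0
  if (sum(fit_ok) >= 10) {
    co <- stats::coef(stats::lm(alpha_raw[fit_ok] ~ I(1 / base_mean[fit_ok])))
    trend <- pmax(0, co[1] + co[2] / pmax(base_mean, 1e-8))
  }
  alpha <- pmax(0, (1 - trendWeight) * alpha_raw + trendWeight * trend)
  names(alpha) <- names(alpha_raw) <- rownames(counts)
  list(alpha = alpha, alphaRaw = alpha_raw, trend = trend,
       method = "moments+trend")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment; a thin, input-checked wrapper so every stage
#' shares one code path.
#'
#' @param p numeric vector of p values in [0, 1].
#' @return adjusted p values, same order.
#' @export
adjustBH <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-probe negative-binomial Wald test, treated vs control
#'
#' Fits, per probe, the two-group NB model with means
#' \code{mu_j = s_j * q * 2^(beta * x_j)} (x = 1 for treated) by maximum
#' likelihood at fixed per-probe dispersion, via the NB GLM with log link
#' and \code{log(s_j)} offsets. Reports the log2 fold change \code{beta},
#' its standard error from the observed information, the two-sided Wald p,
#' and the mean of normalized counts. Probes with all-zero counts in both
#' groups are flagged untestable (\code{lfc = 0, p = 1}).
#'
#' @param counts count matrix.
#' @param treated,control character vectors of sample IDs.
#' @param sizeFactors named per-sample size factors covering both groups.
#' @param dispersions named per-probe dispersions (>= 0; 0 means Poisson).
#' @return data.frame: probe, gene, baseMean, log2FoldChange, lfcSE, stat,
#'   pvalue, testable.
#' @export
nbWaldTest <- function(counts, treated, control, sizeFactors, dispersions) {
  if (length(treated) < 2L || length(control) < 2L)
    stop("need >= 2 samples per group")
  sel <- c(control, treated)
  y <- counts[, sel, drop = FALSE]
  sf <- sizeFactors[sel]
  x <- cbind(1, c(rep(0, length(control)), rep(1, length(treated))))
  off <- log(sf)
  alpha <- dispersions[rownames(counts)]
  if (anyNA(alpha)) stop("dispersions missing for some probes")
  base_mean <- rowMeans(sweep(y, 2, sf, "/"))
  n <- nrow(counts)
  lfc <- se <- pv <- numeric(n)
  testable <- rep(TRUE, n)
  ln2 <- log(2)
  for (i in seq_len(n)) {
    yi <- y[i, ]
    if (all(yi == 0)) {
      lfc[i] <- 0; se[i] <- NA_real_; pv[i] <- 1; testable[i] <- FALSE
      next
    }
    fam <- if (alpha[i] <= 1e-8) stats::poisson()
           else MASS::negative.binomial(theta = 1 / alpha[i])
    fit <- suppressWarnings(
      stats::glm.fit(x, yi, family = fam, offset = off,
                     control = list(maxit = 100)))
    b <- fit$coefficients[2]
    p_rank <- fit$rank
    covmat <- tryCatch(
      chol2inv(fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE]),
      error = function(e) matrix(NA_real_, 2, 2))
    sei <- sqrt(covmat[2, 2])
    lfc[i] <- b / ln2
    se[i] <- sei / ln2
    z <- b / sei
    pv[i] <- if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else 1
  }
  data.frame(probe = rownames(counts), gene = probeToGene(rownames(counts)),
             baseMean = base_mean, log2FoldChange = lfc, lfcSE = se,
             stat = lfc / se, pvalue = pv, testable = testable,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-time-point differential expression for one compound
#'
#' Runs the treated-vs-time-matched-control NB Wald test at every tested
#' time point, with size factors computed once on the compound's selected
#' samples and dispersions estimated once pooling all time/treatment groups.
#' Significance per probe and time: BH-adjusted p below \code{padjThreshold}
#' and |log2FC| above \code{lfcThreshold}. The peak response time is the
#' earliest time attaining the maximum significant-DEG count.
#'
#' @param counts filtered count matrix for this compound.
#' @param metadata sample metadata.
#' @param compound compound label.
#' @param padjThreshold adjusted-p cut (default 0.01).
#' @param lfcThreshold |log2FC| cut (default 1, i.e. fold change 2).
#' @param trendWeight passed to \code{\link{estimateDispersions}}.
#' @return list: \code{tables} (per-time data.frames with padj and
#'   significant flag), \code{nSignificant} (named count vector),
#'   \code{peakTime}, \code{sizeFactors}, \code{dispersions}.
#' @export
degTimeSeries <- function(counts, metadata, compound,
                          padjThreshold = 0.01, lfcThreshold = 1,
                          trendWeight = 0.3) {
  sel <- selectSamples(metadata, compound)
  samples <- c(sel$treated$sample_id, sel$control$sample_id)
  cts <- counts[, samples, drop = FALSE]
  sf <- sizeFactorsMedianRatio(cts)
  grp <- paste0(ifelse(c(rep(FALSE, nrow(sel$treated)),
                         rep(TRUE, nrow(sel$control))), "veh", "trt"),
                c(sel$treated$time_h, sel$control$time_h))
  disp <- estimateDispersions(cts, sf, grp, trendWeight = trendWeight)
  times <- sort(unique(sel$treated$time_h))
  tables <- list()
  n_sig <- stats::setNames(integer(length(times)), times)
  for (t in times) {
    trt <- sel$treated$sample_id[sel$treated$time_h == t]
    ctl <- sel$control$sample_id[sel$control$time_h == t]
    if (!length(ctl)) stop("missing control samples at ", t, " h")
    res <- nbWaldTest(cts, trt, ctl, sf, disp$alpha)
    res$padj <- adjustBH(res$pvalue)
    res$significant <- res$padj < padjThreshold &
      abs(res$log2FoldChange) > lfcThreshold
    tables[[as.character(t)]] <- res
    n_sig[as.character(t)] <- sum(res$significant)
  }
  peak <- times[which.max(n_sig)]   # which.max takes the earliest maximum
  list(tables = tables, nSignificant = n_sig, peakTime = peak,
       sizeFactors = sf, dispersions = disp)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Pooled-variance one-way ANOVA followed by Dunnett-adjusted two-sided
#' comparisons of every treatment group against the control group. The
#' adjusted p for comparison i is \code{1 - P(max_j |T_j| <= |t_i|)} under
#' the multivariate t with the design's correlation matrix
#' (\code{rho_ij = sqrt(n_i n_j / ((n_i+n0)(n_j+n0)))}), evaluated
#' numerically via \code{mvtnorm::pmvt}.
#'
#' @param values numeric measurements.
#' @param groups group labels, same length.
#' @param controlLabel label of the control group.
#' @return data.frame: group, estimate (mean difference vs control), tstat,
#'   p_adjusted, plus the ANOVA F p value as attribute \code{"anova_p"}.
#' @export
anovaDunnett <- function(values, groups, controlLabel) {
  groups <- as.character(groups)
  if (!controlLabel %in% groups) stop("control group absent")
  lv <- c(controlLabel, setdiff(unique(groups), controlLabel))
  ns <- vapply(lv, function(g) sum(groups == g), 0L)
  if (length(lv) < 2L || any(ns < 2L)) stop("need >= 2 groups with >= 2 replicates")
  means <- vapply(lv, function(g) mean(values[groups == g]), 0)
  ss <- sum(vapply(lv, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }, 0))
  df <- sum(ns) - length(lv)
  s2 <- ss / df
  k <- length(lv) - 1L
  tstat <- (means[-1] - means[1]) / sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  ## zero residual variance: all means equal -> no evidence; else degenerate
  if (s2 <= .Machine$double.eps * max(1, mean(values)^2)) {
    p <- ifelse(abs(means[-1] - means[1]) < .Machine$double.eps^0.5, 1, 0)
    out <- data.frame(group = lv[-1], estimate = means[-1] - means[1],
                      tstat = ifelse(p == 1, 0, Inf), p_adjusted = p,
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "anova_p") <- if (all(p == 1)) 1 else 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  rho <- outer(seq_len(k), seq_len(k), function(i, j)
    sqrt(ns[-1][i] * ns[-1][j] / ((ns[-1][i] + ns[1]) * (ns[-1][j] + ns[1]))))
  diag(rho) <- 1
  p_adj <- vapply(abs(tstat), function(ti) {
    if (!is.finite(ti)) return(0)
    pr <- .withFixedSeed(20240601L, mvtnorm::pmvt(
      lower = rep(-ti, k), upper = rep(ti, k), df = df, corr = rho,
      type = "shifted"))
    min(1, max(0, 1 - as.numeric(pr)))
  }, 0)
  f <- (sum(ns[-1] * (means[-1] - mean(values))^2) +
          ns[1] * (means[1] - mean(values))^2) / (length(lv) - 1) / s2
  out <- data.frame(group = lv[-1], estimate = means[-1] - means[1],
                    tstat = tstat, p_adjusted = p_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "anova_p") <- stats::pf(f, length(lv) - 1, df, lower.tail = FALSE)
  out
}

#' Sample PCA coordinates on log-transformed normalized counts
#'
#' Plain QC export: principal-component coordinates of the samples computed
#' from \code{log2(normalized counts + 1)} on the most variable probes.
#' Treated and control groups of one compound are expected to separate; a
#' negative control should overlap its vehicles.
#'
#' @param counts count matrix (probes x samples).
#' @param sizeFactors per-sample size factors (median-of-ratios when
#'   missing).
#' @param nTop number of most-variable probes used (default 500, capped at
#'   the probe count).
#' @param nComponents number of components returned.
#' @return data.frame: sample_id, PC1..PCk, plus the fraction of variance
#'   per component as attribute \code{"explained"}.
#' @export
pcaCoordinates <- function(counts, sizeFactors = NULL, nTop = 500L,
                           nComponents = 4L) {
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(counts)
  lg <- log2(sweep(counts, 2, sizeFactors[colnames(counts)], "/") + 1)
  rv <- apply(lg, 1, stats::var)
  keep <- order(rv, decreasing = TRUE)[seq_len(min(nTop, nrow(lg)))]
  pc <- stats::prcomp(t(lg[keep, , drop = FALSE]), center = TRUE,
                      scale. = FALSE)
  k <- min(nComponents, ncol(pc$x))
  out <- data.frame(sample_id = colnames(counts),
                    pc$x[, seq_len(k), drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  out
}

#' Baseline-subtract a reporter fluorescence trace
#'
#' @param trace numeric vector of fluorescence intensities over time.
#' @return the trace minus its first value (so the first entry is 0).
#' @export
normalizeReporter <- function(trace) {
  if (!length(trace)) stop("empty trace")
  trace - trace[1]
}

## Evaluate expr under a fixed RNG state, restoring the caller's state.
.withFixedSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
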