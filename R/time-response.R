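#' Build per-replicate log2 fold-change time responses
#'
#' For each probe, the response of treated replicate r at time t is
#' \code{log2(norm_trt + pc) - log2(mean(norm_ctl at t) + pc)} against the
#' time-matched control mean. A t = 0 anchor level is built from the control
#' samples themselves: each control replicate against the mean of the other
#' controls at its time point, then centred at zero per probe. This mirrors
#' the dose-response convention of controls as the zero level when time
#' replaces concentration on the abscissa.
#'
#' @param counts filtered count matrix for the compound.
#' @param metadata sample metadata.
#' @param compound compound label.
#' @param sizeFactors per-sample size factors (computed on the compound's
#'   selected samples when missing).
#' @param pseudocount added before taking log2 (default 1).
#' @return a \linkS4class{TimeResponseSet}.
#' @export
buildTimeResponse <- function(counts, metadata, compound, sizeFactors = NULL,
                              pseudocount = 1) {
  sel <- selectSamples(metadata, compound)
  samples <- c(sel$treated$sample_id, sel$control$sample_id)
  cts <- counts[, samples, drop = FALSE]
  if (is.null(sizeFactors)) sizeFactors <- sizeFactorsMedianRatio(cts)
  norm <- sweep(cts, 2, sizeFactors[samples], "/")
  times <- sort(unique(sel$treated$time_h))

  ## anchor: leave-one-out control deviations at each time point
  anchor_cols <- list()
  for (t in times) {
    ctl <- sel$control$sample_id[sel$control$time_h == t]
    if (length(ctl) < 2L) stop("need >= 2 control replicates at ", t, " h")
    for (s in ctl) {
      others <- setdiff(ctl, s)
      ref <- rowMeans(norm[, others, drop = FALSE])
      anchor_cols[[s]] <- log2(norm[, s] + pseudocount) -
        log2(ref + pseudocount)
    }
  }
  anchor <- do.call(cbind, anchor_cols)
  anchor <- anchor - rowMeans(anchor)   # centre the t = 0 level per probe

  resp_cols <- list(); resp_times <- numeric()
  for (t in times) {
    trt <- sel$treated$sample_id[sel$treated$time_h == t]
    ctl <- sel$control$sample_id[sel$control$time_h == t]
    ref <- rowMeans(norm[, ctl, drop = FALSE])
    for (s in trt) {
      resp_cols[[s]] <- log2(norm[, s] + pseudocount) -
        log2(ref + pseudocount)
      resp_times <- c(resp_times, t)
    }
  }
  resp <- cbind(anchor, do.call(cbind, resp_cols))
  new("TimeResponseSet", response = resp,
      times = c(rep(0, ncol(anchor)), resp_times), compound = compound)
}

#' Williams-type trend test over ordered time levels
#'
#' Statistic: (isotonic amalgamated mean at the last level - anchor mean) /
#' standard error, with amalgamation by pool-adjacent-violators in the
#' hypothesized direction and the pooled within-level variance. Both
#' directions are tested; one-sided p values come from permutation of level
#' labels with the add-one correction, and the reported p is
#' \code{min(1, 2 * min(p_up, p_down))}. Also reports the maximum |log2FC|
#' over the per-time mean responses.
#'
#' @param trs a \linkS4class{TimeResponseSet}, or a numeric vector \code{y}
#'   with \code{times} supplied.
#' @param nPerm number of permutations (default 1000).
#' @param times per-observation times when \code{trs} is a vector.
#' @return data.frame: probe, p, stat_up, stat_down, max_abs_lfc.
#' @export
williamsTrendTest <- function(trs, nPerm = 1000L, times = NULL) {
  if (is(trs, "TimeResponseSet")) {
    Y <- trs@response
    tv <- trs@times
  } else {
    Y <- matrix(trs, nrow = 1)
    tv <- times
    if (is.null(tv)) stop("times required for vector input")
  }
  lev <- sort(unique(tv))
  if (length(lev) < 3L) stop("need >= 2 ordered levels beyond the anchor")
  lcode <- match(tv, lev) - 1L
  res <- .williamsPermMatrix(Y, lcode, length(lev), as.integer(nPerm))
  level_means <- vapply(lev[-1], function(t)
    rowMeans(Y[, tv == t, drop = FALSE]), numeric(nrow(Y)))
  if (is.null(dim(level_means))) level_means <- matrix(level_means, nrow = 1)
  maxfc <- apply(abs(level_means), 1, max)
  data.frame(probe = if (is.null(rownames(Y))) seq_len(nrow(Y)) else rownames(Y),
             p = res[, "p"], stat_up = res[, "stat_up"],
             stat_down = res[, "stat_down"], max_abs_lfc = maxfc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Trend prefilter for curve fitting
#'
#' Probes eligible for benchmark-time modeling: Williams p below
#' \code{alpha} and maximum |log2FC| above \code{lfcThreshold}.
#'
#' @param williams result of \code{\link{williamsTrendTest}}.
#' @param alpha p cut (default 0.05).
#' @param lfcThreshold |log2FC| cut (default 1).
#' @return character (or integer) vector of eligible probe IDs.
#' @export
prefilterTrend <- function(williams, alpha = 0.05, lfcThreshold = 1) {
  williams$probe[williams$p < alpha & williams$max_abs_lfc > lfcThreshold]
}
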