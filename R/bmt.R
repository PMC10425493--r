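#' Resolve a benchmark-response specification
#'
#' Two forms: \code{"sd:<mult>"} (the conventional multiple of the pooled
#' t = 0 anchor standard deviation of the response, default multiplier
#' 1.349) and \code{"abs:<value>"} (an absolute log2 fold change).
#'
#' @param spec character spec, e.g. \code{"sd:1.349"} or \code{"abs:1"}.
#' @param anchorSd pooled anchor standard deviation (required for the sd
#'   form).
#' @return the benchmark response as a positive log2FC magnitude.
#' @export
resolveBmr <- function(spec = "sd:1.349", anchorSd = NULL) {
  parts <- strsplit(spec, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("bmr spec must be 'sd:<mult>' or 'abs:<value>'")
  val <- as.numeric(parts[2])
  if (!is.finite(val) || val <= 0) stop("bmr value must be positive")
  switch(parts[1],
    sd = {
      if (is.null(anchorSd)) stop("anchor SD required for an sd-based bmr")
      val * anchorSd
    },
    abs = val,
    stop("unknown bmr spec type: ", parts[1]))
}

#' Benchmark time of a fitted model
#'
#' Smallest t > 0 at which the fitted mean departs from its t = 0 value by
#' the benchmark response: closed form for Linear/Power/Hill, guarded
#' bisection (up to \code{tmaxFactor} times the last observed time) for the
#' other families. \code{NA} when the change is never reached (including
#' degenerate flat fits).
#'
#' @param fit a converged \linkS4class{ModelFit}.
#' @param bmr benchmark response (positive log2FC magnitude).
#' @param tmaxFactor search horizon as a multiple of the last observed time.
#' @return time in hours, or \code{NA_real_}.
#' @export
computeBMT <- function(fit, bmr, tmaxFactor = 10) {
  if (!fit@converged) return(NA_real_)
  .bmtFromTheta(fit@family, fit@theta, bmr, tmaxFactor * max(fit@t))
}

#' Bootstrap confidence bounds for a benchmark time
#'
#' Parametric bootstrap: Gaussian residual noise at the fitted residual
#' scale (degrees-of-freedom-corrected, RSS/(n - p)) is added to the fitted
#' curve; each replicate refits and re-runs AIC model selection over the
#' supplied candidate families (so model-selection uncertainty propagates
#' into the bounds) and recomputes the BMT. Bounds are the percentile
#' interval at the requested level, undefined (NA) when more than half of
#' the replicates fail to yield a BMT.
#'
#' @param fit the selected converged \linkS4class{ModelFit}.
#' @param bmr benchmark response.
#' @param level confidence level (default 0.90).
#' @param nBoot bootstrap replicates (default 200).
#' @param seed RNG seed for the bootstrap (restores the caller's RNG state).
#' @param families candidate families re-selected per replicate; default the
#'   selected family only.
#' @param tmaxFactor as in \code{\link{computeBMT}}.
#' @return named numeric: \code{bmtl}, \code{bmtu}.
#' @export
bmtConfidence <- function(fit, bmr, level = 0.90, nBoot = 200L, seed = 1L,
                          families = fit@family, tmaxFactor = 10) {
  if (!fit@converged) return(c(bmtl = NA_real_, bmtu = NA_real_))
  n <- length(fit@y)
  sigma <- sqrt(fit@rss / max(1, n - fit@npar))
  mu <- predictCurve(fit, fit@t)
  bmts <- .withFixedSeed(seed, {
    vapply(seq_len(nBoot), function(b) {
      yb <- mu + stats::rnorm(n, 0, sigma)
      fb <- tryCatch(selectBestFit(fitAllFamilies(fit@t, yb, families)),
                     error = function(e) NULL)
      if (is.null(fb)) return(NA_real_)
      computeBMT(fb, bmr, tmaxFactor)
    }, 0)
  })
  if (mean(is.na(bmts)) > 0.5) return(c(bmtl = NA_real_, bmtu = NA_real_))
  qs <- stats::quantile(bmts, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  c(bmtl = max(qs[1], 0), bmtu = qs[2])
}

#' Per-probe benchmark-time analysis
#'
#' For each requested probe of a \linkS4class{TimeResponseSet}: fit the ten
#' families, select by AIC, invert at the benchmark response, bound by
#' parametric bootstrap (re-selecting per replicate among the families with
#' non-negligible support, delta-AIC < 10), and apply the retention filters.
#'
#' @param trs a \linkS4class{TimeResponseSet}.
#' @param probes probe IDs to model (default all rows; normally the
#'   trend-prefiltered set).
#' @param bmrSpec benchmark-response spec (see \code{\link{resolveBmr}});
#'   the sd form uses each probe's own pooled anchor SD.
#' @param level confidence level for the bootstrap bounds.
#' @param nBoot bootstrap replicates per probe.
#' @param seed base RNG seed (per-probe seeds are derived from it).
#' @param families model families to fit.
#' @param predictLfc also fit the weighted 5-PL and report the predicted
#'   log2FC at the BMT.
#' @param tMin,tMax,ratioMax,fitPMin retention-filter settings (see
#'   \code{\link{applyRetentionFilters}}).
#' @return data.frame: probe, gene, best_model, npar, aic, fitPValue, bmr,
#'   bmt, bmtl, bmtu, ratio, retained (and predicted_lfc_at_bmt when
#'   requested).
#' @export
bmtAnalysis <- function(trs, probes = rownames(trs@response),
                        bmrSpec = "sd:1.349", level = 0.90, nBoot = 200L,
                        seed = 1L, families = tenFamilies(),
                        predictLfc = FALSE,
                        tMin = 0.1, tMax = max(trs@times), ratioMax = 40,
                        fitPMin = 0.1) {
  tv <- trs@times
  anchor <- tv == 0
  rows <- match(probes, rownames(trs@response))
  if (anyNA(rows)) stop("unknown probe(s): ",
                        paste(probes[is.na(rows)], collapse = ", "))
  out <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    y <- trs@response[i, ]
    bmr <- resolveBmr(bmrSpec, anchorSd = stats::sd(y[anchor]))
    fits <- fitAllFamilies(tv, y, families)
    best <- tryCatch(selectBestFit(fits), error = function(e) NULL)
    if (is.null(best)) {
      out[[j]] <- data.frame(probe = probes[j], best_model = NA_character_,
                             npar = NA_integer_, aic = NA_real_,
                             fitPValue = NA_real_, bmr = bmr, bmt = NA_real_,
                             bmtl = NA_real_, bmtu = NA_real_,
                             ratio = NA_real_, stringsAsFactors = FALSE)
      next
    }
    bmt <- computeBMT(best, bmr)
    ci <- c(bmtl = NA_real_, bmtu = NA_real_)
    if (is.finite(bmt)) {
      aics <- vapply(fits, function(f) f@aic, 0)
      supported <- names(aics)[is.finite(aics) & aics < min(aics) + 10]
      ci <- bmtConfidence(best, bmr, level = level, nBoot = nBoot,
                          seed = seed + j, families = supported)
    }
    ratio <- if (all(is.finite(ci)) && ci["bmtl"] > 0)
      unname(ci["bmtu"] / ci["bmtl"]) else NA_real_
    row <- data.frame(probe = probes[j], best_model = best@family,
                      npar = best@npar, aic = best@aic,
                      fitPValue = best@fitPValue, bmr = bmr, bmt = bmt,
                      bmtl = unname(ci["bmtl"]), bmtu = unname(ci["bmtu"]),
                      ratio = ratio, stringsAsFactors = FALSE)
    if (predictLfc)
      row$predicted_lfc_at_bmt <- if (is.finite(bmt))
        fit5plPredict(tv, y, bmt)$prediction else NA_real_
    out[[j]] <- row
  }
  res <- do.call(rbind, out)
  res$gene <- probeToGene(res$probe)
  res <- res[, c("probe", "gene",
                 setdiff(names(res), c("probe", "gene"))), drop = FALSE]
  applyRetentionFilters(res, tMin = tMin, tMax = tMax, ratioMax = ratioMax,
                        fitPMin = fitPMin)
}

#' Apply the benchmark-time retention filters
#'
#' A probe is retained iff its BMT lies inside the tested time window, the
#' confidence-bound ratio BMTU/BMTL is strictly below \code{ratioMax}, and
#' the goodness-of-fit p value is strictly above \code{fitPMin}.
#'
#' @param results data.frame with columns bmt, ratio, fitPValue.
#' @param tMin,tMax reporting window in hours (defaults 0.1 h, i.e. 6 min,
#'   and 24 h).
#' @param ratioMax maximum BMTU/BMTL (exclusive; default 40).
#' @param fitPMin minimum fit p value (exclusive; default 0.1).
#' @return the data.frame with a logical \code{retained} column.
#' @export
applyRetentionFilters <- function(results, tMin = 0.1, tMax = 24,
                                  ratioMax = 40, fitPMin = 0.1) {
  results$retained <- !is.na(results$bmt) &
    results$bmt >= tMin & results$bmt <= tMax &
    !is.na(results$ratio) & results$ratio < ratioMax &
    !is.na(results$fitPValue) & results$fitPValue > fitPMin
  results
}

#' Accumulation curve of benchmark times
#'
#' Step-function ECDF in count units: at each sorted BMT, the cumulative
#' number of probes whose BMT falls at or before that time.
#'
#' @param bmts numeric vector of (retained) BMTs.
#' @return data.frame: time, cumulative (empty for an empty input).
#' @export
accumulationCurve <- function(bmts) {
  bmts <- bmts[is.finite(bmts)]
  if (!length(bmts))
    return(data.frame(time = numeric(), cumulative = integer()))
  s <- sort(bmts)
  u <- unique(s)
  data.frame(time = u,
             cumulative = vapply(u, function(t) sum(s <= t), 0L))
}

#' Earliest-response genes from per-time DEG tables
#'
#' Per gene, the earliest time point at which any of its probes meets the
#' DEG cut; genes are ranked by that time (ascending), ties broken by
#' |log2FC| at the first significant time (descending).
#'
#' @param degTables named list of per-time DEG data.frames (as from
#'   \code{\link{degTimeSeries}}), names being times in hours.
#' @return data.frame: gene, first_time_h, log2FoldChange, direction
#'   ("up"/"down"); empty when nothing is significant.
#' @export
earliestResponseGenes <- function(degTables) {
  times <- as.numeric(names(degTables))
  ord <- order(times)
  recs <- list()
  for (i in ord) {
    tab <- degTables[[i]]
    sig <- tab[tab$significant, , drop = FALSE]
    if (!nrow(sig)) next
    ## strongest probe per gene at this time
    sig <- sig[order(-abs(sig$log2FoldChange)), , drop = FALSE]
    sig <- sig[!duplicated(sig$gene), , drop = FALSE]
    new_genes <- setdiff(sig$gene, names(recs))
    for (g in new_genes) {
      row <- sig[sig$gene == g, ][1, ]
      recs[[g]] <- data.frame(gene = g, first_time_h = times[i],
                              log2FoldChange = row$log2FoldChange,
                              direction = if (row$log2FoldChange > 0) "up" else "down",
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(recs))
    return(data.frame(gene = character(), first_time_h = numeric(),
                      log2FoldChange = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, recs)
  out <- out[order(out$first_time_h, -abs(out$log2FoldChange)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
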