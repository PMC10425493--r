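#' Hypergeometric upper-tail p value
#'
#' P(X >= k) for X ~ Hypergeometric(N, m, n): the chance of drawing at least
#' k members of an m-gene set when sampling n genes without replacement from
#' a background of N.
#'
#' @param k observed overlap.
#' @param m set size within the background.
#' @param n input-list size.
#' @param N background size.
#' @return upper-tail probability.
#' @export
hypergeomTailP <- function(k, m, n, N) {
  if (any(k < 0 | k > pmin(m, n) | m > N | n > N))
    stop("inconsistent hypergeometric parameters")
  stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Over-representation analysis of a DEG gene list
#'
#' Tests each gene set for enrichment of the input list against the panel
#' background with the hypergeometric upper tail. Probe-level inputs are
#' collapsed to unique gene symbols beforehand (a gene counts as significant
#' if any of its probes is); sets are intersected with the background; genes
#' outside the background are dropped from the input. Sets reaching the
#' minimum overlap form the tested family for BH correction (the gate can be
#' moved after correction via \code{gateBeforeFDR = FALSE}). Significance
#' requires overlap >= \code{minOverlap}, p < \code{pThreshold} and
#' q < \code{qThreshold}. Results are sorted by q then p.
#'
#' @param degGenes character vector of significant genes (or probe IDs,
#'   collapsed via \code{\link{probeToGene}} when \code{collapseProbes}).
#' @param collection a \linkS4class{GeneSetCollection}.
#' @param background character vector of all tested genes (the panel).
#' @param minOverlap minimum input/set overlap (default 5).
#' @param pThreshold raw-p cut (default 0.01).
#' @param qThreshold FDR cut (default 0.05).
#' @param gateBeforeFDR apply the overlap gate before BH correction.
#' @param collapseProbes treat inputs as probe IDs and collapse to genes.
#' @return data.frame: set, k, m, n, N, p, q, eligible, significant.
#' @export
runORA <- function(degGenes, collection, background, minOverlap = 5L,
                   pThreshold = 0.01, qThreshold = 0.05,
                   gateBeforeFDR = TRUE, collapseProbes = FALSE) {
  if (!length(background)) stop("empty background")
  if (collapseProbes) {
    degGenes <- probeToGene(degGenes)
    background <- probeToGene(background)
  }
  background <- unique(background)
  deg <- unique(intersect(degGenes, background))
  N <- length(background)
  n <- length(deg)
  sets <- lapply(collection@sets, intersect, background)
  m <- lengths(sets)
  k <- vapply(sets, function(s) length(intersect(s, deg)), 0L)
  p <- hypergeomTailP(k, m, n, N)
  eligible <- k >= minOverlap
  q <- rep(NA_real_, length(p))
  if (gateBeforeFDR) {
    q[eligible] <- adjustBH(p[eligible])
  } else {
    q <- adjustBH(p)
  }
  sig <- eligible & !is.na(q) & p < pThreshold & q < qThreshold
  out <- data.frame(set = names(sets), k = k, m = m, n = n, N = N,
                    p = p, q = q, eligible = eligible, significant = sig,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$q, out$p, method = "radix", na.last = TRUE), , drop = FALSE]
}
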