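#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

TEN_FAMILIES <- c("Linear", "Poly2", "Poly3", "Poly4", "Power", "Hill",
                  "Exp2", "Exp3", "Exp4", "Exp5")

#' Container for a targeted transcriptomics time-course experiment
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment} with the sample
#' descriptors a temporal exposure design needs: compound, concentration,
#' exposure time in hours, replicate index and a vehicle-control flag. Rows
#' are panel probes named \code{GENE_probeid}; the gene symbol (everything
#' before the last underscore) is kept in \code{rowData(x)$gene}.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @export
setClass("TempoSeqExperiment", contains = "SummarizedExperiment")

.validTempoSeq <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts - round(cts)) > 1e-8)) msg <- c(msg, "counts must be integral")
  }
  need <- c("compound", "concentration", "time_h", "replicate", "is_vehicle")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate probe IDs")
  if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample IDs")
  if (length(msg)) msg else TRUE
}
setValidity("TempoSeqExperiment", .validTempoSeq)

#' Compound archetype for the synthetic generator
#'
#' Describes how one simulated compound perturbs the planted pathways: for
#' each responding pathway, a model family from the ten-family catalogue, its
#' parameter vector on log2 fold-change scale, and a direction. An inert
#' archetype (the negative control) has no responses.
#'
#' @slot name compound label.
#' @slot concentration exposure concentration label (metadata only).
#' @slot inert logical; an inert compound plants no responders.
#' @slot responses list of per-pathway specs, each a list with elements
#'   \code{pathway}, \code{family}, \code{theta} (named numeric) and
#'   \code{direction} (+1 up, -1 down).
#' @export
setClass("CompoundArchetype",
  representation(name = "character", concentration = "character",
                 inert = "logical", responses = "list"))

setValidity("CompoundArchetype", function(object) {
  msg <- character()
  if (object@inert && length(object@responses))
    msg <- c(msg, "inert archetype must have zero planted responses")
  for (r in object@responses) {
    if (!all(c("pathway", "family", "theta", "direction") %in% names(r)))
      msg <- c(msg, "each response needs pathway/family/theta/direction")
    else if (!r$family %in% TEN_FAMILIES)
      msg <- c(msg, paste0("unknown family '", r$family, "'"))
    else if (!r$direction %in% c(-1, 1))
      msg <- c(msg, "direction must be +1 or -1")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of a synthetic time-course experiment
#'
#' @slot nProbes number of panel probes.
#' @slot pathways named list of disjoint responder gene sets (gene symbols);
#'   probes not in any set are background.
#' @slot compounds list of \linkS4class{CompoundArchetype}.
#' @slot timePointsH strictly increasing positive exposure times (hours).
#' @slot nReplicates biological replicates per condition per time point.
#' @slot libSizeMean,libSizeCV mean and coefficient of variation of the
#'   log-normal per-sample depth factors (mean 1 keeps counts on panel scale).
#' @slot dispMeanLog,dispSdLog log-normal parameters of the per-gene
#'   negative-binomial dispersion distribution.
#' @slot baselineLog10Range range of log10 baseline expected counts; drawn
#'   log-uniform so the low-count filter has non-trivial behaviour.
#' @slot bmr absolute benchmark response (log2FC) at which analytic true
#'   BMTs are tabulated in the ground truth.
#' @slot seed integer RNG seed.
#' @export
setClass("SimulationConfig",
  representation(nProbes = "integer", pathways = "list", compounds = "list",
                 timePointsH = "numeric", nReplicates = "integer",
                 libSizeMean = "numeric", libSizeCV = "numeric",
                 dispMeanLog = "numeric", dispSdLog = "numeric",
                 baselineLog10Range = "numeric", bmr = "numeric",
                 seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  tp <- object@timePointsH
  if (any(tp <= 0) || is.unsorted(tp, strictly = TRUE))
    msg <- c(msg, "time points must be strictly increasing and positive")
  if (object@nReplicates < 2L) msg <- c(msg, "need >= 2 replicates")
  all_members <- unlist(object@pathways, use.names = FALSE)
  if (anyDuplicated(all_members))
    msg <- c(msg, "responder sets must be pairwise disjoint")
  if (length(all_members) > object@nProbes)
    msg <- c(msg, "responder sets exceed the probe panel")
  if (!all(vapply(object@compounds, is, TRUE, "CompoundArchetype")))
    msg <- c(msg, "compounds must be CompoundArchetype objects")
  if (object@bmr <= 0) msg <- c(msg, "bmr must be positive")
  if (length(msg)) msg else TRUE
})

#' Named gene-set collection
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot description one description string per set.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (is.null(names(object@sets)) && length(object@sets))
    msg <- c(msg, "sets must be named")
  if (any(!lengths(object@sets))) msg <- c(msg, "sets must be non-empty")
  if (length(object@description) != length(object@sets))
    msg <- c(msg, "one description per set required")
  if (length(msg)) msg else TRUE
})

#' Per-replicate log2 fold-change responses over a time grid
#'
#' One row per probe; columns are individual replicate responses. All probes
#' share the per-column time annotation, which includes t = 0 anchor columns
#' built from control-vs-control deviations.
#'
#' @slot response numeric matrix, probes x replicate responses (log2FC).
#' @slot times time in hours of each response column (0 marks the anchor).
#' @slot compound compound label the responses refer to.
#' @export
setClass("TimeResponseSet",
  representation(response = "matrix", times = "numeric", compound = "character"))

setValidity("TimeResponseSet", function(object) {
  msg <- character()
  if (length(object@times) != ncol(object@response))
    msg <- c(msg, "times must annotate every response column")
  if (!any(object@times == 0)) msg <- c(msg, "a t = 0 anchor level is required")
  if (min(table(object@times)) < 2)
    msg <- c(msg, ">= 2 replicates per time level required")
  if (length(msg)) msg else TRUE
})

#' A fitted parametric time-response model
#'
#' @slot family one of Linear, Poly2-4, Power, Hill, Exp2-5.
#' @slot theta named parameter vector.
#' @slot rss residual sum of squares.
#' @slot logLik Gaussian maximum log-likelihood.
#' @slot npar number of mean-function parameters.
#' @slot aic 2(npar + 1) - 2 logLik (the +1 counts the variance).
#' @slot fitPValue likelihood-ratio goodness-of-fit p against the saturated
#'   per-time-means model.
#' @slot converged logical.
#' @slot t,y the fitted data (times / responses).
#' @export
setClass("ModelFit",
  representation(family = "character", theta = "numeric", rss = "numeric",
                 logLik = "numeric", npar = "integer", aic = "numeric",
                 fitPValue = "numeric", converged = "logical",
                 t = "numeric", y = "numeric"))

setMethod("show", "TempoSeqExperiment", function(object) {
  cat("TempoSeqExperiment:", nrow(object), "probes x", ncol(object), "samples\n")
  cd <- SummarizedExperiment::colData(object)
  cat("  compounds:", paste(unique(cd$compound), collapse = ", "), "\n")
  cat("  time points (h):", paste(sort(unique(cd$time_h)), collapse = ", "), "\n")
  cat("  vehicle samples:", sum(cd$is_vehicle), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nProbes, "probes,",
      length(object@compounds), "compounds,",
      length(object@timePointsH), "time points x",
      object@nReplicates, "replicates (seed", paste0(object@seed, ")"), "\n")
  cat("  pathways:", paste(sprintf("%s[%d]", names(object@pathways),
                                   lengths(object@pathways)), collapse = " "), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets)) {
    sz <- lengths(object@sets)
    cat("  sizes:", min(sz), "-", max(sz), "members\n")
  }
})

setMethod("show", "TimeResponseSet", function(object) {
  cat("TimeResponseSet:", nrow(object@response), "probes,",
      length(unique(object@times)), "time levels (",
      sum(object@times == 0), "anchor columns ),", object@compound, "\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit <%s> AIC %.3f fitP %.3g %s\n", object@family,
              object@aic, object@fitPValue,
              if (object@converged) "" else "(not converged)"))
})

#' Accessors for gene-set collections
#' @param x a \linkS4class{GeneSetCollection}.
#' @return \code{geneSets} returns the named list of member vectors.
#' @export
geneSets <- function(x) x@sets
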