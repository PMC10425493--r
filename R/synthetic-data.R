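#' Construct a compound archetype
#'
#' @param name compound label.
#' @param responses list of per-pathway response specs; each element is a
#'   list with \code{pathway}, \code{family}, \code{theta} (named numeric in
#'   the family's parameterization, log2FC scale) and \code{direction}
#'   (+1 up-regulated, -1 down-regulated).
#' @param concentration free-text exposure concentration (metadata only).
#' @param inert logical; \code{TRUE} for a negative-control compound that
#'   plants no responders.
#' @return a \linkS4class{CompoundArchetype}.
#' @export
compoundArchetype <- function(name, responses = list(), concentration = "1 uM",
                              inert = length(responses) == 0L) {
  new("CompoundArchetype", name = name, concentration = concentration,
      inert = inert, responses = responses)
}

#' Default planted pathway gene sets
#'
#' Three disjoint stress-response gene sets named after the programmes whose
#' temporal activation the pipeline is built to detect (Nrf2 oxidative
#' stress, unfolded protein response, metal stress), seeded with canonical
#' member genes and padded with synthetic symbols to the requested size.
#'
#' @param size members per pathway.
#' @return named list of gene-symbol vectors.
#' @export
defaultPathways <- function(size = 20L) {
  seeds <- list(
    Nrf2_oxidative_stress = c("HMOX1", "GCLM", "NQO1", "SLC7A11", "SQSTM1",
                              "TXNRD1", "FTL", "MAFG"),
    UPR = c("ASNS", "ATF4", "DDIT3", "DNAJB9", "HSPA5", "PPP1R15A", "TRIB3",
            "XBP1", "ATF3", "ATF6"),
    metal_stress = c("MT1E", "MT1F", "MT1G", "MT1M", "MT1X", "MT2A"))
  lapply(stats::setNames(names(seeds), names(seeds)), function(p) {
    g <- seeds[[p]]
    if (length(g) < size) {
      pad <- sprintf("%sX%02d", toupper(substr(p, 1, 4)), seq_len(size - length(g)))
      g <- c(g, pad)
    }
    g[seq_len(min(size, length(g)))]
  })
}

#' Default compound archetypes
#'
#' Five archetypes mirroring a typical stress-response screening panel: a
#' metalloid-like compound activating all three pathways early, a drug-like
#' compound with sequential activation (metal stress first, UPR late), an
#' ER-stressor with early UPR activation, a mitochondrial toxicant with late
#' UPR activation plus early down-regulation, and an inert negative control.
#' Hill onsets (parameter \code{k}, hours) encode the planted activation
#' order; plateaus (\code{v}, log2FC) exceed the DEG fold-change cut so
#' responders are detectable at some tested time.
#'
#' @return list of \linkS4class{CompoundArchetype}.
#' @export
defaultArchetypes <- function() {
  hill <- function(v, k, n = 3) c(gamma = 0, v = v, k = k, n = n)
  list(
    compoundArchetype("metalloid_early", list(
      list(pathway = "metal_stress", family = "Hill",
           theta = hill(4, 2.5), direction = 1),
      list(pathway = "Nrf2_oxidative_stress", family = "Hill",
           theta = hill(3.5, 3), direction = 1),
      list(pathway = "UPR", family = "Hill",
           theta = hill(2.5, 4), direction = 1)), "10 uM"),
    compoundArchetype("sequential_drug", list(
      list(pathway = "metal_stress", family = "Hill",
           theta = hill(2.5, 3), direction = 1),
      list(pathway = "UPR", family = "Exp4",
           theta = c(a = 1, b = 0.08, c = 3.6), direction = 1)), "50 uM"),
    compoundArchetype("er_stressor", list(
      list(pathway = "UPR", family = "Hill",
           theta = hill(3, 5), direction = 1)), "300 nM"),
    compoundArchetype("mito_toxicant", list(
      list(pathway = "UPR", family = "Hill",
           theta = hill(2.5, 13, n = 4), direction = 1),
      list(pathway = "Nrf2_oxidative_stress", family = "Hill",
           theta = hill(2, 5), direction = -1)), "5 nM"),
    compoundArchetype("inert_control", concentration = "1 uM"))
}

#' Configure a synthetic time-course experiment
#'
#' Defaults reproduce the shape of a targeted-panel temporal study: a
#' 3565-probe panel, nine exposure time points (1-24 h), three biological
#' replicates per condition with matched vehicle controls at every time
#' point, negative-binomial counts with log-normal per-gene dispersion, and
#' log-uniform baselines spanning three orders of magnitude so the low-count
#' filter has non-trivial behaviour.
#'
#' @param nProbes panel size.
#' @param pathways named list of disjoint responder gene sets.
#' @param compounds list of \linkS4class{CompoundArchetype}.
#' @param timePointsH strictly increasing exposure times (hours).
#' @param nReplicates replicates per condition per time point.
#' @param libSizeMean,libSizeCV log-normal depth-factor mean and CV.
#' @param dispMeanLog,dispSdLog log-normal dispersion distribution (on the
#'   log scale); the default centres per-gene dispersion near 0.08.
#' @param baselineLog10Range log10 range of baseline expected counts.
#' @param bmr absolute benchmark response (log2FC) used for analytic true
#'   BMTs in the ground-truth table.
#' @param seed RNG seed.
#' @return a \linkS4class{SimulationConfig}.
#' @export
simulationConfig <- function(nProbes = 3565L,
                             pathways = defaultPathways(),
                             compounds = defaultArchetypes(),
                             timePointsH = c(1, 2, 4, 6, 8, 12, 16, 20, 24),
                             nReplicates = 3L,
                             libSizeMean = 1, libSizeCV = 0.2,
                             dispMeanLog = log(0.08), dispSdLog = 0.4,
                             baselineLog10Range = c(-0.7, 3.3),
                             bmr = 1, seed = 1L) {
  new("SimulationConfig", nProbes = as.integer(nProbes), pathways = pathways,
      compounds = compounds, timePointsH = as.numeric(timePointsH),
      nReplicates = as.integer(nReplicates), libSizeMean = libSizeMean,
      libSizeCV = libSizeCV, dispMeanLog = dispMeanLog, dispSdLog = dispSdLog,
      baselineLog10Range = as.numeric(baselineLog10Range), bmr = bmr,
      seed = as.integer(seed))
}

#' Analytic benchmark time of a planted response curve
#'
#' Smallest t > 0 at which |f(t) - f(0)| equals the benchmark response, via
#' closed form for Linear/Power/Hill and guarded bisection for the other
#' families; \code{NA} if the change never reaches \code{bmr} on
#' \code{(0, tmax]}.
#'
#' @param family one of \code{tenFamilies()}.
#' @param theta named parameter vector.
#' @param bmr benchmark response (> 0), log2FC units.
#' @param tmax search horizon (hours) for the non-closed-form families.
#' @return time in hours, or \code{NA_real_}.
#' @export
trueBmt <- function(family, theta, bmr, tmax = 200) {
  if (!family %in% TEN_FAMILIES) stop("invalid family name: ", family)
  .bmtFromTheta(family, theta, bmr, tmax)
}

## Per-gene jitter of an archetype response: onset and plateau vary gene to
## gene (log-normal), preserving family and direction. The plateau floor
## keeps every responder detectable at the DEG cut (|log2FC| > 1).
.jitterTheta <- function(family, theta, kJitter, vJitter) {
  th <- theta
  if (family == "Hill") {
    th["v"] <- max(1.2, th["v"] * vJitter) * sign(theta["v"])
    th["k"] <- th["k"] * kJitter
  } else if (family == "Exp4" || family == "Exp5") {
    th["b"] <- th["b"] / kJitter
    th["c"] <- 1 + max(1.2, (th["c"] - 1) * vJitter) / abs(th["a"])
  } else if (family == "Linear") {
    th["beta1"] <- th["beta1"] * vJitter
  } else if (family == "Power") {
    th["beta"] <- th["beta"] * vJitter
  } else if (family == "Exp2" || family == "Exp3") {
    th["b"] <- th["b"] * vJitter
  }
  th
}

#' Simulate a targeted-panel temporal count experiment
#'
#' Draws negative-binomial counts with mean
#' \code{s_j * q_g * 2^(f_g(t_j))} for treated samples (\code{f_g = 0} for
#' vehicle samples and non-responders), where \code{s_j} is a log-normal
#' depth factor and \code{q_g} a log-uniform baseline. Every compound gets
#' matched vehicle samples at every time point. Responder curves are the
#' archetype's family with per-gene jittered onset/plateau; the returned
#' ground truth records each planted curve and its analytic BMT at the
#' configured benchmark response.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with elements \code{experiment}
#'   (\linkS4class{TempoSeqExperiment}), \code{truth} (data.frame: compound,
#'   probe, gene, pathway, responder, family, direction, theta list-column,
#'   true_bmt, max_abs_lfc) and \code{config}.
#' @export
simulateExperiment <- function(config) {
  validObject(config)
  set.seed(config@seed)
  tp <- config@timePointsH
  nrep <- config@nReplicates

  ## probe panel: pathway genes first, background fill
  path_genes <- unlist(config@pathways, use.names = FALSE)
  gene2path <- rep(names(config@pathways), lengths(config@pathways))
  n_bg <- config@nProbes - length(path_genes)
  genes <- c(path_genes, sprintf("BG%04d", seq_len(n_bg)))
  pathway_of <- c(gene2path, rep(NA_character_, n_bg))
  probes <- sprintf("%s_%d", genes, 10000L + seq_along(genes))

  q <- 10^stats::runif(config@nProbes, config@baselineLog10Range[1],
                       config@baselineLog10Range[2])
  alpha <- stats::rlnorm(config@nProbes, config@dispMeanLog, config@dispSdLog)

  sdlog <- sqrt(log(1 + config@libSizeCV^2))
  meanlog <- log(config@libSizeMean) - sdlog^2 / 2

  count_blocks <- list(); meta_blocks <- list(); truth_blocks <- list()
  for (cmp in config@compounds) {
    ## planted log2FC curves, f(t) anchored so f(0) = 0
    fmat <- matrix(0, config@nProbes, length(tp))
    truth <- data.frame(compound = cmp@name, probe = probes, gene = genes,
                        pathway = pathway_of, responder = FALSE,
                        family = NA_character_, direction = 0,
                        true_bmt = NA_real_, max_abs_lfc = 0,
                        stringsAsFactors = FALSE)
    truth$theta <- vector("list", config@nProbes)
    if (!cmp@inert) {
      for (resp in cmp@responses) {
        idx <- which(pathway_of == resp$pathway)
        for (i in idx) {
          th <- .jitterTheta(resp$family, resp$theta,
                             kJitter = stats::rlnorm(1, 0, 0.25),
                             vJitter = stats::rlnorm(1, 0, 0.2))
          mu0 <- evalFamily(resp$family, th, 0)
          f <- resp$direction * (evalFamily(resp$family, th, tp) - mu0)
          fmat[i, ] <- f
          truth$responder[i] <- TRUE
          truth$family[i] <- resp$family
          truth$direction[i] <- resp$direction
          truth$theta[[i]] <- th
          truth$true_bmt[i] <- trueBmt(resp$family, th, config@bmr,
                                       tmax = 10 * max(tp))
          truth$max_abs_lfc[i] <- max(abs(f))
        }
      }
    }
    truth_blocks[[cmp@name]] <- truth

    for (vehicle in c(FALSE, TRUE)) {
      for (it in seq_along(tp)) {
        for (r in seq_len(nrep)) {
          sid <- sprintf("%s_%s_t%02dh_r%d", cmp@name,
                         if (vehicle) "veh" else "trt", round(tp[it]), r)
          s_j <- stats::rlnorm(1, meanlog, sdlog)
          mu <- s_j * q * if (vehicle) 1 else 2^fmat[, it]
          cnt <- stats::rnbinom(config@nProbes, mu = mu, size = 1 / alpha)
          count_blocks[[sid]] <- cnt
          meta_blocks[[sid]] <- data.frame(
            sample_id = sid, compound = cmp@name,
            concentration = if (vehicle) "0.1% DMSO" else cmp@concentration,
            time_h = tp[it], replicate = r, is_vehicle = vehicle,
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  counts <- do.call(cbind, count_blocks)
  storage.mode(counts) <- "integer"
  rownames(counts) <- probes
  meta <- do.call(rbind, meta_blocks)
  rownames(meta) <- meta$sample_id
  se <- tempoSeqExperiment(counts, meta)
  truth_all <- do.call(rbind, truth_blocks)
  rownames(truth_all) <- NULL
  list(experiment = se, truth = truth_all, config = config)
}

#' Write a simulated experiment as plain-text fixture files
#'
#' Writes the count matrix and sample metadata as TSV, the planted pathways
#' as GMT, the ground-truth table as TSV (theta serialized as JSON), and a
#' JSON sidecar echoing the seed and configuration. All files round-trip
#' through the package's readers.
#'
#' @param sim result of \code{\link{simulateExperiment}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeFixture <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  se <- sim$experiment
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             gmt = file.path(dir, "pathways.gmt"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  writeCounts(SummarizedExperiment::assay(se, "counts"), paths["counts"])
  writeSampleInfo(as.data.frame(SummarizedExperiment::colData(se)),
                  paths["metadata"])
  cfg <- sim$config
  writeGMT(new("GeneSetCollection", sets = cfg@pathways,
               description = rep("planted", length(cfg@pathways))),
           paths["gmt"])
  truth <- sim$truth
  truth$theta <- vapply(truth$theta, function(th)
    if (is.null(th)) "" else as.character(jsonlite::toJSON(as.list(th),
                                                           auto_unbox = TRUE,
                                                           digits = NA)),
    character(1))
  utils::write.table(truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(seed = cfg@seed, nProbes = cfg@nProbes,
                            timePointsH = cfg@timePointsH,
                            nReplicates = cfg@nReplicates,
                            bmr = cfg@bmr,
                            compounds = vapply(cfg@compounds,
                                               function(x) x@name, "")),
                       paths["config"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
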