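#' Build a TempoSeqExperiment from a count matrix and sample metadata
#'
#' @param counts integer matrix, probes (rows, named \code{GENE_probeid}) x
#'   samples (columns).
#' @param metadata data.frame with columns \code{sample_id}, \code{compound},
#'   \code{concentration}, \code{time_h}, \code{replicate},
#'   \code{is_vehicle}; one row per count-matrix sample.
#' @return a \linkS4class{TempoSeqExperiment}.
#' @export
tempoSeqExperiment <- function(counts, metadata) {
  if (!all(colnames(counts) %in% metadata$sample_id))
    stop("every count-matrix sample needs exactly one metadata row")
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  rd <- S4Vectors::DataFrame(gene = probeToGene(rownames(counts)),
                             row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(metadata, row.names = metadata$sample_id),
    rowData = rd)
  new("TempoSeqExperiment", se)
}

#' Map probe IDs to gene symbols
#'
#' Probe IDs follow the \code{GENE_probeid} convention; the gene symbol is
#' everything before the final underscore (symbols may themselves contain
#' underscores, the trailing numeric suffix may not).
#'
#' @param probes character vector of probe IDs.
#' @return character vector of gene symbols.
#' @export
probeToGene <- function(probes) sub("_[^_]*$", "", probes)

.checkCountMatrix <- function(m) {
  if (anyDuplicated(rownames(m))) stop("duplicate probe IDs")
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs")
  if (any(m < 0)) stop("negative counts")
  if (any(abs(m - round(m)) > 1e-8)) stop("non-integer counts")
  storage.mode(m) <- "integer"
  m
}

#' Read and write probe count matrices
#'
#' TSV layout: header row of sample IDs, first column \code{probe_id}.
#' MTX layout: Matrix Market coordinate file (1-based indices) with
#' \code{<path>.rows} / \code{<path>.cols} sidecar files holding probe and
#' sample IDs, one per line.
#'
#' @param path file to read or write.
#' @param format \code{"tsv"} or \code{"mtx"}; inferred from the extension
#'   when missing.
#' @return \code{readCounts} returns an integer matrix with probe rownames.
#' @export
readCounts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (colnames(df)[1] != "probe_id") stop("malformed header: first column must be 'probe_id'")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$probe_id
  } else {
    mm <- as.matrix(Matrix::readMM(path))
    rownames(mm) <- readLines(paste0(path, ".rows"))
    colnames(mm) <- readLines(paste0(path, ".cols"))
    m <- mm
  }
  .checkCountMatrix(m)
}

#' @rdname readCounts
#' @param counts integer matrix to write.
#' @export
writeCounts <- function(counts, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  if (format == "tsv") {
    df <- data.frame(probe_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rows"))
    writeLines(colnames(counts), paste0(path, ".cols"))
  }
  invisible(path)
}

#' Read and write sample metadata tables
#'
#' @param path TSV file with columns \code{sample_id}, \code{compound},
#'   \code{concentration}, \code{time_h}, \code{replicate},
#'   \code{is_vehicle}.
#' @return \code{readSampleInfo} returns a data.frame.
#' @export
readSampleInfo <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "compound", "concentration", "time_h", "replicate",
            "is_vehicle")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  df$is_vehicle <- as.logical(df$is_vehicle)
  df
}

#' @rdname readSampleInfo
#' @param metadata data.frame to write.
#' @export
writeSampleInfo <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then tab-separated member symbols.
#' Duplicate members within a line are collapsed.
#'
#' @param path GMT file.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(new("GeneSetCollection", sets = stats::setNames(list(), character()),
               description = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-c(1, 2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  new("GeneSetCollection", sets = sets,
      description = vapply(fields, `[`, "", 2L))
}

#' @rdname readGMT
#' @param collection a \linkS4class{GeneSetCollection} to write.
#' @export
writeGMT <- function(collection, path) {
  lines <- mapply(function(nm, desc, members)
    paste(c(nm, desc, members), collapse = "\t"),
    names(collection@sets), collection@description, collection@sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Select treated and matched control samples for one compound
#'
#' Treated samples are the compound's non-vehicle rows at the requested
#' times; controls are vehicle rows at the same times (the compound's own
#' matched vehicles when present, otherwise the shared vehicle samples).
#'
#' @param metadata sample metadata data.frame.
#' @param compound compound label.
#' @param timePoints times (hours) to keep; default all of the compound's.
#' @return list with data.frames \code{treated} and \code{control}.
#' @export
selectSamples <- function(metadata, compound, timePoints = NULL) {
  if (!compound %in% metadata$compound) stop("compound absent: ", compound)
  trt <- metadata[metadata$compound == compound & !metadata$is_vehicle, ,
                  drop = FALSE]
  ctl <- metadata[metadata$compound == compound & metadata$is_vehicle, ,
                  drop = FALSE]
  if (!nrow(ctl)) ctl <- metadata[metadata$is_vehicle, , drop = FALSE]
  if (is.null(timePoints)) timePoints <- sort(unique(trt$time_h))
  for (t in timePoints) {
    if (!any(trt$time_h == t)) stop("no treated samples at time ", t, " h")
    if (!any(ctl$time_h == t)) stop("no control samples at time ", t, " h")
  }
  list(treated = trt[trt$time_h %in% timePoints, , drop = FALSE],
       control = ctl[ctl$time_h %in% timePoints, , drop = FALSE])
}

#' Remove low-read-count probes
#'
#' Retains probes whose row sum across the selected samples (treated plus
#' control of one compound) reaches the threshold. The comparison is
#' inclusive (row sum >= threshold). Intended to be re-run per compound.
#'
#' @param counts count matrix (probes x samples).
#' @param samples character vector of sample IDs defining the row-sum scope.
#' @param threshold minimum row sum; default 100.
#' @return the filtered count matrix.
#' @export
filterLowCounts <- function(counts, samples = colnames(counts), threshold = 100) {
  if (!length(samples)) stop("empty sample selection")
  miss <- setdiff(samples, colnames(counts))
  if (length(miss)) stop("samples not in matrix: ", paste(miss, collapse = ", "))
  keep <- rowSums(counts[, samples, drop = FALSE]) >= threshold
  counts[keep, , drop = FALSE]
}
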