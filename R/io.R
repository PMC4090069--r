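#' @include AllClasses.R
NULL

#' Read a weight matrix from disk
#'
#' Two plain-text formats are supported. \code{dense_csv}: N rows of N
#' comma-separated reals, no header. \code{edge_tsv}: a tab-separated edge
#' list with header \code{src\\tdst\\tweight} and 0-based neuron ids;
#' absent edges are zero, duplicate edges are an error.
#'
#' @param path file to read.
#' @param format "dense_csv" or "edge_tsv".
#' @param n number of neurons for edge lists (default: largest id + 1).
#' @param wMax upper weight bound of the resulting matrix.
#' @return A validated [WeightMatrix-class]. Diagonal entries within 1e-12
#'   of zero are snapped to zero; anything larger is an error.
#' @export
readWeightMatrix <- function(path, format = c("dense_csv", "edge_tsv"),
                             n = NULL, wMax = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "dense_csv") {
    df <- utils::read.csv(path, header = FALSE)
    w <- as.matrix(df)
    if (nrow(w) != ncol(w)) {
      stop(sprintf("matrix not square: %d rows, %d columns", nrow(w),
                   ncol(w)))
    }
    storage.mode(w) <- "double"
  } else {
    df <- utils::read.delim(path)
    if (!all(c("src", "dst", "weight") %in% names(df))) {
      stop("edge list must have columns src, dst, weight")
    }
    if (anyDuplicated(df[, c("src", "dst")])) {
      k <- which(duplicated(df[, c("src", "dst")]))[1]
      stop(sprintf("duplicate edge %d -> %d", df$src[k], df$dst[k]))
    }
    if (is.null(n)) n <- max(df$src, df$dst) + 1
    if (any(df$src < 0 | df$dst < 0 | df$src >= n | df$dst >= n)) {
      stop("edge ids must lie in [0, n)")
    }
    w <- matrix(0, n, n)
    # edge src -> dst lands in row dst (postsynaptic), column src
    w[cbind(df$dst + 1, df$src + 1)] <- df$weight
  }
  d <- diag(w)
  if (any(abs(d) > 1e-12)) {
    k <- which(abs(d) > 1e-12)[1]
    stop(sprintf("nonzero diagonal entry at [%d, %d]: %g", k, k, d[k]))
  }
  diag(w) <- 0
  WeightMatrix(w, wMax = wMax)
}

#' Write a weight matrix as dense CSV
#'
#' @param W a [WeightMatrix-class].
#' @param path output file (N rows of N comma-separated reals, no header).
#' @return \code{path}, invisibly.
#' @export
writeWeightMatrix <- function(W, path) {
  stopifnot(is(W, "WeightMatrix"))
  utils::write.table(W@weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Convert a result object to a plain list
#'
#' Used for JSON serialisation; field names are stable across versions.
#'
#' @param object a [SymmetryReport-class], [NullStatistics-class],
#'   [MotifSummary-class] or [SpectralSummary-class].
#' @return named list of scalar fields.
#' @export
setGeneric("reportAsList", function(object) standardGeneric("reportAsList"))

#' @rdname reportAsList
#' @export
setMethod("reportAsList", "SymmetryReport", function(object) {
  list(type = "symmetry_report", s = object@s, n_counted = object@nCounted,
       n_zero_pairs = object@nZeroPairs, z_score = object@zScore,
       p_value = object@pValue, verdict = object@verdict,
       alpha = object@alpha)
})

#' @rdname reportAsList
#' @export
setMethod("reportAsList", "NullStatistics", function(object) {
  list(type = "null_statistics", family = object@spec@family,
       prune_p = object@spec@pruneP, mu_z = object@muZ, var_z = object@varZ,
       mu_s = object@muS, var_s = object@varS,
       expected_counted_pairs = object@expectedPairs,
       n_neurons = object@nNeurons, method = object@method,
       n_networks = object@nNetworks, seed = object@seed)
})

#' @rdname reportAsList
#' @export
setMethod("reportAsList", "MotifSummary", function(object) {
  list(type = "motif_summary", z_threshold = object@zThreshold,
       frac_unidirectional = object@fracUnidirectional,
       frac_bidirectional = object@fracBidirectional,
       n_counted = object@nCounted)
})

#' @rdname reportAsList
#' @export
setMethod("reportAsList", "SpectralSummary", function(object) {
  list(type = "spectral_summary", fraction_complex = object@fractionComplex,
       n_eigenvalues = object@nEigenvalues, tolerance = object@tolerance)
})

#' Write a result object as JSON
#'
#' Serialises via [reportAsList()] with stable keys and 12 significant
#' digits; the file round-trips through [readReport()].
#'
#' @param object a result object with a [reportAsList()] method.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(object, path) {
  jsonlite::write_json(reportAsList(object), path, auto_unbox = TRUE,
                       digits = I(12), na = "null", null = "null")
  invisible(path)
}

#' Read a JSON report written by [writeReport()]
#'
#' @param path file to read.
#' @return named list of fields.
#' @export
readReport <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' One-line TSV summary of a symmetry report
#'
#' @param object a [SymmetryReport-class].
#' @param path output file; a header line plus one value line.
#' @return \code{path}, invisibly.
#' @export
writeReportTsv <- function(object, path) {
  stopifnot(is(object, "SymmetryReport"))
  df <- as.data.frame(reportAsList(object)[-1])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
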