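#' @import methods
NULL

.validSpace <- c("intensity", "log2")

#' AbundanceMatrix: a samples x proteins abundance matrix with missing entries
#'
#' The central data container of the package. Rows are samples, columns are
#' proteins; missing entries are encoded as `NA` in the `values` slot (the
#' missing mask is therefore `is.na(abundances(x))`). A `space` tag records
#' whether the values are raw intensities (strictly positive) or log2
#' intensities (any real).
#'
#' @slot values numeric matrix with unique sample ids as rownames and unique
#'   protein ids as colnames; `NA` marks missing entries.
#' @slot space `"intensity"` or `"log2"`.
#'
#' @seealso [AbundanceMatrix()] for the constructor, [abundances()],
#'   [missingMask()], [sampleIds()], [proteinIds()], [spaceTag()].
#' @export
setClass("AbundanceMatrix",
  slots = c(values = "matrix", space = "character"))

setValidity("AbundanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must carry sample ids (rownames) and protein ids (colnames)")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, "duplicate sample ids")
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, "duplicate protein ids")
  }
  if (length(object@space) != 1L || !object@space %in% .validSpace)
    msg <- c(msg, "'space' must be one of \"intensity\", \"log2\"")
  if (is.numeric(v) && identical(object@space, "intensity")) {
    obs <- v[!is.na(v)]
    if (length(obs) && any(obs <= 0))
      msg <- c(msg, "intensity-space values must be strictly positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceMatrix
#'
#' @param values numeric matrix, samples in rows and proteins in columns;
#'   `NA` encodes missing entries.
#' @param sampleIds,proteinIds optional id vectors; default to the dimnames of
#'   `values`, or to `sample_1..m` / `protein_1..n` when absent.
#' @param space `"intensity"` (default) or `"log2"`.
#' @return an [AbundanceMatrix-class] object.
#' @examples
#' m <- matrix(c(4, NA, 8, 16), nrow = 2)
#' AbundanceMatrix(m)
#' @export
AbundanceMatrix <- function(values, sampleIds = NULL, proteinIds = NULL,
                            space = "intensity") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sampleIds))
    sampleIds <- if (!is.null(rownames(values))) rownames(values)
                 else paste0("sample_", seq_len(nrow(values)))
  if (is.null(proteinIds))
    proteinIds <- if (!is.null(colnames(values))) colnames(values)
                  else paste0("protein_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sampleIds), as.character(proteinIds))
  new("AbundanceMatrix", values = values, space = space)
}

#' ExternalScores: complete per-sample covariate table
#'
#' Per-sample external measurements (for example pathology grades) used to
#' derive cross-modal sample similarity. Must be complete (no missing values)
#' and aligned by sample id to the abundance matrix it accompanies.
#'
#' @slot scores numeric matrix, samples in rows (unique rownames), one or more
#'   score columns; no `NA` allowed.
#' @export
setClass("ExternalScores", slots = c(scores = "matrix"))

setValidity("ExternalScores", function(object) {
  s <- object@scores
  msg <- character()
  if (!is.numeric(s)) msg <- c(msg, "'scores' must be numeric")
  if (ncol(s) < 1L) msg <- c(msg, "at least one score column is required")
  if (anyNA(s)) msg <- c(msg, "scores must be complete (no missing entries)")
  if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
    msg <- c(msg, "unique sample ids required as rownames")
  if (length(msg)) msg else TRUE
})

#' Construct an ExternalScores table
#'
#' @param scores numeric matrix or data.frame of per-sample scores.
#' @param sampleIds optional sample ids (default rownames).
#' @return an [ExternalScores-class] object.
#' @export
ExternalScores <- function(scores, sampleIds = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (!is.null(sampleIds)) rownames(scores) <- as.character(sampleIds)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("score_", seq_len(ncol(scores)))
  new("ExternalScores", scores = scores)
}

#' GroundTruth: held-out true values at masked/injected positions
#'
#' Records the evaluation index set Omega: for each hidden entry, the sample
#' id, protein id and the true value that was removed, together with the space
#' the values live in. Produced by the injection/masking operations and
#' consumed by the performance measures.
#'
#' @slot sampleIds,proteinIds character vectors (one entry per hidden cell).
#' @slot values numeric vector of true values at those cells.
#' @slot space `"intensity"` or `"log2"`.
#' @export
setClass("GroundTruth",
  slots = c(sampleIds = "character", proteinIds = "character",
            values = "numeric", space = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  n <- length(object@values)
  if (n < 1L) msg <- c(msg, "evaluation set Omega must be nonempty")
  if (length(object@sampleIds) != n || length(object@proteinIds) != n)
    msg <- c(msg, "sampleIds, proteinIds and values must be aligned")
  if (anyDuplicated(paste(object@sampleIds, object@proteinIds, sep = "\r")))
    msg <- c(msg, "duplicate positions in Omega")
  if (length(object@space) != 1L || !object@space %in% .validSpace)
    msg <- c(msg, "invalid space tag")
  if (length(msg)) msg else TRUE
})

#' Construct a GroundTruth evaluation set
#'
#' @param sampleIds,proteinIds character vectors naming the hidden cells.
#' @param values the true values at those cells.
#' @param space `"intensity"` or `"log2"`.
#' @return a [GroundTruth-class] object.
#' @export
GroundTruth <- function(sampleIds, proteinIds, values, space) {
  new("GroundTruth", sampleIds = as.character(sampleIds),
      proteinIds = as.character(proteinIds),
      values = as.numeric(values), space = space)
}

#' ImputationResult: a completed matrix plus provenance
#'
#' @slot completed numeric matrix with no missing entries; agrees exactly with
#'   the input on all observed positions (imputers never alter observed data).
#' @slot method name of the imputation method.
#' @slot params list of parameters and diagnostics (iterations, traces, ...).
#' @slot filled two-column integer matrix of (sample, protein) indices that
#'   were imputed; equals the input's missing set.
#' @slot space `"intensity"` or `"log2"`.
#' @export
setClass("ImputationResult",
  slots = c(completed = "matrix", method = "character", params = "list",
            filled = "matrix", space = "character"))

setValidity("ImputationResult", function(object) {
  msg <- character()
  if (anyNA(object@completed))
    msg <- c(msg, "completed matrix still contains missing entries")
  if (ncol(object@filled) != 2L && nrow(object@filled) > 0L)
    msg <- c(msg, "'filled' must be a two-column index matrix")
  if (length(object@space) != 1L || !object@space %in% .validSpace)
    msg <- c(msg, "invalid space tag")
  if (length(msg)) msg else TRUE
})

#' ScalingParams: invertible per-unit location/scale parameters
#'
#' @slot mode `"sample_normalize"` (per-sample median centering) or
#'   `"protein_standardize"` (per-protein zero-mean unit-population-sd).
#' @slot center,scale numeric vectors (one entry per sample or protein).
#' @export
setClass("ScalingParams",
  slots = c(mode = "character", center = "numeric", scale = "numeric"))

setValidity("ScalingParams", function(object) {
  msg <- character()
  if (!object@mode %in% c("sample_normalize", "protein_standardize"))
    msg <- c(msg, "unknown scaling mode")
  if (any(object@scale <= 0)) msg <- c(msg, "scale entries must be strictly positive")
  if (length(object@center) != length(object@scale))
    msg <- c(msg, "center and scale must be aligned")
  if (length(msg)) msg else TRUE
})

#' SimilarityContext: per-sample neighborhoods for fused regularization
#'
#' @slot neighborhoods list, one integer vector of neighbor sample indices per
#'   sample (self excluded, at most `t` entries).
#' @slot similarities list of cosine similarities aligned to `neighborhoods`.
#' @slot source `"self"` (from the abundance matrix) or `"external"`.
#' @slot t neighborhood size bound.
#' @slot sampleIds sample ids the indices refer to.
#' @export
setClass("SimilarityContext",
  slots = c(neighborhoods = "list", similarities = "list", source = "character",
            t = "numeric", sampleIds = "character"))

setValidity("SimilarityContext", function(object) {
  msg <- character()
  m <- length(object@sampleIds)
  if (length(object@neighborhoods) != m || length(object@similarities) != m)
    msg <- c(msg, "one neighborhood per sample required")
  for (i in seq_len(m)) {
    nb <- object@neighborhoods[[i]]
    if (length(nb) > object@t) { msg <- c(msg, "neighborhood exceeds t"); break }
    if (i %in% nb) { msg <- c(msg, "a sample cannot neighbor itself"); break }
  }
  if (!object@source %in% c("self", "external"))
    msg <- c(msg, "source must be 'self' or 'external'")
  if (length(msg)) msg else TRUE
})

#' FactorModel: low-rank factors with regularization metadata
#'
#' Result of [fitRMF()] / [fitFRMF()]: factor matrices `A` (samples x rank)
#' and `S` (rank x proteins), the regularization weights, and the per-iteration
#' objective trace of the gradient descent.
#'
#' @slot A,S numeric factor matrices.
#' @slot rank factorization rank.
#' @slot lambdaA,lambdaS,alphaFused nonnegative regularization weights.
#' @slot objective numeric objective trace (one value per iteration).
#' @slot converged logical.
#' @slot step final step size after any halvings.
#' @export
setClass("FactorModel",
  slots = c(A = "matrix", S = "matrix", rank = "numeric",
            lambdaA = "numeric", lambdaS = "numeric", alphaFused = "numeric",
            objective = "numeric", converged = "logical", step = "numeric"))

setValidity("FactorModel", function(object) {
  msg <- character()
  if (ncol(object@A) != nrow(object@S))
    msg <- c(msg, "inner dimensions of A and S disagree")
  if (any(!is.finite(object@objective)))
    msg <- c(msg, "objective trace must be finite")
  if (any(c(object@lambdaA, object@lambdaS, object@alphaFused) < 0))
    msg <- c(msg, "regularization weights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: a generated archetype-mixture dataset with known factors
#'
#' @slot ATrue m x k mixing matrix, rows on the probability simplex.
#' @slot STrue k x n nonnegative archetype profiles.
#' @slot markerSets per-archetype lists of marker protein indices (each marker
#'   protein is expressed in exactly one archetype).
#' @slot noiseSigma log-scale sd of the multiplicative noise.
#' @slot complete the complete (no missing) intensity matrix.
#' @export
setClass("SyntheticTruth",
  slots = c(ATrue = "matrix", STrue = "matrix", markerSets = "list",
            noiseSigma = "numeric", complete = "AbundanceMatrix"))

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  if (any(object@ATrue < 0) || any(object@STrue < 0))
    msg <- c(msg, "factors must be nonnegative")
  rs <- rowSums(object@ATrue)
  if (any(abs(rs - 1) > 1e-8))
    msg <- c(msg, "rows of ATrue must sum to 1")
  if (length(msg)) msg else TRUE
})

#' CamModel: convex-analysis-of-mixtures fit
#'
#' @slot k selected archetype count (argmin of the description-length scores).
#' @slot A m x k nonnegative mixing matrix, rows summing to 1.
#' @slot S k x n nonnegative archetype profile matrix.
#' @slot markerSets per-archetype protein index lists (disjoint).
#' @slot mdlByK named numeric vector of description-length scores per
#'   candidate k.
#' @slot nMG total marker count of the selected model.
#' @export
setClass("CamModel",
  slots = c(k = "numeric", A = "matrix", S = "matrix", markerSets = "list",
            mdlByK = "numeric", nMG = "numeric"))

setValidity("CamModel", function(object) {
  msg <- character()
  if (any(object@A < 0) || any(object@S < 0))
    msg <- c(msg, "A and S must be entrywise nonnegative")
  mk <- unlist(object@markerSets)
  if (anyDuplicated(mk)) msg <- c(msg, "marker sets must be disjoint")
  if (length(object@mdlByK)) {
    best <- as.numeric(names(object@mdlByK)[which.min(object@mdlByK)])
    if (best != object@k) msg <- c(msg, "k must be the argmin of mdlByK")
  }
  if (object@nMG != length(mk)) msg <- c(msg, "nMG must equal the total marker count")
  if (length(msg)) msg else TRUE
})
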