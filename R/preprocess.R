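#' Filter proteins by missing rate
#'
#' Retains exactly the proteins whose missing fraction is at most `maxRate`
#' (the common proteomics rule: drop proteins with missing rates strictly
#' above 80%). Protein order is preserved; the ids of removed proteins are
#' attached as `attr(result, "removed")`.
#'
#' @param x an [AbundanceMatrix-class].
#' @param maxRate maximum tolerated missing fraction, default 0.8.
#' @return the filtered [AbundanceMatrix-class]; errors if no protein survives.
#' @export
filterByMissingRate <- function(x, maxRate = 0.8) {
  .assertAbundanceMatrix(x)
  if (ncol(x@values) == 0L) stop("empty matrix", call. = FALSE)
  rate <- colMeans(is.na(x@values))
  keep <- rate <= maxRate
  if (!any(keep)) stop("no proteins survive filter", call. = FALSE)
  removed <- colnames(x@values)[!keep]
  out <- x[, keep]
  attr(out, "removed") <- removed
  out
}

#' Log2-transform an intensity matrix
#'
#' Observed entries become `log2(value)`; the missing mask is unchanged.
#'
#' @param x an intensity-space [AbundanceMatrix-class] (all observed values
#'   strictly positive).
#' @return a log2-space [AbundanceMatrix-class].
#' @seealso [inverseLog2()]
#' @export
log2Transform <- function(x) {
  .assertAbundanceMatrix(x)
  .assertSpace(x, "intensity", "log2Transform")
  obs <- x@values[!is.na(x@values)]
  if (any(obs <= 0))
    stop("nonpositive observed value: clean or mark as missing upstream",
         call. = FALSE)
  AbundanceMatrix(log2(x@values), space = "log2")
}

#' Invert the log2 transform
#'
#' @param x a log2-space [AbundanceMatrix-class].
#' @return the entrywise `2^value` intensity matrix; round-trips with
#'   [log2Transform()] within 1e-12 relative tolerance.
#' @export
inverseLog2 <- function(x) {
  .assertAbundanceMatrix(x)
  .assertSpace(x, "log2", "inverseLog2")
  AbundanceMatrix(2^x@values, space = "intensity")
}

#' Protein-wise standardization
#'
#' Centers and scales each protein so its observed values have mean 0 and
#' population (divide-by-n) standard deviation 1, matching the population
#' variance convention of [nrmse()]. Proteins with zero observed variance get
#' their scale clamped to 1 with a warning.
#'
#' @param x a log2-space [AbundanceMatrix-class]; each protein should have at
#'   least one observed value.
#' @return a list with elements `matrix` (standardized
#'   [AbundanceMatrix-class]) and `params` ([ScalingParams-class]).
#' @seealso [invertScaling()]
#' @export
standardizeProteins <- function(x) {
  .assertAbundanceMatrix(x)
  v <- x@values
  center <- colMeans(v, na.rm = TRUE)
  scale <- apply(v, 2L, function(col) popSD(col[!is.na(col)]))
  degen <- !is.finite(scale) | scale <= 0
  if (any(degen)) {
    warning(sprintf("%d protein(s) with zero observed variance: scale clamped to 1",
                    sum(degen)))
    scale[degen] <- 1
  }
  std <- sweep(sweep(v, 2L, center, "-"), 2L, scale, "/")
  params <- new("ScalingParams", mode = "protein_standardize",
                center = stats::setNames(center, colnames(v)),
                scale = stats::setNames(scale, colnames(v)))
  list(matrix = AbundanceMatrix(std, space = x@space), params = params)
}

#' Sample-wise normalization (median centering)
#'
#' Subtracts each sample's observed median, a robust per-sample location
#' adjustment in log space.
#'
#' @param x a log2-space [AbundanceMatrix-class]; each sample needs at least
#'   one observed value.
#' @return a list with elements `matrix` and `params`, as
#'   [standardizeProteins()].
#' @export
normalizeSamples <- function(x) {
  .assertAbundanceMatrix(x)
  v <- x@values
  center <- apply(v, 1L, stats::median, na.rm = TRUE)
  norm <- sweep(v, 1L, center, "-")
  params <- new("ScalingParams", mode = "sample_normalize",
                center = stats::setNames(center, rownames(v)),
                scale = stats::setNames(rep(1, nrow(v)), rownames(v)))
  list(matrix = AbundanceMatrix(norm, space = x@space), params = params)
}

#' Invert a standardization or normalization
#'
#' Applies the inverse of [standardizeProteins()] or [normalizeSamples()] to a
#' matrix (or to the completed grid of an [ImputationResult-class]), restoring
#' the original location and scale within 1e-10 relative tolerance on observed
#' entries.
#'
#' @param x an [AbundanceMatrix-class] or [ImputationResult-class].
#' @param params the [ScalingParams-class] returned by the forward operation.
#' @return an object of the same class as `x`.
#' @export
invertScaling <- function(x, params) {
  undo <- function(v) {
    if (params@mode == "protein_standardize")
      sweep(sweep(v, 2L, params@scale[colnames(v)], "*"),
            2L, params@center[colnames(v)], "+")
    else
      sweep(v, 1L, params@center[rownames(v)], "+")
  }
  if (is(x, "ImputationResult")) {
    new("ImputationResult", completed = undo(x@completed), method = x@method,
        params = x@params, filled = x@filled, space = x@space)
  } else {
    .assertAbundanceMatrix(x)
    AbundanceMatrix(undo(x@values), space = x@space)
  }
}
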