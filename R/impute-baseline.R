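#' Half-minimum imputation
#'
#' Fills every missing entry of a protein with half the minimum observed
#' abundance of that protein, a standard below-detection-limit (MNAR) fill.
#' `halfIn` controls what gets halved:
#'
#' * `"intensity"` (default): the minimum is halved on the intensity scale;
#'   on a log2 matrix this subtracts 1 from the observed log2 minimum, which
#'   is the usual definition of the half-minimum rule.
#' * `"stored"`: the stored value itself is halved, whatever the space (in
#'   log2 space, `min/2` rather than `min - 1`).
#'
#' @param x an [AbundanceMatrix-class]; every protein with a missing value
#'   must have at least one observed value (filter upstream).
#' @param halfIn `"intensity"` or `"stored"`, see above.
#' @return an [ImputationResult-class].
#' @export
imputeMin2 <- function(x, halfIn = c("intensity", "stored")) {
  halfIn <- match.arg(halfIn)
  .assertAbundanceMatrix(x)
  v <- x@values
  .checkNoEmptyProteins(v)
  minv <- apply(v, 2L, function(col) min(col, na.rm = TRUE))
  fill <- if (halfIn == "stored" || identical(x@space, "intensity"))
    minv / 2 else minv - 1
  completed <- v
  for (j in which(colSums(is.na(v)) > 0L))
    completed[is.na(v[, j]), j] <- fill[j]
  .makeResult(x, completed, "min2")
}

#' Protein-mean imputation
#'
#' Fills every missing entry of a protein with the arithmetic mean of that
#' protein's observed values.
#'
#' @inheritParams imputeMin2
#' @return an [ImputationResult-class].
#' @export
imputeMean <- function(x) {
  .assertAbundanceMatrix(x)
  v <- x@values
  .checkNoEmptyProteins(v)
  fill <- colMeans(v, na.rm = TRUE)
  completed <- v
  for (j in which(colSums(is.na(v)) > 0L))
    completed[is.na(v[, j]), j] <- fill[j]
  .makeResult(x, completed, "mean")
}

.checkNoEmptyProteins <- function(v) {
  if (any(colSums(!is.na(v)) == 0L))
    stop("cannot impute empty protein: filter all-missing proteins upstream",
         call. = FALSE)
}

# KNN fill engine operating on rows: a missing entry (i, j) is filled from the
# rows that observe column j, weighted by inverse distance. Distances are
# Euclidean over mutually observed columns, divided by sqrt(shared count) so
# rows with different overlap sizes are comparable. Ties among equidistant
# neighbors are broken by smaller row index. Rows without any valid neighbor
# fall back to the column's observed mean, with a message.
.knnFillRows <- function(v, k, epsilon = 1e-9, fallback = c("colmean", "rowmean")) {
  fallback <- match.arg(fallback)
  m <- nrow(v)
  O <- !is.na(v)
  Z <- v; Z[!O] <- 0
  Om <- O * 1
  sq <- (Z * Z) %*% t(Om)            # sq[i,i'] = sum_{j obs both} x_i^2
  cross <- Z %*% t(Z)                # restricted to mutually observed
  shared <- Om %*% t(Om)
  D2 <- sq + t(sq) - 2 * cross
  D2[D2 < 0] <- 0
  D <- sqrt(D2) / sqrt(shared)       # NaN/Inf where shared == 0
  D[shared == 0] <- Inf
  diag(D) <- Inf

  colMean <- colMeans(v, na.rm = TRUE)
  rowMean <- rowMeans(v, na.rm = TRUE)
  completed <- v
  nFallback <- 0L
  for (j in which(colSums(is.na(v)) > 0L)) {
    donors <- which(O[, j])
    for (i in which(is.na(v[, j]))) {
      d <- D[i, donors]
      ok <- is.finite(d)
      if (!any(ok)) {
        completed[i, j] <- if (fallback == "colmean") colMean[j] else rowMean[i]
        nFallback <- nFallback + 1L
        next
      }
      cand <- donors[ok]
      d <- d[ok]
      ord <- order(d, cand)          # tie-break: smaller index first
      use <- ord[seq_len(min(k, length(ord)))]
      w <- 1 / (d[use] + epsilon)
      completed[i, j] <- sum(w * v[cand[use], j]) / sum(w)
    }
  }
  if (nFallback > 0L)
    message(sprintf("KNN: %d entr%s without any candidate neighbor filled by mean fallback",
                    nFallback, if (nFallback == 1L) "y" else "ies"))
  completed
}

#' Sample-wise k-nearest-neighbour imputation
#'
#' A missing entry (i, j) is filled from the k samples nearest to sample i
#' (among samples observing protein j) as a weighted average of their values
#' of protein j, with weights inversely proportional to the normalized
#' Euclidean distance over mutually observed proteins.
#'
#' @param x an [AbundanceMatrix-class].
#' @param k neighbor count, at least 1; fewer candidates than k uses all
#'   candidates.
#' @return an [ImputationResult-class].
#' @export
imputeSWKNN <- function(x, k = 5) {
  .assertAbundanceMatrix(x)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  completed <- .knnFillRows(x@values, k)
  .makeResult(x, completed, "swknn", list(k = k))
}

#' Protein-wise k-nearest-neighbour imputation
#'
#' Symmetric to [imputeSWKNN()] with the roles of proteins and samples
#' exchanged: neighbors are proteins (nearest in normalized Euclidean
#' distance over mutually observed samples) and a missing entry is filled
#' from neighboring proteins' values in the same sample. The input is
#' expected to be protein-standardized (see [standardizeProteins()]); the
#' caller de-standardizes the result.
#'
#' @inheritParams imputeSWKNN
#' @return an [ImputationResult-class] in the (standardized) input space.
#' @export
imputePWKNN <- function(x, k = 5) {
  .assertAbundanceMatrix(x)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  completed <- t(.knnFillRows(t(x@values), k, fallback = "rowmean"))
  .makeResult(x, completed, "pwknn", list(k = k))
}
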