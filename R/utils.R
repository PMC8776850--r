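# internal helpers shared across modules

# population (divide-by-n) variance / sd, the convention used by NRMSE and
# protein standardization throughout the package
popVar <- function(x) mean((x - mean(x))^2)
popSD <- function(x) sqrt(popVar(x))

.assertAbundanceMatrix <- function(x, arg = "matrix") {
  if (!is(x, "AbundanceMatrix"))
    stop(sprintf("'%s' must be an AbundanceMatrix", arg), call. = FALSE)
  invisible(x)
}

.assertComplete <- function(x, what = "this operation") {
  if (anyNA(x@values))
    stop(sprintf("%s requires a complete matrix (no missing entries)", what),
         call. = FALSE)
  invisible(x)
}

.assertSpace <- function(x, space, what) {
  if (!identical(spaceTag(x), space))
    stop(sprintf("%s expects a matrix in %s space, got %s",
                 what, space, spaceTag(x)), call. = FALSE)
  invisible(x)
}

# build an ImputationResult from an input matrix and a fully filled values grid
.makeResult <- function(x, completed, method, params = list()) {
  miss <- which(is.na(x@values), arr.ind = TRUE)
  dimnames(completed) <- dimnames(x@values)
  # observed entries are never altered, by construction
  completed[!is.na(x@values)] <- x@values[!is.na(x@values)]
  new("ImputationResult", completed = completed, method = method,
      params = params, filled = miss, space = x@space)
}

# GroundTruth from positions (2-col index matrix) of a complete matrix
.truthAt <- function(x, pos) {
  GroundTruth(sampleIds = rownames(x@values)[pos[, 1L]],
              proteinIds = colnames(x@values)[pos[, 2L]],
              values = x@values[pos], space = x@space)
}

# indices of truth entries inside a (possibly filtered) matrix; errors on
# ids absent from the matrix
.truthIndex <- function(truth, mat) {
  i <- match(truth@sampleIds, rownames(mat))
  j <- match(truth@proteinIds, colnames(mat))
  if (anyNA(i) || anyNA(j))
    stop("ground-truth ids not found in the matrix", call. = FALSE)
  cbind(i, j)
}

#' Restrict a GroundTruth to a protein subset
#'
#' Used after protein filtering: entries whose protein was removed are dropped
#' from the evaluation set.
#'
#' @param truth a [GroundTruth-class].
#' @param proteins character vector of protein ids to keep.
#' @return a [GroundTruth-class] restricted to `proteins`.
#' @export
subsetTruth <- function(truth, proteins) {
  keep <- truth@proteinIds %in% proteins
  if (!any(keep))
    stop("no ground-truth entries survive the protein subset", call. = FALSE)
  GroundTruth(truth@sampleIds[keep], truth@proteinIds[keep],
              truth@values[keep], truth@space)
}

#' Convert a GroundTruth between intensity and log2 space
#'
#' @param truth a [GroundTruth-class].
#' @param space target space, `"intensity"` or `"log2"`.
#' @return the converted [GroundTruth-class].
#' @export
convertTruth <- function(truth, space = c("log2", "intensity")) {
  space <- match.arg(space)
  if (identical(truth@space, space)) return(truth)
  v <- if (space == "log2") log2(truth@values) else 2^truth@values
  GroundTruth(truth@sampleIds, truth@proteinIds, v, space)
}

# nonnegative least squares ||C x - d||, x >= 0, by the Lawson-Hanson active
# set algorithm; tolerant of rank-deficient / near-degenerate designs (returns
# the best iterate instead of erroring when the active set cycles)
.nnls <- function(C, d) {
  d <- as.numeric(d)
  n <- ncol(C)
  x <- numeric(n)
  P <- logical(n)
  w <- as.numeric(crossprod(C, d))
  tol <- 10 * .Machine$double.eps * max(abs(C)) * max(dim(C))
  outer <- 0L
  while (any(!P & w > tol) && outer < 30L * n) {
    outer <- outer + 1L
    cand <- which(!P)
    P[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      coef <- qr.coef(qr(C[, P, drop = FALSE]), d)
      coef[is.na(coef)] <- 0
      s[P] <- coef
      if (all(s[P] > tol)) { x <- s; break }
      drop <- which(P & s <= tol & x > s)
      if (!length(drop)) { x <- pmax(s, 0); break }
      alpha <- min(x[drop] / (x[drop] - s[drop]))
      x <- x + alpha * (s - x)
      P <- P & x > tol
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- as.numeric(crossprod(C, d - C %*% x))
  }
  x
}

# nonnegative least squares with a soft sum-to-one constraint (convex weights):
# augment with a heavily weighted row of ones
.convexWeights <- function(V, target, weight = NULL) {
  # V: k x m matrix of vertices (rows), target: m-vector
  if (is.null(weight)) weight <- 100 * max(1, max(abs(target)))
  C <- rbind(t(V), rep(weight, nrow(V)))
  d <- c(target, weight)
  .nnls(C, d)
}
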