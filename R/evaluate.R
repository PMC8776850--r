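#' Root-mean-square error at the held-out positions
#'
#' `sqrt(sum((imputed - true)^2) / |Omega|)` over the evaluation set Omega.
#'
#' @param truth a [GroundTruth-class].
#' @param result an [ImputationResult-class] in the same space.
#' @return the scalar RMSE.
#' @seealso [nrmse()], [proteinNRMSE()], [sor()]
#' @export
rmse <- function(truth, result) {
  .checkEvalPair(truth, result)
  idx <- .truthIndex(truth, result@completed)
  sqrt(mean((result@completed[idx] - truth@values)^2))
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the population (divide-by-n) standard deviation of the
#' true values at Omega; with this convention, imputing every entry with
#' `mean(X_Omega)` gives NRMSE = 1 exactly.
#'
#' @inheritParams rmse
#' @return the scalar NRMSE; errors when `|Omega| < 2` or the true values
#'   have zero variance.
#' @export
nrmse <- function(truth, result) {
  .checkEvalPair(truth, result)
  if (length(truth@values) < 2L)
    stop("NRMSE undefined: |Omega| must be at least 2", call. = FALSE)
  s2 <- popVar(truth@values)
  if (s2 <= 0) stop("NRMSE undefined: zero variance of the true values",
                    call. = FALSE)
  rmse(truth, result) / sqrt(s2)
}

.checkEvalPair <- function(truth, result) {
  if (!is(truth, "GroundTruth")) stop("'truth' must be a GroundTruth", call. = FALSE)
  if (!is(result, "ImputationResult"))
    stop("'result' must be an ImputationResult", call. = FALSE)
  if (!identical(truth@space, result@space))
    stop(sprintf("space mismatch: truth in %s, result in %s",
                 truth@space, result@space), call. = FALSE)
}

#' Per-protein NRMSE
#'
#' NRMSE computed protein by protein over each protein's share of Omega.
#' Proteins with fewer than two held-out entries or zero variance of the
#' true values are excluded (returned in `attr(result, "excluded")`).
#'
#' @inheritParams rmse
#' @return a named numeric vector (one NRMSE per evaluable protein).
#' @export
proteinNRMSE <- function(truth, result) {
  .checkEvalPair(truth, result)
  idx <- .truthIndex(truth, result@completed)
  err2 <- (result@completed[idx] - truth@values)^2
  split2 <- split(seq_along(truth@values), truth@proteinIds)
  out <- numeric(0)
  excluded <- character(0)
  for (p in names(split2)) {
    sel <- split2[[p]]
    if (length(sel) < 2L) { excluded <- c(excluded, p); next }
    s2 <- popVar(truth@values[sel])
    if (s2 <= 0) { excluded <- c(excluded, p); next }
    out[p] <- sqrt(mean(err2[sel]) / s2)
  }
  if (length(excluded))
    message(sprintf("proteinNRMSE: %d protein(s) excluded (too few entries or zero variance)",
                    length(excluded)))
  attr(out, "excluded") <- excluded
  out
}

#' Sum of ranks across methods
#'
#' For each protein, methods are ranked by their per-protein NRMSE in
#' ascending order (rank 1 = best, ties get the average rank); each method's
#' SOR is the sum of its ranks over the shared protein set. The vectors must
#' be aligned on an identical protein set. By construction
#' `sum(SOR) = P * M * (M + 1) / 2` for `P` proteins and `M` methods.
#'
#' @param perMethod a named list of per-protein NRMSE vectors (from
#'   [proteinNRMSE()]), one per method, aligned on the same proteins.
#' @return a named numeric vector of SOR values, one per method.
#' @export
sor <- function(perMethod) {
  if (length(perMethod) < 2L)
    stop("SOR needs at least two methods", call. = FALSE)
  prot <- names(perMethod[[1L]])
  for (v in perMethod)
    if (!identical(sort(names(v)), sort(prot)))
      stop("misaligned protein sets across methods", call. = FALSE)
  tab <- vapply(perMethod, function(v) v[prot], numeric(length(prot)))
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list(prot, names(perMethod)))
  ranks <- t(apply(tab, 1L, rank, ties.method = "average"))
  stats::setNames(colSums(ranks), names(perMethod))
}

#' Align per-protein NRMSE vectors for SOR
#'
#' Restricts each method's vector to the proteins evaluable by every method
#' (the aligned subset), preserving rank-sum conservation.
#'
#' @param perMethod a named list of per-protein NRMSE vectors.
#' @return the list restricted to the common proteins.
#' @export
alignProteinNRMSE <- function(perMethod) {
  common <- Reduce(intersect, lapply(perMethod, names))
  if (!length(common))
    stop("no protein evaluable by every method", call. = FALSE)
  lapply(perMethod, function(v) v[common])
}

#' Sweep a parameter grid for one imputation method
#'
#' Evaluates every grid point on held-out ground truth and returns the
#' argmin of the criterion together with the full table. Ties keep the first
#' grid point in order, with a message.
#'
#' @param method method name understood by [imputeWithMethod()].
#' @param grid a data.frame, one row per parameter combination (columns are
#'   parameter names).
#' @param x the [AbundanceMatrix-class] with missing values (log2 space for
#'   all methods except the CAM family).
#' @param truth the [GroundTruth-class] in the evaluation space.
#' @param criterion `"nrmse"` (default) or `"rmse"`.
#' @return a list with `best` (the winning parameter row), `table` (the grid
#'   with a criterion column) and `results` omitted for compactness.
#' @export
sweepParameters <- function(method, grid, x, truth, criterion = c("nrmse", "rmse")) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(grid) || nrow(grid) == 0L)
    stop("empty grid", call. = FALSE)
  metric <- if (criterion == "nrmse") nrmse else rmse
  vals <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    res <- imputeWithMethod(x, method, params)
    vals[g] <- metric(truth, res)
  }
  best <- which.min(vals)
  if (sum(vals == vals[best]) > 1L)
    message("sweepParameters: tie broken by grid order")
  table <- cbind(grid, stats::setNames(data.frame(vals), criterion))
  list(best = grid[best, , drop = FALSE], table = table)
}
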