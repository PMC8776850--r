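# Convex analysis of mixtures (CAM): geometric detection of the vertices of
# the scatter simplex of protein vectors, identifying archetypes, their
# marker proteins and the nonnegative mixture factorization X ~ A S, with the
# archetype count chosen by a minimum-description-length score. Imputation
# runs in original intensity space.

#' Description-length score for a CAM factorization
#'
#' Scores a candidate factorization `X ~ A %*% S` with `k` archetypes. The
#' penalty terms are `((k - 1) * m / 2) * log(nMG)` (mixing proportions,
#' estimated from the `nMG` marker proteins) and `(k * n / 2) * log(m)`
#' (archetype profiles, estimated from the `m` samples). Two forms of the
#' fit term are available:
#'
#' * `"scaled"` (default): `(m * n / 2) * log(RSS / (m * n))`, the Gaussian
#'   description length of the residuals. This is the form used by
#'   [camFit()] for order selection: its fit term is commensurate with the
#'   penalty terms, so the score trades goodness of fit against model
#'   complexity.
#' * `"unscaled"`: `(1 / 2) * log(RSS)`. In this form the fit term is
#'   bounded by a few tens of nats while the penalties grow like `n * m`,
#'   so the score is effectively monotone in `k`; it is provided for
#'   reference and diagnostics, not for order selection.
#'
#' A zero residual is floored at 1e-12 with a warning.
#'
#' @param x a complete intensity-space [AbundanceMatrix-class].
#' @param A m x k nonnegative mixing matrix.
#' @param S k x n nonnegative archetype profile matrix.
#' @param nMG total marker protein count (at least 1).
#' @param form `"scaled"` or `"unscaled"`, see above.
#' @return the scalar score.
#' @export
computeMDL <- function(x, A, S, nMG, form = c("scaled", "unscaled")) {
  form <- match.arg(form)
  .assertAbundanceMatrix(x)
  v <- x@values
  if (nMG < 1) stop("nMG must be at least 1", call. = FALSE)
  if (nrow(A) != nrow(v) || ncol(S) != ncol(v) || ncol(A) != nrow(S))
    stop("factor shapes inconsistent with the matrix", call. = FALSE)
  k <- ncol(A)
  m <- nrow(v); n <- ncol(v)
  rss <- sum((v - A %*% S)^2)
  if (rss <= 0) {
    warning("zero residual floored at 1e-12")
    rss <- 1e-12
  }
  fit <- if (form == "scaled") (m * n / 2) * log(rss / (m * n)) else 0.5 * log(rss)
  fit + ((k - 1) * m / 2) * log(nMG) + (k * n / 2) * log(m)
}

# residual of reconstructing every row of `centers` as a convex combination
# (nonnegative weights summing to 1) of the rows of `vertices`
.convexResidual <- function(centers, vertices) {
  tot <- 0
  for (i in seq_len(nrow(centers))) {
    w <- .convexWeights(vertices, centers[i, ])
    tot <- tot + sum((as.numeric(t(vertices) %*% w) - centers[i, ])^2)
  }
  tot
}

# greedy forward ordering of vertex centers, computed once up to kmax and
# shared across all candidate k (the greedy choice is nested)
.greedyVertexOrder <- function(centers, kmax) {
  nc <- nrow(centers)
  chosen <- integer()
  for (step in seq_len(kmax)) {
    best <- NULL; bestRes <- Inf
    for (cand in setdiff(seq_len(nc), chosen)) {
      res <- .convexResidual(centers, centers[c(chosen, cand), , drop = FALSE])
      if (res < bestRes) { bestRes <- res; best <- cand }
    }
    chosen <- c(chosen, best)
  }
  chosen
}

# single-swap local refinement of a chosen vertex set (at most `maxPasses`)
.swapRefine <- function(centers, chosen, maxPasses = 3L) {
  nc <- nrow(centers)
  k <- length(chosen)
  curRes <- .convexResidual(centers, centers[chosen, , drop = FALSE])
  for (pass in seq_len(maxPasses)) {
    improved <- FALSE
    for (pos in seq_len(k)) {
      for (cand in setdiff(seq_len(nc), chosen)) {
        trial <- chosen
        trial[pos] <- cand
        res <- .convexResidual(centers, centers[trial, , drop = FALSE])
        if (res < curRes - 1e-12) {
          chosen <- trial; curRes <- res; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(vertices = chosen, residual = curRes)
}

#' Fit a convex-analysis-of-mixtures model
#'
#' Pipeline: (1) normalize each protein's sample vector to unit sum, placing
#' the proteins on the scatter simplex; (2) cluster the protein points with
#' seeded k-means into `nClusters` groups; (3) for each candidate archetype
#' count `k`, select the `k` cluster centers that minimize the residual of
#' reconstructing all centers as convex combinations of the selected ones
#' (greedy selection plus single-swap refinement); (4) call proteins close to
#' the selected vertices (within-cluster distance below the `marginQuantile`
#' quantile) the markers of that archetype; (5) estimate the mixing matrix
#' `A` from marker means on the original intensity scale (columns rescaled
#' so rows of `A` sum to 1) and the profiles `S` by nonnegative least squares
#' per protein; (6) score each `k` with [computeMDL()] and keep the argmin.
#'
#' @param x a complete, strictly positive intensity-space
#'   [AbundanceMatrix-class].
#' @param kCandidates integer vector of candidate archetype counts; all must
#'   be below `nClusters`.
#' @param nClusters number of k-means clusters of protein points (default 50,
#'   reduce for small matrices; must be below the protein count).
#' @param marginQuantile quantile of within-cluster distances below which a
#'   protein is called a marker (default 0.1).
#' @param seed integer seed (controls k-means).
#' @param form description-length form passed to [computeMDL()].
#' @return a [CamModel-class].
#' @export
camFit <- function(x, kCandidates = 2:5, nClusters = 50, marginQuantile = 0.1,
                   seed = 1, form = "scaled") {
  .assertAbundanceMatrix(x)
  .assertComplete(x, "camFit")
  .assertSpace(x, "intensity", "camFit")
  v <- x@values
  m <- nrow(v); n <- ncol(v)
  kCandidates <- sort(unique(as.integer(kCandidates)))
  if (max(kCandidates) >= nClusters)
    stop("max(kCandidates) must be below nClusters", call. = FALSE)
  if (nClusters >= n)
    stop("nClusters must be below the protein count", call. = FALSE)

  # proteins as points on the scatter simplex
  colSum <- colSums(v)
  pts <- t(v) / colSum                     # n x m, rows sum to 1

  set.seed(seed)
  km <- stats::kmeans(pts, centers = nClusters, nstart = 5, iter.max = 100)
  centers <- km$centers

  greedy <- .greedyVertexOrder(centers, max(kCandidates))
  fits <- list()
  scores <- numeric()
  for (k in kCandidates) {
    sel <- .swapRefine(centers, greedy[seq_len(k)])
    vert <- centers[sel$vertices, , drop = FALSE]
    if (anyDuplicated(round(vert, 12))) {
      warning(sprintf("candidate k = %d skipped: degenerate (duplicate) vertex set", k))
      next
    }
    # markers: proteins closest to their vertex center
    markerSets <- vector("list", k)
    for (a in seq_len(k)) {
      cl <- sel$vertices[a]
      members <- which(km$cluster == cl)
      d <- sqrt(rowSums((pts[members, , drop = FALSE] -
                           matrix(centers[cl, ], length(members), m,
                                  byrow = TRUE))^2))
      cut <- stats::quantile(d, marginQuantile)
      mk <- members[d <= cut]
      if (!length(mk)) mk <- members[which.min(d)]
      markerSets[[a]] <- sort(mk)
    }
    names(markerSets) <- paste0("archetype_", seq_len(k))
    nMG <- length(unlist(markerSets))

    # mixing matrix from marker means on the original intensity scale,
    # columns rescaled so rows of A sum to 1
    Araw <- vapply(markerSets, function(mk)
      rowMeans(v[, mk, drop = FALSE]), numeric(m))
    d <- .nnls(Araw, rep(1, m))
    if (any(d <= 0)) d[d <= 0] <- 1 / pmax(colMeans(Araw)[d <= 0], 1e-12)
    A <- Araw %*% diag(d, k, k)
    A <- A / rowSums(A)

    # archetype profiles by nonnegative least squares per protein
    S <- matrix(0, k, n)
    for (j in seq_len(n)) S[, j] <- .nnls(A, v[, j])
    dimnames(A) <- list(rownames(v), names(markerSets))
    dimnames(S) <- list(names(markerSets), colnames(v))

    score <- computeMDL(x, A, S, nMG, form = form)
    fits[[as.character(k)]] <- list(A = A, S = S, markerSets = markerSets,
                                    nMG = nMG)
    scores[as.character(k)] <- score
  }
  if (!length(fits)) stop("all candidate k were degenerate", call. = FALSE)
  bestK <- names(scores)[which.min(scores)]
  best <- fits[[bestK]]
  new("CamModel", k = as.numeric(bestK), A = best$A, S = best$S,
      markerSets = best$markerSets, mdlByK = scores, nMG = best$nMG)
}

# positivity floor for reconstructed fills (keeps imputed intensities > 0)
.positiveFill <- function(fill, protObsMin) {
  bad <- fill <= 0
  if (any(bad)) {
    message(sprintf("CAM: %d nonpositive reconstruction(s) floored at half the protein minimum",
                    sum(bad)))
    fill[bad] <- protObsMin[bad] / 2
  }
  fill
}

#' CAM imputation from the fully observed proteins
#'
#' Fits [camFit()] on the submatrix of proteins without any missing value,
#' then, for every protein with missingness, estimates its profile by
#' nonnegative least squares against the mixing matrix over its observed
#' samples only and fills the missing entries with the reconstruction.
#' Proteins observed in fewer samples than archetypes fall back to a
#' protein-mean fill, with a message.
#'
#' @param x an intensity-space [AbundanceMatrix-class] with missing entries;
#'   at least `10 * max(kCandidates)` proteins must be fully observed.
#' @inheritParams camFit
#' @return an [ImputationResult-class] in intensity space.
#' @export
camImputeComplete <- function(x, kCandidates = 2:5, nClusters = 50,
                              marginQuantile = 0.1, seed = 1) {
  .assertAbundanceMatrix(x)
  .assertSpace(x, "intensity", "camImputeComplete")
  v <- x@values
  full <- which(colSums(is.na(v)) == 0L)
  if (length(full) < 10 * max(kCandidates))
    stop("need at least 10 * max(kCandidates) fully observed proteins",
         call. = FALSE)
  model <- camFit(x[, full], kCandidates = kCandidates, nClusters = nClusters,
                  marginQuantile = marginQuantile, seed = seed)
  A <- model@A
  k <- model@k
  completed <- v
  nFallback <- 0L
  for (j in which(colSums(is.na(v)) > 0L)) {
    obs <- which(!is.na(v[, j]))
    missRows <- which(is.na(v[, j]))
    if (length(obs) < k) {
      completed[missRows, j] <- mean(v[obs, j])
      nFallback <- nFallback + 1L
      next
    }
    s <- .nnls(A[obs, , drop = FALSE], v[obs, j])
    fill <- as.numeric(A[missRows, , drop = FALSE] %*% s)
    completed[missRows, j] <- .positiveFill(fill, rep(min(v[obs, j]),
                                                      length(missRows)))
  }
  if (nFallback > 0L)
    message(sprintf("camImputeComplete: %d protein(s) observed in fewer samples than k filled by protein mean",
                    nFallback))
  res <- .makeResult(x, completed, "cam_complete",
                     list(k = k, kCandidates = kCandidates))
  res@params$model <- model
  res
}

#' Hybrid CAM imputation with a low-rank initializer
#'
#' The hybrid strategy: (1) log2-transform; (2) impute with the named
#' low-rank method (SVT or NIPALS, on the protein-standardized log matrix);
#' (3) invert to the original intensity space; (4) fit [camFit()] on the
#' completed intensity matrix; (5) replace only the originally missing
#' entries with the archetype reconstruction `A %*% S` at those positions.
#'
#' @param x an intensity-space [AbundanceMatrix-class] with missing entries.
#' @param initializer `"svt"` or `"nipals"`.
#' @inheritParams camFit
#' @param rank rank for the NIPALS initializer (default `max(kCandidates)`).
#' @param initArgs further arguments passed to the initializer.
#' @return an [ImputationResult-class] in intensity space.
#' @export
camImputeHybrid <- function(x, initializer = c("svt", "nipals"),
                            kCandidates = 2:5, nClusters = 50,
                            marginQuantile = 0.1, seed = 1, rank = NULL,
                            initArgs = list()) {
  initializer <- match.arg(initializer)
  .assertAbundanceMatrix(x)
  .assertSpace(x, "intensity", "camImputeHybrid")
  lg <- log2Transform(x)
  std <- standardizeProteins(lg)
  init <- if (initializer == "svt") {
    do.call(imputeSVT, c(list(std$matrix), initArgs))
  } else {
    if (is.null(rank)) rank <- max(kCandidates)
    do.call(imputeNIPALS, c(list(std$matrix, rank = rank), initArgs))
  }
  initLog <- invertScaling(init, std$params)
  initIntensity <- AbundanceMatrix(2^initLog@completed, space = "intensity")

  model <- camFit(initIntensity, kCandidates = kCandidates,
                  nClusters = nClusters, marginQuantile = marginQuantile,
                  seed = seed)
  rec <- model@A %*% model@S
  v <- x@values
  completed <- v
  miss <- is.na(v)
  protMin <- apply(v, 2L, function(col) min(col, na.rm = TRUE))
  for (j in which(colSums(miss) > 0L)) {
    rows <- which(miss[, j])
    completed[rows, j] <- .positiveFill(rec[rows, j],
                                        rep(protMin[j], length(rows)))
  }
  res <- .makeResult(x, completed, paste0("cam_", initializer),
                     list(k = model@k, initializer = initializer))
  res@params$model <- model
  res
}

#' Serialize a CamModel
#'
#' Writes the mixing matrix and profile matrix as CSV tables plus a JSON
#' sidecar with the selected k, the marker sets and the per-k
#' description-length scores.
#'
#' @param model a [CamModel-class].
#' @param prefix output path prefix; writes `<prefix>_A.csv`,
#'   `<prefix>_S.csv` and `<prefix>.json`.
#' @return `invisible(prefix)`.
#' @export
writeCamModel <- function(model, prefix) {
  utils::write.csv(model@A, paste0(prefix, "_A.csv"))
  utils::write.csv(model@S, paste0(prefix, "_S.csv"))
  side <- list(k = model@k, nMG = model@nMG,
               mdlByK = as.list(model@mdlByK),
               markerSets = model@markerSets)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
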