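#' Generate a synthetic archetype-mixture proteomics dataset
#'
#' Emulates a low-rank nonnegative latent variable model: each sample is a
#' convex mixture of `k` archetype profiles, a fraction of proteins are
#' exclusive markers of one archetype, and intensities carry multiplicative
#' log-normal noise. The complete matrix is
#' `(A %*% S) * intensityScale * exp(N(0, noiseSigma^2))` entrywise.
#'
#' Rows of the mixing matrix are drawn from a flat Dirichlet by default; when
#' `clusterAssignments` is supplied, each sample's Dirichlet concentration is
#' biased toward its assigned archetype (concentration `clusterStrength` on
#' the own archetype, 1 elsewhere), producing distinct sample clusters.
#'
#' @param m,n sample and protein counts (`m > k`, `n > 10 * k`).
#' @param k archetype count, at least 2.
#' @param markerFraction per-archetype fraction of proteins that are exclusive
#'   markers (default 0.1).
#' @param noiseSigma log-scale standard deviation of the multiplicative noise
#'   (default 0.3; 0 gives the exact low-rank product).
#' @param intensityScale overall intensity magnitude (default 1e6, typical of
#'   label-free LC-MS protein abundances).
#' @param seed integer seed; identical seeds give identical outputs.
#' @param clusterAssignments optional integer vector of length `m` with values
#'   in `1..k` assigning each sample to a dominant archetype.
#' @param clusterStrength Dirichlet concentration on the own archetype when
#'   `clusterAssignments` is used (default 8).
#' @return a [SyntheticTruth-class].
#' @export
generateSynthetic <- function(m, n, k, markerFraction = 0.1, noiseSigma = 0.3,
                              intensityScale = 1e6, seed = 1,
                              clusterAssignments = NULL, clusterStrength = 8) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (m <= k) stop("m must exceed k", call. = FALSE)
  if (n <= 10 * k) stop("n must exceed 10 * k", call. = FALSE)
  if (markerFraction <= 0 || markerFraction * k >= 1)
    stop("markerFraction out of range", call. = FALSE)
  if (noiseSigma < 0) stop("noiseSigma must be nonnegative", call. = FALSE)
  set.seed(seed)

  # mixing rows on the simplex via normalized gammas
  if (is.null(clusterAssignments)) {
    G <- matrix(stats::rgamma(m * k, shape = 1, rate = 1), m, k)
  } else {
    if (length(clusterAssignments) != m || !all(clusterAssignments %in% seq_len(k)))
      stop("clusterAssignments must map each sample to an archetype 1..k",
           call. = FALSE)
    G <- matrix(0, m, k)
    for (i in seq_len(m)) {
      alpha <- rep(1, k)
      alpha[clusterAssignments[i]] <- clusterStrength
      G[i, ] <- stats::rgamma(k, shape = alpha, rate = 1)
    }
  }
  A <- G / rowSums(G)

  # archetype profiles: exclusive markers plus broadly expressed proteins
  nMark <- max(1L, round(markerFraction * n))
  S <- matrix(0, k, n)
  markerSets <- vector("list", k)
  pos <- 0L
  for (a in seq_len(k)) {
    idx <- pos + seq_len(nMark)
    markerSets[[a]] <- idx
    S[a, idx] <- stats::rlnorm(nMark, meanlog = 0, sdlog = 0.25) + 0.5
    pos <- pos + nMark
  }
  shared <- (pos + 1L):n
  S[, shared] <- matrix(stats::rgamma(k * length(shared), shape = 2, rate = 2),
                        k, length(shared))

  mu <- (A %*% S) * intensityScale
  noise <- if (noiseSigma > 0)
    exp(matrix(stats::rnorm(m * n, 0, noiseSigma), m, n)) else 1
  complete <- AbundanceMatrix(mu * noise, space = "intensity")
  names(markerSets) <- paste0("archetype_", seq_len(k))
  new("SyntheticTruth", ATrue = A, STrue = S, markerSets = markerSets,
      noiseSigma = noiseSigma, complete = complete)
}

# shared entry check for injection operations
.checkInjectable <- function(count, what = "evaluation set") {
  if (count < 1L) stop("empty ", what, call. = FALSE)
  count
}

#' Inject missing-completely-at-random values
#'
#' Hides exactly `round(alpha * m * n)` entries chosen uniformly without
#' replacement from a complete matrix. If the draw would leave a protein with
#' no observed entries it is redrawn (at most 100 times).
#'
#' @param x a complete [AbundanceMatrix-class].
#' @param alpha target total missing rate in (0, 1).
#' @param seed integer seed.
#' @return a list with elements `matrix` (the matrix with `NA` injected) and
#'   `truth` (the [GroundTruth-class] at the hidden positions).
#' @export
injectMCAR <- function(x, alpha, seed = 1) {
  .assertAbundanceMatrix(x)
  .assertComplete(x, "injectMCAR")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  mn <- length(x@values)
  count <- .checkInjectable(round(alpha * mn))
  set.seed(seed)
  m <- nrow(x@values)
  for (attempt in seq_len(100L)) {
    lin <- sample.int(mn, count)
    v <- x@values
    v[lin] <- NA_real_
    if (all(colSums(!is.na(v)) > 0L)) {
      pos <- cbind((lin - 1L) %% m + 1L, (lin - 1L) %/% m + 1L)
      pos <- pos[order(pos[, 2L], pos[, 1L]), , drop = FALSE]
      return(list(matrix = AbundanceMatrix(v, space = x@space),
                  truth = .truthAt(x, pos)))
    }
  }
  stop("could not draw an MCAR mask leaving every protein observed (100 redraws)",
       call. = FALSE)
}

#' Inject missing-not-at-random values by global quantile cut-off
#'
#' Deterministically hides the lowest `floor(alpha * m * n)` values of the
#' full dataset (ties broken by sample-then-protein order, with a message),
#' emulating below-detection-limit missingness.
#'
#' @inheritParams injectMCAR
#' @return as [injectMCAR()]; additionally every hidden true value is at most
#'   every surviving observed value (the cut-off separation property).
#' @export
injectMNAR <- function(x, alpha) {
  .assertAbundanceMatrix(x)
  .assertComplete(x, "injectMNAR")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  mn <- length(x@values)
  count <- .checkInjectable(floor(alpha * mn))
  m <- nrow(x@values)
  lin <- seq_len(mn)
  row <- (lin - 1L) %% m + 1L
  col <- (lin - 1L) %/% m + 1L
  ord <- order(x@values, row, col)   # ties: (row, column) lexicographic
  cutVal <- x@values[ord[count]]
  if (count < mn && x@values[ord[count + 1L]] == cutVal)
    message("injectMNAR: ties at the cut-off broken by (row, column) order")
  hide <- ord[seq_len(count)]
  v <- x@values
  v[hide] <- NA_real_
  pos <- cbind(row[hide], col[hide])
  pos <- pos[order(pos[, 2L], pos[, 1L]), , drop = FALSE]
  list(matrix = AbundanceMatrix(v, space = x@space), truth = .truthAt(x, pos))
}

#' Inject a mixture of MNAR and MCAR missingness
#'
#' Applies the MNAR quantile cut-off first (so the quantile refers to the full
#' dataset) for `round(beta * alpha * m * n)` entries, then hides
#' `round((1 - beta) * alpha * m * n)` further entries uniformly among the
#' survivors. `beta = 0` reduces to pure MCAR, `beta = 1` to pure MNAR.
#'
#' @inheritParams injectMCAR
#' @param beta MNAR proportion in \[0, 1\].
#' @return as [injectMCAR()].
#' @export
injectMix <- function(x, alpha, beta, seed = 1) {
  .assertAbundanceMatrix(x)
  .assertComplete(x, "injectMix")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (beta < 0 || beta > 1) stop("beta must be in [0, 1]", call. = FALSE)
  mn <- length(x@values)
  nMNAR <- round(beta * alpha * mn)
  nMCAR <- round((1 - beta) * alpha * mn)
  .checkInjectable(nMNAR + nMCAR)

  cur <- x
  truths <- list()
  if (nMNAR >= 1L) {
    # +0.5 guards the floor() in injectMNAR against floating-point round-down
    step <- injectMNAR(x, (nMNAR + 0.5) / mn)
    cur <- step$matrix
    truths$mnar <- step$truth
  }
  if (nMCAR >= 1L) {
    set.seed(seed)
    m <- nrow(cur@values)
    obsLin <- which(!is.na(cur@values))
    # only proteins still observed after the MNAR stage constrain the draw
    # (fully censored proteins are the filter's business, not the draw's)
    alive <- colSums(!is.na(cur@values)) > 0L
    for (attempt in seq_len(100L)) {
      lin <- sample(obsLin, nMCAR)
      v <- cur@values
      v[lin] <- NA_real_
      if (all(colSums(!is.na(v))[alive] > 0L)) {
        pos <- cbind((lin - 1L) %% m + 1L, (lin - 1L) %/% m + 1L)
        truths$mcar <- .truthAt(x, pos)
        cur <- AbundanceMatrix(v, space = x@space)
        break
      }
      if (attempt == 100L)
        stop("could not draw an MCAR mask leaving every protein observed",
             call. = FALSE)
    }
  }
  sid <- unlist(lapply(truths, slot, "sampleIds"), use.names = FALSE)
  pid <- unlist(lapply(truths, slot, "proteinIds"), use.names = FALSE)
  val <- unlist(lapply(truths, slot, "values"), use.names = FALSE)
  list(matrix = cur,
       truth = GroundTruth(sid, pid, val, x@space))
}

#' Inject cluster-consistent dropout
#'
#' Emulates structured missingness shared within sample groups: for each
#' cluster, a random subset of `proneFraction` of the proteins becomes
#' dropout-prone in that cluster, and each (prone protein, cluster sample)
#' entry is hidden independently with probability `dropoutRate`. Proteins
#' that would lose all observations keep one entry. This is the regime where
#' within-data sample similarity carries information that a purely global
#' low-rank fit lacks.
#'
#' @param x a complete [AbundanceMatrix-class].
#' @param clusters integer vector of cluster labels, one per sample.
#' @param proneFraction fraction of proteins that are dropout-prone per
#'   cluster (default 1/3).
#' @param dropoutRate per-entry dropout probability within a prone block
#'   (default 0.6).
#' @param seed integer seed.
#' @return as [injectMCAR()].
#' @export
injectClusterDropout <- function(x, clusters, proneFraction = 1 / 3,
                                 dropoutRate = 0.6, seed = 1) {
  .assertAbundanceMatrix(x)
  .assertComplete(x, "injectClusterDropout")
  v <- x@values
  m <- nrow(v); n <- ncol(v)
  if (length(clusters) != m)
    stop("one cluster label per sample required", call. = FALSE)
  set.seed(seed)
  mask <- matrix(FALSE, m, n)
  for (cl in unique(clusters)) {
    rows <- which(clusters == cl)
    prone <- sample.int(n, round(proneFraction * n))
    mask[rows, prone] <- matrix(stats::runif(length(rows) * length(prone)) <
                                  dropoutRate, length(rows), length(prone))
  }
  for (j in which(colSums(!mask) == 0L)) mask[1L, j] <- FALSE
  if (!any(mask)) stop("empty evaluation set", call. = FALSE)
  pos <- which(mask, arr.ind = TRUE)
  vm <- v
  vm[mask] <- NA_real_
  list(matrix = AbundanceMatrix(vm, space = x@space), truth = .truthAt(x, pos))
}

#' Proportional masking of an authentically incomplete matrix
#'
#' For each protein with authentic missing rate `r_p` and `obs_p` observed
#' entries, hides `round(c * r_p * obs_p)` of its observed entries, with the
#' single constant `c` calibrated (bisection plus a largest-remainder
#' adjustment) so the total masked count equals
#' `round(globalFraction * total observed)`. Proteins with no authentic
#' missingness receive no mask; per-protein masks are capped at `obs_p - 1`
#' so every protein keeps at least one observed entry. Only formerly observed
#' entries enter the ground truth.
#'
#' @param x an [AbundanceMatrix-class] containing authentic missing entries.
#' @param globalFraction target fraction of observed entries to mask, in
#'   (0, 0.5].
#' @param seed integer seed for the within-protein position draws.
#' @return as [injectMCAR()]: the further-masked matrix and the
#'   [GroundTruth-class] of masked entries.
#' @export
maskSetting2 <- function(x, globalFraction, seed = 1) {
  .assertAbundanceMatrix(x)
  if (globalFraction <= 0 || globalFraction > 0.5)
    stop("globalFraction must be in (0, 0.5]", call. = FALSE)
  mask <- is.na(x@values)
  if (!any(mask))
    stop("masking undefined without authentic missingness", call. = FALSE)
  obs <- colSums(!mask)
  if (any(obs < 2L))
    stop("every protein needs at least 2 observed entries", call. = FALSE)
  r <- colMeans(mask)
  raw <- r * obs                       # proportional-allocation weights
  totalObs <- sum(obs)
  target <- round(globalFraction * totalObs)
  if (target < 1L) stop("empty evaluation set", call. = FALSE)
  if (sum(raw) <= 0)
    stop("masking undefined without authentic missingness", call. = FALSE)

  cap <- pmax(obs - 1L, 0L)
  countsAt <- function(cc) pmin(round(cc * raw), cap)
  # bisection on the monotone step function total(c)
  lo <- 0; hi <- 1
  while (sum(countsAt(hi)) < target && hi < 1e12) hi <- hi * 2
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    if (sum(countsAt(mid)) < target) lo <- mid else hi <- mid
  }
  cc <- hi
  counts <- countsAt(cc)
  # largest-remainder repair of any rounding-step discrepancy (ties at the
  # rounding boundary can make the step function jump past the target); each
  # protein is adjusted at most once per sweep
  diff <- sum(counts) - target
  frac <- cc * raw - floor(cc * raw)
  fracDown <- frac
  while (diff > 0L) {
    cand <- which(counts > 0L)
    i <- cand[which.min(fracDown[cand])]
    counts[i] <- counts[i] - 1L
    fracDown[i] <- fracDown[i] + 1
    diff <- diff - 1L
  }
  fracUp <- frac
  while (diff < 0L) {
    cand <- which(counts < cap & raw > 0)
    if (!length(cand)) break
    i <- cand[which.max(fracUp[cand])]
    counts[i] <- counts[i] + 1L
    fracUp[i] <- fracUp[i] - 1
    diff <- diff + 1L
  }

  set.seed(seed)
  v <- x@values
  posList <- vector("list", ncol(v))
  for (j in seq_len(ncol(v))) {
    if (counts[j] < 1L) next
    obsIdx <- which(!mask[, j])
    hide <- if (length(obsIdx) == 1L) obsIdx else sample(obsIdx, counts[j])
    v[hide, j] <- NA_real_
    posList[[j]] <- cbind(hide, j)
  }
  pos <- do.call(rbind, posList)
  list(matrix = AbundanceMatrix(v, space = x@space), truth = .truthAt(x, pos))
}
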