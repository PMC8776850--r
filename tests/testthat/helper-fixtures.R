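# Fixture builders and independent oracle implementations used across the
# suite. Oracles are deliberately written as naive loops, independent of the
# package's vectorized code paths.

randomAbundance <- function(m, n, missFrac = 0.2, space = "log2", seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(m * n, mean = 10, sd = 2), m, n,
              dimnames = list(paste0("s", seq_len(m)), paste0("p", seq_len(n))))
  if (space == "intensity") v <- abs(v) + 1
  if (missFrac > 0) {
    hide <- sample(m * n, round(missFrac * m * n))
    v[hide] <- NA
    # keep every protein and sample observed somewhere
    for (j in which(colSums(!is.na(v)) == 0)) v[1, j] <- 10
    for (i in which(rowSums(!is.na(v)) == 0)) v[i, 1] <- 10
  }
  AbundanceMatrix(v, space = space)
}

# hide entries of a complete matrix at given positions, returning the masked
# matrix and its GroundTruth (used to build bespoke missingness patterns)
maskAt <- function(x, pos) {
  v <- abundances(x)
  truth <- GroundTruth(rownames(v)[pos[, 1]], colnames(v)[pos[, 2]],
                       v[pos], spaceTag(x))
  v[pos] <- NA
  list(matrix = AbundanceMatrix(v, space = spaceTag(x)), truth = truth)
}

popVarOracle <- function(x) sum((x - mean(x))^2) / length(x)

# naive KNN fill over rows: for a missing (i, j), candidates are rows
# observing column j; distance is the root-sum-of-squares over mutually
# observed columns divided by sqrt(overlap); k smallest (ties by row index)
# are averaged with weights 1/(d + 1e-9); no candidate -> column mean
bruteKNNRows <- function(v, k) {
  m <- nrow(v); n <- ncol(v)
  out <- v
  for (i in seq_len(m)) for (j in seq_len(n)) {
    if (!is.na(v[i, j])) next
    cand <- c(); dist <- c()
    for (i2 in seq_len(m)) {
      if (i2 == i || is.na(v[i2, j])) next
      shared <- which(!is.na(v[i, ]) & !is.na(v[i2, ]))
      if (!length(shared)) next
      d <- sqrt(sum((v[i, shared] - v[i2, shared])^2)) / sqrt(length(shared))
      cand <- c(cand, i2); dist <- c(dist, d)
    }
    if (!length(cand)) { out[i, j] <- mean(v[, j], na.rm = TRUE); next }
    ord <- order(dist, cand)[seq_len(min(k, length(cand)))]
    w <- 1 / (dist[ord] + 1e-9)
    out[i, j] <- sum(w * v[cand[ord], j]) / sum(w)
  }
  out
}

# independent rank computation: 1 + number strictly better + half the ties
rankOracle <- function(x) {
  vapply(seq_along(x), function(i)
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2, numeric(1))
}

# best minimum column correlation between estimated and true mixing matrices
# over all column permutations (k <= 4)
permMatchCor <- function(A, ATrue) {
  k <- ncol(ATrue)
  perms <- if (k == 2) list(1:2, 2:1) else
    if (k == 3) list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    else asplit(t(sapply(combinat_perms(seq_len(k)), identity)), 1)
  max(vapply(perms, function(p) min(diag(stats::cor(A[, p], ATrue))), numeric(1)))
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# central finite-difference gradient of the FRMF objective in (A, S)
fdGradient <- function(x, A, S, lambdaA, lambdaS, alphaFused, context,
                       h = 1e-5) {
  gA <- A; gS <- S
  for (idx in seq_along(A)) {
    Ap <- A; Ap[idx] <- A[idx] + h
    Am <- A; Am[idx] <- A[idx] - h
    gA[idx] <- (frmfObjective(x, Ap, S, lambdaA, lambdaS, alphaFused, context) -
                frmfObjective(x, Am, S, lambdaA, lambdaS, alphaFused, context)) / (2 * h)
  }
  for (idx in seq_along(S)) {
    Sp <- S; Sp[idx] <- S[idx] + h
    Sm <- S; Sm[idx] <- S[idx] - h
    gS[idx] <- (frmfObjective(x, A, Sp, lambdaA, lambdaS, alphaFused, context) -
                frmfObjective(x, A, Sm, lambdaA, lambdaS, alphaFused, context)) / (2 * h)
  }
  list(A = gA, S = gS)
}

# cluster-confined missingness fixture for the CAM imputers: missingness
# restricted to a subset of non-marker proteins so enough proteins stay
# fully observed
camFixture <- function(m = 30, n = 120, noiseSigma = 0, seed = 1,
                       nTarget = 40, rate = 0.1) {
  synth <- generateSynthetic(m, n, 3, markerFraction = 0.15,
                             noiseSigma = noiseSigma, seed = seed)
  v <- abundances(synth@complete)
  nonmark <- setdiff(seq_len(n), unlist(synth@markerSets))
  set.seed(seed + 5000)
  target <- sample(nonmark, nTarget)
  mask <- matrix(FALSE, m, n)
  mask[, target] <- matrix(runif(m * nTarget) < rate, m, nTarget)
  for (j in which(colSums(!mask) == 0)) mask[1, j] <- FALSE
  hidden <- maskAt(synth@complete, which(mask, arr.ind = TRUE))
  list(synth = synth, matrix = hidden$matrix, truth = hidden$truth)
}
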