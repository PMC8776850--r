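test_that("self-similarity neighborhoods match a brute-force all-pairs computation", {
  x <- randomAbundance(6, 12, missFrac = 0.2, seed = 100)
  v <- abundances(x)
  ctx <- buildSimilaritySelf(x, t = 3)
  for (i in 1:6) {
    sims <- rep(NA_real_, 6)
    for (k in setdiff(1:6, i)) {
      shared <- which(!is.na(v[i, ]) & !is.na(v[k, ]))
      if (!length(shared)) next
      sims[k] <- sum(v[i, shared] * v[k, shared]) /
        (sqrt(sum(v[i, shared]^2)) * sqrt(sum(v[k, shared]^2)))
    }
    expected <- order(-sims)[seq_len(min(3, sum(!is.na(sims))))]
    expect_equal(ctx@neighborhoods[[i]], expected)
  }
  # duplicated rows are mutual top neighbors with similarity 1
  vd <- rbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(9, 1, 4))
  colnames(vd) <- paste0("p", 1:3)
  cd <- buildSimilaritySelf(AbundanceMatrix(vd, space = "log2"), t = 1)
  expect_equal(cd@neighborhoods[[1]], 2L)
  expect_equal(cd@neighborhoods[[2]], 1L)
  expect_equal(cd@similarities[[1]], 1)
  # orthogonal rows have similarity 0
  vo <- rbind(a = c(1, 0), b = c(0, 1))
  colnames(vo) <- c("p1", "p2")
  co <- buildSimilaritySelf(AbundanceMatrix(vo, space = "log2"), t = 1)
  expect_equal(co@similarities[[1]], 0)
})

test_that("external-score neighborhoods use cosine over complete score vectors", {
  sc <- ExternalScores(rbind(s1 = c(1, 2), s2 = c(2, 4), s3 = c(-1, 5)))
  ctx <- buildSimilarityExternal(sc, t = 2)
  expect_equal(ctx@neighborhoods[[1]][1], 2L)   # parallel vector first
  expect_equal(ctx@similarities[[1]][1], 1)
  # a zero-norm sample is excluded, which also isolates its only partner
  expect_warning(
    expect_warning(buildSimilarityExternal(
      ExternalScores(rbind(s1 = c(0, 0), s2 = c(1, 1)))), "zero-norm"),
    "isolated")
})

test_that("analytic gradients match central finite differences", {
  for (seed in 1:6) {
    set.seed(seed + 200)
    v <- matrix(rnorm(30, 5), 5, 6,
                dimnames = list(paste0("s", 1:5), paste0("p", 1:6)))
    v[sample(30, 6)] <- NA
    x <- AbundanceMatrix(v, space = "log2")
    ctx <- suppressWarnings(buildSimilaritySelf(x, t = 2))
    A <- matrix(rnorm(10), 5, 2)
    S <- matrix(rnorm(12), 2, 6)
    g <- frmfGradient(x, A, S, 0.1, 0.2, 0.7, ctx)
    fd <- fdGradient(x, A, S, 0.1, 0.2, 0.7, ctx)
    expect_lt(max(abs(g$A - fd$A)) / max(abs(fd$A)), 1e-5)
    expect_lt(max(abs(g$S - fd$S)) / max(abs(fd$S)), 1e-5)
  }
})

test_that("RMF factorizes a complete noiseless low-rank matrix essentially exactly", {
  set.seed(210)
  M <- matrix(rnorm(12 * 2), 12, 2) %*% t(matrix(rnorm(18 * 2), 18, 2))
  x <- AbundanceMatrix(M, space = "log2")
  fit <- fitRMF(x, 2, lambdaA = 0, lambdaS = 0, maxIter = 5000, tol = 1e-12)
  rec <- mixingMatrix(fit) %*% profileMatrix(fit)
  expect_lt(sqrt(sum((rec - M)^2)) / sqrt(sum(M^2)), 1e-3)
  tr <- objectiveTrace(fit)
  expect_lt(tr[length(tr)], tr[1])
  # determinism under a shared seed
  fit2 <- fitRMF(x, 2, lambdaA = 0, lambdaS = 0, maxIter = 5000, tol = 1e-12)
  expect_identical(mixingMatrix(fit2), mixingMatrix(fit))
})

test_that("FRMF with alpha = 0 reproduces the RMF trace bitwise under a shared seed", {
  x <- randomAbundance(8, 12, missFrac = 0.2, seed = 220)
  ctx <- buildSimilaritySelf(x, t = 3)
  fitR <- fitRMF(x, 2, seed = 7)
  fitF <- fitFRMF(x, ctx, alphaFused = 0, rank = 2, seed = 7)
  expect_identical(objectiveTrace(fitF), objectiveTrace(fitR))
  expect_identical(mixingMatrix(fitF), mixingMatrix(fitR))
})

test_that("a large fused weight forces duplicate samples to share latent vectors", {
  set.seed(230)
  base <- rnorm(15, 8)
  v <- rbind(s1 = base, s2 = base, s3 = rnorm(15, 8), s4 = rnorm(15, 8),
             s5 = rnorm(15, 8))
  colnames(v) <- paste0("p", 1:15)
  v[1, 3] <- NA; v[2, 9] <- NA; v[4, 1] <- NA
  x <- AbundanceMatrix(v, space = "log2")
  ctx <- buildSimilaritySelf(x, t = 1)
  expect_equal(ctx@neighborhoods[[1]], 2L)   # duplicates are mutual neighbors
  fit <- fitFRMF(x, ctx, alphaFused = 1e3, rank = 2, maxIter = 5000, tol = 1e-12)
  A <- mixingMatrix(fit)
  expect_lt(sqrt(sum((A[1, ] - A[2, ])^2)), 1e-2)
})

test_that("the objective trace is non-increasing after burn-in", {
  x <- randomAbundance(10, 16, missFrac = 0.2, seed = 240)
  fit <- fitRMF(x, 3, seed = 3)
  tr <- objectiveTrace(fit)
  expect_true(all(diff(tr[-(1:5)]) <= 1e-8 * pmax(tr[-c(1:5, length(tr))], 1)))
})

test_that("imputeFromFactors fills exactly the missing set and preserves observed data", {
  x <- randomAbundance(8, 12, missFrac = 0.25, seed = 250)
  fit <- fitRMF(x, 2, seed = 1)
  r <- imputeFromFactors(x, fit)
  obs <- !missingMask(x)
  expect_identical(completedMatrix(r)[obs], abundances(x)[obs])
  expect_equal(nrow(r@filled), sum(missingMask(x)))
  # complete input: nothing filled
  xc <- randomAbundance(8, 12, missFrac = 0, seed = 251)
  rc <- imputeFromFactors(xc, fitRMF(xc, 2, seed = 1))
  expect_identical(completedMatrix(rc), abundances(xc))
  expect_equal(nrow(rc@filled), 0L)
})

test_that("FRMF with self-similarity beats RMF under cluster-consistent dropout", {
  rmfErr <- frmfErr <- numeric(3)
  for (s in 1:3) {
    synth <- generateSynthetic(30, 150, 2, markerFraction = 0.1,
                               noiseSigma = 0.25, seed = 300 + s,
                               clusterAssignments = rep(1:2, each = 15))
    lg <- log2Transform(synth@complete)
    inj <- injectClusterDropout(lg, rep(1:2, each = 15), proneFraction = 1 / 3,
                                dropoutRate = 0.6, seed = 400 + s)
    rmfErr[s] <- nrmse(inj$truth,
                       imputeWithMethod(inj$matrix, "rmf",
                                        list(rank = 2, seed = s)))
    frmfErr[s] <- nrmse(inj$truth,
                        imputeWithMethod(inj$matrix, "frmf_self",
                                         list(rank = 2, alphaFused = 1, t = 5,
                                              seed = s)))
  }
  expect_lte(median(frmfErr), median(rmfErr))
})
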