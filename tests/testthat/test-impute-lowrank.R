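# shared noiseless low-rank fixture
lowRankFixture <- function(m, n, rank, missFrac, seedM, seedMask) {
  set.seed(seedM)
  M <- matrix(rnorm(m * rank), m, rank) %*% t(matrix(rnorm(n * rank), n, rank))
  x <- AbundanceMatrix(M, space = "log2")
  injectMCAR(x, missFrac, seed = seedMask)
}

test_that("SVDImpute recovers a noiseless rank-1 matrix and is the identity without NAs", {
  inj <- lowRankFixture(12, 20, 1, 0.1, 50, 51)
  r <- imputeSVDImpute(inj$matrix, 1)
  expect_lt(rmse(inj$truth, r), 1e-4)
  # refill change sequence is non-increasing after the first few steps
  tr <- r@params$trace
  expect_true(all(diff(tr[-(1:2)]) <= 1e-12))
  # identity on complete data, zero refill iterations
  x <- randomAbundance(6, 8, missFrac = 0, seed = 52)
  r0 <- imputeSVDImpute(x, 2)
  expect_identical(completedMatrix(r0), abundances(x))
  expect_equal(r0@params$iterations, 0L)
})

test_that("NIPALS matches the SVD leading component on complete data and recovers rank-2", {
  set.seed(53)
  M <- matrix(rnorm(15 * 25), 15, 25)
  x <- AbundanceMatrix(M, space = "log2")
  r <- imputeNIPALS(x, 1)
  p <- r@params$loadings[, 1]
  vSvd <- svd(M)$v[, 1]
  expect_gt(abs(sum(p * vSvd)), 0.999)
  # noiseless rank-2, 15% missing, true rank
  inj <- lowRankFixture(15, 30, 2, 0.15, 54, 55)
  r2 <- imputeNIPALS(inj$matrix, 2)
  expect_lt(nrmse(inj$truth, r2), 0.05)
  expect_error(imputeNIPALS(inj$matrix, 0), "rank")
})

test_that("PPCA has a monotone log-likelihood, recovers noiseless data, and is deterministic", {
  inj <- lowRankFixture(20, 40, 1, 0.1, 56, 57)
  r <- imputePPCA(inj$matrix, 1)
  expect_lt(rmse(inj$truth, r), 1e-4)
  # noisy fixture: monotone log-likelihood within slack
  set.seed(58)
  M <- matrix(rnorm(40 * 2), 40, 2) %*% t(matrix(rnorm(60 * 2), 60, 2)) +
    matrix(rnorm(2400, 0, 0.4), 40, 60)
  injN <- injectMCAR(AbundanceMatrix(M, space = "log2"), 0.2, seed = 59)
  rN <- imputePPCA(injN$matrix, 2)
  ll <- rN@params$loglik
  expect_true(all(diff(ll) >= -1e-8 * pmax(abs(ll[-length(ll)]), 1)))
  rN2 <- imputePPCA(injN$matrix, 2)
  expect_identical(completedMatrix(rN), completedMatrix(rN2))
})

test_that("SVT solves the matrix-completion fixture and degenerates sanely at tau = 0", {
  set.seed(60)
  M <- matrix(rnorm(80), 40, 2) %*% t(matrix(rnorm(120), 60, 2))
  x <- AbundanceMatrix(M, space = "log2")
  inj <- injectMCAR(x, 0.3, seed = 61)
  r <- imputeSVT(inj$matrix)
  relErr <- sqrt(sum((completedMatrix(r) - M)^2)) / sqrt(sum(M^2))
  expect_lt(relErr, 1e-2)
  # observed-entry residual is non-increasing from the start and strictly
  # decreasing once the singular values exceed the threshold
  res <- r@params$residuals
  expect_true(all(diff(res[1:10]) <= 0))
  active <- which(res < res[1])[1]
  expect_true(all(diff(res[active:min(active + 10, length(res))]) < 0))
  # tau = 0 on a complete matrix: no shrinkage, reconstruction equals input
  rc <- imputeSVT(x, tau = 0, tol = 1e-8)
  expect_lt(max(abs(completedMatrix(rc) - M)), 1e-5)
})

test_that("all four low-rank methods beat NRMSE 0.05 at the true rank (noiseless, 20% MCAR)", {
  inj <- lowRankFixture(30, 80, 2, 0.2, 62, 63)
  expect_lt(nrmse(inj$truth, imputePPCA(inj$matrix, 2)), 0.05)
  expect_lt(nrmse(inj$truth, imputeNIPALS(inj$matrix, 2)), 0.05)
  expect_lt(nrmse(inj$truth, imputeSVDImpute(inj$matrix, 2)), 0.05)
  expect_lt(nrmse(inj$truth, imputeSVT(inj$matrix)), 0.05)
})

test_that("low-rank imputers never modify observed entries", {
  inj <- lowRankFixture(15, 25, 2, 0.25, 64, 65)
  obs <- !missingMask(inj$matrix)
  for (r in list(imputePPCA(inj$matrix, 2), imputeNIPALS(inj$matrix, 2),
                 imputeSVDImpute(inj$matrix, 2), imputeSVT(inj$matrix)))
    expect_identical(completedMatrix(r)[obs], abundances(inj$matrix)[obs])
})

test_that("imputation error grows with the missing rate in expectation", {
  errLo <- errHi <- numeric(5)
  for (s in 1:5) {
    set.seed(70 + s)
    M <- matrix(rnorm(30 * 2), 30, 2) %*% t(matrix(rnorm(50 * 2), 50, 2)) +
      matrix(rnorm(1500, 0, 0.5), 30, 50)
    x <- AbundanceMatrix(M, space = "log2")
    injLo <- injectMCAR(x, 0.1, seed = 80 + s)
    injHi <- injectMCAR(x, 0.4, seed = 90 + s)
    errLo[s] <- nrmse(injLo$truth, imputeSVDImpute(injLo$matrix, 2))
    errHi[s] <- nrmse(injHi$truth, imputeSVDImpute(injHi$matrix, 2))
  }
  expect_gt(mean(errHi), mean(errLo))
})
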