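test_that("the description-length score evaluates both forms exactly", {
  # 4 x 6 fixture with residual sum exactly 1
  set.seed(500)
  A <- matrix(runif(8, 0.2, 1), 4, 2)
  A <- A / rowSums(A)
  S <- matrix(runif(12, 1, 2), 2, 6)
  v <- A %*% S
  v[1, 1] <- v[1, 1] + 1               # residual = 1
  x <- AbundanceMatrix(v, space = "intensity")
  # unscaled form: (1/2) log(1) + ((k-1) m / 2) log(nMG) + (k n / 2) log(m)
  expect_equal(computeMDL(x, A, S, nMG = 4, form = "unscaled"),
               0 + (1 * 4 / 2) * log(4) + (2 * 6 / 2) * log(4))
  # scaled form replaces the fit term with (mn/2) log(RSS/(mn))
  expect_equal(computeMDL(x, A, S, nMG = 4, form = "scaled"),
               (24 / 2) * log(1 / 24) + (1 * 4 / 2) * log(4) +
                 (2 * 6 / 2) * log(4))
  # residual 1 makes the unscaled fit term zero
  expect_equal(computeMDL(x, A, S, nMG = 4, form = "unscaled") -
                 ((1 * 4 / 2) * log(4) + (2 * 6 / 2) * log(4)), 0)
  # zero residual floors with a warning
  x0 <- AbundanceMatrix(A %*% S, space = "intensity")
  expect_warning(computeMDL(x0, A, S, nMG = 4), "floored")
})

test_that("penalty terms increase strictly with k at fixed residual", {
  set.seed(501)
  m <- 5; n <- 40
  x <- AbundanceMatrix(matrix(rlnorm(m * n, 2), m, n,
                              dimnames = list(paste0("s", 1:m),
                                              paste0("p", 1:n))),
                       space = "intensity")
  penalty <- function(k) ((k - 1) * m / 2) * log(6) + (k * n / 2) * log(m)
  expect_true(all(diff(sapply(2:5, penalty)) > 0))
})

test_that("camFit recovers archetype count and mixing on noiseless 3-archetype data", {
  s <- generateSynthetic(30, 120, 3, markerFraction = 0.15, noiseSigma = 0,
                         seed = 510)
  fit <- camFit(s@complete, kCandidates = 2:4, nClusters = 25, seed = 510)
  expect_equal(fit@k, 3)
  expect_gt(permMatchCor(mixingMatrix(fit), s@ATrue), 0.95)
  # factors nonnegative, markers disjoint, mixing rows on the simplex
  expect_true(all(mixingMatrix(fit) >= 0))
  expect_true(all(profileMatrix(fit) >= 0))
  expect_equal(unname(rowSums(mixingMatrix(fit))), rep(1, 30))
  # marker proteins have a single dominant profile entry in their archetype
  S <- profileMatrix(fit)
  for (a in seq_len(3)) for (j in markerSets(fit)[[a]])
    expect_equal(unname(which.max(S[, j])), a)
  # determinism
  fit2 <- camFit(s@complete, kCandidates = 2:4, nClusters = 25, seed = 510)
  expect_identical(mdlScores(fit2), mdlScores(fit))
  expect_identical(mixingMatrix(fit2), mixingMatrix(fit))
})

test_that("camImputeComplete recovers confined missingness and stays positive", {
  fx <- camFixture(noiseSigma = 0, seed = 520)
  r <- suppressMessages(camImputeComplete(fx$matrix, kCandidates = 2:4,
                                          nClusters = 25, seed = 520))
  expect_lt(nrmse(fx$truth, r), 0.05)
  expect_true(all(completedMatrix(r) > 0))
  expect_identical(spaceTag(r), "intensity")
  obs <- !missingMask(fx$matrix)
  expect_identical(completedMatrix(r)[obs], abundances(fx$matrix)[obs])
  # no missing values anywhere: identity result (noiseless data has zero
  # residual, which the description-length score floors with a warning)
  rc <- suppressWarnings(camImputeComplete(fx$synth@complete,
                                           kCandidates = 2:3, nClusters = 25,
                                           seed = 1))
  expect_identical(completedMatrix(rc), abundances(fx$synth@complete))
})

test_that("hybrid CAM imputation reconstructs through the archetype model", {
  fx <- camFixture(noiseSigma = 0, seed = 530)
  init <- suppressMessages(suppressWarnings(
    camImputeHybrid(fx$matrix, "nipals", kCandidates = 2:4, nClusters = 25,
                    seed = 530)))
  expect_identical(spaceTag(init), "intensity")
  expect_true(all(completedMatrix(init) > 0))
  obs <- !missingMask(fx$matrix)
  expect_identical(completedMatrix(init)[obs], abundances(fx$matrix)[obs])
  expect_lt(nrmse(fx$truth, init), 0.05)
  # hybrid error at the held-out set does not exceed the initializer's
  lg <- log2Transform(fx$matrix)
  std <- standardizeProteins(lg)
  nip <- invertScaling(imputeNIPALS(std$matrix, 3), std$params)
  nipInt <- AbundanceMatrix(2^completedMatrix(nip), space = "intensity")
  nipRes <- new("ImputationResult", completed = abundances(nipInt),
                method = "nipals", params = list(), filled = init@filled,
                space = "intensity")
  expect_lte(nrmse(fx$truth, init), nrmse(fx$truth, nipRes) + 1e-8)
})

test_that("CamModel serialization writes factor tables and a JSON sidecar", {
  s <- generateSynthetic(20, 80, 2, markerFraction = 0.12, noiseSigma = 0,
                         seed = 540)
  fit <- camFit(s@complete, kCandidates = 2:3, nClusters = 15, seed = 540)
  prefix <- file.path(tempdir(), "cam_test")
  writeCamModel(fit, prefix)
  A <- utils::read.csv(paste0(prefix, "_A.csv"), row.names = 1)
  expect_equal(dim(A), c(20, fit@k))
  side <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(side$k, fit@k)
  expect_equal(length(side$markerSets), fit@k)
})
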