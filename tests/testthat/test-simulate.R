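test_that("generateSynthetic honors its structural contracts", {
  s <- generateSynthetic(12, 50, 3, markerFraction = 0.1, noiseSigma = 0,
                         intensityScale = 1e6, seed = 4)
  expect_equal(rowSums(s@ATrue), rep(1, 12))
  # zero noise: complete equals the scaled product exactly
  expect_equal(abundances(s@complete),
               (s@ATrue %*% s@STrue) * 1e6, tolerance = 1e-12,
               ignore_attr = TRUE)
  # marker columns have exactly one positive profile entry
  for (a in seq_along(s@markerSets))
    for (j in s@markerSets[[a]])
      expect_equal(sum(s@STrue[, j] > 0), 1L)
  # determinism
  s2 <- generateSynthetic(12, 50, 3, markerFraction = 0.1, noiseSigma = 0,
                          intensityScale = 1e6, seed = 4)
  expect_identical(abundances(s2@complete), abundances(s@complete))
  # rank-k SVD explains essentially all variance at zero noise
  d <- svd(abundances(s@complete))$d
  expect_gt(sum(d[1:3]^2) / sum(d^2), 0.9999)
  # parameter domain checks
  expect_error(generateSynthetic(5, 50, 1, seed = 1), "k")
  expect_error(generateSynthetic(3, 50, 3, seed = 1), "m")
  expect_error(generateSynthetic(12, 25, 3, seed = 1), "n")
})

test_that("injectMCAR hides an exact count, reproducibly, leaving proteins observed", {
  x <- randomAbundance(10, 10, missFrac = 0, seed = 5)
  inj <- injectMCAR(x, 0.5, seed = 6)
  expect_equal(sum(missingMask(inj$matrix)), 50L)
  expect_equal(length(inj$truth@values), 50L)
  expect_true(all(colSums(!missingMask(inj$matrix)) > 0))
  # truth values equal pre-injection values bit-exactly
  v <- abundances(x)
  idx <- cbind(match(inj$truth@sampleIds, rownames(v)),
               match(inj$truth@proteinIds, colnames(v)))
  expect_identical(inj$truth@values, unname(v[idx]))
  # determinism
  inj2 <- injectMCAR(x, 0.5, seed = 6)
  expect_identical(abundances(inj2$matrix), abundances(inj$matrix))
  # degenerate rate errors
  expect_error(injectMCAR(x, 0.001, seed = 1), "empty evaluation set")
})

test_that("injectMNAR applies the global quantile cut-off deterministically", {
  v <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("s1", "s2"), c("p1", "p2")))
  x <- AbundanceMatrix(v, space = "log2")
  inj <- injectMNAR(x, 0.25)
  expect_equal(sum(missingMask(inj$matrix)), 1L)
  expect_equal(inj$truth@values, 1)        # only the lowest value removed
  # separation: every hidden value <= every surviving value
  y <- randomAbundance(8, 12, missFrac = 0, seed = 7)
  inj2 <- injectMNAR(y, 0.3)
  expect_lte(max(inj2$truth@values),
             min(abundances(inj2$matrix), na.rm = TRUE))
  expect_equal(sum(missingMask(inj2$matrix)), floor(0.3 * 96))
  expect_error(injectMNAR(y, 0), "empty evaluation set")
})

test_that("injectMix composes MNAR-then-MCAR with exact counts and degenerates correctly", {
  x <- randomAbundance(10, 12, missFrac = 0, seed = 8)
  mn <- 120
  inj <- injectMix(x, 0.3, 0.5, seed = 9)
  expect_equal(sum(missingMask(inj$matrix)),
               round(0.5 * 0.3 * mn) + round(0.5 * 0.3 * mn))
  # beta = 1 reduces to pure MNAR
  injB1 <- injectMix(x, 0.3, 1, seed = 9)
  injMNAR <- injectMNAR(x, 0.3)
  expect_identical(abundances(injB1$matrix), abundances(injMNAR$matrix))
  # beta = 0 is pure MCAR with the same count rule
  injB0 <- injectMix(x, 0.3, 0, seed = 9)
  expect_equal(sum(missingMask(injB0$matrix)), round(0.3 * mn))
  # hidden and surviving positions partition the grid
  expect_equal(length(inj$truth@values) + sum(!missingMask(inj$matrix)), mn)
})

test_that("maskSetting2 calibrates the global fraction and allocates proportionally", {
  set.seed(10)
  v3 <- matrix(rlnorm(800, 10), 40, 20,
               dimnames = list(paste0("s", 1:40), paste0("p", 1:20)))
  v3[1:4, 1] <- NA                        # r = 0.1, obs 36 -> w 3.6
  v3[1:16, 2] <- NA                       # r = 0.4, obs 24 -> w 9.6
  for (j in 4:20) v3[sample(40, 10), j] <- NA   # background r = 0.25
  x3 <- AbundanceMatrix(v3)
  msk3 <- maskSetting2(x3, 0.1, seed = 12)
  cnt <- table(factor(msk3$truth@proteinIds, levels = proteinIds(x3)))
  expect_gt(cnt[["p2"]], cnt[["p1"]])     # ~1:2.7 allocation-weight ratio
  # zero-rate proteins receive no mask
  expect_equal(cnt[["p3"]], 0L)
  # global total within one entry of the target
  totObs <- sum(!is.na(v3))
  expect_lte(abs(length(msk3$truth@values) - round(0.1 * totObs)), 1)
  # authentic NAs untouched; masked entries were observed
  expect_true(all(is.na(abundances(msk3$matrix)[is.na(v3)])))
  expect_false(anyNA(v3[cbind(match(msk3$truth@sampleIds, rownames(v3)),
                              match(msk3$truth@proteinIds, colnames(v3)))]))
  # masking requires authentic missingness
  expect_error(maskSetting2(randomAbundance(5, 5, 0, seed = 1), 0.1),
               "authentic")
})

test_that("injectClusterDropout confines dropout to cluster-prone blocks", {
  s <- generateSynthetic(20, 60, 2, seed = 13,
                         clusterAssignments = rep(1:2, each = 10))
  inj <- injectClusterDropout(s@complete, rep(1:2, each = 10),
                              proneFraction = 0.3, dropoutRate = 0.5, seed = 14)
  expect_gt(mean(missingMask(inj$matrix)), 0.05)
  expect_true(all(colSums(!missingMask(inj$matrix)) > 0))
  inj2 <- injectClusterDropout(s@complete, rep(1:2, each = 10),
                               proneFraction = 0.3, dropoutRate = 0.5, seed = 14)
  expect_identical(abundances(inj2$matrix), abundances(inj$matrix))
})
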