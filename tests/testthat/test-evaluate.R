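mkResult <- function(truthMat, completed, space = "log2") {
  new("ImputationResult", completed = completed, method = "test",
      params = list(), filled = matrix(integer(), 0, 2), space = space)
}

test_that("rmse and nrmse evaluate their formulas exactly", {
  v <- matrix(c(1, 3, 5, 7), 2, 2, dimnames = list(c("s1", "s2"), c("p1", "p2")))
  comp <- matrix(c(2, 2, 5, 7), 2, 2, dimnames = dimnames(v))
  truth <- GroundTruth(c("s1", "s2"), c("p1", "p1"), c(1, 3), "log2")
  res <- mkResult(v, comp)
  expect_equal(rmse(truth, res), 1)      # sqrt((1 + 1) / 2)
  expect_equal(nrmse(truth, res), 1)     # population variance of {1,3} is 1
  # perfect imputation
  perfect <- mkResult(v, v)
  expect_equal(rmse(truth, perfect), 0)
  # single-element evaluation set
  t1 <- GroundTruth("s1", "p1", 4, "log2")
  expect_equal(rmse(t1, res), 2)
  expect_error(nrmse(t1, res), "at least 2")
  # space mismatch
  expect_error(rmse(truth, mkResult(v, comp, space = "intensity")), "mismatch")
  # zero variance truth
  t0 <- GroundTruth(c("s1", "s2"), c("p1", "p1"), c(3, 3), "log2")
  expect_error(nrmse(t0, res), "zero variance")
})

test_that("imputing with the evaluation-set mean gives NRMSE exactly 1", {
  for (seed in 1:5) {
    set.seed(seed + 600)
    x <- randomAbundance(8, 10, missFrac = 0.3, seed = seed + 600)
    inj <- maskAt(randomAbundance(8, 10, missFrac = 0, seed = seed),
                  which(matrix(runif(80) < 0.3, 8, 10), arr.ind = TRUE))
    comp <- abundances(inj$matrix)
    comp[is.na(comp)] <- mean(inj$truth@values)
    expect_equal(nrmse(inj$truth, mkResult(comp, comp)), 1, tolerance = 1e-12)
  }
})

test_that("per-protein NRMSE applies guards and matches direct evaluation", {
  v <- matrix(rnorm(20, 10), 4, 5,
              dimnames = list(paste0("s", 1:4), paste0("p", 1:5)))
  x <- AbundanceMatrix(v, space = "log2")
  pos <- rbind(c(1, 1), c(2, 1), c(3, 1), c(1, 2), c(2, 2), c(1, 3))
  hidden <- maskAt(x, pos)
  comp <- abundances(hidden$matrix)
  comp[is.na(comp)] <- 99
  res <- mkResult(comp, comp)
  pn <- suppressMessages(proteinNRMSE(hidden$truth, res))
  # p3 has a single entry: excluded
  expect_false("p3" %in% names(pn))
  expect_true("p3" %in% attr(pn, "excluded"))
  # direct per-protein evaluation
  for (p in c("p1", "p2")) {
    sel <- hidden$truth@proteinIds == p
    tv <- hidden$truth@values[sel]
    expect_equal(unname(pn[p]),
                 sqrt(mean((99 - tv)^2) / popVarOracle(tv)))
  }
  # a perfect method yields zeros
  perfect <- mkResult(v, v)
  pnP <- suppressMessages(proteinNRMSE(hidden$truth, perfect))
  expect_true(all(pnP == 0))
})

test_that("SOR ranks methods per protein with average ties and conserves the rank sum", {
  # method A better on both proteins
  pm <- list(A = c(p1 = 0.1, p2 = 0.2), B = c(p1 = 0.3, p2 = 0.5))
  s <- sor(pm)
  expect_equal(unname(s["A"]), 2)
  expect_equal(unname(s["B"]), 4)
  # exact tie gets 1.5 each
  pmT <- list(A = c(p1 = 0.1, p2 = 0.4), B = c(p1 = 0.1, p2 = 0.2))
  sT <- sor(pmT)
  expect_equal(unname(sT["A"]), 1.5 + 2)
  expect_equal(unname(sT["B"]), 1.5 + 1)
  # rank-sum conservation on random reports, against the rank oracle
  set.seed(610)
  for (rep in 1:10) {
    M <- sample(2:5, 1); P <- sample(3:20, 1)
    tab <- matrix(rnorm(M * P, 1, 0.2), P, M,
                  dimnames = list(paste0("p", 1:P), paste0("m", 1:M)))
    pmR <- lapply(seq_len(M), function(j) tab[, j])
    names(pmR) <- colnames(tab)
    sR <- sor(pmR)
    expect_equal(sum(sR), P * M * (M + 1) / 2)
    oracle <- rowSums(sapply(seq_len(P), function(i) rankOracle(tab[i, ])))
    expect_equal(unname(sR), unname(oracle))
  }
  # misaligned protein sets error
  expect_error(sor(list(A = c(p1 = 1), B = c(p2 = 1))), "misaligned")
})

test_that("sweepParameters returns the argmin and the full table", {
  inj <- maskAt(randomAbundance(15, 30, missFrac = 0, seed = 620),
                which(matrix(runif(450) < 0.15, 15, 30), arr.ind = TRUE))
  # build a noiseless rank-2 matrix so the oracle rank wins
  set.seed(621)
  M <- matrix(rnorm(30), 15, 2) %*% t(matrix(rnorm(60), 30, 2))
  dimnames(M) <- list(paste0("s", 1:15), paste0("p", 1:30))
  x <- AbundanceMatrix(M, space = "log2")
  inj <- injectMCAR(x, 0.15, seed = 622)
  # rank 4 overfits the noiseless rank-2 data and oscillates at the tight
  # tolerance; the sweep still scores it
  sw <- suppressWarnings(sweepParameters("svdimpute",
                                         data.frame(rank = c(1, 2, 4)),
                                         inj$matrix, inj$truth))
  expect_equal(sw$best$rank, 2)
  expect_equal(nrow(sw$table), 3)
  # singleton grid returns its only point
  sw1 <- sweepParameters("mean", data.frame(dummy = 1), inj$matrix, inj$truth)
  expect_equal(nrow(sw1$table), 1)
  expect_error(sweepParameters("mean", data.frame(), inj$matrix, inj$truth),
               "empty grid")
})

test_that("runBenchmark produces the full report grid deterministically", {
  cfg <- list(data = list(m = 20, n = 60, k = 2, noiseSigma = 0.3),
              setting = 1, mechanism = "MCAR", rates = c(0.1, 0.3),
              methods = c("mean", "min2"), trials = 2, seed = 42)
  rep1 <- suppressWarnings(runBenchmark(cfg))
  expect_equal(nrow(rep1), 2 * 2 * 2)    # methods x rates x trials
  expect_true(all(c("rmse", "nrmse", "sor", "space") %in% colnames(rep1)))
  expect_true(all(rep1$space == "log2"))
  # SOR rank-sum conservation within each trial x rate cell
  for (tr in unique(rep1$trial)) for (rt in unique(rep1$rate)) {
    cell <- rep1[rep1$trial == tr & rep1$rate == rt, ]
    P <- sum(cell$sor) / 3               # M = 2 -> sum = P * 3
    expect_equal(P, round(P))
  }
  rep2 <- suppressWarnings(runBenchmark(cfg))
  expect_identical(rep1, rep2)
  expect_false(is.null(attr(rep1, "aggregate")))
})

test_that("runBenchmark supports setting-2 masking on authentic missingness", {
  cfg <- list(data = list(m = 20, n = 60, k = 2, noiseSigma = 0.3),
              setting = 2, rates = 0.1,
              authentic = list(mechanism = "MIX", alpha = 0.2, beta = 0.5),
              methods = c("mean", "swknn"), trials = 1, seed = 43)
  rep <- suppressWarnings(runBenchmark(cfg))
  expect_equal(nrow(rep), 2)
  expect_true(all(rep$mechanism == "MASK"))
  expect_true(all(is.finite(rep$nrmse)))
})
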