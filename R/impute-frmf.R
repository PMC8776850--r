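# Fused regularization matrix factorization: low-rank factorization of the
# observed entries with Frobenius (sparsity) penalties on both factors and an
# optional fused penalty pulling each sample's latent vector toward its
# similarity-defined neighbors.

#' Build sample neighborhoods from within-data cosine similarity
#'
#' Computes between-sample cosine similarity over mutually observed entries
#' and keeps, for each sample, the `t` most similar other samples. Pairs
#' sharing no observed protein are skipped; a sample with no valid pair gets
#' an empty neighborhood with a warning.
#'
#' @param x an [AbundanceMatrix-class] (typically protein-standardized).
#' @param t neighborhood size, default 5.
#' @return a [SimilarityContext-class] with `source = "self"`.
#' @export
buildSimilaritySelf <- function(x, t = 5) {
  .assertAbundanceMatrix(x)
  v <- x@values
  O <- !is.na(v)
  Z <- v; Z[!O] <- 0
  Om <- O * 1
  num <- Z %*% t(Z)                      # sums over mutually observed entries
  sq <- (Z * Z) %*% t(Om)                # ||x_i||^2 restricted to the overlap
  denom <- sqrt(sq * t(sq))
  shared <- Om %*% t(Om)
  sim <- num / denom
  sim[shared == 0 | denom == 0] <- NA
  .contextFromSimilarity(sim, t, "self", rownames(v))
}

#' Build sample neighborhoods from an external score table
#'
#' Cosine similarity over complete per-sample score vectors (for example
#' pathology grades), same neighborhood contract as [buildSimilaritySelf()].
#' Samples with a zero-norm score vector are excluded from all neighborhoods
#' with a warning.
#'
#' @param scores an [ExternalScores-class] aligned to the target matrix (see
#'   [alignScores()]).
#' @param t neighborhood size, default 5.
#' @return a [SimilarityContext-class] with `source = "external"`.
#' @export
buildSimilarityExternal <- function(scores, t = 5) {
  if (!is(scores, "ExternalScores"))
    stop("'scores' must be an ExternalScores object", call. = FALSE)
  P <- scores@scores
  nrm <- sqrt(rowSums(P^2))
  zero <- nrm == 0
  if (any(zero))
    warning(sprintf("%d sample(s) with zero-norm score vector excluded from neighborhoods",
                    sum(zero)))
  sim <- (P %*% t(P)) / outer(nrm, nrm)
  sim[zero, ] <- NA
  sim[, zero] <- NA
  .contextFromSimilarity(sim, t, "external", rownames(P))
}

.contextFromSimilarity <- function(sim, t, source, ids) {
  m <- nrow(sim)
  diag(sim) <- NA
  neighborhoods <- vector("list", m)
  similarities <- vector("list", m)
  isolated <- 0L
  for (i in seq_len(m)) {
    s <- sim[i, ]
    valid <- which(!is.na(s))
    if (!length(valid)) {
      isolated <- isolated + 1L
      neighborhoods[[i]] <- integer()
      similarities[[i]] <- numeric()
      next
    }
    ord <- valid[order(-s[valid], valid)]   # ties: smaller index first
    keep <- ord[seq_len(min(t, length(ord)))]
    neighborhoods[[i]] <- as.integer(keep)
    similarities[[i]] <- as.numeric(pmin(pmax(s[keep], -1), 1))
  }
  if (isolated > 0L)
    warning(sprintf("%d isolated sample(s): empty neighborhood", isolated))
  new("SimilarityContext", neighborhoods = neighborhoods,
      similarities = similarities, source = source, t = t,
      sampleIds = as.character(ids))
}

# directed-neighborhood Laplacian of the fused penalty
# sum_i sum_{k in F(i)} ||A_i - A_k||^2 = tr(A' L A)
.fusedLaplacian <- function(context, m) {
  B <- matrix(0, m, m)
  for (i in seq_along(context@neighborhoods))
    B[i, context@neighborhoods[[i]]] <- 1
  diag(rowSums(B) + colSums(B)) - B - t(B)
}

#' Objective and gradients of the fused-regularization factorization
#'
#' `frmfObjective()` evaluates the minimized criterion at factors `(A, S)`:
#' squared error over observed entries, plus `lambdaA * ||A||_F^2 +
#' lambdaS * ||S||_F^2`, plus `alphaFused` times the pairwise fused penalty
#' `sum_i sum_{k in F(i)} ||A_i - A_k||^2`. `frmfGradient()` returns the
#' exact analytic gradients with respect to `A` and `S` (verifiable by
#' finite differences).
#'
#' @param x an [AbundanceMatrix-class].
#' @param A,S factor matrices (`m x l` and `l x n`).
#' @param lambdaA,lambdaS Frobenius penalty weights.
#' @param alphaFused fused penalty weight (0 disables the fused term).
#' @param context a [SimilarityContext-class]; required when
#'   `alphaFused > 0`.
#' @return `frmfObjective()`: a scalar; `frmfGradient()`: a list with
#'   elements `A` and `S`.
#' @export
frmfObjective <- function(x, A, S, lambdaA, lambdaS, alphaFused = 0,
                          context = NULL) {
  v <- x@values
  O <- !is.na(v)
  E <- (v - A %*% S)
  E[!O] <- 0
  obj <- sum(E^2) + lambdaA * sum(A^2) + lambdaS * sum(S^2)
  if (alphaFused > 0) {
    L <- .fusedLaplacian(context, nrow(A))
    obj <- obj + alphaFused * sum(diag(crossprod(A, L %*% A)))
  }
  obj
}

#' @rdname frmfObjective
#' @export
frmfGradient <- function(x, A, S, lambdaA, lambdaS, alphaFused = 0,
                         context = NULL) {
  v <- x@values
  O <- !is.na(v)
  E <- (v - A %*% S)
  E[!O] <- 0
  gA <- -2 * E %*% t(S) + 2 * lambdaA * A
  gS <- -2 * crossprod(A, E) + 2 * lambdaS * S
  if (alphaFused > 0) {
    L <- .fusedLaplacian(context, nrow(A))
    gA <- gA + 2 * alphaFused * (L %*% A)
  }
  list(A = gA, S = gS)
}

# shared gradient-descent engine; fitRMF is the alphaFused = 0 special case
# and skips the fused term entirely so its trace is bitwise identical to an
# FRMF run with alpha = 0 under the same seed
.fitMF <- function(x, rank, lambdaA, lambdaS, alphaFused, context, step,
                   maxIter, tol, seed, method) {
  .assertAbundanceMatrix(x)
  v <- x@values
  .checkRank(v, rank)
  if (alphaFused > 0 && is.null(context))
    stop("a SimilarityContext is required when alphaFused > 0", call. = FALSE)
  if (!is.null(context) &&
      !identical(context@sampleIds, rownames(v)))
    stop("similarity context is not aligned to the matrix samples", call. = FALSE)
  m <- nrow(v); n <- ncol(v)
  miss <- is.na(v)
  O <- !miss

  # init: scaled truncated SVD of a mean-filled matrix plus seeded noise
  set.seed(seed)
  fillv <- v
  if (any(miss)) {
    colMean <- colMeans(v, na.rm = TRUE)
    colMean[!is.finite(colMean)] <- mean(v, na.rm = TRUE)
    fillv[miss] <- colMean[col(v)[miss]]
  }
  sv <- svd(fillv, nu = rank, nv = rank)
  d <- sqrt(sv$d[seq_len(rank)])
  A <- sv$u %*% diag(d, rank, rank)
  S <- diag(d, rank, rank) %*% t(sv$v)
  scaleA <- mean(abs(A))
  A <- A + matrix(stats::rnorm(m * rank, 0, 0.01 * max(scaleA, 1e-8)), m, rank)
  S <- S + matrix(stats::rnorm(rank * n, 0, 0.01 * max(mean(abs(S)), 1e-8)),
                  rank, n)

  L <- if (alphaFused > 0) .fusedLaplacian(context, m) else NULL
  # Lipschitz-motivated default step from the initial factors
  if (is.null(step)) {
    # at initialization sigma_max(A)^2 = sigma_max(S)^2 = d_1 of the filled
    # matrix, so 2*(2*d_1 + penalties) bounds the local gradient Lipschitz
    # constant; the halving rule guards against later growth
    lip <- 2 * (2 * sv$d[1] + max(lambdaA, lambdaS) +
                  if (alphaFused > 0) 2 * alphaFused * max(diag(L)) else 0)
    step <- 0.25 / lip
  }

  objAt <- function(A, S) {
    E <- v - A %*% S
    E[miss] <- 0
    o <- sum(E^2) + lambdaA * sum(A^2) + lambdaS * sum(S^2)
    if (alphaFused > 0) o <- o + alphaFused * sum(A * (L %*% A))
    list(obj = o, E = E)
  }

  cur <- objAt(A, S)
  trace <- cur$obj
  halvings <- 0L
  increases <- 0L
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    E <- cur$E
    gA <- -2 * E %*% t(S) + 2 * lambdaA * A
    if (alphaFused > 0) gA <- gA + 2 * alphaFused * (L %*% A)
    gS <- -2 * crossprod(A, E) + 2 * lambdaS * S
    A <- A - step * gA
    S <- S - step * gS
    cur <- objAt(A, S)
    trace <- c(trace, cur$obj)
    prev <- trace[length(trace) - 1L]
    if (cur$obj > prev) {
      increases <- increases + 1L
      if (increases >= 5L) {
        halvings <- halvings + 1L
        if (halvings > 10L)
          stop("gradient descent diverged after 10 step halvings", call. = FALSE)
        step <- step / 2
        increases <- 0L
      }
    } else {
      increases <- 0L
      if (abs(prev - cur$obj) < tol * max(prev, .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  dimnames(A) <- list(rownames(v), NULL)
  dimnames(S) <- list(NULL, colnames(v))
  new("FactorModel", A = A, S = S, rank = rank, lambdaA = lambdaA,
      lambdaS = lambdaS, alphaFused = alphaFused, objective = trace,
      converged = converged, step = step)
}

#' Fit a sparsity-regularized matrix factorization (RMF)
#'
#' Gradient descent on the observed-entry squared error with Frobenius
#' penalties on both factors, initialized from a scaled truncated SVD of a
#' mean-filled matrix perturbed by seed-controlled noise. The step size
#' defaults to a Lipschitz-motivated value and is halved (at most 10 times)
#' whenever the objective increases five iterations in a row.
#'
#' @param x an [AbundanceMatrix-class].
#' @param rank factorization rank `l < min(m, n)`.
#' @param lambdaA,lambdaS Frobenius penalty weights (default 0.1).
#' @param step gradient step size; `NULL` picks the default.
#' @param maxIter,tol iteration cap and relative objective tolerance.
#' @param seed integer seed controlling the initialization noise.
#' @return a [FactorModel-class].
#' @seealso [fitFRMF()], [imputeFromFactors()]
#' @export
fitRMF <- function(x, rank, lambdaA = 0.1, lambdaS = 0.1, step = NULL,
                   maxIter = 2000, tol = 1e-6, seed = 1) {
  .fitMF(x, rank, lambdaA, lambdaS, alphaFused = 0, context = NULL,
         step = step, maxIter = maxIter, tol = tol, seed = seed, method = "rmf")
}

#' Fit a fused-regularization matrix factorization (FRMF)
#'
#' Adds to [fitRMF()] a fused penalty
#' `alphaFused * sum_i sum_{k in F(i)} ||A_i - A_k||_F^2` that pulls each
#' sample's latent vector toward its neighbors, where the neighborhoods
#' `F(i)` come from within-data or external cosine similarity. With
#' `alphaFused = 0` the optimization path is identical to [fitRMF()] under
#' the same seed.
#'
#' @inheritParams fitRMF
#' @param context a [SimilarityContext-class] aligned to the samples of `x`.
#' @param alphaFused fused penalty weight.
#' @return a [FactorModel-class].
#' @export
fitFRMF <- function(x, context, alphaFused, rank, lambdaA = 0.1,
                    lambdaS = 0.1, step = NULL, maxIter = 2000, tol = 1e-6,
                    seed = 1) {
  .fitMF(x, rank, lambdaA, lambdaS, alphaFused = alphaFused,
         context = context, step = step, maxIter = maxIter, tol = tol,
         seed = seed, method = "frmf")
}

#' Impute missing entries from fitted factors
#'
#' Missing entries are replaced by the low-rank reconstruction `A %*% S` at
#' those positions; observed entries are preserved.
#'
#' @param x the [AbundanceMatrix-class] the model was fitted to.
#' @param model a [FactorModel-class].
#' @return an [ImputationResult-class].
#' @export
imputeFromFactors <- function(x, model) {
  .assertAbundanceMatrix(x)
  if (!is(model, "FactorModel")) stop("'model' must be a FactorModel", call. = FALSE)
  v <- x@values
  if (nrow(model@A) != nrow(v) || ncol(model@S) != ncol(v))
    stop("factor shapes do not match the matrix", call. = FALSE)
  rec <- model@A %*% model@S
  completed <- v
  completed[is.na(v)] <- rec[is.na(v)]
  method <- if (model@alphaFused > 0) "frmf" else "rmf"
  .makeResult(x, completed, method,
              list(rank = model@rank, lambdaA = model@lambdaA,
                   lambdaS = model@lambdaS, alphaFused = model@alphaFused))
}
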