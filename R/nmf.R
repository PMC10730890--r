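# multiplicative-update NMF (Frobenius objective): V (p x n) ~ W H
nmfFactorize <- function(V, K, seed, maxIter = 500, tol = 1e-5) {
  eps <- 1e-9
  p <- nrow(V); n <- ncol(V)
  set.seed(seed)
  W <- matrix(runif(p * K), p, K)
  H <- matrix(runif(K * n), K, n)
  errPrev <- Inf
  for (it in seq_len(maxIter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10 == 0 || it == maxIter) {
      err <- sqrt(sum((V - W %*% H)^2))
      if (is.finite(errPrev) && abs(errPrev - err) <= tol * max(errPrev, eps))
        break
      errPrev <- err
    }
  }
  list(W = W, H = H)
}

#' Consensus NMF clustering
#'
#' Runs \code{nRuns} non-negative matrix factorizations of the
#' (features x patients) data from seeded random initializations
#' (multiplicative updates minimizing Frobenius error, at most
#' \code{maxIter} iterations or a relative-change tolerance of
#' \code{tol}). Each run assigns every patient to the coefficient row
#' with the largest loading; the consensus matrix is the fraction of
#' runs in which two patients were co-assigned. Final labels come from
#' average-linkage hierarchical clustering of (1 - consensus) cut at K.
#'
#' @param X non-negative patients x features matrix (typically each
#'   feature min-max scaled to [0,1], see \code{\link{minMaxScale}}).
#' @param K number of clusters (2 <= K <= n).
#' @param nRuns number of factorization restarts (default 30).
#' @param seed integer seed.
#' @param maxIter,tol NMF stopping rule.
#' @return a \code{\link{SubtypeResult-class}} (labels in arbitrary
#'   order; see \code{\link{orderBySurvival}}), quality holds this K's
#'   cophenetic score and mean silhouette.
#' @export
nmfConsensus <- function(X, K, nRuns = 30, seed = 1, maxIter = 500,
                         tol = 1e-5) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(X < 0)) stop("NMF input must be non-negative")
  if (K < 2) stop("K must be at least 2")
  if (K > n) stop("K exceeds the number of patients")
  set.seed(seed)
  runSeeds <- sample.int(.Machine$integer.max - 1L, nRuns)
  V <- t(X)
  co <- matrix(0, n, n)
  for (r in seq_len(nRuns)) {
    fac <- nmfFactorize(V, K, seed = runSeeds[r], maxIter = maxIter,
                        tol = tol)
    lab <- max.col(t(fac$H), ties.method = "first")
    co <- co + outer(lab, lab, "==")
  }
  consensus <- co / nRuns
  dimnames(consensus) <- list(rownames(X), rownames(X))
  d <- as.dist(1 - consensus)
  hc <- hclust(d, method = "average")
  labels <- cutree(hc, k = K)
  coph <- suppressWarnings(cor(d, cophenetic(hc)))
  if (!is.finite(coph)) coph <- 0
  sil <- if (length(unique(labels)) > 1)
    mean(cluster::silhouette(labels, d)[, "sil_width"]) else NA_real_
  new("SubtypeResult", rank = as.integer(K),
      labels = setNames(as.integer(labels), rownames(X)),
      consensus = consensus,
      quality = data.frame(K = K, cophenetic = coph, silhouette = sil))
}

#' Min-max scale columns to [0, 1]
#'
#' @param X numeric matrix.
#' @return matrix with each column rescaled to [0,1] (constant columns
#'   map to 0).
#' @export
minMaxScale <- function(X) {
  apply(as.matrix(X), 2, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  })
}

#' NMF rank search
#'
#' Runs \code{\link{nmfConsensus}} for every candidate rank (default
#' 3..15) and scores each by the cophenetic correlation between the
#' consensus dissimilarity and its average-linkage cophenetic distances,
#' and by the mean silhouette of the labels under the consensus
#' dissimilarity. The chosen K maximizes the cophenetic score with
#' silhouette as the tie-breaker.
#'
#' @inheritParams nmfConsensus
#' @param kRange integer vector of candidate ranks (default \code{3:15}).
#' @return list: \code{quality} (data.frame K/cophenetic/silhouette),
#'   \code{bestK}, and \code{result} (the \code{SubtypeResult} at bestK).
#' @export
rankSearch <- function(X, kRange = 3:15, nRuns = 30, seed = 1,
                       maxIter = 500, tol = 1e-5) {
  stopifnot(length(kRange) >= 1, all(kRange >= 2))
  set.seed(seed)
  kSeeds <- sample.int(.Machine$integer.max - 1L, length(kRange))
  fits <- mapply(function(K, s)
    nmfConsensus(X, K, nRuns = nRuns, seed = s, maxIter = maxIter, tol = tol),
    kRange, kSeeds, SIMPLIFY = FALSE)
  quality <- do.call(rbind, lapply(fits, slot, "quality"))
  best <- order(-quality$cophenetic, -quality$silhouette)[1]
  res <- fits[[best]]
  res@quality <- quality
  list(quality = quality, bestK = kRange[best], result = res)
}
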