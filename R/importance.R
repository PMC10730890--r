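#' Hidden-node importance of the two-stage model
#'
#' Scores each of the stage-2 input nodes (the concatenated stage-1
#' hidden activations; 34 under the default sizing) by mean-masking: the
#' drop in the stage-2 partial log-likelihood when that node's column is
#' replaced by its cohort mean, with no refitting. A node whose stage-2
#' pathway is dead (all-zero weights) scores exactly 0. Set
#' \code{method = "permute"} for seeded permutation importance instead.
#'
#' @param model a fitted \code{\link{TwoStageModel-class}}.
#' @param Xsets named list of feature matrices, as used at fit time.
#' @param y the \code{\link{SurvivalOutcome}} used at fit time.
#' @param method \code{"mask"} (default) or \code{"permute"}.
#' @param seed seed for the permutation variant.
#' @return named numeric vector of per-node importances.
#' @export
hiddenImportance <- function(model, Xsets, y, method = c("mask", "permute"),
                             seed = 1) {
  method <- match.arg(method)
  Z <- do.call(cbind, mapply(hiddenOutputs, model@stage1, Xsets,
                             SIMPLIFY = FALSE))
  colnames(Z) <- unlist(lapply(names(model@stage1), function(nm)
    paste0(nm, "_h", seq_len(nrow(model@stage1[[nm]]@W)))))
  s2 <- model@stage2
  llOf <- function(Zm) coxPartialLogLik(
    as.numeric(hiddenOutputs(s2, Zm) %*% s2@beta), y)
  full <- llOf(Z)
  if (method == "permute") set.seed(seed)
  scores <- vapply(seq_len(ncol(Z)), function(j) {
    Zm <- Z
    Zm[, j] <- if (method == "mask") mean(Z[, j]) else sample(Z[, j])
    full - llOf(Zm)
  }, numeric(1))
  setNames(scores, colnames(Z))
}

#' Propagate hidden importance to the original features
#'
#' \deqn{\hat{O} = W^T \hat{H}} — the dot product of each input
#' feature's hidden-layer weights with the hidden importance vector.
#' Exactly linear in H.
#'
#' @param W hidden x input weight matrix (h x p).
#' @param H hidden importance vector (length h).
#' @return length-p numeric vector named by the input features.
#' @examples
#' propagateImportance(matrix(c(1, 3, 2, 4), 2, 2), c(1, 1))  # 4 6
#' @export
propagateImportance <- function(W, H) {
  if (length(H) != nrow(W))
    stop("shape mismatch: length(H) = ", length(H), " but nrow(W) = ", nrow(W))
  out <- as.numeric(crossprod(W, H))
  names(out) <- colnames(W)
  out
}

#' Split stage-2 node importances by origin and propagate per set
#'
#' Partitions the stage-2 node scores by the stage-1 model that produced
#' each node (6/17/11 under default sizing) and propagates each block
#' through that model's weight matrix, yielding one raw importance
#' vector per feature set on the original features (27/268/105 on the
#' post-drop default taxonomy).
#'
#' @param model a \code{\link{TwoStageModel-class}}.
#' @param hiddenScores output of \code{\link{hiddenImportance}} (length =
#'   total stage-1 hidden width, in stage order).
#' @return named list (one per feature set) of raw importance vectors
#'   over that set's original features.
#' @export
splitAndPropagate <- function(model, hiddenScores) {
  widths <- vapply(model@stage1, function(m) nrow(m@W), integer(1))
  if (length(hiddenScores) != sum(widths))
    stop("partition mismatch: ", length(hiddenScores), " scores vs hidden widths ",
         paste(widths, collapse = "+"))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1) + 1L)
  out <- lapply(seq_along(widths), function(k) {
    H <- hiddenScores[starts[k]:ends[k]]
    W <- model@stage1[[k]]@W
    colnames(W) <- model@stage1[[k]]@featureNames
    propagateImportance(W, H)
  })
  names(out) <- names(model@stage1)
  out
}

#' Normalize importances and select top features per set
#'
#' Within each feature set the absolute raw scores are min-max
#' normalized to [0, 1] (the propagated product can be negative; the
#' reported scores are magnitudes). Features with normalized score
#' strictly greater than the set's threshold are selected — defaults
#' 0.5 for the CP densities and 0.75 for the TMI and TCI interaction
#' sets — and the union across sets is returned, capped at \code{cap}
#' features by descending normalized score.
#'
#' @param importanceList named list of raw importance vectors (as from
#'   \code{\link{splitAndPropagate}}).
#' @param thresholds named numeric vector of per-set thresholds.
#' @param cap maximum number of selected features (default 50).
#' @return data.frame with columns \code{feature}, \code{set},
#'   \code{raw}, \code{normalized}, \code{selected}, ordered by set then
#'   descending score.
#' @export
normalizeAndSelect <- function(importanceList,
                               thresholds = c(CP = 0.5, TMI = 0.75, TCI = 0.75),
                               cap = 50) {
  stopifnot(length(importanceList) > 0)
  tabs <- lapply(names(importanceList), function(set) {
    raw <- importanceList[[set]]
    a <- abs(raw)
    rng <- range(a)
    if (diff(rng) == 0) {
      warning("constant importance vector in set ", set,
              "; all normalized scores set to 0")
      norm <- rep(0, length(a))
    } else {
      norm <- (a - rng[1]) / diff(rng)
    }
    thr <- if (set %in% names(thresholds)) thresholds[[set]] else 0.5
    data.frame(feature = names(raw), set = set, raw = unname(raw),
               normalized = norm, selected = norm > thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  if (sum(out$selected) > cap) {
    sel <- which(out$selected)
    keep <- sel[order(out$normalized[sel], decreasing = TRUE)][seq_len(cap)]
    out$selected <- FALSE
    out$selected[keep] <- TRUE
  }
  out[order(out$set, -out$normalized), ]
}
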