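#' Hidden layer sizing rule
#'
#' The hidden width of a one-stage Cox network is the square root of the
#' number of input features, rounded up: 27 inputs give 6 hidden nodes,
#' 268 give 17 and 105 give 11 (so the two-stage model sees
#' 6 + 17 + 11 = 34 inputs).
#'
#' @param p number of input features (>= 1).
#' @return integer hidden width, \code{ceiling(sqrt(p))}.
#' @examples
#' hiddenSize(27)   # 6
#' hiddenSize(268)  # 17
#' hiddenSize(105)  # 11
#' @export
hiddenSize <- function(p) {
  if (length(p) != 1 || !is.finite(p) || p < 1)
    stop("feature count must be a single integer >= 1")
  as.integer(ceiling(sqrt(p)))
}

#' Cox partial log-likelihood (Breslow ties)
#'
#' \deqn{\ell = \sum_{i: \delta_i = 1} \left( \eta_i -
#'   \log \sum_{j: t_j \ge t_i} e^{\eta_j} \right)}
#' Tied event times share one risk set (Breslow). The value is invariant
#' to adding a constant to all scores.
#'
#' @param pi per-patient risk scores (higher = higher hazard).
#' @param y a \code{\link{SurvivalOutcome}} aligned with \code{pi}.
#' @return scalar partial log-likelihood.
#' @export
coxPartialLogLik <- function(pi, y) {
  if (length(pi) != length(y@time)) stop("scores and outcome misaligned")
  if (any(!is.finite(pi))) stop("risk scores must be finite")
  if (sum(y@event) == 0) stop("no events: partial likelihood undefined")
  breslow(pi, y@time, y@event)$loglik
}

# value + gradient wrt eta of the Breslow partial log-likelihood
breslow <- function(eta, time, event) {
  ord <- order(time)
  eta <- eta[ord]; event <- event[ord]; time <- time[ord]
  es <- exp(eta - max(eta))
  riskRev <- rev(cumsum(rev(es)))
  grp <- cumsum(!duplicated(time))       # tie group index, ascending time
  first <- which(!duplicated(time))      # first index of each group
  Sgrp <- riskRev[first]                 # risk-set sum per tie group
  dgrp <- as.numeric(tapply(event, grp, sum))
  loglik <- sum(event * (eta - max(eta))) - sum(dgrp * log(Sgrp))
  # d l / d eta_k = delta_k - e^{eta_k} * sum_{groups g <= group(k)} d_g / S_g
  cumTerm <- cumsum(dgrp / Sgrp)
  grad <- event - es * cumTerm[grp]
  g <- numeric(length(eta)); g[ord] <- grad
  list(loglik = loglik, grad = g)
}

unpackParams <- function(par, h, p) {
  W <- matrix(par[seq_len(h * p)], h, p)
  b <- par[h * p + seq_len(h)]
  beta <- par[h * p + h + seq_len(h)]
  list(W = W, b = b, beta = beta)
}

#' Fit a one-stage Cox network
#'
#' Maximizes the Breslow partial log-likelihood of the prognostic index
#' \eqn{\beta^T \tanh(W x + b)} minus an L2 penalty on all parameters,
#' by full-batch L-BFGS with analytic gradients. Columns are z-scored
#' with statistics of the supplied (training) data; constant columns map
#' to 0. Initialization is small uniform, controlled by \code{seed}, so
#' identical data and seed reproduce identical parameters.
#'
#' When \code{l2 = NULL} the penalty is chosen on an inner 75/25
#' validation split (stratified by event) over \code{l2Grid} by held-out
#' concordance, then the model is refitted on all rows.
#'
#' @param X numeric matrix, patients x features.
#' @param y a \code{\link{SurvivalOutcome}} aligned with the rows of X.
#' @param l2 L2 penalty weight, or \code{NULL} to select from
#'   \code{l2Grid}.
#' @param seed integer seed for initialization (and the inner split).
#' @param hidden hidden width; default \code{hiddenSize(ncol(X))}.
#' @param standardize z-score columns (default TRUE).
#' @param maxit maximum L-BFGS iterations.
#' @param l2Grid candidate penalties for selection.
#' @return a fitted \code{\link{CoxNet-class}} object.
#' @export
fitCoxNet <- function(X, y, l2 = 0.1, seed = 1, hidden = NULL,
                      standardize = TRUE, maxit = 2000,
                      l2Grid = c(0.01, 0.1, 1)) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n != length(y@time)) stop("X rows and outcome misaligned")
  if (n < 10) stop("need at least 10 patients")
  if (sum(y@event) < 3) stop("need at least 3 events")
  if (is.null(hidden)) hidden <- hiddenSize(p)

  if (is.null(l2)) {
    set.seed(seed)
    idxVal <- stratifiedSample(y@event, frac = 0.25)
    tr <- setdiff(seq_len(n), idxVal)
    perf <- vapply(l2Grid, function(lam) {
      m <- fitCoxNet(X[tr, , drop = FALSE], y[tr], l2 = lam, seed = seed,
                     hidden = hidden, standardize = standardize,
                     maxit = maxit)
      tryCatch(cIndex(predictRisk(m, X[idxVal, , drop = FALSE]), y[idxVal]),
               error = function(e) NA_real_)
    }, numeric(1))
    l2 <- l2Grid[which.max(perf)]
    return(fitCoxNet(X, y, l2 = l2, seed = seed, hidden = hidden,
                     standardize = standardize, maxit = maxit))
  }

  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
  } else {
    ctr <- rep(0, p); scl <- rep(1, p)
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  h <- as.integer(hidden)
  time <- y@time; event <- y@event

  fn <- function(par) {
    pr <- unpackParams(par, h, p)
    Z <- tanh(Xs %*% t(pr$W) + rep(pr$b, each = n))
    eta <- as.numeric(Z %*% pr$beta)
    -(breslow(eta, time, event)$loglik) + l2 * sum(par^2)
  }
  gr <- function(par) {
    pr <- unpackParams(par, h, p)
    Zpre <- Xs %*% t(pr$W) + rep(pr$b, each = n)
    Z <- tanh(Zpre)
    eta <- as.numeric(Z %*% pr$beta)
    g <- breslow(eta, time, event)$grad
    dPre <- (g %o% pr$beta) * (1 - Z^2)
    dW <- -(t(dPre) %*% Xs)
    db <- -colSums(dPre)
    dbeta <- -as.numeric(crossprod(Z, g))
    c(as.numeric(dW), db, dbeta) + 2 * l2 * par
  }

  set.seed(seed)
  par0 <- c(runif(h * p, -1, 1) / sqrt(p), rep(0, h), runif(h, -0.1, 0.1))
  fit <- optim(par0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e7))
  if (!all(is.finite(fit$par)))
    stop("Cox network fit diverged: non-finite parameters (l2 = ", l2,
         ", value = ", fit$value, ")")
  pr <- unpackParams(fit$par, h, p)
  new("CoxNet", W = pr$W, b = pr$b, beta = pr$beta, activation = "tanh",
      l2 = l2, featureNames = colnames(X) %||% paste0("f", seq_len(p)),
      center = ctr, scale = scl, logLik = -fit$value,
      converged = fit$convergence == 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stratifiedSample <- function(event, frac) {
  pick <- function(idx) sample(idx, max(1L, round(length(idx) * frac)))
  sort(c(pick(which(event == 1)), pick(which(event == 0))))
}

#' Hidden-layer activations
#'
#' Applies the model's standardization and hidden layer:
#' \code{tanh(Xs W' + b)}. These activations are the inputs the
#' second-stage model is trained on.
#'
#' @param model a fitted \code{\link{CoxNet-class}}.
#' @param X patients x features matrix with \code{ncol(X) == ncol(W)}.
#' @return n x h matrix.
#' @export
hiddenOutputs <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@W))
    stop("width mismatch: model expects ", ncol(model@W), " features, got ",
         ncol(X))
  Xs <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  Z <- tanh(Xs %*% t(model@W) + rep(model@b, each = nrow(X)))
  if (any(!is.finite(Z))) stop("non-finite hidden activations")
  Z
}

#' Prognostic index of a fitted survival model
#'
#' @param model a \code{CoxNet}, \code{TwoStageModel} or Cox baseline.
#' @param X for a \code{CoxNet}: a feature matrix; for a
#'   \code{TwoStageModel}: a named list of matrices (one per stage-1
#'   feature set, same order/names as at fit time).
#' @return numeric vector, higher = higher predicted hazard.
#' @aliases predictRisk
#' @export
setGeneric("predictRisk", function(model, X) standardGeneric("predictRisk"))

#' @export
setMethod("predictRisk", "CoxNet", function(model, X) {
  as.numeric(hiddenOutputs(model, X) %*% model@beta)
})

#' @export
setMethod("predictRisk", "TwoStageModel", function(model, X) {
  if (!is.list(X) || length(X) != length(model@stage1))
    stop("X must be a list with one matrix per stage-1 model")
  nms <- names(model@stage1)
  if (!is.null(names(X)) && all(nms %in% names(X))) X <- X[nms]
  Z <- do.call(cbind, mapply(hiddenOutputs, model@stage1, X,
                             SIMPLIFY = FALSE))
  as.numeric(hiddenOutputs(model@stage2, Z) %*% model@stage2@beta)
})

#' Fit the two-stage Cox network
#'
#' Trains one \code{CoxNet} per feature set, freezes them, concatenates
#' their hidden activations and trains a second-stage \code{CoxNet} on
#' the concatenation (hidden width \code{hiddenSize} of the combined
#' width). By default the stage-2 inputs are the raw tanh activations;
#' set \code{restandardize = TRUE} to z-score them first.
#'
#' @param Xsets named list of patients x features matrices (e.g.
#'   \code{list(CP = ..., TMI = ..., TCI = ...)}), rows aligned.
#' @param y a \code{\link{SurvivalOutcome}}.
#' @param l2 penalty for every stage (scalar, or \code{NULL} to select
#'   per stage).
#' @param seed integer seed.
#' @param restandardize z-score stage-2 inputs (default FALSE).
#' @param ... passed to \code{\link{fitCoxNet}}.
#' @return a \code{\link{TwoStageModel-class}}.
#' @export
fitTwoStage <- function(Xsets, y, l2 = 0.1, seed = 1,
                        restandardize = FALSE, ...) {
  ns <- vapply(Xsets, nrow, integer(1))
  if (length(unique(ns)) != 1 || ns[1] != length(y@time))
    stop("patient misalignment across feature sets and outcome")
  rn <- lapply(Xsets, rownames)
  if (!all(vapply(rn, function(r) is.null(r) || identical(r, rn[[1]]),
                  logical(1))))
    stop("patient misalignment: row names differ across feature sets")
  stage1 <- mapply(function(X, k) fitCoxNet(X, y, l2 = l2, seed = seed + k, ...),
                   Xsets, seq_along(Xsets), SIMPLIFY = FALSE)
  names(stage1) <- names(Xsets)
  Z <- do.call(cbind, mapply(hiddenOutputs, stage1, Xsets, SIMPLIFY = FALSE))
  colnames(Z) <- unlist(lapply(names(stage1), function(nm)
    paste0(nm, "_h", seq_len(nrow(stage1[[nm]]@W)))))
  stage2 <- fitCoxNet(Z, y, l2 = l2, seed = seed,
                      standardize = restandardize, ...)
  new("TwoStageModel", stage1 = stage1, stage2 = stage2)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs (the patient with the shorter
#' follow-up had an observed event, and the times differ) in which the
#' higher predicted risk belongs to the earlier failure; tied risk
#' scores count 0.5.
#'
#' @param pi predicted risk scores.
#' @param y a \code{\link{SurvivalOutcome}}.
#' @return concordance in [0, 1].
#' @export
cIndex <- function(pi, y) {
  if (length(pi) != length(y@time)) stop("scores and outcome misaligned")
  t <- y@time; e <- y@event
  earlier <- outer(t, t, "<") & matrix(e == 1, length(t), length(t))
  nComp <- sum(earlier)
  if (nComp == 0) stop("no comparable pairs")
  conc <- sum(earlier & outer(pi, pi, ">")) +
    0.5 * sum(earlier & outer(pi, pi, "=="))
  conc / nComp
}

#' Clinical Cox proportional-hazards baseline
#'
#' Standard linear Cox model on the encoded clinical covariates
#' (ER, PR, HER2 status and tumor grade), the comparator for the
#' feature-based networks.
#'
#' @param clinical data.frame with columns \code{er}, \code{pr},
#'   \code{her2} (0/1) and \code{grade}.
#' @param y a \code{\link{SurvivalOutcome}} aligned with the rows.
#' @return list with the \code{coxph} fit (\code{$fit}) and training
#'   prognostic indices (\code{$pi}); class \code{"coxBaseline"}.
#' @export
fitCoxBaseline <- function(clinical, y) {
  dat <- data.frame(time = y@time, event = y@event,
                    er = clinical$er, pr = clinical$pr,
                    her2 = clinical$her2, grade = clinical$grade)
  fit <- survival::coxph(survival::Surv(time, event) ~ er + pr + her2 + grade,
                         data = dat)
  if (any(!is.finite(coef(fit))))
    stop("Cox baseline did not converge (separation?)")
  structure(list(fit = fit,
                 pi = unname(predict(fit, type = "lp"))),
            class = "coxBaseline")
}

#' @rdname fitCoxBaseline
#' @param model a \code{coxBaseline}.
#' @param clinicalNew new clinical rows to score.
#' @export
predictBaseline <- function(model, clinicalNew) {
  unname(predict(model$fit, newdata = clinicalNew, type = "lp"))
}

#' Repeated-split model comparison
#'
#' Repeatedly splits the cohort into train/test (default 80/20,
#' stratified by event status), fits each requested model on the
#' training split and evaluates Harrell's C on the held-out split.
#' Splits with fewer than 3 training or 1 test events are resampled with
#' a warning.
#'
#' @param Xsets named list of feature matrices (\code{CP}, \code{TMI},
#'   \code{TCI}).
#' @param clinical clinical covariate data.frame.
#' @param y a \code{\link{SurvivalOutcome}}.
#' @param models subset of
#'   \code{c("coxph", "CP", "TMI", "TCI", "twostage")}.
#' @param nRepeats number of independent splits (default 20).
#' @param trainFrac training fraction (default 0.8).
#' @param seed integer seed.
#' @param l2 penalty passed to the network fits.
#' @param ... passed to \code{\link{fitCoxNet}} / \code{\link{fitTwoStage}}.
#' @return data.frame with columns \code{model}, \code{rep},
#'   \code{c_index}.
#' @export
evaluateModels <- function(Xsets, clinical, y,
                           models = c("coxph", "CP", "TMI", "TCI", "twostage"),
                           nRepeats = 20, trainFrac = 0.8, seed = 1,
                           l2 = 0.1, ...) {
  n <- length(y@time)
  res <- list()
  set.seed(seed)
  for (r in seq_len(nRepeats)) {
    repeat {
      tr <- stratifiedSample(y@event, frac = trainFrac)
      te <- setdiff(seq_len(n), tr)
      if (sum(y@event[tr]) >= 3 && sum(y@event[te]) >= 1 &&
          length(te) >= 2) break
      warning("too few events in a split; resampling")
    }
    ytr <- y[tr]; yte <- y[te]
    for (m in models) {
      ci <- tryCatch({
        if (m == "coxph") {
          bl <- fitCoxBaseline(clinical[tr, , drop = FALSE], ytr)
          cIndex(predictBaseline(bl, clinical[te, , drop = FALSE]), yte)
        } else if (m == "twostage") {
          fitted <- fitTwoStage(lapply(Xsets, function(X) X[tr, , drop = FALSE]),
                                ytr, l2 = l2, seed = seed + r, ...)
          cIndex(predictRisk(fitted,
                             lapply(Xsets, function(X) X[te, , drop = FALSE])),
                 yte)
        } else {
          fitted <- fitCoxNet(Xsets[[m]][tr, , drop = FALSE], ytr, l2 = l2,
                              seed = seed + r, ...)
          cIndex(predictRisk(fitted, Xsets[[m]][te, , drop = FALSE]), yte)
        }
      }, error = function(e) NA_real_)
      res[[length(res) + 1L]] <- data.frame(model = m, rep = r, c_index = ci)
    }
  }
  do.call(rbind, res)
}
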