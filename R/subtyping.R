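kmGroupStats <- function(time, event, tmax) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(sf$surv <= 0.5)) min(sf$time[sf$surv <= 0.5]) else Inf
  sEnd <- summary(sf, times = tmax, extend = TRUE)$surv
  c(median = med, sEnd = sEnd)
}

#' Renumber subtypes by decreasing survival
#'
#' Clusters are relabelled 1..K so that subtype 1 has the best survival:
#' ordering is by decreasing Kaplan-Meier median survival, with the
#' survival probability at the last observed follow-up time as the
#' tie-breaker (groups whose KM curve never reaches 0.5 sort first).
#' The output is invariant to any permutation of the input label ids.
#'
#' @param x a \code{\link{SubtypeResult-class}} or an integer label
#'   vector.
#' @param y a \code{\link{SurvivalOutcome}} aligned with the labels.
#' @return the same type as \code{x}, with labels renumbered.
#' @export
orderBySurvival <- function(x, y) {
  labels <- if (is(x, "SubtypeResult")) x@labels else x
  if (length(labels) != length(y@time)) stop("labels and outcome misaligned")
  ids <- sort(unique(labels))
  tmax <- max(y@time)
  stats <- vapply(ids, function(g) {
    sel <- labels == g
    kmGroupStats(y@time[sel], y@event[sel], tmax)
  }, numeric(2))
  ord <- ids[order(-stats["median", ], -stats["sEnd", ])]
  newLab <- match(labels, ord)
  names(newLab) <- names(labels)
  if (is(x, "SubtypeResult")) {
    x@labels <- setNames(as.integer(newLab), names(labels))
    x
  } else newLab
}

#' Kaplan-Meier curves and multi-group log-rank test
#'
#' Product-limit survival estimates per group plus the (K-1)-df log-rank
#' test of equality of the K survival curves.
#'
#' @param labels group labels (>= 2 groups).
#' @param y a \code{\link{SurvivalOutcome}}.
#' @return list: \code{curves} (data.frame group/time/n_risk/n_event/
#'   surv), \code{chisq}, \code{df}, \code{p}.
#' @export
kmLogrank <- function(labels, y) {
  if (length(unique(labels)) < 2)
    stop("log-rank test needs at least two groups")
  dat <- data.frame(time = y@time, event = y@event,
                    group = factor(labels))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1
  p <- pchisq(sd$chisq, df, lower.tail = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  strata <- rep(names(sf$strata), sf$strata)
  curves <- data.frame(group = sub("^group=", "", strata), time = sf$time,
                       n_risk = sf$n.risk, n_event = sf$n.event,
                       surv = sf$surv)
  list(curves = curves, chisq = unname(sd$chisq), df = df, p = p)
}

#' Concordance of a subtype stratification
#'
#' Harrell's C using the survival-ordered subtype index itself as the
#' risk score (subtype 1 = lowest risk).
#'
#' @param labels survival-ordered subtype labels.
#' @param y a \code{\link{SurvivalOutcome}}.
#' @return concordance in [0, 1].
#' @export
stratificationCindex <- function(labels, y) cIndex(as.numeric(labels), y)

#' Molecular subtype from receptor status
#'
#' Clinical breast cancer classes from ER/PR/HER2 status alone:
#' TNBC = ER-/PR-/HER2-; HER2-enriched = ER-/PR-/HER2+;
#' Luminal A = (ER+ or PR+)/HER2-; Luminal B = (ER+ or PR+)/HER2+.
#' Rows with any missing status are labelled \code{Unknown}.
#'
#' @param clinical data.frame with 0/1 columns \code{er}, \code{pr},
#'   \code{her2}.
#' @return factor with levels Luminal A, Luminal B, HER2-enriched,
#'   TNBC, Unknown.
#' @export
molecularSubtype <- function(clinical) {
  er <- clinical$er; pr <- clinical$pr; her2 <- clinical$her2
  out <- rep("Unknown", nrow(clinical))
  known <- !(is.na(er) | is.na(pr) | is.na(her2))
  hrPos <- er == 1 | pr == 1
  out[known & !hrPos & her2 == 0] <- "TNBC"
  out[known & !hrPos & her2 == 1] <- "HER2-enriched"
  out[known & hrPos & her2 == 0] <- "Luminal A"
  out[known & hrPos & her2 == 1] <- "Luminal B"
  factor(out, levels = c("Luminal A", "Luminal B", "HER2-enriched", "TNBC",
                         "Unknown"))
}

significanceMark <- function(p) {
  # convention follows the source figure legend: "*" is the stronger mark
  ifelse(p < 0.01, "*", ifelse(p < 0.05, "**", ""))
}

#' Characterize subtypes by feature enrichment
#'
#' Each feature is min-max normalized over the cohort; for every
#' (subtype, feature) pair a two-sided Mann-Whitney U test compares the
#' subtype's patients against all others, with Benjamini-Hochberg FDR
#' adjustment across all tests. Significance marks follow the
#' convention \code{"*"}: p < 0.01, \code{"**"}: 0.01 < p < 0.05
#' (note the inverted ordering; kept as published). Constant features
#' are skipped with a note.
#'
#' @param X patients x features matrix.
#' @param labels subtype labels aligned with rows of X.
#' @return data.frame: subtype, feature, median_norm, U, p, p_adj,
#'   mark, note.
#' @export
characterizeSubtypes <- function(X, labels) {
  X <- as.matrix(X)
  if (nrow(X) != length(labels)) stop("features and labels misaligned")
  Xn <- minMaxScale(X)
  constant <- apply(X, 2, function(v) diff(range(v)) == 0)
  rows <- list()
  for (s in sort(unique(labels))) {
    inGrp <- labels == s
    for (j in seq_len(ncol(X))) {
      if (constant[j]) {
        rows[[length(rows) + 1L]] <- data.frame(
          subtype = s, feature = colnames(X)[j],
          median_norm = median(Xn[inGrp, j]), U = NA_real_, p = NA_real_,
          note = "constant feature: test skipped")
        next
      }
      wt <- suppressWarnings(wilcox.test(Xn[inGrp, j], Xn[!inGrp, j],
                                         exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = s, feature = colnames(X)[j],
        median_norm = median(Xn[inGrp, j]), U = unname(wt$statistic),
        p = wt$p.value, note = "")
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p)
  out$p_adj[tested] <- p.adjust(out$p[tested], method = "BH")
  out$mark <- ifelse(tested, significanceMark(out$p_adj), "")
  out[, c("subtype", "feature", "median_norm", "U", "p", "p_adj", "mark",
          "note")]
}

#' Within-subtype feature correlation network
#'
#' For every subtype with at least \code{minSize} patients, pairwise
#' Spearman correlations between features; pairs with rho above
#' \code{threshold} are emitted as an edge table (the data behind a
#' Circos-style plot). Smaller subtypes and constant features are
#' skipped with a note.
#'
#' @param X patients x features matrix.
#' @param labels subtype labels.
#' @param threshold correlation cutoff (default 0.5).
#' @param minSize minimum subtype size (default 3).
#' @return list: \code{edges} (subtype, feature1, feature2, rho),
#'   \code{skipped} (character notes).
#' @export
correlationNetwork <- function(X, labels, threshold = 0.5, minSize = 3) {
  X <- as.matrix(X)
  edges <- list(); skipped <- character()
  for (s in sort(unique(labels))) {
    idx <- which(labels == s)
    if (length(idx) < minSize) {
      skipped <- c(skipped, paste0("subtype ", s, ": fewer than ", minSize,
                                   " patients, skipped"))
      next
    }
    Xi <- X[idx, , drop = FALSE]
    ok <- apply(Xi, 2, function(v) diff(range(v)) > 0)
    if (sum(ok) < 2) next
    rho <- suppressWarnings(cor(Xi[, ok, drop = FALSE], method = "spearman"))
    ut <- which(upper.tri(rho) & rho > threshold, arr.ind = TRUE)
    if (nrow(ut))
      edges[[length(edges) + 1L]] <- data.frame(
        subtype = s, feature1 = rownames(rho)[ut[, 1]],
        feature2 = colnames(rho)[ut[, 2]],
        rho = rho[ut], stringsAsFactors = FALSE)
  }
  list(edges = if (length(edges)) do.call(rbind, edges) else
         data.frame(subtype = integer(0), feature1 = character(0),
                    feature2 = character(0), rho = numeric(0)),
       skipped = skipped)
}

#' Dichotomized survival comparison within clinical classes
#'
#' Collapses the survival-ordered subtypes into a good-survival arm
#' (default subtypes 1-4) and a bad-survival arm (the rest; 5-7 at
#' K = 7), then runs a two-group log-rank test within each molecular
#' subtype, alongside the full subtype x molecular-class contingency
#' table (the data behind a Sankey diagram).
#'
#' @param labels survival-ordered subtype labels.
#' @param clinical clinical data.frame (er/pr/her2 columns).
#' @param y a \code{\link{SurvivalOutcome}}.
#' @param good subtype indices forming the good-survival arm.
#' @param bad subtype indices for the bad arm; default all others.
#' @return list: \code{tests} (data.frame molecular_subtype, n_good,
#'   n_bad, chisq, p, computable), \code{crosstab} (subtype x molecular
#'   class table).
#' @export
dichotomizeAndCompare <- function(labels, clinical, y, good = 1:4,
                                  bad = NULL) {
  if (is.null(bad)) bad <- setdiff(sort(unique(labels)), good)
  mol <- molecularSubtype(clinical)
  arm <- ifelse(labels %in% good, "good",
                ifelse(labels %in% bad, "bad", NA))
  tests <- do.call(rbind, lapply(levels(droplevels(mol)), function(ms) {
    sel <- mol == ms & !is.na(arm)
    ng <- sum(arm[sel] == "good"); nb <- sum(arm[sel] == "bad")
    if (ng == 0 || nb == 0)
      return(data.frame(molecular_subtype = ms, n_good = ng, n_bad = nb,
                        chisq = NA_real_, p = NA_real_, computable = FALSE))
    lr <- kmLogrank(arm[sel], y[which(sel)])
    data.frame(molecular_subtype = ms, n_good = ng, n_bad = nb,
               chisq = lr$chisq, p = lr$p, computable = TRUE)
  }))
  list(tests = tests, crosstab = table(subtype = labels, molecular = mol))
}
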