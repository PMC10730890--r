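#' Pseudo-bulk expression profiles
#'
#' Per-patient arithmetic mean of each marker over all the patient's
#' cells — the single-cell cohort's proxy for bulk expression, used for
#' cross-cohort matching.
#'
#' @param cellExpr data.frame with columns \code{cell_id},
#'   \code{patient_id} and one numeric column per marker.
#' @param patients optional expected patient ids; those with no cells
#'   are excluded with a warning.
#' @return patients x markers numeric matrix.
#' @export
pseudoBulk <- function(cellExpr, patients = NULL) {
  markers <- setdiff(names(cellExpr), c("cell_id", "patient_id"))
  if (!length(markers)) stop("no marker columns found")
  if (anyNA(cellExpr[markers])) stop("every cell must have all marker values")
  sp <- split(cellExpr[markers], cellExpr$patient_id)
  out <- t(vapply(sp, function(d) colMeans(as.matrix(d)),
                  numeric(length(markers))))
  colnames(out) <- markers
  if (!is.null(patients)) {
    missing <- setdiff(patients, rownames(out))
    if (length(missing))
      warning("patient(s) with zero cells excluded: ",
              paste(missing, collapse = ", "))
    out <- out[intersect(patients, rownames(out)), , drop = FALSE]
  }
  out
}

#' Harmonize protein markers with external gene symbols
#'
#' Intersects the internal protein-marker panel with an external gene
#' list under a protein-to-gene name map (case-insensitive), reporting
#' the proteins that found no counterpart.
#'
#' @param markers internal protein marker names.
#' @param genes external gene symbols.
#' @param map data.frame with columns \code{protein}, \code{gene};
#'   markers absent from the map are matched by their own name.
#' @return list: \code{shared} (data.frame protein/gene for retained
#'   markers), \code{dropped} (proteins without an external match).
#' @export
harmonizeMarkers <- function(markers, genes, map = NULL) {
  mapped <- markers
  if (!is.null(map)) {
    hit <- match(tolower(markers), tolower(map$protein))
    mapped[!is.na(hit)] <- map$gene[hit[!is.na(hit)]]
  }
  found <- match(tolower(mapped), tolower(genes))
  keep <- !is.na(found)
  if (!any(keep)) stop("no shared features between cohorts")
  list(shared = data.frame(protein = markers[keep],
                           gene = genes[found[keep]],
                           stringsAsFactors = FALSE),
       dropped = markers[!keep])
}

correlationDistance <- function(source, target) {
  zs <- scale(source); zt <- scale(target)
  zs[!is.finite(zs)] <- 0; zt[!is.finite(zt)] <- 0
  1 - cor(t(zs), t(zt))
}

#' Match patients across cohorts
#'
#' Computes a cross-cohort patient-patient distance on the shared
#' (z-scored per cohort) features — by default one minus the Pearson
#' correlation of the two expression profiles — and retains the closest
#' pairs at a similarity cutoff: cutoff 0.995 keeps the 0.5\% smallest
#' of all cross distances (\code{mode = "global"}), or of each source
#' patient's distances (\code{mode = "per-source"}). Any external
#' pairwise-distance provider can be plugged in via \code{distanceFun}.
#'
#' @param source patients x features matrix (e.g. \code{\link{pseudoBulk}}
#'   output restricted to shared features).
#' @param target external patients x features matrix on the same
#'   features.
#' @param cutoff similarity cutoff in (0, 1]; larger keeps fewer pairs.
#' @param mode quantile applied over all cross pairs or per source
#'   patient.
#' @param distanceFun optional \code{function(source, target)} returning
#'   an nSource x nTarget distance matrix.
#' @return a \code{\link{MatchResult-class}}.
#' @export
matchPatients <- function(source, target, cutoff = 0.995,
                          mode = c("global", "per-source"),
                          distanceFun = NULL) {
  mode <- match.arg(mode)
  if (cutoff <= 0 || cutoff > 1) stop("cutoff must be in (0, 1]")
  if (ncol(source) != ncol(target) || ncol(source) < 3)
    stop("cohorts must share at least 3 features (same columns)")
  D <- if (is.null(distanceFun)) correlationDistance(source, target)
       else distanceFun(source, target)
  rn <- rownames(source) %||% paste0("s", seq_len(nrow(source)))
  cn <- rownames(target) %||% paste0("t", seq_len(nrow(target)))
  keepSmallest <- function(d, k) {
    if (k <= 0) return(integer(0))
    order(d)[seq_len(min(k, length(d)))]
  }
  if (mode == "global") {
    k <- ceiling(length(D) * (1 - cutoff) - 1e-9)
    idx <- keepSmallest(as.numeric(D), k)
    pairs <- data.frame(
      source = rn[(idx - 1) %% nrow(D) + 1],
      target = cn[(idx - 1) %/% nrow(D) + 1],
      distance = as.numeric(D)[idx], stringsAsFactors = FALSE)
  } else {
    k <- ceiling(ncol(D) * (1 - cutoff) - 1e-9)
    pairs <- do.call(rbind, lapply(seq_len(nrow(D)), function(i) {
      j <- keepSmallest(D[i, ], k)
      if (!length(j)) return(NULL)
      data.frame(source = rn[i], target = cn[j], distance = D[i, j],
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs))
      pairs <- data.frame(source = character(0), target = character(0),
                          distance = numeric(0))
  }
  new("MatchResult", pairs = pairs, cutoff = cutoff,
      cutoffDistance = if (nrow(pairs)) max(pairs$distance) else NA_real_)
}

#' Survival of matched vs unmatched external patients
#'
#' Two-group log-rank comparison of the external patients matched to an
#' internal subpopulation against the remaining external patients
#' (optionally within a stratum, e.g. one molecular subtype).
#'
#' @param matches a \code{\link{MatchResult-class}}.
#' @param externalY \code{\link{SurvivalOutcome}} of the external cohort.
#' @param stratum optional character vector of external patient ids to
#'   restrict to.
#' @return list: \code{computable}, and when TRUE \code{chisq},
#'   \code{df}, \code{p}, \code{curves}, \code{groups} (named
#'   matched/other membership).
#' @export
compareMatchedSurvival <- function(matches, externalY, stratum = NULL) {
  ids <- patientIds(externalY)
  if (!is.null(stratum)) ids <- intersect(ids, stratum)
  matched <- intersect(unique(matches@pairs$target), ids)
  other <- setdiff(ids, matched)
  if (!length(matched) || !length(other))
    return(list(computable = FALSE,
                reason = "matched or unmatched arm is empty"))
  grp <- ifelse(ids %in% matched, "matched", "other")
  lr <- kmLogrank(grp, externalY[ids])
  c(list(computable = TRUE, groups = setNames(grp, ids)), lr)
}

#' Differential markers between two patient groups
#'
#' Per-marker two-sided Wilcoxon rank-sum test between the two groups,
#' BH-adjusted across markers, with the sign of the median difference as
#' the effect direction. Constant markers are skipped.
#'
#' @param groupA,groupB patient ids (rownames of \code{expression}).
#' @param expression patients x markers matrix.
#' @return data.frame: marker, direction (+1 up in A, -1 up in B, 0),
#'   p, p_adj, note.
#' @export
differentialMarkers <- function(groupA, groupB, expression) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("need at least 3 patients per group")
  A <- expression[groupA, , drop = FALSE]
  B <- expression[groupB, , drop = FALSE]
  rows <- lapply(colnames(expression), function(m) {
    va <- A[, m]; vb <- B[, m]
    if (diff(range(c(va, vb))) == 0)
      return(data.frame(marker = m, direction = 0, p = NA_real_,
                        note = "constant marker: skipped"))
    wt <- suppressWarnings(wilcox.test(va, vb, exact = FALSE))
    data.frame(marker = m, direction = sign(median(va) - median(vb)),
               p = wt$p.value, note = "")
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  tested <- !is.na(out$p)
  out$p_adj[tested] <- p.adjust(out$p[tested], method = "BH")
  out[, c("marker", "direction", "p", "p_adj", "note")]
}
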