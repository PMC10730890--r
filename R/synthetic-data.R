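#' Canonical feature names
#'
#' Feature columns are named \code{CP_<phenotype>} for per-area phenotype
#' densities and \code{CCIS_<a>__<b>} for pairwise interaction scores,
#' with the pair in palette order so that (a,b) and (b,a) share a name.
#'
#' @param a,b phenotype labels.
#' @param palette a \code{\link{PhenotypePalette}} fixing the order.
#' @return scalar character feature name.
#' @export
ccisFeatureName <- function(a, b, palette) {
  ord <- match(c(a, b), phenotypes(palette))
  if (anyNA(ord)) stop("phenotype not in palette: ", a, " / ", b)
  pair <- c(a, b)[order(ord)]
  paste0("CCIS_", pair[1], "__", pair[2])
}

#' @rdname ccisFeatureName
#' @param phenotype a phenotype label.
#' @export
densityFeatureName <- function(phenotype) paste0("CP_", phenotype)

defaultMixtures <- function(palette, nSubtypes) {
  ph <- phenotypes(palette)
  base <- rep(1, length(ph))
  names(base) <- ph
  # each latent subtype over-represents a distinct epithelial program plus
  # an accompanying immune/stromal context
  boosts <- list(
    c(CK7_CK_hi_Cadherin_hi_Epithelial = 8, Small_Elongated_Fibroblast = 4,
      Small_Circular_Fibroblast = 3, T_and_B_Cells = 3),
    c(Luminal_CK_Epithelial = 8, CK_hi_HR_hi_Epithelial = 5,
      Vim_hi_Fibroblast = 3, T_Cells = 2),
    c(Hypoxic_Epithelial = 8, Macrophage_2 = 5, Vim_hi_Fibroblast = 2,
      Epithelial_low_Expression = 3),
    c(Proliferative_Epithelial = 9, Basal_CK_Epithelial = 4,
      Macrophage_1 = 3, B_Cells = 2),
    c(HER2_hi_Epithelial = 8, CK_hi_HR_low_Epithelial = 4, Endothelial = 3),
    c(CK_low_HR_low_Epithelial = 8, Myofibroblast = 4, Vim_hi_Immune = 3))
  mix <- lapply(seq_len(nSubtypes), function(s) {
    w <- base
    bo <- boosts[[((s - 1L) %% length(boosts)) + 1L]]
    keep <- intersect(names(bo), ph)
    w[keep] <- w[keep] + bo[keep]
    w / sum(w)
  })
  names(mix) <- paste0("S", seq_len(nSubtypes))
  mix
}

defaultClinicalProbs <- function(nSubtypes) {
  # P(positive) per receptor and P(grade 3), conditional on latent subtype;
  # early subtypes skew hormone-receptor-positive / low grade, late ones
  # triple-negative-like / high grade so clinical cross-tabulations are
  # non-degenerate
  base <- rbind(
    c(er = 0.85, pr = 0.75, her2 = 0.10, grade3 = 0.10),
    c(er = 0.80, pr = 0.70, her2 = 0.30, grade3 = 0.25),
    c(er = 0.35, pr = 0.30, her2 = 0.25, grade3 = 0.50),
    c(er = 0.15, pr = 0.10, her2 = 0.20, grade3 = 0.70))
  base[((seq_len(nSubtypes) - 1L) %% nrow(base)) + 1L, , drop = FALSE]
}

#' Synthetic cohort configuration
#'
#' Bundles and validates all knobs of the synthetic cohort generator.
#' Defaults define the reference simulation used throughout the package
#' tests: 1000x1000 um images, spatially clustered cellular communities,
#' patient composition driven by latent subtypes, and exponential
#' proportional-hazards survival whose log-hazard is a linear function of
#' z-scored planted density/interaction features.
#'
#' @param nPatients number of patients.
#' @param nLatentSubtypes number of latent compositional subtypes.
#' @param communitiesPerPatient integer range (min, max) of cellular
#'   communities per image.
#' @param cellsPerCommunity integer range (min, max) of cells per
#'   community.
#' @param communitySpread std dev (um) of the isotropic Gaussian cell
#'   scatter around each community center.
#' @param neighborRadius direct-neighbor distance threshold (um).
#' @param boxSize side length (um) of the square image.
#' @param phenotypeMixtures list (one per subtype) of multinomial
#'   probability vectors over the palette; each must sum to 1.
#' @param effectVector named numeric vector of log-hazard coefficients
#'   per standard deviation of the named feature
#'   (\code{CP_*} / \code{CCIS_*__*} names).
#' @param baselineHazard exponential baseline hazard rate per month.
#' @param censoringWindow months; censoring times are uniform on
#'   (0, censoringWindow].
#' @param clinicalProbs matrix (subtype x \{er, pr, her2, grade3\}) of
#'   Bernoulli probabilities for the clinical covariates.
#' @param palette a \code{\link{PhenotypePalette}}.
#' @param seed integer RNG seed.
#' @return a validated \code{simConfig} list.
#' @examples
#' cfg <- simConfig(nPatients = 5, seed = 1)
#' @export
simConfig <- function(nPatients = 200, nLatentSubtypes = 4,
                      communitiesPerPatient = c(5L, 10L),
                      cellsPerCommunity = c(30L, 80L),
                      communitySpread = 15, neighborRadius = 4,
                      boxSize = 1000,
                      phenotypeMixtures = NULL,
                      effectVector = NULL,
                      baselineHazard = 0.01, censoringWindow = 120,
                      clinicalProbs = NULL,
                      palette = defaultPalette(), seed = 1L) {
  if (is.null(phenotypeMixtures))
    phenotypeMixtures <- defaultMixtures(palette, nLatentSubtypes)
  if (is.null(clinicalProbs))
    clinicalProbs <- defaultClinicalProbs(nLatentSubtypes)
  if (is.null(effectVector)) {
    ph <- phenotypes(palette)
    effectVector <- c(0.7, 0.5, -0.4, 0.5)
    names(effectVector) <- c(
      densityFeatureName("Proliferative_Epithelial"),
      densityFeatureName("Hypoxic_Epithelial"),
      densityFeatureName("T_and_B_Cells"),
      ccisFeatureName("T_and_B_Cells", "Proliferative_Epithelial", palette))
  }
  if (neighborRadius <= 0) stop("neighborRadius must be positive")
  if (baselineHazard <= 0) stop("baselineHazard must be positive")
  if (censoringWindow <= 0) stop("censoringWindow must be positive")
  if (length(phenotypeMixtures) != nLatentSubtypes)
    stop("need one phenotype mixture per latent subtype")
  for (m in phenotypeMixtures) {
    if (length(m) == 0 || all(m == 0)) stop("empty phenotype mixture")
    if (abs(sum(m) - 1) > 1e-8) stop("each phenotype mixture must sum to 1")
    if (!all(names(m) %in% phenotypes(palette)) && !is.null(names(m)))
      stop("mixture names must be palette phenotypes")
  }
  cfg <- list(nPatients = as.integer(nPatients),
              nLatentSubtypes = as.integer(nLatentSubtypes),
              communitiesPerPatient = as.integer(communitiesPerPatient),
              cellsPerCommunity = as.integer(cellsPerCommunity),
              communitySpread = communitySpread,
              neighborRadius = neighborRadius, boxSize = boxSize,
              phenotypeMixtures = phenotypeMixtures,
              effectVector = effectVector,
              baselineHazard = baselineHazard,
              censoringWindow = censoringWindow,
              clinicalProbs = clinicalProbs,
              palette = palette, seed = as.integer(seed))
  class(cfg) <- "simConfig"
  cfg
}

#' Generate a synthetic single-cell survival cohort
#'
#' Per patient, community centers are sampled uniformly in the square
#' image, cell positions are Gaussian around their community center, and
#' phenotypes are drawn from the patient's latent-subtype mixture.
#' Survival times are exponential with hazard
#' \code{baselineHazard * exp(lp)} where \code{lp} is the inner product of
#' the effect vector with the patient's z-scored true feature values
#' (computed from the generated image with the same density/CCIS
#' definitions the analysis uses); censoring is uniform and independent.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a list with elements \code{images} (list of
#'   \code{\link{PatientImage}}), \code{clinical} (data.frame with binary
#'   er/pr/her2 flags and grade), \code{survival}
#'   (\code{\link{SurvivalOutcome}}), \code{truth} (list: subtypeOf,
#'   trueEffects, trueFeatures, trueLinearPredictor), \code{palette},
#'   \code{config}.
#' @examples
#' coh <- generateCohort(simConfig(nPatients = 4, seed = 7,
#'   cellsPerCommunity = c(10L, 20L), communitiesPerPatient = c(2L, 3L)))
#' length(coh$images)
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  pal <- config$palette
  ph <- phenotypes(pal)
  n <- config$nPatients
  ids <- sprintf("P%03d", seq_len(n))
  subtype <- sample.int(config$nLatentSubtypes, n, replace = TRUE)

  images <- vector("list", n)
  for (i in seq_len(n)) {
    nComm <- sample(seq(config$communitiesPerPatient[1],
                        config$communitiesPerPatient[2]), 1)
    centers <- cbind(runif(nComm, 0, config$boxSize),
                     runif(nComm, 0, config$boxSize))
    mix <- config$phenotypeMixtures[[subtype[i]]]
    prob <- rep(0, length(ph)); names(prob) <- ph
    if (is.null(names(mix))) prob[] <- mix else prob[names(mix)] <- mix
    cells <- do.call(rbind, lapply(seq_len(nComm), function(k) {
      nc <- sample(seq(config$cellsPerCommunity[1],
                       config$cellsPerCommunity[2]), 1)
      data.frame(x_um = rnorm(nc, centers[k, 1], config$communitySpread),
                 y_um = rnorm(nc, centers[k, 2], config$communitySpread))
    }))
    cells$cell_id <- sprintf("%s_c%04d", ids[i], seq_len(nrow(cells)))
    cells$phenotype <- sample(ph, nrow(cells), replace = TRUE, prob = prob)
    images[[i]] <- PatientImage(ids[i],
      cells[, c("cell_id", "x_um", "y_um", "phenotype")],
      areaUm2 = config$boxSize^2, neighborRadius = config$neighborRadius)
  }
  names(images) <- ids

  cp <- config$clinicalProbs[subtype, , drop = FALSE]
  clinical <- data.frame(
    patient_id = ids,
    er = as.integer(runif(n) < cp[, "er"]),
    pr = as.integer(runif(n) < cp[, "pr"]),
    her2 = as.integer(runif(n) < cp[, "her2"]),
    grade = ifelse(runif(n) < cp[, "grade3"], 3L,
                   sample(1:2, n, replace = TRUE)),
    stringsAsFactors = FALSE)

  eff <- config$effectVector
  eff <- eff[eff != 0]
  if (length(eff)) {
    trueFeatures <- vapply(images, patientFeatureValues,
                           numeric(length(eff)), names(eff), pal)
    trueFeatures <- matrix(trueFeatures, nrow = length(eff),
                           dimnames = list(names(eff), ids))
    z <- t(scale(t(trueFeatures)))
    z[!is.finite(z)] <- 0  # constant feature across cohort carries no signal
    lp <- as.numeric(crossprod(z, eff))
  } else {
    trueFeatures <- matrix(numeric(0), nrow = 0, ncol = n,
                           dimnames = list(NULL, ids))
    lp <- rep(0, n)
  }
  names(lp) <- ids

  death <- rexp(n, rate = config$baselineHazard * exp(lp))
  cens <- runif(n, 0, config$censoringWindow)
  surv <- SurvivalOutcome(ids, pmax(pmin(death, cens), 1e-6),
                          as.integer(death <= cens))

  list(images = images, clinical = clinical, survival = surv,
       truth = list(subtypeOf = setNames(subtype, ids),
                    trueEffects = config$effectVector,
                    trueFeatures = trueFeatures,
                    trueLinearPredictor = lp),
       palette = pal, config = config)
}

# evaluate named CP_/CCIS_ features on one image
patientFeatureValues <- function(image, featureNames, palette) {
  dens <- NULL; cc <- NULL
  vapply(featureNames, function(fn) {
    if (startsWith(fn, "CP_")) {
      if (is.null(dens)) dens <<- phenotypeDensity(image, palette)
      if (!fn %in% names(dens)) stop("unknown density feature: ", fn)
      unname(dens[fn])
    } else if (startsWith(fn, "CCIS_")) {
      if (is.null(cc)) cc <<- ccis(image, palette)
      if (!fn %in% names(cc)) stop("unknown interaction feature: ", fn)
      unname(cc[fn])
    } else stop("unknown feature name: ", fn)
  }, numeric(1))
}
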