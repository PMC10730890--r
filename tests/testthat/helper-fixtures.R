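# shared fixtures, computed lazily and cached for the whole test run
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# strong planted-signal study conditions: per-SD log-hazard coefficients
# large enough that the generative linear predictor is clearly prognostic
strongEffects <- function(palette = defaultPalette()) {
  c(setNames(1.5, densityFeatureName("Proliferative_Epithelial")),
    setNames(1.0, densityFeatureName("Hypoxic_Epithelial")),
    setNames(-0.5, densityFeatureName("T_and_B_Cells")),
    setNames(0.8, ccisFeatureName("T_and_B_Cells", "Proliferative_Epithelial",
                                  palette)))
}

strongConfig <- function(n = 300, seed = 101)
  simConfig(nPatients = n, seed = seed,
            communitiesPerPatient = c(4L, 6L), cellsPerCommunity = c(20L, 50L),
            effectVector = strongEffects())

strongCohortFeatures <- function() fixture("strongCF", function() {
  coh <- generateCohort(strongConfig())
  fm <- dropZeroFeatures(assembleFeatures(coh$images, coh$palette))
  list(cohort = coh, fm = fm,
       Xsets = list(CP = featureSetMatrix(fm, "CP"),
                    TMI = featureSetMatrix(fm, "TMI"),
                    TCI = featureSetMatrix(fm, "TCI")))
})

nullConfig <- function(n = 400, seed = 202)
  simConfig(nPatients = n, seed = seed,
            communitiesPerPatient = c(2L, 3L), cellsPerCommunity = c(8L, 16L),
            effectVector = c(CP_Proliferative_Epithelial = 0))

# small images for fast unit tests
tinyCohort <- function() fixture("tinyCohort", function()
  generateCohort(simConfig(nPatients = 12, seed = 42,
                           communitiesPerPatient = c(2L, 3L),
                           cellsPerCommunity = c(10L, 20L))))

toyPalette <- function()
  PhenotypePalette(c("a", "b", "c"),
                   c(a = "immune", b = "stromal", c = "epithelial"))

toyImage <- function(x, y, phen, area = 100, radius = 4, id = "pt")
  PatientImage(id, data.frame(cell_id = paste0("c", seq_along(x)),
                              x_um = x, y_um = y, phenotype = phen),
               areaUm2 = area, neighborRadius = radius)

randomImage <- function(n, seed, palette = toyPalette(), box = 60,
                        radius = 4, area = box^2) {
  set.seed(seed)
  toyImage(runif(n, 0, box), runif(n, 0, box),
           sample(phenotypes(palette), n, replace = TRUE),
           area = area, radius = radius)
}

# --- independent oracles -------------------------------------------------

# O(n^2) radius-graph edge list
bruteForceEdges <- function(x, y, r) {
  n <- length(x)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= r)
      out <- rbind(out, c(i, j))
  out
}

# CCIS by direct loops: union-find components, per-node triangle-count
# clustering, per-community pair counts
bruteForceCCIS <- function(image, palette) {
  cells <- cellTable(image)
  n <- nrow(cells)
  r <- image@neighborRadius
  edges <- bruteForceEdges(cells$x_um, cells$y_um, r)
  adj <- lapply(seq_len(n), function(i) integer(0))
  if (!is.null(edges)) for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- rep(NA_integer_, n); cid <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1; queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][is.na(comp[adj[[v]]])])
    }
  }
  localC <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    if (length(nb) < 2) return(0)
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && nb[b] %in% adj[[nb[a]]]) links <- links + 1
    2 * links / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  A <- imageArea(image)
  pairs <- enumeratePairs(palette)
  scores <- setNames(numeric(nrow(pairs)), pairs$feature)
  for (k in unique(comp)) {
    members <- which(comp == k)
    C <- mean(localC[members])
    if (is.null(edges)) next
    for (e in seq_len(nrow(edges))) {
      if (comp[edges[e, 1]] != k) next
      nm <- ccisFeatureName(cells$phenotype[edges[e, 1]],
                            cells$phenotype[edges[e, 2]], palette)
      scores[nm] <- scores[nm] + C / A
    }
  }
  scores
}

# risk-set-by-risk-set Breslow partial log-likelihood
bruteForcePLL <- function(pi, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(pi[d]) - length(d) * log(sum(exp(pi[risk])))
  }
  ll
}

# exhaustive comparable-pair concordance
bruteForceCIndex <- function(pi, time, event) {
  num <- 0; den <- 0
  n <- length(pi)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !(time[i] < time[j] && event[i] == 1)) next
    den <- den + 1
    num <- num + if (pi[i] > pi[j]) 1 else if (pi[i] == pi[j]) 0.5 else 0
  }
  num / den
}

# planted-block non-negative matrix for NMF recovery tests
plantedBlocks <- function(nPerBlock = 15, K = 4, p = 12, noise = 0.05,
                          seed = 1) {
  set.seed(seed)
  lab <- rep(seq_len(K), each = nPerBlock)
  centers <- matrix(0.05, K, p)
  for (k in seq_len(K))
    centers[k, ((k - 1) * floor(p / K) + 1):(k * floor(p / K))] <- 1
  X <- centers[lab, ] + matrix(abs(rnorm(length(lab) * p, 0, noise)),
                               ncol = p)
  rownames(X) <- paste0("pt", seq_along(lab))
  list(X = X, labels = lab)
}

adjRandIndex <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sumij <- comb2(tab)
  sumA <- comb2(rowSums(tab)); sumB <- comb2(colSums(tab))
  expIdx <- sumA * sumB / choose(sum(tab), 2)
  (sumij - expIdx) / ((sumA + sumB) / 2 - expIdx)
}
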