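test_that("consensus NMF recovers well-separated planted blocks", {
  pb <- plantedBlocks(nPerBlock = 12, K = 2, p = 8, noise = 0.05, seed = 3)
  res <- nmfConsensus(pb$X, K = 2, nRuns = 15, seed = 7)
  expect_equal(adjRandIndex(subtypeLabels(res), pb$labels), 1)
  cm <- consensusMatrix(res)
  within <- cm[pb$labels == 1, pb$labels == 1]
  across <- cm[pb$labels == 1, pb$labels == 2]
  expect_gt(min(within), 0.9)
  expect_lt(max(across), 0.1)
})

test_that("consensus matrix is a valid co-assignment frequency matrix", {
  pb <- plantedBlocks(nPerBlock = 8, K = 3, p = 9, noise = 0.2, seed = 5)
  res <- nmfConsensus(pb$X, K = 3, nRuns = 7, seed = 2)
  cm <- consensusMatrix(res)
  expect_equal(cm, t(cm))
  expect_equal(unname(diag(cm)), rep(1, nrow(cm)))
  expect_true(all(cm >= 0 & cm <= 1))

  single <- nmfConsensus(pb$X, K = 3, nRuns = 1, seed = 2)
  expect_true(all(consensusMatrix(single) %in% c(0, 1)))

  # duplicated patients are always co-assigned
  Xd <- rbind(pb$X, pb$X[1, , drop = FALSE])
  rownames(Xd) <- c(rownames(pb$X), "dup")
  resd <- nmfConsensus(Xd, K = 3, nRuns = 7, seed = 2)
  expect_equal(consensusMatrix(resd)["pt1", "dup"], 1)
  expect_equal(subtypeLabels(resd)[["pt1"]], subtypeLabels(resd)[["dup"]])

  expect_error(nmfConsensus(-pb$X, K = 2), "non-negative")
  expect_error(nmfConsensus(pb$X, K = nrow(pb$X) + 1), "exceeds")
  # labels invariant to patient-order permutation (up to relabeling)
  set.seed(9)
  perm <- sample(nrow(pb$X))
  resp <- nmfConsensus(pb$X[perm, ], K = 3, nRuns = 7, seed = 2)
  expect_equal(adjRandIndex(subtypeLabels(resp),
                            subtypeLabels(res)[perm]), 1)
})

test_that("rank search scores crisp structure with cophenetic 1 and finds planted K", {
  pb <- plantedBlocks(nPerBlock = 12, K = 4, p = 12, noise = 0.05, seed = 11)
  rs <- rankSearch(pb$X, kRange = 3:6, nRuns = 8, seed = 13)
  expect_equal(nrow(rs$quality), 4)
  expect_equal(rs$bestK, 4)
  expect_equal(rs$quality$cophenetic[rs$quality$K == 4], 1, tolerance = 0.02)
})

test_that("subtypes are renumbered by decreasing Kaplan-Meier survival", {
  # disjoint survival: group A lives 50-60, group B lives 5-15
  y <- SurvivalOutcome(paste0("p", 1:20),
                       c(seq(50, 60, length.out = 10),
                         seq(5, 15, length.out = 10)),
                       rep(1L, 20))
  labels <- setNames(rep(c(7L, 2L), each = 10), paste0("p", 1:20))
  out <- orderBySurvival(labels, y)
  expect_equal(unname(out[1:10]), rep(1L, 10))
  expect_equal(unname(out[11:20]), rep(2L, 10))
  # invariance to the input label ids
  relab <- setNames(rep(c(1L, 9L), each = 10), paste0("p", 1:20))
  expect_equal(orderBySurvival(relab, y), out)

  # three-cluster toy with hand-computed KM medians 30 / 20 / 10
  y3 <- SurvivalOutcome(paste0("q", 1:9),
                        c(10, 11, 9, 20, 21, 19, 30, 31, 29), rep(1L, 9))
  lab3 <- setNames(c(3L, 3L, 3L, 1L, 1L, 1L, 2L, 2L, 2L), paste0("q", 1:9))
  out3 <- orderBySurvival(lab3, y3)
  expect_equal(unname(out3), c(3L, 3L, 3L, 2L, 2L, 2L, 1L, 1L, 1L))
})

test_that("multi-group log-rank matches hand computation and null behavior", {
  # identical survival in both groups: statistic ~ 0
  t0 <- c(5, 10, 15, 20, 25)
  y <- SurvivalOutcome(paste0("p", 1:10), rep(t0, 2), rep(1L, 10))
  lr <- kmLogrank(rep(c("A", "B"), each = 5), y)
  expect_lt(lr$chisq, 1e-10)
  expect_equal(lr$df, 1)

  # two-group toy: observed - expected computed by hand over event times
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  grp <- c("A", "A", "B", "B", "A", "B")
  yh <- SurvivalOutcome(paste0("h", 1:6), time, event)
  obsA <- sum(event[grp == "A"])
  expA <- 0
  for (t in time[event == 1]) {
    atRisk <- time >= t
    expA <- expA + sum(atRisk & grp == "A") / sum(atRisk) *
      sum(time == t & event == 1)
  }
  lrh <- kmLogrank(grp, yh)
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  expect_equal(unname(sd$obs[1] - sd$exp[1]), obsA - expA)
  expect_equal(lrh$chisq, unname(sd$chisq))
  expect_equal(lrh$p, pchisq(sd$chisq, 1, lower.tail = FALSE))

  # KM curves start at 1 at the first event time at the latest
  expect_true(all(lrh$curves$surv <= 1))
  expect_error(kmLogrank(rep("A", 6), yh), "two groups")
})

test_that("log-rank statistic is chi-square distributed under the null", {
  set.seed(77)
  stats <- replicate(150, {
    y <- SurvivalOutcome(paste0("p", 1:45), rexp(45, 0.1),
                         rbinom(45, 1, 0.8))
    kmLogrank(rep(1:3, each = 15), y)$chisq
  })
  # compare empirical quantiles with chi-square(2)
  qs <- quantile(stats, c(0.25, 0.5, 0.75))
  ref <- qchisq(c(0.25, 0.5, 0.75), df = 2)
  expect_lt(max(abs(qs - ref)), 0.75)
  expect_gt(suppressWarnings(ks.test(stats, pchisq, df = 2)$p.value), 0.01)
})

test_that("stratification concordance treats the subtype index as the risk score", {
  y <- SurvivalOutcome(paste0("p", 1:12), 12:1, rep(1L, 12))
  # fully prognostic ordering (one patient per subtype) gives C = 1
  expect_equal(stratificationCindex(1:12, y), 1)
  # grouped labels: within-subtype pairs are tied scores, counted 0.5
  perfect <- rep(1:4, each = 3)
  expect_equal(stratificationCindex(perfect, y),
               bruteForceCIndex(perfect, y@time, y@event))
  set.seed(5)
  shuffled <- sample(perfect)
  expect_equal(stratificationCindex(shuffled, y),
               bruteForceCIndex(shuffled, y@time, y@event))
})

test_that("molecular subtype classification follows receptor definitions", {
  clin <- data.frame(er = c(0, 0, 1, 0, 1, NA),
                     pr = c(0, 0, 1, 1, 0, 1),
                     her2 = c(0, 1, 0, 1, 1, 0))
  out <- molecularSubtype(clin)
  expect_equal(as.character(out),
               c("TNBC", "HER2-enriched", "Luminal A", "Luminal B",
                 "Luminal B", "Unknown"))
})

test_that("subtype characterization normalizes, tests and adjusts correctly", {
  set.seed(19)
  n <- 60
  labels <- rep(1:2, each = n / 2)
  X <- cbind(shifted = c(rnorm(n / 2, 3), rnorm(n / 2, 0)),
             flat = rnorm(n),
             const = rep(1, n))
  tab <- characterizeSubtypes(X, labels)
  expect_true(all(tab$p_adj >= tab$p, na.rm = TRUE))
  expect_lt(tab$p_adj[tab$feature == "shifted" & tab$subtype == 1], 0.01)
  expect_equal(tab$mark[tab$feature == "shifted" & tab$subtype == 1], "*")
  expect_gt(tab$p[tab$feature == "flat" & tab$subtype == 1], 0.05)
  constRows <- tab[tab$feature == "const", ]
  expect_true(all(constRows$note != ""))
  expect_true(all(is.na(constRows$p)))
  # min-max normalization bounds the reported medians
  expect_true(all(tab$median_norm >= 0 & tab$median_norm <= 1))
})

test_that("correlation networks use Spearman rank correlation within subtypes", {
  set.seed(23)
  n <- 20
  base <- rnorm(n)
  X <- cbind(a = base, b = exp(base), c = rnorm(n))  # b monotone in a
  labels <- rep(1L, n)
  net <- correlationNetwork(X, labels, threshold = 0.5)
  ab <- net$edges[net$edges$feature1 == "a" & net$edges$feature2 == "b", ]
  expect_equal(ab$rho, 1)  # rank correlation is transform invariant

  # hand computation on 5 points
  x5 <- c(3, 1, 4, 1.5, 5); y5 <- c(2, 0.5, 2.5, 3, 4)
  handRho <- 1 - 6 * sum((rank(x5) - rank(y5))^2) / (5 * (5^2 - 1))
  X5 <- cbind(u = x5, v = y5, w = 5:1)
  net5 <- correlationNetwork(X5, rep(1L, 5), threshold = -1.1)
  uv <- net5$edges[net5$edges$feature1 == "u" & net5$edges$feature2 == "v", ]
  expect_equal(uv$rho, handRho)

  # undersized subtypes are skipped with a note
  netSmall <- correlationNetwork(X, rep(1:10, 2), minSize = 3)
  expect_length(netSmall$skipped, 10)
})

test_that("dichotomized comparison tests good vs bad arms within clinical classes", {
  set.seed(29)
  n <- 160
  labels <- sample(1:7, n, replace = TRUE)
  clin <- data.frame(er = rbinom(n, 1, 0.6), pr = rbinom(n, 1, 0.5),
                     her2 = rbinom(n, 1, 0.3))
  bad <- labels >= 5
  time <- rexp(n, 0.02 * exp(1.5 * bad))
  cens <- runif(n, 0, 100)
  y <- SurvivalOutcome(paste0("p", 1:n), pmin(time, cens),
                       as.integer(time <= cens))
  out <- dichotomizeAndCompare(labels, clin, y)
  expect_equal(unname(rowSums(out$crosstab)),
               as.integer(table(factor(labels, 1:7))))
  mol <- molecularSubtype(clin)
  big <- names(which.max(table(mol)))
  expect_lt(out$tests$p[out$tests$molecular_subtype == big], 0.05)

  # swapping the arms only relabels the groups: same test statistic
  swap <- dichotomizeAndCompare(labels, clin, y, good = 5:7, bad = 1:4)
  expect_equal(swap$tests$chisq, out$tests$chisq, tolerance = 1e-12)

  # empty arm is flagged not-computable
  out2 <- dichotomizeAndCompare(rep(1L, n), clin, y, good = 1:4)
  expect_true(all(!out2$tests$computable))
})
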