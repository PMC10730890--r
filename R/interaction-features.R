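#' Build the cell neighborhood graph
#'
#' Direct neighbors are cells whose centroids lie within
#' \code{neighborRadius} micrometres of each other (inclusive threshold:
#' a pair exactly at the radius is an edge). Cellular communities are the
#' connected components of this radius graph — the locally connected
#' groups of cells that interaction scoring iterates over.
#'
#' @param image a \code{\link{PatientImage}}.
#' @param radius optional override of the image's neighbor radius (um).
#' @return an \code{igraph} undirected graph with vertex attributes
#'   \code{name} (cell id), \code{phenotype} and \code{community}.
#' @examples
#' img <- PatientImage("p1", data.frame(cell_id = c("a", "b"),
#'   x_um = c(0, 3), y_um = c(0, 0), phenotype = c("A", "B")), areaUm2 = 10)
#' igraph::ecount(buildNeighborGraph(img))
#' @export
buildNeighborGraph <- function(image, radius = NULL) {
  cells <- image@cells
  if (nrow(cells) == 0) stop("empty image: no cells to build a graph on")
  r <- if (is.null(radius)) image@neighborRadius else radius
  if (r <= 0) stop("radius must be positive")
  xy <- cbind(cells$x_um, cells$y_um)
  n <- nrow(xy)
  # grid-bucketed neighbor search: only adjacent buckets can hold cells
  # within r, so the all-pairs scan is confined to local blocks
  gx <- floor(xy[, 1] / r); gy <- floor(xy[, 2] / r)
  key <- paste(gx, gy)
  buckets <- split(seq_len(n), key)
  edges <- vector("list", length(buckets))
  bkey <- do.call(rbind, strsplit(names(buckets), " "))
  bx <- as.numeric(bkey[, 1]); by <- as.numeric(bkey[, 2])
  lookup <- new.env(hash = TRUE)
  for (i in seq_along(buckets)) assign(names(buckets)[i], i, envir = lookup)
  r2 <- r * r
  out <- list(); oi <- 0L
  for (i in seq_along(buckets)) {
    idx <- buckets[[i]]
    cand <- idx
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      j <- mget(paste(bx[i] + dx, by[i] + dy), envir = lookup,
                ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) cand <- c(cand, buckets[[j]])
    }
    if (length(cand) < 2) next
    for (a in idx) {
      b <- cand[cand > a]
      if (!length(b)) next
      d2 <- (xy[b, 1] - xy[a, 1])^2 + (xy[b, 2] - xy[a, 2])^2
      hit <- b[d2 <= r2]
      if (length(hit)) {
        oi <- oi + 1L
        out[[oi]] <- rbind(a, hit)
      }
    }
  }
  el <- if (oi > 0) {
    m <- do.call(cbind, out[seq_len(oi)])
    t(m)
  } else matrix(integer(0), ncol = 2)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- cells$cell_id
  igraph::V(g)$phenotype <- cells$phenotype
  igraph::V(g)$community <- igraph::components(g)$membership
  g
}

#' Per-community statistics for interaction scoring
#'
#' For every cellular community (connected component of the neighbor
#' graph) computes the clustering coefficient \eqn{C} — the mean local
#' clustering coefficient over the community's cells, with cells of
#' degree < 2 contributing 0 — and the undirected phenotype-pair edge
#' counts \eqn{B_{xy}} (each edge counted once).
#'
#' @param graph output of \code{\link{buildNeighborGraph}}.
#' @return a list with one element per community, each containing
#'   \code{community_id}, \code{size}, \code{C} and \code{pairCounts}
#'   (named numeric, names \code{"x||y"} with x, y sorted).
#' @export
communityStats <- function(graph) {
  comm <- igraph::V(graph)$community
  if (is.null(comm)) stop("graph has no community assignment")
  localC <- igraph::transitivity(graph, type = "local", isolates = "zero")
  localC[igraph::degree(graph) < 2] <- 0
  el <- igraph::as_edgelist(graph, names = FALSE)
  phen <- igraph::V(graph)$phenotype
  edgeComm <- comm[el[, 1]]
  p1 <- phen[el[, 1]]; p2 <- phen[el[, 2]]
  key <- ifelse(p1 <= p2, paste(p1, p2, sep = "||"), paste(p2, p1, sep = "||"))
  lapply(sort(unique(comm)), function(k) {
    members <- which(comm == k)
    ek <- which(edgeComm == k)
    counts <- if (length(ek)) table(key[ek]) else table(character(0))
    list(community_id = k, size = length(members),
         C = mean(localC[members]),
         pairCounts = setNames(as.numeric(counts), names(counts)))
  })
}

#' Cell-cell interaction scores (CCIS)
#'
#' For every unordered phenotype pair (x, y), including self-pairs, the
#' score is \deqn{CCIS(x,y) = \sum_{N} C \cdot B_{xy} / A} where the sum
#' runs over the cellular communities of the image, \eqn{C} is the
#' community's clustering coefficient, \eqn{B_{xy}} its count of edges
#' joining a cell of phenotype x to one of phenotype y, and \eqn{A} the
#' total tissue area. Scores are symmetric, non-negative and have units
#' of 1/um^2; pairs with no supporting edges score 0.
#'
#' @param image a \code{\link{PatientImage}}.
#' @param palette a \code{\link{PhenotypePalette}}; defines the pair
#'   universe and the canonical feature names.
#' @param graph optionally a precomputed neighbor graph.
#' @return named numeric vector over all pairs of the palette, names per
#'   \code{\link{ccisFeatureName}}.
#' @export
ccis <- function(image, palette, graph = NULL) {
  A <- imageArea(image)
  if (A <= 0) stop("image area must be positive")
  if (is.null(graph)) graph <- buildNeighborGraph(image)
  pairs <- enumeratePairs(palette)
  scores <- setNames(numeric(nrow(pairs)), pairs$feature)
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) == 0) return(scores)
  comm <- igraph::V(graph)$community
  localC <- igraph::transitivity(graph, type = "local", isolates = "zero")
  localC[igraph::degree(graph) < 2] <- 0
  commC <- as.numeric(tapply(localC, comm, mean))  # indexed by community id
  phen <- igraph::V(graph)$phenotype
  ord <- match(phen, phenotypes(palette))
  p1 <- el[, 1]; p2 <- el[, 2]
  swap <- ord[p1] > ord[p2]
  a <- ifelse(swap, phen[p2], phen[p1])
  b <- ifelse(swap, phen[p1], phen[p2])
  feat <- paste0("CCIS_", a, "__", b)
  w <- commC[comm[p1]]
  agg <- rowsum(w, feat)
  scores[rownames(agg)] <- agg[, 1] / A
  scores
}

#' Phenotype densities (CP features)
#'
#' Counts of each palette phenotype per unit area (cells/um^2).
#'
#' @inheritParams ccis
#' @return named numeric vector, names per \code{\link{densityFeatureName}};
#'   absent phenotypes score 0.
#' @export
phenotypeDensity <- function(image, palette) {
  A <- imageArea(image)
  if (A <= 0) stop("image area must be positive")
  counts <- table(factor(image@cells$phenotype, levels = phenotypes(palette)))
  setNames(as.numeric(counts) / A,
           densityFeatureName(phenotypes(palette)))
}

#' Enumerate phenotype pairs and their taxonomy categories
#'
#' All unordered pairs of palette phenotypes, including self-pairs, each
#' labelled by the compartments of its two members (immune-immune,
#' immune-stromal, immune-epithelial, stromal-stromal,
#' stromal-epithelial, epithelial-epithelial). Under the default
#' 6/7/14 palette this gives 378 pairs: 21 + 42 + 84 + 28 + 98 + 105.
#'
#' @param palette a \code{\link{PhenotypePalette}}.
#' @return data.frame with columns \code{feature}, \code{member1},
#'   \code{member2}, \code{category}, \code{set} (TCI for
#'   epithelial-epithelial, TMI otherwise).
#' @examples
#' nrow(enumeratePairs(defaultPalette()))  # 378
#' @export
enumeratePairs <- function(palette) {
  ph <- phenotypes(palette)
  cls <- phenotypeClass(palette)
  if (anyNA(cls[ph])) stop("phenotype without class assignment")
  idx <- seq_along(ph)
  grid <- which(upper.tri(diag(length(ph)), diag = TRUE), arr.ind = TRUE)
  m1 <- ph[grid[, "row"]]; m2 <- ph[grid[, "col"]]
  catOf <- function(a, b) {
    cc <- sort(factor(c(cls[[a]], cls[[b]]),
                      levels = c("immune", "stromal", "epithelial")))
    paste(cc, collapse = "-")
  }
  category <- mapply(catOf, m1, m2, USE.NAMES = FALSE)
  data.frame(feature = mapply(ccisFeatureName, m1, m2,
                              MoreArgs = list(palette = palette),
                              USE.NAMES = FALSE),
             member1 = m1, member2 = m2, category = category,
             set = ifelse(category == "epithelial-epithelial", "TCI", "TMI"),
             stringsAsFactors = FALSE)
}

#' Assemble the cohort feature matrix
#'
#' Computes, for every patient image, the CP phenotype densities and all
#' pairwise CCIS values, and returns them as a
#' \code{SummarizedExperiment} with features as rows (assay
#' \code{"features"}), patients as columns, and per-feature metadata
#' (\code{set} = CP/TMI/TCI, \code{category}, pair members) in
#' \code{rowData}. Under the default palette: 27 CP + 273 TMI + 105 TCI.
#'
#' @param images list of \code{\link{PatientImage}} (one palette).
#' @param palette a \code{\link{PhenotypePalette}}.
#' @return a \code{SummarizedExperiment}.
#' @export
assembleFeatures <- function(images, palette) {
  bad <- unlist(lapply(images, function(im)
    setdiff(unique(im@cells$phenotype), phenotypes(palette))))
  if (length(bad))
    stop("inconsistent palettes: phenotype(s) not in palette: ",
         paste(unique(bad), collapse = ", "))
  pairs <- enumeratePairs(palette)
  vals <- vapply(images, function(im) {
    g <- buildNeighborGraph(im)
    c(phenotypeDensity(im, palette), ccis(im, palette, graph = g))
  }, numeric(length(phenotypes(palette)) + nrow(pairs)))
  vals <- matrix(vals, ncol = length(images),
                 dimnames = list(c(densityFeatureName(phenotypes(palette)),
                                   pairs$feature),
                                 vapply(images, slot, "", "patientId")))
  meta <- S4Vectors::DataFrame(
    set = c(rep("CP", length(phenotypes(palette))), pairs$set),
    category = c(rep("density", length(phenotypes(palette))),
                 pairs$category),
    member1 = c(phenotypes(palette), pairs$member1),
    member2 = c(rep(NA_character_, length(phenotypes(palette))),
                pairs$member2),
    row.names = rownames(vals))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals), rowData = meta)
}

#' Drop features that are identically zero
#'
#' Removes features whose value is 0 for every patient (phenotype pairs
#' that never touch anywhere in the cohort); the dropped names are kept
#' in \code{metadata(x)$dropped}.
#'
#' @param x a \code{SummarizedExperiment} from
#'   \code{\link{assembleFeatures}}.
#' @return the filtered \code{SummarizedExperiment}.
#' @export
dropZeroFeatures <- function(x) {
  vals <- SummarizedExperiment::assay(x, "features")
  zero <- rowSums(vals != 0) == 0
  out <- x[!zero, ]
  S4Vectors::metadata(out)$dropped <- rownames(vals)[zero]
  out
}

#' Extract one feature set as a patients x features matrix
#'
#' @param x a feature \code{SummarizedExperiment}.
#' @param set one of \code{"CP"}, \code{"TMI"}, \code{"TCI"}.
#' @return numeric matrix, patients in rows.
#' @export
featureSetMatrix <- function(x, set) {
  keep <- SummarizedExperiment::rowData(x)$set == set
  if (!any(keep)) stop("no features in set ", set)
  t(SummarizedExperiment::assay(x, "features")[keep, , drop = FALSE])
}
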