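## Feature construction: each simulated or empirical duplicate is summarized
## as p = 4m+84 derived features combining the scaled duplication time, the
## raw expression triplet, per-tissue parent+child sums, Euclidean distances,
## three-point branch lengths, Pearson correlations, and ranks and first
## eight raw moments of the differences against the single-copy background
## distributions dist(G) and cor(G).

.asTripletMatrix <- function(triplets) {
  if (is.null(dim(triplets))) triplets <- matrix(triplets, nrow = 1L)
  if (ncol(triplets) %% 3L != 0L)
    stop("triplet matrix must have 3m columns (eP, eC, eA per tissue)")
  triplets
}

.tripletParts <- function(triplets) {
  m <- ncol(triplets) / 3L
  list(P = triplets[, 3L * seq_len(m) - 2L, drop = FALSE],
       C = triplets[, 3L * seq_len(m) - 1L, drop = FALSE],
       A = triplets[, 3L * seq_len(m), drop = FALSE])
}

#' Pairwise Euclidean expression distances of a triplet
#'
#' Euclidean distances over the m tissues between parent and child, parent
#' and ancestor, child and ancestor, and between the per-tissue parent+child
#' sum and the ancestor.
#'
#' @param triplets numeric 3m-vector or N x 3m matrix in
#'   \code{eP1, eC1, eA1, ...} order.
#' @return N x 4 matrix with columns distPC, distPA, distCA, distPCA.
#' @examples
#' pairwiseDistances(c(0, 4, 0, 3, 0, 0))  # m = 2
#' @export
pairwiseDistances <- function(triplets) {
  triplets <- .asTripletMatrix(triplets)
  x <- .tripletParts(triplets)
  cbind(distPC = sqrt(rowSums((x$P - x$C)^2)),
        distPA = sqrt(rowSums((x$P - x$A)^2)),
        distCA = sqrt(rowSums((x$C - x$A)^2)),
        distPCA = sqrt(rowSums((x$P + x$C - x$A)^2)))
}

#' Three-point branch lengths from pairwise distances
#'
#' The additive three-point formulas
#' \code{branchP = (distPC + distPA - distCA)/2},
#' \code{branchC = (distPC + distCA - distPA)/2},
#' \code{branchA = (distPA + distCA - distPC)/2}. Negative values (possible
#' when the three-point condition fails) are passed through unmodified: these
#' are classifier features, not tree estimates.
#'
#' @param distPC,distPA,distCA pairwise distances (vectors), or a matrix as
#'   returned by [pairwiseDistances()] passed as \code{distPC}.
#' @return N x 3 matrix with columns branchP, branchC, branchA.
#' @examples
#' branchLengths(5, 4, 3)  # 3, 2, 1
#' @export
branchLengths <- function(distPC, distPA = NULL, distCA = NULL) {
  if (is.matrix(distPC) && is.null(distPA)) {
    distPA <- distPC[, "distPA"]; distCA <- distPC[, "distCA"]
    distPC <- distPC[, "distPC"]
  }
  cbind(branchP = (distPC + distPA - distCA) / 2,
        branchC = (distPC + distCA - distPA) / 2,
        branchA = (distPA + distCA - distPC) / 2)
}

#' Pairwise Pearson correlations of a triplet
#'
#' Correlations across the m tissues for the same four comparisons as
#' [pairwiseDistances()]; the PC,A comparison correlates the per-tissue
#' parent+child sum with the ancestor. A constant vector yields 0 with a
#' warning (the same policy as the background module).
#'
#' @inheritParams pairwiseDistances
#' @return N x 4 matrix with columns corPC, corPA, corCA, corPCA,
#'   values in [-1, 1].
#' @export
pairwiseCorrelations <- function(triplets) {
  triplets <- .asTripletMatrix(triplets)
  x <- .tripletParts(triplets)
  if (ncol(x$P) < 2L)
    return(cbind(corPC = rep(0, nrow(triplets)), corPA = 0, corCA = 0,
                 corPCA = 0))
  cbind(corPC = .rowCor(x$P, x$C),
        corPA = .rowCor(x$P, x$A),
        corCA = .rowCor(x$C, x$A),
        corPCA = .rowCor(x$P + x$C, x$A))
}

#' Rank of values among a background pool
#'
#' One-based rank by the count-strictly-less convention:
#' \code{rank = 1 + #\{pool < value\}}; ties are awarded the lower rank.
#' Ranks are left unnormalized (1 to |pool|+1); the network's feature
#' standardization absorbs the scale.
#'
#' @param values numeric vector.
#' @param pool nonempty numeric background multiset.
#' @return integer-valued numeric vector of ranks.
#' @examples
#' rankAmong(2, c(1, 2, 3))  # 2
#' @export
rankAmong <- function(values, pool) {
  if (length(pool) == 0L) stop("empty pool")
  findInterval(values, sort(pool), left.open = TRUE) + 1
}

#' Precompute normalized power sums of a background pool
#'
#' The kth raw moment of the difference distribution,
#' \code{(1/|pool|) * sum_i ((value - pool_i)/c)^k}, is evaluated for all
#' observations via the binomial expansion over the pool's power sums
#' \code{T_j = sum_i (pool_i/c)^j}, making the per-observation cost
#' independent of the pool size. The pool is normalized before the power
#' sums are taken, so no large intermediate magnitudes arise.
#'
#' @param pool numeric background multiset.
#' @param normalizer positive scale c (max of dist(G) for the distance
#'   features, 1 for the correlation features).
#' @param kMax highest moment order (8).
#' @return object passed to [poolMoments()].
#' @export
poolMomentTable <- function(pool, normalizer = 1, kMax = 8L) {
  if (length(pool) == 0L) stop("empty pool")
  stopifnot(normalizer > 0)
  z <- pool / normalizer
  Tj <- vapply(0:kMax, function(j) sum(z^j), numeric(1))
  structure(list(Tj = Tj, n = length(pool), normalizer = normalizer,
                 kMax = as.integer(kMax)), class = "poolMomentTable")
}

#' Raw moments of value-minus-pool differences
#'
#' @param values numeric vector of observed statistics.
#' @param table a [poolMomentTable()].
#' @return N x kMax matrix; column k holds the kth raw moment of
#'   \code{(value - pool)/normalizer}.
#' @examples
#' poolMoments(2, poolMomentTable(c(1, 2), normalizer = 2))[, 1:2]
#' @export
poolMoments <- function(values, table) {
  stopifnot(inherits(table, "poolMomentTable"))
  v <- values / table$normalizer
  kMax <- table$kMax
  out <- matrix(0, length(v), kMax)
  vpow <- outer(v, 0:kMax, `^`)              # v^j, columns j = 0..kMax
  for (k in seq_len(kMax)) {
    j <- 0:k
    coef <- choose(k, j) * (-1)^j * table$Tj[j + 1L] / table$n
    out[, k] <- drop(vpow[, k - j + 1L, drop = FALSE] %*% coef)
  }
  colnames(out) <- paste0("m", seq_len(kMax))
  out
}

#' Feature names in the fixed layout
#'
#' @param m number of tissues.
#' @return character(4m+84) of versioned column names
#'   (\code{f001_tpc} ... \code{f108_corPCA_m8} for m = 6).
#' @export
featureNames <- function(m = 6L) {
  mom <- function(stem) paste0(stem, "_m", 1:8)
  short <- c("tpc",
             as.vector(t(outer(seq_len(m), c("eP", "eC", "eA"),
                               function(j, pre) paste0(pre, j)))),
             paste0("sumPC", seq_len(m)),
             c("distPC", "distPA", "distCA", "distPCA"),
             c("branchP", "branchC", "branchA"),
             paste0("rank", c("DistPC", "DistPA", "DistCA", "DistPCA")),
             unlist(lapply(c("distPC", "distPA", "distCA", "distPCA"), mom)),
             c("corPC", "corPA", "corCA", "corPCA"),
             paste0("rank", c("CorPC", "CorPA", "CorCA", "CorPCA")),
             unlist(lapply(c("corPC", "corPA", "corCA", "corPCA"), mom)))
  sprintf("f%03d_%s", seq_along(short), short)
}

#' Assemble the p = 4m+84 feature matrix
#'
#' Builds the full derived feature layout for one or more expression
#' triplets: [1] tPC; [2..3m+1] the raw triplet; [3m+2..4m+1] per-tissue
#' parent+child sums; four Euclidean distances; three branch lengths; four
#' ranks among dist(G); 8 moments x 4 distance comparisons (normalized by
#' max dist(G)); four correlations; four ranks among cor(G); 8 moments x 4
#' correlation comparisons (unnormalized). Deterministic, and invariant to
#' the gene order of the background.
#'
#' @param triplets numeric 3m-vector or N x 3m matrix.
#' @param tPC scaled duplication time(s), length 1 or N.
#' @param background a [BackgroundDistributions-class].
#' @return N x (4m+84) matrix with [featureNames()] column names.
#' @examples
#' bg <- backgroundSummaries(simulateSingleCopySet(
#'   synthesizeBackgroundFits(100, seed = 1), nGenes = 100, m = 6, seed = 1))
#' sc <- drawScenarios("Conserved", n = 2, m = 6, seed = 1)
#' x <- assembleFeatures(sampleExpressionTriplets(sc, seed = 1),
#'                       tpcTimes(sc), bg)
#' dim(x)  # 2 x 108
#' @export
assembleFeatures <- function(triplets, tPC, background) {
  stopifnot(is(background, "BackgroundDistributions"))
  triplets <- .asTripletMatrix(triplets)
  n <- nrow(triplets); m <- ncol(triplets) / 3L
  if (length(tPC) == 1L) tPC <- rep(tPC, n)
  if (length(tPC) != n) stop("tPC length must be 1 or nrow(triplets)")
  d <- pairwiseDistances(triplets)
  b <- branchLengths(d)
  r <- pairwiseCorrelations(triplets)
  distTab <- poolMomentTable(background@dist, background@maxDist)
  corTab <- poolMomentTable(background@cor, 1)
  x <- .tripletParts(triplets)
  out <- cbind(tPC, triplets, x$P + x$C, d, b,
               rankAmong(d[, 1L], background@dist),
               rankAmong(d[, 2L], background@dist),
               rankAmong(d[, 3L], background@dist),
               rankAmong(d[, 4L], background@dist),
               poolMoments(d[, 1L], distTab), poolMoments(d[, 2L], distTab),
               poolMoments(d[, 3L], distTab), poolMoments(d[, 4L], distTab),
               r,
               rankAmong(r[, 1L], background@cor),
               rankAmong(r[, 2L], background@cor),
               rankAmong(r[, 3L], background@cor),
               rankAmong(r[, 4L], background@cor),
               poolMoments(r[, 1L], corTab), poolMoments(r[, 2L], corTab),
               poolMoments(r[, 3L], corTab), poolMoments(r[, 4L], corTab))
  stopifnot(ncol(out) == 4L * m + 84L)
  colnames(out) <- featureNames(m)
  out
}

#' Write / read a feature matrix with its versioned header
#'
#' Tab-separated, header row carrying the fixed versioned feature names;
#' reading verifies the header against [featureNames()].
#' @param x feature matrix from [assembleFeatures()].
#' @param path file path.
#' @export
writeFeatureMatrix <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  x <- as.matrix(df)
  m <- (ncol(x) - 84L) / 4L
  if (m < 1L || m != round(m) ||
      !identical(colnames(x), featureNames(m)))
    stop("feature header does not match the versioned layout")
  x
}
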