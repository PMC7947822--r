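## Single-copy gene background: the divergence baseline. Expression of each
## single-copy gene is observed in both species; under Brownian motion on the
## two-species tree with root height one and divergence at the root, the two
## tips are iid Normal(theta, sigma2), giving closed-form per-tissue MLEs.
## A pool of (theta, sigma2) fits drives simulation of a background set G,
## summarized as dist(G) and cor(G).

#' Two-tip Brownian-motion fit of single-copy expression
#'
#' Per-tissue maximum-likelihood estimates of the ancestral expression state
#' and BM rate from a two-species expression pair, assuming independent
#' tissues and a two-species tree of root height one whose lineages split at
#' the root (tips iid Normal(theta, sigma2)):
#' \code{theta = (s1 + s2)/2}, \code{sigma2 = (s1 - s2)^2/4}.
#'
#' @param s1,s2 numeric m-vectors of species-1 / species-2 expression
#'   (log10 units), or n x m matrices (one gene per row).
#' @return list with numeric components \code{theta} and \code{sigma2}
#'   (same shape as the input).
#' @examples
#' fitBmTwoTip(1, 3)  # theta 2, sigma2 1
#' @export
fitBmTwoTip <- function(s1, s2) {
  stopifnot(length(s1) == length(s2), all(is.finite(s1)), all(is.finite(s2)))
  list(theta = (s1 + s2) / 2, sigma2 = (s1 - s2)^2 / 4)
}

#' Synthesize a pool of background (theta, sigma2) fits
#'
#' Fixture used when no empirical single-copy table is available: ancestral
#' states theta uniform on [-1, 3] (a broad log10-FPKM-like range) and BM
#' rates sigma2 log-uniform on [1e-2, 1]. The pool plays the role of the
#' empirical distribution of two-tip BM fits.
#'
#' @param nPool pool size (number of (theta, sigma2) pairs).
#' @param seed integer seed.
#' @param thetaRange,log10sigma2Range fixture ranges.
#' @return list(theta, sigma2) of numeric vectors, as [fitBmTwoTip()].
#' @export
synthesizeBackgroundFits <- function(nPool = 10000L, seed,
                                     thetaRange = c(-1, 3),
                                     log10sigma2Range = c(-2, 0)) {
  set.seed(childSeed(seed, "background.fits"))
  list(theta = runif(nPool, thetaRange[1L], thetaRange[2L]),
       sigma2 = 10^runif(nPool, log10sigma2Range[1L], log10sigma2Range[2L]))
}

#' Simulate a single-copy gene set from a pool of BM fits
#'
#' For each simulated gene and tissue, one (theta, sigma2) pair is drawn
#' uniformly at random from the fit pool (jointly, preserving any
#' theta-sigma2 dependence in the pool), and the two species' expression
#' values are drawn iid Normal(theta, sigma2).
#'
#' @param fits list(theta, sigma2) as returned by [fitBmTwoTip()] (flattened
#'   over genes and tissues) or [synthesizeBackgroundFits()].
#' @param nGenes number of simulated single-copy genes (default 10000, the
#'   standard background size).
#' @param m number of tissues.
#' @param seed integer seed.
#' @return list with n x m matrices \code{s1} and \code{s2}.
#' @export
simulateSingleCopySet <- function(fits, nGenes = 10000L, m = 6L, seed) {
  theta <- as.vector(fits$theta); sigma2 <- as.vector(fits$sigma2)
  if (length(theta) == 0L) stop("empty fit pool")
  stopifnot(length(theta) == length(sigma2), all(sigma2 >= 0))
  set.seed(childSeed(seed, "background.sim"))
  idx <- sample.int(length(theta), nGenes * m, replace = TRUE)
  th <- matrix(theta[idx], nGenes, m)
  sg <- matrix(sqrt(sigma2[idx]), nGenes, m)
  list(s1 = th + sg * matrix(rnorm(nGenes * m), nGenes, m),
       s2 = th + sg * matrix(rnorm(nGenes * m), nGenes, m))
}

## Row-wise Pearson correlation between two n x m matrices; rows with zero
## variance on either side get 0 with one aggregated warning (the "no linear
## relationship" policy shared with the feature module).
.rowCor <- function(a, b) {
  ac <- a - rowMeans(a); bc <- b - rowMeans(b)
  den <- sqrt(rowSums(ac^2) * rowSums(bc^2))
  out <- ifelse(den > 0, rowSums(ac * bc) / den, 0)
  nbad <- sum(den == 0)
  if (nbad > 0)
    warning(nbad, " constant expression vector(s); correlation set to 0")
  pmin(1, pmax(-1, out))
}

#' Background divergence summaries dist(G) and cor(G)
#'
#' Computes, for each single-copy gene, the Euclidean distance and the
#' Pearson correlation between its species-1 and species-2 multi-tissue
#' expression vectors, and caches the maximum distance. These multisets are
#' the baseline against which all rank and moment features are taken.
#' Genes with a constant expression vector in either species get
#' correlation 0 with a warning.
#'
#' @param s1,s2 n x m matrices (or a list with elements \code{s1}, \code{s2}
#'   as returned by [simulateSingleCopySet()] passed as \code{s1}).
#' @return a [BackgroundDistributions-class].
#' @examples
#' g <- simulateSingleCopySet(synthesizeBackgroundFits(100, seed = 1),
#'                            nGenes = 50, m = 6, seed = 1)
#' backgroundSummaries(g)
#' @export
backgroundSummaries <- function(s1, s2 = NULL) {
  if (is.list(s1) && is.null(s2)) { s2 <- s1$s2; s1 <- s1$s1 }
  s1 <- as.matrix(s1); s2 <- as.matrix(s2)
  stopifnot(all(dim(s1) == dim(s2)), nrow(s1) >= 2L)
  d <- sqrt(rowSums((s1 - s2)^2))
  r <- if (ncol(s1) >= 2L) .rowCor(s1, s2) else rep(0, nrow(s1))
  new("BackgroundDistributions", dist = d, cor = r, maxDist = max(d))
}

#' Read / write single-copy expression tables
#'
#' Tab-separated with a header row: \code{gene_id}, then m species-1 tissue
#' columns, then m species-2 tissue columns.
#'
#' @param path file path.
#' @param m number of tissues.
#' @return list(s1, s2) matrices with gene ids as row names.
#' @export
readSingleCopyTable <- function(path, m) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) != 2L * m + 1L)
    stop("expected gene_id + ", 2L * m, " expression columns, found ",
         ncol(df))
  if (anyDuplicated(df[[1L]])) stop("duplicate gene ids in ", path)
  vals <- as.matrix(df[, -1L])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  rownames(vals) <- df[[1L]]
  list(s1 = vals[, seq_len(m), drop = FALSE],
       s2 = vals[, m + seq_len(m), drop = FALSE])
}

#' @rdname readSingleCopyTable
#' @param genes list(s1, s2) matrices.
#' @export
writeSingleCopyTable <- function(genes, path) {
  m <- ncol(genes$s1)
  ids <- rownames(genes$s1)
  if (is.null(ids)) ids <- paste0("sc", seq_len(nrow(genes$s1)))
  df <- data.frame(gene_id = ids, genes$s1, genes$s2, check.names = FALSE)
  names(df) <- c("gene_id", paste0("sp1_t", seq_len(m)),
                 paste0("sp2_t", seq_len(m)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
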