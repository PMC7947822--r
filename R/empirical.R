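## Empirical orchestration: expression tables, duplicate triplet lists,
## Newick gene trees, duplication-time extraction, and the end-to-end
## tailored classify+predict pipeline. Upstream products (alignments, tree
## inference, ortholog identification, FPKM quantification, quantile
## normalization) are assumed done; this module consumes their outputs and
## validates them.

#' Read a per-gene expression table
#'
#' Tab-separated with a header row: \code{gene_id} followed by m numeric
#' tissue columns. Values flagged as linear-scale are log10-transformed on
#' read (the model operates on log10 expression throughout). Genes whose
#' expression is below \code{minExpression} in every tissue are dropped with
#' a message reporting the count (applied on the scale of the returned
#' values).
#'
#' @param path file path.
#' @param logScale TRUE when the file already holds log10 values (no
#'   transform applied); FALSE for linear-scale values, which are
#'   log10-transformed after flooring at \code{linearFloor} to keep zeros
#'   finite.
#' @param minExpression optional low-expression filter threshold (log10
#'   scale); NULL disables filtering.
#' @param linearFloor floor applied before log10 when \code{logScale} is
#'   FALSE.
#' @return numeric matrix, genes in rows (named), tissues in columns.
#' @export
readExpressionTable <- function(path, logScale = TRUE, minExpression = NULL,
                                linearFloor = 1e-4) {
  df <- tryCatch(
    read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
               colClasses = NA),
    error = function(e) stop("malformed expression table ", path, ": ",
                             conditionMessage(e)))
  if (ncol(df) < 2L) stop("expression table needs gene_id + tissue columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate gene id '", dup, "' at line ",
         which(ids == dup)[2L] + 1L, " of ", path)
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals[[j]]))))[1L]
      stop("non-numeric expression value at line ", bad + 1L, ", column '",
           names(vals)[j], "' of ", path)
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- ids
  if (!logScale) x <- log10(pmax(x, linearFloor))
  if (!is.null(minExpression)) {
    low <- rowSums(x >= minExpression) == 0L
    if (any(low))
      message("dropping ", sum(low),
              " gene(s) below the expression threshold in all tissues")
    x <- x[!low, , drop = FALSE]
  }
  x
}

#' Extract scaled duplication times from a gene tree
#'
#' Given a Newick gene tree containing the parent, child and ancestral tips,
#' the tree is pruned to the triplet and required to have the
#' ((parent, child), ancestor) topology. Node heights are computed as the
#' mean root-to-tip path length below each node (so non-ultrametric
#' maximum-likelihood trees are handled; a strict mode errors on
#' non-ultrametric input instead): the root height is TPCA, the mean path
#' length below the parent-child ancestor is TPC, and the scaled duplication
#' time is tPC = TPC/TPCA, clamped into [epsilon, 1 - epsilon] with a
#' warning when degenerate. A rooted input must already have the ancestor
#' alone on one side of the root; an unrooted (maximum-likelihood style)
#' input is rooted on the ancestor's pendant branch, with the root placed so
#' that the ancestor's root-to-tip path equals the mean parent/child
#' root-to-tip path (for an ultrametric tree this recovers the original
#' root exactly).
#'
#' @param tree an \code{ape::phylo} object or path to a Newick file.
#' @param parent,child,ancestor tip labels of the triplet.
#' @param epsilon clamp bound for degenerate times (1e-3).
#' @param strictUltrametric error on non-ultrametric trees instead of
#'   averaging path lengths.
#' @return list(tPC, tPCA = 1, rawTPC, rawTPCA) with tPC in (0, 1).
#' @examples
#' tr <- ape::read.tree(text = "((P:0.3,C:0.3):0.7,A:1.0);")
#' extractTreeTimes(tr, "P", "C", "A")$tPC  # 0.3
#' @export
extractTreeTimes <- function(tree, parent, child, ancestor,
                             epsilon = 1e-3, strictUltrametric = FALSE) {
  if (is.character(tree)) tree <- ape::read.tree(tree)
  stopifnot(inherits(tree, "phylo"))
  trip <- c(parent, child, ancestor)
  if (length(unique(trip)) != 3L)
    stop("parent, child and ancestor ids must be distinct")
  missing <- setdiff(trip, tree$tip.label)
  if (length(missing))
    stop("triplet (", paste(trip, collapse = ", "),
         "): tip(s) missing from tree: ", paste(missing, collapse = ", "))
  tree <- ape::keep.tip(tree, trip)
  rootNode <- 4L                       # Ntip + 1 for the pruned 3-tip tree
  if (ape::is.rooted(tree)) {
    ## the supplied rooting must place the ancestor alone on one side of the
    ## root (equivalently, parent and child must be sisters)
    kids <- tree$edge[tree$edge[, 1L] == rootNode, 2L]
    aIdx <- match(ancestor, tree$tip.label)
    if (!(aIdx %in% kids))
      stop("triplet (", paste(trip, collapse = ", "),
           "): parent and child are not sisters after rooting on the ",
           "ancestor")
    dep <- ape::node.depth.edgelength(tree)   # root-to-node path lengths
    tipIdx <- match(trip, tree$tip.label)
    tipDepths <- dep[tipIdx]
    if (strictUltrametric &&
        diff(range(tipDepths)) > 1e-8 * max(tipDepths, 1))
      stop("tree is not ultrametric and strictUltrametric = TRUE")
    mrcaPC <- ape::getMRCA(tree, c(parent, child))
    rootHeight <- mean(tipDepths)                       # TPCA
    pcHeight <- mean(dep[tipIdx[1:2]]) - dep[mrcaPC]    # TPC
  } else {
    ## unrooted maximum-likelihood tree: a 3-tip star. Root on the
    ## ancestor's pendant branch, placed so that the ancestor's root-to-tip
    ## path equals the mean parent/child root-to-tip path (this recovers the
    ## original root exactly for an ultrametric tree).
    pend <- tree$edge.length[match(1:3, tree$edge[, 2L])]
    names(pend) <- tree$tip.label
    if (strictUltrametric &&
        abs(pend[parent] - pend[child]) >
          1e-8 * max(abs(pend), 1))
      stop("tree is not ultrametric and strictUltrametric = TRUE")
    pcHeight <- mean(pend[c(parent, child)])            # TPC
    rootHeight <- (pcHeight + pend[ancestor]) / 2       # TPCA
  }
  if (rootHeight <= 0)
    stop("triplet (", paste(trip, collapse = ", "), "): zero root height")
  tPC <- unname(pcHeight / rootHeight)
  if (tPC < epsilon || tPC > 1 - epsilon) {
    warning("tPC = ", signif(tPC, 4), " clamped into [",
            epsilon, ", ", 1 - epsilon, "]")
    tPC <- min(max(tPC, epsilon), 1 - epsilon)
  }
  list(tPC = tPC, tPCA = 1, rawTPC = pcHeight, rawTPCA = rootHeight)
}

#' Scaled duplication times for a table of duplicate triplets
#'
#' @param triplets data.frame with columns \code{parent_id},
#'   \code{child_id}, \code{ancestor_id} and \code{tree_file}.
#' @param treeDir directory prefixed to \code{tree_file} paths (optional).
#' @param ... passed to [extractTreeTimes()].
#' @return numeric vector of tPC values, one per triplet.
#' @export
treeTimePool <- function(triplets, treeDir = NULL, ...) {
  need <- c("parent_id", "child_id", "ancestor_id", "tree_file")
  if (!all(need %in% names(triplets)))
    stop("triplet table needs columns: ", paste(need, collapse = ", "))
  vapply(seq_len(nrow(triplets)), function(i) {
    f <- triplets$tree_file[i]
    if (!is.null(treeDir)) f <- file.path(treeDir, f)
    extractTreeTimes(f, triplets$parent_id[i], triplets$child_id[i],
                     triplets$ancestor_id[i], ...)$tPC
  }, numeric(1))
}

#' Read a duplicate-triplet table
#'
#' Tab-separated with header: \code{parent_id}, \code{child_id},
#' \code{ancestor_id}, \code{tree_file}.
#' @param path file path.
#' @export
readTripletTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("parent_id", "child_id", "ancestor_id")
  if (!all(need %in% names(df)))
    stop("triplet table needs columns: ", paste(need, collapse = ", "))
  bad <- df$parent_id == df$child_id | df$parent_id == df$ancestor_id |
         df$child_id == df$ancestor_id
  if (any(bad))
    stop("triplet rows with non-distinct ids: ",
         paste(which(bad), collapse = ", "))
  df
}

#' End-to-end tailored classify + predict pipeline
#'
#' Runs the full empirical workflow: (1) builds the background
#' [backgroundSummaries()] from the empirical single-copy set; (2) fits the
#' two-tip Brownian-motion pool [fitBmTwoTip()] from the same set and
#' extracts the duplication-time pool from the gene trees; (3) generates a
#' tailored balanced training set against that background and trains a
#' classifier and a predictor; (4) assembles features for every duplicate
#' triplet and returns class calls plus 5m parameter estimates.
#'
#' @param expr1,expr2 expression matrices (genes x m tissues, log10 scale)
#'   for species 1 and species 2, as from [readExpressionTable()].
#' @param duplicates duplicate-triplet data.frame
#'   (see [readTripletTable()]); parent and child ids must appear in
#'   \code{expr1}, ancestor ids in \code{expr2}.
#' @param singleCopy data.frame or two-column matrix of single-copy ortholog
#'   id pairs (species-1 id, species-2 id), all present in the expression
#'   matrices.
#' @param treeDir directory holding the per-triplet Newick files named in
#'   \code{duplicates$tree_file}.
#' @param nPerClass training observations per class (10,000 in the standard
#'   design; reduce for small runs).
#' @param classifierConfig,predictorConfig [networkConfig()]s for the two
#'   models; defaults use the simulation-optimal regularization
#'   (lambda = 1.778e-4, gamma = 1 classifier; lambda = 7.499e-8,
#'   gamma = 0.8 predictor) with L = 2.
#' @param seed master integer seed.
#' @param outDir optional directory to write \code{calls.tsv},
#'   \code{params.tsv} and \code{manifest.txt}.
#' @return list with \code{calls} (data.frame: ids, class probabilities,
#'   call), \code{parameters} (data.frame of 5m estimates), \code{tpc},
#'   \code{background}, \code{classifier}, \code{predictor}.
#' @export
runEmpiricalPipeline <- function(expr1, expr2, duplicates, singleCopy,
                                 treeDir = NULL, nPerClass = 10000L,
                                 classifierConfig = networkConfig(
                                   "classify", L = 2L, lambda = 1.778e-4,
                                   gamma = 1),
                                 predictorConfig = networkConfig(
                                   "predict", L = 2L, lambda = 7.499e-8,
                                   gamma = 0.8),
                                 seed, outDir = NULL) {
  m <- ncol(expr1)
  if (ncol(expr2) != m) stop("species expression tables differ in tissues")
  singleCopy <- as.data.frame(singleCopy)
  if (nrow(singleCopy) == 0L) stop("empty single-copy set")
  miss1 <- setdiff(singleCopy[[1L]], rownames(expr1))
  miss2 <- setdiff(singleCopy[[2L]], rownames(expr2))
  missP <- setdiff(duplicates$parent_id, rownames(expr1))
  missC <- setdiff(duplicates$child_id, rownames(expr1))
  missA <- setdiff(duplicates$ancestor_id, rownames(expr2))
  offenders <- c(miss1, miss2, missP, missC, missA)
  if (length(offenders))
    stop("gene ids missing from expression tables: ",
         paste(unique(offenders), collapse = ", "))

  s1 <- expr1[singleCopy[[1L]], , drop = FALSE]
  s2 <- expr2[singleCopy[[2L]], , drop = FALSE]
  background <- backgroundSummaries(s1, s2)
  fits <- fitBmTwoTip(s1, s2)
  tpc <- if (!is.null(duplicates$tree_file))
    treeTimePool(duplicates, treeDir) else NULL

  train <- generateTrainingSet(nPerClass = nPerClass, m = m,
                               background = background, tpcPool = tpc,
                               seed = childSeed(seed, "pipeline.train"))
  classifier <- trainNetwork(train, config = classifierConfig,
                             seed = childSeed(seed, "pipeline.classifier"))
  predictor <- trainNetwork(train, config = predictorConfig,
                            seed = childSeed(seed, "pipeline.predictor"))

  trip <- cbind(expr1[duplicates$parent_id, , drop = FALSE],
                expr1[duplicates$child_id, , drop = FALSE],
                expr2[duplicates$ancestor_id, , drop = FALSE])
  ## reorder from (P tissues, C tissues, A tissues) to interleaved eP,eC,eA
  ord <- as.vector(rbind(seq_len(m), m + seq_len(m), 2L * m + seq_len(m)))
  trip <- trip[, ord, drop = FALSE]
  tpcDup <- if (is.null(tpc)) rep(0.5, nrow(duplicates)) else tpc
  x <- assembleFeatures(trip, tpcDup, background)

  cls <- classifyDuplicates(classifier, x)
  pars <- predictParameters(predictor, x)
  calls <- data.frame(parent_id = duplicates$parent_id,
                      child_id = duplicates$child_id,
                      ancestor_id = duplicates$ancestor_id,
                      tPC = tpcDup,
                      cls$probabilities,
                      call = cls$labels, check.names = FALSE)
  params <- data.frame(parent_id = duplicates$parent_id,
                       child_id = duplicates$child_id, pars,
                       check.names = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(calls, file.path(outDir, "calls.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(params, file.path(outDir, "params.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeLines(c(paste("seed", seed), paste("nPerClass", nPerClass),
                 paste("m", m), paste("generated", format(Sys.time()))),
               file.path(outDir, "manifest.txt"))
  }
  list(calls = calls, parameters = params, tpc = tpcDup,
       background = background, classifier = classifier,
       predictor = predictor)
}
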