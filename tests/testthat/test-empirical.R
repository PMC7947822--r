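# Empirical I/O: expression tables, tree-time extraction, and the tailored
# end-to-end pipeline on a fully synthetic fixture.

writeExprFile <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("expression tables round-trip, transform and filter", {
  x <- matrix(c(1.2, -0.3, 0.8,
                2.0, 1.5, 0.1,
                -3.5, -3.9, -3.2), 3, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"),
                              paste0("t", 1:3)))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExprFile(x, path)
  got <- readExpressionTable(path, logScale = TRUE)
  expect_equal(got, x, tolerance = 1e-8)
  # linear-scale flag applies log10 on read
  lin <- 10^x
  pathLin <- withr::local_tempfile(fileext = ".tsv")
  writeExprFile(lin, pathLin)
  gotLin <- readExpressionTable(pathLin, logScale = FALSE)
  expect_equal(gotLin, x, tolerance = 1e-6)
  # the all-tissues low-expression filter drops gC and reports it
  expect_message(flt <- readExpressionTable(path, minExpression = -3),
                 "1 gene")
  expect_identical(rownames(flt), c("gA", "gB"))
})

test_that("malformed expression tables fail with located errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tt1\tt2", "gA\t1\t2", "gA\t3\t4"), path)
  expect_error(readExpressionTable(path), "duplicate gene id 'gA' at line 3")
  writeLines(c("gene_id\tt1\tt2", "gA\t1\t2", "gB\toops\t4"), path)
  expect_error(readExpressionTable(path), "non-numeric")
})

test_that("tree times follow the mean-path-length convention", {
  tr <- ape::read.tree(text = "((P:0.3,C:0.3):0.7,A:1.0);")
  est <- extractTreeTimes(tr, "P", "C", "A")
  expect_equal(est$tPC, 0.3)
  expect_equal(est$rawTPCA, 1.0)
  # non-ultrametric: parent/child path lengths are averaged
  tr2 <- ape::read.tree(text = "((P:0.2,C:0.4):0.7,A:1.0);")
  expect_equal(extractTreeTimes(tr2, "P", "C", "A")$tPC, 0.3)
  expect_error(extractTreeTimes(tr2, "P", "C", "A",
                                strictUltrametric = TRUE),
               "ultrametric")
  # invariance to tip order / branch rotation in the Newick string
  tr3 <- ape::read.tree(text = "(A:1.0,(C:0.3,P:0.3):0.7);")
  expect_equal(extractTreeTimes(tr3, "P", "C", "A")$tPC, 0.3)
  # extra taxa are pruned away first
  tr4 <- ape::read.tree(
    text = "(((P:0.3,C:0.3):0.7,A:1.0):0.5,OUT:1.5);")
  expect_equal(extractTreeTimes(tr4, "P", "C", "A")$tPC, 0.3)
})

test_that("tree-time extraction rejects bad input and clamps degenerate times", {
  tr <- ape::read.tree(text = "((P:0.3,C:0.3):0.7,A:1.0);")
  expect_error(extractTreeTimes(tr, "P", "C", "X"), "missing from tree")
  expect_error(extractTreeTimes(tr, "P", "P", "A"), "distinct")
  wrong <- ape::read.tree(text = "((P:0.3,A:0.3):0.7,C:1.0);")
  expect_error(extractTreeTimes(wrong, "P", "C", "A"), "not sisters")
  degen <- ape::read.tree(text = "((P:0.0,C:0.0):1.0,A:1.0);")
  expect_warning(est <- extractTreeTimes(degen, "P", "C", "A"), "clamped")
  expect_equal(est$tPC, 1e-3)
})

test_that("a triplet table drives the duplication-time pool", {
  dir <- withr::local_tempdir()
  writeLines("((p1:0.2,c1:0.2):0.8,a1:1.0);", file.path(dir, "tr1.nwk"))
  writeLines("((p2:0.5,c2:0.5):0.5,a2:1.0);", file.path(dir, "tr2.nwk"))
  trip <- data.frame(parent_id = c("p1", "p2"), child_id = c("c1", "c2"),
                     ancestor_id = c("a1", "a2"),
                     tree_file = c("tr1.nwk", "tr2.nwk"))
  expect_equal(treeTimePool(trip, dir), c(0.2, 0.5))
  bad <- trip; bad$child_id[1] <- "p1"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readTripletTable(path), "non-distinct")
})

test_that("the tailored pipeline recovers planted retention mechanisms", {
  m <- 6L
  nDup <- 30L
  # synthetic empirical world: single-copy genes for the background ...
  g <- simulateSingleCopySet(synthesizeBackgroundFits(2000, seed = 71),
                             nGenes = 2000, m = m, seed = 71)
  rownames(g$s1) <- paste0("sc", 1:2000, "_sp1")
  rownames(g$s2) <- paste0("sc", 1:2000, "_sp2")
  # ... and duplicates planted under strongly separated regimes
  easy <- parameterRanges(log10alpha = c(3, 3), log10sigma2 = c(-2, -2))
  plant <- function(cl, tag, seed) {
    sc <- drawScenarios(cl, n = nDup, m = m, ranges = easy, seed = seed)
    list(sc = sc, trip = sampleExpressionTriplets(sc, seed = seed + 1),
         ids = paste0(tag, seq_len(nDup)))
  }
  neo <- plant("NeofunctionalizedChild", "neo", seed = 72)
  con <- plant("Conserved", "con", seed = 74)
  pick <- function(x, prefix) {
    cols <- grep(prefix, colnames(x))
    x[, cols, drop = FALSE]
  }
  expr1 <- rbind(g$s1,
                 `rownames<-`(pick(neo$trip, "^eP"), paste0(neo$ids, "_P")),
                 `rownames<-`(pick(neo$trip, "^eC"), paste0(neo$ids, "_C")),
                 `rownames<-`(pick(con$trip, "^eP"), paste0(con$ids, "_P")),
                 `rownames<-`(pick(con$trip, "^eC"), paste0(con$ids, "_C")))
  expr2 <- rbind(g$s2,
                 `rownames<-`(pick(neo$trip, "^eA"), paste0(neo$ids, "_A")),
                 `rownames<-`(pick(con$trip, "^eA"), paste0(con$ids, "_A")))
  colnames(expr1) <- colnames(expr2) <- paste0("t", 1:m)
  dir <- withr::local_tempdir()
  allIds <- c(neo$ids, con$ids)
  allTpc <- c(tpcTimes(neo$sc), tpcTimes(con$sc))
  dups <- data.frame(parent_id = paste0(allIds, "_P"),
                     child_id = paste0(allIds, "_C"),
                     ancestor_id = paste0(allIds, "_A"),
                     tree_file = paste0(allIds, ".nwk"))
  for (i in seq_along(allIds)) {
    t1 <- allTpc[i]
    writeLines(sprintf("((%s_P:%.4f,%s_C:%.4f):%.4f,%s_A:1.0);",
                       allIds[i], t1, allIds[i], t1, 1 - t1,
                       allIds[i]),
               file.path(dir, dups$tree_file[i]))
  }
  singles <- data.frame(sp1 = rownames(g$s1), sp2 = rownames(g$s2))
  res <- runEmpiricalPipeline(
    expr1, expr2, dups, singles, treeDir = dir, nPerClass = 800L,
    classifierConfig = networkConfig("classify", L = 2, lambda = 1.778e-4,
                                     gamma = 1, epochs = 120,
                                     batchSize = 1000),
    predictorConfig = networkConfig("predict", L = 2, lambda = 7.499e-8,
                                    gamma = 0.8, epochs = 120,
                                    batchSize = 1000),
    seed = 75, outDir = file.path(dir, "out"))
  expect_identical(nrow(res$calls), nrow(dups))
  expect_identical(ncol(res$parameters) - 2L, 5L * m)
  # recovered duplication times match the planted trees
  expect_equal(res$tpc, allTpc, tolerance = 2e-4)
  # planted neofunctionalized-child duplicates are called as such
  neoCalls <- res$calls$call[seq_len(nDup)]
  expect_gte(mean(neoCalls == "NeofunctionalizedChild"), 0.9)
  # planted conserved duplicates: theta estimates indistinguishable across
  # copies (tissue-averaged), mirroring the expectation for conservation
  conPar <- res$parameters[nDup + seq_len(nDup), -(1:2)]
  thP <- rowMeans(conPar[, grep("^thetaP", colnames(conPar))])
  thC <- rowMeans(conPar[, grep("^thetaC", colnames(conPar))])
  thA <- rowMeans(conPar[, grep("^thetaA", colnames(conPar))])
  expect_gt(t.test(thP, thC)$p.value, 0.01)
  expect_gt(t.test(thP, thA)$p.value, 0.01)
  expect_true(file.exists(file.path(dir, "out", "calls.tsv")))
  expect_true(file.exists(file.path(dir, "out", "manifest.txt")))
  # rerunning with the same seed reproduces the calls
  res2 <- runEmpiricalPipeline(
    expr1, expr2, dups[1:3, ], singles, treeDir = dir, nPerClass = 100L,
    classifierConfig = networkConfig("classify", L = 0, epochs = 20,
                                     batchSize = 500),
    predictorConfig = networkConfig("predict", L = 0, epochs = 20,
                                    batchSize = 500),
    seed = 76)
  res3 <- runEmpiricalPipeline(
    expr1, expr2, dups[1:3, ], singles, treeDir = dir, nPerClass = 100L,
    classifierConfig = networkConfig("classify", L = 0, epochs = 20,
                                     batchSize = 500),
    predictorConfig = networkConfig("predict", L = 0, epochs = 20,
                                    batchSize = 500),
    seed = 76)
  expect_identical(res2$calls, res3$calls)
  # missing cross-references are reported with the offending ids
  badDups <- dups[1:3, ]; badDups$parent_id[1] <- "ghost"
  expect_error(runEmpiricalPipeline(expr1, expr2, badDups, singles,
                                    treeDir = dir, nPerClass = 10L,
                                    seed = 77),
               "ghost")
})
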