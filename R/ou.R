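## Ornstein-Uhlenbeck model of expression evolution on the three-gene tree
## (parent copy P and child copy C in species 1, ancestral single-copy
## ortholog A in species 2). Time is measured in units of the gene-tree root
## height: the root (speciation) lies t_pca = 1 in the past, the duplication
## t_pc in (0, t_pca). The pre-duplication optima equal the ancestral optimum
## (theta_PC = theta_PCA = theta_A), so at stationarity each tissue's triplet
## (eP, eC, eA) is trivariate normal with the closed forms below.

.checkOUParams <- function(alpha, sigma2 = 1, tPC = 0.5, tPCA = 1) {
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be finite and > 0")
  if (any(!is.finite(sigma2)) || any(sigma2 <= 0))
    stop("sigma2 must be finite and > 0")
  if (any(!is.finite(tPC)) || any(tPC <= 0) || any(tPC >= tPCA))
    stop("tPC must satisfy 0 < tPC < tPCA")
  invisible(TRUE)
}

#' Expected expression of the (parent, child, ancestor) triplet
#'
#' Closed-form mean of the OU process on the three-gene tree for one tissue.
#' The parent and child means are convex combinations of their own optimum and
#' the ancestral optimum with weight \code{exp(-alpha * tPC)} on the ancestral
#' state; the ancestral gene stays at its optimum.
#'
#' @param thetaP,thetaC,thetaA optimal expression states (log10 units).
#' @param alpha selection strength, > 0, per unit tree height.
#' @param tPC scaled duplication time in (0, tPCA).
#' @param tPCA scaled root time (1 after scaling; exposed for completeness).
#' @return numeric(3): expected (eP, eC, eA).
#' @examples
#' ouMean(2, -1, 0, alpha = 1, tPC = 0.5)
#' @seealso [ouCovariance()], [sampleExpressionTriplets()]
#' @export
ouMean <- function(thetaP, thetaC, thetaA, alpha, tPC, tPCA = 1) {
  .checkOUParams(alpha, tPC = tPC, tPCA = tPCA)
  w <- exp(-alpha * tPC)
  c((1 - w) * thetaP + w * thetaA,
    (1 - w) * thetaC + w * thetaA,
    thetaA)
}

#' Covariance of the (parent, child, ancestor) triplet
#'
#' Closed-form 3 x 3 stationary OU covariance for one tissue:
#' \code{sigma2/(2*alpha)} times a correlation matrix with unit diagonal,
#' parent-child correlation \code{exp(-2*alpha*tPC)} and
#' parent-ancestor = child-ancestor correlation \code{exp(-2*alpha*tPCA)}.
#' Symmetric positive definite for all valid parameters.
#'
#' @inheritParams ouMean
#' @param sigma2 phenotypic drift variance rate, > 0.
#' @return 3 x 3 numeric matrix, rows/cols ordered (P, C, A).
#' @examples
#' ouCovariance(alpha = 1, sigma2 = 2, tPC = 0.5)
#' @export
ouCovariance <- function(alpha, sigma2, tPC, tPCA = 1) {
  .checkOUParams(alpha, sigma2, tPC, tPCA)
  a <- exp(-2 * alpha * tPC)
  b <- exp(-2 * alpha * tPCA)
  (sigma2 / (2 * alpha)) *
    matrix(c(1, a, b,
             a, 1, b,
             b, b, 1), 3L, 3L,
           dimnames = list(c("P", "C", "A"), c("P", "C", "A")))
}

## Vectorized sampler: one trivariate-normal draw per (observation, tissue)
## using the analytic Cholesky factor of the structured correlation matrix
##   [1 a b; a 1 b; b b 1],  a = exp(-2*alpha*tPC), b = exp(-2*alpha*tPCA).
## L11 = 1; L21 = a, L22 = sqrt(1-a^2); L31 = b, L32 = b(1-a)/L22,
## L33 = sqrt(1 - b^2 - L32^2). Verified against chol() in the tests.
.rTripletVec <- function(muP, muC, muA, alpha, sigma2, tPC, tPCA = 1) {
  a <- exp(-2 * alpha * tPC)
  b <- exp(-2 * alpha * tPCA)
  s <- sqrt(sigma2 / (2 * alpha))
  l22 <- sqrt(pmax(0, 1 - a^2))
  l32 <- ifelse(l22 > 0, b * (1 - a) / l22, 0)
  l33 <- sqrt(pmax(0, 1 - b^2 - l32^2))
  n <- length(muP)
  z1 <- rnorm(n); z2 <- rnorm(n); z3 <- rnorm(n)
  eP <- muP + s * z1
  eC <- muC + s * (a * z1 + l22 * z2)
  eA <- muA + s * (b * z1 + l32 * z2 + l33 * z3)
  cbind(eP, eC, eA)
}

#' Simulate expression triplets under a set of duplicate-gene scenarios
#'
#' Draws one multivariate-normal expression triplet per tissue for each
#' scenario, independently across tissues, with per-tissue mean
#' [ouMean()] and covariance [ouCovariance()]. With \code{n > 1}, each
#' scenario is replicated n times (rows ordered scenario-major).
#'
#' @param scenarios a [DuplicateScenarioSet-class].
#' @param n replicates per scenario (default 1, the one-triplet-per-draw
#'   design used throughout the simulation experiments).
#' @param seed integer seed; same seed, same output.
#' @return numeric matrix with \code{length(scenarios) * n} rows and 3m
#'   columns ordered \code{eP1, eC1, eA1, ..., ePm, eCm, eAm}.
#' @examples
#' sc <- drawScenarios("Conserved", n = 3, m = 2, seed = 1)
#' sampleExpressionTriplets(sc, seed = 1)
#' @export
sampleExpressionTriplets <- function(scenarios, n = 1L, seed) {
  stopifnot(is(scenarios, "DuplicateScenarioSet"), n >= 1L)
  validObject(scenarios)
  set.seed(childSeed(seed, "triplets"))
  m <- nTissues(scenarios)
  ns <- length(scenarios)
  rep1 <- function(x) if (n == 1L) x else x[rep(seq_len(ns), each = n), ,
                                            drop = FALSE]
  thetaP <- rep1(scenarios@thetaP); thetaC <- rep1(scenarios@thetaC)
  thetaA <- rep1(scenarios@thetaA); alpha <- rep1(scenarios@alpha)
  sigma2 <- rep1(scenarios@sigma2)
  tPC <- rep(scenarios@tPC, each = n)
  out <- matrix(0, ns * n, 3L * m)
  w <- exp(-alpha * tPC)
  for (j in seq_len(m)) {
    muP <- (1 - w[, j]) * thetaP[, j] + w[, j] * thetaA[, j]
    muC <- (1 - w[, j]) * thetaC[, j] + w[, j] * thetaA[, j]
    out[, (3L * j - 2L):(3L * j)] <-
      .rTripletVec(muP, muC, thetaA[, j], alpha[, j], sigma2[, j], tPC)
  }
  colnames(out) <- as.vector(t(outer(seq_len(m), c("eP", "eC", "eA"),
                                     function(j, p) paste0(p, j))))
  out
}

#' Default evolutionary parameter ranges
#'
#' The training-simulation ranges: optima theta uniform on [-4, 4] (log10
#' expression scale), selection strength alpha log-uniform with
#' log10(alpha) on [0, 3], drift rate sigma2 log-uniform with log10(sigma2)
#' on [-2, 3]. Restricted test regimes are expressed by overriding
#' \code{log10alpha}/\code{log10sigma2}.
#'
#' @param theta numeric(2) range for the optima.
#' @param log10alpha numeric(2) range for log10(alpha).
#' @param log10sigma2 numeric(2) range for log10(sigma2).
#' @param tPC numeric(2) range for the scaled duplication time, used when no
#'   empirical tree-time pool is supplied.
#' @return named list of ranges.
#' @export
parameterRanges <- function(theta = c(-4, 4), log10alpha = c(0, 3),
                            log10sigma2 = c(-2, 3), tPC = c(0.05, 0.95)) {
  list(theta = theta, log10alpha = log10alpha,
       log10sigma2 = log10sigma2, tPC = tPC)
}

## Draw per-tissue optima under one retention class's constraint.
## Equality constraints are built exactly; inequality ("not equal")
## constraints are enforced by rejection at tolerance 1e-6 (equality is a
## measure-zero event for continuous draws, but exact class identity must be
## testable). Returns list(thetaP, thetaC, thetaA) vectors of length nm.
.drawThetas <- function(cls, nm, range) {
  tol <- 1e-6
  u <- function() runif(nm, range[1L], range[2L])
  redraw <- function(x, bad) { x[bad] <- runif(sum(bad), range[1L], range[2L]); x }
  switch(cls,
    Conserved = {
      th <- u()
      list(thetaP = th, thetaC = th, thetaA = th)
    },
    NeofunctionalizedParent = {
      th <- u(); tp <- u()
      repeat { bad <- abs(tp - th) < tol
               if (!any(bad)) break
               tp <- redraw(tp, bad) }
      list(thetaP = tp, thetaC = th, thetaA = th)
    },
    NeofunctionalizedChild = {
      th <- u(); tc <- u()
      repeat { bad <- abs(tc - th) < tol
               if (!any(bad)) break
               tc <- redraw(tc, bad) }
      list(thetaP = th, thetaC = tc, thetaA = th)
    },
    Subfunctionalized = {
      ta <- u(); tp <- u()
      repeat { tc <- ta - tp    # theta_P + theta_C = theta_A, exactly
               bad <- abs(tp - ta) < tol | abs(tc - ta) < tol
               if (!any(bad)) break
               tp <- redraw(tp, bad) }
      list(thetaP = tp, thetaC = ta - tp, thetaA = ta)
    },
    Specialized = {
      ta <- u(); tp <- u(); tc <- u()
      repeat { bad <- abs(tp - ta) < tol | abs(tc - ta) < tol |
                      abs(tp + tc - ta) < tol
               if (!any(bad)) break
               tp <- redraw(tp, bad); tc <- redraw(tc, bad) }
      list(thetaP = tp, thetaC = tc, thetaA = ta)
    },
    stop("unknown retention class: ", cls))
}

#' Draw duplicate-gene scenarios under retention-class constraints
#'
#' Samples n scenarios of per-tissue OU parameters for a given retention
#' class (or a per-tissue mixture of two classes). For each tissue
#' independently, alpha and sigma2 are drawn log-uniformly and the optima
#' uniformly subject to the class constraint: Conserved shares one optimum
#' across P, C, A; the neofunctionalized classes free one copy's optimum;
#' Subfunctionalized enforces thetaP + thetaC = thetaA exactly;
#' Specialized draws all three freely subject to thetaP, thetaC differing
#' from thetaA and thetaP + thetaC differing from thetaA. "Not equal"
#' constraints are enforced by resampling at tolerance 1e-6.
#'
#' @param cls retention class label (see [retentionClasses()]); or a
#'   character vector of length m giving one label per tissue for
#'   mixed-mechanism scenarios.
#' @param n number of scenarios.
#' @param m number of tissues (6 in the standard six-tissue setting).
#' @param ranges parameter ranges, see [parameterRanges()].
#' @param tpcPool optional numeric vector of scaled duplication times to
#'   resample from (e.g. extracted from empirical gene trees); when NULL,
#'   tPC is drawn uniformly from \code{ranges$tPC}.
#' @param seed integer seed.
#' @return a [DuplicateScenarioSet-class].
#' @examples
#' drawScenarios("Subfunctionalized", n = 5, m = 6, seed = 7)
#' @export
drawScenarios <- function(cls, n, m = 6L, ranges = parameterRanges(),
                          tpcPool = NULL, seed) {
  stopifnot(n >= 1L, m >= 1L)
  perTissue <- length(cls) > 1L
  if (perTissue && length(cls) != m)
    stop("per-tissue class vector must have length m")
  if (!all(cls %in% retentionClasses()))
    stop("unknown retention class: ", paste(setdiff(cls, retentionClasses()),
                                            collapse = ", "))
  set.seed(childSeed(seed, paste0("scenario.", paste(cls, collapse = "+"))))
  tPC <- if (is.null(tpcPool)) runif(n, ranges$tPC[1L], ranges$tPC[2L])
         else sample(tpcPool, n, replace = TRUE)
  alpha <- matrix(10^runif(n * m, ranges$log10alpha[1L],
                           ranges$log10alpha[2L]), n, m)
  sigma2 <- matrix(10^runif(n * m, ranges$log10sigma2[1L],
                            ranges$log10sigma2[2L]), n, m)
  thetaP <- thetaC <- thetaA <- matrix(0, n, m)
  classes <- matrix("", n, m)
  if (perTissue) {
    for (j in seq_len(m)) {
      th <- .drawThetas(cls[j], n, ranges$theta)
      thetaP[, j] <- th$thetaP; thetaC[, j] <- th$thetaC
      thetaA[, j] <- th$thetaA
      classes[, j] <- cls[j]
    }
  } else {
    th <- .drawThetas(cls, n * m, ranges$theta)
    thetaP[] <- th$thetaP; thetaC[] <- th$thetaC; thetaA[] <- th$thetaA
    classes[] <- cls
  }
  new("DuplicateScenarioSet", tPC = tPC, thetaP = thetaP, thetaC = thetaC,
      thetaA = thetaA, alpha = alpha, sigma2 = sigma2, classes = classes)
}

#' Concatenate scenario sets
#' @param ... DuplicateScenarioSet objects with equal tissue counts.
#' @return a single [DuplicateScenarioSet-class].
#' @export
bindScenarios <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L,
            all(vapply(xs, is, logical(1), "DuplicateScenarioSet")))
  new("DuplicateScenarioSet",
      tPC = unlist(lapply(xs, function(x) x@tPC)),
      thetaP = do.call(rbind, lapply(xs, function(x) x@thetaP)),
      thetaC = do.call(rbind, lapply(xs, function(x) x@thetaC)),
      thetaA = do.call(rbind, lapply(xs, function(x) x@thetaA)),
      alpha = do.call(rbind, lapply(xs, function(x) x@alpha)),
      sigma2 = do.call(rbind, lapply(xs, function(x) x@sigma2)),
      classes = do.call(rbind, lapply(xs, function(x) x@classes)))
}

#' Per-tissue parameter targets of a scenario set
#'
#' The regression targets used by the parameter predictor: for each tissue,
#' (thetaP, thetaC, thetaA, log10 alpha, log10 sigma2), tissues concatenated.
#' alpha and sigma2 are regressed on the log10 scale, the scale on which the
#' training draws are uniform.
#'
#' @param object a [DuplicateScenarioSet-class] or [LabeledDataset-class].
#' @return n x 5m matrix with columns \code{thetaP1, thetaC1, thetaA1,
#'   log10alpha1, log10sigma21, thetaP2, ...}.
#' @export
parameterTargets <- function(object) {
  if (is(object, "LabeledDataset")) object <- object@scenarios
  stopifnot(is(object, "DuplicateScenarioSet"))
  m <- nTissues(object)
  cols <- lapply(seq_len(m), function(j)
    cbind(object@thetaP[, j], object@thetaC[, j], object@thetaA[, j],
          log10(object@alpha[, j]), log10(object@sigma2[, j])))
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(seq_len(m), function(j)
    paste0(c("thetaP", "thetaC", "thetaA", "log10alpha", "log10sigma2"), j),
    character(5)))
  out
}

#' Write scenario truth as a tab-separated table
#'
#' One row per scenario: per-tissue class labels, tPC, and the 5m per-tissue
#' parameters (on their natural scales).
#' @param scenarios a [DuplicateScenarioSet-class].
#' @param path output file path.
#' @export
writeScenarioTable <- function(scenarios, path) {
  stopifnot(is(scenarios, "DuplicateScenarioSet"))
  m <- nTissues(scenarios)
  pars <- scenarioParameters(scenarios)
  df <- data.frame(class = apply(scenarios@classes, 1L, paste,
                                 collapse = ";"),
                   tPC = scenarios@tPC)
  for (j in seq_len(m)) {
    blk <- data.frame(pars$thetaP[, j], pars$thetaC[, j], pars$thetaA[, j],
                      pars$alpha[, j], pars$sigma2[, j])
    names(blk) <- paste0(c("thetaP", "thetaC", "thetaA", "alpha", "sigma2"), j)
    df <- cbind(df, blk)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
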