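# site-pattern compression: integer matrix (taxa x sites) -> list(patterns
# matrix taxa x npat, weights)
compressPatterns <- function(enc) {
  key <- apply(enc, 2, paste, collapse = "\r")
  ux <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[ux])))
  list(patterns = enc[, ux, drop = FALSE], weights = w)
}

#' Felsenstein pruning log-likelihood of an alignment on a tree
#'
#' Computes the log-likelihood of the masked alignment on the given tree
#' under a substitution model with optional invariable-site and
#' discrete-gamma mixtures, using the pruning algorithm with site-pattern
#' compression and per-node rescaling.  Gap, \code{?} and N residues are
#' treated as missing data (partial likelihood 1 for every state), so an
#' all-gap taxon leaves the likelihood unchanged.
#'
#' @param aln a BarcodeAlignment whose taxa include all tree tips.
#' @param tree phylo (rooted or unrooted) with branch lengths in expected
#'   substitutions per site.
#' @param model a SubstitutionModel.
#' @return log-likelihood (finite, or an error naming the offending
#'   pattern).
#' @export
treeLogLik <- function(aln, tree, model) {
  missing <- setdiff(tree$tip.label, taxa(aln))
  if (length(missing))
    stop("tree tips absent from alignment: ", paste(missing, collapse = ", "))
  m <- maskedMatrix(aln)[tree$tip.label, , drop = FALSE]
  enc <- matrix(match(m, DNA_BASES), nrow(m), ncol(m))
  cp <- compressPatterns(enc)
  pat <- cp$patterns; w <- cp$weights
  npat <- ncol(pat)
  ntip <- nrow(pat)
  nnode <- tree$Nnode
  ed <- modelEigen(model)
  rates <- gammaCategoryRates(model@alpha, model@nCat, model@pInv)
  pInv <- model@pInv
  pi <- model@pi

  # tip partials (4 x npat per tip), shared across categories
  tipPart <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    X <- matrix(0, 4, npat)
    b <- pat[i, ]
    obs <- !is.na(b)
    X[, !obs] <- 1
    X[cbind(b[obs], which(obs))] <- 1
    tipPart[[i]] <- X
  }

  tr <- ape::reorder.phylo(tree, "postorder")
  parent <- tr$edge[, 1]; child <- tr$edge[, 2]; elen <- tr$edge.length
  root <- parent[length(parent)]
  nChildren <- tabulate(parent, nbins = ntip + nnode)

  siteLvar <- matrix(0, length(rates), npat)
  for (ci in seq_along(rates)) {
    part <- vector("list", ntip + nnode)
    done <- integer(ntip + nnode)
    scaleLog <- rep(0, npat)
    Ps <- lapply(elen, function(t) pFromEigen(ed, t * rates[ci]))
    for (e in seq_along(parent)) {
      ch <- child[e]
      X <- if (ch <= ntip) tipPart[[ch]] else part[[ch]]
      contrib <- Ps[[e]] %*% X
      pa <- parent[e]
      part[[pa]] <- if (is.null(part[[pa]])) contrib else part[[pa]] * contrib
      done[pa] <- done[pa] + 1L
      if (done[pa] == nChildren[pa]) {
        mx <- apply(part[[pa]], 2, max)
        mx[mx <= 0] <- 1
        part[[pa]] <- sweep(part[[pa]], 2, mx, "/")
        scaleLog <- scaleLog + log(mx)
      }
    }
    siteLvar[ci, ] <- colSums(pi * part[[root]]) * exp(scaleLog)
  }
  Lvar <- colMeans(siteLvar)

  siteL <- (1 - pInv) * Lvar
  if (pInv > 0) {
    # invariant-class likelihood: sum_b pi_b * prod_tips 1{tip compatible b}
    comp <- matrix(1, 4, npat)
    for (i in seq_len(ntip)) comp <- comp * tipPart[[i]]
    siteL <- siteL + pInv * colSums(pi * comp)
  }
  if (any(siteL <= 0))
    stop("zero likelihood at site pattern ", which(siteL <= 0)[1])
  ll <- sum(w * log(siteL))
  if (!is.finite(ll)) stop("non-finite tree log-likelihood")
  ll
}

modelToPml <- function(aln, tree, model) {
  dat <- alignmentToPhyDat(aln)
  phangorn::pml(tree, dat, bf = as.numeric(model@pi),
                Q = as.numeric(model@rates),
                inv = model@pInv,
                k = if (is.na(model@alpha)) 1L else model@nCat,
                shape = if (is.na(model@alpha)) 1 else model@alpha)
}

#' Strict molecular clock likelihood-ratio test
#'
#' Compares the maximum log-likelihood of free branch lengths (2n-3
#' parameters on the unrooted topology) against branch lengths constrained
#' to a strict clock (n-1 node heights on the rooted topology).  The model
#' parameters are held fixed; only branch lengths / node heights are
#' optimised.  \eqn{LR = 2(\log L_{free} - \log L_{clock})} is referred to
#' a chi-squared distribution with n-2 degrees of freedom.
#'
#' @param aln a BarcodeAlignment.
#' @param topology phylo; if unrooted it is midpoint-rooted (or rooted on
#'   \code{outgroup} when given).  If NULL, the JC69 NJ tree is used.
#' @param model a SubstitutionModel.
#' @param outgroup optional tip label(s) to root on.
#' @return list with \code{logLFree}, \code{logLClock}, \code{LR},
#'   \code{df}, \code{p}, and the two optimised trees.
#' @export
strictClockTest <- function(aln, topology = NULL, model, outgroup = NULL) {
  if (is.null(topology)) topology <- jcGuideTree(aln)
  n <- length(topology$tip.label)
  if (n < 3) stop("need at least 3 taxa")
  rooted <- if (!is.null(outgroup))
    ape::root(ape::unroot(topology), outgroup = outgroup,
              resolve.root = TRUE)
  else if (ape::is.rooted(topology)) topology
  else phangorn::midpoint(topology)
  rooted <- ape::multi2di(rooted)

  ctl <- phangorn::pml.control(trace = 0, epsilon = 1e-8, maxit = 50)
  fitFree <- phangorn::optim.pml(
    modelToPml(aln, ape::unroot(rooted), model),
    optEdge = TRUE, control = ctl)

  dm <- distanceMatrix(aln, method = "jc69")
  start <- phangorn::nnls.tree(as.dist(dm@values[rooted$tip.label,
                                                 rooted$tip.label]),
                               rooted, method = "ultrametric")
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  fitClock <- phangorn::optim.pml(
    modelToPml(aln, start, model),
    optEdge = TRUE, optRooted = TRUE, control = ctl)

  logLFree <- fitFree$logLik
  logLClock <- fitClock$logLik
  if (logLClock > logLFree + 1e-4)
    stop("internal error: clock optimum exceeds free optimum (",
         logLClock, " > ", logLFree, ")")
  LR <- max(0, 2 * (logLFree - logLClock))
  df <- n - 2
  list(logLFree = logLFree, logLClock = logLClock, LR = LR, df = df,
       p = pchisq(LR, df, lower.tail = FALSE),
       freeTree = fitFree$tree, clockTree = fitClock$tree)
}
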