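# phangorn rate-sharing patterns (order rAC, rAG, rAT, rCG, rCT, rGT;
# 0 = reference rate, equal positive integers share one free rate)
FAMILY_SUBS <- list(
  JC69  = c(0, 0, 0, 0, 0, 0),
  K80   = c(0, 1, 0, 0, 1, 0),
  F81   = c(0, 0, 0, 0, 0, 0),
  HKY85 = c(0, 1, 0, 0, 1, 0),
  TIM2  = c(1, 2, 1, 0, 3, 0),
  GTR   = c(1, 2, 3, 4, 5, 0))

# free parameters besides branch lengths (base frequencies counted as
# parameters even when set empirically, the jModelTest convention)
FAMILY_K <- c(JC69 = 0, K80 = 1, F81 = 3, HKY85 = 4, TIM2 = 6, GTR = 8)

alignmentToPhyDat <- function(aln) {
  m <- tolower(maskedMatrix(aln))
  m[m == "?"] <- "-"
  phangorn::phyDat(m, type = "DNA")
}

# JC69 NJ guide tree from the masked alignment
jcGuideTree <- function(aln) {
  dm <- distanceMatrix(aln, method = "jc69")
  if (any(dm@saturated))
    stop("saturated JC69 distances; cannot build the guide tree")
  neighborJoining(dm)
}

#' Estimate substitution-model parameters on a fixed guide topology
#'
#' Follows the classic distance-software workflow: a Jukes-Cantor
#' neighbor-joining guide tree is built from the masked alignment, then
#' branch lengths and the free model parameters (exchangeabilities, base
#' frequencies if requested, proportion of invariable sites, gamma shape)
#' are jointly optimised by maximising the Felsenstein pruning likelihood.
#' Base frequencies default to their empirical values; ML estimation is
#' optional.  The optimisation (coordinate ascent with fixed starting
#' values) is deterministic given the data.
#'
#' @param aln a BarcodeAlignment with at least 4 taxa.
#' @param family model family.
#' @param withInv estimate a proportion of invariable sites.
#' @param withGamma estimate a discrete-gamma shape (4 categories).
#' @param mlFreq optimise base frequencies by ML instead of using
#'   empirical frequencies (families with free frequencies only).
#' @param nCat gamma categories.
#' @param guideTree optional phylo to use instead of the JC69 NJ tree.
#' @return A \linkS4class{SubstitutionModel} with attributes
#'   \code{logLik}, \code{df} (free parameter count including branch
#'   lengths) and \code{tree} (the optimised guide tree).
#' @export
estimateModelParameters <- function(aln, family = "GTR", withInv = FALSE,
                                    withGamma = FALSE, mlFreq = FALSE,
                                    nCat = 4L, guideTree = NULL) {
  family <- match.arg(family, MODEL_FAMILIES)
  if (nrow(aln@seqs) < 4) stop("need at least 4 taxa")
  dat <- alignmentToPhyDat(aln)

  if (length(unique(apply(maskedMatrix(aln), 1, paste, collapse = ""))) == 1) {
    # degenerate: all rows identical; likelihood is maximised at zero
    # branch lengths with the invariable proportion at its boundary
    mod <- substitutionModel(family, pi = empiricalBaseFreqs(aln),
                             pInv = if (withInv) 1 - 1e-8 else 0,
                             alpha = if (withGamma) 100 else NA_real_,
                             nCat = nCat)
    attr(mod, "logLik") <- NA_real_
    attr(mod, "df") <- NA_real_
    attr(mod, "tree") <- NULL
    return(mod)
  }

  tree <- if (is.null(guideTree)) jcGuideTree(aln) else guideTree
  tree <- ape::unroot(tree)
  tree$edge.length[tree$edge.length < 1e-8] <- 1e-8
  bf <- if (family %in% c("JC69", "K80")) rep(0.25, 4) else
    as.numeric(empiricalBaseFreqs(aln))
  fit <- phangorn::pml(tree, dat, bf = bf,
                       k = if (withGamma) nCat else 1L,
                       shape = 1, inv = 0)
  subs <- FAMILY_SUBS[[family]]
  optQ <- any(subs > 0) || family == "GTR"
  optBf <- mlFreq && !family %in% c("JC69", "K80")
  fit <- tryCatch(
    phangorn::optim.pml(fit, optEdge = TRUE, optQ = optQ, optBf = optBf,
                        optInv = withInv, optGamma = withGamma, subs = subs,
                        control = phangorn::pml.control(trace = 0,
                                                        epsilon = 1e-8,
                                                        maxit = 25)),
    error = function(e) stop("model optimisation failed for ", family, ": ",
                             conditionMessage(e), call. = FALSE))
  mod <- substitutionModel(family, pi = fit$bf, rates = fit$Q,
                           kappa = if (family %in% c("K80", "HKY85"))
                             fit$Q[2] else NULL,
                           pInv = if (withInv) fit$inv else 0,
                           alpha = if (withGamma) fit$shape else NA_real_,
                           nCat = nCat)
  k <- FAMILY_K[[family]] + withInv + withGamma +
    length(fit$tree$edge.length)
  attr(mod, "logLik") <- fit$logLik
  attr(mod, "df") <- k
  attr(mod, "tree") <- fit$tree
  mod
}

#' Rank candidate models by AIC
#'
#' Fits every requested family x rate-variation combination on the same
#' Jukes-Cantor neighbor-joining guide topology and ranks them by
#' \eqn{AIC = 2k - 2\log L}, where k counts the free model parameters plus
#' the branch lengths.  Candidates whose optimisation fails are reported in
#' the \code{failed} attribute and excluded.  Ties are broken toward the
#' smaller k.
#'
#' @param aln a BarcodeAlignment.
#' @param families model families to consider.
#' @param variants subset of \code{c("plain", "I", "G", "IG")}.
#' @param mlFreq optimise base frequencies by ML.
#' @return data.frame with columns model, logL, k, AIC, in ascending AIC
#'   order.
#' @export
rankModelsAIC <- function(aln, families = MODEL_FAMILIES,
                          variants = c("plain", "I", "G", "IG"),
                          mlFreq = FALSE) {
  families <- match.arg(families, MODEL_FAMILIES, several.ok = TRUE)
  variants <- match.arg(variants, c("plain", "I", "G", "IG"),
                        several.ok = TRUE)
  guide <- jcGuideTree(aln)
  rows <- list(); failed <- character(0)
  for (fam in families) for (v in variants) {
    withInv <- v %in% c("I", "IG")
    withGamma <- v %in% c("G", "IG")
    label <- paste0(fam, if (withInv) "+I" else "",
                    if (withGamma) "+G" else "")
    mod <- tryCatch(
      estimateModelParameters(aln, fam, withInv, withGamma, mlFreq,
                              guideTree = guide),
      error = function(e) NULL)
    if (is.null(mod) || is.na(attr(mod, "logLik"))) {
      failed <- c(failed, label)
      next
    }
    rows[[label]] <- data.frame(model = label,
                                logL = attr(mod, "logLik"),
                                k = attr(mod, "df"),
                                AIC = 2 * attr(mod, "df") -
                                  2 * attr(mod, "logLik"))
  }
  if (!length(rows)) stop("every candidate model failed")
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$AIC, tab$k), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "failed") <- failed
  tab
}
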