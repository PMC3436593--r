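#' Construct a substitution model
#'
#' Builds a \linkS4class{SubstitutionModel} enforcing the family
#' constraints.  For JC69 and K80 the base frequencies are fixed uniform;
#' for K80 and HKY85 a single transition/transversion ratio \code{kappa}
#' parameterises the rates; TIM2 constrains \code{rAC = rAT} and
#' \code{rCG = rGT}; GTR leaves all six exchangeabilities free.
#'
#' @param family one of \code{"JC69","K80","F81","HKY85","TIM2","GTR"}.
#' @param pi base frequencies (A, C, G, T); ignored (forced uniform) for
#'   JC69/K80.
#' @param rates six exchangeabilities \code{rAC,rAG,rAT,rCG,rCT,rGT}; for
#'   JC69/F81 they are forced equal, for K80/HKY85 derived from
#'   \code{kappa}.
#' @param kappa transition/transversion rate ratio (K80, HKY85).
#' @param pInv proportion of invariable sites in [0, 1).
#' @param alpha gamma shape (> 0) or \code{NA} for no rate variation.
#' @param nCat discrete gamma categories.
#' @return A \linkS4class{SubstitutionModel}.
#' @export
substitutionModel <- function(family = "JC69", pi = rep(0.25, 4),
                              rates = rep(1, 6), kappa = NULL,
                              pInv = 0, alpha = NA_real_, nCat = 4L) {
  family <- match.arg(family, MODEL_FAMILIES)
  pi <- unname(pi)
  if (family %in% c("JC69", "K80")) pi <- rep(0.25, 4)
  if (family %in% c("JC69", "F81")) rates <- rep(1, 6)
  if (family %in% c("K80", "HKY85")) {
    if (is.null(kappa)) kappa <- rates[2]
    rates <- c(1, kappa, 1, 1, kappa, 1)
  }
  if (family == "TIM2") rates <- c(rates[1], rates[2], rates[1],
                                   rates[4], rates[5], rates[4])
  new("SubstitutionModel", family = family,
      pi = setNames(pi / sum(pi), DNA_BASES),
      rates = setNames(unname(rates), RATE_NAMES),
      pInv = pInv, alpha = as.numeric(alpha), nCat = as.integer(nCat))
}

setMethod("show", "SubstitutionModel", function(object) {
  tag <- object@family
  if (object@pInv > 0) tag <- paste0(tag, "+I")
  if (!is.na(object@alpha)) tag <- paste0(tag, "+G")
  cat("SubstitutionModel:", tag, "\n")
  cat("  pi:   ", paste(sprintf("%s=%.4f", DNA_BASES, object@pi),
                        collapse = " "), "\n")
  cat("  rates:", paste(sprintf("%s=%.4f", RATE_NAMES, object@rates),
                        collapse = " "), "\n")
  if (object@pInv > 0) cat("  pInv: ", format(object@pInv), "\n")
  if (!is.na(object@alpha))
    cat("  alpha:", format(object@alpha), " (", object@nCat, "categories )\n")
})

#' Model tag string, e.g. "GTR+I+G"
#' @param model a SubstitutionModel.
#' @export
modelTag <- function(model) {
  tag <- model@family
  if (model@pInv > 0) tag <- paste0(tag, "+I")
  if (!is.na(model@alpha)) tag <- paste0(tag, "+G")
  tag
}

#' Normalised instantaneous rate matrix
#'
#' Q with \code{Q[i,j] = r_ij * pi_j} off the diagonal, rows summing to
#' zero, scaled so the expected substitution rate \eqn{-\sum_i \pi_i Q_{ii}}
#' is 1.  Detailed balance \eqn{\pi_i Q_{ij} = \pi_j Q_{ji}} holds by
#' construction.
#'
#' @param model a SubstitutionModel.
#' @return 4x4 numeric matrix (A, C, G, T).
#' @export
rateMatrix <- function(model) {
  r <- model@rates; pi <- model@pi
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  Q[1, 2] <- r[1]; Q[1, 3] <- r[2]; Q[1, 4] <- r[3]
  Q[2, 3] <- r[4]; Q[2, 4] <- r[5]; Q[3, 4] <- r[6]
  Q <- Q + t(Q)
  Q <- Q * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu <= 0) stop("degenerate rate matrix (all rates zero?)")
  Q / mu
}

#' Discrete-gamma category rates
#'
#' Mean-one discretisation of a Gamma(alpha, alpha) distribution into
#' \code{nCat} equal-probability categories, each category's rate being the
#' mean of its quantile slice.  When \code{pInv > 0} the rates are rescaled
#' by 1/(1 - pInv) so that branch lengths keep counting expected
#' substitutions per site averaged over all sites.
#'
#' @param alpha gamma shape (NA = single category of rate 1).
#' @param nCat number of categories.
#' @param pInv proportion of invariable sites.
#' @return numeric vector of category rates.
#' @export
gammaCategoryRates <- function(alpha, nCat = 4L, pInv = 0) {
  if (is.na(alpha)) {
    r <- 1
  } else {
    # slice means: E[X | q_{i-1} < X <= q_i] via the Gamma(alpha+1) trick
    q <- qgamma(seq(0, 1, length.out = nCat + 1), alpha, alpha)
    p1 <- pgamma(q, alpha + 1, alpha)
    r <- diff(p1) * nCat
    r <- r / mean(r)
  }
  r / (1 - pInv)
}

# Symmetric eigendecomposition of Q for fast, stable matrix exponentials.
# Returns closures shared by the pairwise-distance and pruning engines.
modelEigen <- function(model) {
  Q <- rateMatrix(model)
  pi <- model@pi
  s <- sqrt(pi)
  B <- Q * rep(s, times = 4) / rep(s, each = 4)  # diag(s) Q diag(1/s)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors / rep(s, times = 4)        # diag(1/s) V
  Vt <- t(e$vectors * rep(s, times = 4))    # t(diag(s) V)
  list(values = e$values, U = U, Vt = Vt)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a SubstitutionModel.
#' @param t branch length (expected substitutions per site); category rate
#'   scaling is applied by the callers, not here.
#' @return 4x4 stochastic matrix.
#' @export
transitionProb <- function(model, t) {
  if (t < 0) stop("negative branch length")
  ed <- modelEigen(model)
  P <- ed$U %*% (exp(ed$values * t) * ed$Vt)
  P[P < 0] <- 0
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  P
}

pFromEigen <- function(ed, t) {
  P <- ed$U %*% (exp(ed$values * t) * ed$Vt)
  P[P < 0] <- 0
  P
}

#' Empirical base frequencies of an alignment
#'
#' Frequencies of A, C, G, T over the included columns, ignoring gaps and
#' missing residues.
#'
#' @param aln a BarcodeAlignment.
#' @return named numeric vector of length 4.
#' @export
empiricalBaseFreqs <- function(aln) {
  m <- maskedMatrix(aln)
  counts <- vapply(DNA_BASES, function(b) sum(m == b), 0)
  if (sum(counts) == 0) stop("no unambiguous bases in alignment")
  counts / sum(counts)
}

#' Write model parameters as a flat key=value block
#'
#' @param model a SubstitutionModel.
#' @param path output path.
#' @export
writeModelParameters <- function(model, path) {
  lines <- c(paste0("family=", model@family),
             paste0("pi", DNA_BASES, "=", format(model@pi, digits = 10)),
             paste0(RATE_NAMES, "=", format(model@rates, digits = 10)),
             paste0("pInv=", format(model@pInv, digits = 10)),
             paste0("alpha=", format(model@alpha, digits = 10)),
             paste0("nCat=", model@nCat))
  writeLines(lines, path)
  invisible(path)
}
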