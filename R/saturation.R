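#' Sitewise nucleotide entropies
#'
#' Shannon entropy (bits) of the base composition of each included column,
#' computed over the taxa carrying a plain base.  Columns containing any
#' gap/\code{?}/N are excluded entirely (the test is run "under exclusion
#' of gaps"); columns left without an unambiguous base are likewise
#' excluded and counted in the \code{excluded} attribute.
#'
#' @param aln a BarcodeAlignment.
#' @return numeric vector of per-column entropies with attribute
#'   \code{excluded} (number of dropped columns).
#' @export
sitewiseEntropy <- function(aln) {
  m <- maskedMatrix(aln)
  enc <- apply(m, 2, encodeRow)
  gapped <- colSums(is.na(enc)) > 0
  H <- apply(enc[, !gapped, drop = FALSE], 2, function(col) {
    f <- tabulate(col, 4)
    f <- f[f > 0] / sum(f)
    -sum(f * log2(f))
  })
  structure(H, excluded = sum(gapped))
}

columnBases <- function(aln) {
  # per ungapped column: the constant base (1..4) or NA when variable
  m <- maskedMatrix(aln)
  enc <- apply(m, 2, encodeRow)
  gapped <- colSums(is.na(enc)) > 0
  apply(enc[, !gapped, drop = FALSE], 2, function(col) {
    u <- unique(col)
    if (length(u) == 1) u else NA_integer_
  })
}

issCore <- function(aln, pInv) {
  # returns list(iss, se, nSites) or NULL when no usable signal
  m <- maskedMatrix(aln)
  enc <- apply(m, 2, encodeRow)
  gapped <- colSums(is.na(enc)) > 0
  enc <- enc[, !gapped, drop = FALSE]
  if (ncol(enc) == 0) return(NULL)
  H <- apply(enc, 2, function(col) {
    f <- tabulate(col, 4)
    f <- f[f > 0] / sum(f)
    -sum(f * log2(f))
  })
  constBase <- apply(enc, 2, function(col) {
    u <- unique(col); if (length(u) == 1) u else NA_integer_
  })
  keep <- rep(TRUE, ncol(enc))
  if (pInv > 0) {
    # remove the estimated invariable fraction, allocated over the
    # constant-column base types proportionally to their abundance
    nInv <- pInv * ncol(enc)
    for (b in 1:4) {
      idx <- which(!is.na(constBase) & constBase == b)
      if (!length(idx)) next
      drop <- min(length(idx),
                  round(nInv * length(idx) / sum(!is.na(constBase))))
      if (drop > 0) keep[idx[seq_len(drop)]] <- FALSE
    }
  }
  H <- H[keep]
  enc <- enc[, keep, drop = FALSE]
  if (!length(H) || all(H == 0)) return(NULL)
  f <- tabulate(as.vector(enc), 4)
  f <- f[f > 0] / sum(f)
  hFull <- -sum(f * log2(f))
  if (hFull <= 0) return(NULL)
  list(iss = mean(H) / hFull,
       se = sd(H) / sqrt(length(H)) / hFull,
       nSites = length(H))
}

#' Test for substitution saturation (entropy-based index)
#'
#' Computes the index of substitution saturation: the mean of the sitewise
#' entropies divided by the full-saturation entropy expected from the
#' global base frequencies.  The externally estimated proportion of
#' invariable sites is removed from the constant columns before averaging.
#' The index is compared against critical values for symmetric and
#' asymmetric true topologies by a two-sided t-test using the standard
#' error of the sitewise entropies.  Data sets larger than 32 taxa are
#' evaluated on random subsamples of \code{nOtu} taxa, averaged over
#' \code{nResamples} rounds.
#'
#' Verdict (decision table): index below the critical value with a
#' significant difference = \code{"low saturation"}; below but not
#' significant = \code{"substantial saturation"}; above and not significant
#' = \code{"poor"}; above with a significant difference = \code{"useless"}.
#'
#' @param aln a BarcodeAlignment with at least 4 taxa.
#' @param pInv proportion of invariable sites from an external
#'   maximum-likelihood estimate.
#' @param nOtu taxa per evaluation: 4, 8, 16 or 32.
#' @param nResamples resampling rounds for data sets larger than
#'   \code{nOtu}.
#' @param seed RNG seed for the OTU resampling.
#' @param criticalTable optional critical-value table (see
#'   \code{\link{issCriticalValue}}).
#' @param alpha significance level of the t-test.
#' @return A \linkS4class{SaturationResult}.
#' @export
issTest <- function(aln, pInv = 0, nOtu = 32, nResamples = 100, seed = 1,
                    criticalTable = NULL, alpha = 0.05) {
  n <- nrow(aln@seqs)
  if (n < 4) stop("need at least 4 taxa")
  nOtu <- as.integer(match.arg(as.character(nOtu), c("4", "8", "16", "32")))
  nOtu <- min(nOtu, n)
  set.seed(seed)

  if (n > nOtu) {
    res <- vector("list", nResamples)
    for (r in seq_len(nResamples)) {
      idx <- sample(n, nOtu)
      sub <- new("BarcodeAlignment",
                 seqs = aln@seqs[idx, , drop = FALSE], mask = aln@mask)
      res[[r]] <- issCore(sub, pInv)
    }
    res <- res[!vapply(res, is.null, TRUE)]
    nRes <- length(res)
    if (!nRes) {
      out <- NULL
    } else {
      out <- list(iss = mean(vapply(res, `[[`, 0, "iss")),
                  se = mean(vapply(res, `[[`, 0, "se")),
                  nSites = as.integer(round(
                    mean(vapply(res, `[[`, 0, "nSites")))))
    }
    nResamples <- max(nRes, 1L)
  } else {
    out <- issCore(aln, pInv)
    nResamples <- 1L
  }

  if (is.null(out))
    return(new("SaturationResult", iss = 0, seIss = 0,
               issCSym = NA_real_, issCAsym = NA_real_,
               pSym = NA_real_, pAsym = NA_real_,
               nOtuUsed = nOtu, nResamples = nResamples,
               nSites = 0L, verdict = "no signal"))

  cSym <- issCriticalValue(nOtu, out$nSites, "symmetric", criticalTable)
  cAsym <- issCriticalValue(nOtu, out$nSites, "asymmetric", criticalTable)
  tp <- function(crit) {
    if (is.na(crit) || out$se == 0) return(NA_real_)
    tval <- (out$iss - crit) / out$se
    2 * pt(abs(tval), df = out$nSites - 1, lower.tail = FALSE)
  }
  pSym <- tp(cSym); pAsym <- tp(cAsym)
  verdictOf <- function(crit, p) {
    if (is.na(crit) || is.na(p)) return("no signal")
    sig <- p < alpha
    if (out$iss < crit) {
      if (sig) "low saturation" else "substantial saturation"
    } else {
      if (sig) "useless" else "poor"
    }
  }
  new("SaturationResult", iss = out$iss, seIss = out$se,
      issCSym = cSym, issCAsym = cAsym, pSym = pSym, pAsym = pAsym,
      nOtuUsed = nOtu, nResamples = as.integer(nResamples),
      nSites = as.integer(out$nSites),
      verdict = verdictOf(cSym, pSym))
}

setMethod("show", "SaturationResult", function(object) {
  cat("Substitution-saturation test\n")
  cat(sprintf("  Iss = %.4f (se %.4f; %d sites, %d OTUs, %d resamples)\n",
              object@iss, object@seIss, object@nSites, object@nOtuUsed,
              object@nResamples))
  cat(sprintf("  Iss.c symmetric  = %.4f  (p = %.4g)\n",
              object@issCSym, object@pSym))
  cat(sprintf("  Iss.c asymmetric = %.4f  (p = %.4g)\n",
              object@issCAsym, object@pAsym))
  cat("  verdict:", object@verdict, "\n")
})

#' @describeIn issTest key=value report block plus verdict sentence.
#' @param result a SaturationResult.
#' @export
formatSaturationReport <- function(result) {
  c(paste0("iss=", format(result@iss, digits = 8)),
    paste0("se_iss=", format(result@seIss, digits = 8)),
    paste0("iss_c_sym=", format(result@issCSym, digits = 8)),
    paste0("iss_c_asym=", format(result@issCAsym, digits = 8)),
    paste0("p_sym=", format(result@pSym, digits = 8)),
    paste0("p_asym=", format(result@pAsym, digits = 8)),
    paste0("n_otu_used=", result@nOtuUsed),
    paste0("n_resamples=", result@nResamples),
    paste0("n_sites=", result@nSites),
    paste0("verdict=", result@verdict))
}

issTableCache <- new.env(parent = emptyenv())

loadIssTable <- function() {
  if (!is.null(issTableCache$tab)) return(issTableCache$tab)
  path <- system.file("extdata", "issc_table.tsv", package = "BarcodeDelim")
  if (path == "")
    path <- file.path("inst", "extdata", "issc_table.tsv")
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  issTableCache$tab <- tab
  tab
}

#' Critical value of the saturation index
#'
#' Looks up the critical index for the given OTU count, the nearest
#' tabulated sequence length, and the topology class.  The shipped table
#' was re-derived empirically with \code{\link{regenerateIssCritical}}
#' (simulating sequences on symmetric and asymmetric model trees of
#' increasing depth and locating the deepest depth at which
#' neighbor-joining still recovers the true topology reliably); it is a
#' synthetic stand-in for the published simulation tables, with the same
#' structure.
#'
#' @param nOtu 4, 8, 16 or 32.
#' @param nSites sequence length.
#' @param topology \code{"symmetric"} or \code{"asymmetric"}.
#' @param table optional data.frame with columns \code{n_otu},
#'   \code{n_sites}, \code{topology}, \code{iss_c} overriding the shipped
#'   table.
#' @return critical index value.
#' @export
issCriticalValue <- function(nOtu, nSites, topology = "symmetric",
                             table = NULL) {
  topology <- match.arg(topology, c("symmetric", "asymmetric"))
  tab <- if (is.null(table)) loadIssTable() else table
  tab <- tab[tab$topology == topology, , drop = FALSE]
  if (!nrow(tab)) return(NA_real_)
  at <- function(no) {
    sub <- tab[tab$n_otu == no, , drop = FALSE]
    if (!nrow(sub)) return(NA_real_)
    sub$iss_c[which.min(abs(sub$n_sites - nSites))]
  }
  otus <- sort(unique(tab$n_otu))
  if (nOtu %in% otus) return(at(nOtu))
  # interpolate linearly in log2(OTU count) between bracketing rows
  lo <- max(otus[otus < nOtu], -Inf)
  hi <- min(otus[otus > nOtu], Inf)
  if (!is.finite(lo)) return(at(hi))
  if (!is.finite(hi)) return(at(lo))
  w <- (log2(nOtu) - log2(lo)) / (log2(hi) - log2(lo))
  (1 - w) * at(lo) + w * at(hi)
}

# balanced (symmetric) or pectinate (asymmetric) n-tip topology with every
# branch of length `depth / levels`
issModelTree <- function(nOtu, topology, depth) {
  if (topology == "symmetric") {
    tree <- ape::stree(nOtu, type = "balanced")
    tree <- ape::compute.brlen(tree, 1)
    lev <- log2(nOtu)
    tree$edge.length <- rep(depth / lev, length(tree$edge.length))
  } else {
    tree <- ape::stree(nOtu, type = "left")
    tree <- ape::compute.brlen(tree, 1)
    tree$edge.length <- rep(depth / (nOtu - 1), length(tree$edge.length))
  }
  tree
}

#' Re-derive critical saturation indices by simulation
#'
#' For each (OTU count, sequence length, topology class) cell, sequences
#' are evolved under JC69 on the model topology over a log-spaced grid of
#' tree depths; tree-recovery performance at each depth is measured as
#' the mean fraction of true internal bipartitions present in the
#' neighbor-joining estimate.  The critical index is the mean observed
#' index at the deepest depth whose performance is still at least
#' \code{recoveryTarget} of the best performance across the grid (the
#' point where saturation starts to erode phylogenetic signal).  Slow;
#' intended for regenerating the shipped lookup table, not for routine
#' use.
#'
#' @param nOtus OTU counts.
#' @param lengths sequence lengths.
#' @param nReplicates replicates per depth evaluation.
#' @param recoveryTarget fraction of the best recovery that still counts
#'   as unimpaired.
#' @param depths depth grid (tree height in expected substitutions per
#'   site).
#' @param seed RNG seed.
#' @return data.frame with columns n_otu, n_sites, topology, iss_c.
#' @export
regenerateIssCritical <- function(nOtus = c(4, 8, 16, 32),
                                  lengths = c(200, 400, 800, 1600),
                                  nReplicates = 40,
                                  recoveryTarget = 0.95,
                                  depths = exp(seq(log(0.05), log(8),
                                                   length.out = 12)),
                                  seed = 1) {
  set.seed(seed)
  jc <- substitutionModel("JC69")
  evalDepth <- function(nOtu, L, topo, depth) {
    tree <- issModelTree(nOtu, topo, depth)
    truth <- ape::unroot(tree)
    splitSum <- 0; issSum <- 0; used <- 0
    for (r in seq_len(nReplicates)) {
      aln <- simulateAlignment(tree, jc, L, seed = sample.int(2^31 - 2, 1))
      dm <- tryCatch(distanceMatrix(aln, method = "jc69"),
                     error = function(e) NULL)
      if (is.null(dm) || any(dm@saturated)) next
      used <- used + 1
      est <- neighborJoining(dm)
      # fraction of true bipartitions recovered
      rf <- ape::dist.topo(truth, est)
      nSplits <- truth$Nnode - 1
      splitSum <- splitSum + 1 - rf / (2 * nSplits)
      core <- issCore(aln, 0)
      if (!is.null(core)) issSum <- issSum + core$iss
    }
    if (used == 0) return(c(rate = 0, iss = 1))
    c(rate = splitSum / used, iss = issSum / used)
  }
  rows <- list()
  for (nOtu in nOtus) for (L in lengths)
    for (topo in c("symmetric", "asymmetric")) {
      perf <- vapply(depths, function(d) evalDepth(nOtu, L, topo, d), c(0, 0))
      ok <- perf["rate", ] >= recoveryTarget * max(perf["rate", ])
      crit <- max(which(ok))
      rows[[length(rows) + 1]] <- data.frame(
        n_otu = nOtu, n_sites = L, topology = topo,
        iss_c = round(unname(perf["iss", crit]), 4))
    }
  do.call(rbind, rows)
}
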