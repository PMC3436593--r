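# small fixtures shared across test files

alnFromStrings <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)))
    names(seqs) <- letters[seq_along(seqs)]
  barcodeAlignment(seqs)
}

writeFastaTemp <- function(seqs) {
  tf <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", names(seqs), "\n", seqs), tf)
  tf
}

# JC69 correction of a p-distance, used as an independent closed form
jcClosedForm <- function(p) -0.75 * log(1 - 4 * p / 3)

# kappa maximum-likelihood estimate from the observed transition and
# transversion proportions (profile companion of the K2P closed form)
kappaHat <- function(a, b) {
  ia <- match(a, c("A", "C", "G", "T"))
  ib <- match(b, c("A", "C", "G", "T"))
  ok <- !is.na(ia) & !is.na(ib)
  ts <- sum((ia == 1 & ib == 3) | (ia == 3 & ib == 1) |
              (ia == 2 & ib == 4) | (ia == 4 & ib == 2))
  diffs <- sum(ia[ok] != ib[ok])
  n <- sum(ok)
  P <- ts / n; Q <- (diffs - ts) / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  (-0.5 * log(w1) + 0.25 * log(w2)) / (-0.25 * log(w2))
}

# exhaustive-summation oracle for the pruning likelihood: enumerate all
# internal-state assignments per site
bruteForceLogLik <- function(aln, tree, model) {
  m <- maskedMatrix(aln)[tree$tip.label, , drop = FALSE]
  n <- nrow(m)
  nNode <- n + tree$Nnode
  ed <- tree$edge
  rates <- gammaCategoryRates(model@alpha, model@nCat, model@pInv)
  pi <- as.numeric(model@pi)
  root <- setdiff(ed[, 1], ed[, 2])
  Pfun <- function(t) transitionProb(model, t)
  ll <- 0
  for (s in seq_len(ncol(m))) {
    obs <- match(m[, s], c("A", "C", "G", "T"))
    Lvar <- 0
    for (r in rates) {
      Ps <- lapply(tree$edge.length, function(t) Pfun(t * r))
      tot <- 0
      grid <- as.matrix(expand.grid(rep(list(1:4), tree$Nnode)))
      for (g in seq_len(nrow(grid))) {
        states <- c(obs, grid[g, ])
        pr <- pi[states[root]]
        okAll <- TRUE
        for (e in seq_len(nrow(ed))) {
          a <- states[ed[e, 1]]; b <- states[ed[e, 2]]
          if (is.na(b)) next                  # missing tip: sum to 1
          pr <- pr * Ps[[e]][a, b]
        }
        tot <- tot + pr
      }
      Lvar <- Lvar + tot / length(rates)
    }
    Linv <- 0
    if (model@pInv > 0) {
      for (b in 1:4) if (all(is.na(obs) | obs == b))
        Linv <- Linv + pi[b]
    }
    ll <- ll + log(model@pInv * Linv + (1 - model@pInv) * Lvar)
  }
  ll
}
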