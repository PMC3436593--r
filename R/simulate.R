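# build a phylo object from parent/child edge lists with lengths
assemblePhylo <- function(edge, edgeLength, tipLabels, nNode) {
  structure(list(edge = edge, edge.length = edgeLength,
                 tip.label = tipLabels, Nnode = nNode),
            class = "phylo", order = "cladewise")
}

#' Simulate a Yule (pure-birth) species tree
#'
#' Forward construction: with k extant lineages the waiting time to the
#' next speciation is Exponential(k * lambda); the lineage that splits is
#' chosen uniformly.  The returned tree is ultrametric by construction,
#' with the age of the root equal to the total simulated time span.
#'
#' @param nSpecies number of tips (>= 2).
#' @param lambda per-lineage speciation rate.
#' @param seed RNG seed (mandatory: simulations are bit-reproducible).
#' @return rooted binary ultrametric phylo with tips
#'   \code{sp1..spN}.
#' @export
simulateYuleTree <- function(nSpecies, lambda = 1, seed) {
  stopifnot(nSpecies >= 2, lambda > 0)
  set.seed(seed)
  # splitting times measured forward from the root
  t <- 0
  splitTimes <- numeric(nSpecies - 1)
  for (k in 1:(nSpecies - 1)) {
    t <- t + rexp(1, k * lambda)
    splitTimes[k] <- t
  }
  depth <- t + rexp(1, nSpecies * lambda)  # run until the next (uncut) split
  # coalescent-style assembly backward from the present
  ages <- depth - splitTimes               # node ages, oldest first
  lineages <- seq_len(nSpecies)            # current lineage -> node id
  nTot <- 2 * nSpecies - 1
  edge <- matrix(0L, nTot - 1, 2); elen <- numeric(nTot - 1)
  heights <- numeric(nTot)                 # age of each node
  nodeId <- nSpecies
  ei <- 0
  for (j in rev(seq_along(ages))) {        # youngest split first
    pick <- sample(length(lineages), 2)
    nodeId <- nodeId + 1L
    for (ch in lineages[pick]) {
      ei <- ei + 1
      edge[ei, ] <- c(nodeId, ch)
      elen[ei] <- ages[j] - heights[ch]
    }
    heights[nodeId] <- ages[j]
    lineages <- c(lineages[-pick], nodeId)
  }
  tree <- assemblePhylo(edge, elen, paste0("sp", seq_len(nSpecies)),
                        nSpecies - 1L)
  renumberPhylo(tree)
}

# renumber internal nodes into ape convention (root = n+1, internal ids
# in preorder, edges listed cladewise)
renumberPhylo <- function(tree) {
  n <- length(tree$tip.label)
  edge <- tree$edge
  root <- setdiff(edge[, 1], edge[, 2])
  map <- integer(n + tree$Nnode)
  map[seq_len(n)] <- seq_len(n)
  childrenOf <- split(seq_len(nrow(edge)), edge[, 1])
  newEdge <- matrix(0L, nrow(edge), 2)
  newLen <- numeric(nrow(edge))
  nextId <- n
  ei <- 0
  visit <- function(v) {
    nextId <<- nextId + 1L
    map[v] <<- nextId
    for (e in childrenOf[[as.character(v)]]) {
      ch <- edge[e, 2]
      ei <<- ei + 1
      mine <- ei
      if (ch > n) {
        visit(ch)
      } else map[ch] <<- ch
      newEdge[mine, ] <<- c(map[v], map[ch])
      newLen[mine] <<- tree$edge.length[e]
    }
  }
  visit(root)
  assemblePhylo(newEdge, newLen, tree$tip.label, tree$Nnode)
}

#' Graft within-species coalescent genealogies onto a species tree
#'
#' For each species tip, a Kingman coalescent over its samples is
#' simulated (pairwise coalescence rate \eqn{n(n-1)/2} per unit of
#' \eqn{\theta}, so a pair coalesces at expected depth \eqn{\theta}) and
#' grafted at the species tip.  Genealogies must complete before the
#' species' terminal branch ends; otherwise theta is halved and the
#' genealogy redrawn (up to \code{maxRescale} times, with a warning).
#'
#' @param speciesTree ultrametric phylo over species tips.
#' @param samplesPerSpecies single count or per-species named/positional
#'   vector.
#' @param theta coalescent depth scale, single value or per-species.
#' @param seed RNG seed.
#' @param maxRescale rescaling attempts per species.
#' @return list with \code{tree} (ultrametric phylo over samples, tips
#'   \code{<species>_1} etc.) and \code{partition} (the true
#'   \linkS4class{SpeciesPartition}).
#' @export
simulateSpeciesCoalescents <- function(speciesTree, samplesPerSpecies,
                                       theta, seed, maxRescale = 10) {
  set.seed(seed)
  sp <- speciesTree$tip.label
  nSp <- length(sp)
  samplesPerSpecies <- rep_len(samplesPerSpecies, nSp)
  theta <- rep_len(theta, nSp)
  # available time on each terminal branch
  termLen <- speciesTree$edge.length[match(seq_len(nSp),
                                           speciesTree$edge[, 2])]
  tree <- speciesTree
  assign <- character(0)
  for (i in seq_len(nSp)) {
    m <- samplesPerSpecies[i]
    labels <- paste0(sp[i], "_", seq_len(m))
    assign[labels] <- sp[i]
    if (m == 1) {
      tree$tip.label[tree$tip.label == sp[i]] <- labels
      next
    }
    th <- theta[i]
    sub <- NULL
    for (attempt in seq_len(maxRescale)) {
      cand <- kingmanTree(m, th, labels)
      if (max(nodeAges(cand)) < termLen[i] * 0.999) { sub <- cand; break }
      th <- th / 2
    }
    if (is.null(sub))
      stop("coalescent for species ", sp[i],
           " does not complete before its origin even after rescaling")
    if (th < theta[i])
      warning("theta rescaled to ", th, " for species ", sp[i])
    # shorten the terminal branch so the grafted genealogy's tips land
    # exactly at the present
    tipIdx <- which(tree$tip.label == sp[i])
    eIdx <- which(tree$edge[, 2] == tipIdx)
    tree$edge.length[eIdx] <- termLen[i] - max(nodeAges(sub))
    tree <- ape::bind.tree(tree, sub, where = tipIdx)
  }
  tree <- renumberPhylo(tree)
  list(tree = tree, partition = speciesPartition(assign))
}

# Kingman coalescent genealogy over m samples; the subtree keeps its root
# edge of length 0 so bind.tree grafts it at the species tip
kingmanTree <- function(m, theta, labels) {
  ages <- numeric(m - 1)
  t <- 0
  for (j in m:2) {
    t <- t + rexp(1, j * (j - 1) / 2 / theta)
    ages[m - j + 1] <- t
  }
  lineages <- seq_len(m)
  nTot <- 2 * m - 1
  edge <- matrix(0L, nTot - 1, 2); elen <- numeric(nTot - 1)
  heights <- numeric(nTot)
  nodeId <- m; ei <- 0
  for (a in ages) {
    pick <- sample(length(lineages), 2)
    nodeId <- nodeId + 1L
    for (ch in lineages[pick]) {
      ei <- ei + 1
      edge[ei, ] <- c(nodeId, ch)
      elen[ei] <- a - heights[ch]
    }
    heights[nodeId] <- a
    lineages <- c(lineages[-pick], nodeId)
  }
  tr <- assemblePhylo(edge, elen, labels, m - 1L)
  tr <- renumberPhylo(tr)
  tr$root.edge <- 0
  tr
}

#' Evolve an alignment along a tree
#'
#' Forward simulation under the implemented likelihood conventions: root
#' states are drawn from the stationary frequencies; each site is
#' invariable with probability \code{pInv}, otherwise it is assigned a
#' discrete-gamma category whose rate is rescaled by 1/(1 - pInv) (the
#' same discretisation the likelihood engine uses); states evolve along
#' each branch with \eqn{P(t \rho_c)}.  Branch lengths are expected
#' substitutions per site.
#'
#' @param tree phylo with branch lengths.
#' @param model a SubstitutionModel.
#' @param nSites number of sites.
#' @param seed RNG seed.
#' @return A \linkS4class{BarcodeAlignment}.
#' @export
simulateAlignment <- function(tree, model, nSites, seed) {
  set.seed(seed)
  n <- length(tree$tip.label)
  nNode <- n + tree$Nnode
  ed <- modelEigen(model)
  rates <- gammaCategoryRates(model@alpha, model@nCat, model@pInv)
  siteCat <- ifelse(runif(nSites) < model@pInv, 0L,
                    sample.int(length(rates), nSites, replace = TRUE))
  states <- matrix(0L, nNode, nSites)
  tr <- ape::reorder.phylo(tree, "cladewise")
  root <- tr$edge[1, 1]
  states[root, ] <- sample.int(4, nSites, replace = TRUE,
                               prob = as.numeric(model@pi))
  cats <- sort(unique(siteCat[siteCat > 0]))
  for (e in seq_len(nrow(tr$edge))) {
    pa <- tr$edge[e, 1]; ch <- tr$edge[e, 2]; t <- tr$edge.length[e]
    states[ch, ] <- states[pa, ]
    for (cc in cats) {
      idx <- which(siteCat == cc)
      if (!length(idx)) next
      P <- pFromEigen(ed, t * rates[cc])
      P[P < 0] <- 0
      for (b in 1:4) {
        ib <- idx[states[pa, idx] == b]
        if (length(ib))
          states[ch, ib] <- sample.int(4, length(ib), replace = TRUE,
                                       prob = P[b, ])
      }
    }
  }
  m <- matrix(DNA_BASES[states[seq_len(n), , drop = FALSE]], nrow = n)
  rownames(m) <- tree$tip.label
  barcodeAlignment(m)
}

#' Simulate a full multi-species data set
#'
#' Convenience wrapper: Yule species tree, within-species coalescents,
#' and sequence evolution, returning every piece of the stated world
#' (tree, true partition, alignment, and the specification used).
#'
#' @param nSpecies number of species.
#' @param lambda Yule speciation rate.
#' @param samplesPerSpecies samples per species (scalar or vector).
#' @param separation ratio of the youngest species divergence to the mean
#'   pairwise coalescent depth; the coalescent scale is derived as
#'   \code{theta = youngest species split / separation}, so that every
#'   interspecific divergence is at least \code{separation} times older
#'   than the expected intraspecific pairwise coalescence.
#' @param model SubstitutionModel for sequence evolution (NULL = no
#'   sequences).
#' @param nSites sites to simulate.
#' @param seed RNG seed.
#' @return list with \code{tree}, \code{partition}, \code{alignment}
#'   (or NULL) and \code{spec}.
#' @export
simulateDataset <- function(nSpecies = 5, lambda = 1,
                            samplesPerSpecies = 5, separation = 100,
                            model = NULL, nSites = 1000, seed = 1) {
  spTree <- simulateYuleTree(nSpecies, lambda, seed = seed)
  agesInt <- nodeAges(spTree)[(nSpecies + 1):(2 * nSpecies - 1)]
  theta <- min(agesInt) / separation
  sim <- simulateSpeciesCoalescents(spTree, samplesPerSpecies, theta,
                                    seed = seed + 1)
  aln <- if (!is.null(model))
    simulateAlignment(sim$tree, model, nSites, seed = seed + 2)
  list(tree = sim$tree, partition = sim$partition, alignment = aln,
       spec = list(nSpecies = nSpecies, lambda = lambda,
                   samplesPerSpecies = samplesPerSpecies,
                   separation = separation, theta = theta,
                   nSites = nSites, seed = seed))
}

#' Simulate a single-population Kingman coalescent genealogy
#'
#' Backward construction: with j lineages the waiting time to the next
#' coalescence is Exponential(j(j-1) / (2 theta)), so a sample pair
#' coalesces at expected depth theta.
#'
#' @param nSamples number of tips.
#' @param theta coalescent depth scale.
#' @param seed RNG seed.
#' @return rooted binary ultrametric phylo with tips \code{t1..tN}.
#' @export
simulateCoalescentTree <- function(nSamples, theta = 1, seed) {
  stopifnot(nSamples >= 2, theta > 0)
  set.seed(seed)
  tr <- kingmanTree(nSamples, theta, paste0("t", seq_len(nSamples)))
  tr$root.edge <- NULL
  tr
}

# deterministic species-size profile of the 64-taxon surrogate set:
# sums to 64 taxa and 114 intraspecific pairs, and contains the
# structures the modification experiment needs (a 5-member species, a
# 3-member species to be recoded 2+1, and two designated singletons to
# be duplicated four times each)
DUPLICATION_PROFILE <- c(10, 8, 6, 5, 4, 3, 3, 2, 2, 2, 2, rep(1, 17))

#' Surrogate data set for the taxon-sampling duplication experiment
#'
#' Builds a 64-taxon data set whose species-size profile yields exactly
#' 114 intraspecific pairwise distances, with two designated singletons
#' and one 3-member species.  Applying \code{\link{duplicateAndRecode}}
#' with the returned \code{modification} recipe (duplicate both
#' singletons four times, recode the 3-member species as two species of
#' sizes 2 and 1) yields 72 taxa, 2556 distances, 132 intraspecific and
#' 2424 interspecific ones.
#'
#' @param seed RNG seed.
#' @param nSites alignment length.
#' @param withSequences simulate sequences (TRUE) or return only the
#'   tree-based pieces.
#' @return list with \code{alignment} (or NULL), \code{tree},
#'   \code{partition} and \code{modification} (list with
#'   \code{duplications} and \code{recodings} ready for
#'   \code{duplicateAndRecode}).
#' @export
makeDuplicationFixture <- function(seed = 1, nSites = 600,
                                   withSequences = TRUE) {
  profile <- DUPLICATION_PROFILE
  nSp <- length(profile)
  spTree <- simulateYuleTree(nSp, lambda = 1, seed = seed)
  agesInt <- nodeAges(spTree)[(nSp + 1):(2 * nSp - 1)]
  theta <- min(agesInt) / 100
  sim <- simulateSpeciesCoalescents(spTree, profile, theta,
                                    seed = seed + 1)
  # rescale to a barcode-realistic depth (deepest divergence ~0.3
  # substitutions per site) so corrected distances stay estimable
  sim$tree$edge.length <- sim$tree$edge.length * 0.3 /
    max(nodeAges(sim$tree))
  aln <- if (withSequences) {
    model <- substitutionModel("GTR",
                               pi = c(0.27, 0.22, 0.26, 0.25),
                               rates = c(1.2, 3.5, 0.8, 1.1, 4.2, 1),
                               alpha = 0.7)
    simulateAlignment(sim$tree, model, nSites, seed = seed + 2)
  }
  sizes <- speciesSizes(sim$partition)
  singles <- names(sizes)[sizes == 1][1:2]
  three <- names(sizes)[sizes == 3][1]
  singleTaxa <- names(sim$partition@assignments)[
    sim$partition@assignments %in% singles]
  threeTaxa <- names(sim$partition@assignments)[
    sim$partition@assignments == three]
  modification <- list(
    duplications = setNames(c(4L, 4L), singleTaxa),
    recodings = setNames(c(paste0(three, "a"), paste0(three, "a"),
                           paste0(three, "b")), threeTaxa))
  list(alignment = aln, tree = sim$tree, partition = sim$partition,
       modification = modification)
}
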