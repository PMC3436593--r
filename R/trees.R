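#' Read / write Newick trees
#'
#' Thin wrappers around the ape parser with the validation the downstream
#' stages need: unique tip labels and finite non-negative branch lengths.
#' Internal node labels are preserved as annotations (support values).
#'
#' @param path file path (or, for \code{readNewick}, a literal Newick
#'   string containing a semicolon).
#' @param requireLengths error when branch lengths are absent.
#' @return \code{readNewick}: an ape \code{phylo}.
#' @rdname newickIO
#' @export
readNewick <- function(path, requireLengths = TRUE) {
  tree <- if (grepl(";", path)) ape::read.tree(text = path)
    else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (requireLengths) {
    if (is.null(tree$edge.length)) stop("branch lengths are required")
    if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
      stop("branch lengths must be finite and non-negative")
  }
  tree
}

#' @param tree a phylo.
#' @rdname newickIO
#' @export
writeNewick <- function(tree, path = NULL) {
  if (is.null(path)) ape::write.tree(tree)
  else { ape::write.tree(tree, file = path); invisible(path) }
}

#' Node ages of a rooted tree
#'
#' Age (height above the present) of every node; tips of an ultrametric
#' tree have age ~0.  Indexing follows ape: 1..n are tips, n+1.. the
#' internal nodes.
#'
#' @param tree rooted phylo with branch lengths.
#' @return numeric vector of node ages.
#' @export
nodeAges <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  max(depth) - depth
}

#' Is a rooted tree ultrametric?
#'
#' All root-to-tip path lengths must agree within
#' \code{tol * root height}.
#'
#' @param tree rooted phylo.
#' @param tol relative tolerance.
#' @export
isUltrametric <- function(tree, tol = 1e-6) {
  ages <- nodeAges(tree)
  n <- length(tree$tip.label)
  h <- max(ages)
  if (h == 0) return(TRUE)
  all(abs(ages[seq_len(n)]) <= tol * h)
}

assertUltrametric <- function(tree, tol = 1e-6) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree must be strictly bifurcating; resolve polytomies first")
  if (!isUltrametric(tree, tol))
    stop("tree is not ultrametric (root-to-tip path lengths differ)")
  invisible(tree)
}

#' Neighbor joining from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via ape), with negative branch
#' lengths clamped to zero; the clamped deficit is recorded in the
#' \code{clamped} attribute.  Saturated (NA) entries are an error: use a
#' model under which all pairs are estimable.
#'
#' @param dm a \linkS4class{PairwiseDistances} (or plain symmetric matrix).
#' @return unrooted phylo.
#' @export
neighborJoining <- function(dm) {
  v <- if (is(dm, "PairwiseDistances")) dm@values else as.matrix(dm)
  if (any(is.na(v)))
    stop("distance matrix contains saturated/undefined entries; ",
         "re-estimate under a different model")
  if (nrow(v) < 3) stop("need at least 3 taxa")
  tree <- ape::nj(as.dist(v))
  deficit <- -sum(tree$edge.length[tree$edge.length < 0])
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- deficit
  tree
}

#' Lineage-through-time curve of an ultrametric tree
#'
#' One step per internal node, ordered from the root (2 lineages) to the
#' present (n lineages).  Times are reported as negative relative times
#' before the present (0 = present), matching the axis convention of
#' LTT plots in barcoding studies.
#'
#' @param tree rooted binary ultrametric phylo.
#' @return data.frame with columns \code{time} and \code{lineages}.
#' @export
lttCurve <- function(tree) {
  assertUltrametric(tree)
  n <- length(tree$tip.label)
  ages <- nodeAges(tree)[(n + 1):(n + tree$Nnode)]
  ages <- sort(ages, decreasing = TRUE)
  data.frame(time = c(-ages, 0),
             lineages = c(2:(length(ages) + 1), n))
}

#' @describeIn lttCurve write the curve as 2-column TSV.
#' @param curve data.frame from \code{lttCurve}.
#' @param path output path.
#' @export
writeLtt <- function(curve, path) {
  write.table(curve, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining bootstrap support
#'
#' Resamples the included alignment columns with replacement, rebuilds the
#' NJ tree under the chosen distance method for each replicate, and scores
#' every bipartition of the original NJ tree by the percentage of
#' replicates containing it.  Replicates in which some distance is
#' undefined (saturated) are dropped and counted.
#'
#' @param aln a BarcodeAlignment.
#' @param method distance method, as in \code{\link{distanceMatrix}}.
#' @param model model for \code{method = "ml"} (parameters held fixed
#'   across replicates).
#' @param nReplicates bootstrap replicates (>= 1).
#' @param seed RNG seed (recorded in the result).
#' @return the original NJ tree with \code{node.label} support percentages
#'   and attributes \code{support}, \code{dropped}, \code{seed}.
#' @export
njBootstrap <- function(aln, method = "k2p_closed", model = NULL,
                        nReplicates = 100, seed = 1) {
  stopifnot(nReplicates >= 1)
  set.seed(seed)
  dmObs <- distanceMatrix(aln, method = method, model = model)
  obs <- neighborJoining(dmObs)
  keep <- which(aln@mask)
  boots <- vector("list", nReplicates)
  dropped <- 0L
  for (r in seq_len(nReplicates)) {
    cols <- sample(keep, length(keep), replace = TRUE)
    repAln <- new("BarcodeAlignment",
                  seqs = aln@seqs[, cols, drop = FALSE],
                  mask = rep(TRUE, length(cols)))
    tr <- tryCatch(neighborJoining(
      distanceMatrix(repAln, method = method, model = model)),
      error = function(e) NULL)
    if (is.null(tr)) dropped <- dropped + 1L else boots[[r]] <- tr
  }
  boots <- boots[!vapply(boots, is.null, TRUE)]
  if (!length(boots)) stop("all bootstrap replicates failed")
  counts <- ape::prop.clades(obs, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  support <- 100 * counts / length(boots)
  obs$node.label <- round(support, 1)
  attr(obs, "support") <- support
  attr(obs, "dropped") <- dropped
  attr(obs, "seed") <- seed
  obs
}
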