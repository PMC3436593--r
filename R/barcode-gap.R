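#' Bin distances into half-open frequency classes
#'
#' Value v falls into class \code{floor(v / width) + 1}, i.e. class k
#' covers \eqn{[w(k-1), wk[} with closed lower and open upper limit; exact
#' multiples of the width go to the upper class, v = 0 to class 1.  No
#' means or standard deviations are computed for the distributions.
#'
#' @param values non-negative finite distances (intra/inter labels may be
#'   attached via \code{intraFlags}).
#' @param classWidth class width (default 0.005).
#' @param intraFlags optional logical vector parallel to \code{values}
#'   marking intraspecific distances, producing the intra/inter split.
#' @return A \linkS4class{FrequencyDistribution}.
#' @export
binDistances <- function(values, classWidth = 0.005, intraFlags = NULL) {
  if (length(values)) {
    bad <- which(!is.finite(values) | values < 0)
    if (length(bad))
      stop("negative or non-finite distance at index ", bad[1])
  }
  if (classWidth <= 0) stop("classWidth must be positive")
  idx <- floor(values / classWidth) + 1L
  K <- if (length(idx)) max(idx) else 0L
  counts <- tabulate(idx, nbins = K)
  if (!is.null(intraFlags)) {
    stopifnot(length(intraFlags) == length(values))
    intra <- tabulate(idx[intraFlags], nbins = K)
    inter <- tabulate(idx[!intraFlags], nbins = K)
  } else {
    intra <- integer(0); inter <- integer(0)
  }
  new("FrequencyDistribution", classWidth = classWidth,
      counts = as.integer(counts), intra = as.integer(intra),
      inter = as.integer(inter), nTotal = length(values))
}

setMethod("show", "FrequencyDistribution", function(object) {
  cat("FrequencyDistribution:", object@nTotal, "distances in",
      length(object@counts), "classes of width", object@classWidth, "\n")
})

#' @describeIn binDistances table of class bounds and counts, written as
#'   TSV when \code{path} is given.
#' @param fd a FrequencyDistribution.
#' @param path optional output path.
#' @export
frequencyTable <- function(fd, path = NULL) {
  K <- length(fd@counts)
  tab <- data.frame(class = seq_len(K),
                    lower = fd@classWidth * (seq_len(K) - 1),
                    upper = fd@classWidth * seq_len(K),
                    count = fd@counts)
  if (length(fd@intra)) { tab$intra <- fd@intra; tab$inter <- fd@inter }
  if (!is.null(path)) {
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Split pairwise distances into intra- and interspecific sets
#'
#' A pair is intraspecific iff both taxa carry the same species
#' identifier.  The count identity
#' \eqn{|intra| = \sum_s \binom{size_s}{2}} and
#' \eqn{|intra| + |inter| = \binom{n}{2}} hold by construction.
#'
#' @param dm a PairwiseDistances whose taxa are all assigned in
#'   \code{part}.
#' @param part a SpeciesPartition.
#' @return list with numeric vectors \code{intra} and \code{inter}.
#' @export
partitionDistances <- function(dm, part) {
  labels <- rownames(dm@values)
  sp <- speciesOf(part, labels)
  un <- labels[is.na(sp)]
  if (length(un))
    stop("unassigned taxa: ", paste(un, collapse = ", "))
  n <- length(labels)
  same <- outer(sp, sp, "==")
  lt <- lower.tri(dm@values)
  list(intra = dm@values[lt & same], inter = dm@values[lt & !same])
}

#' Locate candidate barcode gaps in a frequency distribution
#'
#' Reports the interior empty classes (count 0 strictly between nonempty
#' classes) and the interior local minima with their flanking counts.
#' Leading or trailing zero classes are never reported, and nothing is
#' extrapolated beyond the occupied range.  Whether any reported gap
#' deserves the name "barcode gap" (clear and stable slopes on both
#' flanks) is left to the investigator.
#'
#' @param fd a FrequencyDistribution with at least two nonempty classes.
#' @return list with \code{emptyClasses} (integer vector), \code{minima}
#'   (data.frame class/count/left/right) and \code{notes}.
#' @export
findGaps <- function(fd) {
  counts <- fd@counts
  occ <- which(counts > 0)
  if (length(occ) < 2) stop("need at least two nonempty classes")
  lo <- min(occ); hi <- max(occ)
  interior <- seq(lo + 1, length.out = max(0, hi - lo - 1))
  emptyClasses <- interior[counts[interior] == 0]
  minima <- list()
  for (k in interior) {
    if (counts[k] == 0) next
    left <- counts[max(lo, k - 1)]; right <- counts[min(hi, k + 1)]
    if (counts[k] < left && counts[k] <= right)
      minima[[length(minima) + 1]] <-
        data.frame(class = k, count = counts[k], left = left, right = right)
  }
  minima <- if (length(minima)) do.call(rbind, minima) else
    data.frame(class = integer(0), count = integer(0),
               left = integer(0), right = integer(0))
  notes <- if (length(emptyClasses))
    paste0("empty interior class(es): ",
           paste(emptyClasses, collapse = ", "))
  else "no empty interior classes"
  list(emptyClasses = as.integer(emptyClasses), minima = minima,
       notes = notes)
}

dupLabels <- function(taxon, count) paste0(taxon, "__dup", seq_len(count))

#' Duplicate taxa and recode species membership
#'
#' The taxon-sampling modification experiment: designated sequences are
#' duplicated (copies named \code{taxon__dup1}, ...), so every distance
#' involving a copy equals that of its source, and designated taxa are
#' recoded to new species identifiers.  Works on a
#' \linkS4class{BarcodeAlignment} or directly on a
#' \linkS4class{PairwiseDistances}.
#'
#' @param x a BarcodeAlignment or PairwiseDistances.
#' @param part a SpeciesPartition assigning every duplicated taxon.
#' @param duplications named integer vector: taxon -> number of copies to
#'   add.
#' @param recodings named character vector: taxon -> new species
#'   identifier.
#' @return list with the modified \code{data} (same class as \code{x}),
#'   the updated \code{partition} and a \code{summary} of
#'   intra/inter/total pair counts before and after.
#' @export
duplicateAndRecode <- function(x, part, duplications = integer(0),
                               recodings = character(0)) {
  labels <- if (is(x, "BarcodeAlignment")) taxa(x) else rownames(x@values)
  for (tx in names(duplications)) {
    if (!tx %in% labels) stop("unknown taxon: ", tx)
    if (is.na(speciesOf(part, tx)))
      stop("cannot duplicate unassigned taxon: ", tx)
  }
  for (tx in names(recodings)) if (!tx %in% labels)
    stop("unknown taxon: ", tx)

  assign <- part@assignments
  pairCounts <- function(a) {
    sz <- table(a)
    intra <- sum(choose(sz, 2))
    n <- length(a)
    c(total = choose(n, 2), intra = intra, inter = choose(n, 2) - intra)
  }
  before <- pairCounts(assign[labels[labels %in% names(assign)]])

  newRows <- character(0)
  for (tx in names(duplications)) {
    copies <- dupLabels(tx, duplications[[tx]])
    newRows <- c(newRows, setNames(rep(tx, length(copies)), copies))
    assign[copies] <- assign[[tx]]
  }
  assign[names(recodings)] <- recodings
  # copies of a recoded taxon follow it into the new species
  for (cp in names(newRows)) assign[cp] <- assign[[newRows[[cp]]]]

  if (is(x, "BarcodeAlignment")) {
    seqs <- rbind(x@seqs, x@seqs[newRows, , drop = FALSE])
    rownames(seqs) <- c(rownames(x@seqs), names(newRows))
    data <- new("BarcodeAlignment", seqs = seqs, mask = x@mask)
    allLabels <- rownames(seqs)
  } else {
    src <- c(rownames(x@values), unname(newRows))
    allLabels <- c(rownames(x@values), names(newRows))
    v <- x@values[src, src]
    s <- x@saturated[src, src]
    dimnames(v) <- dimnames(s) <- list(allLabels, allLabels)
    diag(v) <- 0
    data <- new("PairwiseDistances", values = v, saturated = s,
                modelTag = x@modelTag, units = x@units)
  }
  newPart <- speciesPartition(assign)
  after <- pairCounts(assign[allLabels[allLabels %in% names(assign)]])
  list(data = data, partition = newPart,
       summary = data.frame(stage = c("before", "after"),
                            n = c(length(labels), length(allLabels)),
                            total = c(before["total"], after["total"]),
                            intra = c(before["intra"], after["intra"]),
                            inter = c(before["inter"], after["inter"]),
                            row.names = NULL))
}
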