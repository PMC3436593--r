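#' @import methods
#' @importFrom stats optimize nlminb pchisq qgamma pgamma rexp runif sd
#'   setNames var median quantile pt rbinom as.dist
#' @importFrom utils combn read.table write.table packageVersion head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N", "-", "?")
DNA_BASES <- c("A", "C", "G", "T")

#' Masked nucleotide alignment
#'
#' Equal-length nucleotide rows keyed by unique taxon labels, together with a
#' logical column-inclusion mask.  Columns flagged \code{FALSE} (e.g.
#' non-alignable regions pruned before distance or saturation analyses) are
#' ignored by every downstream computation.  Allowed residues are
#' \code{A,C,G,T,N,-,?}; \code{U} is normalised to \code{T} on input and
#' \code{-}/\code{?} are both treated as gap/missing.
#'
#' @slot seqs character matrix, one row per taxon (rownames are the taxon
#'   labels), one column per alignment position.
#' @slot mask logical vector, one flag per column; \code{TRUE} = included.
#' @export
setClass("BarcodeAlignment",
  representation(seqs = "matrix", mask = "logical"))

setValidity("BarcodeAlignment", function(object) {
  m <- object@seqs
  if (!is.character(m)) return("seqs must be a character matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    return("taxon labels must be present and unique")
  if (any(!nzchar(rownames(m)))) return("empty taxon label")
  if (length(object@mask) != ncol(m))
    return("mask length must equal the number of columns")
  bad <- setdiff(unique(as.vector(m)), DNA_ALPHABET)
  if (length(bad))
    return(paste0("disallowed residue(s): ", paste(bad, collapse = ", ")))
  TRUE
})

#' Species partition
#'
#' A mapping from taxon label to species identifier.  Taxa absent from the
#' mapping are simply unassigned (this is reported, not an error).
#'
#' @slot assignments named character vector: names are taxon labels, values
#'   species identifiers.
#' @export
setClass("SpeciesPartition", representation(assignments = "character"))

setValidity("SpeciesPartition", function(object) {
  a <- object@assignments
  if (length(a) && (is.null(names(a)) || anyDuplicated(names(a))))
    return("taxon labels must be unique")
  if (any(!nzchar(a))) return("empty species identifier")
  TRUE
})

#' Nucleotide substitution model
#'
#' A reversible substitution model from the family
#' \{JC69, K80, F81, HKY85, TIM2, GTR\}, optionally extended with a
#' proportion of invariable sites (+I) and discrete-gamma among-site rate
#' variation (+G).  The instantaneous rate matrix built from the
#' exchangeabilities and base frequencies is normalised so that one unit of
#' branch length equals one expected substitution per site (averaged over
#' all sites; variable-site category rates are rescaled by 1/(1 - pInv)).
#'
#' @slot family model family name.
#' @slot pi base frequencies (A, C, G, T), each > 0, summing to 1.
#' @slot rates six exchangeabilities in the order
#'   \code{rAC, rAG, rAT, rCG, rCT, rGT}, subject to the family constraints.
#' @slot pInv proportion of invariable sites in [0, 1).
#' @slot alpha gamma shape parameter (> 0); \code{NA} means no rate
#'   variation.
#' @slot nCat number of discrete gamma categories (default 4).
#' @export
setClass("SubstitutionModel",
  representation(family = "character", pi = "numeric", rates = "numeric",
                 pInv = "numeric", alpha = "numeric", nCat = "integer"))

MODEL_FAMILIES <- c("JC69", "K80", "F81", "HKY85", "TIM2", "GTR")
RATE_NAMES <- c("rAC", "rAG", "rAT", "rCG", "rCT", "rGT")

setValidity("SubstitutionModel", function(object) {
  if (!object@family %in% MODEL_FAMILIES)
    return(paste("unknown family:", object@family))
  if (length(object@pi) != 4 || any(object@pi <= 0) ||
      abs(sum(object@pi) - 1) > 1e-8)
    return("pi must be 4 positive frequencies summing to 1")
  if (length(object@rates) != 6 || any(object@rates < 0))
    return("rates must be 6 non-negative exchangeabilities")
  r <- object@rates
  ok <- switch(object@family,
    JC69 = all(abs(r - r[1]) < 1e-9) && all(abs(object@pi - 0.25) < 1e-9),
    K80 = abs(r[2] - r[5]) < 1e-9 && max(abs(r[c(1, 3, 4, 6)] - r[1])) < 1e-9 &&
      all(abs(object@pi - 0.25) < 1e-9),
    F81 = all(abs(r - r[1]) < 1e-9),
    HKY85 = abs(r[2] - r[5]) < 1e-9 && max(abs(r[c(1, 3, 4, 6)] - r[1])) < 1e-9,
    TIM2 = abs(r[1] - r[3]) < 1e-9 && abs(r[4] - r[6]) < 1e-9,
    GTR = TRUE)
  if (!ok) return(paste("rates violate the", object@family, "constraints"))
  if (length(object@pInv) != 1 || object@pInv < 0 || object@pInv >= 1)
    return("pInv must lie in [0, 1)")
  if (length(object@alpha) != 1 || (!is.na(object@alpha) && object@alpha <= 0))
    return("alpha must be positive or NA")
  if (object@nCat < 1) return("nCat must be >= 1")
  TRUE
})

#' Pairwise distance matrix
#'
#' Symmetric pairwise distances with zero diagonal, tagged with the model
#' and units used.  Saturated pairs (closed-form correction undefined, or
#' the ML optimum hitting the upper search bound) carry \code{NA} in
#' \code{values} and \code{TRUE} in \code{saturated}.
#'
#' @slot values symmetric numeric matrix with taxon dimnames.
#' @slot saturated logical matrix parallel to \code{values}.
#' @slot modelTag description of the distance model.
#' @slot units either \code{"proportion"} or
#'   \code{"expected substitutions per site"}.
#' @export
setClass("PairwiseDistances",
  representation(values = "matrix", saturated = "matrix",
                 modelTag = "character", units = "character"))

setValidity("PairwiseDistances", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("values must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    return("values needs matching taxon dimnames")
  if (!isTRUE(all.equal(v, t(v), tolerance = 1e-8, check.attributes = FALSE)))
    return("values must be symmetric")
  if (any(abs(diag(v)) > 1e-12)) return("diagonal must be zero")
  if (any(v[!is.na(v)] < 0)) return("distances must be non-negative")
  if (any(is.na(v) & !object@saturated))
    return("NA distances must be flagged saturated")
  TRUE
})

#' Frequency distribution of genetic distances
#'
#' Counts of pairwise distances in half-open classes
#' \eqn{[w(k-1), wk[} of width \eqn{w} (closed lower, open upper limit;
#' class indices are 1-based).  When a species partition is supplied the
#' counts are split into parallel intra- and interspecific vectors.
#'
#' @slot classWidth positive class width.
#' @slot counts integer vector, element k = count of class k.
#' @slot intra,inter optional parallel split (lengths 0 or equal to counts).
#' @slot nTotal number of distances binned.
#' @export
setClass("FrequencyDistribution",
  representation(classWidth = "numeric", counts = "integer",
                 intra = "integer", inter = "integer", nTotal = "integer"))

setValidity("FrequencyDistribution", function(object) {
  if (object@classWidth <= 0) return("classWidth must be positive")
  if (sum(object@counts) != object@nTotal)
    return("counts must sum to nTotal")
  if (length(object@intra) &&
      (length(object@intra) != length(object@counts) ||
       length(object@inter) != length(object@counts)))
    return("intra/inter must parallel counts")
  if (length(object@intra) &&
      any(object@intra + object@inter != object@counts))
    return("intra + inter must equal counts")
  TRUE
})

#' Substitution-saturation test result
#'
#' Xia's entropy-based index of substitution saturation with critical
#' values for symmetric and asymmetric topologies and the four-way verdict.
#'
#' @slot iss observed index.
#' @slot seIss standard error from the sitewise entropies.
#' @slot issCSym,issCAsym critical values.
#' @slot pSym,pAsym two-sided t-test p-values.
#' @slot nOtuUsed taxa per evaluation (at most 32).
#' @slot nResamples resampling rounds (1 when no resampling was needed).
#' @slot nSites usable (ungapped, post invariant-removal) sites.
#' @slot verdict one of \code{"low saturation"},
#'   \code{"substantial saturation"}, \code{"poor"}, \code{"useless"},
#'   \code{"no signal"}.
#' @export
setClass("SaturationResult",
  representation(iss = "numeric", seIss = "numeric", issCSym = "numeric",
                 issCAsym = "numeric", pSym = "numeric", pAsym = "numeric",
                 nOtuUsed = "integer", nResamples = "integer",
                 nSites = "integer", verdict = "character"))

#' Waiting-time schedule of a mixed Yule-coalescent model
#'
#' Inter-event waiting times of an ultrametric tree, ordered from the root
#' toward the present, with the per-interval lineage counts of the
#' diversification (Yule) class and the pooled coalescent pair count
#' \eqn{\sum_j n_j (n_j - 1)}.  The final interval runs from the youngest
#' branching event to the present and ends without an event (it enters the
#' likelihood only through its survival term).
#'
#' @slot times interval lengths x_i; their sum is the root height.
#' @slot lineages total lineage count during each interval.
#' @slot k diversification-class lineage count per interval.
#' @slot coalCounts matrix of within-species lineage counts n_{i,j}, one
#'   row per species, one column per interval (0 while the species'
#'   lineage is in the diversification class).
#' @slot coalPairs pooled coalescent pair count
#'   \eqn{\sum_j n_{i,j}(n_{i,j}-1)} per interval.
#' @slot event logical, TRUE when the interval ends in a branching event.
#' @slot speciesRoots node numbers delimiting the coalescent subtrees.
#' @export
setClass("WaitingTimeSchedule",
  representation(times = "numeric", lineages = "integer", k = "integer",
                 coalCounts = "matrix", coalPairs = "numeric",
                 event = "logical", speciesRoots = "integer"))

setValidity("WaitingTimeSchedule", function(object) {
  n <- length(object@times)
  if (length(object@lineages) != n || length(object@k) != n ||
      length(object@coalPairs) != n || length(object@event) != n)
    return("slot lengths differ")
  if (any(object@times < 0)) return("negative waiting time")
  if (any(object@k > object@lineages))
    return("class counts exceed total lineages")
  TRUE
})

#' Fitted GMYC model
#'
#' Result of fitting the general mixed Yule-coalescent model to an
#' ultrametric tree: thresholds (as negative relative times before the
#' present), rate/scaling parameters for the diversification and coalescent
#' classes, log-likelihoods, the likelihood-ratio test against the
#' coalescent-only null, and the delimited clusters, singletons and
#' entities with a 2-log-likelihood-unit confidence range on the cluster
#' count.
#'
#' @slot mode \code{"null"}, \code{"single"} or \code{"multiple"}.
#' @slot thresholds switch times, reported negative (before present).
#' @slot parameters named vector: lambdaDiv, pDiv, lambdaCoal, pCoal (the
#'   null fit stores lambda and p).
#' @slot logLik model log-likelihood.
#' @slot nullLogLik coalescent-only log-likelihood.
#' @slot LR,df,pValue likelihood-ratio test against the null.
#' @slot clusters list of tip-label vectors (size >= 2 each).
#' @slot singletons tip labels outside any cluster.
#' @slot confidence min/max cluster count within 2 logL units.
#' @slot candidates data.frame of evaluated thresholds (single mode).
#' @slot tree the input tree.
#' @export
setClass("GmycFit",
  representation(mode = "character", thresholds = "numeric",
                 parameters = "numeric", logLik = "numeric",
                 nullLogLik = "numeric", LR = "numeric", df = "numeric",
                 pValue = "numeric", clusters = "list",
                 singletons = "character", confidence = "numeric",
                 candidates = "data.frame", tree = "ANY"))
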