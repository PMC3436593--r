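# integer encoding A,C,G,T -> 1..4; gap/missing/N -> NA
encodeRow <- function(x) {
  match(x, DNA_BASES)
}

# 4x4 pair-pattern counts over columns where both rows carry a plain base
pairPatternCounts <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  counts <- matrix(0, 4, 4)
  if (any(ok)) {
    tab <- tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L)
    counts <- matrix(tab, 4, 4, byrow = TRUE)
  }
  counts
}

#' Uncorrected proportional distance between two aligned rows
#'
#' Two definitions are offered.  \code{"paper_total_length"} counts
#' mismatches plus sites where exactly one row is gapped/missing and divides
#' by the total (masked) alignment length, the convention used when
#' divergences including gaps are expressed against full alignment length.
#' \code{"pairwise_deletion"} drops every column where either row carries a
#' gap, \code{?} or N and divides mismatches by the remaining length (the
#' behaviour of common distance software).
#'
#' @param a,b character vectors of equal length (rows of a masked
#'   alignment), or a two-row character matrix in \code{a}.
#' @param mode counting convention, see above.
#' @return proportion in [0, 1].
#' @export
pDistance <- function(a, b = NULL,
                      mode = c("pairwise_deletion", "paper_total_length")) {
  mode <- match.arg(mode)
  if (is.null(b)) { b <- a[2, ]; a <- a[1, ] }
  if (length(a) != length(b)) stop("rows differ in length")
  ia <- encodeRow(a); ib <- encodeRow(b)
  if (mode == "paper_total_length") {
    both <- !is.na(ia) & !is.na(ib)
    one <- xor(is.na(ia), is.na(ib))
    (sum(ia[both] != ib[both]) + sum(one)) / length(a)
  } else {
    both <- !is.na(ia) & !is.na(ib)
    if (!any(both)) stop("no usable columns under pairwise deletion")
    sum(ia[both] != ib[both]) / sum(both)
  }
}

#' Kimura two-parameter (K80) distance, closed form
#'
#' \eqn{d = -\frac12 \ln(1 - 2P - Q) - \frac14 \ln(1 - 2Q)} with P and Q
#' the transition and transversion proportions over pairwise-deleted
#' columns.  When an argument of a logarithm is not positive the distance
#' is undefined (substitution saturation); \code{NA} is returned with
#' attribute \code{saturated = TRUE}.
#'
#' @param a,b character vectors (rows of a masked alignment).
#' @return distance in expected substitutions per site, with a logical
#'   \code{saturated} attribute.
#' @export
k2pDistance <- function(a, b) {
  ia <- encodeRow(a); ib <- encodeRow(b)
  cnt <- pairPatternCounts(ia, ib)
  n <- sum(cnt)
  if (n == 0) stop("no usable columns under pairwise deletion")
  # transitions: A<->G (1,3), C<->T (2,4)
  P <- (cnt[1, 3] + cnt[3, 1] + cnt[2, 4] + cnt[4, 2]) / n
  Q <- (sum(cnt) - sum(diag(cnt))) / n - P
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(structure(NA_real_, saturated = TRUE))
  structure(max(0, -0.5 * log(w1) - 0.25 * log(w2)), saturated = FALSE)
}

#' Jukes-Cantor distance, closed form
#'
#' \eqn{d = -\frac34 \ln(1 - \frac43 p)} with p the pairwise-deletion
#' proportion of differences.
#'
#' @param a,b character vectors (rows of a masked alignment).
#' @return distance with a \code{saturated} attribute.
#' @export
jc69Distance <- function(a, b) {
  p <- pDistance(a, b, mode = "pairwise_deletion")
  w <- 1 - 4 * p / 3
  if (w <= 0) return(structure(NA_real_, saturated = TRUE))
  structure(max(0, -0.75 * log(w)), saturated = FALSE)
}

# two-sequence log-likelihood at divergence t for fixed model machinery
pairLogLik <- function(t, cnt, pi, ed, rates, pInv) {
  M <- matrix(0, 4, 4)
  for (r in rates) M <- M + pFromEigen(ed, t * r)
  M <- M / length(rates)
  L <- (1 - pInv) * (pi * M)            # pi_x * P_xy, averaged over categories
  if (pInv > 0) diag(L) <- diag(L) + pInv * pi
  if (any(L[cnt > 0] <= 0)) return(-Inf)
  sum(cnt * log(L + (cnt == 0)))        # guard log(0) on unused cells
}

#' Maximum-likelihood pairwise distance under a substitution model
#'
#' Maximises the two-sequence likelihood
#' \deqn{\sum_{sites} \log\left[p_{inv}\,\pi_x 1\{x=y\} +
#'   (1-p_{inv}) \tfrac1{n_{cat}} \sum_c \pi_x P_{xy}(t\rho_c)\right]}
#' over the divergence \eqn{t \ge 0}, with \eqn{P(t) = e^{Qt}} and
#' \eqn{\rho_c} the discrete-gamma category rates (rescaled by
#' \eqn{1/(1-p_{inv})}).  Columns with a gap or N in either row are
#' dropped.  The search is bounded; an optimum at the upper bound is
#' reported as saturated (\code{NA} with attribute).
#'
#' @param a,b character vectors (rows of a masked alignment).
#' @param model a fully parameterised \linkS4class{SubstitutionModel}.
#' @param upper upper search bound in substitutions per site.
#' @param tol optimisation tolerance.
#' @return distance with a \code{saturated} attribute.
#' @export
mlPairwiseDistance <- function(a, b, model, upper = 10, tol = 1e-8) {
  ia <- encodeRow(a); ib <- encodeRow(b)
  cnt <- pairPatternCounts(ia, ib)
  if (sum(cnt) == 0) stop("no usable columns under pairwise deletion")
  ed <- modelEigen(model)
  rates <- gammaCategoryRates(model@alpha, model@nCat, model@pInv)
  f <- function(t) pairLogLik(t, cnt, model@pi, ed, rates, model@pInv)
  opt <- optimize(f, c(0, upper), maximum = TRUE, tol = tol)
  t_hat <- opt$maximum
  ll <- opt$objective
  if (!is.finite(ll))
    stop("non-finite pairwise likelihood for this pair")
  if (t_hat < 1e-5 && f(0) >= ll) { t_hat <- 0; ll <- f(0) }
  if (t_hat > upper * 0.999 && f(upper) >= ll - 1e-10)
    return(structure(NA_real_, saturated = TRUE))
  structure(t_hat, saturated = FALSE)
}

#' All pairwise distances of an alignment
#'
#' Applies the chosen pairwise estimator to all n(n-1)/2 unordered pairs of
#' the masked alignment.
#'
#' @param aln a BarcodeAlignment.
#' @param method \code{"p"} (uncorrected), \code{"jc69"} or
#'   \code{"k2p_closed"} (closed forms), or \code{"ml"} (maximum likelihood
#'   under \code{model}).
#' @param model SubstitutionModel, required for \code{method = "ml"}.
#' @param pMode p-distance convention (see \code{\link{pDistance}}).
#' @param upper upper search bound for ML distances.
#' @return A \linkS4class{PairwiseDistances}.
#' @export
distanceMatrix <- function(aln, method = c("p", "jc69", "k2p_closed", "ml"),
                           model = NULL,
                           pMode = c("pairwise_deletion", "paper_total_length"),
                           upper = 10) {
  method <- match.arg(method)
  pMode <- match.arg(pMode)
  m <- maskedMatrix(aln)
  n <- nrow(m)
  enc <- lapply(seq_len(n), function(i) encodeRow(m[i, ]))
  vals <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(vals))
  if (method == "ml") {
    if (is.null(model)) stop("method = 'ml' needs a model")
    ed <- modelEigen(model)
    rates <- gammaCategoryRates(model@alpha, model@nCat, model@pInv)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- withCallingHandlers(
      switch(method,
        p = pDistance(m[i, ], m[j, ], mode = pMode),
        jc69 = jc69Distance(m[i, ], m[j, ]),
        k2p_closed = k2pDistance(m[i, ], m[j, ]),
        ml = {
          cnt <- pairPatternCounts(enc[[i]], enc[[j]])
          if (sum(cnt) == 0)
            stop("no usable columns for pair ", rownames(m)[i], " / ",
                 rownames(m)[j])
          f <- function(t) pairLogLik(t, cnt, model@pi, ed, rates, model@pInv)
          opt <- optimize(f, c(0, upper), maximum = TRUE, tol = 1e-8)
          t_hat <- opt$maximum
          if (t_hat < 1e-5 && f(0) >= opt$objective) t_hat <- 0
          if (t_hat > upper * 0.999 && f(upper) >= opt$objective - 1e-10)
            structure(NA_real_, saturated = TRUE)
          else structure(t_hat, saturated = FALSE)
        }),
      error = function(e)
        stop("pair ", rownames(m)[i], " / ", rownames(m)[j], ": ",
             conditionMessage(e), call. = FALSE))
    vals[i, j] <- vals[j, i] <- as.numeric(d)
    s <- isTRUE(attr(d, "saturated"))
    sat[i, j] <- sat[j, i] <- s
  }
  units <- if (method == "p") "proportion" else "expected substitutions per site"
  tag <- switch(method, p = paste0("p (", pMode, ")"), jc69 = "JC69",
                k2p_closed = "K2P", ml = paste0("ML ", modelTag(model)))
  new("PairwiseDistances", values = vals, saturated = sat,
      modelTag = tag, units = units)
}

#' @describeIn distanceMatrix the numeric matrix of a PairwiseDistances.
#' @param dm a PairwiseDistances.
#' @export
distanceValues <- function(dm) dm@values

#' @describeIn distanceMatrix the n(n-1)/2 unordered pair values.
#' @export
pairwiseValues <- function(dm) dm@values[lower.tri(dm@values)]

setMethod("show", "PairwiseDistances", function(object) {
  n <- nrow(object@values)
  cat("PairwiseDistances:", n, "taxa,", n * (n - 1) / 2, "pairs;",
      object@modelTag, "(", object@units, ")\n")
  if (any(object@saturated))
    cat("  saturated pairs:", sum(object@saturated) / 2, "\n")
})

#' Write a distance matrix as square TSV
#'
#' Header row and first column carry the taxon labels.
#'
#' @param dm a PairwiseDistances.
#' @param path output path.
#' @export
writeDistanceMatrix <- function(dm, path) {
  tab <- data.frame(taxon = rownames(dm@values), dm@values,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
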