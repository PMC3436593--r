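# provenance block written beside every workflow output
writeProvenance <- function(outDir, config) {
  lines <- c(paste0("package=BarcodeDelim ",
                    as.character(packageVersion("BarcodeDelim"))),
             vapply(names(config), function(k)
               paste0(k, "=", paste(format(config[[k]]), collapse = ",")),
               ""))
  writeLines(lines, file.path(outDir, "provenance.txt"))
}

#' Distance frequency-distribution workflow
#'
#' Computes pairwise distances of one alignment under one or more distance
#' methods, bins them with one shared class width (identical binning
#' across methods for comparability), optionally splits intra- versus
#' interspecific distances using a species partition, optionally applies a
#' duplication/recoding modification first (emitting both baseline and
#' modified tables), and writes one frequency table per method plus a gap
#' report.
#'
#' @param aln a BarcodeAlignment.
#' @param methods character vector from
#'   \code{c("p", "jc69", "k2p_closed", "ml")}.
#' @param model SubstitutionModel for \code{"ml"} entries.
#' @param partition optional SpeciesPartition for the intra/inter split.
#' @param classWidth shared class width.
#' @param modification optional list(duplications, recodings) applied via
#'   \code{\link{duplicateAndRecode}}.
#' @param outDir output directory (created if needed); NULL = no files.
#' @param seed recorded in the provenance block.
#' @return named list, one entry per method (and per stage when a
#'   modification is given), each holding the
#'   \linkS4class{FrequencyDistribution} and the gap report.
#' @export
runDistFreq <- function(aln, methods = c("p", "k2p_closed"), model = NULL,
                        partition = NULL, classWidth = 0.005,
                        modification = NULL, outDir = NULL, seed = 1) {
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  stages <- list(baseline = list(aln = aln, part = partition))
  if (!is.null(modification)) {
    if (is.null(partition))
      stop("a modification requires a species partition")
    mod <- duplicateAndRecode(aln, partition,
                              duplications = modification$duplications,
                              recodings = modification$recodings)
    stages$modified <- list(aln = mod$data, part = mod$partition)
  }
  out <- list()
  for (sg in names(stages)) {
    for (mth in methods) {
      dm <- distanceMatrix(stages[[sg]]$aln, method = mth, model = model)
      if (!is.null(stages[[sg]]$part)) {
        sp <- partitionDistances(dm, stages[[sg]]$part)
        vals <- c(sp$intra, sp$inter)
        flags <- rep(c(TRUE, FALSE), c(length(sp$intra), length(sp$inter)))
        fd <- binDistances(vals, classWidth, intraFlags = flags)
      } else {
        fd <- binDistances(pairwiseValues(dm), classWidth)
      }
      key <- if (is.null(modification)) mth else paste(sg, mth, sep = ".")
      gaps <- tryCatch(findGaps(fd), error = function(e) NULL)
      out[[key]] <- list(distances = dm, distribution = fd, gaps = gaps)
      if (!is.null(outDir)) {
        frequencyTable(fd, file.path(outDir, paste0("freq_", key, ".tsv")))
        if (!is.null(gaps))
          writeLines(c(gaps$notes,
                       paste("empty classes:",
                             paste(gaps$emptyClasses, collapse = " "))),
                     file.path(outDir, paste0("gaps_", key, ".txt")))
      }
    }
  }
  if (!is.null(outDir))
    writeProvenance(outDir, list(workflow = "distfreq", methods = methods,
                                 classWidth = classWidth, seed = seed))
  invisible(out)
}

#' GMYC delimitation workflow
#'
#' Runs the coalescent-only null, the single- and (optionally) the
#' multiple-threshold GMYC models on an ultrametric tree, prints the
#' likelihood-ratio tests, and writes the fit summary, the entity table
#' and the lineage-through-time curve with threshold markers.
#'
#' @param tree rooted binary ultrametric phylo (or path to a Newick
#'   file).
#' @param mode \code{"single"} or \code{"both"} (single + multiple).
#' @param outDir output directory; NULL = no files.
#' @param seed recorded in the provenance block.
#' @return list with the fitted models and the LTT curve.
#' @export
runGmyc <- function(tree, mode = c("both", "single"), outDir = NULL,
                    seed = 1) {
  mode <- match.arg(mode)
  if (is.character(tree)) tree <- readNewick(tree)
  assertUltrametric(tree)
  fits <- list(null = fitGmyc(tree, "null"),
               single = fitGmyc(tree, "single"))
  if (mode == "both") fits$multiple <- fitGmyc(tree, "multiple")
  curve <- lttCurve(tree)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    lines <- character(0)
    for (nm in names(fits)) {
      f <- fits[[nm]]
      lines <- c(lines,
                 paste0(nm, ".logL=", format(f@logLik, digits = 10)),
                 paste0(nm, ".thresholds=",
                        paste(format(f@thresholds, digits = 6),
                              collapse = ",")),
                 paste0(nm, ".clusters=", length(f@clusters)),
                 paste0(nm, ".singletons=", length(f@singletons)),
                 paste0(nm, ".entities=", nEntities(f)),
                 paste0(nm, ".LR=", format(f@LR, digits = 8)),
                 paste0(nm, ".p=", format(f@pValue, digits = 6)))
    }
    if (mode == "both") {
      cmp <- compareGmyc(fits$multiple, fits$single)
      lines <- c(lines,
                 paste0("multiple_vs_single.LR=", format(cmp$LR, digits = 8)),
                 paste0("multiple_vs_single.df=", cmp$df),
                 paste0("multiple_vs_single.p=", format(cmp$p, digits = 6)))
    } else lines <- c(lines, "multiple=skipped")
    writeLines(lines, file.path(outDir, "gmyc_summary.txt"))
    extractEntities(fits$single, file.path(outDir, "entities_single.tsv"))
    if (mode == "both")
      extractEntities(fits$multiple,
                      file.path(outDir, "entities_multiple.tsv"))
    thrTab <- data.frame(model = "single",
                         threshold = fits$single@thresholds)
    if (mode == "both")
      thrTab <- rbind(thrTab,
                      data.frame(model = "multiple",
                                 threshold = fits$multiple@thresholds))
    writeLtt(curve, file.path(outDir, "ltt.tsv"))
    write.table(thrTab, file.path(outDir, "ltt_thresholds.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    writeProvenance(outDir, list(workflow = "gmyc", mode = mode,
                                 seed = seed))
  }
  invisible(c(fits, list(ltt = curve)))
}

#' Substitution-saturation workflow
#'
#' Runs the entropy-based saturation test and writes a key=value report
#' with a verdict sentence.
#'
#' @param aln a BarcodeAlignment.
#' @param pInv externally estimated proportion of invariable sites.
#' @param nOtu taxa per evaluation (4, 8, 16 or 32).
#' @param nResamples resampling rounds.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param outDir output directory; NULL = no files.
#' @return the \linkS4class{SaturationResult}.
#' @export
runSaturation <- function(aln, pInv = 0, nOtu = 32, nResamples = 100,
                          seed, outDir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  res <- issTest(aln, pInv = pInv, nOtu = nOtu, nResamples = nResamples,
                 seed = seed)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    verdictSentence <- switch(res@verdict,
      "low saturation" = "Iss is significantly below Iss.c: saturation probably is low in the data set.",
      "substantial saturation" = "Iss is below Iss.c but not significantly: substantial saturation cannot be excluded.",
      "poor" = "Iss exceeds Iss.c without a significant difference: the quality of the data set for phylogenetic analyses is poor.",
      "useless" = "Iss significantly exceeds Iss.c: the data set is useless for phylogenetic analyses.",
      "no signal" = "No variable sites remain after invariant removal: no saturation signal can be assessed.")
    writeLines(c(formatSaturationReport(res), verdictSentence),
               file.path(outDir, "saturation.txt"))
    writeProvenance(outDir, list(workflow = "saturation", pInv = pInv,
                                 nOtu = nOtu, nResamples = nResamples,
                                 seed = seed))
  }
  res
}
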