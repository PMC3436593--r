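#' Construct a BarcodeAlignment from a character matrix
#'
#' @param seqs character matrix of single residues with taxon rownames, or a
#'   named character vector of equal-length sequence strings.
#' @param mask optional logical column mask (default: all columns included).
#' @return A \linkS4class{BarcodeAlignment}.
#' @export
barcodeAlignment <- function(seqs, mask = NULL) {
  if (!is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1)
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
    seqs <- do.call(rbind, lapply(strsplit(seqs, ""), identity))
  }
  seqs <- toupper(seqs)
  seqs[seqs == "U"] <- "T"
  if (is.null(mask)) mask <- rep(TRUE, ncol(seqs))
  new("BarcodeAlignment", seqs = seqs, mask = mask)
}

#' @describeIn barcodeAlignment taxon labels.
#' @param x,aln a BarcodeAlignment.
#' @export
taxa <- function(x) rownames(x@seqs)

#' @describeIn barcodeAlignment total column count.
#' @export
alignmentLength <- function(x) ncol(x@seqs)

#' @describeIn barcodeAlignment number of included (unmasked) columns.
#' @export
maskedLength <- function(x) sum(x@mask)

#' @describeIn barcodeAlignment character matrix restricted to included
#'   columns.
#' @export
maskedMatrix <- function(x) x@seqs[, x@mask, drop = FALSE]

setMethod("show", "BarcodeAlignment", function(object) {
  cat("BarcodeAlignment:", nrow(object@seqs), "taxa,",
      ncol(object@seqs), "columns (", sum(object@mask), "included )\n")
})

#' Read a FASTA alignment
#'
#' Reads a sequential or line-wrapped FASTA file into a
#' \linkS4class{BarcodeAlignment} with a full-true column mask.  Lowercase
#' is normalised to uppercase and U to T.  Ambiguity codes other than N are
#' rejected, ragged row lengths and duplicated labels are errors.
#'
#' @param path path to a FASTA file with at least two records.
#' @param format currently only \code{"fasta"}.
#' @return A \linkS4class{BarcodeAlignment}.
#' @export
readAlignment <- function(path, format = "fasta") {
  format <- match.arg(format, "fasta")
  if (!file.exists(path)) stop("file not found: ", path)
  recs <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(recs) == 0) stop("empty FASTA file: ", path)
  if (length(recs) < 2) stop("need at least two records, got ", length(recs))
  labels <- sub("\\s.*$", "", names(recs))   # first token of the header
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop("duplicate label(s): ", paste(unique(dup), collapse = ", "))
  lens <- Biostrings::width(recs)
  if (length(unique(lens)) > 1)
    stop("ragged alignment: row lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  m <- do.call(rbind, strsplit(toupper(as.character(recs)), ""))
  rownames(m) <- labels
  bad <- setdiff(unique(as.vector(m)), c(DNA_ALPHABET, "U"))
  if (length(bad))
    stop("disallowed residue(s) (only A,C,G,T,U,N,-,? accepted): ",
         paste(bad, collapse = ", "))
  barcodeAlignment(m)
}

#' Write a BarcodeAlignment as FASTA
#'
#' Writes all columns (the mask is not applied); the mask can be stored
#' separately with \code{\link{writeMask}}.
#'
#' @param aln a BarcodeAlignment.
#' @param path output file path.
#' @export
writeAlignment <- function(aln, path) {
  rows <- apply(aln@seqs, 1, paste, collapse = "")
  writeLines(paste0(">", names(rows), "\n", rows), path)
  invisible(path)
}

#' Mask alignment columns
#'
#' Marks the union of the given 1-based closed column intervals as excluded
#' (e.g. non-alignable regions pruned before analysis).  Masking is
#' cumulative and idempotent.
#'
#' @param aln a BarcodeAlignment.
#' @param excludedRanges list of 1-based closed intervals
#'   \code{c(first, last)}, or a two-column matrix.
#' @return A BarcodeAlignment with the updated mask.
#' @export
applyColumnMask <- function(aln, excludedRanges) {
  if (is.matrix(excludedRanges))
    excludedRanges <- split(excludedRanges, seq_len(nrow(excludedRanges)))
  mask <- aln@mask
  L <- alignmentLength(aln)
  for (iv in excludedRanges) {
    if (length(iv) != 2 || iv[1] > iv[2])
      stop("intervals must be c(first, last) with first <= last")
    if (iv[1] < 1 || iv[2] > L)
      stop("interval [", iv[1], ",", iv[2], "] out of bounds 1..", L)
    mask[iv[1]:iv[2]] <- FALSE
  }
  new("BarcodeAlignment", seqs = aln@seqs, mask = mask)
}

#' Read / write exclusion masks
#'
#' Sidecar text format: one 1-based closed interval per line,
#' \dQuote{first last}, '#' comments allowed.
#'
#' @param path file path.
#' @rdname maskIO
#' @export
readMask <- function(path) {
  tab <- read.table(path, comment.char = "#",
                    col.names = c("first", "last"))
  lapply(seq_len(nrow(tab)), function(i) c(tab$first[i], tab$last[i]))
}

#' @param aln a BarcodeAlignment whose excluded columns are written as
#'   maximal runs.
#' @rdname maskIO
#' @export
writeMask <- function(aln, path) {
  excl <- which(!aln@mask)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# excluded column intervals (1-based, closed)", con)
  if (length(excl)) {
    runs <- split(excl, cumsum(c(1, diff(excl) != 1)))
    for (r in runs) writeLines(paste(min(r), max(r)), con)
  }
  invisible(path)
}

#' Construct a species partition
#'
#' @param assignments named character vector mapping taxon label to species
#'   identifier.
#' @return A \linkS4class{SpeciesPartition}.
#' @export
speciesPartition <- function(assignments) {
  new("SpeciesPartition", assignments = assignments)
}

#' @describeIn speciesPartition member count per species.
#' @param part a SpeciesPartition.
#' @export
speciesSizes <- function(part) {
  if (!length(part@assignments)) return(integer(0))
  tab <- table(part@assignments)
  setNames(as.integer(tab), names(tab))
}

#' @describeIn speciesPartition species identifiers of given taxa
#'   (NA when unassigned).
#' @param labels taxon labels to look up.
#' @export
speciesOf <- function(part, labels) {
  unname(part@assignments[labels])
}

setMethod("show", "SpeciesPartition", function(object) {
  sz <- speciesSizes(object)
  cat("SpeciesPartition:", length(object@assignments), "taxa in",
      length(sz), "species\n")
})

#' Read a species-partition table
#'
#' Two-column tab-separated text, \code{taxon TAB species}; lines starting
#' with '#' are comments.  Listing a taxon twice with different species is
#' a conflict error; duplicated identical rows are tolerated.
#'
#' @param path file path.
#' @return A \linkS4class{SpeciesPartition}.
#' @export
readSpeciesPartition <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(speciesPartition(character(0)))
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) != 2))
    stop("expected two tab-separated columns in ", path)
  tax <- vapply(parts, `[`, "", 1)
  sp <- vapply(parts, `[`, "", 2)
  key <- !duplicated(paste(tax, sp, sep = "\r"))
  tax <- tax[key]; sp <- sp[key]
  dup <- tax[duplicated(tax)]
  if (length(dup))
    stop("conflicting species for taxon/taxa: ",
         paste(unique(dup), collapse = ", "))
  speciesPartition(setNames(sp, tax))
}

#' @describeIn readSpeciesPartition write the table back.
#' @param part a SpeciesPartition.
#' @export
writeSpeciesPartition <- function(part, path) {
  writeLines(c("# taxon\tspecies",
               paste(names(part@assignments), part@assignments, sep = "\t")),
             path)
  invisible(path)
}
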