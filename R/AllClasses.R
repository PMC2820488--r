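#' @import methods
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement readDNAStringSet
#'   writeXStringSet pairwiseAlignment nmatch score pattern subject
#'   letterFrequency width subseq
#' @importFrom IRanges IRanges findOverlaps pintersect overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats rbinom runif cor setNames aggregate
#' @importFrom utils write.table head tail
NULL

DNA_ALPHABET_STRICT <- c("A", "C", "G", "T", "N")

#' CloneLibrary: a c0t clone library
#'
#' An ordered collection of uniquely named DNA sequences (clone inserts) with a
#' library name. Sequences are restricted to the alphabet A/C/G/T/N.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet} with unique, non-empty names.
#' @slot name Library name (single string).
#' @export
setClass("CloneLibrary",
         representation(seqs = "DNAStringSet", name = "character"))

setValidity("CloneLibrary", function(object) {
  s <- object@seqs
  if (length(object@name) != 1L) return("'name' must be a single string")
  if (length(s) > 0L) {
    if (is.null(names(s)) || any(!nzchar(names(s))))
      return("all clones must be named")
    if (anyDuplicated(names(s)))
      return(paste0("duplicate clone id: ",
                    names(s)[duplicated(names(s))][1L]))
    if (any(width(s) == 0L)) return("empty sequences are not allowed")
    bad <- .checkAlphabet(as.character(s))
    if (!is.null(bad)) return(bad)
  }
  TRUE
})

# returns NULL or an error message naming record and position
.checkAlphabet <- function(seqs) {
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    off <- which(!(ch %in% DNA_ALPHABET_STRICT))
    if (length(off))
      return(sprintf("invalid character '%s' in record %s at position %d",
                     ch[off[1L]],
                     if (!is.null(names(seqs))) names(seqs)[i] else i,
                     off[1L]))
  }
  NULL
}

#' Construct a CloneLibrary
#'
#' @param seqs Named character vector or DNAStringSet of clone sequences.
#' @param name Library name.
#' @return A \linkS4class{CloneLibrary}.
#' @export
CloneLibrary <- function(seqs = DNAStringSet(), name = "library") {
  if (is.character(seqs)) {
    ids <- names(seqs)
    seqs <- toupper(seqs)
    seqs <- chartr("U", "T", seqs)
    bad <- .checkAlphabet(stats::setNames(seqs, ids))
    if (!is.null(bad)) stop(bad)
    seqs <- DNAStringSet(seqs)
    names(seqs) <- ids
  }
  new("CloneLibrary", seqs = seqs, name = name)
}

#' @describeIn CloneLibrary Clone sequences as a DNAStringSet
#' @param x,object A CloneLibrary.
#' @export
setGeneric("clones", function(x) standardGeneric("clones"))
#' @export
setMethod("clones", "CloneLibrary", function(x) x@seqs)

#' @export
setGeneric("libraryName", function(x) standardGeneric("libraryName"))
#' @export
setMethod("libraryName", "CloneLibrary", function(x) x@name)

#' @export
setGeneric("totalBases", function(x) standardGeneric("totalBases"))
#' @export
setMethod("totalBases", "CloneLibrary", function(x) sum(width(x@seqs)))

#' @export
setMethod("length", "CloneLibrary", function(x) length(x@seqs))

#' @export
setMethod("names", "CloneLibrary", function(x) names(x@seqs))

#' @export
setMethod("[", "CloneLibrary", function(x, i, j, ..., drop = TRUE) {
  new("CloneLibrary", seqs = x@seqs[i], name = x@name)
})

setMethod("show", "CloneLibrary", function(object) {
  cat(sprintf("CloneLibrary '%s': %d clones, %d bp total\n",
              object@name, length(object), totalBases(object)))
  if (length(object))
    cat(sprintf("  insert lengths %d-%d bp\n",
                min(width(object@seqs)), max(width(object@seqs))))
})

#' RepeatPanel: labeled reference repeat sequences
#'
#' Reference repeat sequences with a repeat class tag per entry
#' (satellite, minisatellite, microsatellite, retroelement, transposon,
#' MITE, organellar, telomere, rDNA, other) and an optional accession.
#'
#' @slot seqs DNAStringSet with unique names.
#' @slot repeatClass Character vector parallel to \code{seqs}.
#' @slot accession Character vector parallel to \code{seqs} (may be NA).
#' @export
setClass("RepeatPanel",
         representation(seqs = "DNAStringSet", repeatClass = "character",
                        accession = "character"))

REPEAT_CLASSES <- c("satellite", "minisatellite", "microsatellite",
                    "retroelement", "transposon", "MITE", "organellar",
                    "telomere", "rDNA", "other")

setValidity("RepeatPanel", function(object) {
  n <- length(object@seqs)
  if (n == 0L) return(TRUE)
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    return("panel entry names must be unique and non-empty")
  if (length(object@repeatClass) != n || length(object@accession) != n)
    return("repeatClass/accession must parallel the sequences")
  if (any(!(object@repeatClass %in% REPEAT_CLASSES)))
    return(paste0("unknown repeat class: ",
                  setdiff(object@repeatClass, REPEAT_CLASSES)[1L]))
  if (any(width(object@seqs) == 0L)) return("empty panel sequence")
  TRUE
})

#' Construct a RepeatPanel
#' @param seqs Named character vector or DNAStringSet.
#' @param repeatClass Class tag per entry.
#' @param accession Optional accession per entry.
#' @return A \linkS4class{RepeatPanel}.
#' @export
RepeatPanel <- function(seqs, repeatClass, accession = NA_character_) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    seqs <- DNAStringSet(chartr("U", "T", toupper(seqs)))
    names(seqs) <- ids
  }
  new("RepeatPanel", seqs = seqs,
      repeatClass = rep_len(repeatClass, length(seqs)),
      accession = rep_len(accession, length(seqs)))
}

#' @export
setMethod("length", "RepeatPanel", function(x) length(x@seqs))
#' @export
setMethod("names", "RepeatPanel", function(x) names(x@seqs))
#' @export
setGeneric("panelClasses", function(x) standardGeneric("panelClasses"))
#' @export
setMethod("panelClasses", "RepeatPanel",
          function(x) stats::setNames(x@repeatClass, names(x@seqs)))
#' @export
setGeneric("panelSeqs", function(x) standardGeneric("panelSeqs"))
#' @export
setMethod("panelSeqs", "RepeatPanel", function(x) x@seqs)

setMethod("show", "RepeatPanel", function(object) {
  cat(sprintf("RepeatPanel: %d entries\n", length(object)))
  if (length(object)) {
    tab <- table(object@repeatClass)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' TandemArray: one detected tandem array
#'
#' A tandem array detected in a sequence: 0-based half-open interval, repeat
#' period, phase of the first full monomer, monomer decomposition and
#' canonical consensus. The concatenation of the monomers (first and last
#' possibly partial) reconstructs the array substring exactly.
#'
#' @slot seqId Identifier of the carrying sequence.
#' @slot start,end 0-based half-open interval on the sequence.
#' @slot period Repeat period in bp (smallest period explaining the array).
#' @slot phase Offset of the first full monomer within the array, in [0, period).
#' @slot copyNumber Array length / period.
#' @slot monomers Ordered monomer strings; first/last may be partial.
#' @slot partial Logical flag per monomer.
#' @slot consensus Canonical (lexicographically minimal rotation) consensus.
#' @slot conformity Percent identity of the array to its period-shifted self.
#' @export
setClass("TandemArray",
         representation(seqId = "character", start = "integer", end = "integer",
                        period = "integer", phase = "integer",
                        copyNumber = "numeric", monomers = "character",
                        partial = "logical", consensus = "character",
                        conformity = "numeric"))

setValidity("TandemArray", function(object) {
  if (object@period < 2L) return("period must be >= 2")
  if (object@start < 0L || object@end <= object@start)
    return("invalid interval")
  if (object@phase < 0L || object@phase >= object@period)
    return("phase must be in [0, period)")
  if (object@copyNumber < 2) return("copy number must be >= 2")
  if (nchar(object@consensus) != object@period)
    return("consensus length must equal period")
  if (sum(nchar(object@monomers)) != object@end - object@start)
    return("monomers must reconstruct the array substring")
  TRUE
})

setMethod("show", "TandemArray", function(object) {
  cat(sprintf(
    "TandemArray %s:[%d,%d) period=%d copies=%.1f conformity=%.1f%%\n  consensus %s\n",
    object@seqId, object@start, object@end, object@period,
    object@copyNumber, object@conformity, object@consensus))
})

#' @export
setGeneric("arrayPeriod", function(x) standardGeneric("arrayPeriod"))
#' @export
setMethod("arrayPeriod", "TandemArray", function(x) x@period)
#' @export
setGeneric("arrayInterval", function(x) standardGeneric("arrayInterval"))
#' @export
setMethod("arrayInterval", "TandemArray", function(x) c(x@start, x@end))
#' @export
setGeneric("arrayConsensus", function(x) standardGeneric("arrayConsensus"))
#' @export
setMethod("arrayConsensus", "TandemArray", function(x) x@consensus)
#' @export
setGeneric("arrayMonomers", function(x) standardGeneric("arrayMonomers"))
#' @export
setMethod("arrayMonomers", "TandemArray", function(x) x@monomers)
#' @export
setGeneric("arrayCopyNumber", function(x) standardGeneric("arrayCopyNumber"))
#' @export
setMethod("arrayCopyNumber", "TandemArray", function(x) x@copyNumber)

#' RepeatFamily: a cluster of tandem-bearing clones
#'
#' A family of tandem arrays grouped by consensus similarity, with the
#' Table-style statistics: monomer size (or range), number of library clones
#' (c0t hits), G/C content, pairwise monomer identity range, representative
#' monomer, and a size-derived class label (microsatellite, minisatellite or
#' satellite).
#'
#' @export
setClass("RepeatFamily",
         representation(name = "character", memberIds = "character",
                        periods = "integer", cotHits = "integer",
                        gcPercent = "numeric", identityMin = "numeric",
                        identityMax = "numeric", representative = "character",
                        label = "character"))

setValidity("RepeatFamily", function(object) {
  if (length(object@periods) == 0L) return("empty monomer size range")
  if (object@identityMin > object@identityMax || object@identityMax > 100)
    return("identity range must satisfy min <= max <= 100")
  TRUE
})

setMethod("show", "RepeatFamily", function(object) {
  pr <- range(object@periods)
  sz <- if (pr[1] == pr[2]) as.character(pr[1]) else paste(pr, collapse = "-")
  cat(sprintf(
    "RepeatFamily %s (%s): size %s bp, %d clones, GC %.0f%%, identity %.0f - %.0f\n",
    object@name, object@label, sz, object@cotHits, object@gcPercent,
    object@identityMin, object@identityMax))
})

#' @export
setGeneric("familyName", function(x) standardGeneric("familyName"))
#' @export
setMethod("familyName", "RepeatFamily", function(x) x@name)
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))
#' @export
setMethod("familyMembers", "RepeatFamily", function(x) x@memberIds)
#' @export
setGeneric("familyRepresentative", function(x) standardGeneric("familyRepresentative"))
#' @export
setMethod("familyRepresentative", "RepeatFamily", function(x) x@representative)

#' GenomeSimulation: a synthetic genome with planted repeat truth
#'
#' Holds the simulated genome, the per-array truth table (family, 0-based
#' half-open interval, orientation, junction/flank annotation) and the
#' per-family table (class, consensus, copy numbers).
#'
#' @export
setClass("GenomeSimulation",
         representation(genome = "DNAStringSet", arrays = "data.frame",
                        families = "data.frame", spec = "list"))

setMethod("show", "GenomeSimulation", function(object) {
  cat(sprintf("GenomeSimulation: %d bp genome, %d planted arrays, %d families\n",
              sum(width(object@genome)), nrow(object@arrays),
              nrow(object@families)))
})

#' @export
setGeneric("simGenome", function(x) standardGeneric("simGenome"))
#' @export
setMethod("simGenome", "GenomeSimulation", function(x) x@genome)
#' @export
setGeneric("simArrays", function(x) standardGeneric("simArrays"))
#' @export
setMethod("simArrays", "GenomeSimulation", function(x) x@arrays)
#' @export
setGeneric("simFamilies", function(x) standardGeneric("simFamilies"))
#' @export
setMethod("simFamilies", "GenomeSimulation", function(x) x@families)
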