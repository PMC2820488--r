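# Genomic abundance from hit counts against a sparse genome sample
# (BAC-end-sequence style): hits are counted per sample record, binned the
# way the library survey reports them, and extrapolated to genome copy
# numbers through the sampled coverage fraction.

#' Count sample records hit by a query
#'
#' Number of distinct genome-sample records with at least one acceptable
#' local alignment to the query (records, not alignments, are counted).
#'
#' @param query A single DNA string.
#' @param sampleSet Named character vector or DNAStringSet of sample records.
#' @param index Optional precomputed \code{\link{seedIndex}} of the sample
#'   set (reused across queries).
#' @param ... Acceptance thresholds passed to \code{\link{seededLocalAlign}}.
#' @return Integer hit count.
#' @export
countHits <- function(query, sampleSet, index = NULL, ...) {
  if (is(sampleSet, "DNAStringSet")) {
    nm <- names(sampleSet); sampleSet <- as.character(sampleSet)
    names(sampleSet) <- nm
  }
  if (length(sampleSet) == 0L) stop("empty sample set")
  hits <- seededLocalAlign(query, sampleSet, index = index, ...)
  length(unique(hits$target_id))
}

#' Bin a hit count the way the library survey reports it
#'
#' Hit counts of at most 10 are "low", 11-300 "mid" and more than 300 "high".
#'
#' @param hits Non-negative integer vector.
#' @return Character vector of bins.
#' @export
binHits <- function(hits) {
  if (any(hits < 0)) stop("hits must be non-negative")
  ifelse(hits <= 10L, "low", ifelse(hits <= 300L, "mid", "high"))
}

#' Extrapolate genomic copy number from sample hits
#'
#' With a genome sample covering fraction f of the genome, a dispersed
#' element with N copies is expected in about N x f records, so
#' \code{hits / f} estimates N.
#'
#' @param hits Non-negative hit count(s).
#' @param coverageFraction Fraction of the genome covered by the sample,
#'   in (0, 1].
#' @return Estimated copy number(s).
#' @export
estimateCopies <- function(hits, coverageFraction) {
  if (any(coverageFraction <= 0) || any(coverageFraction > 1))
    stop("coverageFraction must be in (0, 1]")
  hits / coverageFraction
}

#' Abundance table for a set of queries
#'
#' @param queries Named character vector of query sequences.
#' @param sampleSet Named character vector or DNAStringSet of sample records.
#' @param coverageFraction Fraction of the genome covered by the sample.
#' @param ... Acceptance thresholds passed to \code{\link{seededLocalAlign}}.
#' @return data.frame(query_id, hits, bin, estimated_copies).
#' @export
abundanceTable <- function(queries, sampleSet, coverageFraction, ...) {
  if (is(sampleSet, "DNAStringSet")) {
    nm <- names(sampleSet); sampleSet <- as.character(sampleSet)
    names(sampleSet) <- nm
  }
  if (length(sampleSet) == 0L) stop("empty sample set")
  idx <- seedIndex(sampleSet)
  hits <- vapply(seq_along(queries), function(i)
    countHits(queries[[i]], sampleSet, index = idx, ...), 0L)
  data.frame(query_id = names(queries), hits = hits, bin = binHits(hits),
             estimated_copies = estimateCopies(hits, coverageFraction),
             stringsAsFactors = FALSE)
}
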