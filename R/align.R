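# Shared alignment machinery. Scoring follows the package-wide scheme:
# match +1, mismatch -1, linear gap -2; N never matches anything, including N.

.substMatrix <- local({
  m <- matrix(-1L, 5L, 5L,
              dimnames = list(DNA_ALPHABET_STRICT, DNA_ALPHABET_STRICT))
  diag(m)[1:4] <- 1L
  m
})

.validateSeq <- function(seq, arg = "seq") {
  if (!is.character(seq) || length(seq) != 1L)
    stop("'", arg, "' must be a single character string")
  bad <- .checkAlphabet(seq)
  if (!is.null(bad)) stop(bad)
  seq
}

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed; N maps to N. Vectorized over a character
#' vector. Invalid characters raise an error.
#'
#' @param seq Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @examples
#' revComp("GATCA")   # "TGATC"
#' @export
revComp <- function(seq) {
  bad <- .checkAlphabet(seq)
  if (!is.null(bad)) stop(bad)
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' G/C content of a DNA sequence
#'
#' Fraction (G+C)/(A+C+G+T); N is excluded from both numerator and
#' denominator.
#'
#' @param seq A single DNA string.
#' @return Fraction in [0, 1].
#' @export
gcContent <- function(seq) {
  .validateSeq(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ch <- ch[ch != "N"]
  if (length(ch) == 0L) stop("sequence contains only N")
  sum(ch %in% c("G", "C")) / length(ch)
}

# identity (percent) from a PairwiseAlignments object, per element:
# matches / alignment columns, columns including internal gaps
.alnIdentity <- function(aln) {
  nid <- Biostrings::nindel(aln)
  cols <- nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(nid)[, "WidthSum"] +
    Biostrings::deletion(nid)[, "WidthSum"]
  unname(ifelse(cols == 0L, 0, 100 * nmatch(aln) / cols))  # empty: 0
}

.pairAlign <- function(pattern, subject, type) {
  pairwiseAlignment(pattern, subject, type = type,
                    substitutionMatrix = .substMatrix,
                    gapOpening = 0, gapExtension = 2)
}

#' Global identity of two sequences
#'
#' Percent identity under global alignment with free terminal gaps
#' (match +1, mismatch -1, gap -2): matches / alignment columns x 100.
#'
#' @param a,b DNA strings.
#' @return Percent identity in [0, 100].
#' @export
globalIdentity <- function(a, b) {
  .validateSeq(a, "a"); .validateSeq(b, "b")
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  # co-optimal ends-free alignments can differ between argument orders;
  # canonicalizing the order makes the measure exactly symmetric
  if (nchar(a) > nchar(b) || (nchar(a) == nchar(b) && a > b)) {
    tmp <- a; a <- b; b <- tmp
  }
  aln <- .pairAlign(a, b, "overlap")
  .alnIdentity(aln)
}

#' Rotation- and strand-tolerant consensus identity
#'
#' Identity of the shorter sequence against the doubled longer sequence
#' (global in the shorter, local in the doubled longer), maximized over
#' strands. Used to compare tandem-repeat consensus sequences, whose start
#' point within the monomer is arbitrary.
#'
#' @param a,b DNA strings (typically monomer consensi).
#' @param bothStrands Also try the reverse complement of \code{b}.
#' @return Percent identity in [0, 100].
#' @export
rotationIdentity <- function(a, b, bothStrands = TRUE) {
  .validateSeq(a, "a"); .validateSeq(b, "b")
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  cand <- paste0(b, b)
  best <- .alnIdentity(.pairAlign(a, cand, "global-local"))
  if (bothStrands) {
    rc <- revComp(b)
    best <- max(best, .alnIdentity(.pairAlign(a, paste0(rc, rc), "global-local")))
  }
  best
}

# enumerate k-mers of a string; returns character(0) if too short
.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

# k-mer index over a set of target sequences -> data.table(kmer, tid)
#' Build a k-mer seed index over target sequences
#'
#' Precomputes the exact k-mer index used by \code{\link{seededLocalAlign}} so
#' that many queries can be screened against the same target set cheaply.
#'
#' @param targets Named character vector or DNAStringSet.
#' @param k Seed length.
#' @return An object to pass as \code{index} to \code{seededLocalAlign}.
#' @export
seedIndex <- function(targets, k = 11L) {
  if (is(targets, "DNAStringSet")) {
    tn <- names(targets); targets <- as.character(targets); names(targets) <- tn
  }
  kl <- lapply(targets, .kmers, k = k)
  dt <- data.table::data.table(
    kmer = unlist(kl, use.names = FALSE),
    tid = rep(names(targets), lengths(kl)))
  dt <- unique(dt)
  data.table::setkey(dt, kmer)
  structure(list(dt = dt, k = k, targets = targets), class = "cotrepSeedIndex")
}

# which targets share a k-mer with 'seq' (character)
.seedCandidates <- function(seq, index) {
  km <- unique(.kmers(seq, index$k))
  if (length(km) == 0L) return(character(0))
  hits <- index$dt[data.table::data.table(kmer = km), on = "kmer",
                   nomatch = NULL]
  unique(hits$tid)
}

#' Seeded local alignment against a target set
#'
#' Screens targets for an exact shared k-mer with the query (on either
#' strand), then computes a full local alignment (match +1, mismatch -1,
#' gap -2) for each candidate pair. One best hit per target and strand is
#' reported. Hits are filtered by minimum score, aligned length and percent
#' identity, sorted by score (descending) with deterministic tie-break by
#' (target id, target start).
#'
#' @param query A single DNA string.
#' @param targets Named character vector or DNAStringSet of target sequences.
#' @param k Seed length (seed longer than the query yields an empty result).
#' @param minScore,minLen,minIdentity Acceptance thresholds; the defaults
#'   (30, 50 bp, 70 percent) are the package's internal equivalent of a
#'   database-search e-value cutoff.
#' @param index Optional precomputed \code{\link{seedIndex}} of the targets.
#' @return A data.frame with columns query_id, target_id, strand, qstart,
#'   qend, tstart, tend, identity, score. Intervals are 0-based half-open.
#' @export
seededLocalAlign <- function(query, targets, k = 11L, minScore = 30,
                             minLen = 50L, minIdentity = 70, index = NULL) {
  queryId <- if (!is.null(names(query))) names(query)[1L] else "query"
  query <- .validateSeq(unname(query), "query")
  if (is.null(index)) index <- seedIndex(targets, k = k)
  emptyHits <- data.frame(query_id = character(), target_id = character(),
                          strand = character(), qstart = integer(),
                          qend = integer(), tstart = integer(),
                          tend = integer(), identity = numeric(),
                          score = numeric(), stringsAsFactors = FALSE)
  if (nchar(query) < index$k) return(emptyHits)
  qrc <- revComp(query)
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else qrc
    cand <- .seedCandidates(q, index)
    if (length(cand) == 0L) next
    tgt <- DNAStringSet(index$targets[cand])
    aln <- .pairAlign(tgt, DNAString(q), "local")
    sc <- score(aln)
    idn <- .alnIdentity(aln)
    # subject = query, pattern = target
    qs <- Biostrings::start(subject(aln)) - 1L
    qe <- Biostrings::end(subject(aln))
    ts <- Biostrings::start(pattern(aln)) - 1L
    te <- Biostrings::end(pattern(aln))
    alnLen <- qe - qs
    if (strand == "-") {
      L <- nchar(query)
      tmp <- qs
      qs <- L - qe
      qe <- L - tmp
    }
    keep <- sc >= minScore & alnLen >= minLen & idn >= minIdentity
    if (!any(keep)) next
    out[[strand]] <- data.frame(
      query_id = queryId, target_id = cand[keep], strand = strand,
      qstart = qs[keep], qend = qe[keep], tstart = ts[keep], tend = te[keep],
      identity = idn[keep], score = sc[keep], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(emptyHits)
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$target_id, res$tstart), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Drop clones shorter than a minimum insert length
#'
#' @param library A \linkS4class{CloneLibrary}.
#' @param minLen Minimum retained length in bp (records with length
#'   \code{>= minLen} are kept; the library-construction convention excludes
#'   inserts shorter than 50 bp).
#' @return A CloneLibrary with the retained records in their original order.
#' @export
filterMinLength <- function(library, minLen = 50L) {
  stopifnot(is(library, "CloneLibrary"), minLen >= 1L)
  library[width(clones(library)) >= minLen]
}

#' Round half-up to a fixed number of decimals
#'
#' Exact half values round away from zero (printed-report convention), unlike
#' base \code{round}'s round-half-even.
#'
#' @param x Non-negative numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Percentage of a count, rounded half-up
#'
#' @param count,total Non-negative numbers, \code{count <= total}.
#' @param digits Decimal places (default 1, the report convention).
#' @return \code{count/total*100} rounded half-up.
#' @export
percentHalfUp <- function(count, total, digits = 1L) {
  if (any(total <= 0)) stop("total must be positive")
  roundHalfUp(count / total * 100, digits)
}
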