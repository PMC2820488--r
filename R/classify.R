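# Clone classification against a labeled repeat panel, plus motif detectors
# for telomere-like runs and microsatellite arrays, and the composition
# report. Precedence when several detectors fire: panel homology (known
# repeat / organellar) > telomere > microsatellite > novel.

#' CompositionReport: library composition summary
#'
#' Per-category counts and percentages over a clone library (the categories
#' partition the library; an explicit remainder row is appended when the
#' supplied counts do not exhaust the total), plus optional per-family counts
#' of the known-repeat fraction.
#'
#' @export
setClass("CompositionReport",
         representation(categories = "data.frame", families = "data.frame",
                        total = "integer"))

setValidity("CompositionReport", function(object) {
  if (nrow(object@categories) &&
      sum(object@categories$count) != object@total)
    return("category counts must sum to the total")
  TRUE
})

setMethod("show", "CompositionReport", function(object) {
  cat(sprintf("CompositionReport: %d clones\n", object@total))
  for (i in seq_len(nrow(object@categories)))
    cat(sprintf("  %-22s %6d  %5.1f%%\n", object@categories$category[i],
                object@categories$count[i], object@categories$percent[i]))
})

#' @export
setGeneric("reportCategories", function(x) standardGeneric("reportCategories"))
#' @export
setMethod("reportCategories", "CompositionReport", function(x) x@categories)
#' @export
setGeneric("reportFamilies", function(x) standardGeneric("reportFamilies"))
#' @export
setMethod("reportFamilies", "CompositionReport", function(x) x@families)

#' Per-category percentages of a clone total
#'
#' Percentages are count/total x 100, rounded half-up to one decimal (the
#' printed-report convention). If the named counts do not exhaust the total an
#' explicit \code{unassigned} remainder row completes the partition.
#'
#' @param counts Named non-negative integer vector.
#' @param total Positive total (>= sum(counts)).
#' @return A \linkS4class{CompositionReport}.
#' @export
compositionPercentages <- function(counts, total) {
  if (total <= 0) stop("total must be positive")
  if (sum(counts) > total) stop("counts exceed total")
  nm <- names(counts)
  if (is.null(nm)) nm <- paste0("category", seq_along(counts))
  df <- data.frame(category = nm, count = as.integer(counts),
                   percent = percentHalfUp(as.numeric(counts), total),
                   stringsAsFactors = FALSE)
  rem <- total - sum(counts)
  if (rem > 0)
    df <- rbind(df, data.frame(category = "unassigned", count = rem,
                               percent = percentHalfUp(rem, total)))
  new("CompositionReport", categories = df,
      families = data.frame(), total = as.integer(total))
}

TELOMERE_MOTIF <- "TTTAGGG"

#' Detect a telomere-like tandem motif run
#'
#' Finds the longest run of at least \code{minCopies} tandem copies of the
#' plant telomere motif TTTAGGG, on either strand, allowing at most one
#' mismatch per copy.
#'
#' @param seq DNA string.
#' @param minCopies Minimum tandem copies (default 3).
#' @return A list(start, end, copies, strand) with a 0-based half-open
#'   interval in \code{seq} coordinates, or NULL.
#' @export
detectTelomereMotif <- function(seq, minCopies = 3L) {
  .validateSeq(seq)
  if (minCopies < 2L) stop("minCopies must be >= 2")
  M <- strsplit(TELOMERE_MOTIF, "")[[1L]]
  w <- length(M)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revComp(seq)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    if (n < w) next
    nw <- n - w + 1L
    mm <- integer(nw)
    for (j in 0:(w - 1L)) mm <- mm + (ch[(1L + j):(nw + j)] != M[j + 1L])
    ok <- mm <= 1L
    copies <- integer(nw)
    for (i in rev(seq_len(nw)))
      if (ok[i]) copies[i] <- 1L +
          (if (i + w <= nw && ok[i + w]) copies[i + w] else 0L)
    if (!any(copies >= minCopies)) next
    i <- which.max(copies)
    cp <- copies[i]
    st <- i - 1L; en <- st + w * cp
    if (strand == "-") { tmp <- st; st <- n - en; en <- n - tmp }
    if (is.null(best) || cp > best$copies)
      best <- list(start = st, end = en, copies = cp, strand = strand)
  }
  best
}

#' Detect microsatellite arrays (2-5 bp motifs)
#'
#' Reports maximal arrays of a repeated short motif covering at least
#' \code{minArrayBp} with at least 90 percent motif conformity. The motif is
#' reported in canonical (lexicographically minimal rotation) form.
#' Homopolymer runs are excluded (motif length >= 2 with more than one
#' distinct base).
#'
#' @param seq DNA string.
#' @param motifLenRange Motif lengths considered, default c(2, 5).
#' @param minArrayBp Minimum array span in bp (default 20).
#' @param minConformity Conformity floor in percent (default 90).
#' @return data.frame(start, end, motif) with 0-based half-open intervals.
#' @export
detectMicrosatellite <- function(seq, motifLenRange = c(2L, 5L),
                                 minArrayBp = 20L, minConformity = 90) {
  .validateSeq(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  conf <- minConformity / 100
  res <- data.frame(start = integer(), end = integer(), motif = character(),
                    stringsAsFactors = FALSE)
  for (L in seq(motifLenRange[1L], motifLenRange[2L])) {
    if (n < L + 1L) break
    m <- ch[seq_len(n - L)] == ch[(L + 1L):n]
    m[ch[seq_len(n - L)] == "N" | ch[(L + 1L):n] == "N"] <- FALSE
    segs <- .maximalSegments(ifelse(m, 1 - conf, -conf))
    if (nrow(segs) == 0L) next
    for (r in seq_len(nrow(segs))) {
      a <- segs[r, "start"]; b <- segs[r, "end"]
      start0 <- a - 1L; end0 <- b + L
      if (end0 - start0 < minArrayBp) next
      if (100 * mean(m[a:b]) < minConformity) next
      # modal in-frame L-mer defines the motif
      starts <- seq(start0 + 1L, end0 - L + 1L, by = L)
      words <- substring(seq, starts, starts + L - 1L)
      motif <- names(sort(table(words), decreasing = TRUE))[1L]
      if (length(unique(strsplit(motif, "")[[1L]])) == 1L) next  # homopolymer
      if (nrow(res)) {                  # already explained at a shorter motif
        ov <- pmin(res$end, end0) - pmax(res$start, start0)
        if (any(ov > 0.5 * (end0 - start0))) next
      }
      res <- rbind(res, data.frame(start = start0, end = end0,
                                   motif = canonicalRotation(motif),
                                   stringsAsFactors = FALSE))
    }
  }
  res[order(res$start), , drop = FALSE]
}

# best acceptable panel hit per clone, batched over (entry, strand)
.panelAssignments <- function(seqs, panel, k = 11L, minScore = 30,
                              minLen = 50L, minIdentity = 70) {
  idx <- seedIndex(panelSeqs(panel), k = k)
  ids <- names(seqs)
  rcs <- revComp(seqs)
  # one bulk join: every clone k-mer (both strands) against the panel index
  mkTask <- function(strand) {
    src <- if (strand == "+") seqs else rcs
    kl <- lapply(src, .kmers, k = k)
    qdt <- data.table::data.table(
      kmer = unlist(kl, use.names = FALSE),
      ci = rep(seq_along(src), lengths(kl)))
    qdt <- unique(qdt)
    m <- idx$dt[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(m) == 0L) return(NULL)
    u <- unique(m[, c("ci", "tid")])
    data.frame(ci = u$ci, entry = u$tid, strand = strand,
               stringsAsFactors = FALSE)
  }
  tdf <- rbind(mkTask("+"), mkTask("-"))
  if (is.null(tdf) || nrow(tdf) == 0L)
    return(data.frame(clone_id = character(), entry = character(),
                      class = character(), identity = numeric(),
                      aligned_bp = integer(), score = numeric()))
  cls <- panelClasses(panel)
  entryOrder <- stats::setNames(seq_along(names(panel)), names(panel))
  out <- list()
  for (grp in split(seq_len(nrow(tdf)),
                    paste(tdf$entry, tdf$strand, sep = "\r"))) {
    entry <- tdf$entry[grp[1L]]
    strand <- tdf$strand[grp[1L]]
    ci <- tdf$ci[grp]
    pats <- if (strand == "+") seqs[ci] else rcs[ci]
    aln <- .pairAlign(DNAStringSet(pats),
                      DNAString(idx$targets[[entry]]), "local")
    sc <- score(aln)
    idn <- .alnIdentity(aln)
    ab <- Biostrings::end(pattern(aln)) - Biostrings::start(pattern(aln)) + 1L
    keep <- sc >= minScore & ab >= minLen & idn >= minIdentity
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      ci = ci[keep], entry = entry, class = unname(cls[entry]),
      identity = idn[keep], aligned_bp = ab[keep], score = sc[keep],
      strand = strand, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(clone_id = character(), entry = character(),
                      class = character(), identity = numeric(),
                      aligned_bp = integer(), score = numeric()))
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$ci, -hits$score, entryOrder[hits$entry]), ]
  best <- hits[!duplicated(hits$ci), ]
  best$clone_id <- ids[best$ci]
  best[, c("clone_id", "entry", "class", "identity", "aligned_bp", "score")]
}

#' Best panel hit for one clone
#'
#' Highest-scoring acceptable local alignment of the clone against all panel
#' entries (both strands); ties broken by panel order.
#'
#' @param clone A single DNA string (optionally named).
#' @param panel A \linkS4class{RepeatPanel}.
#' @param minScore,minLen,minIdentity Acceptance thresholds
#'   (see \code{\link{seededLocalAlign}}).
#' @return A one-row data.frame (entry, class, identity, aligned_bp, score)
#'   or NULL when no acceptable hit exists.
#' @export
bestPanelHit <- function(clone, panel, minScore = 30, minLen = 50L,
                         minIdentity = 70) {
  if (length(panel) == 0L) stop("empty panel")
  nm <- if (!is.null(names(clone))) names(clone)[1L] else "clone"
  res <- .panelAssignments(stats::setNames(unname(clone), nm), panel,
                           minScore = minScore, minLen = minLen,
                           minIdentity = minIdentity)
  if (nrow(res) == 0L) return(NULL)
  res[1L, c("entry", "class", "identity", "aligned_bp", "score")]
}

#' Classify every clone of a library
#'
#' Assigns each clone to one of the categories known_repeat, chloroplast,
#' telomere, microsatellite or novel, with precedence
#' known_repeat > chloroplast > telomere > microsatellite > novel (specific
#' homology beats generic motif content; among panel hits the
#' highest-scoring acceptable alignment decides, and an organellar-class
#' best hit yields category chloroplast).
#'
#' @param library A \linkS4class{CloneLibrary} (already length-filtered).
#' @param panel A \linkS4class{RepeatPanel}.
#' @param minScore,minLen,minIdentity Panel-hit acceptance thresholds.
#' @param telomereMinCopies Minimum telomere motif copies (default 3).
#' @return A list with \code{assignments} (data.frame clone_id, category,
#'   best_hit_name, identity_percent, aligned_bp) and \code{report}
#'   (a \linkS4class{CompositionReport} with per-family counts).
#' @export
classifyLibrary <- function(library, panel, minScore = 30, minLen = 50L,
                            minIdentity = 70, telomereMinCopies = 3L) {
  if (length(library) == 0L) stop("empty library")
  seqs <- stats::setNames(as.character(clones(library)), names(library))
  best <- if (length(panel) > 0L)
    .panelAssignments(seqs, panel, minScore = minScore, minLen = minLen,
                      minIdentity = minIdentity)
  else data.frame(clone_id = character(), entry = character(),
                  class = character(), identity = numeric(),
                  aligned_bp = integer(), score = numeric())
  category <- rep("novel", length(seqs))
  hitName <- rep(NA_character_, length(seqs))
  idn <- rep(NA_real_, length(seqs))
  ab <- rep(NA_integer_, length(seqs))
  mi <- match(names(seqs), best$clone_id)
  has <- !is.na(mi)
  category[has] <- ifelse(best$class[mi[has]] == "organellar",
                          "chloroplast", "known_repeat")
  hitName[has] <- best$entry[mi[has]]
  idn[has] <- best$identity[mi[has]]
  ab[has] <- best$aligned_bp[mi[has]]
  for (i in which(!has)) {
    tel <- detectTelomereMotif(seqs[[i]], minCopies = telomereMinCopies)
    if (!is.null(tel)) { category[i] <- "telomere"; next }
    ms <- detectMicrosatellite(seqs[[i]])
    if (nrow(ms)) category[i] <- "microsatellite"
  }
  assignments <- data.frame(
    clone_id = names(seqs), category = category, best_hit_name = hitName,
    identity_percent = idn, aligned_bp = ab, stringsAsFactors = FALSE)
  lev <- c("known_repeat", "chloroplast", "telomere", "microsatellite",
           "novel")
  counts <- vapply(lev, function(l) sum(category == l), 0L)
  report <- compositionPercentages(counts, length(seqs))
  known <- assignments[assignments$category %in%
                         c("known_repeat", "chloroplast"), ]
  if (nrow(known)) {
    ftab <- table(known$best_hit_name)
    report@families <- data.frame(
      family = names(ftab), count = as.integer(ftab),
      percent = percentHalfUp(as.numeric(ftab), length(seqs)),
      stringsAsFactors = FALSE)
  }
  list(assignments = assignments, report = report)
}
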