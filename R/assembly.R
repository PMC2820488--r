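# Greedy overlap-layout-consensus assembly of short clone reads. The overlap
# model is gapless suffix-prefix (substitutions only): candidate relative
# offsets come from shared k-mers, overlaps are scored by percent identity,
# and the best-overlapping pair (longer overlap first, then higher identity,
# then lexicographic id) is merged until no acceptable overlap remains.

#' Contig: an assembled consensus with its member reads
#' @slot id Contig identifier.
#' @slot consensus Consensus sequence (majority per column, ties
#'   alphabetical).
#' @slot members data.frame(clone_id, strand, offset): read placements on the
#'   consensus (0-based offsets; strand relative to the consensus).
#' @export
setClass("Contig",
         representation(id = "character", consensus = "character",
                        members = "data.frame"))

setValidity("Contig", function(object) {
  if (nrow(object@members) < 2L)
    return("a contig has at least 2 members; singletons are reported separately")
  TRUE
})

setMethod("show", "Contig", function(object) {
  cat(sprintf("Contig %s: %d bp, %d members\n", object@id,
              nchar(object@consensus), nrow(object@members)))
})

#' @export
setGeneric("contigConsensus", function(x) standardGeneric("contigConsensus"))
#' @export
setMethod("contigConsensus", "Contig", function(x) x@consensus)
#' @export
setGeneric("contigMembers", function(x) standardGeneric("contigMembers"))
#' @export
setMethod("contigMembers", "Contig", function(x) x@members)
#' @export
setMethod("length", "Contig", function(x) nchar(x@consensus))

.ALPHA_SORTED <- c("A", "C", "G", "N", "T")

# majority consensus of oriented member sequences placed at given offsets
.memberConsensus <- function(seqs, offsets, len) {
  votes <- matrix(0L, nrow = 5L, ncol = len,
                  dimnames = list(.ALPHA_SORTED, NULL))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
    idx <- (offsets[i] + 1L):(offsets[i] + length(ch))
    code <- match(ch, .ALPHA_SORTED)
    for (r in 1:5) {
      sel <- idx[code == r]
      if (length(sel)) votes[r, sel] <- votes[r, sel] + 1L
    }
  }
  paste(.ALPHA_SORTED[apply(votes, 2L, which.max)], collapse = "")
}

# cached per-unit overlap index: character vector, k-mer position maps for
# the forward and reverse-complement orientation
.unitInfo <- function(seq, k) {
  chr <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ak <- .kmers(seq, k)
  rseq <- revComp(seq)
  rk <- .kmers(rseq, k)
  list(seq = seq, chr = chr, len = nchar(seq),
       pos = split(seq_along(ak), ak),
       rchr = strsplit(rseq, "", fixed = TRUE)[[1L]],
       rpos = split(seq_along(rk), rk))
}

# best gapless overlap between units a and b (b possibly revcomp'ed):
# returns list(orient, d, ov, ident) or NULL. d = offset of b relative to a.
.bestOverlap <- function(ia, ib, minOv, minIdent, maxOffsets = 20L) {
  la <- ia$len
  best <- NULL
  for (orient in c("+", "-")) {
    bpos <- if (orient == "+") ib$pos else ib$rpos
    bchr <- if (orient == "+") ib$chr else ib$rchr
    lb <- ib$len
    common <- intersect(names(ia$pos), names(bpos))
    if (length(common) == 0L) next
    if (length(common) > 40L)           # highly repetitive pair: subsample
      common <- common[seq(1L, length(common), length.out = 40L)]
    ds <- integer(0)
    for (km in common)
      ds <- c(ds, as.vector(outer(ia$pos[[km]], bpos[[km]], `-`)))
    dt <- sort(table(ds), decreasing = TRUE)
    dvals <- as.integer(names(dt))[seq_len(min(length(dt), maxOffsets))]
    for (d in dvals) {
      sa <- max(0L, d); ea <- min(la, d + lb)
      ov <- ea - sa
      if (ov < minOv) next
      ai <- (sa + 1L):ea
      bi <- (sa - d + 1L):(ea - d)
      mm <- sum(ia$chr[ai] != bchr[bi] | ia$chr[ai] == "N")
      ident <- 100 * (1 - mm / ov)
      if (ident < minIdent) next
      if (is.null(best) || ov > best$ov ||
          (ov == best$ov && ident > best$ident))
        best <- list(orient = orient, d = d, ov = ov, ident = ident)
    }
  }
  best
}

#' Greedy overlap assembly of clone reads
#'
#' Iteratively merges the best-overlapping pair of sequences (suffix-prefix,
#' either strand, gapless) until no overlap of at least \code{minOverlapBp}
#' at \code{minOverlapIdentity} percent identity remains. The consensus is
#' the per-column majority over member reads (ties alphabetical); a contig's
#' orientation is anchored to its first member in input order. Deterministic
#' given the input order.
#'
#' @param x CloneLibrary, DNAStringSet or named character vector of reads.
#' @param minOverlapBp Minimum overlap length (default 30, >= 20 enforced).
#' @param minOverlapIdentity Minimum overlap identity in percent (default 90).
#' @param k Seed k-mer length for candidate overlap offsets.
#' @return list(contigs = list of \linkS4class{Contig}, singletons =
#'   character vector of unassembled read ids).
#' @export
greedyAssemble <- function(x, minOverlapBp = 30L, minOverlapIdentity = 90,
                           k = 12L) {
  stopifnot(minOverlapBp >= 20L)
  if (is(x, "CloneLibrary")) x <- clones(x)
  if (is(x, "DNAStringSet")) {
    nm <- names(x); x <- as.character(x); names(x) <- nm
  }
  n <- length(x)
  reads <- x
  if (n == 0L) return(list(contigs = list(), singletons = character(0)))
  units <- vector("list", n)
  for (i in seq_len(n))
    units[[i]] <- list(active = TRUE, seq = unname(reads[[i]]),
                       members = data.frame(clone_id = names(reads)[i],
                                            strand = "+", offset = 0L,
                                            stringsAsFactors = FALSE),
                       firstIdx = i,
                       label = names(reads)[i])
  infos <- lapply(units, function(u) .unitInfo(u$seq, k))
  shares <- function(i, j)
    any(names(infos[[i]]$pos) %in% names(infos[[j]]$pos)) ||
    any(names(infos[[i]]$pos) %in% names(infos[[j]]$rpos))
  ovl <- new.env(parent = emptyenv())   # "i_j" -> overlap or NULL
  evalPair <- function(i, j) {
    key <- paste0(i, "_", j)
    if (!shares(i, j)) { assign(key, NULL, envir = ovl); return(invisible()) }
    assign(key, .bestOverlap(infos[[i]], infos[[j]],
                             minOverlapBp, minOverlapIdentity), envir = ovl)
  }
  act <- function() which(vapply(units, `[[`, TRUE, "active"))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) evalPair(i, j)
  repeat {
    ids <- act()
    bestKey <- NULL; best <- NULL; bi <- bj <- 0L
    if (length(ids) > 1L) {
      for (ii in seq_len(length(ids) - 1L)) for (jj in (ii + 1L):length(ids)) {
        i <- ids[ii]; j <- ids[jj]
        o <- get0(paste0(i, "_", j), envir = ovl, ifnotfound = NULL)
        if (is.null(o)) next
        better <- FALSE
        if (is.null(best)) better <- TRUE
        else if (o$ov > best$ov) better <- TRUE
        else if (o$ov == best$ov && o$ident > best$ident) better <- TRUE
        else if (o$ov == best$ov && o$ident == best$ident &&
                 paste(units[[i]]$label, units[[j]]$label) <
                 paste(units[[bi]]$label, units[[bj]]$label)) better <- TRUE
        if (better) { best <- o; bi <- i; bj <- j }
      }
    }
    if (is.null(best)) break
    a <- units[[bi]]; b <- units[[bj]]
    bm <- b$members
    bSeqLen <- nchar(b$seq)
    if (best$orient == "-") {
      rl <- nchar(reads[bm$clone_id])
      bm$offset <- bSeqLen - (bm$offset + rl)
      bm$strand <- ifelse(bm$strand == "+", "-", "+")
    }
    d <- best$d
    shift <- max(0L, -d)
    am <- a$members
    am$offset <- am$offset + shift
    bm$offset <- bm$offset + d + shift
    members <- rbind(am, bm)
    newLen <- max(nchar(a$seq) + shift, d + shift + bSeqLen)
    oriented <- ifelse(members$strand == "+", reads[members$clone_id],
                       revComp(reads[members$clone_id]))
    cons <- .memberConsensus(oriented, members$offset, newLen)
    units[[bi]] <- list(active = TRUE, seq = cons, members = members,
                        firstIdx = min(a$firstIdx, b$firstIdx),
                        label = min(a$label, b$label))
    units[[bj]]$active <- FALSE
    infos[[bi]] <- .unitInfo(cons, k)
    for (j in act()) {
      if (j == bi) next
      i1 <- min(bi, j); j1 <- max(bi, j)
      evalPair(i1, j1)
    }
  }
  contigs <- list(); singles <- character(0)
  cnum <- 0L
  for (i in order(vapply(units, `[[`, 0L, "firstIdx"))) {
    u <- units[[i]]
    if (!u$active) next
    if (nrow(u$members) == 1L) {
      singles <- c(singles, u$members$clone_id)
      next
    }
    m <- u$members
    first <- m[which.min(match(m$clone_id, names(reads))), ]
    if (first$strand == "-") {          # anchor contig to its first member
      L <- nchar(u$seq)
      rl <- nchar(reads[m$clone_id])
      m$offset <- L - (m$offset + rl)
      m$strand <- ifelse(m$strand == "+", "-", "+")
      u$seq <- revComp(u$seq)
    }
    cnum <- cnum + 1L
    contigs[[cnum]] <- new("Contig", id = sprintf("contig%03d", cnum),
                           consensus = u$seq,
                           members = m[order(m$offset, m$clone_id), ])
  }
  list(contigs = contigs, singletons = singles)
}

#' Summary statistics of a contig set
#'
#' @param contigs List of \linkS4class{Contig} objects.
#' @return list(count, min_bp, max_bp, mean_bp) with the mean rounded to the
#'   nearest integer; all zeros for an empty set.
#' @export
contigSummary <- function(contigs) {
  if (length(contigs) == 0L)
    return(list(count = 0L, min_bp = 0L, max_bp = 0L, mean_bp = 0L))
  lens <- vapply(contigs, length, 0L)
  list(count = length(lens), min_bp = min(lens), max_bp = max(lens),
       mean_bp = as.integer(roundHalfUp(mean(lens), 0L)))
}
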