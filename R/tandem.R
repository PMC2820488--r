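# De novo tandem array detection: candidate periods from the distances
# between identical k-mers, verified by aligning the sequence against its own
# period-shifted copy; maximal high-conformity segments become arrays, with
# the smallest valid period winning.

# All maximal scoring subsequences (Ruzzo-Tompa) of a numeric score vector.
# Returns a matrix with columns start, end (1-based inclusive) and score.
.maximalSegments <- function(x) {
  n <- length(x)
  starts <- integer(0); ends <- integer(0)
  Ls <- numeric(0); Rs <- numeric(0)
  cum <- 0
  for (i in seq_len(n)) {
    s <- x[i]
    cum <- cum + s
    if (s <= 0) next
    cst <- i; cen <- i; cL <- cum - s; cR <- cum
    repeat {
      j <- 0L
      k <- length(Ls)
      while (k >= 1L) {                 # rightmost j with L_j < candidate L
        if (Ls[k] < cL) { j <- k; break }
        k <- k - 1L
      }
      if (j == 0L || Rs[j] >= cR) {
        starts <- c(starts, cst); ends <- c(ends, cen)
        Ls <- c(Ls, cL); Rs <- c(Rs, cR)
        break
      }
      # merge candidate into I_j and retry with the merged subsequence
      cst <- starts[j]; cL <- Ls[j]
      keep <- seq_len(j - 1L)
      starts <- starts[keep]; ends <- ends[keep]
      Ls <- Ls[keep]; Rs <- Rs[keep]
    }
  }
  cbind(start = starts, end = ends, score = Rs - Ls)
}

# candidate repeat periods from distances between successive identical k-mers
.candidatePeriods <- function(ch, k, maxPeriod) {
  n <- length(ch)
  if (n < k + 2L) return(integer(0))
  b <- match(ch, c("A", "C", "G", "T")) - 1L   # NA for N
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code + b[(1L + j):(m + j)] * 4^(k - 1L - j)
  ok <- !is.na(code)
  pos <- which(ok)
  grp <- split(pos, code[ok])
  d <- unlist(lapply(grp, function(p) if (length(p) > 1L) diff(p)), use.names = FALSE)
  d <- d[d >= 2L & d <= maxPeriod]
  if (length(d) == 0L) return(integer(0))
  tab <- table(d)
  cand <- as.integer(names(tab)[tab >= 2L])
  if (length(cand) == 0L) cand <- as.integer(names(tab))
  # sub-periods of a mutated array surface as multiples; add divisors
  divs <- unlist(lapply(cand, function(p) {
    dd <- seq_len(p %/% 2L)
    dd[dd >= 2L & p %% dd == 0L]
  }))
  sort(unique(c(cand, divs)))
}

#' Detect tandem arrays in a sequence
#'
#' Candidate periods are read from the histogram of distances between
#' identical k-mers (plus their divisors); each candidate period p is verified
#' by comparing the sequence with its own p-shifted copy, and maximal
#' segments whose conformity (percent agreement with the shifted self)
#' reaches the floor become arrays. Periods are tried smallest-first, so an
#' array is reported at the smallest period that explains it at the required
#' conformity; candidate arrays mostly covered by an accepted smaller-period
#' array are dropped.
#'
#' @param seq A DNA string.
#' @param seqId Identifier recorded in the annotations.
#' @param k Seed k-mer size for period discovery (default 5).
#' @param minCopy Minimum copy number (array length / period; default 2.5).
#' @param minArrayBp Minimum array length in bp (default 20).
#' @param maxPeriod Largest period considered (default 500).
#' @param minConformity Conformity floor in percent (default 80). This floor
#'   is what keeps higher-order monomers (e.g. a 30 bp unit built from
#'   degenerate 5 bp motifs) from being reported at their noisy sub-period.
#' @return A list of \linkS4class{TandemArray} objects, ordered by position.
#' @export
detectTandem <- function(seq, seqId = "seq", k = 5L, minCopy = 2.5,
                         minArrayBp = 20L, maxPeriod = 500L,
                         minConformity = 80) {
  .validateSeq(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cands <- .candidatePeriods(ch, k, min(maxPeriod, n %/% 2L))
  conf <- minConformity / 100
  acc <- list()
  accIv <- matrix(numeric(0), ncol = 2)
  for (p in cands) {
    if (n < p + 1L) next
    m <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    m[ch[seq_len(n - p)] == "N" | ch[(p + 1L):n] == "N"] <- FALSE
    segs <- .maximalSegments(ifelse(m, 1 - conf, -conf))
    if (nrow(segs) == 0L) next
    for (r in seq_len(nrow(segs))) {
      a <- unname(segs[r, "start"]); b <- unname(segs[r, "end"])
      start0 <- a - 1L
      end0 <- b + p
      len <- end0 - start0
      if (len < minArrayBp) next
      copies <- len / p
      if (copies < minCopy) next
      conform <- 100 * mean(m[a:b])
      if (conform < minConformity) next
      # skip if mostly covered by an accepted (smaller-period) array
      if (nrow(accIv)) {
        ov <- pmin(accIv[, 2], end0) - pmax(accIv[, 1], start0)
        if (any(ov > 0.5 * len)) next
      }
      dec <- decomposeMonomers(seq, c(start0, end0), p, phase = 0L)
      full <- dec$monomers[!dec$partial]
      cons <- if (length(full) >= 2L) canonicalConsensus(full) else
        canonicalRotation(full[1L])
      ta <- new("TandemArray", seqId = seqId, start = as.integer(start0),
                end = as.integer(end0), period = as.integer(p),
                phase = 0L, copyNumber = copies, monomers = dec$monomers,
                partial = dec$partial, consensus = cons,
                conformity = conform)
      acc[[length(acc) + 1L]] <- ta
      accIv <- rbind(accIv, c(start0, end0))
    }
  }
  if (length(acc) > 1L)
    acc <- acc[order(vapply(acc, function(x) x@start, 0L))]
  acc
}

#' Cut a tandem array into its monomers
#'
#' Cuts the array substring at phase, phase+period, ...; the first and last
#' monomers may be partial and are flagged. The concatenation of the returned
#' monomers reconstructs the array substring exactly.
#'
#' @param seq The carrying DNA string.
#' @param interval 0-based half-open c(start, end) within \code{seq}.
#' @param period Monomer period in bp (> 0).
#' @param phase Offset of the first full monomer within the array.
#' @return A list with \code{monomers} (character) and \code{partial}
#'   (logical).
#' @export
decomposeMonomers <- function(seq, interval, period, phase = 0L) {
  if (period <= 0L) stop("period must be positive")
  start0 <- interval[1L]; end0 <- interval[2L]
  if (start0 < 0L || end0 > nchar(seq) || end0 <= start0)
    stop("interval out of bounds")
  if (phase < 0L || phase >= period) stop("phase must be in [0, period)")
  arr <- substr(seq, start0 + 1L, end0)
  len <- nchar(arr)
  monomers <- character(0); partial <- logical(0)
  if (phase > 0L) {
    monomers <- substr(arr, 1L, phase)
    partial <- TRUE
  }
  pos <- phase
  while (pos + period <= len) {
    monomers <- c(monomers, substr(arr, pos + 1L, pos + period))
    partial <- c(partial, FALSE)
    pos <- pos + period
  }
  if (pos < len) {
    monomers <- c(monomers, substr(arr, pos + 1L, len))
    partial <- c(partial, TRUE)
  }
  list(monomers = monomers, partial = partial)
}

#' Lexicographically minimal rotation of a string
#'
#' Canonical form used for monomer consensi and microsatellite motifs, so
#' that the arbitrary start point of a tandem array does not change the
#' reported sequence.
#'
#' @param s A string.
#' @return The minimal rotation.
#' @export
canonicalRotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  rots <- substring(strrep(s, 2L), seq_len(n), seq_len(n) + n - 1L)
  min(rots)
}

#' Majority-rule consensus of full monomers, canonically rotated
#'
#' Per-column majority over full (equal-length) monomers, ties broken
#' alphabetically, then rotated to the lexicographically minimal rotation.
#'
#' @param monomers Character vector of at least 2 equal-length monomers.
#' @return The canonical consensus string.
#' @export
canonicalConsensus <- function(monomers) {
  if (length(monomers) < 2L) stop("need at least 2 full monomers")
  w <- unique(nchar(monomers))
  if (length(w) != 1L) stop("monomers must have equal length")
  mat <- do.call(rbind, strsplit(monomers, "", fixed = TRUE))
  cons <- apply(mat, 2L, function(col) {
    tab <- table(col)
    names(tab)[tab == max(tab)][1L]   # table() is alphabetical; first = min
  })
  canonicalRotation(paste(cons, collapse = ""))
}

#' Monomer sample statistics: G/C content and pairwise identity range
#'
#' Takes a (seeded) random sample of at most \code{sampleN} monomers, reports
#' G/C content over the concatenated sample and the minimum/maximum pairwise
#' \code{\link{globalIdentity}}.
#'
#' @param monomers Character vector of monomers (>= 2).
#' @param sampleN Sample size cap (default 20, the reporting convention).
#' @param seed RNG seed for the subsample (default 1763).
#' @return A list with \code{gcPercent}, \code{identityMin},
#'   \code{identityMax} and the \code{sample} used.
#' @export
monomerStats <- function(monomers, sampleN = 20L, seed = 1763L) {
  if (length(monomers) < 2L) stop("need at least 2 monomers")
  sel <- monomers
  if (length(monomers) > sampleN) {
    sel <- .withSeed(seed, sample(monomers, sampleN))
  }
  gc <- 100 * gcContent(paste(sel, collapse = ""))
  ids <- c()
  np <- length(sel)
  for (i in seq_len(np - 1L))
    for (j in (i + 1L):np)
      ids <- c(ids, globalIdentity(sel[i], sel[j]))
  list(gcPercent = gc, identityMin = min(ids), identityMax = max(ids),
       sample = sel)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv())
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Classify a tandem repeat family by monomer size
#'
#' Monomer sizes of 2-5 bp are microsatellites, 6-100 bp minisatellites and
#' anything larger a satellite.
#'
#' @param monomerSize Monomer size in bp (>= 2).
#' @return One of "microsatellite", "minisatellite", "satellite".
#' @export
classifyFamilySize <- function(monomerSize) {
  if (monomerSize < 2) stop("monomer size must be >= 2")
  if (monomerSize <= 5) "microsatellite"
  else if (monomerSize <= 100) "minisatellite"
  else "satellite"
}

# union-find
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# best (rotation, strand) of consensus 'a' against equal-length consensus
# 'b' by exhaustive hamming scan; returns list(identity, strand, rot)
.bestRotation <- function(a, b) {
  p <- nchar(a)
  bInt <- utf8ToInt(b)
  best <- list(identity = -1, strand = "+", rot = 0L)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") a else revComp(a)
    dInt <- utf8ToInt(strrep(s, 2L))
    for (r in 0:(p - 1L)) {
      d <- sum(dInt[(r + 1L):(r + p)] != bInt)
      idn <- 100 * (1 - d / p)
      if (idn > best$identity)
        best <- list(identity = idn, strand = strand, rot = r)
    }
  }
  best
}

# rotation/strand-tolerant identity with cheap fast paths: exact equality,
# then equal-length hamming rotation scan, then the alignment-based fallback
# (needed when periods differ)
.fastRotationIdentity <- function(a, b) {
  if (a == b) return(100)
  if (nchar(a) == nchar(b)) return(.bestRotation(a, b)$identity)
  rotationIdentity(a, b)
}

#' Group tandem arrays into repeat families
#'
#' Single-linkage clustering of tandem-bearing sequences by consensus
#' similarity: two arrays are linked when their consensi align at or above
#' the identity threshold under rotation- and strand-tolerant comparison.
#' Arrays whose periods differ by more than 30 percent are never linked
#' directly (variable-size families such as a 32-39 bp monomer range remain
#' linked through intermediate members).
#'
#' @param annotations List of \linkS4class{TandemArray} objects.
#' @param identityThreshold Linkage threshold in percent (default 70).
#' @return A list of \linkS4class{RepeatFamily} objects, ordered by modal
#'   monomer size. Family monomer size is the modal member period (reported
#'   as a range when member periods differ); cotHits counts distinct member
#'   sequences; the representative monomer is the consensus of the largest
#'   member array.
#' @export
clusterFamilies <- function(annotations, identityThreshold = 70) {
  if (length(annotations) == 0L) return(list())
  cons <- vapply(annotations, arrayConsensus, "")
  periods <- vapply(annotations, arrayPeriod, 0L)
  uCons <- unique(cons)
  uPer <- nchar(uCons)
  nu <- length(uCons)
  parent <- seq_len(nu)
  if (nu > 1L) {
    for (j in 2:nu) {
      gate <- seq_len(j - 1L)
      ratio <- pmax(uPer[gate] / uPer[j], uPer[j] / uPer[gate])
      gate <- gate[ratio <= 1.3]
      for (i in gate) {
        # an edge inside one component is redundant for single linkage
        ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
        if (ri == rj) next
        if (.fastRotationIdentity(uCons[i], uCons[j]) >= identityThreshold)
          parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(nu), function(i) .ufFind(parent, i), 0L)
  memberComp <- comp[match(cons, uCons)]
  fams <- list()
  for (cc in unique(memberComp)) {
    idx <- which(memberComp == cc)
    anns <- annotations[idx]
    pers <- periods[idx]
    tab <- table(pers)
    modal <- as.integer(names(tab)[which.max(tab)])
    label <- classifyFamilySize(modal)
    # largest member array supplies the representative monomer; monomers of
    # the other arrays are strand-oriented and re-phased to it before the
    # identity statistics (arrays are cut at arbitrary phase and strand, and
    # the aligned-monomer statistics assume a common register)
    lens <- vapply(anns, function(a) a@end - a@start, 0L)
    rep <- arrayConsensus(anns[[which.max(lens)]])
    monos <- unlist(lapply(anns, function(a) {
      full <- a@monomers[!a@partial]
      if (length(full) == 0L) return(character(0))
      cons <- arrayConsensus(a)
      if (nchar(cons) == nchar(rep)) {
        br <- .bestRotation(cons, rep)
        if (br$strand == "-") full <- revComp(full)
        if (br$rot > 0L) {
          p <- nchar(rep)
          full <- substr(strrep(full, 2L), br$rot + 1L, br$rot + p)
        }
      } else if (rotationIdentity(cons, rep, bothStrands = FALSE) <
                 rotationIdentity(revComp(cons), rep, bothStrands = FALSE)) {
        full <- revComp(full)
      }
      full
    }))
    st <- if (length(monos) >= 2L) monomerStats(monos) else
      list(gcPercent = 100 * gcContent(rep), identityMin = 100,
           identityMax = 100)
    fams[[length(fams) + 1L]] <- new(
      "RepeatFamily", name = "", memberIds = unique(vapply(anns, function(a) a@seqId, "")),
      periods = as.integer(sort(unique(pers))),
      cotHits = length(unique(vapply(anns, function(a) a@seqId, ""))),
      gcPercent = st$gcPercent, identityMin = st$identityMin,
      identityMax = st$identityMax, representative = rep, label = label)
  }
  ord <- order(vapply(fams, function(f) min(f@periods), 0L),
               -vapply(fams, function(f) f@cotHits, 0L))
  fams <- fams[ord]
  counters <- c(microsatellite = 0L, minisatellite = 0L, satellite = 0L)
  prefix <- c(microsatellite = "Micro", minisatellite = "MSat",
              satellite = "Sat")
  for (i in seq_along(fams)) {
    lb <- fams[[i]]@label
    counters[lb] <- counters[lb] + 1L
    fams[[i]]@name <- sprintf("%s%02d", prefix[[lb]], counters[[lb]])
  }
  fams
}
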