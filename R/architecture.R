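# Array architecture: higher-order repeat (HOR) structure of
# microsatellite-derived monomers, head-to-head junction detection via a
# per-monomer orientation track, conserved flank extraction, and an
# imperfect-palindrome scanner.

.hamming <- function(a, b) sum(a != b | a == "N")

# minimal hamming distance of window chars against all rotations of the
# (doubled) consensus chars; returns percent identity
.rotIdentChars <- function(w, cc2, p) {
  best <- p
  for (r in 0:(p - 1L)) {
    d <- .hamming(w, cc2[(r + 1L):(r + p)])
    if (d < best) best <- d
    if (best == 0L) break
  }
  100 * (1 - best / p)
}

#' Higher-order repeat structure of a microsatellite-derived array
#'
#' Decomposes the array into consecutive base-period units, labels units by
#' greedy clustering at up to one mismatch (degenerate variants of the base
#' motif receive distinct labels), and looks for the smallest repeating label
#' pattern. Returns NULL when the label alphabet is trivial (a pure
#' microsatellite), when the units do not recur (no tandem structure at the
#' base period), or when no label period reaches the required coverage.
#'
#' @param arraySeq The array sequence.
#' @param baseMotif Base motif of 2-10 bp (e.g. "GATCA").
#' @param minUnitConformity Minimum fraction of units belonging to a
#'   recurring unit variant (default 0.6).
#' @param patternCoverage Minimum fraction of unit positions agreeing with
#'   the label pattern at the reported period (default 0.8).
#' @return NULL, or a list with baseMotif, basePeriodBp, horPeriodUnits,
#'   horPeriodBp, unitPattern (modal unit sequence per pattern position),
#'   exactBaseCount (pattern positions identical to the base motif) and the
#'   per-unit labels.
#' @export
detectHOR <- function(arraySeq, baseMotif, minUnitConformity = 0.6,
                      patternCoverage = 0.8) {
  .validateSeq(arraySeq); .validateSeq(baseMotif, "baseMotif")
  p <- nchar(baseMotif)
  if (p < 2L || p > 10L) stop("base motif must be 2-10 bp")
  n <- nchar(arraySeq)
  nU <- n %/% p
  if (nU < 6L) return(NULL)
  starts <- seq(1L, by = p, length.out = nU)
  units <- substring(arraySeq, starts, starts + p - 1L)
  uchr <- strsplit(units, "", fixed = TRUE)
  exemplars <- list()
  labels <- integer(nU)
  for (i in seq_len(nU)) {
    hit <- 0L
    for (e in seq_along(exemplars)) {
      if (.hamming(uchr[[i]], exemplars[[e]]) <= 1L) { hit <- e; break }
    }
    if (hit == 0L) {
      exemplars[[length(exemplars) + 1L]] <- uchr[[i]]
      hit <- length(exemplars)
    }
    labels[i] <- hit
  }
  tab <- table(labels)
  recur <- sum(tab[tab >= 2L]) / nU
  if (recur < minUnitConformity) return(NULL)
  if (length(tab) == 1L) return(NULL)      # single-variant: plain microsatellite
  horU <- 0L
  for (u in 2:(nU %/% 3L)) {
    agree <- mean(labels[seq_len(nU - u)] == labels[(u + 1L):nU])
    if (agree >= patternCoverage) { horU <- u; break }
  }
  if (horU == 0L) return(NULL)
  pattern <- character(horU)
  for (r in seq_len(horU)) {
    sel <- units[seq(r, nU, by = horU)]
    pattern[r] <- names(sort(table(sel), decreasing = TRUE))[1L]
  }
  list(baseMotif = baseMotif, basePeriodBp = p, horPeriodUnits = horU,
       horPeriodBp = horU * p, unitPattern = pattern,
       exactBaseCount = sum(pattern == baseMotif), labels = labels)
}

#' Detect head-to-head / tail-to-tail junctions in a tandem array region
#'
#' Tiles the sequence with monomer-sized windows and assigns each window the
#' orientation (consensus vs its reverse complement) with the better
#' rotation-tolerant identity, requiring at least \code{minIdentity}.
#' Consecutive windows of equal orientation form blocks (at least
#' \code{minMonomers} monomers each); a junction is reported at every
#' orientation switch whose block gap is at most \code{maxGap} bp. Block
#' boundaries at the switch are refined to single-base resolution, so
#' \code{junction_pos} is the start of the first opposite-orientation
#' monomer (0-based).
#'
#' @param seq Sequence to scan.
#' @param consensus Monomer consensus from tandem detection.
#' @param minIdentity Orientation-call identity floor in percent (default 70).
#' @param maxGap Maximum unassigned gap between the two arrays in bp
#'   (default 60; accommodates a conserved spacer/flank at the junction).
#' @param minMonomers Minimum monomers per block (default 2).
#' @param seqId Identifier recorded in the result.
#' @return data.frame(sequence_id, junction_pos, left_start, left_end,
#'   right_start, right_end, left_orientation, right_orientation,
#'   junction_type); zero rows when no junction is found.
#' @export
detectInvertedJunction <- function(seq, consensus, minIdentity = 70,
                                   maxGap = 60L, minMonomers = 2L,
                                   seqId = "seq") {
  .validateSeq(seq); .validateSeq(consensus, "consensus")
  p <- nchar(consensus)
  n <- nchar(seq)
  empty <- data.frame(sequence_id = character(), junction_pos = integer(),
                      left_start = integer(), left_end = integer(),
                      right_start = integer(), right_end = integer(),
                      left_orientation = character(),
                      right_orientation = character(),
                      junction_type = character(), stringsAsFactors = FALSE)
  if (n < 2L * p * minMonomers) return(empty)
  cc2 <- strsplit(strrep(consensus, 2L), "", fixed = TRUE)[[1L]]
  rc2 <- strsplit(strrep(revComp(consensus), 2L), "", fixed = TRUE)[[1L]]
  chr <- strsplit(seq, "", fixed = TRUE)[[1L]]
  orientAt <- function(s0) {            # 0-based window start
    w <- chr[(s0 + 1L):(s0 + p)]
    f <- .rotIdentChars(w, cc2, p)
    r <- .rotIdentChars(w, rc2, p)
    if (f >= minIdentity && f >= r) "+"
    else if (r >= minIdentity && r > f) "-"
    else "."
  }
  starts <- seq(0L, n - p, by = p)
  ors <- vapply(starts, orientAt, "")
  # blocks of consecutive identical non-"." orientations
  blocks <- list()
  i <- 1L
  while (i <= length(ors)) {
    if (ors[i] == ".") { i <- i + 1L; next }
    j <- i
    while (j + 1L <= length(ors) && ors[j + 1L] == ors[i]) j <- j + 1L
    if (j - i + 1L >= minMonomers)
      blocks[[length(blocks) + 1L]] <-
        list(start = starts[i], end = starts[j] + p, orient = ors[i])
    i <- j + 1L
  }
  if (length(blocks) < 2L) return(empty)
  res <- empty
  for (bi in seq_len(length(blocks) - 1L)) {
    L <- blocks[[bi]]; R <- blocks[[bi + 1L]]
    if (L$orient == R$orient) next
    # refine boundaries at single-base resolution within the gap region:
    # the last left-orientation monomer is the one scoring best against the
    # left consensus (ties resolved away from the junction), and likewise
    # for the first right-orientation monomer. Chimeric windows straddling
    # the junction score strictly worse than in-register monomers.
    lo <- max(0L, L$end - p)
    hi <- min(n - p, R$start + p)
    scan <- seq(lo, hi)
    fL <- fR <- numeric(length(scan))
    for (si in seq_along(scan)) {
      w <- chr[(scan[si] + 1L):(scan[si] + p)]
      fL[si] <- .rotIdentChars(w, if (L$orient == "+") cc2 else rc2, p)
      fR[si] <- .rotIdentChars(w, if (R$orient == "+") cc2 else rc2, p)
    }
    le <- L$end
    if (any(fL >= minIdentity))
      le <- max(scan[fL == max(fL)]) + p
    rs <- R$start
    if (any(fR >= minIdentity))
      rs <- min(scan[fR == max(fR)])
    if (rs - le > maxGap) next
    res <- rbind(res, data.frame(
      sequence_id = seqId, junction_pos = rs,
      left_start = L$start, left_end = le, right_start = rs,
      right_end = R$end, left_orientation = L$orient,
      right_orientation = R$orient,
      junction_type = if (L$orient == "+") "head_to_head" else "tail_to_tail",
      stringsAsFactors = FALSE))
  }
  res
}

#' Extract and summarize a conserved flank motif over several loci
#'
#' Extracts \code{flankBp} of sequence on the given side of each locus
#' interval, builds the per-column majority consensus and reports the
#' pairwise identity range. Loci with insufficient flanking sequence are
#' excluded with a warning; at least two usable loci are required.
#'
#' @param loci data.frame with columns \code{seq}, \code{start}, \code{end}
#'   (0-based half-open array interval within \code{seq}).
#' @param side "left" or "right" of the interval.
#' @param flankBp Flank length in bp.
#' @return list(consensus, flanks, identityMin, identityMax, side).
#' @export
extractFlankMotif <- function(loci, side = c("left", "right"), flankBp) {
  side <- match.arg(side)
  flanks <- character(0)
  skipped <- character(0)
  for (i in seq_len(nrow(loci))) {
    s <- loci$seq[i]
    if (side == "left") {
      a <- loci$start[i] - flankBp
      if (a < 0L) { skipped <- c(skipped, as.character(i)); next }
      flanks <- c(flanks, substr(s, a + 1L, loci$start[i]))
    } else {
      b <- loci$end[i] + flankBp
      if (b > nchar(s)) { skipped <- c(skipped, as.character(i)); next }
      flanks <- c(flanks, substr(s, loci$end[i] + 1L, b))
    }
  }
  if (length(skipped))
    warning("excluded ", length(skipped), " locus/loci with <", flankBp,
            " bp of ", side, " flank: ", paste(skipped, collapse = ", "))
  if (length(flanks) < 2L) stop("need at least 2 usable loci")
  cons <- .memberConsensus(flanks, rep(0L, length(flanks)), flankBp)
  ids <- c()
  for (i in seq_len(length(flanks) - 1L))
    for (j in (i + 1L):length(flanks))
      ids <- c(ids, globalIdentity(flanks[i], flanks[j]))
  list(consensus = cons, flanks = flanks, identityMin = min(ids),
       identityMax = max(ids), side = side)
}

#' Find imperfect palindromes (inverted repeats with a short spacer)
#'
#' Scans all arm/spacer placements for intervals whose left arm matches the
#' reverse complement of the right arm within a per-arm mismatch budget of
#' \code{floor(maxMismatchFrac * armLength)}. For every axis (center and
#' spacer) the maximal valid arm is kept; hits sharing an axis (centers
#' within 2 bp) are merged to the highest-scoring one, while overlapping
#' hits with distinct axes are all reported.
#'
#' @param seq DNA string.
#' @param minArm Minimum arm length (default 6).
#' @param maxMismatchFrac Mismatch budget per arm as a fraction of the arm
#'   length (default 0.25).
#' @param maxSpacer Maximum unpaired spacer between the arms (default 5).
#' @return data.frame(start, end, arm_length, mismatches, spacer) with
#'   0-based half-open intervals, sorted by score (arm matches) descending.
#' @export
findImperfectPalindromes <- function(seq, minArm = 6L, maxMismatchFrac = 0.25,
                                     maxSpacer = 5L) {
  .validateSeq(seq)
  chr <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- chartr("ACGTN", "TGCAN", seq)
  cchr <- strsplit(comp, "", fixed = TRUE)[[1L]]
  n <- length(chr)
  hits <- data.frame(start = integer(), end = integer(),
                     arm_length = integer(), mismatches = integer(),
                     spacer = integer(), score = numeric(),
                     stringsAsFactors = FALSE)
  for (g in 0:maxSpacer) {
    for (c0 in seq_len(n)) {            # c0 = 0-based left-arm end position
      maxL <- min(c0, n - c0 - g)
      if (maxL < minArm) next
      mm <- 0L
      bestL <- 0L; bestMM <- 0L
      for (L in seq_len(maxL)) {
        lb <- chr[c0 - L + 1L]
        rb <- cchr[c0 + g + L]          # complement of right-arm base
        if (lb != rb || lb == "N") mm <- mm + 1L
        if (L >= minArm && mm <= floor(maxMismatchFrac * L)) {
          bestL <- L; bestMM <- mm
        }
      }
      if (bestL == 0L) next
      hits <- rbind(hits, data.frame(
        start = c0 - bestL, end = c0 + g + bestL, arm_length = bestL,
        mismatches = bestMM, spacer = g, score = bestL - bestMM,
        stringsAsFactors = FALSE))
    }
  }
  if (nrow(hits) == 0L) return(hits[, 1:5])
  hits$axis <- (hits$start + hits$end) / 2
  hits <- hits[order(-hits$score, hits$spacer, hits$start), ]
  keep <- logical(nrow(hits))
  axes <- numeric(0)
  for (i in seq_len(nrow(hits))) {
    if (length(axes) == 0L || all(abs(axes - hits$axis[i]) > 2)) {
      keep[i] <- TRUE
      axes <- c(axes, hits$axis[i])
    }
  }
  out <- hits[keep, c("start", "end", "arm_length", "mismatches", "spacer",
                      "score")]
  rownames(out) <- NULL
  out
}
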