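# Synthetic genome and c0t library simulator. A genome specification plants
# tandem repeat families (satellites, minisatellites, a microsatellite-derived
# higher-order family, a head-to-head family with a conserved palindromic
# flank), dispersed element families, an organellar-like block, telomere-like
# and microsatellite arrays into i.i.d. background sequence, and the sampler
# draws clones under second-order renaturation kinetics with retention
# probability increasing with copy number. Truth tables make every pipeline
# stage testable offline.

.randomSeq <- function(n, gc = 0.35) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# per-base substitutions at the given rate (always to a different base)
.mutateSeq <- function(s, rate) {
  if (rate <= 0) return(s)
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  i <- which(runif(length(ch)) < rate & ch != "N")
  if (length(i)) {
    code <- match(ch[i], c("A", "C", "G", "T")) - 1L
    ch[i] <- c("A", "C", "G", "T")[(code + sample(1:3, length(i),
                                                  replace = TRUE)) %% 4L + 1L]
  }
  paste(ch, collapse = "")
}

#' Specify a planted repeat family
#'
#' @param name Family name.
#' @param consensus Monomer (tandem), element (dispersed) or module
#'   (organellar) consensus sequence.
#' @param type One of "tandem", "dispersed", "organellar", "telomere",
#'   "microsatellite".
#' @param repeatClass Panel class tag (see \linkS4class{RepeatPanel}).
#' @param nArrays Number of arrays (tandem/telomere/microsatellite) or 1.
#' @param monomersPerArray c(min, max) monomers per array.
#' @param copies Element count for dispersed families.
#' @param mutationRate Per-base substitution rate applied to each copy
#'   (in [0, 0.3]).
#' @param headToHeadFraction Fraction of arrays built as an inverted pair
#'   (head-to-tail block + flank + reverse-complemented head-to-tail block).
#' @param flankMotif Conserved motif inserted at head-to-head junctions.
#' @param horPattern Ordered base-motif vector; when given, the monomer
#'   consensus is their concatenation (a higher-order repeat).
#' @param inPanel Whether the family is part of the known reference panel.
#' @return A classed list ("cotFamilySpec").
#' @export
familySpec <- function(name, consensus, type = "tandem",
                       repeatClass = "minisatellite", nArrays = 1L,
                       monomersPerArray = c(10L, 20L), copies = 0L,
                       mutationRate = 0.04, headToHeadFraction = 0,
                       flankMotif = NULL, horPattern = NULL,
                       inPanel = FALSE) {
  if (!is.null(horPattern)) consensus <- paste(horPattern, collapse = "")
  stopifnot(nchar(consensus) > 0, mutationRate >= 0, mutationRate <= 0.3,
            headToHeadFraction >= 0, headToHeadFraction <= 1)
  structure(list(name = name, consensus = consensus, type = type,
                 repeatClass = repeatClass, nArrays = as.integer(nArrays),
                 monomersPerArray = as.integer(monomersPerArray),
                 copies = as.integer(copies), mutationRate = mutationRate,
                 headToHeadFraction = headToHeadFraction,
                 flankMotif = flankMotif, horPattern = horPattern,
                 inPanel = inPanel),
            class = "cotFamilySpec")
}

#' Specify a synthetic genome
#'
#' @param genomeLengthBp Total genome length.
#' @param families List of \code{\link{familySpec}} objects.
#' @param backgroundGC G/C fraction of the background sequence.
#' @param seed RNG seed; the whole simulation is deterministic given it.
#' @return A classed list ("cotGenomeSpec").
#' @export
genomeSpec <- function(genomeLengthBp, families = list(),
                       backgroundGC = 0.35, seed = 1L) {
  stopifnot(genomeLengthBp > 0)
  structure(list(genomeLengthBp = as.integer(genomeLengthBp),
                 families = families, backgroundGC = backgroundGC,
                 seed = as.integer(seed)),
            class = "cotGenomeSpec")
}

# build the blocks (sequences + annotation) for one family spec
.familyBlocks <- function(fs) {
  blocks <- list()
  addBlock <- function(seq, orientation, nMono, junctionOff = NA_integer_,
                       flankOff = NA_integer_, flankLen = NA_integer_) {
    blocks[[length(blocks) + 1L]] <<- list(
      family = fs$name, type = fs$type, seq = seq,
      orientation = orientation, nMonomers = nMono,
      junctionOff = junctionOff, flankOff = flankOff, flankLen = flankLen)
  }
  if (fs$type == "dispersed") {
    for (i in seq_len(fs$copies)) {
      strand <- if (runif(1) < 0.5) "+" else "-"
      s <- .mutateSeq(fs$consensus, fs$mutationRate)
      addBlock(if (strand == "+") s else revComp(s), strand, 1L)
    }
  } else if (fs$type == "organellar") {
    s <- paste(vapply(seq_len(fs$copies), function(i)
      .mutateSeq(fs$consensus, fs$mutationRate), ""), collapse = "")
    addBlock(s, "+", fs$copies)
  } else {
    mono <- function() .mutateSeq(fs$consensus, fs$mutationRate)
    for (a in seq_len(fs$nArrays)) {
      nMono <- if (fs$monomersPerArray[1L] == fs$monomersPerArray[2L])
        fs$monomersPerArray[1L]
      else sample(fs$monomersPerArray[1L]:fs$monomersPerArray[2L], 1L)
      if (runif(1) < fs$headToHeadFraction && nMono >= 4L) {
        n1 <- nMono %/% 2L; n2 <- nMono - n1
        fwd <- paste(vapply(seq_len(n1), function(i) mono(), ""),
                     collapse = "")
        rev2 <- revComp(paste(vapply(seq_len(n2), function(i) mono(), ""),
                              collapse = ""))
        fl <- if (is.null(fs$flankMotif)) "" else fs$flankMotif
        addBlock(paste0(fwd, fl, rev2), "+", nMono,
                 junctionOff = nchar(fwd) + nchar(fl),
                 flankOff = if (nzchar(fl)) nchar(fwd) else NA_integer_,
                 flankLen = if (nzchar(fl)) nchar(fl) else NA_integer_)
      } else {
        s <- paste(vapply(seq_len(nMono), function(i) mono(), ""),
                   collapse = "")
        strand <- if (runif(1) < 0.5) "+" else "-"
        addBlock(if (strand == "+") s else revComp(s), strand, nMono)
      }
    }
  }
  blocks
}

#' Simulate a genome with planted repeat families
#'
#' Arrays are placed uniformly at random without overlap into i.i.d.
#' background sequence; monomer copies are mutated at the per-family rate;
#' head-to-head arrays are built as array + flank + reverse-complemented
#' array; higher-order families repeat their motif-unit concatenation.
#' Deterministic given the spec seed.
#'
#' @param spec A \code{\link{genomeSpec}}.
#' @return A \linkS4class{GenomeSimulation} whose truth tables record one
#'   row per planted array (0-based half-open intervals, orientation,
#'   junction and flank positions) and one row per family (consensus, class,
#'   monomer copies, planted bp).
#' @export
simulateGenome <- function(spec) {
  stopifnot(inherits(spec, "cotGenomeSpec"))
  .withSeed(spec$seed, {
    blocks <- list()
    for (fs in spec$families) blocks <- c(blocks, .familyBlocks(fs))
    lens <- vapply(blocks, function(b) nchar(b$seq), 0L)
    bg <- spec$genomeLengthBp - sum(lens)
    if (bg < 0)
      stop("planted content (", sum(lens), " bp) exceeds genome length (",
           spec$genomeLengthBp, " bp)")
    ord <- sample(length(blocks))
    blocks <- blocks[ord]
    lens <- lens[ord]
    nb <- length(blocks)
    gaps <- as.vector(stats::rmultinom(1L, bg, rep(1, nb + 1L)))
    bgSeq <- .randomSeq(bg, spec$backgroundGC)
    pieces <- character(2L * nb + 1L)
    starts <- integer(nb)
    pos <- 0L; bgPos <- 0L
    for (i in seq_len(nb)) {
      pieces[2L * i - 1L] <- substr(bgSeq, bgPos + 1L, bgPos + gaps[i])
      bgPos <- bgPos + gaps[i]
      pos <- pos + gaps[i]
      starts[i] <- pos
      pieces[2L * i] <- blocks[[i]]$seq
      pos <- pos + lens[i]
    }
    pieces[2L * nb + 1L] <- substr(bgSeq, bgPos + 1L, bg)
    genome <- paste(pieces, collapse = "")
    arrays <- data.frame(
      family = vapply(blocks, `[[`, "", "family"),
      type = vapply(blocks, `[[`, "", "type"),
      start = starts, end = starts + lens,
      orientation = vapply(blocks, `[[`, "", "orientation"),
      n_monomers = vapply(blocks, `[[`, 0L, "nMonomers"),
      junction_pos = starts + vapply(blocks, `[[`, NA_integer_, "junctionOff"),
      flank_start = starts + vapply(blocks, `[[`, NA_integer_, "flankOff"),
      flank_len = vapply(blocks, `[[`, NA_integer_, "flankLen"),
      stringsAsFactors = FALSE)
    fam <- do.call(rbind, lapply(spec$families, function(fs) {
      bp <- sum(arrays$end[arrays$family == fs$name] -
                  arrays$start[arrays$family == fs$name])
      monomerCopies <- if (fs$type == "dispersed") fs$copies
      else sum(arrays$n_monomers[arrays$family == fs$name])
      data.frame(family = fs$name, type = fs$type,
                 repeatClass = fs$repeatClass, consensus = fs$consensus,
                 monomer_bp = nchar(fs$consensus),
                 n_arrays = sum(arrays$family == fs$name),
                 total_bp = bp, monomer_copies = monomerCopies,
                 in_panel = fs$inPanel, stringsAsFactors = FALSE)
    }))
    if (is.null(fam))
      fam <- data.frame(family = character(), type = character(),
                        repeatClass = character(), consensus = character(),
                        monomer_bp = integer(), n_arrays = integer(),
                        total_bp = integer(), monomer_copies = integer(),
                        in_panel = logical(), stringsAsFactors = FALSE)
    gseq <- DNAStringSet(genome)
    names(gseq) <- "synthetic_genome"
    new("GenomeSimulation", genome = gseq, arrays = arrays,
        families = fam, spec = list(genomeLengthBp = spec$genomeLengthBp,
                                    backgroundGC = spec$backgroundGC,
                                    seed = spec$seed))
  })
}

#' Library retention probability under second-order renaturation kinetics
#'
#' The double-stranded (library-retained) fraction of a sequence with N
#' genomic copies at renaturation parameter C0t is
#' f = k N C0t / (1 + k N C0t): proportional to copy number when rare,
#' saturating at 1. Strictly increasing in N.
#'
#' @param copyNumber Copy number(s), >= 1.
#' @param kUnit Per-copy second-order rate constant (default 0.01, chosen so
#'   a 1000-copy family is >= 90 percent retained at C0t = 1).
#' @param c0t Renaturation parameter (default 1).
#' @return Retention probability in (0, 1).
#' @export
retentionProbability <- function(copyNumber, kUnit = 0.01, c0t = 1) {
  if (kUnit <= 0 || c0t <= 0) stop("kUnit and c0t must be positive")
  if (any(copyNumber < 1)) stop("copyNumber must be >= 1")
  x <- kUnit * copyNumber * c0t
  x / (1 + x)
}

#' c0t sampling model parameters
#'
#' @param c0t Renaturation parameter.
#' @param kUnit Per-copy rate constant.
#' @param insertRange c(min, max) insert length in bp.
#' @param minInsert Shortest insert retained after the library size filter.
#' @param nClones Library size to emit.
#' @return A classed list ("cotSamplingModel").
#' @export
cotSamplingModel <- function(c0t = 1, kUnit = 0.01,
                             insertRange = c(100L, 600L), minInsert = 50L,
                             nClones = 2000L) {
  stopifnot(c0t > 0, kUnit > 0, insertRange[1L] <= insertRange[2L])
  structure(list(c0t = c0t, kUnit = kUnit,
                 insertRange = as.integer(insertRange),
                 minInsert = as.integer(minInsert),
                 nClones = as.integer(nClones)),
            class = "cotSamplingModel")
}

# kinetic copy number per family: for tandem-array (and organellar) families
# the renaturation partner concentration of a fragment-sized locus is the
# family's genomic bp divided by the fragment scale; for dispersed elements
# it is the element count
.kineticCopies <- function(families, meanInsert) {
  ifelse(families$type == "dispersed", pmax(1, families$monomer_copies),
         pmax(1, families$total_bp / meanInsert))
}

#' Sample a c0t-style clone library from a simulated genome
#'
#' Fragments are drawn uniformly with lengths uniform over the insert range;
#' each fragment is retained with the \code{\link{retentionProbability}} of
#' its dominant family's kinetic copy number (background fragments have copy
#' number 1), where a family dominates a fragment when its planted arrays
#' cover at least half of the insert. Retained fragments shorter than the
#' minimum insert are discarded. Deterministic given the seed.
#'
#' @param sim A \linkS4class{GenomeSimulation}.
#' @param model A \code{\link{cotSamplingModel}}.
#' @param seed RNG seed.
#' @return list(library = \linkS4class{CloneLibrary}, truth = data.frame
#'   (clone_id, start, end, family), kinetics = per-family kinetic copy
#'   numbers used).
#' @export
simulateCotLibrary <- function(sim, model = cotSamplingModel(), seed = 1L) {
  G <- sum(width(simGenome(sim)))
  if (G < model$insertRange[2L]) stop("genome shorter than the longest insert")
  genome <- as.character(simGenome(sim))[[1L]]
  arr <- simArrays(sim)
  fam <- simFamilies(sim)
  meanInsert <- mean(model$insertRange)
  kin <- .kineticCopies(fam, meanInsert)
  names(kin) <- fam$family
  famRet <- retentionProbability(kin, model$kUnit, model$c0t)
  bgRet <- retentionProbability(1, model$kUnit, model$c0t)
  arrRanges <- IRanges(start = arr$start + 1L, end = arr$end)
  .withSeed(seed, {
    keptSeq <- character(0); keptStart <- integer(0)
    keptLen <- integer(0); keptFam <- character(0)
    totalDraws <- 0L
    while (length(keptSeq) < model$nClones) {
      m <- 4L * model$nClones
      totalDraws <- totalDraws + m
      len <- sample(model$insertRange[1L]:model$insertRange[2L], m,
                    replace = TRUE)
      start0 <- floor(runif(m) * (G - len)) # 0-based
      fr <- IRanges(start = start0 + 1L, width = len)
      ov <- findOverlaps(fr, arrRanges)
      ow <- width(pintersect(fr[queryHits(ov)], arrRanges[subjectHits(ov)]))
      dom <- rep("background", m)
      if (length(ov)) {
        odf <- data.frame(q = queryHits(ov), f = arr$family[subjectHits(ov)],
                          w = ow, stringsAsFactors = FALSE)
        agg <- aggregate(w ~ q + f, data = odf, FUN = sum)
        agg <- agg[order(agg$q, -agg$w), ]
        best <- agg[!duplicated(agg$q), ]
        sel <- best$w >= 0.5 * len[best$q]
        dom[best$q[sel]] <- best$f[sel]
      }
      p <- ifelse(dom == "background", bgRet, famRet[dom])
      keep <- rbinom(m, 1L, p) == 1L & len >= model$minInsert
      if (!any(keep)) next
      keptSeq <- c(keptSeq, substring(genome, start0[keep] + 1L,
                                      start0[keep] + len[keep]))
      keptStart <- c(keptStart, start0[keep])
      keptLen <- c(keptLen, len[keep])
      keptFam <- c(keptFam, dom[keep])
    }
    n <- model$nClones
    ids <- sprintf("clone_%05d", seq_len(n))
    seqs <- stats::setNames(keptSeq[seq_len(n)], ids)
    truth <- data.frame(clone_id = ids, start = keptStart[seq_len(n)],
                        end = keptStart[seq_len(n)] + keptLen[seq_len(n)],
                        family = keptFam[seq_len(n)],
                        stringsAsFactors = FALSE)
    list(library = CloneLibrary(seqs, name = "synthetic_cot1"),
         truth = truth, kinetics = kin, draws = totalDraws,
         retainedTotal = length(keptSeq))
  })
}

#' Sample a sparse genome record set (BAC-end-sequence style)
#'
#' Uniform fragments without any retention bias, used for abundance
#' estimation.
#'
#' @param sim A \linkS4class{GenomeSimulation}.
#' @param nRecords Number of records.
#' @param recordLen Record length in bp.
#' @param seed RNG seed.
#' @return list(records = named character vector, coverage = fraction of the
#'   genome covered).
#' @export
simulateGenomeSample <- function(sim, nRecords = 4000L, recordLen = 250L,
                                 seed = 1L) {
  G <- sum(width(simGenome(sim)))
  genome <- as.character(simGenome(sim))[[1L]]
  .withSeed(seed, {
    start0 <- floor(runif(nRecords) * (G - recordLen))
    recs <- stats::setNames(
      substring(genome, start0 + 1L, start0 + recordLen),
      sprintf("bes_%05d", seq_len(nRecords)))
    list(records = recs, coverage = nRecords * recordLen / G,
         starts = start0)
  })
}

#' Reference repeat panel of a simulation
#'
#' Panel entries for the families flagged \code{in_panel} in the simulation
#' (the "previously described" repeats), with their class tags.
#'
#' @param sim A \linkS4class{GenomeSimulation}.
#' @return A \linkS4class{RepeatPanel}.
#' @export
referencePanel <- function(sim) {
  fam <- simFamilies(sim)
  fam <- fam[fam$in_panel, ]
  if (nrow(fam) == 0L) stop("no panel families in this simulation")
  RepeatPanel(stats::setNames(fam$consensus, fam$family),
              repeatClass = fam$repeatClass)
}

#' Reference study-scale genome specification
#'
#' The default synthetic landscape used throughout the package's validation:
#' a 2 Mb genome, ~64 percent repetitive, carrying three known high-copy
#' satellites (centromeric-, intercalary- and subtelomeric-style), dispersed
#' retroelement-, MITE- and SINE-like families, a plastid-like organellar
#' block, telomere-like and microsatellite arrays, and twelve novel tandem
#' families: three satellites (130/173/325 bp monomers, the first G/C-rich)
#' and nine minisatellites (10-96 bp) including a microsatellite-derived
#' higher-order family (GAAAA-AATAA-GTTCA + 3x GATCA) and a head-to-head
#' family with a conserved palindromic 51 bp flank. Family footprints span
#' about a ninefold range so that library frequencies resolve their
#' abundance ranking.
#'
#' @param seed Seed controlling both the random consensus sequences and the
#'   genome assembly.
#' @return A \code{\link{genomeSpec}}.
#' @export
referenceCotSpec <- function(seed = 1L) {
  consensi <- .withSeed(seed + 7919L, {
    list(ksatA = .randomSeq(160, 0.32), ksatB = .randomSeq(170, 0.38),
         ksatC = .randomSeq(330, 0.35), retro = .randomSeq(1500, 0.42),
         mite = .randomSeq(100, 0.38), sine = .randomSeq(120, 0.45),
         chloro = .randomSeq(2000, 0.37),
         nsat1 = .randomSeq(130, 0.60), nsat2 = .randomSeq(173, 0.33),
         nsat3 = .randomSeq(325, 0.45), nm1 = .randomSeq(10, 0.30),
         nm2 = .randomSeq(15, 0.33), nm3 = .randomSeq(21, 0.29),
         nm5 = .randomSeq(32, 0.48), nm6 = .randomSeq(40, 0.33),
         nm7 = .randomSeq(51, 0.24), nm8 = .randomSeq(96, 0.41),
         nm9 = .randomSeq(60, 0.30))
  })
  h2hFlank <- "GTCGTCCGACCAAAGATTATGGTCGGACGAGTCCGACACAATACGTTCTCT"
  fams <- list(
    familySpec("KSatA", consensi$ksatA, "tandem", "satellite", nArrays = 6,
               monomersPerArray = c(220, 280), mutationRate = 0.03,
               inPanel = TRUE),
    familySpec("KSatB", consensi$ksatB, "tandem", "satellite", nArrays = 5,
               monomersPerArray = c(150, 200), mutationRate = 0.03,
               inPanel = TRUE),
    familySpec("KSatC", consensi$ksatC, "tandem", "satellite", nArrays = 4,
               monomersPerArray = c(60, 90), mutationRate = 0.03,
               inPanel = TRUE),
    familySpec("RetroLTR", consensi$retro, "dispersed", "retroelement",
               copies = 50, mutationRate = 0.05, inPanel = TRUE),
    familySpec("MITE1", consensi$mite, "dispersed", "MITE", copies = 800,
               mutationRate = 0.05, inPanel = TRUE),
    familySpec("SINE1", consensi$sine, "dispersed", "retroelement",
               copies = 500, mutationRate = 0.05, inPanel = TRUE),
    familySpec("Chloro", consensi$chloro, "organellar", "organellar",
               copies = 40, mutationRate = 0.01, inPanel = TRUE),
    familySpec("Telo", "TTTAGGG", "telomere", "telomere", nArrays = 4,
               monomersPerArray = c(25, 35), mutationRate = 0.01),
    familySpec("MicroAG", "AG", "microsatellite", "microsatellite",
               nArrays = 3, monomersPerArray = c(25, 35),
               mutationRate = 0.01),
    familySpec("MicroGATCA", "GATCA", "microsatellite", "microsatellite",
               nArrays = 2, monomersPerArray = c(10, 14),
               mutationRate = 0.01),
    familySpec("NSat1", consensi$nsat1, "tandem", "satellite", nArrays = 9,
               monomersPerArray = c(65, 90)),
    familySpec("NSat2", consensi$nsat2, "tandem", "satellite", nArrays = 7,
               monomersPerArray = c(50, 70)),
    familySpec("NSat3", consensi$nsat3, "tandem", "satellite", nArrays = 6,
               monomersPerArray = c(25, 35)),
    familySpec("NM8", consensi$nm8, "tandem", "minisatellite", nArrays = 49,
               monomersPerArray = c(8, 12)),
    familySpec("NM9", consensi$nm9, "tandem", "minisatellite", nArrays = 42,
               monomersPerArray = c(13, 19)),
    familySpec("NM7", consensi$nm7, "tandem", "minisatellite", nArrays = 37,
               monomersPerArray = c(15, 21)),
    familySpec("NM6", consensi$nm6, "tandem", "minisatellite", nArrays = 37,
               monomersPerArray = c(17, 23)),
    familySpec("NM5", consensi$nm5, "tandem", "minisatellite", nArrays = 42,
               monomersPerArray = c(17, 23)),
    familySpec("NM4", NULL, "tandem", "minisatellite", nArrays = 34,
               monomersPerArray = c(21, 27), mutationRate = 0.02,
               horPattern = c("GAAAA", "AATAA", "GTTCA", "GATCA", "GATCA",
                              "GATCA")),
    familySpec("NM3", consensi$nm3, "tandem", "minisatellite", nArrays = 30,
               monomersPerArray = c(32, 40), headToHeadFraction = 0.5,
               flankMotif = h2hFlank),
    familySpec("NM2", consensi$nm2, "tandem", "minisatellite", nArrays = 33,
               monomersPerArray = c(38, 46)),
    familySpec("NM1", consensi$nm1, "tandem", "minisatellite", nArrays = 40,
               monomersPerArray = c(45, 55)))
  genomeSpec(2e6, fams, backgroundGC = 0.35, seed = seed)
}

#' Compare pipeline output with the planted truth
#'
#' A planted novel tandem family counts as recovered when some reported
#' family's representative monomer aligns to the planted consensus at
#' >= 80 percent rotation/strand-tolerant identity. The abundance rank
#' correlation is Spearman's rho between planted kinetic copy numbers and
#' truth-labeled library clone counts over the tandem-array and organellar
#' families (dispersed short elements rarely dominate an insert and are
#' excluded). When a genome sample is supplied, copy numbers of dispersed
#' families with >= 100 copies are re-estimated from record hit counts.
#'
#' @param reportedFamilies List of \linkS4class{RepeatFamily} from the
#'   pipeline.
#' @param sim The \linkS4class{GenomeSimulation}.
#' @param cloneTruth Truth data.frame from \code{\link{simulateCotLibrary}}.
#' @param sample Optional result of \code{\link{simulateGenomeSample}}.
#' @param model Sampling model (for the kinetic copy numbers).
#' @return list(recall, precision, nPlanted, nRecovered, perFamily,
#'   rankCorrelation, copyEstimates).
#' @export
evaluateRecovery <- function(reportedFamilies, sim, cloneTruth = NULL,
                             sample = NULL, model = cotSamplingModel()) {
  fam <- simFamilies(sim)
  if (nrow(fam) == 0L) stop("empty truth")
  novel <- fam[fam$type == "tandem" & !fam$in_panel, ]
  reps <- vapply(reportedFamilies, familyRepresentative, "")
  recovered <- logical(nrow(novel))
  matched <- logical(length(reps))
  for (i in seq_len(nrow(novel))) {
    if (length(reps) == 0L) break
    # only periods within 30 percent are comparable: a short monomer aligned
    # inside a much longer consensus is a motif match, not a family match
    ratio <- pmax(nchar(reps) / novel$monomer_bp[i],
                  novel$monomer_bp[i] / nchar(reps))
    ids <- rep(0, length(reps))
    ids[ratio <= 1.3] <- vapply(reps[ratio <= 1.3], function(r)
      rotationIdentity(r, novel$consensus[i]), 0)
    recovered[i] <- any(ids >= 80)
    matched[ids >= 80] <- TRUE
  }
  rankCor <- NA_real_
  if (!is.null(cloneTruth)) {
    sel <- fam$type %in% c("tandem", "organellar")
    kin <- .kineticCopies(fam, mean(model$insertRange))
    counts <- vapply(fam$family, function(f)
      sum(cloneTruth$family == f), 0L)
    rankCor <- stats::cor(kin[sel], counts[sel], method = "spearman")
  }
  copyEst <- NULL
  if (!is.null(sample)) {
    disp <- fam[fam$type == "dispersed" & fam$monomer_copies >= 100L, ]
    if (nrow(disp)) {
      idx <- seedIndex(sample$records)
      hits <- vapply(seq_len(nrow(disp)), function(i)
        countHits(disp$consensus[i], sample$records, index = idx), 0L)
      copyEst <- data.frame(
        family = disp$family, planted = disp$monomer_copies, hits = hits,
        estimated = estimateCopies(hits, sample$coverage),
        stringsAsFactors = FALSE)
      copyEst$ratio <- copyEst$estimated / copyEst$planted
    }
  }
  list(recall = mean(recovered), precision = if (length(reps))
    mean(matched) else NA_real_, nPlanted = nrow(novel),
    nRecovered = sum(recovered),
    perFamily = data.frame(family = novel$family, recovered = recovered,
                           stringsAsFactors = FALSE),
    rankCorrelation = rankCor, copyEstimates = copyEst)
}
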