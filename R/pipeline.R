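# End-to-end pipeline: classify -> tandem-detect novel clones -> group
# families -> assemble the non-tandem remainder -> array architecture ->
# abundance, with fixed-schema TSV reports. Tandem families are built from
# unassembled clones so that per-clone family hit counts match the
# library-hit convention of the family table.

#' Write the family table (Table-style) as TSV
#'
#' Columns: name, size_bp (single size or "a-b" range), cot_hits,
#' gc_percent, identity_range ("min - max"), representative_monomer.
#'
#' @param families List of \linkS4class{RepeatFamily}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFamilyTable <- function(families, path) {
  rows <- lapply(families, function(f) {
    pr <- range(f@periods)
    data.frame(
      name = f@name,
      size_bp = if (pr[1] == pr[2]) as.character(pr[1]) else
        paste0(pr[1], "-", pr[2]),
      cot_hits = f@cotHits,
      gc_percent = roundHalfUp(f@gcPercent, 0L),
      identity_range = paste(roundHalfUp(f@identityMin, 0L), "-",
                             roundHalfUp(f@identityMax, 0L)),
      representative_monomer = f@representative,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(), size_bp = character(),
               cot_hits = integer(), gc_percent = numeric(),
               identity_range = character(),
               representative_monomer = character())
  .writeTsv(df, path)
}

#' Write the composition report as TSV
#'
#' One row per category and (when present) per known repeat family, with
#' count and percent (one decimal, half-up). The category counts are
#' validated against the clone total before writing.
#'
#' @param report A \linkS4class{CompositionReport}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeCompositionReport <- function(report, path) {
  validObject(report)
  cats <- report@categories
  cats$family <- ""
  cats <- cats[, c("category", "family", "count", "percent")]
  if (nrow(report@families)) {
    fams <- data.frame(category = "known_family",
                       family = report@families$family,
                       count = report@families$count,
                       percent = report@families$percent,
                       stringsAsFactors = FALSE)
    cats <- rbind(cats, fams)
  }
  .writeTsv(cats, path)
}

#' Write tandem array annotations as GFF-like TSV
#' @param annotations List of \linkS4class{TandemArray}.
#' @param path Output path.
#' @export
writeTandemTable <- function(annotations, path) {
  df <- if (length(annotations)) do.call(rbind, lapply(annotations, function(a)
    data.frame(sequence_id = a@seqId, start = a@start, end = a@end,
               period = a@period, copies = round(a@copyNumber, 2),
               conformity = round(a@conformity, 1), consensus = a@consensus,
               stringsAsFactors = FALSE)))
  else data.frame(sequence_id = character(), start = integer(),
                  end = integer(), period = integer(), copies = numeric(),
                  conformity = numeric(), consensus = character())
  .writeTsv(df, path)
}

#' Write an abundance table as TSV
#' @param tab data.frame from \code{\link{abundanceTable}}.
#' @param path Output path.
#' @export
writeAbundanceTable <- function(tab, path) .writeTsv(tab, path)

# architecture scan of one repeat family over its member clones
.familyArchitecture <- function(fam, seqs) {
  consensus <- familyRepresentative(fam)
  p <- nchar(consensus)
  hor <- NULL
  longest <- seqs[[which.max(nchar(seqs))]]
  for (d in 2:10) {
    if (p %% d != 0L || p == d) next
    frames <- seq(1L, nchar(consensus), by = d)
    units <- table(substring(consensus, frames, frames + d - 1L))
    base <- names(sort(units, decreasing = TRUE))[1L]
    # a genuine microsatellite-derived monomer is dominated by its base
    # motif; a mere divisor decomposition is not
    if (max(units) / sum(units) < 1 / 3) next
    h <- detectHOR(longest, base)
    if (!is.null(h) && h$exactBaseCount >= 1L) { hor <- h; break }
  }
  juncs <- list()
  for (id in names(seqs)) {
    j <- detectInvertedJunction(seqs[[id]], consensus, seqId = id)
    if (nrow(j)) juncs[[length(juncs) + 1L]] <- j
  }
  juncs <- if (length(juncs)) do.call(rbind, juncs) else NULL
  flank <- NULL; palindromes <- NULL
  if (!is.null(juncs)) {
    gaps <- juncs$right_start - juncs$left_end
    usable <- which(gaps >= 20)
    if (length(usable) >= 2L) {
      fb <- min(gaps[usable])
      loci <- data.frame(seq = unname(vapply(juncs$sequence_id[usable],
                                             function(i) seqs[[i]], "")),
                         start = juncs$junction_pos[usable],
                         end = juncs$junction_pos[usable])
      flank <- tryCatch(
        suppressWarnings(extractFlankMotif(loci, "left", fb)),
        error = function(e) NULL)
      if (!is.null(flank))
        palindromes <- findImperfectPalindromes(flank$consensus)
    }
  }
  list(family = familyName(fam), hor = hor, junctions = juncs,
       flank = flank, palindromes = palindromes)
}

#' Run the full c0t library characterization pipeline
#'
#' Length-filters the library, classifies all clones against the panel,
#' detects tandem arrays in the novel fraction and groups them into repeat
#' families, assembles the remaining (non-tandem) novel clones into contigs,
#' characterizes family array architecture (higher-order structure,
#' head-to-head junctions, conserved flanks and their palindromes) and, when
#' a genome sample is supplied, estimates genomic abundance. Writes the
#' composition report, per-clone assignments, tandem annotations, family
#' table, contig summary and membership, architecture report, abundance
#' table and a parameter log to \code{outDir}. Deterministic given the
#' inputs and seed.
#'
#' @param library CloneLibrary or FASTA path.
#' @param panel RepeatPanel or panel FASTA path.
#' @param outDir Output directory (created if needed).
#' @param sampleSet Optional genome-sample records (named character vector,
#'   DNAStringSet or FASTA path) for abundance estimation.
#' @param coverageFraction Fraction of the genome covered by
#'   \code{sampleSet}.
#' @param minInsert Minimum insert length retained (default 50).
#' @param minScore,minLen,minIdentity Panel/abundance acceptance thresholds.
#' @param clusterIdentity Family-linkage identity threshold (default 70).
#' @param seed Seed for the monomer sampling statistics.
#' @return Invisibly, a list with the classification, families, contigs,
#'   architecture and abundance results plus the written file paths.
#' @export
runPipeline <- function(library, panel, outDir, sampleSet = NULL,
                        coverageFraction = NULL, minInsert = 50L,
                        minScore = 30, minLen = 50L, minIdentity = 70,
                        clusterIdentity = 70, seed = 1763L) {
  if (is.character(library)) {
    if (!file.exists(library)) stop("library FASTA not found: ", library)
  }
  if (is.character(panel)) {
    if (!file.exists(panel)) stop("panel FASTA not found: ", panel)
  }
  if (is.character(sampleSet) && length(sampleSet) == 1L &&
      file.exists(sampleSet))
    sampleSet <- clones(readFastaLibrary(sampleSet))
  if (is.character(library)) library <- readFastaLibrary(library)
  if (is.character(panel)) panel <- readRepeatPanel(panel)
  if (is(sampleSet, "DNAStringSet")) {
    nm <- names(sampleSet); sampleSet <- as.character(sampleSet)
    names(sampleSet) <- nm
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  lib <- filterMinLength(library, minInsert)
  cls <- classifyLibrary(lib, panel, minScore = minScore, minLen = minLen,
                         minIdentity = minIdentity)
  paths$composition <- file.path(outDir, "composition_report.tsv")
  writeCompositionReport(cls$report, paths$composition)
  paths$assignments <- file.path(outDir, "clone_assignments.tsv")
  .writeTsv(cls$assignments, paths$assignments)

  # tandem scan covers the novel fraction plus microsatellite-bearing
  # clones: minisatellites derived from a microsatellite motif (higher-order
  # arrays) live in the microsatellite category
  novelIds <- cls$assignments$clone_id[cls$assignments$category %in%
                                         c("novel", "microsatellite")]
  seqs <- stats::setNames(as.character(clones(lib)), names(lib))
  annotations <- list()
  for (id in novelIds) {
    ann <- detectTandem(seqs[[id]], seqId = id)
    annotations <- c(annotations, ann)
  }
  paths$tandem <- file.path(outDir, "tandem_arrays.tsv")
  writeTandemTable(annotations, paths$tandem)
  families <- clusterFamilies(annotations,
                              identityThreshold = clusterIdentity)
  paths$families <- file.path(outDir, "family_table.tsv")
  writeFamilyTable(families, paths$families)

  tandemIds <- unique(vapply(annotations, function(a) a@seqId, ""))
  asmIds <- setdiff(novelIds, tandemIds)
  asm <- greedyAssemble(seqs[asmIds])
  paths$contigs <- file.path(outDir, "contigs.fasta")
  if (length(asm$contigs)) {
    writeFastaLibrary(stats::setNames(
      vapply(asm$contigs, contigConsensus, ""),
      vapply(asm$contigs, function(ct) ct@id, "")), paths$contigs)
  } else writeLines(character(0), paths$contigs)
  paths$contigMembers <- file.path(outDir, "contig_members.tsv")
  mdf <- if (length(asm$contigs)) do.call(rbind, lapply(asm$contigs,
    function(ct) cbind(contig_id = ct@id, contigMembers(ct))))
  else data.frame(contig_id = character(), clone_id = character(),
                  strand = character(), offset = integer())
  .writeTsv(mdf, paths$contigMembers)
  cs <- contigSummary(asm$contigs)
  paths$contigSummary <- file.path(outDir, "contig_summary.tsv")
  .writeTsv(data.frame(count = cs$count, min_bp = cs$min_bp,
                       max_bp = cs$max_bp, mean_bp = cs$mean_bp),
            paths$contigSummary)

  arch <- list()
  for (f in families) {
    mem <- seqs[familyMembers(f)]
    arch[[familyName(f)]] <- .familyArchitecture(f, mem)
  }
  archRows <- lapply(arch, function(a) data.frame(
    family = a$family,
    hor_base = if (!is.null(a$hor)) a$hor$baseMotif else "",
    hor_period_units = if (!is.null(a$hor)) a$hor$horPeriodUnits else NA,
    hor_period_bp = if (!is.null(a$hor)) a$hor$horPeriodBp else NA,
    hor_exact_base = if (!is.null(a$hor)) a$hor$exactBaseCount else NA,
    n_junctions = if (!is.null(a$junctions)) nrow(a$junctions) else 0L,
    flank_consensus = if (!is.null(a$flank)) a$flank$consensus else "",
    n_flank_palindromes = if (!is.null(a$palindromes))
      nrow(a$palindromes) else NA,
    stringsAsFactors = FALSE))
  paths$architecture <- file.path(outDir, "architecture_report.tsv")
  .writeTsv(do.call(rbind, c(archRows, list(make.row.names = FALSE))),
            paths$architecture)

  abundance <- NULL
  if (!is.null(sampleSet) && length(families)) {
    if (is.null(coverageFraction))
      stop("coverageFraction is required with a sample set")
    # query with the clone carrying each family's largest array (the
    # library-sequence-vs-genome-sample convention); a bare short monomer
    # could not reach the minimum acceptable alignment length
    repClone <- vapply(families, function(f) {
      mem <- familyMembers(f)
      best <- ""; bl <- -1L
      for (a in annotations) {
        if (!(a@seqId %in% mem)) next
        l <- a@end - a@start
        if (l > bl) { bl <- l; best <- a@seqId }
      }
      best
    }, "")
    reps <- stats::setNames(unname(seqs[repClone]),
                            vapply(families, familyName, ""))
    abundance <- abundanceTable(reps, sampleSet, coverageFraction,
                                minScore = minScore, minLen = minLen,
                                minIdentity = minIdentity)
    paths$abundance <- file.path(outDir, "abundance_table.tsv")
    writeAbundanceTable(abundance, paths$abundance)
  }

  paths$log <- file.path(outDir, "run_log.txt")
  writeLines(c(
    sprintf("cotrep pipeline"),
    sprintf("library=%s clones=%d bases=%d", libraryName(lib), length(lib),
            totalBases(lib)),
    sprintf("panel_entries=%d", length(panel)),
    sprintf("minInsert=%d minScore=%g minLen=%d minIdentity=%g", minInsert,
            minScore, minLen, minIdentity),
    sprintf("clusterIdentity=%g seed=%d", clusterIdentity, seed),
    sprintf("sample_records=%d coverage=%s",
            if (is.null(sampleSet)) 0L else length(sampleSet),
            if (is.null(coverageFraction)) "NA" else
              format(coverageFraction)),
    sprintf("novel=%d tandem_bearing=%d families=%d contigs=%d",
            length(novelIds), length(tandemIds), length(families),
            cs$count)), paths$log)

  invisible(list(classification = cls, annotations = annotations,
                 families = families, assembly = asm, architecture = arch,
                 abundance = abundance, paths = paths))
}
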