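# Independent brute-force oracles and fixture builders. These deliberately
# avoid the package's own code paths (and Biostrings' aligner): expected
# values asserted against them are computed by enumeration.

randSeq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutSeq <- function(s, rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  i <- which(runif(length(ch)) < rate)
  for (j in i) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
  paste(ch, collapse = "")
}

# quadratic Smith-Waterman top score: match +1, mismatch -1, linear gap -2,
# N matches nothing
bruteLocalScore <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  prev <- numeric(m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j] && A[i] != "N") 1 else -1
      cur[j + 1L] <- max(0, prev[j] + s, prev[j + 1L] - 2, cur[j] - 2)
    }
    best <- max(best, max(cur))
    prev <- cur
  }
  best
}

# smallest period p (2..n/2) whose shifted-self identity over the whole
# string reaches minConformity percent
bruteSmallestPeriod <- function(s, minConformity = 80) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  for (p in 2:(n %/% 2L)) {
    conf <- 100 * mean(ch[seq_len(n - p)] == ch[(p + 1L):n])
    if (conf >= minConformity) return(p)
  }
  NA_integer_
}

# enumerate all valid imperfect palindromes (start, end, armLen, mismatches,
# spacer), 0-based half-open, by scanning every (left-arm end, spacer, arm)
brutePalindromes <- function(s, minArm = 6L, frac = 0.25, maxSpacer = 5L) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  cm <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  n <- length(ch)
  out <- list()
  for (g in 0:maxSpacer) for (c0 in seq_len(n)) {
    maxL <- min(c0, n - c0 - g)
    if (maxL < minArm) next
    for (L in minArm:maxL) {
      lhs <- ch[(c0 - L + 1L):c0]
      rhs <- rev(vapply(ch[(c0 + g + 1L):(c0 + g + L)],
                        function(x) cm[[x]], ""))
      mm <- sum(lhs != rhs)
      if (mm <= floor(frac * L))
        out[[length(out) + 1L]] <- c(start = c0 - L, end = c0 + g + L,
                                     arm = L, mm = mm, spacer = g)
    }
  }
  if (length(out)) do.call(rbind, out) else NULL
}

# the two palindromic motifs and the conserved flank printed for the
# head-to-head family, used verbatim as fixtures
H2H_FLANK <- "GTCGTCCGACCAAAGATTATGGTCGGACGAGTCCGACACAATACGTTCTCT"
H2H_PAL1 <- "TCGTCCGACCAAAGATTATGGTCGGACGA"
H2H_PAL2 <- "GTCGGACGAGTCCGAC"

# representative monomers of the published family table
MONOMER_BVMSAT07 <- "GAAAAAATAAGTTCAGATCAGATCAGATCA"
MONOMER_BVMSAT05 <- "ACTGAAAAAAAATGAAGACTA"
MONOMER_FOKI <- paste0(
  "GGGACTTAGGAGAGTGACCCAACCAAGGAGGGAGACCTCCTTGGGCTGAGT",
  "TGGGTGGACGCGGCTCGGATGAGGGGCCAATGAGCCCCACGCTTGTCCGAG",
  "CCGGTGCCGTCTCTCGCCATGTCAATCT")

# write a temporary FASTA file from a named character vector
tmpFasta <- function(seqs, width = 60L) {
  path <- tempfile(fileext = ".fasta")
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  close(con)
  path
}

# small two-family simulation used by several pipeline-level tests
smallTestSim <- function(seed = 5L) {
  fams <- list(
    familySpec("KnownSat", randSeqFixed(150, seed + 1L), "tandem",
               "satellite", nArrays = 3, monomersPerArray = c(40, 60),
               mutationRate = 0.03, inPanel = TRUE),
    familySpec("NovA", randSeqFixed(24, seed + 2L), "tandem",
               "minisatellite", nArrays = 20,
               monomersPerArray = c(20, 30), mutationRate = 0.04),
    familySpec("NovB", randSeqFixed(55, seed + 3L), "tandem",
               "minisatellite", nArrays = 10,
               monomersPerArray = c(10, 16), mutationRate = 0.04))
  simulateGenome(genomeSpec(2e5, fams, seed = seed))
}

randSeqFixed <- function(n, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  s <- randSeq(n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}
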