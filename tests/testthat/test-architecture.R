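test_that("the microsatellite-derived higher-order unit is decomposed", {
  unit <- paste0("GAAAA", "AATAA", "GTTCA", "GATCA", "GATCA", "GATCA")
  h <- detectHOR(strrep(unit, 5), "GATCA")
  expect_equal(h$horPeriodUnits, 6L)
  expect_equal(h$horPeriodBp, 30L)
  expect_equal(h$exactBaseCount, 3L)
  # GAAAA and AATAA are distinct variants; GTTCA is a single substitution
  # away from GATCA and may share its label, which does not disturb the
  # modal unit pattern
  expect_gte(length(unique(h$labels)), 3L)
  expect_equal(sum(h$unitPattern == "GATCA"), 3L)
  # a pure microsatellite has a single-label pattern: no higher order
  expect_null(detectHOR(strrep("GATCA", 30), "GATCA"))
})

test_that("HOR detection is invariant to rotating the array by base periods", {
  unit <- paste0("GAAAA", "AATAA", "GTTCA", "GATCA", "GATCA", "GATCA")
  arr <- strrep(unit, 5)
  for (shift in c(1L, 2L, 4L)) {
    r <- shift * 5L
    rot <- paste0(substr(arr, r + 1, nchar(arr)), substr(arr, 1, r))
    h <- detectHOR(rot, "GATCA")
    expect_equal(h$horPeriodUnits, 6L)
    expect_equal(h$exactBaseCount, 3L)
  }
})

test_that("i.i.d. unit sequences yield no higher-order period", {
  # three well-separated 5 bp variants arranged independently at random
  variants <- c("GATCA", "GCGGA", "ATTCC")
  set.seed(24)
  nulls <- 0L
  for (trial in 1:100) {
    lab <- sample(3L, 30L, replace = TRUE)
    arr <- paste(variants[lab], collapse = "")
    if (is.null(detectHOR(arr, "GATCA"))) nulls <- nulls + 1L
  }
  expect_gte(nulls, 95L)
})

test_that("head-to-head junctions are found once and only at real inversions", {
  set.seed(25)
  hits <- 0L
  for (i in 1:20) {
    M <- randSeq(21)
    j <- detectInvertedJunction(paste0(strrep(M, 6), revComp(strrep(M, 6))), M)
    expect_equal(nrow(j), 1L)
    expect_equal(j$junction_type, "head_to_head")
    expect_equal(j$left_orientation, "+")
    expect_equal(j$right_orientation, "-")
    expect_lte(abs(j$junction_pos - 126L), 21L)
    if (j$junction_pos == 126L) hits <- hits + 1L
    expect_equal(nrow(detectInvertedJunction(strrep(M, 12), M)), 0L)
  }
  expect_gte(hits, 10L)  # boundary-base coincidences shift a minority by <1 monomer
})

test_that("no junctions on pure head-to-tail arrays across monomer sizes", {
  set.seed(26)
  for (i in 1:100) {
    p <- sample(10:100, 1)
    M <- randSeq(p)
    arr <- paste(vapply(1:8, function(k) mutSeq(M, 0.05), ""), collapse = "")
    expect_equal(nrow(detectInvertedJunction(arr, M)), 0L)
  }
})

test_that("a junction with a conserved spacer is bridged by the gap allowance", {
  set.seed(27)
  for (i in 1:5) {
    M <- randSeq(21)
    s <- paste0(strrep(M, 6), H2H_FLANK, revComp(strrep(M, 6)))
    j <- detectInvertedJunction(s, M, maxGap = 60)
    expect_equal(nrow(j), 1L)
    expect_lte(abs(j$junction_pos - 177L), 21L)
    # without the allowance the two blocks are disjoint
    j2 <- detectInvertedJunction(s, M, maxGap = 20)
    expect_equal(nrow(j2), 0L)
  }
})

test_that("asymmetric inverted constructions are found at the built position", {
  set.seed(28)
  for (i in 1:10) {
    p <- sample(10:100, 1)
    a <- sample(2:6, 1); b <- sample(2:6, 1)
    M <- randSeq(p)
    s <- paste0(strrep(M, a), revComp(strrep(M, b)))
    j <- detectInvertedJunction(s, M)
    expect_equal(nrow(j), 1L)
    expect_lte(abs(j$junction_pos - a * p), p)
  }
})

test_that("conserved flank motifs are extracted with identity ranges", {
  set.seed(29)
  flank <- randSeq(51)
  mkLocus <- function(fl) {
    arr <- strrep(randSeq(20), 10)
    list(seq = paste0(randSeq(10), fl, arr), start = 61L,
         end = 61L + nchar(arr))
  }
  loci <- do.call(rbind, lapply(1:10, function(i)
    as.data.frame(mkLocus(flank), stringsAsFactors = FALSE)))
  fm <- extractFlankMotif(loci, "left", 51L)
  expect_equal(fm$consensus, flank)
  expect_equal(c(fm$identityMin, fm$identityMax), c(100, 100))
  # mutated flanks: consensus recovers the planted motif, identities spread
  loci2 <- do.call(rbind, lapply(1:10, function(i)
    as.data.frame(mkLocus(mutSeq(flank, 0.05)), stringsAsFactors = FALSE)))
  fm2 <- extractFlankMotif(loci2, "left", 51L)
  expect_equal(fm2$consensus, flank)
  # two flanks each 5% mutated differ at ~10% of positions; the worst of
  # 45 pairs sits a few points below the ~90% mean
  expect_gte(fm2$identityMin, 75)
  expect_lte(fm2$identityMax, 100)
  expect_gte(mean(c(fm2$identityMin, fm2$identityMax)), 85)
  # loci too short on that side are excluded with a warning
  lociShort <- rbind(loci, data.frame(seq = "ACGTACGT", start = 4L, end = 8L))
  expect_warning(fm3 <- extractFlankMotif(lociShort, "left", 51L), "excluded")
  expect_equal(fm3$consensus, flank)
  expect_error(suppressWarnings(
    extractFlankMotif(loci[1, ], "left", 51L)), "at least 2")
})

test_that("perfect palindromes are found with zero mismatches", {
  h <- findImperfectPalindromes("GAATTC", minArm = 3L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$arm_length, 3L)
  expect_equal(nrow(findImperfectPalindromes(strrep("A", 40))), 0L)
})

test_that("the printed 51 nt flank contains both printed palindromic motifs", {
  expect_equal(nchar(H2H_FLANK), 51L)
  i1 <- as.integer(regexpr(H2H_PAL1, H2H_FLANK, fixed = TRUE)) - 1L
  i2 <- as.integer(regexpr(H2H_PAL2, H2H_FLANK, fixed = TRUE)) - 1L
  expect_gte(i1, 0L); expect_gte(i2, 0L)
  m1 <- c(i1, i1 + nchar(H2H_PAL1))
  m2 <- c(i2, i2 + nchar(H2H_PAL2))
  hits <- findImperfectPalindromes(H2H_FLANK)
  expect_true(any(hits$start <= m1[1] & hits$end >= m1[2]))
  expect_true(any(hits$start <= m2[1] & hits$end >= m2[2]))
  # every reported hit is valid under the brute-force enumeration
  oracle <- brutePalindromes(H2H_FLANK)
  key <- paste(oracle[, "start"], oracle[, "end"], oracle[, "spacer"])
  expect_true(all(paste(hits$start, hits$end, hits$spacer) %in% key))
})

test_that("palindrome scores agree with brute-force enumeration on short strings", {
  set.seed(30)
  for (i in 1:15) {
    s <- randSeq(sample(30:100, 1))
    hits <- findImperfectPalindromes(s)
    oracle <- brutePalindromes(s)
    if (is.null(oracle)) {
      expect_equal(nrow(hits), 0L)
    } else {
      expect_gte(nrow(hits), 1L)
      bestOracle <- max(oracle[, "arm"] - oracle[, "mm"])
      expect_equal(max(hits$score), bestOracle)
      key <- paste(oracle[, "start"], oracle[, "end"], oracle[, "spacer"])
      expect_true(all(paste(hits$start, hits$end, hits$spacer) %in% key))
    }
  }
})
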