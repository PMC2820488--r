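test_that("perfect arrays are detected at the exact period and copy number", {
  r <- detectTandem(strrep("ACGTT", 8))
  expect_length(r, 1L)
  expect_equal(arrayPeriod(r[[1L]]), 5L)
  expect_equal(arrayCopyNumber(r[[1L]]), 8)
  expect_equal(r[[1L]]@conformity, 100)
  # smallest-period rule: ATAT... is period 2, not 4
  r2 <- detectTandem(strrep("ATAT", 10))
  expect_equal(arrayPeriod(r2[[1L]]), 2L)
})

test_that("perfect p-periodic strings are recovered over a period grid", {
  set.seed(10)
  for (p in c(2L, 3L, 7L, 11L, 25L, 60L, 100L)) {
    mono <- randSeq(p)
    if (!is.na(bruteSmallestPeriod(strrep(mono, 4))) &&
        bruteSmallestPeriod(strrep(mono, 4)) < p) next  # degenerate monomer
    for (n in c(3L, 8L, 16L)) {
      if (p * n < 20L) next             # below the default minimum array span
      r <- detectTandem(strrep(mono, n))
      expect_length(r, 1L)
      expect_equal(arrayPeriod(r[[1L]]), p)
      expect_equal(arrayCopyNumber(r[[1L]]), n, tolerance = 1e-9)
    }
  }
})

test_that("detected period equals the brute-force smallest period on mutated arrays", {
  set.seed(11)
  checked <- 0L
  for (i in 1:40) {
    p <- sample(5:60, 1)
    mono <- randSeq(p)
    arr <- paste(vapply(1:8, function(j) mutSeq(mono, 0.06), ""),
                 collapse = "")
    if (is.na(bruteSmallestPeriod(arr))) next
    r <- detectTandem(arr)
    expect_gte(length(r), 1L)
    main <- r[[which.max(vapply(r, function(a) a@end - a@start, 0L))]]
    # the smallest-period claim holds on the reported interval: no
    # sub-period explains that substring at the conformity floor
    sub <- substr(arr, main@start + 1L, main@end)
    expect_equal(arrayPeriod(main), bruteSmallestPeriod(sub))
    checked <- checked + 1L
  }
  expect_gte(checked, 30L)
})

test_that("a higher-order monomer is reported at its full period, not the base motif", {
  # the 30 bp microsatellite-derived monomer: its 5 bp sub-structure only
  # explains ~half the positions, far below the 80% conformity floor
  arr <- strrep(MONOMER_BVMSAT07, 4)
  ch <- strsplit(arr, "")[[1L]]
  conf5 <- 100 * mean(ch[1:(120 - 5)] == ch[6:120])
  expect_lt(conf5, 80)
  expect_equal(bruteSmallestPeriod(arr), 30L)
  r <- detectTandem(arr)
  expect_equal(arrayPeriod(r[[1L]]), 30L)
})

test_that("a planted array in random background is localized", {
  set.seed(42)
  bg <- randSeq(500)
  s <- paste0(substr(bg, 1, 100), strrep("GATCA", 6), substr(bg, 131, 500))
  r <- detectTandem(s)
  expect_length(r, 1L)
  expect_equal(arrayInterval(r[[1L]]), c(100L, 130L))
  expect_equal(arrayPeriod(r[[1L]]), 5L)
})

test_that("monomer decomposition reconstructs the array substring exactly", {
  arr <- randSeqFixed(90, 61)
  d <- decomposeMonomers(arr, c(0L, 90L), 30L, 0L)
  expect_length(d$monomers, 3L)
  expect_false(any(d$partial))
  big <- randSeqFixed(100, 62)
  d2 <- decomposeMonomers(big, c(0L, 100L), 30L, 10L)
  expect_equal(nchar(d2$monomers[1L]), 10L)
  expect_true(d2$partial[1L])
  expect_equal(sum(!d2$partial), 3L)
  expect_error(decomposeMonomers(arr, c(0L, 90L), 0L), "positive")
  set.seed(12)
  for (i in 1:10) {
    n <- sample(50:200, 1); p <- sample(3:30, 1)
    s <- randSeq(n)
    a <- sort(sample(0:(n - p - 1L), 2))
    if (a[2] - a[1] < p + 1) next
    ph <- sample(0:(p - 1L), 1)
    d <- decomposeMonomers(s, a, p, ph)
    expect_identical(paste(d$monomers, collapse = ""),
                     substr(s, a[1] + 1L, a[2]))
  }
})

test_that("canonical consensus is majority-rule and rotation-invariant", {
  expect_equal(canonicalConsensus(rep("GATCA", 5)), "AGATC")
  ms <- c(rep("GATCA", 9), "GTTCA")
  expect_equal(canonicalConsensus(ms), "AGATC")
  expect_error(canonicalConsensus("GATCA"), "at least 2")
  set.seed(13)
  for (i in 1:10) {
    p <- sample(6:30, 1)
    mono <- randSeq(p)
    arr <- strrep(mono, 6)
    r <- sample(0:(p - 1L), 1)
    rot <- paste0(substr(arr, r + 1, nchar(arr)), substr(arr, 1, r))
    m1 <- decomposeMonomers(arr, c(0L, nchar(arr)), p, 0L)
    m2 <- decomposeMonomers(rot, c(0L, nchar(rot)), p, 0L)
    expect_identical(canonicalConsensus(m1$monomers[!m1$partial]),
                     canonicalConsensus(m2$monomers[!m2$partial]))
  }
})

test_that("monomer statistics: identity range, G/C, seeded sampling", {
  st <- monomerStats(rep("GATCA", 20))
  expect_equal(st$identityMin, 100)
  expect_equal(st$identityMax, 100)
  expect_equal(st$gcPercent, 40)
  expect_error(monomerStats("GATCA"), "at least 2")
  # sampling is deterministic under the default seed
  set.seed(99)
  monos <- vapply(1:50, function(i) mutSeq(randSeqFixed(30, 71), 0.08), "")
  s1 <- monomerStats(monos); s2 <- monomerStats(monos)
  expect_identical(s1, s2)
  expect_length(s1$sample, 20L)
})

test_that("mean pairwise identity of mutated monomers matches the analytic rate", {
  # two independently mutated copies (rate r, always to a different base)
  # differ at a position with prob 2r(1-r) + r^2*(2/3)
  set.seed(14)
  r <- 0.1
  cons <- randSeq(30)
  monos <- vapply(1:20, function(i) mutSeq(cons, r), "")
  ids <- c()
  for (i in 1:19) for (j in (i + 1):20)
    ids <- c(ids, globalIdentity(monos[i], monos[j]))
  expected <- 100 * (1 - (2 * r * (1 - r) + r^2 * 2 / 3))
  expect_lt(abs(mean(ids) - expected), 5)
})

test_that("family size classes follow the monomer-size convention", {
  expect_equal(classifyFamilySize(10), "minisatellite")
  expect_equal(classifyFamilySize(130), "satellite")
  expect_equal(classifyFamilySize(5), "microsatellite")
  expect_equal(classifyFamilySize(2), "microsatellite")
  expect_equal(classifyFamilySize(6), "minisatellite")
  expect_equal(classifyFamilySize(100), "minisatellite")
  expect_equal(classifyFamilySize(101), "satellite")
  expect_error(classifyFamilySize(1), ">= 2")
})

test_that("clustering groups planted families correctly", {
  set.seed(15)
  nfam <- 12L
  consensi <- vapply(seq_len(nfam), function(i) randSeq(sample(12:60, 1)), "")
  anns <- list(); truthFam <- integer(0)
  cloneNum <- 0L
  for (i in seq_len(nfam)) {
    for (j in seq_len(if (i <= 11) 3L else 2L)) {   # 35 tandem clones
      cloneNum <- cloneNum + 1L
      arr <- paste(vapply(1:6, function(k) mutSeq(consensi[i], 0.05), ""),
                   collapse = "")
      r <- detectTandem(arr, seqId = sprintf("c%02d", cloneNum))
      main <- r[[which.max(vapply(r, function(a) a@end - a@start, 0L))]]
      anns <- c(anns, main)
      truthFam <- c(truthFam, i)
    }
  }
  fams <- clusterFamilies(anns)
  expect_equal(length(fams), nfam)
  # membership matches the planted grouping
  ids <- vapply(anns, function(a) a@seqId, "")
  assign1 <- integer(length(anns))
  for (fi in seq_along(fams))
    assign1[ids %in% familyMembers(fams[[fi]])] <- fi
  expect_equal(length(unique(paste(truthFam, assign1))), nfam)
  # invariant to input order and to reverse-complementing members
  fams2 <- clusterFamilies(rev(anns))
  expect_equal(length(fams2), nfam)
  sizes1 <- sort(vapply(fams, function(f) f@cotHits, 0L))
  sizes2 <- sort(vapply(fams2, function(f) f@cotHits, 0L))
  expect_identical(sizes1, sizes2)
  rcArr <- revComp(paste(vapply(1:6, function(k) mutSeq(consensi[1], 0.05),
                                ""), collapse = ""))
  rAnn <- detectTandem(rcArr, seqId = "rc1")
  main <- rAnn[[which.max(vapply(rAnn, function(a) a@end - a@start, 0L))]]
  fams3 <- clusterFamilies(c(anns, main))
  expect_equal(length(fams3), nfam)   # rc clone joins family 1
})

test_that("unrelated consensi give singleton families; empty input is empty", {
  expect_equal(clusterFamilies(list()), list())
  set.seed(16)
  a1 <- detectTandem(strrep(randSeq(20), 5), seqId = "x")[[1L]]
  a2 <- detectTandem(strrep(randSeq(21), 5), seqId = "y")[[1L]]
  fams <- clusterFamilies(list(a1, a2))
  expect_equal(length(fams), 2L)
  expect_equal(sort(vapply(fams, function(f) f@cotHits, 0L)), c(1L, 1L))
})
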