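test_that("FASTA reading normalizes, totals and validates", {
  p <- tmpFasta(c(cl1 = randSeqFixed(100, 11), cl2 = randSeqFixed(342, 12)))
  lib <- readFastaLibrary(p)
  expect_s4_class(lib, "CloneLibrary")
  expect_equal(length(lib), 2L)
  expect_equal(totalBases(lib), 442L)
  expect_equal(names(lib), c("cl1", "cl2"))

  p2 <- tmpFasta(c(lo = "acgtu"))
  expect_equal(as.character(clones(readFastaLibrary(p2))[[1L]]), "ACGTT")

  p3 <- tmpFasta(c(bad = "ACGXGT"))
  err <- tryCatch(readFastaLibrary(p3), error = function(e) conditionMessage(e))
  expect_match(err, "bad")
  expect_match(err, "4")

  p4 <- tmpFasta(c(a = "ACGT", a = "ACGT"))
  expect_error(readFastaLibrary(p4), "duplicate.*a")
  expect_error(readFastaLibrary(tempfile()), "not found")
})

test_that("FASTA round trip preserves sequences", {
  set.seed(21)
  seqs <- setNames(vapply(1:5, function(i) randSeq(sample(60:200, 1)), ""),
                   paste0("s", 1:5))
  p <- tmpFasta(seqs)
  lib <- readFastaLibrary(p)
  p2 <- tempfile(fileext = ".fasta")
  writeFastaLibrary(lib, p2)
  lib2 <- readFastaLibrary(p2)
  expect_identical(as.character(clones(lib2)), as.character(clones(lib)))
})

test_that("reverse complement is correct and involutive", {
  expect_equal(revComp("GATCA"), "TGATC")
  expect_equal(revComp("GAATTC"), "GAATTC")   # a perfect palindrome
  expect_equal(revComp("ANGT"), "ACNT")
  expect_error(revComp("ACGB"), "invalid character")
  set.seed(1)
  for (i in 1:20) {
    x <- randSeq(sample(5:100, 1))
    expect_identical(revComp(revComp(x)), x)
  }
})

test_that("gcContent counts G+C with N excluded", {
  expect_equal(gcContent("GATCA"), 0.4)
  expect_equal(gcContent("AAAA"), 0)
  expect_equal(gcContent("GCNN"), 1)
  expect_error(gcContent(""), "empty")
  # the 130 bp representative satellite monomer: direct character count
  ch <- strsplit(MONOMER_FOKI, "")[[1L]]
  expect_equal(gcContent(MONOMER_FOKI), sum(ch %in% c("G", "C")) / 130)
  expect_equal(sum(ch %in% c("G", "C")), 82L)
  set.seed(2)
  for (i in 1:10) {
    x <- randSeq(50)
    expect_equal(gcContent(revComp(x)), gcContent(x))
  }
})

test_that("globalIdentity matches direct expectations and is symmetric", {
  x <- randSeqFixed(30, 31)
  expect_equal(globalIdentity(x, x), 100)
  expect_equal(globalIdentity("AACTTATTGG", "AACTTATAGG"), 90)
  expect_error(globalIdentity("", "ACGT"), "empty")
  set.seed(3)
  for (i in 1:50) {
    a <- randSeq(sample(10:60, 1)); b <- randSeq(sample(10:60, 1))
    expect_equal(globalIdentity(a, b), globalIdentity(b, a))
  }
})

test_that("seededLocalAlign finds planted hits with correct geometry", {
  set.seed(4)
  tgt <- randSeq(1000)
  q <- substr(tgt, 301, 500)
  h <- seededLocalAlign(q, c(t1 = tgt))
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 100)
  expect_equal(c(h$tstart, h$tend), c(300L, 500L))
  expect_equal(h$strand, "+")
  # reverse-strand recovery with query coordinates mapped back
  h2 <- seededLocalAlign(revComp(q), c(t1 = tgt))
  expect_equal(h2$strand, "-")
  expect_equal(c(h2$tstart, h2$tend), c(300L, 500L))
  # no shared 11-mer: empty, and seed longer than query: empty not error
  expect_equal(nrow(seededLocalAlign(randSeq(300), c(t = randSeq(300)))), 0L)
  expect_equal(nrow(seededLocalAlign("ACGTACG", c(t = tgt))), 0L)
})

test_that("seeded alignment scores agree with brute-force Smith-Waterman", {
  set.seed(5)
  for (i in 1:12) {
    tgt <- randSeq(180)
    core <- substr(tgt, 41, 140)
    q <- paste0(randSeq(30), mutSeq(core, 0.15), randSeq(30))
    h <- seededLocalAlign(q, c(t = tgt), minScore = 10, minLen = 20,
                          minIdentity = 50)
    sw <- max(bruteLocalScore(q, tgt), bruteLocalScore(revComp(q), tgt))
    if (nrow(h)) expect_equal(h$score[1L], sw)
  }
})

test_that("planted-identity hits are recovered near the planted value", {
  set.seed(6)
  for (i in 1:5) {
    pan <- randSeq(400)
    q <- mutSeq(substr(pan, 101, 250), 0.15)   # ~85% identity, 150 bp
    h <- seededLocalAlign(q, c(panel = pan))
    expect_gte(nrow(h), 1L)
    expect_gte(h$identity[1L], 82 - 3)
    expect_lte(h$identity[1L], 100)
  }
})

test_that("length filtering keeps records at the boundary and order", {
  lib <- CloneLibrary(c(a = randSeqFixed(49, 41), b = randSeqFixed(50, 42),
                        c = randSeqFixed(600, 43)))
  f <- filterMinLength(lib, 50)
  expect_equal(names(f), c("b", "c"))
  expect_equal(length(filterMinLength(CloneLibrary(), 50)), 0L)
  all50 <- CloneLibrary(c(x = randSeqFixed(80, 44), y = randSeqFixed(90, 45)))
  expect_identical(names(filterMinLength(all50, 50)), names(all50))
})

test_that("CloneLibrary enforces its invariants", {
  expect_error(CloneLibrary(c(a = "")), "empty|invalid")
  expect_error(validObject(new("CloneLibrary",
                               seqs = Biostrings::DNAStringSet(c(a = "ACGT", a = "ACGT")),
                               name = "x")),
               "duplicate")
})
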