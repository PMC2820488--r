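test_that("composition percentages use half-up rounding and partition", {
  r <- compositionPercentages(c(pBV = 147, pEV = 87), 500)
  df <- reportCategories(r)
  expect_equal(df$percent[df$category == "pBV"], 29.4)
  expect_equal(df$category[3L], "unassigned")
  expect_equal(sum(df$count), 500L)
  expect_equal(reportCategories(compositionPercentages(c(x = 0), 100))$percent[1L], 0)
  # exact half values round up, not to even
  expect_equal(percentHalfUp(125, 1000), 12.5)
  expect_equal(roundHalfUp(0.25, 1), 0.3)
  expect_equal(roundHalfUp(0.35, 1), 0.4)
  expect_error(compositionPercentages(c(a = 10), 0), "positive")
  expect_error(compositionPercentages(c(a = 10), 5), "exceed")
})

test_that("telomere motif runs are detected on both strands", {
  s <- paste0("ACGTACGT", strrep("TTTAGGG", 5), "GGCC")
  tel <- detectTelomereMotif(s)
  expect_equal(tel$end - tel$start, 35L)
  expect_equal(tel$copies, 5L)
  set.seed(7)
  expect_null(detectTelomereMotif(randSeq(300)))
  expect_null(detectTelomereMotif(strrep("TTTAGGG", 2), minCopies = 3))
  # one mismatch per copy tolerated
  s2 <- paste0(strrep("TTTAGGG", 2), "TTTAGGC", strrep("TTTAGGG", 2))
  expect_equal(detectTelomereMotif(s2)$copies, 5L)
  # reverse strand
  telR <- detectTelomereMotif(paste0("AC", revComp(strrep("TTTAGGG", 4)), "GG"))
  expect_equal(telR$strand, "-")
  expect_equal(telR$end - telR$start, 28L)
})

test_that("microsatellite arrays are canonical, long enough, not homopolymer", {
  ms <- detectMicrosatellite(strrep("GATCA", 8))
  expect_equal(nrow(ms), 1L)
  expect_equal(ms$motif, "AGATC")       # canonical rotation of GATCA
  expect_equal(ms$end - ms$start, 40L)
  expect_equal(nrow(detectMicrosatellite("ACACAC")), 0L)
  expect_equal(nrow(detectMicrosatellite(strrep("A", 30))), 0L)
  ms2 <- detectMicrosatellite(paste0(randSeqFixed(50, 51), strrep("AT", 15),
                                     randSeqFixed(50, 52)))
  expect_equal(nrow(ms2), 1L)
  expect_equal(ms2$motif, "AT")
})

test_that("best panel hit picks the highest-identity entry", {
  set.seed(8)
  monomer <- randSeq(100)
  clone <- strrep(monomer, 3)
  near <- mutSeq(monomer, 0.05)
  far <- mutSeq(monomer, 0.20)
  panel <- RepeatPanel(c(near_e = near, far_e = far, other = randSeq(150)),
                       repeatClass = c("satellite", "satellite",
                                       "retroelement"))
  hit <- bestPanelHit(clone, panel)
  expect_equal(hit$entry, "near_e")
  expect_null(bestPanelHit(randSeq(300), panel))
  expect_error(bestPanelHit(clone, RepeatPanel(character(0), character(0))),
               "empty")
})

test_that("library classification partitions, applies precedence, is deterministic", {
  set.seed(9)
  sat <- randSeq(120)
  panel <- RepeatPanel(c(satX = sat, chlA = randSeq(800)),
                       repeatClass = c("satellite", "organellar"))
  seqs <- c(
    setNames(vapply(1:6, function(i) mutSeq(strrep(sat, 3), 0.03), ""),
             paste0("k", 1:6)),
    setNames(vapply(1:4, function(i) randSeq(250), ""), paste0("n", 1:4)))
  # a clone with both a panel hit and a telomere run: homology wins
  seqs <- c(seqs, both = paste0(mutSeq(sat, 0.02), strrep("TTTAGGG", 5)))
  seqs <- c(seqs, tel = paste0(randSeq(100), strrep("TTTAGGG", 4)))
  seqs <- c(seqs, chl = mutSeq(substr(strrep(panelSeqs(panel)[["chlA"]],
                                             1), 101, 400), 0.02))
  lib <- CloneLibrary(seqs)
  out <- classifyLibrary(lib, panel)
  a <- out$assignments
  expect_equal(nrow(a), length(lib))
  expect_equal(sum(a$category == "known_repeat"), 7L)  # 6 sats + "both"
  expect_equal(a$category[a$clone_id == "both"], "known_repeat")
  expect_equal(a$category[a$clone_id == "tel"], "telomere")
  expect_equal(a$category[a$clone_id == "chl"], "chloroplast")
  expect_equal(sum(a$category == "novel"), 4L)
  cats <- reportCategories(out$report)
  expect_equal(sum(cats$count), length(lib))
  expect_lte(abs(sum(cats$percent) - 100), 0.3)
  out2 <- classifyLibrary(lib, panel)
  expect_identical(out, out2)
  expect_error(classifyLibrary(CloneLibrary(), panel), "empty")
})

test_that("known-repeat recall on simulated clones is high", {
  sim <- smallTestSim()
  libres <- simulateCotLibrary(sim, cotSamplingModel(nClones = 300),
                               seed = 6)
  panel <- referencePanel(sim)
  out <- classifyLibrary(libres$library, panel)
  known <- libres$truth$family == "KnownSat"
  cls <- out$assignments$category[match(libres$truth$clone_id,
                                        out$assignments$clone_id)]
  expect_gte(mean(cls[known] == "known_repeat"), 0.95)
})
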