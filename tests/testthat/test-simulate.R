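test_that("genome simulation is deterministic and truth-complete", {
  sim1 <- smallTestSim(); sim2 <- smallTestSim()
  expect_identical(as.character(simGenome(sim1)),
                   as.character(simGenome(sim2)))
  expect_identical(simArrays(sim1), simArrays(sim2))
  fam <- simFamilies(sim1)
  arr <- simArrays(sim1)
  for (i in seq_len(nrow(fam)))
    expect_equal(sum(arr$family == fam$family[i]), fam$n_arrays[i])
  # planted intervals do not overlap and lie within the genome
  o <- order(arr$start)
  expect_true(all(arr$start[o][-1] >= arr$end[o][-nrow(arr)]))
  expect_true(all(arr$end <= sum(Biostrings::width(simGenome(sim1)))))
})

test_that("a family-free genome yields no truth arrays and no tandem calls", {
  sim <- simulateGenome(genomeSpec(2e5, list(), seed = 8))
  expect_equal(nrow(simArrays(sim)), 0L)
  libres <- simulateCotLibrary(sim, cotSamplingModel(nClones = 150),
                               seed = 9)
  spurious <- 0L
  for (s in as.character(clones(libres$library)))
    spurious <- spurious + length(detectTandem(s))
  expect_lte(spurious, 1L)   # <= 1 per ~50 kb of sampled sequence
})

test_that("planted content larger than the genome is rejected up front", {
  fams <- list(familySpec("big", randSeqFixed(150, 91), "tandem",
                          "satellite", nArrays = 100,
                          monomersPerArray = c(100, 100)))
  expect_error(simulateGenome(genomeSpec(1e5, fams, seed = 1)),
               "exceeds genome length")
})

test_that("retention follows second-order kinetics", {
  expect_equal(retentionProbability(100, kUnit = 0.01, c0t = 1), 0.5)
  expect_equal(retentionProbability(1000, kUnit = 0.01) /
                 retentionProbability(1, kUnit = 0.01),
               (10 / 11) / (0.01 / 1.01))
  expect_lt(abs(retentionProbability(1e9) - 1), 1e-6)
  n <- c(1, 5, 50, 500, 5000)
  expect_true(all(diff(retentionProbability(n)) > 0))
  expect_error(retentionProbability(10, kUnit = 0), "positive")
  expect_error(retentionProbability(0.5), ">= 1")
})

test_that("background-only retention matches the closed form", {
  sim <- simulateGenome(genomeSpec(3e5, list(), seed = 10))
  model <- cotSamplingModel(c0t = 1, kUnit = 0.001, nClones = 60L)
  res <- simulateCotLibrary(sim, model, seed = 11)
  p <- 0.001 / 1.001
  frac <- res$retainedTotal / res$draws
  sd3 <- 3 * sqrt(p * (1 - p) / res$draws)
  expect_lt(abs(frac - p), sd3)
})

test_that("library clones respect the insert-length contract and seed", {
  sim <- smallTestSim()
  res <- simulateCotLibrary(sim, cotSamplingModel(nClones = 200), seed = 12)
  w <- Biostrings::width(clones(res$library))
  expect_true(all(w >= 50 & w <= 600))
  expect_equal(length(res$library), 200L)
  res2 <- simulateCotLibrary(sim, cotSamplingModel(nClones = 200), seed = 12)
  expect_identical(as.character(clones(res2$library)),
                   as.character(clones(res$library)))
})

test_that("library frequencies increase with planted kinetic copy number", {
  sim <- smallTestSim()
  kins <- cors <- numeric(0)
  for (s in 1:8) {
    res <- simulateCotLibrary(sim, cotSamplingModel(nClones = 400), seed = s)
    fam <- simFamilies(sim)
    counts <- vapply(fam$family, function(f) sum(res$truth$family == f), 0L)
    kin <- res$kinetics[fam$family]
    cors <- c(cors, cor(kin, counts, method = "spearman"))
  }
  expect_gte(mean(cors), 0.9)
})

test_that("recovery evaluation handles perfect and deficient outputs", {
  sim <- smallTestSim()
  fam <- simFamilies(sim)
  novel <- fam[fam$type == "tandem" & !fam$in_panel, ]
  mkFam <- function(cons, nm) new("RepeatFamily", name = nm,
    memberIds = "x", periods = nchar(cons), cotHits = 1L, gcPercent = 50,
    identityMin = 90, identityMax = 100, representative = cons,
    label = classifyFamilySize(nchar(cons)))
  full <- lapply(seq_len(nrow(novel)), function(i)
    mkFam(novel$consensus[i], paste0("F", i)))
  ev <- evaluateRecovery(full, sim)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  ev2 <- evaluateRecovery(full[-1L], sim)
  expect_equal(ev2$nRecovered, nrow(novel) - 1L)
  expect_error(evaluateRecovery(full, new("GenomeSimulation",
    genome = Biostrings::DNAStringSet("ACGT"),
    arrays = data.frame(), families = data.frame(), spec = list())),
    "empty")
})
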