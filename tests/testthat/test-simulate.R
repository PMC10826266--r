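test_that("synthetic alleles are reproducible with boosted anchor pockets", {
  a1 <- makeAllele("X", seed = 5, anchorStrength = 3)
  a2 <- makeAllele("X", seed = 5, anchorStrength = 3)
  expect_identical(a1, a2)
  expect_identical(nchar(a1$pseudo), 34L)
  expect_identical(dim(a1$pwm), c(9L, 20L))
  gap <- apply(a1$pwm, 1, function(r) max(r) - mean(r))
  expect_gt(min(gap[c(1, 4, 6, 9)]), max(gap[-c(1, 4, 6, 9)]))
  expect_error(makeAllele("X", 1, anchorStrength = 0), "> 0")
  b <- makeAllele("Y", seed = 6)
  expect_false(identical(a1$pwm, b$pwm))
})

test_that("sampled peptides respect the length range and background", {
  withSeed(31, {
    p9 <- samplePeptide(50, c(9, 9))
    expect_true(all(nchar(p9) == 9))
    ps <- samplePeptide(3000, c(9, 22))
    expect_identical(sort(unique(nchar(ps))), 9:22)
    expect_true(all(strsplit(paste(ps, collapse = ""), "")[[1]] %in%
                      aminoAcids()))
  })
  expect_identical(withSeed(1, samplePeptide(5)), withSeed(1, samplePeptide(5)))
  expect_error(samplePeptide(1, c(8, 22)), "9..22")
})

test_that("ground-truth affinity scores windows against the energy matrix", {
  al <- makeAllele("X", seed = 7, noiseSd = 0)
  # single window for a 9-mer
  t9 <- trueAffinity("ACDEFGHIK", al, noiseSd = 0)
  expect_identical(t9$coreStart, 0L)
  expect_true(t9$affinity >= 0 && t9$affinity <= 1)
  # a peptide containing the matrix's argmax 9-mer puts the core there
  best <- paste(aminoAcids()[apply(al$pwm, 1, which.max)], collapse = "")
  flank <- withSeed(2, samplePeptide(1, c(9, 9)))
  pep <- paste0(substr(flank, 1, 4), best, substr(flank, 5, 9))
  tb <- trueAffinity(pep, al, noiseSd = 0)
  expect_identical(tb$coreStart, 4L)
  # affinity bounded for extreme inputs
  z <- vapply(withSeed(3, samplePeptide(50, c(9, 22))), function(p)
    trueAffinity(p, al, noiseSd = 0)$affinity, numeric(1))
  expect_true(all(z >= 0 & z <= 1))
})

test_that("the noise-free core is recovered by an independent window oracle", {
  al <- makeAllele("X", seed = 11, noiseSd = 0)
  peps <- withSeed(12, samplePeptide(60, c(9, 22)))
  for (pep in peps) {
    o <- oracleBestWindow(pep, al$pwm)
    expect_identical(trueAffinity(pep, al, noiseSd = 0)$coreStart, o$best)
  }
})

test_that("dataset generation is deterministic with the declared shape", {
  s1 <- simulateDataset(nAlleles = 2, nPerAllele = 100, seed = 21)
  s2 <- simulateDataset(nAlleles = 2, nPerAllele = 100, seed = 21)
  expect_identical(bindingRecords(s1), bindingRecords(s2))
  r <- bindingRecords(s1)
  expect_identical(nrow(r), 200L)
  expect_identical(sort(unique(r$split)), c("test", "train"))
  expect_true(all(r$coreStart + 9 <= nchar(r$peptide)))
  # group id is the true core 9-mer
  expect_identical(r$group,
                   substr(r$peptide, r$coreStart + 1, r$coreStart + 9))
  # grouped split: no motif group spans train and test
  for (a in unique(r$allele)) {
    sub <- r[r$allele == a, ]
    both <- intersect(sub$group[sub$split == "train"],
                      sub$group[sub$split == "test"])
    expect_length(both, 0L)
  }
  s3 <- simulateDataset(nAlleles = 2, nPerAllele = 100, seed = 22)
  expect_false(identical(bindingRecords(s1), bindingRecords(s3)))
  # held-out alleles are fully held out
  sh <- simulateDataset(nAlleles = 1, nPerAllele = 30, nHeldoutAlleles = 1,
                        seed = 23)
  rh <- bindingRecords(sh)
  expect_identical(sort(unique(rh$split)), c("heldout", "test", "train"))
  expect_true(all(rh$split[rh$allele == names(syntheticAlleles(sh))[2]] ==
                    "heldout"))
})

test_that("implanted binder cores carry the allele's preferred residues", {
  sim <- simulateDataset(nAlleles = 1, nPerAllele = 300, fracBinder = 1,
                         noiseSd = 0, seed = 31)
  r <- bindingRecords(sim)
  al <- syntheticAlleles(sim)[[1]]
  pfm <- pfmFromCores(r$group)
  anchors <- c(1, 4, 6, 9)
  expect_gt(mean(pfm$ic[anchors]), mean(pfm$ic[-anchors]))
  # binder affinities sit well above pure background affinities
  bg <- simulateDataset(nAlleles = 1, nPerAllele = 300, fracBinder = 0,
                        noiseSd = 0, seed = 31)
  expect_gt(mean(r$affinity), mean(bindingRecords(bg)$affinity))
})

test_that("written datasets round-trip through the parsers byte-identically", {
  tmp <- withr::local_tempdir()
  sim <- simulateDataset(nAlleles = 2, nPerAllele = 40, nHeldoutAlleles = 1,
                         seed = 41)
  d1 <- file.path(tmp, "a"); d2 <- file.path(tmp, "b")
  writeDataset(sim, d1)
  writeDataset(simulateDataset(nAlleles = 2, nPerAllele = 40,
                               nHeldoutAlleles = 1, seed = 41), d2)
  for (f in c("pseudo.txt", "train.txt", "test.txt", "heldout.txt",
              "cores.txt", "manifest.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  ps <- parsePseudoSequences(file.path(d1, "pseudo.txt"))
  expect_identical(ps, pseudoMap(sim))
  tr <- parseBindingData(file.path(d1, "train.txt"), ps)
  orig <- bindingRecords(sim)
  orig <- orig[orig$split == "train", ]
  expect_identical(tr$peptide, orig$peptide)
  expect_identical(tr$group, orig$group)
  expect_equal(tr$affinity, orig$affinity, tolerance = 1e-6)
  # core annotations are the binder complexes (BC2015-style benchmark)
  cb <- parseCoreBenchmark(file.path(d1, "cores.txt"), ps)
  expect_identical(nrow(cb), sum(bindingRecords(sim)$binder))
  expect_gt(nrow(cb), 0L)
})

test_that("heavy noise destroys the learnable signal (degradability)", {
  # the same peptides with noise_sd 10 carry almost no usable affinity
  # signal: correlation between noisy and clean targets collapses
  al0 <- makeAllele("X", seed = 51, noiseSd = 0)
  peps <- withSeed(52, samplePeptide(150, c(9, 22)))
  clean <- vapply(peps, function(p) trueAffinity(p, al0, 0)$affinity, 0)
  noisy <- withSeed(53, vapply(peps, function(p)
    trueAffinity(p, al0, noiseSd = 10)$affinity, 0))
  expect_lt(abs(pccScore(clean, noisy)), 0.3)
})
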