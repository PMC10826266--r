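test_that("embedding lookup zeroes pads and is deterministic", {
  cfg <- tinyConfig()
  ps <- tinyPseudo(1)
  m <- newBiclModel(peStrategy("none"), cfg, seed = 3)
  pad <- padPeptide("ACDEFGHIK", cfg$Lmax)
  e <- embedPair(pad, ps[[1]], m)
  expect_identical(dim(e$X), c(cfg$Lmax, cfg$d))
  expect_identical(dim(e$Y), c(34L, cfg$d))
  expect_true(all(e$X[seq_len(leftPad(pad)), ] == 0))
  e2 <- embedPair(pad, ps[[1]], m)
  expect_identical(e, e2)
  # pad row of the table is fixed at zero
  expect_true(all(modelParams(m)$embP[1, ] == 0))
})

test_that("pre-PE injection is plain matrix addition honouring the scope", {
  X <- matrix(as.numeric(1:6), 3); Y <- matrix(as.numeric(1:8), 4)
  px <- matrix(0.5, 3, 2); py <- matrix(0.25, 4, 2)
  o <- applyPrePE(X, Y, px, py, "T")
  expect_equal(o$X, X + px)
  expect_equal(o$Y, Y + py)
  oO <- applyPrePE(X, Y, px, py, "O")
  expect_identical(oO$Y, Y)
  z <- applyPrePE(X, Y, 0 * px, 0 * py, "T")
  expect_identical(z$X, X)
  expect_error(applyPrePE(X, Y, t(px), py, "O"), "shape")
})

test_that("biclForward matches the triple-loop oracle on random instances", {
  d <- 4L
  for (rep in 1:20) {
    withSeed(1000 + rep, {
      L <- sample(11:14, 1)
      s <- sample(c(9L, 11L), 1)
      h <- sample(2:5, 1)
      X <- matrix(rnorm(L * d), L, d)
      Y <- matrix(rnorm(34 * d), 34, d)
      W <- array(rnorm(h * s * 34, sd = 0.2), c(h, s, 34))
      b <- rnorm(h, sd = 0.1)
      C <- biclForward(X, Y, list(list(W = W, b = b)))[[1]]
      expect_equal(C, oracleBicl(X, Y, W, b), tolerance = 1e-5)
      expect_true(all(C >= 0))
      expect_identical(dim(C), c(L - s + 1L, h))
    })
  }
  expect_error(biclForward(matrix(0, 5, d), matrix(0, 34, d),
                           list(list(W = array(0, c(2, 9, 34)),
                                     b = numeric(2)))),
               "shorter than kernel")
})

test_that("post-PE operators match loop oracles and reduce to zero", {
  d <- 4L
  pe <- directPE(padPeptide("ACDEFGHIKLM", 13), d)
  peY <- pseudoPE(d)
  for (rep in 1:10) {
    withSeed(2000 + rep, {
      h <- sample(2:4, 1); s <- 9L
      Wo <- array(rnorm(h * s * d, sd = 0.3), c(h, s, d))
      bo <- rnorm(h, sd = 0.1)
      expect_equal(postPeO(pe, list(list(W = Wo, b = bo)))[[1]],
                   oraclePeConv(pe, Wo, bo), tolerance = 1e-5)
      Wt <- array(rnorm(h * s * 34, sd = 0.2), c(h, s, 34))
      bt <- rnorm(h, sd = 0.1)
      expect_equal(postPeT(pe, peY, list(list(W = Wt, b = bt)))[[1]],
                   oracleBicl(pe, peY, Wt, bt), tolerance = 1e-5)
    })
  }
  zeroW <- list(list(W = array(0, c(3, 9, d)), b = numeric(3)))
  expect_true(all(postPeO(pe, zeroW)[[1]] == 0))
  zeroT <- list(list(W = array(0, c(3, 9, 34)), b = numeric(3)))
  expect_true(all(postPeT(pe, peY, zeroT)[[1]] == 0))
  # postPeT is literally the BICL contract on PE inputs
  withSeed(5, {
    Wt <- array(rnorm(3 * 9 * 34, sd = 0.2), c(3, 9, 34))
    bt <- rnorm(3)
    expect_identical(postPeT(pe, peY, list(list(W = Wt, b = bt))),
                     biclForward(pe, peY, list(list(W = Wt, b = bt))))
  })
})

test_that("combineInfoRep adds per-size blocks elementwise", {
  A <- list(matrix(1:4, 2), matrix(5:8, 2))
  B <- list(matrix(0.5, 2, 2), matrix(0.25, 2, 2))
  expect_identical(combineInfoRep(A), A)
  expect_equal(combineInfoRep(A, B)[[2]], A[[2]] + B[[2]])
  expect_equal(combineInfoRep(A, B), combineInfoRep(B, A))
  expect_error(combineInfoRep(A, B[1]), "length")
  expect_error(combineInfoRep(A, list(matrix(0, 3, 2), B[[2]])), "shape")
})

test_that("affinity head maps to [0,1] deterministically for both designs", {
  ps <- tinyPseudo(1)
  for (headType in c("windowed", "pooled")) {
    cfg <- tinyConfig(head = headType)
    m <- newBiclModel(peStrategy("none"), cfg, seed = 11)
    f <- forwardPair(m, "ACDEFGHIKLM", ps[[1]])
    expect_true(f$affinity >= 0 && f$affinity <= 1)
    f2 <- forwardPair(m, "ACDEFGHIKLM", ps[[1]])
    expect_identical(f$affinity, f2$affinity)
  }
})

test_that("max-pooled features are monotone in uniform activation shifts", {
  withSeed(21, {
    C <- list(matrix(runif(12), 4), matrix(runif(8), 2))
    f0 <- panMHCII:::.pooledFeatures(C)
    f1 <- panMHCII:::.pooledFeatures(lapply(C, function(M) M + 0.3))
    expect_true(all(f1 >= f0))
  })
})

test_that("core scoring masks pad windows and reports unpadded offsets", {
  cfg <- tinyConfig()
  ps <- tinyPseudo(1)
  m <- newBiclModel(peStrategy("none"), cfg, seed = 2)
  for (n in 9:14) {
    pep <- withSeed(n, paste(sample(aminoAcids(), n, TRUE), collapse = ""))
    f <- forwardPair(m, pep, ps[[1]])
    expect_length(f$coreScores, n - 8L)
    expect_true(f$coreStart >= 0 && f$coreStart + 9 <= n)
  }
  # length 9: a single admissible window, trivially the argmax
  f9 <- forwardPair(m, "ACDEFGHIK", ps[[1]])
  expect_identical(f9$coreStart, 0L)
})

test_that("predictCoreFromScores takes the smallest argmax", {
  expect_identical(predictCoreFromScores(c(0.1, 0.9, 0.2)), 1L)
  expect_identical(predictCoreFromScores(c(0.7, 0.2, 0.7)), 0L)
  expect_error(predictCoreFromScores(numeric(0)), "empty")
})

test_that("all 8 strategies and the baseline run on every peptide length", {
  ps <- tinyPseudo(1)
  cfg <- modelConfig(d = 4L, Lmax = 26L, kernelSizes = c(9L, 11L),
                     kernelCounts = c(4L, 3L))
  for (st in allPEStrategies()) {
    m <- newBiclModel(st, cfg, seed = 5)
    for (n in 9:22) {
      pep <- withSeed(n, paste(sample(aminoAcids(), n, TRUE), collapse = ""))
      f <- forwardPair(m, pep, ps[[1]])
      expect_true(is.finite(f$affinity) && f$affinity >= 0 &&
                    f$affinity <= 1)
      expect_true(all(unlist(f$C) >= 0))   # rectifier output
    }
  }
})

test_that("zero-PE pre-strategies reproduce the baseline bit-identically", {
  # the calibrated/direct pre-PE model with its PE matrices forced to zero
  # is the baseline computation; emulate by padZero + a peptide with no pads
  ps <- tinyPseudo(1)
  cfg <- tinyConfig()
  base <- newBiclModel(peStrategy("none"), cfg, seed = 8)
  for (scope in c("O", "T")) {
    pre <- newBiclModel(peStrategy("calibrated", "pre", scope), cfg, seed = 8)
    pre@params <- base@params      # same weights
    pad <- padPeptide("ACDEFGHIKLM", cfg$Lmax)
    emb <- embedPair(pad, ps[[1]], base)
    zx <- matrix(0, cfg$Lmax, cfg$d); zy <- matrix(0, 34, cfg$d)
    o <- applyPrePE(emb$X, emb$Y, zx, zy, scope)
    expect_identical(biclForward(o$X, o$Y, base@params$conv),
                     biclForward(emb$X, emb$Y, base@params$conv))
  }
})

test_that("zero-weight post-strategies reproduce the baseline", {
  ps <- tinyPseudo(2)
  cfg <- tinyConfig()
  recs <- tinyRecords(10, ps, seed = 31)
  base <- newBiclModel(peStrategy("none"), cfg, seed = 12)
  for (scope in c("O", "T")) {
    post <- newBiclModel(peStrategy("direct", "post", scope), cfg, seed = 12)
    post@params$embP <- base@params$embP
    post@params$embQ <- base@params$embQ
    post@params$conv <- base@params$conv
    post@params$W2 <- base@params$W2
    post@params$b2 <- base@params$b2
    post@params$wLen <- base@params$wLen
    slot <- if (scope == "O") "postO" else "postT"
    post@params[[slot]] <- lapply(post@params[[slot]], function(k) {
      k$W[] <- 0; k$b[] <- 0; k
    })
    expect_identical(predictAffinity(post, recs, ps),
                     predictAffinity(base, recs, ps))
    expect_identical(predictBindingCore(post, recs, ps)$coreStart,
                     predictBindingCore(base, recs, ps)$coreStart)
  }
})
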