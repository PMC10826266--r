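# Independent brute-force oracles and tiny fixtures shared across tests.

# scalar-loop sinusoidal encoding: explicit even/odd dimension pairs
# sin(pos / 1000^(2k/d)), cos(pos / 1000^((2k+1)/d))
oracleSinRow <- function(pos, d) {
  out <- numeric(d)
  for (k in 0:(d / 2 - 1)) {
    out[2 * k + 1] <- sin(pos / 1000^((2 * k) / d))
    out[2 * k + 2] <- cos(pos / 1000^((2 * k + 1) / d))
  }
  out
}

# triple-loop BICL oracle: kernels f(W Y), valid convolution over X
oracleBicl <- function(X, Y, W, b) {
  h <- dim(W)[1]; s <- dim(W)[2]; d <- ncol(X)
  L <- nrow(X); P <- L - s + 1
  K <- array(0, c(h, s, d))
  for (i in 1:h) for (a in 1:s) for (bb in 1:d)
    K[i, a, bb] <- max(0, sum(W[i, a, ] * Y[, bb]))
  C <- matrix(0, P, h)
  for (p in 1:P) for (i in 1:h) {
    acc <- b[i]
    for (a in 1:s) for (bb in 1:d)
      acc <- acc + K[i, a, bb] * X[p + a - 1, bb]
    C[p, i] <- max(0, acc)
  }
  C
}

# loop oracle for the peptide-only PE convolution (no kernel generation)
oraclePeConv <- function(peX, W, b) {
  h <- dim(W)[1]; s <- dim(W)[2]; d <- ncol(peX)
  P <- nrow(peX) - s + 1
  C <- matrix(0, P, h)
  for (p in 1:P) for (i in 1:h) {
    acc <- b[i]
    for (a in 1:s) for (bb in 1:d)
      acc <- acc + W[i, a, bb] * peX[p + a - 1, bb]
    C[p, i] <- max(0, acc)
  }
  C
}

# exhaustive pair-counting AUC with tied pairs worth 1/2
oracleAUC <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# window-scoring oracle for the synthetic ground truth
oracleBestWindow <- function(peptide, pwm) {
  idx <- tokenIndex(strsplit(peptide, "", fixed = TRUE)[[1]])
  n <- length(idx)
  e <- vapply(0:(n - 9), function(off) {
    tot <- 0
    for (j in 1:9) tot <- tot + pwm[j, idx[off + j]]
    tot
  }, numeric(1))
  list(energies = e, best = which.max(e) - 1L)
}

# small model configuration keeping unit tests fast
tinyConfig <- function(...) {
  modelConfig(d = 4L, Lmax = 14L, kernelSizes = c(9L, 11L),
              kernelCounts = c(6L, 4L), ...)
}

# deterministic pseudo-sequence table with n alleles
tinyPseudo <- function(n = 2L, seed = 404L) {
  withSeed(seed, {
    ps <- vapply(seq_len(n), function(i)
      paste(sample(aminoAcids(), 34, replace = TRUE), collapse = ""),
      character(1))
    names(ps) <- paste0("AL", seq_len(n))
    ps
  })
}

# random record table over the tiny pseudo map
tinyRecords <- function(n, pseudo, seed = 99L, lengthRange = c(9L, 14L)) {
  withSeed(seed, {
    data.frame(peptide = samplePeptide(n, lengthRange),
               affinity = runif(n),
               allele = sample(names(pseudo), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
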