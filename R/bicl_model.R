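#' Model hyperparameter configuration
#'
#' Defaults follow the published setup: embedding width d = 16, four kernel
#' sizes 9/11/13/15 with 256/128/64/64 MHC-conditioned kernels, ReLU
#' activation.  The frame length `Lmax = 26` (max peptide 22 plus two
#' context positions per side) and the affinity head (global max-pool per
#' kernel, one hidden rectified layer of width 256, logistic output) are
#' package choices inherited from the DeepMHCII lineage.
#'
#' @param d even embedding width
#' @param Lmax padded frame length (>= 22)
#' @param kernelSizes integer vector of convolution window sizes
#' @param kernelCounts number of kernels per size (same length)
#' @param head `"windowed"` scores every admissible 9-mer core window by a
#'   learned combination of the size-9 kernels at the window and the larger
#'   kernels centred on it (core plus symmetric flanks), and takes
#'   `plogis(max)` over windows, so affinity prediction and core
#'   localisation share one mechanism; `"pooled"` is the
#'   max-pool-per-kernel head with a dense hidden layer
#' @param windowPooling how the windowed head reduces per-window logits to
#'   one affinity: `"logsumexp"` treats the windows as competing binding
#'   registers and pools them like a Boltzmann ensemble (smooth, dense
#'   gradients), `"max"` scores only the single best register
#' @param windowTemp temperature of the log-sum-exp register ensemble
#'   (logit units; smaller is closer to the hard max)
#' @param hidden width of the pooled head's hidden layer (ignored by the
#'   windowed head; 0 gives a linear pooled head)
#' @param dropout training-time dropout rate on the kernel feature vector
#'   (inverted dropout; inactive at prediction time)
#' @param peConvention `"paper"` (base 1000, asymmetric cosine exponent) or
#'   `"transformer"`; see [sinusoidalRow()]
#' @param padZeroPE encode pad positions as all-zero rows instead of the
#'   position-0 sinusoid in calibrated PE
#' @param sharedEmbedding use one embedding table for peptide and
#'   pseudo-sequence instead of two separate tables
#' @param coreScoring `"contribution"` weights each size-9 kernel's
#'   activation by its contribution to the predicted affinity (the head
#'   gradient with respect to the pooled feature), so the score of a window
#'   is the model's own per-window binding strength; `"mean"` is the plain
#'   unweighted kernel average
#' @param coreFromCombined score binding cores from the combined
#'   information-representation matrix C (post-PE influences core calls);
#'   FALSE restricts core scoring to C_Emb
#' @return a validated configuration list
#' @export
modelConfig <- function(d = 16L, Lmax = 26L,
                        kernelSizes = c(9L, 11L, 13L, 15L),
                        kernelCounts = c(256L, 128L, 64L, 64L),
                        head = c("windowed", "pooled"),
                        windowPooling = c("logsumexp", "max"),
                        windowTemp = 1, hidden = 256L, dropout = 0.2,
                        peConvention = c("paper", "transformer"),
                        padZeroPE = FALSE, sharedEmbedding = FALSE,
                        coreScoring = c("contribution", "mean"),
                        coreFromCombined = TRUE) {
  peConvention <- match.arg(peConvention)
  coreScoring <- match.arg(coreScoring)
  head <- match.arg(head)
  windowPooling <- match.arg(windowPooling)
  if (windowTemp <= 0) stop("windowTemp must be > 0")
  if (head == "windowed" && any(kernelSizes %% 2L == 0L))
    stop("the windowed head needs odd kernel sizes (symmetric flanks)")
  if (d %% 2L != 0L) stop("d must be even")
  if (length(kernelSizes) != length(kernelCounts))
    stop("kernelSizes and kernelCounts must pair up")
  if (Lmax < max(kernelSizes)) stop("Lmax smaller than the largest kernel")
  if (!9L %in% kernelSizes)
    stop("a size-9 kernel bank is required for binding-core scoring")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  list(d = as.integer(d), Lmax = as.integer(Lmax),
       kernelSizes = as.integer(kernelSizes),
       kernelCounts = as.integer(kernelCounts), head = head,
       windowPooling = windowPooling, windowTemp = windowTemp,
       hidden = as.integer(hidden), dropout = dropout,
       peConvention = peConvention, padZeroPE = isTRUE(padZeroPE),
       sharedEmbedding = isTRUE(sharedEmbedding), coreScoring = coreScoring,
       coreFromCombined = isTRUE(coreFromCombined))
}

# Glorot-style uniform init on the effective fan of each linear map.
#' @keywords internal
.glorot <- function(dims, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

#' Construct an untrained BICL model
#'
#' Initialises all weights with a fan-based uniform (Glorot-style) scheme
#' under the given seed; the pad row of each embedding table is fixed at
#' zero and never updated.  Which parameter groups exist depends on the
#' strategy: post-PE strategies carry separate injector weights
#' (a peptide-PE convolution bank for scope "O", a second kernel-generator
#' bank driven by the pseudo-sequence PE for scope "T").
#'
#' @param strategy a [peStrategy()] descriptor
#' @param config a [modelConfig()] list
#' @param seed integer initialisation seed
#' @return a [BiclModel-class]
#' @examples
#' m <- newBiclModel(peStrategy("calibrated", "pre", "T"), seed = 1)
#' m
#' @export
newBiclModel <- function(strategy = peStrategy("none"),
                         config = modelConfig(), seed = 1L) {
  stopifnot(is.list(strategy), is.list(config))
  d <- config$d
  params <- withSeed(as.integer(seed), {
    p <- list()
    p$embP <- .glorot(c(21L, d), 21, d)
    p$embP[1L, ] <- 0
    if (!config$sharedEmbedding) {
      p$embQ <- .glorot(c(21L, d), 21, d)
      p$embQ[1L, ] <- 0
    }
    p$conv <- .initKernelBank(config, fanIn34 = TRUE)
    if (strategy$method != "none" && strategy$site == "post") {
      if (strategy$scope == "O") {
        p$postO <- .initPeConvBank(config)
      } else {
        p$postT <- .initKernelBank(config, fanIn34 = TRUE)
      }
    }
    nFeat <- sum(config$kernelCounts)
    if (config$head == "pooled" && config$hidden > 0L) {
      p$W1 <- .glorot(c(nFeat, config$hidden), nFeat, config$hidden)
      p$b1 <- numeric(config$hidden)
      p$W2 <- as.numeric(.glorot(c(config$hidden), config$hidden, 1))
    } else {
      p$W2 <- as.numeric(.glorot(c(nFeat), nFeat, 1))
    }
    if (config$head == "windowed") p$wLen <- 0   # PFR-count coefficient
    p$b2 <- 0
    p
  })
  new("BiclModel", params = params, strategy = strategy, config = config,
      seed = as.integer(seed))
}

#' @keywords internal
.initKernelBank <- function(config, fanIn34 = TRUE) {
  mapply(function(s, h) {
    list(W = .glorot(c(h, s, 34L), 34, config$d), b = numeric(h))
  }, config$kernelSizes, config$kernelCounts, SIMPLIFY = FALSE)
}

#' @keywords internal
.initPeConvBank <- function(config) {
  mapply(function(s, h) {
    list(W = .glorot(c(h, s, config$d), s * config$d, 1), b = numeric(h))
  }, config$kernelSizes, config$kernelCounts, SIMPLIFY = FALSE)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so package internals never perturb a user's
#' random stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @export
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## --- single-instance operations (the reference semantics) -----------------

#' Embed a padded peptide and a pseudo-sequence
#'
#' Looks up each token's row in the learned embedding tables; pad tokens
#' (index 0) map to the fixed all-zero row.
#'
#' @param padded a [PaddedPeptide-class]
#' @param pseudoSeq a 34-residue pseudo-sequence string
#' @param model a [BiclModel-class]
#' @return list with `X` (`Lmax x d`) and `Y` (`34 x d`) embedding matrices
#' @export
embedPair <- function(padded, pseudoSeq, model) {
  p <- model@params
  embQ <- if (model@config$sharedEmbedding) p$embP else p$embQ
  X <- p$embP[peptideIndices(padded) + 1L, , drop = FALSE]
  Y <- embQ[tokenIndex(strsplit(pseudoSeq, "", fixed = TRUE)[[1L]]) + 1L, ,
            drop = FALSE]
  list(X = X, Y = Y)
}

#' Inject positional encodings before the convolution (pre-PE)
#'
#' Adds the peptide PE matrix to the peptide embedding and, under scope
#' `"T"`, the pseudo-sequence PE matrix to the MHC embedding.
#'
#' @param X,Y embedding matrices (`L x d` and `34 x d`)
#' @param peX,peY positional-encoding matrices of matching shape
#' @param scope `"O"` (peptide only) or `"T"` (both)
#' @return list with the combined `X` and `Y`
#' @export
applyPrePE <- function(X, Y, peX, peY, scope = c("O", "T")) {
  scope <- match.arg(scope)
  if (!all(dim(X) == dim(peX))) stop("peX shape does not match X")
  if (scope == "T" && !all(dim(Y) == dim(peY)))
    stop("peY shape does not match Y")
  list(X = X + peX, Y = if (scope == "T") Y + peY else Y)
}

# im2col: L x d matrix -> (L-s+1) x (s*d) window matrix, column (a,b) at
# index (a-1)*d + b.
#' @keywords internal
.im2col <- function(X, s) {
  L <- nrow(X); d <- ncol(X); P <- L - s + 1L
  idx <- as.vector(outer(seq_len(s), 0:(P - 1L), "+"))
  Xw <- X[idx, , drop = FALSE]
  dim(Xw) <- c(s, P, d)
  M <- aperm(Xw, c(2L, 3L, 1L))
  dim(M) <- c(P, d * s)
  M
}

# (h, s, d) kernel array -> (s*d) x h matrix aligned with .im2col columns.
#' @keywords internal
.kernelMat <- function(K) {
  dm <- dim(K)
  Km <- aperm(K, c(3L, 2L, 1L))
  dim(Km) <- c(dm[2L] * dm[3L], dm[1L])
  Km
}

#' Binding-interaction convolution (BICL) forward pass
#'
#' The layer first generates MHC-conditioned kernels
#' `K = f(W^k Y)` of shape `h^k x s^k x d` from the pseudo-sequence
#' representation `Y`, then slides them over the peptide representation
#' `X` in a valid convolution:
#' `C[p, h] = f( sum_{a,b} K[h,a,b] X[p+a, b] + b^k[h] )`,
#' with `f` the rectifier.  One information-representation matrix of shape
#' `(L - s^k + 1) x h^k` is produced per kernel size.
#'
#' @param X peptide representation, `L x d`
#' @param Y MHC representation, `34 x d`
#' @param bank kernel bank: list per size of `list(W, b)` with `W` an
#'   `h x s x 34` array (as in `modelParams(model)$conv`)
#' @return list (one per kernel size) of non-negative matrices
#'   `(L - s + 1) x h`
#' @export
biclForward <- function(X, Y, bank) {
  lapply(bank, function(k) {
    h <- dim(k$W)[1L]; s <- dim(k$W)[2L]
    if (nrow(X) < s) stop("peptide frame shorter than kernel size ", s)
    Wm <- k$W
    dim(Wm) <- c(h * s, 34L)
    Kf <- pmax(Wm %*% Y, 0)            # generated kernels, (h*s) x d
    dim(Kf) <- c(h, s, ncol(Y))
    M <- .im2col(X, s)
    P <- nrow(M)
    C <- M %*% .kernelMat(Kf) + rep(k$b, each = P)
    pmax(C, 0)
  })
}

#' Post-convolution PE injection, peptide-only (scope O)
#'
#' A plain learned 1D convolution over the peptide PE matrix; its output is
#' added to the BICL output.  `C_PE[p, h] = f(W_PE-O^k * peX at p + b)`.
#'
#' @param peX peptide PE matrix, `L x d`
#' @param weights list per size of `list(W, b)` with `W` an `h x s x d`
#'   array (as in `modelParams(model)$postO`)
#' @return list of non-negative `(L - s + 1) x h` matrices
#' @export
postPeO <- function(peX, weights) {
  lapply(weights, function(k) {
    s <- dim(k$W)[2L]
    M <- .im2col(peX, s)
    P <- nrow(M)
    pmax(M %*% .kernelMat(k$W) + rep(k$b, each = P), 0)
  })
}

#' Post-convolution PE injection, peptide and MHC (scope T)
#'
#' Reuses the BICL structure with the PE matrices as inputs: kernels are
#' generated from the pseudo-sequence PE and convolved over the peptide PE.
#'
#' @param peX peptide PE matrix, `L x d`
#' @param peY pseudo-sequence PE matrix, `34 x d`
#' @param weights list per size of `list(W, b)`, `W` an `h x s x 34` array
#' @return list of non-negative `(L - s + 1) x h` matrices
#' @export
postPeT <- function(peX, peY, weights) {
  biclForward(peX, peY, weights)
}

#' Combine embedding and PE information-representation matrices
#'
#' Elementwise `C = C_Emb + C_PE`; with `Cpe = NULL` (baseline and pre-PE
#' strategies) `C_Emb` is returned unchanged.
#'
#' @param Cemb,Cpe lists of per-size matrices of matching shape
#' @return list of per-size matrices
#' @export
combineInfoRep <- function(Cemb, Cpe = NULL) {
  if (is.null(Cpe)) return(Cemb)
  if (length(Cemb) != length(Cpe)) stop("per-size lists differ in length")
  mapply(function(a, b) {
    if (!all(dim(a) == dim(b))) stop("InfoRep shape mismatch")
    a + b
  }, Cemb, Cpe, SIMPLIFY = FALSE)
}

#' Affinity head: information-representation matrices to a score in \[0, 1\]
#'
#' The default windowed head assigns every admissible 9-mer core window a
#' logit `t_p = b + sum_k w_k . C_k[p - o_k, ]`, combining the size-9
#' kernels at the window with the larger kernels centred on it (offset
#' `o_k = (s_k - 9)/2`, i.e. core plus symmetric flanking context), and
#' returns `plogis(max_p t_p)`; the maximising window is the predicted
#' binding core, so affinity and core share one mechanism.  The pooled
#' head max-pools each kernel over its admissible windows, concatenates
#' across sizes and applies a dense (optionally hidden) logistic layer.
#' Admissible windows are those covering at least one complete 9-mer of
#' the unpadded peptide (all windows when `padded` is NULL).
#'
#' @param C list of per-size information-representation matrices
#' @param model a [BiclModel-class] (its head weights are used)
#' @param padded optional [PaddedPeptide-class] enabling the admissible
#'   window mask
#' @return scalar predicted affinity in \[0, 1\]
#' @export
affinityHead <- function(C, model, padded = NULL) {
  p <- model@params
  if (model@config$head == "windowed") {
    t <- .windowLogits(C, model, padded)
    tau <- model@config$windowTemp
    zpre <- if (model@config$windowPooling == "logsumexp") {
      mx <- max(t)
      mx + tau * log(sum(exp((t - mx) / tau)))
    } else max(t)
    if (!is.null(padded))
      zpre <- zpre + p$wLen * (trueLength(padded) - 9L)
    return(stats::plogis(zpre))
  }
  feat <- .pooledFeatures(C, padded)
  if (model@config$hidden > 0L) {
    hid <- pmax(as.vector(feat %*% p$W1) + p$b1, 0)
    stats::plogis(sum(hid * p$W2) + p$b2)
  } else {
    stats::plogis(sum(feat * p$W2) + p$b2)
  }
}

# per-window logits of the windowed head; returns the vector t_p over
# admissible 9-mer windows, named by 0-based unpadded window starts.
#' @keywords internal
.windowLogits <- function(C, model, padded = NULL) {
  cfg <- model@config
  w <- model@params$W2
  sizes <- cfg$kernelSizes
  counts <- cfg$kernelCounts
  colOff <- c(0L, cumsum(counts))
  P9 <- nrow(C[[match(9L, sizes)]])
  t <- rep(model@params$b2, P9)
  for (k in seq_along(sizes)) {
    o <- (sizes[k] - 9L) %/% 2L
    Pk <- nrow(C[[k]])
    wk <- w[(colOff[k] + 1L):colOff[k + 1L]]
    t[(o + 1L):(o + Pk)] <- t[(o + 1L):(o + Pk)] + as.vector(C[[k]] %*% wk)
  }
  if (!is.null(padded)) {
    lo <- leftPad(padded) + 1L
    hi <- leftPad(padded) + trueLength(padded) - 8L
    t <- t[lo:hi]
    names(t) <- as.character(seq_along(t) - 1L)
  }
  t
}

# max-pool each per-size matrix over its admissible windows (all windows
# when padded is NULL) and concatenate.
#' @keywords internal
.pooledFeatures <- function(C, padded = NULL) {
  unlist(lapply(C, function(M) {
    if (!is.null(padded)) {
      s <- length(peptideIndices(padded)) - nrow(M) + 1L
      lo <- max(1L, leftPad(padded) + 10L - s)
      hi <- min(nrow(M), leftPad(padded) + trueLength(padded) - 8L)
      M <- M[lo:hi, , drop = FALSE]
    }
    apply(M, 2L, max)
  }), use.names = FALSE)
}

# gradient of the pre-logistic affinity with respect to the pooled feature
# vector; the per-kernel "contribution weights" used by core scoring.
#' @keywords internal
.headFeatureGrad <- function(params, config, feat) {
  if (config$hidden > 0L) {
    act <- as.vector(feat %*% params$W1) + params$b1 > 0
    as.vector(params$W1 %*% (params$W2 * act))
  } else {
    params$W2
  }
}

#' Per-window binding-core scores
#'
#' Aggregates the size-9 kernel block of the combined
#' information-representation matrix into one score per 9-mer window,
#' reported only for windows that lie fully inside the unpadded peptide.
#' With `weights = NULL` the aggregate is the plain kernel mean; with a
#' weight vector (one per size-9 kernel, typically the head gradient of
#' the predicted affinity with respect to the pooled features) it is the
#' weighted sum, i.e. the model's per-window binding strength.
#'
#' @param C list of per-size matrices (from a forward pass)
#' @param padded the [PaddedPeptide-class] the pass was run on
#' @param kernelSizes the model's kernel sizes (to locate the size-9 block)
#' @param weights optional per-kernel weight vector
#' @return numeric vector of length `L' - 8`, named by 0-based unpadded
#'   window starts
#' @export
coreWindowScores <- function(C, padded, kernelSizes = c(9L, 11L, 13L, 15L),
                             weights = NULL) {
  k9 <- match(9L, kernelSizes)
  if (is.na(k9)) stop("no size-9 kernel block in this model")
  sc <- if (is.null(weights)) rowMeans(C[[k9]])
  else as.vector(C[[k9]] %*% weights)
  lp <- leftPad(padded); n <- trueLength(padded)
  valid <- (lp + 1L):(lp + n - 8L)     # padded-frame window starts
  out <- sc[valid]
  names(out) <- as.character(seq_along(valid) - 1L)
  out
}

#' Pick the binding core from window scores
#'
#' @param scores numeric vector of per-window scores in unpadded
#'   coordinates (as from [coreWindowScores()])
#' @return 0-based core start; ties resolved to the smallest index
#' @export
predictCoreFromScores <- function(scores) {
  if (!length(scores)) stop("empty score vector")
  unname(which.max(scores)) - 1L
}

#' Full single-pair forward pass
#'
#' Reference-path prediction for one peptide/allele pair, composing the
#' exported building blocks exactly as the strategy dictates.  The batched
#' trainer follows the same semantics.
#'
#' @param model a [BiclModel-class]
#' @param peptide peptide string
#' @param pseudoSeq 34-residue pseudo-sequence
#' @return list: `affinity` (scalar), `coreStart` (0-based), `coreScores`,
#'   and the combined per-size matrices `C`
#' @export
forwardPair <- function(model, peptide, pseudoSeq) {
  cfg <- model@config
  st <- model@strategy
  padded <- padPeptide(peptide, cfg$Lmax)
  emb <- embedPair(padded, pseudoSeq, model)
  X <- emb$X; Y <- emb$Y
  peX <- peY <- NULL
  if (st$method != "none") {
    peX <- if (st$method == "direct")
      directPE(padded, cfg$d, cfg$peConvention)
    else calibratedPE(padded, cfg$d, cfg$peConvention, cfg$padZeroPE)
    peY <- pseudoPE(cfg$d, cfg$peConvention)
  }
  Cpe <- NULL
  if (st$method != "none" && st$site == "pre") {
    pre <- applyPrePE(X, Y, peX, peY, st$scope)
    X <- pre$X; Y <- pre$Y
  }
  Cemb <- biclForward(X, Y, model@params$conv)
  if (st$method != "none" && st$site == "post") {
    Cpe <- if (st$scope == "O") postPeO(peX, model@params$postO)
    else postPeT(peX, peY, model@params$postT)
  }
  C <- combineInfoRep(Cemb, Cpe)
  if (cfg$head == "windowed") {
    ## the windowed head scores cores from the same combined matrices that
    ## drive the affinity, so the two predictions are one mechanism
    scores <- .windowLogits(C, model, padded)
  } else {
    Ccore <- if (cfg$coreFromCombined) C else Cemb
    w9 <- NULL
    if (cfg$coreScoring == "contribution") {
      feat <- .pooledFeatures(C, padded)
      k9 <- match(9L, cfg$kernelSizes)
      cols <- (c(0L, cumsum(cfg$kernelCounts))[k9] + 1L):
        cumsum(cfg$kernelCounts)[k9]
      w9 <- .headFeatureGrad(model@params, cfg, feat)[cols]
    }
    scores <- coreWindowScores(Ccore, padded, cfg$kernelSizes, w9)
  }
  list(affinity = affinityHead(C, model, padded),
       coreStart = predictCoreFromScores(scores),
       coreScores = scores, C = C)
}
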