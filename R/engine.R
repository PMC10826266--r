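# Batched forward/backward engine.
#
# The exported single-pair operations in bicl_model.R define the semantics;
# this file reimplements them as grouped BLAS matrix products so training is
# tractable on one CPU.  Batches are grouped by allele (kernels are
# generated once per allele) and by positional-encoding layout (calibrated
# PE depends only on the pad split, so per-layout PE convolutions are
# computed once and reused).  Equality of the two paths is asserted in the
# test suite.
#
# Layout conventions (all 1-based):
#   Xall   (B*Lmax) x d, sample-major: row (i-1)*Lmax + t = token t of sample i
#   M^k    (B*P) x (s*d), window-major: row p + (i-1)*P, column (a-1)*d + b
#   C^k    (B*P) x h

# forward pass over a batch.
#   enc       from .encodePeptides
#   alleleOf  integer vector (length B) indexing YidxList
#   YidxList  list of 34-token index vectors, one per allele
#' @keywords internal
.batchForward <- function(params, config, strategy, enc, alleleOf, YidxList,
                          wantCache = FALSE, wantCore = FALSE,
                          dropMask = NULL) {
  B <- nrow(enc$idx); Lmax <- config$Lmax; d <- config$d
  sizes <- config$kernelSizes; counts <- config$kernelCounts
  st <- strategy
  peY <- if (st$method != "none") pseudoPE(d, config$peConvention) else NULL
  embQ <- if (config$sharedEmbedding) params$embP else params$embQ
  groups <- split(seq_len(B), alleleOf)
  gAllele <- as.integer(names(groups))      # allele id of each group

  ## embeddings
  tIdx <- as.vector(t(enc$idx))                       # (t fast, i slow)
  Xall <- params$embP[tIdx + 1L, , drop = FALSE]
  Yidx <- lapply(gAllele, function(a) YidxList[[a]])
  Ylist <- lapply(Yidx, function(yi) embQ[yi + 1L, , drop = FALSE])

  ## positional encodings
  peVar <- NULL
  if (st$method != "none") {
    peVar <- .peVariants(st$method, Lmax, enc$leftPad, enc$trueLen, d,
                         config$peConvention, config$padZeroPE)
  }
  if (st$method != "none" && st$site == "pre") {
    peStack <- do.call(rbind, peVar$mats)
    rowIdx <- rep((peVar$variantOf - 1L) * Lmax, each = Lmax) +
      rep(seq_len(Lmax), B)
    Xall <- Xall + peStack[rowIdx, , drop = FALSE]
    if (st$scope == "T")
      Ylist <- lapply(Ylist, function(Y) Y + peY)
  }

  nSize <- length(sizes)
  Clist <- vector("list", nSize)
  Cemb9 <- NULL
  cache <- if (wantCache) list(M = vector("list", nSize),
                               Kf = vector("list", nSize),
                               CembPos = vector("list", nSize),
                               CpeV = vector("list", nSize),
                               MpeV = vector("list", nSize),
                               argP = vector("list", nSize)) else NULL
  feats <- vector("list", nSize)

  for (k in seq_len(nSize)) {
    s <- sizes[k]; h <- counts[k]; P <- Lmax - s + 1L
    ## im2col over the whole batch
    off <- rep((seq_len(B) - 1L) * Lmax, each = s * P)
    ap <- rep(as.vector(outer(seq_len(s), 0:(P - 1L), "+")), times = B)
    Xw <- Xall[off + ap, , drop = FALSE]
    dim(Xw) <- c(s, P * B, d)
    M <- aperm(Xw, c(2L, 3L, 1L))
    dim(M) <- c(P * B, d * s)

    ## MHC-conditioned kernels, one GEMM per allele
    Wm <- params$conv[[k]]$W
    dim(Wm) <- c(h * s, 34L)
    bk <- params$conv[[k]]$b
    Cpre <- matrix(0, P * B, h)
    Kfs <- vector("list", length(groups))
    for (g in seq_along(groups)) {
      Kf <- pmax(Wm %*% Ylist[[g]], 0)               # (h*s) x d
      Kfs[[g]] <- Kf
      KfArr <- Kf
      dim(KfArr) <- c(h, s, d)
      rows <- rep((groups[[g]] - 1L) * P, each = P) +
        rep(seq_len(P), length(groups[[g]]))
      Cpre[rows, ] <- M[rows, , drop = FALSE] %*% .kernelMat(KfArr)
    }
    Cpre <- Cpre + rep(bk, each = P * B)
    Cemb <- pmax(Cpre, 0)
    if (wantCore && s == 9L && !config$coreFromCombined) Cemb9 <- Cemb

    ## post-PE injection, once per PE layout
    C <- Cemb
    if (st$method != "none" && st$site == "post") {
      nv <- length(peVar$mats)
      CpeV <- MpeV <- vector("list", nv)
      for (v in seq_len(nv)) {
        Mpe <- .im2col(peVar$mats[[v]], s)
        MpeV[[v]] <- Mpe
        if (st$scope == "O") {
          CpeV[[v]] <- pmax(Mpe %*% .kernelMat(params$postO[[k]]$W) +
                              rep(params$postO[[k]]$b, each = P), 0)
        } else {
          Wt <- params$postT[[k]]$W
          dim(Wt) <- c(h * s, 34L)
          Kpe <- pmax(Wt %*% peY, 0)
          dim(Kpe) <- c(h, s, d)
          CpeV[[v]] <- pmax(Mpe %*% .kernelMat(Kpe) +
                              rep(params$postT[[k]]$b, each = P), 0)
        }
      }
      expand <- rep((peVar$variantOf - 1L) * P, each = P) +
        rep(seq_len(P), B)
      Cstack <- do.call(rbind, CpeV)
      C <- Cemb + Cstack[expand, , drop = FALSE]
      if (wantCache) { cache$CpeV[[k]] <- CpeV; cache$MpeV[[k]] <- MpeV }
    }
    Clist[[k]] <- C

    if (config$head == "pooled") {
      ## global max-pool over admissible window positions, tracking argmax.
      ## A window is admissible when it covers at least one complete 9-mer
      ## of the unpadded peptide (for s = 9 this is exactly the core-call
      ## mask); windows lying mostly in the pad region never feed the head.
      pLo <- pmax(1L, enc$leftPad + 10L - s)
      pHi <- pmin(P, enc$leftPad + enc$trueLen - 8L)
      Carr <- C
      dim(Carr) <- c(P, B, h)
      mx <- matrix(-Inf, B, h)
      ag <- matrix(1L, B, h)
      for (p in seq_len(P)) {
        cur <- matrix(Carr[p, , ], B, h)
        cur[p < pLo | p > pHi, ] <- -Inf
        upd <- cur > mx
        mx[upd] <- cur[upd]
        ag[upd] <- p
      }
      feats[[k]] <- mx
      if (wantCache) cache$argP[[k]] <- ag
    }
    if (wantCache) {
      cache$M[[k]] <- M
      cache$Kf[[k]] <- Kfs
      cache$CembPos[[k]] <- Cemb > 0
    }
  }

  colOff <- c(0L, cumsum(counts))
  if (config$head == "windowed") {
    ## per-window logits: size-9 kernels at the window plus larger kernels
    ## centred on it; windows are competing binding registers, pooled by
    ## log-sum-exp (Boltzmann ensemble) or hard max.  The top register is
    ## the predicted core.
    P9 <- Lmax - 8L
    SV <- numeric(P9 * B)
    CW <- vector("list", nSize)
    for (k in seq_len(nSize)) {
      s <- sizes[k]; o <- (s - 9L) %/% 2L; Pk <- Lmax - s + 1L
      wk <- params$W2[(colOff[k] + 1L):colOff[k + 1L]]
      Ck <- Clist[[k]]
      if (!is.null(dropMask))
        Ck <- Ck * dropMask[rep(seq_len(B), each = Pk),
                            (colOff[k] + 1L):colOff[k + 1L], drop = FALSE]
      V <- as.vector(Ck %*% wk)
      idxS <- rep((seq_len(B) - 1L) * P9, each = Pk) +
        rep((o + 1L):(o + Pk), B)
      SV[idxS] <- SV[idxS] + V
      if (wantCache) CW[[k]] <- Ck         # masked activations
    }
    Sm <- SV
    dim(Sm) <- c(P9, B)
    zpre <- numeric(B)
    argS <- integer(B)
    smW <- if (config$windowPooling == "logsumexp") matrix(0, P9, B)
    for (i in seq_len(B)) {
      lo <- enc$leftPad[i] + 1L
      hi <- enc$leftPad[i] + enc$trueLen[i] - 8L
      v <- Sm[lo:hi, i]
      m <- which.max(v)
      argS[i] <- lo + m - 1L
      if (config$windowPooling == "logsumexp") {
        e <- exp((v - v[m]) / config$windowTemp)
        se <- sum(e)
        zpre[i] <- v[m] + config$windowTemp * log(se) + params$b2
        smW[lo:hi, i] <- e / se
      } else {
        zpre[i] <- v[m] + params$b2
      }
      zpre[i] <- zpre[i] + params$wLen * (enc$trueLen[i] - 9L)
    }
    if (wantCache) {
      cache$CW <- CW
      cache$argS <- argS
      cache$smW <- smW
    }
    H1 <- NULL
    feat <- NULL
    Swin <- Sm
  } else {
    feat <- do.call(cbind, feats)                     # B x nFeat
    if (!is.null(dropMask)) feat <- feat * dropMask   # inverted dropout
    if (config$hidden > 0L) {
      H1pre <- feat %*% params$W1 + rep(params$b1, each = B)
      H1 <- pmax(H1pre, 0)
      zpre <- as.vector(H1 %*% params$W2) + params$b2
    } else {
      H1 <- NULL
      zpre <- as.vector(feat %*% params$W2) + params$b2
    }
  }
  z <- stats::plogis(zpre)

  out <- list(z = z)
  if (wantCore) {
    coreStart <- integer(B)
    coreScores <- vector("list", B)
    if (config$head == "windowed") {
      for (i in seq_len(B)) {
        lo <- enc$leftPad[i] + 1L
        hi <- enc$leftPad[i] + enc$trueLen[i] - 8L
        v <- Swin[lo:hi, i] + params$b2
        names(v) <- as.character(seq_along(v) - 1L)
        coreScores[[i]] <- v
        coreStart[i] <- argS[i] - lo
      }
    } else {
      k9 <- match(9L, sizes)
      C9 <- if (config$coreFromCombined) Clist[[k9]] else Cemb9
      P9 <- Lmax - 9L + 1L
      h9 <- counts[k9]
      cols9 <- (colOff[k9] + 1L):colOff[k9 + 1L]
      if (config$coreScoring == "contribution") {
        ## per-sample head gradient wrt the size-9 pooled features
        if (config$hidden > 0L) {
          gAct <- (H1 > 0) * rep(params$W2, each = B) # B x hidden
          w9 <- (gAct %*% t(params$W1))[, cols9, drop = FALSE]
        } else {
          w9 <- matrix(params$W2[cols9], B, h9, byrow = TRUE)
        }
      }
      for (i in seq_len(B)) {
        lp <- enc$leftPad[i]; n <- enc$trueLen[i]
        rows <- ((i - 1L) * P9 + lp + 1L):((i - 1L) * P9 + lp + n - 8L)
        v <- if (config$coreScoring == "contribution")
          as.vector(C9[rows, , drop = FALSE] %*% w9[i, ])
        else rowMeans(C9[rows, , drop = FALSE])
        names(v) <- as.character(seq_along(v) - 1L)
        coreScores[[i]] <- v
        coreStart[i] <- which.max(v) - 1L
      }
    }
    out$coreStart <- coreStart
    out$coreScores <- coreScores
  }
  if (wantCache) {
    cache$feat <- feat
    cache$dropMask <- dropMask
    cache$H1 <- H1
    cache$z <- z
    cache$groups <- groups
    cache$Ylist <- Ylist
    cache$Yidx <- Yidx
    cache$tIdx <- tIdx
    cache$peVar <- peVar
    cache$B <- B
    cache$peY <- peY
    cache$enc <- enc
    out$cache <- cache
  }
  out
}

# gradient of the scalar loss wrt all parameters; dz = dLoss/dz per sample.
# Returns a list with the same shape as params.
#' @keywords internal
.batchBackward <- function(params, config, strategy, cache, dz) {
  B <- cache$B; Lmax <- config$Lmax; d <- config$d
  sizes <- config$kernelSizes; counts <- config$kernelCounts
  st <- strategy
  groups <- cache$groups
  g <- list()

  ## head
  z <- cache$z
  dzpre <- dz * z * (1 - z)
  g$b2 <- sum(dzpre)
  if (config$head == "windowed") {
    g$W2 <- numeric(sum(counts))                      # filled per size below
    g$wLen <- sum(dzpre * (cache$enc$trueLen - 9L))
    dFeat <- NULL
  } else if (config$hidden > 0L) {
    g$W2 <- as.vector(crossprod(cache$H1, dzpre))
    dH1 <- outer(dzpre, params$W2) * (cache$H1 > 0)
    g$W1 <- crossprod(cache$feat, dH1)
    g$b1 <- colSums(dH1)
    dFeat <- dH1 %*% t(params$W1)                     # B x nFeat
    if (!is.null(cache$dropMask)) dFeat <- dFeat * cache$dropMask
  } else {
    g$W2 <- as.vector(crossprod(cache$feat, dzpre))
    dFeat <- outer(dzpre, params$W2)
    if (!is.null(cache$dropMask)) dFeat <- dFeat * cache$dropMask
  }

  dXall <- matrix(0, B * Lmax, d)
  dYlist <- lapply(cache$Ylist, function(Y) matrix(0, 34L, d))
  g$conv <- vector("list", length(sizes))
  if (!is.null(params$postO)) g$postO <- vector("list", length(sizes))
  if (!is.null(params$postT)) g$postT <- vector("list", length(sizes))

  colOff <- c(0L, cumsum(counts))
  for (k in seq_along(sizes)) {
    s <- sizes[k]; h <- counts[k]; P <- Lmax - s + 1L
    cols <- (colOff[k] + 1L):colOff[k + 1L]

    if (config$head == "windowed") {
      o <- (s - 9L) %/% 2L
      if (config$windowPooling == "logsumexp") {
        ## dense gradients: every admissible register gets its Boltzmann
        ## weight times the loss gradient
        dT <- cache$smW[(o + 1L):(o + P), , drop = FALSE] *
          rep(dzpre, each = P)                        # P x B
        vT <- as.vector(dT)
        wM <- matrix(params$W2[cols], P * B, h, byrow = TRUE)
        if (!is.null(cache$dropMask))
          wM <- wM * cache$dropMask[rep(seq_len(B), each = P), cols,
                                    drop = FALSE]
        dC <- vT * wM
        g$W2[cols] <- as.vector(crossprod(cache$CW[[k]], vT))
      } else {
        ## hard max: gradient enters each sample's argmax window only
        q <- cache$argS - o
        ok <- q >= 1L & q <= P
        dC <- matrix(0, P * B, h)
        if (any(ok)) {
          rows <- (which(ok) - 1L) * P + q[ok]
          wM <- matrix(params$W2[cols], sum(ok), h, byrow = TRUE)
          if (!is.null(cache$dropMask))
            wM <- wM * cache$dropMask[ok, cols, drop = FALSE]
          dC[rows, ] <- dzpre[ok] * wM
          g$W2[cols] <- as.vector(crossprod(
            cache$CW[[k]][rows, , drop = FALSE], dzpre[ok]))
        }
      }
    } else {
      ## scatter pooled gradients to the argmax windows
      dfeat <- dFeat[, cols, drop = FALSE]
      ag <- cache$argP[[k]]
      dC <- numeric(P * B * h)
      bI <- as.vector(row(ag)); hI <- as.vector(col(ag))
      lin <- as.vector(ag) + (bI - 1L) * P + (hI - 1L) * P * B
      dC[lin] <- as.vector(dfeat)
      dim(dC) <- c(P * B, h)
    }

    ## post-PE branch
    if (st$method != "none" && st$site == "post") {
      variantOf <- cache$peVar$variantOf
      nv <- length(cache$peVar$mats)
      db <- numeric(h)
      if (st$scope == "T") {
        Wt <- params$postT[[k]]$W
        dim(Wt) <- c(h * s, 34L)
        Kpe <- pmax(Wt %*% cache$peY, 0)              # (h*s) x d
        dKpeAcc <- matrix(0, d * s, h)
      } else {
        dWoAcc <- matrix(0, d * s, h)
      }
      for (v in seq_len(nv)) {
        members <- which(variantOf == v)
        if (!length(members)) next
        Sv <- matrix(0, P, h)
        for (i in members) {
          rows <- ((i - 1L) * P + 1L):(i * P)
          Sv <- Sv + dC[rows, , drop = FALSE]
        }
        dCpePre <- Sv * (cache$CpeV[[k]][[v]] > 0)
        db <- db + colSums(dCpePre)
        acc <- crossprod(cache$MpeV[[k]][[v]], dCpePre)  # (s*d) x h
        if (st$scope == "T") dKpeAcc <- dKpeAcc + acc else
          dWoAcc <- dWoAcc + acc
      }
      if (st$scope == "O") {
        dim(dWoAcc) <- c(d, s, h)
        g$postO[[k]] <- list(W = aperm(dWoAcc, c(3L, 2L, 1L)), b = db)
      } else {
        dim(dKpeAcc) <- c(d, s, h)
        dKf <- aperm(dKpeAcc, c(3L, 2L, 1L))
        dim(dKf) <- c(h * s, d)
        dKf <- dKf * (Kpe > 0)
        dWt <- dKf %*% t(cache$peY)                   # (h*s) x 34
        dim(dWt) <- c(h, s, 34L)
        g$postT[[k]] <- list(W = dWt, b = db)
      }
    }

    ## main BICL branch
    dCembPre <- dC * cache$CembPos[[k]]
    dbk <- colSums(dCembPre)
    Wm <- params$conv[[k]]$W
    dim(Wm) <- c(h * s, 34L)
    dWm <- matrix(0, h * s, 34L)
    dM <- matrix(0, P * B, d * s)
    M <- cache$M[[k]]
    for (gi in seq_along(groups)) {
      rows <- rep((groups[[gi]] - 1L) * P, each = P) +
        rep(seq_len(P), length(groups[[gi]]))
      Kf <- cache$Kf[[k]][[gi]]                       # (h*s) x d
      KfArr <- Kf
      dim(KfArr) <- c(h, s, d)
      Km <- .kernelMat(KfArr)                         # (s*d) x h
      dCg <- dCembPre[rows, , drop = FALSE]
      dM[rows, ] <- dCg %*% t(Km)
      dKm <- crossprod(M[rows, , drop = FALSE], dCg)  # (s*d) x h
      dim(dKm) <- c(d, s, h)
      dKf <- aperm(dKm, c(3L, 2L, 1L))
      dim(dKf) <- c(h * s, d)
      dKf <- dKf * (Kf > 0)
      dWm <- dWm + dKf %*% t(cache$Ylist[[gi]])
      dYlist[[gi]] <- dYlist[[gi]] + crossprod(Wm, dKf)
    }
    dim(dWm) <- c(h, s, 34L)
    g$conv[[k]] <- list(W = dWm, b = dbk)

    ## fold window gradients back onto Xall
    dim(dM) <- c(P * B, d, s)
    dMarr <- aperm(dM, c(3L, 1L, 2L))                 # s x (P*B) x d
    baseRows <- rep((seq_len(B) - 1L) * Lmax, each = P) + rep(seq_len(P), B)
    for (a in seq_len(s)) {
      rows <- baseRows + (a - 1L)
      dXall[rows, ] <- dXall[rows, , drop = FALSE] +
        matrix(dMarr[a, , ], P * B, d)
    }
  }

  ## embeddings (pad row stays fixed at zero)
  dEmbP <- matrix(0, 21L, d)
  rs <- rowsum(dXall, cache$tIdx)
  dEmbP[as.integer(rownames(rs)) + 1L, ] <- rs
  dEmbQ <- matrix(0, 21L, d)
  for (gi in seq_along(groups)) {
    rsY <- rowsum(dYlist[[gi]], cache$Yidx[[gi]])
    tr <- as.integer(rownames(rsY)) + 1L
    dEmbQ[tr, ] <- dEmbQ[tr, , drop = FALSE] + rsY
  }
  if (config$sharedEmbedding) {
    g$embP <- dEmbP + dEmbQ
  } else {
    g$embP <- dEmbP
    g$embQ <- dEmbQ
  }
  g$embP[1L, ] <- 0
  if (!is.null(g$embQ)) g$embQ[1L, ] <- 0
  g
}

# flatten a nested parameter list into a flat named list (dot paths);
# used by the optimizer so state bookkeeping stays trivial.
#' @keywords internal
.flattenParams <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  if (is.null(nms)) nms <- as.character(seq_along(p))
  for (i in seq_along(p)) {
    v <- p[[i]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
    if (is.list(v)) out <- c(out, .flattenParams(v, key))
    else out[[key]] <- v
  }
  out
}

#' @keywords internal
.unflattenInto <- function(skeleton, flat, prefix = "") {
  nms <- names(skeleton)
  if (is.null(nms)) nms <- as.character(seq_along(skeleton))
  for (i in seq_along(skeleton)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nms[i]) else nms[i]
    if (is.list(skeleton[[i]]))
      skeleton[[i]] <- .unflattenInto(skeleton[[i]], flat, key)
    else skeleton[[i]] <- flat[[key]]
  }
  skeleton
}
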