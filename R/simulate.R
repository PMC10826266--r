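# Synthetic multi-allele benchmark generator.
#
# Emulates the structure of the public MHC-II benchmarks (a multi-allele
# training table with motif-grouped CV folds, a held-out-allele test set,
# and a core-annotated complex set) with a known ground truth: each allele
# carries a 9 x 20 position energy matrix whose anchor pockets 1, 4, 6 and
# 9 dominate specificity, plus a linear flanking-residue bonus, so the true
# binding core and the true affinity of every peptide are recoverable by an
# independent window-scoring oracle.

#' Create a synthetic MHC-II allele
#'
#' Draws a random 34-residue pseudo-sequence and a 9 x 20 position energy
#' matrix with the four anchor pockets (1, 4, 6, 9) scaled by
#' `anchorStrength`, so anchor rows have a strictly larger max-minus-mean
#' energy gap than non-anchor rows (enforced).  The matrix is centred so
#' that the best-window energy of a random background peptide is roughly
#' zero, placing affinities near the middle of the unit interval.
#'
#' @param name allele name
#' @param seed integer; the allele is reproducible from this seed alone
#' @param anchorStrength multiplier (> 0) on the anchor-pocket energies
#' @param noiseSd standard deviation of the Gaussian affinity noise (on the
#'   logistic scale)
#' @param flankBonus affinity bonus per peptide-flanking residue
#' @param energySd base per-entry energy standard deviation
#' @return a list with fields name, pseudo, pwm, anchors, flankBonus,
#'   noiseSd
#' @export
makeAllele <- function(name, seed, anchorStrength = 3, noiseSd = 0.05,
                       flankBonus = 0.05, energySd = 0.25) {
  if (anchorStrength <= 0) stop("anchorStrength must be > 0")
  anchors <- c(1L, 4L, 6L, 9L)
  withSeed(seed, {
    pseudo <- paste(sample(aminoAcids(), 34L, replace = TRUE), collapse = "")
    pwm <- matrix(stats::rnorm(180L, sd = energySd), 9L, 20L,
                  dimnames = list(NULL, aminoAcids()))
    pwm[anchors, ] <- pwm[anchors, ] * anchorStrength
    gap <- apply(pwm, 1L, function(r) max(r) - mean(r))
    while (min(gap[anchors]) <= max(gap[-anchors])) {
      pwm[anchors, ] <- pwm[anchors, ] * 1.1
      gap <- apply(pwm, 1L, function(r) max(r) - mean(r))
    }
    ## centre: subtract the mean best-window energy of background peptides
    probe <- vapply(1:200, function(i) {
      pep <- sample.int(20L, sample(9:22, 1L), replace = TRUE)
      max(.windowEnergies(pep, pwm))
    }, numeric(1))
    pwm <- pwm - mean(probe) / 9
    list(name = name, pseudo = pseudo, pwm = pwm, anchors = anchors,
         flankBonus = flankBonus, noiseSd = noiseSd)
  })
}

# energies of all 9-mer windows of a peptide given as residue indices 1..20
#' @keywords internal
.windowEnergies <- function(pepIdx, pwm) {
  n <- length(pepIdx)
  vapply(0:(n - 9L), function(off) {
    sum(pwm[cbind(1:9, pepIdx[(off + 1L):(off + 9L)])])
  }, numeric(1))
}

#' Sample random peptides
#'
#' Lengths uniform over `lengthRange`, residues i.i.d. from `background`
#' (uniform over the 20 standard amino acids by default).  Uses the
#' current RNG stream; seed with [withSeed()] or `set.seed()`.
#'
#' @param n number of peptides
#' @param lengthRange inclusive length range within 9..22
#' @param background length-20 residue probability vector
#' @return character vector of peptides
#' @export
samplePeptide <- function(n = 1L, lengthRange = c(9L, 22L),
                          background = rep(1 / 20, 20L)) {
  if (lengthRange[1] < 9L || lengthRange[2] > 22L ||
      lengthRange[1] > lengthRange[2])
    stop("lengthRange must lie within 9..22")
  lens <- if (lengthRange[1] == lengthRange[2])
    rep(as.integer(lengthRange[1]), n)
  else sample(lengthRange[1]:lengthRange[2], n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(aminoAcids(), L, replace = TRUE, prob = background),
          collapse = ""), character(1))
}

# sample a binder peptide: a 9-mer core drawn from the allele's Boltzmann
# distribution exp(pwm[j, ]) per pocket, implanted at a uniform register
# inside a background peptide.
#' @keywords internal
.sampleBinderPeptide <- function(allele, lengthRange = c(9L, 22L)) {
  L <- if (lengthRange[1] == lengthRange[2]) lengthRange[1]
  else sample(lengthRange[1]:lengthRange[2], 1L)
  core <- vapply(1:9, function(j) {
    p <- exp(allele$pwm[j, ])
    sample(aminoAcids(), 1L, prob = p / sum(p))
  }, character(1))
  off <- if (L == 9L) 0L else sample.int(L - 9L + 1L, 1L) - 1L
  flank <- sample(aminoAcids(), L - 9L, replace = TRUE)
  paste(c(if (off > 0L) flank[seq_len(off)], core,
          if (L - 9L - off > 0L) flank[(off + 1L):(L - 9L)]), collapse = "")
}

#' Ground-truth affinity and binding core of a peptide
#'
#' Scores every 9-mer window against the allele's energy matrix; the best
#' window (ties to the smallest offset) is the true core.  The affinity is
#' `plogis(bestEnergy + flankBonus * (L' - 9) + noise)` with Gaussian noise
#' of standard deviation `noiseSd`, clipped to \[0, 1\].
#'
#' @param peptide peptide string
#' @param allele a [makeAllele()] object
#' @param noiseSd noise level; defaults to the allele's own; pass 0 for the
#'   noise-free oracle value
#' @return list: `affinity` in \[0, 1\], `coreStart` (0-based)
#' @export
trueAffinity <- function(peptide, allele, noiseSd = allele$noiseSd) {
  pepIdx <- tokenIndex(strsplit(peptide, "", fixed = TRUE)[[1L]])
  e <- .windowEnergies(pepIdx, allele$pwm)
  core <- which.max(e) - 1L
  lin <- e[core + 1L] + allele$flankBonus * (length(pepIdx) - 9L)
  if (noiseSd > 0) lin <- lin + stats::rnorm(1L, sd = noiseSd)
  list(affinity = pmin(1, pmax(0, stats::plogis(lin))), coreStart = core)
}

#' Generate a complete synthetic benchmark
#'
#' Produces `nAlleles` training alleles with `nPerAllele` peptides each
#' (split into motif-grouped train/test portions) and optionally
#' `nHeldoutAlleles` additional alleles whose records are all held out,
#' emulating an independent-allele evaluation set.  Mirroring real binding
#' panels, a fraction `fracBinder` of the peptides carry an implanted
#' binding motif: a 9-mer core sampled from the allele's Boltzmann residue
#' preferences, placed at a uniformly random register; the remainder are
#' pure background.  The motif group id of a record is its true core
#' 9-mer, so grouped fold assignment keeps shared motifs in one fold.
#' Regenerable bit-identically from `(seed, parameters)`.
#'
#' @param nAlleles number of training alleles
#' @param nPerAllele peptides per allele
#' @param anchorStrength see [makeAllele()]
#' @param noiseSd see [makeAllele()]
#' @param lengthRange peptide length range
#' @param fracBinder fraction of peptides with an implanted motif core
#' @param fracTest fraction of each training allele's records held out as
#'   a test split (grouped by motif)
#' @param nHeldoutAlleles additional alleles fully held out
#' @param seed master seed
#' @return a [SyntheticMHCData-class]
#' @examples
#' sim <- simulateDataset(nAlleles = 2, nPerAllele = 20, seed = 7)
#' sim
#' @export
simulateDataset <- function(nAlleles = 2L, nPerAllele = 500L,
                            anchorStrength = 3, noiseSd = 0.05,
                            lengthRange = c(9L, 22L), fracBinder = 0.5,
                            fracTest = 0.2,
                            nHeldoutAlleles = 0L, seed = 1L) {
  if (nAlleles < 1L || nPerAllele < 1L) stop("counts must be positive")
  params <- list(nAlleles = nAlleles, nPerAllele = nPerAllele,
                 anchorStrength = anchorStrength, noiseSd = noiseSd,
                 lengthRange = lengthRange, fracBinder = fracBinder,
                 fracTest = fracTest,
                 nHeldoutAlleles = nHeldoutAlleles)
  nTotal <- nAlleles + nHeldoutAlleles
  alleles <- lapply(seq_len(nTotal), function(a) {
    makeAllele(sprintf("SYN-%02d", a), seed = seed + 7919L * a,
               anchorStrength = anchorStrength, noiseSd = noiseSd)
  })
  names(alleles) <- vapply(alleles, `[[`, character(1), "name")
  records <- withSeed(seed, {
    rows <- lapply(seq_len(nTotal), function(a) {
      al <- alleles[[a]]
      isBinder <- stats::runif(nPerAllele) < fracBinder
      peps <- vapply(isBinder, function(b) {
        if (b) .sampleBinderPeptide(al, lengthRange)
        else samplePeptide(1L, lengthRange)
      }, character(1))
      tv <- lapply(peps, trueAffinity, allele = al)
      data.frame(peptide = peps,
                 affinity = vapply(tv, `[[`, numeric(1), "affinity"),
                 allele = al$name,
                 coreStart = vapply(tv, `[[`, integer(1), "coreStart"),
                 binder = isBinder,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$group <- substr(df$peptide, df$coreStart + 1L, df$coreStart + 9L)
    ## grouped train/test split for the training alleles
    df$split <- "heldout"
    for (a in seq_len(nAlleles)) {
      i <- which(df$allele == alleles[[a]]$name)
      gs <- unique(df$group[i])
      gs <- gs[sample.int(length(gs))]
      sizes <- cumsum(table(df$group[i])[gs])
      nTest <- round(fracTest * length(i))
      testGroups <- if (nTest > 0L)
        gs[seq_len(which(sizes >= nTest)[1L])] else character(0)
      df$split[i] <- ifelse(df$group[i] %in% testGroups, "test", "train")
    }
    df
  })
  new("SyntheticMHCData", alleles = alleles, records = records,
      seed = as.integer(seed), params = params)
}

#' Write a synthetic benchmark to disk in the package's file dialects
#'
#' Emits `pseudo.txt` (allele, 34-mer), `train.txt` / `test.txt` /
#' `heldout.txt` (peptide, affinity, allele, group), `cores.txt`
#' (peptide, allele, 0-based core start) and `manifest.json` (seed and
#' generation parameters).  All files round-trip through the package's
#' parsers; regeneration under the same seed is byte-identical.
#'
#' @param dataset a [SyntheticMHCData-class]
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- pseudoMap(dataset)
  writeLines(sprintf("%s %s", names(ps), ps), file.path(dir, "pseudo.txt"))
  df <- dataset@records
  for (sp in c("train", "test", "heldout")) {
    sub <- df[df$split == sp, , drop = FALSE]
    if (sp == "heldout" && !nrow(sub)) next
    writeLines(sprintf("%s %.6f %s %s", sub$peptide, sub$affinity,
                       sub$allele, sub$group), file.path(dir,
                                                         paste0(sp, ".txt")))
  }
  ## core annotations cover the binder complexes only: a background peptide
  ## forms no complex, so it has no physical binding core to annotate
  cx <- df[df$binder, , drop = FALSE]
  writeLines(sprintf("%s %s %d", cx$peptide, cx$allele, cx$coreStart),
             file.path(dir, "cores.txt"))
  manifest <- c(list(seed = dataset@seed), dataset@params)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
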