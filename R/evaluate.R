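#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic via mid-ranks: a tied
#' positive/negative score pair counts 1/2.
#'
#' @param labels binary vector (0/1), both classes present
#' @param scores numeric vector of the same length
#' @return AUC in \[0, 1\]
#' @examples
#' aucScore(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))  # 0.75
#' @export
aucScore <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binarize continuous affinities for AUC
#'
#' Label 1 iff affinity >= threshold.  The default 0.426 corresponds to the
#' conventional 500 nM binder cutoff under the IC50 transform of
#' [ic50ToScore()].
#'
#' @param affinities numeric vector in \[0, 1\]
#' @param threshold binder threshold in (0, 1)
#' @return integer 0/1 vector
#' @export
binarizeAffinity <- function(affinities, threshold = 0.426) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  as.integer(affinities >= threshold)
}

#' Pearson and Spearman correlation
#'
#' `pccScore` is the product-moment correlation; `srccScore` is the
#' Pearson correlation of mid-ranks (average ranks for ties).
#'
#' @param x,y numeric vectors, length >= 2, non-degenerate
#' @return correlation in \[-1, 1\]
#' @export
pccScore <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  stats::cor(x, y)
}

#' @rdname pccScore
#' @export
srccScore <- function(x, y) {
  pccScore(rank(x, ties.method = "average"),
           rank(y, ties.method = "average"))
}

#' Per-allele evaluation report
#'
#' One row per allele with n, AUC (after binarizing the measured affinities
#' at `threshold`), PCC, SRCC and MSE, plus an unweighted `Average` row.
#' Metrics that are undefined for an allele (single-class labels for AUC,
#' zero variance for correlations) are reported as NA and excluded from
#' that metric's average.
#'
#' @param records data.frame with columns allele and affinity (measured)
#' @param predictions numeric vector of predicted affinities
#' @param threshold binder threshold for AUC binarization
#' @return data.frame with columns allele, n, auc, pcc, srcc, mse
#' @export
perAlleleReport <- function(records, predictions, threshold = 0.426) {
  if (nrow(records) != length(predictions))
    stop("every record needs a prediction")
  if (anyNA(predictions)) stop("missing prediction")
  alleles <- sort(unique(records$allele))
  rows <- lapply(alleles, function(a) {
    i <- records$allele == a
    y <- records$affinity[i]; p <- predictions[i]
    lab <- binarizeAffinity(y, threshold)
    auc <- if (length(unique(lab)) == 2L) aucScore(lab, p) else NA_real_
    ok <- length(y) >= 2L && stats::sd(y) > 0 && stats::sd(p) > 0
    data.frame(allele = a, n = sum(i), auc = auc,
               pcc = if (ok) pccScore(y, p) else NA_real_,
               srcc = if (ok) srccScore(y, p) else NA_real_,
               mse = mean((y - p)^2), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(allele = "Average", n = sum(out$n),
                    auc = mean(out$auc, na.rm = TRUE),
                    pcc = mean(out$pcc, na.rm = TRUE),
                    srcc = mean(out$srcc, na.rm = TRUE),
                    mse = mean(out$mse), stringsAsFactors = FALSE)
  rbind(out, avg)
}

#' Binding-core prediction accuracy
#'
#' @param predicted,annotated integer vectors of 0-based 9-mer core starts
#' @return list: `exactMatchRate` (fraction with identical start) and
#'   `meanOverlap` (mean 9-mer window intersection / 9)
#' @export
coreAccuracy <- function(predicted, annotated) {
  if (length(predicted) != length(annotated)) stop("length mismatch")
  if (!length(predicted)) stop("empty input")
  ov <- pmax(0L, 9L - abs(predicted - annotated)) / 9
  list(exactMatchRate = mean(predicted == annotated), meanOverlap = mean(ov))
}

#' Position-frequency matrix and information content from 9-mer cores
#'
#' Builds the 9 x 20 relative-frequency matrix over core positions
#' ("pockets" 1-9) and the per-position information content in bits,
#' `IC = log2(20) - H`, with `H` the Shannon entropy of the column.  This
#' is the matrix behind a sequence logo: total column height is the IC,
#' letter heights are the residue frequencies.
#'
#' @param cores character vector of 9-mer core sequences
#' @return list: `pfm` (9 x 20 matrix, rows sum to 1, columns named by
#'   residue) and `ic` (length-9 vector of bits)
#' @export
pfmFromCores <- function(cores) {
  if (!length(cores)) stop("no core sequences")
  if (any(nchar(cores) != 9L)) stop("all cores must be 9-mers")
  mat <- matrix(0, 9L, 20L, dimnames = list(pocket = 1:9,
                                            residue = aminoAcids()))
  letters <- do.call(rbind, strsplit(cores, "", fixed = TRUE))
  for (p in 1:9) {
    tab <- table(factor(letters[, p], levels = aminoAcids()))
    mat[p, ] <- as.numeric(tab) / length(cores)
  }
  ic <- apply(mat, 1L, function(f) {
    nz <- f[f > 0]
    log2(20) + sum(nz * log2(nz))
  })
  list(pfm = mat, ic = unname(ic))
}

#' Export logo inputs: PFM as TSV, cores as FASTA
#'
#' Writes the position-frequency matrix (with an IC column) as TSV and the
#' core sequences as FASTA for external sequence-logo renderers.
#'
#' @param pfm result of [pfmFromCores()]
#' @param file output TSV path
#' @export
writePFM <- function(pfm, file) {
  df <- data.frame(pocket = 1:9, ic_bits = pfm$ic,
                   as.data.frame(pfm$pfm), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writePFM
#' @param cores character vector of core sequences
#' @param names optional FASTA record names
#' @export
writeCoresFasta <- function(cores, file, names = NULL) {
  if (is.null(names)) names <- sprintf("core_%d", seq_along(cores))
  writeLines(as.vector(rbind(paste0(">", names), cores)), file)
  invisible(file)
}
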