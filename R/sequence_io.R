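#' IC50 to normalized binding score
#'
#' The conventional NetMHC-lineage transform mapping a half-maximal
#' inhibitory concentration (nM) onto the unit interval:
#' `score = 1 - log(ic50) / log(50000)`, clipped to \[0, 1\].  An IC50 of
#' 1 nM maps to 1, 50000 nM maps to 0; the transform is monotonically
#' decreasing (stronger binders score higher).
#'
#' @param ic50 numeric vector of IC50 values in nM, strictly positive
#' @return numeric vector of scores in \[0, 1\]
#' @examples
#' ic50ToScore(c(1, 500, 50000))
#' scoreToIc50(0.426)
#' @export
ic50ToScore <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0))
    stop("IC50 must be finite and > 0 nM")
  pmin(1, pmax(0, 1 - log(ic50) / log(50000)))
}

#' @rdname ic50ToScore
#' @param score numeric vector in \[0, 1\]
#' @export
scoreToIc50 <- function(score) {
  if (any(score < 0 | score > 1)) stop("score must lie in [0, 1]")
  exp((1 - score) * log(50000))
}

#' Pad a peptide into a fixed-length frame
#'
#' Pads are split as evenly as possible between the two ends of the
#' peptide; when the total pad count is odd the extra pad token goes to the
#' right.  Pad positions carry token index 0 and embed to the zero vector.
#'
#' @param peptide a single peptide string (9--22 standard residues)
#' @param Lmax frame length, default 26
#' @return a [PaddedPeptide-class] object
#' @examples
#' padPeptide("ILKEPVHGV", Lmax = 13)
#' @export
padPeptide <- function(peptide, Lmax = 26L) {
  n <- nchar(peptide)
  if (n < 9L) stop("peptide shorter than 9 residues: ", peptide)
  if (n > Lmax) stop("peptide of length ", n, " exceeds the frame Lmax = ", Lmax)
  idx <- tokenIndex(strsplit(peptide, "", fixed = TRUE)[[1L]])
  if (any(idx == 0L)) stop("pad symbol inside a peptide")
  pad <- Lmax - n
  lp <- pad %/% 2L
  out <- integer(Lmax)
  out[(lp + 1L):(lp + n)] <- idx
  new("PaddedPeptide", indices = out, trueLength = as.integer(n),
      leftPad = as.integer(lp), source = peptide)
}

#' Parse a pseudo-sequence table
#'
#' Each MHC-II allele is represented by a fixed 34-residue pseudo-sequence
#' (15 peptide-contacting residues from the alpha chain, 19 from the beta
#' chain).  The file format is line-oriented whitespace-delimited text with
#' two fields: allele name and the 34-residue string.
#'
#' @param text either a file path or a character vector of lines
#' @return named character vector, allele name -> 34-residue string
#' @examples
#' parsePseudoSequences(c("DRB1_0101 QEFFIASGAAVDAIMHLRSYTQYNREFLVHFRNQ"))
#' @export
parsePseudoSequences <- function(text) {
  lines <- .asLines(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "[[:space:]]+")[[1L]]
    if (length(fields) < 2L)
      stop("pseudo-sequence line ", i, ": expected 'allele sequence'")
    allele <- fields[[1L]]; seq <- fields[[2L]]
    if (nchar(seq) != 34L)
      stop("pseudo-sequence line ", i, " (", allele, "): length ",
           nchar(seq), ", expected 34")
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- setdiff(chars, aminoAcids())
    if (length(bad))
      stop("pseudo-sequence line ", i, " (", allele,
           "): non-standard residue(s) ", paste(bad, collapse = ""))
    if (allele %in% names(out) && !identical(unname(out[allele]), seq))
      stop("conflicting pseudo-sequences for allele ", allele)
    out[allele] <- seq
  }
  out
}

#' Parse a binding-affinity table
#'
#' Whitespace-delimited text, one record per line, columns
#' `peptide affinity allele [group]` (NetMHCIIpan training-file order).
#' Affinities are normalized to \[0, 1\]; with `ic50 = TRUE` the affinity
#' column holds raw IC50 nM values and is passed through [ic50ToScore()].
#'
#' @param text a file path or character vector of lines
#' @param pseudo named pseudo-sequence vector as from [parsePseudoSequences()]
#' @param ic50 logical; affinity column is raw IC50 in nM
#' @param lenient logical; skip records with unknown alleles (with a
#'   warning) instead of failing
#' @param columns integer positions of peptide, affinity, allele and
#'   (optionally) group fields, for other dialects
#' @return data.frame with columns peptide, affinity, allele, group
#' @export
parseBindingData <- function(text, pseudo, ic50 = FALSE, lenient = FALSE,
                             columns = c(peptide = 1L, affinity = 2L,
                                         allele = 3L, group = 4L)) {
  lines <- .asLines(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n <- length(lines)
  pep <- aff <- all_ <- grp <- character(n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[[i]], "[[:space:]]+")[[1L]]
    if (length(fields) < 3L)
      stop("binding line ", i, ": expected at least 3 fields")
    pep[i] <- fields[[columns[["peptide"]]]]
    aff[i] <- fields[[columns[["affinity"]]]]
    all_[i] <- fields[[columns[["allele"]]]]
    grp[i] <- if (length(fields) >= columns[["group"]])
      fields[[columns[["group"]]]] else NA_character_
    if (!all_[i] %in% names(pseudo)) {
      if (lenient) {
        warning("skipping line ", i, ": unknown allele ", all_[i])
        next
      }
      stop("binding line ", i, ": allele ", all_[i],
           " absent from the pseudo-sequence table")
    }
    np <- nchar(pep[i])
    if (np < 9L || np > 22L)
      stop("binding line ", i, ": peptide length ", np,
           " outside the 9-22 range")
    tokenIndex(strsplit(pep[i], "", fixed = TRUE)[[1L]])  # validates alphabet
    keep[i] <- TRUE
  }
  affn <- suppressWarnings(as.numeric(aff[keep]))
  if (anyNA(affn)) stop("non-numeric affinity value in binding table")
  if (ic50) {
    affn <- ic50ToScore(affn)
  } else if (any(affn < 0 | affn > 1)) {
    stop("normalized affinity outside [0, 1]; use ic50 = TRUE for raw nM")
  }
  data.frame(peptide = pep[keep], affinity = affn, allele = all_[keep],
             group = grp[keep], stringsAsFactors = FALSE)
}

#' Parse a binding-core benchmark table
#'
#' Columns: peptide, allele, annotated 0-based 9-mer core start.
#'
#' @inheritParams parseBindingData
#' @return data.frame with columns peptide, allele, coreStart
#' @export
parseCoreBenchmark <- function(text, pseudo) {
  lines <- .asLines(text)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "[[:space:]]+")[[1L]]
    if (length(fields) < 3L) stop("core line ", i, ": expected 3 fields")
    st <- suppressWarnings(as.integer(fields[[3L]]))
    if (is.na(st) || st < 0L) stop("core line ", i, ": bad core start")
    if (st + 9L > nchar(fields[[1L]]))
      stop("core line ", i, ": core extends past the peptide end")
    if (!fields[[2L]] %in% names(pseudo))
      stop("core line ", i, ": unknown allele ", fields[[2L]])
    data.frame(peptide = fields[[1L]], allele = fields[[2L]], coreStart = st,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write a prediction table
#'
#' One TSV line per record: peptide, allele, predicted affinity, 0-based
#' core start in unpadded peptide coordinates, and the 9-mer core sequence.
#'
#' @param records data.frame with peptide and allele columns
#' @param predictions numeric vector of predicted affinities
#' @param cores integer vector of predicted 0-based core starts
#' @param file optional path; when NULL the lines are returned invisibly
#' @param oneBased logical; report core starts 1-based for display
#' @return character vector of output lines (invisibly when `file` given)
#' @export
writePredictions <- function(records, predictions, cores, file = NULL,
                             oneBased = FALSE) {
  if (nrow(records) != length(predictions) ||
      nrow(records) != length(cores))
    stop("records, predictions and cores must have equal length")
  coreSeq <- substr(records$peptide, cores + 1L, cores + 9L)
  lines <- c("peptide\tallele\taffinity\tcore_start\tcore",
             if (nrow(records))
               sprintf("%s\t%s\t%.6f\t%d\t%s", records$peptide,
                       records$allele, predictions,
                       cores + as.integer(oneBased), coreSeq))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' @keywords internal
.asLines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text)
  else unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

# Batch-encode peptides into an index matrix (rows = peptides) plus the pad
# bookkeeping vectors; the workhorse behind training and prediction.
#' @keywords internal
.encodePeptides <- function(peptides, Lmax) {
  B <- length(peptides)
  n <- nchar(peptides)
  if (any(n > Lmax)) stop("peptide exceeds the model frame Lmax = ", Lmax)
  lp <- (Lmax - n) %/% 2L
  X <- matrix(0L, B, Lmax)
  for (i in seq_len(B)) {
    X[i, (lp[i] + 1L):(lp[i] + n[i])] <-
      tokenIndex(strsplit(peptides[[i]], "", fixed = TRUE)[[1L]])
  }
  list(idx = X, leftPad = as.integer(lp), trueLen = as.integer(n))
}

#' @keywords internal
.encodePseudo <- function(seqs) {
  t(vapply(seqs, function(s) tokenIndex(strsplit(s, "", fixed = TRUE)[[1L]]),
           integer(34L)))
}
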