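#' Sinusoidal positional-encoding row
#'
#' The fixed (training-free) sinusoidal encoding of a single sequence
#' position.  Under the default `"paper"` convention, 0-based dimension
#' `j` holds `sin(pos / 1000^(j/d))` when `j` is even and
#' `cos(pos / 1000^(j/d))` when `j` is odd — i.e. base 1000 with the
#' cosine exponent `(2k+1)/d` rather than the shared-pair Transformer
#' exponent.  `convention = "transformer"` gives the classic base-10000
#' encoding with exponent `2*floor(j/2)/d` for both members of a pair.
#'
#' @param pos non-negative integer position (0 is the shared pad position)
#' @param d even embedding width, default 16
#' @param convention `"paper"` or `"transformer"`
#' @return numeric vector of length `d`, entries in \[-1, 1\]
#' @examples
#' sinusoidalRow(0)           # alternating 0 / 1
#' sinusoidalRow(1, d = 16)[1] # sin(1)
#' @export
sinusoidalRow <- function(pos, d = 16L,
                          convention = c("paper", "transformer")) {
  convention <- match.arg(convention)
  if (length(pos) != 1L || !is.finite(pos) || pos < 0)
    stop("pos must be a single non-negative integer")
  if (d %% 2L != 0L) stop("embedding width d must be even")
  j <- 0:(d - 1L)
  if (convention == "paper") {
    angle <- pos / 1000^(j / d)
  } else {
    angle <- pos / 10000^(2 * (j %/% 2L) / d)
  }
  ifelse(j %% 2L == 0L, sin(angle), cos(angle))
}

#' @keywords internal
.peRows <- function(positions, d, convention) {
  t(vapply(positions, sinusoidalRow, numeric(d), d = d,
           convention = convention))
}

#' Direct and calibrated positional-encoding matrices
#'
#' `directPE()` numbers the padded frame itself: matrix row i receives the
#' encoding of position i (1-based), so pad rows get ordinary position
#' encodings and the same residue lands on different encodings depending on
#' where the padding fell.  `calibratedPE()` instead numbers the true
#' residues 1..L' wherever they sit in the frame, and maps every pad
#' position to the shared position-0 row, so a residue's encoding is
#' invariant to the pad split.
#'
#' @param padded a [PaddedPeptide-class] (or anything with leftPad/trueLength
#'   for `calibratedPE`)
#' @param d even embedding width, default 16
#' @param convention see [sinusoidalRow()]
#' @param padZero logical; encode pads as the all-zero vector instead of the
#'   position-0 sinusoid (ablation variant)
#' @return an `Lmax x d` numeric matrix
#' @examples
#' p <- padPeptide("ILKEPVHGV", Lmax = 13)
#' dim(directPE(p))
#' calibratedPE(p)[1, ]  # pad row: position-0 encoding
#' @export
directPE <- function(padded, d = 16L, convention = "paper") {
  L <- length(peptideIndices(padded))
  .peRows(seq_len(L), d, convention)
}

#' @rdname directPE
#' @export
calibratedPE <- function(padded, d = 16L, convention = "paper",
                         padZero = FALSE) {
  L <- length(peptideIndices(padded))
  lp <- leftPad(padded)
  n <- trueLength(padded)
  pos <- integer(L)                      # pads at position 0
  pos[(lp + 1L):(lp + n)] <- seq_len(n)  # residues at 1..L'
  M <- .peRows(pos, d, convention)
  if (padZero) M[pos == 0L, ] <- 0
  M
}

#' Positional encoding of the 34-residue pseudo-sequence
#'
#' The pseudo-sequence is never padded, so direct and calibrated encodings
#' coincide: row j is the encoding of position j, j = 1..34.
#'
#' @inheritParams directPE
#' @return a `34 x d` numeric matrix
#' @export
pseudoPE <- function(d = 16L, convention = "paper") {
  .peRows(1:34, d, convention)
}

#' Positional-encoding strategy descriptor
#'
#' The eight strategies combine the encoding method (direct vs calibrated),
#' the injection site (pre: added to the embeddings before the BICL; post:
#' convolved separately and added to the BICL output), and the scope
#' (`"O"`: peptide only; `"T"`: peptide and MHC pseudo-sequence together).
#' `method = "none"` denotes the PE-free baseline, for which site and scope
#' are ignored.
#'
#' @param method `"none"`, `"direct"` or `"calibrated"`
#' @param site `"pre"` or `"post"`
#' @param scope `"O"` or `"T"`
#' @return a validated strategy list
#' @examples
#' peStrategy("calibrated", "pre", "T")
#' allPEStrategies()   # the 8 strategies plus the baseline
#' @export
peStrategy <- function(method = c("none", "direct", "calibrated"),
                       site = c("pre", "post"), scope = c("O", "T")) {
  method <- match.arg(method)
  site <- match.arg(site)
  scope <- match.arg(scope)
  if (method == "none") { site <- "pre"; scope <- "O" }  # canonical baseline
  list(method = method, site = site, scope = scope)
}

#' @rdname peStrategy
#' @param baseline include the PE-free baseline as the first entry
#' @export
allPEStrategies <- function(baseline = TRUE) {
  out <- list()
  if (baseline) out <- list(baseline = peStrategy("none"))
  for (m in c("calibrated", "direct"))
    for (s in c("pre", "post"))
      for (sc in c("O", "T"))
        out[[sprintf("%s_%s_%s", m, s, sc)]] <- peStrategy(m, s, sc)
  out
}

#' @keywords internal
.strategyLabel <- function(st) {
  if (st$method == "none") return("baseline")
  sprintf("%s %s-PE(%s)",
          if (st$method == "calibrated") "Calibrated" else "Direct",
          if (st$site == "pre") "Pre" else "Post", st$scope)
}

# Peptide PE matrix for one pad layout; pos vector keyed by (leftPad, L').
#' @keywords internal
.peForLayout <- function(method, Lmax, lp, n, d, convention, padZero) {
  if (method == "direct") return(.peRows(seq_len(Lmax), d, convention))
  pos <- integer(Lmax)
  pos[(lp + 1L):(lp + n)] <- seq_len(n)
  M <- .peRows(pos, d, convention)
  if (padZero) M[pos == 0L, ] <- 0
  M
}

# Unique PE variants for a batch: direct PE has a single variant; calibrated
# PE one per (leftPad, trueLen) layout. Returns list(mats, variantOf).
#' @keywords internal
.peVariants <- function(method, Lmax, lp, n, d, convention, padZero) {
  if (method == "direct") {
    return(list(mats = list(.peRows(seq_len(Lmax), d, convention)),
                variantOf = rep(1L, length(lp))))
  }
  key <- paste(lp, n)
  uk <- unique(key)
  mats <- lapply(uk, function(k) {
    i <- match(k, key)
    .peForLayout("calibrated", Lmax, lp[i], n[i], d, convention, padZero)
  })
  list(mats = mats, variantOf = match(key, uk))
}
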