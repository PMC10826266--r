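#' @import methods
NULL

#' The amino-acid alphabet used throughout the package
#'
#' Twenty standard amino acids in alphabetical one-letter order, preceded by
#' the pad token \code{"-"} at integer index 0.  Residues map to indices
#' 1..20; the pad index is always 0 and embeds to the zero vector.
#'
#' @return `aminoAcids()` returns the 20-letter residue vector;
#'   `padSymbol()` returns the pad character.
#' @examples
#' aminoAcids()
#' tokenIndex(c("A", "C", "-"))
#' @export
aminoAcids <- function() .AA_RESIDUES

.AA_RESIDUES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.AA_PAD <- "-"
# lookup table: names are tokens, values 0..20
.AA_INDEX <- stats::setNames(0:20, c(.AA_PAD, .AA_RESIDUES))

#' @rdname aminoAcids
#' @export
padSymbol <- function() .AA_PAD

#' @rdname aminoAcids
#' @param tokens character vector of single-letter tokens (residues or pad)
#' @export
tokenIndex <- function(tokens) {
  idx <- .AA_INDEX[tokens]
  if (anyNA(idx))
    stop("character(s) outside the amino-acid alphabet: ",
         paste(unique(tokens[is.na(idx)]), collapse = ", "))
  unname(idx)
}

#' @rdname aminoAcids
#' @param indices integer vector in 0..20
#' @export
tokenFromIndex <- function(indices) {
  if (any(indices < 0L | indices > 20L)) stop("token index outside 0..20")
  c(.AA_PAD, .AA_RESIDUES)[indices + 1L]
}

## ---------------------------------------------------------------------------

#' PaddedPeptide: a peptide embedded in a fixed-length padded frame
#'
#' MHC-II binders are 9--22 residues long; the model works on a fixed frame
#' of length \code{Lmax} with pad tokens (index 0) split between the two
#' ends.  The object records the original peptide, the pad split and the
#' integer token indices of the padded frame.
#'
#' @slot indices integer vector of length `Lmax`; pads are 0, residues 1..20
#' @slot trueLength integer, number of real residues
#' @slot leftPad integer, number of leading pad tokens
#' @slot source the original peptide string
#' @seealso [padPeptide()]
#' @export
setClass("PaddedPeptide",
         representation(indices = "integer", trueLength = "integer",
                        leftPad = "integer", source = "character"))

setValidity("PaddedPeptide", function(object) {
  L <- length(object@indices)
  lp <- object@leftPad
  n <- object@trueLength
  msg <- character()
  if (nchar(object@source) != n)
    msg <- c(msg, "trueLength does not match source peptide")
  if (lp < 0L || lp + n > L)
    msg <- c(msg, "pad layout exceeds the frame")
  body <- object@indices[(lp + 1L):(lp + n)]
  if (any(body == 0L))
    msg <- c(msg, "pad token inside the residue body")
  if (any(object@indices[-((lp + 1L):(lp + n))] != 0L))
    msg <- c(msg, "non-pad token outside the residue body")
  if (!identical(paste(tokenFromIndex(body), collapse = ""), object@source))
    msg <- c(msg, "indices do not round-trip to the source peptide")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PaddedPeptide", function(object) {
  cat(sprintf("PaddedPeptide: %s (L'=%d, frame %d, left pad %d)\n",
              object@source, object@trueLength, length(object@indices),
              object@leftPad))
})

#' @rdname PaddedPeptide-class
#' @param object a `PaddedPeptide`
#' @export
trueLength <- function(object) object@trueLength

#' @rdname PaddedPeptide-class
#' @export
leftPad <- function(object) object@leftPad

#' @rdname PaddedPeptide-class
#' @export
peptideIndices <- function(object) object@indices

## ---------------------------------------------------------------------------

#' BiclModel: a single BICL predictor with a positional-encoding strategy
#'
#' Holds the learned weights of one binding-interaction convolutional
#' network: peptide and pseudo-sequence embedding tables, the
#' kernel-generator bank (one generator per kernel size, producing
#' MHC-conditioned convolution kernels), optional post-PE injector weights,
#' and the affinity head.
#'
#' @slot params named list of weight arrays
#' @slot strategy positional-encoding strategy, see [peStrategy()]
#' @slot config model hyperparameters, see [modelConfig()]
#' @slot seed integer seed the weights were initialised with
#' @seealso [newBiclModel()], [trainModel()], [predictAffinity()]
#' @export
setClass("BiclModel",
         representation(params = "list", strategy = "list",
                        config = "list", seed = "integer"))

setMethod("show", "BiclModel", function(object) {
  st <- object@strategy
  lab <- if (st$method == "none") "baseline (no PE)" else
    sprintf("%s %s-PE(%s)", st$method, st$site, st$scope)
  np <- sum(vapply(rapply(object@params, identity, how = "unlist"),
                   length, 1L))
  cat(sprintf("BiclModel: %s | d=%d Lmax=%d | kernels %s x %s | %d parameters\n",
              lab, object@config$d, object@config$Lmax,
              paste(object@config$kernelSizes, collapse = "/"),
              paste(object@config$kernelCounts, collapse = "/"),
              np))
})

#' @rdname BiclModel-class
#' @param object a `BiclModel` or `BiclEnsemble`
#' @export
setGeneric("peStrategyOf", function(object) standardGeneric("peStrategyOf"))

#' @rdname BiclModel-class
#' @export
setMethod("peStrategyOf", "BiclModel", function(object) object@strategy)

#' @rdname BiclModel-class
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname BiclModel-class
#' @export
setMethod("modelParams", "BiclModel", function(object) object@params)

## ---------------------------------------------------------------------------

#' BiclEnsemble: T independently initialised models averaged at prediction
#'
#' @slot members list of [BiclModel-class] objects
#' @slot baseSeed integer; member i was seeded `baseSeed + i - 1`
#' @export
setClass("BiclEnsemble",
         representation(members = "list", baseSeed = "integer"))

setValidity("BiclEnsemble", function(object) {
  if (length(object@members) < 1L) return("ensemble needs at least 1 member")
  if (!all(vapply(object@members, is, TRUE, "BiclModel")))
    return("all members must be BiclModel")
  TRUE
})

setMethod("show", "BiclEnsemble", function(object) {
  cat(sprintf("BiclEnsemble of %d model(s), base seed %d\n",
              length(object@members), object@baseSeed))
  show(object@members[[1L]])
})

#' @rdname BiclEnsemble-class
#' @param object a `BiclEnsemble`
#' @export
ensembleMembers <- function(object) object@members

#' @rdname BiclEnsemble-class
#' @export
setMethod("peStrategyOf", "BiclEnsemble",
          function(object) object@members[[1L]]@strategy)

## ---------------------------------------------------------------------------

#' SyntheticMHCData: a simulated multi-allele binding-affinity benchmark
#'
#' Bundles simulated alleles (pseudo-sequence + ground-truth 9-mer energy
#' matrix with boosted anchor pockets), a binding table with hidden true
#' core offsets and motif group ids, a train/test split, and the generator
#' seed/parameters so the object is regenerable bit-identically.
#'
#' @slot alleles named list of synthetic alleles (see [makeAllele()])
#' @slot records data.frame: peptide, affinity, allele, coreStart, binder,
#'   group, split
#' @slot seed integer generator seed
#' @slot params generation parameter list
#' @export
setClass("SyntheticMHCData",
         representation(alleles = "list", records = "data.frame",
                        seed = "integer", params = "list"))

setMethod("show", "SyntheticMHCData", function(object) {
  cat(sprintf(
    "SyntheticMHCData: %d alleles, %d records (%d train / %d test), seed %d\n",
    length(object@alleles), nrow(object@records),
    sum(object@records$split == "train"),
    sum(object@records$split == "test"), object@seed))
})

#' @rdname SyntheticMHCData-class
#' @param object a `SyntheticMHCData`
#' @export
bindingRecords <- function(object) object@records

#' @rdname SyntheticMHCData-class
#' @export
syntheticAlleles <- function(object) object@alleles

#' @rdname SyntheticMHCData-class
#' @export
pseudoMap <- function(object)
  vapply(object@alleles, function(a) a$pseudo, character(1))
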