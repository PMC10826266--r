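#' Predict binding affinities
#'
#' Runs the forward pass over a table of peptide/allele pairs.  For an
#' ensemble the prediction is the arithmetic mean of the member
#' predictions.
#'
#' @param object a [BiclModel-class] or [BiclEnsemble-class]
#' @param records data.frame with columns `peptide` and `allele`
#' @param pseudo named pseudo-sequence vector (allele -> 34-mer)
#' @param batchSize internal batch size
#' @return numeric vector of predicted affinities in \[0, 1\]
#' @export
setGeneric("predictAffinity",
           function(object, records, pseudo, batchSize = 256L)
             standardGeneric("predictAffinity"))

#' @rdname predictAffinity
#' @export
setMethod("predictAffinity", "BiclModel",
          function(object, records, pseudo, batchSize = 256L) {
  prep <- .prepareSet(records, pseudo, object@config$Lmax)
  n <- nrow(records)
  out <- numeric(n)
  for (start in seq(1L, n, by = batchSize)) {
    i <- start:min(start + batchSize - 1L, n)
    out[i] <- .batchForward(object@params, object@config, object@strategy,
                            .sliceEnc(prep$enc, i), prep$alleleOf[i],
                            prep$YidxList)$z
  }
  out
})

#' @rdname predictAffinity
#' @export
setMethod("predictAffinity", "BiclEnsemble",
          function(object, records, pseudo, batchSize = 256L) {
  preds <- vapply(object@members, predictAffinity, numeric(nrow(records)),
                  records = records, pseudo = pseudo, batchSize = batchSize)
  if (nrow(records) == 1L) mean(preds) else rowMeans(matrix(preds,
                                                            nrow(records)))
})

#' Predict 9-mer binding cores
#'
#' Scores every 9-mer window that lies fully inside the unpadded peptide
#' (mean activation of the size-9 kernels of the combined
#' information-representation matrix) and reports the argmax window.  For
#' an ensemble, window scores are averaged across members before the
#' argmax.
#'
#' @inheritParams predictAffinity
#' @return data.frame: peptide, allele, coreStart (0-based, unpadded
#'   coordinates), core (9-mer sequence); the per-window score vectors are
#'   attached as attribute `"scores"`
#' @export
setGeneric("predictBindingCore",
           function(object, records, pseudo, batchSize = 256L)
             standardGeneric("predictBindingCore"))

#' @rdname predictBindingCore
#' @export
setMethod("predictBindingCore", "BiclModel",
          function(object, records, pseudo, batchSize = 256L) {
  prep <- .prepareSet(records, pseudo, object@config$Lmax)
  n <- nrow(records)
  scores <- vector("list", n)
  for (start in seq(1L, n, by = batchSize)) {
    i <- start:min(start + batchSize - 1L, n)
    fw <- .batchForward(object@params, object@config, object@strategy,
                        .sliceEnc(prep$enc, i), prep$alleleOf[i],
                        prep$YidxList, wantCore = TRUE)
    scores[i] <- fw$coreScores
  }
  .coreTable(records, scores)
})

#' @rdname predictBindingCore
#' @export
setMethod("predictBindingCore", "BiclEnsemble",
          function(object, records, pseudo, batchSize = 256L) {
  all <- lapply(object@members, function(m) {
    attr(predictBindingCore(m, records, pseudo, batchSize), "scores")
  })
  scores <- lapply(seq_len(nrow(records)), function(i) {
    Reduce(`+`, lapply(all, `[[`, i)) / length(all)
  })
  .coreTable(records, scores)
})

#' @keywords internal
.coreTable <- function(records, scores) {
  starts <- vapply(scores, predictCoreFromScores, integer(1))
  out <- data.frame(peptide = records$peptide, allele = records$allele,
                    coreStart = starts,
                    core = substr(records$peptide, starts + 1L, starts + 9L),
                    stringsAsFactors = FALSE)
  attr(out, "scores") <- scores
  out
}
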