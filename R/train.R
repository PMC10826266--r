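#' Training configuration
#'
#' Defaults are the published protocol: minibatch size 128, 20 epochs,
#' Adadelta with learning rate 0.9 and weight decay 1e-4, ensembles of
#' T = 20 models.  Adadelta's decay constant rho = 0.9 and epsilon = 1e-6
#' are the optimizer's standard values (not stated in the protocol).
#' Weight decay is applied to weight matrices and embeddings but not to
#' biases or the fixed pad row.
#'
#' @param batchSize minibatch size
#' @param epochs number of passes over the training data
#' @param learningRate Adadelta learning-rate multiplier
#' @param rho Adadelta running-average decay
#' @param epsilon Adadelta numerical-stability constant
#' @param weightDecay L2 penalty coefficient
#' @param ensembleSize number of independently initialised models T
#' @param baseSeed seed of the first ensemble member (member i uses
#'   `baseSeed + i - 1`)
#' @param strategy a [peStrategy()]
#' @param model a [modelConfig()]
#' @return a configuration list
#' @export
trainConfig <- function(batchSize = 128L, epochs = 20L, learningRate = 0.9,
                        rho = 0.9, epsilon = 1e-6, weightDecay = 1e-4,
                        ensembleSize = 20L, baseSeed = 1L,
                        strategy = peStrategy("none"),
                        model = modelConfig()) {
  stopifnot(batchSize >= 1L, epochs >= 1L, learningRate > 0, rho > 0,
            rho < 1, epsilon > 0, weightDecay >= 0, ensembleSize >= 1L)
  list(batchSize = as.integer(batchSize), epochs = as.integer(epochs),
       learningRate = learningRate, rho = rho, epsilon = epsilon,
       weightDecay = weightDecay, ensembleSize = as.integer(ensembleSize),
       baseSeed = as.integer(baseSeed), strategy = strategy, model = model)
}

#' Mean squared error
#'
#' @param predictions,targets numeric vectors of equal positive length
#' @return mean of squared differences
#' @export
mseLoss <- function(predictions, targets) {
  if (!length(predictions)) stop("empty input")
  if (length(predictions) != length(targets)) stop("length mismatch")
  mean((predictions - targets)^2)
}

# resolve records against the pseudo-sequence table and encode everything
# once; shared by training and prediction.
#' @keywords internal
.prepareSet <- function(records, pseudo, Lmax) {
  missing <- setdiff(unique(records$allele), names(pseudo))
  if (length(missing))
    stop("allele(s) absent from the pseudo-sequence table: ",
         paste(missing, collapse = ", "))
  alleles <- unique(records$allele)
  list(enc = .encodePeptides(records$peptide, Lmax),
       alleleOf = match(records$allele, alleles),
       YidxList = lapply(alleles, function(a)
         tokenIndex(strsplit(pseudo[[a]], "", fixed = TRUE)[[1L]])),
       alleles = alleles)
}

#' @keywords internal
.sliceEnc <- function(enc, i) {
  list(idx = enc$idx[i, , drop = FALSE], leftPad = enc$leftPad[i],
       trueLen = enc$trueLen[i])
}

# one Adadelta step over the flat parameter list; returns updated state.
#' @keywords internal
.adadeltaStep <- function(flatP, flatG, state, config) {
  lr <- config$learningRate; rho <- config$rho; eps <- config$epsilon
  wd <- config$weightDecay
  for (key in names(flatP)) {
    gr <- flatG[[key]]
    if (is.null(gr)) next
    decay <- !grepl("(\\.b$|^b[12]$)", key)
    if (decay && wd > 0) gr <- gr + wd * flatP[[key]]
    state$Eg[[key]] <- rho * state$Eg[[key]] + (1 - rho) * gr^2
    dx <- -sqrt((state$Ed[[key]] + eps) / (state$Eg[[key]] + eps)) * gr
    state$Ed[[key]] <- rho * state$Ed[[key]] + (1 - rho) * dx^2
    flatP[[key]] <- flatP[[key]] + lr * dx
  }
  list(p = flatP, state = state)
}

#' Train a single BICL model
#'
#' Minimises the mean squared error between predicted and target affinities
#' with Adadelta, shuffling the records every epoch.  Fully deterministic
#' given the seed: weight initialisation uses `seed` and the shuffling
#' stream uses `seed + 1`.
#'
#' @param records data.frame with columns peptide, affinity, allele
#' @param pseudo named pseudo-sequence vector (allele -> 34-mer)
#' @param config a [trainConfig()]
#' @param seed integer; default the config's `baseSeed`
#' @param verbose print per-epoch training loss
#' @return a trained [BiclModel-class]; per-epoch losses are attached as
#'   attribute `"trainLog"`
#' @export
trainModel <- function(records, pseudo, config = trainConfig(),
                       seed = config$baseSeed, verbose = FALSE) {
  if (!nrow(records)) stop("no training records")
  prep <- .prepareSet(records, pseudo, config$model$Lmax)
  model <- newBiclModel(config$strategy, config$model, seed)
  flatP <- .flattenParams(model@params)
  state <- list(Eg = lapply(flatP, function(x) x * 0),
                Ed = lapply(flatP, function(x) x * 0))
  n <- nrow(records)
  target <- records$affinity
  bs <- config$batchSize
  nFeat <- sum(config$model$kernelCounts)
  log <- numeric(config$epochs)
  withSeed(as.integer(seed) + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      lossAcc <- 0
      params <- .unflattenInto(model@params, flatP)
      for (start in seq(1L, n, by = bs)) {
        batch <- ord[start:min(start + bs - 1L, n)]
        dr <- config$model$dropout
        dropMask <- if (dr > 0)
          matrix(stats::rbinom(length(batch) * nFeat, 1L, 1 - dr) / (1 - dr),
                 length(batch), nFeat)
        fw <- .batchForward(params, config$model, config$strategy,
                            .sliceEnc(prep$enc, batch),
                            prep$alleleOf[batch], prep$YidxList,
                            wantCache = TRUE, dropMask = dropMask)
        err <- fw$z - target[batch]
        lossAcc <- lossAcc + sum(err^2)
        dz <- 2 * err / length(batch)
        grads <- .batchBackward(params, config$model, config$strategy,
                                fw$cache, dz)
        names(grads$conv) <- names(params$conv)
        if (!is.null(grads$postO)) names(grads$postO) <- names(params$postO)
        if (!is.null(grads$postT)) names(grads$postT) <- names(params$postT)
        upd <- .adadeltaStep(flatP, .flattenParams(grads), state, config)
        flatP <- upd$p
        state <- upd$state
        params <- .unflattenInto(params, flatP)
      }
      log[epoch] <- lossAcc / n
      if (verbose)
        message(sprintf("epoch %3d  train MSE %.5f", epoch, log[epoch]))
    }
  })
  model@params <- .unflattenInto(model@params, flatP)
  attr(model, "trainLog") <- log
  model
}

#' Train an ensemble of T models
#'
#' Member i is initialised and shuffled with seed `baseSeed + i - 1`; the
#' ensemble prediction is the arithmetic mean of the member predictions.
#'
#' @inheritParams trainModel
#' @param verbose print progress per member
#' @return a [BiclEnsemble-class]
#' @export
trainEnsemble <- function(records, pseudo, config = trainConfig(),
                          verbose = FALSE) {
  members <- lapply(seq_len(config$ensembleSize), function(i) {
    if (verbose) message("training ensemble member ", i, "/",
                         config$ensembleSize)
    trainModel(records, pseudo, config, seed = config$baseSeed + i - 1L)
  })
  new("BiclEnsemble", members = members, baseSeed = config$baseSeed)
}

#' Assign records to cross-validation folds, keeping motif groups intact
#'
#' Records sharing a `group` value (peptides with a common binding motif)
#' are always placed in the same fold, mirroring motif-grouped benchmark
#' splits that prevent leakage of near-duplicate peptides across folds.
#' Groups are assigned greedily, largest first, to the currently smallest
#' fold.  If the records carry a pre-existing `fold` column it is returned
#' verbatim.
#'
#' @param records data.frame; optional columns `group` and `fold`
#' @param nFolds number of folds (>= 2)
#' @param seed seed for tie-breaking among equal-sized groups
#' @return integer vector of 0-based fold ids, one per record
#' @export
assignFolds <- function(records, nFolds = 5L, seed = 1L) {
  if (nFolds < 2L) stop("need at least 2 folds")
  if (!is.null(records$fold)) {
    f <- as.integer(records$fold)
    if (any(is.na(f) | f < 0L | f >= nFolds)) stop("bad pre-existing fold id")
    return(f)
  }
  grp <- records$group
  if (is.null(grp)) grp <- rep(NA_character_, nrow(records))
  grp <- ifelse(is.na(grp) | grp == "" | grp == "NA",
                paste0(".singleton", seq_along(grp)), grp)
  tab <- table(grp)
  ord <- withSeed(seed, order(-as.integer(tab), stats::runif(length(tab))))
  sizes <- integer(nFolds)
  foldOfGroup <- integer(length(tab))
  names(foldOfGroup) <- names(tab)
  for (i in ord) {
    f <- which.min(sizes)
    foldOfGroup[i] <- f - 1L
    sizes[f] <- sizes[f] + as.integer(tab[i])
  }
  unname(foldOfGroup[grp])
}

#' Motif-grouped k-fold cross-validation
#'
#' For each fold, trains on the remaining folds and predicts the held-out
#' records, so every record receives exactly one out-of-fold prediction.
#'
#' @inheritParams trainModel
#' @param nFolds number of folds
#' @param foldIds optional integer vector of 0-based fold ids; computed
#'   with [assignFolds()] when absent
#' @param ensembleSize models trained per fold (defaults to the config's
#'   ensemble size)
#' @param threshold binder threshold for the per-fold reports
#' @param verbose print progress
#' @return list: `predictions` (out-of-fold, in record order), `folds`,
#'   `foldReports` (per-fold [perAlleleReport()] tables)
#' @export
crossValidate <- function(records, pseudo, config = trainConfig(),
                          nFolds = 5L, foldIds = NULL,
                          ensembleSize = config$ensembleSize,
                          threshold = 0.426, verbose = FALSE) {
  if (is.null(foldIds))
    foldIds <- assignFolds(records, nFolds, seed = config$baseSeed)
  if (length(foldIds) != nrow(records)) stop("foldIds length mismatch")
  counts <- tabulate(foldIds + 1L, nFolds)
  if (any(counts == 0L)) stop("a fold has zero records")
  predictions <- rep(NA_real_, nrow(records))
  foldReports <- vector("list", nFolds)
  cfg <- config
  cfg$ensembleSize <- as.integer(ensembleSize)
  for (f in seq_len(nFolds) - 1L) {
    if (verbose) message("fold ", f, ": training on ",
                         sum(foldIds != f), " records")
    hold <- which(foldIds == f)
    fit <- if (cfg$ensembleSize == 1L)
      trainModel(records[-hold, , drop = FALSE], pseudo, cfg)
    else trainEnsemble(records[-hold, , drop = FALSE], pseudo, cfg)
    predictions[hold] <- predictAffinity(fit, records[hold, , drop = FALSE],
                                         pseudo)
    foldReports[[f + 1L]] <-
      perAlleleReport(records[hold, , drop = FALSE], predictions[hold],
                      threshold = threshold)
  }
  list(predictions = predictions, folds = foldIds, foldReports = foldReports)
}
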