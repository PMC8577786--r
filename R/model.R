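#' Encode a context set as integer codon labels
#'
#' Maps each codon of the concatenated pre+post context to its 1..64 index.
#' Region masking sets an entire half to the null label 0, which the model
#' embeds at the origin: a masked half contributes nothing to the logits.
#'
#' @param contexts a [ContextSet-class]
#' @param region "both" (no masking), "pre_only" (post half masked) or
#'   "post_only" (pre half masked)
#' @return integer matrix, one row per example, L = 2*C/3 columns
#' @export
encodeContexts <- function(contexts, region = c("both", "pre_only", "post_only")) {
  region <- match.arg(region)
  m <- .codonMatrix(contexts)
  idx <- matrix(codonIndex()[as.vector(m)], nrow = nrow(m))
  k <- ncol(idx) %/% 2L
  if (region == "pre_only") idx[, k + seq_len(k)] <- 0L
  if (region == "post_only") idx[, seq_len(k)] <- 0L
  storage.mode(idx) <- "integer"
  idx
}

#' Default training configuration
#'
#' @param learningRate SGD learning rate (default 0.001)
#' @param batchSize mini-batch size (default 64)
#' @param dim embedding dimension d (default 2)
#' @param maxEpochs maximum training epochs (default 500)
#' @param patience epochs without validation-AUC improvement before stopping
#'   (default 20)
#' @param region which context half the model sees (default "both")
#' @param seed integer seed governing initialisation, oversampling and batch
#'   order
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 64L, dim = 2L,
                        maxEpochs = 500L, patience = 20L,
                        region = c("both", "pre_only", "post_only"), seed = 1L) {
  list(learningRate = learningRate, batchSize = as.integer(batchSize),
       dim = as.integer(dim), maxEpochs = as.integer(maxEpochs),
       patience = as.integer(patience), region = match.arg(region),
       seed = as.integer(seed))
}

#' Initialise an untrained codon-context classifier
#'
#' Embeddings and output weights start from a small-scale uniform draw;
#' the null-label embedding (row 0) is pinned at the origin and stays there
#' throughout training. The output layer has no bias, so an all-masked input
#' always scores exactly 0.5.
#'
#' @param contextNt context size C in nucleotides per flank
#' @param dim embedding dimension d
#' @param seed integer seed for the initial draw
#' @return a [CodonContextModel-class]
#' @export
newCodonContextModel <- function(contextNt = 162L, dim = 2L, seed = 1L) {
  stopifnot(contextNt %% 3L == 0L)
  L <- 2L * contextNt %/% 3L
  set.seed(seed)
  E <- matrix(stats::runif(65L * dim, -0.05, 0.05), nrow = 65L)
  E[1L, ] <- 0
  rownames(E) <- c("<null>", allCodons())
  W <- matrix(stats::runif(L * dim * 2L, -0.05, 0.05), ncol = 2L)
  colnames(W) <- c("hit", "decoy")
  methods::new("CodonContextModel", embedding = E, weights = W,
               contextNt = as.integer(contextNt), dim = as.integer(dim),
               codonIndex = codonIndex(), config = list(seed = seed),
               history = data.frame())
}

#' Score encoded or raw contexts
#'
#' @param model a [CodonContextModel-class]
#' @param contexts a [ContextSet-class] or an integer encoding matrix
#' @param region masking applied when \code{contexts} is a ContextSet
#'   (defaults to the region the model was trained with, else "both")
#' @return numeric vector of hit probabilities in (0, 1)
#' @export
predictScores <- function(model, contexts, region = NULL) {
  if (methods::is(contexts, "ContextSet")) {
    if (is.null(region)) region <- model@config$region %||% "both"
    idx <- encodeContexts(contexts, region)
  } else {
    idx <- contexts
  }
  if (ncol(idx) != 2L * model@contextNt %/% 3L) {
    stop("encoding has ", ncol(idx), " positions; model expects ",
         2L * model@contextNt %/% 3L)
  }
  as.vector(cpp_forward(model@embedding, model@weights, idx))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve
#'
#' Probability that a random hit outranks a random decoy, ties counted one
#' half (the rank-statistic form of the AUC).
#'
#' @param scores numeric scores, higher = more hit-like
#' @param labels logical / 0-1 / "hit"-"decoy" labels
#' @return AUC in [0, 1]
#' @export
aucScore <- function(scores, labels) {
  pos <- if (is.character(labels)) labels == "hit" else as.logical(labels)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("need at least one example of each class")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Train the codon-context classifier
#'
#' Mini-batch SGD on softmax cross-entropy with per-epoch oversampling: at
#' each epoch the minority hits are resampled with replacement up to the decoy
#' count, so the network sees balanced classes. Early stopping monitors
#' validation AUC; the parameters from the best validation epoch are returned.
#'
#' @param split a [ContextSplit-class]
#' @param config list from [trainConfig()]
#' @return a [CodonContextModel-class] with training history
#' @export
trainModel <- function(split, config = trainConfig()) {
  region <- config$region %||% "both"
  trIdx <- encodeContexts(split@train, region)
  vaIdx <- encodeContexts(split@validation, region)
  trLab <- exampleLabels(split@train) == "hit"
  vaLab <- exampleLabels(split@validation) == "hit"
  if (!any(trLab) || all(trLab) || !any(vaLab) || all(vaLab)) {
    stop("train and validation subsets must both contain hits and decoys")
  }
  model <- newCodonContextModel(contextSize(split@train), config$dim, config$seed)
  E <- model@embedding; W <- model@weights
  posI <- which(trLab); negI <- which(!trLab)
  nMaj <- max(length(posI), length(negI))
  set.seed(config$seed)
  bestAuc <- -Inf; bestE <- E; bestW <- W; sinceBest <- 0L
  hist <- vector("list", config$maxEpochs)
  y <- as.integer(trLab)
  for (epoch in seq_len(config$maxEpochs)) {
    # oversample the minority class with replacement to balance the epoch
    posEp <- if (length(posI) < nMaj) sample(posI, nMaj, replace = TRUE) else posI
    negEp <- if (length(negI) < nMaj) sample(negI, nMaj, replace = TRUE) else negI
    ord <- sample(c(posEp, negEp)) - 1L
    res <- cpp_sgd_epoch(E, W, trIdx, y, ord, config$learningRate, config$batchSize)
    E <- res$E; W <- res$W
    vauc <- aucScore(as.vector(cpp_forward(E, W, vaIdx)), vaLab)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = res$loss,
                                validation_auc = vauc)
    if (vauc > bestAuc + 1e-12) {
      bestAuc <- vauc; bestE <- E; bestW <- W; sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest >= config$patience) break
    }
  }
  rownames(bestE) <- rownames(model@embedding)
  colnames(bestW) <- colnames(model@weights)
  methods::new("CodonContextModel", embedding = bestE, weights = bestW,
               contextNt = model@contextNt, dim = model@dim,
               codonIndex = model@codonIndex,
               config = c(config, list(bestValidationAuc = bestAuc)),
               history = do.call(rbind, hist[!vapply(hist, is.null, logical(1))]))
}

#' Save / load a model as human-readable JSON
#'
#' The file carries the embedding, output weights, codon index snapshot and
#' training configuration, so a saved model is self-describing and
#' language-neutral.
#'
#' @param model a [CodonContextModel-class]
#' @param path JSON path
#' @export
writeModel <- function(model, path) {
  obj <- list(
    context_nt = model@contextNt, dim = model@dim,
    codon_index = as.list(model@codonIndex),
    embedding = unname(apply(model@embedding, 1L, as.numeric, simplify = FALSE)),
    weights = unname(apply(model@weights, 1L, as.numeric, simplify = FALSE)),
    config = model@config[setdiff(names(model@config), "bestValidationAuc")]
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  # row-wise lists may come back simplified to a matrix already
  E <- if (is.matrix(obj$embedding)) obj$embedding else
    matrix(unlist(obj$embedding), nrow = 65L, byrow = TRUE)
  rownames(E) <- c("<null>", allCodons())
  W <- if (is.matrix(obj$weights)) obj$weights else
    matrix(unlist(obj$weights), ncol = 2L, byrow = TRUE)
  colnames(W) <- c("hit", "decoy")
  ci <- unlist(obj$codon_index)
  methods::new("CodonContextModel", embedding = E, weights = W,
               contextNt = as.integer(obj$context_nt), dim = as.integer(obj$dim),
               codonIndex = structure(as.integer(ci), names = names(ci)),
               config = as.list(obj$config), history = data.frame())
}
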