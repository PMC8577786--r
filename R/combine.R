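#' Keep peptides predicted to bind at least one allele
#'
#' Filters feature rows to ligand rank <= maxRank (percentile rank, lower is
#' stronger; the boundary is inclusive). When several alleles supply ranks the
#' minimum rank should already represent the peptide.
#'
#' @param rows data.frame with a \code{ligand_rank} column (percent)
#' @param maxRank inclusive rank threshold (default 1)
#' @export
binderFilter <- function(rows, maxRank = 1) {
  rows[!is.na(rows$ligand_rank) & rows$ligand_rank <= maxRank, , drop = FALSE]
}

#' Collapse multi-origin peptides to one feature row each
#'
#' Keeps one row per peptide: the maximum expression over origins, the minimum
#' ligand rank over alleles/origins, the maximum classifier score, and the
#' label "hit" if any origin row is a hit.
#'
#' @param rows data.frame (peptide, context_score, ligand_rank, expression, label)
#' @export
collapseByPeptide <- function(rows) {
  sp <- split(rows, rows$peptide)
  out <- lapply(sp, function(g) {
    data.frame(peptide = g$peptide[1L],
               context_score = max(g$context_score),
               ligand_rank = min(g$ligand_rank),
               expression = max(g$expression),
               label = if (any(g$label == "hit")) "hit" else "decoy",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Min-max scaler learned on training data
#'
#' @param train data.frame; \code{features} columns are scaled to [0, 1] using
#'   the training min/max; the same transform is applied unchanged to test
#'   data. Degenerate features (min = max) map to 0.
#' @param features character vector of column names
#' @return scaler object (list with mins/maxs) for [applyScaler()]
#' @export
fitScaler <- function(train, features) {
  list(features = features,
       min = vapply(features, function(f) min(train[[f]]), numeric(1)),
       max = vapply(features, function(f) max(train[[f]]), numeric(1)))
}

#' @rdname fitScaler
#' @param scaler object from [fitScaler()]
#' @param rows data.frame to transform
#' @export
applyScaler <- function(scaler, rows) {
  for (f in scaler$features) {
    span <- scaler$max[[f]] - scaler$min[[f]]
    rows[[f]] <- if (span > 0) (rows[[f]] - scaler$min[[f]]) / span else 0
  }
  rows
}

#' Fit a presentation combiner over peptide-level features
#'
#' Combines classifier score, ligand rank and transcript expression (any
#' subset) into a presentation predictor. "logistic" is an L2-regularised
#' logistic regression with 10-fold cross-validation over the regularisation
#' strength; "mlp" is a single-hidden-layer perceptron. Classes are balanced
#' through case weights and features are min-max scaled on the training data.
#'
#' @param train data.frame with the feature columns and a \code{label} column
#'   ("hit"/"decoy")
#' @param features character vector of feature column names
#' @param kind "logistic" or "mlp"
#' @param seed integer seed (fold assignment / weight initialisation)
#' @param hidden hidden-layer width for the MLP (reference setting 1000; a
#'   smaller width is adequate for the few-feature problems here)
#' @param maxit iteration cap for the MLP optimiser (reference setting 4000);
#'   the MLP relies on the cap rather than a held-out early-stopping monitor
#' @return combiner object for [predictCombiner()]
#' @export
fitCombiner <- function(train, features, kind = c("logistic", "mlp"),
                        seed = 1L, hidden = 1000L, maxit = 4000L) {
  kind <- match.arg(kind)
  if (length(unique(train$label)) < 2L) stop("training data needs both classes")
  scaler <- fitScaler(train, features)
  tr <- applyScaler(scaler, train)
  y <- as.integer(tr$label == "hit")
  w <- ifelse(y == 1L, 0.5 / mean(y == 1L), 0.5 / mean(y == 0L))
  x <- as.matrix(tr[, features, drop = FALSE])
  pad <- ncol(x) < 2L
  if (pad) x <- cbind(x, .pad = 0)   # glmnet needs >= 2 columns
  set.seed(seed)
  fit <- if (kind == "logistic") {
    foldid <- sample(rep(seq_len(10L), length.out = nrow(x)))
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = 0, foldid = foldid,
                      weights = w, maxit = 1000L, standardize = FALSE)
  } else {
    nnet::nnet(x, y, size = hidden, weights = w, entropy = TRUE,
               maxit = maxit, MaxNWts = (ncol(x) + 2L) * hidden + 1000L,
               trace = FALSE)
  }
  structure(list(kind = kind, features = features, scaler = scaler,
                 pad = pad, fit = fit), class = "presentationCombiner")
}

#' Score rows with a fitted combiner
#' @param combiner object from [fitCombiner()]
#' @param rows data.frame with the feature columns
#' @return numeric vector of hit probabilities
#' @export
predictCombiner <- function(combiner, rows) {
  rows <- applyScaler(combiner$scaler, rows)
  x <- as.matrix(rows[, combiner$features, drop = FALSE])
  if (combiner$pad) x <- cbind(x, .pad = 0)
  if (combiner$kind == "logistic") {
    as.vector(stats::predict(combiner$fit, newx = x, s = "lambda.min",
                             type = "response"))
  } else {
    as.vector(stats::predict(combiner$fit, x))
  }
}

#' Matthews correlation coefficient at a score cutoff
#'
#' @param labels "hit"/"decoy", logical or 0/1 truth
#' @param scores numeric predictions
#' @param cutoff scores above this are called positive (default 0.5)
#' @return MCC in [-1, 1]; 0 when any margin of the confusion table is empty
#' @export
matthewsCC <- function(labels, scores, cutoff = 0.5) {
  truth <- if (is.character(labels)) labels == "hit" else as.logical(labels)
  call <- scores > cutoff
  tp <- sum(call & truth); tn <- sum(!call & !truth)
  fp <- sum(call & !truth); fn <- sum(!call & truth)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

#' Peptides needed to capture a fraction of the true hits
#'
#' Rank-orders peptides by descending score and finds the smallest prefix
#' containing ceiling(fraction * n_hits) hits; peptides tied with the boundary
#' score are all included. Reports the prefix size and its false positive rate.
#'
#' @param scores numeric predictions
#' @param labels "hit"/"decoy", logical or 0/1 truth
#' @param fraction fraction of hits to capture, in (0, 1]
#' @return list(n_peptides, fpr, hits_captured, hits_required)
#' @export
captureAtFraction <- function(scores, labels, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  truth <- if (is.character(labels)) labels == "hit" else as.logical(labels)
  if (!any(truth)) stop("need at least one hit")
  need <- ceiling(fraction * sum(truth))
  ord <- order(scores, decreasing = TRUE)
  cumHits <- cumsum(truth[ord])
  nMin <- which(cumHits >= need)[1L]
  # include every peptide tied with the boundary score (deterministic)
  boundary <- scores[ord][nMin]
  n <- max(which(scores[ord] >= boundary))
  hitsCaptured <- cumHits[n]
  list(n_peptides = n, fpr = (n - hitsCaptured) / n,
       hits_captured = hitsCaptured, hits_required = need)
}

#' Compare feature subsets on a train/test split
#'
#' Fits one combiner per feature subset on a stratified 70/30 split and
#' reports test MCC and the capture table at the requested hit fractions.
#'
#' @param rows peptide-level feature rows (after [collapseByPeptide()] and
#'   [binderFilter()] as appropriate)
#' @param featureSets named list of character vectors of feature columns
#' @param kind "logistic" or "mlp"
#' @param fractions hit fractions for the capture table
#' @param trainFraction train share of the split (default 0.7)
#' @param seed integer seed (split and fitting)
#' @param ... passed to [fitCombiner()]
#' @return list with \code{mcc} (named numeric), \code{capture} (data.frame)
#'   and the split indices
#' @export
evaluateFeatureSets <- function(rows, featureSets, kind = "logistic",
                                fractions = c(0.01, 0.05, 0.10, 0.50),
                                trainFraction = 0.7, seed = 1L, ...) {
  set.seed(seed)
  byClass <- split(seq_len(nrow(rows)), rows$label)
  trainIdx <- sort(unlist(lapply(byClass, function(i)
    sample(i, round(trainFraction * length(i))))))
  testIdx <- setdiff(seq_len(nrow(rows)), trainIdx)
  train <- rows[trainIdx, , drop = FALSE]
  test <- rows[testIdx, , drop = FALSE]
  mcc <- numeric(0)
  cap <- list()
  for (nm in names(featureSets)) {
    fit <- fitCombiner(train, featureSets[[nm]], kind, seed = seed, ...)
    sc <- predictCombiner(fit, test)
    mcc[nm] <- matthewsCC(test$label, sc)
    for (f in fractions) {
      cp <- captureAtFraction(sc, test$label, f)
      cap[[length(cap) + 1L]] <- data.frame(
        features = nm, fraction = f, n_peptides = cp$n_peptides,
        fpr = cp$fpr, hits_captured = cp$hits_captured)
    }
  }
  list(mcc = mcc, capture = do.call(rbind, cap),
       trainIdx = trainIdx, testIdx = testIdx)
}
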