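#' Position labels for a context of C nucleotides per flank
#'
#' Positions are indexed relative to the MCC: -C/3..-1 upstream, +1..+C/3
#' downstream.
#' @param contextNt context size C in nucleotides per flank
#' @export
positionLabels <- function(contextNt) {
  k <- contextNt %/% 3L
  c(-k:-1, 1:k)
}

# 64 x L count matrix: occurrences of each codon at each position
.positionalCounts <- function(contexts, which = NULL) {
  L <- 2L * contextSize(contexts) %/% 3L
  m <- .codonMatrix(contexts)
  if (!is.null(which)) m <- m[which, , drop = FALSE]
  counts <- if (nrow(m) == 0L) matrix(0L, 64L, L) else {
    idx <- matrix(codonIndex()[as.vector(m)], nrow = nrow(m), ncol = L)
    vapply(seq_len(L), function(x) tabulate(idx[, x], 64L), integer(64L))
  }
  dimnames(counts) <- list(allCodons(), positionLabels(contextSize(contexts)))
  counts
}

#' Positional distribution of a codon within a class
#'
#' The probability of finding codon c at position i, given codon c: counts of
#' c per position divided by the codon's total count over all positions (MCC
#' positions are excluded by construction since contexts never contain them).
#'
#' @param contexts a [ContextSet-class]
#' @param codon codon, e.g. "CTG"
#' @param class "hit" or "decoy"
#' @return data.frame (position, count, prob); \code{prob} is NA everywhere
#'   when the codon never occurs in the class
#' @export
positionalDistribution <- function(contexts, codon, class = c("hit", "decoy")) {
  class <- match.arg(class)
  stopifnot(codon %in% allCodons())
  counts <- .positionalCounts(contexts, exampleLabels(contexts) == class)[codon, ]
  tot <- sum(counts)
  data.frame(position = positionLabels(contextSize(contexts)),
             count = as.integer(counts),
             prob = if (tot > 0) counts / tot else rep(NA_real_, length(counts)))
}

#' Kullback-Leibler divergence between two positional distributions
#'
#' D(P||Q) = sum_i P(i) log(P(i)/Q(i)), in nats. With \code{eps} > 0 both
#' distributions receive the pseudo-probability before renormalisation, so
#' empirical zeros do not produce infinities.
#'
#' @param p,q non-negative vectors of equal length (renormalised internally)
#' @param eps smoothing pseudo-probability added to every cell (default 0)
#' @return non-negative divergence in nats; 0 iff P = Q after smoothing
#' @export
klDivergence <- function(p, q, eps = 0) {
  stopifnot(length(p) == length(q), eps >= 0)
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  if (any(q == 0 & p > 0)) stop("Q has zero mass where P > 0 and eps = 0: divergence infinite")
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

#' Per-codon KL divergence in original versus shuffled sequences
#'
#' For each of the 61 sense codons, computes the divergence between its hit
#' and decoy positional distributions in the original data (y) and in the
#' shuffled data (x). Codons lying above the diagonal (y > x) carry more
#' class information in their codon-level placement than survives synonymous
#' shuffling, i.e. information beyond amino-acid usage.
#'
#' @param hits,decoys,shuffledHits,shuffledDecoys [ContextSet-class]s sharing
#'   one context size
#' @param eps smoothing pseudo-probability; default 1/(total positional count
#'   of the two distributions being compared)
#' @return data.frame (codon, amino_acid, kl_original, kl_shuffled) with
#'   attribute \code{fractionAboveDiagonal}
#' @export
klScatter <- function(hits, decoys, shuffledHits, shuffledDecoys, eps = NULL) {
  Cs <- vapply(list(hits, decoys, shuffledHits, shuffledDecoys),
               contextSize, integer(1))
  if (length(unique(Cs)) != 1L) stop("all four sets must share one context size")
  cp <- .positionalCounts(hits); cd <- .positionalCounts(decoys)
  csp <- .positionalCounts(shuffledHits); csd <- .positionalCounts(shuffledDecoys)
  aa <- codonToAminoAcid()
  sense <- allCodons()[aa != "*"]
  klPair <- function(a, b) {
    e <- if (is.null(eps)) 1 / max(1, sum(a) + sum(b)) else eps
    klDivergence(a, b, e)
  }
  out <- data.frame(
    codon = sense, amino_acid = unname(aa[sense]),
    kl_original = vapply(sense, function(c) klPair(cp[c, ], cd[c, ]), numeric(1)),
    kl_shuffled = vapply(sense, function(c) klPair(csp[c, ], csd[c, ]), numeric(1)),
    row.names = NULL
  )
  attr(out, "fractionAboveDiagonal") <- mean(out$kl_original > out$kl_shuffled)
  out
}

#' Analytic per-codon positional preferences
#'
#' The preference of codon c at position x is the model's output probability
#' when every position is masked except x, which carries c. Because the model
#' has no bias and no hidden layer this equals softmax(E_c %*% W_x) in closed
#' form; 0.5 is neutral, values above/below 0.5 push towards hit/decoy. A
#' codon whose embedding sits at the origin is neutral (0.5) at every
#' position.
#'
#' @param model a [CodonContextModel-class]
#' @return 64 x L matrix of preferences in (0, 1); rows are codons, columns
#'   the positions -C/3..-1, +1..+C/3
#' @export
preferences <- function(model) {
  d <- model@dim
  L <- 2L * model@contextNt %/% 3L
  E <- model@embedding[-1L, , drop = FALSE]  # 64 codon rows
  out <- matrix(NA_real_, 64L, L,
                dimnames = list(allCodons(), positionLabels(model@contextNt)))
  for (x in seq_len(L)) {
    Wx <- model@weights[(x - 1L) * d + seq_len(d), , drop = FALSE]
    logits <- E %*% Wx
    out[, x] <- 1 / (1 + exp(logits[, 2L] - logits[, 1L]))
  }
  out
}

#' Learned codon embedding coordinates
#'
#' @param model a [CodonContextModel-class]
#' @return data.frame (codon, amino_acid, e1..ed); the null label is excluded
#'   (it is fixed at the origin)
#' @export
embeddingCoordinates <- function(model) {
  E <- model@embedding[-1L, , drop = FALSE]
  out <- data.frame(codon = allCodons(),
                    amino_acid = unname(codonToAminoAcid()),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(E))) out[[paste0("e", j)]] <- unname(E[, j])
  out
}

#' Write a preference matrix (codon x position) to TSV
#' @param pref matrix from [preferences()]
#' @param path TSV path
#' @export
writePreferences <- function(pref, path) {
  utils::write.table(data.frame(codon = rownames(pref), pref, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
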