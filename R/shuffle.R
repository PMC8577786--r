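#' @useDynLib codonMAP, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# n x L character matrix of codons (pre then post) for a ContextSet
.codonMatrix <- function(contexts) {
  ex <- exampleTable(contexts)
  comb <- paste0(ex$pre, ex$post)
  L <- 2L * contextSize(contexts) %/% 3L
  m <- matrix("", nrow = length(comb), ncol = L)
  for (x in seq_len(L)) m[, x] <- substr(comb, 3L * x - 2L, 3L * x)
  m
}

# rebuild a ContextSet from a codon matrix, keeping all metadata columns
.fromCodonMatrix <- function(contexts, m) {
  ex <- exampleTable(contexts)
  k <- contextSize(contexts) %/% 3L
  join <- function(cols) do.call(paste0, as.data.frame(m[, cols, drop = FALSE]))
  ex$pre <- join(seq_len(k))
  ex$post <- join(k + seq_len(k))
  methods::new("ContextSet", examples = ex, contextNt = contextSize(contexts))
}

.shuffleMatTranscriptome <- function(m, usage) {
  wff <- withinFamilyFreq(usage)
  fam <- synonymFamilies()
  aa <- codonToAminoAcid()
  present <- unique(as.vector(m))
  famSums <- vapply(present, function(c) sum(wff[fam[[aa[[c]]]]]), numeric(1))
  if (any(famSums <= 0)) {
    stop("usage table does not cover codon(s): ",
         paste(present[famSums <= 0], collapse = ", "))
  }
  out <- m
  for (c in present) {
    syn <- fam[[aa[[c]]]]
    idx <- which(m == c)
    if (length(syn) == 1L) next
    out[idx] <- sample(syn, length(idx), replace = TRUE, prob = wff[syn])
  }
  out
}

.shuffleMatCodonSwap <- function(m) {
  n <- nrow(m); L <- ncol(m)
  aa <- codonToAminoAcid()[as.vector(m)]
  row <- rep(seq_len(n), times = L)
  # two independent random orderings within each (example, amino acid) group:
  # mapping one onto the other permutes codons uniformly within groups
  o1 <- order(row, aa, stats::runif(n * L))
  o2 <- order(row, aa, stats::runif(n * L))
  out <- m
  out[o2] <- m[o1]
  out
}

.shuffleMatThirdNt <- function(m, proposalsPerSite = 10L) {
  ci <- codonIndex()
  idx <- matrix(ci[as.vector(m)], nrow = nrow(m))
  aaCode <- as.integer(factor(codonToAminoAcid()))  # 1..21 per codon index
  shuf <- cpp_third_nt_shuffle(idx, aaCode, proposalsPerSite)
  matrix(allCodons()[shuf], nrow = nrow(m))
}

#' Synonymous-shuffling null models
#'
#' Three label-blind shuffles that erase codon-level signal while preserving
#' the amino-acid sequence of every example:
#' \describe{
#'   \item{transcriptome}{each codon is independently replaced by a synonym
#'     (possibly itself) drawn with the transcriptome-wide within-family usage
#'     frequencies; removes class-specific synonymous usage and per-example GC
#'     differences.}
#'   \item{codonswap}{synonymous codons within one example are permuted among
#'     the positions they occupy; preserves the per-example codon multiset and
#'     hence GC content exactly.}
#'   \item{thirdnt}{third codon nucleotides are swapped pairwise within an
#'     example, a swap being accepted only when both resulting codons remain
#'     synonymous to their originals (a rejection Markov chain of
#'     10 proposals per site); preserves the per-example third-position
#'     nucleotide multiset and hence GC content, ignoring usage frequencies.}
#' }
#' Pre and post flanks are shuffled jointly as one example.
#'
#' @param contexts a [ContextSet-class]
#' @param method one of "transcriptome", "codonswap", "thirdnt"
#' @param usage a [CodonUsageTable-class]; required for "transcriptome"
#' @param seed integer seed
#' @return a [ContextSet-class] with the same schema and metadata
#' @export
shuffleExamples <- function(contexts, method = c("transcriptome", "codonswap", "thirdnt"),
                            usage = NULL, seed = 1L) {
  method <- match.arg(method)
  set.seed(seed)
  m <- .codonMatrix(contexts)
  m2 <- switch(method,
    transcriptome = {
      if (is.null(usage)) stop("transcriptome shuffling needs a usage table")
      .shuffleMatTranscriptome(m, usage)
    },
    codonswap = .shuffleMatCodonSwap(m),
    thirdnt = .shuffleMatThirdNt(m)
  )
  .fromCodonMatrix(contexts, m2)
}

#' @rdname shuffleExamples
#' @details \code{shuffleCodons()} applies a method to a bare codon vector
#'   (one example) and returns the shuffled codon vector; convenient for
#'   property checks on single sequences.
#' @param codons character vector of codons (one example)
#' @export
shuffleCodons <- function(codons, method = c("transcriptome", "codonswap", "thirdnt"),
                          usage = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(codons, nrow = 1L)
  m2 <- switch(method,
    transcriptome = {
      if (is.null(usage)) stop("transcriptome shuffling needs a usage table")
      .shuffleMatTranscriptome(m, usage)
    },
    codonswap = .shuffleMatCodonSwap(m),
    thirdnt = .shuffleMatThirdNt(m)
  )
  as.vector(m2)
}
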