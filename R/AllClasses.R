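#' @import methods
NULL

#' Codon usage table
#'
#' Holds codon counts over a collection of coding sequences together with two
#' normalisations: the global relative frequency of each codon over all counted
#' codons, and the relative frequency of each codon within its synonym family
#' (the codons encoding the same amino acid, stop treated as its own family).
#' Within-family frequencies are the sampling weights used by the
#' transcriptome-level synonymous shuffle.
#'
#' @slot table data.frame with columns \code{codon}, \code{amino_acid},
#'   \code{count}, \code{global_freq}, \code{within_family_freq}, one row per
#'   codon (64 rows, fixed order).
#' @seealso [codonUsage()], [shuffleTranscriptome()]
#' @export
setClass("CodonUsageTable", representation(table = "data.frame"))

setValidity("CodonUsageTable", function(object) {
  tab <- object@table
  need <- c("codon", "amino_acid", "count", "global_freq", "within_family_freq")
  if (!all(need %in% names(tab))) {
    return(paste("missing columns:", paste(setdiff(need, names(tab)), collapse = ", ")))
  }
  if (nrow(tab) != 64L || anyDuplicated(tab$codon)) {
    return("table must have one row per codon (64 rows)")
  }
  if (any(tab$global_freq < 0) || any(tab$within_family_freq < 0, na.rm = TRUE)) {
    return("frequencies must be non-negative")
  }
  # within-family frequencies sum to 1 in every observed family
  fam <- split(tab$within_family_freq, tab$amino_acid)
  sums <- vapply(fam, function(v) sum(v, na.rm = TRUE), numeric(1))
  observed <- vapply(fam, function(v) any(v > 0), logical(1))
  if (any(observed & abs(sums - 1) > 1e-9)) {
    return("within-family frequencies must sum to 1 in each observed family")
  }
  TRUE
})

#' Set of labelled codon-context examples
#'
#' A hit/decoy example is the pair of in-frame codon windows flanking a
#' peptide-coding region (the MAP-coding codons, MCC): \code{pre} holds the
#' C/3 codons immediately upstream and \code{post} the C/3 codons immediately
#' downstream, where C is the context size in nucleotides. The MCC itself is
#' excluded by construction and never stored.
#'
#' @slot examples data.frame with at least \code{transcript_id},
#'   \code{mcc_start} (0-based codon index of the MCC on its transcript),
#'   \code{mcc_len} (MCC length in codons), \code{label} ("hit"/"decoy"),
#'   \code{pre}, \code{post} (nucleotide strings of length contextNt).
#'   Additional metadata columns (expression, gc, ranks, ...) pass through.
#' @slot contextNt integer, context size C in nucleotides per flank
#'   (9, 27, 81 or 162 in the reference analyses; any multiple of 3 works).
#' @export
setClass("ContextSet", representation(examples = "data.frame", contextNt = "integer"))

setValidity("ContextSet", function(object) {
  ex <- object@examples
  C <- object@contextNt
  need <- c("transcript_id", "mcc_start", "mcc_len", "label", "pre", "post")
  if (!all(need %in% names(ex))) {
    return(paste("missing columns:", paste(setdiff(need, names(ex)), collapse = ", ")))
  }
  if (length(C) != 1L || is.na(C) || C %% 3L != 0L || C <= 0L) {
    return("contextNt must be a positive multiple of 3")
  }
  if (nrow(ex) > 0) {
    if (!all(ex$label %in% c("hit", "decoy"))) return("labels must be 'hit' or 'decoy'")
    if (any(nchar(ex$pre) != C) || any(nchar(ex$post) != C)) {
      return("pre/post flanks must each span contextNt nucleotides")
    }
  }
  TRUE
})

#' Redundancy-aware train/validation/test split
#'
#' Examples with identical concatenated pre+post sequences are always
#' co-assigned to one subset, so no context sequence straddles subsets.
#'
#' @slot train,validation,test ContextSet
#' @slot seed integer seed used for the assignment
#' @export
setClass("ContextSplit", representation(
  train = "ContextSet", validation = "ContextSet", test = "ContextSet",
  seed = "integer"
))

setValidity("ContextSplit", function(object) {
  key <- function(cs) paste0(cs@examples$pre, cs@examples$post)
  ktr <- key(object@train); kva <- key(object@validation); kte <- key(object@test)
  if (length(intersect(ktr, kva)) || length(intersect(ktr, kte)) ||
      length(intersect(kva, kte))) {
    return("identical context sequences must not straddle subsets")
  }
  TRUE
})

#' Codon-context classifier parameters
#'
#' A two-layer model: a codon embedding (65 rows: the null/mask label 0 pinned
#' at the origin, plus the 64 codons) followed by a bias-free linear map from
#' the concatenated per-position embeddings to two logits and a softmax. With
#' no bias and no hidden layer the positive-vs-negative logit difference is
#' additive over positions, which makes per-codon positional preferences and
#' exact per-position synonymous optimisation analytic.
#'
#' @slot embedding numeric matrix, 65 x d; row 1 is the null label, fixed at 0.
#' @slot weights numeric matrix, (L*d) x 2 where L = 2*contextNt/3 positions;
#'   rows are grouped by position (d consecutive rows per position); no bias.
#' @slot contextNt integer context size C (nt per flank).
#' @slot dim integer embedding dimension d.
#' @slot codonIndex named integer vector, codon -> 1..64 (0 reserved for null),
#'   snapshotted so saved models are self-describing.
#' @slot config list of training settings actually used.
#' @slot history data.frame of per-epoch train/validation loss and AUC.
#' @export
setClass("CodonContextModel", representation(
  embedding = "matrix", weights = "matrix", contextNt = "integer",
  dim = "integer", codonIndex = "integer", config = "list",
  history = "data.frame"
))

setValidity("CodonContextModel", function(object) {
  d <- object@dim
  L <- 2L * object@contextNt / 3L
  if (nrow(object@embedding) != 65L || ncol(object@embedding) != d) {
    return("embedding must be 65 x d")
  }
  if (any(object@embedding[1L, ] != 0)) return("null embedding row must stay at the origin")
  if (nrow(object@weights) != L * d || ncol(object@weights) != 2L) {
    return("weights must be (L*d) x 2")
  }
  if (length(object@codonIndex) != 64L ||
      !setequal(object@codonIndex, seq_len(64L))) {
    return("codonIndex must be a bijection onto 1..64")
  }
  TRUE
})

setMethod("show", "CodonUsageTable", function(object) {
  tab <- object@table
  cat("CodonUsageTable:", sum(tab$count), "codons counted,",
      sum(tab$count > 0), "distinct codons observed\n")
})

setMethod("show", "ContextSet", function(object) {
  ex <- object@examples
  cat("ContextSet: ", nrow(ex), " examples (",
      sum(ex$label == "hit"), " hits / ", sum(ex$label == "decoy"),
      " decoys), context ", object@contextNt, " nt per flank\n", sep = "")
})

setMethod("show", "ContextSplit", function(object) {
  cat("ContextSplit (seed ", object@seed, "): train ",
      nrow(object@train@examples), " / validation ",
      nrow(object@validation@examples), " / test ",
      nrow(object@test@examples), " examples\n", sep = "")
})

setMethod("show", "CodonContextModel", function(object) {
  cat("CodonContextModel: context ", object@contextNt, " nt per flank (",
      2L * object@contextNt / 3L, " positions), embedding dim ", object@dim,
      if (nrow(object@history)) paste0(", trained ", nrow(object@history), " epochs")
      else ", untrained",
      "\n", sep = "")
})

#' @describeIn ContextSet-class number of examples
#' @param x a ContextSet
#' @export
nExamples <- function(x) nrow(x@examples)

#' @describeIn ContextSet-class the example table (data.frame)
#' @export
exampleTable <- function(x) x@examples

#' @describeIn ContextSet-class context size in nucleotides per flank
#' @export
contextSize <- function(x) x@contextNt

#' @describeIn ContextSet-class example labels ("hit"/"decoy")
#' @export
exampleLabels <- function(x) x@examples$label

#' @describeIn CodonUsageTable-class the usage table (data.frame)
#' @param x a CodonUsageTable
#' @export
usageTable <- function(x) x@table
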