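#' Per-position logit contributions of an encoded context
#'
#' With no bias and no hidden layer, the hit-minus-decoy logit difference is a
#' sum over positions of E_c(x) . (W_x[hit] - W_x[decoy]); masked positions
#' contribute exactly 0, and the softmax output is monotone in the sum.
#'
#' @param model a [CodonContextModel-class]
#' @param encoded integer vector of codon labels (0..64) of length L, or a
#'   1-row encoding matrix
#' @return numeric vector of per-position contributions summing to the total
#'   logit difference
#' @export
positionContributions <- function(model, encoded) {
  encoded <- as.integer(encoded)
  d <- model@dim
  L <- 2L * model@contextNt %/% 3L
  if (length(encoded) != L) stop("encoding has ", length(encoded),
                                 " positions; model expects ", L)
  wdiff <- model@weights[, 1L] - model@weights[, 2L]       # (L*d)
  vapply(seq_len(L), function(x) {
    e <- model@embedding[encoded[x] + 1L, ]
    sum(e * wdiff[(x - 1L) * d + seq_len(d)])
  }, numeric(1))
}

# contribution of placing codon index c (1..64) at position x
.codonContribution <- function(model, x, cIdx) {
  d <- model@dim
  wdiff <- model@weights[(x - 1L) * d + seq_len(d), 1L] -
    model@weights[(x - 1L) * d + seq_len(d), 2L]
  as.vector(model@embedding[cIdx + 1L, , drop = FALSE] %*% wdiff)
}

#' Globally optimal synonymous variant of a codon context
#'
#' At every non-frozen position the synonym with the extremal per-position
#' contribution is selected independently. Because the logit difference is
#' additive over positions with no interaction terms, this per-position argmax
#' is the global optimum over all synonymous variants. Ties are broken toward
#' the original codon (minimal edit). Stop codons and frozen positions are
#' never changed; the translation is preserved exactly.
#'
#' @param model a [CodonContextModel-class]
#' @param codons character vector of L codons (pre then post flank)
#' @param direction "max" or "min"
#' @param frozen integer positions (1..L) that must keep their original codon
#' @return list with \code{codons} (the variant), \code{score} (model output
#'   for the variant) and \code{changed} (positions that differ)
#' @export
optimizeSynonymous <- function(model, codons, direction = c("max", "min"),
                               frozen = integer(0)) {
  direction <- match.arg(direction)
  L <- 2L * model@contextNt %/% 3L
  stopifnot(length(codons) == L)
  ci <- codonIndex()
  fam <- synonymFamilies()
  aa <- codonToAminoAcid()
  out <- codons
  for (x in setdiff(seq_len(L), frozen)) {
    a <- aa[[codons[x]]]
    if (a == "*") next
    syn <- fam[[a]]
    contrib <- .codonContribution(model, x, ci[syn])
    best <- if (direction == "max") max(contrib) else min(contrib)
    cand <- syn[abs(contrib - best) < 1e-12]
    out[x] <- if (codons[x] %in% cand) codons[x] else cand[1L]
  }
  idx <- matrix(ci[out], nrow = 1L)
  storage.mode(idx) <- "integer"
  list(codons = out,
       score = as.vector(cpp_forward(model@embedding, model@weights, idx)),
       changed = which(out != codons))
}

#' Design a synonymous construct variant around a peptide-coding window
#'
#' Rewrites only the C nucleotides upstream and downstream of the MCC with the
#' synonymous codons that maximise (or minimise) the classifier score; the MCC
#' codons and everything outside the context window are returned bit-identical.
#'
#' @param model a [CodonContextModel-class]
#' @param cds full-length in-frame CDS nucleotide string
#' @param mccStart 0-based codon index of the peptide-coding window
#' @param mccLen peptide length in codons
#' @param direction "max" (enhance) or "min" (reduce predicted presentation)
#' @return list: \code{cds} (variant), \code{scoreBefore}, \code{scoreAfter},
#'   \code{changedCodons} (0-based codon indices on the CDS),
#'   \code{nucleotideIdentity} (fraction identical over the full CDS) and
#'   \code{report} (data.frame of changed codon positions)
#' @export
designConstruct <- function(model, cds, mccStart, mccLen = 9L,
                            direction = c("max", "min")) {
  direction <- match.arg(direction)
  C <- model@contextNt
  k <- C %/% 3L
  ctx <- extractContext(cds, mccStart, mccLen, C)
  codons <- c(.splitCodons(ctx$pre), .splitCodons(ctx$post))
  ci <- codonIndex()
  idx0 <- matrix(ci[codons], nrow = 1L); storage.mode(idx0) <- "integer"
  before <- as.vector(cpp_forward(model@embedding, model@weights, idx0))
  opt <- optimizeSynonymous(model, codons, direction)
  # splice the optimised flanks back into the full CDS
  newPre <- paste(opt$codons[seq_len(k)], collapse = "")
  newPost <- paste(opt$codons[k + seq_len(k)], collapse = "")
  variant <- paste0(
    substr(cds, 1L, (mccStart - k) * 3L), newPre,
    substr(cds, mccStart * 3L + 1L, (mccStart + mccLen) * 3L), newPost,
    substr(cds, (mccStart + mccLen + k) * 3L + 1L, nchar(cds))
  )
  stopifnot(nchar(variant) == nchar(cds))
  changedLocal <- opt$changed
  cdsCodon <- ifelse(changedLocal <= k,
                     mccStart - k + changedLocal - 1L,
                     mccStart + mccLen + changedLocal - k - 1L)
  mm <- sum(strsplit(variant, "")[[1L]] != strsplit(cds, "")[[1L]])
  list(cds = variant, scoreBefore = before, scoreAfter = opt$score,
       changedCodons = sort(cdsCodon),
       nucleotideIdentity = 1 - mm / nchar(cds),
       report = data.frame(
         cds_codon = cdsCodon,
         original = codons[changedLocal],
         variant = opt$codons[changedLocal]))
}
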