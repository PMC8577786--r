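#' Classify transcripts as source / non-source for peptide presentation
#'
#' Removes transcripts with very low expression (at or below the 1st
#' percentile of positive expression values), then partitions the rest by
#' whether their in-frame translation contains at least one detected peptide.
#' A transcript is a source if it encodes a detected peptide of the target MCC
#' length; transcripts encoding a detected peptide of any length (8-11-mers)
#' are excluded from the non-source (negative) pool even when they carry no
#' peptide of the target length.
#'
#' @param transcripts data.frame with columns \code{id}, \code{cds},
#'   \code{expression}.
#' @param peptides character vector of detected peptide sequences (8-11-mers).
#' @param mccLength target peptide length in amino acids for the positive set
#'   (default 9); \code{NULL} accepts every detected length as source.
#' @param expressionPercentile fraction of the positive-expression
#'   distribution below which transcripts are dropped (default 0.01); ties at
#'   the threshold are dropped too.
#' @return list with data.frames \code{source}, \code{nonSource},
#'   \code{excluded} (expressed transcripts encoding only off-length
#'   peptides) and the numeric \code{threshold} used.
#' @export
classifyTranscripts <- function(transcripts, peptides, mccLength = 9L,
                                expressionPercentile = 0.01) {
  if (is.null(transcripts) || nrow(transcripts) == 0L) stop("empty transcript set")
  if (length(peptides) == 0L) stop("empty peptide list")
  stopifnot(all(c("id", "cds", "expression") %in% names(transcripts)))
  if (!all(nchar(peptides) %in% 8:11)) {
    stop("peptides must be 8-11 amino acids long")
  }
  pos <- transcripts$expression[transcripts$expression > 0]
  thr <- if (length(pos)) stats::quantile(pos, expressionPercentile, names = FALSE) else 0
  kept <- transcripts[transcripts$expression > thr, , drop = FALSE]

  prot <- vapply(kept$cds, translateCodons, character(1), USE.NAMES = FALSE)
  hasPep <- function(lens) {
    sub <- peptides[nchar(peptides) %in% lens]
    if (!length(sub)) return(rep(FALSE, length(prot)))
    Reduce(`|`, lapply(sub, function(p) grepl(p, prot, fixed = TRUE)))
  }
  anyHit <- hasPep(8:11)
  srcHit <- if (is.null(mccLength)) anyHit else hasPep(mccLength)
  list(
    source = kept[srcHit, , drop = FALSE],
    nonSource = kept[!anyHit, , drop = FALSE],
    excluded = kept[anyHit & !srcHit, , drop = FALSE],
    threshold = thr
  )
}

#' Extract the codon context flanking a peptide-coding window
#'
#' Returns the C/3 codons upstream and downstream of the MCC window; the MCC
#' codons themselves are excluded. Coordinates are 0-based half-open codon
#' indices. A transcript too short for the requested context (CDS shorter than
#' 2C + 3*mccLen nucleotides, or a window too close to either end) is
#' ineligible.
#'
#' @param cds in-frame CDS nucleotide string
#' @param mccStart 0-based codon index where the MCC starts
#' @param mccLen MCC length in codons (9 for training sets)
#' @param contextNt context size C in nucleotides per flank (multiple of 3)
#' @param transcriptId id used in error messages and the output row
#' @return one-row data.frame (transcript_id, mcc_start, mcc_len, pre, post)
#' @export
extractContext <- function(cds, mccStart, mccLen = 9L, contextNt = 162L,
                           transcriptId = NA_character_) {
  stopifnot(contextNt %% 3L == 0L, contextNt > 0L)
  if (nchar(cds) %% 3L != 0L) stop("CDS length not divisible by 3")
  k <- contextNt %/% 3L
  ncod <- nchar(cds) %/% 3L
  if (mccStart < k || mccStart + mccLen + k > ncod) {
    stop("ineligible transcript", if (!is.na(transcriptId)) paste0(" '", transcriptId, "'"),
         ": context of ", contextNt, " nt does not fit around codons [",
         mccStart, ", ", mccStart + mccLen, ")")
  }
  pre <- substr(cds, (mccStart - k) * 3L + 1L, mccStart * 3L)
  post <- substr(cds, (mccStart + mccLen) * 3L + 1L, (mccStart + mccLen + k) * 3L)
  data.frame(transcript_id = transcriptId, mcc_start = mccStart,
             mcc_len = mccLen, pre = pre, post = post, stringsAsFactors = FALSE)
}

.contextHasStop <- function(pre, post) {
  grepl("*", translateCodons(pre), fixed = TRUE) |
    grepl("*", translateCodons(post), fixed = TRUE)
}

#' Build hit examples around detected peptides on source transcripts
#'
#' Locates every in-frame occurrence of each detected peptide of the target
#' length on the source transcripts, extracts the flanking context, drops
#' windows whose context would not fit or would overlap a stop codon, and
#' deduplicates identical concatenated contexts.
#'
#' @inheritParams classifyTranscripts
#' @param source data.frame of source transcripts (id, cds, expression)
#' @param contextNt context size C in nucleotides per flank
#' @return [ContextSet-class] of hit examples with columns \code{peptide},
#'   \code{expression}, \code{gc} added
#' @export
buildHitExamples <- function(source, peptides, contextNt = 162L, mccLength = 9L) {
  peps <- unique(peptides[nchar(peptides) == mccLength])
  rows <- vector("list", 0L)
  for (t in seq_len(nrow(source))) {
    prot <- translateCodons(source$cds[t])
    for (p in peps) {
      hits <- gregexpr(p, prot, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (aaPos in hits) {          # 1-based AA position -> 0-based codon index
        ex <- tryCatch(
          extractContext(source$cds[t], aaPos - 1L, mccLength, contextNt,
                         source$id[t]),
          error = function(e) NULL)
        if (is.null(ex) || .contextHasStop(ex$pre, ex$post)) next
        ex$peptide <- p
        ex$expression <- source$expression[t]
        rows[[length(rows) + 1L]] <- ex
      }
    }
  }
  ex <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), mcc_start = integer(),
               mcc_len = integer(), pre = character(), post = character(),
               peptide = character(), expression = numeric())
  ex <- ex[!duplicated(paste0(ex$pre, ex$post)), , drop = FALSE]
  ex$label <- rep("hit", nrow(ex))
  ex$gc <- gcContent(paste0(ex$pre, ex$post))
  methods::new("ContextSet", examples = ex, contextNt = as.integer(contextNt))
}

#' Sample decoy contexts from non-source transcripts
#'
#' Draws \code{n} windows uniformly over all eligible in-frame windows of the
#' non-source transcripts and extracts their flanking contexts. Windows whose
#' context overlaps a stop codon are ineligible; duplicate concatenated
#' contexts are dropped and replaced until \code{n} unique decoys are found.
#'
#' @param nonSource data.frame of non-source transcripts (id, cds, expression)
#' @param n number of decoys to draw
#' @param mccLen decoy window length in codons (matches the hit MCC length)
#' @param contextNt context size C in nucleotides per flank
#' @param seed integer seed (draws are reproducible given the seed)
#' @return [ContextSet-class] of decoy examples
#' @export
sampleDecoys <- function(nonSource, n, mccLen = 9L, contextNt = 162L, seed = 1L) {
  stopifnot(n > 0)
  k <- contextNt %/% 3L
  ncod <- nchar(nonSource$cds) %/% 3L
  nWin <- pmax(0L, ncod - mccLen - 2L * k + 1L)
  if (sum(nWin) < n) {
    stop("fewer eligible windows (", sum(nWin), ") than requested decoys (", n, ")")
  }
  tx <- rep(seq_len(nrow(nonSource)), nWin)
  start <- unlist(lapply(nWin, function(w) if (w > 0) k + seq_len(w) - 1L else integer(0)))
  set.seed(seed)
  ord <- sample.int(length(tx))
  rows <- vector("list", n)
  seen <- character(0)
  got <- 0L
  for (i in ord) {
    ex <- extractContext(nonSource$cds[tx[i]], start[i], mccLen, contextNt,
                         nonSource$id[tx[i]])
    if (.contextHasStop(ex$pre, ex$post)) next
    key <- paste0(ex$pre, ex$post)
    if (key %in% seen) next
    seen <- c(seen, key)
    ex$expression <- nonSource$expression[tx[i]]
    got <- got + 1L
    rows[[got]] <- ex
    if (got == n) break
  }
  if (got < n) {
    stop("only ", got, " unique eligible decoy contexts available; requested ", n)
  }
  ex <- do.call(rbind, rows)
  ex$peptide <- NA_character_
  ex$label <- "decoy"
  ex$gc <- gcContent(paste0(ex$pre, ex$post))
  methods::new("ContextSet", examples = ex, contextNt = as.integer(contextNt))
}

#' Combine hit and decoy sets into one ContextSet
#' @param ... ContextSets sharing one context size
#' @export
combineContexts <- function(...) {
  sets <- list(...)
  C <- unique(vapply(sets, contextSize, integer(1)))
  if (length(C) != 1L) stop("context sizes differ")
  tabs <- lapply(sets, exampleTable)
  cols <- Reduce(union, lapply(tabs, names))
  tabs <- lapply(tabs, function(t) {
    for (m in setdiff(cols, names(t))) t[[m]] <- NA
    t[, cols, drop = FALSE]
  })
  methods::new("ContextSet", examples = do.call(rbind, tabs), contextNt = C)
}

#' Count possible origins of a peptide across expressed transcripts
#'
#' An origin is a distinct (transcript, codon-window) in-frame exact match of
#' the peptide in a transcript's translation.
#'
#' @param peptide amino-acid string (8-11-mer), vectorised
#' @param transcripts data.frame with \code{cds} (expressed transcripts)
#' @return integer vector of origin counts
#' @export
countOrigins <- function(peptide, transcripts) {
  prot <- vapply(transcripts$cds, translateCodons, character(1), USE.NAMES = FALSE)
  vapply(peptide, function(p) {
    sum(vapply(prot, function(s) {
      m <- gregexpr(p, s, fixed = TRUE)[[1L]]
      if (m[1L] == -1L) 0L else length(m)
    }, integer(1)))
  }, integer(1), USE.NAMES = FALSE)
}

#' Drop hit examples whose peptide has too many possible origins
#'
#' @param contexts a [ContextSet-class] whose hit rows carry an
#'   \code{origin_count} column (see [countOrigins()]); decoys pass through.
#' @param maxOrigins maximum allowed origin count (e.g. 3 or 10);
#'   \code{Inf} keeps everything.
#' @export
filterByOriginCount <- function(contexts, maxOrigins = Inf) {
  ex <- exampleTable(contexts)
  if (is.infinite(maxOrigins)) return(contexts)
  if (is.null(ex$origin_count)) stop("origin_count column missing; run countOrigins() first")
  drop <- ex$label == "hit" & !is.na(ex$origin_count) & ex$origin_count > maxOrigins
  methods::new("ContextSet", examples = ex[!drop, , drop = FALSE],
               contextNt = contextSize(contexts))
}

#' Resample decoys to match the hits' covariate distribution
#'
#' Bins the covariate over the pooled range of hits and decoy pool, then draws
#' decoys so the per-bin histogram matches the hits' histogram (the
#' construction used to control for expression level, binding affinity and GC
#' content). When a bin holds fewer decoys than requested the whole bin is
#' taken and a warning reports the shortfall (best effort).
#'
#' @param hits,decoyPool [ContextSet-class]s (or data.frames)
#' @param covariate column name of the covariate (e.g. "expression", "gc")
#' @param n number of decoys to select (default 5 per hit)
#' @param nBins number of equal-width bins (default 20)
#' @param logScale bin on log10 scale (recommended for expression)
#' @param seed integer seed
#' @return decoy subset, same class as \code{decoyPool}
#' @export
matchedDecoySampling <- function(hits, decoyPool, covariate = "expression",
                                 n = NULL, nBins = 20L, logScale = FALSE,
                                 seed = 1L) {
  hx <- if (methods::is(hits, "ContextSet")) exampleTable(hits) else hits
  px <- if (methods::is(decoyPool, "ContextSet")) exampleTable(decoyPool) else decoyPool
  if (is.null(n)) n <- min(5L * nrow(hx), nrow(px))
  hv <- hx[[covariate]]
  pv <- px[[covariate]]
  if (logScale) { hv <- log10(hv); pv <- log10(pv) }
  rng <- range(c(hv, pv), finite = TRUE)
  set.seed(seed)
  if (diff(rng) == 0) {
    warning("constant covariate: degenerate single bin, uniform sample returned")
    sel <- sample.int(nrow(px), n)
  } else {
    edges <- seq(rng[1L], rng[2L], length.out = nBins + 1L)
    bin <- function(v) pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nBins)
    hb <- bin(hv); pb <- bin(pv)
    prop <- tabulate(hb, nBins) / length(hb)
    target <- floor(n * prop)
    rem <- n - sum(target)
    if (rem > 0) {
      frac <- n * prop - target
      target[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        target[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
    }
    sel <- integer(0)
    short <- 0L
    for (b in which(target > 0L)) {
      avail <- which(pb == b)
      take <- min(target[b], length(avail))
      short <- short + target[b] - take
      if (take > 0) sel <- c(sel, sample(avail, take))
    }
    if (short > 0) warning("decoy pool short by ", short, " examples in occupied bins")
  }
  out <- px[sel, , drop = FALSE]
  if (methods::is(decoyPool, "ContextSet")) {
    methods::new("ContextSet", examples = out, contextNt = contextSize(decoyPool))
  } else out
}

#' Redundancy-aware train/validation/test split
#'
#' Groups examples by identical concatenated pre+post sequence and assigns
#' whole groups to subsets, so no context sequence appears in two subsets.
#' Groups are taken in random order and each goes to the subset with the
#' largest remaining deficit relative to its target share.
#'
#' @param contexts a [ContextSet-class]
#' @param ratios train/validation/test shares, must sum to 1 (default 60/20/20)
#' @param seed integer seed
#' @return a [ContextSplit-class]
#' @export
splitExamples <- function(contexts, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3L, abs(sum(ratios) - 1) < 1e-9)
  ex <- exampleTable(contexts)
  key <- paste0(ex$pre, ex$post)
  groups <- split(seq_len(nrow(ex)), key)
  if (length(groups) < 3L) stop("fewer than 3 distinct context sequences; cannot split")
  set.seed(seed)
  ord <- sample.int(length(groups))
  n <- nrow(ex)
  target <- ratios * n
  assigned <- numeric(3L)
  subset <- integer(length(groups))
  for (g in ord) {
    s <- which.max(target - assigned)
    subset[g] <- s
    assigned[s] <- assigned[s] + length(groups[[g]])
  }
  pick <- function(s) {
    idx <- sort(unlist(groups[subset == s], use.names = FALSE))
    methods::new("ContextSet", examples = ex[idx, , drop = FALSE],
                 contextNt = contextSize(contexts))
  }
  methods::new("ContextSplit", train = pick(1L), validation = pick(2L),
               test = pick(3L), seed = as.integer(seed))
}

#' Build a labelled hit/decoy context dataset from raw inputs
#'
#' End-to-end convenience: classify transcripts, build hit contexts around the
#' detected peptides, sample decoys at the requested ratio, annotate origin
#' counts and return the combined set.
#'
#' @inheritParams classifyTranscripts
#' @param contextNt context size C in nucleotides per flank
#' @param decoyRatio decoys per hit (default 5, mirroring the reference
#'   19,656 hits : 98,290 decoys design)
#' @param seed integer seed for decoy sampling
#' @return a [ContextSet-class]
#' @export
buildContextDataset <- function(transcripts, peptides, contextNt = 162L,
                                mccLength = 9L, decoyRatio = 5L, seed = 1L) {
  cls <- classifyTranscripts(transcripts, peptides, mccLength)
  hits <- buildHitExamples(cls$source, peptides, contextNt, mccLength)
  if (nExamples(hits) == 0L) stop("no eligible hit contexts")
  ht <- exampleTable(hits)
  expressed <- rbind(cls$source, cls$nonSource, cls$excluded)
  ht$origin_count <- countOrigins(ht$peptide, expressed)
  hits <- methods::new("ContextSet", examples = ht, contextNt = as.integer(contextNt))
  decoys <- sampleDecoys(cls$nonSource, decoyRatio * nExamples(hits),
                         mccLength, contextNt, seed)
  combineContexts(hits, decoys)
}

#' Write / read a context example table as TSV
#' @param contexts a [ContextSet-class]
#' @param path TSV path
#' @export
writeContexts <- function(contexts, path) {
  tab <- exampleTable(contexts)
  attr(tab, "contextNt") <- NULL
  utils::write.table(cbind(context_nt = contextSize(contexts), tab), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContexts
#' @export
readContexts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  C <- unique(tab$context_nt)
  if (length(C) != 1L) stop("mixed context sizes in ", path)
  tab$context_nt <- NULL
  methods::new("ContextSet", examples = tab, contextNt = as.integer(C))
}
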