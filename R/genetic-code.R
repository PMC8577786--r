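#' Genetic-code tables and codon indexing
#'
#' The standard (human/mouse nuclear) genetic code only. Codons are indexed
#' 1..64 in lexicographic order over {A,C,G,T}^3; index 0 is reserved for the
#' null/mask label used by the classifier. Stop codons keep their indices so
#' the encoding is total, although extracted contexts never contain them.
#'
#' @return \code{allCodons()} returns the 64 codons in index order;
#'   \code{codonIndex()} the named codon -> 1..64 map; \code{codonOf()} the
#'   inverse; \code{codonToAminoAcid()} the named codon -> amino-acid map
#'   (stop = "*"); \code{synonymFamilies()} a list amino acid -> codons.
#' @examples
#' codonIndex()[["AAA"]]   # 1
#' codonOf(64)             # "TTT"
#' @export
allCodons <- function() {
  nt <- c("A", "C", "G", "T")
  as.vector(vapply(nt, function(a)
    vapply(nt, function(b) paste0(a, b, nt), character(4)), character(16)))
}

#' @rdname allCodons
#' @export
codonIndex <- function() {
  structure(seq_len(64L), names = allCodons())
}

#' @rdname allCodons
#' @param index integer vector in 1..64
#' @export
codonOf <- function(index) {
  stopifnot(all(index %in% 1:64))
  allCodons()[index]
}

#' @rdname allCodons
#' @export
codonToAminoAcid <- function() {
  gc <- Biostrings::GENETIC_CODE
  structure(unname(gc[allCodons()]), names = allCodons())
}

#' @rdname allCodons
#' @export
synonymFamilies <- function() {
  aa <- codonToAminoAcid()
  split(names(aa), aa)
}

.splitCodons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3: ", n, " nt")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a codon vector
#'
#' @param codons character vector of codons over {A,C,G,T}, or a single
#'   in-frame nucleotide string.
#' @return single amino-acid string, stop rendered as \code{*}.
#' @examples
#' translateCodons(c("TTA", "TTG", "CTT"))  # "LLL"
#' @export
translateCodons <- function(codons) {
  if (length(codons) == 1L && nchar(codons) > 3L) codons <- .splitCodons(codons)
  aa <- codonToAminoAcid()[codons]
  if (anyNA(aa)) {
    bad <- which(is.na(aa))[1L]
    stop("invalid codon '", codons[bad], "' at codon position ", bad)
  }
  paste(aa, collapse = "")
}

#' Compute a codon usage table from coding sequences
#'
#' Counts every codon of every supplied CDS once (unweighted by expression)
#' and derives global relative frequencies and within-synonym-family relative
#' frequencies. Families with no observed codon get within-family frequency 0
#' for all members.
#'
#' @param cds character vector (or Biostrings::DNAStringSet) of in-frame CDS
#'   nucleotide sequences; each length must be divisible by 3.
#' @return a [CodonUsageTable-class]
#' @examples
#' u <- codonUsage(c("TTATTATTG"))
#' usageTable(u)[usageTable(u)$codon == "TTA", "within_family_freq"]  # 2/3
#' @export
codonUsage <- function(cds) {
  if (methods::is(cds, "DNAStringSet")) cds <- as.character(cds)
  if (length(cds) == 0L) stop("no coding sequences supplied")
  bad <- which(nchar(cds) %% 3L != 0L)
  if (length(bad)) {
    nm <- names(cds)[bad[1L]]
    stop("CDS length not divisible by 3: record ",
         if (is.null(nm) || is.na(nm) || nm == "") bad[1L] else nm)
  }
  codons <- unlist(lapply(cds, .splitCodons), use.names = FALSE)
  if (!all(codons %in% allCodons())) {
    stop("invalid codon encountered: ", setdiff(codons, allCodons())[1L])
  }
  counts <- table(factor(codons, levels = allCodons()))
  .usageFromCounts(as.integer(counts))
}

.usageFromCounts <- function(counts) {
  stopifnot(length(counts) == 64L)
  aa <- codonToAminoAcid()
  total <- sum(counts)
  fam_tot <- stats::ave(counts, unname(aa), FUN = sum)
  wff <- ifelse(fam_tot > 0, counts / fam_tot, 0)
  tab <- data.frame(
    codon = allCodons(), amino_acid = unname(aa), count = counts,
    global_freq = if (total > 0) counts / total else rep(0, 64L),
    within_family_freq = wff, stringsAsFactors = FALSE
  )
  methods::new("CodonUsageTable", table = tab)
}

#' Within-family frequencies as a named vector
#' @param usage a [CodonUsageTable-class]
#' @export
withinFamilyFreq <- function(usage) {
  structure(usage@table$within_family_freq, names = usage@table$codon)
}

#' Read coding sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that validates frame.
#' @param path FASTA file of CDS records
#' @return named character vector of sequences
#' @export
readCdsFasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bad <- which(nchar(seqs) %% 3L != 0L)
  if (length(bad)) stop("CDS length not divisible by 3: record ", names(seqs)[bad[1L]])
  seqs
}

#' Write a codon usage table to TSV
#' @param usage a [CodonUsageTable-class]
#' @param path output path
#' @export
writeUsageTable <- function(usage, path) {
  utils::write.table(usage@table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a codon usage table written by [writeUsageTable()]
#' @param path TSV path
#' @export
readUsageTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab <- tab[match(allCodons(), tab$codon), ]
  methods::new("CodonUsageTable", table = tab)
}

#' GC fraction of a nucleotide string (or several, concatenated per element)
#' @param x character vector of nucleotide strings
#' @return numeric vector of fractions in [0, 1]
#' @examples gcContent("GGCC")  # 1
#' @export
gcContent <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GCgc]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}
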