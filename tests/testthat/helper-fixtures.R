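# Shared fixtures, all generated in code.

# a random sense-codon string of n codons (no stops)
randomCds <- function(nCodons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- allCodons()[codonToAminoAcid() != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}

# CDS that carries a given peptide starting at a 0-based codon index,
# padded with random sense codons
cdsWithPeptide <- function(peptide, startCodon, totalCodons, seed = 1L) {
  set.seed(seed)
  sense <- allCodons()[codonToAminoAcid() != "*"]
  fam <- synonymFamilies()
  pepCodons <- vapply(strsplit(peptide, "")[[1]],
                      function(a) fam[[a]][1L], character(1))
  stopifnot(startCodon + length(pepCodons) <= totalCodons)
  cod <- sample(sense, totalCodons, replace = TRUE)
  cod[startCodon + seq_along(pepCodons)] <- pepCodons
  paste(cod, collapse = "")
}

# small ContextSet of random sense-codon contexts
randomContexts <- function(n, contextNt = 27L, seed = 1L,
                           labels = rep(c("hit", "decoy"), length.out = n)) {
  set.seed(seed)
  k <- contextNt %/% 3L
  sense <- allCodons()[codonToAminoAcid() != "*"]
  mk <- function() paste(sample(sense, k, replace = TRUE), collapse = "")
  ex <- data.frame(
    transcript_id = sprintf("tx%04d", seq_len(n)), mcc_start = k,
    mcc_len = 9L, label = labels,
    pre = replicate(n, mk()), post = replicate(n, mk()),
    stringsAsFactors = FALSE
  )
  new("ContextSet", examples = ex, contextNt = as.integer(contextNt))
}

# model with parameters drawn at a visible scale (for analytic/optimiser tests)
randomModel <- function(contextNt = 9L, d = 2L, seed = 1L, scale = 1) {
  set.seed(seed)
  L <- 2L * contextNt %/% 3L
  E <- matrix(stats::runif(65L * d, -scale, scale), nrow = 65L)
  E[1L, ] <- 0
  rownames(E) <- c("<null>", allCodons())
  W <- matrix(stats::runif(L * d * 2L, -scale, scale), ncol = 2L)
  colnames(W) <- c("hit", "decoy")
  new("CodonContextModel", embedding = E, weights = W,
      contextNt = as.integer(contextNt), dim = as.integer(d),
      codonIndex = codonIndex(), config = list(), history = data.frame())
}

# brute-force oracle: enumerate every synonymous variant and score it
enumerateOptimum <- function(model, codons, direction = "max") {
  fam <- synonymFamilies()
  aa <- codonToAminoAcid()
  choices <- lapply(codons, function(c) if (aa[[c]] == "*") c else fam[[aa[[c]]]])
  grid <- as.matrix(expand.grid(choices, stringsAsFactors = FALSE))
  idx <- matrix(codonIndex()[as.vector(grid)], nrow = nrow(grid))
  storage.mode(idx) <- "integer"
  scores <- predictScores(model, idx)
  best <- if (direction == "max") which.max(scores) else which.min(scores)
  list(codons = unname(grid[best, ]), score = scores[best], all = scores)
}

# peptide-level feature rows where each feature carries independent signal
syntheticFeatureRows <- function(n = 3000L, seed = 1L) {
  set.seed(seed)
  expr <- stats::rlnorm(n, 2, 1)
  rank <- stats::runif(n, 0, 1)            # already binder-filtered scale
  ctx <- stats::runif(n)
  lin <- 1.2 * scale(log(expr)) - 1.2 * scale(rank) + 1.2 * scale(ctx)
  label <- ifelse(stats::runif(n) < stats::plogis(lin - 1), "hit", "decoy")
  data.frame(peptide = sprintf("PEP%05d", seq_len(n)), context_score = ctx,
             ligand_rank = rank, expression = expr, label = label,
             stringsAsFactors = FALSE)
}
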