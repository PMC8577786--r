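translationOf <- function(cs) {
  ex <- exampleTable(cs)
  vapply(paste0(ex$pre, ex$post), translateCodons, character(1), USE.NAMES = FALSE)
}

sortedCodons <- function(cs) {
  m <- codonMAP:::.codonMatrix(cs)
  apply(m, 1L, function(r) paste(sort(r), collapse = " "))
}

test_that("all three shuffles preserve the amino-acid sequence", {
  cs <- randomContexts(60, 27L, seed = 1)
  usage <- humanCodonUsage()
  before <- translationOf(cs)
  for (method in c("transcriptome", "codonswap", "thirdnt")) {
    after <- translationOf(shuffleExamples(cs, method, usage = usage, seed = 2))
    expect_equal(after, before, info = method)
  }
})

test_that("single-codon families are immutable under every shuffle", {
  codons <- c("ATG", "TGG", "ATG")
  for (method in c("transcriptome", "codonswap", "thirdnt")) {
    expect_equal(shuffleCodons(codons, method, usage = humanCodonUsage(), seed = 3),
                 codons, info = method)
  }
})

test_that("codon-swap preserves per-example codon multisets and GC exactly", {
  cs <- randomContexts(40, 27L, seed = 4)
  sh <- shuffleExamples(cs, "codonswap", seed = 5)
  expect_equal(sortedCodons(sh), sortedCodons(cs))
  expect_equal(gcContent(paste0(exampleTable(sh)$pre, exampleTable(sh)$post)),
               gcContent(paste0(exampleTable(cs)$pre, exampleTable(cs)$post)))
  # an example with at most one codon per amino acid cannot move
  codons <- c("AAA", "TGC", "GGG")
  expect_equal(shuffleCodons(codons, "codonswap", seed = 6), codons)
  # multiset conserved on a mixed-family example
  out <- shuffleCodons(c("CTT", "CTG", "AAA"), "codonswap", seed = 7)
  expect_equal(sort(out), sort(c("CTT", "CTG", "AAA")))
  expect_equal(out[3], "AAA")
})

test_that("third-nucleotide shuffle permutes only third positions and keeps GC", {
  cs <- randomContexts(40, 27L, seed = 8)
  sh <- shuffleExamples(cs, "thirdnt", seed = 9)
  m0 <- codonMAP:::.codonMatrix(cs); m1 <- codonMAP:::.codonMatrix(sh)
  expect_equal(substr(m1, 1, 2), substr(m0, 1, 2))   # first/second untouched
  third <- function(m) apply(m, 1L, function(r) paste(sort(substr(r, 3, 3)), collapse = ""))
  expect_equal(third(m1), third(m0))                 # nt multiset preserved
  expect_equal(gcContent(paste0(exampleTable(sh)$pre, exampleTable(sh)$post)),
               gcContent(paste0(exampleTable(cs)$pre, exampleTable(cs)$post)))
  expect_equal(shuffleCodons(c("ATG", "TGG"), "thirdnt", seed = 1), c("ATG", "TGG"))
})

test_that("third-nucleotide shuffle actually moves nucleotides when it can", {
  # all 4-fold-degenerate glycine/alanine codons: every permutation is valid
  codons <- c("GGA", "GGC", "GGG", "GGT", "GCA", "GCC", "GCG", "GCT")
  moved <- FALSE
  for (s in 1:10) {
    out <- shuffleCodons(codons, "thirdnt", seed = s)
    expect_equal(translateCodons(out), translateCodons(codons))
    if (!identical(out, codons)) moved <- TRUE
  }
  expect_true(moved)
})

test_that("transcriptome shuffle converges to the usage table frequencies", {
  usage <- humanCodonUsage()
  n <- 1e5
  out <- shuffleCodons(rep("CTA", n), "transcriptome", usage = usage, seed = 10)
  obs <- table(factor(out, levels = synonymFamilies()[["L"]]))
  p <- withinFamilyFreq(usage)[synonymFamilies()[["L"]]]
  gof <- stats::chisq.test(as.integer(obs), p = p / sum(p))
  expect_gt(gof$p.value, 0.001)
})

test_that("transcriptome shuffle requires usage coverage and a usage table", {
  cs <- randomContexts(4, 9L, seed = 11)
  expect_error(shuffleExamples(cs, "transcriptome", usage = NULL), "usage table")
  empty <- codonUsage("ATGATG")   # only Met observed
  expect_error(shuffleExamples(cs, "transcriptome", usage = empty), "cover")
})

test_that("shuffling is deterministic given the seed", {
  cs <- randomContexts(20, 27L, seed = 12)
  for (method in c("transcriptome", "codonswap", "thirdnt")) {
    a <- shuffleExamples(cs, method, usage = humanCodonUsage(), seed = 13)
    b <- shuffleExamples(cs, method, usage = humanCodonUsage(), seed = 13)
    expect_identical(exampleTable(a), exampleTable(b), info = method)
  }
})

test_that("transcriptome shuffling erases the planted hit/decoy usage difference", {
  usage <- humanCodonUsage()
  gen <- generateDataset(1500, 1500, 27L, usage,
                         plantedSignal(0.9, halfLife = 1e6, seed = 14), seed = 15)
  freqDiff <- function(cs) {
    m <- codonMAP:::.codonMatrix(cs)
    hit <- table(factor(m[exampleLabels(cs) == "hit", ], levels = allCodons()))
    dec <- table(factor(m[exampleLabels(cs) == "decoy", ], levels = allCodons()))
    max(abs(hit / sum(hit) - dec / sum(dec)))
  }
  before <- freqDiff(gen$contexts)
  after <- freqDiff(shuffleExamples(gen$contexts, "transcriptome", usage, seed = 16))
  expect_gt(before, 5 * after)   # planted signal shrinks toward 0
})
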