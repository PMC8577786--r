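makeTranscriptTable <- function() {
  # tx1 carries a 9-mer, tx2 a 10-mer only, tx3 nothing, tx4 low expression
  pep9 <- "MKLVACDEF"
  pep10 <- "WKLVACDEFG"
  data.frame(
    id = c("tx1", "tx2", "tx3", "tx4"),
    cds = c(cdsWithPeptide(pep9, 20, 60, seed = 1),
            cdsWithPeptide(pep10, 20, 60, seed = 2),
            randomCds(60, seed = 3),
            randomCds(60, seed = 4)),
    expression = c(10, 20, 30, 0.0001),
    stringsAsFactors = FALSE
  )
}

test_that("transcripts are classified into source / non-source / excluded", {
  tx <- makeTranscriptTable()
  peps <- c("MKLVACDEF", "WKLVACDEFG")
  cls <- classifyTranscripts(tx, peps, mccLength = 9L)
  expect_equal(cls$source$id, "tx1")
  expect_equal(cls$nonSource$id, "tx3")
  # 10-mer-only transcript is excluded from both sets
  expect_equal(cls$excluded$id, "tx2")
  # below the expression percentile: absent everywhere
  expect_false("tx4" %in% c(cls$source$id, cls$nonSource$id, cls$excluded$id))
  expect_error(classifyTranscripts(tx[0, ], peps), "empty transcript")
  expect_error(classifyTranscripts(tx, character(0)), "empty peptide")
  expect_error(classifyTranscripts(tx, "SHORT"), "8-11")
})

test_that("context extraction uses 0-based codon coordinates and excludes the MCC", {
  # 27 + 27 + 27 nt CDS, 9-codon MCC centred, C = 27: pre/post are the ends
  cds <- randomCds(27, seed = 5)
  ex <- extractContext(cds, mccStart = 9L, mccLen = 9L, contextNt = 27L)
  expect_equal(ex$pre, substr(cds, 1, 27))
  expect_equal(ex$post, substr(cds, 55, 81))

  # C = 162 gives 54 codons per flank
  big <- randomCds(130, seed = 6)
  ex2 <- extractContext(big, 54L, 9L, 162L)
  expect_equal(nchar(ex2$pre) / 3, 54)
  expect_equal(nchar(ex2$post) / 3, 54)

  # minimum eligible CDS for C = 162, 9-codon MCC is 2*162 + 27 = 351 nt
  exact <- randomCds(117, seed = 7)            # 351 nt
  expect_silent(extractContext(exact, 54L, 9L, 162L))
  short <- randomCds(116, seed = 8)
  expect_error(extractContext(short, 54L, 9L, 162L), "ineligible")
  expect_error(extractContext(exact, 53L, 9L, 162L), "ineligible")
})

test_that("hit contexts round-trip: pre + MCC + post reproduces the peptide in frame", {
  pep <- "MKLVACDEF"
  tx <- data.frame(id = "tx1", cds = cdsWithPeptide(pep, 20, 60, seed = 9),
                   expression = 5, stringsAsFactors = FALSE)
  hits <- buildHitExamples(tx, pep, contextNt = 27L, mccLength = 9L)
  expect_equal(nExamples(hits), 1L)
  ex <- exampleTable(hits)
  mcc <- substr(tx$cds, ex$mcc_start * 3 + 1, (ex$mcc_start + 9) * 3)
  full <- translateCodons(paste0(ex$pre, mcc, ex$post))
  expect_equal(substr(full, 10, 18), pep)
  expect_false(grepl("*", translateCodons(ex$pre), fixed = TRUE))
  expect_false(grepl("*", translateCodons(ex$post), fixed = TRUE))
})

test_that("decoy sampling is uniform over eligible windows and reproducible", {
  # a single 351-nt transcript has exactly one eligible window at C = 162
  one <- data.frame(id = "t", cds = randomCds(117, seed = 10), expression = 1,
                    stringsAsFactors = FALSE)
  d <- sampleDecoys(one, 1L, mccLen = 9L, contextNt = 162L, seed = 3)
  expect_equal(exampleTable(d)$mcc_start, 54L)
  expect_error(sampleDecoys(one, 2L, 9L, 162L, seed = 3), "fewer eligible")

  pool <- data.frame(id = sprintf("t%d", 1:5),
                     cds = vapply(1:5, function(s) randomCds(80, seed = 100 + s),
                                  character(1)),
                     expression = 1:5, stringsAsFactors = FALSE)
  d1 <- sampleDecoys(pool, 20L, 9L, 27L, seed = 7)
  d2 <- sampleDecoys(pool, 20L, 9L, 27L, seed = 7)
  expect_identical(exampleTable(d1), exampleTable(d2))   # determinism
  expect_equal(anyDuplicated(paste0(exampleTable(d1)$pre, exampleTable(d1)$post)), 0L)
  expect_true(all(exampleTable(d1)$label == "decoy"))
})

test_that("covariate-matched decoy sampling mirrors the hit histogram", {
  # two-value toy: hits 70/30 across bins, pool 50/50, n = 100 -> 70/30
  hits <- data.frame(expression = c(rep(1, 70), rep(10, 30)))
  pool <- data.frame(expression = c(rep(1, 500), rep(10, 500)))
  sel <- matchedDecoySampling(hits, pool, "expression", n = 100L, nBins = 2L,
                              seed = 4)
  expect_equal(sum(sel$expression == 1), 70)
  expect_equal(sum(sel$expression == 10), 30)

  # hits concentrated in one bin -> all selections from that bin
  hits2 <- data.frame(expression = rep(10, 40))
  sel2 <- matchedDecoySampling(hits2, pool, "expression", n = 50L, nBins = 2L,
                               seed = 4)
  expect_true(all(sel2$expression == 10))

  expect_warning(
    matchedDecoySampling(data.frame(expression = rep(1, 10)),
                         data.frame(expression = rep(1, 100)),
                         "expression", n = 10L, seed = 1),
    "constant covariate")
})

test_that("matched sampling per-bin frequencies stay within rounding slack", {
  set.seed(42)
  hits <- data.frame(expression = stats::rlnorm(300, 1, 1))
  pool <- data.frame(expression = stats::rlnorm(6000, 2, 1.5))
  n <- 900L; nb <- 10L
  sel <- matchedDecoySampling(hits, pool, "expression", n = n, nBins = nb,
                              logScale = TRUE, seed = 5)
  edges <- seq(min(log10(c(hits$expression, pool$expression))),
               max(log10(c(hits$expression, pool$expression))), length.out = nb + 1)
  bin <- function(v) pmin(pmax(findInterval(log10(v), edges, rightmost.closed = TRUE), 1L), nb)
  fh <- tabulate(bin(hits$expression), nb) / nrow(hits)
  fs <- tabulate(bin(sel$expression), nb) / nrow(sel)
  expect_lt(max(abs(fh - fs)), 1 / n + 1e-2)
})

test_that("origin counting and filtering follow the multi-origin rule", {
  pep <- "MKLVACDEF"
  txs <- data.frame(
    id = sprintf("t%d", 1:5),
    cds = c(vapply(1:4, function(s) cdsWithPeptide(pep, 15, 50, seed = 200 + s),
                   character(1)), randomCds(50, seed = 205)),
    expression = 1, stringsAsFactors = FALSE)
  expect_equal(countOrigins(pep, txs), 4L)
  expect_equal(countOrigins(pep, txs[5, , drop = FALSE]), 0L)
  expect_equal(countOrigins(pep, txs[1, , drop = FALSE]), 1L)

  cs <- randomContexts(6, 27L, seed = 6)
  # labels alternate hit/decoy; hit rows carry origin counts 4, 11 and 1
  ex <- exampleTable(cs); ex$origin_count <- c(4, 1, 11, 2, 1, 1)
  cs <- new("ContextSet", examples = ex, contextNt = 27L)
  kept3 <- exampleTable(filterByOriginCount(cs, 3))
  expect_equal(nrow(kept3), 4L)                       # hits with >3 origins removed
  expect_true(all(kept3$origin_count <= 3 | kept3$label == "decoy"))
  expect_identical(exampleTable(filterByOriginCount(cs, Inf)), ex)  # identity
})

test_that("splits are redundancy-aware, complete and deterministic", {
  cs <- randomContexts(10, 27L, seed = 7)
  sp <- splitExamples(cs, seed = 1)
  sizes <- c(nExamples(sp@train), nExamples(sp@validation), nExamples(sp@test))
  expect_equal(sizes, c(6, 2, 2))                    # all-unique 10 -> 6/2/2

  # identical contexts are always co-assigned
  ex <- exampleTable(cs)
  ex <- rbind(ex, transform(ex[1:3, ], transcript_id = "dup"))
  dup <- new("ContextSet", examples = ex, contextNt = 27L)
  for (s in 1:5) {
    sp2 <- splitExamples(dup, seed = s)
    key <- function(x) paste0(exampleTable(x)$pre, exampleTable(x)$post)
    expect_length(intersect(key(sp2@train), key(sp2@validation)), 0)
    expect_length(intersect(key(sp2@train), key(sp2@test)), 0)
    expect_length(intersect(key(sp2@validation), key(sp2@test)), 0)
    # union of subsets is the input
    expect_equal(sort(c(key(sp2@train), key(sp2@validation), key(sp2@test))),
                 sort(paste0(ex$pre, ex$post)))
  }
  expect_identical(exampleTable(splitExamples(cs, seed = 9)@train),
                   exampleTable(splitExamples(cs, seed = 9)@train))
  few <- new("ContextSet", examples = ex[c(1, 1, 1), ], contextNt = 27L)
  expect_error(splitExamples(few, seed = 1), "fewer than 3")
})

test_that("the end-to-end builder produces a labelled 1:5 dataset", {
  pep <- "MKLVACDEF"
  set.seed(30)
  txs <- data.frame(
    id = sprintf("t%02d", 1:12),
    cds = c(cdsWithPeptide(pep, 12, 40, seed = 301),
            vapply(2:12, function(s) randomCds(40, seed = 300 + s), character(1))),
    expression = stats::rlnorm(12, 2, 1) + 1, stringsAsFactors = FALSE)
  ds <- buildContextDataset(txs, pep, contextNt = 27L, decoyRatio = 5L, seed = 2)
  tab <- exampleTable(ds)
  expect_equal(sum(tab$label == "hit"), 1L)
  expect_equal(sum(tab$label == "decoy"), 5L)
  expect_equal(tab$origin_count[tab$label == "hit"], 1L)
  expect_equal(anyDuplicated(paste0(tab$pre, tab$post)), 0L)

  tmp <- tempfile(fileext = ".tsv")
  writeContexts(ds, tmp)
  back <- readContexts(tmp)
  expect_equal(contextSize(back), 27L)
  expect_equal(exampleTable(back)$pre, tab$pre)
})
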