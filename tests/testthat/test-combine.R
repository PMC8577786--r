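test_that("the binder filter keeps ranks up to and including 1%", {
  rows <- data.frame(ligand_rank = c(0.5, 1.0, 2.0), label = "hit")
  kept <- binderFilter(rows)
  expect_equal(kept$ligand_rank, c(0.5, 1.0))
})

test_that("multi-origin peptides collapse to max expression and min rank", {
  rows <- data.frame(peptide = c("A", "A", "B"),
                     context_score = c(0.2, 0.9, 0.5),
                     ligand_rank = c(0.8, 0.3, 1.0),
                     expression = c(5, 50, 2),
                     label = c("decoy", "hit", "decoy"))
  col <- collapseByPeptide(rows)
  a <- col[col$peptide == "A", ]
  expect_equal(a$expression, 50)
  expect_equal(a$ligand_rank, 0.3)
  expect_equal(a$context_score, 0.9)
  expect_equal(a$label, "hit")
})

test_that("the min-max scaler is learned on train and reused unchanged", {
  train <- data.frame(x = c(2, 4, 6), z = c(1, 1, 1))
  sc <- fitScaler(train, c("x", "z"))
  out <- applyScaler(sc, data.frame(x = c(2, 6, 8), z = c(3, 1, 0)))
  expect_equal(out$x, c(0, 1, 1.5))   # test values outside [0,1] pass through
  expect_equal(out$z, c(0, 0, 0))     # degenerate feature maps to 0
})

test_that("Matthews correlation matches hand-computed contingencies", {
  expect_equal(matthewsCC(c(1, 1, 0, 0), c(0.9, 0.8, 0.1, 0.2)), 1)
  expect_equal(matthewsCC(c(1, 1, 0, 0), c(0.1, 0.2, 0.9, 0.8)), -1)
  # TP=3, FP=1, FN=1, TN=5 -> (3*5 - 1*1)/sqrt(4*4*6*6) = 14/24
  labels <- c(rep(1, 4), rep(0, 6))
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, rep(0.1, 5))
  expect_equal(matthewsCC(labels, scores), 14 / 24, tolerance = 1e-12)
  expect_equal(matthewsCC(c(1, 1), c(0.9, 0.9)), 0)  # empty margin convention
})

test_that("capture-at-fraction finds the smallest prefix and handles ties", {
  # oracle ordering: all hits first
  scores <- c(seq(1, 0.51, length.out = 100), seq(0.5, 0.01, length.out = 400))
  labels <- c(rep("hit", 100), rep("decoy", 400))
  cp <- captureAtFraction(scores, labels, 0.10)
  expect_equal(cp$n_peptides, 10L)
  expect_equal(cp$fpr, 0)

  # all scores equal: the prefix is the whole list, FPR the decoy share
  cp2 <- captureAtFraction(rep(0.5, 500), labels, 0.10)
  expect_equal(cp2$n_peptides, 500L)
  expect_equal(cp2$fpr, 0.8)

  # hand list of 6: scores 0.9h 0.8d 0.7h 0.6d 0.5h 0.4d, f=0.5 -> 2 of 3 hits
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  l <- c("hit", "decoy", "hit", "decoy", "hit", "decoy")
  cp3 <- captureAtFraction(s, l, 0.5)
  expect_equal(cp3$hits_required, 2L)
  expect_equal(cp3$n_peptides, 3L)
  expect_equal(cp3$fpr, 1 / 3)

  # prefix nesting: n_peptides is non-decreasing in the fraction
  set.seed(1)
  sc <- stats::runif(500)
  ns <- vapply(c(0.01, 0.05, 0.1, 0.5, 1), function(f)
    captureAtFraction(sc, labels, f)$n_peptides, numeric(1))
  expect_true(all(diff(ns) >= 0))
  expect_error(captureAtFraction(sc, rep("decoy", 500), 0.1), "at least one hit")
})

test_that("a perfectly separating feature yields perfect held-out predictions", {
  set.seed(2)
  rows <- data.frame(x = c(stats::runif(100, 0.6, 1), stats::runif(100, 0, 0.4)),
                     label = rep(c("hit", "decoy"), each = 100))
  tr <- rows[c(1:70, 101:170), ]; te <- rows[c(71:100, 171:200), ]
  fit <- fitCombiner(tr, "x", "logistic", seed = 3)
  sc <- predictCombiner(fit, te)
  expect_equal(matthewsCC(te$label, sc), 1)

  fit2 <- fitCombiner(tr, "x", "logistic", seed = 3)
  expect_equal(predictCombiner(fit2, te), sc, tolerance = 1e-12)  # determinism

  mlp <- fitCombiner(tr, "x", "mlp", seed = 3, hidden = 8L, maxit = 200L)
  expect_equal(matthewsCC(te$label, predictCombiner(mlp, te)), 1)
})

test_that("a pure-noise feature does not wreck cross-validated performance", {
  rows <- syntheticFeatureRows(1500, seed = 4)
  rows$noise <- stats::runif(nrow(rows))
  ev <- evaluateFeatureSets(rows,
    list(signal = c("expression", "ligand_rank", "context_score"),
         with_noise = c("expression", "ligand_rank", "context_score", "noise")),
    seed = 5)
  expect_gt(ev$mcc["with_noise"], ev$mcc["signal"] - 0.1)
})

test_that("adding an independent classifier score improves MCC and capture", {
  rows <- syntheticFeatureRows(4000, seed = 6)
  ev <- evaluateFeatureSets(rows,
    list(two = c("expression", "ligand_rank"),
         three = c("expression", "ligand_rank", "context_score")),
    fractions = 0.10, seed = 7)
  expect_gte(ev$mcc[["three"]], ev$mcc[["two"]])
  n2 <- ev$capture$n_peptides[ev$capture$features == "two"]
  n3 <- ev$capture$n_peptides[ev$capture$features == "three"]
  expect_lt(n3, n2)
})
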