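---
title: "Modelling MHC-I peptide presentation from flanking codon context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling MHC-I peptide presentation from flanking codon context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

A large fraction of MHC class I associated peptides (MAPs) is thought to arise
co-translationally, from defective ribosomal products rather than from the
steady-state proteome. If that is so, the mRNA around a peptide-coding region
— and specifically its *synonymous codon arrangement*, which influences
translation speed and fidelity without touching the protein — should carry
information about whether the peptide is presented. `codonMAP` implements the
full machinery to test and exploit that idea on any supplied data:

1. build labelled **hit/decoy datasets** of codon contexts around
   peptide-coding codons (MCC), with the MCC itself excluded so the model
   never sees the peptide;
2. erase codon-level signal with three **synonymous shuffling null models**
   that preserve the amino-acid sequence;
3. train a deliberately shallow **codon-embedding classifier** on the flanking
   codons only;
4. read the trained model analytically (**positional preferences**, embedding
   geometry, per-codon Kullback–Leibler diagnostics);
5. **design synonymous variants** of a coding sequence that maximise or
   minimise the model score while leaving the protein untouched; and
6. **combine** the context score with MHC ligand rank and transcript
   expression into a presentation predictor.

## The classifier

Each context is the pair of flanks of `C` nucleotides (`C`/3 codons) on each
side of the MCC, concatenated into `L = 2C/3` codon positions. Codons are
integer-encoded 1..64 (lexicographic over `{A,C,G,T}^3`); 0 is a null/mask
label. The model is two layers with no hidden processing:

- an embedding `E` (65 × d, default d = 2) mapping each codon label to
  coordinates; the null label's row is pinned at the origin and receives no
  gradient;
- a bias-free linear map `W` ((L·d) × 2) from the concatenated per-position
  embeddings to two logits, followed by a softmax.

Because there is no bias and no hidden layer, the hit-minus-decoy logit is
**additive over positions**:
`logit = Σ_x E[c(x)] · (W_x[hit] − W_x[decoy])`. Three useful consequences,
each verified by tests to machine precision:

- an all-masked input scores exactly 0.5;
- the *preference* of codon `c` at position `x` — the output when only that
  codon is unmasked — has the closed form `softmax(E_c W_x)`, with 0.5
  neutral;
- for a fixed protein sequence, the score is maximised (or minimised) over
  all synonymous variants by independently picking the extremal synonym at
  each position. Per-position selection is therefore *globally exact*; no
  heuristic search is involved, and the test suite confirms equality with
  exhaustive enumeration on random models.

## Training

Stochastic gradient descent on softmax cross-entropy with learning rate
0.001, mini-batches of 64 and 2-D embeddings. Decoys outnumber hits (the
default design ratio is 1:5), so at each epoch the hits are resampled with
replacement up to the decoy count and the balanced pool is shuffled into
batches. Early stopping monitors validation AUC with a patience of 20 epochs
(cap 500) by default; the parameters from the best validation epoch are kept.
The exact early-stopping monitor and patience were open choices; validation
AUC is the quantity we report, so it is also the one monitored, and the
choice is recorded in the model's stored configuration. The optimiser is
plain SGD; momentum variants would converge faster but the shallow model and
small parameter count (~130 embedding + ~430 output weights at d = 2,
C = 162) do not need them.

Splits are 60/20/20 train/validation/test, assigned by *group*: examples with
identical concatenated context sequences always land in the same subset.
Redundancy is defined as exact string identity of the concatenated context —
the minimal, testable reading of "no example in multiple subsets".

# Dataset construction rules

- Transcripts at or below the 1st percentile of positive expression values
  are removed before anything else; ties at the threshold are removed too
  (the rule is "below the 1st percentile", and keeping boundary ties would
  make the filter depend on quantile interpolation minutiae).
- A transcript is a *source* if its canonical-frame translation contains a
  detected peptide of the target length (9-mers for training sets); any
  transcript containing a detected peptide of *any* length 8–11 is excluded
  from the decoy pool, so decoys come only from transcripts with no known
  MAP.
- Coordinates are 0-based half-open codon indices internally. A context of
  `C` nt per flank around a 9-codon MCC needs a CDS of at least `2C + 27` nt;
  shorter transcripts are ineligible and raise an explicit error so
  eligibility statistics can be collected.
- Decoy windows are drawn uniformly over all eligible in-frame windows of the
  decoy pool; windows may overlap, but duplicate concatenated contexts are
  dropped so every sequence in a dataset is unique. Contexts never overlap a
  stop codon.
- `matchedDecoySampling()` reproduces the covariate-mirroring construction
  used to control for expression, binding affinity and GC content: 20
  equal-width bins over the pooled covariate range (log scale recommended for
  expression), decoys drawn per bin to match the hits' histogram.
- Multi-origin peptides: `countOrigins()` counts distinct
  (transcript, window) matches; `filterByOriginCount()` removes hits above a
  cap (3 or 10 in the reference analyses). For peptide-level feature tables,
  `collapseByPeptide()` keeps the maximum expression and minimum ligand rank
  across origins.

# Shuffling null models

All three preserve the translation of every example exactly, and all are
applied to the pre+post flanks jointly:

- **transcriptome**: every codon replaced by a synonym drawn from
  within-family usage frequencies computed over a CDS collection (unweighted
  by expression). Erases class-specific synonymous usage *and* per-example GC
  differences.
- **codon swap**: synonymous codons within one example permuted among their
  positions. Preserves each example's codon multiset and GC exactly; only
  positional information is destroyed.
- **third nucleotide**: third codon positions swapped pairwise within an
  example, a swap accepted only when both resulting codons stay synonymous to
  their originals. Preserves amino acids and the third-position nucleotide
  multiset (hence GC) while ignoring usage frequencies. The constraint is
  enforced per codon — the strictest reading. The algorithm is a rejection
  Markov chain of 10·L random pairwise proposals per example; at these
  lengths that mixes well, and when no valid non-identity permutation exists
  the chain simply returns the identity.

# The synthetic-data generator

`generateDataset()` produces the study conditions every end-to-end check
runs under. Amino-acid sequences for hits and decoys are drawn i.i.d. from
human-like amino-acid frequencies (derived from the bundled human codon usage
table), so the two classes are *identical at the amino-acid level by
construction* and any learnable signal is purely synonymous — this is what
makes the original-vs-shuffled AUC gap a clean readout. Decoy codons follow
background within-family usage; hit codons follow a tilted distribution that
interpolates (strength θ ∈ [0,1]) between the background and a point mass on
one preferred synonym per family, with θ decaying exponentially away from the
MCC (half-life 18 codons by default, emulating the near-MCC dominance of
codon effects while leaving long-range signal for large contexts to exploit).

What the generator does *not* emulate: real amino-acid composition structure
around cleavage sites, expression–usage covariation, homologous multi-origin
peptides, GC isochores, or MHC binding motifs. Passing the recovery suite
therefore shows the pipeline detects and localises planted synonymous signal;
it does not by itself certify performance on real immunopeptidomes.

`recoverySuite()` trains 12 replicate classifiers (distinct split seeds) on
the original and transcriptome-shuffled copies of one generated dataset and
reports the AUC gap and the fraction of the ten most-tilted codons whose
near-MCC preference sign matches the planted direction. Reference conditions:
5,000 hits / 25,000 decoys, C = 162, θ = 0.6. At these sizes the suite caps
training at 30 epochs (patience 5): the planted signal saturates the
validation AUC well before that, and the cap keeps a full 12-replicate run on
one CPU in minutes. `thetaSweep()` repeats the comparison at
θ ∈ {0, 0.3, 0.6, 1} with 2 replicates and 20 epochs as a trend check.

# Numerical choices

- KL divergences are in nats. Default smoothing adds a pseudo-probability of
  1/(total count of the two distributions compared) before renormalisation;
  with eps = 0, a zero in Q where P has mass is an explicit error rather than
  an infinity.
- Preference positions are labelled −C/3..−1 and +1..+C/3 relative to the
  MCC.
- Synonym ties in variant design break toward the original codon (minimal
  edit); stop codons and the MCC are always frozen.
- Weight initialisation is uniform on ±0.05 with a recorded seed; all
  randomness (initialisation, oversampling, batch order, shuffles, sampling)
  flows through R's RNG, so every result is reproducible from the seeds
  stored in outputs. The SGD inner loop is compiled code but consumes no
  randomness.
- The logistic combiner is ridge logistic regression with 10-fold
  cross-validation over the penalty (`glmnet`), class-balanced weights and
  min-max scaling fitted on the training split only; the MLP combiner
  (`nnet`, one hidden layer) relies on an iteration cap rather than a
  held-out early-stopping monitor, which the underlying optimiser does not
  expose. Matthews correlation uses the 0.5 cutoff; an empty confusion-table
  margin yields 0 by convention. Capture curves include all peptides tied at
  the prefix-boundary score, which makes them deterministic under ties.

# Worked example

```{r, eval = FALSE}
library(codonMAP)

usage <- humanCodonUsage()
gen <- generateDataset(nHits = 1000, nDecoys = 5000, contextNt = 27,
                       usage = usage, signal = plantedSignal(0.8, seed = 1),
                       seed = 2)
split <- splitExamples(gen$contexts, seed = 3)
model <- trainModel(split, trainConfig(maxEpochs = 50, patience = 10, seed = 4))
aucScore(predictScores(model, split@test), exampleLabels(split@test))

shuffled <- shuffleExamples(gen$contexts, "transcriptome", usage, seed = 5)
pref <- preferences(model)          # 64 x 18 matrix, 0.5 = neutral
```

# Known limitations

- Contexts are extracted from spliced CDS FASTA in the canonical frame only;
  genome-coordinate extraction across introns and non-canonical reading
  frames are out of scope.
- MHC binding prediction is consumed as an input column (ligand rank), never
  computed.
- The bundled human codon usage table is a fixed reference constant;
  `codonUsage()` recomputes usage from any CDS collection when fidelity to a
  particular annotation matters.
- With d = 2 the embedding is intentionally low-capacity; the package fixes
  the reference architecture rather than exposing deeper variants.
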