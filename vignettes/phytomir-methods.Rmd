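---
title: "Plant miRNA target prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant miRNA target prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant miRNAs silence their targets through near-full complementarity along
the whole miRNA, not through the short 5' "seed" match that dominates
animal targeting. Tools built around the canonical seed rule therefore
miss a substantial fraction of genuine plant sites, including
*non-canonical* sites carrying two or more mismatches in the seed region.
`phytomir` implements a plant-focused pipeline: complementarity scanning
finds candidate sites anywhere on a transcript, each miRNA:site duplex is
summarised by eleven features, and a small random forest converts the
features into a confidence in [0, 1].

## Pipeline stages

### 1. Candidate-site scanning (`scanCandidateSites`)

A miRanda-style local alignment of the miRNA against each transcript
window, read antiparallel (the site is reversed before alignment so the
duplex geometry is explicit). Scoring, chosen to reward complementarity
rather than sequence identity:

| parameter | default | rationale |
|---|---|---|
| `matchScore` | +5 | Watson-Crick pair (A:U, G:C) |
| `wobbleScore` | +1 | G:U wobble — stable but weaker, counted as paired |
| `mismatchPenalty` | -3 | unpaired opposition |
| `gapOpen` / `gapExtend` | -8 / -2 | bulges are rare in plant duplexes |
| `minScore` | 80 | a ~21-nt site needs near-full complementarity to reach it |
| `maxEnergy` | -15 kcal/mol | discards windows that align but cannot hybridize stably |
| `maxGapSlack` | 4 | site length may differ from miRNA length by at most this |

The alignment is an affine-gap three-state dynamic program (implemented in
C++ for the inner loop) with deterministic tie-breaking, so identical
inputs always give identical sites. Windows pass a score filter, then an
energy filter, then greedy overlap-merging (best score, then best energy,
then leftmost).

### 2. Duplex features (`extractFeatures`)

Eleven features per site, in the package's canonical order
(`targetFeatureNames()`):

1. **folding_energy** — hybridization free energy of the miRNA:site
   duplex from ViennaRNA's `RNAduplex` (nearest-neighbor model), clamped
   to ≤ 0 so "no duplex" and "indifferent duplex" coincide at zero.
2. **seed_match** — paired positions among miRNA positions 2-8 (G:U
   counts as paired, as throughout).
3. **accessibility** — mean probability that each site nucleotide is
   unpaired in the transcript's local structure ensemble, from
   `RNAplfold` over a ±70-nt context with folding window `-W 80` and
   maximum pair span `-L 40`. Local folding is the field-standard
   compromise: full-transcript partition functions cost quadratically
   more and change little for site-scale accessibility.
4. **au_content** — A/U fraction of the site plus a 10-nt flank on each
   side (clipped at transcript ends).
5. **me_motif** — agreement (fraction of positions) between the observed
   paired/unpaired vector and a fixed reference profile that is paired at
   miRNA positions 2-8 and 13-16 and unpaired elsewhere: a stand-in for
   the empirically derived pairing motif of effective sites.
6. **n_paired** — total paired positions.
7. **site_length** — length of the transcript site.
8. **longest_run** — length of the longest consecutive paired stretch.
9. **longest_run_pos** — 5'-most miRNA position of that stretch (first
   one on ties).
10. **n_paired_3p** — paired positions from miRNA position 13 to its 3'
    end.
11. **seed_minus_3p** — `seed_match - n_paired_3p`, the 5' vs 3' pairing
    asymmetry that separates cleavage-competent plant duplexes from
    animal-style seed-only sites.

### 3. Negative exemplars (`generateNegative`, `buildNegativeSet`)

Databases record where a miRNA *does* bind; a classifier also needs
credible non-sites. For each positive, the negative is the transcript
window of the same length that (a) does not overlap the positive site,
(b) matches its CG-dinucleotide frequency within a tolerance ladder
(0.05, then 0.10, then 0.20 — relaxed only when a rung leaves no
candidates), and (c) has the *lowest* hybridization energy among the
survivors. Choosing the hardest (most stably hybridizing) decoy forces
the forest to learn more than "does any pairing exist".

### 4. Homology control (`pairwiseIdentity`, `clusterMirnas`, `makeSplit`)

miRNA families recur across species; naive splits leak near-identical
miRNAs between train and test and inflate every metric. Identity here is
the CD-HIT convention: identical aligned positions in the optimal global
alignment (equivalently the longest-common-subsequence length, which
makes the measure symmetric and exactly computable), divided by the
shorter length. `makeSplit` holds out one species, deduplicates test
examples with identical feature vectors, and removes every training
example whose miRNA reaches 70% identity to any test miRNA; the boundary
is included (≥ 0.70 excludes) — the conservative reading.
`auditSplit` re-checks the result by exhaustive all-pairs identity.

### 5. Scoring and thresholding (`trainTargetModel`, `selectThresholdCv`)

A 13-tree random forest (other hyperparameters at the usual defaults);
the confidence is the fraction of trees voting "positive", so scores live
on a grid of fourteenths and determinism is exact under a fixed seed. The
deployment threshold is chosen by stratified 5-fold cross-validation: the
smallest threshold whose mean out-of-fold precision reaches the target
(default 1.0), with the accompanying recall reported. Evaluation uses
the closed rule score ≥ t, threshold 0.5 by default, plus a
precision-recall curve integrated step-wise (rectangular; interpolation
in PR space is optimistic).

## The synthetic corpus (`corpusSpec`, `generateCorpus`)

Real training sets (plant interaction databases, CLASH chimeras) require
downloads and licenses; the package instead ships a generator whose
defaults are the package's study conditions:

- 60 miRNAs (20-24 nt) × 300 transcripts (150-300 nt), uniform base
  composition, one planted site per transcript at recorded coordinates.
- Plant-style sites are the miRNA's reverse complement mutated at 5% of
  positions; 10% of sites are forced non-canonical (two mismatches in the
  positions facing the miRNA seed). Animal-style corpora instead pair
  only opposite miRNA positions 1-9 on an A/U-rich background,
  emulating canonical-seed 3'-UTR targeting.
- 20% of miRNAs are cross-species homolog copies at 80-95% identity,
  exercising the leakage controls; species labels cycle over `gma`/`osa`.

What the generator deliberately does **not** emulate: real secondary
structure statistics, expression levels, isomiR variation, multi-site
transcripts, and database noise. Conclusions drawn from it are about the
pipeline's mechanics (recovery of planted signal, regime sensitivity,
leakage control), not about biological effect sizes.

## Numerical choices

- Energies come from ViennaRNA's command-line tools (`RNAduplex`,
  `RNAplfold`), called in batches (one process per batch, not per
  sequence); the `100000.00` no-duplex sentinel maps to 0.
- All thermodynamic values are clamped to ≤ 0 kcal/mol.
- Alignment and LCS dynamic programs are exact integer/double DPs with
  first-maximum tie-breaking; nothing is stochastic outside the forest
  and the generator, and both take explicit seeds.
- PR-AUC uses exact tie-grouped thresholds; no binning anywhere.

## Limitations

- Accessibility uses local folding (`-W 80 -L 40`); long-range pairing
  beyond 40 nt is invisible to the feature.
- The m/e motif profile is fixed, not learned from data.
- The forest is deliberately tiny (13 trees); confidences are coarse
  (multiples of 1/13) and threshold grids short.
- Identity is computed on mature miRNAs only; transcript-side homology is
  not controlled.

## A minimal run

```{r}
library(phytomir)

corpus <- generateCorpus(corpusSpec(nMirna = 20L, nTranscript = 100L,
                                    seed = 1L))
examples <- corpusToExamples(corpus)
split <- makeSplit(examples, corpus$mirnas, testSpecies = "gma")
model <- trainTargetModel(trainExamples(split), seed = 1L)
scores <- predictConfidence(model, testExamples(split))
metricsAtThreshold(scores, testExamples(split)$label)
prAuc(prCurve(scores, testExamples(split)$label))
```
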