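# phytomir

Plant miRNA target prediction with duplex features and a random forest.

Plant miRNAs silence their targets through extensive complementarity
along the whole miRNA — not the short 5' "seed" match that dominates
animal targeting — and a meaningful fraction of genuine plant sites are
*non-canonical*, carrying two or more seed-region mismatches. `phytomir`
implements a plant-focused prediction pipeline:

1. **Scanning** — a miRanda-style local complementarity alignment
   (Watson–Crick and G:U wobble pairing, affine gaps) finds candidate
   sites anywhere on a transcript, followed by a hybridization-energy
   filter (ViennaRNA `RNAduplex`).
2. **Features** — each miRNA:site duplex is summarised by eleven
   features: folding energy, seed match, site accessibility (`RNAplfold`
   local unpaired probabilities), AU content, an m/e pairing-motif score
   and six pairing-geometry counts (`targetFeatureNames()`).
3. **Negatives** — for every known positive, the matched negative is the
   non-overlapping, CG-dinucleotide-matched transcript window with the
   *lowest* hybridization energy: the hardest credible decoy.
4. **Homology control** — train/test splits remove every training
   example whose miRNA reaches 70% identity (CD-HIT convention) to any
   test miRNA, emulating prediction on an unannotated species, with an
   exhaustive post-hoc leakage audit.
5. **Scoring** — a 13-tree random forest; the confidence is the fraction
   of trees voting "positive". A deployment threshold is chosen by
   stratified 5-fold cross-validation against a precision target.
6. **Synthetic corpora** — a generator plants ground-truth sites (plant-
   or canonical-seed-style) with recorded coordinates, non-canonical
   fractions and cross-species homolog families, so the whole pipeline is
   testable end to end without downloads.

The methods vignette (`vignettes/phytomir-methods.Rmd`) documents the
model, every default, and the generator's deliberate simplifications.

## Requirements

R ≥ 4.3 with Bioconductor (`Biostrings`, `S4Vectors`, `IRanges`),
`randomForest`, `Rcpp`, and ViennaRNA's `RNAduplex` and `RNAplfold` on
the `PATH`.

```sh
R CMD INSTALL .
```

## Quick start

```r
library(phytomir)

corpus   <- generateCorpus(corpusSpec(nMirna = 20L, nTranscript = 100L, seed = 1L))
examples <- corpusToExamples(corpus)                      # features + matched negatives
split    <- makeSplit(examples, corpus$mirnas, testSpecies = "gma")
model    <- trainTargetModel(trainExamples(split), seed = 1L)
scores   <- predictConfidence(model, testExamples(split))

metricsAtThreshold(scores, testExamples(split)$label)
#>   threshold tp fp tn fn    recall precision  accuracy
#> 1       0.5 44  1 44  1 0.9777778 0.9777778 0.9777778

prAuc(prCurve(scores, testExamples(split)$label))
#> [1] 0.9981173

selectThresholdCv(trainExamples(split), seed = 1L)
#> ThresholdReport (k = 5): threshold 0.5385 | recall 1.000 +/- 0.000, precision 1.000 +/- 0.000
```

Whole-transcriptome prediction reports every candidate site with its
seed location and confidence:

```r
pred <- runPredict(corpus$mirnas[1:2], corpus$transcripts[1:6], model)
head(pred[, c("mirna_id", "transcript_id", "site_start", "site_end",
              "mirna_seed_seq", "confidence")], 2)
#>   mirna_id transcript_id site_start site_end     mirna_seed_seq confidence
#> 1   mir001        tx0001        166      185 GUGCAUACUGAUAUUACG          1
#> 2   mir002        tx0002        150      172 CCCGUUGAGGGUGGACAG          1
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/phytomir.R` (subcommands `simulate`, `featurize`, `train`,
`threshold`, `predict`, `evaluate`; exit codes 0 success / 2 usage /
3 data error / 4 internal).

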