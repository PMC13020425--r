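# casforge

Mining and rational engineering of Cas9 proteins with a CNN-LSTM sequence
classifier.

## The problem

New Cas9 endonucleases are hard to find by homology alone: validated Cas9s
often share under 25% pairwise identity, and large protein collections are
coarsely annotated. casforge implements a sequence-only route for protein
engineers and computational biologists:

1. **Composition-controlled classification.** A CNN-LSTM is trained to
   separate Cas9-like sequences from *partially shuffled* copies of
   themselves. Shuffling a fraction *p* of positions preserves the
   amino-acid composition exactly, so the classifier must learn positional
   features. Sweeping *p* from 0.1 to 1.0 produces the canonical ten
   negative datasets.
2. **Fingerprints.** Grad-CAM on the last convolutional layer gives a
   per-residue saliency vector; called peaks ("the Cas9 fingerprint")
   co-locate with functionally important regions.
3. **Mining cascade.** Length window (800–1600 aa) → 100-aa bins → the bin
   richest in multi-domain Cas9 Pfam annotations (RuvC_III, Cas9_BH,
   Cas9_REC, HNH_4, Cas9_PI) → model score thresholds (report > 0.5, keep
   ≥ 0.9) → candidates with > 50 CRISPR repeats, ranked by score. Domain
   hits and repeat counts come from external tools (HMMER, CRISPR
   detectors) as plain TSV.
4. **Mutation design.** Over a homolog alignment, a *characteristic
   matrix* C[s, a] (mean Grad-CAM saliency of homologs carrying residue a
   at reference position s) is combined with a *conservation matrix*
   P[s, a] (position-specific amino-acid probabilities, pseudocount α = 1):

       ΔC = C[s, mut] − C[s, wt],   ΔP = P[s, mut] − P[s, wt]

   Both Diff lists are ranked descending; candidates whose summed rank is
   strictly below 30 are reported as wtPOSmut (e.g. V623I) designs.

A seeded synthetic-data module (motif-planted positives, shuffled
negatives, homolog families, toy mining tables) makes the entire pipeline
testable without any external database.

## Worked example

```r
library(casforge)

pos <- make_positive_set(n = 400, seed = 101)       # 800-1200 aa, 3 motifs
neg <- build_negative_dataset(pos, threshold = 1.0, seed = 202)

model <- train_classifier(pos, neg,
                          model_config(split_seed = 11, init_seed = 21),
                          encoder_spec(max_len = 1200))
glance(model)[, c("train_accuracy", "test_accuracy", "precision", "recall", "f1", "auc")]
#> # A tibble: 1 x 6
#>   train_accuracy test_accuracy precision recall    f1   auc
#>            <dbl>         <dbl>     <dbl>  <dbl> <dbl> <dbl>
#> 1              1             1         1      1     1     1

fp <- compute_fingerprints(model, head(pos, 20)) |> detect_peaks()
saliency_enrichment(fp, motif_spans(pos)) |> dplyr::summarise(mean(fraction))

tab <- make_mining_table(mining_table_preset(), seed = 5)
res <- mine_cascade(tab)
res$stages
#> # A tibble: 6 x 2
#>   stage             n
#>   <chr>         <int>
#> 1 input            35
#> 2 in_window        33
#> 3 chosen_bin       12
#> 4 score_report      9
#> 5 score_keep        6
#> 6 repeat_ranked     3
```

On this synthetic benchmark the classifier separates motif-bearing
positives from fully shuffled negatives essentially perfectly (the table
above is real output); fingerprint peaks co-locate with the planted
motifs, with roughly half of the top-5% saliency positions falling
strictly inside the 36 motif residues (the rest sit mostly on the
receptive-field shoulders of the motif clusters — see the methods
vignette for the geometry); and the mining cascade reproduces its
hand-enumerated survivor counts, including the strict >50-repeat and
≥0.9-score boundaries.

A command-line front end (`exec/casforge`) exposes the same stages as
subcommands (`shuffle`, `train`, `predict`, `fingerprint`, `mine`,
`design`, `synth`, `pipeline`).

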