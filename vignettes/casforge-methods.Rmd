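---
title: "Mining and engineering Cas9 proteins from sequence alone: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and engineering Cas9 proteins from sequence alone: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(casforge)
```

## The problem

Cas9 endonucleases are scattered across bacterial genomes with low pairwise
sequence identity, so mining new ones from large protein collections — and
deciding which residues of a newly mined Cas9 to mutate — cannot rely on
simple homology. casforge approaches both problems through a single learned
object: a binary sequence classifier trained to tell Cas9-like proteins from
*partially shuffled* copies of themselves. Because a shuffled copy has
exactly the same amino-acid composition as its source, the classifier cannot
win on composition; it is forced to learn positional sequence features —
which is what makes its saliency maps and internal activations useful
downstream.

The package provides four connected stages:

1. **shuffle** — negative-set construction at a configurable shuffle
   threshold $p$;
2. **net** — a CNN-LSTM classifier with a full evaluation battery;
3. **fingerprint** — Grad-CAM per-residue saliency and peak calling;
4. **mine / design** — a filter cascade for genome mining, and a
   mutation-ranking scheme combining the model's characteristic matrix with
   a PSAP conservation matrix.

A fifth module, the synthetic-data generator, defines the study conditions
under which everything is tested.

## Shuffled negatives

`shuffle_sequence(x, p, seed)` selects $k = \mathrm{round}(p \cdot L)$
positions uniformly at random without replacement and applies a uniform
random permutation to the residues at those positions. Selected positions
may map to themselves (no derangement is forced): this is the simplest
contract that exactly preserves the residue multiset, and the expected
fraction of moved residues is still $\approx k/L \cdot (1 - 1/k)$. Whether
the positions should instead form one contiguous block is an open choice;
scattered positions disrupt features everywhere at equal rate, which is the
property the negative set needs, so scattered selection is implemented and
block selection is not.

Per-sequence seeds are derived by hashing the base seed with the sequence
id, making datasets independent of record order. One negative is generated
per positive (balanced classes). `shuffle_sweep()` builds the canonical ten
datasets at $p = 0.1, \dots, 1.0$.

## The classifier

The network is: token embedding (width 16) → two 1-D convolution blocks
(32 filters each, kernel widths 7 then 3, ReLU, max-pool widths 2 then 8) →
LSTM (32 units) → dense ReLU (16) → sigmoid score. Tokens cover the 20 standard
residues plus X/B/Z/U/O, with a PAD token; every sequence is processed at
its true length, so padding never influences scores or saliency.

Design notes, in decreasing order of consequence:

* **LSTM readout.** The classifier reads out the *mean of the LSTM hidden
  states over time* rather than the final state. With a final-state
  readout the gradient reaching the convolutional layer concentrates on
  the sequence region nearest the readout, and Grad-CAM then highlights
  only the last informative motif; a max-over-time readout trains fastest
  of all but lets the recurrent layer solve the task with cumulative state,
  leaving the convolutional filters poorly localized. The mean readout
  distributes credit along the whole sequence, which is what makes the
  fingerprints usable. All three readouts are available via
  `model_config(lstm_readout=)`.
* **Pool widths 2 then 8, kernels 7 then 3.** The Grad-CAM target is the
  last convolutional layer, so its resolution (one value per 2 residues)
  and its receptive field (7 + 2·2 = 11 residues with the narrow second
  kernel) bound how sharply saliency can localize; the second, coarser
  pool keeps the LSTM input to roughly $L/16$ steps. Placing all pooling
  after the convolutions (a full-resolution CAM) was tried and gives
  visibly noisier maps: the intermediate pool regularizes the second
  block's features.
* **Optimizer.** Adam at learning rate $2 \times 10^{-3}$, batch 32,
  40 epochs, with decoupled (AdamW-style) weight decay $10^{-4}$ on weight
  matrices. The mean readout divides readout gradients by the number of
  timesteps, which produces a long plateau at chance loss before the conv
  filters break symmetry; the raised learning rate and epoch count are set
  so that the breakthrough happens reliably, and the weight decay
  suppresses filters that are not discriminative, denoising the
  class-activation maps. Because an unlucky initialization can still leave
  training stuck at chance, `train_classifier()` detects a final training
  accuracy below 0.6 and restarts from a deterministically derived init
  seed (at most `restarts = 3` times); the attempt count is recorded on
  the training history.
* **Sizing.** All widths are an order of magnitude smaller than what a GPU
  setup would use; they are sized for single-CPU training in about a
  minute per model at the study conditions below, and every number is
  overridable through `model_config()`.

Training is binary cross-entropy on a stratified 80/20 split; all
randomness (initialization, minibatch order, dropout, split) is seeded and
the C++ core uses its own deterministic generator, so a (data, config,
seeds) triple reproduces byte-identical parameters.

Evaluation reports the confusion counts at a 0.5 cutoff (a prediction is
positive when the score is strictly above the cutoff), accuracy, precision,
recall, F1 and AUC. AUC is computed by the Mann-Whitney rank statistic with
ties counted one half; the test suite checks it against brute-force pairwise
concordance and against pROC.

## Grad-CAM fingerprints

For a trained model and one sequence, the positive-class logit is
differentiated with respect to the last convolutional layer's post-ReLU
activation map $A \in \mathbb{R}^{C \times T}$. Channel weights are the
position-means of the gradient, $\alpha_c = \frac{1}{T}\sum_t
\partial z / \partial A_{c,t}$, and the class-activation map is the
rectified weighted sum $\mathrm{CAM}_t = \max(0, \sum_c \alpha_c A_{c,t})$
— standard Grad-CAM, with the logit (not the sigmoid output)
differentiated. The CAM is linearly interpolated from conv resolution back
to residue resolution and min-max normalized to $[0, 1]$; an all-zero CAM
stays all-zero, and a constant positive CAM normalizes to all ones.

Peak calling makes the visual notion of a fingerprint algorithmic: peaks
are local maxima exceeding mean $+ z \cdot$ sd of the sequence's saliency
(default $z = 2$; the sd guard means a flat map has no peaks), pruned so
that no two peaks are closer than 20 residues (the higher one wins). Both
parameters are exposed because the right values depend on how broad the
model's receptive field is relative to the features of interest.

## The mining cascade

Mining consumes an annotation table produced by external tools — profile-HMM
domain search for Pfam hits and a CRISPR repeat detector for repeat counts —
as plain TSV; casforge does not reimplement either. The cascade is:

1. keep proteins of 800–1600 residues (inclusive);
2. partition into eight 100-residue bins — bins are half-open
   $[\mathrm{lo}, \mathrm{lo}+100)$ with the final bin closed, labeled
   "lo+1–hi" to match the inclusive phrasing conventional in the field;
3. choose the bin with the most entries carrying $\ge 3$ distinct
   Cas9-related Pfam domains (RuvC_III, Cas9_BH, Cas9_REC, HNH_4, Cas9_PI;
   multiple hits of one domain count once, since the signal is domain
   *diversity*); ties break toward the longer bin, with a warning;
4. score the chosen bin's sequences with the classifier, reporting counts
   strictly above 0.5 and keeping those at or above 0.9;
5. among keepers, require more than 50 CRISPR repeats (strict, so exactly
   50 is excluded; candidates with no repeat information are excluded with
   a log, since an empty genome cannot corroborate its candidate), and
   rank the rest by score.

Each stage's survivors are a subset of the previous stage's, and the
survivor counts at every stage are returned so a screen can be audited.

## Mutation design

Given an alignment of homologs of a reference (column map taken from the
reference row), two matrices are built over (reference position, residue):

* the **conservation matrix** (PSAP):
  $P[s,a] = (n_{s,a} + \alpha)/(N_s + 20\alpha)$ with pseudocount
  $\alpha = 1$; gaps and non-standard letters are excluded from the counts,
  and an empty column falls back to uniform with a warning.
* the **characteristic matrix**: each homolog's ungapped sequence is
  fingerprinted, saliency is projected into reference coordinates, and
  $C[s,a]$ is the mean saliency of homologs carrying residue $a$ at
  position $s$, defined only where at least `min_support` (default 3)
  homologs support the cell. Stratifying saliency by residue identity is
  the minimal construction that yields a position-by-residue matrix from
  per-residue saliency. Core sites are positions whose across-homolog mean
  saliency exceeds the 75th percentile; the percentile form keeps the rule
  scale-free.

Candidates are all (core site $s$, residue $a \ne$ wild type) pairs with
both $C[s,a]$ and $C[s,\mathrm{wt}]$ defined. Each gets
$\Delta C = C[s,a] - C[s,\mathrm{wt}]$ and
$\Delta P = P[s,a] - P[s,\mathrm{wt}]$; both lists are ranked descending
with ties sharing the minimum rank, and the total ranking score is the sum
of the two ranks (the alternative — ranking a combined score — is not what
"comparing the ranks" suggests, and the sum is what is implemented).
Candidates with total rank strictly below 30 survive, sorted by total rank,
then position, then residue, and are reported in wtPOSmut notation (e.g.
V623I). An in-silico-mutagenesis variant of $\Delta C$ (rescoring each
mutated sequence) would be a natural extension point; the matrix-level
difference is what is implemented.

## Synthetic study conditions

The generator defines what "works" means at desk scale:

* **Positives**: 400 sequences of 800–1200 residues, background uniform
  over the 20 standard residues (a Swiss-Prot-like frequency preset
  exists), with three fixed width-12 motifs planted at relative positions
  0.15 / 0.50 / 0.85 with ±25 residues of jitter. Motif width sits at the
  top of the supported 8–12 range deliberately: the three spans total 36
  residues, commensurate with the 40–60 positions that make up the top 5%
  of saliency for these lengths, so motif-localization of saliency is
  geometrically measurable at all. Spans are recorded as ground truth.
* **Negatives**: the positives shuffled at threshold $p$; at $p = 1$ the
  motifs are destroyed almost surely, at small $p$ most motif copies
  survive partially, which is what makes low-$p$ classification genuinely
  harder and produces the accuracy-vs-threshold trend.
* **Homolog families**: indel-free point-substituted copies of a reference
  (conserved positions at one tenth the rate), so the column map is the
  identity and matrix logic is isolated from alignment artifacts. This is
  explicitly not a protein-evolution simulator.
* **Mining tables**: explicit per-record specifications, so cascade
  survivors are hand-enumerable; `mining_table_preset()` ships a
  deterministic table whose eight bins, score thresholds and repeat counts
  probe every boundary (strict >50 repeats, ≥0.9 keep, >0.5 report, the
  top scorer lacking repeat support).

What passing these tests shows — and does not. The fixture isolates the
mechanisms: composition-matched discrimination, saliency localization of
planted features, exact cascade arithmetic, conservation recovery. Real
Cas9 data differ in ways the fixture does not emulate: motifs there are
degenerate families rather than verbatim strings, backgrounds are not
i.i.d., homologs have indels, and annotation tables carry noise. Results on
the fixture therefore validate the machinery, not any claim about wet-lab
performance.

A quantitative note on saliency localization under these conditions: the
planted motifs cover 36 of 800–1200 residues (3–4.5%), while the top 5% of
saliency positions number 40–60 per sequence. With the CAM computed at
half-residue resolution through an 11-residue receptive field, each motif's
activation cluster is necessarily a few residues wider than the motif
itself, so even a noise-free map places roughly a third of its top
positions on cluster shoulders just outside the strict spans. Converged
models place about half of the top-5% positions strictly inside the spans
(and 60–80% within ten residues of a span); across readouts, kernels, pool
placements, weight decay and training lengths this fraction moved between
roughly 0.45 and 0.63, with the shipped defaults chosen at the top of that
range. Sharper-than-Grad-CAM attribution (e.g. elementwise
gradient-times-activation) would tighten the maps but is deliberately out
of scope: the fingerprint contract is standard Grad-CAM.

## Numerical and degenerate-input choices

* Sequences longer than the encoder capacity are truncated with a warning
  (mining inputs are pre-filtered to ≤1600 residues anyway); residues
  outside the alphabet fail loudly at encoding, and are skipped per record
  (with a warning and an `NA` score) during batch prediction.
* `evaluate_scores()` refuses one-class inputs (AUC undefined) and reports
  precision 0 with a warning when nothing is predicted positive.
* Peak suppression breaks saliency ties toward the earlier position;
  mutation ranking breaks total-rank ties by position then residue — all
  outputs are deterministic under permutation of the input.
* Training aborts with the epoch index if the loss turns non-finite;
  an `epochs = 0` model predicts at chance and refuses to be
  fingerprinted.
* Problem sizes in the tests and the acceptance script (400+400 sequences,
  3 seeds per condition, 500-homolog conservation checks) are the
  package's chosen desk-scale study conditions; they run end to end in
  minutes on one CPU.

## Known limitations

* The characteristic matrix conditions on residue identity at a single
  column; epistatic or structural context is out of scope, as is any
  combination modeling of double mutants.
* Grad-CAM resolution is bounded by the first pool width; features
  narrower than ~4 residues will not be resolved.
* The classifier is binary; typing (Cas12/Cas13 heads) is a non-goal.
* No MSA construction: the design stage takes an alignment as input.
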