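---
title: "Classification and turnover of tRNA-derived small RNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification and turnover of tRNA-derived small RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfdecay)
library(dplyr)
```

## Scope

`trfdecay` quantifies the turnover of tRNA-derived small RNAs (tRFs)
from small-RNA sequencing. It covers four analysis stages — positional
tRF classification, decay-profile-normalised half-life estimation under
transcription shut-off, Argonaute RIP/input enrichment, and anchored
metagene coverage — and a synthetic-data generator that produces all of
their inputs with known ground truth. This vignette explains the models
and the choices behind them; the README shows the quick-start workflow.

## The positional classification model

A pre-tRNA is leader + mature body (possibly interrupted by one intron
inserted one base 3′ of the anticodon) + trailer, the trailer ending at
the Pol III poly-U terminator. `build_reference()` derives three
transcript-oriented sequences per locus — the full pre-tRNA, the spliced
mature body, and mature+CCA — plus an optional miRNA reference.
`map_sequence()` reports every end-to-end alignment with Hamming
distance ≤ 1 (no indels; `N` counts as a mismatch; exact hits suppress
1-mismatch hits). Classification then works on transcript-frame
offsets:

* **tRF-1** — 5′ end within 2 nt of the first trailer base, read 3′ of
  the discriminator;
* **tRF-leader** — 3′ end within 2 nt of the last leader base;
* **tRF-5** — 5′ end at mature position 0 (±1 nt);
* **tRF-3** — 3′ end at the mature terminus, matched against mature or
  mature+CCA. The CCA is post-transcriptional and absent from the
  genome, so it is treated as an optional non-templated suffix that
  must match exactly and never consumes the mismatch budget; without
  this, CCA-tailed tRF-3s would be unmappable.
* **intron-tRF** — read inside an intron block (±2 nt);
* **misc-tRF** — any other mature-body overlap; miRNA-reference hits are
  **miRNA**; unmapped reads are **unassigned**.

The boundary tolerances (±1 for the tRF-5 anchor, ±2 elsewhere) absorb
ribonuclease-site heterogeneity and are arguments of
`classify_reads()`. When one sequence satisfies several rules —
possibly at different loci — a fixed, overridable precedence resolves
the conflict: miRNA > tRF-1 > tRF-5 > tRF-3 > tRF-leader > intron-tRF >
misc-tRF. Counting is sequence-centric: collapsing (`collapse_reads()`)
merges identical sequences and keeps distinct-length isoforms distinct,
each unique sequence is classified once, and multi-mapping within a
class never multiplies counts. Reads of 14 nt or shorter are discarded
(`min_len = 15`), matching the practical size floor of small-RNA
library preparation.

## Half-life estimation under transcription shut-off

After transcription inhibition (actinomycin D), total cellular RNA
decays. Libraries are sequenced to a fixed depth, so a perfectly stable
species *appears* to increase in library-relative counts — by exactly
the factor the total pool has shrunk. Decay-profile normalisation turns
this artifact into the correction itself:

1. `size_normalize()` — reads per million (`rpm`), or `spike_in`
   scaling when exogenous controls of fixed absolute amount are
   present;
2. `t0_normalize()` — divide each sequence by its mean t = 0 level, so
   every retained trajectory starts at 1 (sequences absent at t = 0 are
   excluded and reported);
3. `identify_stable()` — the stable set is every sequence with an
   *apparent increase over time*, operationalised as a positive OLS
   slope of the T0-relative values against time with detection in at
   least one library of every timepoint. The slope sign is a
   deliberately threshold-free reading of "apparent increase"; both it
   and the detection rule are exposed through the returned table so a
   stricter set can be substituted.
4. `decay_factors()` — the decay factor at each timepoint is the
   arithmetic mean (the natural reading of "average") over stable
   sequences of their mean T0-relative value; it is 1 at t = 0 by
   construction.
5. `apply_decay_normalization()` — divide by the factor. The stable-set
   mean trajectory is then exactly 1 at every timepoint, an algebraic
   identity the test suite checks to machine precision; applying the
   step twice changes nothing.

`fit_decay()` fits A(t) = A₀·e^(−k·t) by bounded nonlinear least
squares (A₀ > 0, k ≥ 0; L-BFGS-B) initialised from a log-linear
regression on the positive values. Zeros — fully decayed observations —
stay in the least-squares objective and only leave the initialiser,
because log-fitting would otherwise discard the strongest evidence of
fast decay. Non-convergence falls back to the log-linear estimate,
flagged in `status`. Half-life = ln 2 / k; k below 1e-12 is reported as
exactly 0, and any half-life beyond the cap (default: the last observed
timepoint, 12 h in the default design) is reported *as* the cap with
`capped = TRUE`, mirroring the convention that a chase cannot resolve
half-lives longer than itself. Replicates enter the fit as independent
points by default (`replicate_mode = "mean"` averages them first); the
fit runs on decay-normalised T0-relative values so A₀ ≈ 1, keeping the
two normalisation steps ahead of the curve fit in the same order as the
procedure above.

`expression_filters()` applies the 10-read total floor and flags
sequences reaching 50 normalised counts (inclusive) in any library as
highly expressed. `class_summaries()` reports per class the median
half-life (capped values enter at the cap), median t = 0 expression,
and the median per-sequence log2 fold change between two timepoints
with a 0.5-count pseudocount (default) so fully decayed tRF-1s do not
produce −∞.

## RIP enrichment and metagene profiles

`fold_enrichment()` computes (mean normalised RIP + pc)/(mean
normalised input + pc) per sequence and condition — replicate means,
not pooled counts, so a dropout replicate cannot dominate.
`class_shift()` gives per-sequence log2 fold changes of RIP association
between conditions and class medians; it is purely descriptive (no
negative-binomial testing — differential-expression calls belong to
dedicated tools). Enrichment on library-size-normalised counts carries
a compositional scaling (every fold is divided by the
abundance-weighted mean enrichment); spike-in normalisation removes it,
which is why the generator carries spike-ins into RIP libraries.

`compute_profile()` aggregates read coverage across genes after
anchoring each at the mature 3′ end (or the gene 5′ end) and orienting
by strand; offset +1 is the first base downstream of the anchor, there
is no offset 0. Full-read coverage is the default; a 5′-end-only mode
suits crosslinking data. Windows running off a chromosome are truncated
rather than dropped. Total profile mass equals the overlapping
read-count mass divided by the gene count — a conservation property
the tests verify against a per-base oracle, as is exact invariance
under reverse-complementing the whole dataset.

## What the generator emulates

`sim_params()` defaults define the study conditions: 0/1/2/4/8/12 h in
triplicate; per-class log-normal decay rates with tRF-1s at a median
half-life of 0.3 h and no stable members, tRF-5/tRF-3 at 6 h with a
quarter stable, miRNAs 90 % stable (residual median 20 h); tRF-leaders
and intron-tRFs intermediate and unstable, consistent with their
accumulation when the degrading exonuclease is lost. Sequencing depth
(5×10⁵ expected mapped reads) and negative-binomial dispersion (0.05,
i.e. ~22 % biological CV) are free parameters with no published values;
they were chosen once as typical for small-RNA triplicates and are
flagged here as assumptions. Twenty spike-ins of fixed absolute
abundance emulate an exogenous control mix.

The compositional artifact is produced mechanically: each library draws
counts around depth × (absolute abundance / total pool), where the pool
includes an unannotated background mass (half the library at t = 0)
decaying at 0.08 h⁻¹. The per-library `total_count` includes that
background, so totals fluctuate around the configured depth while the
annotated rows' shares rise as the pool shrinks. RIP libraries multiply
abundances by per-sequence enrichment folds and renormalise to depth;
spike-ins and background stay at fold 1.

Fragments are exact substrings of the simulated pre-tRNAs at the
class-defining positions; tRF-3s carry CCA; tRF-1s get 0–3 nt of 3′
shortening emulating variable Pol III termination (donor trailers are
18–25 nt so jittered fragments stay above the 15 nt floor, and trailer
isoforms remain distinct countable sequences). One RNG stream per
generator function, seeded from `seed` plus a documented fixed offset,
makes every output byte-identical under the same parameters.

What the generator does **not** emulate — read-level sequencing errors,
adapter/ligation bias, RNA modifications blocking reverse
transcription, multi-copy tRNA families with near-identical paralogs,
and cell-to-cell heterogeneity. Passing recovery tests therefore shows
the pipeline's statistical machinery is correct under its stated noise
model, not that real libraries are free of these additional effects.

## Numerical and design notes

* Coordinates are 0-based half-open genomically; transcript offsets are
  0-based from the pre-tRNA 5′ end. BED12 output encodes the mature
  span as thickStart/thickEnd and the mature exons as blocks; because
  blocks do not abut the locus ends this dialect is written and parsed
  directly by `write_models_bed()`/`read_models_bed()` rather than via
  generic BED importers, and the header line documents it.
* Problem sizes in the tests and acceptance script (a ~190-sequence
  default experiment, 500 sequences for rate recovery, 200 per class
  for enrichment medians) were chosen as the smallest sizes at which
  the Monte-Carlo summaries are stable; all run in well under a minute
  each.
* Sequences undetected at late timepoints are fitted on their available
  points (minimum 3 spanning 2 timepoints), not dropped — shortening
  below the cloning cutoff is part of degradation, so truncated
  trajectories still carry signal. Fewer points skip the sequence with
  a recorded reason.
* `fit_decay()` agrees with an exhaustive profiled grid search over k
  (step 1e-3) on every tested trajectory; the exactly-halving
  trajectory recovers k = ln 2 to machine precision because the
  log-linear initialiser already solves it.

## Limitations

Classification assumes pre-trimmed, collapsed input and toy-scale
reference sets (every candidate locus is scanned; there is no indexed
genome aligner). Half-life estimation assumes first-order decay — no
synthesis term, no hierarchical shrinkage across sequences. Enrichment
is descriptive only. Metagene profiling reads intervals, not
alignments, so soft-clipped bases are invisible beyond the CCA handling
in the classifier.
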