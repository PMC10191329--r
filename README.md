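# trfdecay

Turnover kinetics and positional classification of tRNA-derived small
RNAs (tRFs) from small-RNA sequencing data.

## The problem

Small-RNA libraries are crowded with fragments the size of miRNAs, the
most prominent being tRNA fragments. Precursor tRNAs carry a leader, a
trailer ending at the Pol III poly-U terminator, and sometimes an
intron; processing releases positional fragment classes — tRF-leaders,
tRF-1s (trailers), intron-tRFs — while the mature tRNA yields tRF-5s,
tRF-3s (often with the non-templated 3′ CCA) and internal misc-tRFs.
Although tRF-1s are among the most abundantly *produced* small RNAs,
they are extremely short-lived and largely excluded from Argonaute.
Measuring that requires three things this package provides:

1. **Positional classification** of collapsed small-RNA sequences
   against pre-tRNA gene models (end-to-end mapping, ≤ 1 mismatch,
   CCA-aware), into the closed class set
   `tRF-leader / tRF-1 / tRF-5 / tRF-3 / intron-tRF / misc-tRF / miRNA / unassigned`.
2. **Half-life estimation** from transcription shut-off (actinomycin D)
   time courses. Because total RNA shrinks during the chase, stable
   species *appear* to rise in library-relative counts; the package
   applies decay-profile normalization — T0-normalize, identify the
   apparently-increasing stable set, divide each timepoint by the
   stable-set mean ("decay factor") — then fits per sequence

   A(t) = A₀·e^(−k·t),  half-life = ln(2)/k,

   capping half-lives beyond the experiment duration (default 12 h).
3. **Argonaute RIP enrichment** (mean normalized RIP / input folds,
   class-level condition shifts) and **strand-aware metagene profiles**
   anchored at the mature tRNA 3′ end, where tRF-1 coverage lives.

A fully deterministic synthetic-data generator (toy genome, pre-tRNA
annotations, negative-binomial libraries with spike-ins and a shrinking
background pool, RIP pairs with known per-sequence enrichment) provides
ground truth for validating every stage.

## Worked example

```r
library(trfdecay)
library(dplyr)

params <- sim_params(seed = 1)          # the default study conditions
sim    <- simulate_experiment(params)   # genome + truth + counts
tc     <- sim$timecourse

rel  <- tc$counts |> size_normalize(tc$samples) |> t0_normalize()
stab <- identify_stable(rel)
dn   <- rel |> apply_decay_normalization(decay_factors(rel, stab))
fits <- fit_decay_all(dn, cap_h = 12)

glance(fits)
#> # A tibble: 1 × 6
#>   n_sequences n_fit n_capped cap_h median_k median_half_life_h
#>         <int> <int>    <int> <dbl>    <dbl>              <dbl>
#> 1         212   212       98    12   0.0876               7.91

class_summaries(fits, rel)
#> # A tibble: 8 × 5
#>   class          n median_half_life_h median_expr_t0 median_log2fc
#>   <chr>      <int>              <dbl>          <dbl>         <dbl>
#> 1 intron-tRF    12              1.64            788.      -0.545
#> 2 miRNA         60             12              1834.       0.220
#> 3 misc-tRF      12              3.67           1173.      -0.211
#> 4 spike-in      20             12              1354.       0.212
#> 5 tRF-1         40              0.319          1409.      -2.89
#> 6 tRF-3         30              7.87           1262.       0.107
#> 7 tRF-5         30              6.41           1553.       0.00660
#> 8 tRF-leader     8              0.810          2171.      -1.05
```

Reading the table: tRF-1s are highly expressed at steady state yet have
a median half-life of ~0.3 h and are depleted almost 8-fold within one
hour of transcription shut-off (`median_log2fc` ≈ −2.9 between 0 and
1 h), while miRNAs sit at the 12 h cap and barely move — the
compositional artifact that would have masked this is removed by the
decay-factor step (`n_capped` counts the stable sequences). Plots:
`autoplot(fits)`, `autoplot(compute_profile(...))`,
`plot_trajectories(...)`.

`run_pipeline(out_dir, params)` chains
simulate → classify → half-life on one parameter set and writes genome
FASTA, BED12 gene models, counts/sample-sheet/truth TSVs, per-sequence
fits, class summaries and a JSON run manifest with checksums.

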