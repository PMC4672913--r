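# tstructseq

Targeted DMS probing of RNA secondary structure in cells, from aligned
RT-stop sequencing reads to reactivity-constrained structure models.

## The problem

Dimethyl sulfate (DMS) methylates accessible (unpaired or weakly
structured) A and C bases of RNA inside living cells. Reverse
transcriptase (RT) halts one nucleotide 3' of a methylated base, so
sequencing the cDNA products of transcript-specific RT primers reads out,
per base, how often the RT stopped there. Comparing a DMS-treated sample
with an untreated control separates chemistry from spontaneous drop-off
and yields a per-base modification probability — an in-cell accessibility
profile that can constrain thermodynamic structure prediction of long
non-coding RNAs and other large transcripts that are intractable to probe
by electrophoresis.

`tstructseq` implements the full computational pipeline for such targeted
RT-stop experiments:

1. **readproc** — clip the leading random-mer from raw reads, ingest
   SAM/BAM alignments, filter (aligned length ≥ 60 nt, ≤ 2 mismatches),
   split multi-mapped read weight evenly across sites, assign reads to RT
   primers, and tally weighted termination events `n(i)` and read-through
   events `r(i)` per position, excluding positions within 25 nt of a
   primer annealing site.
2. **reactivity** — the hazard-style estimator

   ```
   P_term(i) = n_T(i) / r_T(i)      (treated)
   P_spont(i) = n_U(i) / r_U(i)     (untreated control)
   P_DMS(i) = P_term(i) - P_spont(i)
   ```

   combined across primers by averaging positions 100–380 nt from each
   primer with > 1000 read-through events in both conditions; strong
   reactivity is `P_DMS ≥ 0.8%`, moderate `0.4% < P_DMS < 0.8%`. QC
   metrics: A+C fraction among top-ranked positions, inter-primer and
   inter-condition agreement (Pearson r, least-squares slope).
3. **thermoscan** — sliding-window (150 nt / 10 nt steps) thermodynamic
   z-score `z = (dG_native − mean dG_shuffled) / sd(dG_shuffled)` over 25
   same-composition shuffles per window; overlapping windows below a
   cutoff (by default one standard deviation more favorable than the
   transcript mean) merge into structured regions.
4. **foldmodel** — minimum-free-energy folding at 37 °C with
   chemical-modification constraints: a strongly reactive base may not
   occupy a Watson–Crick pair flanked on both sides by Watson–Crick pairs
   (helix-terminal pairing and unpaired states remain allowed). A
   self-contained nearest-neighbor dynamic-programming engine implements
   these semantics exactly and is verified against brute-force
   enumeration; a ViennaRNA adapter (`RNAfold`/`RNAeval`) provides full
   Turner-model energies for unconstrained folding and evaluation.
   Bootstrap support refolds the fragment (1000× by default) under random
   constraint subsets; consensus pairs appear in > 50% of replicates.
5. **conservation** — maps model pairs through a multiple sequence
   alignment and scores per-pair canonical fraction (GU wobble included),
   consistent mutations (single substitutions preserving pairing) and
   compensatory mutations (double substitutions preserving pairing).
6. **simdata** — a generative model of the whole experiment: transcript
   with planted stem-loops, per-position modification probabilities, and
   an RT hazard walk that emits treated/untreated aligned reads (and SAM),
   so every stage can be validated against ground truth.
7. **cli** — `run_pipeline()` / `run_cli()` plus the `inst/cli/tstructseq`
   Rscript orchestrate the stages from a YAML config with a metadata
   record per run.

## Worked example

Simulate a probing experiment under the default study conditions
(2 kb transcript, planted stems, 10^4 reads per primer), classify
reactivity, and fold a fragment under the derived constraints:

```r
library(tstructseq)
ex <- sim_experiment(sim_config(seed = 7))
prof <- classify_reactivity(ex$combined)
table(prof$class)
#>   strong moderate      low
#>      491       66     1143

ac_specificity(prof, ex$transcript, ranks = c(50, 200, 500))
#>   rank ac_fraction
#> 1   50           1
#> 2  200           1
#> 3  500           1

frag <- substr(ex$transcript$sequence, 401, 560)
cons <- make_constraints(subset_profile(prof, 401, 560))   # 40 positions
st <- mfe_fold(frag, cons, engine_builtin())
st
#> Secondary structure: transcript
#>   length: 160 nt; 39 base pairs
#>   energy: -48.70 kcal/mol

bs <- bootstrap_support(frag, cons, engine_builtin(), n = 200, seed = 7)
sum(bs$consensus)
#> [1] 39
```

The 491 strong positions are overwhelmingly the planted accessible A/C
sites (the A+C fraction of 1.0 at every rank cutoff is the expected DMS
specificity), and 39 of the 42 pairs ever observed across bootstrap
replicates are consensus pairs, i.e. the constrained model is stable
under constraint resampling.

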