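---
title: "Methods: from RT-stop reads to conserved RNA structure models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RT-stop reads to conserved RNA structure models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tstructseq)
```

This vignette documents the models and numerical choices behind
`tstructseq`, in the order the pipeline runs them.

## The measurement model

DMS methylates N1 of adenine and N3 of cytosine when those faces are not
engaged in Watson–Crick pairing. A reverse transcriptase walking 3'→5'
along the template halts one base short of a methylated position, so the
5'-most aligned base of a cDNA read at position $a$ implies a block at
$t = a - 1$; $t = 0$ denotes runoff past the transcript's 5' end and
contributes no termination count. All coordinates are 1-based and
inclusive on the RNA.

Per primer and condition we accumulate weighted termination counts
$n(i)$ and read-through counts $r(i)$ (a read covers $i$ without stopping
there; by construction a read never covers its own termination position).
Multi-mapped reads contribute $1/k$ at each of their $k$ reported sites,
so total weight per read is conserved. Read-through is not counted within
25 nt of a primer's annealing-proximal end — the annealing site itself is
chemistry-free signal — and the rule is strict (distance > 25 kept).

The per-base modification probability is the difference of two hazard
estimates,

$$P_{\mathrm{DMS}}(i) = \frac{n_T(i)}{r_T(i)} - \frac{n_U(i)}{r_U(i)},$$

which is invariant to sequencing depth in either condition and can be
legitimately negative (sampling noise around zero); values are never
clamped. Positions lacking read-through in either condition are NA, not
zero.

**Combining primers.** A primer informs a position only when the position
lies 100–380 nt from its annealing start and the position's read-through
exceeds 1000 in *both* conditions — both denominators must be stable,
which is why the coverage requirement applies to treated and untreated
alike. The combined value is the plain arithmetic mean over eligible
primers; we deliberately do not pool raw counts across primers, because
the eligibility windows differ per primer and pooling would re-weight
positions by coverage. Classification thresholds: strong
$P_{\mathrm{DMS}} \ge 0.8\%$, moderate $0.4\% < P_{\mathrm{DMS}} <
0.8\%$ (both bounds strict for moderate), low otherwise.

**QC.** Because DMS should mark only A and C, ranking positions by
reactivity and reporting the A+C fraction among the top ranks measures
specificity; ties are broken by ascending position so the report is
deterministic. Inter-primer and inter-condition agreement use Pearson
correlation and a least-squares slope over positions with defined,
non-zero values in both profiles — zeros are excluded *before*
correlation, since exact zeros mostly encode absence of events rather
than measured agreement.

## Thermodynamic z-score scan

Windows of 150 nt advance in 10-nt steps; the final partial window is
dropped (a strict sliding scheme keeps all windows the same size, so
their energies are comparable). Each window's native minimum free energy
is compared with 25 mononucleotide shuffles — permutations with identical
composition; a dinucleotide-preserving shuffle is available as an option
but is not the default, since the control of interest is composition, not
stacking statistics. Then

$$z = \frac{\Delta G^\circ_{\mathrm{native}} -
  \overline{\Delta G^\circ_{\mathrm{random}}}}{\sigma},$$

with $\sigma$ the sample standard deviation of the shuffle energies.
Windows whose shuffles all fold to the same energy (e.g. unpairable
sequence) get $z = \mathrm{NA}$ rather than $\pm\infty$. Shuffle RNG
streams are derived per window from (seed, window start), so a scan is
bit-reproducible and window results do not depend on evaluation order.

**Region calling.** Windows with $z$ below the cutoff merge by interval
union when they share at least one nucleotide; abutting windows stay
separate. The automatic cutoff is the transcript mean $z$ minus one
*population* (n-denominator) standard deviation of the window z
distribution. An optional `gap_join` merges called regions separated by
at most that many nucleotides; it is off by default because joining
adjacent domains is a curation decision, not a property of the scan.
Lowering the cutoff can only shrink the total called span
(a tested monotonicity invariant).

## Folding engines and constraint semantics

The chemical-modification constraint is *not* "force single-stranded": a
strongly reactive base may still pair at a helix end or in isolation.
What it may not do is occupy a Watson–Crick pair flanked on both sides by
Watson–Crick pairs, i.e. sit helix-internal, where the modified face
would be sequestered. The built-in engine implements this exactly by
splitting the paired-state dynamic-programming array into "enclosing
positions pair" / "do not pair" variants and forbidding the immediate
stack transition for flagged pairs in the former.

The built-in engine is a Zuker-style recursion over nested structures
with canonical pairs (AU, UA, CG, GC, GU, UG), minimum hairpin loop of
3 nt, stacking energies from a compact embedded table (Watson–Crick and
wobble doublets, symmetric under helix reversal), logarithmic
hairpin/bulge/internal-loop penalties, a linear multiloop model, no
dangling ends and no coaxial stacking, interior loops capped at 30
unpaired nt. Energies are handled as integer hundredths of kcal/mol, so
MFE and re-evaluation agree exactly and ties are resolved identically
across platforms. The engine exists so that every test and the entire
constraint machinery run without external software; it is validated by
exhaustive enumeration (all nested structures of random sequences up to
18 nt, scored with the same energy function, with and without
constraints), not by agreement with any external program.

The ViennaRNA adapter (`RNAfold`/`RNAeval`) supplies full Turner-model
energies at 37 °C for unconstrained folding, batch window scans and
evaluation of given structures. RNAfold's constraint language cannot
express the helix-internal exclusion, so constrained folds are routed to
the built-in engine and the adapter raises an actionable error if asked.

**Bootstrap support.** Each of $n$ replicates (default 1000) folds under
$\lceil f\,|C|\rceil$ constraints sampled without replacement from the
strong-reactivity set $C$; the subset fraction $f$ defaults to 0.5 — the
resampling scheme is a design choice, recorded in the output metadata,
chosen to perturb roughly half the evidence per replicate. Support is
the fraction of replicates containing a pair; consensus pairs exceed
0.5. Identical subsets are folded once and reused, which changes nothing
statistically (folding is deterministic) and bounds runtime by the
number of distinct subsets.

## Conservation scoring

Model pairs are mapped through the reference row's gap structure to
alignment columns. A species' pair is canonical if its two residues form
AU/UA/CG/GC/GU/UG; a gap in either residue counts as non-canonical in
the denominator (the conservative reading — an indel is evidence against
the pair, not missing data). The reference row is included in the
per-pair fraction, so a pair absent everywhere else still scores
$1/S$. Mutations are classified per species against the reference — not
against a phylogeny: *consistent* means exactly one residue differs and
pairing is preserved; *compensatory* means both differ and pairing is
preserved. The classes are disjoint per species per pair; model-level
counts tally pairs with at least one species in each class. Row-subset
filters support scoring, e.g., a rodent-only panel of a mammalian
alignment.

## The simulator: what it emulates and what it does not

`sim_config()` defaults define the study conditions used throughout the
tests:

| parameter | default | meaning |
|---|---|---|
| `p_hit` | 0.01 | per-encounter RT-stop probability at accessible (unpaired) A/C under treatment |
| `p_bg` | 5e-4 | stop probability at protected A/C |
| `p_spont` | 2e-3 /nt | spontaneous drop-off, both conditions |
| `min_recovered_length` | 100 nt | library loss of short RT products |
| `reads_per_primer` | 10^4 | per condition |
| `primer_spacing` | 200 nt | transcript-specific primer panel |

`p_hit` is set so recovered strong-site reactivity lands near the 0.8%
strong threshold; `p_spont` gives the untreated control a realistic
background an order of magnitude above `p_bg`. Termination is modeled as
a per-position hazard during the RT walk, which makes the expectation of
the $n/r$ estimator available in closed form: the estimator recovers
`p_hit` directly at planted sites (a tested property). G and U positions
are never modified in the default `ac_only` mode, so A+C specificity of
top-ranked positions is 100% by construction — the QC metric's positive
control.

Not emulated: PCR duplication, ligation bias, quality-score structure,
misalignment (an optional uniform mismatch injection exists only to
exercise the mismatch filter). Passing the recovery tests therefore
demonstrates correctness of the estimator and plumbing under the stated
generative model, not robustness to every artifact of real libraries.

Problem sizes in the tests and acceptance script — a 2 kb transcript,
10^4 reads per primer, 200 enumeration cases up to 18 nt, 1000 window-set
oracle cases, 1000 bootstrap replicates — were chosen as the smallest
sizes at which the statistical assertions have comfortable margins.

## Degenerate inputs and numerical conventions

* Empty read sets produce all-zero counts, not errors; empty SAM input is
  a warning.
* Positions with zero read-through are NA through every downstream stage;
  NA reactivity is never constrained and never classified.
* `z` is NA when the shuffle standard deviation is zero; all-NA scans
  call no regions (with a warning).
* The folding grammar enforces $j - i \ge 4$ and at most one pair per
  position; crossing pairs are rejected at container construction.
* Dot-bracket and CT round-trips are lossless for any valid structure.
* Energies are reported in kcal/mol at 37 °C; the built-in engine's
  integer representation makes `energy_of(mfe_fold(...))` exact to
  0.01 kcal/mol.

## Known limitations

* The built-in energy table is compact, not the full Turner 2004 set:
  no dangles, coaxial stacking, terminal-AU penalties or tetraloop
  bonuses. Absolute energies differ from RNAstructure/ViennaRNA;
  structure-level conclusions in the tests rely on enumeration
  equivalence, not literature energies.
* Pseudoknots and partition-function (pair-probability) folding are out
  of scope.
* Conservation counting is alignment-quality-bound and phylogeny-naive;
  it counts species, not independent substitution events.
* Primer assignment uses a 5-nt slack around the annealing start; reads
  from unanticipated priming sites are dropped as off-target rather than
  rescued.
```{r session}
sessionInfo()
```
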