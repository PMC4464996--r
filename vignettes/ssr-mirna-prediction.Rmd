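---
title: "Predicting plant pre-miRNAs from homology, folding descriptors and SSR signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting plant pre-miRNAs from homology, folding descriptors and SSR signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrmir)
```

## The problem

Plant microRNAs are processed from precursor transcripts (pre-miRs) that
fold into characteristic stem-loop hairpins. Because mature miRNAs are
strongly conserved across plant species, new miRNAs in a poorly annotated
species can be predicted by scanning its EST/GSS or genomic sequences for
near-exact copies of known mature miRNAs and then asking whether the
surrounding sequence can fold into a credible pre-miR hairpin. The
difficulty is the second step: many genomic windows fold into *some*
hairpin, so the structural filter decides the false-positive rate.

`ssrmir` implements a prediction pipeline that combines three kinds of
evidence:

1. **Homology** — an ungapped, full-query-coverage scan of subject
   sequences (both strands) for copies of known mature miRNAs with at
   most 3 substitutions and at least one exact 7-mer seed.
2. **Folding descriptors with distribution-derived cutoffs** — instead of
   fixed thresholds, each descriptor is screened against the central (or
   one-sided) 99% probability region of its empirical distribution over a
   reference set of known precursors.
3. **Conserved SSR signatures** — each miRNA family carries a
   trinucleotide simple-sequence-repeat signature (the shared 3-mer with
   maximal average density); a candidate must carry its family's
   signature at sufficient density.

## Descriptors

For a sequence of length $L$ with minimum folding energy $\mathrm{MFE}$
(kcal/mol) and ensemble base-pair probabilities $p_{ij}$:

$$\mathrm{AMFE} = \frac{-\mathrm{MFE}}{L}\times 100,\qquad
  \mathrm{MFEI} = \frac{\mathrm{AMFE}}{(G+C)\%}$$

$$NQ = -\frac{1}{L}\sum_{i<j} p_{ij}\log_2 p_{ij},\qquad
  ND = \frac{1}{L}\sum_{i<j} p_{ij}(1-p_{ij}),\qquad
  N_{pb} = \frac{\#\{\text{pairs in MFE structure}\}}{L}$$

$NQ$ (normalized Shannon entropy) and $ND$ (normalized base-pair
distance) measure how concentrated the Boltzmann ensemble is: a genuine
pre-miR folds into one dominant hairpin, giving low values. $N_{pb}$
(base-pairing propensity) lies in $[0, 0.5]$ by construction, with real
precursors densely paired. The GC percentage enters MFEI on the percent
scale (50, not 0.5), which puts typical precursor MFEI near 1.

`derive_cutoffs()` turns a reference descriptor table into acceptance
ranges: central coverage intervals for length and AU% (quantiles at
$(1-c)/2$ and $1-(1-c)/2$), one-sided quantiles for MFEI and $N_{pb}$
(lower) and for $NQ$ and $ND$ (upper). Quantiles use linear interpolation
of order statistics (R type 7); the exact convention behind a "99%
probability range" is not uniquely determined by the phrase, and this is
the package's choice. `viridiplantae_cutoffs()` ships the published
ranges for miRBase-20 Viridiplantae precursors (length 55–505 nt,
AU 22–77%, MFEI ≥ 0.41, NQ ≤ 0.45, ND ≤ 0.15, Npb ≥ 0.25). The
literature states the AU range both as 22–77% and as 27–77%; the wider
Methods value is the default and the stricter one is available via
`viridiplantae_cutoffs(au = "results")`.

**Cutoffs are backend-relative.** The published numbers assume a full
thermodynamic folder. The built-in engine (below) uses a simplified
energy model on a different scale, so cutoffs must be re-derived from a
reference population folded with the same backend. All synthetic-data
tests do exactly that.

## The folding engine

The built-in engine implements a base-pair energy model: every allowed
pair (G:C $-3.0$, A:U $-2.0$, G:U wobble $-1.0$ kcal/mol, configurable)
contributes independently, hairpin loops enclose at least 3 unpaired
bases, and structures are pseudoknot-free. The MFE structure is computed
by exact interval dynamic programming; ties are broken toward fewer pairs
and then by a deterministic earliest-partner traceback. Ensemble pair
probabilities come from an inside–outside partition-function recursion
over the same model with Boltzmann weights $e^{-E/RT}$, $RT = 0.616$
kcal/mol, computed in extended precision with MFE-density scaling. Both
routines are validated in the test suite against exhaustive structure
enumeration (energies and probabilities to $10^{-9}$) for hundreds of
random sequences up to length 18.

This model was chosen over a full nearest-neighbour implementation
because it admits an exact, independent enumeration oracle at desk scale;
the backend interface (`builtin_backend()`, `vienna_backend()`) lets a
thermodynamic folder such as RNAfold stand in, changing only numeric
values, never contracts.

## The seven criteria

A candidate window passes when:

* **c1** it folds with MFE < 0 and MFEI at or above the cutoff;
* **c2** the mature lies on one arm, outside any terminal loop;
* **c3** the mature/star duplex has fewer than 6 mismatches (a mismatch
  is an unpaired mature position; G:U counts as a pair);
* **c4** the star is contiguous — no position inside the star span pairs
  outside the mature ("no loop or break in the star");
* **c5** AU% lies in the cutoff range;
* **c6** NQ, ND and Npb are inside their cutoffs;
* **c7** the query's family has a catalog signature and the window
  carries that motif at R ≥ 2.5 per 100 nt.

Criterion c2 is enforced locally (mature and star on one stem, mature not
in a terminal loop) rather than demanding the entire window be a single
unbranched hairpin; real plant precursors often have branched flanks.
"Loop or break in the star" has no formal published definition; the
star-contiguity reading above is the testable operationalization used
here. Whether the duplex mismatch count should also include star-side
bulges is likewise unstated; this implementation counts unpaired
mature positions only.

Among all windows of one homology hit that pass every criterion,
`select_best()` keeps the window maximizing MFEI, then R, then the
shorter window, then the smaller start — the first two keys follow the
published selection rule, the last two make the choice deterministic.
`run_pipeline()` evaluates windows in best-first order computed from the
cheap MFE stage, so the expensive ensemble descriptors run only until the
optimum passes; the result is provably the same window, at a fraction of
the cost.

## SSR signatures

Signature counting is overlapping exact occurrence counting of k-mers
(k = 3 by default; the published analysis concluded window size three).
$R = \text{count}/L \times 100$. For multi-member families, candidate
motifs must occur in *every* member and the winner maximizes the family
average R (ties broken lexicographically); single-member families take
the member's max-R motif. An alternative reading — that the motif must
occur as a tandem repeat — is available via `tandem_only = TRUE`, but
occurrence counting is the default because an R threshold of 2.5 per 100
nt and a full 64-trinucleotide catalog are consistent with occurrence
counts. Whether "present in all members" means count ≥ 1 or per-member
R ≥ 2.5 is also unstated; count ≥ 1 is used, with the 2.5 threshold
applied to the family average.

## Coordinates and formats

All internal intervals are 1-based closed, the R/Bioconductor (IRanges)
convention; conversion happens once at each format boundary (BLAST
tabular input is converted on ingestion, FASTA description output prints
1-based coordinates). Sequences are uppercased and T→U-normalized on
ingestion for all RNA-role inputs; DNA subjects are compared in U-space.
Collapsed small-RNA reads use the common `<id>_x<count>` header dialect,
with plain FASTQ collapsed on the fly; reads shorter than 14 nt are
removed and counts of retained reads conserved.

No e-value is computed in the homology scan: at the published settings
(e-value cutoff 1000, word size 7) the e-value filter is vacuous and the
operative constraints are the exact-word seed and the mismatch cap.
Externally computed tabular hits can be ingested instead.

## The synthetic data generator

Because the original inputs (miRBase 20, GenBank EST/GSS pools, genomes)
are external downloads, every pipeline input can be generated
synthetically with ground truth. A generated precursor is

```
tail5 | clamp | pad | mature | clamp | loop | clamp' | star | pad' | clamp' | tail3
```

where the star is the reverse complement of the mature with a chosen
number of pair-breaking substitutions planted in its middle third, loops
are drawn from {A, C} (self-unpairable), and short all-GC clamp helices
close both stem ends so that competing pairings between unpaired regions
and the stem interior would have to cross a clamp and cannot win under
the built-in model. Substitution sites keep at least one designed pair
between them and three at each stem end, and replacement letters avoid
pairing the facing base and its neighbours. Because a self-similar mature
can still admit equal-energy shifted registers, the generator
rejection-samples its random parts deterministically (child seeds) until
the folded MFE structure realizes the designed duplex; the returned truth
record is therefore guaranteed consistent with `analyze_duplex()`.

Default study conditions: 21-nt matures, 2 duplex mismatches, 8-nt loop,
5-nt pads, 12-nt tails, GC fraction 0.5, four planted signature copies
(≈ 96-nt precursors, signature density R ≈ 4.2). The reference population
for cutoff derivation varies mature length 20–22, pads 3–8, loops 6–10,
tails 8–16, GC 0.35–0.65 and duplex mismatches 0–5 — the full range the
duplex criterion admits. Corpus family motifs are AU-rich trinucleotides
(at least two of A/U), matching the composition that dominates published
plant signature distributions, and family construction verifies that the
planted motif really is the family's catalog signature (redrawing
deterministically otherwise), since the ground truth presumes criterion
c7 is checkable against it.

What the generator does **not** emulate: thermodynamically realistic
nearest-neighbour energetics, genomic repeat structure, sequencing error
in reads, and expression heterogeneity. Passing tests on this corpus
demonstrate the pipeline's correctness as an algorithm — recovery of
planted signal and rejection of composition-matched decoys — not its
empirical accuracy on real EST data, which depends on the thermodynamic
backend and curated reference sets.

Decoys are dinucleotide shuffles (Altschul–Erikson Eulerian-path
construction, preserving exact dinucleotide counts), iid random
sequences, or random sequences embedding reverse-translated protein
stretches for exercising the coding filter.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 1000 reference
precursors for cutoff derivation; a corpus of 20 planted precursors in
60-nt EST flanks plus 200 shuffled decoys; window enumeration at stride 4
with the window length range taken from the derived length cutoffs;
folding oracles at 200 random sequences of length ≤ 18. These sizes keep
a full run in a few minutes on one CPU while leaving every statistic
well-determined; stride 1 (fully exhaustive enumeration) is the library
default and is exposed on the CLI for larger runs.

## Known limitations

* The built-in energy model ignores stacking context, dangles and loop
  sizes beyond the minimum; absolute MFE values are not comparable to
  thermodynamic folders, which is why cutoffs are backend-relative.
* The partition-function outside recursion is $O(n^4)$; sequences at the
  505-nt extraction maximum take seconds each, which the pipeline
  mitigates by evaluating ensembles only for best-first candidates.
* Specificity against a "candidate universe" (for TN-based metrics) is
  computable only when the caller defines that universe; the published
  table's TN convention is not recoverable from the text.
* Predictions are deduplicated at both precursor and mature level and
  both counts are reported, since the published narrative (310 precursors
  → 208 matures) does not state where its deduplication happened.
* Target prediction itself is out of scope; `psrnatarget_params()` only
  generates the submission-ready parameter profile for each mature
  length.
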