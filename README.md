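# ssrmir

Homology-based prediction of plant precursor and mature microRNAs, using
RNA-folding descriptors screened against 99%-probability cutoff ranges
and conserved trinucleotide SSR (simple sequence repeat) family
signatures as the false-positive filter.

## Who this is for

Plant small-RNA researchers who want to predict pre-miR hairpins in
EST/GSS or genomic sequence from known mature miRNAs of related species
— and anyone who needs the building blocks: an exactly testable RNA
folding engine (MFE + McCaskill-style ensemble base-pair probabilities),
folding descriptors (AMFE, MFEI, NQ, ND, Npb) with distribution-derived
cutoffs, SSR signature catalogs, confusion-matrix / TPM / 2^-dCT
validation utilities, and seeded synthetic-data generators with ground
truth.

## The method in brief

Known mature miRNAs are scanned against subject sequences (both strands,
ungapped, full query coverage, ≥ 1 exact 7-mer seed, < 4 mismatches).
Around each hit, candidate precursor windows of all lengths in the
derived length range are enumerated and screened through seven criteria:

1. hairpin fold with MFE < 0 and `MFEI = (−MFE/L·100) / GC% ≥` cutoff;
2. mature on one arm, outside the terminal loop;
3. fewer than 6 mature/star duplex mismatches;
4. no loop or break in the star;
5. AU% within the cutoff range;
6. `NQ = −(1/L)·Σ p·log2 p`, `ND = (1/L)·Σ p(1−p)` within upper cutoffs
   and `Npb = pairs/L` above its lower cutoff (p are ensemble base-pair
   probabilities);
7. the family's SSR signature present in the window at `R = count/L·100
   ≥ 2.5`.

Per hit, the passing window with maximal MFEI (then maximal R) becomes
the predicted precursor; matures are extracted at the hit, named
miRBase-style (`pvu-miR399a`, ...) and deduplicated. Cutoffs are the
empirical 99% probability ranges of each descriptor over a reference
precursor set — `viridiplantae_cutoffs()` ships the published
miRBase-20 values for use with a thermodynamic folder; with the built-in
energy model they are re-derived via `derive_cutoffs()`.

## Worked example

Everything below is synthetic and seeded; no downloads are needed.

```r
library(ssrmir)

corpus    <- make_corpus(n_planted = 5, n_decoys = 50, seed = 42)
reference <- make_reference_set(500, seed = 43)
cutoffs   <- derive_cutoffs(descriptor_table(reference))
catalog   <- build_catalog(corpus$families)

cfg <- pipeline_config(corpus$queries, corpus$subjects, cutoffs, catalog,
                       species_prefix = "syn", stride = 4L)
res <- run_pipeline(cfg)
res
#> pipeline_result: 7 predicted mature miRNA(s)
#>                    stage count
#>                 subjects    55
#>                     hits    10
#>        candidate_windows  1530
#>  windows_rejected_coding     0
#>     predicted_precursors     7
#>        predicted_matures     7
```

The stage counts mirror the funnel of the method: 55 subjects produce 10
homology hits; 1530 candidate windows collapse to 7 precursors that pass
all seven criteria. The predictions carry the quantities the filter
acted on:

```r
res$predictions[, c("name", "mature_seq", "mfei", "r_signature")]
#>          name            mature_seq     mfei r_signature
#> 1 syn-miR101a AAUAGGUAGGUUCUGAUCCGA 2.121951    4.444444
#> 2 syn-miR102a UCAGUUAUUACAGUGAUCGAG 2.166667    2.830189
#> ...
mean(corpus$truth$mature_seq %in% res$predictions$mature_seq)
#> [1] 1
```

All 5 planted matures are recovered (the extra predictions are the
star-arm homologs the scan legitimately finds on the opposite strand);
none of the 50 decoys yields a prediction. Expression validation against
a read library reports supporting counts and TPM per prediction:

```r
reads <- make_reads(corpus$truth$mature_seq,
                    counts = c(1290, 2, 40, 7, 330),
                    n_noise = 100, seed = 44)
validation_report(res$predictions[1:3, ], reads)[
  , c("name", "read_count", "tpm", "confirmed")]
#>          name read_count        tpm confirmed
#> 1 syn-miR101a       1290 729225.551      TRUE
#> 2 syn-miR102a          2   1130.582      TRUE
#> 3 syn-miR102b          0      0.000     FALSE
```

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/ssrmir.R", package = "ssrmir"))')
Rscript $CLI simulate --out sim --planted 5 --decoys 50 --seed 42
Rscript $CLI cutoffs  --precursors sim/known_precursors.fasta --out sim/cutoffs.json
Rscript $CLI catalog  --precursors sim/known_precursors.fasta --out sim/catalog.tsv
Rscript $CLI predict  --queries sim/queries.fasta --subjects sim/subjects.fasta \
                      --cutoffs sim/cutoffs.json --catalog sim/catalog.tsv \
                      --out sim/pred --stride 4 --prefix syn
Rscript $CLI validate --matures sim/pred/matures.fasta --reads sim/reads.fasta \
                      --out sim/validation.tsv
```

`predict` accepts real FASTA inputs the same way (queries named
miRBase-style; optional `--proteins` enables the coding-sequence
exclusion; `--backend vienna` switches folding to RNAfold, after which
cutoffs must be re-derived with that backend).

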