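# pgtcnv

Copy-number analysis of single blastomeres from day-3 embryos for
preimplantation genetic testing (PGT) in couples carrying structural
chromosomal rearrangements — reciprocal and Robertsonian translocations,
inversions, deletions/duplications and insertions. The package is aimed at
people building or evaluating low-pass single-cell CNV pipelines in the
PGT-SR/PGT-A setting: it covers the full chain from the referral karyotype
to a transfer decision, and ships a calibrated synthetic-data generator so
every stage can be tested against known ground truth without any patient
data.

## What it computes

**Signal model.** A blastomere is MALBAC-amplified and sequenced shallowly
(~3×10⁶ single-end 55 bp reads, ~0.04× depth). Reads are counted in 1 Mb
bins; after GC and reference-panel normalization a per-bin ratio r = 1
corresponds to two copies. A gain 2→3 copies raises r by 50%, a loss 2→1
lowers it by 50%. For a segment with mean ratio r̄, the continuous copy
number is c = 2r̄, and

* |c − 2| ≥ 0.8 → full aneuploidy (integer call round(c)),
* 0.4 < |c − 2| < 0.8 → mosaic aneuploidy with fraction f = |c − 2|,
* |c − 2| ≤ 0.4 → no call.

An embryo with any event above the 40% mosaic rule is not fit for
transfer; only normal/balanced (Type V) embryos are transferable.

**Segmentation** is recursive: the two-sided mean-shift statistic
t = |m₁ − m₀| / (s·√(1/n₁ + 1/n₀)) of a candidate interval against the
rest of its segment is maximized over all sub-intervals and a split is
accepted at t > 5, followed by boundary refinement and re-merging. On
noiseless input it equals an exhaustive changepoint search.

**Meiosis.** Carrier gametes are enumerated from the quadrivalent
(reciprocal: alternate / adjacent-1 / adjacent-2 / 3:1 / 4:0; 18 classes,
2 balanced, under the default counting), trivalent (Robertsonian; 8
classes, 2 balanced) or inversion loop (4 classes, 2 balanced). The
theoretical couple euploidy probability is the product of the parents'
balanced-gamete masses in exact rational arithmetic — e.g. 1/9 × 1/9 =
1/81 for a double reciprocal-translocation couple.

**Classification.** Called events are matched against the catalogue of
imbalances the parental rearrangements can produce (same chromosome and
sign; whole-chromosome products match whole-chromosome calls, segmental
products match within 5 Mb breakpoint tolerance and ≥ 50% reciprocal
overlap): Type I parental-related only, II de novo only, III both, IV
multiple aneuploidy (≥ 3 chromosomes), V normal/balanced. Cohort tables
report rates as `x.y(n/d)` with chi-square / Fisher's exact comparisons.

## Worked example

```r
library(pgtcnv)

## theoretical euploidy for a double translocation-carrier couple
m  <- cytoband_map()
km <- parse_karyotype("46,XX,t(2;8)(q24;p22)")
kf <- parse_karyotype("46,XY,t(11;22)(q23;q11.2)")
couple_euploid_probability(km, kf, m)
#> euploid probability = 1/81 (0.01235)

## simulate a blastomere carrying a maternal 4.6 Mb deletion in 21q22.3,
## then run QC -> normalize -> segment -> call -> classify
grid  <- build_bin_grid(m, 1e6, seed = 1)
set.seed(42)
panel <- build_reference(lapply(1:10, function(i)
  simulate_blastomere_counts(NULL, "XX", grid, sim_config(),
                             sample_id = paste0("ref", i))), grid)
band  <- band_interval(m, "21", "q22.3")
start <- band[1] + (diff(band) - 4.6e6) / 2
del   <- data.frame(chrom = "21", start = start, end = start + 4.6e6,
                    delta = -1, fraction = 1)
set.seed(1)
cts   <- simulate_blastomere_counts(del, "XX", grid, sim_config(),
                                    sample_id = "embryo_01")
calls <- call_embryo(cts, panel, grid)
calls
#> <embryo_callset> embryo_01 sex=XX: 1 abnormal segment(s)
#>   chrom   start     end call f mosaic whole_chromosome size_mb
#> 1    21 4.3e+07 4.7e+07    1 1  FALSE            FALSE       4

classify_embryo(calls, parse_karyotype("46,XX,del(21)(q22.3)"),
                parse_karyotype("46,XY"), m)
#> <embryo_classification> embryo_01: Type I (not transferable)
```

The 4.6 Mb one-copy loss is recovered as a 4 Mb loss segment (bin-grid
resolution) at the right position, called copy number 1, and classified as
parental-related (Type I) because the mother carries the deletion.

Cohort tabulation works on any per-embryo classification records; on the
bundled fixture counts it reproduces the familiar clinical table layout:

```r
tab <- tabulate_cohort(expand_classification_counts(pgt_fixture("rearrangement")),
                       groups = c("RecT", "RobT", "Inv", "NoCR", "Other"))
tab[tab$group %in% c("RecT", "RobT", "Overall"),
    c("group", "informative_rate", "euploid_rate", "type_I_III")]
#>    group informative_rate   euploid_rate     type_I_III
#>     RecT    93.9(629/670)  16.1(101/629)  45.3(285/629)
#>     RobT    94.5(275/291)   28.0(77/275)   28.7(79/275)
#>  Overall  94.3(1168/1239) 21.9(256/1168) 33.5(391/1168)

outcome_summary(pgt_fixture("transfers"))$implantation_rate
#> [1] "44.4(100/225)"
```

An end-to-end simulated run (cohort generation, panel, calling,
classification, tabulation) is available as `run_pipeline()` with a YAML/
JSON config, or from a shell via `inst/scripts/pgt_pipeline.R`.

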