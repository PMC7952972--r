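---
title: "Methods: low-pass single-blastomere CNV analysis for day-3 PGT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-pass single-blastomere CNV analysis for day-3 PGT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgtcnv)
```

# Scope and model

`pgtcnv` analyses single-blastomere low-pass sequencing data for
preimplantation genetic testing in couples carrying structural chromosomal
rearrangements. The data regime it targets is MALBAC whole-genome
amplification followed by shallow sequencing: roughly three million valid
single-end 55 bp reads per cell, about 0.04x genome-wide depth, read counts
binned at 1 Mb. At this depth the only usable signal is read depth: a gain
from two to three copies raises the affected bins' expected counts by 50%,
a loss from two copies to one lowers them by 50%, and intermediate shifts
are read as mosaic fractions. B-allele frequencies are not available, so
polyploidy and haploidy (uniform-ratio genomes) are undetectable by design;
this is a documented limitation, not an oversight.

The pipeline has five analysis stages — QC, normalization against a
reference panel, segmentation, copy-number/mosaic calling, and embryo
classification — plus a meiotic segregation model used both to interpret
results (which imbalances a carrier couple is expected to produce) and to
generate synthetic cohorts with known truth.

# The cytogenetic frame

Karyotypes enter as ISCN strings restricted to the constructs that occur in
PGT-SR referrals: `t(A;B)(p/q..;p/q..)`, `rob(A;B)(q10;q10)` (also written
`der(..)(q10;q10)`), `inv`, `del`, `dup`, and `ins`. Anything else raises
an explicit "unsupported" error; a malformed body of a supported construct
raises a parse error naming the token. Silent misparses are worse than
honest failures in a clinical-style pipeline.

Band names are resolved against a bundled band map
(`inst/extdata/cytoband_hg19_synthetic.tsv`). Its chromosome lengths and
centromere positions are the standard hg19 values; its band *names* are the
standard ISCN band lists (sub-band resolution where the package needs it,
e.g. 21q22.1-q22.3, Xp22.1-p22.33); its band *widths* are spaced uniformly
within each arm. The file is labelled synthetic because measured band
boundaries are not bundled: no published table ties the analysed cases to a
stated genome build, so the map is a declared coordinate convention, not a
claim about any particular reference. All results that depend on absolute
coordinates (for example, that a 4.6 Mb deletion fits inside 21q22.3) are
self-consistent within this frame. A breakpoint named only at band
resolution is placed at the band midpoint; a sub-band missing from the map
falls back to its parent band. Coordinates are 0-based half-open
throughout, matching the BED-like bin files.

# Meiotic segregation model

For a reciprocal translocation, carriers form a quadrivalent of four
elements (the two normal homologues and the two derivatives). The package
enumerates 2:2 segregations (alternate, adjacent-1, adjacent-2), 3:1
segregations (eight products), and 4:0 segregations. Two counting
conventions are implemented and deliberately not reconciled:

* **18-class counting (default).** The three 2:2 modes contribute two
  classes each, 3:1 contributes eight, and 4:0 contributes four — the two
  4:0 products listed once per division orientation. Balanced mass is
  2/18 = 1/9 per carrier, so a couple of two independent reciprocal
  carriers has a theoretical euploidy probability of exactly 1/81. The
  computation is carried in integer arithmetic
  (`couple_euploid_probability()` returns an exact numerator/denominator).
* **16-class counting** (`convention = "classes16"`). Distinct gamete
  compositions only; balanced mass 1/8 per carrier.

Counselling texts differ on which counting they use; the default was chosen
to match the per-couple figure quoted in day-3 PGT practice, and the
alternative is one flag away.

Robertsonian carriers form a trivalent: eight gamete classes (alternate
normal/balanced, four adjacent, two 3:0), two balanced. The derivative is
modelled as carrying the full dosage-relevant content of both acrocentrics:
the lost short arms are satellite/stalk material with no reliable read-depth
signal, so rob-derived imbalances are treated as whole-chromosome events —
which is also how they are reported clinically.

Inversion carriers yield two balanced non-recombinant classes and two
recombinant classes; a pericentric recombinant is a duplication of one
flank plus a deletion of the other, while paracentric recombinants are
acentric/dicentric and flagged nonviable (excluded from zygote formation by
default). Deletion/duplication carriers transmit the normal or the carried
homolog (1/2 each); insertion carriers additionally produce
segment-duplication and segment-deletion recombinants.

Weights: the `"theoretical"` set is uniform over classes (this is what
"theoretically 1/81" means); the `"realistic"` set, used as the simulator
default, skews mass toward alternate segregation — reciprocal
.45/.30/.10/.12/.03 over alternate/adjacent-1/adjacent-2/3:1/4:0, Robertsonian
.85/.13/.02, inversion recombination probability 0.2. These are one-time
choices in the range reported for sperm-FISH and PGT segregation studies;
they shape the simulated cohort composition but no numerical acceptance
check depends on them.

# Synthetic data generator

`simulate_blastomere_counts()` draws per-bin counts with expectation
proportional to (local copy number / 2) x GC bias x reads/bins:

* **Noise**: negative binomial with dispersion alpha = 0.02
  (variance mu + alpha mu^2), the standard overdispersed count model; the
  Poisson limit is used when alpha = 0, and `noiseless = TRUE` returns
  exact expectations for threshold-scan tests. At ~970 reads per 1 Mb bin
  this gives a bin-ratio CV of ~0.15 and a MAPD of ~0.14, inside the range
  reported for MALBAC single cells at this bin size.
* **GC bias**: multiplicative log-quadratic, `exp(b1*g + b2*g^2)` with
  `g = gc - 0.40` and defaults (-0.8, -8); smooth and invertible so a
  correct pipeline can remove it. Bin GC values come from a spatially
  correlated AR(1) model clipped to [0.30, 0.60].
* **Dropout**: 1% of bins are zeroed (MALBAC locus dropout); the
  expectation is rescaled so the configured read budget is met in
  expectation.
* **Whole-sample failure** (probability 0.057): emulated in-band as extreme
  dispersion (alpha = 5) plus 50% dropout rather than as a missing file, so
  the QC stage is exercised by failures exactly as often as the study's
  no-result rate.

`simulate_embryo()` composes: one gamete per parent drawn by segregation
weights; de novo meiotic whole-chromosome aneuploidies with Poisson mean
0.9 and per-chromosome weights peaked at chromosomes 22, 19, 21 and 16 (the
common hotspot order); a chaotic-embryo channel (probability 0.12, adding
4-8 aneuploidies) feeding the multiple-aneuploidy category; and one mitotic
mosaic event with probability 0.2 and fraction uniform on [0.2, 1]. The
rates were chosen once so that a no-rearrangement couple produces roughly
30% fully normal embryos, matching the day-3 cleavage-stage literature;
they are configuration, not calibration against any test.

Truth labels are produced by applying the *classifier's own rules* to the
true event list. This matters for identifiability: a de novo trisomy 13 in
a rob(13;14) family is indistinguishable from an adjacent-segregation
product at the signal level, so truth and pipeline agree to call it
parental-related rather than scoring a phantom error.

What the generator does **not** emulate: real MALBAC waviness beyond the
smooth GC model, chimerism between biopsied cells, segmental de novo
events (only whole-chromosome de novo events are drawn), and read-level
artefacts (no FASTQ, no alignment). Passing tests therefore demonstrate
correct behaviour under a faithful but idealized noise model, not
performance on any particular sequencer's output.

# QC, normalization, calling

**QC.** A sample is informative iff its usable reads reach 100 per bin on
average and its MAPD (median absolute pairwise difference of neighbouring
autosomal bin ratios) is at most 0.35. Simulated failures exceed this by an
order of magnitude; the thresholds are declared defaults, since the
original no-result criteria are not published.

**Reference panel.** Per-bin factor = median across euploid samples of
(count / sample autosomal median), rescaled to autosomal median 1; bins
with factor < 0.1 are masked. The panel absorbs the shared GC bias.

**Normalization** (`normalize_counts()`), in order: (1) counts are scaled
by a diploid baseline taken as the *median of per-autosome medians* — on a
reduced genome a whole-chromosome trisomy is a third of all bins, and a
plain global median would be contaminated; (2) division by the panel
factor; (3) zero-count runs of at most two bins are masked as dropout (a true
homozygous loss of 1-2 Mb is below the detection floor at 0.04x, while
dropout runs of that length are common enough to masquerade as nullisomy); (4) residual GC correction by 2%-wide GC strata, with three
robustness rules: stratum factors are estimated only from diploid-looking
bins of *other* chromosomes (leave-one-chromosome-out, so an aneuploid
chromosome is corrected symmetrically with a diploid one and never absorbs
its own signal), a stratum needs at least 30 reference bins before its
factor is applied, and all applied factors are normalized to their median
so the correction is mean-neutral (an exact no-op on a bias-free profile);
(5) rescaling to diploid level using a two-pass estimator — a
median-of-chromosome-medians pilot flags aneuploid-looking chromosomes
(outside 0.85-1.15), then the remaining chromosome medians are averaged.
The two-pass form matters on small genomes: with one trisomic chromosome
out of three, the pilot median alone equals the larger of the two normal
chromosome medians and is biased high.

Sex is inferred before any X/Y expectation is applied: XY samples show a
median X ratio near 0.5 and Y above 0.25, XX samples a Y ratio near zero.
Y absence in an XX sample is not an event.

**Segmentation.** Per chromosome, recursive splitting driven by the
two-sided mean-shift statistic of a candidate *interval* against the rest
of the segment, maximized over all sub-intervals (the CBS-style form): for
interval mean m1 over n1 bins against m0 over n0, t = |m1 - m0| / (s *
sqrt(1/n1 + 1/n0)), with s a robust per-chromosome scale (MAPD/1.349*sqrt(2),
floored at 0.01 so noiseless input is handled). The interval form is
essential: a single binary split cannot detect a short interior event (a
5-bin dip in a 48-bin chromosome never reaches a usable single-split
statistic at study noise). A split is accepted at t > 5 with a minimum
shift of 0.1; boundaries are then refined by reassigning boundary-adjacent
bins to the nearer segment mean, and adjacent segments closer than 0.1 are
re-merged. On noiseless input the result equals the exhaustive changepoint
oracle (tested on all instances up to 50 bins in the suite).

**Calling.** Continuous copy number c = 2 x mean ratio against the
sex-adjusted expectation. |c - expected| >= 0.8 is a full aneuploidy
(integer call round(c)); 0.4 < |c - expected| < 0.8 is a mosaic event with
fraction f = |c - expected|; at or below 0.4 no call (the strict "> 40%"
transfer rule; an epsilon guards the exact boundary against floating-point
residue). Whether the published "mosaic rate" is exactly |c - 2| x 100% is
an inference from the copy-number wording; it is implemented as a declared
convention. The minimum reported event is 3 bins, overridden for 1-bin
events at amplitude >= 0.8 ("up to 1 Mb resolution" is honoured as a
configurable limit, not a promise of single-bin sensitivity at default
noise). A segment covering >= 90% of its chromosome's usable bins is
flagged whole-chromosome.

# Classification and transfer policy

The expected-imbalance catalogue is the union over both parents of the
zygote-level profiles of all unbalanced, viable gamete classes; a carried
deletion/duplication enters the catalogue directly, so an inherited
microdeletion is matched as parental-related. A called event is **related**
iff a catalogue entry has the same sign on the same chromosome and either
both are whole-chromosome scale (Robertsonian-type products) or the event
is segmental with a non-centromeric breakpoint within 5 Mb of a catalogue
breakpoint and reciprocal overlap at least 0.5. Band-level breakpoints are
imprecise at megabase scale, hence the 5 Mb default; both knobs are
configurable, and matching is monotone in the tolerance. How events on a
rearranged chromosome but far from the breakpoints were handled in the
original analysis is unknown; the distance rule is this package's
convention.

Categories: Type I related-only, Type II de novo-only, Type III both,
Type IV multiple aneuploidy of chromosomes (MAC), Type V normal/balanced.
MAC is defined here as abnormal events on >= 3 distinct chromosomes and
overrides I-III; no numerical MAC definition is published, so the threshold
is configurable. Mosaic events above the 40% rule are counted inside their
I-IV category by event identity (whether the original analysis counted
mosaics inside the types or separately is unstated; this is a declared
convention) and always block transfer: an embryo is transferable iff it is
Type V. Non-informative samples are excluded from all rates, mirroring the
informative-denominator style of the published tables.

# Cohort statistics

Rates are formatted `x.y(n/d)` with one decimal so tabulated output can be
compared against printed tables character-for-character. Chi-square is
Pearson without continuity correction; Fisher's exact is the two-sided
hypergeometric sum; `compare_counts()` switches to Fisher when an expected
cell is below 5. No multiple-testing adjustment is applied, matching
per-comparison reporting. Clinical outcome definitions: implantation =
gestational sacs per embryo transferred; clinical pregnancy, live birth and
early miscarriage are per transfer cycle.

The bundled fixtures encode the published per-rearrangement classification
counts and a per-cycle transfer table solved exactly from the published
single/double-embryo-transfer marginals; the small mixed "Other" carrier
group's within-row type split is a reconstruction (marked in the file) used
only to complete cohort totals.

# Problem sizes and numerical choices in the test suite

The suite exercises two genome scales: a reduced synthetic genome (3-4
identical 50 Mb chromosomes, ~150-200 bins, read budget scaled to keep
~970 reads/bin) for linearity, mosaic-policy and property tests, and the
full bundled genome (~3,100 bins) for segmental detection, sex inference
and the end-to-end cohort. The end-to-end recovery check runs 200 embryos
per rearrangement group at low dispersion (alpha = 0.002) and requires at
least 95% agreement between pipeline and truth categories; the segmental
check simulates ten replicates of a 4.6 Mb one-copy loss centred in
21q22.3 and requires the called size within one bin in at least nine.
These sizes were chosen as the smallest at which the checked quantities are
statistically stable.

# Known limitations

* Depth-only signal: polyploidy/haploidy invisible; mosaic fractions near
  the 40% boundary are assigned by a point estimate and can flip under
  noise.
* At the default dispersion, short (2-6 bin) noise clusters in the mosaic
  amplitude range are called in roughly one in six euploid samples, even
  after dropout masking and single-bin spike trimming. This mirrors the
  recognized excess of segmental/mosaic findings in single-blastomere
  low-pass data; lower dispersion or a higher segmentation threshold
  suppresses them, at the cost of sensitivity to short true events.
* Band-midpoint breakpoints and uniform band widths: absolute coordinates
  are conventional; only self-consistent within the bundled map.
* Whole-chromosome de novo model: segmental de novo events are not
  simulated, so classifier performance on them is only covered via
  parental-type segmental products.
* The 18-class reciprocal counting is one of two defensible conventions;
  both are implemented, and the exact-rational couple probability makes the
  choice auditable.
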