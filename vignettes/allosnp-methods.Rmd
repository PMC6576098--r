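---
title: "Models and methods behind allosnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind allosnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allosnp)
```

`allosnp` packages the computational backbone of a genome-wide SNP array
study in an allopolyploid crop system: marker selection from variant
calls, cross-species genotyping QC, diversity analytics, subgenome
assignment and linkage statistics, all exercisable on a built-in
synthetic-data generator. This vignette records the models, the
parameters that matter, and the numerical conventions, so that every
design choice is inspectable.

## The biological setting

An allotetraploid species carries two diploid subgenomes (here "A-like"
and "B-like") contributed by two progenitor species. On a biallelic
assay, a fixed difference between the subgenomes produces *fixed
heterozygosity*: every individual appears heterozygous although no
allelic variation segregates. A *dihaploid* — a plant with a single
haplotype per subgenome — is the key instrument: it has no
within-subgenome variation, so any heterozygous call in the dihaploid
flags a homeologous (inter-subgenome) position, and its homozygous calls
mark positions usable as ordinary codominant markers.

## The synthetic-data generator

The generator (`sim_config()` + `simulate_study()`) emulates the panel
structure such studies use. Its defaults are the study conditions, not
tuning knobs.

**Genome.** Eleven anchored pseudo-chromosomes (default 0.5 Mb each for
test-scale runs) plus a virtual unanchored pseudo-chromosome "0"
excluded from density and LD summaries. Genes are placed without
overlap at a target genic fraction (default 0.4, matching arrays that
put ~40% of markers in genes); gene lengths are gamma-distributed around
3 kb and uniform gaps spread them over the chromosome, so the realized
genic fraction is exact up to per-gene rounding.

**Species A (structured outcrosser).** Each locus has an ancestral
frequency `p ~ U(0.05, 0.95)`; each of the eight genetic groups draws
its frequency from the Balding–Nichols distribution
`Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_a` (default 0.2). This
one-parameter hierarchical model produces the discrete,
well-differentiated group structure that a diversity panel of an
outcrossing crop shows, and a Hudson-type estimator applied to two
simulated groups recovers `F` directly (tested at ±0.05).

**Linkage disequilibrium.** Haplotypes are *not* drawn independently per
locus: a standard-normal AR(1) process runs along each chromosome with
lag correlation `exp(-d / ld_corr_bp)` between loci `d` bp apart, and
allele *i* is 1 when `pnorm(z_i) < freq_i`. The probability-integral
transform keeps every locus exactly Bernoulli(freq), so group
differentiation is unaffected, while neighbouring loci are correlated
and pairwise r² decays smoothly with distance. The default scale
(6 kb) puts the realized half-decay of a multi-group discovery panel on
the order of 10 kb, as observed in outcrossing perennial crops; because
the panel mixes groups, a constant admixture-LD baseline remains, which
is why the half-decay summary is defined relative to the maximum binned
mean (below). This is a phenomenological LD model: it reproduces decay
with distance, not coalescent haplotype block structure.

**Species B (low-diversity diploid).** Most loci are fixed (the fixed
allele is drawn with the ancestral frequency, which creates
inter-species divergent sites); a locus stays polymorphic with
probability `diversity_b` (default 0.05, giving a polymorphism rate of
a few percent in a six-individual panel, as seen for narrow-range wild
congeners).

**Allotetraploid and dihaploid.** Each tetraploid unites two haplotypes
from one species-A group (the *donor group*) and two from species B; the
reported call collapses the four copies to `{0, het, 2}`. At loci
divergently fixed between the pools this yields 100% heterozygosity —
the fixed-heterozygosity signature — and the dihaploid (one haplotype
per pool) is heterozygous exactly where its two haplotypes differ.

**Subgenome-specific assays.** With fully collapsed calls, a locus can
show two accessions homozygous for different alleles only if *both*
subgenomes are polymorphic there — essentially never. Real assays and
read mapping recover within-subgenome dosage because many probes/reads
are subgenome-specific: at diverged positions, material from the other
subgenome fails to hybridize or map. The generator models this with
`specific_a_fraction` (default 0.25): that fraction of loci reports only
the A-subgenome dosage in tetraploid-species samples (the dihaploid's
single A haplotype then reads as homozygous). This is the mechanism
that makes dihaploid-filtered codominant marker discovery possible, and
it is the main idealization to keep in mind: specificity is assigned
per locus at random, not from sequence divergence.

**Mapping progenies.** Gametes are generated per chromosome by a Markov
walk over the locus sequence: between adjacent loci at genetic distance
`d` cM the gamete switches parental haplotype with probability
`kosambi_r(d) = 0.5·tanh(d/50)`. Two-point recombination fractions
between adjacent loci therefore match the Kosambi map function by
construction (a Poisson crossover process would instead give Haldane
fractions). The F1 pseudo-testcross unites one gamete from each parent
(default n = 93); the F2 design builds an F1 from the two founders and
selfs it (default n = 138). The F2 family is scored *family-calibrated
codominant*: where the founders' shared B-subgenome pair is homozygous
(or the assay is A-specific) the call is the segregating A-subgenome
dosage; where that pair is heterozygous every individual reads as a
constant heterozygote, i.e. a homeologous, non-segregating marker. Both
founders share one B-subgenome haplotype pair — a simplification
justified by species B's low diversity.

**Missingness** is uniform per call (default 3%); platform-style cluster
failures are out of scope. All randomness is keyed by
`(seed, stream, id)` sub-streams, so the same configuration yields
byte-identical FASTA/GFF3/VCF/TSV/JSON output, and adding samples never
perturbs existing draws.

## Array design

`basic_quality_filter()` keeps biallelic SNPs with QUAL strictly above
40 (the boundary fails) and no other variant call within 60 bp on either
side; the flank test runs against *all* input records, including ones
that themselves fail, since a rejected neighbouring variant still sits
in the probe sequence. Reference-sequence uniqueness screening is not
modelled. `subgenome_allelic_filter()` applies the dihaploid rule
(heterozygous-or-missing dihaploid calls are removed) plus the
requirement that at least two accessions are homozygous for different
alleles. `recurrence_filter()` needs the minor allele in at least two
distinct carriers (het or hom each count once). `spacing_selection()`
scans each chromosome left to right keeping loci at least 40 kb apart;
candidate-gene loci are force-included and exempt from spacing (trait
markers are wanted regardless of redundancy); to approach genic/
non-genic parity the scan prefers, within a one-window lookahead past
the spacing constraint, the first locus of the currently
under-represented class. The procedure is deterministic with ties
broken toward the lower coordinate; the achieved balance is reported,
not enforced exactly. `design_summary()` reports per-chromosome counts,
SNPs/Mb and mean adjacent spacing, excluding pseudo-chromosome "0" from
genome-wide means.

## Genotyping QC accounting

A call fails if its locus-level clustering score is below 0.6 or its
per-call score below 0.2 (scores equal to a threshold pass). A locus is
*scorable* in a panel when at least `scorable_min_fraction` (default
0.75 — the literature rarely quantifies "scorable", so this is explicit
and configurable) of its calls are non-missing, and *polymorphic* when
two dosage states appear among called samples. For the tetraploid
species, loci heterozygous in the dihaploid are homeologous, missing
ones are unusable, and only the remaining allelic candidates may count
as polymorphic. Percentages follow report conventions exactly:
scorable% of synthesized loci, polymorphic% and dihaploid-het% of
scorable loci, rounded half-up to one decimal — including the
convention that allelic polymorphism, although *counted* on the
allelic-candidate subset, is *expressed* as a percentage of all
scorable loci. Every summary is audited internally: percentages must
recompute from their counts.

## Diversity analytics

r² is the squared Pearson correlation of dosage vectors over jointly
called samples (composite LD on unphased genotypes; haplotype-EM r² is
out of scope). The LD filter is strict on both sides (MAF > 0.10,
missingness < 10%) and drops pseudo-chromosome "0". The decay curve
averages r² in 1-kb bins; the half-decay distance is where the binned
mean first drops to half the *maximum binned mean* (not r² at distance
zero, which is unobservable), linearly interpolated between straddling
bin midpoints and flagged as undefined when the curve never crosses.

Trees are neighbour-joining (Saitou–Nei, via ape) on Euclidean distances
over loci without missing data. Negative NJ branch lengths are clamped
to zero with the deficit moved to the adjacent edge. Support values
resample loci in consecutive blocks of 100 SNPs (the trailing partial
block is kept) with replacement up to the original block count — block
resampling respects LD between neighbouring markers, which ordinary
per-SNP bootstrap would break — and count each reference bipartition
across 100 replicate trees.

## Subgenome assignment

The haploid-downscaling IBS procedure mitigates the ambiguity of
heterozygous calls in the allotetraploid (which mix homeologous and
allelic heterozygosity): for each of `n_runs = 200` runs, every
heterozygous genotype — in queries *and* references (a query-only mode
exists) — is resolved to a random haploid allele; IBS distance is the
mismatch fraction over the shared complete-locus set; distances are
averaged over runs per query, then mean ± SD across queries are
reported per reference and per group (unweighted mean over the group's
individuals), ranked ascending. Admixed reference individuals are
excluded — a mixed-ancestry genotype is not a meaningful
single-population reference. Monte-Carlo error at 200 runs is below
0.01 on the averaged distances (seed-invariance is tested); with eight
groups at Fst 0.2 and ≥1000 shared loci the true donor group ranks
first in ≥95% of 50 seeded replicates.

## Linkage statistics

Distortion is tested by Pearson χ² against the Mendelian expectation of
the segregation type (1:1 for het×hom pseudo-testcross loci, 1:2:1
codominant), df = classes − 1, no continuity correction (progeny counts
are large). In the F2 design only founder-divergent loci (founders
homozygous for different alleles) are informative; a heterozygous
founder call in an allotetraploid is ambiguous and left unscored.
Two-point recombination fractions come from direct mismatch counts for
fully informative F1 pairs (phase chosen to give r ≤ 0.5) and from EM
over the ambiguous double-heterozygote class for codominant F2 pairs
(start r = 0.25, tolerance 1e−8, max 500 iterations; both phases fitted
and the higher likelihood kept), with LOD against r = 0.5. Markers with
zero observed recombinants (identical informative patterns up to a
phase flip) merge into unique map positions by transitive closure. Map
summaries report coverage, adjacent distances over all markers and over
unique positions (the unique-position mean is the primary figure — it
matches how published per-group means behave), the gap distribution and
the array-SNP share. Full multipoint ordering is out of scope; the
summaries consume simulator-truth or externally supplied orders.

## Numerical conventions and degenerate inputs

Rounding of printed percentages is half-up (`floor(x·10 + 0.5)/10`).
`kosambi_cm()` rejects r ≥ 0.5 (or caps at 0.499 with a warning in
batch mode). Empty catalogs give empty manifests; a single-marker
linkage group reports zero coverage and an undefined mean distance;
zero-variance locus pairs are skipped in r²; an all-monomorphic
distance set raises an error rather than returning a degenerate tree.
Seeds are 31-bit; every stochastic routine takes an explicit seed.

## What the tests do and do not show

The test suite validates the machinery against independent oracles
(exhaustive enumeration for the dihaploid filter, brute-force scans for
flanking/recurrence/annotation/IBS/cosegregation, closed forms for χ²
and Kosambi, planted additive trees for NJ, planted decay curves and
recombination fractions) and validates the *procedures* on synthetic
data whose ground truth is known. Test-scale problem sizes (0.5-Mb
chromosomes, 1000–2000 loci, 50 recovery replicates) are the package's
own choices to keep the suite fast. What passing tests do **not** show:
that real intensity-based cluster calling behaves like the collapsed
and subgenome-specific call model; that coalescent haplotype structure
matches the AR(1) LD model; or that real reference panels are free of
admixture beyond the declared flags. Conclusions about any real dataset
still require the usual QC of that dataset.
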