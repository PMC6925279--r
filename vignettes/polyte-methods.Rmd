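---
title: "Methods: TE insertion detection and cross-ploidy population genetics with polyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE insertion detection and cross-ploidy population genetics with polyte}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`polyte` implements a complete pipeline for studying non-reference
transposable element (TE) insertions in a mixed cohort of diploid and
autotetraploid individuals: calling insertions from split-read and
discordant-pair evidence in short-read alignments, describing the
resulting carrier-frequency landscape across genomic compartments, and
testing two competing explanations for a TE excess in tetraploids —
relaxed purifying selection under polysomic masking versus a
transposition burst at the time of genome duplication. Because cohorts
of hundreds of resequenced genomes are not portable, the package ships
a synthetic-data generator that produces every input the pipeline
consumes (reference genome, annotation, TE library, sample sheet,
per-individual alignments, expression matrix) together with the ground
truth, so that every stage can be validated against known answers.

# The detection model

A non-reference insertion leaves three read-level signatures in an
alignment against an insertion-free reference: reads soft-clipped at
the insertion breakpoint whose clipped tail matches a TE sequence;
read pairs with one mate on the flank and the other inside the TE
(unmapped against the reference, or mapped discordantly); and, in
non-carriers, uninterrupted read depth across the breakpoint.
Detection proceeds in five stages:

1. **Candidate extraction** (`extract_candidates`): soft-clips of at
   least `min_clip` (default 20 bp) become split candidates anchored at
   the clip position; the clip side records which boundary they
   support. Pairs with an unmapped mate, or mapped but not properly
   paired, become discordant candidates.
2. **TE assignment** (`assign_te`): the clipped tail (or unmapped
   mate) is matched against the TE family library in both orientations,
   requiring identity of at least `min_identity` (0.9) over at least
   `min_match` (15) bp; equal-best hits go to the first family in
   library order and are flagged ambiguous.
3. **Site definition** (`define_sites`): anchors of one family within
   `cluster_window` (100 bp) chain into one candidate site per
   individual. The two split-read boundary anchors bracket the
   target-site duplication (TSD), so the site interval is a few bp
   wide.
4. **Intersection and support filtering** (`intersect_sites`):
   per-individual sites of the same family that overlap are merged; a
   site survives only if at least one individual supports it with three
   or more reads including at least one upstream and one downstream
   junction read.
5. **State assignment** (`assign_states`): an individual is a carrier
   where its own evidence meets the same support rule. Otherwise its
   *negative coverage* — the minimum aligned depth over the two site
   boundaries — decides: within `[5, 100]` it is a confident
   non-carrier, outside that range (too little data, or a repetitive
   pile-up more than ten times the average depth) it is NA. Sites
   where the NA count exceeds the tolerance in *both* ploidy groups
   are non-informative and removed. We read the "both groups" rule
   conjunctively because that is its literal wording; a disjunctive
   switch (`na_rule = "or"`) is provided. The tolerance itself was
   calibrated for cohorts of roughly 100–180 individuals per ploidy
   (where it is 10), so the default scales as `ceiling(0.1 * group
   size)`.

Boundary inclusivity follows the literal reading of the rule: "less
than five" and "more than 100" exclude 4 and 101, so negative coverage
of exactly 5 or exactly 100 still supports a non-carrier call.
Zygosity is deliberately never inferred: at the coverages this design
targets, heterozygous and homozygous carriers cannot be separated from
positive and negative coverage, so all downstream analysis works with
carrier frequencies, not allele frequencies. The clip-length,
identity, and clustering parameters are not dictated by the biology;
the defaults above are strict enough for clean synthetic reads and are
all exposed as arguments.

# Hardy–Weinberg dosage math under polysomy

Carrier frequency $f$ (fraction of individuals with allele dosage at
least 1) and allele frequency $p$ are linked under Hardy–Weinberg
equilibrium by $(1-p)^k = 1-f$ for ploidy $k$. `hw_convert` inverts
this exactly, returns the binomial genotype-class probabilities, and
reports the fraction of carriers in the minimal-dosage class
(heterozygotes for $k=2$, simplex heterozygotes for $k=4$). At the
same carrier frequency, tetraploid allele frequencies are roughly
half the diploid ones, which is why cross-ploidy comparisons in this
package are always made on the carrier-frequency scale. A
spectrum-averaged variant (`hw_dosage1_spectrum`) weights the
per-frequency enumeration by the expected number of carriers; point
evaluation at a single boundary frequency and spectrum averaging give
slightly different numbers, and both are provided.

# Landscape statistics

Carrier frequency is computed over non-NA individuals only. The
low/high-frequency classes (LF/HF) are the 10th and 90th percentiles
of the *diploid* spectrum, computed with linear interpolation between
order statistics (no percentile rule is canonical; interpolation is
R's default type 7) and applied unchanged to tetraploids.

Each site is assigned exactly one genomic category with the priority
order 3'UTR > 5'UTR > exon > intron > upstream<250 bp >
downstream<250 bp, then near-gene (<2 kb) and intergenic by distance;
outside genes, every base is attributed to its closest gene (ties to
the leftmost), which resolves sites lying between two genes. The same
single partition of the genome drives three things — the synthetic
generator's insertion placement, site classification, and the
whole-genome category footprint used as the expectation in proportion
tests — so they cannot drift apart. The footprint can be weighted by
a mappability/coverage track (mean depth in 10-kb windows of a
high-coverage alignment) to correct for unequally detectable
territory.

Densities are counted in 100-kb windows and smoothed with LOWESS
(tricube, span 0.1, one robustness iteration) strictly for plotting;
statistics always use raw counts. The arm/pericentromere split uses
the insertion midpoint and a distance threshold from the centromere
midpoint (5 Mb at full genome scale; on the 10-Mb synthetic
chromosomes the pipeline scales it to the configured pericentromere
half-width, 1 Mb). The distance-to-gene comparison bootstraps the
median distance (1000 resamples; the mean is available by flag) and
compares cohorts with a two-sided t-test.

# Content models and burst tests

Per-individual TE content is stratified by category group (non-genic;
introns and UTRs; exonic) and/or frequency class, with haplo-coverage
(sequencing depth per haploid genome — coverage divided by ploidy) as
the detection-sensitivity covariate. `fit_stepwise_mlm` selects terms
bidirectionally by the p-value of the F-test on the change in residual
sum of squares (enter below 0.05, leave above 0.10 — classical
defaults, the source procedure states none), respects model hierarchy,
and logs a full selection trace. Coefficients are reported with 95%
confidence intervals and t-statistic p-values.

`subsampled_content` draws 100 subsamples of 100 individuals per
ploidy (scaled down with a warning when a cohort is smaller) and
compares strata with two-sided Welch t-tests across subsample means
(pooled-variance by flag). Because subsamples are drawn from one
finite cohort, these t-tests inherit the pseudo-replication of the
original design: they are extremely sensitive to any realized cohort
difference. We therefore treat them as descriptive; where a class is
expected to show *no* ploidy effect, the package's validation uses a
ploidy-label permutation null of the per-capita content difference
(classification included), which is properly calibrated at any
stratum size. Frequency classes in content comparisons are
cohort-specific: the diploid-derived thresholds are applied to each
cohort's own carrier frequencies, so a site can be LF in tetraploids
while mid-frequency in diploids.

`burst_family_test` restricts to families with more than 10
non-reference copies in each ploidy group (strictly more, i.e. at
least 11) and contrasts the proportion of high-frequency non-genic
insertions between ploidies with a 2x2 chi-square per family. Raw
p-values mirror the original analysis; a Benjamini–Hochberg column is
always attached. A family is "flagged" only for a significant excess
*in the tetraploids*, the direction a WGD-associated burst predicts.

# Clade analysis and expression

`classify_by_clade` marks sites whose carriers all fall in one clade
as clade-specific (private with one carrier, shared with two or more)
and flags locally high-frequency insertions (HF3: three or more
carriers within the clade). The HF3 proportion is contrasted between
ploidies within three compartments (intergenic, within-or-near genes
at <250 bp, and within-or-near a designated gene class such as
stimulus-response genes); the gene class is a user-supplied table, and
enrichment of any gene class is tested with a local hypergeometric
test plus an optional length-matched resampling null (10,000 draws
matched on target length deciles) to control for the longer length of
some gene classes. Both normalizations of the clade-specific classes
(over clade-specific sites, and over all sites) are emitted, since
either denominator is defensible.

`cnc_ratios` compares mean expression between carrier populations (at
least one member carries the gene's nearest insertion) and
non-carrier populations, per gene, for the near-genic (<250 bp) and
intergenic (>2 kb) tiers. The input matrix is taken as already
normalized — the package does not impose a normalization — and ratios
are analysed as log2 internally to symmetrize. The near-genic ratio
distribution is tested against a random relabelling null and against
the intergenic tier with two-sample KS tests.

# The synthetic-data generator

The generator is first-class, tested code. Its defaults define the
study conditions:

* **Genome**: 2 chromosomes of 10 Mb, centromere at the midpoint,
  pericentromere ±1 Mb; 400 genes placed with an 8:1 arm:pericentromere
  density ratio and 300 annotated reference TEs at the inverse
  contrast, mirroring gene-dense arms and TE-dense pericentromeres.
  Counts per compartment are allocated deterministically (rounded
  expectation), positions uniformly by stick-breaking, so the
  configured density ratio is honored up to rounding noise.
* **Cohort**: 20 diploids and 20 tetraploids in four clades of two
  populations each; per-individual coverage uniform on 3–14X (mean
  ≈8.5X, matching resequencing depths of roughly 3–18X averaging
  ~8X). Desk-scale validation runs fix coverage at 8X.
* **Insertions**: eight superfamilies (two families each), 25
  insertions per superfamily by default; type A superfamilies (Copia,
  Gypsy, CACTA, hAT) lean genic in their category preferences, type B
  (LINE, Mariner, MuDR, Harbinger) lean intergenic. TSD length
  defaults to 5 bp (the value observed for Copia-type insertions),
  overridable per superfamily. TE lengths are 400–1200 bp (a solo-LTR
  is ~442 bp), kept at least twice the read length so no read spans
  two junctions.
* **Frequencies**: each insertion draws a *carrier* frequency from
  Beta(0.3, 5) — strongly low-frequency-skewed, as site-frequency
  spectra are — shared across ploidies, and the cohort allele
  frequency follows by the Hardy–Weinberg inversion. This makes the
  two ploidies' carrier-frequency spectra identical under neutrality,
  which is the empirical observation the cross-ploidy comparisons
  rest on. `selection_mode = "purifying"` removes each genic or
  near-genic (<250 bp) insertion with probability 0.7;
  `"relaxed_in_4x"` lets those purged insertions persist in
  tetraploids with probability 0.9 as *young* copies at 0.3 times
  their base frequency. The young-copy model encodes the mechanism
  under test: insertions sheltered by polysomy are recent and
  therefore still rare, so the tetraploid excess concentrates in the
  LF class while the HF class, fed by old shared insertions, stays
  comparable. No quantitative magnitude for this release is
  observable, so all three parameters are explicit configuration.
* **Reads**: error-free 100-bp paired-end reads (insert 300±30 bp) at
  full per-haplotype coverage within ±300 bp of each planted
  breakpoint; carrier haplotypes contribute soft-clipped junction
  reads whose clips are genuine TE library sequence, discordant pairs
  whose TE-internal mate is emitted as an unmapped record, and a
  duplicated TSD. Reads far from every breakpoint cannot contribute
  junction evidence or boundary depth, so genome-wide background is
  off by default (`background_coverage` enables it); this is purely a
  cost choice and changes no computed statistic. Sequencing errors
  are available (`error_rate`) but default to zero: the synthetic data
  test detection logic, not aligner robustness. Fragments falling
  entirely inside the TE are not emitted; against the reference they
  could never anchor evidence at the site.
* **Expression**: log-normal baselines; a carried insertion within a
  gene or <250 bp multiplies expression by 0.5 (cis effects are mostly
  negative); insertions ≥2 kb away have no effect, making the
  intergenic tier an internal negative control.

Determinism: one master seed yields derived per-stage streams, so the
same configuration reproduces every file byte for byte. What the
generator does *not* emulate: sequencing error profiles, indels,
mappability biases, reference-TE polymorphism, linkage between sites,
and population structure beyond discrete clades. Passing tests on
synthetic data therefore demonstrate the correctness of the
*machinery* — the filters, the estimators, the direction of recovered
effects — not calling performance on real short reads.

# Problem sizes and numerical choices

Validation runs use the 2×10 Mb genome with 40 individuals and 200
insertions for detection (recall and false discovery against truth,
with truth-aware matching within 100 bp), 300 individuals for
Hardy–Weinberg convergence checks, 1000 synthetic null families for
the burst test's type-I calibration, 100 seeded read sets for the
locus genotyper, and — for the selection-regime recovery, which is
run on the planted truth without read simulation — 1200 insertions
across 300 individuals with a relaxed 300-bp breakpoint spacing, so
that the frequency-class strata carry enough sites for calibrated
comparisons. These sizes give stable statistics at desk scale.
Degenerate inputs are rejected loudly: an all-NA site is excluded with
a warning, a degenerate frequency spectrum (equal percentiles) is an
error, bootstraps require at least 100 resamples and two sites per
cohort, subsampling requires at least two replicates, and chi-square
tests are skipped when an expected cell falls below 1. Ties in TE
assignment go to library order (flagged), and interaction terms are
matched canonically so that `a:b` and `b:a` are one term.

# The targeted locus genotyper

For a known insertion allele (e.g. a solo-LTR in an exon of a
flowering-time gene), `call_locus` re-maps reads against two local
references — with and without the insertion — and calls a carrier on
a single read bridging an insertion extremity with at least 20
aligned bases on *each* side (the stricter of the two literal
readings; per-extremity evidence is pooled), a non-carrier on zero
bridging reads plus at least four reads spanning the full TSD with a
base to spare on each side, and NA otherwise. With error-free reads a
carrier/non-carrier confusion is structurally impossible — a read
cannot match both allele references across the junction — so miscalls
measure implementation faults, not sampling noise; NA calls at low
coverage are expected and are not miscalls.

# Pipeline

`run_pipeline` chains simulate → detect → landscape → stats → clades →
expression, writes one directory per stage plus a resolved
configuration snapshot and a run log, and re-runs a stage (and
everything downstream) only when its parameters changed or its
outputs are missing. All tables share one TSV dialect: tab-separated,
UTF-8, `.` decimal, one `#`-prefixed header line. Coordinates are
1-based inclusive in GFF3 and site tables, 0-based half-open in BED.
The exported functions and this pipeline are the package's interface;
they are designed to be driven from R scripts.

# Known limitations

Detection requires the TE library to contain the active families;
insertions of unknown families are dropped at assignment. Discordant
anchors use the mate's proximal alignment end, which sits up to an
insert length from the junction; with the default 100-bp clustering
window some discordant evidence lands outside its site and is simply
ignored (junction reads carry the calls). The negative-coverage upper
bound assumes roughly uniform coverage; CNVs would masquerade as NA.
The burst test treats sites shared between ploidies as independent
observations in its 2x2 table, which makes it conservative when the
same sites feed both margins. Finally, the expression analysis cannot
separate insertion effects from insertion preferences for
differentially expressed haplotypes; it reports associations.
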