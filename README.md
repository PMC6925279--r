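# polyte

Detection and cross-ploidy population genetics of non-reference
transposable element (TE) insertions.

## The problem

Whole-genome duplication creates autopolyploids in which every locus is
carried in four copies with tetrasomic segregation. Polysomy shelters
recessive deleterious alleles — including TE insertions in and around
genes — from purifying selection, so autotetraploids are predicted to
accumulate genic TE insertions faster than their diploid relatives. The
competing explanation for any TE excess after genome duplication is a
transposition burst ("genomic shock"). Distinguishing the two requires
calling non-reference TE insertions across hundreds of short-read
genomes of mixed ploidy and comparing where in the genome, and at what
population frequencies, the insertions sit: relaxed selection predicts
a tetraploid excess of *low-frequency, genic* (especially exonic)
insertions, while a burst predicts an excess of *high-frequency,
non-genic* ones concentrated in specific TE families.

`polyte` implements that entire analysis for R users:

* **Detection** — split-read / discordant-pair calling of non-reference
  insertions from per-individual BAMs against a TE library: soft-clips
  ≥20 bp matched to TE families at ≥90% identity, per-individual sites
  clustered within 100 bp, retained when one individual has ≥3
  supporting reads including both an upstream and a downstream junction
  read; carrier / non-carrier / NA states per individual with the
  negative-coverage rule (confident absence needs 5–100× depth over
  both boundaries) and removal of sites with too many NA individuals in
  both ploidy groups.
* **Landscape** — carrier frequencies over non-NA individuals; LF/HF
  classes at the 10th/90th percentiles of the diploid spectrum (applied
  unchanged to tetraploids); one-category-per-site genomic
  classification with the priority order 3'UTR > 5'UTR > exon > intron
  > upstream<250 bp > downstream<250 bp and a closest-gene rule between
  genes; arm vs pericentromere fractions; 100-kb densities with LOWESS
  smoothing; coverage-weighted whole-genome category footprints;
  bootstrap distance-to-gene comparisons.
* **Statistics** — Hardy–Weinberg dosage math under polysomy
  (`(1-p)^ploidy = 1-f`); 2×2 χ² proportion tests; stepwise multiple
  linear models of TE content (haplo-coverage, ploidy, category,
  frequency class; F-tests on the change in residual sum of squares);
  ploidy comparisons over 100 subsamples of 100 individuals;
  family-level transposition-burst tests over families with >10 copies
  per ploidy group.
* **Clades** — clade-specific (private/shared) insertion classes,
  locally high-frequency insertions (HF3: ≥3 carriers in one clade),
  per-compartment ploidy contrasts, and hypergeometric gene-class
  enrichment with an optional length-matched null.
* **Expression** — carrier vs non-carrier population expression ratios
  per gene for near-genic (<250 bp) and intergenic (>2 kb) insertion
  tiers, with Kolmogorov–Smirnov tests against random-relabelling and
  intergenic nulls.
* **Targeted genotyping** — presence/absence calls for one known
  insertion from reads re-mapped to with/without-insertion references
  (carrier: ≥1 read bridging an insertion extremity by ≥20 bp on each
  side; non-carrier: no bridging read and ≥4 reads spanning the TSD).
* **Synthetic data** — a seeded generator producing the genome,
  annotation, TE library, cohort, alignments (SAM/BAM), expression
  matrix and the ground truth, so the whole pipeline is testable
  offline. See the methods vignette (`vignettes/polyte-methods.Rmd`)
  for the generative model and its deliberate simplifications.

## Worked example

Simulate a small cohort (12 diploids + 12 tetraploids at 8X on a
2×2 Mb genome), call insertions, and look at the results:

```r
library(polyte)

cfg <- sim_config(seed = 42, chrom_length = 2e6,
                  pericentromere_halfwidth = 3e5, n_genes = 120,
                  n_individuals_2x = 12, n_individuals_4x = 12,
                  coverage_range = c(8, 8))
genome <- simulate_genome(cfg)
truth  <- simulate_population(genome, cfg)
reads  <- simulate_reads(truth, genome, "run/alignments")
bams   <- vapply(reads$sam, sam_to_bam, character(1))
det    <- detect_insertions(bams, genome$te_library, truth$samples)

det$sites[1:3, c("site_id", "chrom", "start", "end", "family",
                 "carrier_freq", "name")]
#>      site_id  chrom  start    end     family carrier_freq        name
#> 1: site00001   chr1  21695  21769 Gypsy_fam1   0.08333333 Gypsy_new-1
#> 2: site00002   chr1 163330 163334 Gypsy_fam1   0.25000000 Gypsy_new-2
#> 3: site00003   chr1 204552 204556 Gypsy_fam2   0.33333333 Gypsy_new-3

table(det$states, useNA = "ifany")
#>    C    N <NA>
#>  176 1498    6
```

Each row is one retained insertion site: its breakpoint interval (the
few bases bracketing the duplicated target site), the TE family its
junction reads matched, and the carrier frequency over non-NA
individuals (site00002 is carried by 6 of 24). The state table counts
carrier (`C`), confident non-carrier (`N`) and missing-information
(`NA`) calls over all sites × individuals.

The Hardy–Weinberg layer converts between carrier and allele
frequency at either ploidy:

```r
hw_convert(f = 0.122, ploidy = 2)
#> HW 2x: f = 0.1220, p = 0.0630, dosage-1 carriers = 0.967
hw_convert(f = 0.122, ploidy = 4)
#> HW 4x: f = 0.1220, p = 0.0320, dosage-1 carriers = 0.952
```

A carrier frequency of 12.2% corresponds to an allele frequency of
6.3% in diploids but only 3.2% in tetraploids, and nearly all carriers
are minimal-dosage (heterozygous / simplex) — which is why the package
compares cohorts on the carrier-frequency scale.

`run_pipeline(cfg, "out/")` chains all stages (simulate → detect →
landscape → stats → clades → expression) into one output directory
with a resolved-configuration snapshot, per-stage TSV tables, and
resumable stage tracking.

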