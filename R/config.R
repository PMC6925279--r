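#' Configuration for the synthetic dataset generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genome()], [simulate_population()], [simulate_reads()] and
#' [simulate_expression()]. All defaults describe a desk-scale genome
#' (2 chromosomes of 10 Mb with a +/- 1 Mb pericentromere) carrying the
#' eight TE superfamilies, with diploid and autotetraploid clades sequenced
#' at realistic low coverage (uniform 3-14X, mean ~8.5X, emulating field
#' resequencing depths of roughly 3-18X).
#'
#' @param seed Integer master seed. Per-stage random streams are derived
#'   from it, so identical seed + configuration reproduce every output.
#' @param n_chromosomes,chrom_length Number of chromosomes and their length
#'   in bp (`chrom_length` is recycled across chromosomes).
#' @param centromere_pos Centromere midpoint per chromosome (bp); default
#'   chromosome midpoint.
#' @param pericentromere_halfwidth Half-width (bp) of the TE-dense,
#'   gene-poor pericentromeric compartment around each centromere.
#' @param centromere_width Width (bp) of the centromere interval written to
#'   BED.
#' @param n_genes Number of gene models.
#' @param gene_structure List of uniform ranges (bp) for gene anatomy:
#'   `n_exons`, `exon_len`, `intron_len`, `utr5_len`, `utr3_len`.
#' @param gene_arm_density_ratio Target ratio of per-bp gene density on
#'   chromosome arms over pericentromeres. Gene counts per compartment are
#'   allocated deterministically to hit this ratio up to rounding.
#' @param n_ref_tes,te_peri_density_ratio Annotated reference-TE features
#'   and their pericentromere/arm per-bp density ratio (TEs are denser
#'   around centromeres, mirroring real chromosome organisation).
#' @param n_individuals_2x,n_individuals_4x Cohort sizes for diploids and
#'   autotetraploids.
#' @param clades Data frame with columns `clade`, `ploidy`,
#'   `n_individuals`, `n_populations`; default two clades per ploidy with
#'   two populations each.
#' @param coverage_range Per-individual sequencing coverage (X), drawn
#'   uniformly.
#' @param read_length,insert_mean,insert_sd Read length and fragment-size
#'   distribution (bp) of the paired-end simulator.
#' @param read_window Half-width (bp) of the region around each planted
#'   breakpoint in which reads are generated at full coverage. Reads
#'   further away can never contribute junction evidence or boundary
#'   depth, so the simulator concentrates its effort there; set
#'   `background_coverage > 0` to add genome-wide background pairs.
#' @param background_coverage Coverage (X) of uniform genome-wide
#'   background read pairs (default 0).
#' @param error_rate Uniform per-base substitution rate of simulated reads
#'   (default 0: the detection logic, not aligner robustness, is what the
#'   synthetic data exercise).
#' @param te_superfamilies Named list, one entry per superfamily, each a
#'   list with `n_families`, `n_insertions`, `te_len_range`, `tsd_len` and
#'   `category_weights` (probabilities over
#'   `r paste(CATEGORY_LEVELS, collapse = ", ")`, summing to 1).
#'   Defaults give type A superfamilies a genic insertion preference and
#'   type B a mostly intergenic one.
#' @param spectrum_shape1,spectrum_shape2 Beta parameters of the
#'   carrier-frequency spectrum from which each insertion's carrier
#'   frequency `f` is drawn (a low-frequency-skewed Beta; no generative
#'   spectrum is observable in real cohorts). The cohort allele frequency
#'   is then `p = 1 - (1 - f)^(1/ploidy)`, so that under neutrality both
#'   ploidies share one carrier-frequency spectrum — allele frequencies
#'   are correspondingly about halved in tetraploids.
#' @param selection_mode One of `"neutral"`, `"purifying"`,
#'   `"relaxed_in_4x"`. Under `"purifying"`, a genic or near-genic
#'   (<250 bp) insertion escapes purging with probability `purify_retain`
#'   (otherwise it segregates in neither cohort). Under
#'   `"relaxed_in_4x"`, insertions purged from diploids additionally
#'   persist in tetraploids with probability `relaxed_retain` — as young,
#'   tetraploid-only insertions whose carrier frequency is scaled by
#'   `young_scale` (recent insertions sheltered by polysomy have not had
#'   time to rise in frequency), emulating polysomic masking.
#' @param purify_retain,relaxed_retain,young_scale Selection parameters
#'   (see above); defaults 0.3, 0.9, 0.3.
#' @param burst Optional list describing a family-specific transposition
#'   burst in tetraploids: `superfamily`, `n_insertions`, `freq_range`
#'   (carrier-frequency range of the burst copies, present in 4x only,
#'   all non-genic).
#' @param min_insertion_spacing Minimum distance (bp) between planted
#'   breakpoints, kept larger than the detection clustering window.
#' @param expression_effect Multiplicative cis effect on a gene's
#'   expression when an individual carries an insertion within the gene or
#'   closer than `expr_near_bp`; default 0.5 (effects are mostly
#'   negative). Insertions >=2 kb away have no effect.
#' @param expr_near_bp Distance (bp) defining "near-genic" for the
#'   expression effect (default 250).
#' @param expr_meanlog,expr_sdlog,expr_noise_sdlog Log-normal baseline
#'   expression parameters and per-individual log-normal noise.
#'
#' @return An object of class `sim_config` (a validated list, with derived
#'   per-stage seeds in `$stage_seeds`).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50, chrom_length = 1e6,
#'                   pericentromere_halfwidth = 2e5)
#' cfg$stage_seeds
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chrom_length = 1e7,
                       centromere_pos = NULL,
                       pericentromere_halfwidth = 1e6,
                       centromere_width = 1e5,
                       n_genes = 400L,
                       gene_structure = list(n_exons = c(2L, 6L),
                                             exon_len = c(150L, 400L),
                                             intron_len = c(80L, 300L),
                                             utr5_len = c(50L, 150L),
                                             utr3_len = c(100L, 250L)),
                       gene_arm_density_ratio = 8,
                       n_ref_tes = 300L,
                       te_peri_density_ratio = 8,
                       n_individuals_2x = 20L,
                       n_individuals_4x = 20L,
                       clades = NULL,
                       coverage_range = c(3, 14),
                       read_length = 100L,
                       insert_mean = 300,
                       insert_sd = 30,
                       read_window = 300L,
                       background_coverage = 0,
                       error_rate = 0,
                       te_superfamilies = NULL,
                       spectrum_shape1 = 0.3,
                       spectrum_shape2 = 5,
                       selection_mode = c("neutral", "purifying", "relaxed_in_4x"),
                       purify_retain = 0.3,
                       relaxed_retain = 0.9,
                       young_scale = 0.3,
                       burst = NULL,
                       min_insertion_spacing = 2000L,
                       expression_effect = 0.5,
                       expr_near_bp = 250L,
                       expr_meanlog = 3,
                       expr_sdlog = 1,
                       expr_noise_sdlog = 0.2) {
  selection_mode <- match.arg(selection_mode)
  chrom_length <- rep_len(as.numeric(chrom_length), n_chromosomes)
  if (is.null(centromere_pos)) centromere_pos <- round(chrom_length / 2)
  centromere_pos <- rep_len(as.numeric(centromere_pos), n_chromosomes)
  if (is.null(clades)) clades <- default_clades(n_individuals_2x, n_individuals_4x)
  if (is.null(te_superfamilies)) te_superfamilies <- default_superfamilies()

  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length,
              centromere_pos = centromere_pos,
              pericentromere_halfwidth = pericentromere_halfwidth,
              centromere_width = centromere_width,
              n_genes = as.integer(n_genes),
              gene_structure = gene_structure,
              gene_arm_density_ratio = gene_arm_density_ratio,
              n_ref_tes = as.integer(n_ref_tes),
              te_peri_density_ratio = te_peri_density_ratio,
              n_individuals_2x = as.integer(n_individuals_2x),
              n_individuals_4x = as.integer(n_individuals_4x),
              clades = clades,
              coverage_range = coverage_range,
              read_length = as.integer(read_length),
              insert_mean = insert_mean,
              insert_sd = insert_sd,
              read_window = as.integer(read_window),
              background_coverage = background_coverage,
              error_rate = error_rate,
              te_superfamilies = te_superfamilies,
              spectrum_shape1 = spectrum_shape1,
              spectrum_shape2 = spectrum_shape2,
              selection_mode = selection_mode,
              purify_retain = purify_retain,
              relaxed_retain = relaxed_retain,
              young_scale = young_scale,
              burst = burst,
              min_insertion_spacing = as.integer(min_insertion_spacing),
              expression_effect = expression_effect,
              expr_near_bp = as.integer(expr_near_bp),
              expr_meanlog = expr_meanlog,
              expr_sdlog = expr_sdlog,
              expr_noise_sdlog = expr_noise_sdlog)
  cfg$stage_seeds <- derive_stage_seeds(cfg$seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

default_clades <- function(n2, n4) {
  split2 <- c(ceiling(n2 / 2), floor(n2 / 2))
  split4 <- c(ceiling(n4 / 2), floor(n4 / 2))
  dt <- data.frame(clade = c("dip_A", "dip_B", "tet_A", "tet_B"),
                   ploidy = c(2L, 2L, 4L, 4L),
                   n_individuals = c(split2, split4),
                   n_populations = 2L,
                   stringsAsFactors = FALSE)
  dt[dt$n_individuals > 0L, , drop = FALSE]
}

default_superfamilies <- function() {
  # category preferences: type A superfamilies lean genic, type B intergenic
  w_a <- c(utr3 = 0.06, utr5 = 0.06, exon = 0.18, intron = 0.12,
           up250 = 0.08, down250 = 0.08, near2kb = 0.12, intergenic = 0.30)
  w_b <- c(utr3 = 0.02, utr5 = 0.02, exon = 0.04, intron = 0.06,
           up250 = 0.04, down250 = 0.04, near2kb = 0.13, intergenic = 0.65)
  out <- lapply(TE_SUPERFAMILIES, function(sf) {
    list(n_families = 2L,
         n_insertions = 25L,
         te_len_range = c(400L, 1200L),
         tsd_len = 5L,
         category_weights = if (sf %in% TYPE_A_SUPERFAMILIES) w_a else w_b)
  })
  names(out) <- TE_SUPERFAMILIES
  out
}

# one master seed, derived per-stage streams
derive_stage_seeds <- function(seed) {
  stages <- c("genome", "population", "reads", "expression", "locus", "pipeline")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(stages)), stages)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (any(cfg$chrom_length <= 0)) stop("chromosome lengths must be positive")
  if (any(cfg$centromere_pos <= 0 | cfg$centromere_pos >= cfg$chrom_length)) {
    stop("centromere_pos must lie within its chromosome")
  }
  if (cfg$read_length >= cfg$insert_mean - 2 * cfg$insert_sd) {
    stop("read length too large for the configured fragment length")
  }
  if (cfg$coverage_range[1] <= 0 || diff(cfg$coverage_range) < 0) {
    stop("coverage_range must be positive and non-decreasing")
  }
  for (sf in names(cfg$te_superfamilies)) {
    spec <- cfg$te_superfamilies[[sf]]
    w <- spec$category_weights
    if (!setequal(names(w), CATEGORY_LEVELS)) {
      stop("category_weights for ", sf, " must cover all categories")
    }
    if (abs(sum(w) - 1) > 1e-8) {
      stop("category_weights for ", sf, " must sum to 1")
    }
    if (any(w < 0)) stop("category_weights must be non-negative")
    if (spec$te_len_range[1] < 2L * cfg$read_length) {
      stop("TE length must be at least twice the read length")
    }
  }
  bad_sf <- setdiff(names(cfg$te_superfamilies), TE_SUPERFAMILIES)
  if (length(bad_sf) > 0L) stop("unknown superfamily: ", paste(bad_sf, collapse = ", "))
  if (!all(c("clade", "ploidy", "n_individuals", "n_populations") %in%
           names(cfg$clades))) {
    stop("clades needs columns clade, ploidy, n_individuals, n_populations")
  }
  if (!all(cfg$clades$ploidy %in% c(2L, 4L))) stop("ploidy must be 2 or 4")
  n2 <- sum(cfg$clades$n_individuals[cfg$clades$ploidy == 2L])
  n4 <- sum(cfg$clades$n_individuals[cfg$clades$ploidy == 4L])
  if (n2 != cfg$n_individuals_2x || n4 != cfg$n_individuals_4x) {
    stop("clade sizes must sum to n_individuals_2x / n_individuals_4x")
  }
  # rough footprint check: expected total gene span must fit on the arms
  gs <- cfg$gene_structure
  mean_gene <- mean(gs$utr5_len) + mean(gs$utr3_len) +
    mean(gs$n_exons) * mean(gs$exon_len) +
    (mean(gs$n_exons) - 1) * mean(gs$intron_len)
  arm_bp <- sum(cfg$chrom_length) - 2 * cfg$pericentromere_halfwidth *
    cfg$n_chromosomes
  if (cfg$n_genes * mean_gene > 0.6 * sum(cfg$chrom_length)) {
    stop("gene footprint exceeds chromosome capacity: reduce n_genes or gene sizes")
  }
  if (arm_bp <= 0) stop("pericentromere_halfwidth leaves no chromosome arms")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|", x$n_chromosomes, "chromosome(s) of",
      paste(format(x$chrom_length, scientific = FALSE), collapse = ", "),
      "bp\n")
  cat("  individuals: ", x$n_individuals_2x, " diploid + ",
      x$n_individuals_4x, " tetraploid in ", nrow(x$clades), " clades\n",
      sep = "")
  cat("  insertions:",
      sum(vapply(x$te_superfamilies, `[[`, integer(1), "n_insertions")),
      "across", length(x$te_superfamilies), "superfamilies; selection_mode =",
      x$selection_mode, "\n")
  invisible(x)
}

# run a block with a dedicated RNG stream, restoring the caller's stream
with_stage_seed <- function(cfg, stage, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(cfg$stage_seeds[[stage]])
  expr
}
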