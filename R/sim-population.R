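#' Simulate a population with planted TE insertions
#'
#' Draws a cohort of diploid and autotetraploid individuals organised in
#' clades and populations, plants non-reference TE insertions with
#' per-superfamily category preferences, and assigns per-individual allele
#' dosages under Hardy-Weinberg equilibrium: each insertion draws a
#' carrier frequency `f` from a Beta spectrum (shared across ploidies),
#' the cohort allele frequency is `p = 1 - (1 - f)^(1/ploidy)`, and each
#' individual's dosage is Binomial(ploidy, p). Under
#' `selection_mode = "relaxed_in_4x"`, genic and near-genic (<250 bp)
#' insertions purged from diploids persist in tetraploids as young
#' low-frequency copies, emulating polysomic masking of their deleterious
#' effects.
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param cfg Optional [sim_config()]; defaults to `genome$config`.
#' @return Object of class `sim_truth`: list with `insertions`
#'   (data.table: ins_id, chrom, pos, family, superfamily, type, te_len,
#'   tsd_len, category, p2, p4), `dosage` (integer matrix insertions x
#'   individuals), `samples` (data.table: id, population, clade, ploidy,
#'   coverage) and `partition` (the category partition used for
#'   placement).
#' @export
simulate_population <- function(genome, cfg = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  with_stage_seed(cfg, "population", {
    samples <- build_samples(cfg)
    partition <- category_partition(genome$annotation)
    ins <- plant_insertions(genome, cfg, partition)
    ins <- draw_frequencies(ins, cfg)
    dosage <- draw_dosages(ins, samples)
    structure(list(insertions = ins, dosage = dosage, samples = samples,
                   partition = partition, config = cfg),
              class = "sim_truth")
  })
}

build_samples <- function(cfg) {
  rows <- lapply(seq_len(nrow(cfg$clades)), function(i) {
    cl <- cfg$clades[i, ]
    pop <- sprintf("%s_p%d", cl$clade,
                   rep_len(seq_len(cl$n_populations), cl$n_individuals))
    data.table(id = sprintf("%s_i%03d", cl$clade, seq_len(cl$n_individuals)),
               population = pop, clade = cl$clade,
               ploidy = as.integer(cl$ploidy),
               coverage = round(runif(cl$n_individuals, cfg$coverage_range[1],
                                      cfg$coverage_range[2]), 2))
  })
  rbindlist(rows)
}

plant_insertions <- function(genome, cfg, partition) {
  fams <- genome$te_families
  margin <- cfg$read_window + cfg$insert_mean + 4 * cfg$insert_sd
  seqlens <- genome$annotation$seqlengths
  rows <- list()
  for (sf in names(cfg$te_superfamilies)) {
    spec <- cfg$te_superfamilies[[sf]]
    if (spec$n_insertions == 0L) next
    cats <- sample(CATEGORY_LEVELS, spec$n_insertions, replace = TRUE,
                   prob = spec$category_weights[CATEGORY_LEVELS])
    fam_pool <- fams[fams$superfamily == sf, ]
    fam <- fam_pool[sample.int(nrow(fam_pool), spec$n_insertions,
                               replace = TRUE), ]
    rows[[sf]] <- data.table(superfamily = sf, family = fam$family,
                             te_len = fam$length, tsd_len = fam$tsd_len,
                             category = cats, cohort = "both")
  }
  if (!is.null(cfg$burst)) {
    b <- cfg$burst
    fam_pool <- fams[fams$superfamily == b$superfamily, ]
    rows[["burst"]] <- data.table(superfamily = b$superfamily,
                                  family = fam_pool$family[1],
                                  te_len = fam_pool$length[1],
                                  tsd_len = fam_pool$tsd_len[1],
                                  category = "intergenic", cohort = "4x_only")
  }
  ins <- rbindlist(rows)
  if (!is.null(cfg$burst)) {
    ins <- rbind(ins[cohort == "both"],
                 ins[cohort == "4x_only"][rep(1L, cfg$burst$n_insertions)])
  }
  ins[, pos := sample_category_positions(category, partition, seqlens,
                                         margin, cfg$min_insertion_spacing)]
  ins[, chrom := attr(pos, "chrom")]
  ins[, pos := as.numeric(pos)]
  # the recorded category is re-derived from the breakpoint interval (the
  # duplicated target site) with the same priority rules the classifier
  # applies, so truth and classification agree by construction
  iv <- GRanges(ins$chrom, IRanges(ins$pos - ins$tsd_len + 1, ins$pos))
  ins[, category := classify_intervals(iv, partition)]
  setorder(ins, chrom, pos)
  ins[, ins_id := sprintf("ins%04d", .I)]
  ins[, type := selection_type(superfamily)]
  setcolorder(ins, c("ins_id", "chrom", "pos", "family", "superfamily",
                     "type", "te_len", "tsd_len", "category", "cohort"))
  ins[]
}

# draw one breakpoint base per requested category, respecting a margin
# from chromosome ends and a minimum spacing between breakpoints
sample_category_positions <- function(categories, partition, seqlens,
                                      margin, spacing) {
  pos <- numeric(length(categories))
  chrom <- character(length(categories))
  placed <- list()
  cat_part <- split(partition, mcols(partition)$category)
  for (i in seq_along(categories)) {
    gr <- cat_part[[categories[i]]]
    if (is.null(gr) || length(gr) == 0L) {
      stop("no genomic territory for category ", categories[i])
    }
    w <- as.numeric(width(gr))
    for (try in seq_len(200L)) {
      j <- sample.int(length(gr), 1L, prob = w)
      p <- start(gr)[j] + floor(runif(1) * w[j])
      ch <- as.character(seqnames(gr))[j]
      if (p < margin || p > seqlens[[ch]] - margin) next
      prev <- placed[[ch]]
      if (!is.null(prev) && any(abs(prev - p) < spacing)) next
      pos[i] <- p; chrom[i] <- ch
      placed[[ch]] <- c(prev, p)
      break
    }
    if (pos[i] == 0) stop("could not place insertion in category ",
                          categories[i], "; territory too small")
  }
  structure(pos, chrom = chrom)
}

# carrier-frequency spectrum shared across ploidies; selection modes act
# on genic/near-genic insertions by purging or sheltering them
draw_frequencies <- function(ins, cfg) {
  n <- nrow(ins)
  f0 <- pmin(rbeta(n, cfg$spectrum_shape1, cfg$spectrum_shape2), 0.99)
  genic_near <- ins$category %in% c(GENIC_CATEGORIES, NEAR_CATEGORIES)
  f2 <- f4 <- f0
  if (cfg$selection_mode %in% c("purifying", "relaxed_in_4x")) {
    purged <- genic_near & runif(n) > cfg$purify_retain
    f2[purged] <- 0
    f4[purged] <- 0
    if (cfg$selection_mode == "relaxed_in_4x") {
      # purged insertions persist in tetraploids as young, low-frequency
      # copies sheltered by polysomy
      young <- purged & runif(n) < cfg$relaxed_retain
      f4[young] <- f0[young] * cfg$young_scale
    }
  }
  ins[, f2 := f2]
  ins[, f4 := f4]
  if ("cohort" %in% names(ins) && any(ins$cohort == "4x_only")) {
    ins[cohort == "4x_only", f2 := 0]
    nb <- sum(ins$cohort == "4x_only")
    ins[cohort == "4x_only",
        f4 := runif(nb, cfg$burst$freq_range[1], cfg$burst$freq_range[2])]
  }
  # Hardy-Weinberg inversion of the carrier frequency at each ploidy
  ins[, p2 := 1 - (1 - f2)^(1 / 2)]
  ins[, p4 := 1 - (1 - f4)^(1 / 4)]
  ins[]
}

draw_dosages <- function(ins, samples) {
  n_ins <- nrow(ins)
  dos <- matrix(0L, n_ins, nrow(samples),
                dimnames = list(ins$ins_id, samples$id))
  for (j in seq_len(nrow(samples))) {
    pl <- samples$ploidy[j]
    p <- if (pl == 2L) ins$p2 else ins$p4
    dos[, j] <- rbinom(n_ins, pl, p)
  }
  dos
}

#' Truth carrier states
#'
#' Converts the planted dosage matrix into a carrier/non-carrier state
#' matrix (`"C"` where dosage >= 1, `"N"` otherwise; the truth has no
#' missingness). Useful for running the landscape and statistics layers
#' directly on the simulated truth, bypassing read simulation.
#'
#' @param truth A `sim_truth`.
#' @return Character matrix, insertions x individuals.
#' @export
truth_states <- function(truth) {
  st <- ifelse(truth$dosage >= 1L, "C", "N")
  dimnames(st) <- dimnames(truth$dosage)
  st
}

#' Truth site table
#'
#' Formats the planted insertions as a site table compatible with the
#' detection output (`chrom, start, end, family, superfamily, type, name`),
#' for truth-based runs of the downstream analyses.
#'
#' @param truth A `sim_truth`.
#' @return data.table keyed like [detect_insertions()]'s site table.
#' @export
truth_sites <- function(truth) {
  ins <- truth$insertions
  data.table(site_id = ins$ins_id, chrom = ins$chrom,
             start = ins$pos - ins$tsd_len + 1, end = ins$pos,
             family = ins$family, superfamily = ins$superfamily,
             type = ins$type, name = ins$ins_id)
}

#' Write truth table and sample sheet
#' @param truth A `sim_truth`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_truth_files <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(truth = file.path(dir, "truth_insertions.tsv"),
                dosage = file.path(dir, "truth_dosage.tsv"),
                samples = file.path(dir, "samples.tsv"))
  write_tsv(truth$insertions, paths$truth)
  dos <- data.table(ins_id = rownames(truth$dosage))
  dos <- cbind(dos, as.data.table(truth$dosage))
  write_tsv(dos, paths$dosage)
  write_tsv(truth$samples, paths$samples)
  invisible(paths)
}
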