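test_that("configuration validation rejects impossible setups", {
  expect_error(sim_config(centromere_pos = 2e7, chrom_length = 1e7),
               "centromere")
  bad_sf <- polyte:::default_superfamilies()
  bad_sf$Copia$category_weights["exon"] <- 0.5
  expect_error(sim_config(te_superfamilies = bad_sf), "sum to 1")
  expect_error(sim_config(read_length = 300L, insert_mean = 300), "fragment")
  expect_error(sim_config(n_genes = 5e5, chrom_length = 1e6,
                          n_chromosomes = 1L), "footprint")
})

test_that("genome simulation is deterministic under a fixed seed", {
  cfg <- tiny_cfg(seed = 9, n_genes = 40L)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$reference), as.character(g2$reference))
  expect_identical(as.character(g1$te_library), as.character(g2$te_library))
  expect_equal(g1$annotation$genes, g2$annotation$genes)
  d1 <- file.path(tempdir(), "gdet1"); d2 <- file.path(tempdir(), "gdet2")
  write_genome_files(g1, d1); write_genome_files(g2, d2)
  for (f in c("reference.fa", "annotation.gff3", "centromeres.bed")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("gene density contrast between arms and pericentromere matches the configured ratio", {
  cfg <- sim_config(seed = 3, n_chromosomes = 2L, chrom_length = 2e6,
                    pericentromere_halfwidth = 4e5, n_genes = 200L,
                    gene_arm_density_ratio = 8, n_ref_tes = 0L)
  g <- simulate_genome(cfg)
  genes <- g$annotation$genes
  mid <- (start(genes) + end(genes)) / 2
  cen <- centromere_midpoints(g$annotation)
  in_peri <- abs(mid - cen[as.character(seqnames(genes))]) <= 4e5
  peri_bp <- 2 * 2 * 4e5
  arm_bp <- 2 * 2e6 - peri_bp
  ratio <- (sum(!in_peri) / arm_bp) / (sum(in_peri) / peri_bp)
  expect_gt(ratio, 8 * 0.9)
  expect_lt(ratio, 8 * 1.1)
})

test_that("a genome with zero genes is valid and has an empty gene track", {
  cfg <- tiny_cfg(seed = 5, n_genes = 0L)
  g <- simulate_genome(cfg)
  expect_length(g$annotation$genes, 0L)
  part <- category_partition(g$annotation)
  expect_true(all(part$category == "intergenic"))
})

test_that("planted dosages follow Hardy-Weinberg carrier fractions", {
  cfg <- tiny_cfg(seed = 21, n_per_sf = 25L, chrom_length = 2e6,
                  n_genes = 150L,
                  n_individuals_2x = 300L, n_individuals_4x = 300L,
                  clades = data.frame(clade = c("d", "t"), ploidy = c(2, 4),
                                      n_individuals = 300L,
                                      n_populations = 3L))
  g <- simulate_genome(cfg)
  tr <- simulate_population(g, cfg)
  expect_true(all(tr$dosage[, tr$samples$ploidy == 2L] <= 2L))
  expect_true(all(tr$dosage <= 4L))
  for (pl in c(2L, 4L)) {
    ids <- tr$samples$id[tr$samples$ploidy == pl]
    p <- if (pl == 2L) tr$insertions$p2 else tr$insertions$p4
    f_exp <- 1 - (1 - p)^pl
    f_obs <- rowMeans(tr$dosage[, ids] >= 1L)
    se <- sqrt(pmax(f_exp * (1 - f_exp), 1e-9) / length(ids))
    within3 <- abs(f_obs - f_exp) <= pmax(3 * se, 1e-9)
    expect_gt(mean(within3), 0.95)
  }
  # truth carrier frequency equals the dosage>=1 fraction (no missingness)
  st <- truth_states(tr)
  expect_equal(unname(suppressWarnings(carrier_frequency(st))),
               unname(rowMeans(tr$dosage >= 1L)))
})

test_that("planted categories agree with the site classifier for every insertion", {
  cfg <- tiny_cfg(seed = 8, n_per_sf = 10L)
  g <- simulate_genome(cfg)
  tr <- simulate_population(g, cfg)
  info <- classify_sites(truth_sites(tr), g$annotation, arm_threshold = 1e5)
  expect_identical(info$category, tr$insertions$category)
})

test_that("expression cis effects apply within 250 bp and vanish when effect = 1", {
  cfg0 <- tiny_cfg(seed = 13, n_per_sf = 8L, expression_effect = 1.0)
  g <- simulate_genome(cfg0)
  tr <- simulate_population(g, cfg0)
  e0 <- simulate_expression(tr, g, cfg0)
  aff <- attr(e0, "affected")
  lr <- function(expr, truth, affected) {
    out <- numeric(0)
    carrier <- truth$dosage >= 1L
    for (r in seq_len(nrow(affected))) {
      cc <- carrier[affected$ins_id[r], ]
      if (sum(cc) == 0L || sum(!cc) == 0L) next
      out <- c(out, log2(mean(expr[affected$gene_id[r], cc]) /
                           mean(expr[affected$gene_id[r], !cc])))
    }
    out
  }
  expect_lt(abs(mean(lr(e0, tr, aff))), 0.2)

  cfg1 <- tiny_cfg(seed = 13, n_per_sf = 8L, expression_effect = 0.5)
  e1 <- simulate_expression(tr, g, cfg1)
  ratios <- lr(e1, tr, attr(e1, "affected"))
  expect_gt(length(ratios), 3L)
  expect_lt(median(2^ratios), 0.65)
  expect_gt(median(2^ratios), 0.35)
})

test_that("read simulation produces junction evidence for carriers and clean coverage for non-carriers", {
  cfg <- tiny_cfg(seed = 17, n_per_sf = 3L, n_individuals_2x = 4L,
                  n_individuals_4x = 4L,
                  clades = data.frame(clade = c("d", "t"), ploidy = c(2, 4),
                                      n_individuals = 4L, n_populations = 2L))
  g <- simulate_genome(cfg)
  tr <- simulate_population(g, cfg)
  rd <- simulate_reads(tr, g, file.path(tempdir(), "rsim"))
  ev <- rd$evidence

  # evidence only where dosage >= 1
  dos <- data.table::as.data.table(as.table(tr$dosage))
  data.table::setnames(dos, c("ins_id", "id", "dosage"))
  m <- merge(ev, dos, by = c("ins_id", "id"))
  expect_true(all(m[dosage == 0L, n_up + n_down + n_disc] == 0L))

  # most carrier site x individual pairs at 8X have both junction sides
  carried <- m[dosage >= 1L]
  expect_gt(nrow(carried), 10L)
  expect_gt(mean(carried$n_up >= 1L & carried$n_down >= 1L), 0.75)

  # non-carrier individuals: no split candidates near the site, depth ~ 8X
  bam <- sam_to_bam(rd$sam[[1]])
  id1 <- names(rd$sam)[1]
  absent <- tr$insertions[tr$dosage[, id1] == 0L]
  cand <- extract_candidates(bam)
  splits <- cand[cand$side != "disc"]
  for (i in seq_len(min(5L, nrow(absent)))) {
    hit <- splits[splits$chrom == absent$chrom[i] &
                    abs(splits$anchor - absent$pos[i]) < 150]
    expect_equal(nrow(hit), 0L)
  }
  nc <- negative_coverage(bam, data.table::data.table(
    chrom = absent$chrom, start = absent$pos - 2L, end = absent$pos + 2L))
  expect_gt(median(nc), 3)
  expect_lt(median(nc), 16)

  # byte-identical SAM on rerun with the same seed
  rd2 <- simulate_reads(tr, g, file.path(tempdir(), "rsim2"))
  expect_identical(unname(tools::md5sum(rd$sam[[1]])),
                   unname(tools::md5sum(rd2$sam[[1]])))
})
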