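# shared fixtures, built in code at test time

# a small but complete simulation configuration
tiny_cfg <- function(seed = 42L, n_per_sf = 4L, ...) {
  sf <- polyte:::default_superfamilies()
  for (n in names(sf)) sf[[n]]$n_insertions <- n_per_sf
  args <- modifyList(list(seed = seed, n_chromosomes = 2L,
                          chrom_length = 6e5,
                          pericentromere_halfwidth = 1e5,
                          n_genes = 60L, n_ref_tes = 30L,
                          n_individuals_2x = 6L, n_individuals_4x = 6L,
                          coverage_range = c(8, 8),
                          te_superfamilies = sf),
                     list(...))
  do.call(sim_config, args)
}

# deterministic hand-built annotation on one 100 kb chromosome:
#   geneA (+) 10000..11999 with a 3'UTR at 11900..11999
#   geneB (+) 28000..29999, geneC (+) 30300..31299
hand_annotation <- function() {
  sl <- c(c1 = 1e5)
  gr <- function(s, e, strand, id) {
    GenomicRanges::GRanges("c1", IRanges::IRanges(s, e), strand = strand,
                           gene_id = id)
  }
  genes <- c(gr(10000, 11999, "+", "gA"), gr(28000, 29999, "+", "gB"),
             gr(30300, 31299, "+", "gC"))
  utr5 <- c(gr(10000, 10099, "+", "gA"), gr(28000, 28099, "+", "gB"),
            gr(30300, 30399, "+", "gC"))
  exons <- c(gr(10100, 10499, "+", "gA"), gr(11500, 11899, "+", "gA"),
             gr(28100, 29799, "+", "gB"), gr(30400, 31199, "+", "gC"))
  utr3 <- c(gr(11900, 11999, "+", "gA"), gr(29800, 29999, "+", "gB"),
            gr(31200, 31299, "+", "gC"))
  cen <- GenomicRanges::GRanges("c1", IRanges::IRanges(49500, 50500))
  genome_annotation(sl, genes, exons, utr5, utr3, centromeres = cen)
}

micro_fixture <- function() {
  d <- system.file("extdata", "micro", package = "polyte")
  samples <- read_sample_sheet(file.path(d, "samples.tsv"))
  sites <- read_tsv_table(file.path(d, "sites.tsv"))
  evidence <- read_tsv_table(file.path(d, "evidence.tsv"))
  ncov_dt <- read_tsv_table(file.path(d, "negcov.tsv"))
  neg_cov <- as.matrix(ncov_dt[, -1])
  rownames(neg_cov) <- ncov_dt$site_id
  exp_dt <- read_tsv_table(file.path(d, "expected_states.tsv"))
  expected <- as.matrix(exp_dt[, -1])
  mode(expected) <- "character"
  rownames(expected) <- exp_dt$site_id
  list(samples = samples, sites = sites, evidence = evidence,
       neg_cov = neg_cov, expected = expected)
}

# write a SAM file from a record table and return an indexed BAM path
sam_fixture <- function(recs, seqlengths = c(chr1 = 1e4), dir = tempdir()) {
  sam <- tempfile(tmpdir = dir, fileext = ".sam")
  polyte:::write_sam(data.table::as.data.table(recs), sam, seqlengths)
  sam_to_bam(sam)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
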