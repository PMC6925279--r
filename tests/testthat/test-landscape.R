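test_that("carrier frequency counts carriers over non-NA individuals", {
  m <- rbind(a = c(rep("C", 3), rep("N", 97)),
             b = c(rep("C", 3), rep("N", 90), rep(NA, 7)))
  colnames(m) <- paste0("i", 1:100)
  f <- carrier_frequency(m)
  expect_equal(unname(f["a"]), 0.03)
  expect_equal(unname(f["b"]), 3 / 93)
  m2 <- rbind(m, z = rep(NA_character_, 100))
  expect_warning(f2 <- carrier_frequency(m2), "all states NA")
  expect_true(is.na(f2["z"]))
})

test_that("LF/HF thresholds are the 10th/90th diploid percentiles with interpolation", {
  cl <- lf_hf_classes((1:100) / 100)
  expect_equal(cl$lf_threshold, 0.109)
  expect_equal(cl$hf_threshold, 0.901)
  expect_equal(frequency_class(c(cl$lf_threshold, 0.5, cl$hf_threshold, NA),
                               cl),
               c("LF", "mid", "HF", NA))
  expect_error(lf_hf_classes(rep(0.05, 50)), "degenerate")
  expect_error(lf_hf_classes(c(0.1, 0.2)), "at least 10")
})

test_that("category classification follows the priority order and the closest-gene rule", {
  ann <- hand_annotation()
  sites <- data.table::data.table(
    site_id = paste0("x", 1:5), chrom = "c1",
    #           exon+3'UTR   downstream gB   intergenic   intron gA   upstream gA
    start = c(11880L, 30100L, 34300L, 10700L, 9897L),
    end   = c(11920L, 30104L, 34304L, 10704L, 9901L))
  info <- classify_sites(sites, ann, arm_threshold = 3e4)
  expect_equal(info$category,
               c("utr3", "down250", "intergenic", "intron", "up250"))
  expect_equal(info$nearest_gene[2], "gB")   # 100 bp beats gC's 195 bp
  expect_equal(info$gene_distance[2], 100)
  expect_equal(info$gene_distance[3], 3000)
  expect_equal(info$gene_distance[4], 0)     # genic => distance 0
  expect_error(classify_sites(data.table::data.table(
    site_id = "y", chrom = "c9", start = 1L, end = 2L), ann), "absent")
})

test_that("classification is invariant under strand flip plus coordinate mirroring", {
  ann <- hand_annotation()
  L <- 1e5
  mirror <- function(gr) {
    out <- GenomicRanges::GRanges(
      "c1", IRanges::IRanges(L + 1 - GenomicRanges::end(gr),
                             L + 1 - GenomicRanges::start(gr)),
      strand = ifelse(GenomicRanges::strand(gr) == "+", "-", "+"))
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out
  }
  ann_m <- genome_annotation(c(c1 = L), mirror(ann$genes), mirror(ann$exons),
                             mirror(ann$utr5), mirror(ann$utr3),
                             centromeres = mirror(ann$centromeres))
  set.seed(7)
  pos <- sample(setdiff(2000:98000, 30149:30151), 400)  # skip midpoint ties
  fwd <- classify_sites(data.table::data.table(
    site_id = paste0("p", seq_along(pos)), chrom = "c1",
    start = pos, end = pos), ann)
  rev <- classify_sites(data.table::data.table(
    site_id = paste0("p", seq_along(pos)), chrom = "c1",
    start = L + 1 - pos, end = L + 1 - pos), ann_m)
  expect_identical(fwd$category, rev$category)
})

test_that("arm fraction reflects distance from the centromere", {
  cen <- c(chr1 = 1e7)
  at <- function(pos) data.table::data.table(chrom = "chr1", start = pos,
                                             end = pos)
  expect_equal(arm_fraction(at(c(1e5, 1.99e7)), cen), 1)
  expect_equal(arm_fraction(at(c(1e7, 1.01e7)), cen), 0)
  grid <- at(seq(5e4, 2e7 - 5e4, by = 1e5))
  expect_equal(arm_fraction(grid, cen), 0.5, tolerance = 0.02)
})

test_that("density profiles conserve counts and handle empty input", {
  sl <- c(chr1 = 1e6)
  feats <- data.table::data.table(chrom = "chr1",
                                  start = rep(123456L, 100),
                                  end = rep(123456L, 100))
  d <- density_profile(feats, sl)
  expect_equal(sum(d$count), 100)
  expect_equal(d$count[d$win_start == 100001], 100)
  d0 <- density_profile(feats[0], sl)
  expect_true(all(d0$count == 0))
  expect_equal(nrow(d0), 10)
})

test_that("category footprints are exact and respect coverage weighting", {
  # one gene that is entirely exon, occupying 20% of a 100 kb chromosome
  sl <- c(c1 = 1e5)
  g <- GenomicRanges::GRanges("c1", IRanges::IRanges(10001, 30000),
                              strand = "+", gene_id = "g1")
  empty <- GenomicRanges::GRanges()
  ann <- genome_annotation(sl, g, g, empty, empty)
  fp <- reference_category_footprint(ann)
  expect_equal(fp[fp$category == "exon", ]$proportion, 0.2)
  expect_equal(sum(fp$proportion), 1)
  # halved coverage over the exonic windows scales its weighted footprint
  # by 0.5 / mean coverage
  win <- GenomicRanges::GRanges("c1", IRanges::IRanges(
    seq(1, 1e5, by = 1e4), width = 1e4))
  win$score <- ifelse(GenomicRanges::start(win) %in% c(10001, 20001), 0.5, 1)
  fpw <- reference_category_footprint(ann, coverage = win)
  expect_equal(fpw[fpw$category == "exon", ]$weighted_bp,
               20000 * 0.5 / 0.9, tolerance = 1e-6)

  # no annotation at all: everything is intergenic
  ann0 <- genome_annotation(sl, empty, empty, empty, empty)
  fp0 <- reference_category_footprint(ann0)
  expect_equal(fp0[fp0$category == "intergenic", ]$proportion, 1)
})

test_that("gene-distance bootstrap detects a planted shift", {
  set.seed(11)
  a <- runif(300, 0, 5000)
  b <- a + 100
  res <- gene_distance_bootstrap(a, b, n_boot = 500)
  expect_equal(res$delta, 100, tolerance = 40)
  expect_lt(res$p_value, 0.01)
  expect_error(gene_distance_bootstrap(a, b, n_boot = 1), "at least 100")
  expect_error(gene_distance_bootstrap(numeric(0), b), "at least 2")
})
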