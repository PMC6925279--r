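make_read <- function(qname, flag, pos, cigar, seq, pnext = pos,
                      rname = "chr1", mapq = 60L) {
  data.table::data.table(qname = qname, flag = flag, rname = rname,
                         pos = pos, mapq = mapq, cigar = cigar,
                         rnext = "=", pnext = pnext, tlen = 0L, seq = seq,
                         qual = strrep("I", nchar(seq)))
}

test_that("candidate extraction separates split, proper and discordant reads", {
  set.seed(1)
  te_piece <- random_seq(20)
  recs <- rbind(
    make_read("r1", 3L, 1000L, "80M20S", paste0(random_seq(80), te_piece)),
    make_read("r2", 3L, 1200L, "100M", random_seq(100)),
    make_read("r3", 3L, 2000L, "20S80M", paste0(te_piece, random_seq(80))),
    make_read("r4", 73L, 3000L, "100M", random_seq(100)),   # mate unmapped
    make_read("r4", 133L, 3000L, "*", random_seq(100), mapq = 0L))
  bam <- sam_fixture(recs)
  cand <- extract_candidates(bam, min_clip = 20L)
  up <- cand[cand$side == "up"]
  expect_equal(up$qname, "r1")
  expect_equal(up$anchor, 1079L)          # clip at the alignment 3' end
  expect_equal(up$seq, te_piece)
  dn <- cand[cand$side == "down"]
  expect_equal(dn$qname, "r3")
  expect_equal(dn$anchor, 2000L)
  expect_false("r2" %in% cand$qname)      # clean proper pair excluded
  dd <- cand[cand$side == "disc"]
  expect_equal(dd$qname, "r4")
  expect_false(is.na(dd$seq))             # unmapped mate sequence attached

  # sub-threshold clips are not split candidates
  expect_equal(nrow(extract_candidates(bam, min_clip = 25L)[side != "disc"]),
               0L)
})

test_that("alignment inputs are validated and empty files give empty sets", {
  empty <- sam_fixture(make_read("x", 3L, 1L, "100M", random_seq(100))[0, ])
  expect_equal(nrow(extract_candidates(empty)), 0L)
  expect_error(extract_candidates(tempfile(fileext = ".bam")), "no such")
  bam <- sam_fixture(make_read("r", 3L, 100L, "100M", random_seq(100)))
  file.remove(paste0(bam, ".bai"))
  expect_error(extract_candidates(bam), "index")
})

test_that("TE assignment honors identity and length thresholds and flags ambiguity", {
  set.seed(2)
  lib <- Biostrings::DNAStringSet(c(fam1 = random_seq(400),
                                    fam2 = random_seq(400)))
  cand <- function(seq, side = "up") {
    data.table::data.table(qname = "q", chrom = "chr1", anchor = 100L,
                           side = side, seq = seq)
  }
  exact <- substr(as.character(lib[["fam1"]]), 1, 30)
  a <- assign_te(cand(exact), lib)
  expect_equal(a$family, "fam1")
  expect_equal(a$identity, 1.0)

  # one mismatch in 18 bp: identity ~0.944, above the 0.9 floor
  near <- substr(as.character(lib[["fam2"]]), 50, 67)
  substr(near, 9, 9) <- setdiff(c("A", "C", "G", "T"),
                                substr(near, 9, 9))[1]
  b <- assign_te(cand(near), lib)
  expect_equal(b$family, "fam2")
  expect_equal(b$identity, 1 - 1 / 18, tolerance = 1e-9)

  expect_equal(nrow(assign_te(cand(random_seq(40)), lib)), 0L)   # no hit
  expect_equal(nrow(assign_te(cand(substr(exact, 1, 10)), lib)), 0L)  # short

  # equal-best hit in two families: first by library order, flagged
  lib2 <- Biostrings::DNAStringSet(c(famA = as.character(lib[["fam1"]]),
                                     famB = as.character(lib[["fam1"]])))
  d <- assign_te(cand(exact), lib2)
  expect_equal(d$family, "famA")
  expect_true(d$ambiguous)
})

test_that("anchor clustering merges by family within the window", {
  tr <- function(anchor, side, family) {
    data.table::data.table(qname = "q", chrom = "chr1", anchor = anchor,
                           side = side, seq = NA_character_,
                           family = family, identity = 1, ambiguous = FALSE)
  }
  one <- rbind(tr(1000L, "up", "F"), tr(1000L, "up", "F"),
               tr(1005L, "down", "F"))
  s1 <- define_sites(one)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$split_up, 2L)
  expect_equal(s1$split_down, 1L)
  expect_equal(c(s1$start, s1$end), c(1000L, 1005L))

  two_fam <- rbind(tr(1000L, "up", "F"), tr(1005L, "down", "G"))
  expect_equal(nrow(define_sites(two_fam)), 2L)

  spread <- rbind(tr(1000L, "up", "F"), tr(1151L, "down", "F"))
  expect_equal(nrow(define_sites(spread, cluster_window = 100L)), 2L)
  expect_equal(nrow(define_sites(spread, cluster_window = 200L)), 1L)
})

test_that("cross-individual intersection applies the three-read two-side support rule", {
  site <- function(start, end, up, down, disc, family = "F") {
    data.table::data.table(chrom = "chr1", start = start, end = end,
                           family = family, split_up = up,
                           split_down = down, discordant = disc)
  }
  res <- intersect_sites(list(
    a = rbind(site(1000L, 1005L, 2L, 1L, 0L),      # retained: 3 reads, 2 sides
              site(2000L, 2005L, 3L, 0L, 0L),      # dropped: one side only
              site(3000L, 3005L, 1L, 1L, 0L)),     # dropped: 2 reads total
    b = site(1003L, 1008L, 0L, 1L, 0L)))           # merges with a's first
  expect_equal(nrow(res$sites), 1L)
  expect_equal(c(res$sites$start, res$sites$end), c(1000L, 1008L))
  expect_equal(sort(res$evidence$id), c("a", "b"))
})

test_that("state assignment reproduces the negative-coverage boundary semantics exactly", {
  fx <- micro_fixture()
  st <- assign_states(fx$sites, fx$evidence, fx$samples, fx$neg_cov)
  expect_identical(st$states, fx$expected)
  expect_length(st$dropped, 0L)

  # carrier frequencies over non-NA individuals
  expect_equal(unname(st$sites$carrier_freq),
               c(1 / 4, 1 / 5, 1 / 4, 1 / 4))

  # disjunctive NA rule drops the sites with >1 NA in one ploidy group
  st_or <- assign_states(fx$sites, fx$evidence, fx$samples, fx$neg_cov,
                         na_rule = "or")
  expect_setequal(st_or$dropped, c("s3", "s4"))

  # states partition the cohort and every retained site has a carrier
  expect_true(all(rowSums(st$states == "C", na.rm = TRUE) +
                    rowSums(st$states == "N", na.rm = TRUE) +
                    rowSums(is.na(st$states)) == nrow(fx$samples)))
  expect_true(all(rowSums(st$states == "C", na.rm = TRUE) >= 1L))

  bad_ev <- data.table::copy(fx$evidence)[1, id := "ghost"]
  expect_error(assign_states(fx$sites, bad_ev, fx$samples, fx$neg_cov),
               "ghost")
})

test_that("site naming uses known annotation, synthetic names and duplicate suffixes", {
  sites <- data.table::data.table(
    site_id = paste0("s", 1:4), chrom = "chr1",
    start = c(100L, 500L, 900L, 1300L), end = c(104L, 504L, 904L, 1304L),
    family = c("Mariner_fam1", "Mariner_fam1", "LINE_fam1", "LINE_fam1"),
    superfamily = c("Mariner", "Mariner", "LINE", "LINE"),
    type = c("B", "B", "B", "B"))
  known <- data.table::data.table(
    chrom = "chr1", start = c(890L, 1290L), end = c(910L, 1310L),
    name = c("ALLINE1_2", "ALLINE1_2"), family = "LINE_fam1")
  nm <- name_sites(sites, known)$name
  expect_equal(nm, c("Mariner_new-1", "Mariner_new-2",
                     "ALLINE1_2.1", "ALLINE1_2.2"))
  expect_true(all(grepl("_new-", name_sites(sites, NULL)$name)))
})
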