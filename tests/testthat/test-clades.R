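clade_samples <- function() {
  data.table::data.table(
    id = c(paste0("a", 1:5), paste0("b", 1:5), paste0("c", 1:5)),
    population = rep(c("pA", "pB", "pC"), each = 5),
    clade = rep(c("A", "B", "C"), each = 5),
    ploidy = rep(c(2L, 2L, 4L), each = 5),
    coverage = 8)
}

test_that("clade classes distinguish private, shared and multi-clade sites", {
  s <- clade_samples()
  st <- matrix("N", 4, 15, dimnames = list(paste0("s", 1:4), s$id))
  st["s1", "a1"] <- "C"                         # private
  st["s2", c("a1", "a2", "a3", "a4")] <- "C"    # shared + HF3
  st["s3", c("a1", "b1")] <- "C"                # multi-clade
  st["s4", c("c1", "c2")] <- "C"                # shared, below HF3
  cc <- classify_by_clade(st, s)
  expect_equal(cc$clade_class, c("private", "shared", "multi_clade",
                                 "shared"))
  expect_equal(cc$hf3, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(cc[site_id == "s2", local_carriers], 4L)
  expect_true(is.na(cc[site_id == "s3", clade]))

  # counts partition all sites; HF3 is monotone in its threshold
  expect_equal(sum(table(cc$clade_class)), 4L)
  cc4 <- classify_by_clade(st, s, hf3_min = 4L)
  expect_lte(sum(cc4$hf3), sum(cc$hf3))
  cc2 <- classify_by_clade(st, s, hf3_min = 2L)
  expect_gte(sum(cc2$hf3), sum(cc$hf3))

  bad <- data.table::copy(s)[1, clade := NA_character_]
  expect_error(classify_by_clade(st, bad), "without clade")
})

test_that("the local HF3 contrast responds only in the enriched compartment", {
  set.seed(61)
  n_side <- 100L
  s <- data.table::data.table(
    id = c(paste0("d", 1:20), paste0("t", 1:20)),
    population = "p", clade = rep(c("D", "T"), each = 20),
    ploidy = rep(c(2L, 4L), each = 20), coverage = 8)
  mk <- function(prefix, n, clade, hf3_rate, category) {
    data.table::data.table(
      site_id = paste0(prefix, seq_len(n)), clade = clade,
      clade_class = "shared", n_carriers = 2L, n_clades = 1L,
      local_carriers = 2L, hf3 = runif(n) < hf3_rate,
      category = category)
  }
  cc <- rbind(mk("ig_d", n_side, "D", 0.2, "intergenic"),
              mk("ig_t", n_side, "T", 0.2, "intergenic"),
              mk("ge_d", n_side, "D", 0.2, "exon"),
              mk("ge_t", n_side, "T", 0.55, "exon"))
  info <- data.table::data.table(site_id = cc$site_id,
                                 category = cc$category,
                                 nearest_gene = NA_character_,
                                 gene_distance = 0,
                                 superfamily = "Copia")
  res <- local_selection_contrast(cc[, !"category"], info, s)
  expect_lt(res[compartment == "genic_near", chi2_p], 0.01)
  expect_gt(res[compartment == "genic_near", prop_4x],
            res[compartment == "genic_near", prop_2x])
  expect_gt(res[compartment == "intergenic", chi2_p], 0.05)

  # a compartment with a single insertion skips the test
  one <- rbind(cc[1], cc[site_id == "ig_t1"],
               mk("solo_d", 1L, "D", 1, "exon"),
               mk("solo_t", 1L, "T", 1, "exon"))
  info1 <- data.table::data.table(site_id = one$site_id,
                                  category = one$category,
                                  nearest_gene = NA_character_,
                                  gene_distance = 0,
                                  superfamily = "Copia")
  res1 <- local_selection_contrast(one[, !"category"], info1, s)
  expect_true(is.na(res1[compartment == "genic_near", chi2_p]))
})

test_that("hypergeometric enrichment matches exhaustive enumeration and flags extremes", {
  universe <- paste0("g", 1:12)
  classes <- data.table::data.table(
    gene_id = c(paste0("g", 1:5), paste0("g", 6:12)),
    class = rep(c("red", "blue"), c(5, 7)))
  target <- c("g1", "g2", "g3", "g6")
  res <- gene_class_enrichment(target, classes, universe)
  p_oracle <- hyper_oracle(universe, paste0("g", 1:5), 4L, 3L)
  expect_equal(res[res$class == "red", ]$p_value, p_oracle,
               tolerance = 1e-12)

  # target exactly one class: minimal p, fold = universe/class ratio
  res2 <- gene_class_enrichment(paste0("g", 1:5), classes, universe)
  expect_equal(res2$class[1], "red")
  expect_equal(res2[res2$class == "red", ]$fold, 12 / 5)
  expect_equal(res2[res2$class == "red", ]$p_value,
               1 / choose(12, 5), tolerance = 1e-12)

  # classes with no member in the universe are skipped
  cl3 <- rbind(classes,
               data.table::data.table(gene_id = "zz", class = "ghost"))
  expect_false("ghost" %in% gene_class_enrichment(target, cl3,
                                                  universe)$class)
  expect_error(gene_class_enrichment(c("g1", "nope"), classes, universe),
               "nope")
})

test_that("random targets give well-calibrated enrichment p-values", {
  set.seed(71)
  universe <- paste0("g", 1:200)
  classes <- data.table::data.table(gene_id = universe,
                                    class = rep(paste0("c", 1:10), 20))
  ps <- replicate(100, {
    gene_class_enrichment(sample(universe, 20), classes, universe)$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.75)
  expect_lt(mean(ps < 0.05), 0.10)   # discrete test, at most nominal-ish
})

test_that("the length-matched null reports a calibrated empirical p", {
  set.seed(72)
  universe <- paste0("g", 1:100)
  lens <- setNames(exp(rnorm(100, 7, 1)), universe)
  classes <- data.table::data.table(gene_id = universe,
                                    class = rep(c("a", "b"), 50))
  res <- gene_class_enrichment(sample(universe, 15), classes, universe,
                               gene_lengths = lens, n_resample = 500L)
  expect_true(all(res$p_length_matched > 0 & res$p_length_matched <= 1))
})
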