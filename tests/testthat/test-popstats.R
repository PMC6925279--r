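test_that("the 2x2 chi-square matches its closed form and handles edge tables", {
  expect_equal(chi2_2x2(10, 90, 10, 90)$statistic, 0)
  expect_equal(chi2_2x2(10, 90, 10, 90)$p_value, 1)
  expect_equal(chi2_2x2(10, 90, 20, 80)$statistic,
               chi2_closed_form(10, 90, 20, 80), tolerance = 1e-12)
  ex <- chi2_2x2(0, 100, 100, 0)
  expect_equal(ex$statistic, 200)
  expect_lt(ex$p_value, 1e-40)
  expect_error(chi2_2x2(0, 0, 5, 5), "margin")
  expect_error(chi2_2x2(-1, 2, 3, 4), "non-negative")

  set.seed(99)
  for (i in 1:200) {
    t4 <- sample(1:100, 4, replace = TRUE)
    expect_equal(chi2_2x2(t4[1], t4[2], t4[3], t4[4])$statistic,
                 chi2_closed_form(t4[1], t4[2], t4[3], t4[4]),
                 tolerance = 1e-10)
  }
})

test_that("Hardy-Weinberg conversions are exact, round-trip, and behave at the limits", {
  h2 <- hw_convert(f = 0.122, ploidy = 2)
  expect_equal(round(h2$p, 3), 0.063)
  h4 <- hw_convert(f = 0.122, ploidy = 4)
  expect_equal(h4$p, 1 - 0.878^0.25, tolerance = 1e-12)
  expect_equal(round(h4$p, 4), 0.0320)

  z <- hw_convert(f = 0, ploidy = 4)
  expect_equal(z$p, 0)
  expect_equal(unname(z$genotype_probs["dosage0"]), 1)

  # dosage-1 fraction among carriers at the diploid boundary frequency
  d1 <- hw_convert(p = 0.063, ploidy = 2)$dosage1_carrier_fraction
  expect_equal(d1, 2 * 0.063 * 0.937 / (1 - 0.937^2), tolerance = 1e-12)
  expect_equal(d1, 0.9675, tolerance = 1e-3)

  for (pl in c(2L, 4L)) {
    f <- seq(0, 0.99, by = 0.01)
    back <- vapply(f, function(x)
      hw_convert(p = hw_convert(f = x, ploidy = pl)$p, ploidy = pl)$f,
      numeric(1))
    expect_equal(back, f, tolerance = 1e-12)
    expect_true(all(vapply(f, function(x)
      abs((1 - hw_convert(f = x, ploidy = pl)$p)^pl - (1 - x)) < 1e-12,
      logical(1))))
    # minimal-dosage carrier fraction: -> 1 as p -> 0, decreasing in p
    ps <- seq(1e-6, 0.95, length.out = 50)
    d <- vapply(ps, function(p)
      hw_convert(p = p, ploidy = pl)$dosage1_carrier_fraction, numeric(1))
    expect_gt(d[1], 1 - 1e-4)
    expect_true(all(diff(d) < 0))
    expect_true(all(abs(vapply(ps, function(p)
      sum(hw_convert(p = p, ploidy = pl)$genotype_probs), numeric(1)) - 1)
      < 1e-12))
  }
  expect_warning(hw_convert(f = 1, ploidy = 2), "monomorphic")
  expect_error(hw_convert(f = 0.1, p = 0.1), "exactly one")
})

test_that("content tables stratify carried insertions with haplo-coverage", {
  states <- rbind(s1 = c("C", "N", "C", "N"),
                  s2 = c("C", "C", NA, "N"),
                  s3 = c("N", "N", "C", "C"))
  colnames(states) <- c("a", "b", "c", "d")
  info <- data.table::data.table(site_id = c("s1", "s2", "s3"),
                                 category = c("exon", "intron", "intergenic"))
  samples <- data.table::data.table(id = c("a", "b", "c", "d"),
                                    ploidy = c(2L, 2L, 4L, 4L),
                                    coverage = c(8, 6, 8, 12))
  ct <- content_table(states, info, samples)
  expect_equal(ct[id == "a" & cat_group == "exonic", count], 1L)
  expect_equal(ct[id == "c" & cat_group == "non_genic", count], 1L)
  expect_equal(ct[id == "c" & cat_group == "intron_utr", count], 0L)
  expect_equal(unique(ct[id == "d", haplo_coverage]), 3)
  # strata partition carried insertions
  expect_equal(sum(ct$count), sum(states == "C", na.rm = TRUE))
})

test_that("stepwise selection recovers a planted effect and reduces to full OLS", {
  set.seed(31)
  exact <- 0L; found <- 0L
  for (r in 1:100) {
    n <- 200
    d <- data.frame(x = runif(n, 2, 9), z = runif(n),
                    g = factor(sample(c("u", "v"), n, replace = TRUE)))
    d$y <- 1 + 2 * d$x + rnorm(n)
    fit <- fit_stepwise_mlm(d, "y", c("x", "z", "g"), alpha_in = 0.01)
    if ("x" %in% fit$included) found <- found + 1L
    if (identical(fit$included, "x")) exact <- exact + 1L
  }
  expect_equal(found, 100L)   # the real effect is never missed
  expect_gte(exact, 95L)      # spurious terms enter at the nominal rate

  # alpha_in = alpha_out = 1 gives the saturated model
  set.seed(32)
  d <- data.frame(x = runif(60), w = runif(60))
  d$y <- 1 + d$x - 2 * d$w + rnorm(60, sd = 0.3)
  full <- lm(y ~ (x + w)^2, data = d)
  sw <- fit_stepwise_mlm(d, "y", c("x", "w"), alpha_in = 1, alpha_out = 1)
  canon <- function(x) vapply(strsplit(x, ":"), function(p)
    paste(sort(p), collapse = ":"), character(1))
  cs <- coef(sw$fit); names(cs) <- canon(names(cs))
  cf <- coef(full); names(cf) <- canon(names(cf))
  expect_equal(sort(names(cs)), sort(names(cf)))
  expect_equal(cs[names(cf)], cf, tolerance = 1e-8)
})

test_that("stepwise selection recovers a planted ploidy-by-exonic interaction", {
  set.seed(33)
  n <- 150
  d <- expand.grid(id = seq_len(n), cat_group = c("exonic", "non_genic"))
  d$ploidy <- rep(sample(c(2, 4), n, replace = TRUE), 2)
  d$haplo_coverage <- rep(runif(n, 2, 8), 2)
  d$count <- 5 + 0.5 * d$haplo_coverage +
    2 * (d$ploidy == 4) * (d$cat_group == "exonic") + rnorm(nrow(d), sd = 0.7)
  fit <- fit_stepwise_mlm(d, "count",
                          c("haplo_coverage", "ploidy", "cat_group"))
  expect_true(any(grepl(":", fit$included)))
  inter <- fit$coefficients[grepl(":", term) & grepl("ploidy", term) &
                              grepl("cat_group", term)]
  expect_gt(nrow(inter), 0L)
  expect_gt(abs(inter$estimate[1]), 0)
})

test_that("subsampled content converges to per-capita counts and flags a planted LF-exonic excess", {
  set.seed(41)
  n2 <- 80L; n4 <- 80L
  samples <- data.table::data.table(
    id = c(paste0("d", 1:n2), paste0("t", 1:n4)),
    ploidy = rep(c(2L, 4L), c(n2, n4)),
    coverage = 8)
  # 60 exonic-LF sites: tetraploids carry 30% more of them
  n_sites <- 60L
  st <- matrix("N", n_sites, n2 + n4,
               dimnames = list(sprintf("s%02d", 1:n_sites), samples$id))
  st[, 1:n2][matrix(runif(n_sites * n2) < 0.10, n_sites)] <- "C"
  st[, (n2 + 1):(n2 + n4)][matrix(runif(n_sites * n4) < 0.13,
                                  n_sites)] <- "C"
  info <- data.table::data.table(site_id = rownames(st), category = "exon",
                                 freq_class = "LF")
  res <- suppressWarnings(subsampled_content(st, info, samples,
                                             n_per_group = 50L, reps = 80L))
  row <- res[stratum == "exonic.LF"]
  expect_gt(row$delta_4x, 0)
  expect_lt(row$t_p, 0.05)
  # subsample means stay close to the full-cohort per-capita count
  expect_equal(row$mean_2x, mean(colSums(st[, 1:n2] == "C")),
               tolerance = 3 * row$sd_2x / sqrt(80) + 0.05)
  expect_error(subsampled_content(st, info, samples, reps = 1L), "reps")
  expect_error(subsampled_content(st, info, samples, n_per_group = 1L),
               "n_per_group")
})

test_that("the family burst test excludes small families and flags a real excess", {
  n2 <- 40L; n4 <- 40L
  samples <- data.table::data.table(
    id = c(paste0("d", 1:n2), paste0("t", 1:n4)),
    ploidy = rep(c(2L, 4L), c(n2, n4)), coverage = 8)
  ids2 <- samples$id[1:n2]; ids4 <- samples$id[-(1:n2)]

  set.seed(51)
  mk_family <- function(fam, n_sites, hf_rate2, hf_rate4) {
    st <- matrix("N", n_sites, n2 + n4,
                 dimnames = list(paste0(fam, "_", seq_len(n_sites)),
                                 samples$id))
    f2 <- ifelse(runif(n_sites) < hf_rate2, 0.8, 0.05)
    f4 <- ifelse(runif(n_sites) < hf_rate4, 0.8, 0.05)
    for (i in seq_len(n_sites)) {
      st[i, ids2][runif(n2) < f2[i]] <- "C"
      st[i, ids4][runif(n4) < f4[i]] <- "C"
      if (all(st[i, ids2] == "N")) st[i, sample(ids2, 1)] <- "C"
      if (all(st[i, ids4] == "N")) st[i, sample(ids4, 1)] <- "C"
    }
    st
  }
  st <- rbind(mk_family("null", 50L, 0.3, 0.3),
              mk_family("burst", 50L, 0.1, 0.6),
              mk_family("tiny", 9L, 0.3, 0.3))
  info <- data.table::data.table(site_id = rownames(st),
                                 family = sub("_[0-9]+$", "", rownames(st)),
                                 category = "intergenic")
  classes <- structure(list(lf_threshold = 0.02, hf_threshold = 0.5),
                       class = "freq_classes")
  res <- burst_family_test(st, info, samples, classes = classes,
                           min_copies = 10L)
  expect_false("tiny" %in% res$family)   # 9 copies: below the >10 rule
  expect_true(res[family == "burst", flagged])
  expect_true(res[family == "burst", excess_4x])
  expect_false(res[family == "null", flagged])

  expect_warning(burst_family_test(st[1:5, ], info[1:5], samples,
                                   classes = classes), "no family")
})
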