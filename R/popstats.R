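#' Pearson 2x2 chi-square test
#'
#' One-degree-of-freedom Pearson chi-square on a 2x2 contingency table,
#' without continuity correction by default (the package's proportion
#' comparisons all use this form).
#'
#' @param a,b,c,d Cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `p_value`, `table`.
#' @export
#' @examples
#' chi2_2x2(10, 90, 20, 80)$statistic  # ~3.922
chi2_2x2 <- function(a, b, c, d, correct = FALSE) {
  tab <- rbind(c(a, b), c(c, d))
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("2x2 table has a zero margin")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value),
       table = tab)
}

#' Hardy-Weinberg carrier/allele frequency conversion under polysomy
#'
#' Under Hardy-Weinberg equilibrium the carrier frequency `f` (fraction of
#' individuals with dosage >= 1) and the allele frequency `p` are linked by
#' `(1 - p)^ploidy = 1 - f`. Given either quantity this returns the other,
#' the binomial genotype-class probabilities, and the fraction of carriers
#' in the minimal-dosage class (heterozygotes in diploids, simplex
#' heterozygotes in autotetraploids).
#'
#' @param f Carrier frequency in `[0, 1]` (give exactly one of `f`, `p`).
#' @param p Allele frequency in `[0, 1]`.
#' @param ploidy 2 or 4.
#' @return Object of class `hw_result`: list with `ploidy`, `f`, `p`,
#'   `genotype_probs` (dosage 0..ploidy) and `dosage1_carrier_fraction`.
#' @export
#' @examples
#' hw_convert(f = 0.122, ploidy = 2)$p  # ~0.063
hw_convert <- function(f = NULL, p = NULL, ploidy = c(2L, 4L)) {
  ploidy <- as.integer(ploidy)[1]
  if (!ploidy %in% c(2L, 4L)) stop("ploidy must be 2 or 4")
  if (is.null(f) == is.null(p)) stop("give exactly one of f or p")
  if (!is.null(f)) {
    if (f < 0 || f > 1) stop("f must be in [0, 1]")
    if (f == 1) warning("f = 1 implies a monomorphic insertion (p = 1)")
    p <- 1 - (1 - f)^(1 / ploidy)
  } else {
    if (p < 0 || p > 1) stop("p must be in [0, 1]")
    f <- 1 - (1 - p)^ploidy
  }
  gp <- dbinom(0:ploidy, ploidy, p)
  names(gp) <- paste0("dosage", 0:ploidy)
  d1 <- if (f > 0) gp[["dosage1"]] / (1 - gp[["dosage0"]]) else NA_real_
  structure(list(ploidy = ploidy, f = f, p = p, genotype_probs = gp,
                 dosage1_carrier_fraction = d1),
            class = "hw_result")
}

#' @export
print.hw_result <- function(x, ...) {
  cat(sprintf("HW %dx: f = %.4f, p = %.4f, dosage-1 carriers = %s\n",
              x$ploidy, x$f, x$p,
              ifelse(is.na(x$dosage1_carrier_fraction), "NA",
                     sprintf("%.3f", x$dosage1_carrier_fraction))))
  invisible(x)
}

#' Spectrum-averaged minimal-dosage carrier fraction
#'
#' Averages the dosage-1 fraction among carriers over an empirical
#' carrier-frequency spectrum, weighting each site by its expected number
#' of carriers.
#'
#' @param f_values Carrier frequencies of the sites in the spectrum.
#' @param ploidy 2 or 4.
#' @return Weighted average fraction of carriers at dosage 1.
#' @export
hw_dosage1_spectrum <- function(f_values, ploidy) {
  f_values <- f_values[!is.na(f_values) & f_values > 0]
  res <- vapply(f_values, function(f)
    hw_convert(f = f, ploidy = ploidy)$dosage1_carrier_fraction, numeric(1))
  sum(res * f_values) / sum(f_values)
}

#' Per-individual TE content table
#'
#' Builds the response table of the content models: one row per
#' individual and stratum, counting the insertions the individual carries.
#' Strata are the category group (`non_genic` = intergenic/near-gene,
#' `intron_utr`, `exonic`) and/or the frequency class (`LF`/`mid`/`HF`).
#' Haplo-coverage (sequencing coverage per haploid genome, i.e. coverage
#' divided by ploidy) is attached for use as a model covariate.
#'
#' @param states State matrix sites x individuals.
#' @param site_info Classified site table (needs `site_id`, `category`
#'   and, if stratifying by frequency, either one `freq_class` column or
#'   the cohort-specific pair `freq_class_2x` / `freq_class_4x`; with the
#'   pair, each individual's counts use the class from its own ploidy
#'   cohort — the diploid-derived thresholds applied to each cohort's own
#'   frequencies).
#' @param samples Sample sheet.
#' @param strata Character subset of `c("cat_group", "freq_class")`.
#' @return data.table: id, ploidy, haplo_coverage, stratum columns, count.
#' @export
content_table <- function(states, site_info, samples,
                          strata = "cat_group") {
  site_info <- as.data.table(site_info)
  samples <- as.data.table(samples)
  stopifnot(all(rownames(states) %in% site_info$site_id))
  info <- site_info[match(rownames(states), site_id)]
  per_ploidy <- "freq_class" %in% strata &&
    all(c("freq_class_2x", "freq_class_4x") %in% names(info))
  build <- function(ids, fc_col) {
    dims <- list()
    if ("cat_group" %in% strata) {
      dims$cat_group <- category_group(info$category)
    }
    if ("freq_class" %in% strata) dims$freq_class <- info[[fc_col]]
    if (length(dims) == 0L) dims$all <- rep("all", nrow(info))
    key <- do.call(paste, c(dims, sep = "\r"))
    carrier <- states[, ids, drop = FALSE] == "C"
    carrier[is.na(carrier)] <- FALSE
    counts <- rowsum(carrier + 0L, key)
    rows <- list()
    for (r in seq_len(nrow(counts))) {
      parts <- strsplit(rownames(counts)[r], "\r", fixed = TRUE)[[1]]
      dt <- data.table(id = ids, count = counts[r, ])
      for (dk in seq_along(dims)) dt[[names(dims)[dk]]] <- parts[dk]
      rows[[r]] <- dt
    }
    rbindlist(rows)
  }
  out <- if (per_ploidy) {
    rbind(build(samples$id[samples$ploidy == 2L], "freq_class_2x"),
          build(samples$id[samples$ploidy == 4L], "freq_class_4x"))
  } else {
    build(colnames(states), "freq_class")
  }
  out <- out[samples[, .(id, ploidy, coverage)], on = "id"]
  out[is.na(count), count := 0L]
  out[, haplo_coverage := coverage / ploidy]
  setcolorder(out, c("id", "ploidy", "haplo_coverage"))
  out[]
}

#' Category group of a category label
#' @param category Character vector of category codes.
#' @return `"exonic"`, `"intron_utr"` or `"non_genic"`.
#' @export
category_group <- function(category) {
  ifelse(category == "exon", "exonic",
         ifelse(category %in% c("intron", "utr5", "utr3"), "intron_utr",
                "non_genic"))
}

#' Stepwise multiple linear model with F-test term selection
#'
#' Bidirectional stepwise ordinary least squares: at each iteration the
#' candidate term with the smallest F-test p-value for the change in
#' residual sum of squares is added if below `alpha_in`; otherwise the
#' included term with the largest p-value is removed if above
#' `alpha_out`. Model hierarchy is respected: an interaction can only
#' enter once all its main effects are in, and a term supporting an
#' included interaction cannot leave. Iterates to a fixed point.
#'
#' @param data Data frame with the response and candidate covariates.
#' @param response Response variable name.
#' @param terms Character vector of main-effect names.
#' @param max_order Highest interaction order among `terms` to consider
#'   (default 2).
#' @param alpha_in,alpha_out Entry / removal thresholds (defaults 0.05 and
#'   0.10).
#' @param max_iter Safety cap on iterations.
#' @return Object of class `stepwise_mlm`: list with `fit` (the `lm`),
#'   `coefficients` (estimate, 95% CI, t-statistic p-value), `sse`,
#'   `trace` (data.table of add/drop events).
#' @export
fit_stepwise_mlm <- function(data, response, terms, max_order = 2L,
                             alpha_in = 0.05, alpha_out = 0.10,
                             max_iter = 50L) {
  data <- as.data.frame(data)
  if (nrow(data) < 10L) stop("need at least 10 rows to fit content models")
  scope <- as.formula(paste("~ (", paste(terms, collapse = " + "), ")^",
                            max_order))
  all_terms <- attr(terms(scope), "term.labels")
  fit <- lm(as.formula(paste(response, "~ 1")), data = data)
  included <- character(0)
  # term labels come back from add1/drop1 in model order (w:x vs x:w), so
  # membership is checked on a canonical form
  canon <- function(tt) vapply(strsplit(tt, ":", fixed = TRUE), function(p)
    paste(sort(p), collapse = ":"), character(1))
  trace <- list()
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    # hierarchy: only offer terms whose lower-order components are in
    eligible <- all_terms[!canon(all_terms) %in% canon(included)]
    eligible <- eligible[vapply(eligible, function(tt) {
      comp <- strsplit(tt, ":", fixed = TRUE)[[1]]
      if (length(comp) == 1L) return(TRUE)
      sub <- unlist(lapply(seq_len(length(comp) - 1L), function(k)
        utils::combn(comp, k, paste, collapse = ":")))
      all(canon(sub) %in% canon(included))
    }, logical(1))]
    if (length(eligible) > 0L) {
      ad <- add1(fit, scope = as.formula(paste("~ . +",
                                               paste(eligible, collapse = "+"))),
                 test = "F")
      pv <- ad[["Pr(>F)"]][-1]
      names(pv) <- rownames(ad)[-1]
      pv <- pv[!is.na(pv)]
      if (length(pv) > 0L && min(pv) < alpha_in) {
        term_in <- names(pv)[which.min(pv)]
        fit <- update(fit, as.formula(paste(". ~ . +", term_in)))
        included <- c(included, term_in)
        trace[[length(trace) + 1L]] <- data.table(
          step = it, action = "add", term = term_in, p = min(pv))
        moved <- TRUE
      }
    }
    if (!moved && length(included) > 0L) {
      dr <- drop1(fit, test = "F")  # only non-marginal terms are offered
      pv <- dr[["Pr(>F)"]][-1]
      names(pv) <- rownames(dr)[-1]
      pv <- pv[!is.na(pv)]
      if (length(pv) > 0L && max(pv) > alpha_out) {
        term_out <- names(pv)[which.max(pv)]
        fit <- update(fit, as.formula(paste(". ~ . -", term_out)))
        included <- included[canon(included) != canon(term_out)]
        trace[[length(trace) + 1L]] <- data.table(
          step = it, action = "drop", term = term_out, p = max(pv))
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  sm <- summary(fit)
  ci <- suppressMessages(confint(fit))
  coefs <- data.table(term = rownames(sm$coefficients),
                      estimate = sm$coefficients[, 1],
                      ci_lo = ci[, 1], ci_hi = ci[, 2],
                      t_value = sm$coefficients[, 3],
                      p_value = sm$coefficients[, 4])
  structure(list(fit = fit, included = included, coefficients = coefs,
                 sse = sum(residuals(fit)^2),
                 trace = if (length(trace)) rbindlist(trace) else
                   data.table(step = integer(), action = character(),
                              term = character(), p = numeric())),
            class = "stepwise_mlm")
}

#' @export
print.stepwise_mlm <- function(x, ...) {
  cat("stepwise MLM:", deparse(formula(x$fit)), "\n")
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Subsampled TE content by ploidy
#'
#' Draws `reps` subsamples of `n_per_group` individuals (without
#' replacement) from each ploidy group, counts the insertions carried per
#' individual in each stratum (category group x frequency class), and
#' compares ploidies per stratum with two-sided t-tests across the
#' subsample means.
#'
#' @param states State matrix sites x individuals.
#' @param site_info Classified site table with `freq_class`.
#' @param samples Sample sheet.
#' @param n_per_group Individuals per ploidy per subsample (default 100;
#'   scaled down with a warning if a group is smaller).
#' @param reps Number of subsamples (default 100; at least 2).
#' @param strata Stratification, as in [content_table()].
#' @return data.table per stratum and ploidy: mean and SD of the total
#'   content across subsamples, plus `t_p` and `delta_4x` (4x - 2x).
#' @export
subsampled_content <- function(states, site_info, samples,
                               n_per_group = 100L, reps = 100L,
                               strata = c("cat_group", "freq_class")) {
  if (reps < 2L) stop("reps must be at least 2 (SD undefined otherwise)")
  if (n_per_group < 2L) stop("n_per_group must be at least 2")
  samples <- as.data.table(samples)
  ids2 <- samples[ploidy == 2L, id]
  ids4 <- samples[ploidy == 4L, id]
  n_eff <- min(n_per_group, length(ids2), length(ids4))
  if (n_eff < n_per_group) {
    warning("n_per_group reduced to ", n_eff, " (smallest ploidy group)")
  }
  ct <- content_table(states, site_info, samples, strata = strata)
  scols <- intersect(c("cat_group", "freq_class", "all"), names(ct))
  ct[, stratum := do.call(paste, c(.SD, sep = ".")), .SDcols = scols]
  per_ind <- ct[, .(count = sum(count)), by = .(id, ploidy, stratum)]
  strata_lv <- unique(per_ind$stratum)
  acc <- array(NA_real_, c(reps, length(strata_lv), 2),
               dimnames = list(NULL, strata_lv, c("2", "4")))
  for (r in seq_len(reps)) {
    pick <- c(sample(ids2, n_eff), sample(ids4, n_eff))
    sub <- per_ind[id %in% pick,
                   .(total = sum(count) / n_eff), by = .(ploidy, stratum)]
    for (q in seq_len(nrow(sub))) {
      acc[r, sub$stratum[q], as.character(sub$ploidy[q])] <- sub$total[q]
    }
  }
  rows <- lapply(strata_lv, function(s) {
    a2 <- acc[, s, "2"]; a4 <- acc[, s, "4"]
    a2[is.na(a2)] <- 0; a4[is.na(a4)] <- 0
    tt <- tryCatch(t.test(a4, a2), error = function(e) list(p.value = NA))
    data.table(stratum = s, mean_2x = mean(a2), sd_2x = sd(a2),
               mean_4x = mean(a4), sd_4x = sd(a4),
               delta_4x = mean(a4) - mean(a2), t_p = tt$p.value)
  })
  rbindlist(rows)
}

#' Family-level transposition-burst test
#'
#' For every TE family with more than `min_copies` non-reference
#' insertions in each ploidy group, compares the proportion of
#' high-frequency (HF) non-genic insertions between tetraploids and
#' diploids with a 2x2 chi-square. A family is flagged when p < `alpha`
#' with an HF excess in the tetraploids — the hallmark a family-specific
#' transposition burst at the time of genome duplication would leave.
#'
#' @param states State matrix sites x individuals.
#' @param site_info Classified site table (`family`, `category`).
#' @param samples Sample sheet.
#' @param classes `freq_classes` from the diploid spectrum; if `NULL`,
#'   computed from the diploid cohort frequencies.
#' @param min_copies Strict lower bound on per-ploidy family copy number
#'   (default 10, i.e. families need >= 11 copies present per group).
#' @param alpha Significance threshold on the raw per-family p-value
#'   (default 0.05); a Benjamini-Hochberg column is always reported.
#' @return data.table per eligible family: copies and HF proportions per
#'   ploidy, `chi2_p`, `bh_q`, `excess_4x`, `flagged`.
#' @export
burst_family_test <- function(states, site_info, samples, classes = NULL,
                              min_copies = 10L, alpha = 0.05) {
  samples <- as.data.table(samples)
  site_info <- as.data.table(site_info)
  ids2 <- samples[ploidy == 2L, id]
  ids4 <- samples[ploidy == 4L, id]
  st2 <- states[, ids2, drop = FALSE]
  st4 <- states[, ids4, drop = FALSE]
  present2 <- rowSums(st2 == "C", na.rm = TRUE) > 0L
  present4 <- rowSums(st4 == "C", na.rm = TRUE) > 0L
  f2 <- suppressWarnings(carrier_frequency(st2))
  f4 <- suppressWarnings(carrier_frequency(st4))
  if (is.null(classes)) classes <- lf_hf_classes(f2[present2])
  info <- site_info[match(rownames(states), site_id)]
  non_genic <- category_group(info$category) == "non_genic"
  fams <- info[, .(n2 = sum(present2[.I]), n4 = sum(present4[.I])),
               by = family]
  eligible <- fams[n2 > min_copies & n4 > min_copies, family]
  if (length(eligible) == 0L) {
    warning("no family has more than ", min_copies,
            " copies in both ploidy groups")
    return(data.table(family = character(), n2 = integer(), n4 = integer(),
                      hf2 = integer(), hf4 = integer(), prop_hf_2x = numeric(),
                      prop_hf_4x = numeric(), chi2_p = numeric(),
                      bh_q = numeric(), excess_4x = logical(),
                      flagged = logical()))
  }
  rows <- lapply(eligible, function(fm) {
    sel2 <- info$family == fm & non_genic & present2
    sel4 <- info$family == fm & non_genic & present4
    hf2 <- sum(frequency_class(f2[sel2], classes) == "HF", na.rm = TRUE)
    hf4 <- sum(frequency_class(f4[sel4], classes) == "HF", na.rm = TRUE)
    n2 <- sum(sel2); n4 <- sum(sel4)
    p <- if (n2 > 0L && n4 > 0L && (hf2 + hf4) > 0L &&
             (hf2 + hf4) < (n2 + n4)) {
      chi2_2x2(hf4, n4 - hf4, hf2, n2 - hf2)$p_value
    } else {
      NA_real_
    }
    data.table(family = fm, n2 = n2, n4 = n4, hf2 = hf2, hf4 = hf4,
               prop_hf_2x = ifelse(n2 > 0, hf2 / n2, NA_real_),
               prop_hf_4x = ifelse(n4 > 0, hf4 / n4, NA_real_),
               chi2_p = p)
  })
  out <- rbindlist(rows)
  out[, bh_q := p.adjust(chi2_p, "BH")]
  out[, excess_4x := prop_hf_4x > prop_hf_2x]
  out[, flagged := !is.na(chi2_p) & chi2_p < alpha & excess_4x]
  out[]
}
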