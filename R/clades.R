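#' Classify sites by clade occurrence
#'
#' A site is clade-specific when all its carriers belong to one clade:
#' private if it has exactly one carrier overall, shared if two or more.
#' Sites with carriers in several clades are multi-clade. Clade-specific
#' sites shared by `hf3_min` or more individuals of their clade are at
#' locally high frequency (HF3). NA individuals are excluded from all
#' counts.
#'
#' @param states State matrix sites x individuals.
#' @param samples Sample sheet with a `clade` column covering every
#'   individual.
#' @param hf3_min Minimum local carrier count for the HF3 flag (default 3).
#' @return data.table: site_id, n_carriers, n_clades, clade (of
#'   occurrence, for clade-specific sites), clade_class
#'   (`private`/`shared`/`multi_clade`), local_carriers, hf3.
#' @export
classify_by_clade <- function(states, samples, hf3_min = 3L) {
  samples <- as.data.table(samples)
  if (any(is.na(samples$clade) | samples$clade == "")) {
    stop("individual(s) without clade label: ",
         paste(samples$id[is.na(samples$clade) | samples$clade == ""],
               collapse = ", "))
  }
  clade_of <- setNames(samples$clade, samples$id)
  rows <- lapply(seq_len(nrow(states)), function(i) {
    carriers <- colnames(states)[which(states[i, ] == "C")]
    cl <- unique(clade_of[carriers])
    n <- length(carriers)
    cls <- if (length(cl) > 1L) "multi_clade" else if (n == 1L) "private"
    else "shared"
    data.table(site_id = rownames(states)[i], n_carriers = n,
               n_clades = length(cl),
               clade = if (length(cl) == 1L) cl else NA_character_,
               clade_class = if (n == 0L) NA_character_ else cls,
               local_carriers = if (length(cl) == 1L) n else NA_integer_,
               hf3 = length(cl) == 1L && n >= hf3_min)
  })
  rbindlist(rows)
}

#' Local high-frequency contrast between ploidies
#'
#' Among clade-specific insertions, compares per ploidy the fraction at
#' locally high frequency (HF3) within three compartments: intergenic
#' (including near-gene beyond 250 bp), within-or-near genes (<250 bp),
#' and within-or-near a designated gene class (e.g. stimulus-response
#' genes). Per compartment a 2x2 chi-square contrasts ploidies; the test
#' is skipped (NA) when an expected cell is below `min_expected`. Can be
#' restricted to one superfamily.
#'
#' @param clade_classes Output of [classify_by_clade()].
#' @param site_info Classified site table (`category`, `nearest_gene`,
#'   `gene_distance`, `superfamily`).
#' @param samples Sample sheet (`clade`, `ploidy`).
#' @param gene_class_genes Optional character vector of gene ids forming
#'   the designated class.
#' @param superfamily Optional superfamily restriction.
#' @param near_bp Distance defining "near" (default 250 bp).
#' @param min_expected Minimum expected cell count to run the chi-square.
#' @return data.table per compartment: counts, HF3 proportions per ploidy
#'   and `chi2_p`.
#' @export
local_selection_contrast <- function(clade_classes, site_info, samples,
                                     gene_class_genes = NULL,
                                     superfamily = NULL, near_bp = 250L,
                                     min_expected = 1) {
  samples <- as.data.table(samples)
  site_info <- as.data.table(site_info)
  clade_ploidy <- samples[, .(ploidy = ploidy[1]), by = clade]
  if (nrow(samples[, .N, by = .(clade, ploidy)]) != nrow(clade_ploidy)) {
    stop("clades must not mix ploidies")
  }
  dt <- merge(clade_classes[clade_class %in% c("private", "shared")],
              site_info, by = "site_id")
  dt <- merge(dt, clade_ploidy, by = "clade")
  if (!is.null(superfamily)) {
    dt <- dt[dt$superfamily == superfamily]
  }
  genic_near <- dt$category %in% c(GENIC_CATEGORIES, NEAR_CATEGORIES)
  dt[, compartment := ifelse(genic_near, "genic_near", "intergenic")]
  comps <- list(intergenic = dt[compartment == "intergenic"],
                genic_near = dt[compartment == "genic_near"])
  if (!is.null(gene_class_genes)) {
    comps$gene_class <- dt[compartment == "genic_near" &
                             nearest_gene %in% gene_class_genes]
  }
  rows <- lapply(names(comps), function(cp) {
    d <- comps[[cp]]
    res <- data.table(compartment = cp,
                      n_2x = nrow(d[ploidy == 2L]),
                      n_4x = nrow(d[ploidy == 4L]),
                      hf3_2x = nrow(d[ploidy == 2L & hf3 == TRUE]),
                      hf3_4x = nrow(d[ploidy == 4L & hf3 == TRUE]))
    if (res$n_2x == 0L || res$n_4x == 0L) {
      warning("empty compartment ", cp, " in one ploidy; proportions NA")
      res[, c("prop_2x", "prop_4x", "chi2_p") :=
            .(ifelse(n_2x > 0, hf3_2x / n_2x, NA_real_),
              ifelse(n_4x > 0, hf3_4x / n_4x, NA_real_), NA_real_)]
      return(res)
    }
    res[, prop_2x := hf3_2x / n_2x]
    res[, prop_4x := hf3_4x / n_4x]
    tab <- rbind(c(res$hf3_4x, res$n_4x - res$hf3_4x),
                 c(res$hf3_2x, res$n_2x - res$hf3_2x))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    res[, chi2_p := if (any(colSums(tab) == 0) || any(expected < min_expected))
      NA_real_ else chi2_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])$p_value]
    res
  })
  rbindlist(rows, fill = TRUE)
}

#' Hypergeometric gene-class enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a target gene set
#' (e.g. genes within 250 bp of insertions of interest) and each gene
#' class of an annotation table, within a stated gene universe.
#' Benjamini-Hochberg q-values are reported alongside raw p-values. An
#' optional length-matched resampling null draws random gene sets matching
#' the target's length-decile profile and reports an empirical p-value,
#' controlling for gene-length confounding.
#'
#' @param target Character vector of target gene ids (must be a subset of
#'   `universe`).
#' @param gene_classes data.table with columns `gene_id`, `class`.
#' @param universe Character vector of all considered gene ids.
#' @param gene_lengths Optional named vector of gene lengths enabling the
#'   length-matched null.
#' @param n_resample Draws for the length-matched null (default 10000).
#' @return data.table per class: class size in universe, overlap, fold
#'   enrichment, `p_value`, `bh_q`, and `p_length_matched` when lengths
#'   are supplied.
#' @export
gene_class_enrichment <- function(target, gene_classes, universe,
                                  gene_lengths = NULL, n_resample = 10000L) {
  target <- unique(target)
  universe <- unique(universe)
  off <- setdiff(target, universe)
  if (length(off) > 0L) {
    stop("target genes outside the universe: ", paste(off, collapse = ", "))
  }
  gene_classes <- as.data.table(gene_classes)[gene_id %in% universe]
  N <- length(universe)
  n_t <- length(target)
  cls <- split(gene_classes$gene_id, gene_classes$class)
  cls <- cls[vapply(cls, length, integer(1)) > 0L]  # classes void in universe
  null_draws <- NULL
  if (!is.null(gene_lengths)) {
    dec <- cut(rank(gene_lengths[universe], ties.method = "first"),
               breaks = 10, labels = FALSE)
    names(dec) <- universe
    pool <- split(universe, dec)
    prof <- table(factor(dec[target], levels = 1:10))
    null_draws <- replicate(n_resample, unlist(lapply(1:10, function(d)
      if (prof[d] > 0L) sample(pool[[as.character(d)]], prof[d]) else NULL),
      use.names = FALSE), simplify = FALSE)
  }
  rows <- lapply(names(cls), function(cl) {
    members <- unique(cls[[cl]])
    K <- length(members)
    k <- length(intersect(target, members))
    p <- phyper(k - 1L, K, N - K, n_t, lower.tail = FALSE)
    fold <- (k / n_t) / (K / N)
    out <- data.table(class = cl, class_size = K, overlap = k,
                      fold = fold, p_value = p)
    if (!is.null(null_draws)) {
      null_k <- vapply(null_draws, function(g)
        length(intersect(g, members)), integer(1))
      out[, p_length_matched := (1 + sum(null_k >= k)) / (1 + n_resample)]
    }
    out
  })
  out <- rbindlist(rows)
  out[, bh_q := p.adjust(p_value, "BH")]
  setorder(out, p_value)
  out[]
}
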