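#' Run the full synthetic-to-analysis pipeline
#'
#' Executes the stages `simulate` (genome, population, reads,
#' expression), `detect`, `landscape`, `stats`, `clades` and
#' `expression` in dependency order, writing each stage's tables under
#' its own sub-directory of `out_dir` together with a resolved
#' configuration snapshot and a run log. Each stage records the
#' parameters it ran with; on re-runs with `resume = TRUE`, stages whose
#' parameters and outputs are unchanged are skipped, and any parameter
#' change re-executes that stage and everything downstream.
#'
#' @param config A [sim_config()], a list of `sim_config` arguments, or a
#'   path to a YAML file of them.
#' @param out_dir Output directory.
#' @param detect_args Named list of overrides for [detect_insertions()]
#'   thresholds.
#' @param arm_threshold Arm distance threshold (bp) for the landscape
#'   stage; defaults to the configured pericentromere half-width, i.e.
#'   "arm" means beyond the pericentromere on the synthetic genome.
#' @param resume Skip up-to-date stages (default TRUE).
#' @return Invisibly, a list with the key in-memory artifacts of the run.
#' @export
run_pipeline <- function(config, out_dir, detect_args = list(),
                         arm_threshold = NULL, resume = TRUE) {
  cfg <- if (inherits(config, "sim_config")) config
  else if (is.character(config)) do.call(sim_config, yaml::read_yaml(config))
  else do.call(sim_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pdir <- file.path(out_dir, ".params")
  dir.create(pdir, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                            "\n", file = log_path, append = TRUE)
  if (is.null(arm_threshold)) arm_threshold <- cfg$pericentromere_halfwidth

  snap <- cfg
  snap$clades <- as.list(as.data.frame(snap$clades))
  class(snap) <- NULL
  yaml::write_yaml(snap, file.path(out_dir, "config_resolved.yaml"))

  stage_key <- function(stage, params) {
    as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = 12))
  }
  invalidated <- FALSE
  stage_fresh <- function(stage, params, outputs) {
    key_file <- file.path(pdir, paste0(stage, ".json"))
    key <- stage_key(stage, params)
    fresh <- resume && !invalidated && file.exists(key_file) &&
      identical(readLines(key_file, warn = FALSE), key) &&
      all(file.exists(outputs))
    if (!fresh) invalidated <<- TRUE
    fresh
  }
  stage_done <- function(stage, params) {
    writeLines(stage_key(stage, params), file.path(pdir,
                                                   paste0(stage, ".json")))
  }

  sim_dir <- file.path(out_dir, "sim")
  sim_outputs <- file.path(sim_dir, c("reference.fa", "annotation.gff3",
                                      "samples.tsv", "truth_insertions.tsv",
                                      "expression.tsv"))
  sim_params <- snap
  art <- list(config = cfg)
  if (stage_fresh("simulate", sim_params, sim_outputs)) {
    logf("simulate: up to date, skipped")
    genome <- simulate_genome(cfg)
    truth <- simulate_population(genome, cfg)
    art$bams <- read_bam_list(file.path(sim_dir, "bam_paths.txt"))
  } else {
    logf("simulate: seed", cfg$seed)
    genome <- simulate_genome(cfg)
    truth <- simulate_population(genome, cfg)
    write_genome_files(genome, sim_dir)
    write_truth_files(truth, sim_dir)
    reads <- simulate_reads(truth, genome, file.path(sim_dir, "alignments"))
    bams <- vapply(reads$sam, sam_to_bam, character(1))
    names(bams) <- names(reads$sam)
    writeLines(paste(names(bams), bams, sep = "\t"),
               file.path(sim_dir, "bam_paths.txt"))
    expr <- simulate_expression(truth, genome, cfg)
    write_expression(expr, file.path(sim_dir, "expression.tsv"))
    art$bams <- bams
    art$reads_evidence <- reads$evidence
    stage_done("simulate", sim_params)
  }
  art$genome <- genome
  art$truth <- truth

  det_dir <- file.path(out_dir, "detect")
  det_params <- c(detect_args, list(seed = cfg$seed))
  det_out <- file.path(det_dir, c("sites.tsv", "states.tsv", "sites.bed"))
  if (stage_fresh("detect", det_params, det_out)) {
    logf("detect: up to date, skipped")
    sites <- read_site_table(det_out[1])
    states <- read_state_matrix(det_out[2])
  } else {
    logf("detect: ", length(art$bams), "alignments")
    dir.create(det_dir, showWarnings = FALSE)
    det <- do.call(detect_insertions,
                   c(list(bam_files = art$bams,
                          te_library = genome$te_library,
                          samples = truth$samples), detect_args))
    sites <- det$sites
    states <- det$states
    write_site_table(sites, det_out[1])
    write_state_matrix(states, det_out[2])
    write_site_bed(sites, det_out[3])
    stage_done("detect", det_params)
  }
  art$sites <- sites
  art$states <- states

  with_stage_seed(cfg, "pipeline", {
    land_dir <- file.path(out_dir, "landscape")
    dir.create(land_dir, showWarnings = FALSE)
    samples <- truth$samples
    info <- classify_sites(sites, genome$annotation,
                           arm_threshold = arm_threshold)
    ids2 <- samples[samples$ploidy == 2L, ][["id"]]
    ids4 <- samples[samples$ploidy == 4L, ][["id"]]
    f2 <- suppressWarnings(
      carrier_frequency(states[, ids2, drop = FALSE]))
    f4 <- suppressWarnings(
      carrier_frequency(states[, ids4, drop = FALSE]))
    classes <- lf_hf_classes(f2[!is.na(f2) & f2 > 0])
    info[, freq_class := frequency_class(carrier_freq, classes)]
    info[, freq_class_2x := frequency_class(f2, classes)]
    info[, freq_class_4x := frequency_class(f4, classes)]
    write_tsv(info, file.path(land_dir, "annotated_sites.tsv"))
    dens <- density_profile(info, genome$annotation$seqlengths)
    write_tsv(dens, file.path(land_dir, "density_100kb.tsv"))
    fp <- reference_category_footprint(genome$annotation)
    write_tsv(fp, file.path(land_dir, "category_footprint.tsv"))
    logf("landscape:", nrow(info), "sites; LF<=", classes$lf_threshold,
         "HF>=", classes$hf_threshold)
    art$site_info <- info
    art$freq_classes <- classes

    stats_dir <- file.path(out_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    ct <- content_table(states, info, samples)
    mlm <- fit_stepwise_mlm(ct, "count",
                            c("haplo_coverage", "ploidy", "cat_group"))
    write_tsv(mlm$coefficients, file.path(stats_dir, "mlm_coefficients.tsv"))
    write_tsv(mlm$trace, file.path(stats_dir, "mlm_trace.tsv"))
    n_sub <- min(100L, sum(samples$ploidy == 2L), sum(samples$ploidy == 4L))
    sub <- suppressWarnings(
      subsampled_content(states, info, samples, n_per_group = n_sub))
    write_tsv(sub, file.path(stats_dir, "subsampled_content.tsv"))
    burst <- suppressWarnings(
      burst_family_test(states, info, samples, classes = classes))
    write_tsv(burst, file.path(stats_dir, "burst_families.tsv"))
    hw <- rbindlist(lapply(c(2L, 4L), function(pl)
      data.table(ploidy = pl,
                 f = c(0.01, 0.05, 0.122, 0.5),
                 p = vapply(c(0.01, 0.05, 0.122, 0.5), function(f)
                   hw_convert(f = f, ploidy = pl)$p, numeric(1)))))
    write_tsv(hw, file.path(stats_dir, "hw_table.tsv"))
    logf("stats: mlm terms [", paste(mlm$included, collapse = ", "), "]")
    art$content <- ct
    art$mlm <- mlm
    art$subsampled <- sub
    art$burst <- burst

    clades_dir <- file.path(out_dir, "clades")
    dir.create(clades_dir, showWarnings = FALSE)
    cc <- classify_by_clade(states, samples)
    write_tsv(cc, file.path(clades_dir, "clade_classes.tsv"))
    contrast <- suppressWarnings(
      local_selection_contrast(cc, info, samples))
    write_tsv(contrast, file.path(clades_dir, "hf3_contrast.tsv"))
    art$clade_classes <- cc
    art$contrast <- contrast

    expr_dir <- file.path(out_dir, "expression")
    dir.create(expr_dir, showWarnings = FALSE)
    expr_dt <- read_tsv_table(file.path(sim_dir, "expression.tsv"))
    expr_m <- as.matrix(expr_dt[, -1, drop = FALSE])
    rownames(expr_m) <- expr_dt$gene_id
    genic <- cnc_ratios(expr_m, info, states, samples, tier = "genic")
    inter <- cnc_ratios(expr_m, info, states, samples, tier = "intergenic")
    write_tsv(genic, file.path(expr_dir, "cnc_genic.tsv"))
    write_tsv(inter, file.path(expr_dir, "cnc_intergenic.tsv"))
    tst <- tryCatch(cnc_tests(genic, inter, expr_m, samples),
                    error = function(e) NULL)
    if (!is.null(tst)) {
      write_tsv(data.table(
        comparison = c("vs_random", "vs_intergenic"),
        statistic = c(tst$ks_random$statistic, tst$ks_intergenic$statistic),
        p_value = c(tst$ks_random$p_value, tst$ks_intergenic$p_value)),
        file.path(expr_dir, "cnc_tests.tsv"))
    }
    art$cnc <- list(genic = genic, intergenic = inter, tests = tst)
  })
  logf("pipeline complete")
  invisible(art)
}

# tiny helper: read the "id\tpath" table written for the BAM list
read_bam_list <- function(path) {
  ln <- readLines(path)
  parts <- strsplit(ln, "\t", fixed = TRUE)
  setNames(vapply(parts, `[`, character(1), 2),
           vapply(parts, `[`, character(1), 1))
}
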