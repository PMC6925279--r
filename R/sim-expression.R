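#' Simulate an expression matrix with cis insertion effects
#'
#' Gives every gene a log-normal baseline expression and multiplies an
#' individual's expression by `expression_effect` for every carried
#' insertion lying within the gene or closer than `expr_near_bp`
#' (default 250 bp) to it. Insertions 2 kb or further away have no effect,
#' so the intergenic tier acts as a built-in negative control.
#'
#' @param truth A `sim_truth` from [simulate_population()].
#' @param genome The `sim_genome` the truth was planted on.
#' @param cfg Optional [sim_config()]; defaults to `truth$config`.
#' @return Numeric matrix genes x individuals, with attribute
#'   `"affected"`: a data.table (gene_id, ins_id, distance) of the
#'   gene/insertion pairs subject to the cis effect.
#' @export
simulate_expression <- function(truth, genome, cfg = truth$config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(genome, "sim_genome"))
  with_stage_seed(cfg, "expression", {
    genes <- genome$annotation$genes
    samples <- truth$samples
    n_g <- length(genes)
    if (n_g == 0L) stop("annotation has no genes to express")
    base <- rlnorm(n_g, cfg$expr_meanlog, cfg$expr_sdlog)
    ins_gr <- GRanges(truth$insertions$chrom,
                      IRanges(truth$insertions$pos, width = 1L))
    hits <- findOverlaps(genes, ins_gr, maxgap = cfg$expr_near_bp)
    affected <- data.table(
      gene_id = mcols(genes)$gene_id[queryHits(hits)],
      ins_id = truth$insertions$ins_id[subjectHits(hits)],
      distance = distance(genes[queryHits(hits)], ins_gr[subjectHits(hits)]))
    carrier <- truth$dosage >= 1L
    expr <- matrix(rep(base, nrow(samples)), n_g, nrow(samples),
                   dimnames = list(mcols(genes)$gene_id, samples$id))
    if (nrow(affected) > 0L) {
      for (r in seq_len(nrow(affected))) {
        gi <- match(affected$gene_id[r], rownames(expr))
        carried <- carrier[affected$ins_id[r], ]
        expr[gi, carried] <- expr[gi, carried] * cfg$expression_effect
      }
    }
    noise <- matrix(rlnorm(length(expr), 0, cfg$expr_noise_sdlog),
                    nrow(expr), ncol(expr))
    expr <- expr * noise
    attr(expr, "affected") <- affected
    expr
  })
}

#' Write an expression matrix as TSV
#' @param expr Matrix from [simulate_expression()] (genes x individuals).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table(gene_id = rownames(expr))
  dt <- cbind(dt, as.data.table(unclass(expr)[seq_len(nrow(expr)), , drop = FALSE]))
  write_tsv(dt, path)
  invisible(path)
}
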