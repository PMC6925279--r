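#' TSV readers and writers
#'
#' All tabular artifacts use one dialect: tab-separated, UTF-8, `.` decimal
#' separator, with a single `#`-prefixed header line.
#'
#' @param x A data.frame / data.table.
#' @param path File path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv_table` returns a
#'   data.table.
#' @export
write_tsv <- function(x, path) {
  con <- file(path, "wb")
  writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  close(con)
  fwrite(x, path, sep = "\t", quote = FALSE, col.names = FALSE,
         append = TRUE, eol = "\n", na = "NA")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_table <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#")) stop("missing '#' header line in ", path)
  cols <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  dt <- fread(path, sep = "\t", skip = 1L, header = FALSE, na.strings = "NA")
  if (ncol(dt) != length(cols)) stop("malformed TSV at ", path,
                                     ": header/body column mismatch")
  setnames(dt, cols)
  dt
}

#' Read a sample sheet
#'
#' Columns: `id`, `population`, `clade`, `ploidy`, `coverage`.
#' @param path Path to the TSV sample sheet.
#' @return data.table.
#' @export
read_sample_sheet <- function(path) {
  dt <- read_tsv_table(path)
  need <- c("id", "population", "clade", "ploidy", "coverage")
  miss <- setdiff(need, names(dt))
  if (length(miss) > 0L) stop("sample sheet lacks columns: ",
                              paste(miss, collapse = ", "))
  dt[, ploidy := as.integer(ploidy)]
  dt
}

#' Convert, sort and index a SAM file
#'
#' Thin wrapper around [Rsamtools::asBam()] producing a coordinate-sorted,
#' indexed BAM next to (or at) the requested destination.
#'
#' @param sam Path to a SAM file.
#' @param destination Output path without the `.bam` extension; defaults to
#'   the SAM path minus its extension.
#' @return Path to the BAM file.
#' @export
sam_to_bam <- function(sam, destination = sub("\\.sam$", "", sam)) {
  if (!file.exists(sam)) stop("no such SAM file: ", sam)
  asBam(sam, destination, overwrite = TRUE, indexDestination = TRUE)
}

#' Write / read a site table
#'
#' The site table lists retained insertion sites with 1-based inclusive
#' breakpoint intervals: columns `site_id, chrom, start, end, family,
#' superfamily, type, name, carrier_freq`.
#'
#' @param sites data.table as produced by [detect_insertions()].
#' @param path File path.
#' @return See [write_tsv()].
#' @export
write_site_table <- function(sites, path) write_tsv(sites, path)

#' @rdname write_site_table
#' @export
read_site_table <- function(path) read_tsv_table(path)

#' Write / read a state matrix
#'
#' States are written individuals x sites with values `C`, `N` or `NA`.
#' Internally the package keeps states as a sites x individuals character
#' matrix; `read_state_matrix` returns that orientation.
#'
#' @param states Character matrix, sites x individuals.
#' @param path File path.
#' @export
write_state_matrix <- function(states, path) {
  dt <- data.table(id = colnames(states))
  dt <- cbind(dt, as.data.table(t(states)))
  write_tsv(dt, path)
}

#' @rdname write_state_matrix
#' @export
read_state_matrix <- function(path) {
  dt <- read_tsv_table(path)
  m <- t(as.matrix(dt[, -1, drop = FALSE]))
  colnames(m) <- dt$id
  mode(m) <- "character"
  m
}

#' Export sites as BED
#'
#' Writes the breakpoint intervals 0-based half-open with the site name as
#' the BED name field.
#' @param sites Site table (data.table).
#' @param path Output path.
#' @export
write_site_bed <- function(sites, path) {
  gr <- GRanges(sites$chrom, IRanges(sites$start, sites$end),
                name = sites$name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
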