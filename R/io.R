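# On-disk formats. BED and bedGraph are 0-based half-open; report tables
# (calls TSV, starts TSV) use 1-based positions; internal objects are
# always 0-based. Writers prepend '#' comment headers, readers skip them.

write_header <- function(con, what, extra = NULL) {
  cat(sprintf("# nucspacing %s | %s\n", what,
              format(Sys.time(), "%Y-%m-%d")), file = con)
  if (!is.null(extra)) cat(sprintf("# %s\n", extra), file = con, append = TRUE)
}

#' Read aligned MNase fragments
#'
#' Reads either a BED3+ file of fragment intervals (0-based half-open) or
#' a stranded start-count table with columns chromosome, position
#' (1-based in the file), strand (`F`/`R`) and count.
#'
#' @param path File path.
#' @param format `"bed"` or `"starts"`.
#' @param chrom_lengths Named chromosome lengths; required for
#'   `format = "starts"` (a `start_track` is returned), optional for BED.
#' @return For `"bed"`, a fragment data.frame (`chrom`, `start`, `end`);
#'   for `"starts"`, a `start_track`.
#' @export
read_fragments <- function(path, format = c("bed", "starts"),
                           chrom_lengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (format == "bed") {
    if (ncol(tab) < 3L) stopf("%s: BED needs >= 3 columns", path)
    out <- data.frame(chrom = as.character(tab[[1L]]),
                      start = as.integer(tab[[2L]]),
                      end = as.integer(tab[[3L]]),
                      stringsAsFactors = FALSE)
    bad <- which(is.na(out$start) | is.na(out$end) | out$start < 0 |
                   out$start >= out$end)
    if (length(bad)) stopf("%s: malformed BED interval at data line %d",
                           path, bad[1])
    out
  } else {
    if (is.null(chrom_lengths))
      stopf("chrom_lengths is required for starts format")
    if (ncol(tab) < 4L) stopf("%s: starts table needs 4 columns", path)
    starts <- data.frame(chrom = as.character(tab[[1L]]),
                         pos = as.integer(tab[[2L]]) - 1L,  # 1-based on disk
                         strand = as.character(tab[[3L]]),
                         count = as.integer(tab[[4L]]),
                         stringsAsFactors = FALSE)
    start_track_from_counts(starts, chrom_lengths)
  }
}

#' Write fragments as BED3
#' @param fragments Fragment data.frame.
#' @param path Output path.
#' @param header Optional extra header line (e.g. config hash and seed).
#' @export
write_fragments_bed <- function(fragments, path, header = NULL) {
  write_header(path, "fragments BED3 (0-based half-open)", header)
  utils::write.table(fragments[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED6 gene annotation
#'
#' @param path BED6 file: chrom, start, end, name, score, strand.
#' @return Gene data.frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_genes_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stopf("%s: gene BED needs 6 columns", path)
  bad <- which(!tab[[6L]] %in% c("+", "-"))
  if (length(bad)) stopf("%s: bad strand at data line %d", path, bad[1])
  data.frame(gene_id = as.character(tab[[4L]]),
             chrom = as.character(tab[[1L]]),
             start = as.integer(tab[[2L]]),
             end = as.integer(tab[[3L]]),
             strand = as.character(tab[[6L]]),
             stringsAsFactors = FALSE)
}

#' Write a BED6 gene annotation
#' @param genes Gene data.frame.
#' @inheritParams write_fragments_bed
#' @export
write_genes_bed <- function(genes, path, header = NULL) {
  write_header(path, "genes BED6 (0-based half-open)", header)
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Write an occupancy track as bedGraph
#' @param track An `occupancy_track`.
#' @inheritParams write_fragments_bed
#' @export
write_bedgraph <- function(track, path, header = NULL) {
  write_header(path, "occupancy bedGraph (0-based half-open)", header)
  for (cn in names(track$values)) {
    v <- track$values[[cn]]
    r <- rle(v)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    utils::write.table(data.frame(cn, start[keep], end[keep],
                                  signif(r$values[keep], 8)),
                       path, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Write nucleosome calls as TSV (1-based positions)
#' @param calls A `nucleosome_calls` data.frame.
#' @inheritParams write_fragments_bed
#' @export
write_calls_tsv <- function(calls, path, header = NULL) {
  write_header(path, "nucleosome calls (dyad 1-based)", header)
  out <- data.frame(chrom = calls$chrom, dyad = calls$dyad + 1L,
                    score = calls$score,
                    template_length = calls$template_length)
  suppressWarnings(utils::write.table(out, path, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE,
                                      append = TRUE))
  invisible(path)
}

#' Read a nucleosome-calls TSV written by [write_calls_tsv()]
#' @param path File path.
#' @return A `nucleosome_calls` data.frame (0-based dyads).
#' @export
read_calls_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  out <- data.frame(chrom = as.character(tab$chrom),
                    dyad = as.integer(tab$dyad) - 1L,
                    score = as.numeric(tab$score),
                    template_length = as.integer(tab$template_length),
                    stringsAsFactors = FALSE)
  class(out) <- c("nucleosome_calls", "data.frame")
  out
}

#' Write a truth map as JSON
#' @param map A `true_nucleosome_map`.
#' @param path Output path.
#' @export
write_truth_json <- function(map, path) {
  obj <- list(
    chrom_lengths = as.list(map$genome$chrom_lengths),
    genes = map$genome$genes,
    dyads = map$dyads,
    ndr = map$ndr,
    perturbation = map$perturbation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read per-gene scores from a two-column TSV
#' @param path TSV with columns gene id and numeric score.
#' @return Data.frame `gene_id`, `score`.
#' @export
read_scores_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("%s: scores table needs 2 columns", path)
  data.frame(gene_id = as.character(tab[[1L]]),
             score = as.numeric(tab[[2L]]), stringsAsFactors = FALSE)
}
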