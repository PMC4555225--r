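# +1-aligned occupancy metaprofiles.

#' +1-aligned gene metaprofile of normalized occupancy
#'
#' For each mapped gene, extracts normalized coverage from `upstream` bp
#' upstream of the +1 nucleosome's upstream edge to the end of the gene
#' (mirrored for minus-strand genes so that transcription runs left to
#' right), averages it in `bin` bp bins (a final partial bin is
#' dropped), and averages across genes per bin over the genes long
#' enough to cover that bin.
#'
#' @param track A normalized `occupancy_track`.
#' @param maps A `gene_nuc_maps` object carrying the +1 calls.
#' @param upstream Bp upstream of the +1 edge where bin 0 starts.
#' @param bin Bin width, bp.
#' @return List of class `metaprofile`: `bin`, `upstream`, `profile`
#'   (mean normalized occupancy per bin), `n_genes_per_bin`, and `rows`
#'   (gene x bin matrix, NA-padded).
#' @export
plus1_aligned_metaprofile <- function(track, maps, upstream = 500L,
                                      bin = 10L) {
  stopifnot(inherits(track, "occupancy_track"),
            inherits(maps, "gene_nuc_maps"))
  if (bin <= 0) stopf("bin must be > 0")
  if (!isTRUE(track$normalized))
    warning("metaprofile computed on an unnormalized track")
  rows <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    v <- track$values[[m$chrom]]
    L <- length(v)
    half <- m$footprint %/% 2L
    if (m$strand == "+") {
      edge <- m$plus1$dyad - half
      gpos <- (edge - upstream):(m$end - 1L)
    } else {
      edge <- m$plus1$dyad + half
      gpos <- (edge + upstream):m$start
    }
    vals <- rep(NA_real_, length(gpos))
    ok <- gpos >= 0L & gpos < L
    vals[ok] <- v[gpos[ok] + 1L]
    nb <- length(vals) %/% bin
    if (nb < 1L) next
    mat <- matrix(vals[seq_len(nb * bin)], nrow = bin)
    rows[[i]] <- colMeans(mat)
  }
  widths <- vapply(rows, length, integer(1))
  nb_max <- max(widths, 0L)
  if (nb_max == 0L) stopf("no gene produced a complete bin")
  rowmat <- t(vapply(rows, function(r) c(r, rep(NA_real_, nb_max - length(r))),
                     numeric(nb_max)))
  rownames(rowmat) <- names(maps)
  structure(list(bin = as.integer(bin), upstream = as.integer(upstream),
                 profile = colMeans(rowmat, na.rm = TRUE),
                 n_genes_per_bin = colSums(!is.na(rowmat)),
                 rows = rowmat),
            class = "metaprofile")
}
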