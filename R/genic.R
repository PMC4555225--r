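# Gene-anchored nucleosome architecture: promoter NDR detection, -1/+1
# designation, genic nucleosome indexing, spacing metrics and nucleosome
# repeat length estimation.
#
# Transcriptional ("rel") coordinates are bp from the coding start,
# positive downstream: rel = dyad - start on the + strand and
# rel = (end - 1) - dyad on the - strand. Linker length between two calls
# is operationalized throughout as center-to-center distance - footprint.

#' Anchor nucleosome calls to genes via the promoter NDR
#'
#' For each gene, scans calls up to `max_upstream` bp upstream of the
#' coding start for the promoter nucleosome-depleted region: the first
#' adjacent call pair whose linker (center distance - `footprint`)
#' exceeds `ndr_linker` bp. The downstream member of that pair becomes
#' the +1 nucleosome, the upstream member the -1; all calls from the +1
#' to the gene end (in transcriptional direction) become the genic
#' nucleosomes +1, +2, ... . When several pairs qualify within the
#' window, the one whose downstream member lies closest to the coding
#' start is used. Minus-strand genes are handled by a mirrored scan.
#' Genes with no qualifying NDR (or no calls) are excluded and reported.
#'
#' @param calls A `nucleosome_calls` data.frame (or any data.frame with
#'   `chrom` and `dyad`).
#' @param genes Gene table: data.frame with `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open).
#' @param max_upstream Scan window upstream of the coding start, bp.
#' @param ndr_linker Minimum linker length defining an NDR, bp (strictly
#'   greater than).
#' @param footprint Nucleosome footprint used to convert center distances
#'   to linker lengths, bp.
#' @return An object of class `gene_nuc_maps`: a named list of per-gene
#'   maps (each with `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `minus1`, `plus1` (lists with `dyad`, `rel`), and `genic`, a
#'   data.frame `index`, `dyad`, `rel`), with an `excluded` attribute
#'   (data.frame `gene_id`, `reason`).
#' @examples
#' calls <- data.frame(chrom = "chr1", dyad = c(700, 950, 1120))
#' genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000,
#'                     end = 3000, strand = "+")
#' maps <- map_gene_nucleosomes(calls, genes)
#' maps$g1$plus1$dyad  # 950
#' @export
map_gene_nucleosomes <- function(calls, genes, max_upstream = 500L,
                                 ndr_linker = 100L, footprint = 147L) {
  stopifnot(all(c("chrom", "dyad") %in% names(calls)),
            all(c("gene_id", "chrom", "start", "end", "strand") %in%
                  names(genes)))
  half <- footprint %/% 2L
  maps <- list()
  excluded <- list()
  calls_by_chrom <- split(calls$dyad, calls$chrom)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    len <- g$end - g$start
    dy <- calls_by_chrom[[g$chrom]]
    if (is.null(dy) || !length(dy)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(gene_id = g$gene_id, reason = "no_calls")
      next
    }
    rel <- if (g$strand == "+") dy - g$start else (g$end - 1L) - dy
    ord <- order(rel)
    rel <- rel[ord]
    dy <- dy[ord]
    # adjacent pairs whose downstream member can serve as +1
    cand <- which(rel >= -max_upstream & rel < len)
    cand <- cand[cand >= 2L]
    if (!length(cand)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(gene_id = g$gene_id, reason = "no_ndr")
      next
    }
    linker <- rel[cand] - rel[cand - 1L] - footprint
    qual <- cand[linker > ndr_linker]
    if (!length(qual)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(gene_id = g$gene_id, reason = "no_ndr")
      next
    }
    j <- qual[which.min(abs(rel[qual]))]
    genic_idx <- which(rel >= rel[j] & rel < len)
    genic <- data.frame(index = seq_along(genic_idx),
                        dyad = dy[genic_idx], rel = rel[genic_idx])
    maps[[g$gene_id]] <- list(
      gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end,
      minus1 = list(dyad = dy[j - 1L], rel = rel[j - 1L]),
      plus1 = list(dyad = dy[j], rel = rel[j]),
      genic = genic,
      footprint = as.integer(footprint),
      plus1_edge_rel = rel[j] - half)
  }
  excluded <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(gene_id = character(), reason = character())
  structure(maps, excluded = excluded, class = "gene_nuc_maps")
}

#' @export
`[.gene_nuc_maps` <- function(x, i) {
  structure(NextMethod(), excluded = attr(x, "excluded"),
            class = "gene_nuc_maps")
}

#' Per-gene internucleosome spacing metrics
#'
#' For each mapped gene, computes center-to-center distances between
#' adjacent genic nucleosomes, their mean, the +1 to +3 and +3 to +5
#' center distances (when those indices exist), and the distance of each
#' genic nucleosome from the +1 upstream edge (+1 dyad - footprint/2).
#' Genes with fewer than two genic calls get missing distance fields.
#'
#' @param maps A `gene_nuc_maps` object.
#' @return An object of class `spacing_summary`: data.frame with
#'   `gene_id`, `n_genic`, `mean_adjacent`, `d13`, `d35`; the pooled
#'   adjacent-distance sample is in `attr(, "pooled")` and per-call
#'   distances from the +1 edge in `attr(, "edge_distances")`.
#' @export
spacing_metrics <- function(maps) {
  stopifnot(inherits(maps, "gene_nuc_maps"))
  rows <- vector("list", length(maps))
  pooled <- vector("list", length(maps))
  edged <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    r <- m$genic$rel
    adj <- if (length(r) >= 2L) diff(r) else numeric(0)
    d13 <- if (length(r) >= 3L) r[3L] - r[1L] else NA_real_
    d35 <- if (length(r) >= 5L) r[5L] - r[3L] else NA_real_
    rows[[i]] <- data.frame(
      gene_id = m$gene_id, n_genic = length(r),
      mean_adjacent = if (length(adj)) mean(adj) else NA_real_,
      d13 = d13, d35 = d35, stringsAsFactors = FALSE)
    pooled[[i]] <- adj
    edged[[i]] <- data.frame(gene_id = m$gene_id, index = m$genic$index,
                             edge_distance = r - m$plus1_edge_rel,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(gene_id = character(), n_genic = integer(),
               mean_adjacent = numeric(), d13 = numeric(), d35 = numeric())
  rownames(out) <- NULL
  attr(out, "pooled") <- unlist(pooled) %||% numeric(0)
  attr(out, "edge_distances") <- do.call(rbind, edged)
  class(out) <- c("spacing_summary", "data.frame")
  out
}

#' Estimate the nucleosome repeat length by pooled regression
#'
#' Pools, over all genes with at least two genic calls, the distance of
#' each genic nucleosome from its gene's +1 dyad against the nucleosome
#' index, and reports the least-squares slope as the nucleosome repeat
#' length (bp per nucleosome). Only indices up to `max_index` enter the
#' fit.
#'
#' @param maps A `gene_nuc_maps` object.
#' @param max_index Highest genic nucleosome index used.
#' @return List of class `nrl_estimate`: `slope` (the NRL, bp),
#'   `intercept`, `n_genes`, `n_points`, `max_index`.
#' @export
estimate_nrl <- function(maps, max_index = 7L) {
  stopifnot(inherits(maps, "gene_nuc_maps"))
  xs <- list(); ys <- list(); n_genes <- 0L
  for (m in maps) {
    gi <- m$genic[m$genic$index <= max_index, , drop = FALSE]
    if (nrow(gi) < 2L) next
    n_genes <- n_genes + 1L
    xs[[length(xs) + 1L]] <- gi$index - 1L
    ys[[length(ys) + 1L]] <- gi$rel - m$plus1$rel
  }
  if (n_genes < 2L)
    stopf("estimate_nrl needs >= 2 genes with >= 2 genic calls, got %d",
          n_genes)
  x <- unlist(xs); y <- unlist(ys)
  fit <- stats::lm.fit(cbind(1, x), y)
  structure(list(slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L]),
                 n_genes = n_genes, n_points = length(x),
                 max_index = as.integer(max_index)),
            class = "nrl_estimate")
}

#' @export
print.nrl_estimate <- function(x, ...) {
  cat(sprintf("NRL estimate: %.2f bp/nucleosome (intercept %.2f bp, %d genes, %d points, indices <= %d)\n",
              x$slope, x$intercept, x$n_genes, x$n_points, x$max_index))
  invisible(x)
}

#' Empirical CDF of internucleosome distances
#'
#' @param distances Numeric vector of distances (e.g. the pooled sample
#'   from [spacing_metrics()]).
#' @return List of class `spacing_cdf`: `table` (sorted unique distances
#'   with cumulative fraction) and `fun` (right-continuous step function
#'   evaluable at arbitrary x).
#' @examples
#' cdf <- spacing_cdf(c(160, 170))
#' cdf$fun(c(159, 160, 170))  # 0 0.5 1
#' @export
spacing_cdf <- function(distances) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) stopf("spacing_cdf needs at least one distance")
  f <- stats::ecdf(distances)
  x <- sort(unique(distances))
  structure(list(table = data.frame(distance = x, cum_fraction = f(x)),
                 fun = f, n = length(distances)),
            class = "spacing_cdf")
}

#' Mean linker length of a mapped dataset
#'
#' Pooled mean adjacent center-to-center distance minus the footprint.
#'
#' @param maps A `gene_nuc_maps` object.
#' @param footprint Footprint subtracted from center distances, bp.
#' @return Mean linker length, bp.
#' @export
mean_linker <- function(maps, footprint = 147L) {
  pooled <- attr(spacing_metrics(maps), "pooled")
  if (!length(pooled)) stopf("no adjacent distances available")
  mean(pooled) - footprint
}

#' Stratify genes into quantile groups by a numeric score
#'
#' Ranks genes by score (ties broken by gene id for determinism) and
#' splits them into `n_groups` equal-rank bins; group 1 holds the lowest
#' scores. Genes with missing scores are dropped and counted.
#'
#' @param scores Data.frame with `gene_id` and `score`.
#' @param n_groups Number of quantile groups.
#' @return Data.frame `gene_id`, `score`, `group` (1 = lowest scores),
#'   with attribute `n_dropped`.
#' @examples
#' stratify_genes(data.frame(gene_id = letters[1:8], score = 8:1), 4)
#' @export
stratify_genes <- function(scores, n_groups = 4L) {
  stopifnot(all(c("gene_id", "score") %in% names(scores)))
  n_dropped <- sum(is.na(scores$score))
  sc <- scores[!is.na(scores$score), , drop = FALSE]
  if (nrow(sc) < n_groups)
    stopf("need at least %d genes with scores, got %d", n_groups, nrow(sc))
  ord <- order(sc$score, sc$gene_id)
  sc <- sc[ord, , drop = FALSE]
  sc$group <- ceiling(seq_len(nrow(sc)) * n_groups / nrow(sc))
  rownames(sc) <- NULL
  attr(sc, "n_dropped") <- n_dropped
  sc
}
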