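# Strain-versus-strain comparison: index-matched nucleosome pairing,
# per-index shift statistics (paired t), and regional spacing differences.

#' Pair nucleosomes between two strains by index
#'
#' For every gene mapped in both strains and every nucleosome index
#' present in both maps (-1 and +1, +2, ...), pairs the index-matched
#' nucleosomes and records the distance of each from its own strain's +1
#' upstream edge. Pairs whose positional difference is `max_shift` bp or
#' more are dropped, to avoid nucleosomes that were lost, gained or
#' miscalled between strains. Indices present in only one strain
#' contribute nothing.
#'
#' @param maps_a,maps_b `gene_nuc_maps` for the two strains, anchored to
#'   the same gene set.
#' @param max_shift Retention threshold on |difference|, bp (strictly
#'   less than).
#' @return Data.frame of class `paired_shift_table`: `gene_id`, `index`,
#'   `dist_a`, `dist_b`, `diff` (B - A, bp); attribute `n_dropped`
#'   counts filtered pairs.
#' @export
match_nucleosomes <- function(maps_a, maps_b, max_shift = 150L) {
  stopifnot(inherits(maps_a, "gene_nuc_maps"),
            inherits(maps_b, "gene_nuc_maps"))
  shared <- intersect(names(maps_a), names(maps_b))
  if (!length(shared))
    stopf("the two strains share no mapped genes")
  rows <- vector("list", length(shared))
  n_dropped <- 0L
  for (i in seq_along(shared)) {
    ma <- maps_a[[shared[i]]]
    mb <- maps_b[[shared[i]]]
    # distances from each strain's own +1 upstream edge, indices -1, 1, 2, ...
    ia <- c(-1L, ma$genic$index)
    da <- c(ma$minus1$rel, ma$genic$rel) - ma$plus1_edge_rel
    ib <- c(-1L, mb$genic$index)
    db <- c(mb$minus1$rel, mb$genic$rel) - mb$plus1_edge_rel
    common <- intersect(ia, ib)
    da <- da[match(common, ia)]
    db <- db[match(common, ib)]
    dd <- db - da
    keep <- abs(dd) < max_shift
    n_dropped <- n_dropped + sum(!keep)
    if (!any(keep)) next
    rows[[i]] <- data.frame(gene_id = shared[i], index = common[keep],
                            dist_a = da[keep], dist_b = db[keep],
                            diff = dd[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows) %||%
    data.frame(gene_id = character(), index = integer(), dist_a = numeric(),
               dist_b = numeric(), diff = numeric())
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("paired_shift_table", "data.frame")
  out
}

#' Per-index shift statistics (paired t-test)
#'
#' For each nucleosome index, computes the mean shift (strain B minus
#' strain A, bp) over genes, the paired t statistic
#' t = mean(d) / (sd(d) / sqrt(n)) with n - 1 degrees of freedom, and the
#' two-tailed p-value from the exact t distribution. Indices with fewer
#' than two pairs get NA statistics. A degenerate all-equal sample yields
#' t = 0, p = 1 when the mean shift is zero.
#'
#' @param pairs A `paired_shift_table` from [match_nucleosomes()].
#' @return Data.frame `index`, `n`, `mean_shift`, `t`, `p`.
#' @export
shift_statistics <- function(pairs) {
  stopifnot(inherits(pairs, "paired_shift_table"))
  idx <- sort(unique(pairs$index))
  out <- lapply(idx, function(k) {
    d <- pairs$diff[pairs$index == k]
    n <- length(d)
    if (n < 2L)
      return(data.frame(index = k, n = n, mean_shift = mean(d),
                        t = NA_real_, p = NA_real_))
    m <- mean(d)
    s <- stats::sd(d)
    if (s == 0) {
      tstat <- if (m == 0) 0 else sign(m) * Inf
      p <- if (m == 0) 1 else 0
    } else {
      tstat <- m / (s / sqrt(n))
      p <- 2 * stats::pt(-abs(tstat), df = n - 1L)
    }
    data.frame(index = k, n = n, mean_shift = m, t = tstat, p = p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Regional internucleosome spacing difference between strains
#'
#' Compares adjacent center-to-center distances between two strains over
#' a region of the genic array: `"5prime"` uses the linkers between +1
#' and +`after_index` (linker j for j < `after_index`), `"body"` the
#' linkers downstream of +`after_index` (j >= `after_index`). For each
#' shared gene, only linker indices measurable in both strains enter,
#' and linkers whose between-strain change exceeds `max_shift` bp are
#' dropped as lost/gained/miscalled. Returns the mean over genes of the
#' per-gene mean difference (B - A, bp) with a seeded bootstrap
#' confidence interval over genes.
#'
#' @param maps_a,maps_b `gene_nuc_maps` for the two strains.
#' @param region `"body"` or `"5prime"`.
#' @param after_index Boundary nucleosome index separating the 5' region
#'   from the gene body.
#' @param max_shift Per-linker retention threshold, bp.
#' @param n_boot Bootstrap resamples for the CI.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `spacing_comparison`: `region`, `difference`
#'   (bp), `ci` (bootstrap percentile interval), `n_genes`, `per_gene`
#'   (data.frame `gene_id`, `mean_a`, `mean_b`, `diff`, `n_linkers`).
#' @export
compare_spacing <- function(maps_a, maps_b, region = c("body", "5prime"),
                            after_index = 3L, max_shift = 150L,
                            n_boot = 1000L, conf = 0.95, seed = 1L) {
  region <- match.arg(region)
  stopifnot(inherits(maps_a, "gene_nuc_maps"),
            inherits(maps_b, "gene_nuc_maps"))
  shared <- intersect(names(maps_a), names(maps_b))
  if (!length(shared)) stopf("the two strains share no mapped genes")
  rows <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    ma <- maps_a[[shared[i]]]
    mb <- maps_b[[shared[i]]]
    na <- nrow(ma$genic)
    nb <- nrow(mb$genic)
    jmax <- min(na, nb) - 1L
    if (jmax < 1L) next
    j <- seq_len(jmax)   # linker j spans +j to +(j+1)
    j <- if (region == "5prime") j[j < after_index] else j[j >= after_index]
    if (!length(j)) next
    la <- diff(ma$genic$rel)[j]
    lb <- diff(mb$genic$rel)[j]
    keep <- abs(lb - la) < max_shift
    if (!any(keep)) next
    rows[[i]] <- data.frame(gene_id = shared[i],
                            mean_a = mean(la[keep]), mean_b = mean(lb[keep]),
                            diff = mean(lb[keep] - la[keep]),
                            n_linkers = sum(keep), stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows)
  if (is.null(per_gene) || !nrow(per_gene))
    stopf("no comparable linkers in region '%s'", region)
  rownames(per_gene) <- NULL
  difference <- mean(per_gene$diff)
  ci <- with_seed(seed, {
    n <- nrow(per_gene)
    boots <- vapply(seq_len(n_boot), function(b)
      mean(per_gene$diff[sample.int(n, n, replace = TRUE)]), numeric(1))
    stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  })
  structure(list(region = region, difference = difference, ci = ci,
                 conf = conf, n_genes = nrow(per_gene),
                 per_gene = per_gene),
            class = "spacing_comparison")
}

#' @export
print.spacing_comparison <- function(x, ...) {
  cat(sprintf("spacing difference (%s region): %+.3f bp [%.0f%% CI %+.3f, %+.3f], %d genes\n",
              x$region, x$difference, 100 * x$conf, x$ci[1], x$ci[2],
              x$n_genes))
  invisible(x)
}
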