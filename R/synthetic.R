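# Synthetic MNase-Seq generator: genome layout, ground-truth nucleosome
# architectures, strain-swap perturbations and fragment simulation.
# All coordinates are 0-based half-open; dyads are 0-based positions.

#' Generate a synthetic genome annotation
#'
#' Lays out `n_genes` non-overlapping genes of fixed length, separated by
#' fixed intergenic spacers, on one or more chromosomes (up to
#' `genes_per_chrom` genes each). Strands alternate gene by gene so that
#' both orientations are exercised downstream. The layout is fully
#' deterministic.
#'
#' @param config A [sim_config()].
#' @param genes_per_chrom Maximum genes per chromosome.
#' @return An object of class `genome_annotation`: a list with
#'   `chrom_lengths` (named integer vector, bp) and `genes` (data.frame
#'   with columns `gene_id`, `chrom`, `start`, `end`, `strand`; 0-based
#'   half-open).
#' @examples
#' gen <- generate_genome(sim_config(n_genes = 4))
#' gen$genes
#' @export
generate_genome <- function(config, genes_per_chrom = 100L) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  gl <- config$gene_length
  ig <- config$intergenic
  if (n == 0L) {
    return(structure(list(
      chrom_lengths = c(chr1 = as.integer(2L * max(ig, 1000L))),
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), stringsAsFactors = FALSE),
      config = config), class = "genome_annotation"))
  }
  idx <- seq_len(n)
  chrom_i <- (idx - 1L) %/% genes_per_chrom + 1L
  within <- (idx - 1L) %% genes_per_chrom
  start <- ig + within * (gl + ig)
  genes <- data.frame(
    gene_id = sprintf("g%04d", idx),
    chrom = sprintf("chr%d", chrom_i),
    start = as.integer(start),
    end = as.integer(start + gl),
    strand = ifelse(idx %% 2L == 1L, "+", "-"),
    stringsAsFactors = FALSE)
  per_chrom <- tabulate(chrom_i)
  lens <- as.integer(ig + per_chrom * (gl + ig))
  names(lens) <- sprintf("chr%d", seq_along(lens))
  structure(list(chrom_lengths = lens, genes = genes, config = config),
            class = "genome_annotation")
}

#' Place ground-truth nucleosomes on a synthetic genome
#'
#' For each gene, places a -1 nucleosome, a promoter NDR of
#' `params$ndr_width`, a +1 nucleosome at `params$plus1_offset` downstream
#' of the coding start, and successive genic nucleosomes spaced
#' `repeat_length` bp apart with Gaussian jitter whose sd grows linearly
#' with nucleosome index (`fuzz_sd * (1 + fuzz_growth * (k - 1))` for the
#' linker following the +k nucleosome). The jitter is truncated
#' symmetrically to +/- (`repeat_length` - `footprint`), which keeps
#' adjacent dyads at least one footprint apart without biasing the mean
#' spacing away from `repeat_length`. Minus-strand genes are mirrored: all placement is
#' done in transcriptional coordinates and mapped back to the genome.
#'
#' @param genome A [generate_genome()] annotation.
#' @param params A [chromatin_params()].
#' @param seed Integer seed for the jitter draws.
#' @return An object of class `true_nucleosome_map`: list with `genome`,
#'   `params`, `dyads` (data.frame `gene_id`, `index` (-1, 1, 2, ...),
#'   `offset` (bp from coding start, transcriptional), `chrom`, `pos`
#'   (genomic dyad, 0-based)), `ndr` (per-gene genomic NDR interval) and
#'   `perturbation` (NULL until [apply_swap_perturbation()] is used).
#' @examples
#' gen <- generate_genome(sim_config(n_genes = 2))
#' truth <- place_true_nucleosomes(gen, chromatin_params(fuzz_sd = 0), seed = 1)
#' head(truth$dyads)
#' @export
place_true_nucleosomes <- function(genome, params, seed = 1L) {
  stopifnot(inherits(genome, "genome_annotation"),
            inherits(params, "chromatin_params"))
  fp <- params$footprint
  half <- fp %/% 2L
  genes <- genome$genes
  with_seed(seed, {
    res <- vector("list", nrow(genes))
    ndr <- vector("list", nrow(genes))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      len <- g$end - g$start
      minus1_off <- params$plus1_offset - fp - params$ndr_width
      # genic array: draw spacings linker by linker until the gene end
      n_max <- max(0L, (len - params$plus1_offset) %/% fp + 2L)
      offs <- params$plus1_offset
      if (n_max > 0L) {
        sds <- params$fuzz_sd * (1 + params$fuzz_growth * (seq_len(n_max) - 1))
        # symmetric truncated-normal jitter: keeps adjacent dyads at least
        # one footprint apart while leaving the mean spacing at exactly
        # repeat_length (a one-sided clamp would inflate it)
        cmax <- params$repeat_length - fp
        if (params$fuzz_sd > 0 && cmax > 0) {
          lo <- stats::pnorm(-cmax / sds)
          hi <- stats::pnorm(cmax / sds)
          eps <- stats::qnorm(lo + stats::runif(n_max) * (hi - lo)) * sds
        } else {
          eps <- numeric(n_max)
        }
        gaps <- params$repeat_length + eps
        offs <- params$plus1_offset + cumsum(c(0, gaps))
      }
      offs <- round(offs[offs <= len - (fp - half)])
      all_off <- c(minus1_off, offs)
      index <- c(-1L, seq_along(offs))
      pos <- if (g$strand == "+") g$start + all_off else g$end - 1L - all_off
      res[[i]] <- data.frame(gene_id = g$gene_id, index = index,
                             offset = as.integer(all_off),
                             chrom = g$chrom, pos = as.integer(pos),
                             stringsAsFactors = FALSE)
      ndr_lo_off <- minus1_off + half + 1L
      ndr_hi_off <- params$plus1_offset - half
      if (g$strand == "+") {
        lo <- g$start + ndr_lo_off; hi <- g$start + ndr_hi_off
      } else {
        lo <- g$end - ndr_hi_off; hi <- g$end - ndr_lo_off
      }
      ndr[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                             start = as.integer(lo), end = as.integer(hi),
                             stringsAsFactors = FALSE)
    }
    structure(list(genome = genome, params = params,
                   dyads = do.call(rbind, res) %||%
                     data.frame(gene_id = character(), index = integer(),
                                offset = integer(), chrom = character(),
                                pos = integer()),
                   ndr = do.call(rbind, ndr),
                   perturbation = NULL),
              class = "true_nucleosome_map")
  })
}

#' Apply a strain-swap spacing perturbation to a truth map
#'
#' Widens linkers in the genic array, leaving the -1 and +1 nucleosomes in
#' place: linkers between +1 and +`after_index` are each widened by
#' `delta5` bp, and linkers downstream of +`after_index` by `delta_body`
#' bp. Dyads shift downstream (in transcriptional direction) by the
#' accumulated real-valued widening, rounded to the nearest bp when
#' applied. The number of nucleosomes per gene never changes.
#'
#' @param map A `true_nucleosome_map`.
#' @param delta5 Widening of each 5' linker (indices 1..`after_index`-1), bp.
#' @param delta_body Widening of each body linker (indices >=
#'   `after_index`), bp.
#' @param after_index Nucleosome index after which the body widening
#'   applies (>= 1).
#' @param gene_ids Optional character vector restricting the perturbation
#'   to a subset of genes.
#' @return A new `true_nucleosome_map` with shifted dyads and the
#'   perturbation recorded in `$perturbation`.
#' @examples
#' gen <- generate_genome(sim_config(n_genes = 1))
#' truth <- place_true_nucleosomes(gen, chromatin_params(fuzz_sd = 0))
#' sw <- swap_preset("klac-chd1")
#' pert <- apply_swap_perturbation(truth, sw$delta5, sw$delta_body, sw$after_index)
#' @export
apply_swap_perturbation <- function(map, delta5 = 0, delta_body = 0,
                                    after_index = 3L, gene_ids = NULL) {
  stopifnot(inherits(map, "true_nucleosome_map"))
  if (!is_count(after_index) || after_index < 1L)
    stopf("after_index must be an integer >= 1")
  d <- map$dyads
  sel <- d$index >= 2L
  if (!is.null(gene_ids)) sel <- sel & d$gene_id %in% gene_ids
  k <- d$index[sel]
  # cumulative widening of the k-1 linkers upstream of nucleosome +k
  n5 <- pmin(k - 1L, after_index - 1L)
  nb <- pmax(0L, k - after_index)
  shift <- round(delta5 * n5 + delta_body * nb)
  d$offset[sel] <- d$offset[sel] + as.integer(shift)
  genes <- map$genome$genes
  gi <- match(d$gene_id, genes$gene_id)
  d$pos <- ifelse(genes$strand[gi] == "+",
                  genes$start[gi] + d$offset,
                  genes$end[gi] - 1L - d$offset)
  d$pos <- as.integer(d$pos)
  out <- map
  out$dyads <- d
  out$perturbation <- list(delta5 = delta5, delta_body = delta_body,
                           after_index = as.integer(after_index),
                           gene_ids = gene_ids)
  out
}

#' Simulate MNase-Seq fragments from a truth map
#'
#' Draws, for each true dyad, a Binomial(`coverage`, p) number of
#' mononucleosome-sized fragments centered on the dyad, where
#' p = min(1, `occupancy_prob` * `digestion`): the digestion level scales
#' fragment recovery only and never moves dyads. Fragment lengths are
#' Normal(`footprint`, `frag_sd`), rounded and truncated to
#' [`frag_min`, `frag_max`]. A `background` fraction of uniformly placed
#' fragments is added. Fully deterministic given `config$seed`.
#'
#' @param map A `true_nucleosome_map`.
#' @param config A [sim_config()]; `coverage`, `frag_*`, `background`,
#'   `digestion` and `seed` are used.
#' @return A fragment table: data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), sorted by chromosome and start.
#' @examples
#' gen <- generate_genome(sim_config(n_genes = 1, coverage = 10))
#' truth <- place_true_nucleosomes(gen, chromatin_params())
#' frags <- simulate_fragments(truth, sim_config(n_genes = 1, coverage = 10))
#' head(frags)
#' @export
simulate_fragments <- function(map, config) {
  stopifnot(inherits(map, "true_nucleosome_map"),
            inherits(config, "sim_config"))
  if (config$coverage <= 0) stopf("coverage must be > 0 to simulate fragments")
  params <- map$params
  p <- min(1, params$occupancy_prob * config$digestion)
  d <- map$dyads
  lens_tbl <- map$genome$chrom_lengths
  with_seed(config$seed, {
    counts <- stats::rbinom(nrow(d), config$coverage, p)
    centers <- rep(d$pos, counts)
    chrom <- rep(d$chrom, counts)
    n_sig <- length(centers)
    draw_lengths <- function(n) {
      l <- round(stats::rnorm(n, params$footprint, config$frag_sd))
      pmin(pmax(l, config$frag_min), config$frag_max)
    }
    lens <- draw_lengths(n_sig)
    start <- centers - lens %/% 2L
    end <- start + lens
    frag <- data.frame(chrom = chrom, start = as.integer(start),
                       end = as.integer(end), stringsAsFactors = FALSE)
    if (config$background > 0 && n_sig > 0) {
      n_bg <- round(config$background / (1 - config$background) * n_sig)
      if (n_bg > 0) {
        bchrom <- sample(names(lens_tbl), n_bg, replace = TRUE,
                         prob = as.numeric(lens_tbl))
        blens <- draw_lengths(n_bg)
        bmax <- lens_tbl[bchrom]
        bstart <- floor(stats::runif(n_bg, 0, pmax(1, bmax - blens)))
        frag <- rbind(frag, data.frame(chrom = bchrom,
                                       start = as.integer(bstart),
                                       end = as.integer(bstart + blens),
                                       stringsAsFactors = FALSE))
      }
    }
    # drop fragments that fall off chromosome ends
    ok <- frag$start >= 0L & frag$end <= lens_tbl[frag$chrom]
    frag <- frag[ok, , drop = FALSE]
    frag <- frag[order(frag$chrom, frag$start, frag$end), , drop = FALSE]
    rownames(frag) <- NULL
    frag
  })
}

#' @export
print.true_nucleosome_map <- function(x, ...) {
  cat(sprintf("true_nucleosome_map: %d genes, %d dyads (%s)\n",
              nrow(x$genome$genes), nrow(x$dyads),
              if (is.null(x$perturbation)) "unperturbed"
              else sprintf("perturbed: delta5=%.2g delta_body=%.2g after +%d",
                           x$perturbation$delta5, x$perturbation$delta_body,
                           x$perturbation$after_index)))
  invisible(x)
}
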