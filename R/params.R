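#' Chromatin architecture parameters
#'
#' Parameter set describing the genic chromatin architecture the simulator
#' emulates: a promoter nucleosome-depleted region (NDR) flanked by the -1
#' and +1 nucleosomes, followed by a phased genic array with a
#' species-specific nucleosome repeat length and positional fuzziness that
#' grows toward the 3' end of the gene.
#'
#' Two species presets are provided, with repeat lengths taken as the
#' midpoints of the ranges commonly reported for the two yeasts:
#' \describe{
#'   \item{`"scer"`}{*S. cerevisiae*-like spacing, repeat length 162 bp.}
#'   \item{`"klac"`}{*K. lactis*-like spacing, repeat length 177 bp.}
#' }
#'
#' @param preset Optional preset name, `"scer"` or `"klac"`. Explicit
#'   arguments override preset values.
#' @param ndr_width Width of the promoter NDR in bp (linker between the -1
#'   and +1 nucleosomes).
#' @param plus1_offset Position of the +1 dyad relative to the coding start,
#'   bp downstream.
#' @param repeat_length Center-to-center distance between adjacent genic
#'   nucleosomes, bp.
#' @param footprint Nucleosomal DNA footprint, bp (canonically 147).
#' @param fuzz_sd Standard deviation of Gaussian positional jitter applied
#'   to each internucleosomal spacing, bp.
#' @param fuzz_growth Linear growth factor of `fuzz_sd` per nucleosome
#'   index, modelling increasing 5'->3' fuzziness (0.1 = +10% per index).
#' @param occupancy_prob Per-nucleosome recovery probability at nominal
#'   digestion (0-1).
#' @return An object of class `chromatin_params`.
#' @examples
#' chromatin_params("klac")
#' chromatin_params(repeat_length = 165, fuzz_sd = 0)
#' @export
chromatin_params <- function(preset = NULL,
                             ndr_width = 150L,
                             plus1_offset = 60L,
                             repeat_length = 162,
                             footprint = 147L,
                             fuzz_sd = 10,
                             fuzz_growth = 0.1,
                             occupancy_prob = 0.9) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("scer", "klac"))
    if (missing(repeat_length))
      repeat_length <- switch(preset, scer = 162, klac = 177)
  }
  if (repeat_length < footprint)
    stopf("repeat_length (%s) must be >= footprint (%s)",
          format(repeat_length), format(footprint))
  if (fuzz_sd < 0) stopf("fuzz_sd must be >= 0")
  if (fuzz_growth < 0) stopf("fuzz_growth must be >= 0")
  check_fraction(occupancy_prob, "occupancy_prob")
  if (occupancy_prob == 0) stopf("occupancy_prob must be > 0")
  if (ndr_width <= 0 || plus1_offset < 0 || footprint <= 0)
    stopf("ndr_width and footprint must be positive, plus1_offset >= 0")
  structure(list(preset = preset %||% "custom",
                 ndr_width = as.integer(ndr_width),
                 plus1_offset = as.integer(plus1_offset),
                 repeat_length = repeat_length,
                 footprint = as.integer(footprint),
                 fuzz_sd = fuzz_sd,
                 fuzz_growth = fuzz_growth,
                 occupancy_prob = occupancy_prob),
            class = "chromatin_params")
}

#' Strain-swap perturbation presets
#'
#' Linker-widening presets describing the spacing phenotype of a
#' remodeler-swap strain relative to its parent. The `"klac-chd1"` preset
#' encodes the Chd1-swap phenotype: a ~1.5 bp increase in the 5' repeat
#' length (linkers between +1 and +3) and a 3 bp expansion of
#' internucleosome spacing downstream of the +3 nucleosome.
#'
#' @param name Preset name; currently `"klac-chd1"`.
#' @return A list with elements `delta5`, `delta_body` (bp) and
#'   `after_index`, suitable for [apply_swap_perturbation()].
#' @examples
#' swap_preset("klac-chd1")
#' @export
swap_preset <- function(name = "klac-chd1") {
  name <- match.arg(name, "klac-chd1")
  list(name = name, delta5 = 1.5, delta_body = 3, after_index = 3L)
}

#' Simulation configuration
#'
#' Run-level settings for the synthetic MNase-Seq generator: genome layout,
#' sequencing depth, fragment-length dispersion, background and digestion
#' level. The digestion level scales per-nucleosome fragment recovery only;
#' it never moves dyads, mirroring the observation that under- or
#' over-digestion changes apparent occupancy but not linker lengths.
#'
#' @param n_genes Number of genes to simulate.
#' @param gene_length Gene length, bp (fixed for all genes).
#' @param intergenic Intergenic spacer length, bp.
#' @param coverage Expected fragments per fully recovered nucleosome.
#' @param frag_sd Standard deviation of fragment length around the
#'   nucleosomal footprint, bp.
#' @param frag_min,frag_max Truncation bounds on fragment length, bp.
#' @param background Fraction of total fragments that are uniform genomic
#'   background (0-1).
#' @param digestion Digestion level; multiplies the per-nucleosome recovery
#'   probability (capped at 1).
#' @param seed Integer seed fixing all randomness of a run.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(n_genes = 50, coverage = 30, seed = 1)
#' @export
sim_config <- function(n_genes = 200L,
                       gene_length = 3000L,
                       intergenic = 1000L,
                       coverage = 30L,
                       frag_sd = 8,
                       frag_min = 100L,
                       frag_max = 250L,
                       background = 0.05,
                       digestion = 1,
                       seed = 1L) {
  if (!is_count(n_genes)) stopf("n_genes must be a non-negative integer")
  if (gene_length <= 0 || intergenic < 0)
    stopf("gene_length must be > 0 and intergenic >= 0")
  if (coverage < 0) stopf("coverage must be >= 0")
  if (frag_sd < 0) stopf("frag_sd must be >= 0")
  if (frag_min <= 0 || frag_max < frag_min)
    stopf("need 0 < frag_min <= frag_max")
  check_fraction(background, "background")
  if (background >= 1) stopf("background must be < 1")
  if (digestion < 0) stopf("digestion must be >= 0")
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 intergenic = as.integer(intergenic),
                 coverage = as.integer(coverage),
                 frag_sd = frag_sd,
                 frag_min = as.integer(frag_min),
                 frag_max = as.integer(frag_max),
                 background = background,
                 digestion = digestion,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.chromatin_params <- function(x, ...) {
  cat(sprintf(paste0("chromatin_params [%s]: NRL %.1f bp, footprint %d bp, ",
                     "NDR %d bp, +1 offset %d bp, fuzz %.1f bp (+%.0f%%/index), ",
                     "occupancy %.2f\n"),
              x$preset, x$repeat_length, x$footprint, x$ndr_width,
              x$plus1_offset, x$fuzz_sd, 100 * x$fuzz_growth,
              x$occupancy_prob))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d genes x %d bp (+%d bp intergenic), ",
                     "coverage %d, frag sd %.1f bp [%d, %d], background %.0f%%, ",
                     "digestion %.2gx, seed %d\n"),
              x$n_genes, x$gene_length, x$intergenic, x$coverage, x$frag_sd,
              x$frag_min, x$frag_max, 100 * x$background, x$digestion,
              x$seed))
  invisible(x)
}
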