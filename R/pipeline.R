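# Pipeline driver: simulate (optional) -> process -> call -> genic ->
# compare, with all artifacts written to an output directory.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its default:
#' the NDR scan window (500 bp) and linker threshold (100 bp), the
#' nucleosomal footprint (147 bp), the shift-filter cutoff (150 bp), the
#' metaprofile bin (10 bp), the cross-correlation search window
#' (50-300 bp), the template lengths (120-180 bp), the call threshold
#' and the minimum call separation (120 bp).
#'
#' @param sim A [sim_config()] driving simulation, or NULL to analyse
#'   files given in `fragments_a` / `genes`.
#' @param preset_a,preset_b Chromatin presets for the two simulated
#'   strains (`preset_b = NULL` runs a single-strain analysis).
#' @param swap Optional [swap_preset()] applied to strain B's truth map
#'   (strain B then shares strain A's architecture plus the perturbation).
#' @param fragments_a,fragments_b,genes Input paths used when `sim` is
#'   NULL: fragment BED file(s) and a BED6 gene file.
#' @param fragment_length `"auto"` (cross-correlation) or a fixed bp value.
#' @param max_upstream,ndr_linker,footprint,max_shift,bin,k_min,k_max,template_lengths,spread_sd,threshold,min_separation
#'   Analysis thresholds; see the module functions for their meaning.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            preset_a = chromatin_params("scer"),
                            preset_b = NULL,
                            swap = NULL,
                            fragments_a = NULL, fragments_b = NULL,
                            genes = NULL,
                            fragment_length = "auto",
                            max_upstream = 500L, ndr_linker = 100L,
                            footprint = 147L, max_shift = 150L,
                            bin = 10L, k_min = 50L, k_max = 300L,
                            template_lengths = seq(120L, 180L, by = 10L),
                            spread_sd = 10, threshold = 0.01,
                            min_separation = 120L) {
  if (is.null(sim)) {
    if (is.null(fragments_a)) stopf("config error: 'fragments_a' is required when simulation is disabled")
    if (is.null(genes)) stopf("config error: 'genes' is required when simulation is disabled")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

run_one_strain <- function(frags, genes, chrom_lengths, cfg) {
  track <- count_read_starts(frags, chrom_lengths)
  fl <- if (identical(cfg$fragment_length, "auto"))
    infer_fragment_length(track, cfg$k_min, cfg$k_max)
  else as.integer(cfg$fragment_length)
  occ <- normalize_track(extend_and_count(track, fl))
  templates <- build_templates(cfg$template_lengths, cfg$spread_sd)
  calls <- call_positions(template_score(track, templates),
                          threshold = cfg$threshold,
                          min_separation = cfg$min_separation)
  maps <- map_gene_nucleosomes(calls, genes,
                               max_upstream = cfg$max_upstream,
                               ndr_linker = cfg$ndr_linker,
                               footprint = cfg$footprint)
  list(track = track, fragment_length = fl, occupancy = occ,
       calls = calls, maps = maps)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> start-track processing -> nucleosome
#' calling -> gene anchoring -> (if two strains) index-matched shift
#' statistics and regional spacing comparison, writing fragments (BED3),
#' truth maps (JSON), occupancy (bedGraph), calls (TSV), per-gene
#' spacing (TSV), NRL estimates (JSON), the per-index shift table (TSV)
#' and the spacing comparison (JSON) to `out_dir`, plus a run log. Every
#' output carries a header naming the config hash and seed. Runs are
#' byte-identical for identical configs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results per strain and
#'   the comparison (when two strains were analysed).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "sim")])
  seed <- if (!is.null(config$sim)) config$sim$seed else NA_integer_
  stamp <- sprintf("config_hash=%s seed=%s", hash, seed)
  log <- file.path(out_dir, "run_log.txt")
  cat(sprintf("nucspacing %s\n%s\n",
              as.character(utils::packageVersion("nucspacing")), stamp),
      file = log)

  if (!is.null(config$sim)) {
    genome <- generate_genome(config$sim)
    genes <- genome$genes
    chrom_lengths <- genome$chrom_lengths
    truth_a <- place_true_nucleosomes(genome, config$preset_a,
                                      seed = config$sim$seed)
    frags_a <- simulate_fragments(truth_a, config$sim)
    write_genes_bed(genes, file.path(out_dir, "genes.bed"), stamp)
    write_truth_json(truth_a, file.path(out_dir, "truth_a.json"))
    write_fragments_bed(frags_a, file.path(out_dir, "fragments_a.bed"), stamp)
    frags_b <- NULL
    if (!is.null(config$swap) || !is.null(config$preset_b)) {
      truth_b <- if (!is.null(config$swap))
        apply_swap_perturbation(truth_a, config$swap$delta5,
                                config$swap$delta_body,
                                config$swap$after_index)
      else place_true_nucleosomes(genome, config$preset_b,
                                  seed = config$sim$seed)
      frags_b <- simulate_fragments(truth_b, config$sim)
      write_truth_json(truth_b, file.path(out_dir, "truth_b.json"))
      write_fragments_bed(frags_b, file.path(out_dir, "fragments_b.bed"),
                          stamp)
    }
  } else {
    genes <- read_genes_bed(config$genes)
    frags_a <- read_fragments(config$fragments_a, "bed")
    frags_b <- if (!is.null(config$fragments_b))
      read_fragments(config$fragments_b, "bed") else NULL
    chrom_lengths <- tapply(c(frags_a$end, genes$end),
                            c(frags_a$chrom, genes$chrom), max)
    chrom_lengths <- stats::setNames(as.integer(chrom_lengths),
                                     names(chrom_lengths))
  }

  strains <- list(a = run_one_strain(frags_a, genes, chrom_lengths, config))
  if (!is.null(frags_b))
    strains$b <- run_one_strain(frags_b, genes, chrom_lengths, config)

  for (sn in names(strains)) {
    st <- strains[[sn]]
    write_bedgraph(st$occupancy,
                   file.path(out_dir, sprintf("occupancy_%s.bedgraph", sn)),
                   stamp)
    write_calls_tsv(st$calls,
                    file.path(out_dir, sprintf("calls_%s.tsv", sn)), stamp)
    sm <- spacing_metrics(st$maps)
    write_header(file.path(out_dir, sprintf("spacing_%s.tsv", sn)),
                 "per-gene spacing (bp)", stamp)
    suppressWarnings(utils::write.table(
      as.data.frame(sm), file.path(out_dir, sprintf("spacing_%s.tsv", sn)),
      sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    nrl <- tryCatch(estimate_nrl(st$maps), error = function(e) NULL)
    if (!is.null(nrl))
      jsonlite::write_json(
        list(stamp = stamp, slope = nrl$slope, intercept = nrl$intercept,
             n_genes = nrl$n_genes),
        file.path(out_dir, sprintf("nrl_%s.json", sn)),
        auto_unbox = TRUE, digits = NA)
  }

  comparison <- NULL
  if (length(strains) == 2L) {
    pairs <- match_nucleosomes(strains$a$maps, strains$b$maps,
                               max_shift = config$max_shift)
    shifts <- shift_statistics(pairs)
    write_header(file.path(out_dir, "shift_table.tsv"),
                 "per-index shifts (bp, B - A)", stamp)
    suppressWarnings(utils::write.table(
      shifts, file.path(out_dir, "shift_table.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE, append = TRUE))
    boot_seed <- if (is.na(seed)) 1L else seed
    cmp5 <- compare_spacing(strains$a$maps, strains$b$maps, "5prime",
                            max_shift = config$max_shift, seed = boot_seed)
    cmpb <- compare_spacing(strains$a$maps, strains$b$maps, "body",
                            max_shift = config$max_shift, seed = boot_seed)
    jsonlite::write_json(
      list(stamp = stamp,
           five_prime = list(difference = cmp5$difference, ci = cmp5$ci,
                             n_genes = cmp5$n_genes),
           body = list(difference = cmpb$difference, ci = cmpb$ci,
                       n_genes = cmpb$n_genes)),
      file.path(out_dir, "spacing_comparison.json"),
      auto_unbox = TRUE, digits = NA)
    comparison <- list(pairs = pairs, shifts = shifts,
                       five_prime = cmp5, body = cmpb)
  }
  cat("completed\n", file = log, append = TRUE)
  invisible(list(strains = strains, comparison = comparison,
                 out_dir = out_dir, stamp = stamp))
}
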