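# Shared fixtures, built in code.

# Small single-gene annotation with full control over coordinates.
one_gene <- function(start = 1000L, end = 4000L, strand = "+",
                     chrom_len = 6000L) {
  structure(list(genes = data.frame(gene_id = "g1", chrom = "chr1",
                                    start = start, end = end,
                                    strand = strand,
                                    stringsAsFactors = FALSE),
                 chrom_lengths = c(chr1 = chrom_len)),
            class = "genome_annotation")
}

# Reflect a genome annotation: flip strands and coordinates.
mirror_annotation <- function(genome) {
  out <- genome
  L <- genome$chrom_lengths[genome$genes$chrom]
  s <- genome$genes$start
  out$genes$start <- as.integer(L - genome$genes$end)
  out$genes$end <- as.integer(L - s)
  out$genes$strand <- ifelse(genome$genes$strand == "+", "-", "+")
  out
}

# Simulate one strain and run it through calling + gene mapping.
run_strain <- function(truth, cfg) {
  gen <- truth$genome
  frags <- simulate_fragments(truth, cfg)
  calls <- call_nucleosomes(frags, gen$chrom_lengths)
  map_gene_nucleosomes(calls, gen$genes)
}

# Use the simulator's ground-truth dyads directly as "calls", to test the
# gene-anchoring logic independently of the caller.
truth_as_calls <- function(truth) {
  out <- data.frame(chrom = truth$dyads$chrom, dyad = truth$dyads$pos,
                    score = 1, template_length = 147L,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$dyad), ]
  rownames(out) <- NULL
  class(out) <- c("nucleosome_calls", "data.frame")
  out
}

# Build a start_track directly from vectors of 0-based start positions.
track_from_positions <- function(watson, crick, len, chrom = "chr1") {
  counts <- list(list(watson = tabulate(watson + 1L, nbins = len),
                      crick = tabulate(crick + 1L, nbins = len)))
  names(counts) <- chrom
  lens <- stats::setNames(as.integer(len), chrom)
  structure(list(counts = counts, chrom_lengths = lens),
            class = "start_track")
}
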