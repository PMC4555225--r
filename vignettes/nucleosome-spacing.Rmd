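---
title: "Measuring internucleosome spacing from MNase-Seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring internucleosome spacing from MNase-Seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Eukaryotic genes carry a stereotyped chromatin architecture: a
nucleosome-depleted region (NDR) over the promoter, well-positioned −1
and +1 nucleosomes flanking it, and a phased array of nucleosomes over
the gene body whose regularity decays toward the 3′ end. Two
quantitative traits of this architecture differ between species and
between remodeler mutants: the nucleosome repeat length (NRL, the mean
center-to-center distance of adjacent nucleosomes in the array) and
equivalently the linker length (center distance minus the ~147 bp
nucleosomal footprint). Effects of interest are small — single base
pairs of spacing change against ~10–25 bp of positional noise per
nucleosome — so the pipeline is built around paired, index-matched
comparisons that cancel shared noise, and it is validated by parameter
recovery on a generator whose ground truth is known exactly.

`nucspacing` implements the full chain: stranded read-start tracks →
fragment sizing → occupancy and metaprofiles → template-filter dyad
calling → gene anchoring via the NDR → spacing statistics →
strain-versus-strain comparison, together with the synthetic generator.

# Coordinate and unit conventions

All internal coordinates are 0-based, half-open; BED and bedGraph files
on disk follow the same convention; report tables (calls TSV, starts
TSV) are 1-based, and every writer says so in its `#` header.
Transcriptional ("rel") coordinates are bp downstream of the coding
start. Linker length is everywhere center-to-center distance − 147 bp;
the footprint parameter is explicit wherever it enters.

# From fragments to dyad calls

**Stranded starts.** The Watson start of a fragment is its 5′-most
base, the Crick start its 3′-most base (the 5′ end of the reverse
read). With this convention a single fragment `[s, e)` contributes
starts at `s` and `e − 1`, and the fragment length is recovered from a
single fragment exactly.

**Fragment sizing.** The cross-correlation estimator maximizes
Σₓ W(x)·C(x + k) over shifts k in a 50–300 bp window (defaults; the
window brackets every plausible mononucleosomal length) and reports
k* + 1. Ties break toward the smaller length, making the estimator
deterministic on degenerate inputs. The estimator is invariant to
translating fragments and to rescaling all counts.

**Occupancy.** Starts are extended to the inferred length (Watson
rightward, Crick leftward, clipped at chromosome ends) and summed.
Because both ends of every fragment are tabulated, the extended track
is exactly twice the direct interval coverage of the fragments; the
factor is immaterial because tracks are immediately normalized to
genome-wide mean 1 (the mean is taken over every position of every
chromosome, zeros included). An all-zero track is a hard error rather
than a silent NaN track.

**Metaprofiles.** Per gene, normalized coverage from 500 bp upstream of
the +1 nucleosome's upstream edge (dyad − 73) to the gene end is
averaged in 10 bp bins, minus-strand genes mirrored first. A final
partial bin is dropped rather than padded, and the cross-gene mean in
each bin is taken over the genes long enough to cover it — genes of
unequal length therefore contribute to exactly the bins they span.

**Template filtering.** Dyads are called by matched filtering against
seven templates with nominal fragment lengths 120–180 bp in 10 bp
steps, covering the size range produced by varying digestion extents.
Each template is a Gaussian Watson start profile (sd 10 bp) centered
L/2 upstream of the dyad and its mirror-image Crick profile downstream,
discretized over ±3 sd and normalized to sum 1 per strand. The
published template-filtering approach this reimplements does not
specify machine-readable template shapes or its matching statistic;
mirrored Gaussians with correlation matching are this package's
operationalization, validated against ground truth rather than claimed
as a byte-level reproduction.

The score at position d is the best template's response divided by the
total start count in a 300 bp window centered at d (0 where the window
is empty), which makes the score — and hence the call threshold —
independent of sequencing depth: doubling all counts changes no call
coordinate. With sum-1 profiles the best achievable response at a
perfectly sharp nucleosome is about 2·dnorm(0, 0, 10) ≈ 0.08 of the
window mass, and an isolated well-covered nucleosome sits near 0.02
because its own window holds roughly four strands' worth of starts
(its own two plus one from each neighbor). The default threshold 0.01
— about half the ideal response — was calibrated on the generator at
nominal conditions (coverage 30, fuzz 10) and leaves a factor-two
margin in both directions: real peaks score well above it, and stray
background fragments inside NDRs score far below it because the
flanking nucleosomes dominate their window mass.

Selection is greedy: repeatedly take the highest-scoring remaining
position above threshold (ties toward the smaller coordinate) and
suppress positions strictly closer than 120 bp. The 120 bp separation
is below the 147 bp footprint, tolerating fuzzy alternative positions
while preventing double calls of one nucleosome; on zero-noise
simulations the caller is exact (every true dyad called, 0 bp error),
and the test suite verifies ≥ 95% recall within 20 bp under standard
noise.

# Gene anchoring and spacing statistics

The NDR scan walks adjacent call pairs whose downstream member lies
within 500 bp upstream of the coding start (or inside the gene) and
accepts pairs whose linker exceeds 100 bp — strictly: a 100 bp linker
is rejected, 101 bp accepted, and the boundary is tested. When several
pairs qualify, the one whose downstream member is closest to the
coding start wins; that member becomes +1, its partner −1. Genes with
no qualifying pair are excluded and reported, not dropped silently.
The "+1 edge" used for anchoring distances and metaprofiles is the
upstream edge, dyad − ⌊147/2⌋; the choice is a convention and is
applied identically to both strains of any comparison, so it cancels
from all differences.

The NRL is estimated as the slope of the pooled least-squares
regression of distance-from-+1-dyad on nucleosome index − 1 (indices
up to 7), over genes with at least two genic calls. A regression
pools information across genes of different array lengths and is exact
on perfect arrays (slope = spacing, intercept = 0); the unit test
checks it against the closed-form normal equations, and on unperturbed
simulations at coverage ≥ 30 it recovers the generative repeat length
within 1 bp.

# Comparing strains

Nucleosomes are paired by index — each strain anchored at its own +1 —
not by nearest genomic coordinate, because per-index tables of
distance-from-+1 are the quantity of interest and because index
pairing is stable when entire arrays shift. Pairs whose positional
difference is 150 bp or more are discarded as lost, gained or
miscalled nucleosomes; the per-index mean shift is then tested with an
exact two-tailed paired *t* (no normal approximation; an all-zero
difference vector returns t = 0, p = 1 rather than 0/0). Regional
spacing differences split linkers at the +3 nucleosome: "5prime" means
linkers within +1…+3, "body" linkers downstream of +3, matching the
phenotype structure being measured (remodeler-swap effects concentrate
in the gene body). The bootstrap CI on the regional difference (1000
gene-level resamples, seeded) is an extension for interpretability,
not part of the original analysis style. Self-comparison yields shift
0 and p = 1 at every index, and compare(A, B) = −compare(B, A)
exactly.

# The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not any real genome:

* **Layout** — `n_genes` fixed-length genes (default 3 kb, a long-gene
  regime where arrays of 15+ nucleosomes make body spacing measurable)
  separated by 1 kb intergenic spacers, alternating strands, up to 100
  genes per chromosome. One gene per array; no divergent or
  overlapping promoters.
* **Architecture** — per gene: a −1 dyad, an NDR of `ndr_width`
  (default 150 bp, a typical yeast promoter NDR), the +1 dyad
  `plus1_offset` (default 60 bp) into the gene, then spacings of
  `repeat_length` plus truncated-Gaussian jitter. The jitter sd grows
  10%/index by default, emulating 5′→3′ fuzziness. The truncation is
  symmetric at ±(repeat_length − footprint): it enforces the
  physical constraint that adjacent dyads sit at least a footprint
  apart *and* keeps the mean spacing exactly at `repeat_length` — a
  one-sided clamp would inflate the realized repeat by ~2 bp at these
  noise levels and the generative parameter would no longer mean what
  it says.
* **Species presets** — `scer` NRL 162 bp, `klac` 177 bp, midpoints of
  the ranges reported for the two species; their linker difference is
  15 bp by construction.
* **Swap preset** — `klac-chd1`: each linker between +1 and +3 widens
  by 1.5 bp, each linker after +3 by 3 bp; dyads shift by the
  accumulated real-valued widening rounded to integer bp; −1 and +1
  stay fixed and no nucleosome is gained or lost. The two components
  are treated as independent per-linker increments (whether they
  compound beyond +3 in vivo is not established; the preset keeps them
  orthogonal so each can be recovered separately).
* **Fragments** — per dyad, Binomial(coverage, p) fragments with
  p = min(1, occupancy_prob × digestion): digestion level scales
  recovery only and never moves dyads, mirroring the observation that
  under-digestion changes apparent occupancy but not linker length.
  Lengths are Normal(147, 8) bp truncated to [100, 250]
  ("mononucleosome-sized"), fragments centered on the dyad. A 5%
  uniform background exercises caller robustness.
* **Determinism** — every stochastic step derives from the config
  seed; identical configs give byte-identical outputs at every stage.

What the generator does **not** emulate — sequence-dependent MNase
bias, divergent promoters, gene-length and expression heterogeneity,
replication or transcription dynamics, paired-end length mixtures from
di-/tri-nucleosomes — bounds what passing tests show: they demonstrate
that the estimators are correct and unbiased under the stated
statistical model, not that real-data measurements are free of the
biological confounders above.

# Validation scales and degenerate inputs

The packaged tests run the full pipeline at 200 genes / coverage 30
for swap-effect recovery, 500 genes for the species linker difference,
and 100 k fragments for fragment sizing — sizes chosen so each
recovery's sampling error is several times smaller than the effect
being recovered while the whole suite stays desk-scale. Degenerate
inputs fail loudly and early: empty strands for the cross-correlation,
all-zero tracks for normalization, fewer than two usable genes for the
NRL, disjoint gene sets for comparisons; empty call lists and
zero-gene genomes are valid and return empty results.

# Known limitations

* Template shapes are a reimplementation choice; absolute call scores
  are not comparable to other template-filter implementations, though
  call positions validate against ground truth.
* The NDR rule requires a called −1; genes whose upstream nucleosome
  is missing from the data are excluded rather than anchored on the +1
  alone.
* NRL-by-regression assumes approximate linearity of
  distance-from-+1 in index over the fitted range (indices ≤ 7).
* Pairing by index misassigns when a nucleosome is lost in one strain
  and all downstream indices shift by one; the 150 bp shift filter
  removes most such pairs but cannot re-align the array.
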