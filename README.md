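# nucspacing

Nucleosome positioning and internucleosome spacing analysis for
MNase-Seq, for chromatin biologists comparing nucleosome architecture
between strains or species — for example, remodeler deletion or
ortholog-swap strains in budding yeast, where the question is whether a
*trans*-acting factor changes the average linker length of genic
nucleosome arrays.

## What it computes

Starting from aligned mononucleosomal fragments (BED3, or a stranded
read-start table), the package:

1. **Tabulates stranded read starts** — Watson starts at each fragment's
   5′-most base, Crick starts at its 3′-most base — and infers the
   fragment length *L* by Watson/Crick cross-correlation:
   *L* = argmax₍ₖ₎ Σₓ W(x)·C(x+k) + 1.
2. **Builds occupancy tracks** by extending starts to *L* and
   normalizing so the genome-average per-bp count is 1, plus
   +1-aligned metaprofiles in 10 bp bins.
3. **Calls nucleosome dyads** by template filtering: matched filters
   against seven templates (nominal fragment lengths 120–180 bp, each a
   mirror-symmetric pair of Gaussian start profiles centered ±L/2 from
   the dyad), score-normalized by local read depth, with greedy peak
   selection at a 120 bp minimum separation.
4. **Anchors calls to genes**: scans up to 500 bp upstream of each
   coding start for the promoter NDR (adjacent call pair with linker
   > 100 bp, linker = center distance − 147), designates the flanking
   calls −1 and +1, and indexes the genic array +1, +2, … . From these
   it computes adjacent center-to-center distances, d(+1,+3), d(+3,+5),
   spacing CDFs, and the nucleosome repeat length (NRL) as the pooled
   regression slope of distance-from-+1 on nucleosome index.
5. **Compares two strains** by index-matched pairing of each gene's
   nucleosomes (distances measured from each strain's own +1 edge),
   discarding pairs shifted ≥ 150 bp (lost/gained/miscalled), and
   reports per-index mean shifts with two-tailed paired *t*-tests, plus
   regional spacing differences (5′: linkers within +1…+3; body:
   linkers after +3) with bootstrap CIs.

A synthetic MNase-Seq generator produces ground-truthed data with the
architecture this analysis assumes — promoter NDRs, well-positioned +1
nucleosomes, phased arrays with species-specific repeat length
(presets: `scer` 162 bp, `klac` 177 bp), 5′→3′ increasing fuzziness,
digestion-dependent recovery, uniform background — and a remodeler-swap
perturbation preset (`klac-chd1`: +1.5 bp per 5′ linker, +3 bp per
linker after the +3 nucleosome), so the whole pipeline can be validated
by parameter recovery.

## Worked example

Two synthetic strains, identical except strain B carries the
`klac-chd1` spacing perturbation; full pipeline on both, then the
per-index shift table and regional spacing differences:

```r
library(nucspacing)
cfg <- sim_config(n_genes = 60, coverage = 30, seed = 1)
gen <- generate_genome(cfg)
truth_a <- place_true_nucleosomes(gen, chromatin_params("scer"), seed = 1)
sw <- swap_preset("klac-chd1")
truth_b <- apply_swap_perturbation(truth_a, sw$delta5, sw$delta_body, sw$after_index)

run <- function(truth) {
  frags <- simulate_fragments(truth, cfg)
  calls <- call_nucleosomes(frags, gen$chrom_lengths)
  map_gene_nucleosomes(calls, gen$genes)
}
maps_a <- run(truth_a); maps_b <- run(truth_b)

head(shift_statistics(match_nucleosomes(maps_a, maps_b)), 8)
#>   index  n mean_shift     t         p
#> 1    -1 60       0.00   0.0  1.00e+00
#> 2     1 60       0.00   0.0  1.00e+00
#> 3     2 60       2.00  59.5  2.24e-54
#> 4     3 60       3.02  80.4  5.36e-62
#> 5     4 60       6.03 181.0  1.07e-82
#> 6     5 60       8.98 178.3  2.57e-82
#> 7     6 60      11.97 359.0 3.15e-100
#> 8     7 60      14.98 399.3 5.90e-103

compare_spacing(maps_a, maps_b, "body")
#> spacing difference (body region): +2.997 bp [95% CI +2.988, +3.006], 60 genes
compare_spacing(maps_a, maps_b, "5prime")
#> spacing difference (5prime region): +1.508 bp [95% CI +1.475, +1.542], 60 genes
estimate_nrl(maps_a)
#> NRL estimate: 161.40 bp/nucleosome (intercept 0.08 bp, 60 genes, 420 points, indices <= 7)
```

Reading the table: the −1 and +1 nucleosomes do not move (distances are
measured from each strain's own +1, so shifts there are null by
construction and by the unperturbed promoter); from +2 onward each
nucleosome's cumulative displacement grows by ~1.5 bp per 5′ linker and
~3 bp per body linker, exactly the generative perturbation. The
regional spacing differences recover both preset components to within
a few hundredths of a bp at this depth.

`run_pipeline(pipeline_config(...), out_dir)` drives the same steps
from a single configuration object and writes stamped BED / bedGraph /
TSV / JSON artifacts; see the vignette in `vignettes/` for the model,
parameter meanings and design choices.

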