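# Gene anchoring, spacing metrics, NRL estimation, stratification.

test_that("NDR scan designates -1/+1 by the linker rule", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 3000L, strand = "+")
  calls <- data.frame(chrom = "chr1", dyad = c(700, 950, 1120))
  maps <- map_gene_nucleosomes(calls, genes)
  expect_equal(maps$g1$minus1$dyad, 700)
  expect_equal(maps$g1$plus1$dyad, 950)
  expect_equal(maps$g1$genic$dyad, c(950, 1120))
  expect_equal(maps$g1$genic$index, c(1L, 2L))

  # no qualifying NDR within the window -> excluded, reported
  calls2 <- data.frame(chrom = "chr1", dyad = c(800, 950, 1120))
  maps2 <- map_gene_nucleosomes(calls2, genes)
  expect_length(maps2, 0L)
  expect_equal(attr(maps2, "excluded")$reason, "no_ndr")

  # no calls at all -> excluded
  maps3 <- map_gene_nucleosomes(data.frame(chrom = "chr2", dyad = 1),
                                genes)
  expect_equal(attr(maps3, "excluded")$reason, "no_calls")
})

test_that("NDR linker threshold is sharp at 100 vs 101 bp", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 3000L, strand = "+")
  # center distance 247 -> linker exactly 100: not an NDR
  at100 <- data.frame(chrom = "chr1", dyad = c(703, 950, 1120))
  expect_length(map_gene_nucleosomes(at100, genes), 0L)
  # center distance 248 -> linker 101: accepted
  at101 <- data.frame(chrom = "chr1", dyad = c(702, 950, 1120))
  maps <- map_gene_nucleosomes(at101, genes)
  expect_equal(maps$g1$plus1$dyad, 950)
})

test_that("minus-strand mapping equals the coordinate-reflection oracle", {
  L <- 4000L
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 3000L, strand = "+")
  calls <- data.frame(chrom = "chr1", dyad = c(700, 950, 1120, 1290, 1458))
  fwd <- map_gene_nucleosomes(calls, genes)

  genes_m <- data.frame(gene_id = "g1", chrom = "chr1",
                        start = L - genes$end, end = L - genes$start,
                        strand = "-")
  calls_m <- data.frame(chrom = "chr1", dyad = L - 1L - calls$dyad)
  rev_map <- map_gene_nucleosomes(calls_m, genes_m)
  expect_equal(rev_map$g1$genic$rel, fwd$g1$genic$rel)
  expect_equal(rev_map$g1$minus1$rel, fwd$g1$minus1$rel)
  expect_equal(rev_map$g1$genic$dyad, L - 1L - fwd$g1$genic$dyad)
})

test_that("spacing metrics compute center distances and +1-edge distances", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 300L,
                      end = 1200L, strand = "+")
  calls <- data.frame(chrom = "chr1",
                      dyad = c(-300, 0, 165, 330, 495, 660) + 300)
  maps <- map_gene_nucleosomes(calls, genes)
  sm <- spacing_metrics(maps)
  expect_equal(sm$mean_adjacent, 165)
  expect_equal(sm$d13, 330)
  expect_equal(sm$d35, 330)
  ed <- attr(sm, "edge_distances")
  expect_equal(ed$edge_distance, c(0, 165, 330, 495, 660) + 73)
  expect_equal(attr(sm, "pooled"), rep(165, 4))

  # two genic calls: mean defined, d13 missing
  calls2 <- data.frame(chrom = "chr1", dyad = c(0, 300, 460))
  genes2 <- data.frame(gene_id = "g1", chrom = "chr1", start = 300L,
                       end = 520L, strand = "+")
  sm2 <- spacing_metrics(map_gene_nucleosomes(calls2, genes2))
  expect_equal(sm2$mean_adjacent, 160)
  expect_true(is.na(sm2$d13))
})

test_that("truth-table maps recover the generative repeat length", {
  cfg <- sim_config(n_genes = 500, seed = 1)
  gen <- generate_genome(cfg)
  truth <- place_true_nucleosomes(gen, chromatin_params("klac"), seed = 1)
  maps <- map_gene_nucleosomes(truth_as_calls(truth), gen$genes)
  expect_gte(length(maps), 490L)
  sm <- spacing_metrics(maps)
  expect_lt(abs(mean(attr(sm, "pooled")) - 177), 1)
  # d(+1,+3) is the sum of the two intervening adjacent distances
  for (gid in names(maps)[1:25]) {
    r <- maps[[gid]]$genic$rel
    expect_equal(sm$d13[sm$gene_id == gid], (r[2] - r[1]) + (r[3] - r[2]))
  }
})

test_that("NRL regression is exact on perfect arrays and matches closed form", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(1000L, 6000L), end = c(4000L, 9000L),
                      strand = "+")
  dy <- c(703 - 2, 950, 1115, 1280, 1445,
          5703 - 2, 5950, 6115, 6280, 6445)
  maps <- map_gene_nucleosomes(data.frame(chrom = "chr1", dyad = dy), genes)
  nrl <- estimate_nrl(maps)
  expect_equal(nrl$slope, 165)
  expect_equal(nrl$intercept, 0)

  # degenerate input
  one <- maps["g1"]
  one$g1$genic <- one$g1$genic[1, ]
  class(one) <- "gene_nuc_maps"
  expect_error(estimate_nrl(one), ">= 2 genes")

  # noisy maps: slope equals the normal-equations oracle
  cfg <- sim_config(n_genes = 80, seed = 4)
  gen <- generate_genome(cfg)
  truth <- place_true_nucleosomes(gen, chromatin_params("scer"), seed = 4)
  m <- map_gene_nucleosomes(truth_as_calls(truth), gen$genes)
  est <- estimate_nrl(m, max_index = 7)
  x <- c(); y <- c()
  for (mm in m) {
    gi <- mm$genic[mm$genic$index <= 7, ]
    if (nrow(gi) < 2) next
    x <- c(x, gi$index - 1)
    y <- c(y, gi$rel - mm$plus1$rel)
  }
  slope_oracle <- (mean(x * y) - mean(x) * mean(y)) /
    (mean(x^2) - mean(x)^2)
  expect_equal(est$slope, slope_oracle, tolerance = 1e-9)
})

test_that("spacing CDF is the right-continuous empirical CDF", {
  cdf <- spacing_cdf(c(160, 170))
  expect_equal(cdf$fun(c(159, 160, 170)), c(0, 0.5, 1))
  expect_equal(spacing_cdf(rep(155, 5))$fun(c(154.9, 155)), c(0, 1))
  expect_error(spacing_cdf(numeric(0)), "at least one")

  # species presets: klac CDF right-shifted at every decile
  cfg <- sim_config(n_genes = 150, seed = 2)
  gen <- generate_genome(cfg)
  pooled <- lapply(c("scer", "klac"), function(p) {
    truth <- place_true_nucleosomes(gen, chromatin_params(p), seed = 2)
    maps <- map_gene_nucleosomes(truth_as_calls(truth), gen$genes)
    attr(spacing_metrics(maps), "pooled")
  })
  qs <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(quantile(pooled[[2]], qs) > quantile(pooled[[1]], qs)))
})

test_that("gene stratification splits by rank with deterministic ties", {
  sc <- stratify_genes(data.frame(gene_id = letters[1:8], score = c(8:1)), 4)
  expect_equal(unname(table(sc$group)), rep(2L, 4), ignore_attr = TRUE)
  expect_equal(sc$gene_id[sc$group == 4], c("b", "a"))  # highest scores

  ties <- stratify_genes(data.frame(gene_id = letters[8:1], score = 1), 4)
  expect_equal(ties$gene_id, letters[1:8])  # id order on ties
  expect_equal(ties$group, rep(1:4, each = 2))

  nas <- stratify_genes(data.frame(gene_id = letters[1:9],
                                   score = c(1:8, NA)), 4)
  expect_equal(attr(nas, "n_dropped"), 1L)
})

test_that("stratification separates genes by their true spacing response", {
  cfg <- sim_config(n_genes = 100, coverage = 30, seed = 5)
  gen <- generate_genome(cfg)
  truth_a <- place_true_nucleosomes(gen, chromatin_params("scer"), seed = 5)
  responders <- gen$genes$gene_id[1:50]
  truth_b <- apply_swap_perturbation(truth_a, 0, 6, 3,
                                     gene_ids = responders)
  maps_a <- map_gene_nucleosomes(truth_as_calls(truth_a), gen$genes)
  maps_b <- map_gene_nucleosomes(truth_as_calls(truth_b), gen$genes)

  scores <- data.frame(gene_id = gen$genes$gene_id,
                       score = ifelse(gen$genes$gene_id %in% responders,
                                      1, 0))
  strata <- stratify_genes(scores, 4)
  top <- strata$gene_id[strata$group == 4]
  bottom <- strata$gene_id[strata$group == 1]
  shift_for <- function(ids) {
    compare_spacing(maps_a[names(maps_a) %in% ids],
                    maps_b[names(maps_b) %in% ids], "body")$difference
  }
  expect_gt(shift_for(top), shift_for(bottom) + 3)
})
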