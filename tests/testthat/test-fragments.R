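# Stranded start tracks, cross-correlation fragment sizing, occupancy.

test_that("read starts are tabulated at the fragment ends and conserved", {
  tr <- count_read_starts(data.frame(chrom = "chr1", start = 100, end = 247),
                          c(chr1 = 500))
  expect_equal(which(tr$counts$chr1$watson > 0) - 1L, 100L)
  expect_equal(which(tr$counts$chr1$crick > 0) - 1L, 246L)
  expect_equal(sum(tr$counts$chr1$watson), 1L)

  empty <- count_read_starts(data.frame(chrom = character(),
                                        start = integer(), end = integer()),
                             c(chr1 = 100))
  expect_true(all(empty$counts$chr1$watson == 0L))
  expect_true(all(empty$counts$chr1$crick == 0L))

  set.seed(42)
  st <- sample(0:800, 1000, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = st,
                   end = st + sample(100:180, 1000, replace = TRUE))
  tr <- count_read_starts(fr, c(chr1 = 1100))
  expect_equal(sum(tr$counts$chr1$watson), 1000L)
  expect_equal(sum(tr$counts$chr1$crick), 1000L)

  expect_error(count_read_starts(data.frame(chrom = "chr1", start = -1,
                                            end = 50), c(chr1 = 100)),
               "out-of-bounds")
})

test_that("cross-correlation recovers fragment length", {
  tr <- count_read_starts(data.frame(chrom = "chr1", start = 100, end = 247),
                          c(chr1 = 500))
  expect_equal(infer_fragment_length(tr), 147L)

  # fixed length anywhere: shift invariance
  set.seed(1)
  st <- sample(0:2000, 400, replace = TRUE)
  tr <- count_read_starts(data.frame(chrom = "chr1", start = st,
                                     end = st + 170), c(chr1 = 2400))
  expect_equal(infer_fragment_length(tr), 170L)

  # doubling all counts leaves the argmax unchanged
  tr2 <- tr
  tr2$counts$chr1$watson <- 2L * tr$counts$chr1$watson
  tr2$counts$chr1$crick <- 2L * tr$counts$chr1$crick
  expect_equal(infer_fragment_length(tr2), 170L)

  empty <- count_read_starts(data.frame(chrom = character(),
                                        start = integer(), end = integer()),
                             c(chr1 = 100))
  expect_error(infer_fragment_length(empty), "no reads")
})

test_that("cross-correlation matches an exhaustive brute-force scan", {
  set.seed(1)
  st <- sample(0:1500, 300, replace = TRUE)
  len <- pmin(pmax(round(rnorm(300, 147, 8)), 100), 250)
  tr <- count_read_starts(data.frame(chrom = "chr1", start = st,
                                     end = st + len), c(chr1 = 1800))
  # independent oracle: direct double loop over every shift in the window
  w <- tr$counts$chr1$watson
  cr <- tr$counts$chr1$crick
  n <- length(w)
  best <- -Inf; best_k <- NA
  for (k in 49:299) {
    s <- 0
    for (x in seq_len(n - k)) s <- s + w[x] * cr[x + k]
    if (s > best) { best <- s; best_k <- k }
  }
  expect_equal(infer_fragment_length(tr), best_k + 1L)
})

test_that("extending starts reproduces exact fragment coverage", {
  tr <- track_from_positions(watson = 100L, crick = integer(0), len = 400)
  occ <- extend_and_count(tr, 147)
  expect_equal(which(occ$values$chr1 > 0) - 1L, 100:246)

  trc <- track_from_positions(watson = integer(0), crick = 246L, len = 400)
  occ_c <- extend_and_count(trc, 147)
  expect_equal(which(occ_c$values$chr1 > 0) - 1L, 100:246)

  # duality: extending a full-fragment track (both ends tabulated) by the
  # true length gives exactly twice the direct interval coverage, hence
  # identical normalized tracks
  set.seed(9)
  st <- sample(0:900, 200, replace = TRUE)
  fr <- data.frame(chrom = "chr1", start = st, end = st + 160)
  tr <- count_read_starts(fr, c(chr1 = 1200))
  ext <- extend_and_count(tr, 160)
  direct <- fragment_coverage(fr, c(chr1 = 1200))
  expect_equal(ext$values$chr1, 2 * direct$values$chr1)
  expect_equal(normalize_track(ext)$values$chr1,
               normalize_track(direct)$values$chr1)

  # per-bp oracle on a mixed small track
  set.seed(10)
  wp <- sample(0:300, 40); cp <- sample(100:340, 40)
  trm <- track_from_positions(wp, cp, len = 400)
  occ_m <- extend_and_count(trm, 120)$values$chr1
  oracle <- numeric(400)
  for (p in wp) for (x in p:min(p + 119, 399)) oracle[x + 1] <- oracle[x + 1] + 1
  for (q in cp) for (x in max(q - 119, 0):q) oracle[x + 1] <- oracle[x + 1] + 1
  expect_equal(occ_m, oracle)
})

test_that("normalization sets the genome-wide mean to 1", {
  mk <- function(v) structure(list(values = list(chr1 = v),
                                   chrom_lengths = c(chr1 = length(v)),
                                   normalized = FALSE),
                              class = "occupancy_track")
  expect_equal(normalize_track(mk(c(2, 2, 2, 2)))$values$chr1, rep(1, 4))
  expect_equal(normalize_track(mk(c(0, 4)))$values$chr1, c(0, 2))
  expect_error(normalize_track(mk(c(0, 0))), "all-zero")

  cfg <- sim_config(n_genes = 5, coverage = 10, seed = 3)
  gen <- generate_genome(cfg)
  truth <- place_true_nucleosomes(gen, chromatin_params("scer"), seed = 3)
  fr <- simulate_fragments(truth, cfg)
  occ <- normalize_track(fragment_coverage(fr, gen$chrom_lengths))
  m <- sum(vapply(occ$values, sum, numeric(1))) /
    sum(as.numeric(occ$chrom_lengths))
  expect_lt(abs(m - 1), 1e-9)
})

test_that("metaprofile is anchored at the +1 edge and strand-symmetric", {
  # constant track of 1 -> every complete bin is 1
  gen <- one_gene(start = 1000L, end = 2000L, chrom_len = 4000L)
  flat <- structure(list(values = list(chr1 = rep(1, 4000)),
                         chrom_lengths = c(chr1 = 4000), normalized = TRUE),
                    class = "occupancy_track")
  calls <- data.frame(chrom = "chr1", dyad = c(700, 1060, 1225))
  maps <- map_gene_nucleosomes(calls, gen$genes)
  mp <- plus1_aligned_metaprofile(flat, maps)
  expect_true(all(abs(mp$profile - 1) < 1e-12))
  # row spans edge-500 .. gene end in complete 10 bp bins
  expect_equal(length(mp$profile), ((2000 - (1060 - 73)) + 500) %/% 10)

  # minus-strand gene with asymmetric coverage equals the mirrored
  # plus-strand computation
  v <- sin(seq_len(4000) / 40) + 2
  tr_p <- structure(list(values = list(chr1 = v),
                         chrom_lengths = c(chr1 = 4000), normalized = TRUE),
                    class = "occupancy_track")
  tr_m <- structure(list(values = list(chr1 = rev(v)),
                         chrom_lengths = c(chr1 = 4000), normalized = TRUE),
                    class = "occupancy_track")
  gen_m <- mirror_annotation(gen)
  calls_m <- data.frame(chrom = "chr1", dyad = 4000 - 1 - calls$dyad)
  maps_m <- map_gene_nucleosomes(calls_m, gen_m$genes)
  prof_p <- plus1_aligned_metaprofile(tr_p, maps)$rows[1, ]
  prof_m <- plus1_aligned_metaprofile(tr_m, maps_m)$rows[1, ]
  expect_equal(prof_m, prof_p)
})

test_that("metaprofile equals a naive per-gene binning oracle", {
  cfg <- sim_config(n_genes = 50, coverage = 20, seed = 4)
  gen <- generate_genome(cfg)
  truth <- place_true_nucleosomes(gen, chromatin_params("scer"), seed = 4)
  fr <- simulate_fragments(truth, cfg)
  occ <- normalize_track(fragment_coverage(fr, gen$chrom_lengths))
  maps <- map_gene_nucleosomes(truth_as_calls(truth), gen$genes)
  mp <- plus1_aligned_metaprofile(occ, maps, upstream = 500, bin = 10)

  # independent oracle: explicit loop, explicit indexing
  rows <- list()
  for (gid in names(maps)) {
    m <- maps[[gid]]
    v <- occ$values[[m$chrom]]
    if (m$strand == "+") {
      pos <- (m$plus1$dyad - 73 - 500):(m$end - 1)
    } else {
      pos <- (m$plus1$dyad + 73 + 500):m$start
    }
    vals <- v[pos + 1]
    nb <- length(vals) %/% 10
    bins <- numeric(nb)
    for (b in seq_len(nb)) bins[b] <- mean(vals[((b - 1) * 10 + 1):(b * 10)])
    rows[[gid]] <- bins
  }
  nb_max <- max(lengths(rows))
  for (b in seq_len(nb_max)) {
    have <- vapply(rows, function(r) length(r) >= b, logical(1))
    oracle_mean <- mean(vapply(rows[have], `[`, numeric(1), b))
    expect_equal(unname(mp$profile[b]), oracle_mean, tolerance = 1e-12)
  }
})

test_that("zero-noise metaprofile peaks at the true dyad bins", {
  pa <- chromatin_params(repeat_length = 165, fuzz_sd = 0, occupancy_prob = 1)
  cfg <- sim_config(n_genes = 4, coverage = 30, frag_sd = 0, background = 0,
                    seed = 6)
  gen <- generate_genome(cfg)
  truth <- place_true_nucleosomes(gen, pa, seed = 6)
  fr <- simulate_fragments(truth, cfg)
  occ <- normalize_track(fragment_coverage(fr, gen$chrom_lengths))
  maps <- map_gene_nucleosomes(truth_as_calls(truth), gen$genes)
  mp <- plus1_aligned_metaprofile(occ, maps)
  # +1 dyad sits 573 bp into the row (500 upstream + 73 half-footprint):
  # local maxima of the profile should fall within 1 bin of the true
  # dyad bins 57, 73, 90, ... (574/10, (574+165)/10, ...)
  for (k in 0:5) {
    dyad_bin <- (573 + k * 165) %/% 10 + 1
    window <- mp$profile[(dyad_bin - 8):(dyad_bin + 8)]
    # flat-topped occupancy: locate the center of the maximal plateau
    run <- which(window >= max(window) - 1e-9)
    expect_lte(abs(mean(range(run)) - 9), 1)
  }
})
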