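# Template-filter nucleosome calling: matched filtering of stranded
# read-start tracks against a bank of fragment-size-specific templates.

#' Build nucleosome templates
#'
#' Builds one matched-filter template per nominal fragment length L. Each
#' template has a Gaussian Watson read-start profile centered L/2 bp
#' upstream of the dyad and a mirror-image Crick profile centered L/2 bp
#' downstream, discretized over +/- 3 sd and normalized to sum 1 per
#' strand. Seven lengths spanning 120-180 bp capture fragments from
#' varying digestion extents.
#'
#' @param lengths Nominal fragment lengths, bp.
#' @param spread_sd Standard deviation of the start-position spread, bp.
#' @return A list of class `template_bank`; each element has `length`,
#'   `w_off`/`w_wt` (Watson offsets relative to the dyad and weights) and
#'   `c_off`/`c_wt` (Crick).
#' @examples
#' length(build_templates())  # 7
#' @export
build_templates <- function(lengths = seq(120L, 180L, by = 10L),
                            spread_sd = 10) {
  if (spread_sd <= 0) stopf("spread_sd must be > 0")
  if (any(lengths < 2 * spread_sd))
    stopf("all template lengths must be >= 2 * spread_sd")
  bank <- lapply(lengths, function(L) {
    half <- L / 2
    r <- ceiling(3 * spread_sd)
    w_off <- seq.int(floor(-half) - r, ceiling(-half) + r)
    w_wt <- stats::dnorm(w_off, -half, spread_sd)
    w_wt <- w_wt / sum(w_wt)
    # Crick profile is the mirror image of the Watson profile
    c_off <- rev(-w_off)
    c_wt <- rev(w_wt)
    list(length = as.integer(L), w_off = as.integer(w_off), w_wt = w_wt,
         c_off = as.integer(c_off), c_wt = c_wt)
  })
  structure(bank, class = "template_bank")
}

# Cross-correlate one weighted profile against a count vector:
# out[i] = sum_j wt[j] * x[i + off[j]] (zero outside the chromosome).
profile_xcorr <- function(x, off, wt) {
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(off)) {
    o <- off[j]
    lo <- max(1L, 1L - o)
    hi <- min(n, n - o)
    if (lo > hi) next
    idx <- lo:hi
    out[idx] <- out[idx] + wt[j] * x[idx + o]
  }
  out
}

#' Score candidate dyad positions with the template bank
#'
#' For every base pair d, computes the matched-filter response of each
#' template (Watson profile against Watson starts plus Crick profile
#' against Crick starts, both centered at d), takes the best template,
#' and normalizes by the total start count in a 300 bp window centered at
#' d (score 0 where the window is empty). The normalization makes the
#' score — and hence the call threshold — independent of sequencing depth.
#'
#' @param track A `start_track`.
#' @param templates A `template_bank` from [build_templates()].
#' @param norm_window Width of the local-mass normalization window, bp.
#' @return An object of class `score_track`: per chromosome a list with
#'   `score` (numeric) and `template_length` (best template per position).
#' @export
template_score <- function(track, templates = build_templates(),
                           norm_window = 300L) {
  stopifnot(inherits(track, "start_track"),
            inherits(templates, "template_bank"))
  half_w <- norm_window %/% 2L
  chroms <- lapply(track$counts, function(ci) {
    w <- as.numeric(ci$watson)
    cr <- as.numeric(ci$crick)
    n <- length(w)
    best <- numeric(n)
    best_len <- integer(n)
    for (tp in templates) {
      raw <- profile_xcorr(w, tp$w_off, tp$w_wt) +
        profile_xcorr(cr, tp$c_off, tp$c_wt)
      better <- raw > best
      best[better] <- raw[better]
      best_len[better] <- tp$length
    }
    # local total start count in the window [d - half_w, d + half_w)
    cs <- cumsum(w + cr)
    idx <- seq_len(n)
    hi <- pmin(n, idx + half_w - 1L)
    lo <- pmax(1L, idx - half_w)
    mass <- cs[hi] - c(0, cs)[lo]
    score <- ifelse(mass > 0, best / mass, 0)
    list(score = score, template_length = best_len)
  })
  structure(list(chroms = chroms, chrom_lengths = track$chrom_lengths),
            class = "score_track")
}

#' Call nucleosome positions from a score track
#'
#' Greedy peak selection: repeatedly takes the highest-scoring remaining
#' position with score >= `threshold`, emits a call, and suppresses all
#' positions closer than `min_separation` bp. Ties are broken toward the
#' smaller coordinate. No two calls on a chromosome end up closer than
#' `min_separation`.
#'
#' @param scores A `score_track` from [template_score()].
#' @param threshold Minimum normalized score for a call.
#' @param min_separation Suppression radius between calls, bp.
#' @return Data.frame of class `nucleosome_calls`: `chrom`, `dyad`
#'   (0-based), `score`, `template_length`, sorted by chromosome and dyad.
#' @export
call_positions <- function(scores, threshold = 0.01, min_separation = 120L) {
  stopifnot(inherits(scores, "score_track"))
  if (threshold <= 0) stopf("threshold must be > 0")
  res <- list()
  for (cn in names(scores$chroms)) {
    sc <- scores$chroms[[cn]]$score
    n <- length(sc)
    cand <- which(sc >= threshold)
    if (!length(cand)) next
    ord <- cand[order(-sc[cand], cand)]
    suppressed <- logical(n)
    keep <- integer(0)
    for (p in ord) {
      if (suppressed[p]) next
      keep <- c(keep, p)
      suppressed[max(1L, p - min_separation + 1L):
                   min(n, p + min_separation - 1L)] <- TRUE
    }
    keep <- sort(keep)
    res[[cn]] <- data.frame(
      chrom = cn, dyad = keep - 1L, score = sc[keep],
      template_length = scores$chroms[[cn]]$template_length[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), dyad = integer(), score = numeric(),
               template_length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("nucleosome_calls", "data.frame")
  out
}

#' Run start-track processing and nucleosome calling in one step
#'
#' Convenience wrapper: counts read starts, scores with the template
#' bank, and calls positions.
#'
#' @inheritParams count_read_starts
#' @inheritParams call_positions
#' @param templates A `template_bank`.
#' @return A `nucleosome_calls` data.frame.
#' @export
call_nucleosomes <- function(fragments, chrom_lengths,
                             templates = build_templates(),
                             threshold = 0.01, min_separation = 120L) {
  track <- count_read_starts(fragments, chrom_lengths)
  call_positions(template_score(track, templates),
                 threshold = threshold, min_separation = min_separation)
}
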