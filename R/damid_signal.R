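# Fragment-level Fisher exact signal --------------------------------------
#
# The DamID signal for one factor/genotype is, per GATC fragment, the
# two-sided Fisher exact test P comparing the fragment's share of reads in
# the Dam-fusion library against the Dam-alone control, reported as
# -log10(P) with the direction (enriched vs depleted) carried as a sign.

#' Fisher exact test per fragment
#'
#' Two-sided Fisher exact test on the 2x2 table
#' `[count_x, total_x - count_x; count_dam, total_dam - count_dam]`:
#' the probability, under the hypergeometric null fixing all margins, of a
#' table at most as probable as the observed one (tables within relative
#' tolerance 1e-7 of the observed probability are included, the usual
#' convention for this test). All arguments are vectorized and recycled.
#'
#' @param count_x,total_x Fragment count and library total for the
#'   Dam-fusion channel.
#' @param count_dam,total_dam Fragment count and library total for the
#'   Dam-alone channel.
#' @return data.frame with columns `p_value` and `sign` (+1 if the fusion
#'   proportion exceeds the control proportion, -1 if below, 0 if equal).
#' @examples
#' fisher_fragment_test(50, 10000, 5, 10000)
#' @export
fisher_fragment_test <- function(count_x, total_x, count_dam, total_dam) {
  n <- max(length(count_x), length(total_x), length(count_dam),
           length(total_dam))
  a <- rep_len(as.numeric(count_x), n)
  m <- rep_len(as.numeric(total_x), n)
  b <- rep_len(as.numeric(count_dam), n)
  d <- rep_len(as.numeric(total_dam), n)
  .assert(all(m > 0) && all(d > 0), "library totals must be positive")
  .assert(all(a >= 0) && all(b >= 0), "counts must be non-negative")
  .assert(all(a <= m) && all(b <= d), "counts cannot exceed totals")
  data.frame(p_value = .fisher_p(a, m, b, d),
             sign = sign(a / m - b / d))
}

# Vectorized two-sided Fisher P. Tables are grouped by their margins
# (total_x, total_dam, count_x + count_dam); within a group the full
# hypergeometric pmf over the support is computed once and the two-sided
# tail for every observed count is read off a sorted cumulative sum.
.fisher_p <- function(a, m, b, d) {
  k <- a + b
  p <- numeric(length(a))
  groups <- split(seq_along(a), paste(m, d, k))
  for (g in groups) {
    mi <- m[g[1L]]; di <- d[g[1L]]; ki <- k[g[1L]]
    lo <- max(0, ki - di); hi <- min(ki, mi)
    pmf <- stats::dhyper(lo:hi, mi, di, ki)
    s <- sort(pmf)
    cs <- cumsum(s)
    pa <- pmf[a[g] - lo + 1L]
    idx <- findInterval(pa * (1 + 1e-7), s)
    p[g] <- pmin(cs[idx], 1)
  }
  p
}

#' Build the signed -log10(P) signal track
#'
#' Replicate counts are summed per channel (replicates are reserved for the
#' noise-based FDR calibration, see [noise_track()]), each fragment is
#' tested with [fisher_fragment_test()], and a depth-normalized log2 ratio
#' is computed with a pseudocount. Positive sign marks fragments enriched
#' for the fused factor, negative sign depleted ones.
#'
#' @param x_reps,dam_reps A `FragmentCounts` or list of replicate
#'   `FragmentCounts` for the Dam-fusion and Dam-alone channels.
#' @param map The `FragmentMap` shared by all counts.
#' @param pseudocount Added to raw counts before depth normalization for the
#'   log2 ratio only; the Fisher test uses raw counts (margins
#'   self-normalize). Default 0.5.
#' @param cap Ceiling for `neglog10_p` (default 300), preventing -Inf in
#'   serialized tracks when P underflows.
#' @param factor,genotype Labels stored on the track.
#' @return A `SignalTrack`: list with per-fragment vectors `neglog10_p`,
#'   `sign`, `log2_ratio`, `counts_x`, `counts_dam`, the channel totals, and
#'   the `map`.
#' @export
build_signal_track <- function(x_reps, dam_reps, map, pseudocount = 0.5,
                               cap = 300, factor = "factor",
                               genotype = "wt") {
  cx <- .sum_reps(x_reps, map)
  cd <- .sum_reps(dam_reps, map)
  tx <- sum(cx); td <- sum(cd)
  .assert(tx > 0 && td > 0, "each channel needs a positive read total")
  ft <- fisher_fragment_test(cx, tx, cd, td)
  lr <- log2(((cx + pseudocount) / tx) / ((cd + pseudocount) / td))
  structure(list(factor = factor, genotype = genotype,
                 neglog10_p = pmin(-log10(ft$p_value), cap),
                 sign = ft$sign, log2_ratio = lr,
                 counts_x = cx, counts_dam = cd,
                 total_x = tx, total_dam = td,
                 pseudocount = pseudocount, cap = cap, map = map),
            class = "SignalTrack")
}

.sum_reps <- function(reps, map) {
  if (inherits(reps, "FragmentCounts")) reps <- list(reps)
  .assert(length(reps) >= 1, "at least one replicate required")
  for (r in reps) {
    .assert(inherits(r, "FragmentCounts"), "replicates must be FragmentCounts")
    .assert(r$n_fragments == nrow(map),
            "replicate is on a different fragment map (%d vs %d fragments)",
            r$n_fragments, nrow(map))
  }
  Reduce(`+`, lapply(reps, `[[`, "counts"))
}

#' @export
print.SignalTrack <- function(x, ...) {
  cat(sprintf(
    "SignalTrack %s/%s: %d fragments, %d with -log10(P) > 3 (%d enriched)\n",
    x$factor, x$genotype, length(x$neglog10_p), sum(x$neglog10_p > 3),
    sum(x$neglog10_p > 3 & x$sign > 0)))
  invisible(x)
}

#' Signed -log10(P) vector of a track
#'
#' @param track A `SignalTrack`.
#' @return Numeric vector, positive where enriched, negative where depleted.
#' @export
signal_signed <- function(track) track$sign * track$neglog10_p

#' Write / read a signal track
#'
#' The track is serialized as a bedGraph-like TSV (chrom, start, end,
#' signed -log10 P) plus companion columns `log2_ratio`, `count_x`,
#' `count_dam` so the reader can reconstruct the track exactly.
#'
#' @param track A `SignalTrack`.
#' @param path Output/input path.
#' @param map `FragmentMap` (reader only).
#' @export
write_signal_track <- function(track, path) {
  m <- track$map
  df <- data.frame(chrom = m$chrom, start = m$start, end = m$end,
                   signed_neglog10_p = signal_signed(track),
                   log2_ratio = track$log2_ratio,
                   count_x = track$counts_x, count_dam = track$counts_dam)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# factor=%s genotype=%s pseudocount=%g cap=%g",
                     track$factor, track$genotype, track$pseudocount,
                     track$cap), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_track
#' @export
read_signal_track <- function(path, map) {
  header <- readLines(path, n = 1L)
  kv <- regmatches(header, gregexpr("[a-z0-9_]+=[^ ]+", header))[[1]]
  meta <- stats::setNames(sub("^[^=]+=", "", kv), sub("=.*$", "", kv))
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  x <- fragment_counts(df$count_x, map, construct = "dam_fusion")
  d <- fragment_counts(df$count_dam, map, construct = "dam_alone")
  build_signal_track(x, d, map,
                     pseudocount = as.numeric(meta[["pseudocount"]]),
                     cap = as.numeric(meta[["cap"]]),
                     factor = meta[["factor"]], genotype = meta[["genotype"]])
}
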