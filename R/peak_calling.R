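# Replicate-calibrated FDR and peak calling -------------------------------
#
# Significance thresholds are calibrated empirically: the same Fisher track
# machinery is run on biological replicate 1 vs replicate 2 of the fusion
# construct, where every "peak" is experimental noise. The FDR at a
# threshold t is the ratio of noise peaks to signal peaks called at t, and
# the working threshold t* is the loosest grid point with FDR at or below
# the cutoff (0.05 throughout).

#' Replicate-vs-replicate noise track
#'
#' Fisher signal track treating replicate 1 as "treatment" and replicate 2
#' as "control". On a pair of true biological replicates every significant
#' fragment is noise, which is what the FDR calibration measures.
#'
#' @param rep1,rep2 `FragmentCounts` of two biological replicates of the
#'   same construct and genotype.
#' @param map The shared `FragmentMap`.
#' @param ... Passed to [build_signal_track()].
#' @return A `SignalTrack`.
#' @export
noise_track <- function(rep1, rep2, map, ...) {
  .assert(inherits(rep1, "FragmentCounts") && inherits(rep2, "FragmentCounts"),
          "noise_track needs two FragmentCounts replicates")
  .assert(identical(rep1$construct, rep2$construct) &&
            identical(rep1$genotype, rep2$genotype),
          "replicates must share construct and genotype")
  build_signal_track(rep1, rep2, map, ...,
                     factor = paste0(rep1$sample_id, ".noise"),
                     genotype = rep1$genotype)
}

# Merged-interval peak count at one threshold. Eligibility is identical for
# signal and noise tracks; runs of adjacent eligible fragments (same
# chromosome, consecutive rows of the map) are counted as one peak.
.eligible <- function(track, p_cutoff, ratio_cutoff, direction = 1L) {
  nlp <- -log10(p_cutoff)
  if (direction > 0L) {
    track$sign > 0 & track$neglog10_p >= nlp & track$log2_ratio > ratio_cutoff
  } else {
    track$sign < 0 & track$neglog10_p >= nlp & track$log2_ratio < -ratio_cutoff
  }
}

.run_starts <- function(eligible, chrom) {
  new_chrom <- c(TRUE, chrom[-1L] != chrom[-length(chrom)])
  eligible & (c(FALSE, eligible[-length(eligible)]) == FALSE | new_chrom)
}

.count_peaks <- function(track, p_cutoff, ratio_cutoff, direction = 1L) {
  e <- .eligible(track, p_cutoff, ratio_cutoff, direction)
  sum(.run_starts(e, track$map$chrom))
}

#' Calibrate the FDR threshold from a noise track
#'
#' For each P-value cutoff on the grid, counts merged peaks on the signal
#' track (`n_signal`) and on the replicate noise track (`n_noise`) under the
#' same compound criteria, and reports `fdr = n_noise / max(n_signal, 1)`.
#' The chosen threshold `t_star` is the loosest grid point whose FDR is at
#' most `fdr_cutoff`; if no grid point qualifies, the tightest point is
#' returned with a warning.
#'
#' @param signal,noise `SignalTrack`s on the same map (see [noise_track()]).
#' @param grid Decreasing sequence of P-value cutoffs; default 50 log-spaced
#'   points from 1e-3 to 1e-12.
#' @param fdr_cutoff Maximum tolerated FDR (default 0.05).
#' @param ratio_cutoff log2-ratio criterion applied on both tracks
#'   (default 1).
#' @return An `FdrCurve`: data.frame with columns `p_cutoff`, `n_signal`,
#'   `n_noise`, `fdr`, with the selected threshold in `attr(, "t_star")`.
#' @export
calibrate_fdr <- function(signal, noise,
                          grid = 10^seq(-3, -12, length.out = 50),
                          fdr_cutoff = 0.05, ratio_cutoff = 1) {
  .assert(length(grid) > 0, "threshold grid is empty")
  .assert(nrow(signal$map) == nrow(noise$map),
          "signal and noise tracks are on different maps")
  grid <- sort(grid, decreasing = TRUE)
  n_signal <- vapply(grid, function(t) .count_peaks(signal, t, ratio_cutoff),
                     numeric(1))
  n_noise <- vapply(grid, function(t) .count_peaks(noise, t, ratio_cutoff),
                    numeric(1))
  fdr <- n_noise / pmax(n_signal, 1)
  curve <- data.frame(p_cutoff = grid, n_signal = n_signal,
                      n_noise = n_noise, fdr = fdr)
  ok <- which(fdr <= fdr_cutoff)
  if (length(ok) == 0L) {
    warning("no grid point reaches the FDR cutoff; using the tightest one")
    t_star <- grid[length(grid)]
  } else {
    t_star <- grid[ok[1L]]  # loosest passing point (grid is decreasing)
  }
  attr(curve, "t_star") <- t_star
  attr(curve, "fdr_cutoff") <- fdr_cutoff
  attr(curve, "ratio_cutoff") <- ratio_cutoff
  class(curve) <- c("FdrCurve", "data.frame")
  curve
}

#' Call enrichment peaks
#'
#' A fragment is peak-eligible when it is enriched (sign +1), its Fisher P
#' is at most the effective cutoff `min(t_star, p_cutoff)`, and its log2
#' ratio exceeds `ratio_cutoff`. Runs of adjacent eligible fragments are
#' merged into one peak (strict adjacency: a single ineligible fragment
#' breaks a peak); the summit is the fragment with the largest -log10 P,
#' leftmost on ties, and the peak's position for distance computations is
#' the summit fragment midpoint.
#'
#' @param signal A `SignalTrack`.
#' @param t_star FDR-calibrated P cutoff (see [calibrate_fdr()]).
#' @param p_cutoff Hard significance cutoff, default 1e-3.
#' @param ratio_cutoff log2(Dam-X/Dam) must exceed this, default 1.
#' @return A `PeakSet`: data.frame with columns `chrom`, `start`, `end`,
#'   `name`, `score` (max -log10 P), `log2_ratio` (at the summit),
#'   `summit_start`, `summit_end`, `summit_mid`, `n_fragments`; calling
#'   parameters in `attr(, "params")`.
#' @export
call_peaks <- function(signal, t_star, p_cutoff = 1e-3, ratio_cutoff = 1) {
  .call_runs(signal, min(t_star, p_cutoff), ratio_cutoff, direction = 1L,
             params = list(t_star = t_star, p_cutoff = p_cutoff,
                           ratio_cutoff = ratio_cutoff, direction = "enriched"))
}

#' Call depleted regions
#'
#' Mirror of [call_peaks()] for the depleted side: sign -1 and
#' `log2_ratio < -ratio_cutoff`.
#'
#' @inheritParams call_peaks
#' @return A `PeakSet` (scores are the depleted fragments' -log10 P).
#' @export
depleted_regions <- function(signal, t_star, p_cutoff = 1e-3,
                             ratio_cutoff = 1) {
  .call_runs(signal, min(t_star, p_cutoff), ratio_cutoff, direction = -1L,
             params = list(t_star = t_star, p_cutoff = p_cutoff,
                           ratio_cutoff = ratio_cutoff, direction = "depleted"))
}

.call_runs <- function(track, p_eff, ratio_cutoff, direction, params) {
  m <- track$map
  e <- .eligible(track, p_eff, ratio_cutoff, direction)
  starts <- which(.run_starts(e, m$chrom))
  if (length(starts) == 0L) {
    peaks <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        score = numeric(), log2_ratio = numeric(),
                        summit_start = integer(), summit_end = integer(),
                        summit_mid = integer(), n_fragments = integer())
  } else {
    run_id <- cumsum(.run_starts(e, m$chrom)) * e  # 0 where ineligible
    idx <- which(e)
    rid <- run_id[idx]
    summit <- vapply(split(idx, rid), function(ii) {
      ii[which.max(track$neglog10_p[ii])]  # which.max: leftmost on ties
    }, numeric(1))
    first <- vapply(split(idx, rid), min, numeric(1))
    last <- vapply(split(idx, rid), max, numeric(1))
    peaks <- data.frame(
      chrom = m$chrom[first],
      start = m$start[first],
      end = m$end[last],
      name = paste0("peak_", seq_along(first)),
      score = track$neglog10_p[summit],
      log2_ratio = track$log2_ratio[summit],
      summit_start = m$start[summit],
      summit_end = m$end[summit],
      summit_mid = (m$start[summit] + m$end[summit]) %/% 2L,
      n_fragments = as.integer(last - first + 1L),
      stringsAsFactors = FALSE)
  }
  attr(peaks, "params") <- params
  attr(peaks, "factor") <- track$factor
  attr(peaks, "genotype") <- track$genotype
  class(peaks) <- c("PeakSet", "data.frame")
  peaks
}

#' Peak summits as width-1 GRanges
#'
#' @param peaks A `PeakSet`.
#' @return GRanges of summit midpoints (1-based).
#' @export
peak_summit_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$summit_mid + 1L, width = 1L))
}

#' Peak intervals as GRanges
#'
#' @param peaks A `PeakSet`.
#' @return GRanges of full peak intervals (1-based closed).
#' @export
peak_granges <- function(peaks) {
  GenomicRanges::GRanges(peaks$chrom,
                         IRanges::IRanges(peaks$start + 1L, peaks$end))
}

#' Write / read a peak set as BED6+
#'
#' Columns: chrom, start, end, name, score (max -log10 P), strand (`.`),
#' then log2_ratio, summit_start, summit_end, summit_mid, n_fragments.
#' Calling parameters are echoed into `#` header lines.
#'
#' @param peaks A `PeakSet`.
#' @param path Output/input path.
#' @export
write_peaks <- function(peaks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- attr(peaks, "params")
  writeLines(sprintf("# factor=%s genotype=%s %s", attr(peaks, "factor"),
                     attr(peaks, "genotype"),
                     paste(names(p), unlist(p), sep = "=", collapse = " ")),
             con)
  df <- data.frame(peaks$chrom, peaks$start, peaks$end, peaks$name,
                   peaks$score, ".", peaks$log2_ratio, peaks$summit_start,
                   peaks$summit_end, peaks$summit_mid, peaks$n_fragments)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand", "log2_ratio",
            "summit_start", "summit_end", "summit_mid", "n_fragments")
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = cols, stringsAsFactors = FALSE)
  df$strand <- NULL
  class(df) <- c("PeakSet", "data.frame")
  df
}

#' Write an FDR calibration curve as TSV
#'
#' @param curve An `FdrCurve`.
#' @param path Output path.
#' @export
write_fdr_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t_star=%g fdr_cutoff=%g ratio_cutoff=%g",
                     attr(curve, "t_star"), attr(curve, "fdr_cutoff"),
                     attr(curve, "ratio_cutoff")), con)
  write.table(as.data.frame(curve), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
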