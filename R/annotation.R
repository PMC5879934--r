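# Gene models and peak annotation -----------------------------------------
#
# Gene models carry one TSS per transcript (alternative TSSs are separate
# transcripts) plus 5'UTR/CDS/intron/3'UTR blocks. The promoter is the
# 400 bp immediately upstream of the TSS, strand-aware. All coordinates are
# 0-based half-open internally; GFF3 (1-based closed) is converted on IO.

#' Construct a gene-model set
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (`"+"`/`"-"`), `start`, `end` (0-based half-open
#'   transcript extent). The TSS is derived: `start` on plus, `end - 1` on
#'   minus strand.
#' @param features data.frame with columns `transcript_id`, `type` (one of
#'   `five_prime_UTR`, `CDS`, `intron`, `three_prime_UTR`), `start`, `end`.
#' @return A `GeneModels` object.
#' @export
gene_models <- function(transcripts, features) {
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  .assert(all(need %in% names(transcripts)),
          "transcripts need columns: %s", paste(need, collapse = ", "))
  .assert(all(transcripts$strand %in% c("+", "-")),
          "strand must be '+' or '-'")
  .assert(!anyDuplicated(transcripts$transcript_id),
          "transcript_id must be unique")
  .assert(all(features$transcript_id %in% transcripts$transcript_id),
          "features refer to unknown transcripts")
  ok_types <- c("five_prime_UTR", "CDS", "intron", "three_prime_UTR")
  .assert(all(features$type %in% ok_types),
          "feature types must be among: %s", paste(ok_types, collapse = ", "))
  transcripts$tss <- ifelse(transcripts$strand == "+",
                            transcripts$start, transcripts$end - 1L)
  ext <- transcripts[match(features$transcript_id, transcripts$transcript_id), ]
  .assert(all(features$start >= ext$start & features$end <= ext$end),
          "feature blocks must lie within their transcript extent")
  structure(list(transcripts = transcripts, features = features),
            class = "GeneModels")
}

#' @export
print.GeneModels <- function(x, ...) {
  cat(sprintf("GeneModels: %d transcripts (%d genes) on %d chromosome(s)\n",
              nrow(x$transcripts), length(unique(x$transcripts$gene_id)),
              length(unique(x$transcripts$chrom))))
  invisible(x)
}

#' TSS table of a gene-model set
#'
#' @param genes A `GeneModels`.
#' @return data.frame `transcript_id`, `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based position of the first transcribed base).
#' @export
tss_table <- function(genes) {
  genes$transcripts[, c("transcript_id", "gene_id", "chrom", "strand", "tss")]
}

#' Promoter intervals (400 bp upstream of each TSS, strand-aware)
#'
#' @param genes A `GeneModels`.
#' @param length Promoter length in bp upstream of the TSS (default 400).
#' @param chrom_lengths Optional named vector for right-edge truncation.
#' @return GRanges, one promoter per transcript (truncated at chromosome
#'   edges).
#' @export
promoter_ranges <- function(genes, length = 400, chrom_lengths = NULL) {
  tt <- genes$transcripts
  # 0-based half-open promoter, then to 1-based GRanges
  p_start <- ifelse(tt$strand == "+", tt$tss - length, tt$tss + 1L)
  p_end <- ifelse(tt$strand == "+", tt$tss, tt$tss + 1L + length)
  p_start <- pmax(p_start, 0L)
  if (!is.null(chrom_lengths))
    p_end <- pmin(p_end, chrom_lengths[tt$chrom])
  keep <- p_end > p_start
  GenomicRanges::GRanges(tt$chrom[keep],
                         IRanges::IRanges(p_start[keep] + 1L, p_end[keep]),
                         transcript_id = tt$transcript_id[keep])
}

.feature_granges <- function(genes, type) {
  f <- genes$features[genes$features$type == type, , drop = FALSE]
  if (nrow(f) == 0L) return(GenomicRanges::GRanges())
  chrom <- genes$transcripts$chrom[match(f$transcript_id,
                                         genes$transcripts$transcript_id)]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(f$start + 1L, f$end))
}

.subset_genes <- function(genes, universe) {
  if (is.null(universe)) return(genes)
  keep <- genes$transcripts$transcript_id %in% universe
  structure(list(transcripts = genes$transcripts[keep, , drop = FALSE],
                 features = genes$features[
                   genes$features$transcript_id %in% universe, , drop = FALSE]),
            class = "GeneModels")
}

#' Default feature precedence for summit classification
#' @export
feature_precedence <- function() {
  c("promoter", "five_prime_UTR", "CDS", "intron", "three_prime_UTR")
}

#' Classify peak summits into gene-feature categories
#'
#' Each peak summit (midpoint of the summit fragment) is assigned the
#' highest-precedence category it overlaps across all transcripts;
#' non-overlapping summits are `"other"` (intergenic). The paper-style
#' categories overlap between transcripts, so a total precedence order
#' makes the classification single-valued.
#'
#' @param peaks A `PeakSet`.
#' @param genes A `GeneModels`.
#' @param precedence Character vector ordering the categories, highest
#'   first; default [feature_precedence()].
#' @param merge_exon If `TRUE`, relabel `five_prime_UTR`, `CDS` and
#'   `three_prime_UTR` assignments as a single `exon` category.
#' @param promoter_length Promoter size in bp (default 400).
#' @return Character vector of categories, one per peak.
#' @export
classify_peak_feature <- function(peaks, genes,
                                  precedence = feature_precedence(),
                                  merge_exon = FALSE, promoter_length = 400) {
  summits <- peak_summit_granges(peaks)
  cat_ranges <- .category_ranges(genes, precedence, promoter_length)
  out <- rep("other", nrow(peaks))
  for (cat in rev(precedence)) {  # low precedence first, high overwrites
    gr <- cat_ranges[[cat]]
    if (length(gr) == 0L) next
    hit <- IRanges::overlapsAny(summits, gr)
    out[hit] <- cat
  }
  if (merge_exon)
    out[out %in% c("five_prime_UTR", "CDS", "three_prime_UTR")] <- "exon"
  out
}

.category_ranges <- function(genes, precedence, promoter_length) {
  out <- list()
  for (cat in precedence) {
    out[[cat]] <- if (cat == "promoter") {
      promoter_ranges(genes, promoter_length)
    } else {
      .feature_granges(genes, cat)
    }
  }
  out
}

#' Feature-category enrichment of a peak set
#'
#' Observed summit counts per category versus the probability expected from
#' the genomic base-pair coverage of that category (made disjoint by the
#' precedence order, within the given gene universe), with a one-sided
#' binomial test for over-representation. The `other` row collects summits
#' in none of the categories; its expected probability is the remainder, so
#' expected probabilities sum to 1.
#'
#' @inheritParams classify_peak_feature
#' @param genome_size Total genome length in bp (e.g.
#'   `sum(attr(map, "chrom_lengths"))`).
#' @param universe Optional vector of transcript_ids restricting the gene
#'   models (e.g. a tissue-specific transcript set).
#' @return A `FeatureDistribution` data.frame: `category`, `observed`,
#'   `expected_prob`, `expected_count`, `fold`, `p_value`.
#' @export
feature_enrichment <- function(peaks, genes, genome_size, universe = NULL,
                               precedence = feature_precedence(),
                               promoter_length = 400) {
  genes <- .subset_genes(genes, universe)
  cat_ranges <- .category_ranges(genes, precedence, promoter_length)
  # disjoint coverage by precedence
  cover <- numeric(length(precedence))
  names(cover) <- precedence
  higher <- GenomicRanges::GRanges()
  for (cat in precedence) {
    r <- GenomicRanges::reduce(cat_ranges[[cat]])
    eff <- GenomicRanges::setdiff(r, higher)
    cover[cat] <- sum(IRanges::width(eff))
    higher <- GenomicRanges::reduce(c(higher, r))
  }
  probs <- cover / genome_size
  obs_cat <- classify_peak_feature(peaks, genes, precedence,
                                   promoter_length = promoter_length)
  n <- nrow(peaks)
  categories <- c(precedence, "other")
  observed <- vapply(categories, function(cat) sum(obs_cat == cat), numeric(1))
  probs <- c(probs, other = max(0, 1 - sum(probs)))
  p <- ifelse(rep(n, length(categories)) == 0, 1,
              stats::pbinom(observed - 1, n, probs, lower.tail = FALSE))
  out <- data.frame(category = categories, observed = observed,
                    expected_prob = probs, expected_count = n * probs,
                    fold = ifelse(probs > 0, (observed / max(n, 1)) / probs, NA),
                    p_value = p, row.names = NULL)
  class(out) <- c("FeatureDistribution", "data.frame")
  out
}

# Nearest subject position per query, matched within chromosomes.
.nearest_position <- function(q_chrom, q_pos, s_chrom, s_pos) {
  out <- rep(NA_real_, length(q_pos))
  for (chr in unique(q_chrom)) {
    qi <- which(q_chrom == chr)
    sp <- sort(s_pos[s_chrom == chr])
    if (length(sp) == 0L) next
    idx <- findInterval(q_pos[qi], sp)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, length(sp))
    d_lo <- abs(q_pos[qi] - sp[lo])
    d_hi <- abs(q_pos[qi] - sp[hi])
    out[qi] <- ifelse(idx == 0L, sp[hi],
                      ifelse(idx >= length(sp) | d_lo <= d_hi,
                             sp[lo], sp[hi]))
  }
  out
}

#' Nearest-peak distance per TSS and its binned histogram
#'
#' For every transcript, the distance from its TSS to the nearest peak
#' summit is computed; transcripts with no peak within `window` are
#' reported but excluded from the histogram. Bins are half-open
#' `[0, bin), [bin, 2*bin), ...` on unsigned distances (default), or 2x as
#' many signed bins with upstream distances negative (strand-aware) when
#' `signed = TRUE`.
#'
#' @param genes A `GeneModels` (alternative TSSs are separate transcripts).
#' @param peaks A `PeakSet`.
#' @param window Maximum distance retained in the histogram (default 10000).
#' @param bin Bin width in bp (default 1000).
#' @param signed Use signed, strand-oriented distances (default `FALSE`).
#' @return list with `distances` (data.frame: `transcript_id`, `tss`,
#'   `nearest_summit`, `distance`, `signed_distance`) and `histogram`
#'   (data.frame: `bin_lo`, `bin_hi`, `count`).
#' @export
tss_distance_bins <- function(genes, peaks, window = 10000, bin = 1000,
                              signed = FALSE) {
  tt <- tss_table(genes)
  nearest <- .nearest_position(tt$chrom, tt$tss, peaks$chrom, peaks$summit_mid)
  d <- abs(tt$tss - nearest)
  sd_ <- ifelse(tt$strand == "+", nearest - tt$tss, tt$tss - nearest)
  distances <- data.frame(transcript_id = tt$transcript_id, chrom = tt$chrom,
                          tss = tt$tss, nearest_summit = nearest,
                          distance = d, signed_distance = sd_)
  if (signed) {
    breaks <- seq(-window, window, by = bin)
    vals <- sd_[!is.na(sd_) & abs(sd_) <= window & d <= window]
  } else {
    breaks <- seq(0, window, by = bin)
    vals <- d[!is.na(d) & d <= window]
  }
  idx <- pmin(findInterval(vals, breaks), length(breaks) - 1L)
  hist <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                     count = tabulate(idx, nbins = length(breaks) - 1L))
  list(distances = distances, histogram = hist)
}

#' Averaged peak profile around TSSs
#'
#' Restricted to transcripts with at least one peak interval overlapping
#' the window around the TSS, counts for each strand-oriented coordinate in
#' `-window..window` (upstream negative) the number of peaks covering it,
#' summed over transcripts, and normalizes to unit maximum. A baseline from
#' peaks re-placed uniformly at random (widths preserved, per chromosome)
#' is computed with the same procedure and reported on the same scale.
#'
#' @param genes A `GeneModels`.
#' @param peaks A `PeakSet`.
#' @param chrom_lengths Named vector of chromosome lengths (for the
#'   randomized baseline).
#' @param window Half-window in bp (default 1000).
#' @param n_baseline Number of randomizations averaged (default 10).
#' @return data.frame with `position` (-window..window), `count`,
#'   `profile` (unit max), `baseline_count`, `baseline` (same scale as
#'   `profile`), plus `n_genes` in an attribute.
#' @export
averaged_tss_profile <- function(genes, peaks, chrom_lengths, window = 1000,
                                 n_baseline = 10) {
  obs <- .tss_profile_counts(genes, peaks, window)
  base <- rep(0, 2 * window + 1)
  for (i in seq_len(n_baseline)) {
    rp <- .randomize_peaks(peaks, chrom_lengths)
    base <- base + .tss_profile_counts(genes, rp, window)$counts
  }
  base <- base / max(1, n_baseline)
  scale <- max(obs$counts, 1)
  out <- data.frame(position = -window:window, count = obs$counts,
                    profile = obs$counts / scale,
                    baseline_count = base, baseline = base / scale)
  attr(out, "n_genes") <- obs$n_genes
  out
}

.tss_profile_counts <- function(genes, peaks, window) {
  tt <- tss_table(genes)
  counts <- rep(0, 2 * window + 1)
  n_genes <- 0L
  for (chr in unique(tt$chrom)) {
    pk <- peaks[peaks$chrom == chr, , drop = FALSE]
    if (nrow(pk) == 0L) next
    for (ti in which(tt$chrom == chr)) {
      tss <- tt$tss[ti]
      ov <- which(pk$start < tss + window + 1 & pk$end > tss - window)
      if (length(ov) == 0L) next
      n_genes <- n_genes + 1L
      for (pi in ov) {
        rel_lo <- pk$start[pi] - tss
        rel_hi <- pk$end[pi] - 1L - tss  # inclusive covered positions
        if (tt$strand[ti] == "-") {
          tmp <- rel_lo; rel_lo <- -rel_hi; rel_hi <- -tmp
        }
        rel_lo <- max(rel_lo, -window)
        rel_hi <- min(rel_hi, window)
        idx <- (rel_lo + window + 1L):(rel_hi + window + 1L)
        counts[idx] <- counts[idx] + 1
      }
    }
  }
  list(counts = counts, n_genes = n_genes)
}

.randomize_peaks <- function(peaks, chrom_lengths) {
  w <- peaks$end - peaks$start
  new_start <- floor(runif(nrow(peaks), 0,
                           pmax(chrom_lengths[peaks$chrom] - w, 1)))
  out <- peaks
  out$start <- as.integer(new_start)
  out$end <- as.integer(new_start + w)
  out$summit_mid <- as.integer(new_start + w %/% 2L)
  out
}

#' Intergenic peaks
#'
#' Peaks whose summit lies at least `min_dist` bp from every TSS and
#' outside all transcript extents.
#'
#' @param peaks A `PeakSet`.
#' @param genes A `GeneModels`; an empty model set makes every peak
#'   intergenic.
#' @param min_dist Minimum summit-to-TSS distance in bp (default 1000);
#'   summits strictly closer are excluded.
#' @return The qualifying subset of `peaks`.
#' @export
intergenic_peaks <- function(peaks, genes, min_dist = 1000) {
  if (nrow(genes$transcripts) == 0L) return(peaks)
  tt <- tss_table(genes)
  nearest <- .nearest_position(peaks$chrom, peaks$summit_mid, tt$chrom, tt$tss)
  far <- is.na(nearest) | abs(peaks$summit_mid - nearest) >= min_dist
  tx_gr <- GenomicRanges::GRanges(
    genes$transcripts$chrom,
    IRanges::IRanges(genes$transcripts$start + 1L, genes$transcripts$end))
  outside <- !IRanges::overlapsAny(peak_summit_granges(peaks), tx_gr)
  out <- peaks[far & outside, , drop = FALSE]
  class(out) <- c("PeakSet", "data.frame")
  out
}

#' Observed/expected colocalization curve between two peak sets
#'
#' Signed offsets from each anchor summit to every query summit within
#' `max_offset` are binned; the expected bin frequency comes from placing
#' the same number of query summits on uniformly sampled GATC fragment
#' midpoints (`n_perm` draws, averaged). The enrichment is observed/expected
#' per bin with a one-sided binomial P for over-representation.
#'
#' @param anchor,query `PeakSet`s (both non-empty).
#' @param map The `FragmentMap` supplying the random-GATC baseline.
#' @param max_offset Half-range of offsets in bp (default 5000).
#' @param bin_width Offset bin width in bp (default 500).
#' @param n_perm Random placements averaged for the baseline (default 100).
#' @return data.frame: `offset_lo`, `offset_hi`, `observed`, `expected`,
#'   `enrichment`, `p_value`.
#' @export
colocalization_curve <- function(anchor, query, map, max_offset = 5000,
                                 bin_width = 500, n_perm = 100) {
  .assert(nrow(anchor) > 0 && nrow(query) > 0,
          "anchor and query peak sets must be non-empty")
  breaks <- seq(-max_offset, max_offset, by = bin_width)
  obs <- .offset_hist(anchor, query$chrom, query$summit_mid, breaks)
  exp_counts <- rep(0, length(breaks) - 1L)
  mids <- (map$start + map$end) %/% 2L
  for (i in seq_len(n_perm)) {
    pick <- sample.int(nrow(map), nrow(query), replace = TRUE)
    exp_counts <- exp_counts +
      .offset_hist(anchor, map$chrom[pick], mids[pick], breaks)
  }
  expected <- exp_counts / n_perm
  n_pairs <- nrow(anchor) * nrow(query)
  p0 <- pmin(expected / n_pairs, 1)
  p <- ifelse(p0 > 0, stats::pbinom(obs - 1, n_pairs, p0, lower.tail = FALSE),
              ifelse(obs > 0, 0, 1))
  data.frame(offset_lo = breaks[-length(breaks)], offset_hi = breaks[-1L],
             observed = obs, expected = expected,
             enrichment = ifelse(expected > 0, obs / expected, NA),
             p_value = p)
}

.offset_hist <- function(anchor, q_chrom, q_pos, breaks) {
  counts <- rep(0, length(breaks) - 1L)
  lo <- breaks[1L]; hi <- breaks[length(breaks)]
  for (chr in unique(anchor$chrom)) {
    ap <- anchor$summit_mid[anchor$chrom == chr]
    qp <- sort(q_pos[q_chrom == chr])
    if (length(qp) == 0L) next
    for (p in ap) {
      i1 <- findInterval(p + lo, qp) + 1L  # first qp > p + lo
      i2 <- findInterval(p + hi, qp)       # last qp <= p + hi
      if (i2 < i1) next
      off <- qp[i1:i2] - p
      idx <- pmin(findInterval(off, breaks), length(breaks) - 1L)
      idx <- pmax(idx, 1L)
      counts <- counts + tabulate(idx, nbins = length(breaks) - 1L)
    }
  }
  counts
}

#' Exact intersection partition of 2-3 peak sets
#'
#' Peaks from all sets are merged into loci (single-linkage by >= 1 bp
#' overlap); each locus contributes one count to the partition named by the
#' sets it contains, so a peak overlapping several peaks of another set is
#' counted once (Euler-diagram counting).
#'
#' @param sets Named list of 2-3 `PeakSet`s.
#' @return data.frame: `sets` (e.g. `"A&B"`), `count`, including zero rows
#'   for empty partitions.
#' @export
intersect_peak_sets <- function(sets) {
  .assert(is.list(sets) && length(sets) >= 2 && length(sets) <= 3 &&
            !is.null(names(sets)), "sets must be a named list of 2-3 PeakSets")
  grl <- lapply(sets, peak_granges)
  all_gr <- do.call(c, unname(grl))
  if (length(all_gr) == 0L) {
    loci <- GenomicRanges::GRanges()
  } else {
    loci <- GenomicRanges::reduce(all_gr)
  }
  member <- vapply(grl, function(gr) IRanges::overlapsAny(loci, gr),
                   logical(length(loci)))
  member <- matrix(member, nrow = length(loci), ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                 drop = FALSE]
  names(combos) <- names(sets)
  sig <- apply(combos, 1, function(row)
    paste(names(sets)[as.logical(row)], collapse = "&"))
  count <- apply(combos, 1, function(row) {
    if (length(loci) == 0L) return(0L)
    sum(apply(member, 1, function(m) identical(unname(m), as.logical(row))))
  })
  data.frame(sets = sig, count = as.integer(count), row.names = NULL)
}

# GFF3 IO ------------------------------------------------------------------

#' Write / read gene models as GFF3
#'
#' Transcripts are emitted as `mRNA` rows (ID = transcript_id, the gene in
#' `gene_id`), feature blocks as child rows of their transcript. rtracklayer
#' handles the 1-based closed GFF3 convention.
#'
#' @param genes A `GeneModels`.
#' @param path Output/input path.
#' @export
write_gene_models <- function(genes, path) {
  tt <- genes$transcripts
  ff <- genes$features
  fchrom <- tt$chrom[match(ff$transcript_id, tt$transcript_id)]
  fstrand <- tt$strand[match(ff$transcript_id, tt$transcript_id)]
  gr <- c(
    GenomicRanges::GRanges(tt$chrom, IRanges::IRanges(tt$start + 1L, tt$end),
                           strand = tt$strand, type = "mRNA",
                           ID = tt$transcript_id, gene_id = tt$gene_id),
    GenomicRanges::GRanges(fchrom, IRanges::IRanges(ff$start + 1L, ff$end),
                           strand = fstrand, type = ff$type,
                           ID = NA_character_, gene_id = NA_character_,
                           Parent = ff$transcript_id))
  gr$phase <- ifelse(gr$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  is_tx <- type %in% c("mRNA", "transcript")
  tx <- gr[is_tx]
  transcripts <- data.frame(
    transcript_id = as.character(tx$ID),
    gene_id = as.character(tx$gene_id),
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    start = GenomicRanges::start(tx) - 1L,
    end = GenomicRanges::end(tx),
    stringsAsFactors = FALSE)
  fe <- gr[!is_tx & type %in% c("five_prime_UTR", "CDS", "intron",
                                "three_prime_UTR")]
  parent <- vapply(fe$Parent, function(p) as.character(p)[1], character(1))
  features <- data.frame(
    transcript_id = parent,
    type = as.character(fe$type),
    start = GenomicRanges::start(fe) - 1L,
    end = GenomicRanges::end(fe),
    stringsAsFactors = FALSE)
  gene_models(transcripts, features)
}
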