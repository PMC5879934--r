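# GATC fragment coordinate system ---------------------------------------
#
# DamID resolves protein-DNA contacts to the genomic intervals between
# consecutive GATC motifs (the DpnII recognition site, its own reverse
# complement). Every signal, peak and annotation downstream lives on this
# partition. Coordinates are 0-based half-open throughout; BED on disk.

#' Build the GATC fragment map of a genome
#'
#' Partitions every chromosome into fragments delimited by occurrences of
#' the GATC motif. A fragment begins at the G of its left GATC; the first
#' fragment of a chromosome starts at 0 and the last one ends at the
#' chromosome end, so fragments tile each chromosome without gaps or
#' overlaps. The motif is searched on the forward strand only (GATC is
#' palindromic).
#'
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @return A `FragmentMap`: a data.frame with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `fragment_id` (1-based row index, stable
#'   across the whole map), with the chromosome lengths in
#'   `attr(, "chrom_lengths")`.
#' @examples
#' build_fragment_map(c(chrA = "AAGATCTTGATCAA"))
#' @export
build_fragment_map <- function(genome) {
  seqs <- .as_dnastringset(genome)
  .assert(length(seqs) > 0, "genome contains no sequences")
  .assert(all(Biostrings::width(seqs) > 0), "genome contains an empty sequence")
  .assert(!is.null(names(seqs)) && !anyNA(names(seqs)) &&
            !anyDuplicated(names(seqs)),
          "genome sequences must have unique names")
  pieces <- lapply(seq_along(seqs), function(i) {
    len <- Biostrings::width(seqs)[i]
    hits <- Biostrings::start(Biostrings::matchPattern("GATC", seqs[[i]]))
    if (length(hits) == 0L) {
      warning(sprintf("chromosome '%s' has no GATC site; one fragment spans it",
                      names(seqs)[i]))
    }
    bounds <- unique(c(0L, as.integer(hits) - 1L, len))  # to 0-based
    bounds <- sort(bounds)
    data.frame(chrom = names(seqs)[i],
               start = bounds[-length(bounds)],
               end   = bounds[-1L],
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  map$fragment_id <- seq_len(nrow(map))
  attr(map, "chrom_lengths") <- stats::setNames(Biostrings::width(seqs),
                                                names(seqs))
  class(map) <- c("FragmentMap", "data.frame")
  map
}

.as_dnastringset <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    return(Biostrings::readDNAStringSet(genome))
  if (is.character(genome))
    return(Biostrings::DNAStringSet(toupper(genome)))
  stop("genome must be a DNAStringSet, named character vector, or FASTA path")
}

#' @export
print.FragmentMap <- function(x, ...) {
  cat(sprintf("FragmentMap: %d fragments on %d chromosome(s), %d bp total\n",
              nrow(x), length(attr(x, "chrom_lengths")),
              sum(attr(x, "chrom_lengths"))))
  invisible(x)
}

#' Fragment map as GRanges
#'
#' @param map A `FragmentMap`.
#' @return A [GenomicRanges::GRanges] (1-based closed, as usual for GRanges).
#' @export
fragment_granges <- function(map) {
  gr <- GenomicRanges::GRanges(
    map$chrom,
    IRanges::IRanges(start = map$start + 1L, end = map$end),
    fragment_id = map$fragment_id,
    seqlengths = attr(map, "chrom_lengths"))
  gr
}

#' Write / read a fragment map as BED4
#'
#' @param map A `FragmentMap`.
#' @param path Output/input path.
#' @return `path` (writer) or a `FragmentMap` (reader). The reader recovers
#'   chromosome lengths from the rightmost fragment end per chromosome.
#' @export
write_fragment_map <- function(map, path) {
  write.table(map[, c("chrom", "start", "end", "fragment_id")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragment_map
#' @export
read_fragment_map <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "fragment_id"),
                   stringsAsFactors = FALSE)
  lens <- tapply(df$end, df$chrom, max)
  attr(df, "chrom_lengths") <- stats::setNames(as.integer(lens), names(lens))
  class(df) <- c("FragmentMap", "data.frame")
  df
}

# Per-fragment counts -----------------------------------------------------

#' Construct a per-fragment count object
#'
#' @param counts Non-negative integer vector, one entry per fragment of `map`.
#' @param map The `FragmentMap` the counts live on.
#' @param sample_id,genotype,construct,replicate Sample metadata. `construct`
#'   is `"dam_fusion"` or `"dam_alone"`; `genotype` one of wt, bam, aly, can,
#'   comr, mip40 or a custom label.
#' @return A `FragmentCounts` object.
#' @export
fragment_counts <- function(counts, map, sample_id = "sample",
                            genotype = "wt",
                            construct = c("dam_fusion", "dam_alone"),
                            replicate = 1L) {
  construct <- match.arg(construct)
  .assert(.is_count(counts), "counts must be non-negative integers")
  .assert(length(counts) == nrow(map),
          "counts length (%d) != number of fragments (%d)",
          length(counts), nrow(map))
  structure(list(sample_id = sample_id, genotype = genotype,
                 construct = construct, replicate = as.integer(replicate),
                 counts = as.numeric(counts), total_reads = sum(counts),
                 n_fragments = nrow(map)),
            class = "FragmentCounts")
}

#' @export
print.FragmentCounts <- function(x, ...) {
  cat(sprintf("FragmentCounts '%s' (%s, %s, rep %d): %d fragments, %g reads\n",
              x$sample_id, x$genotype, x$construct, x$replicate,
              x$n_fragments, x$total_reads))
  invisible(x)
}

#' Write / read per-fragment counts as TSV
#'
#' Two columns, `fragment_id` and `count`, with a header line.
#' @param fc A `FragmentCounts`.
#' @param path Output/input path.
#' @param map `FragmentMap` the file refers to (reader only).
#' @param ... Metadata passed to [fragment_counts()] (reader only).
#' @export
write_fragment_counts <- function(fc, path) {
  .write_tsv(data.frame(fragment_id = seq_len(fc$n_fragments),
                        count = fc$counts), path)
}

#' @rdname write_fragment_counts
#' @export
read_fragment_counts <- function(path, map, ...) {
  df <- .read_tsv(path)
  .assert(all(c("fragment_id", "count") %in% names(df)),
          "counts TSV needs columns fragment_id and count")
  counts <- numeric(nrow(map))
  counts[df$fragment_id] <- df$count
  fragment_counts(counts, map, ...)
}

#' Filter GATC-anchored reads and count them per fragment
#'
#' DamID amplicons start and end at GATC, so a genuine read must begin with
#' the motif; reads that do not are discarded as non-specific. Surviving
#' reads are assigned to the fragment whose boundary matches the read's
#' 5'-most mapped position: plus-strand reads anchor at a fragment's left
#' boundary, minus-strand reads at the last base of the GATC closing a
#' fragment on its right (position `end + 3`). Reads anchored at no
#' boundary, mapped to an unknown chromosome, or multi-mapping (when
#' `multimap = "drop"`) are discarded.
#'
#' @param reads data.frame with columns `chrom`, `pos` (0-based 5'-most
#'   mapped position of the read), `strand` (`"+"`/`"-"`), `seq` (read
#'   sequence as sequenced, 5' to 3'). An optional logical `multi` column
#'   flags multi-mapping reads.
#' @param map A `FragmentMap`.
#' @param multimap `"drop"` (default) discards reads flagged multi-mapping;
#'   `"keep"` retains them.
#' @param ... Metadata passed to [fragment_counts()].
#' @return A `FragmentCounts` whose `stats` attribute tallies kept reads and
#'   each discard reason (kept + discarded = input).
#' @export
filter_and_count_reads <- function(reads, map, multimap = c("drop", "keep"),
                                   ...) {
  multimap <- match.arg(multimap)
  .assert(all(c("chrom", "pos", "strand", "seq") %in% names(reads)),
          "reads need columns chrom, pos, strand, seq")
  n <- nrow(reads)
  starts_gatc <- startsWith(toupper(reads$seq), "GATC")
  multi <- if ("multi" %in% names(reads)) reads$multi else rep(FALSE, n)
  drop_multi <- multimap == "drop" & multi

  # boundary lookup keys: "<chrom>:<pos>"
  plus_key  <- paste0(map$chrom, ":", map$start)
  minus_key <- paste0(map$chrom, ":", map$end + 3L)
  read_key  <- paste0(reads$chrom, ":", reads$pos)
  frag <- ifelse(reads$strand == "+",
                 match(read_key, plus_key),
                 match(read_key, minus_key))
  keep <- starts_gatc & !drop_multi & !is.na(frag)
  counts <- tabulate(frag[keep], nbins = nrow(map))
  stats <- c(input = n,
             kept = sum(keep),
             discarded_no_gatc = sum(!starts_gatc),
             discarded_multimap = sum(starts_gatc & drop_multi),
             discarded_unanchored = sum(starts_gatc & !drop_multi & is.na(frag)))
  fc <- fragment_counts(counts, map, ...)
  attr(fc, "stats") <- stats
  fc
}
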