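# Shared fixtures, all built in code at test time.

# Small random genome and its fragment map.
tiny_genome <- function(len = 20000, seed = 42, name = "chr1") {
  set.seed(seed)
  stats::setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                        collapse = ""), name)
}

tiny_map <- function(len = 20000, seed = 42) {
  build_fragment_map(tiny_genome(len, seed))
}

# Hand-built gene models on one chromosome: plus- and minus-strand
# transcripts with the standard block layout used by the generator.
toy_genes <- function() {
  tx <- data.frame(
    transcript_id = c("txA", "txB", "txC"),
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    strand = c("+", "-", "+"),
    start = c(2000L, 6000L, 10000L),
    end = c(3500L, 7500L, 11500L),
    stringsAsFactors = FALSE)
  blocks <- function(s, e, strand) {
    offs <- rbind(five_prime_UTR = c(0, 150), CDS = c(150, 550),
                  intron = c(550, 850), CDS = c(850, 1250),
                  three_prime_UTR = c(1250, 1500))
    if (strand == "+") b <- s + offs else b <- e - offs[, c(2, 1)]
    data.frame(type = sub("[0-9]*$", "", rownames(offs)),
               start = b[, 1], end = b[, 2])
  }
  feat <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    b <- blocks(tx$start[i], tx$end[i], tx$strand[i])
    data.frame(transcript_id = tx$transcript_id[i], b,
               stringsAsFactors = FALSE)
  }))
  gene_models(tx, feat)
}

# A PeakSet with summits at given positions (width-40 peaks).
toy_peaks <- function(summits, chrom = "chr1", score = 10, ratio = 2) {
  n <- length(summits)
  out <- data.frame(chrom = rep_len(chrom, n), start = summits - 20L,
                    end = summits + 20L,
                    name = sprintf("peak_%d", seq_len(n)),
                    score = rep_len(score, n),
                    log2_ratio = rep_len(ratio, n), summit_start = summits - 20L,
                    summit_end = summits + 20L, summit_mid = as.integer(summits),
                    n_fragments = rep_len(1L, n), stringsAsFactors = FALSE)
  class(out) <- c("PeakSet", "data.frame")
  out
}

# A SignalTrack with prescribed per-fragment values on a given map.
toy_track <- function(map, neglog10_p, sign, log2_ratio,
                      factor = "toy", genotype = "wt") {
  structure(list(factor = factor, genotype = genotype,
                 neglog10_p = neglog10_p, sign = sign,
                 log2_ratio = log2_ratio,
                 counts_x = rep(0, nrow(map)), counts_dam = rep(0, nrow(map)),
                 total_x = 1, total_dam = 1, pseudocount = 0.5, cap = 300,
                 map = map),
            class = "SignalTrack")
}

# Independent two-sided Fisher oracle: hypergeometric pmf from log-binomial
# coefficients, explicit tail accumulation (no dhyper, no findInterval).
oracle_fisher_p <- function(a, m, b, n) {
  k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  supp <- lo:hi
  pmf <- exp(lchoose(m, supp) + lchoose(n, k - supp) - lchoose(m + n, k))
  sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)])
}

# Null simulation used for calibration checks: Poisson counting noise, no
# planted fragments (the exact test's calibration is a multinomial-sampling
# property; the NB default exercises the replicate-FDR machinery instead).
null_experiment <- function(seed, len = 1e6, depth = 2e5) {
  set.seed(seed)
  cfg <- sim_config(seed = seed, chrom_length = len, depth = depth,
                    dispersion = 0)
  genome <- stats::setNames(paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = ""),
                            "chr1")
  map <- build_fragment_map(genome)
  sc <- simulate_counts(cfg, map, integer(0))
  list(cfg = cfg, map = map, counts = sc)
}
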