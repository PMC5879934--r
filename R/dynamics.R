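# Cross-genotype binding dynamics -------------------------------------------
#
# Binding of one factor is profiled in several genotypes spanning germline
# differentiation (spermatogonia arrested in bam mutants, spermatocytes of
# aly and can mutants, wild type). Per transcript, presence = a peak summit
# within +/- 300 bp of the TSS in that genotype; the boolean presence
# pattern over the genotype order (bam, aly, can, wt) is mapped to dynamics
# groups I-VI. Groups I/II/V/VI carry the spermatogonial (bam) bit; groups
# III/IV acquire binding only in spermatocytes (bam bit 0, wt bit 1).

#' Genotype order of the dynamics analysis
#'
#' The developmental series the presence patterns are read over:
#' spermatogonia (bam), spermatocytes without tMAC (aly), spermatocytes
#' without tTAFs (can), wild type.
#' @export
GENOTYPE_ORDER <- c("bam", "aly", "can", "wt")

#' Per-genotype TSS presence matrix
#'
#' @param peaksets Named list of `PeakSet`s, one per genotype; must cover
#'   all of `genotypes`.
#' @param genes A `GeneModels` (shared across genotypes).
#' @param window Half-window around the TSS in bp (default 300, inclusive).
#' @param mode `"summit"` (default): presence requires the summit midpoint
#'   within the window; `"interval"`: any peak overlap with the window.
#' @param genotypes Genotype column order (default bam, aly, can, wt).
#' @return A `PresenceMatrix`: logical matrix transcripts x genotypes, with
#'   rownames = transcript_ids. All transcripts are kept here; grouping
#'   retains only rows with at least one presence.
#' @export
presence_matrix <- function(peaksets, genes, window = 300,
                            mode = c("summit", "interval"),
                            genotypes = GENOTYPE_ORDER) {
  mode <- match.arg(mode)
  missing <- setdiff(genotypes, names(peaksets))
  .assert(length(missing) == 0, "missing genotype peak set(s): %s",
          paste(missing, collapse = ", "))
  tt <- tss_table(genes)
  pm <- vapply(genotypes, function(g) {
    pk <- peaksets[[g]]
    if (mode == "summit") {
      nearest <- .nearest_position(tt$chrom, tt$tss, pk$chrom, pk$summit_mid)
      !is.na(nearest) & abs(tt$tss - nearest) <= window
    } else {
      tss_gr <- GenomicRanges::GRanges(
        tt$chrom,
        IRanges::IRanges(pmax(tt$tss - window, 0) + 1L, tt$tss + window))
      IRanges::overlapsAny(tss_gr, peak_granges(pk))
    }
  }, logical(nrow(tt)))
  pm <- matrix(pm, nrow = nrow(tt), dimnames = list(tt$transcript_id,
                                                    genotypes))
  class(pm) <- c("PresenceMatrix", class(pm))
  pm
}

#' Default presence-pattern to group mapping
#'
#' Patterns over (bam, aly, can, wt). I = bound in all four genotypes and
#' II = bound only in spermatogonia are anchored definitions; III-VI are
#' shipped conventions consistent with the group constraints (III/IV
#' spermatocyte-acquired, V/VI spermatogonial) and fully configurable.
#'
#' @return Logical matrix, rows I-VI, columns bam/aly/can/wt.
#' @export
default_group_patterns <- function() {
  m <- rbind(I   = c(1, 1, 1, 1),
             II  = c(1, 0, 0, 0),
             III = c(0, 0, 0, 1),
             IV  = c(0, 0, 1, 1),
             V   = c(1, 1, 0, 0),
             VI  = c(1, 0, 1, 1)) == 1
  colnames(m) <- GENOTYPE_ORDER
  m
}

#' Assign transcripts to binding-dynamics groups
#'
#' Rows with no presence anywhere are dropped; each remaining pattern is
#' matched against the pattern table. Unmatched patterns become `"minor"`,
#' or, with `merge_minor = TRUE`, are merged to the group with the nearest
#' canonical pattern by Hamming distance (ties stay `"minor"`).
#'
#' @param pm A `PresenceMatrix`.
#' @param patterns Pattern table as from [default_group_patterns()]. Groups
#'   I, II, V, VI must carry the bam bit; III and IV must have bam = 0 and
#'   wt = 1 (the type's invariants; violations are an error).
#' @param merge_minor Hamming-merge unmatched patterns (default `FALSE`).
#' @return A `DynamicsAssignment` data.frame: `transcript_id`, `pattern`
#'   (e.g. `"1011"`), `group`, `bam_bound`.
#' @export
assign_groups <- function(pm, patterns = default_group_patterns(),
                          merge_minor = FALSE) {
  .assert(all(colnames(pm) == colnames(patterns)),
          "presence matrix and pattern table must share genotype order")
  spermatogonial <- intersect(rownames(patterns), c("I", "II", "V", "VI"))
  .assert(all(patterns[spermatogonial, "bam"]),
          "groups I, II, V and VI must have the bam bit set")
  spermatocyte <- intersect(rownames(patterns), c("III", "IV"))
  .assert(all(!patterns[spermatocyte, "bam"] & patterns[spermatocyte, "wt"]),
          "groups III and IV must have bam = 0 and wt = 1")
  keep <- rowSums(pm) > 0
  pm2 <- pm[keep, , drop = FALSE]
  pat_str <- apply(pm2, 1, function(r) paste(as.integer(r), collapse = ""))
  canon <- apply(patterns, 1, function(r) paste(as.integer(r), collapse = ""))
  group <- rownames(patterns)[match(pat_str, canon)]
  minor <- is.na(group)
  if (merge_minor && any(minor)) {
    for (i in which(minor)) {
      d <- colSums(abs(t(patterns) - as.numeric(pm2[i, ])))
      best <- which(d == min(d))
      group[i] <- if (length(best) == 1L) rownames(patterns)[best] else NA
    }
  }
  group[is.na(group)] <- "minor"
  out <- data.frame(transcript_id = rownames(pm2), pattern = pat_str,
                    group = group, bam_bound = pm2[, "bam"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "patterns") <- patterns
  class(out) <- c("DynamicsAssignment", "data.frame")
  out
}

#' Gene-set enrichment per dynamics group
#'
#' For each group, the observed number of member transcripts in the gene
#' set versus the expectation `|group| * |geneset| / |universe|`, with a
#' two-sided chi-square (or Fisher exact for small expected cells) on the
#' 2x2 (in group x in geneset) over the universe.
#'
#' @param assign A `DynamicsAssignment`.
#' @param geneset Transcript ids (must be a subset of `universe`).
#' @param universe Transcript ids (default: all assigned transcripts).
#' @return data.frame per group: `group`, `n_group`, `observed`, `expected`,
#'   `fold`, `p_value` (NA rows for empty groups).
#' @export
group_geneset_enrichment <- function(assign, geneset, universe = NULL) {
  if (is.null(universe)) universe <- assign$transcript_id
  .assert(all(geneset %in% universe), "geneset must be a subset of universe")
  groups <- unique(c(rownames(attr(assign, "patterns")),
                     sort(unique(assign$group))))
  n_u <- length(universe)
  n_set <- sum(universe %in% geneset)
  rows <- lapply(groups, function(g) {
    members <- intersect(assign$transcript_id[assign$group == g], universe)
    n_g <- length(members)
    if (n_g == 0L)
      return(data.frame(group = g, n_group = 0L, observed = NA, expected = NA,
                        fold = NA, p_value = NA))
    obs <- sum(members %in% geneset)
    expd <- n_g * n_set / n_u
    tab <- rbind(c(obs, n_g - obs),
                 c(n_set - obs, n_u - n_g - (n_set - obs)))
    data.frame(group = g, n_group = n_g, observed = obs, expected = expd,
               fold = if (expd > 0) obs / expd else NA,
               p_value = .chisq_or_exact(tab))
  })
  do.call(rbind, rows)
}

#' Repressed-to-activated expression ratio per dynamics group
#'
#' Transcripts changing at least `fold`-fold in the mutant (either
#' direction) are retained. Repressed transcripts are those UP-regulated in
#' the mutant (the factor normally represses them); activated transcripts
#' are DOWN-regulated in the mutant. Per group the ratio of the two counts
#' is compared with the global ratio over all retained transcripts by
#' chi-square on the 2x2 (in group x direction).
#'
#' @param assign A `DynamicsAssignment`.
#' @param expr An `ExpressionTable`.
#' @param mutant Mutant genotype column of `expr`.
#' @param fold Fold-change retention cutoff (default 4).
#' @param pseudocount FPKM pseudocount (default 1).
#' @param require_sig Require the `sig_<mutant>` flag where present.
#' @return data.frame per group: `group`, `n_up`, `n_down`, `ratio`
#'   (up:down), `expected_ratio` (global), `p_value`; NA row when a group
#'   retains no changed transcripts.
#' @export
repression_activation_ratio <- function(assign, expr, mutant, fold = 4,
                                        pseudocount = 1, require_sig = TRUE) {
  fold_down <- .fold_down(expr, mutant, pseudocount)
  sig <- .sig_flag(expr, mutant, require_sig)
  up_ids <- expr$transcript_id[sig & 1 / fold_down >= fold]
  down_ids <- expr$transcript_id[sig & fold_down >= fold]
  tot_up <- length(up_ids); tot_down <- length(down_ids)
  expected_ratio <- if (tot_down > 0) tot_up / tot_down else NA_real_
  groups <- unique(c(rownames(attr(assign, "patterns")),
                     sort(unique(assign$group))))
  rows <- lapply(groups, function(g) {
    members <- assign$transcript_id[assign$group == g]
    n_up <- sum(members %in% up_ids)
    n_down <- sum(members %in% down_ids)
    if (n_up + n_down == 0L)
      return(data.frame(group = g, n_up = 0L, n_down = 0L, ratio = NA,
                        expected_ratio = expected_ratio, p_value = NA))
    tab <- rbind(c(n_up, n_down),
                 c(tot_up - n_up, tot_down - n_down))
    data.frame(group = g, n_up = n_up, n_down = n_down,
               ratio = if (n_down > 0) n_up / n_down else Inf,
               expected_ratio = expected_ratio,
               p_value = .chisq_or_exact(tab))
  })
  do.call(rbind, rows)
}

#' Tissue-specific transcripts from a tissue ratio matrix
#'
#' A transcript is specific to the target tissue when its
#' log2(tissue/whole-fly mean) ratio is positive there AND every other
#' tissue is negative or has null (missing, `NA`) expression.
#'
#' @param mat Numeric matrix, transcripts x tissues (rownames =
#'   transcript_ids, colnames = tissue names), log2 ratios with `NA` for
#'   null expression.
#' @param target_tissue Column name of the target tissue.
#' @return Character vector of qualifying transcript ids.
#' @export
tissue_specific_transcripts <- function(mat, target_tissue) {
  .assert(target_tissue %in% colnames(mat),
          "tissue '%s' absent from the matrix", target_tissue)
  .assert(ncol(mat) >= 2, "matrix needs at least one non-target tissue")
  target <- mat[, target_tissue]
  others <- mat[, setdiff(colnames(mat), target_tissue), drop = FALSE]
  ok <- !is.na(target) & target > 0 &
    apply(others, 1, function(r) all(is.na(r) | r < 0))
  rownames(mat)[ok]
}

#' Write / read a tissue ratio matrix as TSV (`NA` for null expression)
#'
#' @param mat Matrix as in [tissue_specific_transcripts()].
#' @param path Output/input path.
#' @export
write_tissue_matrix <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat), mat, check.names = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_tissue_matrix
#' @export
read_tissue_matrix <- function(path) {
  df <- .read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$transcript_id
  m
}
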