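# Direct / indirect target classification ----------------------------------
#
# A transcript is a DIRECT target of a factor when it is at least
# `fold_cutoff`-fold down-regulated in that factor's mutant AND has an
# enrichment peak of the factor within `dist_cutoff` of a TSS (defaults 8x
# and 1 kb). Down-regulated transcripts without a nearby peak are INDIRECT;
# everything else is unaffected. Expression arrives as an FPKM table
# (differential expression is consumed, never computed here).

#' Build an expression table
#'
#' @param df data.frame with `transcript_id`, one `fpkm_<genotype>` column
#'   per genotype (wt plus mutants), and optionally one logical
#'   `sig_<mutant>` column per mutant (multiple-testing-passed flag from the
#'   upstream differential-expression tool).
#' @return An `ExpressionTable` (validated data.frame).
#' @export
expression_table <- function(df) {
  .assert("transcript_id" %in% names(df), "needs a transcript_id column")
  fpkm_cols <- grep("^fpkm_", names(df), value = TRUE)
  .assert("fpkm_wt" %in% fpkm_cols, "needs an fpkm_wt column")
  .assert(length(fpkm_cols) >= 2, "needs at least one mutant fpkm column")
  for (cc in fpkm_cols)
    .assert(all(df[[cc]] >= 0, na.rm = TRUE), "FPKM must be non-negative (%s)", cc)
  class(df) <- c("ExpressionTable", "data.frame")
  df
}

#' @rdname expression_table
#' @param path TSV path.
#' @export
read_expression_table <- function(path) expression_table(.read_tsv(path))

#' @rdname expression_table
#' @param expr An `ExpressionTable`.
#' @export
write_expression_table <- function(expr, path) .write_tsv(expr, path)

# wt-over-mutant fold (>= 1 means down in the mutant), FPKM + pseudocount.
.fold_down <- function(expr, mutant, pseudocount = 1) {
  col <- paste0("fpkm_", mutant)
  .assert(col %in% names(expr), "expression table lacks genotype '%s'", mutant)
  (expr$fpkm_wt + pseudocount) / (expr[[col]] + pseudocount)
}

.sig_flag <- function(expr, mutant, require_sig) {
  col <- paste0("sig_", mutant)
  if (!require_sig || !(col %in% names(expr))) return(rep(TRUE, nrow(expr)))
  expr[[col]]
}

# Is any TSS of each transcript within `dist` of a peak summit?
.peak_within <- function(genes, peaks, dist) {
  tt <- tss_table(genes)
  nearest <- .nearest_position(tt$chrom, tt$tss, peaks$chrom, peaks$summit_mid)
  d <- abs(tt$tss - nearest)
  within <- !is.na(d) & d <= dist
  list(tss = tt, distance = d, within = within)
}

#' Classify direct, indirect and unaffected targets
#'
#' @param expr An `ExpressionTable`.
#' @param peaks The factor's `PeakSet` (called in the relevant genotype).
#' @param genes A `GeneModels`; a transcript is peak-proximal if any of its
#'   annotated TSSs (alternative TSSs are separate transcript rows of the
#'   same gene) is within `dist_cutoff` of a summit.
#' @param mutant Genotype column of `expr` carrying the factor's mutant.
#' @param fold_cutoff Minimum wt/mutant down-regulation (default 8).
#' @param dist_cutoff Maximum summit-to-TSS distance in bp (default 1000,
#'   inclusive).
#' @param pseudocount Added to FPKM on both sides of the fold (default 1).
#' @param require_sig Require the `sig_<mutant>` flag where present
#'   (default `TRUE`).
#' @return A `TargetTable` data.frame: `transcript_id`, `gene_id`,
#'   `distance` (NA when no peak on the chromosome), `fold_down`,
#'   `fc_class` (`up4`, `down4`, `down8`, `none`), `label`
#'   (`direct`/`indirect`/`unaffected`). Transcripts of `expr` missing from
#'   the annotation are skipped with a warning (count in
#'   `attr(, "n_unmatched")`).
#' @export
classify_targets <- function(expr, peaks, genes, mutant, fold_cutoff = 8,
                             dist_cutoff = 1000, pseudocount = 1,
                             require_sig = TRUE) {
  pw <- .peak_within(genes, peaks, dist_cutoff)
  matched <- expr$transcript_id %in% pw$tss$transcript_id
  n_unmatched <- sum(!matched)
  if (n_unmatched > 0)
    warning(sprintf("%d expression rows have no annotated transcript; skipped",
                    n_unmatched))
  expr <- expr[matched, , drop = FALSE]
  i <- match(expr$transcript_id, pw$tss$transcript_id)
  # gene-level "any TSS within": aggregate over transcripts of the same gene
  gene_of <- pw$tss$gene_id
  within_gene <- tapply(pw$within, gene_of, any)
  within <- as.logical(within_gene[gene_of[i]])
  fold_down <- .fold_down(expr, mutant, pseudocount)
  sig <- .sig_flag(expr, mutant, require_sig)
  fold_up <- 1 / fold_down
  fc_class <- rep("none", nrow(expr))
  fc_class[sig & fold_up >= 4] <- "up4"
  fc_class[sig & fold_down >= 4] <- "down4"
  fc_class[sig & fold_down >= 8] <- "down8"
  down <- sig & fold_down >= fold_cutoff
  label <- ifelse(down & within, "direct",
                  ifelse(down, "indirect", "unaffected"))
  out <- data.frame(transcript_id = expr$transcript_id,
                    gene_id = gene_of[i],
                    distance = pw$distance[i],
                    fold_down = fold_down,
                    fc_class = fc_class,
                    label = label,
                    stringsAsFactors = FALSE)
  attr(out, "n_unmatched") <- n_unmatched
  attr(out, "params") <- list(mutant = mutant, fold_cutoff = fold_cutoff,
                              dist_cutoff = dist_cutoff,
                              pseudocount = pseudocount,
                              require_sig = require_sig)
  class(out) <- c("TargetTable", "data.frame")
  out
}

#' Write a target table as TSV
#' @param targets A `TargetTable`.
#' @param path Output path.
#' @export
write_target_table <- function(targets, path) .write_tsv(targets, path)

#' TSS-distance histograms for up- vs down-regulated transcripts
#'
#' Transcripts changing at least `fold`-fold in the mutant are split by
#' direction; each set gets a nearest-peak distance histogram (as in
#' [tss_distance_bins()]) and the within-`bin` proportions of the two
#' directions are compared with a chi-square test on the 2x2 table
#' (direction x peak-within-first-bin). With one direction empty, the
#' histogram of the populated side is returned without a test.
#'
#' @inheritParams classify_targets
#' @param fold Fold-change cutoff defining the sets (default 4).
#' @param window,bin Histogram extent and width (defaults 10000, 1000).
#' @return list with `hist_down`, `hist_up`, `n_down`, `n_up`,
#'   `prop_within` (named proportions within the first bin), `chisq_p`.
#' @export
fold_change_distance_analysis <- function(expr, peaks, genes, mutant,
                                          fold = 4, window = 10000,
                                          bin = 1000, pseudocount = 1,
                                          require_sig = TRUE) {
  fold_down <- .fold_down(expr, mutant, pseudocount)
  sig <- .sig_flag(expr, mutant, require_sig)
  down_ids <- expr$transcript_id[sig & fold_down >= fold]
  up_ids <- expr$transcript_id[sig & 1 / fold_down >= fold]
  one <- function(ids) {
    g <- .subset_genes(genes, ids)
    if (nrow(g$transcripts) == 0L) return(NULL)
    tss_distance_bins(g, peaks, window = window, bin = bin)
  }
  res_down <- one(down_ids)
  res_up <- one(up_ids)
  within <- function(res) {
    if (is.null(res)) return(c(n = 0, k = 0))
    d <- res$distances$distance
    c(n = sum(!is.na(d)), k = sum(!is.na(d) & d <= bin))
  }
  wd <- within(res_down); wu <- within(res_up)
  chisq_p <- NA_real_
  if (wd["n"] > 0 && wu["n"] > 0) {
    tab <- rbind(c(wd["k"], wd["n"] - wd["k"]),
                 c(wu["k"], wu["n"] - wu["k"]))
    chisq_p <- .chisq_or_exact(tab)
  }
  list(hist_down = if (is.null(res_down)) NULL else res_down$histogram,
       hist_up = if (is.null(res_up)) NULL else res_up$histogram,
       n_down = unname(wd["n"]), n_up = unname(wu["n"]),
       prop_within = c(down = unname(ifelse(wd["n"] > 0, wd["k"] / wd["n"], NA)),
                       up = unname(ifelse(wu["n"] > 0, wu["k"] / wu["n"], NA))),
       chisq_p = chisq_p)
}

# Chi-square without Yates correction; Fisher exact when any expected
# cell < 5 (small-count guard).
.chisq_or_exact <- function(tab) {
  exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp_cells < 5)) {
    stats::fisher.test(tab)$p.value
  } else {
    stats::chisq.test(tab, correct = FALSE)$p.value
  }
}

#' Co-binding enrichment of factor B at factor A's targets
#'
#' Observed: the fraction of A-target transcripts carrying a B peak within
#' `dist_cutoff` of a TSS. Expected: the same fraction over the transcript
#' universe. Significance: chi-square on the 2x2 (in target set x B-bound),
#' Fisher exact when any expected cell is below 5; a Benjamini-Hochberg
#' q-value can be added across factor pairs by the caller via
#' [stats::p.adjust()].
#'
#' @param target_ids Transcript ids of factor A's target set (e.g. direct
#'   targets from [classify_targets()]).
#' @param peaks_b `PeakSet` of factor B.
#' @param genes A `GeneModels`.
#' @param universe Transcript ids forming the universe (default: all
#'   annotated transcripts). Must contain the target set.
#' @param dist_cutoff Summit-to-TSS distance defining "bound" (default 1000).
#' @return list: `observed_pct`, `expected_pct`, `fold`, `p_value`,
#'   `n_targets`, `n_universe`. An empty target set gives NA fold.
#' @export
cobinding_enrichment <- function(target_ids, peaks_b, genes, universe = NULL,
                                 dist_cutoff = 1000) {
  if (is.null(universe)) universe <- genes$transcripts$transcript_id
  .assert(all(target_ids %in% universe),
          "universe must contain the target set")
  pw <- .peak_within(genes, peaks_b, dist_cutoff)
  bound <- pw$tss$transcript_id[pw$within]
  n_t <- length(target_ids)
  n_u <- length(universe)
  obs_k <- sum(target_ids %in% bound)
  exp_k <- sum(universe %in% bound)
  observed_pct <- if (n_t > 0) 100 * obs_k / n_t else NA_real_
  expected_pct <- 100 * exp_k / n_u
  fold <- if (n_t > 0 && expected_pct > 0) observed_pct / expected_pct
          else NA_real_
  p <- NA_real_
  if (n_t > 0) {
    rest <- setdiff(universe, target_ids)
    tab <- rbind(c(obs_k, n_t - obs_k),
                 c(sum(rest %in% bound), length(rest) - sum(rest %in% bound)))
    p <- .chisq_or_exact(tab)
  }
  list(observed_pct = observed_pct, expected_pct = expected_pct, fold = fold,
       p_value = p, n_targets = n_t, n_universe = n_u)
}

#' Categorize DamID signal around each TSS
#'
#' The maximum signed -log10(P) over fragments overlapping the window
#' around any TSS of the transcript is mapped to a category:
#' `no_binding` when the factor is not enriched over the Dam control
#' (max signed value <= 0), `nonsignificant` in (0, lower],
#' `medium` in (lower, upper], `high` above upper. The default upper
#' boundary 3 mirrors an FDR-0.05-style threshold; pass
#' `-log10(t_star)` to use the calibrated one.
#'
#' @param track A `SignalTrack` (carries its `FragmentMap`).
#' @param genes A `GeneModels`.
#' @param window Half-window around the TSS in bp (default 1000).
#' @param boundaries Strictly increasing numeric pair
#'   (lower, upper) in -log10 P units; default `c(1, 3)`.
#' @return data.frame `transcript_id`, `max_signed`, `category`.
#' @export
signal_category_at_tss <- function(track, genes, window = 1000,
                                   boundaries = c(1, 3)) {
  .assert(length(boundaries) == 2 && diff(boundaries) > 0,
          "boundaries must be strictly increasing (lower, upper)")
  m <- track$map
  tt <- tss_table(genes)
  sv <- signal_signed(track)
  frag_gr <- fragment_granges(m)
  tss_gr <- GenomicRanges::GRanges(
    tt$chrom, IRanges::IRanges(pmax(tt$tss - window, 0) + 1L, tt$tss + window))
  hits <- GenomicRanges::findOverlaps(tss_gr, frag_gr)
  max_signed <- rep(-Inf, nrow(tt))
  agg <- tapply(sv[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), max)
  max_signed[as.integer(names(agg))] <- agg
  category <- ifelse(max_signed <= 0, "no_binding",
              ifelse(max_signed <= boundaries[1], "nonsignificant",
              ifelse(max_signed <= boundaries[2], "medium", "high")))
  data.frame(transcript_id = tt$transcript_id, max_signed = max_signed,
             category = category, stringsAsFactors = FALSE)
}
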