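# Expression fixture on toy_genes(): txA TSS 2000, txB TSS 7499, txC TSS 10000.
toy_expr <- function(fpkm_wt = c(100, 100, 100), fpkm_can = c(10, 10, 100),
                     sig = TRUE) {
  expression_table(data.frame(
    transcript_id = c("txA", "txB", "txC"),
    fpkm_wt = fpkm_wt, fpkm_can = fpkm_can,
    sig_can = rep_len(sig, 3), stringsAsFactors = FALSE))
}

test_that("direct targets need >=8-fold down AND a peak within 1 kb", {
  genes <- toy_genes()
  # txA: 10-fold down, summit 900 bp away -> direct
  # txB: 10-fold down, summit 1100 bp away -> indirect
  # txC: unchanged, peak adjacent -> unaffected
  pk <- toy_peaks(c(2900, 8599, 10100))
  tg <- classify_targets(toy_expr(), pk, genes, mutant = "can")
  expect_equal(tg$label[match(c("txA", "txB", "txC"), tg$transcript_id)],
               c("direct", "indirect", "unaffected"))
})

test_that("up-regulated transcripts are never direct targets", {
  genes <- toy_genes()
  pk <- toy_peaks(c(2000, 7499, 10000))  # peaks at every TSS
  expr <- toy_expr(fpkm_wt = c(10, 10, 10), fpkm_can = c(100, 100, 100))
  tg <- classify_targets(expr, pk, genes, mutant = "can")
  expect_true(all(tg$label == "unaffected"))
  expect_equal(tg$fc_class, rep("up4", 3))
})

test_that("distance and fold boundaries are exact", {
  genes <- toy_genes()
  expr <- toy_expr(fpkm_wt = c(799, 800, 100), fpkm_can = c(99, 99, 0.001))
  # fold_down with pseudocount 1: txA (800/100)=8 exactly, txB 801/100 > 8
  pk <- toy_peaks(c(3000, 8499, 11000))  # distances 1000, 1000, 1000
  tg <- classify_targets(expr, pk, genes, mutant = "can")
  expect_equal(tg$label[tg$transcript_id == "txA"], "direct")   # fold == 8
  expect_equal(tg$label[tg$transcript_id == "txB"], "direct")   # dist == 1000
  pk2 <- toy_peaks(c(3001, 8499, 11000))                        # dist 1001
  tg2 <- classify_targets(expr, pk2, genes, mutant = "can")
  expect_equal(tg2$label[tg2$transcript_id == "txA"], "indirect")
  expr3 <- toy_expr(fpkm_wt = c(798.9, 100, 100), fpkm_can = c(99, 100, 100))
  tg3 <- classify_targets(expr3, pk, genes, mutant = "can")
  expect_equal(tg3$label[tg3$transcript_id == "txA"], "unaffected")  # < 8
})

test_that("labels partition all matched transcripts", {
  genes <- toy_genes()
  pk <- toy_peaks(c(2900, 8599))
  tg <- classify_targets(toy_expr(), pk, genes, mutant = "can")
  expect_setequal(tg$transcript_id, c("txA", "txB", "txC"))
  expect_true(all(tg$label %in% c("direct", "indirect", "unaffected")))
})

test_that("raising cutoffs moves labels monotonically", {
  set.seed(41)
  cfg <- sim_config(seed = 41, chrom_length = 3e5, n_genes = 80, depth = 5e4)
  sim <- simulate_damid_experiment(cfg)
  bf <- sim$truth$bound_fragments
  frag <- bf$fragment_id[bf$factor == "can"]
  pk <- toy_peaks((sim$map$start[frag] + sim$map$end[frag]) %/% 2)
  n_changed <- function(fold, dist) {
    tg <- classify_targets(sim$expr, pk, sim$genes, mutant = "can",
                           fold_cutoff = fold, dist_cutoff = dist)
    c(changed = sum(tg$label != "unaffected"), direct = sum(tg$label == "direct"))
  }
  a <- n_changed(8, 1000); b <- n_changed(16, 1000); c <- n_changed(8, 5000)
  expect_lte(b["changed"], a["changed"])
  expect_gte(c["direct"], a["direct"])
})

test_that("unmatched transcript ids are skipped with a warning", {
  genes <- toy_genes()
  expr <- expression_table(data.frame(
    transcript_id = c("txA", "ghost"), fpkm_wt = c(100, 100),
    fpkm_can = c(10, 10), stringsAsFactors = FALSE))
  expect_warning(tg <- classify_targets(expr, toy_peaks(2900), genes, "can"),
                 "no annotated transcript")
  expect_equal(attr(tg, "n_unmatched"), 1L)
  expect_equal(nrow(tg), 1L)
})

test_that("down-regulated genes with planted promoter peaks separate from up", {
  # 200 down-regulated genes, half with promoter peaks; 200 up, none
  set.seed(42)
  n <- 400
  tx <- data.frame(transcript_id = sprintf("t%03d", 1:n),
                   gene_id = sprintf("g%03d", 1:n), chrom = "chr1",
                   strand = "+", start = (1:n) * 5000L,
                   end = (1:n) * 5000L + 1500L, stringsAsFactors = FALSE)
  genes <- gene_models(tx, data.frame(transcript_id = character(),
                                      type = character(), start = integer(),
                                      end = integer()))
  down <- 1:200; up <- 201:400
  expr <- expression_table(data.frame(
    transcript_id = tx$transcript_id,
    fpkm_wt = c(rep(100, 200), rep(10, 200)),
    fpkm_can = c(rep(10, 200), rep(100, 200)), stringsAsFactors = FALSE))
  with_peak <- sample(down, 100)
  pk <- toy_peaks(tx$start[with_peak] + 200L)
  res <- fold_change_distance_analysis(expr, pk, genes, mutant = "can")
  expect_lt(res$chisq_p, 1e-3)
  expect_gt(res$prop_within["down"], 0.4)
  # exact oracle for the 2x2
  tab <- rbind(c(100, res$n_down - 100), c(0, res$n_up))
  expect_equal(res$chisq_p, chisq.test(tab, correct = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("one-sided analyses skip the test when a direction is empty", {
  genes <- toy_genes()
  expr <- toy_expr(fpkm_wt = c(100, 100, 100), fpkm_can = c(10, 10, 10))
  res <- fold_change_distance_analysis(expr, toy_peaks(2900), genes, "can")
  expect_null(res$hist_up)
  expect_true(is.na(res$chisq_p))
})

test_that("cobinding enrichment recovers planted overlap and nulls", {
  set.seed(43)
  n <- 1000
  tx <- data.frame(transcript_id = sprintf("t%04d", 1:n),
                   gene_id = sprintf("g%04d", 1:n), chrom = "chr1",
                   strand = "+", start = (1:n) * 4000L,
                   end = (1:n) * 4000L + 1500L, stringsAsFactors = FALSE)
  genes <- gene_models(tx, data.frame(transcript_id = character(),
                                      type = character(), start = integer(),
                                      end = integer()))
  targets <- tx$transcript_id[1:100]
  # planted: B peaks at 50% of targets plus 5% background elsewhere
  b_at <- c(sample(1:100, 50), sample(101:n, round(0.05 * (n - 100))))
  pk <- toy_peaks(tx$start[b_at] + 100L)
  res <- cobinding_enrichment(targets, pk, genes)
  expect_gt(res$fold, 4)
  expect_lt(res$p_value, 1e-6)
  # null: B peaks independent of the target set
  b_null <- sample(1:n, 100)
  res0 <- cobinding_enrichment(targets, toy_peaks(tx$start[b_null] + 100L),
                               genes)
  expect_lt(abs(res0$fold - 1), 1.2)
  expect_true(is.na(cobinding_enrichment(character(), pk, genes)$fold))
  expect_error(cobinding_enrichment(c("nope"), pk, genes), "universe")
})

test_that("signal categories at the TSS follow the boundaries", {
  map <- tiny_map(20000)
  genes <- toy_genes()
  sv <- rep(0, nrow(map)); sg <- rep(0L, nrow(map))
  fA <- max(which(map$start <= 2000))
  fB <- max(which(map$start <= 7499))
  fC <- max(which(map$start <= 10000))
  nl <- rep(0, nrow(map))
  nl[fA] <- 0.5; sg[fA] <- 1L    # weak positive -> nonsignificant
  nl[fB] <- 5;   sg[fB] <- -1L   # depleted -> no_binding
  nl[fC] <- 4;   sg[fC] <- 1L    # strong -> high
  tr <- toy_track(map, nl, sg, rep(0, nrow(map)))
  res <- signal_category_at_tss(tr, genes)
  got <- res$category[match(c("txA", "txB", "txC"), res$transcript_id)]
  expect_equal(got, c("nonsignificant", "no_binding", "high"))
  # medium band boundary: (1, 3]
  nl[fC] <- 3
  res2 <- signal_category_at_tss(toy_track(map, nl, sg, rep(0, nrow(map))),
                                 genes)
  expect_equal(res2$category[res2$transcript_id == "txC"], "medium")
  expect_error(signal_category_at_tss(tr, genes, boundaries = c(3, 1)),
               "increasing")
})
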