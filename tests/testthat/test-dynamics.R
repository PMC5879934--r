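toy_peaksets <- function(genes, bound) {
  # bound: named list genotype -> transcript ids with a summit at the TSS
  tt <- tss_table(genes)
  lapply(bound, function(ids) {
    toy_peaks(tt$tss[match(ids, tt$transcript_id)])
  })
}

test_that("presence window is exact at +/-300 bp around the TSS", {
  genes <- toy_genes()
  tt <- tss_table(genes)
  mk <- function(offset) {
    pos <- tt$tss[tt$transcript_id == "txA"] + offset
    list(bam = toy_peaks(pos), aly = toy_peaks(integer()),
         can = toy_peaks(integer()), wt = toy_peaks(integer()))
  }
  pm299 <- presence_matrix(mk(299L), genes)
  pm300 <- presence_matrix(mk(300L), genes)
  pm301 <- presence_matrix(mk(301L), genes)
  expect_true(pm299["txA", "bam"])
  expect_true(pm300["txA", "bam"])
  expect_false(pm301["txA", "bam"])
  expect_error(presence_matrix(mk(0)[1:3], genes), "missing genotype")
})

test_that("a peak spanning the TSS with a distant summit is absent in summit mode", {
  genes <- toy_genes()
  tt <- tss_table(genes)
  tssA <- tt$tss[tt$transcript_id == "txA"]
  wide <- toy_peaks(tssA + 500L)
  wide$start <- tssA - 50L  # interval covers the TSS, summit at +500
  sets <- list(bam = wide, aly = toy_peaks(integer()),
               can = toy_peaks(integer()), wt = toy_peaks(integer()))
  expect_false(presence_matrix(sets, genes)["txA", "bam"])
  expect_true(presence_matrix(sets, genes, mode = "interval")["txA", "bam"])
})

test_that("anchored patterns map to groups I and II; others as configured", {
  genes <- toy_genes()
  sets <- toy_peaksets(genes, list(
    bam = c("txA", "txB"), aly = "txA", can = "txA", wt = c("txA", "txC")))
  pm <- presence_matrix(sets, genes)
  asg <- assign_groups(pm)
  expect_equal(asg$group[asg$transcript_id == "txA"], "I")    # 1111
  expect_equal(asg$group[asg$transcript_id == "txB"], "II")   # 1000
  expect_equal(asg$group[asg$transcript_id == "txC"], "III")  # 0001
  expect_equal(nrow(asg), 3L)  # all-zero rows never appear
})

test_that("group assignment is a pure function of the pattern", {
  pm <- matrix(c(TRUE, TRUE, FALSE, FALSE,
                 TRUE, TRUE, FALSE, FALSE), nrow = 2, byrow = TRUE,
               dimnames = list(c("t1", "t2"), GENOTYPE_ORDER))
  class(pm) <- c("PresenceMatrix", class(pm))
  asg <- assign_groups(pm)
  expect_equal(asg$group, c("V", "V"))
})

test_that("unmapped patterns go to minor, or Hamming-merge when asked", {
  pm <- matrix(c(TRUE, TRUE, TRUE, FALSE,   # 1110: distance 1 from I and V
                 FALSE, TRUE, FALSE, FALSE), nrow = 2, byrow = TRUE,
               dimnames = list(c("t1", "t2"), GENOTYPE_ORDER))
  class(pm) <- c("PresenceMatrix", class(pm))
  expect_equal(assign_groups(pm)$group, c("minor", "minor"))
  merged <- assign_groups(pm, merge_minor = TRUE)
  expect_equal(merged$group[1], "minor")  # tie between I and V stays minor
  # 0100 is distance 1 from V (1100) only -> merged there
  expect_equal(merged$group[2], "V")
})

test_that("pattern tables violating the group invariants are rejected", {
  bad <- default_group_patterns()
  bad["III", "bam"] <- TRUE
  pm <- presence_matrix(toy_peaksets(toy_genes(), list(
    bam = "txA", aly = "txA", can = "txA", wt = "txA")), toy_genes())
  expect_error(assign_groups(pm, patterns = bad), "bam = 0")
})

test_that("group sizes plus minor equal the retained rows", {
  set.seed(51)
  n <- 200
  pm <- matrix(runif(n * 4) < 0.4, nrow = n,
               dimnames = list(sprintf("t%03d", 1:n), GENOTYPE_ORDER))
  class(pm) <- c("PresenceMatrix", class(pm))
  asg <- assign_groups(pm)
  expect_equal(nrow(asg), sum(rowSums(pm) > 0))
  expect_equal(sum(table(asg$group)), nrow(asg))
})

test_that("geneset enrichment is exact for trivial and planted sets", {
  set.seed(52)
  n <- 600
  pm <- matrix(FALSE, nrow = n, ncol = 4,
               dimnames = list(sprintf("t%03d", 1:n), GENOTYPE_ORDER))
  pats <- default_group_patterns()
  grp <- sample(rownames(pats), n, replace = TRUE)
  for (i in 1:n) pm[i, ] <- pats[grp[i], ]
  class(pm) <- c("PresenceMatrix", class(pm))
  asg <- assign_groups(pm)
  expect_equal(asg$group, grp)
  # geneset = universe -> fold exactly 1
  res <- group_geneset_enrichment(asg, asg$transcript_id)
  expect_true(all(res$fold[res$n_group > 0] == 1))
  # planted: geneset 5x denser in group III
  g3 <- asg$transcript_id[asg$group == "III"]
  rest <- setdiff(asg$transcript_id, g3)
  geneset <- c(sample(g3, round(0.5 * length(g3))),
               sample(rest, round(0.1 * length(rest))))
  res2 <- group_geneset_enrichment(asg, geneset)
  fold3 <- res2$fold[res2$group == "III"]
  expect_gt(fold3, 2)
  expect_lt(res2$p_value[res2$group == "III"], 1e-3)
})

test_that("repression/activation ratios flag planted repressed groups", {
  set.seed(53)
  n <- 300
  ids <- sprintf("t%03d", 1:n)
  pats <- default_group_patterns()
  grp <- sample(rownames(pats), n, replace = TRUE)
  pm <- matrix(FALSE, nrow = n, ncol = 4, dimnames = list(ids, GENOTYPE_ORDER))
  for (i in 1:n) pm[i, ] <- pats[grp[i], ]
  class(pm) <- c("PresenceMatrix", class(pm))
  asg <- assign_groups(pm)
  # group II genes up in the mutant (repressed), group III genes down
  up <- grp == "II"; down <- grp == "III"
  expr <- expression_table(data.frame(
    transcript_id = ids,
    fpkm_wt = rep(100, n),
    fpkm_mip40 = ifelse(up, 1000, ifelse(down, 10, 100)),
    stringsAsFactors = FALSE))
  res <- repression_activation_ratio(asg, expr, "mip40")
  r2 <- res[res$group == "II", ]
  r3 <- res[res$group == "III", ]
  expect_gt(r2$ratio, r2$expected_ratio)
  expect_lt(r3$ratio, r3$expected_ratio)
  expect_lt(r2$p_value, 1e-6)
  # a group with no changed transcripts reports NA
  expr0 <- expr; expr0$fpkm_mip40[grp == "I"] <- 100
  res0 <- repression_activation_ratio(asg, expr0, "mip40")
  expect_true(is.na(res0$ratio[res0$group == "I"]))
})

test_that("tissue-specific rule matches its definition and brute force", {
  m <- rbind(t1 = c(testis = 2, ovary = -0.5, gut = -0.5),
             t2 = c(testis = 2, ovary = 0.1, gut = -0.5),
             t3 = c(testis = 2, ovary = NA, gut = -1),
             t4 = c(testis = -0.1, ovary = -1, gut = -1))
  expect_equal(tissue_specific_transcripts(m, "testis"), c("t1", "t3"))
  expect_error(tissue_specific_transcripts(m, "brain"), "absent")
  set.seed(54)
  big <- matrix(rnorm(1000 * 10), nrow = 1000,
                dimnames = list(sprintf("tx%04d", 1:1000),
                                c("testis", "ovary", sprintf("tis%d", 1:8))))
  big[sample.int(length(big), 800)] <- NA
  got <- tissue_specific_transcripts(big, "testis")
  brute <- character()
  for (i in 1:1000) {
    r <- big[i, ]
    if (!is.na(r["testis"]) && r["testis"] > 0) {
      rest <- r[setdiff(colnames(big), "testis")]
      if (all(is.na(rest) | rest < 0))
        brute <- c(brute, rownames(big)[i])
    }
  }
  expect_identical(got, brute)
})

test_that("dynamics groups are stable across peak-calling stringencies", {
  cfg <- sim_config(seed = 55, factors = "mip40")
  sim <- simulate_damid_experiment(cfg)
  call_at <- function(p_cutoff) {
    sets <- lapply(stats::setNames(GENOTYPE_ORDER, GENOTYPE_ORDER),
                   function(gt) {
      cc <- sim$counts$mip40[[gt]]
      tr <- build_signal_track(cc$fusion, cc$dam, sim$map,
                               factor = "mip40", genotype = gt)
      nz <- noise_track(cc$fusion[[1]], cc$fusion[[2]], sim$map)
      curve <- suppressWarnings(calibrate_fdr(tr, nz))
      call_peaks(tr, attr(curve, "t_star"), p_cutoff = p_cutoff)
    })
    assign_groups(presence_matrix(sets, sim$genes))
  }
  loose <- call_at(1e-3)
  tight <- call_at(1e-6)
  common <- intersect(loose$transcript_id, tight$transcript_id)
  agree <- mean(loose$group[match(common, loose$transcript_id)] ==
                  tight$group[match(common, tight$transcript_id)])
  expect_gte(agree, 0.8)
})
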