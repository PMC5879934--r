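# toy_genes(): txA + strand TSS 2000, txB - strand TSS 7499, txC + TSS 10000.

test_that("summit classification honors the 400 bp promoter and precedence", {
  genes <- toy_genes()
  pk <- toy_peaks(c(1800,   # 200 bp upstream of txA TSS -> promoter
                    1599,   # 401 bp upstream -> not promoter
                    2050,   # inside txA 5'UTR
                    2300,   # inside txA CDS
                    2700,   # inside txA intron
                    3300,   # inside txA 3'UTR
                    7600,   # 101 bp upstream of minus-strand txB -> promoter
                    5000))  # intergenic
  got <- classify_peak_feature(pk, genes)
  expect_equal(got, c("promoter", "other", "five_prime_UTR", "CDS", "intron",
                      "three_prime_UTR", "promoter", "other"))
  merged <- classify_peak_feature(pk, genes, merge_exon = TRUE)
  expect_equal(merged[3:6], c("exon", "exon", "intron", "exon"))
})

test_that("promoter boundary is exact at 400 bp", {
  genes <- toy_genes()
  expect_equal(classify_peak_feature(toy_peaks(1600), genes), "promoter")
  expect_equal(classify_peak_feature(toy_peaks(1599), genes), "other")
  # minus strand: promoter covers (tss, tss + 400]
  expect_equal(classify_peak_feature(toy_peaks(7899), genes), "promoter")
  expect_equal(classify_peak_feature(toy_peaks(7900), genes), "other")
})

test_that("random summits match genomic category coverage", {
  genes <- toy_genes()
  genome_size <- 20000
  set.seed(31)
  pk <- toy_peaks(sample.int(genome_size - 100, 400))
  fd <- feature_enrichment(pk, genes, genome_size)
  expect_equal(sum(fd$observed), nrow(pk))
  expect_lte(sum(fd$expected_prob), 1 + 1e-12)
  # uniform summits: no category should be extremely enriched
  expect_true(all(fd$p_value > 1e-6))
  # chi-square goodness of fit of observed vs coverage-expected counts
  keep <- fd$expected_count > 0
  chi <- sum((fd$observed[keep] - fd$expected_count[keep])^2 /
               fd$expected_count[keep])
  expect_lt(chi, qchisq(0.999, sum(keep) - 1))
})

test_that("promoter-planted peaks are detected by the binomial test", {
  genes <- toy_genes()
  set.seed(32)
  pk <- toy_peaks(rep(c(1800, 7600, 9800), length.out = 100))
  fd <- feature_enrichment(pk, genes, 20000)
  prow <- fd[fd$category == "promoter", ]
  expect_equal(prow$observed, 100)
  expect_lt(prow$p_value, 1e-6)
  # exact binomial oracle
  expect_equal(prow$p_value,
               pbinom(99, 100, prow$expected_prob, lower.tail = FALSE))
})

test_that("empty peak set gives zero counts and P = 1", {
  fd <- feature_enrichment(toy_peaks(integer()), toy_genes(), 20000)
  expect_true(all(fd$observed == 0))
  expect_true(all(fd$p_value == 1))
})

test_that("nearest-peak distances and bins follow the nearest rule", {
  genes <- toy_genes()
  # summits at 900 and 2500 from txA TSS (2000): nearest is 10900? no --
  # place summits 10900 (900 from txC TSS) and 12500
  pk <- toy_peaks(c(10900, 12500))
  td <- tss_distance_bins(genes, pk)
  dC <- td$distances[td$distances$transcript_id == "txC", ]
  expect_equal(dC$distance, 900)
  expect_equal(dC$nearest_summit, 10900)
  expect_equal(td$histogram$count[1], 1)  # only txC within 1 kb
  expect_true(all(td$histogram$bin_hi <= 10000))
  # every histogram entry comes from a distance <= window
  expect_equal(sum(td$histogram$count),
               sum(td$distances$distance <= 10000, na.rm = TRUE))
})

test_that("nearest distances match a brute-force all-pairs scan", {
  genes <- toy_genes()
  set.seed(33)
  pk <- toy_peaks(sort(sample.int(19000, 25)))
  td <- tss_distance_bins(genes, pk)
  tt <- tss_table(genes)
  for (i in seq_len(nrow(tt))) {
    brute <- min(abs(tt$tss[i] - pk$summit_mid))
    expect_equal(td$distances$distance[i], brute)
  }
})

test_that("signed distances are strand-oriented", {
  genes <- toy_genes()
  pk <- toy_peaks(c(1800, 7600))  # both upstream of their TSSs
  td <- tss_distance_bins(genes, pk, signed = TRUE)
  dA <- td$distances[td$distances$transcript_id == "txA", "signed_distance"]
  dB <- td$distances[td$distances$transcript_id == "txB", "signed_distance"]
  expect_lt(dA, 0)  # upstream of plus-strand TSS
  expect_lt(dB, 0)  # upstream of minus-strand TSS (higher coordinate)
})

test_that("averaged TSS profile peaks at zero for TSS-centered peaks", {
  genes <- toy_genes()
  tt <- tss_table(genes)
  pk <- toy_peaks(tt$tss)
  set.seed(34)
  prof <- averaged_tss_profile(genes, pk, c(chr1 = 20000), window = 500,
                               n_baseline = 3)
  expect_equal(prof$position[which.max(prof$count)], 0, tolerance = 21)
  expect_equal(max(prof$profile), 1)
  expect_equal(attr(prof, "n_genes"), 3L)
})

test_that("upstream-planted peaks shift the profile mass upstream", {
  genes <- toy_genes()
  tt <- tss_table(genes)
  up <- ifelse(tt$strand == "+", tt$tss - 700L, tt$tss + 700L)
  set.seed(35)
  prof <- averaged_tss_profile(genes, toy_peaks(up), c(chr1 = 20000),
                               window = 1000, n_baseline = 2)
  upstream_mass <- sum(prof$count[prof$position < 0])
  downstream_mass <- sum(prof$count[prof$position > 0])
  expect_gt(upstream_mass, 5 * max(downstream_mass, 1))
})

test_that("intergenic filter applies the 1 kb TSS rule and extents", {
  genes <- toy_genes()
  pk <- toy_peaks(c(1001,    # 999 bp from txA TSS -> excluded
                    17000,   # >= 5 kb from everything -> included
                    2600))   # inside txA -> excluded even though TSS-far? no,
                             # 600 bp from TSS -> excluded anyway
  ig <- intergenic_peaks(pk, genes)
  expect_equal(ig$summit_mid, 17000L)
  empty <- gene_models(toy_genes()$transcripts[0, ], toy_genes()$features[0, ])
  expect_equal(nrow(intergenic_peaks(pk, empty)), 3L)
  # boundary: exactly 1000 bp away and outside extents -> included
  pk2 <- toy_peaks(1000)
  expect_equal(nrow(intergenic_peaks(pk2, genes)), 1L)
})

test_that("colocalization of a set with itself spikes at offset zero", {
  map <- tiny_map(20000)
  set.seed(36)
  pk <- toy_peaks(sort(sample.int(19000, 30)))
  cc <- colocalization_curve(pk, pk, map, max_offset = 3000, bin_width = 500,
                             n_perm = 20)
  zero_bin <- which(cc$offset_lo <= 0 & cc$offset_hi > 0)
  expect_equal(which.max(cc$enrichment), zero_bin)
  expect_lt(cc$p_value[zero_bin], 1e-3)
  expect_error(colocalization_curve(toy_peaks(integer()), pk, map),
               "non-empty")
})

test_that("peak-set intersections match a brute-force all-pairs scan", {
  set.seed(37)
  mk <- function(n) {
    s <- sort(sample.int(50000, n))
    toy_peaks(s)
  }
  A <- mk(40); B <- mk(40); C <- mk(30)
  res <- intersect_peak_sets(list(A = A, B = B, C = C))
  # quadratic oracle on merged loci
  iv <- rbind(data.frame(s = A$start, e = A$end, set = "A"),
              data.frame(s = B$start, e = B$end, set = "B"),
              data.frame(s = C$start, e = C$end, set = "C"))
  iv <- iv[order(iv$s), ]
  loci <- list(); cur <- iv[1, c("s", "e")]; members <- iv$set[1]
  for (i in 2:nrow(iv)) {
    if (iv$s[i] < cur$e) {
      cur$e <- max(cur$e, iv$e[i]); members <- union(members, iv$set[i])
    } else {
      loci[[length(loci) + 1]] <- sort(members)
      cur <- iv[i, c("s", "e")]; members <- iv$set[i]
    }
  }
  loci[[length(loci) + 1]] <- sort(members)
  brute <- table(vapply(loci, paste, character(1), collapse = "&"))
  for (j in seq_len(nrow(res))) {
    key <- res$sets[j]
    expect_equal(res$count[j],
                 if (key %in% names(brute)) unname(brute[[key]]) else 0L,
                 info = key)
  }
})

test_that("disjoint and identical sets give degenerate partitions", {
  A <- toy_peaks(c(1000, 3000))
  B <- toy_peaks(c(10000, 12000))
  r <- intersect_peak_sets(list(A = A, B = B))
  expect_equal(r$count[r$sets == "A&B"], 0L)
  expect_equal(r$count[r$sets == "A"], 2L)
  r2 <- intersect_peak_sets(list(A = A, B = A))
  expect_equal(r2$count[r2$sets == "A&B"], 2L)
  expect_equal(r2$count[r2$sets == "A"], 0L)
})

test_that("gene models survive a GFF3 round trip", {
  genes <- toy_genes()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models(genes, path)
  back <- read_gene_models(path)
  expect_equal(back$transcripts[order(back$transcripts$transcript_id), ],
               genes$transcripts[order(genes$transcripts$transcript_id), ],
               ignore_attr = TRUE)
  ord <- function(f) f[order(f$transcript_id, f$start, f$type), ]
  expect_equal(ord(back$features), ord(genes$features), ignore_attr = TRUE)
})
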