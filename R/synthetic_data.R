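# Synthetic DamID experiments with planted truth -----------------------------
#
# Generates every input the pipeline consumes -- genome, gene models,
# fragment counts per construct/replicate/genotype, mutant expression
# tables, a tissue ratio matrix -- from a single seeded configuration, and
# records the planted truth (bound fragments, direct/indirect labels,
# dynamics groups, tissue-specific flags) so downstream recovery can be
# scored exactly.

#' Simulation configuration
#'
#' Defaults describe a desk-scale experiment: one 1 Mb chromosome
#' (~4000 GATC fragments at the 1/256 density of random sequence), 300
#' genes, two biological replicates per channel at 2e5 reads each,
#' negative-binomial overdispersion 0.05 (Poisson replicates would make the
#' replicate-noise FDR calibration degenerate), and an 8-fold enrichment
#' rate ratio at bound fragments.
#'
#' @param seed RNG seed.
#' @param n_chroms,chrom_length Genome shape.
#' @param gatc_density Target GATC starts per bp; random sequence yields
#'   1/256, higher densities are reached by planting extra motifs.
#' @param n_genes,gene_spacing Gene count and center-to-center spacing (bp).
#' @param factors Profiled factors; `mip40` is additionally profiled across
#'   the genotype series (bam, aly, can, wt) for the dynamics analysis.
#' @param effect_size Rate ratio at bound fragments (>= 1).
#' @param depth Reads per channel per replicate.
#' @param dispersion Negative-binomial overdispersion (0 = Poisson).
#' @param accessibility_sd SD of the per-fragment lognormal accessibility
#'   shared by channels and replicates.
#' @param n_reps Biological replicates per channel.
#' @param p_couple Probability a bound gene is coupled to >= 8-fold
#'   down-regulation in the cognate mutant (truth label `direct`).
#' @param frac_group Named fractions of genes planted into dynamics groups
#'   I-VI (rest unbound by mip40).
#' @param frac_bound Named fractions of genes bound by can / comr in wt.
#' @param cobind_frac Fraction of can-bound genes drawn from the comr-bound
#'   set (cooperative binding).
#' @param frac_indirect Fraction of unbound genes planted as indirect
#'   targets (down-regulated without a peak).
#' @param n_tissues,frac_testis,frac_ovary Tissue-matrix shape and planted
#'   tissue-specific fractions.
#' @return A validated `SimConfig` list.
#' @export
sim_config <- function(seed = 1, n_chroms = 1, chrom_length = 1e6,
                       gatc_density = 1 / 256, n_genes = 300,
                       gene_spacing = 3000,
                       factors = c("can", "comr", "mip40"),
                       effect_size = 8, depth = 2e5, dispersion = 0.05,
                       accessibility_sd = 0.5, n_reps = 2, p_couple = 1,
                       frac_group = c(I = 0.10, II = 0.06, III = 0.10,
                                      IV = 0.08, V = 0.05, VI = 0.05),
                       frac_bound = c(can = 0.20, comr = 0.20),
                       cobind_frac = 0.6, frac_indirect = 0.05,
                       n_tissues = 10, frac_testis = 0.2, frac_ovary = 0.1) {
  cfg <- as.list(environment())
  .assert(cfg$depth > 0, "depth must be positive")
  .assert(cfg$effect_size >= 1, "effect size must be >= 1")
  .assert(cfg$dispersion >= 0, "dispersion must be non-negative")
  .assert(all(frac_group >= 0) && sum(frac_group) <= 1,
          "group fractions must be probabilities summing to <= 1")
  .assert(all(frac_bound >= 0 & frac_bound <= 1) && cfg$p_couple >= 0 &&
            cfg$p_couple <= 1, "probabilities must lie in [0, 1]")
  .assert(cfg$frac_testis + cfg$frac_ovary <= 1,
          "tissue-specific fractions must sum to <= 1")
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a genome and gene models
#'
#' Random uniform sequence (natural GATC density 1/256) with extra motifs
#' planted when `gatc_density` asks for more; non-overlapping 1.5 kb gene
#' models (5'UTR, two CDS exons, one intron, 3'UTR) on alternating random
#' strands at `gene_spacing` intervals. Deterministic given the RNG state;
#' callers seed via [simulate_damid_experiment()] or `set.seed()`.
#'
#' @param cfg A `SimConfig`.
#' @return list with `genome` (named character vector) and `genes`
#'   (`GeneModels`).
#' @export
simulate_genome_and_genes <- function(cfg) {
  genome <- stats::setNames(vapply(seq_len(cfg$n_chroms), function(i) {
    s <- sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE)
    extra <- round(cfg$gatc_density * cfg$chrom_length) -
      round(cfg$chrom_length / 256)
    if (extra > 0) {
      at <- sample.int(cfg$chrom_length - 3L, extra)
      for (p in at) s[p:(p + 3L)] <- c("G", "A", "T", "C")
    }
    paste(s, collapse = "")
  }, character(1)), paste0("chr", seq_len(cfg$n_chroms)))

  gene_len <- 1500L
  empty_tx <- data.frame(transcript_id = character(), gene_id = character(),
                         chrom = character(), strand = character(),
                         start = integer(), end = integer())
  empty_feat <- data.frame(transcript_id = character(), type = character(),
                           start = integer(), end = integer())
  if (cfg$n_genes == 0L)
    return(list(genome = genome, genes = gene_models(empty_tx, empty_feat)))
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  .assert(per_chrom * cfg$gene_spacing + gene_len + 1000 <= cfg$chrom_length,
          "genes do not fit the chromosome at the requested spacing")
  tx <- list(); feat <- list(); gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    n_here <- min(per_chrom, cfg$n_genes - (ci - 1L) * per_chrom)
    if (n_here <= 0L) break
    starts <- 500L + (seq_len(n_here) - 1L) * cfg$gene_spacing +
      sample.int(500L, n_here, replace = TRUE)
    strands <- sample(c("+", "-"), n_here, replace = TRUE)
    ids <- sprintf("tx%04d", gi + seq_len(n_here))
    tx[[ci]] <- data.frame(
      transcript_id = ids,
      gene_id = sprintf("gene%04d", gi + seq_len(n_here)),
      chrom = names(genome)[ci], strand = strands,
      start = starts, end = starts + gene_len, stringsAsFactors = FALSE)
    # block layout in transcript coordinates (5' to 3'):
    # 5'UTR 150, CDS 400, intron 300, CDS 400, 3'UTR 250
    offs <- rbind(five_prime_UTR = c(0, 150), CDS1 = c(150, 550),
                  intron = c(550, 850), CDS2 = c(850, 1250),
                  three_prime_UTR = c(1250, 1500))
    feat[[ci]] <- do.call(rbind, lapply(seq_len(n_here), function(j) {
      s <- starts[j]
      if (strands[j] == "+") {
        blocks <- s + offs
      } else {
        blocks <- s + gene_len - offs[, c(2, 1)]
      }
      data.frame(transcript_id = ids[j],
                 type = sub("[0-9]$", "", rownames(offs)),
                 start = blocks[, 1], end = blocks[, 2],
                 stringsAsFactors = FALSE)
    }))
    gi <- gi + n_here
  }
  list(genome = genome,
       genes = gene_models(do.call(rbind, tx), do.call(rbind, feat)))
}

# Fragment containing each position (row index into map), NA when outside.
.fragment_of <- function(map, chrom, pos) {
  out <- rep(NA_integer_, length(pos))
  for (chr in unique(chrom)) {
    rows <- which(map$chrom == chr)
    qi <- which(chrom == chr)
    idx <- findInterval(pos[qi], map$start[rows])
    ok <- idx >= 1L & pos[qi] < max(map$end[rows])
    out[qi[ok]] <- rows[idx[ok]]
  }
  out
}

#' Plant the ground truth
#'
#' Assigns dynamics groups (mip40 presence patterns over bam/aly/can/wt),
#' wt binding for can and comr (with cooperative overlap), direct targets
#' (bound genes coupled to mutant down-regulation with `p_couple`),
#' indirect targets (unbound, down-regulated), mip40-repressed genes
#' (spermatogonially bound groups I/II/V/VI, up-regulated in the mip40
#' mutant), and tissue-specific flags. The bound fragment of a gene is the
#' GATC fragment containing its TSS.
#'
#' @param cfg A `SimConfig`.
#' @param genes `GeneModels` from [simulate_genome_and_genes()].
#' @param map The genome's `FragmentMap`.
#' @return A `TruthSet`: list with `genes` (per-transcript truth table) and
#'   `bound_fragments` (data.frame factor, genotype, transcript_id,
#'   fragment_id).
#' @export
plant_truth <- function(cfg, genes, map) {
  tt <- tss_table(genes)
  n <- nrow(tt)
  tss_frag <- .fragment_of(map, tt$chrom, tt$tss)
  .assert(!anyNA(tss_frag), "every TSS must lie on the fragment map")

  # dynamics groups
  pats <- default_group_patterns()
  group <- rep("none", n)
  pool <- sample.int(n)
  used <- 0L
  for (g in names(cfg$frac_group)) {
    k <- round(cfg$frac_group[[g]] * n)
    if (k > 0) group[pool[used + seq_len(k)]] <- g
    used <- used + k
  }

  # wt binding: comr first, can overlapping it (cooperative)
  bound <- list()
  n_comr <- round(cfg$frac_bound[["comr"]] * n)
  comr_bound <- sample.int(n, n_comr)
  n_can <- round(cfg$frac_bound[["can"]] * n)
  n_shared <- min(round(cfg$cobind_frac * n_can), n_comr)
  can_bound <- c(sample(comr_bound, n_shared),
                 sample(setdiff(seq_len(n), comr_bound), n_can - n_shared))
  bound_idx <- list(can = sort(can_bound), comr = sort(comr_bound))
  # mip40 binding per genotype follows the planted pattern
  mip40_bound <- lapply(GENOTYPE_ORDER, function(gt) {
    which(group %in% rownames(pats)[pats[, gt]])
  })
  names(mip40_bound) <- GENOTYPE_ORDER

  bf <- rbind(
    do.call(rbind, lapply(intersect(cfg$factors, c("can", "comr")),
                          function(f) data.frame(
      factor = f, genotype = "wt",
      transcript_id = tt$transcript_id[bound_idx[[f]]],
      fragment_id = tss_frag[bound_idx[[f]]], stringsAsFactors = FALSE))),
    if ("mip40" %in% cfg$factors)
      do.call(rbind, lapply(GENOTYPE_ORDER, function(gt) {
        idx <- mip40_bound[[gt]]
        if (length(idx) == 0L) return(NULL)
        data.frame(factor = "mip40", genotype = gt,
                   transcript_id = tt$transcript_id[idx],
                   fragment_id = tss_frag[idx], stringsAsFactors = FALSE)
      })))

  # expression coupling: direct = bound & coupled; indirect = unbound & down
  truth <- data.frame(transcript_id = tt$transcript_id,
                      gene_id = tt$gene_id, tss_fragment = tss_frag,
                      dyn_group = group, stringsAsFactors = FALSE)
  wt_bound <- list(can = bound_idx$can, comr = bound_idx$comr,
                   mip40 = mip40_bound$wt)
  for (f in cfg$factors) {
    b <- logical(n); b[wt_bound[[f]]] <- TRUE
    coupled <- b & (runif(n) < cfg$p_couple)
    if (f == "mip40") {
      # repression by the spermatogonial complex excludes activation targets
      repressed <- group %in% c("I", "II", "V", "VI")
      coupled <- coupled & !repressed
      truth$repressed_mip40 <- repressed
    }
    idir <- !b & (runif(n) < cfg$frac_indirect)
    if (f == "mip40") idir <- idir & !truth$repressed_mip40
    truth[[paste0("bound_", f)]] <- b
    truth[[paste0("direct_", f)]] <- coupled
    truth[[paste0("indirect_", f)]] <- idir
  }

  # tissue-specific flags
  spec <- sample(c(rep("testis", round(cfg$frac_testis * n)),
                   rep("ovary", round(cfg$frac_ovary * n))))
  flag <- rep("none", n)
  flag[sample.int(n, length(spec))] <- spec
  truth$testis_specific <- flag == "testis"
  truth$ovary_specific <- flag == "ovary"

  structure(list(genes = truth, bound_fragments = bf), class = "TruthSet")
}

#' Simulate fragment counts for one factor/genotype experiment
#'
#' Dam-alone rates are proportional to fragment length times a lognormal
#' accessibility shared by both channels and all replicates; the fusion
#' channel multiplies the rate by `effect_size` at the bound fragments.
#' Counts are negative binomial (Poisson when `dispersion = 0`) with the
#' requested depth; replicates share rates and differ only by counting
#' noise.
#'
#' @param cfg A `SimConfig`.
#' @param map A `FragmentMap`.
#' @param bound_fragments Integer fragment ids carrying the factor in this
#'   genotype (empty vector = null experiment).
#' @param factor,genotype Metadata labels.
#' @return list with `fusion` and `dam` (lists of `n_reps`
#'   `FragmentCounts`) and `rates` (the per-fragment fusion/background
#'   rates, for oracle checks).
#' @export
simulate_counts <- function(cfg, map, bound_fragments, factor = "factor",
                            genotype = "wt") {
  .assert(all(bound_fragments %in% map$fragment_id),
          "bound fragments must exist in the map")
  n <- nrow(map)
  access <- exp(rnorm(n, 0, cfg$accessibility_sd))
  bg <- (map$end - map$start) * access
  bg <- bg / sum(bg)
  fg <- bg
  fg[bound_fragments] <- fg[bound_fragments] * cfg$effect_size
  fg <- fg / sum(fg)
  draw <- function(rate, rep_i, construct) {
    mu <- cfg$depth * rate
    counts <- if (cfg$dispersion > 0) {
      rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    } else {
      rpois(n, mu)
    }
    fragment_counts(counts, map,
                    sample_id = paste(factor, genotype, construct, rep_i,
                                      sep = "_"),
                    genotype = genotype, construct = construct,
                    replicate = rep_i)
  }
  list(fusion = lapply(seq_len(cfg$n_reps), function(r)
         draw(fg, r, "dam_fusion")),
       dam = lapply(seq_len(cfg$n_reps), function(r)
         draw(bg, r, "dam_alone")),
       rates = list(fusion = fg, background = bg))
}

#' Simulate expression tables and the tissue ratio matrix
#'
#' Direct and indirect targets of each factor are at least 8-fold down in
#' the cognate mutant (guaranteed after the FPKM-plus-1 pseudocount);
#' mip40-repressed genes are at least 4-fold up in the mip40 mutant;
#' everything else gets mild multiplicative noise. The tissue matrix plants
#' the configured testis- and ovary-specific fractions so the selection
#' rule recovers exactly the planted sets; non-specific rows are forced to
#' violate the rule.
#'
#' @param cfg A `SimConfig`.
#' @param truth A `TruthSet` from [plant_truth()].
#' @return list with `expr` (`ExpressionTable`) and `tissues` (matrix).
#' @export
simulate_expression_and_tissues <- function(cfg, truth) {
  tg <- truth$genes
  n <- nrow(tg)
  mutants <- unique(c("bam", "aly", cfg$factors))
  down_by <- lapply(mutants, function(m) {
    if (m %in% cfg$factors) {
      tg[[paste0("direct_", m)]] | tg[[paste0("indirect_", m)]]
    } else rep(FALSE, n)
  })
  names(down_by) <- mutants
  up_by <- lapply(mutants, function(m) {
    if (m == "mip40" && !is.null(tg$repressed_mip40)) tg$repressed_mip40
    else rep(FALSE, n)
  })
  names(up_by) <- mutants
  for (m in mutants)
    .assert(!any(down_by[[m]] & up_by[[m]]),
            "gene planted both up and down in mutant '%s'", m)

  changed <- Reduce(`|`, c(down_by, up_by))
  fpkm_wt <- exp(rnorm(n, 3, 1))
  fpkm_wt[changed] <- pmax(exp(rnorm(sum(changed), 5, 0.5)), 40)
  expr <- data.frame(transcript_id = tg$transcript_id, fpkm_wt = fpkm_wt)
  for (m in mutants) {
    fpkm <- fpkm_wt * 2^rnorm(n, 0, 0.3)
    fpkm[down_by[[m]]] <- fpkm_wt[down_by[[m]]] /
      runif(sum(down_by[[m]]), 12, 20)
    fpkm[up_by[[m]]] <- fpkm_wt[up_by[[m]]] * runif(sum(up_by[[m]]), 6, 12)
    expr[[paste0("fpkm_", m)]] <- fpkm
    expr[[paste0("sig_", m)]] <- down_by[[m]] | up_by[[m]]
  }

  tissues <- c("testis", "ovary",
               paste0("tissue", seq_len(max(cfg$n_tissues - 2, 0))))
  mat <- matrix(rnorm(n * length(tissues), 0, 1), nrow = n,
                dimnames = list(tg$transcript_id, tissues))
  mat[sample.int(length(mat), round(0.1 * length(mat)))] <- NA
  .plant_specific <- function(rows, target) {
    others <- setdiff(tissues, target)
    mat[rows, target] <<- runif(length(rows), 0.5, 3)
    for (o in others) {
      v <- -runif(length(rows), 0.1, 2)
      v[runif(length(rows)) < 0.2] <- NA  # null expression also satisfies
      mat[rows, o] <<- v
    }
  }
  .plant_specific(which(tg$testis_specific), "testis")
  .plant_specific(which(tg$ovary_specific), "ovary")
  # force non-specific rows to violate the rule for both target tissues
  for (target in c("testis", "ovary")) {
    flag <- if (target == "testis") tg$testis_specific else tg$ovary_specific
    others <- setdiff(tissues, target)
    other_target <- setdiff(c("testis", "ovary"), target)
    for (i in which(!flag)) {
      r <- mat[i, others]
      if (!is.na(mat[i, target]) && mat[i, target] > 0 &&
          all(is.na(r) | r < 0)) {
        fix <- sample(setdiff(others, other_target), 1)
        mat[i, fix] <- runif(1, 0.1, 1)
      }
    }
  }
  list(expr = expression_table(expr), tissues = mat)
}

#' Run the whole generator
#'
#' Seeds the RNG from `cfg$seed` and produces every pipeline input plus the
#' truth set. Count tables are generated for can and comr in wt and for
#' mip40 across the genotype series (bam, aly, can, wt).
#'
#' @param cfg A `SimConfig`.
#' @return list: `config`, `genome`, `genes`, `map`, `truth`, `counts`
#'   (nested `counts[[factor]][[genotype]]`), `expr`, `tissues`.
#' @export
simulate_damid_experiment <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  gg <- simulate_genome_and_genes(cfg)
  map <- build_fragment_map(gg$genome)
  truth <- plant_truth(cfg, gg$genes, map)
  counts <- list()
  for (f in cfg$factors) {
    genotypes <- if (f == "mip40") GENOTYPE_ORDER else "wt"
    counts[[f]] <- lapply(stats::setNames(genotypes, genotypes), function(gt) {
      bf <- truth$bound_fragments
      frag <- bf$fragment_id[bf$factor == f & bf$genotype == gt]
      simulate_counts(cfg, map, frag, factor = f, genotype = gt)
    })
  }
  et <- simulate_expression_and_tissues(cfg, truth)
  list(config = cfg, genome = gg$genome, genes = gg$genes, map = map,
       truth = truth, counts = counts, expr = et$expr, tissues = et$tissues)
}

#' Emit toy GATC-anchored reads from planted counts
#'
#' For tests of the read filter: emits, for each fragment, `counts[i]`
#' plus-strand reads anchored at the fragment's left boundary with sequence
#' starting GATC, plus optional contaminating reads that do not start with
#' the motif.
#'
#' @param counts Integer vector per fragment.
#' @param map A `FragmentMap`.
#' @param n_contaminant Number of non-GATC reads to add (default 0).
#' @return data.frame with columns `chrom`, `pos`, `strand`, `seq`.
#' @export
simulate_reads <- function(counts, map, n_contaminant = 0) {
  idx <- rep(seq_len(nrow(map)), counts)
  reads <- data.frame(chrom = map$chrom[idx], pos = map$start[idx],
                      strand = "+",
                      seq = paste0("GATC", strrep("A", 20)),
                      stringsAsFactors = FALSE)
  if (n_contaminant > 0) {
    pick <- sample.int(nrow(map), n_contaminant, replace = TRUE)
    reads <- rbind(reads, data.frame(
      chrom = map$chrom[pick], pos = map$start[pick], strand = "+",
      seq = paste0("AATC", strrep("A", 20)), stringsAsFactors = FALSE))
  }
  reads
}
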