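# Pipeline orchestration ------------------------------------------------------
#
# Stages consume and produce plain-text artifacts under one output
# directory; a JSON manifest records parameters and md5 checksums of every
# input and output, so unchanged stages are skipped on rerun and a tampered
# intermediate is caught before it can poison downstream results.

PIPELINE_STAGES <- c("simulate", "fragments", "signal", "callpeaks",
                     "annotate", "targets", "dynamics", "coloc")

#' Build a run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed for the run.
#' @param fdr_cutoff,p_cutoff,ratio_cutoff Peak-calling thresholds
#'   (defaults 0.05, 1e-3, 1).
#' @param tss_window,presence_window TSS windows in bp for target
#'   classification (1000) and dynamics presence calls (300).
#' @param fold_cutoff,direct_fold_cutoff Fold cutoffs: 4 for the
#'   changed-transcript analyses, 8 for direct targets.
#' @param coloc_permutations Baseline draws for [colocalization_curve()].
#' @param sim Arguments forwarded to [sim_config()] (list); the seed is
#'   taken from `seed`.
#' @param ... Further fields stored verbatim (echoed into the manifest).
#' @return A `RunConfig` list.
#' @export
damid_run_config <- function(out_dir, seed = 1, fdr_cutoff = 0.05,
                             p_cutoff = 1e-3, ratio_cutoff = 1,
                             tss_window = 1000, presence_window = 300,
                             fold_cutoff = 4, direct_fold_cutoff = 8,
                             coloc_permutations = 100, sim = list(), ...) {
  cfg <- c(as.list(environment()), list(...))
  cfg$sim <- do.call(sim_config, c(list(seed = seed), sim))
  .assert(cfg$fdr_cutoff > 0 && cfg$p_cutoff > 0 && cfg$ratio_cutoff > 0,
          "thresholds must be positive")
  .assert(cfg$tss_window >= 1 && cfg$presence_window >= 1 &&
            cfg$tss_window == floor(cfg$tss_window) &&
            cfg$presence_window == floor(cfg$presence_window),
          "windows must be positive integers")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a run configuration from YAML
#'
#' Flat keys matching [damid_run_config()] arguments, with an optional
#' nested `sim:` block of [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param ... Overrides applied after the file (e.g. CLI flags).
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(damid_run_config, y)
}

.manifest_path <- function(cfg) file.path(cfg$out_dir, "manifest.json")

.read_manifest <- function(cfg) {
  p <- .manifest_path(cfg)
  if (file.exists(p)) jsonlite::read_json(p) else list(stages = list())
}

.write_manifest <- function(cfg, manifest) {
  jsonlite::write_json(manifest, .manifest_path(cfg), auto_unbox = TRUE,
                       pretty = TRUE)
}

.checksums <- function(paths) {
  as.list(tools::md5sum(paths))
}

# Atomic write: `fn(path)` writes to a temp file which is then renamed.
.atomic <- function(path, fn) {
  tmp <- paste0(path, ".tmp")
  fn(tmp)
  file.rename(tmp, path)
  path
}

#' Run one pipeline stage
#'
#' Verifies that declared inputs exist and match the checksums recorded
#' when they were produced (a mismatch is an error naming the file), skips
#' the stage when inputs and outputs are unchanged since the last run
#' (unless `force`), and records parameters and output checksums in the run
#' manifest.
#'
#' @param name One of `r paste(PIPELINE_STAGES, collapse = ", ")`.
#' @param cfg A `RunConfig`.
#' @param force Rerun even when up to date.
#' @return Character vector of the stage's output paths (invisibly).
#' @export
run_stage <- function(name, cfg, force = FALSE) {
  .assert(name %in% PIPELINE_STAGES, "unknown stage '%s'; valid: %s", name,
          paste(PIPELINE_STAGES, collapse = ", "))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- .read_manifest(cfg)
  io <- .stage_io(name, cfg)
  missing <- io$inputs[!file.exists(io$inputs)]
  .assert(length(missing) == 0, "stage '%s': missing input(s): %s", name,
          paste(missing, collapse = ", "))
  # integrity: inputs recorded as some stage's output must still match
  for (st in manifest$stages) {
    for (f in names(st$outputs)) {
      if (f %in% io$inputs && file.exists(f) &&
          !identical(unname(tools::md5sum(f)), st$outputs[[f]]))
        stop(sprintf("stage '%s': checksum mismatch for input '%s'",
                     name, f), call. = FALSE)
    }
  }
  prev <- manifest$stages[[name]]
  up_to_date <- !is.null(prev) && all(file.exists(io$outputs)) &&
    identical(.checksums(io$inputs), prev$inputs) &&
    identical(.checksums(io$outputs), prev$outputs)
  if (up_to_date && !force) {
    message(sprintf("stage '%s': up to date, skipped", name))
    return(invisible(io$outputs))
  }
  message(sprintf("stage '%s': running", name))
  .stage_run(name, cfg, io)
  manifest$stages[[name]] <- list(
    stage = name,
    inputs = .checksums(io$inputs),
    outputs = .checksums(io$outputs),
    params = .stage_params(cfg),
    version = as.character(utils::packageVersion("damidflow")),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  .write_manifest(cfg, manifest)
  invisible(io$outputs)
}

#' Run all (or selected) stages in order
#'
#' @param cfg A `RunConfig`.
#' @param stages Stage names, in pipeline order by default.
#' @param force Passed to [run_stage()].
#' @export
run_pipeline <- function(cfg, stages = PIPELINE_STAGES, force = FALSE) {
  for (s in stages) run_stage(s, cfg, force = force)
  invisible(.manifest_path(cfg))
}

.stage_params <- function(cfg) {
  keep <- c("seed", "fdr_cutoff", "p_cutoff", "ratio_cutoff", "tss_window",
            "presence_window", "fold_cutoff", "direct_fold_cutoff",
            "coloc_permutations")
  cfg[keep]
}

.experiment_units <- function(cfg) {
  units <- list()
  for (f in cfg$sim$factors) {
    genotypes <- if (f == "mip40") GENOTYPE_ORDER else "wt"
    for (gt in genotypes) units[[paste(f, gt, sep = "_")]] <-
      list(factor = f, genotype = gt)
  }
  units
}

.stage_io <- function(name, cfg) {
  d <- function(...) file.path(cfg$out_dir, ...)
  units <- names(.experiment_units(cfg))
  count_files <- unlist(lapply(units, function(u)
    d(sprintf("counts_%s_%s_rep%d.tsv",
              rep(u, each = 2 * cfg$sim$n_reps),
              rep(c("fusion", "dam"), each = cfg$sim$n_reps),
              rep(seq_len(cfg$sim$n_reps), 2)))))
  switch(name,
    simulate = list(inputs = character(),
                    outputs = c(d("genome.fa"), d("genes.gff3"), count_files,
                                d("expression.tsv"), d("tissues.tsv"),
                                d("truth.json"))),
    fragments = list(inputs = d("genome.fa"), outputs = d("fragments.bed")),
    signal = list(inputs = c(d("fragments.bed"), count_files),
                  outputs = d(sprintf("signal_%s.tsv", units))),
    callpeaks = list(inputs = c(d("fragments.bed"), count_files,
                                d(sprintf("signal_%s.tsv", units))),
                     outputs = c(d(sprintf("peaks_%s.bed", units)),
                                 d(sprintf("fdr_%s.tsv", units)))),
    annotate = list(inputs = c(d("genes.gff3"), d("peaks_can_wt.bed")),
                    outputs = c(d("feature_distribution.tsv"),
                                d("tss_distances.tsv"))),
    targets = list(inputs = c(d("genes.gff3"), d("expression.tsv"),
                              d(sprintf("peaks_%s_wt.bed", cfg$sim$factors))),
                   outputs = d(sprintf("targets_%s.tsv", cfg$sim$factors))),
    dynamics = list(inputs = c(d("genes.gff3"), d("expression.tsv"),
                               d(sprintf("peaks_mip40_%s.bed",
                                         GENOTYPE_ORDER))),
                    outputs = c(d("presence_matrix.tsv"),
                                d("dynamics_groups.tsv"))),
    coloc = list(inputs = c(d("fragments.bed"), d("peaks_can_wt.bed"),
                            d("peaks_comr_wt.bed")),
                 outputs = d("colocalization.tsv")))
}

.stage_run <- function(name, cfg, io) {
  d <- function(...) file.path(cfg$out_dir, ...)
  if (name == "simulate") {
    sim <- simulate_damid_experiment(cfg$sim)
    .atomic(d("genome.fa"), function(p)
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), p))
    .atomic(d("genes.gff3"), function(p) write_gene_models(sim$genes, p))
    for (u in names(.experiment_units(cfg))) {
      unit <- .experiment_units(cfg)[[u]]
      cc <- sim$counts[[unit$factor]][[unit$genotype]]
      for (r in seq_len(cfg$sim$n_reps)) {
        .atomic(d(sprintf("counts_%s_fusion_rep%d.tsv", u, r)), function(p)
          write_fragment_counts(cc$fusion[[r]], p))
        .atomic(d(sprintf("counts_%s_dam_rep%d.tsv", u, r)), function(p)
          write_fragment_counts(cc$dam[[r]], p))
      }
    }
    .atomic(d("expression.tsv"), function(p)
      write_expression_table(sim$expr, p))
    .atomic(d("tissues.tsv"), function(p) write_tissue_matrix(sim$tissues, p))
    .atomic(d("truth.json"), function(p)
      jsonlite::write_json(list(genes = sim$truth$genes,
                                bound_fragments = sim$truth$bound_fragments),
                           p, digits = NA))
  } else if (name == "fragments") {
    map <- build_fragment_map(d("genome.fa"))
    .atomic(d("fragments.bed"), function(p) write_fragment_map(map, p))
  } else if (name == "signal") {
    map <- read_fragment_map(d("fragments.bed"))
    for (u in names(.experiment_units(cfg))) {
      unit <- .experiment_units(cfg)[[u]]
      fus <- lapply(seq_len(cfg$sim$n_reps), function(r)
        read_fragment_counts(d(sprintf("counts_%s_fusion_rep%d.tsv", u, r)),
                             map, construct = "dam_fusion", replicate = r))
      dam <- lapply(seq_len(cfg$sim$n_reps), function(r)
        read_fragment_counts(d(sprintf("counts_%s_dam_rep%d.tsv", u, r)),
                             map, construct = "dam_alone", replicate = r))
      tr <- build_signal_track(fus, dam, map, factor = unit$factor,
                               genotype = unit$genotype)
      .atomic(d(sprintf("signal_%s.tsv", u)), function(p)
        write_signal_track(tr, p))
    }
  } else if (name == "callpeaks") {
    map <- read_fragment_map(d("fragments.bed"))
    for (u in names(.experiment_units(cfg))) {
      tr <- read_signal_track(d(sprintf("signal_%s.tsv", u)), map)
      fus <- lapply(1:2, function(r)
        read_fragment_counts(d(sprintf("counts_%s_fusion_rep%d.tsv", u, r)),
                             map, construct = "dam_fusion", replicate = r))
      nz <- noise_track(fus[[1]], fus[[2]], map)
      curve <- calibrate_fdr(tr, nz, fdr_cutoff = cfg$fdr_cutoff,
                             ratio_cutoff = cfg$ratio_cutoff)
      peaks <- call_peaks(tr, attr(curve, "t_star"), p_cutoff = cfg$p_cutoff,
                          ratio_cutoff = cfg$ratio_cutoff)
      .atomic(d(sprintf("fdr_%s.tsv", u)), function(p)
        write_fdr_curve(curve, p))
      .atomic(d(sprintf("peaks_%s.bed", u)), function(p)
        write_peaks(peaks, p))
    }
  } else if (name == "annotate") {
    genes <- read_gene_models(d("genes.gff3"))
    peaks <- read_peaks(d("peaks_can_wt.bed"))
    map <- read_fragment_map(d("fragments.bed"))
    fd <- feature_enrichment(peaks, genes,
                             genome_size = sum(attr(map, "chrom_lengths")))
    .atomic(d("feature_distribution.tsv"), function(p) .write_tsv(fd, p))
    td <- tss_distance_bins(genes, peaks, window = 10 * cfg$tss_window)
    .atomic(d("tss_distances.tsv"), function(p)
      .write_tsv(td$distances, p))
  } else if (name == "targets") {
    genes <- read_gene_models(d("genes.gff3"))
    expr <- read_expression_table(d("expression.tsv"))
    for (f in cfg$sim$factors) {
      peaks <- read_peaks(d(sprintf("peaks_%s_wt.bed", f)))
      tg <- classify_targets(expr, peaks, genes, mutant = f,
                             fold_cutoff = cfg$direct_fold_cutoff,
                             dist_cutoff = cfg$tss_window)
      .atomic(d(sprintf("targets_%s.tsv", f)), function(p)
        write_target_table(tg, p))
    }
  } else if (name == "dynamics") {
    genes <- read_gene_models(d("genes.gff3"))
    peaksets <- lapply(stats::setNames(GENOTYPE_ORDER, GENOTYPE_ORDER),
                       function(gt)
                         read_peaks(d(sprintf("peaks_mip40_%s.bed", gt))))
    pm <- presence_matrix(peaksets, genes, window = cfg$presence_window)
    assign <- assign_groups(pm)
    .atomic(d("presence_matrix.tsv"), function(p)
      .write_tsv(data.frame(transcript_id = rownames(pm), pm * 1L,
                            check.names = FALSE), p))
    .atomic(d("dynamics_groups.tsv"), function(p) .write_tsv(assign, p))
  } else if (name == "coloc") {
    map <- read_fragment_map(d("fragments.bed"))
    set.seed(cfg$seed)
    curve <- colocalization_curve(read_peaks(d("peaks_can_wt.bed")),
                                  read_peaks(d("peaks_comr_wt.bed")), map,
                                  n_perm = cfg$coloc_permutations)
    .atomic(d("colocalization.tsv"), function(p) .write_tsv(curve, p))
  }
}
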