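#' Read and validate a pipeline run configuration
#'
#' YAML configuration with strict schema checking: unknown keys are
#' rejected, probabilities must lie in \[0, 1\], counts must be positive.
#' Top-level keys: `fasta` (path), `gene` (optional label), `n_controls`,
#' `seed`, and the nested blocks `model` (`p_frameshift`, `ploidy`,
#' `efficiency`), `simulation` (`domains` as a list of
#' `{start_aa, end_aa, d}`, `s_scr`, `s_ref`, `T_pre`, `T_scr`, `coverage`,
#' `depth`, `bottleneck`, `n_replicates`, `mode`) and `analysis`
#' (`pseudocount`, `bandwidth`, `min_support`, `B`, `alpha`, `min_len`,
#' `max_gap`). All omitted values take the package defaults.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return Validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  schema <- list(
    top = c("fasta", "gene", "n_controls", "seed", "model", "simulation",
            "analysis"),
    model = c("p_frameshift", "ploidy", "efficiency"),
    simulation = c("domains", "s_scr", "s_ref", "T_pre", "T_scr", "coverage",
                   "depth", "bottleneck", "n_replicates", "mode"),
    analysis = c("pseudocount", "bandwidth", "min_support", "B", "alpha",
                 "min_len", "max_gap"))
  reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra))
      stop("unknown config key(s) in ", where, ": ",
           paste(extra, collapse = ", "))
  }
  reject_unknown(cfg, schema$top, "top level")
  for (blk in c("model", "simulation", "analysis"))
    if (!is.null(cfg[[blk]])) reject_unknown(cfg[[blk]], schema[[blk]], blk)
  if (is.null(cfg$fasta)) stop("config requires 'fasta'")
  if (is.null(cfg$seed)) stop("config requires 'seed'")
  cfg$n_controls <- cfg$n_controls %||% 99L
  prob_keys <- list(c("model", "p_frameshift"), c("model", "efficiency"),
                    c("simulation", "s_scr"), c("simulation", "s_ref"),
                    c("analysis", "alpha"))
  for (pk in prob_keys) {
    v <- cfg[[pk[1]]][[pk[2]]]
    if (!is.null(v) && (v < 0 || v > 1))
      stop(pk[1], "$", pk[2], " must lie in [0, 1]")
  }
  for (ck in c("coverage", "depth", "n_replicates"))
    if (!is.null(cfg$simulation[[ck]]) && cfg$simulation[[ck]] < 1)
      stop("simulation$", ck, " must be positive")
  if (!is.null(cfg$simulation$domains)) {
    for (dmn in cfg$simulation$domains)
      if (!all(c("start_aa", "end_aa", "d") %in% names(dmn)))
        stop("each simulation domain needs start_aa, end_aa, d")
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Run the full tiling-screen pipeline
#'
#' Chains design -> simulate -> score -> scan -> evaluate from a single
#' configuration, writing every artifact (library, counts, truth, scores,
#' track, regions, BED export, evaluation, manifest, log) under `out_dir`.
#' All randomness derives from the single config seed through named
#' per-stage substreams, so rerunning with the same configuration
#' reproduces every output byte-identically.
#'
#' @param config A `run_config` (or path to one, or a plain list).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`library`, `counts`, `scores`, `track`, `regions`, `evaluation`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else
    read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, open = "wb")
  on.exit(close(log_con))
  say <- function(...) {
    msg <- paste0(...)
    message("[tilescreen] ", msg)
    writeLines(paste0("[tilescreen] ", msg), log_con, sep = "\n")
  }
  seed <- as.integer(cfg$seed)
  seeds <- vapply(c("design", "simulate", "score", "scan"),
                  function(st) stage_seed(seed, st), integer(1))

  say("stage design: reading ", cfg$fasta)
  cds_all <- read_cds_fasta(cfg$fasta)
  cds <- cds_all[[1]]
  if (length(cds_all) > 1L)
    say("multiple FASTA records; using first ('", cds$id, "')")
  lib <- design_tiling_library(cds, n_controls = cfg$n_controls,
                               gene = cfg$gene %||% cds$id,
                               seed = seeds[["design"]])
  n_drop <- nrow(attr(lib, "dropped"))
  say("stage design: ", sum(!lib$is_control), " targeting + ",
      sum(lib$is_control), " control guides (", n_drop, " dropped)")
  write_library(lib, file.path(out_dir, "library.tsv"))

  simc <- cfg$simulation %||% list()
  dom <- if (is.null(simc$domains))
    data.frame(start_aa = integer(), end_aa = integer(), d = numeric())
  else do.call(rbind, lapply(simc$domains, as.data.frame))
  truth <- sim_truth(protein_length = protein_length(cds), domains = dom,
                     s_scr = simc$s_scr %||% 0.3, s_ref = simc$s_ref %||% 0,
                     T_pre = simc$T_pre %||% 21L, T_scr = simc$T_scr %||% 20L,
                     coverage = simc$coverage %||% 1000L,
                     depth = simc$depth %||% 1e6,
                     bottleneck = simc$bottleneck, seed = seed)
  modelc <- cfg$model %||% list()
  model <- repair_outcome_model(
    p_frameshift = modelc$p_frameshift %||% (2 / 3),
    ploidy = modelc$ploidy %||% 2L,
    efficiency = modelc$efficiency %||% 1)
  say("stage simulate: ", nrow(truth$domains), " implanted domain(s), mode ",
      simc$mode %||% "expectation")
  counts <- simulate_screen(lib, truth,
                            n_replicates = simc$n_replicates %||% 2L,
                            model = model,
                            mode = simc$mode %||% "expectation",
                            seed = seeds[["simulate"]])
  write_counts(counts, file.path(out_dir, "counts.tsv"))
  jsonlite::write_json(
    list(protein_length = truth$protein_length, domains = truth$domains,
         s_scr = truth$s_scr, s_ref = truth$s_ref, T_pre = truth$T_pre,
         T_scr = truth$T_scr, coverage = truth$coverage,
         depth = truth$depth, seed = seed),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  anac <- cfg$analysis %||% list()
  say("stage score: ", ncol(counts$counts), " samples")
  scores <- score_guides(counts, lib,
                         pseudocount = anac$pseudocount %||% 0.5)
  write_scores(scores, file.path(out_dir, "scores.tsv"))

  say("stage scan: bandwidth ", anac$bandwidth %||% 5, ", B ",
      anac$B %||% 1000L)
  track <- smooth_track(scores, lib, bandwidth = anac$bandwidth %||% 5,
                        min_support = anac$min_support %||% 0.1)
  track <- permutation_null(track, B = anac$B %||% 1000L,
                            seed = seeds[["scan"]])
  regions <- call_regions(track, alpha = anac$alpha %||% 0.05,
                          min_len = anac$min_len %||% 3L,
                          max_gap = anac$max_gap %||% 2L)
  say("stage scan: ", nrow(regions), " region(s) called")
  write_track(track, file.path(out_dir, "track.tsv"))
  write_regions(regions, file.path(out_dir, "regions.tsv"))
  write_regions_bed(regions, file.path(out_dir, "regions.bed"))

  evaluation <- evaluate_calls(regions, truth)
  jsonlite::write_json(evaluation, file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "tilescreen",
    version = as.character(packageVersion("tilescreen")),
    seed = seed,
    stage_seeds = as.list(seeds),
    config = unclass(cfg),
    outputs = c("library.tsv", "counts.tsv", "truth.json", "scores.tsv",
                "track.tsv", "regions.tsv", "regions.bed",
                "evaluation.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done")
  invisible(list(library = lib, counts = counts, scores = scores,
                 track = track, regions = regions, evaluation = evaluation,
                 manifest = manifest))
}

#' Write coding sequences to FASTA
#'
#' @param cds_list A `coding_sequence` or list of them.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_cds_fasta <- function(cds_list, path, width = 70L) {
  if (inherits(cds_list, "coding_sequence")) cds_list <- list(cds_list)
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (cds in cds_list) {
    writeLines(paste0(">", cds$id), con, sep = "\n")
    starts <- seq(1L, nchar(cds$seq), by = width)
    writeLines(substring(cds$seq, starts,
                         pmin(starts + width - 1L, nchar(cds$seq))),
               con, sep = "\n")
  }
  invisible(path)
}
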