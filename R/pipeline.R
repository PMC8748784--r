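#' Default pipeline configuration
#'
#' Returns the full run configuration with the published parameterization
#' of the zebrafish CNCC atlas study as the `"zebrafish_cncc"` preset:
#' timepoint weight `a = 12`, skew cutoff 1 (earliest stage 0.4 with max
#' score > 15), priming alpha 0.05, LSI rank 30 with components 2..30,
#' neighbourhood k = 20, enriched-peak alpha 0.001, and deviation
#' backgrounds n = 50.
#'
#' @param preset Preset name; currently `"zebrafish_cncc"`.
#' @return Named list of class `run_config`.
#' @export
default_config <- function(preset = "zebrafish_cncc") {
  if (preset != "zebrafish_cncc") stopf("unknown preset '%s'", preset)
  structure(list(
    preset = preset,
    seed = 1L,
    stages = list(simulate = TRUE, qc = TRUE, score = TRUE,
                  competency = TRUE, constellation = TRUE, priming = TRUE,
                  stitch = TRUE),
    simulate = list(n_tissues = 10L, n_timepoints = 5L,
                    cells_per_timepoint = 2000L, peaks_per_tissue = 50L,
                    background_peaks = 1000L, effect_size = 3),
    qc = list(frip_min = 0.5, frag_lo = 1000, frag_hi = 20000),
    score = list(n_background = 50L, k_candidates = 100L),
    competency = list(skew_cutoff = 1, earliest_skew_cutoff = 0.4,
                      earliest_max_score = 15),
    constellation = list(a = 12, linkage = "average", normalize = FALSE),
    priming = list(alpha = 0.05),
    stitch = list(rank = 30L, k_intra = 20L, k_link = 10L),
    output_dir = NULL
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Range-checks every parameter and rejects unknown keys; returns a report
#' rather than raising on invalid values.
#'
#' @param config A list as returned by [default_config()] (possibly
#'   modified), or a YAML path.
#' @return List with `valid` (logical) and `problems` (character vector).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  probs <- character(0)
  bad_keys <- setdiff(names(config), names(ref))
  if (length(bad_keys))
    probs <- c(probs, paste("unknown key(s):", paste(bad_keys, collapse = ", ")))
  for (sec in c("simulate", "qc", "score", "competency", "constellation",
                "priming", "stitch")) {
    if (is.null(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bad))
      probs <- c(probs, sprintf("unknown key(s) in %s: %s", sec,
                                paste(bad, collapse = ", ")))
  }
  g <- function(sec, key) config[[sec]][[key]] %||% ref[[sec]][[key]]
  if (g("constellation", "a") < 0) probs <- c(probs, "constellation$a must be >= 0")
  if (g("simulate", "effect_size") < 1) probs <- c(probs, "simulate$effect_size must be >= 1")
  if (g("qc", "frag_lo") >= g("qc", "frag_hi"))
    probs <- c(probs, "qc fragment range must have lo < hi")
  if (g("priming", "alpha") < 0 || g("priming", "alpha") > 1)
    probs <- c(probs, "priming$alpha must lie in [0, 1]")
  if (g("competency", "earliest_skew_cutoff") > g("competency", "skew_cutoff"))
    probs <- c(probs, "earliest skew cutoff must not exceed the main cutoff")
  if (g("score", "n_background") < 2) probs <- c(probs, "score$n_background must be >= 2")
  if (g("stitch", "rank") < 2) probs <- c(probs, "stitch$rank must be >= 2")
  if (!is.null(config$output_dir) && !is.null(config$stages)) {
    en <- unlist(config$stages)
    if (any(en) && !dir.exists(dirname(config$output_dir)) &&
        dirname(config$output_dir) != ".")
      probs <- c(probs, sprintf("output_dir parent '%s' does not exist",
                                dirname(config$output_dir)))
  }
  list(valid = length(probs) == 0L, problems = probs)
}

#' Run the full retrograde competency pipeline
#'
#' Executes the enabled stages in dependency order on a simulated atlas:
#' simulate, QC, module scoring (retrograde application of terminal-stage
#' tissue peak sets), competency calls and establishment table,
#' constellation distance + embedding + grouping, priming regression, and
#' the temporal graph. All artifacts are written under `out_dir` together
#' with a JSON manifest recording parameters, seeds and output checksums.
#'
#' @param config A [default_config()]-style list or YAML path.
#' @param out_dir Output directory (overrides `config$output_dir`).
#' @return Invisible list of in-memory stage results plus the `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- modifyList(unclass(default_config()), config)
  chk <- validate_config(config)
  if (!chk$valid)
    stopf("invalid config: %s", paste(chk$problems, collapse = "; "))
  out_dir <- out_dir %||% config$output_dir %||% tempfile("constellatr_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  res <- list()
  timing <- list()
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fn(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    out
  }

  if (isTRUE(stages$simulate)) {
    res$sim <- run_stage("simulate", function() {
      sm <- config$simulate
      spec <- lineage_spec(
        tissues = paste0("tissue", seq_len(sm$n_tissues)),
        timepoints = paste0("t", seq_len(sm$n_timepoints)),
        cells_per_timepoint = sm$cells_per_timepoint,
        peaks_per_tissue = sm$peaks_per_tissue,
        background_peaks = sm$background_peaks,
        effect_size = sm$effect_size, seed = config$seed)
      simulate_atlas(spec)
    })
    write_truth_report(res$sim$truth, file.path(out_dir, "truth.tsv"))
  }
  atlases <- res$sim$atlases

  if (isTRUE(stages$qc)) {
    res$qc <- run_stage("qc", function()
      lapply(atlases, qc_filter_cells, frip_min = config$qc$frip_min,
             frag_range = c(config$qc$frag_lo, config$qc$frag_hi)))
    atlases <- res$qc
  }

  if (isTRUE(stages$score)) {
    res$scores <- run_stage("score", function()
      score_all(atlases, res$sim$module_sets,
                n_background = config$score$n_background,
                seed = config$seed,
                k_candidates = config$score$k_candidates))
    for (tp in names(res$scores))
      write.table(res$scores[[tp]]$scores,
                  file.path(out_dir, paste0("scores_", tp, ".tsv")),
                  sep = "\t", quote = FALSE)
  }

  if (isTRUE(stages$competency)) {
    res$competency <- run_stage("competency", function() {
      cfg <- competency_config(config$competency$skew_cutoff,
                               config$competency$earliest_skew_cutoff,
                               config$competency$earliest_max_score)
      rep_ <- competency_report(res$scores, cfg)
      list(report = rep_, establishment = establishment_table(rep_))
    })
    write_competency_report(res$competency$report,
                            file.path(out_dir, "competency.tsv"))
    write.table(res$competency$establishment,
                file.path(out_dir, "establishment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(stages$constellation)) {
    res$constellation <- run_stage("constellation", function() {
      cd <- build_distance(res$scores, a = config$constellation$a,
                           normalize = config$constellation$normalize,
                           linkage = config$constellation$linkage)
      map <- embed_constellation(cd, seed = config$seed,
                                 statuses = res$competency$report)
      list(dist = cd, map = map)
    })
    write_constellation(res$constellation$dist,
                        file.path(out_dir, "constellation"))
    write.table(res$constellation$map, file.path(out_dir, "constellation_map.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(stages$priming)) {
    res$priming <- run_stage("priming", function() {
      est <- res$competency$establishment
      tps <- names(res$scores)
      # regress each tissue at its establishment timepoint (fallback: first)
      pairs <- list()
      for (tissue in colnames(res$scores[[1]]$scores)) {
        tp <- est$establishment[est$tissue == tissue]
        if (is.na(tp)) tp <- tps[1]
        pr <- pair_motif_tf(
          res$scores[[tp]]$scores[, tissue, drop = FALSE],
          res$sim$motif_activity[[tp]][rownames(res$scores[[tp]]$scores), , drop = FALSE],
          res$sim$tf_activity[[tp]][rownames(res$scores[[tp]]$scores), , drop = FALSE],
          res$sim$pairing, alpha = config$priming$alpha)
        pairs[[tissue]] <- pr$pairs
      }
      do.call(rbind, pairs)
    })
    write.table(res$priming, file.path(out_dir, "priming_pairs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (isTRUE(stages$stitch)) {
    res$stitch <- run_stage("stitch", function()
      build_temporal_graph(atlases, rank = config$stitch$rank,
                           k_intra = config$stitch$k_intra,
                           k_link = config$stitch$k_link))
    write_temporal_graph(res$stitch, file.path(out_dir, "temporal_graph"))
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  sums <- tools::md5sum(files)
  names(sums) <- list.files(out_dir, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("constellatr")),
    preset = config$preset, seed = config$seed,
    parameters = config[c("simulate", "qc", "score", "competency",
                          "constellation", "priming", "stitch")],
    timing_s = timing,
    checksums = as.list(sums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
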