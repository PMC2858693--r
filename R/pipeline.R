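# End-to-end orchestration: prep -> nucleosome calling (both strains) ->
# cross-strain alignment -> SNEP scan -> profiles -> enrichment, with a
# structured JSON run report.

#' Run the full pipeline from a configuration
#'
#' The configuration is a named list (or path to a YAML file) with entries:
#' \describe{
#'   \item{inputs}{paths: `by_probes`, `rm_probes`, `blocks`,
#'     `polymorphisms`, `intensities`, `manifest`, `genes` (optional).
#'     Alternatively `simulate: TRUE` plus `sim:` overrides for
#'     [sim_config()] generates the inputs in memory.}
#'   \item{slack_bp}{probe correspondence slack (default 3).}
#'   \item{window_bp, step_bp}{HMM sliding-window geometry (default
#'     1000/500).}
#'   \item{fdr}{FDR level for SNEP calling (default 0.0001).}
#'   \item{min_shared}{minimum shared probes per pair (default 15).}
#'   \item{seed}{seed for all stochastic stages (mandatory).}
#'   \item{out_dir}{output directory; `NULL` skips file output.}
#' }
#' Stage failures abort with an error naming the stage. The report counts
#' probes retained, nucleosomes called per strain, pairs aligned, pairs
#' tested, SNEPs at the FDR level and their direction split, plus the
#' implied genome-wide p-value cutoff `k * alpha / m`.
#'
#' @param config list or YAML file path.
#' @return list with `report` and the main stage outputs (`calls_by`,
#'   `calls_rm`, `pairs`, `snep` ...).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("pipeline config must set a seed", call. = FALSE)
  seed <- as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim %||% list()
    sim_args$seed <- seed
    sim <- stage("simulate", simulate_dataset(do.call(sim_config, sim_args)))
    probes_by <- sim$probes_by; probes_rm <- sim$probes_rm
    blocks <- sim$truth$blocks; polymorphisms <- sim$truth$polymorphisms
    raw <- sim$intensities; genes <- sim$truth$genes
  } else {
    inp <- config$inputs
    for (f in c("by_probes", "rm_probes", "blocks", "polymorphisms",
                "intensities", "manifest")) {
      if (is.null(inp[[f]]) || !file.exists(inp[[f]]))
        stop(sprintf("pipeline stage 'inputs': missing file for '%s'%s", f,
                     if (!is.null(inp[[f]])) sprintf(" (%s)", inp[[f]]) else ""),
             call. = FALSE)
    }
    probes_by <- stage("inputs", read_probe_map(inp$by_probes))
    probes_rm <- stage("inputs", read_probe_map(inp$rm_probes))
    blocks <- stage("inputs", read_blocks(inp$blocks))
    polymorphisms <- stage("inputs", read_polymorphisms(inp$polymorphisms))
    raw <- stage("inputs", read_intensities(inp$intensities, inp$manifest))
    genes <- if (!is.null(inp$genes)) stage("inputs", read_genes(inp$genes)) else NULL
    sim <- NULL
  }
  if (nrow(raw$values) == 0L)
    stop("pipeline stage 'prep': empty intensity matrix", call. = FALSE)

  # --- prep -----------------------------------------------------------------
  slack <- config$slack_bp %||% 3
  dual <- stage("prep", select_dual_probes(probes_by, probes_rm, blocks,
                                           polymorphisms, slack_bp = slack))
  norm <- stage("prep", quantile_normalize(
    intensity_matrix(raw$values[rownames(raw$values) %in% dual, , drop = FALSE],
                     raw$manifest)))

  # --- nucleosome calling ---------------------------------------------------
  window_bp <- config$window_bp %||% 1000
  step_bp <- config$step_bp %||% (window_bp / 2)
  cfg_for <- function(track) {
    spacing <- stats::median(diff(sort(track$position[track$chrom == track$chrom[1]])))
    hmm_config(spacing, window_bp = window_bp, step_bp = step_bp)
  }
  track_by <- stage("callnuc", build_probe_track(norm, probes_by, "BY", "nuc"))
  res_by <- stage("callnuc", call_nucleosomes(track_by, cfg_for(track_by),
                                              strain = "BY", seed = seed))
  track_rm <- stage("callnuc", build_probe_track(norm, probes_rm, "RM", "nuc"))
  res_rm <- stage("callnuc", call_nucleosomes(track_rm, cfg_for(track_rm),
                                              strain = "RM", seed = seed))

  # --- alignment ------------------------------------------------------------
  rm_proj <- stage("alignnuc", liftover_calls(res_rm$calls, blocks))
  rm_post_proj <- res_rm$posteriors
  lifted_pos <- lift_intervals_to_ref(rm_post_proj$chrom,
                                      floor(rm_post_proj$position),
                                      floor(rm_post_proj$position) + 1L, blocks)
  rm_post_proj$chrom <- lifted_pos$ref_chrom
  rm_post_proj$position <- lifted_pos$ref_start + 0.5
  rm_post_proj <- rm_post_proj[!is.na(rm_post_proj$position), , drop = FALSE]
  pairs <- stage("alignnuc", align_maps(res_by$calls, rm_proj,
                                        by_post = res_by$posteriors,
                                        rm_post = rm_post_proj))

  # --- SNEP scan ------------------------------------------------------------
  fdr <- config$fdr %||% 1e-4
  min_shared <- config$min_shared %||% 15
  dual_map <- probes_by[probes_by$probe_id %in% dual, , drop = FALSE]
  snep <- stage("snep", snep_scan(pairs, norm, dual_map,
                                  min_shared = min_shared, alpha_fdr = fdr))

  # --- report ---------------------------------------------------------------
  tests <- snep$tests
  report <- list(
    seed = seed,
    n_probes_input = nrow(raw$values),
    n_probes_dual = length(dual),
    n_calls_by = nrow(res_by$calls),
    n_calls_rm = nrow(res_rm$calls),
    n_pairs = nrow(pairs),
    n_aligned = sum(pairs$status == "aligned"),
    n_insertion = sum(pairs$status == "insertion"),
    n_deletion = sum(pairs$status == "deletion"),
    n_tested = snep$m,
    n_sneps = snep$k,
    n_byac = sum(tests$significant & tests$direction == "BYac"),
    n_rmac = sum(tests$significant & tests$direction == "RMac"),
    fdr = fdr,
    bh_cutoff = snep$cutoff
  )
  out <- list(report = report, calls_by = res_by$calls, calls_rm = res_rm$calls,
              posteriors_by = res_by$posteriors, posteriors_rm = rm_post_proj,
              pairs = pairs, snep = snep, normalized = norm, genes = genes,
              dual_probes = dual, sim = sim)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_calls_gff3(res_by$calls, file.path(config$out_dir, "calls_by.gff3"))
    write_calls_gff3(res_rm$calls, file.path(config$out_dir, "calls_rm.gff3"))
    write_tsv(pairs, file.path(config$out_dir, "pairs.tsv"))
    write_tsv(tests, file.path(config$out_dir, "sneps.tsv"))
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
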