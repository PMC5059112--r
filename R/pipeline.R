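# Pipeline orchestration: simulate -> count -> analyze, with provenance
# metadata (inputs, parameters, seed, package version) written next to
# every output set.

write_provenance <- function(out_dir, step, params) {
  meta <- list(step = step,
               package = "pathscreen",
               version = as.character(utils::packageVersion("pathscreen")),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
               params = params)
  jsonlite::write_json(meta, file.path(out_dir,
                                       paste0("provenance_", step, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Run the simulate step
#'
#' Generates a full synthetic screen and writes FASTQ files, the sample
#' sheet, the truth table, a scenario echo (YAML) and provenance JSON to
#' `out_dir`.
#'
#' @param out_dir output directory.
#' @param preset optional [scenario_preset()] name.
#' @param scenario a [screen_scenario()]; overrides `preset`.
#' @param manifest a manifest (default: the packaged library).
#' @param seed master seed (applied to the scenario).
#' @return the `screen_run`, invisibly.
#' @export
cmd_simulate <- function(out_dir, preset = NULL, scenario = NULL,
                         manifest = NULL, seed = 0L) {
  if (is.null(scenario)) {
    if (is.null(preset)) {
      stop("usage error: provide a scenario or a preset name", call. = FALSE)
    }
    scenario <- scenario_preset(preset, seed = seed)
  } else {
    scenario$seed <- as.integer(seed)
  }
  if (is.null(manifest)) manifest <- default_manifest()
  run <- generate_screen(scenario, manifest, out_dir = out_dir)
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  write_provenance(out_dir, "simulate",
                   list(preset = preset %||% "custom", seed = seed,
                        n_cells = scenario$n_cells, moi = scenario$moi,
                        doses = as.list(scenario$doses),
                        days = scenario$days,
                        read_depth = scenario$read_depth,
                        error_rate = scenario$error_rate))
  invisible(run)
}

#' Run the count step
#'
#' @param fastq character vector of FASTQ paths.
#' @param samplesheet path to the sample-sheet TSV.
#' @param manifest path to the manifest TSV (default: packaged library).
#' @param out_dir output directory for `counts.tsv` + QC JSON + provenance.
#' @param max_linker_mm,max_index_mm mismatch tolerances.
#' @return the `count_table`, invisibly.
#' @export
cmd_count <- function(fastq, samplesheet, manifest = NULL, out_dir = ".",
                      max_linker_mm = 2L, max_index_mm = 0L) {
  m <- if (is.null(manifest)) default_manifest() else load_manifest(manifest)
  sheet <- load_samplesheet(samplesheet)
  ct <- count_barcodes(fastq, read_layout(), sheet, m,
                       max_linker_mm = max_linker_mm,
                       max_index_mm = max_index_mm)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_counts(ct, file.path(out_dir, "counts.tsv"))
  write_provenance(out_dir, "count",
                   list(fastq = fastq, samplesheet = samplesheet,
                        max_linker_mm = max_linker_mm,
                        max_index_mm = max_index_mm))
  invisible(ct)
}

#' Run the analyze step
#'
#' Chains fractional representation, replicate averaging, vehicle
#' normalization, control baselining and hit calling; writes fractions,
#' enrichment and hit TSVs plus provenance.
#'
#' @param counts path to a counts TSV from [cmd_count()], or a
#'   `count_table`.
#' @param samplesheet path to the sample-sheet TSV, or a data.frame.
#' @param manifest path to the manifest TSV (default: packaged library), or
#'   a manifest object.
#' @param out_dir output directory.
#' @param alpha pseudocount for vehicle normalization.
#' @param threshold hit threshold on relative enrichment (default 1.5).
#' @param min_doses minimum passing doses per construct (default 2).
#' @return the `hit_report`, invisibly.
#' @export
cmd_analyze <- function(counts, samplesheet, manifest = NULL, out_dir = ".",
                        alpha = 1e-6, threshold = 1.5, min_doses = 2L) {
  m <- if (is.null(manifest)) default_manifest()
       else if (inherits(manifest, "pathscreen_manifest")) manifest
       else load_manifest(manifest)
  sheet <- if (is.data.frame(samplesheet)) samplesheet
           else load_samplesheet(samplesheet)
  ct <- if (inherits(counts, "count_table")) counts else read_counts(counts)
  miss <- setdiff(as.data.frame(m)$construct_id, rownames(ct$counts))
  if (length(miss)) {
    stop("schema error: counts table lacks construct(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  e <- compute_enrichment(ct, sheet, alpha = alpha)
  baseline <- control_baseline(e, m)
  rel <- relative_enrichment(e, baseline)
  report <- call_hits(rel, m, threshold = threshold, min_doses = min_doses)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- fractional_representation(ct)
  fr_df <- data.frame(construct_id = rownames(f), unclass(f),
                      check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(fr_df, file.path(out_dir, "fractions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_enrichment(e, file.path(out_dir, "enrichment.tsv"),
                   excluded = attr(f, "excluded"))
  write_hits(report, file.path(out_dir, "hits.tsv"))
  write_provenance(out_dir, "analyze",
                   list(alpha = alpha, threshold = threshold,
                        min_doses = min_doses,
                        controls = manifest_controls(m)))
  invisible(report)
}

#' Run a full in-memory screen pipeline
#'
#' Convenience wrapper used heavily in simulation studies: generate a
#' screen, count its reads, and call hits, all without touching disk.
#'
#' @param scenario a [screen_scenario()].
#' @param manifest a manifest (default: packaged library).
#' @param alpha,threshold,min_doses analysis parameters.
#' @return list with the `screen_run`, `count_table`, `enrichment_table`,
#'   relative enrichment and `hit_report`.
#' @export
run_screen_pipeline <- function(scenario, manifest = NULL, alpha = 1e-6,
                                threshold = 1.5, min_doses = 2L) {
  if (is.null(manifest)) manifest <- default_manifest()
  run <- generate_screen(scenario, manifest)
  ct <- count_barcodes(run$reads, scenario$layout, run$samplesheet, manifest)
  e <- compute_enrichment(ct, run$samplesheet, alpha = alpha)
  baseline <- control_baseline(e, manifest)
  rel <- relative_enrichment(e, baseline)
  report <- call_hits(rel, manifest, threshold = threshold,
                      min_doses = min_doses)
  list(run = run, counts = ct, enrichment = e, relative = rel,
       hits = report)
}
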