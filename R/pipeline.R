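#' Pipeline configuration
#'
#' Validated configuration binding the stages into one run. Unknown keys
#' are rejected so that typos fail before any stage runs.
#'
#' @param locus A \code{\link{locus_config}} or a path to a locus JSON.
#' @param seed Integer seed driving all stage randomness.
#' @param outdir Output directory (created if absent).
#' @param n_cells Cells in the simulated allele population.
#' @param n_long_reads Long reads emitted and decomposed.
#' @param short_coverage Short-read fold coverage.
#' @param cohort_n Individuals in the simulated phenotype cohort.
#' @param cohort_cells Cells per cohort individual.
#' @param log_level \code{"info"} or \code{"quiet"}.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(locus = fame3_locus(), seed = 1L,
                            outdir = "famex_out", n_cells = 100L,
                            n_long_reads = 30L, short_coverage = 30,
                            cohort_n = 6L, cohort_cells = 60L,
                            log_level = c("info", "quiet")) {
  if (is.character(locus)) {
    if (!file.exists(locus)) {
      stop("locus config file not found: ", locus, call. = FALSE)
    }
    locus <- read_locus_config(locus)
  }
  validate_locus_config(locus)
  log_level <- match.arg(log_level)
  structure(list(locus = locus, seed = as.integer(seed), outdir = outdir,
                 n_cells = as.integer(n_cells),
                 n_long_reads = as.integer(n_long_reads),
                 short_coverage = short_coverage,
                 cohort_n = as.integer(cohort_n),
                 cohort_cells = as.integer(cohort_cells),
                 log_level = log_level),
            class = "pipeline_config")
}

#' Validate a pipeline configuration list read from JSON
#' @param lst Named list (parsed JSON).
#' @return A \code{\link{pipeline_config}}.
#' @export
pipeline_config_from_list <- function(lst) {
  allowed <- c("locus", "seed", "outdir", "n_cells", "n_long_reads",
               "short_coverage", "cohort_n", "cohort_cells", "log_level")
  unknown <- setdiff(names(lst), allowed)
  if (length(unknown)) {
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, lst)
}

#' @keywords internal
pipe_log <- function(cfg, stage, ...) {
  if (cfg$log_level != "quiet") {
    message("[famex:", stage, "] ", ...)
  }
}

#' Run the full simulate-and-analyze pipeline
#'
#' Executes, in order: allele-population simulation; long-read emission and
#' decomposition; short-read emission and screening; combing-table emission,
#' allele calling and per-individual summary; cohort emission and
#' genotype-phenotype correlation. All stage tables are written as TSV
#' under \code{cfg$outdir} together with a JSON run manifest (seed, package
#' version, config hash, per-stage status and outputs). The run is
#' deterministic given the seed. On a stage failure, partial outputs are
#' retained and the manifest records the failure point.
#'
#' @param cfg A \code{\link{pipeline_config}}.
#' @return The manifest, invisibly (list). Manifest \code{status} is
#'   \code{"ok"} or \code{"failed"}.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outdir, f)
  locus_path <- out("locus.json")
  write_locus_config(cfg$locus, locus_path)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(packageVersion("famex")),
                   config_hash = unname(tools::md5sum(locus_path)),
                   stages = list(), outputs = character(), status = "ok")
  run_stage <- function(name, fun) {
    pipe_log(cfg, name, "running")
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      manifest$status <<- "failed"
      manifest$failed_at <<- name
      FALSE
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      TRUE
    }
  }
  env <- new.env()
  ok <- run_stage("simulate", function() {
    env$model <- expansion_model()
    env$cells <- simulate_allele_population(env$model,
                                            n_cells = cfg$n_cells,
                                            seed = cfg$seed)
    famex_write_tsv(env$cells, out("alleles_truth.tsv"))
  })
  if (ok) ok <- run_stage("decompose", function() {
    reads <- emit_long_reads(env$cells, cfg$locus,
                             n_reads = cfg$n_long_reads,
                             seed = cfg$seed + 1L,
                             out = out("long_reads.fastq"))
    dec <- decompose_reads(setNames(reads$sequence, reads$read_id),
                           cfg$locus)
    famex_write_tsv(decomposition_table(dec), out("decomposition.tsv"))
    summ <- summarize_reads(dec)
    jsonlite::write_json(summ, out("nanopore_summary.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  })
  if (ok) ok <- run_stage("screen", function() {
    sr <- emit_short_reads(env$cells, cfg$locus,
                           coverage = cfg$short_coverage,
                           seed = cfg$seed + 2L)
    res <- genotype_locus(c(sr$r1$sequence, sr$r2$sequence), cfg$locus)
    famex_write_tsv(screen_table(res, "SIM1"), out("screen.tsv"))
  })
  if (ok) ok <- run_stage("comb", function() {
    comb <- emit_combing_table(env$cells, seed = cfg$seed + 3L,
                               out = out("combing_measurements.tsv"))
    calls <- call_alleles(comb, cfg$locus$thresholds)
    famex_write_tsv(calls, out("combing_alleles.tsv"))
    famex_write_tsv(cohort_summary(calls), out("combing_summary.tsv"))
  })
  if (ok) ok <- run_stage("correlate", function() {
    models <- default_cohort_models(cfg$cohort_n)
    cohort <- emit_cohort(models, n_cells = cfg$cohort_cells,
                          seed = cfg$seed + 4L, out = out("cohort.tsv"))
    famex_write_tsv(onset_correlation_report(cohort),
                    out("correlations.tsv"))
  })
  manifest$outputs <- list.files(cfg$outdir)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       na = "null")
  pipe_log(cfg, "done", "status=", manifest$status)
  invisible(manifest)
}
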