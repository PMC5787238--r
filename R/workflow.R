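# End-to-end orchestration: a single config drives database build, read
# preparation, profiling, grouping and postprocessing, with a JSON run
# manifest sufficient to re-execute the run.

#' Default run configuration
#'
#' All parameter defaults are the method's stated operating values:
#' per-base error probability 0.005, primer and read/k-mer mismatch caps 2,
#' low-frequency read filter 1e-4, group frequency floor 0.1%, EM tolerance
#' 1e-8.
#'
#' @param ... Name = value overrides of any default field.
#' @return Named list of class `smurf_config`.
#' @export
smurf_config <- function(...) {
  cfg <- list(
    reference_fasta = NULL, taxonomy = NULL, primers = NULL,
    fastq = NULL, fastq2 = NULL, out_dir = NULL,
    read_len = 75L, mode = "paired",
    p_e = 0.005, primer_mismatch = 2L, read_mismatch = 2L,
    barcode_len = 0L, read_threshold = 1e-4,
    min_group_freq = 0.001, taxonomy_level = "species",
    tol = 1e-8, max_iter = 10000L, seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  class(cfg) <- c("smurf_config", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `smurf_config`.
#' @return `read_config` returns a `smurf_config`; `write_config` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  do.call(smurf_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the complete profiling workflow
#'
#' Executes build-db, read preparation, profiling, footprint grouping and
#' postprocessing under one configuration, persisting every intermediate
#' artifact under `config$out_dir` (when set) together with a JSON manifest
#' holding the config snapshot, package version, input checksums and
#' per-stage record counts.  Identical config + inputs + seed yields
#' identical outputs.
#'
#' @param config A `smurf_config` (or path to its YAML file).
#' @return List of class `smurf_run` with `fit`, `groups`, `report`,
#'   `ambiguity`, `manifest`.
#' @export
smurf_run <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "smurf_config"))
  set.seed(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  t0 <- Sys.time()
  ref <- stage("reference", read_reference(config$reference_fasta,
                                           config$taxonomy))
  primers <- stage("primers", if (is.null(config$primers)) default_primers()
                   else read_primers(config$primers))
  db <- stage("build-db", build_region_kmer_db(
    ref, primers, k = config$read_len, mode = config$mode,
    max_mismatch = config$primer_mismatch))
  reads <- stage("prep", prepare_reads(
    config$fastq, primers, L = config$read_len, fastq2 = config$fastq2,
    barcode_len = config$barcode_len, max_mismatch = config$primer_mismatch,
    threshold = config$read_threshold))
  fit <- stage("profile", smurf(
    reads, db, p_e = config$p_e, cap = config$read_mismatch,
    tol = config$tol, max_iter = config$max_iter))
  groups <- stage("resolve", assign_groups(fit))
  report <- stage("postprocess", postprocess_profile(
    groups, level = config$taxonomy_level, min_freq = config$min_group_freq))
  ambiguity <- stage("ambiguity", ambiguity_report(
    groups, level = config$taxonomy_level))

  inputs <- c(config$reference_fasta, config$taxonomy, config$primers,
              config$fastq, config$fastq2)
  manifest <- list(
    tool = "smurf16S", version = as.character(utils::packageVersion("smurf16S")),
    config = unclass(config),
    input_checksums = as.list(tools::md5sum(inputs[!vapply(inputs, is.null,
                                                           logical(1))])),
    stages = list(
      reference = nrow(ref),
      kmer_rows = nrow(db$kmer_rows),
      reads = as.list(reads$stats),
      candidates = length(fit$taxon),
      supported = sum(fit$x > 0),
      groups = nrow(groups),
      reported = nrow(report)
    ),
    em = list(iterations = fit$iterations, converged = fit$converged,
              loglik = fit$loglik[length(fit$loglik)]),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_kmer_db(db, file.path(config$out_dir, "db"))
    wtsv <- function(d, f) utils::write.table(
      d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wtsv(profile_table(fit), "profile.tsv")
    wtsv(as.data.frame(groups), "groups.tsv")
    wtsv(report, "report.tsv")
    wtsv(ambiguity, "ambiguity.tsv")
    utils::write.table(
      data.frame(iteration = seq_along(fit$loglik), loglik = fit$loglik),
      file.path(config$out_dir, "loglik_trace.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    # manifest written last, atomically: its presence marks a finished run
    tmp <- file.path(config$out_dir, ".manifest.json.tmp")
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    file.rename(tmp, file.path(config$out_dir, "manifest.json"))
  }
  structure(list(fit = fit, groups = groups, report = report,
                 ambiguity = ambiguity, manifest = manifest),
            class = "smurf_run")
}

#' @export
print.smurf_run <- function(x, ...) {
  cat("smurf_run: ", x$manifest$stages$reads$retained, " reads -> ",
      x$manifest$stages$supported, " supported taxa -> ",
      nrow(x$report), " reported entries\n", sep = "")
  print(x$report)
  invisible(x)
}
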