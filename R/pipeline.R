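#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML file (or an equivalent list) with exactly one
#' of `synthetic:` (a block of [synthetic_config()] fields) or `inputs:`
#' (paths `births` and `lab_records` to delimited tables). Optional blocks:
#' `catalogue` (path to a pattern file), `window` (`before_days`,
#' `after_days`), `inclusion_threshold`, `period_bins` (`start`, `end`
#' vectors), `validation` (`n_pos`, `n_neg`, `seed`), `prophylaxis_scope`,
#' `seed` and `outdir`.
#'
#' @param config Path to a YAML file or a list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("`config` must be a YAML path or a list", class = "rbcscreen_config_error")
  }
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp) {
    abort("config must contain exactly one of `synthetic` or `inputs`",
          class = "rbcscreen_config_error")
  }
  if (has_inp) {
    for (f in c("births", "lab_records")) {
      if (is.null(config$inputs[[f]])) {
        abort(sprintf("config field `inputs$%s` is required", f),
              class = "rbcscreen_config_error")
      }
    }
  }
  tau <- config$inclusion_threshold %||% 0.8
  if (!is.numeric(tau) || tau <= 0 || tau > 1) {
    abort("config field `inclusion_threshold` must be in (0, 1]",
          class = "rbcscreen_config_error")
  }
  win <- config$window %||% list()
  before <- win$before_days %||% 270
  after <- win$after_days %||% 14
  if (before < 0 || after < 0) {
    abort("config fields `window$before_days`/`after_days` must be non-negative",
          class = "rbcscreen_config_error")
  }
  pb <- config$period_bins
  bins <- if (is.null(pb)) default_period_bins() else period_bins(pb$start, pb$end)
  val <- config$validation %||% list()
  structure(list(
    synthetic = config$synthetic, inputs = config$inputs,
    catalogue = config$catalogue,
    window_before = before, window_after = after,
    inclusion_threshold = tau, bins = bins,
    validation = list(n_pos = val$n_pos %||% 100, n_neg = val$n_neg %||% 100,
                      seed = val$seed %||% (config$seed %||% 1L)),
    prophylaxis_scope = config$prophylaxis_scope %||% "pregnancy",
    seed = config$seed %||% 1L,
    outdir = config$outdir %||% "rbcscreen-output"
  ), class = "pipeline_config")
}

#' Run the full database-construction pipeline
#'
#' Orchestrates generation (or loading) of the registry tables, cleaning,
#' linkage within the pregnancy window, antibody extraction and
#' classification, coverage assessment with the sustained-coverage
#' inclusion rule, prevalence tabulation and (when ground truth is
#' available) chart-review-style validation. All outputs are written as
#' UTF-8 CSV files plus a JSON manifest; identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config A path to a YAML configuration, a list, or a
#'   `pipeline_config` (see [read_pipeline_config()]).
#' @param outdir Output directory (overrides the config); created if
#'   needed.
#' @param quiet Suppress stage progress messages.
#' @return The manifest, invisibly: a list with the configuration hash,
#'   seed, per-stage row counts and output file names.
#' @export
#' @examples
#' \donttest{
#' cfg <- system.file("extdata", "demo_config.yaml", package = "rbcscreen")
#' manifest <- run_pipeline(cfg, outdir = tempfile())
#' }
run_pipeline <- function(config, outdir = NULL, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- read_pipeline_config(config)
  outdir <- outdir %||% config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  files <- character(0)
  counts <- list()
  emit <- function(data, name) {
    drop <- vapply(data, is.list, logical(1))
    path <- file.path(outdir, paste0(name, ".csv"))
    write.csv(data[, !drop, drop = FALSE], path, row.names = FALSE,
              fileEncoding = "UTF-8")
    files <<- c(files, basename(path))
    invisible(path)
  }

  catalogue <- if (is.null(config$catalogue)) default_catalogue() else
    compile_catalogue(config$catalogue)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    syn_args <- config$synthetic
    syn_args$rng_seed <- syn_args$rng_seed %||% config$seed
    if (!is.null(syn_args$counties)) {
      syn_args$counties <- as_tibble(as.data.frame(
        lapply(syn_args$counties, unlist)))
    }
    if (!is.null(syn_args$antibody_probs)) {
      syn_args$antibody_probs <- unlist(syn_args$antibody_probs)
    }
    syn_args$catalogue <- catalogue
    scfg <- do.call(synthetic_config, syn_args)
    say("generate: %d mothers, years %d-%d", scfg$n_mothers,
        scfg$years[1], scfg$years[2])
    reg <- generate_population(scfg)
    raw_births <- reg$births
    raw_labs <- reg$lab_records
    truth <- reg$truth
    emit(raw_births, "births")
    emit(raw_labs, "lab_records")
    emit(reg$truth, "ground_truth")
  } else {
    raw_births <- as_tibble(read.csv(config$inputs$births,
                                     stringsAsFactors = FALSE))
    raw_labs <- as_tibble(read.csv(config$inputs$lab_records,
                                   stringsAsFactors = FALSE))
  }
  counts$raw_births <- nrow(raw_births)
  counts$raw_lab_records <- nrow(raw_labs)

  births <- clean_births(raw_births)
  labs <- clean_labs(raw_labs)
  log <- dplyr::bind_rows(
    dplyr::mutate(rejection_log(births), table = "births"),
    dplyr::mutate(rejection_log(labs), table = "lab_records")
  )
  emit(log, "rejection_log")
  counts$clean_births <- nrow(births)
  counts$clean_lab_records <- nrow(labs)
  say("clean: %d births, %d lab records (%d rejections)",
      nrow(births), nrow(labs), sum(log$n))

  linked <- link_records(births, labs, config$window_before,
                         config$window_after)
  emit(linked[, c("birth_id", "record_id", "sample_date")], "linked_records")
  counts$linked_pairs <- nrow(linked)

  profiles <- classify_births(births, linked, catalogue,
                              prophylaxis_scope = config$prophylaxis_scope)
  emit(mentions(profiles), "mentions")
  emit(profiles, "profiles")
  counts$antibody_positive_births <- sum(profiles$any_antibody)
  say("classify: %d antibody-positive births", counts$antibody_positive_births)

  births <- flag_screening(births, linked)
  cells <- coverage_table(births, complete = TRUE)
  emit(cells, "coverage")
  study_end <- max(cells$year)
  inclusion <- sustained_inclusion(cells, config$inclusion_threshold, study_end)
  emit(inclusion, "inclusion")
  study <- apply_inclusion(births, inclusion)
  counts$study_population <- nrow(study)
  say("include: %d of %d births in the study population",
      nrow(study), nrow(births))

  study_profiles <- profiles[match(study$birth_id, profiles$birth_id), ]
  prev <- tabulate_prevalence(study_profiles, study, config$bins, catalogue)
  emit(dplyr::filter(prev, .data$panel == "main"), "prevalence_main")
  emit(dplyr::filter(prev, .data$panel == "rare"), "prevalence_rare")
  emit(combination_counts(study_profiles), "combinations")
  emit(characteristics_table(study, config$bins), "characteristics")
  emit(yearly_prevalence(study_profiles, study), "yearly_prevalence")

  if (!is.null(truth)) {
    v <- config$validation
    enough <- sum(study_profiles$any_antibody) >= v$n_pos &&
      sum(!study_profiles$any_antibody & study_profiles$has_screening) >= v$n_neg
    if (enough) {
      report <- validate_extraction(study_profiles, truth,
                                    n_pos = v$n_pos, n_neg = v$n_neg,
                                    seed = v$seed)
      emit(tidy(report), "validation_report")
      emit(report$sample, "validation_sample")
      counts$validation_sample <- nrow(report$sample)
    } else {
      say("validate: skipped (insufficient stratum sizes)")
    }
  }

  manifest <- list(
    package = "rbcscreen",
    config_hash = rlang::hash(config),
    seed = config$seed,
    counts = counts,
    files = files
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: %d output files in %s", length(files) + 1L, outdir)
  invisible(manifest)
}
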