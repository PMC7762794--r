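#' Read and validate a pipeline run configuration
#'
#' A run configuration is a YAML (or JSON) file with blocks:
#' \describe{
#'   \item{`community:`}{list of taxa (`taxon_id`, `abundance`, `viability`,
#'     optional `lineage`, `group_label`), required when simulating;}
#'   \item{`design:`}{arguments for [htc_design()];}
#'   \item{`thresholds:`}{`min_reads`, `dominant`, `majority`, `minor`,
#'     `alpha` (defaults 20, 0.90, 0.50, 0.05, 0.05);}
#'   \item{`stages:`}{logical toggles `simulate`, `curate`, `classify`,
#'     `culturability`, `compare` (all default on);}
#'   \item{`inputs:`}{paths `counts`, `metadata`, `taxonomy`, `env_counts`
#'     used when `simulate` is off;}
#'   \item{plus `seed`, `experiment`, `isolate_prefix`, `n_controls`.}
#' }
#'
#' @param path path to the YAML/JSON configuration file.
#' @return a validated config list with defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  validate_run_config(yaml::read_yaml(path))
}

validate_run_config <- function(config) {
  th <- config$thresholds %||% list()
  th <- utils::modifyList(
    list(min_reads = 20, dominant = 0.90, majority = 0.50, minor = 0.05,
         alpha = 0.05), th)
  check_thresholds(th$minor, th$majority, th$dominant)
  if (th$min_reads < 1) abort("min_reads must be >= 1")
  config$thresholds <- th
  stages <- config$stages %||% list()
  config$stages <- utils::modifyList(
    list(simulate = TRUE, curate = TRUE, classify = TRUE,
         culturability = TRUE, compare = TRUE), stages)
  config$seed <- config$seed %||% 1L
  config$experiment <- config$experiment %||% "sim1"
  config$isolate_prefix <- config$isolate_prefix %||% "HIMB"
  config$n_controls <- config$n_controls %||% 0L
  config
}

#' Run the dilution-to-extinction analysis pipeline end to end
#'
#' Executes the enabled stages in order -- simulate, curate, classify,
#' culturability, compare -- and writes their tabular outputs plus a
#' `run_manifest.json` (package version, seed, thresholds, per-output row
#' counts and checksums) into `out_dir`. Outputs are staged in a temporary
#' directory and committed only if every enabled stage succeeds, so a failed
#' run leaves no partial outputs. Reruns with the same configuration and
#' seed are byte-identical.
#'
#' @param config a config list (see [read_run_config()]) or the path to a
#'   config file.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @param seed overrides `config$seed` if given.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) abort("an output directory is required")
  seed <- as.integer(seed %||% config$seed)
  th <- config$thresholds
  stages <- config$stages
  stage_dir <- tempfile("htculture_stage_")
  dir.create(stage_dir, recursive = TRUE)
  on.exit(unlink(stage_dir, recursive = TRUE), add = TRUE)
  artifacts <- character(0)
  emit <- function(tbl, name) {
    path <- file.path(stage_dir, name)
    readr::write_tsv(tbl, path, progress = FALSE)
    artifacts <<- c(artifacts, name)
    invisible(tbl)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  counts <- metadata <- taxonomy <- env_counts <- NULL
  if (isTRUE(stages$simulate)) {
    run_stage("simulate", {
      community <- community_profile(dplyr::bind_rows(config$community))
      design <- do.call(htc_design, config$design)
      sim <- simulate_experiment(community, design, seed = seed,
                                 experiment = config$experiment,
                                 n_controls = config$n_controls)
      counts <- sim$counts; metadata <- sim$metadata
      taxonomy <- sim$taxonomy; env_counts <- sim$env
      emit(sim$wells, "wells_truth.tsv")
      emit(counts, "culture_counts.tsv")
      emit(env_counts, "env_counts.tsv")
      emit(metadata, "sample_metadata.tsv")
      emit(taxonomy, "taxonomy.tsv")
    })
  } else {
    run_stage("load_inputs", {
      inp <- config$inputs %||% abort("inputs block required when simulate is off")
      counts <- read_count_table(inp$counts, inp$metadata)
      metadata <- sample_metadata(counts)
      if (!is.null(inp$taxonomy)) taxonomy <- read_taxonomy(inp$taxonomy)
      if (!is.null(inp$env_counts)) {
        env_counts <- read_count_table(inp$env_counts, inp$metadata)
      }
    })
  }

  curated <- props <- env_props <- NULL
  if (isTRUE(stages$curate)) {
    run_stage("curate", {
      cult_ids <- if (is.null(metadata)) counts$sample_id else
        metadata$sample_id[metadata$role %in% c("culture", "control")]
      cult <- counts[counts$sample_id %in% cult_ids, , drop = FALSE]
      attr(cult, "metadata") <- metadata
      curated <- curate_culture_counts(cult, min_reads = th$min_reads)
      props <- relative_abundance(curated)
      emit(curated, "curated_counts.tsv")
      if (!is.null(env_counts) && !is.null(taxonomy)) {
        env_cur <- curate_environment(env_counts, taxonomy,
                                      min_reads = th$min_reads)
        env_props <- relative_abundance(env_cur)
        emit(env_cur, "env_curated_counts.tsv")
      }
    })
  }

  calls <- isolates <- NULL
  if (isTRUE(stages$classify)) {
    run_stage("classify", {
      if (is.null(curated)) abort("classify requires the curate stage")
      calls <- classify_cultures(curated, metadata,
                                 dominant = th$dominant,
                                 majority = th$majority,
                                 minor = th$minor)
      isolates <- assign_isolate_ids(calls, prefix = config$isolate_prefix)
      emit(flatten_calls(calls), "culture_calls.tsv")
      emit(category_tally(calls), "category_tally.tsv")
      emit(isolates, "isolates.tsv")
    })
  }

  estimates <- NULL
  if (isTRUE(stages$culturability)) {
    run_stage("culturability", {
      if (is.null(calls)) abort("culturability requires the classify stage")
      n_wells <- config$n_inoculated %||%
        sum(metadata$role == "culture", na.rm = TRUE)
      X <- config$design$cells_per_well %||%
        unique(metadata$cells_per_well[metadata$role == "culture"])[1]
      estimates <- experiment_summary(calls, n_wells = n_wells, X = X,
                                      alpha = th$alpha)
      emit(tidy(estimates), "culturability.tsv")
    })
  }

  if (isTRUE(stages$compare)) {
    run_stage("compare", {
      if (is.null(isolates) || is.null(taxonomy)) {
        abort("compare requires the classify stage and a taxonomy")
      }
      if (!is.null(env_props)) {
        env_long <- normalise_env_proportions(env_props)
        sets <- c(list(environment = env_long$asv_id[env_long$proportion > 0]),
                  split(isolates$asv_id, isolates$experiment))
        if (length(sets) >= 2) {
          venn <- venn_membership(sets)
          emit(tibble(region = venn$region, n = venn$n,
                      asv_ids = vapply(venn$asv_ids, paste,
                                       character(1), collapse = ";")),
               "venn_regions.tsv")
        }
      }
      emit(group_summary(isolates, taxonomy, env_props), "group_summary.tsv")
      mixed <- calls[calls$category == "mixed", , drop = FALSE]
      emit(cooccurrence(mixed), "cooccurrence.tsv")
    })
  }

  manifest <- list(
    package = "htculture",
    version = as.character(utils::packageVersion("htculture")),
    seed = seed,
    experiment = config$experiment,
    thresholds = th,
    stages = stages,
    outputs = lapply(setNames(artifacts, artifacts), function(f) {
      list(rows = length(readr::read_lines(file.path(stage_dir, f),
                                           progress = FALSE)) - 1L,
           md5 = unname(tools::md5sum(file.path(stage_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(stage_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  artifacts <- c(artifacts, "run_manifest.json")

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(file.path(stage_dir, artifacts), out_dir, overwrite = TRUE)
  if (!all(ok)) abort("failed to commit pipeline outputs")
  invisible(manifest)
}

# Serialise the members list-column for TSV output.
flatten_calls <- function(calls) {
  calls %>%
    mutate(members = vapply(.data$members, function(m) {
      paste(sprintf("%s:%.6f", m$asv_id, m$proportion), collapse = ";")
    }, character(1)))
}
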