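# End-to-end orchestration: synthesize -> behavior -> integrate -> couple ->
# brainblood, from a single YAML config, with a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    out_dir = "olfnet_run",
    seed = 1L,
    stages = c("synth", "behavior", "integrate", "couple", "brainblood"),
    data_dir = NULL,          # existing fixture bundle; NULL = synthesize
    gmt = NULL,               # optional gene-set file for enrichment
    n_subjects = 465L,
    use_table1_preset = TRUE,
    n_regions = 64L,          # connectome parcellation for synthetic runs
    alpha = 0.5,              # Elastic Net mixing weight
    n_folds = 10L,            # CV folds
    boot = 1000L,             # bootstrap iterations for the sumcor CI
    perm = 1000L,             # permutations for the sumcor p-value
    weight_threshold = 0.05,  # subnetwork weight cutoff
    k_blood = 10L,            # blood eigengenes
    k_region = 4L,            # per-brain-region PCs
    fdr_level = 0.05)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML key-value file (or takes a list), fills defaults, and
#' rejects unknown keys and out-of-domain values with an error naming the
#' first violation.
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return the fully resolved configuration list (class `olfnet_config`).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_config("config file not found: ", config)
    config <- yaml::read_yaml(config) %||% list()
  }
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_config("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  ok_stages <- pipeline_defaults()$stages
  bad <- setdiff(cfg$stages, ok_stages)
  if (length(bad))
    stop_config("unknown stage(s): ", paste(bad, collapse = ", "))
  if (cfg$alpha < 0 || cfg$alpha > 1)
    stop_config("alpha must lie in [0, 1], got ", cfg$alpha)
  if (cfg$weight_threshold < 0)
    stop_config("weight_threshold must be nonnegative")
  if (cfg$fdr_level <= 0 || cfg$fdr_level >= 1)
    stop_config("fdr_level must lie in (0, 1)")
  for (nm in c("n_folds", "boot", "perm", "k_blood", "k_region",
               "n_subjects", "n_regions", "seed"))
    cfg[[nm]] <- as.integer(cfg[[nm]])
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
    stop_config("gmt file not found: ", cfg$gmt)
  if (!is.null(cfg$data_dir) && !dir.exists(cfg$data_dir))
    stop_config("data_dir not found: ", cfg$data_dir)
  class(cfg) <- c("olfnet_config", "list")
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on a fixture bundle
#' (synthesized under `out_dir/data` unless `data_dir` points at an
#' existing bundle) and writes a JSON manifest with parameters, seeds,
#' stage timings and output checksums. Identical config and seed reproduce
#' identical checksums.
#'
#' @param config an [validate_config()] result, a path, or a list.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "olfnet_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  outputs <- character(0)
  timed <- function(stage, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e) {
      stop_data("stage '", stage, "' failed: ", conditionMessage(e),
                "; outputs so far: ",
                paste(basename(outputs), collapse = ", "))
    })
    log[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  emit <- function(path) {
    outputs <<- c(outputs, path)
    path
  }

  data_dir <- cfg$data_dir
  spec <- simulation_spec(
    n_subjects = cfg$n_subjects,
    cell_counts = if (cfg$use_table1_preset) table1_cell_counts() else NULL,
    n_regions = cfg$n_regions, seed = cfg$seed)
  if ("synth" %in% cfg$stages && is.null(data_dir)) {
    data_dir <- file.path(cfg$out_dir, "data")
    timed("synth", write_fixture_bundle(data_dir, spec))
  }
  if (is.null(data_dir))
    stop_config("no data_dir and synth stage disabled")

  traits <- read.csv(file.path(data_dir, "traits.csv"),
                     stringsAsFactors = TRUE)
  traits$subject_id <- as.character(traits$subject_id)
  traits$age_group <- factor(traits$age_group)

  behavior_summary <- NULL
  if (any(c("behavior", "integrate") %in% cfg$stages)) {
    trials <- read.csv(file.path(data_dir, "behavior_trials.csv"))
    behavior_summary <- summarize_behavior(trials)
  }
  if ("behavior" %in% cfg$stages) {
    timed("behavior", {
      write.csv(behavior_summary,
                emit(file.path(cfg$out_dir, "behavior_summary.csv")),
                row.names = FALSE)
      merged <- merge(behavior_summary, traits,
                      by.x = "subject", by.y = "subject_id")
      eff <- lapply(c("anhedonia", "auc_norm", "ri_24h"), function(oc) {
        tab <- factorial_anova(merged[[oc]], merged,
                               terms = c("apoe", "diet", "age_group",
                                         "nos2", "sex"),
                               max_order = 2)
        cbind(outcome = oc, tab)
      })
      write.csv(do.call(rbind, eff),
                emit(file.path(cfg$out_dir, "behavior_effect_sizes.csv")),
                row.names = FALSE)
    })
  }

  if ("integrate" %in% cfg$stages) {
    timed("integrate", {
      conn_files <- sort(list.files(data_dir, "^connectome_.*\\.tsv$",
                                    full.names = TRUE))
      conns <- lapply(conn_files, read_connectome)
      names(conns) <- sub("^connectome_(.*)\\.tsv$", "\\1",
                          basename(conn_files))
      res <- integrate_domains(conns, behavior_summary, traits,
                               alpha = cfg$alpha, n_folds = cfg$n_folds,
                               threshold = cfg$weight_threshold,
                               seed = cfg$seed)
      rs <- resample_sumcor(res$domains, B = cfg$boot, P = cfg$perm,
                            seed = cfg$seed)
      write.csv(res$subnetwork$retained_edges,
                emit(file.path(cfg$out_dir, "subnetwork_edges.csv")),
                row.names = FALSE)
      jsonlite::write_json(
        as.list(res$subnetwork$stage_counts),
        emit(file.path(cfg$out_dir, "stage_counts.json")),
        auto_unbox = TRUE)
      jsonlite::write_json(
        list(sumcor = rs$sumcor_observed,
             ci95 = unname(rs$ci95), permutation_p = rs$permutation_p,
             B = cfg$boot, P = cfg$perm),
        emit(file.path(cfg$out_dir, "resampling.json")),
        auto_unbox = TRUE, digits = NA)
    })
  }

  blood_es <- NULL
  if (any(c("couple", "brainblood") %in% cfg$stages)) {
    blood <- read_expression(file.path(data_dir, "expr_blood.tsv"))
    blood_es <- compute_eigengenes(normalize_expression(blood),
                                   K = cfg$k_blood, tissue = "blood")
  }
  if ("couple" %in% cfg$stages) {
    timed("couple", {
      imaging <- read.csv(file.path(data_dir, "imaging.csv"))
      grid <- coupling_grid(imaging, blood_es$scores,
                            regions = olf_regions,
                            metrics = coupling_metrics,
                            fdr_level = cfg$fdr_level)
      write.csv(grid, emit(file.path(cfg$out_dir, "coupling_grid.csv")),
                row.names = FALSE)
      write.csv(top_regions_per_pair(grid),
                emit(file.path(cfg$out_dir, "coupling_top_regions.csv")),
                row.names = FALSE)
    })
  }

  if ("brainblood" %in% cfg$stages) {
    timed("brainblood", {
      expr_files <- sort(list.files(data_dir, "^expr_.*\\.tsv$",
                                    full.names = TRUE))
      tissues <- sub("^expr_(.*)\\.tsv$", "\\1", basename(expr_files))
      sets <- list()
      for (i in seq_along(tissues)) {
        k <- if (tissues[i] == "blood") cfg$k_blood else cfg$k_region
        mat <- read_expression(expr_files[i])
        sets[[tissues[i]]] <- compute_eigengenes(
          normalize_expression(mat), K = min(k, ncol(mat) - 1),
          tissue = tissues[i])
      }
      records <- pc_pair_correlations(sets, top_k = cfg$k_region,
                                      fdr_level = cfg$fdr_level)
      collection <- if (!is.null(cfg$gmt)) read_gmt(cfg$gmt) else NULL
      files <- coupling_report(records, sets, collection,
                               file.path(cfg$out_dir, "brainblood"))
      for (f in files) emit(f)
    })
  }

  manifest <- list(
    config = unclass(cfg),
    stage_seconds = log,
    outputs = lapply(sort(outputs), function(f)
      list(path = sub(paste0("^", cfg$out_dir, "/?"), "", f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
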