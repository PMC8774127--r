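# Orchestration: one reproducible run of simulate -> coupling -> PLS ->
# regression, driven by a YAML/JSON config, with stage artifacts written
# to disk and a manifest capturing parameters and seeds.

pipeline_defaults <- list(
  n_perm = 10000, n_boot = 1000, bsr_threshold = 2.58,
  split = "subject", normalize = "per_tr", family = "per_metric")

#' Validate and resolve a pipeline configuration
#'
#' Reads a YAML (or JSON) config, rejects unknown keys, applies documented
#' defaults (10000 permutations, 1000 bootstrap iterations, BSR threshold
#' 2.58, subject-wise energy split, per-TR normalization, per-metric FDR
#' family) and returns a fully-resolved config.  Either a `simulate`
#' block (fields of [simulation_config()]) or a `data` block (paths to a
#' directory written by [write_cohort()]) must be present, plus a
#' mandatory integer `seed`.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#' @return resolved config list of class `"run_config"`; defaulted keys
#'   are recorded in attribute `"defaulted"`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  known <- c(names(pipeline_defaults), "seed", "simulate", "data", "out")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(config$seed))
    stop("config must set `seed`", call. = FALSE)
  if (!is.numeric(config$seed) || config$seed != round(config$seed))
    stop("`seed` must be an integer", call. = FALSE)
  defaulted <- character()
  for (key in names(pipeline_defaults)) {
    if (is.null(config[[key]])) {
      config[[key]] <- pipeline_defaults[[key]]
      defaulted <- c(defaulted, key)
    }
  }
  if (config$n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (config$n_boot < 2) stop("n_boot must be >= 2", call. = FALSE)
  if (!config$split %in% c("subject", "group_mean"))
    stop("split must be 'subject' or 'group_mean'", call. = FALSE)
  if (!config$normalize %in% c("per_tr", "none"))
    stop("normalize must be 'per_tr' or 'none'", call. = FALSE)
  if (!config$family %in% c("per_metric", "joint"))
    stop("family must be 'per_metric' or 'joint'", call. = FALSE)
  if (is.null(config$simulate) && is.null(config$data))
    stop("config needs a `simulate` block or a `data` directory",
         call. = FALSE)
  if (!is.null(config$data) && !dir.exists(config$data))
    stop("data directory not found: ", config$data, call. = FALSE)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(sim_args$effect))
      sim_args$effect <- do.call(planted_effect, sim_args$effect)
    sim_args$seed <- sim_args$seed %||% config$seed
    config$simulate <- do.call(simulation_config, sim_args)
  }
  structure(config, class = "run_config", defaulted = defaulted)
}

load_cohort_dir <- function(dir) {
  labels <- file.path(dir, "labels.tsv")
  subjects <- read_subjects(file.path(dir, "subjects.tsv"))
  network_of <- read_labels(labels)
  connectomes <- list(); bolds <- list()
  for (id in subjects$subject_id) {
    connectomes[[id]] <- read_connectome(
      file.path(dir, paste0(id, "_connectome.tsv")), labels)
    bolds[[id]] <- read_timeseries(file.path(dir, paste0(id, "_bold.tsv")))
  }
  list(subjects = subjects, connectomes = connectomes, bolds = bolds,
       network_of = network_of)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), per-subject
#' structure-function decomposition, behavior PLS with permutation and
#' bootstrap inference, mass-univariate quadratic age regression, and
#' cohort statistics.  All stage outputs are written under `out` as the
#' standard file set plus a JSON manifest; re-running with the same config
#' reproduces every number (all stochastic stages are seeded from the
#' config seed).
#'
#' @param config a path, list, or resolved [validate_config()] output.
#' @param out output directory (overrides `config$out`).
#' @return a `run_report` list: `lv_table`, `network_summary`,
#'   `regression_min_q`, `cohort_stats`, `motion`, `pls`, `regression`,
#'   `timing_s`, `warnings`, and `files` written.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  out <- out %||% config$out %||% stop("no output directory configured",
                                       call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  warn_log <- character()
  note <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  timing <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timing[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    val
  }

  cohort <- tick("cohort", {
    if (!is.null(config$simulate)) {
      ch <- generate_cohort(config$simulate)
      write_cohort(ch, file.path(out, "cohort"))
      ch
    } else load_cohort_dir(config$data)
  })

  profiles <- tick("coupling", note(
    cohort_coupling(cohort$connectomes, cohort$bolds,
                    split = config$split, normalize = config$normalize)))
  prof_tab <- do.call(rbind, lapply(names(profiles), function(id)
    data.frame(subject_id = id,
               node_id = names(profiles[[id]]$s_c),
               network = cohort$network_of[names(profiles[[id]]$s_c)],
               s_c = profiles[[id]]$s_c, s_d = profiles[[id]]$s_d,
               sdi = profiles[[id]]$s_d / profiles[[id]]$s_c,
               row.names = NULL)))
  utils::write.table(prof_tab, file.path(out, "coupling_profiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  pls <- tick("pls", note(
    pls_brain_age(profiles, cohort$subjects, cohort$network_of,
                  n_perm = config$n_perm, n_boot = config$n_boot,
                  bsr_threshold = config$bsr_threshold,
                  seed = config$seed)))
  reg <- tick("regression", note(
    run_mass_univariate(pls$stack, family = config$family)))
  stats <- tick("cohort_stats", note(
    if (length(unique(cohort$subjects$group)) == 2)
      cohort_stats(cohort$subjects) else NULL))

  manifest <- list(
    seed = config$seed,
    n_perm = config$n_perm, n_boot = config$n_boot,
    bsr_threshold = config$bsr_threshold,
    split = config$split, normalize = config$normalize,
    family = config$family,
    simulated = !is.null(config$simulate),
    warnings = unique(warn_log))
  files <- tick("write", write_results(pls, reg, out, manifest = manifest))

  lv_table <- data.frame(
    lv = seq_along(pls$singular_values),
    singular_value = pls$singular_values,
    perm_p = pls$perm_p)
  structure(
    list(lv_table = lv_table,
         network_summary = pls$network_summary,
         regression_min_q = attr(reg, "min_q"),
         cohort_stats = stats,
         motion = pls$motion,
         pls = pls, regression = reg,
         timing_s = timing,
         warnings = unique(warn_log),
         files = c(file.path(out, "coupling_profiles.tsv"), files)),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run:", length(x$lv_table$lv), "latent variables\n")
  print(x$lv_table, row.names = FALSE)
  cat("min FDR-adjusted quadratic-age q per metric:\n")
  print(x$regression_min_q)
  if (length(x$warnings))
    cat(length(x$warnings), "distinct warning(s) during run\n")
  invisible(x)
}
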