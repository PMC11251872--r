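#' Pipeline run configuration
#'
#' Collects the analysis parameters with their standard defaults: 50/5 TR
#' windows, sparsity 0.2, 0.15 mm FD censoring, 0.01--0.10 Hz band, 0.7 mm
#' FWHM, alpha 0.05, Davies-Bouldin selection over k = 2..8.
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param input_dir directory of an existing simulated study (default: the
#'   simulate stage writes into `out_dir/data`).
#' @param stages which stages to run, in dependency order.
#' @param width,step sliding-window parameters (TR units).
#' @param sparsity graph sparsity threshold.
#' @param k_range,k_fixed state-count selection.
#' @param n_init k-means restarts.
#' @param alpha significance level.
#' @param cleaning a [cleaning_config()].
#' @param generator a [generator_config()] (default: small two-condition
#'   study at the standard scan length, so a full run stays desk-scale).
#' @param voxel_conditions conditions for the voxel stage (default awake +
#'   ISO, one subject each).
#' @param path optional YAML or JSON file whose top-level keys override the
#'   above.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 42, out_dir = "dynfc_out", input_dir = NULL,
                       stages = c("simulate", "preprocess", "static_fc",
                                  "dynamic_fc", "graph", "voxel"),
                       width = 50, step = 5, sparsity = 0.2,
                       k_range = 2:8, k_fixed = NULL, n_init = 50,
                       alpha = 0.05,
                       cleaning = cleaning_config(),
                       generator = NULL,
                       voxel_conditions = c("awake", "ISO"),
                       path = NULL) {
  cfg <- list(seed = seed, out_dir = out_dir, input_dir = input_dir,
              stages = stages, width = width, step = step,
              sparsity = sparsity, k_range = k_range, k_fixed = k_fixed,
              n_init = n_init, alpha = alpha, cleaning = cleaning,
              generator = generator, voxel_conditions = voxel_conditions)
  if (!is.null(path)) {
    over <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
            else jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in names(over)) cfg[[k]] <- over[[k]]
  }
  if (is.null(cfg$generator)) {
    cfg$generator <- generator_config(
      seed = cfg$seed, groups = c("awake", "PRO", "ISO"),
      n_subjects_per_group = c(awake = 6, PRO = 6, ISO = 6))
  }
  structure(cfg, class = "run_config")
}

.provenance <- function(dir, stage, params, seed, inputs = character(0)) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  jsonlite::write_json(
    list(stage = stage, parameters = params, seed = seed,
         input_hashes = hashes),
    file.path(dir, paste0(stage, "_provenance.json")),
    auto_unbox = TRUE, digits = NA, force = TRUE)
}

#' Validate a study directory
#'
#' Checks that the design parses, per-subject files exist and are readable,
#' ROI columns match the expected region set, and motion tables align with
#' the series. Always returns a report; `fatal` findings make downstream
#' stages refuse to run.
#'
#' @param dir study directory.
#' @param rois expected `roi_set`.
#' @return Data frame of findings with columns `level` (`"warning"` /
#'   `"fatal"`), `subject`, `message`; zero rows means a clean bill.
#' @export
validate_inputs <- function(dir, rois = default_roi_set()) {
  findings <- list()
  add <- function(level, subject, message) {
    findings[[length(findings) + 1]] <<- data.frame(
      level = level, subject = subject, message = message,
      stringsAsFactors = FALSE)
  }
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(design_path)) {
    add("fatal", NA, "design.csv missing")
  } else {
    design <- tryCatch(read_design(design_path), error = function(e) NULL)
    if (is.null(design) ||
        !all(c("subject_id", "group") %in% names(design))) {
      add("fatal", NA, "design.csv unreadable or missing columns")
    } else {
      for (i in seq_len(nrow(design))) {
        id <- design$subject_id[i]
        bp <- file.path(dir, paste0(id, "_bold.tsv"))
        mp <- file.path(dir, paste0(id, "_motion.txt"))
        if (!file.exists(bp)) { add("fatal", id, "bold series missing"); next }
        series <- tryCatch(read_roi_tsv(bp), error = function(e) NULL)
        if (is.null(series)) { add("fatal", id, "bold series unreadable"); next }
        missing_rois <- setdiff(rois$names, colnames(series))
        if (length(missing_rois)) {
          add("fatal", id, sprintf("missing ROI column(s): %s",
                                   paste(missing_rois, collapse = ", ")))
        }
        if (!file.exists(mp)) {
          add("fatal", id, "motion table missing")
        } else {
          motion <- tryCatch(read_motion(mp), error = function(e) NULL)
          if (is.null(motion)) {
            add("fatal", id, "motion table unreadable")
          } else if (nrow(motion) != nrow(series)) {
            add("fatal", id,
                sprintf("motion rows (%d) do not match series rows (%d)",
                        nrow(motion), nrow(series)))
          }
        }
      }
    }
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(0), subject = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order on a simulated (or
#' previously written) study, writing artifacts and provenance sidecars
#' under `out_dir` and returning an aggregated report. Rerunning with
#' unchanged inputs and the same configuration is a no-op unless
#' `force = TRUE`.
#'
#' @param config a [run_config()].
#' @param force rerun even if an identical completed run exists.
#' @return A `pipeline_report` list with one entry per executed stage.
#' @export
run_pipeline <- function(config = run_config(), force = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report_path <- file.path(config$out_dir, "report.json")
  cfg_digest <- paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n")
  if (!force && file.exists(report_path)) {
    prev <- tryCatch(jsonlite::read_json(report_path),
                     error = function(e) NULL)
    if (!is.null(prev) && identical(prev$config_digest,
                                    digest_string(cfg_digest))) {
      message("identical completed run found; use force = TRUE to rerun")
      return(invisible(structure(prev, class = "pipeline_report")))
    }
  }
  report <- list(config_digest = digest_string(cfg_digest), stages = list())
  rois <- default_roi_set()
  stages <- config$stages
  data_dir <- if (!is.null(config$input_dir)) config$input_dir
              else file.path(config$out_dir, "data")

  if ("simulate" %in% stages) {
    sim <- simulate_roi_timeseries(config$generator, rois)
    write_simulation(sim, data_dir)
    .provenance(config$out_dir, "simulate",
                list(groups = config$generator$groups,
                     T_volumes = config$generator$T_volumes),
                config$seed, file.path(data_dir, "design.csv"))
    report$stages$simulate <- list(
      n_subjects = length(sim$subjects),
      groups = as.list(table(sim$design$group)))
  }
  validation <- validate_inputs(data_dir, rois)
  report$validation <- list(n_fatal = sum(validation$level == "fatal"),
                            n_warning = sum(validation$level == "warning"))
  if (any(validation$level == "fatal")) {
    report$error <- "fatal validation findings; aborting"
    .write_report(report, report_path)
    stop("fatal validation findings in ", data_dir)
  }
  study <- read_simulation(data_dir)
  cleaned <- NULL
  if ("preprocess" %in% stages) {
    cleaned <- lapply(study$subjects, clean_roi_subject,
                      config = config$cleaning)
    names(cleaned) <- study$design$subject_id
    report$stages$preprocess <- list(
      n_subjects = length(cleaned),
      mean_censored = mean(vapply(cleaned, function(s)
        length(s$censored), numeric(1))))
  }
  need_clean <- function(stage) {
    if (is.null(cleaned)) stop("stage '", stage,
                               "' requires the preprocess stage")
    cleaned
  }
  fc <- NULL
  if ("static_fc" %in% stages) {
    cl <- need_clean("static_fc")
    fc <- lapply(cl, function(s) fc_matrix(s$series))
    sim_all <- similarity_analysis(fc, "all", rois, study$design)
    groups <- unique(study$design$group)
    edge_tests <- list()
    if (length(groups) >= 2) {
      base <- fc[study$design$group == groups[1]]
      for (g in groups[-1]) {
        edge_tests[[g]] <- edgewise_group_test(
          base, fc[study$design$group == g], config$alpha, rois = rois)
      }
    }
    report$stages$static_fc <- list(
      n_matrices = length(fc),
      mean_cross_condition_zr = cross_condition_similarity(sim_all),
      significant_edges = lapply(edge_tests, function(t) sum(t$significant)))
  }
  wfc <- NULL
  if ("dynamic_fc" %in% stages) {
    cl <- need_clean("dynamic_fc")
    wfc <- lapply(cl, function(s)
      windowed_fc(s$series, config$width, config$step))
    names(wfc) <- study$design$subject_id
    model <- cluster_states(wfc, study$design, k_range = config$k_range,
                            k_fixed = config$k_fixed, seed = config$seed,
                            n_init = config$n_init, rois = rois)
    stats_rep <- state_statistics(model, study$design, config$alpha)
    utils::write.csv(
      data.frame(subject = model$subject,
                 window = stats::ave(seq_along(model$labels), model$subject,
                                     FUN = seq_along),
                 state = model$labels),
      file.path(config$out_dir, "state_assignments.csv"), row.names = FALSE)
    report$stages$dynamic_fc <- list(
      windows_per_subject = length(wfc[[1]]$windows),
      selected_k = model$k,
      dbi_curve = as.list(model$dbi_curve),
      anova_significant_states = sum(stats_rep$anova$significant))
  }
  if ("graph" %in% stages) {
    if (is.null(wfc)) stop("stage 'graph' requires the dynamic_fc stage")
    trm <- lapply(wfc, time_resolved_metrics, sparsity = config$sparsity)
    mean_eff <- vapply(trm, function(x) mean(x$series$efficiency),
                       numeric(1))
    report$stages$graph <- list(
      sparsity = config$sparsity,
      edges_per_window = sum(binarize_by_sparsity(
        wfc[[1]]$windows[[1]], config$sparsity)) / 2,
      mean_nodal_efficiency = mean(mean_eff))
  }
  if ("voxel" %in% stages) {
    vox <- list()
    for (cond in config$voxel_conditions) {
      scan <- simulate_voxel_scan(config$generator, rois, condition = cond)
      scan <- clean_voxel_scan(scan, config$cleaning)
      wvm <- windowed_indices(scan, config$width, config$step,
                              fwhm = config$cleaning$fwhm)
      conc <- concordance_maps(wvm)
      stab <- stability_map(scan, config$width, config$step)
      vox[[cond]] <- list(
        volumewise_concordance = conc$volumewise,
        mean_voxelwise_concordance = mean(conc$voxelwise, na.rm = TRUE),
        mean_stability = mean(stab$stability, na.rm = TRUE))
    }
    report$stages$voxel <- vox
  }
  .write_report(report, report_path)
  invisible(structure(report, class = "pipeline_report"))
}

.write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
}

#' Stable digest of a string (no external digest dependency)
#'
#' @param s a character scalar.
#' @return md5 hex digest.
#' @export
digest_string <- function(s) {
  tf <- tempfile()
  writeLines(s, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `validate`, `run-all`. Flags: `--config FILE`
#' (YAML/JSON overrides), `--seed INT`, `--out DIR`, `--in DIR`, `--force`.
#' Exit status: 0 ok, 1 warnings, 2 fatal.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: dynfc <simulate|validate|run-all> [--config FILE]",
        "[--seed INT] [--out DIR] [--in DIR] [--force]\n")
    return(invisible(2L))
  }
  cmd <- args[1]
  opt <- list(seed = 42L, out = "dynfc_out", input = NULL, config = NULL,
              force = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--force") { opt$force <- TRUE; i <- i + 1; next }
    val <- args[i + 1]; i <- i + 2
    switch(a,
           "--seed" = { opt$seed <- as.integer(val) },
           "--out" = { opt$out <- val },
           "--in" = { opt$input <- val },
           "--config" = { opt$config <- val },
           { cat("unknown flag:", a, "\n"); return(invisible(2L)) })
  }
  status <- 0L
  if (cmd == "simulate") {
    cfg <- generator_config(seed = opt$seed)
    sim <- simulate_roi_timeseries(cfg)
    write_simulation(sim, opt$out)
    cat(sprintf("wrote %d subjects to %s\n", length(sim$subjects), opt$out))
  } else if (cmd == "validate") {
    dir <- if (!is.null(opt$input)) opt$input else opt$out
    v <- validate_inputs(dir)
    if (nrow(v)) {
      print(v)
      status <- if (any(v$level == "fatal")) 2L else 1L
    } else cat("validation clean\n")
  } else if (cmd == "run-all") {
    cfg <- run_config(seed = opt$seed, out_dir = opt$out,
                      input_dir = opt$input, path = opt$config)
    rep <- run_pipeline(cfg, force = opt$force)
    cat(sprintf("pipeline complete; report at %s\n",
                file.path(opt$out, "report.json")))
  } else {
    cat("unknown subcommand:", cmd, "\n")
    status <- 2L
  }
  invisible(status)
}
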