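pipeline_defaults <- function() {
  list(
    contact_cutoff = 8,
    coordination_cutoff = 4,
    tica_lag = 2,
    tica_dim = 3L,
    n_clusters = NULL,
    msm_lag = NULL,
    lag_scan = NULL,
    n_macrostates = 5L,
    temperature = 298,
    concentration = NULL,
    bootstrap = list(n_runs = 7L, drop_fraction = 0.2),
    seed = 1L,
    write_intermediates = TRUE
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (contact cutoff 8 A, coordination cutoff 4 A, TICA lag
#' 2 ns with 3 components, 5 macrostates, 298 K, 7 bootstrap runs dropping
#' 20%), checks units and positivity, and rejects unknown keys.  The result
#' is idempotent: `validate_config(validate_config(x))` equals
#' `validate_config(x)`.
#'
#' @param config A named list, or a path to a JSON or YAML file with the
#'   same keys.  `n_clusters` and `msm_lag` have no default and must be
#'   supplied before [run_pipeline()] is called.
#' @return A normalized `pipeline_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_config_file(config)
  }
  if (inherits(config, "pipeline_config")) config <- unclass(config)
  if (!is.list(config)) stop_ligandmsm("`config` must be a list or a file path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop_ligandmsm(sprintf("unknown configuration key(s): %s",
                           paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  for (key in c("contact_cutoff", "coordination_cutoff", "tica_lag",
                "temperature")) {
    check_scalar_positive(cfg[[key]], key)
  }
  cfg$tica_dim <- check_count(cfg$tica_dim, "tica_dim")
  cfg$n_macrostates <- check_count(cfg$n_macrostates, "n_macrostates", min = 2L)
  cfg$seed <- check_seed(cfg$seed)
  if (!is.null(cfg$n_clusters)) cfg$n_clusters <- check_count(cfg$n_clusters, "n_clusters")
  if (!is.null(cfg$msm_lag)) check_scalar_positive(cfg$msm_lag, "msm_lag")
  if (!is.null(cfg$concentration)) check_scalar_positive(cfg$concentration, "concentration")
  if (!is.null(cfg$lag_scan)) {
    cfg$lag_scan <- as.numeric(cfg$lag_scan)
    if (any(cfg$lag_scan <= 0)) stop_ligandmsm("`lag_scan` lags must be positive")
  }
  if (!is.null(cfg$bootstrap)) {
    bs <- cfg$bootstrap
    if (inherits(bs, "bootstrap_spec")) bs <- unclass(bs)
    allowed <- c("n_runs", "drop_fraction", "seed")
    unknown <- setdiff(names(bs), allowed)
    if (length(unknown)) {
      stop_ligandmsm(sprintf("unknown bootstrap key(s): %s",
                             paste(unknown, collapse = ", ")))
    }
    bs <- utils::modifyList(list(n_runs = 7L, drop_fraction = 0.2), bs)
    spec <- bootstrap_spec(bs$n_runs, bs$drop_fraction, bs$seed %||% cfg$seed)
    cfg$bootstrap <- list(n_runs = spec$n_runs,
                          drop_fraction = spec$drop_fraction,
                          seed = spec$seed)
  }
  cfg$write_intermediates <- isTRUE(cfg$write_intermediates)
  structure(cfg, class = "pipeline_config")
}

read_config_file <- function(path) {
  if (!file.exists(path)) stop_ligandmsm(sprintf("config file '%s' not found", path))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_ligandmsm("YAML configuration requires the 'yaml' package")
    }
    yaml::read_yaml(path) %||% list()
  } else {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  }
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Run the full binding-kinetics pipeline
#'
#' Executes featurize -> TICA -> k-centers -> reversible MSM (with optional
#' implied-timescale lag scan) -> PCCA -> kinetics -> bootstrap on either a
#' trajectory bundle or a synthetic benchmark, writing all artifacts under
#' one run directory (`features/`, `tica/`, `clusters/`, `msm/`,
#' `kinetics/`, `bootstrap/`), including a machine-readable
#' `kinetics/kinetics.json` and a human-readable `summary.txt`.  Every
#' output carries provenance (configuration hash, seed, package version).
#'
#' @param input Either a [trajectory_bundle()] (or a portable bundle
#'   directory path), or a synthetic request
#'   `list(preset = "binding5", n_traj = ..., n_frames = ...)`.
#' @param config A [validate_config()] result (or raw list / file path);
#'   `n_clusters` and `msm_lag` are required.
#' @param out_dir Output run directory (created).
#' @return Invisibly, a list with the fitted pipeline stages, the kinetics
#'   and the bootstrap error table (`NULL` if bootstrap is disabled).
#' @export
run_pipeline <- function(input, config, out_dir) {
  config <- validate_config(config)
  if (is.null(config$n_clusters)) {
    stop_ligandmsm("configuration is missing required `n_clusters` [cluster stage]")
  }
  if (is.null(config$msm_lag)) {
    stop_ligandmsm("configuration is missing required `msm_lag` [msm stage]")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  prep <- prepare_pipeline_input(input, config)
  features <- prep$features
  flags <- prep$flags
  if (is.null(config$concentration)) config$concentration <- prep$concentration
  if (is.null(config$concentration)) {
    stop_ligandmsm("configuration is missing `concentration` and the input declares no box metadata [kinetics stage]")
  }

  cfg_file <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       digits = NA, null = "null")
  provenance <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ligandmsm"))
  )

  fit <- fit_msm_pipeline(features, config, flags = flags)

  if (config$write_intermediates) {
    write_pipeline_artifacts(out_dir, features, flags, fit, provenance)
  }
  scan <- NULL
  if (!is.null(config$lag_scan)) {
    scan <- lag_scan(fit$dtrajs, config$lag_scan,
                     n_timescales = config$n_macrostates)
    dir.create(file.path(out_dir, "msm"), showWarnings = FALSE)
    utils::write.csv(scan$table, file.path(out_dir, "msm", "lag_scan.csv"),
                     row.names = FALSE)
  }
  boot <- NULL
  if (!is.null(config$bootstrap)) {
    spec <- bootstrap_spec(config$bootstrap$n_runs,
                           config$bootstrap$drop_fraction,
                           config$bootstrap$seed %||% config$seed)
    boot <- bootstrap_observables(features, config, flags = flags, spec = spec)
    dir.create(file.path(out_dir, "bootstrap"), showWarnings = FALSE)
    utils::write.csv(boot, file.path(out_dir, "bootstrap", "errors.csv"),
                     row.names = FALSE)
  }

  kin <- fit$kinetics
  err <- function(name) {
    if (is.null(boot)) NULL else boot$sd[boot$observable == name]
  }
  report <- list(
    kon_M_s = kin$kon, koff_s = kin$koff, dG0_kcal_mol = kin$dG0,
    Kd_M = kin$Kd,
    mfpt_s = kin$mfpt_matrix_ns * 1e-9,
    labels = kin$labels,
    errors = list(kon_M_s = err("kon_M_s"), koff_s = err("koff_s"),
                  dG0_kcal_mol = err("dG0_kcal_mol")),
    tau2_ns = fit$timescales$timescales[1L],
    suggested_lag_ns = if (!is.null(scan)) scan$suggested_lag,
    temperature_K = kin$temperature,
    concentration_M = kin$concentration,
    provenance = provenance
  )
  dir.create(file.path(out_dir, "kinetics"), showWarnings = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "kinetics", "kinetics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       matrix = "rowmajor")
  write_summary(file.path(out_dir, "summary.txt"), report, fit)
  invisible(list(fit = fit, kinetics = kin, bootstrap = boot, scan = scan,
                 report = report, out_dir = out_dir))
}

prepare_pipeline_input <- function(input, config) {
  if (is.character(input) && length(input) == 1L) {
    input <- read_bundle(input)
  }
  if (inherits(input, "trajectory_bundle")) {
    streams <- split_ligand_copies(input)
    features <- lapply(streams, contact_map_features,
                       cutoff = config$contact_cutoff)
    flags <- NULL
    if (length(input$ion_atoms) && !is.null(input$phosphate_atoms)) {
      flags <- lapply(streams, coordination_flags,
                      cutoff = config$coordination_cutoff)
    }
    return(list(features = features, flags = flags, concentration = NULL))
  }
  if (is.list(input) && !is.null(input$preset)) {
    system <- msm_preset(input$preset)
    n_traj <- check_count(input$n_traj %||% 100L, "n_traj")
    n_frames <- check_count(input$n_frames %||% 2000L, "n_frames", min = 2L)
    dtrajs <- sample_ctmc_trajectories(system, n_traj, n_frames,
                                       seed = config$seed)
    features <- lapply(seq_along(dtrajs), function(i) {
      embed_states(dtrajs[[i]], system$embedding, seed = config$seed + i)
    })
    conc <- if (!is.null(system$box_volume)) {
      concentration_from_box(system$n_ligand_copies %||% 1L, system$box_volume)
    }
    return(list(features = features, flags = NULL, concentration = conc))
  }
  stop_ligandmsm("`input` must be a trajectory bundle, a bundle path, or list(preset = ...)")
}

write_pipeline_artifacts <- function(out_dir, features, flags, fit, provenance) {
  for (d in c("features", "tica", "clusters", "msm")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  feat_meta <- list(
    n_trajectories = length(features),
    n_frames = vapply(features, function(f) nrow(f$frames), 1L),
    n_features = ncol(features[[1L]]$frames),
    frame_dt_ns = features[[1L]]$frame_dt,
    has_flags = !is.null(flags),
    provenance = provenance
  )
  jsonlite::write_json(feat_meta, file.path(out_dir, "features", "features.json"),
                       auto_unbox = TRUE, digits = NA)
  write_tica_model(fit$tica, file.path(out_dir, "tica", "model.json"))
  jsonlite::write_json(
    list(centers = fit$cluster$centers, k_geometric = fit$cluster$k_geometric,
         n_microstates = fit$cluster$n_microstates,
         covering_radius = fit$cluster$covering_radius,
         flag_split_map = fit$cluster$flag_split_map,
         provenance = provenance),
    file.path(out_dir, "clusters", "model.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor", null = "null")
  for (i in seq_along(fit$dtrajs)) {
    writeLines(as.character(fit$dtrajs[[i]]$states),
               file.path(out_dir, "clusters", sprintf("dtraj_%04d.txt", i)))
  }
  write_transition_model(fit$model, file.path(out_dir, "msm", "model.json"))
}

write_summary <- function(path, report, fit) {
  lines <- c(
    "ligandmsm pipeline summary",
    sprintf("package %s, seed %d, config %s",
            report$provenance$package_version, report$provenance$seed,
            report$provenance$config_hash),
    "",
    sprintf("microstates (active): %d", nrow(fit$model$T)),
    sprintf("macrostates: %s", paste(report$labels, collapse = ", ")),
    sprintf("slowest implied timescale: %.4g ns", report$tau2_ns),
    "",
    sprintf("kon  = %.4g 1/(M s)", report$kon_M_s),
    sprintf("koff = %.4g 1/s", report$koff_s),
    sprintf("Kd   = %.4g M", report$Kd_M),
    sprintf("dG0  = %.3f kcal/mol at %g K (C0 = 1 M)",
            report$dG0_kcal_mol, report$temperature_K),
    sprintf("simulation concentration: %g M", report$concentration_M)
  )
  writeLines(lines, path)
}
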