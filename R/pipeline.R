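#' Run the structural network analysis pipeline
#'
#' Orchestrates the stage graph for one of four modes and writes all
#' results plus a run manifest to `out_dir`:
#'
#' * `synthetic-cohort`: generate a calibrated synthetic cohort, write the
#'   per-subject connectome CSVs and covariates CSV, compute raw and
#'   null-normalized metrics, run the group and correlation statistics.
#' * `from-matrices`: read per-subject connectome CSVs plus a covariates
#'   CSV and run metrics + statistics.
#' * `from-streamlines`: read a streamline file (TRK or TSV) plus a NIfTI
#'   label volume and write the fiber-density connectivity matrix.
#' * `phantom-e2e`: generate a bar phantom, fit tensors from its signals,
#'   track, and build the connectome - the end-to-end integration path.
#'
#' The same config and seed always reproduce identical result files.
#'
#' @param config Named list (or path to a YAML file with the same fields):
#'   `mode`, `out_dir`, `seed`, `n_null`, `swaps_per_edge`, `n_perm`,
#'   optional `cohort` (arguments to [cohort_config()]), and mode-specific
#'   paths `matrices_dir`, `covariates_csv`, `streamlines`, `labels`.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  mode <- match.arg(config$mode, c("synthetic-cohort", "from-matrices",
                                   "from-streamlines", "phantom-e2e"))
  out_dir <- config$out_dir %||% stop("config$out_dir is required",
                                      call. = FALSE)
  check_pipeline_inputs(config, mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  n_null <- config$n_null %||% 100
  swaps <- config$swaps_per_edge %||% 10
  n_perm <- config$n_perm %||% 10000

  timings <- list()
  clock <- function(nm, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    timings[[nm]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    res
  }
  results <- list()

  if (mode %in% c("synthetic-cohort", "from-matrices")) {
    cohort <- if (mode == "synthetic-cohort") {
      cfg <- do.call(cohort_config, config$cohort %||% list())
      clock("generate", {
        ch <- generate_cohort(cfg, seed = seed)
        mat_dir <- file.path(out_dir, "connectomes")
        dir.create(mat_dir, showWarnings = FALSE)
        purrr::walk2(ch$connectome, ch$subject_id, function(w, id) {
          write_connectome_csv(w, file.path(mat_dir, paste0(id, ".csv")))
        })
        readr::write_csv(
          dplyr::select(ch, -"connectome"),
          file.path(out_dir, "covariates.csv"))
        ch
      })
    } else {
      clock("load", read_cohort_dir(config$matrices_dir,
                                    config$covariates_csv))
    }
    metrics <- clock("metrics", compute_network_metrics(
      cohort, n_null = n_null, swaps_per_edge = swaps, seed = seed))
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"))
    analysis <- clock("analyze", analyze_cohort(metrics, n_perm = n_perm,
                                                seed = seed))
    readr::write_csv(tidy(analysis$group_comparisons),
                     file.path(out_dir, "group_comparisons.csv"))
    readr::write_csv(tidy(analysis$correlations),
                     file.path(out_dir, "correlations.csv"))
    results <- list(cohort = cohort, metrics = metrics, analysis = analysis)
  } else if (mode == "from-streamlines") {
    ss <- clock("load", {
      if (grepl("\\.trk$", config$streamlines)) read_trk(config$streamlines)
      else read_streamlines_tsv(config$streamlines)
    })
    labels <- read_nifti_volume(config$labels)
    vs <- attr(labels, "voxel_size") %||% c(1, 1, 1)
    w <- clock("connectome", build_connectome(
      ss, array(as.integer(labels), base::dim(labels)), voxel_size = vs,
      min_streamlines = config$min_streamlines %||% 3))
    write_connectome_csv(w, file.path(out_dir, "connectome.csv"))
    results <- list(streamlines = ss, connectome = w)
  } else {  # phantom-e2e
    ph_cfg <- do.call(bar_phantom_config,
                      c(config$phantom %||% list(), list(seed = seed)))
    ph <- clock("phantom", generate_tensor_phantom(ph_cfg))
    tv <- clock("fit", fit_tensor(ph$signals, ph$bvals, ph$bvecs,
                                  dim = ph_cfg$grid_shape,
                                  voxel_size = ph_cfg$voxel_size))
    sc <- tensor_scalars(tv)
    ss <- clock("track", track_all(tv, sc$FA, seed = seed))
    write_trk(ss, file.path(out_dir, "streamlines.trk"))
    w <- clock("connectome", build_connectome(ss, ph$labels,
                                              voxel_size = tv$voxel_size))
    write_connectome_csv(w, file.path(out_dir, "connectome.csv"))
    results <- list(phantom = ph, tensors = tv, streamlines = ss,
                    connectome = w)
  }

  manifest <- list(
    mode = mode, seed = seed,
    n_null = n_null, swaps_per_edge = swaps, n_perm = n_perm,
    config = config[setdiff(names(config), "out_dir")],
    package_version = as.character(utils::packageVersion("tractnet")),
    r_version = R.version.string,
    timings_sec = timings,
    significance_threshold = 0.05,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(c(results, list(manifest = manifest)))
}

check_pipeline_inputs <- function(config, mode) {
  need <- switch(mode,
    "from-matrices" = c("matrices_dir", "covariates_csv"),
    "from-streamlines" = c("streamlines", "labels"),
    character(0))
  missing_fields <- need[vapply(need, function(f) is.null(config[[f]]),
                                logical(1))]
  missing_files <- setdiff(need, missing_fields)
  missing_files <- missing_files[!vapply(
    missing_files, function(f) file.exists(config[[f]]), logical(1))]
  problems <- c(
    if (length(missing_fields)) paste("missing config field:",
                                      missing_fields),
    if (length(missing_files)) paste0("missing input: ", missing_files,
                                      " (", unlist(config[missing_files]),
                                      ")"))
  if (length(problems)) {
    stop("pipeline inputs incomplete:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a cohort from per-subject connectome CSVs plus a covariates CSV
#'
#' @param matrices_dir Directory of `<subject_id>.csv` connectivity
#'   matrices.
#' @param covariates_csv Cohort covariates file with at least
#'   `subject_id` and `group` columns.
#' @return Cohort tibble with a `connectome` list-column.
#' @export
read_cohort_dir <- function(matrices_dir, covariates_csv) {
  cov <- readr::read_csv(covariates_csv, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "group") %in% names(cov)))
  cov$group <- factor(cov$group, levels = c("control", "patient"))
  paths <- file.path(matrices_dir, paste0(cov$subject_id, ".csv"))
  missing <- cov$subject_id[!file.exists(paths)]
  if (length(missing)) {
    stop("no connectome CSV for subject(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cov$connectome <- lapply(paths, read_connectome_csv)
  class(cov) <- c("tractnet_cohort", class(cov))
  cov
}
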