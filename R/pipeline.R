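# Report assembly: the two study workflows as reproducible pipelines.  The
# trajectory pipeline derives all structural observables from a multi-model
# PDB; the thermodynamics pipeline fits every melting/ITC dataset found in
# the configuration and tabulates the results.

.CONFIG_KEYS <- c(
  "trajectory_path", "construct", "melting_files", "itc_files",
  "hbond_max_dist", "hbond_min_angle", "stack_max_dist", "stack_max_angle",
  "flip_in_threshold", "flip_out_threshold", "flip_residues",
  "cluster_cutoffs", "cluster_stride", "occupancy_threshold", "window",
  "seed", "outdir")

#' Pipeline run configuration
#'
#' Validated, JSON-serializable configuration shared by
#' [run_trajectory_pipeline()] and [run_thermo_pipeline()].  Unknown keys
#' are rejected.
#'
#' @param trajectory_path multi-model PDB input.
#' @param construct `"prokaryotic"` or `"eukaryotic"` (registry construct).
#' @param melting_files named numeric vector: CSV path -> c0 (M).
#' @param itc_files character vector of ITC CSV paths.
#' @param hbond_max_dist,hbond_min_angle hydrogen-bond criteria.
#' @param stack_max_dist,stack_max_angle stacking criteria.
#' @param flip_in_threshold,flip_out_threshold flip-state thresholds (deg).
#' @param flip_residues residues for the flip-angle report.
#' @param cluster_cutoffs gromos RMSD criteria (Angstrom).
#' @param cluster_stride clustering frame stride.
#' @param occupancy_threshold minimum reported pair occupancy.
#' @param window frames per averaging window for the time series.
#' @param seed integer seed recorded in the report.
#' @param outdir output directory for the report bundle.
#' @return list of class `run_config`.
#' @export
run_config <- function(trajectory_path = NULL, construct = "prokaryotic",
                       melting_files = NULL, itc_files = NULL,
                       hbond_max_dist = 3.5, hbond_min_angle = 150,
                       stack_max_dist = 4.5, stack_max_angle = 30,
                       flip_in_threshold = 50, flip_out_threshold = 140,
                       flip_residues = c("A1492", "A1493", "U1498"),
                       cluster_cutoffs = c(1.5, 2.0, 2.5),
                       cluster_stride = 1L, occupancy_threshold = 0.05,
                       window = 5L, seed = 1L, outdir = tempfile("asite_run_")) {
  cfg <- list(trajectory_path = trajectory_path, construct = construct,
              melting_files = melting_files, itc_files = itc_files,
              hbond_max_dist = hbond_max_dist,
              hbond_min_angle = hbond_min_angle,
              stack_max_dist = stack_max_dist,
              stack_max_angle = stack_max_angle,
              flip_in_threshold = flip_in_threshold,
              flip_out_threshold = flip_out_threshold,
              flip_residues = flip_residues,
              cluster_cutoffs = cluster_cutoffs,
              cluster_stride = cluster_stride,
              occupancy_threshold = occupancy_threshold,
              window = window, seed = seed, outdir = outdir)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(raw), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_run_config(config, tf)
  unname(tools::md5sum(tf))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

# best-window region labels of an oligomer on the construct's B strand
oligomer_region_labels <- function(oligomer, strandB) {
  rep <- count_mismatches(oligomer, strandB)
  pos <- rep$window_start + seq_len(length(oligomer)) - 1L
  strandB$numbering[pos]
}

#' Run the full trajectory-analysis workflow
#'
#' Produces the report bundle of the structural workflow: RMSD and RMSF
#' series, windowed WC-WC / non-WC-WC hydrogen-bond counts, stacking time
#' series and region averages for the three oligomer target regions,
#' flip-angle series, base-pair occupancy table, gromos cluster summaries
#' for each cutoff, and block-standard-error curves for the RMSD and
#' stacking series.  All artifacts are written as CSV under
#' `config$outdir` together with a JSON report carrying the configuration
#' hash and seed.  Deterministic given the configuration.
#'
#' @param config a [run_config] with `trajectory_path` set (or `traj`
#'   supplied directly).
#' @param traj optional in-memory [rna_trajectory] overriding
#'   `trajectory_path`.
#' @return invisible list with the computed artifacts and `files`, the
#'   paths written.
#' @export
run_trajectory_pipeline <- function(config, traj = NULL) {
  stopifnot(inherits(config, "run_config"))
  registry <- build_registry()
  construct <- registry[[config$construct]]
  if (is.null(construct)) stop("unknown construct: ", config$construct)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(traj))
    traj <- run_stage("read_trajectory",
                      read_trajectory(config$trajectory_path, construct))
  traj$construct <- construct
  out <- list()
  files <- character()
  emit <- function(name, df) {
    p <- file.path(config$outdir, paste0(name, ".csv"))
    write.csv(df, p, row.names = FALSE)
    files[[name]] <<- p
    df
  }

  out$rmsd <- run_stage("rmsd", {
    v <- rmsd_timeseries(traj)
    emit("rmsd", data.frame(frame = seq_along(v), rmsd = v))
  })
  out$rmsf <- run_stage("rmsf", emit("rmsf", rmsf(traj)))
  out$hbond_counts <- run_stage("hbond_counts",
    emit("hbond_counts", hbond_count_timeseries(traj, config$window)))
  params <- load_ff_params()
  out$stacking_raw <- run_stage("stacking", stacking_timeseries(traj, params, 1L))
  out$stacking <- run_stage("stacking", {
    idx <- split(seq_len(nrow(out$stacking_raw)),
                 ceiling(seq_len(nrow(out$stacking_raw)) / config$window))
    emit("stacking_timeseries", data.frame(
      window = seq_along(idx),
      frame_from = vapply(idx, min, 0L),
      frame_to = vapply(idx, max, 0L),
      coulomb = vapply(idx, function(ii) mean(out$stacking_raw$coulomb[ii]), 0),
      vdw = vapply(idx, function(ii) mean(out$stacking_raw$vdw[ii]), 0),
      total = vapply(idx, function(ii) mean(out$stacking_raw$total[ii]), 0)))
  })
  out$stacking_regions <- run_stage("stacking_regions", {
    rows <- lapply(c("oligo_1489", "oligo_1490", "oligo_1491"), function(o) {
      labs <- oligomer_region_labels(registry[[o]], construct$strandB)
      cbind(data.frame(model = construct$label, oligomer = o),
            region_average(traj, labs, params))
    })
    emit("stacking_regions", do.call(rbind, rows))
  })
  out$flips <- run_stage("flip_angles",
    emit("flip_angles",
         flip_timeseries_report(traj, config$flip_residues, construct,
                                config$flip_in_threshold,
                                config$flip_out_threshold)))
  out$occupancy <- run_stage("pair_occupancy", {
    occ <- pair_occupancy(traj, config$occupancy_threshold)
    emit("pair_occupancy", occ$report)
    occ
  })
  out$clusters <- run_stage("clusters", {
    M <- pairwise_rmsd(traj,
                       frames = seq(1L, n_frames(traj),
                                    by = config$cluster_stride))
    cl <- lapply(config$cluster_cutoffs, function(co) gromos_cluster(M, co))
    emit("clusters", data.frame(
      cutoff = config$cluster_cutoffs,
      n_clusters = vapply(cl, function(x) length(x$sizes), 0L),
      top_cluster_fraction = vapply(cl, function(x)
        max(x$sizes) / sum(x$sizes), 0)))
    cl
  })
  out$bse <- run_stage("bse", {
    b1 <- block_standard_error(out$rmsd$rmsd)
    b2 <- block_standard_error(out$stacking_raw$total)
    emit("bse", rbind(cbind(series = "rmsd", as.data.frame(b1)),
                      cbind(series = "stacking_total", as.data.frame(b2))))
  })
  report <- list(workflow = "trajectory", construct = construct$label,
                 n_frames = n_frames(traj), seed = config$seed,
                 config_hash = config_hash(config),
                 files = as.list(files))
  rp <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA)
  files[["report"]] <- rp
  out$files <- files
  invisible(out)
}

#' Run the solution-thermodynamics workflow
#'
#' Fits every configured melting curve (two-state model with sloping
#' baselines plus van't Hoff analysis) and ITC series (1:1 binding model),
#' and writes result tables with `dH`, `TdS` and `dG` at 294.15 K plus the
#' cross-method consistency column `-RT ln Ka`.  Fit failures are recorded
#' per dataset and do not abort the pipeline.
#'
#' @param config a [run_config] with `melting_files` and/or `itc_files`.
#' @return invisible list with `melt_fits`, `itc_fits`, per-file `status`,
#'   and `files`.
#' @export
run_thermo_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  melt_rows <- list(); itc_rows <- list()
  melt_fits <- list(); itc_fits <- list()
  for (nm in names(config$melting_files)) {
    res <- tryCatch({
      curve <- read_melting_csv(nm, config$melting_files[[nm]])
      fit <- fit_two_state(curve)
      if (!fit$converged) stop(fit$message)
      melt_fits[[nm]] <- fit
      melt_rows[[nm]] <- data.frame(
        dataset = basename(nm), dH = fit$dH, TdS = fit$TdS, dG = fit$dG,
        Tm_C = fit$Tm_C)
      "ok"
    }, error = function(e) conditionMessage(e))
    status[[nm]] <- res
  }
  for (nm in config$itc_files) {
    res <- tryCatch({
      fit <- fit_itc(read_itc_csv(nm))
      if (!fit$converged) stop(fit$message)
      itc_fits[[nm]] <- fit
      itc_rows[[nm]] <- data.frame(
        dataset = basename(nm), dH = fit$dH, TdS = fit$TdS, dG = fit$dG,
        Ka_1e7 = fit$ka / 1e7, N = fit$n,
        dG_from_Ka = gibbs_from_ka(fit$ka, fit$T_K))
      "ok"
    }, error = function(e) conditionMessage(e))
    status[[nm]] <- res
  }
  files <- character()
  if (length(melt_rows)) {
    p <- file.path(config$outdir, "melt_fits.csv")
    write.csv(do.call(rbind, melt_rows), p, row.names = FALSE)
    files[["melt_fits"]] <- p
  }
  if (length(itc_rows)) {
    p <- file.path(config$outdir, "itc_fits.csv")
    write.csv(do.call(rbind, itc_rows), p, row.names = FALSE)
    files[["itc_fits"]] <- p
  }
  report <- list(workflow = "thermodynamics", seed = config$seed,
                 config_hash = config_hash(config),
                 status = status, files = as.list(files))
  rp <- file.path(config$outdir, "report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA)
  files[["report"]] <- rp
  invisible(list(melt_fits = melt_fits, itc_fits = itc_fits,
                 status = status, files = files))
}
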