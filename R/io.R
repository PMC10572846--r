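# Standard-format exchange: CSV for schedules, TACs and input curves,
# NIfTI-1 for volumes, JSON for configuration and sidecars, and the
# end-to-end pipeline runner.

#' Read / write a frame schedule as CSV
#'
#' Columns `frame_start_min`, `frame_end_min`.
#'
#' @param path CSV path.
#' @return [frame_schedule()] (read); `path` invisibly (write).
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_start_min", "frame_end_min")
  if (!all(need %in% names(df)))
    stop("schedule CSV needs columns: ", paste(need, collapse = ", "))
  frame_schedule(df$frame_start_min, df$frame_end_min)
}

#' @rdname read_schedule
#' @param schedule An [frame_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "fpet_schedule"))
  utils::write.csv(
    data.frame(frame_start_min = schedule$start, frame_end_min = schedule$end),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read / write a time-activity curve as CSV
#'
#' Columns `frame_start_min`, `frame_end_min`, `value_Bq_per_mL`.
#'
#' @param path CSV path.
#' @return [tac()] (read); `path` invisibly (write).
#' @export
read_tac_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_start_min", "frame_end_min", "value_Bq_per_mL")
  if (!all(need %in% names(df)))
    stop("TAC CSV needs columns: ", paste(need, collapse = ", "))
  tac(frame_schedule(df$frame_start_min, df$frame_end_min), df$value_Bq_per_mL)
}

#' @rdname read_tac_csv
#' @param x An [tac()].
#' @export
write_tac_csv <- function(x, path) {
  stopifnot(inherits(x, "fpet_tac"))
  utils::write.csv(
    data.frame(frame_start_min = x$schedule$start,
               frame_end_min = x$schedule$end,
               value_Bq_per_mL = x$values),
    path, row.names = FALSE
  )
  invisible(path)
}

#' Read / write an input function as CSV
#'
#' Columns `time_min`, `ca_Bq_per_mL`; `t2` and `pvc` travel as a comment
#' header line `# t2_min=<v> pvc=<v>`.
#'
#' @param path CSV path.
#' @param t2,pvc Used when the file has no header comment.
#' @return [input_function()] (read); `path` invisibly (write).
#' @export
read_input_csv <- function(path, t2 = 20, pvc = 1) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    m <- regmatches(first, gregexpr("[a-z0-9_]+=[0-9.eE+-]+", first))[[1L]]
    kv <- strsplit(m, "=")
    for (p in kv) {
      if (p[1L] == "t2_min") t2 <- as.numeric(p[2L])
      if (p[1L] == "pvc") pvc <- as.numeric(p[2L])
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("time_min", "ca_Bq_per_mL")
  if (!all(need %in% names(df)))
    stop("input-function CSV needs columns: ", paste(need, collapse = ", "))
  input_function(df$time_min, df$ca_Bq_per_mL, t2 = t2, pvc = pvc)
}

#' @rdname read_input_csv
#' @param x An [input_function()].
#' @export
write_input_csv <- function(x, path) {
  stopifnot(inherits(x, "fpet_input"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# t2_min=%g pvc=%g", x$t2, x$pvc), con)
  utils::write.csv(
    data.frame(time_min = x$time, ca_Bq_per_mL = x$ca), con, row.names = FALSE
  )
  invisible(path)
}

#' Read a dynamic image with its frame schedule
#'
#' Loads a 4D NIfTI-1 volume and a schedule sidecar (CSV, see
#' [read_schedule()]); the frame counts must agree.
#'
#' @param path NIfTI path (`.nii` / `.nii.gz`).
#' @param schedule_path Schedule CSV path, or an [frame_schedule()].
#' @return An [dynamic_image()].
#' @export
read_dynamic <- function(path, schedule_path) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 4L)
    stop("expected a 4D dynamic volume in ", path)
  sched <- if (inherits(schedule_path, "fpet_schedule")) schedule_path
    else read_schedule(schedule_path)
  nf <- dim(nii$data)[4L]
  ns <- length(sched$start)
  if (nf != ns)
    stop(sprintf("frame-count mismatch: image has %d frames, schedule has %d rows",
                 nf, ns))
  dynamic_image(nii$data, sched, nii$voxel_size_mm, nii$affine)
}

#' Write a dynamic image and its schedule sidecar
#'
#' @param dyn An [dynamic_image()].
#' @param path NIfTI path; the schedule is written next to it as
#'   `<stem>_frames.csv` unless `schedule_path` is given.
#' @param schedule_path Optional explicit sidecar path.
#' @return `path`, invisibly.
#' @export
write_dynamic <- function(dyn, path, schedule_path = NULL) {
  stopifnot(inherits(dyn, "fpet_dynimg"))
  write_nifti(dyn$data, path, dyn$voxel_size_mm, dyn$affine)
  if (is.null(schedule_path)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    schedule_path <- paste0(stem, "_frames.csv")
  }
  write_schedule(dyn$schedule, schedule_path)
  invisible(path)
}

#' Write parametric maps as NIfTI volumes with a JSON sidecar
#'
#' One float32 NIfTI per map (deterministic names `<prefix><map>.nii`),
#' preserving the input affine; missing-valued voxels are stored as NaN. The
#' sidecar `<prefix>maps.json` records the configuration (including the
#' delta-Ki denominator), per-map summary statistics, a config hash and the
#' package version.
#'
#' @param maps An `fpet_maps` from [fit_voxelwise()].
#' @param out_dir Output directory (created if missing).
#' @param prefix Filename prefix (default `""`).
#' @param overwrite Overwrite existing files (default `FALSE`; an error
#'   names the first existing file otherwise).
#' @return Named character vector of the files written, invisibly.
#' @export
write_maps <- function(maps, out_dir, prefix = "", overwrite = FALSE) {
  stopifnot(inherits(maps, "fpet_maps"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  map_names <- c("ki_baseline", "ki_activation", "delta_ki", "v0",
                 "k1_base", "k2_base", "k3_base", "k1_act", "k2_act",
                 "residual")
  files <- character(0)
  for (nm in map_names) {
    f <- file.path(out_dir, paste0(prefix, nm, ".nii"))
    if (file.exists(f) && !overwrite)
      stop("output exists (use overwrite = TRUE): ", f)
    write_nifti(maps[[nm]], f, maps$voxel_size_mm, maps$affine)
    files[nm] <- f
  }
  cfg <- maps$config
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               null = "null")
  summarize <- function(a) {
    v <- a[maps$mask]
    list(n = sum(is.finite(v)), mean = mean(v, na.rm = TRUE),
         median = stats::median(v, na.rm = TRUE),
         sd = stats::sd(v, na.rm = TRUE))
  }
  sidecar <- list(
    software = paste0("fpetkin ", as.character(utils::packageVersion("fpetkin"))),
    config = cfg,
    config_hash = sprintf("%d", sum(utf8ToInt(as.character(cfg_json)) *
                                      (seq_len(nchar(cfg_json)) %% 97 + 1))),
    delta_ki_denominator = cfg$delta_ki_denominator,
    n_voxels = sum(maps$mask),
    n_converged = sum(maps$converged, na.rm = TRUE),
    n_bound_hit = sum(maps$bound_hit, na.rm = TRUE),
    summary = lapply(
      stats::setNames(map_names, map_names),
      function(nm) summarize(maps[[nm]])
    )
  )
  sf <- file.path(out_dir, paste0(prefix, "maps.json"))
  if (file.exists(sf) && !overwrite)
    stop("output exists (use overwrite = TRUE): ", sf)
  jsonlite::write_json(sidecar, sf, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE, force = TRUE)
  files["sidecar"] <- sf
  invisible(files)
}

#' Read a pipeline run configuration (JSON)
#'
#' A JSON object with optional blocks `paths` (`dynamic`, `schedule`,
#' `brain_mask`, `bkg_mask`, `idif`, `out_dir`), `fit` (arguments of
#' [fit_config()]), `idif` (`threshold_fraction`, `dilate_mm`, `pvc`,
#' `early_window`), `simulate` (arguments of [phantom_spec()]), `seed`,
#' `overwrite`. Missing values take the package defaults.
#'
#' @param path JSON path.
#' @return A list of class `fpet_runconfig`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "fpet_runconfig")
}

run_config_defaults <- function(cfg = list()) {
  cfg$paths <- cfg$paths %||% list()
  idif_d <- list(threshold_fraction = 0.5, dilate_mm = 6, pvc = 1,
                 early_window = c(0, 1))
  cfg$idif <- utils::modifyList(idif_d, as.list(cfg$idif %||% list()))
  cfg$fit <- as.list(cfg$fit %||% list())
  cfg$simulate <- as.list(cfg$simulate %||% list())
  cfg$seed <- cfg$seed %||% 42
  cfg$overwrite <- isTRUE(cfg$overwrite)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline
#'
#' Orchestrates simulate (optional) -> IDIF -> voxelwise fit -> map
#' writing from a single configuration. When `config$paths$dynamic` is
#' absent, a phantom is generated from `config$simulate` (with
#' `config$seed`). The IDIF stage segments vessels on the early image,
#' dilates, subtracts the background VOI if given, and rescales by PVC;
#' `config$paths$idif` can instead point at a ready-made input-function
#' CSV. Per-stage voxel and convergence counts are logged via `message()`.
#'
#' @param config An `fpet_runconfig`, a path to one, or a plain list.
#' @return Invisibly, a list with the fitted `maps`, the `input_fn` used,
#'   and the output `files`; errors propagate with stage context.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- run_config_defaults(unclass(config))
  out_dir <- cfg$paths$out_dir %||% stop("config$paths$out_dir is required")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  truth <- NULL
  dyn <- stage("load", {
    if (!is.null(cfg$paths$dynamic)) {
      if (!file.exists(cfg$paths$dynamic))
        stop("dynamic image not found: ", cfg$paths$dynamic)
      read_dynamic(cfg$paths$dynamic, cfg$paths$schedule)
    } else {
      sim_args <- cfg$simulate
      sim_args$seed <- sim_args$seed %||% cfg$seed
      if (!is.null(sim_args$tissue_params) && !inherits(sim_args$tissue_params, "fpet_params"))
        sim_args$tissue_params <- do.call(kinetic_params, as.list(sim_args$tissue_params))
      ph <- generate_phantom(do.call(phantom_spec, sim_args))
      truth <- ph$truth
      message(sprintf("[simulate] phantom %s, %d frames",
                      paste(dim(ph$image$data)[1:3], collapse = "x"),
                      dim(ph$image$data)[4L]))
      ph$image
    }
  })

  fit_cfg <- stage("config", do.call(fit_config, cfg$fit))

  input_fn <- stage("idif", {
    if (!is.null(cfg$paths$idif)) {
      read_input_csv(cfg$paths$idif, t2 = fit_cfg$t2)
    } else {
      early <- make_early_image(dyn, cfg$idif$early_window)
      vessel <- segment_vessels(early, cfg$idif$threshold_fraction)
      vessel <- dilate_mask(vessel, cfg$idif$dilate_mm, dyn$voxel_size_mm)
      bkg <- NULL
      if (!is.null(cfg$paths$bkg_mask)) {
        if (!file.exists(cfg$paths$bkg_mask))
          stop("background mask not found: ", cfg$paths$bkg_mask)
        bkg <- voi_mask(read_nifti(cfg$paths$bkg_mask)$data > 0, "background")
      } else if (!is.null(truth)) {
        bkg <- truth$bkg
      }
      idif <- extract_idif(dyn, vessel, bkg, pvc = cfg$idif$pvc,
                           t2 = fit_cfg$t2)
      message(sprintf("[idif] vessel VOI %d voxels (dilated %g mm), %d negative samples clipped",
                      sum(vessel$voxels), vessel$dilation_mm,
                      attr(idif, "n_clipped")))
      idif
    }
  })

  brain <- stage("mask", {
    if (!is.null(cfg$paths$brain_mask)) {
      if (!file.exists(cfg$paths$brain_mask))
        stop("brain mask not found: ", cfg$paths$brain_mask)
      voi_mask(read_nifti(cfg$paths$brain_mask)$data > 0, "brain")
    } else if (!is.null(truth)) truth$brain else NULL
  })

  t0 <- Sys.time()
  maps <- stage("fit", fit_voxelwise(dyn, input_fn, brain, fit_cfg))
  message(sprintf("[fit] %d voxels fit in %.1f s, %d converged, %d at bounds",
                  sum(maps$mask),
                  as.numeric(Sys.time() - t0, units = "secs"),
                  sum(maps$converged, na.rm = TRUE),
                  sum(maps$bound_hit, na.rm = TRUE)))

  files <- stage("write", {
    f <- write_maps(maps, out_dir, overwrite = cfg$overwrite)
    write_input_csv(input_fn, file.path(out_dir, "idif.csv"))
    f["idif"] <- file.path(out_dir, "idif.csv")
    f
  })
  invisible(list(maps = maps, input_fn = input_fn, files = files,
                 truth = truth))
}
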