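#' Read a 3D volume from a NIfTI file
#'
#' Accepts NIfTI-1/2, plain or gzipped; 4D payloads with trailing singleton
#' dimensions are accepted as 3D. Complex or RGB payloads are rejected.
#'
#' @param path file path.
#' @return A list: `data` (3D double array) and `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (!is.numeric(img))
    stop("unsupported NIfTI payload (complex/RGB) in ", path)
  vs <- RNifti::pixdim(img)
  d <- dim(img)
  if (length(d) > 3) {
    if (all(d[-(1:3)] == 1L)) dim(img) <- d[1:3]
    else stop("non-3D payload in ", path, " (dims ",
              paste(d, collapse = "x"), ")")
  } else if (length(d) < 3) stop("non-3D payload in ", path)
  arr <- array(as.double(img), dim(img))
  list(data = arr, voxel_size = as.numeric(vs[1:3]))
}

#' Write a 3D volume to a NIfTI file
#'
#' Data are stored as float32; voxel sizes go to the header. The file is
#' written to a temporary name and renamed into place so failures leave no
#' partial output.
#'
#' @param data 3D array or any volume container.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size mm per axis.
#' @return The path, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = c(1, 1, 1)) {
  arr <- as_volume_array(data)
  attr(arr, "pixdim") <- as.numeric(voxel_size)
  img <- RNifti::asNifti(arr, datatype = "float")
  tmp <- paste0(path, ".tmp", Sys.getpid(),
                if (grepl("\\.gz$", path)) ".nii.gz" else ".nii")
  RNifti::writeNifti(img, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Rescale raw scanner phase to radians in (-pi, pi]
#'
#' Scanner phase exports are rarely stored in radians. Conventions:
#' `radians` passes values through (after verifying the range);
#' `siemens_int` maps the stored integer range \[0, 4095\] linearly onto
#' (-pi, pi\] using bin centres (value v maps to
#' `(v + 0.5) / 4096 * 2 * pi - pi`); `minmax` maps the observed data range
#' linearly onto (-pi, pi).
#'
#' @param raw 3D numeric array of raw phase values.
#' @param convention `"radians"`, `"siemens_int"` or `"minmax"`.
#' @param voxel_size mm per axis.
#' @return A wrapped `phase_volume`.
#' @export
rescale_phase <- function(raw, convention = c("radians", "siemens_int",
                                              "minmax"),
                          voxel_size = c(1, 1, 1)) {
  convention <- match.arg(convention)
  raw <- as_volume_array(raw)
  out <- switch(convention,
    radians = {
      if (any(raw < -pi - 1e-3 | raw > pi + 1e-3))
        stop("values outside [-pi, pi]: not radians; try convention = ",
             "\"siemens_int\" or \"minmax\"")
      wrap_phase(raw)
    },
    siemens_int = {
      (raw + 0.5) / 4096 * 2 * pi - pi
    },
    minmax = {
      rng <- range(raw)
      if (diff(rng) == 0) stop("degenerate (constant) image for minmax")
      (raw - rng[1]) / diff(rng) * (2 * pi - 1e-6) - pi + 5e-7
    })
  phase_volume(out, wrapped = TRUE, voxel_size = voxel_size)
}

#' Run the full correction pipeline
#'
#' Wires the stages end to end: wrapped echo difference -> graph-cut
#' unwrapping -> min-marginal confidence -> fieldmap (Hz) -> phase-encode
#' displacement -> Jacobian-modulated EPI correction -> (optionally, when a
#' reference structural image is given) confidence-modulated B-spline
#' registration refinement and re-correction. Writes every intermediate
#' volume plus a JSON run report and returns the results invisibly.
#'
#' @param config a list with entries: `echo1`, `echo2`, `magnitude`, `epi`
#'   (file paths or in-memory volumes), optional `t1`, `outdir`,
#'   `acquisition` (an [acquisition_params()] or list of its arguments),
#'   optional `unwrap` ([unwrap_config()]), `registration`
#'   ([reg_config()]), `confidence_stride`, `seed`, `verbosity`.
#' @return Invisibly, a list with the stage outputs and the report.
#' @export
run_pipeline <- function(config) {
  t_start <- proc.time()[["elapsed"]]
  need <- c("echo1", "echo2", "epi", "outdir")
  missing_f <- setdiff(need, names(config))
  if (length(missing_f))
    stop("pipeline config is missing: ", paste(missing_f, collapse = ", "))
  acq <- config$acquisition
  if (is.null(acq)) acq <- acquisition_params()
  if (!inherits(acq, "acquisition_params"))
    acq <- do.call(acquisition_params, acq)
  ucfg <- if (is.null(config$unwrap)) unwrap_config() else config$unwrap
  rcfg <- if (is.null(config$registration)) reg_config()
          else config$registration
  verb <- isTRUE(config$verbosity)
  say <- function(...) if (verb) message(sprintf(...))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    say("stage %-12s %.2fs", name, timings[[name]])
    out
  }
  load_vol <- function(x) {
    if (is.character(x)) read_volume(x)
    else if (inherits(x, c("phase_volume", "magnitude_volume")))
      list(data = x$data, voxel_size = x$voxel_size)
    else list(data = as_volume_array(x), voxel_size = c(1, 1, 1))
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  e1 <- load_vol(config$echo1); e2 <- load_vol(config$echo2)
  epi <- load_vol(config$epi)
  mag <- if (!is.null(config$magnitude)) {
    m <- load_vol(config$magnitude)
    magnitude_volume(m$data, m$voxel_size)
  } else NULL
  vs <- e1$voxel_size
  p1 <- phase_volume(wrap_phase(e1$data), TRUE, vs)
  p2 <- phase_volume(wrap_phase(e2$data), TRUE, vs)

  dphi <- stage("difference", phase_difference(p1, p2))
  uw <- stage("unwrap", unwrap(dphi, mag, ucfg))
  conf <- stage("confidence", unwrap_confidence(
    uw, stride = if (is.null(config$confidence_stride)) 1L
                 else config$confidence_stride))
  fmap <- stage("fieldmap",
                fieldmap_from_unwrapped_difference(uw$unwrapped, acq))
  disp <- stage("displacement", displacement_from_fieldmap(fmap, acq))
  corr <- stage("correct", correct_epi(epi$data, disp))

  reg <- NULL; corr_ref <- NULL
  if (!is.null(config$t1)) {
    t1 <- load_vol(config$t1)
    reg <- stage("register",
                 register(t1$data, epi$data, init = disp, conf = conf,
                          config = rcfg))
    corr_ref <- stage("correct_refined", correct_epi(epi$data, reg))
  }

  o <- function(name) file.path(config$outdir, name)
  write_volume(uw$unwrapped, o("unwrapped_phase.nii.gz"), vs)
  write_volume(array(as.double(uw$counts), dim(uw$counts)),
               o("wrap_counts.nii.gz"), vs)
  write_volume(conf$omega, o("confidence.nii.gz"), vs)
  write_volume(fmap, o("fieldmap_hz.nii.gz"), vs)
  write_volume(disp, o("displacement_vox.nii.gz"), vs)
  write_volume(corr, o("epi_corrected.nii.gz"), vs)
  if (!is.null(reg)) {
    write_volume(reg, o("displacement_refined_vox.nii.gz"), vs)
    write_volume(corr_ref, o("epi_corrected_refined.nii.gz"), vs)
  }
  sidecar <- list(pe_axis = acq$pe_axis - 1L, pe_sign = acq$pe_sign,
                  te1_s = acq$te1, te2_s = acq$te2, tacq_s = acq$tacq,
                  displacement_units = "voxels")
  reg_trace <- if (!is.null(reg)) attr(reg, "energy_trace") else NULL
  report <- list(
    package = "phaseflow",
    version = as.character(packageVersion("phaseflow")),
    r_version = R.version.string,
    seed = config$seed,
    acquisition = sidecar,
    unwrap = list(energy_trace = uw$energy_trace,
                  converged = uw$converged,
                  moves = length(uw$energy_trace) - 1L,
                  counts_range = range(uw$counts)),
    confidence = list(median_omega = stats::median(conf$omega)),
    registration = if (!is.null(reg_trace)) list(
      energy_trace = reg_trace,
      # initial/final objective of the finest level (one monotone solve)
      initial_cost = reg_trace[[length(reg_trace)]][1],
      final_cost = tail_num(reg_trace)) else NULL,
    timings_s = timings,
    total_s = proc.time()[["elapsed"]] - t_start)
  tmp <- file.path(config$outdir, ".report.json.tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  file.rename(tmp, file.path(config$outdir, "report.json"))
  writeLines(jsonlite::toJSON(sidecar, auto_unbox = TRUE),
             file.path(config$outdir, "acquisition.json"))
  invisible(list(unwrap = uw, confidence = conf, fieldmap = fmap,
                 displacement = disp, corrected = corr,
                 registration = reg, corrected_refined = corr_ref,
                 report = report))
}

# last objective value of a per-level trace list
tail_num <- function(traces) {
  v <- unlist(traces)
  if (!length(v)) return(NA_real_)
  v[length(v)]
}
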