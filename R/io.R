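#' Read a physiological trace file (CSV or TSV)
#'
#' Reads a delimited trace file (delimiter sniffed from the header line)
#' with a `time_s` column plus gas (`po2_mmHg`, `pco2_mmHg`, `resp`)
#' and/or Doppler (`cbfv_cm_s`) columns. Time must be strictly
#' increasing; timestamp jitter below 1% of the median step is accepted
#' and the series regridded, larger jitter is an error.
#'
#' @param path file path.
#' @return a `gas_traces` tibble (when gas columns are present) or a
#'   `cbfv_trace` tibble (velocity only), with attribute `fs`.
#' @export
read_trace_csv <- function(path) {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!"time_s" %in% names(tbl)) {
    stop_cvreact("Trace file must contain a 'time_s' column.",
                 "cvreact_bad_trace")
  }
  tt <- tbl$time_s
  if (any(diff(tt) <= 0)) {
    stop_cvreact("time not monotone: trace timestamps must strictly increase.",
                 "cvreact_bad_trace")
  }
  step <- median(diff(tt))
  jitter <- max(abs(diff(tt) - step))
  if (jitter > 0.01 * step) {
    stop_cvreact(sprintf(
      "Timestamp jitter (%.3g s) exceeds 1%% of the sampling step (%.3g s).",
      jitter, step), "cvreact_bad_trace")
  }
  fs <- 1 / step
  grid <- seq(tt[1], tt[length(tt)], by = step)
  regrid <- function(v) approx(tt, v, xout = grid, rule = 2, ties = "ordered")$y

  if (all(c("po2_mmHg", "pco2_mmHg") %in% names(tbl))) {
    out <- tibble::tibble(
      time_s = grid,
      po2 = regrid(tbl$po2_mmHg),
      pco2 = regrid(tbl$pco2_mmHg),
      resp = if ("resp" %in% names(tbl)) regrid(tbl$resp) else 0
    )
    return(new_gas_traces(out, fs = fs))
  }
  if ("cbfv_cm_s" %in% names(tbl)) {
    out <- tibble::tibble(time_s = grid, velocity = regrid(tbl$cbfv_cm_s))
    return(tibble::new_tibble(out, class = "cbfv_trace", fs = fs))
  }
  stop_cvreact(
    "Trace file needs po2_mmHg/pco2_mmHg columns or a cbfv_cm_s column.",
    "cvreact_bad_trace")
}

#' Write traces as tidy CSV
#'
#' Gas traces are written with columns `time_s`, `po2_mmHg`,
#' `pco2_mmHg`, `resp` (and `cbfv_cm_s` for velocity traces), the
#' format [read_trace_csv()] reads back.
#'
#' @param trace a `gas_traces` or `cbfv_trace` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "gas_traces")) {
    out <- tibble::tibble(time_s = trace$time_s, po2_mmHg = trace$po2,
                          pco2_mmHg = trace$pco2, resp = trace$resp)
  } else if (inherits(trace, "cbfv_trace")) {
    out <- tibble::tibble(time_s = trace$time_s, cbfv_cm_s = trace$velocity)
  } else {
    stop_cvreact("Expected a gas_traces or cbfv_trace object.")
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' Write / read a BOLD dataset as NIfTI-1 volumes with a JSON sidecar
#'
#' `write_bold_nifti()` stores the 4D data, mask, parcellation and (when
#' present) ground-truth CVR volume as NIfTI-1 files under a common
#' prefix, plus a JSON sidecar with the repetition time and simulation
#' parameters. `read_bold_nifti()` reads them back, discarding the
#' initial pre-equilibrium volumes once at read time.
#'
#' @param bold a `bold_dataset`.
#' @param prefix path prefix (files `<prefix>_bold.nii.gz` etc.).
#' @param discard number of initial volumes to discard on read
#'   (default 12; use 0 for synthetic data written without dummies).
#' @return the prefix (write) or a `bold_dataset` (read).
#' @export
write_bold_nifti <- function(bold, prefix) {
  stopifnot(inherits(bold, "bold_dataset"))
  pd <- bold$voxel_dims_mm
  wr <- function(arr, suffix) {
    img <- RNifti::asNifti(arr, pixdim = c(pd, bold$tr_s)[seq_len(length(dim(arr)))])
    RNifti::writeNifti(img, paste0(prefix, "_", suffix, ".nii.gz"))
  }
  wr(bold$data, "bold")
  wr(bold$mask * 1L, "mask")
  wr(bold$parcellation, "parc")
  if (!is.null(bold$truth_cvr)) wr(bold$truth_cvr, "truth")
  sidecar <- list(tr_s = bold$tr_s, voxel_dims_mm = bold$voxel_dims_mm,
                  params = unclass(bold$params))
  jsonlite::write_json(sidecar, paste0(prefix, "_sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_bold_nifti
#' @export
read_bold_nifti <- function(prefix, discard = 12L) {
  rd <- function(suffix) {
    p <- paste0(prefix, "_", suffix, ".nii.gz")
    if (!file.exists(p)) return(NULL)
    arr <- as.array(RNifti::readNifti(p))
    attributes(arr) <- list(dim = dim(arr))
    arr
  }
  sidecar <- jsonlite::read_json(paste0(prefix, "_sidecar.json"),
                                 simplifyVector = TRUE)
  bold <- structure(list(
    data = rd("bold"),
    tr_s = sidecar$tr_s,
    mask = rd("mask") > 0,
    parcellation = rd("parc"),
    voxel_dims_mm = sidecar$voxel_dims_mm,
    truth_cvr = rd("truth"),
    params = sidecar$params
  ), class = "bold_dataset")
  discard_initial_volumes(bold, n = discard)
}

#' Write an RGE series or any tidy result table as CSV
#'
#' @param x a tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path)
  invisible(path)
}
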