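# broom-style tidiers for the package's result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a wavelet-coherence result into a long tibble
#'
#' @param x a `wtc_result`.
#' @param ... unused.
#' @return tibble with one row per (scale, time) cell: `period_s`,
#'   `freq_hz`, `time_s`, `coherence`, `phase`, `in_coi`, `significant`
#'   (`NA` when no threshold is attached).
#' @export
tidy.wtc_result <- function(x, ...) {
  n_s <- length(x$periods)
  n_t <- length(x$times)
  sig <- if (is.null(x$sig_threshold)) {
    NA
  } else {
    sweep(x$coherence, 1, x$sig_threshold, `>`)
  }
  tibble::tibble(
    period_s = rep(x$periods, times = n_t),
    freq_hz = rep(x$freqs, times = n_t),
    time_s = rep(x$times, each = n_s),
    coherence = as.vector(x$coherence),
    phase = as.vector(x$phase),
    in_coi = as.vector(!off_coi_mask(x)),
    significant = if (is.logical(sig)) NA else as.vector(sig)
  )
}

#' @rdname tidy.wtc_result
#' @export
glance.wtc_result <- function(x, ...) {
  off <- off_coi_mask(x)
  tibble::tibble(
    n_scales = length(x$scales),
    n_times = length(x$times),
    dt_s = x$params$dt,
    mean_offcoi_coherence = mean(x$coherence[off]),
    has_threshold = !is.null(x$sig_threshold)
  )
}

#' Tidy CVR maps into a per-voxel tibble
#'
#' @param x a `cvr_maps` object.
#' @param ... unused.
#' @return tibble with voxel indices `i`, `j`, `k` and columns `slope`,
#'   `tstat`, `p`, `in_mask`, `significant`.
#' @export
tidy.cvr_maps <- function(x, ...) {
  d <- dim(x$slope)
  idx <- arrayInd(seq_len(prod(d)), d)
  tibble::tibble(
    i = idx[, 1], j = idx[, 2], k = idx[, 3],
    slope = as.vector(x$slope),
    tstat = as.vector(x$tstat),
    p = as.vector(x$p),
    in_mask = as.vector(x$mask),
    significant = if (is.null(x$sig_mask)) NA else as.vector(x$sig_mask)
  )
}

#' @rdname tidy.cvr_maps
#' @export
glance.cvr_maps <- function(x, ...) {
  inm <- x$mask
  tibble::tibble(
    regressor = x$regressor_name,
    n_voxels = sum(inm),
    mean_slope = mean(x$slope[inm], na.rm = TRUE),
    pct_significant = if (is.null(x$sig_mask)) NA_real_ else
      100 * sum(x$sig_mask[inm]) / sum(inm),
    cluster_min_mm3 = x$cluster_min_mm3
  )
}
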