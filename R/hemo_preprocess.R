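#' Remove artifactual spikes from a velocity trace with a running median
#'
#' @param v a `cbfv_trace` tibble (`time_s`, `velocity`) with attribute
#'   `fs`, or any tibble with those columns plus an `fs` argument.
#' @param window_s median window, seconds; rounded to an odd number of
#'   samples (>= 3). Edges are handled by reflection.
#' @param fs sampling rate, Hz (taken from the object when present).
#' @return the trace with `velocity` median-filtered.
#' @export
despike_median <- function(v, window_s = 0.1, fs = attr(v, "fs")) {
  stopifnot(!is.null(fs))
  k <- max(3L, round(window_s * fs))
  if (k %% 2L == 0L) k <- k + 1L
  n <- nrow(v)
  if (k > n) stop_cvreact("Median window is longer than the trace.")
  h <- (k - 1L) %/% 2L
  x <- v$velocity
  xp <- c(rev(x[seq_len(h) + 1L]), x, rev(x[n - seq_len(h)]))
  v$velocity <- as.numeric(runmed(xp, k, endrule = "keep"))[(h + 1L):(h + n)]
  v
}

#' Detect cardiac cycles on a blood-flow-velocity trace
#'
#' Finds systolic peaks by prominence-based search with the inter-beat
#' interval constrained to `hr_range_bpm`, then places the end-diastolic
#' trough between consecutive peaks, enforcing peak/trough alternation.
#' Inter-beat gaps longer than allowed by the heart-rate range are
#' flagged as artifact gaps rather than interpolated.
#'
#' @param v a `cbfv_trace` tibble with attribute `fs`.
#' @param hr_range_bpm plausible heart-rate range `(lo, hi)`, beats/min.
#' @param fs sampling rate, Hz.
#' @return A tibble of beats: `t_systolic_s`, `t_diastolic_s` (the trough
#'   following the peak), and `gap_after` (`TRUE` when the interval to
#'   the next peak exceeds the heart-rate range, marking an artifact
#'   gap). Empty, with a warning, for a flat trace.
#' @export
detect_cardiac_cycles <- function(v, hr_range_bpm = c(40, 120),
                                  fs = attr(v, "fs")) {
  stopifnot(!is.null(fs))
  x <- v$velocity
  empty <- tibble::tibble(t_systolic_s = numeric(0),
                          t_diastolic_s = numeric(0),
                          gap_after = logical(0))
  if (sd(x) < .Machine$double.eps^0.5) {
    warn("Flat velocity trace: no cardiac cycles detected.")
    return(empty)
  }
  min_ibi <- 60 / hr_range_bpm[2]
  max_ibi <- 60 / hr_range_bpm[1]
  prom <- 0.25 * stats::IQR(x)
  peaks <- find_peaks(x, min_prominence = prom,
                      min_separation = round(min_ibi * fs))
  if (length(peaks) < 2L) {
    warn("Fewer than two systolic peaks found.")
    return(empty)
  }
  troughs <- vapply(seq_len(length(peaks) - 1L), function(j) {
    w <- peaks[j]:peaks[j + 1L]
    w[which.min(x[w])]
  }, integer(1))
  ibi <- diff(v$time_s[peaks])
  tibble::tibble(
    t_systolic_s = v$time_s[peaks[-length(peaks)]],
    t_diastolic_s = v$time_s[troughs],
    gap_after = ibi > max_ibi
  )
}

#' Beat-average a velocity trace and convert to percent change
#'
#' Averages the velocity over each cardiac cycle (systolic peak to the
#' next systolic peak), stamps the mean at the cycle midpoint, drops
#' cycles flagged as artifact gaps or overlapping user-supplied artifact
#' spans, and converts the cycle means to percent change against the
#' baseline window via [percent_change()].
#'
#' @param v a `cbfv_trace` tibble.
#' @param beats beat table from [detect_cardiac_cycles()].
#' @param artifact_spans optional two-column matrix/data frame of
#'   `(start_s, end_s)` intervals to exclude.
#' @param baseline_window_s baseline window `(start, end)`, seconds.
#' @param fs sampling rate, Hz.
#' @return A `hemo_series` tibble: `time_s`, `value` (percent change).
#' @export
beat_average <- function(v, beats, artifact_spans = NULL,
                         baseline_window_s = c(0, 30), fs = attr(v, "fs")) {
  stopifnot(!is.null(fs), nrow(beats) >= 1L)
  t_start <- beats$t_systolic_s
  t_end <- c(beats$t_systolic_s[-1L],
             beats$t_systolic_s[nrow(beats)] +
               median(diff(beats$t_systolic_s)))
  keep <- !beats$gap_after
  if (!is.null(artifact_spans)) {
    spans <- as.matrix(artifact_spans)
    overlaps <- vapply(seq_along(t_start), function(i) {
      any(t_start[i] < spans[, 2] & t_end[i] > spans[, 1])
    }, logical(1))
    keep <- keep & !overlaps
  }
  means <- vapply(seq_along(t_start), function(i) {
    mean(v$velocity[v$time_s >= t_start[i] & v$time_s < t_end[i]])
  }, numeric(1))
  cycles <- tibble::tibble(time_s = (t_start + t_end) / 2,
                           value = means)[keep, ]
  percent_change(cycles, baseline_window_s = baseline_window_s)
}

#' Convert a series to percent change against an initial baseline
#'
#' `value_t = 100 * (x_t - mean_baseline) / mean_baseline`, where the
#' baseline is the mean over `baseline_window_s` -- by convention the
#' first 30 s of the record, before the first challenge epoch.
#'
#' @param series tibble with `time_s` and `value`.
#' @param baseline_window_s `(start, end)` seconds.
#' @return A `hemo_series` tibble (`time_s`, `value` in percent), with
#'   attribute `baseline_window_s`.
#' @export
percent_change <- function(series, baseline_window_s = c(0, 30)) {
  stopifnot(is.data.frame(series), all(c("time_s", "value") %in% names(series)))
  inb <- series$time_s >= baseline_window_s[1] &
    series$time_s <= baseline_window_s[2]
  if (!any(inb)) stop_cvreact("Baseline window lies outside the record.")
  b <- mean(series$value[inb])
  if (!is.finite(b) || b <= 0) {
    stop_cvreact("Baseline mean must be positive for percent change.",
                 "cvreact_bad_baseline")
  }
  out <- tibble::tibble(time_s = series$time_s,
                        value = 100 * (series$value - b) / b)
  tibble::new_tibble(out, class = "hemo_series",
                     baseline_window_s = baseline_window_s)
}

#' Normalize and polynomially detrend a BOLD voxel series
#'
#' Divides the series by its temporal mean (x100, giving percent of
#' mean), removes a least-squares polynomial of the given order to strip
#' slow scanner drift, and recenters the residual at 0 percent. A
#' constant series returns zeros.
#'
#' @param y numeric voxel time series (raw intensity).
#' @param order polynomial order (default 5).
#' @return numeric percent-change series, mean zero.
#' @export
detrend_bold <- function(y, order = 5L) {
  n <- length(y)
  if (n <= order + 1L) stop_cvreact("Series shorter than the polynomial basis.")
  m <- mean(y)
  if (!is.finite(m) || m == 0 || sd(y) == 0) return(numeric(n))
  pct <- 100 * y / m
  if (order == 0L) return(pct - mean(pct))
  basis <- poly(seq_len(n), degree = order)
  r <- stats::lm.fit(cbind(1, basis), pct)$residuals
  r - mean(r)
}

#' Extract detrended ROI-mean BOLD series from a 4D dataset
#'
#' Applies [detrend_bold()] to every in-mask voxel of each requested
#' parcellation region and averages per volume. Standard labels
#' `LGM`, `RGM`, `LWM`, `RWM` map to regions 1--4 of the default
#' synthetic parcellation; integer label ids are accepted directly.
#'
#' @param bold a `bold_dataset`.
#' @param labels character or integer vector of region labels.
#' @param detrend_order polynomial order passed to [detrend_bold()].
#' @return A named list of `hemo_series` tibbles (`time_s`, `value`),
#'   one per label.
#' @export
extract_roi <- function(bold, labels = c("LGM", "RGM", "LWM", "RWM"),
                        detrend_order = 5L) {
  stopifnot(inherits(bold, "bold_dataset"))
  std <- c(LGM = 1L, RGM = 2L, LWM = 3L, RWM = 4L)
  ids <- if (is.character(labels)) {
    unname(std[labels])
  } else {
    as.integer(labels)
  }
  if (any(is.na(ids))) stop_cvreact("Unknown ROI label.")
  d <- dim(bold$data)
  n_vol <- d[4]
  t_vol <- (seq_len(n_vol) - 1L) * bold$tr_s
  mat <- matrix(bold$data, prod(d[1:3]), n_vol)
  out <- purrr::map(seq_along(ids), function(j) {
    sel <- which(as.vector(bold$parcellation) == ids[j] & as.vector(bold$mask))
    if (length(sel) == 0L) {
      stop_cvreact(sprintf("Parcellation label '%s' selects no voxels.",
                           as.character(labels[j])), "cvreact_empty_label")
    }
    det <- t(apply(mat[sel, , drop = FALSE], 1, detrend_bold,
                   order = detrend_order))
    tibble::new_tibble(
      tibble::tibble(time_s = t_vol, value = colMeans(det)),
      class = "hemo_series", baseline_window_s = NULL)
  })
  names(out) <- as.character(labels)
  out
}

#' Discard initial pre-equilibrium volumes from a BOLD dataset
#'
#' The first volumes of an EPI run are acquired before equilibrium
#' magnetization and are dropped once, at read time, before any other
#' processing.
#'
#' @param bold a `bold_dataset`.
#' @param n number of volumes to discard (default 12).
#' @return the trimmed `bold_dataset`.
#' @export
discard_initial_volumes <- function(bold, n = 12L) {
  d <- dim(bold$data)
  if (n >= d[4]) stop_cvreact("Cannot discard all volumes.")
  if (n > 0L) {
    bold$data <- bold$data[, , , -(seq_len(n)), drop = FALSE]
    bold$n_discarded <- n
  }
  bold
}
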