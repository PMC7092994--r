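#' Align two series onto a common uniform grid
#'
#' Linearly interpolates both series onto a shared grid spanning the
#' overlap of their time supports; non-overlapping ends are trimmed.
#'
#' @param a,b tibbles with `time_s` and one numeric value column (the
#'   first non-time numeric column is used).
#' @param grid_dt_s grid spacing, seconds.
#' @return tibble with `time_s`, `a`, `b`.
#' @export
align_series <- function(a, b, grid_dt_s = 0.5) {
  va <- value_column(a); vb <- value_column(b)
  lo <- max(min(a$time_s), min(b$time_s))
  hi <- min(max(a$time_s), max(b$time_s))
  if (hi <= lo) stop_cvreact("Series have disjoint time supports.",
                             "cvreact_no_overlap")
  grid <- seq(lo, hi, by = grid_dt_s)
  if (length(grid) < 10L) {
    stop_cvreact("Overlap shorter than 10 grid points.", "cvreact_no_overlap")
  }
  tibble::tibble(
    time_s = grid,
    a = approx(a$time_s, a[[va]], xout = grid, ties = "ordered")$y,
    b = approx(b$time_s, b[[vb]], xout = grid, ties = "ordered")$y
  )
}

value_column <- function(x) {
  stopifnot(is.data.frame(x), "time_s" %in% names(x))
  cand <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], "time_s")
  if (length(cand) == 0L) stop_cvreact("No numeric value column found.")
  cand[1]
}

#' Pearson correlation with Fisher Z transform
#'
#' Correlates two aligned series: Pearson r, a two-sided p-value from the
#' t distribution with n - 2 degrees of freedom, and the Fisher
#' Z = atanh(r) used for group statistics. A correlation of exactly
#' +/- 1 would give an infinite Z; it is capped at `atanh(1 - 1e-15)`
#' and flagged `saturated`.
#'
#' @param pair tibble with columns `a` and `b` (from [align_series()]),
#'   or supply `a` and `b` vectors via the two-argument form
#'   `correlate_series(a, b)`.
#' @param b optional second vector when `pair` is a numeric vector.
#' @param metric_name,source_label optional labels carried into the
#'   result.
#' @return A one-row `coupling_result` tibble: `metric_name`,
#'   `source_label`, `r`, `p`, `z`, `n_points`, `saturated`.
#' @export
correlate_series <- function(pair, b = NULL, metric_name = NA_character_,
                             source_label = NA_character_) {
  if (is.numeric(pair) && !is.null(b)) {
    pair <- tibble::tibble(a = pair, b = b)
  }
  x <- pair$a; y <- pair$b
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_cvreact("Need at least 3 paired points.")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_cvreact("zero variance: cannot correlate a constant series.",
                 "cvreact_zero_variance")
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * pt(-abs(tstat), df = n - 2)
  saturated <- abs(r) >= 1 - 1e-15
  z <- atanh(if (saturated) sign(r) * (1 - 1e-15) else r)
  tibble::new_tibble(
    tibble::tibble(metric_name = metric_name, source_label = source_label,
                   r = r, p = p, z = z, n_points = n,
                   saturated = saturated),
    class = "coupling_result")
}

#' Correlate every RGE metric with a hemodynamic series
#'
#' Convenience wrapper: resamples the RGE series over breath holds,
#' aligns each metric with the hemodynamic series on a common grid and
#' returns one [correlate_series()] row per metric.
#'
#' @param rge an `rge_series`.
#' @param hemo a `hemo_series` (`time_s`, `value`).
#' @param metrics metric columns to use.
#' @param grid_dt_s alignment grid, seconds.
#' @param source_label label carried into the results.
#' @return a `coupling_result` tibble with one row per metric.
#' @export
couple_rge_hemo <- function(rge, hemo, metrics = c("ber", "dpo2", "dpco2", "tob_s"),
                            grid_dt_s = 0.5, source_label = NA_character_) {
  res <- interpolate_over_breath_holds(rge, grid_dt_s = grid_dt_s,
                                       metrics = metrics)
  purrr::map_dfr(metrics, function(m) {
    a <- tibble::tibble(time_s = res$time_s, value = res[[m]])
    a <- a[is.finite(a$value), ]
    pair <- align_series(a, hemo, grid_dt_s = grid_dt_s)
    correlate_series(pair, metric_name = m, source_label = source_label)
  })
}

#' Paired comparison of Fisher Z scores against a reference metric
#'
#' For each metric other than the reference, runs a paired t-test of the
#' per-subject Fisher Z scores (reference vs metric) within each source
#' label. Subjects with a missing value in a pair are dropped pairwise.
#'
#' @param z_table tibble with columns `subject`, `source_label`,
#'   `metric_name`, `z`.
#' @param reference_metric the reference (default `"ber"`).
#' @return tibble with one row per (source_label, metric): `metric_a`,
#'   `metric_b`, `mean_dz`, `t`, `p`, `n_subjects`. Zero-variance
#'   differences are flagged `degenerate` with `p = 0`.
#' @export
compare_metric_correlations <- function(z_table, reference_metric = "ber") {
  stopifnot(all(c("subject", "source_label", "metric_name", "z") %in%
                  names(z_table)))
  wide <- tidyr::pivot_wider(z_table, id_cols = c("subject", "source_label"),
                             names_from = "metric_name", values_from = "z")
  others <- setdiff(unique(z_table$metric_name), reference_metric)
  purrr::map_dfr(unique(wide$source_label), function(lab) {
    w <- wide[wide$source_label == lab, ]
    purrr::map_dfr(others, function(m) {
      d <- w[[reference_metric]] - w[[m]]
      d <- d[is.finite(d)]
      n <- length(d)
      if (n < 3L) stop_cvreact("Need at least 3 complete subject pairs.")
      if (sd(d) == 0) {
        if (all(d == 0)) {
          return(tibble::tibble(source_label = lab,
                                metric_a = reference_metric, metric_b = m,
                                mean_dz = 0, t = 0, p = 1, n_subjects = n,
                                degenerate = FALSE))
        }
        return(tibble::tibble(source_label = lab,
                              metric_a = reference_metric, metric_b = m,
                              mean_dz = mean(d), t = Inf * sign(mean(d)),
                              p = 0, n_subjects = n, degenerate = TRUE))
      }
      tt <- t.test(d)
      tibble::tibble(source_label = lab, metric_a = reference_metric,
                     metric_b = m, mean_dz = mean(d),
                     t = unname(tt$statistic), p = tt$p.value,
                     n_subjects = n, degenerate = FALSE)
    })
  })
}

#' Pairwise correlation matrix of RGE metrics
#'
#' @param rge an `rge_series`.
#' @param metrics metric columns to include.
#' @return symmetric correlation matrix with unit diagonal (pairwise
#'   complete observations; the first breath's undefined `tob_s` is
#'   dropped pairwise).
#' @export
metric_intercorrelation <- function(rge,
                                    metrics = c("ber", "dpo2", "dpco2",
                                                "petco2", "peto2", "tob_s")) {
  m <- as.matrix(rge[, metrics])
  if (nrow(m) < 3L) stop_cvreact("Need at least 3 breaths.")
  cor(m, use = "pairwise.complete.obs")
}
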