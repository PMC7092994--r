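#' Voxelwise CVR regression of BOLD percent change on a vasoactive regressor
#'
#' Cerebrovascular reactivity is the percent BOLD signal change per unit
#' change of the vasoactive stimulus, quantified as the slope of an
#' ordinary least-squares regression (with intercept) of each in-mask
#' voxel's percent-change series on the regressor. Voxel series are
#' detrended with [detrend_bold()] unless `detrend_order` is `NA`.
#'
#' @param bold a `bold_dataset` (raw intensity; detrended internally).
#' @param regressor tibble with `time_s`, `value` sampled at the TR grid
#'   (resampled linearly if not), or a numeric vector of length
#'   `n_volumes`.
#' @param regressor_name label stored in the result (`"ber"`,
#'   `"petco2"`, `"tob"`, ...).
#' @param detrend_order polynomial detrending order; `NA` to skip.
#' @return A `cvr_maps` object: list with 3D arrays `slope`, `tstat`,
#'   `p`, the `mask`, `voxel_dims_mm`, `regressor_name`, and slots
#'   `sig_mask` / `cluster_min_mm3` filled by
#'   [apply_cluster_threshold()].
#' @export
regress_voxelwise <- function(bold, regressor, regressor_name = "ber",
                              detrend_order = 5L) {
  stopifnot(inherits(bold, "bold_dataset"))
  d <- dim(bold$data)
  n_vol <- d[4]
  x <- if (is.numeric(regressor)) {
    if (length(regressor) != n_vol) {
      stop_cvreact("Regressor length must equal the number of volumes.")
    }
    as.numeric(regressor)
  } else {
    t_vol <- (seq_len(n_vol) - 1L) * bold$tr_s
    approx(regressor$time_s, regressor[[value_column(regressor)]],
           xout = t_vol, rule = 2)$y
  }
  if (sd(x) == 0) stop_cvreact("Constant regressor.", "cvreact_zero_variance")

  mat <- matrix(bold$data, prod(d[1:3]), n_vol)
  sel <- which(as.vector(bold$mask))
  ymat <- mat[sel, , drop = FALSE]
  if (!is.na(detrend_order)) {
    ymat <- t(apply(ymat, 1, detrend_bold, order = detrend_order))
  }

  xc <- x - mean(x)
  sxx <- sum(xc^2)
  yc <- ymat - rowMeans(ymat)
  slope <- as.vector(yc %*% xc) / sxx
  df <- n_vol - 2L
  rss <- rowSums((yc - outer(slope, xc))^2)
  se <- sqrt(rss / df / sxx)
  tstat <- slope / se
  pval <- 2 * pt(-abs(tstat), df = df)

  mk_vol <- function(v) {
    out <- array(NA_real_, dim = d[1:3])
    out[sel] <- v
    out
  }
  structure(list(slope = mk_vol(slope), tstat = mk_vol(tstat),
                 p = mk_vol(pval), mask = bold$mask,
                 voxel_dims_mm = bold$voxel_dims_mm,
                 regressor_name = regressor_name,
                 sig_mask = NULL, cluster_min_mm3 = NA_real_,
                 voxel_p = NA_real_, n_volumes = n_vol),
            class = "cvr_maps")
}

#' @export
print.cvr_maps <- function(x, ...) {
  d <- dim(x$slope)
  cat(sprintf("<cvr_maps: %dx%dx%d, regressor '%s'%s>\n", d[1], d[2], d[3],
              x$regressor_name,
              if (is.null(x$sig_mask)) "" else
                sprintf(", cluster-corrected at %.0f mm3", x$cluster_min_mm3)))
  invisible(x)
}

# Label face-adjacent (6-neighbor) connected components of a 3D logical
# array. Returns an integer array of labels (0 = background).
label_clusters <- function(mask3d) {
  d <- dim(mask3d)
  n <- prod(d)
  lab <- integer(n)
  idx <- which(mask3d)
  if (length(idx) == 0L) return(array(lab, dim = d))
  nxy <- d[1] * d[2]
  current <- 0L
  queue <- integer(length(idx))
  inmask <- logical(n)
  inmask[idx] <- TRUE
  for (start in idx) {
    if (lab[start] != 0L) next
    current <- current + 1L
    qh <- 1L; qt <- 1L
    queue[1L] <- start
    lab[start] <- current
    while (qh <= qt) {
      v <- queue[qh]; qh <- qh + 1L
      i <- (v - 1L) %% d[1] + 1L
      j <- ((v - 1L) %/% d[1]) %% d[2] + 1L
      k <- (v - 1L) %/% nxy + 1L
      nb <- c(if (i > 1L) v - 1L, if (i < d[1]) v + 1L,
              if (j > 1L) v - d[1], if (j < d[2]) v + d[1],
              if (k > 1L) v - nxy, if (k < d[3]) v + nxy)
      for (w in nb) {
        if (inmask[w] && lab[w] == 0L) {
          lab[w] <- current
          qt <- qt + 1L
          queue[qt] <- w
        }
      }
    }
  }
  array(lab, dim = d)
}

# separable Gaussian smoothing of a 3D array (FWHM in mm per axis)
smooth_gaussian_3d <- function(vol, fwhm_mm, voxel_dims_mm) {
  if (all(fwhm_mm <= 0)) return(vol)
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  d <- dim(vol)
  for (ax in 1:3) {
    sig_vox <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / voxel_dims_mm[ax]
    if (sig_vox <= 0) next
    half <- max(1L, ceiling(3 * sig_vox))
    kern <- exp(-0.5 * ((-half):half / sig_vox)^2)
    kern <- kern / sum(kern)
    vol <- apply(vol, setdiff(1:3, ax), function(line) {
      np <- length(line) + 2L * half
      xp <- c(rep(line[1], half), line, rep(line[length(line)], half))
      as.numeric(stats::filter(xp, kern, sides = 2))[(half + 1L):(half + length(line))]
    })
    vol <- aperm(array(vol, dim = c(d[ax], d[setdiff(1:3, ax)])),
                 order(c(ax, setdiff(1:3, ax))))
  }
  vol
}

#' Calibrate the cluster-extent threshold by Monte Carlo simulation
#'
#' Estimates the minimum cluster volume guaranteeing a family-wise
#' cluster significance of `alpha` when voxels are thresholded at
#' `voxel_p`: simulates `n_iter` null volumes of Gaussian noise smoothed
#' to `smoothness_mm` FWHM, thresholds each at the two-sided `voxel_p`
#' level, records the largest face-adjacent cluster, and returns the
#' smallest cluster size whose exceedance probability under the null is
#' at most `alpha`, converted to mm3.
#'
#' @param mask 3D logical array defining the search volume.
#' @param voxel_dims_mm voxel dimensions, mm.
#' @param voxel_p per-voxel probability threshold (default 0.005).
#' @param alpha family-wise significance level (default 0.05).
#' @param n_iter Monte Carlo iterations (>= 100; 2000 for production
#'   use).
#' @param smoothness_mm assumed spatial smoothness (FWHM, mm); 0 for
#'   unsmoothed noise.
#' @param seed integer seed.
#' @return list with `cluster_min_mm3`, `cluster_min_voxels`, and
#'   `max_cluster_sizes` (the simulated null distribution).
#' @export
cluster_extent_calibrate <- function(mask, voxel_dims_mm = c(3.4, 3.4, 6),
                                     voxel_p = 0.005, alpha = 0.05,
                                     n_iter = 2000, smoothness_mm = 8,
                                     seed = 1L) {
  if (n_iter < 100) stop_cvreact("Need at least 100 iterations.",
                                 "cvreact_invalid_parameter")
  d <- dim(mask)
  fov_mm <- d * voxel_dims_mm
  if (any(smoothness_mm >= fov_mm)) {
    stop_cvreact("Smoothness exceeds the field of view.",
                 "cvreact_invalid_parameter")
  }
  zthr <- qnorm(1 - voxel_p / 2)
  maxes <- with_seed(seed, {
    vapply(seq_len(n_iter), function(b) {
      vol <- array(rnorm(prod(d)), dim = d)
      if (any(smoothness_mm > 0)) {
        vol <- smooth_gaussian_3d(vol, smoothness_mm, voxel_dims_mm)
        vol <- (vol - mean(vol)) / sd(vol)
      }
      supra <- abs(vol) > zthr & mask
      if (!any(supra)) return(0L)
      lab <- label_clusters(supra)
      max(tabulate(lab[lab > 0L]))
    }, integer(1))
  })
  k <- 1L
  while (mean(maxes >= k) > alpha) k <- k + 1L
  list(cluster_min_voxels = k,
       cluster_min_mm3 = k * prod(voxel_dims_mm),
       max_cluster_sizes = maxes,
       voxel_p = voxel_p, alpha = alpha, n_iter = n_iter, seed = seed)
}

#' Apply a cluster-extent threshold to CVR maps
#'
#' Groups voxels with `p < voxel_p` by face adjacency and keeps clusters
#' whose volume reaches `cluster_min_mm3` (boundary included).
#'
#' @param maps a `cvr_maps` object.
#' @param cluster_min_mm3 minimum cluster volume, mm3 (from
#'   [cluster_extent_calibrate()]).
#' @param voxel_p per-voxel threshold (default 0.005).
#' @return the `cvr_maps` with `sig_mask` filled in.
#' @export
apply_cluster_threshold <- function(maps, cluster_min_mm3,
                                    voxel_p = 0.005) {
  stopifnot(inherits(maps, "cvr_maps"))
  supra <- !is.na(maps$p) & maps$p < voxel_p & maps$mask
  sig <- array(FALSE, dim = dim(supra))
  if (any(supra)) {
    lab <- label_clusters(supra)
    sizes <- tabulate(lab[lab > 0L])
    vox_mm3 <- prod(maps$voxel_dims_mm)
    good <- which(sizes * vox_mm3 >= cluster_min_mm3)
    sig <- array(lab %in% good & lab > 0L, dim = dim(supra))
  }
  maps$sig_mask <- sig
  maps$cluster_min_mm3 <- cluster_min_mm3
  maps$voxel_p <- voxel_p
  maps
}

#' Regional CVR and vCVR summary
#'
#' Per parcellation region: the mean CVR slope and `vcvr`, the
#' percentage of the region's voxels whose CVR survived cluster
#' correction -- the precision with which the vasoactive stimulus
#' predicts the regional hemodynamic response.
#'
#' @param maps a `cvr_maps` with `sig_mask` attached.
#' @param parcellation 3D integer label array (0 = background).
#' @param region_names optional named character vector mapping ids to
#'   names.
#' @return tibble with `region_id`, `region_name`, `n_voxels`,
#'   `mean_cvr`, `vcvr` (empty regions get `n_voxels = 0` and `NA`
#'   summaries).
#' @export
regional_summary <- function(maps, parcellation,
                             region_names = c(`1` = "LGM", `2` = "RGM",
                                              `3` = "LWM", `4` = "RWM")) {
  stopifnot(inherits(maps, "cvr_maps"))
  if (is.null(maps$sig_mask)) {
    stop_cvreact("Apply a cluster threshold before summarizing (see apply_cluster_threshold()).")
  }
  if (!identical(dim(parcellation), dim(maps$slope))) {
    stop_cvreact("Parcellation grid does not match the maps.",
                 "cvreact_grid_mismatch")
  }
  ids <- sort(setdiff(unique(as.vector(parcellation)), 0L))
  purrr::map_dfr(ids, function(id) {
    inr <- parcellation == id & maps$mask
    n <- sum(inr)
    tibble::tibble(
      region_id = id,
      region_name = unname(region_names[as.character(id)]) %||% as.character(id),
      n_voxels = n,
      mean_cvr = if (n > 0) mean(maps$slope[inr], na.rm = TRUE) else NA_real_,
      vcvr = if (n > 0) 100 * sum(maps$sig_mask[inr]) / n else NA_real_
    )
  })
}

#' Voxelwise one-sample group test with FDR control
#'
#' One-sample t-test of subject volumes against zero at every in-mask
#' voxel, with Benjamini-Hochberg false-discovery-rate adjustment across
#' in-mask voxels. Voxels with zero between-subject variance are flagged
#' (`NA` statistics).
#'
#' @param vols list of 3D arrays (one per subject, common grid).
#' @param mask 3D logical array.
#' @return list with 3D arrays `t`, `p`, `p_fdr`, and
#'   `zero_variance` (logical).
#' @export
group_onesample <- function(vols, mask = NULL) {
  stopifnot(length(vols) >= 3L)
  d <- dim(vols[[1]])
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  mat <- vapply(vols, as.vector, numeric(prod(d)))
  sel <- which(as.vector(mask))
  m <- rowMeans(mat[sel, , drop = FALSE])
  s <- apply(mat[sel, , drop = FALSE], 1, sd)
  n <- length(vols)
  # an exactly-zero difference with zero spread is a clean null (t = 0);
  # a nonzero mean with zero spread is degenerate and flagged
  zerov <- s == 0 & m != 0
  tstat <- ifelse(s == 0, ifelse(m == 0, 0, NA_real_), m / (s / sqrt(n)))
  pval <- 2 * pt(-abs(tstat), df = n - 1)
  p_fdr <- rep(NA_real_, length(sel))
  ok <- !is.na(pval)
  p_fdr[ok] <- p.adjust(pval[ok], method = "BH")
  mk <- function(v, init = NA_real_) {
    out <- array(init, dim = d); out[sel] <- v; out
  }
  list(t = mk(tstat), p = mk(pval), p_fdr = mk(p_fdr),
       zero_variance = mk(zerov, init = FALSE))
}

#' Voxelwise paired group test with FDR control
#'
#' Paired t-test between two matched lists of subject volumes (a - b),
#' Benjamini-Hochberg adjusted across in-mask voxels.
#'
#' @param vols_a,vols_b matched lists of 3D arrays (same subjects, same
#'   order).
#' @param mask 3D logical array.
#' @return as [group_onesample()], for the paired differences.
#' @export
group_paired <- function(vols_a, vols_b, mask = NULL) {
  if (length(vols_a) != length(vols_b)) {
    stop_cvreact("Subject lists must be matched.", "cvreact_unmatched")
  }
  diffs <- purrr::map2(vols_a, vols_b, `-`)
  group_onesample(diffs, mask = mask)
}
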