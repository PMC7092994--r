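mk_maps <- function(p_vol, mask = NULL, vox = c(1, 1, 1)) {
  d <- dim(p_vol)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  structure(list(slope = array(1, d), tstat = array(1, d), p = p_vol,
                 mask = mask, voxel_dims_mm = vox, regressor_name = "x",
                 sig_mask = NULL, cluster_min_mm3 = NA_real_,
                 voxel_p = NA_real_, n_volumes = 100),
            class = "cvr_maps")
}

test_that("a noiseless linear voxel recovers its slope exactly", {
  p <- generate_protocol("breath_hold", 1, 30, c(60, 60), seed = 1)
  tv <- seq(0, 160, by = 1.45)
  reg <- tibble::tibble(time_s = tv, value = sin(tv / 10))
  bd <- simulate_bold(p, reg, truth_cvr = 2,
                      hemo_sim_params(response_delay_s = 0,
                                      dispersion_tau_s = 0, noise_sd = 0),
                      grid = c(4, 4, 2), tr_s = 1.45, n_volumes = 100)
  m <- regress_voxelwise(bd, bd$regressor, detrend_order = NA)
  expect_equal(as.vector(m$slope), rep(2, 32), tolerance = 1e-10)
  expect_lt(max(m$p), 1e-20)
  expect_error(regress_voxelwise(bd, rep(1, 100)),
               class = "cvreact_zero_variance")
})

test_that("pure-noise voxels show near-zero slopes and calibrated p-values", {
  set.seed(20)
  p <- generate_protocol("breath_hold", 1, 30, c(60, 60), seed = 1)
  tv <- seq(0, 600, by = 1.45)
  reg <- tibble::tibble(time_s = tv, value = rnorm(length(tv)))
  bd <- simulate_bold(p, reg, truth_cvr = 0,
                      hemo_sim_params(noise_sd = 1, ar1_coef = 0,
                                      seed = 21),
                      grid = c(8, 8, 4), tr_s = 1.45, n_volumes = 400)
  m <- regress_voxelwise(bd, bd$regressor, detrend_order = NA)
  expect_lt(abs(mean(m$slope)), 0.01)
  # p roughly uniform: about 5% below 0.05
  expect_lt(abs(mean(m$p < 0.05) - 0.05), 0.05)
})

test_that("slope recovery is unbiased against the stored ground truth", {
  p <- generate_protocol("breath_hold", 1, 30, c(60, 60), seed = 1)
  tv <- seq(0, 600, by = 1.45)
  set.seed(22)
  reg <- tibble::tibble(time_s = tv, value = rnorm(length(tv)))
  truth <- array(runif(8 * 8 * 4, 1, 3), c(8, 8, 4))
  bd <- simulate_bold(p, reg, truth,
                      hemo_sim_params(response_delay_s = 0,
                                      dispersion_tau_s = 0,
                                      noise_sd = 1, ar1_coef = 0.3, seed = 23),
                      grid = c(8, 8, 4), tr_s = 1.45, n_volumes = 400)
  m <- regress_voxelwise(bd, bd$regressor, detrend_order = NA)
  se <- abs(m$slope / m$tstat)
  expect_lt(mean(abs(m$slope - truth)), 2 * mean(se))
})

test_that("cluster calibration obeys its limiting and ordering properties", {
  mask <- array(TRUE, c(12, 12, 6))
  cal_loose <- cluster_extent_calibrate(mask, c(1, 1, 1), voxel_p = 0.005,
                                        alpha = 1, n_iter = 100,
                                        smoothness_mm = 0, seed = 31)
  expect_equal(cal_loose$cluster_min_voxels, 1)
  cal5 <- cluster_extent_calibrate(mask, c(1, 1, 1), voxel_p = 0.005,
                                   alpha = 0.05, n_iter = 200,
                                   smoothness_mm = 0, seed = 32)
  cal1 <- cluster_extent_calibrate(mask, c(1, 1, 1), voxel_p = 0.001,
                                   alpha = 0.05, n_iter = 200,
                                   smoothness_mm = 0, seed = 32)
  expect_lte(cal1$cluster_min_mm3, cal5$cluster_min_mm3)
  expect_error(cluster_extent_calibrate(mask, c(1, 1, 1), smoothness_mm = 50),
               class = "cvreact_invalid_parameter")
})

test_that("cluster labeling agrees with an independent graph-components oracle", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:3) {
    supra <- array(runif(16^3) < 0.1, c(16, 16, 16))
    lab <- cvreact:::label_clusters(supra)
    sizes <- sort(tabulate(lab[lab > 0]))
    d <- dim(supra)
    idx <- which(supra)
    ai <- arrayInd(idx, d)
    edges <- NULL
    for (off in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      nb <- sweep(ai, 2, off, `+`)
      ok <- nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
      lin <- (nb[, 3] - 1) * d[1] * d[2] + (nb[, 2] - 1) * d[1] + nb[, 1]
      sel <- ok & lin %in% idx
      edges <- rbind(edges, cbind(match(idx[sel], idx), match(lin[sel], idx)))
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, length(idx) - igraph::vcount(g))
    sizes2 <- sort(as.vector(table(igraph::components(g)$membership)))
    expect_equal(as.integer(sizes), as.integer(sizes2))
  }
})

test_that("cluster-extent thresholding respects size and connectivity", {
  d <- c(6, 6, 2)
  # all p = 1: nothing survives
  m0 <- apply_cluster_threshold(mk_maps(array(1, d)), cluster_min_mm3 = 1)
  expect_false(any(m0$sig_mask))
  # one cluster exactly at threshold size is retained
  pv <- array(1, d); pv[2:4, 2, 1] <- 1e-6
  m1 <- apply_cluster_threshold(mk_maps(pv), cluster_min_mm3 = 3)
  expect_equal(sum(m1$sig_mask), 3)
  # checkerboard: all clusters are singletons under face adjacency
  pv2 <- array(1, d)
  idx <- arrayInd(seq_len(prod(d)), d)
  pv2[(idx[, 1] + idx[, 2] + idx[, 3]) %% 2 == 0] <- 1e-6
  m2 <- apply_cluster_threshold(mk_maps(pv2), cluster_min_mm3 = 2)
  expect_false(any(m2$sig_mask))
  m3 <- apply_cluster_threshold(mk_maps(pv2), cluster_min_mm3 = 1)
  expect_equal(sum(m3$sig_mask), sum(pv2 < 0.005))
})

test_that("regional summaries count significant voxels as percentages", {
  d <- c(4, 4, 2)
  parc <- array(1L, d); parc[3:4, , ] <- 2L
  pv <- array(1, d)
  pv[1:2, , ] <- 1e-6                      # region 1 fully significant
  pv[3, 1:2, 1] <- 1e-6                    # 2 of 16 voxels in region 2
  maps <- apply_cluster_threshold(mk_maps(pv), cluster_min_mm3 = 1)
  out <- regional_summary(maps, parc, region_names = c(`1` = "A", `2` = "B"))
  expect_equal(out$vcvr[out$region_name == "A"], 100)
  expect_equal(out$vcvr[out$region_name == "B"], 100 * 2 / 16)
  # half-significant region
  pv3 <- array(1, d); pv3[, , 1] <- 1e-6
  m3 <- apply_cluster_threshold(mk_maps(pv3), cluster_min_mm3 = 1)
  out3 <- regional_summary(m3, array(1L, d))
  expect_equal(out3$vcvr, 50)
})

test_that("vcvr is monotone non-increasing in the cluster threshold", {
  set.seed(34)
  pv <- array(runif(8 * 8 * 4)^3, c(8, 8, 4))
  maps <- mk_maps(pv)
  v <- vapply(c(1, 2, 4, 8), function(k) {
    m <- apply_cluster_threshold(maps, cluster_min_mm3 = k)
    regional_summary(m, array(1L, dim(pv)))$vcvr
  }, numeric(1))
  expect_true(all(diff(v) <= 0))
})

test_that("group one-sample maps match a hand-rolled step-up FDR", {
  set.seed(35)
  d <- c(5, 5, 2)
  vols <- lapply(1:8, function(i) array(rnorm(prod(d), 0.3, 1), d))
  g <- group_onesample(vols)
  # independent Benjamini-Hochberg implementation
  pv <- as.vector(g$p)
  m <- length(pv)
  o <- order(pv)
  adj <- pv[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  expect_equal(as.vector(g$p_fdr)[o], pmin(adj, 1), tolerance = 1e-12)
  # worked step-up example
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
})

test_that("degenerate voxels are flagged and exact nulls give t = 0", {
  d <- c(3, 3, 1)
  vols <- lapply(1:5, function(i) array(2, d))     # identical nonzero
  g <- group_onesample(vols)
  expect_true(all(g$zero_variance))
  expect_true(all(is.na(g$t)))
  gp <- group_paired(vols, vols)                    # a - b identically zero
  expect_true(all(gp$t == 0))
  expect_true(all(gp$p == 1))
  expect_false(any(gp$zero_variance))
  expect_error(group_paired(vols, vols[1:3]), class = "cvreact_unmatched")
})

test_that("a consistent effect survives FDR and an offset is detected paired", {
  d <- c(4, 4, 2)
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    vols <- lapply(1:10, function(i) array(rnorm(prod(d), 0.5, 0.1), d))
    g <- group_onesample(vols)
    hits <- hits + (g$p_fdr[1, 1, 1] < 0.05)
  }
  expect_gte(hits, 19)
  set.seed(36)
  a <- lapply(1:10, function(i) array(rnorm(prod(d), 1, 0.1), d))
  b <- lapply(1:10, function(i) array(rnorm(prod(d), 0, 0.1), d))
  gp <- group_paired(a, b)
  expect_true(all(gp$p_fdr < 0.05))
})
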