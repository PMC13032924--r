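rig <- stereo_rig()

test_that("unclipped shell volumes converge to the analytic sphere-shell volume", {
  vol <- shell_volumes(rig, shell_edges = c(6, 9), clip_mode = "none",
                       mc_samples = 5e4, seed = 1)
  expect_equal(vol$clipped_volume_m3, 4 / 3 * pi * (9^3 - 6^3),
               tolerance = 0.01)
  expect_equal(vol$clipped_volume_m3, vol$full_volume_m3)
})

test_that("shells entirely outside both view frustums have zero volume", {
  vol <- shell_volumes(rig, nacelle_ref = c(0, 800, 100),
                       shell_edges = c(0, 3, 6), mc_samples = 5e3, seed = 2)
  expect_equal(vol$clipped_volume_m3, c(0, 0))
  expect_true(all(is.na(vol$mc_volume_rel_se)))
})

test_that("clipping is monotone: both cameras <= either camera <= unclipped", {
  edges <- seq(0, 60, by = 6)
  v_both <- shell_volumes(rig, shell_edges = edges, clip_mode = "both_cameras",
                          mc_samples = 2e4, seed = 3)
  v_either <- shell_volumes(rig, shell_edges = edges,
                            clip_mode = "either_camera",
                            mc_samples = 2e4, seed = 3)
  v_none <- shell_volumes(rig, shell_edges = edges, clip_mode = "none",
                          mc_samples = 2e4, seed = 3)
  # same seed means the three runs share the Monte-Carlo sample, so the
  # set inclusion holds exactly
  expect_true(all(v_both$clipped_volume_m3 <= v_either$clipped_volume_m3))
  expect_true(all(v_either$clipped_volume_m3 <= v_none$clipped_volume_m3))
})

test_that("densities are counts over clipped volumes with conservation and overflow", {
  vol <- data.frame(lower_m = c(0, 3), upper_m = c(3, 6),
                    full_volume_m3 = c(113.1, 791.7),
                    clipped_volume_m3 = c(100, 500),
                    mc_volume_rel_se = c(0, 0))
  pos <- data.frame(r_nacelle_m = c(rep(1, 10), rep(4, 5), 7, 9))
  dp <- density_profile(pos, vol)
  expect_equal(dp$position_count, c(10, 5))
  expect_equal(dp$density_per_m3, c(0.1, 0.01))
  expect_equal(attr(dp, "overflow"), 2)
  expect_equal(sum(dp$position_count) + attr(dp, "overflow"), nrow(pos))
})

test_that("densities are invariant to rigid rotation about the nacelle when unclipped", {
  sc <- simulate_flight_scene(rig, seed = 5, n_positions = 300,
                              pixel_noise_sd = 0)
  vol <- shell_volumes(rig, shell_edges = seq(0, 60, 3), clip_mode = "none",
                       mc_samples = 1e4, seed = 1)
  base <- density_profile(sc$truth, vol)
  # random rotation (orthogonal, det +1) about the nacelle
  set.seed(6)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  rot <- as.data.frame(as.matrix(sc$truth[, c("x", "y", "z")]) %*% t(M))
  names(rot) <- c("x", "y", "z")
  rotated <- density_profile(rot, vol)
  expect_equal(rotated$position_count, base$position_count)
  expect_equal(rotated$density_per_m3, base$density_per_m3)
})

test_that("the attraction fit recovers known parameters from Poisson shell counts", {
  set.seed(9)
  vol <- shell_volumes(rig, shell_edges = seq(0, 60, 3), mc_samples = 2e4,
                       seed = 4)
  a <- 0.05; lambda <- 15; cc <- 0.004
  r_mid <- (vol$lower_m + vol$upper_m) / 2
  mu <- (a * exp(-r_mid / lambda) + cc) * vol$clipped_volume_m3
  counts <- rpois(length(mu), mu)
  tab <- vol
  tab$position_count <- counts
  tab$density_per_m3 <- counts / tab$clipped_volume_m3
  class(tab) <- c("shell_density", "data.frame")
  fit <- fit_attraction_model(tab)
  expect_lt(abs(fit$lambda_m - lambda) / lambda, 0.2)
  expect_gt(fit$a, 0)
  # weighted residual sum is at least as good as a coarse grid oracle
  ok <- r_mid >= 10
  grid_ss <- min(vapply(seq(5, 40, by = 0.25), function(lam) {
    X <- cbind(exp(-r_mid[ok] / lam), 1)
    w <- counts[ok]
    cf <- stats::coef(stats::lm.wfit(X * sqrt(w),
                                     tab$density_per_m3[ok] * sqrt(w),
                                     w = rep(1, sum(ok))))
    cf <- pmax(cf, 0)
    sum(w * (tab$density_per_m3[ok] - X %*% cf)^2)
  }, numeric(1)))
  expect_lte(fit$residual_ss, grid_ss * 1.01)
})

test_that("constant-density profiles fit to a flat model", {
  vol <- shell_volumes(rig, shell_edges = seq(0, 60, 3), clip_mode = "none",
                       mc_samples = 1e4, seed = 7)
  tab <- vol
  tab$density_per_m3 <- rep(0.01, nrow(tab))
  tab$position_count <- round(tab$density_per_m3 * tab$clipped_volume_m3)
  class(tab) <- c("shell_density", "data.frame")
  fit <- fit_attraction_model(tab)
  expect_lt(fit$a, 0.01 * 0.05)
  expect_equal(fit$c, 0.01, tolerance = 0.05)
})

test_that("front and rear half-space densities both decline on attracted scenes", {
  sc <- simulate_flight_scene(rig, seed = 12, n_positions = 900,
                              a = 0.01, lambda_m = 15, c_floor = 0.001,
                              pixel_noise_sd = 0)
  edges <- seq(0, 60, 6)
  for (normal in list(c(1, 0, 0), c(-1, 0, 0))) {
    vol <- shell_volumes(rig, shell_edges = edges, mc_samples = 2e4,
                         seed = 8, hemisphere_normal = normal)
    half <- sc$truth[sign(sc$truth$x) == sign(normal[1]), ]
    dp <- density_profile(half, vol)
    r_mid <- (dp$lower_m + dp$upper_m) / 2
    use <- r_mid >= 10 & !is.na(dp$density_per_m3) & dp$position_count > 0
    rho <- suppressWarnings(
      cor(r_mid[use], dp$density_per_m3[use], method = "spearman"))
    expect_lt(rho, -0.4)
  }
})
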