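.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
.unit <- function(v) v / sqrt(sum(v^2))

#' Pinhole thermal-camera model
#'
#' A camera is defined by its position, an aim point (the shared
#' convergence point of the stereo rig), field of view and sensor size.
#' Pixel coordinates are 0-based with origin top-left, `u` rightward and
#' `v` downward; the mapping between pixels and viewing directions is
#' angular with per-pixel angle `fov/pixels` (no lens distortion, matching
#' the field set-up).
#'
#' @param position Numeric xyz position in metres (world frame, z up).
#' @param target Numeric xyz aim point (the optical axis passes through
#'   it).
#' @param fov_deg Horizontal and vertical field of view in degrees.
#' @param pixels Sensor size (width, height) in pixels.
#' @param focal_length_mm Lens focal length (metadata).
#' @param frame_rate_hz Frame rate (metadata).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(position, target, fov_deg = c(17.5, 13.1),
                         pixels = c(640L, 480L), focal_length_mm = 50,
                         frame_rate_hz = 11) {
  stopifnot(length(position) == 3, length(target) == 3, frame_rate_hz > 0)
  ppa <- fov_deg / pixels          # per-pixel angle, deg
  if (abs(ppa[1] - ppa[2]) / ppa[1] > 0.05)
    stop("field of view inconsistent with pixel aspect (per-pixel angles differ by > 5%)",
         call. = FALSE)
  fwd <- .unit(target - position)
  up_world <- c(0, 0, 1)
  if (abs(sum(fwd * up_world)) > 0.999)
    stop("optical axis may not be vertical", call. = FALSE)
  right <- .unit(.cross3(fwd, up_world))
  up <- .cross3(right, fwd)
  structure(list(position = as.numeric(position),
                 target = as.numeric(target),
                 forward = fwd, right = right, up = up,
                 fov_deg = fov_deg, pixels = as.integer(pixels),
                 focal_length_mm = focal_length_mm,
                 frame_rate_hz = frame_rate_hz,
                 pixel_angle_rad = ppa[1] * pi / 180),
            class = "camera_model")
}

#' Stereo thermal-camera rig
#'
#' Two cameras separated by a base distance, both aimed at one shared
#' convergence point (the nacelle). The default geometry mirrors the field
#' deployment: cameras near ground level about 200 m (horizontally) from
#' the turbine, 16 m base distance, converging on a nacelle 100 m up.
#'
#' @param nacelle Convergence point (world xyz, metres).
#' @param stand_off_m Horizontal distance from the camera midpoint to the
#'   tower axis.
#' @param base_distance_m Distance between the two cameras.
#' @param camera_height_m Height of the cameras above ground.
#' @param ... Further arguments passed to [camera_model()].
#' @return An object of class `stereo_rig` with elements `left`, `right`,
#'   `convergence_point`, `base_distance_m`, `stand_off_m`.
#' @examples
#' rig <- stereo_rig()
#' @export
stereo_rig <- function(nacelle = c(0, 0, 100), stand_off_m = 200,
                       base_distance_m = 16, camera_height_m = 1.5, ...) {
  mid <- c(stand_off_m, 0, camera_height_m)
  offset <- c(0, base_distance_m / 2, 0)
  left <- camera_model(mid + offset, nacelle, ...)
  right <- camera_model(mid - offset, nacelle, ...)
  structure(list(left = left, right = right,
                 convergence_point = as.numeric(nacelle),
                 base_distance_m = base_distance_m,
                 stand_off_m = sqrt(sum((mid - nacelle)^2))),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat(sprintf("<stereo_rig> base %.1f m, stand-off %.1f m, convergence (%.1f, %.1f, %.1f)\n",
              x$base_distance_m, x$stand_off_m, x$convergence_point[1],
              x$convergence_point[2], x$convergence_point[3]))
  invisible(x)
}

#' Viewing ray through a pixel
#'
#' Maps a (possibly sub-pixel) sensor coordinate to a world-frame ray
#' using the angular pinhole model: the azimuth/elevation offsets from the
#' optical axis are `(u - cu) * fov_x / W` and `-(v - cv) * fov_y / H`,
#' with the principal point `cu = (W-1)/2`, `cv = (H-1)/2`.
#'
#' @param cam A [camera_model()].
#' @param u,v Pixel coordinates (0-based, origin top-left).
#' @return List with `origin` and unit `direction` (world frame).
#' @export
pixel_to_ray <- function(cam, u, v) {
  W <- cam$pixels[1]; H <- cam$pixels[2]
  if (u < -0.5 || u > W - 0.5 || v < -0.5 || v > H - 0.5)
    stop("pixel coordinates outside the sensor", call. = FALSE)
  az <- (u - (W - 1) / 2) * cam$fov_deg[1] / W * pi / 180
  el <- -(v - (H - 1) / 2) * cam$fov_deg[2] / H * pi / 180
  dir <- cos(el) * (cos(az) * cam$forward + sin(az) * cam$right) +
    sin(el) * cam$up
  list(origin = cam$position, direction = dir)
}

#' Project world points into a camera
#'
#' Inverse of [pixel_to_ray()]: computes the angular offsets of each point
#' from the optical axis and converts them to sensor coordinates. Points
#' behind the camera or outside the field of view are flagged as not
#' visible (their pixel coordinates are still returned).
#'
#' @param cam A [camera_model()].
#' @param points Numeric matrix (n x 3) or length-3 vector of world
#'   coordinates.
#' @return Data.frame with `u`, `v`, `visible`.
#' @export
project_point <- function(cam, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  d <- sweep(p, 2, cam$position)
  pf <- drop(d %*% cam$forward)
  pr <- drop(d %*% cam$right)
  pu <- drop(d %*% cam$up)
  az <- atan2(pr, pf)
  el <- atan2(pu, sqrt(pf^2 + pr^2))
  W <- cam$pixels[1]; H <- cam$pixels[2]
  u <- (W - 1) / 2 + az * 180 / pi * W / cam$fov_deg[1]
  v <- (H - 1) / 2 - el * 180 / pi * H / cam$fov_deg[2]
  visible <- pf > 0 & abs(az) <= cam$fov_deg[1] / 2 * pi / 180 &
    abs(el) <= cam$fov_deg[2] / 2 * pi / 180
  data.frame(u = u, v = v, visible = visible)
}

# vectorised closest-approach midpoint of ray pairs.
# o1, o2: length-3 origins; D1, D2: n x 3 unit direction matrices.
.triangulate_rays <- function(o1, D1, o2, D2, min_angle_rad = 1e-4) {
  b <- rowSums(D1 * D2)
  denom <- 1 - b^2
  degenerate <- denom < sin(min_angle_rad)^2
  w <- matrix(o1 - o2, nrow = nrow(D1), ncol = 3, byrow = TRUE)
  d <- rowSums(D1 * w)
  e <- rowSums(D2 * w)
  t1 <- (b * e - d) / denom
  t2 <- (e - b * d) / denom
  P1 <- matrix(o1, nrow(D1), 3, byrow = TRUE) + D1 * t1
  P2 <- matrix(o2, nrow(D2), 3, byrow = TRUE) + D2 * t2
  mid <- (P1 + P2) / 2
  gap <- sqrt(rowSums((P1 - P2)^2))
  list(mid = mid, gap_m = gap, degenerate = degenerate)
}

#' Triangulate one stereo detection pair
#'
#' Returns the midpoint of the shortest segment between the two viewing
#' rays, together with the closest-approach distance `gap_m` as a quality
#' metric.
#'
#' @param rig A [stereo_rig()].
#' @param uL,vL Pixel coordinates in the left camera.
#' @param uR,vR Pixel coordinates in the right camera.
#' @return List with `position` (world xyz) and `gap_m`.
#' @export
triangulate <- function(rig, uL, vL, uR, vR) {
  rayL <- pixel_to_ray(rig$left, uL, vL)
  rayR <- pixel_to_ray(rig$right, uR, vR)
  res <- .triangulate_rays(rayL$origin, matrix(rayL$direction, 1, 3),
                           rayR$origin, matrix(rayR$direction, 1, 3))
  if (res$degenerate[1])
    stop("degenerate geometry: rays are near-parallel", call. = FALSE)
  list(position = drop(res$mid), gap_m = res$gap_m[1])
}

#' Triangulate a table of synchronized stereo detections
#'
#' Pairs left- and right-camera detections frame by frame and
#' triangulates each pair. Within a frame with multiple detections per
#' camera, pairs are chosen greedily by smallest ray gap; pairs whose
#' closest-approach distance exceeds `max_gap_m` are rejected.
#'
#' @param rig A [stereo_rig()].
#' @param detections Data.frame with columns `camera_id` (`"L"`/`"R"`),
#'   `frame_index`, `u`, `v`.
#' @param max_gap_m Maximum accepted ray gap (default 3 m, twice the
#'   nominal distance resolution of the default rig).
#' @return Data.frame of world-frame positions: `frame_index`, `x`, `y`,
#'   `z`, `gap_m`.
#' @export
triangulate_detections <- function(rig, detections, max_gap_m = 3) {
  stopifnot(all(c("camera_id", "frame_index", "u", "v") %in% names(detections)))
  out <- list()
  for (fr in unique(detections$frame_index)) {
    L <- detections[detections$frame_index == fr & detections$camera_id == "L", ]
    R <- detections[detections$frame_index == fr & detections$camera_id == "R", ]
    if (nrow(L) == 0 || nrow(R) == 0) next
    # all candidate pairs
    pairs <- expand.grid(i = seq_len(nrow(L)), j = seq_len(nrow(R)))
    DL <- t(vapply(pairs$i, function(i)
      pixel_to_ray(rig$left, L$u[i], L$v[i])$direction, numeric(3)))
    DR <- t(vapply(pairs$j, function(j)
      pixel_to_ray(rig$right, R$u[j], R$v[j])$direction, numeric(3)))
    res <- .triangulate_rays(rig$left$position, DL, rig$right$position, DR)
    ok <- !res$degenerate & res$gap_m <= max_gap_m
    ord <- order(res$gap_m)
    used_i <- logical(nrow(L)); used_j <- logical(nrow(R))
    for (k in ord) {
      if (!ok[k]) next
      i <- pairs$i[k]; j <- pairs$j[k]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        frame_index = fr, x = res$mid[k, 1], y = res$mid[k, 2],
        z = res$mid[k, 3], gap_m = res$gap_m[k])
    }
  }
  if (length(out) == 0)
    return(data.frame(frame_index = integer(), x = numeric(), y = numeric(),
                      z = numeric(), gap_m = numeric()))
  do.call(rbind, out)
}

#' Express positions in the nacelle-referenced frame
#'
#' Subtracts the triangulated nacelle reference point, so all positions
#' are relative to the nacelle centre; pairwise distances are unchanged.
#' Adds the radial distance `r_nacelle_m`.
#'
#' @param positions Data.frame with columns `x`, `y`, `z` (world frame).
#' @param nacelle_ref Numeric xyz of the triangulated nacelle point.
#' @return `positions` with `x`, `y`, `z` recentred and `r_nacelle_m`
#'   added.
#' @export
normalize_to_nacelle <- function(positions, nacelle_ref) {
  if (any(!is.finite(nacelle_ref)))
    stop("`nacelle_ref` must be finite", call. = FALSE)
  positions$x <- positions$x - nacelle_ref[1]
  positions$y <- positions$y - nacelle_ref[2]
  positions$z <- positions$z - nacelle_ref[3]
  positions$r_nacelle_m <- sqrt(positions$x^2 + positions$y^2 + positions$z^2)
  positions
}

#' Analytic stereo range resolution
#'
#' One-pixel-disparity range resolution of a stereo rig at range `r`:
#' `r^2 * pixel_angle / base_distance`.
#'
#' @param rig A [stereo_rig()].
#' @param r_m Range in metres (default: the rig stand-off distance).
#' @return Resolution in metres.
#' @examples
#' range_resolution(stereo_rig(), 200)
#' @export
range_resolution <- function(rig, r_m = rig$stand_off_m) {
  r_m^2 * rig$left$pixel_angle_rad / rig$base_distance_m
}

# logical visibility of world points under a clip mode
.visible_points <- function(rig, pts, clip_mode) {
  if (clip_mode == "none") return(rep(TRUE, nrow(pts)))
  vl <- project_point(rig$left, pts)$visible
  vr <- project_point(rig$right, pts)$visible
  if (clip_mode == "both_cameras") vl & vr else vl | vr
}

#' Monte-Carlo volumes of camera-clipped spherical shells
#'
#' Volume of each spherical shell around the nacelle intersected with the
#' stereo visibility region. This realises the cut-off of shells by the
#' cameras' viewing angles: only the part of a shell seen by the cameras
#' contributes detectable positions, so densities must be computed against
#' the clipped volume. Sampling is uniform within each shell (radius drawn
#' by inverse transform on r^3), seeded and reproducible; the relative
#' Monte-Carlo standard error of each volume is reported.
#'
#' @param rig A [stereo_rig()].
#' @param nacelle_ref World xyz of the nacelle (shell centre); defaults to
#'   the rig convergence point.
#' @param shell_edges Increasing vector of shell radii in metres (default
#'   0 to 60 m in 3 m steps).
#' @param clip_mode `"both_cameras"` (default; point must lie in both view
#'   frustums), `"either_camera"`, or `"none"`.
#' @param mc_samples Monte-Carlo samples per shell (>= 1e5 targets < 1%
#'   relative SE for well-covered shells).
#' @param seed Seed for the sampler.
#' @param hemisphere_normal Optional unit vector: restrict shells to the
#'   half-space `dot(x - nacelle, normal) >= 0` (hemispherical-shell
#'   sensitivity analysis).
#' @return Data.frame with `lower_m`, `upper_m`, `full_volume_m3`,
#'   `clipped_volume_m3`, `mc_volume_rel_se`.
#' @export
shell_volumes <- function(rig, nacelle_ref = rig$convergence_point,
                          shell_edges = seq(0, 60, by = 3),
                          clip_mode = c("both_cameras", "either_camera",
                                        "none"),
                          mc_samples = 1e5, seed = 1,
                          hemisphere_normal = NULL) {
  clip_mode <- match.arg(clip_mode)
  if (is.unsorted(shell_edges, strictly = TRUE))
    stop("`shell_edges` must be strictly increasing", call. = FALSE)
  set.seed(seed)
  n_shell <- length(shell_edges) - 1
  out <- data.frame(lower_m = shell_edges[-length(shell_edges)],
                    upper_m = shell_edges[-1])
  out$full_volume_m3 <- 4 / 3 * pi * (out$upper_m^3 - out$lower_m^3)
  out$clipped_volume_m3 <- NA_real_
  out$mc_volume_rel_se <- NA_real_
  for (k in seq_len(n_shell)) {
    r0 <- out$lower_m[k]; r1 <- out$upper_m[k]
    r <- (runif(mc_samples) * (r1^3 - r0^3) + r0^3)^(1 / 3)
    z <- runif(mc_samples, -1, 1)
    phi <- runif(mc_samples, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    dir <- cbind(s * cos(phi), s * sin(phi), z)
    pts <- sweep(dir * r, 2, nacelle_ref, "+")
    keep <- .visible_points(rig, pts, clip_mode)
    if (!is.null(hemisphere_normal)) {
      hn <- .unit(hemisphere_normal)
      keep <- keep & (dir %*% hn)[, 1] >= 0
    }
    p_hat <- mean(keep)
    out$clipped_volume_m3[k] <- out$full_volume_m3[k] * p_hat
    se <- out$full_volume_m3[k] * sqrt(p_hat * (1 - p_hat) / mc_samples)
    out$mc_volume_rel_se[k] <- if (p_hat > 0) se / out$clipped_volume_m3[k]
                               else NA_real_
  }
  attr(out, "clip_mode") <- clip_mode
  attr(out, "mc_samples") <- mc_samples
  attr(out, "seed") <- seed
  out
}

#' Distance-binned bat density around the nacelle
#'
#' Counts nacelle-referenced positions per spherical shell and divides by
#' the clipped shell volume. Positions beyond the outermost shell edge are
#' excluded and reported in the `overflow` attribute.
#'
#' @param positions Data.frame with `r_nacelle_m` (or `x`, `y`, `z` in the
#'   nacelle frame, from which radii are computed).
#' @param volumes Shell-volume table from [shell_volumes()] (same edges).
#' @return Data.frame (`shell_density`): shell edges, `position_count`,
#'   `clipped_volume_m3`, `density_per_m3` (NA where the clipped volume is
#'   0), `mc_volume_rel_se`.
#' @export
density_profile <- function(positions, volumes) {
  if (!"r_nacelle_m" %in% names(positions)) {
    positions$r_nacelle_m <- sqrt(positions$x^2 + positions$y^2 +
                                    positions$z^2)
  }
  edges <- c(volumes$lower_m, volumes$upper_m[nrow(volumes)])
  r <- positions$r_nacelle_m
  inside <- r >= edges[1] & r <= edges[length(edges)]
  bin <- findInterval(r[inside], edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = nrow(volumes))
  out <- volumes
  out$position_count <- counts
  out$density_per_m3 <- ifelse(out$clipped_volume_m3 > 0,
                               counts / out$clipped_volume_m3, NA_real_)
  attr(out, "overflow") <- sum(!inside)
  class(out) <- c("shell_density", "data.frame")
  out
}

#' Fit the exponential attraction model to a density profile
#'
#' Fits `d(r) = a * exp(-r / lambda) + c` to shell densities by weighted
#' least squares (weights = position counts), restricted to shells beyond
#' `r_min` (default 10 m; the nacelle body occupies much of the innermost
#' shells, depressing apparent densities there). `a` measures the excess
#' density at the nacelle, `lambda` the decay length of attraction in
#' metres, and `c` the free-air-space floor.
#'
#' @param table A [density_profile()] result.
#' @param r_min Smallest shell mid-radius used in the fit.
#' @return List with `a`, `lambda_m`, `c`, the `nls` fit object, and
#'   `residual_ss`.
#' @export
fit_attraction_model <- function(table, r_min = 10) {
  r_mid <- (table$lower_m + table$upper_m) / 2
  ok <- r_mid >= r_min & !is.na(table$density_per_m3) &
    table$clipped_volume_m3 > 0
  if (sum(ok) < 5)
    stop("need at least 5 usable shells beyond r_min", call. = FALSE)
  d <- data.frame(r = r_mid[ok], dens = table$density_per_m3[ok],
                  w = table$position_count[ok])
  if (all(d$w == 0)) d$w <- rep(1, nrow(d))

  # profile the decay length on a grid, solving (a, c) by weighted linear
  # least squares at each lambda; supplies robust start values and a
  # deterministic fallback when the curvature is degenerate (e.g. flat
  # profiles, where a = 0 and lambda is unidentifiable)
  profile_ss <- function(lam) {
    X <- cbind(exp(-d$r / lam), 1)
    sw <- sqrt(d$w)
    cf <- tryCatch(unname(stats::coef(stats::lm.fit(X * sw, d$dens * sw))),
                   error = function(e) c(NA, NA))
    if (any(!is.finite(cf))) return(list(ss = Inf, a = NA, c = NA))
    if (cf[1] < 0 || cf[2] < 0) {
      cf <- c(max(cf[1], 0), max(cf[2], 0))
      if (cf[1] == 0) cf[2] <- sum(d$w * d$dens) / sum(d$w)
    }
    res <- d$dens - X %*% cf
    list(ss = sum(d$w * res^2), a = cf[1], c = cf[2])
  }
  lam_grid <- seq(2, 60, by = 0.5)
  prof <- lapply(lam_grid, profile_ss)
  best <- which.min(vapply(prof, `[[`, numeric(1), "ss"))
  start <- list(a = max(prof[[best]]$a, 1e-12), lambda = lam_grid[best],
                c0f = max(prof[[best]]$c, 1e-12))

  fit <- tryCatch(
    minpack.lm::nlsLM(dens ~ a * exp(-r / lambda) + c0f,
                      data = d, weights = d$w, start = start,
                      lower = c(0, 1e-3, 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- coef(fit)
    out <- list(a = unname(cf["a"]), lambda_m = unname(cf["lambda"]),
                c = unname(cf["c0f"]), fit = fit,
                residual_ss = sum(d$w * resid(fit)^2), method = "nls")
    # keep whichever solution is better; LM can stall on flat likelihoods
    if (out$residual_ss <= prof[[best]]$ss + 1e-12) return(out)
  }
  if (!is.finite(prof[[best]]$ss))
    stop("attraction model did not converge; weighted residuals of the ",
         "constant model: ",
         paste(signif(d$dens - sum(d$w * d$dens) / sum(d$w), 3),
               collapse = ", "), call. = FALSE)
  list(a = prof[[best]]$a, lambda_m = lam_grid[best], c = prof[[best]]$c,
       fit = NULL, residual_ss = prof[[best]]$ss, method = "grid_profile")
}
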