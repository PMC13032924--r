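#' Default species parameter table for simulations
#'
#' Alias for [species_parameters()]: the seven singing species with their
#' acoustic and kinematic parameters, used to parameterise the synthetic
#' call-event generator.
#'
#' @return A data.frame, see [species_parameters()].
#' @export
make_default_species_table <- function() species_parameters()

# truncated-lognormal background (search-phase) pulse intervals, ms.
# Bounded below at 30 ms so background intervals are cleanly separated
# from the 10 ms feeding-buzz criterion.
.background_intervals_ms <- function(n, floor_ms = 30) {
  floor_ms + stats::rlnorm(n, meanlog = log(50), sdlog = 0.6)
}

#' Simulate one night of triggered acoustic recordings
#'
#' Generates species-parameterised call-event streams with planted feeding
#' buzzes, social calls and song events, plus a ground-truth ledger that
#' scores every classifier operation. Pure function of `(config, seed)`:
#' the same arguments always produce identical output.
#'
#' Each synthetic recording contains a search-phase echolocation pulse
#' train of one species (end frequencies strictly inside the species
#' band, background pulse intervals > 30 ms), optionally followed by a
#' feeding buzz (a run of intervals drawn from 6--9 ms), social calls,
#' and/or a song-element sequence. Pipistrelloid/Plecotus songs are
#' planted with at least five consecutive elements. Received levels follow
#' the one-way propagation model at the simulated bat distance, closing
#' the loop with [atmospheric_absorption()].
#'
#' @param seed Integer seed.
#' @param n_recordings Number of triggered recordings.
#' @param species_table Species parameter table.
#' @param species_mix Named probabilities over `species_table$species`
#'   (default uniform).
#' @param buzz_prob,social_prob,song_prob Per-recording insertion
#'   probabilities.
#' @param n_search Range (min, max) of search-phase calls per recording.
#' @param song_duration_s Range of planted song-event durations (the
#'   observed field range of song events).
#' @param turbine_id,night_date Labels carried into the event table.
#' @param echolocation_source_level_db Source level assumed for
#'   echolocation calls and social calls when computing received levels.
#' @return List with `events` (call-event table), `recordings`
#'   (per-recording metadata incl. `valid` flag and simulated bat
#'   distance) and `ledger` (list of `planted_buzzes`, `planted_songs`,
#'   `species` per recording).
#' @export
simulate_night <- function(seed = 1, n_recordings = 50,
                           species_table = species_parameters(),
                           species_mix = NULL,
                           buzz_prob = 0.2, social_prob = 0.15,
                           song_prob = 0.15,
                           n_search = c(6, 20),
                           song_duration_s = c(2, 30),
                           turbine_id = "T1", night_date = "2015-08-01",
                           echolocation_source_level_db = 110) {
  if (song_prob > 0 && n_recordings == 0)
    stop("cannot plant songs without recordings", call. = FALSE)
  if (is.null(species_mix)) {
    species_mix <- stats::setNames(rep(1 / nrow(species_table),
                                       nrow(species_table)),
                                   species_table$species)
  }
  if (abs(sum(species_mix) - 1) > 1e-8)
    stop("`species_mix` probabilities must sum to 1", call. = FALSE)
  set.seed(seed)
  atm <- atmosphere()
  events <- list(); rec_meta <- list()
  planted_buzzes <- list(); planted_songs <- list()
  for (i in seq_len(n_recordings)) {
    rid <- sprintf("rec%04d", i)
    sp <- sample(names(species_mix), 1, prob = species_mix)
    prof <- species_table[species_table$species == sp, , drop = FALSE]
    lo <- prof$endfreq_lo_khz + 0.2; hi <- prof$endfreq_hi_khz - 0.2
    t0 <- (i - 1) * 120                      # recordings 2 min apart
    dist_m <- stats::runif(1, 5, 60)

    ns <- sample(seq(n_search[1], n_search[2]), 1)
    iv <- .background_intervals_ms(ns - 1)
    times <- t0 + c(0, cumsum(iv)) / 1000
    ef <- stats::runif(ns, lo, hi)
    mk_call <- function(times, end_f, category, source_db, peak_f = NULL) {
      n <- length(times)
      if (is.null(peak_f)) peak_f <- end_f + 2
      start_f <- end_f + stats::runif(n, 10, 30)
      dur <- stats::runif(n, 3, 8)
      rl <- source_db - 20 * log10(dist_m) -
        atmospheric_absorption(pmin(pmax(peak_f, 1), 200), atm) * dist_m
      data.frame(recording_id = rid, turbine_id = turbine_id,
                 night_date = night_date, time_s = times,
                 duration_ms = dur, start_freq_khz = start_f,
                 end_freq_khz = end_f, peak_freq_khz = peak_f,
                 sweep_rate_khz_per_ms = -(start_f - end_f) / dur,
                 received_level_db_spl = rl, category = category,
                 truth_species = sp, stringsAsFactors = FALSE)
    }
    rec_events <- mk_call(times, ef, "echolocation",
                          echolocation_source_level_db)
    t_cursor <- max(times)
    n_buzz <- 0L
    if (stats::runif(1) < buzz_prob) {
      n_int <- sample(5:12, 1)
      biv <- stats::runif(n_int, 6, 9)
      bt <- t_cursor + 0.05 + c(0, cumsum(biv)) / 1000
      bf <- stats::runif(n_int + 1, lo, hi)
      rec_events <- rbind(rec_events,
                          mk_call(bt, bf, "echolocation",
                                  echolocation_source_level_db))
      planted_buzzes[[length(planted_buzzes) + 1]] <- data.frame(
        recording_id = rid, species = sp, start_time_s = bt[1],
        end_time_s = bt[length(bt)], n_calls = n_int + 1L,
        stringsAsFactors = FALSE)
      t_cursor <- max(bt)
      n_buzz <- 1L
    }
    if (stats::runif(1) < social_prob) {
      n_soc <- sample(1:4, 1)
      st <- t_cursor + 0.2 + cumsum(stats::runif(n_soc, 0.05, 0.2))
      sf <- stats::runif(n_soc, max(lo - 5, 8.5), lo)
      rec_events <- rbind(rec_events,
                          mk_call(st, sf, "social_call",
                                  echolocation_source_level_db))
      t_cursor <- max(st)
    }
    planted_song <- FALSE; song_dur <- NA_real_; n_el <- NA_integer_
    if (stats::runif(1) < song_prob) {
      song_dur <- stats::runif(1, song_duration_s[1], song_duration_s[2])
      ioi <- stats::rgamma(200, shape = 4, rate = 10)   # ~0.4 s inter-onset
      el_t <- t_cursor + 0.5 + c(0, cumsum(ioi))
      el_t <- el_t[el_t <= t_cursor + 0.5 + song_dur]
      if (length(el_t) < 5)                   # guarantee a scoreable song
        el_t <- t_cursor + 0.5 + seq(0, song_dur, length.out = 5)
      fpk <- prof$song_peak_freq_khz
      song_events_df <- mk_call(el_t, rep(fpk, length(el_t)), "song_element",
                                prof$source_level_db_pespl_1m,
                                peak_f = rep(fpk, length(el_t)))
      rec_events <- rbind(rec_events, song_events_df)
      planted_song <- TRUE
      song_dur <- max(el_t) - min(el_t)       # realised duration
      n_el <- length(el_t)
      planted_songs[[length(planted_songs) + 1]] <- data.frame(
        recording_id = rid, species = sp, start_time_s = min(el_t),
        end_time_s = max(el_t), duration_s = song_dur,
        n_elements = n_el, stringsAsFactors = FALSE)
    }
    rec_events <- rec_events[order(rec_events$time_s), , drop = FALSE]
    events[[i]] <- rec_events
    rec_meta[[i]] <- data.frame(
      recording_id = rid, turbine_id = turbine_id, night_date = night_date,
      trigger_time_s = t0, species = sp, distance_m = dist_m,
      n_planted_buzzes = n_buzz, planted_song = planted_song,
      valid = TRUE, stringsAsFactors = FALSE)
  }
  empty_buzz <- data.frame(recording_id = character(), species = character(),
                           start_time_s = numeric(), end_time_s = numeric(),
                           n_calls = integer(), stringsAsFactors = FALSE)
  empty_song <- data.frame(recording_id = character(), species = character(),
                           start_time_s = numeric(), end_time_s = numeric(),
                           duration_s = numeric(), n_elements = integer(),
                           stringsAsFactors = FALSE)
  list(events = do.call(rbind, events),
       recordings = do.call(rbind, rec_meta),
       ledger = list(
         planted_buzzes = if (length(planted_buzzes) > 0)
           do.call(rbind, planted_buzzes) else empty_buzz,
         planted_songs = if (length(planted_songs) > 0)
           do.call(rbind, planted_songs) else empty_song))
}

#' Simulate a 3D flight scene around the nacelle
#'
#' Draws bat positions by thinning a uniform point process in the stereo
#' visibility region with acceptance probability proportional to the
#' radial density model `d(r) = a exp(-r / lambda) + c` (a
#' nacelle-attracted exponential component over a uniform free-air-space
#' floor), then projects each position into both cameras with Gaussian
#' pixel noise.
#'
#' @param rig A [stereo_rig()].
#' @param seed Integer seed.
#' @param n_positions Number of accepted positions.
#' @param a Attraction amplitude (relative density units).
#' @param lambda_m Attraction decay length (m).
#' @param c_floor Free-air-space density floor (same units as `a`).
#' @param max_r Outer radius of the simulated region around the nacelle
#'   (m); default 60 m as in the density analysis.
#' @param pixel_noise_sd Gaussian pixel noise SD applied to the projected
#'   detections.
#' @param clip_mode Visibility requirement for candidate positions.
#' @return List with `truth` (nacelle-frame positions with
#'   `r_nacelle_m`), `truth_world` and `detections` (stereo pixel
#'   detections, one L and one R row per frame).
#' @export
simulate_flight_scene <- function(rig, seed = 1, n_positions = 600,
                                  a = 0.01, lambda_m = 15, c_floor = 0.001,
                                  max_r = 60, pixel_noise_sd = 0.5,
                                  clip_mode = c("both_cameras",
                                                "either_camera", "none")) {
  clip_mode <- match.arg(clip_mode)
  stopifnot(a >= 0, c_floor >= 0, lambda_m > 0, max_r > 0)
  if (a + c_floor <= 0) stop("density model is identically zero",
                             call. = FALSE)
  set.seed(seed)
  nac <- rig$convergence_point
  dmax <- a + c_floor
  acc <- matrix(numeric(0), 0, 3)
  tries <- 0
  while (nrow(acc) < n_positions) {
    tries <- tries + 1
    if (tries > 2000)
      stop("visibility region appears empty for this rig/geometry",
           call. = FALSE)
    m <- 20000
    u <- matrix(stats::runif(3 * m, -max_r, max_r), m, 3)
    r <- sqrt(rowSums(u^2))
    keep <- r <= max_r
    u <- u[keep, , drop = FALSE]; r <- r[keep]
    pts <- sweep(u, 2, nac, "+")
    vis <- .visible_points(rig, pts, clip_mode)
    u <- u[vis, , drop = FALSE]; r <- r[vis]
    if (length(r) == 0) next
    p_acc <- (a * exp(-r / lambda_m) + c_floor) / dmax
    take <- stats::runif(length(r)) < p_acc
    acc <- rbind(acc, sweep(u[take, , drop = FALSE], 2, nac, "+"))
  }
  acc <- acc[seq_len(n_positions), , drop = FALSE]
  truth_world <- data.frame(frame_index = seq_len(n_positions),
                            x = acc[, 1], y = acc[, 2], z = acc[, 3])
  truth <- normalize_to_nacelle(truth_world, nac)
  det <- list()
  for (side in c("L", "R")) {
    cam <- if (side == "L") rig$left else rig$right
    pr <- project_point(cam, acc)
    u <- pr$u + stats::rnorm(n_positions, 0, pixel_noise_sd)
    v <- pr$v + stats::rnorm(n_positions, 0, pixel_noise_sd)
    u <- pmin(pmax(u, -0.49), cam$pixels[1] - 0.51)
    v <- pmin(pmax(v, -0.49), cam$pixels[2] - 0.51)
    det[[side]] <- data.frame(camera_id = side,
                              frame_index = seq_len(n_positions),
                              u = u, v = v, stringsAsFactors = FALSE)
  }
  list(truth = truth, truth_world = truth_world,
       detections = rbind(det$L, det$R))
}

#' Simulate a turbine-year x month activity dataset
#'
#' Binomial draws from the logit-linear activity model with site and
#' observation-level normal random intercepts, on the design of the
#' motivating field study: 26 turbine-years over 6 sites, months
#' April--October, two species groups, overdispersed recording counts per
#' cell. Effect defaults are the published fixed-effect estimates for the
#' chosen response; set them to zero for null simulations.
#'
#' @param seed Integer seed.
#' @param response `"feeding"` or `"social"`: selects the default effect
#'   sizes and the output count column.
#' @param n_sites,n_turbine_years Design size.
#' @param months Integer month labels (ordered).
#' @param intercept Baseline log-odds (default: published intercepts
#'   -4.85 feeding / -6.65 social).
#' @param group_effect Pipistrelloid-minus-Nyctaloid log-odds difference
#'   (default 0.93 feeding / 1.88 social).
#' @param month_effects,interaction_effects Coefficients on the
#'   orthonormal month contrasts (length <= number of months - 1);
#'   defaults are the published estimates.
#' @param site_sd,olre_sd Random-intercept standard deviations.
#' @param mean_recordings Mean bat recordings per cell.
#' @param dispersion Negative-binomial size for recording counts (smaller
#'   = more overdispersed; zero-recording cells can occur and are
#'   excluded, mirroring the field analysis).
#' @param drop_zero_cells Drop cells with zero recordings (default TRUE);
#'   when FALSE they are kept so downstream exclusion can be exercised.
#' @return Activity-cell data.frame (`site_id`, `turbine_year_id`,
#'   `month`, `group`, `n_recordings`, `n_<response>`), with the
#'   generating parameters in `attr(, "truth")`.
#' @export
simulate_activity_dataset <- function(seed = 1,
                                      response = c("feeding", "social"),
                                      n_sites = 6, n_turbine_years = 26,
                                      months = 4:10,
                                      intercept = NULL, group_effect = NULL,
                                      month_effects = NULL,
                                      interaction_effects = NULL,
                                      site_sd = 0.5, olre_sd = 0.5,
                                      mean_recordings = 310,
                                      dispersion = 1.5,
                                      drop_zero_cells = TRUE) {
  response <- match.arg(response)
  defaults <- list(
    feeding = list(intercept = -4.85, group = 0.93,
                   month = c(-0.51, -0.74, -1.19, 0.06, -0.68),
                   inter = c(0.16, 0.98, 1.37, -0.26, 0.09)),
    social = list(intercept = -6.65, group = 1.88,
                  month = c(-1.16, -2.58, 0.11, 0.24, -0.15),
                  inter = c(3.00, 2.52, -0.08, 0.05, 0.32)))[[response]]
  if (is.null(intercept)) intercept <- defaults$intercept
  if (is.null(group_effect)) group_effect <- defaults$group
  if (is.null(month_effects)) month_effects <- defaults$month
  if (is.null(interaction_effects)) interaction_effects <- defaults$inter
  stopifnot(all(is.finite(c(intercept, group_effect, month_effects,
                            interaction_effects))),
            site_sd >= 0, olre_sd >= 0, mean_recordings >= 0)
  set.seed(seed)
  ty_site <- sort(rep_len(seq_len(n_sites), n_turbine_years))
  cells <- expand.grid(turbine_year_id = seq_len(n_turbine_years),
                       month = months,
                       group = c("Nyctaloid", "Pipistrelloid"),
                       stringsAsFactors = FALSE)
  cells$site_id <- paste0("site", ty_site[cells$turbine_year_id])
  cells$turbine_year_id <- paste0("ty", cells$turbine_year_id)
  ctr <- orthogonal_month_contrasts(length(months),
                                    degree = length(month_effects))
  mi <- match(cells$month, months)
  xm <- ctr[mi, , drop = FALSE]
  is_pip <- as.numeric(cells$group == "Pipistrelloid")
  site_re <- stats::rnorm(n_sites, 0, site_sd)
  names(site_re) <- paste0("site", seq_len(n_sites))
  eta <- intercept + group_effect * is_pip +
    drop(xm %*% month_effects) +
    is_pip * drop(xm %*% interaction_effects) +
    site_re[cells$site_id] +
    stats::rnorm(nrow(cells), 0, olre_sd)
  cells$n_recordings <- stats::rnbinom(nrow(cells), mu = mean_recordings,
                                       size = dispersion)
  k <- stats::rbinom(nrow(cells), cells$n_recordings, stats::plogis(eta))
  cells[[paste0("n_", response)]] <- k
  cells <- cells[, c("site_id", "turbine_year_id", "month", "group",
                     "n_recordings", paste0("n_", response))]
  if (drop_zero_cells) cells <- cells[cells$n_recordings > 0, , drop = FALSE]
  rownames(cells) <- NULL
  attr(cells, "truth") <- list(response = response, intercept = intercept,
                               group_effect = group_effect,
                               month_effects = month_effects,
                               interaction_effects = interaction_effects,
                               site_sd = site_sd, olre_sd = olre_sd)
  cells
}
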