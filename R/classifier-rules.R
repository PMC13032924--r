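#' Rule set for acoustic event classification
#'
#' Bundles every threshold used by the acoustic classifiers: the trigger
#' filter that emulates the deployed recorder's bat-call filter, the
#' end-frequency bands used for species and species-group identification,
#' the feeding-buzz pulse-interval rule, and the song-element rules.
#'
#' End-frequency identification follows the deployed scheme: species bands
#' are half-open exactly as published (*N. noctula* < 22 kHz; Nyctaloid
#' group (22, 29\]; *P. nathusii* (30, 42\]; *P. pipistrellus* (42, 51\];
#' *P. pygmaeus* > 51 kHz), end frequencies in the published gap
#' (29, 30\] kHz are assigned "Chiroptera", and the recorder-level group
#' bands are Nyctaloid \[8, 33) and Pipistrelloid \[33, 65) kHz.
#'
#' @param buzz_max_pulse_interval_ms Maximum inter-call interval inside a
#'   feeding buzz (default 10 ms, i.e. a repetition rate >= 100 calls/s).
#' @param buzz_min_intervals Minimum number of consecutive qualifying
#'   intervals for a buzz (default 3, i.e. >= 4 calls); guards against
#'   single-interval artifacts.
#' @param min_search_calls_for_id Minimum number of search-phase
#'   echolocation calls required for a species(-group) assignment.
#' @param min_consecutive_song_elements_pip Minimum run length of
#'   consecutive song elements for a Pipistrelloid or *Plecotus*
#'   vocalisation to count as song.
#' @param song_event_max_gap_s Maximum silent gap between successive song
#'   elements merged into one song event.
#' @param trigger_dialect `"recording"` uses the deployed 15--80 kHz
#'   trigger band; `"renebat"` uses the 15--100 kHz identification band.
#'
#' @return An object of class `classifier_rules`.
#' @examples
#' classifier_rules()
#' @export
classifier_rules <- function(buzz_max_pulse_interval_ms = 10,
                             buzz_min_intervals = 3,
                             min_search_calls_for_id = 2,
                             min_consecutive_song_elements_pip = 5,
                             song_event_max_gap_s = 5,
                             trigger_dialect = c("recording", "renebat")) {
  trigger_dialect <- match.arg(trigger_dialect)
  stopifnot(buzz_max_pulse_interval_ms > 0, buzz_min_intervals >= 1,
            min_search_calls_for_id >= 1,
            min_consecutive_song_elements_pip >= 1,
            song_event_max_gap_s > 0)
  structure(list(
    group_bands = data.frame(
      group = c("Nyctaloid", "Pipistrelloid"),
      lo_khz = c(8, 33), hi_khz = c(33, 65),   # [lo, hi)
      stringsAsFactors = FALSE),
    # species thresholds (see Details); applied in classify_end_frequency()
    species_thresholds_khz = c(noctula_below = 22, nyctaloid_upto = 29,
                               gap_upto = 30, nathusii_upto = 42,
                               pipistrellus_upto = 51, pygmaeus_below = 65),
    buzz_max_pulse_interval_ms = buzz_max_pulse_interval_ms,
    buzz_min_intervals = buzz_min_intervals,
    min_search_calls_for_id = min_search_calls_for_id,
    min_consecutive_song_elements_pip = min_consecutive_song_elements_pip,
    song_event_max_gap_s = song_event_max_gap_s,
    trigger_filter = list(
      fm_min_duration_ms = 1, fm_max_duration_ms = 30,
      fm_sweep_khz_per_ms = c(-9, -1),
      cf_min_duration_ms = 2, cf_max_duration_ms = 30,
      cf_sweep_khz_per_ms = c(-2, 1),
      freq_range_khz = if (trigger_dialect == "recording") c(15, 80)
                       else c(15, 100),
      dialect = trigger_dialect),
    pre_trigger_s = 0.3, post_trigger_s = 1.0,
    calibration_tolerance_db = 6
  ), class = "classifier_rules")
}

#' @export
print.classifier_rules <- function(x, ...) {
  cat("<classifier_rules>\n",
      sprintf("  buzz: intervals <= %g ms, >= %d consecutive\n",
              x$buzz_max_pulse_interval_ms, x$buzz_min_intervals),
      sprintf("  song: >= %d consecutive elements (Pipistrelloid/Plecotus), event gap <= %g s\n",
              x$min_consecutive_song_elements_pip, x$song_event_max_gap_s),
      sprintf("  trigger dialect: %s (%g-%g kHz)\n",
              x$trigger_filter$dialect, x$trigger_filter$freq_range_khz[1],
              x$trigger_filter$freq_range_khz[2]))
  invisible(x)
}

#' Species(-group) assignment of a single end frequency
#'
#' Maps echolocation end frequencies (kHz) onto the species identification
#' bands (see [classifier_rules()]). Values in the published gap
#' (29, 30\] kHz map to `"Chiroptera"`; values outside \[8, 65) kHz map to
#' `NA`.
#'
#' @param end_freq_khz Numeric vector of end frequencies.
#' @param rules A [classifier_rules()] object.
#' @return Character vector of species(-group) labels.
#' @examples
#' classify_end_frequency(c(20, 25, 29.5, 35, 45, 55))
#' @export
classify_end_frequency <- function(end_freq_khz, rules = classifier_rules()) {
  f <- end_freq_khz
  out <- rep(NA_character_, length(f))
  out[f >= 8 & f < 22] <- "Nyctalus noctula"
  out[f >= 22 & f <= 29] <- "Nyctaloid"
  out[f > 29 & f <= 30] <- "Chiroptera"
  out[f > 30 & f <= 42] <- "Pipistrellus nathusii"
  out[f > 42 & f <= 51] <- "Pipistrellus pipistrellus"
  out[f > 51 & f < 65] <- "Pipistrellus pygmaeus"
  out
}

#' Recorder-level species group of an end frequency
#'
#' @param end_freq_khz Numeric vector of end frequencies (kHz).
#' @param rules A [classifier_rules()] object.
#' @return `"Nyctaloid"` for \[8, 33) kHz, `"Pipistrelloid"` for
#'   \[33, 65) kHz, `NA` otherwise.
#' @export
group_of_end_frequency <- function(end_freq_khz, rules = classifier_rules()) {
  gb <- rules$group_bands
  out <- rep(NA_character_, length(end_freq_khz))
  for (i in seq_len(nrow(gb))) {
    sel <- end_freq_khz >= gb$lo_khz[i] & end_freq_khz < gb$hi_khz[i]
    out[sel] <- gb$group[i]
  }
  out
}
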