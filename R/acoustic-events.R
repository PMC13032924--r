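#' Validate a call-event table
#'
#' Checks the tabular call-event schema used throughout the acoustic
#' module: one row per parameterised vocalisation with timing, frequency
#' and category fields.
#'
#' @param events Data.frame of call events.
#' @param require_sorted Require events to be time-sorted within each
#'   recording.
#' @return `events`, invisibly, after validation.
#' @export
validate_call_events <- function(events, require_sorted = TRUE) {
  req <- c("recording_id", "time_s", "duration_ms", "start_freq_khz",
           "end_freq_khz", "category")
  missing <- setdiff(req, names(events))
  if (length(missing) > 0)
    stop("call-event table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(events$duration_ms)) || any(events$duration_ms <= 0))
    stop("`duration_ms` must be finite and > 0", call. = FALSE)
  bad <- setdiff(unique(events$category),
                 c("echolocation", "social_call", "song_element"))
  if (length(bad) > 0)
    stop("unknown event categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (require_sorted) {
    unsorted <- tapply(events$time_s, events$recording_id,
                       function(t) is.unsorted(t))
    if (any(unlist(unsorted)))
      stop("events must be time-sorted within each recording", call. = FALSE)
  }
  invisible(events)
}

#' Read a call-event table from CSV
#'
#' @param path Path to a CSV file with the call-event schema (columns
#'   `recording_id, turbine_id, night_date, time_s, duration_ms,
#'   start_freq_khz, end_freq_khz, peak_freq_khz, sweep_rate_khz_per_ms,
#'   received_level_db_spl, category`).
#' @return A validated data.frame of call events.
#' @export
read_call_events <- function(path) {
  events <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_call_events(events, require_sorted = FALSE)
  events
}

#' Apply the recorder's bat-call trigger filter
#'
#' Reproduces the deployed recorder's trigger criteria: an event is
#' accepted when it satisfies the FM rule (duration 1--30 ms, sweep rate
#' -9 to -1 kHz/ms) or the CF rule (duration 2--30 ms, sweep rate -2 to
#' 1 kHz/ms) and its frequency band overlaps the trigger range (15--80 kHz
#' in the recording dialect). Pure function of the event parameters.
#'
#' @param events Data.frame with columns `duration_ms`,
#'   `sweep_rate_khz_per_ms`, `start_freq_khz`, `end_freq_khz`.
#' @param rules A [classifier_rules()] object.
#' @return Logical vector, one element per event row.
#' @examples
#' ev <- data.frame(duration_ms = c(5, 0.5), sweep_rate_khz_per_ms = c(-5, -5),
#'                  start_freq_khz = c(40, 40), end_freq_khz = c(25, 35))
#' apply_trigger_filter(ev)
#' @export
apply_trigger_filter <- function(events, rules = classifier_rules()) {
  tf <- rules$trigger_filter
  d <- events$duration_ms
  s <- events$sweep_rate_khz_per_ms
  if (any(!is.finite(d)) || any(d <= 0))
    stop("`duration_ms` must be finite and > 0", call. = FALSE)
  if (any(!is.finite(s)))
    stop("`sweep_rate_khz_per_ms` must be finite", call. = FALSE)
  fm <- d >= tf$fm_min_duration_ms & d <= tf$fm_max_duration_ms &
    s >= tf$fm_sweep_khz_per_ms[1] & s <= tf$fm_sweep_khz_per_ms[2]
  cf <- d >= tf$cf_min_duration_ms & d <= tf$cf_max_duration_ms &
    s >= tf$cf_sweep_khz_per_ms[1] & s <= tf$cf_sweep_khz_per_ms[2]
  f_lo <- pmin(events$start_freq_khz, events$end_freq_khz)
  f_hi <- pmax(events$start_freq_khz, events$end_freq_khz)
  in_band <- f_hi >= tf$freq_range_khz[1] & f_lo <= tf$freq_range_khz[2]
  (fm | cf) & in_band
}

#' Classify an echolocation call sequence to species(-group)
#'
#' Assigns a call sequence using the end frequencies of its search-phase
#' echolocation calls. A species label is returned when all measured end
#' frequencies fall into one species band; a group label
#' (`"Pipistrellus spp."` or `"Nyctaloid"`) when the frequencies straddle
#' adjacent species bands within one group; otherwise the sequence remains
#' unidentified (`"Chiroptera"`). Deterministic for fixed input.
#'
#' @param events Data.frame of call events (only `category ==
#'   "echolocation"` rows are used), or a numeric vector of end
#'   frequencies.
#' @param rules A [classifier_rules()] object.
#' @return A list with elements `label` and `level`
#'   (`"species"`, `"group"` or `"unknown"`).
#' @examples
#' classify_sequence(c(20, 21))   # N. noctula
#' classify_sequence(c(41, 43))   # Pipistrellus spp. (group level)
#' @export
classify_sequence <- function(events, rules = classifier_rules()) {
  f <- if (is.numeric(events)) events
       else events$end_freq_khz[events$category == "echolocation"]
  if (length(f) < rules$min_search_calls_for_id)
    return(list(label = "unknown", level = "unknown"))
  sp <- classify_end_frequency(f, rules)
  if (any(is.na(sp)))
    return(list(label = "unknown", level = "unknown"))
  u <- unique(sp)
  if (length(u) == 1) {
    level <- switch(u, "Nyctaloid" = "group", "Chiroptera" = "unknown",
                    "species")
    return(list(label = u, level = level))
  }
  pip_species <- c("Pipistrellus nathusii", "Pipistrellus pipistrellus",
                   "Pipistrellus pygmaeus")
  nyc_members <- c("Nyctalus noctula", "Nyctaloid")
  if (all(u %in% pip_species))
    return(list(label = "Pipistrellus spp.", level = "group"))
  if (all(u %in% nyc_members))
    return(list(label = "Nyctaloid", level = "group"))
  list(label = "Chiroptera", level = "unknown")
}

# maximal runs of TRUE in a logical vector -> data.frame(start, end, length)
.runs_of <- function(x) {
  if (length(x) == 0) return(data.frame(start = integer(), end = integer(),
                                        length = integer()))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep],
             length = r$lengths[keep])
}

#' Detect feeding buzzes in call-event streams
#'
#' A feeding buzz is a maximal run of at least `buzz_min_intervals`
#' consecutive inter-call intervals of at most
#' `buzz_max_pulse_interval_ms` (default 10 ms, i.e. repetition rate
#' >= 100 calls/s) within a recording's echolocation calls. Each buzz is
#' assigned to a species(-group) from the search-phase calls preceding it
#' (at least `min_search_calls_for_id` calls, via [classify_sequence()]);
#' with too few preceding search calls the assignment falls back to the
#' recorder-level group band of the buzz calls themselves.
#'
#' @param events Validated, time-sorted call-event table (may span several
#'   recordings; buzzes are detected per recording).
#' @param rules A [classifier_rules()] object.
#' @return Data.frame with one row per buzz: `recording_id`,
#'   `start_time_s`, `end_time_s`, `n_calls`, `min_pulse_interval_ms`,
#'   `assignment`, `assignment_level`, and the global row indices
#'   `first_row`/`last_row` of the first and last buzz call in `events`.
#' @export
detect_feeding_buzzes <- function(events, rules = classifier_rules()) {
  validate_call_events(events)
  out <- list()
  row_id <- seq_len(nrow(events))
  for (rec in unique(events$recording_id)) {
    sel <- events$recording_id == rec & events$category == "echolocation"
    idx <- row_id[sel]
    if (length(idx) < rules$buzz_min_intervals + 1) next
    t_ms <- events$time_s[idx] * 1000
    dt <- diff(t_ms)
    runs <- .runs_of(dt <= rules$buzz_max_pulse_interval_ms)
    runs <- runs[runs$length >= rules$buzz_min_intervals, , drop = FALSE]
    if (nrow(runs) == 0) next
    in_buzz <- rep(FALSE, length(idx))
    for (k in seq_len(nrow(runs)))
      in_buzz[runs$start[k]:(runs$end[k] + 1)] <- TRUE
    for (k in seq_len(nrow(runs))) {
      i0 <- runs$start[k]; i1 <- runs$end[k] + 1L  # call indices within idx
      search <- which(!in_buzz & seq_along(idx) < i0)
      if (length(search) >= rules$min_search_calls_for_id) {
        asg <- classify_sequence(events$end_freq_khz[idx[search]], rules)
      } else {
        g <- unique(group_of_end_frequency(events$end_freq_khz[idx[i0:i1]],
                                           rules))
        asg <- if (length(g) == 1 && !is.na(g))
          list(label = g, level = "group")
        else list(label = "unknown", level = "unknown")
      }
      out[[length(out) + 1]] <- data.frame(
        recording_id = rec,
        start_time_s = events$time_s[idx[i0]],
        end_time_s = events$time_s[idx[i1]],
        n_calls = i1 - i0 + 1L,
        min_pulse_interval_ms = min(dt[runs$start[k]:runs$end[k]]),
        assignment = asg$label, assignment_level = asg$level,
        first_row = idx[i0], last_row = idx[i1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(recording_id = character(), start_time_s = numeric(),
                      end_time_s = numeric(), n_calls = integer(),
                      min_pulse_interval_ms = numeric(),
                      assignment = character(), assignment_level = character(),
                      first_row = integer(), last_row = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# species(-group) labels handled with the strict (>=5 consecutive elements)
# song rule: all Pipistrelloid assignments plus Plecotus, and unidentified
# sequences (conservative).
.strict_song_rule <- function(assignment) {
  lenient <- c("Nyctalus noctula", "Nyctalus leisleri", "Vespertilio murinus",
               "Nyctaloid")
  !(assignment %in% lenient)
}

#' Label social calls and song-eligible song elements
#'
#' Social calls pass through unchanged. Song elements are song-eligible
#' only when, for Pipistrelloid and *Plecotus* assignments, they belong to
#' a run of at least `min_consecutive_song_elements_pip` consecutive song
#' elements (echolocation calls interleaved with the run are ignored; a
#' social call breaks the run). Shorter Pipistrelloid runs are downgraded
#' to social calls. Nyctaloid song elements are song-eligible with no
#' minimum run length.
#'
#' @param events Validated call-event table.
#' @param rules A [classifier_rules()] object.
#' @param assignment Optional named character vector of per-recording
#'   species(-group) assignments; when `NULL` each recording is assigned
#'   via [classify_sequence()] on its echolocation calls.
#' @return `events` with added columns `assignment`, `assignment_level`
#'   and `label` (`"echolocation"`, `"social_call"` or `"song"`).
#' @export
detect_social_and_song_elements <- function(events,
                                            rules = classifier_rules(),
                                            assignment = NULL) {
  validate_call_events(events)
  events$label <- ifelse(events$category == "echolocation", "echolocation",
                         "social_call")
  events$assignment <- NA_character_
  events$assignment_level <- NA_character_
  row_id <- seq_len(nrow(events))
  for (rec in unique(events$recording_id)) {
    sel <- events$recording_id == rec
    if (is.null(assignment) || is.null(assignment[[rec]])) {
      asg <- classify_sequence(events[sel, , drop = FALSE], rules)
    } else {
      asg <- list(label = assignment[[rec]], level = "species")
    }
    events$assignment[sel] <- asg$label
    events$assignment_level[sel] <- asg$level
    # runs of song elements among non-echolocation events
    nidx <- row_id[sel & events$category != "echolocation"]
    if (length(nidx) == 0) next
    is_song <- events$category[nidx] == "song_element"
    runs <- .runs_of(is_song)
    min_run <- if (.strict_song_rule(asg$label))
      rules$min_consecutive_song_elements_pip else 1L
    for (k in seq_len(nrow(runs))) {
      if (runs$length[k] >= min_run)
        events$label[nidx[runs$start[k]:runs$end[k]]] <- "song"
    }
  }
  events
}

#' Assemble song events from song-eligible elements
#'
#' Consecutive song-eligible elements with the same species(-group)
#' assignment and inter-element gaps of at most `song_event_max_gap_s`
#' merge into one song event, which may span several triggered
#' recordings. Event duration is last-element time minus first-element
#' time.
#'
#' @param elements Data.frame of song-eligible elements from one
#'   turbine-night, with columns `time_s`, `assignment` (or
#'   `species_or_group`), `recording_id`, and optionally `turbine_id`.
#' @param rules A [classifier_rules()] object.
#' @return Data.frame with one row per song event: `species_or_group`,
#'   `start_time_s`, `end_time_s`, `duration_s`, `n_elements`,
#'   `n_recordings`, `recording_ids`.
#' @export
assemble_song_events <- function(elements, rules = classifier_rules()) {
  if ("turbine_id" %in% names(elements) &&
      length(unique(elements$turbine_id)) > 1)
    stop("song events must be assembled per turbine-night; got multiple turbines",
         call. = FALSE)
  if (!"assignment" %in% names(elements) &&
      "species_or_group" %in% names(elements))
    elements$assignment <- elements$species_or_group
  out <- list()
  for (sp in unique(elements$assignment)) {
    el <- elements[elements$assignment == sp, , drop = FALSE]
    el <- el[order(el$time_s), , drop = FALSE]
    gap <- c(Inf, diff(el$time_s))
    cluster <- cumsum(gap > rules$song_event_max_gap_s)
    for (cl in unique(cluster)) {
      e <- el[cluster == cl, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        species_or_group = sp,
        start_time_s = min(e$time_s), end_time_s = max(e$time_s),
        duration_s = max(e$time_s) - min(e$time_s),
        n_elements = nrow(e),
        n_recordings = length(unique(e$recording_id)),
        recording_ids = paste(unique(e$recording_id), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(species_or_group = character(), start_time_s = numeric(),
                      end_time_s = numeric(), duration_s = numeric(),
                      n_elements = integer(), n_recordings = integer(),
                      recording_ids = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start_time_s), , drop = FALSE]
}

#' Run the full acoustic classification for one turbine-night
#'
#' Convenience wrapper chaining [detect_feeding_buzzes()],
#' [detect_social_and_song_elements()] and [assemble_song_events()], and
#' returning a small run manifest (rule settings and result counts).
#'
#' @param events Validated call-event table for one turbine-night.
#' @param rules A [classifier_rules()] object.
#' @return List with `labelled` (event table with labels), `buzzes`,
#'   `song_events` and `manifest`.
#' @export
classify_night <- function(events, rules = classifier_rules()) {
  buzzes <- detect_feeding_buzzes(events, rules)
  labelled <- detect_social_and_song_elements(events, rules)
  song_el <- labelled[labelled$label == "song", , drop = FALSE]
  song_events <- assemble_song_events(song_el, rules)
  manifest <- list(
    n_events = nrow(events),
    n_recordings = length(unique(events$recording_id)),
    n_buzzes = nrow(buzzes),
    n_social_calls = sum(labelled$label == "social_call"),
    n_song_elements = sum(labelled$label == "song"),
    n_song_events = nrow(song_events),
    rules = list(
      buzz_max_pulse_interval_ms = rules$buzz_max_pulse_interval_ms,
      buzz_min_intervals = rules$buzz_min_intervals,
      min_consecutive_song_elements_pip =
        rules$min_consecutive_song_elements_pip,
      song_event_max_gap_s = rules$song_event_max_gap_s,
      trigger_dialect = rules$trigger_filter$dialect))
  list(labelled = labelled, buzzes = buzzes, song_events = song_events,
       manifest = manifest)
}
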