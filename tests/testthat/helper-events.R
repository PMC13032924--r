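# compact builder for call-event tables used across the acoustic tests
make_events <- function(time_s, end_freq_khz,
                        category = "echolocation",
                        recording_id = "r1", turbine_id = "T1",
                        duration_ms = 5, sweep = -5) {
  n <- length(time_s)
  data.frame(
    recording_id = rep_len(recording_id, n),
    turbine_id = rep_len(turbine_id, n),
    night_date = "2015-08-01",
    time_s = time_s,
    duration_ms = rep_len(duration_ms, n),
    start_freq_khz = end_freq_khz + 20,
    end_freq_khz = end_freq_khz,
    peak_freq_khz = end_freq_khz + 2,
    sweep_rate_khz_per_ms = rep_len(sweep, n),
    received_level_db_spl = 60,
    category = rep_len(category, n),
    stringsAsFactors = FALSE)
}

# echolocation pulse train with given inter-pulse intervals (ms)
pulse_train <- function(intervals_ms, end_freq_khz = 45, t0 = 0, ...) {
  times <- t0 + c(0, cumsum(intervals_ms)) / 1000
  make_events(times, rep_len(end_freq_khz, length(times)), ...)
}
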