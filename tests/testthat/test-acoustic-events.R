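test_that("trigger filter applies the FM/CF duration, sweep and band criteria", {
  ev <- data.frame(
    duration_ms = c(5, 0.5, 5, 5, 2.5, 40),
    sweep_rate_khz_per_ms = c(-5, -5, -5, -12, 0.5, -5),
    start_freq_khz = c(40, 40, 12, 40, 40, 40),
    end_freq_khz = c(25, 35, 9, 25, 39, 25))
  got <- apply_trigger_filter(ev)
  # FM call in band; too short; entirely below 15 kHz; sweep too steep;
  # CF call in band; too long
  expect_identical(got, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_error(apply_trigger_filter(data.frame(
    duration_ms = -1, sweep_rate_khz_per_ms = -5,
    start_freq_khz = 40, end_freq_khz = 25)), "duration")
  # renebat dialect admits calls up to 100 kHz
  hi <- data.frame(duration_ms = 5, sweep_rate_khz_per_ms = -5,
                   start_freq_khz = 95, end_freq_khz = 85)
  expect_false(apply_trigger_filter(hi))
  expect_true(apply_trigger_filter(hi,
    classifier_rules(trigger_dialect = "renebat")))
})

test_that("sequence classification follows the end-frequency bands", {
  expect_equal(classify_sequence(c(20, 21)),
               list(label = "Nyctalus noctula", level = "species"))
  expect_equal(classify_sequence(c(45, 46)),
               list(label = "Pipistrellus pipistrellus", level = "species"))
  expect_equal(classify_sequence(c(41, 43)),
               list(label = "Pipistrellus spp.", level = "group"))
  expect_equal(classify_sequence(c(50, 52)),
               list(label = "Pipistrellus spp.", level = "group"))
  expect_equal(classify_sequence(c(21, 25)),
               list(label = "Nyctaloid", level = "group"))
  expect_equal(classify_sequence(c(25, 26))$label, "Nyctaloid")
  # the published gap between bands stays unidentified
  expect_equal(classify_sequence(c(29.5, 29.6))$label, "Chiroptera")
  # spanning both groups cannot be resolved
  expect_equal(classify_sequence(c(20, 45))$level, "unknown")
  # too few search calls
  expect_equal(classify_sequence(c(45))$level, "unknown")
  expect_equal(classify_sequence(numeric(0))$level, "unknown")
})

test_that("species assignment is band-consistent on synthetic single-species sequences", {
  tab <- species_parameters()
  set.seed(11)
  for (i in seq_len(nrow(tab))) {
    for (rep in 1:20) {
      f <- runif(sample(2:8, 1), tab$endfreq_lo_khz[i] + 0.1,
                 tab$endfreq_hi_khz[i] - 0.1)
      got <- classify_sequence(f)
      expect_identical(got$label, expected_assignment(tab$species[i]))
    }
  }
})

test_that("buzz detection finds maximal qualifying runs and assigns species", {
  # 5 search calls at 45 kHz then 9 calls at 8 ms spacing
  rec <- rbind(pulse_train(rep(100, 4), end_freq_khz = 45),
               pulse_train(rep(8, 8), end_freq_khz = 45, t0 = 0.6))
  rec <- rec[order(rec$time_s), ]
  bz <- detect_feeding_buzzes(rec)
  expect_equal(nrow(bz), 1)
  expect_equal(bz$n_calls, 9)
  expect_equal(bz$assignment, "Pipistrellus pipistrellus")
  expect_equal(bz$assignment_level, "species")
  expect_lte(bz$min_pulse_interval_ms, 10)

  # uniform 50 ms spacing contains no buzz
  expect_equal(nrow(detect_feeding_buzzes(pulse_train(rep(50, 20)))), 0)

  # two qualifying runs separated by search-phase calls
  rec2 <- rbind(pulse_train(rep(50, 4), end_freq_khz = 20),
                pulse_train(rep(7, 6), end_freq_khz = 20, t0 = 0.5),
                pulse_train(rep(50, 19), end_freq_khz = 20, t0 = 0.8),
                pulse_train(rep(9, 5), end_freq_khz = 20, t0 = 2.2))
  rec2 <- rec2[order(rec2$time_s), ]
  bz2 <- detect_feeding_buzzes(rec2)
  expect_equal(nrow(bz2), 2)
  expect_true(all(bz2$assignment == "Nyctalus noctula"))

  # unsorted events are rejected
  bad <- pulse_train(rep(8, 5))
  bad <- bad[rev(seq_len(nrow(bad))), ]
  expect_error(detect_feeding_buzzes(bad), "sorted")
})

test_that("buzz boundaries match the exhaustive window-scan oracle on random trains", {
  set.seed(42)
  for (rep in 1:25) {
    n_iv <- sample(10:60, 1)
    iv <- ifelse(runif(n_iv) < 0.3, runif(n_iv, 4, 10), runif(n_iv, 12, 80))
    rec <- pulse_train(iv, end_freq_khz = 35)
    bz <- detect_feeding_buzzes(rec)
    t_ms <- rec$time_s * 1000
    oracle <- buzz_windows_oracle(t_ms, max_iv = 10, min_int = 3)
    expect_equal(nrow(bz), nrow(oracle))
    if (nrow(bz) > 0) {
      expect_equal(bz$first_row, oracle$first)
      expect_equal(bz$last_row, oracle$last)
      # contiguity: buzz calls are a contiguous subsequence
      expect_true(all(bz$last_row - bz$first_row + 1 == bz$n_calls))
    }
  }
})

test_that("the five-consecutive-element song rule applies to Pipistrelloid but not Nyctaloid", {
  # Pipistrelloid (P. nathusii search calls), 4 song elements -> all social
  p4 <- rbind(make_events(c(0, 0.1), c(35, 36)),
              make_events(seq(1, 1.6, by = 0.2), 18, category = "song_element"))
  lab4 <- detect_social_and_song_elements(p4)
  expect_equal(sum(lab4$label == "song"), 0)
  expect_equal(sum(lab4$label == "social_call"), 4)

  # 5 elements -> all song-eligible
  p5 <- rbind(make_events(c(0, 0.1), c(35, 36)),
              make_events(seq(1, 1.8, by = 0.2), 18, category = "song_element"))
  lab5 <- detect_social_and_song_elements(p5)
  expect_equal(sum(lab5$label == "song"), 5)

  # N. noctula: two song motifs within a second are song-eligible
  n2 <- rbind(make_events(c(0, 0.1), c(20, 20.5)),
              make_events(c(1, 1.5), 15, category = "song_element"))
  labn <- detect_social_and_song_elements(n2)
  expect_equal(sum(labn$label == "song"), 2)

  # interleaved echolocation does not break a song run; a social call does
  mix <- rbind(make_events(c(0, 0.05), c(35, 36)),
               make_events(c(1, 1.2, 1.4, 1.6, 1.8), 18,
                           category = "song_element"),
               make_events(1.3, 35))
  mix <- mix[order(mix$time_s), ]
  labm <- detect_social_and_song_elements(mix)
  expect_equal(sum(labm$label == "song"), 5)
  broken <- rbind(make_events(c(0, 0.05), c(35, 36)),
                  make_events(c(1, 1.2, 1.4), 18, category = "song_element"),
                  make_events(1.5, 17, category = "social_call"),
                  make_events(c(1.6, 1.8), 18, category = "song_element"))
  broken <- broken[order(broken$time_s), ]
  labb <- detect_social_and_song_elements(broken)
  expect_equal(sum(labb$label == "song"), 0)
})

test_that("labelling conserves events and categories", {
  night <- simulate_night(seed = 3, n_recordings = 30)
  lab <- detect_social_and_song_elements(night$events)
  expect_equal(nrow(lab), nrow(night$events))
  expect_equal(sum(lab$label == "echolocation"),
               sum(night$events$category == "echolocation"))
  expect_equal(sum(lab$label %in% c("social_call", "song")),
               sum(night$events$category != "echolocation"))
})

test_that("song events merge elements across gaps up to the threshold", {
  el <- make_events(0:17, 18, category = "song_element")
  el$assignment <- "Nyctalus noctula"
  ev <- assemble_song_events(el)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 17)
  expect_equal(ev$n_elements, 18)

  el2 <- make_events(c(0:3, 14:16), 18, category = "song_element")
  el2$assignment <- "Nyctalus noctula"
  ev2 <- assemble_song_events(el2)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$duration_s, c(3, 2))

  # mixed turbines are rejected
  elx <- el
  elx$turbine_id <- rep(c("T1", "T2"), 9)
  expect_error(assemble_song_events(elx), "turbine")
})

test_that("song-event count equals the gap-partition oracle on random layouts", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    times <- sort(cumsum(runif(n, 0.2, 9)))
    el <- make_events(times, 18, category = "song_element")
    el$assignment <- "Vespertilio murinus"
    got <- assemble_song_events(el)
    expect_equal(nrow(got), partition_count_oracle(times, 5))
    expect_equal(sum(got$n_elements), n)
  }
})

test_that("classification is deterministic and the manifest counts add up", {
  night <- simulate_night(seed = 8, n_recordings = 25)
  a <- classify_night(night$events)
  b <- classify_night(night$events)
  expect_identical(a$buzzes, b$buzzes)
  expect_identical(a$song_events, b$song_events)
  expect_equal(a$manifest$n_events, nrow(night$events))
  expect_equal(a$manifest$n_social_calls + a$manifest$n_song_elements +
                 sum(a$labelled$label == "echolocation"),
               nrow(night$events))
})
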