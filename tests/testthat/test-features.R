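## piecewise-linear fixture: value `vals[k]` at 0-based sample `nodes[k]`,
## linear in between, constant outside
ramp_wave <- function(nodes, vals, n) {
  approx(nodes, vals, xout = 0:(n - 1), rule = 2)$y
}

test_that("peak/trough marking matches the brute-force rules", {
  ## triangle: flat to sample 20, +1 at 100, -0.5 at 200, back to 0 at 260
  v <- ramp_wave(c(0, 20, 100, 200, 260), c(0, 0, 1, -0.5, 0), 300)
  mk <- mark_peak_trough(v)
  expect_equal(mk$peak_index, 100)
  expect_equal(mk$trough_index, 200)
  expect_equal(mk$peak_voltage, 1)
  expect_equal(mk$trough_voltage, -0.5)

  expect_error(mark_peak_trough(rep(0, 300)),
               class = "nap_error_degenerate_waveform")
  ## peak at the window end leaves no trough search window
  expect_error(mark_peak_trough(ramp_wave(c(0, 30, 99), c(0, 0, 1), 100)),
               class = "nap_error_degenerate_waveform")

  ## tie-break: equal maxima at samples 90 and 140 -> earliest wins
  v2 <- ramp_wave(c(0, 30, 90, 110, 140, 200, 250),
                  c(0, 0, 1, 0.2, 1, -1, 0), 300)
  expect_equal(mark_peak_trough(v2)$peak_index, 90)
})

test_that("half-level latencies and slope amplitudes follow their definitions", {
  fs <- 1e5                            # 0.01 ms/sample: offsets land on-grid
  ## symmetric triangle: -1 to +1 over 1 ms, +1 to -1 over 1 ms
  v <- ramp_wave(c(0, 49, 59, 159, 259, 300, 350),
                 c(0, 0, -1, 1, -1, 0, 0), 400)
  f <- extract_features(v, sample_rate = fs)
  expect_equal(f[["rise_latency"]], 0.5, tolerance = 1e-9)
  expect_equal(f[["decline_latency"]], 0.5, tolerance = 1e-9)
  expect_equal(f[["duration"]], 1.0, tolerance = 1e-9)
  expect_equal(f[["peak_to_peak_amplitude"]], 2)

  ## descent slope -10 units/ms from a peak of +1 -> decline amplitude 0.8
  v2 <- ramp_wave(c(0, 20, 100, 120, 300), c(0, 0, 1, -1, -1), 400)
  f2 <- extract_features(v2, sample_rate = fs)
  expect_equal(f2[["decline_amplitude"]], 0.8, tolerance = 1e-9)

  ## peak latency 0.5 ms at 1 cm -> 20 m/s
  v3 <- ramp_wave(c(0, 20, 50, 80, 300), c(0, 0, 1, -1, -0.2), 400)
  f3 <- extract_features(v3, sample_rate = fs, electrode_distance_cm = 1)
  expect_equal(f3[["velocity"]], 20, tolerance = 1e-9)

  ## recovery never reaching the half-level is missing, not an error
  v4 <- ramp_wave(c(0, 20, 100, 150, 400), c(0, 0, 1, -1, -1), 400)
  f4 <- extract_features(v4, sample_rate = fs)
  expect_true(is.na(f4[["recovery_latency"]]))
})

test_that("fractional marks agree with the dense-scan oracle", {
  for (i in 1:100) {
    v <- rand_nap(i)
    mk <- tryCatch(mark_peak_trough(v), nap_error = function(e) NULL)
    or <- oracle_mark(v)
    if (is.null(mk) || is.null(or)) next
    expect_equal(mk$peak_index, or$pk0, tolerance = 1e-12)
    expect_equal(mk$trough_index, or$tr0, tolerance = 1e-12)
    f <- extract_features(v)
    dt <- 1000 / 99000
    half <- (or$vp + or$vt) / 2
    dn <- oracle_cross_down(or$u, half, or$pk0)
    expect_equal(f[["decline_latency"]], (dn - or$pk0) * dt, tolerance = 1e-9)
    up <- oracle_last_up_before(or$u, half, or$pk0, 10)
    expect_equal(f[["rise_latency"]], (or$pk0 - up) * dt, tolerance = 1e-9)
    rec <- oracle_cross_up(or$u, or$vt / 2, or$tr0)
    expect_equal(f[["recovery_latency"]],
                 if (is.na(rec)) NA_real_ else (rec - or$tr0) * dt,
                 tolerance = 1e-9)
  }
})

test_that("features are scale- and shift-equivariant", {
  amp_feats <- c("peak_to_peak_amplitude", "peak_amplitude",
                 "trough_amplitude", "decline_amplitude", "rise_amplitude",
                 "recovery_amplitude")
  lat_feats <- c("velocity", "duration", "decline_latency", "rise_latency",
                 "recovery_latency")
  for (i in 1:20) {
    v <- rand_nap(i)
    f <- extract_features(v)
    s <- 2.5
    fs_ <- extract_features(v * s)
    expect_equal(fs_[amp_feats], f[amp_feats] * s, tolerance = 1e-9)
    expect_equal(fs_[lat_feats], f[lat_feats], tolerance = 1e-9)
    ## delay by 7 samples (front-padded with the pre-artifact value)
    d <- 7L
    vd <- c(rep(v[1], d), v[seq_len(length(v) - d)])
    ## guard: padding must not disturb the baseline window estimate
    if (abs(mean(vd[11:20]) - mean(v[11:20])) > 1e-6) next
    fd <- extract_features(vd)
    expect_equal(fd[["duration"]], f[["duration"]], tolerance = 1e-8)
    expect_equal(fd[["decline_latency"]], f[["decline_latency"]],
                 tolerance = 1e-8)
    expect_lt(fd[["velocity"]], f[["velocity"]])
  }
})

test_that("stimulus response ratios use the per-set reference", {
  expect_equal(compute_srr(c(1, 2, 3, 4, 5, 6, 8), 0),
               c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 1))
  expect_equal(compute_srr(c(2, 1, 1, 1, 1, 1, 1), 1)[1], 1)
  expect_error(compute_srr(c(0, 1, 1, 1, 1, 1, 1), 1),
               class = "nap_error_undefined_ratio")
  expect_error(compute_srr(1:5, 0), class = "nap_error_invalid_input")
})

test_that("baseline normalization divides by the segment-3 mean", {
  feat <- data.table::rbindlist(lapply(3:6, function(j)
    feat_row(nerve = 1, conc = 0, value = 2.0, expttime = j)))
  feat$value <- c(2.0, 1.2, 2.0, 2.0)
  norm <- normalize_to_baseline(feat, 3, 4:6)
  expect_equal(norm$normalized_value, c(0.6, 1, 1))
  expect_identical(sort(unique(norm$expttime)), 4:6)

  ## zero baseline -> missing, never infinite
  featz <- data.table::rbindlist(list(
    feat_row(1, 0, 0, expttime = 3), feat_row(1, 0, 1.5, expttime = 4)))
  nz <- normalize_to_baseline(featz, 3, 4)
  expect_true(is.na(nz$normalized_value))
  expect_error(normalize_to_baseline(feat_row(1, 0, 1, expttime = 5), 3, 4:6),
               class = "nap_error_insufficient_data")
})

test_that("batch feature tables propagate degenerate records as missing", {
  ds <- simulate_experiment(tiny_design(), population = tiny_pop(0),
                            seed = 6, segments = 3:4, sets = 0, nerves = 1:3)
  ## records that are flat after the artifact (no recruited class at zero
  ## noise) must come out missing, the rest finite
  feat <- features_table(ds)
  flat <- vapply(seq_len(nrow(ds$meta)), function(i) {
    x <- ds$waveforms[i, 11:256]
    max(x) == min(x)
  }, logical(1))
  expect_gt(sum(flat), 0L)              # 1 mA is sub-threshold for some nerves
  f1 <- feat[feat$parameter == "peak_to_peak_amplitude", ]
  data.table::setorderv(f1, c("nerve", "expttime", "stim_set", "seq"))
  m2 <- data.table::copy(ds$meta)[, row := .I]
  data.table::setorderv(m2, c("nerve", "expttime", "stim_set", "seq"))
  expect_identical(is.na(f1$value), flat[m2$row])
  f7 <- feat[feat$seq == 7 & feat$parameter == "peak_to_peak_amplitude", ]
  expect_true(all(is.finite(f7$value)))
  ## srr for set 0 is relative to SEQ 7
  s7 <- feat[feat$seq == 7 & feat$parameter == "srr", ]
  expect_true(all(abs(s7$value - 1) < 1e-12))
})
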