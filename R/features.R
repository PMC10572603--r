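#' Marking configuration for automated NAP feature extraction
#'
#' @param artifact_samples samples excluded at the window start (stimulus
#'   artifact region)
#' @param baseline_len samples used for the baseline estimate, starting at
#'   `artifact_samples` (a pre-response window)
#' @param slope_offset_rise_decline_ms fixed offset for the rise/decline
#'   amplitude descriptors, ms
#' @param slope_offset_recovery_ms fixed offset for the recovery amplitude
#'   descriptor, ms
#' @return an object of class `nap_marking`
#' @export
mark_config <- function(artifact_samples = 10, baseline_len = 10,
                        slope_offset_rise_decline_ms = 0.08,
                        slope_offset_recovery_ms = 0.16) {
  if (artifact_samples < 0 || baseline_len < 1)
    nap_stop("invalid marking window sizes", "nap_error_invalid_config")
  if (slope_offset_rise_decline_ms <= 0 || slope_offset_recovery_ms <= 0)
    nap_stop("slope offsets must be > 0", "nap_error_invalid_config")
  structure(list(artifact_samples = as.integer(artifact_samples),
                 baseline_len = as.integer(baseline_len),
                 slope_offset_rise_decline_ms = slope_offset_rise_decline_ms,
                 slope_offset_recovery_ms = slope_offset_recovery_ms),
            class = "nap_marking")
}

## linear interpolation at fractional 0-based index, clamped to the window
interp_at <- function(v, idx0) {
  n <- length(v)
  idx0 <- pmin(pmax(idx0, 0), n - 1)
  lo <- floor(idx0)
  fr <- idx0 - lo
  lo1 <- lo + 1
  hi1 <- pmin(lo1 + 1, n)
  (1 - fr) * v[lo1] + fr * v[hi1]
}

## first index (0-based, fractional) at or after `from0` where v crosses
## `level` in the given direction ("down": from >= level to < level;
## "up": from <= level to > level); NA if never
first_crossing <- function(v, level, from0, direction) {
  n <- length(v)
  i0 <- max(0L, ceiling(from0))
  if (i0 >= n - 1L) return(NA_real_)
  idx <- (i0 + 1L):(n - 1L)         # 1-based left endpoints i0+1 .. n-1
  a <- v[idx]
  b <- v[idx + 1L]
  hit <- if (direction == "down") a >= level & b < level else
    a <= level & b > level
  if (!any(hit)) return(NA_real_)
  j <- idx[which(hit)[1L]]          # 1-based left endpoint
  frac <- if (b[which(hit)[1L]] == a[which(hit)[1L]]) 0 else
    (level - v[j]) / (v[j + 1L] - v[j])
  (j - 1L) + frac                   # 0-based fractional index
}

## last upward crossing of `level` strictly before 0-based index `before0`,
## searching no earlier than `from0`
last_up_crossing_before <- function(v, level, before0, from0) {
  i_lo <- max(0L, floor(from0))
  i_hi <- floor(before0) - 1L
  if (i_hi < i_lo) return(NA_real_)
  idx <- (i_lo + 1L):(i_hi + 1L)    # 1-based left endpoints
  a <- v[idx]
  b <- v[idx + 1L]
  hit <- a <= level & b > level
  if (!any(hit)) return(NA_real_)
  j <- idx[tail(which(hit), 1L)]
  frac <- (level - v[j]) / (v[j + 1L] - v[j])
  (j - 1L) + frac
}

#' Mark the peak and trough of one NAP trace
#'
#' The peak is the maximum voltage after the artifact region and the trough
#' the minimum voltage after the peak (positive-peak-first polarity). Ties
#' are broken by the earliest sample. Voltages are reported after
#' subtraction of the baseline, estimated as the mean of a pre-response
#' window at the start of the post-artifact region.
#'
#' @param samples numeric vector of voltages
#' @param cfg a [mark_config()]
#' @return list with `peak_index`, `trough_index` (0-based, as doubles),
#'   `peak_voltage`, `trough_voltage` (baseline-subtracted) and `baseline`
#' @export
mark_peak_trough <- function(samples, cfg = mark_config()) {
  n <- length(samples)
  a <- cfg$artifact_samples
  if (n <= a + 4L)
    nap_stop("window too short for marking", "nap_error_invalid_input")
  base <- mean(samples[(a + 1L):min(n, a + cfg$baseline_len)])
  v <- samples - base
  post <- (a + 1L):n
  if (max(v[post]) == min(v[post]))
    nap_stop("flat post-artifact trace cannot be marked",
             "nap_error_degenerate_waveform")
  pk <- post[which.max(v[post])]            # earliest tie, 1-based
  if (pk >= n)
    nap_stop("empty trough search window (peak at window end)",
             "nap_error_degenerate_waveform")
  after <- (pk + 1L):n
  tr <- after[which.min(v[after])]
  list(peak_index = as.numeric(pk - 1L), trough_index = as.numeric(tr - 1L),
       peak_voltage = v[pk], trough_voltage = v[tr], baseline = base)
}

#' Extract the NAP feature vector from one trace
#'
#' Computes eleven of the twelve descriptors (the stimulus response ratio is
#' defined only relative to the other stimuli of a set; see
#' [compute_srr()]): peak-to-peak / peak / trough amplitudes, conduction
#' velocity (electrode distance over peak latency), duration (peak-to-trough
#' time), half-level rise/decline latencies, fixed-offset rise/decline
#' amplitudes (0.08 ms), recovery latency (first return to halfway between
#' trough and baseline) and recovery amplitude (0.16 ms past the trough).
#' Half-level crossings are located by linear interpolation between
#' bracketing samples; off-grid voltages are linearly interpolated. A
#' recovery half-level never reached within the window yields `NA` (missing,
#' not an error).
#'
#' @param samples numeric vector of voltages
#' @param cfg a [mark_config()]
#' @param electrode_distance_cm stimulating-to-recording distance, cm
#' @param sample_rate Hz
#' @return named numeric vector over [nap_parameters()] (with `srr = NA`);
#'   latencies and duration in ms, velocity in m/s
#' @export
extract_features <- function(samples, cfg = mark_config(),
                             electrode_distance_cm = 1, sample_rate = 99000) {
  mk <- mark_peak_trough(samples, cfg)
  v <- samples - mk$baseline
  dt_ms <- 1000 / sample_rate
  pk <- mk$peak_index
  tr <- mk$trough_index
  vp <- mk$peak_voltage
  vt <- mk$trough_voltage
  half_pt <- (vp + vt) / 2

  peak_latency_ms <- pk * dt_ms
  velocity <- (electrode_distance_cm / 100) / (peak_latency_ms / 1000)
  duration <- (tr - pk) * dt_ms

  dn <- first_crossing(v, half_pt, pk, "down")
  decline_latency <- if (is.na(dn)) NA_real_ else (dn - pk) * dt_ms
  up <- last_up_crossing_before(v, half_pt, pk, cfg$artifact_samples)
  rise_latency <- if (is.na(up)) NA_real_ else (pk - up) * dt_ms

  half_rec <- vt / 2                       # halfway trough -> baseline (= 0)
  rec <- first_crossing(v, half_rec, tr, "up")
  recovery_latency <- if (is.na(rec)) NA_real_ else (rec - tr) * dt_ms

  off1 <- cfg$slope_offset_rise_decline_ms / dt_ms
  off2 <- cfg$slope_offset_recovery_ms / dt_ms
  decline_amplitude <- vp - interp_at(v, pk + off1)
  rise_amplitude <- vp - interp_at(v, pk - off1)
  recovery_amplitude <- interp_at(v, tr + off2) - vt

  c(peak_to_peak_amplitude = vp - vt,
    peak_amplitude = vp,
    trough_amplitude = vt,
    velocity = velocity,
    duration = duration,
    decline_latency = decline_latency,
    rise_latency = rise_latency,
    decline_amplitude = decline_amplitude,
    rise_amplitude = rise_amplitude,
    recovery_latency = recovery_latency,
    recovery_amplitude = recovery_amplitude,
    srr = NA_real_)
}

#' Stimulus response ratios within one seven-stimulus set
#'
#' For set 0 (increasing current) each peak-to-peak amplitude is divided by
#' that of the last stimulus (largest current); for set 1 (shortening ISI)
#' by that of the first stimulus (longest ISI).
#'
#' @param pp peak-to-peak amplitudes ordered by SEQ 1..7
#' @param set_id 0 or 1
#' @return numeric vector of 7 ratios
#' @export
compute_srr <- function(pp, set_id) {
  if (length(pp) != 7L)
    nap_stop("all 7 SEQ amplitudes are required", "nap_error_invalid_input")
  ref <- if (set_id == 0) pp[7L] else pp[1L]
  if (is.na(ref) || ref <= 0)
    nap_stop("reference amplitude must be > 0", "nap_error_undefined_ratio")
  pp / ref
}

## fast peak-to-peak only extraction for one record (post-artifact peak, then
## trough after the peak) -- used by the power/calibration loops
pp_only <- function(samples, artifact_samples) {
  v <- samples[(artifact_samples + 1L):length(samples)]
  pk <- which.max(v)
  if (pk >= length(v)) return(NA_real_)
  v[pk] - min(v[(pk + 1L):length(v)])
}

#' Build the long feature table of a dataset
#'
#' Runs the marking algorithm on every record, then attaches the stimulus
#' response ratio per (nerve, segment, set). Records whose marking fails
#' (flat or otherwise degenerate traces) contribute missing values for all
#' parameters rather than aborting the batch.
#'
#' @param dataset a `nap_dataset`
#' @param cfg a [mark_config()]
#' @param parameters `NULL` for all twelve, or `"peak_to_peak_amplitude"`
#'   for a fast amplitude-only path
#' @return data.table with columns nerve, conc, expttime, stim_set, seq,
#'   parameter, value
#' @export
features_table <- function(dataset, cfg = mark_config(), parameters = NULL) {
  m <- dataset$meta
  W <- dataset$waveforms
  ed <- if (!is.null(dataset$design)) dataset$design$electrode_distance_cm else 1
  fs <- if (!is.null(dataset$design)) dataset$design$sample_rate else 99000

  if (identical(parameters, "peak_to_peak_amplitude")) {
    pp <- vapply(seq_len(nrow(W)), function(i)
      pp_only(W[i, ], cfg$artifact_samples), numeric(1))
    out <- data.table::copy(m)
    out[, `:=`(parameter = "peak_to_peak_amplitude", value = pp)]
    return(out[])
  }

  nfeat <- length(NAP_PARAMETERS)
  F <- matrix(NA_real_, nrow = nrow(W), ncol = nfeat,
              dimnames = list(NULL, NAP_PARAMETERS))
  for (i in seq_len(nrow(W))) {
    f <- tryCatch(extract_features(W[i, ], cfg, ed, fs),
                  nap_error_degenerate_waveform = function(e) NULL)
    if (!is.null(f)) F[i, ] <- f
  }
  ## SRR per (nerve, expttime, set) from the seven peak-to-peak amplitudes
  key <- paste(m$nerve, m$expttime, m$stim_set)
  for (g in split(seq_len(nrow(m)), key)) {
    if (length(g) != 7L) next
    ord <- g[order(m$seq[g])]
    srr <- tryCatch(compute_srr(F[ord, "peak_to_peak_amplitude"],
                                m$stim_set[ord[1L]]),
                    nap_error = function(e) rep(NA_real_, 7))
    F[ord, "srr"] <- srr
  }
  long <- data.table::data.table(
    nerve = rep(m$nerve, nfeat), conc = rep(m$conc, nfeat),
    expttime = rep(m$expttime, nfeat), stim_set = rep(m$stim_set, nfeat),
    seq = rep(m$seq, nfeat),
    parameter = rep(NAP_PARAMETERS, each = nrow(m)),
    value = as.vector(F))
  if (!is.null(parameters)) long <- long[parameter %in% parameters]
  long[]
}

#' Normalize abstracted parameters to the pre-drug baseline segment
#'
#' Every parameter is divided by its own value in the baseline segment
#' (segment 3, the last pre-drug segment) per (nerve, set, SEQ, parameter),
#' so all parameters equal 1 there; only the drug-phase analysis segments
#' are retained. A zero or missing baseline marks the parameter missing for
#' that key (never infinite).
#'
#' @param feat long feature table from [features_table()]
#' @param baseline_segment segment used as the normalizer
#' @param segments analysis segments to retain (intersected with those
#'   present)
#' @return the table restricted to analysis segments, with a
#'   `normalized_value` column added
#' @export
normalize_to_baseline <- function(feat, baseline_segment = 3,
                                  segments = 4:36) {
  base <- feat[expttime == baseline_segment,
               .(base = mean(value)),
               by = .(nerve, stim_set, seq, parameter)]
  if (nrow(base) == 0L)
    nap_stop("baseline segment absent from the feature table",
             "nap_error_insufficient_data")
  out <- feat[expttime %in% segments]
  out <- base[out, on = c("nerve", "stim_set", "seq", "parameter")]
  out[, normalized_value := ifelse(is.na(base) | base == 0, NA_real_,
                                   value / base)]
  out[, base := NULL]
  data.table::setcolorder(out, c("nerve", "conc", "expttime", "stim_set",
                                 "seq", "parameter", "value",
                                 "normalized_value"))
  out[]
}
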