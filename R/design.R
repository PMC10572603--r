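#' Stimulus protocol: two interleaved seven-stimulus sets
#'
#' The default protocol delivers two alternating sets of seven stimuli.
#' Set 0 increases the stimulus current from 1 to 15 mA at a fixed 4 ms
#' inter-stimulus interval (ISI); set 1 holds the current at the
#' supramaximal 15 mA and shortens the ISI from 166 ms down to 1 ms,
#' probing refractoriness. One set is delivered every 4 s so a full cycle
#' of both sets takes 8 s.
#'
#' @param set0_currents stimulus currents of set 0 in mA, strictly increasing,
#'   length 7
#' @param set0_isi inter-stimulus interval within set 0, ms
#' @param set1_current constant current of set 1, mA
#' @param set1_isis ISIs of set 1 in ms, strictly decreasing, length 7
#' @param sets_per_cycle number of sets per stimulation cycle
#' @param cycle_period seconds per full cycle
#' @return an object of class `nap_protocol`
#' @export
nap_protocol <- function(set0_currents = c(1, 2, 3, 4, 6, 10, 15),
                         set0_isi = 4,
                         set1_current = 15,
                         set1_isis = c(166, 8, 4, 3, 2, 1.5, 1),
                         sets_per_cycle = 2,
                         cycle_period = 8) {
  if (length(set0_currents) != 7L || any(diff(set0_currents) <= 0))
    nap_stop("set0_currents must be 7 strictly increasing values",
             "nap_error_invalid_config")
  if (length(set1_isis) != 7L || any(diff(set1_isis) >= 0))
    nap_stop("set1_isis must be 7 strictly decreasing values",
             "nap_error_invalid_config")
  if (any(c(set0_currents, set0_isi, set1_current, set1_isis) <= 0))
    nap_stop("all currents and ISIs must be strictly positive",
             "nap_error_invalid_config")
  structure(list(set0_currents = as.numeric(set0_currents),
                 set0_isi = as.numeric(set0_isi),
                 set1_current = as.numeric(set1_current),
                 set1_isis = as.numeric(set1_isis),
                 sets_per_cycle = sets_per_cycle,
                 cycle_period = cycle_period),
            class = "nap_protocol")
}

## current and preceding ISI for stimulus `seq` (1..7) of set `set` (0/1).
## The first stimulus of either set follows the long inter-set gap, treated
## as an infinite recovery interval; within set 1 the listed ISI of position
## k is the interval preceding stimulus k.
protocol_condition <- function(protocol, set, seq) {
  if (set == 0L) {
    list(current = protocol$set0_currents[seq],
         isi = if (seq == 1L) Inf else protocol$set0_isi)
  } else {
    list(current = protocol$set1_current,
         isi = protocol$set1_isis[seq])
  }
}

#' Experiment design: concentration groups and segment schedule
#'
#' Describes one multi-nerve bath-application experiment: nine concentration
#' groups coded by the ordinal variable CONC (0 = vehicle), 36 thirty-minute
#' segments (EXPTTIME) with the compound added at the start of segment 4,
#' and the acquisition geometry (sampling rate, stored window, distance from
#' stimulating to recording electrodes).
#'
#' @param conc_molar molar concentration per CONC ordinal 0..8
#' @param n_nerves nerves per CONC group (defaults sum to 112)
#' @param n_segments number of 30-min segments
#' @param drug_onset_segment segment at whose start the compound is added
#' @param sample_rate digitization rate, Hz
#' @param window_samples samples stored per averaged NAP
#' @param electrode_distance_cm stimulating-to-recording distance, cm
#' @return an object of class `nap_design`
#' @export
nap_design <- function(conc_molar = c(0, 70e-12, 700e-12, 7e-9, 70e-9,
                                      700e-9, 7e-6, 70e-6, 700e-6),
                       n_nerves = c(40, 8, 8, 8, 8, 8, 8, 8, 16),
                       n_segments = 36,
                       drug_onset_segment = 4,
                       sample_rate = 99000,
                       window_samples = 512,
                       electrode_distance_cm = 1) {
  if (length(conc_molar) != length(n_nerves))
    nap_stop("conc_molar and n_nerves must have equal length",
             "nap_error_invalid_config")
  if (any(n_nerves <= 0) || any(n_nerves != round(n_nerves)))
    nap_stop("group nerve counts must be positive integers",
             "nap_error_invalid_config")
  stopifnot_scalar_num(sample_rate, "sample_rate")
  stopifnot_scalar_num(window_samples, "window_samples")
  stopifnot_scalar_num(electrode_distance_cm, "electrode_distance_cm")
  structure(list(conc_molar = as.numeric(conc_molar),
                 n_nerves = as.integer(n_nerves),
                 n_segments = as.integer(n_segments),
                 drug_onset_segment = as.integer(drug_onset_segment),
                 sample_rate = as.numeric(sample_rate),
                 window_samples = as.integer(window_samples),
                 electrode_distance_cm = as.numeric(electrode_distance_cm)),
            class = "nap_design")
}

#' @export
print.nap_design <- function(x, ...) {
  cat(sprintf("<nap_design> %d nerves in %d CONC groups, %d segments, %g kHz\n",
              sum(x$n_nerves), length(x$n_nerves), x$n_segments,
              x$sample_rate / 1000))
  invisible(x)
}

#' Segments entering the statistical analyses
#'
#' The first two segments are equilibration, segment 3 is the normalization
#' baseline, and the compound is present from `drug_onset_segment` onward;
#' only those drug-phase segments are analysed.
#'
#' @param design a [nap_design()]
#' @return integer vector of analysis segments (default 4..36)
#' @export
analysis_segments <- function(design = nap_design()) {
  seq.int(design$drug_onset_segment, design$n_segments)
}

#' Axon population model for the compound-NAP simulator
#'
#' A nerve is modelled as `n_classes` axon classes with lognormal conduction
#' velocities and recruitment thresholds. Each class contributes a biphasic
#' unit potential (difference of two Gaussians, positive lobe first) delayed
#' by conduction time over the electrode distance. A class fires when the
#' stimulus current exceeds its (possibly drug-elevated) threshold, scaled
#' by an availability factor `1 - exp(-ISI/refractory_tau)` that models
#' residual sodium-channel inactivation at short inter-stimulus intervals.
#' Slow multiplicative amplitude decline with time constant `wallerian_tau`
#' (in segments) emulates Wallerian degeneration of the excised nerve.
#'
#' Electrode-placement variability across nerves enters through a lognormal
#' per-nerve gain, a lognormal perturbation of the nominal electrode
#' distance and a small constant voltage offset; these are what the
#' template-registration stage is designed to remove.
#'
#' @param n_classes number of axon classes
#' @param velocity_meanlog,velocity_sdlog lognormal conduction velocity (m/s)
#' @param threshold_meanlog,threshold_sdlog lognormal recruitment threshold (mA)
#' @param pos_width_ms,neg_width_ms widths of the positive and negative lobes
#'   of the unit kernel, ms
#' @param lobe_ratio amplitude of the negative lobe relative to the positive,
#'   in (0, 1]
#' @param refractory_tau_ms recovery time constant of availability, ms
#' @param wallerian_tau amplitude-decline time constant, segments
#' @param noise_sd additive Gaussian noise, as a fraction of the nerve's
#'   baseline (supramaximal, fully recovered) peak-to-peak amplitude
#' @param artifact_amp amplitude of the deterministic stimulus artifact
#'   confined to the first 10 samples, absolute units
#' @param gain_sdlog lognormal sd of the per-nerve recording gain
#' @param distance_sdlog lognormal sd of the per-nerve electrode distance
#' @param offset_sd sd of the per-nerve constant voltage offset
#' @return an object of class `nap_population`
#' @export
axon_population <- function(n_classes = 120,
                            velocity_meanlog = log(40), velocity_sdlog = 0.35,
                            threshold_meanlog = log(3), threshold_sdlog = 0.5,
                            pos_width_ms = 0.15, neg_width_ms = 0.30,
                            lobe_ratio = 0.6,
                            refractory_tau_ms = 1.0,
                            wallerian_tau = 60,
                            noise_sd = 0.02,
                            artifact_amp = 0.5,
                            gain_sdlog = 0.2,
                            distance_sdlog = 0.08,
                            offset_sd = 0.01) {
  for (nm in c("pos_width_ms", "neg_width_ms", "refractory_tau_ms",
               "wallerian_tau"))
    stopifnot_scalar_num(get(nm), nm)
  if (lobe_ratio <= 0 || lobe_ratio > 1)
    nap_stop("lobe_ratio must be in (0, 1]", "nap_error_invalid_config")
  if (noise_sd < 0)
    nap_stop("noise_sd must be >= 0", "nap_error_invalid_config")
  structure(as.list(environment()), class = "nap_population")
}

#' Drug-effect model: non-monotonic dose response with slow onset
#'
#' `effect_by_conc` gives, per CONC ordinal, the maximal fractional
#' depression of NAP amplitude once the effect has fully developed. The
#' default profile is non-monotonic: zero in vehicle, growing through the
#' picomolar-nanomolar range to a maximum of 25% at CONC 4 (70 nM), and
#' falling back to near zero at the highest concentrations. The effect
#' ramps in sigmoidally over roughly 10-15 segments (5-8 h) after the
#' compound is added. Two unitless couplings let the same latent effect
#' elevate recruitment thresholds (so low currents are hit harder) and
#' elongate the refractory time constant (so short ISIs are hit harder).
#'
#' @param effect_by_conc maximal fractional amplitude depression per CONC
#'   ordinal; first entry (vehicle) must be 0
#' @param onset_mid sigmoid midpoint, segments after drug onset
#' @param onset_width sigmoid width, segments
#' @param threshold_shift_gain coupling of effect to threshold elevation
#' @param refractory_gain coupling of effect to refractory elongation
#' @return an object of class `nap_drug`
#' @export
drug_effect <- function(effect_by_conc = c(0, 0.06, 0.10, 0.16, 0.25,
                                           0.18, 0.10, 0.03, 0.01),
                        onset_mid = 6, onset_width = 2,
                        threshold_shift_gain = 1,
                        refractory_gain = 1) {
  if (effect_by_conc[1] != 0)
    nap_stop("effect_by_conc must be 0 for the vehicle group (CONC 0)",
             "nap_error_invalid_config")
  if (any(effect_by_conc < 0) || any(effect_by_conc >= 1))
    nap_stop("effect_by_conc entries must be in [0, 1)",
             "nap_error_invalid_config")
  structure(list(effect_by_conc = as.numeric(effect_by_conc),
                 onset_mid = onset_mid, onset_width = onset_width,
                 threshold_shift_gain = threshold_shift_gain,
                 refractory_gain = refractory_gain),
            class = "nap_drug")
}

#' Null drug model (no effect at any concentration)
#' @param n_conc number of concentration groups
#' @return a [drug_effect()] with all effects zero
#' @export
null_drug <- function(n_conc = 9) drug_effect(effect_by_conc = rep(0, n_conc))

#' Onset ramp of the drug effect
#'
#' Zero before the onset segment, then a logistic rise reaching >= 0.95
#' within 10-15 segments after onset at the default midpoint/width.
#'
#' @param segment segment index (EXPTTIME), vectorized
#' @param drug a [drug_effect()]
#' @param onset_segment segment at which the compound is added
#' @return ramp values in \[0, 1\], non-decreasing in `segment`
#' @export
drug_ramp <- function(segment, drug, onset_segment = 4) {
  r <- plogis((segment - onset_segment - drug$onset_mid) / drug$onset_width)
  r[segment < onset_segment] <- 0
  r
}
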