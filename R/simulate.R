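## ---- low-level simulator machinery ----------------------------------------

## biphasic unit potential: difference of two Gaussians, positive lobe first.
## t_ms is time relative to the arrival of the unit at the recording site.
unit_kernel <- function(t_ms, pop) {
  pw <- pop$pos_width_ms
  nw <- pop$neg_width_ms
  lag <- 2 * pw + 1.5 * (pw + nw)   # trough center relative to arrival
  exp(-0.5 * ((t_ms - 2 * pw) / pw)^2) -
    pop$lobe_ratio * exp(-0.5 * ((t_ms - lag) / nw)^2)
}

## kernel matrix: window_samples x n_classes, column c = unit potential of
## class c delayed by its conduction time tau_ms[c]
kernel_matrix <- function(tau_ms, t_ms, pop) {
  vapply(tau_ms, function(tau) unit_kernel(t_ms - tau, pop),
         numeric(length(t_ms)))
}

## deterministic stimulus artifact confined to samples 0..9 (0-based)
artifact_vector <- function(window_samples, amp) {
  v <- numeric(window_samples)
  i <- 0:9
  v[i + 1L] <- amp * exp(-i / 2) * cos(1.8 * i)
  v
}

## availability of sodium channels after a preceding ISI (ms); Inf -> 1
availability <- function(isi_ms, tau_ms) {
  ifelse(is.infinite(isi_ms), 1, 1 - exp(-isi_ms / tau_ms))
}

## draw the fixed per-nerve quantities from the nerve's own RNG stream
draw_nerve <- function(pop, seed) {
  set.seed(seed)
  list(
    velocity = rlnorm(pop$n_classes, pop$velocity_meanlog, pop$velocity_sdlog),
    threshold = rlnorm(pop$n_classes, pop$threshold_meanlog,
                       pop$threshold_sdlog),
    gain = rlnorm(1, 0, pop$gain_sdlog),
    dist_factor = rlnorm(1, 0, pop$distance_sdlog),
    offset = rnorm(1, 0, pop$offset_sd)
  )
}

## ---- single-waveform simulation -------------------------------------------

#' Simulate one compound NAP waveform
#'
#' Sums the delayed biphasic unit potentials of all axon classes recruited at
#' the given stimulus current, each weighted by the availability factor for
#' the preceding inter-stimulus interval, then adds the stimulus artifact
#' (samples 0-9 only) and optional Gaussian noise. Deterministic for a fixed
#' seed.
#'
#' @param population an [axon_population()]
#' @param current stimulus current, mA (> 0)
#' @param preceding_isi preceding inter-stimulus interval, ms (> 0 or `Inf`
#'   for the first stimulus of a set)
#' @param amplitude_scale multiplicative amplitude factor (Wallerian decline
#'   times drug depression)
#' @param threshold_scale multiplicative elevation of recruitment thresholds
#' @param seed RNG seed for the class draws and noise
#' @param sample_rate Hz
#' @param window_samples stored samples
#' @param distance_cm conduction distance, cm
#' @return numeric vector of `window_samples` voltages
#' @export
simulate_nap <- function(population, current, preceding_isi,
                         amplitude_scale = 1, threshold_scale = 1,
                         seed = 1, sample_rate = 99000,
                         window_samples = 512, distance_cm = 1) {
  if (!is.numeric(current) || current <= 0)
    nap_stop("stimulus current must be > 0", "nap_error_invalid_input")
  if (!is.numeric(preceding_isi) || preceding_isi <= 0)
    nap_stop("preceding ISI must be > 0 (or Inf)", "nap_error_invalid_input")
  nv <- draw_nerve(population, seed)
  t_ms <- (seq_len(window_samples) - 1) / sample_rate * 1000
  tau_ms <- distance_cm * 10 / nv$velocity   # (cm/100)/v in s -> ms
  K <- kernel_matrix(tau_ms, t_ms, population)
  recruit <- nv$threshold * threshold_scale <= current
  avail <- availability(preceding_isi, population$refractory_tau_ms)
  w <- recruit * avail / population$n_classes * amplitude_scale
  v <- drop(K %*% w)
  ref <- drop(K %*% rep(1 / population$n_classes, population$n_classes))
  pp_ref <- max(ref) - min(ref)
  v <- v + artifact_vector(window_samples, population$artifact_amp)
  if (population$noise_sd > 0)
    v <- v + rnorm(window_samples, 0, population$noise_sd * pp_ref)
  v
}

## ---- whole-experiment simulation ------------------------------------------

#' Simulate a multi-nerve bath-application experiment
#'
#' Produces one segment-mean waveform per (nerve, segment, stimulus set, SEQ).
#' The amplitude scale of nerve n at segment j is
#' `exp(-(j-1)/wallerian_tau) * (1 - effect * ramp(j))`, where `effect` is the
#' maximal fractional depression for the nerve's CONC group and `ramp` is the
#' sigmoidal onset; the same latent quantity elevates recruitment thresholds
#' and elongates the refractory time constant through the drug couplings.
#' Vehicle (CONC 0) records carry no drug effect at any segment.
#'
#' Each nerve draws its axon classes and electrode-placement factors from a
#' private RNG stream derived by fixed hashing from `seed`, so a nerve's
#' records do not depend on which subset of nerves/segments is generated.
#'
#' @param design a [nap_design()]
#' @param protocol a [nap_protocol()]
#' @param population an [axon_population()]
#' @param drug a [drug_effect()]
#' @param seed root seed
#' @param segments segments to simulate (default all `1:n_segments`)
#' @param sets stimulus sets to simulate, subset of `c(0, 1)`
#' @param seqs stimulus positions to simulate, subset of `1:7`
#' @param nerves nerve ids to simulate (default all)
#' @return a `nap_dataset`: list with `meta` (data.table with columns nerve,
#'   conc, expttime, stim_set, seq) and `waveforms` (matrix, one row per
#'   record), plus the generating objects and seed
#' @export
simulate_experiment <- function(design = nap_design(),
                                protocol = nap_protocol(),
                                population = axon_population(),
                                drug = drug_effect(),
                                seed = 1,
                                segments = NULL, sets = c(0L, 1L),
                                seqs = 1:7, nerves = NULL) {
  if (length(drug$effect_by_conc) != length(design$conc_molar))
    nap_stop("drug effect_by_conc length must match the number of CONC groups",
             "nap_error_invalid_config")
  if (is.null(segments)) segments <- seq_len(design$n_segments)
  segments <- sort(unique(as.integer(segments)))
  sets <- sort(unique(as.integer(sets)))
  conc_of_nerve <- rep(seq_along(design$n_nerves) - 1L, design$n_nerves)
  if (is.null(nerves)) nerves <- seq_along(conc_of_nerve)

  ## stimulus condition grid (per set/seq), fixed across nerves/segments
  cond <- data.table::CJ(stim_set = sets, seq = sort(unique(as.integer(seqs))))
  cc <- mapply(function(s, k) unlist(protocol_condition(protocol, s, k)),
               cond$stim_set, cond$seq)
  cond[, `:=`(current = cc["current", ], isi = cc["isi", ])]

  n_cond <- nrow(cond)
  n_seg <- length(segments)
  ws <- design$window_samples
  t_ms <- (seq_len(ws) - 1) / design$sample_rate * 1000
  art <- artifact_vector(ws, population$artifact_amp)
  wallerian <- exp(-(segments - 1) / population$wallerian_tau)
  ramp <- drug_ramp(segments, drug, design$drug_onset_segment)

  rows_per_nerve <- n_seg * n_cond
  W <- matrix(0, nrow = length(nerves) * rows_per_nerve, ncol = ws)
  meta_list <- vector("list", length(nerves))

  for (ni in seq_along(nerves)) {
    n <- nerves[ni]
    conc <- conc_of_nerve[n]
    eff <- drug$effect_by_conc[conc + 1L]
    nv <- draw_nerve(population, nerve_seed(seed, n))
    tau_ms <- design$electrode_distance_cm * nv$dist_factor * 10 / nv$velocity
    K <- kernel_matrix(tau_ms, t_ms, population)
    ref <- drop(K %*% rep(1 / population$n_classes, population$n_classes))
    pp_ref <- nv$gain * (max(ref) - min(ref))

    ## class weights for every (segment x condition) column at once
    de <- eff * ramp                                   # per segment
    amp <- wallerian * (1 - de) * nv$gain
    thr_scale <- 1 + drug$threshold_shift_gain * de
    tau_eff <- population$refractory_tau_ms * (1 + drug$refractory_gain * de)
    CW <- matrix(0, nrow = population$n_classes, ncol = n_seg * n_cond)
    col <- 0L
    for (sj in seq_len(n_seg)) {
      recruit_base <- outer(nv$threshold * thr_scale[sj], cond$current, `<=`)
      avail <- availability(cond$isi, tau_eff[sj])
      CW[, col + seq_len(n_cond)] <-
        recruit_base * rep(avail, each = population$n_classes) *
        (amp[sj] / population$n_classes)
      col <- col + n_cond
    }
    V <- t(K %*% CW)                                   # rows: seg-major
    V <- sweep(V, 2, art, `+`) + nv$offset
    if (population$noise_sd > 0)
      V <- V + matrix(rnorm(length(V), 0, population$noise_sd * pp_ref),
                      nrow = nrow(V))
    idx <- (ni - 1L) * rows_per_nerve + seq_len(rows_per_nerve)
    W[idx, ] <- V
    meta_list[[ni]] <- data.table::data.table(
      nerve = n, conc = conc,
      expttime = rep(segments, each = n_cond),
      stim_set = rep(cond$stim_set, n_seg),
      seq = rep(cond$seq, n_seg))
  }
  meta <- data.table::rbindlist(meta_list)
  structure(list(meta = meta, waveforms = W, design = design,
                 protocol = protocol, population = population, drug = drug,
                 seed = seed),
            class = "nap_dataset")
}

#' @export
print.nap_dataset <- function(x, ...) {
  cat(sprintf(
    "<nap_dataset> %d records (%d nerves, %d segments, %d samples/record)\n",
    nrow(x$meta), data.table::uniqueN(x$meta$nerve),
    data.table::uniqueN(x$meta$expttime), ncol(x$waveforms)))
  invisible(x)
}

## logical row index into a nap_dataset meta table
ds_rows <- function(ds, stim_set = NULL, seq = NULL, expttime = NULL,
                    conc_max = NULL) {
  m <- ds$meta
  keep <- rep(TRUE, nrow(m))
  if (!is.null(stim_set)) keep <- keep & m$stim_set %in% stim_set
  if (!is.null(seq)) keep <- keep & m$seq %in% seq
  if (!is.null(expttime)) keep <- keep & m$expttime %in% expttime
  if (!is.null(conc_max)) keep <- keep & m$conc <= conc_max
  which(keep)
}

## ---- persistence -----------------------------------------------------------

#' Write a simulated dataset as a long-format CSV (plus JSON sidecar)
#'
#' One row per (record, sample): columns nerve, conc, expttime, stim_set,
#' seq, sample_index (0-based), voltage. A `<path>.json` sidecar echoes the
#' generating configuration and seed.
#'
#' @param dataset a `nap_dataset`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_dataset <- function(dataset, path) {
  if (!inherits(dataset, "nap_dataset") || nrow(dataset$meta) == 0L)
    nap_stop("dataset must be a non-empty nap_dataset", "nap_error_invalid_input")
  ws <- ncol(dataset$waveforms)
  long <- dataset$meta[rep(seq_len(nrow(dataset$meta)), each = ws)]
  long[, sample_index := rep(0:(ws - 1L), nrow(dataset$meta))]
  long[, voltage := as.vector(t(dataset$waveforms))]
  data.table::fwrite(long, path)
  side <- list(seed = dataset$seed,
               design = unclass(dataset$design),
               protocol = unclass(dataset$protocol),
               population = unclass(dataset$population),
               drug = unclass(dataset$drug))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a long-format dataset CSV written by [write_dataset()]
#'
#' @param path CSV path
#' @return a `nap_dataset` (meta + waveform matrix; generating objects are
#'   restored from the JSON sidecar when present)
#' @export
read_dataset <- function(path) {
  long <- data.table::fread(path)
  need <- c("nerve", "conc", "expttime", "stim_set", "seq",
            "sample_index", "voltage")
  if (!all(need %in% names(long)))
    nap_stop("dataset CSV is missing required columns", "nap_error_io")
  data.table::setorderv(long, c("nerve", "expttime", "stim_set", "seq",
                                "sample_index"))
  ws <- max(long$sample_index) + 1L
  meta <- unique(long[, .(nerve, conc, expttime, stim_set, seq)])
  W <- matrix(long$voltage, ncol = ws, byrow = TRUE)
  out <- list(meta = meta, waveforms = W)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    out$seed <- side$seed
    out$design <- do.call(nap_design, side$design[names(side$design) %in%
                                                    names(formals(nap_design))])
  }
  structure(out, class = "nap_dataset")
}
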