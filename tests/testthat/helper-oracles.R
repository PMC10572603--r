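## Independent brute-force oracles and small fixture builders.
## The oracles deliberately use explicit loops / dense scans so they share
## no code path with the package implementation.

oracle_mark <- function(v, artifact = 10, nbase = 10) {
  base <- mean(v[(artifact + 1):(artifact + nbase)])
  u <- v - base
  n <- length(u)
  pk <- NA_integer_; best <- -Inf
  for (i in (artifact + 1):n) if (u[i] > best) { best <- u[i]; pk <- i }
  if (pk >= n) return(NULL)
  tr <- NA_integer_; worst <- Inf
  for (i in (pk + 1):n) if (u[i] < worst) { worst <- u[i]; tr <- i }
  list(pk0 = pk - 1, tr0 = tr - 1, vp = u[pk], vt = u[tr], u = u)
}

## first downward crossing of `level` at or after 0-based index from0
oracle_cross_down <- function(u, level, from0) {
  n <- length(u)
  for (i0 in seq(from0, n - 2)) {
    a <- u[i0 + 1]; b <- u[i0 + 2]
    if (a >= level && b < level) return(i0 + (level - a) / (b - a))
  }
  NA_real_
}

## first upward crossing of `level` at or after 0-based index from0
oracle_cross_up <- function(u, level, from0) {
  n <- length(u)
  for (i0 in seq(from0, n - 2)) {
    a <- u[i0 + 1]; b <- u[i0 + 2]
    if (a <= level && b > level) return(i0 + (level - a) / (b - a))
  }
  NA_real_
}

## last upward crossing of `level` strictly before 0-based index before0,
## not earlier than 0-based index lo0
oracle_last_up_before <- function(u, level, before0, lo0) {
  for (i0 in seq(floor(before0) - 1, lo0)) {
    a <- u[i0 + 1]; b <- u[i0 + 2]
    if (a <= level && b > level) return(i0 + (level - a) / (b - a))
  }
  NA_real_
}

## one random synthetic NAP (varied kernel shape, current, ISI, noise)
rand_nap <- function(i, window = 256) {
  set.seed(100000 + i)
  pop <- axon_population(n_classes = 40,
                         noise_sd = runif(1, 0.01, 0.08),
                         pos_width_ms = runif(1, 0.10, 0.20),
                         neg_width_ms = runif(1, 0.20, 0.40),
                         lobe_ratio = runif(1, 0.3, 1))
  simulate_nap(pop, current = runif(1, 2, 15),
               preceding_isi = sample(c(Inf, 166, 8, 4, 2, 1), 1),
               seed = 2 * i + 1, window_samples = window)
}

## construct w such that a * w(b*i + c) - d reproduces `tmpl` exactly
## (up to interpolation); used for registration parameter recovery
inverse_transform <- function(tmpl, a, b, c, d) {
  n <- length(tmpl)
  i <- 0:(n - 1)
  xi <- pmin(pmax((i - c) / b, 0), n - 1)
  (stats::approx(i, tmpl, xout = xi)$y + d) / a
}

tiny_design <- function(...) {
  nap_design(n_nerves = c(4, 2, 2, 2, 2, 2, 2, 2, 2), n_segments = 6,
             window_samples = 256, ...)
}

tiny_pop <- function(noise_sd = 0, ...) {
  axon_population(n_classes = 40, noise_sd = noise_sd, ...)
}

## wrap a waveform matrix + metadata as a nap_dataset
fake_dataset <- function(W, meta, design = NULL) {
  structure(list(meta = data.table::as.data.table(meta), waveforms = W,
                 design = design),
            class = "nap_dataset")
}

## long feature table builder for hand-constructed statistics examples
feat_row <- function(nerve, conc, value, expttime = 36, stim_set = 1,
                     seq = 1, parameter = "peak_to_peak_amplitude") {
  data.table::data.table(nerve = nerve, conc = conc, expttime = expttime,
                         stim_set = stim_set, seq = seq,
                         parameter = parameter, value = value,
                         normalized_value = value)
}
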