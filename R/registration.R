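#' Fitting weights for waveform registration
#'
#' Piecewise weight vector: 0 over the stimulus-artifact prefix, 1 over the
#' main body of the NAP, then an exponential taper
#' `exp(-(i - plateau_end)/taper_tau)` that suppresses the long tail.
#'
#' @param window_samples window length
#' @param zero_prefix samples forced to 0 at the start (0-based indices
#'   `0 .. zero_prefix-1`)
#' @param plateau_end first 0-based index of the taper
#' @param taper_tau taper time constant, samples
#' @return numeric weight vector in \[0, 1\]
#' @export
build_weights <- function(window_samples, zero_prefix = 10,
                          plateau_end = 100, taper_tau = 20) {
  if (!(zero_prefix < plateau_end && plateau_end < window_samples))
    nap_stop("need zero_prefix < plateau_end < window_samples",
             "nap_error_invalid_config")
  stopifnot_scalar_num(taper_tau, "taper_tau")
  i <- 0:(window_samples - 1L)
  v <- rep(1, window_samples)
  v[i < zero_prefix] <- 0
  tail_i <- i >= plateau_end
  v[tail_i] <- exp(-(i[tail_i] - plateau_end) / taper_tau)
  v
}

#' Apply the four-parameter waveform transform
#'
#' `out(i) = a * w(b*i + c) - d` over 0-based sample indices, with linear
#' interpolation at fractional query points; queries outside the window
#' clamp to the edge value.
#'
#' @param samples input waveform
#' @param a amplitude scale (> 0)
#' @param b time-scale ("duration index", > 0)
#' @param c latency shift, samples
#' @param d voltage offset
#' @return transformed waveform of the same length
#' @export
nap_transform <- function(samples, a, b, c, d) {
  if (a <= 0 || b <= 0)
    nap_stop("a and b must be > 0", "nap_error_invalid_input")
  n <- length(samples)
  q <- pmin(pmax(b * (0:(n - 1L)) + c, 0), n - 1L)
  a * interp_at(samples, q) - d
}

#' Weighted mean-square registration objective
#'
#' Weighted mean of squared differences between the transformed waveform
#' and the template: `sum(v_i * (a*w(b*i+c) - d - template_i)^2) / np`.
#'
#' @param par numeric `c(a, b, c, d)`
#' @param waveform waveform being registered
#' @param template exemplar waveform
#' @param weights weight vector from [build_weights()]
#' @return nonnegative scalar
#' @export
registration_objective <- function(par, waveform, template, weights) {
  if (length(waveform) != length(template) ||
      length(waveform) != length(weights))
    nap_stop("waveform, template and weights must have equal length",
             "nap_error_invalid_input")
  if (par[1] <= 0 || par[2] <= 0) return(Inf)
  tw <- nap_transform(waveform, par[1], par[2], par[3], par[4])
  sum(weights * (tw - template)^2) / length(waveform)
}

## baseline used for the offset initialization: mean over samples 10..19
reg_baseline <- function(x, zero_prefix = 10) {
  mean(x[(zero_prefix + 1L):min(length(x), zero_prefix + 10L)])
}

#' Fit registration parameters against a template
#'
#' Minimizes the weighted mean-square objective over (a, b, c, d) by
#' Nelder-Mead simplex, starting from `a = pp(template)/pp(waveform)`,
#' `b = 1`, `c = 0` and the offset that matches pre-response baselines.
#' Convergence: relative objective change below `reltol` or `maxit`
#' iterations.
#'
#' @param waveform waveform to register (the record from the first segment)
#' @param template exemplar waveform for the same (set, SEQ)
#' @param weights weight vector
#' @param init optional `c(a, b, c, d)` start
#' @param reltol relative convergence tolerance
#' @param maxit maximum simplex iterations
#' @return list with `a`, `b`, `c`, `d`, `objective`, `convergence`
#' @export
fit_registration <- function(waveform, template, weights = NULL,
                             init = NULL, reltol = 1e-10, maxit = 500) {
  if (is.null(weights)) weights <- build_weights(length(waveform))
  pp_w <- max(waveform) - min(waveform)
  if (pp_w == 0)
    nap_stop("waveform has zero peak-to-peak amplitude; cannot register",
             "nap_error_unregistrable")
  if (is.null(init)) {
    a0 <- (max(template) - min(template)) / pp_w
    if (!is.finite(a0) || a0 <= 0) a0 <- 1
    d0 <- a0 * reg_baseline(waveform) - reg_baseline(template)
    init <- c(a0, 1, 0, d0)
  }
  fit <- optim(init, registration_objective, waveform = waveform,
               template = template, weights = weights,
               method = "Nelder-Mead",
               control = list(reltol = reltol, maxit = maxit))
  if (!is.finite(fit$value) || fit$par[1] <= 0 || fit$par[2] <= 0)
    nap_stop("registration fit failed (non-finite objective or a,b <= 0)",
             "nap_error_fit_failure")
  list(a = fit$par[1], b = fit$par[2], c = fit$par[3], d = fit$par[4],
       objective = fit$value, convergence = fit$convergence)
}

#' Register every nerve of a dataset against an exemplar nerve
#'
#' For each (nerve, set, SEQ) the transform is fitted once, matching the
#' nerve's first-segment waveform to the exemplar nerve's first-segment
#' waveform for the same stimulus, and then applied unchanged to all
#' segments of that key. This removes electrode-placement differences in
#' gain, latency scale and offset while leaving within-nerve dynamics
#' (Wallerian decline, drug effects) untouched.
#'
#' @param dataset a `nap_dataset` that includes `template_segment`
#' @param template_nerve exemplar nerve id (default: lowest id present)
#' @param template_segment segment used for fitting (default 1)
#' @param zero_prefix,plateau_end,taper_tau weight parameters, see
#'   [build_weights()]
#' @return list with `dataset` (registered copy; waveforms replaced by the
#'   transformed ones) and `params` (data.table: nerve, stim_set, seq, a, b,
#'   c, d, objective)
#' @export
register_dataset <- function(dataset, template_nerve = NULL,
                             template_segment = 1,
                             zero_prefix = 10, plateau_end = 100,
                             taper_tau = 20) {
  m <- dataset$meta
  W <- dataset$waveforms
  ws <- ncol(W)
  weights <- build_weights(ws, zero_prefix, plateau_end, taper_tau)
  if (is.null(template_nerve)) template_nerve <- min(m$nerve)
  if (!any(m$nerve == template_nerve & m$expttime == template_segment))
    nap_stop("template nerve/segment not present in dataset",
             "nap_error_invalid_input")

  keys <- unique(m[, .(stim_set, seq)])
  templates <- lapply(seq_len(nrow(keys)), function(i) {
    r <- which(m$nerve == template_nerve & m$expttime == template_segment &
                 m$stim_set == keys$stim_set[i] & m$seq == keys$seq[i])
    W[r[1L], ]
  })
  names(templates) <- paste(keys$stim_set, keys$seq)

  out <- W
  nerves <- unique(m$nerve)
  params <- vector("list", length(nerves) * nrow(keys))
  pi <- 0L
  for (n in nerves) {
    for (i in seq_len(nrow(keys))) {
      s <- keys$stim_set[i]; k <- keys$seq[i]
      rows <- which(m$nerve == n & m$stim_set == s & m$seq == k)
      fit_row <- rows[m$expttime[rows] == template_segment]
      if (length(fit_row) == 0L)
        nap_stop("a nerve lacks the template segment; cannot fit",
                 "nap_error_invalid_input")
      tmpl <- templates[[paste(s, k)]]
      fp <- fit_registration(W[fit_row[1L], ], tmpl, weights)
      for (r in rows)
        out[r, ] <- nap_transform(W[r, ], fp$a, fp$b, fp$c, fp$d)
      pi <- pi + 1L
      params[[pi]] <- data.table::data.table(
        nerve = n, stim_set = s, seq = k, a = fp$a, b = fp$b, c = fp$c,
        d = fp$d, objective = fp$objective)
    }
  }
  reg <- dataset
  reg$waveforms <- out
  list(dataset = reg, params = data.table::rbindlist(params[seq_len(pi)]),
       template_nerve = template_nerve, template_segment = template_segment,
       weights = weights, templates = templates)
}
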