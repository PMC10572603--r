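#' Pointwise Spearman correlation map along the waveform
#'
#' For one (set, SEQ, EXPTTIME) slice of a (registered) dataset, correlates
#' the voltage at every sample across nerves of the low-concentration
#' subset with the CONC ordinal, yielding a Spearman R and p per time
#' point. Samples with constant voltage across nerves are undefined
#' (missing R). Two significance masks are attached: raw p below
#' `raw_p_threshold`, and Benjamini-Hochberg FDR below `fdr_q` over the
#' defined samples of the slice.
#'
#' @param dataset a `nap_dataset` (typically the registered one)
#' @param stim_set,seq,expttime slice selectors
#' @param conc_max largest CONC ordinal included (default 4, the monotone
#'   range of the dose response)
#' @param raw_p_threshold,fdr_q significance settings
#' @return data.table with columns sample_index (0-based), R, p, sig_raw,
#'   sig_fdr; attributes `n_nerves`, `stim_set`, `seq`, `expttime`
#' @export
pointwise_spearman <- function(dataset, stim_set, seq, expttime,
                               conc_max = 4, raw_p_threshold = 0.01,
                               fdr_q = 0.05) {
  rows <- ds_rows(dataset, stim_set = stim_set, seq = seq,
                  expttime = expttime, conc_max = conc_max)
  if (length(rows) == 0L)
    nap_stop("no records in the requested slice", "nap_error_insufficient_data")
  conc <- dataset$meta$conc[rows]
  if (length(unique(conc)) < 3L)
    nap_stop("need >= 3 distinct CONC values", "nap_error_insufficient_data")
  V <- dataset$waveforms[rows, , drop = FALSE]
  n <- nrow(V)
  cr <- rank(conc)
  cr <- (cr - mean(cr)) / sqrt(sum((cr - mean(cr))^2))
  Rk <- apply(V, 2, rank)
  const <- apply(V, 2, function(x) min(x) == max(x))
  Rk <- scale(Rk)                        # column-standardized ranks
  R <- as.vector(crossprod(Rk, cr)) / sqrt(n - 1)
  R[const] <- NA_real_
  p <- rep(NA_real_, length(R))
  ok <- !is.na(R) & abs(R) < 1
  tt <- R[ok] * sqrt((n - 2) / (1 - R[ok]^2))
  p[ok] <- 2 * pt(abs(tt), n - 2, lower.tail = FALSE)
  p[!is.na(R) & abs(R) >= 1] <- 0
  out <- data.table::data.table(
    sample_index = 0:(ncol(V) - 1L), R = R, p = p,
    sig_raw = !is.na(p) & p < raw_p_threshold,
    sig_fdr = bh_fdr(p, fdr_q))
  data.table::setattr(out, "n_nerves", n)
  data.table::setattr(out, "stim_set", stim_set)
  data.table::setattr(out, "seq", seq)
  data.table::setattr(out, "expttime", expttime)
  out[]
}

#' Correlation between the |R| profile and the template voltage profile
#'
#' Tests whether the time points most correlated with concentration are the
#' time points where the NAP voltage is largest -- the signature of a
#' purely multiplicative (amplitude-only) drug effect. By default both
#' profiles enter as magnitudes (|R| against |template voltage|), since an
#' amplitude-scaling effect drives |R| at the trough as much as at the
#' peak; set `use_abs = FALSE` to correlate signed profiles.
#'
#' @param map a slice from [pointwise_spearman()]
#' @param template template waveform on the same sample grid
#' @param use_abs correlate magnitudes (default) rather than signed values
#' @param support optional integer (1-based) sample positions over which to
#'   compare the profiles; typically the support of the registration
#'   weights, so that the zero-signal tail of the window does not dilute
#'   the comparison. Default: all samples.
#' @return list with `rho` (Spearman), `p`, `n`
#' @export
r_vs_voltage_profile <- function(map, template, use_abs = TRUE,
                                 support = NULL) {
  if (length(template) != nrow(map))
    nap_stop("template length must match the correlation map",
             "nap_error_invalid_input")
  ok <- !is.na(map$R)
  if (!is.null(support)) ok <- ok & seq_len(nrow(map)) %in% support
  if (sum(ok) < 3L)
    nap_stop("fewer than 3 defined points in the correlation map",
             "nap_error_insufficient_data")
  x <- map$R[ok]
  y <- template[ok]
  if (use_abs) { x <- abs(x); y <- abs(y) }
  if (sd(x) == 0 || sd(y) == 0)
    nap_stop("constant profile; correlation undefined",
             "nap_error_insufficient_data")
  rp <- spearman_rp(x, y)
  list(rho = rp[1], p = rp[2], n = sum(ok))
}

#' Chi-squared test of clustering of significant time points
#'
#' Counts, per waveform sample, the number of analysis segments whose
#' pointwise correlation has p below the threshold, bins the counts over
#' the post-artifact window, and tests the binned counts against a uniform
#' distribution. Bins are halved until the expected count per bin is at
#' least 5 (or only 2 bins remain).
#'
#' @param maps list of [pointwise_spearman()] slices (one per EXPTTIME) for
#'   a single (set, SEQ)
#' @param threshold raw p threshold (default 0.01)
#' @param n_bins initial number of equal-width bins
#' @param artifact_samples samples excluded at the window start
#' @return list with `chi2`, `df`, `p`, `bin_counts`, `total`; NA statistic
#'   when no significant points exist
#' @export
timepoint_chi2 <- function(maps, threshold = 0.01, n_bins = 8,
                           artifact_samples = 10) {
  if (length(maps) == 0L)
    nap_stop("no correlation maps supplied", "nap_error_invalid_input")
  ns <- nrow(maps[[1L]])
  counts <- Reduce(`+`, lapply(maps, function(m)
    as.integer(!is.na(m$p) & m$p < threshold)))
  keep <- (artifact_samples + 1L):ns
  counts <- counts[keep]
  tot <- sum(counts)
  if (tot == 0)
    return(list(chi2 = NA_real_, df = NA_integer_, p = NA_real_,
                bin_counts = NULL, total = 0L))
  nb <- n_bins
  while (nb > 2L && tot / nb < 5) nb <- ceiling(nb / 2)
  if (nb < 2L)
    nap_stop("cannot form >= 2 bins", "nap_error_invalid_input")
  bin <- cut(seq_along(counts), breaks = nb, labels = FALSE)
  bc <- tapply(counts, bin, sum)
  res <- chi2_uniform(as.numeric(bc))
  list(chi2 = res$chi2, df = res$df, p = res$p,
       bin_counts = as.numeric(bc), total = tot)
}
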