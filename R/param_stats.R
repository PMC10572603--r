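#' Configuration of the statistical battery
#'
#' Family-wise levels follow a Bonferroni split over the twelve NAP
#' descriptors: the per-test ANOVA level is `family_alpha_anova / n_tests`
#' (0.05/12, conventionally rounded to 0.004) and the confirmatory
#' Kruskal-Wallis level `family_alpha_kw / n_tests` (0.1/12, 0.008). The
#' correlation screens use Benjamini-Hochberg FDR at `fdr_q` with a
#' companion raw-p threshold, restricted to the low-concentration subset
#' `CONC <= conc_subset_max` where the dose response is monotone.
#'
#' @param family_alpha_anova family-wise ANOVA level
#' @param n_tests number of descriptors tested
#' @param family_alpha_kw family-wise Kruskal-Wallis level
#' @param fdr_q Benjamini-Hochberg false discovery rate
#' @param raw_p_threshold companion uncorrected threshold
#' @param conc_subset_max largest CONC ordinal entering correlation and
#'   repeated-measures analyses
#' @return an object of class `nap_stats_config`
#' @export
stats_config <- function(family_alpha_anova = 0.05, n_tests = 12,
                         family_alpha_kw = 0.1, fdr_q = 0.05,
                         raw_p_threshold = 0.01, conc_subset_max = 4) {
  for (x in c(family_alpha_anova, family_alpha_kw, fdr_q, raw_p_threshold))
    if (x <= 0 || x >= 1)
      nap_stop("alpha/q values must be in (0, 1)", "nap_error_invalid_config")
  structure(list(
    family_alpha_anova = family_alpha_anova, n_tests = n_tests,
    family_alpha_kw = family_alpha_kw, fdr_q = fdr_q,
    raw_p_threshold = raw_p_threshold, conc_subset_max = conc_subset_max,
    bonferroni_anova = family_alpha_anova / n_tests,
    bonferroni_kw = family_alpha_kw / n_tests),
    class = "nap_stats_config")
}

## subset the normalized feature table to one endpoint cell
## (arguments rebound to fresh names so data.table scoping cannot capture
## same-named columns)
endpoint_values <- function(feat_norm, parameter, expttime, seq, stim_set) {
  .pm <- parameter; .j <- expttime; .k <- seq; .s <- stim_set
  d <- feat_norm[feat_norm$parameter == .pm &
                   feat_norm$expttime == .j &
                   feat_norm$seq == .k &
                   feat_norm$stim_set == .s &
                   !is.na(feat_norm$normalized_value)]
  if (nrow(d) == 0L)
    nap_stop("no observations for the requested endpoint cell",
             "nap_error_insufficient_data")
  d
}

#' One-way fixed-effects ANOVA of a descriptor across CONC groups
#'
#' Tests the end-of-experiment value of a normalized descriptor (by default
#' the first stimulus of set 1 at segment 36) across all concentration
#' groups; with the full design the degrees of freedom are (8, 103).
#' Implemented from explicit between/within sums of squares (the `aov`
#' route serves as an independent check in the test suite).
#'
#' @param feat_norm normalized feature table from [normalize_to_baseline()]
#' @param parameter descriptor name, see [nap_parameters()]
#' @param expttime,seq,stim_set endpoint cell (defaults: 36, 1, 1)
#' @return list with `F`, `df_between`, `df_within`, `p`, `n`
#' @export
endpoint_anova <- function(feat_norm, parameter = "peak_to_peak_amplitude",
                           expttime = 36, seq = 1, stim_set = 1) {
  d <- endpoint_values(feat_norm, parameter, expttime, seq, stim_set)
  y <- d$normalized_value
  g <- factor(d$conc)
  ng <- table(g)
  if (length(ng) < 2L || any(ng < 2L))
    nap_stop("need >= 2 groups with >= 2 observations each",
             "nap_error_insufficient_data")
  gm <- tapply(y, g, mean)
  grand <- mean(y)
  ssb <- sum(ng * (gm - grand)^2)
  ssw <- sum((y - gm[g])^2)
  df1 <- length(ng) - 1L
  df2 <- length(y) - length(ng)
  Fv <- (ssb / df1) / (ssw / df2)
  list(F = Fv, df_between = df1, df_within = df2,
       p = pf(Fv, df1, df2, lower.tail = FALSE), n = length(y))
}

#' Kruskal-Wallis confirmation of the endpoint concentration effect
#'
#' @inheritParams endpoint_anova
#' @return list with `H`, `df`, `p`, `n`
#' @export
endpoint_kruskal <- function(feat_norm, parameter = "peak_to_peak_amplitude",
                             expttime = 36, seq = 1, stim_set = 1) {
  d <- endpoint_values(feat_norm, parameter, expttime, seq, stim_set)
  if (length(unique(d$conc)) < 2L)
    nap_stop("need >= 2 groups", "nap_error_insufficient_data")
  kt <- kruskal.test(d$normalized_value, factor(d$conc))
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, n = nrow(d))
}

#' Quadratic dose regression of a descriptor on the CONC ordinal
#'
#' Ordinary least squares of the normalized endpoint value on CONC and
#' CONC^2 (CONC as the numeric ordinal 0..8), capturing the non-monotonic
#' dose response.
#'
#' @inheritParams endpoint_anova
#' @return data.frame with columns term, estimate, p
#' @export
quadratic_regression <- function(feat_norm,
                                 parameter = "peak_to_peak_amplitude",
                                 expttime = 36, seq = 1, stim_set = 1) {
  d <- endpoint_values(feat_norm, parameter, expttime, seq, stim_set)
  if (length(unique(d$conc)) < 3L)
    nap_stop("need >= 3 distinct CONC values for the quadratic fit",
             "nap_error_insufficient_data")
  fit <- lm(normalized_value ~ conc + I(conc^2), data = d)
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 3L)
    nap_stop("rank-deficient quadratic regression", "nap_error_rank_deficient")
  data.frame(term = c("intercept", "CONC", "CONC2"),
             estimate = unname(sm[, 1]), p = unname(sm[, 4]),
             row.names = NULL)
}

#' Repeated-measures ANOVA over a within-nerve stimulus factor
#'
#' Split-plot ANOVA of the normalized peak-to-peak amplitude (or another
#' descriptor) with CONC as the between-nerve factor and EXPTTIME plus the
#' chosen stimulus factor as within-nerve factors. `within = "isi"` uses the
#' seven ISIs of set 1; `within = "current"` uses the stimulus currents of
#' set 0 with the lowest (frequently sub-threshold) current dropped, giving
#' six levels. Analysis is restricted to the low-concentration subset where
#' the dose response is monotone. The panel must be balanced; missing cells
#' raise an error rather than being imputed.
#'
#' @param feat_norm normalized feature table
#' @param within `"isi"` or `"current"`
#' @param parameter descriptor name
#' @param conc_max largest CONC ordinal included
#' @param segments EXPTTIME values included (default: all present)
#' @param drop_lowest_current drop the 1 mA stimulus from the current factor
#' @return data.table with columns effect, df, df_error, F, p
#' @export
repeated_measures <- function(feat_norm, within = c("isi", "current"),
                              parameter = "peak_to_peak_amplitude",
                              conc_max = 4, segments = NULL,
                              drop_lowest_current = TRUE) {
  within <- match.arg(within)
  set_id <- if (within == "isi") 1L else 0L
  seqs <- if (within == "isi") 1:7 else if (drop_lowest_current) 2:7 else 1:7
  if (length(seqs) < 2L)
    nap_stop("within factor needs >= 2 levels", "nap_error_invalid_input")
  .pm <- parameter; .cm <- conc_max
  d <- feat_norm[feat_norm$parameter == .pm &
                   feat_norm$stim_set == set_id &
                   feat_norm$seq %in% seqs &
                   feat_norm$conc <= .cm]
  if (!is.null(segments)) d <- d[d$expttime %in% segments]
  if (nrow(d) == 0L)
    nap_stop("no data for the requested repeated-measures design",
             "nap_error_insufficient_data")
  if (anyNA(d$normalized_value))
    nap_stop("missing cells in the repeated-measures panel",
             "nap_error_unbalanced")
  n_nerve <- length(unique(d$nerve))
  n_seg <- length(unique(d$expttime))
  if (nrow(d) != n_nerve * n_seg * length(seqs))
    nap_stop("unbalanced repeated-measures panel", "nap_error_unbalanced")
  split_plot_anova(y = d$normalized_value, group = d$conc, subject = d$nerve,
                   A = d$expttime, B = d$seq,
                   labels = c(group = "CONC", A = "EXPTTIME",
                              B = toupper(within)))
}

## Split-plot (mixed) ANOVA with one between-subjects factor and two fully
## crossed within-subjects factors, computed from cell means. Exact for
## designs balanced over the within factors (enforced upstream); group
## sizes may be unequal. Matches aov(y ~ g*A*B + Error(subject/(A*B)))
## on such designs (checked against aov in the test suite).
split_plot_anova <- function(y, group, subject, A, B, labels) {
  d <- data.table::data.table(y = y, g = as.character(group),
                              s = as.character(subject),
                              a = as.character(A), b = as.character(B))
  subj <- unique(d[, .(s, g)])
  N <- nrow(subj)
  G <- length(unique(subj$g))
  na <- length(unique(d$a))
  nb <- length(unique(d$b))
  ng <- subj[, .N, by = g]

  row <- function(effect, ss, df, ss_err, df_err) {
    ms <- ss / df
    mse <- ss_err / df_err
    Fv <- ms / mse
    data.table::data.table(effect = effect, df = df, df_error = df_err,
                           F = Fv, p = pf(Fv, df, df_err, lower.tail = FALSE))
  }
  lab <- function(...) paste(labels[c(...)], collapse = ":")

  ## between stratum: subject means (scaled back by na*nb)
  ms_s <- d[, .(m = mean(y)), by = .(s, g)]
  grand <- mean(ms_s$m)
  mg <- ms_s[, .(m = mean(m), n = .N), by = g]
  ss_g <- na * nb * sum(mg$n * (mg$m - grand)^2)
  ss_se <- na * nb * sum((ms_s$m - mg$m[match(ms_s$g, mg$g)])^2)
  out <- list(row(lab("group"), ss_g, G - 1L, ss_se, N - G))

  ## one within factor (z = subject x level means averaged over the other)
  within_stratum <- function(z, nlev, scale, lab_main, lab_int) {
    ## z: data.table s, g, lev, m
    zl <- z[, .(m = mean(m)), by = lev]
    zs <- z[, .(m = mean(m)), by = s]
    zgl <- z[, .(m = mean(m)), by = .(g, lev)]
    zg <- z[, .(m = mean(m)), by = g]
    ss_main <- scale * N * sum((zl$m - mean(zs$m))^2)
    zgl[, dev := m - zg$m[match(g, zg$g)] - zl$m[match(lev, zl$lev)] +
          mean(zs$m)]
    ss_int <- scale * sum(ng$N[match(zgl$g, ng$g)] * zgl$dev^2)
    z[, fit := zs$m[match(s, zs$s)] + zgl$m[match(paste(g, lev),
                                                 paste(zgl$g, zgl$lev))] -
        zg$m[match(g, zg$g)]]
    ss_err <- scale * sum((z$m - z$fit)^2)
    df_err <- (N - G) * (nlev - 1L)
    list(row(lab_main, ss_main, nlev - 1L, ss_err, df_err),
         row(lab_int, ss_int, (G - 1L) * (nlev - 1L), ss_err, df_err))
  }
  za <- d[, .(m = mean(y)), by = .(s, g, lev = a)]
  out <- c(out, within_stratum(za, na, nb, lab("A"), lab("group", "A")))
  zb <- d[, .(m = mean(y)), by = .(s, g, lev = b)]
  out <- c(out, within_stratum(zb, nb, na, lab("B"), lab("group", "B")))

  ## A x B stratum: per-subject double-centered interaction scores
  d[, `:=`(ms = mean(y)), by = s]
  d[, `:=`(mza = mean(y)), by = .(s, a)]
  d[, `:=`(mzb = mean(y)), by = .(s, b)]
  d[, dd := y - mza - mzb + ms]
  zab <- d[, .(m = mean(dd)), by = .(a, b)]
  ss_ab <- N * sum(zab$m^2)
  zgab <- d[, .(m = mean(dd)), by = .(g, a, b)]
  zgab[, dev := m - zab$m[match(paste(a, b), paste(zab$a, zab$b))]]
  ss_gab <- sum(ng$N[match(zgab$g, ng$g)] * zgab$dev^2)
  d[, fitab := zgab$m[match(paste(g, a, b), paste(zgab$g, zgab$a, zgab$b))]]
  ss_err_ab <- sum((d$dd - d$fitab)^2)
  df_ab <- (na - 1L) * (nb - 1L)
  df_err_ab <- (N - G) * df_ab
  out <- c(out, list(
    row(lab("A", "B"), ss_ab, df_ab, ss_err_ab, df_err_ab),
    row(lab("group", "A", "B"), ss_gab, (G - 1L) * df_ab, ss_err_ab,
        df_err_ab)))
  data.table::rbindlist(out)
}

#' Benjamini-Hochberg step-up rejection mask
#'
#' Rejects all hypotheses with `p <= p_(k*)`, where
#' `k* = max{k : p_(k) <= k q / m}` over the `m` non-missing p-values.
#'
#' @param p p-values in \[0, 1\] (NAs allowed; never rejected)
#' @param q target false discovery rate
#' @return logical mask of the same length as `p`
#' @export
bh_fdr <- function(p, q = 0.05) {
  ok <- !is.na(p)
  m <- sum(ok)
  out <- rep(FALSE, length(p))
  if (m == 0L) return(out)
  ps <- sort(p[ok])
  k <- which(ps <= seq_len(m) * q / m)
  if (length(k) == 0L) return(out)
  out[ok] <- p[ok] <= ps[max(k)]
  out
}

## Spearman rank correlation p-value (t approximation, two-sided); NA when
## either margin is constant or fewer than 3 pairs remain
spearman_rp <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(c(NA_real_, NA_real_))
  x <- rank(x[ok]); y <- rank(y[ok])
  if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
  r <- cor(x, y)
  if (abs(r) >= 1) return(c(r, 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r, 2 * pt(abs(tt), n - 2, lower.tail = FALSE))
}

#' Spearman screen of every (parameter, SEQ, EXPTTIME) cell against CONC
#'
#' For one stimulus set, computes the Spearman rank correlation between the
#' normalized descriptor values and the CONC ordinal across nerves of the
#' low-concentration subset, for every descriptor, stimulus position and
#' analysis segment.
#'
#' @param feat_norm normalized feature table
#' @param stim_set 0 or 1
#' @param conc_max largest CONC ordinal included
#' @return data.table with columns parameter, seq, expttime, R, p, n
#' @export
spearman_screen <- function(feat_norm, stim_set, conc_max = 4) {
  .s <- stim_set; .cm <- conc_max
  d <- feat_norm[feat_norm$stim_set == .s & feat_norm$conc <= .cm]
  if (nrow(d) == 0L)
    nap_stop("no data for the requested Spearman screen",
             "nap_error_insufficient_data")
  res <- d[, {
    rp <- spearman_rp(normalized_value, conc)
    .(R = rp[1], p = rp[2], n = sum(!is.na(normalized_value)))
  }, by = .(parameter, seq, expttime)]
  res[]
}

#' Significance-count table over descriptors and stimulus positions
#'
#' Counts, per (descriptor, SEQ) cell of one stimulus set, the number of
#' analysis segments whose Spearman correlation with CONC is significant --
#' either with BH FDR below `fdr_q` (family: all descriptor x SEQ x
#' EXPTTIME tests of the set) or with raw p below `raw_p_threshold` -- and
#' tests the 12 x 7 table for independence of descriptor and stimulus
#' position with a chi-squared statistic on df = (12-1)(7-1) = 66.
#'
#' @param feat_norm normalized feature table
#' @param stim_set 0 or 1
#' @param mode `"fdr"` or `"raw"`
#' @param cfg a [stats_config()]
#' @return list with `table` (12 x 7 integer matrix), `chi2`, `df`, `p`,
#'   `mode`, `screen` (the underlying Spearman screen)
#' @export
build_count_table <- function(feat_norm, stim_set, mode = c("fdr", "raw"),
                              cfg = stats_config()) {
  mode <- match.arg(mode)
  scr <- spearman_screen(feat_norm, stim_set, cfg$conc_subset_max)
  scr[, sig := if (mode == "fdr") bh_fdr(p, cfg$fdr_q) else
    !is.na(p) & p < cfg$raw_p_threshold]
  counts <- scr[, .(count = sum(sig)), by = .(parameter, seq)]
  tab <- matrix(0L, nrow = length(NAP_PARAMETERS), ncol = 7L,
                dimnames = list(NAP_PARAMETERS, paste0("seq", 1:7)))
  tab[cbind(match(counts$parameter, NAP_PARAMETERS), counts$seq)] <-
    as.integer(counts$count)
  chi <- chi2_independence(tab)
  list(table = tab, chi2 = chi$chi2, df = chi$df, p = chi$p, mode = mode,
       screen = scr)
}

## chi-squared independence test of a count table with fixed nominal df
## (rows-1)(cols-1); cells with zero expectation contribute nothing.
## An all-zero table is not applicable (NA statistic).
chi2_independence <- function(tab) {
  tot <- sum(tab)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (tot == 0)
    return(list(chi2 = NA_real_, df = df, p = NA_real_))
  E <- outer(rowSums(tab), colSums(tab)) / tot
  ok <- E > 0
  chi2 <- sum((tab[ok] - E[ok])^2 / E[ok])
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}

#' Goodness-of-fit chi-squared against a uniform distribution of counts
#'
#' @param counts nonnegative integer counts per bin
#' @return list with `chi2`, `df`, `p`; NA statistic when all counts are 0
#' @export
chi2_uniform <- function(counts) {
  if (length(counts) < 2L)
    nap_stop("need >= 2 bins (df would be 0)", "nap_error_invalid_input")
  tot <- sum(counts)
  df <- length(counts) - 1L
  if (tot == 0) return(list(chi2 = NA_real_, df = df, p = NA_real_))
  E <- tot / length(counts)
  chi2 <- sum((counts - E)^2 / E)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE))
}
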