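test_that("stats config carries the Bonferroni splits", {
  s <- stats_config()
  expect_equal(s$bonferroni_anova, 0.05 / 12)
  expect_equal(s$bonferroni_kw, 0.1 / 12)
  expect_error(stats_config(fdr_q = 0), class = "nap_error_invalid_config")
})

test_that("endpoint ANOVA reproduces hand-computed sums of squares", {
  ## two groups {1,2,3} vs {4,5,6}: SSB = 13.5, SSW = 4, F = 13.5
  feat <- feat_row(nerve = 1:6, conc = rep(0:1, each = 3),
                   value = c(1, 2, 3, 4, 5, 6))
  an <- endpoint_anova(feat)
  expect_equal(an$F, 13.5, tolerance = 1e-12)
  expect_identical(c(an$df_between, an$df_within), c(1L, 4L))

  ## full design: 112 nerves in 9 groups -> df (8, 103)
  set.seed(1)
  feat2 <- feat_row(nerve = 1:112,
                    conc = rep(0:8, c(40, 8, 8, 8, 8, 8, 8, 8, 16)),
                    value = rnorm(112))
  an2 <- endpoint_anova(feat2)
  expect_identical(c(an2$df_between, an2$df_within), c(8L, 103L))

  ## agreement with the aov oracle on random data
  set.seed(2)
  feat3 <- feat_row(nerve = 1:24, conc = rep(0:3, each = 6), value = rnorm(24))
  an3 <- endpoint_anova(feat3)
  ref <- summary(stats::aov(value ~ factor(conc), data = feat3))[[1]]
  expect_equal(an3$F, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(an3$p, ref[1, "Pr(>F)"], tolerance = 1e-10)

  expect_error(endpoint_anova(feat_row(1:3, c(0, 0, 1), 1:3)),
               class = "nap_error_insufficient_data")
})

test_that("Kruskal-Wallis endpoint test matches the rank formula", {
  ## groups {1,2} vs {3,4}: H = 12/(N(N+1)) * sum n_i (Rbar_i - (N+1)/2)^2 = 2.4
  feat <- feat_row(nerve = 1:4, conc = c(0, 0, 1, 1), value = c(1, 2, 3, 4))
  kw <- endpoint_kruskal(feat)
  expect_equal(kw$H, 2.4, tolerance = 1e-12)
  expect_identical(kw$df, 1L)
  expect_error(endpoint_kruskal(feat_row(1:4, rep(0, 4), 1:4)),
               class = "nap_error_insufficient_data")
})

test_that("quadratic regression recovers exact polynomials and curvature", {
  conc <- rep(0:8, each = 3)
  y <- 1 - 0.1 * conc + 0.01 * conc^2
  feat <- feat_row(nerve = seq_along(conc), conc = conc, value = y)
  q <- suppressWarnings(quadratic_regression(feat))  # exact fit: lm warns
  expect_equal(q$estimate, c(1, -0.1, 0.01), tolerance = 1e-10)

  ## U-shaped group means (minimum at CONC 4) -> positive curvature
  set.seed(3)
  yu <- 1 - 0.08 * conc + 0.01 * conc^2 + rnorm(length(conc), 0, 0.01)
  qu <- quadratic_regression(feat_row(seq_along(conc), conc, yu))
  expect_gt(qu$estimate[3], 0)
})

test_that("split-plot ANOVA matches the aov oracle, balanced and not", {
  run_check <- function(ngroups) {
    subj <- data.table::data.table(s = seq_len(sum(ngroups)),
                                   g = rep(seq_along(ngroups), ngroups))
    d <- data.table::CJ(s = subj$s, a = 1:3, b = 1:4)
    d <- merge(d, subj, by = "s")
    set.seed(7)
    d[, y := rnorm(.N) + 0.3 * g + 0.2 * a + 0.1 * g * b]
    mine <- napamyloid:::split_plot_anova(
      d$y, d$g, d$s, d$a, d$b,
      labels = c(group = "CONC", A = "EXPTTIME", B = "ISI"))
    dd <- data.frame(y = d$y, g = factor(d$g), a = factor(d$a),
                     b = factor(d$b), s = factor(d$s))
    fit <- stats::aov(y ~ g * a * b + Error(s / (a * b)), data = dd)
    map <- c("g" = "CONC", "a" = "EXPTTIME", "b" = "ISI",
             "g:a" = "CONC:EXPTTIME", "g:b" = "CONC:ISI",
             "a:b" = "EXPTTIME:ISI", "g:a:b" = "CONC:EXPTTIME:ISI")
    for (st in summary(fit)) {
      tab <- st[[1]]
      rn <- trimws(rownames(tab))
      for (i in which(rn != "Residuals")) {
        mv <- mine[mine$effect == map[[rn[i]]], ]
        expect_equal(mv$F, tab[i, "F value"], tolerance = 1e-8)
        expect_equal(as.numeric(mv$df), as.numeric(tab[i, "Df"]))
      }
    }
  }
  run_check(c(3, 3, 3))
  run_check(c(5, 2, 3))
})

test_that("repeated-measures wrapper enforces a balanced panel", {
  ds <- simulate_experiment(tiny_design(), population = tiny_pop(0.03),
                            seed = 14, segments = 3:6, sets = 1)
  feat <- features_table(ds, parameters = "peak_to_peak_amplitude")
  norm <- normalize_to_baseline(feat, 3, 4:6)
  rm <- repeated_measures(norm, "isi", conc_max = 4)
  expect_setequal(rm$effect, c("CONC", "EXPTTIME", "ISI", "CONC:EXPTTIME",
                               "CONC:ISI", "EXPTTIME:ISI",
                               "CONC:EXPTTIME:ISI"))
  expect_true(all(rm$p >= 0 & rm$p <= 1))
  ## removing one cell breaks the balance
  expect_error(repeated_measures(norm[-5], "isi", conc_max = 4),
               class = "nap_error_unbalanced")
  ## an NA cell is an unbalanced panel, not silently imputed
  norm2 <- data.table::copy(norm)
  norm2$normalized_value[10] <- NA
  expect_error(repeated_measures(norm2, "isi", conc_max = 4),
               class = "nap_error_unbalanced")
  ## set-0 panel drops the lowest current -> 6 within levels
  ds0 <- simulate_experiment(tiny_design(), population = tiny_pop(0.03),
                             seed = 14, segments = 3:6, sets = 0)
  feat0 <- features_table(ds0, parameters = "peak_to_peak_amplitude")
  norm0 <- normalize_to_baseline(feat0, 3, 4:6)
  rm0 <- repeated_measures(norm0, "current", conc_max = 4)
  expect_identical(rm0[rm0$effect == "CURRENT", ]$df, 5L)
})

test_that("BH step-up matches the hand rule and dominates Bonferroni", {
  expect_identical(bh_fdr(c(0.001, 0.01, 0.02, 0.04, 0.9), 0.05),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_identical(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_identical(bh_fdr(rep(0, 5), 0.05), rep(TRUE, 5))
  set.seed(4)
  for (i in 1:50) {
    p <- runif(40)^sample(1:3, 1)
    q <- 0.05
    mask <- bh_fdr(p, q)
    expect_identical(mask, p.adjust(p, "BH") <= q)       # independent oracle
    expect_true(all(mask[p <= q / length(p)]))           # Bonferroni subset
  }
  expect_identical(bh_fdr(c(0.001, NA), 0.05), c(TRUE, FALSE))
})

test_that("Spearman helper agrees with cor.test", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rep(0:4, 3)
    rp <- napamyloid:::spearman_rp(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(rp[1], unname(ref$estimate), tolerance = 1e-10)
    expect_equal(rp[2], ref$p.value, tolerance = 1e-10)
  }
  expect_true(all(is.na(napamyloid:::spearman_rp(rep(1, 5), 1:5))))
})

test_that("count tables count significant segments and test independence", {
  ## synthetic feature table: pp responds to conc, others are noise
  set.seed(6)
  grid <- data.table::CJ(nerve = 1:20, expttime = 4:23, seq = 1:7,
                         parameter = nap_parameters())
  grid[, conc := (nerve - 1L) %% 5L]
  grid[, stim_set := 1L]
  ## concentration effect on pp only, and only at the first four stimulus
  ## positions, so the parameter x SEQ pattern is genuinely non-independent
  grid[, value := ifelse(parameter == "peak_to_peak_amplitude" & seq <= 4,
                         1 - 0.15 * conc + rnorm(.N, 0, 0.05),
                         rnorm(.N))]
  grid[, normalized_value := value]
  ct <- build_count_table(grid, stim_set = 1, mode = "fdr")
  expect_identical(dim(ct$table), c(12L, 7L))
  expect_identical(ct$df, 66L)
  expect_true(all(ct$table >= 0 & ct$table <= 20))
  expect_identical(names(which.max(rowSums(ct$table))),
                   "peak_to_peak_amplitude")
  expect_lt(ct$p, 0.01)
  ct_raw <- build_count_table(grid, stim_set = 1, mode = "raw")
  expect_identical(ct_raw$mode, "raw")

  ## all-zero table is not applicable rather than an error
  grid0 <- data.table::copy(grid)[, `:=`(value = 0, normalized_value = 0)]
  ct0 <- build_count_table(grid0, stim_set = 1, mode = "fdr")
  expect_true(is.na(ct0$chi2))
  expect_identical(ct0$df, 66L)
})

test_that("uniformity chi-square matches the hand computation", {
  res <- chi2_uniform(c(20, 0, 0, 0))
  expect_equal(res$chi2, 60)
  expect_identical(res$df, 3L)
  expect_error(chi2_uniform(5), class = "nap_error_invalid_input")
  expect_true(is.na(chi2_uniform(c(0, 0, 0))$chi2))
})
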