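#' Default end-to-end pipeline configuration
#'
#' Nested list with one section per stage: `design`, `protocol`,
#' `population`, `drug` (the stated experimental world), plus `marking`,
#' `registration`, `stats` and `waveform` (analysis settings). Any section
#' can be overridden by a user configuration file; see [read_config()].
#'
#' @return nested configuration list
#' @export
default_config <- function() {
  list(
    design = list(),
    protocol = list(),
    population = list(),
    drug = list(),
    marking = list(),
    registration = list(zero_prefix = 10, plateau_end = 100, taper_tau = 20,
                        template_nerve = NULL, template_segment = 1),
    stats = list(),
    waveform = list(n_bins = 8)
  )
}

#' Read a pipeline configuration file (JSON or YAML)
#'
#' Sections present in the file override the defaults section-wise; fields
#' not given keep their default values.
#'
#' @param path path to a `.json` (or `.yaml`, if the yaml package is
#'   installed) configuration file
#' @return nested configuration list
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    nap_stop(sprintf("config file not found: %s", path), "nap_error_io")
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      nap_stop("YAML config requires the 'yaml' package; use JSON instead",
               "nap_error_config")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  utils::modifyList(default_config(), cfg)
}

validate_config <- function(config) {
  for (section in c("design", "protocol", "population", "drug"))
    if (is.null(config[[section]]))
      nap_stop(sprintf("config section missing: %s", section),
               "nap_error_config")
  invisible(config)
}

## construct the stage objects from a config, passing only known arguments
cfg_build <- function(constructor, args) {
  args <- args[names(args) %in% names(formals(constructor))]
  do.call(constructor, args)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    nap_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             "nap_error_stage")
  })
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Executes simulate -> feature extraction -> baseline normalization ->
#' endpoint statistics (ANOVA, Kruskal-Wallis, quadratic regression) ->
#' repeated-measures ANOVA -> significance-count tables -> template
#' registration -> pointwise waveform correlation analysis, and assembles a
#' deterministic report. All randomness flows from `seed`. If `out_dir` is
#' given, tidy CSVs and `report.json`/`report.md` are written there;
#' outputs of completed stages are retained even if a later stage fails.
#'
#' @param config nested configuration list, see [default_config()]
#' @param seed root seed
#' @param out_dir optional output directory
#' @param verbose print stage progress
#' @return the report, an invisible list
#' @export
run_nap_pipeline <- function(config = default_config(), seed = 1,
                             out_dir = NULL, verbose = FALSE) {
  validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))
  emit_csv <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      data.table::fwrite(x, file.path(out_dir, name))
    }
  }
  cfg_hash <- fnv1a32(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                                    null = "null")))

  design <- cfg_build(nap_design, config$design)
  protocol <- cfg_build(nap_protocol, config$protocol)
  population <- cfg_build(axon_population, config$population)
  drug <- cfg_build(drug_effect, config$drug)
  marking <- cfg_build(mark_config, config$marking)
  scfg <- cfg_build(stats_config, config$stats)
  segs <- analysis_segments(design)

  say("stage simulate")
  ds <- with_stage("simulate",
    simulate_experiment(design, protocol, population, drug, seed = seed))

  say("stage features")
  feat <- with_stage("features", features_table(ds, marking))
  norm <- with_stage("features",
    normalize_to_baseline(feat, baseline_segment = design$drug_onset_segment - 1L,
                          segments = segs))
  emit_csv(norm, "features.csv")

  say("stage param_stats")
  endpoint <- with_stage("param_stats", {
    rows <- lapply(NAP_PARAMETERS, function(pm) {
      an <- tryCatch(endpoint_anova(norm, pm, expttime = design$n_segments),
                     error = function(e) NULL)
      kw <- tryCatch(endpoint_kruskal(norm, pm, expttime = design$n_segments),
                     error = function(e) NULL)
      data.table::data.table(
        parameter = pm,
        F = if (is.null(an)) NA_real_ else an$F,
        df_between = if (is.null(an)) NA_integer_ else an$df_between,
        df_within = if (is.null(an)) NA_integer_ else an$df_within,
        p_anova = if (is.null(an)) NA_real_ else an$p,
        H = if (is.null(kw)) NA_real_ else kw$H,
        p_kw = if (is.null(kw)) NA_real_ else kw$p)
    })
    data.table::rbindlist(rows)
  })
  emit_csv(endpoint, "anova.csv")
  quad <- with_stage("param_stats",
    quadratic_regression(norm, "peak_to_peak_amplitude",
                         expttime = design$n_segments))
  emit_csv(quad, "regression.csv")

  rm_isi <- with_stage("param_stats",
    tryCatch(repeated_measures(norm, "isi",
                               conc_max = scfg$conc_subset_max),
             nap_error_unbalanced = function(e) NULL))
  rm_cur <- with_stage("param_stats",
    tryCatch(repeated_measures(norm, "current",
                               conc_max = scfg$conc_subset_max),
             nap_error_unbalanced = function(e) NULL))
  if (!is.null(rm_isi)) emit_csv(rm_isi, "rm_anova_isi.csv")
  if (!is.null(rm_cur)) emit_csv(rm_cur, "rm_anova_current.csv")

  count_tables <- with_stage("param_stats", {
    out <- list()
    for (s in sort(unique(ds$meta$stim_set)))
      for (md in c("fdr", "raw"))
        out[[sprintf("set%d_%s", s, md)]] <-
          build_count_table(norm, s, md, scfg)
    out
  })
  if (!is.null(out_dir))
    for (nm in names(count_tables))
      emit_csv(data.table::as.data.table(count_tables[[nm]]$table,
                                         keep.rownames = "parameter"),
               sprintf("count_table_%s.csv", nm))

  say("stage registration")
  reg <- with_stage("registration",
    register_dataset(ds,
                     template_nerve = config$registration$template_nerve,
                     template_segment = config$registration$template_segment,
                     zero_prefix = config$registration$zero_prefix,
                     plateau_end = config$registration$plateau_end,
                     taper_tau = config$registration$taper_tau))
  emit_csv(reg$params, "registration_params.csv")

  say("stage waveform_stats")
  waveform <- with_stage("waveform_stats", {
    out <- list()
    set1_seqs <- sort(unique(ds$meta$seq[ds$meta$stim_set == 1L]))
    for (k in set1_seqs) {
      maps <- lapply(segs, function(j)
        pointwise_spearman(reg$dataset, 1L, k, j,
                           conc_max = scfg$conc_subset_max,
                           raw_p_threshold = scfg$raw_p_threshold,
                           fdr_q = scfg$fdr_q))
      final <- maps[[length(maps)]]
      tmpl <- reg$templates[[paste(1, k)]]
      prof <- tryCatch(r_vs_voltage_profile(final, tmpl,
                                            support = which(reg$weights > 0.01)),
                       nap_error = function(e) list(rho = NA_real_,
                                                    p = NA_real_, n = 0L))
      chi <- timepoint_chi2(maps, threshold = scfg$raw_p_threshold,
                            n_bins = config$waveform$n_bins)
      out[[paste0("seq", k)]] <- list(
        profile_rho = prof$rho, profile_p = prof$p,
        chi2 = chi$chi2, chi2_df = chi$df, chi2_p = chi$p,
        n_sig_raw_final = sum(final$sig_raw),
        n_sig_fdr_final = sum(final$sig_fdr))
    }
    out
  })

  p_an <- endpoint$p_anova
  report <- list(
    seed = seed,
    config_hash = cfg_hash,
    n_records = nrow(ds$meta),
    endpoint = endpoint,
    quadratic = quad,
    rm_anova_isi = rm_isi,
    rm_anova_current = rm_cur,
    count_table_totals = lapply(count_tables, function(ct)
      list(total = sum(ct$table), chi2 = ct$chi2, df = ct$df, p = ct$p)),
    waveform = waveform,
    flags = list(
      significant_concentration_effect =
        any(p_an < scfg$bonferroni_anova, na.rm = TRUE),
      min_amplitude_conc = {
        d <- norm[parameter == "peak_to_peak_amplitude" & stim_set == 1L &
                    seq == 1L & expttime == design$n_segments]
        gm <- tapply(d$normalized_value, d$conc, mean, na.rm = TRUE)
        as.integer(names(gm)[which.min(gm)])
      })
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
    writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  }
  invisible(report)
}

report_markdown <- function(report) {
  c("# NAP pipeline report",
    sprintf("- seed: %d; config hash: %d; records: %d",
            report$seed, report$config_hash, report$n_records),
    sprintf("- significant concentration effect: %s",
            report$flags$significant_concentration_effect),
    sprintf("- CONC group with minimal end-of-experiment amplitude: %d",
            report$flags$min_amplitude_conc),
    "", "## Endpoint tests (segment 36, set 1, SEQ 1)",
    sprintf("- %s: F = %.3g (p = %.3g), H = %.3g (p = %.3g)",
            report$endpoint$parameter, report$endpoint$F,
            report$endpoint$p_anova, report$endpoint$H,
            report$endpoint$p_kw))
}
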