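# Configuration-driven orchestration: simulate/load -> demography ->
# differential expression -> categorization -> enrichment -> concordance.

#' Build a run configuration
#'
#' Exactly one source per data kind: either simulation configs (the
#' default) or paths to user TSVs. All thresholds default to the values
#' used throughout the analysis (FDR 0.05, 1.5-fold hazard separation,
#' 25 percent convergence tolerance).
#'
#' @param expr_sim an [expr_sim_config()], or NULL when `expr_path` is given.
#' @param cohort_sim a [cohort_sim_config()], or NULL when `events_path` is
#'   given.
#' @param expr_path,meta_path paths to an expression matrix + metadata TSV.
#' @param events_path path to an event-records TSV.
#' @param gmt_path optional GMT file for enrichment.
#' @param fdr FDR threshold.
#' @param separation_fold,separation_k hazard-separation detector settings.
#' @param convergence_tol,convergence_k convergence detector settings.
#' @param hazard_window centered pooling window (days) for hazard estimates.
#' @param rules [category_rules()] for the indeterminate categories.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling any simulation.
#' @return list of class `run_config`.
#' @export
run_config <- function(expr_sim = expr_sim_config(seed = seed),
                       cohort_sim = cohort_sim_config(seed = seed),
                       expr_path = NULL, meta_path = NULL, events_path = NULL,
                       gmt_path = NULL,
                       fdr = 0.05,
                       separation_fold = 1.5, separation_k = 3,
                       convergence_tol = 0.25, convergence_k = 2,
                       hazard_window = 3,
                       rules = category_rules(),
                       out_dir = "dietswitch_run",
                       seed = 1L) {
  if (!is.null(expr_path) && is.null(meta_path)) {
    stop("meta_path required with expr_path", call. = FALSE)
  }
  if (!is.null(expr_path)) expr_sim <- NULL
  if (!is.null(events_path)) cohort_sim <- NULL
  if (is.null(expr_path) && is.null(expr_sim)) {
    stop("provide either expr_path or expr_sim", call. = FALSE)
  }
  if (is.null(events_path) && is.null(cohort_sim)) {
    stop("provide either events_path or cohort_sim", call. = FALSE)
  }
  stopifnot(fdr > 0, fdr < 1, separation_fold > 1, convergence_tol > 0)
  structure(list(expr_sim = expr_sim, cohort_sim = cohort_sim,
                 expr_path = expr_path, meta_path = meta_path,
                 events_path = events_path, gmt_path = gmt_path,
                 fdr = fdr, separation_fold = separation_fold,
                 separation_k = separation_k,
                 convergence_tol = convergence_tol,
                 convergence_k = convergence_k,
                 hazard_window = hazard_window, rules = rules,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields of [run_config()] map directly to YAML keys; `expr_sim`
#' and `cohort_sim` are nested maps of the corresponding constructor
#' arguments.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(y$seed)) as.integer(y$seed) else 1L
  expr_sim <- if (!is.null(y$expr_sim)) {
    do.call(expr_sim_config, c(y$expr_sim, if (is.null(y$expr_sim$seed)) list(seed = seed)))
  } else if (is.null(y$expr_path)) expr_sim_config(seed = seed) else NULL
  cohort_sim <- if (!is.null(y$cohort_sim)) {
    do.call(cohort_sim_config, c(y$cohort_sim, if (is.null(y$cohort_sim$seed)) list(seed = seed)))
  } else if (is.null(y$events_path)) cohort_sim_config(seed = seed) else NULL
  args <- y[intersect(names(y), c("expr_path", "meta_path", "events_path",
                                  "gmt_path", "fdr", "separation_fold",
                                  "separation_k", "convergence_tol",
                                  "convergence_k", "hazard_window",
                                  "out_dir"))]
  do.call(run_config, c(list(expr_sim = expr_sim, cohort_sim = cohort_sim,
                             seed = seed), args))
}

#' Run the full diet-switch analysis
#'
#' Stages: (1) obtain expression and survival data (simulate or read);
#' (2) demography -- life tables, hazards, log-rank RF vs CF, maximum
#' lifespans, mortality-separation day and post-switch convergence lag;
#' (3) time-paired differential expression with pooled BH FDR;
#' (4) category assignment, switch times and fast-switcher curation;
#' (5) optional gene-set enrichment of Category I genes. All stage outputs
#' are written as TSV under `out_dir` together with a JSON + text report;
#' a rerun with the same configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return the report (named list), invisibly; also written to
#'   `out_dir/report.json` and `out_dir/report.txt`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[dietswitch] ", sprintf(...))
  report <- list(parameters = list(
    fdr = config$fdr, separation_fold = config$separation_fold,
    separation_k = config$separation_k,
    convergence_tol = config$convergence_tol,
    convergence_k = config$convergence_k,
    hazard_window = config$hazard_window, seed = config$seed))

  # -- stage 1: data -----------------------------------------------------
  truth_expr <- NULL
  if (!is.null(config$expr_path)) {
    say("reading expression from %s", config$expr_path)
    expr <- read_expression(config$expr_path, config$meta_path)
  } else {
    say("simulating expression (%d genes, seed %d)",
        config$expr_sim$n_genes, config$expr_sim$seed)
    sim <- simulate_expression(config$expr_sim)
    expr <- sim$expr
    truth_expr <- sim$truth
    write_expression(expr, file.path(config$out_dir, "expression.tsv"),
                     file.path(config$out_dir, "samples.tsv"),
                     truth = truth_expr,
                     truth_path = file.path(config$out_dir, "expression_truth.tsv"))
  }
  if (!is.null(config$events_path)) {
    say("reading events from %s", config$events_path)
    events <- read_events(config$events_path)
    switch_day <- NA_integer_
  } else {
    say("simulating cohorts (%d flies/cohort, seed %d)",
        config$cohort_sim$n_flies, config$cohort_sim$seed)
    events <- simulate_cohorts(config$cohort_sim)$events
    switch_day <- config$cohort_sim$switch_day
    write_events(events, file.path(config$out_dir, "events.tsv"))
  }

  # -- stage 2: demography ----------------------------------------------
  say("demography")
  by_cohort <- split(events, events$cohort)
  lt <- lapply(by_cohort, function(ev) build_life_table(ev, ev$cohort[1]))
  hz <- lapply(lt, hazard, window = config$hazard_window)
  for (co in names(lt)) {
    write_life_table(lt[[co]],
                     file.path(config$out_dir, sprintf("life_table_%s.tsv", co)),
                     window = config$hazard_window)
  }
  lr <- log_rank(by_cohort$RF, by_cohort$CF)
  sep_day <- detect_separation(hz$CF, hz$RF, fold = config$separation_fold,
                               k = config$separation_k)
  conv_lag <- if (!is.na(switch_day)) {
    detect_convergence(hz$SF, hz$RF, switch_day,
                       tol = config$convergence_tol, k = config$convergence_k)
  } else NA_integer_
  report$demography <- list(
    n_flies = vapply(by_cohort, nrow, integer(1)),
    n_deaths = vapply(by_cohort, function(e) sum(e$status == "death"), integer(1)),
    max_lifespan = vapply(by_cohort, max_lifespan, numeric(1)),
    log_rank_RF_vs_CF = lr,
    separation_day_CF_over_RF = sep_day,
    convergence_lag_days = conv_lag)

  # -- stage 3: differential expression ---------------------------------
  say("time-paired differential expression (pooled BH)")
  comp <- run_comparisons(expr)
  write_comparisons(comp, file.path(config$out_dir, "comparisons.tsv"))
  sig_rf_cf <- comp$q < config$fdr & comp$comparison == "RF_vs_CF"
  report$differential_expression <- list(
    n_genes = nrow(expr$values),
    n_diet_dependent = sum(sig_rf_cf),
    prop_down_among_diet_dependent =
      if (any(sig_rf_cf)) mean(comp$mean_diff_log2[sig_rf_cf] < 0) else NA_real_)

  # -- stage 4: categories ----------------------------------------------
  say("category assignment")
  gstats <- gene_level_stats(expr, config$rules)
  assign <- assign_categories(comp, fdr = config$fdr, rules = config$rules,
                              stats = gstats)
  st <- switch_times(expr)
  fast <- curate_fast_switchers(assign, st)
  out_assign <- merge(assign, st, by = "gene_id", sort = FALSE)
  utils::write.table(out_assign, file.path(config$out_dir, "categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- category_counts(assign)
  utils::write.table(counts, file.path(config$out_dir, "category_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report$categories <- list(
    counts = stats::setNames(as.list(counts$n), counts$category),
    up_down = counts[, c("category", "n_up", "n_down")],
    n_fast_switch_up = length(fast$up),
    n_fast_switch_down = length(fast$down))
  if (!is.null(truth_expr)) {
    report$truth_recovery <- archetype_recovery(assign, truth_expr)
  }

  # -- stage 5: enrichment (optional) -----------------------------------
  if (!is.null(config$gmt_path)) {
    say("gene-set enrichment (category I, by direction)")
    coll <- read_gmt(config$gmt_path)
    enr <- enrich_by_direction(assign, coll, categories = "I")
    utils::write.table(enr, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$enrichment <- list(n_sets_tested = nrow(enr),
                              n_significant = sum(enr$q < config$fdr))
  }

  report$categories$up_down <- NULL   # data.frame not JSON-stable; TSV has it
  json_path <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(format_report(report), file.path(config$out_dir, "report.txt"))
  say("done; report at %s", json_path)
  invisible(report)
}

#' Recovery of planted archetypes by the category assignment
#'
#' For each simulated archetype, the fraction of its genes assigned to the
#' category that archetype is designed to produce (switch_up/switch_down ->
#' I, refractory -> II, responsive and slow_switch -> III, deviating -> IV,
#' null -> V).
#'
#' @param assignments a [assign_categories()] result.
#' @param truth truth table from [simulate_expression()].
#' @return data.frame `archetype`, `intended`, `n`, `n_recovered`,
#'   `recovery`.
#' @export
archetype_recovery <- function(assignments, truth) {
  intended <- c(null = "V", switch_up = "I", switch_down = "I",
                refractory = "II", responsive = "III", slow_switch = "III",
                deviating = "IV")
  cat_ <- as.character(assignments$category[match(truth$gene_id,
                                                  assignments$gene_id)])
  sp <- split(cat_, truth$archetype)
  arch <- names(sp)
  data.frame(
    archetype = arch,
    intended = unname(intended[arch]),
    n = vapply(sp, length, integer(1)),
    n_recovered = vapply(arch, function(a) sum(sp[[a]] == intended[a]), integer(1)),
    recovery = vapply(arch, function(a) mean(sp[[a]] == intended[a]), numeric(1)),
    row.names = NULL)
}

format_report <- function(report) {
  d <- report$demography
  c(
    "dietswitch run report",
    "=====================",
    sprintf("seed: %d, FDR: %g", report$parameters$seed, report$parameters$fdr),
    "",
    "Demography:",
    sprintf("  flies per cohort: %s",
            paste(sprintf("%s=%d", names(d$n_flies), d$n_flies), collapse = ", ")),
    sprintf("  maximum lifespan (mean of longest-lived 10%%): %s",
            paste(sprintf("%s=%.1f d", names(d$max_lifespan), d$max_lifespan),
                  collapse = ", ")),
    sprintf("  log-rank RF vs CF: chi-sq=%.2f, p=%.3g",
            d$log_rank_RF_vs_CF$statistic, d$log_rank_RF_vs_CF$p),
    sprintf("  CF/RF hazard separation (>= %gx for %d d): day %s",
            report$parameters$separation_fold, report$parameters$separation_k,
            d$separation_day_CF_over_RF),
    sprintf("  SF-onto-RF convergence lag: %s d", d$convergence_lag_days),
    "",
    "Differential expression:",
    sprintf("  diet-dependent genes (RF vs CF, q < %g): %d of %d",
            report$parameters$fdr,
            report$differential_expression$n_diet_dependent,
            report$differential_expression$n_genes),
    "",
    "Categories:",
    sprintf("  %s", paste(sprintf("%s=%d", names(report$categories$counts),
                                  unlist(report$categories$counts)),
                          collapse = ", ")),
    sprintf("  fast switchers (<= 8 h): %d up, %d down",
            report$categories$n_fast_switch_up,
            report$categories$n_fast_switch_down)
  )
}
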