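# End-to-end orchestration: simulate -> preprocess -> extract -> select ->
# match -> fwhm -> stats, seeded and reproducible, with artifact writers.

#' Default pipeline configuration
#'
#' Protocol constants default to the study values: candidate synergy numbers
#' 1-30, fivefold cross-validation, 50 NMF restarts capped at 3000
#' iterations, matching correlation threshold 0.9 with 10 robustness
#' repeats, significance level 0.05. Smaller settings can be supplied for
#' desk-scale runs.
#'
#' @param cohort cohort configuration (see [default_study_config()]).
#' @return Config list for [run_full_pipeline()].
#' @export
default_pipeline_config <- function(cohort = default_study_config()) {
  list(
    cohort = cohort,
    extraction = list(n_max = 30, folds = 5, restarts = 50, max_iter = 3000),
    matching = list(cor_threshold = 0.9, repeats = 10, restarts = 50,
                    iter_max = 1000),
    stats = list(alpha = 0.05),
    preprocess = list(skip_ecg = FALSE),
    out_dir = NULL
  )
}

#' Run the full synergy analysis pipeline
#'
#' Generates (or accepts) a cohort, preprocesses raw recordings when needed,
#' amplitude-normalizes per participant, and then for every
#' movement-by-floor-by-strategy dataset: computes cross-validated R^2
#' curves for the temporal and spatial models, selects the number of
#' synergies (knee and global/local criteria), extracts the final temporal
#' model, accounts compactness, matches activation profiles across the
#' strategies of each task, measures FWHM, and runs the two-stage
#' support-condition mixed-model analysis. Deterministic given `seed`.
#'
#' @param config configuration list, see [default_pipeline_config()].
#' @param seed master integer seed.
#' @return A summary list (invisibly written to `config$out_dir` when set):
#'   `selection` (per-dataset synergy numbers), `compactness`,
#'   `count_difference`, `matching` (per task), `fwhm` (per dataset),
#'   `stats` (per dataset), `seed`.
#' @export
run_full_pipeline <- function(config, seed) {
  # merge settings groups shallowly; the cohort spec (which contains unnamed
  # task lists) replaces the default wholesale
  cfg <- default_pipeline_config()
  for (nm in names(config)) {
    cfg[[nm]] <- if (nm %in% c("extraction", "matching", "stats", "preprocess")) {
      utils::modifyList(cfg[[nm]], config[[nm]])
    } else config[[nm]]
  }
  ext <- cfg$extraction
  mat <- cfg$matching

  # --- stage 1: simulate -----------------------------------------------
  cohort <- if (!is.null(cfg$cohort$trials)) cfg$cohort
            else generate_cohort(cfg$cohort, seed = split_seed(seed, "cohort"))
  meta <- cohort$metadata

  # --- stage 2: preprocess / normalize ---------------------------------
  is_raw <- inherits(cohort$trials[[1]], "raw_trial")
  if (is_raw) {
    pp <- preprocess_cohort(cohort, skip_ecg = isTRUE(cfg$preprocess$skip_ecg),
                            seed = split_seed(seed, "preprocess"))
    envelopes <- lapply(pp$trials, `[[`, "envelope")
  } else {
    envelopes <- vector("list", nrow(meta))
    for (pid in unique(meta$participant)) {
      rows <- which(meta$participant == pid)
      nrm <- normalize_amplitude(lapply(cohort$trials[rows], `[[`, "envelope"))
      envelopes[rows] <- nrm$envelopes
    }
  }

  # --- stage 3-4: per-dataset extraction and model selection -----------
  meta$task <- paste(meta$movement, meta$floor, sep = ".")
  datasets <- list()
  for (task in unique(meta$task)) {
    for (strat in unique(meta$strategy[meta$task == task])) {
      rows <- which(meta$task == task & meta$strategy == strat)
      label <- paste(task, strat, sep = ".")
      datasets[[label]] <- build_strategy_dataset(
        envelopes[rows], label = label, meta = meta[rows, ])
    }
  }
  selection <- list()
  models <- list()
  compact <- list()
  for (label in names(datasets)) {
    ds <- datasets[[label]]
    n_range <- seq_len(min(ext$n_max, 30))
    sel <- list(label = label)
    for (kind in c("temporal", "spatial")) {
      curve <- cross_validated_curve(
        ds, kind = kind, n_range = n_range, folds = ext$folds,
        restarts = ext$restarts, max_iter = ext$max_iter,
        seed = split_seed(seed, paste("cv", label, kind)))
      knee <- tryCatch(select_n_knee(curve)$n_knee, error = function(e) NA)
      nstar <- tryCatch(select_n_star(curve)$n_star, error = function(e) NA)
      sel[[kind]] <- list(curve = curve, n_knee = knee, n_star = nstar)
    }
    selection[[label]] <- sel
    n_t <- sel$temporal$n_knee
    models[[label]] <- nmf_extract(
      ds, n_t, kind = "temporal", restarts = ext$restarts,
      max_iter = ext$max_iter, seed = split_seed(seed, paste("final", label)))
    if (!is.na(n_t) && !is.na(sel$spatial$n_knee))
      compact[[label]] <- compactness_summary(n_t, sel$spatial$n_knee)
  }
  compactness <- if (length(compact)) do.call(rbind, compact) else NULL
  count_difference <- if (length(compact) >= 2) {
    compare_model_counts(compactness$n_temporal, compactness$n_spatial)
  } else NULL

  # --- stage 5: matching across strategies within a task ---------------
  matching <- list()
  for (task in unique(meta$task)) {
    labels <- grep(paste0("^", task, "\\."), names(models), value = TRUE)
    profs <- do.call(rbind, lapply(labels, function(l)
      t(models[[l]]$trial_independent)))
    strat_of <- unlist(lapply(labels, function(l)
      rep(sub(paste0("^", task, "\\."), "", l), models[[l]]$n)))
    sol <- find_min_valid_k(profs, strat_of,
                            seed = split_seed(seed, paste("match", task)),
                            restarts = mat$restarts, iter_max = mat$iter_max,
                            cor_threshold = mat$cor_threshold)
    sol <- order_clusters_chronologically(sol)
    rob <- suppressWarnings(robustness_check(
      profs, strat_of, repeats = mat$repeats,
      seed = split_seed(seed, paste("robust", task)),
      restarts = mat$restarts, iter_max = mat$iter_max,
      cor_threshold = mat$cor_threshold))
    matching[[task]] <- list(solution = sol, robustness = rob$agreement)
  }

  # --- stage 6: FWHM timing --------------------------------------------
  fwhm_tables <- lapply(names(models), function(label) {
    tab <- fwhm_table(t(models[[label]]$trial_independent))
    tab$dataset <- label
    tab
  })
  fwhm_all <- do.call(rbind, fwhm_tables)

  # --- stage 7: support statistics -------------------------------------
  stats_out <- list()
  for (label in names(models)) {
    ds <- datasets[[label]]
    sup <- unique(ds$meta$support)
    if (length(sup) < 2 || length(unique(ds$meta$participant)) < 2) next
    stats_out[[label]] <- analyze_support_effects(
      models[[label]]$trial_dependent, ds$meta, alpha = cfg$stats$alpha)
  }

  summary <- list(
    seed = seed,
    selection = lapply(selection, function(s) list(
      label = s$label,
      n_temporal = s$temporal$n_knee, n_temporal_star = s$temporal$n_star,
      n_spatial = s$spatial$n_knee, n_spatial_star = s$spatial$n_star)),
    compactness = compactness,
    count_difference = count_difference,
    matching = lapply(matching, function(m) list(
      k = m$solution$k,
      singletons = sum(m$solution$singletons),
      strategy_specific = m$solution$strategy_specific,
      robustness = m$robustness)),
    fwhm = fwhm_all,
    stats = lapply(stats_out, function(st) list(
      alpha_corrected_stage1 = st$alpha_corrected_stage1,
      n_tests_stage1 = st$n_tests_stage1,
      significant = vapply(st$synergies, `[[`, TRUE, "significant")))
  )

  if (!is.null(cfg$out_dir)) {
    write_pipeline_outputs(cfg, seed, cohort, envelopes, selection, models,
                           matching, fwhm_all, stats_out, summary)
  }
  invisible(structure(list(summary = summary, selection = selection,
                           models = models, matching = matching,
                           datasets = datasets, stats = stats_out,
                           cohort = cohort),
                      class = "pipeline_run"))
}

write_pipeline_outputs <- function(cfg, seed, cohort, envelopes, selection,
                                   models, matching, fwhm_all, stats_out,
                                   summary) {
  dir <- cfg$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snapshot <- cfg
  snapshot$out_dir <- NULL
  jsonlite::write_json(list(seed = seed, config = rapply(
    snapshot, function(x) x, how = "replace")),
    file.path(dir, "config.json"), digits = NA, auto_unbox = TRUE,
    force = TRUE)
  write_cohort(list(trials = lapply(envelopes, function(e) list(envelope = e)),
                    metadata = cohort$metadata),
               file.path(dir, "processed_trials"))
  dir.create(file.path(dir, "models"), showWarnings = FALSE)
  for (label in names(models)) {
    write_model_json(models[[label]],
                     file.path(dir, "models", paste0(label, ".json")))
    curve <- selection[[label]]$temporal$curve
    write.table(
      data.frame(n = curve$n_values, r2_mean = curve$r2_mean,
                 r2_sd = curve$r2_sd),
      file.path(dir, "models", paste0(label, ".cv_temporal.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (task in names(matching)) {
    sol <- matching[[task]]$solution
    jsonlite::write_json(
      list(k = sol$k, assignments = sol$assignments,
           strategies = sol$strategies, singletons = sol$singletons,
           robustness = matching[[task]]$robustness),
      file.path(dir, paste0("clusters_", task, ".json")),
      digits = NA, auto_unbox = TRUE)
    write_trial_tsv(t(sol$centroids),
                    file.path(dir, paste0("centroids_", task, ".tsv")))
  }
  write.table(fwhm_all, file.path(dir, "fwhm.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (label in names(stats_out)) {
    st <- stats_out[[label]]
    rows <- do.call(rbind, lapply(st$synergies, function(sy) {
      co <- sy$stage1_ua$coefficients
      co$synergy <- sy$synergy
      co$reference <- "UA"
      co2 <- sy$stage1_lt$coefficients
      co2$synergy <- sy$synergy
      co2$reference <- "LT"
      rbind(co, co2)
    }))
    rows$alpha_corrected <- st$alpha_corrected_stage1
    write.table(rows, file.path(dir, paste0("stats_", label, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)
  invisible(dir)
}
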