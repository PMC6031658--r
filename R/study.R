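#' Study configuration
#'
#' Bundles the simulation, preprocessing and evaluation settings of one
#' reproducible study run. `scale = "paper"` uses the full recording-scale
#' generator defaults (18 subjects, 64 channels, 1 kHz, 80 epochs per
#' condition); `scale = "demo"` is a reduced configuration (fewer subjects,
#' channels and samples) whose runtime fits interactive use while keeping
#' every stage statistically meaningful.
#'
#' @param scale `"demo"` or `"paper"`.
#' @param methods decoding methods to evaluate (see [run_loso()]).
#' @param training_conditions training conditions to evaluate.
#' @param modalities modalities to simulate.
#' @param seed master seed.
#' @param n_exclude number of poor performers dropped from training rosters.
#' @param rho fixed sparse-regression penalty (NULL = inner validation).
#' @param grid_step regularized-CSP tuning grid step.
#' @param sim_overrides named list of [sim_config()] fields to override.
#' @return A list of class `study_config`.
#' @export
study_config <- function(scale = c("demo", "paper"),
                         methods = c("csp_lda", "csp_bagging", "regcsp",
                                     "pooling", "l1_mtl", "l21_mtl"),
                         training_conditions = c("MI", "PM"),
                         modalities = "MEG",
                         seed = 1L, n_exclude = NULL, rho = 2,
                         grid_step = NULL, sim_overrides = list()) {
  scale <- match.arg(scale)
  base <- if (scale == "paper") {
    list(n_subjects = 18L, n_epochs_per_condition = 80L, sfreq = 1000,
         n_low_quality = 5L, n_exclude = 5L, grid_step = 0.1,
         decimation = 10L, n_channels = c(MEG = 64L, EEG = 28L))
  } else {
    list(n_subjects = 8L, n_epochs_per_condition = 24L, sfreq = 250,
         n_low_quality = 2L, n_exclude = 2L, grid_step = 0.5,
         decimation = 10L, n_channels = c(MEG = 16L, EEG = 12L))
  }
  structure(list(scale = scale, methods = methods,
                 training_conditions = training_conditions,
                 modalities = modalities, seed = as.integer(seed),
                 n_exclude = n_exclude %||% base$n_exclude,
                 rho = rho, grid_step = grid_step %||% base$grid_step,
                 base = base, sim_overrides = sim_overrides),
            class = "study_config")
}

study_sim_config <- function(cfg, modality) {
  args <- list(n_subjects = cfg$base$n_subjects,
               n_channels = unname(cfg$base$n_channels[[modality]]),
               modality = modality, sfreq = cfg$base$sfreq,
               n_epochs_per_condition = cfg$base$n_epochs_per_condition,
               n_low_quality = cfg$base$n_low_quality,
               seed = derive_seed(cfg$seed, match(modality, c("MEG", "EEG"))))
  args[names(cfg$sim_overrides)] <- cfg$sim_overrides
  do.call(sim_config, args)
}

#' Run the full decoding study end to end
#'
#' Simulates the multi-subject pool(s), preprocesses every epoch set,
#' computes within-subject baselines, excludes the poorest performers from
#' the training rosters, runs leave-one-subject-out decoding for every
#' requested method / training condition / modality, and computes the
#' statistics suite (chance level, Friedman + post-hoc rank tests,
#' t-tests against chance). When `out_dir` is given, accuracy tables
#' (TSV with a metadata header), the exclusion report, a statistics summary
#' and a bar-chart figure are written there.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @return A list with one entry per modality: `tables` (accuracy_table per
#'   training condition), `within`, `exclusion`, `stats`, `chance`.
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  results <- list()
  for (modality in config$modalities) {
    scfg <- study_sim_config(config, modality)
    pool <- simulate_pool(scfg)
    pp <- preproc_config(epoch_window = scfg$epoch_window,
                         baseline_window = c(scfg$epoch_window[1L], 0),
                         reference = if (modality == "EEG")
                           "common_average" else "none")
    pool$subjects <- lapply(pool$subjects, function(s)
      lapply(s, preprocess_epochs, cfg = pp))
    ids <- vapply(pool$subjects, function(s) s$MI$subject_id, integer(1))

    within <- vapply(seq_along(ids), function(i) {
      s <- pool$subjects[[i]]
      c(within_l1 = within_subject_l1(
          flatten_features(s$MI, config$base$decimation), rho = config$rho),
        within_pm_csp = within_subject_pm_csp(
          s$PM, s$MI, s$rest, n_csp = min(10L, dim(s$MI$data)[2L] - 2L)))
    }, numeric(2))
    colnames(within) <- paste0("S", ids)
    mean_within <- colMeans(within)
    excl <- exclude_poor(stats::setNames(mean_within, ids),
                         k = config$n_exclude)

    tables <- list()
    for (cond in config$training_conditions) {
      cols <- lapply(config$methods, function(m)
        run_loso(pool, m, cond, roster = excl$kept_ids,
                 decimation = config$base$decimation,
                 rho = config$rho, grid_step = config$grid_step))
      tab <- accuracy_table(do.call(cbind, cols),
                            subject_ids = paste0("S", ids),
                            method_names = config$methods,
                            modality = modality, training_condition = cond)
      tables[[cond]] <- tab
    }
    chance <- chance_level(scfg$n_epochs_per_condition)
    stats_out <- lapply(tables, function(tab) {
      full <- cbind(tab$values, within_l1 = within["within_l1", ])
      list(friedman = friedman_rank_test(full),
           posthoc = posthoc_rank_tests(full),
           vs_chance = apply(tab$values, 2L, compare_to_chance,
                             n_trials = scfg$n_epochs_per_condition),
           paired = paired_ttests(full))
    })
    results[[modality]] <- list(tables = tables, within = within,
                                exclusion = excl, stats = stats_out,
                                chance = chance, sim_config = scfg)
  }
  if (!is.null(out_dir)) write_study_outputs(results, config, out_dir)
  invisible(results)
}

#' Recompute every statistic derivable from the bundled reference tables
#'
#' Verifies, against the values printed in the study the tables come from:
#' the binomial chance level, each table's column means, the number of
#' subjects whose online accuracy fell below chance, the excluded-subject
#' set, and the four Friedman chi-square statistics.
#'
#' @param tol_mean tolerance on column means.
#' @param tol_chi2 tolerance on chi-square statistics.
#' @return Data frame with columns `check`, `computed`, `expected`, `pass`.
#' @export
verify_fixtures <- function(tol_mean = 0.01, tol_chi2 = 0.01) {
  rows <- list()
  add <- function(check, computed, expected, pass)
    rows[[length(rows) + 1L]] <<- data.frame(check = check,
                                             computed = computed,
                                             expected = expected, pass = pass)
  add("chance_level(80, 0.05)", chance_level(80, 0.05), 58.75,
      isTRUE(all.equal(chance_level(80, 0.05), 58.75)))
  for (nm in c("meg_within", "meg_mi", "eeg_mi", "meg_pm", "eeg_pm")) {
    tab <- ref_table(nm)
    cm <- colMeans(tab$values)
    for (j in seq_along(cm))
      add(sprintf("%s mean[%s]", nm, names(cm)[j]), cm[[j]],
          tab$printed_mean[[j]],
          abs(cm[[j]] - tab$printed_mean[[j]]) <= tol_mean + 1e-9)
  }
  t1 <- ref_table("meg_within")
  thr <- chance_level(80, 0.05)
  below <- sum(t1$values[, "online_pm"] < thr)
  add("subjects below chance online", below, 7, below == 7)
  excl <- exclude_poor(t1$values[, "average"], k = 5,
                       ids = as.integer(rownames(t1$values)))
  add("excluded set = {3,5,11,12,14}", paste(excl$excluded_ids, collapse = ","),
      "3,5,11,12,14", identical(excl$excluded_ids, c(3L, 5L, 11L, 12L, 14L)))
  chi_exp <- c(meg_mi = 34.29, eeg_mi = 19.84, meg_pm = 16.81, eeg_pm = 34.21)
  for (nm in names(chi_exp)) {
    chi <- friedman_rank_test(ref_table(nm)$values)$chi2
    add(sprintf("friedman chi2 %s", nm), chi, chi_exp[[nm]],
        abs(chi - chi_exp[[nm]]) <= tol_chi2 + 1e-9)
  }
  do.call(rbind, rows)
}

write_study_outputs <- function(results, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# crossmi study | scale=%s | seed=%d | %s",
                   config$scale, config$seed, format(Sys.time(), "%Y-%m-%d"))
  for (modality in names(results)) {
    res <- results[[modality]]
    for (cond in names(res$tables)) {
      f <- file.path(out_dir, sprintf("accuracy_%s_%s.tsv", modality, cond))
      con <- file(f, "w")
      writeLines(c(stamp, sprintf("# modality=%s training=%s chance=%.2f",
                                  modality, cond, res$chance)), con)
      utils::write.table(res$tables[[cond]]$values, con, sep = "\t",
                         quote = FALSE, col.names = NA)
      close(con)
    }
    writeLines(c(stamp,
                 sprintf("excluded: %s",
                         paste(res$exclusion$excluded_ids, collapse = ", ")),
                 sprintf("chance level: %.2f%%", res$chance),
                 vapply(names(res$stats), function(cond)
                   sprintf("%s: friedman chi2=%.3f p=%.4g", cond,
                           res$stats[[cond]]$friedman$chi2,
                           res$stats[[cond]]$friedman$p), character(1))),
               file.path(out_dir, sprintf("stats_%s.txt", modality)))
    p <- plot_study_summary(res, modality)
    ggplot2::ggsave(file.path(out_dir, sprintf("summary_%s.pdf", modality)),
                    p, width = 7, height = 4)
  }
  saveRDS_config <- file.path(out_dir, "config.txt")
  writeLines(c(stamp, utils::capture.output(utils::str(config))), saveRDS_config)
  invisible(out_dir)
}

#' Bar-chart summary of a study run
#'
#' Mean accuracy per method and training condition with standard-deviation
#' error bars and the binomial chance level as a dashed line.
#'
#' @param result one modality's entry from [run_study()].
#' @param modality label for the plot title.
#' @return A ggplot object.
#' @export
plot_study_summary <- function(result, modality = "MEG") {
  rows <- do.call(rbind, lapply(names(result$tables), function(cond) {
    v <- result$tables[[cond]]$values
    data.frame(method = colnames(v), condition = cond,
               mean = colMeans(v), sd = apply(v, 2L, stats::sd))
  }))
  ggplot2::ggplot(rows, ggplot2::aes(x = method, y = mean, fill = condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::geom_hline(yintercept = result$chance, linetype = "dashed") +
    ggplot2::labs(title = sprintf("LOSO decoding accuracy (%s)", modality),
                  x = NULL, y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
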