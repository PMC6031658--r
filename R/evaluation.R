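#' Binomial chance level for classifier accuracy
#'
#' The accuracy a fair-coin classifier must strictly exceed to be
#' significant at level `alpha`: the smallest `k` with
#' `P(Binomial(n, 0.5) > k) < alpha` (equivalently the binomial quantile
#' `qbinom(1 - alpha, n, 1/2)`), expressed as `100 * k / n` percent.
#' Exceeding the threshold - not reaching it - is significant. For 80
#' trials at `alpha = 0.05` this is 58.75% (more than 47 of 80 correct).
#'
#' @param n_trials number of test trials.
#' @param alpha significance level.
#' @return Threshold accuracy in percent.
#' @export
chance_level <- function(n_trials, alpha = 0.05) {
  stopifnot(n_trials >= 1, alpha > 0, alpha < 1)
  100 * stats::qbinom(1 - alpha, n_trials, 0.5) / n_trials
}

#' Tie-corrected Friedman rank test
#'
#' Within-subject (row-wise) midranks of the accuracy table, chi-square
#' statistic with the standard tie correction, p-value from the chi-square
#' distribution with `methods - 1` degrees of freedom.
#'
#' @param values subjects x methods accuracy matrix (or an
#'   `accuracy_table`).
#' @return List with `chi2`, `df`, `p`, `mean_ranks`.
#' @export
friedman_rank_test <- function(values) {
  if (inherits(values, "accuracy_table")) values <- values$values
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) stop("friedman_rank_test: need >= 2 rows and columns")
  r <- t(apply(values, 1L, rank))
  Rj <- colSums(r)
  ties <- 0
  for (i in seq_len(n)) {
    tt <- table(r[i, ])
    ties <- ties + sum(tt^3 - tt)
  }
  denom <- n * k * (k + 1) - ties / (k - 1)
  # fully tied table (e.g. identical columns): no evidence of any effect
  chi2 <- if (denom <= 0) 0 else 12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  df <- k - 1L
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE),
       mean_ranks = Rj / n)
}

#' Bonferroni-corrected post-hoc rank comparisons
#'
#' Pairwise comparisons of the Friedman mean ranks: the rank-mean
#' difference is scored against its large-sample standard error
#' `sqrt(k (k + 1) / (12 n))`, two-sided normal p-values are multiplied by
#' the number of pairs (capped at 1), and significance is flagged at
#' `alpha`.
#'
#' @param values subjects x methods accuracy matrix or `accuracy_table`.
#' @param alpha family-wise significance level.
#' @return List with matrices `p_adjusted`, `p_raw`, `significant`, and the
#'   `mean_ranks`.
#' @export
posthoc_rank_tests <- function(values, alpha = 0.05) {
  if (inherits(values, "accuracy_table")) values <- values$values
  values <- as.matrix(values)
  n <- nrow(values); k <- ncol(values)
  mr <- colSums(t(apply(values, 1L, rank))) / n
  se <- sqrt(k * (k + 1) / (12 * n))
  npair <- choose(k, 2)
  praw <- padj <- matrix(1, k, k, dimnames = list(colnames(values), colnames(values)))
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    z <- (mr[a] - mr[b]) / se
    p <- 2 * stats::pnorm(-abs(z))
    praw[a, b] <- praw[b, a] <- p
    padj[a, b] <- padj[b, a] <- min(1, p * npair)
  }
  list(p_adjusted = padj, p_raw = praw,
       significant = padj < alpha & row(padj) != col(padj),
       mean_ranks = mr)
}

#' One-sided t-test of subject accuracies against chance
#'
#' @param column per-subject accuracies, percent.
#' @param n_trials trials per subject (defines the chance threshold).
#' @param alpha alpha for the chance threshold itself.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return p-value.
#' @export
compare_to_chance <- function(column, n_trials = 80L, alpha = 0.05,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  chance <- chance_level(n_trials, alpha)
  if (stats::sd(column) == 0) {
    log_msg("compare_to_chance: zero variance column")
    return(if (mean(column) > chance) 0 else 1)
  }
  stats::t.test(column, mu = chance, alternative = alternative)$p.value
}

#' Bonferroni-corrected paired t-tests over all method pairs
#'
#' @param values subjects x methods accuracy matrix or `accuracy_table`.
#' @return Matrix of corrected two-sided p-values (diagonal = 1).
#' @export
paired_ttests <- function(values) {
  if (inherits(values, "accuracy_table")) values <- values$values
  values <- as.matrix(values)
  k <- ncol(values)
  npair <- choose(k, 2)
  out <- matrix(1, k, k, dimnames = list(colnames(values), colnames(values)))
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    d <- values[, a] - values[, b]
    p <- if (stats::sd(d) == 0) {
      log_msg("paired_ttests: zero-variance difference, p set to 1")
      1
    } else stats::t.test(values[, a], values[, b], paired = TRUE)$p.value
    out[a, b] <- out[b, a] <- min(1, p * npair)
  }
  out
}

#' Exclude the poorest-performing subjects
#'
#' Ranks subjects by mean within-subject accuracy (ascending, ties broken
#' by subject id) and excludes the lowest `k`; excluded subjects remain
#' test subjects but never enter a training set.
#'
#' @param mean_acc named numeric vector of per-subject mean accuracies
#'   (names = subject ids) or unnamed with `ids` supplied.
#' @param k number of subjects to exclude.
#' @param ids subject ids if `mean_acc` is unnamed.
#' @return List of class `exclusion_report` with `mean_acc`,
#'   `excluded_ids`, `k`, `kept_ids`.
#' @export
exclude_poor <- function(mean_acc, k = 5L, ids = NULL) {
  ids <- ids %||% as.integer(names(mean_acc))
  if (is.null(ids) || any(is.na(ids)))
    stop("exclude_poor: subject ids required")
  if (k >= length(ids)) stop("exclude_poor: k must be below the subject count")
  ord <- order(mean_acc, ids)
  excluded <- sort(ids[ord][seq_len(k)])
  structure(list(mean_acc = stats::setNames(mean_acc, ids),
                 excluded_ids = excluded, k = as.integer(k),
                 kept_ids = sort(setdiff(ids, excluded))),
            class = "exclusion_report")
}

#' Within-subject accuracy by stratified 10-fold l1 logistic regression
#'
#' Stratified k-fold cross-validation of [fit_pooled_l1()] on one subject's
#' feature matrix; returns the mean held-out accuracy in percent.
#'
#' @param features a `feature_matrix` (e.g. from [flatten_features()]).
#' @param rho l1 penalty weight.
#' @param folds number of folds.
#' @return Accuracy in percent.
#' @export
within_subject_l1 <- function(features, rho = 1, folds = 10L) {
  X <- features$values; y <- features$labels
  if (folds < 2L) stop("within_subject_l1: need >= 2 folds")
  fold <- integer(length(y))
  for (cl in c(1L, -1L)) {
    idx <- which(y == cl)
    if (length(idx) < folds / 2)
      stop("within_subject_l1: cannot stratify folds with both classes")
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  hits <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
    fit <- suppressWarnings(
      fit_pooled_l1(X[tr, , drop = FALSE], y[tr], rho,
                    tol = 1e-5, max_iter = 500L))
    mean(predict_unseen(fit, X[!tr, , drop = FALSE])$labels == y[!tr])
  }, numeric(1))
  100 * mean(hits, na.rm = TRUE)
}

#' Within-subject transfer from passive movement to motor imagery
#'
#' Trains the full SSD + CSP + LDA chain on the subject's own PM epochs
#' (band selected from rest vs. PM when rest epochs are available,
#' otherwise the canonical 10 +/- 3 Hz) and scores all of that subject's MI
#' epochs.
#'
#' @param pm,mi the subject's PM and MI [epoch_set()]s.
#' @param rest optional rest [epoch_set()] for band selection.
#' @param n_ssd,n_csp component counts.
#' @return Accuracy in percent.
#' @export
within_subject_pm_csp <- function(pm, mi, rest = NULL,
                                  n_ssd = 20L, n_csp = 10L) {
  band <- if (is.null(rest)) spectral_band(10, 3) else select_band(rest, pm)
  n_ssd <- min(n_ssd, dim(pm$data)[2L])
  n_csp <- min(n_csp, n_ssd)
  pm_f <- bandpass(pm, c(band$low, band$high))
  mi_f <- bandpass(mi, c(band$low, band$high))
  ssd <- fit_ssd(pm, band, n_ssd)
  pm_proj <- project_epochs(pm_f, ssd)
  csp <- fit_csp(pm_proj, pm$labels, n_csp)
  model <- fit_lda(csp_logpower_features_proj(pm_proj, pm$labels, csp))
  mi_proj <- project_epochs(mi_f, ssd)
  pred <- predict_lda(model, csp_logpower_features_proj(mi_proj, mi$labels, csp)$values)
  100 * mean(pred$labels == mi$labels)
}

# project an epoch_set's channels through spatial filters -> 3D array
project_epochs <- function(epochs, filt) {
  d <- epochs$data
  out <- array(0, dim = c(dim(d)[1L], ncol(filt$filters), dim(d)[3L]))
  for (e in seq_len(dim(d)[1L]))
    out[e, , ] <- t(filt$filters) %*% d[e, , , drop = TRUE]
  out
}

# log-power features from an already-projected array
csp_logpower_features_proj <- function(proj, labels, csp) {
  vals <- matrix(0, dim(proj)[1L], ncol(csp$filters))
  for (e in seq_len(dim(proj)[1L])) {
    z <- t(csp$filters) %*% proj[e, , , drop = TRUE]
    vals[e, ] <- log(pmax(rowMeans(z^2), 1e-300))
  }
  feature_matrix(vals, labels, NA_integer_, "csp_logpower")
}

#' Leave-one-subject-out evaluation of one decoding method
#'
#' For every subject in the pool, a decoder is trained on the roster minus
#' that subject (using MI or PM epochs as the training condition dictates)
#' and scored on the subject's MI epochs. Excluded (poor-performing)
#' subjects may be absent from `roster`: they are then tested against a
#' model trained on the full roster. The regularized-CSP method uses only
#' the test subject's label-free pooled covariance for its similarity
#' weighting, so no test labels ever reach training.
#'
#' @param pool a pool from [simulate_pool()] (or a compatible list with
#'   `subjects`).
#' @param method one of `"csp_lda"`, `"csp_bagging"`, `"regcsp"`,
#'   `"pooling"`, `"l1_mtl"`, `"l21_mtl"`.
#' @param training_condition `"MI"` or `"PM"`.
#' @param roster subject ids allowed in training sets (default: all).
#' @param band spectral band for the CSP family.
#' @param n_ssd,n_csp component counts for the CSP family.
#' @param decimation decimation factor for the sparse-regression family.
#' @param rho penalty weight for the sparse-regression family; `NULL`
#'   selects it by inner leave-one-task-out validation on the l2,1 model
#'   (the selected value is then shared by all three sparse methods).
#' @param rho_grid candidate penalty weights used when `rho` is `NULL`.
#' @param grid_step regularized-CSP tuning grid resolution.
#' @return Named numeric vector of per-subject accuracies in percent.
#' @export
run_loso <- function(pool, method = c("csp_lda", "csp_bagging", "regcsp",
                                      "pooling", "l1_mtl", "l21_mtl"),
                     training_condition = c("MI", "PM"), roster = NULL,
                     band = spectral_band(10, 3), n_ssd = 20L, n_csp = 10L,
                     decimation = 10L, rho = NULL,
                     rho_grid = c(0.5, 2, 8), grid_step = 0.1) {
  method <- match.arg(method)
  training_condition <- match.arg(training_condition)
  subjects <- pool$subjects
  all_ids <- vapply(subjects, function(s) s$MI$subject_id, integer(1))
  roster <- roster %||% all_ids
  if (length(roster) < 2L) stop("run_loso: training roster too small")
  n_ch <- dim(subjects[[1L]]$MI$data)[2L]
  n_ssd <- min(n_ssd, n_ch)
  n_csp <- min(n_csp, n_ssd)

  acc <- vapply(all_ids, function(test_id) {
    train_ids <- setdiff(roster, test_id)
    tr <- subjects[match(train_ids, all_ids)]
    train_sets <- lapply(tr, `[[`, training_condition)
    test_set <- subjects[[match(test_id, all_ids)]]$MI
    switch(method,
      csp_lda = loso_csp_lda(train_sets, test_set, band, n_ssd, n_csp, FALSE),
      csp_bagging = loso_csp_lda(train_sets, test_set, band, n_ssd, n_csp, TRUE),
      regcsp = loso_regcsp(train_sets, test_set, n_csp, grid_step),
      loso_sparse(train_sets, test_set, method, decimation, rho, rho_grid))
  }, numeric(1))
  stats::setNames(acc, paste0("S", all_ids))
}

loso_csp_lda <- function(train_sets, test_set, band, n_ssd, n_csp, bagging) {
  train_f <- lapply(train_sets, bandpass, band = c(band$low, band$high))
  pooled <- pool_epoch_sets(train_sets)
  ssd <- fit_ssd(pooled, band, n_ssd)
  proj <- lapply(train_f, project_epochs, filt = ssd)
  all_proj <- abind_epochs(proj)
  all_labels <- unlist(lapply(train_sets, `[[`, "labels"))
  csp <- fit_csp(all_proj, all_labels, n_csp)
  test_f <- bandpass(test_set, c(band$low, band$high))
  test_feat <- csp_logpower_features_proj(project_epochs(test_f, ssd),
                                          test_set$labels, csp)
  if (!bagging) {
    model <- fit_lda(csp_logpower_features_proj(all_proj, all_labels, csp))
    pred <- predict_lda(model, test_feat$values)
  } else {
    members <- lapply(seq_along(train_sets), function(i)
      fit_lda(csp_logpower_features_proj(proj[[i]], train_sets[[i]]$labels, csp)))
    pred <- bagged_predict(bagged_ensemble(members), test_feat$values)
  }
  100 * mean(pred$labels == test_set$labels)
}

loso_regcsp <- function(train_sets, test_set, n_csp, grid_step) {
  params <- tune_regcsp(train_sets, grid_step, n_csp)
  ids <- vapply(train_sets, function(s) s$subject_id, integer(1))
  halves <- split_opt_train(ids)
  tr_sets <- train_sets[match(halves$train, ids)]
  tr_covs <- lapply(tr_sets, subject_class_covariances)
  C1 <- Reduce(`+`, lapply(tr_covs, `[[`, "C1")) / length(tr_covs)
  C2 <- Reduce(`+`, lapply(tr_covs, `[[`, "C2")) / length(tr_covs)
  test_pooled <- epoch_covariance(test_set$data)   # label-free
  gen <- generic_covariance(tr_covs, test_pooled)
  filt <- fit_regcsp(list(C1 = C1, C2 = C2), gen, params, n_csp)
  model <- lda_on_sets(filt, tr_sets)
  pred <- predict_lda(model, csp_logpower_features(test_set, filt)$values)
  100 * mean(pred$labels == test_set$labels)
}

loso_sparse <- function(train_sets, test_set, method, decimation, rho, rho_grid) {
  feats <- lapply(train_sets, flatten_features, decimation = decimation)
  Xall <- do.call(rbind, lapply(feats, `[[`, "values"))
  center <- colMeans(Xall)
  scl <- pmax(apply(Xall, 2L, stats::sd), 1e-12)
  tasks <- lapply(seq_along(train_sets), function(i) {
    raw <- flatten_features(train_sets[[i]], decimation, center, scl)
    list(x = raw$values, y = raw$labels, subject_id = raw$subject_id)
  })
  if (is.null(rho))
    rho <- select_rho(tasks, rho_grid, penalty = "l21")
  test_x <- flatten_features(test_set, decimation, center, scl)$values
  pred <- if (method == "pooling") {
    Xp <- do.call(rbind, lapply(tasks, `[[`, "x"))
    yp <- unlist(lapply(tasks, `[[`, "y"))
    fit <- suppressWarnings(fit_pooled_l1(Xp, yp, rho, tol = 1e-5,
                                          max_iter = 500L))
    predict_unseen(fit, test_x)
  } else {
    pen <- if (method == "l1_mtl") "l1" else "l21"
    fit <- suppressWarnings(fit_mtl(tasks, rho, pen, tol = 1e-5,
                                    max_iter = 500L))
    predict_unseen(fit, test_x)
  }
  100 * mean(pred$labels == test_set$labels)
}

# concatenate epoch_sets along the epoch axis (shared metadata)
pool_epoch_sets <- function(sets) {
  d <- abind_epochs(lapply(sets, `[[`, "data"))
  labels <- unlist(lapply(sets, `[[`, "labels"))
  s1 <- sets[[1L]]
  epoch_set(d, labels, s1$condition, s1$modality, s1$subject_id,
            s1$sfreq, s1$t0)
}

abind_epochs <- function(arrays) {
  d1 <- dim(arrays[[1L]])
  out <- array(0, dim = c(sum(vapply(arrays, function(a) dim(a)[1L], integer(1))),
                          d1[2L], d1[3L]))
  at <- 0L
  for (a in arrays) {
    out[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out
}

#' Accuracy table container
#'
#' @param values subjects x methods matrix of accuracies in percent.
#' @param subject_ids,method_names dimension labels.
#' @param modality `"MEG"` or `"EEG"`.
#' @param training_condition `"MI"` or `"PM"`.
#' @return A list of class `accuracy_table`.
#' @export
accuracy_table <- function(values, subject_ids = rownames(values),
                           method_names = colnames(values),
                           modality = NA_character_,
                           training_condition = NA_character_) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 100))
    stop("accuracy_table: values must be finite percentages in [0, 100]")
  dimnames(values) <- list(subject_ids, method_names)
  structure(list(values = values, subject_ids = subject_ids,
                 method_names = method_names, modality = modality,
                 training_condition = training_condition),
            class = "accuracy_table")
}

#' Bundled reference accuracy tables
#'
#' Per-subject decoding accuracies (percent) transcribed from the published
#' study this pipeline re-implements: within-subject baselines and the six
#' inter-subject methods, for MEG/EEG and MI/PM training. The printed
#' column-mean row of each table is kept separately in `printed_mean` so
#' that recomputed means can be checked against it.
#'
#' @param name one of `"meg_within"`, `"meg_mi"`, `"eeg_mi"`, `"meg_pm"`,
#'   `"eeg_pm"`.
#' @return List with `values` (subjects x methods matrix, rownames =
#'   subject ids) and `printed_mean` (named vector).
#' @export
ref_table <- function(name = c("meg_within", "meg_mi", "eeg_mi",
                               "meg_pm", "eeg_pm")) {
  name <- match.arg(name)
  file <- switch(name,
                 meg_within = "table1_within_subject.tsv",
                 meg_mi = "table2_meg_mi.tsv",
                 eeg_mi = "table3_eeg_mi.tsv",
                 meg_pm = "table4_meg_pm.tsv",
                 eeg_pm = "table5_eeg_pm.tsv")
  path <- system.file("extdata", file, package = "crossmi", mustWork = TRUE)
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  mean_row <- d$subject == "mean"
  vals <- vapply(d[!mean_row, -1L, drop = FALSE],
                 as.numeric, numeric(sum(!mean_row)))
  rownames(vals) <- d$subject[!mean_row]
  list(values = vals,
       printed_mean = stats::setNames(as.numeric(d[mean_row, -1L]),
                                      colnames(vals)))
}
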