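#' Per-class covariance matrices for one subject
#'
#' Trace-normalized averages of per-epoch sample covariances, computed
#' separately for the two classes and pooled over all epochs (label-free).
#' The pooled matrix is what the unsupervised cross-subject weighting uses:
#' no test-subject labels are ever needed.
#'
#' @param epochs an [epoch_set()] containing both classes.
#' @return List with `C1` (class +1), `C2` (class -1), `pooled`, and
#'   `subject_id`.
#' @export
subject_class_covariances <- function(epochs) {
  if (length(unique(epochs$labels)) < 2L)
    stop("subject_class_covariances: both classes must be present")
  d <- epochs$data
  list(C1 = epoch_covariance(d, which(epochs$labels == 1L)),
       C2 = epoch_covariance(d, which(epochs$labels == -1L)),
       pooled = epoch_covariance(d),
       subject_id = epochs$subject_id)
}

#' Generic cross-subject covariance pool
#'
#' For each class c the generic covariance is the similarity-weighted sum
#' `G_c = (1/N) * sum_i (1/fn_i) C_c^i`, where `fn_i` is the squared
#' Frobenius distance between the test subject's label-free pooled
#' covariance and training subject i's pooled covariance (optionally its
#' square root with `squared = FALSE`). Subjects whose covariance resembles
#' the test subject's therefore dominate the pool. Identical matrices
#' (`fn_i = 0`) get a large capped weight.
#'
#' @param train_covs list of [subject_class_covariances()] results, one per
#'   training subject.
#' @param test_cov the test subject's [subject_class_covariances()] result
#'   (only its `pooled` element is used) or a bare pooled covariance matrix.
#' @param squared use the squared Frobenius distance (default) or its root.
#' @return List of class `generic_covariance` with `G1`, `G2`, `weights`,
#'   `distances`, `N`.
#' @export
generic_covariance <- function(train_covs, test_cov, squared = TRUE) {
  if (length(train_covs) < 1L)
    stop("generic_covariance: need at least one training subject")
  Cpool <- if (is.matrix(test_cov)) test_cov else test_cov$pooled
  fn <- vapply(train_covs, function(tc) {
    d <- sum((Cpool - tc$pooled)^2)
    if (squared) d else sqrt(d)
  }, numeric(1))
  w <- ifelse(fn > 0, 1 / fn, {
    log_msg("generic_covariance: zero Frobenius distance, weight capped")
    1e12
  })
  N <- length(train_covs)
  G1 <- Reduce(`+`, Map(function(tc, wi) wi * tc$C1, train_covs, w)) / N
  G2 <- Reduce(`+`, Map(function(tc, wi) wi * tc$C2, train_covs, w)) / N
  structure(list(G1 = G1, G2 = G2, weights = w, distances = fn, N = N),
            class = "generic_covariance")
}

#' Regularized CSP parameters
#'
#' @param beta pooling weight towards the generic covariance, on the grid
#'   `{0, grid_step, ..., 1}`.
#' @param gamma shrinkage weight towards the identity, same grid.
#' @param grid_step grid resolution used by [tune_regcsp()].
#' @param identity_sign `"plus"` (default; keeps the shrunk covariance
#'   positive definite) or `"minus"` to reproduce the subtractive form.
#' @return List of class `regcsp_params`.
#' @export
regcsp_params <- function(beta = 0, gamma = 0, grid_step = 0.1,
                          identity_sign = c("plus", "minus")) {
  identity_sign <- match.arg(identity_sign)
  if (beta < 0 || beta > 1 || gamma < 0 || gamma > 1)
    stop("regcsp_params: beta and gamma must lie in [0, 1]")
  structure(list(beta = beta, gamma = gamma, grid_step = grid_step,
                 identity_sign = identity_sign),
            class = "regcsp_params")
}

# shrink one class covariance: (1 - gamma) * ((1-beta) C + beta G) +/- gamma I
shrink_cov <- function(Cc, Gc, params) {
  Chat <- (1 - params$beta) * Cc + params$beta * Gc
  I <- diag(nrow(Chat)) * mean(diag(Chat))  # identity on the matrix's scale
  s <- if (params$identity_sign == "plus") 1 else -1
  (1 - params$gamma) * Chat + s * params$gamma * I
}

#' Fit regularized CSP filters
#'
#' Shrinks each class covariance first towards the generic cross-subject
#' pool (`beta`) and then towards the identity (`gamma`), and extracts CSP
#' filters from the shrunk pair by the same both-ends generalized
#' eigendecomposition as [fit_csp()]. At `beta = gamma = 0` this reduces
#' exactly to ordinary CSP on the training covariances. Under the
#' subtractive identity form a non-positive-definite denominator gets an
#' eigenvalue floor (logged).
#'
#' @param subject_covs list with `C1`, `C2`: the training-data class
#'   covariances (e.g. averaged over the training subjects).
#' @param generic a [generic_covariance()].
#' @param params a [regcsp_params()].
#' @param n_components number of CSP components.
#' @return A `spatial_filter` of kind `"regCSP"`.
#' @export
fit_regcsp <- function(subject_covs, generic, params = regcsp_params(),
                       n_components = 10L) {
  Ct1 <- shrink_cov(subject_covs$C1, generic$G1, params)
  Ct2 <- shrink_cov(subject_covs$C2, generic$G2, params)
  if (params$identity_sign == "minus") {
    m1 <- min(eigen((Ct1 + t(Ct1)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    m2 <- min(eigen((Ct2 + t(Ct2)) / 2, symmetric = TRUE, only.values = TRUE)$values)
    if (min(m1, m2) <= 0) {
      log_msg("fit_regcsp: indefinite matrices under minus sign, flooring eigenvalues")
      scale <- max(abs(diag(Ct1)), abs(diag(Ct2)))
      ridge <- abs(min(m1, m2)) + 1e-6 * scale
      Ct1 <- Ct1 + diag(nrow(Ct1)) * ridge
      Ct2 <- Ct2 + diag(nrow(Ct2)) * ridge
    }
  }
  m <- csp_from_covariances(Ct1, Ct2, n_components)
  m$kind <- "regCSP"
  m
}

# deterministic optimization/training split of a sorted subject roster:
# even positions -> optimization half, odd -> training half
split_opt_train <- function(ids) {
  ids <- sort(ids)
  pos <- seq_along(ids)
  list(opt = ids[pos %% 2L == 0L], train = ids[pos %% 2L == 1L])
}

# argmax over the (beta, gamma) grid with ties broken toward smaller values
# (beta scanned first, then gamma). `acc` is a matrix [i_beta, i_gamma].
grid_argmax <- function(acc, grid) {
  best <- which(acc == max(acc), arr.ind = TRUE)
  ord <- order(grid[best[, 1L]] + grid[best[, 2L]],
               grid[best[, 1L]], grid[best[, 2L]])
  b <- best[ord[1L], ]
  c(beta = grid[b[1L]], gamma = grid[b[2L]])
}

#' Tune the regularized-CSP parameters
#'
#' Deterministically splits the training roster into an optimization half
#' (even positions after sorting by subject id) and a training half (odd
#' positions). For every `(beta, gamma)` on the grid, each optimization
#' subject is held out in turn: filters are fitted from the training half
#' (with the generic pool weighted against the held-out subject's pooled
#' covariance), an LDA is trained on the training half's log-power features,
#' and the held-out subject is scored. The pair with the highest mean
#' accuracy wins; ties break toward smaller `(beta, gamma)`, so an
#' uninformative grid returns `(0, 0)`.
#'
#' @param train_sets named list of training [epoch_set()]s (one per subject).
#' @param grid_step grid resolution in `[0, 1]`.
#' @param n_components CSP components.
#' @param identity_sign see [regcsp_params()].
#' @return A [regcsp_params()] carrying the selected pair.
#' @export
tune_regcsp <- function(train_sets, grid_step = 0.1, n_components = 10L,
                        identity_sign = "plus") {
  ids <- vapply(train_sets, function(s) s$subject_id, integer(1))
  if (length(ids) < 4L)
    stop("tune_regcsp: need at least 4 training subjects")
  halves <- split_opt_train(ids)
  covs <- lapply(train_sets, subject_class_covariances)
  names(covs) <- as.character(ids)
  grid <- seq(0, 1, by = grid_step)
  acc <- matrix(0, length(grid), length(grid))
  tr_covs <- covs[as.character(halves$train)]
  C1 <- Reduce(`+`, lapply(tr_covs, `[[`, "C1")) / length(tr_covs)
  C2 <- Reduce(`+`, lapply(tr_covs, `[[`, "C2")) / length(tr_covs)
  tr_sets <- train_sets[match(halves$train, ids)]
  for (ib in seq_along(grid)) {
    for (ig in seq_along(grid)) {
      params <- regcsp_params(grid[ib], grid[ig], grid_step, identity_sign)
      hits <- vapply(halves$opt, function(v) {
        gen <- generic_covariance(tr_covs, covs[[as.character(v)]])
        filt <- fit_regcsp(list(C1 = C1, C2 = C2), gen, params, n_components)
        model <- lda_on_sets(filt, tr_sets)
        vset <- train_sets[[match(v, ids)]]
        mean(predict_lda(model, csp_logpower_features(vset, filt)$values)$labels ==
               vset$labels)
      }, numeric(1))
      acc[ib, ig] <- mean(hits)
    }
  }
  bg <- grid_argmax(acc, grid)
  regcsp_params(bg[["beta"]], bg[["gamma"]], grid_step, identity_sign)
}

# fit an LDA on the pooled log-power features of several epoch sets
lda_on_sets <- function(filt, sets, ssd = NULL) {
  feats <- lapply(sets, function(s) csp_logpower_features(s, filt, ssd))
  X <- do.call(rbind, lapply(feats, `[[`, "values"))
  y <- unlist(lapply(feats, `[[`, "labels"))
  fit_lda(feature_matrix(X, y))
}
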