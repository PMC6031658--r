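#' Linear discriminant analysis with pooled covariance
#'
#' Two-class LDA under equal priors (the study design is balanced 40/40):
#' `w = S^-1 (m1 - m2)`, bias placed at the midpoint of the projected class
#' means. When the pooled covariance is ill-conditioned it is shrunk toward
#' its diagonal (logged) before inversion.
#'
#' @param features a `feature_matrix` (see [feature_matrix()]), or a plain
#'   matrix with `labels` supplied.
#' @param labels per-sample labels in `{+1, -1}` for matrix input.
#' @param shrink shrinkage weight applied when the covariance condition
#'   number exceeds `1e8`.
#' @return A list of class `lda_model` with `w`, `b`, `class_means`.
#' @export
fit_lda <- function(features, labels = NULL, shrink = 0.05) {
  if (inherits(features, "feature_matrix")) {
    labels <- features$labels
    features <- features$values
  }
  X <- as.matrix(features)
  if (is.null(labels)) stop("fit_lda: labels required")
  if (length(unique(labels)) < 2L) stop("fit_lda: both classes must be present")
  if (nrow(X) <= 2L) stop("fit_lda: need more than 2 samples")
  i1 <- labels == 1L
  m1 <- colMeans(X[i1, , drop = FALSE])
  m2 <- colMeans(X[!i1, , drop = FALSE])
  X1 <- sweep(X[i1, , drop = FALSE], 2L, m1)
  X2 <- sweep(X[!i1, , drop = FALSE], 2L, m2)
  S <- (crossprod(X1) + crossprod(X2)) / (nrow(X) - 2L)
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || max(ev) / max(min(ev), .Machine$double.eps) > 1e8) {
    log_msg("fit_lda: ill-conditioned covariance, shrinking toward diagonal")
    S <- (1 - shrink) * S + shrink * diag(pmax(diag(S), 1e-12), ncol(S))
  }
  w <- drop(solve(S, m1 - m2))
  b <- -sum(w * (m1 + m2) / 2)
  structure(list(w = w, b = b, class_means = rbind(`+1` = m1, `-1` = m2)),
            class = "lda_model")
}

#' Predict from an LDA model
#'
#' The class `+1` probability is the logistic of the discriminant score;
#' the label is `+1` iff that probability strictly exceeds 0.5, so an exact
#' tie (a sample on the decision boundary) resolves to `-1`.
#'
#' @param model an `lda_model`.
#' @param features matrix or `feature_matrix` of samples to score.
#' @return List with `labels` and `prob` (class `+1` probabilities).
#' @export
predict_lda <- function(model, features) {
  if (inherits(features, "feature_matrix")) features <- features$values
  X <- as.matrix(features)
  if (ncol(X) != length(model$w))
    stop("predict_lda: feature dimension mismatch")
  score <- drop(X %*% model$w) + model$b
  prob <- stats::plogis(score)
  list(labels = ifelse(prob > 0.5, 1L, -1L), prob = prob)
}

#' Per-subject bagged LDA ensemble
#'
#' One LDA per training subject; predictions aggregate either the
#' unweighted mean of member class `+1` probabilities (default, thresholded
#' at 0.5 with ties to `-1`) or a majority vote.
#'
#' @param members named list of `lda_model`s, one per training subject.
#' @param aggregation `"mean_probability"` or `"majority"`.
#' @return A list of class `bagged_ensemble`.
#' @export
bagged_ensemble <- function(members,
                            aggregation = c("mean_probability", "majority")) {
  if (length(members) < 1L) stop("bagged_ensemble: need at least one member")
  structure(list(members = members, aggregation = match.arg(aggregation)),
            class = "bagged_ensemble")
}

#' @rdname bagged_ensemble
#' @param ensemble a `bagged_ensemble`.
#' @param features matrix or `feature_matrix` of samples to score.
#' @export
bagged_predict <- function(ensemble, features) {
  preds <- lapply(ensemble$members, predict_lda, features = features)
  if (ensemble$aggregation == "mean_probability") {
    p <- rowMeans(vapply(preds, `[[`, numeric(nrow(as.matrix(
      if (inherits(features, "feature_matrix")) features$values else features))),
      "prob"))
    list(labels = ifelse(p > 0.5, 1L, -1L), prob = p)
  } else {
    votes <- rowMeans(vapply(preds, function(p) as.numeric(p$labels),
                             numeric(length(preds[[1L]]$labels))))
    list(labels = ifelse(votes > 0, 1L, -1L), prob = (votes + 1) / 2)
  }
}
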