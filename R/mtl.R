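#' Multi-task sample container
#'
#' @param tasks list of tasks, each a list with `x` (samples x features
#'   matrix), `y` (labels in `{+1, -1}`) and `subject_id`. All tasks must
#'   share the feature dimension.
#' @return A list of class `task_set`.
#' @export
task_set <- function(tasks) {
  p <- unique(vapply(tasks, function(t) ncol(t$x), integer(1)))
  if (length(p) != 1L) stop("task_set: all tasks must share the feature dimension")
  for (t in tasks) {
    if (nrow(t$x) != length(t$y)) stop("task_set: labels must align with rows")
    if (!all(t$y %in% c(1, -1))) stop("task_set: labels must be +1/-1")
  }
  structure(list(tasks = tasks, p = p, t = length(tasks),
                 n = vapply(tasks, function(t) nrow(t$x), integer(1))),
            class = "task_set")
}

#' l2,1 norm of a weight matrix
#'
#' Sum over feature rows of the Euclidean norm of each row across tasks;
#' the group-sparsity penalty that forces a feature to be selected for all
#' tasks or none.
#'
#' @param W features x tasks matrix.
#' @return Scalar norm.
#' @export
l21_norm <- function(W) sum(sqrt(rowSums(as.matrix(W)^2)))

# numerically stable log(1 + exp(-z))
log1pexp_neg <- function(z) ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))

penalty_value <- function(W, penalty) {
  if (penalty == "l21") l21_norm(W) else sum(abs(W))
}

# smooth part: sum of logistic losses over all tasks and samples
mtl_smooth_loss <- function(W, c_int, tasks) {
  loss <- 0
  for (i in seq_along(tasks)) {
    m <- drop(tasks[[i]]$x %*% W[, i]) + c_int[i]
    loss <- loss + sum(log1pexp_neg(tasks[[i]]$y * m))
  }
  loss
}

mtl_smooth_grad <- function(W, c_int, tasks) {
  gW <- matrix(0, nrow(W), ncol(W))
  gc <- numeric(length(c_int))
  for (i in seq_along(tasks)) {
    y <- tasks[[i]]$y
    m <- drop(tasks[[i]]$x %*% W[, i]) + c_int[i]
    s <- stats::plogis(-y * m)           # sigma(-y m)
    gW[, i] <- -drop(crossprod(tasks[[i]]$x, y * s))
    gc[i] <- -sum(y * s)
  }
  list(W = gW, c = gc)
}

#' Full multi-task objective
#'
#' Sum over tasks and samples of the logistic loss of task `i`'s weight
#' column, plus `rho` times the penalty on `W` (intercepts unpenalized).
#'
#' @param model an `mtl_model` (or a list with `W`, `c`, `rho`, `penalty`).
#' @param tasks a [task_set()].
#' @return Scalar objective value.
#' @export
mtl_objective <- function(model, tasks) {
  if (inherits(tasks, "task_set")) tasks <- tasks$tasks
  mtl_smooth_loss(model$W, model$c, tasks) +
    model$rho * penalty_value(model$W, model$penalty)
}

#' Proximal operator of the scaled penalty
#'
#' For `l21`, each feature row is scaled by
#' `max(0, 1 - step * rho / ||row||_2)` (rows below the threshold vanish
#' exactly); for `l1`, elementwise soft-thresholding at `step * rho`.
#'
#' @param W features x tasks matrix.
#' @param step step size (> 0).
#' @param rho penalty weight (>= 0).
#' @param penalty `"l21"` or `"l1"`.
#' @return The shrunk matrix.
#' @export
prox_step <- function(W, step, rho, penalty = c("l21", "l1")) {
  penalty <- match.arg(penalty)
  if (step <= 0) stop("prox_step: step must be positive")
  thr <- step * rho
  if (thr == 0) return(W)
  W <- as.matrix(W)
  if (penalty == "l21") {
    rn <- sqrt(rowSums(W^2))
    scale <- pmax(0, 1 - thr / pmax(rn, .Machine$double.eps))
    W * scale
  } else {
    sign(W) * pmax(abs(W) - thr, 0)
  }
}

#' Fit the regularized multi-task logistic regression
#'
#' Accelerated proximal-gradient (FISTA) minimization of the summed
#' logistic loss plus `rho` times the `l2,1` or `l1` penalty on the weight
#' matrix, with backtracking line search, zero initialization, unpenalized
#' intercepts, and adaptive momentum restart so the recorded objective
#' trace is non-increasing. Convergence is declared when the relative
#' objective change drops below `tol`; hitting `max_iter` first returns the
#' best iterate with a warning.
#'
#' @param tasks a [task_set()] or plain list of tasks.
#' @param rho penalty weight (>= 0).
#' @param penalty `"l21"` (shared row support across tasks) or `"l1"`.
#' @param tol relative objective-change tolerance.
#' @param max_iter iteration cap.
#' @return A list of class `mtl_model` with `W` (features x tasks), `c`
#'   (intercepts), `rho`, `penalty`, `objective` (trace over accepted
#'   iterations), `converged`, `iterations`.
#' @export
fit_mtl <- function(tasks, rho, penalty = c("l21", "l1"),
                    tol = 1e-6, max_iter = 2000L) {
  penalty <- match.arg(penalty)
  if (inherits(tasks, "task_set")) tasks <- tasks$tasks
  if (length(tasks) < 1L) stop("fit_mtl: need at least one task")
  if (rho < 0) stop("fit_mtl: rho must be non-negative")
  p <- ncol(tasks[[1L]]$x)
  t <- length(tasks)
  W <- matrix(0, p, t); c_int <- numeric(t)
  Wy <- W; cy <- c_int                      # momentum point
  L <- 1; tk <- 1
  obj <- mtl_smooth_loss(W, c_int, tasks) + rho * penalty_value(W, penalty)
  trace <- obj
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    g <- mtl_smooth_grad(Wy, cy, tasks)
    fy <- mtl_smooth_loss(Wy, cy, tasks)
    repeat {
      Wn <- prox_step(Wy - g$W / L, 1 / L, rho, penalty)
      cn <- cy - g$c / L
      dW <- Wn - Wy; dc <- cn - cy
      fn <- mtl_smooth_loss(Wn, cn, tasks)
      quad <- fy + sum(g$W * dW) + sum(g$c * dc) +
        L / 2 * (sum(dW^2) + sum(dc^2))
      if (fn <= quad + 1e-12 * abs(quad)) break
      L <- L * 2
      if (L > 1e18) break
    }
    new_obj <- fn + rho * penalty_value(Wn, penalty)
    if (new_obj > obj) {
      # momentum overshoot: restart from the last accepted iterate
      tk <- 1; Wy <- W; cy <- c_int
      g <- mtl_smooth_grad(Wy, cy, tasks)
      fy <- mtl_smooth_loss(Wy, cy, tasks)
      repeat {
        Wn <- prox_step(Wy - g$W / L, 1 / L, rho, penalty)
        cn <- cy - g$c / L
        dW <- Wn - Wy; dc <- cn - cy
        fn <- mtl_smooth_loss(Wn, cn, tasks)
        quad <- fy + sum(g$W * dW) + sum(g$c * dc) +
          L / 2 * (sum(dW^2) + sum(dc^2))
        if (fn <= quad + 1e-12 * abs(quad)) break
        L <- L * 2
        if (L > 1e18) break
      }
      new_obj <- fn + rho * penalty_value(Wn, penalty)
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Wy <- Wn + ((tk - 1) / tk1) * (Wn - W)
    cy <- cn + ((tk - 1) / tk1) * (cn - c_int)
    tk <- tk1
    rel <- abs(obj - new_obj) / max(1, abs(obj))
    W <- Wn; c_int <- cn
    if (new_obj <= obj) obj <- new_obj
    trace <- c(trace, obj)
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("fit_mtl: maximum iterations reached before convergence")
  structure(list(W = W, c = c_int, rho = rho, penalty = penalty,
                 objective = trace, converged = converged,
                 iterations = length(trace) - 1L),
            class = "mtl_model")
}

#' Pooled l1-regularized logistic regression
#'
#' Single-task special case of [fit_mtl()]: all subjects' samples are
#' concatenated into one task and fitted with the `l1` penalty.
#'
#' @param x samples x features matrix.
#' @param y labels in `{+1, -1}`.
#' @inheritParams fit_mtl
#' @return An `mtl_model` with a single weight column.
#' @export
fit_pooled_l1 <- function(x, y, rho, tol = 1e-6, max_iter = 2000L) {
  if (length(unique(y)) < 2L) stop("fit_pooled_l1: both classes must be present")
  fit_mtl(list(list(x = as.matrix(x), y = y, subject_id = NA_integer_)),
          rho = rho, penalty = "l1", tol = tol, max_iter = max_iter)
}

#' Predict labels for an unseen subject
#'
#' The unseen test subject has no column of its own, so the consensus model
#' - the mean over task weight columns plus the mean intercept - scores the
#' test samples; label `+1` iff the logistic of the score strictly exceeds
#' 0.5 (ties to `-1`).
#'
#' @param model an `mtl_model`.
#' @param x_test samples x features matrix.
#' @return List with `labels` and `prob`.
#' @export
predict_unseen <- function(model, x_test) {
  w <- rowMeans(model$W)
  b <- mean(model$c)
  prob <- stats::plogis(drop(as.matrix(x_test) %*% w) + b)
  list(labels = ifelse(prob > 0.5, 1L, -1L), prob = prob)
}

#' Select the penalty weight by inner leave-one-task-out validation
#'
#' For every candidate, each training task is held out in turn, the model is
#' fitted on the remaining tasks, and [predict_unseen()] accuracy on the
#' held-out task is recorded. The candidate with the best mean accuracy
#' wins; ties break toward the larger (sparser) value. Only training tasks
#' are ever touched, so the choice cannot leak test-subject information.
#'
#' @param tasks a [task_set()] or list of >= 3 tasks.
#' @param candidates numeric vector of penalty weights.
#' @param penalty `"l21"` or `"l1"`.
#' @inheritParams fit_mtl
#' @return The selected penalty weight.
#' @export
select_rho <- function(tasks, candidates, penalty = "l21",
                       tol = 1e-5, max_iter = 500L) {
  if (inherits(tasks, "task_set")) tasks <- tasks$tasks
  if (length(candidates) == 1L) return(candidates)
  if (length(tasks) < 3L) stop("select_rho: need at least 3 tasks")
  acc <- vapply(candidates, function(r) {
    mean(vapply(seq_along(tasks), function(h) {
      fit <- suppressWarnings(
        fit_mtl(tasks[-h], rho = r, penalty = penalty,
                tol = tol, max_iter = max_iter))
      mean(predict_unseen(fit, tasks[[h]]$x)$labels == tasks[[h]]$y)
    }, numeric(1)))
  }, numeric(1))
  best <- which(acc >= max(acc) - 1e-12)
  max(candidates[best])
}

#' Flattened, standardized time-course features for the sparse decoders
#'
#' Decimates each epoch and flattens the channels x samples block into one
#' feature row. Columns are z-scored with the supplied (training) statistics;
#' when none are given they are computed from the data itself and returned,
#' so the caller can re-apply them to a test subject.
#'
#' @param epochs an [epoch_set()].
#' @param decimation decimation factor (see [decimate_epochs()]).
#' @param center,scale optional per-feature statistics from the training set.
#' @return A `feature_matrix` of kind `"flattened_timecourse"` with
#'   attributes `center` and `scale`.
#' @export
flatten_features <- function(epochs, decimation = 10L,
                             center = NULL, scale = NULL) {
  dec <- decimate_epochs(epochs, decimation)
  d <- dec$data
  X <- matrix(d, nrow = dim(d)[1L])   # epochs x (channels*samples)
  if (is.null(center)) {
    center <- colMeans(X)
    scale <- pmax(apply(X, 2L, stats::sd), 1e-12)
  }
  X <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fm <- feature_matrix(X, dec$labels, dec$subject_id, "flattened_timecourse")
  attr(fm, "center") <- center
  attr(fm, "scale") <- scale
  fm
}
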