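test_that("the l2,1 norm and the objective follow their closed forms", {
  expect_equal(l21_norm(matrix(0, 4, 3)), 0)
  expect_equal(l21_norm(matrix(c(3, 4), 1, 2)), 5)
  W <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(l21_norm(W), l21_norm(W[c(3, 1, 4, 2), ]))

  tasks <- make_shared_tasks(n_tasks = 2L, n = 7L, p = 3L)
  n_tot <- sum(vapply(tasks, function(t) length(t$y), integer(1)))
  m0 <- list(W = matrix(0, 3, 2), c = c(0, 0), rho = 1.5, penalty = "l21")
  expect_equal(mtl_objective(m0, task_set(tasks)), n_tot * log(2))

  W1 <- matrix(stats::rnorm(6), 3, 2)
  m1 <- list(W = W1, c = c(0, 0), rho = 1, penalty = "l21")
  m2 <- list(W = W1, c = c(0, 0), rho = 2, penalty = "l21")
  expect_gt(mtl_objective(m2, tasks), mtl_objective(m1, tasks))

  one <- list(list(x = matrix(c(2, 0, 0), 1, 3), y = 1L, subject_id = 1L))
  m <- list(W = matrix(c(5, 1, 1), 3, 1), c = 0, rho = 0, penalty = "l1")
  expect_equal(mtl_objective(m, one), log(1 + exp(-10)))
})

test_that("the proximal operator matches its closed forms", {
  W <- matrix(c(3, 4, 0.1, 0.1), 2, 2, byrow = TRUE)  # row norms 5 and ~0.14
  out <- prox_step(W, step = 1, rho = 5, penalty = "l21")
  expect_equal(out[2, ], c(0, 0))            # below threshold: exactly zero
  expect_equal(out[1, ], c(0, 0))            # norm 5 at threshold 5: zero
  half <- prox_step(matrix(c(3, 4), 1, 2), step = 0.5, rho = 5, penalty = "l21")
  expect_equal(half, matrix(c(1.5, 2), 1, 2))
  expect_equal(prox_step(W, 1, 0, "l21"), W)
  soft <- prox_step(matrix(c(-2, 0.5, 3), 1, 3), step = 1, rho = 1, "l1")
  expect_equal(soft, matrix(c(-1, 0, 2), 1, 3))
})

test_that("the smooth gradient matches central finite differences", {
  tasks <- make_shared_tasks(n_tasks = 2L, n = 10L, p = 6L, seed = 5)
  withr::with_seed(6, {
    W <- matrix(stats::rnorm(12, sd = 0.3), 6, 2)
    cc <- stats::rnorm(2, sd = 0.2)
  })
  g <- crossmi:::mtl_smooth_grad(W, cc, tasks)
  h <- 1e-5
  num_gW <- W
  for (i in seq_len(6)) for (j in 1:2) {
    Wp <- W; Wp[i, j] <- W[i, j] + h
    Wm <- W; Wm[i, j] <- W[i, j] - h
    num_gW[i, j] <- (crossmi:::mtl_smooth_loss(Wp, cc, tasks) -
                       crossmi:::mtl_smooth_loss(Wm, cc, tasks)) / (2 * h)
  }
  expect_lt(max(abs(g$W - num_gW)) / max(abs(num_gW)), 1e-5)
  num_gc <- vapply(1:2, function(j) {
    cp <- cc; cp[j] <- cc[j] + h; cm <- cc; cm[j] <- cc[j] - h
    (crossmi:::mtl_smooth_loss(W, cp, tasks) -
       crossmi:::mtl_smooth_loss(W, cm, tasks)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(g$c - num_gc)) / max(abs(num_gc)), 1e-5)
})

test_that("the solver trace is monotone and solutions satisfy optimality", {
  tasks <- make_shared_tasks(n_tasks = 3L, n = 25L, p = 12L, support = 1:4,
                             seed = 11)
  fit <- fit_mtl(tasks, rho = 2, penalty = "l21", tol = 1e-11, max_iter = 10000L)
  expect_true(fit$converged)
  expect_true(all(diff(fit$objective) <= 1e-10))

  g <- crossmi:::mtl_smooth_grad(fit$W, fit$c, tasks)
  rn <- sqrt(rowSums(fit$W^2))
  for (i in seq_len(12)) {
    if (rn[i] > 1e-8) {
      resid <- g$W[i, ] + 2 * fit$W[i, ] / rn[i]
      expect_lt(sqrt(sum(resid^2)), 1e-4)
    } else {
      expect_lte(sqrt(sum(g$W[i, ]^2)), 2 * (1 + 1e-4))
    }
  }
  # shared row support: a feature is active for all tasks or none
  active <- abs(fit$W) > 0
  expect_true(all(rowSums(active) %in% c(0L, ncol(fit$W))))

  # huge rho kills W and leaves intercepts to carry class imbalance
  skew <- list(list(x = matrix(stats::rnorm(60), 20, 3),
                    y = c(rep(1L, 14), rep(-1L, 6)), subject_id = 1L))
  big <- fit_mtl(skew, rho = 1e4, penalty = "l1", tol = 1e-10)
  expect_equal(max(abs(big$W)), 0)
  expect_equal(stats::plogis(big$c), 0.7, tolerance = 1e-3)
})

test_that("single-task l1 agrees with the glmnet reference solver", {
  skip_if_not_installed("glmnet")
  withr::with_seed(12, {
    n <- 60L; p <- 10L
    X <- matrix(stats::rnorm(n * p), n, p)
    y <- ifelse(stats::runif(n) < stats::plogis(X[, 1] - X[, 2]), 1L, -1L)
  })
  rho <- 3
  mine <- fit_pooled_l1(X, y, rho, tol = 1e-10, max_iter = 5000L)
  ref <- glmnet::glmnet(X, factor(y, levels = c(-1, 1)), family = "binomial",
                        lambda = rho / n, standardize = FALSE, thresh = 1e-14)
  w_ref <- as.numeric(ref$beta); c_ref <- as.numeric(ref$a0)
  obj <- function(w, b) {
    m <- drop(X %*% w) + b
    sum(log1p(exp(-y * m))) + rho * sum(abs(w))
  }
  o_mine <- obj(mine$W[, 1], mine$c)
  o_ref <- obj(w_ref, c_ref)
  expect_lt(abs(o_mine - o_ref) / abs(o_ref), 1e-3)
  expect_lte(o_mine, o_ref * (1 + 1e-3))   # we should not be worse
})

test_that("pooled l1 is the single-task reduction and support shrinks with rho", {
  tasks <- make_shared_tasks(n_tasks = 2L, n = 20L, p = 8L, seed = 13)
  Xc <- rbind(tasks[[1]]$x, tasks[[2]]$x)
  yc <- c(tasks[[1]]$y, tasks[[2]]$y)
  a <- fit_pooled_l1(Xc, yc, 1, tol = 1e-9)
  b <- fit_mtl(list(list(x = Xc, y = yc, subject_id = 1L)), 1, "l1", tol = 1e-9)
  expect_equal(a$W, b$W, tolerance = 1e-9)

  nnz <- vapply(c(0.1, 1, 5, 25, 1e3), function(r)
    sum(abs(fit_pooled_l1(Xc, yc, r, tol = 1e-9)$W) > 1e-8), numeric(1))
  expect_true(all(diff(nnz) <= 0))
  expect_equal(nnz[5], 0)

  huge <- fit_pooled_l1(Xc, yc, 1e4, tol = 1e-10)
  maj <- max(mean(yc == 1), mean(yc == -1))
  expect_equal(mean(predict_unseen(huge, Xc)$labels == yc), maj)
})

test_that("unseen-subject prediction uses the consensus column mean", {
  w <- c(1, -2, 0.5)
  W <- cbind(w, w, w)
  m <- structure(list(W = W, c = c(0.3, 0.3, 0.3), rho = 1, penalty = "l21"),
                 class = "mtl_model")
  single <- structure(list(W = matrix(w), c = 0.3, rho = 1, penalty = "l21"),
                      class = "mtl_model")
  withr::with_seed(14, X <- matrix(stats::rnorm(15), 5, 3))
  expect_equal(predict_unseen(m, X), predict_unseen(single, X))

  null_m <- structure(list(W = matrix(0, 3, 2), c = c(0, 0)), class = "mtl_model")
  expect_equal(predict_unseen(null_m, X)$labels, rep(-1L, 5))  # 0.5 tie -> -1
  neg <- structure(list(W = matrix(0, 3, 2), c = c(-1, -1)), class = "mtl_model")
  expect_equal(predict_unseen(neg, X)$labels, rep(-1L, 5))
  pos <- structure(list(W = matrix(0, 3, 2), c = c(2, 2)), class = "mtl_model")
  expect_equal(predict_unseen(pos, X)$labels, rep(1L, 5))
})

test_that("rho selection is deterministic and avoids degenerate candidates", {
  tasks <- make_shared_tasks(n_tasks = 4L, n = 30L, p = 10L, support = 1:2,
                             signal = 3, seed = 15)
  expect_equal(select_rho(tasks, 7), 7)
  r1 <- select_rho(tasks, c(0.5, 2, 1e6))
  r2 <- select_rho(tasks, c(0.5, 2, 1e6))
  expect_identical(r1, r2)
  expect_lt(r1, 1e6)     # the chance-level candidate cannot win
  expect_error(select_rho(tasks[1:2], c(1, 2)), "3 tasks")
})
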