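test_that("subject covariances are symmetric, normalized, and see planted structure", {
  white <- toy_epochs(n_ep = 30L, n_ch = 5L, n_s = 500L, sfreq = 250)
  cv <- subject_class_covariances(white)
  corr <- stats::cov2cor(cv$pooled)
  expect_lt(max(abs(corr[upper.tri(corr)])), 0.1)
  expect_equal(cv$C1, t(cv$C1))

  pair <- toy_epochs(n_ep = 20L, n_ch = 4L, n_s = 400L, sfreq = 200)
  pair$data[, 2, ] <- pair$data[, 1, ] + 0.1 * pair$data[, 2, ]
  cp <- stats::cov2cor(subject_class_covariances(pair)$pooled)
  off <- abs(cp[upper.tri(cp)])
  expect_equal(which.max(off), 1L)          # the (1,2) entry dominates
  expect_gt(max(off), 0.9)

  dup <- white
  dup$data <- dup$data[rep(1:30, 2), , ]
  dup$labels <- rep(white$labels, 2)
  expect_equal(subject_class_covariances(dup)$pooled, cv$pooled,
               tolerance = 1e-12)
  solo <- white; solo$labels <- rep(1L, 30)
  expect_error(subject_class_covariances(solo), "classes")
})

test_that("generic covariance implements the inverse-Frobenius weighting", {
  mk <- function(C1, C2, pooled) list(C1 = C1, C2 = C2, pooled = pooled)
  A <- diag(2); B <- matrix(c(2, 0.5, 0.5, 1), 2)
  # pooled distances to the test subject: 1 and 4 -> weights 1 and 0.25
  test_cov <- mk(A, A, diag(2))
  tr1 <- mk(A, B, diag(2) + matrix(c(1, 0, 0, 0), 2))
  tr2 <- mk(B, A, diag(2) + matrix(c(0, 0, 0, 2), 2))
  g <- generic_covariance(list(tr1, tr2), test_cov)
  expect_equal(g$distances, c(1, 4))
  expect_equal(g$weights, c(1, 0.25))
  expect_equal(g$G1, (1 * A + 0.25 * B) / 2)
  expect_equal(g$G2, (1 * B + 0.25 * A) / 2)

  # single training subject at unit distance reproduces its covariance
  g1 <- generic_covariance(list(tr1), test_cov)
  expect_equal(g1$G1, A)

  # order invariance
  g_rev <- generic_covariance(list(tr2, tr1), test_cov)
  expect_equal(g$G1, g_rev$G1)

  # identical matrices -> capped weight, G proportional to the shared matrix
  expect_message(g0 <- generic_covariance(list(mk(B, B, diag(2))),
                                          mk(A, A, diag(2) * 1)), "capped")
  expect_equal(g0$G1 / g0$G1[1, 1], B / B[1, 1])

  # square-root variant
  gs <- generic_covariance(list(tr1, tr2), test_cov, squared = FALSE)
  expect_equal(gs$weights, c(1, 0.5))
})

test_that("regularized CSP reduces to CSP at (0,0) and degenerates as expected", {
  x <- toy_epochs(n_ep = 20L, n_ch = 6L, n_s = 300L, sfreq = 150,
                  fill = function(e, ch, t) stats::rnorm(length(t), sd = ch / 3))
  cv <- subject_class_covariances(x)
  other <- toy_epochs(n_ep = 20L, n_ch = 6L, n_s = 300L, sfreq = 150, seed = 3)
  gen <- generic_covariance(list(subject_class_covariances(other)), cv)

  plain <- fit_csp(x, n_components = 4L)
  reg0 <- fit_regcsp(cv, gen, regcsp_params(0, 0), 4L)
  expect_equal(reg0$filters, plain$filters, tolerance = 1e-9)
  expect_equal(reg0$eigenvalues, plain$eigenvalues, tolerance = 1e-12)

  # beta = 1: only the generic pool matters
  cv_b <- cv; cv_b$C1 <- cv$C1 * 3 + diag(6) * 0.1
  r1 <- fit_regcsp(cv, gen, regcsp_params(1, 0), 4L)
  r2 <- fit_regcsp(cv_b, gen, regcsp_params(1, 0), 4L)
  expect_equal(r1$filters, r2$filters)

  # gamma = 1 with plus sign: flat spectrum at 1/2
  rI <- fit_regcsp(cv, gen, regcsp_params(0, 1), 4L)
  expect_equal(rI$eigenvalues, rep(0.5, 4), tolerance = 1e-9)

  # joint rescaling of both covariances leaves filters invariant
  cv_s <- lapply(cv[1:3], function(m) m * 7); cv_s$subject_id <- 1L
  gen_s <- gen; gen_s$G1 <- gen$G1 * 7; gen_s$G2 <- gen$G2 * 7
  rs <- fit_regcsp(cv_s, gen_s, regcsp_params(0.3, 0.2), 4L)
  rb <- fit_regcsp(cv, gen, regcsp_params(0.3, 0.2), 4L)
  expect_equal(abs(rs$filters / rb$filters), matrix(1 / sqrt(7), 6, 4),
               tolerance = 1e-8)

  # subtractive identity sign floors an indefinite denominator
  expect_message(fit_regcsp(cv, gen, regcsp_params(0, 0.9, identity_sign = "minus"), 4L),
                 "floor")
})

test_that("the tuning grid argmax breaks ties toward small (beta, gamma)", {
  grid <- seq(0, 1, 0.5)
  acc <- matrix(0.6, 3, 3)
  expect_equal(crossmi:::grid_argmax(acc, grid), c(beta = 0, gamma = 0))
  acc[2, 1] <- 0.9
  expect_equal(crossmi:::grid_argmax(acc, grid), c(beta = 0.5, gamma = 0))
  acc[1, 3] <- 0.9   # tie between (0.5, 0) and (0, 1): smaller sum wins
  expect_equal(crossmi:::grid_argmax(acc, grid), c(beta = 0.5, gamma = 0))
})

test_that("tuning returns on-grid parameters and pooling helps under jitter", {
  pool <- cached_pool("jitter", function()
    simulate_pool(tiny_cfg(seed = 41, n_subjects = 6L, n_channels = 8L,
                           n_epochs_per_condition = 12L,
                           pattern_jitter = 1.5, n_low_quality = 0L),
                  conditions = "MI"))
  sets <- lapply(pool$subjects, `[[`, "MI")
  params <- tune_regcsp(sets, grid_step = 0.5, n_components = 4L)
  expect_true(params$beta %in% seq(0, 1, 0.5))
  expect_true(params$gamma %in% seq(0, 1, 0.5))
  expect_error(tune_regcsp(sets[1:2], 0.5, 4L), "at least 4")

  # under strong pattern jitter the similarity-weighted pool is sometimes
  # preferred; tuning must be able to leave the (0, 0) corner (beta is only
  # a second-order reweighting here because both covariance terms pool the
  # same training subjects, so it is not selected on every draw)
  betas <- vapply(1:10, function(i) {
    p <- simulate_pool(tiny_cfg(seed = 500L + i, n_subjects = 8L,
                                n_channels = 8L, sfreq = 200,
                                n_epochs_per_condition = 20L,
                                pattern_jitter = 1.2, n_low_quality = 0L),
                       conditions = "MI")
    tune_regcsp(lapply(p$subjects, `[[`, "MI"), 0.5, 4L)$beta
  }, numeric(1))
  expect_gt(sum(betas > 0), 0)
})
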