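test_that("one standardized feature with y = 2x is fitted exactly at a = 1", {
  set.seed(4)
  x <- scale(rnorm(30))
  X <- matrix(x, ncol = 1)
  y <- 2 * drop(x)
  m <- pma_fit(X, y, 1)
  fitted <- drop(m$scores %*% m$coeffs) + m$y_mean
  expect_lt(max(abs(fitted - y)), 1e-12)
})

test_that("fit matches the loop-level transcription on the integer example", {
  X <- matrix(c(1, 2, 0,
                0, 1, 1,
                2, 0, 1,
                1, 1, 2), 4, 3, byrow = TRUE)
  y <- c(1, 2, 3, 4)
  m <- pma_fit(X, y, 2)
  # frozen from the loop oracle (also recomputed here)
  expect_equal(m$scores[, 1],
               c(-0.801783725737273, 0.267261241912424,
                 1.33630620956212, 1.33630620956212), tolerance = 1e-12)
  expect_equal(m$loadings[1, ],
               c(0.748331477354788, 0, 0.997775303139718), tolerance = 1e-12)
  expect_equal(m$coeffs[1], 0.873053390247253, tolerance = 1e-12)
  expect_equal(m$coeffs[2], 0.313873059173948, tolerance = 1e-12)
  o <- pma_brute(X, y, 2)
  expect_equal(m$scores, o$S, tolerance = 1e-12)
  expect_equal(m$loadings, o$P, tolerance = 1e-12)
  expect_equal(m$coeffs, o$q, tolerance = 1e-12)
})

test_that("fit reproduces the loop oracle and NIPALS PLS1 on random data", {
  set.seed(11)
  for (rep in 1:3) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    y <- rnorm(20)
    a <- 5
    m <- pma_fit(X, y, a)
    o <- pma_brute(X, y, a)
    rel <- function(d, s) max(abs(d)) / max(abs(s))
    expect_lt(rel(m$scores - o$S, o$S), 1e-10)
    expect_lt(rel(m$loadings - o$P, o$P), 1e-10)
    expect_lt(rel(m$coeffs - o$q, o$q), 1e-10)
    # training predictions coincide with the textbook NIPALS PLS1
    ref <- nipals_pls1(X, y, a)
    fitted <- drop(m$scores %*% m$coeffs) + m$y_mean
    expect_lt(max(abs(fitted - ref$fitted)), 1e-10)
    # score orthogonality
    G <- crossprod(m$scores)
    offdiag <- G - diag(diag(G))
    expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
    # undeflated-y coefficient equals the deflated-y variant under
    # orthogonality
    yn <- y - mean(y)
    for (n in seq_len(a)) {
      s <- m$scores[, n]
      expect_equal(m$coeffs[n], sum(yn * s) / sum(s^2), tolerance = 1e-8)
      yn <- yn - m$coeffs[n] * s
    }
  }
})

test_that("exact-rank reconstruction and monotone deflation residual", {
  set.seed(21)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  a <- 8  # = rank(X)
  m <- pma_fit(X, y, a)
  recon <- Reduce(`+`, lapply(seq_len(a), function(n)
    tcrossprod(m$scores[, n], m$loadings[n, ])))
  expect_lt(norm(X - recon, "F"), 1e-8)
  resid <- vapply(seq_len(a), function(n) {
    norm(X - Reduce(`+`, lapply(seq_len(n), function(u)
      tcrossprod(m$scores[, u], m$loadings[u, ]))), "F")
  }, numeric(1))
  expect_true(all(diff(resid) < 1e-10))
})

test_that("rank exhaustion raises an informative error", {
  X <- cbind(scale(rnorm(10)))
  y <- 2 * drop(X)
  expect_error(pma_fit(X, y, 3), "rank exhausted")
  expect_error(pma_fit(X, 0 * y, 1), "rank exhausted")
})

test_that("prediction closed forms and projection-rule discrepancy", {
  set.seed(31)
  X <- matrix(rnorm(20 * 8), 20, 8)
  y <- rnorm(20)
  m <- pma_fit(X, y, 3)
  # the zero row (the mean motion) predicts the training mean
  expect_equal(predict(m, matrix(0, 1, 8)), m$y_mean)
  # single-component model, X_new = t * p1: yhat = intercept + q1 t ||p1||^2
  m1 <- pma_fit(X, y, 1)
  t0 <- 1.7
  expect_equal(predict(m1, matrix(t0 * m1$loadings[1, ], 1)),
               m1$y_mean + m1$coeffs[1] * t0 * sum(m1$loadings[1, ]^2),
               tolerance = 1e-10)
  # on the training data the two projection rules differ in general:
  # the direct loading projection is NOT the training-score recursion
  m8 <- pma_fit(X, y, 8)
  yh_paper <- predict(m8, X, projection = "paper")
  yh_rot <- predict(m8, X, projection = "pls_rotation")
  yh_train <- drop(m8$scores %*% m8$coeffs) + m8$y_mean
  expect_lt(max(abs(yh_rot - yh_train)), 1e-8)
  expect_gt(max(abs(yh_paper - yh_train)), 1e-6)
  expect_error(predict(m8, matrix(0, 2, 7)), "columns")
})

test_that("noiseless latent data is recovered exactly at a = n_factors", {
  d <- make_latent_dataset(latent_spec(n_samples = 150, noise_sd = 0,
                                       x_noise_sd = 0, seed = 7))
  Xs <- scale(d$X)
  Xs[, apply(d$X, 2, sd) < 1e-12] <- 0
  m <- pma_fit(Xs, d$y, 3)
  fitted <- drop(m$scores %*% m$coeffs) + m$y_mean
  expect_lt(max(abs(fitted - d$y)), 1e-8)
  # held-out prediction via weight rotation is exact too
  cv <- pma_cross_validate(d$X, d$y, a_max = 3, seed = 5,
                           projection = "pls_rotation")
  expect_lt(cv$table$rmse_mean[3], 1e-8)
})

test_that("cross-validation separates signal from noise", {
  set.seed(17)
  # pure-noise response: held-out correlation is small, RMSE near sd(y)
  d <- make_latent_dataset(latent_spec(n_samples = 200, seed = 3))
  y_noise <- rnorm(200)
  cv <- pma_cross_validate(d$X, y_noise, a_max = 3, folds = 5, repeats = 4,
                           seed = 23)
  expect_lt(max(abs(cv$table$r_mean)), 0.2)
  expect_lt(abs(cv$table$rmse_mean[1] - sd(y_noise)), 0.15 * sd(y_noise))
  expect_error(pma_cross_validate(d$X[1:4, ], y_noise[1:4], folds = 5),
               "fewer samples than folds")
})

test_that("cross-validation is reproducible and fold-partitioned", {
  d <- make_latent_dataset(latent_spec(n_samples = 100, seed = 9))
  cv1 <- pma_cross_validate(d$X, d$y, a_max = 2, repeats = 2, seed = 77)
  cv2 <- pma_cross_validate(d$X, d$y, a_max = 2, repeats = 2, seed = 77)
  expect_identical(cv1$table, cv2$table)
  for (f in cv1$fold_assignments) {
    expect_equal(length(f), 100L)
    expect_equal(sort(unique(f)), 1:5)
  }
  # grouped folds never split a group
  groups <- rep(1:10, each = 10)
  cvg <- pma_cross_validate(d$X, d$y, a_max = 2, repeats = 2, seed = 7,
                            groups = groups)
  for (f in cvg$fold_assignments)
    expect_true(all(tapply(f, groups, function(z) length(unique(z))) == 1))
})

test_that("component contributions are ordered on paper-like latent data", {
  # factor-response covariance decreasing by construction; the component
  # contributions |q_n| sd(s_n) inherit the ordering
  for (s in c(101, 202, 303)) {
    d <- make_latent_dataset(latent_spec(seed = s))
    m <- pma_fit(.safe_zscore_for_test(d$X), d$y, 3)
    contrib <- abs(m$coeffs) * apply(m$scores, 2, sd)
    expect_true(all(diff(contrib) < 0))
  }
})

test_that("regression_equation reports q with intercept", {
  set.seed(41)
  X <- matrix(rnorm(30 * 6), 30)
  y <- rnorm(30)
  m <- pma_fit(X, y, 1)
  q <- regression_equation(m)
  expect_named(q, "q1")
  s1 <- m$scores[, 1]
  expect_equal(unname(q[1]), sum((y - mean(y)) * s1) / sum(s1^2))
  expect_equal(attr(q, "intercept"), mean(y))
})

test_that("model YAML serialisation round-trips predictions", {
  set.seed(51)
  X <- matrix(rnorm(40 * 6), 40)
  st <- list(mean = colMeans(X), sd = apply(X, 2, sd))
  Xs <- sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
  m <- pma_fit(Xs, rnorm(40), 2, feature_stats = st)
  path <- file.path(withr::local_tempdir(), "m.yaml")
  write_pma_model(m, path)
  back <- read_pma_model(path)
  Xnew <- matrix(rnorm(12), 2)
  expect_equal(predict(back, Xnew, standardize = TRUE),
               predict(m, Xnew, standardize = TRUE), tolerance = 1e-6)
})
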