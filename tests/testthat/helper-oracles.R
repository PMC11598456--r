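# Independent oracles used across the suite. These deliberately avoid the
# package's vectorised code paths: the PMA transcription is written with
# explicit element loops, and the PLS1 reference follows the textbook
# NIPALS recursion.

# literal loop transcription of the score/loading/coefficient recursion
# (centred response, undeflated-y coefficient)
pma_brute <- function(X, y, a) {
  k <- nrow(X); p <- ncol(X)
  ym <- sum(y) / k
  yc <- y - ym
  Xn <- X; yn <- yc
  S <- matrix(0, k, a); P <- matrix(0, a, p); q <- numeric(a)
  for (n in 1:a) {
    v <- numeric(p)
    for (j in 1:p) for (i in 1:k) v[j] <- v[j] + Xn[i, j] * yn[i]
    nv <- sqrt(sum(v^2))
    s <- numeric(k)
    for (i in 1:k) for (j in 1:p) s[i] <- s[i] + Xn[i, j] * v[j] / nv
    ss <- sum(s^2)
    pn <- numeric(p)
    for (j in 1:p) pn[j] <- sum(Xn[, j] * s) / ss
    qn <- sum(yc * s) / ss
    S[, n] <- s; P[n, ] <- pn; q[n] <- qn
    for (i in 1:k) for (j in 1:p) Xn[i, j] <- Xn[i, j] - s[i] * pn[j]
    yn <- yn - qn * s
  }
  list(S = S, P = P, q = q, y_mean = ym, X_residual = Xn)
}

# textbook NIPALS PLS1 (unit weight vector, X-deflation only) with the
# standard weight-rotation prediction
nipals_pls1 <- function(X, y, a) {
  yc <- y - mean(y)
  Xn <- X
  W <- P <- matrix(0, ncol(X), a)
  Tm <- matrix(0, nrow(X), a)
  q <- numeric(a)
  for (n in 1:a) {
    w <- drop(crossprod(Xn, yc))
    w <- w / sqrt(sum(w^2))
    t <- drop(Xn %*% w)
    p <- drop(crossprod(Xn, t)) / sum(t^2)
    q[n] <- sum(yc * t) / sum(t^2)
    W[, n] <- w; P[, n] <- p; Tm[, n] <- t
    Xn <- Xn - tcrossprod(t, p)
  }
  fitted <- drop(Tm %*% q) + mean(y)
  beta <- W %*% solve(t(P) %*% W) %*% q
  list(W = W, P = P, scores = Tm, q = q, fitted = fitted,
       predict = function(Xnew) drop(Xnew %*% beta) + mean(y))
}

# shared default walker fixture, built once per test run
.fixture_env <- new.env(parent = emptyenv())

default_walker <- function() {
  if (is.null(.fixture_env$walker))
    .fixture_env$walker <- make_walker(walker_spec())
  .fixture_env$walker
}

default_walker_analysis <- function() {
  if (is.null(.fixture_env$analysis))
    .fixture_env$analysis <- analyse_trial(default_walker()$trial)
  .fixture_env$analysis
}

rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0),
                           c(0, 0, 1))

# column z-score with a guard for constant columns
.safe_zscore_for_test <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv < 1e-12] <- 1
  sweep(sweep(X, 2, mu), 2, sdv, "/")
}

# rotate a whole trial rigidly about the vertical axis
rotate_trial <- function(trial, angle) {
  R <- rot_z(angle)
  trial$markers <- lapply(trial$markers, function(m) m %*% t(R))
  trial
}
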