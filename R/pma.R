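#' Fit a supervised principal motion analysis model
#'
#' Decomposes a standardized feature matrix `X` (rows = steps, columns =
#' time-normalised velocity samples) into `a` orthogonal-score components
#' ("principal motions") chosen to maximise the covariance between their
#' scores and the response, exactly as in PLS1 regression. Iterating
#' n = 1..a on the deflated matrices:
#' \deqn{s_n = X_n X_n^T y_n / ||X_n^T y_n||}
#' \deqn{p_n = X_n^T s_n / (s_n^T s_n), \quad q_n = y^T s_n / (s_n^T s_n)}
#' \deqn{X_{n+1} = X_n - s_n p_n^T, \quad y_{n+1} = y_n - q_n s_n}
#' The coefficient `q_n` uses the undeflated response; under exact score
#' orthogonality this equals the deflated-response variant. The response is
#' centred internally and its training mean stored as the model intercept
#' (scores of column-centred data have zero mean, so the component sum can
#' only reproduce the centred response).
#'
#' @param X k x p numeric matrix, columns standardized (see
#'   [assemble_features()]).
#' @param y Length-k numeric response (critical MoS values, m).
#' @param a Number of principal motions, >= 1 and <= rank(X).
#' @param feature_stats Optional standardisation statistics to carry along
#'   for later prediction (taken from `attr(X, "stats")` when present).
#' @return Object of class `pma_model` with elements `a`, `weights` (a x p),
#'   `loadings` (a x p), `coeffs` (length a), `scores` (k x a), `y_mean`,
#'   `y_kind`, `feature_stats`.
#' @param y_kind Label for the response (`"mediolateral"`, `"anterior"`, ...).
#' @export
pma_fit <- function(X, y, a, y_kind = "response", feature_stats = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  k <- nrow(X); p <- ncol(X)
  if (length(y) != k) stop("length(y) must match nrow(X)")
  if (a < 1L) stop("`a` must be at least 1")
  if (is.null(feature_stats)) feature_stats <- attr(X, "stats")
  y_mean <- mean(y)
  yc <- y - y_mean
  Xn <- X; yn <- yc
  W <- P <- matrix(0, a, p)
  S <- matrix(0, k, a)
  q <- numeric(a)
  for (n in seq_len(a)) {
    w <- drop(crossprod(Xn, yn))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(Xn^2))))
      stop("rank exhausted: no covariance left after ", n - 1L,
           " principal motions (requested a = ", a, ")")
    w <- w / nw
    s <- drop(Xn %*% w)
    ss <- sum(s^2)
    pn <- drop(crossprod(Xn, s)) / ss
    qn <- sum(yc * s) / ss
    W[n, ] <- w; P[n, ] <- pn; q[n] <- qn; S[, n] <- s
    Xn <- Xn - tcrossprod(s, pn)
    yn <- yn - qn * s
  }
  structure(list(a = a, weights = W, loadings = P, coeffs = q, scores = S,
                 y_mean = y_mean, y_kind = y_kind,
                 feature_stats = feature_stats),
            class = "pma_model")
}

#' @export
print.pma_model <- function(x, ...) {
  cat(sprintf("<pma_model (%s): a = %d, %d features>\n", x$y_kind, x$a,
              ncol(x$loadings)))
  cat("  coefficients q:", paste(signif(x$coeffs, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Predict critical MoS values from a fitted PMA model
#'
#' Two test-score rules are available. `"paper"` projects the (undeflated)
#' standardized test data directly onto the loadings,
#' `s_n = X_new p_n`, and sums `q_n s_n`; this is the literal published
#' rule. `"pls_rotation"` uses the standard PLS1 weight rotation
#' `R = W^T (P W^T)^{-1}`, which reproduces the training-score recursion
#' exactly and is exact on noiseless full-rank data. The two differ in
#' general because loadings are not mutually orthogonal. The stored
#' training mean of the response is added back.
#'
#' @param object A `pma_model`.
#' @param newdata m x p matrix standardized with the model's feature
#'   statistics (done automatically when `standardize = TRUE` and the model
#'   carries statistics).
#' @param a Number of components to use (default: all fitted).
#' @param projection `"paper"` or `"pls_rotation"`.
#' @param standardize Apply the stored feature statistics to `newdata`.
#' @param ... Unused.
#' @return Numeric vector of predictions (same units as the training
#'   response).
#' @export
predict.pma_model <- function(object, newdata, a = object$a,
                              projection = c("paper", "pls_rotation"),
                              standardize = FALSE, ...) {
  projection <- match.arg(projection)
  X <- as.matrix(newdata)
  if (ncol(X) != ncol(object$loadings))
    stop("newdata has ", ncol(X), " columns; model expects ",
         ncol(object$loadings))
  if (a > object$a) stop("requested more components than fitted")
  if (standardize) {
    st <- object$feature_stats
    if (is.null(st)) stop("model carries no feature statistics")
    X <- sweep(sweep(X, 2, st$mean), 2, st$sd, "/")
  }
  idx <- seq_len(a)
  if (projection == "paper") {
    S_new <- X %*% t(object$loadings[idx, , drop = FALSE])
  } else {
    W <- t(object$weights[idx, , drop = FALSE])   # p x a
    P <- object$loadings[idx, , drop = FALSE]     # a x p
    S_new <- X %*% W %*% solve(P %*% W)
  }
  drop(S_new %*% object$coeffs[idx]) + object$y_mean
}

#' Reported regression equation of a fitted model
#'
#' Returns the score coefficients `q_1 .. q_a` (the printed linear model
#' `mos-hat = q_1 s_1 + ... + q_a s_a`, plus the intercept) for reporting.
#'
#' @param model A `pma_model`.
#' @return Named numeric vector `q1 ... qa` with attribute `intercept`.
#' @export
regression_equation <- function(model) {
  q <- model$coeffs
  names(q) <- paste0("q", seq_along(q))
  attr(q, "intercept") <- model$y_mean
  q
}

#' Cross-validated selection of the number of principal motions
#'
#' Repeated k-fold cross-validation: per repeat the samples (steps) are
#' randomly partitioned; per fold the feature columns are standardized with
#' training-fold statistics (set `standardize = "global"` for the variant
#' that standardizes once on all samples before splitting, which leaks test
#' information and is provided for comparison only), a model with `a_max`
#' components is fitted on the training folds and every prefix a = 1..a_max
#' is evaluated on the held-out fold. Per repeat and per `a`, the Pearson
#' correlation between pooled held-out predictions and observations is
#' computed, and the RMSE is pooled over all held-out samples; both are
#' then averaged over repeats. The selected `a` is the smallest whose mean
#' pooled RMSE is within `rmse_tol` (relative) of the minimum.
#'
#' @param X k x p raw (unstandardized) feature matrix.
#' @param y Length-k response (m).
#' @param a_max Largest number of components to consider.
#' @param folds Number of CV folds.
#' @param repeats Number of random re-partitions.
#' @param seed Integer seed controlling the partitions.
#' @param projection Passed to [predict.pma_model()].
#' @param standardize `"fold"` (training statistics, default), `"global"`
#'   (leaky pre-CV z-scoring) or `"none"`.
#' @param rmse_tol Relative tolerance for the parsimony tie-break.
#' @param groups Optional grouping factor (e.g. subject); folds are drawn
#'   over groups so no group straddles folds.
#' @return Object of class `pma_cv`: data frame `table` (per `a`: `r_mean`,
#'   `r_sd`, `rmse_mean` in the response units and `rmse_cm`), `chosen_a`,
#'   `a_max` actually evaluated, `folds`, `repeats`, `seed`.
#' @export
pma_cross_validate <- function(X, y, a_max = 5L, folds = 5L, repeats = 5L,
                               seed = 1L,
                               projection = c("paper", "pls_rotation"),
                               standardize = c("fold", "global", "none"),
                               rmse_tol = 0.01, groups = NULL) {
  projection <- match.arg(projection)
  standardize <- match.arg(standardize)
  X <- as.matrix(X); y <- as.numeric(y)
  k <- nrow(X)
  if (k < folds) stop("fewer samples than folds")
  if (standardize == "global") X <- .safe_zscore(X)
  units <- if (is.null(groups)) seq_len(k) else unique(groups)
  if (length(units) < folds) stop("fewer groups than folds")
  set.seed(seed)
  preds <- array(NA_real_, dim = c(repeats, a_max, k))
  a_eff <- a_max
  assignments <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of_unit <- sample(rep_len(seq_len(folds), length(units)))
    fold_id <- if (is.null(groups)) fold_of_unit
               else fold_of_unit[match(groups, units)]
    assignments[[r]] <- fold_id
    for (f in seq_len(folds)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      if (length(test) < 2L || length(train) < 2L)
        stop("fold with fewer than 2 samples")
      if (standardize == "fold") {
        st <- .column_stats(X[train, , drop = FALSE])
        Xtr <- .apply_stats(X[train, , drop = FALSE], st)
        Xte <- .apply_stats(X[test, , drop = FALSE], st)
      } else {
        Xtr <- X[train, , drop = FALSE]
        Xte <- X[test, , drop = FALSE]
      }
      a_fit <- a_max
      model <- NULL
      while (is.null(model) && a_fit >= 1L) {
        model <- tryCatch(pma_fit(Xtr, y[train], a_fit),
                          error = function(e) NULL)
        if (is.null(model)) a_fit <- a_fit - 1L
      }
      if (is.null(model)) stop("PMA fit failed even with a = 1")
      a_eff <- min(a_eff, a_fit)
      for (a in seq_len(a_fit))
        preds[r, a, test] <- predict(model, Xte, a = a,
                                     projection = projection)
    }
  }
  if (a_eff < a_max)
    warning("rank exhausted: evaluating a = 1..", a_eff, " instead of ", a_max)
  tab <- do.call(rbind, lapply(seq_len(a_eff), function(a) {
    rs <- vapply(seq_len(repeats), function(r)
      stats::cor(preds[r, a, ], y), numeric(1))
    rmses <- vapply(seq_len(repeats), function(r)
      sqrt(mean((preds[r, a, ] - y)^2)), numeric(1))
    data.frame(a = a, r_mean = mean(rs), r_sd = stats::sd(rs),
               rmse_mean = mean(rmses), rmse_cm = 100 * mean(rmses))
  }))
  best <- min(tab$rmse_mean)
  chosen <- tab$a[tab$rmse_mean <= best * (1 + rmse_tol)][1]
  structure(list(table = tab, chosen_a = chosen, a_max = a_eff,
                 folds = folds, repeats = repeats, seed = seed,
                 projection = projection, standardize = standardize,
                 fold_assignments = assignments),
            class = "pma_cv")
}

#' @export
print.pma_cv <- function(x, ...) {
  cat(sprintf("<pma_cv: %d-fold x %d repeats, chosen a = %d>\n",
              x$folds, x$repeats, x$chosen_a))
  print(x$table, row.names = FALSE)
  invisible(x)
}

.column_stats <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1        # guard degenerate columns inside CV
  list(mean = mu, sd = sdv)
}

.apply_stats <- function(X, st) sweep(sweep(X, 2, st$mean), 2, st$sd, "/")

.safe_zscore <- function(X) .apply_stats(X, .column_stats(X))

#' Serialise a fitted PMA model to a flat YAML file
#'
#' Stores loadings, weights, coefficients, intercept and feature
#' statistics as plain lists so the model can be reloaded without R
#' serialisation.
#'
#' @param model A `pma_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pma_model <- function(model, path) {
  obj <- list(a = model$a, y_kind = model$y_kind, y_mean = model$y_mean,
              coeffs = as.numeric(model$coeffs),
              weights = apply(model$weights, 1, as.numeric, simplify = FALSE),
              loadings = apply(model$loadings, 1, as.numeric, simplify = FALSE),
              feature_stats = if (is.null(model$feature_stats)) NULL else
                list(mean = as.numeric(model$feature_stats$mean),
                     sd = as.numeric(model$feature_stats$sd)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Load a PMA model written by [write_pma_model()]
#' @param path File path.
#' @return A `pma_model` (without training scores).
#' @export
read_pma_model <- function(path) {
  obj <- yaml::read_yaml(path)
  structure(list(a = obj$a, y_kind = obj$y_kind, y_mean = obj$y_mean,
                 coeffs = as.numeric(obj$coeffs),
                 weights = do.call(rbind, lapply(obj$weights, as.numeric)),
                 loadings = do.call(rbind, lapply(obj$loadings, as.numeric)),
                 scores = NULL,
                 feature_stats = if (is.null(obj$feature_stats)) NULL else
                   list(mean = as.numeric(obj$feature_stats$mean),
                        sd = as.numeric(obj$feature_stats$sd))),
            class = "pma_model")
}
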