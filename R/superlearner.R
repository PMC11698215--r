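#' Super Learner controls
#'
#' Fixes the learner library, the number of cross-validation folds, the
#' seed for stochastic learners and fold assignment, and the probability
#' clipping bounds. Learner hyperparameters are versioned here rather than
#' tuned: CART with minimum leaf 20, random forests with 500 trees, a
#' single-hidden-layer neural network with 8 units.
#'
#' @param library character vector from `mean`, `linear`, `logistic`,
#'   `cart`, `random_forest`, `neural_net`.
#' @param folds cross-validation folds (default 2).
#' @param seed integer seed for fold assignment and stochastic learners.
#' @param clip predictions are clipped to `[clip, 1 - clip]`.
#' @return list of class `"sl_control"`.
#' @export
sl_control <- function(library = c("mean", "linear", "logistic", "cart",
                                   "random_forest", "neural_net"),
                       folds = 2, seed = 1, clip = 1e-6) {
  known <- c("mean", "linear", "logistic", "cart", "random_forest",
             "neural_net")
  bad <- setdiff(library, known)
  if (length(bad))
    stop("unknown learner(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(library = library, folds = folds, seed = seed, clip = clip),
            class = "sl_control")
}

#' Balanced cross-validation fold assignment
#'
#' @param n number of observations.
#' @param k number of folds.
#' @param seed integer seed; the same seed reproduces the same labels.
#' @return integer fold labels in `1..k`, balanced to within one.
#' @export
assign_folds <- function(n, k = 2, seed = 1) {
  if (n < k) stop("need at least as many observations as folds",
                  call. = FALSE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample(rep_len(seq_len(k), n))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

clip_prob <- function(p, clip) pmin(pmax(p, clip), 1 - clip)

# seed derived from the learner *name* (not its library position) so that
# permuting the library leaves stochastic learners unchanged
learner_seed <- function(ctl, name, fold = 0)
  (as.integer(ctl$seed) + 131L * sum(utf8ToInt(name)) + 7919L * fold) %%
    2147483647L

# each learner: fit(x, y, ctl, seed) -> function(newx) -> probabilities.
# y may be binary or a continuous pseudo-outcome in [0, 1] (iterated
# regressions); learners switch mode accordingly.
learner_fit <- function(name, x, y, ctl, seed) {
  binary <- all(y %in% c(0, 1))
  switch(name,
    mean = {
      m <- mean(y)
      function(newx) rep(m, nrow(newx))
    },
    linear = {
      fit <- stats::lm.fit(cbind(1, x), y)
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      function(newx) as.numeric(cbind(1, newx) %*% beta)
    },
    logistic = {
      beta <- fast_logit_fit(cbind(1, x), y)
      function(newx) stats::plogis(as.numeric(cbind(1, newx) %*% beta))
    },
    cart = {
      df <- as.data.frame(x)
      if (binary) {
        df$.y <- factor(y, levels = c(0, 1))
        fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                            control = rpart::rpart.control(minbucket = 20,
                                                           cp = 0.01))
        function(newx)
          as.numeric(predict(fit, as.data.frame(newx), type = "prob")[, 2])
      } else {
        df$.y <- y
        fit <- rpart::rpart(.y ~ ., data = df, method = "anova",
                            control = rpart::rpart.control(minbucket = 20,
                                                           cp = 0.01))
        function(newx) as.numeric(predict(fit, as.data.frame(newx)))
      }
    },
    random_forest = {
      df <- as.data.frame(x)
      if (binary) {
        df$.y <- factor(y, levels = c(0, 1))
        fit <- ranger::ranger(.y ~ ., data = df, num.trees = 500,
                              probability = TRUE, seed = seed,
                              num.threads = 1)
        function(newx)
          as.numeric(predict(fit, as.data.frame(newx),
                             num.threads = 1)$predictions[, "1"])
      } else {
        df$.y <- y
        fit <- ranger::ranger(.y ~ ., data = df, num.trees = 500,
                              seed = seed, num.threads = 1)
        function(newx)
          as.numeric(predict(fit, as.data.frame(newx),
                             num.threads = 1)$predictions)
      }
    },
    neural_net = {
      set.seed(seed)
      fit <- nnet::nnet(x, y, size = 8, decay = 0.01, maxit = 200,
                        entropy = TRUE, trace = FALSE)
      function(newx) as.numeric(predict(fit, newx))
    },
    stop("unknown learner: ", name, call. = FALSE))
}

# plain IRLS for Bernoulli/quasi-Bernoulli regression (y in [0, 1]); falls
# back to stats::glm.fit when the lean loop does not converge cleanly.
# Aliased columns get coefficient 0 through the ridge-free pivoting of
# qr.coef; a tiny ridge guards near-singular weighted designs.
fast_logit_fit <- function(X, y, maxit = 25, tol = 1e-9) {
  beta <- numeric(ncol(X))
  beta[1] <- stats::qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    A <- crossprod(X, X * w)
    diag(A) <- diag(A) + 1e-10
    beta_new <- tryCatch(
      as.numeric(solve(A, crossprod(X, w * eta + (y - mu)))),
      error = function(e) NULL)
    if (is.null(beta_new) || anyNA(beta_new) ||
        max(abs(beta_new)) > 1e4) {
      fit <- suppressWarnings(
        stats::glm.fit(X, y, family = stats::quasibinomial()))
      return(ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  beta
}

# mean negative Bernoulli log-likelihood; valid for y in [0, 1]
bernoulli_loss <- function(y, p, clip = 1e-6) {
  p <- clip_prob(p, clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Fit a cross-validated Super Learner ensemble
#'
#' Computes out-of-fold predictions for every learner in the library, finds
#' convex weights minimising the cross-validated negative Bernoulli
#' log-likelihood over the probability simplex (exponentiated-gradient
#' descent, with a final comparison against every vertex so the ensemble is
#' never worse than the best single learner), and refits each learner on the
#' full data for prediction. A learner that fails to fit gets weight 0 with
#' a warning; it never aborts the ensemble. A single-learner library skips
#' cross-validation and receives weight 1.
#'
#' @param x numeric matrix (or data frame) of features.
#' @param y outcomes: binary, or continuous in `[0, 1]` for iterated
#'   regressions.
#' @param control an [sl_control()].
#' @return object of class `"mono_sl"`: `weights`, `cv_loss` (per learner),
#'   `cv_ensemble_loss`, `folds`, and the fitted learner closures.
#' @export
fit_super_learner <- function(x, y, control = sl_control()) {
  x <- as.matrix(x)
  if (anyNA(y)) stop("missing labels are not allowed", call. = FALSE)
  lib <- control$library
  if (length(lib) < 1) stop("need at least one learner", call. = FALSE)
  fits <- vector("list", length(lib))
  ok <- logical(length(lib))
  for (j in seq_along(lib)) {
    res <- tryCatch(
      suppressWarnings(
        learner_fit(lib[j], x, y, control, learner_seed(control, lib[j]))),
      error = function(e) {
        warning("learner '", lib[j], "' failed to fit (", conditionMessage(e),
                "); weight forced to 0", call. = FALSE)
        NULL
      })
    ok[j] <- !is.null(res)
    if (ok[j]) fits[[j]] <- res
  }
  if (!any(ok)) stop("every learner failed to fit", call. = FALSE)

  if (length(lib) == 1 || sum(ok) == 1) {
    w <- as.numeric(ok)
    out <- list(library = lib, weights = w / sum(w),
                cv_loss = rep(NA_real_, length(lib)),
                cv_ensemble_loss = NA_real_, folds = NULL, fits = fits,
                control = control, p = ncol(x))
    class(out) <- "mono_sl"
    return(out)
  }

  folds <- assign_folds(length(y), control$folds, control$seed)
  P <- matrix(NA_real_, length(y), length(lib))
  for (j in which(ok)) {
    for (f in seq_len(control$folds)) {
      tr <- folds != f
      pf <- tryCatch(suppressWarnings({
        g <- learner_fit(lib[j], x[tr, , drop = FALSE], y[tr], control,
                         learner_seed(control, lib[j], f))
        g(x[!tr, , drop = FALSE])
      }), error = function(e) NULL)
      if (is.null(pf)) {
        ok[j] <- FALSE
        warning("learner '", lib[j],
                "' failed during cross-validation; weight forced to 0",
                call. = FALSE)
        break
      }
      P[!tr, j] <- pf
    }
  }
  P <- clip_prob(P, control$clip)
  cv_loss <- rep(NA_real_, length(lib))
  cv_loss[ok] <- apply(P[, ok, drop = FALSE], 2, bernoulli_loss, y = y,
                       clip = control$clip)
  w <- numeric(length(lib))
  w[ok] <- solve_simplex_weights(P[, ok, drop = FALSE], y, control$clip)
  out <- list(library = lib, weights = w, cv_loss = cv_loss,
              cv_ensemble_loss = bernoulli_loss(
                y, as.numeric(P[, ok, drop = FALSE] %*% w[ok]), control$clip),
              folds = folds, fits = fits, control = control, p = ncol(x))
  class(out) <- "mono_sl"
  out
}

# convex weights minimising CV negative log-likelihood: deterministic
# exponentiated-gradient descent from the uniform point, then a sweep over
# the simplex vertices so the solution is never worse than any single
# learner
solve_simplex_weights <- function(P, y, clip, iters = 2000, tol = 1e-12) {
  m <- ncol(P)
  if (m == 1) return(1)
  loss <- function(w) bernoulli_loss(y, as.numeric(P %*% w), clip)
  w <- rep(1 / m, m)
  best_w <- w
  best <- loss(w)
  for (it in seq_len(iters)) {
    q <- clip_prob(as.numeric(P %*% w), clip)
    g <- as.numeric(crossprod(P, (q - y) / (q * (1 - q)))) / length(y)
    g <- g - max(g)
    w_new <- w * exp(-g / max(1, sqrt(sum(g^2))))
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
    l <- loss(w)
    if (l < best) { best <- l; best_w <- w }
  }
  vertex_losses <- apply(P, 2, bernoulli_loss, y = y, clip = clip)
  if (min(vertex_losses) < best) {
    best_w <- as.numeric(seq_len(m) == which.min(vertex_losses))
  }
  best_w
}

#' Predict from a fitted Super Learner
#'
#' The convex weighted combination of the learners' full-data predictions,
#' clipped away from 0 and 1.
#'
#' @param fit a `"mono_sl"` object.
#' @param x feature matrix with the training schema.
#' @return probabilities in `(0, 1)`.
#' @export
predict_ensemble <- function(fit, x) {
  x <- as.matrix(x)
  if (ncol(x) != fit$p)
    stop("feature schema mismatch: expected ", fit$p, " columns, got ",
         ncol(x), call. = FALSE)
  pred <- numeric(nrow(x))
  for (j in seq_along(fit$library)) {
    if (fit$weights[j] > 0)
      pred <- pred + fit$weights[j] * fit$fits[[j]](x)
  }
  clip_prob(pred, fit$control$clip)
}

#' @export
predict.mono_sl <- function(object, newdata, ...) {
  predict_ensemble(object, newdata)
}

#' @export
print.mono_sl <- function(x, ...) {
  cat("<mono_sl>\n")
  print(data.frame(learner = x$library, weight = round(x$weights, 4),
                   cv_loss = round(x$cv_loss, 5)))
  invisible(x)
}
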