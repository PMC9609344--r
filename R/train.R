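# Network training: Levenberg-Marquardt (the algorithm the prosthesis
# uses) plus four comparison optimizers — BFGS quasi-Newton, Polak-Ribiere
# conjugate gradient, one-step secant, and gradient descent with momentum
# and adaptive learning rate. All share the early-stopping rule: training
# halts after `max_fail` validation-error increases since the best epoch,
# and the returned model is the best-validation snapshot.

#' Training hyperparameters
#'
#' @param algorithm one of `"lm"`, `"bfgs"`, `"cgp"`, `"oss"`, `"gdx"`.
#' @param max_epochs epoch budget (default 1000).
#' @param goal stop when training MSE falls below this (default 0: never).
#' @param mu0,mu_inc,mu_dec,mu_max Levenberg-Marquardt damping: initial
#'   value, factor on a rejected step, factor on an accepted step, abort
#'   ceiling. Defaults 1e-3 / 10 / 0.1 / 1e10.
#' @param lr0,lr_inc,lr_dec,momentum adaptive gradient descent (gdx):
#'   initial rate, growth on improvement, shrink on rejection (MSE rise
#'   > 4%), momentum term.
#' @param max_fail consecutive validation failures tolerated (default 6).
#' @return A `train_hyper` list.
#' @export
train_hyper <- function(algorithm = c("lm", "bfgs", "cgp", "oss", "gdx"),
                        max_epochs = 1000, goal = 0,
                        mu0 = 1e-3, mu_inc = 10, mu_dec = 0.1, mu_max = 1e10,
                        lr0 = 0.01, lr_inc = 1.05, lr_dec = 0.7,
                        momentum = 0.9, max_fail = 6) {
  algorithm <- match.arg(algorithm)
  stopifnot(mu_inc > 1, mu_dec < 1, mu_dec > 0, lr0 > 0, max_epochs >= 1)
  structure(list(algorithm = algorithm, max_epochs = max_epochs, goal = goal,
                 mu0 = mu0, mu_inc = mu_inc, mu_dec = mu_dec, mu_max = mu_max,
                 lr0 = lr0, lr_inc = lr_inc, lr_dec = lr_dec,
                 momentum = momentum, max_fail = max_fail),
            class = "train_hyper")
}

# Backtracking Armijo line search along direction d from theta.
# Returns list(theta, mse, alpha) or NULL when no decrease is found.
.line_search <- function(model, X, Z, theta, d, g, mse0, alpha0 = 1) {
  gd <- sum(g * d)
  if (!is.finite(gd) || gd >= 0) return(NULL)
  alpha <- alpha0
  for (i in 1:40) {
    th <- theta + alpha * d
    m <- mlp_mse(mlp_unpack(model, th), X, Z)
    if (is.finite(m) && m <= mse0 + 1e-4 * alpha * gd)
      return(list(theta = th, mse = m, alpha = alpha))
    alpha <- alpha / 2
  }
  NULL
}

#' Train a multilayer perceptron
#'
#' One epoch is one optimizer update (for LM, one accepted damped
#' Gauss-Newton step \eqn{(J^\top J + \mu I)\,\Delta = J^\top e}, with
#' \eqn{\mu} escalated by `mu_inc` while the proposed step raises the
#' training MSE and relaxed by `mu_dec` on acceptance). Stopping reasons:
#' MSE goal reached, epoch budget, `mu > mu_max` (LM), line-search failure
#' (quasi-Newton family), non-finite loss, or `max_fail` validation
#' failures since the best validation epoch. The returned model carries the
#' parameters of the best-validation epoch.
#'
#' @param model an [mlp_init()] model.
#' @param X,Z training inputs (n x d) and one-hot targets (n x K).
#' @param validation optional list(X, Z) monitored for early stopping.
#' @param test optional list(X, Z), tracked for the report only.
#' @param hyper a [train_hyper()] object.
#' @return list(model, report) where `report` is a `training_report` with
#'   per-epoch `curves`, `best_epoch`, `best_val_mse`, `stop_reason`.
#' @export
train_mlp <- function(model, X, Z, validation = NULL, test = NULL,
                      hyper = train_hyper()) {
  stopifnot(inherits(model, "mlp_model"), inherits(hyper, "train_hyper"))
  theta <- mlp_pack(model)
  n_par <- length(theta)
  mse_tr <- mlp_mse(model, X, Z)

  val_mse <- function(th) {
    if (is.null(validation)) return(NA_real_)
    mlp_mse(mlp_unpack(model, th), validation$X, validation$Z)
  }
  test_mse <- function(th) {
    if (is.null(test)) return(NA_real_)
    mlp_mse(mlp_unpack(model, th), test$X, test$Z)
  }

  curves <- data.frame(epoch = integer(), train_mse = numeric(),
                       val_mse = numeric(), test_mse = numeric())
  best_theta <- theta
  best_val <- val_mse(theta)
  best_epoch <- 0L
  fails <- 0L
  stop_reason <- "max_epochs"

  mu <- hyper$mu0
  lr <- hyper$lr0
  velocity <- numeric(n_par)
  Hinv <- diag(n_par)
  g_prev <- NULL; d_prev <- NULL; s_prev <- NULL
  alg <- hyper$algorithm

  for (epoch in seq_len(hyper$max_epochs)) {
    ok <- TRUE
    cur <- mlp_unpack(model, theta)
    if (alg == "lm") {
      jac <- mlp_jacobian(cur, X, Z)
      JtJ <- crossprod(jac$J)
      Jte <- crossprod(jac$J, jac$e)
      repeat {
        step <- tryCatch(
          solve(JtJ + mu * diag(n_par), -Jte),
          error = function(e) NULL)
        if (!is.null(step)) {
          th_try <- theta + as.vector(step)
          m_try <- mlp_mse(mlp_unpack(model, th_try), X, Z)
        } else m_try <- Inf
        if (is.finite(m_try) && m_try < mse_tr) {
          theta <- th_try; mse_tr <- m_try
          mu <- max(mu * hyper$mu_dec, 1e-20)
          break
        }
        mu <- mu * hyper$mu_inc
        if (mu > hyper$mu_max) { ok <- FALSE; stop_reason <- "mu_max"; break }
      }
    } else if (alg == "gdx") {
      g <- mlp_grad(cur, X, Z)
      v_try <- hyper$momentum * velocity - lr * g
      th_try <- theta + v_try
      m_try <- mlp_mse(mlp_unpack(model, th_try), X, Z)
      if (!is.finite(m_try)) { ok <- FALSE; stop_reason <- "non_finite_loss" }
      else if (m_try > mse_tr * 1.04) {
        lr <- lr * hyper$lr_dec               # rejected: shrink, reset momentum
        velocity <- numeric(n_par)
      } else {
        if (m_try < mse_tr) lr <- lr * hyper$lr_inc
        theta <- th_try; velocity <- v_try; mse_tr <- m_try
      }
    } else {
      g <- mlp_grad(cur, X, Z)
      d <- switch(alg,
        bfgs = -as.vector(Hinv %*% g),
        cgp = {
          if (is.null(g_prev) || (epoch %% n_par) == 0) -g
          else {
            beta <- max(0, sum(g * (g - g_prev)) / sum(g_prev^2))
            -g + beta * d_prev
          }
        },
        oss = {
          if (is.null(s_prev)) -g
          else {
            yv <- g - g_prev
            sy <- sum(s_prev * yv)
            if (abs(sy) < 1e-20) -g
            else {
              A <- -(1 + sum(yv^2) / sy) * (sum(s_prev * g) / sy) +
                sum(yv * g) / sy
              B <- sum(s_prev * g) / sy
              -g + A * s_prev + B * yv
            }
          }
        })
      ls <- .line_search(model, X, Z, theta, d, g, mse_tr)
      if (is.null(ls)) {                      # direction failed: restart steepest
        ls <- .line_search(model, X, Z, theta, -g, g, mse_tr)
        if (alg == "bfgs") Hinv <- diag(n_par)
      }
      if (is.null(ls)) { ok <- FALSE; stop_reason <- "line_search_failed" }
      else {
        s <- ls$theta - theta
        if (alg == "bfgs" && !is.null(g_prev) || alg == "bfgs") {
          g_new <- mlp_grad(mlp_unpack(model, ls$theta), X, Z)
          yv <- g_new - g
          sy <- sum(s * yv)
          if (sy > 1e-12) {
            rho <- 1 / sy
            I <- diag(n_par)
            V <- I - rho * outer(s, yv)
            Hinv <- V %*% Hinv %*% t(V) + rho * outer(s, s)
          }
          g_prev <- g
        } else {
          g_prev <- g
        }
        s_prev <- s; d_prev <- d
        theta <- ls$theta; mse_tr <- ls$mse
      }
    }

    vm <- val_mse(theta)
    curves <- rbind(curves, data.frame(
      epoch = epoch, train_mse = mse_tr, val_mse = vm,
      test_mse = test_mse(theta)))

    if (!is.na(vm)) {
      if (is.na(best_val) || vm < best_val) {
        best_val <- vm; best_theta <- theta; best_epoch <- epoch; fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= hyper$max_fail) { stop_reason <- "validation_stop"; break }
      }
    } else {
      best_theta <- theta; best_epoch <- epoch
    }
    if (!ok) break
    if (mse_tr <= hyper$goal) { stop_reason <- "goal"; break }
  }

  model <- mlp_unpack(model, best_theta)
  report <- structure(
    list(curves = curves, best_epoch = best_epoch, best_val_mse = best_val,
         final_train_mse = mse_tr, stop_reason = stop_reason,
         algorithm = alg),
    class = "training_report")
  list(model = model, report = report)
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(
    "<training_report> %s: %d epochs, best validation MSE %.6g at epoch %d (%s)\n",
    x$algorithm, nrow(x$curves), x$best_val_mse, x$best_epoch, x$stop_reason))
  invisible(x)
}

#' Train the gesture classifier on a feature dataset
#'
#' Standardizes features on the training split only, one-hot encodes the
#' labels, trains the 20-15-5 network and embeds the scaler in the returned
#' model so [predict.mlp_model()] can be fed raw feature vectors.
#'
#' @param fd a `feature_dataset` from [batch_extract()].
#' @param split index partition from [split_dataset()] (train/validation
#'   and optionally test).
#' @param hyper a [train_hyper()] object.
#' @param hidden hidden-layer width (default 15).
#' @param seed initialization seed.
#' @return list(model, report, split) with per-split accuracies attached to
#'   the report.
#' @export
train_gesture_classifier <- function(fd, split, hyper = train_hyper(),
                                     hidden = 15, seed = 1) {
  stopifnot(inherits(fd, "feature_dataset"))
  scaler <- fit_scaler(fd$X[, split$train, drop = FALSE])
  Xs <- t(apply_scaler(fd$X, scaler))
  Z <- one_hot(fd$labels, 5)

  model <- mlp_init(c(nrow(fd$X), hidden, 5), seed = seed)
  sets <- lapply(split, function(idx)
    list(X = Xs[idx, , drop = FALSE], Z = Z[idx, , drop = FALSE],
         labels = fd$labels[idx]))
  fit <- train_mlp(model, sets$train$X, sets$train$Z,
                   validation = sets$validation, test = sets$test,
                   hyper = hyper)
  fit$model$scaler <- scaler
  fit$report$accuracy <- vapply(sets, function(s) {
    pred <- max.col(mlp_forward(fit$model,
                                s$X)$Y, ties.method = "first") - 1L
    100 * mean(pred == s$labels)
  }, numeric(1))
  fit$split <- split
  fit
}

#' Compare the five training algorithms
#'
#' Trains the same initialization with each algorithm on the same
#' (typically 60/20/20) partition and tabulates best validation MSE, the
#' epoch it occurred at, and test-split accuracy. Reproducible per seed.
#'
#' @param fd a `feature_dataset`.
#' @param split partition from [split_dataset()]; should include a test set.
#' @param algorithms algorithms to run (default all five).
#' @param max_epochs shared epoch budget.
#' @param seed shared initialization seed.
#' @return data.frame(algorithm, best_val_mse, best_epoch, accuracy_pct).
#' @export
compare_training_functions <- function(fd, split,
                                       algorithms = c("lm", "bfgs", "cgp",
                                                      "oss", "gdx"),
                                       max_epochs = 300, seed = 1) {
  rows <- lapply(algorithms, function(alg) {
    fit <- train_gesture_classifier(
      fd, split, hyper = train_hyper(alg, max_epochs = max_epochs),
      seed = seed)
    acc <- fit$report$accuracy
    eval_split <- if ("test" %in% names(acc)) "test" else "validation"
    data.frame(algorithm = alg,
               best_val_mse = fit$report$best_val_mse,
               best_epoch = fit$report$best_epoch,
               accuracy_pct = unname(acc[eval_split]))
  })
  do.call(rbind, rows)
}
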