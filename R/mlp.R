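# Multilayer perceptron, written from first principles: the network, its
# forward pass, the MSE loss, the analytic gradient and the per-residual
# Jacobian that Levenberg-Marquardt needs. Layer sizes are free so tiny
# nets can be checked against finite differences; the gesture classifier
# uses 20-15-5 with logistic sigmoid activations throughout.

.act <- function(z, kind) {
  switch(kind,
         logistic = 1 / (1 + exp(-z)),
         identity = z,
         stop("unknown activation '", kind, "'", call. = FALSE))
}

.act_prime <- function(a, kind) {
  # derivative expressed through the activation value
  switch(kind,
         logistic = a * (1 - a),
         identity = array(1, dim = dim(a)))
}

#' Initialize a multilayer perceptron
#'
#' Weights drawn uniformly in \eqn{\pm 1/\sqrt{\mathrm{fan~in}}} per layer,
#' biases zero; fully reproducible from the seed. The default architecture
#' is the 20-15-5 gesture classifier (395 parameters) with logistic sigmoid
#' hidden and output activations.
#'
#' @param sizes integer vector of layer widths, input first (default
#'   c(20, 15, 5)).
#' @param seed integer seed.
#' @param hidden_activation,output_activation `"logistic"` or `"identity"`.
#' @return An `mlp_model`: `sizes`, weight matrices `W` (rows = units,
#'   columns = inputs), biases `b`, per-layer `activations`, `seed`.
#' @export
mlp_init <- function(sizes = c(20, 15, 5), seed = 1,
                     hidden_activation = "logistic",
                     output_activation = "logistic") {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  set.seed(as.integer(seed))
  L <- length(sizes) - 1
  W <- b <- vector("list", L)
  for (l in seq_len(L)) {
    r <- 1 / sqrt(sizes[l])
    W[[l]] <- matrix(stats::runif(sizes[l + 1] * sizes[l], -r, r),
                     nrow = sizes[l + 1], ncol = sizes[l])
    b[[l]] <- numeric(sizes[l + 1])
  }
  acts <- c(rep(hidden_activation, max(L - 1, 0)), output_activation)
  structure(list(sizes = sizes, W = W, b = b, activations = acts,
                 seed = as.integer(seed), scaler = NULL),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s, %d parameters, activations: %s\n",
              paste(x$sizes, collapse = "-"), length(mlp_pack(x)),
              paste(x$activations, collapse = "/")))
  invisible(x)
}

#' Flatten / restore model parameters
#'
#' Parameters are ordered layer by layer, each layer's weight matrix in
#' column-major order followed by its bias vector.
#'
#' @param model an `mlp_model`.
#' @return `mlp_pack`: numeric parameter vector. `mlp_unpack`: the model
#'   with parameters replaced by `theta`.
#' @export
mlp_pack <- function(model) {
  unlist(lapply(seq_along(model$W),
                function(l) c(as.vector(model$W[[l]]), model$b[[l]])))
}

#' @rdname mlp_pack
#' @param theta numeric parameter vector from [mlp_pack()].
#' @export
mlp_unpack <- function(model, theta) {
  at <- 0
  for (l in seq_along(model$W)) {
    nw <- length(model$W[[l]])
    model$W[[l]][] <- theta[at + seq_len(nw)]
    at <- at + nw
    nb <- length(model$b[[l]])
    model$b[[l]] <- theta[at + seq_len(nb)]
    at <- at + nb
  }
  model
}

#' Forward pass
#'
#' @param model an `mlp_model`.
#' @param X numeric matrix, cases in rows (n x sizes[1]); a single vector is
#'   treated as one case.
#' @return list(Y = n x K output matrix, A = list of activations per layer
#'   starting with the input, Z = pre-activations).
#' @export
mlp_forward <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != model$sizes[1])
    stop("input has ", ncol(X), " features; model expects ", model$sizes[1],
         call. = FALSE)
  L <- length(model$W)
  A <- vector("list", L + 1)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Zl <- A[[l]] %*% t(model$W[[l]])
    Zl <- sweep(Zl, 2, model$b[[l]], "+")
    A[[l + 1]] <- .act(Zl, model$activations[l])
  }
  list(Y = A[[L + 1]], A = A)
}

#' Predict gesture classes
#'
#' Argmax over the output units; ties break to the lowest class id.
#'
#' @param object an `mlp_model` (with an embedded scaler if trained through
#'   [train_gesture_classifier()]).
#' @param X feature matrix: n x 20 (cases in rows) or a `feature_dataset`.
#' @param ... unused.
#' @return Integer class ids (0-based).
#' @export
predict.mlp_model <- function(object, X, ...) {
  if (inherits(X, "feature_dataset")) X <- t(X$X)
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  if (!is.null(object$scaler))
    X <- t(apply_scaler(t(X), object$scaler))
  Y <- mlp_forward(object, X)$Y
  max.col(Y, ties.method = "first") - 1L
}

#' Mean squared error
#'
#' Mean of the squared residuals \eqn{e = z - y} over all output units and
#' cases, against one-hot targets.
#'
#' @param model an `mlp_model`.
#' @param X n x d input matrix.
#' @param Z n x K one-hot target matrix.
#' @return Scalar MSE.
#' @export
mlp_mse <- function(model, X, Z) {
  Y <- mlp_forward(model, X)$Y
  if (!all(dim(Y) == dim(Z))) stop("target shape mismatch", call. = FALSE)
  mean((Z - Y)^2)
}

#' One-hot encode class labels
#' @param labels integer labels 0..K-1.
#' @param K number of classes (default 5).
#' @return n x K matrix of 0/1 targets.
#' @export
one_hot <- function(labels, K = 5) {
  n <- length(labels)
  Z <- matrix(0, n, K)
  Z[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  Z
}

#' Gradient of the MSE
#'
#' Analytic backpropagation gradient of [mlp_mse()] with respect to the
#' packed parameter vector.
#'
#' @inheritParams mlp_mse
#' @return Numeric vector, same layout as [mlp_pack()].
#' @export
mlp_grad <- function(model, X, Z) {
  fw <- mlp_forward(model, X)
  L <- length(model$W)
  n_res <- length(Z)
  delta <- -(2 / n_res) * (Z - fw$Y) *
    .act_prime(fw$A[[L + 1]], model$activations[L])
  g <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW <- t(delta) %*% fw$A[[l]]
    gb <- colSums(delta)
    g[[l]] <- c(as.vector(gW), gb)
    if (l > 1)
      delta <- (delta %*% model$W[[l]]) *
        .act_prime(fw$A[[l]], model$activations[l - 1])
  }
  unlist(g)
}

#' Jacobian of the residuals
#'
#' Matrix of \eqn{\partial e_{r}/\partial \theta_j} for every residual
#' \eqn{e = z - y} (rows: cases stacked per output unit, outputs in blocks)
#' and every packed parameter (columns), computed by per-output
#' backpropagation. This is the J of the Levenberg-Marquardt normal
#' equations.
#'
#' @inheritParams mlp_mse
#' @return list(J = (n*K) x n_params matrix, e = residual vector aligned
#'   with J's rows).
#' @export
mlp_jacobian <- function(model, X, Z) {
  fw <- mlp_forward(model, X)
  L <- length(model$W)
  n <- nrow(X)
  K <- model$sizes[length(model$sizes)]
  n_par <- length(mlp_pack(model))
  J <- matrix(0, n * K, n_par)
  e <- as.vector(Z - fw$Y)            # column-major: cases within output
  outprime <- .act_prime(fw$A[[L + 1]], model$activations[L])
  for (o in seq_len(K)) {
    rows <- (o - 1) * n + seq_len(n)
    # D = d e_o / d z_l ; residual e = z - y so the output seed is -act'
    D <- matrix(0, n, K)
    D[, o] <- -outprime[, o]
    at_end <- n_par
    for (l in rev(seq_len(L))) {
      nw <- length(model$W[[l]])
      nb <- length(model$b[[l]])
      cols_b <- at_end - nb + seq_len(nb)
      cols_W <- at_end - nb - nw + seq_len(nw)
      at_end <- at_end - nb - nw
      J[rows, cols_b] <- D
      # dW[p, q] column index within layer block: (q-1)*n_out + p
      n_out <- nrow(model$W[[l]])
      n_in <- ncol(model$W[[l]])
      for (q in seq_len(n_in)) {
        J[rows, cols_W[(q - 1) * n_out + seq_len(n_out)]] <-
          D * fw$A[[l]][, q]
      }
      if (l > 1)
        D <- (D %*% model$W[[l]]) *
          .act_prime(fw$A[[l]], model$activations[l - 1])
    }
  }
  list(J = J, e = e)
}

#' Serialize / restore a model as JSON
#'
#' Stores layer sizes, weights, biases, activations, the standardization
#' parameters and training metadata.
#'
#' @param model an `mlp_model`.
#' @param path JSON file path.
#' @return `path` invisibly (write); an `mlp_model` (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "mlp_model"))
  obj <- list(sizes = model$sizes,
              W = model$W,
              b = model$b, activations = model$activations,
              seed = model$seed, scaler = model$scaler,
              training = model$training)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mlp_init(obj$sizes, seed = if (is.null(obj$seed)) 1 else obj$seed)
  m$W <- lapply(obj$W, function(w) {
    w <- as.matrix(w)
    dimnames(w) <- NULL
    w
  })
  m$b <- obj$b
  m$activations <- obj$activations
  if (!is.null(obj$scaler))
    m$scaler <- list(center = unlist(obj$scaler$center),
                     scale = unlist(obj$scaler$scale))
  m$training <- obj$training
  m
}
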