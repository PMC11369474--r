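# One-vs-rest target encoding at +/-0.9: tansig output saturates at +/-1,
# which destabilizes least-squares training at the rails.
encode_targets <- function(class_idx, n_class = 5L, hi = 0.9) {
  t <- matrix(-hi, length(class_idx), n_class)
  t[cbind(seq_along(class_idx), class_idx + 1L)] <- hi
  t
}

# Pack/unpack weights: W1 (H x n_in), b1 (H), W2 (O x H), b2 (O).
ann_unpack <- function(theta, n_in, H, O) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(H * n_in)], H, n_in); i <- i + H * n_in
  b1 <- theta[i + seq_len(H)]; i <- i + H
  W2 <- matrix(theta[i + seq_len(O * H)], O, H); i <- i + O * H
  b2 <- theta[i + seq_len(O)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# Forward pass; returns hidden activations and outputs (both tansig).
ann_forward <- function(w, X) {
  a1 <- tanh(sweep(X %*% t(w$W1), 2, w$b1, "+"))
  out <- tanh(sweep(a1 %*% t(w$W2), 2, w$b2, "+"))
  list(a1 = a1, out = out)
}

ann_mse <- function(out, targets) mean((targets - out)^2)

# Jacobian of the residual vector r = vec(targets - out) w.r.t. all weights.
# Rows are ordered (output unit o outer, sample n inner). N*O x n_par.
ann_jacobian <- function(w, X, fwd) {
  N <- nrow(X); n_in <- ncol(X)
  H <- nrow(w$W1); O <- nrow(w$W2)
  n_par <- H * n_in + H + O * H + O
  J <- matrix(0, N * O, n_par)
  dtan1 <- 1 - fwd$a1^2            # N x H
  dtan2 <- 1 - fwd$out^2           # N x O
  for (o in seq_len(O)) {
    rows <- (o - 1L) * N + seq_len(N)
    g2 <- dtan2[, o]               # d out_o / d z2_o
    # hidden-layer weights: d r / d W1[h, i] = -g2 * W2[o,h] * (1 - a1_h^2) * x_i
    delta1 <- (g2 * dtan1) * matrix(w$W2[o, ], N, H, byrow = TRUE)  # N x H
    # W1 stored column-major as H x n_in: index (h, i) -> (i-1)*H + h
    for (h in seq_len(H)) {
      J[rows, (seq_len(n_in) - 1L) * H + h] <- -delta1[, h] * X
    }
    # hidden biases
    J[rows, H * n_in + seq_len(H)] <- -delta1
    # output weights W2[o, ]: index (o, h) -> H*n_in + H + (h-1)*O + o
    J[rows, H * n_in + H + (seq_len(H) - 1L) * O + o] <- -g2 * fwd$a1
    # output bias b2[o]
    J[rows, H * n_in + H + O * H + o] <- -g2
  }
  J
}

#' Train a tansig feed-forward network by Levenberg-Marquardt
#'
#' Trains a single-hidden-layer feed-forward network (tansig activations in
#' both hidden and output layers) on standardized features with one-vs-rest
#' `+/-0.9` target vectors, using damped Gauss-Newton (Levenberg-Marquardt)
#' full-batch optimization: a proposed step is accepted only if the training
#' MSE does not increase, the damping factor adapting multiplicatively.
#' Overtraining is prevented by early stopping on a validation set — training
#' halts after `patience` consecutive epochs without a new validation-MSE
#' minimum, and the returned weights are those of the best-validation epoch.
#'
#' @param x_train,y_train Training features (matrix or data frame) and class
#'   indices in `0..n_class-1`.
#' @param x_val,y_val Validation partition, same encoding.
#' @param n_hidden Hidden-layer size (`>= 1`).
#' @param n_class Number of classes / output units (default 5).
#' @param seed Integer seed for the weight initialization.
#' @param max_epochs Maximum LM epochs (default 150).
#' @param patience Early-stopping patience in epochs (default 8).
#' @param n_restarts Independent weight initializations to train; the run
#'   with the lowest validation MSE is kept (default 3). Full-batch LM on a
#'   small network can park an output unit in a dead local minimum;
#'   multi-start training selected on validation error is the standard
#'   counter-measure.
#' @return A `powder_ann` object: layer sizes, weights (list `W1, b1, W2,
#'   b2`), input scaling (`center`, `scale`), per-epoch `trace` tibble
#'   (epoch, train_mse, val_mse, mu, accepted), `best_epoch`, `seed`.
#' @export
train_ann <- function(x_train, y_train, x_val, y_val, n_hidden = 10L,
                      n_class = 5L, seed = 1L, max_epochs = 150L,
                      patience = 8L, n_restarts = 3L) {
  if (n_hidden < 1) abort("`n_hidden` must be >= 1.")
  if (n_restarts < 1) abort("`n_restarts` must be >= 1.")
  if (n_restarts > 1L) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      train_ann(x_train, y_train, x_val, y_val, n_hidden = n_hidden,
                n_class = n_class, seed = derive_seed(seed, 17L, r),
                max_epochs = max_epochs, patience = patience, n_restarts = 1L)
    })
    vals <- vapply(runs, `[[`, numeric(1), "best_val_mse")
    best <- runs[[which.min(vals)]]
    best$seed <- as.integer(seed)
    best$restarts_val_mse <- vals
    return(best)
  }
  x_train <- as.matrix(x_train); x_val <- as.matrix(x_val)
  n_in <- ncol(x_train)
  center <- colMeans(x_train)
  scale <- apply(x_train, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  Xt <- sweep(sweep(x_train, 2, center), 2, scale, "/")
  Xv <- sweep(sweep(x_val, 2, center), 2, scale, "/")
  Tt <- encode_targets(as.integer(y_train), n_class)
  Tv <- encode_targets(as.integer(y_val), n_class)

  n_par <- n_hidden * n_in + n_hidden + n_class * n_hidden + n_class
  theta <- with_seed(seed, runif(n_par, -0.5, 0.5))
  w <- ann_unpack(theta, n_in, n_hidden, n_class)

  fwd <- ann_forward(w, Xt)
  train_mse <- ann_mse(fwd$out, Tt)
  val_mse <- ann_mse(ann_forward(w, Xv)$out, Tv)
  best <- list(w = w, val = val_mse, epoch = 0L)
  mu <- 1e-2
  stall <- 0L
  trace <- list(tibble::tibble(epoch = 0L, train_mse = train_mse,
                               val_mse = val_mse, mu = mu, accepted = TRUE))

  for (epoch in seq_len(max_epochs)) {
    r <- as.vector(Tt - fwd$out)   # column-major: output unit outer
    J <- ann_jacobian(w, Xt, fwd)
    JtJ <- crossprod(J)
    Jtr <- crossprod(J, r)
    accepted <- FALSE
    for (try in 1:12) {
      A <- JtJ
      diag(A) <- diag(A) + mu
      step <- tryCatch(solve(A, Jtr), error = function(e) NULL)
      if (!is.null(step)) {
        theta_new <- theta - as.vector(step)
        w_new <- ann_unpack(theta_new, n_in, n_hidden, n_class)
        fwd_new <- ann_forward(w_new, Xt)
        mse_new <- ann_mse(fwd_new$out, Tt)
        if (is.finite(mse_new) && mse_new <= train_mse) {
          theta <- theta_new; w <- w_new; fwd <- fwd_new
          train_mse <- mse_new
          mu <- max(mu / 10, 1e-12)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * 10
      if (mu > 1e10) break
    }
    val_mse <- ann_mse(ann_forward(w, Xv)$out, Tv)
    trace[[length(trace) + 1L]] <- tibble::tibble(
      epoch = epoch, train_mse = train_mse, val_mse = val_mse,
      mu = mu, accepted = accepted
    )
    if (!is.finite(train_mse)) {
      abort(sprintf("ANN training diverged at epoch %d.", epoch))
    }
    if (accepted && val_mse < best$val - 1e-12) {
      best <- list(w = w, val = val_mse, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= patience || !accepted) break
  }

  structure(
    list(
      n_in = n_in, n_hidden = as.integer(n_hidden), n_class = as.integer(n_class),
      weights = best$w, center = center, scale = scale,
      trace = dplyr::bind_rows(trace), best_epoch = best$epoch,
      best_val_mse = best$val, seed = as.integer(seed),
      features = colnames(x_train)
    ),
    class = "powder_ann"
  )
}

#' Network outputs and predicted classes
#'
#' @param object A `powder_ann`.
#' @param x Feature matrix or data frame with the model's feature columns.
#' @param type `"class"` for 0-based class indices, `"raw"` for the tansig
#'   output matrix.
#' @param ... Unused.
#' @export
predict.powder_ann <- function(object, x, type = c("class", "raw"), ...) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    if (!all(object$features %in% colnames(x))) {
      abort("Prediction data lacks the model's feature columns.")
    }
    x <- x[, object$features, drop = FALSE]
  }
  if (ncol(x) != object$n_in) {
    abort(sprintf("Model expects %d features, got %d.", object$n_in, ncol(x)))
  }
  Xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  out <- ann_forward(object$weights, Xs)$out
  if (type == "raw") out else max.col(out, ties.method = "first") - 1L
}

#' @export
print.powder_ann <- function(x, ...) {
  cat(sprintf(
    "<powder_ann> %d-%d-%d tansig network, LM-trained; best validation MSE %.5f at epoch %d\n",
    x$n_in, x$n_hidden, x$n_class, x$best_val_mse, x$best_epoch
  ))
  invisible(x)
}

#' @describeIn train_ann Per-epoch training/validation MSE trace.
#' @param x A `powder_ann` object.
#' @param ... Unused.
#' @export
tidy.powder_ann <- function(x, ...) x$trace

#' @describeIn train_ann One-row summary (architecture, best epoch/MSE).
#' @export
glance.powder_ann <- function(x, ...) {
  tibble::tibble(
    n_in = x$n_in, n_hidden = x$n_hidden, n_class = x$n_class,
    epochs = max(x$trace$epoch), best_epoch = x$best_epoch,
    best_val_mse = x$best_val_mse, seed = x$seed
  )
}

#' Scan hidden-layer sizes for the optimal architecture
#'
#' Trains one network per candidate hidden size and returns the model with
#' the highest validation accuracy, preferring fewer neurons on ties.
#'
#' @inheritParams train_ann
#' @param sizes Candidate hidden sizes (default `5:20`).
#' @return The best `powder_ann`, with a `scan` tibble attribute
#'   (`n_hidden`, `val_accuracy`).
#' @export
scan_ann_hidden <- function(x_train, y_train, x_val, y_val, sizes = 5:20,
                            n_class = 5L, seed = 1L, max_epochs = 150L,
                            patience = 8L) {
  results <- purrr::map(sizes, function(H) {
    m <- train_ann(x_train, y_train, x_val, y_val, n_hidden = H,
                   n_class = n_class, seed = derive_seed(seed, H),
                   max_epochs = max_epochs, patience = patience)
    acc <- mean(predict(m, x_val) == as.integer(y_val))
    list(model = m, acc = acc)
  })
  accs <- vapply(results, `[[`, numeric(1), "acc")
  best <- which.max(accs) # first maximum -> fewest neurons on ties
  model <- results[[best]]$model
  attr(model, "scan") <- tibble::tibble(n_hidden = sizes, val_accuracy = accs)
  model
}
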