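#' Train a one-against-one multiclass SVM
#'
#' Trains one binary soft-margin SVM per unordered class pair — `K(K-1)/2 =
#' 10` machines for the five adulteration levels — on features standardized
#' from the training data. Prediction is by majority vote over the machines;
#' vote ties are broken by the largest sum of signed decision values among
#' the tied classes. When `cost`/`gamma` are `NULL` they are chosen by
#' stratified cross-validated grid search on the training data.
#'
#' @param x Training feature matrix or data frame.
#' @param y Class indices in `0..K-1` (at least 2 samples per class).
#' @param kernel `"radial"` (default) or `"linear"`.
#' @param cost,gamma Kernel hyperparameters; `NULL` (default) triggers a
#'   5-fold CV grid over `cost in {0.1, 1, 10}` and, for the radial kernel,
#'   `gamma in {0.01, 0.1, 1}`.
#' @param folds CV folds of the tuning grid.
#' @param seed Integer seed for CV fold assignment.
#' @return A `powder_svm` object holding the 10 binary machines, the class
#'   pair of each, the feature scaling, and the tuned hyperparameters.
#' @export
train_svm <- function(x, y, kernel = c("radial", "linear"), cost = NULL,
                      gamma = NULL, folds = 5L, seed = 1L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as.integer(y)
  classes <- sort(unique(y))
  if (any(table(y) < 2)) abort("Every class needs at least 2 training samples.")

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  tuned <- NULL
  if (is.null(cost) || (kernel == "radial" && is.null(gamma))) {
    grid <- expand.grid(
      cost = if (is.null(cost)) c(0.1, 1, 10) else cost,
      gamma = if (kernel == "radial") {
        if (is.null(gamma)) c(0.01, 0.1, 1) else gamma
      } else NA_real_
    )
    fold_id <- stratified_folds(y, folds, derive_seed(seed, 7L))
    acc <- vapply(seq_len(nrow(grid)), function(gi) {
      correct <- 0L
      scored <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        if (all(tr) || any(table(factor(y[tr], levels = classes)) < 2)) next
        m <- svm_ovo_fit(xs[tr, , drop = FALSE], y[tr], classes, kernel,
                         grid$cost[gi], grid$gamma[gi])
        pred <- svm_ovo_predict(m, xs[!tr, , drop = FALSE], classes)
        correct <- correct + sum(pred == y[!tr])
        scored <- scored + sum(!tr)
      }
      if (scored == 0L) return(NA_real_)
      correct / scored
    }, numeric(1))
    if (all(is.na(acc))) abort("Too few samples per class to tune the SVM grid.")
    tuned <- grid[which.max(acc), ]
    cost <- tuned$cost
    gamma <- if (kernel == "radial") tuned$gamma else NULL
  }

  machines <- svm_ovo_fit(xs, y, classes, kernel, cost, gamma)
  structure(
    list(
      machines = machines, classes = classes, kernel = kernel,
      cost = cost, gamma = gamma, center = center, scale = scale,
      features = colnames(x), seed = as.integer(seed)
    ),
    class = "powder_svm"
  )
}

# Fit the K(K-1)/2 binary machines on already-standardized data.
svm_ovo_fit <- function(xs, y, classes, kernel, cost, gamma) {
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  lapply(pairs, function(pr) {
    idx <- y %in% pr
    yy <- factor(y[idx], levels = pr)
    args <- list(
      x = xs[idx, , drop = FALSE], y = yy, kernel = kernel, cost = cost,
      scale = FALSE, type = "C-classification"
    )
    if (kernel == "radial") args$gamma <- gamma
    list(pair = pr, fit = do.call(e1071::svm, args))
  })
}

# Majority vote with signed-decision-value tie-break, on standardized data.
svm_ovo_predict <- function(machines, xs, classes) {
  n <- nrow(xs)
  if (n == 0L) return(integer(0))
  K <- length(classes)
  votes <- matrix(0L, n, K)
  score <- matrix(0, n, K) # summed signed decision values, oriented per class
  for (m in machines) {
    pred <- predict(m$fit, xs, decision.values = TRUE)
    dvm <- attr(pred, "decision.values")
    dv <- as.numeric(dvm)
    # e1071 names the decision column "a/b": a positive value favours a
    lv <- as.numeric(strsplit(colnames(dvm)[1], "/", fixed = TRUE)[[1]])
    ci1 <- match(lv[1], classes); ci2 <- match(lv[2], classes)
    win <- ifelse(as.integer(as.character(pred)) == lv[1], ci1, ci2)
    votes[cbind(seq_len(n), win)] <- votes[cbind(seq_len(n), win)] + 1L
    score[, ci1] <- score[, ci1] + dv
    score[, ci2] <- score[, ci2] - dv
  }
  out <- integer(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[which.max(score[i, top])]
    out[i] <- classes[top]
  }
  out
}

#' @export
#' @describeIn train_svm Predict 0-based class indices for new data.
#' @param object A `powder_svm`.
#' @param newdata Feature matrix or data frame.
#' @param ... Unused.
predict.powder_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features) && !is.null(colnames(x))) {
    if (!all(object$features %in% colnames(x))) {
      abort("Prediction data lacks the model's feature columns.")
    }
    x <- x[, object$features, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  svm_ovo_predict(object$machines, xs, object$classes)
}

#' @export
print.powder_svm <- function(x, ...) {
  cat(sprintf(
    "<powder_svm> one-against-one, %d binary machines (%s kernel, cost %g%s)\n",
    length(x$machines), x$kernel, x$cost,
    if (!is.null(x$gamma)) sprintf(", gamma %g", x$gamma) else ""
  ))
  invisible(x)
}

#' @describeIn train_svm One row per binary machine (class pair, support
#'   vector count).
#' @param x A `powder_svm` object.
#' @export
tidy.powder_svm <- function(x, ...) {
  tibble::tibble(
    class_a = vapply(x$machines, function(m) m$pair[1], numeric(1)),
    class_b = vapply(x$machines, function(m) m$pair[2], numeric(1)),
    n_support = vapply(x$machines, function(m) m$fit$tot.nSV, numeric(1))
  )
}

#' @describeIn train_svm One-row summary (kernel, hyperparameters).
#' @export
glance.powder_svm <- function(x, ...) {
  tibble::tibble(
    n_machines = length(x$machines), kernel = x$kernel, cost = x$cost,
    gamma = if (is.null(x$gamma)) NA_real_ else x$gamma, seed = x$seed
  )
}
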