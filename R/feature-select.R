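# Stratified fold assignment: within each class, folds are dealt round-robin
# over a shuffled order, so every fold sees every class when n_c >= folds.
stratified_folds <- function(labels, folds, seed) {
  y <- as.integer(factor(labels))
  assign <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      labels <- rep_len(seq_len(folds), length(idx))
      assign[idx] <- labels[sample.int(length(idx))]
    }
  })
  assign
}

# Fit ridge multinomial logistic on (x, y01) and return class probabilities
# for newx. Standardization parameters come from the training data only.
fit_multinom_probs <- function(x, y01, newx, lambda = 1e-4) {
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  xs <- cbind(1, sweep(sweep(x, 2, mu), 2, sg, "/"))
  ns <- cbind(1, sweep(sweep(newx, 2, mu), 2, sg, "/"))
  K <- length(unique(y01))
  fit <- multinom_ridge_fit(xs, as.integer(y01), K = max(y01) + 1L,
                            lambda = lambda)
  multinom_ridge_prob(ns, fit$coef)
}

#' Cross-validated deviance of a multinomial fit
#'
#' The criterion driving sequential forward selection: a ridge-stabilized
#' multinomial logistic model is fitted on each training fold (features
#' z-scored from the training fold's own statistics) and the summed held-out
#' deviance `-2 sum log p_hat(true class)` is returned. Folds are stratified
#' by class. Deviance generalizes the residual sum of squares to
#' classification likelihoods: smaller is better, and a feature set carrying
#' no class information scores near the null deviance `2 n log K`.
#'
#' @param features Numeric matrix, `n x k`.
#' @param labels Class labels, `n` values with at least 2 distinct classes.
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @param lambda Ridge penalty (default 1e-4), for numerical stability only.
#' @return Single numeric: summed held-out deviance.
#' @export
deviance_criterion <- function(features, labels, folds = 5L, seed = 1L,
                               lambda = 1e-4) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (folds < 2 || n < folds) abort("Need `n >= folds >= 2`.")
  y <- as.integer(factor(labels)) - 1L
  K <- length(unique(y))
  if (K < 2) abort("Need at least 2 classes.")
  fold_id <- stratified_folds(labels, folds, seed)
  dev <- 0
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (all(tr)) next # fold received no held-out rows (n close to folds)
    if (length(unique(y[tr])) < K) {
      abort("A class is absent from a training fold; use fewer folds.")
    }
    pr <- fit_multinom_probs(features[tr, , drop = FALSE], y[tr],
                             features[!tr, , drop = FALSE], lambda)
    p_true <- pr[cbind(seq_len(sum(!tr)), y[!tr] + 1L)]
    dev <- dev - 2 * sum(log(pmax(p_true, 1e-300)))
  }
  dev
}

# Null deviance of labels under the best constant model: 2 * sum(-log phat_k).
null_deviance <- function(labels) {
  p <- table(labels) / length(labels)
  -2 * sum(as.vector(table(labels)) * log(as.vector(p)))
}

#' Sequential forward selection of efficient features
#'
#' Greedy wrapper selection: starting from the empty set, repeatedly add the
#' feature whose inclusion most reduces the cross-validated deviance
#' criterion, stopping when the relative improvement falls below
#' `min_improvement` or `max_k` features are selected. Ties are broken by
#' canonical feature order. The first step is measured against the null
#' deviance of the labels.
#'
#' @param table Feature table tibble (see [extract_dataset()]); classes are
#'   its `fraction` column.
#' @param max_k Maximum number of selected features (default 20).
#' @param min_improvement Minimum relative criterion improvement to accept a
#'   feature (default 1e-3).
#' @param folds,seed,lambda Passed to [deviance_criterion()].
#' @param candidates Optional character vector restricting the search space;
#'   default all feature columns.
#' @return A `powder_selection` object: list with `selected` (ordered feature
#'   names), `criterion_trace` (deviance after each accepted feature),
#'   `null_deviance`, `folds`, `seed`.
#' @export
sequential_forward_select <- function(table, max_k = 20L, min_improvement = 1e-3,
                                      folds = 5L, seed = 1L, lambda = 1e-4,
                                      candidates = NULL) {
  if (nrow(table) == 0) abort("Feature table is empty.")
  feats <- candidates %||% table_features(table)
  labels <- table$fraction
  x_all <- as.matrix(table[feats])
  current <- character(0)
  trace <- numeric(0)
  best_prev <- null_deviance(labels)
  d0 <- best_prev
  while (length(current) < max_k && length(current) < length(feats)) {
    remaining <- setdiff(feats, current)
    crit <- vapply(remaining, function(f) {
      deviance_criterion(x_all[, c(current, f), drop = FALSE], labels,
                         folds = folds, seed = seed, lambda = lambda)
    }, numeric(1))
    best_i <- which.min(crit) # which.min takes the first (canonical) minimum
    best_val <- unname(crit[best_i])
    improvement <- (best_prev - best_val) / abs(best_prev)
    if (!is.finite(improvement) || improvement < min_improvement) break
    current <- c(current, remaining[best_i])
    trace <- c(trace, best_val)
    best_prev <- best_val
  }
  structure(
    list(selected = current, criterion_trace = trace, null_deviance = d0,
         folds = as.integer(folds), seed = as.integer(seed),
         max_k = as.integer(max_k), min_improvement = min_improvement),
    class = "powder_selection"
  )
}

#' @export
print.powder_selection <- function(x, ...) {
  cat(sprintf(
    "<powder_selection> %d features (null deviance %.1f)\n",
    length(x$selected), x$null_deviance
  ))
  if (length(x$selected)) {
    print(tidy(x), n = length(x$selected))
  }
  invisible(x)
}

#' @describeIn sequential_forward_select One row per accepted feature with
#'   the criterion value after its inclusion.
#' @param x A `powder_selection` object.
#' @param ... Unused.
#' @export
tidy.powder_selection <- function(x, ...) {
  tibble::tibble(
    step = seq_along(x$selected),
    feature = x$selected,
    criterion = x$criterion_trace
  )
}

#' @describeIn sequential_forward_select One-row summary.
#' @export
glance.powder_selection <- function(x, ...) {
  tibble::tibble(
    n_selected = length(x$selected),
    null_deviance = x$null_deviance,
    final_criterion = if (length(x$criterion_trace)) {
      x$criterion_trace[length(x$criterion_trace)]
    } else NA_real_,
    folds = x$folds,
    seed = x$seed
  )
}

#' Serialize / restore a selection result
#'
#' @param x A `powder_selection`.
#' @param path JSON path.
#' @return `write_selection` invisibly returns `x`; `read_selection` the
#'   restored object.
#' @export
write_selection <- function(x, path) {
  jsonlite::write_json(
    list(selected = x$selected, criterion_trace = x$criterion_trace,
         null_deviance = x$null_deviance, folds = x$folds, seed = x$seed,
         max_k = x$max_k, min_improvement = x$min_improvement),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(x)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(selected = as.character(d$selected),
         criterion_trace = as.numeric(d$criterion_trace),
         null_deviance = d$null_deviance, folds = as.integer(d$folds),
         seed = as.integer(d$seed), max_k = as.integer(d$max_k),
         min_improvement = d$min_improvement),
    class = "powder_selection"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
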