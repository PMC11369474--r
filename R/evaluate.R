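#' Stratified train/validation/test split
#'
#' Randomly assigns each row of a feature table to a partition, stratified by
#' class, with per-class and overall partition sizes within one sample of the
#' exact fractional targets: leftover slots after flooring each class's
#' allocation go to the partitions with the largest cumulative deficit.
#'
#' @param table Feature table tibble; classes are its `fraction` column.
#' @param fractions Named numeric `(train, validation, test)` summing to 1.
#'   A zero fraction yields an empty partition.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return `table` with an added `.split` factor column
#'   (`train`/`validation`/`test`).
#' @export
#' @examples
#' tb <- tibble::tibble(product = "p", fraction = rep(0:4 / 10, each = 18),
#'                      replicate = rep(0:17, 5), f1 = rnorm(90))
#' table(split_data(tb, seed = 1)$.split)
split_data <- function(table, fractions = c(train = 0.6, validation = 0.2, test = 0.2),
                       seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1.")
  if (any(fractions < 0)) abort("`fractions` must be >= 0.")
  parts <- names(fractions) %||% c("train", "validation", "test")[seq_along(fractions)]
  n <- nrow(table)
  y <- as.character(table$fraction)
  assign <- character(n)
  allocated <- stats::setNames(numeric(length(fractions)), parts)
  seen <- 0
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      n_c <- length(idx)
      base <- floor(fractions * n_c)
      leftover <- n_c - sum(base)
      seen <- seen + n_c
      counts <- base
      for (k in seq_len(leftover)) {
        deficit <- fractions * seen - (allocated + counts)
        counts[which.max(deficit)] <- counts[which.max(deficit)] + 1
      }
      if (min(counts) < 0) abort("Stratification failed for a class.")
      assign[idx] <- rep(parts, times = counts)
      allocated <- allocated + counts
    }
  })
  table$.split <- factor(assign, levels = parts)
  table
}

#' Confusion matrix of true vs predicted classes
#'
#' @param truth,predicted Integer class indices in `0..n_class-1`.
#' @param n_class Number of classes (default 5).
#' @param labels Optional class labels for the dimnames; default the five
#'   adulteration levels `0%..50%`.
#' @return `n_class x n_class` integer matrix, rows = true class.
#' @export
confusion_matrix <- function(truth, predicted, n_class = 5L, labels = NULL) {
  if (is.null(labels)) {
    labels <- if (n_class == 5L) c("0%", "5%", "15%", "30%", "50%") else
      as.character(seq_len(n_class) - 1L)
  }
  cm <- matrix(0L, n_class, n_class, dimnames = list(truth = labels, predicted = labels))
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, predicted[i] + 1L] <- cm[truth[i] + 1L, predicted[i] + 1L] + 1L
  }
  cm
}

#' Correct classification rate of a confusion matrix
#'
#' `100 * trace / total`, in percent.
#'
#' @param cm Square count matrix from [confusion_matrix()].
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' cm <- diag(18, 5); cm[2, 1] <- 2; cm[2, 2] <- 16
#' correct_classification_rate(cm) # 88 of 90 -> 97.78
correct_classification_rate <- function(cm) {
  100 * sum(diag(cm)) / sum(cm)
}

#' Pearson correlation between target and output vectors
#'
#' Used to summarize how closely the network's continuous outputs track the
#' `+/-0.9` target encoding; computed over the flattened target/output pairs.
#'
#' @param targets,outputs Numeric vectors or matrices of equal size.
#' @return Pearson r.
#' @export
correlation_coefficient <- function(targets, outputs) {
  t <- as.numeric(targets); o <- as.numeric(outputs)
  if (length(t) != length(o) || length(t) < 2) {
    abort("`targets` and `outputs` must have equal length >= 2.")
  }
  if (stats::sd(t) < 1e-12 || stats::sd(o) < 1e-12) {
    abort("Correlation undefined: zero variance.")
  }
  stats::cor(t, o)
}

# Map the study's fraction levels to 0-based class indices.
fraction_to_class <- function(fraction, levels = c(0, 0.05, 0.15, 0.30, 0.50)) {
  idx <- match(round(fraction, 6), round(levels, 6))
  if (anyNA(idx)) abort("Unknown adulteration fraction in table.")
  idx - 1L
}

#' Evaluate a classifier on a feature table
#'
#' Produces the evaluation artefacts of the study: a 5x5 confusion matrix and
#' correct classification rate over all samples, the same restricted to the
#' held-out test partition, and — for the neural network — Pearson r between
#' target and output vectors per partition and pooled.
#'
#' @param model A `powder_ann` or `powder_svm`.
#' @param table Feature table, typically carrying a `.split` column from
#'   [split_data()]; without one only the all-samples scope is reported.
#' @param levels Adulteration fractions defining the class indexing.
#' @return A `powder_eval` object: list with `confusion_all`,
#'   `confusion_test` (or `NULL`), `rate_all`, `rate_test`, `regression_r`
#'   (tibble, ANN only), `n`, `classifier`.
#' @export
evaluate <- function(model, table, levels = c(0, 0.05, 0.15, 0.30, 0.50)) {
  feats <- if (!is.null(model$features)) model$features else table_features(table)
  missing <- setdiff(feats, names(table))
  if (length(missing)) {
    abort(paste0("Table lacks the model's features: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  x <- as.matrix(table[feats])
  truth <- fraction_to_class(table$fraction, levels)
  pred <- predict(model, x)
  cm_all <- confusion_matrix(truth, pred, n_class = length(levels))
  has_split <- ".split" %in% names(table)
  cm_test <- NULL
  if (has_split) {
    te <- table$.split == "test"
    cm_test <- confusion_matrix(truth[te], pred[te], n_class = length(levels))
  }

  reg <- NULL
  if (inherits(model, "powder_ann")) {
    out <- predict(model, x, type = "raw")
    tgt <- encode_targets(truth, model$n_class)
    scopes <- list(all = rep(TRUE, nrow(x)))
    if (has_split) {
      scopes <- c(list(
        train = table$.split == "train",
        validation = table$.split == "validation",
        test = table$.split == "test"
      ), scopes)
    }
    reg <- dplyr::bind_rows(purrr::imap(scopes, function(idx, nm) {
      tibble::tibble(
        partition = nm,
        r = correlation_coefficient(tgt[idx, , drop = FALSE],
                                    out[idx, , drop = FALSE]),
        n = sum(idx)
      )
    }))
  }

  structure(
    list(
      classifier = class(model)[1],
      confusion_all = cm_all, confusion_test = cm_test,
      rate_all = correct_classification_rate(cm_all),
      rate_test = if (!is.null(cm_test)) correct_classification_rate(cm_test) else NA_real_,
      regression_r = reg, n = nrow(table)
    ),
    class = "powder_eval"
  )
}

#' @export
print.powder_eval <- function(x, ...) {
  cat(sprintf(
    "<powder_eval> %s: all-samples rate %.2f %% (n = %d)%s\n",
    x$classifier, x$rate_all, x$n,
    if (!is.na(x$rate_test)) sprintf(", test-only %.2f %%", x$rate_test) else ""
  ))
  cat("Confusion matrix (all samples):\n")
  print(x$confusion_all)
  invisible(x)
}

#' @describeIn evaluate Long-format confusion counts of the all-samples
#'   matrix with per-class recalls.
#' @param x A `powder_eval` object.
#' @param ... Unused.
#' @export
tidy.powder_eval <- function(x, ...) {
  cm <- x$confusion_all
  tb <- tibble::as_tibble(as.data.frame.table(cm, responseName = "count"))
  names(tb) <- c("truth", "predicted", "count")
  recalls <- diag(cm) / pmax(rowSums(cm), 1)
  tb$recall <- recalls[as.integer(tb$truth)]
  tb
}

#' @describeIn evaluate One-row summary: rates and (ANN) pooled regression r.
#' @export
glance.powder_eval <- function(x, ...) {
  r_all <- if (!is.null(x$regression_r)) {
    x$regression_r$r[x$regression_r$partition == "all"]
  } else NA_real_
  tibble::tibble(
    classifier = x$classifier, n = x$n,
    rate_all = x$rate_all, rate_test = x$rate_test, r_all = r_all
  )
}
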