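# Independent brute-force oracles used to freeze expected values.

# Double-loop pair counter for the co-occurrence matrix: enumerates every
# pixel and offset explicitly. Deliberately naive and independent of
# compute_glcm's vectorized path.
brute_glcm <- function(plane, levels, offsets, symmetric = TRUE) {
  h <- nrow(plane); w <- ncol(plane)
  q <- matrix(pmin(floor(plane * levels), levels - 1L) + 1L, h, w)
  counts <- matrix(0, levels, levels)
  for (off in offsets) {
    for (r in seq_len(h)) {
      for (cc in seq_len(w)) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          counts[q[r, cc], q[r2, c2]] <- counts[q[r, cc], q[r2, c2]] + 1
        }
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Two well-separated Gaussian classes in one feature.
separated_feature <- function(n = 100, gap = 3, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    list(
      x = matrix(c(rnorm(n / 2, 0, sd), rnorm(n / 2, gap, sd)), ncol = 1),
      y = rep(0:1, each = n / 2)
    )
  })
}

# Balanced K-class toy table with `informative` separating features and
# `noise` pure-noise features, as a feature-table-shaped tibble.
toy_feature_table <- function(n_per_class = 18, informative = 2, noise = 4,
                              gap = 2, seed = 1) {
  levels <- c(0, 0.05, 0.15, 0.30, 0.50)
  withr::with_seed(seed, {
    cls <- rep(seq_along(levels) - 1L, each = n_per_class)
    n <- length(cls)
    x <- matrix(rnorm(n * (informative + noise)), n, informative + noise)
    for (j in seq_len(informative)) x[, j] <- x[, j] + gap * cls
    colnames(x) <- paste0("f", seq_len(ncol(x)))
    dplyr::bind_cols(
      tibble::tibble(product = "toy", fraction = levels[cls + 1L],
                     replicate = rep(seq_len(n_per_class) - 1L, length(levels))),
      tibble::as_tibble(x)
    )
  })
}

# A minimal valid 266-column feature table built from rendered images.
tiny_image_table <- function(n_per_level = 2, levels = c(0, 0.25, 0.5),
                             size = 48, seed = 3) {
  pd <- default_powders()
  rows <- list()
  for (li in seq_along(levels)) {
    for (r in seq_len(n_per_level)) {
      s <- render_sample(pd$black_pepper, pd$chickpea, levels[li],
                         size, size, seed = seed + 31 * li + r, replicate = r - 1)
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(product = s$product, fraction = s$fraction,
                       replicate = s$replicate),
        tibble::as_tibble(as.list(extract_features(s$pixels)))
      )
    }
  }
  dplyr::bind_rows(rows)
}
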