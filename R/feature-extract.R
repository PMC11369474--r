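#' Statistic order of the feature vector
#'
#' Nine first-order (colour) statistics followed by five co-occurrence
#' (Haralick) texture statistics. Combined with the 19 channels of
#' [channel_names()] this yields the 266-element feature vector.
#'
#' @return Character vector of the 14 statistic names.
#' @export
statistic_names <- function() {
  c("min", "max", "mean", "median", "mode", "sd", "cv", "kurtosis", "skewness",
    "energy", "contrast", "entropy", "correlation", "homogeneity")
}

#' Canonical 266 feature names
#'
#' @return Character vector `"<channel>.<statistic>"`, channels outer,
#'   statistics inner.
#' @export
feature_names <- function() {
  as.vector(t(outer(channel_names(), statistic_names(), paste, sep = ".")))
}

#' First-order statistics of one channel plane
#'
#' Distributional statistics of a channel's intensities, ignoring spatial
#' arrangement. Moments are population moments (divisor N); kurtosis is the
#' Pearson (non-excess) form `m4/sd^4`. Degenerate planes (sd below 1e-12)
#' report 0 for cv, skewness and kurtosis rather than NaN. The mode is the
#' centre of the most populated of 256 equal bins on `[0, 1]`, the lowest bin
#' winning ties.
#'
#' @param plane Numeric vector or matrix with values in `[0, 1]`.
#' @return Named numeric of length 9:
#'   min, max, mean, median, mode, sd, cv, kurtosis, skewness.
#' @export
#' @examples
#' first_order_stats(c(0, 0, 1, 1))
first_order_stats <- function(plane) {
  x <- as.numeric(plane)
  if (length(x) == 0) abort("`plane` is empty.")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2)
  s <- sqrt(m2)
  if (s < 1e-12) {
    skw <- 0; krt <- 0
  } else {
    skw <- mean(d^3) / s^3
    krt <- mean(d^4) / s^4
  }
  cv <- if (abs(m) < 1e-12) 0 else s / m
  bins <- tabulate(pmin(floor(x * 256), 255) + 1L, nbins = 256L)
  mode_bin <- which.max(bins) # ties -> lowest bin
  c(
    min = min(x), max = max(x), mean = m, median = stats::median(x),
    mode = (mode_bin - 0.5) / 256, sd = s, cv = cv, kurtosis = krt,
    skewness = skw
  )
}

#' Standard GLCM pixel offsets
#'
#' Offsets `(dr, dc)` for the four standard orientations at a given pixel
#' distance: 0, 45, 90 and 135 degrees.
#'
#' @param distance Pixel distance (default 1).
#' @return List of length-2 integer vectors.
#' @export
glcm_offsets <- function(distance = 1L) {
  d <- as.integer(distance)
  list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
}

#' Grey-level co-occurrence matrix of a channel plane
#'
#' Quantizes the plane into `levels` equal bins on `[0, 1]` and counts
#' co-occurring level pairs over the given offsets; with `symmetric = TRUE`
#' the transposed counts are added, as in Haralick's original construction.
#' Counts are normalized to sum to 1.
#'
#' @param plane Numeric matrix with values in `[0, 1]`.
#' @param levels Number of quantization levels (`>= 2`).
#' @param offsets List of `(dr, dc)` integer offsets; default the four
#'   standard orientations at distance 1 ([glcm_offsets()]).
#' @param symmetric Add transposed counts (default `TRUE`).
#' @return A `glcm` object: list with `p` (`levels x levels` matrix summing
#'   to 1), `levels`, `offsets`, `symmetric`.
#' @export
#' @examples
#' p <- matrix(c(0, 0, 1, 1), 2, 2)
#' compute_glcm(p, levels = 2, offsets = list(c(0, 1)))$p
compute_glcm <- function(plane, levels = 32L, offsets = glcm_offsets(1L),
                         symmetric = TRUE) {
  if (!is.matrix(plane)) plane <- as.matrix(plane)
  if (levels < 2) abort("`levels` must be >= 2.")
  h <- nrow(plane); w <- ncol(plane)
  q <- matrix(pmin(floor(plane * levels), levels - 1L) + 1L, h, w)
  counts <- matrix(0, levels, levels)
  any_pairs <- FALSE
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    rlo <- max(1L, 1L - dr); rhi <- min(h, h - dr)
    clo <- max(1L, 1L - dc); chi <- min(w, w - dc)
    if (rlo > rhi || clo > chi) next
    r1 <- rlo:rhi
    c1 <- clo:chi
    i <- q[r1, c1, drop = FALSE]
    j <- q[r1 + dr, c1 + dc, drop = FALSE]
    any_pairs <- TRUE
    counts <- counts + matrix(
      tabulate((i - 1L) * levels + j, nbins = levels * levels),
      levels, levels, byrow = TRUE
    )
  }
  if (!any_pairs) abort("Plane is smaller than every offset; no pixel pairs.")
  if (symmetric) counts <- counts + t(counts)
  structure(
    list(p = counts / sum(counts), levels = as.integer(levels),
         offsets = offsets, symmetric = symmetric),
    class = "glcm"
  )
}

#' Haralick texture features of a co-occurrence matrix
#'
#' Energy `sum(p^2)`, contrast `sum((i-j)^2 p)`, entropy `-sum(p log2 p)`
#' (with `0 log 0 = 0`), homogeneity `sum(p / (1 + |i-j|))`, and correlation
#' `sum((i - mu_i)(j - mu_j) p) / (sigma_i sigma_j)`, defined as 1 for a
#' degenerate matrix whose marginal spread vanishes.
#'
#' @param glcm A [compute_glcm()] result, or a normalized matrix.
#' @return Named numeric of length 5:
#'   energy, contrast, entropy, correlation, homogeneity.
#' @export
haralick_features <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else as.matrix(glcm)
  if (abs(sum(p) - 1) > 1e-6) abort("GLCM is not normalized (sum != 1).")
  L <- nrow(p)
  idx <- seq_len(L)
  di <- outer(idx, idx, `-`)
  energy <- sum(p^2)
  contrast <- sum(di^2 * p)
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  homogeneity <- sum(p / (1 + abs(di)))
  pi_ <- rowSums(p); pj <- colSums(p)
  mi <- sum(idx * pi_); mj <- sum(idx * pj)
  si <- sqrt(sum((idx - mi)^2 * pi_)); sj <- sqrt(sum((idx - mj)^2 * pj))
  correlation <- if (si * sj < 1e-12) 1 else {
    sum(outer(idx - mi, idx - mj) * p) / (si * sj)
  }
  c(energy = energy, contrast = contrast, entropy = entropy,
    correlation = correlation, homogeneity = homogeneity)
}

#' Extract the 266-element feature vector of one image
#'
#' Computes, for each of the 19 channels of the stack, the nine first-order
#' statistics and the five Haralick features of the channel's co-occurrence
#' matrix averaged over the four standard orientations.
#'
#' @param stack A [to_channel_stack()] result (or an RGB array, converted
#'   on the fly).
#' @param glcm_levels GLCM quantization levels (default 32).
#' @param glcm_distance GLCM pixel distance (default 1).
#' @return Named numeric of length 266 in the order of [feature_names()].
#' @export
extract_features <- function(stack, glcm_levels = 32L, glcm_distance = 1L) {
  if (!inherits(stack, "channel_stack")) stack <- to_channel_stack(stack)
  if (length(stack) != 19L) abort("Channel stack must have exactly 19 planes.")
  offsets <- glcm_offsets(glcm_distance)
  out <- unlist(lapply(channel_names(), function(ch) {
    plane <- stack[[ch]]
    fo <- first_order_stats(plane)
    g <- compute_glcm(plane, levels = glcm_levels, offsets = offsets,
                      symmetric = TRUE)
    hl <- haralick_features(g)
    stats::setNames(c(fo, hl), paste(ch, c(names(fo), names(hl)), sep = "."))
  }))
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Extract the feature table of a generated dataset
#'
#' Reads every image in a manifest, crops the central window, and extracts
#' its 266 features.
#'
#' @param manifest Tibble from [generate_dataset()] (or its `manifest.csv`),
#'   with columns `path, product, fraction, replicate`.
#' @param crop Central crop size in pixels (default 192); `NULL` to skip
#'   cropping.
#' @param glcm_levels,glcm_distance Passed to [extract_features()].
#' @return A feature table: tibble with `product`, `fraction`, `replicate`
#'   and the 266 feature columns, one row per image.
#' @export
extract_dataset <- function(manifest, crop = 192L, glcm_levels = 32L,
                            glcm_distance = 1L) {
  if (is.character(manifest)) manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  feats <- purrr::pmap(
    list(manifest$path),
    function(path) {
      img <- read_image(path)
      if (!is.null(crop)) img <- center_crop(img, crop, crop)
      extract_features(img, glcm_levels = glcm_levels,
                       glcm_distance = glcm_distance)
    }
  )
  dplyr::bind_cols(
    tibble::tibble(product = manifest$product, fraction = manifest$fraction,
                   replicate = manifest$replicate),
    tibble::as_tibble(do.call(rbind, feats))
  )
}

#' Feature column names of a feature table
#'
#' @param table A feature table tibble.
#' @return Character vector of the feature columns present, in table order.
#' @export
table_features <- function(table) {
  nm <- setdiff(names(table), c("product", "fraction", "replicate"))
  nm[!startsWith(nm, ".")] # drop bookkeeping columns such as .split
}

#' Write / read a feature table as CSV
#'
#' The CSV preserves values to full double precision and the canonical column
#' order `product, fraction, replicate, <266 features>`. Reading validates
#' the column set — missing or extra feature columns raise an error naming
#' them — and reorders permuted columns back to canonical order.
#'
#' @param table Feature table tibble.
#' @param path CSV path.
#' @return `write_feature_table` returns `table` invisibly;
#'   `read_feature_table` returns the tibble.
#' @export
write_feature_table <- function(table, path) {
  canonical <- c("product", "fraction", "replicate", feature_names())
  missing <- setdiff(canonical, names(table))
  if (length(missing)) {
    abort(paste0("Feature table is missing columns: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  readr::write_csv(table[canonical], path)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  canonical <- c("product", "fraction", "replicate", feature_names())
  missing <- setdiff(canonical, names(tb))
  extra <- setdiff(names(tb), canonical)
  if (length(missing) || length(extra)) {
    abort(sprintf(
      "Feature table column mismatch. Missing: %s. Extra: %s.",
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"
    ))
  }
  tb[canonical]
}
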