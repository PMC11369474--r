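test_that("first-order statistics match hand-computed moments", {
  # {0, 0, 1, 1}: symmetric two-point distribution
  s1 <- first_order_stats(c(0, 0, 1, 1))
  expect_equal(s1[["mean"]], 0.5)
  expect_equal(s1[["sd"]], 0.5)
  expect_equal(s1[["cv"]], 1.0)
  expect_equal(s1[["skewness"]], 0)
  expect_equal(s1[["kurtosis"]], 1.0)
  expect_equal(s1[["median"]], 0.5) # midpoint rule

  # {0, 0, 0, 1}: m2 = 3/16, m3 = 3/32, m4 = 21/256
  s2 <- first_order_stats(c(0, 0, 0, 1))
  expect_equal(s2[["mean"]], 0.25)
  expect_equal(s2[["sd"]], sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(s2[["skewness"]], 2 / sqrt(3), tolerance = 1e-10)
  expect_equal(s2[["kurtosis"]], 7 / 3, tolerance = 1e-10)
})

test_that("degenerate constant planes yield the documented guard values", {
  s <- first_order_stats(rep(0.4, 9))
  expect_equal(s[["min"]], 0.4)
  expect_equal(s[["max"]], 0.4)
  expect_equal(s[["sd"]], 0)
  expect_equal(s[["cv"]], 0)
  expect_equal(s[["skewness"]], 0)
  expect_equal(s[["kurtosis"]], 0)
  # mode = centre of the 256-bin cell containing 0.4: bin 103 of [0,1]
  expect_equal(s[["mode"]], 102.5 / 256)
  expect_error(first_order_stats(numeric(0)), "empty")
})

test_that("first-order statistics match direct formula evaluation on random vectors", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      x <- runif(200)
      s <- first_order_stats(x)
      m <- mean(x); m2 <- mean((x - m)^2)
      expect_equal(s[["mean"]], m, tolerance = 1e-10)
      expect_equal(s[["sd"]], sqrt(m2), tolerance = 1e-10)
      expect_equal(s[["cv"]], sqrt(m2) / m, tolerance = 1e-10)
      expect_equal(s[["skewness"]], mean((x - m)^3) / m2^1.5, tolerance = 1e-10)
      expect_equal(s[["kurtosis"]], mean((x - m)^4) / m2^2, tolerance = 1e-10)
      expect_equal(s[["median"]], median(x), tolerance = 1e-12)
    }
  })
})

test_that("a 2x2 checker plane yields the enumerated two-pair GLCM", {
  plane <- matrix(c(0, 0, 1, 1), 2, 2) # columns: (0,0), (1,1)
  g <- compute_glcm(plane, levels = 2, offsets = list(c(0L, 1L)), symmetric = TRUE)
  expect_equal(g$p, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("constant planes concentrate the GLCM in one cell", {
  g <- compute_glcm(matrix(0.7, 5, 5), levels = 8)
  q <- floor(0.7 * 8) + 1
  expect_equal(g$p[q, q], 1)
  expect_equal(sum(g$p), 1)
})

test_that("GLCM equals the brute-force pair-counting oracle on random planes", {
  withr::with_seed(21, {
    for (rep in 1:6) {
      h <- sample(4:16, 1); w <- sample(4:16, 1)
      plane <- matrix(runif(h * w), h, w)
      levels <- sample(c(4L, 8L, 16L), 1)
      offs <- glcm_offsets(1L)
      g <- compute_glcm(plane, levels, offs, symmetric = TRUE)
      expect_equal(g$p, brute_glcm(plane, levels, offs, TRUE), tolerance = 1e-12)
      g1 <- compute_glcm(plane, levels, list(c(0L, 1L)), symmetric = FALSE)
      expect_equal(g1$p, brute_glcm(plane, levels, list(c(0L, 1L)), FALSE),
                   tolerance = 1e-12)
    }
  })
})

test_that("Haralick features match closed forms on degenerate and uniform matrices", {
  single <- matrix(0, 4, 4); single[2, 2] <- 1
  h <- haralick_features(single)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["contrast"]], 0)
  expect_equal(h[["entropy"]], 0)
  expect_equal(h[["homogeneity"]], 1)
  expect_equal(h[["correlation"]], 1)

  L <- 4
  unif <- matrix(1 / L^2, L, L)
  hu <- haralick_features(unif)
  expect_equal(hu[["energy"]], 1 / L^2) # 0.0625
  expect_equal(hu[["entropy"]], 2 * log2(L)) # 4 bits
  expect_equal(hu[["correlation"]], 0, tolerance = 1e-12)

  expect_error(haralick_features(matrix(1, 2, 2)), "normalized")
})

test_that("gradient-plane contrast equals the brute-force off-diagonal sum", {
  L <- 8
  plane <- matrix(rep(seq(0, 1 - 1e-9, length.out = 16), each = 16), 16, 16)
  g <- compute_glcm(plane, L, list(c(0L, 1L)), symmetric = TRUE)
  p_ref <- brute_glcm(plane, L, list(c(0L, 1L)), TRUE)
  idx <- seq_len(L)
  contrast_ref <- sum(outer(idx, idx, `-`)^2 * p_ref)
  expect_equal(haralick_features(g)[["contrast"]], contrast_ref, tolerance = 1e-12)
})

test_that("extract_features returns 266 finite named values in canonical order", {
  pd <- default_powders()
  s <- render_sample(pd$red_pepper, pd$chickpea, 0.15, 48, 48, seed = 2)
  fv <- extract_features(s$pixels)
  expect_length(fv, 266)
  expect_identical(names(fv), feature_names())
  expect_true(all(is.finite(fv)))
  expect_false(any(duplicated(names(fv))))
})

test_that("a constant image degenerates every channel's features as documented", {
  img <- array(0.5, c(48, 48, 3))
  fv <- extract_features(img)
  for (ch in channel_names()) {
    expect_equal(fv[[paste0(ch, ".sd")]], 0)
    expect_equal(fv[[paste0(ch, ".cv")]], 0)
    expect_equal(fv[[paste0(ch, ".contrast")]], 0)
    expect_equal(fv[[paste0(ch, ".entropy")]], 0)
    expect_equal(fv[[paste0(ch, ".energy")]], 1)
    expect_equal(fv[[paste0(ch, ".homogeneity")]], 1)
  }
})

test_that("spatial permutation preserves first-order but not texture features", {
  withr::with_seed(31, {
    img <- array(runif(32 * 32 * 3), c(32, 32, 3))
    perm <- sample(32 * 32)
    img_p <- array(0, dim(img))
    for (ch in 1:3) img_p[, , ch] <- matrix(as.vector(img[, , ch])[perm], 32, 32)
    fv <- extract_features(img)
    fv_p <- extract_features(img_p)
    fo <- paste(rep(channel_names(), each = 9),
                rep(statistic_names()[1:9], 19), sep = ".")
    expect_equal(fv_p[fo], fv[fo], tolerance = 1e-12)
    tex <- setdiff(feature_names(), fo)
    expect_false(isTRUE(all.equal(fv_p[tex], fv[tex], tolerance = 1e-6)))
  })
})

test_that("feature tables round-trip through CSV and validate their columns", {
  tb <- tiny_image_table(n_per_level = 1, levels = c(0, 0.5), size = 48)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tb, path)
  back <- read_feature_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tb), tolerance = 1e-9)

  # permuted columns are reordered to canonical order with values intact
  shuffled <- tb[, c(1:3, sample(4:ncol(tb)))]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(shuffled, path2)
  reread <- read_feature_table(path2)
  expect_identical(names(reread), c("product", "fraction", "replicate", feature_names()))
  expect_equal(as.data.frame(reread), as.data.frame(tb), tolerance = 1e-9)

  # a missing feature column is named in the error
  broken <- tb[, setdiff(names(tb), "Gray.mean")]
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path3)
  expect_error(read_feature_table(path3), "Gray.mean")
})
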