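test_that("degenerate mixtures draw every pixel from a single material", {
  base <- powder_spec("dark", c(0.3, 0.3, 0.3), c(0.02, 0.02, 0.02),
                      illumination_sd = 0)
  adult <- powder_spec("light", c(0.7, 0.7, 0.7), c(0.02, 0.02, 0.02),
                       illumination_sd = 0)
  n <- 64 * 64
  s0 <- render_sample(base, adult, 0, 64, 64, seed = 11)
  for (ch in 1:3) {
    se <- base$color_sd[ch] / sqrt(n)
    expect_lt(abs(mean(s0$pixels[, , ch]) - base$color_mean[ch]), 3 * se)
  }
  s1 <- render_sample(base, adult, 1, 64, 64, seed = 12)
  for (ch in 1:3) {
    se <- adult$color_sd[ch] / sqrt(n)
    expect_lt(abs(mean(s1$pixels[, , ch]) - adult$color_mean[ch]), 3 * se)
  }
})

test_that("a 50/50 mixture of grey 0.30 and grey 0.70 has mean grey 0.50", {
  base <- powder_spec("dark", c(0.3, 0.3, 0.3), illumination_sd = 0)
  adult <- powder_spec("light", c(0.7, 0.7, 0.7), illumination_sd = 0)
  means <- vapply(1:10, function(seed) {
    mean(render_sample(base, adult, 0.5, 64, 64, seed = seed)$pixels)
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.50), 0.02)
})

test_that("adulterant occupancy is calibrated to the requested fraction", {
  base <- powder_spec("dark", c(0.1, 0.1, 0.1), c(0.01, 0.01, 0.01),
                      illumination_sd = 0)
  adult <- powder_spec("light", c(0.9, 0.9, 0.9), c(0.01, 0.01, 0.01),
                       illumination_sd = 0)
  for (frac in c(0.05, 0.15, 0.30, 0.50)) {
    s <- render_sample(base, adult, frac, 64, 64, seed = 5)
    share <- mean(s$pixels[, , 1] > 0.5) # materials are 40 sd apart
    expect_lt(abs(share - frac), 0.01)
  }
})

test_that("rendering is deterministic given the seed and validates inputs", {
  pd <- default_powders()
  a <- render_sample(pd$cinnamon, pd$chickpea, 0.3, 32, 32, seed = 99)
  b <- render_sample(pd$cinnamon, pd$chickpea, 0.3, 32, 32, seed = 99)
  expect_identical(a$pixels, b$pixels)
  expect_error(render_sample(pd$cinnamon, pd$chickpea, 1.2, 32, 32), "fraction")
  expect_error(render_sample(pd$cinnamon, pd$chickpea, 0.5, 8, 32), ">= 32")
  expect_error(powder_spec("bad", c(1.5, 0, 0)), "\\[0, 1\\]")
})

test_that("generate_dataset writes the configured design with a unique manifest", {
  out <- withr::local_tempdir()
  cfg <- generator_config(
    products = default_powders()[c("black_pepper", "red_pepper")],
    levels = c(0, 0.5), replicates = 2, height = 32, width = 32,
    master_seed = 3
  )
  # height/width floor is enforced by render_sample
  cfg$height <- 32L; cfg$width <- 32L
  mani <- generate_dataset(cfg, out)
  expect_equal(nrow(mani), 2 * 2 * 2)
  expect_equal(nrow(dplyr::distinct(mani, product, fraction, replicate)), nrow(mani))
  expect_true(all(file.exists(mani$path)))
  expect_true(file.exists(file.path(out, "manifest.csv")))

  # single-cell design
  out2 <- withr::local_tempdir()
  cfg2 <- generator_config(products = default_powders()["cinnamon"],
                           levels = 0, replicates = 1, height = 32, width = 32)
  expect_equal(nrow(generate_dataset(cfg2, out2)), 1)
})

test_that("the same master seed reproduces byte-identical images", {
  cfg <- generator_config(products = default_powders()["black_pepper"],
                          levels = c(0, 0.15), replicates = 2,
                          height = 32, width = 32, master_seed = 8)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, out1)
  m2 <- generate_dataset(cfg, out2)
  for (i in seq_len(nrow(m1))) {
    expect_identical(readBin(m1$path[i], "raw", file.size(m1$path[i])),
                     readBin(m2$path[i], "raw", file.size(m2$path[i])))
  }
})

test_that("mean grey increases monotonically with adulteration level", {
  pd <- default_powders()
  levels <- c(0, 0.05, 0.15, 0.30, 0.50)
  for (prod in c("black_pepper", "red_pepper", "cinnamon")) {
    level_means <- vapply(seq_along(levels), function(li) {
      mean(vapply(1:6, function(r) {
        s <- render_sample(pd[[prod]], pd$chickpea, levels[li], 64, 64,
                           seed = derive_seed(1L, li, r))
        g <- to_channel_stack(s$pixels)$Gray
        mean(g)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(level_means) > 0), label = paste(prod, "grey trend"))
  }
})
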