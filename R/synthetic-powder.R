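#' Describe the colour and granularity of one powdered material
#'
#' A `powder_spec` carries the per-material statistical model used by the
#' synthetic image generator: a mean RGB colour, per-channel colour spread,
#' the correlation length of powder clumps, and the between-image illumination
#' variability of the imaging rig.
#'
#' @param name Material label, e.g. `"black_pepper"`.
#' @param color_mean Length-3 numeric, mean RGB in `[0, 1]`.
#' @param color_sd Length-3 numeric, per-channel SD in `[0, 1]`.
#' @param granule_scale Correlation length of the clump field, in pixels
#'   (`>= 1`). Controls how coarse the adulterant patches look.
#' @param illumination_sd SD of the per-image multiplicative illumination
#'   factor (`>= 0`); the factor is drawn once per image from
#'   `Normal(1, illumination_sd)` truncated to `[0.7, 1.3]`.
#'
#' @return An object of class `powder_spec`.
#' @export
#' @examples
#' powder_spec("chickpea", c(0.85, 0.75, 0.55), c(0.05, 0.05, 0.05))
powder_spec <- function(name, color_mean, color_sd = c(0.05, 0.05, 0.05),
                        granule_scale = 4, illumination_sd = 0.01) {
  color_mean <- as.numeric(color_mean)
  color_sd <- as.numeric(color_sd)
  if (length(color_mean) != 3 || length(color_sd) != 3) {
    abort("`color_mean` and `color_sd` must be RGB triples.")
  }
  if (any(color_mean < 0 | color_mean > 1) || any(color_sd < 0 | color_sd > 1)) {
    abort("`color_mean` and `color_sd` must lie in [0, 1] componentwise.")
  }
  if (granule_scale < 1) abort("`granule_scale` must be >= 1 pixel.")
  if (illumination_sd < 0) abort("`illumination_sd` must be >= 0.")
  structure(
    list(
      name = as.character(name), color_mean = color_mean, color_sd = color_sd,
      granule_scale = granule_scale, illumination_sd = illumination_sd
    ),
    class = "powder_spec"
  )
}

#' @export
print.powder_spec <- function(x, ...) {
  cat(sprintf(
    "<powder_spec> %s  mean RGB (%.2f, %.2f, %.2f)  sd (%.2f, %.2f, %.2f)  granules %g px\n",
    x$name, x$color_mean[1], x$color_mean[2], x$color_mean[3],
    x$color_sd[1], x$color_sd[2], x$color_sd[3], x$granule_scale
  ))
  invisible(x)
}

#' Default material palette of the study design
#'
#' Colour models for the three base products and the chickpea-flour
#' adulterant. The adulterant is the lightest material and cinnamon is the
#' closest base product to it, so cinnamon mixtures are the hardest to
#' classify.
#'
#' @return Named list of four [powder_spec()] objects:
#'   `black_pepper`, `red_pepper`, `cinnamon`, `chickpea`.
#' @export
default_powders <- function() {
  list(
    black_pepper = powder_spec("black_pepper", c(0.28, 0.26, 0.24)),
    red_pepper   = powder_spec("red_pepper",   c(0.65, 0.30, 0.18)),
    cinnamon     = powder_spec("cinnamon",     c(0.55, 0.40, 0.30)),
    chickpea     = powder_spec("chickpea",     c(0.85, 0.75, 0.55))
  )
}

# Smooth Gaussian random field with correlation length `sigma` pixels,
# generated by circular convolution in the Fourier domain (periodic
# boundaries are harmless for a noise field).
clump_field <- function(height, width, sigma) {
  noise <- matrix(rnorm(height * width), height, width)
  fr <- c(0:(height %/% 2), -((height - height %/% 2 - 1):1)) / height
  fc <- c(0:(width %/% 2), -((width - width %/% 2 - 1):1)) / width
  if (height == 1) fr <- 0
  if (width == 1) fc <- 0
  transfer <- exp(-2 * pi^2 * sigma^2 * outer(fr^2, fc^2, `+`))
  Re(stats::fft(stats::fft(noise) * transfer, inverse = TRUE)) / (height * width)
}

#' Render one synthetic powder-mixture image
#'
#' Generates an RGB image of a two-material powder mixture: a spatially
#' correlated clump field decides which pixels the adulterant occupies (its
#' share is calibrated to `fraction` exactly, up to one pixel), each pixel's
#' colour is drawn from the occupying material's truncated-normal colour
#' model, and the whole frame is scaled by one random illumination factor.
#'
#' @param base,adulterant [powder_spec()] objects for the base product and
#'   the adulterant.
#' @param fraction Adulterant mass fraction in `[0, 1]`, treated as the areal
#'   occupancy share of adulterant pixels.
#' @param height,width Image size in pixels (`>= 32`).
#' @param seed Integer seed; the image is a pure function of its arguments.
#'
#' @return An `adulteration_sample`: list with `pixels` (`height x width x 3`
#'   array in `[0, 1]`), `product`, `fraction`, `replicate`, `seed`.
#' @export
#' @examples
#' pd <- default_powders()
#' s <- render_sample(pd$black_pepper, pd$chickpea, 0.15, 64, 64, seed = 1)
#' str(s$pixels)
render_sample <- function(base, adulterant, fraction, height = 256, width = 256,
                          seed = 1L, replicate = 0L) {
  stopifnot(inherits(base, "powder_spec"), inherits(adulterant, "powder_spec"))
  if (!is.numeric(fraction) || length(fraction) != 1 || is.na(fraction) ||
      fraction < 0 || fraction > 1) {
    abort("`fraction` must be a single number in [0, 1].")
  }
  if (height < 32 || width < 32) abort("`height` and `width` must be >= 32.")

  n <- height * width
  pixels <- with_seed(seed, {
    field <- clump_field(height, width, adulterant$granule_scale)
    n_adult <- round(fraction * n)
    occupied <- logical(n)
    if (n_adult > 0) {
      # occupy exactly the top-n_adult cells of the smoothed field
      occupied[order(field, decreasing = TRUE)[seq_len(n_adult)]] <- TRUE
    }
    img <- array(0, dim = c(height, width, 3))
    for (ch in 1:3) {
      plane <- rnorm(n, base$color_mean[ch], base$color_sd[ch])
      if (n_adult > 0) {
        plane[occupied] <- rnorm(n_adult, adulterant$color_mean[ch],
                                 adulterant$color_sd[ch])
      }
      img[, , ch] <- plane
    }
    illum <- min(max(rnorm(1, 1, base$illumination_sd), 0.7), 1.3)
    pmin(pmax(img * illum, 0), 1)
  })
  structure(
    list(pixels = pixels, product = base$name, fraction = fraction,
         replicate = as.integer(replicate), seed = as.integer(seed)),
    class = "adulteration_sample"
  )
}

#' Default generator configuration of the study design
#'
#' Three base products, chickpea-flour adulterant, five adulteration levels
#' (0, 5, 15, 30, 50 % by weight), 18 replicate images per product and level:
#' 3 x 5 x 18 = 270 images of 256 x 256 pixels.
#'
#' @param products Named list of base-product [powder_spec()]s.
#' @param adulterant Adulterant [powder_spec()].
#' @param levels Numeric adulteration fractions.
#' @param replicates Images per (product, level).
#' @param height,width Image size in pixels.
#' @param master_seed Integer master seed; per-image seeds derive from it.
#' @return A named list, the `generator` block of the pipeline config.
#' @export
generator_config <- function(products = default_powders()[c("black_pepper", "red_pepper", "cinnamon")],
                             adulterant = default_powders()$chickpea,
                             levels = c(0, 0.05, 0.15, 0.30, 0.50),
                             replicates = 18, height = 256, width = 256,
                             master_seed = 42L) {
  list(products = products, adulterant = adulterant, levels = levels,
       replicates = as.integer(replicates), height = as.integer(height),
       width = as.integer(width), master_seed = as.integer(master_seed))
}

#' Generate the full synthetic image dataset
#'
#' Writes one 8-bit RGB PNG per (product, level, replicate) — 270 images under
#' the default design — together with a CSV manifest. Per-image seeds are
#' derived deterministically from the master seed, so the same configuration
#' always reproduces byte-identical images.
#'
#' @param config A [generator_config()] list.
#' @param out_dir Output directory (created if absent).
#' @return A tibble manifest with columns
#'   `path, product, fraction, replicate, seed`, also written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_dataset <- function(config = generator_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }
  rows <- list()
  products <- config$products
  for (pi in seq_along(products)) {
    base <- products[[pi]]
    for (li in seq_along(config$levels)) {
      frac <- config$levels[li]
      for (rep in seq_len(config$replicates)) {
        seed <- derive_seed(config$master_seed, pi, li, rep)
        sample <- render_sample(base, config$adulterant, frac,
                                config$height, config$width,
                                seed = seed, replicate = rep - 1L)
        fname <- sprintf("%s_l%02.0f_r%02d.png", base$name, 100 * frac, rep - 1L)
        path <- file.path(out_dir, fname)
        png::writePNG(sample$pixels, path)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          path = path, product = base$name, fraction = frac,
          replicate = rep - 1L, seed = seed
        )
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}
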