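#' Canonical channel order of the feature pipeline
#'
#' The 19 scalar channel planes derived from an RGB image: the raw channels,
#' luminance, chromaticity coordinates, HSV, CIE L*a*b*, the Ohta components
#' i1/i2/i3, and BT.601 chroma (Cb, Cr) plus a green-difference chroma Cg.
#' Feature names are `<channel>.<statistic>` in this channel order.
#'
#' @return Character vector of the 19 channel names.
#' @export
channel_names <- function() {
  c("R", "G", "B", "Gray", "Nr", "Ng", "Nb", "Hue", "Saturation", "Value",
    "L", "a", "b", "i1", "i2", "i3", "Cb", "Cr", "Cg")
}

# sRGB gamma expansion (IEC 61966-2-1), used only for the L*a*b* conversion.
srgb_linearize <- function(u) {
  ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
}

# Vectorized sRGB -> CIE L*a*b*, D65/2 degrees. Inputs gamma-encoded [0,1].
# Returns list of raw-scale L (0..100), a, b.
rgb_to_lab <- function(r, g, b) {
  rl <- srgb_linearize(r); gl <- srgb_linearize(g); bl <- srgb_linearize(b)
  x <- 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl
  y <- 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl
  z <- 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl
  xn <- 0.95047; yn <- 1.0; zn <- 1.08883
  f <- function(t) {
    eps <- (6 / 29)^3
    ifelse(t > eps, t^(1 / 3), t / (3 * (6 / 29)^2) + 4 / 29)
  }
  fx <- f(x / xn); fy <- f(y / yn); fz <- f(z / zn)
  list(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Vectorized RGB -> HSV by the hexcone formulas, Hue scaled to [0,1].
rgb_to_hsv01 <- function(r, g, b) {
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  d <- v - mn
  s <- ifelse(v > 0, d / v, 0)
  h <- numeric(length(r))
  nz <- d > 0
  rr <- r[nz]; gg <- g[nz]; bb <- b[nz]; vv <- v[nz]; dd <- d[nz]
  hh <- numeric(sum(nz))
  i <- vv == rr
  hh[i] <- ((gg[i] - bb[i]) / dd[i]) %% 6
  i <- vv == gg & vv != rr
  hh[i] <- (bb[i] - rr[i]) / dd[i] + 2
  i <- vv == bb & vv != rr & vv != gg
  hh[i] <- (rr[i] - gg[i]) / dd[i] + 4
  h[nz] <- hh / 6
  list(h = h %% 1, s = s, v = v)
}

#' Expand an RGB image into the 19-channel stack
#'
#' Computes, per pixel, the 19 scalar channels over which all colour and
#' texture features are defined. Signed or unbounded channels are affinely
#' mapped into `[0, 1]` so that histogram binning, GLCM quantization and
#' entropy scales are uniform across channels: `L/100`, `(a+128)/255`,
#' `(b+128)/255`, `i2 + 0.5`, `i3 + 0.5`, `Cb/Cr/Cg` offset by `+0.5`.
#' Every plane is clipped to `[0, 1]`.
#'
#' @param image `H x W x 3` RGB array in `[0, 1]`.
#' @return A named list of class `channel_stack`: 19 `H x W` matrices in the
#'   order of [channel_names()].
#' @export
#' @examples
#' img <- array(0.5, c(32, 32, 3))
#' st <- to_channel_stack(img)
#' names(st)
to_channel_stack <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) abort("`image` must be an H x W x 3 array.")
  if (anyNA(image)) abort("`image` contains NA/NaN pixels.")
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]

  gray <- 0.2989 * r + 0.5870 * g + 0.1140 * b

  tot <- r + g + b
  zero <- tot == 0
  tot[zero] <- 1
  nr <- r / tot; ng <- g / tot; nb <- b / tot
  nr[zero] <- 1 / 3; ng[zero] <- 1 / 3; nb[zero] <- 1 / 3

  hsv <- rgb_to_hsv01(r, g, b)
  lab <- rgb_to_lab(r, g, b)

  i1 <- (r + g + b) / 3
  i2 <- (r - b) / 2 + 0.5
  i3 <- (2 * g - r - b) / 4 + 0.5

  y601 <- 0.299 * r + 0.587 * g + 0.114 * b
  cb <- 0.5 + 0.564 * (b - y601)
  cr <- 0.5 + 0.713 * (r - y601)
  cg <- 0.5 + 0.5 * (g - y601)

  shape <- function(v) matrix(pmin(pmax(v, 0), 1), d[1], d[2])
  planes <- list(
    R = r, G = g, B = b, Gray = gray, Nr = nr, Ng = ng, Nb = nb,
    Hue = hsv$h, Saturation = hsv$s, Value = hsv$v,
    L = lab$L / 100, a = (lab$a + 128) / 255, b = (lab$b + 128) / 255,
    i1 = i1, i2 = i2, i3 = i3, Cb = cb, Cr = cr, Cg = cg
  )
  structure(lapply(planes, shape), class = "channel_stack")
}

#' Map a [0, 1]-scale channel statistic back to its raw scale
#'
#' Internally every channel lives on `[0, 1]`; this inverts the affine
#' mapping for location statistics (min, max, mean, median, mode) so values
#' can be reported on the conventional scale of the channel (e.g. CIE a* on
#' roughly -128..127, L* on 0..100).
#'
#' @param value Numeric statistic(s) on the internal `[0, 1]` scale.
#' @param channel One of [channel_names()].
#' @return Numeric on the channel's raw scale.
#' @export
channel_raw_scale <- function(value, channel) {
  switch(channel,
    L = value * 100,
    a = value * 255 - 128,
    b = value * 255 - 128,
    i2 = value - 0.5,
    i3 = value - 0.5,
    Cb = value - 0.5,
    Cr = value - 0.5,
    Cg = value - 0.5,
    value
  )
}
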