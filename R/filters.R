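# Low-level raster filters. All convolutions use reflective padding (the
# border pixel is mirrored, scipy-style "reflect": d c b a | a b c d) so
# that constant rasters are exact fixed points and the tests'
# hand-convolution oracles can reproduce results bit for bit.

pad_reflect <- function(x, k) {
  n <- nrow(x); m <- ncol(x)
  if (k >= n || k >= m) stop("padding exceeds image size")
  ri <- c(k:1, seq_len(n), n:(n - k + 1))
  ci <- c(k:1, seq_len(m), m:(m - k + 1))
  x[ri, ci, drop = FALSE]
}

# separable 1-D convolution along rows then columns with a symmetric kernel
conv_separable <- function(x, kernel) {
  k <- (length(kernel) - 1L) %/% 2L
  n <- nrow(x); m <- ncol(x)
  p <- pad_reflect(x, k)
  # rows
  out <- matrix(0, n + 2 * k, m)
  for (j in seq_along(kernel))
    out <- out + kernel[j] * p[, (j - 1L) + seq_len(m), drop = FALSE]
  # columns
  res <- matrix(0, n, m)
  for (i in seq_along(kernel))
    res <- res + kernel[i] * out[(i - 1L) + seq_len(n), , drop = FALSE]
  res
}

gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur <- function(x, sigma) conv_separable(x, gaussian_kernel_1d(sigma))

# 3x3 cross-correlation with reflective padding
conv3x3 <- function(x, kernel) {
  stopifnot(all(dim(kernel) == c(3L, 3L)))
  n <- nrow(x); m <- ncol(x)
  if (n < 3L || m < 3L) stop("image must be at least 3x3")
  p <- pad_reflect(x, 1L)
  out <- matrix(0, n, m)
  for (di in -1:1) for (dj in -1:1)
    out <- out + kernel[di + 2L, dj + 2L] *
      p[(2L + di):(n + 1L + di), (2L + dj):(m + 1L + dj), drop = FALSE]
  out
}

#' Unsharp masking of a temperature raster
#'
#' Sharpens by subtracting a weighted Gaussian blur and rescaling:
#' \deqn{S = (I - w\,G_\sigma(I)) / (1 - w)}
#' with \eqn{\sigma} equal to `radius` (pixels) and `weight` \eqn{w} in
#' (0, 1). This is the standard definition of the "Unsharp Mask" command of
#' common image-processing tools. Constant images are unchanged; boundary
#' handling is reflective. The sharpened raster is only used to build
#' segmentation masks — temperatures are always read from the original
#' raster, since sharpening distorts radiometry.
#'
#' @param image numeric matrix (temperatures, degrees Celsius).
#' @param radius Gaussian standard deviation in pixels; default 2.
#' @param weight mask weight in (0, 1); default 0.9.
#' @return sharpened matrix of the same dimensions.
#' @export
unsharp_mask <- function(image, radius = 2, weight = 0.9) {
  stopifnot(is.matrix(image), is.numeric(image))
  if (!is.finite(weight) || weight <= 0 || weight >= 1)
    stop("weight must be strictly inside (0, 1)")
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  (image - weight * gaussian_blur(image, radius)) / (1 - weight)
}

#' Sobel gradient magnitude
#'
#' Edge strength as \eqn{\sqrt{G_x^2 + G_y^2}} with the standard 3x3 Sobel
#' kernels and reflective boundary handling. Zero on constant images; a
#' vertical unit step yields magnitude 4 on the columns flanking the step.
#'
#' @param image numeric matrix, at least 3x3.
#' @return matrix of gradient magnitudes, same dimensions as `image`.
#' @export
detect_edges <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- conv3x3(image, kx)
  gy <- conv3x3(image, t(kx))
  sqrt(gx^2 + gy^2)
}

# Otsu's split of a numeric sample: the cut maximizing between-class
# variance on a `bins`-bin histogram. Used to separate high-gradient edge
# pixels from plant-interior pixels inside the candidate plant set.
otsu_split <- function(values, bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- tabulate(findInterval(values, edges, rightmost.closed = TRUE), nbins = bins)
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * centers)
  tot_w <- w[bins]; tot_mu <- mu[bins]
  w0 <- w[-bins]; w1 <- tot_w - w0
  valid <- w0 > 0 & w1 > 0
  between <- rep(-Inf, bins - 1L)
  between[valid] <- (tot_w * mu[-bins][valid] - tot_mu * w0[valid])^2 /
    (w0[valid] * w1[valid])
  k <- which.max(between)
  edges[k + 1L]
}

# binary dilation with a (2k+1)x(2k+1) square structuring element
dilate_mask <- function(mask, k) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (k <= 0L) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  for (di in -k:k) for (dj in -k:k) {
    if (di == 0L && dj == 0L) next
    src_r <- max(1L, 1L - di):min(n, n - di)
    src_c <- max(1L, 1L - dj):min(m, m - dj)
    out[src_r + di, src_c + dj] <- out[src_r + di, src_c + dj] |
      mask[src_r, src_c]
  }
  out
}
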