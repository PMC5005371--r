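#' Intermodes histogram threshold
#'
#' Histogram-based automatic threshold for separating plant tissue from a
#' heated background. A `bins`-bin equal-width histogram of the values is
#' smoothed repeatedly with the kernel (1, 2, 1)/4 (zero outside the
#' histogram support) until exactly two local maxima remain; the threshold
#' is the midpoint of the two mode bin centers. All smoothing arithmetic is
#' additions and divisions by four, which are exact in binary floating
#' point, so the result is reproducible bit for bit.
#'
#' @param values numeric sample (e.g. pixel temperatures); must span a
#'   nonzero range.
#' @param bins number of histogram bins; default 256.
#' @param max_iter smoothing iteration cap; default 10000. If the histogram
#'   has not become bimodal by then (or collapses to a single mode), the
#'   input is not bimodal and an error is raised.
#' @return threshold on the scale of `values`.
#' @export
#' @examples
#' x <- c(rep(20, 500), rep(40, 500))
#' intermodes_threshold(x)   # 30: midpoint of symmetric delta peaks
intermodes_threshold <- function(values, bins = 256L, max_iter = 10000L) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least two finite values")
  rng <- range(values)
  if (diff(rng) <= 1e-8 * max(1, abs(rng[1]), abs(rng[2])))
    stop("constant input: not bimodal")
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- as.numeric(tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                           nbins = bins))
  centers <- (edges[-1] + edges[-(bins + 1L)]) / 2

  n_peaks <- function(h) {
    hp <- c(0, h, 0)
    sum(hp[2:(bins + 1L)] > hp[1:bins] & hp[2:(bins + 1L)] > hp[3:(bins + 2L)])
  }
  iter <- 0L
  repeat {
    np <- n_peaks(h)
    if (np == 2L) break
    if (np < 2L) stop("not bimodal")
    if (iter >= max_iter) stop("not bimodal (iteration cap reached)")
    h <- (c(0, h[-bins]) + 2 * h + c(h[-1], 0)) / 4
    iter <- iter + 1L
  }
  hp <- c(0, h, 0)
  peaks <- which(hp[2:(bins + 1L)] > hp[1:bins] &
                 hp[2:(bins + 1L)] > hp[3:(bins + 2L)])
  mean(centers[peaks])
}
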