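#' Segmentation configuration
#'
#' Parameters of the image-processing chain that separates plant tissue
#' from the heated background plates and reads region temperatures.
#'
#' @param unsharp_radius Gaussian sigma of the unsharp mask, px; default 2.
#' @param unsharp_weight mask weight in (0, 1); default 0.9.
#' @param edge_dilation_px dilation of the high-gradient edge mask before
#'   removal, px; default 1.
#' @param histogram_bins bins for intermodes thresholding; default 256.
#' @param emissivities named list of apparent emission coefficients for the
#'   canopy, wet reference and dry reference. Defaults (canopy 0.90,
#'   wet 0.95, dry 0.93) are the calibrated values for Scots pine needles
#'   and the artificial reference surfaces; use 1.0 throughout to skip
#'   correction (e.g. on synthetic scenes whose ground truth is stored on
#'   the apparent scale).
#' @param edge_removal remove high-gradient (mixed) edge pixels? Default
#'   `TRUE`; disabling is only useful for ablation comparisons.
#' @param min_region_px minimum pixel count below which a region median is
#'   flagged as unreliable; default 25.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(unsharp_radius = 2, unsharp_weight = 0.9,
                                edge_dilation_px = 1L, histogram_bins = 256L,
                                emissivities = list(canopy = 0.90, wet = 0.95,
                                                    dry = 0.93),
                                edge_removal = TRUE, min_region_px = 25L) {
  if (unsharp_weight <= 0 || unsharp_weight >= 1)
    stop("unsharp_weight must be in (0, 1)")
  if (edge_dilation_px < 0) stop("edge_dilation_px must be >= 0")
  stopifnot(all(c("canopy", "wet", "dry") %in% names(emissivities)))
  if (any(unlist(emissivities) <= 0 | unlist(emissivities) > 1))
    stop("emissivities must be in (0, 1]")
  structure(list(unsharp_radius = unsharp_radius,
                 unsharp_weight = unsharp_weight,
                 edge_dilation_px = as.integer(edge_dilation_px),
                 histogram_bins = as.integer(histogram_bins),
                 emissivities = emissivities,
                 edge_removal = isTRUE(edge_removal),
                 min_region_px = as.integer(min_region_px)),
            class = "segmentation_config")
}

rect_mask <- function(dim, rect) {
  m <- matrix(FALSE, dim[1], dim[2])
  if (rect[1] < 1 || rect[2] < 1 || rect[3] > dim[1] || rect[4] > dim[2])
    stop("reference rectangle outside image")
  m[rect[1]:rect[3], rect[2]:rect[4]] <- TRUE
  m
}

# median of a reference rectangle after discarding the hottest decile
# (rims, shadows and plate bleed-over sit in the upper tail)
reference_median <- function(values) {
  keep <- values <= stats::quantile(values, 0.9, names = FALSE)
  stats::median(values[keep])
}

#' Segment a thermal scene into canopy, references, and background
#'
#' The chain mirrors a greenhouse phenotyping setup in which the plant
#' stands in front of heated plates (approx. 40 degrees C) that are hotter
#' than any transpiring canopy: (1) unsharp-mask the raster; (2) intermodes
#' threshold on the canopy search region (the frame minus the reference
#' rectangles) of the sharpened image; (3) keep pixels *below* the
#' threshold (the plant is the cool class); (4) remove mixed edge pixels —
#' those whose Sobel gradient magnitude on the sharpened image exceeds an
#' Otsu split within the kept set — after dilating the edge mask; (5) read
#' region medians from the ORIGINAL raster and correct them by the
#' per-region emission coefficients. Reference medians are computed inside
#' their fixed rectangles after discarding the hottest decile.
#'
#' @param image numeric matrix of apparent temperatures (degrees C), or a
#'   `thermal_scene` object (its raster is used).
#' @param layout list with integer vectors `wet` and `dry`, each
#'   `c(r0, c0, r1, c1)` (1-based, inclusive) locating the reference
#'   rectangles, as read by [read_region_layout()].
#' @param config a [segmentation_config()].
#' @return object of class `segmentation_result`: boolean masks (`canopy`,
#'   `wet`, `dry`, `background`), `median_temps` (emissivity-corrected,
#'   degrees C), `median_temps_apparent`, `threshold_used`, `n_pixels`, and
#'   `flags` for regions with fewer than `min_region_px` pixels.
#' @export
segment_scene <- function(image, layout, config = segmentation_config()) {
  if (inherits(image, "thermal_scene")) image <- image$raster
  stopifnot(is.matrix(image), is.numeric(image))
  if (any(!is.finite(image))) stop("non-finite temperatures in image")
  if (nrow(image) < 32L || ncol(image) < 32L)
    stop("image must be at least 32x32")
  stopifnot(all(c("wet", "dry") %in% names(layout)))

  dm <- dim(image)
  wet_m <- rect_mask(dm, layout$wet)
  dry_m <- rect_mask(dm, layout$dry)
  if (any(wet_m & dry_m)) stop("reference rectangles overlap")
  search <- !(wet_m | dry_m)

  sharp <- unsharp_mask(image, config$unsharp_radius, config$unsharp_weight)
  # For thresholding, saturate the sharpened values at the original value
  # range (as an integer image would): unsharp masking amplifies values
  # near crisp boundaries roughly tenfold, and unbounded over/undershoot
  # would stretch the equal-width histogram until the tissue and
  # background modes merge.
  v <- pmin(pmax(sharp[search], min(image)), max(image))
  thr <- intermodes_threshold(v, config$histogram_bins)
  candidates <- search & (sharp < thr)
  if (!any(candidates)) stop("no plant pixels below the background threshold")

  if (config$edge_removal) {
    grad <- detect_edges(sharp)
    cut <- otsu_split(grad[candidates])
    edge <- candidates & (grad > cut)
    edge <- dilate_mask(edge, config$edge_dilation_px)
    canopy_m <- candidates & !edge
  } else {
    canopy_m <- candidates
  }
  if (!any(canopy_m)) stop("no plant pixels left after edge removal")

  eps <- config$emissivities
  apparent <- c(canopy = stats::median(image[canopy_m]),
                wet = reference_median(image[wet_m]),
                dry = reference_median(image[dry_m]))
  corrected <- c(canopy = correct_emissivity(apparent[["canopy"]], eps$canopy),
                 wet = correct_emissivity(apparent[["wet"]], eps$wet),
                 dry = correct_emissivity(apparent[["dry"]], eps$dry))
  n_px <- c(canopy = sum(canopy_m), wet = sum(wet_m), dry = sum(dry_m))
  structure(list(canopy_mask = canopy_m, wet_mask = wet_m, dry_mask = dry_m,
                 background_mask = !(canopy_m | wet_m | dry_m),
                 median_temps = corrected,
                 median_temps_apparent = apparent,
                 threshold_used = thr,
                 n_pixels = n_px,
                 flags = names(n_px)[n_px < config$min_region_px]),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("segmentation_result\n")
  cat(sprintf("  threshold: %.2f C\n", x$threshold_used))
  for (r in names(x$median_temps))
    cat(sprintf("  %-7s median %6.2f C (apparent %6.2f C, n = %d)\n", r,
                x$median_temps[[r]], x$median_temps_apparent[[r]],
                x$n_pixels[[r]]))
  if (length(x$flags))
    cat("  flagged (too few pixels):", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate replicate segmentations into daily mean temperatures
#'
#' Each tree is imaged one to three times per measuring day; the daily
#' region temperature is the arithmetic mean of the replicate medians.
#' Failed replicates (`NULL` entries, e.g. from a caught segmentation
#' error) are skipped with a warning; if all replicates failed an error is
#' raised.
#'
#' @param replicates list of 1--3 [segment_scene()] results (entries may be
#'   `NULL` for failed replicates).
#' @return list with `mean_temps` (named: canopy, wet, dry, corrected
#'   scale), `n_replicates` used, and `n_failed`.
#' @export
aggregate_daily <- function(replicates) {
  if (inherits(replicates, "segmentation_result")) replicates <- list(replicates)
  if (length(replicates) < 1L || length(replicates) > 3L)
    stop("expected 1-3 replicate results")
  ok <- Filter(function(r) inherits(r, "segmentation_result"), replicates)
  n_failed <- length(replicates) - length(ok)
  if (n_failed > 0L)
    warning(sprintf("skipping %d failed replicate(s)", n_failed))
  if (length(ok) == 0L) stop("all replicates failed")
  meds <- vapply(ok, function(r) r$median_temps, numeric(3))
  list(mean_temps = rowMeans(meds), n_replicates = length(ok),
       n_failed = n_failed)
}
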