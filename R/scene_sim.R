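#' Parameters of a synthetic thermal scene
#'
#' Describes the simulated imaging setup: a cool conifer canopy rendered as
#' thin needle-like line segments radiating from a stem axis, wet and dry
#' reference rectangles, and a heated-plate background that is strictly
#' hotter than the canopy (the contrast the segmentation relies on). A band
#' of mixed pixels along the canopy boundary emulates the needle-edge
#' interference that edge removal addresses: each boundary pixel becomes,
#' with probability `edge_mix_fraction`, a mixture
#' \eqn{\alpha T_{canopy} + (1-\alpha) T_{plate}} with
#' \eqn{\alpha \sim U(0.2, 0.8)}.
#'
#' @param image_height,image_width pixel counts, each at least 32.
#' @param canopy_temp,wet_temp,dry_temp,plate_temp region temperatures,
#'   degrees C (apparent scale, camera emissivity 1). The plates default to
#'   40, the operating temperature of black heated background plates;
#'   `plate_temp` must exceed `canopy_temp` and `wet_temp < dry_temp`.
#' @param noise_sd i.i.d. Gaussian pixel noise, degrees C; >= 0.
#' @param needle_width_px needle thickness, px (1--3 are realistic).
#' @param n_needles number of needle segments; default 60.
#' @param n_clusters number of dense needle whorls (filled ellipses along
#'   the stem where overlapping needles are unresolved); default 4. These
#'   give the crown contiguous interior area, as in overhead views of
#'   young pines.
#' @param edge_mix_fraction probability that a canopy-boundary pixel is a
#'   plant/background mixture, in \[0, 1\]; default 0.3.
#' @param seed integer RNG seed; the generator is a pure function of
#'   (params, seed).
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_height = 96L, image_width = 128L,
                         canopy_temp = 30, wet_temp = 22, dry_temp = 38,
                         plate_temp = 40, noise_sd = 0.2,
                         needle_width_px = 2L, n_needles = 60L,
                         n_clusters = 4L, edge_mix_fraction = 0.3,
                         seed = 1L) {
  if (image_height < 32L || image_width < 32L)
    stop("image dimensions must be at least 32 pixels")
  if (wet_temp >= dry_temp) stop("wet_temp must be below dry_temp")
  if (plate_temp <= canopy_temp)
    stop("plate_temp must be strictly greater than canopy_temp (contrast assumption)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (edge_mix_fraction < 0 || edge_mix_fraction > 1)
    stop("edge_mix_fraction must be in [0, 1]")
  if (needle_width_px < 1L || needle_width_px > 3L)
    stop("needle_width_px must be 1-3")
  structure(list(image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 canopy_temp = canopy_temp, wet_temp = wet_temp,
                 dry_temp = dry_temp, plate_temp = plate_temp,
                 noise_sd = noise_sd,
                 needle_width_px = as.integer(needle_width_px),
                 n_needles = as.integer(n_needles),
                 n_clusters = as.integer(n_clusters),
                 edge_mix_fraction = edge_mix_fraction,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# reference rectangles in the top corners; canopy confined to the region
# below them. Returns list(wet=, dry=, canopy_box=).
scene_layout <- function(h, w) {
  rh <- max(6L, as.integer(round(0.22 * h)))
  rw <- max(8L, as.integer(round(0.24 * w)))
  wet <- c(3L, 3L, 2L + rh, 2L + rw)
  dry <- c(3L, w - 1L - rw, 2L + rh, w - 2L)
  if (dry[2] <= wet[4] + 2L)
    stop("degenerate geometry: reference rectangles overlap or do not fit")
  canopy_box <- c(rh + 6L, 4L, h - 3L, w - 3L)
  if (canopy_box[1] >= canopy_box[3] - 8L)
    stop("degenerate geometry: no room for the canopy below the references")
  list(wet = wet, dry = dry, canopy_box = canopy_box)
}

# rasterize a line segment of given width into logical matrix `m`
draw_segment <- function(m, r0, c0, r1, c1, width, box) {
  len <- max(abs(r1 - r0), abs(c1 - c0), 1)
  t <- seq(0, 1, length.out = 2L * ceiling(len) + 1L)
  rr <- round(r0 + t * (r1 - r0))
  cc <- round(c0 + t * (c1 - c0))
  keep <- rr >= box[1] & rr <= box[3] & cc >= box[2] & cc <= box[4]
  seg <- matrix(FALSE, nrow(m), ncol(m))
  seg[cbind(rr[keep], cc[keep])] <- TRUE
  if (width > 1L) {
    # thicken the new segment only, clipped to the canopy box
    seg <- dilate_mask(seg, (width - 1L) %/% 2L + (width %% 2L == 0L))
    boxm <- matrix(FALSE, nrow(m), ncol(m))
    boxm[box[1]:box[3], box[2]:box[4]] <- TRUE
    seg <- seg & boxm
  }
  m | seg
}

# filled ellipse (dense needle whorl) clipped to the canopy box
draw_cluster <- function(m, cr, cc, a, b, theta, box) {
  ri <- box[1]:box[3]; ci <- box[2]:box[4]
  dr <- outer(ri - cr, rep(1, length(ci)))
  dc <- outer(rep(1, length(ri)), ci - cc)
  x <- dr * cos(theta) + dc * sin(theta)
  y <- -dr * sin(theta) + dc * cos(theta)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  m[box[1]:box[3], box[2]:box[4]] <- m[box[1]:box[3], box[2]:box[4]] | inside
  m
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic thermal scene with ground truth
#'
#' Composes a temperature raster from a plate-temperature background,
#' needle-like canopy structures, wet/dry reference rectangles, a band of
#' plant/background mixed edge pixels, and i.i.d. Gaussian noise. Alongside
#' the raster it returns the ground-truth region masks, the true (noise-
#' and mixture-free) region temperatures, and the reference-rectangle
#' layout needed by [segment_scene()]. The union of the masks (canopy, wet,
#' dry, edge, background) covers every pixel exactly once. Identical
#' parameters, including the seed, give a bit-identical raster.
#'
#' @param params a [scene_params()] object.
#' @return object of class `thermal_scene`: `raster` (matrix, degrees C,
#'   apparent scale), `masks` (list of logical matrices), `true_temps`
#'   (named: canopy, wet, dry, plate), `layout` (wet/dry rectangles),
#'   `params`.
#' @export
generate_thermal_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_height; w <- params$image_width
  lay <- scene_layout(h, w)
  with_seed(params$seed, {
    canopy <- matrix(FALSE, h, w)
    box <- lay$canopy_box
    # stem axis down the middle of the canopy box
    stem_c <- as.integer(round((box[2] + box[4]) / 2))
    stem_top <- box[1] + 2L
    canopy <- draw_segment(canopy, stem_top, stem_c, box[3] - 1L, stem_c,
                           params$needle_width_px, box)
    for (i in seq_len(params$n_clusters)) {
      cr <- sample(stem_top:(box[3] - 1L), 1L)
      cc <- stem_c + sample(-15:15, 1L)
      canopy <- draw_cluster(canopy, cr, cc, stats::runif(1, 4, 9),
                             stats::runif(1, 4, 9),
                             stats::runif(1, 0, pi), box)
    }
    max_len <- 0.22 * w
    for (i in seq_len(params$n_needles)) {
      r0 <- sample(stem_top:(box[3] - 1L), 1L)
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.35, 1) * max_len
      canopy <- draw_segment(canopy, r0, stem_c,
                             r0 + len * sin(ang), stem_c + len * cos(ang),
                             params$needle_width_px, box)
    }
    wet_m <- rect_mask(c(h, w), lay$wet)
    dry_m <- rect_mask(c(h, w), lay$dry)
    canopy <- canopy & !(wet_m | dry_m)

    raster <- matrix(params$plate_temp, h, w)
    raster[canopy] <- params$canopy_temp
    raster[wet_m] <- params$wet_temp
    raster[dry_m] <- params$dry_temp

    # mixed edge band along the canopy boundary
    band <- dilate_mask(canopy, 1L) & !canopy & !wet_m & !dry_m
    edge_m <- band & (matrix(stats::runif(h * w), h, w) <
                        params$edge_mix_fraction)
    if (any(edge_m)) {
      alpha <- stats::runif(sum(edge_m), 0.2, 0.8)
      raster[edge_m] <- alpha * params$canopy_temp +
        (1 - alpha) * params$plate_temp
    }
    if (params$noise_sd > 0)
      raster <- raster + matrix(stats::rnorm(h * w, 0, params$noise_sd), h, w)

    structure(list(raster = raster,
                   masks = list(canopy = canopy, wet = wet_m, dry = dry_m,
                                edge = edge_m,
                                background = !(canopy | wet_m | dry_m | edge_m)),
                   true_temps = c(canopy = params$canopy_temp,
                                  wet = params$wet_temp,
                                  dry = params$dry_temp,
                                  plate = params$plate_temp),
                   layout = lay[c("wet", "dry")],
                   params = params),
              class = "thermal_scene")
  })
}

#' @export
print.thermal_scene <- function(x, ...) {
  cat(sprintf("thermal_scene %dx%d px; canopy %.1f C (%d px), plate %.1f C\n",
              nrow(x$raster), ncol(x$raster), x$true_temps[["canopy"]],
              sum(x$masks$canopy), x$true_temps[["plate"]]))
  invisible(x)
}

# --- scene I/O: 32-bit TIFF + sidecar ground-truth JSON -------------------

SCENE_T_OFFSET <- -20
SCENE_T_SCALE <- 100   # degrees C span mapped onto [0, 1]

#' Write / read a thermal scene
#'
#' The raster is stored as a single-band 32-bit TIFF. TIFF samples live on
#' \[0, 1\], so temperatures are mapped by `(T - offset)/scale` with the
#' affine map (default offset -20 degrees C, scale 100) recorded in the
#' sidecar JSON `<prefix>.json` together with the reference layout, true
#' temperatures and scene parameters; region masks go to
#' `<prefix>_masks.tif` (integer codes: 0 background, 1 canopy, 2 wet,
#' 3 dry, 4 edge). `read_scene()` inverts the mapping.
#'
#' @param scene a `thermal_scene`.
#' @param prefix file path prefix (writes `<prefix>.tif`, `<prefix>.json`,
#'   `<prefix>_masks.tif`).
#' @return `write_scene()`: the prefix, invisibly. `read_scene()`: a
#'   `thermal_scene`.
#' @export
write_scene <- function(scene, prefix) {
  stopifnot(inherits(scene, "thermal_scene"))
  scaled <- (scene$raster - SCENE_T_OFFSET) / SCENE_T_SCALE
  if (any(scaled < 0 | scaled > 1))
    stop("temperatures outside the storable -20..80 C span")
  tiff::writeTIFF(scaled, paste0(prefix, ".tif"), bits.per.sample = 32L)
  codes <- matrix(0L, nrow(scene$raster), ncol(scene$raster))
  codes[scene$masks$canopy] <- 1L
  codes[scene$masks$wet] <- 2L
  codes[scene$masks$dry] <- 3L
  codes[scene$masks$edge] <- 4L
  tiff::writeTIFF(codes / 255, paste0(prefix, "_masks.tif"),
                  bits.per.sample = 8L)
  meta <- list(t_offset = SCENE_T_OFFSET, t_scale = SCENE_T_SCALE,
               true_temps = as.list(scene$true_temps),
               layout = scene$layout,
               params = unclass(scene$params))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_scene
#' @export
read_scene <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  raster <- tiff::readTIFF(paste0(prefix, ".tif")) * meta$t_scale +
    meta$t_offset
  codes <- round(tiff::readTIFF(paste0(prefix, "_masks.tif")) * 255)
  masks <- list(canopy = codes == 1, wet = codes == 2, dry = codes == 3,
                edge = codes == 4, background = codes == 0)
  structure(list(raster = raster, masks = masks,
                 true_temps = unlist(meta$true_temps),
                 layout = lapply(meta$layout, as.integer),
                 params = do.call(scene_params, meta$params)),
            class = "thermal_scene")
}

#' Read a reference-surface layout from JSON
#'
#' The layout file locates the fixed wet/dry reference rectangles in every
#' frame: `{"wet": [r0, c0, r1, c1], "dry": [...]}` with 1-based inclusive
#' pixel indices.
#'
#' @param path JSON file path.
#' @return list with integer vectors `wet` and `dry`.
#' @export
read_region_layout <- function(path) {
  lay <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("wet", "dry") %in% names(lay)))
    stop("layout must name 'wet' and 'dry' rectangles")
  lapply(lay[c("wet", "dry")], function(r) {
    if (length(r) != 4L) stop("rectangles are [r0, c0, r1, c1]")
    as.integer(r)
  })
}
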