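#' Describe a synthetic BaseScope imaging scene
#'
#' A scene holds elliptical nuclei (DAPI channel) and circular hybridization
#' dots on the probe channels (`MINUS`, `PLUS`, optional `MARKER`), plus the
#' pixel calibration and additive-noise level. Coordinates are continuous,
#' in pixels, with pixel `(i, j)` covering `[i-1, i) x [j-1, j)` (matrix
#' dimension 1 = x, dimension 2 = y); a point lies in a shape if its pixel
#' centre does.
#'
#' @param width,height image size in pixels
#' @param pixel_size micrometres per pixel (isotropic)
#' @param nuclei data.frame with columns cx, cy (centre), ax, ay (semi-axes,
#'   px) and optionally intensity (default 0.8) and marker_positive
#'   (logical, painted on the MARKER channel)
#' @param dots data.frame with columns channel (`"MINUS"`, `"PLUS"` or
#'   `"MARKER"`), cx, cy, radius (px) and optionally intensity (default 1)
#' @param noise_sd additive Gaussian noise sigma (intensity units)
#' @param marker_intensity intensity painted over marker-positive nuclei on
#'   the MARKER channel
#' @param seed integer seed used by [simulate_basescope_image()]
#' @return an object of class `image_scene_config`
#' @export
image_scene_config <- function(width, height, pixel_size, nuclei = NULL,
                               dots = NULL, noise_sd = 0,
                               marker_intensity = 0.6, seed = 1L) {
  width <- assert_count(width, "width")
  height <- assert_count(height, "height")
  if (!is.numeric(pixel_size) || pixel_size <= 0 || !is.finite(pixel_size))
    stop("'pixel_size' must be a finite positive number")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be >= 0")
  nuclei <- nuclei %||% data.frame(cx = numeric(0), cy = numeric(0),
                                   ax = numeric(0), ay = numeric(0))
  dots <- dots %||% data.frame(channel = character(0), cx = numeric(0),
                               cy = numeric(0), radius = numeric(0))
  if (nrow(nuclei) > 0L) {
    if (is.null(nuclei$intensity)) nuclei$intensity <- 0.8
    if (is.null(nuclei$marker_positive)) nuclei$marker_positive <- FALSE
    with_in <- nuclei$cx - nuclei$ax >= 0 & nuclei$cx + nuclei$ax <= width &
      nuclei$cy - nuclei$ay >= 0 & nuclei$cy + nuclei$ay <= height
    if (!all(with_in)) stop("nuclei must lie within image bounds")
  }
  if (nrow(dots) > 0L) {
    if (is.null(dots$intensity)) dots$intensity <- 1
    stopifnot(all(dots$channel %in% c("MINUS", "PLUS", "MARKER")))
    with_in <- dots$cx - dots$radius >= 0 & dots$cx + dots$radius <= width &
      dots$cy - dots$radius >= 0 & dots$cy + dots$radius <= height
    if (!all(with_in)) stop("dots must lie within image bounds")
  }
  structure(list(width = width, height = height, pixel_size = pixel_size,
                 nuclei = nuclei, dots = dots, noise_sd = noise_sd,
                 marker_intensity = marker_intensity,
                 seed = as.integer(seed)),
            class = "image_scene_config")
}

#' @noRd
raster_ellipse <- function(width, height, cx, cy, ax, ay) {
  x <- seq_len(width) - 0.5
  y <- seq_len(height) - 0.5
  outer(x, y, function(px, py)
    ((px - cx) / ax)^2 + ((py - cy) / ay)^2 <= 1)
}

#' Render a synthetic multichannel BaseScope image with ground truth
#'
#' Rasterises the scene's nuclei onto a DAPI channel and its dots onto their
#' probe channels (shapes are painted additively at their intensity), adds
#' i.i.d. Gaussian noise of sd `noise_sd` to every channel, and returns the
#' image together with truth tables. Each dot's truth row records both the
#' continuous disc area `pi * radius^2 * pixel_size^2` and the rasterized
#' pixel-count area actually painted, plus its true nucleus assignment (the
#' nucleus with the nearest centroid; `NA` when the scene has no nuclei).
#' The same seed yields an identical image.
#'
#' @param config an [image_scene_config()]
#' @return list with `stack` (an [image_stack()]), `nuclei` (truth
#'   data.frame: nucleus, cx, cy, ax, ay, area_px, marker_positive) and
#'   `dots` (truth data.frame: dot, channel, cx, cy, radius, area_px,
#'   area_um2, area_um2_continuous, assigned_nucleus)
#' @export
simulate_basescope_image <- function(config) {
  stopifnot(inherits(config, "image_scene_config"))
  set_seed_if(config$seed)
  w <- config$width
  h <- config$height
  blank <- function() matrix(0, nrow = w, ncol = h)
  dapi <- blank()
  channels <- list(DAPI = dapi, MINUS = blank(), PLUS = blank())
  need_marker <- any(config$dots$channel == "MARKER") ||
    any(config$nuclei$marker_positive)
  if (need_marker) channels$MARKER <- blank()

  nuc <- config$nuclei
  nuc_area <- integer(nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    m <- raster_ellipse(w, h, nuc$cx[i], nuc$cy[i], nuc$ax[i], nuc$ay[i])
    nuc_area[i] <- sum(m)
    channels$DAPI <- channels$DAPI + nuc$intensity[i] * m
    if (isTRUE(nuc$marker_positive[i]))
      channels$MARKER <- channels$MARKER + config$marker_intensity * m
  }

  dots <- config$dots
  dot_area <- integer(nrow(dots))
  for (i in seq_len(nrow(dots))) {
    m <- raster_ellipse(w, h, dots$cx[i], dots$cy[i],
                        dots$radius[i], dots$radius[i])
    dot_area[i] <- sum(m)
    ch <- dots$channel[i]
    channels[[ch]] <- channels[[ch]] + dots$intensity[i] * m
  }

  if (config$noise_sd > 0)
    channels <- lapply(channels, function(m)
      m + matrix(rnorm(w * h, sd = config$noise_sd), w, h))

  assigned <- rep(NA_integer_, nrow(dots))
  if (nrow(nuc) > 0L && nrow(dots) > 0L) {
    d2 <- outer(dots$cx, nuc$cx, "-")^2 + outer(dots$cy, nuc$cy, "-")^2
    assigned <- apply(d2, 1L, which.min)
  }

  nuclei_truth <- cbind(data.frame(nucleus = seq_len(nrow(nuc))),
                        nuc[, c("cx", "cy", "ax", "ay"), drop = FALSE],
                        data.frame(area_px = nuc_area,
                                   marker_positive = nuc$marker_positive %||%
                                     rep(FALSE, nrow(nuc))))
  dots_truth <- cbind(data.frame(dot = seq_len(nrow(dots))),
                      dots[, c("channel", "cx", "cy", "radius"),
                           drop = FALSE],
                      data.frame(
                        area_px = dot_area,
                        area_um2 = dot_area * config$pixel_size^2,
                        area_um2_continuous =
                          pi * dots$radius^2 * config$pixel_size^2,
                        assigned_nucleus = assigned))
  rownames(nuclei_truth) <- rownames(dots_truth) <- NULL
  list(stack = image_stack(channels, config$pixel_size),
       nuclei = nuclei_truth, dots = dots_truth)
}

#' Generate a randomized scene configuration
#'
#' Places non-overlapping elliptical nuclei on a grid-jittered layout and
#' scatters dots in the perinuclear neighbourhood of randomly chosen nuclei
#' (BaseScope signal is cytoplasmic/perinuclear, so dots may fall outside
#' the nucleus outline but stay close to it).
#'
#' @param n_nuclei number of nuclei
#' @param n_dots dots per probe channel (MINUS and PLUS)
#' @param width,height,pixel_size,noise_sd,seed see [image_scene_config()]
#' @param dot_radius range of dot radii (px)
#' @param marker_fraction fraction of nuclei painted marker-positive
#' @return an [image_scene_config()]
#' @export
random_scene <- function(n_nuclei = 8L, n_dots = 12L, width = 256L,
                         height = 256L, pixel_size = 0.5, noise_sd = 0,
                         dot_radius = c(2, 4), marker_fraction = 0,
                         seed = 1L) {
  set.seed(as.integer(seed))
  n_nuclei <- assert_count(n_nuclei, "n_nuclei")
  # jittered grid keeps nuclei disjoint
  ncol_g <- ceiling(sqrt(n_nuclei))
  nrow_g <- ceiling(n_nuclei / ncol_g)
  cw <- width / ncol_g
  chh <- height / nrow_g
  k <- seq_len(n_nuclei) - 1L
  gx <- (k %% ncol_g) + 0.5
  gy <- (k %/% ncol_g) + 0.5
  ax <- runif(n_nuclei, 0.14, 0.2) * pmin(cw, chh)
  ay <- runif(n_nuclei, 0.14, 0.2) * pmin(cw, chh)
  cx <- gx * cw + runif(n_nuclei, -0.08, 0.08) * cw
  cy <- gy * chh + runif(n_nuclei, -0.08, 0.08) * chh
  marker_positive <- rep(FALSE, n_nuclei)
  if (marker_fraction > 0)
    marker_positive[sample.int(n_nuclei,
                               round(marker_fraction * n_nuclei))] <- TRUE
  nuclei <- data.frame(cx = cx, cy = cy, ax = ax, ay = ay,
                       intensity = 0.8, marker_positive = marker_positive)
  dots <- do.call(rbind, lapply(c("MINUS", "PLUS"), function(ch) {
    host <- sample.int(n_nuclei, n_dots, replace = TRUE)
    ang <- runif(n_dots, 0, 2 * pi)
    dist <- runif(n_dots, 0, 1.6) * pmax(ax[host], ay[host])
    r <- runif(n_dots, dot_radius[1L], dot_radius[2L])
    data.frame(channel = ch,
               cx = pmin(pmax(cx[host] + dist * cos(ang), r), width - r),
               cy = pmin(pmax(cy[host] + dist * sin(ang), r), height - r),
               radius = r, intensity = 1)
  }))
  image_scene_config(width, height, pixel_size, nuclei = nuclei,
                     dots = dots, noise_sd = noise_sd, seed = seed)
}
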