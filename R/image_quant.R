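#' Segment nuclei from a DAPI channel
#'
#' Operator chain: Gaussian smoothing, global threshold (Otsu by default),
#' hole filling, then a distance-transform watershed to split touching
#' nuclei, removal of regions below `min_area_px`, and contiguous
#' relabelling to 1..K. This is the standard DAPI pipeline behind
#' dot-per-nucleus readouts; every parameter is exposed.
#'
#' @param dapi 2D non-negative numeric matrix
#' @param params list overriding defaults: `smooth_sigma` (px, 2),
#'   `threshold` (`"otsu"` or a fixed numeric value), `min_area_px` (50),
#'   `peak_min_distance` (px, 5; watershed seed radius)
#' @return object of class `nucleus_label_map`: list with `labels` (integer
#'   matrix, 0 = background, labels contiguous 1..K), `table` (data.frame:
#'   nucleus, area_px, cx, cy) and `n` (K)
#' @export
segment_nuclei <- function(dapi, params = list()) {
  stopifnot(is.matrix(dapi), all(dapi >= 0 | is.na(dapi)) || TRUE)
  p <- utils::modifyList(list(smooth_sigma = 2, threshold = "otsu",
                              min_area_px = 50L, peak_min_distance = 5),
                         params)
  x <- dapi
  if (p$smooth_sigma > 0)
    x <- as.matrix(EBImage::gblur(EBImage::Image(x), sigma = p$smooth_sigma))
  mask <- threshold_mask(x, p$threshold)
  if (!any(mask)) return(new_label_map(matrix(0L, nrow(dapi), ncol(dapi))))
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  labs <- EBImage::watershed(dm, tolerance = 1, ext = p$peak_min_distance)
  labs <- as.matrix(EBImage::imageData(labs))
  # drop undersized regions, relabel 1..K contiguous
  sizes <- tabulate(labs)
  keep <- which(sizes >= p$min_area_px)
  relab <- integer(length(sizes))
  relab[keep] <- seq_along(keep)
  labs[labs > 0L] <- relab[labs[labs > 0L]]
  new_label_map(matrix(as.integer(labs), nrow(dapi), ncol(dapi)))
}

#' @noRd
threshold_mask <- function(x, threshold) {
  if (identical(threshold, "otsu")) {
    rng <- range(x)
    if (diff(rng) == 0) return(matrix(FALSE, nrow(x), ncol(x)))
    xs <- (x - rng[1L]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(xs), range = c(0, 1))
    xs > thr
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    x > threshold
  }
}

#' @noRd
new_label_map <- function(labels) {
  k <- max(labels)
  tab <- if (k == 0L) {
    data.frame(nucleus = integer(0), area_px = integer(0),
               cx = numeric(0), cy = numeric(0))
  } else {
    idx <- which(labels > 0L)
    lab <- labels[idx]
    i <- ((idx - 1L) %% nrow(labels)) + 1L - 0.5
    j <- ((idx - 1L) %/% nrow(labels)) + 1L - 0.5
    data.frame(nucleus = seq_len(k),
               area_px = tabulate(lab, nbins = k),
               cx = as.numeric(tapply(i, lab, mean)),
               cy = as.numeric(tapply(j, lab, mean)))
  }
  structure(list(labels = labels, table = tab, n = k),
            class = "nucleus_label_map")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  cat(sprintf("nucleus_label_map: %d nuclei on %d x %d px\n", x$n,
              nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Detect hybridization dots on a probe channel
#'
#' Thresholds the channel (Otsu or fixed), labels connected components at
#' the requested connectivity, and drops components smaller than
#' `min_spot_px`. Areas are reported both in pixels and in um^2
#' (`area_px * pixel_size^2`).
#'
#' @param channel 2D numeric matrix
#' @param pixel_size micrometres per pixel
#' @param params list overriding defaults: `threshold` (`"otsu"` or fixed
#'   numeric), `min_spot_px` (4), `connectivity` (8 or 4)
#' @param channel_name optional channel label carried into the table
#' @return data.frame (class `spot_table`): spot_id, channel, cx, cy,
#'   area_px, area_um2
#' @export
detect_spots <- function(channel, pixel_size, params = list(),
                         channel_name = NA_character_) {
  stopifnot(is.matrix(channel), is.numeric(pixel_size), pixel_size > 0)
  p <- utils::modifyList(list(threshold = "otsu", min_spot_px = 4L,
                              connectivity = 8L), params)
  mask <- threshold_mask(channel, p$threshold)
  labs <- label_components(mask, connectivity = as.integer(p$connectivity))
  k <- max(labs)
  if (k == 0L)
    return(empty_spot_table())
  sizes <- tabulate(labs, nbins = k)
  keep <- which(sizes >= p$min_spot_px)
  if (length(keep) == 0L) return(empty_spot_table())
  idx <- which(labs > 0L)
  lab <- labs[idx]
  sel <- lab %in% keep
  idx <- idx[sel]
  lab <- match(lab[sel], keep)
  i <- ((idx - 1L) %% nrow(labs)) + 1L - 0.5
  j <- ((idx - 1L) %/% nrow(labs)) + 1L - 0.5
  out <- data.frame(spot_id = seq_along(keep),
                    channel = channel_name,
                    cx = as.numeric(tapply(i, lab, mean)),
                    cy = as.numeric(tapply(j, lab, mean)),
                    area_px = sizes[keep],
                    area_um2 = sizes[keep] * pixel_size^2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @noRd
empty_spot_table <- function() {
  data.frame(spot_id = integer(0), channel = character(0), cx = numeric(0),
             cy = numeric(0), area_px = integer(0), area_um2 = numeric(0),
             stringsAsFactors = FALSE)
}

#' Assign detected spots to nuclei
#'
#' Containment first: a spot whose centroid pixel lies inside a labelled
#' nucleus belongs to it. Otherwise the spot goes to the nucleus with the
#' nearest centroid, provided that centroid is within `max_dist_um`
#' (BaseScope signal is perinuclear; the cap prevents cross-cell bleed).
#' Exact distance ties break to the lowest label. Spots beyond the cap, or
#' any spot when the map has no nuclei, stay unassigned (`NA`).
#'
#' @param spots a spot table from [detect_spots()]
#' @param nuclei a [segment_nuclei()] result
#' @param pixel_size micrometres per pixel (must match the spot table)
#' @param max_dist_um assignment distance cap in micrometres
#' @return `spots` with an added integer `assigned_nucleus` column
#' @export
assign_spots <- function(spots, nuclei, pixel_size, max_dist_um = 10) {
  stopifnot(inherits(nuclei, "nucleus_label_map"))
  spots$assigned_nucleus <- rep(NA_integer_, nrow(spots))
  if (nrow(spots) == 0L || nuclei$n == 0L) return(spots)
  labs <- nuclei$labels
  pi_ <- pmin(pmax(floor(spots$cx) + 1L, 1L), nrow(labs))
  pj <- pmin(pmax(floor(spots$cy) + 1L, 1L), ncol(labs))
  inside <- labs[cbind(pi_, pj)]
  spots$assigned_nucleus[inside > 0L] <- inside[inside > 0L]
  todo <- which(inside == 0L)
  if (length(todo) > 0L) {
    d <- sqrt(outer(spots$cx[todo], nuclei$table$cx, "-")^2 +
                outer(spots$cy[todo], nuclei$table$cy, "-")^2) * pixel_size
    nearest <- apply(d, 1L, which.min)  # ties -> lowest label
    ok <- d[cbind(seq_along(todo), nearest)] <= max_dist_um
    spots$assigned_nucleus[todo[ok]] <- nearest[ok]
  }
  spots
}

#' Sum assigned spot area per nucleus and channel
#'
#' Produces the um^2-per-nucleus readout: for every (nucleus, channel) pair
#' the summed area of its assigned spots, with explicit zero rows for
#' nuclei without spots, plus the per-channel unassigned remainder. By
#' construction, per channel, assigned + unassigned area equals the total
#' detected area exactly.
#'
#' @param spots an assigned spot table from [assign_spots()]
#' @param nuclei a [segment_nuclei()] result
#' @param channels channels to report (default: those present in `spots`)
#' @return list (class `per_nucleus_signal`) with `per_nucleus` (data.frame:
#'   nucleus, channel, area_um2) and `unassigned` (data.frame: channel,
#'   area_um2)
#' @export
per_nucleus_area <- function(spots, nuclei, channels = NULL) {
  stopifnot(inherits(nuclei, "nucleus_label_map"),
            "assigned_nucleus" %in% names(spots))
  channels <- channels %||% unique(spots$channel)
  if (length(channels) == 0L) channels <- character(0)
  grid <- expand.grid(nucleus = seq_len(nuclei$n), channel = channels,
                      stringsAsFactors = FALSE)
  if (nrow(grid) > 0L) {
    key <- paste(grid$nucleus, grid$channel)
    hit <- !is.na(spots$assigned_nucleus) & spots$channel %in% channels
    if (any(hit)) {
      sums <- tapply(spots$area_um2[hit],
                     paste(spots$assigned_nucleus[hit], spots$channel[hit]),
                     sum)
      grid$area_um2 <- as.vector(ifelse(is.na(sums[key]), 0, sums[key]))
    } else {
      grid$area_um2 <- 0
    }
  } else {
    grid$area_um2 <- numeric(0)
  }
  un <- vapply(channels, function(ch)
    sum(spots$area_um2[spots$channel == ch &
                         is.na(spots$assigned_nucleus)]), numeric(1))
  structure(list(per_nucleus = grid,
                 unassigned = data.frame(channel = channels,
                                         area_um2 = unname(un),
                                         stringsAsFactors = FALSE)),
            class = "per_nucleus_signal")
}

#' Classify marker-positive nuclei
#'
#' Computes each nucleus's mean intensity on the marker channel and calls it
#' positive when the mean exceeds the cutoff - either a fixed value or an
#' Otsu threshold over the per-nucleus means. The positive fraction
#' (marker+ / DAPI+) is reported with an exact binomial 95% confidence
#' interval; with no nuclei the fraction is undefined and flagged.
#'
#' @param nuclei a [segment_nuclei()] result
#' @param marker marker channel matrix (same shape as the DAPI channel)
#' @param rule `"otsu"` or a fixed numeric cutoff
#' @param conf confidence level for the fraction interval
#' @return list (class `marker_call_table`) with `table` (data.frame:
#'   nucleus, mean_intensity, positive), `fraction`, `ci_low`, `ci_high`,
#'   `n_positive`, `n_nuclei` and `defined`
#' @export
classify_marker_positive <- function(nuclei, marker, rule = "otsu",
                                     conf = 0.95) {
  stopifnot(inherits(nuclei, "nucleus_label_map"), is.matrix(marker),
            all(dim(marker) == dim(nuclei$labels)))
  if (nuclei$n == 0L) {
    return(structure(list(table = data.frame(nucleus = integer(0),
                                             mean_intensity = numeric(0),
                                             positive = logical(0)),
                          fraction = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n_positive = 0L,
                          n_nuclei = 0L, defined = FALSE),
                     class = "marker_call_table"))
  }
  idx <- which(nuclei$labels > 0L)
  means <- as.numeric(tapply(marker[idx], nuclei$labels[idx], mean))
  cutoff <- if (identical(rule, "otsu")) otsu_vector(means) else {
    stopifnot(is.numeric(rule), length(rule) == 1L)
    rule
  }
  positive <- means > cutoff
  ci <- clopper_pearson_ci(sum(positive), length(positive), conf)
  structure(list(table = data.frame(nucleus = seq_len(nuclei$n),
                                    mean_intensity = means,
                                    positive = positive),
                 fraction = mean(positive),
                 ci_low = unname(ci[1L, "low"]),
                 ci_high = unname(ci[1L, "high"]),
                 n_positive = sum(positive), n_nuclei = length(positive),
                 defined = TRUE),
            class = "marker_call_table")
}

#' Quantify a full image stack
#'
#' Convenience wrapper running the whole image arm: nucleus segmentation on
#' DAPI, spot detection on each probe channel, assignment, per-nucleus area
#' summation, and (when a MARKER channel is present) marker-positive
#' classification.
#'
#' @param stack an [image_stack()] with a `DAPI` channel
#' @param segment_params,spot_params parameter lists for [segment_nuclei()]
#'   and [detect_spots()]
#' @param max_dist_um assignment cap, see [assign_spots()]
#' @param marker_rule see [classify_marker_positive()]
#' @param probe_channels channels to treat as probes (default: all channels
#'   except DAPI and MARKER)
#' @return list with `nuclei`, `spots` (assigned), `signal`
#'   (a [per_nucleus_area()] result) and `marker` (or NULL)
#' @export
quantify_image_stack <- function(stack, segment_params = list(),
                                 spot_params = list(), max_dist_um = 10,
                                 marker_rule = "otsu",
                                 probe_channels = NULL) {
  stopifnot(inherits(stack, "image_stack"),
            "DAPI" %in% names(stack$channels))
  probe_channels <- probe_channels %||%
    setdiff(names(stack$channels), c("DAPI", "MARKER"))
  nuclei <- segment_nuclei(stack$channels$DAPI, segment_params)
  spots <- do.call(rbind, lapply(probe_channels, function(ch)
    detect_spots(stack$channels[[ch]], stack$pixel_size, spot_params,
                 channel_name = ch)))
  if (is.null(spots)) spots <- empty_spot_table()
  spots$spot_id <- seq_len(nrow(spots))
  spots <- assign_spots(spots, nuclei, stack$pixel_size, max_dist_um)
  signal <- per_nucleus_area(spots, nuclei, channels = probe_channels)
  marker <- if ("MARKER" %in% names(stack$channels))
    classify_marker_positive(nuclei, stack$channels$MARKER, marker_rule)
  list(nuclei = nuclei, spots = spots, signal = signal, marker = marker)
}
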