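test_that("disjoint nuclei are segmented at their true count and blank
           images give an empty map", {
  sim <- simulate_basescope_image(grid_scene(3))
  seg <- segment_nuclei(sim$stack$channels$DAPI)
  expect_equal(seg$n, 3L)
  expect_true(all(seg$table$area_px >= 50))
  # labels contiguous 1..K
  expect_setequal(setdiff(unique(as.vector(seg$labels)), 0L), 1:3)
  # centroids recover the scene truth to sub-pixel accuracy
  ord <- apply(outer(seg$table$cx, sim$nuclei$cx, function(a, b)
    abs(a - b)), 1, which.min)
  expect_equal(seg$table$cx, sim$nuclei$cx[ord], tolerance = 1e-2)
  expect_equal(seg$table$cy, sim$nuclei$cy[ord], tolerance = 1e-2)

  blank <- segment_nuclei(matrix(0, 64, 64))
  expect_equal(blank$n, 0L)
  expect_equal(nrow(blank$table), 0L)
})

test_that("watershed splits touching nuclei with separated centres", {
  sc <- image_scene_config(128, 128, 0.5,
                           nuclei = data.frame(cx = c(54, 74), cy = 64,
                                               ax = 12, ay = 12))
  sim <- simulate_basescope_image(sc)
  # the two discs overlap into one foreground component
  expect_equal(max(EBImage::bwlabel(
    EBImage::Image(sim$stack$channels$DAPI > 0))), 1)
  seg <- segment_nuclei(sim$stack$channels$DAPI)
  expect_equal(seg$n, 2L)
})

test_that("spot detection reports calibrated areas and honours the size
           filter", {
  img <- matrix(0, 64, 64)
  img[10:14, 10:14] <- 1  # 25 px square "dot"
  spots <- detect_spots(img, pixel_size = 0.5,
                        params = list(threshold = 0.5))
  expect_equal(nrow(spots), 1L)
  expect_equal(spots$area_px, 25L)
  expect_equal(spots$area_um2, 6.25)
  expect_equal(c(spots$cx, spots$cy), c(11.5, 11.5))

  img2 <- matrix(0, 64, 64)
  img2[c(10, 11), 10] <- 1
  img2[40, c(40, 41, 42)] <- 1  # two components of 2 and 3 px
  none <- detect_spots(img2, 0.5, params = list(threshold = 0.5,
                                                min_spot_px = 4))
  expect_equal(nrow(none), 0L)
})

test_that("connectivity setting controls diagonal merging", {
  img <- matrix(0, 32, 32)
  img[cbind(10:13, 10:13)] <- 1  # diagonal chain
  s8 <- detect_spots(img, 1, params = list(threshold = 0.5,
                                           min_spot_px = 1,
                                           connectivity = 8))
  s4 <- detect_spots(img, 1, params = list(threshold = 0.5,
                                           min_spot_px = 1,
                                           connectivity = 4))
  expect_equal(nrow(s8), 1L)
  expect_equal(nrow(s4), 4L)
})

test_that("doubling pixel_size multiplies every area_um2 by exactly 4", {
  sim <- simulate_basescope_image(random_scene(n_nuclei = 4, n_dots = 6,
                                               seed = 17))
  a <- detect_spots(sim$stack$channels$MINUS, 0.5)
  b <- detect_spots(sim$stack$channels$MINUS, 1.0)
  expect_identical(a$area_px, b$area_px)
  expect_equal(b$area_um2, 4 * a$area_um2)
})

test_that("spot assignment follows containment, nearest centroid, cap and
           tie rules", {
  labs <- matrix(0L, 100, 100)
  labs[11:20, 11:20] <- 1L   # centroid (15.5, 15.5)
  labs[31:40, 11:20] <- 2L   # centroid (35.5, 15.5)
  nuclei <- structure(list(
    labels = labs,
    table = data.frame(nucleus = 1:2, area_px = 100,
                       cx = c(15.5, 35.5), cy = 15.5),
    n = 2L), class = "nucleus_label_map")
  spots <- data.frame(spot_id = 1:4, channel = "MINUS",
                      cx = c(15, 25.5, 30, 15.5),
                      cy = c(15, 15.5, 90, 28),
                      area_px = 9L, area_um2 = 2.25)
  got <- assign_spots(spots, nuclei, pixel_size = 0.5, max_dist_um = 10)
  expect_equal(got$assigned_nucleus[1], 1L)  # containment
  expect_equal(got$assigned_nucleus[2], 1L)  # exact tie -> lowest label
  expect_true(is.na(got$assigned_nucleus[3]))  # beyond 10 um cap
  expect_equal(got$assigned_nucleus[4], 1L)  # nearest within cap

  empty <- structure(list(labels = matrix(0L, 100, 100),
                          table = data.frame(nucleus = integer(0),
                                             area_px = integer(0),
                                             cx = numeric(0),
                                             cy = numeric(0)),
                          n = 0L), class = "nucleus_label_map")
  none <- assign_spots(spots, empty, 0.5)
  expect_true(all(is.na(none$assigned_nucleus)))
})

test_that("per-nucleus sums include zero rows and conserve total area", {
  labs <- matrix(0L, 50, 50)
  labs[5:10, 5:10] <- 1L
  labs[30:35, 30:35] <- 2L
  nuclei <- structure(list(
    labels = labs,
    table = data.frame(nucleus = 1:2, area_px = 36, cx = c(7.5, 32.5),
                       cy = c(7.5, 32.5)),
    n = 2L), class = "nucleus_label_map")
  spots <- data.frame(spot_id = 1:3, channel = "MINUS",
                      cx = c(7, 8, 45), cy = c(7, 8, 45), area_px = 16L,
                      area_um2 = c(4, 6, 5),
                      assigned_nucleus = c(1L, 1L, NA))
  sig <- per_nucleus_area(spots, nuclei, channels = c("MINUS", "PLUS"))
  pn <- sig$per_nucleus
  expect_equal(pn$area_um2[pn$nucleus == 1 & pn$channel == "MINUS"], 10)
  expect_equal(pn$area_um2[pn$nucleus == 2 & pn$channel == "MINUS"], 0)
  expect_equal(pn$area_um2[pn$channel == "PLUS"], c(0, 0))
  expect_equal(sig$unassigned$area_um2[sig$unassigned$channel == "MINUS"],
               5)
  expect_equal(sum(pn$area_um2) + sum(sig$unassigned$area_um2),
               sum(spots$area_um2))
})

test_that("area conservation holds exactly on randomized scenes", {
  for (s in 1:20) {
    sim <- simulate_basescope_image(random_scene(
      n_nuclei = 6, n_dots = 10, noise_sd = 0.03, seed = 100 + s))
    q <- quantify_image_stack(sim$stack,
                              spot_params = list(threshold = 0.5))
    for (ch in c("MINUS", "PLUS")) {
      detected <- sum(q$spots$area_um2[q$spots$channel == ch])
      assigned <- sum(q$signal$per_nucleus$area_um2[
        q$signal$per_nucleus$channel == ch])
      un <- q$signal$unassigned$area_um2[
        q$signal$unassigned$channel == ch]
      expect_equal(assigned + un, detected, tolerance = 1e-12)
    }
  }
})

test_that("marker-positive nuclei are recovered exactly on clean scenes", {
  sc <- grid_scene(10, marker_positive = rep(c(TRUE, FALSE),
                                             c(4, 6)))
  sim <- simulate_basescope_image(sc)
  seg <- segment_nuclei(sim$stack$channels$DAPI)
  mk <- classify_marker_positive(seg, sim$stack$channels$MARKER)
  expect_equal(mk$fraction, 0.4)
  expect_equal(mk$n_positive, 4L)
  # which nuclei: match segmented labels to scene truth by centroid
  ord <- apply(outer(seg$table$cx, sim$nuclei$cx, function(a, b)
    abs(a - b))^2 + outer(seg$table$cy, sim$nuclei$cy, function(a, b)
      abs(a - b))^2, 1, which.min)
  expect_equal(mk$table$positive, sim$nuclei$marker_positive[ord])
  # exact binomial CI around the fraction
  ref <- binom.test(4, 10)$conf.int
  expect_equal(c(mk$ci_low, mk$ci_high), as.numeric(ref),
               tolerance = 1e-10)
})

test_that("marker classification handles fixed cutoffs and empty maps", {
  sim <- simulate_basescope_image(grid_scene(4))
  seg <- segment_nuclei(sim$stack$channels$DAPI)
  mk <- classify_marker_positive(seg, matrix(0, 200, 200), rule = 0.5)
  expect_equal(mk$fraction, 0)
  empty <- segment_nuclei(matrix(0, 64, 64))
  mk0 <- classify_marker_positive(empty, matrix(0, 64, 64))
  expect_false(mk0$defined)
  expect_true(is.na(mk0$fraction))
})
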