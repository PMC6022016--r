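# Descriptors and windowed variance features: ellipse fitting, the six raw
# measurements, the k-window variance, and their qualitative behaviour on
# simulated falls.

blob_from_mask <- function(mask) {
  extract_person_blob(mask, segmentation_params(min_person_size = 1))
}

test_that("moment fit of an axis-aligned rectangle is vertical with 3:1 axes", {
  m <- matrix(FALSE, 100, 100)
  m[21:80, 41:60] <- TRUE  # h = 60, w = 20
  fit <- fit_ellipse(m)
  expect_equal(fit$theta, 90)
  expect_equal(fit$major_len / fit$minor_len, 3, tolerance = 1e-10)
})

test_that("a disk is isotropic: unit ratio, upright by convention", {
  m <- rasterize_blob(c(80, 80), c(40, 40), c(20, 20), 0)
  fit <- fit_ellipse(m)
  expect_equal(fit$major_len / fit$minor_len, 1, tolerance = 0.02)
  expect_equal(fit$theta, 90)
})

test_that("moment fit recovers the rasterizer's orientation and axis ratio", {
  m <- rasterize_blob(c(200, 200), c(100, 100), c(40, 15), 30)
  fit <- fit_ellipse(m)
  expect_lt(abs(fit$theta - 30), 2)
  expect_lt(abs(fit$major_len / fit$minor_len - 80 / 30) / (80 / 30), 0.05)
  expect_lt(abs(fit$major_len - 80) / 80, 0.05)
})

test_that("ellipse fitting rejects tiny blobs and survives collinear ones", {
  m <- matrix(FALSE, 10, 10); m[3, 3:5] <- TRUE
  expect_error(fit_ellipse(m), "area < 5")
  # a 1-px-wide line: the pixel-extent (1/12) moment correction keeps the
  # minor axis at the single-pixel width, no degenerate zero
  line <- matrix(FALSE, 30, 30); line[5:25, 9] <- TRUE
  fit <- fit_ellipse(line)
  expect_equal(fit$minor_len, 4 * sqrt(1 / 12))
  expect_equal(fit$theta, 90)
})

test_that("person angle is 90 upright, 0 lying, and tracks a simulated fall", {
  vert <- rasterize_blob(c(100, 100), c(50, 50), c(30, 10), 90)
  expect_equal(person_angle(fit_ellipse(vert)), 90, tolerance = 0.5)
  horiz <- rasterize_blob(c(100, 100), c(50, 50), c(30, 10), 0)
  expect_equal(person_angle(fit_ellipse(horiz)), 0, tolerance = 0.5)

  sim <- simulate_sequence(small_spec("fall", seed = 4, noise_sigma = 0))
  desc <- compute_descriptors(sim$sequence)
  action <- which(sim$truth$angle < 90 & sim$truth$angle > 0)
  # measured angle tracks the ground truth within raster tolerance,
  # hence is monotone non-increasing up to that tolerance
  expect_true(all(abs(desc$pa[action] - sim$truth$angle[action]) <= 3))
  expect_true(all(diff(desc$pa[action]) <= 3))
})

test_that("oriented ellipse ratio flips under 90-degree rotation", {
  up <- fit_ellipse(rasterize_blob(c(150, 150), c(75, 75), c(36, 12), 90))
  er_up <- ellipse_ratio(up)
  expect_gt(er_up, 1)
  expect_equal(er_up, 3, tolerance = 0.05)
  flat <- fit_ellipse(rasterize_blob(c(150, 150), c(75, 75), c(36, 12), 0))
  er_flat <- ellipse_ratio(flat)
  expect_equal(er_flat, 1 / er_up, tolerance = 0.01)
  # strict definition never drops below 1
  expect_equal(ellipse_ratio(flat, oriented = FALSE), er_up, tolerance = 0.01)
  disk <- fit_ellipse(rasterize_blob(c(80, 80), c(40, 40), c(20, 20), 0))
  expect_equal(ellipse_ratio(disk), 1, tolerance = 0.02)
})

test_that("upper-half area counts foreground rows above the bbox midline", {
  m <- matrix(FALSE, 60, 60); m[11:50, 21:40] <- TRUE  # solid, h = 40
  expect_equal(upper_half_area(blob_from_mask(m)), 20 * 20)
  # top-heavy T shape holds more than half its mass up top
  tee <- matrix(FALSE, 60, 60)
  tee[11:20, 11:50] <- TRUE   # crossbar: 400 px
  tee[21:50, 28:33] <- TRUE   # stem: 180 px
  b <- blob_from_mask(tee)
  expect_gt(upper_half_area(b), b$area / 2)
})

test_that("upper-half area equals a row-by-row count on random blobs", {
  set.seed(9)
  for (i in 1:10) {
    m <- rasterize_blob(c(70, 90), c(runif(1, 25, 65), runif(1, 20, 50)),
                        c(runif(1, 8, 16), runif(1, 4, 7)), runif(1, 0, 90))
    b <- blob_from_mask(m)
    bb <- b$bbox
    want <- 0
    for (r in bb["y"]:(bb["y"] + ceiling(bb["h"] / 2) - 1))
      want <- want + sum(m[r, ])
    expect_equal(upper_half_area(b), want)
  }
})

test_that("geometric centre averages boundary pixels, not member pixels", {
  one <- matrix(FALSE, 10, 10); one[4, 7] <- TRUE
  b1 <- extract_person_blob(one, segmentation_params(min_person_size = 1))
  expect_equal(geometric_center(b1), c(x = 7, y = 4))
  sq <- matrix(FALSE, 40, 40); sq[11:30, 16:35] <- TRUE
  expect_equal(geometric_center(blob_from_mask(sq)), c(x = 25.5, y = 20.5))
  set.seed(13)
  for (i in 1:5) {
    m <- rasterize_blob(c(60, 60), c(30, 30), c(runif(1, 8, 14), runif(1, 4, 7)),
                        runif(1, 0, 90))
    b <- blob_from_mask(m)
    pts <- oracle_boundary(m)
    expect_equal(geometric_center(b),
                 c(x = mean(pts[, "x"]), y = mean(pts[, "y"])))
  }
})

test_that("motion magnitude is the Euclidean displacement", {
  expect_equal(motion_magnitude(c(0, 0), c(3, 4)), 5)
  expect_equal(motion_magnitude(c(2, 2), c(2, 2)), 0)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(2, -50, 50); b <- runif(2, -50, 50)
    expect_equal(motion_magnitude(a, b), sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2),
                 tolerance = 1e-12)
  }
})

test_that("temporal variance uses denominator k over the trailing window", {
  expect_equal(temporal_variance(rep(3.7, 40), 30), 0)
  expect_equal(temporal_variance(1:30, 30), (30^2 - 1) / 12)
  set.seed(21)
  for (i in 1:25) {
    s <- rnorm(50, sd = 10)
    k <- sample(2:50, 1)
    expect_equal(temporal_variance(s, k), oracle_variance(s, k),
                 tolerance = 1e-9)
  }
  expect_error(temporal_variance(1:5, 10), "shorter")
  # invariant under shift, quadratic under scale
  s <- rnorm(30)
  expect_equal(temporal_variance(s + 17, 30), temporal_variance(s, 30))
  expect_equal(temporal_variance(3 * s, 30), 9 * temporal_variance(s, 30))
})

make_descriptors <- function(n, value = 1) {
  data.frame(frame = seq_len(n), valid = TRUE,
             ar = value, pa = value, er = value, sd = value,
             gcx = value, gcy = value,
             mv = c(0, rep(value, n - 1)),
             mv_defined = c(FALSE, rep(TRUE, n - 1)))
}

test_that("windowing arithmetic: k frames give one vector, k+1 give two", {
  d <- make_descriptors(30)
  fv <- build_feature_vectors(d, window_config(k = 30))
  expect_equal(nrow(fv), 1)
  expect_equal(fv$frame_index, 30)
  expect_true(all(fv[1, grep("^var_", names(fv))] == 0))
  fv2 <- build_feature_vectors(make_descriptors(31), window_config(k = 30))
  expect_equal(fv2$frame_index, c(30, 31))
  expect_error(build_feature_vectors(make_descriptors(20), window_config(k = 30)),
               "fewer than k")
})

test_that("invalid frames are skipped or interpolated per policy", {
  d <- make_descriptors(40, value = 2)
  d[35, c("ar", "pa", "er", "sd", "gcx", "gcy", "mv")] <- NA
  d$valid[35] <- FALSE
  skip_fv <- build_feature_vectors(d, window_config(k = 30, invalid_policy = "skip"))
  expect_false(any(skip_fv$frame_index %in% 35:40))  # windows touching the gap
  interp_fv <- build_feature_vectors(d, window_config(k = 30,
                                                      invalid_policy = "interpolate"))
  expect_true(all(30:40 %in% interp_fv$frame_index))
})

test_that("include_raw appends the current frame's descriptors", {
  d <- make_descriptors(30, value = 5)
  fv <- build_feature_vectors(d, window_config(k = 30, include_raw = TRUE))
  expect_true(all(c("ar", "pa", "er", "sd", "gcx", "gcy", "mv") %in% names(fv)))
  expect_equal(fv$ar, 5)
})

test_that("fall windows dominate walking windows in variance", {
  sim <- simulate_sequence(small_spec("fall", seed = 6))
  fv <- extract_features(sim$sequence, sim$truth)
  onset <- min(which(sim$truth$labels == "fall"))
  walk_max_ar <- max(fv$var_ar[fv$frame_index < onset])
  fall_max_ar <- max(fv$var_ar[fv$label == "fall"])
  expect_gt(fall_max_ar, walk_max_ar)
  expect_gt(max(fv$var_pa[fv$label == "fall"]),
            max(fv$var_pa[fv$frame_index < onset]))
  # every variance feature peaks within k frames of the true onset
  k <- 30
  for (col in grep("^var_", names(fv), value = TRUE)) {
    peak_frame <- fv$frame_index[which.max(fv[[col]])]
    expect_lte(abs(peak_frame - onset), k)
  }
})

test_that("descriptor scale covariance: doubling the view scales sd, mv, gc", {
  p0 <- segmentation_params(distance_floor = 0, erosion_radius = 0,
                            min_person_size = 10)
  frames1 <- list(
    planted_frame(rasterize_blob(c(90, 120), c(40, 60), c(15, 5), 70)),
    planted_frame(rasterize_blob(c(90, 120), c(43, 62), c(15, 5), 70)))
  frames2 <- list(
    planted_frame(rasterize_blob(c(180, 240), c(80, 120), c(30, 10), 70)),
    planted_frame(rasterize_blob(c(180, 240), c(86, 124), c(30, 10), 70)))
  s1 <- structure(list(frames = frames1, fps = 30,
                       background = matrix(120, 90, 120)),
                  class = "frame_sequence")
  s2 <- structure(list(frames = frames2, fps = 30,
                       background = matrix(180 * 0 + 120, 180, 240)),
                  class = "frame_sequence")
  d1 <- compute_descriptors(s1, p0)
  d2 <- compute_descriptors(s2, p0)
  expect_equal(d2$ar, d1$ar, tolerance = 0.1)        # scale-free (raster jitter)
  expect_equal(d2$pa, d1$pa, tolerance = 2)          # scale-free
  expect_equal(d2$er, d1$er, tolerance = 0.1)        # scale-invariant by design
  expect_equal(d2$sd, 4 * d1$sd, tolerance = 0.05)   # area scales as s^2
  expect_equal(d2$gcx, 2 * d1$gcx, tolerance = 0.02) # positions scale as s
  expect_equal(d2$mv[2], 2 * d1$mv[2], tolerance = 0.05)
})

test_that("bounding-box aspect ratio inverts under 90-degree rotation", {
  m <- matrix(FALSE, 100, 100); m[31:70, 46:55] <- TRUE  # 10 x 40
  ar1 <- with(as.list(blob_from_mask(m)$bbox), w / h)
  mt <- matrix(FALSE, 100, 100); mt[46:55, 31:70] <- TRUE
  ar2 <- with(as.list(blob_from_mask(mt)$bbox), w / h)
  expect_equal(ar2, 1 / ar1)
})
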