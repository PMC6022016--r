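# Per-frame motion/geometry descriptors and their temporal variances over a
# sliding k-frame window. Six raw measurements are taken from each segmented
# person blob -- bounding-box aspect ratio (ar), fitted-ellipse person angle
# (pa) and axis ratio (er), upper-half bounding-box foreground area (sd),
# boundary geometric centre (gcx, gcy) and centroid motion magnitude (mv) --
# and the classifier consumes their variances over the trailing k frames
# (k = 30, one second at 30 fps).

#' Fit an ellipse to a person blob by second-order moments
#'
#' Central moments of the blob mask (with the 1/12 per-pixel correction for
#' pixel extent) give the orientation `theta = 0.5 * atan2(2*mu11,
#' mu20 - mu02)` and the axis lengths `4 * sqrt(eigenvalue)` (full-length
#' convention, exact for a uniformly filled ellipse). `theta` is the
#' major-axis angle from the horizontal x-axis, folded into `[0, 90]`
#' degrees; an isotropic blob (disk) is assigned 90 degrees by convention.
#'
#' @param blob a `person_blob`, or a logical mask matrix.
#' @return object of class `ellipse_fit` with fields `center` (x, y),
#'   `major_len`, `minor_len` (full axis lengths, px) and `theta` (degrees).
#' @export
fit_ellipse <- function(blob) {
  mask <- if (inherits(blob, "person_blob")) blob$mask else blob
  px <- which(mask, arr.ind = TRUE)
  n <- nrow(px)
  if (n < 5L) stop("blob too small for ellipse fitting (area < 5 px)")
  x <- px[, 2]; y <- px[, 1]
  mx <- mean(x); my <- mean(y)
  # 1/12 term: variance of a unit pixel about its own centre
  mu20 <- mean((x - mx)^2) + 1 / 12
  mu02 <- mean((y - my)^2) + 1 / 12
  mu11 <- mean((x - mx) * (y - my))

  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  major <- 4 * sqrt(max(l1, 0))
  minor <- 4 * sqrt(max(l2, 0))
  if (minor < 1) {
    warning("degenerate (near-collinear) blob; minor axis clamped to 1 px")
    minor <- 1
  }

  eps <- 1e-9
  if (abs(mu20 - mu02) < eps && abs(mu11) < eps) {
    theta <- 90  # isotropic: no preferred axis, treat as upright
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
    theta <- abs(theta)  # fold into [0, 90]: left/right tilt merged
  }
  structure(list(center = c(x = mx, y = my),
                 major_len = major, minor_len = minor, theta = theta),
            class = "ellipse_fit")
}

#' Person angle from an ellipse fit
#'
#' Angle between the fitted major axis and the horizontal image axis:
#' about 90 degrees for an upright person, tending to 0 when lying.
#'
#' @param fit an `ellipse_fit`.
#' @return angle in degrees, in `[0, 90]`.
#' @export
person_angle <- function(fit) fit$theta

#' Ellipse axis ratio
#'
#' With `oriented = TRUE` (default) the ratio is the length of the axis
#' whose direction lies within 45 degrees of vertical divided by the other
#' axis length, so a standing person gives er > 1 and a fallen person
#' er < 1 (e.g. about 2 upright, about 0.4 lying for a 2:1 body). With
#' `oriented = FALSE` the strict major/minor ratio (always >= 1) is
#' returned.
#'
#' @param fit an `ellipse_fit`.
#' @param oriented use the orientation-signed definition (default TRUE).
#' @return dimensionless ratio.
#' @export
ellipse_ratio <- function(fit, oriented = TRUE) {
  if (fit$minor_len <= 0) stop("minor axis length must be positive")
  if (!oriented) return(fit$major_len / fit$minor_len)
  if (fit$theta >= 45) fit$major_len / fit$minor_len
  else fit$minor_len / fit$major_len
}

#' Foreground area of the upper half of the bounding box
#'
#' The bounding box is split into two halves at row `y + ceiling(h/2)`; for
#' odd heights the upper half gets the extra row. Returns the count of
#' foreground pixels in the upper half.
#'
#' @param blob a `person_blob`.
#' @return pixel count.
#' @export
upper_half_area <- function(blob) {
  bb <- blob$bbox
  top <- bb["y"]
  rows <- top:(top + ceiling(bb["h"] / 2) - 1)
  sum(blob$mask[rows, , drop = FALSE])
}

#' Geometric centre of a blob's boundary
#'
#' Mean of the x- and y-coordinates of the blob's boundary (edge) pixels --
#' boundary pixels, not all member pixels, which distinguishes this from the
#' centroid.
#'
#' @param blob a `person_blob`.
#' @return named vector `(x, y)`.
#' @export
geometric_center <- function(blob) {
  if (nrow(blob$boundary) < 1L) stop("blob has no boundary points")
  c(x = mean(blob$boundary[, "x"]), y = mean(blob$boundary[, "y"]))
}

#' Motion magnitude between consecutive centroids
#'
#' Euclidean norm of the centroid displacement between two frames,
#' in px/frame.
#'
#' @param prev_centroid,centroid `(x, y)` positions.
#' @return non-negative scalar.
#' @export
motion_magnitude <- function(prev_centroid, centroid) {
  sqrt(sum((centroid - prev_centroid)^2))
}

#' Temporal variance over the trailing window
#'
#' Population-style variance with denominator exactly `k` (not `k - 1`),
#' computed over the `k` most recent values of the series.
#'
#' @param series numeric vector (most recent value last).
#' @param k window length (>= 2).
#' @return sigma^2, non-negative.
#' @export
temporal_variance <- function(series, k) {
  if (k < 2) stop("window length k must be >= 2")
  if (length(series) < k) stop("series shorter than window length k")
  w <- series[(length(series) - k + 1):length(series)]
  mu <- mean(w)
  sum((w - mu)^2) / k
}

#' Sliding-window configuration
#'
#' @param k window length in frames (default 30, one second at 30 fps).
#' @param step window stride in frames (default 1).
#' @param invalid_policy how to treat windows containing frames in which no
#'   person was found: `"skip"` emits no vector; `"interpolate"` linearly
#'   fills gaps of up to 3 frames and skips otherwise.
#' @param include_raw append the current frame's six raw descriptors to each
#'   feature vector (default FALSE: variances only).
#' @param use_sd report standard deviations instead of variances.
#' @return object of class `window_config`.
#' @export
window_config <- function(k = 30L, step = 1L,
                          invalid_policy = c("skip", "interpolate"),
                          include_raw = FALSE, use_sd = FALSE) {
  if (k < 2) stop("k must be >= 2")
  if (step < 1) stop("step must be >= 1")
  structure(list(k = as.integer(k), step = as.integer(step),
                 invalid_policy = match.arg(invalid_policy),
                 include_raw = include_raw, use_sd = use_sd),
            class = "window_config")
}

#' Per-frame descriptors for a whole sequence
#'
#' Segments each frame and computes the six raw measurements. Frames in
#' which no person blob survives are marked invalid (`valid = FALSE`, NA
#' measurements). The motion magnitude of the first valid frame (or of a
#' valid frame whose predecessor is invalid) is 0 by convention and flagged
#' via `mv_defined = FALSE`.
#'
#' @param sequence a `frame_sequence`.
#' @param params a [segmentation_params()].
#' @param background optional background matrix (takes precedence over the
#'   sequence's own background and the temporal-median estimate).
#' @param oriented_er passed to [ellipse_ratio()].
#' @return data.frame with columns `frame`, `valid`, `ar`, `pa`, `er`, `sd`,
#'   `gcx`, `gcy`, `mv`, `mv_defined`.
#' @export
compute_descriptors <- function(sequence, params = segmentation_params(),
                                background = NULL, oriented_er = TRUE) {
  blobs <- segment_sequence(sequence, params, background)
  n <- length(blobs)
  out <- data.frame(frame = seq_len(n), valid = FALSE,
                    ar = NA_real_, pa = NA_real_, er = NA_real_,
                    sd = NA_real_, gcx = NA_real_, gcy = NA_real_,
                    mv = NA_real_, mv_defined = FALSE)
  prev_centroid <- NULL
  for (t in seq_len(n)) {
    b <- blobs[[t]]
    if (is.null(b)) { prev_centroid <- NULL; next }
    fit <- fit_ellipse(b)
    gc <- geometric_center(b)
    out$valid[t] <- TRUE
    out$ar[t] <- b$bbox[["w"]] / b$bbox[["h"]]
    out$pa[t] <- person_angle(fit)
    out$er[t] <- ellipse_ratio(fit, oriented = oriented_er)
    out$sd[t] <- upper_half_area(b)
    out$gcx[t] <- gc[["x"]]
    out$gcy[t] <- gc[["y"]]
    if (!is.null(prev_centroid)) {
      out$mv[t] <- motion_magnitude(prev_centroid, b$centroid)
      out$mv_defined[t] <- TRUE
    } else {
      out$mv[t] <- 0
    }
    prev_centroid <- b$centroid
  }
  out
}

descriptor_cols <- c("ar", "pa", "er", "sd", "gcx", "gcy")

#' Build feature vectors from per-frame descriptors
#'
#' One feature vector per window end position `frame_index = k, k + step,
#' ...` (warm-up frames emit nothing), holding the seven temporal variances
#' `var_ar`, `var_pa`, `var_mv`, `var_sd`, `var_gcx`, `var_gcy`, `var_er`
#' over the trailing `k` frames. The geometric centre contributes its x and
#' y variances separately. The motion variance is computed over the window
#' frames whose `mv` is defined (its denominator is the number of values
#' used). Windows containing invalid frames follow
#' `config$invalid_policy`.
#'
#' @param descriptors data.frame from [compute_descriptors()].
#' @param config a [window_config()].
#' @return data.frame of feature vectors with a `frame_index` column.
#' @export
build_feature_vectors <- function(descriptors, config = window_config()) {
  k <- config$k
  n <- nrow(descriptors)
  if (n < k)
    stop("fewer than k = ", k, " frames of descriptors (got ", n, ")")

  d <- descriptors
  if (config$invalid_policy == "interpolate" && any(!d$valid)) {
    for (col in c(descriptor_cols, "mv")) {
      d[[col]] <- zoo::na.approx(d[[col]], maxgap = 3, na.rm = FALSE)
    }
    filled <- stats::complete.cases(d[c(descriptor_cols, "mv")])
    d$mv_defined <- d$mv_defined | (filled & !d$valid)
    d$valid <- filled
  }

  ends <- seq(k, n, by = config$step)
  rows <- vector("list", length(ends))
  for (i in seq_along(ends)) {
    t <- ends[i]
    win <- (t - k + 1):t
    if (!all(d$valid[win])) next
    v <- vapply(descriptor_cols, function(col)
      temporal_variance(d[[col]][win], k), numeric(1))
    mvs <- d$mv[win][d$mv_defined[win]]
    var_mv <- if (length(mvs) >= 2) temporal_variance(mvs, length(mvs)) else 0
    row <- c(var_ar = v[["ar"]], var_pa = v[["pa"]], var_mv = var_mv,
             var_sd = v[["sd"]], var_gcx = v[["gcx"]], var_gcy = v[["gcy"]],
             var_er = v[["er"]])
    if (config$use_sd) row <- sqrt(row)
    if (config$include_raw) {
      raw <- unlist(d[t, c(descriptor_cols, "mv")])
      names(raw) <- c(descriptor_cols, "mv")
      row <- c(row, raw)
    }
    rows[[i]] <- c(row, frame_index = t)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    nm <- c(paste0("var_", c("ar", "pa", "mv", "sd", "gcx", "gcy", "er")),
            if (config$include_raw) c(descriptor_cols, "mv"), "frame_index")
    out <- as.data.frame(matrix(numeric(0), 0, length(nm)))
    names(out) <- nm
    return(out)
  }
  as.data.frame(do.call(rbind, rows))
}

#' Descriptors and labelled feature vectors for one sequence
#'
#' Convenience wrapper: segments the sequence, computes descriptors and
#' window variances, and (when ground truth is supplied) attaches the label
#' of the frame each window ends at.
#'
#' @param sequence a `frame_sequence`.
#' @param truth optional `ground_truth` (or a character vector of per-frame
#'   labels).
#' @param params a [segmentation_params()].
#' @param config a [window_config()].
#' @param background optional background matrix.
#' @return feature data.frame, with a `label` column when truth is given.
#' @export
extract_features <- function(sequence, truth = NULL,
                             params = segmentation_params(),
                             config = window_config(),
                             background = NULL) {
  desc <- compute_descriptors(sequence, params, background)
  fv <- build_feature_vectors(desc, config)
  if (!is.null(truth)) {
    labels <- if (inherits(truth, "ground_truth")) truth$labels else truth
    fv$label <- labels[fv$frame_index]
  }
  fv
}
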