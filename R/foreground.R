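# Person segmentation: background subtraction with a per-pixel relative
# threshold, distance-transform noise suppression, morphology, and
# connected-component filtering at a minimum person size.

#' Segmentation parameters
#'
#' @param change_fraction per-pixel relative change threshold; a pixel is
#'   foreground when its absolute difference from the background exceeds this
#'   fraction of the background pixel value (default 0.15, i.e. 15%).
#' @param distance_floor minimum Euclidean distance-transform value (px) a
#'   changed pixel must have to survive; removes thin/noisy structures.
#'   0 disables the filter.
#' @param erosion_radius radius (px) of the disc structuring element used for
#'   erosion; 0 disables erosion.
#' @param min_person_size minimum connected-component area. Values < 1 are
#'   interpreted as a fraction of the frame area (default 0.005, i.e. 0.5%);
#'   values >= 1 as an absolute pixel count.
#' @param connectivity 4 or 8 (default 8).
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(change_fraction = 0.15,
                                distance_floor = 2,
                                erosion_radius = 1,
                                min_person_size = 0.005,
                                connectivity = 8L) {
  if (change_fraction <= 0 || change_fraction >= 1)
    stop("change_fraction must be in (0, 1)")
  if (min_person_size <= 0) stop("min_person_size must be > 0")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(change_fraction = change_fraction,
                 distance_floor = distance_floor,
                 erosion_radius = erosion_radius,
                 min_person_size = min_person_size,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

min_size_pixels <- function(params, frame_dim) {
  if (params$min_person_size < 1)
    params$min_person_size * prod(frame_dim)
  else
    params$min_person_size
}

#' Estimate a clean background frame
#'
#' Pixel-wise temporal median of the first `n_frames` frames. Robust to a
#' moving person as long as each pixel is person-free in more than half of
#' the sampled frames. A user-supplied background image, when available,
#' should be preferred over this estimate.
#'
#' @param frames a `frame_sequence` or a list of equal-size matrices.
#' @param n_frames how many leading frames to use (clipped to the sequence
#'   length).
#' @return an intensity matrix with the dimensions of the input frames.
#' @export
estimate_background <- function(frames, n_frames = 60L) {
  if (inherits(frames, "frame_sequence")) frames <- frames$frames
  if (length(frames) == 0L) stop("empty sequence")
  n <- min(n_frames, length(frames))
  stack <- vapply(frames[seq_len(n)], as.numeric,
                  numeric(length(frames[[1]])))
  med <- apply(stack, 1L, median)
  matrix(med, nrow(frames[[1]]), ncol(frames[[1]]))
}

#' Detect changed pixels against the background
#'
#' A pixel is flagged when `|frame - background|` exceeds `change_fraction`
#' times that pixel's background value (floored at 1 intensity unit to avoid
#' a degenerate zero threshold on black backgrounds).
#'
#' @param frame,background intensity matrices of identical dimensions.
#' @param change_fraction relative threshold (default 0.15).
#' @return logical change mask.
#' @export
detect_change <- function(frame, background, change_fraction = 0.15) {
  if (!identical(dim(frame), dim(background)))
    stop("dimension mismatch between frame and background")
  abs(frame - background) > change_fraction * pmax(background, 1)
}

#' Refine a change mask: distance transform, erosion, hole filling
#'
#' In order: the Euclidean distance transform is computed inside the changed
#' region and pixels closer than `distance_floor` to the background are
#' dropped (suppressing thin noise); the mask is eroded with a disc of radius
#' `erosion_radius`; interior holes are filled (flood fill from the frame
#' border on the complement).
#'
#' @param change_mask logical/binary matrix.
#' @param params a [segmentation_params()].
#' @return refined logical mask.
#' @export
refine_mask <- function(change_mask, params = segmentation_params()) {
  m <- matrix(as.numeric(change_mask), nrow(change_mask), ncol(change_mask))
  if (!any(m > 0)) return(m > 0)
  if (params$distance_floor > 0) {
    d <- EBImage::distmap(m)
    m[d < params$distance_floor] <- 0
  }
  if (params$erosion_radius > 0 && any(m > 0)) {
    m <- EBImage::erode(m, disc_kernel(params$erosion_radius))
  }
  if (any(m > 0)) m <- EBImage::fillHull(m)
  matrix(m > 0.5, nrow(change_mask), ncol(change_mask))
}

# Label connected components. EBImage::bwlabel is 4-connected; for
# 8-connectivity, labels that touch diagonally are merged with union-find.
label_components <- function(mask, connectivity = 8L) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (connectivity == 4L || nlab <= 1L) return(lab)

  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # diagonal down-right
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # diagonal down-left
  pairs <- rbind(
    cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
    cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2]))
  if (nrow(pairs) > 0) {
    parent <- seq_len(nlab)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(nrow(pairs))) {
      ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    roots <- vapply(seq_len(nlab), find, integer(1))
    relabel <- match(roots, sort(unique(roots)))
    nz <- lab > 0
    lab[nz] <- relabel[lab[nz]]
  }
  lab
}

# Inner boundary: component pixels with at least one 4-neighbour outside the
# component (frame border counts as outside).
boundary_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  up <- rbind(FALSE, mask[-nr, , drop = FALSE])
  down <- rbind(mask[-1, , drop = FALSE], FALSE)
  left <- cbind(FALSE, mask[, -nc, drop = FALSE])
  right <- cbind(mask[, -1, drop = FALSE], FALSE)
  mask & !(up & down & left & right)
}

#' Extract the person blob from a refined mask
#'
#' Connected components are labelled at the configured connectivity;
#' components smaller than the minimum person size are discarded (frames not
#' containing a full person are skipped downstream); among the survivors the
#' largest is returned. If more than one component survives, a warning is
#' emitted since the pipeline assumes a single person.
#'
#' @param mask logical/binary matrix.
#' @param params a [segmentation_params()].
#' @return a `person_blob` (fields `mask`, `bbox` = `(x, y, w, h)` with
#'   1-based top-left origin, `centroid` = `(x, y)` mean of member pixels,
#'   `boundary` = n x 2 matrix of boundary pixel `(x, y)`, `area`), or `NULL`
#'   when no component survives.
#' @export
extract_person_blob <- function(mask, params = segmentation_params()) {
  if (!any(mask)) return(NULL)
  lab <- label_components(mask, params$connectivity)
  areas <- tabulate(lab[lab > 0])
  min_size <- min_size_pixels(params, dim(mask))
  survivors <- which(areas >= min_size)
  if (length(survivors) == 0L) return(NULL)
  if (length(survivors) > 1L)
    warning("multiple components exceed the minimum person size; ",
            "keeping the largest")
  keep <- survivors[which.max(areas[survivors])]
  bm <- lab == keep

  px <- which(bm, arr.ind = TRUE)  # (row, col)
  rows <- range(px[, 1]); cols <- range(px[, 2])
  bnd <- which(boundary_mask(bm), arr.ind = TRUE)
  structure(list(
    mask = bm,
    bbox = c(x = cols[1], y = rows[1],
             w = cols[2] - cols[1] + 1L, h = rows[2] - rows[1] + 1L),
    centroid = c(x = mean(px[, 2]), y = mean(px[, 1])),
    boundary = cbind(x = bnd[, 2], y = bnd[, 1]),
    area = nrow(px)
  ), class = "person_blob")
}

#' Segment the person in a single frame
#'
#' Composition of [detect_change()], [refine_mask()] and
#' [extract_person_blob()].
#'
#' @inheritParams detect_change
#' @param params a [segmentation_params()].
#' @return a `person_blob` or `NULL`.
#' @export
segment_frame <- function(frame, background, params = segmentation_params()) {
  ch <- detect_change(frame, background, params$change_fraction)
  extract_person_blob(refine_mask(ch, params), params)
}

#' Segment every frame of a sequence
#'
#' @param sequence a `frame_sequence`.
#' @param params a [segmentation_params()].
#' @param background optional background matrix; defaults to the sequence's
#'   own background if present, otherwise a temporal-median estimate.
#' @return list of `person_blob`/`NULL`, one per frame.
#' @export
segment_sequence <- function(sequence, params = segmentation_params(),
                             background = NULL) {
  bg <- background %||% sequence$background %||% estimate_background(sequence)
  lapply(sequence$frames, segment_frame, background = bg, params = params)
}
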