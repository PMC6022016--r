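# Disk formats: numbered PNG frame directories with labels.csv and
# background.png, blob summary CSVs, and pipeline configs (YAML).

#' Write a simulated sequence to a frame directory
#'
#' Frames go to `frame_%05d.png` (8-bit grayscale), the background to
#' `background.png`, and per-frame labels (when ground truth is given) to
#' `labels.csv` with columns `frame_index, label`.
#'
#' @param sequence a `frame_sequence`.
#' @param dir output directory (created if missing).
#' @param truth optional `ground_truth`.
#' @return `dir`, invisibly.
#' @export
write_sequence <- function(sequence, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(sequence$frames)) {
    png::writePNG(sequence$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%05d.png", i)))
  }
  if (!is.null(sequence$background))
    png::writePNG(sequence$background / 255, file.path(dir, "background.png"))
  if (!is.null(truth)) {
    labels <- if (inherits(truth, "ground_truth")) truth$labels else truth
    utils::write.csv(
      data.frame(frame_index = seq_along(labels), label = labels),
      file.path(dir, "labels.csv"), row.names = FALSE)
  }
  invisible(dir)
}

read_frame_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
         else as.array(EBImage::readImage(path))
  if (length(dim(img)) == 3L) {
    # ITU-R 601 luma for colour input
    img <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  }
  if (!grepl("\\.png$", path, ignore.case = TRUE)) img <- t(img)
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Load a frame-directory dataset
#'
#' Reads numbered image frames (sorted by their numeric index), an optional
#' `background.png`, and an optional `labels.csv`. Layout `"frames"` expects
#' the files written by [write_sequence()]; `"mcf-like"` and `"urfd-like"`
#' accept any `<anything><number>.png/.jpg` naming, as used by the public
#' fall-detection frame dumps (the data itself is not bundled).
#'
#' @param path directory containing the frames.
#' @param layout one of `"frames"`, `"mcf-like"`, `"urfd-like"`.
#' @param fps frame rate to record on the sequence (default 30).
#' @return a list with `sequence` (class `frame_sequence`) and `labels`
#'   (per-frame character vector, `"unknown"` when no labels file exists).
#' @export
load_frame_dataset <- function(path, layout = c("frames", "mcf-like", "urfd-like"),
                               fps = 30) {
  layout <- match.arg(layout)
  if (!dir.exists(path)) stop("directory does not exist: ", path)
  pattern <- if (layout == "frames") "^frame_([0-9]+)\\.png$"
             else "^.*?([0-9]+)\\.(png|jpg|jpeg)$"
  files <- list.files(path, full.names = FALSE)
  files <- files[grepl(pattern, files, ignore.case = TRUE)]
  if (length(files) == 0L) stop("no frames found in ", path)
  idx <- as.integer(sub(pattern, "\\1", files, ignore.case = TRUE))
  ord <- order(idx)
  files <- files[ord]; idx <- idx[ord]
  expected <- seq(min(idx), max(idx))
  if (!identical(idx, expected)) {
    stop("gap in frame numbering; missing indices: ",
         paste(setdiff(expected, idx), collapse = ", "))
  }
  frames <- lapply(file.path(path, files), read_frame_image)

  bg_path <- file.path(path, "background.png")
  background <- if (file.exists(bg_path)) read_frame_image(bg_path)

  labels_path <- file.path(path, "labels.csv")
  labels <- if (file.exists(labels_path)) {
    lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
    if (!all(c("frame_index", "label") %in% names(lab)))
      stop("unreadable labels: labels.csv needs frame_index and label columns")
    out <- rep("unknown", length(frames))
    out[lab$frame_index - min(idx) + 1L] <- lab$label
    out
  } else rep("unknown", length(frames))

  list(sequence = structure(list(frames = frames, fps = fps,
                                 background = background),
                            class = "frame_sequence"),
       labels = labels)
}

#' Write per-frame blob summaries as CSV
#'
#' One row per frame: `frame_index, x, y, w, h, cx, cy, area` (NA rows for
#' frames without a person blob).
#'
#' @param blobs list of `person_blob`/`NULL` from [segment_sequence()].
#' @param path output CSV path.
#' @return the summary data.frame, invisibly.
#' @export
write_blob_summary <- function(blobs, path) {
  rows <- lapply(seq_along(blobs), function(i) {
    b <- blobs[[i]]
    if (is.null(b))
      data.frame(frame_index = i, x = NA, y = NA, w = NA, h = NA,
                 cx = NA, cy = NA, area = NA)
    else
      data.frame(frame_index = i, x = b$bbox[["x"]], y = b$bbox[["y"]],
                 w = b$bbox[["w"]], h = b$bbox[["h"]],
                 cx = b$centroid[["x"]], cy = b$centroid[["y"]],
                 area = b$area)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
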