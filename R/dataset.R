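# Dataset plumbing: label-aware augmentation and PNG/CSV round-tripping.

#' Horizontal flip of a scan and its annotation
#'
#' Mirrors the columns (`x -> width - 1 - x`) and swaps the left/right labels,
#' because the mirrored left extreme becomes the right extreme. Applying the
#' flip twice restores the original pair.
#'
#' @param scan a [bscan()].
#' @param ann an [annotation()].
#' @return `list(scan, ann)` with the flipped image and relabelled points.
#' @export
augment_hflip <- function(scan, ann) {
  stopifnot(inherits(scan, "bscan"), inherits(ann, "annotation"))
  w <- ncol(scan$pixels)
  flipped <- scan$pixels[, w:1, drop = FALSE]
  new_left <- c(w - 1 - ann$right[["x"]], ann$right[["y"]])
  new_right <- c(w - 1 - ann$left[["x"]], ann$left[["y"]])
  list(scan = bscan(flipped, scan$patient_id, scan$frame_index),
       ann = annotation(new_left, new_right))
}

#' Translate a scan and its annotation
#'
#' Shifts the image by `(dx, dy)` pixels with edge-replicated fill and moves
#' both annotated points accordingly. A shift that would push either point
#' outside the image is rejected.
#'
#' @param scan a [bscan()].
#' @param ann an [annotation()].
#' @param dx,dy integer shift in pixels (positive = right/down).
#' @return `list(scan, ann)`.
#' @export
augment_shift <- function(scan, ann, dx, dy) {
  stopifnot(inherits(scan, "bscan"), inherits(ann, "annotation"))
  h <- nrow(scan$pixels); w <- ncol(scan$pixels)
  for (p in list(ann$left, ann$right)) {
    nx <- p[["x"]] + dx; ny <- p[["y"]] + dy
    if (nx < 0 || nx > w - 1 || ny < 0 || ny > h - 1)
      stop("shift (", dx, ", ", dy, ") pushes an annotated point out of bounds")
  }
  src_x <- pmin(pmax(seq_len(w) - dx, 1L), w)
  src_y <- pmin(pmax(seq_len(h) - dy, 1L), h)
  shifted <- scan$pixels[src_y, src_x, drop = FALSE]
  list(scan = bscan(shifted, scan$patient_id, scan$frame_index),
       ann = annotation(ann$left + c(dx, dy), ann$right + c(dx, dy)))
}

#' Write a list of patient series to disk
#'
#' Images are stored as 8-bit grayscale PNG under `<dir>/images/`; all
#' annotations go into one `manifest.csv` with columns `patient_id`,
#' `frame_index`, `image_path`, `left_x`, `left_y`, `right_x`, `right_y`.
#'
#' @param series_list list of `patient_series` objects.
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_dataset <- function(series_list, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (series in series_list) {
    stopifnot(inherits(series, "patient_series"))
    for (item in series$scans) {
      scan <- item$scan; ann <- item$ann
      rel <- file.path("images", sprintf("%s_%03d.png", scan$patient_id,
                                         scan$frame_index))
      png::writePNG(scan$pixels / 255, file.path(dir, rel))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = scan$patient_id, frame_index = scan$frame_index,
        image_path = rel,
        left_x = ann$left[["x"]], left_y = ann$left[["y"]],
        right_x = ann$right[["x"]], right_y = ann$right[["y"]])
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' `read_dataset(write_dataset(x))` is the identity on images and
#' annotations. An empty or manifest-less directory yields an empty list;
#' malformed manifest rows and missing image files raise errors naming the
#' offending row.
#'
#' @param dir dataset directory.
#' @return List of `patient_series` objects.
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) return(list())
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  required <- c("patient_id", "frame_index", "image_path",
                "left_x", "left_y", "right_x", "right_y")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols))
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "))
  series <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    coords <- unlist(row[c("left_x", "left_y", "right_x", "right_y")])
    if (any(is.na(suppressWarnings(as.numeric(coords)))) ||
        any(as.numeric(coords) != round(as.numeric(coords))))
      stop("manifest row ", i, ": non-integer coordinates")
    img_path <- file.path(dir, row$image_path)
    if (!file.exists(img_path))
      stop("manifest row ", i, ": image file not found: ", row$image_path)
    px <- round(png::readPNG(img_path) * 255)
    if (length(dim(px)) == 3L) px <- px[, , 1L]
    item <- list(scan = bscan(px, row$patient_id, row$frame_index),
                 ann = annotation(c(row$left_x, row$left_y),
                                  c(row$right_x, row$right_y)))
    pid <- as.character(row$patient_id)
    if (is.null(series[[pid]]))
      series[[pid]] <- structure(list(patient_id = pid, scans = list(),
                                      d_max = NA_integer_),
                                 class = "patient_series")
    series[[pid]]$scans[[length(series[[pid]]$scans) + 1L]] <- item
  }
  unname(series)
}

# flatten patient series into the list(scan, ann) pairs used for training
#' Flatten patient series into training pairs
#' @param series_list list of `patient_series`.
#' @return List of `list(scan, ann)` pairs over all frames.
#' @export
dataset_pairs <- function(series_list) {
  do.call(c, lapply(series_list, function(s) s$scans))
}
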