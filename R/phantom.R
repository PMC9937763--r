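#' Configuration for the synthetic OCT B-scan phantom generator
#'
#' The phantom emulates the structures the localization method relies on:
#' stacked bright retinal bands on a dark vitreous background, one dark
#' dome-shaped fluid pocket (a neurosensory detachment) whose flat base
#' chord sits on a band, multiplicative speckle noise, and ground-truth
#' boundary points at the dome's lateral extremes. Across the frames of one
#' patient the chord diameter follows a chord-of-sphere profile, so central
#' frames show the largest lesion.
#'
#' @param image_height,image_width image size in pixels.
#' @param n_frames_per_patient number of B-scan frames per patient stack.
#' @param lesion_max_diameter_range `c(min, max)` range (pixels) the
#'   patient-level maximum chord diameter is drawn from.
#' @param lesion_height_range `c(min, max)` dome height range in pixels.
#' @param band_intensity_levels grayscale means (0-255) of the bright bands,
#'   listed top to bottom.
#' @param speckle_sigma unitless scale of the multiplicative speckle model
#'   `I * (1 + sigma * eps)`, `eps ~ N(0, 1)`; 0 disables noise.
#' @param background_level grayscale mean (0-255) of the vitreous background;
#'   the fluid pocket is rendered at this level.
#' @param seed integer seed making every derived dataset reproducible.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(image_height = 128L, image_width = 128L,
                           n_frames_per_patient = 24L,
                           lesion_max_diameter_range = c(24L, 60L),
                           lesion_height_range = c(10L, 22L),
                           band_intensity_levels = c(170, 210, 150),
                           speckle_sigma = 0.2,
                           background_level = 20,
                           seed = 1L) {
  cfg <- list(image_height = as.integer(image_height),
              image_width = as.integer(image_width),
              n_frames_per_patient = as.integer(n_frames_per_patient),
              lesion_max_diameter_range = as.integer(lesion_max_diameter_range),
              lesion_height_range = as.integer(lesion_height_range),
              band_intensity_levels = as.numeric(band_intensity_levels),
              speckle_sigma = as.numeric(speckle_sigma),
              background_level = as.numeric(background_level),
              seed = as.integer(seed))
  stopifnot(cfg$image_height >= 32L, cfg$image_width >= 16L,
            cfg$n_frames_per_patient >= 1L,
            length(cfg$lesion_max_diameter_range) == 2L,
            length(cfg$lesion_height_range) == 2L,
            all(cfg$band_intensity_levels >= 0),
            all(cfg$band_intensity_levels <= 255),
            cfg$speckle_sigma >= 0,
            cfg$background_level >= 0, cfg$background_level <= 255)
  if (cfg$lesion_max_diameter_range[2] > cfg$image_width - 2L)
    stop("lesion_max_diameter_range exceeds image_width - 2")
  class(cfg) <- "phantom_config"
  cfg
}

#' Construct a B-scan object
#'
#' @param pixels numeric matrix of grayscale intensities in \[0, 255\],
#'   rows = y (top to bottom), columns = x.
#' @param patient_id,frame_index identity of the scan within a patient stack.
#' @return A list of class `bscan`.
#' @export
bscan <- function(pixels, patient_id = "anon", frame_index = 0L) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L,
            frame_index >= 0L)
  structure(list(pixels = pixels, patient_id = as.character(patient_id),
                 frame_index = as.integer(frame_index)),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan %s/frame %d: %d x %d px, range [%g, %g]>\n",
              x$patient_id, x$frame_index, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a keypoint annotation
#'
#' Coordinates are 0-based with `x` = column and `y` = row, origin at the
#' image's top-left corner; this convention is used uniformly throughout the
#' package.
#'
#' @param left,right numeric `c(x, y)` integer pixel coordinates of the left
#'   and right lesion boundary points; `left[1] < right[1]` is required.
#' @return A list of class `annotation`.
#' @export
annotation <- function(left, right) {
  left <- as.numeric(left); right <- as.numeric(right)
  stopifnot(length(left) == 2L, length(right) == 2L)
  if (left[1] >= right[1]) stop("left point must lie strictly left of right point")
  structure(list(left = c(x = left[1], y = left[2]),
                 right = c(x = right[1], y = right[2])),
            class = "annotation")
}

# internal geometry shared by single scans and patient series
phantom_geometry <- function(cfg) {
  h <- cfg$image_height
  n_bands <- length(cfg$band_intensity_levels)
  block_h <- max(3L * n_bands, round(0.42 * h))
  r0 <- round((h - block_h) / 2)
  r1 <- r0 + block_h - 1L
  base_margin <- max(3L, round(0.12 * block_h))
  list(r0 = r0, r1 = r1, block_h = block_h,
       base_y = r1 - base_margin)
}

#' Generate one synthetic B-scan with a lesion of a given chord diameter
#'
#' Bright horizontal bands are drawn over the dark background; a dark
#' half-ellipse dome of the requested chord diameter is carved into the band
#' block, its flat base resting on a band row. The annotation returns the two
#' chord endpoints. Speckle noise is applied multiplicatively and the image
#' clipped to \[0, 255\] and rounded to 8-bit levels.
#'
#' @param config a [phantom_config()].
#' @param diameter lesion chord diameter in pixels; must lie in
#'   `[4, image_width - 2]`. `NA` renders a lesion-free scan (annotation is
#'   `NULL`), useful as a negative example for the presence head of the
#'   multitask initializer.
#' @param seed integer seed; defaults to `config$seed`.
#' @param center_x,base_y optional fixed lesion geometry (pixels); when `NULL`
#'   a small seeded jitter around the image centre is used. Patient series
#'   fix these so only the diameter varies across frames.
#' @param patient_id,frame_index identity stored in the returned scan.
#' @return `list(scan = bscan, ann = annotation or NULL)`.
#' @export
generate_bscan <- function(config, diameter, seed = config$seed,
                           center_x = NULL, base_y = NULL,
                           patient_id = "phantom", frame_index = 0L) {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$image_height; w <- config$image_width
  lesion <- !is.na(diameter)
  if (lesion && (diameter < 4 || diameter > w - 2))
    stop("diameter must be in [4, image_width - 2] = [4, ", w - 2,
         "], got ", diameter)
  withr_seed(seed)

  geom <- phantom_geometry(config)
  img <- matrix(config$background_level, h, w)
  # band block: equal horizontal slices of the configured intensities
  bounds <- round(seq(geom$r0, geom$r1 + 1L,
                      length.out = length(config$band_intensity_levels) + 1L))
  for (b in seq_along(config$band_intensity_levels)) {
    rows <- bounds[b]:(bounds[b + 1L] - 1L)
    img[rows + 1L, ] <- config$band_intensity_levels[b]
  }

  ann <- NULL
  if (lesion) {
    d <- as.integer(round(diameter))
    if (is.null(center_x)) {
      jitter_max <- max(0L, min(5L, (w - 2L - d) %/% 2L - 1L))
      center_x <- round(w / 2) + sample.int(2L * jitter_max + 1L, 1L) - jitter_max - 1L
    }
    if (is.null(base_y)) base_y <- geom$base_y
    left_x <- as.integer(round(center_x - d / 2))
    left_x <- max(1L, min(left_x, w - 2L - d))
    right_x <- left_x + d
    a <- d / 2
    ecx <- left_x + a
    hgt <- round(runif(1, config$lesion_height_range[1], config$lesion_height_range[2]))
    hgt <- min(hgt, base_y - geom$r0 - 2L)        # keep the dome inside the band block
    hgt <- max(hgt, 2L)
    xs <- 0:(w - 1L); ys <- 0:(h - 1L)
    ex <- ((xs - ecx) / a)^2
    ey <- ((base_y - ys) / hgt)^2
    inside <- outer(ey, ex, `+`) <= 1 & outer(ys <= base_y & ys >= base_y - hgt,
                                              rep(TRUE, w), `&`)
    img[inside] <- config$background_level
    ann <- annotation(c(left_x, base_y), c(right_x, base_y))
  }

  if (config$speckle_sigma > 0) {
    img <- img * (1 + config$speckle_sigma * matrix(rnorm(h * w), h, w))
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(scan = bscan(img, patient_id, frame_index), ann = ann)
}

#' Chord-of-sphere diameter profile across the frames of a patient stack
#'
#' A serous detachment is approximately dome-shaped in 3-D, so the chord seen
#' by frame `k` of `n` follows
#' `d_k = D_max * sqrt(1 - (2k/(n-1) - 1)^2)` (0-based `k`), rounded and
#' floored at the minimum renderable diameter of 4 px. For `n = 1` the single
#' frame carries `D_max`.
#'
#' @param d_max patient-level maximum chord diameter (pixels).
#' @param n number of frames.
#' @param min_renderable floor applied after rounding (default 4 px).
#' @return Integer vector of `n` per-frame diameters.
#' @export
diameter_profile <- function(d_max, n, min_renderable = 4L) {
  stopifnot(n >= 1L, d_max >= min_renderable)
  if (n == 1L) return(as.integer(round(d_max)))
  k <- seq_len(n) - 1L
  d <- round(d_max * sqrt(pmax(0, 1 - (2 * k / (n - 1) - 1)^2)))
  as.integer(pmax(d, min_renderable))
}

#' Generate a full patient stack of B-scans
#'
#' Per-frame diameters follow [diameter_profile()]; the lesion centre and
#' base row are fixed within a patient so that only the chord varies.
#'
#' @param config a [phantom_config()].
#' @param patient_id identity stored in every frame.
#' @param seed integer seed; defaults to `config$seed`.
#' @return A list of class `patient_series` with elements `patient_id` and
#'   `scans` (a list of `list(scan, ann)` in increasing frame order).
#' @export
generate_patient_series <- function(config, patient_id = "patient01",
                                    seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_frames_per_patient
  withr_seed(seed)
  d_max <- round(runif(1, config$lesion_max_diameter_range[1],
                       config$lesion_max_diameter_range[2]))
  geom <- phantom_geometry(config)
  w <- config$image_width
  jitter_max <- max(0L, min(5L, (w - 2L - d_max) %/% 2L - 1L))
  center_x <- round(w / 2) + sample.int(2L * jitter_max + 1L, 1L) - jitter_max - 1L
  frame_seeds <- sample.int(.Machine$integer.max - 1L, n)
  diams <- diameter_profile(d_max, n)
  scans <- lapply(seq_len(n), function(k) {
    generate_bscan(config, diams[k], seed = frame_seeds[k],
                   center_x = center_x, base_y = geom$base_y,
                   patient_id = patient_id, frame_index = k - 1L)
  })
  structure(list(patient_id = patient_id, scans = scans, d_max = d_max),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series %s: %d frames, max diameter %d px>\n",
              x$patient_id, length(x$scans), x$d_max))
  invisible(x)
}

# seed the session RNG for a generator call; NULL continues the current stream
withr_seed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(seed)
}
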