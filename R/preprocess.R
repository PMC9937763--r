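# Preprocessing: region-of-interest cropping and speckle denoising.

#' Crop a B-scan to a rectangle
#'
#' @param scan a [bscan()].
#' @param rect `c(x0, y0, width, height)` in 0-based pixel coordinates; must
#'   lie fully inside the image and have positive size.
#' @return The cropped [bscan()]. Annotations are the caller's to translate,
#'   via [shift_annotation()] with `(-x0, -y0)`.
#' @export
crop_bscan <- function(scan, rect) {
  stopifnot(inherits(scan, "bscan"), length(rect) == 4L)
  x0 <- rect[1]; y0 <- rect[2]; w <- rect[3]; h <- rect[4]
  if (w < 1 || h < 1) stop("crop rectangle must have positive width and height")
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(scan$pixels) || y0 + h > nrow(scan$pixels))
    stop("crop rectangle extends outside the image")
  bscan(scan$pixels[(y0 + 1):(y0 + h), (x0 + 1):(x0 + w), drop = FALSE],
        scan$patient_id, scan$frame_index)
}

#' Translate an annotation
#'
#' Companion to [crop_bscan()]: translating by `(-x0, -y0)` maps annotation
#' coordinates into the cropped frame.
#'
#' @param ann an [annotation()].
#' @param dx,dy translation in pixels.
#' @return The translated [annotation()].
#' @export
shift_annotation <- function(ann, dx, dy) {
  annotation(ann$left + c(dx, dy), ann$right + c(dx, dy))
}

#' Denoise a B-scan
#'
#' Counters the multiplicative speckle the phantom generator (and real OCT)
#' exhibits. `"bm3d"` is a first-stage collaborative filter: similar 8x8
#' patches are grouped, jointly transformed (2-D DCT within patches, an
#' orthogonal Hadamard across the group), hard-thresholded, and aggregated
#' with sparsity-based weights. `"nlm"` is non-local means over a search
#' window; `"median"` is a running median filter. For a constant image every
#' method returns the input unchanged.
#'
#' @param scan a [bscan()].
#' @param method one of `"bm3d"`, `"nlm"`, `"median"`, `"none"`.
#' @param strength noise scale: for `"bm3d"` and `"nlm"` the assumed noise
#'   standard deviation on the 0-255 intensity scale; for `"median"` the
#'   filter radius in pixels. `0` is the identity for `"nlm"` and `"median"`.
#' @return The denoised [bscan()]; dimensions unchanged, intensities in
#'   \[0, 255\].
#' @export
denoise_bscan <- function(scan, method = c("bm3d", "nlm", "median", "none"),
                          strength = 25) {
  stopifnot(inherits(scan, "bscan"))
  method <- match.arg(method)
  img <- scan$pixels
  out <- switch(method,
    none = img,
    median = {
      if (strength <= 0) img
      else t(EBImage::medianFilter(t(img) / 255, size = as.integer(strength))) * 255
    },
    nlm = if (strength <= 0) img else nlm_filter(img, sigma = strength),
    bm3d = bm3d_filter(img, sigma = strength))
  out <- pmin(pmax(out, 0), 255)
  bscan(out, scan$patient_id, scan$frame_index)
}

# ---- non-local means (shifted-window formulation) -------------------------

nlm_filter <- function(img, sigma, patch_radius = 3L, search_radius = 5L) {
  h <- nrow(img); w <- ncol(img)
  acc <- matrix(0, h, w); wsum <- matrix(0, h, w)
  filt_h2 <- (0.6 * sigma)^2 * (2 * patch_radius + 1)^2
  box <- function(m, r) {
    # box filter via cumulative sums with edge replication
    pad_y <- c(rep(1L, r), seq_len(h), rep(h, r))
    pad_x <- c(rep(1L, r), seq_len(w), rep(w, r))
    p <- m[pad_y, pad_x, drop = FALSE]
    cs <- apply(apply(p, 2L, cumsum), 1L, cumsum)  # transposed cumsum matrix
    cs <- t(cs)
    n <- 2L * r + 1L
    z <- matrix(0, nrow(p) + 1L, ncol(p) + 1L)
    z[-1, -1] <- cs
    z[(n + 1):(h + n), (n + 1):(w + n)] - z[1:h, (n + 1):(w + n)] -
      z[(n + 1):(h + n), 1:w] + z[1:h, 1:w]
  }
  shift_img <- function(m, dy, dx) {
    sy <- pmin(pmax(seq_len(h) + dy, 1L), h)
    sx <- pmin(pmax(seq_len(w) + dx, 1L), w)
    m[sy, sx, drop = FALSE]
  }
  for (dy in -search_radius:search_radius) {
    for (dx in -search_radius:search_radius) {
      sh <- shift_img(img, dy, dx)
      d2 <- box((img - sh)^2, patch_radius)
      wgt <- exp(-pmax(d2 - 2 * sigma^2 * (2 * patch_radius + 1)^2, 0) / filt_h2)
      acc <- acc + wgt * sh
      wsum <- wsum + wgt
    }
  }
  acc / wsum
}

# ---- first-stage BM3D (hard thresholding) ---------------------------------

bm3d_filter <- function(img, sigma, patch = 8L, ref_step = 4L,
                        cand_step = 2L, search = 16L, group_size = 8L) {
  h <- nrow(img); w <- ncol(img)
  if (h < patch || w < patch) return(img)
  # 2-D DCT basis for 8x8 patches as one 64x64 orthogonal matrix
  dct1 <- sapply(seq_len(patch) - 1L, function(k) {
    v <- cos(pi * (2 * (seq_len(patch) - 1L) + 1) * k / (2 * patch))
    v * ifelse(k == 0, sqrt(1 / patch), sqrt(2 / patch))
  })
  dct1 <- t(dct1)                       # rows = frequency, cols = space
  T2 <- kronecker(dct1, dct1)           # applies to column-major 8x8 patches
  # Hadamard transform across the group (orthogonal, symmetric)
  H <- matrix(1, 1, 1)
  while (nrow(H) < group_size) H <- rbind(cbind(H, H), cbind(H, -H))
  H <- H / sqrt(group_size)

  cand_y <- unique(c(seq(1L, h - patch + 1L, cand_step), h - patch + 1L))
  cand_x <- unique(c(seq(1L, w - patch + 1L, cand_step), w - patch + 1L))
  pos <- expand.grid(y = cand_y, x = cand_x)
  npos <- nrow(pos)
  # all candidate patches as columns (column-major within patch)
  idx_patch <- as.vector(outer(seq_len(patch), (seq_len(patch) - 1L) * h, `+`))
  base_idx <- (pos$x - 1L) * h + pos$y
  P <- matrix(img[rep(idx_patch, npos) +
                  rep(base_idx - 1L, each = patch * patch)],
              patch * patch, npos)
  TP <- T2 %*% P
  lambda <- 2.7 * sigma

  acc <- matrix(0, h, w); wacc <- matrix(0, h, w)
  ref_y <- unique(c(seq(1L, h - patch + 1L, ref_step), h - patch + 1L))
  ref_x <- unique(c(seq(1L, w - patch + 1L, ref_step), w - patch + 1L))
  ppix <- patch * patch
  for (ry in ref_y) {
    for (rx in ref_x) {
      cand <- which(abs(pos$y - ry) <= search & abs(pos$x - rx) <= search)
      ref_id <- cand[which.min(abs(pos$y[cand] - ry) + abs(pos$x[cand] - rx))]
      d <- colSums((TP[, cand, drop = FALSE] - TP[, ref_id])^2)
      sel <- cand[order(d)[seq_len(min(group_size, length(cand)))]]
      if (length(sel) < group_size) sel <- rep(sel, length.out = group_size)
      G <- TP[, sel, drop = FALSE] %*% H
      keep <- abs(G) >= lambda
      keep[1, 1] <- TRUE                 # always keep the group DC term
      G[!keep] <- 0
      wgt <- 1 / (sum(keep) + 1)
      Ph <- crossprod(T2, G %*% H)       # inverse transforms
      for (j in seq_len(group_size)) {
        yy <- pos$y[sel[j]]; xx <- pos$x[sel[j]]
        ys <- yy:(yy + patch - 1L); xs <- xx:(xx + patch - 1L)
        acc[ys, xs] <- acc[ys, xs] + wgt * matrix(Ph[, j], patch, patch)
        wacc[ys, xs] <- wacc[ys, xs] + wgt
      }
    }
  }
  covered <- wacc > 0
  out <- img
  out[covered] <- acc[covered] / wacc[covered]
  out
}
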