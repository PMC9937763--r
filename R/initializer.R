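# Initial location of the two lesion boundary points. Either a deterministic
# heuristic detector (dark-blob extremes) or a small multitask CNN plays this
# role; the refinement agents only consume the coordinates, so any detector
# honouring the interface can be plugged in.

#' Construct an initial-points result
#' @param left,right `c(x, y)` 0-based coordinates.
#' @param source `"heuristic"` or `"cnn"`.
#' @param fallback logical; `TRUE` when the detector fell back to image-centre
#'   defaults because no lesion-like structure was found.
#' @return A list of class `initial_points`.
#' @export
initial_points <- function(left, right, source = "heuristic", fallback = FALSE) {
  structure(list(left = c(x = as.numeric(left[1]), y = as.numeric(left[2])),
                 right = c(x = as.numeric(right[1]), y = as.numeric(right[2])),
                 source = source, fallback = isTRUE(fallback)),
            class = "initial_points")
}

#' Heuristic initializer: extremes of the central dark blob
#'
#' Thresholds the image at the between-class-variance (Otsu) level, labels
#' the dark connected components, keeps the largest whose centroid lies in
#' the central half of the image (both axes), and returns its leftmost and
#' rightmost pixels (row = median row at the extreme column). If no such
#' component exists the image-centre +/- quarter-width fallback points are
#' returned with a warning and `fallback = TRUE`.
#'
#' The operator commutes with horizontal flips: flipping the image mirrors
#' and swaps the two returned points.
#'
#' @param scan a [bscan()].
#' @param min_area smallest component size (pixels) considered lesion-like.
#' @return An [initial_points()] with `source = "heuristic"`.
#' @export
heuristic_initializer <- function(scan, min_area = 9L) {
  stopifnot(inherits(scan, "bscan"))
  px <- scan$pixels
  h <- nrow(px); w <- ncol(px)
  img01 <- t(px) / 255                       # EBImage images are (x, y)
  thr <- tryCatch(EBImage::otsu(EBImage::Image(img01)), error = function(e) NA)
  fallback <- initial_points(c(round(w / 2 - w / 4), round(h / 2)),
                             c(round(w / 2 + w / 4), round(h / 2)),
                             source = "heuristic", fallback = TRUE)
  if (is.na(thr) || min(px) == max(px)) {
    warning("heuristic initializer: no dark component found; using fallback points")
    return(fallback)
  }
  mask <- EBImage::Image(img01 < thr)
  labels <- EBImage::bwlabel(mask)
  lab <- EBImage::imageData(labels)          # (x, y) indexed matrix
  n_comp <- max(lab)
  if (n_comp < 1) {
    warning("heuristic initializer: no dark component found; using fallback points")
    return(fallback)
  }
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  best <- 0L; best_size <- 0L
  for (id in which(sizes >= min_area)) {
    pix <- which(lab == id, arr.ind = TRUE)   # col1 = x+1, col2 = y+1
    cx <- mean(pix[, 1]) - 1; cy <- mean(pix[, 2]) - 1
    central <- cx >= w / 4 && cx < 3 * w / 4 && cy >= h / 4 && cy < 3 * h / 4
    if (central && sizes[id] > best_size) { best <- id; best_size <- sizes[id] }
  }
  if (best == 0L) {
    warning("heuristic initializer: no central dark component; using fallback points")
    return(fallback)
  }
  pix <- which(lab == best, arr.ind = TRUE)
  xs <- pix[, 1] - 1L; ys <- pix[, 2] - 1L
  xl <- min(xs); xr <- max(xs)
  yl <- round(median(ys[xs == xl]))
  yr <- round(median(ys[xs == xr]))
  if (xl == xr) xr <- min(xl + 1, w - 1)     # degenerate one-column blob
  initial_points(c(xl, yl), c(xr, yr), source = "heuristic")
}

#' Training configuration for the multitask initializer network
#'
#' Defaults follow the adaptive-moment training recipe used for the
#' initial-location network: 40 epochs, learning rate 0.001, batch size 20.
#'
#' @param epochs,learning_rate,batch_size optimizer settings.
#' @param presence_weight,coord_weight loss weights of the lesion-presence
#'   (binary cross-entropy) and coordinate (smooth-L1 on normalized
#'   coordinates) heads; defaults 1:1.
#' @param input_size side of the square the scan is resized to before the
#'   network (pixels).
#' @param conv_filters,fc_units architecture of the shared trunk.
#' @param smooth_l1_beta transition point of the smooth-L1 loss on the
#'   normalized \[0, 1\] coordinate scale.
#' @return A list of class `initializer_config`.
#' @export
initializer_config <- function(epochs = 40L, learning_rate = 0.001,
                               batch_size = 20L,
                               presence_weight = 1, coord_weight = 1,
                               input_size = 64L,
                               conv_filters = c(8L, 16L, 32L),
                               fc_units = 128L,
                               smooth_l1_beta = 0.05) {
  cfg <- list(epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              presence_weight = presence_weight, coord_weight = coord_weight,
              input_size = as.integer(input_size),
              conv_filters = as.integer(conv_filters),
              fc_units = as.integer(fc_units),
              smooth_l1_beta = smooth_l1_beta)
  stopifnot(cfg$epochs >= 1L, cfg$learning_rate > 0, cfg$batch_size >= 1L,
            cfg$presence_weight > 0, cfg$coord_weight > 0)
  class(cfg) <- "initializer_config"
  cfg
}

# resize a scan to the network input and scale to [0, 1]
init_net_input <- function(px, size) {
  r <- EBImage::resize(EBImage::Image(t(px) / 255), w = size, h = size)
  t(EBImage::imageData(r))
}

smooth_l1 <- function(x, beta) {
  ifelse(abs(x) < beta, 0.5 * x^2 / beta, abs(x) - 0.5 * beta)
}

smooth_l1_grad <- function(x, beta) {
  pmin(pmax(x / beta, -1), 1)
}

#' Train the multitask initializer network
#'
#' A small convolutional trunk feeds two heads: a lesion-presence score
#' (sigmoid + binary cross-entropy) and four normalized coordinates
#' `(x_L, y_L, x_R, y_R)` in \[0, 1\] (smooth-L1 loss, masked for
#' lesion-free examples). Optimized with Adam; the per-epoch mean loss is
#' logged in `loss_curve`.
#'
#' @param train list of `list(scan, ann)` pairs; `ann = NULL` marks a
#'   lesion-free negative example for the presence head.
#' @param config an [initializer_config()].
#' @param seed integer seed controlling initialisation and shuffling.
#' @return A list of class `initializer_model` with `weights`, `spec`,
#'   `config` and `loss_curve`.
#' @export
train_initializer <- function(train, config = initializer_config(), seed = 1L) {
  stopifnot(inherits(config, "initializer_config"))
  if (length(train) < 1L) stop("training set must contain at least one pair")
  set.seed(as.integer(seed))
  s <- config$input_size
  n <- length(train)
  X <- array(0, c(s, s, 1L, n))
  presence <- numeric(n)
  coords <- matrix(0, 4L, n)
  for (i in seq_len(n)) {
    scan <- train[[i]]$scan; ann <- train[[i]]$ann
    X[, , 1L, i] <- init_net_input(scan$pixels, s)
    if (!is.null(ann)) {
      presence[i] <- 1
      wd <- ncol(scan$pixels) - 1; ht <- nrow(scan$pixels) - 1
      coords[, i] <- c(ann$left[["x"]] / wd, ann$left[["y"]] / ht,
                       ann$right[["x"]] / wd, ann$right[["y"]] / ht)
    }
  }
  spec <- nn_spec(s, 1L, config$conv_filters, config$fc_units,
                  n_out = 5L, dueling = FALSE)
  weights <- nn_init_weights(spec)
  opt <- adam_state(weights)
  loss_curve <- numeric(config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, config$batch_size)) {
      ids <- ord[start:min(start + config$batch_size - 1L, n)]
      B <- length(ids)
      xb <- X[, , , ids, drop = FALSE]
      fwd <- nn_forward(weights, spec, xb)
      p_logit <- fwd[1L, ]
      p_hat <- 1 / (1 + exp(-p_logit))
      diffs <- fwd[2:5, , drop = FALSE] - coords[, ids, drop = FALSE]
      mask <- rep(presence[ids], each = 4L)
      bce <- -(presence[ids] * log(pmax(p_hat, 1e-12)) +
               (1 - presence[ids]) * log(pmax(1 - p_hat, 1e-12)))
      sl1 <- matrix(smooth_l1(diffs, config$smooth_l1_beta) * mask, 4L, B)
      # coordinate loss: per-image sum of the four smooth-L1 terms
      loss <- config$presence_weight * mean(bce) +
        config$coord_weight * mean(colSums(sl1))
      grad_out <- matrix(0, 5L, B)
      grad_out[1L, ] <- config$presence_weight * (p_hat - presence[ids]) / B
      grad_out[2:5, ] <- config$coord_weight *
        smooth_l1_grad(diffs, config$smooth_l1_beta) * mask / B
      bw <- nn_grad(weights, spec, xb, grad_out)
      upd <- adam_step(weights, bw$grads, opt, config$learning_rate)
      weights <- upd$weights; opt <- upd$state
      losses <- c(losses, loss)
    }
    loss_curve[epoch] <- mean(losses)
  }
  structure(list(weights = weights, spec = spec, config = config,
                 loss_curve = loss_curve, seed = as.integer(seed)),
            class = "initializer_model")
}

#' Predict initial boundary points
#'
#' Dispatches on the initializer: the string `"heuristic"`, a trained
#' [train_initializer()] model, or any function `scan -> initial_points`.
#' Coordinates are rounded to integers and clamped inside the image.
#'
#' @param object the initializer.
#' @param scan a [bscan()].
#' @return An [initial_points()].
#' @export
predict_initial <- function(object, scan) {
  stopifnot(inherits(scan, "bscan"))
  if (is.character(object) && identical(object, "heuristic"))
    return(heuristic_initializer(scan))
  if (is.function(object)) return(object(scan))
  if (!inherits(object, "initializer_model"))
    stop("unsupported initializer of class ", paste(class(object), collapse = "/"))
  s <- object$config$input_size
  x <- array(init_net_input(scan$pixels, s), c(s, s, 1L, 1L))
  out <- drop(nn_forward(object$weights, object$spec, x))
  wd <- ncol(scan$pixels) - 1; ht <- nrow(scan$pixels) - 1
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  left <- c(clamp(round(out[2] * wd), 0, wd), clamp(round(out[3] * ht), 0, ht))
  right <- c(clamp(round(out[4] * wd), 0, wd), clamp(round(out[5] * ht), 0, ht))
  if (right[1] <= left[1]) right[1] <- min(left[1] + 1, wd)  # keep ordering
  initial_points(left, right, source = "cnn",
                 fallback = out[1] < 0)      # negative presence logit
}
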