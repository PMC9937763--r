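# Evaluation metrics and the clinical end product: keypoint error, lesion
# diameter and per-patient summaries.

# accept location_result, initial_points, or plain list(left=, right=)
result_points <- function(r) {
  if (inherits(r, "location_result"))
    return(list(left = r$left$final, right = r$right$final))
  if (inherits(r, "initial_points") || (is.list(r) && !is.null(r$left)))
    return(list(left = r$left, right = r$right))
  stop("cannot extract keypoints from object of class ",
       paste(class(r), collapse = "/"))
}

#' Average Euclidean distance (AED) of predicted boundary points
#'
#' `AED = (1 / 2N) * sum_i (||LG_i|| + ||RG_i||)` where `LG_i` and `RG_i`
#' are the left and right error vectors (prediction minus ground truth) of
#' image `i`. Zero iff every predicted point is exact; invariant under a
#' common translation of predictions and truths.
#'
#' @param results list of predictions ([locate_joint()] results,
#'   [initial_points()], or `list(left, right)` pairs).
#' @param truths list of [annotation()]s, aligned with `results`.
#' @return AED in pixels.
#' @export
aed <- function(results, truths) {
  if (length(results) != length(truths))
    stop("results and truths must have the same length")
  if (length(results) < 1L) stop("need at least one image")
  per_image <- vapply(seq_along(results), function(i) {
    p <- result_points(results[[i]])
    euclid_dist(p$left, truths[[i]]$left) + euclid_dist(p$right, truths[[i]]$right)
  }, numeric(1))
  sum(per_image) / (2 * length(results))
}

#' Lesion chord diameter
#'
#' The 2-norm of the vector between the two boundary points; symmetric in
#' its arguments and translation invariant.
#'
#' @param left,right `c(x, y)` boundary points.
#' @return Diameter in pixels.
#' @export
lesion_diameter <- function(left, right) {
  euclid_dist(left, right)
}

#' Successful-correction rate of the cascade over its initializer
#'
#' An image is successfully corrected when the single-image AED of the
#' refined points is strictly below that of the initial points; ties count
#' as non-corrections.
#'
#' @param init_results,joint_results aligned prediction lists (see [aed()]).
#' @param truths aligned list of [annotation()]s.
#' @return `list(rate, n_success, n, n_tie)`.
#' @export
correction_rate <- function(init_results, joint_results, truths) {
  n <- length(truths)
  if (length(init_results) != n || length(joint_results) != n)
    stop("init_results, joint_results and truths must have the same length")
  single <- function(r, t) aed(list(r), list(t))
  init_aed <- vapply(seq_len(n), function(i)
    single(init_results[[i]], truths[[i]]), numeric(1))
  joint_aed <- vapply(seq_len(n), function(i)
    single(joint_results[[i]], truths[[i]]), numeric(1))
  n_success <- sum(joint_aed < init_aed)
  list(rate = n_success / n, n_success = n_success, n = n,
       n_tie = sum(joint_aed == init_aed))
}

#' Per-patient lesion diameter summary
#'
#' @param results list of per-frame predictions (see [aed()]) or a numeric
#'   vector of per-frame diameters.
#' @return `c(max, min, mean)` of the per-frame diameters in pixels.
#' @export
patient_summary <- function(results) {
  if (length(results) < 1L) stop("need at least one frame")
  diams <- if (is.numeric(results)) results
  else vapply(results, function(r) {
    p <- result_points(r)
    lesion_diameter(p$left, p$right)
  }, numeric(1))
  c(max = max(diams), min = min(diams), mean = mean(diams))
}
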