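# Test-time location: one greedy agent episode per side, cascaded behind an
# initializer.

#' Run one greedy test episode from a start point
#'
#' The agent starts at `start`, its active region is the `region_side` box
#' centred there, actions are pure argmax (epsilon = 0), the per-step
#' maximum Q value is recorded, and the episode stops when the Q-plateau
#' rule of [tt_update()] fires or the step budget is exhausted.
#'
#' @param scan a [bscan()].
#' @param model object with a [q_values()] method.
#' @param start `c(x, y)` start position.
#' @param region_side active-region side (default 80 px).
#' @param patch_size observation patch side.
#' @param threshold,t_q,n_test test-termination settings, see
#'   [test_termination()].
#' @return `list(initial, final, q_trace, positions, steps, terminated_by)`.
#' @export
locate_side <- function(scan, model, start, region_side = 80L,
                        patch_size = 32L, threshold = 0.3, t_q = 2L,
                        n_test = 60L) {
  w <- ncol(scan$pixels); h <- nrow(scan$pixels)
  start <- c(min(max(round(start[1]), 0), w - 1),
             min(max(round(start[2]), 0), h - 1))
  region <- active_region(start, w, h, side = region_side)
  state <- agent_reset(scan, region, start, patch_size)
  tt <- test_termination(threshold, t_q, n_test)
  positions <- matrix(state$position, 1L, 2L)
  q_trace <- c()
  repeat {
    qv <- q_values(model, state)
    a <- select_action(qv, epsilon = 0)
    res <- agent_step(scan, region, state, a, target = NULL)
    state <- res$state
    positions <- rbind(positions, state$position)
    upd <- tt_update(tt, max(qv))
    tt <- upd$tt
    q_trace <- c(q_trace, max(qv))
    if (upd$terminate) break
  }
  list(initial = c(x = start[1], y = start[2]),
       final = state$position,
       q_trace = q_trace, positions = positions,
       steps = tt$step, terminated_by = tt$reason)
}

#' Locate both lesion boundary points on a B-scan
#'
#' The cascade: the initializer proposes the two points; for each side an
#' independent agent refines its point inside an 80-px active region centred
#' on the initial point, running greedily until its Q values plateau or the
#' step budget runs out.
#'
#' @param scan a [bscan()].
#' @param initializer `"heuristic"`, a trained initializer model, a function
#'   `scan -> initial_points`, or an [initial_points()] object used as-is.
#' @param left_model,right_model the per-side agents (anything with a
#'   [q_values()] method).
#' @param region_side,patch_size,threshold,t_q,n_test see [locate_side()].
#' @return A list of class `location_result` with per-side entries (`left`,
#'   `right`: each `initial`, `final`, `q_trace`, `steps`, `terminated_by`)
#'   plus `init_source` and `init_fallback`.
#' @export
locate_joint <- function(scan, initializer, left_model, right_model,
                         region_side = 80L, patch_size = 32L,
                         threshold = 0.3, t_q = 2L, n_test = 60L) {
  init <- if (inherits(initializer, "initial_points")) initializer
          else predict_initial(initializer, scan)
  left <- locate_side(scan, left_model, init$left, region_side, patch_size,
                      threshold, t_q, n_test)
  right <- locate_side(scan, right_model, init$right, region_side, patch_size,
                       threshold, t_q, n_test)
  structure(list(left = left, right = right,
                 init_source = init$source, init_fallback = init$fallback),
            class = "location_result")
}

#' @export
print.location_result <- function(x, ...) {
  cat(sprintf(paste0("<location_result: left (%g, %g) -> (%g, %g) [%s, %d steps], ",
                     "right (%g, %g) -> (%g, %g) [%s, %d steps]>\n"),
              x$left$initial[1], x$left$initial[2],
              x$left$final[1], x$left$final[2],
              x$left$terminated_by, x$left$steps,
              x$right$initial[1], x$right$initial[2],
              x$right$final[1], x$right$final[2],
              x$right$terminated_by, x$right$steps))
  invisible(x)
}

#' Locate boundary points on every frame of a patient stack
#'
#' @param series a `patient_series`.
#' @param initializer,left_model,right_model as in [locate_joint()].
#' @param ... further arguments to [locate_joint()].
#' @return List of `location_result` (or, for frames whose processing
#'   failed, `list(error = <message>)`), in frame order.
#' @export
run_patient <- function(series, initializer, left_model, right_model, ...) {
  stopifnot(inherits(series, "patient_series"))
  lapply(series$scans, function(pair) {
    tryCatch(locate_joint(pair$scan, initializer, left_model, right_model, ...),
             error = function(e) list(error = conditionMessage(e)))
  })
}
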