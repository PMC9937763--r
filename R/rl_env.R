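# The Markov decision process the refinement agent lives in: positions,
# patches, the four unit actions, the clipped distance-decrease reward and
# the train/test termination rules.
#
# Coordinates are 0-based, x = column, y = row, origin top-left; UP decreases
# y (screen convention).

#' The four agent actions
#'
#' Integer codes 1-4 = UP, DOWN, LEFT, RIGHT; each moves the agent one pixel.
#' @format Named integer vector of length 4.
#' @export
ACTIONS <- c(UP = 1L, DOWN = 2L, LEFT = 3L, RIGHT = 4L)

action_delta <- function(action) {
  switch(action, c(0, -1), c(0, 1), c(-1, 0), c(1, 0))
}

#' Euclidean distance between two pixel positions
#' @param p,q `c(x, y)` positions.
#' @return Distance in pixels.
#' @export
euclid_dist <- function(p, q) {
  sqrt(sum((as.numeric(p[1:2]) - as.numeric(q[1:2]))^2))
}

#' Step reward: clipped decrease in distance to the target
#'
#' `R = clip(D(before, target) - D(after, target), -1, 1)`: positive when the
#' action moved the agent closer to the target point. For unit steps the
#' raw difference already lies in \[-1, 1\] (triangle inequality), so the
#' clip only matters for hypothetical multi-pixel moves.
#'
#' @param pos_before,pos_after agent position before/after the action.
#' @param target the ground-truth boundary point.
#' @return Reward in \[-1, 1\].
#' @export
compute_reward <- function(pos_before, pos_after, target) {
  r <- euclid_dist(pos_before, target) - euclid_dist(pos_after, target)
  min(max(r, -1), 1)
}

#' The agent's active region
#'
#' An axis-aligned square box (default side 80 px) centred on the
#' initializer's point and clipped to the image; the agent's position is
#' confined to it, while observation patches may extend beyond (they are
#' edge-padded from the image).
#'
#' @param center `c(x, y)` box centre (the initial point).
#' @param image_width,image_height image dimensions in pixels.
#' @param side box side in pixels.
#' @return A list of class `active_region` with fields `x0, x1, y0, y1`.
#' @export
active_region <- function(center, image_width, image_height, side = 80L) {
  stopifnot(side >= 1L)
  half <- side %/% 2L
  x0 <- max(0L, as.integer(round(center[1])) - half)
  y0 <- max(0L, as.integer(round(center[2])) - half)
  x1 <- min(image_width - 1L, x0 + side - 1L)
  y1 <- min(image_height - 1L, y0 + side - 1L)
  structure(list(x0 = x0, x1 = x1, y0 = y0, y1 = y1,
                 center = c(x = as.numeric(center[1]), y = as.numeric(center[2]))),
            class = "active_region")
}

in_region <- function(pos, region) {
  pos[1] >= region$x0 && pos[1] <= region$x1 &&
    pos[2] >= region$y0 && pos[2] <= region$y1
}

clamp_region <- function(pos, region) {
  c(min(max(pos[1], region$x0), region$x1),
    min(max(pos[2], region$y0), region$y1))
}

#' Extract the observation patch at a position
#'
#' A `size x size` patch with the agent position mapped to the floor-centre
#' index (`size/2 - 1`, 0-based) for even sizes. Out-of-image pixels are
#' filled by edge replication; intensities are scaled to \[0, 1\].
#'
#' @param scan a [bscan()].
#' @param pos `c(x, y)` position; must lie inside the image.
#' @param size patch side (default 32).
#' @return A `size x size` numeric matrix in \[0, 1\].
#' @export
extract_patch <- function(scan, pos, size = 32L) {
  px <- scan$pixels
  h <- nrow(px); w <- ncol(px)
  x <- as.integer(round(pos[1])); y <- as.integer(round(pos[2]))
  if (x < 0 || x > w - 1 || y < 0 || y > h - 1)
    stop("patch position (", x, ", ", y, ") outside the image")
  lo <- size %/% 2L - 1L
  xs <- pmin(pmax((x - lo):(x - lo + size - 1L), 0L), w - 1L)
  ys <- pmin(pmax((y - lo):(y - lo + size - 1L), 0L), h - 1L)
  px[ys + 1L, xs + 1L, drop = FALSE] / 255
}

#' Reset the agent to a start position
#'
#' The 4-deep patch history is initialised by replicating the start patch.
#'
#' @param scan a [bscan()].
#' @param region an [active_region()].
#' @param start `c(x, y)` start position; must lie inside the region.
#' @param patch_size observation patch side.
#' @return An `agent_state`: position plus a `(size, size, 4)` patch stack,
#'   newest patch last.
#' @export
agent_reset <- function(scan, region, start, patch_size = 32L) {
  if (!in_region(start, region))
    stop("start position (", start[1], ", ", start[2], ") outside the active region")
  p <- extract_patch(scan, start, patch_size)
  structure(list(position = c(x = as.numeric(start[1]), y = as.numeric(start[2])),
                 patches = array(rep(p, 4L), c(patch_size, patch_size, 4L))),
            class = "agent_state")
}

#' Advance the environment by one action
#'
#' The candidate position is the current one displaced by one pixel; it is
#' clamped to the active region (a move into the wall leaves the position
#' unchanged, and the reward of such a move is 0 because the distance to the
#' target does not change). The patch stack shifts by one (oldest dropped).
#'
#' @param scan a [bscan()].
#' @param region an [active_region()].
#' @param state the current `agent_state`.
#' @param action one of [ACTIONS].
#' @param target optional ground-truth point; when given (training) the
#'   clipped distance-decrease reward is returned, at test time `NULL`.
#' @return `list(state, reward)`.
#' @export
agent_step <- function(scan, region, state, action, target = NULL) {
  stopifnot(inherits(state, "agent_state"), action %in% 1:4)
  before <- state$position
  after <- clamp_region(before + action_delta(action), region)
  size <- dim(state$patches)[1]
  new_patch <- extract_patch(scan, after, size)
  patches <- array(0, dim(state$patches))
  patches[, , 1:3] <- state$patches[, , 2:4]
  patches[, , 4L] <- new_patch
  reward <- if (is.null(target)) NULL else compute_reward(before, after, target)
  list(state = structure(list(position = c(x = after[1], y = after[2]),
                              patches = patches),
                         class = "agent_state"),
       reward = reward)
}

#' Training termination rule
#'
#' Terminates when the agent is within one pixel of the target (the default
#' `"leq"` rule, `D <= 1`; the `"strict"` rule `D < 1` requires an exact
#' hit on the integer grid) or when the step budget is exhausted.
#'
#' @param pos agent position.
#' @param target ground-truth point.
#' @param step steps taken so far.
#' @param n_train step budget (default 100).
#' @param rule `"leq"` or `"strict"`.
#' @return Logical.
#' @export
train_terminated <- function(pos, target, step, n_train = 100L,
                             rule = c("leq", "strict")) {
  rule <- match.arg(rule)
  d <- euclid_dist(pos, target)
  hit <- if (rule == "leq") d <= 1 else d < 1
  hit || step >= n_train
}

#' Convergence statistic of the recorded Q values
#'
#' The absolute difference between the mean of the first eight and the mean
#' of the last eight of the most recent 16 recorded Q values. Invariant to
#' adding a constant to all Q values.
#'
#' @param q_history numeric vector of recorded Q values (newest last).
#' @return The statistic, or `NA_real_` when fewer than 16 values exist
#'   ("not ready").
#' @export
delta_q <- function(q_history) {
  n <- length(q_history)
  if (n < 16L) return(NA_real_)
  last16 <- q_history[(n - 15L):n]
  abs(mean(last16[1:8]) - mean(last16[9:16]))
}

#' Create a test-time termination tracker
#'
#' At test time no ground truth exists, so the agent stops when its Q values
#' plateau: each step the maximum Q value is recorded; once 16 values exist
#' and the statistic [delta_q()] falls below `threshold` (within the step
#' budget) a sub-threshold event is counted, and the episode terminates when
#' the event count reaches `t_q` with the statistic still sub-threshold, or
#' when the step budget `n_test` is exhausted. Events accumulate (they need
#' not be consecutive).
#'
#' @param threshold plateau threshold on the statistic (default 0.3).
#' @param t_q required number of sub-threshold events (default 2).
#' @param n_test step budget (default 60).
#' @return A list of class `test_termination`.
#' @export
test_termination <- function(threshold = 0.3, t_q = 2L, n_test = 60L) {
  structure(list(q_history = numeric(0), q = 0L, step = 0L,
                 threshold = threshold, t_q = as.integer(t_q),
                 n_test = as.integer(n_test)),
            class = "test_termination")
}

#' Update the test-time termination tracker with a new Q value
#'
#' @param tt a [test_termination()] tracker.
#' @param new_q the Q value recorded at this step (the per-step maximum of
#'   the four-action Q vector).
#' @return `list(tt, terminate)` where `terminate` is logical and `tt$reason`
#'   records `"delta_q"` or `"budget"` once terminal.
#' @export
tt_update <- function(tt, new_q) {
  stopifnot(inherits(tt, "test_termination"))
  tt$step <- tt$step + 1L
  tt$q_history <- c(tt$q_history, new_q)
  dq <- delta_q(tt$q_history)
  sub <- !is.na(dq) && dq < tt$threshold
  if (sub && tt$step < tt$n_test) tt$q <- tt$q + 1L
  terminate <- (sub && tt$q == tt$t_q) || tt$step >= tt$n_test
  if (terminate) tt$reason <- if (sub && tt$q == tt$t_q) "delta_q" else "budget"
  list(tt = tt, terminate = terminate)
}
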