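# Training of the per-side refinement agents and the grid-offset evaluation
# protocol used for checkpoint selection.

#' Training configuration for a refinement agent
#'
#' Defaults follow the adaptive-moment training recipe of the method: 80
#' epochs, learning rate 1e-4, batch size 32, at most 25 episodes per image,
#' target-network sync every 50 updates, one optimizer step each time the
#' replay memory size is a multiple of 5 (and at least one batch), a step
#' budget of 100 per training episode, discount 0.95, and episode starts at
#' the ground truth displaced per-axis by a margin drawn from
#' `c(-4, -6, -8, -10, -12, -14, 4, 6, 8, 10, 12, 14)`.
#'
#' @param epochs,learning_rate,batch_size optimizer settings.
#' @param max_episode episodes per image per epoch (P).
#' @param update_frequency target-network sync period in optimizer steps (L).
#' @param sample_step memory-size modulus triggering an optimizer step (S).
#' @param n_train per-episode step budget.
#' @param gamma discount factor.
#' @param train_margins nonzero integer offsets (pixels) the per-axis start
#'   displacement is drawn from.
#' @param region_side active-region side in pixels.
#' @param patch_size observation patch side.
#' @param term_rule `"leq"` (distance <= 1 px) or `"strict"` (< 1 px).
#' @param eps_start,eps_end epsilon-greedy schedule: linear decay from
#'   `eps_start` to `eps_end` over the first half of all episodes, then
#'   constant.
#' @param seed integer seed for the whole training run.
#' @return A list of class `sarlm_config`.
#' @export
sarlm_config <- function(epochs = 80L, learning_rate = 1e-4, batch_size = 32L,
                         max_episode = 25L, update_frequency = 50L,
                         sample_step = 5L, n_train = 100L, gamma = 0.95,
                         train_margins = c(-4L, -6L, -8L, -10L, -12L, -14L,
                                           4L, 6L, 8L, 10L, 12L, 14L),
                         region_side = 80L, patch_size = 32L,
                         term_rule = c("leq", "strict"),
                         eps_start = 1.0, eps_end = 0.1, seed = 1L) {
  cfg <- list(epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              max_episode = as.integer(max_episode),
              update_frequency = as.integer(update_frequency),
              sample_step = as.integer(sample_step),
              n_train = as.integer(n_train), gamma = gamma,
              train_margins = as.integer(train_margins),
              region_side = as.integer(region_side),
              patch_size = as.integer(patch_size),
              term_rule = match.arg(term_rule),
              eps_start = eps_start, eps_end = eps_end,
              seed = as.integer(seed))
  stopifnot(cfg$epochs >= 1L, cfg$learning_rate > 0, cfg$batch_size >= 1L,
            cfg$max_episode >= 1L, cfg$update_frequency >= 1L,
            cfg$sample_step >= 1L, cfg$n_train >= 1L,
            cfg$gamma > 0, cfg$gamma < 1,
            all(cfg$train_margins != 0L),
            cfg$region_side >= cfg$patch_size)
  class(cfg) <- "sarlm_config"
  cfg
}

dist_hit <- function(pos, target, rule) {
  d <- euclid_dist(pos, target)
  if (rule == "leq") d <= 1 else d < 1
}

annotation_side <- function(ann, side) {
  if (side == "left") ann$left else ann$right
}

batch_targets <- function(online, target_net, batch, gamma, variant) {
  B <- length(batch)
  ps <- dim(batch[[1]]$s)
  xs <- array(0, c(ps, B)); xsp <- array(0, c(ps, B))
  for (i in seq_len(B)) {
    xs[, , , i] <- batch[[i]]$s
    xsp[, , , i] <- batch[[i]]$sp
  }
  rewards <- vapply(batch, `[[`, numeric(1), "r")
  terminal <- vapply(batch, `[[`, logical(1), "terminal")
  actions <- vapply(batch, `[[`, integer(1), "a")
  q_next_target <- q_values_batch(target_net, xsp)
  q_next_online <- if (variant %in% c("ddqn", "duelddqn"))
    q_values_batch(online, xsp) else NULL
  targets <- td_target(rewards, terminal, gamma, variant,
                       q_next_target, q_next_online)
  list(xs = xs, actions = actions, targets = targets)
}

#' Train one refinement agent
#'
#' Implements the per-side training loop: per epoch the images are shuffled;
#' per image the replay memory is reset and `max_episode` episodes are run,
#' each starting at the ground-truth point displaced per-axis by a margin
#' drawn from `train_margins` (clamped into the image); the agent interacts
#' epsilon-greedily until the termination rule fires or the step budget is
#' exhausted; transitions are stored, and whenever the memory holds at least
#' one batch and its size is a multiple of `sample_step` a batch is sampled,
#' TD targets are formed per the variant, and one Adam step is taken; the
#' target network is synced every `update_frequency` optimizer steps.
#'
#' The left and right agents share an architecture but never weights; train
#' them separately.
#'
#' @param dataset list of `list(scan, ann)` pairs.
#' @param side `"left"` or `"right"`.
#' @param cfg a [sarlm_config()].
#' @param variant Q-network variant, see [q_network()].
#' @param conv_filters,fc_units network architecture.
#' @param validation optional list of `list(scan, ann)` pairs; when given
#'   together with `eval_every > 0`, [evaluate_grid()] runs every
#'   `eval_every` epochs and the weights with minimum grid AED are kept.
#' @param eval_every epochs between validation evaluations (0 = off).
#' @param verbose print per-epoch progress.
#' @return A list of class `sarlm_model` with the trained network, the
#'   per-epoch mean episode reward curve, the recorded episode start offsets,
#'   and (when validated) the AED curve and selected epoch.
#' @export
train_sarlm <- function(dataset, side = c("left", "right"),
                        cfg = sarlm_config(), variant = "dqn",
                        conv_filters = c(32L, 32L, 32L), fc_units = 256L,
                        validation = NULL, eval_every = 0L, verbose = FALSE) {
  side <- match.arg(side)
  stopifnot(inherits(cfg, "sarlm_config"), length(dataset) >= 1L)
  set.seed(cfg$seed)
  online <- q_network(variant, conv_filters, fc_units,
                      patch_size = cfg$patch_size, gamma = cfg$gamma)
  target_net <- online
  opt <- adam_state(online$weights)
  update_count <- 0L
  n_img <- length(dataset)
  total_episodes <- cfg$epochs * n_img * cfg$max_episode
  half_episodes <- max(1L, total_episodes %/% 2L)
  episode_counter <- 0L
  reward_curve <- numeric(cfg$epochs)
  val_curve <- c()
  best <- list(aed = Inf, weights = NULL, epoch = NA_integer_)
  offsets_log <- matrix(NA_integer_, 0L, 2L)
  capacity <- cfg$max_episode * cfg$n_train

  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_img)
    ep_rewards <- c()
    for (j in ord) {
      scan <- dataset[[j]]$scan
      ann <- dataset[[j]]$ann
      if (is.null(ann)) {
        warning("image ", j, " has no annotation for side '", side, "'; skipped")
        next
      }
      tgt <- annotation_side(ann, side)
      w <- ncol(scan$pixels); h <- nrow(scan$pixels)
      mem <- replay_memory(capacity)
      for (ep in seq_len(cfg$max_episode)) {
        episode_counter <- episode_counter + 1L
        epsilon <- cfg$eps_start + (cfg$eps_end - cfg$eps_start) *
          min(1, episode_counter / half_episodes)
        off <- c(sample(cfg$train_margins, 1L), sample(cfg$train_margins, 1L))
        offsets_log <- rbind(offsets_log, off)
        start <- c(min(max(tgt[1] + off[1], 0), w - 1),
                   min(max(tgt[2] + off[2], 0), h - 1))
        region <- active_region(start, w, h, side = cfg$region_side)
        state <- agent_reset(scan, region, start, cfg$patch_size)
        step <- 0L
        total_r <- 0
        repeat {
          qv <- q_values(online, state)
          a <- select_action(qv, epsilon)
          res <- agent_step(scan, region, state, a, tgt)
          step <- step + 1L
          hit <- dist_hit(res$state$position, tgt, cfg$term_rule)
          mem_push(mem, list(s = state$patches, a = as.integer(a),
                             r = res$reward, sp = res$state$patches,
                             terminal = hit))
          total_r <- total_r + res$reward
          state <- res$state
          if (mem_size(mem) >= cfg$batch_size &&
              mem_size(mem) %% cfg$sample_step == 0L) {
            batch <- mem_sample(mem, cfg$batch_size)
            bt <- batch_targets(online, target_net, batch, cfg$gamma, variant)
            q_pred <- q_values_batch(online, bt$xs)
            taken <- cbind(bt$actions, seq_along(bt$actions))
            grad_out <- matrix(0, 4L, length(bt$actions))
            grad_out[taken] <- 2 * (q_pred[taken] - bt$targets) /
              length(bt$actions)
            bw <- nn_grad(online$weights, online$spec, bt$xs, grad_out)
            upd <- adam_step(online$weights, bw$grads, opt, cfg$learning_rate)
            online$weights <- upd$weights
            opt <- upd$state
            update_count <- update_count + 1L
            if (update_count %% cfg$update_frequency == 0L)
              target_net <- sync_target(target_net, online)
          }
          if (hit || step >= cfg$n_train) break
        }
        ep_rewards <- c(ep_rewards, total_r)
      }
    }
    reward_curve[epoch] <- mean(ep_rewards)
    if (!is.null(validation) && eval_every > 0L && epoch %% eval_every == 0L) {
      model_now <- structure(list(network = online, side = side,
                                  variant = variant, cfg = cfg),
                             class = "sarlm_model")
      g <- evaluate_grid(model_now, validation, side)
      val_curve <- c(val_curve, g$aed)
      if (g$aed < best$aed) best <- list(aed = g$aed, weights = online$weights,
                                         epoch = epoch)
      if (verbose) message(sprintf("epoch %d: reward %.3f, grid AED %.2f",
                                   epoch, reward_curve[epoch], g$aed))
    } else if (verbose) {
      message(sprintf("epoch %d: reward %.3f", epoch, reward_curve[epoch]))
    }
  }
  if (!is.null(best$weights)) online$weights <- best$weights
  structure(list(network = online, side = side, variant = variant, cfg = cfg,
                 reward_curve = reward_curve, val_curve = val_curve,
                 best_epoch = best$epoch, start_offsets = offsets_log,
                 n_updates = update_count),
            class = "sarlm_model")
}

#' @export
q_values.sarlm_model <- function(net, state) q_values(net$network, state)

#' @export
print.sarlm_model <- function(x, ...) {
  cat(sprintf("<sarlm_model %s/%s: %d epochs, %d updates, final mean reward %.3f>\n",
              x$variant, x$side, length(x$reward_curve), x$n_updates,
              tail(x$reward_curve, 1)))
  invisible(x)
}

#' The 16-point validation start grid
#'
#' Cartesian product of the per-axis margins (default `c(-4, -14, 4, 14)`
#' for both axes), giving 16 start offsets around the ground truth with
#' initial distances between `sqrt(32)` (~5.66 px) and `sqrt(392)`
#' (~19.8 px).
#'
#' @param x_margins,y_margins per-axis offsets in pixels.
#' @return Integer matrix with columns `dx`, `dy`.
#' @export
grid_offsets <- function(x_margins = c(-4L, -14L, 4L, 14L),
                         y_margins = c(-4L, -14L, 4L, 14L)) {
  g <- expand.grid(dx = as.integer(x_margins), dy = as.integer(y_margins))
  as.matrix(g)
}

#' Evaluate an agent from the 16-offset start grid
#'
#' For each scan and each offset of [grid_offsets()], the agent starts at
#' the ground truth plus the offset (clamped into the image) and runs
#' greedily under the test-time termination rule; the mean Euclidean
#' distance of the final positions to the ground truth is reported.
#'
#' @param model a `sarlm_model` (or any object with a [q_values()] method).
#' @param scans list of `list(scan, ann)` pairs.
#' @param side `"left"` or `"right"`.
#' @param x_margins,y_margins grid margins.
#' @param region_side,patch_size,threshold,t_q,n_test test-episode settings,
#'   see [locate_side()].
#' @return `list(aed, final_dists, initial_dists)`.
#' @export
evaluate_grid <- function(model, scans, side = c("left", "right"),
                          x_margins = c(-4L, -14L, 4L, 14L),
                          y_margins = c(-4L, -14L, 4L, 14L),
                          region_side = 80L, patch_size = 32L,
                          threshold = 0.3, t_q = 2L, n_test = 60L) {
  side <- match.arg(side)
  offsets <- grid_offsets(x_margins, y_margins)
  finals <- c(); initials <- c()
  for (pair in scans) {
    tgt <- annotation_side(pair$ann, side)
    w <- ncol(pair$scan$pixels); h <- nrow(pair$scan$pixels)
    for (k in seq_len(nrow(offsets))) {
      start <- c(min(max(tgt[1] + offsets[k, 1], 0), w - 1),
                 min(max(tgt[2] + offsets[k, 2], 0), h - 1))
      res <- locate_side(pair$scan, model, start, region_side, patch_size,
                         threshold, t_q, n_test)
      finals <- c(finals, euclid_dist(res$final, tgt))
      initials <- c(initials, euclid_dist(start, tgt))
    }
  }
  list(aed = mean(finals), final_dists = finals, initial_dists = initials)
}
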