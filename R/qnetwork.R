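# Value networks for the refinement agent: plain DQN, double DQN, and the
# dueling variants, plus the experience replay memory.

#' Create a Q-network
#'
#' Input is the `(32, 32, 4)` patch-history state; output is one Q value per
#' action (UP, DOWN, LEFT, RIGHT). The trunk is a stack of 3x3 conv / ReLU /
#' 2x2 max-pool stages followed by a ReLU fully-connected layer. Dueling
#' variants split into a scalar value head and a four-way advantage head
#' aggregated as `Q(s, a) = V(s) + A(s, a) - mean_a A(s, a)`, so that
#' `mean_a Q(s, a) = V(s)` exactly. The variant also selects the TD-target
#' estimator used during training (see [td_target()]).
#'
#' @param variant one of `"dqn"`, `"ddqn"`, `"dueldqn"`, `"duelddqn"`.
#' @param conv_filters filters per conv stage.
#' @param fc_units fully-connected width.
#' @param patch_size,n_channels input geometry.
#' @param n_actions output dimension (4).
#' @param gamma discount factor (default 0.95).
#' @param seed optional seed for weight initialisation.
#' @return A list of class `dqn_network` with `weights`, `spec`, `variant`,
#'   `gamma`.
#' @export
q_network <- function(variant = c("dqn", "ddqn", "dueldqn", "duelddqn"),
                      conv_filters = c(32L, 32L, 32L), fc_units = 256L,
                      patch_size = 32L, n_channels = 4L, n_actions = 4L,
                      gamma = 0.95, seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dueling <- variant %in% c("dueldqn", "duelddqn")
  spec <- nn_spec(patch_size, n_channels, conv_filters, fc_units,
                  n_out = n_actions, dueling = dueling)
  structure(list(weights = nn_init_weights(spec), spec = spec,
                 variant = variant, gamma = gamma),
            class = "dqn_network")
}

#' Q values of a state
#'
#' Generic so that trained models (and test doubles) can stand in for the
#' bare network. The returned vector is named by action in the fixed order
#' UP, DOWN, LEFT, RIGHT.
#'
#' @param net a `dqn_network`, a trained `sarlm_model`, or any object with a
#'   method.
#' @param state an `agent_state` from [agent_reset()] / [agent_step()].
#' @return Named numeric vector of length 4.
#' @export
q_values <- function(net, state) UseMethod("q_values")

#' @export
q_values.dqn_network <- function(net, state) {
  stopifnot(inherits(state, "agent_state"))
  d <- dim(state$patches)
  if (d[1] != net$spec$in_hw || d[3] != net$spec$in_ch)
    stop("state patch stack is ", d[1], "x", d[2], "x", d[3],
         ", expected ", net$spec$in_hw, "x", net$spec$in_hw, "x", net$spec$in_ch)
  setNames(drop(nn_forward(net$weights, net$spec, state$patches)), names(ACTIONS))
}

#' @export
q_values.function <- function(net, state) {
  # a plain function `state -> Q vector` can stand in for a network
  setNames(as.numeric(net(state)), names(ACTIONS))
}

# batched forward over an (size, size, 4, N) array of states
q_values_batch <- function(net, x) {
  nn_forward(net$weights, net$spec, x)
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action; otherwise the argmax
#' of the Q vector with ties broken toward the lowest action index.
#'
#' @param qvec numeric Q vector of length 4.
#' @param epsilon exploration probability in \[0, 1\].
#' @return An action code from [ACTIONS].
#' @export
select_action <- function(qvec, epsilon = 0) {
  stopifnot(length(qvec) == 4L, epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && runif(1) < epsilon) return(sample.int(4L, 1L))
  which.max(qvec)
}

#' TD targets for a batch of transitions
#'
#' Terminal transitions bootstrap nothing: the target is the reward alone.
#' Non-terminal targets depend on the variant: the single-estimator rule
#' (`dqn`, `dueldqn`) takes `R + gamma * max_a' Q(s', a'; theta')` from the
#' target network; the double-estimator rule (`ddqn`, `duelddqn`) selects the
#' argmax action with the online network and evaluates it with the target
#' network, `R + gamma * Q(s', argmax_a' Q(s', a'; theta); theta')`.
#'
#' @param rewards numeric vector of rewards.
#' @param terminal logical vector of terminal flags.
#' @param gamma discount factor.
#' @param variant network variant string.
#' @param q_next_target matrix (4 x N) of target-network Q values at `s'`.
#' @param q_next_online matrix (4 x N) of online-network Q values at `s'`;
#'   required for the double-estimator variants.
#' @return Numeric vector of targets.
#' @export
td_target <- function(rewards, terminal, gamma, variant,
                      q_next_target, q_next_online = NULL) {
  stopifnot(length(rewards) == length(terminal),
            ncol(q_next_target) == length(rewards))
  double_est <- variant %in% c("ddqn", "duelddqn")
  if (double_est && is.null(q_next_online))
    stop("double-estimator variants need the online network's Q(s', .)")
  boot <- if (double_est) {
    idx <- apply(q_next_online, 2L, which.max)
    q_next_target[cbind(idx, seq_along(rewards))]
  } else {
    apply(q_next_target, 2L, max)
  }
  rewards + gamma * boot * !terminal
}

#' Mean squared TD error
#'
#' @param q_taken Q values of the taken actions under the online network.
#' @param targets TD targets from [td_target()].
#' @return Scalar loss.
#' @export
dqn_loss <- function(q_taken, targets) {
  stopifnot(length(q_taken) == length(targets))
  mean((targets - q_taken)^2)
}

#' Copy online weights into the target network
#'
#' @param target_net,online_net `dqn_network` objects of identical
#'   architecture.
#' @return `target_net` with the online weights.
#' @export
sync_target <- function(target_net, online_net) {
  if (!identical(lapply(target_net$weights, dim), lapply(online_net$weights, dim)))
    stop("network architectures do not match")
  target_net$weights <- online_net$weights
  target_net
}

# ---- experience replay -----------------------------------------------------

#' Create an experience replay memory
#'
#' FIFO store of transitions `(s, a, R, s', terminal)` with bounded capacity.
#'
#' @param capacity maximum number of stored transitions.
#' @return An environment of class `replay_memory`.
#' @export
replay_memory <- function(capacity = 2500L) {
  m <- new.env(parent = emptyenv())
  m$records <- vector("list", capacity)
  m$capacity <- as.integer(capacity)
  m$size <- 0L
  m$head <- 0L       # index of the most recently written slot
  class(m) <- "replay_memory"
  m
}

#' Store a transition
#' @param m a [replay_memory()].
#' @param transition `list(s, a, r, sp, terminal)` where `s`/`sp` are the
#'   patch-stack arrays of the state and next state.
#' @return The memory size after insertion, invisibly.
#' @export
mem_push <- function(m, transition) {
  m$head <- m$head %% m$capacity + 1L
  m$records[[m$head]] <- transition
  m$size <- min(m$size + 1L, m$capacity)
  invisible(m$size)
}

#' Number of stored transitions
#' @param m a [replay_memory()].
#' @export
mem_size <- function(m) m$size

#' Sample a batch of stored transitions uniformly at random
#' @param m a [replay_memory()].
#' @param n batch size.
#' @return List of transitions.
#' @export
mem_sample <- function(m, n) {
  stopifnot(m$size >= 1L)
  m$records[sample.int(m$size, n, replace = n > m$size)]
}
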