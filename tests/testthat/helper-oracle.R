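# Independent tabular Q-learning oracle on a small grid world sharing the
# package's action set, reward and termination semantics. Used to check that
# the deep agent's environment is the textbook MDP it claims to be.

# deltas must match the package ACTIONS ordering (UP, DOWN, LEFT, RIGHT)
oracle_deltas <- list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0))

oracle_clamp <- function(p, n) pmin(pmax(p, 0L), n - 1L)

# off-policy tabular Q-learning with a uniform behaviour policy; alpha = 1 is
# exact for a deterministic environment
tabular_q_learn <- function(n = 9L, target = c(4L, 4L), gamma = 0.95,
                            episodes = 2000L, max_steps = 40L, seed = 1L) {
  set.seed(seed)
  Q <- array(0, c(n, n, 4L))      # [x + 1, y + 1, action]
  for (ep in seq_len(episodes)) {
    pos <- c(sample.int(n, 1L) - 1L, sample.int(n, 1L) - 1L)
    step <- 0L
    while (!train_terminated(pos, target, step, n_train = max_steps,
                             rule = "strict")) {
      a <- sample.int(4L, 1L)
      nxt <- oracle_clamp(pos + oracle_deltas[[a]], n)
      r <- compute_reward(pos, nxt, target)
      hit <- euclid_dist(nxt, target) < 1
      boot <- if (hit) 0 else max(Q[nxt[1] + 1L, nxt[2] + 1L, ])
      Q[pos[1] + 1L, pos[2] + 1L, a] <- r + gamma * boot
      pos <- nxt
      step <- step + 1L
    }
  }
  Q
}

# greedy rollout; returns the visited positions (including start and end)
tabular_greedy_path <- function(Q, start, target, n = 9L, max_steps = 100L) {
  pos <- start
  path <- list(pos)
  step <- 0L
  while (euclid_dist(pos, target) >= 1 && step < max_steps) {
    a <- which.max(Q[pos[1] + 1L, pos[2] + 1L, ])
    pos <- oracle_clamp(pos + oracle_deltas[[a]], n)
    path[[length(path) + 1L]] <- pos
    step <- step + 1L
  }
  path
}
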