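# The scaled-down end-to-end phantom study shared by the acceptance tests:
# 40 training / 10 test phantoms at 128 x 128, left and right DQN agents at
# reduced settings (6 epochs, 5 episodes per image), the heuristic
# initializer perturbed by 8-14 px per axis standing in for a realistic
# coarse locator. Trained once per session and memoised.

.study_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(.study_cache$fx)) return(.study_cache$fx)
  seed <- 2024L
  train <- make_scan_pairs(40L, seed0 = seed + 100L)
  test <- make_scan_pairs(10L, seed0 = seed + 900L)

  cfg <- function(s) sarlm_config(epochs = 6L, max_episode = 5L,
                                  n_train = 100L, seed = s)
  left <- train_sarlm(train, "left", cfg(seed + 1L), variant = "dqn",
                      conv_filters = c(8L, 8L, 16L), fc_units = 64L)
  right <- train_sarlm(train, "right", cfg(seed + 2L), variant = "dqn",
                       conv_filters = c(8L, 8L, 16L), fc_units = 64L)

  # heuristic initial points displaced by +/- 8-14 px per axis
  set.seed(seed + 3L)
  inits <- lapply(test, function(pair) {
    base <- heuristic_initializer(pair$scan)
    w <- ncol(pair$scan$pixels); h <- nrow(pair$scan$pixels)
    jit <- function(p) {
      mag <- sample(8:14, 2L, replace = TRUE)
      sgn <- sample(c(-1L, 1L), 2L, replace = TRUE)
      c(min(max(p[1] + mag[1] * sgn[1], 0), w - 1),
        min(max(p[2] + mag[2] * sgn[2], 0), h - 1))
    }
    initial_points(jit(base$left), jit(base$right), source = base$source)
  })
  joints <- lapply(seq_along(test), function(i)
    locate_joint(test[[i]]$scan, inits[[i]], left, right))
  truths <- lapply(test, `[[`, "ann")

  .study_cache$fx <- list(train = train, test = test, left = left,
                          right = right, inits = inits, joints = joints,
                          truths = truths)
  .study_cache$fx
}
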