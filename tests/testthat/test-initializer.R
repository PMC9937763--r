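test_that("heuristic initializer recovers the endpoints of the dark dome", {
  for (seed in c(7, 21, 35)) {
    g <- generate_bscan(noiseless_config(seed = seed), 50, seed = seed)
    ip <- heuristic_initializer(g$scan)
    expect_false(ip$fallback)
    expect_lte(euclid_dist(ip$left, g$ann$left), 2)
    expect_lte(euclid_dist(ip$right, g$ann$right), 2)
  }
})

test_that("heuristic initializer falls back with a warning on blank images", {
  blank <- bscan(matrix(255, 96, 96))
  expect_warning(ip <- heuristic_initializer(blank), "fallback")
  expect_true(ip$fallback)
  expect_equal(unname(ip$left), c(24, 48))
  expect_equal(unname(ip$right), c(72, 48))
})

test_that("heuristic initializer commutes with horizontal flips", {
  g <- generate_bscan(noiseless_config(seed = 13), 42, seed = 13)
  ip <- heuristic_initializer(g$scan)
  fl <- augment_hflip(g$scan, g$ann)
  ipf <- heuristic_initializer(fl$scan)
  w <- ncol(g$scan$pixels)
  expect_equal(unname(ipf$left), c(w - 1 - ip$right[["x"]], ip$right[["y"]]))
  expect_equal(unname(ipf$right), c(w - 1 - ip$left[["x"]], ip$left[["y"]]))
})

test_that("multitask initializer trains to within the agent's reachable radius", {
  # 200 phantoms (1 in 10 lesion-free for the presence head), 40 epochs
  mkpairs <- function(n, seed0) lapply(seq_len(n), function(i) {
    set.seed(seed0 + i)
    d <- if (i %% 10 == 0) NA else sample(24:60, 1)
    generate_bscan(phantom_config(seed = seed0 + i), d, seed = seed0 + i)
  })
  train <- mkpairs(200, 3000)
  val <- Filter(function(p) !is.null(p$ann), mkpairs(40, 8000))
  model <- train_initializer(train, initializer_config(), seed = 5)
  # training curve decreases once smoothed over 5 epochs
  sm <- stats::filter(model$loss_curve, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.01))    # non-increasing up to noise
  expect_lt(tail(sm, 1), head(sm, 1) / 5)
  # held-out endpoint errors stay inside the refinement agent's 19-px radius
  errs <- vapply(val, function(p) {
    ip <- predict_initial(model, p$scan)
    max(euclid_dist(ip$left, p$ann$left), euclid_dist(ip$right, p$ann$right))
  }, numeric(1))
  expect_lte(max(errs), 19)
  # predictions are integer-valued and clamped inside the image
  ip <- predict_initial(model, val[[1]]$scan)
  expect_true(all(c(ip$left, ip$right) >= 0))
  expect_true(all(c(ip$left[["x"]], ip$right[["x"]]) <= ncol(val[[1]]$scan$pixels) - 1))
  expect_identical(c(ip$left, ip$right), round(c(ip$left, ip$right)))
})

test_that("initializer training is seed-deterministic and accepts one image", {
  pairs <- make_scan_pairs(10, seed0 = 4000)
  cfg <- initializer_config(epochs = 3, batch_size = 5,
                            conv_filters = c(4L, 8L), fc_units = 16L)
  m1 <- train_initializer(pairs, cfg, seed = 9)
  m2 <- train_initializer(pairs, cfg, seed = 9)
  expect_identical(m1$loss_curve, m2$loss_curve)
  expect_identical(m1$weights, m2$weights)
  m3 <- train_initializer(pairs[1], cfg, seed = 9)   # degenerate but legal
  expect_length(m3$loss_curve, 3L)
  expect_error(train_initializer(list(), cfg, seed = 9), "at least one")
})
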