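# End-to-end orchestration: phantom generation -> preprocessing ->
# initializer -> per-side agent training -> cascaded location -> evaluation.

#' Default pipeline configuration
#'
#' A complete, editable configuration for [run_pipeline()]. The `phantom`
#' section mirrors [phantom_config()]; `initializer` selects the heuristic
#' detector or the multitask CNN and an optional start-point perturbation
#' (to emulate a less accurate initial locator); `agent` mirrors
#' [sarlm_config()] plus the network architecture.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @return Nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    phantom = list(n_train_patients = 5L, n_test_patients = 2L,
                   image_height = 128L, image_width = 128L,
                   n_frames_per_patient = 8L,
                   lesion_max_diameter_range = c(24L, 60L),
                   lesion_height_range = c(10L, 22L),
                   band_intensity_levels = c(170, 210, 150),
                   speckle_sigma = 0.2, background_level = 20),
    preprocess = list(denoise = "none", strength = 25),
    initializer = list(type = "heuristic", perturb = c(0L, 0L),
                       epochs = 40L, learning_rate = 0.001, batch_size = 20L),
    agent = list(variant = "dqn", epochs = 4L, max_episode = 5L,
                 learning_rate = 1e-4, batch_size = 32L,
                 update_frequency = 50L, sample_step = 5L, n_train = 100L,
                 gamma = 0.95, region_side = 80L,
                 conv_filters = c(8L, 8L, 16L), fc_units = 64L),
    evaluate = list(threshold = 0.3, t_q = 2L, n_test = 60L)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
    else jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  required <- list(seed = NULL,
                   phantom = c("n_train_patients", "n_test_patients"),
                   initializer = c("type"),
                   agent = c("variant", "epochs", "max_episode"),
                   evaluate = NULL)
  for (section in names(required)) {
    if (is.null(config[[section]]))
      stop("config is missing required field '", section, "'")
    for (f in required[[section]])
      if (is.null(config[[section]][[f]]))
        stop("config is missing required field '", section, ".", f, "'")
  }
  defaults <- default_pipeline_config(config$seed)
  for (section in c("phantom", "preprocess", "initializer", "agent", "evaluate")) {
    merged <- defaults[[section]]
    for (nm in names(config[[section]])) merged[[nm]] <- config[[section]][[nm]]
    config[[section]] <- merged
  }
  config
}

pipeline_stage <- function(name, log_path, expr) {
  cat(sprintf("[%s] stage %s\n", format(Sys.time(), "%H:%M:%S"), name),
      file = log_path, append = TRUE)
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

perturb_initializer <- function(base, magnitudes, seed) {
  force(base); force(magnitudes)
  counter <- new.env(parent = emptyenv()); counter$i <- 0L
  function(scan) {
    init <- predict_initial(base, scan)
    counter$i <- counter$i + 1L
    set.seed(seed + counter$i)
    w <- ncol(scan$pixels); h <- nrow(scan$pixels)
    jit <- function(p) {
      mag <- sample(magnitudes[1]:magnitudes[2], 2L, replace = TRUE)
      sgn <- sample(c(-1L, 1L), 2L, replace = TRUE)
      c(min(max(p[1] + mag[1] * sgn[1], 0), w - 1),
        min(max(p[2] + mag[2] * sgn[2], 0), h - 1))
    }
    initial_points(jit(init$left), jit(init$right),
                   source = init$source, fallback = init$fallback)
  }
}

#' Run the complete phantom study end to end
#'
#' Generates phantom patient stacks, optionally denoises them, prepares the
#' initializer (heuristic or trained CNN, optionally perturbed), trains the
#' left and right agents, locates the boundary points on every test frame,
#' and writes datasets, result tables, a JSON report, and a log (including
#' the exact configuration) into `out_dir`. Rerunning with the same
#' configuration reproduces the result tables bit for bit.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or
#'   the path of a JSON/YAML file with the same structure.
#' @param out_dir artifact directory, created if missing.
#' @return Invisibly, `list(report, results, models)`; `report` holds the
#'   evaluation summary written to `report.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = tempfile("dqloc_run_")) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  seed <- as.integer(config$seed)

  ph <- config$phantom
  data <- pipeline_stage("generate", log_path, {
    mk_cfg <- function(s) phantom_config(
      image_height = ph$image_height, image_width = ph$image_width,
      n_frames_per_patient = ph$n_frames_per_patient,
      lesion_max_diameter_range = ph$lesion_max_diameter_range,
      lesion_height_range = ph$lesion_height_range,
      band_intensity_levels = ph$band_intensity_levels,
      speckle_sigma = ph$speckle_sigma,
      background_level = ph$background_level, seed = s)
    train_series <- lapply(seq_len(ph$n_train_patients), function(i)
      generate_patient_series(mk_cfg(seed + 1000L + i),
                              patient_id = sprintf("train%02d", i)))
    test_series <- lapply(seq_len(ph$n_test_patients), function(i)
      generate_patient_series(mk_cfg(seed + 2000L + i),
                              patient_id = sprintf("test%02d", i)))
    write_dataset(train_series, file.path(out_dir, "data", "train"))
    write_dataset(test_series, file.path(out_dir, "data", "test"))
    list(train = train_series, test = test_series)
  })

  pp <- config$preprocess
  data <- pipeline_stage("preprocess", log_path, {
    if (identical(pp$denoise, "none")) data
    else {
      den <- function(series_list) lapply(series_list, function(s) {
        s$scans <- lapply(s$scans, function(pair) {
          pair$scan <- denoise_bscan(pair$scan, pp$denoise, pp$strength)
          pair
        })
        s
      })
      list(train = den(data$train), test = den(data$test))
    }
  })
  train_pairs <- dataset_pairs(data$train)
  test_pairs <- dataset_pairs(data$test)

  ic <- config$initializer
  initializer <- pipeline_stage("train-init", log_path, {
    base <- if (identical(ic$type, "cnn")) {
      model <- train_initializer(train_pairs,
        initializer_config(epochs = ic$epochs, learning_rate = ic$learning_rate,
                           batch_size = ic$batch_size),
        seed = seed + 31L)
      saveRDS(model, file.path(out_dir, "initializer.rds"))
      model
    } else "heuristic"
    if (any(ic$perturb > 0)) perturb_initializer(base, ic$perturb, seed + 57L)
    else base
  })

  ag <- config$agent
  models <- pipeline_stage("train-agent", log_path, {
    cfg_side <- function(s) sarlm_config(
      epochs = ag$epochs, learning_rate = ag$learning_rate,
      batch_size = ag$batch_size, max_episode = ag$max_episode,
      update_frequency = ag$update_frequency, sample_step = ag$sample_step,
      n_train = ag$n_train, gamma = ag$gamma, region_side = ag$region_side,
      seed = s)
    left <- train_sarlm(train_pairs, "left", cfg_side(seed + 71L),
                        variant = ag$variant, conv_filters = ag$conv_filters,
                        fc_units = ag$fc_units)
    right <- train_sarlm(train_pairs, "right", cfg_side(seed + 72L),
                         variant = ag$variant, conv_filters = ag$conv_filters,
                         fc_units = ag$fc_units)
    saveRDS(left, file.path(out_dir, "agent_left.rds"))
    saveRDS(right, file.path(out_dir, "agent_right.rds"))
    list(left = left, right = right)
  })

  ev <- config$evaluate
  located <- pipeline_stage("locate", log_path, {
    inits <- lapply(test_pairs, function(p) {
      ip <- if (is.function(initializer)) initializer(p$scan)
            else predict_initial(initializer, p$scan)
      ip
    })
    joints <- lapply(seq_along(test_pairs), function(i)
      locate_joint(test_pairs[[i]]$scan, inits[[i]], models$left, models$right,
                   region_side = ag$region_side, threshold = ev$threshold,
                   t_q = ev$t_q, n_test = ev$n_test))
    list(inits = inits, joints = joints)
  })

  report <- pipeline_stage("evaluate", log_path, {
    truths <- lapply(test_pairs, `[[`, "ann")
    rows <- lapply(seq_along(test_pairs), function(i) {
      j <- located$joints[[i]]; ini <- located$inits[[i]]
      data.frame(patient_id = test_pairs[[i]]$scan$patient_id,
                 frame_index = test_pairs[[i]]$scan$frame_index,
                 init_left_x = ini$left[["x"]], init_left_y = ini$left[["y"]],
                 init_right_x = ini$right[["x"]], init_right_y = ini$right[["y"]],
                 final_left_x = j$left$final[["x"]], final_left_y = j$left$final[["y"]],
                 final_right_x = j$right$final[["x"]], final_right_y = j$right$final[["y"]],
                 left_steps = j$left$steps, right_steps = j$right$steps,
                 left_terminated_by = j$left$terminated_by,
                 right_terminated_by = j$right$terminated_by,
                 diameter = lesion_diameter(j$left$final, j$right$final),
                 truth_diameter = lesion_diameter(truths[[i]]$left, truths[[i]]$right))
    })
    results <- do.call(rbind, rows)
    write.csv(results, file.path(out_dir, "results.csv"), row.names = FALSE)
    cr <- correction_rate(located$inits, located$joints, truths)
    rep <- list(seed = seed,
                n_train_images = length(train_pairs),
                n_test_images = length(test_pairs),
                initializer_aed = aed(located$inits, truths),
                joint_aed = aed(located$joints, truths),
                correction_rate = cr$rate, corrected = cr$n_success,
                mean_reward_left = tail(models$left$reward_curve, 1),
                mean_reward_right = tail(models$right$reward_curve, 1))
    jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })

  invisible(list(report = report, results = file.path(out_dir, "results.csv"),
                 models = models, out_dir = out_dir))
}
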