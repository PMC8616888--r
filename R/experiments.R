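# Reproducible experiment drivers for the 1D deconvolution case study and the
# three failure-mode detection protocols (prediction error, adversarial
# perturbation, atypical artifact).

#' Experiment configuration for the deconvolution case study
#'
#' Collects the problem, architecture, training-schedule, and evaluation
#' parameters. Every experiment run is fully determined by the configuration
#' and its `seed`; stage seeds (data, base training, interval training, ...)
#' are derived deterministically from the global seed.
#'
#' @param n,nu Signal dimension and spectral decay exponent.
#' @param sigma,noise_mode Training-time noise configuration (see
#'   [inverse_problem()]).
#' @param n_total,split_sizes Dataset size and train/validation/test split.
#' @param jump_count_range,height_range Signal sampler parameters.
#' @param n_layers,channels,kernel_size Architecture of the convolutional
#'   reconstruction network.
#' @param dropout_sites,dropout_rate Dropout positions (also the MCDrop
#'   sampling sites) and rate.
#' @param epochs_base,epochs_inn,epochs_probout Training epochs per stage.
#' @param batch_size,learning_rate Optimiser settings shared by all stages.
#' @param beta Interval tightness parameter; `NULL` selects the mean absolute
#'   error heuristic [select_beta()].
#' @param interval_layers Layers carrying trainable intervals (`NULL` = all).
#' @param mcdrop_T Number of MCDrop forward passes.
#' @param sigma_grid Noise levels for [run_noise_sweep()].
#' @param methods UQ methods to evaluate: subset of
#'   `c("inn", "mcdrop", "probout")`.
#' @param repetitions Repetition count for mean/sd reporting.
#' @param n_eval Optional cap on the number of test samples used by the
#'   detection protocols (`NULL` = all).
#' @param artifact_amplitude,artifact_length Atypical-artifact insertion
#'   parameters.
#' @param attack An [attack_config()] for the adversarial protocol.
#' @param seed Global integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n = 512, nu = 8, sigma = 0.05,
                              noise_mode = "measurement_and_signal",
                              n_total = 2000,
                              split_sizes = c(train = 1600, validation = 200,
                                              test = 200),
                              jump_count_range = c(4, 12),
                              height_range = c(0, 1),
                              n_layers = 10, channels = 32, kernel_size = 5,
                              dropout_sites = c(3, 5, 7), dropout_rate = 0.1,
                              epochs_base = 100, epochs_inn = 100,
                              epochs_probout = 100,
                              batch_size = 32, learning_rate = 1e-3,
                              beta = 2e-3, interval_layers = NULL,
                              mcdrop_T = 64,
                              sigma_grid = c(0, 0.01, 0.02, 0.05, 0.1),
                              methods = c("inn", "mcdrop", "probout"),
                              repetitions = 3, n_eval = NULL,
                              artifact_amplitude = 0.5, artifact_length = 50,
                              attack = attack_config(), seed = 1) {
  methods <- match.arg(methods, c("inn", "mcdrop", "probout"),
                       several.ok = TRUE)
  if (repetitions < 1) stop_contract("`repetitions` must be >= 1")
  cfg <- as.list(environment())
  structure(cfg, class = "experiment_config")
}

# Deterministic per-stage seeds derived from the global seed.
stage_seed <- function(seed, stage) {
  offsets <- c(data = 1L, base = 2L, inn = 3L, probout = 4L, mcdrop = 5L,
               sweep = 6L, adv = 7L, artifact = 8L, eval = 9L)
  (abs(as.integer(seed)) %% 2000000000L) + offsets[[stage]]
}

#' Train all models of the case study
#'
#' Generates the dataset and trains, on its training split, the base
#' reconstruction network, the post-hoc interval network, and (if selected)
#' the direct variance estimation network. All stages are seeded from the
#' configuration seed.
#'
#' @param cfg An [experiment_config()].
#' @return A list of class `uq_experiment` with elements `problem`, `data`,
#'   `base`, `inn`, `probout` (or `NULL`), and `cfg`.
#' @export
train_reference_models <- function(cfg = experiment_config()) {
  problem <- inverse_problem(cfg$n, cfg$nu, noise_mode = cfg$noise_mode,
                             sigma = cfg$sigma)
  data <- make_dataset(problem, cfg$n_total, cfg$split_sizes,
                       cfg$jump_count_range, cfg$height_range,
                       seed = stage_seed(cfg$seed, "data"))
  tr <- dataset_split(data, "train")
  base <- make_conv_net(cfg$n_layers, cfg$channels, cfg$kernel_size,
                        dropout_sites = cfg$dropout_sites,
                        dropout_rate = cfg$dropout_rate,
                        seed = stage_seed(cfg$seed, "base"))
  base <- train_network(base, tr$z, tr$x,
                        training_config(epochs = cfg$epochs_base,
                                        batch_size = cfg$batch_size,
                                        learning_rate = cfg$learning_rate,
                                        seed = stage_seed(cfg$seed, "base")))
  inn <- NULL
  if ("inn" %in% cfg$methods) {
    inn <- wrap_network(base, interval_layers = cfg$interval_layers)
    inn <- train_inn(inn, tr$z, tr$x,
                     training_config(beta = cfg$beta,
                                     epochs = cfg$epochs_inn,
                                     batch_size = cfg$batch_size,
                                     learning_rate = cfg$learning_rate,
                                     seed = stage_seed(cfg$seed, "inn")))
  }
  probout <- NULL
  if ("probout" %in% cfg$methods) {
    probout <- make_probout_net(cfg$n_layers, cfg$channels, cfg$kernel_size,
                                dropout_sites = cfg$dropout_sites,
                                dropout_rate = cfg$dropout_rate,
                                seed = stage_seed(cfg$seed, "probout"))
    probout <- train_probout(probout, tr$z, tr$x,
                             training_config(epochs = cfg$epochs_probout,
                                             batch_size = cfg$batch_size,
                                             learning_rate = cfg$learning_rate,
                                             seed = stage_seed(cfg$seed, "probout")))
  }
  structure(
    list(problem = problem, data = data, base = base, inn = inn,
         probout = probout, cfg = cfg),
    class = "uq_experiment"
  )
}

# Per-method uncertainty heatmaps for a batch of inputs (n x B matrices).
method_uncertainty <- function(bundle, method, z, seed = NULL) {
  switch(method,
    inn = {
      fi <- forward_interval(bundle$inn, z)
      uncertainty_score(fi$lower, fi$upper)
    },
    mcdrop = mcdrop_uncertainty(bundle$base, z, T = bundle$cfg$mcdrop_T,
                                seed = seed),
    probout = probout_uncertainty(probout_predict(bundle$probout, z)$var),
    stop_contract("unknown method '%s'", method)
  )
}

# Per-method point predictions: the base network for INN/MCDrop, the mean
# head for ProbOut.
method_prediction <- function(bundle, method, z) {
  if (method == "probout") {
    probout_predict(bundle$probout, z)$mean
  } else {
    predict_network(bundle$base, z)
  }
}

eval_indices <- function(bundle) {
  idx <- which(bundle$data$split == "test")
  if (!is.null(bundle$cfg$n_eval)) idx <- idx[seq_len(min(bundle$cfg$n_eval, length(idx)))]
  idx
}

#' Mean uncertainty across a noise-level sweep
#'
#' Re-simulates the test-split measurements at every noise level of the grid
#' (under the given noise mode) and reports the mean uncertainty score of
#' each selected UQ method, mirroring the mean-uncertainty-versus-noise
#' summaries of the case study.
#'
#' @param bundle A [train_reference_models()] result.
#' @param sigma_grid Noise levels; defaults to the configuration grid.
#' @param noise_mode Noise model for the sweep.
#' @param methods Methods to evaluate; defaults to the configured ones.
#' @return Data frame with columns `sigma`, `method`, `mean_uncertainty`.
#' @export
run_noise_sweep <- function(bundle, sigma_grid = NULL, noise_mode = NULL,
                            methods = NULL) {
  cfg <- bundle$cfg
  sigma_grid <- sigma_grid %||% cfg$sigma_grid
  noise_mode <- noise_mode %||% cfg$noise_mode
  methods <- methods %||% cfg$methods
  idx <- eval_indices(bundle)
  x_test <- bundle$data$signals[, idx, drop = FALSE]
  rows <- list()
  for (si in seq_along(sigma_grid)) {
    s <- sigma_grid[si]
    problem_s <- inverse_problem(cfg$n, cfg$nu,
                                 noise_mode = if (s == 0) "none" else noise_mode,
                                 sigma = s)
    z <- simulate_measurements(problem_s, x_test,
                               seed = stage_seed(cfg$seed, "sweep") + si)$z
    for (m in methods) {
      u <- method_uncertainty(bundle, m, z,
                              seed = stage_seed(cfg$seed, "mcdrop") + si)
      rows[[length(rows) + 1]] <- data.frame(
        sigma = s, method = m, mean_uncertainty = mean(u))
    }
  }
  do.call(rbind, rows)
}

#' Prediction-error detection protocol
#'
#' Computes, per test sample and method, the performance-weighted correlation
#' coefficient between the uncertainty heatmap and the absolute prediction
#' error, plus the sample's mean squared error.
#'
#' @param bundle A [train_reference_models()] result.
#' @param methods Methods to evaluate.
#' @return Data frame with columns `sample`, `method`, `pwcc`, `mse`.
#' @export
run_error_detection <- function(bundle, methods = NULL) {
  cfg <- bundle$cfg
  methods <- methods %||% cfg$methods
  idx <- eval_indices(bundle)
  z <- bundle$data$z[, idx, drop = FALSE]
  x <- bundle$data$signals[, idx, drop = FALSE]
  rows <- list()
  for (m in methods) {
    u <- method_uncertainty(bundle, m, z, seed = stage_seed(cfg$seed, "mcdrop"))
    pred <- method_prediction(bundle, m, z)
    for (j in seq_len(ncol(z))) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = idx[j], method = m,
        pwcc = pwcc(pred[, j], x[, j], u[, j]),
        mse = mean((pred[, j] - x[, j])^2))
    }
  }
  do.call(rbind, rows)
}

#' Adversarial-perturbation detection protocol
#'
#' For each evaluated test sample, constructs an adversarial target by
#' depressing a random contiguous region of the reconstruction, finds a
#' box-constrained adversarial input, and correlates the change in each
#' method's uncertainty heatmap with the change in the reconstruction.
#'
#' @param bundle A [train_reference_models()] result.
#' @param methods Methods to evaluate.
#' @param n_samples Number of test samples to attack (`NULL` = configured
#'   `n_eval`, or all).
#' @return List with `per_sample` (data frame: `sample`, `method`,
#'   `correlation`, `objective`) and `summary` (mean correlation, sd, and
#'   excluded-count per method).
#' @export
run_adv_detection <- function(bundle, methods = NULL, n_samples = NULL) {
  cfg <- bundle$cfg
  methods <- methods %||% cfg$methods
  idx <- eval_indices(bundle)
  if (!is.null(n_samples)) idx <- idx[seq_len(min(n_samples, length(idx)))]
  rows <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    z <- bundle$data$z[, i]
    x_rec <- as.numeric(predict_network(bundle$base, z))
    region <- sample_attack_region(cfg$n, cfg$attack$region_size,
                                   seed = stage_seed(cfg$seed, "adv") + j)
    tar <- make_adversarial_target(x_rec, region, cfg$attack$depth_factor)
    atk <- adversarial_perturb(bundle$base, pmin(pmax(z, cfg$attack$box[1]),
                                                 cfg$attack$box[2]),
                               tar, cfg$attack)
    change <- abs(x_rec - as.numeric(predict_network(bundle$base, atk$z_adv)))
    for (m in methods) {
      u_ref <- as.numeric(method_uncertainty(bundle, m, z,
                                             seed = stage_seed(cfg$seed, "mcdrop") + 2L * j))
      u_adv <- as.numeric(method_uncertainty(bundle, m, atk$z_adv,
                                             seed = stage_seed(cfg$seed, "mcdrop") + 2L * j + 1L))
      rows[[length(rows) + 1]] <- data.frame(
        sample = i, method = m,
        correlation = heatmap_change_correlation(u_ref, u_adv, change),
        objective = atk$objective)
    }
  }
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       summary = summarize_correlations(per_sample))
}

#' Atypical-artifact detection protocol
#'
#' Inserts an out-of-distribution block artifact into each evaluated test
#' signal, re-simulates measurements and model-based inversions exactly as
#' for clean data, and correlates the change in the uncertainty heatmaps with
#' the binary insertion mask.
#'
#' @param bundle A [train_reference_models()] result.
#' @param methods Methods to evaluate.
#' @param amplitude,block_length Artifact parameters; default to the
#'   configured values.
#' @return List with `per_sample` and `summary` as in [run_adv_detection()].
#' @export
run_artifact_detection <- function(bundle, methods = NULL, amplitude = NULL,
                                   block_length = NULL) {
  cfg <- bundle$cfg
  methods <- methods %||% cfg$methods
  amplitude <- amplitude %||% cfg$artifact_amplitude
  block_length <- block_length %||% cfg$artifact_length
  idx <- eval_indices(bundle)
  rows <- list()
  for (j in seq_along(idx)) {
    i <- idx[j]
    x <- bundle$data$signals[, i]
    art <- insert_artifact(x, amplitude = amplitude,
                           block_length = block_length,
                           seed = stage_seed(cfg$seed, "artifact") + j)
    z_ood <- simulate_measurements(bundle$problem, art$x_ood,
                                   seed = stage_seed(cfg$seed, "artifact") +
                                     length(idx) + j)$z
    z <- bundle$data$z[, i]
    for (m in methods) {
      u_ref <- as.numeric(method_uncertainty(bundle, m, z,
                                             seed = stage_seed(cfg$seed, "mcdrop") + 2L * j))
      u_ood <- as.numeric(method_uncertainty(bundle, m, z_ood,
                                             seed = stage_seed(cfg$seed, "mcdrop") + 2L * j + 1L))
      rows[[length(rows) + 1]] <- data.frame(
        sample = i, method = m,
        correlation = heatmap_change_correlation(u_ref, u_ood, art$mask),
        objective = NA_real_)
    }
  }
  per_sample <- do.call(rbind, rows)
  list(per_sample = per_sample,
       summary = summarize_correlations(per_sample))
}

# Mean/sd of per-sample correlations per method, excluding undefined values
# with a logged count.
summarize_correlations <- function(per_sample) {
  methods <- unique(per_sample$method)
  do.call(rbind, lapply(methods, function(m) {
    v <- per_sample$correlation[per_sample$method == m]
    data.frame(method = m,
               mean_correlation = mean(v, na.rm = TRUE),
               sd_correlation = stats::sd(v, na.rm = TRUE),
               n_used = sum(!is.na(v)),
               n_excluded = sum(is.na(v)))
  }))
}

#' Aggregate a metric over repeated experimental runs
#'
#' @param values Numeric vector, one value per repetition.
#' @return Data frame with `mean`, `sd`, and `n`.
#' @export
summarize_repetitions <- function(values) {
  data.frame(mean = mean(values, na.rm = TRUE),
             sd = stats::sd(values, na.rm = TRUE),
             n = sum(!is.na(values)))
}

#' Directionality evaluation of a trained interval network
#'
#' Convenience wrapper: interval forward pass on the test split and
#' [directionality_accuracy()] binning, plus the coverage at the requested
#' enlargement factors.
#'
#' @param bundle A [train_reference_models()] result (with an INN).
#' @param dr_bins Bin specification for [directionality_accuracy()].
#' @param lambdas Enlargement factors for [empirical_coverage()].
#' @return List with `da` (per-bin table), `coverage` (named vector), and
#'   `containment` (fraction of components with `lower <= prediction <=
#'   upper`; 1 unless the guarantee is broken).
#' @export
evaluate_directionality <- function(bundle, dr_bins = 20, lambdas = c(1, 2, 4)) {
  if (is.null(bundle$inn)) stop_contract("bundle has no trained interval network")
  idx <- eval_indices(bundle)
  z <- bundle$data$z[, idx, drop = FALSE]
  x <- bundle$data$signals[, idx, drop = FALSE]
  fi <- forward_interval(bundle$inn, z)
  da <- directionality_accuracy(fi$lower, fi$upper, fi$prediction, x,
                                dr_bins = dr_bins)
  cov <- vapply(lambdas, function(l) {
    empirical_coverage(fi$lower, fi$upper, x, l, bundle$inn$beta)
  }, numeric(1))
  names(cov) <- paste0("lambda_", lambdas)
  containment <- mean(fi$lower <= fi$prediction & fi$prediction <= fi$upper)
  list(da = da, coverage = cov, containment = containment)
}
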