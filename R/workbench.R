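#' Read and validate an experiment configuration
#'
#' Configurations are plain-text YAML with a top-level `experiment` name
#' (`train`, `recurrent-train`, `sorn`, `cable`, or `analyze`), a `seed`,
#' and one section per module whose keys override the documented defaults.
#' All defaults are filled in explicitly so that the manifest written by
#' [run_experiment()] records every value actually used.
#'
#' @param config a file path to a YAML config or a named list.
#' @return The validated, default-completed config list.
#' @export
read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a file path or a named list")
  known <- c("train", "recurrent-train", "sorn", "cable", "analyze")
  if (is.null(config$experiment) || !(config$experiment %in% known)) {
    stop("config$experiment must be one of: ", paste(known, collapse = ", "))
  }
  if (is.null(config$seed)) config$seed <- 1
  if (!is.numeric(config$seed) || config$seed != round(config$seed)) {
    stop("config$seed must be an integer")
  }
  defaults <- switch(config$experiment,
    "train" = list(M = 30, layers = 1, epsilon = 0.2, zeta = 0.15,
                   eta = 0.05, minibatch = 10, epochs = 5,
                   n_per_class = 50, n_test_per_class = 20, noise_sd = 0.3,
                   scheme = "0", excitability = "constant",
                   activation = "sigmoid"),
    "recurrent-train" = list(M = 50, epsilon = 0.3, zeta = 0.15,
                             eta = 0.05, minibatch = 10, epochs = 20,
                             epoch_len = 250, m_bits = 20,
                             sparse_input = FALSE, scheme = "0",
                             excitability = "constant"),
    "sorn" = list(N_e = 100, N_i = 60, epochs = 25, epoch_len = 300,
                  n_rep = 4, point_neuron = FALSE, n_words_readout = 200,
                  readout_epochs = 10),
    "cable" = list(op = "transfer_resistance", r = 1, l = 500, r_a = 100,
                   g_l = 5e-5, c = 1, rho = 0, tau_f = 0.002,
                   tau_s = 0.05, theta_syn = 1, delta_syn = 1,
                   grid_points = 50),
    "analyze" = list(n = 50, p = 0.3, reps = 100, fan_in = 784, M = 100,
                     epsilon = 0.2))
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  config
}

# parse a scheme spec like "0", "0,2", or "none" into a norm_scheme or NULL
.parse_scheme <- function(spec, excitability = "constant") {
  if (is.null(spec) || identical(spec, "none")) return(NULL)
  orders <- as.integer(strsplit(as.character(spec), ",")[[1]])
  norm_scheme(orders, excitability)
}

#' Run a configured experiment
#'
#' Executes one experiment (`train`, `recurrent-train`, `sorn`, `cable`, or
#' `analyze`) from a configuration, writes its metric outputs as CSV and a
#' JSON run manifest capturing the complete configuration (defaults filled
#' in), the seed, the package version, and summary metrics, so that every
#' run is reproducible from its manifest alone.
#'
#' @param config a file path or list accepted by [read_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the manifest list (with `curve`/`results` attached).
#' @export
run_experiment <- function(config, out_dir = ".") {
  cfg <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  results <- switch(cfg$experiment,
    "train" = .exp_train(cfg),
    "recurrent-train" = .exp_recurrent(cfg),
    "sorn" = .exp_sorn(cfg),
    "cable" = .exp_cable(cfg),
    "analyze" = .exp_analyze(cfg))
  stem <- file.path(out_dir, paste0(cfg$experiment, "-seed", cfg$seed))
  if (!is.null(results$curve)) {
    utils::write.csv(cbind(results$curve, seed = cfg$seed),
                     paste0(stem, "-curve.csv"), row.names = FALSE)
  }
  manifest <- list(experiment = cfg$experiment, seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "experiment")],
                   package_version =
                     as.character(utils::packageVersion("dendnorm")),
                   metrics = results$metrics)
  jsonlite::write_json(manifest, paste0(stem, "-manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$curve <- results$curve
  manifest$results <- results
  invisible(manifest)
}

.exp_train <- function(cfg) {
  scheme <- .parse_scheme(cfg$scheme, cfg$excitability)
  train <- gen_synthetic_images(cfg$n_per_class, noise_sd = cfg$noise_sd)
  test <- gen_synthetic_images(cfg$n_test_per_class,
                               noise_sd = cfg$noise_sd,
                               templates = train$templates)
  sizes <- c(ncol(train$images), rep(cfg$M, cfg$layers), 10)
  net <- sparse_network(sizes, cfg$epsilon, scheme,
                        activation = cfg$activation)
  fit <- train_network(net, train$images, train$labels, cfg$epochs,
                       minibatch = cfg$minibatch, eta = cfg$eta,
                       zeta = cfg$zeta, test_images = test$images,
                       test_labels = test$labels)
  last <- fit$curve[nrow(fit$curve), ]
  list(curve = fit$curve, net = fit$net,
       metrics = list(final_train_cost = last$train_cost,
                      final_test_accuracy = last$test_accuracy))
}

.exp_recurrent <- function(cfg) {
  scheme <- .parse_scheme(cfg$scheme, cfg$excitability)
  rnet <- recurrent_network(cfg$M, cfg$epsilon, scheme,
                            sparse_input = cfg$sparse_input)
  fit <- train_recurrent(rnet, cfg$epochs, epoch_len = cfg$epoch_len,
                         m = cfg$m_bits, minibatch = cfg$minibatch,
                         eta = cfg$eta, zeta = cfg$zeta)
  aspl <- average_shortest_path(fit$rnet$rec)
  metrics <- list(final_mse = fit$curve$train_cost[cfg$epochs],
                  final_accuracy = fit$curve$test_accuracy[cfg$epochs],
                  aspl = aspl)
  if (cfg$sparse_input) {
    metrics$both_input_fraction <- both_input_fraction(fit$rnet)
  }
  list(curve = fit$curve, rnet = fit$rnet, metrics = metrics)
}

.exp_sorn <- function(cfg) {
  scfg <- sorn_config(N_e = cfg$N_e, N_i = cfg$N_i,
                      epoch_len = cfg$epoch_len,
                      point_neuron = cfg$point_neuron)
  res <- run_sorn(scfg, epochs = cfg$epochs, n_rep = cfg$n_rep,
                  n_words_readout = cfg$n_words_readout,
                  readout_epochs = cfg$readout_epochs)
  list(curve = res$metrics, state = res$state,
       metrics = list(score = res$score$score,
                      raw_accuracy = res$score$accuracy,
                      theta_spike = res$state$config$theta_spike,
                      calibrated_rate = res$state$config$calibrated_rate,
                      final_weight_cv =
                        res$metrics$w_cv[nrow(res$metrics)]))
}

.exp_cable <- function(cfg) {
  p <- cable_params(r = cfg$r, l = cfg$l, r_a = cfg$r_a, g_l = cfg$g_l,
                    c = cfg$c, rho = cfg$rho)
  k <- syn_kernel(cfg$tau_f, cfg$tau_s, cfg$theta_syn, cfg$delta_syn)
  np <- cfg$grid_points
  curve <- switch(cfg$op,
    "transfer_resistance" = {
      X <- seq(0, p$L, length.out = np)
      data.frame(X = X, value = transfer_resistance(p, X))
    },
    "steady_moments" = {
      m <- steady_moments(p, cfg$delta_syn)
      data.frame(mean = m$mean, variance = m$variance)
    },
    "impulse_response" = {
      T_grid <- seq(0.01, 5, length.out = np)
      data.frame(T = T_grid,
                 value = impulse_response(p, p$L / 2, T_grid))
    },
    "mean_synaptic_voltage" = {
      t <- seq(0, 20 * max(cfg$tau_f, cfg$tau_s, p$tau_l),
               length.out = np)
      data.frame(t = t, value = mean_synaptic_voltage(p, k, t))
    },
    "voltage_variance" = {
      t <- seq(0, 20 * max(cfg$tau_f, cfg$tau_s, p$tau_l),
               length.out = np)
      data.frame(t = t, value = voltage_variance(p, k, t))
    },
    "total_voltage" = {
      tv <- total_voltage(p, k)
      data.frame(mean = tv$mean, variance = tv$variance)
    },
    "peak_voltage" = {
      pk <- peak_voltage(p, k)
      data.frame(t_star = pk$t_star, v_max = pk$v_max)
    },
    stop("unknown cable operation: ", cfg$op))
  list(curve = curve, metrics = list(op = cfg$op, L = p$L))
}

.exp_analyze <- function(cfg) {
  aspl <- replicate(cfg$reps, {
    m <- matrix(stats::runif(cfg$n^2) < cfg$p, cfg$n, cfg$n)
    average_shortest_path(m)
  })
  layer <- init_sparse(cfg$fan_in, cfg$M, cfg$epsilon)
  stats_ <- degree_and_weight_stats(layer)
  list(curve = data.frame(rep = seq_along(aspl), aspl = aspl),
       metrics = list(aspl_mean = mean(aspl), aspl_sd = stats::sd(aspl),
                      mean_in_degree = mean(stats_$in_degree)))
}

#' Summarise metric curves across repeated runs
#'
#' Aggregates the learning curves of several runs of the same experiment
#' (different seeds) into per-epoch means and standard deviations, the form
#' in which repeated-trial results are usually presented.
#'
#' @param runs a list of manifests from [run_experiment()], of curve data
#'   frames, or of paths to curve CSV files.
#' @return A data frame with one row per epoch: for every numeric metric,
#'   columns `<metric>_mean` and `<metric>_sd`, plus `n_runs`.
#' @export
compare_runs <- function(runs) {
  stopifnot(length(runs) >= 1)
  curves <- lapply(runs, function(r) {
    if (is.character(r)) r <- utils::read.csv(r)
    if (is.list(r) && !is.null(r$curve)) r <- r$curve
    stopifnot(is.data.frame(r), "epoch" %in% names(r))
    r
  })
  metrics <- setdiff(names(curves[[1]]),
                     c("epoch", "seed"))
  metrics <- metrics[vapply(curves[[1]][metrics], is.numeric, logical(1))]
  epochs <- curves[[1]]$epoch
  out <- data.frame(epoch = epochs, n_runs = length(curves))
  for (m in metrics) {
    vals <- vapply(curves, function(cv) cv[[m]][match(epochs, cv$epoch)],
                   numeric(length(epochs)))
    vals <- matrix(vals, nrow = length(epochs))
    out[[paste0(m, "_mean")]] <- rowMeans(vals)
    out[[paste0(m, "_sd")]] <- if (ncol(vals) == 1) {
      rep(0, length(epochs)) # a single run has no between-run spread
    } else {
      apply(vals, 1, stats::sd)
    }
  }
  out
}
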