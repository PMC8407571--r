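#' Configuration for the self-organising recurrent network
#'
#' Parameters of the spiking reservoir of size-tracking dendritic neurons.
#' Excitatory and inhibitory neurons are modelled as equivalent-cylinder
#' passive dendrites whose length is kept exactly proportional to their
#' afferent connectivity, so that the dendritic normalisation arises
#' intrinsically from the cable physics rather than from an imposed rule.
#'
#' @param N_e,N_i excitatory and inhibitory population sizes. The default
#'   ratio `N_i = 0.6 N_e` balances the worst-case synchronous
#'   excitatory-excitatory input (`p_ee N_e` afferents at the STDP drift
#'   fixed point, half of `synmax`) against the inhibitory feedback
#'   (`p_ie N_i` afferents at the mean initial weight), so that global
#'   synchrony is self-extinguishing without any homeostatic threshold
#'   mechanism.
#' @param p_ee,p_ei,p_ie initial connection fractions for excitatory to
#'   excitatory, excitatory to inhibitory, and inhibitory to excitatory
#'   edges (there are no inhibitory-inhibitory connections).
#' @param gamma_shape,gamma_rate shape and rate of the gamma distribution
#'   of local synaptic weight magnitudes. The default `(0.2, 1)` follows the
#'   explicit density parameters; `gamma_moments = "mean_sd"` instead
#'   matches a mean and standard deviation of 0.2 (shape 1, rate 5), which
#'   is the alternative reading of the stated weight statistics (the two
#'   are mutually inconsistent; a message flags the choice at
#'   initialisation).
#' @param gamma_moments `"shape_rate"` (default) or `"mean_sd"`.
#' @param synmax upper bound on local excitatory-excitatory weights; initial
#'   and regrown gamma draws are clipped to `[0, synmax]`. The default is
#'   twice the mean initial weight: under the symmetric pair-STDP rule the
#'   long-run drift of an active synapse settles near `synmax / 2`, so this
#'   choice keeps the population mean weight near its initial value and the
#'   calibrated spike threshold valid throughout training.
#' @param eta_stdp STDP learning rate: potentiation moves a weight towards
#'   `synmax` by `eta_stdp` times the remaining distance, depression
#'   towards 0 likewise (soft bounds).
#' @param theta_spike somatic voltage threshold; `NULL` means calibrate
#'   with [calibrate_threshold()] before running.
#' @param epoch_len stimulus presentations (timesteps) per epoch.
#' @param zeta_set SET excision fraction applied to the E-E pool per epoch.
#' @param mean_length_e,mean_length_i initial mean dendrite lengths (um).
#' @param cable a [cable_params()] template giving the intrinsic properties
#'   (radius, resistivities); its length field is ignored, the per-neuron
#'   length is used instead.
#' @param point_neuron if `TRUE`, all synapses impinge on a compact soma:
#'   every synapse sees the same fixed transfer resistance regardless of
#'   dendrite length or location, severing the length-connectivity link
#'   (the control condition).
#' @param n_input number of excitatory neurons receiving external drive
#'   (the first `n_input` excitatory indices).
#' @return An object of class `sorn_config`.
#' @export
sorn_config <- function(N_e = 100, N_i = 60, p_ee = 0.30, p_ei = 0.70,
                        p_ie = 0.70, gamma_shape = 0.2, gamma_rate = 1,
                        gamma_moments = c("shape_rate", "mean_sd"),
                        synmax = 0.4, eta_stdp = 0.05, theta_spike = NULL,
                        epoch_len = 1000, zeta_set = 0.15,
                        mean_length_e = 1000, mean_length_i = 500,
                        cable = cable_params(r = 1, l = 1000, r_a = 100,
                                             g_l = 5e-5, c = 1),
                        point_neuron = FALSE, n_input = 30) {
  gamma_moments <- match.arg(gamma_moments)
  if (gamma_moments == "mean_sd") {
    # mean 0.2, sd 0.2: shape = (mean/sd)^2 = 1, rate = mean/sd^2 = 5
    gamma_shape <- 1
    gamma_rate <- 5
    message("gamma weight distribution: matching mean/sd 0.2 ",
            "(shape 1, rate 5)")
  }
  stopifnot(N_e >= n_input, N_i >= 1, p_ee > 0, p_ee <= 1, p_ei > 0,
            p_ei <= 1, p_ie > 0, p_ie <= 1, gamma_shape > 0,
            gamma_rate > 0, synmax > 0, eta_stdp >= 0, zeta_set >= 0,
            zeta_set < 1)
  structure(list(N_e = N_e, N_i = N_i, p_ee = p_ee, p_ei = p_ei,
                 p_ie = p_ie, gamma_shape = gamma_shape,
                 gamma_rate = gamma_rate, synmax = synmax,
                 eta_stdp = eta_stdp, theta_spike = theta_spike,
                 epoch_len = epoch_len, zeta_set = zeta_set,
                 mean_length_e = mean_length_e,
                 mean_length_i = mean_length_i, cable = cable,
                 point_neuron = point_neuron, n_input = n_input),
            class = "sorn_config")
}

# per-synapse steady transfer resistance to the soma of its post neuron.
# lengths: vector of all neuron lengths (um); for point neurons the fixed
# somatic resistance of the initial mean-length cable is used instead
.sorn_rsyn <- function(state, idx = seq_along(state$syn$post)) {
  cfg <- state$config
  cp <- cfg$cable
  lambda <- cp$lambda # um, independent of length
  post <- state$syn$post[idx]
  if (cfg$point_neuron) {
    return(state$R_soma[ifelse(post <= cfg$N_e, 1L, 2L)])
  }
  L <- state$length[post] / lambda
  X <- state$syn$x[idx] / lambda
  X <- pmin(X, L) # guard rounding at the distal tip
  cosh(L - X) / (cp$G_inf * sinh(L))
}

#' Initialise the self-organising recurrent network
#'
#' Samples the sparse connectivity (E-E, E-I, and I-E edges by their
#' respective fractions; never I-I), draws local weight magnitudes from the
#' gamma distribution with the appropriate sign, places afferent synapses
#' uniformly along each dendrite, and sizes dendrites in proportion to
#' afferent connectivity via [resize_dendrites()].
#'
#' @param config a [sorn_config()].
#' @param seed optional integer seed.
#' @return An object of class `sorn_state` with neuron lengths, synapse
#'   arrays (`pre`, `post` as global indices with excitatory neurons first,
#'   `w` local magnitude, `sign`, `x` location in um, `r_syn` transfer
#'   resistance, `is_ee`), spike state, and the config.
#' @export
init_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sorn_config"))
  .with_seed(seed, {
    N_e <- config$N_e
    N_i <- config$N_i
    N <- N_e + N_i
    edges <- function(pre_set, post_set, p, no_self = FALSE) {
      g <- expand.grid(pre = pre_set, post = post_set)
      if (no_self) g <- g[g$pre != g$post, ]
      g[stats::runif(nrow(g)) < p, ]
    }
    ee <- edges(1:N_e, 1:N_e, config$p_ee, no_self = TRUE)
    ei <- edges(1:N_e, N_e + 1:N_i, config$p_ei)
    ie <- edges(N_e + 1:N_i, 1:N_e, config$p_ie)
    syn <- list(
      pre = c(ee$pre, ei$pre, ie$pre),
      post = c(ee$post, ei$post, ie$post),
      w = pmin(stats::rgamma(nrow(ee) + nrow(ei) + nrow(ie),
                             config$gamma_shape, config$gamma_rate),
               config$synmax),
      sign = c(rep(1, nrow(ee) + nrow(ei)), rep(-1, nrow(ie))),
      is_ee = c(rep(TRUE, nrow(ee)), rep(FALSE, nrow(ei) + nrow(ie)))
    )
    syn$x <- rep(0, length(syn$pre)) # placed by resize_dendrites
    state <- structure(list(
      config = config,
      length = c(rep(config$mean_length_e, N_e),
                 rep(config$mean_length_i, N_i)),
      syn = syn,
      spike = rep(FALSE, N), prev_spike = rep(FALSE, N),
      V = rep(0, N),
      R_soma = c(transfer_resistance(
        .cable_with_length(config$cable, config$mean_length_e), 0),
        transfer_resistance(
          .cable_with_length(config$cable, config$mean_length_i), 0))
    ), class = "sorn_state")
    resize_dendrites(state)
  })
}

# cable params template with a different physical length
.cable_with_length <- function(cp, l) {
  cable_params(r = cp$r, l = l, r_a = cp$r_a, g_l = cp$g_l, c = cp$c,
               rho = cp$rho)
}

#' Resize dendrites to match afferent connectivity
#'
#' Sets every neuron's dendrite length so that, within each population, the
#' ratio of length to afferent contact count is exactly the population
#' mean ratio computed before resizing: `l_i <- n_i * (mean(l) / mean(n))`.
#' All afferent synapse locations on a resized neuron are re-drawn
#' uniformly along the new length, and per-synapse transfer resistances are
#' recomputed.
#'
#' @param state a `sorn_state`.
#' @param populations which populations to resize (`"e"`, `"i"`, or both).
#' @return The updated state.
#' @export
resize_dendrites <- function(state, populations = c("e", "i")) {
  stopifnot(inherits(state, "sorn_state"))
  cfg <- state$config
  N_e <- cfg$N_e
  N <- N_e + cfg$N_i
  n_aff <- tabulate(state$syn$post, nbins = N)
  for (popn in populations) {
    idx <- if (popn == "e") seq_len(N_e) else (N_e + 1):N
    if (sum(n_aff[idx]) == 0) {
      stop("population '", popn, "' has no afferent contacts: ",
           "length-connectivity ratio undefined")
    }
    ratio <- mean(state$length[idx]) / mean(n_aff[idx])
    state$length[idx] <- n_aff[idx] * ratio
    moved <- which(state$syn$post %in% idx)
    state$syn$x[moved] <- stats::runif(length(moved)) *
      state$length[state$syn$post[moved]]
  }
  state$syn$r_syn <- .sorn_rsyn(state)
  state
}

#' Advance the network by one timestep
#'
#' Each neuron's somatic voltage is the sum, over afferent synapses whose
#' pre-synaptic neuron spiked on the previous timestep, of the signed local
#' weight times the synapse's steady transfer resistance to the soma, plus
#' any external drive. Neurons whose voltage exceeds the spike threshold
#' spike, and their efferent synapses carry current on the next timestep.
#'
#' @param state a `sorn_state` with a calibrated `theta_spike` in its
#'   config.
#' @param drive external input current per excitatory neuron (length
#'   `N_e`), zero for undriven cells.
#' @return The updated state (fields `V`, `spike`, `prev_spike`).
#' @export
sorn_step <- function(state, drive) {
  cfg <- state$config
  if (is.null(cfg$theta_spike)) {
    stop("theta_spike is not set; run calibrate_threshold() first")
  }
  stopifnot(length(drive) == cfg$N_e)
  N <- cfg$N_e + cfg$N_i
  prev <- state$spike
  V <- numeric(N)
  act <- prev[state$syn$pre]
  if (any(act)) {
    contrib <- (state$syn$sign * state$syn$w * state$syn$r_syn)[act]
    agg <- rowsum(contrib, state$syn$post[act])
    V[as.integer(rownames(agg))] <- agg[, 1]
  }
  V[seq_len(cfg$N_e)] <- V[seq_len(cfg$N_e)] + drive
  state$prev_spike <- prev
  state$spike <- V > cfg$theta_spike
  state$V <- V
  state
}

#' Spike-timing dependent plasticity on E-E synapses
#'
#' Soft-bounded pair STDP across one timestep: a synapse whose pre-synaptic
#' neuron spiked on the previous step and whose post-synaptic neuron spikes
#' now potentiates by `eta_stdp` times its distance to `synmax`; a synapse
#' whose post-synaptic neuron spiked on the previous step while the
#' pre-synaptic neuron spikes now depresses by `eta_stdp` times its
#' distance to zero. Weights therefore remain in `[0, synmax]`.
#'
#' @param state a `sorn_state` (after [sorn_step()], so that `prev_spike`
#'   and `spike` hold consecutive timesteps).
#' @return The updated state.
#' @export
stdp_update <- function(state) {
  cfg <- state$config
  eta <- cfg$eta_stdp
  if (eta == 0) return(state)
  ee <- state$syn$is_ee
  pre <- state$syn$pre[ee]
  post <- state$syn$post[ee]
  w <- state$syn$w[ee]
  pot <- state$prev_spike[pre] & state$spike[post]
  dep <- state$prev_spike[post] & state$spike[pre]
  w[pot] <- w[pot] + eta * (cfg$synmax - w[pot])
  w[dep] <- w[dep] - eta * w[dep]
  state$syn$w[ee] <- w
  state
}

#' Calibrate the somatic spike threshold
#'
#' The model has no homeostatic threshold adjustment, so the spike
#' threshold must place the network in a regime where stimulus-locked
#' assemblies can recruit spikes but global synchrony cannot persist. The
#' threshold is set to the somatic voltage contributed by `K` co-active
#' excitatory synapses of average transfer resistance whose weights sit at
#' the long-run STDP drift fixed point `synmax * (1 - eta) / (2 - eta)`
#' (where potentiation and depression balance): a neuron then spikes
#' exactly when at least `K` strongly potentiated afferents are co-active.
#' Together with the default balanced population sizes (under which the
#' synchronous excitatory and inhibitory inputs cancel), this yields
#' stable, stimulus-structured activity. The driven stream is simulated
#' once at the chosen threshold to record the achieved initial spike
#' probability in `config$calibrated_rate`.
#'
#' @param state a `sorn_state`.
#' @param stream a [gen_word_stream()] used to report the achieved rate.
#' @param K number of co-active fixed-point synapses required to reach
#'   threshold.
#' @param steps simulated steps for the achieved-rate report.
#' @return The state with `config$theta_spike`, `config$drive_amp` (twice
#'   the threshold) and `config$calibrated_rate` set.
#' @export
calibrate_threshold <- function(state, stream, K = 3, steps = 200) {
  stopifnot(inherits(state, "sorn_state"), K > 0)
  cfg <- state$config
  w_fp <- cfg$synmax * (1 - cfg$eta_stdp) / (2 - cfg$eta_stdp)
  ee <- state$syn$is_ee
  e_idx <- seq_len(cfg$N_e)
  theta <- K * w_fp * mean(state$syn$r_syn[ee])
  state$config$theta_spike <- theta
  state$config$drive_amp <- 2 * theta
  # report the achieved initial rate under the stimulus
  st <- state
  steps <- min(steps, ncol(stream$drive))
  spikes <- 0
  for (t in seq_len(steps)) {
    drv <- numeric(cfg$N_e)
    drv[seq_len(cfg$n_input)] <- st$config$drive_amp * stream$drive[, t]
    st <- sorn_step(st, drv)
    spikes <- spikes + sum(st$spike[e_idx])
  }
  state$config$calibrated_rate <- spikes / (steps * cfg$N_e)
  state
}

#' Run one training epoch of the self-organising network
#'
#' Steps the network through the stimulus stream with STDP active, then
#' applies SET rewiring to the E-E pool (the `floor(zeta_set * E_ee)`
#' weakest E-E contacts by local weight are excised and replaced by new
#' random E-E pairs with gamma-distributed weights placed uniformly on the
#' post-synaptic dendrite), and finally resizes the excitatory dendrites to
#' their new afferent connectivity.
#'
#' @param state a calibrated `sorn_state`.
#' @param stream a [gen_word_stream()]; one letter is presented per
#'   timestep as a suprathreshold current to its input neuron group.
#' @param stdp apply plasticity (set `FALSE` for frozen evaluation runs).
#' @param rewire_and_resize apply the end-of-epoch SET and resizing.
#' @return The updated state; attribute `"spike_record"` holds the
#'   excitatory spike matrix (`N_e x T`) of the epoch.
#' @export
run_epoch <- function(state, stream, stdp = TRUE, rewire_and_resize = TRUE) {
  stopifnot(inherits(state, "sorn_state"))
  cfg <- state$config
  amp <- if (!is.null(cfg$drive_amp)) cfg$drive_amp else
    2 * cfg$theta_spike
  T_len <- ncol(stream$drive)
  rec <- matrix(FALSE, cfg$N_e, T_len)
  for (t in seq_len(T_len)) {
    drv <- numeric(cfg$N_e)
    drv[seq_len(cfg$n_input)] <- amp * stream$drive[, t]
    state <- sorn_step(state, drv)
    if (stdp) state <- stdp_update(state)
    rec[, t] <- state$spike[seq_len(cfg$N_e)]
  }
  if (rewire_and_resize && cfg$zeta_set > 0) {
    state <- .sorn_set(state)
    state <- resize_dendrites(state, "e")
  }
  attr(state, "spike_record") <- rec
  state
}

# SET on the E-E pool: excise the floor(zeta * E) smallest local weights
# (ties broken randomly), regrow the same number of absent E-E pairs with
# gamma weights at uniform locations
.sorn_set <- function(state) {
  cfg <- state$config
  ee_idx <- which(state$syn$is_ee)
  E <- length(ee_idx)
  k <- floor(cfg$zeta_set * E)
  if (k == 0) return(state)
  w_ee <- state$syn$w[ee_idx]
  drop_local <- ee_idx[order(w_ee, stats::runif(E))[seq_len(k)]]
  keep <- setdiff(seq_along(state$syn$pre), drop_local)
  # current E-E occupancy after excision
  occupied <- matrix(FALSE, cfg$N_e, cfg$N_e)
  kept_ee <- intersect(keep, ee_idx)
  occupied[cbind(state$syn$pre[kept_ee], state$syn$post[kept_ee])] <- TRUE
  diag(occupied) <- TRUE # no self-connections
  absent <- which(!occupied)
  if (length(absent) < k) stop("E-E pool saturated during regrowth")
  new_lin <- sample(absent, k)
  new_pre <- (new_lin - 1) %% cfg$N_e + 1
  new_post <- (new_lin - 1) %/% cfg$N_e + 1
  state$syn <- lapply(state$syn, `[`, keep)
  state$syn$pre <- c(state$syn$pre, new_pre)
  state$syn$post <- c(state$syn$post, new_post)
  state$syn$w <- c(state$syn$w,
                   pmin(stats::rgamma(k, cfg$gamma_shape, cfg$gamma_rate),
                        cfg$synmax))
  state$syn$sign <- c(state$syn$sign, rep(1, k))
  state$syn$is_ee <- c(state$syn$is_ee, rep(TRUE, k))
  state$syn$x <- c(state$syn$x,
                   stats::runif(k) * state$length[new_post])
  state$syn$r_syn <- .sorn_rsyn(state)
  state
}

#' Train a readout on frozen network activity and score prediction
#'
#' With plasticity frozen, runs the network on a fresh stimulus stream,
#' records the instantaneous excitatory spike vectors, and trains a
#' feedforward classifier with 30 hidden units to predict the next letter
#' from the current spike vector. The raw held-out accuracy is rescaled to
#' the normalised score
#' \deqn{score = (acc - b) / (m^* - b)}
#' where `m*` is the best achievable fraction given that the first letter
#' of each word is unpredictable (perfect within words, a coin flip at word
#' boundaries) and `b` is the accuracy of a letter-frequency-matched
#' guesser; both constants are computed from the evaluation stream itself.
#' A score of 1 therefore means prediction as good as the stream allows; 0
#' means chance.
#'
#' @param state a trained, calibrated `sorn_state`.
#' @param n_words words in the evaluation stream.
#' @param n_rep middle-letter repeats of the evaluation stream.
#' @param readout_epochs SGD epochs for the readout network.
#' @param holdout fraction of timesteps held out for scoring.
#' @param eta readout learning rate.
#' @return A list with `score` (normalised), `accuracy` (raw), `b`,
#'   `m_star`, and the trained `readout` network.
#' @export
readout_and_score <- function(state, n_words = 300, n_rep = 4,
                              readout_epochs = 20, holdout = 0.25,
                              eta = 0.5) {
  stopifnot(inherits(state, "sorn_state"), n_rep >= 1)
  stream <- gen_word_stream(n_words, n_rep)
  if (length(unique(stream$letters)) < 2) {
    stop("degenerate stream: a single letter cannot define a prediction task")
  }
  state <- run_epoch(state, stream, stdp = FALSE,
                     rewire_and_resize = FALSE)
  spikes <- attr(state, "spike_record")
  T_len <- ncol(spikes)
  X <- t(spikes[, -T_len, drop = FALSE]) * 1 # (T-1) x N_e
  y <- stream$letter_index[-1] - 1L          # classes 0..5
  n <- nrow(X)
  n_train <- floor((1 - holdout) * n)
  net <- sparse_network(c(state$config$N_e, 30, 6), epsilon = 1)
  fit <- train_network(net, X[seq_len(n_train), , drop = FALSE],
                       y[seq_len(n_train)], epochs = readout_epochs,
                       minibatch = 10, eta = eta, zeta = 0)
  test_idx <- (n_train + 1):n
  ev <- evaluate_network(fit$net, X[test_idx, , drop = FALSE], y[test_idx])
  W <- n_rep + 2
  m_star <- ((W - 1) + 0.5) / W
  f <- table(factor(y[test_idx], levels = 0:5)) / length(test_idx)
  b <- sum(f^2)
  list(score = (ev$accuracy - b) / (m_star - b), accuracy = ev$accuracy,
       b = b, m_star = m_star, readout = fit$net)
}

#' Run a full self-organisation experiment
#'
#' Initialises, calibrates, trains for `epochs` epochs of `epoch_len`
#' presentations, and scores a frozen readout. The point-neuron control is
#' obtained by `point_neuron = TRUE` in the config: initialisation is
#' identical but every synapse sees a fixed somatic resistance, severing
#' the dendritic normalisation.
#'
#' @param config a [sorn_config()].
#' @param epochs training epochs.
#' @param n_rep middle-letter repeats of the training stimulus.
#' @param seed optional integer seed.
#' @param score if `TRUE`, train and score the readout after training.
#' @param n_words_readout words in the readout stream.
#' @param readout_epochs readout training epochs.
#' @return A list with the final `state`, a per-epoch `metrics` data frame
#'   (mean and sd of dendrite length, in-degree sd, local-weight mean, sd
#'   and coefficient of variation, spike rate), the initial metrics row
#'   (`epoch = 0`), and `score` (or `NULL`).
#' @export
run_sorn <- function(config, epochs = 50, n_rep = 4, seed = NULL,
                     score = TRUE, n_words_readout = 300,
                     readout_epochs = 20) {
  .with_seed(seed, {
    state <- init_population(config)
    calib_stream <- gen_word_stream(ceiling(250 / (n_rep + 2)), n_rep)
    state <- calibrate_threshold(state, calib_stream)
    summarise <- function(state, ep, rate = NA_real_) {
      ee <- state$syn$is_ee
      n_aff <- tabulate(state$syn$post, nbins = config$N_e)
      w <- state$syn$w[ee]
      data.frame(epoch = ep,
                 mean_length = mean(state$length[seq_len(config$N_e)]),
                 sd_length = stats::sd(state$length[seq_len(config$N_e)]),
                 sd_indegree = stats::sd(n_aff),
                 w_mean = mean(w), w_sd = stats::sd(w),
                 w_cv = stats::sd(w) / mean(w),
                 spike_rate = rate)
    }
    metrics <- summarise(state, 0)
    words_per_epoch <- ceiling(config$epoch_len / (n_rep + 2))
    for (ep in seq_len(epochs)) {
      stream <- gen_word_stream(words_per_epoch, n_rep)
      state <- run_epoch(state, stream)
      rate <- mean(attr(state, "spike_record"))
      metrics <- rbind(metrics, summarise(state, ep, rate))
    }
    sc <- if (score) {
      readout_and_score(state, n_words = n_words_readout, n_rep = n_rep,
                        readout_epochs = readout_epochs)
    }
    list(state = state, metrics = metrics, score = sc)
  })
}
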