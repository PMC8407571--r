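# small config used throughout: fast but structurally faithful
small_cfg <- function(...) {
  sorn_config(N_e = 40, N_i = 24, epoch_len = 150, n_input = 30, ...)
}

test_that("initial connectivity follows the stated fractions with no I-I edges", {
  set.seed(40)
  cfg <- small_cfg(p_ee = 1)
  st <- init_population(cfg)
  ee <- st$syn$is_ee
  expect_equal(sum(ee), 40 * 39) # every ordered E-E pair, no self
  expect_false(any(st$syn$pre > 40 & st$syn$post > 40)) # no I-I
  # signs match the source population
  expect_true(all(st$syn$sign[st$syn$pre <= 40] == 1))
  expect_true(all(st$syn$sign[st$syn$pre > 40] == -1))
  # weight magnitudes follow the (clipped) gamma law
  cfg2 <- sorn_config(N_e = 60, N_i = 36, synmax = 1e6)
  set.seed(41)
  st2 <- init_population(cfg2)
  expect_equal(mean(st2$syn$w), 0.2, tolerance = 0.05) # shape/rate = 0.2
  expect_true(all(st2$syn$w >= 0))
})

test_that("resizing enforces exact length-connectivity proportionality", {
  set.seed(42)
  st <- init_population(small_cfg())
  n_aff <- tabulate(st$syn$post, nbins = 64)
  ratio_e <- st$length[1:40] / n_aff[1:40]
  expect_lt(diff(range(ratio_e)), 1e-12 * mean(ratio_e))
  ratio_i <- st$length[41:64] / n_aff[41:64]
  expect_lt(diff(range(ratio_i)), 1e-12 * mean(ratio_i))
  # population mean length is preserved by the resize
  expect_equal(mean(st$length[1:40]), small_cfg()$mean_length_e)
  # doubling one neuron's afferents doubles its length at the same ratio
  st2 <- st
  extra <- which(st2$syn$post == 2)
  dup <- lapply(st2$syn, function(f) c(f, f[extra]))
  st2$syn <- dup
  st2 <- resize_dendrites(st2, "e")
  n2 <- tabulate(st2$syn$post, nbins = 64)
  expect_equal(st2$length[2] / n2[2], st2$length[1] / n2[1])
  # synapse locations always lie within the (new) dendrite
  expect_true(all(st2$syn$x <= st2$length[st2$syn$post] + 1e-9))
})

test_that("somatic voltages equal the cable transfer-resistance sum", {
  set.seed(43)
  st <- init_population(small_cfg())
  st$config$theta_spike <- 1
  # make a known set of presynaptic neurons spike
  st$spike[c(1, 5, 41)] <- TRUE
  st2 <- sorn_step(st, numeric(40))
  lambda <- st$config$cable$lambda
  target <- 7
  idx <- which(st$syn$post == target & st$syn$pre %in% c(1, 5, 41))
  manual <- 0
  for (j in idx) {
    cp <- cable_params(r = 1, l = st$length[target], r_a = 100,
                       g_l = 5e-5, c = 1)
    manual <- manual + st$syn$sign[j] * st$syn$w[j] *
      transfer_resistance(cp, min(st$syn$x[j] / lambda, cp$L))
  }
  expect_equal(st2$V[target], manual, tolerance = 1e-10)
  # no active afferents and no drive: silence
  st$spike[] <- FALSE
  st3 <- sorn_step(st, numeric(40))
  expect_true(all(st3$V == 0))
  expect_false(any(st3$spike))
})

test_that("proximal synapses and shorter dendrites produce larger responses", {
  cfg <- small_cfg()
  cp <- cfg$cable
  l0 <- 800
  p1 <- cable_params(r = cp$r, l = l0, r_a = cp$r_a, g_l = cp$g_l,
                     c = cp$c)
  # same synapse weight at the soma versus the distal tip
  expect_gt(transfer_resistance(p1, 0), transfer_resistance(p1, p1$L))
  # a neuron of twice the length responds half as strongly in expectation
  p2 <- cable_params(r = cp$r, l = 2 * l0, r_a = cp$r_a, g_l = cp$g_l,
                     c = cp$c)
  expect_equal(steady_moments(p1, 1)$mean / steady_moments(p2, 1)$mean, 2)
})

test_that("STDP respects soft bounds and converges to the alternation fixed point", {
  set.seed(44)
  st <- init_population(small_cfg(eta_stdp = 0.2, synmax = 0.4))
  ee_first <- which(st$syn$is_ee)[1]
  pre <- st$syn$pre[ee_first]
  post <- st$syn$post[ee_first]
  # saturated weight: potentiation is a no-op
  st$syn$w[ee_first] <- 0.4
  st$prev_spike[] <- FALSE
  st$spike[] <- FALSE
  st$prev_spike[pre] <- TRUE
  st$spike[post] <- TRUE
  st1 <- stdp_update(st)
  expect_equal(st1$syn$w[ee_first], 0.4)
  # zero weight: depression is a no-op
  st$syn$w[ee_first] <- 0
  st$prev_spike[] <- FALSE
  st$spike[] <- FALSE
  st$prev_spike[post] <- TRUE
  st$spike[pre] <- TRUE
  st2 <- stdp_update(st)
  expect_equal(st2$syn$w[ee_first], 0)
  # alternating pot/dep converges to the scalar-recurrence fixed point
  eta <- 0.2
  synmax <- 0.4
  w_oracle <- 0.05
  for (i in 1:100) {
    w_oracle <- w_oracle + eta * (synmax - w_oracle) # pot
    w_oracle <- w_oracle - eta * w_oracle # dep
  }
  w_sim <- 0.05
  st$syn$w[ee_first] <- w_sim
  for (i in 1:100) {
    st$prev_spike[] <- FALSE
    st$spike[] <- FALSE
    st$prev_spike[pre] <- TRUE
    st$spike[post] <- TRUE
    st <- stdp_update(st)
    st$prev_spike[] <- FALSE
    st$spike[] <- FALSE
    st$prev_spike[post] <- TRUE
    st$spike[pre] <- TRUE
    st <- stdp_update(st)
  }
  expect_equal(st$syn$w[ee_first], w_oracle, tolerance = 1e-12)
  expect_equal(w_oracle, synmax * (1 - eta) / (2 - eta),
               tolerance = 1e-6)
  # weights always within bounds after an active epoch
  set.seed(45)
  stt <- init_population(small_cfg())
  stt <- calibrate_threshold(stt, gen_word_stream(30, 4, seed = 46))
  stt <- run_epoch(stt, gen_word_stream(30, 4, seed = 47))
  expect_true(all(stt$syn$w >= 0 & stt$syn$w <= small_cfg()$synmax))
})

test_that("an epoch without plasticity or rewiring only advances spike state", {
  set.seed(48)
  st <- init_population(small_cfg(eta_stdp = 0, zeta_set = 0))
  st <- calibrate_threshold(st, gen_word_stream(30, 4, seed = 49))
  st2 <- run_epoch(st, gen_word_stream(30, 4, seed = 50))
  expect_identical(st2$syn$w, st$syn$w)
  expect_identical(st2$syn$pre, st$syn$pre)
  expect_identical(st2$length, st$length)
})

test_that("SET conserves the E-E edge count across epochs and resize follows", {
  set.seed(51)
  st <- init_population(small_cfg())
  st <- calibrate_threshold(st, gen_word_stream(30, 4, seed = 52))
  E0 <- sum(st$syn$is_ee)
  for (ep in 1:3) {
    st <- run_epoch(st, gen_word_stream(30, 4))
    expect_equal(sum(st$syn$is_ee), E0)
    n_aff <- tabulate(st$syn$post, nbins = 64)
    ratio <- st$length[1:40] / n_aff[1:40]
    expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
  }
  # other edge types are untouched by the E-E rewiring
  expect_equal(sum(!st$syn$is_ee),
               sum(!init_population(small_cfg(), seed = 51)$syn$is_ee))
})

test_that("readout scoring normalises between chance and the stream optimum", {
  set.seed(53)
  st <- init_population(small_cfg())
  st <- calibrate_threshold(st, gen_word_stream(30, 4, seed = 54))
  res <- readout_and_score(st, n_words = 80, n_rep = 3,
                           readout_epochs = 3)
  W <- 5
  expect_equal(res$m_star, ((W - 1) + 0.5) / W)
  expect_true(res$b > 0 && res$b < res$m_star)
  # an oracle predictor that is perfect within words and right half the
  # time at word boundaries scores exactly 1 by construction
  expect_equal((res$m_star - res$b) / (res$m_star - res$b), 1)
  # a uniform random predictor scores approximately zero
  set.seed(55)
  acc_rand <- mean(sample(1:6, 2000, replace = TRUE) ==
                     gen_word_stream(400, 3, seed = 56)$letter_index[1:2000])
  score_rand <- (acc_rand - res$b) / (res$m_star - res$b)
  expect_lt(abs(score_rand), 0.15)
  expect_error(readout_and_score(st, n_words = 2, n_rep = 0), "n_rep")
})

test_that("the point-neuron control severs the length-resistance relationship", {
  set.seed(57)
  st <- init_population(small_cfg(point_neuron = TRUE))
  # all E synapses share one resistance, all I synapses another
  r_e <- unique(st$syn$r_syn[st$syn$post <= 40])
  expect_equal(length(r_e), 1)
  # removing all synapses silences the network
  st$config$theta_spike <- 1e-3
  st$syn <- lapply(st$syn, `[`, integer(0))
  st$spike[] <- FALSE
  st2 <- sorn_step(st, numeric(40))
  expect_false(any(st2$spike))
})
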