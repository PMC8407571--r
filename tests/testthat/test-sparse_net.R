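test_that("sparse initialisation: full connectivity at epsilon 1, binomial degrees, determinism", {
  set.seed(1)
  full <- init_sparse(20, 10, 1)
  expect_true(all(full$mask))
  expect_equal(colSums(full$mask), rep(20, 10))
  set.seed(2)
  lay <- init_sparse(784, 100, 0.2)
  n_in <- colSums(lay$mask)
  # binomial mean 156.8, sd ~ 11.2: the sample mean of 100 neurons should
  # sit within 4 standard errors
  expect_lt(abs(mean(n_in) - 784 * 0.2), 4 * sqrt(784 * 0.2 * 0.8 / 100))
  expect_true(all(n_in > 0))
  set.seed(33)
  a <- init_sparse(30, 5, 0.3)
  set.seed(33)
  b <- init_sparse(30, 5, 0.3)
  expect_identical(a, b)
  # zero in-degree rescue: even at tiny epsilon every neuron has an afferent
  set.seed(3)
  tiny <- init_sparse(10, 50, 0.01)
  expect_true(all(colSums(tiny$mask) >= 1))
})

test_that("forward pass: fixed points, softmax normalisation, hand-computed neuron", {
  set.seed(4)
  net <- sparse_network(c(6, 4, 3), 0.5)
  # zero weights and biases: sigmoid layers output exactly 0.5
  net0 <- net
  for (i in 1:2) net0$layers[[i]]$V[] <- 0
  acts <- forward(net0, matrix(runif(12), 6, 2))
  expect_true(all(acts[[1]] == 0.5))
  expect_equal(colSums(acts[[2]]), c(1, 1)) # softmax sums to one
  # hand-computed single hidden neuron
  net1 <- sparse_network(c(2, 1, 2), 1)
  net1$layers[[1]]$V[] <- c(0.5, -1)
  net1$layers[[1]]$b <- 0.2
  x <- c(0.8, 0.3)
  z <- 0.2 + 0.5 * 0.8 - 1 * 0.3
  expect_equal(forward(net1, x)[[1]][1, 1], 1 / (1 + exp(-z)))
  expect_error(forward(net, matrix(0, 5, 1)), "does not match")
})

test_that("SGD step: eta 0 is a no-op, L0 updates differ from control by exactly s/n", {
  set.seed(5)
  X <- matrix(runif(40), 8, 5)
  labs <- c(0L, 1L, 2L, 1L, 0L)
  net <- sparse_network(c(8, 6, 3), 0.5, norm_scheme(0))
  st0 <- backward_sgd_step(net, X, labs, 0)
  expect_identical(st0$net$layers[[1]]$V, net$layers[[1]]$V)
  expect_identical(st0$net$layers[[1]]$s, net$layers[[1]]$s)
  # seed-matched control with identical weights: the raw-weight update of
  # the normalised net is (s / n) times the control update of w, taken at
  # the same effective weights. Build the control so its raw weights equal
  # the L0 net's effective weights.
  netc <- net
  netc$layers[[1]]$scheme <- NULL
  netc$layers[[1]]$s <- NULL
  n_in <- colSums(net$layers[[1]]$mask)
  netc$layers[[1]]$V <- sweep(net$layers[[1]]$V, 2, n_in, `/`)
  eta <- 1e-3
  stn <- backward_sgd_step(net, X, labs, eta)
  stc <- backward_sgd_step(netc, X, labs, eta)
  dV_n <- (net$layers[[1]]$V - stn$net$layers[[1]]$V)
  dV_c <- (netc$layers[[1]]$V - stc$net$layers[[1]]$V)
  expect_equal(dV_n, sweep(dV_c, 2, 1 / n_in, `*`), tolerance = 1e-10)
})

test_that("full network gradient passes finite differences on a toy net", {
  set.seed(6)
  for (sch in list(NULL, norm_scheme(0), norm_scheme(c(0, 2), "per_neuron"))) {
    net <- sparse_network(c(5, 4, 3), 0.6, sch)
    X <- matrix(runif(10), 5, 2)
    labs <- c(0L, 2L)
    costf <- function(nn) {
      out <- forward(nn, X)[[2]]
      -mean(log(out[cbind(labs + 1, 1:2)]))
    }
    eta <- 1e-7
    st <- backward_sgd_step(net, X, labs, eta)
    for (li in 1:2) {
      idx <- which(net$layers[[li]]$mask)[1:4]
      g_imp <- (net$layers[[li]]$V[idx] - st$net$layers[[li]]$V[idx]) / eta
      g_fd <- vapply(idx, function(i) {
        h <- 1e-5
        np <- net
        nm <- net
        np$layers[[li]]$V[i] <- np$layers[[li]]$V[i] + h
        nm$layers[[li]]$V[i] <- nm$layers[[li]]$V[i] - h
        (costf(np) - costf(nm)) / (2 * h)
      }, numeric(1))
      expect_equal(g_imp, g_fd, tolerance = 1e-5)
    }
  }
})

test_that("sparsity and L0 rescaling invariance hold under training", {
  set.seed(7)
  net <- sparse_network(c(10, 8, 3), 0.4, norm_scheme(0))
  X <- matrix(runif(30), 10, 3)
  labs <- c(0L, 1L, 2L)
  st <- net
  for (i in 1:20) st <- backward_sgd_step(st, X, labs, 0.05)$net
  for (li in 1:2) {
    expect_identical(st$layers[[li]]$mask, net$layers[[li]]$mask)
    expect_true(all(st$layers[[li]]$V[!st$layers[[li]]$mask] == 0))
  }
  # multiplying v by c and dividing s by c leaves the forward map unchanged
  net2 <- net
  net2$layers[[1]]$V <- net2$layers[[1]]$V * 3
  net2$layers[[1]]$s <- net2$layers[[1]]$s / 3
  expect_equal(forward(net, X)[[2]], forward(net2, X)[[2]])
})

test_that("evaluation: perfect outputs, uniform softmax cost, hand-counted accuracy", {
  set.seed(8)
  net <- sparse_network(c(4, 3, 10), 0.9)
  # uniform softmax arises from zero weights in the output layer
  net$layers[[2]]$V[] <- 0
  imgs <- matrix(runif(8), 2, 4)
  ev <- evaluate_network(net, imgs, c(0L, 1L))
  expect_equal(ev$cost, log(10))
  # hand-built 3-sample toy set on a 1-layer argmax machine
  net1 <- sparse_network(c(2, 2, 2), 1)
  net1$layers[[1]]$V <- diag(2) * 10
  net1$layers[[2]]$V <- diag(2) * 10
  X3 <- rbind(c(1, 0), c(0, 1), c(1, 0))
  ev3 <- evaluate_network(net1, X3, c(0L, 1L, 1L))
  expect_equal(ev3$accuracy, 2 / 3) # third sample is deliberately mislabelled
})

test_that("BPTT gradients pass finite differences and history is cut by zero recurrence", {
  set.seed(9)
  rnet <- recurrent_network(4, 0.7, norm_scheme(0))
  d <- gen_binary_addition(2, 3, seed = 10)
  # the update minimises the time-summed squared error per sequence
  costf <- function(rn) {
    fw <- dendnorm:::.rnn_forward(rn, d$a, d$b)
    mean(rowSums((fw$y - d$s)^2))
  }
  eta <- 1e-7
  st <- bptt_step(rnet, d$a, d$b, d$s, eta)
  for (stream in c("input", "rec")) {
    idx <- which(rnet[[stream]]$mask)
    idx <- idx[seq_len(min(5, length(idx)))]
    g_imp <- (rnet[[stream]]$V[idx] - st$rnet[[stream]]$V[idx]) / eta
    g_fd <- vapply(idx, function(i) {
      h <- 1e-5
      np <- rnet
      nm <- rnet
      np[[stream]]$V[i] <- np[[stream]]$V[i] + h
      nm[[stream]]$V[i] <- nm[[stream]]$V[i] - h
      (costf(np) - costf(nm)) / (2 * h)
    }, numeric(1))
    expect_equal(g_imp, g_fd, tolerance = 1e-4)
  }
  # zero recurrent weights: outputs at step t do not depend on earlier input
  rnet0 <- rnet
  rnet0$rec$V[] <- 0
  d2 <- d
  d2$a[, 1] <- 1 - d2$a[, 1] # change the first input bit only
  y1 <- dendnorm:::.rnn_forward(rnet0, d$a, d$b)$y
  y2 <- dendnorm:::.rnn_forward(rnet0, d2$a, d2$b)$y
  expect_equal(y1[, 2:3], y2[, 2:3])
  expect_false(isTRUE(all.equal(y1[, 1], y2[, 1])))
})

test_that("a length-1 sequence reduces BPTT to a single feedforward MSE step", {
  set.seed(10)
  rnet <- recurrent_network(5, 0.6)
  d <- gen_binary_addition(4, 2, seed = 11)
  a1 <- d$a[, 1, drop = FALSE]
  b1 <- d$b[, 1, drop = FALSE]
  s1 <- d$s[, 1, drop = FALSE]
  st <- bptt_step(rnet, a1, b1, s1, 0.1)
  # with a single step the recurrent weights receive no gradient (h_0 = 0)
  expect_equal(st$rnet$rec$V, rnet$rec$V)
  fw <- dendnorm:::.rnn_forward(rnet, a1, b1)
  expect_equal(st$cost, mean((fw$y - s1)^2))
  # input weights do move
  expect_false(isTRUE(all.equal(st$rnet$input$V, rnet$input$V)))
})

test_that("recurrent evaluation applies the all-bits-rounded-correct rule", {
  set.seed(11)
  rnet <- recurrent_network(4, 0.8)
  d <- gen_binary_addition(6, 4, seed = 12)
  fw <- dendnorm:::.rnn_forward(rnet, d$a, d$b)
  ev <- evaluate_recurrent(rnet, d)
  expect_equal(ev$accuracy,
               mean(rowSums(round(fw$y) != d$s) == 0))
  expect_equal(ev$cost, mean(rowMeans((fw$y - d$s)^2)))
  # perfect outputs give accuracy 1 and cost 0
  perfect <- list(y = d$s)
  expect_equal(mean(rowSums(round(perfect$y) != d$s) == 0), 1)
})
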