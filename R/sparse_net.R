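# activation functions and derivatives (as functions of the activation a
# where convenient)
.sigmoid <- function(z) 1 / (1 + exp(-z))
.act <- function(z, activation) {
  switch(activation,
         sigmoid = .sigmoid(z),
         threshold_linear = pmax(0, z),
         softmax = {
           zm <- sweep(z, 2, apply(z, 2, max), `-`)
           ez <- exp(zm)
           sweep(ez, 2, colSums(ez), `/`)
         },
         stop("unknown activation: ", activation))
}
.act_deriv <- function(a, z, activation) {
  switch(activation,
         sigmoid = a * (1 - a),
         threshold_linear = (z > 0) * 1,
         stop("no elementwise derivative for: ", activation))
}

#' Initialise a sparse afferent layer
#'
#' Draws an Erdős–Rényi connection mask in which every possible (pre, post)
#' edge exists independently with probability `epsilon`, with raw weights
#' drawn from a standard normal. Any post-synaptic neuron left with zero
#' in-degree is assigned one uniformly random afferent, since the dendritic
#' normalisation divides by the in-degree and an empty neuron is degenerate.
#'
#' @param fan_in number of pre-synaptic units.
#' @param M number of post-synaptic neurons.
#' @param epsilon connection probability in `(0, 1]`.
#' @param scheme a [norm_scheme()], or `NULL` for an unnormalised control
#'   layer that uses the raw weights directly.
#' @param activation `"sigmoid"`, `"threshold_linear"`, or `"softmax"`.
#' @param s_init initial excitability: a number, or `"indegree"` to start
#'   at the layer's mean in-degree. With order-0 normalisation the
#'   excitability rescales the whole layer, and its gradient-descent
#'   optimisation converges towards the scale at which effective weights
#'   are comparable to raw ones; `"indegree"` starts there, which matters
#'   for wide layers where bootstrapping the scale from 1 costs many
#'   epochs. The default 1 is the neutral choice.
#' @return An object of class `sparse_layer` with fields `V` (raw weights,
#'   `fan_in x M`, zero off the support), `mask` (logical), `b` (biases,
#'   initialised to zero), `scheme`, `s` or `g` (excitability), and
#'   `activation`.
#' @export
init_sparse <- function(fan_in, M, epsilon, scheme = NULL,
                        activation = "sigmoid", s_init = 1) {
  stopifnot(epsilon > 0, epsilon <= 1, fan_in >= 1, M >= 1)
  mask <- matrix(stats::runif(fan_in * M) < epsilon, fan_in, M)
  empty <- which(colSums(mask) == 0)
  for (j in empty) mask[sample.int(fan_in, 1), j] <- TRUE
  V <- matrix(0, fan_in, M)
  V[mask] <- stats::rnorm(sum(mask))
  layer <- list(V = V, mask = mask, b = rep(0, M), scheme = scheme,
                activation = activation)
  if (!is.null(scheme)) {
    s0 <- if (identical(s_init, "indegree")) mean(colSums(mask))
          else s_init
    if (scheme$excitability == "constant") layer$s <- s0
    else layer$g <- rep(s0, M)
  }
  class(layer) <- "sparse_layer"
  layer
}

# current excitability values of a layer (scalar s, vector g, or 1)
.layer_excit <- function(layer) {
  if (is.null(layer$scheme)) 1
  else if (layer$scheme$excitability == "constant") layer$s
  else layer$g
}

# effective weight matrix of a layer; guards empty columns
.layer_weights <- function(layer) {
  if (is.null(layer$scheme)) return(layer$V)
  n <- colSums(layer$mask)
  N <- .col_norm_product(layer$V, layer$mask, layer$scheme$orders, n)
  N[n == 0] <- 1
  sweep(layer$V, 2, .layer_excit(layer) / N, `*`)
}

#' Build a sparse feedforward network
#'
#' Stacks sparse hidden layers and a fully connected softmax output layer
#' (the standard architecture for the image classification experiments; the
#' output layer can also be made sparse).
#'
#' @param sizes integer vector of layer sizes, `c(input, hidden..., output)`.
#' @param epsilon connection probability for the sparse layers.
#' @param scheme a [norm_scheme()] applied to every sparse hidden layer, or
#'   `NULL` for the unnormalised control.
#' @param activation hidden activation, `"sigmoid"` or `"threshold_linear"`.
#' @param cost `"log_likelihood"` (with softmax output) or `"mse"` (with
#'   sigmoid output).
#' @param output_epsilon connection probability of the output layer
#'   (default 1, fully connected).
#' @param s_init initial excitability of the sparse layers, see
#'   [init_sparse()].
#' @return An object of class `sparse_network`.
#' @export
sparse_network <- function(sizes, epsilon, scheme = NULL,
                           activation = "sigmoid",
                           cost = c("log_likelihood", "mse"),
                           output_epsilon = 1, s_init = 1) {
  cost <- match.arg(cost)
  stopifnot(length(sizes) >= 2)
  nl <- length(sizes) - 1
  layers <- vector("list", nl)
  for (i in seq_len(nl - 1)) {
    layers[[i]] <- init_sparse(sizes[i], sizes[i + 1], epsilon, scheme,
                               activation, s_init = s_init)
  }
  out_act <- if (cost == "log_likelihood") "softmax" else "sigmoid"
  layers[[nl]] <- init_sparse(sizes[nl], sizes[nl + 1], output_epsilon,
                              NULL, out_act)
  structure(list(layers = layers, cost = cost, sizes = sizes),
            class = "sparse_network")
}

#' Forward pass through a sparse network
#'
#' @param net a [sparse_network()].
#' @param X input batch, `input_dim x batch` matrix (or a vector for a
#'   single sample).
#' @return A list of activation matrices, one per layer (the input is not
#'   included); the last element is the network output.
#' @export
forward <- function(net, X) {
  stopifnot(inherits(net, "sparse_network"))
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != net$sizes[1]) {
    stop("input dimension ", nrow(X), " does not match network input ",
         net$sizes[1])
  }
  a <- X
  acts <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    lay <- net$layers[[i]]
    z <- crossprod(.layer_weights(lay), a) + lay$b
    a <- .act(z, lay$activation)
    acts[[i]] <- a
  }
  acts
}

# one-hot encode labels 0..K-1 as K x n matrix
.one_hot <- function(labels, K) {
  Y <- matrix(0, K, length(labels))
  Y[cbind(labels + 1, seq_along(labels))] <- 1
  Y
}

# batch cost given output activations (K x n) and one-hot targets
.batch_cost <- function(A, Y, cost) {
  if (cost == "log_likelihood") {
    -mean(log(pmax(colSums(A * Y), 1e-300)))
  } else {
    mean(colMeans((A - Y)^2))
  }
}

#' One minibatch stochastic gradient descent step
#'
#' Runs a forward and backward pass over a minibatch and applies one SGD
#' update to all raw weights, biases and excitability parameters. The
#' minibatch gradient is the mean over samples, so the learning rate is
#' independent of minibatch size. Gradients pass through the layer's
#' normalisation via the exact chain rule; connection supports are never
#' modified.
#'
#' @param net a [sparse_network()].
#' @param X input batch, `input_dim x batch`.
#' @param labels integer class labels `0..K-1` (for `"log_likelihood"`), or
#'   a `K x batch` target matrix (for `"mse"`).
#' @param eta learning rate.
#' @return A list with the updated `net` and the pre-update batch `cost`.
#' @export
backward_sgd_step <- function(net, X, labels, eta) {
  stopifnot(inherits(net, "sparse_network"), eta >= 0)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  batch <- ncol(X)
  K <- net$sizes[length(net$sizes)]
  Y <- if (is.matrix(labels)) labels else .one_hot(labels, K)
  nl <- length(net$layers)

  # forward, keeping pre-activations
  acts <- vector("list", nl)
  zs <- vector("list", nl)
  a <- X
  for (i in seq_len(nl)) {
    lay <- net$layers[[i]]
    z <- crossprod(.layer_weights(lay), a) + lay$b
    a <- .act(z, lay$activation)
    zs[[i]] <- z
    acts[[i]] <- a
  }
  cost <- .batch_cost(acts[[nl]], Y, net$cost)

  # output delta dC/dz
  out_act <- net$layers[[nl]]$activation
  delta <- if (net$cost == "log_likelihood" && out_act == "softmax") {
    (acts[[nl]] - Y) / batch
  } else if (net$cost == "mse") {
    2 / (K * batch) * (acts[[nl]] - Y) *
      .act_deriv(acts[[nl]], zs[[nl]], out_act)
  } else {
    stop("cost ", net$cost, " incompatible with output activation ", out_act)
  }

  for (i in rev(seq_len(nl))) {
    lay <- net$layers[[i]]
    a_prev <- if (i == 1) X else acts[[i - 1]]
    GW <- a_prev %*% t(delta)
    GW[!lay$mask] <- 0
    if (is.null(lay$scheme)) {
      gv <- GW
    } else {
      n <- colSums(lay$mask)
      res <- .col_grads(lay$V, lay$mask, lay$scheme, .layer_excit(lay), GW,
                        n)
      gv <- res$grad_v
      ge <- res$grad_e
      ge[n == 0] <- 0
      if (lay$scheme$excitability == "constant") {
        net$layers[[i]]$s <- lay$s - eta * sum(ge)
      } else {
        net$layers[[i]]$g <- lay$g - eta * ge
      }
    }
    gb <- rowSums(delta)
    if (i > 1) { # propagate before updating weights
      delta <- (.layer_weights(lay) %*% delta) *
        .act_deriv(acts[[i - 1]], zs[[i - 1]],
                   net$layers[[i - 1]]$activation)
    }
    net$layers[[i]]$V <- lay$V - eta * gv
    net$layers[[i]]$V[!lay$mask] <- 0
    net$layers[[i]]$b <- lay$b - eta * gb
  }
  list(net = net, cost = cost)
}

#' Evaluate a network on a labelled dataset
#'
#' For feedforward classification, accuracy is the fraction of samples whose
#' arg-max output matches the label; the cost is the mean of the network's
#' cost function.
#'
#' @param net a [sparse_network()].
#' @param images `n x input_dim` matrix of samples (rows).
#' @param labels integer labels `0..K-1`.
#' @return A list with `cost` and `accuracy`.
#' @export
evaluate_network <- function(net, images, labels) {
  stopifnot(nrow(images) == length(labels), length(labels) >= 1)
  A <- forward(net, t(images))
  out <- A[[length(A)]]
  K <- net$sizes[length(net$sizes)]
  Y <- .one_hot(labels, K)
  pred <- max.col(t(out)) - 1
  list(cost = .batch_cost(out, Y, net$cost),
       accuracy = mean(pred == labels))
}

# ---- recurrent network -----------------------------------------------------

#' Build a recurrent network for sequence addition
#'
#' Two input units feed a hidden layer of `M` sigmoid units with sparse
#' recurrent connectivity; a single sigmoid output unit reads the hidden
#' state. The feedforward stream is dense by default (every input connects
#' to every hidden unit) or sparse; when normalised, the feedforward and
#' recurrent streams carry separate shared excitability parameters. The
#' cost is the mean squared error over the output sequence.
#'
#' @param M hidden layer size.
#' @param epsilon connection probability of the sparse stream(s).
#' @param scheme a [norm_scheme()] applied to the sparse streams, or `NULL`
#'   for the control.
#' @param sparse_input if `TRUE`, the feedforward stream is also sparse and
#'   participates in the joint SET pool.
#' @param allow_self if `FALSE`, recurrent self-connections are excluded
#'   from the mask (and from SET regrowth).
#' @return An object of class `recurrent_network` with streams `input`,
#'   `rec` (both `sparse_layer`-like), hidden bias `b`, and a dense sigmoid
#'   readout (`w_out`, `b_out`).
#' @export
recurrent_network <- function(M, epsilon, scheme = NULL,
                              sparse_input = FALSE, allow_self = TRUE) {
  input <- if (sparse_input) {
    init_sparse(2, M, epsilon, scheme)
  } else {
    lay <- init_sparse(2, M, 1, scheme)
    lay
  }
  rec <- init_sparse(M, M, epsilon, scheme)
  if (!allow_self) {
    diag(rec$mask) <- FALSE
    diag(rec$V) <- 0
    empty <- which(colSums(rec$mask) == 0)
    for (j in empty) {
      k <- sample(setdiff(seq_len(M), j), 1)
      rec$mask[k, j] <- TRUE
      rec$V[k, j] <- stats::rnorm(1)
    }
  }
  structure(list(input = input, rec = rec, b = rep(0, M),
                 w_out = stats::rnorm(M, 0, 1 / sqrt(M)), b_out = 0,
                 M = M, sparse_input = sparse_input,
                 allow_self = allow_self, scheme = scheme),
            class = "recurrent_network")
}

# forward pass over a batch of bit sequences; A, B are batch x m matrices.
# returns hidden states and outputs at every step
.rnn_forward <- function(rnet, A, B) {
  batch <- nrow(A)
  m <- ncol(A)
  W_in <- .layer_weights(rnet$input)
  W_rec <- .layer_weights(rnet$rec)
  H <- vector("list", m)
  Zs <- vector("list", m)
  y <- matrix(0, batch, m)
  zy <- matrix(0, batch, m)
  h <- matrix(0, rnet$M, batch)
  for (t in seq_len(m)) {
    x <- rbind(A[, t], B[, t])
    z <- crossprod(W_in, x) + crossprod(W_rec, h) + rnet$b
    h <- .sigmoid(z)
    Zs[[t]] <- z
    H[[t]] <- h
    zy[, t] <- drop(crossprod(h, rnet$w_out)) + rnet$b_out
    y[, t] <- .sigmoid(zy[, t])
  }
  list(H = H, Zs = Zs, y = y, zy = zy, W_in = W_in, W_rec = W_rec)
}

#' One BPTT minibatch step for the recurrent network
#'
#' Exact backpropagation through time over each full sequence (the hidden
#' state is reset to zero at every sequence start), through the stream
#' normalisations, followed by one SGD update. The cost per sequence is the
#' mean squared error of the raw outputs over the `m` timesteps, averaged
#' over the minibatch.
#'
#' @param rnet a [recurrent_network()].
#' @param A,B `batch x m` 0/1 matrices of addend bits (LSB first).
#' @param S `batch x m` target sum bits.
#' @param eta learning rate.
#' @return A list with the updated `rnet` and the pre-update `cost`.
#' @export
bptt_step <- function(rnet, A, B, S, eta) {
  stopifnot(inherits(rnet, "recurrent_network"), nrow(A) == nrow(S),
            ncol(A) == ncol(S))
  batch <- nrow(A)
  m <- ncol(A)
  fw <- .rnn_forward(rnet, A, B)
  cost <- mean(rowMeans((fw$y - S)^2))

  # the reported cost is the per-sequence mean squared error, but the
  # gradient accumulates over the sequence (standard BPTT), so the
  # effective step size does not shrink with sequence length
  d_out <- 2 / batch * (fw$y - S) * fw$y * (1 - fw$y) # dC/dzy
  GW_in <- matrix(0, 2, rnet$M)
  GW_rec <- matrix(0, rnet$M, rnet$M)
  gb <- rep(0, rnet$M)
  g_wout <- rep(0, rnet$M)
  g_bout <- 0
  e_next <- matrix(0, rnet$M, batch) # dC/dz_{t+1}
  for (t in rev(seq_len(m))) {
    h <- fw$H[[t]]
    dh <- rnet$w_out %o% rep(1, batch) *
      matrix(d_out[, t], rnet$M, batch, byrow = TRUE) +
      fw$W_rec %*% e_next
    e_t <- dh * h * (1 - h)
    x <- rbind(A[, t], B[, t])
    h_prev <- if (t == 1) matrix(0, rnet$M, batch) else fw$H[[t - 1]]
    GW_in <- GW_in + x %*% t(e_t)
    GW_rec <- GW_rec + h_prev %*% t(e_t)
    gb <- gb + rowSums(e_t)
    g_wout <- g_wout + drop(h %*% d_out[, t])
    g_bout <- g_bout + sum(d_out[, t])
    e_next <- e_t
  }

  for (stream in c("input", "rec")) {
    lay <- rnet[[stream]]
    GW <- if (stream == "input") GW_in else GW_rec
    GW[!lay$mask] <- 0
    if (is.null(lay$scheme)) {
      gv <- GW
    } else {
      n <- colSums(lay$mask)
      res <- .col_grads(lay$V, lay$mask, lay$scheme, .layer_excit(lay), GW,
                        n)
      gv <- res$grad_v
      ge <- res$grad_e
      ge[n == 0] <- 0
      if (lay$scheme$excitability == "constant") {
        rnet[[stream]]$s <- lay$s - eta * sum(ge)
      } else {
        rnet[[stream]]$g <- lay$g - eta * ge
      }
    }
    rnet[[stream]]$V <- lay$V - eta * gv
    rnet[[stream]]$V[!lay$mask] <- 0
  }
  rnet$b <- rnet$b - eta * gb
  rnet$w_out <- rnet$w_out - eta * g_wout
  rnet$b_out <- rnet$b_out - eta * g_bout
  list(rnet = rnet, cost = cost)
}

#' Evaluate the recurrent network on binary addition data
#'
#' The cost is the mean squared error of the raw outputs; a trial counts as
#' accurate only if every output in the sequence, rounded to the nearest
#' integer, equals the corresponding sum bit.
#'
#' @param rnet a [recurrent_network()].
#' @param data a list with `a`, `b`, `s` as from [gen_binary_addition()].
#' @return A list with `cost` and `accuracy`.
#' @export
evaluate_recurrent <- function(rnet, data) {
  stopifnot(nrow(data$a) >= 1)
  fw <- .rnn_forward(rnet, data$a, data$b)
  pred <- round(fw$y)
  list(cost = mean(rowMeans((fw$y - data$s)^2)),
       accuracy = mean(rowSums(pred != data$s) == 0))
}
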