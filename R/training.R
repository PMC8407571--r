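#' Train a sparse feedforward network with SGD and SET
#'
#' Runs minibatch stochastic gradient descent over the training set, and at
#' the end of every epoch applies SET rewiring to each sparse hidden layer
#' (each layer is its own pool; the fully connected output layer is never
#' rewired). Training defaults follow the study conditions: minibatch 10,
#' learning rate 0.05, excision fraction 0.15.
#'
#' @param net a [sparse_network()].
#' @param images `n x input_dim` training samples.
#' @param labels integer training labels `0..K-1`.
#' @param epochs number of epochs.
#' @param minibatch minibatch size.
#' @param eta learning rate.
#' @param zeta SET excision fraction; `0` disables rewiring.
#' @param test_images,test_labels optional held-out set evaluated after
#'   every epoch.
#' @param rank_by passed to [rewire()].
#' @return A list with the trained `net`, `curve` (a data frame with one
#'   row per epoch: `epoch`, `train_cost` the mean minibatch cost,
#'   `test_accuracy`, `test_cost`, `edges` the total sparse connection
#'   count), and `reports` (per-epoch SET reports).
#' @export
train_network <- function(net, images, labels, epochs, minibatch = 10,
                          eta = 0.05, zeta = 0.15, test_images = NULL,
                          test_labels = NULL, rank_by = "effective") {
  stopifnot(inherits(net, "sparse_network"), epochs >= 1, minibatch >= 1)
  n <- nrow(images)
  nl <- length(net$layers)
  sparse_idx <- seq_len(nl - 1)
  curve <- data.frame(epoch = seq_len(epochs), train_cost = NA_real_,
                      test_cost = NA_real_, test_accuracy = NA_real_,
                      edges = NA_real_)
  reports <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    costs <- c()
    for (start in seq(1, n, by = minibatch)) {
      sel <- ord[start:min(start + minibatch - 1, n)]
      step <- backward_sgd_step(net, t(images[sel, , drop = FALSE]),
                                labels[sel], eta)
      net <- step$net
      costs <- c(costs, step$cost)
    }
    if (zeta > 0 && length(sparse_idx) > 0) {
      rep_list <- vector("list", length(sparse_idx))
      for (i in sparse_idx) {
        rw <- rewire(net$layers[[i]], zeta, rank_by = rank_by)
        net$layers[[i]] <- rw$layers
        rep_list[[i]] <- rw$report
      }
      reports[[ep]] <- rep_list
    }
    curve$train_cost[ep] <- mean(costs)
    curve$edges[ep] <- sum(vapply(net$layers[sparse_idx],
                                  function(l) sum(l$mask), numeric(1)))
    if (!is.null(test_images)) {
      ev <- evaluate_network(net, test_images, test_labels)
      curve$test_cost[ep] <- ev$cost
      curve$test_accuracy[ep] <- ev$accuracy
    }
  }
  list(net = net, curve = curve, reports = reports)
}

#' Train a recurrent network on binary addition with BPTT and SET
#'
#' The binary addition task has an unlimited supply of data, so each epoch
#' consists of `epoch_len` freshly generated sequences, followed by SET
#' rewiring: on the recurrent stream alone when the feedforward stream is
#' dense, or on the joint feedforward + recurrent pool when both streams
#' are sparse (so weak feedforward contacts compete with weak recurrent
#' contacts for survival).
#'
#' @param rnet a [recurrent_network()].
#' @param epochs number of epochs.
#' @param epoch_len sequences per epoch.
#' @param m bits per sequence.
#' @param minibatch minibatch size.
#' @param eta learning rate.
#' @param zeta SET excision fraction; `0` disables rewiring.
#' @param eval_n sequences in the fresh per-epoch evaluation set
#'   (`0` skips evaluation).
#' @param rank_by passed to [rewire()].
#' @return A list with the trained `rnet`, `curve` (`epoch`, `train_cost`,
#'   `test_cost`, `test_accuracy`, `edges`), and `reports`.
#' @export
train_recurrent <- function(rnet, epochs, epoch_len = 1000, m = 50,
                            minibatch = 10, eta = 0.05, zeta = 0.15,
                            eval_n = 200, rank_by = "effective") {
  stopifnot(inherits(rnet, "recurrent_network"), epochs >= 1)
  if (!rnet$allow_self && is.null(rnet$rec$forbid)) {
    rnet$rec$forbid <- diag(TRUE, rnet$M)
  }
  joint_pool <- rnet$sparse_input
  curve <- data.frame(epoch = seq_len(epochs), train_cost = NA_real_,
                      test_cost = NA_real_, test_accuracy = NA_real_,
                      edges = NA_real_)
  reports <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    data <- gen_binary_addition(epoch_len, m)
    costs <- c()
    for (start in seq(1, epoch_len, by = minibatch)) {
      sel <- start:min(start + minibatch - 1, epoch_len)
      step <- bptt_step(rnet, data$a[sel, , drop = FALSE],
                        data$b[sel, , drop = FALSE],
                        data$s[sel, , drop = FALSE], eta)
      rnet <- step$rnet
      costs <- c(costs, step$cost)
    }
    if (zeta > 0) {
      if (joint_pool) {
        rw <- rewire(list(rnet$input, rnet$rec), zeta, rank_by = rank_by)
        rnet$input <- rw$layers[[1]]
        rnet$rec <- rw$layers[[2]]
      } else {
        rw <- rewire(rnet$rec, zeta, rank_by = rank_by)
        rnet$rec <- rw$layers
      }
      reports[[ep]] <- rw$report
    }
    curve$train_cost[ep] <- mean(costs)
    curve$edges[ep] <- sum(rnet$rec$mask) +
      if (joint_pool) sum(rnet$input$mask) else 0
    if (eval_n > 0) {
      ev <- evaluate_recurrent(rnet, gen_binary_addition(eval_n, m))
      curve$test_cost[ep] <- ev$cost
      curve$test_accuracy[ep] <- ev$accuracy
    }
  }
  list(rnet = rnet, curve = curve, reports = reports)
}
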