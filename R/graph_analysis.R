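# coerce an adjacency representation (logical/numeric matrix, sparse layer,
# or igraph) to a directed igraph without self-loops
.as_digraph <- function(g) {
  if (inherits(g, "igraph")) return(g)
  if (is.list(g) && !is.null(g$mask)) g <- g$mask
  stopifnot(is.matrix(g), nrow(g) == ncol(g))
  adj <- (g != 0) * 1
  diag(adj) <- 0
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

#' Average shortest path length of a directed connectivity graph
#'
#' Mean over all ordered pairs `(i, j)`, `i != j`, of the directed
#' shortest-path length, with unreachable pairs excluded from the mean.
#' Self-pairs and self-loops are always excluded. Set
#' `directed = FALSE` to symmetrise the graph first.
#'
#' @param g an adjacency matrix (rows are sources), a `sparse_layer` whose
#'   mask is square (recurrent connectivity), or an igraph object.
#' @param directed treat edges as directed (default) or symmetrise.
#' @return The average shortest path length.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- m[2, 3] <- m[3, 1] <- 1
#' average_shortest_path(m) # directed 3-cycle: (1 + 2) / 2
#' @export
average_shortest_path <- function(g, directed = TRUE) {
  g <- .as_digraph(g)
  if (igraph::vcount(g) < 2) stop("graph must have at least 2 nodes")
  d <- igraph::distances(g, mode = if (directed) "out" else "all")
  diag(d) <- NA
  finite <- is.finite(d)
  if (!any(finite, na.rm = TRUE)) {
    stop("no reachable ordered pairs: average path length undefined")
  }
  mean(d[which(finite)])
}

#' Degree, weight, and input histograms of a sparse layer
#'
#' Structural statistics of a (trained or untrained) sparse layer: the
#' distribution of in-degrees (afferent contacts per post-synaptic neuron),
#' the distribution of absolute effective weights, and optionally the mean
#' weighted input to each neuron over an evaluation set.
#'
#' @param layer a `sparse_layer`.
#' @param data optional `n x fan_in` matrix of samples over which to average
#'   the weighted input (activations of the pre-synaptic layer).
#' @param degree_breaks,weight_breaks,input_breaks bin edges passed to
#'   [graphics::hist()]-style binning; defaults let [hist()] choose.
#' @return A list with `in_degree` (vector), `degree_hist`, `weight_hist`
#'   (histogram objects), and if `data` is given `mean_input` (per-neuron
#'   mean of the weighted input, excluding the bias) and `input_hist`.
#' @export
degree_and_weight_stats <- function(layer, data = NULL,
                                    degree_breaks = "Sturges",
                                    weight_breaks = "Sturges",
                                    input_breaks = "Sturges") {
  stopifnot(!is.null(layer$mask))
  n_in <- colSums(layer$mask)
  W <- .layer_weights(layer)
  w_abs <- abs(W[layer$mask])
  out <- list(
    in_degree = n_in,
    degree_hist = graphics::hist(n_in, breaks = degree_breaks,
                                 plot = FALSE),
    weight_hist = graphics::hist(w_abs, breaks = weight_breaks,
                                 plot = FALSE)
  )
  if (!is.null(data)) {
    if (nrow(data) < 1) stop("empty dataset for the input statistic")
    stopifnot(ncol(data) == nrow(layer$V))
    z <- data %*% W # n x M weighted inputs
    out$mean_input <- colMeans(z)
    out$input_hist <- graphics::hist(out$mean_input, breaks = input_breaks,
                                     plot = FALSE)
  }
  out
}

#' Efferent connection counts per input pixel
#'
#' Counts the outgoing connections of each input unit of a sparse layer and
#' arranges them on the input image grid, reproducing the efferent-contact
#' maps used to visualise which pixels the rewired connectivity favours.
#'
#' @param layer a `sparse_layer` whose fan-in equals `prod(image_shape)`.
#' @param image_shape integer vector `c(rows, cols)`.
#' @return A `rows x cols` matrix of efferent counts; the sum equals the
#'   layer's total connection count.
#' @export
efferent_map <- function(layer, image_shape) {
  stopifnot(!is.null(layer$mask), length(image_shape) == 2)
  if (nrow(layer$mask) != prod(image_shape)) {
    stop("layer fan-in ", nrow(layer$mask), " does not match image shape ",
         paste(image_shape, collapse = "x"))
  }
  matrix(rowSums(layer$mask), image_shape[1], image_shape[2])
}

#' Fraction of hidden neurons connected to both input units
#'
#' For a recurrent network with two input units and sparse feedforward
#' connectivity, the fraction of hidden neurons that receive at least one
#' connection from each input unit.
#'
#' @param rnet a [recurrent_network()] with `sparse_input = TRUE`, or a
#'   layer-like object with a 2-row feedforward mask.
#' @return The fraction in `[0, 1]`.
#' @export
both_input_fraction <- function(rnet) {
  mask <- if (inherits(rnet, "recurrent_network")) {
    if (!rnet$sparse_input) {
      stop("both-input fraction applies to the sparse feedforward variant")
    }
    rnet$input$mask
  } else {
    rnet$mask
  }
  stopifnot(nrow(mask) == 2)
  mean(mask[1, ] & mask[2, ])
}
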