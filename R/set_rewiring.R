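#' Sparse evolutionary rewiring (SET)
#'
#' Applies one round of sparse evolutionary training to one or more sparse
#' layers sharing a pool: the `floor(zeta * E)` connections with the
#' smallest ranking weight across the pooled `E` connections are excised,
#' and the same number of new connections are created uniformly at random
#' among the currently absent (pre, post) pairs of the pool, with fresh
#' weights drawn from `regrow_weights`. In-degrees are implicitly
#' recomputed since they are always derived from the mask. Ties in the
#' ranking are broken by a random permutation.
#'
#' "Weakest" is measured on the absolute effective weight `|w|` after
#' normalisation by default, since the effective weight is the functional
#' strength of a contact; under the dendritic scheme a contact's survival
#' therefore depends on its neuron's in-degree. Set `rank_by = "raw"` to
#' rank on `|v|` instead.
#'
#' @param layers a single `sparse_layer` (or layer-like list with `V`,
#'   `mask`, `scheme` and excitability fields) or a list of them forming a
#'   joint pool, e.g. the feedforward and recurrent streams of a recurrent
#'   network. A layer may carry a logical `forbid` matrix marking pairs
#'   that must never be wired (e.g. recurrent self-connections).
#' @param zeta excision fraction in `[0, 1)`.
#' @param rank_by `"effective"` (|w|, default) or `"raw"` (|v|).
#' @param regrow_weights function taking a count and returning that many new
#'   raw weights; defaults to standard normal draws.
#' @return A list with `layers` (updated, same shape as the input) and
#'   `report`, itself a list with `excised`, `regrown`, and
#'   `per_stream_counts` (excisions and regrowths per layer).
#' @export
rewire <- function(layers, zeta, rank_by = c("effective", "raw"),
                   regrow_weights = stats::rnorm) {
  rank_by <- match.arg(rank_by)
  stopifnot(zeta >= 0, zeta < 1)
  single <- !is.null(layers$mask)
  if (single) layers <- list(layers)
  n_stream <- length(layers)

  edge_counts <- vapply(layers, function(l) sum(l$mask), numeric(1))
  E <- sum(edge_counts)
  k <- floor(zeta * E)
  report <- list(excised = k, regrown = k,
                 per_stream_counts = data.frame(
                   stream = seq_len(n_stream),
                   excised = rep(0L, n_stream),
                   regrown = rep(0L, n_stream)))
  if (k == 0) {
    out <- if (single) layers[[1]] else layers
    return(list(layers = out, report = report))
  }

  # pooled ranking of existing edges
  stream_id <- integer(0)
  lin_idx <- integer(0)
  strength <- numeric(0)
  for (i in seq_len(n_stream)) {
    lay <- layers[[i]]
    idx <- which(lay$mask)
    w_mat <- if (rank_by == "effective") .layer_weights(lay) else lay$V
    stream_id <- c(stream_id, rep(i, length(idx)))
    lin_idx <- c(lin_idx, idx)
    strength <- c(strength, abs(w_mat[idx]))
  }
  ord <- order(strength, sample.int(length(strength)))
  drop_sel <- ord[seq_len(k)]
  for (i in seq_len(n_stream)) {
    sel <- drop_sel[stream_id[drop_sel] == i]
    if (length(sel) > 0) {
      layers[[i]]$mask[lin_idx[sel]] <- FALSE
      layers[[i]]$V[lin_idx[sel]] <- 0
    }
    report$per_stream_counts$excised[i] <- length(sel)
  }

  # pooled regrowth among absent pairs
  absent_stream <- integer(0)
  absent_idx <- integer(0)
  for (i in seq_len(n_stream)) {
    lay <- layers[[i]]
    absent <- !lay$mask
    if (!is.null(lay$forbid)) absent <- absent & !lay$forbid
    idx <- which(absent)
    absent_stream <- c(absent_stream, rep(i, length(idx)))
    absent_idx <- c(absent_idx, idx)
  }
  if (length(absent_idx) < k) {
    stop("pool saturated: only ", length(absent_idx),
         " absent pairs available for ", k, " regrowths")
  }
  new_sel <- sample.int(length(absent_idx), k)
  new_w <- regrow_weights(k)
  for (i in seq_len(n_stream)) {
    sel <- new_sel[absent_stream[new_sel] == i]
    if (length(sel) > 0) {
      layers[[i]]$mask[absent_idx[sel]] <- TRUE
      layers[[i]]$V[absent_idx[sel]] <- new_w[absent_stream[new_sel] == i]
    }
    report$per_stream_counts$regrown[i] <- length(sel)
  }
  out <- if (single) layers[[1]] else layers
  list(layers = out, report = report)
}
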