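#' Afferent weight normalisation scheme
#'
#' Defines the family of reparametrisations `w = f(v)` applied to a
#' neuron's afferent weight vector. The effective weights are the raw
#' weights divided by one or two norms of the raw vector, scaled by an
#' excitability parameter that is either shared across all neurons
#' (`"constant"`, the scalar `s`) or neuron-specific (`"per_neuron"`, the
#' vector `g`):
#' \deqn{w_i = \frac{e_i}{\prod_{p \in orders} \|v_i\|_p} v_i}
#' Order 0 is the dendritic normalisation (division by the number of
#' afferent contacts, \eqn{\|v\|_0 = n}); order 2 is the heterosynaptic
#' (Euclidean) normalisation; joint pairs such as `c(0, 2)` divide by the
#' product of both norms.
#'
#' @param orders integer vector of norm orders, drawn from `0:5`; one or two
#'   distinct elements.
#' @param excitability `"constant"` (one shared scalar `s`) or
#'   `"per_neuron"` (one `g_i` per neuron).
#' @return An object of class `norm_scheme`.
#' @examples
#' norm_scheme(0)                     # dendritic normalisation
#' norm_scheme(2, "per_neuron")       # heterosynaptic normalisation
#' norm_scheme(c(0, 2), "per_neuron") # joint dendritic + heterosynaptic
#' @export
norm_scheme <- function(orders, excitability = c("constant", "per_neuron")) {
  excitability <- match.arg(excitability)
  orders <- sort(unique(as.integer(orders)))
  if (length(orders) < 1 || length(orders) > 2) {
    stop("orders must contain one or two distinct norm orders")
  }
  if (any(orders < 0 | orders > 5)) {
    stop("norm orders must lie in 0..5")
  }
  structure(list(orders = orders, excitability = excitability),
            class = "norm_scheme")
}

#' @export
print.norm_scheme <- function(x, ...) {
  cat("Norm scheme: L", paste(x$orders, collapse = " * L"),
      " (", x$excitability, " excitability)\n", sep = "")
  invisible(x)
}

# product of the scheme's norms for one support vector; n is the in-degree
# (L0 norm), which is tracked separately so that a raw weight passing
# through zero does not change it
.norm_product <- function(v, orders, n) {
  N <- 1
  for (p in orders) {
    if (p == 0) {
      N <- N * n
    } else {
      np <- sum(abs(v)^p)^(1 / p)
      if (np == 0) {
        stop("degenerate norm: ||v||_", p, " is zero")
      }
      N <- N * np
    }
  }
  N
}

#' Normalise an afferent weight vector
#'
#' Maps raw afferent weights `v` (the values on a neuron's existing
#' connections) to effective weights `w = e * v / prod(norms)`. Entries that
#' are zero stay exactly zero, and the off-support structure is never
#' touched.
#'
#' @param v numeric vector of raw weights on the support (existing
#'   connections).
#' @param scheme a [norm_scheme()].
#' @param e excitability value for this neuron (the shared `s` or the
#'   neuron's `g_i`); default 1.
#' @param n in-degree (the L0 norm). Defaults to `length(v)`; pass it
#'   explicitly if `v` holds transient exact zeros on existing connections.
#' @return Effective weights `w`, same shape as `v`.
#' @examples
#' normalise(rep(1, 4), norm_scheme(0))          # each w = 1/4
#' normalise(c(3, 4), norm_scheme(c(0, 2)))      # (3,4) / (2 * 5)
#' @export
normalise <- function(v, scheme, e = 1, n = length(v)) {
  stopifnot(inherits(scheme, "norm_scheme"), n >= 1)
  e * v / .norm_product(v, scheme$orders, n)
}

#' Cost gradient with respect to raw weights
#'
#' Exact chain-rule transformation of a cost gradient through the
#' normalisation map: given `grad_w = dC/dw`, returns `dC/dv` restricted to
#' the support. For the dendritic scheme this is `(e/n) * grad_w`; for
#' orders `p >= 1` the Jacobian of \eqn{\|v\|_p} uses
#' \eqn{sign(v_j) |v_j|^{p-1}}, the sign-correct generalisation of
#' \eqn{v_j^{p-1}} to signed weights.
#'
#' @inheritParams normalise
#' @param grad_w gradient of the cost with respect to the effective weights
#'   `w`, same shape as `v`.
#' @return Gradient of the cost with respect to `v`.
#' @export
grad_v <- function(v, scheme, grad_w, e = 1, n = length(v)) {
  stopifnot(inherits(scheme, "norm_scheme"), length(grad_w) == length(v))
  N <- .norm_product(v, scheme$orders, n)
  corr <- rep(0, length(v))
  dot <- sum(grad_w * v)
  for (p in scheme$orders[scheme$orders >= 1]) {
    corr <- corr + sign(v) * abs(v)^(p - 1) / sum(abs(v)^p)
  }
  (e / N) * (grad_w - dot * corr)
}

#' Cost gradient with respect to the excitability parameter
#'
#' Exact chain-rule derivative of the cost with respect to a neuron's
#' excitability: `(1/N) * grad_w . v` where `N` is the product of the
#' scheme's norms. In constant mode the network-level update sums this
#' quantity over all afferent vectors sharing `s`; here the per-vector
#' contribution is returned.
#'
#' @inheritParams grad_v
#' @return Scalar contribution `dC/de` for this afferent vector.
#' @export
grad_excitability <- function(v, scheme, grad_w, n = length(v)) {
  stopifnot(inherits(scheme, "norm_scheme"), length(grad_w) == length(v))
  sum(grad_w * v) / .norm_product(v, scheme$orders, n)
}

#' Relative gradient magnitude over connectivity and weight scale
#'
#' For each combination of in-degree `n` and mean absolute weight, draws
#' random normally distributed afferent vectors, rescales them to the
#' target mean absolute weight, and records the scheme's scalar gradient
#' prefactor `1 / prod(norms)` (the factor multiplying `dC/dw` in
#' [grad_v()]), averaged over `reps` draws. The resulting matrix is scaled
#' linearly so its maximum is 1, making schemes comparable: the dendritic
#' scheme depends only on `n`, the Euclidean scheme on both `n` and the
#' weight scale.
#'
#' @param scheme a [norm_scheme()].
#' @param n_grid in-degrees to evaluate (rows). Defaults to a plausible
#'   range for an input layer of `input_dim` units connected with
#'   probability `epsilon`.
#' @param meanabs_grid target mean absolute weights (columns).
#' @param input_dim size of the notional input layer (used only for the
#'   default `n_grid`).
#' @param epsilon connection probability in `(0, 1)` (used only for the
#'   default `n_grid`).
#' @param reps random draws per cell.
#' @return A matrix of relative gradient magnitudes with maximum exactly 1,
#'   rows indexed by `n_grid` and columns by `meanabs_grid`.
#' @export
gradient_magnitude_surface <- function(scheme, n_grid = NULL,
                                       meanabs_grid = seq(0.1, 2, length.out = 10),
                                       input_dim = 784, epsilon = 0.2,
                                       reps = 20) {
  stopifnot(inherits(scheme, "norm_scheme"),
            epsilon > 0, epsilon < 1, reps >= 1)
  if (is.null(n_grid)) {
    mu <- input_dim * epsilon
    sd <- sqrt(input_dim * epsilon * (1 - epsilon))
    n_grid <- unique(round(seq(max(1, mu - 3 * sd), mu + 3 * sd,
                               length.out = 10)))
  }
  stopifnot(length(n_grid) >= 1, length(meanabs_grid) >= 1)
  out <- matrix(0, length(n_grid), length(meanabs_grid),
                dimnames = list(n = n_grid, meanabs = signif(meanabs_grid, 4)))
  for (i in seq_along(n_grid)) {
    n <- n_grid[i]
    for (j in seq_along(meanabs_grid)) {
      target <- meanabs_grid[j]
      acc <- 0
      for (r in seq_len(reps)) {
        v <- stats::rnorm(n)
        v <- v * target / mean(abs(v))
        acc <- acc + 1 / .norm_product(v, scheme$orders, n)
      }
      out[i, j] <- acc / reps
    }
  }
  out / max(out)
}

# ---- matrix-level internals used by the network code -----------------------
# V: fan_in x M raw weight matrix (zero off support); mask: logical matrix;
# columns are post-synaptic neurons.

# per-column product of the scheme's norms; n from the mask, not from
# non-zero counting
.col_norm_product <- function(V, mask, orders, n = colSums(mask)) {
  N <- rep(1, ncol(V))
  for (p in orders) {
    if (p == 0) {
      N <- N * n
    } else {
      N <- N * colSums(abs(V)^p)^(1 / p)
    }
  }
  N
}

# effective weight matrix W = e * V / N per column
.col_normalise <- function(V, mask, scheme, e, n = colSums(mask)) {
  if (is.null(scheme)) return(V)
  N <- .col_norm_product(V, mask, scheme$orders, n)
  sweep(V, 2, e / N, `*`)
}

# chain-rule gradients through the per-column normalisation.
# GW: fan_in x M gradient wrt effective weights (already masked).
# returns list(grad_v = matrix, grad_e = per-column dC/de)
.col_grads <- function(V, mask, scheme, e, GW, n = colSums(mask)) {
  if (is.null(scheme)) {
    return(list(grad_v = GW, grad_e = rep(0, ncol(V))))
  }
  N <- .col_norm_product(V, mask, scheme$orders, n)
  dots <- colSums(GW * V)
  corr <- matrix(0, nrow(V), ncol(V))
  for (p in scheme$orders[scheme$orders >= 1]) {
    corr <- corr + sweep(sign(V) * abs(V)^(p - 1), 2,
                         colSums(abs(V)^p), `/`)
  }
  gv <- sweep(GW - sweep(corr, 2, dots, `*`), 2, e / N, `*`)
  gv[!mask] <- 0
  list(grad_v = gv, grad_e = dots / N)
}
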