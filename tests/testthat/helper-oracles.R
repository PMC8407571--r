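# shared independent oracles and small utilities for the test suite

# central finite-difference gradient of f at x
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x
    xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1))
}

# brute-force all-pairs shortest paths on a small directed adjacency matrix
floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj != 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
    }
  }
  d
}

aspl_bruteforce <- function(adj) {
  d <- floyd_warshall(adj)
  diag(d) <- NA
  mean(d[is.finite(d) & !is.na(d)])
}

# integer value of an LSB-first bit vector
bits_to_int <- function(bits) sum(bits * 2^(seq_along(bits) - 1))

# standard cable fixture: the intrinsic parameters used throughout
fig_cable <- function(l = 500, rho = 0) {
  cable_params(r = 1, l = l, r_a = 100, g_l = 5e-5, c = 1, rho = rho)
}

std_kernel <- function(theta = 1) {
  syn_kernel(tau_f = 0.002, tau_s = 0.05, theta_syn = theta)
}
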