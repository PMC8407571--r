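#' Passive cable parameters
#'
#' Physical constants of an unbranched passive dendritic cylinder with an
#' optional electrotonically compact soma at the root, together with the
#' derived electrotonic constants. Lengths are given in micrometres and
#' converted internally to CGS-electrical units (cm, S, s, A).
#'
#' @param r dendrite radius (um).
#' @param l physical dendrite length (um).
#' @param r_a axial resistivity (Ohm cm).
#' @param g_l membrane leak conductivity (S/cm^2).
#' @param c specific membrane capacitance (uF/cm^2).
#' @param rho soma radius (um); `0` means no soma.
#'
#' @return An object of class `cable_params` with the inputs plus the derived
#'   quantities: `lambda` the length constant (um), `L` the electrotonic
#'   length (dimensionless), `G_inf` the input conductance of a sealed
#'   semi-infinite cable (S), `G_s` the somatic leak conductance (S), and
#'   `tau_l` the membrane time constant (s). Derived fields are always
#'   recomputed from the physical fields.
#'
#' @details The length constant is \eqn{\lambda = \sqrt{r / (2 r_a g_l)}},
#'   the electrotonic length \eqn{L = l/\lambda}, the semi-infinite input
#'   conductance \eqn{G_\infty = \pi r^2 / (\lambda r_a)} and the somatic
#'   leak \eqn{G_s = 4 \pi \rho^2 g_l}.
#'
#' @examples
#' p <- cable_params(r = 1, l = 500, r_a = 100, g_l = 5e-5, c = 1)
#' p$L # electrotonic length
#' @export
cable_params <- function(r = 1, l = 500, r_a = 100, g_l = 5e-5, c = 1,
                         rho = 0) {
  stopifnot(r > 0, l > 0, r_a > 0, g_l > 0, c > 0, rho >= 0)
  um <- 1e-4 # um in cm
  r_cm <- r * um
  l_cm <- l * um
  rho_cm <- rho * um
  lambda_cm <- sqrt(r_cm / (2 * r_a * g_l))
  obj <- list(
    r = r, l = l, r_a = r_a, g_l = g_l, c = c, rho = rho,
    lambda = lambda_cm / um,
    L = l_cm / lambda_cm,
    G_inf = pi * r_cm^2 / (lambda_cm * r_a),
    G_s = 4 * pi * rho_cm^2 * g_l,
    tau_l = (c * 1e-6) / g_l
  )
  class(obj) <- "cable_params"
  obj
}

#' @export
print.cable_params <- function(x, ...) {
  cat("Passive cable: r =", x$r, "um, l =", x$l, "um, rho =", x$rho, "um\n")
  cat(sprintf("  lambda = %.4g um, L = %.4g, G_inf = %.4g S, tau_l = %.4g s\n",
              x$lambda, x$L, x$G_inf, x$tau_l))
  invisible(x)
}

#' Double-exponential synaptic current kernel
#'
#' The synaptic current time course
#' \eqn{\zeta(t) = \Theta_{syn} (e^{-t/\tau_f} - e^{-t/\tau_s}) / (\tau_f - \tau_s)},
#' which integrates to the total charge `theta_syn`. The kernel is singular
#' when the two time constants coincide, so equal values are rejected.
#'
#' @param tau_f fast synaptic time constant (s).
#' @param tau_s slow synaptic time constant (s).
#' @param theta_syn total synaptic charge scale (mA s).
#' @param delta_syn steady perturbation magnitude (mA), used for the
#'   steady-state moments.
#' @return An object of class `syn_kernel`.
#' @examples
#' k <- syn_kernel(tau_f = 0.002, tau_s = 0.05)
#' @export
syn_kernel <- function(tau_f, tau_s, theta_syn = 1, delta_syn = 1) {
  stopifnot(tau_f > 0, tau_s > 0)
  if (tau_f == tau_s) {
    stop("tau_f and tau_s must differ: the difference-of-exponentials ",
         "kernel is singular at equality")
  }
  structure(list(tau_f = tau_f, tau_s = tau_s, theta_syn = theta_syn,
                 delta_syn = delta_syn),
            class = "syn_kernel")
}

#' Evaluate the synaptic current kernel
#' @param kernel a [syn_kernel()].
#' @param t time(s) in seconds, non-negative.
#' @return Current values (same units as `theta_syn` per second).
#' @export
syn_current <- function(kernel, t) {
  stopifnot(all(t >= 0))
  with(kernel, theta_syn * (exp(-t / tau_f) - exp(-t / tau_s)) /
         (tau_f - tau_s))
}

# denominator shared by the soma-loaded transfer resistance and moments
.cable_denom <- function(params) {
  params$G_inf * sinh(params$L) + params$G_s * cosh(params$L)
}

#' Steady-state transfer resistance
#'
#' Somatic voltage per unit steady current injected at electrotonic distance
#' `X` from the root of a sealed passive cable, optionally loaded by a
#' compact soma at the root. Without a soma this is
#' \eqn{R_L(X) = \cosh(L - X) / (G_\infty \sinh L)}; with a soma the
#' denominator gains the somatic leak term,
#' \eqn{G_\infty \sinh L + G_s \cosh L}.
#'
#' @param params a [cable_params()].
#' @param X electrotonic distance(s) from the soma, in `[0, L]`.
#' @return Transfer resistance(s) in Ohms.
#' @examples
#' p <- cable_params(l = 500)
#' transfer_resistance(p, 0)      # somatic input resistance, coth(L)/G_inf
#' transfer_resistance(p, p$L / 2)
#' @export
transfer_resistance <- function(params, X) {
  stopifnot(inherits(params, "cable_params"))
  if (any(X < 0 | X > params$L)) {
    stop("X must lie within [0, L] = [0, ", signif(params$L, 6), "]")
  }
  cosh(params$L - X) / .cable_denom(params)
}

#' Moments of the somatic response to a steady local weight change
#'
#' Mean and variance, over a synaptic location uniformly distributed along
#' the dendrite, of the steady-state somatic voltage change produced by a
#' perturbation `delta_syn` of local synaptic current. The mean is
#' \eqn{\Delta_{syn} / (L G_\infty)} for a cable without a soma; with a soma
#' the denominator picks up the somatic leak. The variance is the exact
#' population variance of \eqn{\Delta_{syn} R_L(X)} under
#' \eqn{X \sim U(0, L)}, derived in closed form.
#'
#' @param params a [cable_params()].
#' @param delta_syn steady perturbation magnitude (mA).
#' @return A list with elements `mean` and `variance`.
#' @export
steady_moments <- function(params, delta_syn) {
  stopifnot(inherits(params, "cable_params"))
  L <- params$L
  D <- .cable_denom(params)
  m <- delta_syn * sinh(L) / (L * D)
  # E[R^2] = (L + sinh L cosh L) / (2 L D^2); var = E[R^2] - E[R]^2
  er2 <- (L + sinh(L) * cosh(L)) / (2 * L * D^2)
  v <- delta_syn^2 * (er2 - (sinh(L) / (L * D))^2)
  list(mean = m, variance = v)
}

# truncated cosine mode sum: sum_{n>=1} coef(n), stopping when the next
# term bound falls below tol * |running sum|, hard cap max_terms
.mode_sum <- function(term_fun, bound_fun, tol = 1e-9, max_terms = 1e4) {
  total <- 0
  for (n in seq_len(max_terms)) {
    total <- total + term_fun(n)
    if (bound_fun(n + 1) < tol * max(abs(total), .Machine$double.xmin)) {
      break
    }
  }
  total
}

#' Somatic impulse response of a sealed cable
#'
#' Response density at the root at normalised delay `T = t / tau_l` to an
#' impulse at electrotonic location `X`:
#' \eqn{\varepsilon(X, T) = e^{-T}/L \, [1/2 + \sum_{n \ge 1}
#' \cos(n\pi X/L) e^{-(\pi n/L)^2 T}]}.
#' The series is truncated once the next term's bound drops below `tol`
#' relative to the running sum (hard cap `max_terms` terms). The returned
#' value is in the normalised response units in which the time integral over
#' `T` equals \eqn{G_\infty R_L(X) / 2}; multiply by
#' \eqn{2 / (G_\infty \tau_l)} for volts per unit charge.
#'
#' @param params a [cable_params()] (the soma is ignored here; responses are
#'   for the sealed cable).
#' @param X electrotonic location in `[0, L]`.
#' @param T normalised delay(s), `T >= 0`.
#' @param tol relative truncation tolerance for the mode series.
#' @param max_terms hard cap on the number of series terms.
#' @return Response value(s), vectorised over `T`.
#' @export
impulse_response <- function(params, X, T, tol = 1e-9, max_terms = 1e4) {
  stopifnot(inherits(params, "cable_params"))
  if (any(T < 0)) stop("normalised delay T must be non-negative")
  if (X < 0 || X > params$L) stop("X must lie within [0, L]")
  L <- params$L
  vapply(T, function(Ti) {
    s <- .mode_sum(
      term_fun = function(n) cos(n * pi * X / L) * exp(-(pi * n / L)^2 * Ti),
      bound_fun = function(n) exp(-(pi * n / L)^2 * Ti),
      tol = tol, max_terms = max_terms
    )
    exp(-Ti) / L * (0.5 + s)
  }, numeric(1))
}

.check_kernel_times <- function(kernel, tau_l) {
  taus <- c(kernel$tau_f, kernel$tau_s, tau_l)
  if (any(duplicated(taus))) {
    stop("tau_f, tau_s and tau_l must be pairwise distinct; the ",
         "double-exponential convolution is degenerate at coincidence")
  }
}

#' Expected somatic voltage for a double-exponential synaptic current
#'
#' The location-averaged somatic voltage time course for a synaptic current
#' kernel arriving at a uniformly random dendritic location: the convolution
#' of the kernel with the location-averaged impulse response
#' \eqn{e^{-T} / (2L)}, in closed form. The result is proportional to
#' \eqn{1/L} at every time.
#'
#' @param params a [cable_params()].
#' @param kernel a [syn_kernel()].
#' @param t time(s) in seconds, `t >= 0`.
#' @return Mean voltage(s) in the same normalised response units as
#'   [impulse_response()].
#' @export
mean_synaptic_voltage <- function(params, kernel, t) {
  stopifnot(inherits(params, "cable_params"), inherits(kernel, "syn_kernel"))
  if (any(t < 0)) stop("t must be non-negative")
  .check_kernel_times(kernel, params$tau_l)
  L <- params$L
  tl <- params$tau_l
  tf <- kernel$tau_f
  ts <- kernel$tau_s
  el <- exp(-t / tl)
  kernel$theta_syn * tl / (2 * L * (tf - ts)) *
    (tf / (tf - tl) * (exp(-t / tf) - el) -
       ts / (ts - tl) * (exp(-t / ts) - el))
}

# per-mode response amplitude B_n(t): convolution of the unit-charge kernel
# shape with e^{-t/tau_n}, times tau-dependent prefactors; shared by the
# variance mode sums
.mode_response <- function(n, t, L, tau_l, tau_f, tau_s) {
  tn <- tau_l / (1 + (pi * n / L)^2)
  tau_f * tn / (tau_f - tn) * (exp(-t / tau_f) - exp(-t / tn)) -
    tau_s * tn / (tau_s - tn) * (exp(-t / tau_s) - exp(-t / tn))
}

#' Variance of the somatic voltage over synaptic location
#'
#' Variance, over a uniformly random synaptic location, of the somatic
#' voltage at time `t` in response to one synaptic current kernel. Computed
#' as the cosine-mode sum with effective mode time constants
#' \eqn{\tau_n = \tau_l (1 + (\pi n / L)^2)^{-1}}; each mode contributes
#' half its squared amplitude because the location average of
#' \eqn{\cos^2(n \pi X / L)} is exactly one half.
#'
#' @inheritParams mean_synaptic_voltage
#' @param tol relative truncation tolerance for the mode series.
#' @param max_terms hard cap on the number of series terms.
#' @return Voltage variance(s), vectorised over `t`.
#' @export
voltage_variance <- function(params, kernel, t, tol = 1e-9, max_terms = 1e4) {
  stopifnot(inherits(params, "cable_params"), inherits(kernel, "syn_kernel"))
  if (any(t < 0)) stop("t must be non-negative")
  .check_kernel_times(kernel, params$tau_l)
  L <- params$L
  tl <- params$tau_l
  tf <- kernel$tau_f
  ts <- kernel$tau_s
  pref <- kernel$theta_syn^2 / (2 * L^2 * (tf - ts)^2)
  vapply(t, function(ti) {
    if (ti == 0) return(0)
    s <- .mode_sum(
      term_fun = function(n) .mode_response(n, ti, L, tl, tf, ts)^2,
      # mode amplitudes are bounded by (tf + ts) * tau_n / min(tf, ts) decay
      bound_fun = function(n) {
        tn <- tl / (1 + (pi * n / L)^2)
        (2 * tn * max(tf, ts) / abs(min(tf, ts) - tn))^2
      },
      tol = tol, max_terms = max_terms
    )
    pref * s
  }, numeric(1))
}

#' Peak of the expected somatic voltage
#'
#' Finds the time `t_star` at which the location-averaged somatic voltage
#' [mean_synaptic_voltage()] is maximal, by bracketed root-finding on its
#' time derivative, and returns the peak voltage. The peak time is
#' independent of the dendritic length (only the amplitude scales with
#' \eqn{1/L}).
#'
#' @inheritParams mean_synaptic_voltage
#' @return A list with `t_star` (s) and `v_max`.
#' @export
peak_voltage <- function(params, kernel) {
  stopifnot(inherits(params, "cable_params"), inherits(kernel, "syn_kernel"))
  .check_kernel_times(kernel, params$tau_l)
  tl <- params$tau_l
  tf <- kernel$tau_f
  ts <- kernel$tau_s
  # stationarity condition: (ts - tl)(tf e^{-t/tl} - tl e^{-t/tf})
  #                       = (tf - tl)(ts e^{-t/tl} - tl e^{-t/ts})
  f <- function(t) {
    (ts - tl) * (tf * exp(-t / tl) - tl * exp(-t / tf)) -
      (tf - tl) * (ts * exp(-t / tl) - tl * exp(-t / ts))
  }
  t_hi <- 20 * max(tf, ts, tl)
  # t = 0 is a trivial root (the response rises quadratically); bracket the
  # interior root by scanning a log-spaced grid for a sign change
  grid <- exp(seq(log(1e-6 * min(tf, ts, tl)), log(t_hi), length.out = 400))
  fv <- f(grid)
  idx <- which(fv[-1] * fv[-length(fv)] < 0)
  if (length(idx) == 0) {
    stop("peak time not bracketed in (0, 20 max(tau)]")
  }
  i <- idx[[1]]
  t_star <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-14)$root
  list(t_star = t_star,
       v_max = mean_synaptic_voltage(params, kernel, t_star))
}

#' Time-integrated somatic voltage: mean and variance
#'
#' The mean total (time-integrated) somatic voltage from a single synaptic
#' activation at a uniformly random location is exactly
#' \eqn{\bar V = \Theta_{syn} \tau_l / (2 L)}, independent of the synaptic
#' time constants. The reported variance is the time integral of the
#' instantaneous location variance [voltage_variance()], evaluated in closed
#' form mode by mode (each mode response is a sum of three exponentials
#' whose squared integral is analytic).
#'
#' @inheritParams mean_synaptic_voltage
#' @param tol relative truncation tolerance for the variance mode series.
#' @param max_terms hard cap on the number of series terms.
#' @return A list with `mean` and `variance`.
#' @export
total_voltage <- function(params, kernel, tol = 1e-9, max_terms = 1e4) {
  stopifnot(inherits(params, "cable_params"), inherits(kernel, "syn_kernel"))
  .check_kernel_times(kernel, params$tau_l)
  L <- params$L
  tl <- params$tau_l
  tf <- kernel$tau_f
  ts <- kernel$tau_s
  m <- kernel$theta_syn * tl / (2 * L)
  if (kernel$theta_syn == 0) {
    return(list(mean = 0, variance = 0))
  }
  mode_integral <- function(n) {
    tn <- tl / (1 + (pi * n / L)^2)
    P <- tf * tn / (tf - tn)
    Q <- ts * tn / (ts - tn)
    co <- c(P, -Q, Q - P)
    th <- c(tf, ts, tn)
    # integral of (sum_j co_j e^{-t/th_j})^2 over t in (0, Inf)
    acc <- 0
    for (j in 1:3) {
      for (k in 1:3) {
        acc <- acc + co[j] * co[k] * th[j] * th[k] / (th[j] + th[k])
      }
    }
    acc
  }
  s <- .mode_sum(
    term_fun = mode_integral,
    bound_fun = function(n) {
      tn <- tl / (1 + (pi * n / L)^2)
      9 * (2 * tn * max(tf, ts) / abs(min(tf, ts) - tn))^2 * max(tf, ts)
    },
    tol = tol, max_terms = max_terms
  )
  v <- kernel$theta_syn^2 / (2 * L^2 * (tf - ts)^2) * s
  list(mean = m, variance = v)
}

#' Compartmental finite-difference oracle for the passive cable
#'
#' Independent numerical check of the closed-form cable quantities. The
#' cable is discretised into `n_comp` isopotential compartments joined by
#' axial conductances, with sealed ends and the somatic leak (and
#' capacitance) lumped onto the root compartment. For a steady input the
#' somatic voltage is obtained by a sparse linear solve; for a
#' double-exponential current kernel the full linear system is
#' diagonalised, so that each spatial mode is propagated with an exact
#' closed-form convolution in time (no time-stepping error).
#'
#' @param params a [cable_params()].
#' @param synapse_X electrotonic injection location in `[0, L]`.
#' @param input either a single number (steady current, mA) or a
#'   [syn_kernel()] (transient current).
#' @param n_comp number of compartments, at least 200.
#' @param t times (s) at which to report the transient somatic voltage;
#'   ignored for steady input.
#' @return For steady input, the somatic voltage (V per the input units).
#'   For a kernel, a list with `t` and somatic voltage `v`.
#' @export
compartmental_oracle <- function(params, synapse_X, input, n_comp = 400,
                                 t = NULL) {
  stopifnot(inherits(params, "cable_params"))
  if (n_comp < 200) stop("compartment count must be at least 200")
  if (synapse_X < 0 || synapse_X > params$L) stop("X must lie within [0, L]")
  um <- 1e-4
  r_cm <- params$r * um
  l_cm <- params$l * um
  dx <- l_cm / n_comp
  g_a <- pi * r_cm^2 / (params$r_a * dx)      # axial, between neighbours
  g_m <- 2 * pi * r_cm * dx * params$g_l      # membrane leak per compartment
  c_m <- 2 * pi * r_cm * dx * params$c * 1e-6 # capacitance per compartment (F)
  # conductance matrix (tridiagonal), soma lumped on compartment 1
  diag_g <- rep(g_m + 2 * g_a, n_comp)
  diag_g[c(1, n_comp)] <- g_m + g_a # sealed ends
  diag_g[1] <- diag_g[1] + params$G_s
  G <- diag(diag_g)
  off <- cbind(seq_len(n_comp - 1), 2:n_comp)
  G[off] <- -g_a
  G[off[, 2:1]] <- -g_a
  # injection compartment nearest the physical location X * lambda
  k <- min(n_comp, max(1, round(synapse_X / params$L * n_comp + 0.5)))

  if (is.numeric(input) && length(input) == 1) {
    i_vec <- rep(0, n_comp)
    i_vec[k] <- input * 1e-3 # mA -> A
    v <- solve(G, i_vec)
    return(v[1])
  }
  if (!inherits(input, "syn_kernel")) {
    stop("input must be a steady current or a syn_kernel")
  }
  if (is.null(t)) stop("times t are required for a transient input")
  cap <- rep(c_m, n_comp)
  cap[1] <- cap[1] + 4 * pi * (params$rho * um)^2 * params$c * 1e-6
  s_half <- 1 / sqrt(cap)
  A <- G * outer(s_half, s_half) # symmetric C^{-1/2} G C^{-1/2}
  eig <- eigen(A, symmetric = TRUE)
  lam <- eig$values # decay rates (1/s)
  Q <- eig$vectors
  e_k <- rep(0, n_comp)
  e_k[k] <- 1
  amp <- drop(crossprod(Q, s_half * e_k)) # modal drive amplitudes
  tf <- input$tau_f
  ts <- input$tau_s
  conv_exp <- function(alpha, lambda, tt) {
    # integral_0^t e^{-alpha u} e^{-lambda (t - u)} du
    (exp(-alpha * tt) - exp(-lambda * tt)) / (lambda - alpha)
  }
  pref <- input$theta_syn * 1e-3 / (tf - ts)
  v <- vapply(t, function(tt) {
    y <- pref * amp * (conv_exp(1 / tf, lam, tt) - conv_exp(1 / ts, lam, tt))
    sum(s_half[1] * Q[1, ] * y)
  }, numeric(1))
  list(t = t, v = v)
}
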