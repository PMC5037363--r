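# Weakly nonlinear layer.
#
# Near the double-zero threshold the dispersion relation is approximated
# locally by a quadratic maximum at k0 tied to the Goldstone zero at k = 0,
#   Omega(k) ~ (k/k0)^2 [ mu * gap_rate - xi0^2 (k - k0)^2 ],
# with mu = (Lambda - Lambda0)/Lambda0 the relative gap. Galilean invariance
# (x -> x - v t, u -> u + v) fixes the only consistent quadratic nonlinearity
# of the interface-velocity deviation u, giving the front equation
#   du/dt = L u + 1/2 d(u^2)/dx,
# a Kuramoto-Sivashinsky-type equation whose unknown quadratic coefficient is
# absorbed into the scale of u.
#
# The multiscale expansion about threshold (pattern amplitude A at k0, real
# mean-velocity mode B at k ~ 0, X = eps x, T = eps^2 t, mu = eps^2) yields the
# coupled Turing-Hopf amplitude equations used here,
#   A_T = mu A + 4 A_XX - |A|^2 A + B (i A + A_X)
#   B_T = 37 B_XX + 36 d|A|^2/dX ,
# whose plane-wave stability problem reproduces exactly the coefficients
#   c1(q) = (41 + 144 q - 52 q^2)/(1 - 4 q^2),  c2(q) = -288 q (q + 1)
# of the long-wavelength growth-rate quadratic eta^2 + c1 p^2 eta + c2 p^2 = 0.
MEANFIELD_DIFFUSIVITY <- 37
MEANFIELD_COUPLING    <- 36

#' Local (quadratic) approximation of the dispersion relation near threshold
#'
#' @param k Wavenumber(s), in the same units as the threshold point.
#' @param mu Relative gap from threshold, `(Lambda - Lambda0)/Lambda0`.
#' @param threshold A [find_threshold()] object supplying `k0`, `xi0sq` and
#'   `gap_rate`.
#' @return The approximate growth rate; exactly 0 at `k = 0` (Goldstone) and
#'   `mu * gap_rate` at `k = k0`.
#' @export
linear_symbol <- function(k, mu, threshold) {
  stopifnot(inherits(threshold, "threshold_point"))
  k0 <- threshold$k0
  (k / k0)^2 * (mu * threshold$gap_rate - threshold$xi0sq * (k - k0)^2)
}

#' Periodic interface-velocity field
#'
#' Grid container for the front equation, in rescaled units where the selected
#' wavenumber k0 maps to 1 (the physical scale factor is kept in the object).
#'
#' @param n Number of grid points (a power of two).
#' @param n_periods Domain length in multiples of `2*pi` (rescaled units).
#' @param values Initial values (length `n`), or `NULL` for zeros.
#' @param k0 Physical selected wavenumber (scale factor; 1 by default).
#' @param t Initial time.
#' @return An object of class `"front_field"`.
#' @export
front_field <- function(n = 256, n_periods = 8, values = NULL, k0 = 1, t = 0) {
  if (bitwAnd(n, n - 1L) != 0L) stop("n must be a power of two", call. = FALSE)
  L <- 2 * pi * n_periods
  x <- seq(0, L, length.out = n + 1)[seq_len(n)]
  if (is.null(values)) values <- numeric(n)
  stopifnot(length(values) == n)
  structure(list(x = x, u = as.numeric(values), L = L, n = n,
                 n_periods = n_periods, k0 = k0, t = t),
            class = "front_field")
}

#' @export
print.front_field <- function(x, ...) {
  cat(sprintf("front_field: n = %d, L = %g (x%g periods), t = %g, k0 = %g\n",
              x$n, x$L, x$n_periods, x$t, x$k0))
  invisible(x)
}

# wavenumber layout of stats::fft for a real field on [0, L)
fft_wavenumbers <- function(n, L) {
  c(0:(n / 2), (-n / 2 + 1):(-1)) * (2 * pi / L)
}

# ETDRK4 coefficients for a diagonal linear symbol Lh = h * symbol, evaluated
# with the complex-contour mean to avoid cancellation at small |Lh|
etdrk4_coefs <- function(Lh) {
  M <- 32
  r <- exp(2i * pi * (seq_len(M) - 0.5) / M)
  LR <- outer(Lh, r, `+`)
  f <- function(expr) Re(rowMeans(expr))
  list(
    E  = exp(Lh), E2 = exp(Lh / 2),
    Q  = f((exp(LR / 2) - 1) / LR),
    f1 = f((-4 - LR + exp(LR) * (4 - 3 * LR + LR^2)) / LR^3),
    f2 = f((2 + LR + exp(LR) * (-2 + LR)) / LR^3),
    f3 = f((-4 - 3 * LR - LR^2 + exp(LR) * (4 - LR)) / LR^3))
}

#' Integrate the Galilean-invariant front equation
#'
#' Pseudo-spectral exponential time differencing (ETDRK4) integration of
#' `du/dt = L u + 1/2 d(u^2)/dx` on a periodic domain, with the Fourier
#' multiplier `L` given by [linear_symbol()] and 2/3-rule dealiasing of the
#' quadratic term. The spatial mean of `u` is conserved (the symbol vanishes at
#' k = 0 and the flux-form nonlinearity has zero mean).
#'
#' @param u0 A [front_field()] initial condition.
#' @param mu Relative gap from threshold.
#' @param threshold A [find_threshold()] object (scales of the symbol).
#' @param t_end Integration time.
#' @param dt Time step.
#' @param save_every Save a snapshot every this many steps (0: final only).
#' @param blowup Abort when `max|u|` exceeds this bound.
#' @return A list with `field` (final [front_field()]), and when snapshots are
#'   kept, `times` and `snapshots` (matrix, one row per saved time).
#' @export
evolve_front <- function(u0, mu, threshold, t_end, dt = 0.05, save_every = 0,
                         blowup = 1e6) {
  stopifnot(inherits(u0, "front_field"))
  n <- u0$n
  kk <- fft_wavenumbers(n, u0$L)          # rescaled wavenumbers, k0 -> 1
  sym <- linear_symbol(abs(kk) * u0$k0, mu, threshold)
  cf <- etdrk4_coefs(dt * sym)
  dealias <- abs(kk) <= (n / 3) * (2 * pi / u0$L)
  g <- 0.5i * kk * u0$k0                  # (1/2) d/dx in physical units
  Nl <- function(vh) {
    u <- Re(stats::fft(vh, inverse = TRUE)) / n
    g * stats::fft(u * u) * dealias
  }
  vh <- stats::fft(u0$u)
  nsteps <- max(1L, round(t_end / dt))
  keep <- save_every > 0
  times <- numeric(0); snaps <- NULL
  if (keep) {
    snaps <- matrix(NA_real_, nrow = floor(nsteps / save_every) + 1L, ncol = n)
    snaps[1, ] <- u0$u; times <- u0$t; ridx <- 1L
  }
  for (s in seq_len(nsteps)) {
    Nv <- Nl(vh)
    av <- cf$E2 * vh + cf$Q * dt * Nv;  Na <- Nl(av)
    bv <- cf$E2 * vh + cf$Q * dt * Na;  Nb <- Nl(bv)
    cv <- cf$E2 * av + cf$Q * dt * (2 * Nb - Nv); Nc <- Nl(cv)
    vh <- cf$E * vh + dt * (cf$f1 * Nv + 2 * cf$f2 * (Na + Nb) + cf$f3 * Nc)
    if (max(Mod(vh)) / n > blowup)
      stop(sprintf("front equation blow-up at t = %g (|u| > %g)",
                   u0$t + s * dt, blowup), call. = FALSE)
    if (keep && s %% save_every == 0) {
      ridx <- ridx + 1L
      snaps[ridx, ] <- Re(stats::fft(vh, inverse = TRUE)) / n
      times <- c(times, u0$t + s * dt)
    }
  }
  out <- front_field(n, u0$n_periods, Re(stats::fft(vh, inverse = TRUE)) / n,
                     k0 = u0$k0, t = u0$t + nsteps * dt)
  if (keep) list(field = out, times = times, snapshots = snaps[seq_along(times), , drop = FALSE])
  else list(field = out)
}

#' Amplitude state for the coupled Turing-Hopf equations
#'
#' @param A Complex pattern amplitude over the slow periodic grid X.
#' @param B Real mean-velocity shift field (same length).
#' @param mu Relative gap from threshold (> 0 in the weakly nonlinear regime).
#' @param n_periods Domain length in multiples of `2*pi` (slow variable X).
#' @param q Detuning bookkeeping value (`(k - k0)/k0` rescaled), optional.
#' @param T Slow time.
#' @return An object of class `"amplitude_state"`.
#' @export
amplitude_state <- function(A, B = NULL, mu = 1, n_periods = 1, q = NA_real_,
                            T = 0) {
  n <- length(A)
  if (bitwAnd(n, n - 1L) != 0L) stop("grid size must be a power of two", call. = FALSE)
  if (is.null(B)) B <- numeric(n)
  stopifnot(length(B) == n)
  L <- 2 * pi * n_periods
  X <- seq(0, L, length.out = n + 1)[seq_len(n)]
  structure(list(A = as.complex(A), B = as.numeric(B), X = X, L = L, n = n,
                 n_periods = n_periods, mu = mu, q = q, T = T),
            class = "amplitude_state")
}

#' Plane-wave amplitude of the Turing-Hopf system
#'
#' Steady solutions `A = A0 exp(i q X)`, `B = 0` exist for `q^2 < 1/4` with
#' `|A0| = sqrt(mu (1 - 4 q^2))` (detuning `q` measured in band-width units, so
#' the existence band is `|q| < 1/2` for every `mu > 0`).
#'
#' @param q Detuning.
#' @param mu Gap from threshold (> 0).
#' @return `|A0|`.
#' @export
steady_amplitude <- function(q, mu = 1) {
  if (mu <= 0) stop("steady patterns require mu > 0", call. = FALSE)
  if (any(q^2 >= 0.25))
    stop("no steady plane wave outside the band q^2 < 1/4", call. = FALSE)
  sqrt(mu * (1 - 4 * q^2))
}

#' Stability coefficients of the plane-wave solutions
#'
#' @param q Detuning (`q^2 < 1/4`).
#' @return Named vector `(c1, c2)` with
#'   `c1 = (41 + 144 q - 52 q^2)/(1 - 4 q^2)` and `c2 = -288 q (q + 1)`.
#' @export
stability_coefficients <- function(q) {
  if (any(abs(abs(q) - 0.5) < 1e-14))
    stop("c1 has a pole at q = +/- 1/2", call. = FALSE)
  c(c1 = (41 + 144 * q - 52 * q^2) / (1 - 4 * q^2),
    c2 = -288 * q * (q + 1))
}

#' Long-wavelength growth rates of plane-wave perturbations
#'
#' Perturbing `A = (A0 + r) e^{i(qX + phi)}`, `B = psi` with
#' `r, phi, psi ~ e^{eta T + i p X}` gives, after elimination of the fast
#' amplitude mode, the quadratic `eta^2 + c1 p^2 eta + c2 p^2 = 0`
#' (`method = "quadratic"`). `method = "matrix"` returns the two slow
#' eigenvalues of the full 3x3 linearization (exact at finite `p`; the
#' quadratic is its long-wavelength limit).
#'
#' @param q Detuning (`q^2 < 1/4`).
#' @param p Perturbation wavenumber (small).
#' @param method `"quadratic"` (closed-form coefficients) or `"matrix"`.
#' @return Complex vector of the two growth rates, ordered by decreasing real
#'   part.
#' @export
growth_roots <- function(q, p, method = c("quadratic", "matrix")) {
  method <- match.arg(method)
  if (method == "quadratic") {
    cc <- stability_coefficients(q)
    b <- cc[["c1"]] * p^2
    disc <- as.complex(b^2 - 4 * cc[["c2"]] * p^2)
    eta <- c((-b + sqrt(disc)) / 2, (-b - sqrt(disc)) / 2)
  } else {
    M <- plane_wave_jacobian(q, p)
    ev <- eigen(M, only.values = TRUE)$values
    eta <- ev[order(-Re(ev))][1:2]
  }
  eta[order(-Re(eta), -Im(eta))]
}

# exact 3x3 linearization of the amplitude equations about the plane wave
# (variables r, phi, psi; mu = 1 normalization)
plane_wave_jacobian <- function(q, p) {
  A0 <- sqrt(1 - 4 * q^2)
  at <- 1 + q
  matrix(c(-2 * A0^2 - 4 * p^2, -8i * q * A0 * p,              0,
            8i * q * p / A0,    -4 * p^2,                      at,
            2i * MEANFIELD_COUPLING * A0 * p, 0, -MEANFIELD_DIFFUSIVITY * p^2),
         3, 3, byrow = TRUE)
}

#' Hopf detuning of the plane-wave band
#'
#' The negative root of the numerator of `c1(q)`, `41 + 144 q - 52 q^2 = 0`,
#' inside the existence band: the left edge of the stable band, where the
#' complex perturbation pair crosses the imaginary axis.
#'
#' @return `q_h` (~ -0.260).
#' @export
#' @examples
#' hopf_point()
hopf_point <- function() {
  (144 - sqrt(144^2 + 4 * 52 * 41)) / (2 * 52)
}

#' Hopf oscillation frequency
#'
#' At `q = q_h` the growth-rate pair is purely imaginary with frequency
#' `omega_h * p`, linear in the perturbation wavenumber.
#'
#' @param p Perturbation wavenumber(s).
#' @return `omega_h * p`, with `omega_h = sqrt(c2(q_h))`.
#' @export
hopf_frequency <- function(p) {
  qh <- hopf_point()
  sqrt(stability_coefficients(qh)[["c2"]]) * p
}

#' Integrate the coupled Turing-Hopf amplitude equations
#'
#' Pseudo-spectral ETDRK4 for
#' `A_T = mu A + 4 A_XX - |A|^2 A + B (i A + A_X)`,
#' `B_T = 37 B_XX + 36 d|A|^2/dX`. A spatially homogeneous `A` forces no mean
#' flow, so `B = 0` is preserved exactly.
#'
#' @param state An [amplitude_state()].
#' @param T_end Slow-time horizon.
#' @param dT Time step.
#' @param save_every Snapshot cadence in steps (0: final only).
#' @param blowup Abort bound on `max(|A|, |B|)`.
#' @return List with `state` (final), and `times`, `A_snapshots`,
#'   `B_snapshots` when requested.
#' @export
evolve_amplitudes <- function(state, T_end, dT = 0.01, save_every = 0,
                              blowup = 1e6) {
  stopifnot(inherits(state, "amplitude_state"))
  n <- state$n
  kk <- fft_wavenumbers(n, state$L)
  mu <- state$mu
  symA <- mu - 4 * kk^2
  symB <- -MEANFIELD_DIFFUSIVITY * kk^2
  cfA <- etdrk4_coefs_complex(dT * symA)
  cfB <- etdrk4_coefs_complex(dT * symB)
  dealias <- abs(kk) <= (n / 3) * (2 * pi / state$L)
  ifft <- function(h) stats::fft(h, inverse = TRUE) / n
  Nl <- function(Ah, Bh) {
    A <- ifft(Ah); B <- Re(ifft(Bh))
    AX <- ifft(1i * kk * Ah)
    NA_ <- stats::fft(-Mod(A)^2 * A + B * (1i * A + AX)) * dealias
    NB_ <- (1i * kk * MEANFIELD_COUPLING) * stats::fft(Mod(A)^2) * dealias
    list(A = NA_, B = NB_)
  }
  Ah <- stats::fft(state$A); Bh <- stats::fft(as.complex(state$B))
  nsteps <- max(1L, round(T_end / dT))
  keep <- save_every > 0
  times <- numeric(0); Asn <- NULL; Bsn <- NULL
  if (keep) {
    m <- floor(nsteps / save_every) + 1L
    Asn <- matrix(NA_complex_, m, n); Bsn <- matrix(NA_real_, m, n)
    Asn[1, ] <- state$A; Bsn[1, ] <- state$B; times <- state$T; ridx <- 1L
  }
  step1 <- function(cf, vh, Nv, Na, Nb, Nc)
    cf$E * vh + dT * (cf$f1 * Nv + 2 * cf$f2 * (Na + Nb) + cf$f3 * Nc)
  for (s in seq_len(nsteps)) {
    Nv <- Nl(Ah, Bh)
    aA <- cfA$E2 * Ah + cfA$Q * dT * Nv$A
    aB <- cfB$E2 * Bh + cfB$Q * dT * Nv$B
    Na <- Nl(aA, aB)
    bA <- cfA$E2 * Ah + cfA$Q * dT * Na$A
    bB <- cfB$E2 * Bh + cfB$Q * dT * Na$B
    Nb <- Nl(bA, bB)
    cA <- cfA$E2 * aA + cfA$Q * dT * (2 * Nb$A - Nv$A)
    cB <- cfB$E2 * aB + cfB$Q * dT * (2 * Nb$B - Nv$B)
    Nc <- Nl(cA, cB)
    Ah <- step1(cfA, Ah, Nv$A, Na$A, Nb$A, Nc$A)
    Bh <- step1(cfB, Bh, Nv$B, Na$B, Nb$B, Nc$B)
    if (max(Mod(Ah), Mod(Bh)) / n > blowup)
      stop(sprintf("amplitude equations blow-up at T = %g", state$T + s * dT),
           call. = FALSE)
    if (keep && s %% save_every == 0) {
      ridx <- ridx + 1L
      Asn[ridx, ] <- ifft(Ah); Bsn[ridx, ] <- Re(ifft(Bh))
      times <- c(times, state$T + s * dT)
    }
  }
  fin <- amplitude_state(ifft(Ah), Re(ifft(Bh)), mu = mu,
                         n_periods = state$n_periods, q = state$q,
                         T = state$T + nsteps * dT)
  if (keep) list(state = fin, times = times,
                 A_snapshots = Asn[seq_along(times), , drop = FALSE],
                 B_snapshots = Bsn[seq_along(times), , drop = FALSE])
  else list(state = fin)
}

# complex-symbol variant of the ETDRK4 tables (A-equation symbol is real here,
# but keep complex arithmetic throughout; no Re() projection)
etdrk4_coefs_complex <- function(Lh) {
  M <- 32
  r <- exp(2i * pi * (seq_len(M) - 0.5) / M)
  LR <- outer(as.complex(Lh), r, `+`)
  f <- function(expr) rowMeans(expr)
  list(
    E  = exp(Lh), E2 = exp(Lh / 2),
    Q  = f((exp(LR / 2) - 1) / LR),
    f1 = f((-4 - LR + exp(LR) * (4 - 3 * LR + LR^2)) / LR^3),
    f2 = f((2 + LR + exp(LR) * (-2 + LR)) / LR^3),
    f3 = f((-4 - 3 * LR - LR^2 + exp(LR) * (4 - LR)) / LR^3))
}

#' Reconstruct the interface from amplitude fields
#'
#' Maps `(A, B)` back through the decomposition
#' `u(x) = 2 sqrt(mu) Re(A(X) e^{i k0 x}) + mu B(X)` (rescaled units,
#' `X = sqrt(mu) x`), advances the interface by `zeta_t = u + U0`, and reports
#' the spatial-mean velocity.
#'
#' @param state An [amplitude_state()].
#' @param threshold A [find_threshold()] object (sets `k0`).
#' @param U0 Base front speed.
#' @param t Fast-time value(s) at which to evaluate the profile.
#' @param n_fast Fast-grid resolution per slow grid point.
#' @return List with `x`, `u` (velocity deviation profile at `t[1]`),
#'   `zeta` (interface profile, matrix over `t`), `mean_velocity` (vector over
#'   `t`).
#' @export
reconstruct_interface <- function(state, threshold, U0, t = 0, n_fast = 16) {
  stopifnot(inherits(state, "amplitude_state"),
            inherits(threshold, "threshold_point"))
  mu <- max(state$mu, .Machine$double.eps)
  eps <- sqrt(mu)
  k0 <- threshold$k0
  # fast grid spanning the slow domain: x = X / eps
  nx <- state$n * n_fast
  x <- seq(0, state$L / eps, length.out = nx + 1)[seq_len(nx)]
  idx <- pmin(state$n, 1 + floor(state$n * (x * eps) / state$L))
  Af <- state$A[idx]; Bf <- state$B[idx]
  u <- 2 * eps * Re(Af * exp(1i * k0 * x)) + mu * Bf
  mean_u <- mean(u)
  zeta <- vapply(t, function(tt) (U0 + u) * tt, numeric(nx))
  list(x = x, u = u, zeta = t(zeta),
       mean_velocity = rep(U0 + mean_u, length(t)))
}
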