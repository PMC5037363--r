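# Independent numerical oracles used by the tests. These deliberately avoid
# the package's closed-form solution path: the steady front is re-solved by
# finite differences, and perturbation growth rates are re-measured by time
# integration of the discretized linearized free-boundary system.

# Thomas algorithm for a tridiagonal system (lower, diag, upper, rhs)
tridiag_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- c[1] / b[1]; dp[1] <- d[1] / b[1]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1]
    cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i] * dp[i - 1]) / m
  }
  x <- numeric(n); x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# Finite-difference residual of the steady free-boundary problem at trial
# front speed U: solves the morphogen two-sided problem with the jump and
# flux conditions, then the pressure balance, and returns U + P'(0) (zero at
# the true travelling-wave speed).
fd_steady_residual <- function(U, Lambda, alpha, P_i, N0, refine = 1) {
  r_e_true <- (-U + sqrt(U^2 + 4)) / 2
  Le <- 25 / min(r_e_true, max(alpha, 0.2))
  Lw <- 25 / max(U, 1)
  ne <- 4096L * refine
  nw <- ceiling(Lw * 4096 / Le) * refine   # same grids at every refinement
  h <- Le / ne
  # epithelium solve with Dirichlet C(-Le) = 0, C(0) = ce0 (parameterized)
  solve_e <- function(ce0) {
    n <- ne - 1                      # interior nodes
    a <- rep(1 / h^2 - U / (2 * h), n)
    b <- rep(-2 / h^2 - 1, n)
    cc <- rep(1 / h^2 + U / (2 * h), n)
    d <- rep(0, n)
    d[n] <- d[n] - cc[n] * ce0
    c(0, tridiag_solve(a, b, cc, d), ce0)
  }
  solve_w <- function(cw0) {
    n <- nw - 1
    a <- rep(1 / h^2 - U / (2 * h), n)
    b <- rep(-2 / h^2, n)
    cc <- rep(1 / h^2 + U / (2 * h), n)
    d <- rep(0, n)
    d[1] <- d[1] - a[1] * cw0
    c(cw0, tridiag_solve(a, b, cc, d), 0)
  }
  d_iface_e <- function(v) (3 * v[length(v)] - 4 * v[length(v) - 1] +
                              v[length(v) - 2]) / (2 * h)
  d_iface_w <- function(v) (-3 * v[1] + 4 * v[2] - v[3]) / (2 * h)
  # flux(ce0) is affine: flux jump must equal N0 * U
  flux_of <- function(ce0) {
    Ce <- solve_e(ce0); Cw <- solve_w(ce0 - 1)   # jump condition C_e - C_w = 1
    d_iface_e(Ce) - d_iface_w(Cw)
  }
  f0 <- flux_of(0); f1 <- flux_of(1)
  ce0 <- (N0 * U - f0) / (f1 - f0)
  Ce <- solve_e(ce0)
  # pressure: P'' = alpha^2 P - Lambda C_e'' with P(-Le) = 0, P(0) = P_i
  Cpp <- (Ce[3:(ne + 1)] - 2 * Ce[2:ne] + Ce[1:(ne - 1)]) / h^2
  n <- ne - 1
  a <- rep(1 / h^2, n); b <- rep(-2 / h^2 - alpha^2, n); cc <- rep(1 / h^2, n)
  d <- -Lambda * Cpp
  d[n] <- d[n] - cc[n] * P_i
  P <- c(0, tridiag_solve(a, b, cc, d), P_i)
  U + (3 * P[ne + 1] - 4 * P[ne] + P[ne - 1]) / (2 * h)
}

# Richardson-extrapolated residual and root in U
oracle_steady_velocity <- function(Lambda, alpha, P_i, N0, bracket) {
  # three-level Richardson: the one-sided interface derivatives leave a
  # third-order error term alongside the second-order bulk error
  res <- function(U) {
    r1 <- fd_steady_residual(U, Lambda, alpha, P_i, N0, refine = 1L)
    r2 <- fd_steady_residual(U, Lambda, alpha, P_i, N0, refine = 2L)
    r4 <- fd_steady_residual(U, Lambda, alpha, P_i, N0, refine = 4L)
    e12 <- (4 * r2 - r1) / 3
    e24 <- (4 * r4 - r2) / 3
    (8 * e24 - e12) / 7
  }
  stats::uniroot(res, bracket, tol = 1e-10)$root
}

# Growth rate of a single transverse Fourier mode from an independent
# finite-difference discretization of the linearized free-boundary system
# (state x = (c_e interior, c_w interior, zeta)). The pressure balance is
# solved with a fourth-order Numerov scheme, interface derivatives use
# fourth-order one-sided stencils, and the steep water-side boundary layer
# (decay rate ~ l_w >= U) gets its own fine grid. The jump-condition algebra
# also carries a fast non-physical branch, so the physical rate is identified
# as the eigenvalue near `target`, which must be isolated from all others by
# a factor `sep`; closeness to the package value is only asserted afterwards
# by the test.
oracle_mode_growth <- function(k, Lambda, U, alpha = 1, N0 = 1, sigma = 1e-3,
                               L = 16, h = 0.02, Lw = 4, hw = h / 5,
                               target = 0, sep = 5) {
  r_e <- (-U + sqrt(U^2 + 4)) / 2
  C0 <- r_e * U * (1 + N0); Cw0 <- C0 - 1
  P_i <- (Lambda * (1 + N0) * r_e^3 * U / (alpha + r_e) - U) / alpha
  G2 <- Lambda * C0 * r_e^2 / (alpha^2 - r_e^2); A <- P_i - G2
  dP0 <- alpha * A + r_e * G2; d2P0 <- alpha^2 * A + r_e^2 * G2
  n <- ceiling(L / h); ne <- n - 1
  nwn <- ceiling(Lw / hw); nw <- nwn - 1
  m2 <- k^2 + alpha^2
  dR5 <- function(v) (25 * v[n + 1] - 48 * v[n] + 36 * v[n - 1] -
                        16 * v[n - 2] + 3 * v[n - 3]) / (12 * h)
  numerov <- function(s_full, w0) {
    aa <- rep(1 / h^2 - m2 / 12, ne); bb <- rep(-2 / h^2 - 10 * m2 / 12, ne)
    d <- (s_full[3:(n + 1)] + 10 * s_full[2:n] + s_full[1:(n - 1)]) / 12
    d[ne] <- d[ne] - aa[ne] * w0
    c(0, tridiag_solve(aa, bb, aa, d), w0)
  }
  rhs <- function(x) {
    ce <- x[1:ne]; cw <- x[ne + (1:nw)]; zeta <- x[ne + nw + 1]
    dEof <- function(ce0) (25 * ce0 - 48 * ce[ne] + 36 * ce[ne - 1] -
                             16 * ce[ne - 2] + 3 * ce[ne - 3]) / (12 * h)
    dWof <- function(cw0) (-25 * cw0 + 48 * cw[1] - 36 * cw[2] +
                             16 * cw[3] - 3 * cw[4]) / (12 * hw)
    pprime <- function(ce0) {
      s_full <- -alpha^2 * Lambda * c(0, ce, ce0)
      w <- numerov(s_full, sigma * k^2 * zeta - dP0 * zeta + Lambda * ce0)
      dR5(w) - Lambda * dEof(ce0)
    }
    da <- pprime(0); db <- pprime(1) - da
    dEb <- 25 / (12 * h); dWb <- -25 / (12 * hw)
    dEa <- dEof(0); dWa <- dWof(N0 * U * zeta)
    lhs_b <- dEb - dWb + N0 * db
    lhs_a <- dEa - dWa + N0 * (d2P0 * zeta + da) +
      (r_e^2 * C0 - U^2 * Cw0) * zeta
    ce0 <- -lhs_a / lhs_b; cw0 <- ce0 + N0 * U * zeta
    zdot <- -d2P0 * zeta - da - db * ce0
    cfull_e <- c(0, ce, ce0); cfull_w <- c(cw0, cw, 0)
    lapg <- function(v, hh, nn) (v[3:(nn + 1)] - 2 * v[2:nn] +
                                   v[1:(nn - 1)]) / hh^2
    grdg <- function(v, hh, nn) (v[3:(nn + 1)] - v[1:(nn - 1)]) / (2 * hh)
    c(lapg(cfull_e, h, n) + U * grdg(cfull_e, h, n) - (1 + k^2) * ce,
      lapg(cfull_w, hw, nwn) + U * grdg(cfull_w, hw, nwn) - k^2 * cw, zdot)
  }
  nx <- ne + nw + 1
  M <- matrix(0, nx, nx)
  for (j in seq_len(nx)) {
    e <- numeric(nx); e[j] <- 1
    M[, j] <- rhs(e)
  }
  ev <- eigen(M, only.values = TRUE)$values
  ev <- ev[abs(Im(ev)) < 1e-8]
  d <- abs(Re(ev) - target)
  o <- order(d)
  stopifnot(d[o[2]] > sep * max(d[o[1]], 1e-3))   # isolation of the branch
  Re(ev[o[1]])
}

# Numerically linearized propagator of evolve_amplitudes about the plane wave
# A0 e^{iqX}, B = 0, restricted to the (cos pX, sin pX) block of (r, phi, psi).
# Returns the two slowest eigenvalues.
linearized_amplitude_roots <- function(q, p, hT = 0.02, eps = 1e-6,
                                       n = 128, n_periods = round(1 / p)) {
  # both the carrier detuning q and the sideband p must fit the domain
  stopifnot(abs(n_periods * p - round(n_periods * p)) < 1e-9,
            abs(n_periods * q - round(n_periods * q)) < 1e-9)
  L <- 2 * pi * n_periods
  X <- seq(0, L, length.out = n + 1)[seq_len(n)]
  A0 <- chemofront::steady_amplitude(q, 1)
  base_A <- A0 * exp(1i * q * X)
  mk_state <- function(z) {
    r <- z[1] * cos(p * X) + z[2] * sin(p * X)
    ph <- z[3] * cos(p * X) + z[4] * sin(p * X)
    ps <- z[5] * cos(p * X) + z[6] * sin(p * X)
    chemofront::amplitude_state((A0 + r) * exp(1i * (q * X + ph)), ps,
                                mu = 1, n_periods = n_periods, q = q)
  }
  project <- function(st) {
    w <- st$A * exp(-1i * q * X)
    r <- Mod(w) - A0; ph <- Arg(w); ps <- st$B
    cfit <- function(v) c(2 * mean(v * cos(p * X)), 2 * mean(v * sin(p * X)))
    c(cfit(r), cfit(ph), cfit(ps))
  }
  prop <- function(z) {
    st <- mk_state(z)
    out <- chemofront::evolve_amplitudes(st, T_end = hT, dT = hT / 4)
    project(out$state)
  }
  P <- matrix(0, 6, 6)
  for (j in 1:6) {
    e <- numeric(6); e[j] <- eps
    P[, j] <- prop(e) / eps
  }
  ev <- eigen(P, only.values = TRUE)$values
  eta <- log(ev) / hT
  eta[order(-Re(eta))][1:2]
}
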