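ref_threshold <- function() {
  # cached threshold at the reference speed for symbol-based tests
  if (is.null(.GlobalEnv$.chemofront_tp7))
    assign(".chemofront_tp7", find_threshold(7), envir = .GlobalEnv)
  get(".chemofront_tp7", envir = .GlobalEnv)
}

test_that("local dispersion approximation pins the threshold structure", {
  tp <- ref_threshold()
  expect_equal(linear_symbol(tp$k0, 0, tp), 0)
  expect_equal(linear_symbol(0, 0.3, tp), 0)        # Goldstone constraint
  expect_equal(linear_symbol(tp$k0, 0.05, tp), 0.05 * tp$gap_rate)
  # symmetric negative quadratic maximum at mu = 0
  d <- 0.05
  sp <- linear_symbol(tp$k0 + d, 0, tp); sm <- linear_symbol(tp$k0 - d, 0, tp)
  expect_lt(sp, 0); expect_lt(sm, 0)
  expect_lt(abs(sp - sm), 0.1 * abs(sp))
  # matches the full dispersion relation near threshold
  for (d in c(-0.3, 0.15, 0.3)) {
    full <- growth_rate(tp$k0 + d, tp$Lambda0, 7)
    loc <- linear_symbol(tp$k0 + d, 0, tp)
    expect_lt(abs(full - loc), 0.15 * abs(full) + 1e-4)
  }
  # gap normalization matches a true change of Lambda
  mu <- 0.02
  full <- growth_rate(tp$k0, tp$Lambda0 * (1 + mu), 7)
  expect_equal(linear_symbol(tp$k0, mu, tp), full, tolerance = 0.05)
})

test_that("front equation damps below threshold and grows at the selected mode", {
  tp <- ref_threshold()
  set.seed(11)
  u0 <- front_field(128, 8, values = 1e-3 * rnorm(128), k0 = tp$k0)
  out <- evolve_front(u0, mu = -0.1, tp, t_end = 2, dt = 0.02)
  expect_lt(max(abs(out$field$u)), max(abs(u0$u)))
  # seeded k0 mode grows at the rate of the linear symbol (1% on the log fit)
  x <- front_field(256, 8)$x
  useed <- front_field(256, 8, values = 1e-6 * cos(x), k0 = tp$k0)
  mu <- 0.1
  tr <- evolve_front(useed, mu, tp, t_end = 1.5, dt = 0.01, save_every = 15)
  amp <- apply(tr$snapshots, 1, function(u) Mod(stats::fft(u))[8 + 1])
  fit <- stats::coef(stats::lm(log(amp) ~ tr$times))[2]
  expect_equal(unname(fit), mu * tp$gap_rate, tolerance = 0.01)
})

test_that("front equation is Galilean equivariant and conserves the mean", {
  tp <- ref_threshold()
  set.seed(7)
  n <- 128; nper <- 4
  u0v <- 0.05 * rnorm(n)
  u1 <- front_field(n, nper, values = u0v, k0 = tp$k0)
  v <- 0.3; dt <- 0.01; nsteps <- 100
  t_end <- dt * nsteps
  a <- evolve_front(u1, 0.05, tp, t_end, dt)
  u2 <- front_field(n, nper, values = u0v + v, k0 = tp$k0)
  b <- evolve_front(u2, 0.05, tp, t_end, dt)
  # boosted solution equals the shifted unboosted one plus v:
  # u2(x, t) = u1(x + v t, t) + v, shift applied spectrally (x is rescaled, so
  # the shift is k0 * v * t)
  kk <- c(0:(n / 2), (-n / 2 + 1):(-1)) * (2 * pi / (2 * pi * nper))
  shifted <- Re(stats::fft(stats::fft(a$field$u) *
                             exp(1i * kk * tp$k0 * v * t_end),
                           inverse = TRUE)) / n
  expect_lt(max(abs(b$field$u - (shifted + v))), 1e-6)
  # spatial mean is conserved (zero-mean nonlinearity, symbol(0) = 0)
  expect_equal(mean(a$field$u), mean(u0v), tolerance = 1e-10)
  expect_equal(mean(b$field$u), mean(u0v) + v, tolerance = 1e-10)
})

test_that("plane-wave amplitudes exist only inside the band", {
  expect_error(steady_amplitude(0.5, 1), "band")
  expect_error(steady_amplitude(-0.6, 1), "band")
  expect_error(steady_amplitude(0.1, -0.5), "mu")
  qs <- seq(-0.45, 0.45, by = 0.15)
  amps <- vapply(qs, steady_amplitude, numeric(1), mu = 1)
  expect_equal(max(amps), steady_amplitude(0, 1))     # maximal at q = 0
  expect_equal(steady_amplitude(0.4999, 1), 0, tolerance = 0.03)
  expect_equal(steady_amplitude(0.2, 0.3), sqrt(0.3 * (1 - 4 * 0.04)))
  # the plane wave is an exact steady state of the amplitude equations
  # (the detuning must be representable on the periodic domain: q * 20 = -3)
  q <- -0.15; n <- 128; n_periods <- 20
  X <- seq(0, 2 * pi * n_periods, length.out = n + 1)[seq_len(n)]
  st <- amplitude_state(steady_amplitude(q, 1) * exp(1i * q * X), q = q,
                        n_periods = n_periods)
  out <- evolve_amplitudes(st, T_end = 2, dT = 0.01)
  expect_lt(max(Mod(out$state$A - st$A)), 1e-8)
  expect_lt(max(abs(out$state$B)), 1e-8)
})

test_that("homogeneous amplitudes never force the mean-velocity mode", {
  st <- amplitude_state(rep(0.3 + 0.1i, 64))
  out <- evolve_amplitudes(st, T_end = 6, dT = 0.01)
  expect_lt(max(abs(out$state$B)), 1e-12)
  expect_equal(Mod(out$state$A[1]), 1, tolerance = 1e-3)  # saturates at sqrt(mu)
})

test_that("stability coefficients match their closed forms", {
  cc <- stability_coefficients(0)
  expect_equal(cc[["c1"]], 41)
  expect_equal(cc[["c2"]], 0)
  expect_equal(stability_coefficients(-1)[["c2"]], 0)   # root of -288 q (q+1)
  expect_error(stability_coefficients(0.5), "pole")
  qh <- hopf_point()
  expect_lt(abs(stability_coefficients(qh)[["c1"]]), 1e-10)
})

test_that("the Hopf detuning is the admissible root of the c1 numerator", {
  qh <- hopf_point()
  expect_equal(qh, -0.260, tolerance = 2e-3)
  expect_lt(abs(41 + 144 * qh - 52 * qh^2), 1e-10)
  other <- (144 + sqrt(144^2 + 4 * 52 * 41)) / (2 * 52)
  expect_equal(other, 3.029, tolerance = 1e-3)
  expect_gt(other^2, 0.25)       # outside the existence band, discarded
})

test_that("growth roots reproduce the three plane-wave regimes", {
  p <- 0.1
  # q > 0: real pair of opposite signs -> exponential growth (forbidden band)
  eta <- growth_roots(0.1, p)
  expect_true(all(abs(Im(eta)) < 1e-12))
  expect_gt(Re(eta[1]), 0); expect_lt(Re(eta[2]), 0)
  # q_h < q < 0: damped oscillation
  eta <- growth_roots(-0.1, p)
  expect_true(all(Re(eta) < 0))
  expect_gt(abs(Im(eta[1])), 0)
  expect_equal(eta[1], Conj(eta[2]))
  # q = q_h: purely imaginary pair at frequency omega_h p
  eta <- growth_roots(hopf_point(), p)
  expect_lt(max(abs(Re(eta))), 1e-10)
  expect_equal(abs(Im(eta[1])), hopf_frequency(p), tolerance = 1e-10)
  # q < q_h: oscillatory growth
  eta <- growth_roots(-0.35, p)
  expect_gt(Re(eta[1]), 0)
  expect_gt(abs(Im(eta[1])), 0)
})

test_that("hopf frequency is linear in the perturbation wavenumber", {
  expect_equal(hopf_frequency(0), 0)
  expect_equal(hopf_frequency(0.2) / hopf_frequency(0.1), 2, tolerance = 1e-6)
  # consistent with the full matrix linearization at small p
  eta <- growth_roots(hopf_point(), 0.05, method = "matrix")
  expect_equal(abs(Im(eta[1])), hopf_frequency(0.05), tolerance = 0.05)
})

test_that("quadratic and matrix growth roots agree in the long-wavelength limit", {
  for (q in c(-0.2, -0.1, 0.1)) {
    e1 <- sort(Re(growth_roots(q, 0.02)))
    e2 <- sort(Re(growth_roots(q, 0.02, method = "matrix")))
    expect_equal(e1[2], e2[2], tolerance = 0.02)
    i1 <- sort(abs(Im(growth_roots(q, 0.02))))
    i2 <- sort(abs(Im(growth_roots(q, 0.02, method = "matrix"))))
    expect_lt(max(abs(i1 - i2)), 0.01)
  }
})

test_that("the linearized integrator matches the matrix growth roots", {
  # detunings representable on the chosen domains (q * n_periods integer)
  for (cfg in list(c(q = -0.1, p = 0.1, np = 10),
                   c(q = -0.26, p = 0.1, np = 50))) {
    eta_m <- growth_roots(cfg[["q"]], cfg[["p"]], method = "matrix")
    eta_i <- linearized_amplitude_roots(cfg[["q"]], cfg[["p"]],
                                        n_periods = cfg[["np"]])
    m <- sort(Re(eta_m)); i <- sort(Re(eta_i))
    expect_lt(max(abs(m - i)), 1e-4)
    expect_lt(max(abs(sort(abs(Im(eta_m))) - sort(abs(Im(eta_i))))), 1e-4)
  }
})

test_that("interface reconstruction maps amplitudes to front shapes", {
  tp <- ref_threshold()
  n <- 64
  X <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  # flat state advances at U0
  flat <- amplitude_state(rep(0, n), mu = 0.04)
  rc <- reconstruct_interface(flat, tp, U0 = 7, t = c(0, 1))
  expect_equal(unique(round(rc$u, 12)), 0)
  expect_equal(rc$mean_velocity, c(7, 7))
  # plane wave: static undulation near k0
  q <- -0.1
  pw <- amplitude_state(steady_amplitude(q, 1) * exp(1i * q * X), mu = 0.04,
                        q = q)
  rc <- reconstruct_interface(pw, tp, U0 = 7)
  sp <- Mod(stats::fft(rc$u))
  kgrid <- (seq_along(rc$x) - 1) * 2 * pi / max(rc$x + rc$x[2])
  kpk <- kgrid[which.max(sp[2:(length(sp) / 2)]) + 1]
  expect_equal(kpk, tp$k0, tolerance = 0.1)
  expect_equal(rc$mean_velocity[1], 7, tolerance = 0.01)
})

test_that("perturbed Hopf-point pattern oscillates at the Hopf frequency", {
  # plane wave near q_h with a small sideband p: the mean-velocity field
  # oscillates; frequency approaches omega_h * p in the long-wavelength limit
  p <- 0.1; n_periods <- 50; n <- 512
  q <- -0.26                       # q * n_periods = -13, representable
  L <- 2 * pi * n_periods
  X <- seq(0, L, length.out = n + 1)[seq_len(n)]
  A <- steady_amplitude(q, 1) * exp(1i * q * X) * (1 + 1e-2 * cos(p * X))
  st <- amplitude_state(A, mu = 1, n_periods = n_periods, q = q)
  out <- evolve_amplitudes(st, T_end = 120, dT = 0.02, save_every = 20)
  psi <- vapply(seq_along(out$times), function(i)
    2 * mean(out$B_snapshots[i, ] * cos(p * X)), numeric(1))
  m <- length(psi)
  w <- Mod(stats::fft(psi - mean(psi)))[2:(m %/% 2)]
  freqs <- 2 * pi * (1:(m %/% 2 - 1)) / (out$times[m] - out$times[1])
  fpk <- freqs[which.max(w)]
  # matches the finite-p linearization, and the omega_h p law to ~12%
  eta_m <- growth_roots(q, p, method = "matrix")
  expect_equal(fpk, abs(Im(eta_m[1])), tolerance = 0.1)
  expect_equal(fpk, hopf_frequency(p), tolerance = 0.15)
})
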