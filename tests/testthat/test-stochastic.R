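tp7 <- function() {
  if (is.null(.GlobalEnv$.chemofront_tp7))
    assign(".chemofront_tp7", find_threshold(7), envir = .GlobalEnv)
  get(".chemofront_tp7", envir = .GlobalEnv)
}

test_that("relaxation rate is positive below threshold with minimum at k0", {
  tp <- tp7()
  lg <- seq(0.2, 10, by = 0.2)
  for (mu in c(-0.05, -0.2)) {
    G <- relaxation_rate(lg, mu, tp)
    expect_true(all(G > 0))
    expect_equal(lg[which.min(G)], lg[which.min(abs(lg - tp$k0))])
  }
  # vanishes at k0 as mu -> 0-
  expect_equal(relaxation_rate(tp$k0, -1e-9, tp), 0, tolerance = 1e-6)
  # symmetric quadratic around k0
  expect_equal(relaxation_rate(tp$k0 + 0.5, -0.1, tp),
               relaxation_rate(tp$k0 - 0.5, -0.1, tp))
  expect_warning(relaxation_rate(5, 0.1, tp), "mu")
})

test_that("langevin modes follow the exact Ornstein-Uhlenbeck law", {
  # noise-free: pure exponential decay
  ens <- langevin_mode(Gamma = 0.8, C0 = 0, t_end = 5, dt = 0.1, zeta0 = 2)
  expect_equal(ens$zeta[1, ], 2 * exp(-0.8 * ens$t), tolerance = 1e-12)
  # determinism: same seed gives bit-identical trajectories
  e1 <- langevin_mode(1, 0.05, 10, 0.1, n_realizations = 3, seed = 42)
  e2 <- langevin_mode(1, 0.05, 10, 0.1, n_realizations = 3, seed = 42)
  expect_identical(e1$zeta, e2$zeta)
  # stationary variance C0/(2 Gamma) within 3 MC standard errors, 3x3 grid
  for (G in c(0.5, 1, 2)) for (C0 in c(0.01, 0.05, 0.2)) {
    ens <- langevin_mode(G, C0, t_end = 60 / G, dt = 0.25 / G,
                         n_realizations = 200, seed = 1000 + round(100 * G * C0))
    i0 <- floor(length(ens$t) / 2)
    vr <- rowMeans(ens$zeta[, i0:length(ens$t)]^2)
    se <- stats::sd(vr) / sqrt(length(vr))
    expect_lt(abs(mean(vr) - C0 / (2 * G)), 3 * se + 0.02 * C0 / (2 * G))
  }
})

test_that("autocorrelation decays at the relaxation rate from the variance", {
  ens <- langevin_mode(1, 0.1, 100, 0.2, n_realizations = 300, seed = 5)
  ac <- autocorrelation(ens, max_lag = 15)
  expect_equal(ac$sigma_zeta[1], 0.05, tolerance = 0.15)  # S = C0/(2 Gamma)
  fit <- stats::coef(stats::lm(log(ac$sigma_zeta[1:8]) ~ ac$tau[1:8]))[2]
  expect_equal(unname(fit), -1, tolerance = 0.2)
  # decays towards zero at large lags
  expect_lt(abs(ac$sigma_zeta[nrow(ac)]), abs(ac$sigma_zeta[1]) / 2)
})

test_that("analytic structure function peaks at k0 and diverges at threshold", {
  tp <- tp7()
  ns <- noise_spec(C0 = 0.01, seed = 3)
  lg <- seq(tp$k0 - 3, tp$k0 + 3, by = 0.25)
  sa1 <- structure_function_analytic(lg, -0.1, ns, tp)
  expect_equal(sa1$lambda[which.max(sa1$S)], tp$k0, tolerance = 0.13)
  expect_true(all(sa1$S >= 0))
  # closer to threshold the peak grows
  sa2 <- structure_function_analytic(lg, -0.02, ns, tp)
  expect_gt(max(sa2$S), max(sa1$S))
  # 1/|mu| divergence of the peak: slope -1 on log-log
  mus <- -c(0.2, 0.1, 0.05, 0.025, 0.0125)
  Sk0 <- vapply(mus, function(m)
    structure_function_analytic(tp$k0, m, ns, tp)$S, numeric(1))
  sl <- stats::coef(stats::lm(log(Sk0) ~ log(abs(mus))))[2]
  expect_equal(unname(sl), -1, tolerance = 1e-10)
  expect_error(structure_function_analytic(lg, 0.1, ns, tp), "mu")
})

test_that("empirical structure function converges to the analytic one", {
  tp <- tp7()
  ns <- noise_spec(C0 = 0.02, seed = 11)
  lg <- seq(tp$k0 - 2, tp$k0 + 2, by = 0.5)
  sa <- structure_function_analytic(lg, -0.1, ns, tp)
  se <- structure_function_empirical(lg, -0.1, ns, tp, n_realizations = 64)
  expect_true(all(abs(se$S - sa$S) < 3 * se$stderr + 0.03 * sa$S))
  # zero noise gives an identically zero structure function
  s0 <- structure_function_empirical(lg, -0.1, noise_spec(C0 = 0), tp)
  expect_true(all(s0$S == 0))
  # doubling the intensity doubles the variance (exact for matched seeds)
  s1 <- structure_function_empirical(lg, -0.1, noise_spec(C0 = 0.02, seed = 9), tp,
                                     n_realizations = 16)
  s2 <- structure_function_empirical(lg, -0.1, noise_spec(C0 = 0.04, seed = 9), tp,
                                     n_realizations = 16)
  expect_equal(s2$S, 2 * s1$S, tolerance = 1e-12)
})

test_that("multiplicative sensitivities match the operating-point linearization", {
  mp <- model_params(Lambda = 7.65, alpha = 1, N0 = 1)
  s <- multiplicative_sensitivities(mp, 7)
  expect_equal(s[["s4"]], 0.5)
  expect_equal(s[["s5"]], 2 / 7.65, tolerance = 1e-12)
  # off the steady branch: rejected
  mp_off <- model_params(Lambda = 7.65, alpha = 1, N0 = 1, P_i = -6.76)
  expect_error(multiplicative_sensitivities(mp_off, 12), "off the steady branch")
  # on-branch with P_i supplied: accepted
  U <- front_velocity(7.65, 1, -6.76)
  expect_silent(multiplicative_sensitivities(mp_off, U))
  # no chemotactic coupling: no multiplicative channel
  expect_error(multiplicative_sensitivities(model_params(Lambda = 0), 2),
               "Lambda")
})

test_that("boundary-noise mapping produces finite transfer coefficients", {
  mp <- model_params(Lambda = 7.65, alpha = 1, N0 = 1)
  nm <- noise_mapping(mp, 7, k = 5)
  expect_true(all(is.finite(c(nm$E3, nm$E4, nm$E5, nm$X0))))
  expect_gt(nm$r_ep, 0); expect_gt(nm$r_wp, 0)
  # quasi-static rates reduce to the steady decay rates at k = 0
  nm0 <- noise_mapping(mp, 7, k = 1e-8)
  expect_equal(nm0$r_ep, nm0$r_0, tolerance = 1e-6)
  expect_equal(nm0$r_wp, 7, tolerance = 1e-6)
  # production-rate noise destabilizes (positive transfer onto the interface)
  expect_true(abs(nm$E4) > 0 && abs(nm$E5) > 0)
})

test_that("the Novikov shift moves the effective threshold by C1", {
  expect_equal(novikov_shift(-0.3, 0)$mu_eff, -0.3)
  ns <- novikov_shift(-0.05, 0.1)
  expect_equal(ns$mu_eff, 0.05)
  expect_true(ns$crossed)
  expect_false(novikov_shift(-0.3, 0.1)$crossed)
  expect_error(novikov_shift(-0.1, -1), "C1")
  # numerical confirmation of the shift: a Stratonovich (Heun) simulation of
  # the k0 mode with gap noise of strength C1 (in gap units) makes the
  # ensemble mean grow at gap_rate * (mu + C1) although mu < 0
  tp <- tp7()
  mu <- -0.02; C1 <- 0.05
  g <- tp$gap_rate
  c1raw <- 2 * C1 / g           # intensity whose Stratonovich drift is g*C1
  dt <- 1e-3; nt <- 2000; nreal <- 4000
  set.seed(77)
  z <- rep(0.01, nreal)
  mlog <- numeric(4)
  for (i in 1:nt) {
    dW <- stats::rnorm(nreal, sd = sqrt(dt))
    drift1 <- g * mu * z
    diff1 <- g * sqrt(c1raw) * z
    zp <- z + dt * drift1 + diff1 * dW
    z <- z + dt * (drift1 + g * mu * zp) / 2 +
      (diff1 + g * sqrt(c1raw) * zp) * dW / 2
    if (i %% (nt / 4) == 0) mlog[i / (nt / 4)] <- log(mean(z))
  }
  tt <- (1:4) * (nt / 4) * dt
  rate <- stats::coef(stats::lm(mlog ~ tt))[2]
  expect_equal(unname(rate), g * (mu + C1), tolerance = 0.25)
  expect_gt(rate, 0)            # noise-induced growth despite mu < 0
  # ensemble variance grows as well once the effective gap is positive
  expect_gt(exp(2 * mlog[4]), exp(2 * mlog[2]))
})

test_that("the stochastic front equation reduces to the deterministic one without noise", {
  tp <- tp7()
  set.seed(2)
  u0 <- front_field(64, 4, values = 0.01 * rnorm(64), k0 = tp$k0)
  a <- evolve_front(u0, -0.1, tp, t_end = 1, dt = 0.02)
  b <- sde_evolve_front(u0, -0.1, tp, noise_spec(C0 = 0, C1 = 0), t_end = 1,
                        dt = 0.02)
  expect_identical(a$field$u, b$field$u)
})

test_that("stochastic front modes reach their Ornstein-Uhlenbeck variance", {
  # the linearized stochastic front equation makes every Fourier mode an
  # OU process with rate -symbol(k); check the k0 mode against the closed form
  tp <- tp7()
  n <- 128; nper <- 8
  u0 <- front_field(n, nper, k0 = tp$k0)
  C0 <- 1e-4
  ns <- noise_spec(C0 = C0, seed = 21)
  out <- sde_evolve_front(u0, -0.2, tp, ns, t_end = 60, dt = 0.02,
                          save_every = 25)
  sn <- out$snapshots[out$times > 20, ]
  Gk0 <- -linear_symbol(tp$k0, -0.2, tp)
  pred <- n^2 * C0 / u0$L / (2 * Gk0)
  meas <- mean(apply(sn, 1, function(u) Mod(stats::fft(u)[nper + 1])^2))
  expect_equal(meas, pred, tolerance = 0.35)
})

test_that("heaviside follows the stated convention", {
  expect_identical(heaviside(c(-1, 0, 1)), c(0, 0.5, 1))
  expect_identical(heaviside(1e-300), 1)
})
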