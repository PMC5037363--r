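# Noise-driven interface dynamics below the fingering threshold.
#
# Below threshold (mu < 0) each interface Fourier mode zeta_lambda relaxes at
# rate Gamma(lambda) = xi0^2 (lambda - k0)^2 - mu * gap_rate > 0 and is forced
# by the biochemical noise, giving an Ornstein-Uhlenbeck process whose
# stationary variance is the structure function S(lambda) = C0(lambda) /
# (2 Gamma(lambda)): maximal at lambda = k0 and divergent as mu -> 0-, so the
# pattern wavelength is selected by noise even below the instability.
#
# Noise sources: the concentration jump (eta3), the border production rate
# N0 -> N0 + eta4, and the chemotactic constant Lambda -> Lambda + eta5.
# eta4/eta5 also shift the bifurcation gap itself (multiplicative noise eta1);
# all other sources lump into the additive noise eta2.

#' Gaussian white-in-time noise specification
#'
#' @param C0 Additive-noise spatial spectrum: a constant or a function of the
#'   wavenumber `lambda`; must be non-negative.
#' @param C1 Multiplicative-noise strength (>= 0).
#' @param seed Integer seed; realization `i` of an ensemble uses `seed + i`.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(C0 = 0.01, C1 = 0, seed = 1L) {
  C0f <- if (is.function(C0)) C0 else function(lambda) rep(C0, length(lambda))
  if (any(C0f(c(0.5, 1, 5)) < 0)) stop("C0 must be non-negative", call. = FALSE)
  if (C1 < 0) stop("C1 must be non-negative", call. = FALSE)
  structure(list(C0 = C0f, C1 = C1, white_in_time = TRUE,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Relaxation rate of an interface Fourier mode below threshold
#'
#' Quadratic approximation of `-Omega` around the selected wavenumber:
#' `Gamma(lambda) = xi0^2 (lambda - k0)^2 - mu * gap_rate`.
#'
#' @param lambda Wavenumber(s).
#' @param mu Gap from threshold (negative below threshold).
#' @param threshold A [find_threshold()] object.
#' @return `Gamma(lambda)`; positive for all `lambda` when `mu < 0`. A warning
#'   is issued for `mu >= 0` (the rate can vanish or turn negative).
#' @export
relaxation_rate <- function(lambda, mu, threshold) {
  stopifnot(inherits(threshold, "threshold_point"))
  if (mu >= 0)
    warning("mu >= 0: relaxation rate may vanish or become negative")
  threshold$xi0sq * (lambda - threshold$k0)^2 - mu * threshold$gap_rate
}

#' Langevin trajectory of one interface mode
#'
#' Ornstein-Uhlenbeck dynamics `d zeta = -Gamma zeta dt + sqrt(C0) dW`,
#' integrated with the exact transition density (mean `exp(-Gamma dt)`,
#' variance `C0 (1 - exp(-2 Gamma dt))/(2 Gamma)`), so the result is free of
#' time-step bias.
#'
#' @param Gamma Relaxation rate (> 0).
#' @param C0 Noise intensity of this mode.
#' @param t_end,dt Time horizon and output step (`dt * Gamma` may be large; the
#'   update is exact).
#' @param zeta0 Initial value.
#' @param n_realizations Number of independent trajectories.
#' @param seed Integer seed.
#' @return List with `t` and `zeta` (matrix `n_realizations x length(t)`).
#' @export
langevin_mode <- function(Gamma, C0, t_end, dt, zeta0 = 0,
                          n_realizations = 1, seed = 1L) {
  if (Gamma <= 0) stop("Gamma must be positive", call. = FALSE)
  if (dt * Gamma > 0.5 && C0 == 0)
    NULL # deterministic decay is exact anyway
  tt <- seq(0, t_end, by = dt)
  nt <- length(tt)
  a <- exp(-Gamma * dt)
  svar <- C0 * (1 - a^2) / (2 * Gamma)
  # one noise row per realization, seeded as seed + index, then a single
  # vectorized time recursion
  noise <- matrix(0, n_realizations, nt - 1)
  if (svar > 0) {
    for (r in seq_len(n_realizations)) {
      set.seed(as.integer(seed) + r - 1L)
      noise[r, ] <- stats::rnorm(nt - 1, sd = sqrt(svar))
    }
  }
  z <- matrix(NA_real_, n_realizations, nt)
  z[, 1] <- zeta0
  for (i in 2:nt) z[, i] <- a * z[, i - 1] + noise[, i - 1]
  list(t = tt, zeta = z)
}

#' Empirical autocorrelation of a stationary mode ensemble
#'
#' @param ens Output of [langevin_mode()].
#' @param burn_frac Fraction of each trajectory discarded as transient.
#' @param max_lag Maximum lag (in output steps).
#' @return Data frame `(tau, sigma_zeta)` where `sigma_zeta(0)` estimates the
#'   structure function `S(lambda)`.
#' @export
autocorrelation <- function(ens, burn_frac = 0.5, max_lag = 50) {
  z <- ens$zeta
  i0 <- max(2L, floor(ncol(z) * burn_frac))
  zs <- z[, i0:ncol(z), drop = FALSE]
  dt <- ens$t[2] - ens$t[1]
  nlag <- min(max_lag, ncol(zs) - 1)
  ac <- vapply(0:nlag, function(l) {
    m <- ncol(zs) - l
    mean(zs[, 1:m, drop = FALSE] * zs[, (1 + l):(m + l), drop = FALSE])
  }, numeric(1))
  if (nrow(z) * ncol(zs) < 1e3)
    warning("few samples: autocorrelation estimate has wide confidence bands")
  data.frame(tau = (0:nlag) * dt, sigma_zeta = ac)
}

#' Analytic structure function below threshold
#'
#' `S(lambda) = C0(lambda) / (2 Gamma(lambda))`: the stationary variance of
#' each interface mode. Peaks where `Gamma` is minimal (at `k0`) and diverges
#' there as `mu -> 0-` like `1/|mu|`.
#'
#' @param lambda_grid Wavenumbers.
#' @param mu Gap from threshold (must be negative).
#' @param noise A [noise_spec()].
#' @param threshold A [find_threshold()] object.
#' @return An object of class `"structure_function"`: data frame
#'   `(lambda, S)` with attribute `provenance = "analytic"`.
#' @export
structure_function_analytic <- function(lambda_grid, mu, noise, threshold) {
  if (mu >= 0) stop("analytic structure function requires mu < 0", call. = FALSE)
  stopifnot(inherits(noise, "noise_spec"))
  G <- relaxation_rate(lambda_grid, mu, threshold)
  structure(data.frame(lambda = lambda_grid, S = noise$C0(lambda_grid) / (2 * G)),
            provenance = "analytic", mu = mu,
            class = c("structure_function", "data.frame"))
}

#' Monte-Carlo structure function
#'
#' Estimates the stationary variance of each mode from an ensemble of exact
#' Ornstein-Uhlenbeck trajectories, with Monte-Carlo standard errors.
#'
#' @inheritParams structure_function_analytic
#' @param n_realizations Ensemble size per mode.
#' @param t_end,dt Trajectory horizon and step; the second half of each
#'   trajectory (stationary window) enters the estimate.
#' @return A `"structure_function"` data frame `(lambda, S, stderr)` with
#'   attribute `provenance = "empirical"` and ensemble metadata.
#' @export
structure_function_empirical <- function(lambda_grid, mu, noise, threshold,
                                         n_realizations = 64, t_end = NULL,
                                         dt = NULL) {
  if (mu >= 0) stop("below-threshold estimator requires mu < 0", call. = FALSE)
  stopifnot(inherits(noise, "noise_spec"))
  G <- relaxation_rate(lambda_grid, mu, threshold)
  S <- numeric(length(lambda_grid)); se <- numeric(length(lambda_grid))
  for (i in seq_along(lambda_grid)) {
    Gi <- G[i]
    ti <- if (is.null(t_end)) 20 / Gi else t_end
    di <- if (is.null(dt)) 0.2 / Gi else dt
    ens <- langevin_mode(Gi, noise$C0(lambda_grid[i]), ti, di,
                         n_realizations = n_realizations,
                         seed = noise$seed + 1000L * i)
    i0 <- floor(length(ens$t) / 2)
    zs <- ens$zeta[, i0:length(ens$t), drop = FALSE]
    vr <- rowMeans(zs^2)            # per-realization stationary variance
    S[i] <- mean(vr)
    se[i] <- stats::sd(vr) / sqrt(length(vr))
  }
  structure(data.frame(lambda = lambda_grid, S = S, stderr = se),
            provenance = "empirical", mu = mu,
            n_realizations = n_realizations, seed = noise$seed,
            class = c("structure_function", "data.frame"))
}

#' @export
print.structure_function <- function(x, ...) {
  cat(sprintf("structure function (%s), %d modes, mu = %g; peak at lambda = %g\n",
              attr(x, "provenance"), nrow(x), attr(x, "mu"),
              x$lambda[which.max(x$S)]))
  invisible(x)
}

#' Multiplicative-noise sensitivities of the bifurcation gap
#'
#' Fluctuations of the border production rate (`N0 -> N0 + eta4`) and of the
#' chemotactic constant (`Lambda -> Lambda + eta5`) shake the bifurcation gap:
#' `eta1 = -(s4 eta4 + s5 eta5)`. The gap responds through the relative
#' chemotactic forcing `S = Lambda (1 + N0)` of the velocity relation and, for
#' `eta5`, additionally through the direct appearance of `Lambda` as the
#' bifurcation parameter, so
#' `s4 = dlnS/dN0 = 1/(1 + N0)` and `s5 = dlnS/dLambda + 1/Lambda = 2/Lambda`.
#' At the reference operating point (`alpha = N0 = 1`, `Lambda = 7.65`,
#' `U = 7`) this gives `s4 = 0.5` and `s5 = 0.26`.
#'
#' @param mp A [model_params()] object with `Lambda > 0`.
#' @param U Front speed; must lie on the steady branch of `(mp, P_i)` when
#'   `mp$P_i` is set (checked through the velocity relation).
#' @return Named vector `(s4, s5)`.
#' @export
#' @examples
#' mp <- model_params(Lambda = 7.65, alpha = 1, N0 = 1)
#' multiplicative_sensitivities(mp, U = 7)
multiplicative_sensitivities <- function(mp, U) {
  stopifnot(inherits(mp, "model_params"))
  if (mp$Lambda <= 0)
    stop("multiplicative sensitivities require chemotactic coupling Lambda > 0",
         call. = FALSE)
  if (U <= 0) stop("U must be positive", call. = FALSE)
  if (!is.null(mp$P_i) && mp$alpha > 0) {
    res <- velocity_residual(U, mp$Lambda, mp$alpha, mp$P_i, mp$N0)
    if (abs(res) > 1e-6 * max(1, U))
      stop(sprintf("(%g, %g) is off the steady branch: velocity residual %.3g",
                   mp$Lambda, U, res), call. = FALSE)
  }
  c(s4 = 1 / (1 + mp$N0), s5 = 2 / mp$Lambda)
}

#' Boundary-noise transfer coefficients onto the interface equation
#'
#' Linear-response coefficients `E3, E4, E5` mapping the three boundary-
#' condition noises (concentration jump, production rate, chemotactic
#' constant) to the Langevin equation of an interface mode,
#' `d zeta/dt = -Gamma zeta + E3 eta3 + E4 eta4 + E5 eta5`. Each coefficient
#' is computed by implicit differentiation of the dispersion residual,
#' `E_j = -(dF/d eta_j)/(dF/dOmega)` at the mode's relaxation rate, together
#' with the auxiliary quasi-static decay rates of the derivation.
#'
#' @param mp A [model_params()] object.
#' @param U Front speed on the steady branch.
#' @param k Wavenumber of the mode.
#' @return An object of class `"noise_mapping"` with `E3`, `E4`, `E5`, the
#'   quasi-static rates `r_ep`, `r_wp`, `r_0`, the combination `X0`, and the
#'   multiplicative sensitivities `s4`, `s5`.
#' @export
noise_mapping <- function(mp, U, k) {
  stopifnot(inherits(mp, "model_params"))
  Om <- growth_rate(k, mp$Lambda, U, mp$alpha, mp$N0, mp$sigma)
  dF <- function(f, h) (f(h) - f(-h)) / (2 * h)
  h <- 1e-6
  dFdOm <- dF(function(e) dispersion_residual(Om + e, k, mp$Lambda, U,
                                              mp$alpha, mp$N0, mp$sigma), h)
  # eta3: additive shift of the concentration-jump condition enters the
  # perturbed amplitude balance exactly like a unit of -l_w * a-forcing
  resid_eta3 <- function(e) {
    # re-derive the residual with jump condition C_e - C_w = 1 + e
    r_e <- (-U + sqrt(U^2 + 4)) / 2
    C0  <- r_e * U * (1 + mp$N0); Cw0 <- C0 - 1
    P_i <- (mp$Lambda * (1 + mp$N0) * r_e^3 * U / (mp$alpha + r_e) - U) / mp$alpha
    cfp <- steady_pressure_coefs(U, mp$Lambda, mp$alpha, mp$N0, P_i)
    l_e <- (-U + sqrt(U^2 + 4 * (1 + k^2 + Om))) / 2
    l_w <- ( U + sqrt(U^2 + 4 * (k^2 + Om))) / 2
    chi <- sqrt(k^2 + mp$alpha^2)
    a_e <- (mp$N0 * Om - mp$N0 * U * l_w - r_e^2 * C0 + U^2 * Cw0 - l_w * e) /
      (l_e + l_w)
    Q <- mp$Lambda * a_e * (l_e^2 - k^2) / (l_e^2 - k^2 - mp$alpha^2)
    b <- mp$sigma * k^2 + U + Q
    Om + cfp$d2P0 + chi * b - l_e * Q
  }
  E3 <- -dF(resid_eta3, h) / dFdOm
  E4 <- -dF(function(e) dispersion_residual(Om, k, mp$Lambda, U, mp$alpha,
                                            mp$N0 + e, mp$sigma), h) / dFdOm
  E5 <- -dF(function(e) dispersion_residual(Om, k, mp$Lambda + e, U, mp$alpha,
                                            mp$N0, mp$sigma), h) / dFdOm
  r_0  <- (-U + sqrt(U^2 + 4)) / 2
  r_ep <- (-U + sqrt(U^2 + 4 * (1 + k^2))) / 2
  r_wp <- ( U + sqrt(U^2 + 4 * k^2)) / 2
  X0 <- (-U * (mp$N0 + 1) * r_0 - mp$N0 * U * (r_wp - U)) / (r_ep + r_wp)
  s <- multiplicative_sensitivities(mp, U)
  structure(list(E3 = E3, E4 = E4, E5 = E5, r_0 = r_0, r_ep = r_ep,
                 r_wp = r_wp, X0 = X0, s4 = s[["s4"]], s5 = s[["s5"]],
                 k = k, Omega = Om),
            class = "noise_mapping")
}

#' Novikov shift of the bifurcation threshold
#'
#' Multiplicative noise of strength `C1` renormalizes the mean bifurcation gap
#' to `mu + C1`; the front can jump into the unstable domain although `mu < 0`.
#'
#' @param mu Deterministic gap.
#' @param C1 Multiplicative-noise strength (>= 0).
#' @return List with `mu_eff = mu + C1` and the logical `crossed`
#'   (`mu < 0 <= mu_eff`: noise-induced instability).
#' @export
novikov_shift <- function(mu, C1) {
  if (C1 < 0) stop("C1 must be non-negative", call. = FALSE)
  mu_eff <- mu + C1
  list(mu_eff = mu_eff, crossed = (mu < 0) && (mu_eff >= 0))
}

#' Stochastic front equation
#'
#' Integrates `du/dt = L u + 1/2 d(u^2)/dx + eta1 u + eta2` with additive
#' spatio-temporal white noise `eta2` (intensity `C0` per unit length and
#' time) and, optionally, multiplicative gap noise `eta1` (scalar white noise
#' of intensity `C1`, Ito update). Exponential time differencing of the
#' deterministic part; noise increments scale as `sqrt(dt)`. With all noise
#' strengths zero the path coincides with [evolve_front()].
#'
#' @inheritParams evolve_front
#' @param noise A [noise_spec()]; `C0` may be a function of the (rescaled)
#'   wavenumber.
#' @param seed Integer seed (defaults to `noise$seed`).
#' @return As [evolve_front()].
#' @export
sde_evolve_front <- function(u0, mu, threshold, noise, t_end, dt = 0.05,
                             save_every = 0, seed = NULL, blowup = 1e6) {
  stopifnot(inherits(u0, "front_field"), inherits(noise, "noise_spec"))
  if (is.null(seed)) seed <- noise$seed
  n <- u0$n
  kk <- fft_wavenumbers(n, u0$L)
  sym <- linear_symbol(abs(kk) * u0$k0, mu, threshold)
  cf <- etdrk4_coefs(dt * sym)
  dealias <- abs(kk) <= (n / 3) * (2 * pi / u0$L)
  g <- 0.5i * kk * u0$k0
  Nl <- function(vh) {
    u <- Re(stats::fft(vh, inverse = TRUE)) / n
    g * stats::fft(u * u) * dealias
  }
  dx <- u0$L / n
  C0k <- noise$C0(abs(kk) * u0$k0)
  any_noise <- any(C0k > 0) || noise$C1 > 0
  vh <- stats::fft(u0$u)
  nsteps <- max(1L, round(t_end / dt))
  keep <- save_every > 0
  times <- numeric(0); snaps <- NULL
  if (keep) {
    snaps <- matrix(NA_real_, floor(nsteps / save_every) + 1L, n)
    snaps[1, ] <- u0$u; times <- u0$t; ridx <- 1L
  }
  if (any_noise) set.seed(as.integer(seed))
  for (s in seq_len(nsteps)) {
    Nv <- Nl(vh)
    av <- cf$E2 * vh + cf$Q * dt * Nv;  Na <- Nl(av)
    bv <- cf$E2 * vh + cf$Q * dt * Na;  Nb <- Nl(bv)
    cv <- cf$E2 * av + cf$Q * dt * (2 * Nb - Nv); Nc <- Nl(cv)
    vh <- cf$E * vh + dt * (cf$f1 * Nv + 2 * cf$f2 * (Na + Nb) + cf$f3 * Nc)
    if (any_noise) {
      u <- Re(stats::fft(vh, inverse = TRUE)) / n
      if (any(C0k > 0)) {
        # white-in-space additive noise: per-cell variance C0/(dx dt)
        xi <- stats::rnorm(n, sd = sqrt(mean(C0k) * dt / dx))
        u <- u + xi
      }
      if (noise$C1 > 0) {
        u <- u + u * stats::rnorm(1, sd = sqrt(noise$C1 * dt))
      }
      vh <- stats::fft(u)
    }
    if (max(Mod(vh)) / n > blowup)
      stop(sprintf("stochastic front blow-up at t = %g", u0$t + s * dt),
           call. = FALSE)
    if (keep && s %% save_every == 0) {
      ridx <- ridx + 1L
      snaps[ridx, ] <- Re(stats::fft(vh, inverse = TRUE)) / n
      times <- c(times, u0$t + s * dt)
    }
  }
  out <- front_field(n, u0$n_periods, Re(stats::fft(vh, inverse = TRUE)) / n,
                     k0 = u0$k0, t = u0$t + nsteps * dt)
  if (keep) list(field = out, times = times,
                 snapshots = snaps[seq_along(times), , drop = FALSE])
  else list(field = out)
}

#' Heaviside step function
#'
#' The convention used in the noise-correlation integrals: 1 for `x > 0`, 0
#' for `x < 0`, 1/2 at `x = 0`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of 0, 1/2, 1.
#' @export
heaviside <- function(x) {
  ifelse(x > 0, 1, ifelse(x < 0, 0, 0.5))
}
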