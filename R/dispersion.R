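# Linear stability of the planar travelling front.
#
# A sinusoidal perturbation of the interface, zeta = U t + eps e^{ikx} e^{Omega t},
# perturbs the morphogen fields, the pressure and the interface position. The
# perturbed concentration fields decay with Omega-dependent rates
#   l_e = (-U + sqrt(U^2 + 4(1 + k^2 + Omega)))/2   (epithelium)
#   l_w = ( U + sqrt(U^2 + 4(k^2 + Omega)))/2       (water)
# and the homogeneous pressure response decays with chi = sqrt(k^2 + alpha^2).
# Roots with positive real part are selected so that all perturbations decay
# away from the interface. Eliminating the field amplitudes against the
# perturbed jump, flux, Laplace and kinematic conditions leaves one scalar
# residual F(Omega, k) whose root is the growth rate; the relation is implicit
# because l_e and l_w depend on Omega. The capillary term sigma k^2 enters the
# Laplace condition and is the large-k stabilizer.

#' Residual of the implicit dispersion relation
#'
#' `growth_rate()` drives this residual to zero. Exposed for diagnostics and
#' for independent cross-checks.
#'
#' @param Omega Trial growth rate.
#' @param k Transverse wavenumber (>= 0).
#' @param Lambda,U,alpha,N0,sigma Model parameters and front speed. `P_i` is
#'   implied by `(Lambda, U)` through the steady velocity relation.
#' @return The scalar residual.
#' @export
dispersion_residual <- function(Omega, k, Lambda, U, alpha = 1, N0 = 1,
                                sigma = 1e-3) {
  r_e <- (-U + sqrt(U^2 + 4)) / 2
  C0  <- r_e * U * (1 + N0)
  Cw0 <- C0 - 1
  P_i <- (Lambda * (1 + N0) * r_e^3 * U / (alpha + r_e) - U) / alpha
  cf  <- steady_pressure_coefs(U, Lambda, alpha, N0, P_i)
  l_e <- (-U + sqrt(U^2 + 4 * (1 + k^2 + Omega))) / 2
  l_w <- ( U + sqrt(U^2 + 4 * (k^2 + Omega))) / 2
  chi <- sqrt(k^2 + alpha^2)
  # perturbed concentration amplitudes from the jump and flux conditions
  a_e <- (N0 * Omega - N0 * U * l_w - r_e^2 * C0 + U^2 * Cw0) / (l_e + l_w)
  # particular pressure response driven by the perturbed morphogen field
  den <- l_e^2 - k^2 - alpha^2
  if (abs(den) < 1e-12) den <- sign(den + (den == 0)) * 1e-12
  Q <- Lambda * a_e * (l_e^2 - k^2) / den
  # Laplace condition fixes the homogeneous pressure amplitude
  b <- sigma * k^2 + U + Q
  # kinematic condition: Omega zeta = -(P0'' zeta + p'(0))
  Omega + cf$d2P0 + chi * b - l_e * Q
}

#' Growth rate of a sinusoidal interface perturbation
#'
#' Solves the implicit dispersion relation for the real growth rate on the
#' branch continuously connected to the translational (Goldstone) zero mode
#' `Omega(k -> 0) = 0`.
#'
#' @inheritParams dispersion_residual
#' @param k Wavenumber (scalar).
#' @param guess Initial guess / continuation value for the root search.
#' @return The growth rate `Omega(k)`; `NA` with a warning if no real root is
#'   found near the searched branch.
#' @export
#' @examples
#' growth_rate(5, Lambda = 7.65, U = 7)   # ~ 0 at the marginal point
growth_rate <- function(k, Lambda, U, alpha = 1, N0 = 1, sigma = 1e-3,
                        guess = 0) {
  f <- function(Om) dispersion_residual(Om, k, Lambda, U, alpha, N0, sigma)
  # real decay rates require Omega above the branch point of l_w
  floor_Om <- -(k^2) - U^2 / 4 + 1e-12
  step <- 2
  lo <- max(guess - step, floor_Om); hi <- guess + step
  found <- FALSE
  for (i in 1:60) {
    if (f(lo) * f(hi) < 0) { found <- TRUE; break }
    step <- step * 1.6
    lo <- max(lo - step, floor_Om); hi <- hi + step
    if (lo <= floor_Om + 1e-12 && hi > 1e6) break
  }
  if (!found) {
    warning(sprintf("no real growth-rate root found at k = %g", k))
    return(NA_real_)
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-13)$root
}

#' Dispersion spectrum over a wavenumber grid
#'
#' Computes `Omega(k)` by continuation along the grid and classifies the
#' spectrum as `"stable"` (Omega < 0 for all k > 0), `"unstable"` (a finite
#' band with Omega > 0) or `"marginal"` (tangency at the threshold).
#'
#' @inheritParams dispersion_residual
#' @param k_grid Strictly increasing non-negative wavenumbers.
#' @param tol Tolerance used by the classification.
#' @return An object of class `"dispersion_spectrum"`: a data frame with
#'   columns `k`, `Omega`, `flag`, plus attributes `classification` and
#'   `params`.
#' @export
dispersion_spectrum <- function(k_grid, Lambda, U, alpha = 1, N0 = 1, sigma = 1e-3,
                     tol = 1e-6) {
  stopifnot(all(diff(k_grid) > 0), all(k_grid >= 0))
  om <- numeric(length(k_grid)); flag <- logical(length(k_grid)); g <- 0
  for (i in seq_along(k_grid)) {
    oi <- suppressWarnings(
      growth_rate(k_grid[i], Lambda, U, alpha, N0, sigma, guess = g))
    flag[i] <- is.na(oi)
    if (!is.na(oi)) g <- oi
    om[i] <- oi
  }
  interior <- k_grid > tol
  mx <- suppressWarnings(max(om[interior], na.rm = TRUE))
  cls <- if (!is.finite(mx)) "flagged"
         else if (mx > tol) "unstable"
         else if (mx < -tol) "stable"
         else "marginal"
  structure(data.frame(k = k_grid, Omega = om, flag = flag),
            classification = cls,
            params = list(Lambda = Lambda, U = U, alpha = alpha, N0 = N0,
                          sigma = sigma),
            class = c("dispersion_spectrum", "data.frame"))
}

#' @export
print.dispersion_spectrum <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(
    "Dispersion spectrum (%d points), Lambda = %g, U = %g: %s\n",
    nrow(x), p$Lambda, p$U, attr(x, "classification")))
  invisible(x)
}

# dOmega/dk by central differences with one Richardson step
omega_kderiv <- function(k, Lambda, U, alpha, N0, sigma, Om, h = 1e-4) {
  d1 <- (growth_rate(k + h, Lambda, U, alpha, N0, sigma, Om) -
         growth_rate(k - h, Lambda, U, alpha, N0, sigma, Om)) / (2 * h)
  d2 <- (growth_rate(k + h / 2, Lambda, U, alpha, N0, sigma, Om) -
         growth_rate(k - h / 2, Lambda, U, alpha, N0, sigma, Om)) / h
  (4 * d2 - d1) / 3
}

threshold_newton <- function(U, alpha, N0, sigma, Lambda_start, k_start,
                             maxit = 60, tol = 1e-12) {
  x <- c(Lambda_start, k_start)
  for (it in seq_len(maxit)) {
    Lam <- x[1]; k <- x[2]
    if (Lam <= 0 || k <= 0) return(NULL)
    Om <- suppressWarnings(growth_rate(k, Lam, U, alpha, N0, sigma))
    if (is.na(Om)) return(NULL)
    dOk <- omega_kderiv(k, Lam, U, alpha, N0, sigma, Om)
    hL <- 1e-6 * max(1, Lam); hk <- 1e-4 * max(1, k)
    OmL  <- growth_rate(k, Lam + hL, U, alpha, N0, sigma, Om)
    dOkL <- omega_kderiv(k, Lam + hL, U, alpha, N0, sigma, OmL)
    d2Ok <- (growth_rate(k + hk, Lam, U, alpha, N0, sigma, Om) - 2 * Om +
             growth_rate(k - hk, Lam, U, alpha, N0, sigma, Om)) / hk^2
    J <- matrix(c((OmL - Om) / hL, dOk,
                  (dOkL - dOk) / hL, d2Ok), 2, 2, byrow = TRUE)
    step <- tryCatch(solve(J, -c(Om, dOk)), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    step <- pmax(pmin(step, c(2, 2)), c(-2, -2))
    x <- x + step
    if (max(abs(step)) < tol) break
  }
  Lam <- x[1]; k <- x[2]
  Om <- suppressWarnings(growth_rate(k, Lam, U, alpha, N0, sigma))
  if (is.na(Om)) return(NULL)
  dOk <- omega_kderiv(k, Lam, U, alpha, N0, sigma, Om)
  if (abs(Om) > 1e-8 || abs(dOk) > 1e-8) return(NULL)
  c(Lambda0 = Lam, k0 = k, Omega = Om, dOmega_dk = dOk)
}

#' Marginal (double-zero) fingering threshold at fixed front speed
#'
#' Finds `(Lambda0, k0)` such that the growth rate and its k-derivative vanish
#' simultaneously: the onset of a steady periodic pattern at wavenumber `k0`.
#' Several Newton starts are used; when more than one marginal point exists the
#' one with the smaller `Lambda0` is selected as the physical boundary.
#'
#' @param U Front speed.
#' @param alpha,N0,sigma Model parameters.
#' @param k_starts Wavenumber starting points for the 2-D Newton search.
#' @return An object of class `"threshold_point"` with `U`, `Lambda0`, `k0`,
#'   `xi0sq` (minus half the curvature of Omega(k) at `k0`), `gap_rate`
#'   (`Lambda0 * dOmega/dLambda` at the threshold, the growth rate per unit
#'   relative gap `mu`), `P_i_implied`, and `solutions` (all distinct marginal
#'   points found).
#' @export
#' @examples
#' tp <- find_threshold(U = 7)
#' c(tp$Lambda0, tp$k0)    # ~ (7.67, 4.96)
find_threshold <- function(U, alpha = 1, N0 = 1, sigma = 1e-3,
                           k_starts = NULL) {
  if (is.null(k_starts)) k_starts <- c(0.7, 0.4, 1.0, 1.6) * U
  # crude Lambda scale from the U = 7 anchor scaling, refined by Newton
  Lam_start <- max(2, 7.67 * U / 7 * 2 / (1 + N0))
  sols <- list()
  for (ks in k_starts) {
    for (Ls in Lam_start * c(1, 0.5, 2)) {
      s <- threshold_newton(U, alpha, N0, sigma, Ls, ks)
      if (!is.null(s)) {
        dup <- any(vapply(sols, function(z)
          abs(z[["Lambda0"]] - s[["Lambda0"]]) < 1e-5 &&
          abs(z[["k0"]] - s[["k0"]]) < 1e-5, logical(1)))
        if (!dup) sols <- c(sols, list(s))
        break
      }
    }
  }
  if (length(sols) == 0)
    stop(sprintf(paste0("no marginal point found for U = %g, alpha = %g, ",
                        "N0 = %g, sigma = %g (scanned k starts: %s)"),
                 U, alpha, N0, sigma, paste(signif(k_starts, 3), collapse = ", ")),
         call. = FALSE)
  ord <- order(vapply(sols, `[[`, numeric(1), "Lambda0"))
  sols <- sols[ord]
  sel <- sols[[1]]
  Lam0 <- sel[["Lambda0"]]; k0 <- sel[["k0"]]
  hk <- 1e-3 * k0
  Om0 <- growth_rate(k0, Lam0, U, alpha, N0, sigma)
  d2 <- (growth_rate(k0 + hk, Lam0, U, alpha, N0, sigma, Om0) - 2 * Om0 +
         growth_rate(k0 - hk, Lam0, U, alpha, N0, sigma, Om0)) / hk^2
  hL <- 1e-5 * Lam0
  dOdL <- (growth_rate(k0, Lam0 + hL, U, alpha, N0, sigma, Om0) -
           growth_rate(k0, Lam0 - hL, U, alpha, N0, sigma, Om0)) / (2 * hL)
  structure(list(U = U, Lambda0 = Lam0, k0 = k0,
                 xi0sq = -d2 / 2,
                 gap_rate = Lam0 * dOdL,
                 P_i_implied = implied_interface_pressure(U, Lam0, alpha, N0),
                 alpha = alpha, N0 = N0, sigma = sigma,
                 solutions = sols),
            class = "threshold_point")
}

#' @export
print.threshold_point <- function(x, ...) {
  cat(sprintf(
    "Fingering threshold at U = %g:\n  Lambda0 = %.6g, k0 = %.6g, P_i = %.6g\n",
    x$U, x$Lambda0, x$k0, x$P_i_implied))
  cat(sprintf("  xi0^2 = %.6g, gap rate = %.6g", x$xi0sq, x$gap_rate))
  if (length(x$solutions) > 1)
    cat(sprintf("  (%d marginal points found; smallest Lambda0 selected)",
                length(x$solutions)))
  cat("\n")
  invisible(x)
}

#' Threshold at prescribed interface pressure
#'
#' Simultaneously satisfies the steady velocity relation and the two marginal
#' conditions: solves for `(U, Lambda0, k0)` given `P_i`.
#'
#' @param P_i Dimensionless interface pressure.
#' @param alpha,N0,sigma Model parameters.
#' @param U_scan Range scanned for a sign change of the implied pressure.
#' @return A `"threshold_point"` (with `U` solved, `P_i_implied ~ P_i`).
#' @export
#' @examples
#' tp <- threshold_for_interface_pressure(-6.76)
#' c(tp$U, tp$k0, tp$Lambda0)     # ~ (7.02, 4.98, 7.67)
threshold_for_interface_pressure <- function(P_i, alpha = 1, N0 = 1,
                                             sigma = 1e-3,
                                             U_scan = c(2, 30)) {
  f <- function(U) find_threshold(U, alpha, N0, sigma)$P_i_implied - P_i
  br <- scan_bracket(f, U_scan)
  U <- stats::uniroot(f, br, tol = 1e-9)$root
  find_threshold(U, alpha, N0, sigma)
}

# find a sign-change bracket of f over [rng[1], rng[2]], skipping points where
# f is undefined
scan_bracket <- function(f, rng, n = 16) {
  us <- seq(rng[1], rng[2], length.out = n)
  vals <- vapply(us, function(u)
    tryCatch(f(u), error = function(e) NA_real_), numeric(1))
  ok <- which(!is.na(vals))
  for (i in seq_len(length(ok) - 1)) {
    a <- ok[i]; b <- ok[i + 1]
    if (vals[a] * vals[b] <= 0) return(c(us[a], us[b]))
  }
  stop("no sign change found on the scanned range; extend U_scan",
       call. = FALSE)
}

#' Front speed at which a given wavenumber is selected
#'
#' Inverts the threshold curve `k0(U)`.
#'
#' @param k0_target Selected wavenumber.
#' @param alpha,N0,sigma Model parameters.
#' @param U_scan Range scanned for the inversion.
#' @return A `"threshold_point"` whose `k0` equals `k0_target`.
#' @export
threshold_velocity_for_k0 <- function(k0_target, alpha = 1, N0 = 1,
                                      sigma = 1e-3, U_scan = c(2, 30)) {
  f <- function(U) find_threshold(U, alpha, N0, sigma)$k0 - k0_target
  br <- scan_bracket(f, U_scan)
  U <- stats::uniroot(f, br, tol = 1e-9)$root
  find_threshold(U, alpha, N0, sigma)
}

#' Selected wavenumber versus front speed
#'
#' @param U_grid Front speeds.
#' @param alpha,N0,sigma Model parameters.
#' @return Data frame `(U, Lambda0, k0, P_i_implied, found)`.
#' @export
k0_vs_U_curve <- function(U_grid, alpha = 1, N0 = 1, sigma = 1e-3) {
  rows <- lapply(U_grid, function(U) {
    tp <- tryCatch(find_threshold(U, alpha, N0, sigma), error = function(e) NULL)
    if (is.null(tp))
      data.frame(U = U, Lambda0 = NA_real_, k0 = NA_real_,
                 P_i_implied = NA_real_, found = FALSE)
    else
      data.frame(U = U, Lambda0 = tp$Lambda0, k0 = tp$k0,
                 P_i_implied = tp$P_i_implied, found = TRUE)
  })
  do.call(rbind, rows)
}

#' Phase diagram in the (Lambda, U) plane
#'
#' Labels each point by the relative gap `mu = (Lambda - Lambda0(U))/Lambda0(U)`:
#' `"stable"` for `mu <= 0`, `"weakly-nonlinear"` for `0 < mu <= mu_band`,
#' `"spatio-temporal"` beyond.
#'
#' @param Lambda_grid,U_grid Grids of chemotactic constants and front speeds.
#' @param alpha,N0,sigma Model parameters.
#' @param mu_band Width of the weakly nonlinear band (relative gap).
#' @return Data frame `(Lambda, U, Lambda0, mu, label)`.
#' @export
phase_diagram <- function(Lambda_grid, U_grid, alpha = 1, N0 = 1,
                          sigma = 1e-3, mu_band = 0.1) {
  th <- k0_vs_U_curve(U_grid, alpha, N0, sigma)
  rows <- lapply(seq_along(U_grid), function(i) {
    L0 <- th$Lambda0[i]
    mu <- (Lambda_grid - L0) / L0
    lab <- ifelse(is.na(mu), "unknown",
           ifelse(mu <= 0, "stable",
           ifelse(mu <= mu_band, "weakly-nonlinear", "spatio-temporal")))
    data.frame(Lambda = Lambda_grid, U = U_grid[i], Lambda0 = L0,
               mu = mu, label = lab)
  })
  do.call(rbind, rows)
}
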