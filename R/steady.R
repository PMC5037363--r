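# Steady planar travelling front: morphogen profiles, pressure profile and the
# implicit front-velocity relation.
#
# Co-moving coordinate convention: Y = y - U t, interface at Y = 0, epithelium
# at Y < 0, water at Y > 0. In these units the steady morphogen field is
#   C_e(Y) = C0 exp(r_e Y),  r_e = (-U + sqrt(U^2 + 4))/2   (Y < 0)
#   C_w(Y) = Cw0 exp(-r_w Y), r_w = U                        (Y > 0)
# with interface conditions C_e - C_w = 1 and d/dn (C_e - C_w) = N0 * v_n,
# which give C0 = r_e U (1 + N0). The pressure obeys
# Delta(P + Lambda C_e) - alpha^2 P = 0 with P(0) = P_i (planar) and the Darcy
# kinematic condition U = -P'(0).

#' Decay rates of the steady morphogen profiles
#'
#' @param U Dimensionless front speed (> 0).
#' @return Named vector with `r_e` (epithelium side) and `r_w = U` (water side).
#' @export
decay_rates <- function(U) {
  if (any(U <= 0)) stop("receding or static fronts (U <= 0) are not modeled",
                        call. = FALSE)
  c(r_e = (-U + sqrt(U^2 + 4)) / 2, r_w = U)
}

#' Steady morphogen concentration profiles in the co-moving frame
#'
#' @param U Dimensionless front speed (> 0).
#' @param N0 Border morphogen production rate.
#' @return List with `U`, `N0`, `C0`, `Cw0`, decay rates `r_e`, `r_w`, and
#'   evaluators `C_e(Y)` (for Y <= 0) and `C_w(Y)` (for Y >= 0).
#' @export
#' @examples
#' pr <- morphogen_profile(U = 5, N0 = 1)
#' pr$C0                 # equals r_e * U * (1 + N0)
#' pr$C_e(0) - pr$C_w(0) # concentration jump = 1
morphogen_profile <- function(U, N0 = 1) {
  r <- decay_rates(U)
  C0  <- r[["r_e"]] * U * (1 + N0)
  Cw0 <- C0 - 1
  list(U = U, N0 = N0, C0 = C0, Cw0 = Cw0,
       r_e = r[["r_e"]], r_w = r[["r_w"]],
       C_e = function(Y) C0 * exp(r[["r_e"]] * Y),
       C_w = function(Y) Cw0 * exp(-r[["r_w"]] * Y))
}

# Coefficients of the steady pressure field P(Y) = A exp(alpha Y) + part(Y).
# Off resonance (alpha != r_e) part(Y) = G2 exp(r_e Y) with
# G2 = Lambda C0 r_e^2/(alpha^2 - r_e^2); at resonance part(Y) =
# -(Lambda C0 alpha/2) Y exp(alpha Y).
steady_pressure_coefs <- function(U, Lambda, alpha, N0, P_i) {
  pr <- morphogen_profile(U, N0)
  r_e <- pr$r_e
  resonant <- isTRUE(abs(alpha - r_e) < 1e-10)
  if (resonant) {
    Gr <- -Lambda * pr$C0 * alpha / 2
    A  <- P_i
    dP0  <- alpha * A + Gr            # P'(0)
    d2P0 <- alpha^2 * A + 2 * alpha * Gr
    list(resonant = TRUE, A = A, Gr = Gr, dP0 = dP0, d2P0 = d2P0, prof = pr)
  } else {
    G2 <- Lambda * pr$C0 * r_e^2 / (alpha^2 - r_e^2)
    A  <- P_i - G2
    dP0  <- alpha * A + r_e * G2
    d2P0 <- alpha^2 * A + r_e^2 * G2
    list(resonant = FALSE, A = A, G2 = G2, dP0 = dP0, d2P0 = d2P0, prof = pr)
  }
}

#' Steady pressure profile of the travelling front
#'
#' Returns the pressure field satisfying the bulk balance
#' `(P + Lambda C_e)'' = alpha^2 P` in the epithelium, the planar interface
#' condition `P(0) = P_i`, and boundedness at `Y -> -Inf`.
#'
#' @param U Front speed (> 0); should satisfy the velocity relation
#'   [front_velocity()] for a self-consistent front, but any U > 0 gives a
#'   valid bulk solution.
#' @param Lambda,alpha,N0,P_i Model parameters.
#' @return List with the evaluator `P(Y)` (Y <= 0), the interface derivatives
#'   `dP0`, `d2P0` and the coefficient set.
#' @export
pressure_profile <- function(U, Lambda, alpha, N0, P_i) {
  if (alpha == 0 && Lambda == 0) {
    # no proliferation, no chemotaxis: bounded harmonic pressure is uniform
    return(list(P = function(Y) rep(P_i, length(Y)),
                dP0 = 0, d2P0 = 0, degenerate = TRUE))
  }
  if (alpha == 0) {
    # P + Lambda C_e harmonic and bounded => constant: P = P_i + Lambda(C0 - C_e)
    pr <- morphogen_profile(U, N0)
    return(list(
      P = function(Y) P_i + Lambda * (pr$C0 - pr$C_e(Y)),
      dP0 = -Lambda * pr$r_e * pr$C0,
      d2P0 = -Lambda * pr$r_e^2 * pr$C0,
      degenerate = FALSE))
  }
  cf <- steady_pressure_coefs(U, Lambda, alpha, N0, P_i)
  P <- if (cf$resonant) {
    function(Y) cf$A * exp(alpha * Y) + cf$Gr * Y * exp(alpha * Y)
  } else {
    function(Y) cf$A * exp(alpha * Y) + cf$G2 * exp(cf$prof$r_e * Y)
  }
  list(P = P, dP0 = cf$dP0, d2P0 = cf$d2P0, degenerate = FALSE, coefs = cf)
}

# residual of the implicit velocity relation
#   U = -alpha P_i + Lambda (1 + N0) r_e(U)^3 U / (alpha + r_e(U))
velocity_residual <- function(U, Lambda, alpha, P_i, N0) {
  r_e <- (-U + sqrt(U^2 + 4)) / 2
  U - (-alpha * P_i + Lambda * (1 + N0) * r_e^3 * U / (alpha + r_e))
}

#' Front velocity from the implicit steady-state relation
#'
#' Solves the implicit relation between the front speed `U`, the chemotactic
#' forcing `Lambda (1 + N0)` and the proliferative drive `-alpha P_i`. Limits:
#' `Lambda = 0` gives the proliferative front `U = -alpha P_i`; `alpha = 0`
#' gives the chemotaxis-only front `U = sqrt(S) - 1/sqrt(S)` with
#' `S = Lambda (1 + N0)` (which requires S > 1).
#'
#' @param Lambda Chemotactic migration constant.
#' @param alpha Proliferation coefficient.
#' @param P_i Dimensionless interface pressure.
#' @param N0 Border production rate.
#' @param all_roots If `TRUE`, also return every positive root found on the
#'   scanned bracket `[1e-4, 1e3]`.
#' @return The smallest positive root `U` (or a list with `U` and `roots` when
#'   `all_roots = TRUE`).
#' @export
#' @examples
#' front_velocity(Lambda = 0, alpha = 1, P_i = -2)          # 2
#' front_velocity(Lambda = 7.65, alpha = 1, P_i = -6.76)    # ~ 7
front_velocity <- function(Lambda, alpha, P_i, N0 = 1, all_roots = FALSE) {
  if (alpha == 0) {
    S <- Lambda * (1 + N0)
    if (S <= 1)
      stop("no advancing chemotaxis-only front: Lambda*(1+N0) must exceed 1",
           call. = FALSE)
    U <- sqrt(S) - 1 / sqrt(S)
    return(if (all_roots) list(U = U, roots = U) else U)
  }
  if (Lambda == 0) {
    U <- -alpha * P_i
    if (U <= 0) stop("no advancing front: alpha * P_i must be negative",
                     call. = FALSE)
    return(if (all_roots) list(U = U, roots = U) else U)
  }
  f <- function(U) velocity_residual(U, Lambda, alpha, P_i, N0)
  grid <- exp(seq(log(1e-4), log(1e3), length.out = 400))
  fg <- vapply(grid, f, numeric(1))
  sgn <- sign(fg)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0)
    stop("no advancing front found on U in [1e-4, 1e3]: ",
         sprintf("residual range [%.3g, %.3g]", min(fg), max(fg)),
         call. = FALSE)
  roots <- vapply(idx, function(i)
    stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)$root, numeric(1))
  roots <- sort(unique(roots))
  if (all_roots) list(U = roots[1], roots = roots) else roots[1]
}

#' Interface pressure implied by a prescribed front speed
#'
#' Inverts the velocity relation for `P_i` at given `(U, Lambda, alpha, N0)`.
#'
#' @inheritParams front_velocity
#' @param U Front speed.
#' @return Implied `P_i`.
#' @export
implied_interface_pressure <- function(U, Lambda, alpha, N0 = 1) {
  if (alpha == 0) stop("P_i does not enter the alpha = 0 relation", call. = FALSE)
  r_e <- (-U + sqrt(U^2 + 4)) / 2
  (Lambda * (1 + N0) * r_e^3 * U / (alpha + r_e) - U) / alpha
}

#' Assemble the full steady travelling front
#'
#' @param mp A [model_params()] object; `mp$P_i` must be set unless `U` is
#'   given (in which case the implied `P_i` is reported).
#' @param U Optional prescribed front speed; by default solved from
#'   [front_velocity()].
#' @return An object of class `"steady_front"` with fields `U`, `C0`, `r_e`,
#'   `r_w`, `P_i`, evaluators `C_e(Y)`, `C_w(Y)`, `P(Y)`, and parameters.
#' @export
#' @examples
#' mp <- model_params(Lambda = 7.65, alpha = 1, N0 = 1, P_i = -6.76)
#' sf <- steady_front(mp)
#' sf$U
steady_front <- function(mp, U = NULL) {
  stopifnot(inherits(mp, "model_params"))
  if (is.null(U)) {
    if (is.null(mp$P_i)) stop("either mp$P_i or U must be supplied", call. = FALSE)
    U <- front_velocity(mp$Lambda, mp$alpha, mp$P_i, mp$N0)
    P_i <- mp$P_i
  } else {
    P_i <- if (mp$alpha > 0)
      implied_interface_pressure(U, mp$Lambda, mp$alpha, mp$N0)
    else mp$P_i
  }
  pr <- morphogen_profile(U, mp$N0)
  pp <- pressure_profile(U, mp$Lambda, mp$alpha, mp$N0, P_i)
  structure(list(U = U, C0 = pr$C0, Cw0 = pr$Cw0, r_e = pr$r_e, r_w = pr$r_w,
                 P_i = P_i, C_e = pr$C_e, C_w = pr$C_w, P = pp$P,
                 dP0 = pp$dP0, d2P0 = pp$d2P0, params = mp),
            class = "steady_front")
}

#' @export
print.steady_front <- function(x, ...) {
  cat(sprintf("Steady travelling front: U = %.6g (P_i = %.6g)\n", x$U, x$P_i))
  cat(sprintf("  C0 = %.6g, r_e = %.6g, r_w = %.6g\n", x$C0, x$r_e, x$r_w))
  invisible(x)
}

#' Tabulate steady-front profiles
#'
#' @param sf A [steady_front()] object.
#' @param n Number of grid points per side.
#' @param n_decay Truncation length in units of the slowest decay length.
#' @return A data frame with columns `Y`, `C_e`, `C_w`, `P` (fields are `NA`
#'   outside their domain).
#' @export
front_profile_table <- function(sf, n = 200, n_decay = 20) {
  stopifnot(inherits(sf, "steady_front"))
  Lmin <- n_decay / min(sf$r_e, sf$params$alpha + (sf$params$alpha == 0))
  Ye <- seq(-Lmin, 0, length.out = n)
  Yw <- seq(0, n_decay / sf$r_w, length.out = n)[-1]
  data.frame(
    Y   = c(Ye, Yw),
    C_e = c(sf$C_e(Ye), rep(NA_real_, length(Yw))),
    C_w = c(rep(NA_real_, length(Ye)), sf$C_w(Yw)),
    P   = c(sf$P(Ye), rep(NA_real_, length(Yw))))
}
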