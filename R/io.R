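# Configuration, result tables and the command dispatcher behind the
# command-line interface.

#' Read a run configuration
#'
#' JSON configuration with exactly one of the blocks `"dimensionless"` (fields
#' `Lambda`, `alpha`, `N0`, `sigma`, `P_i`) or `"dimensional"` (fields of
#' [dimensional_params()] plus `N0`, optionally `sigma`, `P_i`), plus optional
#' command settings (`seed`, grids, `dt`, `t_end`, ...).
#'
#' @param path Path to a JSON file.
#' @return A list with the resolved [model_params()] under `$params`, the raw
#'   settings under `$settings`, and `$seed`.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  has_dl <- !is.null(cfg$dimensionless); has_dm <- !is.null(cfg$dimensional)
  if (has_dl == has_dm)
    stop("config must contain exactly one of 'dimensionless' or 'dimensional'",
         call. = FALSE)
  if (has_dl) {
    b <- cfg$dimensionless
    mp <- model_params(Lambda = b$Lambda,
                       alpha = if (is.null(b$alpha)) 1 else b$alpha,
                       N0 = if (is.null(b$N0)) 1 else b$N0,
                       sigma = if (is.null(b$sigma)) 1e-3 else b$sigma,
                       P_i = b$P_i)
  } else {
    b <- cfg$dimensional
    dp <- dimensional_params(D_e = b$D_e, tau_e = b$tau_e, K_e = b$K_e,
                             K_p = if (is.null(b$K_p)) 0 else b$K_p,
                             lambda_0 = if (is.null(b$lambda_0)) 0 else b$lambda_0,
                             c_i = if (is.null(b$c_i)) 1 else b$c_i,
                             S_T = if (is.null(b$S_T)) 0 else b$S_T)
    mp <- nondimensionalize(dp, N0 = if (is.null(b$N0)) 1 else b$N0,
                            P_i = b$P_i,
                            sigma = b$sigma)
  }
  cfg$dimensionless <- cfg$dimensional <- NULL
  list(params = mp,
       settings = cfg,
       seed = if (is.null(cfg$seed)) 0L else as.integer(cfg$seed))
}

#' Write a result table with a provenance header
#'
#' Comma-separated values with '.' decimal marks, preceded by '#'-prefixed
#' header lines recording the command, parameters, seed and timestamp, so the
#' run can be reproduced from the file alone.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param command Command name recorded in the header.
#' @param params Named list recorded in the header.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path, command = "", params = list(),
                               seed = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chemofront %s", command), con)
  if (length(params))
    writeLines(sprintf("# params: %s",
                       paste(names(params), unlist(params), sep = "=",
                             collapse = " ")), con)
  writeLines(sprintf("# seed: %d", as.integer(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path File path.
#' @return The data frame, with the header lines in attribute `"provenance"`.
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"))
  attr(df, "provenance") <- lines[hdr]
  df
}

#' Run a named command
#'
#' Dispatcher used by the command-line wrapper. Commands: `steady` (velocity
#' and steady-front summary, optionally over a Lambda scan), `dispersion`
#' (spectrum over a k grid), `threshold` (marginal point at fixed U or fixed
#' P_i), `phase-diagram`, `simulate` (front or amplitude equations),
#' `stability` (plane-wave stability report), `stochastic` (analytic +
#' empirical structure function).
#'
#' @param name Command name.
#' @param config A list as returned by [read_run_config()], or a path to a
#'   JSON config.
#' @return A data frame or list of results (also written to files when
#'   `config$settings$out` is set).
#' @export
run_command <- function(name, config) {
  if (is.character(config)) config <- read_run_config(config)
  mp <- config$params; st <- config$settings; seed <- config$seed
  name <- match.arg(name, c("steady", "dispersion", "threshold",
                            "phase-diagram", "simulate", "stability",
                            "stochastic"))
  out <- switch(name,
    "steady" = {
      Lams <- if (!is.null(st$lambda_scan))
        seq(st$lambda_scan[1], st$lambda_scan[2], length.out = st$lambda_scan[3])
      else mp$Lambda
      rows <- lapply(Lams, function(L) {
        U <- front_velocity(L, mp$alpha, mp$P_i, mp$N0)
        r <- decay_rates(U)
        data.frame(Lambda = L, alpha = mp$alpha, N0 = mp$N0, P_i = mp$P_i,
                   U = U, C0 = r[["r_e"]] * U * (1 + mp$N0),
                   r_e = r[["r_e"]], r_w = r[["r_w"]])
      })
      do.call(rbind, rows)
    },
    "dispersion" = {
      U <- st$U
      kg <- seq(if (is.null(st$kmin)) 0 else st$kmin,
                if (is.null(st$kmax)) 12 else st$kmax,
                length.out = if (is.null(st$nk)) 200 else st$nk)
      kg <- kg[kg >= 0]
      sp <- dispersion_spectrum(kg, mp$Lambda, U, mp$alpha, mp$N0, mp$sigma)
      as.data.frame(sp)
    },
    "threshold" = {
      tp <- if (!is.null(st$U)) find_threshold(st$U, mp$alpha, mp$N0, mp$sigma)
            else threshold_for_interface_pressure(mp$P_i, mp$alpha, mp$N0,
                                                  mp$sigma)
      list(U = tp$U, Lambda0 = tp$Lambda0, k0 = tp$k0,
           P_i_implied = tp$P_i_implied, xi0sq = tp$xi0sq,
           gap_rate = tp$gap_rate)
    },
    "phase-diagram" = {
      phase_diagram(st$Lambda_grid, st$U_grid, mp$alpha, mp$N0, mp$sigma,
                    mu_band = if (is.null(st$mu_band)) 0.1 else st$mu_band)
    },
    "simulate" = {
      tp <- find_threshold(if (is.null(st$U)) 7 else st$U,
                           mp$alpha, mp$N0, mp$sigma)
      if (identical(st$what, "amplitudes")) {
        n <- if (is.null(st$n)) 64 else st$n
        q <- if (is.null(st$q)) -0.1 else st$q
        stt <- amplitude_state(steady_amplitude(q) * exp(1i * q *
                 seq(0, 2 * pi, length.out = n + 1)[seq_len(n)] *
                 (if (is.null(st$n_periods)) 1 else st$n_periods)),
                 n_periods = if (is.null(st$n_periods)) 1 else st$n_periods,
                 q = q)
        tr <- evolve_amplitudes(stt, if (is.null(st$t_end)) 10 else st$t_end,
                                if (is.null(st$dt)) 0.01 else st$dt,
                                save_every = if (is.null(st$save_every)) 100
                                             else st$save_every)
        tr
      } else {
        n <- if (is.null(st$n)) 256 else st$n
        set.seed(seed)
        u0 <- front_field(n, if (is.null(st$n_periods)) 8 else st$n_periods,
                          values = 1e-3 * stats::rnorm(n), k0 = tp$k0)
        evolve_front(u0, if (is.null(st$mu)) 0.1 else st$mu, tp,
                     if (is.null(st$t_end)) 10 else st$t_end,
                     if (is.null(st$dt)) 0.05 else st$dt,
                     save_every = if (is.null(st$save_every)) 0 else st$save_every)
      }
    },
    "stability" = {
      q <- if (is.null(st$q)) hopf_point() else st$q
      p <- if (is.null(st$p)) 0.1 else st$p
      cc <- stability_coefficients(q)
      eta <- growth_roots(q, p)
      regime <- if (q > 0) "unstable"
        else if (q > hopf_point()) "stable-oscillatory"
        else if (abs(q - hopf_point()) < 1e-10) "hopf"
        else "oscillatory-unstable"
      list(q = q, p = p, c1 = cc[["c1"]], c2 = cc[["c2"]],
           eta = eta, regime = regime,
           hopf_frequency = if (regime %in% c("hopf")) hopf_frequency(p) else NA)
    },
    "stochastic" = {
      U <- if (is.null(st$U)) 7 else st$U
      tp <- find_threshold(U, mp$alpha, mp$N0, mp$sigma)
      mu <- if (is.null(st$mu)) -0.1 else st$mu
      ns <- noise_spec(C0 = if (is.null(st$C0)) 0.01 else st$C0, seed = seed)
      lg <- if (is.null(st$lambda_grid))
        seq(0.5 * tp$k0, 1.5 * tp$k0, length.out = 41) else st$lambda_grid
      sa <- structure_function_analytic(lg, mu, ns, tp)
      se <- structure_function_empirical(lg, mu, ns, tp,
              n_realizations = if (is.null(st$n)) 64 else st$n)
      data.frame(lambda = lg, S_analytic = sa$S, S_empirical = se$S,
                 stderr = se$stderr)
    })
  if (!is.null(st$out)) {
    if (is.data.frame(out))
      write_result_table(out, st$out, command = name,
                         params = mp[!vapply(mp, is.null, logical(1))],
                         seed = seed)
    else
      jsonlite::write_json(out, st$out, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  }
  out
}

#' Generate small deterministic test assets
#'
#' Produces a fixture bundle used by examples and smoke tests: a 50-point
#' spectrum at the reference marginal point (U = 7), a 20-realization
#' Ornstein-Uhlenbeck ensemble, and a short amplitude-equation trajectory on a
#' 64-point grid.
#'
#' @param seed Integer seed (recorded in the bundle; default 0).
#' @param dir Optional directory; when given, the fixtures are written as CSV
#'   with provenance headers.
#' @return List with `spectrum`, `ou_ensemble`, `amplitude_trajectory`, `seed`.
#' @export
make_fixtures <- function(seed = 0L, dir = NULL) {
  seed <- if (is.null(seed) || is.na(seed)) 0L else as.integer(seed)
  tp <- find_threshold(7)
  kg <- seq(0.1, 10, length.out = 50)
  sp <- dispersion_spectrum(kg, tp$Lambda0, 7)
  ou <- langevin_mode(Gamma = 1, C0 = 0.02, t_end = 40, dt = 0.2,
                      n_realizations = 20, seed = seed + 1L)
  q <- -0.1; n <- 64
  X <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  stt <- amplitude_state(steady_amplitude(q) * exp(1i * q * X), q = q)
  tr <- evolve_amplitudes(stt, T_end = 1, dT = 0.01, save_every = 20)
  fx <- list(spectrum = sp, ou_ensemble = ou, amplitude_trajectory = tr,
             threshold = tp, seed = seed)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_result_table(as.data.frame(sp), file.path(dir, "spectrum.csv"),
                       "fixture-spectrum",
                       list(U = 7, Lambda0 = tp$Lambda0), seed)
    write_result_table(
      data.frame(t = ou$t, t(ou$zeta)),
      file.path(dir, "ou_ensemble.csv"), "fixture-ou",
      list(Gamma = 1, C0 = 0.02), seed)
    write_result_table(
      data.frame(T = tr$times, ReA1 = Re(tr$A_snapshots[, 1]),
                 ImA1 = Im(tr$A_snapshots[, 1]), B1 = tr$B_snapshots[, 1]),
      file.path(dir, "amplitude_trajectory.csv"), "fixture-amplitude",
      list(q = q, mu = 1), seed)
  }
  fx
}
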