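#' Uniform steady states of the single-functional-group model
#'
#' The single-group model keeps one biomass variable `B` (trait value
#' `chi`) together with `W` and `H`.  Its uniform equilibria satisfy
#' `Lambda(B) W = M`, `I(B) H = P` and `P = W (L(B) + Gamma B)`; the
#' bare-soil root `(0, P/L0, P/(f A))` always exists, vegetated roots are
#' located by a sign-change scan plus root polishing on the scalar
#' water-balance residual.
#'
#' @param P precipitation, mm/y.
#' @param chi trait value in `[0, 1]`.
#' @param params a [dc_params()] object.
#' @param B_max upper end of the biomass scan range, kg/m^2.
#' @return A list of equilibria, each a list `(B, W, H)`, sorted by
#'   increasing `B`; the first entry is always bare soil.
#' @export
uniform_steady_states <- function(P, chi, params, B_max = 2) {
  if (P <= 0) stop("'P' must be positive", call. = FALSE)
  tr <- trait_values(chi, params)
  eqs <- list(list(B = 0, W = P / params$L0, H = P / (params$f * params$A)))
  # water balance at the fixed point, as a function of B alone
  res <- function(B) {
    W <- tr$M * (B + tr$K) / (params$Lambda0 * tr$K)
    W * (params$L0 / (1 + params$R * B) + params$Gamma * B) - P
  }
  Bs <- seq(1e-8, B_max, length.out = 4000)
  rv <- vapply(Bs, res, numeric(1))
  sgn <- which(diff(sign(rv)) != 0)
  for (i in sgn) {
    root <- tryCatch(
      stats::uniroot(res, c(Bs[i], Bs[i + 1]), tol = 1e-13)$root,
      error = function(e) NA_real_)
    if (!is.na(root) && root > 0) {
      W <- tr$M * (root + tr$K) / (params$Lambda0 * tr$K)
      I <- infiltration_rate(tr$Y * root, params)
      eqs[[length(eqs) + 1L]] <- list(B = root, W = W, H = P / I)
    }
  }
  eqs[order(vapply(eqs, `[[`, numeric(1), "B"))]
}

#' Precipitation threshold of bare-soil stability
#'
#' Linearising the biomass equation about bare soil (`W = P/L0`) gives
#' the growth rate `Lambda0 P / L0 - M(chi)`; bare soil loses stability
#' to group `chi` above
#' \deqn{P_B(\chi) = M(\chi) L_0 / \Lambda_0 .}
#'
#' @inheritParams uniform_steady_states
#' @return Threshold precipitation, mm/y.
#' @examples
#' bare_soil_threshold(1, dc_params())   # 62.5
#' bare_soil_threshold(0, dc_params())   # 112.5
#' @export
bare_soil_threshold <- function(chi, params) {
  tr <- trait_values(chi, params)
  tr$M * params$L0 / params$Lambda0
}

# 3x3 Jacobian of the single-group reaction terms about (B, W, H)
single_group_jacobian <- function(eq, chi, params) {
  tr <- trait_values(chi, params)
  B <- eq$B; W <- eq$W; H <- eq$H
  K <- tr$K; M <- tr$M; Y <- tr$Y
  Lam <- params$Lambda0 * K / (B + K)
  dLam <- -params$Lambda0 * K / (B + K)^2
  I <- params$A * (Y * B + params$f * params$Q) / (Y * B + params$Q)
  dI <- params$A * Y * params$Q * (1 - params$f) / (Y * B + params$Q)^2
  L <- params$L0 / (1 + params$R * B)
  dL <- -params$L0 * params$R / (1 + params$R * B)^2
  rbind(
    c(dLam * W * B + Lam * W - M, Lam * B,                      0),
    c(dI * H - dL * W - params$Gamma * W, -L - params$Gamma * B, I),
    c(-dI * H,                           0,                     -I))
}

#' Linear dispersion relation of the uniform vegetated state
#'
#' For each wavenumber `k` the linearisation of the single-group model
#' about its (largest) vegetated uniform equilibrium is the reaction
#' Jacobian minus `k^2 diag(DB, DW, DH)`; the returned growth rate is
#' the largest real part of its eigenvalues.  A positive maximum at
#' finite `k` while `k = 0` is stable signals a Turing instability.
#'
#' @inheritParams uniform_steady_states
#' @param k wavenumber grid, 1/m; the default covers wavelengths of
#'   5--500 m with 200 log-spaced values.
#' @param refine if `TRUE`, the maximum is polished by golden-section
#'   search around the best grid point.
#' @return An object of class `dispersion_relation`: list with `k`,
#'   `sigma_max` (per-`k` growth rates, 1/y), `kc` (maximising
#'   wavenumber), `sigma_c` (growth rate at `kc`), `wavelength`
#'   (`2*pi/kc`), and the `equilibrium` used.
#' @export
dispersion_relation <- function(P, chi, params,
                                k = default_k_grid(), refine = TRUE) {
  eqs <- uniform_steady_states(P, chi, params)
  veg <- Filter(function(e) e$B > 0, eqs)
  if (!length(veg))
    stop("no vegetated uniform equilibrium at P = ", P, call. = FALSE)
  eq <- veg[[length(veg)]]
  J <- single_group_jacobian(eq, chi, params)
  D <- c(params$DB, params$DW, params$DH)
  sig <- function(kk)
    max(Re(eigen(J - kk^2 * diag(D), only.values = TRUE)$values))
  s <- vapply(k, sig, numeric(1))
  j <- which.max(s)
  kc <- k[j]; sc <- s[j]
  if (refine && j > 1 && j < length(k)) {
    op <- stats::optimize(sig, c(k[j - 1], k[j + 1]),
                          maximum = TRUE, tol = 1e-10)
    kc <- op$maximum; sc <- op$objective
  }
  structure(list(k = k, sigma_max = s, kc = kc, sigma_c = sc,
                 wavelength = 2 * pi / kc, equilibrium = eq,
                 P = P, chi = chi),
            class = "dispersion_relation")
}

default_k_grid <- function(wl_min = 5, wl_max = 500, n = 200)
  2 * pi / exp(seq(log(wl_max), log(wl_min), length.out = n))

#' @export
print.dispersion_relation <- function(x, ...) {
  cat(sprintf("<dispersion_relation> P = %g, chi = %g\n", x$P, x$chi))
  cat(sprintf("  max growth %.4g 1/y at k = %.4g 1/m (wavelength %.4g m)\n",
              x$sigma_c, x$kc, x$wavelength))
  invisible(x)
}

#' Turing instability threshold of uniform vegetation
#'
#' Bisects on precipitation until the maximal growth rate over finite
#' wavenumbers crosses zero, giving the Turing threshold `PT(chi)`, the
#' critical wavenumber `kc` and the critical wavelength `2*pi/kc`.
#'
#' @inheritParams uniform_steady_states
#' @param P_bracket precipitation interval known to contain the
#'   threshold (maximal finite-`k` growth rate positive at the lower
#'   end, negative at the upper end).
#' @param tol_sigma bisection stops once `|sigma_c|` falls below this.
#' @return List with `PT` (mm/y), `kc` (1/m), `wavelength` (m), and the
#'   `dispersion` at the threshold.
#' @export
turing_point <- function(chi, params, P_bracket = c(65, 200),
                         tol_sigma = 1e-8) {
  sig_at <- function(P)
    tryCatch(dispersion_relation(P, chi, params)$sigma_c,
             error = function(e) NA_real_)
  lo <- P_bracket[1]; hi <- P_bracket[2]
  s_lo <- sig_at(lo); s_hi <- sig_at(hi)
  if (is.na(s_lo) || is.na(s_hi) || s_lo <= 0 || s_hi >= 0)
    stop("'P_bracket' does not bracket a sign change of the maximal ",
         "growth rate", call. = FALSE)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    s <- sig_at(mid)
    if (is.na(s)) stop("lost the vegetated equilibrium during bisection",
                       call. = FALSE)
    if (abs(s) < tol_sigma) break
    if (s > 0) lo <- mid else hi <- mid
  }
  PT <- (lo + hi) / 2
  disp <- dispersion_relation(PT, chi, params)
  list(PT = PT, kc = disp$kc, wavelength = disp$wavelength,
       dispersion = disp)
}

#' Trace single-group solution branches by sweeping precipitation
#'
#' Hysteresis-aware continuation by time integration: the model is run
#' to its asymptotic state at the first precipitation value, and each
#' subsequent value is seeded from the previous asymptotic state (plus a
#' small perturbation so linear instabilities are expressed).  Records
#' the L2 biomass norm, the detected wavelength and whether the state
#' remained vegetated.  Only stable states can be traced this way;
#' unstable branches are invisible to time integration.  A change of
#' detected wavelength between consecutive sweep points is recorded as a
#' branch-end event, and collapse to bare soil terminates the sweep.
#'
#' @inheritParams uniform_steady_states
#' @param P_sweep precipitation values in sweep order.
#' @param domain_wavelengths domain length in units of the chi-dependent
#'   critical wavelength.
#' @param nx spatial grid points.
#' @param t_per_stage integration horizon per sweep point, y.
#' @param noise_amplitude relative perturbation applied at each stage.
#' @param seed RNG seed for the perturbations.
#' @param start one of `"uniform"` (start from the uniform vegetated
#'   equilibrium) or `"pattern"` (start from a strongly modulated state).
#' @return A data frame with columns `P`, `norm`, `wavelength`,
#'   `vegetated`, `event` (`""`, `"wavelength_change"` or
#'   `"collapse"`).
#' @export
trace_branch <- function(chi, params, P_sweep, domain_wavelengths = 4,
                         nx = 128, t_per_stage = 5e3,
                         noise_amplitude = 1e-3, seed = 1,
                         start = c("uniform", "pattern")) {
  start <- match.arg(start)
  tp <- turing_point(chi, params)
  domain <- domain_wavelengths * tp$wavelength
  grid1 <- structure(list(N = 1L, dchi = 1, chi = chi,
                          K = trait_values(chi, params)$K,
                          M = trait_values(chi, params)$M,
                          Y = trait_values(chi, params)$Y),
                     class = "trait_grid")
  state <- NULL
  rows <- vector("list", length(P_sweep))
  prev_wl <- NA_real_
  for (j in seq_along(P_sweep)) {
    pj <- modify_params(params, P = P_sweep[j])
    if (is.null(state)) {
      state <- make_initial("single_group", grid1, pj, nx = nx,
                            domain = domain, chi = chi,
                            noise_amplitude = noise_amplitude,
                            seed = seed)
      if (start == "pattern") {
        x <- (seq_len(nx) - 1) * state$dx
        state$B <- state$B * rep(1 + cos(2 * pi * x / tp$wavelength),
                                 each = 1)
      }
    } else {
      # reperturb so instabilities of the carried-over state can grow
      set.seed(seed + j)
      state$B <- state$B *
        (1 + noise_amplitude * matrix(stats::runif(length(state$B), -1, 1),
                                      nrow(state$B)))
    }
    run <- tryCatch(
      integrate_spatial(state, grid1, pj, t_end = t_per_stage,
                        steady_tol = 1e-5),
      error = function(e) NULL)
    if (is.null(run)) {
      rows[[j]] <- data.frame(P = P_sweep[j], norm = NA_real_,
                              wavelength = NA_real_, vegetated = NA,
                              event = "integration_failure")
      break
    }
    state <- run$state
    nrm <- biomass_norm(state)
    veg <- nrm > 1e-6
    wl <- pattern_wavelength(state, contrast_threshold = 0.05)
    event <- ""
    if (!veg) event <- "collapse"
    else if (!is.na(prev_wl) && !is.na(wl) && abs(wl - prev_wl) > state$dx)
      event <- "wavelength_change"
    rows[[j]] <- data.frame(P = P_sweep[j], norm = nrm, wavelength = wl,
                            vegetated = veg, event = event)
    if (!veg) break
    prev_wl <- wl
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
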