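#' Community state on a periodic 1-D domain
#'
#' Bundles the biomass matrix `B` (functional groups by grid points, each
#' entry the per-area biomass of one trait bin), soil water `W` and
#' surface water `H` (vectors over grid points), the grid spacing `dx`
#' and the simulation time `t`.  All fields are in kg/m^2; `B` is the
#' biomass of a `dchi` trait bin, not a trait-space density (the density
#' view is `N * B`).
#'
#' @param B numeric `N x Nx` matrix of per-bin biomass.
#' @param W,H numeric vectors of length `Nx`.
#' @param dx grid spacing, m.
#' @param t simulation time, y.
#' @return An object of class `community_state`.
#' @export
community_state <- function(B, W, H, dx, t = 0) {
  B <- as.matrix(B)
  nx <- ncol(B)
  if (nx < 4L) stop("need at least 4 grid points", call. = FALSE)
  if (length(W) != nx || length(H) != nx)
    stop("W and H must match the spatial dimension of B", call. = FALSE)
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0)
    stop("'dx' must be a positive scalar", call. = FALSE)
  if (any(!is.finite(B)) || any(!is.finite(W)) || any(!is.finite(H)))
    stop("state fields must be finite", call. = FALSE)
  if (min(B) < 0 || min(W) < 0 || min(H) < 0)
    stop("state fields must be non-negative", call. = FALSE)
  structure(list(B = B, W = as.numeric(W), H = as.numeric(H),
                 dx = dx, t = t),
            class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("<community_state> %d groups x %d points, L = %.1f m, t = %g y\n",
              nrow(x$B), ncol(x$B), ncol(x$B) * x$dx, x$t))
  cat(sprintf("  total biomass %.4g kg/m^2, W in [%.3g, %.3g], H in [%.3g, %.3g]\n",
              mean(colSums(x$B)), min(x$W), max(x$W), min(x$H), max(x$H)))
  invisible(x)
}

#' Bare-soil equilibrium values
#'
#' The vegetation-free uniform state `B = 0`, `W = P/L0`, `H = P/(f A)`
#' is an exact equilibrium of the model at every precipitation.
#'
#' @param params a [dc_params()] object.
#' @return Named list with `W` and `H`.
#' @export
bare_soil_state <- function(params) {
  list(W = params$P / params$L0, H = params$P / (params$f * params$A))
}

#' Construct initial conditions for spatial simulations
#'
#' All-group initial states follow the convention that every functional
#' group is present, if only at a small seed biomass.  Four kinds are
#' provided:
#' \describe{
#'   \item{`uniform_community`}{every group at `floor_biomass` (or a
#'     supplied per-group profile), plus optional multiplicative noise.}
#'   \item{`bare_soil`}{`B = 0` with the exact bare-soil water values.}
#'   \item{`single_group`}{only the group nearest `chi` is seeded, at the
#'     vegetated single-group equilibrium if one exists (else at
#'     `floor_biomass`), plus noise.}
#'   \item{`hybrid`}{a patterned subdomain occupying `patterned_fraction`
#'     of the domain (biomass modulated by a raised cosine at
#'     `wavelength`), embedded in uniform vegetation elsewhere.}
#' }
#'
#' @param kind one of `"uniform_community"`, `"bare_soil"`,
#'   `"single_group"`, `"hybrid"`.
#' @param grid a [trait_grid()].
#' @param params a [dc_params()] object.
#' @param nx number of grid points (at least 4).
#' @param domain domain length, m.
#' @param noise_amplitude relative amplitude of uniform multiplicative
#'   noise applied to `B` (0 disables).
#' @param seed RNG seed for the noise; the same seed reproduces the state
#'   bit for bit.
#' @param floor_biomass per-bin seed biomass for freshly introduced
#'   groups, kg/m^2.
#' @param profile optional per-group biomass profile (length `N`)
#'   replacing the flat floor, e.g. a previously computed equilibrium.
#' @param chi trait value for `kind = "single_group"`.
#' @param patterned_fraction fraction of the domain occupied by the
#'   patterned subdomain (`kind = "hybrid"`), quantised to a whole number
#'   of wavelengths.
#' @param wavelength modulation wavelength of the patterned subdomain, m;
#'   defaults to a quarter of the domain.
#' @return A [community_state()].
#' @export
make_initial <- function(kind = c("uniform_community", "bare_soil",
                                  "single_group", "hybrid"),
                         grid, params, nx = 128, domain = 300,
                         noise_amplitude = 0, seed = NULL,
                         floor_biomass = 1e-3, profile = NULL,
                         chi = 1, patterned_fraction = 0.5,
                         wavelength = domain / 4) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("unknown initial-state kind",
                                            call. = FALSE))
  N <- grid$N
  dx <- domain / nx
  bs <- bare_soil_state(params)

  base_profile <- if (is.null(profile)) rep(floor_biomass, N) else {
    if (length(profile) != N) stop("'profile' must have length N", call. = FALSE)
    pmax(profile, 0)
  }

  if (kind == "bare_soil") {
    return(community_state(matrix(0, N, nx), rep(bs$W, nx), rep(bs$H, nx), dx))
  }

  B <- matrix(base_profile, N, nx)
  W <- rep(bs$W, nx); H <- rep(bs$H, nx)

  if (kind == "single_group") {
    B[] <- 0
    i <- which.min(abs(grid$chi - chi))
    eq <- uniform_steady_states(params$P, grid$chi[i], params)
    veg <- Filter(function(e) e$B > 0, eq)
    if (length(veg)) {
      top <- veg[[length(veg)]]
      B[i, ] <- top$B; W[] <- top$W; H[] <- top$H
    } else B[i, ] <- floor_biomass
  }

  if (kind == "hybrid") {
    if (patterned_fraction < 0 || patterned_fraction > 1)
      stop("'patterned_fraction' must lie in [0, 1]", call. = FALSE)
    # quantise the patterned subdomain to whole wavelengths so the
    # modulation closes smoothly
    n_wl <- round(patterned_fraction * domain / wavelength)
    frac_cells <- round(n_wl * wavelength / dx)
    frac_cells <- min(frac_cells, nx)
    if (frac_cells > 0) {
      x <- (seq_len(frac_cells) - 1) * dx
      modulation <- 1 + cos(2 * pi * x / wavelength)  # in [0, 2]
      B[, seq_len(frac_cells)] <-
        B[, seq_len(frac_cells), drop = FALSE] *
        rep(modulation, each = N)
    }
  }

  if (noise_amplitude > 0) {
    if (!is.null(seed)) {
      runif(1)  # force RNG initialisation so .Random.seed exists
      old <- .Random.seed
      on.exit(assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    B <- B * (1 + noise_amplitude * matrix(stats::runif(N * nx, -1, 1), N, nx))
  }

  community_state(B, W, H, dx)
}
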