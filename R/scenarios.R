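#' Community emergence with and without trait diffusion
#'
#' Integrates the spatially decoupled model at one precipitation for a
#' set of trait-diffusion rates.  Without mutations (`Dchi = 0`)
#' interspecific competition drives competitive exclusion: the number of
#' occupied bins shrinks toward a single survivor.  With slow trait
#' diffusion the asymptotic distribution is a stationary hump of finite
#' width: the emergent community.
#'
#' @param params a [dc_params()] object; its `P` sets the scenario
#'   precipitation (180 mm/y in the reference experiment).
#' @param Dchi_values trait-diffusion rates to compare.
#' @param N number of functional groups.
#' @param t_end integration horizon per run, y.
#' @param seedling_threshold richness threshold (density scale).
#' @param occupancy_fraction a bin counts as occupied when it holds more
#'   than this fraction of the maximum bin.
#' @return List of class `emergence_run` with one element per `Dchi`:
#'   the [integrate_uniform()] result plus `n_occupied`, `metrics`;
#'   and a `manifest`.
#' @export
run_emergence <- function(params = dc_params(P = 180),
                          Dchi_values = c(0, 1e-6),
                          N = params$N, t_end = 1e7,
                          seedling_threshold = 1e-3,
                          occupancy_fraction = 0.01) {
  grid <- trait_grid(N, params)
  out <- lapply(Dchi_values, function(dc) {
    pj <- modify_params(params, Dchi = dc)
    run <- integrate_uniform(grid = grid, params = pj, t_end = t_end)
    dist <- biomass_distribution(run)
    n_occ <- sum(run$B > occupancy_fraction * max(run$B))
    n_seed <- sum(grid$N * run$B > seedling_threshold)
    list(run = run, n_occupied = n_occ, n_above_threshold = n_seed,
         metrics = community_metrics(dist, seedling_threshold))
  })
  names(out) <- paste0("Dchi_", Dchi_values)
  structure(list(results = out,
                 manifest = list(scenario = "emergence", P = params$P,
                                 N = N, Dchi_values = Dchi_values,
                                 t_end = t_end)),
            class = "emergence_run")
}

#' Precipitation downshift: uniform reassembly, then pattern-induced
#' reversal
#'
#' Runs a decreasing precipitation sequence in stages, each seeded from
#' the previous asymptotic state.  Stages above the Turing threshold of
#' the stress-tolerant group (`chi = 1`) use the spatially decoupled
#' model; stages below it run the full spatial model from the previous
#' uniform distribution plus small seeded noise, letting the Turing
#' instability express itself.  For every spatial stage the (unstable)
#' uniform equilibrium at the same precipitation is also computed, so the
#' composition reversal and the biomass gain due to patterning can be
#' read off directly.
#'
#' @param P_sequence decreasing precipitation stages, mm/y.
#' @param params a [dc_params()] object.
#' @param N number of functional groups.
#' @param nx spatial grid points (spatial stages).
#' @param domain_wavelengths spatial domain length in units of the
#'   `chi = 1` critical wavelength.
#' @param noise_amplitude relative noise seeding the spatial stages.
#' @param seed RNG seed.
#' @param t_uniform,t_spatial integration horizons, y.
#' @param seedling_threshold richness threshold (density scale).
#' @return List of class `downshift_run`: `stages` (per-P list with
#'   `kind`, final distribution, metrics, wavelength, and for spatial
#'   stages the uniform-reference metrics), `table` (metrics data
#'   frame), `manifest`.
#' @export
run_downshift <- function(P_sequence = c(150, 100, 80),
                          params = dc_params(), N = params$N,
                          nx = 128, domain_wavelengths = 4,
                          noise_amplitude = 1e-2, seed = 1,
                          t_uniform = 1e7, t_spatial = 1e6,
                          seedling_threshold = 1e-3) {
  if (any(diff(P_sequence) >= 0))
    stop("'P_sequence' must be strictly decreasing", call. = FALSE)
  grid <- trait_grid(N, params)
  tp <- turing_point(1, params)
  domain <- domain_wavelengths * tp$wavelength
  stages <- vector("list", length(P_sequence))
  B_seed <- NULL
  spatial_state <- NULL
  for (j in seq_along(P_sequence)) {
    P <- P_sequence[j]
    pj <- modify_params(params, P = P)
    spatial <- P < tp$PT
    uni <- integrate_uniform(B0 = B_seed, grid = grid, params = pj,
                             t_end = t_uniform)
    if (!spatial) {
      dist <- biomass_distribution(uni)
      stages[[j]] <- list(P = P, kind = "uniform", run = uni,
                          distribution = dist,
                          metrics = community_metrics(dist, seedling_threshold),
                          wavelength = NA_real_)
      spatial_state <- NULL
    } else {
      state0 <- if (is.null(spatial_state)) {
        make_initial("uniform_community", grid, pj, nx = nx,
                     domain = domain, noise_amplitude = noise_amplitude,
                     seed = seed + j, profile = B_seed)
      } else spatial_state
      run <- integrate_spatial(state0, grid, pj, t_end = t_spatial)
      dist <- biomass_distribution(run$state)
      uref <- community_metrics(biomass_distribution(uni),
                                seedling_threshold)
      stages[[j]] <- list(P = P, kind = "patterned", run = run,
                          distribution = dist,
                          metrics = community_metrics(dist, seedling_threshold),
                          wavelength = pattern_wavelength(run$state),
                          uniform_reference = uref)
      spatial_state <- run$state
    }
    B_seed <- pmax(if (spatial) rowMeans(stages[[j]]$run$state$B)
                   else uni$B, 1e-10)
  }
  tab <- do.call(rbind, lapply(stages, function(s)
    cbind(data.frame(P = s$P, kind = s$kind, wavelength = s$wavelength),
          s$metrics)))
  structure(list(stages = stages, table = tab,
                 manifest = list(scenario = "downshift",
                                 P_sequence = P_sequence, N = N, nx = nx,
                                 domain = domain, seed = seed,
                                 noise_amplitude = noise_amplitude,
                                 t_uniform = t_uniform,
                                 t_spatial = t_spatial)),
            class = "downshift_run")
}

#' Buffering of community structure along pattern branches
#'
#' Starting from a converged patterned community state, sweeps
#' precipitation downward and continues the pattern by time integration.
#' Along a fixed-wavelength branch the composition (`chi_max`) and
#' richness stay nearly constant while the vegetation patches thin;
#' eventually patches are eliminated (a wavelength-change event) or the
#' system collapses to bare soil (terminal event).
#'
#' @param P_sweep decreasing precipitation values; the first must admit
#'   the starting patterned state.
#' @param start_state a converged patterned [community_state()] at
#'   `P_sweep[1]` (e.g. from [run_downshift()]); if `NULL` one is grown
#'   from noise.
#' @inheritParams run_downshift
#' @param t_per_stage horizon per sweep point, y.
#' @return List of class `buffering_run`: `table` (per-P `chi_max`,
#'   `FR`, `wavelength`, `n_patches`, `patch_width`, `event`), final
#'   `states`, `manifest`.
#' @export
run_buffering <- function(P_sweep = seq(80, 45, by = -5),
                          params = dc_params(), N = params$N,
                          start_state = NULL, nx = 128,
                          domain_wavelengths = 4, seed = 1,
                          t_per_stage = 2e5,
                          seedling_threshold = 1e-3) {
  grid <- trait_grid(N, params)
  tp <- turing_point(1, params)
  domain <- domain_wavelengths * tp$wavelength
  state <- start_state
  if (is.null(state)) {
    p1 <- modify_params(params, P = P_sweep[1])
    uni <- integrate_uniform(grid = grid, params = p1)
    st0 <- make_initial("uniform_community", grid, p1, nx = nx,
                        domain = domain, noise_amplitude = 1e-2,
                        seed = seed, profile = pmax(uni$B, 1e-10))
    state <- integrate_spatial(st0, grid, p1, t_end = 1e6)$state
  }
  rows <- list(); states <- list()
  prev_wl <- pattern_wavelength(state)
  for (j in seq_along(P_sweep)) {
    pj <- modify_params(params, P = P_sweep[j])
    run <- tryCatch(
      integrate_spatial(state, grid, pj, t_end = t_per_stage),
      error = function(e) NULL)
    if (is.null(run)) {
      rows[[j]] <- data.frame(P = P_sweep[j], chi_max = NA, FR = NA,
                              wavelength = NA, n_patches = NA,
                              patch_width = NA, total_biomass = NA,
                              event = "integration_failure")
      break
    }
    state <- run$state
    veg <- max(state$B) > 1e-8
    if (!veg) {
      rows[[j]] <- data.frame(P = P_sweep[j], chi_max = NA, FR = 0,
                              wavelength = NA, n_patches = 0L,
                              patch_width = NA, total_biomass = 0,
                              event = "collapse")
      break
    }
    dist <- biomass_distribution(state)
    wl <- pattern_wavelength(state)
    pp <- patch_properties(state)
    event <- if (!is.na(prev_wl) && !is.na(wl) &&
                 abs(wl - prev_wl) > state$dx) "wavelength_change" else ""
    rows[[j]] <- data.frame(P = P_sweep[j], chi_max = chi_max(dist),
                            FR = functional_richness(dist, seedling_threshold),
                            wavelength = wl, n_patches = pp$n,
                            patch_width = pp$width,
                            total_biomass = sum(dist$B),
                            event = event)
    states[[j]] <- state
    prev_wl <- wl
  }
  structure(list(table = do.call(rbind, rows), states = states,
                 manifest = list(scenario = "buffering", P_sweep = P_sweep,
                                 N = N, nx = nx, domain = domain,
                                 seed = seed, t_per_stage = t_per_stage)),
            class = "buffering_run")
}

# count patches of the total-biomass profile and their mean width at
# half maximum (periodic domain)
patch_properties <- function(state) {
  v <- colSums(state$B)
  thr <- (max(v) + min(v)) / 2
  above <- v > thr
  if (all(above) || all(!above)) return(list(n = 0L, width = NA_real_))
  d <- diff(c(above[length(above)], above))
  n <- sum(d == 1)
  list(n = n, width = sum(above) * state$dx / max(n, 1L))
}

#' Hybrid uniform/patterned community states
#'
#' Within the bistability range of uniform and patterned vegetation,
#' composite initial states -- a patterned subdomain embedded in the
#' uniform community -- relax to stationary hybrid states with pinned
#' fronts.  Niche differentiation between the domains (stress-tolerant
#' groups in the uniform part, fast-growing groups in the patterned
#' part) raises the whole-system functional richness above either pure
#' state, and the relative domain sizes tune the evenness.
#'
#' @param patterned_fractions fractions of the domain initially occupied
#'   by the patterned subdomain.
#' @param params a [dc_params()] object; its `P` (default 100 mm/y)
#'   must lie in the bistability range.
#' @inheritParams run_downshift
#' @param t_end integration horizon per fraction, y.
#' @param front_tol maximal front displacement (in cells) between the
#'   two final snapshots for the hybrid to count as pinned.
#' @param pattern_state optional converged patterned
#'   [community_state()] on the same grid (e.g. the patterned stage of
#'   [run_downshift()]); when absent, a pattern is grown from noise at
#'   `P_pattern` and continued at `P`.
#' @param P_pattern precipitation used to grow the pattern template from
#'   the linear instability (a value below the Turing threshold).
#' @return List of class `hybrid_run`: per-fraction results (`outcome`
#'   one of `"hybrid"`, `"uniform"`, `"patterned"`, `"moving_front"`;
#'   metrics; front displacement; mean trait inside each domain),
#'   reference metrics of the pure states, a `table`, and a `manifest`.
#' @export
run_hybrid <- function(patterned_fractions = c(0.25, 0.5),
                       params = dc_params(P = 100), N = params$N,
                       nx = 128, domain_wavelengths = 4, seed = 1,
                       t_end = 1e5, seedling_threshold = 1e-3,
                       front_tol = 2, pattern_state = NULL,
                       P_pattern = params$P - 20) {
  grid <- trait_grid(N, params)
  tp <- turing_point(1, params)
  domain <- domain_wavelengths * tp$wavelength
  wl <- domain / domain_wavelengths

  # pure uniform reference
  uni <- integrate_uniform(grid = grid, params = params)
  ud <- biomass_distribution(uni)
  uniform_metrics <- community_metrics(ud, seedling_threshold)

  # pure patterned reference at P: grown from the Turing instability at
  # P_pattern if no template is supplied, then continued at P
  if (is.null(pattern_state)) {
    pg <- modify_params(params, P = P_pattern)
    st_g <- make_initial("uniform_community", grid, pg, nx = nx,
                         domain = domain, noise_amplitude = 1e-2,
                         seed = seed, profile = pmax(uni$B, 1e-10))
    pattern_state <- integrate_spatial(st_g, grid, pg, t_end = 1e5)$state
  }
  run_p <- integrate_spatial(pattern_state, grid, params, t_end = t_end)
  pat <- run_p$state
  patterned_metrics <- community_metrics(
    biomass_distribution(pat), seedling_threshold)

  # splice converged patterned and uniform states over a whole number of
  # wavelengths
  wl_cells <- max(1L, round(wl / pat$dx))
  uni_B <- matrix(pmax(uni$B, 1e-10), grid$N, nx)
  res <- lapply(patterned_fractions, function(fr) {
    n_cells <- min(nx, round(fr * nx / wl_cells) * wl_cells)
    mask <- c(rep(TRUE, n_cells), rep(FALSE, nx - n_cells))
    B0 <- uni_B; B0[, mask] <- pat$B[, mask, drop = FALSE]
    st0 <- community_state(B0,
                           ifelse(mask, pat$W, uni$W),
                           ifelse(mask, pat$H, uni$H), pat$dx)
    run <- integrate_spatial(st0, grid, params, t_end = t_end,
                             times = c(0, t_end / 4, t_end / 2,
                                       3 * t_end / 4, t_end))
    n_snap <- length(run$snapshots)
    m_prev <- domain_mask(run$snapshots[[n_snap - 1L]], wl)
    m_fin <- domain_mask(run$snapshots[[n_snap]], wl)
    displacement <- sum(xor(m_prev, m_fin))
    frac_fin <- mean(m_fin)
    outcome <- if (frac_fin > 0.95) "patterned"
               else if (frac_fin < 0.05) "uniform"
               else if (displacement <= front_tol) "hybrid"
               else "moving_front"
    dist <- biomass_distribution(run$state)
    Bp <- run$state$B
    wmean <- function(mask) {
      if (!any(mask)) return(NA_real_)
      prof <- rowMeans(Bp[, mask, drop = FALSE])
      sum(grid$chi * prof) / sum(prof)
    }
    list(fraction = fr, outcome = outcome, run = run,
         displacement = displacement, final_fraction = frac_fin,
         metrics = community_metrics(dist, seedling_threshold),
         chi_mean_patterned = wmean(m_fin),
         chi_mean_uniform = wmean(!m_fin))
  })
  tab <- do.call(rbind, lapply(res, function(r)
    cbind(data.frame(fraction = r$fraction, outcome = r$outcome,
                     final_fraction = r$final_fraction,
                     chi_mean_patterned = r$chi_mean_patterned,
                     chi_mean_uniform = r$chi_mean_uniform),
          r$metrics)))
  structure(list(results = res, table = tab,
                 uniform_metrics = uniform_metrics,
                 patterned_metrics = patterned_metrics,
                 manifest = list(scenario = "hybrid", P = params$P, N = N,
                                 nx = nx, domain = domain, seed = seed,
                                 fractions = patterned_fractions,
                                 t_end = t_end)),
            class = "hybrid_run")
}

#' Classify grid cells as patterned or uniform
#'
#' A cell counts as patterned when the standard deviation of the total
#' biomass within a centred window of one wavelength exceeds
#' `rel_sd_threshold` times the window mean.
#'
#' @param state a [community_state()].
#' @param wavelength window width, m.
#' @param rel_sd_threshold relative-variability cutoff.
#' @return Logical vector over grid cells.
#' @export
domain_mask <- function(state, wavelength, rel_sd_threshold = 0.1) {
  v <- colSums(state$B)
  nx <- length(v)
  w <- max(3L, round(wavelength / state$dx))
  half <- w %/% 2
  idx <- outer(seq_len(nx), -half:half, "+")
  idx <- ((idx - 1L) %% nx) + 1L
  win <- matrix(v[idx], nx)
  m <- rowMeans(win)
  s <- sqrt(pmax(rowMeans(win^2) - m^2, 0))
  s > rel_sd_threshold * pmax(m, 1e-300)
}

#' Write a scenario manifest as JSON
#'
#' @param x a scenario result (`emergence_run`, `downshift_run`,
#'   `buffering_run`, `hybrid_run`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(x$manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
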