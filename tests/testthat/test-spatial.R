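test_that("pattern wavelength is read off the biomass spectrum", {
  dx <- 324 / 128
  x <- (0:127) * dx
  expect_equal(pattern_wavelength(1 + 0.1 * cos(2 * pi * x / 81), dx = dx),
               81)
  v <- 1 + 0.3 * cos(2 * pi * 2 * x / 324) + 0.1 * cos(2 * pi * 6 * x / 324)
  expect_equal(pattern_wavelength(v, dx = dx), 162)   # dominant mode
  expect_true(is.na(pattern_wavelength(rep(2, 128), dx = dx)))
  expect_true(is.na(pattern_wavelength(1 + 1e-5 * cos(2 * pi * x / 81),
                                       dx = dx, contrast_threshold = 1e-3)))
})

test_that("initial-condition generator is reproducible and consistent", {
  p <- dc_params(P = 100, N = 8)
  g <- trait_grid(8, p)
  a <- make_initial("uniform_community", g, p, nx = 64, domain = 300,
                    noise_amplitude = 0.01, seed = 99)
  b <- make_initial("uniform_community", g, p, nx = 64, domain = 300,
                    noise_amplitude = 0.01, seed = 99)
  expect_identical(a$B, b$B)
  # hybrid with zero patterned fraction degenerates to the uniform state
  h0 <- make_initial("hybrid", g, p, nx = 64, domain = 300,
                     patterned_fraction = 0, noise_amplitude = 0.01,
                     seed = 99)
  expect_identical(h0$B, a$B)
  h1 <- make_initial("hybrid", g, p, nx = 64, domain = 300,
                     patterned_fraction = 0.5, wavelength = 75,
                     seed = 99)
  expect_false(identical(h1$B[1, 1], h1$B[1, 64]))
  expect_error(make_initial("what", g, p), "unknown")
  expect_error(make_initial("hybrid", g, p, patterned_fraction = 1.5),
               "patterned_fraction")
})

test_that("uniform states above the Turing point stay uniform", {
  p <- dc_params(P = 100, N = 4, Dchi = 0)
  g <- trait_grid(4, p)
  eq <- uniform_steady_states(100, 1, p)
  veg <- Filter(function(e) e$B > 0, eq)[[1]]
  B <- matrix(0, 4, 96); B[4, ] <- veg$B
  st <- community_state(B, rep(veg$W, 96), rep(veg$H, 96), dx = 300 / 96)
  run <- integrate_spatial(st, g, p, t_end = 200, times = c(0, 200),
                           rtol = 1e-9, atol = 1e-13)
  spread <- max(run$state$B[4, ]) - min(run$state$B[4, ])
  expect_lt(spread / veg$B, 1e-8)
})

test_that("the emerging pattern matches the linear dispersion prediction", {
  # single stress-tolerant group just below its Turing point: the mode
  # that grows from weak noise is the critical one
  p <- dc_params(P = 91, N = 4, Dchi = 0)
  tp <- turing_point(1, p)
  expect_gt(tp$PT, 91)
  g1 <- structure(list(N = 1L, dchi = 1, chi = 1,
                       K = trait_values(1, p)$K, M = trait_values(1, p)$M,
                       Y = trait_values(1, p)$Y), class = "trait_grid")
  nx <- 128
  domain <- 4 * tp$wavelength
  st <- make_initial("single_group", g1, p, nx = nx, domain = domain,
                     chi = 1, noise_amplitude = 1e-3, seed = 4)
  run <- integrate_spatial(st, g1, p, t_end = 4000, times = c(0, 4000))
  wl <- pattern_wavelength(run$state, contrast_threshold = 0.05)
  expect_false(is.na(wl))
  # within one grid spacing of 2*pi/kc (domain-quantised)
  expect_lt(abs(wl - tp$wavelength), domain / nx + 1e-9)
})

test_that("grid refinement leaves the converged pattern unchanged", {
  p <- dc_params(P = 80, N = 4, Dchi = 0)
  g1 <- structure(list(N = 1L, dchi = 1, chi = 1,
                       K = 0.1, M = 0.5, Y = 0.5), class = "trait_grid")
  domain <- 4 * 75.687
  res <- lapply(c(96, 192), function(nx) {
    st <- make_initial("single_group", g1, p, nx = nx, domain = domain,
                       chi = 1, noise_amplitude = 1e-2, seed = 5)
    run <- integrate_spatial(st, g1, p, t_end = 4000, times = c(0, 4000))
    run$state
  })
  n1 <- biomass_norm(res[[1]]); n2 <- biomass_norm(res[[2]])
  expect_equal(n1, n2, tolerance = 0.01)
  w1 <- pattern_wavelength(res[[1]]); w2 <- pattern_wavelength(res[[2]])
  expect_lt(abs(w1 - w2), domain / 96 + 1e-9)
})

test_that("dynamics commute with periodic translations", {
  p <- dc_params(P = 80, N = 4, Dchi = 0)
  g1 <- structure(list(N = 1L, dchi = 1, chi = 1,
                       K = 0.1, M = 0.5, Y = 0.5), class = "trait_grid")
  nx <- 96; domain <- 2 * 75.687
  st <- make_initial("single_group", g1, p, nx = nx, domain = domain,
                     chi = 1, noise_amplitude = 1e-2, seed = 6)
  shift <- 17
  rot <- function(M, m) M[, c((nx - m + 1):nx, 1:(nx - m)), drop = FALSE]
  st_shift <- community_state(rot(st$B, shift),
                              st$W[c((nx - shift + 1):nx, 1:(nx - shift))],
                              st$H[c((nx - shift + 1):nx, 1:(nx - shift))],
                              st$dx)
  r1 <- integrate_spatial(st, g1, p, t_end = 1500, times = c(0, 1500))
  r2 <- integrate_spatial(st_shift, g1, p, t_end = 1500, times = c(0, 1500))
  expect_equal(rot(r1$state$B, shift), r2$state$B, tolerance = 1e-4)
})

test_that("converged patterned states are stationary", {
  p <- dc_params(P = 80, N = 4, Dchi = 0)
  g1 <- structure(list(N = 1L, dchi = 1, chi = 1,
                       K = 0.1, M = 0.5, Y = 0.5), class = "trait_grid")
  st <- make_initial("single_group", g1, p, nx = 96, domain = 2 * 75.687,
                     chi = 1, noise_amplitude = 1e-2, seed = 8)
  run <- integrate_spatial(st, g1, p, t_end = 1e4, steady_tol = 1e-7)
  expect_true(run$converged)
  expect_lt(run$resid, 1e-7)
})
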