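# frozen linearization anchors for chi = 1, computed independently by a
# simultaneous solve of det(J - k^2 D) = 0 and d(det)/d(k^2) = 0 on the
# symbolic Jacobian (threshold precipitation, critical wavenumber)
PT1_expected <- 92.9535
KC1_expected <- 0.083016

test_that("uniform steady states satisfy the fixed-point equations", {
  p <- dc_params(P = 200)
  eqs <- uniform_steady_states(200, 1, p)
  expect_equal(eqs[[1]]$B, 0)
  expect_equal(eqs[[1]]$W, 50)           # P/L0
  expect_equal(eqs[[1]]$H, 500)          # P/(f A)
  veg <- Filter(function(e) e$B > 0, eqs)
  expect_gte(length(veg), 1)
  for (e in veg) {
    tr <- trait_values(1, p)
    lam <- p$Lambda0 * tr$K / (e$B + tr$K)
    # growth balances mortality
    expect_lt(abs(lam * e$W - tr$M), 1e-10)
    # water balance
    I <- infiltration_rate(tr$Y * e$B, p)
    expect_lt(abs(I * e$H - 200), 1e-8)
    expect_lt(abs(I * e$H - evaporation_rate(e$B, p) * e$W -
                    p$Gamma * e$W * e$B), 1e-8)
  }
  expect_error(uniform_steady_states(-5, 1, p), "positive")
})

test_that("a small vegetated root emerges just above the bare-soil threshold", {
  p <- dc_params()
  PB <- bare_soil_threshold(1, p)        # 62.5
  above <- uniform_steady_states(PB + 1, 1, dc_params(P = PB + 1))
  veg <- Filter(function(e) e$B > 0, above)
  expect_gte(length(veg), 1)
  expect_lt(min(vapply(veg, `[[`, numeric(1), "B")), 0.02)
})

test_that("bare-soil threshold closed form agrees with direct simulation", {
  p0 <- dc_params(N = 4, Dchi = 0)
  expect_equal(bare_soil_threshold(1, p0), 62.5)
  expect_equal(bare_soil_threshold(0, p0), 112.5)
  chis <- seq(0, 1, length.out = 9)
  expect_true(all(diff(bare_soil_threshold(chis, p0)) < 0))

  seed_rate <- function(P, chi) {
    p <- dc_params(P = P, N = 4, Dchi = 0)
    tr <- trait_values(chi, p)
    g1 <- structure(list(N = 1L, dchi = 1, chi = chi, K = tr$K,
                         M = tr$M, Y = tr$Y), class = "trait_grid")
    rhs <- function(t, y, parms) {
      d <- uniform_rhs(y[1], y[2], y[3], g1, p)
      list(c(d$dB, d$dW, d$dH))
    }
    bs <- bare_soil_state(p)
    out <- deSolve::ode(c(1e-9, bs$W, bs$H), c(0, 1), rhs, NULL,
                        method = "lsoda", rtol = 1e-12, atol = 1e-20)
    log(out[2, 2] / out[1, 2])
  }
  for (chi in c(0.3, 1)) {
    PB <- bare_soil_threshold(chi, dc_params())
    # growth flips sign within +/- 0.5 mm/y of the closed form
    expect_gt(seed_rate(PB + 0.5, chi), 0)
    expect_lt(seed_rate(PB - 0.5, chi), 0)
  }
})

test_that("dispersion relation at k = 0 matches an independent Jacobian", {
  p <- dc_params(P = 120)
  disp <- dispersion_relation(120, 1, p, k = c(1e-9, 0.05, 0.083))
  eq <- disp$equilibrium
  J_fd <- fd_single_group_jacobian(eq, 1, p)
  sigma0_oracle <- max(Re(eigen(J_fd, only.values = TRUE)$values))
  expect_equal(disp$sigma_max[1], sigma0_oracle, tolerance = 1e-6)
})

test_that("short-wavelength modes are strongly damped", {
  p <- dc_params(P = 100)
  ks <- 2 * pi / c(500, 100, 20, 5, 1)
  disp <- dispersion_relation(100, 1, p, k = ks, refine = FALSE)
  s <- disp$sigma_max
  # decreasing and very negative beyond the pattern-forming band
  expect_lt(s[5], -30)   # dominated by biomass dispersal, -DB*k^2
  expect_lt(s[5], s[4])
  expect_lt(s[4], s[3])
})

test_that("Turing point of the stress-tolerant group matches the frozen anchors", {
  p <- dc_params()
  tp <- turing_point(1, p)
  expect_equal(tp$PT, PT1_expected, tolerance = 1e-3)
  expect_equal(tp$kc, KC1_expected, tolerance = 1e-3)
  expect_equal(tp$wavelength, 2 * pi / KC1_expected, tolerance = 1e-3)
  # maximal growth rate is zero at threshold, at finite wavenumber
  expect_lt(abs(tp$dispersion$sigma_c), 1e-6)
  expect_gt(tp$kc, 0.01)
  expect_error(turing_point(1, p, P_bracket = c(150, 200)), "bracket")
})

test_that("growth-investing groups pattern at higher precipitation", {
  p <- dc_params()
  PT1 <- turing_point(1, p)$PT
  PT0 <- turing_point(0, p, P_bracket = c(113, 250))$PT
  expect_gt(PT0, PT1)
  # the downshift experiment's precipitation stages straddle PT(1)
  expect_gt(PT1, 80)
  expect_lt(PT1, 100)
})

test_that("the pattern branch persists below and above the Turing point", {
  p <- dc_params()
  # subcriticality: sweeping a patterned state upward in P keeps a
  # patterned state beyond PT (bistability with uniform vegetation)
  br <- trace_branch(1, p, P_sweep = c(80, 90, 96), nx = 96,
                     t_per_stage = 3e3, start = "pattern", seed = 3)
  expect_true(all(br$vegetated))
  expect_true(all(!is.na(br$wavelength)))
  # norms stay well above the bare-soil branch
  expect_true(all(br$norm > 0.01))
})


test_that("the linear threshold matches the onset of patterning in simulation", {
  p <- dc_params(N = 4, Dchi = 0)
  tp <- turing_point(1, p)
  g1 <- structure(list(N = 1L, dchi = 1, chi = 1, K = 0.1, M = 0.5,
                       Y = 0.5), class = "trait_grid")
  contrast_at <- function(P) {
    pp <- dc_params(P = P, N = 4, Dchi = 0)
    st <- make_initial("single_group", g1, pp, nx = 96,
                       domain = 2 * tp$wavelength, chi = 1,
                       noise_amplitude = 1e-3, seed = 11)
    run <- integrate_spatial(st, g1, pp, t_end = 4000, times = c(0, 4000))
    v <- colSums(run$state$B)
    (max(v) - min(v)) / mean(v)
  }
  # weak noise grows into a pattern below PT and decays above it,
  # bracketing the threshold to better than 2 mm/y
  expect_gt(contrast_at(tp$PT - 1.5), 0.5)
  expect_lt(contrast_at(tp$PT + 1.5), 0.05)
})
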