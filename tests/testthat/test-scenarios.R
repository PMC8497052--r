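# scenario-layer checks run at reduced size (N = 16/32, short horizons);
# the full-scale experiments live in the acceptance suite

test_that("emergence: exclusion without mutations, finite width with them", {
  p <- dc_params(P = 180, N = 32)
  em <- run_emergence(params = p, Dchi_values = c(0, 1e-6), N = 32,
                      t_end = 1e7)
  r0 <- em$results$Dchi_0
  r1 <- em$results$`Dchi_1e-06`
  expect_lte(r0$n_occupied, 2)          # competitive exclusion
  expect_gt(r1$n_above_threshold / 32, 0.25)   # finite-width community
  expect_gt(r0$metrics$total_biomass, 0)
  expect_gt(r1$metrics$total_biomass, 0)
  expect_true(is.finite(r1$metrics$FR))
})

test_that("downshift reproduces reassembly, reversal and biomass gain", {
  p <- dc_params(N = 32)
  ds <- run_downshift(P_sequence = c(150, 100, 80), params = p, N = 32,
                      nx = 96, seed = 1, t_uniform = 2e6, t_spatial = 2e5)
  tab <- ds$table
  expect_identical(tab$kind, c("uniform", "uniform", "patterned"))
  # uniform stage: drier -> more stress-tolerant, poorer
  expect_gt(tab$chi_max[2], tab$chi_max[1])
  expect_lt(tab$FR[2], tab$FR[1])
  # patterned stage: reversal of both trends
  expect_lt(tab$chi_max[3], tab$chi_max[2])
  expect_gt(tab$FR[3], tab$FR[2])
  # patterning gains biomass over the (unstable) uniform equilibrium
  uref <- ds$stages[[3]]$uniform_reference
  expect_gt(tab$total_biomass[3], uref$total_biomass)
  expect_false(is.na(tab$wavelength[3]))
})

test_that("scenario runs are reproducible from their manifests", {
  p <- dc_params(N = 16)
  ds1 <- run_downshift(P_sequence = c(150, 100, 80), params = p, N = 16,
                       nx = 96, seed = 7, t_uniform = 1e6, t_spatial = 1e4)
  ds2 <- run_downshift(P_sequence = c(150, 100, 80), params = p, N = 16,
                       nx = 96, seed = 7, t_uniform = 1e6, t_spatial = 1e4)
  expect_equal(ds1$table$chi_max, ds2$table$chi_max, tolerance = 1e-12)
  expect_equal(ds1$table$total_biomass, ds2$table$total_biomass,
               tolerance = 1e-12)
  expect_identical(ds1$stages[[3]]$run$state$B, ds2$stages[[3]]$run$state$B)
  path <- tempfile(fileext = ".json")
  write_manifest(ds1, path)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(man$scenario, "downshift")
  expect_equal(man$seed, 7)
  unlink(path)
})

test_that("domain classification separates patterned from uniform cells", {
  p <- dc_params(N = 4)
  g <- trait_grid(4, p)
  nx <- 96; dx <- 300 / 96
  x <- (seq_len(nx) - 1) * dx
  B <- matrix(0.05, 4, nx)
  patterned <- x < 150
  B[, patterned] <- B[, patterned] *
    rep(1 + cos(2 * pi * x[patterned] / 75), each = 4)
  st <- community_state(B, rep(1, nx), rep(1, nx), dx)
  mask <- domain_mask(st, 75)
  # the bulk of each half is classified correctly (edges are ambiguous)
  core_p <- patterned & x > 20 & x < 130
  core_u <- !patterned & x > 190 & x < 260  # clear of the periodic wrap
  expect_true(all(mask[core_p]))
  expect_true(all(!mask[core_u]))
})

test_that("patch properties count bumps and their half-max width", {
  p <- dc_params(N = 4)
  nx <- 120; dx <- 300 / nx
  x <- (seq_len(nx) - 1) * dx
  B <- matrix(rep(1 + cos(2 * pi * 4 * x / 300), each = 4) / 4, 4, nx)
  st <- community_state(B, rep(1, nx), rep(1, nx), dx)
  pp <- drycomm:::patch_properties(st)
  expect_equal(pp$n, 4L)
  expect_equal(pp$width, 300 / 8, tolerance = 0.1)   # half of each period
})

test_that("patterned communities buffer further drying", {
  p <- dc_params(N = 16)
  ds <- run_downshift(P_sequence = c(100, 80), params = p, N = 16,
                      nx = 96, seed = 2, t_uniform = 1e6, t_spatial = 5e4)
  bf <- run_buffering(P_sweep = c(80, 70, 60), params = p, N = 16,
                      start_state = ds$stages[[2]]$run$state, nx = 96,
                      seed = 2, t_per_stage = 5e4)
  tab <- bf$table
  expect_true(all(tab$event == ""))
  # composition pinned to within one trait bin, richness nearly constant
  expect_lte(diff(range(tab$chi_max)), 1 / 16 + 1e-12)
  expect_lt(diff(range(tab$FR)), 0.03)
  # patches thin and productivity falls as the branch is descended
  expect_true(all(diff(tab$patch_width) < 0))
  expect_true(all(diff(tab$total_biomass) < 0))
  expect_equal(tab$wavelength[1], tab$wavelength[3])
})
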