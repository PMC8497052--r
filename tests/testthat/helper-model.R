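# shared fixtures: small, fast configurations used across test files

p_ref <- dc_params()                 # reference parameter set
p_small <- dc_params(N = 16)
g_small <- trait_grid(16, p_small)

# forward-difference Jacobian of the single-group reaction terms,
# independent of the analytic Jacobian used by dispersion_relation()
fd_single_group_jacobian <- function(eq, chi, params, h = 1e-7) {
  tr <- trait_values(chi, params)
  f <- function(v) {
    B <- v[1]; W <- v[2]; H <- v[3]
    Lam <- params$Lambda0 * tr$K / (B + tr$K)
    I <- params$A * (tr$Y * B + params$f * params$Q) /
      (tr$Y * B + params$Q)
    L <- params$L0 / (1 + params$R * B)
    c(Lam * W * B - tr$M * B,
      I * H - L * W - params$Gamma * W * B,
      params$P - I * H)
  }
  v0 <- c(eq$B, eq$W, eq$H)
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    d <- h * max(1, abs(v0[j]))
    vp <- v0; vp[j] <- vp[j] + d
    vm <- v0; vm[j] <- vm[j] - d
    J[, j] <- (f(vp) - f(vm)) / (2 * d)
  }
  J
}

# smooth reference hump used for metric discretization checks
hump_profile <- function(N, centre = 0.6, width = 0.1, amp = 1.5) {
  chi <- seq_len(N) / N
  amp * exp(-((chi - centre) / width)^2) / N
}

# parameter set with a different precipitation
modify_P <- function(p, P) do.call(dc_params, modifyList(unclass(p), list(P = P)))
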