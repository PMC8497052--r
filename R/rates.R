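#' Local rate functions of the community model
#'
#' The reaction part of the model is built from three biomass-dependent
#' rates, evaluated pointwise in space:
#' growth `Lambda_i = Lambda0 K_i / (Bbar + K_i)` (shading-limited, with
#' `Bbar` the total biomass), infiltration
#' `I = A (Bbb + f Q) / (Bbb + Q)` (with `Bbb` the Y-weighted biomass),
#' and evaporation `L = L0 / (1 + R Bbar)` (shading-reduced).
#'
#' @param B_total total biomass `Bbar = sum_j B_j`, kg/m^2 (scalar or
#'   vector over grid points).
#' @param grid a [trait_grid()].
#' @param params a [dc_params()] object.
#' @return `growth_rates()`: matrix (groups x points) or vector of
#'   per-group growth rates, m^2/(kg y).
#' @examples
#' p <- dc_params(); g <- trait_grid(8, p)
#' growth_rates(0, g, p)          # all equal Lambda0
#' infiltration_rate(0, p)        # bare-soil value f*A
#' evaporation_rate(0.1, p)
#' @export
growth_rates <- function(B_total, grid, params) {
  if (any(!is.finite(B_total)) || any(B_total < 0))
    stop("total biomass must be finite and non-negative", call. = FALSE)
  r <- params$Lambda0 * grid$K / outer(grid$K, B_total, "+")
  if (length(B_total) == 1L) drop(r) else r
}

#' @param B_weighted infiltration-weighted biomass `Bbb = sum_j Y_j B_j`,
#'   kg/m^2.
#' @rdname growth_rates
#' @return `infiltration_rate()`: infiltration rate(s) in `[f A, A]`, 1/y.
#' @export
infiltration_rate <- function(B_weighted, params) {
  if (any(!is.finite(B_weighted)) || any(B_weighted < 0))
    stop("weighted biomass must be finite and non-negative", call. = FALSE)
  params$A * (B_weighted + params$f * params$Q) / (B_weighted + params$Q)
}

#' @rdname growth_rates
#' @return `evaporation_rate()`: evaporation rate(s) in `(0, L0]`, 1/y.
#' @export
evaporation_rate <- function(B_total, params) {
  if (any(!is.finite(B_total)) || any(B_total < 0))
    stop("total biomass must be finite and non-negative", call. = FALSE)
  params$L0 / (1 + params$R * B_total)
}

#' Discrete trait-diffusion operator
#'
#' Second difference along the trait axis, `N^2 (B_{i+1} - 2 B_i +
#' B_{i-1})`, modelling mutations to neighbouring functional groups.
#' Zero-flux boundaries are realised by reflecting ghost bins
#' (`B_0 = B_1`, `B_{N+1} = B_N`), which makes the operator conserve
#' total biomass exactly: its output sums to zero along the trait axis.
#'
#' @param B numeric vector of length `N`, or an `N x Nx` matrix (groups by
#'   grid points); the operator acts along the trait (first) dimension.
#' @param N number of functional groups; defaults to the trait dimension
#'   of `B`.
#' @return Same shape as `B`.
#' @examples
#' trait_laplacian(c(0, 1, 0, 0))   # 16 * (1, -2, 1, 0)
#' @export
trait_laplacian <- function(B, N = if (is.matrix(B)) nrow(B) else length(B)) {
  if (is.matrix(B)) {
    if (nrow(B) != N) stop("trait dimension mismatch", call. = FALSE)
    if (N < 2) return(0 * B)
    up <- rbind(B[1L, , drop = FALSE], B[-N, , drop = FALSE])
    dn <- rbind(B[-1L, , drop = FALSE], B[N, , drop = FALSE])
    N^2 * (up - 2 * B + dn)
  } else {
    if (length(B) != N) stop("trait dimension mismatch", call. = FALSE)
    if (N < 2) return(0 * B)
    N^2 * (c(B[1L], B[-N]) - 2 * B + c(B[-1L], B[N]))
  }
}
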