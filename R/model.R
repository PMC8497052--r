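#' Right-hand side of the community model
#'
#' Evaluates the tendencies of the full spatial model on a periodic 1-D
#' grid:
#' \deqn{\partial_t B_i = \Lambda_i W B_i - M_i B_i
#'       + D_B \partial_x^2 B_i + D_\chi \partial_\chi^2 B_i,}
#' \deqn{\partial_t W = I H - L W - \Gamma W \bar B
#'       + D_W \partial_x^2 W,}
#' \deqn{\partial_t H = P - I H + D_H \partial_x (H^\alpha \partial_x H),}
#' with all local rates computed pointwise in x and second-order central
#' differences for the spatial operators.  With the default `alpha = 0`
#' surface water spreads by linear diffusion.
#'
#' @param state a [community_state()].
#' @param grid a [trait_grid()] with the same number of groups.
#' @param params a [dc_params()] object.
#' @return A list with fields `dB` (matrix), `dW`, `dH` (vectors), in
#'   units of kg/(m^2 y).
#' @export
community_rhs <- function(state, grid, params) {
  if (nrow(state$B) != grid$N)
    stop("state and trait grid disagree on the number of groups",
         call. = FALSE)
  if (any(!is.finite(state$B)) || min(state$B) < 0 ||
      any(!is.finite(state$W)) || any(!is.finite(state$H)))
    stop("invalid state: fields must be finite and non-negative",
         call. = FALSE)
  d <- rhs_fields(state$B, state$W, state$H, grid, params, state$dx)
  list(dB = d$dB, dW = d$dW, dH = d$dH)
}

# core tendency computation shared by community_rhs and the integrators;
# B is N x Nx, W/H length Nx
rhs_fields <- function(B, W, H, grid, params, dx) {
  Bbar <- colSums(B)
  Bbb <- colSums(grid$Y * B)
  Lam <- params$Lambda0 * grid$K / outer(grid$K, Bbar, "+")
  I <- params$A * (Bbb + params$f * params$Q) / (Bbb + params$Q)
  L <- params$L0 / (1 + params$R * Bbar)
  dB <- sweep(Lam, 2, W, "*") * B - grid$M * B +
    params$DB * lap_x(B, dx) + params$Dchi * trait_laplacian(B, grid$N)
  dW <- I * H - L * W - params$Gamma * W * Bbar + params$DW * lap_xv(W, dx)
  dH <- params$P - I * H + params$DH * flow_term(H, params$alpha, dx)
  list(dB = dB, dW = dW, dH = dH)
}

# periodic second difference along columns of an N x Nx matrix
lap_x <- function(B, dx) {
  nx <- ncol(B)
  (cbind(B[, nx, drop = FALSE], B[, -nx, drop = FALSE]) - 2 * B +
     cbind(B[, -1L, drop = FALSE], B[, 1L, drop = FALSE])) / dx^2
}

lap_xv <- function(v, dx) {
  nx <- length(v)
  (c(v[nx], v[-nx]) - 2 * v + c(v[-1L], v[1L])) / dx^2
}

# overland-flow operator d/dx (H^alpha dH/dx); alpha = 0 reduces to the
# plain Laplacian, alpha > 0 uses a conservative flux form with midpoint
# face values
flow_term <- function(H, alpha, dx) {
  if (alpha == 0) return(lap_xv(H, dx))
  nx <- length(H)
  Hr <- c(H[-1L], H[1L])
  face <- ((H + Hr) / 2)^alpha * (Hr - H) / dx   # flux at i+1/2
  (face - c(face[nx], face[-nx])) / dx
}

# rhs in the flat layout used by the deSolve integrators:
# y = c(B[1, 1:Nx], ..., B[N, 1:Nx], W, H)
rhs_flat <- function(grid, params, nx, dx) {
  N <- grid$N
  iW <- N * nx + seq_len(nx)
  iH <- (N + 1L) * nx + seq_len(nx)
  function(t, y, parms) {
    B <- matrix(y[seq_len(N * nx)], N, nx, byrow = TRUE)
    d <- rhs_fields(B, y[iW], y[iH], grid, params, dx)
    list(c(t(d$dB), d$dW, d$dH))
  }
}

state_to_flat <- function(state) c(t(state$B), state$W, state$H)

flat_to_state <- function(y, N, nx, dx, t = 0, clip_tol = 1e-10) {
  # stiff integrators can undershoot zero at round-off level; clip tiny
  # negatives, fail on anything larger
  low <- min(y)
  if (low < -clip_tol)
    stop(sprintf("integration produced negative fields (min %.3g)", low),
         call. = FALSE)
  y <- pmax(y, 0)
  community_state(matrix(y[seq_len(N * nx)], N, nx, byrow = TRUE),
                  y[N * nx + seq_len(nx)],
                  y[(N + 1L) * nx + seq_len(nx)],
                  dx, t)
}

#' Right-hand side of the spatially decoupled model
#'
#' Tendencies of the mean-field system obtained by dropping all spatial
#' derivatives: `N` biomass bins coupled through competition for water
#' and light plus trait diffusion, one soil-water and one surface-water
#' variable.
#'
#' @param B numeric vector of per-bin biomass (length `N`).
#' @param W,H scalar water contents, kg/m^2.
#' @inheritParams community_rhs
#' @return List with `dB` (length `N`), `dW`, `dH`.
#' @export
uniform_rhs <- function(B, W, H, grid, params) {
  if (length(B) != grid$N) stop("length(B) must equal N", call. = FALSE)
  Bbar <- sum(B)
  Bbb <- sum(grid$Y * B)
  Lam <- params$Lambda0 * grid$K / (Bbar + grid$K)
  I <- params$A * (Bbb + params$f * params$Q) / (Bbb + params$Q)
  L <- params$L0 / (1 + params$R * Bbar)
  list(dB = Lam * W * B - grid$M * B +
         params$Dchi * trait_laplacian(B, grid$N),
       dW = I * H - L * W - params$Gamma * W * Bbar,
       dH = params$P - I * H)
}
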