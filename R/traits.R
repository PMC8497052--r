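#' Build the trait grid of functional groups
#'
#' Divides the tradeoff axis `chi` in (0, 1] into `N` functional groups,
#' `chi_i = i/N`, and assigns each group its traits through the linear
#' tradeoff relations
#' \deqn{K(\chi) = K_{max} + \chi (K_{min} - K_{max}),}
#' \deqn{M(\chi) = M_{max} + \chi (M_{min} - M_{max}),}
#' \deqn{Y(\chi) = Y_{max} + \chi (Y_{min} - Y_{max}).}
#' Groups near `chi = 0` invest in shoot growth (high light-capture
#' capacity K, high mortality M, high infiltration contribution Y);
#' groups near `chi = 1` invest in stress tolerance (low K, M, Y).
#'
#' @param N number of functional groups (integer, at least 2).
#' @param params a [dc_params()] object supplying the trait extremes.
#' @return An object of class `trait_grid`: a list with `N`, `dchi = 1/N`,
#'   and numeric vectors `chi`, `K`, `M`, `Y` of length `N`.
#' @examples
#' g <- trait_grid(128, dc_params())
#' g$K[g$N]   # K(1) = Kmin
#' @export
trait_grid <- function(N, params = dc_params()) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) ||
      N < 2 || N != round(N))
    stop("'N' must be an integer >= 2", call. = FALSE)
  N <- as.integer(N)
  chi <- seq_len(N) / N
  g <- list(N = N, dchi = 1 / N, chi = chi,
            K = params$Kmax + chi * (params$Kmin - params$Kmax),
            M = params$Mmax + chi * (params$Mmin - params$Mmax),
            Y = params$Ymax + chi * (params$Ymin - params$Ymax))
  structure(g, class = "trait_grid")
}

#' Trait values at arbitrary tradeoff positions
#'
#' Evaluates the tradeoff relations at any `chi` in `[0, 1]` (not only at
#' grid positions); used by the single-group stability analysis.
#'
#' @param chi tradeoff value(s) in `[0, 1]`.
#' @inheritParams trait_grid
#' @return A list with numeric fields `K`, `M`, `Y`.
#' @export
trait_values <- function(chi, params = dc_params()) {
  if (any(!is.finite(chi)) || any(chi < 0 | chi > 1))
    stop("'chi' must lie in [0, 1]", call. = FALSE)
  list(K = params$Kmax + chi * (params$Kmin - params$Kmax),
       M = params$Mmax + chi * (params$Mmin - params$Mmax),
       Y = params$Ymax + chi * (params$Ymin - params$Ymax))
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("<trait_grid> N = %d groups, dchi = %.4g\n", x$N, x$dchi))
  cat(sprintf("  K: %.3g .. %.3g | M: %.3g .. %.3g | Y: %.3g .. %.3g\n",
              x$K[1], x$K[x$N], x$M[1], x$M[x$N], x$Y[1], x$Y[x$N]))
  invisible(x)
}
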