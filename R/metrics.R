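#' Space-averaged biomass distribution along the trait axis
#'
#' The object all community metrics act on: the trait grid positions
#' `chi_i` together with the space-averaged per-bin biomass `B_i`
#' (kg/m^2).  Extracted from a [community_state()] (averaging over x),
#' a [integrate_uniform()] result, or built directly from vectors.
#'
#' @param x a `community_state`, a `uniform_run`, or a numeric biomass
#'   vector.
#' @param chi trait positions (required for a plain vector).
#' @return An object of class `biomass_distribution`: list with `chi`,
#'   `B`, `N`.
#' @export
biomass_distribution <- function(x, chi = NULL) {
  if (inherits(x, "community_state")) {
    B <- rowMeans(x$B)
    N <- nrow(x$B)
    chi <- seq_len(N) / N
  } else if (inherits(x, "uniform_run")) {
    B <- x$B
    chi <- x$grid$chi
    N <- x$grid$N
  } else {
    B <- as.numeric(x)
    if (is.null(chi)) stop("'chi' required for a plain vector", call. = FALSE)
    if (length(chi) != length(B)) stop("length mismatch", call. = FALSE)
    N <- length(B)
  }
  if (any(!is.finite(B)) || any(B < 0))
    stop("biomass must be finite and non-negative", call. = FALSE)
  structure(list(chi = chi, B = B, N = N), class = "biomass_distribution")
}

as_distribution <- function(x, chi = NULL) {
  if (inherits(x, "biomass_distribution")) x else biomass_distribution(x, chi)
}

#' Community composition and diversity metrics
#'
#' `chi_max()` is the trait value of the most abundant functional group
#' (ties broken toward lower `chi`).  `shannon_index()` is the Shannon
#' analogue on biomass shares, `H' = -sum b_i log b_i` with
#' `b_i = B_i / sum B_j`.  `pielou_evenness()` is `H' / log N` with `N`
#' the full grid size, zero bins included.
#'
#' @param dist a [biomass_distribution()] (or anything coercible).
#' @return `chi_max()`: a trait value; `shannon_index()`: `H'` in
#'   `[0, log N]`; `pielou_evenness()`: evenness in `[0, 1]`.
#' @examples
#' d <- biomass_distribution(c(0, 2, 1), chi = c(0.25, 0.5, 0.75))
#' chi_max(d)
#' shannon_index(biomass_distribution(c(1, 1), chi = c(0.5, 1)))  # log(2)
#' @export
chi_max <- function(dist) {
  d <- as_distribution(dist)
  if (sum(d$B) <= 0)
    stop("chi_max undefined for an all-zero distribution", call. = FALSE)
  d$chi[which.max(d$B)]
}

#' Functional richness: occupied width of the trait axis
#'
#' The width in `chi` of the region where the biomass distribution
#' exceeds a small "seedling" threshold, with linear interpolation of
#' the crossing positions between bins (which removes the leading-order
#' N-dependence of the width estimate).  The threshold refers to the
#' trait-space biomass density `b = N * B` (kg/m^2 per unit trait), the
#' representation in which the distribution's amplitude does not change
#' with the number of bins; set `density = FALSE` to threshold the raw
#' per-bin biomass instead.
#'
#' @param dist a [biomass_distribution()].
#' @param seedling_threshold threshold biomass density, kg/m^2.
#' @param density logical; threshold the N-independent density `N * B`
#'   (default) or the per-bin biomass.
#' @return Width in trait units, in `[0, 1]`; 0 when no bin exceeds the
#'   threshold.
#' @export
functional_richness <- function(dist, seedling_threshold = 1e-3,
                                density = TRUE) {
  if (seedling_threshold <= 0)
    stop("'seedling_threshold' must be positive", call. = FALSE)
  d <- as_distribution(dist)
  v <- if (density) d$N * d$B else d$B
  above <- which(v > seedling_threshold)
  if (!length(above)) return(0)
  lo <- min(above); hi <- max(above)
  n <- length(v)
  dchi <- if (n > 1) d$chi[2] - d$chi[1] else 1
  chi_lo <- if (lo == 1L) d$chi[1] else
    d$chi[lo - 1] + dchi * (seedling_threshold - v[lo - 1]) /
      (v[lo] - v[lo - 1])
  chi_hi <- if (hi == n) d$chi[n] else
    d$chi[hi] + dchi * (v[hi] - seedling_threshold) / (v[hi] - v[hi + 1])
  chi_hi - chi_lo
}

#' @rdname chi_max
#' @export
shannon_index <- function(dist) {
  d <- as_distribution(dist)
  tot <- sum(d$B)
  if (tot <= 0)
    stop("Shannon index undefined for zero total biomass", call. = FALSE)
  b <- d$B / tot
  -sum(b[b > 0] * log(b[b > 0]))
}

#' @rdname chi_max
#' @param N number of trait bins used in the normalisation `log N`;
#'   defaults to the distribution's own grid size.
#' @export
pielou_evenness <- function(dist, N = NULL) {
  d <- as_distribution(dist)
  if (is.null(N)) N <- d$N
  if (N < 2) stop("'N' must be at least 2", call. = FALSE)
  shannon_index(d) / log(N)
}

#' All community metrics at once
#'
#' @param dist a [biomass_distribution()].
#' @param seedling_threshold passed to [functional_richness()].
#' @return One-row data frame: `chi_max`, `FR`, `H`, `FE`,
#'   `total_biomass`.
#' @export
community_metrics <- function(dist, seedling_threshold = 1e-3) {
  d <- as_distribution(dist)
  data.frame(chi_max = chi_max(d),
             FR = functional_richness(d, seedling_threshold),
             H = shannon_index(d),
             FE = pielou_evenness(d),
             total_biomass = sum(d$B))
}
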