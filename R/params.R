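#' Model parameters for the dryland community model
#'
#' Constructs the full parameter set of the trait-structured
#' vegetation--water model.  Defaults are the reference parameter set used
#' throughout the package: a water-limited ecosystem in which overland
#' water flow and differential infiltration destabilise uniform vegetation
#' towards periodic patterns.
#'
#' The model couples N functional-group biomass densities `B_i` (kg/m^2),
#' soil water `W` and surface water `H` (both kg/m^2).  Precipitation `P`
#' is stated in mm/y; one mm of rain over one m^2 weighs one kg, so mm/y
#' and kg/(m^2 y) are used interchangeably.
#'
#' @param Lambda0 growth rate at zero biomass, m^2/(kg y).
#' @param Gamma water-uptake rate, m^2/(kg y).
#' @param f infiltration contrast in `[0, 1]`; small values mean strongly
#'   differential infiltration (low in bare soil, high under vegetation).
#' @param A maximal infiltration rate, 1/y.
#' @param Q reference biomass at which infiltration is about `A/2` for
#'   small `f`, kg/m^2.
#' @param L0 bare-soil evaporation rate, 1/y.
#' @param R shading reduction of evaporation, m^2/kg.
#' @param Kmin,Kmax extremes of the light-capture capacity K, kg/m^2.
#' @param Mmin,Mmax extremes of the mortality rate M, 1/y.
#' @param Ymin,Ymax extremes of the relative infiltration contribution Y
#'   (dimensionless).
#' @param P precipitation rate, mm/y.
#' @param N number of functional groups along the tradeoff axis.
#' @param DB biomass dispersal coefficient, m^2/y.
#' @param DW soil-water diffusion coefficient, m^2/y.
#' @param DH surface-water diffusion coefficient, m^2/y.
#' @param Dchi trait-diffusion (mutation) rate, 1/y.
#' @param alpha overland-flow nonlinearity exponent; 0 (the default) gives
#'   linear surface-water diffusion.
#'
#' @return An object of class `dc_params` (a validated named list).
#' @examples
#' p <- dc_params()
#' p$P
#' dc_params(P = 80)$P
#' @export
dc_params <- function(Lambda0 = 0.032, Gamma = 20, f = 0.01, A = 40,
                      Q = 0.06, L0 = 4, R = 10,
                      Kmin = 0.1, Kmax = 0.6,
                      Mmin = 0.5, Mmax = 0.9,
                      Ymin = 0.5, Ymax = 1.5,
                      P = 150, N = 128,
                      DB = 1, DW = 100, DH = 1e4,
                      Dchi = 1e-6, alpha = 0) {
  p <- list(Lambda0 = Lambda0, Gamma = Gamma, f = f, A = A, Q = Q,
            L0 = L0, R = R, Kmin = Kmin, Kmax = Kmax, Mmin = Mmin,
            Mmax = Mmax, Ymin = Ymin, Ymax = Ymax, P = P, N = N,
            DB = DB, DW = DW, DH = DH, Dchi = Dchi, alpha = alpha)
  validate_params(p)
  structure(p, class = "dc_params")
}

validate_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p))
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar",
                             call. = FALSE)
  pos <- c("Gamma", "A", "Q", "L0", "R", "Kmin", "Kmax",
           "Mmax", "Ymin", "Ymax", "P", "DB", "DW", "DH")
  for (nm in pos)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be positive",
                           call. = FALSE)
  # Lambda0 = 0 and Mmin = 0 are admitted so growth/mortality can be
  # switched off in transport-only configurations
  if (p$Lambda0 < 0) stop("'Lambda0' must be non-negative", call. = FALSE)
  if (p$Mmin < 0) stop("'Mmin' must be non-negative", call. = FALSE)
  if (p$f < 0 || p$f > 1) stop("'f' must lie in [0, 1]", call. = FALSE)
  if (p$Kmin >= p$Kmax) stop("'Kmin' must be smaller than 'Kmax'", call. = FALSE)
  if (p$Mmin >= p$Mmax) stop("'Mmin' must be smaller than 'Mmax'", call. = FALSE)
  if (p$Ymin >= p$Ymax) stop("'Ymin' must be smaller than 'Ymax'", call. = FALSE)
  if (p$N < 2 || p$N != round(p$N)) stop("'N' must be an integer >= 2",
                                         call. = FALSE)
  if (p$Dchi < 0) stop("'Dchi' must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.dc_params <- function(x, ...) {
  cat("<dc_params> dryland community model parameters\n")
  cat(sprintf("  P = %g mm/y, N = %d groups, Dchi = %g 1/y, alpha = %g\n",
              x$P, as.integer(x$N), x$Dchi, x$alpha))
  cat(sprintf("  growth: Lambda0 = %g; uptake: Gamma = %g; mortality M in [%g, %g]\n",
              x$Lambda0, x$Gamma, x$Mmin, x$Mmax))
  cat(sprintf("  infiltration: A = %g, f = %g, Q = %g, Y in [%g, %g]\n",
              x$A, x$f, x$Q, x$Ymin, x$Ymax))
  cat(sprintf("  evaporation: L0 = %g, R = %g; K in [%g, %g]\n",
              x$L0, x$R, x$Kmin, x$Kmax))
  cat(sprintf("  transport: DB = %g, DW = %g, DH = %g m^2/y\n",
              x$DB, x$DW, x$DH))
  invisible(x)
}

#' Read or write model parameters as a configuration file
#'
#' Parameters are stored as a flat YAML or JSON mapping using the field
#' names of [dc_params()].  Unknown keys are rejected; missing keys fall
#' back to the defaults.
#'
#' @param path file path; the format is chosen by extension
#'   (`.yml`/`.yaml` or `.json`).
#' @param params a `dc_params` object (for writing).
#' @return `read_params()` returns a `dc_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    "yml"  = ,
    "yaml" = yaml::read_yaml(path),
    "json" = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: '", ext, "'", call. = FALSE))
  unknown <- setdiff(names(vals), names(formals(dc_params)))
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(dc_params, vals)
}

#' @rdname read_params
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "dc_params"))
  ext <- tolower(tools::file_ext(path))
  x <- unclass(params)
  switch(ext,
    "yml"  = ,
    "yaml" = yaml::write_yaml(x, path),
    "json" = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported config format: '", ext, "'", call. = FALSE))
  invisible(path)
}
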