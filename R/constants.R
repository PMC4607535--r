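#' Kinetic constants of the reporter system
#'
#' Fixed rate constants of the mRNA/protein/fluorescence layer.  These are
#' configuration constants of the model, not sampled parameters: the per-copy
#' transcription rates are only identified relative to them (and to the
#' copy-number anchor), so their absolute values set the unit system.
#'
#' @param delta_M mRNA degradation rate (1/min).  Default 0.01 (half-life
#'   about 70 min, typical for a reporter transcript).
#' @param delta_P protein degradation rate (1/min).  Default 5e-4: the Venus
#'   class of fluorescent proteins is stable on the time scale of a two-day
#'   movie.
#' @param alpha translation rate (1/min per mRNA).
#' @param kappa fluorescence gain (AU per protein molecule); must be positive.
#' @param sigma2 measurement-noise variance (AU^2) of the Gaussian
#'   observation model F(t) = kappa * P(t) + noise.
#'
#' @return An object of class `kinetic_constants`.
#' @examples
#' kinetic_constants()
#' @export
kinetic_constants <- function(delta_M = 0.01, delta_P = 5e-4, alpha = 1,
                              kappa = 1, sigma2 = 4e4) {
  stopifnot(is.numeric(delta_M), is.numeric(delta_P), is.numeric(alpha),
            is.numeric(kappa), is.numeric(sigma2))
  if (delta_M < 0 || delta_P < 0 || alpha < 0)
    stop("degradation and translation rates must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  structure(list(delta_M = delta_M, delta_P = delta_P, alpha = alpha,
                 kappa = kappa, sigma2 = sigma2),
            class = "kinetic_constants")
}

#' @export
print.kinetic_constants <- function(x, ...) {
  cat("Kinetic constants:\n")
  cat(sprintf("  delta_M = %g /min   delta_P = %g /min\n", x$delta_M, x$delta_P))
  cat(sprintf("  alpha   = %g /min   kappa   = %g AU/molecule\n", x$alpha, x$kappa))
  cat(sprintf("  sigma2  = %g AU^2 (measurement noise)\n", x$sigma2))
  invisible(x)
}

#' Per-cell latent parameters
#'
#' Validates a table of per-cell latent quantities of the telegraph-switch
#' model: plasmid copy number `c`, basal and active per-copy transcription
#' rates `tau0 <= tau1`, switch time `T` and initial molecule numbers
#' `M0`, `P0`.
#'
#' @param c,tau0,tau1,T,M0,P0 numeric vectors of equal length.
#' @param duration length of the observation window (min); `T` must fall in
#'   `[0, duration]`.
#' @return A `data.frame` with one row per cell, classed `cell_params`.
#' @export
cell_params <- function(c, tau0, tau1, T, M0, P0, duration = 2880) {
  df <- data.frame(c = c, tau0 = tau0, tau1 = tau1, T = T, M0 = M0, P0 = P0)
  validate_cell_params(df, duration)
  class(df) <- c("cell_params", "data.frame")
  df
}

#' @rdname cell_params
#' @param params a data frame of per-cell parameters.
#' @export
validate_cell_params <- function(params, duration = 2880) {
  need <- c("c", "tau0", "tau1", "T", "M0", "P0")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing cell parameter columns: ",
                         paste(miss, collapse = ", "))
  with(params, {
    if (any(!is.finite(c)) || any(c <= 0)) stop("copy number must be > 0")
    if (any(tau0 < 0)) stop("tau0 must be >= 0")
    if (any(tau1 < tau0)) stop("tau0 <= tau1 violated")
    if (any(T < 0 | T > duration)) stop("switch time outside [0, duration]")
    if (any(M0 < 0) || any(P0 < 0)) stop("initial molecule numbers must be >= 0")
  })
  invisible(params)
}
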