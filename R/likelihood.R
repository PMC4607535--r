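#' Log-likelihood of a fluorescence trace
#'
#' Gaussian state-space approximation for the telegraph-switch reporter
#' model: the latent (mRNA, protein) mean is propagated between observation
#' times by the drift ODE, the process covariance is accumulated from the
#' chemical-Langevin diffusion evaluated along the predicted mean
#' (continuous-discrete Gaussian filter), and each observation is
#' assimilated under `F = kappa P + N(0, sigma2)`.
#'
#' Because copy number and transcription rate enter the drift and the
#' diffusion only through their product, the likelihood is exactly invariant
#' under `(c, tau) -> (gamma c, tau / gamma)` — the identifiability gap the
#' hierarchical population layer resolves.
#'
#' With `sigma2 = 0` and no accumulated process noise, observations off the
#' deterministic path give `-Inf`.
#'
#' @param trace a [fluor_trace()].
#' @param params a one-row [cell_params()] table.
#' @param k [kinetic_constants()].
#' @param dt filter substep in minutes (mean via RK4, covariance via Euler).
#' @return The log-likelihood (a single number, `-Inf` possible).
#' @export
trace_loglik <- function(trace, params, k, dt = 1) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(k, "kinetic_constants"),
            nrow(params) == 1)
  if (length(trace$time) == 0) stop("data error: empty trace")
  cpp_trace_loglik(trace$time, trace$value, params$c, params$tau0,
                   params$tau1, params$T, params$M0, params$P0,
                   k$delta_M, k$delta_P, k$alpha, k$kappa, k$sigma2, dt)
}

prior_logdens <- function(entry, x) {
  switch(entry$family,
         lognormal = dlnorm(x, entry$a, entry$b, log = TRUE),
         uniform = stats::dunif(x, entry$a, entry$b, log = TRUE),
         stop("configuration error: unsupported prior family '",
              entry$family, "' for the grid oracle"))
}

#' Brute-force grid posterior for one or two free parameters
#'
#' Pointwise prior times likelihood over a supplied grid, normalized to sum
#' to one.  Used as an independent oracle for the MCMC sampler on small
#' instances.
#'
#' @param trace a [fluor_trace()].
#' @param free named list of one or two numeric grid vectors; names must be
#'   cell-parameter names (`c`, `tau0`, `tau1`, `T`, `M0`, `P0`).
#' @param params a one-row [cell_params()] table giving the fixed values.
#' @param priors named list of [hyper_entry()] priors for the free
#'   parameters.
#' @param k [kinetic_constants()].
#' @param dt filter substep (min).
#' @return A data frame with one column per free parameter plus `prob`
#'   (summing to 1).
#' @export
grid_posterior_oracle <- function(trace, free, params, priors, k, dt = 1) {
  if (!length(free) %in% c(1L, 2L))
    stop("configuration error: exactly one or two free parameters")
  if (!all(names(free) %in% c("c", "tau0", "tau1", "T", "M0", "P0")))
    stop("configuration error: unknown free parameter name")
  grid <- expand.grid(free, KEEP.OUT.ATTRS = FALSE)
  lp <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p <- params
    for (nm in names(free)) p[[nm]] <- grid[i, nm]
    lp[i] <- trace_loglik(trace, p, k, dt = dt)
    for (nm in names(free))
      lp[i] <- lp[i] + prior_logdens(priors[[nm]], grid[i, nm])
  }
  w <- exp(lp - max(lp[is.finite(lp)]))
  w[!is.finite(w)] <- 0
  s <- sum(w)
  if (!is.finite(s) || s <= 0) stop("numerical error: zero total posterior mass")
  grid$prob <- w / s
  grid
}
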