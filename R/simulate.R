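#' Fluorescence trace container
#'
#' A single cell's observed reporter time course on a uniform grid.
#'
#' @param cell_id,construct_id identifiers.
#' @param time numeric vector of times (min), strictly increasing with
#'   uniform spacing.
#' @param value fluorescence (AU), one per time point, finite.
#' @param divisions optional division times (min).
#' @param meta optional metadata list (e.g. `degenerate` flag).
#' @return An object of class `fluor_trace`.
#' @export
fluor_trace <- function(cell_id, construct_id, time, value,
                        divisions = numeric(0), meta = list()) {
  if (length(time) != length(value)) stop("time/value length mismatch")
  if (length(time) == 0) stop("empty trace")
  if (any(!is.finite(value))) stop("non-finite fluorescence values")
  if (length(time) > 1) {
    dt <- diff(time)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-8 * max(dt)) stop("times must be uniformly spaced")
  }
  structure(list(cell_id = as.character(cell_id),
                 construct_id = as.character(construct_id),
                 time = as.numeric(time), value = as.numeric(value),
                 divisions = as.numeric(divisions), meta = meta),
            class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("<fluor_trace %s (%s): %d points, %g-%g min, peak %.0f AU>\n",
              x$cell_id, x$construct_id, length(x$time), min(x$time),
              max(x$time), max(x$value)))
  invisible(x)
}

#' @rdname fluor_trace
#' @param traces a list of `fluor_trace` objects.
#' @export
trace_set <- function(traces = list()) {
  ok <- vapply(traces, inherits, logical(1), "fluor_trace")
  if (!all(ok)) stop("all elements must be fluor_trace objects")
  structure(traces, class = "trace_set")
}

#' @export
`[.trace_set` <- function(x, i) trace_set(unclass(x)[i])

#' @export
print.trace_set <- function(x, ...) {
  cons <- vapply(x, `[[`, character(1), "construct_id")
  cat(sprintf("<trace_set: %d traces, %d construct(s)>\n", length(x),
              length(unique(cons))))
  invisible(x)
}

#' @export
as.data.frame.trace_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(tr) {
    data.frame(cell_id = tr$cell_id, construct_id = tr$construct_id,
               time_min = tr$time, fluorescence_au = tr$value,
               division_flag = as.integer(tr$time %in% tr$divisions))
  }))
}

trace_constructs <- function(traces)
  vapply(traces, `[[`, character(1), "construct_id")

#' Simulate latent mRNA/protein paths under the chemical Langevin equation
#'
#' Euler-Maruyama integration of the telegraph-switch reporter model.  Drift
#' is `(c tau(t) - delta_M M, alpha M - delta_P P)` with
#' `tau(t) = tau0` before the switch time and `tau1` after; each species
#' has an independent Wiener term with diffusion equal to the square root of
#' its summed production and degradation propensities.  States are reflected
#' at zero after each substep.
#'
#' @param params a one-row [cell_params()] table.
#' @param k [kinetic_constants()].
#' @param times uniform observation grid (min).
#' @param dt integrator substep (min), must not exceed the grid spacing.
#' @param noise logical; `FALSE` switches the diffusion off (the path then
#'   equals [ode_trajectory()] up to integrator tolerance).
#' @param nrep number of replicate paths.
#' @return A list with `time`, and `M`, `P` matrices (length(times) x nrep).
#' @export
simulate_latent_paths <- function(params, k, times, dt = 0.1, noise = TRUE,
                                  nrep = 1) {
  stopifnot(inherits(k, "kinetic_constants"), nrow(params) == 1)
  if (length(times) > 1 && dt > min(diff(times)) + 1e-12)
    stop("integrator substep must be <= the sampling interval")
  M <- matrix(0, length(times), nrep)
  P <- matrix(0, length(times), nrep)
  for (r in seq_len(nrep)) {
    path <- cpp_simulate_path(times, params$c, params$tau0, params$tau1,
                              params$T, params$M0, params$P0, k$delta_M,
                              k$delta_P, k$alpha, dt, noise)
    M[, r] <- path[, 1]
    P[, r] <- path[, 2]
  }
  list(time = times, M = M, P = P)
}

#' Deterministic mean trajectory of the reporter model
#'
#' Solves the noise-free drift ODE of the single-cell layer (RK4, substeps
#' split at the switch time) and returns the implied mean fluorescence.
#' Serves as the mean propagation inside the likelihood and as the oracle
#' against which the stochastic simulator is checked.
#'
#' @inheritParams simulate_latent_paths
#' @return A data frame with columns `time`, `M`, `P`, `F` (`F = kappa * P`).
#' @export
ode_trajectory <- function(params, k, times, dt = 0.1) {
  stopifnot(inherits(k, "kinetic_constants"), nrow(params) == 1)
  path <- cpp_ode_path(times, params$c, params$tau0, params$tau1, params$T,
                       params$M0, params$P0, k$delta_M, k$delta_P, k$alpha, dt)
  if (any(!is.finite(path))) stop("integration error: non-finite state")
  data.frame(time = times, M = path[, 1], P = path[, 2],
             F = k$kappa * path[, 2])
}

#' Render a protein path into a noisy fluorescence trace
#'
#' Applies the observation model `F_i = kappa P(t_i) + e_i`,
#' `e_i ~ N(0, sigma2)` independently across time points.
#'
#' @param P protein path on the design grid.
#' @param times the design grid (min).
#' @param k [kinetic_constants()]; `sigma2 >= 0` is enforced.
#' @param cell_id,construct_id identifiers for the resulting trace.
#' @param divisions optional division markers to carry along.
#' @return A [fluor_trace()]; a zero `kappa` is flagged as degenerate in the
#'   trace metadata.
#' @export
render_trace <- function(P, times, k, cell_id = "cell", construct_id = "construct",
                         divisions = numeric(0)) {
  stopifnot(inherits(k, "kinetic_constants"))
  if (k$sigma2 < 0) stop("configuration error: sigma2 must be >= 0")
  F <- k$kappa * P + rnorm(length(P), 0, sqrt(k$sigma2))
  meta <- if (k$kappa == 0) list(degenerate = "zero gain") else list()
  fluor_trace(cell_id, construct_id, times, F, divisions = divisions,
              meta = meta)
}

#' Simulate a full multi-construct reporter study
#'
#' Draws per-cell parameters from each construct's population layer (all
#' constructs share the design's single copy-number distribution), integrates
#' the chemical Langevin model for every cell, and renders noisy fluorescence
#' traces.  The generating (ground-truth) parameters are returned alongside
#' the traces so that parameter-recovery checks are possible.
#'
#' @param design a [study_design()].
#' @param k [kinetic_constants()].
#' @param dt Euler-Maruyama substep (min).
#' @return A list with `traces` (a [trace_set()]), `truth` (a data frame of
#'   generating parameters keyed by `cell_id`), and the `design`.
#' @examples
#' des <- default_study_design(n_constructs = 2, seed = 42)
#' des$cells <- c(15L, 15L)
#' study <- simulate_study(des)
#' study$traces
#' @export
simulate_study <- function(design, k = kinetic_constants(), dt = 0.1) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  times <- seq(0, design$duration, by = design$interval)
  traces <- list()
  truth <- list()
  for (j in seq_along(design$constructs)) {
    lab <- design$constructs[j]
    hyper <- design$construct_hypers[[lab]]
    pars <- sample_cell_params(hyper, design$cells[j],
                               duration = design$duration)
    for (i in seq_len(nrow(pars))) {
      id <- sprintf("%s_c%03d", lab, i)
      path <- cpp_simulate_path(times, pars$c[i], pars$tau0[i], pars$tau1[i],
                                pars$T[i], pars$M0[i], pars$P0[i],
                                k$delta_M, k$delta_P, k$alpha, dt, TRUE)
      P <- path[, 2]
      div <- numeric(0)
      if (!is.null(design$division_time)) {
        div <- design$division_time
        P[times >= div] <- P[times >= div] / 2  # reporter dilution at mitosis
      }
      traces[[length(traces) + 1L]] <-
        render_trace(P, times, k, cell_id = id, construct_id = lab,
                     divisions = div)
      truth[[length(truth) + 1L]] <-
        data.frame(cell_id = id, construct_id = lab, pars[i, , drop = FALSE])
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(traces = trace_set(traces), truth = truth, design = design)
}
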