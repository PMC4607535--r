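#' Population-layer distribution entry
#'
#' One hierarchical distribution: a family tag plus its `(a, b)` parameter
#' pair.  Families:
#' \describe{
#'   \item{`lognormal`}{`a` = mean and `b` = sd of the log (b > 0).}
#'   \item{`uniform`}{lower `a`, upper `b` (a < b); used for switch times.}
#'   \item{`frac_uniform`}{for the basal rate only: `tau0 = u * tau1` with
#'     `u ~ Uniform(a, b)`, `0 <= a <= b < 1`, which enforces
#'     `tau0 <= tau1` by construction.}
#'   \item{`fixed`}{degenerate at `a` (`b` ignored).}
#' }
#'
#' @param family one of `"lognormal"`, `"uniform"`, `"frac_uniform"`, `"fixed"`.
#' @param a,b family parameters.
#' @return A classed list with elements `family`, `a`, `b`.
#' @export
hyper_entry <- function(family = c("lognormal", "uniform", "frac_uniform",
                                   "fixed"), a, b = NA_real_) {
  family <- match.arg(family)
  if (!is.numeric(a) || length(a) != 1 || !is.finite(a))
    stop("configuration error: 'a' must be a finite number")
  if (family == "lognormal" && (!is.finite(b) || b < 0))
    stop("configuration error: lognormal needs sdlog b >= 0")
  if (family == "uniform" && (!is.finite(b) || b < a))
    stop("configuration error: uniform needs a <= b")
  if (family == "frac_uniform" &&
      (!is.finite(b) || a < 0 || b < a || b >= 1))
    stop("configuration error: frac_uniform needs 0 <= a <= b < 1")
  structure(list(family = family, a = a, b = b), class = "hyper_entry")
}

#' Population layer for one construct
#'
#' The hierarchical distributions from which per-cell latent parameters are
#' drawn.  One copy-number entry is shared by every construct in a study;
#' rate entries are per construct.
#'
#' @param c copy-number entry (shared across constructs in a study).
#' @param tau1 active-rate entry.
#' @param tau0 basal-rate entry; with the default `frac_uniform` family the
#'   basal rate is a sub-unity fraction of the active rate.
#' @param T switch-time entry.
#' @param M0,P0 initial-condition entries.
#' @return A classed list of `hyper_entry` objects.
#' @export
population_hyper <- function(c = hyper_entry("lognormal", 0, 0.6),
                             tau1 = hyper_entry("lognormal", log(5), 0.7),
                             tau0 = hyper_entry("frac_uniform", 0, 0.2),
                             T = hyper_entry("uniform", 0, 2880),
                             M0 = hyper_entry("lognormal", 0, 1),
                             P0 = hyper_entry("lognormal", 0, 1)) {
  out <- list(c = c, tau1 = tau1, tau0 = tau0, T = T, M0 = M0, P0 = P0)
  ok <- vapply(out, inherits, logical(1), "hyper_entry")
  if (!all(ok)) stop("configuration error: all entries must be hyper_entry objects")
  structure(out, class = "population_hyper")
}

draw_entry <- function(entry, n) {
  switch(entry$family,
         lognormal = rlnorm(n, entry$a, entry$b),
         uniform = runif(n, entry$a, entry$b),
         fixed = rep(entry$a, n),
         stop("frac_uniform is resolved against tau1, not drawn directly"))
}

#' Draw per-cell parameters from the population layer
#'
#' Each latent quantity is an independent draw from its population
#' distribution; the basal rate is constructed as a fraction of the active
#' rate so that `tau0 <= tau1` holds for every cell.
#'
#' @param hyper a [population_hyper()].
#' @param n number of cells (>= 1).
#' @param duration window length (min) used to validate switch times.
#' @return A [cell_params()] data frame with `n` rows.
#' @examples
#' set.seed(1)
#' sample_cell_params(population_hyper(), 5)
#' @export
sample_cell_params <- function(hyper, n, duration = 2880) {
  if (!inherits(hyper, "population_hyper"))
    stop("configuration error: 'hyper' must be a population_hyper")
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("configuration error: n must be >= 1")
  n <- as.integer(n)
  cc <- draw_entry(hyper$c, n)
  t1 <- draw_entry(hyper$tau1, n)
  t0 <- if (hyper$tau0$family == "frac_uniform") {
    runif(n, hyper$tau0$a, hyper$tau0$b) * t1
  } else {
    pmin(draw_entry(hyper$tau0, n), t1)  # clamp preserves the ordering
  }
  Tv <- pmin(pmax(draw_entry(hyper$T, n), 0), duration)
  M0 <- draw_entry(hyper$M0, n)
  P0 <- draw_entry(hyper$P0, n)
  cell_params(cc, t0, t1, Tv, M0, P0, duration = duration)
}

#' Multi-construct study design
#'
#' Describes a simulated transfection study: construct labels, cells per
#' construct, the imaging grid, per-construct population hypers for the
#' rates, and the single copy-number hyper shared by all constructs.
#'
#' @param constructs character vector of construct labels.
#' @param cells_per_construct integer, cells per construct (>= 15), recycled.
#' @param interval sampling interval in minutes (default 30, the imaging
#'   cadence).
#' @param duration window length in minutes (default 2880 = 48 h); must be a
#'   multiple of `interval`.
#' @param copy_hyper the shared copy-number `hyper_entry`.
#' @param construct_hypers named list of [population_hyper()] objects, one
#'   per construct; each entry's `c` slot is overridden by `copy_hyper`.
#' @param seed integer random seed for [simulate_study()].
#' @param division_time optional division time (min); when set, the rendered
#'   signal halves at division and a marker is recorded on each trace.
#' @return A classed list describing the study.
#' @export
study_design <- function(constructs, cells_per_construct = 30, interval = 30,
                         duration = 2880,
                         copy_hyper = hyper_entry("lognormal", 0, 0.6),
                         construct_hypers, seed = 1L, division_time = NULL) {
  if (length(constructs) < 1) stop("configuration error: no constructs")
  if (anyDuplicated(constructs)) stop("configuration error: duplicate construct labels")
  cells <- rep_len(as.integer(cells_per_construct), length(constructs))
  if (any(cells < 15))
    stop("configuration error: need >= 15 cells per construct for robust rate estimates")
  if (duration %% interval != 0)
    stop("configuration error: duration must be a multiple of the sampling interval")
  if (missing(construct_hypers))
    construct_hypers <- setNames(replicate(length(constructs),
                                           population_hyper(), simplify = FALSE),
                                 constructs)
  if (!setequal(names(construct_hypers), constructs))
    stop("configuration error: construct_hypers must be named by construct")
  construct_hypers <- construct_hypers[constructs]
  for (nm in constructs) construct_hypers[[nm]]$c <- copy_hyper
  structure(list(constructs = constructs, cells = cells, interval = interval,
                 duration = duration, copy_hyper = copy_hyper,
                 construct_hypers = construct_hypers, seed = as.integer(seed),
                 division_time = division_time),
            class = "study_design")
}

#' Default study design
#'
#' A 19-construct study at the scale of a typical reporter experiment:
#' 30 cells per construct, images every 30 min for 48 h, per-construct
#' active-rate population means spread geometrically over 2-14 AU (the span
#' seen across promoter and CRM reporters), log-scale rate spread 0.7, and a
#' shared log-normal copy-number distribution with median 1.
#'
#' @param n_constructs number of constructs (default 19).
#' @param seed random seed.
#' @return A [study_design()].
#' @export
default_study_design <- function(n_constructs = 19, seed = 1L) {
  labels <- sprintf("construct_%02d", seq_len(n_constructs))
  means <- exp(seq(log(2), log(14), length.out = n_constructs))
  b <- 0.7
  hypers <- setNames(lapply(means, function(m) {
    population_hyper(tau1 = hyper_entry("lognormal", log(m) - b^2 / 2, b))
  }), labels)
  study_design(labels, cells_per_construct = 30, interval = 30,
               duration = 2880, construct_hypers = hypers, seed = seed)
}
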