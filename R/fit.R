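#' MCMC sampler settings
#'
#' @param iterations total Metropolis-within-Gibbs sweeps per chain.
#' @param burnin sweeps discarded (must be < iterations); proposal step
#'   sizes adapt only during burn-in.
#' @param thin retain every `thin`-th post-burn-in sweep.
#' @param chains number of independent chains (run sequentially).
#' @param step named proposal standard deviations: log-scale random walks for
#'   `c`, `tau1`, `tau0`, `M0`, `P0`; minutes for the reflected `T` walk;
#'   `scale` is the log-step of the likelihood-invariant ridge move
#'   `(c, tau) -> (g c, tau / g)` that carries the chain along the
#'   copy-number/rate ridge.
#' @param adapt logical; Robbins-Monro-style step adaptation towards an
#'   acceptance rate of 0.3 during burn-in.
#' @param adapt_every adaptation cadence (sweeps).
#' @param filter_dt likelihood filter substep (min).
#' @param sigma_step proposal sd for the global log sigma2 update.
#' @param rate_var_prior inverse-gamma hyperprior `c(shape, rate)` on the
#'   log-scale variance of the per-construct rate layers.  The default
#'   (3, 0.06) concentrates on small within-construct rate variance: the
#'   per-copy rate is treated as chiefly a property of the construct, so
#'   cell-to-cell expression differences are apportioned to plasmid copy
#'   number.  Only the product of copy number and rate is
#'   likelihood-identified per cell, so this apportionment is a modelling
#'   commitment, not an estimate.
#' @param copy_var_prior inverse-gamma hyperprior `c(shape, rate)` on the
#'   log-scale variance of the shared copy-number layer (default (2, 0.5),
#'   weak).
#' @return A classed settings list.
#' @export
mcmc_control <- function(iterations = 50000, burnin = 20000, thin = 10,
                         chains = 2,
                         step = c(c = 0.15, tau1 = 0.12, tau0 = 0.4, T = 30,
                                  M0 = 0.6, P0 = 0.6, scale = 0.4),
                         adapt = TRUE, adapt_every = 100, filter_dt = 2,
                         sigma_step = 0.1, rate_var_prior = c(3, 0.06),
                         copy_var_prior = c(2, 0.5)) {
  if (burnin >= iterations) stop("configuration error: burnin must be < iterations")
  if (thin < 1 || chains < 1) stop("configuration error: thin and chains must be >= 1")
  need <- c("c", "tau1", "tau0", "T", "M0", "P0", "scale")
  if (!all(need %in% names(step)) || any(step[need] <= 0))
    stop("configuration error: step sizes must be positive for ",
         paste(need, collapse = ", "))
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 chains = as.integer(chains), step = step[need],
                 adapt = isTRUE(adapt), adapt_every = as.integer(adapt_every),
                 filter_dt = filter_dt, sigma_step = sigma_step,
                 rate_var_prior = rate_var_prior,
                 copy_var_prior = copy_var_prior),
            class = "mcmc_control")
}

# method-of-moments starting point from one trace: the late-time slope of a
# rising onset curve approximates kappa*alpha*c*tau1/delta_M once the mRNA is
# near quasi-steady state; the switch time starts at the 20%-range crossing.
init_cell_params <- function(trace, k, Tmax) {
  F <- trace$value
  t <- trace$time
  n <- length(F)
  i3 <- max(2L, n - max(3L, n %/% 3L))
  slope <- tryCatch(unname(coef(lm(F[i3:n] ~ t[i3:n]))[2]),
                    error = function(e) NA_real_)
  if (!is.finite(slope) || slope <= 0) slope <- max(diff(range(F)) / max(t[n], 1), 1e-3)
  tau1 <- max(slope * k$delta_M / (k$kappa * k$alpha), 0.05)
  cross <- which(F > min(F) + 0.2 * diff(range(F)))[1]
  T0 <- if (is.na(cross)) 0.5 * Tmax else t[cross]
  T0 <- min(max(T0, 0.02 * Tmax), 0.9 * Tmax)
  data.frame(c = 1, tau0 = 0.1 * tau1, tau1 = tau1, T = T0, M0 = 1,
             P0 = max(F[1] / k$kappa, 0.5))
}

# Normal-Inverse-Gamma conjugate update for (a, b) of a normal population on
# the log scale; weak hyperprior a ~ N(m0, b^2/k0), b^2 ~ IG(a0, b0).
update_nig <- function(x, m0 = 0, k0 = 0.01, a0 = 2, b0 = 0.5, b_floor = 0.02) {
  n <- length(x)
  xb <- mean(x)
  kn <- k0 + n
  mn <- (k0 * m0 + n * xb) / kn
  an <- a0 + n / 2
  bn <- b0 + 0.5 * sum((x - xb)^2) + k0 * n * (xb - m0)^2 / (2 * kn)
  s2 <- 1 / rgamma(1, an, rate = bn)
  c(a = rnorm(1, mn, sqrt(s2 / kn)), b = max(sqrt(s2), b_floor))
}

# scale-only update when the location is pinned by the anchor (log c has
# population mean 0 so the copy-number median is 1)
update_scale <- function(x, a0 = 2, b0 = 0.5, b_floor = 0.02) {
  s2 <- 1 / rgamma(1, a0 + length(x) / 2, rate = b0 + 0.5 * sum(x^2))
  max(sqrt(s2), b_floor)
}

#' Fit the hierarchical transcription-rate model
#'
#' Joint Metropolis-within-Gibbs estimation over all cells of all constructs
#' simultaneously.  Per sweep, each cell's copy number, basal and active
#' rates, switch time and initial conditions are updated by Metropolis
#' proposals scored with the state-space likelihood plus the population
#' layer; the population hyperparameters are then redrawn conjugately from
#' the current cell-level values (log-normal families, normal-inverse-gamma
#' updates).  Rate hypers are per construct; one copy-number hyper is shared
#' by every construct, and its median is anchored at 1 so that per-copy
#' rates are estimated relative to a single common copy-number distribution
#' and are therefore comparable across constructs.  The measurement-noise
#' variance is updated globally by a Metropolis step on its log.
#'
#' @param traces a [trace_set()] (ideally after [preprocess_traces()]).
#' @param constants [kinetic_constants()]; `sigma2` provides the initial
#'   noise variance.
#' @param control an [mcmc_control()].
#' @param seed integer seed; chain `i` uses `seed + i - 1`.
#' @param update named logical vector switching parameter blocks on or off
#'   (for restricted runs, e.g. oracle comparisons).
#' @param hyper_update logical; `FALSE` freezes the population layer at
#'   `hyper_init` (the per-cell priors then stay fixed).
#' @param sigma_update logical; `FALSE` freezes `sigma2` at its initial
#'   value.
#' @param hyper_init optional list with elements `rate` (constructs x 4
#'   matrix of `a0, b0, a1, b1` for tau0/tau1), `bc`, `aM0`, `bM0`, `aP0`,
#'   `bP0`, `sigma2`.
#' @param init optional data frame of per-cell starting values (one row per
#'   trace); default is a method-of-moments start, jittered per chain.
#' @param T_window switch-time window `c(min, max)`; defaults to the span
#'   of the observation times.
#' @return An object of class `ratefit`; see [summary.ratefit()],
#'   [coef.ratefit()], [plot.ratefit()].
#' @export
fit_rates <- function(traces, constants = kinetic_constants(),
                      control = mcmc_control(), seed = 1L,
                      update = c(c = TRUE, tau1 = TRUE, tau0 = TRUE, T = TRUE,
                                 M0 = TRUE, P0 = TRUE, scale = TRUE),
                      hyper_update = TRUE, sigma_update = TRUE,
                      hyper_init = NULL, init = NULL, T_window = NULL) {
  stopifnot(inherits(traces, "trace_set"), length(traces) > 0,
            inherits(control, "mcmc_control"))
  k <- constants
  ncell <- length(traces)
  cons_chr <- trace_constructs(traces)
  cons_lev <- unique(cons_chr)
  cons <- match(cons_chr, cons_lev) - 1L  # 0-based for C++
  ncons <- length(cons_lev)
  times <- lapply(traces, `[[`, "time")
  Fs <- lapply(traces, `[[`, "value")
  cell_ids <- vapply(traces, `[[`, character(1), "cell_id")
  if (is.null(T_window))
    T_window <- c(0, max(vapply(times, max, numeric(1))))

  blocks <- c("c", "tau1", "tau0", "T", "M0", "P0", "scale")
  upd <- rep(TRUE, 7)
  names(upd) <- blocks
  upd[names(update)] <- update
  step0 <- control$step[blocks]

  if (is.null(init)) {
    init <- do.call(rbind, lapply(traces, init_cell_params, k = k,
                                  Tmax = T_window[2]))
  }
  stopifnot(nrow(init) == ncell)

  if (is.null(hyper_init)) {
    rate <- matrix(0, ncons, 4)
    for (j in seq_len(ncons)) {
      lt1 <- log(init$tau1[cons == j - 1L])
      rate[j, ] <- c(mean(lt1) - log(10), 0.7, mean(lt1), 0.7)
    }
    hyper_init <- list(rate = rate, bc = 0.6, aM0 = 0, bM0 = 1,
                       aP0 = 0, bP0 = 1, sigma2 = k$sigma2)
  }

  nkeep <- (control$iterations - control$burnin) %/% control$thin
  chains <- vector("list", control$chains)

  for (ch in seq_len(control$chains)) {
    set.seed(seed + ch - 1L)
    st <- init
    if (ch > 1L) {  # jitter non-first chains for overdispersed starts
      for (nm in c("c", "tau0", "tau1", "M0", "P0"))
        st[[nm]] <- st[[nm]] * exp(0.15 * rnorm(ncell))
      st$T <- pmin(pmax(st$T + 30 * rnorm(ncell), T_window[1] + 1e-6),
                   T_window[2] - 1e-6)
    }
    hy <- hyper_init
    sigma2 <- hy$sigma2
    step <- step0
    ll <- cpp_loglik_all(times, Fs, st$c, st$tau0, st$tau1, st$T, st$M0,
                         st$P0, k$delta_M, k$delta_P, k$alpha, k$kappa,
                         sigma2, control$filter_dt)
    if (any(!is.finite(ll)))
      stop("initialization error: non-finite log-likelihood for cell(s) ",
           paste(cell_ids[!is.finite(ll)], collapse = ", "))

    keep <- list(c = matrix(NA_real_, nkeep, ncell),
                 tau0 = matrix(NA_real_, nkeep, ncell),
                 tau1 = matrix(NA_real_, nkeep, ncell),
                 T = matrix(NA_real_, nkeep, ncell),
                 M0 = matrix(NA_real_, nkeep, ncell),
                 P0 = matrix(NA_real_, nkeep, ncell))
    hyper_keep <- array(NA_real_, c(nkeep, ncons, 4),
                        dimnames = list(NULL, cons_lev,
                                        c("a0", "b0", "a1", "b1")))
    bc_keep <- numeric(nkeep)
    sigma2_keep <- numeric(nkeep)
    logpost_keep <- numeric(nkeep)
    acc_tot <- prop_tot <- setNames(numeric(7), blocks)
    acc_win <- prop_win <- setNames(numeric(7), blocks)
    krow <- 0L

    for (s in seq_len(control$iterations)) {
      sw <- cpp_sweep_cells(times, Fs, st$c, st$tau0, st$tau1, st$T, st$M0,
                            st$P0, ll, cons, hy$rate, 0, hy$bc, hy$aM0,
                            hy$bM0, hy$aP0, hy$bP0, T_window[1], T_window[2],
                            unname(step), unname(upd), k$delta_M, k$delta_P,
                            k$alpha, k$kappa, sigma2, control$filter_dt)
      st$c <- sw$c; st$tau0 <- sw$tau0; st$tau1 <- sw$tau1
      st$T <- sw$T; st$M0 <- sw$M0; st$P0 <- sw$P0
      ll <- sw$ll
      acc_win <- acc_win + sw$accept; prop_win <- prop_win + sw$propose
      acc_tot <- acc_tot + sw$accept; prop_tot <- prop_tot + sw$propose

      if (hyper_update) {
        rvp <- control$rate_var_prior
        cvp <- control$copy_var_prior
        for (j in seq_len(ncons)) {
          sel <- cons == j - 1L
          hy$rate[j, 1:2] <- update_nig(log(st$tau0[sel]), a0 = rvp[1],
                                        b0 = rvp[2])
          hy$rate[j, 3:4] <- update_nig(log(st$tau1[sel]), a0 = rvp[1],
                                        b0 = rvp[2])
        }
        hy$bc <- update_scale(log(st$c), a0 = cvp[1], b0 = cvp[2])
        mu <- update_nig(log(st$M0)); hy$aM0 <- mu[1]; hy$bM0 <- mu[2]
        pu <- update_nig(log(st$P0)); hy$aP0 <- pu[1]; hy$bP0 <- pu[2]
      }
      if (sigma_update) {
        s2n <- exp(log(sigma2) + control$sigma_step * rnorm(1))
        lln <- cpp_loglik_all(times, Fs, st$c, st$tau0, st$tau1, st$T, st$M0,
                              st$P0, k$delta_M, k$delta_P, k$alpha, k$kappa,
                              s2n, control$filter_dt)
        if (all(is.finite(lln)) &&
            log(runif(1)) < sum(lln) - sum(ll)) {  # flat prior on log sigma2
          sigma2 <- s2n
          ll <- lln
        }
      }
      if (control$adapt && s <= control$burnin &&
          s %% control$adapt_every == 0L) {
        rate_hat <- ifelse(prop_win > 0, acc_win / prop_win, 0.3)
        step <- pmin(pmax(step * exp(rate_hat - 0.3), step0 / 50), step0 * 50)
        acc_win[] <- 0; prop_win[] <- 0
      }
      if (s > control$burnin &&
          (s - control$burnin) %% control$thin == 0L) {
        krow <- krow + 1L
        for (nm in names(keep)) keep[[nm]][krow, ] <- st[[nm]]
        hyper_keep[krow, , ] <- hy$rate
        bc_keep[krow] <- hy$bc
        sigma2_keep[krow] <- sigma2
        lp <- sum(ll) + sum(dnorm(log(st$c), 0, hy$bc, log = TRUE)) +
          sum(dnorm(log(st$M0), hy$aM0, hy$bM0, log = TRUE)) +
          sum(dnorm(log(st$P0), hy$aP0, hy$bP0, log = TRUE))
        for (j in seq_len(ncons)) {
          sel <- cons == j - 1L
          lp <- lp + sum(dnorm(log(st$tau0[sel]), hy$rate[j, 1],
                               hy$rate[j, 2], log = TRUE)) +
            sum(dnorm(log(st$tau1[sel]), hy$rate[j, 3], hy$rate[j, 4],
                      log = TRUE))
        }
        logpost_keep[krow] <- lp
      }
    }
    chains[[ch]] <- list(c = keep$c, tau0 = keep$tau0, tau1 = keep$tau1,
                         T = keep$T, M0 = keep$M0, P0 = keep$P0,
                         rate_hyper = hyper_keep, bc = bc_keep,
                         sigma2 = sigma2_keep, logpost = logpost_keep,
                         acceptance = ifelse(prop_tot > 0,
                                             acc_tot / prop_tot, NA),
                         step_final = step)
  }

  structure(list(chains = chains, cell_ids = cell_ids,
                 construct = cons_chr, constructs = cons_lev,
                 traces = traces, constants = k, control = control,
                 T_window = T_window, seed = seed, init = init,
                 update = upd),
            class = "ratefit")
}

#' Extract combined posterior samples from a fit
#'
#' @param fit a `ratefit`.
#' @param param one of `"c"`, `"tau0"`, `"tau1"`, `"T"`, `"M0"`, `"P0"`,
#'   `"sigma2"`, `"bc"`, `"logpost"`.
#' @return For per-cell parameters a draws x cells matrix (chains stacked,
#'   columns named by cell id); otherwise a vector.
#' @export
rate_samples <- function(fit, param = "tau1") {
  stopifnot(inherits(fit, "ratefit"))
  parts <- lapply(fit$chains, `[[`, param)
  if (is.matrix(parts[[1]])) {
    out <- do.call(rbind, parts)
    colnames(out) <- fit$cell_ids
    out
  } else {
    do.call(c, parts)
  }
}
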