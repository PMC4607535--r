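# shared fixtures, all built in code

# a trace straight from given values on the 30-min grid
make_trace <- function(values, cell_id = "cell", construct_id = "X",
                       interval = 30, divisions = numeric(0)) {
  fluor_trace(cell_id, construct_id,
              seq(0, by = interval, length.out = length(values)),
              values, divisions = divisions)
}

# Two-construct study with a true active-rate population-mean ratio of 2.0
# (8 vs 4 AU), shared log-normal copy-number hyper (median anchored at 1),
# switch times uniform in [240, 1440] min, measurement noise sd 200 AU.
# Spreads (copy sdlog 0.3, rate sdlog 0.25) are sized so that finite-sample
# design noise in the identified ratio, sd = sqrt((bc^2 + b1^2) * 2 / 20),
# stays well inside the recovery band: only the product of copy number and
# rate is likelihood-identified per cell, so the realized construct-mean
# copy-number difference is an irreducible part of any estimate of the
# rate ratio.
recovery_study <- function(seed = 11) {
  b <- 0.25
  mk <- function(m) population_hyper(
    tau1 = hyper_entry("lognormal", log(m) - b^2 / 2, b),
    tau0 = hyper_entry("frac_uniform", 0, 0.2),
    T = hyper_entry("uniform", 240, 1440))
  des <- study_design(c("A", "B"), cells_per_construct = 20,
                      construct_hypers = list(A = mk(8), B = mk(4)),
                      copy_hyper = hyper_entry("lognormal", 0, 0.3),
                      seed = seed)
  simulate_study(des, kinetic_constants(sigma2 = 200^2))
}

# population-mean rate ratio A/B: per-draw arithmetic construct means for
# the point estimate, hyper-level population means for the credible interval
recovery_ratio <- function(fit) {
  S <- rate_samples(fit, "tau1")
  cons <- fit$construct
  point <- mean(rowMeans(S[, cons == "A"]) / rowMeans(S[, cons == "B"]))
  hy <- lapply(fit$chains, `[[`, "rate_hyper")
  iA <- match("A", fit$constructs); iB <- match("B", fit$constructs)
  draws <- do.call(c, lapply(hy, function(h)
    exp(h[, iA, "a1"] + h[, iA, "b1"]^2 / 2 -
          h[, iB, "a1"] - h[, iB, "b1"]^2 / 2)))
  list(point = point, ci = quantile(draws, c(0.05, 0.95), names = FALSE))
}

# the reduced-budget hierarchical fit shared by the recovery and
# decorrelation checks; computed once per test run
.fit_cache <- new.env(parent = emptyenv())
get_recovery_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    study <- recovery_study()
    pp <- preprocess_traces(study$traces, seed = 2)
    ctl <- mcmc_control(iterations = 20000, burnin = 8000, thin = 10,
                        chains = 2)
    .fit_cache$fit <- fit_rates(pp$traces, kinetic_constants(sigma2 = 200^2),
                                ctl, seed = 3)
    .fit_cache$truth <- study$truth
  }
  list(fit = .fit_cache$fit, truth = .fit_cache$truth)
}

# quick fake ratefit carrying given per-cell sample matrices (for analysis
# and diagnostics units that do not need a real MCMC run)
fake_fit <- function(tau1, tau0 = tau1 / 10, Tm = NULL, cc = NULL,
                     construct = NULL, chains = 1) {
  ncell <- ncol(tau1)
  n <- nrow(tau1)
  if (is.null(Tm)) Tm <- matrix(rep(seq(100, 500, length.out = n), ncell),
                                n, ncell)
  if (is.null(cc)) cc <- matrix(1, n, ncell)
  if (is.null(construct)) construct <- rep("X", ncell)
  ids <- sprintf("cell%02d", seq_len(ncell))
  per_chain <- function() list(c = cc, tau0 = tau0, tau1 = tau1, T = Tm,
                               M0 = cc, P0 = cc,
                               sigma2 = rep(1, n), bc = rep(0.5, n),
                               logpost = rep(0, n),
                               acceptance = setNames(rep(0.3, 7),
                                                     c("c", "tau1", "tau0",
                                                       "T", "M0", "P0",
                                                       "scale")))
  structure(list(chains = replicate(chains, per_chain(), simplify = FALSE),
                 cell_ids = ids, construct = construct,
                 constructs = unique(construct), traces = NULL,
                 constants = kinetic_constants(),
                 control = mcmc_control(iterations = 2 * n, burnin = n,
                                        thin = 1),
                 T_window = c(0, 2880), seed = 1),
            class = "ratefit")
}
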