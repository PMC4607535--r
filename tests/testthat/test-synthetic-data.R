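test_that("population draws honour degenerate and log-normal hypers", {
  hy <- population_hyper(c = hyper_entry("fixed", 10),
                         tau1 = hyper_entry("fixed", 5),
                         tau0 = hyper_entry("frac_uniform", 0, 0.2),
                         T = hyper_entry("uniform", 0, 2880),
                         M0 = hyper_entry("fixed", 1),
                         P0 = hyper_entry("fixed", 1))
  set.seed(1)
  p <- sample_cell_params(hy, 50)
  expect_true(all(p$c == 10))
  expect_true(all(p$tau1 == 5))
  expect_true(all(p$tau0 <= p$tau1))

  # sample mean of log tau1 within 3 standard errors of the hyper log-mean
  mu <- 1.2; s <- 0.5; n <- 10000
  set.seed(2)
  p2 <- sample_cell_params(population_hyper(
    tau1 = hyper_entry("lognormal", mu, s)), n)
  expect_lt(abs(mean(log(p2$tau1)) - mu), 3 * s / sqrt(n))

  expect_error(sample_cell_params(hy, 0), "configuration")
  expect_error(hyper_entry("lognormal", 0, -1), "configuration")
})

test_that("every generated cell satisfies the parameter invariants", {
  set.seed(3)
  for (rep in 1:20) {
    p <- sample_cell_params(population_hyper(), 25)
    expect_true(all(p$c > 0))
    expect_true(all(p$tau0 >= 0 & p$tau0 <= p$tau1))
    expect_true(all(p$T >= 0 & p$T <= 2880))
    expect_true(all(p$M0 >= 0 & p$P0 >= 0))
  }
})

test_that("noise-free dynamics match closed forms", {
  # no degradation, active from t=0: M = c*tau1*t, P = alpha*c*tau1*t^2/2
  k <- kinetic_constants(delta_M = 0, delta_P = 0, alpha = 1, kappa = 1,
                         sigma2 = 0)
  p <- cell_params(c = 2, tau0 = 0, tau1 = 3, T = 0, M0 = 0, P0 = 0)
  tt <- seq(0, 10, by = 1)
  sim <- simulate_latent_paths(p, k, tt, dt = 0.01, noise = FALSE)
  expect_lt(max(abs(sim$M[, 1] - 6 * tt)), 1e-6 * max(6 * tt))
  expect_lt(max(abs(sim$P[, 1] - 3 * tt^2)), 1e-6 * max(3 * tt^2))

  # zero rates from zero initial conditions stay identically zero
  p0 <- cell_params(c = 1, tau0 = 0, tau1 = 0, T = 0, M0 = 0, P0 = 0)
  od0 <- ode_trajectory(p0, kinetic_constants(), seq(0, 2880, 30))
  expect_true(all(od0$F == 0))

  # steady state F -> (alpha/delta_P) * (c tau1 / delta_M)
  k1 <- kinetic_constants(delta_M = 0.1, delta_P = 0.05, alpha = 0.5,
                          kappa = 1, sigma2 = 0)
  p1 <- cell_params(c = 1, tau0 = 0, tau1 = 2, T = 0, M0 = 0, P0 = 0)
  od <- ode_trajectory(p1, k1, seq(0, 2000, 10), dt = 0.05)
  expect_equal(tail(od$F, 1), 200, tolerance = 1e-4)
})

test_that("deterministic path agrees with an adaptive integrator", {
  skip_if_not_installed("deSolve")
  k <- kinetic_constants(delta_M = 0.013, delta_P = 0.002, alpha = 0.8,
                         kappa = 1.5, sigma2 = 0)
  p <- cell_params(c = 1.7, tau0 = 0.4, tau1 = 6.2, T = 600, M0 = 3, P0 = 7)
  tt <- seq(0, 2880, by = 30)
  od <- ode_trajectory(p, k, tt, dt = 0.05)
  rhs <- function(t, y, parms) {
    tau <- if (t < p$T) p$tau0 else p$tau1
    list(c(p$c * tau - k$delta_M * y[1], k$alpha * y[1] - k$delta_P * y[2]))
  }
  ref <- deSolve::lsoda(c(M = p$M0, P = p$P0), tt, rhs, NULL,
                        rtol = 1e-10, atol = 1e-10)
  expect_lt(max(abs(od$M[-1] - ref[-1, "M"]) / ref[-1, "M"]), 1e-8)
  expect_lt(max(abs(od$P[-1] - ref[-1, "P"]) / ref[-1, "P"]), 1e-8)
})

test_that("stochastic ensemble mean tracks the ODE solution", {
  k <- kinetic_constants(delta_M = 0.01, delta_P = 5e-4, alpha = 1,
                         kappa = 1, sigma2 = 0)
  p <- cell_params(c = 1, tau0 = 0.3, tau1 = 5, T = 500, M0 = 2, P0 = 4)
  tt <- seq(0, 1440, by = 120)
  set.seed(4)
  nrep <- 10000
  sim <- simulate_latent_paths(p, k, tt, dt = 0.5, nrep = nrep)
  od <- ode_trajectory(p, k, tt, dt = 0.05)
  mhat <- rowMeans(sim$P)
  se <- apply(sim$P, 1, sd) / sqrt(nrep)
  idx <- which(se > 0)
  expect_true(all(abs(mhat[idx] - od$P[idx]) < 3 * se[idx]))
})

test_that("fluorescence rendering applies gain and Gaussian noise", {
  times <- c(0, 30, 60)
  k0 <- kinetic_constants(kappa = 2, sigma2 = 0)
  tr <- render_trace(c(0, 5, 10), times, k0)
  expect_equal(tr$value, c(0, 10, 20))

  set.seed(5)
  kn <- kinetic_constants(kappa = 1, sigma2 = 25)
  n <- 10000
  F <- render_trace(rep(100, n), seq(0, by = 30, length.out = n), kn)$value
  # variance of the variance estimator: 2 sigma^4 / (n - 1)
  expect_lt(abs(var(F) - 25), 3 * sqrt(2 * 25^2 / (n - 1)))

  kz <- kinetic_constants(kappa = 1e-12, sigma2 = 1)
  kz$kappa <- 0  # bypass constructor guard to probe the degenerate branch
  tr0 <- render_trace(c(1, 2, 3), times, kz)
  expect_identical(tr0$meta$degenerate, "zero gain")
  kneg <- kinetic_constants()
  kneg$sigma2 <- -1
  expect_error(render_trace(c(1), 0, kneg), "sigma2")
})

test_that("a default-scale study has the right shape and is reproducible", {
  des <- default_study_design(seed = 9)
  study <- simulate_study(des)
  expect_length(study$traces, 19 * 30)
  expect_true(all(vapply(study$traces, function(tr) length(tr$time),
                         integer(1)) == 97))
  expect_identical(range(study$traces[[1]]$time), c(0, 2880))
  expect_equal(nrow(study$truth), 570)
  validate_cell_params(study$truth)

  study2 <- simulate_study(des)
  expect_identical(as.data.frame(study$traces), as.data.frame(study2$traces))
  expect_identical(study$truth, study2$truth)
})

test_that("all constructs draw copy numbers from the one shared hyper", {
  hy <- population_hyper()
  des <- study_design(c("P1", "P2"), cells_per_construct = 500,
                      construct_hypers = list(P1 = hy, P2 = hy),
                      copy_hyper = hyper_entry("lognormal", 0, 0.6),
                      seed = 10)
  study <- simulate_study(des, dt = 5)  # coarse: only the truth table matters
  cA <- study$truth$c[study$truth$construct_id == "P1"]
  cB <- study$truth$c[study$truth$construct_id == "P2"]
  expect_gt(suppressWarnings(ks.test(cA, cB)$p.value), 0.01)
})

test_that("law of the traces depends on c and tau only through the product", {
  # same noise stream: gamma-rescaled parameter sets give identical paths
  k <- kinetic_constants()
  tt <- seq(0, 2880, by = 30)
  pa <- cell_params(c = 1, tau0 = 0.5, tau1 = 4, T = 600, M0 = 1, P0 = 1)
  pb <- cell_params(c = 3, tau0 = 0.5 / 3, tau1 = 4 / 3, T = 600, M0 = 1,
                    P0 = 1)
  set.seed(6); A <- simulate_latent_paths(pa, k, tt, nrep = 50)
  set.seed(6); B <- simulate_latent_paths(pb, k, tt, nrep = 50)
  expect_identical(A$M, B$M)
  expect_identical(A$P, B$P)
})

test_that("optional division markers halve the signal and are recorded", {
  hy <- population_hyper(T = hyper_entry("uniform", 0, 240))
  des <- study_design("P", cells_per_construct = 15,
                      construct_hypers = list(P = hy), seed = 12,
                      division_time = 1440)
  study <- simulate_study(des)
  tr <- study$traces[[1]]
  expect_identical(tr$divisions, 1440)
  expect_true(1440 %in% tr$time)
})
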