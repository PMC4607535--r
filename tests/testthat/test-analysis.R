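test_that("cell summaries compute the documented moments", {
  f <- fake_fit(tau1 = matrix(c(1, 2, 3), 3, 1),
                Tm = matrix(c(10, 20, 30), 3, 1))
  s <- summarize_cells(f, multimodal = FALSE)
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)
  expect_equal(s$cv, 0.5)
  expect_equal(s$snr, 2)
  expect_equal(s$switch_median, 20)
  # centered switch samples {-10, 0, 10}: central 90% width of the spread
  expect_equal(s$switch_width90, diff(quantile(c(-10, 0, 10), c(.05, .95))),
               ignore_attr = TRUE)

  # degenerate posterior: SD 0, SNR undefined
  fd <- fake_fit(tau1 = matrix(5, 10, 1))
  sdg <- summarize_cells(fd, multimodal = FALSE)
  expect_equal(sdg$sd, 0)
  expect_true(sdg$snr_undefined)
})

test_that("rate stacks are sorted, normalized and peak near the sample mode", {
  set.seed(40)
  samples <- list(a = rlnorm(2000, log(5), 0.2), b = rlnorm(2000, log(2), 0.2))
  st <- build_rate_stack(samples, n_grid = 250)
  expect_identical(st$cell_ids, c("b", "a"))  # ascending by mean
  integrals <- apply(st$density, 2, function(y)
    sum(diff(st$grid) * (head(y, -1) + tail(y, -1)) / 2))
  expect_true(all(abs(integrals - 1) < 1e-6))

  # peaked posterior: density mode within one grid step of the sample mode
  h <- hist(samples$a, breaks = 60, plot = FALSE)
  sample_mode <- h$mids[which.max(h$counts)]
  dens_mode <- st$grid[which.max(st$density[, "a"])]
  expect_lt(abs(dens_mode - sample_mode), 2 * max(diff(st$grid)))

  expect_error(build_rate_stack(samples, grid = seq(3, 10, length.out = 50)),
               "configuration error")
})

test_that("population statistics and fold changes reproduce hand values", {
  sm <- data.frame(construct_id = rep("P", 3), mean = c(2, 4, 6))
  ps <- population_stats(sm)
  expect_equal(ps$mean, 4)
  expect_equal(ps$sd, 2)
  expect_error(population_stats(data.frame(construct_id = "Q", mean = 1)),
               "Q")

  tab <- msx1_population_stats("basal")
  mouse <- tab[tab$construct_id == "MmMsx1Pro", ]
  fugu <- tab[tab$construct_id == "FuguMsx1Pro", ]
  sv40 <- tab[tab$construct_id == "SV40Pro", ]
  expect_equal(round(fold_change(mouse, fugu), 2), 2.29)
  expect_equal(round(fold_change(sv40, mouse), 2), 2.17)
  expect_equal(fold_change(mouse, mouse), 1.0)
  expect_error(fold_change(mouse, list(mean = 0)), "denominator")
})

test_that("log-normality statistic matches ks.test and rejects bad input", {
  set.seed(41)
  x <- rlnorm(200, 1, 0.5)
  res <- lognormality_ks(x, n_boot = 200)
  ref <- suppressWarnings(
    ks.test(log(x), "pnorm", mean(log(x)), sd(log(x))))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_naive, ref$p.value)
  # bootstrap calibration must not exceed the naive (anti-conservative
  # direction): estimated parameters make the naive p too large
  expect_lte(res$p.value, res$p_naive + 0.1)
  expect_error(lognormality_ks(c(x, 0)), "positive")
  expect_error(lognormality_ks(x[1:5]), "at least 8")
})

test_that("log-space ECDF follows the right-continuous convention", {
  e <- log_ecdf(c(1, 10, 100))
  expect_equal(e$log_rate, log(c(1, 10, 100)))
  expect_equal(e$cdf, c(1, 2, 3) / 3)
  f <- attr(e, "fun")
  expect_equal(f(log(1)), 1 / 3)
  expect_equal(f(log(100)), 1)
  expect_true(all(diff(e$cdf) >= 0) && all(e$cdf >= 0 & e$cdf <= 1))

  # the median cell sits at cumulative 0.5 +/- 1/n
  set.seed(42)
  x <- rlnorm(101, 0, 1)
  e2 <- log_ecdf(x)
  med_pos <- e2$cdf[which(e2$log_rate == median(log(x)))]
  expect_lt(abs(med_pos - 0.5), 1 / length(x) + 1e-12)

  # consistency with the fitted log-normal at large n
  set.seed(43)
  big <- rlnorm(2000, 1, 0.4)
  eb <- log_ecdf(big)
  fitted <- pnorm(eb$log_rate, mean(log(big)), sd(log(big)))
  expect_lt(max(abs(eb$cdf - fitted)), 0.05)

  expect_error(log_ecdf(numeric(0)), "empty")
})

test_that("noise-mean regressions recover constructed slopes", {
  m <- seq(1, 10, length.out = 20)
  s1 <- data.frame(construct_id = "X", mean = m, sd = 0.5 * m,
                   cv = 0.5)
  tr1 <- cv_mean_trend(s1)
  expect_equal(tr1$sd_fit[2], 0.5, tolerance = 1e-10)
  expect_equal(tr1$cv_fit[2], 0, tolerance = 1e-10)

  s2 <- data.frame(construct_id = "X", mean = m, sd = 2, cv = 2 / m)
  expect_lt(cv_mean_trend(s2)$cv_slope_sign, 0)

  # OLS equals the closed-form normal equations
  set.seed(44)
  s3 <- data.frame(mean = runif(30, 1, 10))
  s3$sd <- 1 + 0.3 * s3$mean + rnorm(30, 0, 0.1)
  s3$cv <- s3$sd / s3$mean
  tr3 <- cv_mean_trend(s3)
  X <- cbind(1, s3$mean)
  beta <- solve(t(X) %*% X, t(X) %*% s3$sd)
  expect_equal(tr3$sd_fit, as.numeric(beta), tolerance = 1e-10)

  expect_error(cv_mean_trend(data.frame(mean = rep(2, 5), sd = 1:5,
                                        cv = 1:5 / 2)), "degenerate")
})

test_that("gamma fits to rate SDs are consistent", {
  set.seed(45)
  x <- rgamma(10000, shape = 2, scale = 1)
  f <- fit_sd_gamma(x)
  expect_lt(abs(f$shape - 2) / 2, 0.05)
  expect_lt(abs(f$scale - 1), 0.05)
  # moment identity: fitted mean near the sample mean
  expect_lt(abs(f$mean - mean(x)), 3 * sd(x) / sqrt(length(x)))
  expect_error(fit_sd_gamma(rep(1, 20)), "zero variance")
  expect_error(fit_sd_gamma(c(-1, rgamma(19, 2))), "positive")
})

test_that("containment matches its constructed cases", {
  set.seed(46)
  A <- lapply(1:8, function(i) rnorm(500, i, 1))
  expect_equal(containment_fraction(A, A), 1.0)

  shrunk <- lapply(A, function(s) median(s) + (s - median(s)) / 2)
  expect_equal(containment_fraction(shrunk, A), 1.0)

  shifted <- lapply(A, function(s) s + 100)
  expect_equal(containment_fraction(shifted, A), 0.0)

  expect_error(containment_fraction(list(), A), "empty")
})

test_that("behavior classes recover constructed archetypes and partition", {
  set.seed(47)
  cohort_cv <- 0.3
  cohort_mean <- 5
  fast_high <- rnorm(500, 10, 0.5)
  expect_identical(classify_behavior(fast_high, cohort_cv, cohort_mean),
                   "fast-high")
  fast_low <- rnorm(500, 2, 0.1)
  expect_identical(classify_behavior(fast_low, cohort_cv, cohort_mean),
                   "fast-low")
  slow_wide <- rnorm(500, 5, 2.5)  # wide but symmetric: CV 0.5 > cut
  expect_identical(classify_behavior(slow_wide, 0.3, cohort_mean),
                   "slow-wide")
  bimodal <- c(rnorm(250, 2, 0.2), rnorm(250, 9, 0.2))
  expect_identical(classify_behavior(bimodal, cohort_cv, cohort_mean),
                   "multimodal")
  # independent multimodality oracle: count of kernel-density local maxima
  d <- density(bimodal)
  n_modes <- sum(diff(sign(diff(d$y))) == -2)
  expect_gte(n_modes, 2)

  expect_error(classify_behavior(rnorm(50), 0.3, 5), "100")

  # every cell gets exactly one class
  f <- fake_fit(tau1 = vapply(c(2, 5, 9, 12), function(m)
    rnorm(300, m, 0.1 + 0.05 * m), numeric(300)))
  cls <- classify_cells(f)
  expect_length(cls, 4)
  expect_true(all(cls %in% c("multimodal", "slow-wide", "fast-high",
                             "fast-low")))
})
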