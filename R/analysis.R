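#' Per-cell posterior summaries
#'
#' For each cell: posterior mean, SD, CV (= SD/mean) and SNR (= 1/CV) of the
#' transcription rate, the switch-time median and the width of its central
#' 90\% interval (switch samples are centered around their median so spreads
#' are comparable across cells regardless of absolute activation time), and
#' a multimodality flag.
#'
#' @param fit a `ratefit`.
#' @param rate `"tau1"` (default: the active-rate spectrum the stack plots
#'   show), `"tau0"`, or `"window_mean"` — the time average
#'   `(tau0 T + tau1 (t_end - T)) / t_end` over each cell's window.
#' @param multimodal logical; run the mixture-based bimodality check (slower).
#' @return A data frame of class `cell_summary` with one row per cell.
#' @export
summarize_cells <- function(fit, rate = c("tau1", "tau0", "window_mean"),
                            multimodal = TRUE) {
  stopifnot(inherits(fit, "ratefit"))
  rate <- match.arg(rate)
  S <- rate_samples_for(fit, rate)
  if (nrow(S) == 0) stop("data error: zero retained samples")
  Tm <- rate_samples(fit, "T")
  out <- lapply(seq_along(fit$cell_ids), function(i) {
    s <- S[, i]
    m <- mean(s)
    sdev <- sd(s)
    cv <- if (m > 0) sdev / m else NA_real_
    snr <- if (is.finite(cv) && cv > 0) 1 / cv else NA_real_
    Ts <- Tm[, i]
    Tc <- Ts - median(Ts)  # centered around the median switch time
    data.frame(cell_id = fit$cell_ids[i], construct_id = fit$construct[i],
               mean = m, sd = sdev, cv = cv, snr = snr,
               snr_undefined = !is.finite(snr),
               switch_median = median(Ts),
               switch_width90 = unname(diff(quantile(Tc, c(0.05, 0.95)))),
               multimodal = if (multimodal) is_multimodal(s) else NA)
  })
  out <- do.call(rbind, out)
  class(out) <- c("cell_summary", "data.frame")
  out
}

rate_samples_for <- function(fit, rate) {
  if (rate == "window_mean") {
    t1 <- rate_samples(fit, "tau1")
    t0 <- rate_samples(fit, "tau0")
    Tm <- rate_samples(fit, "T")
    tend <- vapply(fit$traces, function(tr) max(tr$time), numeric(1))
    Tm <- pmin(sweep(Tm, 2, rep(1, ncol(Tm)), "*"), rep(tend, each = nrow(Tm)))
    sweep(t0 * Tm + t1 * (rep(tend, each = nrow(Tm)) - Tm), 2, tend, "/")
  } else {
    rate_samples(fit, rate)
  }
}

# two-component Gaussian mixture vs one component, BIC margin 10
is_multimodal <- function(samples, margin = 10, max_n = 500) {
  s <- if (length(samples) > max_n)
    samples[round(seq(1, length(samples), length.out = max_n))] else samples
  if (sd(s) == 0) return(FALSE)
  bic <- tryCatch(mclust::mclustBIC(s, G = 1:2, modelNames = "V",
                                    verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(bic)) return(FALSE)
  isTRUE(bic["2", "V"] - bic["1", "V"] > margin)  # mclust BIC: larger is better
}

#' Sorted per-cell rate density stack
#'
#' Kernel density of each cell's posterior rate samples on a common
#' log-spaced grid, cells sorted by ascending posterior mean — the matrix
#' behind the heat-map "stack" display.  Bandwidth is Silverman's rule on
#' the log-rate samples; each cell's density integrates to 1 over the grid
#' (trapezoid rule).
#'
#' @param x a `ratefit` or a list of positive posterior sample vectors.
#' @param grid optional rate grid (log-spaced recommended); must cover all
#'   samples.  Default: 200 log-spaced points spanning the samples.
#' @param n_grid grid size when `grid` is not supplied.
#' @return An object of class `rate_stack`: list with `grid`, `density`
#'   (grid x cells, ordered), `order`, `means`, `cell_ids`.
#' @export
build_rate_stack <- function(x, grid = NULL, n_grid = 200) {
  samples <- if (inherits(x, "ratefit")) {
    S <- rate_samples(x, "tau1")
    setNames(lapply(seq_len(ncol(S)), function(i) S[, i]), colnames(S))
  } else x
  if (!length(samples)) stop("data error: no cells")
  lo <- min(vapply(samples, min, numeric(1)))
  hi <- max(vapply(samples, max, numeric(1)))
  if (lo <= 0) stop("data error: rate samples must be positive")
  if (is.null(grid)) {
    grid <- exp(seq(log(lo * 0.8), log(hi * 1.25), length.out = n_grid))
  } else if (min(grid) > lo || max(grid) < hi) {
    stop("configuration error: grid does not cover the sampled rates")
  }
  lg <- log(grid)
  dens <- vapply(samples, function(s) {
    d <- density(log(s), bw = "nrd0", from = min(lg), to = max(lg),
                 n = 512)
    g <- stats::approx(d$x, d$y, xout = lg, rule = 2)$y / grid
    tz <- sum(diff(grid) * (head(g, -1) + tail(g, -1)) / 2)
    g / tz
  }, numeric(length(grid)))
  means <- vapply(samples, mean, numeric(1))
  ord <- order(means)
  structure(list(grid = grid, density = dens[, ord, drop = FALSE],
                 order = ord, means = means[ord],
                 cell_ids = names(samples)[ord]),
            class = "rate_stack")
}

#' @export
print.rate_stack <- function(x, ...) {
  cat(sprintf("<rate_stack: %d cells on a %d-point grid [%.3g, %.3g]>\n",
              ncol(x$density), length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
plot.rate_stack <- function(x, main = "single-cell rate distributions", ...) {
  image(seq_len(ncol(x$density)), log10(x$grid), t(x$density),
        col = hcl.colors(64, "Blues 3", rev = TRUE),
        xlab = "cells (sorted by posterior mean rate)",
        ylab = "log10 transcription rate (AU)", main = main, ...)
  lines(seq_len(ncol(x$density)), log10(x$means), col = "red", lwd = 1.5)
  invisible(x)
}

#' Population-level statistics per construct
#'
#' Unweighted mean and sample SD of the single-cell posterior mean rates —
#' the population table used to compare constructs.
#'
#' @param summaries a [summarize_cells()] data frame (or any data frame with
#'   `construct_id` and `mean` columns).
#' @return A data frame of class `population_stats` with `construct_id`,
#'   `n`, `mean`, `sd`.
#' @export
population_stats <- function(summaries) {
  stopifnot(all(c("construct_id", "mean") %in% names(summaries)))
  if (nrow(summaries) == 0) stop("data error: no cells")
  sp <- split(summaries$mean, summaries$construct_id)
  small <- names(sp)[vapply(sp, length, integer(1)) < 2]
  if (length(small))
    stop("data error: fewer than 2 cells for construct(s): ",
         paste(small, collapse = ", "))
  out <- data.frame(construct_id = names(sp),
                    n = vapply(sp, length, integer(1)),
                    mean = vapply(sp, mean, numeric(1)),
                    sd = vapply(sp, sd, numeric(1)))
  rownames(out) <- NULL
  class(out) <- c("population_stats", "data.frame")
  out
}

#' Fold change between two constructs' population mean rates
#'
#' @param a,b numbers, lists, or one-row data frames with a `mean`
#'   element/column (e.g. rows of [population_stats()] or of
#'   [msx1_population_stats()]).
#' @return `mean(a) / mean(b)`, dimensionless.
#' @examples
#' tab <- msx1_population_stats("basal")
#' fold_change(tab[tab$construct_id == "MmMsx1Pro", ],
#'             tab[tab$construct_id == "FuguMsx1Pro", ])  # ~2.3
#' @export
fold_change <- function(a, b) {
  get_mean <- function(z) {
    if (is.numeric(z) && length(z) == 1) return(z)
    if (is.data.frame(z)) { stopifnot(nrow(z) == 1); return(z$mean) }
    if (is.list(z) && !is.null(z$mean)) return(z$mean)
    stop("cannot extract a mean from the supplied object")
  }
  mb <- get_mean(b)
  if (!is.finite(mb) || mb == 0) stop("data error: zero or non-finite denominator mean")
  get_mean(a) / mb
}

# KS distance of a sample against a normal with moment-estimated parameters
ks_stat_norm <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  u <- pnorm(z)
  i <- seq_len(n)
  max(max(i / n - u), max(u - (i - 1) / n))
}

.ks_null_cache <- new.env(parent = emptyenv())

# Null distribution of the estimated-parameter KS statistic: by location-
# scale invariance it depends only on n, so one standard-normal table per
# (n, B) is simulated under an isolated, fixed RNG state and cached.
ks_null_table <- function(n, B) {
  key <- paste(n, B, sep = "_")
  if (!is.null(.ks_null_cache[[key]])) return(.ks_null_cache[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer((104729L * (n %% 1000L) + B) %% .Machine$integer.max))
  tab <- vapply(seq_len(B), function(i) ks_stat_norm(rnorm(n)), numeric(1))
  .ks_null_cache[[key]] <- tab
  tab
}

#' Kolmogorov-Smirnov test of log-normality with bootstrap calibration
#'
#' Tests whether positive values (typically single-cell posterior mean
#' rates) are log-normal: the KS distance of the log values against a normal
#' with estimated mean and SD.  Estimating the parameters from the data
#' inflates the naive KS p-value, so the reported p comes from a parametric
#' bootstrap (Lilliefors-style); the naive p is returned alongside.
#'
#' @param x positive values, `length(x) >= 8`.
#' @param n_boot bootstrap replicates for the null table.
#' @return A list with `statistic`, `p.value` (bootstrap), `p_naive`, `n`.
#' @export
lognormality_ks <- function(x, n_boot = 1000) {
  if (length(x) < 8) stop("data error: need at least 8 values")
  if (any(!is.finite(x)) || any(x <= 0))
    stop("data error: values must be positive and finite")
  lx <- log(x)
  D <- ks_stat_norm(lx)
  null <- ks_null_table(length(x), n_boot)
  p_naive <- suppressWarnings(
    ks.test(lx, "pnorm", mean(lx), sd(lx))$p.value)
  structure(list(statistic = D,
                 p.value = (1 + sum(null >= D)) / (n_boot + 1),
                 p_naive = p_naive, n = length(x), n_boot = n_boot,
                 method = "KS log-normality test, parametric bootstrap"),
            class = "lognormality_ks")
}

#' @export
print.lognormality_ks <- function(x, ...) {
  cat(sprintf("%s\nD = %.4f, bootstrap p = %.4f (naive p = %.4f), n = %d\n",
              x$method, x$statistic, x$p.value, x$p_naive, x$n))
  invisible(x)
}

#' Empirical CDF of rates in log space
#'
#' @param x positive values (single-cell mean rates).
#' @return A data frame with `log_rate` (sorted) and `cdf` (right-continuous
#'   step heights `i/n`), plus the [stats::ecdf()] function as attribute
#'   `"fun"`.
#' @export
log_ecdf <- function(x) {
  if (length(x) == 0) stop("data error: empty input")
  if (any(x <= 0)) stop("data error: values must be positive")
  lx <- sort(log(x))
  out <- data.frame(log_rate = lx, cdf = seq_along(lx) / length(lx))
  attr(out, "fun") <- stats::ecdf(lx)
  out
}

#' Noise-mean trends across cells
#'
#' Ordinary least squares of intracellular SD on posterior mean rate, and of
#' CV on mean — the regressions behind the mean-noise relationship (SD
#' rises with the mean; CV falls, i.e. SNR rises).
#'
#' @param summaries a [summarize_cells()] data frame (needs `mean`, `sd`,
#'   `cv`).
#' @return A list with `sd_fit` and `cv_fit` (each `c(intercept, slope)`),
#'   slope sign flags, and the underlying `lm` fits.
#' @export
cv_mean_trend <- function(summaries) {
  stopifnot(all(c("mean", "sd", "cv") %in% names(summaries)))
  if (nrow(summaries) < 3) stop("data error: need at least 3 cells")
  if (sd(summaries$mean) == 0)
    stop("data error: degenerate input (all means equal)")
  f1 <- lm(sd ~ mean, data = summaries)
  f2 <- lm(cv ~ mean, data = summaries)
  list(sd_fit = unname(coef(f1)), cv_fit = unname(coef(f2)),
       sd_slope_sign = sign(unname(coef(f1)[2])),
       cv_slope_sign = sign(unname(coef(f2)[2])),
       lm_sd = f1, lm_cv = f2)
}

#' Gamma fits to per-cell rate SDs
#'
#' Maximum-likelihood gamma fit to the standard deviations of single-cell
#' rate posteriors, per group (e.g. CRM class) — narrower fitted means
#' indicate noise repression by the regulatory element.
#'
#' @param sds positive per-cell SDs.
#' @param group optional grouping factor (recycled).
#' @return A data frame with `group`, `n`, `shape`, `scale` and the fitted
#'   mean `shape * scale`.
#' @export
fit_sd_gamma <- function(sds, group = NULL) {
  if (any(!is.finite(sds)) || any(sds <= 0))
    stop("data error: SDs must be positive and finite")
  if (is.null(group)) group <- rep("all", length(sds))
  sp <- split(sds, group)
  out <- lapply(names(sp), function(g) {
    x <- sp[[g]]
    if (length(x) < 10) stop("data error: need >= 10 SDs in group ", g)
    if (var(x) == 0) stop("data error: zero variance in group ", g)
    st <- list(shape = mean(x)^2 / var(x), rate = mean(x) / var(x))
    fit <- MASS::fitdistr(x, "gamma", start = st, lower = c(1e-8, 1e-8))
    data.frame(group = g, n = length(x),
               shape = unname(fit$estimate["shape"]),
               scale = 1 / unname(fit$estimate["rate"]),
               mean = unname(fit$estimate["shape"] / fit$estimate["rate"]))
  })
  do.call(rbind, out)
}

#' Containment fraction between two groups of rate posteriors
#'
#' Quantifies the "filter" action of a regulatory element: cells of group A
#' and group B are rank-matched by posterior-mean quantile, and an A cell is
#' contained if its central `level` posterior interval lies within
#' (closed-interval sense) the matched B cell's interval.  Returns the
#' contained fraction of A.
#'
#' @param samples_a,samples_b lists of per-cell posterior sample vectors.
#' @param level central posterior interval mass (default 0.9).
#' @return Fraction in `[0, 1]`.
#' @export
containment_fraction <- function(samples_a, samples_b, level = 0.9) {
  if (!length(samples_a) || !length(samples_b))
    stop("data error: empty group")
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ia <- order(vapply(samples_a, mean, numeric(1)))
  ib <- order(vapply(samples_b, mean, numeric(1)))
  na <- length(ia); nb <- length(ib)
  eps <- 1e-12
  contained <- vapply(seq_len(na), function(r) {
    j <- which.min(abs((seq_len(nb) - 0.5) / nb - (r - 0.5) / na))
    a <- quantile(samples_a[[ia[r]]], qs, names = FALSE)
    b <- quantile(samples_b[[ib[j]]], qs, names = FALSE)
    a[1] >= b[1] - eps && a[2] <= b[2] + eps
  }, logical(1))
  mean(contained)
}

#' Classify a cell's promoter behavior
#'
#' Assigns one of four behavior classes seen in single-cell rate posteriors:
#' `multimodal` (a two-component Gaussian mixture beats one component by a
#' BIC margin), otherwise `slow-wide` (CV above the cohort's upper-quartile
#' cut: the rate range is traversed slowly), otherwise `fast-high` or
#' `fast-low` by the posterior mean relative to the cohort median.
#'
#' @param samples posterior rate samples for one cell (>= 100).
#' @param cv_upper cohort upper-quartile CV cut.
#' @param mean_cut cohort median of posterior means.
#' @param bic_margin mixture-evidence margin (default 10).
#' @return One of `"multimodal"`, `"slow-wide"`, `"fast-high"`, `"fast-low"`.
#' @seealso [classify_cells()] for whole-cohort classification.
#' @export
classify_behavior <- function(samples, cv_upper, mean_cut, bic_margin = 10) {
  if (length(samples) < 100) stop("data error: need >= 100 samples")
  if (is_multimodal(samples, margin = bic_margin)) return("multimodal")
  m <- mean(samples)
  cv <- sd(samples) / m
  if (cv > cv_upper) return("slow-wide")
  if (m >= mean_cut) "fast-high" else "fast-low"
}

#' @rdname classify_behavior
#' @param fit a `ratefit`.
#' @return `classify_cells`: a named character vector, one class per cell
#'   (the classes partition the cohort).
#' @export
classify_cells <- function(fit, bic_margin = 10) {
  S <- rate_samples(fit, "tau1")
  means <- colMeans(S)
  cvs <- apply(S, 2, sd) / means
  cv_upper <- quantile(cvs, 0.75, names = FALSE)
  mean_cut <- median(means)
  setNames(vapply(seq_len(ncol(S)), function(i)
    classify_behavior(S[, i], cv_upper, mean_cut, bic_margin), character(1)),
    fit$cell_ids)
}
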