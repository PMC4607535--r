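#' @export
print.ratefit <- function(x, ...) {
  cat("Hierarchical transcription-rate fit\n")
  cat(sprintf("  %d cells, %d construct(s): %s\n", length(x$cell_ids),
              length(x$constructs),
              paste(head(x$constructs, 5), collapse = ", ")))
  cat(sprintf("  %d chain(s) x %d iterations (burn-in %d, thin %d): %d retained draws\n",
              length(x$chains), x$control$iterations, x$control$burnin,
              x$control$thin, nrow(x$chains[[1]]$tau1) * length(x$chains)))
  acc <- x$chains[[1]]$acceptance
  cat("  acceptance (chain 1): ",
      paste(sprintf("%s=%.2f", names(acc), acc), collapse = " "), "\n")
  cat(sprintf("  posterior mean sigma2: %.4g\n", mean(rate_samples(x, "sigma2"))))
  invisible(x)
}

#' Summarize a hierarchical rate fit
#'
#' @param object a `ratefit`.
#' @param rate which rate summary to report (see [summarize_cells()]).
#' @param multimodal run the per-cell bimodality check.
#' @param ... unused.
#' @return A `summary.ratefit`: per-cell summaries, per-construct population
#'   statistics and the noise-variance posterior mean.
#' @export
summary.ratefit <- function(object, rate = "tau1", multimodal = FALSE, ...) {
  cells <- summarize_cells(object, rate = rate, multimodal = multimodal)
  structure(list(cells = cells, population = population_stats(cells),
                 sigma2 = mean(rate_samples(object, "sigma2")),
                 rate = rate),
            class = "summary.ratefit")
}

#' @export
print.summary.ratefit <- function(x, ...) {
  cat(sprintf("Population statistics of single-cell mean %s (posterior):\n",
              x$rate))
  print.data.frame(x$population, row.names = FALSE, digits = 3)
  cat(sprintf("\nPosterior mean measurement-noise variance: %.4g\n", x$sigma2))
  cat(sprintf("%d cells summarized; see $cells for per-cell rows\n",
              nrow(x$cells)))
  invisible(x)
}

#' Posterior-mean per-cell parameters
#'
#' @param object a `ratefit`.
#' @param ... unused.
#' @return A cells x parameters matrix of posterior means.
#' @export
coef.ratefit <- function(object, ...) {
  pars <- c("c", "tau0", "tau1", "T", "M0", "P0")
  out <- vapply(pars, function(p) colMeans(rate_samples(object, p)),
                numeric(length(object$cell_ids)))
  rownames(out) <- object$cell_ids
  out
}

#' Predicted mean fluorescence paths
#'
#' Deterministic mean trajectory at the posterior-mean parameters of each
#' cell, on that cell's observation grid.
#'
#' @param object a `ratefit`.
#' @param cells optional cell ids (default all).
#' @param ... unused.
#' @return A named list of data frames (`time`, `F`).
#' @export
predict.ratefit <- function(object, cells = NULL, ...) {
  if (is.null(object$traces)) stop("fit carries no traces (chains loaded from disk)")
  cf <- coef(object)
  ids <- if (is.null(cells)) object$cell_ids else cells
  out <- lapply(ids, function(id) {
    i <- match(id, object$cell_ids)
    p <- as.data.frame(as.list(cf[i, ]))
    tr <- object$traces[[i]]
    ode_trajectory(p, object$constants, tr$time)[, c("time", "F")]
  })
  setNames(out, ids)
}

#' Residuals of a rate fit
#'
#' Observed fluorescence minus the posterior-mean predicted path.
#'
#' @param object a `ratefit`.
#' @param ... unused.
#' @return A long data frame: `cell_id`, `time`, `observed`, `fitted`,
#'   `residual`.
#' @export
residuals.ratefit <- function(object, ...) {
  pred <- predict(object)
  do.call(rbind, lapply(object$cell_ids, function(id) {
    i <- match(id, object$cell_ids)
    tr <- object$traces[[i]]
    data.frame(cell_id = id, time = tr$time, observed = tr$value,
               fitted = pred[[id]]$F,
               residual = tr$value - pred[[id]]$F)
  }))
}

#' Posterior-predictive simulation from a fit
#'
#' Draws a retained posterior sample per replicate and re-simulates each
#' cell's trace through the stochastic forward model and the observation
#' noise — the check that predictive traces bracket the data.
#'
#' @param object a `ratefit`.
#' @param nsim number of replicate trace sets.
#' @param seed optional seed.
#' @param ... unused.
#' @return A list of `nsim` [trace_set()] objects.
#' @export
simulate.ratefit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$traces)) stop("fit carries no traces (chains loaded from disk)")
  if (!is.null(seed)) set.seed(seed)
  k <- object$constants
  S <- lapply(c("c", "tau0", "tau1", "T", "M0", "P0"), rate_samples,
              fit = object)
  names(S) <- c("c", "tau0", "tau1", "T", "M0", "P0")
  s2 <- rate_samples(object, "sigma2")
  ndraw <- nrow(S$c)
  lapply(seq_len(nsim), function(r) {
    d <- sample.int(ndraw, 1)
    kk <- k
    kk$sigma2 <- s2[d]
    trace_set(lapply(seq_along(object$cell_ids), function(i) {
      tr <- object$traces[[i]]
      path <- cpp_simulate_path(tr$time, S$c[d, i], S$tau0[d, i],
                                S$tau1[d, i], S$T[d, i], S$M0[d, i],
                                S$P0[d, i], k$delta_M, k$delta_P, k$alpha,
                                0.1, TRUE)
      render_trace(path[, 2], tr$time, kk, cell_id = tr$cell_id,
                   construct_id = tr$construct_id)
    }))
  })
}

#' Plot a rate fit
#'
#' @param x a `ratefit`.
#' @param type `"stack"` (sorted per-cell rate density heat map),
#'   `"traces"` (observed vs fitted fluorescence), or `"switch"` (centered
#'   switch-time spreads vs rate order).
#' @param n_traces how many cells to overlay for `type = "traces"`.
#' @param ... passed to the underlying plotting call.
#' @return The input, invisibly.
#' @export
plot.ratefit <- function(x, type = c("stack", "traces", "switch"),
                         n_traces = 6, ...) {
  type <- match.arg(type)
  if (type == "stack") {
    plot(build_rate_stack(x), ...)
  } else if (type == "traces") {
    if (is.null(x$traces)) stop("fit carries no traces")
    pred <- predict(x)
    ids <- head(x$cell_ids, n_traces)
    ylim <- range(unlist(lapply(ids, function(id)
      x$traces[[match(id, x$cell_ids)]]$value)))
    plot(NA, xlim = c(0, max(vapply(x$traces, function(tr) max(tr$time),
                                    numeric(1)))),
         ylim = ylim, xlab = "time (min)", ylab = "fluorescence (AU)", ...)
    for (j in seq_along(ids)) {
      tr <- x$traces[[match(ids[j], x$cell_ids)]]
      points(tr$time, tr$value, col = j, pch = 16, cex = 0.4)
      lines(pred[[ids[j]]]$time, pred[[ids[j]]]$F, col = j, lwd = 2)
    }
  } else {
    Tm <- rate_samples(x, "T")
    means <- colMeans(rate_samples(x, "tau1"))
    ord <- order(means)
    w <- apply(Tm, 2, function(s) diff(quantile(s - median(s), c(0.05, 0.95))))
    plot(seq_along(ord), w[ord], xlab = "cells (sorted by mean rate)",
         ylab = "central 90% switch-time width (min)", pch = 16, ...)
  }
  invisible(x)
}
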