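# split-Rhat and effective sample size, standard formulas

split_halves <- function(chains) {
  out <- list()
  for (ch in chains) {
    n2 <- floor(length(ch) / 2)
    out <- c(out, list(ch[seq_len(n2)], ch[n2 + seq_len(n2)]))
  }
  out
}

rhat_split <- function(chains) {
  sp <- split_halves(chains)
  n <- length(sp[[1]])
  if (n < 2) return(NA_real_)
  mat <- vapply(sp, identity, numeric(n))
  W <- mean(apply(mat, 2, var))
  B <- n * var(colMeans(mat))
  if (!is.finite(W) || W < 1e-12) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_basic <- function(chains) {
  sp <- split_halves(chains)
  n <- length(sp[[1]])
  m <- length(sp)
  if (n < 4) return(NA_real_)
  mat <- vapply(sp, identity, numeric(n))
  W <- mean(apply(mat, 2, var))
  B <- n * var(colMeans(mat))
  varplus <- (n - 1) / n * W + B / n
  if (!is.finite(varplus) || varplus < 1e-12) return(NA_real_)
  maxlag <- min(n - 2, 200)
  acovs <- vapply(seq_len(m), function(j) {
    a <- stats::acf(mat[, j], lag.max = maxlag, plot = FALSE,
                    type = "covariance")$acf[, 1, 1]
    a
  }, numeric(maxlag + 1))
  rho <- 1 - (W - rowMeans(acovs)[-1]) / varplus
  # Geyer initial positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  tau <- 1
  for (p in seq_len(npair)) {
    s <- rho[2 * p - 1] + rho[2 * p]
    if (s < 0) break
    tau <- tau + 2 * s
  }
  max(m * n / tau, 1)
}

#' Convergence diagnostics for a fitted model
#'
#' Split potential scale reduction (Rhat) and effective sample size for the
#' per-cell rates, copy numbers and switch times, plus the global noise
#' variance.  Parameters with Rhat above `rhat_max` or ESS below `ess_min`
#' are flagged; constant (degenerate) chains are flagged as such.
#'
#' @param fit a `ratefit` (two or more chains recommended; with a single
#'   chain the halves of that chain are compared and a warning is recorded).
#' @param params which per-cell parameters to assess.
#' @param rhat_max,ess_min flag thresholds.
#' @return A data frame of class `mcmc_diagnostics` with one row per scalar
#'   parameter: `param`, `rhat`, `ess`, `flag`.
#' @export
mcmc_diagnostics <- function(fit, params = c("tau1", "c", "T"),
                             rhat_max = 1.05, ess_min = 100) {
  stopifnot(inherits(fit, "ratefit"))
  single <- length(fit$chains) < 2
  rows <- list()
  add <- function(name, chains) {
    r <- rhat_split(chains)
    e <- ess_basic(chains)
    flag <- if (!is.finite(r)) "degenerate"
    else if (r > rhat_max || (is.finite(e) && e < ess_min)) "check"
    else "ok"
    rows[[length(rows) + 1L]] <<- data.frame(param = name, rhat = r, ess = e,
                                             flag = flag)
  }
  for (p in params) {
    per_chain <- lapply(fit$chains, `[[`, p)
    for (i in seq_along(fit$cell_ids))
      add(sprintf("%s[%s]", p, fit$cell_ids[i]),
          lapply(per_chain, function(m) m[, i]))
  }
  add("sigma2", lapply(fit$chains, `[[`, "sigma2"))
  out <- do.call(rbind, rows)
  attr(out, "warning") <- if (single)
    "single chain: within-chain halves compared only" else NULL
  class(out) <- c("mcmc_diagnostics", "data.frame")
  out
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("MCMC diagnostics: %d parameters, %d flagged\n", nrow(x),
              sum(x$flag != "ok")))
  if (!is.null(attr(x, "warning"))) cat("  note:", attr(x, "warning"), "\n")
  worst <- x[order(-ifelse(is.finite(x$rhat), x$rhat, Inf)), ]
  print.data.frame(head(worst, 10), row.names = FALSE)
  invisible(x)
}
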