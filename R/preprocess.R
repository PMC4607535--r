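#' Background preselection of fluorescence traces
#'
#' Keeps a trace iff it has at least `min_points` samples strictly above the
#' preselection `threshold`.  The defaults are the values used in the imaging
#' workflow this package models: untransfected-cell autofluorescence tops out
#' around 7,000 AU, so a threshold of 8,000 AU with ten or more points above
#' it separates transfected cells from background.
#'
#' @param traces a [trace_set()].
#' @param threshold preselection threshold (AU), non-negative.
#' @param min_points minimum number of samples strictly above threshold.
#' @return A list with `kept` (a [trace_set()], input order preserved) and
#'   `report` (a `qc_report`).
#' @export
preselect <- function(traces, threshold = 8000, min_points = 10) {
  if (length(traces) == 0) stop("data error: no traces supplied")
  if (threshold < 0) stop("configuration error: threshold must be >= 0")
  keep <- vapply(traces, function(tr) sum(tr$value > threshold) >= min_points,
                 logical(1))
  disp <- data.frame(cell_id = vapply(traces, `[[`, character(1), "cell_id"),
                     rule = "preselect", kept = keep,
                     reason = ifelse(keep, "",
                                     sprintf("fewer than %d points above %g AU",
                                             min_points, threshold)))
  list(kept = trace_set(unclass(traces)[keep]),
       report = qc_report(list(disp), n_in = length(traces),
                          n_out = sum(keep)))
}

#' Split a trace into per-generation segments at division markers
#'
#' Each division marker starts a new generation: the split index is the first
#' sample at or after the marker (the post-mitotic sample belongs to the new
#' generation), and each segment is re-indexed so its own time starts at 0.
#' Segments shorter than `min_points` are discarded and recorded.
#'
#' @param trace a [fluor_trace()].
#' @param min_points minimum surviving segment length.
#' @return A list with `segments` (a [trace_set()]) and `dropped` (a data
#'   frame of discarded segments with reasons).
#' @export
synchronize_to_division <- function(trace, min_points = 10) {
  stopifnot(inherits(trace, "fluor_trace"))
  div <- sort(trace$divisions)
  if (any(div < min(trace$time) | div > max(trace$time)))
    stop("data error: division marker outside the trace time range")
  cuts <- vapply(div, function(d) which(trace$time >= d)[1], integer(1))
  cuts <- unique(cuts[!is.na(cuts) & cuts > 1])
  bounds <- c(1L, cuts, length(trace$time) + 1L)
  segs <- list()
  dropped <- list()
  for (g in seq_len(length(bounds) - 1L)) {
    idx <- seq.int(bounds[g], bounds[g + 1L] - 1L)
    id <- if (length(bounds) > 2L) sprintf("%s_g%d", trace$cell_id, g) else trace$cell_id
    if (length(idx) < min_points) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(cell_id = id, rule = "synchronize", kept = FALSE,
                   reason = sprintf("segment of %d < %d points", length(idx),
                                    min_points))
      next
    }
    segs[[length(segs) + 1L]] <-
      fluor_trace(id, trace$construct_id, trace$time[idx] - trace$time[idx[1]],
                  trace$value[idx], meta = trace$meta)
  }
  list(segments = trace_set(segs),
       dropped = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Truncate a trace at its first fluorescence maximum
#'
#' Returns the prefix up to and including the first occurrence of the global
#' maximum.  After division the reporter dilutes into the daughters, so the
#' rising phase up to the peak is the informative single-cycle portion of an
#' onset curve.  Idempotent.
#'
#' @param trace a [fluor_trace()].
#' @return The truncated [fluor_trace()].
#' @export
truncate_at_peak <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  cut <- which.max(trace$value)  # first occurrence on ties
  fluor_trace(trace$cell_id, trace$construct_id, trace$time[seq_len(cut)],
              trace$value[seq_len(cut)],
              divisions = trace$divisions[trace$divisions <= trace$time[cut]],
              meta = trace$meta)
}

#' Random subsample of traces per construct
#'
#' For each construct draws a target count uniformly from
#' `[n_low, n_high]` and selects that many traces uniformly without
#' replacement (capped at availability).  Constructs with fewer than `n_low`
#' traces are passed through unchanged with a warning recorded.
#'
#' @param traces a [trace_set()].
#' @param n_low,n_high selection bounds (default 30-35 curves per construct).
#' @param seed integer seed; the selection is reproducible given the seed.
#' @return A list with `kept` (a [trace_set()]) and `report` (a `qc_report`
#'   whose `warnings` field lists under-sized constructs).
#' @export
subsample_traces <- function(traces, n_low = 30, n_high = 35, seed = 1L) {
  stopifnot(n_low <= n_high, n_low >= 1)
  set.seed(seed)
  cons <- trace_constructs(traces)
  keep <- logical(length(traces))
  warnings <- character(0)
  for (lab in unique(cons)) {
    idx <- which(cons == lab)
    if (length(idx) < n_low) {
      keep[idx] <- TRUE
      warnings <- c(warnings, sprintf(
        "construct %s: only %d traces available (< %d); all kept", lab,
        length(idx), n_low))
      next
    }
    n <- sample(seq.int(n_low, n_high), 1)
    keep[sample(idx, min(n, length(idx)))] <- TRUE
  }
  disp <- data.frame(cell_id = vapply(traces, `[[`, character(1), "cell_id"),
                     rule = "subsample", kept = keep,
                     reason = ifelse(keep, "", "not selected"))
  rep <- qc_report(list(disp), n_in = length(traces), n_out = sum(keep),
                   seed = seed)
  rep$warnings <- warnings
  list(kept = trace_set(unclass(traces)[keep]), report = rep)
}

qc_report <- function(dispositions, n_in, n_out, seed = NA_integer_) {
  structure(list(dispositions = do.call(rbind, dispositions),
                 counts = c(input = n_in, kept = n_out, dropped = n_in - n_out),
                 seed = seed, warnings = character(0)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Trace QC report:\n")
  cat(sprintf("  input %d -> kept %d (dropped %d)\n", x$counts["input"],
              x$counts["kept"], x$counts["dropped"]))
  if (length(x$warnings)) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Full trace quality-control pipeline
#'
#' Applies, in order: background preselection, in-silico division
#' synchronization, truncation at the first fluorescence maximum, a
#' minimum-length filter, and seeded per-construct subsampling.  No emitted
#' trace has fewer than `min_points` samples.
#'
#' @inheritParams preselect
#' @inheritParams subsample_traces
#' @return A list with `traces` (a [trace_set()]) and `report` (a
#'   `qc_report` with per-stage counts and dispositions).
#' @export
preprocess_traces <- function(traces, threshold = 8000, min_points = 10,
                              n_low = 30, n_high = 35, seed = 1L) {
  pre <- preselect(traces, threshold, min_points)
  segs <- list()
  dropped <- list()
  for (tr in pre$kept) {
    sy <- synchronize_to_division(tr, min_points)
    segs <- c(segs, unclass(sy$segments))
    if (!is.null(sy$dropped)) dropped[[length(dropped) + 1L]] <- sy$dropped
  }
  trunc <- lapply(segs, truncate_at_peak)
  long <- vapply(trunc, function(tr) length(tr$time) >= min_points, logical(1))
  for (tr in trunc[!long]) {
    dropped[[length(dropped) + 1L]] <-
      data.frame(cell_id = tr$cell_id, rule = "truncate", kept = FALSE,
                 reason = sprintf("fewer than %d points after peak truncation",
                                  min_points))
  }
  sub <- subsample_traces(trace_set(trunc[long]), n_low, n_high, seed)
  report <- qc_report(c(list(pre$report$dispositions),
                        dropped,
                        list(sub$report$dispositions)),
                      n_in = length(traces), n_out = length(sub$kept),
                      seed = seed)
  report$warnings <- sub$report$warnings
  report$stage_counts <- c(input = length(traces),
                           preselected = length(pre$kept),
                           synchronized = length(segs),
                           truncated = sum(long),
                           subsampled = length(sub$kept))
  list(traces = sub$kept, report = report)
}
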