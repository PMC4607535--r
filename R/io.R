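#' Write and read fluorescence trace tables
#'
#' Traces travel as tab-separated text with columns `cell_id`,
#' `construct_id`, `time_min`, `fluorescence_au`, `division_flag`.
#' Fluorescence is written with 17 significant digits so a write/read round
#' trip reproduces values bit-exactly.
#'
#' @param traces a [trace_set()].
#' @param path file path.
#' @return `write_traces`: the path, invisibly.  `read_traces`: a
#'   [trace_set()] grouped by construct; schema violations raise parse
#'   errors naming the offending row.
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("cell_id\tconstruct_id\ttime_min\tfluorescence_au\tdivision_flag",
             con)
  for (tr in traces) {
    flag <- as.integer(tr$time %in% tr$divisions)
    writeLines(sprintf("%s\t%s\t%.10g\t%.17g\t%d", tr$cell_id,
                       tr$construct_id, tr$time, tr$value, flag), con)
  }
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cell_id", "construct_id", "time_min", "fluorescence_au",
            "division_flag")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("parse error: missing column(s) ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("empty trace file: ", path)
    return(trace_set())
  }
  tm <- suppressWarnings(as.numeric(df$time_min))
  fl <- suppressWarnings(as.numeric(df$fluorescence_au))
  dv <- suppressWarnings(as.integer(df$division_flag))
  bad <- which(!is.finite(tm) | !is.finite(fl) | is.na(dv))
  if (length(bad))
    stop("parse error: non-numeric value at data row(s) ",
         paste(head(bad, 5), collapse = ", "))
  traces <- list()
  for (lab in unique(df$construct_id)) {
    sub <- df$construct_id == lab
    for (id in unique(df$cell_id[sub])) {
      i <- which(sub & df$cell_id == id)
      tt <- tm[i]
      if (length(tt) > 1) {
        dts <- diff(tt)
        if (any(dts <= 0) || max(dts) - min(dts) > 1e-8 * max(dts))
          stop("parse error: non-uniform time grid for cell ", id,
               " (first data row ", i[1], ")")
      }
      traces[[length(traces) + 1L]] <-
        fluor_trace(id, lab, tt, fl[i], divisions = tt[dv[i] == 1L])
    }
  }
  trace_set(traces)
}

#' Write and read ground-truth parameter tables
#'
#' Companion tab-separated table of generating parameters keyed by
#' `cell_id`, as emitted by [simulate_study()].
#'
#' @param truth the truth data frame.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize a QC report as JSON
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @export
write_qc_report <- function(report, path) {
  jsonlite::write_json(list(counts = as.list(report$counts),
                            stage_counts = as.list(report$stage_counts),
                            seed = report$seed,
                            warnings = report$warnings,
                            dispositions = report$dispositions),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

config_defaults <- function() {
  list(paths = list(out_dir = "."),
       seed = 1L,
       design = list(n_constructs = 19L, cells_per_construct = 30L,
                     interval = 30, duration = 2880),
       constants = list(delta_M = 0.01, delta_P = 5e-4, alpha = 1, kappa = 1,
                        sigma2 = 4e4),
       preprocess = list(threshold = 8000, min_points = 10L, n_low = 30L,
                         n_high = 35L),
       mcmc = list(iterations = 50000L, burnin = 20000L, thin = 10L,
                   chains = 2L, filter_dt = 2),
       analysis = list(n_grid = 200L))
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON configuration, fills defaults
#' (30-min interval, 2880-min duration, 8000-AU threshold, 10-point
#' minimum, publication-scale MCMC budget), rejects unknown keys, and
#' checks invariants, reporting every failure at once.
#'
#' @param path config file path.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw)) raw <- list()
  cfg <- config_defaults()
  errs <- character(0)
  unknown_top <- setdiff(names(raw), names(cfg))
  if (length(unknown_top))
    errs <- c(errs, paste0("unknown key(s): ",
                           paste(unknown_top, collapse = ", ")))
  for (sec in intersect(names(raw), names(cfg))) {
    if (sec == "seed") { cfg$seed <- as.integer(raw$seed); next }
    unknown <- setdiff(names(raw[[sec]]), names(cfg[[sec]]))
    if (length(unknown))
      errs <- c(errs, paste0("unknown key(s) in '", sec, "': ",
                             paste(unknown, collapse = ", ")))
    for (nm in intersect(names(raw[[sec]]), names(cfg[[sec]])))
      cfg[[sec]][[nm]] <- raw[[sec]][[nm]]
  }
  if (cfg$mcmc$burnin >= cfg$mcmc$iterations)
    errs <- c(errs, "mcmc: burnin must be < iterations")
  if (cfg$design$duration %% cfg$design$interval != 0)
    errs <- c(errs, "design: duration must be a multiple of interval")
  if (cfg$preprocess$threshold < 0)
    errs <- c(errs, "preprocess: threshold must be >= 0")
  if (cfg$preprocess$n_low > cfg$preprocess$n_high)
    errs <- c(errs, "preprocess: n_low must be <= n_high")
  if (length(errs))
    stop("configuration error:\n  ", paste(errs, collapse = "\n  "))
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

write_meta <- function(path, cfg, extra = list()) {
  jsonlite::write_json(c(list(seed = cfg$seed, config_hash = config_hash(cfg),
                              r_version = as.character(getRversion()),
                              package_version =
                                as.character(utils::packageVersion("ratescope")),
                              timestamp = format(Sys.time(), tz = "UTC")),
                         extra),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Persist and reload posterior chains as delimited text
#'
#' Chains are written as one tab-separated table per chain (long format:
#' draw, cell, parameter columns) plus hyperparameter tables and a JSON
#' metadata file.
#'
#' @param fit a `ratefit`.
#' @param dir output directory (created if needed).
#' @export
write_chains <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pars <- c("c", "tau0", "tau1", "T", "M0", "P0")
  for (ch in seq_along(fit$chains)) {
    cc <- fit$chains[[ch]]
    long <- do.call(rbind, lapply(seq_along(fit$cell_ids), function(i) {
      data.frame(draw = seq_len(nrow(cc$tau1)), cell_id = fit$cell_ids[i],
                 construct_id = fit$construct[i],
                 c = cc$c[, i], tau0 = cc$tau0[, i], tau1 = cc$tau1[, i],
                 T = cc$T[, i], M0 = cc$M0[, i], P0 = cc$P0[, i])
    }))
    utils::write.table(long, file.path(dir, sprintf("chain%d_cells.tsv", ch)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    glob <- data.frame(draw = seq_along(cc$sigma2), sigma2 = cc$sigma2,
                       bc = cc$bc, logpost = cc$logpost)
    utils::write.table(glob, file.path(dir, sprintf("chain%d_global.tsv", ch)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(n_chains = length(fit$chains),
                            cell_ids = fit$cell_ids,
                            construct = fit$construct,
                            constructs = fit$constructs,
                            T_window = fit$T_window, seed = fit$seed,
                            control = unclass(fit$control),
                            constants = unclass(fit$constants)),
                       file.path(dir, "chains_meta.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname write_chains
#' @return `read_chains`: a `ratefit` (without the original traces; methods
#'   needing them, like [predict.ratefit()], are unavailable).
#' @export
read_chains <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "chains_meta.json"))
  chains <- lapply(seq_len(meta$n_chains), function(ch) {
    long <- read.delim(file.path(dir, sprintf("chain%d_cells.tsv", ch)),
                       stringsAsFactors = FALSE)
    glob <- read.delim(file.path(dir, sprintf("chain%d_global.tsv", ch)),
                       stringsAsFactors = FALSE)
    ndraw <- max(long$draw)
    out <- list()
    for (p in c("c", "tau0", "tau1", "T", "M0", "P0"))
      out[[p]] <- vapply(meta$cell_ids, function(id)
        long[[p]][long$cell_id == id], numeric(ndraw))
    out$sigma2 <- glob$sigma2
    out$bc <- glob$bc
    out$logpost <- glob$logpost
    out
  })
  k <- do.call(kinetic_constants, meta$constants)
  structure(list(chains = chains, cell_ids = meta$cell_ids,
                 construct = meta$construct, constructs = meta$constructs,
                 traces = NULL, constants = k, control = meta$control,
                 T_window = meta$T_window, seed = meta$seed),
            class = "ratefit")
}

#' Run one stage of the analysis pipeline
#'
#' Stages, in order: `simulate` (synthetic study to `traces.tsv` +
#' `truth.tsv`), `preprocess` (QC to `preprocessed.tsv` +
#' `qc_report.json`), `infer` (hierarchical fit, chains as text tables),
#' `analyze` (summaries, population table, rate stack, figures).  Each
#' stage checks that its prerequisite artifacts exist and embeds provenance
#' (seed, config hash, versions) in a JSON metadata file; deterministic
#' stages rerun byte-identically under the same config.
#'
#' @param stage one of `"simulate"`, `"preprocess"`, `"infer"`, `"analyze"`.
#' @param config a `pipeline_config` from [load_config()], or a path to one.
#' @param verbose print progress.
#' @return Invisibly, a named list of artifact paths (exit status 0 is
#'   implied by normal return; errors propagate as conditions).
#' @export
run_pipeline <- function(stage = c("simulate", "preprocess", "infer",
                                   "analyze"), config, verbose = FALSE) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- load_config(config)
  out <- config$paths$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  p <- function(f) file.path(out, f)
  need <- function(f, prior) {
    if (!file.exists(p(f)))
      stop("missing prerequisite '", f, "': run the '", prior,
           "' stage first")
  }
  arts <- list()
  if (stage == "simulate") {
    des <- default_study_design(config$design$n_constructs, seed = config$seed)
    des$cells <- rep_len(as.integer(config$design$cells_per_construct),
                         length(des$constructs))
    des$interval <- config$design$interval
    des$duration <- config$design$duration
    k <- do.call(kinetic_constants, config$constants)
    say("simulating %d constructs x %d cells", length(des$constructs),
        des$cells[1])
    study <- simulate_study(des, k)
    write_traces(study$traces, p("traces.tsv"))
    write_ground_truth(study$truth, p("truth.tsv"))
    write_meta(p("simulate_meta.json"), config,
               list(n_traces = length(study$traces)))
    arts <- list(traces = p("traces.tsv"), truth = p("truth.tsv"))
  } else if (stage == "preprocess") {
    need("traces.tsv", "simulate")
    traces <- read_traces(p("traces.tsv"))
    pp <- preprocess_traces(traces, threshold = config$preprocess$threshold,
                            min_points = config$preprocess$min_points,
                            n_low = config$preprocess$n_low,
                            n_high = config$preprocess$n_high,
                            seed = config$seed)
    write_traces(pp$traces, p("preprocessed.tsv"))
    write_qc_report(pp$report, p("qc_report.json"))
    write_meta(p("preprocess_meta.json"), config,
               list(counts = as.list(pp$report$stage_counts)))
    arts <- list(traces = p("preprocessed.tsv"), qc = p("qc_report.json"))
  } else if (stage == "infer") {
    need("preprocessed.tsv", "preprocess")
    traces <- read_traces(p("preprocessed.tsv"))
    k <- do.call(kinetic_constants, config$constants)
    ctl <- mcmc_control(iterations = config$mcmc$iterations,
                        burnin = config$mcmc$burnin,
                        thin = config$mcmc$thin,
                        chains = config$mcmc$chains,
                        filter_dt = config$mcmc$filter_dt)
    say("fitting %d traces (%d iterations x %d chains)", length(traces),
        ctl$iterations, ctl$chains)
    fit <- fit_rates(traces, k, ctl, seed = config$seed)
    write_chains(fit, p("chains"))
    write_meta(p("infer_meta.json"), config,
               list(acceptance = as.list(fit$chains[[1]]$acceptance)))
    arts <- list(chains = p("chains"))
  } else {
    if (!file.exists(p("chains")))
      stop("missing prerequisite 'chains': run the 'infer' stage first")
    fit <- read_chains(p("chains"))
    summ <- summarize_cells(fit, multimodal = FALSE)
    utils::write.table(summ, p("cell_summaries.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    pop <- population_stats(summ)
    utils::write.table(pop, p("population_stats.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    stack <- build_rate_stack(fit, n_grid = config$analysis$n_grid)
    utils::write.table(cbind(rate = stack$grid, stack$density),
                       p("rate_stack.tsv"), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    png(p("rate_stack.png"), width = 900, height = 600)
    plot(stack)
    dev.off()
    ec <- log_ecdf(summ$mean)
    png(p("log_ecdf.png"), width = 700, height = 500)
    plot(ec$log_rate, ec$cdf, type = "s", xlab = "log mean rate",
         ylab = "cumulative fraction of cells")
    dev.off()
    write_meta(p("analyze_meta.json"), config,
               list(n_cells = nrow(summ)))
    arts <- list(summaries = p("cell_summaries.tsv"),
                 population = p("population_stats.tsv"),
                 stack = p("rate_stack.tsv"))
  }
  invisible(arts)
}
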