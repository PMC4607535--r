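test_that("preselection keeps traces with enough points above threshold", {
  above10 <- make_trace(c(rep(9000, 10), rep(5000, 5)), "keep10")
  above9 <- make_trace(c(rep(9000, 9), rep(5000, 6)), "drop9")
  autofluor <- make_trace(rep(7000, 20), "background")
  res <- preselect(trace_set(list(above10, above9, autofluor)))
  ids <- vapply(res$kept, `[[`, character(1), "cell_id")
  expect_identical(ids, "keep10")
  expect_identical(res$report$counts[["dropped"]], 2L)

  # boundary is strict: points exactly at 8000 do not count
  at_thresh <- make_trace(rep(8000, 20), "at")
  expect_length(preselect(trace_set(list(at_thresh, above10)))$kept, 1)

  expect_error(preselect(trace_set(list(above10)), threshold = -1),
               "configuration")
  expect_error(preselect(trace_set()), "no traces")
})

test_that("preselection is monotone in above-threshold points", {
  set.seed(20)
  base <- rep(5000, 30)
  for (rep in 1:20) {
    n_above <- sample(0:15, 1)
    vals <- base
    vals[sample(30, n_above)] <- 9000
    tr <- make_trace(vals)
    kept1 <- length(preselect(trace_set(list(tr)))$kept) == 1
    # add two more above-threshold points: kept can only switch drop -> keep
    vals2 <- vals
    vals2[sample(which(vals == 5000), 2)] <- 9500
    kept2 <- length(preselect(trace_set(list(make_trace(vals2))))$kept) == 1
    expect_true(kept2 >= kept1)
  }
})

test_that("division synchronization splits, re-indexes and drops short segments", {
  tr <- make_trace(seq(1000, by = 100, length.out = 97))
  expect_identical(synchronize_to_division(tr)$segments[[1]]$value, tr$value)

  trd <- make_trace(seq(1000, by = 100, length.out = 97),
                    divisions = 1440)
  sy <- synchronize_to_division(trd)
  expect_length(sy$segments, 2)
  expect_length(sy$segments[[1]]$time, 48)  # samples 0..1410
  expect_length(sy$segments[[2]]$time, 49)  # boundary sample starts gen 2
  expect_identical(sy$segments[[2]]$time[1], 0)

  # marker between grid points: split index = first sample >= marker,
  # cross-checked by a brute-force scan of the grid
  tr15 <- make_trace(seq(1000, by = 100, length.out = 40), divisions = 15)
  sy15 <- synchronize_to_division(tr15, min_points = 1)
  brute <- min(which(tr15$time >= 15))
  expect_length(sy15$segments[[1]]$time, brute - 1)

  short <- make_trace(seq(1000, by = 100, length.out = 20), divisions = 450)
  sy2 <- synchronize_to_division(short, min_points = 10)
  expect_length(sy2$segments, 1)
  expect_identical(sy2$dropped$rule, "synchronize")

  expect_error(synchronize_to_division(
    make_trace(1:5 * 100, divisions = 900)), "data error")
})

test_that("peak truncation cuts at the first global maximum and is idempotent", {
  mono <- make_trace(c(1, 2, 3, 4, 5))
  expect_identical(truncate_at_peak(mono)$value, mono$value)

  expect_identical(truncate_at_peak(make_trace(c(1, 5, 9, 7, 8)))$value,
                   c(1, 5, 9))

  # tie for the maximum: first occurrence wins, checked exhaustively
  vals <- c(1, 2, 9, 4, 5, 3, 9, 6)
  tr <- truncate_at_peak(make_trace(vals))
  first_max <- min(which(vals == max(vals)))
  expect_length(tr$value, first_max)

  set.seed(21)
  for (rep in 1:25) {
    v <- round(runif(30, 0, 10))
    v[1] <- 1  # keep at least one point
    once <- truncate_at_peak(make_trace(v))
    twice <- truncate_at_peak(once)
    expect_identical(once$value, twice$value)
    expect_identical(length(once$value), min(which(v == max(v))))
  }
})

test_that("subsampling selects 30-35 per construct, reproducibly", {
  traces <- trace_set(lapply(1:100, function(i)
    make_trace(rep(9000, 12), cell_id = paste0("c", i))))
  s1 <- subsample_traces(traces, seed = 7)
  s2 <- subsample_traces(traces, seed = 7)
  expect_gte(length(s1$kept), 30)
  expect_lte(length(s1$kept), 35)
  expect_identical(vapply(s1$kept, `[[`, character(1), "cell_id"),
                   vapply(s2$kept, `[[`, character(1), "cell_id"))

  few <- trace_set(lapply(1:20, function(i)
    make_trace(rep(9000, 12), cell_id = paste0("f", i))))
  sf <- subsample_traces(few, seed = 7)
  expect_length(sf$kept, 20)
  expect_match(sf$report$warnings, "all kept")
})

test_that("the composed pipeline never emits traces shorter than min_points", {
  set.seed(22)
  des <- default_study_design(n_constructs = 3, seed = 23)
  des$cells <- rep(15L, 3)
  study <- simulate_study(des)
  pp <- preprocess_traces(study$traces, seed = 8)
  expect_true(all(vapply(pp$traces, function(tr) length(tr$time),
                         integer(1)) >= 10))
  expect_identical(pp$report$counts[["input"]], 45L)
  expect_identical(
    pp$report$counts[["kept"]] + pp$report$counts[["dropped"]], 45L)
})
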