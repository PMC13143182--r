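test_that("mape matches hand-computed values and guards its domain", {
  expect_equal(mape(c(1, 2, 4), c(1, 1, 2)), 1 / 3)
  expect_equal(mape(c(2, 2), c(3, 1)), 0.5)
  x <- runif(20, 0.5, 2)
  expect_equal(mape(x, x), 0)
  expect_error(mape(1:3, 1:4), "length mismatch")
  expect_error(mape(rep(1e-9, 5), rep(1, 5)), "no admissible")
  # trimming drops the largest percentage errors
  x2 <- rep(1, 100); y2 <- rep(1, 100); y2[1] <- 50
  expect_equal(mape(x2, y2, trim = 0.02), 0)
})

test_that("DCT transforms agree with the naive definition and invert exactly", {
  naive_dct <- function(x) {
    n <- length(x)
    vapply(0:(n - 1), function(k) sum(x * cos(pi * ((0:(n - 1)) + 0.5) * k / n)),
           numeric(1))
  }
  for (n in c(2, 5, 8, 33)) {
    x <- withr::with_seed(n, rnorm(n))
    expect_equal(hhmix:::dct2(x), naive_dct(x), tolerance = 1e-10)
    expect_equal(hhmix:::idct2(hhmix:::dct2(x)), x, tolerance = 1e-10)
  }
})

test_that("denoise preserves constants, damps noise and keeps slow structure", {
  expect_equal(denoise(rep(3, 200)), rep(3, 200), tolerance = 1e-10)
  withr::with_seed(1, {
    noise <- rnorm(4000)
    expect_lt(var(denoise(noise)), var(noise))
    t <- seq(0, 4 * pi, length.out = 4000)
    clean <- sin(t)
    noisy <- clean + rnorm(4000, 0, 0.5)
    expect_gt(cor(denoise(noisy, 10), clean), cor(noisy, clean))
  })
  expect_error(denoise(c(1, NA, 3)), "non-finite")
  expect_error(denoise(1:10, factor = -1), "positive")
})

test_that("baseline subtraction zeroes the first 40 ms and is idempotent", {
  times <- seq(0, 99.9, by = 0.1)
  expect_equal(subtract_baseline(times, rep(5, 1000)), rep(0, 1000))
  ramp <- times  # current = t
  shifted <- subtract_baseline(times, ramp)
  expect_equal(mean(ramp[times < 40]), 19.95)
  expect_equal(shifted, ramp - 19.95)
  # idempotence
  expect_equal(subtract_baseline(times, shifted), shifted)
  expect_error(subtract_baseline(times + 50, ramp), "40 ms")
})

test_that("rescale_sweep scales by the peak ratio", {
  expect_equal(rescale_sweep(c(0.1, 0.4), 0.8, 0.4), c(0.2, 0.8))
  expect_equal(rescale_sweep(c(0.1, 0.4), 0.4, 0.4), c(0.1, 0.4))
  expect_error(rescale_sweep(1:3, 1, 0), "positive")
})

test_that("clip_negative_artifacts deletes points without shifting times", {
  r <- clip_negative_artifacts(1:3, c(0.5, -0.02, 0.4))
  expect_equal(r$current, c(0.5, 0.4))
  expect_equal(r$times, c(1, 3))
  r2 <- clip_negative_artifacts(1:5, c(0, -0.005, 0.2, -0.01, 1))
  expect_length(r2$current, 5L)
  x <- withr::with_seed(2, runif(10, -0.5, 0.5))
  r3 <- clip_negative_artifacts(1:10, x)
  expect_length(r3$current, sum(x >= -0.01))
})

test_that("M4 keeps first/last/max/min per bin in time order", {
  r <- m4_downsample(1:6, c(1, 2, 3, 9, 0, 6), 1)
  expect_equal(r$values, c(1, 9, 0, 6))
  # size-4 bin is the identity
  r4 <- m4_downsample(1:4, c(4, 1, 7, 2), 1)
  expect_equal(r4$values, c(4, 1, 7, 2))
  withr::with_seed(3, {
    x <- rnorm(4000)
    r30 <- m4_downsample(seq_along(x), x, 30)
    expect_length(r30$values, 120L)
    # global extrema preserved
    expect_equal(max(r30$values), max(x))
    expect_equal(min(r30$values), min(x))
    expect_true(all(diff(r30$times) >= 0))
  })
  expect_error(m4_downsample(1:7, 1:7, 2), "too short")
})

test_that("downsample_sweep reproduces the per-protocol segment counts", {
  mk <- function(p, k) {
    proto <- build_protocol(p)[[k]]
    t <- seq(0, proto$duration - 0.1, by = 0.1)
    list(t = t, y = sin(t / 50))
  }
  a <- mk("activation", 3)
  da <- downsample_sweep(a$t, a$y, "activation", 3L)
  expect_length(da$current, 9 + 120 + 3)
  d <- mk("deactivation", 5)
  dd <- downsample_sweep(d$t, d$y, "deactivation", 5L)
  expect_length(dd$current, 9 + 72 + 48 + 3)
  i <- mk("inactivation", 2)
  di <- downsample_sweep(i$t, i$y, "inactivation", 2L)
  expect_length(di$current, 9 + 360 + 24 + 3)
  # gap contributes exactly 3 points regardless of duration
  for (k in c(1L, 9L, 16L)) {
    r <- mk("recovery", k)
    dr <- downsample_sweep(r$t, r$y, "recovery", k)
    expect_length(dr$current, 9 + 360 + 3 + 48 + 3)
  }
  expect_error(downsample_sweep(a$t, a$y, "ramp", 1L), "unknown protocol")
})

test_that("repetition selection keeps activation rep 2 and rep 1 elsewhere", {
  sw <- function(p, k, r) list(protocol = p, sweep_index = k, repetition = r,
                               times = 0, current = 0)
  res <- select_repetitions(list(sw("activation", 1L, 1L), sw("activation", 1L, 2L),
                                 sw("activation", 1L, 3L), sw("deactivation", 1L, 1L),
                                 sw("deactivation", 1L, 2L)))
  kept <- vapply(res$sweeps, function(s) paste(s$protocol, s$repetition), character(1))
  expect_setequal(kept, c("activation 2", "deactivation 1"))
  # missing required repetition excludes the family with a reason
  res2 <- select_repetitions(list(sw("activation", 1L, 1L)))
  expect_length(res2$sweeps, 0L)
  expect_match(res2$exclusions$reason, "missing repetition 2")
})

test_that("consistency rules keep matched traces and reject engineered mismatches", {
  cfg <- preprocess_config(consistency_on_smoothed = FALSE, mape_trim = 0)
  proto_a <- build_protocol("activation")
  t_act <- seq(0, 699.9, by = 0.1)
  funcs <- toy_gating_functions()
  p2 <- hh_params()
  act <- lapply(c(15L, 16L, 17L, 18L), function(k) {
    list(protocol = "activation", sweep_index = k, repetition = 2L, times = t_act,
         current = simulate_sweep(proto_a[[k]], funcs, p2, 25, t_act)$current)
  })
  proto_d <- build_protocol("deactivation")[[1]]
  t_d <- seq(0, proto_d$duration - 0.1, by = 0.1)
  de_clean <- list(protocol = "deactivation", sweep_index = 1L, repetition = 1L,
                   times = t_d,
                   current = simulate_sweep(proto_d, funcs, p2, 25, t_d)$current)
  r1 <- consistency_check(de_clean, act, "deactivation", cfg)
  expect_true(r1$keep)
  expect_lt(r1$mape, 0.01)
  # pure amplitude scaling is absorbed by peak matching
  de_scaled <- de_clean; de_scaled$current <- 1.7 * de_clean$current
  expect_true(consistency_check(de_scaled, act, "deactivation", cfg)$keep)
  # an engineered shape mismatch is rejected
  slow <- gating_functions(
    m_inf = lapply(1:2, function(i) function(V, Temp) funcs$m_inf[[i]](V - 15, Temp)),
    tau = lapply(1:2, function(i) function(V, Temp) 4 * funcs$tau[[i]](V, Temp)))
  de_bad <- de_clean
  de_bad$current <- simulate_sweep(proto_d, slow, p2, 25, t_d)$current
  r2 <- consistency_check(de_bad, act, "deactivation", cfg)
  expect_false(r2$keep)
  expect_gt(r2$mape, 0.05)
  # missing matching activation sweep excludes with a reason
  r3 <- consistency_check(de_clean, act[4], "deactivation", cfg)
  expect_false(r3$keep)
  expect_match(r3$reason, "missing")
  # recovery endpoint: a value at the median passes the endpoint criterion
  proto_r <- build_protocol("recovery")[[1]]
  t_r <- seq(0, proto_r$duration - 0.1, by = 0.1)
  re_clean <- list(protocol = "recovery", sweep_index = 1L, repetition = 1L,
                   times = t_r,
                   current = simulate_sweep(proto_r, funcs, p2, 25, t_r)$current)
  ctx <- list(endpoints = stats::setNames(rep(0.5, 3), as.character(1:3)),
              noise_sd = 0.001)
  ctx$endpoints["1"] <- 0.5
  r4 <- consistency_check(re_clean, act, "recovery", cfg, recovery_context = ctx)
  expect_true(r4$keep)
  # far-off endpoint fails it
  ctx2 <- ctx; ctx2$endpoints["1"] <- 5
  r5 <- consistency_check(re_clean, act, "recovery", cfg, recovery_context = ctx2)
  expect_false(r5$keep)
  expect_match(r5$reason, "endpoint")
})

test_that("the pipeline separates injected artifacts from clean sweeps", {
  ds <- qc_population()
  res <- run_pipeline(ds)
  qc <- res$qc
  # every input sweep appears exactly once in the report
  n_in <- sum(vapply(ds$cells, function(c) length(c$sweeps), integer(1)))
  expect_equal(nrow(qc), n_in)
  key <- function(df) paste(df$cell_id, df$protocol, df$sweep_index)
  inc <- ds$truth$artifacts[ds$truth$artifacts$type == "inconsistent", ]
  exc <- qc[qc$decision == "excluded" & grepl("MAPE|endpoint", qc$reason), ]
  # all injected inconsistencies rejected, nothing else
  expect_true(all(key(inc) %in% key(exc)))
  expect_true(all(key(exc) %in% key(inc)))
  # dead cells are dropped whole
  expect_false(any(grepl("DEAD", names(res$dataset$cells))))
  dead_rows <- qc[grepl("DEAD", qc$cell_id), ]
  expect_true(all(dead_rows$decision == "excluded"))
  # negative artifacts are clipped: no processed point below the threshold
  vals <- unlist(lapply(res$dataset$cells, function(c)
    lapply(c$sweeps, `[[`, "current")))
  expect_gte(min(vals), -0.01)
  # normalization: +80 mV activation peak of the downsampled data reaches ~1
  for (cell in res$dataset$cells[1:3]) {
    a80 <- Filter(function(s) s$protocol == "activation" && s$sweep_index == 18L,
                  cell$sweeps)[[1]]
    expect_equal(max(a80$current), 1, tolerance = 0.05)
  }
})

test_that("pipeline decisions are independent of cell order", {
  ds <- tiny_population()
  res1 <- run_pipeline(ds)
  ds2 <- ds
  ds2$cells <- rev(ds2$cells)
  res2 <- run_pipeline(ds2)
  q1 <- res1$qc[order(res1$qc$cell_id, res1$qc$protocol, res1$qc$sweep_index), ]
  q2 <- res2$qc[order(res2$qc$cell_id, res2$qc$protocol, res2$qc$sweep_index), ]
  rownames(q1) <- rownames(q2) <- NULL
  expect_equal(q1, q2)
})
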