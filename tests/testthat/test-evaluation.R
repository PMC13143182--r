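test_that("stratified split is deterministic, disjoint and proportioned", {
  meta <- expand.grid(type = c("A", "B"), temp = c(15, 25, 35), i = 1:10)
  cells <- lapply(seq_len(nrow(meta)), function(r) {
    list(cell_id = sprintf("c%03d", r), channel_type = as.character(meta$type[r]),
         temperature = meta$temp[r], sweeps = list())
  })
  ds <- sweep_dataset(cells)
  sp1 <- split_dataset(ds, seed = 9)
  sp2 <- split_dataset(ds, seed = 9)
  expect_identical(lapply(sp1, function(d) names(d$cells)),
                   lapply(sp2, function(d) names(d$cells)))
  ids <- unlist(lapply(sp1, function(d) names(d$cells)))
  expect_length(ids, 60L)
  expect_false(any(duplicated(ids)))
  # each 10-cell stratum splits 6/2/2
  m1 <- sp1$train$metadata
  expect_equal(unname(table(m1$channel_type, m1$temperature_C)),
               matrix(6L, 2, 3), ignore_attr = TRUE)
  expect_equal(length(sp1$val$cells), 12L)
  expect_equal(length(sp1$test$cells), 12L)
  # a single small stratum warns
  one_stratum <- Filter(function(c) c$channel_type == "A" && c$temperature == 15,
                        cells)[1:3]
  expect_warning(split_dataset(sweep_dataset(one_stratum), seed = 1),
                 "fewer than 5")
})

test_that("unified training roster is balanced with full type hold-out", {
  # paper-scale roster: 20 types x 3 temperatures x >= 7 cells, 3 types held out
  meta <- expand.grid(type = sprintf("Kv%02d", 1:20), temp = c(15, 25, 35), i = 1:9)
  meta <- data.frame(cell_id = sprintf("c%04d", seq_len(nrow(meta))),
                     channel_type = as.character(meta$type),
                     temperature_C = meta$temp)
  held <- c("Kv07", "Kv14", "Kv20")
  ids <- build_unified_training_set(meta, cells_per_stratum = 7L,
                                    exclude_types = held, seed = 3)
  expect_length(ids, 357L)
  sel <- meta[meta$cell_id %in% ids, ]
  expect_false(any(sel$channel_type %in% held))
  expect_true(all(table(sel$channel_type, sel$temperature_C) == 7L))
  # synthetic-scale variant: 4 archetypes, 1 excluded, 2 cells x 3 temps
  meta2 <- expand.grid(type = sprintf("A%d", 1:4), temp = c(15, 25, 35), i = 1:3)
  meta2 <- data.frame(cell_id = sprintf("d%03d", seq_len(nrow(meta2))),
                      channel_type = as.character(meta2$type),
                      temperature_C = meta2$temp)
  ids2 <- build_unified_training_set(meta2, cells_per_stratum = 2L,
                                     exclude_types = "A4", seed = 1)
  expect_length(ids2, 18L)
  # insufficient stratum errors with its name
  expect_error(build_unified_training_set(meta2, cells_per_stratum = 5L),
               "only 3 cells")
})

test_that("rmse_per_sweep matches its definition", {
  expect_equal(rmse_per_sweep(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse_per_sweep(c(0.1, -0.1), c(0, 0)), 0.1)
  withr::with_seed(21, {
    o <- rnorm(50); p <- rnorm(50)
    expect_equal(rmse_per_sweep(o, p), sqrt(mean((o - p)^2)))
  })
  expect_error(rmse_per_sweep(numeric(0), numeric(0)), "empty")
  expect_error(rmse_per_sweep(1:3, 1:2), "mismatch")
})

test_that("compare_models reproduces the rank-sum statistic and effect size", {
  r <- compare_models(c(1, 2, 3), c(4, 5, 6))
  # enumeration oracle: W is the Mann-Whitney count of pairs where A > B
  count_W <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(r$W, count_W(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$median_diff, -3)
  withr::with_seed(22, {
    for (i in 1:5) {
      a <- runif(6); b <- runif(6)
      expect_equal(compare_models(a, b)$W, count_W(a, b))
    }
  })
  # identical samples: zero difference and zero effect size
  x <- c(0.1, 0.2, 0.3, 0.4)
  r0 <- compare_models(x, x)
  expect_equal(r0$median_diff, 0)
  expect_equal(r0$cohens_d, 0)
  expect_false(r0$significant)
  # translation shifts the median difference
  r1 <- compare_models(x, x + 0.5)
  expect_equal(r1$median_diff, -0.5)
  # Bonferroni correction only scales the p value
  rc <- compare_models(c(1, 2, 3), c(4, 5, 6), n_comparisons = 10L)
  expect_equal(rc$p_adjusted, min(1, rc$p_value * 10))
  expect_error(compare_models(1:3, 1:4), "equal length")
})

test_that("weighted residuals are standard normal under the generating model", {
  fd <- tiny_fit_data()
  model <- deep_gating_model(n_onehot = 1, seed = 5)
  model$sigma <- 0.05
  # simulate observations from the model itself at eta = 0
  fd_sim <- fd
  withr::with_seed(23, {
    k <- 0
    fd_sim$cells <- lapply(fd$cells, function(cell) {
      pred <- predict_cell(model, cell, rep(0, 9))
      off <- 0
      cell$sweeps <- lapply(cell$sweeps, function(s) {
        n <- length(s$obs_y)
        s$obs_y <- pred[off + seq_len(n)] + rnorm(n, 0, model$sigma)
        off <<- off + n
        s
      })
      cell
    })
  })
  wr <- weighted_residuals(model, fd_sim, mode = "population",
                           eta_mat = NULL)
  expect_gt(nrow(wr), 1e4)
  expect_lt(abs(mean(wr$wres)), 0.05)
  expect_gt(sd(wr$wres), 0.9)
  expect_lt(sd(wr$wres), 1.1)
  # perfect predictions give zero residuals; halving sigma doubles them
  fd_perfect <- fd_sim
  fd_perfect$cells <- lapply(fd_sim$cells, function(cell) {
    pred <- predict_cell(model, cell, rep(0, 9))
    off <- 0
    cell$sweeps <- lapply(cell$sweeps, function(s) {
      n <- length(s$obs_y)
      s$obs_y <- pred[off + seq_len(n)]
      off <<- off + n
      s
    })
    cell
  })
  wr0 <- weighted_residuals(model, fd_perfect, mode = "population")
  expect_equal(max(abs(wr0$wres)), 0)
  model2 <- model; model2$sigma <- model$sigma / 2
  wr2 <- weighted_residuals(model2, fd_sim, mode = "population")
  expect_equal(wr2$wres, 2 * wr$wres)
})

test_that("EBE pair diagnostics summarize correlations and errors", {
  withr::with_seed(24, {
    eb <- matrix(rnorm(300 * 4), 300, 4)
    eb <- cbind(eb, eb[, 1])   # duplicated component
    d <- ebe_diagnostics(eb, rmse_by_cell = runif(300))
    expect_equal(dim(d$correlation), c(5L, 5L))
    expect_equal(diag(d$correlation), rep(1, 5))
    expect_equal(d$correlation, t(d$correlation))
    expect_equal(d$correlation[1, 5], 1)
    # independent components decorrelate
    off <- d$correlation[1:4, 1:4][upper.tri(diag(4))]
    expect_lt(max(abs(off)), 0.2)
    expect_equal(nrow(d$pairs), choose(5, 2) * 300)
  })
  expect_error(ebe_diagnostics(matrix(1, 1, 3)), "at least 2")
})

test_that("Q10 curves follow their closed forms", {
  flat <- gating_functions(
    m_inf = list(function(V, Temp) 0.5),
    tau = list(function(V, Temp) 7))
  expect_equal(q10_curve(flat, seq(-90, 80, 10), 15, gate = 1),
               rep(1, 18))
  q3 <- gating_functions(
    m_inf = list(function(V, Temp) 0.5),
    tau = list(function(V, Temp) 10 * 3^(-(Temp - 25) / 10)))
  expect_equal(q10_curve(q3, c(-50, 0, 50), 15, gate = 1), rep(3, 3))
  expect_equal(q10_curve(q3, c(-50, 0, 50), 25, gate = 1), rep(3, 3))
})

test_that("VPC bands are ordered, degenerate without noise, and self-consistent", {
  fd <- tiny_fit_data()
  model <- deep_gating_model(n_onehot = 1, seed = 6)
  model$sigma <- 0.04
  Omega <- diag(0.2, 9)
  # observations simulated from the hierarchical model itself
  ch <- chol(Omega)
  fd_sim <- fd
  withr::with_seed(25, {
    fd_sim$cells <- lapply(fd$cells, function(cell) {
      eta <- as.numeric(t(ch) %*% rnorm(9))
      pred <- predict_cell(model, cell, eta)
      off <- 0
      cell$sweeps <- lapply(cell$sweeps, function(s) {
        n <- length(s$obs_y)
        s$obs_y <- pred[off + seq_len(n)] + rnorm(n, 0, model$sigma)
        off <<- off + n
        s
      })
      cell
    })
  })
  v <- vpc(model, fd_sim, Omega = Omega, n_populations = 60L, seed = 26,
           protocols = "activation", grid_points = 31L)
  expect_s3_class(v, "vpc_result")
  for (s in v$sweeps) {
    expect_true(all(s$band_lo <= s$band_hi + 1e-12))
    expect_true(all(s$band_lo[1, ] <= s$band_hi[3, ] + 1e-12))
  }
  expect_gt(vpc_coverage(v), 0.85)
  # sigma = 0 and Omega = 0 collapse the bands onto the deterministic curve
  model0 <- model; model0$sigma <- 1e-12
  v0 <- vpc(model0, fd_sim, Omega = diag(1e-20, 9), n_populations = 10L,
            seed = 27, protocols = "activation", grid_points = 11L)
  s1 <- v0$sweeps[[1]]
  expect_lt(max(s1$band_hi - s1$band_lo), 1e-6)
})
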