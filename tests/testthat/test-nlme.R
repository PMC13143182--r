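test_that("observation log-likelihood matches Gaussian closed forms", {
  expect_equal(observation_loglik(0.3, 0.3, 1 / sqrt(2 * pi)), 0)
  r <- 0.7; s <- 0.2
  expect_equal(observation_loglik(r, 0, s), -log(s * sqrt(2 * pi)) - r^2 / (2 * s^2))
  withr::with_seed(10, {
    y <- rnorm(30); p <- rnorm(30)
    expect_equal(observation_loglik(y, p, 0.5),
                 sum(vapply(1:30, function(i) observation_loglik(y[i], p[i], 0.5),
                            numeric(1))))
  })
  expect_error(observation_loglik(1, 1, 0), "positive")
})

test_that("eta prior is the multivariate normal log-density", {
  expect_equal(eta_logprior(c(0, 0), diag(2)), -log(2 * pi))
  withr::with_seed(11, {
    d <- 4
    vars <- runif(d, 0.5, 3)
    eta <- rnorm(d)
    expect_equal(eta_logprior(eta, diag(vars)),
                 sum(stats::dnorm(eta, 0, sqrt(vars), log = TRUE)))
    # monotone decrease along a ray for identity covariance
    vals <- vapply(c(0.5, 1, 2, 4), function(s) eta_logprior(rep(s, 2), diag(2)),
                   numeric(1))
    expect_true(all(diff(vals) < 0))
  })
  expect_error(eta_logprior(c(1, 1), matrix(c(1, 2, 2, 1), 2)), "positive definite")
})

test_that("theta prior is minus lambda times the L1 norm", {
  expect_equal(theta_logprior(numeric(0), 1), 0)
  expect_equal(theta_logprior(c(0, 0), 0.3), 0)
  expect_equal(theta_logprior(c(1, -2), 1e-4), -3e-4)
  a <- c(1, -1); b <- c(2, 0.5)
  expect_equal(theta_logprior(c(a, b), 0.1),
               theta_logprior(a, 0.1) + theta_logprior(b, 0.1))
  expect_error(theta_logprior(1, -1), "non-negative")
})

test_that("conditional MAP objective decomposes additively over cells", {
  fd <- tiny_fit_data()
  model <- deep_gating_model(n_onehot = 1, seed = 3)
  nC <- length(fd$cells)
  eta <- withr::with_seed(12, matrix(rnorm(nC * 9, 0, 0.2), nC, 9))
  total <- conditional_map_objective(model, fd, eta)
  # brute-force: fixed-effect prior plus per-cell sums of the two terms
  sigma <- model$sigma
  per_cell <- vapply(seq_len(nC), function(i) {
    cell <- fd$cells[[i]]
    pred <- predict_cell(model, cell, eta[i, ])
    observation_loglik(cell_y(model, cell), pred, sigma) +
      eta_logprior(eta[i, ], diag(9))
  }, numeric(1))
  brute <- sum(per_cell) + theta_logprior(hhmix:::theta_values(model), model$lambda)
  expect_equal(total, brute, tolerance = 1e-8)
  # removing one cell removes exactly its contribution
  fd1 <- fd; fd1$cells <- fd$cells[-1]
  total1 <- conditional_map_objective(model, fd1, eta[-1, , drop = FALSE])
  expect_equal(total - total1, per_cell[1], tolerance = 1e-8)
})

test_that("empirical Bayes estimates match the linear-Gaussian posterior mode", {
  sigma <- 0.7; omega2 <- 2.5; M <- 12
  model <- linear_re_model(sigma)
  cells <- make_linear_cells(10, M, omega2, sigma, seed = 13)
  for (cell in cells[1:5]) {
    eb <- estimate_ebe(model, cell, Omega = matrix(omega2))
    closed <- omega2 * M * mean(cell$y) / (omega2 * M + sigma^2)
    expect_equal(eb$eta, closed, tolerance = 1e-5)
    expect_true(eb$converged)
  }
  # shrinkage: higher noise pulls the estimate toward the prior mode
  cell <- cells[[1]]
  est <- vapply(c(0.2, 0.5, 1, 3, 10), function(s)
    abs(estimate_ebe(linear_re_model(s), cell, Omega = matrix(omega2))$eta),
    numeric(1))
  expect_true(all(diff(est) < 0))
  # no information (huge sigma) returns the prior mode
  eb0 <- estimate_ebe(linear_re_model(1e6), cell, Omega = matrix(omega2))
  expect_equal(eb0$eta, 0, tolerance = 1e-3)
})

test_that("EBEs recover generating effects when noise is small", {
  sigma <- 0.01; omega2 <- 4
  model <- linear_re_model(sigma)
  cells <- make_linear_cells(20, 10, omega2, sigma, seed = 14)
  for (cell in cells) {
    eb <- estimate_ebe(model, cell, Omega = matrix(omega2))
    expect_equal(eb$eta, cell$eta_true, tolerance = 0.05)
  }
})

test_that("FOCE equals the exact marginal likelihood for the linear toy", {
  sigma <- 0.8; omega2 <- 1.7
  model <- linear_re_model(sigma)
  for (M in c(1L, 5L)) {
    cells <- make_linear_cells(6, M, omega2, sigma, seed = 15 + M)
    r <- foce_marginal_loglik(model, cells, Omega = matrix(omega2))
    # closed form: y ~ N(0, sigma^2 I + omega2 J)
    exact <- sum(vapply(cells, function(cell) {
      S <- diag(sigma^2, M) + omega2
      -0.5 * (M * log(2 * pi) + determinant(S)$modulus[1] +
                sum(cell$y * solve(S, cell$y)))
    }, numeric(1)))
    expect_equal(r$value, exact, tolerance = 1e-6)
    # additivity across independent cells
    r1 <- foce_marginal_loglik(model, cells[1], Omega = matrix(omega2))
    r2 <- foce_marginal_loglik(model, cells[-1], Omega = matrix(omega2))
    expect_equal(r$value, r1$value + r2$value, tolerance = 1e-6)
  }
})

test_that("FOCE approaches the conditional likelihood at eta = 0 as Omega shrinks", {
  sigma <- 0.5
  model <- linear_re_model(sigma)
  cells <- make_linear_cells(4, 6, 1, sigma, seed = 17)
  cond0 <- sum(vapply(cells, function(cell)
    observation_loglik(cell$y, rep(0, 6), sigma), numeric(1)))
  vals <- vapply(c(1e-2, 1e-4, 1e-6), function(w) {
    foce_marginal_loglik(model, cells, Omega = matrix(w))$value
  }, numeric(1))
  expect_true(all(diff(abs(vals - cond0)) < 0))
  expect_equal(vals[3], cond0, tolerance = 1e-3)
})

test_that("stage-2 recovers the generating random-effect variance", {
  sigma <- 0.5; omega2_true <- 4
  model <- linear_re_model(sigma)
  cells <- make_linear_cells(200, 8, omega2_true, sigma, seed = 18)
  fit <- fit_stage2(model, list(cells = cells), iterations = 10L)
  expect_equal(fit$Omega[1, 1], omega2_true, tolerance = 0.25 * omega2_true)
  # effects generated at zero shrink Omega below its identity start
  cells0 <- make_linear_cells(100, 8, 0, sigma, seed = 19)
  fit0 <- fit_stage2(model, list(cells = cells0), iterations = 10L)
  expect_lt(fit0$Omega[1, 1], 0.5)
})

test_that("stage-1 fitting improves the objective and selects a saved checkpoint", {
  fd <- tiny_fit_data()
  model <- deep_gating_model(n_onehot = 1, seed = 2)
  fs <- fit_stage1(model, fd, fd, epochs = 30L, checkpoint_every = 15L)
  expect_s3_class(fs, "fit_state")
  expect_equal(nrow(fs$trace), length(fs$checkpoints))
  expect_lte(length(fs$checkpoints), ceiling(30 / 15))
  # objective decreases across checkpoints (negative log posterior)
  expect_true(all(diff(fs$trace$objective) <= 1e-8))
  # the selected checkpoint is one of the saved ones
  expect_true(fs$selected %in% seq_along(fs$checkpoints))
  expect_equal(fs$selected_epoch, fs$checkpoints[[fs$selected]]$epoch)
  # the fit beats the initial model on training RMSE
  expect_lt(validation_rmse(fs$model, fd, fs$eta),
            validation_rmse(model, fd, matrix(0, length(fd$cells), 9)))
})

test_that("random-effects-only fitting recovers sigma and dominates eta = 0", {
  fd <- tiny_fit_data()
  ds <- tiny_population()
  # restrict to the cells generated from archetype 1: the frozen structural
  # model is that archetype, so its effects span the generating heterogeneity
  fd$cells <- Filter(function(c) c$channel_type == "A1", fd$cells)
  arch <- ds$truth$archetypes[[1]]
  make_funcs <- function(eta) {
    spec <- arch
    spec$g1$V_half <- spec$g1$V_half + 5 * eta[1]
    spec$g2$V_half <- spec$g2$V_half + 5 * eta[2]
    spec$g1$tau_amp <- spec$g1$tau_amp * exp(0.3 * eta[3])
    spec$g2$tau_amp <- spec$g2$tau_amp * exp(0.3 * eta[4])
    hhmix:::archetype_gating_functions(spec)
  }
  model <- classical_hh_model(make_funcs, n_eta = 4L, sigma = 0.1)
  fit <- fit_random_effects_only(model, fd, iterations = 2L)
  # noise recovery: generator observation noise is 0.02 in amplitude units;
  # normalized per cell the residual SD lands near 0.02 for matching cells
  expect_lt(fit$sigma, 0.06)
  expect_gt(fit$sigma, 0.005)
  # fitting the effects can only reduce the residual against eta = 0
  rmse_eta <- function(eta_mat) {
    mean(vapply(seq_along(fd$cells), function(i) {
      r <- cell_y(model, fd$cells[[i]]) - predict_cell(model, fd$cells[[i]], eta_mat[i, ])
      sqrt(mean(r^2))
    }, numeric(1)))
  }
  expect_lte(rmse_eta(fit$eta), rmse_eta(matrix(0, length(fd$cells), 4)) + 1e-10)
})
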