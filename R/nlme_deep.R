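#' Fitting machinery for the deep gating model
#'
#' The conditional MAP objective is evaluated with all neural-network
#' forwards batched across cells and segments, the sweep trajectories and
#' their sensitivity coefficients computed in compiled code, and the
#' coefficient sums pulled back through the networks by reverse-mode
#' differentiation, giving analytic gradients in all fixed effects and all
#' random effects.
#'
#' @name nlme_deep
NULL

#' Prepare a processed dataset for fitting
#'
#' Converts a processed \code{sweep_dataset} into the flat per-cell
#' structure the estimation code consumes: protocol segment tables, the
#' observation grid of every sweep with its segment assignment, the cell's
#' unique segment voltages (neural-network inputs are batched over these)
#' and the channel-type index.
#'
#' @param dataset a processed \code{sweep_dataset}
#' @param channel_levels optional character vector fixing the channel-type
#'   to index mapping (first level is the reference, all-zero indicator)
#' @param recovery_test_ms recovery test-pulse duration used when the data
#'   were generated
#' @return an \code{hh_fit_data} list of cells
#' @export
prepare_fit_data <- function(dataset, channel_levels = NULL,
                             recovery_test_ms = 200) {
  stopifnot(inherits(dataset, "sweep_dataset"))
  if (is.null(channel_levels)) {
    channel_levels <- sort(unique(dataset$metadata$channel_type))
  }
  cells <- lapply(dataset$cells, function(cell) {
    u_volt <- numeric(0)
    sweeps <- lapply(cell$sweeps, function(s) {
      proto <- build_protocol(s$protocol,
                              overrides = list(recovery_test_ms = recovery_test_ms))[[s$sweep_index]]
      seg <- proto$segments
      obs_seg <- findInterval(s$times, seg$t_start)
      obs_seg[obs_seg < 1L] <- 1L
      obs_seg[obs_seg > nrow(seg)] <- nrow(seg)
      ord <- order(s$times)
      list(protocol = s$protocol, sweep_index = s$sweep_index,
           seg_start = seg$t_start, seg_dur = seg$t_end - seg$t_start,
           volt = seg$voltage, obs_t = s$times[ord], obs_y = s$current[ord],
           obs_seg = obs_seg[ord])
    })
    u_volt <- sort(unique(unlist(lapply(sweeps, `[[`, "volt"))))
    sweeps <- lapply(sweeps, function(s) {
      s$u_idx <- match(s$volt, u_volt)
      s
    })
    list(cell_id = cell$cell_id,
         channel_type = cell$channel_type,
         channel_index = match(cell$channel_type, channel_levels),
         Temp = cell$temperature,
         T_bar = normalize_temperature(cell$temperature),
         u_volt = u_volt,
         sweeps = sweeps,
         n_obs = sum(vapply(sweeps, function(s) length(s$obs_y), integer(1))))
  })
  structure(list(cells = cells, channel_levels = channel_levels,
                 n_obs = sum(vapply(cells, `[[`, integer(1), "n_obs"))),
            class = "hh_fit_data")
}

#' @export
print.hh_fit_data <- function(x, ...) {
  cat(sprintf("<hh_fit_data> %d cells, %d observations, %d channel types\n",
              length(x$cells), x$n_obs, length(x$channel_levels)))
  invisible(x)
}

dg_cell_onehot <- function(model, cell) {
  cell_covariates(cell$channel_index, model$config$n_onehot, cell$Temp)$onehot
}

# per-cell network outputs on the cell's unique voltages
dg_cell_nets <- function(model, cell, eta, cache = FALSE) {
  cfg <- model$config
  eta_star <- eta[1:8]; eta_temp <- eta[9]
  onehot <- dg_cell_onehot(model, cell)
  aug_out <- mlp_forward(model$nets$aug, c(onehot, cell$T_bar + eta_temp))
  et <- eta_star + as.numeric(aug_out)
  T_eff <- cell$T_bar + if (cfg$eta_temp_in_gating) eta_temp else 0
  nu <- length(cell$u_volt)
  Xg <- function(pair) cbind(cell$u_volt / cfg$v_scale, rep(T_eff, nu),
                             matrix(et[pair], nu, 2, byrow = TRUE))
  list(
    minf = cbind(as.numeric(mlp_forward(model$nets$minf1, Xg(1:2))),
                 as.numeric(mlp_forward(model$nets$minf2, Xg(5:6)))),
    tau = cfg$tau_scale * cbind(as.numeric(mlp_forward(model$nets$tau1, Xg(3:4))),
                                as.numeric(mlp_forward(model$nets$tau2, Xg(7:8))))
  )
}

dg_sweep_kernel <- function(model, sweep, nets, y = NULL, want_grad = FALSE) {
  cfg <- model$config
  scale <- (sweep$volt - cfg$E) / (cfg$V_max - cfg$E)
  sweep_kernel_cpp(sweep$seg_start, sweep$seg_dur, scale,
                   nets$minf[sweep$u_idx, , drop = FALSE],
                   nets$tau[sweep$u_idx, , drop = FALSE],
                   cfg$powers, sweep$obs_t, sweep$obs_seg,
                   if (is.null(y)) numeric(length(sweep$obs_t)) else y,
                   want_grad)
}

#' @export
predict_cell.deep_gating_model <- function(model, cell, eta) {
  nets <- dg_cell_nets(model, cell, eta)
  unlist(lapply(cell$sweeps, function(s)
    dg_sweep_kernel(model, s, nets)$pred))
}

#' @export
cell_y.deep_gating_model <- function(model, cell) {
  unlist(lapply(cell$sweeps, `[[`, "obs_y"))
}

#' @export
n_eta.deep_gating_model <- function(model) 9L

#' @export
theta_values.deep_gating_model <- function(model) {
  unlist(lapply(model$nets, mlp_get_params))
}

# ---- batched conditional-MAP objective -------------------------------------

# Evaluate the negative conditional log-posterior and its gradients over a
# set of cells. eta_mat is cells x 9. Returns value plus (optionally)
# grad_theta (fixed effects incl. log sigma) and grad_eta (cells x 9).
dg_eval <- function(model, cells, eta_mat, Omega_inv = diag(9),
                    want_theta = TRUE, want_eta = TRUE) {
  cfg <- model$config
  nC <- length(cells)
  sigma <- model$sigma
  # --- batched forwards ---
  n_rows_c <- vapply(cells, function(c) length(c$u_volt), integer(1))
  offset <- cumsum(c(0L, n_rows_c[-nC]))
  row_cell <- rep(seq_len(nC), n_rows_c)
  v_rows <- unlist(lapply(cells, `[[`, "u_volt"))
  T_bar <- vapply(cells, `[[`, numeric(1), "T_bar")
  eta_temp <- eta_mat[, 9L]
  onehots <- do.call(rbind, lapply(cells, function(c) dg_cell_onehot(model, c)))
  X_aug <- cbind(onehots, T_bar + eta_temp)
  aug_out <- mlp_forward(model$nets$aug, X_aug, cache = TRUE)
  eta_full <- eta_mat[, 1:8, drop = FALSE] + aug_out
  T_eff <- T_bar + if (cfg$eta_temp_in_gating) eta_temp else 0
  gate_inputs <- function(pair) {
    cbind(v_rows / cfg$v_scale, T_eff[row_cell],
          eta_full[row_cell, pair, drop = FALSE])
  }
  X1 <- gate_inputs(1:2); X3 <- gate_inputs(3:4)
  X5 <- gate_inputs(5:6); X7 <- gate_inputs(7:8)
  o_minf1 <- mlp_forward(model$nets$minf1, X1, cache = TRUE)
  o_tau1  <- mlp_forward(model$nets$tau1,  X3, cache = TRUE)
  o_minf2 <- mlp_forward(model$nets$minf2, X5, cache = TRUE)
  o_tau2  <- mlp_forward(model$nets$tau2,  X7, cache = TRUE)
  minf_rows <- cbind(as.numeric(o_minf1), as.numeric(o_minf2))
  tau_rows <- cfg$tau_scale * cbind(as.numeric(o_tau1), as.numeric(o_tau2))
  # --- sweep loop ---
  n_rows <- length(v_rows)
  cot <- list(minf1 = numeric(n_rows), tau1 = numeric(n_rows),
              minf2 = numeric(n_rows), tau2 = numeric(n_rows))
  ssr <- 0; n_obs <- 0
  w <- 1 / sigma^2
  for (ci in seq_len(nC)) {
    cell <- cells[[ci]]
    for (s in cell$sweeps) {
      g_idx <- offset[ci] + s$u_idx
      scale <- (s$volt - cfg$E) / (cfg$V_max - cfg$E)
      res <- sweep_kernel_cpp(s$seg_start, s$seg_dur, scale,
                              minf_rows[g_idx, , drop = FALSE],
                              tau_rows[g_idx, , drop = FALSE],
                              cfg$powers, s$obs_t, s$obs_seg, s$obs_y,
                              want_theta || want_eta)
      ssr <- ssr + res$ssr
      n_obs <- n_obs + length(s$obs_y)
      if (want_theta || want_eta) {
        A <- res$A; B <- res$B
        for (k in seq_along(g_idx)) {
          i <- g_idx[k]
          cot$minf1[i] <- cot$minf1[i] + w * A[1L, k]
          cot$tau1[i]  <- cot$tau1[i]  + w * B[1L, k] * cfg$tau_scale
          cot$minf2[i] <- cot$minf2[i] + w * A[2L, k]
          cot$tau2[i]  <- cot$tau2[i]  + w * B[2L, k] * cfg$tau_scale
        }
      }
    }
  }
  # --- value ---
  eta9 <- eta_mat
  prior_quad <- sum(vapply(seq_len(nC), function(i)
    sum(eta9[i, ] * (Omega_inv %*% eta9[i, ])), numeric(1)))
  ld_omega <- -as.numeric(determinant(Omega_inv)$modulus)  # logdet(Omega)
  theta <- theta_values(model)
  value <- 0.5 * ssr / sigma^2 + n_obs * (log(sigma) + 0.5 * log(2 * pi)) +
    0.5 * prior_quad + 0.5 * nC * (9 * log(2 * pi) + ld_omega) +
    model$lambda * sum(abs(theta))
  out <- list(value = value, ssr = ssr, n_obs = n_obs)
  if (!(want_theta || want_eta)) return(out)
  # --- backward ---
  bk_minf1 <- mlp_backward(model$nets$minf1, o_minf1, cot$minf1)
  bk_tau1  <- mlp_backward(model$nets$tau1,  o_tau1,  cot$tau1)
  bk_minf2 <- mlp_backward(model$nets$minf2, o_minf2, cot$minf2)
  bk_tau2  <- mlp_backward(model$nets$tau2,  o_tau2,  cot$tau2)
  # eta gradients through the gating-net inputs (cols 3:4), per cell
  g_eta_full <- matrix(0, nC, 8L)
  acc <- function(bk, pair) {
    g <- rowsum(bk$gX[, 3:4, drop = FALSE], row_cell)
    g_eta_full[, pair] <<- g_eta_full[, pair] + g
  }
  acc(bk_minf1, 1:2); acc(bk_tau1, 3:4); acc(bk_minf2, 5:6); acc(bk_tau2, 7:8)
  # augmentation backward with the eta cotangents
  bk_aug <- mlp_backward(model$nets$aug, aug_out, g_eta_full)
  g_T_eff <- rowsum(bk_minf1$gX[, 2L] + bk_tau1$gX[, 2L] +
                    bk_minf2$gX[, 2L] + bk_tau2$gX[, 2L], row_cell)
  g_eta_temp <- bk_aug$gX[, cfg$n_onehot + 1L] +
    if (cfg$eta_temp_in_gating) as.numeric(g_T_eff) else 0
  if (want_eta) {
    g_eta <- cbind(g_eta_full, g_eta_temp) + t(Omega_inv %*% t(eta9))
    out$grad_eta <- g_eta
  }
  if (want_theta) {
    eps <- 1e-10
    g_theta <- c(mlp_grad_vector(bk_minf1), mlp_grad_vector(bk_tau1),
                 mlp_grad_vector(bk_minf2), mlp_grad_vector(bk_tau2),
                 mlp_grad_vector(bk_aug))
    g_theta <- g_theta + model$lambda * theta / sqrt(theta^2 + eps)
    g_log_sigma <- n_obs - ssr / sigma^2
    out$grad_theta <- c(g_theta, g_log_sigma)
  }
  out
}

#' @export
cell_nll_grad.deep_gating_model <- function(model, cell, eta) {
  r <- dg_eval(model, list(cell), matrix(eta, 1L), Omega_inv = diag(9) * 0,
               want_theta = FALSE, want_eta = TRUE)
  as.numeric(r$grad_eta)
}

#' Conditional MAP objective
#'
#' log p(Theta) + sum_n [log p(y_n | Theta, eta_n) + log p(eta_n | Omega)],
#' the quantity maximized in stage 1 (Omega is held at identity there).
#'
#' @param model a \code{deep_gating_model}
#' @param fit_data an \code{hh_fit_data}
#' @param eta_mat cells x 9 matrix of random effects
#' @param Omega random-effect prior covariance (default identity)
#' @return scalar to maximize
#' @export
conditional_map_objective <- function(model, fit_data, eta_mat,
                                      Omega = diag(9)) {
  Oinv <- chol2inv(chol(as.matrix(Omega)))
  -dg_eval(model, fit_data$cells, eta_mat, Omega_inv = Oinv,
           want_theta = FALSE, want_eta = FALSE)$value
}

# ---- stage 1 ----------------------------------------------------------------

dg_pack <- function(model, eta_mat) c(model_param_vector(model), as.numeric(eta_mat))

dg_unpack <- function(par, model, nC) {
  np <- length(model_param_vector(model))
  list(model = model_set_params(model, par[seq_len(np)]),
       eta_mat = matrix(par[-seq_len(np)], nC, 9L))
}

#' Mean per-sweep RMSE of a cell set under a model
#'
#' Used as the validation score during stage-1 checkpoint selection. When
#' \code{eta_mat} is NULL the random effects are estimated per cell
#' (empirical Bayes at the given Omega) before scoring.
#'
#' @param model a \code{deep_gating_model}
#' @param fit_data an \code{hh_fit_data}
#' @param eta_mat optional cells x 9 matrix
#' @param Omega prior covariance used when estimating the effects
#' @param ebe_maxit iteration cap for the per-cell estimates
#' @return mean over sweeps of the per-sweep RMSE
#' @export
validation_rmse <- function(model, fit_data, eta_mat = NULL, Omega = diag(9),
                            ebe_maxit = 40L) {
  vals <- unlist(lapply(seq_along(fit_data$cells), function(i) {
    cell <- fit_data$cells[[i]]
    eta <- if (is.null(eta_mat)) estimate_ebe(model, cell, Omega, maxit = ebe_maxit)$eta
           else eta_mat[i, ]
    nets <- dg_cell_nets(model, cell, eta)
    vapply(cell$sweeps, function(s) {
      p <- dg_sweep_kernel(model, s, nets)$pred
      sqrt(mean((s$obs_y - p)^2))
    }, numeric(1))
  }))
  mean(vals)
}

#' Stage-1 conditional MAP fit
#'
#' Jointly maximizes the conditional MAP objective over all network
#' weights, log sigma and all per-cell random effects, with Omega fixed at
#' identity. The optimizer is L-BFGS-B with analytic gradients; one epoch
#' is one optimizer iteration over the full data. Parameters are
#' checkpointed every \code{checkpoint_every} epochs, each checkpoint is
#' scored on the validation cells, and the best-scoring saved checkpoint is
#' returned.
#'
#' @param model a \code{deep_gating_model} (initial fixed effects)
#' @param train an \code{hh_fit_data} used for the objective
#' @param val an \code{hh_fit_data} scored at each checkpoint (may be the
#'   training set at desk scale)
#' @param epochs total optimizer iterations (default 300)
#' @param checkpoint_every checkpoint interval in epochs (default 15)
#' @param eta_init optional starting cells x 9 matrix
#' @param verbose print progress lines
#' @return a \code{fit_state}: best model, its training-cell random
#'   effects, the checkpoint list, objective/validation traces and the
#'   selected checkpoint index
#' @export
fit_stage1 <- function(model, train, val, epochs = 300L,
                       checkpoint_every = 15L, eta_init = NULL,
                       verbose = FALSE) {
  nC <- length(train$cells)
  if (is.null(eta_init)) eta_init <- matrix(0, nC, 9L)
  par <- dg_pack(model, eta_init)
  Oinv <- diag(9)
  fn <- function(p) {
    u <- dg_unpack(p, model, nC)
    v <- dg_eval(u$model, train$cells, u$eta_mat, Oinv,
                 want_theta = FALSE, want_eta = FALSE)$value
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(p) {
    u <- dg_unpack(p, model, nC)
    r <- dg_eval(u$model, train$cells, u$eta_mat, Oinv)
    g <- c(r$grad_theta, as.numeric(r$grad_eta))
    g[!is.finite(g)] <- 0
    g
  }
  n_chunks <- ceiling(epochs / checkpoint_every)
  checkpoints <- list()
  trace <- data.frame(epoch = integer(), objective = numeric(),
                      val_rmse = numeric())
  last_finite <- par
  for (chunk in seq_len(n_chunks)) {
    res <- tryCatch(
      stats::optim(par, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = checkpoint_every)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) {
      warning("optimizer diverged; returning last finite checkpoint")
      break
    }
    par <- res$par
    last_finite <- par
    u <- dg_unpack(par, model, nC)
    vr <- validation_rmse(u$model, val)
    epoch <- min(chunk * checkpoint_every, epochs)
    checkpoints[[chunk]] <- list(epoch = epoch, par = par, val_rmse = vr,
                                 objective = res$value)
    trace <- rbind(trace, data.frame(epoch = epoch, objective = res$value,
                                     val_rmse = vr))
    if (verbose) {
      message(sprintf("epoch %4d  objective %.2f  val RMSE %.5f",
                      epoch, res$value, vr))
    }
    if (res$convergence == 0 && chunk > 1L &&
        abs(checkpoints[[chunk - 1L]]$objective - res$value) < 1e-10) break
  }
  if (!length(checkpoints)) {
    u <- dg_unpack(last_finite, model, nC)
    return(structure(list(model = u$model, eta = u$eta_mat,
                          checkpoints = list(), trace = trace,
                          selected = NA_integer_), class = "fit_state"))
  }
  best <- which.min(vapply(checkpoints, `[[`, numeric(1), "val_rmse"))
  u <- dg_unpack(checkpoints[[best]]$par, model, nC)
  structure(list(model = u$model, eta = u$eta_mat, checkpoints = checkpoints,
                 trace = trace, selected = best,
                 selected_epoch = checkpoints[[best]]$epoch),
            class = "fit_state")
}

#' @export
print.fit_state <- function(x, ...) {
  cat(sprintf("<fit_state> %d checkpoints, selected epoch %s\n",
              length(x$checkpoints),
              if (length(x$checkpoints)) x$selected_epoch else "none"))
  if (nrow(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final objective %.3f, best val RMSE %.5f\n",
                last$objective,
                min(x$trace$val_rmse)))
  }
  invisible(x)
}

# ---- stage 2 ----------------------------------------------------------------

#' Stage-2 estimation of the random-effect prior covariance
#'
#' Holds every fixed effect from stage 1 constant and maximizes the FOCE
#' (Laplace-at-the-mode) marginal log-likelihood over a diagonal Omega by
#' expectation-maximization: each iteration re-estimates every cell's
#' empirical Bayes mode and Gauss-Newton curvature H under the current
#' Omega and updates each prior variance to the mean posterior second
#' moment, \code{mean(eta_j^2 + (H^{-1})_jj)}. The fixed point of this
#' update is a stationary point of the Laplace marginal; on linear-Gaussian
#' models it converges to the exact marginal maximum-likelihood variance.
#'
#' @param model the stage-1 \code{deep_gating_model} (or any model
#'   implementing the cell interface)
#' @param fit_data an \code{hh_fit_data} (or list with a \code{cells} field)
#' @param iterations EM iterations (default 10)
#' @param Omega_init starting covariance (default identity)
#' @return list(Omega, trace = per-iteration variances and FOCE objective,
#'   foce = final objective)
#' @export
fit_stage2 <- function(model, fit_data, iterations = 10L, Omega_init = NULL) {
  d <- n_eta(model)
  if (is.null(Omega_init)) Omega_init <- diag(d)
  cells <- fit_data$cells
  sigma <- model_sigma(model)
  vars <- diag(as.matrix(Omega_init))
  ebe <- NULL
  rows <- list()
  for (it in seq_len(iterations)) {
    Omega <- diag(vars, d)
    Oinv <- diag(1 / vars, d)
    second <- matrix(0, length(cells), d)
    ebe_new <- vector("list", length(cells))
    for (i in seq_along(cells)) {
      cell <- cells[[i]]
      eb <- estimate_ebe(model, cell, Omega,
                         eta_init = if (is.null(ebe)) NULL else ebe[[i]])
      eta <- eb$eta
      J <- vapply(seq_len(d), function(j) {
        h <- 1e-5
        ep <- eta; ep[j] <- ep[j] + h
        em <- eta; em[j] <- em[j] - h
        (predict_cell(model, cell, ep) - predict_cell(model, cell, em)) / (2 * h)
      }, numeric(length(cell_y(model, cell))))
      H <- crossprod(matrix(J, ncol = d)) / sigma^2 + Oinv
      Hinv <- tryCatch(chol2inv(chol(H)), error = function(e) {
        warning("non-positive curvature at an EBE; ridge applied")
        chol2inv(chol(H + diag(1e-6, d)))
      })
      second[i, ] <- eta^2 + diag(Hinv)
      ebe_new[[i]] <- eta
    }
    ebe <- ebe_new
    vars <- pmax(colMeans(second), 1e-8)
    rows[[it]] <- data.frame(iteration = it, t(vars))
  }
  Omega <- diag(vars, d)
  foce <- foce_marginal_loglik(model, cells, Omega, ebe_init = ebe)$value
  list(Omega = Omega, foce = foce, trace = do.call(rbind, rows))
}

# ---- classical parametric baseline ------------------------------------------

#' Classical HH model with random effects on designated parameters
#'
#' Wraps a user-supplied builder that maps a random-effect vector to
#' \code{gating_functions}; the fixed parametric structure and Omega stay
#' frozen while sigma and the per-cell effects are fitted
#' (\code{\link{fit_random_effects_only}}).
#'
#' @param make_funcs function(eta) returning a \code{gating_functions}
#' @param n_eta random-effect dimension
#' @param sigma observation noise
#' @param Omega random-effect prior covariance
#' @param params an \code{hh_params}
#' @return a \code{classical_hh_model}
#' @export
classical_hh_model <- function(make_funcs, n_eta, sigma = 0.1,
                               Omega = diag(n_eta), params = hh_params()) {
  structure(list(make_funcs = make_funcs, n_eta_ = as.integer(n_eta),
                 sigma = sigma, Omega = as.matrix(Omega), params = params),
            class = "classical_hh_model")
}

#' @export
n_eta.classical_hh_model <- function(model) model$n_eta_

#' @export
cell_y.classical_hh_model <- function(model, cell) {
  unlist(lapply(cell$sweeps, `[[`, "obs_y"))
}

#' @export
predict_cell.classical_hh_model <- function(model, cell, eta) {
  funcs <- model$make_funcs(eta)
  pm <- model$params
  unlist(lapply(cell$sweeps, function(s) {
    minf <- vapply(seq_len(pm$G), function(i)
      vapply(s$volt, function(v) funcs$m_inf[[i]](v, cell$Temp), numeric(1)),
      numeric(length(s$volt)))
    tau <- vapply(seq_len(pm$G), function(i)
      vapply(s$volt, function(v) funcs$tau[[i]](v, cell$Temp), numeric(1)),
      numeric(length(s$volt)))
    scale <- (s$volt - pm$E) / (pm$V_max - pm$E)
    sweep_kernel_cpp(s$seg_start, s$seg_dur, scale,
                     matrix(minf, ncol = pm$G), matrix(tau, ncol = pm$G),
                     pm$powers, s$obs_t, s$obs_seg,
                     numeric(length(s$obs_t)), FALSE)$pred
  }))
}

#' Fit only sigma and the random effects of a frozen parametric model
#'
#' The baseline treatment of published parametric models: the structural
#' parameters and Omega stay fixed; per-cell empirical Bayes estimates and
#' the observation noise are estimated by coordinate iteration (sigma is
#' the residual SD given the current effects).
#'
#' @param model a \code{classical_hh_model} (or any cell-interface model)
#' @param fit_data an \code{hh_fit_data}
#' @param iterations coordinate iterations (default 3)
#' @return list(model (sigma updated), eta = cells x d matrix, sigma)
#' @export
fit_random_effects_only <- function(model, fit_data, iterations = 3L) {
  d <- n_eta(model)
  cells <- fit_data$cells
  eta_mat <- matrix(0, length(cells), d)
  for (it in seq_len(iterations)) {
    for (i in seq_along(cells)) {
      eta_mat[i, ] <- estimate_ebe(model, cells[[i]], model$Omega,
                                   eta_init = eta_mat[i, ])$eta
    }
    ssr <- 0; n <- 0
    for (i in seq_along(cells)) {
      r <- cell_y(model, cells[[i]]) - predict_cell(model, cells[[i]], eta_mat[i, ])
      ssr <- ssr + sum(r^2); n <- n + length(r)
    }
    model$sigma <- sqrt(ssr / n)
  }
  list(model = model, eta = eta_mat, sigma = model$sigma)
}

# ---- linear-Gaussian toy model ----------------------------------------------

#' Linear-Gaussian random-effect toy model
#'
#' y_m = eta + epsilon with scalar eta; the workhorse for oracle checks
#' (its marginal likelihood and posterior mode are available in closed
#' form, and the Laplace/FOCE approximation is exact for it).
#'
#' @param sigma observation noise
#' @return a \code{linear_re_model}
#' @export
linear_re_model <- function(sigma = 1) {
  structure(list(sigma = sigma), class = "linear_re_model")
}

#' @export
n_eta.linear_re_model <- function(model) 1L

#' @export
cell_y.linear_re_model <- function(model, cell) cell$y

#' @export
predict_cell.linear_re_model <- function(model, cell, eta) {
  rep(eta[1L], length(cell$y))
}

#' @export
cell_nll_grad.linear_re_model <- function(model, cell, eta) {
  sum(eta[1L] - cell$y) / model$sigma^2
}
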