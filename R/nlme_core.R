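#' Nonlinear mixed-effects estimation machinery
#'
#' The hierarchical model: fixed effects Theta (network weights, the
#' random-effect prior covariance Omega and the observation noise sigma)
#' sit above per-cell random effects eta. Estimation proceeds in two
#' stages: a conditional MAP stage maximizing
#' log p(Theta) + sum_n [log p(y_n | Theta, eta_n) + log p(eta_n | Theta)]
#' jointly over Theta and all eta_n with Omega held at identity, then a
#' stage maximizing a first-order conditional (Laplace-at-the-EBE)
#' approximation of the marginal likelihood over Omega only.
#'
#' @name nlme
NULL

# ---- elementary densities ---------------------------------------------------

#' Gaussian observation log-likelihood
#'
#' Sum of pointwise Normal(pred, sigma) log-densities.
#'
#' @param y observed values
#' @param pred model predictions aligned with y
#' @param sigma observation noise SD (> 0)
#' @return scalar log-density
#' @export
observation_loglik <- function(y, pred, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (length(y) != length(pred)) stop("y/pred length mismatch", call. = FALSE)
  sum(stats::dnorm(y, mean = pred, sd = sigma, log = TRUE))
}

#' Random-effect log-prior
#'
#' Multivariate normal log-density at eta with mean zero and covariance
#' Omega.
#'
#' @param eta random-effect vector
#' @param Omega covariance matrix (symmetric positive definite)
#' @return scalar log-density
#' @export
eta_logprior <- function(eta, Omega) {
  d <- length(eta)
  Omega <- as.matrix(Omega)
  ch <- tryCatch(chol(Omega), error = function(e)
    stop("Omega is not positive definite", call. = FALSE))
  z <- backsolve(ch, eta, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Fixed-effect log-prior (L1)
#'
#' -lambda * sum(|theta|), the Laplace(0, 1/lambda) prior up to its
#' normalizing constant.
#'
#' @param theta fixed-effect vector
#' @param lambda penalty strength (>= 0)
#' @return scalar (constant dropped)
#' @export
theta_logprior <- function(theta, lambda) {
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  -lambda * sum(abs(theta))
}

# ---- generic model interface ------------------------------------------------

#' Predictions of one cell given its random effects
#' @param model a fitted-model object
#' @param cell one cell's prepared data
#' @param eta random-effect vector
#' @return numeric vector aligned with \code{cell_y(model, cell)}
#' @export
predict_cell <- function(model, cell, eta) UseMethod("predict_cell")

#' Observations of one cell
#' @inheritParams predict_cell
#' @return numeric vector
#' @export
cell_y <- function(model, cell) UseMethod("cell_y")

#' Random-effect dimension of a model
#' @param model a fitted-model object
#' @return integer
#' @export
n_eta <- function(model) UseMethod("n_eta")

#' Observation noise of a model
#' @param model a fitted-model object
#' @return sigma
#' @export
model_sigma <- function(model) UseMethod("model_sigma")

#' @export
model_sigma.default <- function(model) model$sigma

theta_values <- function(model) UseMethod("theta_values")

#' @export
theta_values.default <- function(model) numeric(0)

# negative log-likelihood of one cell's data (no prior)
cell_nll <- function(model, cell, eta) {
  -observation_loglik(cell_y(model, cell), predict_cell(model, cell, eta),
                      model_sigma(model))
}

# gradient of cell_nll wrt eta; default central finite differences
cell_nll_grad <- function(model, cell, eta) UseMethod("cell_nll_grad")

#' @export
cell_nll_grad.default <- function(model, cell, eta) {
  h <- 1e-5
  vapply(seq_along(eta), function(j) {
    ep <- eta; ep[j] <- ep[j] + h
    em <- eta; em[j] <- em[j] - h
    (cell_nll(model, cell, ep) - cell_nll(model, cell, em)) / (2 * h)
  }, numeric(1))
}

# ---- empirical Bayes estimates ---------------------------------------------

#' Empirical Bayes estimate of one cell's random effects
#'
#' Maximizes log p(y | Theta, eta) + log p(eta | Omega) over eta with the
#' fixed effects held constant (quasi-Newton with analytic or
#' finite-difference gradients). Non-convergence is flagged and the best
#' iterate returned.
#'
#' @param model a fitted-model object
#' @param cell one cell's prepared data
#' @param Omega random-effect prior covariance
#' @param eta_init starting point (default zero, the prior mode)
#' @param maxit optimizer iteration cap
#' @return list(eta, value = achieved log-posterior, converged)
#' @export
estimate_ebe <- function(model, cell, Omega = diag(n_eta(model)),
                         eta_init = NULL, maxit = 100L) {
  d <- n_eta(model)
  if (is.null(eta_init)) eta_init <- rep(0, d)
  Omega <- as.matrix(Omega)
  Oinv <- chol2inv(chol(Omega))
  fn <- function(eta) cell_nll(model, cell, eta) + 0.5 * sum(eta * (Oinv %*% eta))
  gr <- function(eta) cell_nll_grad(model, cell, eta) + as.numeric(Oinv %*% eta)
  res <- stats::optim(eta_init, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit))
  # fn omits the constant -0.5*logdet(2*pi*Omega) of the prior; restore it so
  # the reported value is the full log posterior at the mode
  list(eta = res$par,
       value = -res$value - 0.5 * as.numeric(determinant(2 * pi * Omega)$modulus),
       converged = res$convergence == 0)
}

# ---- FOCE marginal likelihood ----------------------------------------------

#' First-order conditional approximation of the marginal log-likelihood
#'
#' For each cell the integral over eta is approximated by a Laplace
#' expansion at the empirical Bayes estimate, with the curvature taken in
#' Gauss-Newton form H = J'J / sigma^2 + Omega^{-1} (J the Jacobian of the
#' predictions in eta); a 1e-6 ridge stabilizes non-positive curvature.
#' The fixed-effect prior log p(Theta) is added.
#'
#' @param model a fitted-model object
#' @param cells list of prepared cells
#' @param Omega random-effect prior covariance
#' @param lambda L1 strength of the fixed-effect prior (default from the
#'   model if present, else 0)
#' @param ebe_init optional list of warm-start eta vectors
#' @return list(value, ebe = list of eta vectors, by_cell = numeric vector)
#' @export
foce_marginal_loglik <- function(model, cells, Omega, lambda = NULL,
                                 ebe_init = NULL) {
  d <- n_eta(model)
  Omega <- as.matrix(Omega)
  Oinv <- chol2inv(chol(Omega))
  if (is.null(lambda)) lambda <- model$lambda %||% 0
  sigma <- model_sigma(model)
  by_cell <- numeric(length(cells))
  ebes <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    init <- if (!is.null(ebe_init)) ebe_init[[i]] else NULL
    eb <- estimate_ebe(model, cell, Omega, eta_init = init)
    eta <- eb$eta
    ll_cond <- -cell_nll(model, cell, eta)
    lp <- eta_logprior(eta, Omega)
    J <- vapply(seq_len(d), function(j) {
      h <- 1e-5
      ep <- eta; ep[j] <- ep[j] + h
      em <- eta; em[j] <- em[j] - h
      (predict_cell(model, cell, ep) - predict_cell(model, cell, em)) / (2 * h)
    }, numeric(length(cell_y(model, cell))))
    J <- matrix(J, ncol = d)
    H <- crossprod(J) / sigma^2 + Oinv
    ld <- determinant(H, logarithm = TRUE)
    if (ld$sign <= 0 || !is.finite(ld$modulus)) {
      warning("non-positive curvature at an EBE; ridge applied")
      H <- H + diag(1e-6 + abs(min(eigen(H, only.values = TRUE)$values)), d)
      ld <- determinant(H, logarithm = TRUE)
    }
    by_cell[i] <- ll_cond + lp + 0.5 * d * log(2 * pi) - 0.5 * ld$modulus[1]
    ebes[[i]] <- eta
  }
  list(value = sum(by_cell) + theta_logprior(theta_values(model), lambda),
       ebe = ebes, by_cell = by_cell)
}
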