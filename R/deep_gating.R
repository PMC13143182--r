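#' Neural-network gating functions with random-effect inputs
#'
#' Each gate's steady state and time constant is a small multilayer
#' perceptron taking (scaled voltage, effective normalized temperature, two
#' gate-specific random effects) and ending in a sigmoid head (steady state,
#' range (0,1)) or softplus head (time constant, range (0, Inf)). A
#' covariate-augmentation network maps (channel-type indicator, effective
#' normalized temperature) to an 8-vector of augmentation random effects
#' added element-wise to the free random effects.
#'
#' @name deep_gating
NULL

ACT_TANH <- function(z) tanh(z)
ACT_TANH_D <- function(a) 1 - a^2

head_forward <- function(z, head) {
  switch(head,
    sigmoid = 1 / (1 + exp(-z)),
    softplus = ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
    linear = z)
}
head_deriv <- function(z, out, head) {
  switch(head,
    sigmoid = out * (1 - out),
    softplus = 1 / (1 + exp(-z)),
    linear = z * 0 + 1)
}

#' Create a multilayer perceptron
#'
#' Weights are drawn Normal(0, 1/sqrt(fan_in)); biases start at
#' \code{out_bias} for the output layer and 0 elsewhere. Hidden activation
#' is tanh.
#'
#' @param sizes integer vector of layer widths, input first, output last
#' @param head output nonlinearity: "sigmoid", "softplus" or "linear"
#' @param out_bias initial output-layer bias
#' @param seed integer seed for the deterministic initialization
#' @return an \code{mlp} object
#' @export
mlp_init <- function(sizes, head = c("linear", "sigmoid", "softplus"),
                     out_bias = 0, seed = 1L) {
  head <- match.arg(head)
  stopifnot(length(sizes) >= 2L)
  with_preserved_rng(seed, {
    L <- length(sizes) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      W[[l]] <- matrix(stats::rnorm(sizes[l + 1L] * sizes[l], 0, 1 / sqrt(sizes[l])),
                       nrow = sizes[l + 1L])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    b[[L]] <- rep(out_bias, sizes[L + 1L])
    structure(list(W = W, b = b, sizes = sizes, head = head), class = "mlp")
  })
}

#' Forward pass through an MLP
#'
#' @param net an \code{mlp}
#' @param X input: a vector (one sample) or matrix with samples in rows
#' @param cache keep intermediate activations for \code{\link{mlp_backward}}
#' @return output matrix (samples x output width), with attribute
#'   \code{"cache"} when requested
#' @export
mlp_forward <- function(net, X, cache = FALSE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != net$sizes[1L]) {
    stop("input width ", ncol(X), " does not match first layer size ",
         net$sizes[1L], call. = FALSE)
  }
  L <- length(net$W)
  A <- X
  acts <- if (cache) vector("list", L + 1L) else NULL
  if (cache) acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% t(net$W[[l]]) + matrix(net$b[[l]], nrow(A), length(net$b[[l]]), byrow = TRUE)
    A <- if (l < L) ACT_TANH(Z) else head_forward(Z, net$head)
    if (cache) acts[[l + 1L]] <- A
    if (l == L && cache) attr(acts, "z_out") <- Z
  }
  if (cache) attr(A, "cache") <- acts
  A
}

#' Reverse pass: accumulate weight gradients and input cotangents
#'
#' Given output cotangents u (samples x output width), returns the summed
#' gradient of \code{sum_r u_r . out_r} with respect to every weight and
#' bias, plus the per-sample input gradients.
#'
#' @param net an \code{mlp}
#' @param out forward output produced with \code{cache = TRUE}
#' @param u cotangent matrix (same shape as the output)
#' @return list(gW, gb, gX)
#' @export
mlp_backward <- function(net, out, u) {
  acts <- attr(out, "cache")
  if (is.null(acts)) stop("forward pass must be run with cache = TRUE", call. = FALSE)
  if (is.null(dim(u))) u <- matrix(u, nrow = nrow(out))
  L <- length(net$W)
  z_out <- attr(acts, "z_out")
  delta <- u * head_deriv(z_out, acts[[L + 1L]], net$head)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- t(delta) %*% acts[[l]]
    gb[[l]] <- colSums(delta)
    dA <- delta %*% net$W[[l]]
    if (l > 1L) delta <- dA * ACT_TANH_D(acts[[l]])
  }
  list(gW = gW, gb = gb, gX = dA)
}

mlp_n_params <- function(net) {
  sum(vapply(net$W, length, numeric(1))) + sum(vapply(net$b, length, numeric(1)))
}

mlp_get_params <- function(net) {
  unlist(c(lapply(net$W, as.numeric), net$b))
}

mlp_set_params <- function(net, v) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    k <- length(net$W[[l]])
    net$W[[l]][] <- v[pos + seq_len(k)]; pos <- pos + k
  }
  for (l in seq_along(net$b)) {
    k <- length(net$b[[l]])
    net$b[[l]][] <- v[pos + seq_len(k)]; pos <- pos + k
  }
  net
}

mlp_grad_vector <- function(g) unlist(c(lapply(g$gW, as.numeric), g$gb))

#' Normalized temperature
#'
#' T_bar = (T - 25) / 10, so the three standard recording temperatures map
#' to -1, 0, +1.
#'
#' @param Temp temperature in degrees C
#' @return normalized temperature
#' @export
normalize_temperature <- function(Temp) (Temp - 25) / 10

#' Inverse of \code{\link{normalize_temperature}}
#' @param T_bar normalized temperature
#' @return temperature in degrees C
#' @export
denormalize_temperature <- function(T_bar) T_bar * 10 + 25

#' Neural-network steady-state gating function
#'
#' Evaluates the gate's steady-state network on (V / v_scale, T_eff,
#' eta_m); the sigmoid head keeps the output strictly inside (0, 1).
#'
#' @param net the gate's steady-state \code{mlp} (sigmoid head)
#' @param V voltage, mV (vectorized)
#' @param eta_m the gate's two steady-state random effects
#' @param T_eff effective normalized temperature (T_bar + eta_temp)
#' @param v_scale voltage input scaling (default 100)
#' @return values in (0,1)
#' @export
nn_m_inf <- function(net, V, eta_m, T_eff, v_scale = 100) {
  n <- length(V)
  X <- cbind(V / v_scale, rep(T_eff, n), matrix(eta_m, n, 2, byrow = TRUE))
  as.numeric(mlp_forward(net, X))
}

#' Neural-network time-constant gating function
#'
#' As \code{\link{nn_m_inf}} with a softplus head; output is strictly
#' positive, in ms. \code{tau_scale} multiplies the head purely for
#' conditioning (the default 1 gives the bare softplus).
#'
#' @param net the gate's time-constant \code{mlp} (softplus head)
#' @param V voltage, mV (vectorized)
#' @param eta_tau the gate's two time-constant random effects
#' @param T_eff effective normalized temperature
#' @param v_scale voltage input scaling (default 100)
#' @param tau_scale output scale in ms (default 1)
#' @return time constants in (0, Inf), ms
#' @export
nn_tau <- function(net, V, eta_tau, T_eff, v_scale = 100, tau_scale = 1) {
  n <- length(V)
  X <- cbind(V / v_scale, rep(T_eff, n), matrix(eta_tau, n, 2, byrow = TRUE))
  tau_scale * as.numeric(mlp_forward(net, X))
}

#' Covariate augmentation network
#'
#' Maps the channel-type indicator and the effective normalized temperature
#' to the 8 augmentation random effects (linear head).
#'
#' @param net the augmentation \code{mlp} (linear head, 8 outputs)
#' @param onehot channel-type indicator vector (all zeros is the reference
#'   type)
#' @param T_bar normalized temperature
#' @param eta_temp temperature random effect (default 0)
#' @return numeric vector of 8 augmentation effects
#' @export
augment <- function(net, onehot, T_bar, eta_temp = 0) {
  if (sum(onehot == 1) > 1L || any(!onehot %in% c(0, 1))) {
    stop("onehot must be a 0/1 indicator with at most one 1", call. = FALSE)
  }
  as.numeric(mlp_forward(net, c(onehot, T_bar + eta_temp)))
}

#' Construct a deep gating model
#'
#' Fixed effects: four gating networks (two gates x steady state / time
#' constant; two hidden layers of \code{hidden} units), the augmentation
#' network, the random-effect prior covariance Omega (8 + 1 dimensions,
#' initialized to identity) and the observation noise sigma. Gating
#' networks take 4 inputs (scaled V, effective normalized temperature, two
#' random effects).
#'
#' @param n_onehot width of the channel-type indicator
#' @param hidden hidden layer widths (default c(5, 5))
#' @param tau_scale fixed softplus output scale for the time-constant
#'   networks, ms
#' @param v_scale voltage input scale, mV
#' @param sigma initial observation noise (normalized-current units)
#' @param lambda L1 penalty on the network weights
#' @param powers gating exponents (default c(1, 1))
#' @param E reversal potential, mV
#' @param V_max normalization voltage, mV
#' @param eta_temp_in_gating whether eta_temp perturbs the temperature seen
#'   by the gating networks as well as the augmentation network
#' @param seed initialization seed
#' @return a \code{deep_gating_model}
#' @export
deep_gating_model <- function(n_onehot, hidden = c(5L, 5L), tau_scale = 50,
                              v_scale = 100, sigma = 0.1, lambda = 1e-4,
                              powers = c(1L, 1L), E = -90, V_max = 80,
                              eta_temp_in_gating = TRUE, seed = 1L) {
  g_sizes <- c(4L, hidden, 1L)
  a_sizes <- c(n_onehot + 1L, hidden, 8L)
  inv_softplus <- function(y) log(expm1(y))
  nets <- list(
    minf1 = mlp_init(g_sizes, "sigmoid", out_bias = 0, seed = seed + 11L),
    tau1 = mlp_init(g_sizes, "softplus", out_bias = inv_softplus(80 / tau_scale), seed = seed + 12L),
    minf2 = mlp_init(g_sizes, "sigmoid", out_bias = 0, seed = seed + 13L),
    tau2 = mlp_init(g_sizes, "softplus", out_bias = inv_softplus(5 / tau_scale), seed = seed + 14L),
    aug = mlp_init(a_sizes, "linear", out_bias = 0, seed = seed + 15L)
  )
  structure(list(
    nets = nets, sigma = sigma, Omega = diag(9), lambda = lambda,
    config = list(n_onehot = n_onehot, hidden = hidden, tau_scale = tau_scale,
                  v_scale = v_scale, powers = as.integer(powers), E = E,
                  V_max = V_max, eta_temp_in_gating = eta_temp_in_gating)
  ), class = "deep_gating_model")
}

#' @export
print.deep_gating_model <- function(x, ...) {
  cat(sprintf(
    "<deep_gating_model> 2 gates, hidden [%s], %d-wide type indicator\n  %d fixed-effect parameters, sigma = %.4g\n",
    paste(x$config$hidden, collapse = ","), x$config$n_onehot,
    length(model_param_vector(x)), x$sigma))
  invisible(x)
}

model_param_vector <- function(model) {
  c(unlist(lapply(model$nets, mlp_get_params)), log(model$sigma))
}

model_set_params <- function(model, v) {
  pos <- 0L
  for (nm in names(model$nets)) {
    k <- mlp_n_params(model$nets[[nm]])
    model$nets[[nm]] <- mlp_set_params(model$nets[[nm]], v[pos + seq_len(k)])
    pos <- pos + k
  }
  model$sigma <- exp(v[pos + 1L])
  model
}

model_param_blocks <- function(model) {
  sizes <- vapply(model$nets, mlp_n_params, numeric(1))
  ends <- cumsum(sizes)
  starts <- c(1, ends[-length(ends)] + 1)
  blocks <- Map(function(s, e) s:e, starts, ends)
  names(blocks) <- names(model$nets)
  blocks$log_sigma <- ends[length(ends)] + 1L
  blocks
}

#' Cell covariates
#'
#' @param channel_index 1-based channel-type index; 1 is the reference type
#'   encoded as the all-zero indicator
#' @param n_onehot indicator width
#' @param Temp recording temperature, degrees C
#' @return list(onehot, T_bar)
#' @export
cell_covariates <- function(channel_index, n_onehot, Temp) {
  onehot <- rep(0, n_onehot)
  if (channel_index > 1L) {
    if (channel_index - 1L > n_onehot) stop("channel index exceeds indicator width", call. = FALSE)
    onehot[channel_index - 1L] <- 1
  }
  list(onehot = onehot, T_bar = normalize_temperature(Temp))
}

#' Assemble the gating functions of one cell
#'
#' Curries the fixed effects, the covariates and the cell's random effects
#' into per-gate (V, T) gating functions: eta = eta_star + NN_aug(c, T_eff)
#' and T_eff = T_bar + eta_temp. With all effects zero and a zero
#' augmentation network this is the population model.
#'
#' @param model a \code{deep_gating_model}
#' @param covariates output of \code{\link{cell_covariates}}
#' @param eta_star the 8 free random effects (two per gating function, in
#'   order minf1, tau1, minf2, tau2)
#' @param eta_temp the temperature random effect
#' @return a \code{gating_functions} object
#' @export
assemble_cell_model <- function(model, covariates, eta_star = rep(0, 8),
                                eta_temp = 0) {
  cfg <- model$config
  # the temperature pathway follows the queried T (population predictions at
  # unrecorded temperatures are a supported use), so the augmentation effects
  # are recomputed per call
  eta_at <- function(Temp) {
    T_bar <- normalize_temperature(Temp)
    eta_star + augment(model$nets$aug, covariates$onehot, T_bar, eta_temp)
  }
  gate_T_eff <- function(Temp) {
    normalize_temperature(Temp) + if (cfg$eta_temp_in_gating) eta_temp else 0
  }
  mk_minf <- function(net, sel) function(V, Temp)
    nn_m_inf(net, V, eta_at(Temp)[sel], gate_T_eff(Temp), cfg$v_scale)
  mk_tau <- function(net, sel) function(V, Temp)
    nn_tau(net, V, eta_at(Temp)[sel], gate_T_eff(Temp), cfg$v_scale, cfg$tau_scale)
  gating_functions(
    m_inf = list(mk_minf(model$nets$minf1, 1:2),
                 mk_minf(model$nets$minf2, 5:6)),
    tau = list(mk_tau(model$nets$tau1, 3:4),
               mk_tau(model$nets$tau2, 7:8))
  )
}
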