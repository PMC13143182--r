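#' Data splitting, model comparison and population diagnostics
#'
#' @name evaluation
NULL

largest_remainder_alloc <- function(n, fractions) {
  ideal <- n * fractions
  base <- floor(ideal + 1e-9)
  rem <- ideal - base
  left <- n - sum(base)
  if (left > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(left)]
    base[add] <- base[add] + 1L
  }
  as.integer(base)
}

#' Stratified train/validation/test split
#'
#' Cells are partitioned within each channel-type x temperature stratum
#' (never splitting a cell across sets), deterministically given the seed.
#'
#' @param dataset a \code{sweep_dataset}
#' @param fractions length-3 vector summing to 1 (default 60/20/20)
#' @param seed integer seed
#' @return list(train, val, test) of \code{sweep_dataset}s
#' @export
split_dataset <- function(dataset, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(inherits(dataset, "sweep_dataset"),
            abs(sum(fractions) - 1) < 1e-9, length(fractions) == 3L)
  meta <- dataset$metadata
  strata <- split(meta$cell_id, interaction(meta$channel_type, meta$temperature_C, drop = TRUE))
  sets <- list(train = character(), val = character(), test = character())
  with_preserved_rng(seed, {
    for (ids in strata) {
      ids <- as.character(ids)
      if (length(ids) < 5L) {
        warning("stratum with fewer than 5 cells; best-effort allocation")
      }
      ids <- sample(ids)
      k <- largest_remainder_alloc(length(ids), fractions)
      sets$train <- c(sets$train, ids[seq_len(k[1])])
      sets$val <- c(sets$val, ids[k[1] + seq_len(k[2])])
      sets$test <- c(sets$test, ids[k[1] + k[2] + seq_len(k[3])])
    }
  })
  subset_ds <- function(ids) {
    sweep_dataset(dataset$cells[ids],
                  metadata = meta[meta$cell_id %in% ids, , drop = FALSE],
                  truth = dataset$truth, processed = dataset$processed)
  }
  lapply(sets, subset_ds)
}

#' Balanced unified training roster
#'
#' Takes \code{cells_per_stratum} cells per temperature per channel type,
#' with the listed types held out entirely.
#'
#' @param metadata data.frame with cell_id, channel_type, temperature_C
#'   (or a \code{sweep_dataset}, whose metadata is used)
#' @param cells_per_stratum cells taken per channel type x temperature
#' @param exclude_types channel types fully held out
#' @param seed integer seed for the within-stratum selection
#' @return character vector of selected cell ids
#' @export
build_unified_training_set <- function(metadata, cells_per_stratum = 7L,
                                       exclude_types = character(), seed = 1L) {
  if (inherits(metadata, "sweep_dataset")) metadata <- metadata$metadata
  meta <- metadata[!metadata$channel_type %in% exclude_types, , drop = FALSE]
  strata <- split(meta$cell_id, interaction(meta$channel_type, meta$temperature_C, drop = TRUE))
  with_preserved_rng(seed, {
    unlist(lapply(names(strata), function(nm) {
      ids <- as.character(strata[[nm]])
      if (length(ids) < cells_per_stratum) {
        stop("stratum ", nm, " has only ", length(ids), " cells; ",
             cells_per_stratum, " required", call. = FALSE)
      }
      sort(sample(ids, cells_per_stratum))
    }), use.names = FALSE)
  })
}

#' Per-sweep root-mean-square error
#'
#' @param observed observed values
#' @param predicted predictions aligned with observed
#' @return sqrt of the mean squared residual
#' @export
rmse_per_sweep <- function(observed, predicted) {
  if (length(observed) == 0L) stop("empty sweep in rmse_per_sweep()", call. = FALSE)
  if (length(observed) != length(predicted)) stop("length mismatch", call. = FALSE)
  sqrt(mean((observed - predicted)^2))
}

#' Paired model comparison on per-sweep RMSE values
#'
#' Reports the median difference, the Wilcoxon rank-sum statistic W of the
#' two RMSE samples (exact distribution when both n <= 25 and there are no
#' ties, normal approximation with continuity correction otherwise),
#' Cohen's d on the paired differences (or with pooled SD), and a
#' Bonferroni-adjusted significance flag at alpha.
#'
#' @param rmse_A,rmse_B paired per-sweep RMSE vectors (equal length)
#' @param n_comparisons Bonferroni correction factor
#' @param alpha significance level for the flag (default 1e-6)
#' @param d_method "paired" (mean/sd of differences) or "pooled"
#' @return one-row data.frame (a comparison row)
#' @export
compare_models <- function(rmse_A, rmse_B, n_comparisons = 1L, alpha = 1e-6,
                           d_method = c("paired", "pooled")) {
  d_method <- match.arg(d_method)
  if (length(rmse_A) != length(rmse_B)) stop("paired samples must have equal length", call. = FALSE)
  n <- length(rmse_A)
  diffs <- rmse_A - rmse_B
  exact <- n <= 25L && !any(duplicated(c(rmse_A, rmse_B)))
  wt <- suppressWarnings(stats::wilcox.test(rmse_A, rmse_B, exact = exact,
                                            correct = TRUE))
  d <- if (d_method == "paired") {
    if (stats::sd(diffs) == 0) 0 else mean(diffs) / stats::sd(diffs)
  } else {
    sp <- sqrt((stats::var(rmse_A) + stats::var(rmse_B)) / 2)
    if (sp == 0) 0 else (mean(rmse_A) - mean(rmse_B)) / sp
  }
  p_adj <- min(1, wt$p.value * n_comparisons)
  data.frame(median_diff = stats::median(diffs),
             W = unname(wt$statistic), n = n, cohens_d = d,
             p_value = wt$p.value, p_adjusted = p_adj,
             significant = p_adj < alpha)
}

#' Weighted residuals under population or individual predictions
#'
#' residual = (observed - predicted) / sigma; population mode predicts at
#' eta = 0, individual mode at each cell's estimate.
#'
#' @param model a cell-interface model (e.g. \code{deep_gating_model})
#' @param fit_data an \code{hh_fit_data}
#' @param mode "population" or "individual"
#' @param eta_mat cells x d matrix of estimates (required for individual
#'   mode)
#' @return data.frame(cell_id, sweep, time, observed, predicted, wres)
#' @export
weighted_residuals <- function(model, fit_data, mode = c("population", "individual"),
                               eta_mat = NULL) {
  mode <- match.arg(mode)
  d <- n_eta(model)
  sigma <- model_sigma(model)
  if (mode == "individual" && is.null(eta_mat)) {
    stop("individual mode needs eta_mat (the EBEs)", call. = FALSE)
  }
  rows <- lapply(seq_along(fit_data$cells), function(i) {
    cell <- fit_data$cells[[i]]
    eta <- if (mode == "population") rep(0, d) else eta_mat[i, ]
    pred <- predict_cell(model, cell, eta)
    obs <- cell_y(model, cell)
    sweep_lab <- unlist(lapply(cell$sweeps, function(s)
      rep(paste0(s$protocol, "_", s$sweep_index), length(s$obs_y))))
    tt <- unlist(lapply(cell$sweeps, `[[`, "obs_t"))
    data.frame(cell_id = cell$cell_id, sweep = sweep_lab, time = tt,
               observed = obs, predicted = pred,
               wres = (obs - pred) / sigma)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Empirical Bayes estimate pair diagnostics
#'
#' @param ebes cells x d matrix of estimates
#' @param rmse_by_cell per-cell mean sweep RMSE (same order as rows)
#' @return list(correlation = d x d matrix, pairs = long table joining each
#'   EBE coordinate pair with the cell's RMSE)
#' @export
ebe_diagnostics <- function(ebes, rmse_by_cell = NULL) {
  ebes <- as.matrix(ebes)
  if (nrow(ebes) < 2L) stop("need at least 2 cells", call. = FALSE)
  d <- ncol(ebes)
  sds <- apply(ebes, 2, stats::sd)
  cm <- diag(1, d)
  ok <- sds > 0
  if (sum(ok) >= 2L) cm[ok, ok] <- stats::cor(ebes[, ok, drop = FALSE])
  pairs <- list()
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        cell = seq_len(nrow(ebes)), i = i, j = j,
        eta_i = ebes[, i], eta_j = ebes[, j],
        rmse = if (is.null(rmse_by_cell)) NA_real_ else rmse_by_cell)
    }
  }
  list(correlation = cm, pairs = do.call(rbind, pairs))
}

#' Visual predictive check
#'
#' For every sweep (protocol x sweep index) the observed 10/50/90%
#' quantile curves across cells are compared against 95% confidence bands
#' of the same quantiles computed from \code{n_populations} replicate
#' populations simulated from the fitted hierarchical model (random
#' effects drawn from Omega, observation noise from sigma; each replicate
#' reuses the observed cells' covariates and grids). Curves are
#' interpolated onto a common uniform grid per sweep.
#'
#' @param model a cell-interface model
#' @param fit_data an \code{hh_fit_data} holding the observed cells
#' @param Omega random-effect covariance of the fitted model
#' @param n_populations number of simulated replicate populations
#' @param seed integer seed
#' @param protocols optional subset of protocol names
#' @param grid_points points of the common time grid per sweep
#' @param quantiles data quantiles tracked (default 10/50/90%)
#' @return a \code{vpc_result}: per sweep the grid, observed quantile
#'   curves, the simulated bands and the outside-band mask
#' @export
vpc <- function(model, fit_data, Omega = diag(n_eta(model)),
                n_populations = 200L, seed = 1L, protocols = NULL,
                grid_points = 61L, quantiles = c(0.1, 0.5, 0.9)) {
  d <- n_eta(model)
  sigma <- model_sigma(model)
  Omega <- as.matrix(Omega)
  ch <- chol(Omega)
  cells <- fit_data$cells
  # index sweeps by family
  keys <- unique(unlist(lapply(cells, function(c)
    vapply(c$sweeps, function(s) paste(s$protocol, s$sweep_index), character(1)))))
  if (!is.null(protocols)) {
    keys <- keys[vapply(strsplit(keys, " "), `[[`, character(1), 1L) %in% protocols]
  }
  qmat_on_grid <- function(per_cell_curves, grid) {
    # rows: cells, cols: grid
    do.call(rbind, lapply(per_cell_curves, function(cc)
      stats::approx(cc$t, cc$y, xout = grid, rule = 2)$y))
  }
  results <- list()
  with_preserved_rng(seed, {
    for (key in keys) {
      parts <- strsplit(key, " ")[[1L]]
      pr <- parts[1L]; si <- as.integer(parts[2L])
      idx <- lapply(cells, function(c) {
        w <- which(vapply(c$sweeps, function(s)
          s$protocol == pr && s$sweep_index == si, logical(1)))
        if (length(w)) w[1L] else NA_integer_
      })
      have <- which(!is.na(unlist(idx)))
      if (length(have) < 2L) next
      tmax <- max(unlist(lapply(have, function(i) max(cells[[i]]$sweeps[[idx[[i]]]]$obs_t))))
      grid <- seq(0, tmax, length.out = grid_points)
      obs_curves <- lapply(have, function(i) {
        s <- cells[[i]]$sweeps[[idx[[i]]]]
        list(t = s$obs_t, y = s$obs_y)
      })
      obs_mat <- qmat_on_grid(obs_curves, grid)
      obs_q <- apply(obs_mat, 2, stats::quantile, probs = quantiles, names = FALSE)
      sim_q <- array(NA_real_, c(n_populations, length(quantiles), grid_points))
      for (r in seq_len(n_populations)) {
        sim_curves <- lapply(have, function(i) {
          cell <- cells[[i]]
          s <- cell$sweeps[[idx[[i]]]]
          eta <- as.numeric(t(ch) %*% stats::rnorm(d))
          pred <- predict_cell_sweep(model, cell, idx[[i]], eta)
          list(t = s$obs_t, y = pred + stats::rnorm(length(pred), 0, sigma))
        })
        sm <- qmat_on_grid(sim_curves, grid)
        sim_q[r, , ] <- apply(sm, 2, stats::quantile, probs = quantiles, names = FALSE)
      }
      band_lo <- apply(sim_q, c(2, 3), stats::quantile, probs = 0.025, names = FALSE)
      band_hi <- apply(sim_q, c(2, 3), stats::quantile, probs = 0.975, names = FALSE)
      outside <- obs_q < band_lo | obs_q > band_hi
      results[[key]] <- list(protocol = pr, sweep_index = si, grid = grid,
                             obs_q = obs_q, band_lo = band_lo,
                             band_hi = band_hi, outside = outside)
    }
  })
  structure(list(sweeps = results, quantiles = quantiles,
                 n_populations = n_populations), class = "vpc_result")
}

# predictions of a single sweep of a cell (falls back to slicing the full
# cell prediction when no faster route exists)
predict_cell_sweep <- function(model, cell, sweep_i, eta) {
  UseMethod("predict_cell_sweep")
}

#' @export
predict_cell_sweep.default <- function(model, cell, sweep_i, eta) {
  lens <- vapply(cell$sweeps, function(s) length(s$obs_y), integer(1))
  full <- predict_cell(model, cell, eta)
  off <- cumsum(c(0L, lens))[sweep_i]
  full[off + seq_len(lens[sweep_i])]
}

#' @export
predict_cell_sweep.deep_gating_model <- function(model, cell, sweep_i, eta) {
  nets <- dg_cell_nets(model, cell, eta)
  dg_sweep_kernel(model, cell$sweeps[[sweep_i]], nets)$pred
}

#' Fraction of time points where the observed quantiles sit inside the bands
#'
#' @param x a \code{vpc_result}
#' @return overall coverage in [0, 1]
#' @export
vpc_coverage <- function(x) {
  stopifnot(inherits(x, "vpc_result"))
  outs <- unlist(lapply(x$sweeps, function(s) s$outside))
  1 - mean(outs)
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("<vpc_result> %d sweeps, %d simulated populations, coverage %.3f\n",
              length(x$sweeps), x$n_populations, vpc_coverage(x)))
  invisible(x)
}

#' Q10 temperature-coefficient curve of a gating time constant
#'
#' Q10_i(V) = tau_i(V, T) / tau_i(V, T + 10), evaluated over a voltage
#' grid; for a fitted hierarchical model pass its population gating
#' functions (eta = 0).
#'
#' @param funcs a \code{gating_functions} object
#' @param V voltage grid, mV
#' @param Temp lower temperature of the ratio, degrees C
#' @param gate gate index
#' @return numeric vector of Q10 values over V
#' @export
q10_curve <- function(funcs, V, Temp, gate = 1L) {
  stopifnot(inherits(funcs, "gating_functions"))
  lo <- vapply(V, function(v) funcs$tau[[gate]](v, Temp), numeric(1))
  hi <- vapply(V, function(v) funcs$tau[[gate]](v, Temp + 10), numeric(1))
  lo / hi
}

#' Population gating functions of a deep model
#'
#' The cell model at eta_star = 0, eta_temp = 0 for the given covariates.
#'
#' @param model a \code{deep_gating_model}
#' @param channel_index 1-based channel-type index
#' @param Temp nominal recording temperature (only used to build the
#'   covariate record; the returned functions take their own T argument)
#' @return a \code{gating_functions} object
#' @export
population_gating_functions <- function(model, channel_index = 1L, Temp = 25) {
  cov <- cell_covariates(channel_index, model$config$n_onehot, Temp)
  assemble_cell_model(model, cov)
}
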