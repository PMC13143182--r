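#' Sweep preprocessing and quality control
#'
#' Implements the full sweep-processing pipeline: repetition selection,
#' cross-protocol consistency filtering via the mean absolute percentage
#' error (MAPE), DCT-based smoothing, baseline subtraction, per-cell
#' normalization to the +80 mV activation peak, rescaling of the other
#' protocols to their matching activation peaks, removal of fast negative
#' voltage-step artifacts, and extrema-preserving M4 downsampling.
#'
#' @name preprocess
NULL

#' Default preprocessing configuration
#'
#' @param mape_threshold exclusion threshold for the consistency MAPE (0.05)
#' @param clip normalized-current floor; points below it are deleted (-0.01)
#' @param factor smoothing intensity of \code{\link{denoise}} (1.0)
#' @param mape_rel_floor reference points smaller in magnitude than this
#'   fraction of the reference segment peak are excluded from the MAPE
#'   average (percentage errors at near-zero references are noise-dominated)
#' @param endpoint_noise_mult the recovery endpoint test flags a sweep when
#'   it deviates from the per-cell median by more than
#'   \code{max(SD across sweeps, endpoint_noise_mult * noise SD)}
#' @param i_max_noise_mult a cell is excluded when its +80 mV activation peak
#'   does not exceed \code{i_max_noise_mult} times the estimated noise SD
#' @param consistency_on_smoothed compute consistency checks on smoothed
#'   copies of the traces (default TRUE)
#' @param consistency_factor smoothing intensity used only inside the
#'   consistency checks; heavy smoothing is appropriate there because the
#'   same kernel is applied to both compared traces, so shared shape
#'   distortion cancels while independent noise is suppressed
#' @param min_peak_frac consistency rules are only applied to sweeps whose
#'   own smoothed peak reaches this fraction of the +80 mV activation peak;
#'   below it the peak-ratio scaling amplifies noise past any useful
#'   percentage-error comparison and the sweep is kept
#' @param mape_trim trimmed fraction passed to \code{\link{mape}} inside the
#'   consistency checks (brief step artifacts occupy a small fraction of a
#'   comparison window and should not decide a whole-sweep exclusion)
#' @param recovery_endpoint_smoothed use the smoothed value at 1500 ms
#'   post-baseline in the recovery endpoint test (default TRUE)
#' @return a named list of settings
#' @export
preprocess_config <- function(mape_threshold = 0.05, clip = -0.01, factor = 1.0,
                              mape_rel_floor = 0.3, endpoint_noise_mult = 3,
                              i_max_noise_mult = 5,
                              consistency_on_smoothed = TRUE,
                              consistency_factor = 144,
                              min_peak_frac = 0.25,
                              mape_trim = 0.025,
                              recovery_endpoint_smoothed = TRUE) {
  list(
    mape_threshold = mape_threshold, clip = clip, factor = factor,
    mape_rel_floor = mape_rel_floor, endpoint_noise_mult = endpoint_noise_mult,
    i_max_noise_mult = i_max_noise_mult,
    consistency_on_smoothed = consistency_on_smoothed,
    consistency_factor = consistency_factor,
    min_peak_frac = min_peak_frac,
    mape_trim = mape_trim,
    recovery_endpoint_smoothed = recovery_endpoint_smoothed
  )
}

#' Mean absolute percentage error
#'
#' MAPE(x, y) = mean over admissible i of |(x_i - y_i) / x_i|. Points where
#' the reference magnitude is below \code{max(abs_floor, rel_floor * max|x|)}
#' are excluded from the average, since percentage errors at near-zero
#' references are unbounded.
#'
#' @param x reference series
#' @param y evaluated series (same length)
#' @param rel_floor admissibility floor as a fraction of \code{max(abs(x))}
#' @param abs_floor absolute admissibility floor
#' @param trim fraction of the largest percentage errors dropped before
#'   averaging (robustness against brief artifacts; default 0, the plain
#'   mean)
#' @return non-negative scalar
#' @export
mape <- function(x, y, rel_floor = 0.05, abs_floor = 1e-6, trim = 0) {
  if (length(x) != length(y)) stop("series length mismatch in mape()", call. = FALSE)
  if (length(x) < 1L) stop("empty series in mape()", call. = FALSE)
  floor_val <- max(abs_floor, rel_floor * max(abs(x)))
  ok <- abs(x) >= floor_val
  if (!any(ok)) stop("no admissible points in mape(): reference is near zero everywhere", call. = FALSE)
  r <- abs((x[ok] - y[ok]) / x[ok])
  k <- floor(trim * length(r))
  if (k > 0L) r <- sort(r)[seq_len(length(r) - k)]
  mean(r)
}

# ---- DCT-based smoothing ----------------------------------------------------

# DCT-II (unnormalized): X_k = sum_j x_j cos(pi*(j+1/2)*k/n), via FFT of the
# even-index reordering.
dct2 <- function(x) {
  n <- length(x)
  v <- c(x[seq(1L, n, by = 2L)], rev(x[seq.int(2L, n, by = 2L)]))
  V <- stats::fft(v)
  k <- 0:(n - 1L)
  Re(V * exp(-1i * pi * k / (2 * n)))
}

# Inverse of dct2 (up to the standard 2/n scaling).
idct2 <- function(X) {
  n <- length(X)
  k <- 0:(n - 1L)
  V <- (X - 1i * c(0, rev(X[-1L]))) / 2 * exp(1i * pi * k / (2 * n))
  v <- Re(stats::fft(V, inverse = TRUE)) * 2 / n
  x <- numeric(n)
  half <- ceiling(n / 2)
  x[seq(1L, n, by = 2L)] <- v[seq_len(half)]
  if (n > 1L) x[seq(2L, n, by = 2L)] <- rev(v[(half + 1L):n])
  x
}

#' Smooth a signal by Gaussian attenuation of its DCT spectrum
#'
#' The signal is transformed with the type-II discrete cosine transform, the
#' coefficients are multiplied by a Gaussian kernel
#' g(k) = exp(-(k * factor * pi / n)^2 / 2), and the result is transformed
#' back. The DC component is preserved, so constants pass unchanged.
#'
#' @param x numeric signal (length >= 2, finite)
#' @param factor smoothing intensity (> 0); larger is smoother
#' @return smoothed signal of the same length
#' @export
denoise <- function(x, factor = 1.0) {
  if (length(x) < 2L) stop("denoise() needs at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in denoise() input", call. = FALSE)
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  n <- length(x)
  k <- 0:(n - 1L)
  g <- exp(-(k * factor * pi / n)^2 / 2)
  idct2(dct2(x) * g)
}

# ---- Elementary per-sweep steps --------------------------------------------

#' Subtract the baseline-period mean from a sweep
#'
#' Subtracts the mean of the samples with t < 40 ms from the whole trace, so
#' the first baseline segment has mean zero.
#'
#' @param times times in ms
#' @param current current values
#' @return the shifted current vector
#' @export
subtract_baseline <- function(times, current) {
  sel <- times < 40
  if (!any(sel)) stop("no samples before 40 ms; cannot set baseline", call. = FALSE)
  current - mean(current[sel])
}

#' Rescale a sweep by a matching activation peak
#'
#' Multiplies the trace by \code{matching_activation_peak / own_peak}.
#'
#' @param current current values
#' @param matching_activation_peak peak of the matching activation sweep
#' @param own_peak this sweep's peak (> 0)
#' @return rescaled current vector
#' @export
rescale_sweep <- function(current, matching_activation_peak, own_peak) {
  if (own_peak <= 0) stop("own_peak must be positive for rescaling", call. = FALSE)
  current * (matching_activation_peak / own_peak)
}

#' Delete fast negative artifact points
#'
#' Removes (point deletion, not truncation) every sample whose normalized
#' value is below the threshold; times of the surviving points are unchanged.
#'
#' @param times times in ms
#' @param current normalized current
#' @param threshold deletion threshold (default -0.01)
#' @return list(times, current) with offending points removed
#' @export
clip_negative_artifacts <- function(times, current, threshold = -0.01) {
  keep <- current >= threshold
  list(times = times[keep], current = current[keep])
}

#' M4 extrema-preserving downsampler
#'
#' Partitions the series into \code{b} contiguous near-equal bins (edges at
#' \code{round(j * n / b)}) and keeps, from each bin, its first and last
#' samples plus the maximum and minimum of the remaining samples, emitted in
#' time order. Bins shorter than 4 repeat values so the output length is
#' exactly \code{4 * b}.
#'
#' @param times times in ms (same length as values)
#' @param values series values
#' @param b number of bins (>= 1); requires \code{length(values) >= 4 * b}
#' @return list(times, values) of length 4 * b
#' @export
m4_downsample <- function(times, values, b) {
  n <- length(values)
  if (length(times) != n) stop("times/values length mismatch", call. = FALSE)
  if (b < 1L) stop("b must be >= 1", call. = FALSE)
  if (n < 4L * b) stop("series too short for M4: need length >= 4*b", call. = FALSE)
  edges <- round(seq_len(b) * n / b)
  starts <- c(1L, edges[-b] + 1L)
  out_t <- numeric(4L * b); out_v <- numeric(4L * b)
  for (j in seq_len(b)) {
    lo <- starts[j]; hi <- edges[j]
    sz <- hi - lo + 1L
    if (sz >= 4L) {
      mid <- (lo + 1L):(hi - 1L)
      i_max <- mid[which.max(values[mid])]
      i_min <- mid[which.min(values[mid])]
      idx <- sort(c(lo, i_max, i_min, hi))
    } else if (sz == 3L) {
      idx <- c(lo, lo + 1L, lo + 1L, hi)
    } else if (sz == 2L) {
      idx <- c(lo, lo, hi, hi)
    } else {
      idx <- rep(lo, 4L)
    }
    out_t[(4L * j - 3L):(4L * j)] <- times[idx]
    out_v[(4L * j - 3L):(4L * j)] <- values[idx]
  }
  list(times = out_t, values = out_v)
}

equidistant_3 <- function(idx) {
  n <- length(idx)
  if (n == 0L) return(integer(0))
  unique_3 <- c(1L, floor((n - 1L) / 2L) + 1L, n)
  idx[unique_3]
}

#' Downsample a sweep with the per-protocol segment scheme
#'
#' Baseline: 3 + 3 + 3 equidistant points from [0,40), [40,50), [50,100) ms;
#' final 100 ms: 3 equidistant points. Protocol-specific windows use M4:
#' activation [100,600) to 120 points; deactivation [100,400) to 72 and
#' [400,600) to 48; inactivation [100,1500) to 360 and [1600,1700) to 24;
#' recovery [100,1600) to 360, the variable gap to 3 equidistant points, and
#' the test pulse to 48.
#'
#' @param times times in ms (uniform protocol sampling)
#' @param current current values
#' @param protocol_name one of the four protocol names
#' @param sweep_index sweep number within the family (needed for the
#'   recovery gap duration)
#' @return list(times, current)
#' @export
downsample_sweep <- function(times, current, protocol_name, sweep_index) {
  if (!protocol_name %in% PROTOCOL_NAMES) {
    stop("unknown protocol name: ", protocol_name, call. = FALSE)
  }
  dur <- max(times)
  win <- function(a, b) which(times >= a & times < b)
  pick_eq3 <- function(a, b) equidistant_3(win(a, b))
  m4w <- function(a, b, bins) {
    i <- win(a, b)
    m4_downsample(times[i], current[i], bins)
  }
  base_idx <- c(pick_eq3(0, 40), pick_eq3(40, 50), pick_eq3(50, 100))
  parts <- list(list(times = times[base_idx], values = current[base_idx]))
  if (protocol_name == "activation") {
    parts <- c(parts, list(m4w(100, 600, 30L)))
    final_start <- 600
  } else if (protocol_name == "deactivation") {
    parts <- c(parts, list(m4w(100, 400, 18L), m4w(400, 600, 12L)))
    final_start <- 600
  } else if (protocol_name == "inactivation") {
    parts <- c(parts, list(m4w(100, 1500, 90L), m4w(1600, 1700, 6L)))
    final_start <- 1700
  } else {
    gap <- 50 + 150 * (sweep_index - 1)
    test_start <- 1600 + gap
    # test pulse runs up to the final 100 ms tail, whatever its length
    dt <- stats::median(diff(times))
    test_end <- round(dur + dt) - 100
    gap_idx <- pick_eq3(1600, test_start)
    parts <- c(parts,
               list(m4w(100, 1600, 90L)),
               list(list(times = times[gap_idx], values = current[gap_idx])),
               list(m4w(test_start, test_end, 12L)))
    final_start <- test_end
  }
  fin_idx <- equidistant_3(which(times >= final_start))
  parts <- c(parts, list(list(times = times[fin_idx], values = current[fin_idx])))
  list(
    times = unlist(lapply(parts, `[[`, "times")),
    current = unlist(lapply(parts, `[[`, "values"))
  )
}

# ---- Repetition selection ---------------------------------------------------

#' Select the repetition used from each protocol family
#'
#' Keeps the second repetition of the activation protocol and the first
#' repetition of every other protocol; all other repetitions are dropped.
#' A family whose required repetition is absent is excluded with a reason.
#'
#' @param sweeps list of sweep records (each with protocol, sweep_index,
#'   repetition fields)
#' @return list(sweeps = kept sweep records, exclusions = data.frame)
#' @export
select_repetitions <- function(sweeps) {
  required_rep <- function(p) if (p == "activation") 2L else 1L
  kept <- list(); excl <- list()
  protos <- unique(vapply(sweeps, `[[`, character(1), "protocol"))
  for (p in protos) {
    fam <- Filter(function(s) s$protocol == p, sweeps)
    reps <- vapply(fam, `[[`, integer(1), "repetition")
    need <- required_rep(p)
    if (!need %in% reps) {
      excl[[length(excl) + 1L]] <- data.frame(
        protocol = p,
        sweep_index = vapply(fam, `[[`, integer(1), "sweep_index"),
        repetition = reps,
        reason = sprintf("missing repetition %d", need)
      )
    } else {
      kept <- c(kept, fam[reps == need])
      if (any(reps != need)) {
        drop <- fam[reps != need]
        excl[[length(excl) + 1L]] <- data.frame(
          protocol = p,
          sweep_index = vapply(drop, `[[`, integer(1), "sweep_index"),
          repetition = vapply(drop, `[[`, integer(1), "repetition"),
          reason = "unused repetition"
        )
      }
    }
  }
  list(sweeps = kept, exclusions = if (length(excl)) do.call(rbind, excl) else NULL)
}

# ---- Consistency checks -----------------------------------------------------

seg_window <- function(sweep, a, b) {
  sel <- sweep$times >= a & sweep$times < b
  list(times = sweep$times[sel], current = sweep$current[sel])
}

sweep_peak <- function(current) max(current)

activation_voltage_index <- function(v) {
  # activation sweep k holds at -90 + 10*(k-1) mV
  k <- (v + 90) / 10 + 1
  if (abs(k - round(k)) > 1e-9 || k < 1 || k > 18) return(NA_integer_)
  as.integer(round(k))
}

#' Cross-protocol consistency check for one sweep
#'
#' Applies the protocol-specific rule comparing a deactivation, inactivation,
#' or recovery sweep against the matching activation sweep(s):
#' \describe{
#'   \item{deactivation}{the 100--400 ms (+70 mV) window is compared against
#'     the +70 mV activation sweep after scaling its peak to the activation
#'     peak; MAPE above the threshold excludes the sweep.}
#'   \item{inactivation}{the first 500 ms post-baseline is compared against
#'     the same-voltage activation sweep, both scaled by the +80 mV
#'     activation peak over their own peak.}
#'   \item{recovery}{the first 500 ms of the +50 mV hold is compared against
#'     the +50 mV activation sweep with the same +80 mV scaling; in addition
#'     the value at 1500 ms post-baseline must not deviate from the per-cell
#'     median at that time by more than max(SD across sweeps,
#'     \code{endpoint_noise_mult} x noise SD).}
#' }
#' All traces are baseline-subtracted copies; when
#' \code{config$consistency_on_smoothed} is TRUE (default) they are smoothed
#' first.
#'
#' @param sweep the sweep record to evaluate (times, current, protocol,
#'   sweep_index)
#' @param activation_refs list of the cell's activation sweep records
#'   (repetition already selected), indexed by sweep_index
#' @param rule protocol name of the rule to apply
#' @param config a \code{\link{preprocess_config}} list
#' @param recovery_context optional list(endpoints, noise_sd) for the
#'   recovery endpoint criterion
#' @return list(keep, mape, reason)
#' @export
consistency_check <- function(sweep, activation_refs, rule,
                              config = preprocess_config(),
                              recovery_context = NULL) {
  prep <- function(s) {
    cur <- if (config$consistency_on_smoothed)
      denoise(s$current, config$consistency_factor) else s$current
    list(times = s$times, current = subtract_baseline(s$times, cur))
  }
  get_act <- function(k) {
    for (a in activation_refs) if (a$sweep_index == k) return(a)
    NULL
  }
  thr <- config$mape_threshold
  act80 <- get_act(activation_voltage_index(80))
  if (is.null(act80)) return(list(keep = FALSE, mape = NA_real_, reason = "missing +80 mV activation sweep"))
  peak80 <- sweep_peak(prep(act80)$current)
  # window-based scaled MAPE shared by all three rules; peaks are taken over
  # the compared window so both traces are normalized consistently
  windowed_mape <- function(ref, a, b, ref_scale_to_80 = TRUE) {
    rw <- seg_window(prep(ref), a, b)
    ew <- seg_window(prep(sweep), a, b)
    if (length(rw$current) != length(ew$current)) {
      return(list(keep = FALSE, mape = NA_real_, reason = "sampling mismatch with activation reference"))
    }
    own_peak <- sweep_peak(ew$current)
    if (own_peak < config$min_peak_frac * peak80) {
      # peak-ratio scaling would amplify noise past any useful comparison
      return(list(keep = TRUE, mape = NA_real_, reason = "below comparison floor; not checked"))
    }
    rs <- rw$current * (peak80 / sweep_peak(rw$current))
    es <- ew$current * (peak80 / own_peak)
    # both copies carry independently estimated baselines; their small
    # errors are amplified by the peak-ratio scaling, so remove the median
    # pairwise offset (the rules target shape, not residual offset)
    es <- es - stats::median(es - rs)
    m <- mape(rs, es, rel_floor = config$mape_rel_floor,
              trim = config$mape_trim)
    list(keep = m <= thr, mape = m,
         reason = if (m <= thr) NA_character_ else sprintf("MAPE %.3f > %.2f", m, thr))
  }
  if (rule == "deactivation") {
    ref <- get_act(activation_voltage_index(70))
    if (is.null(ref)) return(list(keep = FALSE, mape = NA_real_, reason = "missing +70 mV activation sweep"))
    return(windowed_mape(ref, 100, 400))
  }
  if (rule == "inactivation") {
    v <- -40 + 10 * (sweep$sweep_index - 1)
    ref <- get_act(activation_voltage_index(v))
    if (is.null(ref)) return(list(keep = FALSE, mape = NA_real_, reason = sprintf("missing %+d mV activation sweep", v)))
    return(windowed_mape(ref, 100, 600))
  }
  if (rule == "recovery") {
    ref <- get_act(activation_voltage_index(50))
    if (is.null(ref)) return(list(keep = FALSE, mape = NA_real_, reason = "missing +50 mV activation sweep"))
    res_m <- windowed_mape(ref, 100, 600)
    if (!res_m$keep || !is.na(res_m$reason)) return(res_m)
    m <- res_m$mape
    if (!is.null(recovery_context)) {
      ends <- recovery_context$endpoints
      own <- ends[as.character(sweep$sweep_index)]
      med <- stats::median(ends)
      tol <- max(stats::sd(ends), config$endpoint_noise_mult * recovery_context$noise_sd)
      if (is.finite(own) && abs(own - med) > tol) {
        return(list(keep = FALSE, mape = m,
                    reason = sprintf("endpoint deviates %.3f > %.3f from median", abs(own - med), tol)))
      }
    }
    return(list(keep = TRUE, mape = m, reason = NA_character_))
  }
  list(keep = TRUE, mape = NA_real_, reason = NA_character_)
}

recovery_endpoint_value <- function(sweep, config) {
  cur <- if (config$recovery_endpoint_smoothed) denoise(sweep$current, config$factor) else sweep$current
  cur <- subtract_baseline(sweep$times, cur)
  # end of the +50 mV hold (1500 ms post-baseline): median over the last
  # 10 ms before the step, out of reach of step artifacts and their smear
  sel <- sweep$times >= 1590 & sweep$times < 1599
  stats::median(cur[sel])
}

estimate_noise_sd <- function(sweep, config) {
  stats::sd(sweep$current - denoise(sweep$current, config$factor))
}

# ---- Pipeline ---------------------------------------------------------------

#' Run the full preprocessing pipeline on a dataset
#'
#' Steps, in order: repetition selection, consistency filtering, smoothing,
#' baseline subtraction, normalization by the +80 mV activation peak,
#' rescaling of the other protocols, negative-artifact deletion, and
#' per-protocol downsampling. One bad sweep never aborts the dataset; every
#' decision is recorded in the QC report.
#'
#' @param dataset a \code{sweep_dataset} (see \code{\link{sweep_dataset}})
#' @param config a \code{\link{preprocess_config}} list
#' @return list(dataset = processed \code{sweep_dataset}, qc = data.frame
#'   with one row per input sweep)
#' @export
run_pipeline <- function(dataset, config = preprocess_config()) {
  stopifnot(inherits(dataset, "sweep_dataset"))
  qc <- list()
  out_cells <- list()
  add_qc <- function(cell_id, protocol, sweep_index, repetition, decision, reason, mape_val = NA_real_) {
    qc[[length(qc) + 1L]] <<- data.frame(
      cell_id = cell_id, protocol = protocol, sweep_index = sweep_index,
      repetition = repetition, decision = decision,
      reason = if (is.na(reason)) NA_character_ else reason, mape = mape_val
    )
  }
  for (cell in dataset$cells) {
    sel <- select_repetitions(cell$sweeps)
    if (!is.null(sel$exclusions)) {
      for (r in seq_len(nrow(sel$exclusions))) {
        e <- sel$exclusions[r, ]
        add_qc(cell$cell_id, e$protocol, e$sweep_index, e$repetition, "excluded", e$reason)
      }
    }
    sweeps <- sel$sweeps
    act <- Filter(function(s) s$protocol == "activation", sweeps)
    others <- Filter(function(s) s$protocol != "activation", sweeps)

    # cell-level exclusion: +80 mV activation peak must clear the noise floor
    act80 <- Filter(function(s) s$sweep_index == 18L, act)
    cell_reason <- NULL
    i_max <- NA_real_
    if (length(act80) == 0L) {
      cell_reason <- "missing +80 mV activation sweep"
    } else {
      a80 <- act80[[1L]]
      sm80 <- subtract_baseline(a80$times, denoise(a80$current, config$factor))
      noise_sd <- estimate_noise_sd(a80, config)
      i_max <- max(sm80)
      if (i_max <= config$i_max_noise_mult * noise_sd) {
        cell_reason <- sprintf("+80 mV activation peak %.4f below noise floor", i_max)
      }
    }
    if (!is.null(cell_reason)) {
      for (s in sweeps) add_qc(cell$cell_id, s$protocol, s$sweep_index, s$repetition, "excluded", cell_reason)
      next
    }

    # consistency filtering (uses baselined, optionally smoothed copies)
    rec_sweeps <- Filter(function(s) s$protocol == "recovery", others)
    recovery_context <- NULL
    if (length(rec_sweeps) > 0L) {
      endpoints <- vapply(rec_sweeps, recovery_endpoint_value, numeric(1), config = config)
      names(endpoints) <- vapply(rec_sweeps, function(s) as.character(s$sweep_index), character(1))
      recovery_context <- list(
        endpoints = endpoints,
        noise_sd = stats::median(vapply(rec_sweeps, estimate_noise_sd, numeric(1), config = config))
      )
    }
    kept <- act
    for (s in act) add_qc(cell$cell_id, s$protocol, s$sweep_index, s$repetition, "kept", NA_character_)
    for (s in others) {
      res <- consistency_check(s, act, s$protocol, config, recovery_context)
      if (res$keep) {
        kept <- c(kept, list(s))
        add_qc(cell$cell_id, s$protocol, s$sweep_index, s$repetition, "kept", NA_character_, res$mape)
      } else {
        add_qc(cell$cell_id, s$protocol, s$sweep_index, s$repetition, "excluded", res$reason, res$mape)
      }
    }

    # smoothing + baseline
    kept <- lapply(kept, function(s) {
      s$current <- subtract_baseline(s$times, denoise(s$current, config$factor))
      s
    })
    # normalization by I_max (peak of the +80 mV activation sweep)
    a80 <- Filter(function(s) s$protocol == "activation" && s$sweep_index == 18L, kept)[[1L]]
    i_max <- max(a80$current)
    kept <- lapply(kept, function(s) { s$current <- s$current / i_max; s })

    # rescaling to the matching activation peaks
    act_peaks <- vapply(Filter(function(s) s$protocol == "activation", kept),
                        function(s) max(s$current), numeric(1))
    names(act_peaks) <- vapply(Filter(function(s) s$protocol == "activation", kept),
                               function(s) as.character(s$sweep_index), character(1))
    peak_of <- function(v) act_peaks[[as.character(activation_voltage_index(v))]]
    rescaled <- list()
    for (s in kept) {
      if (s$protocol != "activation") {
        target <- switch(s$protocol,
          deactivation = peak_of(70),
          inactivation = peak_of(-40 + 10 * (s$sweep_index - 1)),
          recovery = peak_of(50))
        own <- max(s$current)
        if (!is.finite(own) || own <= 0) {
          add_qc(cell$cell_id, s$protocol, s$sweep_index, s$repetition, "excluded", "non-positive peak at rescaling")
          next
        }
        s$current <- rescale_sweep(s$current, target, own)
      }
      rescaled <- c(rescaled, list(s))
    }

    # artifact clipping + downsampling
    processed <- lapply(rescaled, function(s) {
      cl <- clip_negative_artifacts(s$times, s$current, config$clip)
      ds <- downsample_sweep(cl$times, cl$current, s$protocol, s$sweep_index)
      list(protocol = s$protocol, sweep_index = s$sweep_index,
           repetition = s$repetition, times = ds$times, current = ds$current)
    })
    cell$sweeps <- processed
    cell$i_max <- i_max
    out_cells[[cell$cell_id]] <- cell
  }
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(cell_id = character(), protocol = character(), sweep_index = integer(),
               repetition = integer(), decision = character(), reason = character(),
               mape = numeric())
  qc <- qc[order(qc$cell_id, qc$protocol, qc$sweep_index, qc$repetition), ]
  rownames(qc) <- NULL
  list(
    dataset = sweep_dataset(out_cells, metadata = dataset$metadata[
      dataset$metadata$cell_id %in% names(out_cells), , drop = FALSE],
      truth = dataset$truth, processed = TRUE),
    qc = qc
  )
}
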