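#' Voltage-clamp protocol construction
#'
#' The four protocol families used throughout the package (activation,
#' deactivation, inactivation, recovery) are piecewise-constant voltage
#' commands. Every sweep starts with the same 100 ms baseline (0--40 ms at
#' -80 mV, 40--50 ms at -90 mV, 50--100 ms at -80 mV) and ends with a final
#' 100 ms at -80 mV. Segments follow a half-open convention
#' \code{[t_start, t_end)}: a voltage step at time t takes the new value at t.
#'
#' @name protocols
NULL

PROTOCOL_NAMES <- c("activation", "deactivation", "inactivation", "recovery")

#' Protocol family sizes
#'
#' Number of sweeps in each protocol family.
#' @return named integer vector
#' @export
protocol_family_sizes <- function() {
  c(activation = 18L, deactivation = 12L, inactivation = 12L, recovery = 16L)
}

baseline_segments <- function() {
  data.frame(
    t_start = c(0, 40, 50),
    t_end   = c(40, 50, 100),
    voltage = c(-80, -90, -80)
  )
}

new_sweep_protocol <- function(protocol_name, sweep_index, segments) {
  stopifnot(all(segments$t_end > segments$t_start))
  if (nrow(segments) > 1L) {
    stopifnot(all(abs(segments$t_start[-1L] - segments$t_end[-nrow(segments)]) < 1e-9))
  }
  structure(
    list(
      protocol_name = protocol_name,
      sweep_index = as.integer(sweep_index),
      segments = segments,
      duration = segments$t_end[nrow(segments)]
    ),
    class = "sweep_protocol"
  )
}

#' @export
print.sweep_protocol <- function(x, ...) {
  cat(sprintf(
    "<sweep_protocol> %s sweep %d: %d segments, %.0f ms\n",
    x$protocol_name, x$sweep_index, nrow(x$segments), x$duration
  ))
  invisible(x)
}

append_segments <- function(after, holds, voltages) {
  # holds: durations (ms), voltages: matching command levels
  t0 <- after
  out <- data.frame(
    t_start = t0 + c(0, cumsum(holds))[seq_along(holds)],
    t_end   = t0 + cumsum(holds),
    voltage = voltages
  )
  out
}

#' Build a voltage-clamp protocol family
#'
#' Constructs all sweeps of one of the four supported protocol families as
#' piecewise-constant voltage commands, in increasing stimulus order.
#'
#' \describe{
#'   \item{activation}{18 sweeps; hold at -90..+80 mV (10 mV steps) for 500 ms.}
#'   \item{deactivation}{12 sweeps; 300 ms at +70 mV, then 200 ms at
#'     -80..+30 mV (10 mV steps).}
#'   \item{inactivation}{12 sweeps; 1500 ms at -40..+70 mV (10 mV steps),
#'     then 100 ms at +30 mV.}
#'   \item{recovery}{16 sweeps; 1500 ms at +50 mV, a recovery gap at -80 mV of
#'     50..2300 ms (150 ms increments), then a +50 mV test pulse.}
#' }
#'
#' @param protocol_name one of \code{"activation"}, \code{"deactivation"},
#'   \code{"inactivation"}, \code{"recovery"}.
#' @param overrides optional named list overriding protocol parameters; the
#'   only commonly used entry is \code{recovery_test_ms} (defaults to 200 ms;
#'   150 ms is the alternative reading of the protocol description).
#' @return list of \code{sweep_protocol} objects.
#' @export
build_protocol <- function(protocol_name, overrides = list()) {
  if (length(protocol_name) != 1L || !protocol_name %in% PROTOCOL_NAMES) {
    stop("unknown protocol name: ", paste(protocol_name, collapse = ", "),
         call. = FALSE)
  }
  base <- baseline_segments()
  final_ms <- 100
  test_ms <- overrides$recovery_test_ms %||% 200

  sweeps <- switch(protocol_name,
    activation = lapply(seq_len(18L), function(k) {
      v <- -90 + 10 * (k - 1)
      seg <- rbind(base, append_segments(100, 500, v))
      seg <- rbind(seg, append_segments(600, final_ms, -80))
      new_sweep_protocol("activation", k, seg)
    }),
    deactivation = lapply(seq_len(12L), function(k) {
      v <- -80 + 10 * (k - 1)
      seg <- rbind(base, append_segments(100, c(300, 200), c(70, v)))
      seg <- rbind(seg, append_segments(600, final_ms, -80))
      new_sweep_protocol("deactivation", k, seg)
    }),
    inactivation = lapply(seq_len(12L), function(k) {
      v <- -40 + 10 * (k - 1)
      seg <- rbind(base, append_segments(100, c(1500, 100), c(v, 30)))
      seg <- rbind(seg, append_segments(1700, final_ms, -80))
      new_sweep_protocol("inactivation", k, seg)
    }),
    recovery = lapply(seq_len(16L), function(k) {
      gap <- 50 + 150 * (k - 1)
      seg <- rbind(base, append_segments(100, c(1500, gap, test_ms), c(50, -80, 50)))
      seg <- rbind(seg, append_segments(1600 + gap + test_ms, final_ms, -80))
      new_sweep_protocol("recovery", k, seg)
    })
  )
  sweeps
}

#' Evaluate the command voltage of a sweep at a time point
#'
#' Half-open segment convention: a boundary time belongs to the later segment.
#'
#' @param sweep a \code{sweep_protocol}
#' @param t time in ms; vectorized. Must satisfy \code{0 <= t < duration}.
#' @return voltage(s) in mV
#' @export
voltage_at <- function(sweep, t) {
  stopifnot(inherits(sweep, "sweep_protocol"))
  if (any(t < 0 | t >= sweep$duration)) {
    stop("time outside sweep duration [0, ", sweep$duration, ")", call. = FALSE)
  }
  idx <- findInterval(t, sweep$segments$t_start)
  sweep$segments$voltage[idx]
}

#' Uniform sampling grid with duplicated segment boundaries
#'
#' Returns a uniform grid from 0 to the sweep duration with spacing \code{dt},
#' with each interior segment boundary inserted (so both one-sided limits of a
#' voltage discontinuity are representable; duplicates are kept).
#'
#' @param sweep a \code{sweep_protocol}
#' @param dt grid spacing in ms (> 0)
#' @return numeric vector of time points (non-decreasing)
#' @export
sample_grid <- function(sweep, dt) {
  stopifnot(inherits(sweep, "sweep_protocol"), dt > 0)
  g <- seq(0, sweep$duration, by = dt)
  if (g[length(g)] < sweep$duration) g <- c(g, sweep$duration)
  bounds <- sweep$segments$t_start[-1L]
  sort(c(g, bounds))
}

#' Export protocol families as a table
#'
#' @param protocol_names character vector of family names (default all four)
#' @return data.frame with columns protocol, sweep_index, t_start_ms,
#'   t_end_ms, voltage_mV
#' @export
protocol_table <- function(protocol_names = PROTOCOL_NAMES) {
  rows <- lapply(protocol_names, function(p) {
    sw <- build_protocol(p)
    do.call(rbind, lapply(sw, function(s) {
      data.frame(
        protocol = p, sweep_index = s$sweep_index,
        t_start_ms = s$segments$t_start, t_end_ms = s$segments$t_end,
        voltage_mV = s$segments$voltage
      )
    }))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
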