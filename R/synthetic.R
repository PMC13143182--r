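#' Synthetic heterogeneous potassium-channel populations
#'
#' Generates virtual voltage-clamp datasets with known ground truth. Channel
#' archetypes play the role of channel types: each has two gates, a
#' Boltzmann steady state and a bell-shaped time constant per gate, with Q10
#' temperature scaling of the time constants. Cells sampled from an
#' archetype receive random half-activation shifts and log-normal
#' time-constant scalings; recordings add Gaussian observation noise,
#' per-sweep baseline offsets, a per-cell amplitude scale and, with
#' configured probabilities, negative voltage-step spike artifacts and
#' kinetically inconsistent sweeps that the QC pipeline must reject.
#'
#' @name synthetic_data
NULL

#' Population generator configuration
#'
#' Defaults are the package's standing study conditions for synthetic runs.
#'
#' @param n_archetypes number of channel archetypes
#' @param cells_per_archetype_per_temp cells recorded per archetype at each
#'   temperature
#' @param temperatures recording temperatures, degrees C
#' @param s_vhalf SD of the per-cell half-activation shift, mV
#' @param s_log_tau SD of the per-cell log time-constant-amplitude scaling
#' @param sigma_obs observation noise SD (units of the typical amplitude)
#' @param p_spike probability of a negative spike artifact at each interior
#'   voltage step
#' @param p_inconsistent probability that a deactivation/inactivation/
#'   recovery sweep is replaced by a kinetically inconsistent copy
#' @param baseline_offset_sd SD of the per-sweep baseline offset
#' @param amp_meanlog,amp_sdlog log-normal parameters of the per-cell
#'   amplitude scale
#' @param n_dead_cells number of extra cells with no channel current (their
#'   +80 mV peak is pure noise; the pipeline must drop them)
#' @param dt sampling interval, ms
#' @param seed integer seed; the dataset is a deterministic function of
#'   (config, seed)
#' @param exclude_archetypes archetype ids excluded from training rosters
#'   (held-out-type experiments)
#' @param recovery_test_ms recovery test-pulse duration, ms
#' @return a named list of settings
#' @export
population_config <- function(n_archetypes = 2L, cells_per_archetype_per_temp = 3L,
                              temperatures = c(15, 25, 35), s_vhalf = 5,
                              s_log_tau = 0.2, sigma_obs = 0.02, p_spike = 0.1,
                              p_inconsistent = 0.05, baseline_offset_sd = 0.05,
                              amp_meanlog = 0, amp_sdlog = 0.15,
                              n_dead_cells = 0L, dt = 0.1, seed = 20260427L,
                              exclude_archetypes = NULL, recovery_test_ms = 200) {
  list(n_archetypes = as.integer(n_archetypes),
       cells_per_archetype_per_temp = as.integer(cells_per_archetype_per_temp),
       temperatures = temperatures, s_vhalf = s_vhalf, s_log_tau = s_log_tau,
       sigma_obs = sigma_obs, p_spike = p_spike, p_inconsistent = p_inconsistent,
       baseline_offset_sd = baseline_offset_sd, amp_meanlog = amp_meanlog,
       amp_sdlog = amp_sdlog, n_dead_cells = as.integer(n_dead_cells), dt = dt,
       seed = as.integer(seed), exclude_archetypes = exclude_archetypes,
       recovery_test_ms = recovery_test_ms)
}

with_preserved_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

archetype_templates <- function() {
  list(
    # fast activator with pronounced inactivation (A-type like)
    list(g1 = list(V_half = -45, k = -9, tau_base = 25, tau_amp = 150,
                   V_peak = -45, w = 35, Q10 = 2, n = 1L),
         g2 = list(V_half = -25, k = 8, tau_base = 1, tau_amp = 6,
                   V_peak = -30, w = 30, Q10 = 4, n = 1L)),
    # slow activator with slow, shallow inactivation (delayed-rectifier like)
    list(g1 = list(V_half = -30, k = -14, tau_base = 60, tau_amp = 350,
                   V_peak = -30, w = 45, Q10 = 2, n = 1L),
         g2 = list(V_half = -5, k = 12, tau_base = 3, tau_amp = 18,
                   V_peak = -10, w = 40, Q10 = 4, n = 1L)),
    # non-inactivating delayed rectifier (gate 1 effectively open)
    list(g1 = list(V_half = 180, k = -10, tau_base = 100, tau_amp = 100,
                   V_peak = -20, w = 40, Q10 = 2, n = 1L),
         g2 = list(V_half = -10, k = 10, tau_base = 2, tau_amp = 12,
                   V_peak = -20, w = 35, Q10 = 4, n = 1L)),
    # slow activator with fast, complete inactivation
    list(g1 = list(V_half = -55, k = -7, tau_base = 15, tau_amp = 80,
                   V_peak = -55, w = 30, Q10 = 2, n = 1L),
         g2 = list(V_half = 0, k = 14, tau_base = 4, tau_amp = 25,
                   V_peak = 0, w = 45, Q10 = 4, n = 1L))
  )
}

#' Build channel archetypes
#'
#' Deterministically constructs \code{n} distinct archetypes spanning
#' fast/slow activation and present/absent inactivation. Beyond the four
#' base templates, additional archetypes are seeded jitters of them.
#'
#' @param n number of archetypes (>= 1)
#' @param seed integer seed
#' @return list of archetype specs (fields g1, g2 with Boltzmann and
#'   bell-shaped time-constant parameters, Q10 and gating power per gate)
#' @export
make_archetypes <- function(n, seed = 1L) {
  stopifnot(n >= 1L)
  tmpl <- archetype_templates()
  with_preserved_rng(seed, {
    lapply(seq_len(n), function(a) {
      base <- tmpl[[(a - 1L) %% length(tmpl) + 1L]]
      if (a > length(tmpl)) {
        for (g in c("g1", "g2")) {
          base[[g]]$V_half <- base[[g]]$V_half + stats::rnorm(1, 0, 8)
          base[[g]]$tau_amp <- base[[g]]$tau_amp * exp(stats::rnorm(1, 0, 0.3))
        }
      }
      base$id <- a
      base
    })
  })
}

archetype_gating_functions <- function(spec) {
  mk_minf <- function(p) function(V, Temp) boltzmann(V, p$V_half, p$k)
  mk_tau <- function(p) function(V, Temp)
    bell_tau(V, Temp, p$tau_base, p$tau_amp, p$V_peak, p$w, p$Q10)
  gating_functions(
    m_inf = list(mk_minf(spec$g1), mk_minf(spec$g2)),
    tau = list(mk_tau(spec$g1), mk_tau(spec$g2))
  )
}

#' Sample a cell from an archetype
#'
#' Shifts each gate's half-activation voltage by Normal(0, s_vhalf) and
#' scales each gate's time-constant amplitude by exp(Normal(0, s_log_tau)).
#' Draws are taken from the current RNG stream.
#'
#' @param archetype an archetype spec from \code{\link{make_archetypes}}
#' @param config a \code{\link{population_config}}
#' @return cell-level spec (same shape as the archetype) with an added
#'   \code{effects} record of the sampled deviations
#' @export
sample_cell <- function(archetype, config = population_config()) {
  eff <- list(
    dV1 = stats::rnorm(1, 0, config$s_vhalf),
    dV2 = stats::rnorm(1, 0, config$s_vhalf),
    lt1 = stats::rnorm(1, 0, config$s_log_tau),
    lt2 = stats::rnorm(1, 0, config$s_log_tau)
  )
  cell <- archetype
  cell$g1$V_half <- cell$g1$V_half + eff$dV1
  cell$g2$V_half <- cell$g2$V_half + eff$dV2
  cell$g1$tau_amp <- cell$g1$tau_amp * exp(eff$lt1)
  cell$g2$tau_amp <- cell$g2$tau_amp * exp(eff$lt2)
  cell$effects <- eff
  cell
}

distorted_spec <- function(spec) {
  # kinetic inconsistency: slower kinetics and shifted steady states, the
  # kind of drift between protocol blocks the MAPE filter exists to catch
  for (g in c("g1", "g2")) {
    spec[[g]]$tau_base <- spec[[g]]$tau_base * 4
    spec[[g]]$tau_amp <- spec[[g]]$tau_amp * 4
    spec[[g]]$V_half <- spec[[g]]$V_half + 12
  }
  spec
}

simulate_clean_sweep <- function(spec, proto, Temp, dt, params) {
  grid <- seq(0, proto$duration - dt, by = dt)
  sim <- simulate_sweep(proto, archetype_gating_functions(spec), params, Temp,
                        grid = grid)
  sim
}

#' Simulate all recordings of one cell
#'
#' Simulates every sweep of the four protocols at the cell's temperature with
#' uniform \code{dt} sampling, then applies the observation model: per-cell
#' amplitude scale, per-sweep baseline offset, Gaussian noise, negative
#' spike artifacts at voltage steps, and (for the non-activation protocols)
#' occasional kinetically inconsistent sweep replacements. Draws come from
#' the current RNG stream; artifact ground truth is returned alongside.
#'
#' @param cell_spec output of \code{\link{sample_cell}}
#' @param cell_id cell identifier
#' @param Temp recording temperature, degrees C
#' @param config a \code{\link{population_config}}
#' @param amp per-cell amplitude scale (0 gives a dead cell)
#' @param params an \code{hh_params}
#' @return list(sweeps, artifacts) where artifacts is a data.frame of
#'   injected-defect labels
#' @export
simulate_cell <- function(cell_spec, cell_id, Temp, config = population_config(),
                          amp = 1, params = hh_params()) {
  sweeps <- list()
  artifacts <- list()
  add_artifact <- function(protocol, sweep_index, type) {
    artifacts[[length(artifacts) + 1L]] <<- data.frame(
      cell_id = cell_id, protocol = protocol, sweep_index = sweep_index, type = type)
  }
  dt <- config$dt
  # reference peak for inconsistency-injection eligibility: a kinetic
  # distortion of a sweep carrying no measurable current is unobservable
  ref_peak <- if (amp > 0) {
    a80 <- build_protocol("activation")[[18L]]
    max(simulate_clean_sweep(cell_spec, a80, Temp, dt, params)$current)
  } else 0
  for (p in PROTOCOL_NAMES) {
    protos <- build_protocol(p, overrides = list(recovery_test_ms = config$recovery_test_ms))
    reps <- if (p == "activation") c(1L, 2L) else 1L
    for (proto in protos) {
      times <- seq(0, proto$duration - dt, by = dt)
      clean <- if (amp > 0) simulate_clean_sweep(cell_spec, proto, Temp, dt, params)$current
               else rep(0, length(times))
      # eligibility for inconsistency injection mirrors the QC comparison
      # windows: a kinetic distortion is only a detectable (and meaningful)
      # inconsistency when the sweep carries measurable current there
      cmp_win <- if (p == "deactivation") times >= 100 & times < 400
                 else times >= 100 & times < 600
      eligible <- p != "activation" && amp > 0 &&
        max(clean[cmp_win]) >= 0.25 * ref_peak
      inconsistent <- eligible && stats::runif(1) < config$p_inconsistent
      if (inconsistent) {
        distorted <- simulate_clean_sweep(distorted_spec(cell_spec), proto, Temp, dt, params)$current
        if (max(distorted[cmp_win]) >= 0.25 * ref_peak) {
          clean <- distorted
          add_artifact(p, proto$sweep_index, "inconsistent")
        }
      }
      for (rep_i in reps) {
        rundown <- if (p == "activation" && rep_i == 1L) 1.07 else 1
        cur <- amp * rundown * clean +
          stats::rnorm(1, 0, config$baseline_offset_sd) +
          stats::rnorm(length(times), 0, config$sigma_obs)
        # negative deflection artifacts at interior voltage steps
        steps <- proto$segments$t_start[-1L]
        for (ts in steps) {
          if (stats::runif(1) < config$p_spike) {
            A <- stats::runif(1, 0.1, 0.4) * max(amp, 1)
            sel <- which(times >= ts & times < ts + 1.5)
            cur[sel] <- cur[sel] - A * exp(-(times[sel] - ts) / 0.3)
            if (rep_i == max(reps)) add_artifact(p, proto$sweep_index, "spike")
          }
        }
        sweeps[[length(sweeps) + 1L]] <- list(
          protocol = p, sweep_index = proto$sweep_index, repetition = rep_i,
          times = times, current = cur)
      }
    }
  }
  list(sweeps = sweeps,
       artifacts = if (length(artifacts)) do.call(rbind, artifacts) else
         data.frame(cell_id = character(), protocol = character(),
                    sweep_index = integer(), type = character()))
}

truth_row <- function(cell_id, channel_type, Temp, spec, amp, dead) {
  g <- function(gg, f) spec[[gg]][[f]]
  data.frame(
    cell_id = cell_id, channel_type = channel_type, temperature_C = Temp,
    archetype = spec$id, amp = amp, dead = dead,
    V_half1 = g("g1", "V_half"), k1 = g("g1", "k"),
    tau_base1 = g("g1", "tau_base"), tau_amp1 = g("g1", "tau_amp"),
    V_peak1 = g("g1", "V_peak"), w1 = g("g1", "w"), Q10_1 = g("g1", "Q10"),
    V_half2 = g("g2", "V_half"), k2 = g("g2", "k"),
    tau_base2 = g("g2", "tau_base"), tau_amp2 = g("g2", "tau_amp"),
    V_peak2 = g("g2", "V_peak"), w2 = g("g2", "w"), Q10_2 = g("g2", "Q10")
  )
}

#' Generate a full synthetic population
#'
#' Builds the archetypes, samples cells for every archetype x temperature
#' stratum, simulates all protocols per cell, and returns a raw
#' \code{sweep_dataset} with ground truth (cell parameters and injected
#' artifact labels). Fully deterministic given the config (which includes
#' the seed).
#'
#' @param config a \code{\link{population_config}}
#' @return a \code{sweep_dataset} with a \code{truth} component
#' @export
simulate_population <- function(config = population_config()) {
  with_preserved_rng(config$seed, {
    archetypes <- make_archetypes(config$n_archetypes, seed = config$seed + 1L)
    cells <- list()
    truth_cells <- list()
    truth_artifacts <- list()
    for (a in seq_along(archetypes)) {
      for (Temp in config$temperatures) {
        for (j in seq_len(config$cells_per_archetype_per_temp)) {
          cid <- sprintf("A%d_T%02d_c%d", a, round(Temp), j)
          ctype <- sprintf("A%d", a)
          spec <- sample_cell(archetypes[[a]], config)
          amp <- stats::rlnorm(1, config$amp_meanlog, config$amp_sdlog)
          sim <- simulate_cell(spec, cid, Temp, config, amp = amp)
          cells[[cid]] <- list(cell_id = cid, channel_type = ctype,
                               temperature = Temp, sweeps = sim$sweeps)
          truth_cells[[cid]] <- truth_row(cid, ctype, Temp, spec, amp, FALSE)
          truth_artifacts[[cid]] <- sim$artifacts
        }
      }
    }
    if (config$n_dead_cells > 0L) {
      for (j in seq_len(config$n_dead_cells)) {
        cid <- sprintf("DEAD_c%d", j)
        spec <- sample_cell(archetypes[[1L]], config)
        Temp <- config$temperatures[(j - 1L) %% length(config$temperatures) + 1L]
        sim <- simulate_cell(spec, cid, Temp, config, amp = 0)
        cells[[cid]] <- list(cell_id = cid, channel_type = "A1",
                             temperature = Temp, sweeps = sim$sweeps)
        truth_cells[[cid]] <- truth_row(cid, "A1", Temp, spec, 0, TRUE)
        truth_artifacts[[cid]] <- sim$artifacts
      }
    }
    truth <- list(
      archetypes = archetypes,
      cells = do.call(rbind, truth_cells),
      artifacts = do.call(rbind, truth_artifacts)
    )
    rownames(truth$cells) <- NULL
    rownames(truth$artifacts) <- NULL
    sweep_dataset(cells, truth = truth)
  })
}

#' Ground-truth gating functions of a synthetic cell
#'
#' @param truth_cells the \code{truth$cells} table of a synthetic dataset
#' @param cell_id cell identifier
#' @return a \code{gating_functions} object for the cell's true kinetics
#' @export
truth_gating_functions <- function(truth_cells, cell_id) {
  r <- truth_cells[truth_cells$cell_id == cell_id, , drop = FALSE]
  if (nrow(r) != 1L) stop("cell not found in ground truth: ", cell_id, call. = FALSE)
  spec <- list(
    g1 = list(V_half = r$V_half1, k = r$k1, tau_base = r$tau_base1,
              tau_amp = r$tau_amp1, V_peak = r$V_peak1, w = r$w1, Q10 = r$Q10_1),
    g2 = list(V_half = r$V_half2, k = r$k2, tau_base = r$tau_base2,
              tau_amp = r$tau_amp2, V_peak = r$V_peak2, w = r$w2, Q10 = r$Q10_2)
  )
  archetype_gating_functions(spec)
}
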