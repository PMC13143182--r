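# Shared fixtures, built in code. Heavy objects are cached per test run.

tiny_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(population_config(
        n_archetypes = 2, cells_per_archetype_per_temp = 1,
        temperatures = c(15, 35), seed = 5,
        p_spike = 0, p_inconsistent = 0))
    }
    cache
  }
})

qc_population <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_population(population_config(
        n_archetypes = 2, cells_per_archetype_per_temp = 3,
        n_dead_cells = 2, seed = 42))
    }
    cache
  }
})

# a clean, downsampled fit-ready dataset of 4 cells (2 archetypes x 2 temps)
tiny_fit_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pp <- run_pipeline(tiny_population())
      cache <<- prepare_fit_data(pp$dataset)
    }
    cache
  }
})

# simple two-gate parametric kinetics for structural-model tests
toy_gating_functions <- function() {
  gating_functions(
    m_inf = list(function(V, Temp) boltzmann(V, -30, 9),
                 function(V, Temp) boltzmann(V, -45, -8)),
    tau = list(function(V, Temp) bell_tau(V, Temp, 2, 10, -25, 35, 3),
               function(V, Temp) bell_tau(V, Temp, 30, 150, -40, 40, 2))
  )
}

# cells for the linear-Gaussian toy model: y_m = eta + noise
make_linear_cells <- function(n_cells, m_obs, omega2, sigma, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      eta <- rnorm(1, 0, sqrt(omega2))
      list(y = eta + rnorm(m_obs, 0, sigma), eta_true = eta)
    })
  })
}
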