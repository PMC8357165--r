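# shared fixtures: default parameter set, small grids, and a memoised cache
# of short simulations reused across test files (simulations are seconds of
# wall time each; recomputing per test would dominate the suite)

default_params <- nft_params()
default_grid <- grid_spec()

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

sham_30s <- function(seed = 1) {
  cached_sim(paste0("sham30_", seed),
             simulate_nft(default_params, default_grid, stim_protocol("sham"),
                          duration = 30, seed = seed))
}

sham_60s <- function(seed = 2) {
  cached_sim(paste0("sham60_", seed),
             simulate_nft(default_params, default_grid, stim_protocol("sham"),
                          duration = 60, seed = seed))
}

# sine-referenced true phase (degrees) of a unit sinusoid at frequency f
true_phase_deg <- function(t, f) (360 * f * t) %% 360

# causal pre-onset phase: least-squares projection of the two preceding
# cycles onto a sinusoid at f0, evaluated at the onset; used to assess
# phase-locking without contamination from the evoked response
preonset_phase <- function(x, rate, t_on, f0 = 0.85, n_cycles = 2) {
  i1 <- round((t_on - n_cycles / f0) * rate) + 1
  i2 <- round(t_on * rate) + 1
  if (i1 < 1 || i2 > length(x)) return(NA_real_)
  tt <- (i1:i2 - 1) / rate
  cf <- qr.solve(cbind(1, sin(2 * pi * f0 * tt), cos(2 * pi * f0 * tt)),
                 x[i1:i2])
  (atan2(cf[3], cf[2]) * 180 / pi + 360 * f0 * t_on) %% 360
}
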