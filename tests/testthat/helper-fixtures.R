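# Shared fixtures, built once per test run. Expensive simulations are cached
# in this environment so several test files (and several expectations within
# the acceptance suite) can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# small random LJ+charge gas used for energy-oracle comparisons
random_site_system <- function(n = 50, seed = 1, L = 2.5, charged = TRUE) {
  with_seed(seed, {
    sites <- data.frame(
      x = runif(n, 0, L), y = runif(n, 0, L), z = runif(n, 0, L),
      label = "X", charge = if (charged) sample(c(-0.2, 0.2), n, TRUE) else 0,
      sigma = runif(n, 0.25, 0.35), epsilon = runif(n, 0.2, 0.8),
      mass = runif(n, 10, 40), molecule_id = seq_len(n), role = "host",
      hb_role = "", stringsAsFactors = FALSE)
    # push apart any hard overlaps so energies stay finite
    st <- system_state(simulation_box(rep(L, 3)), sites)
    st
  })
}

# short liquid-water trajectory at a cutoff the 64-molecule box allows
mini_water_run <- function() {
  cached("mini_water", simulate_bulk_water(n = 64, equil_ps = 4, prod_ps = 6,
                                           dt = 0.002, frame_ps = 0.25,
                                           cutoff = 0.6, seed = 7))
}

# full-scale bulk-water run shared by the acceptance expectations
acceptance_bulk_run <- function() {
  cached("acceptance_bulk", simulate_bulk_water(equil_ps = 12, seed = 101))
}

# small relaxed surrogate host shared across sorption tests
relaxed_host <- function() {
  cached("relaxed_host", {
    st <- grow_chains(build_recipe(3, 8, 1.2, seed = 1))
    st <- relax_host(st, duration = 30, T = 300, seed = 5)
    attr(st, "traces") <- NULL
    attr(st, "frames") <- NULL
    st
  })
}
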