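# Shared in-code fixtures: everything is generated, nothing read from disk.

tiny_env <- function(n_layers = 3L, shape = c(20L, 20L), seed = 5L,
                     corr_length_km = 4, inter_layer_corr = 0.2,
                     cell_size_km = 1) {
  generate_env_stack(n_layers, shape, corr_length_km = corr_length_km,
                     inter_layer_corr = inter_layer_corr,
                     cell_size_km = cell_size_km, seed = seed)
}

# a fast model-settings list for randomization tests in the suite
fast_settings <- function(...) {
  model_settings(max_iter = 150L, tol = 1e-5, ...)
}

# random probability surface of length n (exponential weights, normalized)
random_surface <- function(n, sparse = FALSE) {
  w <- stats::rexp(n)
  if (sparse) w[sample.int(n, floor(n / 2))] <- 0
  if (sum(w) == 0) w[1] <- 1
  w / sum(w)
}

# closed-form area of the lens of two radius-r circles d apart
lens_area <- function(d, r) {
  2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
}

# the synthetic demo configuration: one full-study run at report scale,
# shared (memoized) across test files
demo_config <- function(seed = 101L) {
  run_config(
    seed = seed,
    env = list(n_layers = 4L, shape = c(25L, 25L)),
    clade = list(n_points_per_tip = 25L, posterior_trees = 20L),
    tests = list(identity_reps = 50L, background_reps = 50L,
                 qvi_rand = 99L, qvi_trees = 20L, k_rand = 199L,
                 arc_sims = 200L))
}

.demo_cache <- new.env(parent = emptyenv())
demo_run <- function() {
  if (is.null(.demo_cache$res)) .demo_cache$res <- run_study(demo_config())
  .demo_cache$res
}
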