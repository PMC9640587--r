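# Shared fixtures, built once per test run and cached in this environment.
.fx <- new.env(parent = emptyenv())

fx_arena <- function() arena_spec()

# A short balanced session with a mixed population, reused by several
# unit-test files.
fx_session <- function() {
  if (is.null(.fx$session)) {
    arena <- fx_arena()
    pop <- neuron_population(arena, n_stable = 10, n_untuned = 4, seed = 101)
    traj <- simulate_trajectory(
      arena, sim_config(duration_s = 300, occupancy_bias = 0.2, seed = 102)
    )
    act <- binarize_events(simulate_events(pop, traj, "bsl", seed = 103))
    .fx$session <- list(arena = arena, pop = pop, traj = traj, act = act,
                        frames = speed_filter(traj))
  }
  .fx$session
}

# A miniature full experiment for pipeline smoke tests.
fx_experiment <- function() {
  if (is.null(.fx$experiment)) {
    arena <- fx_arena()
    pop <- neuron_population(
      arena, n_stable = 14, n_disappear = 6, n_appear = 0, n_untuned = 6,
      disappear_comp = "left", seed = 201
    )
    .fx$experiment <- simulate_experiment(
      arena, pop, duration_s = 240, preferred = "left", seed = 202
    )
  }
  .fx$experiment
}

# Direct single-formula evaluation of the information score, independent
# of the package's implementation (explicit per-bin loop).
oracle_spatial_information <- function(p, lambda_i) {
  lam <- 0
  for (i in seq_along(p)) lam <- lam + p[i] * lambda_i[i]
  s <- 0
  for (i in seq_along(p)) {
    if (lambda_i[i] > 0 && p[i] > 0) {
      s <- s + p[i] * (lambda_i[i] / lam) * log2(lambda_i[i] / lam)
    }
  }
  s
}

# Brute-force naive Bayes posterior in probability space.
oracle_decode <- function(prior, theta, x) {
  post <- numeric(length(prior))
  for (y in seq_along(prior)) {
    p <- prior[y]
    for (i in seq_along(x)) p <- p * theta[y, i]^x[i]
    post[y] <- p
  }
  which.max(post)
}

# Cluster-agreement (adjusted Rand) between two labelings, via mclust.
agreement <- function(a, b) mclust::adjustedRandIndex(a, b)
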