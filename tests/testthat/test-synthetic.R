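test_that("zero-duration trajectories are empty and invalid configs rejected", {
  arena <- fx_arena()
  traj <- simulate_trajectory(arena, sim_config(duration_s = 0))
  expect_equal(nrow(traj), 0)
  expect_named(traj, c("t", "x", "y", "speed", "hd", "compartment"))
  expect_error(sim_config(frame_rate = 0), "frame_rate")
  expect_error(sim_config(occupancy_bias = 1.5))
})

test_that("trajectories stay inside the arena and obey the speed cap", {
  arena <- fx_arena()
  for (s in 1:3) {
    cfg <- sim_config(duration_s = 60, occupancy_bias = 0.3,
                      bias_compartment = "right", seed = s)
    traj <- simulate_trajectory(arena, cfg)
    expect_true(all(traj$x >= 0 & traj$x <= arena$width))
    expect_true(all(traj$y >= 0 & traj$y <= arena$height))
    step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
    expect_lte(max(step), cfg$max_speed / cfg$frame_rate + 1e-9)
    expect_true(all(traj$speed >= 0))
  }
})

test_that("midline crossings only happen through the door", {
  arena <- fx_arena()
  traj <- simulate_trajectory(arena, sim_config(duration_s = 600, seed = 7))
  cross <- which(diff(traj$x < arena$midline) != 0)
  expect_gt(length(cross), 3)  # compartments mix
  y_at_cross <- (traj$y[cross] + traj$y[cross + 1]) / 2
  # allow one step of slack around the door edges
  slack <- max(traj$speed) / 30
  expect_true(all(y_at_cross >= arena$door[1] - slack &
                  y_at_cross <= arena$door[2] + slack))
})

test_that("unbiased occupancy is balanced across seeds and bias shifts it", {
  arena <- fx_arena()
  fr <- vapply(1:20, function(s) {
    traj <- simulate_trajectory(arena,
                                sim_config(duration_s = 1200, seed = s))
    mean(traj$compartment == "left")
  }, numeric(1))
  # Monte-Carlo error over ~40 independent visits per seed, 20 seeds
  expect_lt(abs(mean(fr) - 0.5), 0.06)
  biased <- vapply(1:6, function(s) {
    traj <- simulate_trajectory(
      arena, sim_config(duration_s = 900, occupancy_bias = 0.3,
                        bias_compartment = "right", seed = s)
    )
    mean(traj$compartment == "right")
  }, numeric(1))
  expect_gt(mean(biased), mean(fr) + 0.1)
})

test_that("baseline trajectories cover most spatial bins", {
  arena <- fx_arena()
  traj <- simulate_trajectory(arena, sim_config(duration_s = 900, seed = 11))
  expect_gt(spatial_coverage(traj, arena), 0.9)
})

test_that("generators are deterministic under a fixed seed", {
  arena <- fx_arena()
  cfg <- sim_config(duration_s = 30, seed = 5)
  expect_identical(simulate_trajectory(arena, cfg),
                   simulate_trajectory(arena, cfg))
  pop <- neuron_population(arena, n_stable = 4, n_untuned = 1, seed = 9)
  expect_identical(pop, neuron_population(arena, n_stable = 4,
                                          n_untuned = 1, seed = 9))
  e1 <- simulate_experiment(arena, pop, duration_s = 20, seed = 3)
  e2 <- simulate_experiment(arena, pop, duration_s = 20, seed = 3)
  expect_identical(e1$sessions$bsl$activity$amplitudes,
                   e2$sessions$bsl$activity$amplitudes)
  expect_identical(e1$sessions$test2$traj, e2$sessions$test2$traj)
})

test_that("event simulation honours tuning, labels and alignment", {
  arena <- fx_arena()
  traj <- simulate_trajectory(arena, sim_config(duration_s = 120, seed = 21))
  pop <- neuron_population(arena, n_stable = 2, n_disappear = 1,
                           n_untuned = 0, disappear_comp = "left",
                           baseline_p = 0, seed = 22)
  pop$peak_left[1] <- 0
  pop$peak_right[1] <- 0
  act <- simulate_events(pop, traj, "bsl", seed = 23)
  expect_equal(sum(act$events[1, ]), 0)  # zero peak, zero baseline
  expect_true(all(act$amplitudes >= 0))
  expect_equal(ncol(act$amplitudes), nrow(traj))
  expect_error(simulate_events(pop, traj, "sleep"), "unknown session")
  # disappear neurons lose their in-compartment tuning only at test
  dis <- which(pop$effect == "disappear")
  p_bsl <- cppmap:::event_probability(pop[dis, ], traj, "bsl")
  p_tst <- cppmap:::event_probability(pop[dis, ], traj, "test1")
  left <- traj$compartment == "left"
  expect_true(all(p_tst[left] <= pop$baseline_p[dis] + 1e-12))
  expect_true(any(p_bsl[left] > pop$baseline_p[dis]))
  expect_equal(p_bsl[!left], p_tst[!left])
})

test_that("planted in-field event rates are recovered by simulation", {
  arena <- fx_arena()
  traj <- simulate_trajectory(arena, sim_config(duration_s = 900, seed = 31))
  pop <- neuron_population(arena, n_stable = 1, n_untuned = 0,
                           baseline_p = 0, seed = 32)
  pop$cx_left <- 12; pop$cy_left <- 12
  pop$cx_right <- 37; pop$cy_right <- 12
  pop$peak_left <- 0.1; pop$peak_right <- 0.1; pop$field_sd <- 5
  act <- simulate_events(pop, traj, "bsl", seed = 33)
  p_true <- cppmap:::event_probability(pop[1, ], traj, "bsl")
  infield <- p_true > 0.1 * exp(-0.5)  # within one field width
  expect_gt(sum(infield), 1000)
  observed <- mean(act$events[1, infield])
  expect_lt(abs(observed - mean(p_true[infield])) / mean(p_true[infield]),
            0.15)
})

test_that("population spec rejects impossible label counts gracefully", {
  arena <- fx_arena()
  expect_error(neuron_population(arena, n_stable = 0, n_untuned = 0,
                                 n_disappear = 0))
  pop <- neuron_population(arena, n_stable = 3, n_disappear = 2,
                           n_untuned = 1, seed = 1)
  counts <- table(pop$effect)
  expect_equal(unname(c(counts["stable"], counts["disappear"],
                        counts["untuned"])), c(3L, 2L, 1L))
})
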