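test_that("spatial information matches closed forms and the formula oracle", {
  # uniform firing carries no spatial information
  expect_equal(spatial_information(rep(0.25, 4), rep(2, 4)), 0)
  # all events in one of four equally occupied bins: log2(4) bits
  expect_equal(spatial_information(rep(0.25, 4), c(4, 0, 0, 0)), 2)
  expect_equal(spatial_information(c(0.2, 0.3, 0.5), c(5, 1, 0)),
               oracle_spatial_information(c(0.2, 0.3, 0.5), c(5, 1, 0)),
               tolerance = 1e-12)
  # 100 random small maps against the independent single-formula script
  set.seed(42)
  for (k in 1:100) {
    nb <- sample(3:20, 1)
    p <- runif(nb); p <- p / sum(p)
    lam <- rexp(nb) * (runif(nb) < 0.8)
    if (sum(p * lam) == 0) next
    expect_equal(spatial_information(p, lam),
                 oracle_spatial_information(p, lam), tolerance = 1e-10)
  }
})

test_that("spatial information is non-negative and bounded by log2(bins)", {
  set.seed(7)
  for (k in 1:50) {
    nb <- sample(4:30, 1)
    p <- runif(nb); p <- p / sum(p)
    lam <- rexp(nb) * (runif(nb) < 0.5)
    si <- spatial_information(p, lam)
    if (is.na(si)) next
    expect_gte(si, -1e-12)
    # sharp upper bound: all events concentrated in the rarest active bin
    expect_lte(si, log2(1 / min(p[lam > 0])) + 1e-12)
    # log2(bins) bounds it under uniform occupancy
    si_u <- spatial_information(rep(1 / nb, nb), lam)
    if (!is.na(si_u)) expect_lte(si_u, log2(nb) + 1e-12)
  }
})

test_that("a zero shift reproduces the unshuffled score and thresholds flag tuning", {
  s <- fx_session()
  tuned <- which(s$pop$effect == "stable")[1:3]
  flat <- which(s$pop$effect == "untuned")
  for (n in tuned) {
    st <- shuffle_threshold(s$act$events[n, ], s$traj, s$arena,
                            n = 200, seed = n)
    # shift of zero equals the plain map computation
    m <- compute_maps(s$traj, s$act, s$arena, neuron = n,
                      frames = speed_filter(s$traj))
    expect_equal(st$si, spatial_information(m), tolerance = 1e-12)
    expect_gt(st$si, st$threshold)  # planted field detected
  }
  # a neuron with fewer than two events has no defined threshold
  ev1 <- rep(0, nrow(s$traj)); ev1[100] <- 1
  st1 <- shuffle_threshold(ev1, s$traj, s$arena, n = 50, seed = 1)
  expect_true(is.na(st1$threshold))
})

test_that("shuffle test type-I error is near the nominal 5%", {
  arena <- fx_arena()
  traj <- simulate_trajectory(arena, sim_config(duration_s = 300, seed = 55))
  frames <- speed_filter(traj)
  set.seed(56)
  n_neurons <- 150
  hits <- vapply(seq_len(n_neurons), function(i) {
    ev <- as.numeric(runif(nrow(traj)) < 0.008)  # spatially random
    st <- shuffle_threshold(ev, traj, arena, frames = frames, n = 300,
                            seed = 1000 + i)
    st$si > st$threshold
  }, logical(1))
  ci <- binom.test(sum(hits), n_neurons, 0.05)$conf.int
  expect_lt(ci[1], 0.05)   # 5% inside the 95% CI
  expect_gt(ci[2], 0.05)
})

test_that("PCI classification recovers planted tuning per compartment", {
  s <- fx_session()
  pc <- classify_place_cells(s$traj, s$act, s$arena, n_iter = 10,
                             n_shuffles = 300, seed = 77)
  expect_equal(nrow(pc), 2 * nrow(s$pop))
  expect_true(all(pc$pci >= 0 & pc$pci <= 1, na.rm = TRUE))
  # decision rule: PCI >= 0.3 and mean rate >= 0.1 Hz
  expect_equal(pc$is_place_cell,
               !pc$excluded_low_rate & !is.na(pc$pci) & pc$pci >= 0.3)
  per_neuron <- tapply(pc$is_place_cell, pc$neuron, any)
  tuned <- s$pop$effect == "stable"
  expect_gt(mean(per_neuron[tuned]), 0.7)
  expect_lt(mean(per_neuron[!tuned]), 0.5)
})

test_that("field size matches the analytic half-max ellipse of a Gaussian", {
  # fine 1 cm bins; sigma 6 and 4 cm
  sx <- 6; sy <- 4
  xs <- seq(0.5, 49.5, 1); ys <- seq(0.5, 49.5, 1)
  m <- outer(ys, xs, function(y, x) {
    exp(-((x - 25)^2 / (2 * sx^2) + (y - 25)^2 / (2 * sy^2)))
  })
  fs <- field_size(m, bin_cm = 1)
  analytic <- pi * 2 * log(2) * sx * sy
  expect_equal(fs$field_size_cm2, analytic, tolerance = 0.1)
  expect_equal(fs$n_fields, 1L)
  # flat zero map has no field
  expect_true(is.na(field_size(matrix(0, 5, 5))$field_size_cm2))
  # uniform positive map: a single component spanning everything
  fu <- field_size(matrix(1, 4, 6), bin_cm = 1.8)
  expect_equal(fu$n_fields, 1L)
  expect_equal(fu$field_size_cm2, 24 * 1.8^2)
  # two unequal peaks: area of the larger component is returned
  two <- matrix(0, 9, 21)
  two[3:5, 3:5] <- 1      # 9 bins
  two[3:6, 15:18] <- 0.9  # 16 bins above half-max of 1
  ft <- field_size(two, bin_cm = 1)
  expect_equal(ft$n_fields, 2L)
  expect_equal(ft$field_size_cm2, 16)
})

test_that("connected components use 8-connectivity", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE  # touch diagonally
  lab <- cppmap:::label_components(m)
  expect_equal(max(lab), 1L)
})

test_that("map metrics reproduce correlation and peak-change identities", {
  s <- fx_session()
  frames <- s$frames
  m1 <- compute_maps(s$traj, s$act, s$arena, neuron = 1, frames = frames)
  m2 <- compute_maps(s$traj, s$act, s$arena, neuron = 2, frames = frames)
  self <- map_metrics(m1, m1)
  expect_equal(self$correlation, 1)
  expect_equal(self$peak_rate_change, 0)
  # peak change arithmetic: peaks 4 and 2 give 0.5
  ma <- m1; ma$peak_rate <- 4
  mb <- m1; mb$peak_rate <- 2
  expect_equal(map_metrics(ma, mb)$peak_rate_change, 0.5)
  # cross-map correlation equals a flat-vector Pearson oracle
  cross <- map_metrics(m1, m2)
  common <- m1$included & m2$included
  expect_equal(cross$correlation,
               cor(m1$rate_smooth[common], m2$rate_smooth[common]),
               tolerance = 1e-12)
})
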