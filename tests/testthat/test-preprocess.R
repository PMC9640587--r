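test_that("binarization thresholds at k times the population SD", {
  # all-zero trace stays silent
  z <- matrix(0, 1, 100)
  expect_equal(sum(binarize_events(z)$events), 0)
  # 999 zeros plus one sample of 10: population SD ~ 0.316, threshold
  # ~ 0.949, exactly one supra-threshold frame
  tr <- matrix(c(rep(0, 999), 10), 1, 1000)
  b <- binarize_events(tr)
  sd_pop <- sqrt(mean(tr^2) - mean(tr)^2)
  expect_equal(sd_pop, 0.31607, tolerance = 1e-4)
  expect_equal(sum(b$events), 1)
  expect_equal(which(b$events[1, ] == 1), 1000)
})

test_that("binarization is invariant to positive rescaling", {
  set.seed(4)
  amp <- matrix(rexp(500) * (runif(500) < 0.1), 2, 250)
  b1 <- binarize_events(amp)
  b2 <- binarize_events(amp * 7.3)
  expect_identical(b1$events, b2$events)
})

test_that("constant non-zero traces are flagged degenerate and excluded", {
  amp <- rbind(rep(2, 50), c(rep(0, 49), 5))
  b <- binarize_events(amp)
  expect_true(b$degenerate[1])
  expect_false(b$degenerate[2])
  expect_equal(sum(b$events[1, ]), 0)
})

test_that("speed filter keeps exactly the frames at or above threshold", {
  traj <- tibble::tibble(t = (0:9) / 30, speed = c(5, 1, 3, 0, 2, 2, 1.9,
                                                   8, 0.5, 2.1))
  expect_equal(speed_filter(traj), which(traj$speed >= 2))
  traj_slow <- tibble::tibble(t = (0:4) / 30, speed = rep(1, 5))
  expect_error(speed_filter(traj_slow), "removed every frame")
  traj_fast <- tibble::tibble(t = (0:4) / 30, speed = rep(5, 5))
  expect_equal(speed_filter(traj_fast), 1:5)
})

test_that("rate maps follow the occupancy-normalized event rate", {
  arena <- fx_arena()
  # park the animal in one bin for 2 s with a single event
  n <- 60
  traj <- tibble::tibble(
    t = (seq_len(n) - 1) / 30,
    x = rep(10.0, n), y = rep(10.0, n),
    speed = rep(5, n), hd = rep(0, n),
    compartment = rep("left", n)
  )
  ev <- c(1, rep(0, n - 1))
  m <- compute_maps(traj, ev, arena)
  expect_equal(max(m$rate), 0.5)  # 1 event / 2 s
  expect_equal(sum(m$rate > 0), 1)
  expect_equal(m$mean_rate, 0.5)
})

test_that("mean rate equals the occupancy-weighted sum of bin rates", {
  s <- fx_session()
  for (neuron in c(1, 3, 5)) {
    m <- compute_maps(s$traj, s$act, s$arena, neuron = neuron,
                      frames = s$frames)
    expect_equal(m$mean_rate,
                 sum(m$p_occ[m$included] * m$rate[m$included]),
                 tolerance = 1e-12)
    expect_true(all(m$rate >= 0))
  }
})

test_that("events proportional to occupancy give a flat rate map", {
  arena <- fx_arena()
  s <- fx_session()
  # fire on every frame: rate = frame rate everywhere visited
  ev <- rep(1, nrow(s$traj))
  m <- compute_maps(s$traj, ev, arena, frames = s$frames)
  rates <- m$rate[m$included]
  expect_equal(max(abs(rates - 30)), 0, tolerance = 1e-9)
})

test_that("Gaussian smoothing matches a direct convolution oracle", {
  set.seed(8)
  m <- matrix(rexp(14 * 28), 14, 28)
  sm <- cppmap:::gaussian_smooth(m, 2)
  # direct renormalized convolution
  half <- 8
  k1 <- exp(-(-half:half)^2 / 8)
  direct <- matrix(0, 14, 28)
  for (i in 1:14) for (j in 1:28) {
    acc <- 0; wacc <- 0
    for (di in -half:half) for (dj in -half:half) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 14 && jj >= 1 && jj <= 28) {
        w <- k1[di + half + 1] * k1[dj + half + 1]
        acc <- acc + w * m[ii, jj]; wacc <- wacc + w
      }
    }
    direct[i, j] <- acc / wacc
  }
  expect_equal(sm, direct, tolerance = 1e-12)
  # boundary renormalization approximately preserves total mass
  expect_equal(sum(sm), sum(m), tolerance = 0.03 * sum(m))
  # the batched operator path agrees with the direct path
  grid <- cppmap:::bin_grid(fx_arena(), 1.8)
  S <- cppmap:::smoothing_operator(grid, 2)
  v <- as.vector(t(m))  # vectorized in bin-id order (x fastest)
  sm_op <- matrix(as.vector(S %*% v), nrow = 14, byrow = TRUE)
  expect_equal(sm_op, sm, tolerance = 1e-12)
})

test_that("occupancy matching retains the per-bin minimum on both sides", {
  bins_a <- c(rep(1L, 10), rep(2L, 4), rep(3L, 2))
  bins_b <- c(rep(1L, 4), rep(2L, 9), rep(4L, 5))
  ms <- match_occupancy(bins_a, bins_b, n_iter = 5, seed = 1)
  for (it in seq_along(ms)) {
    ka <- tabulate(bins_a[ms[[it]]$a], 4)
    kb <- tabulate(bins_b[ms[[it]]$b], 4)
    expect_equal(ka, pmin(tabulate(bins_a, 4), tabulate(bins_b, 4)))
    expect_equal(ka, kb)
    expect_true(all(ms[[it]]$a %in% seq_along(bins_a)))
  }
  # identical occupancy: nothing removed
  same <- match_occupancy(bins_a, bins_a, n_iter = 2, seed = 2)
  expect_equal(same[[1]]$a, seq_along(bins_a))
  expect_equal(same[[1]]$b, seq_along(bins_a))
})

test_that("averaging over matching iterations stabilizes map metrics", {
  s <- fx_session()
  # SD across replicate seeds of a 20-iteration average must be smaller
  # than across single-iteration estimates
  one_iter <- vapply(1:6, function(sd_) {
    intercompartment_metrics(s$traj, s$act, s$arena, frames = s$frames,
                             neurons = 1, n_iter = 1,
                             seed = sd_)$correlation
  }, numeric(1))
  many_iter <- vapply(1:6, function(sd_) {
    intercompartment_metrics(s$traj, s$act, s$arena, frames = s$frames,
                             neurons = 1, n_iter = 20,
                             seed = 100 + sd_)$correlation
  }, numeric(1))
  expect_lt(sd(many_iter), sd(one_iter))
})

test_that("spatial coverage counts visited bins", {
  arena <- fx_arena()
  grid <- cppmap:::bin_grid(arena, 1.8)
  still <- tibble::tibble(t = 0, x = 5, y = 5, speed = 0, hd = 0,
                          compartment = "left")
  expect_equal(spatial_coverage(still, arena), 1 / grid$nbins)
  centers <- cppmap:::bin_center(grid, seq_len(grid$nbins))
  full <- tibble::tibble(t = seq_len(grid$nbins) / 30,
                         x = centers[, 1], y = centers[, 2],
                         speed = 5, hd = 0, compartment = "left")
  expect_equal(spatial_coverage(full, arena), 1)
})
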