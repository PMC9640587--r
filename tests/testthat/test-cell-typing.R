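mk_traj <- function(comps, dt = 1 / 30) {
  tibble::tibble(
    t = (seq_along(comps) - 1) * dt,
    x = ifelse(comps == "left", 10, 40), y = 12,
    speed = 5, hd = 0, compartment = comps
  )
}

test_that("CPP score is the drug-paired time difference and antisymmetric", {
  bsl <- mk_traj(rep(c("left", "right"), times = c(300, 300)))
  tst <- mk_traj(rep(c("left", "right"), times = c(100, 500)))
  sc <- cpp_score(bsl, tst, drug_paired = "right")
  expect_equal(sc$cpp_score, (500 - 300) / 30)
  expect_equal(sc$baseline_drug_s + sc$baseline_other_s, 600 / 30)
  # equal times give zero
  expect_equal(cpp_score(bsl, bsl, drug_paired = "right")$cpp_score, 0)
  # swapping the drug-paired side flips the sign (equal session lengths)
  sc_l <- cpp_score(bsl, tst, drug_paired = "left")
  expect_equal(sc_l$cpp_score, -sc$cpp_score)
})

test_that("preferred compartment follows baseline majority with left ties", {
  expect_equal(preferred_compartment(mk_traj(rep("right", 10))), "right")
  expect_equal(preferred_compartment(
    mk_traj(rep(c("left", "right"), 5))), "left")  # exact tie -> left
})

flags_of <- function(bp, t1p, t2p, bn, t1n, t2n) {
  tibble::tibble(
    neuron = 1L,
    session = rep(c("bsl", "test1", "test2"), 2),
    compartment = rep(c("left", "right"), each = 3),
    is_place_cell = c(bp, t1p, t2p, bn, t1n, t2n)
  )
}

test_that("functional cell types follow the definition truth table", {
  # preferred = left throughout
  lab <- function(...) {
    assign_functional_types(flags_of(...), preferred = "left")
  }
  r <- lab(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  expect_true(r$disPCp); expect_false(r$rtPCp)
  expect_equal(r$label, "disPCp")
  # retained in one test session: rtPCp, not disPCp (mutually exclusive)
  r <- lab(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_true(r$rtPCp); expect_false(r$disPCp)
  expect_equal(r$label, "rtPCp")
  # tuned everywhere: rtPCp and never disPCp
  r <- lab(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  expect_true(r$rtPCp); expect_false(r$disPCp)
  # appeared place cells need both test sessions
  r <- lab(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_true(r$aPCp); expect_equal(r$label, "aPCp")
  r <- lab(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_false(r$aPCp); expect_equal(r$label, "other")
  # non-preferred versions mirror the preferred ones
  r <- lab(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE)
  expect_true(r$disPCnp); expect_equal(r$label, "disPCnp")
  r <- lab(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  expect_true(r$aPCnp)
})

test_that("type assignment is invariant to neuron order and flags missing data", {
  set.seed(3)
  flags <- tidyr::expand_grid(
    neuron = 1:12, session = c("bsl", "test1", "test2"),
    compartment = c("left", "right")
  )
  flags$is_place_cell <- runif(nrow(flags)) < 0.5
  t1 <- assign_functional_types(flags, "left")
  t2 <- assign_functional_types(flags[sample(nrow(flags)), ], "left")
  expect_equal(dplyr::arrange(t1, neuron), dplyr::arrange(t2, neuron))
  # missing sessions are skipped with NA label
  t3 <- assign_functional_types(
    flags[flags$session != "test2" | flags$neuron != 5, ], "left"
  )
  expect_true(is.na(t3$label[t3$neuron == 5]))
  expect_false(anyNA(t3$label[t3$neuron != 5]))
})

test_that("rate remapping splits strictly above the 0.4 correlation line", {
  expect_equal(classify_rate_remapping(c(0.41, 0.4, 1, -0.2, NA)),
               c("rate", "non-rate", "rate", "non-rate", NA))
})

test_that("turnover proportions are fractions of the tracked total", {
  flags <- tidyr::expand_grid(
    neuron = 1:100, session = c("bsl", "test1", "test2"),
    compartment = c("left", "right")
  )
  # plant 18 disPCp: tuned in left at bsl only
  flags$is_place_cell <- flags$neuron <= 18 & flags$session == "bsl" &
    flags$compartment == "left"
  types <- assign_functional_types(flags, "left")
  props <- turnover_proportions(types)
  expect_equal(props$fraction[props$type == "disPCp"], 0.18)
  expect_true(all(props$fraction >= 0 & props$fraction <= 1))
  expect_error(turnover_proportions(types[0, ]), "denominator")
})

test_that("CorrDiff is near zero for stable cells and antisymmetric", {
  s <- fx_session()
  stable <- which(s$pop$effect == "stable")[1:5]
  # identical baseline and test data: difference must vanish on average
  r <- corr_diff(s$traj, s$act, s$traj, s$act, s$arena, stable,
                 n_iter = 10, seed = 5)
  expect_lt(abs(r$corr_diff), 0.12)
  # swapping sessions flips the sign exactly: build sessions whose two
  # compartments have exactly homotopic occupancy, so occupancy matching
  # removes nothing and the correlations are deterministic
  arena <- s$arena
  mirror_session <- function(seed) {
    set.seed(seed)
    nf <- 1200
    xl <- runif(nf, 1, 24); yl <- runif(nf, 1, 24)
    traj <- tibble::tibble(
      t = (seq_len(2 * nf) - 1) / 30,
      x = c(xl, xl + 25), y = c(yl, yl),
      speed = 5, hd = 0,
      compartment = rep(c("left", "right"), each = nf)
    )
    ev <- matrix(as.integer(runif(3 * 2 * nf) < 0.05), 3, 2 * nf)
    list(traj = traj, ev = ev)
  }
  s1 <- mirror_session(11)
  s2 <- mirror_session(12)
  f <- corr_diff(s1$traj, s1$ev, s2$traj, s2$ev, arena, 1:3,
                 n_iter = 2, seed = 6)
  b <- corr_diff(s2$traj, s2$ev, s1$traj, s1$ev, arena, 1:3,
                 n_iter = 2, seed = 6)
  expect_equal(f$per_neuron$diff, -b$per_neuron$diff, tolerance = 1e-12)
  expect_equal(corr_diff(s$traj, s$act, s$traj, s$act, arena,
                         integer(0))$corr_diff, NA_real_)
})
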