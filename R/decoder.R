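#' Bin activity and position labels for decoding
#'
#' Sums binarized events over non-overlapping time bins of `dt` seconds
#' (speed-filtered frames, grouped sequentially; the remainder that does
#' not fill a bin is dropped) and labels each time bin with the spatial
#' bin of the mean position within the bin. The mean running speed per
#' time bin is kept for the continuity constraint.
#'
#' @param traj Trajectory tibble.
#' @param events `cpp_events` object or neurons x frames binary matrix.
#' @param arena An [arena_spec()].
#' @param frames Retained frame indices (default [speed_filter()]).
#' @param dt Time-bin width in seconds (default 0.8).
#' @param bin_cm Spatial bin pitch for the location vocabulary.
#' @return A list of class `cpp_binned`: `X` (M x N counts), `label`
#'   (M spatial-bin ids), `pos` (M x 2 true mean positions), `v` (M mean
#'   speeds), `dt`, `grid`.
#' @export
bin_activity <- function(traj, events, arena, frames = speed_filter(traj),
                         dt = 0.8, bin_cm = 1.8) {
  ev <- if (inherits(events, "cpp_events")) events$events else events
  fr <- 1 / diff(traj$t[1:2])
  fpb <- max(1L, round(dt * fr))
  M <- length(frames) %/% fpb
  if (M == 0) stop("not enough retained frames for a single time bin")
  used <- frames[seq_len(M * fpb)]
  grp <- rep(seq_len(M), each = fpb)
  X <- rowsum(t(ev[, used, drop = FALSE]), grp)
  px <- rowsum(traj$x[used], grp)[, 1] / fpb
  py <- rowsum(traj$y[used], grp)[, 1] / fpb
  v <- rowsum(traj$speed[used], grp)[, 1] / fpb
  grid <- bin_grid(arena, bin_cm)
  structure(
    list(
      X = unname(X), label = bin_of(grid, px, py),
      pos = cbind(x = px, y = py), v = v, dt = dt, grid = grid
    ),
    class = "cpp_binned"
  )
}

#' Train the multinomial naive Bayes position decoder
#'
#' Fits, per location, a multinomial ("bag of tokens") distribution over
#' neurons with Laplace smoothing: the parameter for neuron i at location
#' y is the (weighted) total count of events of neuron i in time bins at
#' y, plus one, divided by the total over all neurons plus N. The prior
#' over locations is empirical. With `use_prior_weighting = TRUE`
#' (default) the per-bin observation weights are normalized so that the
#' weights within each location sum to that location's prior probability
#' before counting.
#'
#' @param binned A [bin_activity()] object.
#' @param use_prior_weighting Apply the prior-normalized observation
#'   weighting (default `TRUE`).
#' @return A list of class `cpp_decoder`: `theta` (locations x neurons),
#'   `log_theta`, `prior`, `vocab` (location bin ids), `centers`
#'   (location bin centres, cm), `grid`.
#' @export
train_decoder <- function(binned, use_prior_weighting = TRUE) {
  stopifnot(inherits(binned, "cpp_binned"))
  lab <- binned$label
  vocab <- sort(unique(lab))
  M <- length(lab)
  N <- ncol(binned$X)
  my <- tabulate(match(lab, vocab), length(vocab))
  prior <- my / M
  counts <- rowsum(binned$X, match(lab, vocab))  # |Y| x N
  if (use_prior_weighting) {
    # Observation weights normalized so that the weights within each
    # location sum to that location's prior, rescaled to mean 1 over the
    # session so that the numerator stays the total spike count. Under
    # the empirical prior the per-location scale M * prior_y / M_y is
    # exactly 1; a non-empirical prior would reweight the counts.
    w <- M * prior / my
    counts <- counts * w
  }
  theta <- (counts + 1) / (rowSums(counts) + N)
  structure(
    list(
      theta = theta, log_theta = log(theta), prior = prior,
      vocab = vocab, centers = bin_center(binned$grid, vocab),
      grid = binned$grid, n_neurons = N
    ),
    class = "cpp_decoder"
  )
}

#' @export
print.cpp_decoder <- function(x, ...) {
  cat(sprintf("<cpp_decoder> %d locations x %d neurons\n",
              length(x$vocab), x$n_neurons))
  invisible(x)
}

# Log-posterior scores (M x |Y|) up to the shared normalizer.
decoder_scores <- function(model, X) {
  X %*% t(model$log_theta) +
    matrix(log(model$prior), nrow(X), length(model$prior), byrow = TRUE)
}

#' Decode position (single-step)
#'
#' Maximum a posteriori location per time bin, computed in log space.
#' Ties break toward the smallest location index.
#'
#' @param model A [train_decoder()] model.
#' @param X M x N event-count matrix (or a `cpp_binned` object).
#' @return A tibble with `bin` (decoded location id), `x`, `y` (decoded
#'   bin centres, cm).
#' @export
decode <- function(model, X) {
  if (inherits(X, "cpp_binned")) X <- X$X
  sc <- decoder_scores(model, X)
  pick <- max.col(sc, ties.method = "first")
  tibble::tibble(
    bin = model$vocab[pick],
    x = model$centers[pick, 1],
    y = model$centers[pick, 2]
  )
}

#' Decode position with the two-step continuity constraint
#'
#' Multiplies the single-step posterior by a 2D Gaussian centred on the
#' previously decoded position with SD `sigma_t = a * v_t` (floored at
#' `sigma_floor` so a stationary animal never freezes the trajectory)
#' before taking the argmax. The first bin, and any bin with a missing
#' speed, falls back to the single-step rule.
#'
#' @param model A [train_decoder()] model.
#' @param X M x N counts or a `cpp_binned` object (speeds are taken from
#'   it unless `v` is given).
#' @param v Mean speed per time bin (cm/s).
#' @param a Speed scaling of the constraint (default 2.5).
#' @param sigma_floor Minimum SD in cm (default: one bin width).
#' @return A tibble with `bin`, `x`, `y` as in [decode()].
#' @export
decode_2step <- function(model, X, v = NULL, a = 2.5, sigma_floor = NULL) {
  if (inherits(X, "cpp_binned")) {
    if (is.null(v)) v <- X$v
    X <- X$X
  }
  if (is.null(sigma_floor)) sigma_floor <- model$grid$bin_cm
  sc <- decoder_scores(model, X)
  M <- nrow(sc)
  pick <- integer(M)
  pick[1] <- which.max(sc[1, ])
  cx <- model$centers[, 1]
  cy <- model$centers[, 2]
  for (t in 2:max(M, 2)) {
    if (M < 2) break
    s <- sc[t, ]
    vt <- if (is.null(v)) NA_real_ else v[t]
    if (!is.na(vt)) {
      sig <- max(a * vt, sigma_floor)
      d2 <- (cx - cx[pick[t - 1]])^2 + (cy - cy[pick[t - 1]])^2
      s <- s - d2 / (2 * sig^2)
    }
    pick[t] <- which.max(s)
  }
  tibble::tibble(
    bin = model$vocab[pick],
    x = model$centers[pick, 1],
    y = model$centers[pick, 2]
  )
}

#' Mean Euclidean decoding error
#'
#' @param pred Decoded positions (tibble with `x`, `y` from [decode()] or
#'   a 2-column matrix).
#' @param truth True positions (2-column matrix or tibble/`cpp_binned`).
#' @return Mean Euclidean distance in cm across time bins.
#' @export
decoding_error <- function(pred, truth) {
  if (inherits(truth, "cpp_binned")) truth <- truth$pos
  px <- if (is.data.frame(pred)) pred$x else pred[, 1]
  py <- if (is.data.frame(pred)) pred$y else pred[, 2]
  tx <- if (is.data.frame(truth)) truth$x else truth[, 1]
  ty <- if (is.data.frame(truth)) truth$y else truth[, 2]
  mean(sqrt((px - tx)^2 + (py - ty)^2))
}

#' Chance-level decoding from circularly shuffled activity
#'
#' Circularly shifts the test activity in time (jointly across neurons by
#' default, preserving each neuron's total count) by a random amount
#' between 5% and 95% of the data length, decodes, and records the error.
#'
#' @param model A [train_decoder()] model.
#' @param binned Test data from [bin_activity()].
#' @param n Number of shuffles (default 100).
#' @param shift_range Shift bounds as fractions of the number of time
#'   bins.
#' @param per_neuron If `TRUE`, draw an independent shift per neuron.
#' @param two_step Use the two-step decoder.
#' @param seed Integer seed.
#' @return A tibble with `shuffle`, `shift` (`NA` when per-neuron) and
#'   `error` (cm).
#' @export
shuffle_control <- function(model, binned, n = 100,
                            shift_range = c(0.05, 0.95),
                            per_neuron = FALSE, two_step = FALSE,
                            seed = NULL) {
  M <- nrow(binned$X)
  with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(k) {
      if (per_neuron) {
        shifts <- draw_shifts(ncol(binned$X), M, shift_range)
        Xs <- binned$X
        for (j in seq_len(ncol(Xs))) {
          Xs[, j] <- Xs[circular_shift(seq_len(M), shifts[j], M), j]
        }
        shift <- NA_integer_
      } else {
        shift <- draw_shifts(1, M, shift_range)
        Xs <- binned$X[circular_shift(seq_len(M), shift, M), , drop = FALSE]
      }
      pred <- if (two_step) {
        decode_2step(model, Xs, v = binned$v)
      } else {
        decode(model, Xs)
      }
      tibble::tibble(shuffle = k, shift = as.integer(shift),
                     error = decoding_error(pred, binned))
    })
  })
}

#' Knock-out decoding
#'
#' Zeroes the activity of a chosen neuron subset at prediction time only
#' (the model stays trained on the full population), decodes, and reports
#' the decoding error and the reconstructed CPP time (the fraction of
#' decoded time bins falling in each compartment).
#'
#' @param model A [train_decoder()] model.
#' @param binned Test data from [bin_activity()].
#' @param ko_set Integer indices of knocked-out neurons (may be empty).
#' @param arena An [arena_spec()] (for compartment fractions).
#' @param two_step Use the two-step decoder.
#' @return A list of class `cpp_decode_result`: `pred`, `error` (cm),
#'   `time_left`, `time_right` (decoded-time fractions summing to 1),
#'   `true_time_left`, `ko_set`.
#' @export
knockout_decode <- function(model, binned, ko_set = integer(0), arena,
                            two_step = FALSE) {
  stopifnot(all(ko_set %in% seq_len(ncol(binned$X))))
  if (length(ko_set) == ncol(binned$X)) {
    warning("knocking out every neuron: predictions follow the prior only")
  }
  X <- binned$X
  if (length(ko_set) > 0) X[, ko_set] <- 0
  pred <- if (two_step) decode_2step(model, X, v = binned$v) else decode(model, X)
  left <- mean(pred$x < arena$midline)
  structure(
    list(
      pred = pred,
      error = decoding_error(pred, binned),
      time_left = left, time_right = 1 - left,
      true_time_left = mean(binned$pos[, 1] < arena$midline),
      ko_set = ko_set
    ),
    class = "cpp_decode_result"
  )
}

#' Knock-out versus size-matched random knock-out
#'
#' Convenience wrapper: decodes with the designated knock-out set and with
#' `n_random` random same-size subsets drawn from the remaining neurons.
#'
#' @inheritParams knockout_decode
#' @param n_random Number of random control subsets (default 1).
#' @param candidates Pool for the random draw (default: all neurons).
#' @param seed Integer seed.
#' @return A tibble with one row per condition (`"ko"` or `"random"`):
#'   `error`, `time_left`, `time_right`.
#' @export
ko_contrast <- function(model, binned, ko_set, arena, n_random = 1,
                        candidates = seq_len(ncol(binned$X)),
                        two_step = FALSE, seed = NULL) {
  res_ko <- knockout_decode(model, binned, ko_set, arena, two_step)
  rand <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_random), function(k) {
      rks <- sample(candidates, length(ko_set))
      r <- knockout_decode(model, binned, rks, arena, two_step)
      tibble::tibble(condition = "random", draw = k, error = r$error,
                     time_left = r$time_left, time_right = r$time_right)
    })
  })
  dplyr::bind_rows(
    tibble::tibble(condition = "ko", draw = NA_integer_,
                   error = res_ko$error, time_left = res_ko$time_left,
                   time_right = res_ko$time_right),
    rand
  )
}

#' Decoding with neuron down-sampling
#'
#' Randomly down-samples the population to `n` neurons, retrains and
#' decodes, and averages the error over iterations; used to compare
#' decoding across animals with different population sizes.
#'
#' @param binned_train,binned_test [bin_activity()] objects.
#' @param n Target neuron count (default 150). If `n` equals the total, a
#'   single iteration is run.
#' @param iters Number of random subsets (default 50).
#' @param two_step Use the two-step decoder.
#' @param use_prior_weighting Passed to [train_decoder()].
#' @param seed Master seed.
#' @return A list with `mean_error` and per-iteration `errors`.
#' @export
downsample_neurons <- function(binned_train, binned_test, n = 150,
                               iters = 50, two_step = FALSE,
                               use_prior_weighting = TRUE, seed = NULL) {
  N <- ncol(binned_train$X)
  stopifnot(n <= N)
  if (n == N) iters <- 1L
  seeds <- spawn_seeds(seed, iters)
  errors <- purrr::map_dbl(seq_len(iters), function(k) {
    sel <- with_seed(seeds[[k]], sort(sample.int(N, n)))
    btr <- binned_train
    btr$X <- btr$X[, sel, drop = FALSE]
    bte <- binned_test
    bte$X <- bte$X[, sel, drop = FALSE]
    m <- train_decoder(btr, use_prior_weighting)
    pred <- if (two_step) decode_2step(m, bte) else decode(m, bte)
    decoding_error(pred, bte)
  })
  list(mean_error = mean(errors), errors = errors)
}
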