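#' Binarize deconvolved activity into calcium events
#'
#' Thresholds each neuron's deconvolved amplitude trace at `k` times the
#' standard deviation of the full trace (population SD over all frames,
#' zeros included) and marks supra-threshold frames as events. The rule is
#' invariant to positive rescaling of a neuron's trace. Neurons with a
#' constant non-zero trace (zero SD) are flagged degenerate and excluded
#' from the event matrix.
#'
#' @param amplitudes Neurons x frames non-negative matrix, or a
#'   `cpp_events` object from [simulate_events()].
#' @param k Threshold multiplier (default 3).
#' @param frame_rate Sampling rate in Hz (taken from a `cpp_events` input
#'   when available).
#' @return A list of class `cpp_events` with `amplitudes`, binary
#'   `events`, `frame_rate` and a logical `degenerate` flag per neuron.
#' @examples
#' a <- matrix(c(rep(0, 9), 10), nrow = 1)
#' binarize_events(a, frame_rate = 30)$events
#' @export
binarize_events <- function(amplitudes, k = 3, frame_rate = 30) {
  if (inherits(amplitudes, "cpp_events")) {
    frame_rate <- amplitudes$frame_rate
    amplitudes <- amplitudes$amplitudes
  }
  stopifnot(is.matrix(amplitudes), all(amplitudes >= 0))
  sds <- apply(amplitudes, 1, pop_sd)
  nonzero <- rowSums(amplitudes) > 0
  degenerate <- nonzero & sds == 0
  thr <- k * sds
  events <- (amplitudes > thr) * 1L
  events[degenerate, ] <- 0L
  storage.mode(events) <- "integer"
  structure(
    list(amplitudes = amplitudes, events = events,
         frame_rate = frame_rate, degenerate = degenerate),
    class = "cpp_events"
  )
}

#' Remove low-speed frames
#'
#' Frames in which the animal moves slower than `threshold` are excluded
#' from all downstream spatial analyses.
#'
#' @param traj A trajectory tibble with a `speed` column.
#' @param threshold Speed threshold in cm/s (default 2; frames with
#'   `speed < threshold` are dropped).
#' @return Integer vector of retained frame indices. Raises an error if no
#'   frames survive.
#' @export
speed_filter <- function(traj, threshold = 2) {
  keep <- which(traj$speed >= threshold)
  if (length(keep) == 0) {
    stop("speed filter removed every frame; downstream analyses refuse")
  }
  keep
}

# Occupancy seconds per bin from per-frame bin ids.
occupancy_seconds <- function(bin_ids, nbins, frame_rate) {
  tabulate(bin_ids, nbins) / frame_rate
}

# Event counts per bin for one neuron (event frame subset of bin_ids).
event_counts <- function(bin_ids, event_idx, nbins) {
  tabulate(bin_ids[event_idx], nbins)
}

#' Occupancy and rate maps for one neuron
#'
#' Bins the (speed-filtered) trajectory at a fixed pitch, computes the
#' occupancy probability per bin, the unsmoothed event rate per bin
#' (events divided by occupancy seconds) and a Gaussian-smoothed rate map.
#' Bins occupied for less than `min_occupancy_s` are flagged excluded and
#' drop out of occupancy-normalized statistics; the session mean rate is
#' the occupancy-weighted mean of the unsmoothed rates over included bins.
#'
#' @param traj Trajectory tibble (already speed-filtered, or pass
#'   `frames`).
#' @param events Binary event vector (one neuron, full frame length) or a
#'   `cpp_events` object plus `neuron`.
#' @param arena An [arena_spec()].
#' @param neuron Neuron index when `events` is a `cpp_events` object.
#' @param frames Optional integer vector of retained frame indices (e.g.
#'   from [speed_filter()]).
#' @param bin_cm Spatial bin pitch in cm (default 1.8).
#' @param smooth_sd Gaussian smoothing SD in bins (default 2).
#' @param min_occupancy_s Minimum occupancy per bin in seconds (default
#'   0.1); lower-occupancy bins are excluded.
#' @return A list of class `cpp_ratemap`: matrices `occupancy_s`, `p_occ`,
#'   `rate`, `rate_smooth` (ny x nx), logical `included`, scalars
#'   `mean_rate`, `peak_rate`, and the bin geometry.
#' @export
compute_maps <- function(traj, events, arena, neuron = NULL, frames = NULL,
                         bin_cm = 1.8, smooth_sd = 2,
                         min_occupancy_s = 0.1) {
  if (inherits(events, "cpp_events")) {
    stopifnot(!is.null(neuron))
    ev <- events$events[neuron, ]
  } else {
    ev <- as.numeric(events)
  }
  stopifnot(length(ev) == nrow(traj))
  fr <- 1 / diff(traj$t[1:2])
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  grid <- bin_grid(arena, bin_cm)
  ids <- bin_of(grid, traj$x[frames], traj$y[frames])
  occ <- occupancy_seconds(ids, grid$nbins, fr)
  cnt <- tabulate(ids[ev[frames] > 0], grid$nbins)
  ratemap_from_counts(occ, cnt, grid, smooth_sd, min_occupancy_s)
}

# Shared constructor used by the fast internal paths.
ratemap_from_counts <- function(occ, cnt, grid, smooth_sd = 2,
                                min_occupancy_s = 0.1) {
  included <- occ >= min_occupancy_s
  rate <- ifelse(occ > 0, cnt / occ, 0)
  p_occ <- occ * included
  p_occ <- if (sum(p_occ) > 0) p_occ / sum(p_occ) else p_occ
  mean_rate <- sum(p_occ * rate)
  to_mat <- function(v) matrix(v, nrow = grid$ny, ncol = grid$nx,
                               byrow = TRUE)
  rate_m <- to_mat(rate)
  sm <- gaussian_smooth(rate_m, smooth_sd)
  structure(
    list(
      occupancy_s = to_mat(occ), p_occ = to_mat(p_occ), rate = rate_m,
      rate_smooth = sm, included = to_mat(included),
      mean_rate = mean_rate, peak_rate = max(sm),
      peak_rate_unsmoothed = max(rate), grid = grid
    ),
    class = "cpp_ratemap"
  )
}

#' @export
print.cpp_ratemap <- function(x, ...) {
  cat(sprintf(
    "<cpp_ratemap> %d x %d bins (%g cm), mean rate %.3f ev/s, peak %.3f ev/s\n",
    x$grid$ny, x$grid$nx, x$grid$bin_cm, x$mean_rate, x$peak_rate
  ))
  invisible(x)
}

#' Occupancy-matched down-sampling of two frame sets
#'
#' For every spatial bin, retains `min(count_a, count_b)` frames on each
#' side, removing the surplus uniformly at random; the procedure is
#' repeated over several iterations whose seeds derive from one master
#' seed. The two frame sets must be binned on a common grid (for
#' transverse comparisons, bin ids should be within-compartment ids so
#' that homotopic bins correspond).
#'
#' @param bins_a,bins_b Integer per-frame bin ids for the two conditions.
#' @param n_iter Number of matching iterations (default 50).
#' @param seed Master seed.
#' @return A list of class `cpp_matched`; element `i` holds `a` and `b`,
#'   integer index vectors into the two inputs.
#' @export
match_occupancy <- function(bins_a, bins_b, n_iter = 50, seed = NULL) {
  nb <- max(c(bins_a, bins_b, 1L))
  ca <- tabulate(bins_a, nb)
  cb <- tabulate(bins_b, nb)
  keep <- pmin(ca, cb)
  by_a <- split(seq_along(bins_a), bins_a)
  by_b <- split(seq_along(bins_b), bins_b)
  seeds <- spawn_seeds(seed, n_iter)
  iters <- lapply(seq_len(n_iter), function(it) {
    with_seed(seeds[[it]], {
      pick <- function(by, counts) {
        sel <- lapply(names(by), function(nm) {
          b <- as.integer(nm)
          idx <- by[[nm]]
          k <- keep[b]
          if (k >= length(idx)) idx else sample(idx, k)
        })
        sort(unlist(sel, use.names = FALSE))
      }
      list(a = pick(by_a, ca), b = pick(by_b, cb))
    })
  })
  structure(iters, class = "cpp_matched")
}

#' Spatial coverage of a trajectory
#'
#' Fraction of arena bins physically visited.
#'
#' @param traj Trajectory tibble.
#' @param arena An [arena_spec()].
#' @param bin_cm Bin pitch in cm.
#' @return Scalar in `[0, 1]`.
#' @export
spatial_coverage <- function(traj, arena, bin_cm = 1.8) {
  stopifnot(nrow(traj) > 0)
  grid <- bin_grid(arena, bin_cm)
  ids <- bin_of(grid, traj$x, traj$y)
  length(unique(ids)) / grid$nbins
}
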