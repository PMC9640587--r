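# Spatial information core: P_i occupancy probabilities, lambda_i
# unsmoothed rates over the same (included) bins. Zero-rate bins
# contribute 0; undefined (mean rate 0) returns NA.
si_core <- function(p, lambda_i) {
  lam <- sum(p * lambda_i)
  if (lam <= 0) return(NA_real_)
  pos <- lambda_i > 0 & p > 0
  r <- lambda_i[pos] / lam
  sum(p[pos] * r * log2(r))
}

#' Spatial information in bits per event
#'
#' Skaggs-style information content of a rate map: the occupancy-weighted
#' mean of `(lambda_i / lambda) * log2(lambda_i / lambda)` over included
#' bins, where `lambda_i` is the unsmoothed event rate in bin i and
#' `lambda` the session mean rate. Zero-rate bins contribute zero; a
#' silent neuron (mean rate 0) yields `NA`.
#'
#' @param occupancy Occupancy probabilities per bin (`P_i`), or a
#'   `cpp_ratemap` from [compute_maps()] (in which case `rates` is
#'   ignored).
#' @param rates Unsmoothed event rates per bin, aligned with `occupancy`.
#' @return Spatial information in bits/event.
#' @examples
#' spatial_information(c(0.25, 0.25, 0.25, 0.25), c(4, 0, 0, 0)) # log2(4)
#' @export
spatial_information <- function(occupancy, rates = NULL) {
  if (inherits(occupancy, "cpp_ratemap")) {
    m <- occupancy
    inc <- m$included
    return(si_core(m$p_occ[inc], m$rate[inc]))
  }
  stopifnot(length(occupancy) == length(rates))
  p <- occupancy / sum(occupancy)
  si_core(p, rates)
}

# Vectorized SI for many circular shifts of one neuron's event train.
# ids: per-frame bin ids of the retained frame sequence (length T);
# ev_idx: event positions within that sequence; occ_s: occupancy seconds
# per bin id; included: logical per bin. Returns numeric vector of SI,
# one per shift.
si_shifts <- function(ids, ev_idx, occ_s, included, shifts, nbins) {
  T <- length(ids)
  ne <- length(ev_idx)
  S <- length(shifts)
  sh <- (outer(ev_idx - 1L, shifts, "+") %% T) + 1L
  binm <- ids[sh]
  colix <- rep(seq_len(S), each = ne)
  cnt <- tabulate(binm + (colix - 1L) * nbins, nbins * S)
  dim(cnt) <- c(nbins, S)
  cnt[!included, ] <- 0
  occ <- occ_s
  occ[!included] <- Inf  # excluded bins drop out
  L <- cnt / occ
  p <- occ_s * included
  p <- p / sum(p)
  lam <- colSums(L * p)
  out <- rep(NA_real_, S)
  ok <- lam > 0
  if (any(ok)) {
    R <- sweep(L[, ok, drop = FALSE], 2, lam[ok], "/")
    Rl <- R
    Rl[R <= 0] <- 1  # log term contributes 0
    out[ok] <- colSums(p * R * log2(Rl))
  }
  out
}

# Draw circular shift amounts uniformly over [lo, hi] fractions of T.
draw_shifts <- function(n, T, range = c(0.05, 0.95)) {
  lo <- max(1L, floor(range[1] * T))
  hi <- max(lo, floor(range[2] * T))
  sample(seq.int(lo, hi), n, replace = TRUE)
}

#' Shuffle-based spatial-information threshold for one neuron
#'
#' Circularly shifts the neuron's event train `n` times (shift drawn
#' uniformly over 5-95% of the retained trace length), recomputes spatial
#' information for each shift, and returns the requested percentile of the
#' shuffled distribution. A shift of zero reproduces the unshuffled score
#' and is excluded from the draws.
#'
#' @param events Binary event vector over the full frame length (one
#'   neuron).
#' @param traj Trajectory tibble.
#' @param arena An [arena_spec()].
#' @param frames Retained frame indices (default: [speed_filter()]).
#' @param n Number of shuffles (default 1000).
#' @param pct Percentile of the shuffled distribution (default 95).
#' @param bin_cm Bin pitch in cm.
#' @param shift_range Shift range as fractions of the trace length.
#' @param min_occupancy_s Bin exclusion threshold in seconds.
#' @param seed Integer seed.
#' @return A list with `threshold` (bits/event at `pct`), `si` (the
#'   unshuffled score) and the vector of `shuffled` scores. Neurons with
#'   fewer than two events give an `NA` threshold.
#' @export
shuffle_threshold <- function(events, traj, arena,
                              frames = speed_filter(traj),
                              n = 1000, pct = 95, bin_cm = 1.8,
                              shift_range = c(0.05, 0.95),
                              min_occupancy_s = 0.1, seed = NULL) {
  fr <- 1 / diff(traj$t[1:2])
  grid <- bin_grid(arena, bin_cm)
  ids <- bin_of(grid, traj$x[frames], traj$y[frames])
  occ <- occupancy_seconds(ids, grid$nbins, fr)
  included <- occ >= min_occupancy_s
  ev_idx <- which(events[frames] > 0)
  si <- si_shifts(ids, ev_idx, occ, included, 0L, grid$nbins)
  if (length(ev_idx) < 2) {
    return(list(threshold = NA_real_, si = si, shuffled = numeric(0)))
  }
  T <- length(ids)
  with_seed(seed, {
    shifts <- draw_shifts(n, T, shift_range)
    shuf <- si_shifts(ids, ev_idx, occ, included, shifts, grid$nbins)
    list(
      threshold = unname(quantile(shuf, pct / 100, na.rm = TRUE)),
      si = si, shuffled = shuf
    )
  })
}

#' Occupancy-matched place-cell classification (PCI)
#'
#' Classifies each neuron as a place cell per compartment. The shuffle
#' test (spatial information against the 95th percentile of `n_shuffles`
#' circular shuffles) is repeated over `n_iter` occupancy-matched
#' down-samplings of the two compartments; the place cell agreement index
#' (PCI) is the fraction of iterations in which the neuron passes. A
#' neuron is a place cell in a compartment when `PCI >= pci_threshold` and
#' its overall mean event rate on speed-filtered data is at least
#' `min_rate` Hz (low-rate neurons are excluded before shuffling).
#'
#' @param traj Trajectory tibble for the session.
#' @param events `cpp_events` object or neurons x frames binary matrix.
#' @param arena An [arena_spec()].
#' @param frames Retained frame indices (default [speed_filter()]).
#' @param n_iter Matching iterations (default 20).
#' @param n_shuffles Circular shuffles per iteration (default 1000).
#' @param pci_threshold PCI cutoff (default 0.3).
#' @param min_rate Mean-rate exclusion threshold in Hz (default 0.1).
#' @param min_matched_s Minimum seconds of matched data per compartment
#'   below which the decision is flagged unreliable (default 60).
#' @param bin_cm,pct,shift_range,min_occupancy_s As in
#'   [shuffle_threshold()].
#' @param seed Master seed.
#' @return A tibble with one row per neuron x compartment: `pci`,
#'   `mean_si` and `mean_threshold` (averaged over iterations),
#'   `mean_rate`, `is_place_cell`, `excluded_low_rate`, `unreliable`.
#' @export
classify_place_cells <- function(traj, events, arena,
                                 frames = speed_filter(traj),
                                 n_iter = 20, n_shuffles = 1000,
                                 pci_threshold = 0.3, min_rate = 0.1,
                                 min_matched_s = 60, bin_cm = 1.8,
                                 pct = 95, shift_range = c(0.05, 0.95),
                                 min_occupancy_s = 0.1, seed = NULL) {
  ev <- if (inherits(events, "cpp_events")) events$events else events
  fr <- 1 / diff(traj$t[1:2])
  n_neuron <- nrow(ev)
  comp <- traj$compartment[frames]
  if (length(unique(comp)) < 2) {
    stop("both compartments must be sampled for cross-compartment matching")
  }
  lgrid <- local_grid(arena, bin_cm)
  lids <- local_bin_of(arena, lgrid, traj$x[frames], traj$y[frames])
  f_side <- list(left = which(comp == "left"), right = which(comp == "right"))
  mean_rate <- rowSums(ev[, frames, drop = FALSE]) / (length(frames) / fr)
  active <- which(mean_rate >= min_rate)
  seeds <- spawn_seeds(seed, n_iter + 1)
  matched <- match_occupancy(lids[f_side$left], lids[f_side$right],
                             n_iter = n_iter, seed = seeds[[n_iter + 1]])
  ind <- array(NA, dim = c(n_neuron, 2, n_iter))
  si_acc <- array(NA_real_, dim = c(n_neuron, 2, n_iter))
  thr_acc <- array(NA_real_, dim = c(n_neuron, 2, n_iter))
  unreliable <- FALSE
  for (it in seq_len(n_iter)) {
    it_seeds <- with_seed(seeds[[it]],
                          sample.int(.Machine$integer.max - 1L, 2))
    for (s in 1:2) {
      side <- c("left", "right")[s]
      sub_local <- if (s == 1) matched[[it]]$a else matched[[it]]$b
      idx_in_frames <- f_side[[side]][sub_local]
      sub <- frames[idx_in_frames]
      T <- length(sub)
      if (T / fr < min_matched_s) unreliable <- TRUE
      ids <- lids[idx_in_frames]
      occ <- occupancy_seconds(ids, lgrid$nbins, fr)
      included <- occ >= min_occupancy_s
      shifts <- with_seed(it_seeds[s],
                          draw_shifts(n_shuffles, max(T, 2), shift_range))
      for (n_i in active) {
        ev_idx <- which(ev[n_i, sub] > 0)
        s_obs <- si_shifts(ids, ev_idx, occ, included, 0L, lgrid$nbins)
        si_acc[n_i, s, it] <- s_obs
        if (length(ev_idx) < 2 || is.na(s_obs)) {
          ind[n_i, s, it] <- FALSE
          next
        }
        shuf <- si_shifts(ids, ev_idx, occ, included, shifts, lgrid$nbins)
        thr <- unname(quantile(shuf, pct / 100, na.rm = TRUE))
        thr_acc[n_i, s, it] <- thr
        ind[n_i, s, it] <- s_obs > thr
      }
    }
  }
  pci <- apply(ind, c(1, 2), function(v) mean(v))
  res <- tidyr::expand_grid(
    neuron = seq_len(n_neuron), compartment = c("left", "right")
  )
  sidx <- ifelse(res$compartment == "left", 1L, 2L)
  flat <- cbind(res$neuron, sidx)
  res$pci <- pci[flat]
  res$mean_si <- apply(si_acc, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })[flat]
  res$mean_threshold <- apply(thr_acc, c(1, 2), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })[flat]
  res$mean_rate <- mean_rate[res$neuron]
  res$excluded_low_rate <- res$mean_rate < min_rate
  res$is_place_cell <- !res$excluded_low_rate &
    !is.na(res$pci) & res$pci >= pci_threshold
  res$unreliable <- unreliable
  class(res) <- c("cpp_place_cells", class(res))
  res
}

#' Place-field size from a smoothed rate map
#'
#' Binarizes the smoothed map at 50% of its peak rate, extracts connected
#' components (8-connectivity) and returns the area of the largest field.
#'
#' @param map A `cpp_ratemap` or a numeric matrix (smoothed rates).
#' @param bin_cm Bin pitch in cm (taken from a `cpp_ratemap` input).
#' @param threshold_frac Fraction of the peak used for binarization.
#' @return A tibble with `field_size_cm2`, `n_fields`, `peak_rate`.
#'   A flat zero map yields `NA` size and zero fields.
#' @export
field_size <- function(map, bin_cm = 1.8, threshold_frac = 0.5) {
  if (inherits(map, "cpp_ratemap")) {
    bin_cm <- map$grid$bin_cm
    m <- map$rate_smooth
  } else {
    m <- map
  }
  pk <- max(m)
  if (pk <= 0) {
    return(tibble::tibble(field_size_cm2 = NA_real_, n_fields = 0L,
                          peak_rate = 0))
  }
  mask <- m >= threshold_frac * pk
  lab <- label_components(mask)
  k <- max(lab)
  areas <- tabulate(lab[lab > 0], k) * bin_cm^2
  tibble::tibble(
    field_size_cm2 = max(areas), n_fields = k, peak_rate = pk
  )
}

#' Pairwise rate-map metrics
#'
#' Pearson correlation over mutually included bins plus peak/mean rates
#' and the normalized peak-rate change
#' `abs(peak_a - peak_b) / max(peak_a, peak_b)`.
#'
#' @param map_a,map_b `cpp_ratemap` objects on a common grid.
#' @param use_smoothed Correlate smoothed maps (default) or unsmoothed.
#' @param min_common_bins Minimum number of mutually included bins for the
#'   correlation to be defined (default 10).
#' @return A one-row tibble with `correlation`, `peak_a`, `peak_b`,
#'   `mean_a`, `mean_b`, `peak_rate_change`, `n_common_bins`.
#' @export
map_metrics <- function(map_a, map_b, use_smoothed = TRUE,
                        min_common_bins = 10) {
  stopifnot(inherits(map_a, "cpp_ratemap"), inherits(map_b, "cpp_ratemap"))
  common <- map_a$included & map_b$included
  a <- if (use_smoothed) map_a$rate_smooth else map_a$rate
  b <- if (use_smoothed) map_b$rate_smooth else map_b$rate
  n_common <- sum(common)
  corr <- if (n_common >= min_common_bins &&
              sd(a[common]) > 0 && sd(b[common]) > 0) {
    cor(a[common], b[common])
  } else NA_real_
  pa <- map_a$peak_rate
  pb <- map_b$peak_rate
  prc <- if (max(pa, pb) > 0) abs(pa - pb) / max(pa, pb) else NA_real_
  tibble::tibble(
    correlation = corr, peak_a = pa, peak_b = pb,
    mean_a = map_a$mean_rate, mean_b = map_b$mean_rate,
    peak_rate_change = prc, n_common_bins = n_common
  )
}

# Dense smoothing operator for a grid: row-normalized truncated Gaussian
# over bin distances; applying it to a vectorized map equals
# gaussian_smooth() on the matrix form. Used on batched maps in hot paths.
smoothing_operator <- function(grid, sd_bins = 2) {
  if (sd_bins <= 0) return(diag(grid$nbins))
  half <- ceiling(4 * sd_bins)
  ix <- ((seq_len(grid$nbins) - 1L) %% grid$nx) + 1L
  iy <- ((seq_len(grid$nbins) - 1L) %/% grid$nx) + 1L
  dx <- outer(ix, ix, "-")
  dy <- outer(iy, iy, "-")
  w <- exp(-(dx^2 + dy^2) / (2 * sd_bins^2))
  w[abs(dx) > half | abs(dy) > half] <- 0
  w / rowSums(w)
}

# Matched transverse (left vs right) per-neuron map metrics. Matching is
# shared across neurons within an iteration, as in the down-sampling
# protocol (position samples and the corresponding activity are removed).
# Returns per-neuron averages over iterations.
intercompartment_metrics <- function(traj, events, arena,
                                     frames = speed_filter(traj),
                                     neurons = NULL, n_iter = 50,
                                     bin_cm = 1.8, smooth_sd = 2,
                                     min_occupancy_s = 0.1, seed = NULL) {
  ev <- if (inherits(events, "cpp_events")) events$events else events
  if (is.null(neurons)) neurons <- seq_len(nrow(ev))
  fr <- 1 / diff(traj$t[1:2])
  comp <- traj$compartment[frames]
  lgrid <- local_grid(arena, bin_cm)
  lids <- local_bin_of(arena, lgrid, traj$x[frames], traj$y[frames])
  fL <- which(comp == "left")
  fR <- which(comp == "right")
  matched <- match_occupancy(lids[fL], lids[fR], n_iter = n_iter,
                             seed = seed)
  S <- smoothing_operator(lgrid, smooth_sd)
  acc <- matrix(0, length(neurons), 4)  # corr, peakL, peakR, peak change
  cnt_ok <- matrix(0, length(neurons), 4)
  for (it in seq_len(n_iter)) {
    subL <- fL[matched[[it]]$a]
    subR <- fR[matched[[it]]$b]
    idsL <- lids[subL]
    idsR <- lids[subR]
    occL <- occupancy_seconds(idsL, lgrid$nbins, fr)
    occR <- occupancy_seconds(idsR, lgrid$nbins, fr)
    incL <- occL >= min_occupancy_s
    incR <- occR >= min_occupancy_s
    common <- incL & incR
    evL <- ev[neurons, frames[subL], drop = FALSE]
    evR <- ev[neurons, frames[subR], drop = FALSE]
    # bins x neurons count matrices in one pass
    cntL <- counts_by_bin(idsL, evL, lgrid$nbins)
    cntR <- counts_by_bin(idsR, evR, lgrid$nbins)
    rateL <- cntL / ifelse(occL > 0, occL, Inf)
    rateR <- cntR / ifelse(occR > 0, occR, Inf)
    smL <- S %*% rateL
    smR <- S %*% rateR
    for (j in seq_along(neurons)) {
      a <- smL[common, j]
      b <- smR[common, j]
      if (sum(common) >= 10 && sd(a) > 0 && sd(b) > 0) {
        acc[j, 1] <- acc[j, 1] + cor(a, b)
        cnt_ok[j, 1] <- cnt_ok[j, 1] + 1
      }
      pl <- max(smL[, j]); pr <- max(smR[, j])
      acc[j, 2] <- acc[j, 2] + pl
      acc[j, 3] <- acc[j, 3] + pr
      cnt_ok[j, 2:3] <- cnt_ok[j, 2:3] + 1
      if (max(pl, pr) > 0) {
        acc[j, 4] <- acc[j, 4] + abs(pl - pr) / max(pl, pr)
        cnt_ok[j, 4] <- cnt_ok[j, 4] + 1
      }
    }
  }
  avg <- acc / ifelse(cnt_ok > 0, cnt_ok, NA)
  tibble::tibble(
    neuron = neurons,
    correlation = avg[, 1], peak_left = avg[, 2], peak_right = avg[, 3],
    peak_rate_change = avg[, 4]
  )
}

# bins x neurons event-count matrix: ids per frame, ev neurons x frames.
counts_by_bin <- function(ids, ev, nbins) {
  nn <- nrow(ev)
  out <- matrix(0, nbins, nn)
  for (j in seq_len(nn)) {
    e <- which(ev[j, ] > 0)
    if (length(e) > 0) out[, j] <- tabulate(ids[e], nbins)
  }
  out
}
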