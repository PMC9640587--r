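#' Reconstruct denoised calcium traces from deconvolved events
#'
#' Convolves each neuron's deconvolved amplitude train with a causal
#' exponential indicator kernel (`exp(-t / tau_s)`), producing the
#' denoised-trace analogue that the temporal clustering operates on.
#' Implemented as a first-order recursive filter.
#'
#' @param amplitudes Neurons x frames non-negative matrix, or a
#'   `cpp_events` object.
#' @param tau_s Indicator decay time constant in seconds (default 0.5,
#'   a fast GCaMP6 decay).
#' @param frame_rate Sampling rate in Hz (taken from a `cpp_events`
#'   input when available).
#' @return Neurons x frames matrix of reconstructed traces.
#' @export
calcium_trace <- function(amplitudes, tau_s = 0.5, frame_rate = 30) {
  if (inherits(amplitudes, "cpp_events")) {
    frame_rate <- amplitudes$frame_rate
    amplitudes <- amplitudes$amplitudes
  }
  stopifnot(tau_s > 0, frame_rate > 0)
  decay <- exp(-1 / (tau_s * frame_rate))
  out <- t(apply(amplitudes, 1, function(r) {
    as.numeric(stats::filter(r, decay, method = "recursive"))
  }))
  dimnames(out) <- dimnames(amplitudes)
  out
}

#' Noise-filter denoised calcium traces
#'
#' Zeroes samples of the denoised trace that fall below a per-neuron
#' noise threshold of twice the residual scale between the raw and the
#' denoised trace (SD of `raw - denoised`). The operation is idempotent.
#'
#' @param denoised Neurons x frames matrix of denoised traces.
#' @param raw Matrix of the same shape with the raw traces.
#' @return Filtered matrix of the same shape.
#' @export
filter_traces <- function(denoised, raw) {
  if (!all(dim(raw) == dim(denoised))) {
    stop("raw and denoised traces must have identical dimensions")
  }
  resid_sd <- apply(raw - denoised, 1, stats::sd)
  thr <- 2 * resid_sd
  out <- denoised
  out[out < thr] <- 0
  out
}

#' Consensus matrix from repeated k-means on sub-sampled traces
#'
#' Runs k-means `iters` times, each on a random sub-sample of the frames
#' (`subsample` fraction, without replacement), with neurons represented
#' by their vector of pairwise Pearson correlations to all neurons
#' computed from the sub-sampled data. Each run uses `replicates` random
#' centroid initializations. The consensus matrix is the frequency with
#' which two neurons are assigned to the same cluster.
#'
#' @param traces Neurons x frames activity matrix.
#' @param K Number of clusters (default 5).
#' @param iters Sub-sampling iterations (default 100).
#' @param subsample Fraction of frames kept per iteration (default 0.9).
#' @param replicates k-means restarts per iteration (default 10).
#' @param seed Master seed.
#' @return A list of class `cpp_consensus` with `C` (neurons x neurons,
#'   symmetric, unit diagonal), `K`, `iters` and `included` (neurons with
#'   non-constant traces; excluded neurons get `NA` rows/columns).
#' @export
build_consensus_matrix <- function(traces, K = 5, iters = 100,
                                   subsample = 0.9, replicates = 10,
                                   seed = NULL) {
  n <- nrow(traces)
  stopifnot(n >= K)
  included <- apply(traces, 1, stats::sd) > 0
  use <- which(included)
  if (length(use) < K) stop("fewer non-constant neurons than clusters")
  tr <- t(traces[use, , drop = FALSE])  # frames x neurons
  nf <- nrow(tr)
  seeds <- spawn_seeds(seed, iters)
  co <- matrix(0, length(use), length(use))
  for (it in seq_len(iters)) {
    with_seed(seeds[[it]], {
      sel <- sort(sample.int(nf, round(subsample * nf)))
      R <- suppressWarnings(cor(tr[sel, , drop = FALSE]))
      R[is.na(R)] <- 0
      km <- kmeans(R, centers = K, nstart = replicates, iter.max = 50)
      A <- outer(km$cluster, km$cluster, "==")
      co <- co + A
    })
  }
  C <- matrix(NA_real_, n, n)
  C[use, use] <- co / iters
  diag(C) <- 1
  structure(
    list(C = C, K = K, iters = iters, included = included),
    class = "cpp_consensus"
  )
}

#' Cut the consensus matrix into final clusters
#'
#' Hierarchical clustering with complete linkage on `1 - consensus`
#' distances, cut at `K`.
#'
#' @param consensus A `cpp_consensus` or a consensus matrix.
#' @param K Number of clusters.
#' @return Integer cluster ids (1..K) per neuron; `NA` for excluded
#'   neurons.
#' @export
cut_clusters <- function(consensus, K = NULL) {
  if (inherits(consensus, "cpp_consensus")) {
    if (is.null(K)) K <- consensus$K
    inc <- consensus$included
    C <- consensus$C[inc, inc, drop = FALSE]
  } else {
    stopifnot(!is.null(K))
    inc <- rep(TRUE, nrow(consensus))
    C <- consensus
  }
  h <- hclust(as.dist(1 - C), method = "complete")
  ids <- cutree(h, k = K)
  out <- rep(NA_integer_, length(inc))
  out[inc] <- ids
  out
}

# PAC: fraction of distinct neuron pairs with consensus strictly inside
# the ambiguity band.
pac_score <- function(C, band = c(0.1, 0.9)) {
  v <- C[upper.tri(C)]
  v <- v[!is.na(v)]
  mean(v > band[1] & v < band[2])
}

#' Select the number of clusters via PAC and cophenetic correlation
#'
#' Computes, for each K in `k_range`, a consensus matrix, its Proportion
#' of Ambiguous Clustering (fraction of neuron pairs with consensus in
#' the open interval (0.1, 0.9); lower is crisper) and the cophenetic
#' correlation of the complete-linkage tree with the `1 - consensus`
#' distances. The chosen K is the interior local minimum of PAC with the
#' lowest value (global minimum as fallback); the cophenetic local
#' maximum is reported alongside.
#'
#' @param traces Neurons x frames activity matrix.
#' @param k_range Candidate K values (default 2:10).
#' @param iters,subsample,replicates,seed As in
#'   [build_consensus_matrix()].
#' @return A list of class `cpp_kselect` with `curves` (tibble `K`,
#'   `pac`, `cophenetic`), `best_k_pac`, `best_k_cophenetic`.
#' @export
select_optimal_k <- function(traces, k_range = 2:10, iters = 100,
                             subsample = 0.9, replicates = 10,
                             seed = NULL) {
  seeds <- spawn_seeds(seed, length(k_range))
  rows <- purrr::map_dfr(seq_along(k_range), function(i) {
    K <- k_range[i]
    cons <- build_consensus_matrix(traces, K = K, iters = iters,
                                   subsample = subsample,
                                   replicates = replicates,
                                   seed = seeds[[i]])
    inc <- cons$included
    C <- cons$C[inc, inc]
    d <- as.dist(1 - C)
    h <- hclust(d, method = "complete")
    coph <- cor(cophenetic(h), d)
    tibble::tibble(K = K, pac = pac_score(C), cophenetic = coph)
  })
  # K is selected among interior candidates (the boundary K values are
  # computed only to define local extrema at the edges of the search)
  pick_extremum <- function(v, minimum = TRUE) {
    s <- if (minimum) v else -v
    n <- length(s)
    interior <- seq_len(n)[-c(1, n)]
    if (length(interior) == 0) interior <- seq_len(n)
    locs <- interior[vapply(interior, function(i) {
      s[i] < s[i - 1] && s[i] <= s[i + 1]
    }, logical(1))]
    if (length(locs) == 0) locs <- interior[which.min(s[interior])]
    locs[which.min(s[locs])]
  }
  structure(
    list(
      curves = rows,
      best_k_pac = rows$K[pick_extremum(rows$pac, TRUE)],
      best_k_cophenetic = rows$K[pick_extremum(rows$cophenetic, FALSE)]
    ),
    class = "cpp_kselect"
  )
}

# Min-max normalize a matrix to [0, 1]; constant maps stay 0.
minmax <- function(m) {
  rng <- range(m)
  if (diff(rng) == 0) return(m * 0)
  (m - rng[1]) / diff(rng)
}

#' Summed ensemble rate maps per cluster
#'
#' For each cluster, sums the smoothed rate maps of its member neurons on
#' the full-arena grid.
#'
#' @param traj Trajectory tibble.
#' @param events `cpp_events` or binary matrix.
#' @param arena An [arena_spec()].
#' @param assignment Integer cluster id per neuron (`NA` ignored).
#' @param frames Retained frame indices.
#' @param bin_cm,smooth_sd Map parameters.
#' @return Named list of ny x nx matrices, one per cluster id.
#' @export
ensemble_rate_maps <- function(traj, events, arena, assignment,
                               frames = speed_filter(traj),
                               bin_cm = 1.8, smooth_sd = 2) {
  ev <- if (inherits(events, "cpp_events")) events$events else events
  fr <- 1 / diff(traj$t[1:2])
  grid <- bin_grid(arena, bin_cm)
  ids <- bin_of(grid, traj$x[frames], traj$y[frames])
  occ <- occupancy_seconds(ids, grid$nbins, fr)
  S <- smoothing_operator(grid, smooth_sd)
  cnt <- counts_by_bin(ids, ev[, frames, drop = FALSE], grid$nbins)
  rates <- cnt / ifelse(occ > 0, occ, Inf)
  sm <- S %*% rates
  ks <- sort(unique(assignment[!is.na(assignment)]))
  out <- lapply(ks, function(k) {
    v <- rowSums(sm[, which(assignment == k), drop = FALSE])
    matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  })
  names(out) <- as.character(ks)
  out
}

# Two-field Gaussian sector templates on the full-arena grid. The field
# nearer the midline has variance 12.5 cm^2, the farther one 25 cm^2.
sector_templates <- function(arena, grid) {
  cmp <- arena$compartment_cm
  q <- cmp / 4
  sectors <- list(
    SW = c(q, q), NW = c(q, 3 * q), SE = c(3 * q, q), NE = c(3 * q, 3 * q)
  )
  xs <- rep(grid$xc, each = grid$ny)
  ys <- rep(grid$yc, times = grid$nx)
  # build on (ny x nx) matrices: row = y, col = x
  xm <- matrix(rep(grid$xc, each = grid$ny), grid$ny, grid$nx)
  ym <- matrix(rep(grid$yc, times = grid$nx), grid$ny, grid$nx)
  lapply(sectors, function(ctr) {
    centers <- list(c(ctr[1], ctr[2]), c(ctr[1] + arena$midline, ctr[2]))
    tmpl <- matrix(0, grid$ny, grid$nx)
    for (cc in centers) {
      var_cm2 <- if (abs(cc[1] - arena$midline) < cmp / 2) 12.5 else 25
      tmpl <- tmpl +
        exp(-((xm - cc[1])^2 + (ym - cc[2])^2) / (2 * var_cm2))
    }
    minmax(tmpl)
  })
}

#' Sort temporal clusters onto spatial sectors by template matching
#'
#' Identifies the centre cluster first (the ensemble map whose peak lies
#' closest to the compartment junction) and holds it out; the remaining
#' clusters are assigned to the SW/NW/SE/NE sectors by Pearson
#' correlation against two-field Gaussian templates at homotopic sector
#' positions, using the assignment permutation with the maximum summed
#' correlation.
#'
#' @param maps Named list of ensemble maps from [ensemble_rate_maps()];
#'   requires exactly 5 clusters.
#' @param arena An [arena_spec()].
#' @param bin_cm Grid pitch of the maps.
#' @return A tibble with `cluster`, `sector` and `correlation`
#'   (`NA` for the centre cluster).
#' @export
match_templates <- function(maps, arena, bin_cm = 1.8) {
  stopifnot(length(maps) == 5)
  grid <- bin_grid(arena, bin_cm)
  norm_maps <- lapply(maps, minmax)
  peak_xy <- t(vapply(norm_maps, function(m) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    c(grid$xc[ij[2]], grid$yc[ij[1]])
  }, numeric(2)))
  center_idx <- which.min(abs(peak_xy[, 1] - arena$midline))
  rest <- setdiff(seq_along(maps), center_idx)
  tmpl <- sector_templates(arena, grid)
  cmat <- matrix(NA_real_, length(rest), 4,
                 dimnames = list(names(maps)[rest], names(tmpl)))
  for (i in seq_along(rest)) {
    for (j in seq_along(tmpl)) {
      cmat[i, j] <- cor(as.vector(norm_maps[[rest[i]]]),
                        as.vector(tmpl[[j]]))
    }
  }
  perms <- permutations_4()
  sums <- apply(perms, 1, function(p) sum(cmat[cbind(1:4, p)]))
  best <- perms[which.max(sums), ]
  tibble::tibble(
    cluster = names(maps)[c(center_idx, rest)],
    sector = c("center", colnames(cmat)[best]),
    correlation = c(NA_real_, cmat[cbind(1:4, best)])
  )
}

permutations_4 <- function() {
  p <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  p <- as.matrix(p[apply(p, 1, function(r) length(unique(r)) == 4), ])
  unname(p)
}

#' Intra- versus inter-cluster anatomical distances
#'
#' For each cell of a designated subset, the mean Euclidean distance
#' between anatomical centroids of same-cluster versus other-cluster
#' members of the subset, and per-cluster averages.
#'
#' @param centroids Two-column matrix (or tibble with `anat_x`,
#'   `anat_y`) of anatomical centroid coordinates.
#' @param assignment Integer cluster id per row of `centroids`.
#' @param subset Indices of the cells to analyse (default: all).
#' @return A list with `per_cell` and `per_cluster` tibbles; single
#'   member clusters have `NA` intra-cluster distance.
#' @export
cluster_anatomy <- function(centroids, assignment, subset = NULL) {
  if (is.data.frame(centroids)) {
    centroids <- cbind(centroids$anat_x, centroids$anat_y)
  }
  if (is.null(subset)) subset <- seq_len(nrow(centroids))
  xy <- centroids[subset, , drop = FALSE]
  cl <- assignment[subset]
  d <- as.matrix(dist(xy))
  per_cell <- purrr::map_dfr(seq_along(subset), function(i) {
    same <- which(cl == cl[i])
    same <- setdiff(same, i)
    other <- which(cl != cl[i] & !is.na(cl))
    tibble::tibble(
      cell = subset[i], cluster = cl[i],
      intra = if (length(same) > 0) mean(d[i, same]) else NA_real_,
      inter = if (length(other) > 0) mean(d[i, other]) else NA_real_
    )
  })
  per_cluster <- per_cell |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      intra = if (all(is.na(.data$intra))) NA_real_
              else mean(.data$intra, na.rm = TRUE),
      inter = mean(.data$inter, na.rm = TRUE),
      n = dplyr::n(), .groups = "drop"
    )
  list(per_cell = per_cell, per_cluster = per_cluster)
}

#' @importFrom stats dist
NULL
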