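#' Build the LN-model design matrices
#'
#' Bins speed-filtered behaviour into `dt`-second time bins and builds
#' one-hot design matrices for position (`bin_cm` spatial bins), head
#' direction (`hd_bin_deg` degree bins) and speed (`speed_bin` cm/s bins,
#' capped at `speed_cap` with an open-ended last bin), together with the
#' per-time-bin spike counts of every neuron. Variable bins never visited
#' are dropped from the vocabulary. Sessions can be concatenated by
#' passing pre-combined `traj`/`events` (e.g. two baselines).
#'
#' @param traj Trajectory tibble.
#' @param events `cpp_events` or neurons x frames binary matrix.
#' @param arena An [arena_spec()].
#' @param frames Retained frame indices (default [speed_filter()]).
#' @param dt Time-bin width in seconds (default 0.5).
#' @param bin_cm Position bin pitch (default 1.8).
#' @param hd_bin_deg Head-direction bin width in degrees (default 20).
#' @param speed_bin Speed bin width in cm/s (default 2).
#' @param speed_cap Speed at which the last (open-ended) bin starts.
#' @return A list of class `cpp_ln_design`: sparse matrices `X` per
#'   variable (`P`, `H`, `S`), `counts` (time bins x neurons), `dt`,
#'   adjacency edge lists per variable for the smoothness penalty, and
#'   bin bookkeeping.
#' @export
build_design <- function(traj, events, arena, frames = speed_filter(traj),
                         dt = 0.5, bin_cm = 1.8, hd_bin_deg = 20,
                         speed_bin = 2, speed_cap = 30) {
  ev <- if (inherits(events, "cpp_events")) events$events else events
  fr <- 1 / diff(traj$t[1:2])
  fpb <- max(1L, round(dt * fr))
  M <- length(frames) %/% fpb
  if (M == 0) stop("not enough retained frames for a single time bin")
  used <- frames[seq_len(M * fpb)]
  grp <- rep(seq_len(M), each = fpb)
  counts <- unname(rowsum(t(ev[, used, drop = FALSE]), grp))
  px <- rowsum(traj$x[used], grp)[, 1] / fpb
  py <- rowsum(traj$y[used], grp)[, 1] / fpb
  sp <- rowsum(traj$speed[used], grp)[, 1] / fpb
  hs <- rowsum(sin(traj$hd[used]), grp)[, 1]
  hc <- rowsum(cos(traj$hd[used]), grp)[, 1]
  hd <- atan2(hs, hc)
  grid <- bin_grid(arena, bin_cm)
  pos_id <- bin_of(grid, px, py)
  nh <- as.integer(round(360 / hd_bin_deg))
  hd_id <- pmin(nh, floor((hd + pi) / (2 * pi) * nh) + 1L)
  ns <- as.integer(speed_cap / speed_bin) + 1L
  sp_id <- pmin(ns, floor(sp / speed_bin) + 1L)
  onehot <- function(id) {
    vocab <- sort(unique(id))
    j <- match(id, vocab)
    X <- Matrix::sparseMatrix(i = seq_along(id), j = j,
                              x = 1, dims = c(length(id), length(vocab)))
    list(X = X, vocab = vocab)
  }
  P <- onehot(pos_id)
  H <- onehot(hd_id)
  S <- onehot(sp_id)
  # adjacency (edges between kept bins adjacent in the native topology)
  pos_edges <- {
    ix <- ((P$vocab - 1L) %% grid$nx) + 1L
    iy <- ((P$vocab - 1L) %/% grid$nx) + 1L
    e <- list()
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      nb <- match((ix + d[1]) + (iy + d[2] - 1L) * grid$nx, P$vocab)
      ok <- which(!is.na(nb) & ix + d[1] <= grid$nx & iy + d[2] <= grid$ny)
      if (length(ok)) e[[length(e) + 1]] <- cbind(ok, nb[ok])
    }
    do.call(rbind, e)
  }
  ring_edges <- function(vocab, n_total, circular) {
    nb <- match((vocab %% n_total) + 1L, vocab)
    ok <- which(!is.na(nb))
    if (!circular) ok <- ok[vocab[ok] < n_total]
    cbind(ok, nb[ok])
  }
  structure(
    list(
      X = list(P = P$X, H = H$X, S = S$X),
      vocab = list(P = P$vocab, H = H$vocab, S = S$vocab),
      edges = list(
        P = pos_edges,
        H = ring_edges(H$vocab, nh, circular = TRUE),
        S = ring_edges(S$vocab, ns, circular = FALSE)
      ),
      counts = counts, dt = dt, grid = grid,
      pos_id = pos_id, n_bins = c(P = ncol(P$X), H = ncol(H$X),
                                  S = ncol(S$X))
    ),
    class = "cpp_ln_design"
  )
}

# Penalty Laplacians (one per variable), normalized by the edge count.
penalty_laplacian <- function(edges, p) {
  L <- matrix(0, p, p)
  if (is.null(edges) || nrow(edges) == 0) return(L)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    L[a, a] <- L[a, a] + 1
    L[b, b] <- L[b, b] + 1
    L[a, b] <- L[a, b] - 1
    L[b, a] <- L[b, a] - 1
  }
  L / nrow(edges)
}

#' Fit a linear-nonlinear Poisson model
#'
#' Maximizes the penalized Poisson log-likelihood of the observed spike
#' counts given the model rate `r = exp(sum_i X_i w_i) / dt`, with a
#' smoothness prior on each parameter vector (normalized squared
#' differences of adjacent bins; circular for head direction).
#'
#' @param design A [build_design()] object.
#' @param n Spike-count vector for one neuron (length = time bins), or a
#'   neuron index into `design$counts`.
#' @param vars Included variables, subset of `c("P", "H", "S")`.
#' @param lambda Smoothness penalty weight (default 5).
#' @param rows Optional subset of time bins to fit on (training folds).
#' @param w_init Optional warm-start parameter vector.
#' @param maxit Optimizer iteration cap.
#' @return A list of class `cpp_ln_fit`: `w` (named by variable),
#'   `vars`, `converged`, `neg_loglik`, `design_ref` bookkeeping.
#' @export
fit_ln <- function(design, n, vars = c("P", "H", "S"), lambda = 5,
                   rows = NULL, w_init = NULL, maxit = 250) {
  stopifnot(length(vars) >= 1, all(vars %in% c("P", "H", "S")))
  if (length(n) == 1) n <- design$counts[, n]
  X <- do.call(cbind, design$X[vars])
  if (!is.null(rows)) {
    X <- X[rows, , drop = FALSE]
    n <- n[rows]
  }
  sizes <- vapply(design$X[vars], ncol, integer(1))
  offs <- cumsum(c(0, sizes))
  Ls <- lapply(seq_along(vars), function(i) {
    penalty_laplacian(design$edges[[vars[i]]], sizes[i])
  })
  pen_mult <- 2 * lambda
  ridge <- 1e-6
  fn <- function(w) {
    eta <- as.vector(X %*% w)
    eta <- pmin(eta, 30)
    val <- sum(exp(eta)) - sum(n * eta) + ridge * sum(w^2)
    for (i in seq_along(vars)) {
      wi <- w[(offs[i] + 1):offs[i + 1]]
      val <- val + lambda * as.numeric(wi %*% Ls[[i]] %*% wi)
    }
    val
  }
  gr <- function(w) {
    eta <- as.vector(X %*% w)
    eta <- pmin(eta, 30)
    g <- as.vector(Matrix::crossprod(X, exp(eta) - n)) + 2 * ridge * w
    for (i in seq_along(vars)) {
      idx <- (offs[i] + 1):offs[i + 1]
      g[idx] <- g[idx] + pen_mult * as.vector(Ls[[i]] %*% w[idx])
    }
    g
  }
  p <- sum(sizes)
  w0 <- if (is.null(w_init)) rep(log(mean(n) + 1e-3) / length(vars), p) else w_init
  opt <- optim(w0, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit))
  w_split <- lapply(seq_along(vars), function(i) {
    setNames(opt$par[(offs[i] + 1):offs[i + 1]],
             design$vocab[[vars[i]]])
  })
  names(w_split) <- vars
  structure(
    list(w = w_split, vars = vars, converged = opt$convergence == 0,
         neg_loglik = opt$value, dt = design$dt),
    class = "cpp_ln_fit"
  )
}

# Predicted rate (events/s) per time bin for (a subset of) the design.
predict_ln <- function(fit, design, rows = NULL) {
  X <- do.call(cbind, design$X[fit$vars])
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  w <- unlist(fit$w, use.names = FALSE)
  exp(pmin(as.vector(X %*% w), 30)) / fit$dt
}

#' Cross-validated LN-model performance
#'
#' Ten-fold cross-validation with random 10% folds. The per-fold score is
#' the Pearson correlation between the predicted and the observed firing
#' rate on the held-out bins, minus the 95th percentile of the
#' correlations obtained after circularly shuffling the observed rate 500
#' times.
#'
#' @param design A [build_design()] object.
#' @param n Spike counts for one neuron (vector or neuron index).
#' @param vars Included variables.
#' @param lambda Smoothness penalty weight.
#' @param n_folds Number of folds (default 10).
#' @param n_shuffles Shuffles of the observed rate (default 500).
#' @param contiguous If `TRUE`, use contiguous fold blocks instead of
#'   random bins.
#' @param fold Optional explicit fold assignment (integer vector, one
#'   entry per time bin); lets several candidate models share folds so
#'   their per-fold scores are paired.
#' @param seed Integer seed (governs folds and shuffles).
#' @return Numeric vector of `n_folds` scores.
#' @export
cv_performance <- function(design, n, vars, lambda = 5, n_folds = 10,
                           n_shuffles = 500, contiguous = FALSE,
                           fold = NULL, seed = NULL) {
  if (length(n) == 1) n <- design$counts[, n]
  M <- length(n)
  with_seed(seed, {
    if (is.null(fold)) {
      fold <- if (contiguous) {
        rep(seq_len(n_folds), each = ceiling(M / n_folds))[seq_len(M)]
      } else {
        sample(rep_len(seq_len(n_folds), M))
      }
    }
    warm <- fit_ln(design, n, vars, lambda)
    w0 <- unlist(warm$w, use.names = FALSE)
    vapply(seq_len(n_folds), function(f) {
      test <- which(fold == f)
      train <- which(fold != f)
      fit <- fit_ln(design, n, vars, lambda, rows = train, w_init = w0,
                    maxit = 100)
      pred <- predict_ln(fit, design, rows = test)
      true <- n[test] / design$dt
      if (sd(pred) == 0 || sd(true) == 0) return(NA_real_)
      obs <- cor(pred, true)
      Tn <- length(true)
      shifts <- draw_shifts(n_shuffles, Tn)
      shuf_mat <- vapply(shifts, function(s) {
        true[circular_shift(seq_len(Tn), s, Tn)]
      }, numeric(Tn))
      sc <- suppressWarnings(as.vector(cor(pred, shuf_mat)))
      thr <- quantile(sc, 0.95, na.rm = TRUE)
      obs - unname(thr)
    }, numeric(1))
  })
}

#' Forward model selection over the seven LN model classes
#'
#' Starts from the best single-variable model (by mean cross-validated
#' score) and adds variables only when the larger model significantly
#' improves held-out performance (one-sided sign-rank test across the 10
#' folds, p < 0.05). The neuron is left unclassified when the final
#' model's scores are not significantly above zero.
#'
#' @inheritParams cv_performance
#' @param alpha Significance level for both tests (default 0.05).
#' @return A list of class `cpp_ln_selection`: `model` (one of `"P"`,
#'   `"H"`, `"S"`, `"PH"`, `"PS"`, `"HS"`, `"PHS"` or `"unclassified"`),
#'   `scores` (per-fold scores of every evaluated model) and
#'   `final_scores`.
#' @export
forward_search <- function(design, n, lambda = 5, n_folds = 10,
                           n_shuffles = 500, alpha = 0.05, seed = NULL) {
  if (length(n) == 1) n <- design$counts[, n]
  seeds <- spawn_seeds(seed, 9)
  M <- nrow(design$counts)
  # one fold assignment shared by every candidate model, so the per-fold
  # scores are paired for the sign-rank comparisons
  fold <- with_seed(seeds[[9]], sample(rep_len(seq_len(n_folds), M)))
  cache <- list()
  seed_i <- 0
  get_scores <- function(vars) {
    key <- paste(vars, collapse = "")
    if (is.null(cache[[key]])) {
      seed_i <<- seed_i + 1
      cache[[key]] <<- cv_performance(
        design, n, vars, lambda, n_folds, n_shuffles, fold = fold,
        seed = seeds[[min(seed_i, 8)]]
      )
    }
    cache[[key]]
  }
  if (sum(n) < 2 || sd(n) == 0) {
    return(structure(list(model = "unclassified", scores = list(),
                          final_scores = rep(NA_real_, n_folds)),
                     class = "cpp_ln_selection"))
  }
  singles <- c("P", "H", "S")
  means <- vapply(singles, function(v) mean(get_scores(v), na.rm = TRUE),
                  numeric(1))
  current <- singles[which.max(means)]
  repeat {
    remaining <- setdiff(singles, current)
    if (length(remaining) == 0) break
    cur_scores <- get_scores(current)
    cand <- purrr::map(remaining, function(v) {
      vars <- intersect(singles, c(current, v))  # canonical P,H,S order
      list(vars = vars, scores = get_scores(vars))
    })
    pvals <- vapply(cand, function(cc) {
      ok <- stats::complete.cases(cbind(cc$scores, cur_scores))
      if (sum(ok) < 3) return(1)
      suppressWarnings(wilcox.test(cc$scores[ok], cur_scores[ok],
                                   paired = TRUE,
                                   alternative = "greater")$p.value)
    }, numeric(1))
    if (!any(pvals < alpha)) break
    best <- which.min(pvals)
    current <- cand[[best]]$vars
  }
  final <- get_scores(current)
  ok <- final[!is.na(final)]
  classified <- length(ok) >= 3 &&
    suppressWarnings(wilcox.test(ok, alternative = "greater")$p.value) < alpha
  structure(
    list(
      model = if (classified) paste(current, collapse = "") else "unclassified",
      scores = cache,
      final_scores = final
    ),
    class = "cpp_ln_selection"
  )
}

#' Classify a population of neurons with the LN framework
#'
#' Runs [forward_search()] for each neuron and returns the selected model
#' classes.
#'
#' @param design A [build_design()] object.
#' @param neurons Neuron indices (default: all columns of
#'   `design$counts`).
#' @inheritParams forward_search
#' @return A tibble with `neuron`, `model` and `mean_score`.
#' @export
classify_ln_neurons <- function(design, neurons = NULL, lambda = 5,
                                n_folds = 10, n_shuffles = 500,
                                alpha = 0.05, seed = NULL) {
  if (is.null(neurons)) neurons <- seq_len(ncol(design$counts))
  seeds <- spawn_seeds(seed, length(neurons))
  purrr::map_dfr(seq_along(neurons), function(i) {
    sel <- forward_search(design, design$counts[, neurons[i]],
                          lambda = lambda, n_folds = n_folds,
                          n_shuffles = n_shuffles, alpha = alpha,
                          seed = seeds[[i]])
    tibble::tibble(
      neuron = neurons[i], model = sel$model,
      mean_score = mean(sel$final_scores, na.rm = TRUE)
    )
  })
}
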