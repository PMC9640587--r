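#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a rate map into a per-bin tibble
#'
#' @param x A `cpp_ratemap`.
#' @param ... Unused.
#' @return A tibble with one row per bin: `x`, `y` (bin centres, cm),
#'   `occupancy_s`, `p_occ`, `rate`, `rate_smooth`, `included`.
#' @method tidy cpp_ratemap
#' @export
tidy.cpp_ratemap <- function(x, ...) {
  g <- x$grid
  m <- x
  tibble::tibble(
    x = rep(g$xc, each = g$ny),
    y = rep(g$yc, times = g$nx),
    occupancy_s = as.vector(m$occupancy_s),
    p_occ = as.vector(m$p_occ),
    rate = as.vector(m$rate),
    rate_smooth = as.vector(m$rate_smooth),
    included = as.vector(m$included)
  )
}

#' One-row summary of a rate map
#'
#' @param x A `cpp_ratemap`.
#' @param ... Unused.
#' @method glance cpp_ratemap
#' @export
glance.cpp_ratemap <- function(x, ...) {
  tibble::tibble(
    mean_rate = x$mean_rate, peak_rate = x$peak_rate,
    n_included_bins = sum(x$included),
    spatial_information = spatial_information(x)
  )
}

#' Tidy a trained decoder into per-location parameters
#'
#' @param x A `cpp_decoder`.
#' @param ... Unused.
#' @return A tibble with `location` (bin id), `x`, `y`, `prior` and the
#'   per-neuron multinomial parameters in long format.
#' @method tidy cpp_decoder
#' @export
tidy.cpp_decoder <- function(x, ...) {
  m <- x
  nn <- ncol(m$theta)
  tibble::tibble(
    location = rep(m$vocab, times = nn),
    x = rep(m$centers[, 1], times = nn),
    y = rep(m$centers[, 2], times = nn),
    prior = rep(m$prior, times = nn),
    neuron = rep(seq_len(nn), each = length(m$vocab)),
    theta = as.vector(m$theta)
  )
}

#' @method glance cpp_decoder
#' @export
glance.cpp_decoder <- function(x, ...) {
  tibble::tibble(
    n_locations = length(x$vocab), n_neurons = x$n_neurons,
    bin_cm = x$grid$bin_cm
  )
}

#' Tidy an LN fit into per-bin parameters
#'
#' @param x A `cpp_ln_fit`.
#' @param ... Unused.
#' @return A tibble with `variable`, `bin` and `w` (log-rate
#'   contribution) plus `rate_gain = exp(w)`.
#' @method tidy cpp_ln_fit
#' @export
tidy.cpp_ln_fit <- function(x, ...) {
  purrr::imap_dfr(x$w, function(w, v) {
    tibble::tibble(variable = v, bin = as.integer(names(w)),
                   w = unname(w), rate_gain = exp(unname(w)))
  })
}

#' @method glance cpp_ln_fit
#' @export
glance.cpp_ln_fit <- function(x, ...) {
  tibble::tibble(
    model = paste(x$vars, collapse = ""),
    converged = x$converged,
    neg_loglik = x$neg_loglik
  )
}

#' Tidy an LN model selection
#'
#' @param x A `cpp_ln_selection`.
#' @param ... Unused.
#' @return Per-fold scores of every evaluated model class.
#' @method tidy cpp_ln_selection
#' @export
tidy.cpp_ln_selection <- function(x, ...) {
  purrr::imap_dfr(x$scores, function(s, m) {
    tibble::tibble(model = m, fold = seq_along(s), score = s)
  })
}

#' @method glance cpp_ln_selection
#' @export
glance.cpp_ln_selection <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    mean_score = mean(x$final_scores, na.rm = TRUE)
  )
}

#' Tidy a consensus matrix into pairwise rows
#'
#' @param x A `cpp_consensus`.
#' @param ... Unused.
#' @method tidy cpp_consensus
#' @export
tidy.cpp_consensus <- function(x, ...) {
  n <- nrow(x$C)
  idx <- which(upper.tri(x$C), arr.ind = TRUE)
  tibble::tibble(
    neuron_a = idx[, 1], neuron_b = idx[, 2],
    consensus = x$C[idx]
  )
}

#' @method glance cpp_consensus
#' @export
glance.cpp_consensus <- function(x, ...) {
  inc <- x$included
  tibble::tibble(
    K = x$K, iters = x$iters, n_neurons = sum(inc),
    pac = pac_score(x$C[inc, inc])
  )
}
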