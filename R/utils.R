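#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rgamma quantile sd cor kmeans hclust
#'   cutree cophenetic as.dist optim wilcox.test binom.test median setNames
#'   rpois complete.cases
#' @importFrom utils head tail
#' @importFrom rlang .data
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
spawn_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

# Circularly shift a vector of frame indices on a track of length n_frames.
# shift is in frames; indices are 1-based.
circular_shift <- function(idx, shift, n_frames) {
  ((idx - 1L + shift) %% n_frames) + 1L
}

# Label connected components of a logical matrix under 8-connectivity.
# Returns an integer matrix of component ids (0 = background).
label_components <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        # flood fill from (i, j)
        stack <- matrix(c(i, j), ncol = 2)
        lab[i, j] <- cur
        while (nrow(stack) > 0) {
          p <- stack[nrow(stack), ]
          stack <- stack[-nrow(stack), , drop = FALSE]
          for (di in -1:1) for (dj in -1:1) {
            ii <- p[1] + di
            jj <- p[2] + dj
            if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
                mask[ii, jj] && lab[ii, jj] == 0L) {
              lab[ii, jj] <- cur
              stack <- rbind(stack, c(ii, jj))
            }
          }
        }
      }
    }
  }
  lab
}

# Population standard deviation (denominator n, not n - 1).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

# 2D Gaussian smoothing of a matrix with an edge-renormalized kernel.
# sd is in units of bins; kernel truncated at 4 sd.
gaussian_smooth <- function(m, sd_bins = 2) {
  if (sd_bins <= 0) return(m)
  half <- ceiling(4 * sd_bins)
  k1 <- exp(-(-half:half)^2 / (2 * sd_bins^2))
  kern <- outer(k1, k1)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  wts <- matrix(0, nr, nc)
  for (di in -half:half) {
    si <- max(1, 1 - di):min(nr, nr - di)
    for (dj in -half:half) {
      sj <- max(1, 1 - dj):min(nc, nc - dj)
      w <- kern[di + half + 1, dj + half + 1]
      out[si, sj] <- out[si, sj] + w * m[si + di, sj + dj]
      wts[si, sj] <- wts[si, sj] + w
    }
  }
  out / wts
}
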