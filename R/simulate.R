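#' Simulation configuration for synthetic CPP sessions
#'
#' Parameters of the behavioural generator: a momentum (smoothed) random
#' walk with reflective walls, door-constrained midline crossings driven
#' by stochastic shuttle episodes, and a leave-rate asymmetry that
#' produces a controllable compartment-occupancy bias without teleporting
#' the animal.
#'
#' @param duration_s Session duration in seconds.
#' @param frame_rate Sampling rate in Hz.
#' @param speed_mean,speed_sd Mean and SD of the target step speed (cm/s).
#' @param pause_prob Per-frame probability that the target speed is zero.
#' @param max_speed Hard cap on instantaneous speed (cm/s).
#' @param momentum Velocity persistence in `[0, 1)`; higher is smoother.
#' @param turn_sd SD of the per-frame heading increment (radians).
#' @param shuttle_rate Rate (per second) at which the animal initiates a
#'   door-directed crossing into the other compartment; sets the mixing
#'   between compartments.
#' @param occupancy_bias Asymmetry in `[0, 1]` of the compartment
#'   leave rates: the rate of leaving `bias_compartment` is scaled by
#'   `1 - occupancy_bias` and the rate of entering it by
#'   `1 + occupancy_bias`, so the expected fraction of time spent in the
#'   biased compartment is `(1 + occupancy_bias) / 2`. 0 gives symmetric
#'   occupancy.
#' @param bias_compartment `"left"` or `"right"`.
#' @param hd_noise_sd SD of the wrapped-Gaussian noise added to the
#'   movement heading to produce the head-direction signal (radians).
#' @param seed Integer seed for reproducibility, or `NULL`.
#' @return A list of class `cpp_sim_config`.
#' @export
sim_config <- function(duration_s = 900, frame_rate = 30,
                       speed_mean = 8, speed_sd = 4, pause_prob = 0.05,
                       max_speed = 30, momentum = 0.8, turn_sd = 0.6,
                       shuttle_rate = 0.04,
                       occupancy_bias = 0, bias_compartment = "left",
                       hd_noise_sd = 0.4, seed = NULL) {
  if (frame_rate <= 0) stop("frame_rate must be positive")
  stopifnot(duration_s >= 0, occupancy_bias >= 0, occupancy_bias <= 1)
  bias_compartment <- match.arg(bias_compartment, c("left", "right"))
  structure(
    list(
      duration_s = duration_s, frame_rate = frame_rate,
      speed_mean = speed_mean, speed_sd = speed_sd,
      pause_prob = pause_prob, max_speed = max_speed,
      momentum = momentum, turn_sd = turn_sd,
      shuttle_rate = shuttle_rate,
      occupancy_bias = occupancy_bias,
      bias_compartment = bias_compartment,
      hd_noise_sd = hd_noise_sd, seed = seed
    ),
    class = "cpp_sim_config"
  )
}

#' Simulate a foraging trajectory in the CPP arena
#'
#' Generates a smoothed random walk inside the two-compartment arena.
#' Walls are reflective; the midline partition can only be crossed through
#' the door opening. Compartment changes arise from stochastic
#' door-directed shuttle episodes (a drift toward the door until the
#' crossing completes); `occupancy_bias` skews the shuttle initiation
#' rates so that the animal preferentially dwells in the biased
#' compartment while motion stays continuous.
#'
#' @param arena An [arena_spec()].
#' @param config A [sim_config()].
#' @return A tibble of class `cpp_trajectory` with one row per frame and
#'   columns `t` (s), `x`, `y` (cm), `speed` (cm/s, from displacement),
#'   `hd` (head direction, radians) and `compartment`.
#' @examples
#' traj <- simulate_trajectory(arena_spec(), sim_config(duration_s = 10, seed = 1))
#' head(traj)
#' @export
simulate_trajectory <- function(arena, config = sim_config()) {
  stopifnot(inherits(arena, "cpp_arena"))
  n <- round(config$duration_s * config$frame_rate)
  if (n == 0) {
    out <- tibble::tibble(
      t = numeric(0), x = numeric(0), y = numeric(0),
      speed = numeric(0), hd = numeric(0), compartment = character(0)
    )
    class(out) <- c("cpp_trajectory", class(out))
    return(out)
  }
  dt <- 1 / config$frame_rate
  door_c <- c(arena$midline, mean(arena$door))
  with_seed(config$seed, {
    x <- numeric(n); y <- numeric(n)
    x[1] <- runif(1, 0, arena$width)
    y[1] <- runif(1, 0, arena$height)
    theta <- runif(1, -pi, pi)
    vx <- 0; vy <- 0
    pause <- runif(n) < config$pause_prob
    s_tgt <- pmin(abs(rnorm(n, config$speed_mean, config$speed_sd)),
                  config$max_speed)
    s_tgt[pause] <- 0
    dtheta <- rnorm(n, 0, config$turn_sd)
    u_shuttle <- runif(n)
    base_p <- config$shuttle_rate / config$frame_rate
    shuttling <- FALSE
    shuttle_left <- 0L  # frames remaining before the attempt is abandoned
    timeout <- round(5 * config$frame_rate)
    for (i in 2:max(n, 2)) {
      in_biased <- (x[i - 1] < arena$midline) ==
        (config$bias_compartment == "left")
      if (!shuttling) {
        p_leave <- base_p *
          (if (in_biased) 1 - config$occupancy_bias
           else 1 + config$occupancy_bias)
        if (u_shuttle[i] < p_leave) {
          shuttling <- TRUE
          shuttle_left <- timeout
          start_comp <- x[i - 1] < arena$midline
        }
      }
      theta <- theta + dtheta[i]
      sx <- s_tgt[i] * cos(theta)
      sy <- s_tgt[i] * sin(theta)
      if (shuttling) {
        # directed run at the door until the crossing completes
        gx <- door_c[1] - x[i - 1]
        gy <- door_c[2] - y[i - 1]
        gn <- sqrt(gx^2 + gy^2)
        if (gn > 1e-9) {
          sx <- sx + 1.5 * config$speed_mean * gx / gn
          sy <- sy + 1.5 * config$speed_mean * gy / gn
        }
        shuttle_left <- shuttle_left - 1L
        if ((x[i - 1] < arena$midline) != start_comp ||
            shuttle_left <= 0L) {
          shuttling <- FALSE
        }
      }
      vx <- config$momentum * vx + (1 - config$momentum) * sx
      vy <- config$momentum * vy + (1 - config$momentum) * sy
      spd <- sqrt(vx^2 + vy^2)
      if (spd > config$max_speed) {
        vx <- vx * config$max_speed / spd
        vy <- vy * config$max_speed / spd
      }
      nx <- x[i - 1] + vx * dt
      ny <- y[i - 1] + vy * dt
      if (ny < 0) { ny <- -ny; vy <- -vy }
      if (ny > arena$height) { ny <- 2 * arena$height - ny; vy <- -vy }
      if (nx < 0) { nx <- -nx; vx <- -vx }
      if (nx > arena$width) { nx <- 2 * arena$width - nx; vx <- -vx }
      crossed <- (x[i - 1] < arena$midline) != (nx < arena$midline)
      if (crossed &&
          (!shuttling || !(ny >= arena$door[1] && ny <= arena$door[2]))) {
        # partition is crossed only through the door and only during a
        # deliberate shuttle; otherwise bounce off
        nx <- 2 * arena$midline - nx
        vx <- -vx
      }
      x[i] <- nx
      y[i] <- ny
    }
    if (n == 1) { x <- x[1]; y <- y[1] }
    dx <- c(0, diff(x))
    dy <- c(0, diff(y))
    speed <- sqrt(dx^2 + dy^2) / dt
    hd <- atan2(dy, dx)
    if (n > 1) hd[1] <- hd[2]
    still <- speed < 1e-9
    if (any(still)) {
      # carry the last moving heading through pauses
      ok <- which(!still)
      if (length(ok) > 0) {
        idx <- findInterval(seq_len(n), ok)
        idx[idx == 0] <- 1
        hd <- hd[ok[idx]]
      }
    }
    hd <- (hd + rnorm(n, 0, config$hd_noise_sd) + pi) %% (2 * pi) - pi
    out <- tibble::tibble(
      t = (seq_len(n) - 1) * dt, x = x, y = y, speed = speed, hd = hd,
      compartment = compartment_of(arena, x)
    )
    class(out) <- c("cpp_trajectory", class(out))
    out
  })
}

#' Define a synthetic neuron population with ground truth
#'
#' Builds the per-neuron ground-truth table that drives event simulation:
#' 2D Gaussian place fields (homotopic across compartments with a rate
#' difference, or independent field locations), optional head-direction and
#' speed modulation, planted session effects, temporal-cluster membership
#' tied to spatial sectors, and anatomical centroids.
#'
#' Session-effect labels: `"stable"` (tuning unchanged), `"disappear"`
#' (tuning in `disappear_comp` removed in test sessions), `"appear"`
#' (tuning in `appear_comp` present only in test sessions), `"remap"`
#' (field centres move in test sessions) and `"untuned"` (no place field).
#'
#' @param arena An [arena_spec()].
#' @param n_stable,n_disappear,n_appear,n_remap,n_untuned Counts per
#'   session-effect label.
#' @param disappear_comp,appear_comp Compartment affected by the planted
#'   effect, `"left"` or `"right"`.
#' @param homotopic_frac Fraction of tuned neurons whose two fields sit at
#'   homotopic positions (rate remapping); the rest get independent
#'   per-compartment centres (global remapping).
#' @param field_sd_range Range (cm) of field widths, drawn uniformly.
#' @param peak_range Range of peak event probability per frame.
#' @param rate_ratio_range Range of the cross-compartment peak-rate ratio
#'   for homotopic fields.
#' @param hd_frac,speed_frac Fractions of neurons with head-direction /
#'   speed modulation.
#' @param n_clusters If `> 0` (use 5), neurons are assigned to temporally
#'   coherent clusters whose fields concentrate in the four compartment
#'   sectors (SW, NW, SE, NE, homotopic in both compartments) plus a
#'   junction-centred cluster; anatomical centroids also cluster.
#' @param coactivation Strength of the slow shared excitability gain that
#'   co-modulates the members of a cluster (log-normal SD of the gain;
#'   0 disables). Applied only when `n_clusters > 0`: cluster membership
#'   is expressed both through shared spatial sectors and through genuine
#'   temporal co-activity, as in synchronously active CA1 ensembles.
#' @param baseline_p Spontaneous event probability per frame for every
#'   neuron (keeps shuffle controls non-degenerate).
#' @param seed Integer seed.
#' @return A tibble of class `cpp_truth`, one row per neuron.
#' @export
neuron_population <- function(arena,
                              n_stable = 60, n_disappear = 0, n_appear = 0,
                              n_remap = 0, n_untuned = 20,
                              disappear_comp = "left", appear_comp = "left",
                              homotopic_frac = 0.7,
                              field_sd_range = c(4, 6),
                              peak_range = c(0.05, 0.12),
                              rate_ratio_range = c(0.4, 1),
                              hd_frac = 0, speed_frac = 0,
                              n_clusters = 0, coactivation = 0.6,
                              baseline_p = 0.002,
                              seed = NULL) {
  n <- n_stable + n_disappear + n_appear + n_remap + n_untuned
  stopifnot(n > 0)
  cmp <- arena$compartment_cm
  with_seed(seed, {
    effect <- sample(rep(
      c("stable", "disappear", "appear", "remap", "untuned"),
      c(n_stable, n_disappear, n_appear, n_remap, n_untuned)
    ))
    q <- cmp / 4
    sectors <- list(
      SW = c(q, q), NW = c(q, 3 * q), SE = c(3 * q, q), NE = c(3 * q, 3 * q)
    )
    if (n_clusters > 0) {
      cluster <- sort(rep_len(seq_len(n_clusters), n))
      sector_names <- c(names(sectors), "center")[seq_len(min(n_clusters, 5))]
      sector_of <- rep_len(sector_names, n_clusters)
    } else {
      cluster <- rep(NA_integer_, n)
    }
    draw_center <- function(i) {
      if (n_clusters > 0) {
        sec <- sector_of[cluster[i]]
        if (sec == "center") return(c(NA, NA))  # junction neuron
        pmin(pmax(sectors[[sec]] + rnorm(2, 0, 2.5), 2), cmp - 2)
      } else {
        runif(2, 2, cmp - 2)
      }
    }
    cx_left <- numeric(n); cy_left <- numeric(n)
    cx_right <- numeric(n); cy_right <- numeric(n)
    junction <- logical(n)
    homotopic <- runif(n) < homotopic_frac
    for (i in seq_len(n)) {
      ctr <- draw_center(i)
      if (any(is.na(ctr))) {
        junction[i] <- TRUE
        cx_left[i] <- arena$midline + rnorm(1, 0, 1.5)
        cy_left[i] <- mean(arena$door) + rnorm(1, 0, 1.5)
        cx_right[i] <- cx_left[i]; cy_right[i] <- cy_left[i]
      } else {
        cx_left[i] <- ctr[1]; cy_left[i] <- ctr[2]
        if (homotopic[i]) {
          cx_right[i] <- ctr[1] + arena$midline; cy_right[i] <- ctr[2]
        } else {
          ctr2 <- if (n_clusters > 0) {
            pmin(pmax(ctr + rnorm(2, 0, 4), 2), cmp - 2)
          } else {
            runif(2, 2, cmp - 2)
          }
          cx_right[i] <- ctr2[1] + arena$midline; cy_right[i] <- ctr2[2]
        }
      }
    }
    peak <- runif(n, peak_range[1], peak_range[2])
    ratio <- runif(n, rate_ratio_range[1], rate_ratio_range[2])
    flip <- runif(n) < 0.5  # which compartment gets the weaker field
    peak_left <- ifelse(flip, peak * ratio, peak)
    peak_right <- ifelse(flip, peak, peak * ratio)
    peak_left[effect == "untuned"] <- 0
    peak_right[effect == "untuned"] <- 0
    # untuned neurons stay active (spatially flat) so they pass the
    # mean-rate gate and exercise the specificity of the shuffle test
    base_p <- rep(baseline_p, n)
    base_p[effect == "untuned"] <- runif(sum(effect == "untuned"),
                                         0.004, 0.012)
    # remap targets (used in test sessions by "remap" neurons)
    cx_left2 <- runif(n, 2, cmp - 2)
    cy_left2 <- runif(n, 2, cmp - 2)
    cx_right2 <- runif(n, 2, cmp - 2) + arena$midline
    cy_right2 <- runif(n, 2, cmp - 2)
    if (n_clusters > 0) {
      anat_c <- matrix(runif(2 * max(cluster, 1), 50, 450),
                       ncol = 2)[cluster, , drop = FALSE]
      anat <- anat_c + matrix(rnorm(2 * n, 0, 20), ncol = 2)
    } else {
      anat <- matrix(runif(2 * n, 0, 500), ncol = 2)
    }
    out <- tibble::tibble(
      neuron = seq_len(n),
      effect = effect,
      effect_comp = ifelse(effect == "disappear", disappear_comp,
                           ifelse(effect == "appear", appear_comp, NA)),
      junction = junction,
      cx_left = cx_left, cy_left = cy_left,
      cx_right = cx_right, cy_right = cy_right,
      cx_left_test = cx_left2, cy_left_test = cy_left2,
      cx_right_test = cx_right2, cy_right_test = cy_right2,
      field_sd = runif(n, field_sd_range[1], field_sd_range[2]),
      peak_left = peak_left, peak_right = peak_right,
      hd_pref = runif(n, -pi, pi),
      hd_kappa = ifelse(runif(n) < hd_frac, runif(n, 1.5, 3), 0),
      speed_mod = runif(n) < speed_frac,
      speed_exp = 2,
      baseline_p = base_p,
      cluster = cluster,
      coactivation = ifelse(is.na(cluster), 0, coactivation),
      anat_x = anat[, 1], anat_y = anat[, 2]
    )
    class(out) <- c("cpp_truth", class(out))
    out
  })
}

SESSION_LABELS <- c("pre_bsl", "bsl", "cond", "test1", "test2")

# Per-frame event probability for one neuron in one session.
event_probability <- function(truth_row, traj, session) {
  if (!session %in% SESSION_LABELS) {
    stop("unknown session label: ", session)
  }
  tr <- truth_row
  is_test <- session %in% c("test1", "test2")
  p <- rep(tr$baseline_p, nrow(traj))
  if (nrow(traj) == 0) return(p)
  gauss <- function(cx, cy) {
    exp(-((traj$x - cx)^2 + (traj$y - cy)^2) / (2 * tr$field_sd^2))
  }
  for (comp in c("left", "right")) {
    gain <- 1
    if (!is.na(tr$effect_comp) && tr$effect_comp == comp) {
      if (tr$effect == "disappear" && is_test) gain <- 0
      if (tr$effect == "appear" && !is_test) gain <- 0
    }
    if (gain == 0) next
    if (tr$effect == "remap" && is_test) {
      cx <- if (comp == "left") tr$cx_left_test else tr$cx_right_test
      cy <- if (comp == "left") tr$cy_left_test else tr$cy_right_test
    } else {
      cx <- if (comp == "left") tr$cx_left else tr$cx_right
      cy <- if (comp == "left") tr$cy_left else tr$cy_right
    }
    pk <- if (comp == "left") tr$peak_left else tr$peak_right
    if (pk <= 0) next
    sel <- if (tr$junction) rep(TRUE, nrow(traj)) else traj$compartment == comp
    if (tr$junction && comp == "right") next  # single junction field
    g <- pk * gauss(cx, cy)
    if (tr$hd_kappa > 0) {
      # von Mises gain normalized to unit mean over uniform headings,
      # so head-direction tuning modulates without changing mean rate
      g <- g * exp(tr$hd_kappa * cos(traj$hd - tr$hd_pref)) /
        besselI(tr$hd_kappa, 0)
    }
    if (isTRUE(tr$speed_mod)) {
      # power-law ramp saturating at 15 cm/s, normalized to roughly unit
      # mean over the typical filtered speed distribution
      e <- if ("speed_exp" %in% names(tr)) tr$speed_exp else 2
      g <- g * (pmin(traj$speed, 15) / 7.5)^e / (if (e >= 3) 0.55 else 0.7)
    }
    p[sel] <- p[sel] + g[sel]
  }
  pmin(p, 0.95)
}

#' Simulate deconvolved calcium activity for a population
#'
#' Draws per-frame Bernoulli events from each neuron's tuning evaluated at
#' the animal's position (with optional head-direction and speed gains and
#' a spontaneous baseline probability), applies the planted session effect,
#' and assigns positive amplitudes to event frames.
#'
#' @param truth A [neuron_population()] tibble.
#' @param traj A [simulate_trajectory()] trajectory for the session.
#' @param session One of `"pre_bsl"`, `"bsl"`, `"cond"`, `"test1"`,
#'   `"test2"`.
#' @param seed Integer seed.
#' @return A list of class `cpp_events` with `amplitudes` (neurons x
#'   frames, non-negative), `events` (the generative binary matrix) and
#'   `frame_rate`.
#' @export
simulate_events <- function(truth, traj, session, seed = NULL) {
  stopifnot(inherits(truth, "cpp_truth"))
  if (nrow(traj) == 0) stop("trajectory is empty")
  n <- nrow(truth)
  nf <- nrow(traj)
  fr <- 1 / diff(traj$t[1:2])
  with_seed(seed, {
    amp <- matrix(0, n, nf)
    ev <- matrix(0L, n, nf)
    # slow shared excitability gain per temporally co-active cluster
    gains <- list()
    has_coact <- all(c("cluster", "coactivation") %in% names(truth)) &&
      any(!is.na(truth$cluster) & truth$coactivation > 0)
    if (has_coact) {
      decay <- exp(-1 / (0.5 * fr))  # ~0.5 s correlation time
      norm <- sqrt(1 - decay^2)
      ks <- sort(unique(truth$cluster[!is.na(truth$cluster)]))
      zs <- vapply(ks, function(k) {
        as.numeric(stats::filter(rnorm(nf), decay,
                                 method = "recursive")) * norm
      }, numeric(nf))
      # competitive ensembles: excitability is relative to the momentary
      # population mean, so clusters alternate rather than co-vary
      if (length(ks) > 1) zs <- zs - rowMeans(zs)
      for (j in seq_along(ks)) gains[[as.character(ks[j])]] <- zs[, j]
    }
    for (i in seq_len(n)) {
      p <- event_probability(truth[i, ], traj, session)
      if (has_coact && !is.na(truth$cluster[i]) &&
          truth$coactivation[i] > 0) {
        co <- truth$coactivation[i]
        z <- gains[[as.character(truth$cluster[i])]]
        # log-normal gain with unit mean: tuning scales up and down
        # coherently within the cluster
        p <- pmin(p * exp(co * z - co^2 / 2), 0.95)
      }
      hit <- runif(nf) < p
      k <- sum(hit)
      if (k > 0) {
        ev[i, hit] <- 1L
        amp[i, hit] <- rgamma(k, shape = 2, scale = 0.5) + 0.05
      }
    }
    structure(
      list(amplitudes = amp, events = ev, frame_rate = fr),
      class = "cpp_events"
    )
  })
}

#' Simulate a complete synthetic CPP experiment
#'
#' Generates the ordered sessions of a CPP study (pre-baseline, baseline,
#' test 1, test 2; optionally a conditioning session) with a shared neuron
#' population. Baseline sessions are biased toward the naturally preferred
#' compartment; test sessions shift the bias toward the drug-paired
#' (initially non-preferred) compartment, emulating the conditioned
#' preference.
#'
#' @param arena An [arena_spec()].
#' @param truth A [neuron_population()] ground-truth table.
#' @param duration_s Per-session duration in seconds.
#' @param frame_rate Sampling rate (Hz).
#' @param preferred Naturally preferred compartment (`"left"` or
#'   `"right"`); the drug is paired with the other one.
#' @param baseline_bias Occupancy bias toward `preferred` in pre-baseline
#'   and baseline sessions.
#' @param test_bias Occupancy bias toward the drug-paired compartment in
#'   test sessions.
#' @param include_conditioning If `TRUE`, also simulate a conditioning
#'   session (confined sampling; not analysed downstream).
#' @param seed Master seed; every per-session seed is derived from it.
#' @return A list of class `cpp_experiment` with `arena`, `truth`,
#'   `preferred`, `drug_paired` and `sessions` (each a list with `traj`
#'   and `activity`).
#' @examples
#' arena <- arena_spec()
#' pop <- neuron_population(arena, n_stable = 5, n_untuned = 2, seed = 1)
#' exp <- simulate_experiment(arena, pop, duration_s = 30, seed = 1)
#' names(exp$sessions)
#' @export
simulate_experiment <- function(arena, truth,
                                duration_s = 900, frame_rate = 30,
                                preferred = "left",
                                baseline_bias = 0.2, test_bias = 0.2,
                                include_conditioning = FALSE,
                                seed = NULL) {
  stopifnot(inherits(truth, "cpp_truth"))
  preferred <- match.arg(preferred, c("left", "right"))
  drug <- setdiff(c("left", "right"), preferred)
  sess <- c("pre_bsl", "bsl", if (include_conditioning) "cond",
            "test1", "test2")
  seeds <- spawn_seeds(seed, 2 * length(sess))
  sessions <- list()
  for (k in seq_along(sess)) {
    s <- sess[k]
    bias <- switch(s,
      pre_bsl = , bsl = baseline_bias,
      cond = 0.8,
      test1 = , test2 = test_bias
    )
    comp <- if (s %in% c("test1", "test2", "cond")) drug else preferred
    cfg <- sim_config(
      duration_s = duration_s, frame_rate = frame_rate,
      occupancy_bias = bias, bias_compartment = comp,
      seed = seeds[[2 * k - 1]]
    )
    traj <- simulate_trajectory(arena, cfg)
    act <- simulate_events(truth, traj, s, seed = seeds[[2 * k]])
    sessions[[s]] <- list(traj = traj, activity = act)
  }
  structure(
    list(arena = arena, truth = truth, preferred = preferred,
         drug_paired = drug, frame_rate = frame_rate, sessions = sessions),
    class = "cpp_experiment"
  )
}

#' @export
print.cpp_experiment <- function(x, ...) {
  cat(sprintf(
    "<cpp_experiment> %d neurons, sessions: %s\n",
    nrow(x$truth), paste(names(x$sessions), collapse = ", ")
  ))
  invisible(x)
}
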