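#' Time in each compartment and the CPP score
#'
#' The CPP score is the time spent in the drug-paired compartment in a
#' test session minus the time spent in the same compartment in baseline.
#'
#' @param traj_baseline,traj_test Trajectory tibbles.
#' @param drug_paired Drug-paired compartment, `"left"` or `"right"`.
#' @return A one-row tibble with per-compartment times (s) for both
#'   sessions and `cpp_score` (s).
#' @examples
#' # equal occupancy in both sessions gives a score of 0
#' @export
cpp_score <- function(traj_baseline, traj_test, drug_paired = "right") {
  drug_paired <- match.arg(drug_paired, c("left", "right"))
  dt_b <- diff(traj_baseline$t[1:2])
  dt_t <- diff(traj_test$t[1:2])
  tb <- sum(traj_baseline$compartment == drug_paired) * dt_b
  tt <- sum(traj_test$compartment == drug_paired) * dt_t
  tibble::tibble(
    drug_paired = drug_paired,
    baseline_drug_s = tb,
    test_drug_s = tt,
    baseline_other_s = nrow(traj_baseline) * dt_b - tb,
    test_other_s = nrow(traj_test) * dt_t - tt,
    cpp_score = tt - tb
  )
}

#' Preferred compartment from baseline occupancy
#'
#' The naturally preferred compartment is the one occupied for the
#' majority of the baseline session. Exact ties break toward `"left"`.
#'
#' @param traj Baseline trajectory tibble.
#' @return `"left"` or `"right"`.
#' @export
preferred_compartment <- function(traj) {
  if (sum(traj$compartment == "left") >= sum(traj$compartment == "right")) {
    "left"
  } else {
    "right"
  }
}

#' Functional cell types from per-session place-cell flags
#'
#' Applies the functional taxonomy to per-compartment place-cell flags in
#' baseline and the two test sessions:
#' * `disPCp` / `disPCnp`: place cell in the preferred / non-preferred
#'   compartment at baseline that lost tuning there in **both** test
#'   sessions;
#' * `aPCp` / `aPCnp`: untuned there at baseline but a place cell in
#'   **both** test sessions;
#' * `rtPCp`: preferred-compartment place cell at baseline retaining
#'   tuning there in at least one test session (mutually exclusive with
#'   `disPCp`).
#' A neuron may satisfy definitions in both compartments (e.g. `disPCp`
#' and `aPCnp`); all indicator columns are returned, and `label` reports
#' one type with precedence disPCp > disPCnp > aPCp > aPCnp > rtPCp >
#' other. Neurons with missing flags are skipped (`label = NA`).
#'
#' @param flags A tibble with columns `neuron`, `session` (`"bsl"`,
#'   `"test1"`, `"test2"`), `compartment` (`"left"`/`"right"`) and
#'   `is_place_cell` — e.g. stacked [classify_place_cells()] results.
#' @param preferred The naturally preferred compartment.
#' @return A tibble with one row per neuron: logical columns `disPCp`,
#'   `disPCnp`, `aPCp`, `aPCnp`, `rtPCp` and the `label` summary.
#' @export
assign_functional_types <- function(flags, preferred = "left") {
  preferred <- match.arg(preferred, c("left", "right"))
  nonpref <- setdiff(c("left", "right"), preferred)
  wide <- flags |>
    dplyr::mutate(side = ifelse(.data$compartment == preferred,
                                "pref", "npref")) |>
    dplyr::select("neuron", "session", "side", "is_place_cell") |>
    tidyr::pivot_wider(names_from = c("session", "side"),
                       values_from = "is_place_cell")
  need <- c("bsl_pref", "test1_pref", "test2_pref",
            "bsl_npref", "test1_npref", "test2_npref")
  missing_cols <- setdiff(need, names(wide))
  for (m in missing_cols) wide[[m]] <- NA
  complete <- stats::complete.cases(wide[need])
  w <- wide
  w$disPCp <- w$bsl_pref & !w$test1_pref & !w$test2_pref
  w$disPCnp <- w$bsl_npref & !w$test1_npref & !w$test2_npref
  w$aPCp <- !w$bsl_pref & w$test1_pref & w$test2_pref
  w$aPCnp <- !w$bsl_npref & w$test1_npref & w$test2_npref
  w$rtPCp <- w$bsl_pref & (w$test1_pref | w$test2_pref)
  lab <- rep(NA_character_, nrow(w))
  for (type in c("other", "rtPCp", "aPCnp", "aPCp", "disPCnp", "disPCp")) {
    if (type == "other") {
      lab[complete] <- "other"
    } else {
      lab[complete & w[[type]]] <- type
    }
  }
  w$label <- lab
  w[!complete, c("disPCp", "disPCnp", "aPCp", "aPCnp", "rtPCp")] <- NA
  dplyr::select(
    w, "neuron", dplyr::all_of(need),
    "disPCp", "disPCnp", "aPCp", "aPCnp", "rtPCp", "label"
  )
}

#' Rate versus non-rate remapping
#'
#' Classifies a place cell by its baseline inter-compartment rate-map
#' correlation (computed on occupancy-matched maps): a correlation
#' strictly greater than `threshold` indicates rate remapping (same field
#' location, different rate); otherwise non-rate (global) remapping.
#'
#' @param correlation Numeric vector of inter-compartment correlations.
#' @param threshold Correlation threshold (default 0.4).
#' @return Character vector: `"rate"`, `"non-rate"` or `NA` when the
#'   correlation is undefined.
#' @export
classify_rate_remapping <- function(correlation, threshold = 0.4) {
  ifelse(is.na(correlation), NA_character_,
         ifelse(correlation > threshold, "rate", "non-rate"))
}

#' Proportions of functional cell types
#'
#' @param types Output of [assign_functional_types()].
#' @param total Denominator; defaults to the number of neurons with
#'   complete flags.
#' @return A tibble with one row per type: `n` and `fraction`.
#' @export
turnover_proportions <- function(types, total = NULL) {
  cols <- c("disPCp", "disPCnp", "aPCp", "aPCnp", "rtPCp")
  ok <- !is.na(types$label)
  if (is.null(total)) total <- sum(ok)
  if (total == 0) stop("zero denominator: no neurons with complete flags")
  purrr::map_dfr(cols, function(cl) {
    tibble::tibble(type = cl, n = sum(types[[cl]][ok]),
                   fraction = sum(types[[cl]][ok]) / total)
  })
}

#' Inter-compartment correlation difference (CorrDiff)
#'
#' For each neuron of a designated cell type, the inter-compartment
#' rate-map correlation (occupancy-matched across compartments) is
#' computed in the baseline session and in a test session; CorrDiff is
#' baseline minus test, aggregated over the cells of the type. A session
#' pair yields one value per animal, so baseline versus test 1 and
#' baseline versus test 2 give two values per animal.
#'
#' @param traj_baseline,traj_test Trajectory tibbles.
#' @param events_baseline,events_test `cpp_events` objects or binary
#'   matrices.
#' @param arena An [arena_spec()].
#' @param neurons Indices of the cells of the designated type.
#' @param n_iter Matching iterations per session (default 50).
#' @param aggregate `"mean"` (default) or `"median"` across cells.
#' @param smooth_sd,bin_cm As in [compute_maps()].
#' @param seed Master seed.
#' @return A list with `corr_diff` (the aggregated per-animal value),
#'   `per_neuron` (tibble of baseline/test correlations and differences)
#'   and `n_cells`. Swapping baseline and test flips the sign.
#' @export
corr_diff <- function(traj_baseline, events_baseline,
                      traj_test, events_test, arena, neurons,
                      n_iter = 50, aggregate = c("mean", "median"),
                      smooth_sd = 2, bin_cm = 1.8, seed = NULL) {
  aggregate <- match.arg(aggregate)
  if (length(neurons) == 0) {
    return(list(corr_diff = NA_real_,
                per_neuron = tibble::tibble(), n_cells = 0L))
  }
  seeds <- spawn_seeds(seed, 2)
  mb <- intercompartment_metrics(
    traj_baseline, events_baseline, arena, neurons = neurons,
    n_iter = n_iter, bin_cm = bin_cm, smooth_sd = smooth_sd,
    seed = seeds[[1]]
  )
  mt <- intercompartment_metrics(
    traj_test, events_test, arena, neurons = neurons,
    n_iter = n_iter, bin_cm = bin_cm, smooth_sd = smooth_sd,
    seed = seeds[[2]]
  )
  per <- tibble::tibble(
    neuron = neurons,
    corr_baseline = mb$correlation,
    corr_test = mt$correlation,
    diff = mb$correlation - mt$correlation
  )
  agg_fun <- if (aggregate == "mean") mean else median
  list(
    corr_diff = agg_fun(per$diff, na.rm = TRUE),
    per_neuron = per,
    n_cells = length(neurons)
  )
}
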