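#' Analysis configuration
#'
#' Collects every tunable parameter of the pipeline in one list. Defaults
#' follow the study conditions; iteration counts can be reduced for smoke
#' tests.
#'
#' @param bin_cm Spatial bin pitch (cm).
#' @param smooth_sd Rate-map smoothing SD in bins.
#' @param speed_threshold Speed filter (cm/s).
#' @param event_k Binarization threshold multiplier.
#' @param min_bin_occupancy_s Bin exclusion threshold (s).
#' @param n_match_iters Occupancy-matching iterations for map metrics.
#' @param pci_iters,pci_shuffles Matching iterations and circular
#'   shuffles for place-cell classification.
#' @param decoder_dt Decoder time-bin width (s).
#' @param decoder_shuffles Decoder shuffle-control count.
#' @param two_step Use the two-step decoder in the report.
#' @param cluster_k Number of temporal clusters.
#' @param cluster_iters Consensus iterations.
#' @param ln_enabled Run the LN model stage.
#' @param ln_max_neurons Cap on neurons sent to the LN stage.
#' @param ln_shuffles LN shuffle count per fold.
#' @param seed Master seed for all stochastic sub-procedures.
#' @return A list of class `cpp_config`.
#' @export
analysis_config <- function(bin_cm = 1.8, smooth_sd = 2,
                            speed_threshold = 2, event_k = 3,
                            min_bin_occupancy_s = 0.1,
                            n_match_iters = 50,
                            pci_iters = 20, pci_shuffles = 1000,
                            decoder_dt = 0.8, decoder_shuffles = 100,
                            two_step = TRUE,
                            cluster_k = 5, cluster_iters = 100,
                            ln_enabled = FALSE, ln_max_neurons = 20,
                            ln_shuffles = 500,
                            seed = 1L) {
  structure(as.list(environment()), class = "cpp_config")
}

#' Run the full CPP analysis on one experiment
#'
#' Orchestrates preprocessing, place-cell classification, functional cell
#' typing, CorrDiff, Bayesian decoding with knock-out, temporal
#' clustering with template sorting, and (optionally) LN-model
#' classification on an experiment's baseline and test sessions. All
#' randomness derives from `config$seed`.
#'
#' @param experiment A [simulate_experiment()] object (or one read with
#'   [read_experiment()]).
#' @param config An [analysis_config()].
#' @return A list of class `cpp_report` with tibbles `behavior`,
#'   `place_cells`, `cell_types`, `type_proportions`, `remapping`,
#'   `corr_diff`, `decoding`, `clustering` and (optionally) `ln_models`,
#'   plus a `provenance` list (config and seeds).
#' @export
run_cpp_analysis <- function(experiment, config = analysis_config()) {
  stopifnot(inherits(experiment, "cpp_experiment"))
  arena <- experiment$arena
  seeds <- spawn_seeds(config$seed, 12)
  analyzed <- intersect(c("bsl", "test1", "test2"),
                        names(experiment$sessions))
  stopifnot(all(c("bsl", "test1", "test2") %in% analyzed))
  sess <- lapply(experiment$sessions[analyzed], function(s) {
    act <- binarize_events(s$activity, k = config$event_k)
    frames <- speed_filter(s$traj, config$speed_threshold)
    list(traj = s$traj, act = act, frames = frames)
  })
  preferred <- preferred_compartment(sess$bsl$traj)
  drug <- setdiff(c("left", "right"), preferred)

  behavior <- purrr::map_dfr(c("test1", "test2"), function(ts) {
    dplyr::mutate(
      cpp_score(sess$bsl$traj, sess[[ts]]$traj, drug_paired = drug),
      session = ts, .before = 1
    )
  })

  pc <- purrr::imap_dfr(sess, function(s, nm) {
    dplyr::mutate(
      classify_place_cells(
        s$traj, s$act, arena, frames = s$frames,
        n_iter = config$pci_iters, n_shuffles = config$pci_shuffles,
        bin_cm = config$bin_cm, min_occupancy_s = config$min_bin_occupancy_s,
        seed = seeds[[1]]
      ),
      session = nm, .before = 1
    )
  })

  types <- assign_functional_types(pc, preferred = preferred)
  props <- turnover_proportions(types)

  inter_bsl <- intercompartment_metrics(
    sess$bsl$traj, sess$bsl$act, arena, frames = sess$bsl$frames,
    n_iter = config$n_match_iters, bin_cm = config$bin_cm,
    smooth_sd = config$smooth_sd, seed = seeds[[2]]
  )
  remapping <- dplyr::mutate(
    inter_bsl,
    remap_class = classify_rate_remapping(.data$correlation)
  )

  dis_idx <- which(!is.na(types$disPCp) & types$disPCp)
  cd <- purrr::map_dfr(c("test1", "test2"), function(ts) {
    r <- corr_diff(sess$bsl$traj, sess$bsl$act,
                   sess[[ts]]$traj, sess[[ts]]$act,
                   arena, neurons = dis_idx,
                   n_iter = config$n_match_iters,
                   bin_cm = config$bin_cm, smooth_sd = config$smooth_sd,
                   seed = seeds[[3]])
    tibble::tibble(session = ts, cell_type = "disPCp",
                   corr_diff = r$corr_diff, n_cells = r$n_cells)
  })

  b_train <- bin_activity(sess$bsl$traj, sess$bsl$act, arena,
                          frames = sess$bsl$frames,
                          dt = config$decoder_dt, bin_cm = config$bin_cm)
  b_test <- bin_activity(sess$test1$traj, sess$test1$act, arena,
                         frames = sess$test1$frames,
                         dt = config$decoder_dt, bin_cm = config$bin_cm)
  model <- train_decoder(b_train)
  err1 <- decoding_error(decode(model, b_test), b_test)
  err2 <- decoding_error(decode_2step(model, b_test), b_test)
  shuf <- shuffle_control(model, b_test, n = config$decoder_shuffles,
                          seed = seeds[[4]])
  ko <- if (length(dis_idx) > 0) {
    ko_contrast(model, b_test, dis_idx, arena,
                two_step = config$two_step, seed = seeds[[5]])
  } else tibble::tibble()
  decoding <- tibble::tibble(
    train = "bsl", test = "test1",
    error_1step = err1, error_2step = err2,
    shuffle_error = mean(shuf$error),
    ko_error = if (nrow(ko)) ko$error[ko$condition == "ko"] else NA_real_,
    random_ko_error = if (nrow(ko)) {
      mean(ko$error[ko$condition == "random"])
    } else NA_real_
  )

  cons <- build_consensus_matrix(
    sess$bsl$act$amplitudes, K = config$cluster_k,
    iters = config$cluster_iters, seed = seeds[[6]]
  )
  assignment <- cut_clusters(cons)
  emaps <- ensemble_rate_maps(sess$bsl$traj, sess$bsl$act, arena,
                              assignment, frames = sess$bsl$frames,
                              bin_cm = config$bin_cm,
                              smooth_sd = config$smooth_sd)
  sectors <- if (length(emaps) == 5) {
    match_templates(emaps, arena, bin_cm = config$bin_cm)
  } else tibble::tibble()
  clustering <- tibble::tibble(
    neuron = seq_along(assignment), cluster = assignment
  ) |>
    dplyr::left_join(
      if (nrow(sectors)) {
        dplyr::mutate(sectors, cluster = as.integer(.data$cluster))
      } else tibble::tibble(cluster = integer(0),
                            sector = character(0),
                            correlation = numeric(0)),
      by = "cluster"
    )

  report <- list(
    behavior = behavior,
    place_cells = pc,
    cell_types = types,
    type_proportions = props,
    remapping = remapping,
    corr_diff = cd,
    decoding = decoding,
    clustering = clustering,
    preferred = preferred,
    drug_paired = drug,
    provenance = list(config = unclass(config), seeds = seeds)
  )
  if (config$ln_enabled) {
    keep <- head(order(rowSums(sess$bsl$act$events), decreasing = TRUE),
                 config$ln_max_neurons)
    des <- build_design(sess$bsl$traj, sess$bsl$act, arena,
                        frames = sess$bsl$frames, bin_cm = config$bin_cm)
    report$ln_models <- classify_ln_neurons(
      des, neurons = keep, n_shuffles = config$ln_shuffles,
      seed = seeds[[7]]
    )
  }
  structure(report, class = "cpp_report")
}

#' @export
print.cpp_report <- function(x, ...) {
  cat("<cpp_report>\n")
  cat(sprintf("  preferred: %s, drug-paired: %s\n",
              x$preferred, x$drug_paired))
  cat(sprintf("  CPP scores (s): %s\n",
              paste(sprintf("%s %.1f", x$behavior$session,
                            x$behavior$cpp_score), collapse = ", ")))
  cat(sprintf("  decoding error (cm): 1-step %.2f, 2-step %.2f, chance %.2f\n",
              x$decoding$error_1step, x$decoding$error_2step,
              x$decoding$shuffle_error))
  invisible(x)
}

#' Write an experiment to a plain-text fixture directory
#'
#' Stores one experiment as CSV tables plus a JSON header: per session a
#' trajectory table and a sparse long-format activity table (non-zero
#' amplitudes only), and the ground-truth table when present.
#'
#' @param experiment A `cpp_experiment`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_experiment <- function(experiment, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  hdr <- list(
    compartment_cm = experiment$arena$compartment_cm,
    door_cm = experiment$arena$door_cm,
    preferred = experiment$preferred,
    frame_rate = experiment$frame_rate,
    n_neurons = nrow(experiment$truth),
    sessions = names(experiment$sessions)
  )
  jsonlite::write_json(hdr, file.path(path, "experiment.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in names(experiment$sessions)) {
    ses <- experiment$sessions[[s]]
    utils::write.csv(ses$traj, file.path(path, paste0("traj_", s, ".csv")),
                     row.names = FALSE)
    amp <- ses$activity$amplitudes
    nz <- which(amp > 0, arr.ind = TRUE)
    utils::write.csv(
      data.frame(neuron = nz[, 1], frame = nz[, 2], amplitude = amp[nz]),
      file.path(path, paste0("activity_", s, ".csv")), row.names = FALSE
    )
  }
  if (!is.null(experiment$truth)) {
    utils::write.csv(experiment$truth, file.path(path, "truth.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Read an experiment fixture directory
#'
#' @param path Directory written by [write_experiment()].
#' @return A `cpp_experiment`.
#' @export
read_experiment <- function(path) {
  hdr <- jsonlite::read_json(file.path(path, "experiment.json"),
                             simplifyVector = TRUE)
  arena <- arena_spec(hdr$compartment_cm, hdr$door_cm)
  sessions <- list()
  for (s in hdr$sessions) {
    traj <- tibble::as_tibble(
      utils::read.csv(file.path(path, paste0("traj_", s, ".csv")))
    )
    class(traj) <- c("cpp_trajectory", class(traj))
    act_df <- utils::read.csv(file.path(path, paste0("activity_", s, ".csv")))
    amp <- matrix(0, hdr$n_neurons, nrow(traj))
    if (nrow(act_df) > 0) {
      amp[cbind(act_df$neuron, act_df$frame)] <- act_df$amplitude
    }
    sessions[[s]] <- list(
      traj = traj,
      activity = structure(
        list(amplitudes = amp, events = (amp > 0) * 1L,
             frame_rate = hdr$frame_rate),
        class = "cpp_events"
      )
    )
  }
  truth <- NULL
  tf <- file.path(path, "truth.csv")
  if (file.exists(tf)) {
    truth <- tibble::as_tibble(utils::read.csv(tf))
    class(truth) <- c("cpp_truth", class(truth))
  }
  structure(
    list(arena = arena, truth = truth, preferred = hdr$preferred,
         drug_paired = setdiff(c("left", "right"), hdr$preferred),
         frame_rate = hdr$frame_rate, sessions = sessions),
    class = "cpp_experiment"
  )
}

#' Validate an experiment fixture directory
#'
#' Checks the schema: header present, every session has a trajectory and
#' an activity table, neuron indices within bounds, and neuron counts
#' identical across sessions.
#'
#' @param path Fixture directory.
#' @return A tibble of diagnostics (`file`, `problem`); zero rows when
#'   the fixture is valid.
#' @export
validate_fixture <- function(path) {
  probs <- list()
  note <- function(file, problem) {
    probs[[length(probs) + 1]] <<- tibble::tibble(file = file,
                                                  problem = problem)
  }
  hf <- file.path(path, "experiment.json")
  if (!file.exists(hf)) {
    note("experiment.json", "missing header")
    return(dplyr::bind_rows(probs))
  }
  hdr <- tryCatch(jsonlite::read_json(hf, simplifyVector = TRUE),
                  error = function(e) NULL)
  if (is.null(hdr)) {
    note("experiment.json", "unreadable JSON")
    return(dplyr::bind_rows(probs))
  }
  for (s in hdr$sessions) {
    tf <- file.path(path, paste0("traj_", s, ".csv"))
    af <- file.path(path, paste0("activity_", s, ".csv"))
    if (!file.exists(tf)) {
      note(basename(tf), sprintf("missing trajectory for session %s", s))
      next
    }
    if (!file.exists(af)) {
      note(basename(af), sprintf("missing activity for session %s", s))
      next
    }
    traj <- utils::read.csv(tf)
    if (!all(c("t", "x", "y") %in% names(traj))) {
      note(basename(tf), "trajectory lacks t/x/y columns")
    }
    act <- utils::read.csv(af)
    if (nrow(act) > 0 && max(act$neuron) > hdr$n_neurons) {
      note(basename(af),
           sprintf("session %s has neuron ids beyond n_neurons", s))
    }
    if (nrow(act) > 0 && max(act$frame) > nrow(traj)) {
      note(basename(af),
           sprintf("session %s has frames beyond trajectory length", s))
    }
  }
  dplyr::bind_rows(probs)
}
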