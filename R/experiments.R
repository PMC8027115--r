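#' Seeded representation-learning sweep
#'
#' Runs the exploration architecture over the full crossing of objects,
#' landmark counts and articulation modes, with `tests` independently seeded
#' repetitions per condition (per-test seed = `base_seed + test`, landmark
#' placement re-drawn per test), and collects windowed decoding metrics.
#'
#' @param objects named list of dimension triples, e.g.
#'   `list(cube = c(2, 2, 2), cuboid = c(3, 2, 1))`.
#' @param landmarks vector of landmark counts to cross with the objects.
#' @param articulated logical vector of hand modes to cross (default
#'   articulated only).
#' @param tests seeded repetitions per condition.
#' @param steps successful exploration steps per test.
#' @param phi sliding-window length for the metrics.
#' @param every thin the window series to one row per `every` steps.
#' @param base_seed base seed; test `k` uses `base_seed + k`.
#' @return an object of class `haptic_sweep`: list with `results` (long
#'   tibble: `object`, `landmarks`, `articulated`, `test`, `window_end`,
#'   `metric`, `value`), `summary` (per-condition median end-window metrics
#'   with chance baselines), and the call parameters.
#' @export
representation_sweep <- function(objects = list(cube = c(2, 2, 2)),
                                 landmarks = 0, articulated = TRUE,
                                 tests = 30, steps = 20000, phi = 1000,
                                 every = phi, base_seed = 1) {
  grid <- tidyr::expand_grid(
    object = names(objects), landmarks = landmarks, articulated = articulated
  )
  res <- purrr::pmap(grid, function(object, landmarks, articulated) {
    dims <- objects[[object]]
    purrr::map(seq_len(tests), function(k) {
      seed <- base_seed + k
      obj <- place_landmarks(build_cuboid(dims), landmarks, seed = seed)
      run <- explore(obj, steps = steps, seed = seed, articulated = articulated)
      wm <- window_metrics(run$trace, phi = phi)
      wm <- wm[wm$step %% every == 0 | wm$step == max(wm$step), ]
      dplyr::mutate(
        tidyr::pivot_longer(wm, -"step", names_to = "metric", values_to = "value"),
        object = object, landmarks = landmarks, articulated = articulated,
        test = k, .before = 1
      )
    })
  })
  results <- dplyr::bind_rows(res)
  results <- dplyr::rename(results, window_end = "step")
  end_vals <- results |>
    dplyr::group_by(.data$object, .data$landmarks, .data$articulated,
                    .data$test, .data$metric) |>
    dplyr::slice_max(.data$window_end, n = 1) |>
    dplyr::ungroup()
  chance <- purrr::imap(objects, function(dims, nm) {
    obj <- build_cuboid(dims)
    tibble::tibble(object = nm, chance_pmax = chance_p_max(obj),
                   chance_dgeo = chance_d_geodesic(obj))
  }) |> dplyr::bind_rows()
  summary <- end_vals |>
    dplyr::group_by(.data$object, .data$landmarks, .data$articulated,
                    .data$metric) |>
    dplyr::summarise(median = stats::median(.data$value),
                     q25 = stats::quantile(.data$value, 0.25),
                     q75 = stats::quantile(.data$value, 0.75),
                     .groups = "drop") |>
    dplyr::left_join(chance, by = "object")
  structure(list(results = results, summary = summary, end_values = end_vals,
                 tests = tests, steps = steps, phi = phi,
                 base_seed = base_seed),
            class = "haptic_sweep")
}

#' @export
print.haptic_sweep <- function(x, ...) {
  cat(sprintf("<haptic_sweep: %d conditions x %d tests x %d steps>\n",
              nrow(dplyr::distinct(x$results, .data$object, .data$landmarks,
                                   .data$articulated)),
              x$tests, x$steps))
  print(x$summary)
  invisible(x)
}

#' Goal-oriented learning experiment
#'
#' Runs the two-stage goal learner and the random-walk-with-memory baseline
#' over `tests` seeded repetitions each, and compares end-of-training step
#' counts with a one-sided Mann-Whitney test (model < baseline) over the
#' final `final_frac` of epochs pooled across tests.
#'
#' @param dims object dimensions.
#' @param landmarks landmark count (re-drawn per test seed).
#' @param tests seeded repetitions per condition.
#' @param epochs stage-2 epochs per test.
#' @param rep_epochs stage-1 representation-learning episodes.
#' @param goal,start goal/start `c(face, x, y)`.
#' @param final_frac fraction of final epochs pooled for the end-of-training
#'   comparison (default 0.1, i.e. the last tenth of training).
#' @param base_seed base seed; test `k` uses `base_seed + k`.
#' @param ... further arguments to [learn_goal()].
#' @return an object of class `haptic_rl_experiment`: list with `epochs`
#'   (long tibble: `condition`, `test`, `epoch`, `steps`, `reward`),
#'   `medians` (per-epoch medians across tests), `comparison` (tibble from
#'   [compare_step_distributions()] plus the end medians), `bfs_bound`.
#' @export
rl_experiment <- function(dims = c(2, 2, 2), landmarks = 0, tests = 10,
                          epochs = 5000, rep_epochs = 50,
                          goal = c(3, 1, 2), start = c(1, 1, 1),
                          final_frac = 0.1, base_seed = 1, ...) {
  runs <- purrr::map(seq_len(tests), function(k) {
    seed <- base_seed + k
    obj <- place_landmarks(build_cuboid(dims), landmarks, seed = seed)
    fit <- learn_goal(obj, epochs = epochs, seed = seed, goal = goal,
                      start = start, rep_epochs = rep_epochs, ...)
    base <- random_walk_with_memory(obj, epochs = epochs, seed = seed,
                                    goal = goal, start = start)
    list(
      tab = dplyr::bind_rows(
        dplyr::mutate(fit$epochs[c("epoch", "steps", "reward")],
                      condition = "model", test = k, .before = 1),
        dplyr::mutate(base[c("epoch", "steps")], reward = NA_real_,
                      condition = "random_walk", test = k, .before = 1)
      ),
      bfs = fit$bfs_bound
    )
  })
  tab <- dplyr::bind_rows(purrr::map(runs, "tab"))
  medians <- tab |>
    dplyr::group_by(.data$condition, .data$epoch) |>
    dplyr::summarise(steps = stats::median(.data$steps),
                     reward = stats::median(.data$reward),
                     .groups = "drop")
  from <- floor(epochs * (1 - final_frac)) + 1
  final <- dplyr::filter(tab, .data$epoch >= from)
  ms <- final$steps[final$condition == "model"]
  bs <- final$steps[final$condition == "random_walk"]
  comparison <- dplyr::mutate(
    compare_step_distributions(ms, bs),
    model_median = stats::median(ms), baseline_median = stats::median(bs),
    from_epoch = from
  )
  structure(list(epochs = tab, medians = medians, comparison = comparison,
                 bfs_bound = runs[[1]]$bfs, tests = tests,
                 n_epochs = epochs, base_seed = base_seed),
            class = "haptic_rl_experiment")
}

#' @export
print.haptic_rl_experiment <- function(x, ...) {
  cat(sprintf("<haptic_rl_experiment: %d tests x %d epochs>\n",
              x$tests, x$n_epochs))
  print(x$comparison)
  invisible(x)
}

#' One-sided Mann-Whitney comparison of step counts
#'
#' Tests whether the model's end-of-training step counts are stochastically
#' smaller than the baseline's ([stats::wilcox.test()], one-sided,
#' normal approximation - the step variable is not normally distributed
#' because of the attempt cap).
#'
#' @param model_steps,baseline_steps numeric samples of per-epoch step
#'   counts.
#' @return tibble with `statistic` (U), `p_value`, `n_model`, `n_baseline`.
#' @export
compare_step_distributions <- function(model_steps, baseline_steps) {
  if (length(model_steps) == 0 || length(baseline_steps) == 0) {
    stop("empty sample", call. = FALSE)
  }
  wt <- stats::wilcox.test(model_steps, baseline_steps,
                           alternative = "less", exact = FALSE)
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 n_model = length(model_steps),
                 n_baseline = length(baseline_steps))
}
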