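#' @importFrom generics tidy glance
#' @importFrom rlang .data
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an exploration run
#'
#' @param x a [explore()] result.
#' @param ... unused.
#' @return the per-step trace tibble, with the palm cell's `(face, x, y)`
#'   joined in.
#' @export
tidy.haptic_exploration <- function(x, ...) {
  dplyr::left_join(x$trace, dplyr::rename(x$obj$cells, alpha = "cell"),
                   by = "alpha")
}

#' One-row summary of an exploration run
#'
#' @param x a [explore()] result.
#' @param phi window length for the end-of-run metrics.
#' @param ... unused.
#' @return tibble with end-window `pmax` and `dgeo`, the chance baselines,
#'   the mean attempts per successful step, and the step count.
#' @export
glance.haptic_exploration <- function(x, phi = 1000, ...) {
  tibble::tibble(
    steps = nrow(x$trace),
    pmax = p_max(x$trace, phi),
    dgeo = mean(utils::tail(x$trace$dgeo, min(phi, nrow(x$trace)))),
    chance_pmax = chance_p_max(x$obj),
    chance_dgeo = chance_d_geodesic(x$obj),
    mean_attempts = mean(x$trace$attempts)
  )
}

#' Tidy a goal-learning run
#'
#' @param x a [learn_goal()] result.
#' @param ... unused.
#' @return the per-epoch tibble.
#' @export
tidy.haptic_rl <- function(x, ...) x$epochs

#' One-row summary of a goal-learning run
#'
#' @param x a [learn_goal()] result.
#' @param final_frac fraction of final epochs summarised.
#' @param ... unused.
#' @return tibble with end-of-training median steps and reward, the success
#'   rate, and the BFS lower bound.
#' @export
glance.haptic_rl <- function(x, final_frac = 0.1, ...) {
  n <- nrow(x$epochs)
  fin <- utils::tail(x$epochs, max(1, floor(n * final_frac)))
  tibble::tibble(
    epochs = n,
    median_steps = stats::median(fin$steps),
    median_reward = stats::median(fin$reward),
    success_rate = mean(fin$reached),
    bfs_bound = x$bfs_bound
  )
}

#' @export
tidy.haptic_sweep <- function(x, ...) x$results

#' @export
glance.haptic_sweep <- function(x, ...) x$summary

#' @export
tidy.haptic_rl_experiment <- function(x, ...) x$epochs

#' @export
glance.haptic_rl_experiment <- function(x, ...) x$comparison

#' Plot the windowed decoding metrics of an exploration run
#'
#' @param object a [explore()] result.
#' @param phi sliding-window length.
#' @param ... unused.
#' @return a ggplot: reconstruction accuracy and geodesic error against the
#'   step index, with the chance baselines dashed.
#' @export
autoplot.haptic_exploration <- function(object, phi = 1000, ...) {
  wm <- window_metrics(object$trace, phi = phi)
  long <- tidyr::pivot_longer(wm[c("step", "pmax", "dgeo")], -"step",
                              names_to = "metric", values_to = "value")
  chance <- tibble::tibble(
    metric = c("pmax", "dgeo"),
    value = c(chance_p_max(object$obj), chance_d_geodesic(object$obj))
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(data = chance, ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "exploration step", y = NULL)
}

#' Plot a representation sweep
#'
#' @param object a [representation_sweep()] result.
#' @param metric which metric to show.
#' @param ... unused.
#' @return a ggplot of per-condition end-of-run distributions across tests,
#'   with the chance baseline dashed.
#' @export
autoplot.haptic_sweep <- function(object, metric = "pmax", ...) {
  ev <- object$end_values[object$end_values$metric == metric, ]
  ch_col <- if (metric == "dgeo") "chance_dgeo" else "chance_pmax"
  ch <- dplyr::distinct(object$summary[c("object", ch_col)])
  names(ch)[2] <- "chance"
  ggplot2::ggplot(ev, ggplot2::aes(factor(.data$landmarks), .data$value,
                                   fill = .data$articulated)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(data = ch, ggplot2::aes(yintercept = .data$chance),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~object) +
    ggplot2::labs(x = "tactile landmarks", y = metric)
}

#' Plot a goal-learning experiment
#'
#' @param object a [rl_experiment()] result.
#' @param thin show every `thin`-th epoch median.
#' @param ... unused.
#' @return a ggplot of per-epoch median steps for model and baseline.
#' @export
autoplot.haptic_rl_experiment <- function(object, thin = 50, ...) {
  med <- dplyr::filter(object$medians, .data$epoch %% thin == 0)
  ggplot2::ggplot(med, ggplot2::aes(.data$epoch, .data$steps,
                                    colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$bfs_bound, linetype = "dashed") +
    ggplot2::labs(x = "epoch", y = "median steps to goal")
}
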