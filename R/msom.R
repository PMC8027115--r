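#' Merge self-organizing map (MSOM)
#'
#' A SOM variant for sequence learning.  Each of the `n^2` units on the 2D
#' grid carries a regular weight vector `w_i` (what the input is) and a
#' context weight vector `c_i` (when it tends to occur).  The map keeps a
#' running context `c(t)`, a blend of the previous winner's two weight
#' vectors, so that unit activations depend on the recent input history and
#' units come to encode frequently occurring input *sequences*.
#'
#' For an input `x(t)` the unit distance is the blend
#' `d_i = (1 - zeta) * ||x - w_i||^2 + zeta * ||c(t) - c_i||^2`,
#' the activity is `a_i = exp(-nu * d_i)`, the activity pattern is the
#' normalized activity vector (a probability distribution over units), and
#' the best matching unit (BMU) minimizes `d_i`.  The map context recursion
#' is `c(t) = (1 - iota) * w_bmu(t-1) + iota * c_bmu(t-1)` with `c(0) = 0`.
#' Training moves `w_i` toward `x(t)` and `c_i` toward `c(t)` with a
#' decreasing learning rate and a Gaussian grid neighbourhood around the BMU.
#'
#' Regular weights initialize uniformly in `[0, 1]`; context weights start at
#' zero.
#'
#' @param n map side length (the grid has `n^2` units).
#' @param m input dimension.
#' @param zeta context/content balance in (0, 1); 0.4 by default.
#' @param iota context recursion mix in (0, 1); 0.5 by default.
#' @param nu activity scaling, > 0.  Controls how sharply the activity
#'   pattern concentrates on the closest units; the default 20 makes the
#'   pattern discriminative for the near-one-hot percept inputs (see the
#'   methods vignette).
#' @param lr_start,lr_end learning-rate schedule endpoints (exponential decay).
#' @param sigma_start,sigma_end neighbourhood width endpoints (exponential
#'   decay); `sigma_start` defaults to `n / 2`.
#' @param t_max schedule horizon in steps: `l(t)` and the neighbourhood width
#'   reach their end values at `t = t_max` and stay there.
#' @param seed seed for the weight initialization.
#' @return an object of class `msom`.
#' @export
msom <- function(n = 10, m, zeta = 0.4, iota = 0.5, nu = 20,
                 lr_start = 0.3, lr_end = 0.01,
                 sigma_start = n / 2, sigma_end = 0.5,
                 t_max = 20000, seed = 1) {
  stopifnot(n >= 1, m >= 1, zeta >= 0, zeta < 1, iota >= 0, iota < 1, nu > 0)
  n2 <- n * n
  Wt <- with_preserved_rng(seed, matrix(stats::runif(n2 * m), m, n2))  # m x n2
  Ct <- matrix(0, m, n2)
  gx <- rep(seq_len(n), each = n); gy <- rep(seq_len(n), times = n)
  grid_d2 <- outer(gx, gx, "-")^2 + outer(gy, gy, "-")^2  # squared grid distances
  structure(list(
    n = n, m = m, zeta = zeta, iota = iota, nu = nu,
    lr_start = lr_start, lr_end = lr_end,
    sigma_start = sigma_start, sigma_end = sigma_end, t_max = t_max,
    Wt = Wt, Ct = Ct, grid_d2 = grid_d2,
    c_map = numeric(m), last_bmu = NA_integer_, t = 0L
  ), class = "msom")
}

#' @export
print.msom <- function(x, ...) {
  cat(sprintf("<msom %dx%d, m=%d, zeta=%.2f, iota=%.2f, t=%d>\n",
              x$n, x$n, x$m, x$zeta, x$iota, x$t))
  invisible(x)
}

# exponentially decayed schedule value at step t
sched_val <- function(start, end, t, t_max) {
  if (t >= t_max) return(end)
  start * (end / start)^(t / t_max)
}

#' Blended content/context distances of all units
#'
#' @param map an [msom()].
#' @param x input vector of width `m`.
#' @param c_map map context to use; defaults to the map's current context.
#' @return numeric vector of `n^2` distances.
#' @export
msom_distances <- function(map, x, c_map = map$c_map) {
  if (length(x) != map$m) stop("input width must be m", call. = FALSE)
  (1 - map$zeta) * colSums((map$Wt - x)^2) + map$zeta * colSums((map$Ct - c_map)^2)
}

#' Unit activities from distances
#'
#' `a_i = exp(-nu * d_i)`, in (0, 1] for non-negative distances.
#'
#' @param distances non-negative distance vector.
#' @param nu activity scaling.
#' @return activity vector of the same length.
#' @export
msom_activity <- function(distances, nu = 1) exp(-nu * distances)

#' Normalized activity pattern and winner
#'
#' @param activities positive activity vector.
#' @param distances optional distance vector used for winner selection
#'   (`argmin d_i`); if omitted the winner is `argmax a_i` (equivalent for
#'   monotone activity).  Ties break to the lowest unit index.
#' @return list with `p` (probabilities summing to 1) and `bmu`.
#' @export
activity_pattern <- function(activities, distances = NULL) {
  p <- activities / sum(activities)
  bmu <- if (is.null(distances)) which.max(activities) else which.min(distances)
  list(p = p, bmu = as.integer(bmu))
}

#' Map context for the current step
#'
#' `c(t) = (1 - iota) * w_bmu(t-1) + iota * c_bmu(t-1)`; the zero vector
#' before any input has been seen.
#'
#' @param map an [msom()].
#' @return context vector of width `m`.
#' @export
msom_context <- function(map) {
  if (is.na(map$last_bmu)) return(numeric(map$m))
  (1 - map$iota) * map$Wt[, map$last_bmu] + map$iota * map$Ct[, map$last_bmu]
}

#' Reset the map context
#'
#' Clears the context recursion (and the previous-winner memory) without
#' touching the weights; used when a new episode breaks the percept
#' sequence.
#'
#' @param map an [msom()].
#' @return the map with `c(t)` zeroed.
#' @export
msom_reset_context <- function(map) {
  map$c_map <- numeric(map$m)
  map$last_bmu <- NA_integer_
  map
}

#' Present one input to the map
#'
#' Computes the step's context, distances, winner and activity pattern, then
#' (if `learn = TRUE`) moves every unit's regular weight toward the input and
#' context weight toward the map context, scaled by the learning rate and the
#' Gaussian grid neighbourhood of the winner.  The returned pattern is the
#' pre-update pattern: the one the architecture acts on.
#'
#' @param map an [msom()].
#' @param x input vector of width `m`.
#' @param learn update the weights (default) or only run the forward pass
#'   (frozen map).
#' @return list with `map` (updated), `pattern` (probability vector),
#'   `bmu`, and `distances`.
#' @export
msom_step <- function(map, x, learn = TRUE) {
  c_map <- msom_context(map)
  d <- msom_distances(map, x, c_map)
  a <- msom_activity(d, map$nu)
  ap <- activity_pattern(a, d)
  if (learn) {
    lr <- sched_val(map$lr_start, map$lr_end, map$t, map$t_max)
    sg <- sched_val(map$sigma_start, map$sigma_end, map$t, map$t_max)
    h <- lr * exp(-map$grid_d2[, ap$bmu] / (2 * sg^2))
    hc <- rep(h, each = map$m)
    map$Wt <- map$Wt + (x - map$Wt) * hc
    map$Ct <- map$Ct + (c_map - map$Ct) * hc
  }
  map$c_map <- c_map
  map$last_bmu <- ap$bmu
  map$t <- map$t + 1L
  list(map = map, pattern = ap$p, bmu = ap$bmu, distances = d)
}
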