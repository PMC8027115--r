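#' Unsupervised haptic exploration
#'
#' Runs the full exploration architecture for a given number of successful
#' steps: the next action generator proposes an action from the current MSOM
#' activity pattern; infeasible attempts train the generator (target 0) and
#' trigger reselection without advancing time; a successful action trains the
#' generator (target 1), produces the egocentric percept, trains the MSOM,
#' and is recorded.  A hit map counts (winner unit, actual palm cell) pairs.
#' Per step the current hit map (counts accumulated *before* the step) is
#' used to decode a posterior over object cells from the activity pattern,
#' giving the decoded cell `beta`, the rank of the true cell `alpha` in the
#' posterior, and the posterior-weighted geodesic distance.
#'
#' Decoding, the hit map and the `alpha`/`beta` comparison are purely
#' external evaluation: the model itself never receives the true location.
#'
#' @param obj a [build_cuboid()] object (landmarks already placed, if any).
#' @param steps number of successful exploration steps.
#' @param seed seed for all randomness of the run (action selection,
#'   tie-breaks, and - if models are auto-created - their initialization).
#' @param map an [msom()] to continue training, or `NULL` to create one
#'   (`10 x 10`, `zeta = 0.4`, `iota = 0.5`, schedules spanning `steps`).
#' @param net a [feasibility_net()] or `NULL` to create one.
#' @param hitmap an existing hit-map count matrix to continue, or `NULL`.
#' @param articulated articulated hand (default) or unarticulated mode.
#' @param start,heading passed to [hand_reset()].
#' @param episode_attempts exploration is episodic: every `episode_attempts`
#'   attempts (successful + failed) the hand returns to the start cell and
#'   the map context is cleared, while all weights and the hit map persist.
#'   The default (100) mirrors the attempt budget of the goal-learning
#'   epochs.  Set to `Inf` for one continuous, never-reset walk; on an
#'   unmarked symmetric object continuous exploration carries no absolute
#'   location information, so decoding then stays at chance (see the
#'   methods vignette).
#' @param reset_context zero the MSOM context at the start (default); within
#'   an episode the context is never reset.
#' @param learn train MSOM and generator (default); `FALSE` runs both frozen.
#' @return an object of class `haptic_exploration`: list with `trace`
#'   (tibble: `step`, `episode`, `attempts`, `action`, `bmu`, `alpha`,
#'   `beta`, `alpha_rank`, `match`, `dgeo`), `map`, `net`, `hitmap`, `obj`,
#'   `sg`, `state` (final hand state id), and `articulated`.
#' @export
explore <- function(obj, steps, seed = 1, map = NULL, net = NULL,
                    hitmap = NULL, articulated = TRUE,
                    start = c(1, 1, 1), heading = "N",
                    episode_attempts = 100,
                    reset_context = TRUE, learn = TRUE) {
  stopifnot(inherits(obj, "cuboid"), steps >= 0)
  sg <- state_graph(obj, articulated)
  m <- 13L + obj$n_landmarks
  if (is.null(map)) {
    map <- msom(n = 10, m = m, t_max = max(steps, 1), seed = seed + 1L)
  }
  stopifnot(map$m == m)
  n_act <- length(sg$actions)
  if (is.null(net)) {
    net <- feasibility_net(n_in = map$n^2, n_actions = n_act, seed = seed + 2L)
  }
  if (is.null(hitmap)) hitmap <- matrix(0L, map$n^2, obj$p)
  if (reset_context) map <- msom_reset_context(map)
  st0 <- hand_reset(obj, start, heading, articulated)
  res <- with_preserved_rng(seed, {
    run_explore_engine(obj, sg, map, net, hitmap,
                       sid = state_id(sg, st0), steps = steps,
                       max_attempts = Inf, episode_attempts = episode_attempts,
                       learn = learn)
  })
  structure(list(trace = res$trace, map = res$map, net = res$net,
                 hitmap = res$hitmap, obj = obj, sg = sg,
                 state = res$sid, pattern = res$pattern,
                 articulated = articulated, seed = seed),
            class = "haptic_exploration")
}

#' @export
print.haptic_exploration <- function(x, ...) {
  cat(sprintf("<haptic_exploration: %d steps on %s (%d landmarks)>\n",
              nrow(x$trace), paste(x$obj$dims, collapse = "x"),
              x$obj$n_landmarks))
  invisible(x)
}

# The hot loop.  Works on local copies of all model matrices; models are
# reassembled on exit.  Stops after `steps` successful steps or once
# `max_attempts` attempts (successful + failed) have been made.  When
# `episode_attempts` is finite, the hand is returned to its start state and
# the map context cleared every time that many attempts have been spent,
# while weights and the hit map persist across episodes.
run_explore_engine <- function(obj, sg, map, net, hitmap, sid, steps,
                               max_attempts = Inf, episode_attempts = Inf,
                               learn = TRUE, pattern = NULL) {
  n2 <- map$n^2; m <- map$m; p <- obj$p
  L <- obj$n_landmarks
  zeta <- map$zeta; iota <- map$iota; nu <- map$nu
  Wt <- map$Wt; Ct <- map$Ct; grid_d2 <- map$grid_d2
  tt <- map$t; last_bmu <- map$last_bmu
  W1 <- net$W1; b1 <- net$b1; W2 <- net$W2; b2 <- net$b2; lr_net <- net$lr
  n_act <- length(sg$actions)
  cell_of <- sg$states$cell
  feats <- sg$feats
  slip_slot <- if (sg$articulated) seq_len(n_act) else unname(SLIP_SLOT_UNART)
  G <- geodesic_matrix(obj)
  rs <- rowSums(hitmap)
  if (is.null(pattern)) pattern <- rep(1 / n2, n2)

  o_action <- integer(steps); o_bmu <- integer(steps); o_alpha <- integer(steps)
  o_beta <- integer(steps); o_rank <- integer(steps); o_dgeo <- numeric(steps)
  o_att <- integer(steps); o_epi <- integer(steps)
  x <- numeric(m)
  step <- 0L; attempts_total <- 0L
  sid0 <- sid; pat0 <- rep(1 / n2, n2)
  episode <- 1L; ep_attempts <- 0L
  avail <- seq_len(n_act); att <- 0L

  while (step < steps && attempts_total < max_attempts) {
    if (ep_attempts >= episode_attempts) {
      # episode over: hand back to the start, context broken, weights persist
      episode <- episode + 1L; ep_attempts <- 0L
      sid <- sid0; last_bmu <- NA_integer_; pattern <- pat0
      avail <- seq_len(n_act); att <- 0L
    }
    # --- attempt an action, excluding ones already failed this time step
    h <- stats::plogis(as.vector(W1 %*% pattern) + b1)
    s <- stats::plogis(as.vector(W2 %*% h) + b2)
    a <- if (length(avail) == 1) avail else
      avail[sample.int(length(avail), 1, prob = s[avail])]
    s2 <- sg$trans[sid, a]
    ok <- s2 > 0L
    if (learn) {
      err <- s[a] - as.numeric(ok)
      dh <- W2[a, ] * err * h * (1 - h)
      W2[a, ] <- W2[a, ] - lr_net * err * h
      b2[a] <- b2[a] - lr_net * err
      W1 <- W1 - lr_net * outer(dh, pattern)
      b1 <- b1 - lr_net * dh
    }
    att <- att + 1L; attempts_total <- attempts_total + 1L
    ep_attempts <- ep_attempts + 1L
    if (!ok) {
      avail <- avail[avail != a]
      if (length(avail) == 0) stop("exploration deadlock", call. = FALSE)
      next
    }

    # --- percept and MSOM step (pre-update pattern is the new state)
    sid <- s2
    x[] <- 0
    x[slip_slot[a]] <- 1
    x[11:m] <- feats[, sid]
    c_map <- if (is.na(last_bmu)) numeric(m) else
      (1 - iota) * Wt[, last_bmu] + iota * Ct[, last_bmu]
    d <- (1 - zeta) * colSums((Wt - x)^2) + zeta * colSums((Ct - c_map)^2)
    bmu <- which.min(d)
    act <- exp(-nu * d)
    pat <- act / sum(act)
    if (learn) {
      lr_t <- sched_val(map$lr_start, map$lr_end, tt, map$t_max)
      sg_t <- sched_val(map$sigma_start, map$sigma_end, tt, map$t_max)
      hv <- lr_t * exp(-grid_d2[, bmu] / (2 * sg_t^2))
      hc <- rep(hv, each = m)
      Wt <- Wt + (x - Wt) * hc
      Ct <- Ct + (c_map - Ct) * hc
    }
    last_bmu <- bmu; tt <- tt + 1L
    pattern <- pat

    # --- external decoding from the hit map accumulated so far
    alpha <- cell_of[sid]
    w <- pat / rs
    w[rs == 0] <- 0
    post <- as.vector(crossprod(hitmap, w)) + sum(pat[rs == 0]) / p
    rk <- rank(-post, ties.method = "random")
    beta <- which(rk == 1L)
    dg <- sum(G[, alpha] * post)
    hitmap[bmu, alpha] <- hitmap[bmu, alpha] + 1L
    rs[bmu] <- rs[bmu] + 1L

    step <- step + 1L
    o_action[step] <- a; o_bmu[step] <- bmu; o_alpha[step] <- alpha
    o_beta[step] <- beta; o_rank[step] <- rk[alpha]; o_dgeo[step] <- dg
    o_att[step] <- att; o_epi[step] <- episode
    avail <- seq_len(n_act); att <- 0L
  }

  keep <- seq_len(step)
  map$Wt <- Wt; map$Ct <- Ct; map$t <- tt; map$last_bmu <- last_bmu
  map$c_map <- msom_context(map)
  net$W1 <- W1; net$b1 <- b1; net$W2 <- W2; net$b2 <- b2
  list(
    trace = tibble::tibble(
      step = keep, episode = o_epi[keep], attempts = o_att[keep],
      action = sg$actions[o_action[keep]],
      bmu = o_bmu[keep], alpha = o_alpha[keep], beta = o_beta[keep],
      alpha_rank = o_rank[keep], match = o_alpha[keep] == o_beta[keep],
      dgeo = o_dgeo[keep]),
    map = map, net = net, hitmap = hitmap, sid = sid,
    pattern = pattern, attempts_total = attempts_total, steps = step
  )
}

#' Posterior over object locations from the hit map
#'
#' Mixture decoding: each unit contributes its conditional location
#' distribution (its hit-map row, normalized) weighted by its activity
#' probability.  Units never yet observed as winner contribute a uniform
#' conditional `1/p` - total ignorance.
#'
#' @param hitmap `n^2 x p` count matrix.
#' @param pattern activity pattern (probabilities over units).
#' @return probability vector over the `p` object cells (sums to 1).
#' @export
location_posterior <- function(hitmap, pattern) {
  stopifnot(length(pattern) == nrow(hitmap))
  rs <- rowSums(hitmap)
  w <- pattern / rs
  w[rs == 0] <- 0
  as.vector(crossprod(hitmap, w)) + sum(pattern[rs == 0]) / ncol(hitmap)
}

#' Reconstruction accuracy over a window
#'
#' Fraction of the last `phi` recorded steps where the decoded cell equals
#' the true cell.
#'
#' @param trace exploration trace (tibble with `match`), e.g.
#'   `result$trace` or [tidy()] output.
#' @param phi window length; defaults to the whole trace.
#' @return a number in `[0, 1]`.
#' @export
p_max <- function(trace, phi = nrow(trace)) {
  if (phi < 1 || nrow(trace) < 1) stop("empty window", call. = FALSE)
  phi <- min(phi, nrow(trace))
  mean(utils::tail(trace$match, phi))
}

#' Top-h reconstruction accuracy over a window
#'
#' Fraction of the last `phi` steps where the true cell is among the `h`
#' highest-posterior cells; `h = 1` recovers [p_max()].
#'
#' @inheritParams p_max
#' @param h number of top predictions counted as a hit.
#' @return a number in `[0, 1]`.
#' @export
top_h_accuracy <- function(trace, phi = nrow(trace), h = 1) {
  if (phi < 1 || nrow(trace) < 1) stop("empty window", call. = FALSE)
  phi <- min(phi, nrow(trace))
  mean(utils::tail(trace$alpha_rank, phi) <= h)
}

#' Posterior-weighted geodesic distance
#'
#' Expected surface shortest-path distance between the true cell and the
#' decoded posterior: `sum_o g(l_o, alpha) * p(l_o)`.
#'
#' @param obj a [build_cuboid()] object.
#' @param posterior probability vector over cells.
#' @param alpha true cell index.
#' @return non-negative number.
#' @export
d_geodesic <- function(obj, posterior, alpha) {
  stopifnot(length(posterior) == obj$p)
  sum(geodesic_matrix(obj)[, alpha] * posterior)
}

#' Sliding-window metric series
#'
#' Rolling mean of the per-step match indicator, top-h indicator and
#' geodesic error over windows of length `phi` (one value per window end
#' position).
#'
#' @inheritParams p_max
#' @param h top-h level included alongside `h = 1`.
#' @return tibble with `step` (window end), `pmax`, `top_h`, `dgeo`.
#' @export
window_metrics <- function(trace, phi = 1000, h = 3) {
  n <- nrow(trace)
  phi <- min(phi, n)
  roll <- function(v) {
    cs <- cumsum(v)
    (cs[phi:n] - c(0, cs)[(phi:n) - phi + 1]) / phi
  }
  tibble::tibble(
    step = phi:n,
    pmax = roll(as.numeric(trace$match)),
    top_h = roll(as.numeric(trace$alpha_rank <= h)),
    dgeo = roll(trace$dgeo)
  )
}

#' Chance baselines for the decoding metrics
#'
#' Under a uniform posterior with random tie-breaking the expected
#' reconstruction accuracy is `1/p`, and the expected geodesic error from a
#' cell is the mean surface distance from that cell; `chance_d_geodesic`
#' averages this over all cells.
#'
#' @param obj a [build_cuboid()] object.
#' @return a single number.
#' @export
chance_p_max <- function(obj) 1 / obj$p

#' @rdname chance_p_max
#' @export
chance_d_geodesic <- function(obj) mean(geodesic_matrix(obj))
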