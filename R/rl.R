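#' Actor-critic goal learner over MSOM activity patterns
#'
#' The agent never sees its true location: both the actor (feedforward net
#' emitting one unbounded preference score per action) and the critic
#' (feedforward net, linear value output) take the MSOM activity pattern as
#' their state.  The behaviour policy is
#' `softmax(pi(.|s, theta) * pi(.|s, phi))`: the element-wise product of the
#' actor scores with the frozen next action generator's feasibility scores,
#' passed through a softmax.  The generator factor scales down actions it
#' believes infeasible without zeroing them.  The actor output is linear
#' because the softmax shown is the policy's only normalization: squashing
#' the actor to a probability vector first would confine the product to
#' `[0, 1/n_actions]` and pin the policy within a factor `e^0.1` of uniform
#' for 10 actions, making policy improvement inexpressible.  With
#' `renormalize = TRUE` the policy is instead the renormalized product of a
#' softmax-actor distribution and the generator scores.
#'
#' @param generator the frozen [feasibility_net()] from representation
#'   learning.
#' @param n_in input width (MSOM units).
#' @param n_hidden hidden width.
#' @param n_actions number of actions.
#' @param gamma temporal discount.
#' @param alpha_a,alpha_c actor and critic learning rates.
#' @param renormalize if `TRUE` the policy is the renormalized element-wise
#'   product instead of its softmax.
#' @param seed weight initialization seed.
#' @return an object of class `goal_learner`.
#' @export
goal_learner <- function(generator, n_in = 100, n_hidden = 100, n_actions = 10,
                         gamma = 0.9, alpha_a = 1e-5, alpha_c = 1e-4,
                         renormalize = FALSE, seed = 1) {
  with_preserved_rng(seed, {
    structure(list(
      Wa1 = matrix(stats::runif(n_hidden * n_in, -0.1, 0.1), n_hidden, n_in),
      ba1 = numeric(n_hidden),
      Wa2 = matrix(stats::runif(n_actions * n_hidden, -0.1, 0.1), n_actions, n_hidden),
      ba2 = numeric(n_actions),
      Wc1 = matrix(stats::runif(n_hidden * n_in, -0.1, 0.1), n_hidden, n_in),
      bc1 = numeric(n_hidden),
      wc2 = stats::runif(n_hidden, -0.1, 0.1),
      bc2 = 0,
      generator = generator, gamma = gamma,
      alpha_a = alpha_a, alpha_c = alpha_c,
      renormalize = renormalize,
      n_in = n_in, n_hidden = n_hidden, n_actions = n_actions
    ), class = "goal_learner")
  })
}

#' @export
print.goal_learner <- function(x, ...) {
  cat(sprintf("<goal_learner %dx%dx%d, gamma=%g, alpha_a=%g, alpha_c=%g>\n",
              x$n_in, x$n_hidden, x$n_actions, x$gamma, x$alpha_a, x$alpha_c))
  invisible(x)
}

actor_forward <- function(learner, pattern) {
  h <- stats::plogis(as.vector(learner$Wa1 %*% pattern) + learner$ba1)
  list(h = h, o = as.vector(learner$Wa2 %*% h) + learner$ba2)
}

critic_forward <- function(learner, pattern) {
  h <- stats::plogis(as.vector(learner$Wc1 %*% pattern) + learner$bc1)
  list(h = h, v = sum(learner$wc2 * h) + learner$bc2)
}

#' Behaviour policy distribution
#'
#' @param learner a [goal_learner()].
#' @param pattern MSOM activity pattern.
#' @return probability vector over the actions (sums to 1).
#' @export
policy_distribution <- function(learner, pattern) {
  o <- actor_forward(learner, pattern)$o
  g <- predict_feasibility(learner$generator, pattern)
  if (learner$renormalize) {
    e <- exp(o - max(o))
    z <- (e / sum(e)) * g
    return(z / sum(z))
  }
  z <- o * g
  e <- exp(z - max(z))
  e / sum(e)
}

#' Temporal-difference error
#'
#' `delta = r + gamma * V(next) - V(current)`, dropping the bootstrap term
#' at a terminal transition.
#'
#' @param learner a [goal_learner()].
#' @param pattern current activity pattern.
#' @param reward observed reward.
#' @param next_pattern successor pattern (ignored when `terminal`).
#' @param terminal is the successor a terminal state?
#' @return the TD error.
#' @export
td_error <- function(learner, pattern, reward, next_pattern, terminal = FALSE) {
  v <- critic_forward(learner, pattern)$v
  if (terminal) return(reward - v)
  reward + learner$gamma * critic_forward(learner, next_pattern)$v - v
}

#' Two-stage goal-oriented learning
#'
#' Stage 1 is unsupervised representation learning: the exploration
#' architecture runs for `rep_epochs` episodes (each capped at `attempt_cap`
#' attempts) and learns MSOM and generator weights.  The weights are then
#' frozen.  Stage 2 is episodic actor-critic TD learning: each epoch resets
#' the hand to the start and runs until the palm reaches the goal cell or
#' `attempt_cap` attempts (successful and failed) are used.  The attempt is
#' the clock of stage 2: every attempt costs reward -1 (the goal is worth
#' +1) and drives a TD update.  A failed attempt leaves the hand, the map
#' context and hence the activity pattern unchanged and produces no percept;
#' a successful attempt advances the frozen MSOM and the update bootstraps
#' on the successor pattern.
#'
#' @param obj a [build_cuboid()] object.
#' @param epochs stage-2 training epochs.
#' @param seed seed for the whole run.
#' @param goal,start `c(face, x, y)` goal and start; defaults are the
#'   diagonally opposite corner pair on the cube.
#' @param heading start heading.
#' @param rep_epochs stage-1 episodes (default 50).
#' @param attempt_cap per-epoch attempt budget (default 100).
#' @param gamma,alpha_a,alpha_c,renormalize passed to [goal_learner()].
#' @param articulated hand mode.
#' @param map,net optionally pre-trained models; trained in stage 1
#'   otherwise.
#' @return an object of class `haptic_rl`: list with `epochs` (tibble:
#'   `epoch`, `steps`, `reward`, `reached`), `learner`, `map`, `net`,
#'   `stage1`, `bfs_bound` (shortest feasible action sequence), `goal_cell`.
#' @export
learn_goal <- function(obj, epochs, seed = 1, goal = c(3, 1, 2),
                       start = c(1, 1, 1), heading = "N",
                       rep_epochs = 50, attempt_cap = 100,
                       gamma = 0.9, alpha_a = 1e-5, alpha_c = 1e-4,
                       renormalize = FALSE, articulated = TRUE,
                       map = NULL, net = NULL) {
  stopifnot(inherits(obj, "cuboid"))
  sg <- state_graph(obj, articulated)
  goal_cell <- cell_index(obj, goal[1], goal[2], goal[3])
  st0 <- hand_reset(obj, start, heading, articulated)
  sid0 <- state_id(sg, st0)
  m <- 13L + obj$n_landmarks
  n_act <- length(sg$actions)
  if (is.null(map)) {
    map <- msom(n = 10, m = m, t_max = rep_epochs * attempt_cap, seed = seed + 1L)
  }
  if (is.null(net)) {
    net <- feasibility_net(n_in = map$n^2, n_actions = n_act, seed = seed + 2L)
  }

  with_preserved_rng(seed, {
    # ---- stage 1: unsupervised representation learning
    hitmap <- matrix(0L, map$n^2, obj$p)
    for (ep in seq_len(rep_epochs)) {
      map <- msom_reset_context(map)
      res <- run_explore_engine(obj, sg, map, net, hitmap, sid = sid0,
                                steps = attempt_cap, max_attempts = attempt_cap,
                                learn = TRUE)
      map <- res$map; net <- res$net; hitmap <- res$hitmap
    }
    stage1_hitmap <- hitmap

    # ---- stage 2: freeze representations, actor-critic TD learning
    learner <- goal_learner(net, n_in = map$n^2, n_actions = n_act,
                            gamma = gamma, alpha_a = alpha_a, alpha_c = alpha_c,
                            renormalize = renormalize, seed = seed + 3L)
    res <- run_rl_engine(obj, sg, map, learner, sid0, goal_cell,
                         epochs, attempt_cap)
    structure(list(epochs = res$epochs, learner = res$learner,
                   map = map, net = net, stage1 = stage1_hitmap,
                   bfs_bound = shortest_action_path(obj, st0, goal_cell, sg),
                   goal_cell = goal_cell, obj = obj, seed = seed),
              class = "haptic_rl")
  })
}

#' @export
print.haptic_rl <- function(x, ...) {
  n <- nrow(x$epochs)
  tail_med <- stats::median(utils::tail(x$epochs$steps, max(1, n %/% 10)))
  cat(sprintf("<haptic_rl: %d epochs, end median steps %.1f (BFS bound %d)>\n",
              n, tail_med, x$bfs_bound))
  invisible(x)
}

# stage-2 inner loop on local weight copies.  The attempt is the clock:
# failed attempts keep the state (and pattern) and still cost -1 and update
# the nets; successful attempts advance the frozen MSOM.
run_rl_engine <- function(obj, sg, map, learner, sid0, goal_cell,
                          epochs, attempt_cap) {
  n2 <- map$n^2; m <- map$m; n_act <- learner$n_actions
  zeta <- map$zeta; iota <- map$iota; nu <- map$nu
  Wt <- map$Wt; Ct <- map$Ct
  gen <- learner$generator
  Wa1 <- learner$Wa1; ba1 <- learner$ba1; Wa2 <- learner$Wa2; ba2 <- learner$ba2
  Wc1 <- learner$Wc1; bc1 <- learner$bc1; wc2 <- learner$wc2; bc2 <- learner$bc2
  gamma <- learner$gamma; aa <- learner$alpha_a; ac <- learner$alpha_c
  renorm <- learner$renormalize
  cell_of <- sg$states$cell; feats <- sg$feats
  slip_slot <- if (sg$articulated) seq_len(n_act) else unname(SLIP_SLOT_UNART)
  pat0 <- rep(1 / n2, n2)
  o_steps <- integer(epochs); o_reward <- numeric(epochs)
  o_reached <- logical(epochs)
  x <- numeric(m)
  eye <- diag(n_act)

  for (ep in seq_len(epochs)) {
    sid <- sid0
    last_bmu <- NA_integer_
    pattern <- pat0
    # per-pattern caches (generator is frozen, so gsc only moves with pattern)
    hgen <- stats::plogis(as.vector(gen$W1 %*% pattern) + gen$b1)
    gsc <- stats::plogis(as.vector(gen$W2 %*% hgen) + gen$b2)
    ha <- stats::plogis(as.vector(Wa1 %*% pattern) + ba1)
    oa <- as.vector(Wa2 %*% ha) + ba2
    hc <- stats::plogis(as.vector(Wc1 %*% pattern) + bc1)
    v_cur <- sum(wc2 * hc) + bc2
    attempts <- 0L; reward_sum <- 0; reached <- FALSE
    avail <- seq_len(n_act)

    while (attempts < attempt_cap) {
      if (renorm) {
        epi <- exp(oa - max(oa))
        z <- (epi / sum(epi)) * gsc
        pol <- z / sum(z)
      } else {
        z <- oa * gsc
        e <- exp(z - max(z))
        pol <- e / sum(e)
      }
      a <- if (length(avail) == 1) avail else
        avail[sample.int(length(avail), 1, prob = pol[avail])]
      attempts <- attempts + 1L
      s2 <- sg$trans[sid, a]
      ok <- s2 > 0L
      if (ok) {
        # successful step: percept + frozen MSOM forward
        sid <- s2
        x[] <- 0; x[slip_slot[a]] <- 1; x[11:m] <- feats[, sid]
        c_map <- if (is.na(last_bmu)) numeric(m) else
          (1 - iota) * Wt[, last_bmu] + iota * Ct[, last_bmu]
        d <- (1 - zeta) * colSums((Wt - x)^2) + zeta * colSums((Ct - c_map)^2)
        bmu <- which.min(d)
        acts <- exp(-nu * d)
        pat2 <- acts / sum(acts)
        last_bmu <- bmu
        terminal <- cell_of[sid] == goal_cell
        r <- if (terminal) 1 else -1
        hc2 <- stats::plogis(as.vector(Wc1 %*% pat2) + bc1)
        v_next <- sum(wc2 * hc2) + bc2
        delta <- if (terminal) r - v_cur else r + gamma * v_next - v_cur
      } else {
        # infeasible: state, pattern and value estimate are unchanged
        terminal <- FALSE
        r <- -1
        delta <- r + gamma * v_cur - v_cur
      }
      reward_sum <- reward_sum + r

      # critic: V <- V + alpha_c * delta * grad V(pattern)
      dhc <- wc2 * hc * (1 - hc)
      wc2 <- wc2 + (ac * delta) * hc
      bc2 <- bc2 + ac * delta
      Wc1 <- Wc1 + (ac * delta) * outer(dhc, pattern)
      bc1 <- bc1 + (ac * delta) * dhc
      # actor: theta <- theta + alpha_a * delta * grad log pol[a]
      if (renorm) {
        # d log pol[a] / d pi_theta_k = g_k (1[k=a]/z_a - 1/sum z); then
        # through the actor softmax
        u <- (eye[a, ] - pol) * gsc / z
        pi_theta <- exp(oa - max(oa)); pi_theta <- pi_theta / sum(pi_theta)
        doa <- pi_theta * (u - sum(u * pi_theta))
      } else {
        doa <- (eye[a, ] - pol) * gsc
      }
      dha <- as.vector(crossprod(Wa2, doa)) * ha * (1 - ha)
      Wa2 <- Wa2 + (aa * delta) * outer(doa, ha)
      ba2 <- ba2 + (aa * delta) * doa
      Wa1 <- Wa1 + (aa * delta) * outer(dha, pattern)
      ba1 <- ba1 + (aa * delta) * dha

      if (ok && terminal) { reached <- TRUE; break }
      if (ok) {
        pattern <- pat2
        hgen <- stats::plogis(as.vector(gen$W1 %*% pattern) + gen$b1)
        gsc <- stats::plogis(as.vector(gen$W2 %*% hgen) + gen$b2)
        avail <- seq_len(n_act)
      } else {
        avail <- avail[avail != a]
        if (length(avail) == 0) avail <- seq_len(n_act)  # unreachable in practice
      }
      # actor and critic weights moved: refresh their forward caches
      ha <- stats::plogis(as.vector(Wa1 %*% pattern) + ba1)
      oa <- as.vector(Wa2 %*% ha) + ba2
      hc <- stats::plogis(as.vector(Wc1 %*% pattern) + bc1)
      v_cur <- sum(wc2 * hc) + bc2
    }
    o_steps[ep] <- attempts
    o_reward[ep] <- reward_sum
    o_reached[ep] <- reached
  }

  learner$Wa1 <- Wa1; learner$ba1 <- ba1; learner$Wa2 <- Wa2; learner$ba2 <- ba2
  learner$Wc1 <- Wc1; learner$bc1 <- bc1; learner$wc2 <- wc2; learner$bc2 <- bc2
  list(epochs = tibble::tibble(epoch = seq_len(epochs), steps = o_steps,
                               reward = o_reward, reached = o_reached),
       learner = learner)
}

#' Random walk with memory baseline
#'
#' The same articulated agent performs a random walk under the model's
#' attempt accounting: each attempt picks uniformly from the full action
#' repertoire, infeasible attempts burn budget without moving, and the walk
#' ends at the goal or at `attempt_cap` attempts.  In every test the agent
#' remembers the shortest goal-reaching trajectory seen so far; the
#' per-epoch reported step count is the minimum of the current walk's length
#' and the remembered best, so the reported series never increases.  A walk
#' that misses the goal counts as `attempt_cap` steps.
#'
#' @inheritParams learn_goal
#' @param feasible_only if `TRUE` the walker samples only among feasible
#'   actions (a feasibility-clairvoyant walker whose remembered minimum
#'   converges to the breadth-first-search bound).
#' @return tibble with `epoch`, `walk_steps` (the raw walk), `steps` (the
#'   reported, remembered minimum) and `reached`.
#' @export
random_walk_with_memory <- function(obj, epochs, seed = 1, goal = c(3, 1, 2),
                                    start = c(1, 1, 1), heading = "N",
                                    attempt_cap = 100, articulated = TRUE,
                                    feasible_only = FALSE) {
  stopifnot(inherits(obj, "cuboid"))
  sg <- state_graph(obj, articulated)
  goal_cell <- cell_index(obj, goal[1], goal[2], goal[3])
  sid0 <- state_id(sg, hand_reset(obj, start, heading, articulated))
  n_act <- length(sg$actions)
  feas <- apply(sg$trans, 1, function(row) which(row > 0), simplify = FALSE)
  cell_of <- sg$states$cell
  with_preserved_rng(seed, {
    best <- attempt_cap
    o_walk <- integer(epochs); o_rep <- integer(epochs); o_hit <- logical(epochs)
    for (ep in seq_len(epochs)) {
      sid <- sid0; steps <- 0L; hit <- FALSE
      while (steps < attempt_cap) {
        if (feasible_only) {
          f <- feas[[sid]]
          sid <- sg$trans[sid, if (length(f) == 1) f else f[sample.int(length(f), 1)]]
        } else {
          s2 <- sg$trans[sid, sample.int(n_act, 1)]
          if (s2 > 0L) sid <- s2   # infeasible attempts burn budget in place
        }
        steps <- steps + 1L
        if (cell_of[sid] == goal_cell) { hit <- TRUE; break }
      }
      if (hit) best <- min(best, steps)
      o_walk[ep] <- steps; o_rep[ep] <- min(steps, best); o_hit[ep] <- hit
    }
    tibble::tibble(epoch = seq_len(epochs), walk_steps = o_walk,
                   steps = o_rep, reached = o_hit)
  })
}
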