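#' The articulated one-finger hand
#'
#' The agent is a "palm" plus a single "finger" that is either straight or
#' bent at 90 degrees.  Its state is the palm's surface cell, a heading
#' (a tangent direction of the palm's face), and the finger situation:
#'
#' * `on`   - straight, the finger resting on the cell one step ahead of the
#'            palm on the same face;
#' * `over` - straight, the palm on a boundary cell with the finger extended
#'            over the edge into free space;
#' * `bent` - the finger bent over the edge ahead, contacting the across-edge
#'            neighbour cell on the adjacent face.
#'
#' Whether a straight finger is `on` or `over` is determined by the palm cell
#' and heading, so the reachable state space is small and fully enumerable.
#'
#' The action repertoire has 10 members, each with a distinct slip signature:
#' forward translation ending with the finger on the surface (`fwd_on`) or
#' slipping over the edge (`fwd_over`); backward translation with the finger
#' on the surface (`back_on`) or pulling the finger back over an edge onto
#' the surface (`back_over`); sideways translation `left` / `right`; in-place
#' rotation `rot_ccw` / `rot_cw`; and `bend` / `unbend`.  The finger can only
#' bend when straight and extended over an edge, and only unbend when bent;
#' unbending pivots the palm over the edge onto the adjacent face, which is
#' how the hand moves between faces.  Translations are blocked while bent,
#' and a hand extended over an edge can only translate along the edge or
#' backwards.  Rotations are blocked while bent.
#'
#' In the unarticulated degenerate mode there is no finger: the repertoire is
#' the 4 translations plus the 2 rotations, and translating across a cuboid
#' edge is allowed as a plain translation.
#'
#' @name hand
NULL

ACT_ARTICULATED <- c("fwd_on", "fwd_over", "back_on", "back_over",
                     "left", "right", "rot_ccw", "rot_cw", "bend", "unbend")
ACT_UNARTICULATED <- c("fwd", "back", "left", "right", "rot_ccw", "rot_cw")
# slip-bit slot (1..10 in the percept one-hot) for each unarticulated action
SLIP_SLOT_UNART <- c(fwd = 1L, back = 3L, left = 5L, right = 6L,
                     rot_ccw = 7L, rot_cw = 8L)

#' Action repertoire
#'
#' @param articulated if `FALSE`, the 6-action unarticulated repertoire.
#' @return character vector of action names (length 10 or 6).
#' @export
hand_actions <- function(articulated = TRUE) {
  if (articulated) ACT_ARTICULATED else ACT_UNARTICULATED
}

dir_index <- function(obj, v) {
  for (d in 1:6) if (all(obj$dirs[d, ] == v)) return(d)
  stop("not an axis direction")
}
opp_dir <- function(d) d + ifelse(d %% 2L == 1L, 1L, -1L)

# direction 90 degrees counterclockwise from dv about the outward normal
ccw_dir <- function(obj, cell, d) {
  n <- obj$normals[cell, ]; dv <- obj$dirs[d, ]
  dir_index(obj, c(n[2] * dv[3] - n[3] * dv[2],
                   n[3] * dv[1] - n[1] * dv[3],
                   n[1] * dv[2] - n[2] * dv[1]))
}

straight_config <- function(obj, cell, d) {
  if (is.na(obj$nb_face[cell, d])) "over" else "on"
}

new_hand_state <- function(cell, dir, config, articulated = TRUE) {
  structure(list(cell = cell, dir = dir, config = config,
                 articulated = articulated),
            class = "hand_state")
}

#' @export
print.hand_state <- function(x, ...) {
  cat(sprintf("<hand_state cell=%d dir=%d config=%s%s>\n", x$cell, x$dir,
              x$config, if (x$articulated) "" else " (unarticulated)"))
  invisible(x)
}

#' Place the hand at a start cell
#'
#' The finger starts straight; it is `on` the surface if the cell ahead of
#' the palm exists on the same face, otherwise it extends `over` the edge.
#'
#' @param obj a [build_cuboid()] object.
#' @param start either a cell index or a `c(face, x, y)` triple.
#' @param heading one of `"N"`, `"E"`, `"S"`, `"W"` in the start face's local
#'   frame (`"N"` points toward increasing `y`).
#' @param articulated use the articulated hand (default) or the degenerate
#'   unarticulated mode.
#' @return a `hand_state`.
#' @export
hand_reset <- function(obj, start = c(1, 1, 1), heading = "N", articulated = TRUE) {
  stopifnot(inherits(obj, "cuboid"))
  cell <- if (length(start) == 3) cell_index(obj, start[1], start[2], start[3]) else {
    if (!start %in% seq_len(obj$p)) stop("invalid start cell", call. = FALSE)
    as.integer(start)
  }
  f <- obj$cells$face[cell]
  dv <- switch(match.arg(heading, c("N", "E", "S", "W")),
               N = obj$face_v[f, ], E = obj$face_u[f, ],
               S = -obj$face_v[f, ], W = -obj$face_u[f, ])
  d <- dir_index(obj, dv)
  cfg <- if (articulated) straight_config(obj, cell, d) else "none"
  new_hand_state(cell, d, cfg, articulated)
}

#' Attempt an action
#'
#' Infeasible actions are a signalled outcome, not an error: the exploration
#' architecture learns from failed attempts.  On failure the state is
#' returned unchanged with `success = FALSE`.
#'
#' @param obj a [build_cuboid()] object.
#' @param state a `hand_state`.
#' @param action an action name from [hand_actions()].
#' @return list with elements `state` (new or unchanged) and `success`.
#' @export
apply_action <- function(obj, state, action) {
  stopifnot(inherits(obj, "cuboid"), inherits(state, "hand_state"))
  if (!state$articulated) return(apply_action_unart(obj, state, action))
  if (!action %in% ACT_ARTICULATED) stop("unknown action", call. = FALSE)
  cell <- state$cell; d <- state$dir; cfg <- state$config
  fail <- list(state = state, success = FALSE)
  ok <- function(cell2, d2, cfg2) {
    list(state = new_hand_state(cell2, d2, cfg2), success = TRUE)
  }
  switch(action,
    fwd_on = ,
    fwd_over = {
      if (cfg != "on") return(fail)
      tgt <- obj$nb_face[cell, d]            # exists because cfg == "on"
      cfg2 <- straight_config(obj, tgt, d)
      want <- if (action == "fwd_on") "on" else "over"
      if (cfg2 != want) return(fail)
      ok(tgt, d, cfg2)
    },
    back_on = ,
    back_over = {
      want <- if (action == "back_on") "on" else "over"
      if (cfg != want) return(fail)
      tgt <- obj$nb_face[cell, opp_dir(d)]
      if (is.na(tgt)) return(fail)
      ok(tgt, d, straight_config(obj, tgt, d))  # always "on": the old palm cell is ahead
    },
    left = ,
    right = {
      if (cfg == "bent") return(fail)
      ld <- ccw_dir(obj, cell, d)
      if (action == "right") ld <- opp_dir(ld)
      tgt <- obj$nb_face[cell, ld]
      if (is.na(tgt)) return(fail)
      ok(tgt, d, straight_config(obj, tgt, d))
    },
    rot_ccw = ,
    rot_cw = {
      if (cfg == "bent") return(fail)
      d2 <- ccw_dir(obj, cell, d)
      if (action == "rot_cw") d2 <- opp_dir(d2)
      ok(cell, d2, straight_config(obj, cell, d2))
    },
    bend = {
      if (cfg != "over") return(fail)
      if (is.na(obj$nb_cross[cell, d])) return(fail)  # unreachable on a convex cuboid
      ok(cell, d, "bent")
    },
    unbend = {
      if (cfg != "bent") return(fail)
      tgt <- obj$nb_cross[cell, d]
      d2 <- dir_index(obj, -obj$normals[cell, ])  # travel continues over the edge
      ok(tgt, d2, straight_config(obj, tgt, d2))
    }
  )
}

apply_action_unart <- function(obj, state, action) {
  if (!action %in% ACT_UNARTICULATED) stop("unknown action", call. = FALSE)
  cell <- state$cell; d <- state$dir
  ok <- function(cell2, d2) {
    list(state = new_hand_state(cell2, d2, "none", articulated = FALSE),
         success = TRUE)
  }
  translate <- function(travel, keep_heading) {
    tgt <- obj$nb_face[cell, travel]
    if (!is.na(tgt)) return(ok(tgt, d))
    tgt <- obj$nb_cross[cell, travel]
    t2 <- dir_index(obj, -obj$normals[cell, ])  # travel wraps over the edge
    d2 <- if (keep_heading) d else if (travel == d) t2 else opp_dir(t2)
    ok(tgt, d2)
  }
  switch(action,
    fwd = translate(d, keep_heading = FALSE),
    back = translate(opp_dir(d), keep_heading = FALSE),
    left = translate(ccw_dir(obj, cell, d), keep_heading = TRUE),
    right = translate(opp_dir(ccw_dir(obj, cell, d)), keep_heading = TRUE),
    rot_ccw = ok(cell, ccw_dir(obj, cell, d)),
    rot_cw = ok(cell, opp_dir(ccw_dir(obj, cell, d)))
  )
}

#' Feasible actions from a state
#'
#' @inheritParams apply_action
#' @return character vector of the actions whose attempt would succeed;
#'   never empty for a reachable state.
#' @export
feasible_actions <- function(obj, state) {
  acts <- hand_actions(state$articulated)
  acts[vapply(acts, function(a) apply_action(obj, state, a)$success, logical(1))]
}

#' Percept vector after a successful action
#'
#' The egocentric sensory vector fed to the MSOM: a 10-wide one-hot slip
#' signature identifying the executed action, one Boolean for the hand shape
#' (straight = 0 / bent = 1), Booleans for finger and palm contact, and an
#' `L`-wide one-hot of the tactile landmark under the palm (all zero off
#' landmarks).  Total width `13 + L`.
#'
#' @param obj a [build_cuboid()] object.
#' @param state the hand state *after* the action.
#' @param action the executed action.
#' @return numeric vector of width `13 + obj$n_landmarks`.
#' @export
hand_percept <- function(obj, state, action) {
  L <- obj$n_landmarks
  x <- numeric(13 + L)
  slot <- if (state$articulated) match(action, ACT_ARTICULATED) else
    SLIP_SLOT_UNART[[action]]
  x[slot] <- 1
  x[11] <- as.numeric(identical(state$config, "bent"))
  x[12] <- as.numeric(state$config %in% c("on", "bent"))
  x[13] <- 1  # palm contact: the hand always stays on the object
  lm <- obj$landmarks[state$cell]
  if (lm > 0) x[13 + lm] <- 1
  x
}

#' Enumerate the hand-state graph
#'
#' Enumerates every hand state on the object (palm cell x tangent heading,
#' plus the bent states where bending is possible) and tabulates the outcome
#' of every action from every state.  This table drives the fast exploration
#' loop and the breadth-first shortest-action-path oracle.
#'
#' @param obj a [build_cuboid()] object.
#' @param articulated articulated (default) or unarticulated repertoire.
#' @return list with `states` (tibble: `id`, `cell`, `dir`, `config`),
#'   `trans` (integer matrix states x actions, 0 = infeasible, else the id of
#'   the successor state), `actions`, and `feats` (percept state features,
#'   `(3 + L) x n_states`).
#' @export
state_graph <- function(obj, articulated = TRUE) {
  stopifnot(inherits(obj, "cuboid"))
  acts <- hand_actions(articulated)
  states <- list(); k <- 0L
  for (cell in seq_len(obj$p)) {
    tangent <- which(as.vector(obj$normals[cell, ] %*% t(obj$dirs)) == 0)
    for (d in tangent) {
      if (articulated) {
        cfg <- straight_config(obj, cell, d)
        k <- k + 1L; states[[k]] <- c(cell, d, match(cfg, c("on", "over", "bent")))
        if (cfg == "over") {            # bent state exists exactly where bending can
          k <- k + 1L; states[[k]] <- c(cell, d, 3L)
        }
      } else {
        k <- k + 1L; states[[k]] <- c(cell, d, 4L)
      }
    }
  }
  sm <- do.call(rbind, states)
  cfg_names <- c("on", "over", "bent", "none")
  key <- function(cell, d, cfg_i) paste(cell, d, cfg_i)
  id_of <- stats::setNames(seq_len(nrow(sm)), key(sm[, 1], sm[, 2], sm[, 3]))
  trans <- matrix(0L, nrow(sm), length(acts))
  for (s in seq_len(nrow(sm))) {
    st <- new_hand_state(sm[s, 1], sm[s, 2], cfg_names[sm[s, 3]], articulated)
    for (a in seq_along(acts)) {
      res <- apply_action(obj, st, acts[a])
      if (res$success) {
        s2 <- res$state
        trans[s, a] <- id_of[[key(s2$cell, s2$dir,
                                  match(s2$config, cfg_names))]]
      }
    }
  }
  L <- obj$n_landmarks
  feats <- matrix(0, 3 + L, nrow(sm))
  for (s in seq_len(nrow(sm))) {
    cfg <- cfg_names[sm[s, 3]]
    feats[1, s] <- as.numeric(cfg == "bent")
    feats[2, s] <- as.numeric(cfg %in% c("on", "bent"))
    feats[3, s] <- 1
    lm <- obj$landmarks[sm[s, 1]]
    if (lm > 0) feats[3 + lm, s] <- 1
  }
  list(
    states = tibble::tibble(id = seq_len(nrow(sm)), cell = sm[, 1],
                            dir = sm[, 2], config = cfg_names[sm[, 3]]),
    trans = trans,
    actions = acts,
    feats = feats,
    articulated = articulated
  )
}

state_id <- function(sg, state) {
  cfg_i <- match(state$config, c("on", "over", "bent", "none"))
  i <- which(sg$states$cell == state$cell & sg$states$dir == state$dir &
               sg$states$config == c("on", "over", "bent", "none")[cfg_i])
  if (length(i) != 1) stop("state not in graph", call. = FALSE)
  i
}

#' Shortest feasible action sequence to a goal cell
#'
#' Breadth-first search over the hand-state graph: the minimum number of
#' successful actions needed to move the palm from a start state to the goal
#' cell (any heading and finger situation).  This is the hard lower bound on
#' the per-epoch step count of any goal-directed policy.
#'
#' @param obj a [build_cuboid()] object.
#' @param start a `hand_state` (e.g. from [hand_reset()]).
#' @param goal_cell target palm cell index.
#' @param sg optionally a precomputed [state_graph()].
#' @return integer path length (number of actions); `Inf` if unreachable.
#' @export
shortest_action_path <- function(obj, start, goal_cell, sg = NULL) {
  if (is.null(sg)) sg <- state_graph(obj, start$articulated)
  s0 <- state_id(sg, start)
  if (sg$states$cell[s0] == goal_cell) return(0L)
  dist <- rep(NA_integer_, nrow(sg$states))
  dist[s0] <- 0L
  frontier <- s0
  while (length(frontier) > 0) {
    nxt <- unique(as.vector(sg$trans[frontier, ]))
    nxt <- nxt[nxt > 0]
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- dist[frontier[1]] + 1L
    hit <- nxt[sg$states$cell[nxt] == goal_cell]
    if (length(hit) > 0) return(dist[hit[1]])
    frontier <- nxt
  }
  Inf
}
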